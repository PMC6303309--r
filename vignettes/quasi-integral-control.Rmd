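---
title: "Quasi-integral control of a transcriptional device by sRNA-mediated silencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quasi-integral control of a transcriptional device by sRNA-mediated silencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnaqic)
```

## The problem and the model

A transcriptional (TX) device characterized in isolation can lose a large
fraction of its output the moment another device is switched on, because
both translate from a shared, finite ribosome pool. `srnaqic` models a
device that adapts to such disturbances through a post-transcriptional
feedback loop: the device mRNA is a bicistronic operon coding the output
protein (GFP) and an ECF sigma-factor sensor; the sensor drives
transcription of a small RNA that base-pairs with the very mRNA it came
from, and the duplex is degraded quickly (coupled decay at rate
$\lambda m_1 s_1/\beta$).

The reduced closed-loop model is three ODEs in the mRNA $m_1$, sRNA $s_1$
and output protein $y_1$:

$$\dot m_1 = T D H(u_1) - \lambda m_1 s_1/\beta - \delta m_1, \qquad
  \dot s_1 = k T_s y_1 - \lambda m_1 s_1/\beta - \delta s_1, \qquad
  \dot y_1 = R(1-d)\,m_1/\kappa_{GFP} - \gamma y_1.$$

The exogenous disturbance $0 \le d < 1$ is the fold drop in free-ribosome
availability; $d = 0$ means an untouched pool and $d \to 1$ means almost no
free ribosomes. The reduction relies on two assumptions: (A) both proteins
decay with the same rate constant $\gamma$ (dilution-dominated, so this is
mild), and (B) the experiment starts from steady-state expression. Under
(A)+(B) the sensor protein is slaved to the output, $p_1 = k\,y_1$, with
$k = \kappa_{GFP}/\kappa_{ECF}$ the feedback gain — the ratio of the two
RBS dissociation constants on the shared transcript. The `full` model
variant keeps $p_1$ explicit and is used in the tests to confirm the
reduction: started on the manifold $p_1(0) = k y_1(0)$, the two models'
trajectories coincide because $p_1 - k y_1$ obeys a homogeneous decay and
stays at zero.

Subtracting the sRNA balance from the mRNA balance eliminates the coupled
term and exposes the antithetic integral structure. The memory variable
$z = m_1 - s_1$ obeys

$$\dot z = k T_s\, e - \delta z, \qquad
  e = \frac{T D H(u_1)}{k T_s} - y_1 .$$

With $\delta = 0$ this is exact integral control: at any stable steady
state $y_1^\ast = T D H(u_1)/(k T_s)$, independent of $d$ — perfect
adaptation (the `ideal` variant). With $\delta > 0$ the integrator leaks,
and at equilibrium $e_{ss} = \delta z_{ss}/(k T_s)$: the adaptation error
is proportional to the decayed memory. The leak becomes negligible when all
controller reactions outrun RNA decay:

* (I) $\delta/\lambda \ll 1$ — coupled degradation much faster than RNase
  decay; essentially free in practice,
* (II) $\delta/T \ll 1$ — a reasonably strong device promoter,
* (III) $\delta/(k T_s) \ll 1$ — fast error amplification; the designable
  knob, reached by raising the sensor-RBS strength and hence $k$.

`qic_check()` reports the three raw ratios and flags them at a threshold
$\varepsilon$. "Much less than one" is not a quantity; we quantify it as
$\varepsilon = 0.1$ by default and always carry the raw ratios so a
stricter cutoff costs nothing.

## Parameters, units and the fixture library

All shipped numbers use hours and nM-like arbitrary concentration units.
The twelve `device_fixture()` sets (2 promoters × 3 gains ×
regulated/unregulated) encode:

| parameter | default | rationale |
|---|---|---|
| $\delta$ | 8 /h | ~5 min RNA half-life |
| $\gamma$ | 1.4 /h | dilution-dominated protein loss, ~30 min doubling |
| $\lambda$, $\beta$ | 2000 /h, 1 nM | coupled decay fast (condition I ratio 0.004); only $\lambda/\beta$ enters the dynamics, both kept for traceability |
| $T$ | 300 (stronger) / 100 (weaker) nM/h per copy | condition II holds for both (0.027 / 0.08) |
| $D$ | 10 | medium-copy plasmid |
| $\kappa_{GFP}$ | 100 nM | fixed output RBS |
| $T_s$ | 50 /h | moderate sensor-promoter activity |
| $R$ | 1000 nM/h | ribosome-proportional translation capacity |
| $k$ | 0.580 / 1.157 / 6.647 | sensor-RBS TIRs 565, 1127, 6474 against the output RBS TIR 974 |

The gains come from reported translation-initiation rates under the
convention $TIR \propto 1/\kappa$ with unit proportionality; only the TIR
ratio matters, so the unknown proportionality constant cancels. With these
values condition (III) passes only for the high gain
($\delta/(kT_s) = 0.28, 0.14, 0.024$ for low/medium/high) — by
construction of the library, robustness improves with gain, and the
low-gain device sits outside the quasi-integral regime.

These fixtures are *representative*, not a reproduction of any fitted
parameter table: they emulate the ordering of time scales (fast coupled
decay, fast transcription, RNA decay well above protein dilution) and the
relative gain ladder of the experimental library. They do not emulate
absolute expression levels, growth-rate feedback on $\gamma$, transcription
noise, or the dose-to-disturbance calibration of a real competitor — so a
passing test suite certifies the controller mathematics and the numerics,
not quantitative agreement with any particular strain.

## Numerical choices

* **Integration.** `deSolve::lsoda` with `rtol = 1e-8`, `atol = 1e-10`;
  the method auto-switches to stiff BDF, which these equations need when
  $\lambda m_1 s_1/\beta$ is fast. Piecewise-constant disturbances are
  handled by restarting the integrator at each breakpoint rather than by
  event detection — bit-reproducible and solver-agnostic; each segment is
  reported on 500 evenly spaced points by default. The breakpoint sample
  itself carries the *new* disturbance value (half-open intervals
  $[t_i, t_{i+1})$).
* **Steady states.** The three-state fixed point reduces exactly to one
  scalar equation in $m_1$: subtracting the two RNA balances gives
  $s = m - (TDH - kT_s y(m))/\delta$ with $y(m)$ linear in $m$. The root is
  bracketed on $(0, TDH/\delta]$ — the upper end is the sRNA-free
  (unregulated) mRNA level, at which the residual is $\le 0$ — and found by
  `stats::uniroot`. Local stability is verified from the analytic Jacobian's
  eigenvalues; `validate = TRUE` additionally cross-checks against the
  endpoint of an integration over $50/\min(\delta,\gamma)$ at $10^{-6}$
  relative tolerance. A regulated request with $\delta = 0$ is routed to the
  ideal closed form (the bracket is unbounded there).
* **Degenerate inputs.** $TDH = 0$ returns the all-zero state; an
  unregulated device with $\delta = 0$ has no bounded steady state and
  errors; the saturating-actuator ideal limit errors when the actuator
  ceiling $T_s K$ cannot match the transcription load.
* **Settling time.** First time after which the output stays within 2% of
  its final steady state — the standard control-engineering band,
  configurable via `settle_frac`.
* **Saturating actuator.** Optionally the sRNA production saturates in the
  sensor protein, $T_s p_1/(1 + p_1/K)$, normalized so the linear law is
  recovered as $K \to \infty$; default is the linear actuator. Equal decay
  $\delta$ for mRNA and sRNA is assumed throughout; unequal decay is out of
  scope.

## Performance metrics and their edges

`robustness()` is the perturbed steady-state output as a percentage of the
nominal one; the unregulated closed form makes it exactly $(1-d)\cdot100\%$,
and the ideal limit exactly 100%. `adaptation_error()` is the relative
distance of the leaky loop's output from the ideal set point.

One genuine model feature deserves emphasis: robustness is *not* globally
monotone in the gain. As $k$ grows at fixed $T_s$, the set point
$TDH/(kT_s)$ falls toward the floor set by the residual coupled-decay
balance, $y_{floor} \approx \delta\beta R(1-d)/(\lambda\gamma\kappa_{GFP})$,
which is itself proportional to $(1-d)$ — so at extreme gain robustness
slowly reverts toward the unregulated value. Across the experimentally
motivated gain span (roughly $k \in [0.1, 5]$ for the shipped fixtures)
robustness increases strictly with gain and the relative adaptation error
decreases strictly along a tenfold gain grid; the property tests assert
exactly that range, and the empirical envelope
$error < 5\,\delta/(kT_s)$ at the top of the grid is a documented
observation on these fixtures, not a theorem.

`silencing_dose_response()` reproduces the open-loop control experiment:
sRNA production is driven by an induced sensor level
$p_{sens} = sensor_{max}\,f(dose)$ (Hill induction with optional basal
leak, `sensor_max` defaulting to 100 nM, comparable to the closed-loop
sensor level of the fixtures) instead of by the output. The dose response
is monotone non-increasing, from the unsilenced closed form
$RTD/(\delta\gamma\kappa_{GFP})$ at zero induction toward the coupled-decay
floor at saturating induction. No fitted induction constants are claimed.

`competitor_to_disturbance()` is a labeled convenience that maps an
inducer concentration onto $d$ through a saturating Hill function; the
model itself treats $d$ as exogenous.

## Problem sizes in the shipped tests

The test suite exercises trajectories of 3–4 states on 100–500-point output
grids over horizons of a few protein lifetimes, randomized
steady-state-versus-integration cross-checks on 50 log-uniform parameter
sets, and 20-point gain sweeps — sizes chosen so any single property runs
in seconds while still probing the stiff regime.

## Known limitations

* Deterministic mass-action kinetics only: no stochastic chemical kinetics
  or cell-to-cell variability.
* The ribosome pool is not modeled mechanistically; $d$ is an exogenous
  input, so competitor loading on the pool by the regulated device itself
  is outside the model.
* The controller is post-transcriptional: perturbations entering at
  transcription (plasmid copy number, promoter activity) are not attenuated,
  by design.
* Host growth-rate feedback on dilution ($\gamma$ responding to burden) is
  not represented.
* The leaky-integrator identity used by `memory_residual()` holds for the
  linear actuator only; with actuator saturation the memory dynamics gain a
  state-dependent production term.
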