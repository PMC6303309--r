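# Controller-performance metrics and design diagnostics.

#' Robustness of a device to ribosome competition
#'
#' Robustness is the steady-state output under the active disturbance as a
#' percentage of the nominal output (disturbance off):
#' \deqn{Robustness = \frac{y_1^*(d = d_{active})}{y_1^*(d = 0)} \times 100\%.}
#' A perfectly modular device scores 100%; the unregulated device scores
#' exactly `(1 - d) * 100`%.
#'
#' @inheritParams steady_state
#' @param d_active Disturbance of the perturbed condition, `0 <= d < 1`.
#' @return A list of class `"robustness_result"` with `nominal_output`,
#'   `perturbed_output` and `robustness` (percent).
#' @examples
#' p <- device_params(T_rate = 1, D = 1, kappa_gfp = 1, k = 1, Ts = 0,
#'                    delta = 1, lam = 1, beta = 1, R = 1, gamma = 1)
#' robustness(p, variant = "unregulated", d_active = 0.5)$robustness  # 50
#' @export
robustness <- function(params, variant = "regulated", d_active = 0.5, u1 = 1) {
  check_d(d_active)
  nominal <- steady_state(params, d = 0, u1 = u1, variant = variant)[["y1"]]
  if (nominal <= 0) {
    stop("robustness is undefined: nominal output is zero", call. = FALSE)
  }
  perturbed <- steady_state(params, d = d_active, u1 = u1,
                            variant = variant)[["y1"]]
  structure(list(nominal_output = nominal,
                 perturbed_output = perturbed,
                 robustness = perturbed / nominal * 100,
                 d_active = d_active, variant = variant),
            class = "robustness_result")
}

#' @export
print.robustness_result <- function(x, ...) {
  cat(sprintf("Robustness (%s device, d = %g): %.4g%%\n",
              x$variant, x$d_active, x$robustness))
  cat(sprintf("  nominal output   %.6g\n  perturbed output %.6g\n",
              x$nominal_output, x$perturbed_output))
  invisible(x)
}

#' Quasi-integral control design conditions
#'
#' The leaky antithetic integrator approximates ideal integral control when
#' all controller reactions are much faster than uncoupled-RNA decay:
#' (I) coupled degradation, `delta/lam << 1`; (II) mRNA transcription,
#' `delta/T << 1`; (III) error amplification, `delta/(k*Ts) << 1`.
#' Each ratio is compared against the threshold `epsilon` ("much less than
#' one" quantified, default 0.1); the raw ratios are always reported so a
#' stricter cutoff can be applied downstream.
#'
#' @inheritParams steady_state
#' @param epsilon Pass threshold for each ratio (default 0.1).
#' @return A list of class `"qic_report"` with the three ratios (`r_lambda`,
#'   `r_T`, `r_gain`), per-condition flags and the overall pass flag.
#' @export
qic_check <- function(params, epsilon = 0.1) {
  stopifnot(inherits(params, "device_params"))
  p <- params
  if (p$lam <= 0 || p$T_rate <= 0 || p$k * p$Ts <= 0) {
    stop("qic_check(): lam, T and k*Ts must all be > 0", call. = FALSE)
  }
  ratios <- c(r_lambda = p$delta / p$lam,
              r_T = p$delta / p$T_rate,
              r_gain = p$delta / (p$k * p$Ts))
  flags <- ratios < epsilon
  structure(list(r_lambda = ratios[["r_lambda"]],
                 r_T = ratios[["r_T"]],
                 r_gain = ratios[["r_gain"]],
                 threshold = epsilon,
                 pass_lambda = flags[["r_lambda"]],
                 pass_T = flags[["r_T"]],
                 pass_gain = flags[["r_gain"]],
                 pass = all(flags)),
            class = "qic_report")
}

#' @export
print.qic_report <- function(x, ...) {
  cat(sprintf("Quasi-integral control conditions (threshold %g)\n",
              x$threshold))
  fmt <- function(lbl, r, ok) {
    cat(sprintf("  %-28s %.4g  [%s]\n", lbl, r, if (ok) "pass" else "FAIL"))
  }
  fmt("(I)   delta / lambda", x$r_lambda, x$pass_lambda)
  fmt("(II)  delta / T", x$r_T, x$pass_T)
  fmt("(III) delta / (k Ts)", x$r_gain, x$pass_gain)
  cat(sprintf("  overall: %s\n", if (x$pass) "quasi-integral regime"
              else "outside quasi-integral regime"))
  invisible(x)
}

#' Serialize a QIC report to JSON
#' @param report A [qic_check()] report.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_qic_report <- function(report, path) {
  stopifnot(inherits(report, "qic_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Integrator-leakiness residual of a regulated trajectory
#'
#' Along any trajectory of the regulated reduced model, the memory variable
#' `z = m1 - s1` obeys the leaky-integrator equation
#' `dz/dt = k*Ts*e - delta*z` with tracking error
#' `e = T*D*H(u1)/(k*Ts) - y1` — an exact algebraic consequence of
#' subtracting the sRNA balance from the mRNA balance. This function
#' evaluates `dz/dt` from the model right-hand side at every stored state and
#' returns the worst-case absolute residual against the leaky-integrator
#' form. It should be at numerical round-off; a large value indicates an
#' implementation inconsistency, not a model property.
#'
#' @param traj A [simulate_device()] trajectory of the `regulated` or `ideal`
#'   variant (linear actuator).
#' @return Max over time of `|dz/dt - (k*Ts*e - delta*z)|`.
#' @export
memory_residual <- function(traj) {
  stopifnot(inherits(traj, "circuit_trajectory"))
  variant <- attr(traj, "variant")
  if (!variant %in% c("regulated", "ideal")) {
    stop("memory_residual() applies to the regulated reduced model only",
         call. = FALSE)
  }
  p <- attr(traj, "params")
  if (!is.null(p$actuator_saturation)) {
    stop("memory_residual(): the leaky-integrator identity assumes a linear actuator",
         call. = FALSE)
  }
  u1 <- attr(traj, "u1")
  kTs <- p$k * p$Ts
  res <- vapply(seq_len(nrow(traj)), function(i) {
    st <- c(m1 = traj$m1[i], s1 = traj$s1[i], y1 = traj$y1[i])
    dstate <- rhs_regulated(pmax(st, 0), p, d = traj$d[i], u1 = u1)
    dz <- dstate[["m1"]] - dstate[["s1"]]
    abs(dz - (kTs * traj$e[i] - p$delta * traj$z[i]))
  }, numeric(1))
  max(res)
}

#' Relative steady-state adaptation error
#'
#' Distance of the leaky (`delta > 0`) regulated loop's steady-state output
#' from the ideal-integral set point `y_ideal = T*D*H(u1)/(k*Ts)`:
#' `|y1* - y_ideal| / y_ideal`. Zero in the ideal limit; shrinks as the gain
#' grows (condition III).
#'
#' @inheritParams steady_state
#' @return Nonnegative scalar relative error.
#' @export
adaptation_error <- function(params, d = 0, u1 = 1) {
  stopifnot(inherits(params, "device_params"))
  p <- params
  if (p$k * p$Ts <= 0) {
    stop("adaptation_error() needs an active feedback loop (k*Ts > 0)",
         call. = FALSE)
  }
  y_ideal <- p$T_rate * p$D * p$regulation(u1) / (p$k * p$Ts)
  if (y_ideal <= 0) stop("ideal set point is zero; error undefined",
                         call. = FALSE)
  y <- steady_state(p, d = d, u1 = u1, variant = "regulated")[["y1"]]
  abs(y - y_ideal) / y_ideal
}

#' Parameter sweeps of steady-state output and robustness
#'
#' Sweeps one axis and records the steady state and robustness at each value:
#' * `"gain"` — the feedback gain `k` is varied by changing the sensor RBS
#'   dissociation constant `kappa_ecf` with `kappa_gfp` held fixed, mirroring
#'   the experimental tuning knob; robustness is evaluated at `d_active`.
#' * `"disturbance"` — the values are disturbances `d`; robustness at each
#'   `d` is relative to `d = 0`.
#' * `"input"` — the values are inputs `u1`; robustness at `d_active`.
#'
#' @inheritParams robustness
#' @param axis `"gain"`, `"disturbance"` or `"input"`.
#' @param values Axis values (gains > 0, disturbances in `[0,1)`, or inputs
#'   >= 0).
#' @return A data frame of class `"sweep_result"` with columns `axis_value`,
#'   `m1`, `s1`, `y1`, `robustness_pct`.
#' @export
sweep_device <- function(params, variant = "regulated",
                         axis = c("gain", "disturbance", "input"),
                         values, d_active = 0.5, u1 = 1) {
  stopifnot(inherits(params, "device_params"))
  axis <- match.arg(axis)
  variant <- check_variant(variant)
  rows <- lapply(values, function(v) {
    res <- tryCatch({
      switch(axis,
        gain = {
          pv <- update_params(params, k = v)
          ss <- steady_state(pv, d = d_active, u1 = u1, variant = variant)
          rb <- robustness(pv, variant = variant, d_active = d_active,
                           u1 = u1)$robustness
          c(ss["m1"], s1 = if ("s1" %in% names(ss)) ss[["s1"]] else 0,
            ss["y1"], robustness_pct = rb)
        },
        disturbance = {
          ss <- steady_state(params, d = v, u1 = u1, variant = variant)
          rb <- robustness(params, variant = variant, d_active = v,
                           u1 = u1)$robustness
          c(ss["m1"], s1 = if ("s1" %in% names(ss)) ss[["s1"]] else 0,
            ss["y1"], robustness_pct = rb)
        },
        input = {
          ss <- steady_state(params, d = d_active, u1 = v, variant = variant)
          rb <- robustness(params, variant = variant, d_active = d_active,
                           u1 = v)$robustness
          c(ss["m1"], s1 = if ("s1" %in% names(ss)) ss[["s1"]] else 0,
            ss["y1"], robustness_pct = rb)
        })
    }, error = function(e) {
      stop(sprintf("sweep failed at %s = %g: %s", axis, v,
                   conditionMessage(e)), call. = FALSE)
    })
    res
  })
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(axis_value = as.numeric(values), out)
  structure(out, class = c("sweep_result", "data.frame"),
            axis = axis, variant = variant, d_active = d_active)
}

#' Write a sweep or dose-response table to tidy CSV
#' @param x A [sweep_device()] or [silencing_dose_response()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Map competitor induction to a ribosome disturbance
#'
#' Convenience Hill mapping from an inducer concentration (e.g. AHL driving a
#' resource competitor) onto the model's exogenous disturbance:
#' `d = d_max * inducer^n / (K_half^n + inducer^n)`. The mapping is monotone
#' and saturates at `d_max < 1`; it is a labeled convention, not a fitted
#' relation.
#'
#' @param inducer Inducer concentration(s), >= 0.
#' @param d_max Saturating disturbance, `0 <= d_max < 1`.
#' @param K_half Half-maximal inducer concentration, > 0.
#' @param hill_n Hill coefficient, > 0.
#' @return Disturbance value(s) in `[0, d_max]`.
#' @export
competitor_to_disturbance <- function(inducer, d_max, K_half, hill_n = 1) {
  if (d_max >= 1 || d_max < 0) {
    stop("competitor_to_disturbance(): need 0 <= d_max < 1", call. = FALSE)
  }
  stopifnot(K_half > 0, hill_n > 0, all(inducer >= 0))
  d_max * inducer^hill_n / (K_half^hill_n + inducer^hill_n)
}

#' Open-loop sRNA silencing dose response
#'
#' Models the control experiment that validates the silencing arm with the
#' feedback loop open: the target mRNA is transcribed constitutively while
#' sRNA production is driven by an externally induced sensor level rather
#' than by the output protein. Per dose the steady state of
#' \deqn{dm/dt = T D - \lambda m s/\beta - \delta m, \quad
#'       ds/dt = T_s p_{sens}(dose) - \lambda m s/\beta - \delta s, \quad
#'       dy/dt = R m/\kappa_{GFP} - \gamma y}
#' is solved, where the induced sensor concentration follows a Hill law with
#' optional basal leak,
#' `p_sens(dose) = sensor_max * (basal + (1 - basal) * dose^n/(K^n + dose^n))`.
#' Output is monotone non-increasing in the dose: high induction silences the
#' gene.
#'
#' @inheritParams steady_state
#' @param doses Inducer concentrations, >= 0.
#' @param K_half Half-maximal induction dose, > 0.
#' @param hill_n Hill coefficient of induction, > 0.
#' @param basal Basal (leaky) induction fraction in `[0, 1)`.
#' @param sensor_max Fully induced sensor-protein concentration (default 100,
#'   comparable to the closed-loop sensor level of the shipped fixtures);
#'   sets the scale of sRNA production at saturation.
#' @return A data frame of class `"silencing_result"`: `dose`, `induction`
#'   (the value of `f`), `m1`, `s1`, `y1`.
#' @export
silencing_dose_response <- function(params, doses, K_half, hill_n = 1,
                                    basal = 0, sensor_max = 100, u1 = 1) {
  stopifnot(inherits(params, "device_params"))
  stopifnot(all(doses >= 0), K_half > 0, hill_n > 0,
            basal >= 0, basal < 1, sensor_max > 0)
  p <- params
  if (p$delta <= 0) {
    stop("silencing_dose_response() requires delta > 0", call. = FALSE)
  }
  TDH <- p$T_rate * p$D * p$regulation(u1)
  f <- basal + (1 - basal) * doses^hill_n / (K_half^hill_n + doses^hill_n)
  rows <- lapply(seq_along(doses), function(i) {
    prod_s <- srna_production(p, sensor_max * f[i])
    ss <- solve_coupled_ss(p, prod_m = TDH,
                           prod_s_fun = function(y) prod_s, d = 0)
    c(dose = doses[i], induction = f[i], ss)
  })
  out <- as.data.frame(do.call(rbind, rows))
  structure(out, class = c("silencing_result", "data.frame"))
}
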