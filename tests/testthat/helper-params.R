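# Shared parameter constructors for the test suite.

# All-ones parameter set: makes the RHS arithmetic checkable by hand.
unit_params <- function(...) {
  p <- device_params(T_rate = 1, D = 1, kappa_gfp = 1, k = 1, Ts = 1,
                     delta = 1, lam = 1, beta = 1, R = 1, gamma = 1)
  if (...length() > 0L) p <- update_params(p, ...)
  p
}

# One random device parameter set on log-uniform ranges spanning the
# physically sensible regime (delta > 0, stable closed loop in practice).
random_device_params <- function() {
  rl <- function(lo, hi) 10^stats::runif(1, lo, hi)
  device_params(T_rate = rl(0.5, 2.5), D = sample(1:20, 1),
                kappa_gfp = rl(0, 2.5), k = rl(-1, 1),
                Ts = rl(0, 2), delta = rl(-0.5, 1.2),
                lam = rl(2, 3.5), beta = rl(-0.5, 0.5),
                R = rl(2, 3.5), gamma = rl(-0.5, 0.5))
}
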