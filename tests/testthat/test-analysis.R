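test_that("robustness is the perturbed/nominal percentage", {
  p <- device_fixture("strong-high-unregulated")
  r <- robustness(p, variant = "unregulated", d_active = 0.5)
  expect_equal(r$robustness, 50)
  expect_equal(r$perturbed_output / r$nominal_output * 100, r$robustness)
  # no disturbance -> identical outputs -> 100%
  expect_equal(robustness(p, "unregulated", d_active = 0)$robustness, 100)
  # unregulated robustness equals (1-d)*100 to 1e-9 relative
  for (d in seq(0.1, 0.9, by = 0.2)) {
    expect_equal(robustness(p, "unregulated", d)$robustness, (1 - d) * 100,
                 tolerance = 1e-9)
  }
  expect_error(robustness(update_params(p, T_rate = 0), "unregulated", 0.5),
               "nominal output is zero")
})

test_that("QIC condition ratios and flags follow the definitions", {
  mk <- function(delta, lam, T_rate, k, Ts) {
    unit_params(delta = delta, lam = lam, T_rate = T_rate, k = k, Ts = Ts)
  }
  r <- qic_check(mk(1, 100, 100, 10, 10))
  expect_equal(c(r$r_lambda, r$r_T, r$r_gain), c(0.01, 0.01, 0.01))
  expect_true(r$pass)
  r2 <- qic_check(mk(1, 100, 100, 0.1, 1))
  expect_equal(r2$r_gain, 10)
  expect_false(r2$pass_gain)
  expect_false(r2$pass)
  expect_true(r2$pass_lambda && r2$pass_T)
  # ideal limit: all ratios zero, everything passes
  r3 <- qic_check(mk(0, 100, 100, 10, 10))
  expect_equal(c(r3$r_lambda, r3$r_T, r3$r_gain), c(0, 0, 0))
  expect_true(r3$pass)
  expect_error(qic_check(mk(1, 100, 100, 10, 0)), "must all be > 0")
  # stricter threshold flips a marginal condition
  expect_false(qic_check(mk(1, 100, 100, 10, 10),
                         epsilon = 0.005)$pass)
})

test_that("memory variable obeys the leaky-integrator identity", {
  p <- device_fixture("strong-medium-regulated")
  tr <- simulate_device(p, "regulated", step_disturbance(0.6),
                        t_span = c(-0.5, 2), n_grid = 150L)
  # scale: worst |dz/dt| along the trajectory
  dz <- vapply(seq_len(nrow(tr)), function(i) {
    d <- rhs_regulated(pmax(c(m1 = tr$m1[i], s1 = tr$s1[i], y1 = tr$y1[i]), 0),
                       p, d = tr$d[i])
    d[["m1"]] - d[["s1"]]
  }, numeric(1))
  expect_lt(memory_residual(tr), 1e-6 * max(abs(dz)))
  # misuse: unregulated trajectories have no memory identity
  tru <- simulate_device(device_fixture("strong-high-unregulated"),
                         "unregulated", 0, t_span = c(0, 1), n_grid = 10L)
  expect_error(memory_residual(tru), "regulated reduced model")
})

test_that("with delta = 0 the memory integrates the error exactly", {
  p <- device_fixture("strong-high-regulated", delta = 0)
  tr <- simulate_device(p, "ideal", step_disturbance(0.5),
                        t_span = c(0, 2), n_grid = 400L)
  kTs <- p$k * p$Ts
  # z(t) - z(0) = k*Ts * integral of e (trapezoid on the dense grid)
  intg <- cumsum(c(0, diff(tr$time) * (utils::head(tr$e, -1) +
                                         utils::tail(tr$e, -1)) / 2))
  expect_equal(tr$z - tr$z[1], kTs * intg,
               tolerance = 1e-4 * max(abs(tr$z)))
})

test_that("steady-state error identity e = delta*z/(k*Ts) holds at fixed points", {
  set.seed(11)
  for (i in 1:6) {
    p <- random_device_params()
    d <- stats::runif(1, 0, 0.8)
    ss <- steady_state(p, d = d)
    e_ss <- p$T_rate * p$D / (p$k * p$Ts) - ss[["y1"]]
    z_ss <- ss[["m1"]] - ss[["s1"]]
    expect_equal(e_ss, p$delta * z_ss / (p$k * p$Ts),
                 tolerance = 1e-8 * max(1, abs(e_ss)))
  }
})

test_that("adaptation error vanishes in the ideal limit and shrinks with gain", {
  p0 <- device_fixture("strong-high-regulated", delta = 0)
  for (d in c(0, 0.4, 0.8)) expect_equal(adaptation_error(p0, d), 0)
  p <- device_fixture("strong-low-regulated")
  ks <- p$k * 10^seq(0, 1, length.out = 6)  # tenfold span, low to high gain
  errs <- vapply(ks, function(k) {
    adaptation_error(update_params(p, k = k), d = 0.5)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  # deep QIC regime: error well below 1
  expect_lt(adaptation_error(device_fixture("strong-high-regulated"), 0), 0.05)
})

test_that("sweeps report steady states and robustness along each axis", {
  pu <- device_fixture("strong-high-unregulated")
  sw <- sweep_device(pu, "unregulated", axis = "disturbance",
                     values = seq(0, 0.9, by = 0.1))
  expect_equal(sw$y1, sw$y1[1] * (1 - sw$axis_value), tolerance = 1e-9)
  expect_equal(sw$robustness_pct, (1 - sw$axis_value) * 100,
               tolerance = 1e-9)

  p <- device_fixture("weak-low-regulated")
  # the experimentally accessible gain span; at extreme gain the output
  # approaches the coupled-decay floor and robustness levels off
  ks <- 10^seq(log10(0.1), log10(4), length.out = 20)
  swg <- sweep_device(p, "regulated", axis = "gain", values = ks,
                      d_active = 0.5)
  expect_true(all(diff(swg$robustness_pct) > 0))
  # in the quasi-integral regime the output scales as 1/k (y* ~ T*D/(k*Ts))
  hi <- swg$axis_value >= 2
  prod <- swg$y1[hi] * swg$axis_value[hi]
  expect_lt(diff(range(prod)) / mean(prod), 0.05)
})

test_that("competitor induction maps onto d through a saturating Hill", {
  expect_equal(competitor_to_disturbance(0, 0.6, 30), 0)
  expect_equal(competitor_to_disturbance(30, 0.6, 30), 0.3)
  expect_equal(competitor_to_disturbance(1e9, 0.6, 30), 0.6, tolerance = 1e-6)
  expect_error(competitor_to_disturbance(10, 1, 30), "d_max < 1")
})

test_that("open-loop silencing dose response is monotone and starts unsilenced", {
  p <- device_fixture("strong-high-regulated")
  doses <- c(0, 1, 3, 10, 30, 100, 300, 1000)
  dr <- silencing_dose_response(p, doses, K_half = 30, hill_n = 2)
  # zero induction: the unsilenced closed form R*T*D/(delta*gamma*kappa)
  y_free <- p$R * p$T_rate * p$D / (p$delta * p$gamma * p$kappa_gfp)
  expect_equal(dr$y1[1], y_free, tolerance = 1e-9)
  expect_true(all(diff(dr$y1) <= 1e-9 * y_free))
  expect_lt(dr$y1[nrow(dr)], 0.2 * y_free)  # high dose silences strongly
  # driving Ts very large pushes the output to a basal residual level
  p_hot <- update_params(p, Ts = p$Ts * 1e4)
  dr_hot <- silencing_dose_response(p_hot, c(1000), K_half = 30)
  expect_lt(dr_hot$y1, 0.01 * y_free)
})
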