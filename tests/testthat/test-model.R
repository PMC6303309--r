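test_that("regulated RHS reproduces hand-computed derivatives", {
  p <- unit_params()
  # all rates 1, state (1,1,1): dm = 1-1-1, ds = 1-1-1, dy = 1-1
  expect_equal(rhs_regulated(c(m1 = 1, s1 = 1, y1 = 1), p, d = 0),
               c(m1 = -1, s1 = -1, y1 = 0))
  # zero state: only the transcription source is active
  p2 <- update_params(p, T_rate = 3, D = 2)
  expect_equal(rhs_regulated(c(m1 = 0, s1 = 0, y1 = 0), p2, d = 0),
               c(m1 = 6, s1 = 0, y1 = 0))
  # translation vanishes as d -> 1: dy1 -> -gamma*y1
  eps <- 1e-9
  dy <- rhs_regulated(c(m1 = 2, s1 = 0, y1 = 3), p, d = 1 - eps)[["y1"]]
  expect_equal(dy, -1 * 3, tolerance = 1e-8)
  expect_error(rhs_regulated(c(m1 = 1, s1 = 1, y1 = 1), p, d = 1),
               "0 <= d < 1")
  expect_error(rhs_regulated(c(m1 = -1, s1 = 1, y1 = 1), p, d = 0),
               "nonnegative")
})

test_that("unregulated RHS equals the regulated loop with the sRNA removed", {
  p <- unit_params(T_rate = 2, delta = 0.7, R = 3, gamma = 0.4)
  p0 <- update_params(p, Ts = 0)
  st <- c(m1 = 1.3, s1 = 0, y1 = 0.8)
  reg <- rhs_regulated(st, p0, d = 0.2)
  unreg <- rhs_unregulated(st[c("m1", "y1")], p, d = 0.2)
  expect_equal(unreg, reg[c("m1", "y1")])
  # steady mRNA at m1 = T*D*H/delta
  expect_equal(rhs_unregulated(c(m1 = 2 / 0.7, y1 = 0), p, d = 0)[["m1"]], 0)
})

test_that("full model derivative agrees with the reduced model when p1 = k*y1", {
  p <- unit_params(T_rate = 5, k = 3, Ts = 2, delta = 0.5, gamma = 0.9)
  st <- c(m1 = 0.7, s1 = 0.2, y1 = 1.1)
  full <- rhs_full(c(st, p1 = p$k * st[["y1"]]), p, d = 0.3)
  red <- rhs_regulated(st, p, d = 0.3)
  expect_equal(full[c("m1", "s1", "y1")], red)
  # dp1/dt = k*dy1/dt on the proportional manifold (shared gamma)
  expect_equal(full[["p1"]], p$k * full[["y1"]])
  # zero state with constitutive H: only transcription fires
  expect_equal(rhs_full(c(m1 = 0, s1 = 0, y1 = 0, p1 = 0), p, d = 0),
               c(m1 = 5, s1 = 0, y1 = 0, p1 = 0))
})

test_that("saturating actuator recovers the linear law as K grows", {
  p_lin <- unit_params(Ts = 2, k = 3)
  p_sat <- update_params(p_lin, actuator_saturation = 1e12)
  st <- c(m1 = 1, s1 = 1, y1 = 2)
  expect_equal(rhs_regulated(st, p_sat, d = 0),
               rhs_regulated(st, p_lin, d = 0), tolerance = 1e-9)
  # at finite K the production is strictly below the linear rate
  p_k <- update_params(p_lin, actuator_saturation = 5)
  expect_lt(rhs_regulated(st, p_k, d = 0)[["s1"]],
            rhs_regulated(st, p_lin, d = 0)[["s1"]])
})

test_that("trajectories from nonnegative initial states stay nonnegative", {
  set.seed(101)
  for (i in 1:8) {
    p <- random_device_params()
    init <- c(m1 = stats::runif(1, 0, 5), s1 = stats::runif(1, 0, 5),
              y1 = stats::runif(1, 0, 5))
    tr <- simulate_device(p, "regulated", disturbance = stats::runif(1, 0, 0.9),
                          t_span = c(0, 5 / min(p$delta, p$gamma)),
                          initial = init, n_grid = 200L)
    expect_gte(min(tr$m1, tr$s1, tr$y1), -1e-8 * max(abs(tr$y1), 1))
  }
})
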