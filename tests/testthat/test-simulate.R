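test_that("with all production off the protein decays exponentially", {
  p <- unit_params(T_rate = 0, Ts = 0, gamma = 0.8)
  tr <- simulate_device(p, "unregulated", disturbance = 0,
                        t_span = c(0, 5), initial = c(m1 = 0, y1 = 1),
                        n_grid = 200L)
  expect_equal(tr$y1, exp(-0.8 * tr$time), tolerance = 1e-7)
})

test_that("equilibrated unregulated device halves after a d = 0.5 step", {
  p <- device_fixture("strong-high-unregulated")
  tr <- simulate_device(p, "unregulated", step_disturbance(0.5),
                        t_span = c(-1, 12), n_grid = 300L)
  pre <- tr$y1[1]
  post <- tr$y1[nrow(tr)]
  expect_equal(pre, steady_state(p, 0, variant = "unregulated")[["y1"]],
               tolerance = 1e-9)
  expect_equal(post / pre, 0.5, tolerance = 1e-6)
})

test_that("equilibrated ideal device returns to its pre-step output", {
  p <- device_fixture("strong-high-regulated", delta = 0)
  tr <- simulate_device(p, "ideal", step_disturbance(0.5),
                        t_span = c(-1, 20), n_grid = 300L)
  pre <- tr$y1[1]
  expect_equal(tr$y1[nrow(tr)] / pre, 1, tolerance = 1e-6)
  # the transient dips below the set point before recovering
  expect_lt(min(tr$y1), pre * (1 - 1e-6))
})

test_that("applied disturbance switches exactly at profile breakpoints", {
  p <- device_fixture("weak-low-regulated")
  prof <- disturbance_profile(c(-Inf, 1, 3), c(0, 0.4, 0.2))
  tr <- simulate_device(p, "regulated", prof, t_span = c(0, 5), n_grid = 50L)
  expect_equal(sort(unique(tr$d)), c(0, 0.2, 0.4))
  expect_true(all(tr$d[tr$time < 1] == 0))
  expect_true(all(tr$d[tr$time >= 1 & tr$time < 3] == 0.4))
  expect_true(all(tr$d[tr$time >= 3] == 0.2))
})

test_that("halving solver tolerances leaves the endpoint unchanged", {
  p <- device_fixture("strong-medium-regulated")
  args <- list(p, "regulated", step_disturbance(0.6), t_span = c(-0.5, 4),
               n_grid = 100L)
  t1 <- do.call(simulate_device, c(args, rtol = 1e-8, atol = 1e-10))
  t2 <- do.call(simulate_device, c(args, rtol = 5e-9, atol = 5e-11))
  expect_equal(t1$y1[nrow(t1)], t2$y1[nrow(t2)], tolerance = 1e-6)
})

test_that("trajectory CSV is tidy, ordered and byte-deterministic", {
  p <- device_fixture("strong-high-regulated")
  tr <- simulate_device(p, "regulated", step_disturbance(0.5),
                        t_span = c(-0.5, 1), n_grid = 40L)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, f1)
  write_trajectory(simulate_device(p, "regulated", step_disturbance(0.5),
                                   t_span = c(-0.5, 1), n_grid = 40L), f2)
  expect_identical(readLines(f1), readLines(f2))
  header <- readLines(f1, n = 1)
  expect_identical(header, "time,m1,s1,y1,d,z,e")
  # unregulated device: no feedback, so no error column; z still present
  tru <- simulate_device(device_fixture("strong-high-unregulated"),
                         "unregulated", 0, t_span = c(0, 1), n_grid = 10L)
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tru, f3)
  expect_identical(readLines(f3, n = 1), "time,m1,y1,d,z")
})

test_that("step_response summarizes the adaptation protocol", {
  # no disturbance: flat line, all summary outputs equal
  p <- device_fixture("strong-high-regulated")
  s0 <- step_response(p, d_step = 0, horizon = 2, n_grid = 100L)
  expect_equal(s0$post_min, s0$pre_step, tolerance = 1e-8)
  expect_equal(s0$recovery_ratio, 1, tolerance = 1e-8)
  expect_equal(s0$settling_time, 0)
  # unregulated device: final/pre equals 1 - d_step
  pu <- device_fixture("strong-high-unregulated")
  su <- step_response(pu, variant = "unregulated", d_step = 0.3,
                      horizon = 6, n_grid = 200L)
  expect_equal(su$recovery_ratio, 0.7, tolerance = 1e-8)
  expect_gt(su$settling_time, 0)
  # ideal integral: full recovery for every step size
  pi0 <- update_params(p, delta = 0)
  for (d in c(0.1, 0.5, 0.9)) {
    si <- step_response(pi0, variant = "ideal", d_step = d, horizon = 6,
                        n_grid = 150L)
    expect_equal(si$recovery_ratio, 1, tolerance = 1e-7)
  }
})
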