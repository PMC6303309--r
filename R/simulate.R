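# Stiff time-domain integration of the model variants with piecewise-constant
# disturbance profiles. Discontinuities in d are handled by restarting the
# integrator at each breakpoint, so each segment sees smooth dynamics.

#' Simulate a device model variant over time
#'
#' Integrates the chosen right-hand side with [deSolve::lsoda()] (which
#' switches automatically to a stiff BDF method) over `t_span`, restarting at
#' every disturbance breakpoint so the discontinuities in `d(t)` are handled
#' exactly. With `initial = "equilibrate"` the trajectory starts from the
#' steady state at the profile's initial disturbance — the protocol used
#' throughout: grow the circuit to steady state, then perturb it.
#'
#' @inheritParams steady_state
#' @param disturbance A [disturbance_profile()], or a single number in
#'   `[0, 1)` for a constant disturbance.
#' @param t_span Length-2 numeric, start and end time.
#' @param initial `"equilibrate"` (default) or a named nonnegative state
#'   vector matching the variant's state layout.
#' @param n_grid Output points per disturbance segment (default 500); the
#'   solver's dense output is interpolated onto this grid.
#' @param rtol,atol Solver tolerances.
#' @return An object of class `"circuit_trajectory"`: a data frame with
#'   columns `time`, the state components, the applied disturbance `d`, the
#'   memory variable `z = m1 - s1` and — for variants with an active feedback
#'   loop — the tracking error `e = T*D*H(u1)/(k*Ts) - y1`. Attributes store
#'   the variant, parameters and input.
#' @examples
#' p <- device_params(T_rate = 100, D = 1, kappa_gfp = 100, k = 6.6, Ts = 50,
#'                    delta = 8, lam = 2000, beta = 1, R = 1000, gamma = 1.4)
#' tr <- simulate_device(p, "regulated", step_disturbance(0.5), t_span = c(-1, 3))
#' @export
simulate_device <- function(params, variant = "regulated", disturbance = 0,
                            u1 = 1, t_span = c(0, 10),
                            initial = "equilibrate",
                            n_grid = 500L, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "device_params"))
  variant <- check_variant(variant)
  if (is.numeric(disturbance)) disturbance <- constant_disturbance(disturbance)
  stopifnot(inherits(disturbance, "disturbance_profile"))
  if (!(length(t_span) == 2L && is.finite(t_span[1]) && is.finite(t_span[2]) &&
        t_span[2] > t_span[1])) {
    stop("t_span must be a finite increasing pair of times", call. = FALSE)
  }
  p <- variant_params(params, variant)
  snames <- variant_state_names(variant)

  if (identical(initial, "equilibrate")) {
    d0 <- d_at(disturbance, t_span[1])
    init <- steady_state(p, d = d0, u1 = u1, variant = variant)[snames]
  } else {
    init <- initial
    if (is.null(names(init))) names(init) <- snames
    check_state(init, snames)
    init <- init[snames]
  }

  rhs <- variant_rhs(variant)
  desolve_fun <- function(t, y, parms) {
    names(y) <- snames
    list(rhs(pmax(y, 0), p, d = parms$d, u1 = u1))
  }

  # split t_span at interior breakpoints
  bps <- disturbance$breakpoints
  cuts <- bps[bps > t_span[1] & bps < t_span[2]]
  edges <- c(t_span[1], cuts, t_span[2])

  out <- NULL
  state <- init
  for (i in seq_len(length(edges) - 1L)) {
    seg <- edges[c(i, i + 1L)]
    d_seg <- d_at(disturbance, seg[1])
    times <- seq(seg[1], seg[2], length.out = max(n_grid, 2L))
    sol <- deSolve::lsoda(y = state, times = times, func = desolve_fun,
                          parms = list(d = d_seg), rtol = rtol, atol = atol,
                          maxsteps = 500000L)
    diag <- attributes(sol)
    if (!is.null(diag$istate) && diag$istate[1] < 0) {
      stop(sprintf("ODE solver failed in segment [%g, %g]; last valid time %g",
                   seg[1], seg[2], max(sol[, "time"])), call. = FALSE)
    }
    sol <- as.data.frame(unclass(sol))
    neg <- vapply(sol[snames], min, numeric(1))
    scale <- max(abs(unlist(sol[snames])), 1)
    if (any(neg < -1e-6 * scale)) {
      stop("integration produced a negative state beyond tolerance",
           call. = FALSE)
    }
    sol$d <- d_seg
    # at a junction keep the new segment's first row: d(t) uses half-open
    # intervals, so the breakpoint itself carries the new disturbance
    if (!is.null(out)) out <- out[-nrow(out), , drop = FALSE]
    out <- rbind(out, sol)
    state <- unlist(out[nrow(out), snames])
  }

  out$z <- if ("s1" %in% snames) out$m1 - out$s1 else out$m1
  kTs <- p$k * p$Ts
  if (variant %in% c("regulated", "ideal", "full") && kTs > 0) {
    setpoint <- p$T_rate * p$D * p$regulation(u1) / kTs
    out$e <- setpoint - out$y1
  }
  rownames(out) <- NULL
  structure(out,
            class = c("circuit_trajectory", "data.frame"),
            variant = variant, params = p, u1 = u1,
            disturbance = disturbance)
}

#' @export
print.circuit_trajectory <- function(x, ...) {
  v <- attr(x, "variant")
  cat(sprintf("Circuit trajectory (%s variant): %d time points on [%g, %g]\n",
              v, nrow(x), min(x$time), max(x$time)))
  cat(sprintf("  final state: %s\n",
              paste(sprintf("%s = %.6g",
                            setdiff(names(x), c("time", "d", "z", "e")),
                            unlist(x[nrow(x),
                                     setdiff(names(x),
                                             c("time", "d", "z", "e"))])),
                    collapse = ", ")))
  invisible(x)
}

#' @export
plot.circuit_trajectory <- function(x, what = "y1", ...) {
  stopifnot(what %in% names(x))
  graphics::plot(x$time, x[[what]], type = "l", xlab = "time",
                 ylab = what, ...)
  bps <- attr(x, "disturbance")$breakpoints
  bps <- bps[is.finite(bps) & bps > min(x$time) & bps < max(x$time)]
  if (length(bps)) graphics::abline(v = bps, lty = 3)
  invisible(x)
}

#' Write a trajectory to tidy CSV
#'
#' Deterministic column order `time, m1, s1, y1, p1, d, z, e`; columns absent
#' from the variant (e.g. `p1`, `e`) are omitted entirely, not left blank.
#' Decimal point is always `.` regardless of locale.
#'
#' @param traj A [simulate_device()] trajectory.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "circuit_trajectory"))
  cols <- intersect(c("time", "m1", "s1", "y1", "p1", "d", "z", "e"),
                    names(traj))
  utils::write.csv(as.data.frame(traj)[cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Step-disturbance response with summary statistics
#'
#' Runs the canonical adaptation experiment: equilibrate the device at
#' `d = 0`, apply a step to `d = d_step` at `t = 0`, and follow the output
#' until `horizon`. A short pre-step window is included so the trajectory
#' shows the nominal level. The summary reports the pre-step output, the
#' post-step minimum, the final (new steady-state) output, the recovery ratio
#' final/pre-step, and the settling time — the first time after which the
#' output stays within `settle_frac` (default 2%) of its final steady state.
#'
#' @inheritParams simulate_device
#' @param d_step Disturbance magnitude of the step, `0 <= d_step < 1`.
#' @param horizon Simulation horizon after the step; default `8 / gamma`,
#'   several protein lifetimes.
#' @param settle_frac Settling band as a fraction of the final output.
#' @return A list of class `"step_response"` with elements `trajectory`
#'   (the [simulate_device()] output), `pre_step`, `post_min`, `final`,
#'   `recovery_ratio` and `settling_time`.
#' @export
step_response <- function(params, variant = "regulated", d_step = 0.5,
                          u1 = 1, horizon = NULL, settle_frac = 0.02,
                          n_grid = 500L, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "device_params"))
  variant <- check_variant(variant)
  check_d(d_step)
  p <- variant_params(params, variant)
  if (is.null(horizon)) horizon <- 8 / p$gamma
  prof <- step_disturbance(d_after = d_step, d_before = 0, t_step = 0)
  traj <- simulate_device(p, variant = variant, disturbance = prof, u1 = u1,
                          t_span = c(-0.1 * horizon, horizon),
                          initial = "equilibrate",
                          n_grid = n_grid, rtol = rtol, atol = atol)
  pre <- traj$y1[traj$time < 0][1]
  post <- traj[traj$time >= 0, ]
  y_inf <- steady_state(p, d = d_step, u1 = u1, variant = variant)[["y1"]]
  outside <- abs(post$y1 - y_inf) > settle_frac * abs(y_inf)
  settling <- if (!any(outside)) 0 else {
    last_out <- max(which(outside))
    if (last_out == nrow(post)) NA_real_ else post$time[last_out + 1L]
  }
  structure(list(trajectory = traj,
                 pre_step = pre,
                 post_min = min(post$y1),
                 final = y_inf,
                 recovery_ratio = y_inf / pre,
                 settling_time = settling,
                 d_step = d_step),
            class = "step_response")
}

#' @export
print.step_response <- function(x, ...) {
  cat(sprintf("Step response to d: 0 -> %g\n", x$d_step))
  cat(sprintf("  pre-step output   %.6g\n", x$pre_step))
  cat(sprintf("  post-step minimum %.6g\n", x$post_min))
  cat(sprintf("  final output      %.6g  (recovery ratio %.4f)\n",
              x$final, x$recovery_ratio))
  cat(sprintf("  settling time     %s\n",
              if (is.na(x$settling_time)) "not settled within horizon"
              else format(x$settling_time, digits = 4)))
  invisible(x)
}

#' @export
plot.step_response <- function(x, ...) {
  plot(x$trajectory, what = "y1",
       main = sprintf("step d: 0 -> %g", x$d_step), ...)
  graphics::abline(h = c(x$pre_step, x$final), lty = c(2, 3))
  invisible(x)
}
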