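#' Piecewise-constant ribosome disturbance profile
#'
#' The disturbance `d` models the fold change in free-ribosome availability
#' caused by competing devices: `d = 0` leaves the ribosome pool unchanged and
#' `d -> 1` means almost no free ribosomes remain, so `0 <= d < 1` always.
#' The profile is piecewise constant in time: `values[i]` applies on the
#' half-open interval `[breakpoints[i], breakpoints[i + 1])`, the last value
#' extending to `+Inf`. Times before the first breakpoint take the first
#' value.
#'
#' @param breakpoints Strictly increasing vector of times at which `d`
#'   changes; `breakpoints[1]` is the start of the first interval.
#' @param values Disturbance value per interval, same length as
#'   `breakpoints`, each in `[0, 1)`.
#' @return An object of class `"disturbance_profile"`.
#' @examples
#' prof <- disturbance_profile(breakpoints = c(-Inf, 0), values = c(0, 0.5))
#' d_at(prof, c(-1, 0, 2))   # 0.0 0.5 0.5
#' @export
disturbance_profile <- function(breakpoints, values) {
  if (length(breakpoints) != length(values) || length(values) < 1L) {
    stop("disturbance_profile(): breakpoints and values must have equal, positive length",
         call. = FALSE)
  }
  if (is.unsorted(breakpoints, strictly = TRUE)) {
    stop("disturbance_profile(): breakpoints must be strictly increasing",
         call. = FALSE)
  }
  check_d(values)
  structure(list(breakpoints = as.numeric(breakpoints),
                 values = as.numeric(values)),
            class = "disturbance_profile")
}

check_d <- function(d) {
  if (!is.numeric(d) || any(is.na(d)) || any(d < 0) || any(d >= 1)) {
    stop("disturbance d must satisfy 0 <= d < 1", call. = FALSE)
  }
  invisible(d)
}

#' Constant disturbance profile
#' @param d Disturbance value in `[0, 1)`.
#' @return A [disturbance_profile()] holding `d` for all time.
#' @export
constant_disturbance <- function(d) {
  disturbance_profile(breakpoints = -Inf, values = d)
}

#' Step disturbance profile
#'
#' The protocol used to probe adaptation: the circuit sits at `d_before`
#' (default 0, competitor off), then the competitor is switched on at
#' `t_step`, dropping free-ribosome availability by `d_after`.
#'
#' @param d_after Disturbance after the step, in `[0, 1)`.
#' @param d_before Disturbance before the step (default 0).
#' @param t_step Step time (default 0).
#' @return A [disturbance_profile()].
#' @export
step_disturbance <- function(d_after, d_before = 0, t_step = 0) {
  disturbance_profile(breakpoints = c(-Inf, t_step),
                      values = c(d_before, d_after))
}

#' Evaluate a disturbance profile
#'
#' @param profile A [disturbance_profile()].
#' @param t Numeric vector of times.
#' @return `d` at each time, using half-open intervals `[t_i, t_{i+1})`.
#' @export
d_at <- function(profile, t) {
  stopifnot(inherits(profile, "disturbance_profile"))
  idx <- findInterval(t, profile$breakpoints)
  idx[idx < 1L] <- 1L
  profile$values[idx]
}

#' @export
print.disturbance_profile <- function(x, ...) {
  cat("Piecewise-constant disturbance profile (fold drop in free ribosomes)\n")
  n <- length(x$values)
  to <- c(x$breakpoints[-1], Inf)
  for (i in seq_len(n)) {
    cat(sprintf("  [%g, %g): d = %g\n", x$breakpoints[i], to[i], x$values[i]))
  }
  invisible(x)
}
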