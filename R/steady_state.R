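# Steady states of the model variants: closed forms where they exist,
# otherwise an exact 1-D reduction solved by stats::uniroot.

# Fixed point of the coupled mRNA/sRNA pair with protein readout:
#   0 = prod_m            - lam*m*s/beta - delta*m
#   0 = prod_s_fun(y)     - lam*m*s/beta - delta*s
#   y = R*(1-d)*m/(gamma*kappa_gfp)
# Subtracting the first two equations gives s(m) = m - (prod_m - prod_s)/delta,
# reducing the system to one scalar equation in m on (0, prod_m/delta]:
# the bracket's upper end is the uncoupled (sRNA-free) mRNA level, at which
# the residual is <= 0, while it is > 0 as m -> 0, so a root always exists.
solve_coupled_ss <- function(params, prod_m, prod_s_fun, d,
                             prod_s_dy = NULL, tol = 1e-12) {
  p <- params
  if (p$delta <= 0) {
    stop("coupled steady state requires delta > 0 (use the ideal variant for delta = 0)",
         call. = FALSE)
  }
  ycoef <- p$R * (1 - d) / (p$gamma * p$kappa_gfp)
  if (prod_m <= 0) {
    return(c(m1 = 0, s1 = 0, y1 = 0))
  }
  hi <- prod_m / p$delta
  cb <- p$lam / p$beta
  g <- function(m) {
    y <- ycoef * m
    s <- m - (prod_m - prod_s_fun(y)) / p$delta
    prod_m - cb * m * s - p$delta * m
  }
  lo <- hi * 1e-14
  if (g(lo) < 0) lo <- hi * .Machine$double.xmin / hi  # pathological; retry tiny
  root <- tryCatch(
    stats::uniroot(g, lower = lo, upper = hi, tol = tol * hi,
                   maxiter = 2000L),
    error = function(e) {
      stop("steady-state solver failed: ", conditionMessage(e),
           sprintf(" [bracket (%g, %g), g(lo)=%g, g(hi)=%g]",
                   lo, hi, g(lo), g(hi)),
           call. = FALSE)
    })
  m <- root$root
  y <- ycoef * m
  s <- m - (prod_m - prod_s_fun(y)) / p$delta
  if (s < -1e-9 * hi) {
    stop(sprintf("steady-state solver found negative sRNA level (s1 = %g)", s),
         call. = FALSE)
  }
  c(m1 = m, s1 = max(s, 0), y1 = y)
}

# Ideal-integral (delta = 0) closed form of the regulated loop:
# dz/dt = 0 forces T*D*H = sRNA production at k*y1.
ideal_steady_state <- function(params, d, u1) {
  p <- params
  TDH <- p$T_rate * p$D * p$regulation(u1)
  if (TDH <= 0) return(c(m1 = 0, s1 = 0, y1 = 0))
  if (p$k * p$Ts <= 0) {
    stop("ideal steady state needs an active feedback loop (k * Ts > 0)",
         call. = FALSE)
  }
  if (is.null(p$actuator_saturation)) {
    y <- TDH / (p$k * p$Ts)
  } else {
    K <- p$actuator_saturation
    # Ts * p1 / (1 + p1/K) = TDH with p1 = k*y; needs Ts*K > TDH to saturate
    # above the set point
    if (p$Ts * K <= TDH) {
      stop("saturating actuator cannot reach the transcription load: no steady state",
           call. = FALSE)
    }
    y <- TDH * K / (p$k * (p$Ts * K - TDH))
  }
  if (p$R <= 0 || d >= 1) stop("ideal steady state needs R > 0 and d < 1",
                               call. = FALSE)
  m <- p$gamma * p$kappa_gfp * y / (p$R * (1 - d))
  s <- TDH * p$beta / (p$lam * m)
  c(m1 = m, s1 = s, y1 = y)
}

#' Steady state of a device model variant
#'
#' Computes the fixed point of the chosen model variant at a constant
#' disturbance. The unregulated device has the closed form
#' `m1* = T*D*H/delta`, `y1* = R*(1-d)*T*D*H / (delta*gamma*kappa_gfp)`,
#' linear in `(1 - d)`. In the ideal-integral limit (`delta = 0`,
#' `variant = "ideal"`) the output is `y1* = T*D*H(u1) / (k*Ts)` —
#' independent of the disturbance, i.e. perfect adaptation. For the leaky
#' regulated loop (`delta > 0`) the three-state system is reduced exactly to
#' one scalar equation in `m1` and solved with [stats::uniroot()]; the
#' bracket's upper end is the unregulated mRNA level. A regulated request
#' with `delta = 0` is routed to the ideal closed form. The `full` variant
#' appends the sensor protein at its equilibrium `p1* = k * y1*`.
#'
#' Local stability is checked from the eigenvalues of the analytic Jacobian
#' (regulated variants); an unstable fixed point raises an error. With
#' `validate = TRUE` the fixed point is additionally cross-checked against the
#' endpoint of a long stiff integration.
#'
#' @inheritParams rhs_regulated
#' @param variant One of `"regulated"`, `"unregulated"`, `"full"`, `"ideal"`.
#' @param validate Cross-check against long-time integration (slower).
#' @param validate_rtol Relative tolerance for the cross-check.
#' @return Named vector `c(m1, s1, y1)` (plus `p1` for `"full"`; the
#'   unregulated variant reports `s1 = 0`).
#' @examples
#' p <- device_params(T_rate = 1, D = 1, kappa_gfp = 1, k = 2, Ts = 1,
#'                    delta = 0, lam = 1, beta = 1, R = 1, gamma = 1)
#' steady_state(p, d = 0.3, variant = "ideal")[["y1"]]   # 0.5 for any d
#' @export
steady_state <- function(params, d = 0, u1 = 1, variant = "regulated",
                         validate = FALSE, validate_rtol = 1e-6) {
  stopifnot(inherits(params, "device_params"))
  variant <- check_variant(variant)
  check_d(d)
  p <- variant_params(params, variant)
  H <- p$regulation(u1)
  TDH <- p$T_rate * p$D * H

  ss <- switch(variant,
    unregulated = {
      if (p$delta <= 0 && TDH > 0) {
        stop("unregulated device with delta = 0 has no bounded steady state",
             call. = FALSE)
      }
      m <- if (TDH > 0) TDH / p$delta else 0
      c(m1 = m, s1 = 0,
        y1 = p$R * (1 - d) * m / (p$gamma * p$kappa_gfp))
    },
    ideal = ideal_steady_state(p, d, u1),
    regulated = {
      if (p$delta == 0) {
        ideal_steady_state(p, d, u1)
      } else {
        ss3 <- solve_coupled_ss(
          p, prod_m = TDH,
          prod_s_fun = function(y) srna_production(p, p$k * y), d = d)
        ev <- eigen(jacobian_regulated(ss3, p, d), only.values = TRUE)$values
        if (max(Re(ev)) >= 0) {
          stop(sprintf(
            "fixed point is not locally stable (max Re(eig) = %g)",
            max(Re(ev))), call. = FALSE)
        }
        ss3
      }
    },
    full = {
      ss3 <- steady_state(p, d = d, u1 = u1, variant = "regulated")
      c(ss3, p1 = p$k * ss3[["y1"]])
    })

  if (validate) {
    validate_steady_state(p, ss, d, u1, variant, rtol = validate_rtol)
  }
  ss
}

# Integrate the variant's dynamics for a long horizon and require the endpoint
# to agree with the computed fixed point.
validate_steady_state <- function(params, ss, d, u1, variant, rtol = 1e-6) {
  rates <- c(params$delta, params$gamma)
  rates <- rates[rates > 0]
  t_end <- 50 / min(rates)
  # start away from the fixed point so agreement is informative
  init <- ss * 0.5
  init[init == 0] <- 0
  traj <- simulate_device(params, variant = variant,
                          disturbance = constant_disturbance(d),
                          u1 = u1, t_span = c(0, t_end), initial = init,
                          n_grid = 50L)
  end <- as.data.frame(traj)
  end <- end[nrow(end), ]
  for (nm in names(ss)) {
    scale <- max(abs(ss[[nm]]), 1e-12)
    if (abs(end[[nm]] - ss[[nm]]) > rtol * scale) {
      stop(sprintf(
        "steady-state cross-check failed for %s: solver %g vs integration %g",
        nm, ss[[nm]], end[[nm]]), call. = FALSE)
    }
  }
  invisible(TRUE)
}
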