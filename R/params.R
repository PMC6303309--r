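#' Feedback gain from RBS dissociation constants
#'
#' The feedback gain of the sRNA-mediated controller is the ratio of the
#' output-protein (GFP) to sensor-protein (ECF sigma factor) RBS dissociation
#' constants, \eqn{k = \kappa_{GFP} / \kappa_{ECF}}. A stronger sensor RBS
#' (smaller \eqn{\kappa_{ECF}}) gives a larger gain.
#'
#' @param kappa_gfp RBS dissociation constant of the output protein
#'   (concentration, > 0).
#' @param kappa_ecf RBS dissociation constant of the sensor protein
#'   (concentration, > 0).
#' @return Dimensionless feedback gain.
#' @seealso [gain_from_tir()] for the translation-initiation-rate convention.
#' @examples
#' feedback_gain(2, 1)    # 2
#' @export
feedback_gain <- function(kappa_gfp, kappa_ecf) {
  if (!is.numeric(kappa_gfp) || !is.numeric(kappa_ecf) ||
      any(kappa_gfp <= 0) || any(kappa_ecf <= 0)) {
    stop("feedback_gain(): both dissociation constants must be > 0",
         call. = FALSE)
  }
  kappa_gfp / kappa_ecf
}

#' Feedback gain from translation initiation rates
#'
#' RBS strengths are commonly reported as translation initiation rates (TIR,
#' e.g. from the RBS calculator). Under the convention that TIR is inversely
#' proportional to the RBS dissociation constant, the gain becomes
#' \eqn{k = TIR_{ECF} / TIR_{GFP}}. The proportionality constant cancels in
#' the ratio, so only relative TIRs matter.
#'
#' @param tir_gfp TIR of the output-protein RBS (> 0).
#' @param tir_ecf TIR of the sensor-protein RBS (> 0).
#' @return Dimensionless feedback gain.
#' @examples
#' gain_from_tir(tir_gfp = 974, tir_ecf = 6474)  # ~6.65, a high gain
#' @export
gain_from_tir <- function(tir_gfp, tir_ecf) {
  if (any(tir_gfp <= 0) || any(tir_ecf <= 0)) {
    stop("gain_from_tir(): TIR values must be > 0", call. = FALSE)
  }
  tir_ecf / tir_gfp
}

#' Transcriptional regulation functions H(u)
#'
#' `H(u)` in `[0, 1]` scales the device's transcription rate by its
#' transcription-factor input `u`. Constitutive promoters have `H == 1`;
#' Hill activation and repression forms are provided for regulated promoters.
#'
#' @param K Hill half-activation (or half-repression) constant, > 0.
#' @param n Hill coefficient, > 0.
#' @return An object of class `"regulation"`: a function of `u` returning a
#'   value in `[0, 1]`.
#' @examples
#' H <- hill_activation(K = 10, n = 2)
#' H(10)  # 0.5 at the Hill midpoint
#' @export
constitutive <- function() {
  f <- function(u) rep(1, length(u))
  structure(f, class = "regulation", type = "constitutive")
}

#' @rdname constitutive
#' @export
hill_activation <- function(K, n = 1) {
  stopifnot(K > 0, n > 0)
  f <- function(u) {
    stopifnot(all(u >= 0))
    u^n / (K^n + u^n)
  }
  structure(f, class = "regulation", type = "activation", K = K, n = n)
}

#' @rdname constitutive
#' @export
hill_repression <- function(K, n = 1) {
  stopifnot(K > 0, n > 0)
  f <- function(u) {
    stopifnot(all(u >= 0))
    K^n / (K^n + u^n)
  }
  structure(f, class = "regulation", type = "repression", K = K, n = n)
}

#' Parameters of one transcriptional device and its sRNA controller
#'
#' Bundles all rate constants of the regulated-device model
#' \deqn{dm_1/dt = T D H(u_1) - \lambda m_1 s_1/\beta - \delta m_1,}
#' \deqn{ds_1/dt = k T_s y_1 - \lambda m_1 s_1/\beta - \delta s_1,}
#' \deqn{dy_1/dt = R (1-d) m_1/\kappa_{GFP} - \gamma y_1.}
#'
#' The feedback gain `k` may be given directly or derived from the two RBS
#' dissociation constants via [feedback_gain()]; if both `k` and `kappa_ecf`
#' are supplied they must agree. Units are a consistent set: time in hours and
#' concentrations in nM-like arbitrary units in the shipped fixtures.
#'
#' @param T_rate Transcription rate constant per DNA copy of the device mRNA
#'   (concentration/time/copy). Called `T` in the model; renamed in code to
#'   avoid the `T`/`TRUE` pitfall.
#' @param D Plasmid copy number of the regulated gene (>= 1).
#' @param regulation A [constitutive()], [hill_activation()] or
#'   [hill_repression()] object describing `H(u1)`.
#' @param kappa_gfp Output-protein RBS dissociation constant (concentration).
#' @param kappa_ecf Sensor-protein RBS dissociation constant (concentration);
#'   may be omitted when `k` is given.
#' @param k Feedback gain; derived as `kappa_gfp / kappa_ecf` when omitted.
#' @param Ts Lumped sRNA transcription rate constant (1/time, per unit sensor
#'   protein). Zero for unregulated devices.
#' @param delta Decay rate constant of uncoupled mRNA and sRNA (1/time),
#'   assumed identical for both species. `delta = 0` is the ideal-integral
#'   limit.
#' @param lam mRNA-sRNA coupled decay rate constant (1/time).
#' @param beta Dissociation constant of mRNA-sRNA binding (concentration).
#'   Only the ratio `lam/beta` enters the dynamics; both are kept for
#'   traceability to the biochemistry.
#' @param R Maximum translation rate constant, proportional to total ribosomes
#'   (concentration/time).
#' @param gamma Protein decay/dilution rate constant (1/time).
#' @param actuator_saturation Optional half-saturation constant (concentration)
#'   of sRNA transcription in the sensor protein; `NULL` (default) keeps the
#'   linear actuator. When set, the sRNA production term becomes
#'   `Ts * p1 / (1 + p1 / K)` with `p1 = k * y1`, which recovers the linear
#'   term as `K -> Inf`.
#' @return An object of class `"device_params"` (a validated named list).
#' @examples
#' p <- device_params(T_rate = 300, D = 10, kappa_gfp = 100, k = 6.6,
#'                    Ts = 50, delta = 8, lam = 2000, beta = 1,
#'                    R = 1000, gamma = 1.4)
#' p$k
#' @export
device_params <- function(T_rate, D = 1, regulation = constitutive(),
                          kappa_gfp, kappa_ecf = NULL, k = NULL,
                          Ts, delta, lam, beta, R, gamma,
                          actuator_saturation = NULL) {
  if (is.null(k) && is.null(kappa_ecf)) {
    stop("device_params(): supply the gain `k` or `kappa_ecf` (or both)",
         call. = FALSE)
  }
  if (is.null(k)) k <- feedback_gain(kappa_gfp, kappa_ecf)
  if (is.null(kappa_ecf)) kappa_ecf <- kappa_gfp / k
  p <- list(T_rate = T_rate, D = D, regulation = regulation,
            kappa_gfp = kappa_gfp, kappa_ecf = kappa_ecf, k = k,
            Ts = Ts, delta = delta, lam = lam, beta = beta,
            R = R, gamma = gamma,
            actuator_saturation = actuator_saturation)
  validate_device_params(p)
  structure(p, class = "device_params")
}

validate_device_params <- function(p) {
  num <- c("T_rate", "D", "kappa_gfp", "kappa_ecf", "k", "Ts", "delta",
           "lam", "beta", "R", "gamma")
  for (f in num) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v)) {
      stop(sprintf("device_params(): `%s` must be a single number", f),
           call. = FALSE)
    }
  }
  if (any(unlist(p[num]) < 0)) {
    stop("device_params(): all rate and dissociation constants must be >= 0",
         call. = FALSE)
  }
  if (p$D < 1) stop("device_params(): plasmid copy number D must be >= 1",
                    call. = FALSE)
  if (p$kappa_gfp <= 0 || p$beta <= 0) {
    stop("device_params(): kappa_gfp and beta must be > 0", call. = FALSE)
  }
  if (p$kappa_ecf > 0 &&
      abs(p$k - p$kappa_gfp / p$kappa_ecf) >
        1e-8 * max(1, abs(p$k))) {
    stop("device_params(): k must equal kappa_gfp / kappa_ecf", call. = FALSE)
  }
  if (!inherits(p$regulation, "regulation")) {
    stop("device_params(): `regulation` must be a regulation object",
         call. = FALSE)
  }
  if (!is.null(p$actuator_saturation) &&
      (!is.numeric(p$actuator_saturation) || p$actuator_saturation <= 0)) {
    stop("device_params(): actuator_saturation must be NULL or > 0",
         call. = FALSE)
  }
  invisible(p)
}

#' Modify a device parameter set
#'
#' Returns a copy of `params` with the named fields replaced and the result
#' re-validated. Changing `k` re-derives `kappa_ecf` from the fixed
#' `kappa_gfp` (the RBS-tuning knob used for gain sweeps); changing
#' `kappa_ecf` re-derives `k`.
#'
#' @param params A [device_params()] object.
#' @param ... Named replacement values.
#' @return A `device_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "device_params"))
  repl <- list(...)
  bad <- setdiff(names(repl), c(names(unclass(params))))
  if (length(bad)) {
    stop("update_params(): unknown field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  p <- unclass(params)
  for (nm in names(repl)) p[[nm]] <- repl[[nm]]
  # keep the gain identity k = kappa_gfp / kappa_ecf coherent
  if ("k" %in% names(repl) && !("kappa_ecf" %in% names(repl))) {
    p$kappa_ecf <- p$kappa_gfp / p$k
  } else if ("kappa_ecf" %in% names(repl) && !("k" %in% names(repl))) {
    p$k <- p$kappa_gfp / p$kappa_ecf
  } else if ("kappa_gfp" %in% names(repl) &&
             !any(c("k", "kappa_ecf") %in% names(repl))) {
    p$k <- p$kappa_gfp / p$kappa_ecf
  }
  validate_device_params(p)
  structure(p, class = "device_params")
}

#' @export
print.device_params <- function(x, ...) {
  cat("Transcriptional device parameters\n")
  cat(sprintf("  transcription  T = %g, copy number D = %g, H(u): %s\n",
              x$T_rate, x$D, attr(x$regulation, "type")))
  cat(sprintf("  RBS            kappa_GFP = %g, kappa_ECF = %g  (gain k = %.4g)\n",
              x$kappa_gfp, x$kappa_ecf, x$k))
  cat(sprintf("  sRNA           Ts = %g, coupled decay lam = %g, beta = %g\n",
              x$Ts, x$lam, x$beta))
  cat(sprintf("  decay          delta = %g (RNA), gamma = %g (protein)\n",
              x$delta, x$gamma))
  cat(sprintf("  translation    R = %g\n", x$R))
  if (!is.null(x$actuator_saturation)) {
    cat(sprintf("  actuator half-saturation K = %g\n", x$actuator_saturation))
  }
  invisible(x)
}
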