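# Deterministic dynamics of the regulated / unregulated / full device models.
# State vectors are named: reduced models (m1, s1, y1); full model adds p1.

check_variant <- function(variant) {
  match.arg(variant, MODEL_VARIANTS)
}

# sRNA production rate as a function of the sensor-protein concentration p1.
# Linear actuator Ts * p1 by default; with half-saturation constant K the
# term Ts * p1 / (1 + p1/K) recovers the linear law as K -> Inf.
srna_production <- function(p, p1) {
  if (is.null(p$actuator_saturation)) {
    p$Ts * p1
  } else {
    p$Ts * p1 / (1 + p1 / p$actuator_saturation)
  }
}

# derivative of srna_production w.r.t. p1 (for Jacobians)
srna_production_dp <- function(p, p1) {
  if (is.null(p$actuator_saturation)) {
    p$Ts
  } else {
    K <- p$actuator_saturation
    p$Ts / (1 + p1 / K)^2
  }
}

check_state <- function(state, fields) {
  if (!all(fields %in% names(state))) {
    stop("state must have named components: ", paste(fields, collapse = ", "),
         call. = FALSE)
  }
  if (any(state[fields] < 0)) {
    stop("state components must be nonnegative", call. = FALSE)
  }
  invisible(state)
}

#' Right-hand sides of the device model variants
#'
#' Time derivatives of the coupled mRNA/sRNA/protein dynamics.
#' `rhs_regulated()` is the reduced three-state closed-loop model: the sensor
#' protein is eliminated through the proportionality `p1 = k * y1` (valid when
#' both proteins share the decay constant `gamma` and expression starts at
#' steady state), giving
#' \deqn{dm_1/dt = T D H(u_1) - \lambda m_1 s_1/\beta - \delta m_1,}
#' \deqn{ds_1/dt = k T_s y_1 - \lambda m_1 s_1/\beta - \delta s_1,}
#' \deqn{dy_1/dt = R (1 - d) m_1/\kappa_{GFP} - \gamma y_1.}
#' `rhs_unregulated()` is the open-loop two-state device (sensor promoter and
#' sRNA removed, `s1` identically 0). `rhs_full()` keeps the sensor protein
#' `p1` as an explicit fourth state, relaxing the proportionality assumption.
#'
#' @param state Named nonnegative numeric vector: `c(m1=, s1=, y1=)` for the
#'   reduced models (only `m1`, `y1` are used by the unregulated variant),
#'   plus `p1` for `rhs_full()`.
#' @param params A [device_params()] object.
#' @param d Disturbance, `0 <= d < 1`.
#' @param u1 Transcription-factor input to `H(u1)` (default 1; irrelevant for
#'   constitutive devices).
#' @return Named vector of time derivatives, same layout as `state`.
#' @examples
#' p <- device_params(T_rate = 1, D = 1, kappa_gfp = 1, k = 1, Ts = 1,
#'                    delta = 1, lam = 1, beta = 1, R = 1, gamma = 1)
#' rhs_regulated(c(m1 = 1, s1 = 1, y1 = 1), p, d = 0)   # (-1, -1, 0)
#' @export
rhs_regulated <- function(state, params, d, u1 = 1) {
  stopifnot(inherits(params, "device_params"))
  check_d(d)
  check_state(state, c("m1", "s1", "y1"))
  p <- params
  H <- p$regulation(u1)
  m1 <- state[["m1"]]; s1 <- state[["s1"]]; y1 <- state[["y1"]]
  couple <- p$lam * m1 * s1 / p$beta
  c(m1 = p$T_rate * p$D * H - couple - p$delta * m1,
    s1 = srna_production(p, p$k * y1) - couple - p$delta * s1,
    y1 = p$R * (1 - d) * m1 / p$kappa_gfp - p$gamma * y1)
}

#' @rdname rhs_regulated
#' @export
rhs_unregulated <- function(state, params, d, u1 = 1) {
  stopifnot(inherits(params, "device_params"))
  check_d(d)
  check_state(state, c("m1", "y1"))
  p <- params
  H <- p$regulation(u1)
  m1 <- state[["m1"]]
  c(m1 = p$T_rate * p$D * H - p$delta * m1,
    y1 = p$R * (1 - d) * m1 / p$kappa_gfp - p$gamma * state[["y1"]])
}

#' @rdname rhs_regulated
#' @export
rhs_full <- function(state, params, d, u1 = 1) {
  stopifnot(inherits(params, "device_params"))
  check_d(d)
  check_state(state, c("m1", "s1", "y1", "p1"))
  p <- params
  H <- p$regulation(u1)
  m1 <- state[["m1"]]; s1 <- state[["s1"]]
  y1 <- state[["y1"]]; p1 <- state[["p1"]]
  couple <- p$lam * m1 * s1 / p$beta
  trans <- p$R * (1 - d) * m1 / p$kappa_gfp
  c(m1 = p$T_rate * p$D * H - couple - p$delta * m1,
    s1 = srna_production(p, p1) - couple - p$delta * s1,
    y1 = trans - p$gamma * y1,
    p1 = p$k * trans - p$gamma * p1)
}

# variant -> rhs function and state layout
variant_rhs <- function(variant) {
  switch(variant,
         regulated   = rhs_regulated,
         ideal       = rhs_regulated,   # ideal limit = regulated with delta 0
         unregulated = rhs_unregulated,
         full        = rhs_full)
}

variant_state_names <- function(variant) {
  switch(variant,
         regulated = , ideal = c("m1", "s1", "y1"),
         unregulated = c("m1", "y1"),
         full = c("m1", "s1", "y1", "p1"))
}

# Params as seen by a given variant: "ideal" forces delta = 0,
# "unregulated" removes the sRNA source.
variant_params <- function(params, variant) {
  if (variant == "ideal" && params$delta != 0) {
    params <- update_params(params, delta = 0)
  }
  if (variant == "unregulated" && params$Ts != 0) {
    params <- update_params(params, Ts = 0)
  }
  params
}

# Analytic Jacobian of the reduced regulated model at a state.
jacobian_regulated <- function(state, params, d) {
  p <- params
  m1 <- state[["m1"]]; s1 <- state[["s1"]]; y1 <- state[["y1"]]
  cb <- p$lam / p$beta
  a_dy <- p$k * srna_production_dp(p, p$k * y1)
  matrix(c(-cb * s1 - p$delta, -cb * m1,            0,
           -cb * s1,           -cb * m1 - p$delta,  a_dy,
           p$R * (1 - d) / p$kappa_gfp, 0,         -p$gamma),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("m1", "s1", "y1"), c("m1", "s1", "y1")))
}
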