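# Named parameter sets for the circuit library: 2 promoters x 3 gains x
# {regulated, unregulated}. The gains come from the sensor-RBS translation
# initiation rates (565, 1127, 6474) relative to the fixed output RBS (974)
# under the TIR ~ 1/kappa convention; the remaining constants are
# representative values documented in the methods vignette (time in hours,
# concentrations in nM-like units), not reproductions of a fitted set.

FIXTURE_TIR_GFP <- 974
FIXTURE_TIR_ECF <- c(low = 565, medium = 1127, high = 6474)
FIXTURE_T <- c(strong = 300, weak = 100)

FIXTURE_DEFAULTS <- list(
  D = 10,          # plasmid copies
  kappa_gfp = 100, # nM
  Ts = 50,         # 1/h
  delta = 8,       # 1/h (~5 min RNA half-life)
  lam = 2000,      # 1/h
  beta = 1,        # nM
  R = 1000,        # nM/h
  gamma = 1.4      # 1/h (~30 min doubling, dilution-dominated)
)

#' Names of the shipped device fixtures
#' @return Character vector of the 12 fixture names,
#'   `"<strong|weak>-<low|medium|high>-<regulated|unregulated>"`.
#' @export
device_fixture_names <- function() {
  as.vector(outer(
    as.vector(outer(names(FIXTURE_T), names(FIXTURE_TIR_ECF), paste,
                    sep = "-")),
    c("regulated", "unregulated"), paste, sep = "-"))
}

#' Named device parameter fixtures
#'
#' Returns one of twelve parameter sets covering the circuit library:
#' stronger/weaker device promoter (two transcription rates `T`), low/medium/
#' high feedback gain (sensor-RBS TIRs 565, 1127 and 6474 against the fixed
#' output-RBS TIR 974), each as a regulated device or its unregulated
#' counterpart (sensor promoter and sRNA removed, `Ts = 0`).
#'
#' @param name One of [device_fixture_names()], e.g.
#'   `"strong-high-regulated"`.
#' @param ... Optional overrides passed to [update_params()].
#' @return A [device_params()] object.
#' @examples
#' device_fixture("strong-high-regulated")$k   # ~6.65
#' @export
device_fixture <- function(name, ...) {
  if (length(name) != 1L || !name %in% device_fixture_names()) {
    stop("unknown fixture '", paste(name, collapse = ","),
         "'; available: ", paste(device_fixture_names(), collapse = ", "),
         call. = FALSE)
  }
  parts <- strsplit(name, "-", fixed = TRUE)[[1]]
  promoter <- parts[1]; gain <- parts[2]; loop <- parts[3]
  k <- gain_from_tir(FIXTURE_TIR_GFP, FIXTURE_TIR_ECF[[gain]])
  d <- FIXTURE_DEFAULTS
  p <- device_params(
    T_rate = FIXTURE_T[[promoter]], D = d$D,
    kappa_gfp = d$kappa_gfp, k = k,
    Ts = if (loop == "regulated") d$Ts else 0,
    delta = d$delta, lam = d$lam, beta = d$beta,
    R = d$R, gamma = d$gamma)
  if (...length() > 0L) p <- update_params(p, ...)
  p
}
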