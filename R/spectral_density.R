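#' Per-residue dynamics parameters for the Lipari-Szabo model
#'
#' Constructor and validator for the parameter set of the model-free
#' description of internal N-H bond motion: the generalized order parameter
#' S2, the effective internal correlation time tau_e, a chemical-exchange
#' contribution Rex to R2, and the overall rotational correlation time
#' tau_c. The extended (two-timescale) model adds a fast-motion order
#' parameter Sf2, with the convention S2 = Sf2 * Ss2 and tau_e playing the
#' role of the slow internal time tau_s.
#'
#' @param S2 generalized order parameter, in [0, 1]
#' @param tau_c overall rotational correlation time, seconds (> 0)
#' @param tau_e effective internal correlation time, seconds (>= 0,
#'   < tau_c); for the extended model this is the slow internal time
#' @param Rex chemical exchange contribution to R2, s^-1 (>= 0)
#' @param Sf2 fast-motion order parameter of the extended model, in
#'   [S2, 1]; the default 1 gives the original single-timescale form
#' @param model_id optional model label "M1".."M5"
#' @return a `dynamics_params` list
#' @examples
#' p <- dynamics_params(S2 = 0.85, tau_c = 10e-9, tau_e = 50e-12)
#' @export
dynamics_params <- function(S2, tau_c, tau_e = 0, Rex = 0, Sf2 = 1,
                            model_id = NA_character_) {
  for (nm in c("S2", "tau_c", "tau_e", "Rex", "Sf2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("invalid dynamics parameter '%s': must be a finite number", nm))
    }
  }
  if (S2 < 0 || S2 > 1) stop("invalid dynamics parameter 'S2': must lie in [0, 1]")
  if (Sf2 < 0 || Sf2 > 1) stop("invalid dynamics parameter 'Sf2': must lie in [0, 1]")
  if (S2 > Sf2 + 1e-12) stop("invalid dynamics parameter 'S2': must not exceed Sf2")
  if (tau_c <= 0) stop("invalid dynamics parameter 'tau_c': must be > 0")
  if (tau_e < 0) stop("invalid dynamics parameter 'tau_e': must be >= 0")
  if (tau_e >= tau_c) stop("invalid dynamics parameter 'tau_e': must be < tau_c")
  if (Rex < 0) stop("invalid dynamics parameter 'Rex': must be >= 0")
  structure(list(S2 = S2, tau_c = tau_c, tau_e = tau_e, Rex = Rex,
                 Sf2 = Sf2, model_id = model_id),
            class = "dynamics_params")
}

#' Lipari-Szabo spectral density
#'
#' J(omega) = (2/5) [ S2 tau_c / (1 + (omega tau_c)^2)
#'                  + (Sf2 - S2) tau / (1 + (omega tau)^2) ],
#' with 1/tau = 1/tau_c + 1/tau_e. With Sf2 = 1 this is the original
#' single-timescale form; with Sf2 < 1 it is the extended two-timescale
#' form in the limit of an infinitely fast first motion. Isotropic overall
#' tumbling is assumed (a single tau_c).
#'
#' @param params a [dynamics_params()] object
#' @param omega angular frequency, rad s^-1 (>= 0); may be a vector
#' @return spectral density in s rad^-1, same length as `omega`
#' @examples
#' p <- dynamics_params(S2 = 1, tau_c = 10e-9)
#' spectral_density(p, 0)    # rigid limit: (2/5) tau_c = 4e-9
#' @export
spectral_density <- function(params, omega) {
  stopifnot(inherits(params, "dynamics_params"))
  if (any(omega < 0)) stop("omega must be >= 0")
  tc <- params$tau_c
  J <- 0.4 * params$S2 * tc / (1 + (omega * tc)^2)
  if (params$tau_e > 0 && params$Sf2 > params$S2) {
    tau <- 1 / (1 / tc + 1 / params$tau_e)
    J <- J + 0.4 * (params$Sf2 - params$S2) * tau / (1 + (omega * tau)^2)
  }
  J
}

# unvalidated fast path used by the fitting inner loops; arguments are
# assumed to satisfy the dynamics_params invariants already
.rates_fast <- function(S2, tau_c, tau_e, Rex, Sf2, const) {
  wH <- const$omega_H
  wN <- const$omega_N
  w <- c(0, wN, wH - wN, wH, wH + wN)
  J <- 0.4 * S2 * tau_c / (1 + (w * tau_c)^2)
  if (tau_e > 0 && Sf2 > S2) {
    tau <- 1 / (1 / tau_c + 1 / tau_e)
    J <- J + 0.4 * (Sf2 - S2) * tau / (1 + (w * tau)^2)
  }
  d2 <- const$d^2
  c2 <- const$c^2
  R1 <- (d2 / 4) * (J[3] + 3 * J[2] + 6 * J[5]) + c2 * J[2]
  R2 <- (d2 / 8) * (4 * J[1] + J[3] + 3 * J[2] + 6 * J[4] + 6 * J[5]) +
    (c2 / 6) * (4 * J[1] + 3 * J[2]) + Rex
  NOE <- 1 + (d2 / 4) * (const$gamma_H / const$gamma_N) *
    (6 * J[5] - J[3]) / R1
  c(R1, R2, NOE)
}

#' Forward model: relaxation rates from dynamics parameters
#'
#' Standard dipolar + CSA expressions for amide 15N relaxation:
#' \itemize{
#' \item R1 = (d^2/4)\[J(wH-wN) + 3 J(wN) + 6 J(wH+wN)\] + c^2 J(wN)
#' \item R2 = (d^2/8)\[4 J(0) + J(wH-wN) + 3 J(wN) + 6 J(wH) + 6 J(wH+wN)\]
#'          + (c^2/6)\[4 J(0) + 3 J(wN)\] + Rex
#' \item NOE = 1 + (d^2/4)(gamma_H/gamma_N)\[6 J(wH+wN) - J(wH-wN)\] / R1
#' }
#' Rex enters R2 only. The NOE can be negative for sub-nanosecond overall
#' motion because gamma_N < 0.
#'
#' @param params a [dynamics_params()] object
#' @param const a [spin_constants()] object
#' @return named numeric vector `c(R1 =, R2 =, NOE =)` (rates in s^-1)
#' @examples
#' sc <- spin_constants(700)
#' p <- dynamics_params(S2 = 0.85, tau_c = 10.4e-9, tau_e = 50e-12)
#' predict_rates(p, sc)
#' @export
predict_rates <- function(params, const) {
  stopifnot(inherits(params, "dynamics_params"), inherits(const, "spin_constants"))
  wH <- const$omega_H
  wN <- const$omega_N
  J <- function(w) spectral_density(params, w)
  d2 <- const$d^2
  c2 <- const$c^2
  JwN <- J(wN)
  Jdiff <- J(wH - wN)
  Jsum <- J(wH + wN)
  R1 <- (d2 / 4) * (Jdiff + 3 * JwN + 6 * Jsum) + c2 * JwN
  R2 <- (d2 / 8) * (4 * J(0) + Jdiff + 3 * JwN + 6 * J(wH) + 6 * Jsum) +
    (c2 / 6) * (4 * J(0) + 3 * JwN) + params$Rex
  NOE <- 1 + (d2 / 4) * (const$gamma_H / const$gamma_N) *
    (6 * Jsum - Jdiff) / R1
  c(R1 = R1, R2 = R2, NOE = NOE)
}
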