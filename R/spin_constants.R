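#' Physical constants for amide 15N relaxation
#'
#' Bundles the gyromagnetic ratios, N-H bond length, 15N chemical shift
#' anisotropy and static field into a single object, together with the
#' derived quantities every relaxation expression needs: the Larmor
#' frequencies and the dipolar and CSA interaction constants.
#'
#' Sign convention: Larmor frequencies are stored as magnitudes
#' (`omega_H`, `omega_N` > 0) and used as such inside the spectral density;
#' the negative sign of the 15N gyromagnetic ratio is honoured only where it
#' matters physically, in the heteronuclear NOE expression through the
#' `gamma_H / gamma_N` ratio.
#'
#' Default values are the community-standard choices for backbone amides:
#' gamma_H = 2.6752219e8 rad s^-1 T^-1, gamma_N = -2.7126e7 rad s^-1 T^-1,
#' r_NH = 1.02 Angstrom, CSA = -160 ppm. All are overridable.
#'
#' @param field_MHz proton resonance frequency in MHz (700 MHz corresponds
#'   to a 16.3 T magnet)
#' @param gamma_H 1H gyromagnetic ratio, rad s^-1 T^-1
#' @param gamma_N 15N gyromagnetic ratio, rad s^-1 T^-1 (negative)
#' @param r_NH_angstrom N-H bond length in Angstrom
#' @param csa_ppm 15N chemical shift anisotropy in ppm
#' @return an object of class `spin_constants`: a list with the inputs plus
#'   `B0` (T), `omega_H`, `omega_N` (rad s^-1, magnitudes), dipolar constant
#'   `d` (rad s^-1) and CSA constant `c` (rad s^-1)
#' @examples
#' sc <- spin_constants(700)
#' sc$B0          # ~16.44 T
#' sc$omega_N     # 15N Larmor frequency magnitude
#' @export
spin_constants <- function(field_MHz = 700,
                           gamma_H = 2.6752219e8,
                           gamma_N = -2.7126e7,
                           r_NH_angstrom = 1.02,
                           csa_ppm = -160) {
  if (!is.numeric(field_MHz) || field_MHz <= 0) {
    stop("field_MHz must be a positive number")
  }
  if (r_NH_angstrom <= 0) stop("r_NH_angstrom must be > 0")
  mu0 <- 4e-7 * pi      # vacuum permeability, T m A^-1
  hbar <- 1.054571817e-34  # J s
  r_NH <- r_NH_angstrom * 1e-10
  B0 <- 2 * pi * field_MHz * 1e6 / gamma_H
  omega_H <- gamma_H * B0
  omega_N <- abs(gamma_N) * B0
  # dipolar constant d = (mu0/4pi) hbar gammaH gammaN / r^3 (magnitude)
  d <- (mu0 / (4 * pi)) * hbar * abs(gamma_H * gamma_N) / r_NH^3
  # CSA constant c = omega_N * delta_sigma / sqrt(3) (magnitude)
  cc <- omega_N * abs(csa_ppm) * 1e-6 / sqrt(3)
  structure(
    list(field_MHz = field_MHz, B0 = B0,
         gamma_H = gamma_H, gamma_N = gamma_N,
         r_NH = r_NH, csa_ppm = csa_ppm,
         omega_H = omega_H, omega_N = omega_N,
         d = d, c = cc),
    class = "spin_constants"
  )
}

#' @export
print.spin_constants <- function(x, ...) {
  cat(sprintf("15N-1H spin constants at %.1f MHz (B0 = %.2f T)\n",
              x$field_MHz, x$B0))
  cat(sprintf("  gamma_H = %.6e, gamma_N = %.5e rad s^-1 T^-1\n",
              x$gamma_H, x$gamma_N))
  cat(sprintf("  r_NH = %.3f A, CSA = %.0f ppm\n",
              x$r_NH * 1e10, x$csa_ppm))
  cat(sprintf("  d = %.4e rad s^-1, c = %.4e rad s^-1\n", x$d, x$c))
  invisible(x)
}
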