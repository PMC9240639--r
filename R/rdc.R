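## Residual dipolar couplings: extraction from IPAP splittings and Saupe
## alignment-tensor fitting by SVD, with Q-factor.

#' Extract an RDC from aligned/isotropic IPAP splittings
#'
#' D = splitting(aligned) - splitting(isotropic); uncertainties propagate
#' in quadrature. The sign of the extracted RDC depends on which IPAP
#' component is upfield in the spectra; `flip_sign` negates the result if
#' the opposite convention was used during peak picking.
#'
#' @param splitting_aniso 15N-1H splitting in the aligned medium, Hz
#'   (vectorized)
#' @param splitting_iso splitting in isotropic conditions, Hz
#' @param err_aniso,err_iso optional splitting uncertainties, Hz
#' @param flip_sign negate the extracted couplings (default FALSE)
#' @return data.frame with `D` (Hz) and `D_err` (Hz, NA when no errors given)
#' @examples
#' extract_rdc(94.2, 93.0)$D   # 1.2
#' @export
extract_rdc <- function(splitting_aniso, splitting_iso,
                        err_aniso = NA, err_iso = NA, flip_sign = FALSE) {
  if (any(!is.finite(splitting_aniso)) || any(!is.finite(splitting_iso))) {
    stop("splittings must be finite")
  }
  D <- splitting_aniso - splitting_iso
  if (flip_sign) D <- -D
  D_err <- sqrt(err_aniso^2 + err_iso^2)
  data.frame(D = D, D_err = D_err)
}

#' Fit the Saupe alignment tensor to RDCs by SVD
#'
#' Solves the linear model D_i = D_max * sum_kl S_kl u_ik u_il for the five
#' independent elements of the traceless symmetric Saupe matrix by
#' singular-value decomposition of the orientation design matrix
#' \[ux^2 - uz^2, uy^2 - uz^2, 2 ux uy, 2 ux uz, 2 uy uz\]. Reports the
#' quality factor Q = sqrt(sum((D_obs - D_calc)^2) / sum(D_obs^2)), the
#' axial component Da = D_max * S_zz / 2 (Hz) and the rhombicity
#' R = (2/3)(S_xx - S_yy)/S_zz after ordering the eigenvalues
#' |S_zz| >= |S_yy| >= |S_xx|.
#'
#' @param D observed RDCs, Hz (length >= 5)
#' @param vectors n x 3 matrix of N-H unit vectors (normalized internally)
#' @param D_max dipolar interaction maximum folded into the Saupe scaling;
#'   default -21700 Hz, the 15N-1H value at r = 1.02 Angstrom (the value
#'   used is echoed in the output)
#' @param max_condition design-matrix condition number above which the
#'   orientation set is declared degenerate (default 1e6)
#' @return object of class `alignment_tensor`: list with `S` (3x3 traceless
#'   Saupe matrix), `eigenvalues` (ordered |Szz| >= |Syy| >= |Sxx|), `Da`
#'   (Hz), `rhombicity`, `Q`, `D_calc`, `D_max`, `condition`, `note`
#' @export
fit_tensor <- function(D, vectors, D_max = -21700, max_condition = 1e6) {
  vectors <- as.matrix(vectors)
  if (length(D) < 5) stop("need >= 5 RDCs to fit the 5 Saupe elements")
  if (nrow(vectors) != length(D) || ncol(vectors) != 3) {
    stop("vectors must be an n x 3 matrix matching length(D)")
  }
  nrm <- sqrt(rowSums(vectors^2))
  if (any(nrm == 0)) stop("zero-length N-H vector")
  u <- vectors / nrm
  A <- D_max * cbind(u[, 1]^2 - u[, 3]^2,
                     u[, 2]^2 - u[, 3]^2,
                     2 * u[, 1] * u[, 2],
                     2 * u[, 1] * u[, 3],
                     2 * u[, 2] * u[, 3])
  sv <- svd(A)
  if (sv$d[5] <= 0 || sv$d[1] / sv$d[5] > max_condition) {
    stop("degenerate vector set: orientation design matrix condition number ",
         format(if (sv$d[5] > 0) sv$d[1] / sv$d[5] else Inf, digits = 3))
  }
  s <- sv$v %*% ((t(sv$u) %*% D) / sv$d)
  S <- matrix(c(s[1], s[3], s[4],
                s[3], s[2], s[5],
                s[4], s[5], -s[1] - s[2]), nrow = 3, byrow = TRUE)
  D_calc <- as.vector(A %*% s)
  ssq_obs <- sum(D^2)
  note <- NULL
  if (ssq_obs == 0) {
    Q <- NaN
    note <- "all observed RDCs are zero; Q undefined"
  } else {
    Q <- sqrt(sum((D - D_calc)^2) / ssq_obs)
  }
  ev <- eigen(S, symmetric = TRUE)$values
  ev <- ev[order(abs(ev))]            # |Sxx| <= |Syy| <= |Szz|
  Sxx <- ev[1]; Syy <- ev[2]; Szz <- ev[3]
  structure(list(
    S = S,
    eigenvalues = c(Sxx = Sxx, Syy = Syy, Szz = Szz),
    Da = D_max * Szz / 2,
    rhombicity = if (Szz != 0) (2 / 3) * (Sxx - Syy) / Szz else NaN,
    Q = Q, D_calc = D_calc, D_max = D_max,
    condition = sv$d[1] / sv$d[5], note = note
  ), class = "alignment_tensor")
}

#' @export
print.alignment_tensor <- function(x, ...) {
  cat("Saupe alignment tensor (SVD fit)\n")
  cat(sprintf("  D_max = %.0f Hz; Da = %.3g Hz; rhombicity = %.3f; Q = %.4g\n",
              x$D_max, x$Da, x$rhombicity, x$Q))
  cat(sprintf("  eigenvalues: Sxx = %.3e, Syy = %.3e, Szz = %.3e\n",
              x$eigenvalues[1], x$eigenvalues[2], x$eigenvalues[3]))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Back-calculate RDCs from a Saupe tensor
#'
#' Forward model D_i = D_max * u_i' S u_i, used by the generator and for
#' round-trip checks.
#'
#' @param S 3x3 traceless symmetric Saupe matrix
#' @param vectors n x 3 matrix of unit vectors (normalized internally)
#' @param D_max scaling constant, Hz (must match [fit_tensor()])
#' @return numeric vector of RDCs in Hz
#' @export
backcalc_rdc <- function(S, vectors, D_max = -21700) {
  vectors <- as.matrix(vectors)
  u <- vectors / sqrt(rowSums(vectors^2))
  D_max * rowSums((u %*% S) * u)
}
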