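#' Overall rotational correlation time from R2/R1 ratios
#'
#' Estimates the overall (isotropic) rotational correlation time tau_c from
#' per-residue R2/R1 ratios, the standard field-dependent estimator for
#' well-ordered residues. For each retained residue the rigid-limit ratio
#' R2(tau_c)/R1(tau_c) (S2 = 1, Rex = 0; S2 cancels exactly in the ratio
#' when internal motion is negligible) is inverted by a 1-D root search over
#' tau_c in \[0.5, 50\] ns. The result is the trimmed mean +/- SEM over
#' retained residues.
#'
#' Two filters remove residues whose ratio is biased by internal motion or
#' exchange: (i) residues with NOE below `noe_cutoff` (flexible, sub-ns
#' motion depresses the NOE) and (ii) residues whose R2/R1 ratio deviates
#' from the mean of the NOE-passing set by more than `trim_sd` standard
#' deviations (exchange broadening inflates R2).
#'
#' @param records data.frame of per-residue relaxation data with columns
#'   `res_num`, `R1`, `R2`, `NOE` (see [read_relaxation_table()])
#' @param const [spin_constants()] for the field the data were measured at
#' @param noe_cutoff exclude residues with NOE below this value (default 0.65)
#' @param trim_sd exclude residues whose R2/R1 ratio is more than this many
#'   SD from the mean (default 1.5)
#' @return object of class `tauc_estimate`: list with `tau_c` (s),
#'   `tau_c_err` (SEM, s), `n_used`, `per_residue` (data.frame of res_num and
#'   tau_c), and `excluded` (data.frame of res_num and reason)
#' @examples
#' sc <- spin_constants(700)
#' r <- predict_rates(dynamics_params(S2 = 1, tau_c = 10.4e-9), sc)
#' df <- data.frame(res_num = 1, R1 = r["R1"], R2 = r["R2"], NOE = r["NOE"])
#' estimate_tauc(df, sc)$tau_c * 1e9  # ~10.4 ns
#' @export
estimate_tauc <- function(records, const, noe_cutoff = 0.65, trim_sd = 1.5) {
  stopifnot(is.data.frame(records), inherits(const, "spin_constants"))
  need <- c("res_num", "R1", "R2", "NOE")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records is missing column(s): ", paste(miss, collapse = ", "))

  excluded <- data.frame(res_num = integer(), reason = character())
  keep <- is.finite(records$R1) & is.finite(records$R2) & is.finite(records$NOE)
  if (any(!keep)) {
    excluded <- rbind(excluded, data.frame(
      res_num = records$res_num[!keep], reason = "missing data"))
  }
  low_noe <- keep & records$NOE < noe_cutoff
  if (any(low_noe)) {
    excluded <- rbind(excluded, data.frame(
      res_num = records$res_num[low_noe], reason = "NOE below cutoff"))
  }
  keep <- keep & !low_noe
  if (!any(keep)) stop("no rigid residues available for tumbling estimate")

  ratio <- records$R2 / records$R1
  m <- mean(ratio[keep])
  # population SD, so the trim set (and hence tau_c) is invariant under
  # duplication of the record set
  s <- sqrt(mean((ratio[keep] - m)^2))
  if (is.finite(s) && s > 0) {
    outlier <- keep & abs(ratio - m) > trim_sd * s
    if (any(outlier)) {
      excluded <- rbind(excluded, data.frame(
        res_num = records$res_num[outlier], reason = "ratio outlier"))
    }
    keep <- keep & !outlier
  }
  if (!any(keep)) stop("no rigid residues available for tumbling estimate")

  # rigid-limit ratio is monotone increasing in tau_c over [0.5, 50] ns
  ratio_of_tc <- function(tc) {
    r <- .rates_fast(1, tc, 0, 0, 1, const)
    r[2] / r[1]
  }
  lo <- 0.5e-9
  hi <- 50e-9
  rlo <- ratio_of_tc(lo)
  rhi <- ratio_of_tc(hi)
  idx <- which(keep)
  tcs <- vapply(idx, function(i) {
    target <- ratio[i]
    if (target <= rlo) return(lo)
    if (target >= rhi) return(hi)
    stats::uniroot(function(tc) ratio_of_tc(tc) - target,
                   interval = c(lo, hi), tol = 1e-15)$root
  }, numeric(1))

  n <- length(tcs)
  structure(list(
    tau_c = mean(tcs),
    tau_c_err = if (n > 1) stats::sd(tcs) / sqrt(n) else 0,
    n_used = n,
    per_residue = data.frame(res_num = records$res_num[idx], tau_c = tcs),
    excluded = excluded,
    noe_cutoff = noe_cutoff, trim_sd = trim_sd
  ), class = "tauc_estimate")
}

#' @export
print.tauc_estimate <- function(x, ...) {
  cat(sprintf("tau_c = %.2f +/- %.2f ns  (%d residues used, %d excluded)\n",
              x$tau_c * 1e9, x$tau_c_err * 1e9, x$n_used, nrow(x$excluded)))
  invisible(x)
}
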