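## Amide hydrogen/deuterium exchange: intrinsic rates, observed-rate
## fitting from peak-intensity decays, protection factors, state comparison.

# poly-DL-alanine reference rates at 293 K in D2O (log10; acid and base in
# M^-1 min^-1, water in min^-1) and Arrhenius activation energies
# (kcal/mol), Bai-Englander conventions. pKD is the ion product of D2O.
.hdx_ref <- list(
  log_kA = 1.62, log_kB = 10.05, log_kW = -1.5,
  Ea_acid = 14, Ea_base = 17, Ea_water = 19,
  pKD = 15.05, T_ref = 293
)

.hdx_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "bai1993_exchange_params.tsv",
                          package = "nmrdyn")
      tab <- utils::read.delim(path, comment.char = "#",
                               stringsAsFactors = FALSE)
      rownames(tab) <- tab$aa
      cache <<- tab
    }
    cache
  }
})

#' Intrinsic (unstructured-chain) amide exchange rate
#'
#' Predicts the H/D exchange rate an amide would have in a fully solvent
#' exposed random coil: k_int = k_acid + k_base + k_water, each term
#' corrected for the side-chain identity of the residue itself and of its
#' left (i-1) neighbour, for pD, and for temperature via Arrhenius factors
#' from the 293 K reference. Terminal corrections are applied at the second
#' residue (free N-terminal amine as left neighbour) and at the C-terminal
#' residue (ionized carboxylate). The temperature dependence of the D2O ion
#' product is neglected (pKD held at its 293 K value), a small approximation
#' over the 20-40 degC range these experiments use.
#'
#' @param sequence protein sequence, one-letter codes (single string or
#'   character vector)
#' @param position residue number of the amide, 2..nchar(sequence)
#'   (residue 1 has a free amine, not an amide; proline has no amide NH)
#' @param pH pH meter reading
#' @param temperature_K temperature in Kelvin
#' @param d2o_read if TRUE the reading was taken in D2O and the standard
#'   pD = pH + 0.4 glass-electrode correction is applied (default FALSE)
#' @return intrinsic exchange rate in s^-1
#' @examples
#' intrinsic_rate("AAA", 2, pH = 7.0, temperature_K = 308)
#' @export
intrinsic_rate <- function(sequence, position, pH, temperature_K,
                           d2o_read = FALSE) {
  seq_chars <- if (length(sequence) == 1L) strsplit(sequence, "")[[1]] else sequence
  n <- length(seq_chars)
  if (position < 2 || position > n) {
    stop("position must be in 2..length(sequence): residue 1 has no backbone amide")
  }
  if (pH <= 0 || pH >= 14) stop("pH must lie in (0, 14)")
  tab <- .hdx_table()
  res <- seq_chars[position]
  left <- seq_chars[position - 1]
  for (code in unique(c(res, left))) {
    if (!code %in% rownames(tab)) stop("unknown residue code: ", code)
  }
  if (res == "P") stop("proline has no backbone amide proton")

  lamA <- tab[res, "acid_lambda"]
  lamB <- tab[res, "base_lambda"]
  rhoA <- tab[left, "acid_rho"]
  rhoB <- tab[left, "base_rho"]
  if (position == 2) {       # left neighbour carries the free N-terminus
    rhoA <- rhoA + tab["NT", "acid_rho"]
    rhoB <- rhoB + tab["NT", "base_rho"]
  }
  if (position == n) {       # C-terminal carboxylate correction
    lamA <- lamA + tab["CT", "acid_lambda"]
    lamB <- lamB + tab["CT", "base_lambda"]
  }

  ref <- .hdx_ref
  pD <- if (d2o_read) pH + 0.4 else pH
  Rgas <- 1.987204e-3  # kcal mol^-1 K^-1
  arrh <- function(Ea) exp(-(Ea / Rgas) * (1 / temperature_K - 1 / ref$T_ref))
  k_acid <- 10^(ref$log_kA + lamA + rhoA - pD) * arrh(ref$Ea_acid)
  k_base <- 10^(ref$log_kB + lamB + rhoB + pD - ref$pKD) * arrh(ref$Ea_base)
  k_water <- 10^(ref$log_kW + lamB + rhoB) * arrh(ref$Ea_water)
  (k_acid + k_base + k_water) / 60   # min^-1 -> s^-1
}

#' Fit an observed exchange rate from a peak-intensity decay
#'
#' Least-squares fit of I(t) = I0 exp(-k t) (fixed zero baseline: fully
#' exchanged amides vanish in D2O). If the fitted total decay over the
#' observation window is smaller than twice the intensity noise, the
#' residue is censored: no decay is detectable and only an upper bound on
#' k_obs can be stated, k_upper = ln(1/(1 - `censor_frac`))/t_max
#' (default: less than 5 percent decay over the run).
#'
#' @param times time points in seconds, strictly increasing, >= 3
#' @param intensities peak intensities (arbitrary units)
#' @param errors optional per-point intensity errors; when absent the noise
#'   is estimated from the fit residuals
#' @param censor_frac decay fraction below which the series is censored
#' @return list with `k_obs` (s^-1; the upper bound when censored), `k_err`,
#'   `I0`, `censored` (logical), `noise`
#' @examples
#' t <- seq(0, 900, length.out = 10)
#' fit_exchange_rate(t, 100 * exp(-0.01 * t))$k_obs  # 0.01
#' @export
fit_exchange_rate <- function(times, intensities, errors = NULL,
                              censor_frac = 0.05) {
  if (length(times) < 3) stop("need >= 3 time points to fit an exchange rate")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (length(intensities) != length(times)) stop("times/intensities length mismatch")
  if (all(intensities <= 0)) stop("non-positive intensities throughout; nothing to fit")
  if (sum(intensities > 0) < 3) {
    stop("no detectable signal: amide exchanged before sampling could track it")
  }

  df <- data.frame(t = times, I = intensities)
  pos <- df$I > 0
  lf <- NULL
  if (sum(pos) >= 2) {
    lf <- stats::lm(log(I) ~ t, data = df[pos, ])
    k0 <- max(-unname(stats::coef(lf)[2]), 0)
    I00 <- exp(unname(stats::coef(lf)[1]))
  } else {
    k0 <- 0
    I00 <- max(df$I)
  }
  fit <- tryCatch(
    stats::nls(I ~ I0 * exp(-k * t), data = df,
               start = list(I0 = I00, k = k0),
               algorithm = "port", lower = c(I0 = 0, k = 0),
               control = stats::nls.control(warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit) && !is.null(lf) && sum(pos) >= 3) {
    # nls has a singular gradient when the decay is so fast that the
    # intensities approach the floating-point floor; the log-linear fit is
    # exact for a clean exponential there
    k_hat <- k0
    I0_hat <- I00
    k_se <- tryCatch(
      suppressWarnings(summary(lf)$coefficients["t", "Std. Error"]),
      error = function(e) NA_real_)
    resid <- df$I - I0_hat * exp(-k_hat * df$t)
  } else if (is.null(fit)) {
    # degenerate decays (e.g. exactly constant data): bounded 1-D profile
    ssq <- function(k) {
      w <- exp(-k * df$t)
      i0 <- sum(df$I * w) / sum(w^2)
      sum((df$I - i0 * w)^2)
    }
    o <- stats::optimize(ssq, c(0, 10 / max(df$t)))
    k_hat <- o$minimum
    w <- exp(-k_hat * df$t)
    I0_hat <- sum(df$I * w) / sum(w^2)
    k_se <- NA_real_
    resid <- df$I - I0_hat * w
  } else {
    cf <- stats::coef(fit)
    k_hat <- unname(cf["k"])
    I0_hat <- unname(cf["I0"])
    k_se <- tryCatch(
      suppressWarnings(summary(fit)$coefficients["k", "Std. Error"]),
      error = function(e) NA_real_)
    resid <- stats::resid(fit)
  }
  noise <- if (!is.null(errors)) mean(errors) else stats::sd(resid)
  if (!is.finite(noise)) noise <- 0
  if (noise > 0 && I0_hat < 2 * noise) {
    # an undetectable starting amplitude means the amide was already gone,
    # not that it exchanges slowly
    stop("no detectable signal: amide exchanged before sampling could track it")
  }
  t_max <- max(df$t)
  decay <- I0_hat * (1 - exp(-k_hat * t_max))
  censored <- decay < 2 * noise
  if (censored) {
    k_hat <- log(1 / (1 - censor_frac)) / t_max
    k_se <- NA_real_
  }
  list(k_obs = k_hat, k_err = k_se, I0 = I0_hat,
       censored = censored, noise = noise)
}

#' Protection factor from intrinsic and observed rates
#'
#' PF = k_int / k_obs. For censored residues (no detectable decay) k_obs is
#' an upper bound, so the PF is a lower bound; the `censored` flag carries
#' that provenance. An observed rate more than 10x faster than the intrinsic
#' rate is unphysical under EX2 (possible EX1 behaviour or misassignment)
#' and triggers a warning.
#'
#' @param k_int intrinsic rate, s^-1 (> 0)
#' @param k_obs observed rate (or censored upper bound), s^-1 (> 0)
#' @param censored logical: is k_obs an upper bound?
#' @param k_obs_err optional uncertainty on k_obs
#' @return list with `PF`, `log10_PF`, `PF_err` (NA when unavailable),
#'   `censored` (PF is a lower bound when TRUE)
#' @examples
#' protection_factor(10, 1e-3)$PF  # 1e4
#' @export
protection_factor <- function(k_int, k_obs, censored = FALSE, k_obs_err = NA) {
  if (!is.finite(k_int) || k_int <= 0) stop("k_int must be > 0")
  if (!is.finite(k_obs) || k_obs <= 0) stop("k_obs must be > 0 (or a censored bound)")
  if (k_obs > 10 * k_int) {
    warning("k_obs exceeds k_int by more than 10x: unphysical under EX2 ",
            "(EX1 exchange or misassignment?)")
  }
  pf <- k_int / k_obs
  pf_err <- if (is.finite(k_obs_err)) pf * k_obs_err / k_obs else NA_real_
  list(PF = pf, log10_PF = log10(pf), PF_err = pf_err, censored = censored)
}

#' Protection factors for a whole H/D exchange dataset
#'
#' Runs [fit_exchange_rate()] on every residue's intensity series,
#' computes [intrinsic_rate()]s from the sequence at the experimental pH
#' and temperature, and combines them into protection factors.
#'
#' @param hdx long-format data.frame with columns res_num, time_s,
#'   intensity and optionally intensity_err (see [read_hdx_table()])
#' @param sequence one-letter protein sequence
#' @param pH experimental pH
#' @param temperature_K experimental temperature (K)
#' @param d2o_read passed to [intrinsic_rate()]
#' @return data.frame: res_num, k_obs, k_obs_err, k_int, PF, log10_PF,
#'   censored, flag. `flag` is "ok", "censored" (no detectable decay; PF is
#'   a lower bound) or "no signal" (the amide exchanged before the first
#'   time point -- the fate of unprotected residues at neutral pH -- so no
#'   rate or PF can be stated)
#' @export
hdx_protection <- function(hdx, sequence, pH = 7.0, temperature_K = 308,
                           d2o_read = FALSE) {
  stopifnot(is.data.frame(hdx),
            all(c("res_num", "time_s", "intensity") %in% names(hdx)))
  rows <- lapply(sort(unique(hdx$res_num)), function(rn) {
    sub <- hdx[hdx$res_num == rn, ]
    sub <- sub[order(sub$time_s), ]
    errs <- if ("intensity_err" %in% names(sub) &&
                any(is.finite(sub$intensity_err))) sub$intensity_err else NULL
    ki <- intrinsic_rate(sequence, rn, pH, temperature_K, d2o_read)
    f <- tryCatch(fit_exchange_rate(sub$time_s, sub$intensity, errors = errs),
                  error = function(e) NULL)
    if (is.null(f)) {
      return(data.frame(res_num = rn, k_obs = NA_real_, k_obs_err = NA_real_,
                        k_int = ki, PF = NA_real_, log10_PF = NA_real_,
                        censored = NA, flag = "no signal"))
    }
    pf <- protection_factor(ki, f$k_obs, censored = f$censored,
                            k_obs_err = if (is.null(f$k_err)) NA else f$k_err)
    data.frame(res_num = rn, k_obs = f$k_obs,
               k_obs_err = ifelse(is.null(f$k_err), NA_real_, f$k_err),
               k_int = ki, PF = pf$PF, log10_PF = pf$log10_PF,
               censored = f$censored,
               flag = if (f$censored) "censored" else "ok")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare protection factors between two states
#'
#' Per-residue log10(PF_B / PF_A) over the overlapping residues, with
#' censored lower bounds propagated: when only state B is censored the
#' difference is a lower bound, when only A is censored an upper bound, and
#' when both are censored it is indeterminate.
#'
#' @param pf_a,pf_b protection-factor tables from [hdx_protection()]
#'   (states A and B)
#' @return list with `per_residue` (res_num, log10_PF_a, log10_PF_b,
#'   delta_log10_PF, bound) and `summary` (counts of increased / decreased /
#'   unchanged / censored pairs, median delta)
#' @export
compare_states <- function(pf_a, pf_b) {
  common <- intersect(pf_a$res_num, pf_b$res_num)
  if (length(common) == 0) stop("no overlapping residues between the two states")
  a <- pf_a[match(common, pf_a$res_num), ]
  b <- pf_b[match(common, pf_b$res_num), ]
  delta <- b$log10_PF - a$log10_PF
  bound <- rep("exact", length(common))
  bound[b$censored & !a$censored] <- "lower"
  bound[a$censored & !b$censored] <- "upper"
  bound[a$censored & b$censored] <- "indeterminate"
  per <- data.frame(res_num = common,
                    log10_PF_a = a$log10_PF, log10_PF_b = b$log10_PF,
                    delta_log10_PF = delta, bound = bound)
  usable <- bound != "indeterminate"
  list(per_residue = per,
       summary = list(
         n = length(common),
         increased = sum(delta[usable] > 0),
         decreased = sum(delta[usable] < 0),
         unchanged = sum(delta[usable] == 0),
         censored_pairs = sum(!usable),
         median_delta = stats::median(delta[usable])))
}
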