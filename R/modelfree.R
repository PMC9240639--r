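## Per-residue Lipari-Szabo model fitting, model selection, Monte-Carlo
## uncertainties and exchange classification.

# model definitions: free parameters, in fitting units. The internal
# correlation time is optimized as log10(tau_e / ns) ("log_te"): model-free
# internal times span ps to ns, and the chi2 surface has a well-known
# spurious minimum at (S2 = 1, tau_e ~ tau_c) that a linear grid falls into.
.mf_models <- list(
  M1 = c("S2"),
  M2 = c("S2", "log_te"),
  M3 = c("S2", "Rex"),
  M4 = c("S2", "log_te", "Rex"),
  # extended model: S2 = Sf2 * Ss2, slow internal time tau_s in tau_e slot
  M5 = c("Sf2", "Ss2", "log_te")
)

# assemble dynamics_params from a named free-parameter vector
.mf_params <- function(theta, model_id, tau_c) {
  te <- if ("log_te" %in% names(theta)) 10^theta[["log_te"]] * 1e-9 else 0
  rex <- if ("Rex" %in% names(theta)) theta[["Rex"]] else 0
  if (model_id == "M5") {
    sf2 <- theta[["Sf2"]]
    s2 <- sf2 * theta[["Ss2"]]
  } else {
    sf2 <- 1
    s2 <- theta[["S2"]]
  }
  dynamics_params(S2 = min(max(s2, 0), sf2), tau_c = tau_c, tau_e = te,
                  Rex = max(rex, 0), Sf2 = sf2, model_id = model_id)
}

.mf_bounds <- function(pars, tau_c) {
  # log_te lower bound of -3 (1 ps) is effectively tau_e = 0 for rates
  lo <- c(S2 = 0, Sf2 = 0, Ss2 = 0, log_te = -3, Rex = 0)
  hi <- c(S2 = 1, Sf2 = 1, Ss2 = 1,
          log_te = log10(0.999 * tau_c * 1e9), Rex = 50)
  list(lower = lo[pars], upper = hi[pars])
}

.mf_chi2 <- function(theta, model_id, tau_c, obs, sigma, const) {
  te <- if ("log_te" %in% names(theta)) 10^theta[["log_te"]] * 1e-9 else 0
  rex <- if ("Rex" %in% names(theta)) theta[["Rex"]] else 0
  if (model_id == "M5") {
    sf2 <- theta[["Sf2"]]
    s2 <- sf2 * theta[["Ss2"]]
  } else {
    sf2 <- 1
    s2 <- theta[["S2"]]
  }
  calc <- .rates_fast(s2, tau_c, te, rex, sf2, const)
  sum(((obs - calc) / sigma)^2)
}

#' Fit one Lipari-Szabo model to a residue's relaxation data
#'
#' Minimizes chi2 = sum(((obs - calc)/sigma)^2) over the model's free
#' parameters with tau_c held fixed (two-stage procedure: tau_c comes from
#' [estimate_tauc()]). Candidate models: M1 \{S2\}, M2 \{S2, tau_e\},
#' M3 \{S2, Rex\}, M4 \{S2, tau_e, Rex\}, M5 \{Sf2, S2, tau_s\}.
#' Parameters are bounded (S2, Sf2 in \[0,1\], tau_e in \[0, tau_c),
#' Rex in \[0, 50\] s^-1). A fixed multi-start grid (`grid_n` points per
#' free parameter, fixed ordering) precedes bounded quasi-Newton
#' refinement, so the fit is deterministic.
#'
#' @param record one-row data.frame with columns R1, R1_err, R2, R2_err,
#'   NOE, NOE_err (and optionally res_num)
#' @param tau_c fixed overall correlation time, seconds
#' @param model_id one of "M1".."M5"
#' @param const [spin_constants()]
#' @param grid_n multi-start grid points per free parameter (default 5)
#' @return object of class `mf_fit`: list with `params`
#'   ([dynamics_params()] or NULL on non-convergence), `chi2`, `n_obs`,
#'   `n_par`, `model_id`, `converged`, `saturated` (n_par == n_obs)
#' @export
fit_residue <- function(record, tau_c, model_id, const, grid_n = 5) {
  stopifnot(model_id %in% names(.mf_models))
  obs <- c(R1 = record$R1[1], R2 = record$R2[1], NOE = record$NOE[1])
  sigma <- c(record$R1_err[1], record$R2_err[1], record$NOE_err[1])
  if (any(!is.finite(obs)) || any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("fit_residue needs finite observations and positive uncertainties")
  }
  pars <- .mf_models[[model_id]]
  b <- .mf_bounds(pars, tau_c)
  n_par <- length(pars)

  # deterministic multi-start grid over interior points of each bound
  axes <- lapply(pars, function(p) {
    lo <- b$lower[[p]]; hi <- b$upper[[p]]
    seq(lo + 0.05 * (hi - lo), hi - 0.05 * (hi - lo), length.out = grid_n)
  })
  grid <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- pars
  f <- function(th) {
    names(th) <- pars
    .mf_chi2(th, model_id, tau_c, obs, sigma, const)
  }
  grid_chi2 <- apply(grid, 1, f)
  starts <- grid[order(grid_chi2)[seq_len(min(5, nrow(grid)))], , drop = FALSE]

  best <- NULL
  for (k in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[k, ], f, method = "L-BFGS-B",
                   lower = b$lower, upper = b$upper,
                   control = list(factr = 1e2, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(params = NULL, chi2 = NA_real_, n_obs = 3L,
                          n_par = n_par, model_id = model_id,
                          converged = FALSE, saturated = n_par == 3L),
                     class = "mf_fit"))
  }
  theta <- best$par
  names(theta) <- pars
  structure(list(params = .mf_params(theta, model_id, tau_c),
                 chi2 = best$value, n_obs = 3L, n_par = n_par,
                 model_id = model_id, converged = TRUE,
                 saturated = n_par == 3L),
            class = "mf_fit")
}

#' Select the best model-free model for a residue
#'
#' Candidate fits are ranked by a small-sample-corrected information score,
#' AICc = chi2 + 2k + 2k(k+1)/(n - k - 1). With single-field data (n = 3
#' observables) the correction term is undefined for k >= 2, so whenever
#' any candidate has n - k - 1 <= 0 the plain AIC = chi2 + 2k is used for
#' all candidates, keeping the ranking consistent. Ties are broken toward
#' the model with fewer parameters.
#'
#' @param fits list of `mf_fit` objects for one residue (>= 2 candidates)
#' @return list with `model_id` of the winner, `scores` (named numeric),
#'   and `criterion` ("AICc" or "AIC"); `model_id` is NA if all fits failed
#' @export
select_model <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 2)
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(ok)) {
    return(list(model_id = NA_character_, scores = NULL, criterion = NA_character_))
  }
  fits <- fits[ok]
  k <- vapply(fits, function(f) f$n_par, numeric(1))
  n <- vapply(fits, function(f) f$n_obs, numeric(1))
  chi2 <- vapply(fits, function(f) f$chi2, numeric(1))
  ids <- vapply(fits, function(f) f$model_id, character(1))
  if (any(n - k - 1 <= 0)) {
    crit <- "AIC"
    score <- chi2 + 2 * k
  } else {
    crit <- "AICc"
    score <- chi2 + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  }
  names(score) <- ids
  best <- min(score)
  eligible <- which(score <= best + 1e-9)
  winner <- eligible[which.min(k[eligible])]
  list(model_id = ids[winner], scores = score, criterion = crit)
}

# run expr with a temporary RNG state seeded by `seed`; restores global state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Monte-Carlo parameter uncertainties for a fitted residue
#'
#' Draws `n_draws` synthetic observation triples from
#' Normal(obs, sigma_obs), refits the selected model to each (starting the
#' bounded minimization from the best-fit values), and reports the standard
#' deviation of each fitted parameter. Reproducible for a fixed seed; the
#' global RNG state is left untouched.
#'
#' @param record one-row data.frame as for [fit_residue()]
#' @param fit converged `mf_fit` for the chosen model
#' @param tau_c fixed overall correlation time, seconds
#' @param const [spin_constants()]
#' @param n_draws number of synthetic datasets (>= 100)
#' @param seed integer seed
#' @return named numeric vector of parameter SDs (S2, and tau_e_ns / Rex /
#'   Sf2 as applicable)
#' @export
monte_carlo_errors <- function(record, fit, tau_c, const, n_draws = 200, seed = 1) {
  stopifnot(inherits(fit, "mf_fit"))
  if (!isTRUE(fit$converged)) stop("monte_carlo_errors requires a converged fit")
  if (n_draws < 100) stop("n_draws must be >= 100")
  pars <- .mf_models[[fit$model_id]]
  b <- .mf_bounds(pars, tau_c)
  obs <- c(record$R1[1], record$R2[1], record$NOE[1])
  sigma <- c(record$R1_err[1], record$R2_err[1], record$NOE_err[1])

  p <- fit$params
  start <- c(S2 = p$S2, Sf2 = p$Sf2,
             Ss2 = if (p$Sf2 > 0) p$S2 / p$Sf2 else 0,
             log_te = log10(max(p$tau_e * 1e9, 1e-3)),
             Rex = p$Rex)[pars]
  # keep the start strictly inside the bounds
  start <- pmin(pmax(start, b$lower + 1e-6), b$upper - 1e-6)

  draws <- with_seed(seed, matrix(stats::rnorm(3 * n_draws, mean = rep(obs, n_draws),
                                               sd = rep(sigma, n_draws)),
                                  ncol = 3, byrow = TRUE))
  # SDs are reported for the natural parameters (tau_e in ns, not its log)
  nat_names <- c("S2", if ("log_te" %in% pars) "tau_e_ns",
                 if ("Rex" %in% pars) "Rex",
                 if ("Sf2" %in% pars) "Sf2")
  res <- matrix(NA_real_, nrow = n_draws, ncol = length(nat_names),
                dimnames = list(NULL, nat_names))
  n_fail <- 0L
  for (i in seq_len(n_draws)) {
    oi <- draws[i, ]
    f <- function(th) {
      names(th) <- pars
      .mf_chi2(th, fit$model_id, tau_c, oi, sigma, const)
    }
    o <- tryCatch(stats::optim(start, f, method = "L-BFGS-B",
                               lower = b$lower, upper = b$upper,
                               control = list(factr = 1e4, maxit = 200)),
                  error = function(e) NULL)
    if (is.null(o)) {
      n_fail <- n_fail + 1L
    } else {
      th <- o$par
      names(th) <- pars
      pp <- .mf_params(th, fit$model_id, tau_c)
      res[i, "S2"] <- pp$S2
      if ("tau_e_ns" %in% nat_names) res[i, "tau_e_ns"] <- pp$tau_e * 1e9
      if ("Rex" %in% nat_names) res[i, "Rex"] <- pp$Rex
      if ("Sf2" %in% nat_names) res[i, "Sf2"] <- pp$Sf2
    }
  }
  if (n_fail > 0.2 * n_draws) {
    rn <- if ("res_num" %in% names(record)) record$res_num[1] else NA
    stop(sprintf("Monte-Carlo refits failed for residue %s (%d of %d draws)",
                 rn, n_fail, n_draws))
  }
  apply(res, 2, stats::sd, na.rm = TRUE)
}

#' Classify residues as undergoing conformational exchange
#'
#' A residue is labelled as undergoing millisecond-timescale conformational
#' exchange if and only if its fitted Rex strictly exceeds the threshold
#' (default 2 s^-1); a residue at exactly the threshold is not flagged.
#'
#' @param rex numeric vector of fitted Rex values (s^-1); NA allowed
#' @param threshold Rex threshold in s^-1 (default 2)
#' @return character vector: "conformational exchange" / "none" (NA for NA)
#' @examples
#' classify_exchange(c(0, 2, 2.5))
#' @export
classify_exchange <- function(rex, threshold = 2) {
  out <- ifelse(rex > threshold, "conformational exchange", "none")
  out[!is.finite(rex)] <- NA_character_
  out
}

#' Model-free analysis of a relaxation table
#'
#' Per-residue driver: fits each candidate model, selects the winner by
#' [select_model()], optionally estimates Monte-Carlo uncertainties, and
#' classifies exchange. tau_c is held fixed throughout (two-stage
#' procedure).
#'
#' @param records data.frame with columns res_num, R1, R1_err, R2, R2_err,
#'   NOE, NOE_err (see [read_relaxation_table()])
#' @param tau_c overall correlation time in seconds (e.g. from
#'   [estimate_tauc()])
#' @param const [spin_constants()]
#' @param models candidate model ids (default M1-M4)
#' @param mc_draws Monte-Carlo draws per residue for uncertainties
#'   (0 = skip, default)
#' @param seed seed for the Monte-Carlo stage
#' @param rex_threshold threshold for [classify_exchange()]
#' @return data.frame with one row per residue: res_num, model, S2, S2_err,
#'   tau_e_ps, tau_e_err_ps, Rex, Rex_err, chi2, exchange, flags
#' @export
fit_modelfree <- function(records, tau_c, const,
                          models = c("M1", "M2", "M3", "M4"),
                          mc_draws = 0, seed = 1, rex_threshold = 2) {
  stopifnot(is.data.frame(records), all(models %in% names(.mf_models)))
  rows <- lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, , drop = FALSE]
    if (!all(is.finite(c(rec$R1, rec$R2, rec$NOE)))) {
      return(data.frame(res_num = rec$res_num, model = NA_character_,
                        S2 = NA_real_, S2_err = NA_real_,
                        tau_e_ps = NA_real_, tau_e_err_ps = NA_real_,
                        Rex = NA_real_, Rex_err = NA_real_,
                        chi2 = NA_real_, flags = "missing data"))
    }
    fits <- lapply(models, function(m) fit_residue(rec, tau_c, m, const))
    sel <- select_model(fits)
    if (is.na(sel$model_id)) {
      return(data.frame(res_num = rec$res_num, model = NA_character_,
                        S2 = NA_real_, S2_err = NA_real_,
                        tau_e_ps = NA_real_, tau_e_err_ps = NA_real_,
                        Rex = NA_real_, Rex_err = NA_real_,
                        chi2 = NA_real_, flags = "unassigned"))
    }
    best <- fits[[match(sel$model_id, models)]]
    p <- best$params
    errs <- c(S2 = NA_real_, tau_e_ns = NA_real_, Rex = NA_real_)
    if (mc_draws >= 100) {
      mc <- monte_carlo_errors(rec, best, tau_c, const,
                               n_draws = mc_draws,
                               seed = seed + rec$res_num)
      errs[intersect(names(mc), names(errs))] <-
        mc[intersect(names(mc), names(errs))]
    }
    flags <- character(0)
    if (best$saturated) flags <- c(flags, "saturated")
    data.frame(res_num = rec$res_num, model = sel$model_id,
               S2 = p$S2, S2_err = errs[["S2"]],
               tau_e_ps = p$tau_e * 1e12,
               tau_e_err_ps = errs[["tau_e_ns"]] * 1e3,
               Rex = p$Rex, Rex_err = errs[["Rex"]],
               chi2 = best$chi2,
               flags = if (length(flags)) paste(flags, collapse = ";") else "")
  })
  out <- do.call(rbind, rows)
  out$exchange <- classify_exchange(out$Rex, rex_threshold)
  rownames(out) <- NULL
  out
}
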