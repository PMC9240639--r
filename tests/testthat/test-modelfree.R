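test_that("tau_c estimation inverts the forward model exactly for a rigid residue", {
  df <- mk_record(S2 = 1, tau_c = 10.4e-9)
  est <- estimate_tauc(df, SC700)
  expect_equal(est$tau_c, 10.4e-9, tolerance = 1e-3)
  expect_equal(est$n_used, 1L)
})

test_that("tau_c estimation recovers truth within 2% from a noisy rigid set", {
  df <- mk_rigid_table(100, tau_c = 12.5e-9, seed = 11)
  est <- estimate_tauc(df, SC700)
  expect_equal(est$tau_c, 12.5e-9, tolerance = 0.02)
  expect_gt(est$n_used, 50)
})

test_that("tau_c estimation fails informatively when all residues are flexible", {
  df <- mk_rigid_table(5, tau_c = 10e-9, seed = 2)
  df$NOE <- 0.2
  expect_error(estimate_tauc(df, SC700), "no rigid residues")
})

test_that("tau_c estimation records exclusions with reasons", {
  df <- mk_rigid_table(30, tau_c = 10e-9, seed = 3)
  df$NOE[1] <- 0.1                 # flexible
  df$R2[2] <- df$R2[2] * 1.6       # exchange-broadened ratio outlier
  est <- estimate_tauc(df, SC700)
  expect_true(any(est$excluded$res_num == 1 &
                  est$excluded$reason == "NOE below cutoff"))
  expect_true(any(est$excluded$res_num == 2 &
                  est$excluded$reason == "ratio outlier"))
})

test_that("tau_c estimate is invariant to duplicating every record", {
  df <- mk_rigid_table(40, tau_c = 9e-9, seed = 4)
  est1 <- estimate_tauc(df, SC700)
  est2 <- estimate_tauc(rbind(df, df), SC700)
  expect_equal(est2$tau_c, est1$tau_c, tolerance = 1e-12)
})

test_that("noiseless single-model fits recover generating parameters", {
  tc <- 10e-9
  # M2 round trip
  f2 <- fit_residue(mk_record(0.85, tc, tau_e = 50e-12), tc, "M2", SC700)
  expect_equal(f2$params$S2, 0.85, tolerance = 1e-4)
  expect_equal(f2$params$tau_e, 50e-12, tolerance = 1e-4)
  # rigid data with M1 is exact
  f1 <- fit_residue(mk_record(1, tc), tc, "M1", SC700)
  expect_equal(f1$params$S2, 1, tolerance = 1e-6)
  expect_lt(f1$chi2, 1e-10)
  # additivity: R2 inflated by +4 fitted with M3 absorbs it as Rex
  rec <- mk_record(0.85, tc)
  rec$R2 <- rec$R2 + 4
  f3 <- fit_residue(rec, tc, "M3", SC700)
  expect_equal(f3$params$Rex, 4, tolerance = 1e-3)
  expect_equal(f3$params$S2, 0.85, tolerance = 1e-3)
})

test_that("model selection picks the generating model", {
  tc <- 10e-9
  models <- c("M1", "M2", "M3", "M4")
  # noiseless M1 data -> M1 (ties broken toward fewer parameters)
  fits <- lapply(models, function(m) fit_residue(mk_record(0.9, tc), tc, m, SC700))
  expect_identical(select_model(fits)$model_id, "M1")
  # M3 data with Rex = 6 at 2% noise -> M3 or M4, fitted Rex > 2
  set.seed(7)
  rec <- mk_record(0.85, tc, rex = 6)
  rec$R1 <- rnorm(1, rec$R1, rec$R1_err)
  rec$R2 <- rnorm(1, rec$R2, rec$R2_err)
  rec$NOE <- rnorm(1, rec$NOE, rec$NOE_err)
  fits <- lapply(models, function(m) fit_residue(rec, tc, m, SC700))
  sel <- select_model(fits)
  expect_true(sel$model_id %in% c("M3", "M4"))
  best <- fits[[match(sel$model_id, models)]]
  expect_gt(best$params$Rex, 2)
})

test_that("the simplest model wins for the majority of noisy rigid-core residues", {
  tc <- 10e-9
  set.seed(21)
  n <- 60
  picks <- vapply(seq_len(n), function(i) {
    rec <- mk_record(runif(1, 0.8, 0.95), tc)
    rec$R1 <- rnorm(1, rec$R1, rec$R1_err)
    rec$R2 <- rnorm(1, rec$R2, rec$R2_err)
    rec$NOE <- rnorm(1, rec$NOE, rec$NOE_err)
    fits <- lapply(c("M1", "M2", "M3", "M4"),
                   function(m) fit_residue(rec, tc, m, SC700))
    select_model(fits)$model_id
  }, character(1))
  expect_gt(mean(picks == "M1"), 0.5)
})

test_that("S2 recovery error stays small at 2% noise for core-like residues", {
  tc <- 10.4e-9
  set.seed(31)
  n <- 40
  s2_true <- runif(n, 0.7, 0.95)
  te_true <- runif(n, 20e-12, 80e-12)
  err <- vapply(seq_len(n), function(i) {
    rec <- mk_record(s2_true[i], tc, tau_e = te_true[i])
    rec$R1 <- rnorm(1, rec$R1, rec$R1_err)
    rec$R2 <- rnorm(1, rec$R2, rec$R2_err)
    rec$NOE <- rnorm(1, rec$NOE, rec$NOE_err)
    fits <- lapply(c("M1", "M2", "M3", "M4"),
                   function(m) fit_residue(rec, tc, m, SC700))
    sel <- select_model(fits)
    abs(fits[[match(sel$model_id, c("M1", "M2", "M3", "M4"))]]$params$S2 -
          s2_true[i])
  }, numeric(1))
  expect_lt(median(err), 0.05)
})

test_that("Monte-Carlo uncertainties are reproducible and track real scatter", {
  tc <- 10e-9
  rec <- mk_record(0.85, tc, tau_e = 50e-12)
  set.seed(5)
  rec$R1 <- rnorm(1, rec$R1, rec$R1_err)
  rec$R2 <- rnorm(1, rec$R2, rec$R2_err)
  rec$NOE <- rnorm(1, rec$NOE, rec$NOE_err)
  fit <- fit_residue(rec, tc, "M2", SC700)
  # determinism for a fixed seed
  sd1 <- monte_carlo_errors(rec, fit, tc, SC700, n_draws = 150, seed = 9)
  sd2 <- monte_carlo_errors(rec, fit, tc, SC700, n_draws = 150, seed = 9)
  expect_identical(sd1, sd2)
  # near-zero observation noise gives near-zero parameter SDs
  rec0 <- mk_record(0.85, tc, tau_e = 50e-12)
  rec0$R1_err <- 1e-9 * rec0$R1
  rec0$R2_err <- 1e-9 * rec0$R2
  rec0$NOE_err <- 1e-9
  fit0 <- fit_residue(rec0, tc, "M2", SC700)
  sd0 <- monte_carlo_errors(rec0, fit0, tc, SC700, n_draws = 100, seed = 1)
  expect_lt(sd0[["S2"]], 1e-6)
  # MC SD of S2 within a factor 1.5 of the SD over independent regenerations
  mc <- monte_carlo_errors(rec, fit, tc, SC700, n_draws = 400, seed = 13)
  set.seed(77)
  clean <- mk_record(0.85, tc, tau_e = 50e-12)
  s2s <- vapply(1:50, function(i) {
    ri <- clean
    ri$R1 <- rnorm(1, clean$R1, clean$R1_err)
    ri$R2 <- rnorm(1, clean$R2, clean$R2_err)
    ri$NOE <- rnorm(1, clean$NOE, clean$NOE_err)
    fit_residue(ri, tc, "M2", SC700)$params$S2
  }, numeric(1))
  ratio <- mc[["S2"]] / sd(s2s)
  expect_gt(ratio, 1 / 1.5)
  expect_lt(ratio, 1.5)
})

test_that("exchange classification uses a strict threshold", {
  expect_identical(classify_exchange(2.5), "conformational exchange")
  expect_identical(classify_exchange(0), "none")
  expect_identical(classify_exchange(2.0), "none")  # exactly at threshold
  expect_identical(classify_exchange(c(NA, 3))[1], NA_character_)
})

test_that("the per-residue driver returns the documented table", {
  scn <- make_scenario("apo", seed = 2)
  idx <- c(1:4, 100:103, 210:213)  # tail, core, loop samples
  scn$truth <- scn$truth[idx, ]
  rel <- simulate_relaxation(scn)
  out <- fit_modelfree(rel, scn$tau_c, SC700)
  expect_identical(nrow(out), length(idx))
  expect_true(all(c("res_num", "model", "S2", "tau_e_ps", "Rex", "chi2",
                    "exchange", "flags") %in% names(out)))
  expect_true(all(out$S2 >= 0 & out$S2 <= 1, na.rm = TRUE))
  # missing data propagates as a flagged row, not a failure
  rel$R1[1] <- NA
  out2 <- fit_modelfree(rel, scn$tau_c, SC700)
  expect_identical(out2$flags[1], "missing data")
})
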