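test_that("intrinsic rates match an independent evaluation of the bundled tables", {
  # independent code path: raw arithmetic straight from the parameter file
  tab <- read.delim(system.file("extdata", "bai1993_exchange_params.tsv",
                                package = "nmrdyn"), comment.char = "#")
  rownames(tab) <- tab$aa
  oracle <- function(res, left, pD, TK, nterm = FALSE, cterm = FALSE) {
    la <- tab[res, "acid_lambda"] + if (cterm) tab["CT", "acid_lambda"] else 0
    lb <- tab[res, "base_lambda"] + if (cterm) tab["CT", "base_lambda"] else 0
    ra <- tab[left, "acid_rho"] + if (nterm) tab["NT", "acid_rho"] else 0
    rb <- tab[left, "base_rho"] + if (nterm) tab["NT", "base_rho"] else 0
    R <- 1.987204e-3
    arr <- function(Ea) exp(-(Ea / R) * (1 / TK - 1 / 293))
    (10^(1.62 + la + ra - pD) * arr(14) +
     10^(10.05 + lb + rb + pD - 15.05) * arr(17) +
     10^(-1.5 + lb + rb) * arr(19)) / 60
  }
  # internal alanine at pH 7, 308 K
  expect_equal(intrinsic_rate("AAAAA", 3, 7.0, 308),
               oracle("A", "A", 7.0, 308), tolerance = 1e-12)
  # side-chain and neighbour corrections (internal Gly after Thr)
  expect_equal(intrinsic_rate("ATGKA", 3, 7.0, 308),
               oracle("G", "T", 7.0, 308), tolerance = 1e-12)
  # terminal corrections at both ends
  expect_equal(intrinsic_rate("KLVA", 2, 7.0, 308),
               oracle("L", "K", 7.0, 308, nterm = TRUE), tolerance = 1e-12)
  expect_equal(intrinsic_rate("KLVA", 4, 7.0, 308),
               oracle("A", "V", 7.0, 308, cterm = TRUE), tolerance = 1e-12)
})

test_that("intrinsic rates are pure, base-catalyzed near neutral pH, and monotone", {
  k7 <- intrinsic_rate("AAAAA", 3, 7.0, 308)
  expect_identical(intrinsic_rate("AAAAA", 3, 7.0, 308), k7)  # purity
  # first order in OD-: one pH unit ~ 10x in the base regime
  expect_equal(intrinsic_rate("AAAAA", 3, 8.0, 308) / k7, 10, tolerance = 0.01)
  # increasing in temperature, and in pH above ~5
  for (TK in c(288, 298, 303)) {
    expect_lt(intrinsic_rate("AAAAA", 3, 7.0, TK), k7)
  }
  ph <- c(5.5, 6.5, 7.5, 8.5)
  ks <- vapply(ph, function(p) intrinsic_rate("AAAAA", 3, p, 308), numeric(1))
  expect_true(all(diff(ks) > 0))
  # failure modes name the culprit
  expect_error(intrinsic_rate("AXA", 2, 7, 308), "X")
  expect_error(intrinsic_rate("APA", 2, 7, 308), "proline")
  expect_error(intrinsic_rate("AAA", 1, 7, 308), "amide")
})

test_that("exchange-rate fitting recovers exact and noisy exponentials", {
  t <- seq(0, 900, length.out = 10)
  f <- fit_exchange_rate(t, 100 * exp(-0.01 * t))
  expect_equal(f$k_obs, 0.01, tolerance = 1e-8)
  expect_false(f$censored)
  # noisy decay within 15%
  set.seed(8)
  t2 <- seq(0, 5000, length.out = 12)
  I2 <- 100 * exp(-1e-3 * t2) + rnorm(12, 0, 5)
  f2 <- fit_exchange_rate(t2, I2)
  expect_equal(f2$k_obs, 1e-3, tolerance = 0.15)
  # constant series with noise is censored at the documented bound
  set.seed(9)
  t3 <- seq(600, 86400, length.out = 8)
  f3 <- fit_exchange_rate(t3, 100 + rnorm(8, 0, 1))
  expect_true(f3$censored)
  expect_equal(f3$k_obs, log(1 / 0.95) / 86400, tolerance = 1e-12)
  # failure modes
  expect_error(fit_exchange_rate(t[1:2], c(1, 2)), "3 time points")
  expect_error(fit_exchange_rate(t3, rep(0, 8)), "non-positive")
})

test_that("protection factors behave at the limits and under rescaling", {
  expect_equal(protection_factor(0.5, 0.5)$PF, 1)
  expect_equal(protection_factor(0.5, 0.5)$log10_PF, 0)
  expect_equal(protection_factor(10, 1e-3)$PF, 1e4)
  expect_warning(protection_factor(0.01, 0.5), "10x")
  # PF invariant to scaling the intensity series by a positive constant
  t <- seq(0, 4000, length.out = 10)
  I <- 100 * exp(-2e-3 * t)
  for (scale in c(0.01, 7, 1e4)) {
    f1 <- fit_exchange_rate(t, I)
    f2 <- fit_exchange_rate(t, scale * I)
    expect_equal(protection_factor(1, f2$k_obs)$PF,
                 protection_factor(1, f1$k_obs)$PF, tolerance = 1e-6)
  }
  # time-unit invariance: t in hours with k in h^-1 gives the same PF
  fs <- fit_exchange_rate(t, I)                  # seconds
  fh <- fit_exchange_rate(t / 3600, I)           # hours
  expect_equal(1 / (fh$k_obs / 3600), 1 / fs$k_obs, tolerance = 1e-6)
})

test_that("state comparison counts and propagates censoring", {
  pf <- data.frame(res_num = 1:10, log10_PF = rnorm(10), censored = FALSE)
  same <- compare_states(pf, pf)
  expect_true(all(same$per_residue$delta_log10_PF == 0))
  # complex 10x apo -> median delta exactly 1
  pf_b <- pf
  pf_b$log10_PF <- pf$log10_PF + 1
  cmp <- compare_states(pf, pf_b)
  expect_equal(cmp$summary$median_delta, 1)
  expect_identical(cmp$summary$increased, 10L)
  # censoring in one state marks the pair as a bound
  pf_b$censored[1] <- TRUE
  cmp2 <- compare_states(pf, pf_b)
  expect_identical(cmp2$per_residue$bound[1], "lower")
  # empty overlap fails
  pf_c <- pf
  pf_c$res_num <- 11:20
  expect_error(compare_states(pf, pf_c), "overlap")
})
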