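test_that("scenarios are reproducible and respect their construction", {
  s1 <- make_scenario("apo", seed = 1)
  s2 <- make_scenario("apo", seed = 1)
  expect_identical(s1, s2)
  expect_false(identical(s1, make_scenario("apo", seed = 2)))
  # disordered tail sits below the core in the apo truth
  tail_s2 <- s1$truth$S2[s1$segments$tail]
  core_s2 <- s1$truth$S2[s1$segments$core]
  expect_lt(max(tail_s2), min(core_s2))
  # the mobile loop stays mobile in the complex preset
  sc <- make_scenario("complex", seed = 1)
  expect_lt(max(sc$truth$S2[sc$segments$loop]), min(sc$truth$S2[sc$segments$core]))
  # apo tumbles slower than complex and its tail is far more mobile
  expect_gt(s1$tau_c, sc$tau_c)
  expect_gt(mean(sc$truth$S2[sc$segments$tail]) -
              mean(s1$truth$S2[s1$segments$tail]), 0.3)
})

test_that("tail order parameters sit below the core across seeds (truth)", {
  for (seed in 1:20) {
    s <- make_scenario("apo", seed = seed)
    expect_lt(mean(s$truth$S2[s$segments$tail]),
              mean(s$truth$S2[s$segments$core]))
  }
})

test_that("simulated relaxation equals the forward model when noise is off", {
  scn <- make_scenario("complex", seed = 3)
  scn$truth <- scn$truth[c(5, 60, 210), ]
  tab <- simulate_relaxation(scn, add_noise = FALSE)
  const <- spin_constants(scn$field_MHz)
  for (i in seq_len(nrow(tab))) {
    tr <- scn$truth[i, ]
    expected <- predict_rates(dynamics_params(S2 = tr$S2, tau_c = scn$tau_c,
                                              tau_e = tr$tau_e, Rex = tr$Rex),
                              const)
    expect_equal(tab$R1[i], unname(expected["R1"]), tolerance = 1e-14)
    expect_equal(tab$R2[i], unname(expected["R2"]), tolerance = 1e-14)
    expect_equal(tab$NOE[i], unname(expected["NOE"]), tolerance = 1e-14)
  }
})

test_that("injected noise has the requested standard deviation", {
  scn <- make_scenario("apo", seed = 4)
  scn$truth <- scn$truth[100, , drop = FALSE]   # one core residue
  draws <- vapply(seq_len(1e4), function(i) {
    simulate_relaxation(scn, seed = i)$R1
  }, numeric(1))
  clean <- simulate_relaxation(scn, add_noise = FALSE)
  expect_equal(sd(draws), 0.02 * clean$R1, tolerance = 0.03)
  expect_equal(mean(draws), clean$R1, tolerance = 0.01)
})

test_that("simulated HDX encodes the truth protection factors", {
  scn <- make_scenario("apo", seed = 5)
  # core residues: protected enough to survive until the first time point
  scn$truth <- scn$truth[60:100, ]
  sim <- simulate_hdx(scn, noise_sd = 0)
  # PF = 1 residues decay at k_int by construction
  expect_equal(sim$truth$k_obs, sim$truth$k_int / sim$truth$PF)
  # round trip through the fitting pipeline recovers measurable PFs to <1%
  pf <- hdx_protection(sim$data, scn$sequence)
  ok <- pf$flag == "ok"
  m <- merge(pf[ok, ], sim$truth, by = "res_num", suffixes = c("", ".t"))
  expect_gt(nrow(m), 10)
  expect_lt(max(abs(m$PF - m$PF.t) / m$PF.t), 0.01)
})

test_that("a hugely protected residue is censored on a 24 h grid", {
  scn <- make_scenario("complex", seed = 6)
  scn$truth <- scn$truth[100, , drop = FALSE]
  # protection strong enough that <5% of the signal decays within 24 h
  k_int <- intrinsic_rate(scn$sequence, 100, 7.0, 308)
  pf_true <- k_int * 1e7
  scn$truth$PF <- pf_true
  suppressWarnings(sim <- simulate_hdx(scn, noise_sd = 1, seed = 3))
  pf <- hdx_protection(sim$data, scn$sequence)
  expect_identical(pf$flag, "censored")
  expect_true(pf$censored)
  # the censored PF is a lower bound below the true value
  expect_lt(pf$PF, pf_true)
})

test_that("end-to-end synthetic pipeline reproduces the two-state signature", {
  const <- SC700
  idx <- c(2:13, 110:121)           # 12 tail + 12 core residues
  for (seed in 1:5) {
    res <- lapply(c("apo", "complex"), function(preset) {
      scn <- make_scenario(preset, seed = seed)
      rel_full <- simulate_relaxation(scn)
      tc <- estimate_tauc(rel_full, const)$tau_c
      scn$truth <- scn$truth[idx, ]
      fits <- fit_modelfree(simulate_relaxation(scn), tc, const)
      list(tc = tc, fits = fits, scn = scn)
    })
    apo <- res[[1]]; cplx <- res[[2]]
    # apo tumbles slower
    expect_gt(apo$tc, cplx$tc)
    # fitted tail S2 below fitted core S2 for apo; not so depressed in complex
    tail_rows <- apo$fits$res_num <= 51
    expect_lt(mean(apo$fits$S2[tail_rows], na.rm = TRUE),
              mean(apo$fits$S2[!tail_rows], na.rm = TRUE) - 0.3)
    expect_gt(mean(cplx$fits$S2[cplx$fits$res_num <= 51], na.rm = TRUE), 0.7)
    # exchange labels concentrate on Rex-bearing residues
    truth_rex <- apo$scn$truth$Rex > 2
    labelled <- apo$fits$exchange == "conformational exchange"
    expect_true(all(labelled[truth_rex]))
    expect_lt(mean(labelled[!truth_rex]), 0.2)
  }
})
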