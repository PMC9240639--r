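test_that("spectral density matches closed forms and the high-precision oracle", {
  p_rigid <- dynamics_params(S2 = 1, tau_c = 10e-9)
  # rigid limit at omega = 0: (2/5) tau_c
  expect_equal(spectral_density(p_rigid, 0), 4.0e-9)
  # Lorentzian half-height at omega = 1/tau_c
  expect_equal(spectral_density(p_rigid, 1 / 10e-9), 2.0e-9)
  # 50-digit independent evaluation of the two-term formula at omega_N
  p <- dynamics_params(S2 = 0.85, tau_c = 10e-9, tau_e = 50e-12)
  expect_equal(spectral_density(p, SC700$omega_N), 1.6575056672533902e-10,
               tolerance = 1e-12)
})

test_that("spectral density is positive and strictly decreasing in omega", {
  set.seed(42)
  for (i in 1:20) {
    p <- dynamics_params(S2 = runif(1, 0.2, 1), tau_c = runif(1, 2e-9, 20e-9),
                         tau_e = runif(1, 0, 1e-9))
    w <- sort(runif(50, 0, 1e10))
    J <- spectral_density(p, w)
    expect_true(all(J > 0))
    expect_true(all(diff(J) < 0))
  }
})

test_that("parameter validation names the offending field", {
  expect_error(dynamics_params(S2 = 1.2, tau_c = 1e-8), "S2")
  expect_error(dynamics_params(S2 = 0.5, tau_c = -1e-8), "tau_c")
  expect_error(dynamics_params(S2 = 0.5, tau_c = 1e-8, tau_e = 2e-8), "tau_e")
  expect_error(dynamics_params(S2 = 0.5, tau_c = 1e-8, Rex = -1), "Rex")
  expect_error(spectral_density(dynamics_params(S2 = 1, tau_c = 1e-8), -5),
               "omega")
})

test_that("predicted rates match an independently coded evaluation", {
  # frozen from a 50-digit mpmath transcription of the dipolar+CSA formulas
  r <- predict_rates(dynamics_params(S2 = 1, tau_c = 10.4e-9), SC700)
  expect_equal(unname(r["R1"]), 1.0503628924956397, tolerance = 1e-12)
  expect_equal(unname(r["R2"]), 16.056735810742203, tolerance = 1e-12)
  expect_equal(unname(r["NOE"]), 0.91003997936589518, tolerance = 1e-12)
})

test_that("Rex adds to R2 only", {
  p0 <- dynamics_params(S2 = 0.8, tau_c = 8e-9, tau_e = 30e-12, Rex = 0)
  p5 <- dynamics_params(S2 = 0.8, tau_c = 8e-9, tau_e = 30e-12, Rex = 5)
  r0 <- predict_rates(p0, SC700)
  r5 <- predict_rates(p5, SC700)
  expect_equal(unname(r5["R2"] - r0["R2"]), 5)
  expect_equal(r5["R1"], r0["R1"])
  expect_equal(r5["NOE"], r0["NOE"])
})

test_that("extreme narrowing gives R2/R1 ~ 1 for a dipolar-only spin", {
  sc <- spin_constants(700, csa_ppm = 0)  # c = 0
  r <- predict_rates(dynamics_params(S2 = 1, tau_c = 10e-12), sc)
  expect_equal(unname(r["R2"] / r["R1"]), 1, tolerance = 0.01)
})

test_that("slow-tumbling ordered residues have R2 > R1", {
  for (tc in c(2e-9, 5e-9, 15e-9)) {
    for (s2 in c(0.5, 0.8, 1)) {
      r <- predict_rates(dynamics_params(S2 = s2, tau_c = tc), SC700)
      expect_gt(unname(r["R2"]), unname(r["R1"]))
    }
  }
})

test_that("rates with S2 = 1 are independent of tau_e bookkeeping", {
  # with S2 = 1 the internal-motion term has zero amplitude
  r0 <- predict_rates(dynamics_params(S2 = 1, tau_c = 9e-9, tau_e = 0), SC700)
  r1 <- predict_rates(dynamics_params(S2 = 1, tau_c = 9e-9, tau_e = 500e-12),
                      SC700)
  expect_equal(r0, r1)
})

test_that("the extended model with Sf2 = 1 reduces to the simple model", {
  p_m2 <- dynamics_params(S2 = 0.7, tau_c = 10e-9, tau_e = 800e-12, Sf2 = 1)
  w <- c(0, SC700$omega_N, SC700$omega_H)
  p_m5 <- dynamics_params(S2 = 0.7, tau_c = 10e-9, tau_e = 800e-12, Sf2 = 1,
                          model_id = "M5")
  expect_equal(spectral_density(p_m5, w), spectral_density(p_m2, w))
  expect_equal(predict_rates(p_m5, SC700), predict_rates(p_m2, SC700))
})
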