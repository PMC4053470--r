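test_that("gen_covariates hits its distribution targets and is deterministic", {
  ph <- gen_covariates(1231, seed = 11)
  expect_equal(nrow(ph), 1231)
  expect_true(all(ph$age >= 18))
  expect_lt(abs(mean(ph$age) - 53), 2)
  expect_lt(abs(sd(ph$age) - 19), 2)
  expect_identical(gen_covariates(1000, seed = 7),
                   gen_covariates(1000, seed = 7))
  expect_error(gen_covariates(1, seed = 1), "n must be")
  expect_error(covariate_spec(age_sd = 0), "SDs must be > 0")
})

test_that("gen_genotypes follows Hardy-Weinberg proportions", {
  # p = q = 0.5: heterozygote fraction -> 0.5
  g <- gen_genotypes(20000, list(snp_spec("s", 0.5)), seed = 3)
  expect_lt(abs(mean(g == 1) - 0.5), 0.015)
  # conformance at n = 1e5 within 3 SE per genotype class
  q <- 0.3; p <- 1 - q
  g2 <- gen_genotypes(1e5, list(snp_spec("s", q)), seed = 4)
  exp_f <- c(p^2, 2 * p * q, q^2)
  obs_f <- sapply(0:2, function(k) mean(g2 == k))
  se <- sqrt(exp_f * (1 - exp_f) / 1e5)
  expect_true(all(abs(obs_f - exp_f) < 3 * se))
  expect_error(snp_spec("s", 0.6), "maf")
  expect_error(snp_spec("s", 0), "maf")
})

test_that("HWE chi-square on generated draws is calibrated (maf 0.2, n 1e4)", {
  ok <- vapply(1:200, function(s) {
    g <- gen_genotypes(10000, list(snp_spec("s", 0.2)), seed = s)
    hwe_test(sum(g == 0), sum(g == 1), sum(g == 2))$p > 0.001
  }, TRUE)
  expect_gte(mean(ok), 0.99)
})

test_that("HWE rejection rate rises monotonically with hwe_deviation", {
  rej <- vapply(c(0, 0.05, 0.12), function(f) {
    mean(vapply(1:60, function(s) {
      g <- gen_genotypes(2000, list(snp_spec("s", 0.3, hwe_deviation = f)),
                         seed = s)
      hwe_test(sum(g == 0), sum(g == 1), sum(g == 2))$p < 0.05
    }, TRUE))
  }, 0)
  expect_true(all(diff(rej) > 0))
})

test_that("gen_uae calibrates prevalence and respects the generative model", {
  # betas 0, noise 0 -> identical covariates give identical ACR
  ph <- gen_covariates(50, seed = 1)
  ph2 <- ph[rep(1, 50), ]
  eff0 <- effect_spec(covariate_betas = c(age = 0), noise_sd = 0)
  out <- gen_uae(ph2, NULL, list(), eff0, seed = 1)
  expect_equal(length(unique(out$acr)), 1L)
  # default calibration, mean prevalence over 50 cohorts within +-0.02
  prev <- vapply(1:50, function(s) {
    ph <- gen_covariates(1231, seed = s)
    mean(gen_uae(ph, NULL, list(), effect_spec(), seed = s + 1000)$malb)
  }, 0)
  expect_lt(abs(mean(prev) - 0.07), 0.02)
  # mismatched subject counts
  g <- gen_genotypes(10, list(snp_spec("s", 0.3)), seed = 1)
  expect_error(gen_uae(gen_covariates(20, seed = 1), g,
                       list(snp_spec("s", 0.3)), effect_spec(), seed = 1),
               class = "genometab_alignment_error")
})

test_that("gen_metabolite_levels reproduces the panel's group means", {
  ph <- data.frame(subject_id = sprintf("S%05d", 1:20000),
                   malb = rep(c(0, 1), each = 10000))
  lv <- gen_metabolite_levels(ph, seed = 5)
  expect_equal(dim(lv), c(20000L, 26L))
  expect_true(all(lv >= 0))
  # cholesterol: normo ~3.17, malb ~2.95
  expect_lt(abs(mean(lv[1:10000, "Cholesterol"]) - 3.17), 0.02)
  expect_lt(abs(mean(lv[10001:20000, "Cholesterol"]) - 2.95), 0.02)
  # sd = 0 -> all subjects at the group mean
  pk <- default_peak_specs()[[1]]
  pk$amplitude_sd_normo <- 0; pk$amplitude_sd_malb <- 0
  lv0 <- gen_metabolite_levels(ph[1:10, ], list(pk), seed = 1)
  expect_true(all(lv0 == pk$amplitude_mean_normo))
})

test_that("generated cholesterol difference is detectable at study scale", {
  # two-sample test at n = 1150/81 rejects at p < 0.01 in >= 80% of seeds
  ph <- data.frame(subject_id = sprintf("S%04d", 1:1231),
                   malb = rep(c(0, 1), c(1150, 81)))
  hits <- vapply(1:100, function(s) {
    lv <- gen_metabolite_levels(ph, seed = s)
    welch_p <- t.test(lv[ph$malb == 1, "Cholesterol"],
                      lv[ph$malb == 0, "Cholesterol"])$p.value
    welch_p < 0.01
  }, TRUE)
  expect_gte(mean(hits), 0.80)
})

test_that("gen_spectra: lineshape normalization, determinism, validation", {
  # single unit-amplitude Lorentzian integrates to ~1 over the grid
  ppm <- seq(0.4, 4.8, by = 5e-4)
  y <- (0.002 / pi) / ((ppm - 2.6)^2 + 0.002^2)
  expect_lt(abs(sum(diff(ppm) * (head(y, -1) + tail(y, -1)) / 2) - 1), 0.01)
  ref <- metabolite_reference()
  lv <- matrix(ref$mean_normo, 1, 26, dimnames = list("S1", ref$name))
  s1 <- gen_spectra(lv, seed = 9, noise_sd = 0.01)
  s2 <- gen_spectra(lv, seed = 9, noise_sd = 0.01)
  expect_identical(s1[[1]]$intensity, s2[[1]]$intensity)
  # peak center outside grid errors
  pk <- default_peak_specs()
  expect_error(gen_spectra(lv, pk, ppm_range = c(1.0, 4.8)),
               "outside the ppm grid")
})

test_that("bmi and eGFR formulas evaluate correctly", {
  expect_equal(compute_bmi(81, 1.80), 25.0)
  expect_equal(compute_bmi(70, 1.60), 27.34, tolerance = 1e-3)
  expect_error(compute_bmi(70, 0), "height")
  e_male <- egfr_mdrd(1.0, 50, female = FALSE)
  expect_equal(e_male, 84.1, tolerance = 2e-3)
  expect_equal(egfr_mdrd(1.0, 50, female = TRUE), e_male * 0.742)
  expect_equal(egfr_mdrd(2.0, 50, FALSE) / e_male, 2^-1.154)
})
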