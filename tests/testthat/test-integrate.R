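test_that("cohort_differences: trivial and antisymmetry cases", {
  set.seed(61)
  m <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(c(0, 1), 50)
  # identical groups (same values copied): p = 1, diff = 0
  mid <- rbind(m[1:50, ], m[1:50, ])
  yid <- rep(c(0, 1), each = 50)
  cd <- cohort_differences(mid, yid)
  expect_true(all(cd$diff == 0))
  expect_true(all(cd$p == 1))
  # swapping labels negates diff, keeps p
  c1 <- cohort_differences(m, y)
  c2 <- cohort_differences(m, 1 - y)
  expect_equal(c1$diff, -c2$diff)
  expect_equal(c1$p, c2$p)
  # welch agrees with stats::t.test oracle
  tt <- t.test(m[y == 1, 1], m[y == 0, 1])
  expect_equal(c1$p[1], tt$p.value, tolerance = 1e-12)
})

test_that("stratified_differences reports strata, flags and percentages", {
  co <- make_cohort(n = 400, seed = 91)
  calls <- co$geno[, "rs4359"]
  st <- stratified_differences(co$metab, co$pheno$malb, calls)
  expect_equal(nrow(st), length(unique(calls[!is.na(calls)])) * 26)
  expect_true(all(st$diff == st$mean_malb - st$mean_normo, na.rm = TRUE))
  expect_true(all(st$n_malb >= 0 & st$n_normo >= 0))
  # genotype with zero malb subjects -> flagged unavailable, NA comparisons
  y0 <- rep(0L, 400)
  y0[calls %in% c(0, 1) & co$pheno$malb == 1] <- 1L
  st0 <- stratified_differences(co$metab, y0, calls)
  g2 <- st0[st0$genotype == 2, ]
  if (nrow(g2) > 0 && all(y0[calls %in% 2] == 0)) {
    expect_true(all(g2$flag == "unavailable"))
    expect_true(all(is.na(g2$p)))
  }
})

test_that("significance_pattern maps the four categories monotonically", {
  expect_equal(significance_pattern(c(0.05, 0.0005, 1e-6)), c(0L, 2L, 3L))
  # boundaries are strict: p = 0.001 is category 1, not 2
  expect_equal(significance_pattern(c(0.01, 0.009, 0.001, 0.00001)),
               c(0L, 1L, 1L, 2L))
  p <- sort(runif(50))
  expect_true(all(diff(significance_pattern(p)) <= 0))
})

test_that("normalized_difference_ratio: identity, zero and sign cases", {
  co <- make_cohort(n = 300, seed = 101)
  cd <- cohort_differences(co$metab, co$pheno$malb)
  # stratum = entire cohort -> R = 1 everywhere
  st <- stratified_differences(co$metab, co$pheno$malb,
                               rep(0L, 300))
  r <- normalized_difference_ratio(st, cd)
  expect_equal(r$ratio, rep(1, 26), tolerance = 1e-9)
  # constructed: stratum diff 0 -> R 0; diff = -cohort -> R = -1
  fake <- st[1:2, ]
  fake$diff <- c(0, -cd$diff[cd$metabolite == fake$metabolite[2]])
  r2 <- normalized_difference_ratio(fake, cd)
  expect_equal(r2$ratio, c(0, -1))
  # R invariant to common positive rescaling of a metabolite
  m10 <- co$metab; m10[, 3] <- m10[, 3] * 10
  cd10 <- cohort_differences(m10, co$pheno$malb)
  st10 <- stratified_differences(m10, co$pheno$malb, co$geno[, 1])
  sto <- stratified_differences(co$metab, co$pheno$malb, co$geno[, 1])
  r10 <- normalized_difference_ratio(st10, cd10)
  ro <- normalized_difference_ratio(sto, cd)
  expect_equal(r10$ratio, ro$ratio, tolerance = 1e-9)
})

test_that("count-weighted stratum decomposition reconstructs the cohort diff", {
  co <- make_cohort(n = 500, seed = 111)
  for (sid in colnames(co$geno)[1:4]) {
    calls <- co$geno[, sid]
    ok <- !is.na(calls)
    cd <- cohort_differences(co$metab[ok, , drop = FALSE],
                             co$pheno$malb[ok])
    st <- stratified_differences(co$metab, co$pheno$malb, calls)
    rec <- stratum_weighted_identity(st)
    idx <- match(cd$metabolite, rec$metabolite)
    expect_true(all(abs(rec$diff[idx] - cd$diff) < 1e-9))
  }
})

test_that("stratum_plsda delegates and errors on tiny strata", {
  co <- make_cohort(n = 300, seed = 121)
  idx <- seq_len(200)
  r <- stratum_plsda(co$metab, co$pheno$malb, idx, cv_plan(10, 2), k = 2,
                     seed = 3)
  expect_true(is.finite(r$q2))
  expect_equal(r$n, 200)
  expect_error(stratum_plsda(co$metab, co$pheno$malb, 1:5,
                             cv_plan(10, 2)), "fewer than")
})

test_that("select_discordant applies both criteria and echoes thresholds", {
  co <- make_cohort(n = 600, seed = 131)
  calls <- co$geno[, 1]
  ok <- !is.na(calls)
  cd <- cohort_differences(co$metab[ok, , drop = FALSE], co$pheno$malb[ok])
  st <- stratified_differences(co$metab, co$pheno$malb, calls)
  q2s <- c("0" = 0.5, "1" = 0.5, "2" = -0.05)
  rep1 <- select_discordant(st, cd, q2s, cohort_q2 = 0.4)
  expect_true(all(c("frac_nonsig", "selected") %in% names(rep1)))
  expect_equal(attr(rep1, "criteria")$frac_threshold, 0.8)
  # genotypes with Q2 above the cohort cannot be selected
  expect_true(all(!rep1$selected[rep1$q2 >= 0.4]))
  # no genotype passing -> valid empty selection
  rep2 <- select_discordant(st, cd, c("0" = 0.9, "1" = 0.9, "2" = 0.9),
                            cohort_q2 = 0.4)
  expect_true(all(!rep2$selected))
})

test_that("contingency_chi2 matches chisq.test and handles zero cells", {
  tabs <- list(matrix(c(22, 59, 77, 1073), 2, 2, byrow = TRUE),
               matrix(c(10, 20, 30, 40), 2, 2),
               matrix(c(5, 0, 7, 11), 2, 2))
  for (tb in tabs) {
    got <- contingency_chi2(tb)
    oracle <- suppressWarnings(chisq.test(tb, correct = FALSE))
    expect_equal(got$chi2, unname(oracle$statistic), tolerance = 1e-10)
    expect_equal(got$p, oracle$p.value, tolerance = 1e-10)
  }
  # identical proportions -> chi2 0, p 1
  eq <- contingency_chi2(matrix(c(10, 20, 30, 60), 2, 2, byrow = TRUE))
  expect_equal(eq$chi2, 0, tolerance = 1e-12)
  expect_equal(eq$p, 1)
  # Haldane correction gives a finite OR with a zero cell
  z <- contingency_chi2(matrix(c(5, 0, 7, 11), 2, 2))
  expect_true(is.finite(z$or) && z$or > 0)
})

test_that("summary_ttest reproduces a full-data t test", {
  set.seed(141)
  x1 <- rnorm(30, 1); x2 <- rnorm(45)
  w <- summary_ttest(mean(x1), sd(x1), 30, mean(x2), sd(x2), 45, "welch")
  tt <- t.test(x1, x2)
  expect_equal(w$p, tt$p.value, tolerance = 1e-10)
  expect_equal(w$df, unname(tt$parameter), tolerance = 1e-10)
  s <- summary_ttest(mean(x1), sd(x1), 30, mean(x2), sd(x2), 45, "student")
  ts <- t.test(x1, x2, var.equal = TRUE)
  expect_equal(s$p, ts$p.value, tolerance = 1e-10)
  # equal means -> t = 0, p = 1
  e <- summary_ttest(5, 1, 10, 5, 2, 12)
  expect_equal(e$t, 0)
  expect_equal(e$p, 1)
})

test_that("characterize_subgroup builds the clinical comparison table", {
  co <- make_cohort(n = 500, seed = 151)
  idx <- which(co$geno[, "rs4359"] == 1)
  tb <- characterize_subgroup(co$pheno, idx)
  expect_true("age" %in% tb$variable)
  expect_true(any(grepl("all malb", tb$comparison)))
  # empty stratum: empty table plus warning
  expect_warning(out <- characterize_subgroup(co$pheno, integer(0)),
                 "empty stratum")
  expect_equal(nrow(out), 0L)
  # planted age shift detected at alpha = 0.05 in >= 80% of seeds
  hits <- vapply(1:50, function(s) {
    ph <- gen_covariates(400, seed = s)
    ph <- gen_uae(ph, NULL, list(), effect_spec(), seed = s + 500)
    stratum <- 1:100
    ph$age[intersect(stratum, which(ph$malb == 1))] <-
      ph$age[intersect(stratum, which(ph$malb == 1))] + 25
    tb <- characterize_subgroup(ph, stratum)
    p <- tb$p[tb$variable == "age" &
                tb$comparison == "stratum malb vs stratum normo"]
    isTRUE(p < 0.05)
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})
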