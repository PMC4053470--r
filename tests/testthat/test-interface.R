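test_that("read_phenotypes derives malb/log_uae and rejects ACR <= 0", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(subject_id = c("a", "b", "c", "d"),
                       age = c(40, 50, 60, 70),
                       acr = c(30, 29.9, -1, 12)), f, row.names = FALSE)
  expect_warning(ph <- read_phenotypes(f), "ACR <= 0")
  expect_equal(nrow(ph), 3L)
  expect_equal(attr(ph, "excluded"), "c")
  # ACR = 30 exactly is microalbuminuric (>= convention)
  expect_equal(ph$malb[ph$subject_id == "a"], 1L)
  expect_equal(ph$malb[ph$subject_id == "b"], 0L)
  expect_equal(ph$log_uae, log10(ph$acr))
  # missing acr column names the column
  f2 <- tempfile(fileext = ".csv")
  write.csv(data.frame(subject_id = "a", age = 1), f2, row.names = FALSE)
  err <- tryCatch(read_phenotypes(f2), error = identity)
  expect_s3_class(err, "genometab_schema_error")
  expect_match(conditionMessage(err), "acr")
})

test_that("ped/map and TSV genotype dialects round-trip identically", {
  g <- gen_genotypes(40, list(snp_spec("s1", 0.3), snp_spec("s2", 0.12),
                              snp_spec("s3", 0.45)), seed = 3,
                     missing_rate = 0.05)
  d <- tempfile(); dir.create(d)
  write_genotypes_tsv(g, file.path(d, "g.tsv"))
  write_pedmap(g, file.path(d, "g"))
  g_tsv <- read_genotypes(file.path(d, "g.tsv"))
  g_ped <- read_genotypes(file.path(d, "g.ped"),
                          map = file.path(d, "g.map"))
  expect_equal(unname(g_tsv[, ]), unname(g[, ]))
  expect_equal(unname(g_ped[, ]), unname(g_tsv[, ]))
  expect_equal(colnames(g_ped), colnames(g))
})

test_that("spectra write/read round-trips through the manifest", {
  ph <- data.frame(subject_id = c("P1", "P2"), malb = c(0, 1))
  lv <- gen_metabolite_levels(ph, seed = 8)
  sp <- gen_spectra(lv, seed = 9, dppm = 2e-3)
  d <- tempfile()
  mf <- write_spectra(sp, d)
  back <- read_spectra(file.path(d, "manifest.csv"))
  expect_equal(names(back), c("P1", "P2"))
  expect_equal(back[[1]]$ppm, sp[[1]]$ppm, tolerance = 1e-9)
  expect_equal(back[[1]]$intensity, sp[[1]]$intensity, tolerance = 1e-6)
  q1 <- quantify_metabolites(sp)
  q2 <- quantify_metabolites(back)
  expect_equal(q1, q2, tolerance = 1e-4)
})

test_that("run_config round-trips through YAML and JSON", {
  cfg <- run_config(n = 123, seed = 42, cv_repeats = 3)
  fy <- tempfile(fileext = ".yaml"); fj <- tempfile(fileext = ".json")
  save_config(cfg, fy); save_config(cfg, fj)
  for (f in c(fy, fj)) {
    back <- load_config(f)
    expect_equal(back$n, cfg$n)
    expect_equal(back$seed, cfg$seed)
    expect_equal(back$stages, cfg$stages)
    expect_equal(back$window, cfg$window)
    expect_equal(back$cv_repeats, cfg$cv_repeats)
  }
})

test_that("run_pipeline is deterministic and staging works", {
  base <- run_config(n = 150, seed = 5, cv_repeats = 2, dppm = 2e-3,
                     integrate_snps = c("rs4359", "rs10492025"))
  d1 <- tempfile(); d2 <- tempfile()
  c1 <- base; c1$out_dir <- d1
  c2 <- base; c2$out_dir <- d2
  suppressMessages(rep1 <- run_pipeline(c1))
  suppressMessages(rep2 <- run_pipeline(c2))
  for (f in c("pheno.csv", "metabolites.csv", "association.tsv",
              "significance_pattern.tsv", "difference_ratios.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  expect_equal(rep1$stages$simulate$n, 150)
  expect_true(file.exists(file.path(d1, "run_report.json")))
  # chemometrics off: integrate still runs from precomputed features
  d3 <- tempfile()
  c3 <- run_config(n = 150, seed = 5,
                   stages = c(simulate = FALSE, spectra = FALSE,
                              chemometrics = FALSE, genassoc = FALSE,
                              integrate = TRUE),
                   out_dir = d3,
                   pheno_csv = file.path(d1, "pheno.csv"),
                   geno_tsv = file.path(d1, "geno.tsv"),
                   features_csv = file.path(d1, "metabolites.csv"),
                   integrate_snps = c("rs4359"))
  suppressMessages(rep3 <- run_pipeline(c3))
  expect_true(file.exists(file.path(d3, "significance_pattern.tsv")))
  # a failing stage aborts naming the stage
  c4 <- run_config(stages = c(simulate = FALSE, spectra = TRUE,
                              chemometrics = FALSE, genassoc = FALSE,
                              integrate = FALSE),
                   out_dir = tempfile())
  err <- tryCatch(suppressMessages(run_pipeline(c4)), error = identity)
  expect_s3_class(err, "genometab_stage_error")
  expect_match(conditionMessage(err), "stage spectra")
})

test_that("cli_main answers --version and rejects unknown commands", {
  expect_output(cli_main("--version"), "genometab")
  expect_error(cli_main(c("frobnicate", "--x", "1")), "unknown command")
  expect_output(cli_main(character(0)), "usage")
})
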