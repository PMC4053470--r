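# End-to-end orchestration: configuration, staged execution
# (simulate -> spectra -> chemometrics -> genassoc -> integrate),
# per-stage logging and the run report.

#' Build a pipeline run configuration
#'
#' Every threshold defaults to the canonical analysis value where one
#' exists (0.01 ppm buckets over 0.50-4.70 ppm, >90% call rate, 10-fold
#' Venetian-blind cross-validation run 10 times, significance boundaries
#' 0.01/0.001/0.00001, microalbuminuria cut-off ACR >= 30). A single
#' master `seed` is split deterministically per stage.
#'
#' @param n simulated cohort size.
#' @param seed master seed.
#' @param out_dir output directory.
#' @param stages named logical vector toggling the five stages.
#' @param bin_width,window spectral bucketing parameters.
#' @param spectra_noise_sd,dppm forward-model parameters for simulated
#'   spectra.
#' @param min_call_rate,hwe_alpha genotype QC thresholds.
#' @param cv_folds,cv_repeats,ncomp cross-validation plan; `ncomp = "auto"`
#'   selects k in 1..5 by Q2.
#' @param target_prevalence expected microalbuminuria fraction.
#' @param missing_rate genotype missingness injected by the simulator.
#' @param global_alpha,stratum_alpha,frac_threshold discordance-selection
#'   thresholds.
#' @param integrate_snps SNP ids to stratify (default: the packaged
#'   14-SNP panel).
#' @param pheno_csv,geno_tsv,spectra_manifest,features_csv paths to
#'   precomputed inputs for runs with the simulate (or earlier) stages
#'   toggled off.
#' @return object of class `run_config` (a named list).
#' @export
run_config <- function(n = 300, seed = 1, out_dir = tempfile("genometab_"),
                       stages = c(simulate = TRUE, spectra = TRUE,
                                  chemometrics = TRUE, genassoc = TRUE,
                                  integrate = TRUE),
                       bin_width = 0.01, window = c(0.50, 4.70),
                       spectra_noise_sd = 0.02, dppm = 5e-4,
                       min_call_rate = 0.90, hwe_alpha = 0.001,
                       cv_folds = 10, cv_repeats = 10, ncomp = 2,
                       target_prevalence = 0.07, missing_rate = 0.02,
                       global_alpha = 1e-5, stratum_alpha = 0.01,
                       frac_threshold = 0.8, integrate_snps = NULL,
                       pheno_csv = NULL, geno_tsv = NULL,
                       spectra_manifest = NULL, features_csv = NULL) {
  cfg <- as.list(environment())
  gm_assert(all(c("simulate", "spectra", "chemometrics", "genassoc",
                  "integrate") %in% names(stages)),
            "stages must name all five pipeline stages")
  structure(cfg, class = "run_config")
}

#' Save / load a run configuration (YAML or JSON)
#'
#' Configurations round-trip through serialization unchanged.
#'
#' @param config a [run_config()].
#' @param path destination (`.yaml`/`.yml` or `.json`).
#' @export
save_config <- function(config, path) {
  x <- unclass(config)
  x$stages <- as.list(x$stages)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  x <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  x$stages <- unlist(x$stages)
  x$window <- as.numeric(unlist(x$window))
  do.call(run_config, x[setdiff(names(x), character(0))])
}

log_msg <- function(...) message("[genometab] ", sprintf(...))

#' Run the full pipeline
#'
#' Executes the enabled stages in order, persisting each stage's outputs
#' under `config$out_dir`. Any stage failure aborts with the stage name
#' and cause. Fixed seeds give byte-identical numeric outputs across
#' reruns.
#'
#' @param config a [run_config()].
#' @return a run report (list): per-stage record counts, exclusions with
#'   reasons, parameter echo, package version and seed registry. Also
#'   written to `run_report.json`.
#' @export
run_pipeline <- function(config) {
  gm_assert(inherits(config, "run_config") || is.list(config),
            "config must be a run_config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- config$stages
  seeds <- list()
  report <- list(version = as.character(utils::packageVersion("genometab")),
                 parameters = unclass(config)[
                   !vapply(unclass(config), is.null, TRUE)],
                 stages = list())
  run_stage <- function(name, fn) {
    log_msg("stage %s ...", name)
    tryCatch(fn(), error = function(e) {
      gm_stop(sprintf("stage %s failed: %s", name, conditionMessage(e)),
              class = "genometab_stage_error")
    })
  }

  pheno <- geno <- spectra <- metab <- NULL
  snps <- default_snp_specs()

  if (isTRUE(st[["simulate"]])) {
    run_stage("simulate", function() {
      seeds$simulate <<- derive_seed(config$seed, "simulate")
      pheno <<- gen_covariates(config$n, covariate_spec(),
                               seed = seeds$simulate)
      geno <<- gen_genotypes(config$n, snps,
                             seed = derive_seed(config$seed, "genotypes"),
                             missing_rate = config$missing_rate)
      eff <- effect_spec(target_prevalence = config$target_prevalence)
      pheno <<- gen_uae(pheno, geno, snps, eff,
                        seed = derive_seed(config$seed, "uae"))
      levels <- gen_metabolite_levels(
        pheno, seed = derive_seed(config$seed, "levels"))
      spectra <<- gen_spectra(levels, noise_sd = config$spectra_noise_sd,
                              seed = derive_seed(config$seed, "spectra"),
                              dppm = config$dppm)
      write_phenotypes(pheno, file.path(config$out_dir, "pheno.csv"))
      write_genotypes_tsv(geno, file.path(config$out_dir, "geno.tsv"))
      write_pedmap(geno, file.path(config$out_dir, "geno"))
      write_spectra(spectra, file.path(config$out_dir, "spectra"))
      report$stages$simulate <<- list(n = nrow(pheno),
                                      n_snps = ncol(geno),
                                      prevalence = mean(pheno$malb))
    })
  } else {
    if (!is.null(config$pheno_csv)) pheno <- read_phenotypes(config$pheno_csv)
    if (!is.null(config$geno_tsv)) geno <- read_genotypes(config$geno_tsv)
    if (!is.null(config$spectra_manifest)) {
      spectra <- read_spectra(config$spectra_manifest)
    }
  }

  if (isTRUE(st[["spectra"]])) {
    run_stage("spectra", function() {
      gm_assert(!is.null(spectra),
                "spectra stage needs simulated spectra or a manifest")
      metab <<- quantify_metabolites(spectra, width = config$bin_width,
                                     window = config$window)
      write_feature_matrix(metab,
                           file.path(config$out_dir, "metabolites.csv"))
      report$stages$spectra <<- list(n = nrow(metab),
                                     n_regions = ncol(metab))
    })
  } else if (!is.null(config$features_csv)) {
    metab <- read_feature_matrix(config$features_csv)
  } else if (file.exists(file.path(config$out_dir, "metabolites.csv"))) {
    metab <- read_feature_matrix(file.path(config$out_dir,
                                           "metabolites.csv"))
  }

  cohort_q2 <- NA_real_
  if (isTRUE(st[["chemometrics"]])) {
    run_stage("chemometrics", function() {
      gm_assert(!is.null(metab) && !is.null(pheno),
                "chemometrics needs a feature matrix and phenotypes")
      X <- mean_center(metab)
      plan <- cv_plan(config$cv_folds, config$cv_repeats)
      k <- config$ncomp
      ksel <- NULL
      if (identical(k, "auto")) {
        ksel <- select_ncomp(X, pheno$malb, plan,
                             seed = derive_seed(config$seed, "cv"))
        k <- ksel$k
      }
      cv <- cross_validate(X, pheno$malb, plan, k,
                           seed = derive_seed(config$seed, "cv"))
      model <- fit_plsda(metab, pheno$malb, k)
      vip <- rank_features(model)
      summary <- list(k = k, q2 = cv$q2, q2_press = cv$q2_press,
                      rmscv = cv$rmscv, per_repeat = cv$per_repeat,
                      q2_by_k = if (is.null(ksel)) NULL else
                        as.list(ksel$q2_by_k))
      jsonlite::write_json(summary,
                           file.path(config$out_dir, "plsda_summary.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
      utils::write.table(model$scores,
                         file.path(config$out_dir, "plsda_scores.tsv"),
                         sep = "\t", quote = FALSE)
      utils::write.table(model$x_loadings,
                         file.path(config$out_dir, "plsda_loadings.tsv"),
                         sep = "\t", quote = FALSE)
      utils::write.table(vip, file.path(config$out_dir, "plsda_vip.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      cohort_q2 <<- cv$q2
      report$stages$chemometrics <<- list(k = k, q2 = cv$q2,
                                          rmscv = cv$rmscv)
    })
  }

  assoc <- NULL
  if (isTRUE(st[["genassoc"]])) {
    run_stage("genassoc", function() {
      gm_assert(!is.null(geno) && !is.null(pheno),
                "genassoc needs genotypes and phenotypes")
      qcres <- qc_filter(geno, config$min_call_rate, config$hwe_alpha)
      utils::write.table(qcres$qc, file.path(config$out_dir, "snp_qc.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      assoc <<- assoc_scan(qcres$geno, pheno)
      utils::write.table(assoc,
                         file.path(config$out_dir, "association.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report$stages$genassoc <<- list(
        n_snps_in = ncol(geno), n_snps_passed = ncol(qcres$geno),
        n_excluded = ncol(geno) - ncol(qcres$geno),
        excluded = qcres$qc$snp_id[!qcres$qc$passed])
    })
  }

  if (isTRUE(st[["integrate"]])) {
    run_stage("integrate", function() {
      gm_assert(!is.null(metab) && !is.null(pheno) && !is.null(geno),
                "integrate needs features, phenotypes and genotypes")
      snp_ids <- config$integrate_snps
      if (is.null(snp_ids)) snp_ids <- colnames(geno)
      plan <- cv_plan(config$cv_folds, max(2, config$cv_repeats %/% 2))
      patt <- list(); ratio_tab <- list(); reports <- list()
      for (sid in snp_ids) {
        calls <- geno[, sid]
        gsub_ok <- !is.na(calls)
        cohort <- cohort_differences(metab[gsub_ok, , drop = FALSE],
                                     pheno$malb[gsub_ok])
        strat <- stratified_differences(metab, pheno$malb, calls)
        strat <- normalized_difference_ratio(strat, cohort)
        strat$category <- significance_pattern(strat$p)
        q2s <- vapply(sort(unique(calls[gsub_ok])), function(g) {
          idx <- which(!is.na(calls) & calls == g)
          out <- tryCatch(
            stratum_plsda(metab, pheno$malb, idx, plan,
                          k = min(2L, length(idx) - 1L),
                          seed = derive_seed(config$seed, "stratum"))$q2,
            error = function(e) NA_real_)
          out
        }, 0)
        names(q2s) <- sort(unique(calls[gsub_ok]))
        rep_s <- select_discordant(strat, cohort, q2s, cohort_q2, strat,
                                   config$global_alpha,
                                   config$stratum_alpha,
                                   config$frac_threshold)
        rep_s$snp_id <- sid
        reports[[sid]] <- rep_s
        strat$snp_id <- sid
        patt[[sid]] <- strat
      }
      all_strat <- do.call(rbind, patt)
      utils::write.table(
        all_strat[, c("snp_id", "genotype", "metabolite", "p", "category",
                      "malb_percent", "flag")],
        file.path(config$out_dir, "significance_pattern.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        all_strat[, c("snp_id", "genotype", "metabolite", "diff",
                      "cohort_diff", "ratio", "ratio_flag")],
        file.path(config$out_dir, "difference_ratios.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      disc <- do.call(rbind, reports)
      jsonlite::write_json(disc,
                           file.path(config$out_dir, "discordance.json"),
                           auto_unbox = TRUE, digits = NA,
                           dataframe = "rows")
      sel <- disc[disc$selected %in% TRUE, , drop = FALSE]
      if (nrow(sel)) {
        subtabs <- lapply(seq_len(nrow(sel)), function(i) {
          idx <- which(!is.na(geno[, sel$snp_id[i]]) &
                         geno[, sel$snp_id[i]] == sel$genotype[i])
          tb <- characterize_subgroup(pheno, idx)
          tb$snp_id <- sel$snp_id[i]; tb$genotype <- sel$genotype[i]
          tb
        })
        utils::write.csv(do.call(rbind, subtabs),
                         file.path(config$out_dir, "subgroups.csv"),
                         row.names = FALSE)
      }
      report$stages$integrate <<- list(
        n_snps = length(snp_ids),
        n_selected = sum(disc$selected, na.rm = TRUE))
    })
  }

  report$seeds <- seeds
  jsonlite::write_json(report, file.path(config$out_dir,
                                         "run_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       null = "null", force = TRUE)
  invisible(report)
}
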