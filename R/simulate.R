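# Synthetic cohort generation: covariates, genotypes, urinary albumin
# excretion, serum metabolite levels, and forward-modelled 1H-NMR spectra.
# Every generator is a pure function of (spec, seed).

#' Covariate distribution specification
#'
#' Marginal distributions for the simulated cohort covariates. Defaults are
#' the whole-cohort summaries of the population study the pipeline targets
#' (age 53±19 y, 50.6% men, BMI 26±6 kg/m2, SBP 129±21 mmHg, DBP 79±12 mmHg,
#' fasting glucose 92±20 mg/dl). Serum creatinine defaults (0.9±0.2 mg/dl)
#' are a realistic population value, not a printed one. Covariates are drawn
#' independently; `correlation` accepts an optional correlation matrix over
#' the continuous covariates (identity by default).
#'
#' @param age_mean,age_sd years; age is truncated at >= 18.
#' @param sex_fraction_male proportion of men in `[0,1]`.
#' @param bmi_mean,bmi_sd kg/m2.
#' @param sbp_mean,sbp_sd,dbp_mean,dbp_sd mmHg.
#' @param glucose_mean,glucose_sd mg/dl fasting glucose.
#' @param creatinine_mean,creatinine_sd mg/dl serum creatinine.
#' @param correlation optional correlation matrix (age, bmi, sbp, dbp,
#'   glucose, creatinine order); identity = independent draws.
#' @return object of class `covariate_spec`.
#' @export
covariate_spec <- function(age_mean = 53, age_sd = 19,
                           sex_fraction_male = 0.506,
                           bmi_mean = 26, bmi_sd = 6,
                           sbp_mean = 129, sbp_sd = 21,
                           dbp_mean = 79, dbp_sd = 12,
                           glucose_mean = 92, glucose_sd = 20,
                           creatinine_mean = 0.9, creatinine_sd = 0.2,
                           correlation = NULL) {
  spec <- list(age_mean = age_mean, age_sd = age_sd,
               sex_fraction_male = sex_fraction_male,
               bmi_mean = bmi_mean, bmi_sd = bmi_sd,
               sbp_mean = sbp_mean, sbp_sd = sbp_sd,
               dbp_mean = dbp_mean, dbp_sd = dbp_sd,
               glucose_mean = glucose_mean, glucose_sd = glucose_sd,
               creatinine_mean = creatinine_mean,
               creatinine_sd = creatinine_sd,
               correlation = correlation)
  sds <- spec[grep("_sd$", names(spec))]
  gm_assert(all(unlist(sds) > 0), "all covariate SDs must be > 0")
  gm_assert(sex_fraction_male >= 0 && sex_fraction_male <= 1,
            "sex_fraction_male must lie in [0,1]")
  if (!is.null(correlation)) {
    gm_assert(is.matrix(correlation) && nrow(correlation) == 6 &&
                isTRUE(all.equal(correlation, t(correlation))),
              "correlation must be a symmetric 6x6 matrix")
  }
  structure(spec, class = "covariate_spec")
}

#' SNP simulation specification
#'
#' @param snp_id identifier.
#' @param maf minor-allele frequency in (0, 0.5].
#' @param model genetic model used when this SNP's effect enters the
#'   urinary-albumin-excretion generator: `ADD`, `DOM` or `REC`.
#' @param beta effect on log10 ACR per coded genotype unit.
#' @param hwe_deviation inbreeding-like deviation parameter in `[0,1)`;
#'   0 gives exact Hardy-Weinberg proportions in expectation.
#' @return object of class `snp_spec`.
#' @export
snp_spec <- function(snp_id, maf, model = c("ADD", "DOM", "REC"),
                     beta = 0, hwe_deviation = 0) {
  model <- match.arg(model)
  gm_assert(is.numeric(maf) && length(maf) == 1 && maf > 0 && maf <= 0.5,
            "maf must lie in (0, 0.5]")
  gm_assert(hwe_deviation >= 0 && hwe_deviation < 1,
            "hwe_deviation must lie in [0,1)")
  structure(list(snp_id = as.character(snp_id), maf = maf, model = model,
                 beta = beta, hwe_deviation = hwe_deviation),
            class = "snp_spec")
}

#' Default SNP panel for simulation
#'
#' The 14 urinary-albumin-excretion associated SNPs with their genetic
#' models and published effect sizes on log10 ACR (0.09-0.28 per coded
#' unit). Minor-allele frequencies are synthetic defaults (the source table
#' prints none); they honour the MAF > 0.1 panel-selection rule.
#'
#' @return list of [snp_spec()] objects.
#' @export
default_snp_specs <- function() {
  path <- system.file("extdata", "snp_panel.tsv", package = "genometab",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    snp_spec(tab$snp_id[i], maf = tab$maf_synthetic[i],
             model = tab$model[i], beta = tab$beta[i])
  })
}

#' Effect specification for the urinary albumin excretion generator
#'
#' The generative model is
#' `log10(ACR) = b0 + sum(beta_c * covariate_c) + sum(beta_s * g_s) + e`,
#' `e ~ N(0, noise_sd)`, with the intercept `b0` calibrated by bisection so
#' the expected microalbuminuria prevalence (ACR >= `malb_threshold`)
#' matches `target_prevalence` (default 7%, a typical general-population
#' figure).
#'
#' @param covariate_betas named vector of effects on log10 ACR per unit of
#'   covariate. Defaults give plausible age/BMI/SBP/glucose gradients and a
#'   null sex effect.
#' @param noise_sd residual SD of log10 ACR (>= 0; 0 allowed for exact
#'   deterministic checks).
#' @param malb_threshold ACR cut-off in ug/mg (30 by definition).
#' @param target_prevalence expected microalbuminuria fraction.
#' @return object of class `effect_spec`.
#' @export
effect_spec <- function(covariate_betas = c(age = 0.008, sex = 0,
                                            bmi = 0.010, sbp = 0.006,
                                            glucose = 0.004),
                        noise_sd = 0.45, malb_threshold = 30,
                        target_prevalence = 0.07) {
  gm_assert(noise_sd >= 0, "noise_sd must be >= 0")
  gm_assert(malb_threshold > 0, "malb_threshold must be > 0")
  gm_assert(target_prevalence > 0 && target_prevalence < 1,
            "target_prevalence must lie in (0,1)")
  gm_assert(!is.null(names(covariate_betas)),
            "covariate_betas must be named")
  structure(list(covariate_betas = covariate_betas, noise_sd = noise_sd,
                 malb_threshold = malb_threshold,
                 target_prevalence = target_prevalence),
            class = "effect_spec")
}

#' Simulate cohort covariates
#'
#' @param n subject count (>= 2).
#' @param spec a [covariate_spec()].
#' @param seed integer seed; identical seeds give identical tables.
#' @return data.frame (partial phenotype table) with columns `subject_id`,
#'   `age`, `sex` (0 = female, 1 = male), `bmi`, `sbp`, `dbp`, `glucose`,
#'   `creatinine`, `diabetes` (fasting glucose >= 126 mg/dl),
#'   `hypertension` (SBP >= 140 or DBP >= 90 mmHg).
#' @export
gen_covariates <- function(n, spec = covariate_spec(), seed = 1) {
  gm_assert(is_count(n) && n >= 2, "n must be an integer >= 2")
  gm_assert(inherits(spec, "covariate_spec"), "spec must be a covariate_spec")
  with_seed(seed, {
    cont <- c("age", "bmi", "sbp", "dbp", "glucose", "creatinine")
    lo <- c(age = 18, bmi = 13, sbp = 70, dbp = 40, glucose = 40,
            creatinine = 0.3)
    if (is.null(spec$correlation)) {
      z <- matrix(stats::runif(n * 6), n, 6)
    } else {
      # Gaussian copula: correlated normals -> uniforms
      ch <- chol(spec$correlation)
      z <- stats::pnorm(matrix(stats::rnorm(n * 6), n, 6) %*% ch)
    }
    colnames(z) <- cont
    draw <- function(v) {
      m <- spec[[paste0(v, "_mean")]]; s <- spec[[paste0(v, "_sd")]]
      plo <- stats::pnorm(lo[[v]], m, s)
      stats::qnorm(plo + z[, v] * (1 - plo), m, s)
    }
    out <- data.frame(subject_id = sprintf("S%04d", seq_len(n)))
    for (v in cont) out[[v]] <- draw(v)
    out$sex <- as.integer(stats::runif(n) < spec$sex_fraction_male)
    out$diabetes <- as.integer(out$glucose >= 126)
    out$hypertension <- as.integer(out$sbp >= 140 | out$dbp >= 90)
    out[, c("subject_id", "age", "sex", "bmi", "sbp", "dbp", "glucose",
            "creatinine", "diabetes", "hypertension")]
  })
}

#' Simulate a genotype matrix in Hardy-Weinberg proportions
#'
#' With `hwe_deviation = 0`, genotype frequencies follow (p^2, 2pq, q^2) in
#' expectation; a positive deviation `f` inflates homozygotes as
#' (p^2 + f*p*q, 2pq(1-f), q^2 + f*p*q), the standard inbreeding
#' parameterization.
#'
#' @param n subject count.
#' @param snps list of [snp_spec()] objects.
#' @param seed integer seed.
#' @param missing_rate fraction of calls set missing, in `[0,1)`.
#' @return integer matrix subjects x SNPs, entries 0/1/2 = copies of the
#'   minor allele, `NA` = missing; dimnames = subject ids x snp ids.
#' @export
gen_genotypes <- function(n, snps = default_snp_specs(), seed = 1,
                          missing_rate = 0) {
  gm_assert(is_count(n) && n >= 1, "n must be a positive integer")
  gm_assert(length(snps) >= 1 && all(vapply(snps, inherits, TRUE, "snp_spec")),
            "snps must be a list of snp_spec objects")
  gm_assert(missing_rate >= 0 && missing_rate < 1,
            "missing_rate must lie in [0,1)")
  with_seed(seed, {
    g <- vapply(snps, function(s) {
      q <- s$maf; p <- 1 - q; f <- s$hwe_deviation
      pr <- c(p^2 + f * p * q, 2 * p * q * (1 - f), q^2 + f * p * q)
      sample(0:2, n, replace = TRUE, prob = pr)
    }, integer(n))
    if (n == 1L) g <- matrix(g, nrow = 1L)
    dimnames(g) <- list(sprintf("S%04d", seq_len(n)),
                        vapply(snps, `[[`, "", "snp_id"))
    if (missing_rate > 0) {
      g[stats::runif(length(g)) < missing_rate] <- NA_integer_
    }
    g
  })
}

#' Simulate urinary albumin excretion from covariates and genotypes
#'
#' Completes a phenotype table with `acr` (ug albumin / mg creatinine),
#' `log_uae` = log10(ACR) and the microalbuminuria flag `malb`
#' (ACR >= threshold). The intercept is calibrated by bisection on the
#' analytic expected prevalence so the cohort hits
#' `eff$target_prevalence` in expectation. Missing genotype codes
#' contribute their Hardy-Weinberg expected value so alignment is kept.
#'
#' @param pheno covariate table from [gen_covariates()].
#' @param geno genotype matrix from [gen_genotypes()] (or NULL for a pure
#'   covariate model).
#' @param snps list of [snp_spec()] matching `geno` columns.
#' @param eff an [effect_spec()].
#' @param seed integer seed.
#' @return `pheno` with columns `acr`, `log_uae`, `malb` appended.
#' @export
gen_uae <- function(pheno, geno = NULL, snps = list(), eff = effect_spec(),
                    seed = 1) {
  gm_assert(inherits(eff, "effect_spec"), "eff must be an effect_spec")
  n <- nrow(pheno)
  if (!is.null(geno)) {
    gm_assert(nrow(geno) == n,
              "pheno and geno must describe the same subjects",
              class = "genometab_alignment_error")
  }
  lp <- numeric(n)
  for (v in names(eff$covariate_betas)) {
    gm_assert(v %in% names(pheno), paste0("missing covariate: ", v))
    lp <- lp + eff$covariate_betas[[v]] * pheno[[v]]
  }
  if (!is.null(geno) && length(snps)) {
    ids <- vapply(snps, `[[`, "", "snp_id")
    gm_assert(all(ids %in% colnames(geno)),
              "every snp_spec must have a genotype column",
              class = "genometab_alignment_error")
    for (s in snps) {
      x <- encode_model(geno[, s$snp_id], s$model)
      if (anyNA(x)) {
        q <- s$maf
        ex <- switch(s$model, ADD = 2 * q, DOM = 1 - (1 - q)^2, REC = q^2)
        x[is.na(x)] <- ex
      }
      lp <- lp + s$beta * x
    }
  }
  thr <- log10(eff$malb_threshold)
  prev <- function(b0) {
    if (eff$noise_sd == 0) mean(b0 + lp >= thr)
    else mean(stats::pnorm((b0 + lp - thr) / eff$noise_sd))
  }
  lohi <- c(thr - max(lp) - 10, thr - min(lp) + 10)
  b0 <- stats::uniroot(function(b) prev(b) - eff$target_prevalence,
                       lohi, tol = 1e-10)$root
  with_seed(seed, {
    pheno$log_uae <- b0 + lp +
      (if (eff$noise_sd > 0) stats::rnorm(n, 0, eff$noise_sd) else 0)
    pheno$acr <- 10^pheno$log_uae
    pheno$malb <- as.integer(pheno$acr >= eff$malb_threshold)
    pheno
  })
}

#' Peak specification for one metabolite signal
#'
#' @param metabolite name (must match a quantification window).
#' @param ppm_lo,ppm_hi the metabolite's quantification window.
#' @param centers chemical shift(s) of the Lorentzian line(s); all must lie
#'   inside the window. Several centers model a multiplet (equal weights).
#' @param linewidth_ppm half-width at half-maximum (> 0).
#' @param amplitude_mean_normo,amplitude_sd_normo,amplitude_mean_malb,amplitude_sd_malb
#'   group means/SDs of the relative level (per 100 units of total
#'   aliphatic area).
#' @return object of class `peak_spec`.
#' @export
peak_spec <- function(metabolite, ppm_lo, ppm_hi, centers, linewidth_ppm,
                      amplitude_mean_normo, amplitude_sd_normo,
                      amplitude_mean_malb, amplitude_sd_malb) {
  gm_assert(all(centers > ppm_lo & centers < ppm_hi),
            paste0(metabolite, ": peak centers must lie inside the window"))
  gm_assert(linewidth_ppm > 0, "linewidth must be > 0")
  gm_assert(all(c(amplitude_mean_normo, amplitude_mean_malb) > 0),
            "amplitude means must be > 0")
  gm_assert(all(c(amplitude_sd_normo, amplitude_sd_malb) >= 0),
            "amplitude SDs must be >= 0")
  structure(list(metabolite = metabolite, ppm_lo = ppm_lo, ppm_hi = ppm_hi,
                 centers = centers, linewidth_ppm = linewidth_ppm,
                 amplitude_mean_normo = amplitude_mean_normo,
                 amplitude_sd_normo = amplitude_sd_normo,
                 amplitude_mean_malb = amplitude_mean_malb,
                 amplitude_sd_malb = amplitude_sd_malb),
            class = "peak_spec")
}

#' Default peak specifications for the 26-metabolite serum panel
#'
#' Peaks sit at window midpoints, with two exceptions: alanine is modelled
#' as its doublet at 1.472/1.484 ppm (midpoint 1.478, the referencing
#' anchor) and 3-OH-isovalerate at 2.395 ppm, in the part of its window not
#' shared with pyruvate. Linewidths scale with window width (bounded to
#' 0.0008-0.002 ppm, i.e. ~1-2.4 Hz at 600 MHz).
#'
#' @return list of [peak_spec()] objects, one per panel metabolite.
#' @export
default_peak_specs <- function() {
  ref <- metabolite_reference()
  lapply(seq_len(nrow(ref)), function(i) {
    lo <- ref$ppm_lo[i]; hi <- ref$ppm_hi[i]
    centers <- (lo + hi) / 2
    if (ref$name[i] == "Alanine") centers <- c(1.472, 1.484)
    if (ref$name[i] == "OH_isovalerate") centers <- 2.395
    lw <- min(0.002, max(0.0008, (hi - lo) / 10))
    peak_spec(ref$name[i], lo, hi, centers, lw,
              ref$mean_normo[i], ref$sd_normo[i],
              ref$mean_malb[i], ref$sd_malb[i])
  })
}

#' Simulate per-subject metabolite relative levels
#'
#' Each subject's level for a metabolite is drawn from the group-specific
#' Gaussian of its peak spec (microalbuminuric vs normoalbuminuric),
#' truncated at zero (relative areas are non-negative).
#'
#' @param pheno phenotype table with a `malb` column.
#' @param peaks list of [peak_spec()].
#' @param seed integer seed.
#' @return numeric matrix subjects x metabolites (panel order), rownames =
#'   subject ids.
#' @export
gen_metabolite_levels <- function(pheno, peaks = default_peak_specs(),
                                  seed = 1) {
  gm_assert("malb" %in% names(pheno), "pheno must contain a malb column")
  n <- nrow(pheno)
  malb <- pheno$malb == 1
  with_seed(seed, {
    m <- vapply(peaks, function(p) {
      mu <- ifelse(malb, p$amplitude_mean_malb, p$amplitude_mean_normo)
      sd <- ifelse(malb, p$amplitude_sd_malb, p$amplitude_sd_normo)
      u <- stats::runif(n)
      plo <- stats::pnorm(0, mu, sd)
      out <- stats::qnorm(plo + u * (1 - plo), mu, sd)
      ifelse(sd == 0, mu, out)
    }, numeric(n))
    if (n == 1L) m <- matrix(m, nrow = 1L)
    dimnames(m) <- list(pheno$subject_id,
                        vapply(peaks, `[[`, "", "metabolite"))
    m
  })
}

# Unit-integral Lorentzian line shape (integral 1 over the real line).
lorentzian <- function(x, center, gamma) {
  (gamma / pi) / ((x - center)^2 + gamma^2)
}

#' Forward-model 1H-NMR spectra from metabolite levels
#'
#' Builds one spectrum per subject on a uniform ppm grid over `ppm_range`
#' (wider than the 0.50-4.70 analysis window). Each metabolite contributes
#' Lorentzian line(s) in its window; a broad Lorentzian background fills
#' the unassigned aliphatic signal. Peak and background amplitudes are
#' calibrated per subject by a linear solve so that, noise-free, the
#' quantification pipeline (bin, normalize to total aliphatic area, reduce
#' by window, x100) returns exactly the input levels — i.e. the generator
#' emulates what the measurement reports.
#'
#' @param levels subjects x metabolites matrix from
#'   [gen_metabolite_levels()].
#' @param peaks list of [peak_spec()] matching `levels` columns.
#' @param noise_sd additive Gaussian intensity noise (0 = noise-free).
#' @param seed integer seed.
#' @param ppm_range grid extent; default `c(0.40, 4.80)`.
#' @param dppm grid spacing; default 5e-4 ppm (20 points per 0.01 ppm bin).
#' @param baseline_amplitude optional smooth quadratic baseline height.
#' @return list of `nmr_spectrum` objects (class `nmr_spectra`).
#' @export
gen_spectra <- function(levels, peaks = default_peak_specs(), noise_sd = 0,
                        seed = 1, ppm_range = c(0.40, 4.80), dppm = 5e-4,
                        baseline_amplitude = 0) {
  gm_assert(is.matrix(levels) && ncol(levels) == length(peaks),
            "levels columns must match peaks")
  for (p in peaks) {
    gm_assert(all(p$centers > ppm_range[1] & p$centers < ppm_range[2]),
              paste0(p$metabolite, ": peak center outside the ppm grid"))
  }
  ppm <- seq(ppm_range[1], ppm_range[2], by = dppm)
  ncomp <- length(peaks)
  shapes <- vapply(peaks, function(p) {
    rowMeans(vapply(p$centers,
                    function(ct) lorentzian(ppm, ct, p$linewidth_ppm),
                    numeric(length(ppm))))
  }, numeric(length(ppm)))
  # unassigned-signal background: narrow resonances in the gaps between
  # metabolite windows, so the background contributes little area inside
  # any quantification window and the amplitude solve stays non-negative
  wins <- cbind(vapply(peaks, `[[`, 0, "ppm_lo"),
                vapply(peaks, `[[`, 0, "ppm_hi"))
  wins <- wins[order(wins[, 1]), , drop = FALSE]
  merged <- list(wins[1, ])
  for (i in seq_len(nrow(wins))[-1]) {
    last <- merged[[length(merged)]]
    if (wins[i, 1] <= last[2] + 1e-12) {
      merged[[length(merged)]][2] <- max(last[2], wins[i, 2])
    } else merged[[length(merged) + 1L]] <- wins[i, ]
  }
  mg <- do.call(rbind, merged)
  gaps_lo <- c(0.50, mg[, 2]); gaps_hi <- c(mg[, 1], 4.70)
  keep <- gaps_hi - gaps_lo >= 0.03
  bg <- 0
  for (i in which(keep)) {
    w <- gaps_hi[i] - gaps_lo[i]
    ncent <- max(1L, round(w / 0.2))
    centers <- gaps_lo[i] + w * (seq_len(ncent) - 0.5) / ncent
    # keep the referencing search window free of background resonances
    centers <- centers[centers < 1.42 | centers > 1.54]
    gmw <- min(0.002, w / 20)
    for (ct in centers) bg <- bg + lorentzian(ppm, ct, gmw)
  }
  bg <- bg / trapz(ppm, bg)
  comp <- cbind(shapes, bg)
  # capture matrix: area of each unit component inside each window / total
  capt <- apply(comp, 2, function(y) {
    cf <- cumtrapz_fun(ppm, y)
    c(vapply(peaks, function(p) cf(p$ppm_hi) - cf(p$ppm_lo), 0),
      cf(4.70) - cf(0.50))
  })
  # solve [window areas; total area] = [levels; 100] for amplitudes
  rhs <- rbind(t(levels), 100)
  amps <- solve(capt, rhs)
  if (any(amps < -1e-8)) {
    warning("negative calibrated amplitudes; levels inconsistent with a ",
            "total area of 100 units")
  }
  intens <- comp %*% amps
  base <- if (baseline_amplitude != 0) {
    x01 <- (ppm - ppm_range[1]) / diff(ppm_range)
    baseline_amplitude * 4 * x01 * (1 - x01)
  } else 0
  ids <- rownames(levels)
  if (is.null(ids)) ids <- sprintf("S%04d", seq_len(nrow(levels)))
  spectra <- with_seed(seed, {
    lapply(seq_len(nrow(levels)), function(i) {
      y <- intens[, i] + base
      if (noise_sd > 0) y <- y + stats::rnorm(length(ppm), 0, noise_sd)
      nmr_spectrum(ppm, y, ids[i])
    })
  })
  names(spectra) <- ids
  structure(spectra, class = "nmr_spectra")
}

#' Body mass index
#'
#' @param weight_kg weight in kg.
#' @param height_m height in m (> 0).
#' @return BMI in kg/m2.
#' @export
compute_bmi <- function(weight_kg, height_m) {
  gm_assert(all(height_m > 0), "height must be > 0")
  weight_kg / height_m^2
}

#' Estimated GFR, abbreviated MDRD equation
#'
#' `186 * creatinine^-1.154 * age^-0.203 * (0.742 if female)`.
#'
#' @param creatinine serum creatinine, mg/dl.
#' @param age years.
#' @param female logical (or 0/1).
#' @return eGFR in ml/min/1.73 m2.
#' @export
egfr_mdrd <- function(creatinine, age, female) {
  gm_assert(all(creatinine > 0) && all(age > 0),
            "creatinine and age must be > 0")
  186 * creatinine^-1.154 * age^-0.203 * ifelse(as.logical(female), 0.742, 1)
}
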