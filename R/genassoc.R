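# Genotype QC (call rate, Hardy-Weinberg, MAF), genetic-model association
# of log urinary albumin excretion and microalbuminuria with covariate
# adjustment, Holm-Bonferroni correction, and post-hoc power.

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Pearson chi-square with 1 degree of freedom comparing observed genotype
#' counts to expectations (p^2, 2pq, q^2) at the observed allele frequency.
#' Monomorphic SNPs return chi2 = 0, p = 1.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (major hom, het, minor hom).
#' @return list with `chi2` and `p`.
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  gm_assert(n > 0, "all-zero genotype counts")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  q <- 1 - p
  e <- n * c(p^2, 2 * p * q, q^2)
  o <- c(n_AA, n_Aa, n_aa)
  nz <- e > 0
  chi2 <- sum((o[nz] - e[nz])^2 / e[nz])
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Per-SNP quality control table
#'
#' @param geno integer genotype matrix (0/1/2/NA, subjects x SNPs).
#' @param min_call_rate SNPs must be genotyped in more than this fraction
#'   of subjects (default 0.90, strict inequality).
#' @param hwe_alpha SNPs with Hardy-Weinberg p below this are failed
#'   (default 0.001, the conventional association-QC threshold; the source
#'   analysis does not state its alpha).
#' @return data.frame with one row per SNP: `snp_id`, `call_rate`, `maf`,
#'   `hwe_chi2`, `hwe_p`, `passed`, `fail_reason`.
#' @export
snp_qc <- function(geno, min_call_rate = 0.90, hwe_alpha = 0.001) {
  gm_assert(is.matrix(geno), "geno must be a matrix")
  if (ncol(geno) == 0L) {
    return(data.frame(snp_id = character(), call_rate = numeric(),
                      maf = numeric(), hwe_chi2 = numeric(),
                      hwe_p = numeric(), passed = logical(),
                      fail_reason = character()))
  }
  rows <- lapply(seq_len(ncol(geno)), function(j) {
    g <- geno[, j]
    ok <- !is.na(g)
    cr <- mean(ok)
    n0 <- sum(g[ok] == 0); n1 <- sum(g[ok] == 1); n2 <- sum(g[ok] == 2)
    af <- if (any(ok)) (n1 + 2 * n2) / (2 * sum(ok)) else NA_real_
    maf <- if (is.na(af)) NA_real_ else min(af, 1 - af)
    hw <- if (any(ok)) hwe_test(n0, n1, n2) else list(chi2 = NA_real_,
                                                     p = NA_real_)
    reasons <- character()
    if (!(cr > min_call_rate)) reasons <- c(reasons, "call_rate")
    if (!is.na(hw$p) && hw$p < hwe_alpha) reasons <- c(reasons, "hwe")
    data.frame(snp_id = colnames(geno)[j], call_rate = cr, maf = maf,
               hwe_chi2 = hw$chi2, hwe_p = hw$p,
               passed = length(reasons) == 0,
               fail_reason = paste(reasons, collapse = "+"))
  })
  do.call(rbind, rows)
}

#' Filter SNPs on call rate and Hardy-Weinberg equilibrium
#'
#' @inheritParams snp_qc
#' @return list with `geno` (columns passing QC) and `qc` (full per-SNP
#'   table including the excluded SNPs and their reasons).
#' @export
qc_filter <- function(geno, min_call_rate = 0.90, hwe_alpha = 0.001) {
  qc <- snp_qc(geno, min_call_rate, hwe_alpha)
  keep <- which(qc$passed)
  list(geno = geno[, keep, drop = FALSE], qc = qc)
}

#' Encode genotype calls under a genetic model
#'
#' ADD keeps the minor-allele count (0/1/2); DOM codes carriers as 1
#' (0/1/1); REC codes minor homozygotes as 1 (0/0/1). Missing calls
#' propagate.
#'
#' @param calls integer vector of 0/1/2/NA genotype codes.
#' @param model `"ADD"`, `"DOM"` or `"REC"`.
#' @return numeric vector.
#' @export
encode_model <- function(calls, model = c("ADD", "DOM", "REC")) {
  model <- match.arg(model)
  gm_assert(all(calls %in% c(0, 1, 2) | is.na(calls)),
            "genotype codes must be 0, 1, 2 or NA")
  switch(model,
         ADD = as.numeric(calls),
         DOM = as.numeric(pmin(calls, 1L)),
         REC = as.numeric(calls == 2L))
}

check_design <- function(design) {
  qrD <- qr(design)
  if (qrD$rank < ncol(design)) {
    dropped <- colnames(design)[qrD$pivot[(qrD$rank + 1):ncol(design)]]
    gm_stop(paste0("design matrix is rank deficient; collinear columns: ",
                   paste(dropped, collapse = ", ")),
            class = "genometab_rank_error")
  }
}

#' Linear association of log urinary albumin excretion with a coded SNP
#'
#' Ordinary least squares of log10 UAE on the coded genotype plus the
#' adjustment covariates (age, sex, BMI, systolic BP, fasting glucose in
#' the canonical analysis). Complete-case: subjects with any missing value
#' are dropped and `n_used` reported. The genotype p-value is the
#' two-sided t test of its coefficient.
#'
#' @param log_uae numeric outcome vector.
#' @param geno_coded coded genotype from [encode_model()].
#' @param covariates numeric matrix (or data.frame) of adjustment
#'   covariates; may have zero columns.
#' @param snp_id,model labels copied into the result.
#' @param alpha level used for the post-hoc power column.
#' @return one-row data.frame: `snp_id`, `model`, `beta`, `se`, `p`,
#'   `power`, `n_used`.
#' @export
assoc_linear <- function(log_uae, geno_coded, covariates = NULL,
                         snp_id = "snp", model = "ADD", alpha = 0.05) {
  covariates <- as.matrix(if (is.null(covariates)) {
    matrix(numeric(0), length(log_uae), 0)
  } else covariates)
  cc <- stats::complete.cases(log_uae, geno_coded, covariates)
  gm_assert(sum(cc) >= 10, "fewer than 10 complete cases")
  y <- log_uae[cc]
  g <- geno_coded[cc]
  Z <- covariates[cc, , drop = FALSE]
  gm_assert(stats::var(g) > 0, "genotype column is constant")
  design <- cbind(intercept = 1, genotype = g, Z)
  check_design(design)
  fit <- stats::lm.fit(design, y)
  rdf <- length(y) - ncol(design)
  sigma2 <- sum(fit$residuals^2) / rdf
  XtXinv <- chol2inv(chol(crossprod(design)))
  se <- sqrt(sigma2 * XtXinv[2, 2])
  beta <- fit$coefficients[["genotype"]]
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), rdf, lower.tail = FALSE)
  data.frame(snp_id = snp_id, model = model, beta = beta, se = se, p = p,
             power = posthoc_power(beta, se, alpha), n_used = sum(cc))
}

#' Logistic association of microalbuminuria with a coded SNP
#'
#' Maximum-likelihood logistic regression with Wald p-value for the
#' genotype term. Non-convergence and (quasi-)separation are detected and
#' flagged rather than raised.
#'
#' @param malb 0/1 microalbuminuria flags.
#' @param geno_coded coded genotype from [encode_model()].
#' @inheritParams assoc_linear
#' @return one-row data.frame: `snp_id`, `model`, `beta` (log-odds), `se`,
#'   `p`, `or`, `n_used`, `converged`, `separation`.
#' @export
assoc_logistic <- function(malb, geno_coded, covariates = NULL,
                           snp_id = "snp", model = "ADD") {
  covariates <- as.matrix(if (is.null(covariates)) {
    matrix(numeric(0), length(malb), 0)
  } else covariates)
  cc <- stats::complete.cases(malb, geno_coded, covariates)
  gm_assert(sum(cc) >= 10, "fewer than 10 complete cases")
  y <- as.numeric(malb[cc])
  g <- geno_coded[cc]
  Z <- covariates[cc, , drop = FALSE]
  gm_assert(stats::var(g) > 0, "genotype column is constant")
  design <- cbind(intercept = 1, genotype = g, Z)
  check_design(design)
  fit <- suppressWarnings(
    stats::glm.fit(design, y, family = stats::binomial()))
  mu <- fit$fitted.values
  separation <- any(mu < 1e-8 | mu > 1 - 1e-8) ||
    abs(fit$coefficients[2]) > 15
  W <- mu * (1 - mu)
  cov <- tryCatch(chol2inv(chol(crossprod(design * sqrt(W)))),
                  error = function(e) matrix(NA_real_, ncol(design),
                                             ncol(design)))
  beta <- fit$coefficients[["genotype"]]
  se <- sqrt(cov[2, 2])
  p <- 2 * stats::pnorm(abs(beta / se), lower.tail = FALSE)
  data.frame(snp_id = snp_id, model = model, beta = beta, se = se, p = p,
             or = exp(beta), n_used = sum(cc), converged = fit$converged,
             separation = separation)
}

#' Holm-Bonferroni step-down multiple-testing correction
#'
#' Sorts p-values ascending, compares `p_(i)` with `alpha / (m - i + 1)`
#' and stops at the first failure; adjusted p-values are
#' `max_{j<=i} min(1, (m - j + 1) p_(j))`, monotone non-decreasing in
#' sorted order.
#'
#' @param pvals numeric p-values.
#' @param alpha family-wise error level (default 0.05).
#' @return list with `adjusted` (same order as input) and `reject`.
#' @export
holm_bonferroni <- function(pvals, alpha = 0.05) {
  gm_assert(all(pvals >= 0 & pvals <= 1, na.rm = TRUE),
            "p-values must lie in [0,1]")
  m <- length(pvals)
  o <- order(pvals)
  adj_sorted <- cummax(pmin(1, (m - seq_len(m) + 1) * pvals[o]))
  adjusted <- numeric(m)
  adjusted[o] <- adj_sorted
  # step-down rejection: reject while p_(i) <= alpha/(m-i+1)
  crit <- alpha / (m - seq_len(m) + 1)
  pass <- pvals[o] <= crit
  k <- match(FALSE, pass, nomatch = m + 1L) - 1L
  reject <- logical(m)
  if (k >= 1) reject[o[seq_len(k)]] <- TRUE
  list(adjusted = adjusted, reject = reject)
}

#' Post-hoc power, normal approximation
#'
#' `power = Phi(|beta|/se - z) + Phi(-|beta|/se - z)` with
#' `z = qnorm(1 - alpha/2)`: the probability that a Wald test at level
#' `alpha` rejects when the true effect equals the estimate.
#'
#' @param beta effect estimate.
#' @param se its standard error (> 0).
#' @param alpha test level (default 0.05).
#' @return power fraction in `[0,1]`.
#' @export
posthoc_power <- function(beta, se, alpha = 0.05) {
  gm_assert(all(se > 0), "se must be > 0")
  z <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(abs(beta) / se - z) + stats::pnorm(-abs(beta) / se - z)
}

#' Association scan over SNPs and genetic models
#'
#' Fits the adjusted linear model for every SNP under each requested
#' genetic model, appends Holm-Bonferroni adjusted p-values (computed over
#' all fits), and flags each SNP's minimum-p model.
#'
#' @param geno genotype matrix (0/1/2/NA).
#' @param pheno phenotype table with `log_uae` and the covariate columns.
#' @param covars covariate column names (default age, sex, bmi, sbp,
#'   glucose).
#' @param models genetic models to fit.
#' @param alpha level for Holm rejection and power.
#' @return data.frame of [assoc_linear()] rows with `p_holm`, `reject`,
#'   and `best_model` columns.
#' @export
assoc_scan <- function(geno, pheno,
                       covars = c("age", "sex", "bmi", "sbp", "glucose"),
                       models = c("ADD", "DOM", "REC"), alpha = 0.05) {
  gm_assert(all(covars %in% names(pheno)),
            paste0("missing covariate columns: ",
                   paste(setdiff(covars, names(pheno)), collapse = ", ")))
  Z <- as.matrix(pheno[, covars, drop = FALSE])
  rows <- list()
  for (j in seq_len(ncol(geno))) {
    for (mdl in models) {
      x <- encode_model(geno[, j], mdl)
      res <- tryCatch(
        assoc_linear(pheno$log_uae, x, Z, snp_id = colnames(geno)[j],
                     model = mdl, alpha = alpha),
        genometab_error = function(e) NULL)
      if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  hb <- holm_bonferroni(out$p, alpha)
  out$p_holm <- hb$adjusted
  out$reject <- hb$reject
  best <- stats::aggregate(p ~ snp_id, out, min)
  out$best_model <- out$p == best$p[match(out$snp_id, best$snp_id)]
  rownames(out) <- NULL
  out
}
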