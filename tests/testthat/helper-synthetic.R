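# Small in-code fixtures shared across test files.

# Two Gaussian clouds separated by delta SDs along every feature.
make_clouds <- function(n = 100, p = 5, delta = 0, seed = 1,
                        prevalence = 0.5) {
  set.seed(seed)
  y <- as.integer(seq_len(n) %% round(1 / prevalence) == 0)
  X <- matrix(rnorm(n * p), n, p) + delta * y
  colnames(X) <- sprintf("f%02d", seq_len(p))
  list(X = X, y = y)
}

# Tiny complete cohort (covariates + genotypes + UAE + metabolites).
make_cohort <- function(n = 200, seed = 1, snps = default_snp_specs(),
                        prevalence = 0.07) {
  ph <- gen_covariates(n, seed = seed)
  g <- gen_genotypes(n, snps, seed = seed + 1)
  ph <- gen_uae(ph, g, snps,
                effect_spec(target_prevalence = prevalence),
                seed = seed + 2)
  lv <- gen_metabolite_levels(ph, seed = seed + 3)
  list(pheno = ph, geno = g, metab = lv)
}

# Single-Lorentzian spectrum fixture with known analytic window integral.
lorentz_fixture <- function(center = 2.0, gamma = 0.01, amp = 1,
                            dppm = 5e-4, range = c(0.4, 4.8)) {
  ppm <- seq(range[1], range[2], by = dppm)
  nmr_spectrum(ppm, amp * (gamma / pi) / ((ppm - center)^2 + gamma^2),
               "lorentz")
}

lorentz_integral <- function(lo, hi, center, gamma, amp = 1) {
  amp / pi * (atan((hi - center) / gamma) - atan((lo - center) / gamma))
}
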