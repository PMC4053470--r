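# File-format layer: phenotype CSV, genotype matrices (PLINK-style
# ped/map text and a simple TSV dialect), and per-sample spectrum TSVs
# with a manifest. All text is UTF-8 with '.' decimal separator and a
# mandatory header row (ped/map excepted, per the PLINK convention).

#' Read a phenotype table
#'
#' Requires `subject_id` and `acr` (or a precomputed `log_uae`).
#' `log_uae` is derived as log10(ACR) and `malb` as ACR >= `threshold`
#' (30 ug/mg) when absent. Rows with ACR <= 0 are rejected (log undefined)
#' and reported in attribute `"excluded"`.
#'
#' @param path CSV path.
#' @param threshold microalbuminuria cut-off in ug/mg (default 30; the
#'   `>=` convention).
#' @return phenotype data.frame.
#' @export
read_phenotypes <- function(path, threshold = 30) {
  ph <- utils::read.csv(path, stringsAsFactors = FALSE)
  gm_assert("subject_id" %in% names(ph),
            "phenotype CSV is missing required column: subject_id",
            class = "genometab_schema_error")
  if (!("acr" %in% names(ph)) && "log_uae" %in% names(ph)) {
    ph$acr <- 10^ph$log_uae
  }
  gm_assert("acr" %in% names(ph),
            "phenotype CSV is missing required column: acr",
            class = "genometab_schema_error")
  bad <- !is.na(ph$acr) & ph$acr <= 0
  excluded <- ph$subject_id[bad]
  if (any(bad)) {
    warning(sprintf("%d row(s) with ACR <= 0 rejected (log undefined): %s",
                    sum(bad), paste(excluded, collapse = ", ")))
    ph <- ph[!bad, , drop = FALSE]
  }
  if (is.null(ph$log_uae)) ph$log_uae <- log10(ph$acr)
  if (is.null(ph$malb)) ph$malb <- as.integer(ph$acr >= threshold)
  attr(ph, "excluded") <- excluded
  ph
}

#' Write a phenotype table
#'
#' @param pheno phenotype data.frame.
#' @param path CSV destination.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.csv(pheno, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

code_from_alleles <- function(a1, a2, missing_codes = c("0", "NA", "")) {
  miss <- a1 %in% missing_codes | a2 %in% missing_codes | is.na(a1) |
    is.na(a2)
  alleles <- c(a1[!miss], a2[!miss])
  if (length(alleles) == 0) {
    return(list(code = rep(NA_integer_, length(a1)), minor = NA_character_,
                major = NA_character_))
  }
  tabf <- table(alleles)
  lev <- names(sort(tabf))  # ascending frequency; ties: lexicographic
  if (length(lev) == 1) {   # monomorphic: zero copies of the absent minor
    code <- rep(0L, length(a1))
    code[miss] <- NA_integer_
    return(list(code = code, minor = NA_character_, major = lev[1]))
  }
  minor <- lev[1]
  major <- lev[length(lev)]
  code <- (a1 == minor) + (a2 == minor)
  code[miss] <- NA_integer_
  list(code = as.integer(code), minor = minor, major = major)
}

#' Read a genotype matrix
#'
#' Two text dialects are supported. PLINK-style ped/map: whitespace
#' separated, six leading ped columns, two allele columns per SNP,
#' missing allele = 0. Simple TSV: header row, first column `subject_id`,
#' one column per SNP holding two-letter genotype strings (e.g. `AA`,
#' `AB`, `CT`) or `NA`. The minor allele is recomputed from the data per
#' SNP (ties broken lexicographically); `minor_override` pins reference
#' minor alleles (named character vector) for a reproducible beta sign.
#'
#' @param path ped or TSV path.
#' @param map map-file path (required for the ped dialect).
#' @param dialect `"auto"` (by extension), `"pedmap"` or `"tsv"`.
#' @param minor_override optional named vector snp_id -> minor allele.
#' @return integer matrix subjects x SNPs (0/1/2/NA, copies of the minor
#'   allele) with an `"alleles"` attribute (data.frame snp_id, minor,
#'   major).
#' @export
read_genotypes <- function(path, map = NULL,
                           dialect = c("auto", "pedmap", "tsv"),
                           minor_override = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.ped$", path)) "pedmap" else "tsv"
  }
  if (dialect == "pedmap") {
    gm_assert(!is.null(map), "ped dialect requires a map file",
              class = "genometab_schema_error")
    mp <- utils::read.table(map, header = FALSE, stringsAsFactors = FALSE)
    snp_ids <- as.character(mp[[2]])
    pd <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                            colClasses = "character")
    gm_assert(ncol(pd) == 6 + 2 * length(snp_ids),
              "ped column count does not match the map",
              class = "genometab_schema_error")
    ids <- pd[[2]]
    geno <- matrix(NA_integer_, nrow(pd), length(snp_ids),
                   dimnames = list(ids, snp_ids))
    alleles <- data.frame(snp_id = snp_ids, minor = NA_character_,
                          major = NA_character_)
    for (j in seq_along(snp_ids)) {
      a1 <- pd[[5 + 2 * j]]; a2 <- pd[[6 + 2 * j]]
      cf <- code_from_alleles(a1, a2)
      cf <- apply_minor_override(cf, a1, a2, snp_ids[j], minor_override)
      geno[, j] <- cf$code
      alleles$minor[j] <- cf$minor; alleles$major[j] <- cf$major
    }
  } else {
    tb <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    gm_assert(names(tb)[1] == "subject_id",
              "genotype TSV must start with a subject_id column",
              class = "genometab_schema_error")
    ids <- tb$subject_id
    snp_ids <- names(tb)[-1]
    geno <- matrix(NA_integer_, length(ids), length(snp_ids),
                   dimnames = list(ids, snp_ids))
    alleles <- data.frame(snp_id = snp_ids, minor = NA_character_,
                          major = NA_character_)
    for (j in seq_along(snp_ids)) {
      gs <- tb[[snp_ids[j]]]
      gs[gs %in% c("NA", "")] <- NA
      a1 <- substr(gs, 1, 1); a2 <- substr(gs, 2, 2)
      cf <- code_from_alleles(a1, a2)
      cf <- apply_minor_override(cf, a1, a2, snp_ids[j], minor_override)
      geno[, j] <- cf$code
      alleles$minor[j] <- cf$minor; alleles$major[j] <- cf$major
    }
  }
  attr(geno, "alleles") <- alleles
  geno
}

apply_minor_override <- function(cf, a1, a2, snp_id, minor_override) {
  if (is.null(minor_override) || !(snp_id %in% names(minor_override))) {
    return(cf)
  }
  minor <- minor_override[[snp_id]]
  miss <- is.na(cf$code)
  code <- (a1 == minor) + (a2 == minor)
  code[miss] <- NA_integer_
  major <- setdiff(unique(c(a1, a2)[!(c(a1, a2) %in%
                                        c(minor, "0", "NA", NA))]), minor)
  list(code = as.integer(code), minor = minor,
       major = if (length(major)) major[1] else cf$major)
}

#' Write a genotype matrix in the simple TSV dialect
#'
#' Codes 0/1/2 become `AA`/`AB`/`BB` (A = major, B = minor allele label);
#' missing becomes `NA`.
#'
#' @param geno integer matrix (0/1/2/NA).
#' @param path destination TSV.
#' @export
write_genotypes_tsv <- function(geno, path) {
  lab <- c("AA", "AB", "BB")
  chr <- apply(geno, 2, function(g) ifelse(is.na(g), "NA", lab[g + 1L]))
  out <- data.frame(subject_id = rownames(geno), chr, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a genotype matrix as PLINK-style ped/map text
#'
#' @param geno integer matrix (0/1/2/NA).
#' @param prefix output prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @param chr optional chromosome labels per SNP (default 0).
#' @export
write_pedmap <- function(geno, prefix, chr = NULL) {
  snps <- colnames(geno)
  if (is.null(chr)) chr <- rep(0, length(snps))
  mp <- data.frame(chr = chr, snp = snps, cm = 0, bp = seq_along(snps))
  utils::write.table(mp, paste0(prefix, ".map"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  al <- list(c("A", "A"), c("A", "B"), c("B", "B"))
  ped_alleles <- lapply(seq_len(ncol(geno)), function(j) {
    g <- geno[, j]
    a <- vapply(seq_along(g), function(i) {
      if (is.na(g[i])) c("0", "0") else al[[g[i] + 1L]]
    }, character(2))
    t(a)
  })
  ped <- cbind(rownames(geno), rownames(geno), "0", "0", "0", "-9",
               do.call(cbind, ped_alleles))
  utils::write.table(ped, paste0(prefix, ".ped"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a spectrum collection from a manifest
#'
#' The manifest CSV has columns `sample_id`, `path` (paths relative to the
#' manifest's directory); each spectrum file is a two-column TSV
#' (`ppm`, `intensity`) with a header.
#'
#' @param manifest manifest CSV path.
#' @return list of [nmr_spectrum()] objects.
#' @export
read_spectra <- function(manifest) {
  mf <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  gm_assert(all(c("sample_id", "path") %in% names(mf)),
            "manifest must have columns sample_id, path",
            class = "genometab_schema_error")
  base <- dirname(manifest)
  out <- lapply(seq_len(nrow(mf)), function(i) {
    tb <- utils::read.delim(file.path(base, mf$path[i]))
    gm_assert(all(c("ppm", "intensity") %in% names(tb)),
              paste0("spectrum file lacks ppm/intensity columns: ",
                     mf$path[i]),
              class = "genometab_schema_error")
    nmr_spectrum(tb$ppm, tb$intensity, mf$sample_id[i])
  })
  names(out) <- mf$sample_id
  structure(out, class = "nmr_spectra")
}

#' Write a spectrum collection and its manifest
#'
#' @param spectra list of [nmr_spectrum()] objects.
#' @param dir output directory (created if needed).
#' @param manifest manifest file name inside `dir`.
#' @param digits significant digits for intensities (default 8).
#' @return the manifest path, invisibly.
#' @export
write_spectra <- function(spectra, dir, manifest = "manifest.csv",
                          digits = 8) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(spectra, function(sp) {
    fn <- paste0(sp$sample_id, ".tsv")
    tb <- data.frame(ppm = sp$ppm,
                     intensity = signif(sp$intensity, digits))
    utils::write.table(tb, file.path(dir, fn), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    fn
  }, "")
  mf <- data.frame(sample_id = vapply(spectra, `[[`, "", "sample_id"),
                   path = paths)
  utils::write.csv(mf, file.path(dir, manifest), row.names = FALSE,
                   quote = FALSE)
  invisible(file.path(dir, manifest))
}

#' Write a metabolite (or binned) matrix
#'
#' @param m numeric matrix with row names.
#' @param path CSV destination.
#' @export
write_feature_matrix <- function(m, path) {
  out <- data.frame(subject_id = rownames(m), m, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a metabolite (or binned) matrix written by
#' [write_feature_matrix()]
#'
#' @param path CSV path.
#' @return numeric matrix with subject ids as row names.
#' @export
read_feature_matrix <- function(path) {
  tb <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  gm_assert(names(tb)[1] == "subject_id",
            "feature matrix must start with subject_id",
            class = "genometab_schema_error")
  m <- as.matrix(tb[, -1, drop = FALSE])
  rownames(m) <- tb$subject_id
  m
}
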