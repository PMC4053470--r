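#' Packaged serum metabolite reference panel
#'
#' The 26-region serum panel: metabolite name, ppm window, and group
#' mean/SD of the relative level (per 100 units of total aliphatic
#' spectral area) in normoalbuminuric and microalbuminuric subjects. These
#' values parameterize the synthetic-cohort generator and name the columns
#' of every [quantify_metabolites()] output.
#'
#' @return data.frame with columns `name`, `ppm_lo`, `ppm_hi`,
#'   `mean_normo`, `sd_normo`, `mean_malb`, `sd_malb`.
#' @export
metabolite_reference <- function() {
  path <- system.file("extdata", "metabolite_reference.tsv",
                      package = "genometab", mustWork = TRUE)
  ref <- utils::read.delim(path, stringsAsFactors = FALSE)
  gm_assert(nrow(ref) == 26L, "metabolite reference must have 26 rows")
  ref
}

#' Load packaged or user-supplied spectral region definitions
#'
#' Two region sets are packaged: the 26 metabolite quantification windows
#' (which may overlap, e.g. pyruvate 2.34-2.38 inside 2.34-2.41) and a
#' 51-region non-overlapping analysis tiling of the 0.50-4.70 ppm aliphatic
#' window whose boundaries contain every metabolite window edge.
#'
#' @param role `"metabolite"` (26 windows) or `"analysis"` (51 tiles).
#' @param path optional TSV with columns `name`, `ppm_lo`, `ppm_hi`
#'   (and optionally `role`) overriding the packaged set.
#' @return data.frame with columns `name`, `ppm_lo`, `ppm_hi`, `role`.
#' @export
load_region_definitions <- function(role = c("metabolite", "analysis"),
                                    path = NULL) {
  role <- match.arg(role)
  if (is.null(path)) {
    if (role == "analysis") {
      path <- system.file("extdata", "analysis_regions.tsv",
                          package = "genometab", mustWork = TRUE)
      defs <- utils::read.delim(path, stringsAsFactors = FALSE)
    } else {
      ref <- metabolite_reference()
      defs <- data.frame(name = ref$name, ppm_lo = ref$ppm_lo,
                         ppm_hi = ref$ppm_hi, role = "metabolite_region",
                         stringsAsFactors = FALSE)
    }
  } else {
    defs <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (is.null(defs$role)) {
      defs$role <- if (role == "analysis") "analysis_region" else "metabolite_region"
    }
  }
  validate_regions(defs)
  defs
}

validate_regions <- function(defs) {
  gm_assert(all(c("name", "ppm_lo", "ppm_hi", "role") %in% names(defs)),
            "region definitions need columns name, ppm_lo, ppm_hi, role")
  gm_assert(all(defs$ppm_lo < defs$ppm_hi), "region ppm_lo must be < ppm_hi")
  gm_assert(all(defs$ppm_lo >= 0.50 - 1e-9) && all(defs$ppm_hi <= 4.70 + 1e-9),
            "regions must lie within the 0.50-4.70 ppm aliphatic window")
  ana <- defs[defs$role == "analysis_region", , drop = FALSE]
  if (nrow(ana) > 1L) {
    o <- order(ana$ppm_lo)
    gm_assert(all(ana$ppm_hi[o][-nrow(ana)] <= ana$ppm_lo[o][-1] + 1e-9),
              "analysis regions must not overlap")
  }
  invisible(defs)
}
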