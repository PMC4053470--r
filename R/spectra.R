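# 1H-NMR spectrum preprocessing: alanine-doublet referencing, 0.01 ppm
# bucketing over the 0.50-4.70 ppm aliphatic window, total-area
# normalization, region reduction and metabolite quantification.

#' Construct an NMR spectrum object
#'
#' @param ppm strictly monotone chemical-shift axis (ppm).
#' @param intensity signal, same length as `ppm`.
#' @param sample_id identifier.
#' @return object of class `nmr_spectrum`.
#' @export
nmr_spectrum <- function(ppm, intensity, sample_id = "sample") {
  gm_assert(length(ppm) == length(intensity) && length(ppm) >= 2,
            "ppm and intensity must have equal length >= 2")
  d <- diff(ppm)
  gm_assert(all(d > 0) || all(d < 0), "ppm axis must be strictly monotone")
  if (all(d < 0)) { ppm <- rev(ppm); intensity <- rev(intensity) }
  structure(list(ppm = as.numeric(ppm), intensity = as.numeric(intensity),
                 sample_id = as.character(sample_id)),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum %s: %d points, %.3f-%.3f ppm>\n",
              x$sample_id, length(x$ppm), min(x$ppm), max(x$ppm)))
  invisible(x)
}

#' Reference a spectrum to the alanine doublet
#'
#' Locates the alanine doublet inside the search window (default
#' 1.43-1.53 ppm) and shifts the ppm axis so the doublet midpoint sits at
#' `target_ppm` (1.478 ppm). If only one local maximum is found it is used
#' directly; two maxima closer than `max_doublet_split` are averaged.
#'
#' @param spec an [nmr_spectrum()].
#' @param target_ppm reference position, default 1.478.
#' @param search_window ppm interval searched for the doublet.
#' @param max_doublet_split maximal separation (ppm) for two maxima to be
#'   treated as one doublet; default 0.025.
#' @return the shifted spectrum; the applied shift is in attribute
#'   `"shift"`.
#' @export
reference_spectrum <- function(spec, target_ppm = 1.478,
                               search_window = c(1.43, 1.53),
                               max_doublet_split = 0.025) {
  gm_assert(inherits(spec, "nmr_spectrum"), "spec must be an nmr_spectrum")
  sel <- which(spec$ppm >= search_window[1] & spec$ppm <= search_window[2])
  gm_assert(length(sel) >= 3, "spectrum does not cover the search window",
            class = "genometab_referencing_error")
  y <- spec$intensity[sel]
  i <- 2:(length(y) - 1)
  locmax <- i[y[i] > y[i - 1] & y[i] > y[i + 1]]
  if (length(locmax) == 0) {
    gm_stop(sprintf(
      "no local maximum in [%.2f, %.2f] ppm: cannot reference (flat spectrum?)",
      search_window[1], search_window[2]),
      class = "genometab_referencing_error")
  }
  locmax <- locmax[order(y[locmax], decreasing = TRUE)]
  pk <- spec$ppm[sel][locmax[1]]
  if (length(locmax) >= 2) {
    pk2 <- spec$ppm[sel][locmax[2]]
    # second line of the doublet must be comparable in height
    if (abs(pk2 - pk) <= max_doublet_split &&
        y[locmax[2]] >= 0.5 * y[locmax[1]]) {
      pk <- (pk + pk2) / 2
    }
  }
  shift <- target_ppm - pk
  out <- nmr_spectrum(spec$ppm + shift, spec$intensity, spec$sample_id)
  attr(out, "shift") <- shift
  out
}

#' Bin a spectrum into fixed-width buckets
#'
#' Buckets are half-open `[lo, lo + width)` intervals anchored at the
#' window start (default 0.50 ppm, 0.01 ppm width: exactly 420 buckets over
#' 0.50-4.70). Per-bucket areas come from trapezoidal integration on the
#' native grid, with linear interpolation at bucket edges, so the summed
#' bucket area equals the window integral exactly for piecewise-linear
#' signals.
#'
#' @param spec an [nmr_spectrum()] covering the window.
#' @param width bucket width in ppm (default 0.01).
#' @param window analysis window, default `c(0.50, 4.70)`.
#' @return object of class `binned_spectrum` with fields `bin_edges`,
#'   `bin_areas`, `normalized`, `sample_id`.
#' @export
bin_spectrum <- function(spec, width = 0.01, window = c(0.50, 4.70)) {
  gm_assert(inherits(spec, "nmr_spectrum"), "spec must be an nmr_spectrum")
  gm_assert(min(spec$ppm) <= window[1] + 1e-12 &&
              max(spec$ppm) >= window[2] - 1e-12,
            "spectrum does not cover the analysis window",
            class = "genometab_coverage_error")
  nb <- round((window[2] - window[1]) / width)
  gm_assert(abs(nb * width - (window[2] - window[1])) < 1e-9,
            "window must be an integer number of buckets")
  edges <- window[1] + width * (0:nb)
  cf <- cumtrapz_fun(spec$ppm, spec$intensity)
  areas <- diff(cf(edges))
  structure(list(bin_edges = edges, bin_areas = areas, normalized = FALSE,
                 sample_id = spec$sample_id),
            class = "binned_spectrum")
}

#' Normalize a binned spectrum to total aliphatic area
#'
#' Divides every bucket by the summed area over the whole analysis window,
#' removing differences in total metabolite concentration; the output sums
#' to 1.
#'
#' @param b a [bin_spectrum()] result.
#' @return normalized `binned_spectrum`.
#' @export
normalize_total_area <- function(b) {
  gm_assert(inherits(b, "binned_spectrum"), "b must be a binned_spectrum")
  total <- sum(b$bin_areas)
  gm_assert(is.finite(total) && total > 0,
            "total spectral area must be > 0",
            class = "genometab_normalization_error")
  b$bin_areas <- b$bin_areas / total
  b$normalized <- TRUE
  b
}

#' Reduce a binned spectrum to named regions
#'
#' Each region's value is the sum of bucket areas whose bucket midpoint
#' falls in `[ppm_lo, ppm_hi)`. Analysis regions must not overlap;
#' metabolite regions may (shared area is counted in both).
#'
#' @param b a `binned_spectrum`.
#' @param defs region definitions (see [load_region_definitions()]).
#' @return named numeric vector, one value per region.
#' @export
reduce_regions <- function(b, defs) {
  gm_assert(inherits(b, "binned_spectrum"), "b must be a binned_spectrum")
  validate_regions(defs)
  mids <- utils::head(b$bin_edges, -1) + diff(b$bin_edges) / 2
  out <- vapply(seq_len(nrow(defs)), function(i) {
    sum(b$bin_areas[mids >= defs$ppm_lo[i] & mids < defs$ppm_hi[i]])
  }, 0)
  names(out) <- defs$name
  out
}

#' Quantify metabolite relative levels for a spectrum collection
#'
#' For every spectrum: (optionally) reference to the alanine doublet, bin
#' into 0.01 ppm buckets over 0.50-4.70 ppm, normalize to total aliphatic
#' area, and integrate the metabolite windows. Levels are reported per
#' `scale` units of total aliphatic area (default 100, the scale of the
#' packaged reference panel).
#'
#' @param spectra list of [nmr_spectrum()] objects.
#' @param defs metabolite region definitions (default: packaged 26-window
#'   panel).
#' @param reference reference each spectrum first? Default TRUE.
#' @param scale output scale; default 100.
#' @param width,window bucketing parameters, see [bin_spectrum()].
#' @return numeric matrix subjects x regions (panel column order); row
#'   names are sample ids.
#' @export
quantify_metabolites <- function(spectra,
                                 defs = load_region_definitions("metabolite"),
                                 reference = TRUE, scale = 100,
                                 width = 0.01, window = c(0.50, 4.70)) {
  gm_assert(length(spectra) >= 1, "empty spectrum collection")
  rows <- lapply(spectra, function(sp) {
    if (reference) sp <- reference_spectrum(sp)
    b <- normalize_total_area(bin_spectrum(sp, width = width, window = window))
    reduce_regions(b, defs) * scale
  })
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(spectra, `[[`, "", "sample_id")
  m
}

#' Column mean-centre a matrix
#'
#' @param m numeric matrix.
#' @return centred matrix; the centring vector is kept in attribute
#'   `"center"` so new samples can be projected consistently.
#' @export
mean_center <- function(m) {
  gm_assert(is.matrix(m) && is.numeric(m), "m must be a numeric matrix")
  ctr <- colMeans(m)
  out <- sweep(m, 2, ctr)
  attr(out, "center") <- ctr
  out
}
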