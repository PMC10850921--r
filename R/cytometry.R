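## Flow-cytometry genome-size estimation against an internal standard and
## ploidy inference relative to a diploid baseline.

#' Estimate 1C genome size from a peak pair
#'
#' `size = (sample_peak / internal_peak) * internal_size`: fluorescence is
#' assumed linear in DNA content, calibrated by a single co-processed internal
#' standard (rice, 1C = 373,245,519 bp, by default). Scale-invariant in the
#' peak units.
#'
#' @param sample_peak,internal_peak Fluorescence mode positions (same
#'   arbitrary units).
#' @param internal_size 1C size of the internal standard in bp.
#' @return Estimated 1C size in bp.
#' @export
estimate_genome_size <- function(sample_peak, internal_peak,
                                 internal_size = 373245519) {
  if (any(sample_peak <= 0) || any(internal_peak <= 0) ||
      any(internal_size <= 0))
    stop("peaks and internal size must be positive")
  sample_peak / internal_peak * internal_size
}

#' Infer ploidy from a 1C size and a diploid baseline
#'
#' `ploidy = 2 * round(size_1C / baseline)` (round half up), reporting the
#' raw ratio alongside. Even ploidy by construction.
#'
#' @param size_1C Estimated 1C size (bp).
#' @param baseline_diploid_1C 1C size of a known diploid (bp).
#' @return list(ploidy, ratio, size_1C, baseline_1C).
#' @export
infer_ploidy <- function(size_1C, baseline_diploid_1C) {
  if (size_1C <= 0 || baseline_diploid_1C <= 0)
    stop("sizes must be positive")
  ratio <- size_1C / baseline_diploid_1C
  if (ratio < 0.25)
    stop("size ratio ", signif(ratio, 3),
         " is implausibly low for the chosen baseline")
  ## round half up
  mult <- floor(ratio + 0.5)
  list(ploidy = 2L * as.integer(max(1, mult)), ratio = ratio,
       size_1C = size_1C, baseline_1C = baseline_diploid_1C)
}

#' Genome-size and ploidy report for a peak table
#'
#' @param peaks data.frame with `peak`, `internal_peak`, `internal_size`, an
#'   id column (`sample`), and optionally a logical `diploid_flag`.
#' @param baseline Either a fixed diploid 1C size in bp, or "median-diploid"
#'   to use the median estimated size of rows flagged diploid.
#' @return data.frame mirroring the published layout: sample columns plus
#'   `genome_size`, `ratio`, `ploidy`.
#' @export
batch_report <- function(peaks, baseline = "median-diploid") {
  stopifnot(nrow(peaks) >= 1L,
            all(c("peak", "internal_peak", "internal_size") %in%
                names(peaks)))
  size <- estimate_genome_size(peaks$peak, peaks$internal_peak,
                               peaks$internal_size)
  if (identical(baseline, "median-diploid")) {
    if (is.null(peaks$diploid_flag) || !any(peaks$diploid_flag))
      stop("baseline policy 'median-diploid' needs diploid-flagged rows")
    base <- stats::median(size[peaks$diploid_flag])
  } else {
    base <- as.numeric(baseline)
    if (!is.finite(base) || base <= 0)
      stop("fixed baseline must be a positive size in bp")
  }
  pl <- lapply(size, infer_ploidy, baseline_diploid_1C = base)
  out <- peaks
  out$genome_size <- size
  out$ratio <- vapply(pl, `[[`, 0, "ratio")
  out$ploidy <- vapply(pl, `[[`, 0L, "ploidy")
  attr(out, "baseline_1C") <- base
  out
}
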