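#' Analysis thresholds
#'
#' Bundle of the cutoffs used across the pipeline, with the defaults used
#' throughout the methylation/binding analysis:
#'
#' * `hi_peak_threshold` — a peak is "hi-methyl" when its mean CpG
#'   methylation is strictly greater than this (default 0.6).
#' * `site_high`, `site_low` — binding-site grouping: level > `site_high`
#'   is "high", level < `site_low` is "low", anything between is "middle"
#'   (defaults 0.6 and 0.2).
#' * `min_peak_count` — ChIP-seq datasets with fewer peaks than this are
#'   dropped (default 500; "fewer than" is strict, so 500 peaks survive).
#' * `conserved_occupancy` — a reference peak is conserved when the
#'   fraction of surveyed cell types occupying it is strictly greater
#'   than this (default 0.8).
#' * `flank_bp` — half-width of methylation metaplots around binding-site
#'   centers (default 1600 bp).
#' * `gene_window_bp` — regions are extended by this much on each side
#'   when collecting nearby genes (default 1000 bp).
#'
#' @param hi_peak_threshold,site_high,site_low,min_peak_count,conserved_occupancy,flank_bp,gene_window_bp
#'   Override any default.
#' @return A named list of class `"pipeline_thresholds"`.
#' @examples
#' th <- pipeline_thresholds()
#' th$hi_peak_threshold
#' @export
pipeline_thresholds <- function(hi_peak_threshold = 0.6,
                                site_high = 0.6,
                                site_low = 0.2,
                                min_peak_count = 500,
                                conserved_occupancy = 0.8,
                                flank_bp = 1600,
                                gene_window_bp = 1000) {
  stopifnot(
    is.numeric(site_low), is.numeric(site_high),
    site_low >= 0, site_high <= 1, site_low < site_high,
    hi_peak_threshold >= 0, hi_peak_threshold <= 1,
    min_peak_count >= 0, conserved_occupancy >= 0, conserved_occupancy <= 1,
    flank_bp > 0, gene_window_bp >= 0
  )
  structure(
    list(
      hi_peak_threshold = hi_peak_threshold,
      site_high = site_high,
      site_low = site_low,
      min_peak_count = min_peak_count,
      conserved_occupancy = conserved_occupancy,
      flank_bp = flank_bp,
      gene_window_bp = gene_window_bp
    ),
    class = "pipeline_thresholds"
  )
}
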