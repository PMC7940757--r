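# Cross-cell-type conservation of reference-cell binding regions,
# stratified by methylation, and extraction of genes near regions.

#' Occupancy of reference peaks across cell types
#'
#' For each reference peak, counts the surveyed cell types whose peak set
#' contains at least one peak overlapping it by >= 1 bp. The reference
#' cell always occupies its own peaks, so the count `n_occupied` is at
#' least 1 and at most `n_cells = length(cell_peak_sets) + 1`. A peak is
#' conserved when `n_occupied / n_cells` is strictly greater than
#' `conserved_occupancy` (default 0.8): with six cells, occupancy 5/6
#' (0.833) is conserved, 4/6 is not.
#'
#' @param ref_peaks Reference-cell peak tibble.
#' @param cell_peak_sets List of peak tibbles, one per non-reference cell.
#' @param thresholds A [pipeline_thresholds()] bundle.
#' @return `ref_peaks` with added `n_occupied`, `n_cells`, `conserved`.
#' @export
occupancy <- function(ref_peaks, cell_peak_sets,
                      thresholds = pipeline_thresholds()) {
  n_cells <- length(cell_peak_sets) + 1L
  k <- rep(1L, nrow(ref_peaks))
  if (nrow(ref_peaks) > 0) {
    ref <- GenomicRanges::GRanges(ref_peaks$chrom,
                                  IRanges::IRanges(ref_peaks$start + 1L,
                                                   ref_peaks$end))
    for (set in cell_peak_sets) {
      if (nrow(set) == 0) next
      other <- GenomicRanges::GRanges(set$chrom,
                                      IRanges::IRanges(set$start + 1L,
                                                       set$end))
      k <- k + as.integer(IRanges::overlapsAny(ref, other))
    }
  }
  ref_peaks |>
    mutate(n_occupied = k, n_cells = n_cells,
           conserved = k / n_cells > thresholds$conserved_occupancy)
}

#' Conserved fraction per methylation group
#'
#' @param records Output of [occupancy()] carrying a `group` column
#'   (`"hi"`/`"low"` from peak classification).
#' @return Tibble with `group`, `n`, `conserved_fraction`.
#' @export
conserved_fraction_by_group <- function(records) {
  records <- records[records$group %in% c("hi", "low"), ]
  if (nrow(records) == 0) abort("no classified peaks")
  out <- records |>
    group_by(.data$group) |>
    summarise(n = n(), conserved_fraction = mean(.data$conserved),
              .groups = "drop")
  if (nrow(out) < 2) {
    abort(sprintf("group '%s' is empty",
                  setdiff(c("hi", "low"), out$group)[1]))
  }
  out
}

#' Genes near a set of regions
#'
#' Names of genes whose interval overlaps any region after extending
#' each region by `window` bp on both sides (clipped at the chromosome
#' start). Deduplicated and sorted.
#'
#' @param regions Interval tibble (`chrom`, `start`, `end`).
#' @param genes Gene tibble from [read_gene_bed()].
#' @param window Extension in bp (default 1000).
#' @return Character vector of gene names.
#' @export
genes_near_regions <- function(regions, genes, window = 1000) {
  if (nrow(regions) == 0 || nrow(genes) == 0) return(character())
  ext_start <- pmax(0, regions$start - window)
  ext_end <- regions$end + window
  rg <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(ext_start + 1L, ext_end))
  gn <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start + 1L, genes$end))
  hit <- IRanges::overlapsAny(gn, rg)
  sort(unique(genes$name[hit]))
}
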