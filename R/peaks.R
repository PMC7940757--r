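# Dataset-level filtering and per-peak methylation statistics with the
# hi/low classification of binding regions.

#' Filter ChIP-seq datasets by peak count and pick one per (TF, cell)
#'
#' Datasets with fewer than `min_peak_count` peaks are removed ("fewer
#' than" is strict: a dataset with exactly `min_peak_count` peaks
#' survives). When several datasets remain for the same (TF, cell type)
#' pair, only the one with the most peaks is kept; ties keep the
#' lexicographically smallest `dataset_id` and are logged.
#'
#' @param datasets Tibble with one row per dataset: `dataset_id`, `tf`,
#'   `cell`, and a `peaks` list-column of peak tibbles.
#' @param thresholds A [pipeline_thresholds()] bundle.
#' @return The kept rows, with an added `n_peaks` column.
#' @export
filter_datasets <- function(datasets, thresholds = pipeline_thresholds()) {
  datasets <- datasets |>
    mutate(n_peaks = vapply(.data$peaks, nrow, integer(1))) |>
    filter(.data$n_peaks >= thresholds$min_peak_count)
  kept <- datasets |>
    group_by(.data$tf, .data$cell) |>
    arrange(dplyr::desc(.data$n_peaks), .data$dataset_id, .by_group = TRUE) |>
    mutate(.tied = sum(.data$n_peaks == max(.data$n_peaks)) > 1) |>
    slice(1) |>
    ungroup()
  if (any(kept$.tied)) {
    t <- kept[kept$.tied, ]
    inform(sprintf(
      "peak-count tie for %s/%s: keeping dataset '%s'",
      t$tf, t$cell, t$dataset_id
    ))
  }
  kept |> select(-".tied") |> arrange(.data$tf, .data$cell)
}

#' Per-peak mean CpG methylation
#'
#' The mean of the defined CpG-unit levels falling inside each peak's
#' `[start, end)` interval (unweighted across units, not read-weighted).
#' Peaks containing no covered CpG get an undefined mean and the group
#' `"unassigned"`; otherwise the group is `"hi"` when the mean is strictly
#' above `thresholds$hi_peak_threshold`, else `"low"`.
#'
#' @param peaks Peak tibble (`chrom`, `start`, `end`, ...).
#' @param track A `"methylome"` from [build_track()].
#' @param thresholds A [pipeline_thresholds()] bundle.
#' @return `peaks` with added columns `n_cpgs`, `mean_level`, `group`.
#' @export
peak_mean_methylation <- function(peaks, track,
                                  thresholds = pipeline_thresholds()) {
  if (nrow(peaks) == 0) {
    return(mutate(peaks, n_cpgs = integer(), mean_level = numeric(),
                  group = character()))
  }
  pk <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$start + 1L, peaks$end)
  )
  cg <- track_granges(track)
  ov <- GenomicRanges::findOverlaps(pk, cg)
  lev <- S4Vectors::mcols(cg)$level[S4Vectors::subjectHits(ov)]
  qh <- S4Vectors::queryHits(ov)
  n_cpgs <- tabulate(qh, nbins = nrow(peaks))
  sums <- rep(0, nrow(peaks))
  agg <- rowsum(lev, qh)
  sums[as.integer(rownames(agg))] <- agg[, 1]
  mean_level <- ifelse(n_cpgs > 0, sums / pmax(n_cpgs, 1), NA_real_)
  group <- ifelse(
    is.na(mean_level), "unassigned",
    ifelse(mean_level > thresholds$hi_peak_threshold, "hi", "low")
  )
  peaks |> mutate(n_cpgs = n_cpgs, mean_level = mean_level, group = group)
}

#' Classify a peak's mean methylation as hi or low
#'
#' "hi" iff the level is strictly greater than the hi-methylation
#' threshold (default 0.6): a peak at exactly 0.6 is "low".
#'
#' @param mean_level Defined methylation level(s) in `[0,1]`.
#' @param thresholds A [pipeline_thresholds()] bundle.
#' @return Character vector over `{"hi","low"}`.
#' @export
classify_peak <- function(mean_level, thresholds = pipeline_thresholds()) {
  if (anyNA(mean_level)) {
    abort("classify_peak requires defined levels; skip unassigned peaks")
  }
  ifelse(mean_level > thresholds$hi_peak_threshold, "hi", "low")
}

#' Fraction of hi-methylation peaks
#'
#' The proportion of hi-methyl peaks among peaks with an assigned
#' methylation level; CpG-free (unassigned) peaks are excluded from both
#' numerator and denominator.
#'
#' @param peak_meth Output of [peak_mean_methylation()].
#' @return A single fraction in `[0,1]`.
#' @export
himethyl_fraction <- function(peak_meth) {
  assigned <- peak_meth$group[peak_meth$group != "unassigned"]
  if (length(assigned) == 0) abort("no peaks with assigned methylation")
  mean(assigned == "hi")
}

#' Histogram of peak methylation levels
#'
#' Bins the assigned peaks' mean levels over `[0,1]`; every bin is
#' left-closed right-open except the last, which also includes 1, so
#' counts always sum to the number of assigned peaks regardless of bin
#' width.
#'
#' @param peak_meth Output of [peak_mean_methylation()].
#' @param bin_width Bin width (default 0.05; must divide 1 evenly up to
#'   rounding).
#' @return Tibble with `bin_start`, `bin_end`, `count`.
#' @export
methylation_distribution <- function(peak_meth, bin_width = 0.05) {
  lev <- peak_meth$mean_level[!is.na(peak_meth$mean_level)]
  if (length(lev) == 0) abort("no peaks with assigned methylation")
  n_bins <- max(1L, as.integer(round(1 / bin_width)))
  idx <- pmin(floor(lev / bin_width) + 1L, n_bins)
  tibble(
    bin_start = (seq_len(n_bins) - 1L) * bin_width,
    bin_end = pmin(seq_len(n_bins) * bin_width, 1),
    count = tabulate(idx, nbins = n_bins)
  )
}

#' Per-TF hi-methylation summary
#'
#' One row per (TF, cell): peak counts and the hi-methyl fraction among
#' assigned peaks, mirroring a TF-by-cell heat-map of methylated binding.
#'
#' @param peak_meth Output of [peak_mean_methylation()] carrying `tf` and
#'   `cell` columns.
#' @return Tibble with `tf`, `cell`, `n_peaks`, `n_assigned`,
#'   `hi_fraction`.
#' @export
himethyl_summary <- function(peak_meth) {
  peak_meth |>
    group_by(.data$tf, .data$cell) |>
    summarise(
      n_peaks = n(),
      n_assigned = sum(.data$group != "unassigned"),
      hi_fraction = ifelse(.data$n_assigned > 0,
                           sum(.data$group == "hi") / .data$n_assigned,
                           NA_real_),
      .groups = "drop"
    )
}
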