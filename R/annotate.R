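# Chromatin-state annotation of peaks and methylated-fraction statistics
# for DNase hypersensitive sites.

#' Assign each peak its majority chromatin state
#'
#' The state label with the maximum total overlap with the peak wins;
#' ties break lexicographically by label. Peaks no segment touches get
#' `"Unannotated"` with an undefined overlap fraction. Splitting a
#' segment into adjacent same-label pieces never changes the assignment.
#'
#' @param peaks Peak tibble (`chrom`, `start`, `end`, ...).
#' @param segmentation Labeled-interval tibble from [read_segmentation()].
#' @return `peaks` with added `state` and `state_fraction` (fraction of
#'   the peak covered by the winning label).
#' @export
assign_chromatin_state <- function(peaks, segmentation) {
  if (nrow(peaks) == 0) {
    return(mutate(peaks, state = character(), state_fraction = numeric()))
  }
  state <- rep("Unannotated", nrow(peaks))
  frac <- rep(NA_real_, nrow(peaks))
  if (nrow(segmentation) > 0) {
    pk <- GenomicRanges::GRanges(peaks$chrom,
                                 IRanges::IRanges(peaks$start + 1L, peaks$end))
    sg <- GenomicRanges::GRanges(segmentation$chrom,
                                 IRanges::IRanges(segmentation$start + 1L,
                                                  segmentation$end))
    ov <- GenomicRanges::findOverlaps(pk, sg)
    if (length(ov) > 0) {
      qh <- S4Vectors::queryHits(ov)
      sh <- S4Vectors::subjectHits(ov)
      w <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(pk)[qh], IRanges::ranges(sg)[sh]
      ))
      per <- tibble(peak = qh, state = segmentation$state[sh], w = w) |>
        group_by(.data$peak, .data$state) |>
        summarise(w = sum(.data$w), .groups = "drop_last") |>
        arrange(dplyr::desc(.data$w), .data$state, .by_group = TRUE) |>
        slice(1) |>
        ungroup()
      state[per$peak] <- per$state
      frac[per$peak] <- per$w / (peaks$end[per$peak] - peaks$start[per$peak])
    }
  }
  peaks |> mutate(state = state, state_fraction = frac)
}

#' Chromatin-state composition per methylation group
#'
#' For each methylation group, the fraction of peaks assigned to each
#' state; fractions sum to 1 within every group.
#'
#' @param assignments Output of [assign_chromatin_state()] carrying a
#'   `group` column.
#' @param group_col Name of the grouping column (default `"group"`).
#' @return Tibble with `group`, `state`, `n`, `fraction`.
#' @export
state_composition <- function(assignments, group_col = "group") {
  if (nrow(assignments) == 0) abort("no state assignments")
  assignments |>
    rename(group = dplyr::all_of(group_col)) |>
    count(.data$group, .data$state, name = "n") |>
    group_by(.data$group) |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    ungroup() |>
    arrange(.data$group, dplyr::desc(.data$fraction), .data$state)
}

#' Map segmentation labels to coarse classes
#'
#' Applies a two-column mapping (label TAB class) to state labels,
#' leaving unmapped labels verbatim. Mirrors the optional mnemonic ->
#' class mapping file.
#'
#' @param states Character vector of state labels.
#' @param mapping Tibble/data frame with columns `label`, `class`, or a
#'   path to a two-column tab-separated file.
#' @return Character vector of classes.
#' @export
map_state_labels <- function(states, mapping) {
  if (is.character(mapping) && length(mapping) == 1) {
    mapping <- readr::read_tsv(mapping, col_names = c("label", "class"),
                               col_types = "cc", progress = FALSE)
  }
  idx <- match(states, mapping$label)
  ifelse(is.na(idx), states, mapping$class[idx])
}

#' Fraction of DNase hypersensitive sites that are methylated
#'
#' The fraction of DHS intervals whose mean CpG methylation exceeds the
#' hi-methylation threshold (default 0.6); intervals containing no
#' covered CpG are excluded. Computed with the same machinery as peak
#' classification, so it equals [himethyl_fraction()] on the same
#' intervals.
#'
#' @param dhs_peaks DHS interval tibble (`chrom`, `start`, `end`, ...).
#' @param track A `"methylome"`.
#' @param thresholds A [pipeline_thresholds()] bundle.
#' @return A single fraction in `[0,1]`.
#' @export
dhs_methylated_fraction <- function(dhs_peaks, track,
                                    thresholds = pipeline_thresholds()) {
  himethyl_fraction(peak_mean_methylation(dhs_peaks, track, thresholds))
}
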