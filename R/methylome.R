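# Build a queryable methylome from per-cytosine records: replicate merging
# by read-count summation, optional CpG strand-merging (symmetric
# methylation), per-unit levels, and fast interval queries.

#' Per-cytosine methylation level
#'
#' The ratio of methylated reads to total reads covering a locus.
#' Undefined (`NA`) when no reads cover the locus.
#'
#' @param meth_reads,total_reads Non-negative read counts (vectorized).
#' @return Numeric vector in `[0,1]`, `NA` where `total_reads == 0`.
#' @examples
#' methylation_level(5, 10)  # 0.5
#' methylation_level(0, 0)   # NA
#' @export
methylation_level <- function(meth_reads, total_reads) {
  if (any(meth_reads > total_reads)) {
    abort("meth_reads exceeds total_reads")
  }
  if (any(meth_reads < 0) || any(total_reads < 0)) {
    abort("read counts must be non-negative")
  }
  ifelse(total_reads > 0, meth_reads / total_reads, NA_real_)
}

#' Merge two WGBS replicates by summing read counts
#'
#' Counts are summed per locus `(chrom, pos, strand)`; loci covered by only
#' one replicate pass through unchanged. The operation is commutative and
#' associative, so any number of replicates can be folded in any order.
#'
#' @param rep_a,rep_b Cytosine-record tibbles
#'   (`chrom`, `pos`, `strand`, `meth_reads`, `total_reads`).
#' @return Merged cytosine-record tibble, sorted by `(chrom, pos, strand)`.
#' @export
merge_replicates <- function(rep_a, rep_b) {
  for (r in list(rep_a, rep_b)) {
    key <- paste(r$chrom, r$pos, r$strand)
    if (anyDuplicated(key)) {
      abort(sprintf("duplicate locus within one replicate: %s",
                    key[duplicated(key)][1]))
    }
  }
  dplyr::bind_rows(rep_a, rep_b) |>
    group_by(.data$chrom, .data$pos, .data$strand) |>
    summarise(
      meth_reads = sum(.data$meth_reads),
      total_reads = sum(.data$total_reads),
      .groups = "drop"
    ) |>
    arrange(.data$chrom, .data$pos, .data$strand)
}

cpg_context <- function(genome, chrom, pos, strand) {
  # TRUE when the cytosine at `pos` (0-based, on `strand`) sits in a CpG
  # dinucleotide of the + strand reference; works per chromosome on an
  # exploded character vector so lookups are O(1)
  out <- logical(length(pos))
  for (ch in unique(chrom)) {
    if (!ch %in% names(genome)) next
    chars <- strsplit(genome[[ch]], "", fixed = TRUE)[[1]]
    len <- length(chars)
    i <- which(chrom == ch)
    p <- pos[i]
    plus <- strand[i] == "+"
    ok <- plus & p + 2 <= len
    out[i[ok]] <- chars[p[ok] + 1] == "C" & chars[p[ok] + 2] == "G"
    ok <- !plus & p >= 1 & p + 1 <= len
    out[i[ok]] <- chars[p[ok]] == "C" & chars[p[ok] + 1] == "G"
  }
  out
}

#' Build a queryable methylome track
#'
#' With `merge_cpg_strands = TRUE` (the default) the two symmetric
#' cytosines of each CpG dinucleotide are collapsed into one unit at the
#' position of the + strand C, with read counts summed — the track then
#' measures CpG units rather than strand-specific cytosines. Merging
#' requires the genome so CpG context can be verified; cytosines not in
#' CpG context (CHG/CHH) are dropped with a logged count, since only CpG
#' methylation enters any downstream statistic.
#'
#' Units covered by fewer than `min_coverage` reads get an undefined
#' (`NA`) level and are excluded from all level statistics.
#'
#' @param records Cytosine-record tibble
#'   (`chrom`, `pos`, `strand`, `meth_reads`, `total_reads`).
#' @param merge_cpg_strands Collapse +/- CpG cytosines into one unit.
#' @param genome Named character vector of chromosome sequences; required
#'   when `merge_cpg_strands = TRUE`.
#' @param min_coverage Minimum total reads for a defined level (default 1).
#' @return A tibble of class `"methylome"` with columns `chrom`, `pos`,
#'   `strand` (`"*"` for merged units), `meth_reads`, `total_reads`,
#'   `level`; positions strictly increasing within each chromosome.
#' @export
build_track <- function(records, merge_cpg_strands = TRUE, genome = NULL,
                        min_coverage = 1) {
  stopifnot(all(records$meth_reads <= records$total_reads))
  key <- paste(records$chrom, records$pos, records$strand)
  if (anyDuplicated(key)) {
    abort(sprintf("duplicate cytosine record: %s", key[duplicated(key)][1]))
  }
  if (merge_cpg_strands) {
    if (is.null(genome)) {
      abort("merge_cpg_strands = TRUE requires `genome` to verify CpG context")
    }
    in_cpg <- cpg_context(genome, records$chrom, records$pos, records$strand)
    n_drop <- sum(!in_cpg)
    if (n_drop > 0) {
      inform(sprintf("dropping %d non-CpG cytosine record(s)", n_drop))
    }
    records <- records[in_cpg, ]
    unit_pos <- ifelse(records$strand == "+", records$pos, records$pos - 1)
    track <- tibble(chrom = records$chrom, pos = unit_pos,
                    meth_reads = records$meth_reads,
                    total_reads = records$total_reads) |>
      group_by(.data$chrom, .data$pos) |>
      summarise(meth_reads = sum(.data$meth_reads),
                total_reads = sum(.data$total_reads), .groups = "drop") |>
      mutate(strand = "*")
  } else {
    if (!is.null(genome)) {
      in_cpg <- cpg_context(genome, records$chrom, records$pos, records$strand)
      n_drop <- sum(!in_cpg)
      if (n_drop > 0) {
        inform(sprintf("dropping %d non-CpG cytosine record(s)", n_drop))
      }
      records <- records[in_cpg, ]
    }
    track <- tibble(chrom = records$chrom, pos = records$pos,
                    strand = records$strand,
                    meth_reads = records$meth_reads,
                    total_reads = records$total_reads)
  }
  track <- track |>
    arrange(.data$chrom, .data$pos) |>
    mutate(level = ifelse(
      .data$total_reads >= max(min_coverage, 1),
      .data$meth_reads / pmax(.data$total_reads, 1),
      NA_real_
    )) |>
    select("chrom", "pos", "strand", "meth_reads", "total_reads", "level")
  new_methylome(track, cpg_unit = merge_cpg_strands,
                min_coverage = min_coverage)
}

new_methylome <- function(track, cpg_unit, min_coverage) {
  # row-range index per chromosome supports O(log n) interval queries
  rle_chrom <- rle(track$chrom)
  ends <- cumsum(rle_chrom$lengths)
  idx <- tibble(chrom = rle_chrom$values,
                row_start = c(1L, head(ends, -1) + 1L),
                row_end = ends)
  structure(track,
            class = c("methylome", class(tibble())),
            cpg_unit = cpg_unit,
            min_coverage = min_coverage,
            chrom_index = idx)
}

#' Query a methylome track over a genomic interval
#'
#' Returns the CpG units with `start <= pos < end` whose level is defined,
#' in position order. Lookup is by binary search over the sorted track
#' (sublinear in track size). An unknown chromosome yields an empty
#' result, not an error.
#'
#' @param track A `"methylome"` from [build_track()].
#' @param chrom Chromosome name (exact match, no prefix normalization).
#' @param start,end 0-based half-open interval, `start < end`.
#' @return Tibble with `pos`, `level`, `meth_reads`, `total_reads`.
#' @export
query_interval <- function(track, chrom, start, end) {
  stopifnot(start < end)
  idx <- attr(track, "chrom_index")
  row <- match(chrom, idx$chrom)
  empty <- tibble(pos = track$pos[0], level = track$level[0],
                  meth_reads = track$meth_reads[0],
                  total_reads = track$total_reads[0])
  if (is.na(row)) {
    inform(sprintf("query_interval: chromosome '%s' not in track", chrom))
    return(empty)
  }
  lo <- idx$row_start[row]
  hi <- idx$row_end[row]
  pos <- track$pos[lo:hi]
  i1 <- findInterval(start - 0.5, pos) + 1L   # first pos >= start
  i2 <- findInterval(end - 0.5, pos)          # last pos < end
  if (i1 > i2) return(empty)
  rows <- (lo:hi)[i1:i2]
  out <- tibble(pos = track$pos[rows], level = track$level[rows],
                meth_reads = track$meth_reads[rows],
                total_reads = track$total_reads[rows])
  out[!is.na(out$level), ]
}

#' Dump a methylome track as bedGraph
#' @param track A `"methylome"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track_bedgraph <- function(track, path) {
  keep <- !is.na(track$level)
  readr::write_lines(
    sprintf("%s\t%d\t%d\t%.6g", track$chrom[keep],
            as.integer(track$pos[keep]), as.integer(track$pos[keep]) + 1L,
            track$level[keep]),
    path
  )
  invisible(path)
}

track_granges <- function(track, defined_only = TRUE) {
  keep <- if (defined_only) !is.na(track$level) else rep(TRUE, nrow(track))
  GenomicRanges::GRanges(
    seqnames = track$chrom[keep],
    ranges = IRanges::IRanges(start = track$pos[keep] + 1L, width = 1L),
    level = track$level[keep]
  )
}
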