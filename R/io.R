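# Readers/writers for the external formats: per-cytosine methylation BED
# (count dialect), ENCODE narrowPeak, chromHMM-style labeled BED, gene BED,
# and FASTA. All coordinates are 0-based half-open after parsing.

split_bed_lines <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  strsplit(lines, "\t", fixed = TRUE)
}

parse_coord <- function(x, line, what) {
  v <- suppressWarnings(as.numeric(x))
  if (any(is.na(v)) || any(v != floor(v)) || any(v < 0)) {
    abort(sprintf("line %d: %s is not a non-negative integer", line, what))
  }
  v
}

#' Read per-cytosine methylation calls (Bismark-style count BED)
#'
#' Parses a whole-genome bisulfite methylation call file with one cytosine
#' per line. Two count dialects are supported, selected by `format`:
#'
#' * `"meth_total"`: `chrom start end strand meth_reads total_reads`
#' * `"meth_unmeth"`: `chrom start end strand count_meth count_unmeth`
#'   (converted on read: `total = meth + unmeth`)
#'
#' Percentage-only files are rejected by construction: replicate merging
#' sums read counts, which a percentage cannot provide.
#'
#' @param path File path.
#' @param format Count dialect, see above.
#' @return A tibble with columns `chrom`, `pos` (0-based), `strand`,
#'   `meth_reads`, `total_reads`, one row per input line in input order.
#' @export
read_methylation_bed <- function(path, format = c("meth_total", "meth_unmeth")) {
  format <- match.arg(format)
  fields <- split_bed_lines(path)
  if (length(fields) == 0) {
    return(tibble(
      chrom = character(), pos = numeric(), strand = character(),
      meth_reads = numeric(), total_reads = numeric()
    ))
  }
  n_fields <- lengths(fields)
  bad <- which(n_fields < 6)
  if (length(bad) > 0) {
    abort(sprintf("line %d: expected 6 tab-separated columns, found %d",
                  bad[1], n_fields[bad[1]]))
  }
  m <- t(vapply(fields, function(f) f[1:6], character(6)))
  pos <- parse_coord(m[, 2], 1L, "start")
  strand <- m[, 4]
  if (!all(strand %in% c("+", "-"))) {
    bad <- which(!(strand %in% c("+", "-")))[1]
    abort(sprintf("line %d: strand must be '+' or '-', found '%s'",
                  bad, strand[bad]))
  }
  a <- suppressWarnings(as.numeric(m[, 5]))
  b <- suppressWarnings(as.numeric(m[, 6]))
  if (anyNA(a) || anyNA(b) || any(a < 0) || any(b < 0)) {
    bad <- which(is.na(a) | is.na(b) | a < 0 | b < 0)[1]
    abort(sprintf("line %d: unparseable read counts", bad))
  }
  if (format == "meth_total") {
    meth <- a
    total <- b
  } else {
    meth <- a
    total <- a + b
  }
  if (any(meth > total)) {
    bad <- which(meth > total)[1]
    abort(sprintf("line %d: meth_reads (%g) exceeds total_reads (%g)",
                  bad, meth[bad], total[bad]))
  }
  tibble(
    chrom = m[, 1], pos = pos, strand = strand,
    meth_reads = meth, total_reads = total
  )
}

#' Write per-cytosine methylation calls in the count dialect
#'
#' @param records Tibble as produced by [read_methylation_bed()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_methylation_bed <- function(records, path) {
  lines <- sprintf(
    "%s\t%d\t%d\t%s\t%d\t%d",
    records$chrom, as.integer(records$pos), as.integer(records$pos) + 1L,
    records$strand, as.integer(records$meth_reads), as.integer(records$total_reads)
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read an ENCODE narrowPeak (BED6+4) file
#'
#' @param path File path.
#' @return Tibble with columns `chrom`, `start`, `end` (0-based half-open),
#'   `name`, `score`, `strand`, `signal`, `pvalue`, `qvalue`, `summit`
#'   (offset from `start`; `NA` when the file records -1, meaning unknown —
#'   downstream code then falls back to the interval midpoint).
#' @export
read_narrowpeak <- function(path) {
  fields <- split_bed_lines(path)
  if (length(fields) == 0) {
    return(tibble(
      chrom = character(), start = numeric(), end = numeric(),
      name = character(), score = numeric(), strand = character(),
      signal = numeric(), pvalue = numeric(), qvalue = numeric(),
      summit = numeric()
    ))
  }
  n_fields <- lengths(fields)
  if (any(n_fields < 10)) {
    bad <- which(n_fields < 10)[1]
    abort(sprintf("line %d: narrowPeak requires 10 columns, found %d",
                  bad, n_fields[bad]))
  }
  m <- t(vapply(fields, function(f) f[1:10], character(10)))
  start <- parse_coord(m[, 2], 1L, "start")
  end <- parse_coord(m[, 3], 1L, "end")
  if (any(start >= end)) {
    bad <- which(start >= end)[1]
    abort(sprintf("line %d: start (%g) must be < end (%g)",
                  bad, start[bad], end[bad]))
  }
  summit <- suppressWarnings(as.numeric(m[, 10]))
  summit[!is.na(summit) & summit < 0] <- NA_real_
  tibble(
    chrom = m[, 1], start = start, end = end,
    name = m[, 4],
    score = suppressWarnings(as.numeric(m[, 5])),
    strand = m[, 6],
    signal = suppressWarnings(as.numeric(m[, 7])),
    pvalue = suppressWarnings(as.numeric(m[, 8])),
    qvalue = suppressWarnings(as.numeric(m[, 9])),
    summit = summit
  )
}

#' Write peaks as narrowPeak
#'
#' Inverse of [read_narrowpeak()]: writing then re-reading reproduces the
#' parsed fields exactly (an `NA` summit round-trips through -1).
#'
#' @param peaks Tibble as produced by [read_narrowpeak()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  summit <- ifelse(is.na(peaks$summit), -1, peaks$summit)
  lines <- sprintf(
    "%s\t%d\t%d\t%s\t%s\t%s\t%s\t%s\t%s\t%d",
    peaks$chrom, as.integer(peaks$start), as.integer(peaks$end),
    peaks$name, format(peaks$score, trim = TRUE, scientific = FALSE),
    peaks$strand,
    format(peaks$signal, trim = TRUE, scientific = FALSE),
    format(peaks$pvalue, trim = TRUE, scientific = FALSE),
    format(peaks$qvalue, trim = TRUE, scientific = FALSE),
    as.integer(summit)
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a chromatin-state segmentation (labeled BED)
#'
#' Intervals carry their labels verbatim; they are not assumed to tile the
#' genome and may overlap or leave gaps. Adjacent same-label intervals are
#' not merged.
#'
#' @param path File path (BED with at least 4 columns; column 4 is the
#'   state label).
#' @return Tibble with columns `chrom`, `start`, `end`, `state`.
#' @export
read_segmentation <- function(path) {
  fields <- split_bed_lines(path)
  if (length(fields) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  state = character()))
  }
  n_fields <- lengths(fields)
  if (any(n_fields < 4)) {
    bad <- which(n_fields < 4)[1]
    abort(sprintf("line %d: segmentation BED requires >= 4 columns, found %d",
                  bad, n_fields[bad]))
  }
  m <- t(vapply(fields, function(f) f[1:4], character(4)))
  start <- parse_coord(m[, 2], 1L, "start")
  end <- parse_coord(m[, 3], 1L, "end")
  if (any(start >= end)) {
    bad <- which(start >= end)[1]
    abort(sprintf("line %d: start must be < end", bad))
  }
  tibble(chrom = m[, 1], start = start, end = end, state = m[, 4])
}

#' Write a labeled segmentation BED
#' @param segments Tibble with `chrom`, `start`, `end`, `state`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(segments, path) {
  readr::write_lines(
    sprintf("%s\t%d\t%d\t%s", segments$chrom, as.integer(segments$start),
            as.integer(segments$end), segments$state),
    path
  )
  invisible(path)
}

#' Read gene annotations from BED
#'
#' BED with at least 4 columns; column 4 is the gene name. Strand (column
#' 6) is kept when present.
#'
#' @param path File path.
#' @return Tibble with `chrom`, `start`, `end`, `name`, `strand`.
#' @export
read_gene_bed <- function(path) {
  fields <- split_bed_lines(path)
  if (length(fields) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  name = character(), strand = character()))
  }
  n_fields <- lengths(fields)
  if (any(n_fields < 4)) {
    bad <- which(n_fields < 4)[1]
    abort(sprintf("line %d: gene BED requires >= 4 columns", bad))
  }
  m <- t(vapply(fields, function(f) f[c(1:4, if (length(f) >= 6) 6 else 4)],
                character(5)))
  start <- parse_coord(m[, 2], 1L, "start")
  end <- parse_coord(m[, 3], 1L, "end")
  if (any(start >= end)) abort(sprintf("line %d: start must be < end",
                                       which(start >= end)[1]))
  strand <- ifelse(m[, 5] %in% c("+", "-"), m[, 5], "*")
  tibble(chrom = m[, 1], start = start, end = end, name = m[, 4],
         strand = strand)
}

#' Read a genome from FASTA
#'
#' Sequences are case-folded to uppercase; the result is a named character
#' vector over `{A,C,G,T,N}`, one element per record. Chromosome name is
#' the FASTA header up to the first whitespace.
#'
#' @param path FASTA path.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) abort("FASTA contains no records")
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) {
    abort(sprintf("duplicate FASTA header: '%s'", nm[duplicated(nm)][1]))
  }
  out <- toupper(as.character(seqs))
  names(out) <- nm
  if (any(!nzchar(out))) abort("FASTA contains an empty sequence")
  out
}

#' Write a genome to FASTA
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome), path, width = 70L
  )
  invisible(path)
}
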