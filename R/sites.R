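# Binding-site relocation inside peaks, site-level methylation, the
# high/middle/low/no_cpg grouping, CpG-containing-site fractions, and
# reconstruction of methylation-aware motifs over {A,C,G,T,E}.

#' Relocate binding sites within classified peaks
#'
#' Each "hi" peak is scanned with `pwm_hi` and each "low" peak with
#' `pwm_low`; the maximum-scoring placement becomes the peak's binding
#' site. Genomic coordinates are `peak start + offset`. The stored
#' `sequence` is the scored (reading-strand) sequence: for a `-` strand
#' site it is the reverse complement of the genomic substring.
#'
#' When `track` is supplied, `site_meth` (the maximum defined CpG level
#' overlapping the site) and `methyl_group` are attached.
#'
#' @param peak_meth Output of [peak_mean_methylation()] (carries `group`).
#' @param pwm_hi,pwm_low `"pwm"` objects for the two peak groups (pass the
#'   same object twice to scan all peaks with one motif).
#' @param genome Named character vector of chromosome sequences.
#' @param track Optional `"methylome"` for site-level methylation.
#' @param thresholds A [pipeline_thresholds()] bundle.
#' @return Tibble of binding sites: `name` (peak), `chrom`, `start`,
#'   `end`, `strand`, `score`, `sequence`, `peak_group`, and, with a
#'   track, `site_meth` + `methyl_group`.
#' @export
locate_binding_sites <- function(peak_meth, pwm_hi, pwm_low, genome,
                                 track = NULL,
                                 thresholds = pipeline_thresholds()) {
  scan_group <- function(group, pwm) {
    pk <- peak_meth[peak_meth$group == group, ]
    if (nrow(pk) == 0) return(NULL)
    L <- ncol(pwm$prob)
    hits <- scan_peaks(pwm, pk, genome)
    if (nrow(hits) == 0) return(NULL)
    start <- hits$peak_start + hits$offset
    seq_fwd <- substring(genome[hits$chrom], start + 1, start + L)
    tibble(
      name = hits$name, chrom = hits$chrom,
      start = start, end = start + L,
      strand = hits$strand, score = hits$score,
      sequence = ifelse(hits$strand == "+", seq_fwd,
                        reverse_complement(seq_fwd)),
      peak_group = group
    )
  }
  sites <- bind_rows(scan_group("hi", pwm_hi), scan_group("low", pwm_low))
  if (!is.null(track) && nrow(sites) > 0) {
    sites$site_meth <- site_methylation(sites, track)
    sites$methyl_group <- group_site(sites$site_meth, thresholds)
  }
  sites
}

#' Site-level methylation: maximum CpG level on the binding site
#'
#' A binding site may contain several CpGs; its methylation level is the
#' maximum of the defined CpG-unit levels overlapping the site interval.
#' Undefined (`NA`) when no covered CpG overlaps the site. A merged CpG
#' unit occupies its full dinucleotide, so a site covering only the G of
#' a CpG still overlaps that unit.
#'
#' @param sites Binding-site tibble (`chrom`, `start`, `end`).
#' @param track A `"methylome"`.
#' @return Numeric vector of levels (`NA` where no CpG).
#' @export
site_methylation <- function(sites, track) {
  unit_width <- if (isTRUE(attr(track, "cpg_unit"))) 2L else 1L
  vapply(seq_len(nrow(sites)), function(i) {
    q <- query_interval(track, sites$chrom[i],
                        max(0, sites$start[i] - (unit_width - 1L)),
                        sites$end[i])
    if (nrow(q) == 0) NA_real_ else max(q$level)
  }, numeric(1))
}

#' Group binding sites by methylation level
#'
#' `"high"` when level > `site_high` (default 0.6), `"low"` when level <
#' `site_low` (default 0.2), `"middle"` otherwise — both comparisons are
#' strict, so levels of exactly 0.6 or 0.2 are `"middle"`. Sites without
#' any covered CpG (`NA` level) are `"no_cpg"`.
#'
#' @param level Site methylation level(s), `NA` allowed.
#' @param thresholds A [pipeline_thresholds()] bundle.
#' @return Character vector over `{"high","middle","low","no_cpg"}`.
#' @export
group_site <- function(level, thresholds = pipeline_thresholds()) {
  dplyr::case_when(
    is.na(level) ~ "no_cpg",
    level > thresholds$site_high ~ "high",
    level < thresholds$site_low ~ "low",
    .default = "middle"
  )
}

#' Fraction of binding sites containing a CpG dinucleotide
#'
#' The proportion of sites whose (reading-strand) sequence contains
#' `"CG"`; CpG content is strand-symmetric, so the orientation does not
#' matter.
#'
#' @param sites Binding-site tibble with a `sequence` column.
#' @return A single fraction in `[0,1]`.
#' @export
cpg_site_fraction <- function(sites) {
  if (nrow(sites) == 0) abort("no binding sites")
  mean(grepl("CG", sites$sequence, fixed = TRUE))
}

#' Rebuild a methylation-aware motif over {A,C,G,T,E}
#'
#' Re-reads each located binding site from the genome in reading-strand
#' orientation and records every cytosine that (i) sits in a CpG
#' dinucleotide on the site's reading strand (checked against the genome,
#' so a terminal C followed by a G just outside the site still counts)
#' and (ii) whose CpG-unit methylation level exceeds `e_threshold`, as
#' `E` instead of `C`. All other bases are recorded verbatim. Collapsing
#' `E` back into `C` reproduces the plain base counts of the same sites.
#'
#' @param sites Binding-site tibble from [locate_binding_sites()]; all
#'   sites must share one length.
#' @param track A `"methylome"` (CpG-unit merged).
#' @param genome Named character vector of chromosome sequences.
#' @param e_threshold Methylation level above which a CpG cytosine is
#'   written as `E` (default `site_high` = 0.6, aligning the E call with
#'   the site grouping).
#' @param thresholds A [pipeline_thresholds()] bundle (supplies the
#'   default `e_threshold`).
#' @return An object of class `"methyl_motif"`: list with `counts`
#'   (5 x L matrix, rows A,C,G,T,E) and `n_sites`.
#' @export
rebuild_methyl_motif <- function(sites, track, genome,
                                 e_threshold = NULL,
                                 thresholds = pipeline_thresholds()) {
  if (nrow(sites) == 0) abort("no binding sites")
  e_threshold <- e_threshold %||% thresholds$site_high
  L <- unique(sites$end - sites$start)
  if (length(L) != 1) abort("sites must share one length")
  counts <- matrix(0, nrow = 5, ncol = L,
                   dimnames = list(c(DNA_BASES, "E"), NULL))
  n_used <- 0L
  n_skipped <- 0L
  for (i in seq_len(nrow(sites))) {
    row <- annotate_site_letters(sites$chrom[i], sites$start[i],
                                 sites$strand[i], L, genome, track,
                                 e_threshold)
    if (is.null(row)) {
      n_skipped <- n_skipped + 1L
      next
    }
    counts[cbind(match(row, rownames(counts)), seq_len(L))] <-
      counts[cbind(match(row, rownames(counts)), seq_len(L))] + 1
    n_used <- n_used + 1L
  }
  if (n_skipped > 0) {
    inform(sprintf("rebuild_methyl_motif: skipped %d site(s) containing N",
                   n_skipped))
  }
  if (n_used == 0) abort("no usable (N-free) sites")
  structure(list(counts = counts, n_sites = n_used),
            class = "methyl_motif")
}

# letters of one site in reading-strand orientation, with methylated CpG
# cytosines rewritten as E; NULL when the site contains N
annotate_site_letters <- function(chrom, start, strand, L, genome, track,
                                  e_threshold) {
  seq_fwd <- substring(genome[chrom], start + 1, start + L)
  letters_fwd <- strsplit(seq_fwd, "", fixed = TRUE)[[1]]
  if (any(!(letters_fwd %in% DNA_BASES))) return(NULL)
  letters <- if (strand == "+") letters_fwd else
    rev(COMPLEMENT[letters_fwd])
  # reading position j -> genomic 0-based position of that base
  gpos <- if (strand == "+") start + seq_len(L) - 1 else
    start + L - seq_len(L)
  for (j in seq_len(L)) {
    if (letters[j] != "C") next
    g <- gpos[j]
    # CpG context on the reading strand == CpG dinucleotide on + strand:
    # + site: genome[g, g+1] == CG; - site: genome[g-1, g] == CG
    in_cpg <- if (strand == "+") {
      substring(genome[chrom], g + 1, g + 2) == "CG"
    } else {
      g >= 1 && substring(genome[chrom], g, g + 1) == "CG"
    }
    if (!in_cpg) next
    unit_pos <- if (strand == "+") g else g - 1
    q <- query_interval(track, chrom, unit_pos, unit_pos + 1)
    if (nrow(q) == 1 && q$level > e_threshold) letters[j] <- "E"
  }
  letters
}

#' @export
print.methyl_motif <- function(x, ...) {
  cat(sprintf("methylation-aware motif, %d sites, width %d\n",
              x$n_sites, ncol(x$counts)))
  print(x$counts)
  invisible(x)
}

#' Collapse a methylation-aware motif back to plain base counts
#'
#' Adds the `E` row into `C`, recovering the 4-letter count matrix of the
#' same sites.
#'
#' @param motif A `"methyl_motif"`.
#' @return 4 x L count matrix (rows A,C,G,T).
#' @export
collapse_methyl_motif <- function(motif) {
  m <- motif$counts[DNA_BASES, , drop = FALSE]
  m["C", ] <- m["C", ] + motif$counts["E", ]
  m
}

#' E-fraction per motif column
#'
#' For each column, `E / (C + E)`: the fraction of cytosine observations
#' that were methylated. `NA` where a column has no cytosine observation.
#'
#' @param motif A `"methyl_motif"`.
#' @return Numeric vector of length L.
#' @export
methyl_motif_e_fraction <- function(motif) {
  ce <- motif$counts["C", ] + motif$counts["E", ]
  ifelse(ce > 0, motif$counts["E", ] / pmax(ce, 1), NA_real_)
}

#' Write a methylation-aware motif as a 5-row matrix file
#' @param motif A `"methyl_motif"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_methyl_motif <- function(motif, path) {
  lines <- vapply(rownames(motif$counts), function(b) {
    paste(c(b, format(motif$counts[b, ], trim = TRUE)), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Export a binding-site table
#'
#' Tab-separated with a header: `chrom`, `start`, `end`, `strand`,
#' `peak`, `score`, `site_meth`, `methyl_group`, `sequence`,
#' `e_sequence` (the site sequence with methylated CpG cytosines shown
#' as E).
#'
#' @param sites Binding sites with methylation attached.
#' @param track,genome As in [rebuild_methyl_motif()].
#' @param path Output path.
#' @param e_threshold E cutoff (default 0.6).
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, track, genome, path, e_threshold = 0.6) {
  e_seq <- vapply(seq_len(nrow(sites)), function(i) {
    L <- sites$end[i] - sites$start[i]
    row <- annotate_site_letters(sites$chrom[i], sites$start[i],
                                 sites$strand[i], L, genome, track,
                                 e_threshold)
    if (is.null(row)) NA_character_ else paste0(row, collapse = "")
  }, character(1))
  out <- tibble(
    chrom = sites$chrom, start = as.integer(sites$start),
    end = as.integer(sites$end), strand = sites$strand,
    peak = sites$name, score = sites$score,
    site_meth = sites$site_meth %||% NA_real_,
    methyl_group = sites$methyl_group %||% NA_character_,
    sequence = sites$sequence, e_sequence = e_seq
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
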