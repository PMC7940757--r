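# Synthetic-data generators with known truth: genomes with CpG islands,
# binomially sampled methylomes, peaks centered near planted PWM
# occurrences, multi-cell occupancy plans, and block segmentations.
# Every generator is deterministic given (seed, parameters).

#' Generate a synthetic genome with CpG islands
#'
#' Background sequence is i.i.d. at the requested GC content; islands are
#' CpG-enriched blocks (CpG dinucleotides planted at `cpg_enrichment`
#' times the background expectation, GC-rich composition) embedded at
#' random non-overlapping positions.
#'
#' @param seed RNG seed; the same seed reproduces the genome bit-exactly.
#' @param n_chroms Number of chromosomes (named `chr1`, `chr2`, ...).
#' @param chrom_length Length of each chromosome (>= 10 kb).
#' @param gc Background GC fraction.
#' @param islands List with `count` (islands per chromosome), `length`
#'   (bp each), `cpg_enrichment` (fold CpG-density enrichment).
#' @return List with `genome` (named uppercase character vector) and
#'   `islands` (tibble `chrom`, `start`, `end`).
#' @export
make_genome <- function(seed = 1, n_chroms = 1, chrom_length = 100000,
                        gc = 0.4,
                        islands = list(count = 5, length = 2000,
                                       cpg_enrichment = 8)) {
  if (chrom_length < 10000) abort("chrom_length must be >= 10 kb")
  if (islands$count * islands$length > chrom_length / 2) {
    abort("islands exceed half the chromosome length")
  }
  base_prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  with_local_seed(seed, {
    genome <- character(n_chroms)
    names(genome) <- paste0("chr", seq_len(n_chroms))
    isl <- list()
    for (ci in seq_len(n_chroms)) {
      seq <- sample(DNA_BASES, chrom_length, replace = TRUE,
                    prob = base_prob)
      starts <- place_nonoverlapping(islands$count, islands$length,
                                     chrom_length)
      for (s in starts) {
        island_seq <- cpg_island_sequence(islands$length, gc,
                                          islands$cpg_enrichment)
        seq[(s + 1):(s + islands$length)] <- island_seq
      }
      genome[ci] <- paste0(seq, collapse = "")
      if (length(starts) > 0) {
        isl[[ci]] <- tibble(chrom = names(genome)[ci], start = starts,
                            end = starts + islands$length)
      }
    }
    island_tbl <- if (length(isl) == 0) {
      tibble(chrom = character(), start = numeric(), end = numeric())
    } else {
      bind_rows(isl) |> arrange(.data$chrom, .data$start)
    }
    list(genome = genome, islands = island_tbl)
  })
}

place_nonoverlapping <- function(count, len, total) {
  if (count == 0) return(numeric())
  # grid placement with random slot choice guarantees non-overlap
  slot <- 2 * len
  n_slots <- floor(total / slot)
  if (n_slots < count) abort("cannot place that many non-overlapping blocks")
  chosen <- sort(sample(n_slots, count))
  (chosen - 1) * slot + floor(len / 2)
}

cpg_island_sequence <- function(len, gc_background, enrichment) {
  bg_cpg <- (gc_background / 2)^2
  p_cg <- min(0.4, enrichment * bg_cpg)
  island_prob <- c(A = 0.2, C = 0.3, G = 0.3, T = 0.2)
  out <- character(0)
  while (length(out) < len) {
    if (runif(1) < p_cg) {
      out <- c(out, "C", "G")
    } else {
      out <- c(out, sample(DNA_BASES, 1, prob = island_prob))
    }
  }
  out[seq_len(len)]
}

#' Sample a synthetic methylome over a genome's CpGs
#'
#' Every CpG cytosine (both strands) receives `total_reads ~
#' Poisson(depth)` and `meth_reads ~ Binomial(total, p)` where `p` is
#' the regime mean at its locus: `background_level` unless a row of
#' `regimes` covers the CpG (later rows override earlier ones). Strand
#' merging downstream therefore yields CpG units at about `2 * depth`
#' coverage. With `n_replicates = 2` the sampled reads of each cytosine
#' are split at random into two half-depth replicates, so merging the
#' replicates reproduces the single-file counts exactly.
#'
#' @param genome Named character vector of sequences.
#' @param regimes Optional tibble `chrom`, `start`, `end`, `level`
#'   assigning region methylation means (applied to the CpG's + strand C
#'   position).
#' @param background_level Methylation mean outside all regimes.
#' @param depth Mean per-cytosine read depth.
#' @param seed RNG seed.
#' @param n_replicates 1 or 2.
#' @param error_rate Bisulfite non-conversion rate (an unmethylated C
#'   read as methylated); default 0.
#' @return A cytosine-record tibble, or a list of `n_replicates` such
#'   tibbles.
#' @export
make_methylome <- function(genome, regimes = NULL, background_level = 0.8,
                           depth = 15, seed = 1, n_replicates = 1,
                           error_rate = 0) {
  stopifnot(n_replicates %in% c(1, 2),
            background_level >= 0, background_level <= 1)
  if (!is.null(regimes) && nrow(regimes) > 0 &&
      (any(regimes$level < 0) || any(regimes$level > 1))) {
    abort("regime means must lie in [0,1]")
  }
  units <- purrr::imap_dfr(as.list(genome), function(seq, chrom) {
    m <- gregexpr("CG", seq, fixed = TRUE)[[1]]
    if (m[1] == -1) return(NULL)
    tibble(chrom = chrom, unit_pos = as.numeric(m) - 1)
  })
  level <- rep(background_level, nrow(units))
  if (!is.null(regimes)) {
    for (i in seq_len(nrow(regimes))) {
      hit <- units$chrom == regimes$chrom[i] &
        units$unit_pos >= regimes$start[i] &
        units$unit_pos < regimes$end[i]
      level[hit] <- regimes$level[i]
    }
  }
  # one record per strand cytosine: + at unit_pos, - at unit_pos + 1
  records <- tibble(
    chrom = rep(units$chrom, 2),
    pos = c(units$unit_pos, units$unit_pos + 1),
    strand = rep(c("+", "-"), each = nrow(units)),
    p = rep(level, 2)
  ) |> arrange(.data$chrom, .data$pos, .data$strand)
  p_obs <- records$p + (1 - records$p) * error_rate
  with_local_seed(seed, {
    total <- rpois(nrow(records), depth)
    meth <- rbinom(nrow(records), total, p_obs)
    out <- records |>
      mutate(meth_reads = meth, total_reads = total) |>
      select("chrom", "pos", "strand", "meth_reads", "total_reads")
    if (n_replicates == 1) return(out)
    total_a <- rbinom(nrow(out), total, 0.5)
    meth_a <- vapply(seq_len(nrow(out)), function(i) {
      if (total[i] == 0) return(0)
      # which of the total reads land in replicate A decides how many of
      # the methylated ones do: hypergeometric split
      stats::rhyper(1, m = meth[i], n = total[i] - meth[i], k = total_a[i])
    }, numeric(1))
    list(
      mutate(out, meth_reads = meth_a, total_reads = total_a),
      mutate(out, meth_reads = meth - meth_a, total_reads = total - total_a)
    )
  })
}

#' Build a sharp PWM from a consensus string
#'
#' Each column gives probability `p_major` to the consensus base and
#' splits the rest evenly — a convenient planted-motif generator.
#'
#' @param consensus DNA string.
#' @param p_major Probability of the consensus base per column.
#' @param background Background base probabilities.
#' @return A `"pwm"`.
#' @export
consensus_pwm <- function(consensus, p_major = 0.94, background = NULL) {
  chars <- strsplit(consensus, "", fixed = TRUE)[[1]]
  stopifnot(all(chars %in% DNA_BASES))
  prob <- matrix((1 - p_major) / 3, nrow = 4, ncol = length(chars),
                 dimnames = list(DNA_BASES, NULL))
  prob[cbind(match(chars, DNA_BASES), seq_along(chars))] <- p_major
  new_pwm(prob, background = background)
}

sample_pwm_sequence <- function(pwm) {
  paste0(vapply(seq_len(ncol(pwm$prob)), function(j) {
    sample(DNA_BASES, 1, prob = pwm$prob[, j])
  }, character(1)), collapse = "")
}

write_into_genome <- function(genome, chrom, start, sequence) {
  # 0-based start; replaces nchar(sequence) bases
  s <- genome[chrom]
  genome[chrom] <- paste0(
    substring(s, 1, start),
    sequence,
    substring(s, start + nchar(sequence) + 1, nchar(s))
  )
  genome
}

# plant one site (sampled from pwm, random strand) per slot; peaks are
# centered on the site +- uniform jitter up to jitter_frac * width so the
# nominal summit is offset from the true site, exercising relocation
plant_sites_at <- function(genome, pwm, slots, peak_width,
                           jitter_frac = 0.25, name_prefix = "peak") {
  L <- ncol(pwm$prob)
  rows <- vector("list", nrow(slots))
  for (i in seq_len(nrow(slots))) {
    chrom <- slots$chrom[i]
    site_center <- slots$center[i]
    site_start <- site_center - floor(L / 2)
    strand <- sample(c("+", "-"), 1)
    site_seq <- sample_pwm_sequence(pwm)
    genomic_seq <- if (strand == "+") site_seq else
      reverse_complement(site_seq)
    genome <- write_into_genome(genome, chrom, site_start, genomic_seq)
    max_j <- floor(jitter_frac * peak_width)
    jitter <- sample(seq(-max_j, max_j), 1)
    peak_start <- site_center + jitter - floor(peak_width / 2)
    peak_start <- max(0, min(peak_start, nchar(genome[chrom]) - peak_width))
    rows[[i]] <- tibble(
      chrom = chrom, start = peak_start, end = peak_start + peak_width,
      name = sprintf("%s_%04d", name_prefix, i),
      score = 1000, strand = ".", signal = 10, pvalue = 5, qvalue = 3,
      summit = floor(peak_width / 2),
      site_start = site_start, site_end = site_start + L,
      site_strand = strand, planted = TRUE
    )
  }
  list(genome = genome, peaks = bind_rows(rows))
}

noise_peaks_at <- function(slots, peak_width, name_prefix = "noise") {
  if (nrow(slots) == 0) {
    return(tibble())
  }
  tibble(
    chrom = slots$chrom,
    start = slots$center - floor(peak_width / 2),
    end = slots$center + ceiling(peak_width / 2),
    name = sprintf("%s_%04d", name_prefix, seq_len(nrow(slots))),
    score = 1000, strand = ".", signal = 5, pvalue = 4, qvalue = 2,
    summit = floor(peak_width / 2),
    site_start = NA_real_, site_end = NA_real_,
    site_strand = NA_character_, planted = FALSE
  )
}

slot_grid <- function(genome, slot_width, avoid = NULL, margin = 0) {
  # non-overlapping candidate slots (centers) on a fixed grid, avoiding
  # the `avoid` intervals (tibble chrom/start/end) by `margin`
  grid <- purrr::imap_dfr(as.list(genome), function(seq, chrom) {
    n <- floor(nchar(seq) / slot_width)
    if (n < 1) return(NULL)
    tibble(chrom = chrom,
           center = (seq_len(n) - 1) * slot_width + floor(slot_width / 2))
  })
  if (!is.null(avoid) && nrow(avoid) > 0) {
    bad <- rep(FALSE, nrow(grid))
    half <- floor(slot_width / 2)
    for (i in seq_len(nrow(avoid))) {
      bad <- bad | (grid$chrom == avoid$chrom[i] &
                      grid$center + half + margin > avoid$start[i] &
                      grid$center - half - margin < avoid$end[i])
    }
    grid <- grid[!bad, ]
  }
  grid
}

#' Plant motif occurrences and emit peaks with known truth
#'
#' Places `n_sites` non-overlapping occurrences sampled from `pwm` into
#' the genome (random strand), emits one peak per occurrence centered on
#' the site plus uniform jitter up to 25% of the peak width (so the
#' nominal summit is displaced from the true site), and `n_noise_peaks`
#' peaks containing no occurrence. `methyl_condition` drives the regime
#' map handed to [make_methylome()]: the occurrence's CpGs are
#' hyper-methylated (`"site_methylated"`, mean 0.9) or hypo-methylated
#' (`"site_unmethylated"`, mean 0.05).
#'
#' @param genome Named character vector (is returned modified).
#' @param pwm Planted `"pwm"`.
#' @param n_sites Number of planted occurrences.
#' @param methyl_condition `"site_methylated"` or `"site_unmethylated"`.
#' @param n_noise_peaks Peaks without an occurrence.
#' @param peak_width Width of every peak.
#' @param seed RNG seed.
#' @return List with `genome` (modified), `peaks` (narrowPeak-shaped
#'   tibble), `truth` (per planted peak: site coordinates and strand),
#'   `site_regimes` (regime tibble for [make_methylome()]).
#' @export
plant_peaks <- function(genome, pwm, n_sites,
                        methyl_condition = c("site_methylated",
                                             "site_unmethylated"),
                        n_noise_peaks = 0, peak_width = 200, seed = 1) {
  methyl_condition <- match.arg(methyl_condition)
  with_local_seed(seed, {
    grid <- slot_grid(genome, 2 * peak_width)
    n_total <- n_sites + n_noise_peaks
    if (nrow(grid) < n_total) {
      abort(sprintf("genome can host at most %d peaks of width %d",
                    nrow(grid), peak_width))
    }
    take <- grid[sort(sample(nrow(grid), n_total)), ]
    which_site <- sort(sample(n_total, n_sites))
    planted <- plant_sites_at(genome, pwm, take[which_site, ], peak_width)
    noise <- noise_peaks_at(take[-which_site, , drop = FALSE], peak_width)
    peaks <- bind_rows(planted$peaks, noise) |>
      arrange(.data$chrom, .data$start)
    level <- if (methyl_condition == "site_methylated") 0.9 else 0.05
    tr <- peaks[peaks$planted, ]
    site_regimes <- tibble(chrom = tr$chrom,
                           start = tr$site_start - 1,
                           end = tr$site_end + 1,
                           level = level)
    list(genome = planted$genome, peaks = peaks,
         truth = tr |> select("name", "chrom", "site_start", "site_end",
                              "site_strand"),
         site_regimes = site_regimes)
  })
}

#' Derive multi-cell-type peak sets from a planned occupancy matrix
#'
#' Cell `c` receives a copy of base peak `p` (shifted by up to `jitter`
#' bp) iff `occupancy_plan[p, c]` is 1. Column 1 is the reference cell
#' and must be all ones. A scalar plan in `(0,1)` is expanded to a
#' Bernoulli draw per (peak, non-reference cell).
#'
#' @param base_peaks Peak tibble.
#' @param n_cells Number of cell types including the reference.
#' @param occupancy_plan 0/1 matrix (`nrow(base_peaks)` x `n_cells`) or a
#'   single probability.
#' @param jitter Maximum absolute shift applied to copies (default 0;
#'   must be smaller than the narrowest peak).
#' @param seed RNG seed.
#' @return List with `cells` (list of `n_cells` peak tibbles, reference
#'   first) and `plan` (the realized 0/1 matrix).
#' @export
make_multicell <- function(base_peaks, n_cells, occupancy_plan,
                           jitter = 0, seed = 1) {
  widths <- base_peaks$end - base_peaks$start
  if (jitter >= min(widths)) abort("jitter must be smaller than peak width")
  with_local_seed(seed, {
    if (is.matrix(occupancy_plan)) {
      plan <- occupancy_plan
      stopifnot(nrow(plan) == nrow(base_peaks), ncol(plan) == n_cells)
    } else {
      plan <- cbind(
        1,
        matrix(rbinom(nrow(base_peaks) * (n_cells - 1), 1, occupancy_plan),
               ncol = n_cells - 1)
      )
    }
    if (!all(plan[, 1] == 1)) {
      abort("the reference cell (plan column 1) must contain every peak")
    }
    cells <- lapply(seq_len(n_cells), function(ci) {
      pk <- base_peaks[plan[, ci] == 1, , drop = FALSE]
      if (jitter > 0 && nrow(pk) > 0 && ci > 1) {
        shift <- sample(seq(-jitter, jitter), nrow(pk), replace = TRUE)
        pk$start <- pmax(0, pk$start + shift)
        pk$end <- pk$end + shift
      }
      pk
    })
    list(cells = cells, plan = plan)
  })
}

exact_group_assignment <- function(n, fraction) {
  # exactly round(fraction * n) TRUEs at random positions
  k <- round(fraction * n)
  out <- rep(FALSE, n)
  out[sample(n, k)] <- TRUE
  out
}
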