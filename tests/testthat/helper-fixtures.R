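# Fixture builders and independent brute-force oracles used across the
# suite. Oracles are deliberately naive (nested loops, exhaustive
# enumeration) and share no code with the implementation they check.

`%||%` <- function(x, y) if (is.null(x)) y else x

random_dna <- function(n, prob = rep(0.25, 4)) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
         collapse = "")
}

# a methylome track built directly from explicit unit positions/levels
toy_track <- function(pos, level, chrom = "chr1", coverage = 10) {
  records <- tibble::tibble(
    chrom = chrom, pos = pos, strand = "+",
    meth_reads = round(level * coverage), total_reads = coverage
  )
  build_track(records, merge_cpg_strands = FALSE)
}

random_track <- function(n_units, chrom_len = 1000, chrom = "chr1") {
  pos <- sort(sample(chrom_len, n_units))
  total <- rpois(n_units, 8)
  meth <- rbinom(n_units, total, runif(n_units))
  build_track(
    tibble::tibble(chrom = chrom, pos = pos, strand = "+",
                   meth_reads = meth, total_reads = total),
    merge_cpg_strands = FALSE
  )
}

# -- oracles ----------------------------------------------------------------

oracle_query <- function(track, chrom, start, end) {
  df <- tibble::as_tibble(track)
  hit <- df$chrom == chrom & df$pos >= start & df$pos < end &
    !is.na(df$level)
  df[hit, c("pos", "level")]
}

oracle_peak_mean <- function(track, chrom, start, end) {
  q <- oracle_query(track, chrom, start, end)
  if (nrow(q) == 0) return(list(n = 0L, mean = NA_real_))
  list(n = nrow(q), mean = sum(q$level) / nrow(q))
}

oracle_score <- function(pwm, seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  s <- 0
  for (j in seq_along(chars)) {
    s <- s + log2(pwm$prob[chars[j], j] / pwm$background[chars[j]])
  }
  unname(s)
}

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste0(rev(map[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
}

# exhaustive enumeration of every (offset, strand) placement
oracle_scan <- function(pwm, seq) {
  L <- ncol(pwm$prob)
  n <- nchar(seq)
  best <- NULL
  for (offset in 0:(n - L)) {
    for (strand in c("+", "-")) {
      sub <- substring(seq, offset + 1, offset + L)
      if (strand == "-") sub <- oracle_revcomp(sub)
      if (grepl("N", sub, fixed = TRUE)) next
      sc <- oracle_score(pwm, sub)
      if (is.null(best) || sc > best$score ||
          (sc == best$score && (offset < best$offset ||
                                (offset == best$offset &&
                                 strand == "+" && best$strand == "-")))) {
        best <- list(offset = offset, strand = strand, score = sc)
      }
    }
  }
  best
}

oracle_state <- function(peak_start, peak_end, segs) {
  # segs: tibble start/end/state on one chromosome
  totals <- list()
  for (i in seq_len(nrow(segs))) {
    ov <- min(peak_end, segs$end[i]) - max(peak_start, segs$start[i])
    if (ov <= 0) next
    lab <- segs$state[i]
    totals[[lab]] <- (totals[[lab]] %||% 0) + ov
  }
  if (length(totals) == 0) return("Unannotated")
  labs <- sort(names(totals))
  labs[which.max(unlist(totals[labs]))]
}

oracle_occupancy <- function(ref_start, ref_end, sets) {
  k <- 1L
  for (set in sets) {
    hit <- FALSE
    for (i in seq_len(nrow(set))) {
      if (set$start[i] < ref_end && set$end[i] > ref_start) hit <- TRUE
    }
    if (hit) k <- k + 1L
  }
  k
}

oracle_genes_near <- function(regions, genes, window) {
  out <- character()
  for (g in seq_len(nrow(genes))) {
    for (r in seq_len(nrow(regions))) {
      if (genes$chrom[g] != regions$chrom[r]) next
      s <- max(0, regions$start[r] - window)
      e <- regions$end[r] + window
      if (genes$start[g] < e && genes$end[g] > s) {
        out <- c(out, genes$name[g])
      }
    }
  }
  sort(unique(out))
}

# small random peak tibble on one chromosome
random_peaks <- function(n, chrom_len = 1000, min_w = 5, max_w = 60,
                         chrom = "chr1") {
  start <- sample(chrom_len - max_w, n, replace = TRUE)
  w <- sample(min_w:max_w, n, replace = TRUE)
  tibble::tibble(chrom = chrom, start = start, end = start + w,
                 name = sprintf("p%03d", seq_len(n)),
                 score = 0, strand = ".", signal = 0, pvalue = 0,
                 qvalue = 0, summit = NA_real_)
}

# full-size study (500 motif-bearing peaks per archetype, ~30x CpG
# units), generated once and shared by the recovery checks
.study_cache <- new.env(parent = emptyenv())
full_study_results <- function(seed = 42) {
  if (!exists("res", envir = .study_cache)) {
    st <- simulate_tf_study(seed = seed)
    merged <- merge_replicates(st$methylome_replicates[[1]],
                               st$methylome_replicates[[2]])
    track <- suppressMessages(build_track(merged, genome = st$genome))
    pm <- peak_mean_methylation(st$peaks, track)
    assign("res", list(study = st, track = track, peak_meth = pm),
           envir = .study_cache)
  }
  get("res", envir = .study_cache)
}

# relocate the planted peaks of one archetype, scanning each peak with
# the motif variant that was actually planted in it
matched_variant_sites <- function(res, tf, groups = c("hi", "low")) {
  st <- res$study
  pm <- res$peak_meth
  out <- list()
  for (v in c("cpg", "nocpg")) {
    sel <- pm[pm$tf == tf & pm$planted & pm$variant == v &
                pm$group %in% groups, ]
    if (nrow(sel) == 0) next
    out[[v]] <- locate_binding_sites(
      dplyr::mutate(sel, group = "hi"), st$pwms[[tf]][[v]],
      st$pwms[[tf]][[v]], st$genome, track = res$track
    )
  }
  dplyr::bind_rows(out)
}

# scaled-down study used wherever full size is unnecessary
small_study <- function(seed = 11) {
  simulate_tf_study(
    seed = seed, n_peaks_per_tf = 60, n_noise_peaks = 10,
    n_dhs = 60, n_genes = 80, n_chroms = 2, chrom_length = 300000
  )
}
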