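# Position weight matrices: estimation, log-odds scoring, best-site
# scanning of peaks, seeded de novo discovery, and JASPAR-style import.

#' Build a position weight matrix from aligned sequences
#'
#' Column probabilities are `(count + pseudocount) / (n + 4 * pseudocount)`
#' so every probability is positive whenever `pseudocount > 0`.
#'
#' @param sequences Equal-length DNA strings over `{A,C,G,T}` (sequences
#'   containing `N` are rejected).
#' @param pseudocount Added to every cell (default 0.5).
#' @param background Named base probabilities (`A`,`C`,`G`,`T`); uniform
#'   when omitted. Used for log-odds scoring.
#' @return An object of class `"pwm"`: list with `prob` (4 x L matrix,
#'   rows A,C,G,T), `counts`, `pseudocount`, `background`.
#' @examples
#' pwm <- build_pwm(c("ACGT", "ACGT", "ACGA"), pseudocount = 1)
#' pwm$prob["T", 4]  # 3/7
#' @export
build_pwm <- function(sequences, pseudocount = 0.5, background = NULL) {
  if (length(sequences) == 0) abort("need at least one sequence")
  L <- unique(nchar(sequences))
  if (length(L) != 1) abort("sequences must have equal lengths")
  if (L == 0) abort("sequences must be non-empty")
  chars <- matrix(unlist(strsplit(sequences, "", fixed = TRUE)),
                  nrow = length(sequences), byrow = TRUE)
  if (!all(chars %in% DNA_BASES)) {
    abort("sequences must be over {A,C,G,T}; N is not allowed in a PWM alignment")
  }
  counts <- vapply(seq_len(L), function(j) {
    tabulate(match(chars[, j], DNA_BASES), nbins = 4)
  }, numeric(4))
  dimnames(counts) <- list(DNA_BASES, NULL)
  n <- length(sequences)
  prob <- (counts + pseudocount) / (n + 4 * pseudocount)
  if (pseudocount == 0 && any(prob == 0)) {
    warn("PWM contains zero probabilities (pseudocount = 0); log-odds scores may be -Inf")
  }
  new_pwm(prob, counts = counts, pseudocount = pseudocount,
          background = background)
}

new_pwm <- function(prob, counts = NULL, pseudocount = NA_real_,
                    background = NULL) {
  background <- background %||% setNames(rep(0.25, 4), DNA_BASES)
  stopifnot(all(rownames(prob) == DNA_BASES),
            all(abs(colSums(prob) - 1) < 1e-9))
  structure(
    list(prob = prob, counts = counts, pseudocount = pseudocount,
         background = background[DNA_BASES]),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM of width %d (consensus %s)\n",
              ncol(x$prob), pwm_consensus(x)))
  print(round(x$prob, 3))
  invisible(x)
}

#' Consensus string of a PWM
#' @param pwm A `"pwm"`.
#' @return Character scalar.
#' @export
pwm_consensus <- function(pwm) {
  paste0(DNA_BASES[apply(pwm$prob, 2, which.max)], collapse = "")
}

#' Mononucleotide background from a genome
#' @param genome Named character vector of sequences.
#' @return Named probability vector over `A`,`C`,`G`,`T` (N excluded).
#' @export
genome_background <- function(genome) {
  counts <- rowSums(vapply(
    genome,
    function(s) {
      f <- Biostrings::letterFrequency(Biostrings::DNAString(s),
                                       letters = DNA_BASES)
      as.numeric(f)
    },
    numeric(4)
  ))
  setNames(counts / sum(counts), DNA_BASES)
}

pwm_log_odds <- function(pwm) {
  log2(pwm$prob / pwm$background[DNA_BASES])
}

pwm_reverse_complement <- function(pwm) {
  prob <- pwm$prob[rev(seq_len(4)), rev(seq_len(ncol(pwm$prob))), drop = FALSE]
  rownames(prob) <- DNA_BASES
  new_pwm(prob,
          counts = if (!is.null(pwm$counts)) {
            cm <- pwm$counts[rev(seq_len(4)), rev(seq_len(ncol(pwm$counts))),
                             drop = FALSE]
            rownames(cm) <- DNA_BASES
            cm
          },
          pseudocount = pwm$pseudocount, background = pwm$background)
}

#' Log-odds match score of a sequence against a PWM
#'
#' Sum over positions of `log2(P(base | column) / background(base))`, in
#' bits. The sequence length must equal the PWM width; a sequence
#' containing `N` has an undefined score (`NA`), which the scanner skips.
#'
#' @param pwm A `"pwm"`.
#' @param sequence DNA string(s) of length `ncol(pwm$prob)` (vectorized).
#' @return Numeric score(s) in bits.
#' @export
score_site <- function(pwm, sequence) {
  L <- ncol(pwm$prob)
  if (any(nchar(sequence) != L)) {
    abort(sprintf("sequence length must equal PWM width (%d)", L))
  }
  lom <- pwm_log_odds(pwm)
  vapply(sequence, function(s) {
    code <- match(strsplit(s, "", fixed = TRUE)[[1]], DNA_BASES)
    if (anyNA(code)) return(NA_real_)
    sum(lom[cbind(code, seq_len(L))])
  }, numeric(1), USE.NAMES = FALSE)
}

scan_scores <- function(lom, code) {
  # log-odds score at every placement of a PWM (columns of lom) along an
  # integer-coded sequence; NA propagates from N positions
  L <- ncol(lom)
  n <- length(code)
  n_off <- n - L + 1L
  s <- numeric(n_off)
  for (j in seq_len(L)) {
    s <- s + unname(lom[, j])[code[j:(j + n_off - 1L)]]
  }
  s
}

#' Best PWM placement within one peak sequence
#'
#' Scores every offset on both strands (the reverse strand is scored on
#' the reverse complement) and returns the maximum-scoring placement —
#' the relocated binding site. Ties break deterministically: smaller
#' offset first, then + strand. Placements covering an `N` are skipped.
#'
#' @param pwm A `"pwm"`.
#' @param peak_sequence DNA string at least as long as the PWM.
#' @return One-row tibble with `offset` (0-based within the peak),
#'   `strand`, `score`; zero rows when no placement is scorable
#'   (all placements hit an `N`).
#' @export
scan_peak <- function(pwm, peak_sequence) {
  L <- ncol(pwm$prob)
  n <- nchar(peak_sequence)
  if (n < L) abort(sprintf("peak (%d bp) shorter than PWM width (%d)", n, L))
  lom <- pwm_log_odds(pwm)
  code <- match(strsplit(peak_sequence, "", fixed = TRUE)[[1]], DNA_BASES)
  fwd <- scan_scores(lom, code)
  rc_code <- rev(5L - code)                      # A<->T, C<->G on ints 1..4
  rev_sc <- scan_scores(lom, rc_code)
  # offset o (1-based) on the reverse complement covers forward bases
  # [n - L - o + 2, n - o + 1], i.e. forward 0-based offset n - L - o + 1
  cand <- tibble(
    offset = c(seq_along(fwd) - 1L, n - L - seq_along(rev_sc) + 1L),
    strand = rep(c("+", "-"), c(length(fwd), length(rev_sc))),
    score = c(fwd, rev_sc)
  )
  cand <- cand[!is.na(cand$score), ]
  if (nrow(cand) == 0) return(cand)
  cand[order(-cand$score, cand$offset, cand$strand), ][1, ]
}

#' Scan a set of peaks for their best binding placement
#'
#' @param pwm A `"pwm"`.
#' @param peaks Peak tibble (`chrom`, `start`, `end`, `name`, ...).
#' @param genome Named character vector of chromosome sequences.
#' @return Tibble of scan hits (`name`, `chrom`, `offset`, `strand`,
#'   `score`), one row per scannable peak; peaks shorter than the PWM or
#'   without any N-free placement are skipped with a logged count.
#' @export
scan_peaks <- function(pwm, peaks, genome) {
  L <- ncol(pwm$prob)
  hits <- purrr::pmap(
    list(peaks$chrom, peaks$start, peaks$end, peaks$name),
    function(chrom, start, end, name) {
      if (end - start < L) return(NULL)
      seq <- substring(genome[chrom], start + 1, end)
      hit <- scan_peak(pwm, seq)
      if (nrow(hit) == 0) return(NULL)
      mutate(hit, name = name, chrom = chrom, peak_start = start,
             .before = 1)
    }
  )
  n_skipped <- sum(vapply(hits, is.null, logical(1)))
  if (n_skipped > 0) {
    inform(sprintf("scan_peaks: skipped %d unscannable peak(s)", n_skipped))
  }
  bind_rows(hits)
}

#' De novo motif discovery by seeded ZOOPS refinement
#'
#' A self-contained discovery stage: overrepresented k-mers (relative to a
#' per-sequence letter-shuffled background) seed candidate PWMs; each seed
#' is refined by alternating best-site assignment (one site per sequence,
#' both strands) with PWM re-estimation until the probability matrix
#' changes by less than `tol` or `max_iter` iterations. The candidate
#' whose assigned sites have the highest total log-odds wins. Output is
#' deterministic for a given `seed`.
#'
#' @param sequences DNA strings (at least ~50 recommended).
#' @param width_range Motif widths to try, `c(w_min, w_max)`, each >= 4.
#' @param n_seeds Number of seed k-mers per width (default 5).
#' @param seed RNG seed controlling the shuffled background.
#' @param pseudocount Pseudocount for PWM re-estimation.
#' @param background Base probabilities for log-odds (uniform default).
#' @param max_iter,tol Refinement stopping rule.
#' @return The winning `"pwm"`, with attributes `score` (total assigned
#'   log-odds), `enrichment` (seed k-mer enrichment), `n_iter`.
#' @export
discover_motif <- function(sequences, width_range = c(8, 8), n_seeds = 5,
                           seed = 1, pseudocount = 0.5, background = NULL,
                           max_iter = 100, tol = 1e-4) {
  widths <- seq(width_range[1], width_range[2])
  if (any(widths < 4)) abort("motif widths must be >= 4")
  if (all(nchar(sequences) < min(widths))) {
    abort("all sequences are shorter than the minimum motif width")
  }
  best <- NULL
  with_local_seed(seed, {
    for (w in widths) {
      usable <- sequences[nchar(sequences) >= w]
      seeds <- seed_kmers(usable, w, n_seeds)
      for (i in seq_len(nrow(seeds))) {
        pwm <- kmer_seed_pwm(seeds$kmer[i], background)
        ref <- refine_pwm(pwm, usable, pseudocount, background,
                          max_iter, tol)
        if (is.null(best) || ref$score > attr(best, "score")) {
          best <- ref$pwm
          attr(best, "score") <- ref$score
          attr(best, "enrichment") <- seeds$enrichment[i]
          attr(best, "n_iter") <- ref$n_iter
        }
      }
    }
  })
  best
}

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

count_kmers <- function(sequences, w) {
  windows <- unlist(lapply(sequences, function(s) {
    n <- nchar(s)
    if (n < w) return(character())
    substring(s, 1:(n - w + 1), w:n)
  }))
  windows <- windows[!grepl("N", windows, fixed = TRUE)]
  table(windows)
}

seed_kmers <- function(sequences, w, n_seeds) {
  obs <- count_kmers(sequences, w)
  shuffled <- vapply(sequences, function(s) {
    paste0(sample(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  bg <- count_kmers(shuffled, w)
  kmers <- names(obs)
  enr <- (as.numeric(obs) + 1) / (as.numeric(bg[kmers]) %|na|% 0 + 1)
  ord <- order(-enr, -as.numeric(obs), kmers)   # deterministic
  tibble(kmer = kmers[ord], enrichment = enr[ord])[
    seq_len(min(n_seeds, length(kmers))), ]
}

`%|na|%` <- function(x, y) ifelse(is.na(x), y, x)

kmer_seed_pwm <- function(kmer, background) {
  chars <- strsplit(kmer, "", fixed = TRUE)[[1]]
  prob <- matrix(0.1, nrow = 4, ncol = length(chars),
                 dimnames = list(DNA_BASES, NULL))
  prob[cbind(match(chars, DNA_BASES), seq_along(chars))] <- 0.7
  new_pwm(prob, background = background)
}

refine_pwm <- function(pwm, sequences, pseudocount, background,
                       max_iter, tol) {
  L <- ncol(pwm$prob)
  codes <- lapply(strsplit(sequences, "", fixed = TRUE), match, DNA_BASES)
  n_iter <- 0L
  total <- -Inf
  repeat {
    n_iter <- n_iter + 1L
    lom <- pwm_log_odds(pwm)
    assigned <- vapply(codes, function(code) {
      fwd <- scan_scores(lom, code)
      rev_sc <- scan_scores(lom, rev(5L - code))
      n <- length(code)
      sc <- c(fwd, rev_sc)
      if (all(is.na(sc))) return(NA_character_)
      k <- which.max(replace(sc, is.na(sc), -Inf))
      if (k <= length(fwd)) {
        paste0(DNA_BASES[code[k:(k + L - 1L)]], collapse = "")
      } else {
        o <- k - length(fwd)
        rc <- rev(5L - code)
        paste0(DNA_BASES[rc[o:(o + L - 1L)]], collapse = "")
      }
    }, character(1))
    assigned <- assigned[!is.na(assigned)]
    new <- build_pwm(assigned, pseudocount = pseudocount,
                     background = background)
    total <- sum(score_site(new, assigned))
    delta <- max(abs(new$prob - pwm$prob))
    pwm <- new
    if (delta < tol || n_iter >= max_iter) break
  }
  list(pwm = pwm, score = total, n_iter = n_iter)
}

#' Read a PWM from a JASPAR-style matrix file
#'
#' Accepts the 4-row layout `A [ 1 2 3 ]` (counts or probabilities) with
#' an optional `>name` header, or a bare 4-row whitespace-separated
#' matrix in A,C,G,T row order. Counts are normalized per column.
#'
#' @param path File path.
#' @param pseudocount Pseudocount applied when normalizing counts.
#' @param background Background base probabilities.
#' @return A `"pwm"`.
#' @export
read_pwm <- function(path, pseudocount = 0.5, background = NULL) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), ">")]
  if (length(lines) != 4) abort("PWM file must contain exactly 4 matrix rows")
  rows <- lapply(lines, function(l) {
    l <- gsub("^[ACGTacgt]\\s*|\\[|\\]", " ", l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  })
  if (length(unique(lengths(rows))) != 1) {
    abort("PWM rows have unequal lengths")
  }
  m <- do.call(rbind, rows)
  rownames(m) <- DNA_BASES
  if (all(abs(colSums(m) - 1) < 1e-6)) {
    new_pwm(m, pseudocount = NA_real_, background = background)
  } else {
    n <- colSums(m)
    prob <- sweep(m + pseudocount, 2, n + 4 * pseudocount, "/")
    new_pwm(prob, counts = m, pseudocount = pseudocount,
            background = background)
  }
}

#' Write a PWM as a JASPAR-style probability matrix
#' @param pwm A `"pwm"`.
#' @param path Output path.
#' @param name Header name written after `>`.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(pwm, path, name = "motif") {
  lines <- c(
    paste0(">", name),
    vapply(DNA_BASES, function(b) {
      sprintf("%s [ %s ]", b,
              paste(format(pwm$prob[b, ], digits = 10), collapse = " "))
    }, character(1))
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Best mean column-wise correlation between two PWMs
#'
#' Compares probability columns under small relative shifts and reverse
#' complementation, returning the best mean Pearson correlation over the
#' overlapping columns — the standard yardstick for motif recovery.
#'
#' @param pwm_a,pwm_b `"pwm"` objects (widths may differ slightly).
#' @param max_shift Maximum offset tried in either direction (default 1).
#' @return List with `r` (best mean column correlation), `shift`,
#'   `strand` (`"+"` or `"-"` for the reverse complement of `pwm_b`).
#' @export
pwm_similarity <- function(pwm_a, pwm_b, max_shift = 1) {
  best <- list(r = -Inf, shift = 0L, strand = "+")
  for (strand in c("+", "-")) {
    b <- if (strand == "+") pwm_b else pwm_reverse_complement(pwm_b)
    for (shift in seq(-max_shift, max_shift)) {
      ja <- seq_len(ncol(pwm_a$prob))
      jb <- ja + shift
      keep <- jb >= 1 & jb <= ncol(b$prob)
      if (sum(keep) < 2) next
      rs <- vapply(which(keep), function(j) {
        suppressWarnings(cor(pwm_a$prob[, j], b$prob[, j + shift]))
      }, numeric(1))
      r <- mean(rs, na.rm = TRUE)
      if (!is.na(r) && r > best$r) best <- list(r = r, shift = shift,
                                                strand = strand)
    }
  }
  best
}
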