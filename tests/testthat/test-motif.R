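test_that("PWM estimation matches hand counts with pseudocounts", {
  pwm <- build_pwm(c("ACGT", "ACGT", "ACGA"), pseudocount = 1)
  expect_equal(unname(pwm$prob["T", 4]), 3 / 7)
  expect_equal(unname(pwm$prob["A", 4]), 2 / 7)  # 1 observed + 1 pseudo
  expect_equal(unname(pwm$prob["C", 4]), 1 / 7)
  expect_equal(unname(colSums(pwm$prob)), rep(1, 4), tolerance = 1e-12)

  # zero observed count still gets positive mass
  expect_equal(unname(pwm$prob["G", 1]), 1 / 7)
  expect_true(all(pwm$prob > 0))

  expect_warning(p0 <- build_pwm("A", pseudocount = 0), "zero")
  expect_equal(unname(p0$prob["A", 1]), 1)
  expect_error(build_pwm(c("AC", "ACG")), "equal")
  expect_error(build_pwm(character()), "at least one")
  expect_error(build_pwm("ANCG"), "N is not allowed")
})

test_that("log-odds scores have the expected identities", {
  uniform <- suppressWarnings(
    build_pwm(c("ACGT", "CAGT", "GTAC", "TGCA"), pseudocount = 0)
  )
  expect_equal(score_site(uniform, "AAAA"), 0)
  single <- consensus_pwm("A", p_major = 0.5)
  expect_equal(score_site(single, "A"), 1)  # log2(0.5 / 0.25)
  expect_true(is.na(score_site(single, "N")))
})

test_that("scores agree with a per-position manual sum", {
  set.seed(11)
  for (i in 1:10) {
    pwm <- build_pwm(replicate(6, random_dna(8)), pseudocount = 0.5)
    for (j in 1:10) {
      s <- random_dna(8)
      expect_equal(score_site(pwm, s), oracle_score(pwm, s))
    }
  }
})

test_that("peak scanning matches exhaustive enumeration of placements", {
  set.seed(12)
  for (i in 1:60) {
    L <- sample(4:7, 1)
    pwm <- build_pwm(replicate(5, random_dna(L)), pseudocount = 0.5)
    seq <- random_dna(sample(L:40, 1))
    got <- scan_peak(pwm, seq)
    want <- oracle_scan(pwm, seq)
    expect_equal(got$offset, want$offset)
    expect_equal(got$strand, want$strand)
    expect_equal(got$score, want$score)
  }
  expect_error(scan_peak(consensus_pwm("ACGTACGT"), "ACG"), "shorter")
})

test_that("scan scores are invariant under reverse complementing the peak", {
  set.seed(13)
  for (i in 1:20) {
    pwm <- build_pwm(replicate(5, random_dna(6)), pseudocount = 0.5)
    s <- random_dna(30)
    a <- scan_peak(pwm, s)
    b <- scan_peak(pwm, oracle_revcomp(s))
    expect_equal(a$score, b$score)
  }
})

test_that("palindromic ties resolve to the + strand", {
  pwm <- build_pwm(c("ACGT", "ACGT"), pseudocount = 0.5)
  hit <- scan_peak(pwm, "ACGT")
  expect_equal(hit$strand, "+")
  expect_equal(hit$offset, 0)
})

test_that("adding constant flanks never lowers the best score", {
  set.seed(14)
  for (i in 1:20) {
    pwm <- build_pwm(replicate(4, random_dna(5)), pseudocount = 0.5)
    s <- random_dna(20)
    base <- scan_peak(pwm, s)$score
    flanked <- scan_peak(pwm, paste0("AAAAA", s, "AAAAA"))$score
    expect_gte(flanked, base)
  }
})

test_that("N-containing placements are skipped, not penalized", {
  pwm <- consensus_pwm("ACGT")
  hit <- scan_peak(pwm, "NNNNACGTNN")
  expect_equal(hit$offset, 4)
  expect_equal(nrow(scan_peak(pwm, "NNNNNN")), 0)
})

test_that("motif discovery recovers a planted motif and is deterministic", {
  set.seed(15)
  planted <- consensus_pwm("TGACGTCA", p_major = 0.9)
  seqs <- vapply(1:120, function(i) {
    s <- random_dna(120)
    occ <- paste0(vapply(1:8, function(j) {
      sample(c("A", "C", "G", "T"), 1, prob = planted$prob[, j])
    }, character(1)), collapse = "")
    at <- sample(110, 1)
    paste0(substring(s, 1, at), occ, substring(s, at + 9, 120))
  }, character(1))
  found <- discover_motif(seqs, width_range = c(8, 8), n_seeds = 3,
                          seed = 99)
  sim <- pwm_similarity(planted, found)
  expect_gte(sim$r, 0.8)

  again <- discover_motif(seqs, width_range = c(8, 8), n_seeds = 3,
                          seed = 99)
  expect_identical(found$prob, again$prob)
})

test_that("discovery enrichment is much weaker on pure random sequences", {
  set.seed(16)
  planted <- consensus_pwm("TGACGTCA", p_major = 0.95)
  with_sig <- vapply(1:80, function(i) {
    s <- random_dna(100)
    at <- sample(90, 1)
    paste0(substring(s, 1, at), "TGACGTCA", substring(s, at + 9, 100))
  }, character(1))
  noise <- vapply(1:80, function(i) random_dna(100), character(1))
  e_sig <- attr(discover_motif(with_sig, c(8, 8), n_seeds = 2, seed = 5),
                "enrichment")
  e_noise <- attr(discover_motif(noise, c(8, 8), n_seeds = 2, seed = 5),
                  "enrichment")
  expect_gte(e_sig / e_noise, 2)
})

test_that("PWMs round-trip through JASPAR-style files", {
  f <- withr::local_tempfile()
  pwm <- build_pwm(replicate(6, random_dna(7)), pseudocount = 0.5)
  write_pwm(pwm, f, name = "test")
  back <- read_pwm(f)
  expect_equal(back$prob, pwm$prob, tolerance = 1e-9)

  # count-style input is normalized with the pseudocount
  writeLines(c("A [ 2 0 ]", "C [ 0 2 ]", "G [ 0 0 ]", "T [ 0 0 ]"), f)
  counts <- read_pwm(f, pseudocount = 1)
  expect_equal(unname(counts$prob["A", 1]), 3 / 6)
  expect_equal(unname(counts$prob["G", 1]), 1 / 6)
})

test_that("genome background reflects mononucleotide composition", {
  bg <- genome_background(c(chr1 = "AAAACCGG", chr2 = "TTNN"))
  expect_equal(bg[["A"]], 0.4)
  expect_equal(bg[["T"]], 0.2)
  expect_equal(sum(bg), 1)
})
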