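# one peak whose sequence carries a planted consensus, plus a methylome
# covering its CpG, built in code
site_fixture <- function() {
  set.seed(21)
  left <- random_dna(60)
  right <- random_dna(60)
  genome <- c(chr1 = paste0(left, "TTGCGCAATC", right))
  peaks <- tibble::tibble(chrom = "chr1", start = 40, end = 110,
                          name = "p1", group = "hi")
  # CpG of the consensus sits at 0-based positions 63-64
  rec <- tibble::tibble(chrom = "chr1", pos = c(63, 64), strand = c("+", "-"),
                        meth_reads = c(9, 9), total_reads = c(10, 10))
  track <- build_track(rec, genome = genome)
  list(genome = genome, peaks = peaks, track = track,
       pwm = consensus_pwm("TTGCGCAATC"))
}

test_that("binding sites are relocated to the planted occurrence", {
  fx <- site_fixture()
  sites <- locate_binding_sites(fx$peaks, fx$pwm, fx$pwm, fx$genome,
                                track = fx$track)
  expect_equal(sites$start, 60)
  expect_equal(sites$strand, "+")
  expect_equal(sites$sequence, "TTGCGCAATC")
  expect_equal(sites$site_meth, 0.9)
  expect_equal(sites$methyl_group, "high")
})

test_that("site sequences round-trip: stored sequence is what was scored", {
  st <- small_study(seed = 23)
  merged <- merge_replicates(st$methylome_replicates[[1]],
                             st$methylome_replicates[[2]])
  track <- build_track(merged, genome = st$genome)
  pm <- peak_mean_methylation(st$peaks[st$peaks$tf == "avoiding", ], track)
  pwm <- st$pwms$avoiding$cpg
  sites <- locate_binding_sites(pm, pwm, pwm, st$genome)
  for (i in seq_len(min(nrow(sites), 40))) {
    raw <- unname(substring(st$genome[sites$chrom[i]], sites$start[i] + 1,
                            sites$end[i]))
    expected <- if (sites$strand[i] == "+") raw else oracle_revcomp(raw)
    expect_equal(sites$sequence[i], expected)
    expect_equal(score_site(pwm, sites$sequence[i]), sites$score[i])
  }
})

test_that("site methylation takes the maximum CpG level on the site", {
  tr <- toy_track(c(105, 112), c(0.3, 0.8))
  sites <- tibble::tibble(chrom = "chr1", start = 100, end = 115)
  expect_equal(site_methylation(sites, tr), 0.8)

  one <- tibble::tibble(chrom = "chr1", start = 110, end = 114)
  expect_equal(site_methylation(one, tr), 0.8)
  none <- tibble::tibble(chrom = "chr1", start = 200, end = 220)
  expect_true(is.na(site_methylation(none, tr)))
})

test_that("merged CpG units overlap sites through either cytosine", {
  genome <- c(chr1 = "AAACGAAAAA")
  rec <- tibble::tibble(chrom = "chr1", pos = c(3, 4), strand = c("+", "-"),
                        meth_reads = 5, total_reads = 10)
  tr <- build_track(rec, genome = genome)
  # site covering only the G (position 4) of the CpG at 3-4
  site <- tibble::tibble(chrom = "chr1", start = 4, end = 8)
  expect_equal(site_methylation(site, tr), 0.5)
})

test_that("site grouping uses strict boundaries and handles missing CpGs", {
  expect_equal(group_site(c(0.7, 0.1, 0.4)), c("high", "low", "middle"))
  expect_equal(group_site(c(0.6, 0.2)), c("middle", "middle"))
  expect_equal(group_site(NA_real_), "no_cpg")
})

test_that("CpG-containing-site fraction counts CG substrings", {
  sites <- tibble::tibble(sequence = c("ACGT", "AAAA", "TTCG", "GGGG"))
  expect_equal(cpg_site_fraction(sites), 0.5)
  expect_equal(cpg_site_fraction(tibble::tibble(sequence = c("AT", "TA"))), 0)
  expect_error(cpg_site_fraction(tibble::tibble(sequence = character())),
               "no binding sites")
})

test_that("methyl motifs mark methylated CpG cytosines as E", {
  genome <- c(chr1 = "AACGTTTTTT")
  rec <- tibble::tibble(chrom = "chr1", pos = c(2, 3), strand = c("+", "-"),
                        meth_reads = c(9, 9), total_reads = c(10, 10))
  tr <- build_track(rec, genome = genome)
  site <- tibble::tibble(chrom = "chr1", start = 1, end = 5, strand = "+",
                         name = "s1")
  mm <- rebuild_methyl_motif(site, tr, genome)
  expect_equal(unname(mm$counts["E", 2]), 1)   # the methylated C, column 2 of ACGT
  expect_equal(unname(mm$counts["C", 2]), 0)

  # below the threshold the base stays C
  rec_low <- dplyr::mutate(rec, meth_reads = c(3, 3))
  tr_low <- build_track(rec_low, genome = genome)
  mm_low <- rebuild_methyl_motif(site, tr_low, genome)
  expect_equal(unname(mm_low$counts["C", 2]), 1)
  expect_equal(unname(mm_low$counts["E", 2]), 0)
})

test_that("minus-strand sites are annotated on the reading strand", {
  set.seed(24)
  for (i in 1:25) {
    # genome with one CpG inside a 6 bp window read on the minus strand
    left <- random_dna(10)
    genome <- c(chr1 = paste0(left, "ACGTAA", random_dna(10)))
    rec <- tibble::tibble(chrom = "chr1", pos = c(11, 12),
                          strand = c("+", "-"),
                          meth_reads = 9, total_reads = 10)
    tr <- build_track(rec, genome = genome)
    site <- tibble::tibble(chrom = "chr1", start = 10, end = 16,
                           strand = "-", name = "s")
    mm <- rebuild_methyl_motif(site, tr, genome)
    # reading strand sequence is revcomp(ACGTAA) = TTACGT: its C (column
    # 4) is the minus-strand C of the same CpG unit, so it becomes E
    expect_equal(sum(mm$counts["E", ]), 1)
    expect_equal(unname(mm$counts["E", 4]), 1)
    # hand-worked check of every reading-strand letter
    expected <- strsplit(oracle_revcomp("ACGTAA"), "")[[1]]
    expected[4] <- "E"
    got <- rownames(mm$counts)[apply(mm$counts, 2, which.max)]
    expect_equal(got, expected)
  }
})

test_that("collapsing E into C reproduces the plain PWM counts", {
  st <- small_study(seed = 25)
  merged <- merge_replicates(st$methylome_replicates[[1]],
                             st$methylome_replicates[[2]])
  track <- build_track(merged, genome = st$genome)
  pm <- peak_mean_methylation(st$peaks[st$peaks$tf == "preferring", ], track)
  sites <- locate_binding_sites(pm, st$pwms$preferring$cpg,
                                st$pwms$preferring$nocpg, st$genome,
                                track = track)
  mm <- rebuild_methyl_motif(sites, track, st$genome)
  plain <- suppressWarnings(build_pwm(sites$sequence, pseudocount = 0))$counts
  expect_equal(collapse_methyl_motif(mm), plain, ignore_attr = TRUE)
  expect_equal(sum(mm$counts), mm$n_sites * ncol(mm$counts))
})
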