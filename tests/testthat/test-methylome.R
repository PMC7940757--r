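test_that("methylation_level is the read ratio, undefined at zero coverage", {
  expect_equal(methylation_level(5, 10), 0.5)
  expect_equal(methylation_level(0, 8), 0)
  expect_true(is.na(methylation_level(0, 0)))
  expect_error(methylation_level(6, 5), "exceeds")
})

test_that("replicate merging sums counts and passes single-replicate loci", {
  a <- tibble::tibble(chrom = "chr1", pos = c(100, 200), strand = "+",
                      meth_reads = c(3, 4), total_reads = c(5, 6))
  b <- tibble::tibble(chrom = "chr1", pos = 100, strand = "+",
                      meth_reads = 2, total_reads = 5)
  m <- merge_replicates(a, b)
  expect_equal(m$meth_reads[m$pos == 100], 5)
  expect_equal(m$total_reads[m$pos == 100], 10)
  expect_equal(m$meth_reads[m$pos == 200], 4)

  expect_equal(nrow(merge_replicates(a[0, ], b[0, ])), 0)
  dup <- dplyr::bind_rows(b, b)
  expect_error(merge_replicates(dup, a), "duplicate")
})

test_that("replicate merging is commutative and associative", {
  set.seed(42)
  make_rep <- function() {
    pos <- sample(500, 40)
    tibble::tibble(chrom = sample(c("chr1", "chr2"), 40, replace = TRUE),
                   pos = pos, strand = "+",
                   meth_reads = rbinom(40, 10, 0.5), total_reads = 10)
  }
  for (i in 1:5) {
    r1 <- make_rep(); r2 <- make_rep(); r3 <- make_rep()
    r1 <- dplyr::distinct(r1, chrom, pos, .keep_all = TRUE)
    r2 <- dplyr::distinct(r2, chrom, pos, .keep_all = TRUE)
    r3 <- dplyr::distinct(r3, chrom, pos, .keep_all = TRUE)
    expect_equal(merge_replicates(r1, r2), merge_replicates(r2, r1))
    expect_equal(merge_replicates(merge_replicates(r1, r2), r3),
                 merge_replicates(r1, merge_replicates(r2, r3)))
  }
})

test_that("CpG strand merging collapses symmetric cytosines into one unit", {
  genome <- c(chr1 = "AAACGAAAAA")  # CpG at 0-based positions 3-4
  rec <- tibble::tibble(chrom = "chr1", pos = c(3, 4), strand = c("+", "-"),
                        meth_reads = c(3, 1), total_reads = c(5, 5))
  tr <- build_track(rec, merge_cpg_strands = TRUE, genome = genome)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$pos, 3)
  expect_equal(tr$meth_reads, 4)
  expect_equal(tr$total_reads, 10)
  expect_equal(tr$level, 0.4)

  # without merging the two cytosines stay separate
  tr2 <- build_track(rec, merge_cpg_strands = FALSE)
  expect_equal(nrow(tr2), 2)
})

test_that("non-CpG cytosines are dropped with a logged count", {
  genome <- c(chr1 = "AAACGAACTA")  # CHH C at 0-based position 7
  rec <- tibble::tibble(chrom = "chr1", pos = c(3, 7), strand = "+",
                        meth_reads = c(1, 1), total_reads = c(2, 2))
  expect_message(tr <- build_track(rec, genome = genome), "non-CpG")
  expect_equal(tr$pos, 3)
})

test_that("tracks sort unsorted input and expose coverage-filtered levels", {
  rec <- tibble::tibble(chrom = "chr1", pos = c(300, 100, 200),
                        strand = "+", meth_reads = c(1, 0, 2),
                        total_reads = c(2, 0, 4))
  tr <- build_track(rec, merge_cpg_strands = FALSE)
  expect_equal(tr$pos, c(100, 200, 300))
  expect_true(is.na(tr$level[tr$pos == 100]))  # zero coverage
  expect_equal(tr$level[tr$pos == 200], 0.5)
})

test_that("interval queries respect half-open bounds", {
  tr <- toy_track(c(100, 150, 200), c(0.1, 0.5, 0.9))
  q <- query_interval(tr, "chr1", 100, 200)
  expect_equal(q$pos, c(100, 150))
  expect_equal(nrow(query_interval(tr, "chr1", 201, 300)), 0)
  expect_message(
    expect_equal(nrow(query_interval(tr, "chrX", 0, 100)), 0),
    "not in track"
  )
})

test_that("interval queries agree with a linear-scan oracle", {
  set.seed(101)
  for (i in 1:20) {
    tr <- random_track(50)
    for (j in 1:10) {
      bounds <- sort(sample(0:1000, 2))
      if (bounds[1] == bounds[2]) bounds[2] <- bounds[2] + 1
      got <- query_interval(tr, "chr1", bounds[1], bounds[2])
      want <- oracle_query(tr, "chr1", bounds[1], bounds[2])
      expect_equal(got$pos, want$pos)
      expect_equal(got$level, want$level)
    }
  }
  # whole-chromosome query returns every defined unit in order
  tr <- random_track(80)
  all_units <- query_interval(tr, "chr1", 0, 10000)
  expect_equal(all_units$pos, sort(all_units$pos))
  expect_equal(nrow(all_units), sum(!is.na(tr$level)))
})

test_that("binomially sampled tracks recover their regime mean", {
  gen <- make_genome(seed = 5, chrom_length = 50000, gc = 0.5,
                     islands = list(count = 0, length = 0,
                                    cpg_enrichment = 1))
  rec <- make_methylome(gen$genome, background_level = 0.7, depth = 10,
                        seed = 6)
  tr <- build_track(rec, genome = gen$genome)
  lev <- tr$level[!is.na(tr$level)]
  expect_gt(length(lev), 500)
  se <- sd(lev) / sqrt(length(lev))
  expect_lt(abs(mean(lev) - 0.7), 3 * se)
})
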