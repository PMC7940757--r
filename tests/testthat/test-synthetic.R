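test_that("genome generation is bit-reproducible and honors composition", {
  g1 <- make_genome(seed = 61, chrom_length = 20000)
  g2 <- make_genome(seed = 61, chrom_length = 20000)
  expect_identical(g1$genome, g2$genome)
  expect_false(identical(
    g1$genome, make_genome(seed = 62, chrom_length = 20000)$genome
  ))

  # gc = 0 without islands yields an A/T-only genome
  at <- make_genome(seed = 63, chrom_length = 10000, gc = 0,
                    islands = list(count = 0, length = 0,
                                   cpg_enrichment = 1))
  expect_false(grepl("[CG]", at$genome[[1]]))
})

test_that("islands are visibly CpG-enriched over the background", {
  g <- make_genome(seed = 64, chrom_length = 60000, gc = 0.4,
                   islands = list(count = 4, length = 2000,
                                  cpg_enrichment = 8))
  seq <- g$genome[[1]]
  cpg_density <- function(s) {
    n <- nchar(s)
    length(gregexpr("CG", s, fixed = TRUE)[[1]]) / n
  }
  isl <- g$islands
  island_seq <- paste0(substring(seq, isl$start + 1, isl$end),
                       collapse = "")
  mask <- strsplit(seq, "")[[1]]
  for (i in seq_len(nrow(isl))) mask[(isl$start[i] + 1):isl$end[i]] <- ""
  background_seq <- paste0(mask, collapse = "")
  expect_gt(cpg_density(island_seq), 3 * cpg_density(background_seq))
})

test_that("methylome sampling follows its regime means", {
  gen <- make_genome(seed = 65, chrom_length = 40000, gc = 0.5,
                     islands = list(count = 0, length = 0,
                                    cpg_enrichment = 1))
  # a fully methylated regime yields level 1 wherever coverage exists
  rec <- make_methylome(gen$genome, background_level = 1, depth = 10,
                        seed = 66)
  lev <- methylation_level(rec$meth_reads, rec$total_reads)
  expect_true(all(lev[!is.na(lev)] == 1))

  # an intermediate regime recovers its mean over many CpGs
  reg <- tibble::tibble(chrom = "chr1", start = 0, end = 40000,
                        level = 0.7)
  rec2 <- make_methylome(gen$genome, regimes = reg,
                         background_level = 0.1, depth = 12, seed = 67)
  lev2 <- methylation_level(rec2$meth_reads, rec2$total_reads)
  lev2 <- lev2[!is.na(lev2)]
  expect_gt(length(lev2), 500)
  expect_lt(abs(mean(lev2) - 0.7), 3 * sd(lev2) / sqrt(length(lev2)))
})

test_that("two emitted replicates merge back to the single-file counts", {
  gen <- make_genome(seed = 68, chrom_length = 20000)
  single <- make_methylome(gen$genome, depth = 10, seed = 69,
                           n_replicates = 1)
  pair <- make_methylome(gen$genome, depth = 10, seed = 69,
                         n_replicates = 2)
  merged <- merge_replicates(pair[[1]], pair[[2]])
  single_sorted <- dplyr::arrange(single, chrom, pos, strand)
  expect_equal(merged$total_reads, single_sorted$total_reads)
  expect_equal(merged$meth_reads, single_sorted$meth_reads)
})

test_that("planted peaks carry exactly one recoverable occurrence each", {
  gen <- make_genome(seed = 70, chrom_length = 60000)
  pwm <- consensus_pwm("TGACGTCATG")
  pl <- plant_peaks(gen$genome, pwm, n_sites = 40, n_noise_peaks = 10,
                    methyl_condition = "site_methylated", seed = 71)
  expect_equal(nrow(pl$truth), 40)
  expect_equal(sum(pl$peaks$planted), 40)
  expect_equal(nrow(pl$peaks), 50)
  # every planted site lies inside its peak
  tr <- pl$peaks[pl$peaks$planted, ]
  expect_true(all(tr$site_start >= tr$start & tr$site_end <= tr$end))

  # relocation with the planted PWM recovers >= 90% of sites within 2 bp
  hits <- scan_peaks(pwm, tr, pl$genome)
  m <- match(hits$name, tr$name)
  found <- hits$peak_start + hits$offset
  expect_gte(mean(abs(found - tr$site_start[m]) <= 2), 0.9)
})

test_that("multi-cell generation follows the occupancy plan", {
  set.seed(72)
  base <- random_peaks(10, chrom_len = 100000, min_w = 80, max_w = 120) |>
    dplyr::mutate(group = rep(c("hi", "low"), 5))
  plan <- cbind(1, matrix(rbinom(50, 1, 0.6), ncol = 5))
  mc <- make_multicell(base, 6, plan, seed = 73)
  expect_equal(vapply(mc$cells, nrow, integer(1)), colSums(plan),
               ignore_attr = TRUE)

  # downstream conservation equals the plan-derived truth exactly
  occ <- occupancy(base, mc$cells[-1])
  expect_equal(occ$n_occupied, rowSums(plan), ignore_attr = TRUE)
  truth <- rowSums(plan) / 6 > 0.8
  expect_equal(occ$conserved, truth, ignore_attr = TRUE)

  all_ones <- matrix(1L, 10, 6)
  occ2 <- occupancy(base, make_multicell(base, 6, all_ones)$cells[-1])
  expect_equal(conserved_fraction_by_group(occ2)$conserved_fraction,
               c(1, 1))

  expect_error(make_multicell(base, 3, occupancy_plan = 0.5, jitter = 500),
               "jitter")
})

test_that("the study generator embeds its truth consistently", {
  st <- small_study(seed = 74)
  pk <- st$peaks
  # planted sites lie inside their peaks
  tr <- pk[pk$planted, ]
  expect_true(all(tr$site_start >= tr$start & tr$site_end <= tr$end))
  # planned hi fractions are exact
  expect_equal(mean(pk$group_truth[pk$tf == "preferring"] == "hi"),
               round(0.5718 * 70) / 70)
  # segmentation tiles each chromosome without overlap
  for (ch in names(st$genome)) {
    seg <- st$segmentation[st$segmentation$chrom == ch, ]
    seg <- dplyr::arrange(seg, start)
    expect_true(all(seg$start[-1] >= seg$end[-nrow(seg)]))
  }
  # study generation is reproducible
  st2 <- small_study(seed = 74)
  expect_identical(st$genome, st2$genome)
  expect_identical(st$peaks, st2$peaks)
  expect_identical(st$methylome_replicates, st2$methylome_replicates)
})
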