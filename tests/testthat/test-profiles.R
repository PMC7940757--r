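test_that("profiles over a constant field are flat at that level", {
  pos <- seq(10, 4000, by = 7)
  tr <- toy_track(pos, rep(0.8, length(pos)))
  sites <- tibble::tibble(chrom = "chr1", start = c(1500, 2200),
                          end = c(1510, 2210), strand = c("+", "-"))
  p <- flank_profile(sites, tr, flank = 400, bin = 50)
  expect_equal(nrow(p), 16)
  covered <- p$mean_level[p$n_cpg > 0]
  expect_equal(covered, rep(0.8, length(covered)))
  expect_equal(p$offset, seq(-375, 375, by = 50))
})

test_that("per-bin means equal a direct nested-loop computation", {
  set.seed(31)
  for (rep in 1:10) {
    tr <- random_track(120, chrom_len = 4000)
    n_sites <- 10
    start <- sample(500:3500, n_sites)
    sites <- tibble::tibble(chrom = "chr1", start = start,
                            end = start + 10,
                            strand = sample(c("+", "-"), n_sites, TRUE))
    flank <- 200; bin <- 25
    p <- flank_profile(sites, tr, flank = flank, bin = bin)

    df <- tibble::as_tibble(tr)
    df <- df[!is.na(df$level), ]
    sums <- rep(0, 16); cnt <- rep(0L, 16)
    for (i in seq_len(n_sites)) {
      center <- floor((sites$start[i] + sites$end[i]) / 2)
      for (k in seq_len(nrow(df))) {
        off <- df$pos[k] - center
        if (sites$strand[i] == "-") off <- -off
        if (off < -flank || off >= flank) next
        b <- floor((off + flank) / bin) + 1
        sums[b] <- sums[b] + df$level[k]
        cnt[b] <- cnt[b] + 1L
      }
    }
    expect_equal(p$n_cpg, cnt)
    want <- ifelse(cnt > 0, sums / pmax(cnt, 1), NA_real_)
    expect_equal(p$mean_level, want)
  }
})

test_that("no CpG contribution is lost or duplicated across bins", {
  set.seed(32)
  tr <- random_track(200, chrom_len = 5000)
  start <- sample(1000:4000, 15)
  sites <- tibble::tibble(chrom = "chr1", start = start, end = start + 8,
                          strand = "+")
  p <- flank_profile(sites, tr, flank = 320, bin = 40)
  df <- tibble::as_tibble(tr); df <- df[!is.na(df$level), ]
  pairs <- 0L
  for (i in seq_len(nrow(sites))) {
    center <- floor((sites$start[i] + sites$end[i]) / 2)
    pairs <- pairs + sum(df$pos >= center - 320 & df$pos < center + 320)
  }
  expect_equal(sum(p$n_cpg), pairs)
})

test_that("a planted demethylation valley appears at the profile center", {
  set.seed(33)
  pos <- seq(5, 8000, by = 6)
  centers <- seq(1000, 7000, by = 500)
  level <- rep(0.85, length(pos))
  for (ct in centers) {
    level[abs(pos - ct) <= 100] <- 0.15
  }
  tr <- toy_track(pos, level, coverage = 40)
  sites <- tibble::tibble(chrom = "chr1", start = centers - 5,
                          end = centers + 5,
                          strand = rep(c("+", "-"), length.out = length(centers)))
  p <- flank_profile(sites, tr, flank = 400, bin = 50)
  # minimum sits inside the valley, and the shape is near-symmetric
  expect_lte(abs(p$offset[which.min(p$mean_level)]), 125)
  expect_lt(max(p$mean_level[abs(p$offset) < 100]),
            min(p$mean_level[abs(p$offset) > 150]))
  asym <- abs(rev(p$mean_level) - p$mean_level)
  expect_true(all(asym < 0.15))
})

test_that("profile contrast is zero for identical inputs and checks binning", {
  tr <- toy_track(seq(10, 2000, by = 9), runif(222))
  sites <- tibble::tibble(chrom = "chr1", start = c(800, 1200),
                          end = c(810, 1210), strand = "+")
  p1 <- flank_profile(sites, tr, flank = 200, bin = 25)
  ct <- profile_contrast(p1, p1, n_boot = 50, seed = 4)
  expect_true(all(ct$difference[!is.na(ct$difference)] == 0))
  expect_true(all(ct$lower[!is.na(ct$lower)] <= ct$upper[!is.na(ct$upper)]))

  p2 <- flank_profile(sites, tr, flank = 200, bin = 50)
  expect_error(profile_contrast(p1, p2), "binning")
})
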