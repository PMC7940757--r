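# A complete "two-archetype" synthetic study: a methyl-preferring TF
# (CpG-bearing motif whose high-methyl binding sites carry methylated
# CpGs, CEBPB-like) and a methyl-avoiding TF (CpG-depleted high-methyl
# sites, CTCF-like), over a genome with CpG-island-low vs background-high
# methylation, an enhancer-enriched segmentation, DNase sites, genes, and
# a multi-cell occupancy plan. Every quantity the pipeline later
# estimates is planted here as truth.

STUDY_MOTIFS <- list(
  preferring = list(cpg = "TTGCGCAATC", nocpg = "TTGAGCAATC"),
  avoiding   = list(cpg = "AGCCGGTCAT", nocpg = "AGCAGGTCAT")
)
STUDY_CPG_COLUMN <- 4L  # 1-based column of the planted CpG cytosine

#' Simulate a two-archetype TF binding / methylation study
#'
#' Generates a full synthetic study with recoverable ground truth. Two TF
#' archetypes are planted, 500 motif-bearing peaks plus noise peaks each:
#'
#' * `"preferring"` — methyl-preferring (CEBPB-like): its high-methyl
#'   peaks carry CpG-bearing binding sites whose CpGs are methylated;
#'   the CpG-on-site rate is higher in the hi group (defaults 59.2% vs
#'   35.1%).
#' * `"avoiding"` — methyl-avoiding (CTCF-like): CpG-depleted hi-group
#'   sites (25.3% vs 48.7%), all site CpGs unmethylated, and a planted
#'   demethylation dip around hi-group site centers; its hi-group peaks
#'   are rarely conserved across cell types (18.7% vs 67.2%).
#'
#' Methylation regimes: CpG islands low (0.05), genome background high
#' (0.8, an embryonic-stem-cell-like methylome), hi peaks 0.9, low peaks
#' 0.1; WGBS reads are Poisson x Binomial at ~30x per CpG unit, emitted
#' as two half-depth replicates. Hi peaks sit in enhancer segments at
#' rate 0.8. Peak conservation across `n_cells` cell types follows an
#' exact occupancy plan (conserved peaks occupied by 5 of 6 cells,
#' unconserved by 3). Half the DNase sites are placed in high-methyl
#' background, half in CpG islands.
#'
#' @param seed Master RNG seed; the whole study is deterministic in it.
#' @param n_peaks_per_tf Motif-bearing peaks per archetype.
#' @param n_noise_peaks Additional peaks without a planted occurrence.
#' @param peak_width Peak width in bp.
#' @param depth Mean read depth per cytosine strand (CpG-unit coverage is
#'   about twice this).
#' @param n_cells Cell types surveyed for conservation (incl. reference).
#' @param hi_fraction Named fractions of hi-methyl peaks per archetype.
#' @param cpg_variant_rate Per archetype, named rates (`hi`, `low`) of
#'   planting the CpG-bearing motif variant.
#' @param conserved_rate Per archetype, named conserved fractions.
#' @param enhancer_rate_hi Fraction of hi peaks placed in enhancers.
#' @param promoter_rate_low Fraction of low peaks placed in promoters.
#' @param dhs_methylated Fraction of DNase sites placed in high-methyl
#'   background (the rest go into CpG islands).
#' @param n_dhs,n_genes Numbers of DNase sites and genes.
#' @param n_chroms,chrom_length Genome geometry; the defaults host the
#'   full-size study with peaks spaced so metaplot windows never reach a
#'   neighboring peak.
#' @return A list: `genome`, `islands`, `methylome_replicates` (two
#'   cytosine-record tibbles), `peaks` (per-TF tibble with truth columns
#'   `tf`, `group_truth`, `variant`, `planted`, site coordinates),
#'   `pwms` (per archetype, `cpg`/`nocpg` `"pwm"`s), `segmentation`,
#'   `dhs`, `genes`, `multicell` (per archetype: `cells`, `plan`,
#'   conserved truth), `regimes`, `params`.
#' @export
simulate_tf_study <- function(seed = 1,
                              n_peaks_per_tf = 500,
                              n_noise_peaks = 60,
                              peak_width = 400,
                              depth = 15,
                              n_cells = 6,
                              hi_fraction = c(preferring = 0.5718,
                                              avoiding = 0.30),
                              cpg_variant_rate = list(
                                preferring = c(hi = 0.592, low = 0.3513),
                                avoiding = c(hi = 0.2534, low = 0.4873)
                              ),
                              conserved_rate = list(
                                preferring = c(hi = 0.4191, low = 0.3688),
                                avoiding = c(hi = 0.1873, low = 0.6715)
                              ),
                              enhancer_rate_hi = 0.8,
                              promoter_rate_low = 0.5,
                              dhs_methylated = 0.5,
                              n_dhs = 240,
                              n_genes = 300,
                              n_chroms = 3,
                              chrom_length = 900000) {
  params <- as.list(environment())
  base_seed <- (seed %% 100000) * 101
  level <- list(background = 0.8, island = 0.05, hi = 0.9, low = 0.1,
                site_methylated = 0.95, site_unmethylated = 0.05,
                dip = 0.2, rise = 0.95)
  dip_halfwidth <- 50
  dhs_width <- 200

  gen <- make_genome(seed = base_seed + 1, n_chroms = n_chroms,
                     chrom_length = chrom_length, gc = 0.4,
                     islands = list(count = 8, length = 2000,
                                    cpg_enrichment = 8))
  genome <- gen$genome
  islands <- gen$islands

  pwms <- purrr::map(STUDY_MOTIFS, function(v) {
    purrr::map(v, consensus_pwm)
  })

  tfs <- c("preferring", "avoiding")
  n_pk <- n_peaks_per_tf + n_noise_peaks

  out <- with_local_seed(base_seed + 2, {
    # slots 2 kb apart so the regimes of one peak never reach another
    # peak's 1600 bp metaplot window; islands are kept clear of slots
    grid <- slot_grid(genome, slot_width = 2000, avoid = islands,
                      margin = 200)
    need <- 2 * n_pk + ceiling(n_dhs * dhs_methylated)
    if (nrow(grid) < need) abort("genome too small for the study layout")
    grid <- grid[sample(nrow(grid)), ]
    slot_of <- list(
      preferring = grid[seq_len(n_pk), ],
      avoiding = grid[n_pk + seq_len(n_pk), ],
      dhs = grid[2 * n_pk + seq_len(ceiling(n_dhs * dhs_methylated)), ]
    )

    peak_list <- list()
    for (tf in tfs) {
      slots <- slot_of[[tf]]
      hi <- exact_group_assignment(n_pk, hi_fraction[[tf]])
      planted <- exact_group_assignment(n_pk, n_peaks_per_tf / n_pk)
      variant <- rep(NA_character_, n_pk)
      for (g in c("hi", "low")) {
        in_g <- planted & (hi == (g == "hi"))
        idx <- which(in_g)
        cpg <- idx[exact_group_assignment(length(idx),
                                          cpg_variant_rate[[tf]][[g]])]
        variant[idx] <- "nocpg"
        variant[cpg] <- "cpg"
      }
      parts <- list()
      for (v in c("cpg", "nocpg")) {
        sel <- which(planted & variant == v)
        if (length(sel) == 0) next
        res <- plant_sites_at(genome, pwms[[tf]][[v]], slots[sel, ],
                              peak_width,
                              name_prefix = paste(tf, v, sep = "_"))
        genome <- res$genome
        parts[[v]] <- res$peaks |>
          mutate(.slot = sel, variant = v)
      }
      noise_sel <- which(!planted)
      noise <- noise_peaks_at(slots[noise_sel, , drop = FALSE], peak_width,
                              name_prefix = paste0(tf, "_noise")) |>
        mutate(.slot = noise_sel, variant = NA_character_)
      pk <- bind_rows(c(parts, list(noise))) |>
        mutate(tf = tf,
               group_truth = ifelse(hi[.data$.slot], "hi", "low")) |>
        select(-".slot") |>
        arrange(.data$chrom, .data$start)
      peak_list[[tf]] <- pk
    }
    peaks <- bind_rows(peak_list)

    # chromatin-state truth per peak
    state_pool <- function(group) {
      if (group == "hi") {
        c("7_Enhancer", "13_Quiescent")[1 + !exact_one(enhancer_rate_hi)]
      } else {
        c("1_Promoter", "13_Quiescent")[1 + !exact_one(promoter_rate_low)]
      }
    }
    exact_one <- function(p) runif(1) < p
    peaks$state_truth <- vapply(peaks$group_truth, state_pool, character(1))

    # DNase sites: `dhs_methylated` of them in high-methyl background
    # slots, the rest inside CpG islands (low methylation)
    n_bg <- ceiling(n_dhs * dhs_methylated)
    n_isl <- n_dhs - n_bg
    dhs_bg <- tibble(
      chrom = slot_of$dhs$chrom[seq_len(n_bg)],
      start = slot_of$dhs$center[seq_len(n_bg)] - dhs_width / 2,
      end = slot_of$dhs$center[seq_len(n_bg)] + dhs_width / 2,
      methylated_truth = TRUE
    )
    isl_spots <- purrr::pmap_dfr(islands, function(chrom, start, end) {
      starts <- seq(start + 100, end - dhs_width - 100, by = 2 * dhs_width)
      tibble(chrom = chrom, start = starts, end = starts + dhs_width)
    })
    if (nrow(isl_spots) < n_isl) abort("not enough island room for DNase sites")
    dhs_isl <- isl_spots[sort(sample(nrow(isl_spots), n_isl)), ] |>
      mutate(methylated_truth = FALSE)
    dhs <- bind_rows(dhs_bg, dhs_isl) |>
      arrange(.data$chrom, .data$start) |>
      mutate(name = sprintf("dhs_%04d", row_number()),
             score = 1000, strand = ".", signal = 5, pvalue = 4,
             qvalue = 2, summit = dhs_width / 2)

    # genes: random intervals anywhere
    gene_chrom <- sample(names(genome), n_genes, replace = TRUE)
    gene_start <- floor(runif(n_genes, 0, chrom_length - 3000))
    genes <- tibble(
      chrom = gene_chrom, start = gene_start,
      end = gene_start + floor(runif(n_genes, 500, 3000)),
      name = sprintf("gene_%04d", seq_len(n_genes)), strand = "+"
    ) |> arrange(.data$chrom, .data$start)

    list(genome = genome, peaks = peaks, dhs = dhs, genes = genes)
  })
  genome <- out$genome
  peaks <- out$peaks

  # methylation regimes; later rows override earlier ones
  planted <- peaks[peaks$planted, ]
  center <- floor((planted$site_start + planted$site_end) / 2)
  hi_pref <- planted$tf == "preferring" & planted$group_truth == "hi"
  hi_avoid <- planted$tf == "avoiding" & planted$group_truth == "hi"
  regimes <- bind_rows(
    islands |> mutate(level = level$island),
    tibble(chrom = peaks$chrom, start = peaks$start, end = peaks$end,
           level = ifelse(peaks$group_truth == "hi", level$hi, level$low)),
    tibble(chrom = planted$chrom[hi_avoid],
           start = center[hi_avoid] - dip_halfwidth,
           end = center[hi_avoid] + dip_halfwidth,
           level = level$dip),
    tibble(chrom = planted$chrom[hi_pref],
           start = center[hi_pref] - dip_halfwidth,
           end = center[hi_pref] + dip_halfwidth,
           level = level$rise),
    tibble(chrom = planted$chrom,
           start = planted$site_start - 1, end = planted$site_end + 1,
           level = ifelse(hi_pref, level$site_methylated,
                          level$site_unmethylated))
  )

  reps <- make_methylome(genome, regimes,
                         background_level = level$background,
                         depth = depth, seed = base_seed + 3,
                         n_replicates = 2)

  # block segmentation: peak intervals labeled by their state truth,
  # gaps filled with the quiescent label
  segmentation <- purrr::map_dfr(names(genome), function(ch) {
    pk <- peaks[peaks$chrom == ch, ] |> arrange(.data$start)
    len <- nchar(genome[ch])
    bounds <- rbind(
      cbind(pk$start, pk$end),
      cbind(c(0, pk$end), c(pk$start, len))
    )
    lab <- c(pk$state_truth, rep("13_Quiescent", nrow(pk) + 1))
    keep <- bounds[, 1] < bounds[, 2]
    tibble(chrom = ch, start = bounds[keep, 1], end = bounds[keep, 2],
           state = lab[keep]) |> arrange(.data$start)
  })

  # multi-cell occupancy: conserved peaks occupied by 5 of n_cells,
  # unconserved by 3 (with conserved_occupancy = 0.8 and 6 cells the
  # conservation rule needs occupancy >= 5)
  multicell <- list()
  for (i in seq_along(tfs)) {
    tf <- tfs[i]
    pk <- peaks[peaks$tf == tf, ]
    mc <- with_local_seed(base_seed + 10 + i, {
      conserved <- logical(nrow(pk))
      for (g in c("hi", "low")) {
        idx <- which(pk$group_truth == g)
        conserved[idx] <- exact_group_assignment(length(idx),
                                                 conserved_rate[[tf]][[g]])
      }
      k <- ifelse(conserved, 5L, 3L)
      plan <- matrix(0L, nrow(pk), n_cells)
      plan[, 1] <- 1L
      for (p in seq_len(nrow(pk))) {
        plan[p, 1 + sample(n_cells - 1, k[p] - 1L)] <- 1L
      }
      res <- make_multicell(pk, n_cells, plan, jitter = 0,
                            seed = base_seed + 20 + i)
      c(res, list(conserved_truth = conserved))
    })
    multicell[[tf]] <- mc
  }

  list(
    genome = genome, islands = islands,
    methylome_replicates = reps,
    peaks = peaks, pwms = pwms, cpg_column = STUDY_CPG_COLUMN,
    segmentation = segmentation, dhs = out$dhs, genes = out$genes,
    multicell = multicell, regimes = regimes, levels = level,
    params = params
  )
}
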