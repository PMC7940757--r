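# End-to-end orchestration: chains methylome construction, peak
# classification, motif work, site relocation, E-motif reconstruction,
# metaplots, chromatin-state annotation and conservation, writing
# deterministic result tables plus a run manifest.

#' Run the full analysis pipeline on a synthetic study
#'
#' Chains every stage in workflow order: replicate merging and track
#' construction; per-peak methylation and hi/low classification; binding
#' site relocation (with the study's per-group motifs, or freshly
#' discovered ones when `discover = TRUE`); methylation-aware motif
#' reconstruction; flank metaplots; chromatin-state composition; DNase
#' methylated fraction; cross-cell conservation; nearby-gene extraction.
#' All result tables are written to `output_dir` together with a
#' `manifest.json` recording parameters, seed and package version.
#' Reruns with the same arguments produce byte-identical tables.
#'
#' @param output_dir Directory for result tables (created if needed).
#' @param seed Master seed; also used for `study` when it is generated
#'   here.
#' @param study A [simulate_tf_study()] result; generated from `seed`
#'   when omitted.
#' @param thresholds A [pipeline_thresholds()] bundle.
#' @param discover Discover motifs de novo from each peak group instead
#'   of using the study's planted PWMs (slower).
#' @return Invisibly, a list of in-memory results (`track`, `peak_meth`,
#'   `sites`, `motifs`, `profiles`, `composition`, `conservation`,
#'   `dhs_methylated`, `genes_near_unconserved_hi`, `manifest`).
#' @export
run_pipeline <- function(output_dir, seed = 1, study = NULL,
                         thresholds = pipeline_thresholds(),
                         discover = FALSE) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  study <- study %||% simulate_tf_study(seed = seed)

  merged <- merge_replicates(study$methylome_replicates[[1]],
                             study$methylome_replicates[[2]])
  track <- build_track(merged, merge_cpg_strands = TRUE,
                       genome = study$genome)
  bg <- genome_background(study$genome)

  peak_meth <- peak_mean_methylation(study$peaks, track, thresholds)
  readr::write_tsv(
    peak_meth |>
      select("chrom", "start", "end", "name", "tf", "n_cpgs",
             "mean_level", "group"),
    file.path(output_dir, "peak_methylation.tsv"), progress = FALSE
  )

  tfs <- unique(study$peaks$tf)
  sites <- list()
  motifs <- list()
  profiles <- list()
  for (tf in tfs) {
    pm <- peak_meth[peak_meth$tf == tf, ]
    if (discover) {
      group_pwm <- purrr::map(c(hi = "hi", low = "low"), function(g) {
        pk <- pm[pm$group == g, ]
        seqs <- substring(study$genome[pk$chrom], pk$start + 1, pk$end)
        discover_motif(seqs, width_range = c(10, 10), n_seeds = 3,
                       seed = seed, background = bg)
      })
      pwm_hi <- group_pwm$hi
      pwm_low <- group_pwm$low
    } else {
      dominant <- function(g) {
        rates <- study$params$cpg_variant_rate[[tf]]
        v <- if (rates[[g]] >= 0.5) "cpg" else "nocpg"
        study$pwms[[tf]][[v]]
      }
      pwm_hi <- dominant("hi")
      pwm_low <- dominant("low")
    }
    st <- locate_binding_sites(pm, pwm_hi, pwm_low, study$genome,
                               track = track, thresholds = thresholds)
    sites[[tf]] <- st
    write_site_table(st, track, study$genome,
                     file.path(output_dir, paste0("sites_", tf, ".tsv")),
                     e_threshold = thresholds$site_high)
    motifs[[tf]] <- purrr::map(c(hi = "hi", low = "low"), function(g) {
      sel <- st[st$peak_group == g, ]
      if (nrow(sel) == 0) return(NULL)
      mm <- rebuild_methyl_motif(sel, track, study$genome,
                                 thresholds = thresholds)
      write_methyl_motif(mm, file.path(output_dir,
                                       sprintf("emotif_%s_%s.txt", tf, g)))
      mm
    })
    profiles[[tf]] <- purrr::map(c(hi = "hi", low = "low"), function(g) {
      sel <- st[st$peak_group == g, ]
      if (nrow(sel) == 0) return(NULL)
      flank_profile(sel, track, flank = thresholds$flank_bp)
    })
    write_profile_table(purrr::compact(profiles[[tf]]),
                        file.path(output_dir,
                                  paste0("profiles_", tf, ".tsv")))
  }

  annotated <- assign_chromatin_state(peak_meth, study$segmentation)
  composition <- state_composition(
    annotated[annotated$group != "unassigned", ]
  )
  readr::write_tsv(composition,
                   file.path(output_dir, "state_composition.tsv"),
                   progress = FALSE)

  dhs_frac <- dhs_methylated_fraction(study$dhs, track, thresholds)

  conservation <- purrr::imap(study$multicell, function(mc, tf) {
    ref <- peak_meth[peak_meth$tf == tf, ]
    occ <- occupancy(ref, mc$cells[-1], thresholds)
    conserved_fraction_by_group(occ) |> mutate(tf = tf, .before = 1)
  })
  readr::write_tsv(bind_rows(conservation),
                   file.path(output_dir, "conservation.tsv"),
                   progress = FALSE)

  # genes near unconserved hi-methyl binding regions of each TF
  gene_sets <- purrr::imap(study$multicell, function(mc, tf) {
    ref <- occupancy(peak_meth[peak_meth$tf == tf, ], mc$cells[-1],
                     thresholds)
    regions <- ref[ref$group == "hi" & !ref$conserved, ]
    g <- genes_near_regions(regions, study$genes,
                            window = thresholds$gene_window_bp)
    readr::write_lines(g, file.path(output_dir,
                                    sprintf("genes_unconserved_hi_%s.txt",
                                            tf)))
    g
  })

  manifest <- list(
    package = "methylbind",
    version = as.character(utils::packageVersion("methylbind")),
    seed = seed,
    thresholds = unclass(thresholds),
    n_peaks = nrow(study$peaks),
    n_cpg_units = nrow(track),
    discover = discover
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(
    track = track, peak_meth = peak_meth, sites = sites, motifs = motifs,
    profiles = profiles, composition = composition,
    conservation = bind_rows(conservation), dhs_methylated = dhs_frac,
    genes_near_unconserved_hi = gene_sets, manifest = manifest
  ))
}
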