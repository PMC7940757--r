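# methylbind

Do transcription factors bind methylated DNA in vivo? `methylbind`
integrates whole-genome bisulfite sequencing (WGBS) methylomes with TF
ChIP-seq peaks to answer that question the way the field does it at desk
scale: it quantifies CpG methylation inside binding peaks, classifies
peaks as hi-/low-methyl, relocates the actual binding site within each
peak by PWM scanning, reads the methylation state of the site itself,
rebuilds motifs over a methylation-aware alphabet, profiles methylation
around binding sites, annotates binding by chromatin state, and measures
how well methylated binding is conserved across cell types. It is aimed
at computational epigenomicists working with ENCODE-style inputs
(Bismark-derived methylation BED, narrowPeak, chromHMM segmentations,
FASTA, gene BED) — and it ships a fully parameterized synthetic-data
generator so every stage can be validated against known truth.

## The statistics at the core

For a cytosine (or strand-merged CpG unit) covered by reads,

    level = meth_reads / total_reads ∈ [0, 1]

with replicates merged by *summing read counts* per locus. A peak's
methylation is the unweighted mean level of the CpG units inside its
half-open interval; the peak is **hi-methyl** iff that mean > 0.6. For a
PWM *M* of width *L* with background *b*, a placement *s* scores

    score(s) = Σ_j log2( M[s_j, j] / b(s_j) )   (bits)

and the binding site of a peak is the maximum-scoring placement over all
offsets and both strands. A site's methylation is the **maximum** CpG
level it overlaps; sites group as high (> 0.6), low (< 0.2) or middle.
Rebuilt motifs use the alphabet {A, C, G, T, E}, where **E** is a CpG
cytosine whose unit level exceeds 0.6. A reference-cell peak is
**conserved** when more than 80% of the surveyed cell types have an
overlapping peak (5 of 6 cells qualifies; 4 of 6 does not).

## Worked example

The synthetic study plants two TF archetypes — methyl-preferring
(CEBPB-like: CpG-bearing, methylated binding sites) and methyl-avoiding
(CTCF-like: CpG-depleted hi-methyl sites, rarely conserved) — over a
genome with hypomethylated CpG islands and a globally high background:

```r
library(methylbind)
library(dplyr)

study <- simulate_tf_study(seed = 1, n_peaks_per_tf = 120, n_noise_peaks = 15,
                           n_dhs = 80, n_genes = 100,
                           n_chroms = 2, chrom_length = 400000)

methylome <- merge_replicates(study$methylome_replicates[[1]],
                              study$methylome_replicates[[2]])
track <- build_track(methylome, genome = study$genome)

peaks <- peak_mean_methylation(study$peaks, track)
himethyl_fraction(filter(peaks, tf == "preferring"))  # 0.570
himethyl_fraction(filter(peaks, tf == "avoiding"))    # 0.267
```

More than half the CEBPB-like peaks are hi-methyl (the planted fraction
is 0.5718), versus about a quarter for the CTCF-like factor. Relocating
sites in the preferring archetype's peaks and grouping them by their own
methylation:

```r
pm <- filter(peaks, tf == "preferring")
sites <- locate_binding_sites(pm, study$pwms$preferring$cpg,
                              study$pwms$preferring$nocpg,
                              study$genome, track = track)
table(sites$methyl_group)
#>   high    low no_cpg
#>     52     23     60

emotif <- rebuild_methyl_motif(filter(sites, peak_group == "hi"),
                               track, study$genome)
round(methyl_motif_e_fraction(emotif), 2)
#>  [1] 0.50 1.00 0.33 0.92 0.00 0.00 1.00 0.00   NA 0.12
```

Column 4 is the planted CpG cytosine of the motif: 92% of its cytosine
observations in hi-methyl peaks are methylated (`E`). Conservation across
the six simulated cell types separates the avoiding archetype's
methylation strata:

```r
conserved_fraction_by_group(
  occupancy(filter(peaks, tf == "avoiding"),
            study$multicell$avoiding$cells[-1]))
#> # A tibble: 2 × 3
#>   group     n conserved_fraction
#> 1 hi       36              0.167
#> 2 low      99              0.657
```

Hi-methyl CTCF-like binding is rarely conserved (16.7%) while low-methyl
binding usually is (65.7%) — exactly the planted contrast. `autoplot()`
methods and `plot_flank_profiles()` / `plot_state_composition()` render
the corresponding figures; `run_pipeline(out_dir, seed)` chains every
stage and writes deterministic result tables plus a manifest.

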