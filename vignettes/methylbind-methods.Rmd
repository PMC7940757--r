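---
title: "Methods: integrating WGBS methylomes with TF binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating WGBS methylomes with TF binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylbind)
```

## The problem

Transcription factors (TFs) were long assumed to avoid methylated DNA, yet
in vivo ChIP-seq peaks of several TFs — CEBPB, CTCF, MAFK among them — fall
in regions of high CpG methylation, most strikingly in embryonic stem
cells, whose genome is globally hypermethylated relative to somatic lines.
`methylbind` implements the full desk analysis of this phenomenon:
superimpose a whole-genome bisulfite sequencing (WGBS) methylome on a TF's
narrowPeak intervals, classify peaks by methylation, relocate the actual
binding site inside each peak with a position weight matrix (PWM), read
the methylation state of the site itself, rebuild the motif over an
extended alphabet where `E` marks a methylated CpG cytosine, profile
methylation around site centers, annotate binding by chromatin state, and
ask whether methylated binding is conserved across cell types.

## The model, stage by stage

**Methylome.** A cytosine's methylation level is the ratio of methylated
to total reads covering it; replicates are merged by summing read counts
per locus, never by averaging percentages (which is why the reader only
accepts count dialects). By default the two symmetric cytosines of a CpG
dinucleotide are merged into one *CpG unit* at the position of the
+ strand C — methylation at CpGs is overwhelmingly symmetric, and
per-strand counting would double-count every dinucleotide. Whether the
original analyses merged strands is not documented; both behaviours are
supported (`merge_cpg_strands`), merged is the default. Units below
`min_coverage` (default 1 read) have an undefined level and are invisible
to every statistic: a ratio over zero reads carries no information.
Non-CpG cytosines (CHG/CHH) are dropped on track construction, with a
logged count, because every downstream quantity is defined on CpGs.

**Peak methylation (hi/low classification).** A peak's level is the
unweighted mean of the defined CpG-unit levels inside its half-open
interval. The cutoff is the classical 0.6: a peak is *hi-methyl* iff its
mean is strictly greater than 0.6. Peaks containing no covered CpG are
*unassigned* and excluded from both numerator and denominator of the
hi-methyl fraction — a methylation statement about a CpG-free interval is
vacuous, and including such peaks as "low" would deflate every fraction
by the TF's CpG avoidance rather than its methylation preference.

**Motifs and site relocation.** Motif columns are estimated as
`(count + pseudocount) / (n + 4 * pseudocount)` (pseudocount 0.5 per
cell) and scored as log2 odds against a mononucleotide background
(genome-derived when a genome is supplied, uniform otherwise). The
binding site of a peak is the placement — over all offsets and both
strands — with the maximum match score; ties break to the smaller offset,
then the + strand, so scans are deterministic. Placements covering `N`
are skipped rather than penalized. Because HOMER-style discovery is
external tooling, the package ships its own self-contained stage:
overrepresented k-mers against a per-sequence letter-shuffled background
seed sharp candidate PWMs, which are refined ZOOPS-style (one best site
per sequence, re-estimate, repeat until the matrix moves less than 1e-4
or 100 iterations); the candidate whose assigned sites score highest in
total log-odds wins. Absolute score scales of other tools are not
reproduced — only the argmax behaviour that drives relocation is treated
as meaningful.

**Site methylation and the E alphabet.** A site may span several CpGs;
its level is the *maximum* CpG-unit level on the site. Sites group as
high (> 0.6), low (< 0.2), middle (otherwise), or `no_cpg`. For the
methylation-aware motif, each site is read 5'→3' (minus-strand sites are
reverse-complemented) and every cytosine in CpG context whose unit level
exceeds `e_threshold` is recorded as `E`. The E cutoff is not documented
anywhere; it defaults to the site-grouping "high" cutoff (0.6) so that an
`E` in a motif and a "high" site mean the same thing. Collapsing `E` back
into `C` reproduces the plain counts exactly — an invariant the test
suite enforces. A minus-strand site reads its methylation from the
strand-merged unit (symmetric-methylation assumption); a per-strand mode
exists when merging is off, and only CpG-context cytosines can ever
become `E`.

**Metaplots.** Profiles aggregate CpG-unit levels within ±1600 bp of the
*site center* (the relocated site's midpoint, not the peak summit — the
biology anchors on the bound sequence). Whether "1600 bp upstream and
downstream" counts from the site edge or center is ambiguous; center was
chosen and is configurable. The bin width (25 bp, 64 bins per side) is
undocumented in the source analyses and is a display resolution choice.
Each CpG contributes once per overlapping site window; overlapping
windows deliberately double-count shared CpGs, as metaplots conventionally
do. Contrasts between group profiles carry bootstrap bands from
resampling sites (200 resamples, seeded).

**Chromatin states and conservation.** A peak takes the state label with
the maximum total overlap (ties: lexicographically smallest label;
`Unannotated` if nothing overlaps); majority assignment was chosen over
multi-label because composition fractions must sum to 1 per group.
Conservation counts, for each reference-cell peak, the surveyed cell
types (reference included) whose peak set overlaps it by at least 1 bp;
the peak is conserved when that occupancy fraction strictly exceeds 0.8 —
with six cells, 5/6 ≈ 0.833 is conserved and 4/6 is not. The "more than
80% of occupied cells" phrase is ambiguous; this package reads it as
occupancy over all surveyed cells and exposes the cutoff
(`conserved_occupancy`). No reciprocal-overlap fraction is required.
Genes near a region set are those overlapping the regions extended by
±1000 bp, deduplicated; the gene lists feed external enrichment tools and
no GO computation is attempted here. (The description of the low-methyl
gene extraction contains an apparent typo — "methylation level = 0.6" —
which this package resolves as the complement of the hi-methyl stratum.)

## What the synthetic data emulates

`simulate_tf_study()` generates the study the pipeline is validated on,
and its defaults *are* the study conditions:

* genome: 3 × 900 kb at GC 0.40 with CpG islands (8 per chromosome,
  2 kb, 8-fold CpG enrichment); islands are hypomethylated (0.05) while
  the background sits at 0.8 — an embryonic-stem-cell-like globally high
  methylome;
* WGBS: every CpG cytosine draws `Poisson(15)` reads split into two
  half-depth replicates (≈30× per merged unit), methylated reads
  binomially at the local regime mean — the simplest model matching WGBS
  marginals; bisulfite non-conversion is available (`error_rate`) but
  defaults to 0;
* two TF archetypes, 500 motif-bearing 400-bp peaks plus 60 noise peaks
  each, on slots 2 kb apart so one peak's regimes never leak into a
  neighbour's metaplot window. Peaks are centered on their planted site
  ± up to 25% of the width, so relocation is genuinely exercised.
  The *methyl-preferring* (CEBPB-like) archetype has hi-fraction 0.5718
  and CpG-on-site rates 59.2% (hi) vs 35.1% (low), with hi-site CpGs
  methylated (0.95); the *methyl-avoiding* (CTCF-like) archetype has
  hi-fraction 0.30, CpG-on-site rates 25.3% vs 48.7%, all site CpGs
  unmethylated, and a planted demethylation dip (±50 bp at 0.2) around
  hi-group sites, against a planted rise for the preferring archetype.
  These rates are the published per-TF percentages for CEBPB and CTCF in
  H1-hESC, used here as planted truth;
* conservation: six cell types, conserved peaks occupied by 5 of 6,
  unconserved by 3, at planted conserved rates 41.9%/36.9% (preferring
  hi/low) and 18.7%/67.2% (avoiding hi/low); zero jitter by default so
  downstream fractions must match the plan *exactly*;
* chromatin: hi peaks sit in enhancer segments at rate 0.8, low peaks in
  promoters at 0.5, remainder quiescent; half the DNase sites lie in
  methylated background, half inside islands.

What it does **not** emulate: read-level ChIP-seq noise, peak-width and
signal heterogeneity, chromatin accessibility, non-CpG methylation,
sequence context beyond mononucleotide composition, and real motif
degeneracy beyond a single-mismatch variant pair. Passing the recovery
suite therefore shows the *pipeline arithmetic* is right — thresholds,
coordinates, strand handling, conservation counting — not that the
biological conclusions would survive on arbitrary real data.

## Numerical choices and degenerate inputs

* All coordinates are 0-based half-open after parsing (BED convention);
  abutting intervals do not overlap. Chromosome names match exactly — no
  `chr` prefix normalization, since silent renaming hides data errors.
* All boundary comparisons are strict and tested: peak 0.6 → low; site
  0.6 → middle, 0.2 → middle; occupancy 5/6 → conserved.
* Interval queries run by binary search over the sorted track;
  equivalence with a linear scan is asserted on hundreds of random
  instances, as is exact agreement of scanning, state assignment,
  occupancy and gene proximity with exhaustive oracles.
* Degenerate cases are kept explicit: zero-coverage units exist but have
  undefined levels; CpG-free peaks/sites are `unassigned`/`no_cpg`;
  all-N peaks are skipped with a logged count; dataset peak-count ties
  keep the lexicographically smallest identifier and say so.
* Every stochastic step (generators, discovery, bootstrap) takes an
  explicit seed and restores the caller's RNG state; reruns are
  byte-identical, which the suite checks file by file.

## Problem sizes

The validation suite runs the full-size study (two archetypes × 560
peaks, ~108k CpG units at ~30×) once and shares it across checks;
brute-force oracle comparisons use ≥500 random small instances per
operation; discovery recovery uses 200 sequences of 200 bp with one
planted 8-bp occurrence each. These sizes make the whole suite complete
in a few minutes on a single core while leaving every estimate's
sampling error far smaller than the margins being asserted.

## Limitations

Known limitations worth keeping in mind: the discovery stage is a
compact stand-in, not a reimplementation of HOMER (scores are not
comparable across tools); site methylation uses the maximum-CpG rule,
which is deliberately insensitive to partially methylated multi-CpG
sites; conservation uses 1-bp overlap, so fragmented peak calls in other
cell types can inflate occupancy; and the package performs no
genome-scale indexing, so it targets desk-scale analyses (up to a few
million CpG units) rather than full mammalian WGBS compendia in one
session.
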