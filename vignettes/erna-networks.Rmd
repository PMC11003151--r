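---
title: "From H3K27ac peaks to eRNA-mediated regulatory networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From H3K27ac peaks to eRNA-mediated regulatory networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ernanet)
```

## The analysis in one paragraph

Enhancer RNAs (eRNAs) are short, unstable transcripts produced from active
enhancers; their expression tracks enhancer activity closely enough that
strand-specific RNA-seq over H3K27ac-marked regions can be used to build an
eRNA expression atlas. `ernanet` implements the complete chain of inference
from raw per-region counts to a refined regulatory network: enhancers are
defined from replicate-consistent H3K27ac peaks away from transcription
start sites; each enhancer contributes one candidate eRNA quantified over
its center ± 3 kb (minus annotated transcription units ± 1 kb); detectable
and tissue-specific eRNAs are called; enrichment of tissue-specific eRNAs
in super-enhancers, near tissue-specific genes, and at GWAS/QTL loci is
tested; and a directed network TF → eRNA → target gene is assembled from
motif evidence plus co-expression, constrained by genomic distance and TAD
co-membership, filtered by GWAS proximity, and finally refined to eRNAs
harbouring SNPs with demonstrated allelic enhancer activity in a
STARR-seq-style reporter assay.

## Stage-by-stage model and parameter choices

### Enhancer catalog

Replicate consistency is enforced by intersecting the two replicate peak
sets and merging the result (`intersect_then_merge`). Merging joins
intervals only when they overlap by at least one base; abutting intervals
stay separate. This matches the default semantics of interval-merge tools
operating on half-open coordinates, and the choice only matters on
measure-zero boundary cases. Peaks whose merged form overlaps a TSS ± 1 kb
are removed. Coordinates are 0-based half-open everywhere; GTF input is
converted on read; the midpoint of an even-length region is the floor of
`(start + end) / 2`, and windows are clipped to chromosome ends rather than
rejected so edge regions survive.

Enhancer activity is the IP/INPUT reads-per-million ratio over the center
± 1 kb. Super-enhancers are called with a deliberately simplified
rank-curve procedure: stitch within 12.5 kb, rank stitched regions by
ascending total signal (IP − INPUT rpm floored at zero), min–max scale
both axes, estimate the slope by centered finite differences, and flag
regions strictly above the first rank whose slope exceeds 1. The original
tool's TSS-aware stitching exceptions and gene mapping are not reproduced
because only super-enhancer membership is consumed downstream; the
simplification is deterministic and unit-testable (uniform signal yields no
calls; calls are invariant to rescaling the signal vector).

### eRNA definition, quantification and direction

Each enhancer's transcription region is its center ± 3 kb; quantification
windows subtract all gene and ncRNA bodies ± 1 kb, and records with no
remaining window are dropped. RPM sums plus- and minus-strand reads over
the windows and normalizes by the sample's library size. An eRNA is
detectable in a tissue when the mean RPM over that tissue's two biological
replicates is ≥ 1 (boundary inclusive). Direction uses the plus-strand
read fraction pooled over a breed–tissue group's replicates: bidirectional
within [0.05, 0.95] (both bounds inclusive — treating the stated 5–95 %
band as inclusive avoids a measure-zero ambiguity and is tested at the
boundary), unidirectional otherwise, with a record's single label taken
from the group where it is detectable at the highest mean RPM. GC content
divides G+C by the full window length, counting N in the denominator.
Overlapping regions from adjacent enhancers are kept independently: the
unit of analysis is one eRNA per enhancer.

### Tissue specificity

The specificity index of a per-tissue expression vector is
`sum(1 - x_i) / (N - 1)` with `x_i` normalized by the per-replicate maximum
across tissues. Max-normalization is what bounds the index in [0, 1] and
makes the 0.8 threshold meaningful; without it the printed formula is
unbounded. The index is computed separately per replicate; a feature is
tissue-specific in a breed when the index strictly exceeds 0.8 in both
replicates *and* both replicates agree on the maximal tissue — agreement is
the weakest rule that yields a single unambiguous tissue assignment. Gene
detectability mirrors the eRNA rule (mean TPM ≥ 1).

### Enrichment machinery

Super-enhancer and gene-proximity enrichment use the exact hypergeometric
upper tail. Genomic permutation tests re-place every query element
uniformly: a chromosome is sampled proportional to its length among
chromosomes the element fits on, and the start is uniform on
`[0, chrom_len − len]`, preserving element lengths with no clipping and no
exclusion of assembly gaps (the null is stated fully so it is
reproducible). The Monte-Carlo p-value is `(1 + #{null ≥ obs}) / (R + 1)`
with R = 1000 — it can never return zero. GWAS hits are expanded ± 20 kb
as a proxy for linkage disequilibrium before overlap; QTL intervals are
used as-is because they are already long. Overlap is counted at the element
level (an eRNA overlapping three hits counts once). FDR control is
Benjamini–Hochberg throughout.

### Motif scanning

PWMs are read from HOMER-format text (probabilities floored at 1e-3 and
renormalized); scores are natural-log odds against a uniform 0.25
background, evaluated at every offset on both strands, with any window
containing N unscoreable. Thresholds are interpreted in natural-log units
and the synthetic motif files are generated with the same convention, so
the pipeline is self-consistent; reverse-strand hits are reported at the
forward-strand offset of the site's leftmost base. Known-motif enrichment
replaces the original tool's statistic with a transparent one: count
sequences with ≥ 1 hit in foreground and background, one-sided Fisher
test, BH correction, significance at Q < 0.01. This preserves the
figure-level claim (a ranking of enriched TFs) without reimplementing an
external heuristic.

### Network assembly

TF → eRNA edges require a motif hit in the eRNA's enhancer sequence, the
TF expressed in the eRNA's tissue (mean TPM ≥ 1 over the tissue's samples,
mirroring the detectability rule), Spearman rho > 0.5 (strict) and
BH q < 0.05 across the 20 samples. eRNA → gene edges require rho > 0.3,
q < 0.05, anchor distance ≤ 1 Mb (gene anchor = TSS, eRNA anchor =
enhancer center) and both anchors inside the same TAD (nested TADs resolve
to the smallest containing interval). Correlation p-values use the t
approximation on n − 2 degrees of freedom; ties get average ranks;
constant vectors are dropped with a warning. The multiple-testing family
is per task: all motif-supported TF–eRNA pairs form one batch, all
within-1-Mb eRNA–gene pairs another — the most defensible reading of a
single global "FDR correction" statement. The GWAS proximity filter is
applied to eRNA nodes after edge inference; because it only removes nodes
and incident edges, the final network is the same as filtering first.
STARR refinement drops eRNA nodes whose region contains no regulatory SNP
(allelic Fisher q < 0.05 at coverage > 20, strict), then removes orphaned
TF and gene nodes; it never adds anything. An independent validator
re-derives every edge condition from the raw inputs with separate
primitives (`stats::cor.test`, `stats::p.adjust`, fresh motif scans,
direct arithmetic) and must report zero violations.

### STARR-seq allelic testing

Candidate SNPs must fall inside an eRNA region, differ in east/west
population minor-allele frequency by more than 0.3, and have mixed-pool
MAF above 0.05 (both strict). The four output sequencing libraries
collapse pairwise into two biological replicates, whose per-SNP totals are
checked for correlation (warning below r = 0.8) before summing. The effect
size is the output alt/ref ratio over the input alt/ref ratio; coverage
must strictly exceed 20 in both libraries; significance is the two-tailed
Fisher test on `[[input_ref, input_alt], [output_ref, output_alt]]`,
defined as the sum of probabilities of all same-margin tables no more
probable than the observed one; regulatory calls use BH q < 0.05 — the
published analysis reports a count of regulatory SNPs without naming its
cutoff, and FDR 0.05 matches the conventions used everywhere else in the
pipeline.

## The synthetic data generator

`simulate_bundle()` produces every input the pipeline consumes, with
planted ground truth, so all claims above are testable without downloads.
The study design mirrors the real one: 2 breeds × 5 tissues × 2 replicates
(20 expression samples), H3K27ac peaks for the four breed × assayed-tissue
conditions with ≤ 200 bp replicate jitter, a two-chromosome 5.6 Mb genome
partitioned into 80 kb TADs, ~260 enhancers, 50 planted TF → eRNA → gene
chains (25 muscle, 25 fat), 60 additional tissue-specific eRNAs and 40
tissue-specific genes, and 100 assayed SNPs of which 40 carry a 3× allelic
skew at ~500× depth.

Expression is modelled as a per-feature baseline level (log-normal across
features, meanlog 1, sdlog 0.7) times per-sample variation (sdlog 0.35 on
the log scale) that carries a per-chain latent factor. The latent loading
is calibrated through the bivariate-normal relation
`rho = 2 sin(pi * rho_S / 6)` so chain members reach a pairwise Spearman
near the 0.9 target; because Spearman is rank-based, the variance scales
do not affect it. Splitting the variance this way keeps between-tissue
spread small enough that every planted tissue-specific feature (20-fold in
one tissue of both breeds) exceeds the 0.8 specificity threshold in both
replicates, while decoys — pure per-sample noise — never do, and decoy
pairs show null Spearman at 20 independent samples. Totals are Poisson at
a 2 × 10^7 library size; strand assignment is binomial with a plus-strand
probability drawn from Beta(8, 1) for the unidirectional-designated
quarter of eRNAs and Beta(5, 5) otherwise. Chain TFs get one exact-match
PWM each, embedded only in their chain's enhancer; the generator scans all
enhancer sequences after embedding and destroys chance matches by point
mutation, so motif hits identify chains exactly. Each chain occupies its
own TAD with its target gene (TF genes live in separate TADs), which is
what lets the network stage separate planted from spurious correlations
structurally. GWAS hits are planted inside every chain eRNA and
rejection-sampled background hits stay outside all eRNA ± 20 kb windows.
Deliberately degenerate records — an all-zero eRNA, an all-zero gene row, a
zero-INPUT enhancer, a low-coverage SNP and a zero-cell SNP — exercise the
error paths.

What the generator does not emulate: read-level artefacts (mapping bias,
duplicates), realistic repeat families, GC-dependent background for motif
scanning, inter-tissue correlation structure of real transcriptomes, and
linkage disequilibrium beyond the fixed 20 kb window. Passing tests
therefore demonstrate that the inference machinery recovers planted
structure under the stated statistical model at desk scale, not that the
biological conclusions of any particular dataset are reproduced.

## Numerical and scale choices

Problem sizes are chosen so the complete test suite and the acceptance
script run on a single CPU in minutes: a 5.6 Mb genome, 260 enhancers, 50
chains, R = 1000 permutations. The permutation-calibration check uses 300
query elements against features covering roughly a quarter of a 6 Mb
two-chromosome genome, which keeps the discrete overlap count dense enough
(point mass ≈ 0.013 near the 95th percentile) that the achievable
significance levels bracket 0.05 tightly. Exhaustive statistical oracles
(subset enumeration for the hypergeometric test up to universe size 12,
factorial tail enumeration for every 2×2 table with margins ≤ 40) are run
in full. All randomized stages take explicit seeds; the pipeline derives
stage seeds deterministically from one run seed, and two runs with the same
bundle and seed produce byte-identical output files.

## Known limitations

* The replicate-consistency reading of the peak-merge step (intersection,
  then merge) is one of two defensible interpretations; union-based
  consistency would yield larger catalogs. The intersection reading
  follows the order of the cited commands.
* Expression-based counting rules (fragment vs read, probe merging) of the
  original quantification tool are not recoverable; the documented rule —
  counts supplied per quantification window, summed across windows — stands
  in.
* The super-enhancer caller is a simplified re-implementation; absolute
  super-enhancer counts from the original tool are not comparable,
  only the ranking behaviour.
* Correlation p-values use the t approximation even though n = 20 samples
  come from a structured design (breeds × tissues × replicates);
  planted-versus-decoy separation absorbs the resulting mild
  anti-conservativeness, and the acceptance tests measure recovery, not
  nominal error rates, at this stage.
* With 50 strong planted chains in one BH batch, an occasional weak chain
  pair can fail the q < 0.05 gate; recovery targets are therefore stated as
  recall ≥ 0.9 rather than exact.
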