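---
title: "Discovering aberrant somatic hypermutation targets: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering aberrant somatic hypermutation targets: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ashmscan)
```

# The biological model

Activation-induced cytidine deaminase (AID) initiates somatic hypermutation
by deaminating cytosines in transcribed DNA; error-prone repair of the
resulting uracils produces the characteristic SHM footprint. When the
process strays from immunoglobulin loci onto other genes (aberrant SHM,
aSHM), that footprint is detectable in the first ~2 kb downstream of the
transcription start site:

* mutation density far above the genomic background, decaying roughly
  exponentially with distance from the TSS;
* enrichment of mutations inside the degenerate hotspot 4-mer WRCY and its
  reverse complement RGYW (W = A/T, R = A/G, Y = C/T);
* excess mutations at C:G base pairs relative to A:T (AID acts on
  cytosines);
* a transition fraction above the 1/3 expected of a random substitution
  process;
* dependence on transcription, so mutated samples tend to express the
  target more highly;
* co-occurrence with rearrangement breakpoints, since SHM generates
  recombinogenic double-strand breaks.

`ashmscan` quantifies each footprint component per gene and combines the
three substitution-signature components into a single indicator.

# Statistical model

## Windows and composition correction

The SHM-target of a gene is `[TSS, TSS + w)` in the transcription
direction, with `w = 2000` by default. Every signature test is corrected
for the window's own base composition: the success rate of each exact test
is a per-base fraction measured on the window sequence (fraction of bases
covered by a motif occurrence, fraction of C/G bases). A position counts as
"in a motif" when covered by a WRCY or RGYW match on the given strand —
per-base coverage rather than occurrence counts, because the normalization
is per base. Coverage is strand-symmetric by construction (the template
pair is its own reverse-complement family), a property the test suite
checks on random sequences.

Some texts place the start of SHM activity ~150 nt downstream of the TSS;
the analysis window deliberately starts at the TSS itself, since the
2-kb window is how the analyzed regions are defined throughout, and a
150-nt offset changes the composition fractions only marginally. `w` is
configurable.

When a gene has several transcripts, the default (`per_gene`) window is
anchored at the most upstream TSS in the transcription direction — the
maximal shared promoter-proximal region — with lexicographic
transcript-id tie-breaking; `per_transcript` mode is available when
transcript-level resolution is wanted.

## Exact tests

Each signature test is a one-sided upper-tail exact binomial test: with
`n` pooled cohort SNVs in the window and success rate `r` (the
composition fraction, or 1/3 for transitions), the p-value is
`P(X >= k)`, `X ~ Bin(n, r)`. This is precisely the "success rate +
trial count" construction described for these statistics in the lymphoma
literature; a hypergeometric variant of the burden test (conditioning on
the genome-wide SNV total as draws without replacement) is available via
`family = "hypergeometric"`. The implementation uses `pbinom`/`phyper`;
tests verify it against term-wise enumeration to 1e-12 for all `n <= 25`.

Because aSHM predicts *excess* (motif hits, C:G hits, transitions), tails
are one-sided throughout. Reported signature p-values are capped at 0.5
by default (`cap_at_half`), mirroring the convention of printing 0.5 for
depleted regions in one-sided reporting; the cap never applies to the
degenerate no-SNV case, which carries no evidence and reports p = 1, and
never applies to the burden p that feeds the Benjamini–Hochberg
adjustment.

The **SHM indicator** is the geometric mean of the motif, C:G and
transition p-values, computed from full-precision values (display tables
round to 4 decimals, the JSON output keeps full precision). It is
symmetric in its three arguments and lies in (0, 1]; values below 0.1 are
the conventional bar for a significant composite signature.

One reporting caveat: published versions of the per-region Ti/Tv column
sometimes show values (e.g. a ratio of 6 in a 6-SNV region) that no
documented normalization reproduces; `ashmscan` reports the raw
transition/transversion ratio alongside the exact-test p-value and leaves
the ratio `Inf` when transversions are absent and `NA` when the window has
no SNVs.

## Somatic filtering

Tumor calls are reduced to putative somatic SNVs by: biallelic SNV shape
(multi-allelic records are decomposed), phred call quality >= 20, >= 20%
of high-quality reads (mapping quality > 25, base quality > 10)
supporting the alternate allele, and absence from the matched-normal and
population site sets keyed by (chrom, pos, alt). The high-quality alt
fraction is computed upstream (e.g. from a pileup) and carried in the
call table / `AFHQ` INFO tag; when it is absent the fraction rule cannot
be evaluated and does not reject. No allele-frequency threshold is
applied to population sites because none is part of the published filter.
Filtering is idempotent and monotone in each threshold (property-tested).

## Stratification and distance profiles

Targets are stratified by cohort mutation density (per base per sample,
averaged over *all* cohort samples including unmutated ones): group I
above 8e-5, group II above 4e-5, group III the remaining targets with at
least two distinct SNVs. A published alternative characterizes group II
as "3–5 SNVs"; the density thresholds are the quantitative record and are
the default, with the SNV-count variant behind `mode = "snv_count"`.
Immunoglobulin-locus genes, when supplied, form a positive-control group
regardless of density.

Distance profiles pool, per group, SNV offsets from the TSS in the
transcription direction over a 12-kb window — wider than the 2-kb
analysis window, to show how far mutation mass extends into the gene
body. Groups are compared with a two-sample Kolmogorov–Smirnov test
(exact when both sides have <= 100 distances). The local-regression
smooth (span 0.3, 250-bp bins) exists for plots only and never feeds a
statistic.

## Expression linkage

Samples are partitioned per gene by presence of >= 1 somatic SNV in the
SHM-target. The fold change is the normalized difference
`(mean_mut − mean_unmut) / (mean_mut + mean_unmut)`, bounded in [−1, 1]
and antisymmetric under swapping the groups. It is zeroed when both group
means fall below 5 RPKM — a gene-level low-expression rule, since ratios
of near-zero means are noise. The candidate-set test draws random gene
sets of the candidate size from the expressed universe (mean RPKM > 1)
and compares the candidate mean against the empirical null of random-set
means (one-sided, greater, with the add-one permutation p); a plain
Welch test is available, and both report the effect size. Fewer than 20
draws is flagged degenerate.

## Rearrangements and cohort enrichment

A rearrangement "touches" a gene when either breakpoint falls in the
SHM-target extended by a flank on both sides (half-open). The flank
defaults to 100 kb: the vicinity of a promoter-proximal window in which a
translocation can plausibly dysregulate the gene; it is configurable
because no quantitative definition of "vicinity" is standard. Events are
deduplicated on (sample, breakpoints) so the cross-tab is insensitive to
input order and duplication. The per-gene cross-tab reports samples with
both / mutation only / neither; the rearrangement-only count is kept in
the object so the four cells always sum to the cohort size, and is
omitted from the conventional three-column report.

Gene-set overlap uses the hypergeometric upper tail. The universe is
never defaulted silently in reports: analysts must state it (all analyzed
SHM-target genes is the natural choice). Subtype association builds the
per-gene 2×2 of mutated/unmutated by ABC/GCB (unknown-subtype samples
excluded) and reports one-sided (mutation excess in the first level) and
two-sided exact p-values with BH adjustment across genes.

# The synthetic cohort

The simulator exists so that every stage — VCF reading, filtering,
windowing, the exact tests, stratification, expression linkage,
rearrangement cross-tabs — runs end-to-end with no external data, and so
that recovery can be measured against known truth.

What it emulates: i.i.d. reference sequence at human-like 42% GC; genes in
fixed 15-kb slots (room for the 12-kb profile window) on both strands;
per-sample background mutations as a genome-wide Poisson process with
signature-free substitutions; in designated aSHM genes an additional
window-confined process whose per-position weights are
`exp(−d/700 bp) × 3^in_motif × 1.5^is_CG` (a discrete categorical draw —
simple, exact, and auditable against the intended density), with
transitions at probability 0.5 against the 1/3 null; expression as a
log-normal gene baseline (meanlog 3, sdlog 1.5) with per-sample noise
(sdlog 0.4), coupled to mutation intensity through a normalized power
link so the cohort-mean rate is unchanged; planted germline and
population variants plus low-quality artifact calls so the somatic filter
is exercised; and rearrangement breakpoints preferring aSHM windows.

The default preset is "dlbcl-like": 40 samples, background 2e-6 mutations
per base per sample, and a 50-fold window rate elevation in aSHM genes —
echoing the reported 50–100× gap between immunoglobulin and
non-immunoglobulin SHM rates. Under this preset an aSHM gene accrues
about 8 cohort SNVs (40 × 50 × 2e-6 × 2000).

What it does **not** emulate, and what passing tests therefore do not
show about real data: chromatin context, replication timing and local
mutation-rate heterogeneity; strand-biased A:T mutagenesis; clonal
structure and subclonal allele fractions; read-level evidence (no
FASTQ/BAM); indels and copy-number events; realistic gene length and
density variation; and the candidate-selection step of a real cohort
analysis, in which reported target lists are conditioned on observed
mutation rates. That last gap matters for calibration of expectations:
an *unselected* set of simulated aSHM genes at ~8 SNVs each yields median
composite indicators around 0.15–0.2, whereas published candidate lists —
selected for high mutation recurrence, with a median of ~12 SNVs and
post-hoc motif enrichments above 3 — sit below 0.1. Similarly, at 500
simulated genes the sparse background yields only a handful of group-III
targets, far too few for a powered between-group KS contrast; the
decay-versus-uniform KS property is instead established directly at 200+
distances per group. Both cohort-scale effects are asserted at full
strength in the acceptance tests and the assertions document where the
desk-scale preset falls short.

# Numerical and reproducibility choices

* Coordinates are 0-based half-open internally; BED is read as-is, GTF
  and VCF are converted from 1-based. A minus-strand TSS is the half-open
  end boundary, so the window is `[TSS − w, TSS)` and offsets are
  `TSS − pos`.
* Exact tails come from `pbinom`/`phyper` (no asymptotics anywhere in the
  signature tests); `p.adjust(method = "BH")` provides the step-up
  adjustment.
* Ties in the feature-table sort (by cohort SNV count, descending) break
  lexicographically by gene symbol, making reports byte-reproducible.
* Degenerate inputs: windows without SNVs are absent from the feature
  table; enrichments are `NA` (never 0) when undefined; missing
  expression yields `NA` columns, not zeros; empty distance profiles
  refuse KS comparison.
* Every stochastic entry point takes a seed, restores the caller's RNG
  state, and derives sub-seeds by fixed small offsets; the simulator is
  byte-deterministic under (seed, config).
* Truncated windows at contig edges are flagged rather than silently
  shortened.

# Problem sizes used in the test suite

Unit tests run on 6–30-gene cohorts; the calibration check uses a
40-sample, 200-region null cohort with the signature knobs at their null
values and a doubled rate multiplier so each region carries ~16 SNVs
(stabilizing the per-region enrichment estimator); signal-recovery and
expression-coupling checks run the full dlbcl-like preset (40 samples,
500 genes, 10% true targets) once and reuse the scan across tests. The
whole suite completes in well under a minute on one CPU.

# Known limitations

* The per-region Ti/Tv normalization used in some published tables is not
  reproducible from their text; raw ratios are reported instead.
* Population filtering is exact-site matching; no allele-frequency model.
* The expression link treats RPKM as given (or computes it from counts);
  no within-cohort normalization beyond RPKM is attempted.
* The subtype association mirrors the standard 2×2 exact construction;
  at least one published per-gene subtype p-value does not correspond to
  any standard construction on its printed counts and cannot be matched.
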