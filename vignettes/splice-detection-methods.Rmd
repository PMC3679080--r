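---
title: "Detecting condition-regulated alternative splicing from tiling arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting condition-regulated alternative splicing from tiling arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilesplice)
```

## The problem

Whole-genome tiling arrays interrogate transcription with short (25-mer)
probes spaced at a regular genomic interval (~35 bp), irrespective of
annotation. Because introns are tiled just like exons, an intron that is
retained in the mature transcript under one condition but spliced out under
another leaves a direct footprint: its probes light up in one condition
only, while the flanking exon probes stay unchanged. `tilesplice`
implements an analysis pipeline that exploits this to call
condition-regulated alternative splicing — primarily intron retention —
from two-condition tiling-array experiments with replicate arrays, plus the
companion statistics used to compare such event lists across experiments.

## Gene models and probe mapping

Each gene is reduced to one *base transcript*, the annotated isoform with
the most exons, which maximises the number of annotated splice junctions
available for testing. Ties in exon count are broken by the
lexicographically smallest transcript id; the choice is deterministic.
The base transcript is segmented into exons and the introns between them
(zero-length gaps between abutting exons yield no intron), and segments are
numbered 5'→3' in transcript orientation, so intron numbers for
minus-strand genes run against genomic order. Coordinates are 1-based
inclusive throughout, the GFF3 and IRanges convention.

A probe is retained only when its interval lies fully inside exactly one
segment of exactly one gene. Probes crossing an exon/intron boundary are
uninformative for splicing (they mix the two signals) and are excluded, as
are probes occurring at multiple genomic positions, probes contained in
segments of two overlapping genes (a conservative choice; one could argue
for keeping a primary assignment), control probes, and intergenic probes.
Mapping is purely coordinate-based: probe-to-genome alignment is upstream
of this package, which consumes a probe coordinate table. By default
mapping ignores strand, appropriate when hybridisation targets are
double-stranded cDNA; `stranded = TRUE` restricts probes to same-strand
genes for strand-specific protocols.

## Preprocessing

The fixed order is background correction → quantile normalization → log2.
Background correction uses the normal+exponential convolution model (the
RMA background model): observed = Normal(µ, σ²) noise + Exp(mean θ) signal,
with each intensity replaced by E[signal | observed]. Parameters are
estimated per array by the method of moments (θ³ = half the third central
moment), a closed-form, deterministic estimator; the conditional
expectation itself is evaluated with `limma::normexp.signal()`. The default
is `background = "none"`: the synthetic generator emits background-free
intensities, and real raw scanner data should opt in with `"normexp"`.

Quantile normalization gives every array the same distribution (the
across-array mean of sorted columns), preserving within-array ranks; tied
values receive the mean of the reference quantiles they span, which keeps
the operation idempotent. Note the core assumption: *most probes do not
change between arrays*. When a substantial fraction of probes shifts in one
condition — easy to arrange in a simulation, rare in a genome-scale
experiment — quantile normalization transfers part of that mass onto
unchanged probes and biases downstream tests; the acceptance studies in
`scripts/acceptance.R` therefore run the test cascade on the generator's
already-calibrated arrays (log2 only), and we recommend inspecting MA plots
before trusting quantile normalization on heavily perturbed designs.

Gene summarization is deliberately simpler than full RMA: a gene's
expression on an array is the arithmetic mean of its exon-probe log2
values (no median polish), computed only for genes with more than three
mapped probes.

## The gene-level call

Differential expression per gene: two-sided two-sample t-test
(pooled-variance Student by default, Welch selectable) on the per-array
gene expression values, Benjamini-Hochberg adjustment across all tested
genes, and the call `responsive = (adjusted p ≤ 0.05) AND (|log2 FC| ≥ 1)`.
The log2 fold change is treatment − control, so induced genes are positive.
Degenerate variances (all replicates identical in both groups) give p = 1
when the means agree and otherwise fall back to a pooled-variance floor of
1e-8, so the statistic stays finite while remaining conservative.

## The intron-level splicing test

Genes enter the splicing analysis when they have more than eight mapped
probes, at least one of them intronic, and — in at least one condition —
mean exonic expression above the *exon expression threshold* with mean
intronic signal below the *intron background threshold*. The two thresholds
are global medians over the normalized matrix: the median of all exon-probe
values and the median of all mapped probes' values, respectively. The
histogram mode of the exon-probe distribution (midpoint of the tallest
Freedman-Diaconis bin; continuous data have no exact mode) is reported as a
diagnostic only. This gate selects genes that are expressed but whose
introns are at background, i.e. genes where retention would be visible.

For each intron of an eligible gene:

1. every probe gets a one-sided pooled-variance t-test of
   treatment > control across replicates, giving `p_up`; the opposite
   direction is the complement `p_down = 1 − p_up` (a probe moving against
   the tested direction is assigned the complementary value);
2. the per-probe p-values are combined with Fisher's method,
   X² = −2 Σ ln pᵢ against χ² with 2k degrees of freedom, separately for
   the two directions. Probes within an intron are treated as independent:
   the array's probes do not overlap, and accounting for the residual
   correlation induced by multi-probe cDNA fragments has been reported to
   hurt rather than help this statistic;
3. the intron-level p is the **minimum** of the two combined p-values, and
   the direction is the side achieving it;
4. intron p-values are BH-adjusted across all tested introns; adjusted
   p ≤ 0.1 is called differentially spliced;
5. a significant intron is classified *retained* only when every one of
   its probes has unadjusted p < 0.05 in the winning direction; any other
   pattern (alternative 5'/3' sites, mixed probes) is *unknown*;
6. the *presence* call is the condition with the higher mean intronic
   signal.

### A caution about the min rule

Step 3 is deliberately replicated as published, and it is anti-conservative:
under the null, P(min(P_up, P_down) ≤ x) ≈ 2x for small x, because the two
directional combinations are complementary. BH applied to these p-values
controls the FDR at up to twice the nominal level. Our simulations (2,000
introns, 300 planted retentions, 4 vs 4 replicates, σ = 0.25) measure an
empirical FDR of ≈ 0.15–0.19 at the nominal 0.1 threshold — consistently
the factor-two inflation, and visible only because the simulation knows the
ground truth. The constructor flag `two_sided_correction = TRUE` Bonferroni-
doubles the intron p and restores the nominal guarantee; it is **off by
default** to match the published procedure, and we document the inflation
rather than silently fixing it.

Events shorter than the probe resolution (~35 bp) are undetectable by
construction, and the classifier cannot distinguish exon skipping from
partial intron events: everything non-retained is "unknown".

## Comparing event lists and stress profiles

`overlap_sets()` compares two event lists over a shared universe of tested
introns (events are identified as gene id + intron number under the same
annotation): the representation factor is observed/expected overlap with
expected = n_a·n_b/N, and significance is the exact upper-tail
hypergeometric probability P(X ≥ overlap).

`build_stress_index()` distils an experiment into its 1,000
largest-|log2 FC| genes with unadjusted p < 0.05 (ties broken by gene id);
`correlate_index()` scores another experiment against such an index by
Pearson correlation of signed log2 fold changes over the shared genes, so
+1 means identical direction and intensity of response. Genes absent from
either side are dropped rather than zero-imputed, which would fabricate
agreement; fewer than three shared genes yields `NA`. Pearson on matched
signed fold changes is our choice among the vector-comparison variants in
use; rank-based alternatives behave similarly on these long vectors.

## The synthetic-data generator

`simulate_experiment()` produces a complete fake experiment: an annotation
(one transcript per gene; exons 100–300 bp, introns 150–300 bp by default),
probes tiled every 35 bp, and raw linear intensities for 4 + 4 arrays.
Exon probes sit at mean log2 10, intron probes at 6 — a 16-fold
exon/background separation typical of an expressed gene on these arrays —
with independent Normal(0, 0.25²) log2 noise per probe and array
(log-normal on the linear scale, the standard microarray error model).
Planted retention raises *all* probes of the target intron by the effect
size in the target condition; partial 5'/3' events raise only the probes in
the corresponding half of the intron (transcript orientation); planted DE
genes shift all their exon probes. Truth tables record every planted event,
DE gene, and each probe's true assignment, so recovery can be scored
exactly. Boundary-crossing probes are dropped by default
(`border_probe_fraction`, `n_intergenic_probes`, `n_control_probes` and
`n_multimap_probes` inject them deliberately to exercise every exclusion
branch). All randomness flows from a single recorded seed (default
20130611); identical configurations are byte-identical across runs.

What the generator does *not* emulate: probe-sequence affinity effects and
cross-hybridisation, spatial artifacts, correlated noise between
neighbouring probes, partially expressed isoform mixtures, and background
haze (intensities are background-free, which is why `background = "none"`
is the pipeline default for simulated data). Passing tests on this
generator therefore demonstrate the statistical machinery — calibration of
the probe tests, the Fisher combination, BH behaviour, classifier logic —
not robustness to array artifacts.

## Problem sizes and numerical choices

The packaged simulation studies use 2,000 introns (500 five-exon genes,
300 planted retentions with effects uniform on 2–3 log2) for the
intron-level FDR study and 5,000 single-exon genes (500 with 2 log2 shifts,
~10 probes each) for the gene-level study; both finish in well under a
minute and their empirical FDR estimates carry binomial noise of roughly
±0.02 at these call counts. Other conventions: p-values of exactly 0 are
floored at 1e-300 before taking logs (with a warning); introns without
probes are skipped silently; an empty eligible set downstream of the gate
produces empty result tables with a warning rather than an error; and all
tie-breaks (base transcript, index ranking) are lexicographic, never
platform-dependent.

## A worked run

```{r example, eval = FALSE}
ev <- data.frame(gene = 3, intron = 2, type = "retention",
                 condition = "treatment", effect = 3)
sim <- simulate_experiment(simulation_config(n_genes = 30,
                                             planted_events = ev,
                                             seed = 7))
run <- run_splicing_pipeline(sim$models, sim$probes, sim$intensities)
run$funnel
subset(run$intron_results, significant)
```

The run funnel reports the probe exclusion counts, gated genes, and
tested/significant introns; `write_run()` adds TSV outputs and a JSON
manifest capturing options and thresholds so a run can be reproduced
exactly.
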