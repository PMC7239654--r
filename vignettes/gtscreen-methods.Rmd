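---
title: "Models and methods in gtscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in gtscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtscreen)
```

This vignette documents the statistical models, the parameter choices, and
the numerical conventions behind `gtscreen`, and is explicit about which
design decisions were genuinely open and why they were resolved the way they
were.

## Coordinate and annotation conventions

Everything internal is 0-based half-open (`[start, end)`), the BED
convention; GTF/GFF3 input (1-based inclusive) is converted on read by
subtracting 1 from starts. The analysis is gene-level, not transcript-level:
exons of all transcripts of a gene are merged into a union-exon set, and
"exonic" means inside that union. The gene span is clipped to the exon
extent, which guarantees that union exons and the gaps between them
(introns) tile the span exactly — a property the test suite asserts
(`exon bp + intron bp = span bp`). Promoter or flanking windows are *not*
part of a gene: an insertion upstream of the first exon is intergenic.
Chromosome lengths inferred from an annotation without declared lengths
(e.g. BED12) are treated as lower bounds, so genome-wide insertion tables
beyond the last gene still classify.

## Insertion classification

A gene-trap cassette disrupts its host gene when transcription runs into its
splice acceptor. In an exon, integration truncates the transcript in either
orientation; in an intron, only the sense orientation (cassette strand equal
to the gene strand) captures splicing. Hence the classification rules:

| feature | orientation | classification |
|---|---|---|
| exon | any | inactivating |
| intron | sense | inactivating |
| intron | antisense | non-inactivating |
| intergenic | — | intergenic |

An insertion overlapping several genes (possible with overlapping gene
models) yields one call per gene and counts for each independently; the
alternative — picking one gene by an arbitrary priority — would bias counts
in a way that is hard to reason about, and overlap is rare in practice.

## Per-gene enrichment

For each gene the screen contributes a 2×2 table: `a` unique inactivating
insertions in the gene in the sorted population against the sorted total
`T_s`, and `n_g` unique insertions *of any class* in the gene in the control
population against the control total `T_c`. The one-sided (greater) Fisher
exact test gives the hypergeometric upper-tail p-value
`P(X ≥ a)` with `X ~ Hypergeom(a + n_g, T_s + T_c − a − n_g, T_s)`.

Two aspects of this contract were open and are deliberately isolated in
single functions so they can be swapped:

* **Asymmetric counting.** The sorted side counts only inactivating
  insertions (those are the ones selection acts on) while the control side
  counts all insertions in the gene (the control pool is unselected, so its
  in-gene rate is a background insertional-density estimate independent of
  orientation). `enrichment_test()` is the single place this reading lives.
* **Multiple testing.** "FDR-corrected" is implemented as Benjamini–Hochberg
  step-up across the entire annotated gene universe (all genes, including
  zero-count genes, which get p = 1); fixing the universe keeps q-values
  comparable between screens of the same annotation. `bh_fdr()` wraps the
  standard step-up implementation and is verified in the tests against the
  textbook formula `q_(i) = min_{j≥i} p_(j)·m/j`.

Hit thresholds are strict inequalities: q < 0.01 for inclusion in the
comparative analysis, q < 10⁻⁴ for top hits.

## IGTIOB

The intronic gene-trap insertion orientation bias score summarizes, per
gene, the sense excess among intronic insertions in the sorted population:

$$\mathrm{IGTIOB} = \frac{S - A}{S + A} \in [-1, 1]$$

It is the simplest statistic with the required ingredients that is bounded
and antisymmetric (swapping sense and antisense flips the sign, a property
the tests assert). A gene with no intronic insertions has no defined score;
it is reported as missing, and imputed as 0 (with a flag) only where a
complete matrix is required. Because the score uses only the sorted
population, it does not inherit screen-specific sequencing depth, which is
why *cross-screen* comparison is done on IGTIOB rather than on q-values.

## Cross-screen comparison

Genes with q < 0.01 in at least one screen are collected (relaxing the
top-hit threshold here avoids missing hits private to one screen), their
IGTIOB scores form a genes × screens matrix, and rows are ordered by
agglomerative hierarchical clustering with Euclidean distance and average
linkage. Metric and linkage were not externally constrained; this pair was
chosen for robustness and, importantly, determinism: rows are pre-sorted by
gene id before clustering so the leaf order is invariant under input row
permutation, which the tests check.

## Four-parameter logistic dose-response

The variable-slope agonist model is

$$y = \mathrm{Bottom} + \frac{\mathrm{Top} - \mathrm{Bottom}}
{1 + 10^{\,h\,(\log_{10}\mathrm{EC50} - \log_{10} d)}}$$

fitted by Levenberg–Marquardt least squares. Numerical choices:

* **Parameterization** in `log10(EC50)`: the likelihood surface is far
  better conditioned in log-dose space, and the EC50 standard error is
  recovered on the nM scale by the delta method,
  `se(EC50) = ln(10) · EC50 · se(log10 EC50)`.
* **Initialization**: Bottom = min response, Top = max response, log-EC50 at
  the dose whose response is nearest the half-maximum, h = 1. Convergence
  tolerances are tightened (`ftol = ptol = 1e-15`) so noiseless titrations
  recover parameters to ~1e-6 relative and residual sums of squares below
  1e-10, which the tests assert.
* **Convergence policy**: a fit reports no EC50 (flag `converged = FALSE`)
  when the optimizer fails, the fitted dynamic range is not positive, or
  the fitted EC50 lies more than 10-fold outside the dosed range — in that
  last case the data do not bracket the midpoint and the "estimate" is
  extrapolation. A constant response is rejected up front.
* **Zero-dose wells** have no log-dose and are excluded; optionally
  (`anchor_bottom = TRUE`) their mean fixes Bottom, which then has zero
  standard error and returns one residual degree of freedom to the fit.

"Efficacy" is operationalized as the fitted dynamic range Top − Bottom
relative to a reference fit. EC50s are compared with a two-tailed unpaired
t-statistic on the nM scale using the two curve-fit standard errors, with
Welch–Satterthwaite degrees of freedom built from each fit's residual
degrees of freedom (n − 4 each); when variances and residual dfs are equal
this reduces to their sum. Whether published comparisons of this kind use
fit-level or replicate-level variability is ambiguous in general; the
fit-level contract is documented here and isolated in `compare_ec50()`.

## The synthetic-data generator

`simulate_screen()` is a deliberately minimal generative model of a FACS
reporter screen, built so that its expected enrichment has a closed form:

* one insertion per cell (haploidy makes single insertions penetrant;
  multi-integration cells are not modeled), uniform position, random strand;
* a Bernoulli sorting gate: background cells enter the sorted gate with
  probability φ (`gate_fraction`, default 0.1 — the "lowest ~10%
  fluorescence" gate), cells carrying an insertion that inactivates a
  planted hit gene with φ + (1 − φ)ε, where ε (`penetrance`, default 0.9)
  absorbs reporter effect size and gate position;
* the control population is the whole mutagenized pool, matching the design
  in which unsorted mutagenized cells provide the insertion background.

The expected sorted/control retention ratio for hit-inactivating insertions
is therefore (φ + (1 − φ)ε)/φ — 9.1 at the defaults — and the tests verify
the realized ratio against this closed form within Monte-Carlo error.

Default scale: 100 genes on a 2 Mb chromosome, 5 planted hits, 5×10⁴
cells, and caps of 10⁴ / 2×10⁴ unique insertions reported for the sorted /
control populations. These sizes keep a full simulate–classify–test cycle
around two seconds while leaving planted hits with ~50–100 supporting
insertions, enough for unambiguous recovery. The depth parameters are *caps*
(sequencing saturates the library): when the gated pool yields fewer unique
insertions than the cap — which is the typical regime, since a 10% gate on
5×10⁴ cells yields at most ~5×10³ distinct gated insertions — all of them
are reported; `strict_depth = TRUE` turns an unattainable cap into an error
instead.

The pre-sort `orientation_bias` parameter (default 0.5, i.e. unbiased
integration) exists to model library-construction bias separately from
selection. Note that with unbiased integration the *post-sort* sense excess
at hit genes arises purely from selection — sense intronic insertions are
the inactivating ones and so are preferentially retained by the gate — and
the tests assert exactly that: positive IGTIOB at planted hits, mean ≈ 0
elsewhere.

What the generator does **not** emulate: insertion-site hotspots and
mappability structure, PCR/sequencing duplication artifacts, multiple
integrations per cell, fluorescence as a continuous quantity (the gate is a
coin flip, not a threshold on a simulated reporter distribution), and
chromosome structure beyond a single contig. Consequently, passing recovery
and calibration tests shows the statistical machinery is correct under the
stated model — it does not certify performance on real screens, where
insertional hotspots in particular can violate the uniform-background
assumption that the control population is meant to absorb.

Dose-response simulation adds i.i.d. Gaussian noise to the 4PL mean of each
well, emulating per-well median fluorescence of a few thousand cells; it
does not model cell-to-cell variance or plate effects. For stochastic
recovery tests, titrations use the field-standard design of a three-fold
dilution series centered on the expected EC50 (8 doses, 2 replicate wells,
noise sd 5% of Top); under that design the median relative EC50 error in the
test suite's 100-simulation batches is ~11–12%. An asymmetric grid that
covers the midpoint only near its lowest doses degrades this noticeably —
dose placement, not the fitter, is the binding constraint.

## Determinism

Every simulator is seeded and side-effect free (`withr::with_seed`), and
file outputs are byte-identical across runs under the same configuration;
the annotation stream uses `seed` and the screen stream `seed + 1` so that
gene placement and insertion placement are decoupled. The circle-plot gene
order (genes are displayed in random order along x) is itself a seeded
permutation, computed on a gene-id-sorted table so it is independent of
input row order.

## Problem sizes in the test suite

Unit and property tests run on toy annotations (2–40 genes) and on
10⁴-insertion random tables against a brute-force oracle; exact-test
equivalence is enumerated for all 2×2 tables with margins ≤ 12 (8,100
tables); screen-level recovery uses the default 100-gene configuration
across 10 seeds (planted hits) plus 20 seeds (null calibration); 4PL
recovery uses 100 noisy titrations. These sizes were chosen so the entire
suite completes in about two minutes while keeping Monte-Carlo error well
below the tested margins.

## Known limitations

* The enrichment test treats sorted and control as independent samples; in
  the intended design the sorted pool is a subset of the mutagenized pool,
  which makes the test conservative (the null-calibration test measures
  this: the realized false-positive fraction at q < 0.01 sits far below
  0.01).
* IGTIOB is undefined for genes without intronic insertions — short or
  single-exon genes can be strong hits yet carry no orientation signal.
* Gene-level union-exon classification ignores isoform structure; an
  insertion intronic in the union may be exonic in a minor isoform.
* The 4PL comparison assumes approximately Gaussian EC50 estimates on the
  nM scale; for poorly constrained fits (large `se(log10 EC50)`) the
  delta-method interval can be inaccurate.
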