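# gtscreen

Statistical analysis of reporter-based haploid gene-trap screens and of the
four-parameter logistic dose-response measurements used to quantify ligand
potency — the computational toolkit behind studies of R-spondin (RSPO)
amplification of WNT/β-catenin signaling in HAP1-7TGP reporter cells.

## Who this is for

Two kinds of measurement recur in this line of work:

1. **Haploid gene-trap screens.** Near-haploid cells are mutagenized with a
   gene-trap retrovirus, FACS-sorted for the lowest ~10% WNT reporter
   fluorescence, and the genomic insertion sites of the sorted and of the
   unsorted (control) populations are mapped. Genes whose inactivation
   blunts reporter activity accumulate *inactivating* insertions in the
   sorted population. `gtscreen` starts from the mapped insertion tables
   (BED6) and a gene annotation (GTF/GFF3/BED12) and produces ranked per-gene
   hit tables and cross-screen comparisons.
2. **Dose-response titrations.** Purified ligand variants are titrated on
   reporter cells and per-well median fluorescence is fitted with the
   variable-slope four-parameter logistic (4PL) model to estimate EC50s,
   compare potencies, and test differences.

## The statistics

*Insertion classification.* An insertion in a gene's union-exon extent is
**exonic** (inactivating in either orientation) or **intronic**, where only
the **sense** orientation (splice-acceptor capture) inactivates. All
coordinates are 0-based half-open.

*Per-gene enrichment.* For gene *g*, with `a` unique inactivating insertions
in the sorted population (total `T_s`) and `n_g` unique insertions of any
class in the control population (total `T_c`), the one-sided Fisher exact
test on `[[a, T_s − a], [n_g, T_c − n_g]]` gives the hypergeometric
upper-tail p-value, corrected across all genes by Benjamini–Hochberg.
Hits are called at q < 0.01 (comparative threshold) and q < 10⁻⁴ (top hits).

*Orientation bias.* The intronic gene-trap insertion orientation bias score,
`IGTIOB = (S − A)/(S + A)` with `S`/`A` the sense/antisense intronic counts
in the sorted population, is depth-independent and is what is compared
*across* screens: genes significant in ≥1 screen are clustered on their
IGTIOB profiles (Euclidean distance, average linkage) to build the heat map.

*Dose-response.* `response = Bottom + (Top − Bottom)/(1 + 10^(h·(logEC50 −
log10 dose)))`, fitted by least squares in log10-EC50; `EC50 = 10^logEC50`
with delta-method standard error `ln(10)·EC50·se(logEC50)`; potency
fold-change is an EC50 ratio; EC50s are compared by a two-tailed unpaired
Welch t-test using the curve-fit standard errors.

A synthetic-data module simulates annotations, screens with planted hit
genes (Bernoulli FACS gate: background cells sort with probability φ,
cells carrying a hit-inactivating insertion with φ + (1−φ)ε), and noisy
titrations — so the whole pipeline runs, and can be calibrated, without any
external data.

## Worked example

The numbered scripts under `analysis/` run the full workflow on synthetic
screens (two screens sharing three planted hits, one private hit each):

```sh
Rscript analysis/01_simulate_screens.R
Rscript analysis/02_screen_enrichment.R
Rscript analysis/03_compare_screens.R
Rscript analysis/04_dose_response.R
```

Step 2 prints, per screen, the hit calls and their orientation bias:

```
screen1: 4 genes with q < 0.01 (gene040, gene025, gene070, gene010); 4/4 planted hits recovered; top hit q = 5.14e-28
screen1: IGTIOB at recovered hits: gene040=0.76, gene025=0.78, gene070=0.86, gene010=0.79
```

All four planted hits are recovered at q < 0.01 with strongly positive
IGTIOB (sense-orientation excess, the signature of selection for gene
inactivation). Step 3 then separates shared from screen-specific hits:

```
significant in both screens: gene070, gene010, gene040
significant in one screen: gene055, gene025
heat-map row order: gene055 > gene025 > gene070 > gene010 > gene040
```

Step 4 refits titrations of RSPO3 variants simulated at their reference
EC50s (5%-of-top well noise) and reports potency shifts with Welch tests,
e.g.:

```
RSPO3_dTSPBR vs RSPO3_WT: 96-fold potency change (t = 5.3, df = 12.0, p = 0.00019)
```

In R, the core calls are:

```r
library(gtscreen)
ann <- read_annotation("annotation.gtf")
sorted <- read_insertions("sorted.bed", "screen1", "sorted")
control <- read_insertions("control.bed", "screen1", "control")
res <- screen_enrichment(sorted, control, ann)   # per-gene p, q, IGTIOB, hits
fit <- fit_4pl(read_dose_response("titration.tsv", sample = "RSPO3_WT"))
ec50(fit)                                        # EC50 in nM with SE
```

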