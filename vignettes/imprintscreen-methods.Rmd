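---
title: "Methods: pharmacogenomic association screens for imprinted gene regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pharmacogenomic association screens for imprinted gene regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imprintscreen)
```

## The scientific problem

Imprinted genes — genes expressed from only one parental allele in normal
tissue — cluster in a small number of chromosomal regions, and tumor cells
frequently gain or lose copies of those regions wholesale. This package
implements an association pipeline that asks whether the copy number,
expression, or DNA methylation of imprinted genes in cancer cell lines
predicts response to drug treatment, measured as log10(IC50) (the log of the
drug concentration that halves cell activity; larger values mean a more
resistant line), and whether expression findings replicate in an independent
patient cohort with ex vivo drug response and survival data.

Two statistical features distinguish the pipeline from a generic
feature-versus-response screen:

1. **Gene-region-averaged methylation.** 450K-style array probes are
   filtered by detection quality and SNP overlap, then averaged within six
   UCSC-defined gene regions per gene (TSS1500, TSS200, 5'UTR, 1stExon,
   Body, 3'UTR). The region-averaged beta value near 0.5 — one methylated
   and one unmethylated allele — is the signature of an imprinted
   differentially methylated region, and the distribution summaries expose
   that hemimethylation peak per region group.
2. **Segment-grouped conservative FDR.** Copy-number values of genes in the
   same or adjacent cytobands are strongly correlated, so genes are grouped
   into chromosomal segments and each segment enters the
   Benjamini–Hochberg family once, represented by the *largest* raw p value
   among its member genes. Every member gene then inherits the segment's
   adjusted p. This is deliberately conservative: a segment is only called
   when even its least significant member would survive.

## The pipeline, stage by stage

**Response preparation** (`prepare_response`). Raw IC50 values must be
strictly positive; they are log10-transformed, and duplicate measurements of
an agent (repeated columns of the raw table) are averaged per cell line on
the log scale, missing-aware. Agents shared between data sources are kept as
separate measures under distinct identifiers, never merged.

**Correlation screens** (`correlate`, `run_association_screen`). Every
feature–agent pair is correlated over the cell lines non-missing in both
(pairwise-complete), with the Spearman coefficient computed as the Pearson
correlation of midranks (average ranks for ties) and a two-sided p value
from the t approximation with n − 2 degrees of freedom. The t approximation
is standard at the sample sizes involved (hundreds of lines); an exact
permutation p would be impractical and is not attempted. Pairs with fewer
than `min_pairs` (default 10) complete observations are skipped — the
screens report per-pair sample sizes precisely because missingness varies
by agent. Stratified screens run separately inside each cancer category
with at least 10 cell lines. Expression is analysed on its provided scale;
the headline statistic is rank-based, so monotone transforms are
irrelevant to it.

**Segmentation** (`assign_segments`). Segments start as cytobands (genes on
one cytoband always share a segment) and adjacent segments merge when (a)
their genes share a curated joint-CNA group — literature-supported jointly
lost/gained clusters, applied regardless of the data — or (b) the
correlation linkage between them exceeds `merge_r_threshold` (default 0.7).
Adjacency means consecutive `band_order_index` on the same chromosome,
where the index is the rank of the cytoband among the catalog's cytobands
on that chromosome; the index is supplied in the catalog because
lexicographic cytoband order is not positional order (q11.21 sorts after
q13.2 positionally on neither arm). The linkage statistic is the **median**
of all cross-segment gene-pair Pearson correlations of continuous copy
number. The aggregation had to be chosen here: a single outlying gene pair
should not make or break a merge, which rules out min/max; median was
preferred over mean for the same robustness reason, and both alternatives
remain available via the `linkage` argument. Merging repeats to a fixed
point, so chains of adjacent correlated bands collapse transitively into
multi-band segments (the behaviour required to reproduce long
co-amplified regions such as 20q11–q13.32 from local decisions).

**Methylation filtering** (`filter_probes`). Cell-level beta values with
detection p ≥ 1e−3 are masked; probes with median detection p ≥ 1e−6 are
dropped; SNP-masked probes are dropped. Both thresholds are inclusive. The
probe-level median is computed over all cell lines *before* the cell-level
masking, making the probe-drop criterion independent of step one — the
ordering was left open by the filter definitions, and this choice is the
one that keeps the two filters orthogonal.

**Copy-number summaries** (`round_copy_number`, `summarize_copy_number`).
Continuous copy number feeds every correlation; rounded values exist only
for summaries and histograms. "Nearest integer" is ambiguous at .5, so the
tie rule (half away from zero) and the clamp at zero are explicit, stated,
and monotone. Loss means rounded value ≤ 1, gain means ≥ 3; percentages are
reported half-away-from-zero at one decimal.

**Multiple testing** (`bh_adjust`, `segment_fdr`, `flag_significant`).
`bh_adjust` is the standard step-up with missing entries passed through and
excluded from the family size (only computed tests are tests). The
segment-grouped procedure takes, per (segment, agent, stratum), the maximum
raw p over member genes, BH-adjusts the representatives as one pooled
family, and broadcasts each segment's adjusted p back to its members.
Stratified records pool all (segment, agent, category) triples into a
single family; pancancer and stratified runs are adjusted as separate
families. Significance requires both the FDR criterion (adjusted p < 0.05)
and an effect-size criterion (|rho| > 0.3 headline, 0.25 relaxed) — the
correlation amplitude acts as an explicit effect-size floor, since at
n ≈ 600 trivially small correlations can reach small p values. Segment
grouping applies to copy number only; expression and methylation screens
treat features as independent (`bh_adjust_records`).

**Validation stage** (`validate_expression_response`, `logrank_test`).
Gene-panel expression versus ex vivo log10(IC50) over all specimens with
both measures (specimens, not patients, are the unit — multiple specimens
per patient are not collapsed), with separate BH families for
Spearman-derived and Pearson-derived p values and a laxer FDR level of 0.1
appropriate to a small 9 × 13 panel. The log10 transformation is applied
before any specimen filtering. The survival comparison is a two-group
log-rank test implemented from its definition: at each distinct event time
the observed events in group 1 are compared with their hypergeometric
expectation given the risk sets; ties use the standard hypergeometric
variance; the statistic (ΣO − ΣE)²/ΣV is chi-squared with 1 df. With no
events the statistic is 0 and p = 1. Cox proportional-hazards modelling is
intentionally out of scope; the survival surface is the log-rank path.

## The synthetic cohort generator

`generate_dataset` produces complete cohorts with the statistical structure
the analysis assumes, plus the ground truth needed for calibration and
power studies. Its defaults are fixed at the conditions of the motivating
study design: 645 cell lines in 22 cancer categories, 198 imprinted genes
in 35 chromosomal segments, and 275 drug-response measures (a handful of
agents emitted as duplicate columns).

* **Copy number** is a shared latent segment value plus per-gene noise: an
  equicorrelated Gaussian on a log2-ratio scale (gene-level scatter sd
  0.15), mapped to the nonnegative copy-number scale around a baseline of
  2. The equicorrelation parameter (default 0.8, matching the strong
  observed within-region correlations) is what the `assign_segments`
  correlation merges see. Segment-level gain (+half copy ratio, rate 0.15)
  and loss (−1 copy ratio, rate 0.08) events and rare focal amplifications
  (rate 0.01, 4–12 copies) sit on top of the Gaussian part; with event
  rates zeroed, pairwise within-segment correlation equals the configured
  value.
* **Planted drug effects** act through the latent segment value, not
  individual genes, mirroring region-level signal: the response is built by
  a Gaussian copula on the latent's normal scores with Pearson parameter
  r = 2·sin(π·ρ/6), so the *population Spearman* correlation between
  segment copy number and log10(IC50) equals the configured target ρ
  exactly. Gene-level attenuation is negligible at the default
  equicorrelation.
* **Methylation** draws one mixture component (low ≈ Beta(1.5, 15),
  hemimethylated ≈ Beta(30, 30) centred at 0.5, high ≈ Beta(15, 1.5)) per
  gene region — an imprinted DMR is a region-level state — with
  per-cell-line, per-probe draws from that component. Default weights put
  0.6 hemimethylated mass in TSS200/5'UTR/1stExon and 0.1 in Body/3'UTR,
  reproducing the promoter-proximal 0.5 peak. Detection p values are tiny
  (10^−9–10^−7) except for sporadic failed measurements (configurable
  rate, values ≥ 1e−3) and ~1% globally failed probes; ~2% of probes are
  SNP-masked.
* **Expression** is positively coupled to the copy-number latent on a log2
  scale (unit slope by default).
* **Missingness** is completely at random — the pairwise-complete analysis
  assumes nothing stronger.

`generate_validation_cohort` mirrors the patient cohort: 409 specimens,
9-gene × 13-agent panels, expression-driven response via the same copula
construction, exponential survival with uniform censoring, a
cytogenetic-loss flag (rate 0.12) whose hazard ratio defaults to 1.23, and
a mutation flag carried through to outputs.

What the generator does *not* emulate: tumor-type-specific copy-number
landscapes, array segmentation artefacts, batch effects, informative
missingness, and correlated agents (drugs sharing a mechanism). Passing
calibration and power tests therefore demonstrates the statistical
machinery is correct under the stated model, not that real data meet the
model.

## Numerical choices and degenerate inputs

* Constant feature or response vectors yield a missing coefficient with a
  reason code rather than NaN; pairs below the `min_pairs` floor are
  skipped and excluded from every FDR family size.
* Output orders are deterministic everywhere (sorted identifiers;
  association tables sorted by |rho| descending with feature/agent
  tie-breaks), and screens are invariant to cell-line row order.
* All generator randomness flows from a single integer seed through R's
  default Mersenne-Twister stream; identical configurations give
  bit-identical outputs.
* TSV is the single tabular dialect (UTF-8, `NA` for missing); readers
  reject duplicate identifiers and non-numeric cells with coordinates
  rather than coercing, and writers round-trip finite doubles bit-exactly.

## Problem sizes used in the test and acceptance runs

The Monte-Carlo suites run at the screen's stated operating conditions with
two genes per segment (the segment count, agent count, and cell-line
numbers are what matter for the family structure; per-segment gene count
affects only the max-p representative, and two members already exercise
it): null calibration with 35 segments × 50 agents at n = 300 over 150–200
replicates; planted-effect power (ρ = 0.4, n = 600) over 100 replicates;
validation-cohort power (ρ = 0.3, n = 400) over 60 replicates; log-rank
uniformity under a unit hazard ratio over 500 seeds. Oracle-equivalence
suites compare `bh_adjust` and `segment_fdr` against independent
brute-force reimplementations on 1000 random fixtures.

## Known limitations

* The segment-merge linkage aggregation (median) and the transitivity of
  merging are explicit design choices where the grouping notion admitted
  several readings; both are configurable or documented rather than
  hidden.
* The conservative max-p representative makes segment calls depend on the
  *worst* member gene; a segment with one noisy member can be missed even
  when others are strongly associated.
* Empirical FDR statements are about the generator's null model (Gaussian
  copulas, MCAR missingness); heavy-tailed responses or informative
  missingness are untested territory.
* The stratified family pools all categories into one adjustment; with
  very unbalanced categories this is conservative for the large ones.
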