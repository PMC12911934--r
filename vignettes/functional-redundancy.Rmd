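---
title: "Functional redundancy of MAG communities: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional redundancy of MAG communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fredmag)
```

## The model

A community is a set of MAGs with relative abundances $p_i$ ($\sum p_i = 1$)
and a MAG × trait matrix. Pairwise functional dissimilarity $d_{ij}$ is the
Euclidean distance between trait rows, rescaled by the maximum observed
pairwise distance so $d_{ij} \in [0, 1]$. From these:

$$D = 1 - \sum_i p_i^2, \qquad
  Q = \sum_i \sum_j p_i p_j d_{ij}, \qquad
  U = Q / D, \qquad
  \mathrm{FRed} = 1 - U.$$

$Q$ is Rao's quadratic entropy, the abundance-weighted mean pairwise
dissimilarity; $D$ is its upper bound for unit-bounded dissimilarities, so
$U \in [0, 1]$ and FRed is 1 for functionally identical members and 0 for
maximally distinct ones. The implementation assumes nothing else about the
distances: any symmetric, zero-diagonal, unit-bounded matrix works.

Two assumptions matter. First, the trait table is treated as a faithful
readout of function — annotation error propagates directly into $d_{ij}$.
Second, FRed is abundance-weighted: rare MAGs contribute little however
distinct they are, which is the intended ecology (redundancy as buffering
of realized function), not a defect.

## Parameters that matter

- **Quality filter** (`filter_mags`): completeness > 70 %, contamination
  < 5 %, both strict — the standard high-quality bin rule. Configurable via
  `--min-completeness` / `--max-contamination`.
- **Completeness normalization** (`normalize_by_completeness`): hit counts
  become `100 * hits / total_genes / (order mean completeness / 100)`.
  Completeness enters as a fraction in the denominator, inflating values
  for incomplete genomes; the order mean (not the MAG's own completeness)
  is used so closely related genomes are corrected consistently.
- **Which values enter the distance**: raw hit counts by default for FRed,
  completeness-normalized values for community profiles. The two readings
  are both defensible; both are supported, and the default keeps the FRed
  distance free of the normalization's order-level coupling.
- **Distance scaling scope**: for potential FRed the max-rescaling is done
  once per trait subset over the full MAG set, so values are comparable
  across samples; per-sample rescaling sits behind
  `scale_per_sample = TRUE`. Expressed FRed necessarily rescales per
  sample, because each sample has its own TPM trait table — a documented
  asymmetry.
- **Abundance threshold** (`min_abundance`, default 0): MAGs at or below it
  are dropped before renormalizing $p$; a community needs ≥ 2 retained
  MAGs, otherwise the row is flagged `NA` rather than aborting the run.
- **Expressed-FRed weights**: metagenomic relative abundances by default
  (redundancy combines *abundance* with trait distance; transcript totals
  are not abundances). `weights = "transcript"` exists for sensitivity
  analysis, as does `transform = "log1p"` on TPM; the default distance uses
  raw TPM.
- **TPM**: `rate = count / (length/1000)`, scaled to sum to $10^6$ per
  sample. Genes annotated to several traits contribute full TPM to each —
  annotation multiplicity, not read double-counting.
- **Seasonal contrasts** (`seasonal_log2fc`): `log2((mean_spring + eps) /
  (mean_summer + eps))` with `eps = 1e-8`; an alternative
  mean-log10-difference transform is exposed because the two readings of
  "seasonal fold change" differ only in transform, not in sign. Raw
  Wilcoxon p-values drive significance; BH-adjusted values are reported
  alongside.
- **Statistics**: Wilcoxon is exact for ≤ 20 untied values, otherwise
  normal approximation with continuity correction; the OLS collinearity
  screen drops the later member of any numeric covariate pair with
  $|r| > 0.9$ (threshold configurable); PERMANOVA uses 999 permutations by
  default and requires an explicit seed, with
  $p = (\#\{F^* \ge F\} + 1)/(B + 1)$.
- **PERMANOVA input**: sample dissimilarity is Euclidean distance between
  community-weighted mean trait profiles (`community_trait_profile`) —
  an explicit, configurable choice; any other square symmetric
  dissimilarity can be passed directly.

## The synthetic world

`sim_config()` states one world and the tests live in it:

- **Guild structure**: 8 guilds × 5 members (40 MAGs), 60 traits. Guild
  centroids occupy disjoint one-hot trait blocks, so all centroid pairs are
  mutually equidistant and the noiseless guild model has the closed form
  $\mathrm{FRed} = (m-1)/(g m - 1)$ — the anchor for end-to-end recovery
  tests. Within-guild trait noise sd 0.3 around centroid hit count 5 keeps
  guilds tight but not degenerate.
- **Design**: 2 bays × 2 seasons × 3 salinity classes × 2 replicates = 24
  samples — the magnitude of a two-estuary, two-season metagenome survey
  while staying sub-second.
- **Environmental effects**: one responder guild ("warm-adapted,
  halotolerant") takes log-abundance shifts of 0.15 per °C, +2.0 in summer
  and 0.04 per PSU; all MAGs get lognormal noise (sd 0.3) and a per-sample
  softmax yields relative abundances. In the guild model, responder
  dominance raises FRed, so the injected effects have a known positive sign
  on FRed — that sign, not a magnitude, is what the regression-recovery
  test asserts. Temperature is drawn at 14 ± 4 °C (spring) and 26 ± 4 °C
  (summer): seasonal separation with enough within-season spread that
  season and temperature stay estimable in one model.
- **Quality metrics**: completeness uniform on (80, 100], contamination on
  [0, 5) — inside the filter, since the generator emulates the
  *post-filter* MAG set.
- **Expression**: each encoded (MAG, trait) is one gene variant, length
  uniform 300–3000 bp; per sample it is on with probability π = 0.7,
  activity lognormal(0, 1), and reads are multinomial at depth $10^5$ with
  weight ∝ abundance × encoded value × activity × length. π = 0.7 encodes
  "most encoded traits are expressed somewhere, a substantial minority
  silenced", the qualitative regime of paired metagenome/metatranscriptome
  surveys.
- **Seeding**: one root seed; stages use fixed offsets (+1 traits, +2
  abundances, +3 transcripts) so each stage is independently reproducible,
  and the global RNG state is saved and restored around every generator.

What the generator does **not** emulate: real annotation error,
compositionality of coverage estimates, phylogenetic correlation of traits,
uneven sequencing depth, or the long-tailed abundance distributions of real
estuarine communities. A green test establishes that the pipeline computes
its statistics correctly in a controlled world — not that any biological
conclusion transfers.

One consequence worth stating: because expressed distances are rescaled per
sample, expressed FRed at the default settings need not sit below potential
FRed sample-by-sample; what holds (and is tested) is that lowering the
expression probability weakly lowers expressed FRed, and that with full
expression, constant activity, equal lengths and even abundances the
expressed values reproduce the potential ones up to multinomial noise.

## Numerical choices and degenerate inputs

- Summation order in $Q$ is fixed by sorting MAG ids, so results are
  bitwise reproducible regardless of input order.
- If all pairwise distances are zero the distance matrix is left all-zero
  (no 0/0 rescaling) and FRed is exactly 1.
- $D = 0$ cannot occur for a valid ≥ 2-MAG profile, but is guarded with a
  classed error; `community_fred` converts undefined-community errors into
  flagged `NA` rows. No sample is ever auto-excluded — outlier handling is
  the analyst's decision.
- The result writer formats numerics with 15 significant digits and a fixed
  row order, making output files byte-deterministic.
- Ties in Wilcoxon fall back to the midrank normal approximation; the exact
  path is never used with ties.

## Known limitations

- FRed is a single scalar per community; it does not localize *which*
  traits are redundant (the trait-subset mechanism is the coarse answer).
- No phylogenetic diversity variants or Hill-number generalizations.
- The PERMANOVA is a whole-model test (one pseudo-F for the full design),
  not a sequential per-term decomposition.
- Packaged trait-subset lists are illustrative defaults with field-standard
  marker names; real analyses should supply the gene lists of their own
  annotation run.
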