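---
title: "Scoring excitatory/inhibitory balance in spatial transcriptomics spots: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring excitatory/inhibitory balance in spatial transcriptomics spots: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eispot)
```

## The problem

Spot-level spatial transcriptomics assigns each barcoded capture location
("spot", roughly 1–10 cells) a UMI count vector over genes. Given two
conditions — a control-like and an inflamed/affected brain — the question is
whether hippocampal excitatory (glutamatergic) synaptic signaling is
selectively elevated relative to inhibitory (GABAergic) signaling, and which
genes drive the shift. `eispot` answers this with per-spot gene-set scores,
a median-split spot classification, group statistics, and a
differential-expression screen with spatial-similarity candidate ranking.

Because the motivating study's raw matrices are not publicly deposited, the
package treats a seeded negative-binomial simulator as first-class input:
it encodes the study's design (two samples, ~300–400 hippocampal spots each,
three marker-defined subregions, a glutamatergic condition effect) and
carries ground truth, so every claim the pipeline makes is checked against a
known answer.

## Preprocessing

Spots are kept when they have at least `qc.min_features` detected genes
(default 100) and at most `qc.max_mito` mitochondrial count fraction
(default 0.2, `mt-` prefix, case-insensitive); genes are kept when detected
in at least `qc.min_spots` spots (default 3). The QC axes are the field's
standard ones; the cut-offs are this package's defaults, chosen
conservatively for UMI data of a few hundred to a few thousand counts per
spot — they are configuration values, not claims about the original study,
which reports the axes but not its thresholds.

Normalization removes capture-size preference per spot:
`value = ln(1 + count * scale_factor / spot_total)` with
`norm.scale_factor = 1e4` (counts-per-10k, natural log, pseudocount 1 — the
convention of the ecosystem such data are usually processed in). The
transform is exactly invariant to scaling a spot's counts, which the tests
assert.

## Region assignment

The original workflow selected hippocampal spots manually from cluster maps
and histology images. That step is not reproducible without the images, so
the package substitutes an automated, deterministic stand-in: each
subregion's marker set is scored per spot as the mean of gene-wise z-scores
(genes centered and scaled across spots; zero-variance genes contribute 0),
and a spot is assigned to the argmax region if the winning score reaches
`regions.threshold` (default 0.25), otherwise `"other"`. Ties follow the
fixed order CA1 > CA3 > DG. The hippocampus is the union of the three
subregions. This deviation — automated marker scoring in place of manual
curation — is deliberate and is the package's main methodological
substitution.

With k markers per region, the background (non-hippocampal) mean-z score has
spread ≈ 0.9/√k, so the threshold's selectivity is a joint property of the
threshold and the marker-set size. The simulator therefore models marker
sets of 50 genes per subregion — the scale at which signature-based
annotation is normally practiced, since cluster marker lists run to hundreds
of genes — with the three canonical markers of each subregion
(Itpka/Fibcd1/Spink8; Cabp7/Homer3/Hs3st4; C1ql2/Fam163b/Dsp) leading each
set. Marker genes are simulated at a higher baseline abundance (2 UMI/spot)
than the genome-wide background (0.5), reflecting that top cluster markers
are by construction highly expressed. Under these conditions assignment
accuracy against ground truth is 0.95–0.98 across seeds.

## The per-spot set score

The score is a per-sample (here per-spot) gene-set variation statistic,
implemented from first principles in three stages:

1. **Expression statistic.** `ecdf_transform()` ranks each gene across
   spots with averaged ties and divides by the spot count, giving
   *e* ∈ (0, 1]. A Gaussian-kernel CDF mode (bandwidth sd/4 per gene) is
   provided for fidelity to the continuous-data convention of the cited
   method family; the rank ECDF is the default because it is exactly
   testable against an independent enumeration oracle. On count-derived
   data with more genes than spots the ECDF values tie across genes, which
   the next stage resolves deterministically.
2. **Per-spot ranking.** `spot_rank_stat()` orders genes by decreasing *e*
   within each spot, breaking ties by ascending gene index (determinism over
   randomization), and assigns rank weights |N/2 − R| — largest at both
   extremes of the ranking, so genes that are extreme in either direction
   dominate the walk.
3. **Weighted KS walk.** `random_walk_es()` accumulates the τ-weighted
   in-set weight fraction minus the out-of-set count fraction. The default
   enrichment score is max ν + min(0, ν) ("diff" mode): including the zero
   starting state in the minimum means a walk that only rises never picks up
   a spurious negative term. The "maxabs" mode returns the extremum of
   largest magnitude, preferring the positive one when the two magnitudes
   tie within 1e-12 (ties occur on small symmetric instances; the tolerance
   makes the choice independent of floating-point summation order). If every
   in-set gene carries zero weight — possible only when a single set gene
   sits exactly at rank N/2 — the in-set term is defined as 0 throughout.

τ, the score mode and the ECDF mode are exposed as `score.tau`
(default 1), `score.es_mode` ("diff") and `score.ecdf_mode` ("ecdf"); the
defaults follow the cited method family's published defaults, since the
original study names only the package and version it used. `|ES| ≤ 2` in
"diff" mode and ≤ 1 in "maxabs" mode, asserted as properties.
`permutation_null()` scores random gene sets of a given size under a seed,
for calibrating observed scores against a no-association null.

## E/I classification and group statistics

Each signature's per-spot scores are dichotomized at the **pooled** median
(both groups together); ties at the median go low (strict `>`), which is
deterministic and conservative for "high" calls. Pooling is the reading most
consistent with the motivating study's printed proportion pairs — per-group
medians would force each group to ~50% high by construction, which the
printed values contradict. Crossing the two levels yields four categories;
high-glutamatergic/low-GABAergic spots are excitatory, the reverse
inhibitory.

Group comparisons use the two-sided Mann–Whitney test on scores (matching
the study's stated two-group nonparametric procedure) and a two-proportion
chi-square with continuity correction on the high-glutamatergic and
excitatory fractions; the study does not name the test behind its proportion
panels, so the chi-square is this package's choice, made for its exactness
of reference distribution at these group sizes.

## DE screen and candidate ranking

The screen runs within the assigned hippocampus only. The study used a
count-model DE package; `eispot` deliberately substitutes a two-sided
Wilcoxon rank-sum test — self-contained, assumption-light, and exactly
testable — while keeping the study's thresholds verbatim: pass at
|FC| ≥ 1.25 and Padj < 0.05, top tier at |FC| ≥ 1.5. The test enumerates
all group assignments when n₁+n₂ ≤ 12 (exact under ties); otherwise it uses
the tie-corrected normal approximation *without* continuity correction,
which cross-checks exactly against the classical large-sample statistic and
keeps the null p-value distribution close to uniform on count data (the
null-calibration test asserts a raw p < 0.05 rate in [0.03, 0.07]).
Constant genes get p = 1 by convention. Adjustment is Benjamini–Hochberg
(the study says "adjusted p" without naming a procedure).

Fold change is computed on de-logged normalized means with pseudocount
c = 0.01: the log-normalized values are mapped back through `expm1`,
averaged per group, and the affected/control ratio taken as
(m₁ + c)/(m₀ + c). The study does not state its FC scale; the de-logged
normalized scale is the interpretable one (ratio of average normalized
expression) and c stabilizes near-zero genes without materially moving
ratios at the 1.25 gate for genes that could pass it.

Candidates are the top-tier DE genes belonging to the glutamatergic set,
ranked by Spearman correlation between their per-spot expression and the
glutamatergic score over hippocampal spots of both groups (ties by |FC|).
A constant gene or constant score column yields similarity 0 with a warning.

## The simulator

`sim_config()` defines the study conditions; `generate_dataset()` draws
counts as NB(mean, dispersion α) with variance μ + αμ², the standard UMI
parameterization. The default grid is 40 × 25 per sample with a centered
9-row hippocampal band split into three equal CA1/CA3/DG sub-bands
(360 hippocampal spots per 1000-spot sample, inside the study's reported
300–400 band). Defaults: 1000 genes, baseline mean 0.5, dispersion 0.3,
lognormal library-size factor with CV 0.3, thirteen `mt-` genes holding ~5%
of counts, 30-gene glutamatergic and GABAergic signatures, marker structure
as above, `effect_glut = 1.5` applied multiplicatively to glutamatergic-set
genes in hippocampal spots of the affected sample, `effect_gaba = 1`,
seed 7. Effects act on NB means, not post-hoc on counts, keeping the family
closed.

Two design elements give the signatures realistic biology rather than pure
independent noise:

- a per-spot lognormal **pathway activity factor** (sd 0.3) shared by each
  signature's genes in hippocampal spots of *both* groups. Without it the
  simulated GABA score has essentially zero biological variance, and at
  n ≈ 780 spots the Mann–Whitney test becomes sensitive to a minute
  composition artifact — ~30 affected-elevated genes displacing ranks in a
  1000-gene universe shifts the GABA walk by ~0.02 — that would be
  undetectable in a genome-scale universe. Spot-to-spot pathway variation
  (e.g., varying interneuron content per spot) is also simply a feature of
  real tissue.
- a **receptor-like candidate** (*Grm1*): a glutamatergic-set member with
  loading 2 on the activity factor and an extra 1.4× condition fold
  (total ≈ 2.1×), emulating a receptor gene that both passes the top tier
  and spatially tracks the pathway score — the property the candidate
  ranking is designed to reward.

`null_config()` (all condition multipliers at 1) and `de_spike_config()`
(30 genes spiked at fold 2 as the only true signal) package the calibration
and recovery conditions used by the tests and the acceptance script. The
default config carries no spiked genes.

What the simulator does *not* emulate: spatial autocorrelation beyond the
rectangular region bands, cell-type deconvolution mixtures, batch effects
between samples, genome-scale gene universes (10⁴⁺ genes), or the ~15
non-hippocampal clusters of a real brain section. Passing tests therefore
demonstrate the pipeline's correctness and calibration under NB sampling
with the study's design parameters — not performance on real tissue, where
marker quality, segmentation of regions, and overdispersion structure are
all harsher.

## Numerical choices and degenerate inputs

- Scoring problem sizes: oracle-equivalence tests enumerate instances up to
  8 genes × 5 spots; end-to-end ensembles use 20 seeds of the default
  two-sample design and 10 seeds of the null design, sizes at which the
  whole suite runs in a couple of minutes on one core.
- Seeded determinism throughout: `generate_dataset()` restores the global
  RNG state; two pipeline runs with one config are byte-identical, which a
  test asserts file by file.
- Degenerate inputs fail loudly with the offending name: empty QC result,
  all-zero spots at normalization, marker sets absent from the matrix, a
  set covering no or every gene, groups with fewer than two spots.
- Gene symbol collisions on read are suffixed `.1`, `.2` in file order
  rather than dropped.

## Known limitations

- The marker-score/threshold stand-in for manual region curation is a
  documented deviation; its accuracy is quantified only on simulated bands.
- The rank-sum DE test ignores the count nature of the data; with very low
  counts and heavy ties its power trails count-model tests, which is the
  price of exact testability. Thresholds are unchanged from the study.
- Median-split proportions depend on the pooled-median reading discussed
  above; if the original split was computed otherwise, absolute proportions
  (not the qualitative contrast) would shift.
- The headline percentages of the motivating study are not reproducible
  without its undeposited raw data; the package reproduces the *procedure*
  and validates it on ground-truthed simulation instead.
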