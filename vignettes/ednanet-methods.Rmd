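---
title: "ednanet: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ednanet: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ednanet` implements an end-to-end analysis of multilocus eDNA
metabarcoding time series: occupancy-based OTU filtering, proportional
decontamination, an amplification-bias-robust abundance index, a
permutation-calibrated Kendall correlation, unsigned weighted-network
module detection, and module/taxon-environment association. This
vignette records the models, their assumptions, the tunable parameters,
and the design decisions taken where the method description left the
design open.

## 1. The occupancy model

Each field sample (one water sample at one time point) is assayed by K
PCR replicates. For a single OTU with detections `k` out of `K` at each
sample, the zero-inflated binomial likelihood

$$L(\psi, p) = \prod_{\text{samples}} \left[\psi \binom{K}{k} p^k
(1-p)^{K-k} + (1-\psi)\,\mathbb{1}\{k=0\}\right]$$

is maximized over the unit square by a coarse 0.01 grid refined with
bounded quasi-Newton optimization; exact ties break toward smaller
$\psi$. OTUs with $\hat\psi < 0.8$ (strictly; the boundary is kept) are
eliminated. One $(\psi, p)$ pair is pooled across all field samples — no
detection covariates, no priors.

Two behaviours deserve note. First, degenerate histories sit at the
boundary: all-detected gives $(\hat\psi, \hat p) = (1, 1)$ and
never-detected gives $(0, 0)$, with $p$ unidentifiable in the latter
case and reported as 0 by convention. Second, $\hat\psi$ is **not
monotone** in added certain-detection samples: appending a $k = K$
sample to the history $(1,1,2,2,3,0)$ with $K=3$ *lowers* $\hat\psi$
from 0.921 to 0.901, because the added detection raises $\hat p$, which
in turn makes the $k=0$ sample stronger evidence of true absence. The
test suite pins this counterexample against an exhaustive grid search
rather than asserting the (false) monotonicity.

The 0.8 threshold interacts with seasonality: a taxon genuinely absent
at more than 20% of time points is eliminated by construction. The
synthetic default world therefore keeps taxa *detectable* (not
necessarily abundant) at most time points, which matches the intuition
that eDNA persists at low concentration year-round; the filter's job is
the removal of sporadic false positives, and a dedicated simulation test
verifies the separation (ψ = 0.95 vs ψ = 0.2 classes at 50 samples).

## 2. Decontamination and replicate quality control

The per-OTU contamination proportion $c_i$ is estimated from negative
controls and extraction blanks; "most likely proportional contribution"
is interpreted conservatively as the **maximum** proportion across
control columns (a `mean` estimator is available via config). Field and
control proportions are floored at zero after subtracting $c_i$ and
renormalized, so downstream tables remain proportions. Renormalization
after flooring means a second application of the same profile is not a
no-op in general, but rows already at zero stay at zero (tested).

Replicate QC uses Bray–Curtis dissimilarity
$BC(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)$ on within-sample
proportions. A sample is dropped when its **maximum** pairwise replicate
dissimilarity exceeds 0.49 — strictly greater, so a replicate pair at
exactly 0.49 is retained. The 0.49 value is a config default taken from
the method description, not re-derived from a model of replicate
dissimilarities. Two all-zero replicates have BC = 0 by convention;
single-replicate samples pass trivially.

## 3. The eDNA index and the ensemble

After QC, OTU counts are agglomerated to the most specific rank at or
above Family, proportionalized within samples, and scaled within taxa:
$\mathrm{index}_{ij} = p_{ij} / \max_j p_{ij} \in [0, 1]$, with
$0/0 := 0$ (flagged, not missing). The assumption doing the work is that
primer–template amplification bias is constant across samples within a
taxon–locus pair, so the index is invariant to the (unknown)
multiplicative bias and to per-sample library size — both are tested
properties.

A locus that never detects a taxon carries no information about it, so
the ensemble index averages, cell-wise, only the loci that detect the
taxon **somewhere** (not per time point: a genuine within-locus zero at
a single time point is information and is averaged in). The per-time-
point alternative is available by modifying the detection rule.

One honest limitation: the index is compositional. Within-sample
proportions share a time-varying denominator (the whole community), so
even a noiseless community gives module-summary series whose *ranks*
deviate from the latent dynamics. At the default scenario's seed this
costs one of four planted module–environment pairs ~0.06 of Spearman
correlation. Nothing in the pipeline corrects for compositionality; the
tests document the distortion instead of hiding it.

## 4. Correlation and the permutation null

With eight time points and many zeros, series are short and tie-heavy;
the pairwise statistic is Kendall's tau-b with tie correction,

$$\tau_b = \frac{C - D}{\sqrt{(n_0 - n_1)(n_0 - n_2)}},$$

computed for all pairs at once by recording the sign of every
column-pair difference (ties are the zero signs; the concordant-minus-
discordant counts become one cross-product). Constant series have
undefined tau; such pairs are excluded from testing and from the network
and are listed in an audit attribute.

The null is empirical: each of `n_perm = 100` null datasets permutes
every taxon's values independently across time points (preserving each
taxon's value distribution, destroying cross-taxon association), and all
pairwise tau-b values are pooled. P-values are two-sided on magnitude
with add-one smoothing, $p = (1 + \#\{|\tau_0| \ge |\tau|\}) / (1 + N)$.
Benjamini–Hochberg step-up is applied over all unique pairs (Bonferroni
is reported alongside; the two coincide for a dominant smallest p-value,
which is the defensible reading of the original description's
equivalence remark — for *equal* p-values BH adjusts to p, not mp). The
critical tau is the smallest |tau| with adjusted p ≤ α, `Inf` if none.

Calibration is tested against exhaustive enumeration: for n = 8 untied
series the exact null is all 8! = 40,320 rank orders. Pooled permutation
tail probabilities are compared at several thresholds using the
Monte-Carlo standard error estimated across the 100 null datasets
(pooled taus within one dataset are uncorrelated but not independent, so
the naive binomial CI would be anti-conservative).

## 5. The weighted network

Unsigned soft-threshold adjacency $a_{ij} = |\tau_{ij}|^\beta$ (zero
diagonal, undefined taus → 0), topological overlap

$$\mathrm{TOM}_{ij} = \frac{\sum_u a_{iu}a_{uj} + a_{ij}}
{\min(k_i, k_j) + 1 - a_{ij}},$$

average-linkage clustering on $1 - \mathrm{TOM}$, and a static cut at
`cut_quantile` × the **maximum merge height** (default 0.99, the classic
"tree" variant of dynamic branch cutting). Branches with ≥ `min_size`
(default 5) leaves become modules; smaller branches merge into the
module with the highest mean TOM to their members, else "unassigned".
Labels are colour-style names ordered by module size, with "unassigned"
reserved.

Two design decisions here were forced by implementation evidence:

- **Cut height.** Reading the static cut as the empirical 0.99-quantile
  of the merge-height *distribution* severs fewer than one merge at
  n ≈ 100 leaves ((1-q)(n-1) ≈ 0.7) and returns a single module on the
  package's own default scenario. The fraction-of-maximum reading
  recovers the planted modules and matches field practice (cutreeDynamic's
  `cutHeight` is a fraction of the height range).
- **β default.** The scale-free topology criterion is exposed
  (`beta = "auto"`: smallest candidate with log–log $R^2 \ge 0.8$ and
  negative slope, argmax-$R^2$ fallback with a warning) and verified on a
  constructed power-law network. But on an 8-point tau matrix the fit is
  weak and unstable, and a too-soft fallback exponent leaves
  between-module merge heights below any fixed cut. The pipeline default
  is therefore the published operating point β = 22; selection remains
  one flag away.

Intramodular connectivity is $k_i = \sum_{j \in \text{module}} a_{ij}$;
the top 10% per module (ties broken by taxon id) are reported, plus the
per-module hub (argmax k), plus an edge list thresholded at weight 0.2 —
the visualization rule — so both the weighted and the thresholded
"edge count" notions of connectedness are in the output.

## 6. Environment association

Module profiles (richness = taxa with index > 0 per time point, and mean
ensemble index) are correlated with each environmental variable by
Spearman and Pearson; taxon-level series likewise (Spearman default,
taxa ordered for presentation by clustering their tau matrix). Within a
module, the Spearman correlation between $k_i$ and the taxon-level
environmental correlation $r_i$ quantifies whether hubs track the
driver. With eight time points these p-values are weak evidence; they
are reported, never used to filter.

## 7. The synthetic community generator

The generator is the package's test bed; its defaults are the stated
world of the recovery tests: 120 taxa (10% terrestrial contaminants), 6
planted modules, 8 time points × 3 PCR replicates, 4 loci, library size
20,000 reads, detection probability 0.9 per replicate, contamination
rate 2%, 4 controls at 5% depth, lognormal noise σ = 0.3, 2 OTUs per
taxon.

**Archetypes.** Each module's seasonal profile is a smoothed Gaussian
random series rescaled to a fixed natural-log range of 5 (~150-fold peak
to trough), redrawn until every archetype peaks at its own time point
and all pairwise archetype |tau| ≤ 0.55. The rejection criterion is not
cosmetic: the original plan of unimodal Gaussian bumps makes the two
edge-peaked modules exact rank mirrors (tau = −1 at σ = 0), and an
*unsigned* network cannot distinguish tau = −1 from tau = +1, so exact
recovery of the planted modules would be mathematically impossible —
for any β, at any noise level. Circular (seasonally recurrent) bumps
fail the same way through anti-phase pairs. Bounded pairwise archetype
similarity is exactly the condition under which the unsigned method is
well-posed, and the generator states it explicitly.

**Observation model.** Taxon-by-locus efficiencies are log-normal(0, 1)
with a 25% exact-zero spike (primers that never amplify a taxon; any
taxon left with no amplifying locus is reassigned one, since it would
otherwise be unobservable). Efficiencies are constant across samples —
the assumption the eDNA index needs. Detection failure is Bernoulli per
taxon and replicate; reads are multinomial at fixed depth, mixed with a
terrestrial contaminant pool at the contamination rate; controls draw
from the pool alone at 5% depth. A configurable `corrupt_timepoint`
scrambles one replicate to plant a replicate-QC failure. All randomness
flows through one seeded generator (`withr::with_seed` on derived
sub-streams); identical scenario + seed is bit-identical, and written
outputs contain no wall-clock content so output directories are
byte-identical too.

**What a green test establishes — and what it does not.** The generator
emulates amplification bias, detection dropout, contamination,
replicate noise and compositional read sampling, so the recovery tests
exercise every pipeline stage against a known truth. It does not emulate
sequence-level artifacts (chimeras, tag-jumping structure), taxonomic
misannotation, spatial structure, unbalanced replication, or overdispersed
(non-multinomial) read noise; recovery under those stresses is untested.
Archetype distinctness is enforced, so the tests say nothing about
communities whose true modules are near rank-mirrors — on such data the
unsigned method will merge anticorrelated groups by construction.

## 8. Numerical conventions

- 0/0 → 0 (flagged) in proportions and indices; all-zero columns are
  legal and flagged.
- Occupancy ties break toward smaller ψ, then smaller p; optimizer
  results within 1e−6 of a boundary snap to it.
- `findInterval` tail counts use a 1e−12 tolerance so floating-point
  ties (e.g. tau = 5/7) land on the ≥ side.
- Average-linkage merge heights are clamped monotone (`cummax`) before
  cutting; inversions at the 1e−15 level otherwise break `cutree`.
- Module labels are deterministic: sizes, then the colour palette;
  partitions are invariant to taxon order (tested up to renaming).
- Boundary semantics: ψ̂ ≥ 0.8 retained; BC > 0.49 dropped (0.49
  retained); edge weight > 0.2 shown.

## 9. Known limitations

- The occupancy filter, as specified, removes genuinely seasonal taxa
  absent at > 20% of time points; real datasets with strong absences
  need either a lower threshold or a false-positive-aware occupancy
  model (not implemented).
- The permutation null preserves each taxon's marginal values but not
  temporal autocorrelation; for strongly autocorrelated series the null
  is anti-conservative.
- The unsigned network cannot separate anticorrelated modules; a signed
  variant would, but is out of scope.
- With 8 time points, tau is coarse (28 concordances) and the critical
  tau is quantized; module–environment p-values are descriptive only.
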