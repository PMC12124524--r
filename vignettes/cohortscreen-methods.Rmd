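---
title: "Methods: donor-variable drug response analysis with cohortscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: donor-variable drug response analysis with cohortscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortscreen)
```

# Overview

`cohortscreen` implements an analysis pipeline for multi-donor,
multi-drug Cell Painting screens of induced pluripotent stem cell (iPSC)
lines, together with responder-stratified differential proteomics. The
scientific question it serves is: *when a panel of donor-derived cell
lines is exposed to the same drug, how variable is the morphological
response across donors, and what molecular differences separate strongly
and weakly responding lines?*

The pipeline stages are:

1. **Data model** — well-level feature tables with mandatory metadata
   columns (`run_id`, `plate_id`, `well`, `donor_id`, `drug_id`,
   `dose_uM`, `bioreplicate`, `tech_replicate`, `n_cells`) and
   arbitrarily many numeric morphology features.
2. **Normalization** — per-plate robust Z-scores against DMSO controls.
3. **Feature filtering** — a coefficient-of-variation (CoV) filter on
   DMSO wells and a Spearman redundancy filter.
4. **Phenotype metrics** — the induction score, Euclidean
   distance-to-control, drug–drug induction correlation, and
   low-dimensional embeddings (PCA/UMAP).
5. **Cross-run comparison** — per-feature Earth Mover Distances (EMD)
   between replicate assay runs, calibrated against a DMSO noise band.
6. **Stratified proteomics** — donors are split into high and low
   responders by induction rank, and protein-level drug effects are
   tested within each stratum with a permutation-based FDR.

Every stage is backed by a plate-structured synthetic screen generator
and a DIA-style proteome generator with known ground truth, so the whole
pipeline is testable end to end without external data.

# Normalization: per-plate robust Z

For each plate and feature, let $\mu$ be the median and $M$ the raw
median absolute deviation (MAD, no consistency constant) of the DMSO
control wells on that plate. Every well value $x$ on the plate is scored
as

$$ z = \frac{x - \mu}{c \cdot M}, $$

with `mad_scale` $c = 1.4826$ by default. The constant makes the scaled
MAD a consistent estimator of the standard deviation under normality, so
that $|z| > 2$ corresponds to the familiar Gaussian two-sigma tail
(fraction $2\Phi(-2) \approx 0.0455$ under the null). Passing
`mad_scale = 1` recovers the literal median/MAD form of the score; both
conventions are tested. Features whose DMSO MAD is exactly zero on some
plate cannot be scaled and are dropped with a record in the
`flagged_features` attribute. `check_robust_z()` re-derives the control
contract — DMSO median 0 and scaled MAD 1 on every plate for every
retained feature — and is used as an oracle in the tests.

# Feature filters

**CoV filter** (`filter_cov`, default `max_cov = 0.50`): for each
feature, the sample standard deviation divided by the absolute mean over
the *pooled raw-scale DMSO wells of all plates* must not exceed 0.50.
Pooling is a deliberate policy choice: the filter asks whether a feature
is stable under control conditions across the whole run, not within one
plate. Features with a zero mean (undefined CoV) are reported separately
rather than silently kept or dropped. Fewer than three DMSO wells is an
error because a sample SD of one or two values is not a meaningful
stability estimate.

**Spearman redundancy filter** (`filter_spearman`, default
`max_abs_s = 0.98`): features are scanned greedily in their column
order; a feature is removed if its absolute Spearman correlation with
any *already retained* feature exceeds 0.98. Greedy-in-fixed-order makes
the result deterministic and order-reproducible; the removal report
records, for each dropped feature, the retained partner and the
correlation that triggered removal. The procedure is idempotent, and all
retained pairs are verified to sit below the threshold.

# Induction

For a donor–drug pair, aggregate the robust Z-scores to one profile
(median over wells by default — the median is robust to a single
outlying well and matches the robust spirit of the normalization), then

$$ \text{induction} = \frac{\#\{\,\text{features } f : |z_f| > \sigma\,\}}
                           {\#\{\,\text{features with a valid } z_f\,\}}, $$

with $\sigma = 2$ by default. Missing features are excluded from both
the numerator and the denominator, so a profile of $z = (3,
\mathrm{NA}, 0)$ has induction $1/2$. Induction lies in $[0,1]$ and is
non-increasing in $\sigma$; both invariants are tested on a grid. Under
a pure-noise null with `mad_scale = 1.4826`, induction is calibrated to
$2\Phi(-2)$, which the acceptance suite checks to within 0.01 over
120{,}000 feature scores.

# Earth Mover Distance between runs

Cross-run reproducibility uses the one-dimensional EMD between the
distributions of well-level z-scores of the same (donor, drug, feature)
in two runs. For empirical distributions with uniform weights the 1-D
optimal transport cost has a closed form via sorted quantile functions,
which `emd_1d()` implements. The implementation is verified against two
independent oracles: the integral $\int |F_a - F_b|\,dx$ of the ECDF
difference, and brute-force enumeration of all assignments after
replicating both samples to their least common multiple size.

Per (drug, feature), the EMD is summarized as the median over shared
donors. A *DMSO noise band* — the 95th percentile of DMSO-vs-DMSO EMDs
across shared donors — defines how large an EMD can be while still being
explained by assay noise. Drugs whose features consistently exceed the
band (for example cytotoxic compounds, which distort morphology and
well occupancy) are flagged as irreproducible between runs.

# Responder stratification and differential proteomics

Donors are ranked by induction for the chosen drug; the top $k$ form the
high-responder stratum and the bottom $k$ the low-responder stratum.
Ties at a stratum boundary are broken lexicographically by `donor_id`
and the policy is recorded in the result.

Proteomic intensities (log2) are processed as in standard DIA practice:

* `filter_valid()` keeps proteins quantified in at least one third of
  runs (inclusive boundary).
* `impute_missing()` draws from a per-run downshifted normal with width
  $0.3\,s$ and downshift $1.8\,s$ ($s$ = per-run SD of observed
  values) — the conventional defaults for left-censored
  missingness, reflecting that DIA missingness concentrates at low
  abundance.
* `median_normalize()` equalizes run medians.

`stratified_differential()` computes, per protein, the drug-vs-DMSO
log2 fold change and Student *t*-test separately within the high and the
low stratum. A protein is called a *responder-interaction* hit when it
passes the dual significance gate $P_\text{high} \le 0.05$ **and**
$P_\text{low} \le 0.05$ and the fold-change gate
$|\log_2 FC_\text{high} - \log_2 FC_\text{low}| > 0.263$ (a 1.2-fold
difference between strata). The dual-P gate demands that the drug effect
is *measurable* in both strata; the FC gate demands that its *size
differs* between them.

**Permutation FDR.** Where permutation-based error control is requested
(`pooled_volcano`, `differential` with `n_permutations > 0`), group
labels are permuted, and for each protein the q-value is the median over
permutations of

$$ q = \frac{\#\{\text{null } |t| \ge |t_\text{obs}|\}}
            {\#\{\text{observed } |t| \ge |t_\text{obs}|\}}, $$

clipped to $[0,1]$ and made monotone non-increasing in $|t|$ (so a more
extreme statistic never receives a larger q). Proteins with zero
variance in both groups have no defined *t* and are flagged rather than
scored.

# The synthetic screen generator

`screen_sim_config()` freezes the generative model; its defaults are the
study conditions under which all guarantees are stated.

**Screen dimensions.** 28 donors × 52 drugs (+ DMSO) × 871 features,
13 mechanism-of-action (MoA) classes, 6 technical replicate wells × 2
biological replicates, 384-well plates with 24 DMSO wells per plate
assigned round-robin across the donors on the plate (every plate carries
its own controls, which the robust-Z contract requires).

**Effect model.** Each MoA class has a sparse signed signature: 25% of
features are affected, with entries $\pm U(0.2, 1) \times 3$. The
spread down to 0.2 is deliberate: if all affected features carried
near-maximal weight, strong responders would push *every* affected
feature past $2\sigma$ and induction would saturate at the sparsity
level, producing ties that destroy rank information. With graded
weights, induction remains monotone in the underlying responsiveness.
Each (donor, MoA) pair has a log-normal response magnitude
(`magnitude_sdlog = 0.5`); donors in the top/bottom quartile of
magnitude for a drug's MoA are the planted high/low responders.
Well-level noise is $N(0, 1)$ plus a per-plate shift
($\mathrm{SD} = 0.2$) that the per-plate normalization must remove.
Optional cytotoxic drugs inflate well-level variance 3× and reduce cell
counts, which is what the cross-run EMD band is designed to flag.

**Proteome model.** 5{,}895 proteins with baseline log2 abundance
$N(25, 2)$, run-level noise $\mathrm{SD} = 0.2$, and logistic
intensity-dependent missingness centred at 21.5 with scale 0.5. The
scale was set by the detection-limit interpretation: DIA missingness is
a fairly sharp threshold phenomenon, and a scale of 0.5 keeps
missingness negligible two SDs above the midpoint while censoring the
low tail. Planted differential proteins (100 shared, 50
responder-interaction) are drawn from proteins above the 30th abundance
percentile — planting effects into proteins that sit below the
detection limit would test the imputation, not the statistics.
Interaction effects are `effect_high = 1.1` and `effect_low = 0.5` log2
units. The low-stratum effect must be non-zero because the dual-P gate
requires significance in *both* strata; 0.5 log2 units at noise
$\mathrm{SD}=0.2$ with 6-vs-6 runs gives about 97% power for the
low-stratum test, so the planted interactions are recoverable by design
while remaining far from trivial (the strata differ by 0.6 log2 units,
close to the 0.263 gate relative to fold-change noise).

# Test problem sizes

The test and acceptance suites run on scaled-down instances (for
example 8–16 donors, 6–10 drugs, 60–300 features, 600–1,500 proteins,
250 permutations) chosen so the full suite completes in minutes while
keeping enough replication for stable statistics: 20 seeds for the
stratification and proteomics guarantees, 1,000 random instances for the
EMD oracle comparison, and 120,000 feature scores for the null-induction
calibration. Effect and noise parameters are never changed from the
study defaults in these tests — only the problem dimensions are.

# Worked example

```{r example, eval = FALSE}
cfg <- screen_sim_config(n_donors = 8, n_drugs = 6, n_features = 60,
                         n_moa_classes = 3, cells_per_well = c(50, 80))
gs <- generate_screen(cfg, seed = 1)

z <- robust_z(gs$table)
z <- select_features(z, intersect(feature_names(z),
                                  filter_cov(gs$table)$retained))
z <- select_features(z, filter_spearman(z))

im <- induction(aggregate_features(z, "donor_drug"))
st <- stratify_responders(im, "drug01", k = 2)

q <- generate_proteome(cfg, gs$truth, c(st$high, st$low), "drug01",
                       seed = 2)
q <- median_normalize(impute_missing(filter_valid(q)))
res <- stratified_differential(q, st$high, st$low, "drug01")
res$surviving
```

# Limitations

* The generator produces well-level summaries directly; it does not
  simulate single cells, segmentation error, or spatial plate artefacts
  beyond an additive per-plate shift.
* Feature noise is Gaussian and independent across features given the
  MoA signature; real Cell Painting features have heavier tails and a
  block correlation structure, which is why the Spearman filter matters
  more in practice than in simulation.
* Proteome missingness is a function of abundance only; peptide-level
  effects, interference, and batch effects beyond a run shift are out of
  scope.
* The permutation FDR enumerates random label permutations; with very
  small group sizes the number of distinct permutations is limited and
  q-value resolution is correspondingly coarse.
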