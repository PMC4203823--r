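---
title: "Biogeochemical typing: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biogeochemical typing: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

BGC typing treats an environmental survey as two matrices over the same
ordered sampling points: a *community* matrix of OTU relative abundances
(fused from per-domain amplicon tables: Archaea rRNA, 16S rRNA, 18S rRNA)
and a *chemicals* matrix of measured chemical variables (element
concentrations in ppm, FT-IR region integrals, ¹H-NMR bucket integrals).
The working assumption is monotone co-fluctuation: an OTU belongs to a
biogeochemical sub-system if its abundance rises and falls with some of
the chemical variables across sampling points.  Spearman's rank
correlation is the natural association measure under that assumption —
it is invariant to the unknown, platform-specific monotone calibrations
of each measurement, and insensitive to the heavy right tails of
abundance data.

The pipeline is three steps.

**Filtration.** Each OTU row is correlated against each chemical row;
an OTU is retained when at least one defined coefficient reaches the
threshold in magnitude (inclusive, default |ρ| ≥ 0.70).  Rank
correlations over few sampling points are noisy, so the threshold is
deliberately high; it selects OTUs whose trend is strong enough to
survive ranking with n ≈ 14 points.  Undefined coefficients (constant
profiles) are masked and never count toward retention — a flat profile
shows no trend.  This is also why singleton OTUs (one read over all
sampling points) are removed beforehand: their profile is a single spike
whose rank pattern is meaningless.

**Organization.** The retained OTU × chemical correlation matrix is the
object that gets clustered: each OTU is represented by its correlation
signature, not by its raw abundances, so OTUs cluster together when they
relate to the chemistry in the same way.  The number of types is chosen
from the within-cluster sum-of-squares curve of k-means for k = 1…15,
taking the k that maximizes the discrete second difference
w[k−1] − 2w[k] + w[k+1] (the curve's inflexion).  Ties break toward
smaller k, and a curve with no positive second difference is flagged
"no elbow" with a warning — the full second-difference profile is
attached to the selection so a user can override k.  PCA of the same
matrix provides the score plane on which the types are displayed and the
loadings used by the Description step.

**Description.** Each type is summarized three ways: the per-sampling
point sum of its members' relative abundances (per domain); a taxonomy
breakdown collapsed at the class rank, with lineages that stop short of
class collapsed at their deepest available rank and lineage-free OTUs
grouped as "Unassigned", weighted by total relative abundance; and a
chemical profile.  For the profile, the *average correlation index* of a
type is the arithmetic mean of ρ over its member OTUs, per chemical
variable.  It is compared against the loadings of the principal
component that better explains the type — the PC (among the first two)
with the larger absolute mean score over the type's members.  Because a
PC's sign is arbitrary, the loading vector is flipped when it
anti-correlates with the type's average-correlation vector.  Per
variable, the population standard deviation of the two-element set
{average ρ, loading} — |a−b|/2 — measures how far the type's own
association departs from what the global component structure attributes
to that variable; variables with STDEVP ≥ 0.20 whose raw average
correlation is positive are extracted as the type's chemical signature.

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `threshold` | 0.70 | minimum max-|ρ| (unitless, inclusive) for an OTU to be retained |
| `k_max` | 15 | largest cluster count tested on the WCSS curve |
| `k` | `NULL` | explicit type count; `NULL` selects the elbow |
| `stdevp_cut` | 0.20 | minimum STDEVP for a chemical variable to be extracted |
| `stdevp_compare` | `"raw"` | pair the STDEVP is computed on (see below) |
| `cluster_space` | `"corr_rows"` | k-means space: full correlation rows or first two PC scores |
| `centering` | `"mean"` | PCA column centering (no variance scaling either way) |
| `n_init` | 50 | k-means restarts per k |
| `min_total` | 2 | minimum total reads for an OTU to survive the singleton filter |

The defaults are the survey values the pipeline was built around.

# Design choices

**Clustering space.** k-means on the full correlation rows is exactly
equivalent to k-means on all mean-centered PC scores (Euclidean
distances are preserved under the orthogonal rotation), which the test
suite asserts.  The `pc_scores_2d` option clusters the first two PC
scores instead, reproducing a delimitation drawn on the score plot;
the two agree when the first two components carry the block structure,
but `corr_rows` is the default because it uses all the information.

**PCA centering.** Columns are mean-centered and not variance-scaled:
every entry is already a correlation on a common scale, so scaling would
only amplify noise columns.  `centering = "none"` is available for
sensitivity analysis.

**k-means.** `stats::kmeans` (Hartigan–Wong) with `n_init` random
starts, best total within-SS kept, under a caller-supplied seed.
Restarts rather than a particular seeding heuristic guard against bad
local minima; with 50 restarts on these problem sizes the WCSS curve is
reproducibly non-increasing.  Cluster labels are renumbered by
descending size (ties by smallest member id) so "type 1" is stable
across runs.  The boundary case k = n is returned exactly (0) since the
Hartigan–Wong routine does not accept it.

**Elbow rule.** The visual "curve inflexion" is formalized as the
discrete second difference.  It is reported alongside the chosen k, and
the fit accepts an explicit `k` so a user can overrule the rule — the
curve itself is always part of the output.

**STDEVP comparison mode.** Whether the STDEVP is computed on the raw
pair (average ρ, sign-oriented loading) or on the pair after each vector
is scaled to unit variance without centring is a genuine ambiguity: the
unit-variance scaling is naturally tied to overlaying the two curves in
a single plot, while the extraction cut of 0.20 reads most naturally on
the raw bounded scales (a mean of correlations and a unit-norm loading
entry).  Both modes are implemented.  The default is `"raw"`: on clean
planted-block data the *scaled* average-correlation and loading curves
of the type that dominates its explaining component coincide almost
everywhere, so that type's own variables never clear the cut — the
scaled mode structurally cannot recover planted assignments, and it is
kept only for sensitivity analysis.  Scaled curves are still reported in
the profile table (`scaled_avg_rho`, `scaled_loading`) for plotting.

**Positive-correlation rule.** Extraction requires the raw average ρ to
be positive: a type's chemical signature lists the variables it rises
with.  Negatively associated variables are never listed, whatever their
STDEVP.

**Undefined correlations.** Constant OTU or chemical profiles yield
undefined ρ; these are masked (`NA`) in the correlation matrix and
treated as 0 ("no trend") wherever a complete matrix is required
(PCA, k-means).  They can never satisfy the retention threshold.

**Sample alignment.** Sample ids must match exactly, in order, across
all tables; nothing is reordered silently, because a silent permutation
would corrupt every correlation downstream.

# The synthetic generator

`generate_bgc_dataset()` plants `n_types` association blocks over
`n_samples` sampling points.  Each type g has a latent factor f_g; member
OTU intensities are `6 + 2(f_g + ε)` (or `exp(1.2(f_g + ε))` for the
monotone-nonlinear link) and member chemical values `10 + 4(f_g + ε)`,
with ε ~ N(0, `noise_sd`²).  OTU counts are drawn multinomially per
sampling point at `sequencing_depth` reads within each of three domain
tables (members are dealt round-robin across archaea/16S/18S, so types
span domains, as they do in real surveys); chemical variables are dealt
round-robin across icp/ftir/nmr.  Null OTUs and null chemical variables
are independent noise; singleton OTUs carry exactly one read at a random
sampling point.

**Latent factor geometry.** The factors are regular-simplex contrasts of
a random orthonormal basis over the sampling points: unit population
variance, pairwise correlation −1/(n_types − 1), and exact sum-to-zero
across types at every sampling point.  Two properties motivated this
over raw independent draws.  First, with only 14 sampling points,
independent factors carry chance Spearman correlations up to ~0.5, so
the "distinct" planted blocks are frequently not distinct and the WCSS
elbow legitimately lands at k = 2 — the design would not deliver the
conditions it claims.  Second, sum-to-zero factors cancel out of the
per-sample intensity total, so the multinomial proportions of one type's
members are not distorted by the other types' trends; the residual
negative pairwise correlation also mirrors the compositional reality
that one group's bloom is another's dilution.

**Amplitude and depth.** The signal amplitude (2 for OTU intensities
against a baseline of 6) was calibrated once so that noise-free planted
blocks stay rank-faithful through multinomial sampling at the default
depth of 1e5 reads.  Even noise-free, within-block OTU–chemical Spearman
correlations are not exactly 1: relative abundances share a per-sample
intensity denominator, and 14 sampling points typically contain
near-tied factor values whose ranks flip under any sampling noise.  The
median within-block coefficient is ≈ 0.98–0.99 with occasional pairs
near 0.9, a floor that persists at 100× the default depth; the chemical
side, which passes through no sampling, is exactly rank-identical within
blocks at zero noise.  Tests assert these oracle-measured properties
rather than an idealized 1.0.

**What the generator does not emulate.** Real amplicon data have
sequencing error, chimeras, taxonomy misassignment, library-size
variation, zero inflation far beyond multinomial sampling, and thousands
of rare OTUs; real spectra have baseline drift, peak overlap and
platform-specific noise.  Passing the recovery tests therefore shows the
pipeline's statistical machinery is sound under its own assumptions, not
that the |ρ| ≥ 0.70 / STDEVP ≥ 0.20 defaults are optimal for any given
real survey.

**Free parameters chosen once.** `n_null_otus = 30`,
`n_singleton_otus = 10`, `n_null_chems = 6` and
`sequencing_depth = 1e5` are not prescribed by the survey design; they
were set to values a field survey of this size would consider realistic
(roughly a quarter of OTUs uncorrelated, a handful of uninformative
chemical variables) and left alone.

# Validation and problem sizes

The test suite validates each operation against independent oracles:
Spearman against a hand-written rank-then-Pearson implementation on all
length-4 permutation pairs and 200 random tied vectors; the WCSS curve
against exhaustive-partition minima on 6-row instances; conservation
identities (normalized columns sum to 1, per-type distributions sum to
the filtered subset's column sums, scaled vectors have unit mean square)
at 1e-12.  End-to-end recovery runs the full pipeline on 20 generator
seeds at the default conditions (4 types × 25 OTUs × 5 chemicals,
14 samples, noise 0.1): the elbow must return k = 4 with adjusted Rand
index ≥ 0.9 against the planted types in at least 18 of the 20 runs, and
extracted chemical variables must reach pooled precision and recall
≥ 0.8 against the planted assignments.  These sizes keep the whole suite
under a minute on one CPU while leaving each k-means problem
(≈ 100 × 26) large enough to be non-trivial.

# Known limitations

* The elbow rule is a formalization of a visual judgement; on curves
  with two comparable kinks it picks the smaller k and should be
  overridden via `k` after inspecting the reported second differences.
* The explaining PC is restricted to PC1/PC2.  With more than ~4 types
  the discriminating contrast for some type may live on a later
  component, and the type's chemical profile will be computed against a
  poorly matched loading vector.
* Spearman with n ≈ 14 has a granularity of ≈ 0.005 per rank swap;
  thresholds tighter than ~0.05 on ρ are not meaningful at this sample
  size.
* No multiple-testing control is applied — filtration is by magnitude
  only, by design; retained-but-spurious OTUs are expected at a rate set
  by the threshold and the number of chemical variables.
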