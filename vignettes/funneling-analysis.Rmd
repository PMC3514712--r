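---
title: "Methods: testing developmental axes of cranial shape covariation"
author: "funnelmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: testing developmental axes of cranial shape covariation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funnelmorph)
```

# The question and the statistical design

Craniofacial shape is genetically very complex, yet a long-standing idea in
evolutionary developmental biology holds that most of that complexity
"funnels" through a handful of high-level processes — the growth of the
brain, of the cartilaginous cranial base, and of the body as a whole. If so,
the shape change produced by a discrete perturbation of one such process
(say, a mutation that enlarges the brain) should coincide with an axis of
covariation already present in normal populations, and its magnitude should
be predictable from normal allometry.

The package operationalizes this as a five-stage pipeline:

1. **Superimposition.** Generalized Procrustes Analysis (`gpa()`) of all
   landmark configurations, followed by orthogonal projection onto the
   tangent space at the consensus.
2. **Predictors.** Scalar size variables on their analysis scales: cube-root
   brain volume (mm), chondrocranial length as the hormion–opisthocranion
   distance measured on raw coordinates (mm), and overall size as natural-log
   centroid size (`measure_predictors()`).
3. **Normal covariation.** Pooled within-sex multivariate regression of
   tangent shape coordinates on one predictor
   (`pooled_within_regression()`), with percent variance explained,
   projection scores, and a within-stratum permutation test.
4. **Perturbation effect.** Difference between group mean shapes in a joint
   superimposition (`group_contrast()`), its Procrustes distance, and a
   label-permutation test.
5. **Funneling comparison.** Observed contrast distance versus the distance
   the regression predicts for the observed predictor shift, plus the angle
   between the two shape-change vectors (`funneling_comparison()`).

# Superimposition

Configurations are centered, scaled to unit centroid size, and iteratively
rotated to the evolving consensus using proper rotations only — reflections
are biologically meaningless for homologous unilateral landmark sets, so the
Kabsch solution is constrained to `det(R) = +1` by flipping the smallest
singular direction when necessary. A deterministic sign convention on the
singular vectors (largest-magnitude entry made positive) fixes the rotation
even for degenerate cross-products. Iteration stops when the consensus moves
less than `tol = 1e-10` (root-sum-square) between rounds, with
`max_iter = 100`; both are orders of magnitude below digitizing noise, and
non-convergence returns a flagged result with a warning rather than an
error.

After convergence the aligned, unit-size shapes are projected orthogonally
onto the tangent hyperplane at the consensus (`y = x - (<x, c> - 1) c`, with
`c` the unit-norm flattened consensus). Orthogonal projection is the common
choice in standard morphometric software; it never increases distance to the
consensus, and it makes the shape coordinates an ordinary Euclidean data
matrix for the downstream statistics.

Two consequences matter for interpretation. First, the orientation of the
consensus (and hence of every shape vector) is arbitrary — only statistics
that are rotation-invariant (distances, angles *within* one superimposition,
variance fractions, permutation p-values, projection scores) are meaningful
across runs. When vectors from two superimpositions must be compared, the
package aligns frames explicitly (below). Second, interlandmark predictors
are deliberately measured on the *raw* coordinates, before any scaling,
because they are size variables in mm.

# Pooled within-sex regression

Sexual dimorphism would otherwise masquerade as (or mask) a size effect, so
both the tangent coordinates and the predictor are centered by their sex
means and a single common slope is fitted:

$$\beta \;=\; \frac{\sum_i \tilde x_i \tilde Y_i}{\sum_i \tilde x_i^2},$$

coordinate-wise — the classical pooled within-group regression. Variance
explained is `100 * SS_pred / SS_tot` over all stratum-centered coordinates.
Projection scores deliberately use the *uncentered* deviations from the
consensus projected onto `beta / ||beta||`, so individuals of both sexes are
placed on one axis in Procrustes units; a stratum of size 1 is rejected
(its within-stratum deviations are identically zero).

`predict_shape(model, x)` is linear around the pooled predictor mean, and
`predicted_shape_change(model, delta_x) = |delta_x| * ||beta||`. A predictor
shift must always be expressed on the analysis scale — for a 17% increase of
brain volume, the shift of the cube-root predictor is
`mean * (1.17^(1/3) - 1)`, never 17% of anything on the volume scale.

# Contrasts and the funneling comparison

Procrustes distance between two average shapes only makes sense in a common
shape space, so all specimens entering a contrast (wildtype and mutant) are
superimposed jointly before group means are taken. The estimated distance is
the norm of a noisy mean-difference vector and is therefore biased upward by
sampling noise; no bias correction is applied, and the test suite documents
the bias direction.

The regression model, in contrast, is fitted on the *normal population
only*, so the funneling comparison must bridge two superimpositions. Scalars
(observed and predicted distances, their ratio) are frame-invariant. For the
angle, the regression vector is first rotated by the optimal rotation between
the two consensus shapes, and then **both** vectors are projected onto the
tangent hyperplane at the contrast's consensus before the angle is taken.
The projection step is essential: each vector is orthogonal to its own
consensus, and the two consensuses tilt relative to one another by roughly
half the mean-shape shift, so skipping the projection would inject a
spurious angle of that size even for perfectly collinear effects.

Angles are computed with the atan2 half-angle formula rather than
`acos(cos)`, which is numerically exact near 0 and 180 degrees. Angles are
only ever computed within one (bridged) superimposition; the package
deliberately offers no cross-species angle, because large mean-shape
differences between species make homologous landmark displacements
non-comparable even when the landmarks themselves are homologous.

# Permutation inference

All tests are permutation tests with a mandatory seed:

* regressions permute the predictor **within strata**, preserving the
  dimorphism structure; the statistic is the predicted sum of squares;
* contrasts permute the group labels of the two groups' specimens; the
  statistic is the mean-shape distance;
* p-values use the add-one convention `(1 + #{perm >= obs}) / (n_perm + 1)`,
  so `p = 0` is impossible and the smallest attainable value is
  `1/(n_perm + 1)`; `n_perm = 5000` is the default.

Shapes are *not* re-superimposed within permutations: the superimposition
does not depend on the permuted quantity (predictor values or group labels),
so re-running GPA would reproduce the same aligned coordinates while
multiplying the cost. p-values are bit-reproducible given seed and `n_perm`.

# Thin-plate spline visualization

Deformation grids are 2D (project a 3D shape with `project_to_plane()`
first), matching how such figures are drawn: the classical interpolating TPS
with kernel `U(r) = r^2 log r` is fitted from the reference to
`reference + magnify * (deformed - reference)` and a lattice spanning the
reference's padded bounding box is warped through it. Bending energy is the
quadratic form `w' K w` summed over output dimensions (clamped at zero
against roundoff); it vanishes exactly for affine maps. Collinear or
duplicated source landmarks make the bordered system singular and are
rejected up front. Published figures exaggerate shape changes, so the
magnification factor is an explicit argument, defaulted to 1 nowhere
user-facing, and recorded in every grid object and figure title. `magnify =
0` is allowed and yields the identity grid.

# The synthetic-data generator

No specimen collection ships with the package; instead
`simulate_population()` draws data from exactly the model class the analysis
assumes: tangent-space shapes

$$Y_i = T + \textstyle\sum_e s_e (x_{ei} - \mu_e) V_e + S\,\mathbb{1}[\text{female}_i] + E_i,$$

with latent predictors `x_e ~ N(mu_e, sigma_e)`, isotropic per-coordinate
Gaussian noise `E`, a sexual-dimorphism offset `S`, and a per-specimen
nuisance similarity transform (free rotation, translation, scale) producing
raw coordinates. Key design choices:

* **Effect vectors live in shape space.** Every `V_e` (and `S`) is projected
  into the tangent space at the template — centered, orthogonal to the
  template (scaling direction) and to the infinitesimal rotation directions —
  and stored unit-normalized with the slope carrying magnitude
  (`shape_tangent_vector()`). Variation injected along similarity directions
  would be removed again by GPA and could never be recovered; projecting
  first makes generative-recovery tests exact rather than approximate.
* **Defaults are the study conditions.** n = 48 (a wildtype inbred strain
  sample); cube-root brain volume with mean 7.7 mm and SD 0.37 mm, i.e. a
  coefficient of variation of 0.048 (the mouse regime; the human regime near
  0.10 is reached by raising the SD); slope 0.017 Procrustes units per mm,
  which with per-coordinate noise SD 0.004 puts the predictor's variance
  explained in the single-digit percent range typical of real cranial
  allometry; dimorphism offset 0.01 Procrustes units; nuisance scale uniform
  on 44–56 mm, giving a log-centroid-size CV near 0.017.
* **Reproducibility by construction.** Each specimen draws from its own
  deterministic RNG substream derived from the spec seed, so the same spec is
  bit-identical and enlarging `n` appends specimens without disturbing
  earlier ones. Mutant groups use a disjoint substream block.
* **Mutants** shift the latent mean of one predictor (shape follows through
  the effect vector) or displace the mean shape directly — never both.

The generator emulates linear tangent-space effects, independent Gaussian
noise, and balanced dimorphism. It does **not** emulate curved allometric
trajectories, spatially correlated landmark error, measurement error in the
predictors, asymmetry, or integration structure beyond the specified effect
vectors. Tests that pass on these data therefore validate the estimation
machinery, not the biological adequacy of the linear model for any real
population.

# Numerical tolerances and validation design

The exactness checks in the test suite run the generator noiselessly with
deliberately small effect amplitudes (predictor SD 1e-4, slope 0.01). Shape
space is curved: scaling to unit centroid size and projecting to a tangent
plane leave residuals of order amplitude squared, so "exact" linear-algebra
identities (variance explained = 100, funneling ratio = 1, angle = 0, beta
recovery) only hold below the asserted tolerances when the quadratic terms
sit well under them. At these amplitudes the observed errors are at or below
1e-10 against tolerances of 1e-6 to 1e-8. Vector comparisons against the
generating truth always align frames first (rotating the consensus onto the
template) because GPA's output orientation is arbitrary.

Stochastic validation uses fixed problem sizes chosen to keep the full suite
under a minute of compute while leaving comfortable statistical margins: 50
random small datasets against a per-coordinate `lm()` oracle; 500 seeded
null replicates (n = 20, `n_perm = 199`) whose rejection rates must fall in
the exact binomial 99% band around 0.05 for both tests; 200 replicates of a
100-normal/30-mutant funneling scenario with noise calibrated (SD 5e-4) so
the regression vector is estimated to within a few percent, where the
observed/predicted ratio must land in [0.8, 1.25] at least 90% of the time;
and 40 replicates each at n = 25/100/400 under the default noise, where the
median angle between estimated and true effect vectors must fall
monotonically with n.

Degenerate inputs fail fast with named errors rather than silent repair:
all-coincident landmarks, zero pooled predictor variance, single-specimen
strata, zero-norm regression vectors, empty groups, missing landmark names,
and collinear TPS sources. Missing landmarks are not imputed.

# Known limitations

* Tangent-space statistics assume shape variation is small relative to the
  curvature of shape space — standard for cranial data, but the funneling
  ratio compares distances estimated with different bias (a norm of a noisy
  mean difference is biased upward; a regression slope is not), so ratios
  from small mutant samples drift above 1 even under the null generative
  model.
* The pooled within-sex regression assumes a common slope across sexes;
  sex-specific allometry would be absorbed into the residual.
* Permutation tests assume exchangeability within strata — family structure
  or other dependence among specimens would invalidate the reported
  p-values.
* TPS grids are 2D projections; features orthogonal to the chosen plane are
  invisible, and the magnification factor must be reported with any figure.
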