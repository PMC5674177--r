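---
title: "Placing an unknown wing: methods behind wingmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Placing an unknown wing: methods behind wingmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wingmorph)
```

## The problem

Insect wings are nearly flat, rigid, species-specific structures whose vein
intersections are homologous across related taxa, and they fossilize well.
This makes wing venation one of the few characters by which a fossil bee or
other difficult specimen can be placed quantitatively: digitize the same set
of vein-intersection landmarks on the fossil and on a reference collection
of identified specimens, remove everything about the coordinates that is not
shape, and ask which reference taxon the fossil's shape most plausibly
belongs to.

wingmorph implements that pipeline for 2-D landmark configurations: GLS
(generalized least-squares) Procrustes superimposition, tangent-space
projection with an adequacy check, linear discriminant analysis (LDA)
validated by leave-one-out cross-validation, a posteriori assignment of the
unknown by posterior probability and Mahalanobis distance, and principal
component ordination. A cascade over nested reference datasets (for bees:
all tribes, then the target clade and its most similar tribes, then the
subgenera of the target genus) narrows the placement level by level.

## Shape: superimposition and the tangent space

A configuration of $k$ landmarks $X \in \mathbb{R}^{k \times 2}$ carries
nuisance information — where the wing lay under the camera, how large it
was, how it was rotated. `preshape()` removes translation (centroid to the
origin) and size (centroid size
$\mathrm{CS} = \sqrt{\sum_i \lVert x_i - \bar{x} \rVert^2}$ scaled to 1).
`gpa()` then iteratively rotates all preshapes onto a provisional consensus
and re-estimates the consensus as their mean (rescaled to unit size) until
the consensus moves less than `tol` between iterations.

Numerical choices:

* **Convergence**: `tol = 1e-10` on the consensus movement, `max_iter =
  100`. For $k = 18$ and samples up to a few hundred specimens the loop
  converges in well under ten iterations; the cap only guards pathological
  input. Non-convergence returns a result flagged `converged = FALSE` with
  a warning rather than an error.
* **Rotations only**: the optimal rotation is the Kabsch/SVD solution
  constrained to determinant $+1$. Reflections are *never* absorbed,
  because left and right wings are reflections of each other and a
  silently reflected fit would hide digitization on the wrong wing side.
  A right wing is instead mirrored explicitly (`mirror_config()`, or
  `mirror = TRUE` in `assign_unknown()`). When the cross-covariance
  between two shapes is rank deficient the optimum is not unique; the SVD
  convention (non-negative singular values) picks one deterministically.
* **Orientation tie-break**: after convergence the whole aligned sample is
  rotated so the consensus's first-to-second landmark axis points along
  $+x$. Superimposition is only defined up to a common rotation; fixing it
  makes coordinates reproducible across runs, orderings, and platforms.
* **Degenerate input**: a configuration whose landmarks all coincide has
  no shape; it is reported by specimen id.

Shape space is curved, but ordinary multivariate statistics need a linear
space. Each aligned configuration, flattened to a $2k$-vector $x$ with the
unit consensus vector $c$, is projected to $t = x - (x^\top c)\,c$: the
tangent space at the consensus. The consensus maps to zero. The
`tangent_adequacy()` check computes, over all specimen pairs, the
through-origin regression slope and the correlation between tangent
Euclidean distances and Procrustes distances; both near 1 mean the tangent
plane is a faithful chart of the observed variation. "Procrustes distance"
throughout is the *partial* Procrustes distance (the residual norm after
preshaping and optimal rotation), which is exactly the Euclidean geometry
the aligned coordinates live in, so the adequacy check is self-consistent.

## Classification: LDA, cross-validation, assignment

`shape_lda()` fits the Gaussian equal-covariance model on tangent
coordinates: group means $\mu_g$, one pooled within-group covariance
$\Sigma$. Superimposition leaves at least four exactly null directions in
the $2k$ tangent coordinates (two of translation, one of rotation, one of
size), so the coordinates are first reduced to the principal directions of
total variance with relative variance above $10^{-12}$ — retaining every
non-null dimension while making the pooled covariance invertible. The
reduction map is stored with the model so unknowns can be projected into
the same space. Canonical axes come from the whitened between-group
eigenproblem; at most $G - 1$ exist for $G$ groups.

For an unknown with reduced coordinates $z$,

$$\mathrm{MD}_g = \sqrt{(z - \mu_g)^\top \Sigma^{-1} (z - \mu_g)}, \qquad
  p(g \mid z) = \frac{\exp(-\tfrac12 \mathrm{MD}_g^2 + \log \pi_g)}
                     {\sum_h \exp(-\tfrac12 \mathrm{MD}_h^2 + \log \pi_h)},$$

computed via the Cholesky factor of $\Sigma$ (no explicit inverse) and a
max-shifted softmax. The unknown is assigned to the group with the highest
posterior; with equal priors this is also the group at minimal Mahalanobis
distance. Exact posterior ties are broken toward the alphabetically first
tied group, with a warning — determinism over a silent arbitrary choice.

Tunable parameters that matter:

* **`priors`** (`"equal"`, default, or `"proportional"`): reference
  collections are availability samples of taxa, not random samples of
  individuals, so proportional priors would pull every unknown toward
  well-sampled groups. Proportional mode is provided because it is the
  default in several general-purpose statistics packages.
* **`shrinkage`** ($\lambda \in [0,1]$, default 0): pulls $\Sigma$ toward
  its diagonal. Plain LDA needs roughly $N - G$ at least as large as the
  retained dimensionality (about $2k - 4$, capped by $N - 1$); below that
  the pooled covariance is singular and the fit stops with an error
  naming this flag. Shrinkage is a small-sample workaround, off by
  default to keep the model plain LDA.
* **`var_tol`** ($10^{-12}$): relative-variance cutoff of the preliminary
  reduction; anything this small relative to total variance is a null
  direction of the superimposition, not signal.

`loo_cv()` refits the discriminant model with each specimen held out and
reports per-group and global hit-ratios (percent correctly re-assigned),
the misclassification count, and the confusion table. The Procrustes
alignment is computed once from the full sample and held fixed across
folds — per-fold re-superimposition would put every fold in a slightly
different tangent space; holding it fixed matches how morphometric
software implements cross-validation and keeps folds comparable. A
`realign = TRUE` flag re-runs the superimposition per fold for sensitivity
analysis.

`assign_unknown()` never re-fits anything: the unknown is preshaped,
rotated onto the *fixed* consensus, tangent-projected there, passed through
the stored reduction, and scored. `hierarchical_assign()` repeats this over
an ordered list of reference datasets with successively finer grouping
levels, fitting each stage independently and never gating a later stage on
an earlier outcome, so the full chain of evidence is always reported.

`shape_pca()` ordinates the tangent coordinates (covariance PCA — the
coordinates share one unit, and correlation PCA would distort the
geometry); `project_unknown()` drops the unknown into the fitted space
without refitting. Axes are oriented so the largest-magnitude loading is
positive, for reproducible plots.

## What the synthetic generator emulates — and what it does not

The reference collections this pipeline is designed for (hundreds of
specimens spanning nested tribes and subgenera) are museum data that cannot
ship with a package. `synthetic_spec()` + `generate_dataset()` instead
simulate collections with exactly the structure the analysis assumes:

* a deterministic, asymmetric template wing (`template_wing()`; unit
  centroid size, so noise fractions read directly);
* a nested hierarchy of group mean shapes — each level adds an independent
  centered displacement field of magnitude `separation * within_sd` to its
  subtree, the *same* magnitude at every level, so sibling groups at a
  coarse level differ by two independent displacements and nested groups
  by one;
* isotropic Gaussian landmark noise with standard deviation `within_sd`
  times centroid size — the simplest model consistent with LDA's shared
  covariance assumption;
* a per-specimen similarity nuisance (rotation uniform on $[0, 2\pi)$,
  translation, log-scale), which changes raw coordinates but provably not
  shape.

Defaults — 18 landmarks, 3 coarse times 4 fine groups, 25 specimens per
terminal group, `within_sd = 0.01` (one percent of centroid size, a
realistic magnitude for combined digitization error and within-taxon wing
variation), `separation = 10` — describe a clearly discriminable nested
design at desk scale.

What the generator deliberately does *not* model: landmark-specific and
correlated noise (real digitization error varies by landmark), allometry,
unbalanced and phylogenetically structured sampling, and measurement of
damaged specimens. Passing tests therefore demonstrate that the
*machinery* is correct — superimposition invariances, classifier
calibration, assignment coherence — not that any particular real
collection would achieve a particular hit-ratio. The one distortion that
is modelled, because it is the central worry with fossils, is taphonomy:
`make_unknown()` can shear the specimen (`shear`) and/or mirror it, and
the test suite verifies that the true-group posterior degrades
monotonically with shear and that mirroring is fatal until corrected.

## Problem sizes and open choices

The test suite and the acceptance script run entirely on generated data at
the sizes above (50 specimens for the adequacy check; 100 specimens for
cross-validation and chance-level controls; 100 replicate unknowns for
assignment and cascade accuracy; a 400-specimen group for the convex-hull
ordination property, which needs a dense reference cloud). Two choices the
method description leaves open are resolved as follows: priors default to
equal (rationale above), and the per-level displacement scale of the
synthetic hierarchy is 1 at every level — coarse levels are then separated
from each other no more strongly than fine ones, which is conservative for
the cascade. The number of cascade stages is configurable rather than
fixed; nested designs of two or three stages are what the package's tests
exercise.

## Known limitations

* Strictly 2-D, fixed-landmark data: no semilandmarks, curves, or 3-D
  records (`LM3=` files are rejected, not skipped).
* Plain LDA: no quadratic discriminants and no phylogenetic correction;
  groups with very unequal covariances will be scored by a shared pooled
  covariance regardless.
* Mahalanobis distances of genuinely out-of-distribution unknowns (a taxon
  absent from the reference) are large for *every* group; the posterior
  still sums to one and will confidently pick the least-distant group.
  Inspect the distances, not only the posterior, before believing an
  assignment.
* Leave-one-out hit-ratios estimate re-identification within the reference
  collection; they say nothing about taxa the collection lacks.
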