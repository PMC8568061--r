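---
title: "Selecting weighted conformational ensembles from backbone chemical shifts"
author: "ShiftEnsemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting weighted conformational ensembles from backbone chemical shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ShiftEnsemble)
```

## The problem

Dynamic, partially disordered proteins — monomeric transthyretin variants
are the motivating case — populate many conformational states at once.
A deposited NMR structure bundle captures only the dominant ones. Backbone
chemical shifts, in contrast, are population-weighted averages over *all*
states, so they carry information about minor conformers that never make
it into an NOE-derived model. Given

* an experimental reference table $y$ of backbone shifts
  ($^1H_N$, $^{15}N_H$, $^{13}C_\alpha$, $^{13}C_\beta$), and
* a *structural library* $\{X_i\}_{i=1}^n$ of candidate conformations with
  per-conformer predicted shift tables (from UCBShift, SHIFTX2, SPARTA+ or
  any predictor that writes a table),

the package estimates non-negative weights $w$ with $\sum_i w_i = 1$ such
that $y \approx \sum_i w_i X_i$. Under those constraints the coefficients
are interpretable as appearance probabilities of the conformers in the
solution ensemble.

## The regression scheme

**Residue exclusion.** Only residues fully assigned for all four nuclei in
the reference *and* present in every library table enter the fit.
Prolines (no amide proton) and glycines (no $C_\beta$) are therefore
always excluded; `applyExclusionMask()` returns the excluded list for
reporting.

**Scaling.** The four nuclei live on very different ppm scales
($^1H_N$ spans ~1 ppm, $^{15}N_H$ ~25 ppm). Each value is mapped through

$$f(x) = \log_a\!\left(\frac{x - y_{min}}{y_{max} - y_{min}} + 1\right) + \theta,$$

where $y_{min}, y_{max}$ are the per-nucleus extrema of the *reference*,
$a \in [1.1, 10]$ is the logarithm base and $\theta$ is an additive offset
used for the amide proton only. $f$ is strictly increasing with an exact
closed-form inverse, so predictions can always be mapped back to ppm.

Two structural properties of this map are worth recording, because they
shape what hyperparameter tuning can and cannot do once the sum-to-one
constraint is enforced:

* changing $a$ rescales every scaled value by $1/\ln a$ uniformly across
  nuclei, which multiplies the whole least-squares objective by a constant
  and leaves the constrained minimizer $w$ unchanged — the objective is
  strictly decreasing in $a$, so the tuned base lands on the upper bound
  $a = 10$;
* $\theta$ shifts the reference and every library column by the same
  constant, and since $\sum_i w_i = 1$ it cancels from the residual
  exactly.

`tuneScaling()` implements the stated tuning loop faithfully (a
multi-start bounded quasi-Newton search whose objective is the residual of
the inner constrained fit), and its flat-objective tie-break keeps the
defaults $(a, \theta) = (10, 0)$. The offset becomes informative only for
fits whose coefficient sum is unconstrained, such as the first-stage NNLS
pass; we treat $\theta$ as a dimensionless offset in scaled space (it is
added after the logarithm, so ppm units would not type-check) and tune it
in $[-0.2, 0.2]$.

**Constrained solve.** `solveEnsembleWeights()` minimizes
$\lVert y - Xw \rVert^2$ subject to $w \ge 0$, $\sum w_i = 1$, in two
stages: a Lawson–Hanson NNLS pass (`pracma::lsqnonneg`) provides a warm
start, then an exact primal active-set quadratic program enforces the
equality constraint to KKT optimality. Singular working-set systems fall
back to the minimum-norm (pseudo-inverse) solution, which doubles as the
tie-break among equal-residual optima. The iteration cap is $50n + 100$;
bound multipliers are accepted at $-10^{-9}\max|Q|$.
`simplexGridSearch()` — a compiled exhaustive enumeration of the simplex
at step 0.001 — serves as an independent oracle for problems of up to
four conformers and is used in the test-suite cross-checks.

**Feature selection and refit.** The support is
$S = \{j : w_j \ge \varepsilon\, \max_k w_k\}$ with $\varepsilon = 10^{-5}$
(inclusive comparison, applied once, not iterated), followed by a refit of
the constrained problem restricted to $S$; conformers outside $S$ end with
weight exactly zero.

**Scoring.** Per nucleus, $R^2 = 1 - RSS/TSS$ is computed in original ppm
space: the scaled prediction $Xw$ is mapped back through $f^{-1}$ before
comparison. The total score is the product over the four nuclei. Scoring
in ppm rather than scaled space is a deliberate choice — the per-nucleus
numbers are then directly comparable to the shift-predictor literature,
and the product total retains its published meaning. A nucleus whose
reference column is constant has an undefined score and is reported as
missing rather than silently patched.

## Structural validation

**Contact maps and clustering.** Contacts are $C_\alpha$ pairs strictly
closer than 7.5 Å (the boundary itself is not a contact; the convention is
recorded here because the cutoff's openness is not standardized). The
weighted predicted ensemble is clustered by PCA of the flattened
upper-triangle contact maps — conformer rows weighted by their regression
coefficients, because the clustered object is the predicted ensemble whose
members appear with unequal probability — followed by k-means on the
leading components under a fixed seed. $k$ is a user choice; an average
silhouette helper (`silhouetteScores()`) is provided but never
auto-applied.

**Secondary structure.** External STRIDE or DSSP reports are parsed onto
the five-class alphabet (H→α-helix, G→3₁₀, E/B→β-sheet, T→turn, else
coil; the mapping is configurable and unknown codes become coil with a
warning). When no report is available, `assignSecondaryStructure()` offers
a lightweight $C_\alpha$-geometry assigner: helices from $i,i{+}3$ /
$i,i{+}4$ distance windows, strands from extended local spacing, and
β-sheet only when an extended partner strand lies within pairing distance
(5.5 Å) — an isolated extended chain is never β. It is documented as
approximate and is not a STRIDE re-implementation. Proportion statistics
follow the counting definitions: $P_i(\zeta)$ is the fraction of
conformers with class $\zeta$ at residue $i$ (weight-averaged when weights
are supplied), the β-core $B$ contains residues with *strictly* more than
50 % β-sheet, and the per-conformer β fraction $P_n$ counts over $B$ (or
over any user-supplied residue subset, e.g. one sheet of a sandwich, since
published per-sheet densities can be read either way).

**Order parameters.** The weighted ensemble is expanded to exactly 1,000
frames by largest-remainder apportionment of $1000\,w_i$ (each conformer
with $w_i \ge 1/2000$ is guaranteed a copy), and per-residue $S^2$ of the
N–H vectors is computed with the isotropic reorientational eigenmode
(iRED) approach: eigendecompose
$M_{ij} = \langle P_2(\mu_i\!\cdot\!\mu_j)\rangle$, attribute the five
largest-eigenvalue modes to overall reorientation, and set
$S^2_i = 1 - \sum_{m>5}\lambda_m m_i^2$. Five discarded modes is the
method's convention for separating overall from internal motion. Values
are reported raw — small negatives from finite sampling are diagnostic —
with an optional clamp to $[0,1]$. A structural fact worth knowing when
reading the tests: for $N$ vectors undergoing *uncorrelated* internal
motion, the five discarded modes absorb a share of internal variance of
order $5/N$, so iRED approaches closed-form single-vector models only for
long chains; the cone-model checks therefore run on 120-residue vector
sets, where the residual bias is within the stated tolerance.

**Shift error in projection space.** Per residue and nucleus the error is
$f(\delta_{reg}) - f(\delta_{ref})$. The combined per-residue error is the
Euclidean (root-sum-square) norm over nuclei by default; a `norm = "sum"`
option gives the plain summed form (of absolute values, so the quantity
stays a norm) for users who prefer the literal reading — the two differ
only by Jensen-type factors and rank nearly identically.
`errorCorrelation()` reports the Spearman correlation between this error
and $|\Delta S^2|$ on the shared residues.

## The synthetic layer

The generators stand in for what, at full scale, would be a
temperature-replica-exchange structural library (hundreds of thousands of
conformers), predictor runs over it, and deposited experimental shifts —
none of which is reproducible at desk scale. They emulate:

* `makeToyEnsemble()` — backbone traces from ideal α-helix, β-strand,
  coil and β-hairpin segments (phase-matched strand pairing at 4.8 Å),
  with consistent N, H (1.02 Å bond), $C_\beta$ placement, Gaussian
  coordinate noise per conformer, and an optional hinge rotation to hit a
  requested marker-pair distance (the AB-loop-style observable between
  residues 17 and 24);
* `makeShiftLibrary()` — per-conformer tables as random-coil base value
  (packaged literature-style constants) + secondary-structure offset
  (β lowers $C_\alpha$ and raises $C_\beta$; helix the opposite) +
  Gaussian noise with per-nucleus scale
  (HN 0.1, NH 1.0, CA 0.4, CB 0.4 ppm — the order of predictor
  conformer-to-conformer spread); the offset and base tables are packaged
  constants whose exact values are not load-bearing: tests rely on
  relative structure only;
* `makeReference()` — the regression target as a known convex mixture.
  By default the mixture is made exact *in the regression's operating
  (scaled) space* through a small fixed-point construction, so that the
  ranges the pipeline refits on the resulting reference reproduce the
  generating map and the ground truth is exactly recoverable; a
  `space = "ppm"` option mixes raw tables instead, in which case the log
  map's curvature leaves an irreducible ~1 % weight bias — a property of
  the method worth knowing, not a bug of the generator;
* `makeConeEnsemble()` — N–H vectors uniform within per-residue cones in
  a rigid frame, under uniformly random global rotations, the oracle input
  for iRED (closed form $S^2 = [\cos\alpha(1+\cos\alpha)/2]^2$).

What the generators do *not* emulate: physical force-field sampling,
correlated inter-residue motions, predictor systematic biases, chemical
exchange, or re-referencing errors in deposited data. Passing tests
demonstrate the estimator's correctness and its noise response, not that
any particular experimental system is well described.

Default study conditions (chosen once, as realistic for the motivating
system): a 127-residue chain, a 200-conformer library, a three-state
mixture $w = (0.5, 0.3, 0.2)$, noiseless reference; the test suite runs
reduced copies (16–40 residues, 5–25 conformers) where the check does not
depend on size, and the full 127×200 problem plus 5,000-frame, 120-vector
iRED ensembles where it does.

## Numerical choices and degenerate inputs

* Feature rows are ordered by residue number then canonical nucleus order;
  conformer order follows the library. Both are deterministic.
* All-zero design columns are dropped with a warning and reported with
  weight zero. A constant reference column (scaling undefined) is fatal.
* Empty supports cannot arise: the selection rule always keeps the
  maximum-weight conformer.
* k-means uses 25 restarts under the user seed; if the contact maps admit
  fewer distinct conformations than $k$, the count is reduced with a
  warning rather than failing.
* Eigenvalues are sorted descending with index tie-breaks; iRED requires
  more than five vectors and at least two frames by construction.
* Residue joins between reference and library are on residue number only;
  name mismatches warn (numbering drift between depositions is common)
  but do not stop the run. Unassigned means absent — no sentinel values.
* The pH at which predictor tables were computed may differ from the
  experimental buffer; it is carried as metadata only and never
  "corrected".

## Limitations

* The method inherits the predictors' accuracy; the projection-space
  error analysis exists precisely because prediction error is the main
  limiting factor.
* With more conformers than retained features the zero-residual solution
  set can be non-unique; sparsity of the true mixture and the
  non-negativity constraint usually restore uniqueness, but the package
  makes no guarantee — the residual and support size are always reported
  so degeneracy is visible.
* The geometric secondary-structure assigner is a fallback for synthetic
  backbones and coarse summaries, not a substitute for STRIDE/DSSP on
  real coordinates.
* iRED order parameters from short chains carry the $5/N$ mode-separation
  bias discussed above.

## Worked example

```{r example}
spec <- syntheticSpec(nConformers = 40, nResidues = 60, seed = 11)
sim <- runSimulate(spec, file.path(tempdir(), "bundle"))
cfg <- runConfig(
  reference = file.path(tempdir(), "bundle", "reference.csv"),
  referenceFormat = "csv",
  library = file.path(tempdir(), "bundle", "library"),
  dialect = "generic-csv",
  ensemble = file.path(tempdir(), "bundle", "ensemble.pdb"),
  outputDir = file.path(tempdir(), "run"),
  k = 2, tune = FALSE, seed = 1
)
fit <- runFit(cfg)
fit$weights
round(ensembleWeights(fit$weights)[supportSet(fit$weights)], 4)
```

The recovered support is the planted three-state mixture; per-nucleus and
total $R^2$ are 1 because the reference is a noiseless mixture.
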