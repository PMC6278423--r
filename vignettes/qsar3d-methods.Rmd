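---
title: "qsar3d: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{qsar3d: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsar3d)
```

# The modelling problem

Comparative molecular field analysis treats a congeneric series of
aligned 3D molecules as points in a very high-dimensional descriptor
space: interaction energies between each molecule and a probe atom,
evaluated on a shared lattice.  Partial least squares then correlates
that matrix with an activity (pIC50) and external-validation statistics
decide whether the model predicts rather than memorises.  qsar3d
implements that pipeline — structure I/O, charges, alignment, fields,
PLS/LOO, validation — with the validation layer designed to reproduce a
published reference result (a 35-compound purine CDK2-inhibitor series,
28 train / 7 test) from its printed prediction tables, which ship as
fixtures.

Key assumptions inherited from the method family:

* molecules are rigid and pre-aligned in a common frame — alignment
  quality directly limits model quality;
* fields are additive atom sums (no polarisation or many-body terms);
* a linear latent-variable model in field space suffices for the SAR.

# Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| grid spacing | 2.0 | Å | the method's standard lattice interval |
| grid margin | 4.0 | Å | lattice extends ≥ 4 Å beyond every molecule |
| energy cutoff | 30.0 | kcal/mol | steric/electrostatic truncation |
| LJ probe | sp³ C, charge +1 | — | r = 1.70 Å, ε = 0.107 kcal/mol from the element table |
| similarity probe | r = 1 Å, +1 everything | — | standard similarity-index probe |
| attenuation α | 0.3 | Å⁻² | published similarity-field default |
| min σ (column filter) | 2.0 | field units | the usual column-filter default; use ~0.005 for similarity fields, whose magnitudes are much smaller |
| PEOE iterations | 6 | — | published damping schedule (1/2)ᵏ |
| c_max (components) | 10 | — | LOO search upper bound, capped at n − 3 |

Grid anchoring: `origin = floor((min − margin)/spacing)·spacing` per
axis, so rebuilding after translating all molecules by a lattice
multiple shifts the origin exactly and lattices are reproducible.

Combination rules for the Lennard-Jones kernel are arithmetic radii /
geometric well depths.  The Coulomb term uses a constant dielectric of 1
with 332.0 kcal·Å·mol⁻¹·e⁻²; a distance-dependent dielectric is a known
variant of the original software but is not reproducible from printed
outputs, so the simpler choice is the default.  Electrostatic values at
sterically buried points (steric value at +cutoff) are replaced by the
training column mean; the exclusion mask and fill values are persisted
so prediction rows reuse the training fill.

# Partial charges

`gasteiger_charges()` implements σ-PEOE: electronegativity
χ(Q) = a + bQ + cQ², charge transferred along each bond proportional to
the χ difference over the cation electronegativity of the less
electronegative partner (20.02 for H), damped by (1/2)ᵏ per iteration.
The π-Hückel component of "Gasteiger–Hückel" charges is deliberately
omitted: its parameterisation is not published precisely enough to
reproduce, and no packaged result depends on it.  Conjugated systems
therefore receive plain PEOE charges.  The test oracle is an independent
PEOE implementation (values frozen at 12 iterations); the 6-iteration
default agrees with it to ~2×10⁻³ per atom — the damping tail.

# PLS, LOO and the sample-distance fast path

NIPALS with a univariate response; X and y are mean-centred, no
autoscaling beyond block scaling ("each field gets the same potential
influence": every surviving block is rescaled to equal total variance).
`loo_q2()` computes PRESS with the full-training-set mean in the
denominator — the convention of the covariance-matrix (sample-distance)
formulation — and its default path runs kernel PLS on the n × n Gram
matrix per fold, which is algebraically identical to refitting on each
fold (tested to 1e-8; typically agrees to machine precision) but avoids
touching the p ≫ n descriptor matrix.  Degrees of freedom: SEE uses
n − c − 1, F uses (c, n − c − 1); with r² = 0.984, n = 28, c = 5 the F
formula gives ≈ 270.6, consistent with a printed 273.426 once r² is
rounded to three decimals — that consistency is documented, not asserted
as equality, because the original descriptor matrix is not recoverable.

ONC selection takes the smallest component count attaining the maximal
q² (ties → simpler model).

# The validation battery

All statistics operate on an observed/predicted table with train/test
roles.  Two deliberate formula choices, both forced by arithmetic
against the reference tables and both exposed as options:

* **R0²/R′0² ("as-printed" vs standard).**  The default computes
  `R0² = 1 − Σ(Ypred − k·Ypred)²/Σ(Ypred − Ȳpred)²` (and the primed
  analogue on Yobs with k′).  This contracts to
  `1 − (1−k)²ΣY²/Σ(Y−Ȳ)²` and is what reproduces the reference
  R0² = 0.999 from the printed test rows.  `standard = TRUE` gives the
  conventional through-origin definitions
  (`1 − Σ(Yobs − k·Ypred)²/Σ(Yobs − Ȳobs)²`) for comparison; which was
  intended by the original authors is not decidable from the printed
  numbers, so both are provided.
* **rm² radical.**  `rm² = R²test(1 − √|R²test − R0²|)`.  The radical
  is required: without it the reference rm²(test) = 0.902 is not
  reproduced.
* **σ in the MAE criteria** uses the population divisor n
  (reproduces σ_test = 0.054; n − 1 gives 0.059).

Report display rounds half-up to 3 decimals; all internal arithmetic is
full precision.  Note the reference table prints rm²(avg) = 0.902 for a
model whose full-precision average is 0.9015 — the printed value averages
the two already-rounded inputs; both are within the ±0.01 acceptance
band.

Progressive scrambling sorts y, cuts it into bins (default 2–8),
permutes within bins, records (r²yy′, q²′) over seeded repetitions, fits
a quadratic and reports its value (Q²) and slope at the critical point
r²yy′ = 0.85.  The published Q²/slope for the reference models require
the original descriptor matrix and are out of scope; only the procedure
is tested (identity-scramble limit, pure-noise limit, per-level
agreement with a scramble-and-refit oracle).

Pareto ranking maximises (q², r², F) and minimises SEE with standard
non-dominated sorting; fronts are ordered by q² within level.

# The synthetic-data generator

`generate_toy_series()` emulates an R-group series: a fixed rigid
scaffold (shared by all molecules, so the set is born aligned) plus, per
substituent site, a per-seed library of two discrete poses (offset and
element drawn once per series); each molecule occupies each site with
probability 0.8 by one library pose, with a 0.05 Å per-molecule
micro-jitter and a random partial charge.  Activities are a sparse
linear model over designated steric-field columns, rescaled to the
2.62–8.52 pIC50 span of the reference series, plus Gaussian noise
(default σ = 0.1).

Two design points deserve explanation:

* **Why a discrete pose library?**  The generator must support two
  properties at once: (i) noiseless activities should be essentially
  perfectly cross-validated (the pipeline-recovery check), which
  requires the field matrix to be near low-rank so a left-out molecule
  lies in the span of the rest; and (ii) the designated effect columns
  must be *identifiable* — rankable above their neighbours by
  |β|·sd — which requires per-column idiosyncratic variance.  These
  pull in opposite directions: free positional jitter gives
  identifiability but caps noiseless LOO q² near 0.95; a purely
  discrete world gives exact recovery but creates perfectly collinear
  column clones that crowd the ranking.  The adopted compromise
  (2-pose library + 0.05 Å jitter) keeps the parameter-recovery check
  comfortably green (median q² ≈ 0.99, true columns in the top-5
  ranking in 18/20 seeds) and reaches q² > 0.99 — though not
  arbitrarily close to 1 — on noiseless data.  A green recovery test
  therefore establishes that the pipeline finds a planted sparse linear
  signal under realistic collinearity; it does not establish exact
  noiseless interpolation, which no world with identifiable columns
  provides.
* **Effect coefficients per unit sd.**  Default coefficients
  (1, −0.8, 0.6) are applied per unit column standard deviation so each
  informative column contributes comparable signal; otherwise the
  ranking check would be dominated by whichever column happens to have
  the largest raw variance.

What the generator does **not** emulate: real chemistry (atoms are
parameter-table pseudo-atoms without bonds), conformational flexibility,
activity cliffs, and correlated experimental error.  Green synthetic
tests validate the numerics, not chemical realism.

# Numerical choices and degenerate inputs

* NIPALS: deterministic y-initialisation, tolerance 1e-12, max 500
  inner iterations (the univariate response converges in one pass);
  rank exhaustion raises an error naming the component.
* Kabsch: proper rotation enforced via the determinant sign correction;
  < 3 pairs or collinear cores are rejected.
* Lattice point exactly on an atom: steric value set to +cutoff (no
  division by zero escapes); the point is flagged excluded for the
  electrostatic companion.
* Zero-variance response, empty descriptor set after filtering,
  duplicate ids, non-positive IC50, missing mappings: all hard errors
  with the offending record named.
* Contour thresholds resolve ties by reporting the included-set size as
  well as the level, so an all-equal score vector yields exactly
  ⌈0.8 n⌉ favoured points.
* Tie-break in ONC selection: smallest c at the maximum.

# Known limitations

* The model-building side (q², r², SEE, F of the reference models) is
  not desk-reproducible — the original 3D structures are not recoverable
  from the source tables — so the acceptance surface is the validation
  layer plus property-based checks of the modelling core, per the build
  contract.
* SDF reading is V2000 only; MOL2 parsing covers the MOLECULE/ATOM/BOND
  sections.
* Donor/acceptor assignment is a coarse rule table (N/O with H → donor;
  N/O → acceptor unless quaternary N); hydrophobicity is a per-element
  contribution, not a fragment scheme.
* Torsional adjustment during alignment and automated MCS detection are
  out of scope; the rigid fit consumes an externally supplied mapping.
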