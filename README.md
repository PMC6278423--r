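# qsar3d

3D-QSAR modelling in R: grid molecular fields, PLS with leave-one-out
cross-validation, and a complete external-validation battery.

## What this is for

Medicinal chemists and cheminformaticians building comparative molecular
field models (CoMFA/CoMSIA style) for congeneric small-molecule series —
for example, kinase-inhibitor SAR series — need three things wired
together:

1. **Field computation.** Aligned 3D molecules are surrounded by a
   regular lattice (2 Å spacing, extending 4 Å beyond every molecule).
   At each lattice point a probe atom records interaction energies:

   - steric: Lennard-Jones
     `E(r) = ε_ip [(R_ip/r)^12 − 2 (R_ip/r)^6]`, with
     `R_ip = r_i + r_probe`, `ε_ip = √(ε_i ε_probe)`, truncated at
     ±30 kcal/mol;
   - electrostatic: Coulomb `E(r) = 332 q_i q_probe / r`, clamped at
     ±30 kcal/mol, with sterically buried points replaced by training
     column means;
   - similarity indices (steric, electrostatic, hydrophobic, H-bond
     donor/acceptor): Gaussian-attenuated atom sums
     `−Σ_i w_i exp(−α r²)` with α = 0.3 Å⁻², needing no cutoff.

2. **PLS modelling.** The molecules × lattice-points matrix is
   column-filtered (σ ≥ 2.0), block-scaled so each field has equal total
   variance, and regressed on activity (pIC50 = −log₁₀ IC50[M]) by
   NIPALS partial least squares.  Leave-one-out cross-validation via a
   sample-distance (Gram-matrix) fast path yields
   `q²(c) = 1 − PRESS/Σ(y−ȳ)²`; the optimal component count maximises
   q².  Reported fit statistics: r², SEE = √(RSS/(n−c−1)),
   F = [r²/(1−r²)]·[(n−c−1)/c], per-field contribution fractions, and
   StDev×Coeff contour maps at 80 %/20 % contribution levels.

3. **External validation.** Over an observed/predicted table with
   train/test roles: r²pred = (SD−PRESS)/SD; through-origin slopes
   k, k′; origin-constrained R0², R′0²; Golbraikh–Tropsha checklist
   (q² > 0.5, R²test > 0.6, |relative R0² gaps| < 0.1,
   0.85 ≤ k, k′ ≤ 1.15); rm² metrics
   `rm² = R²test (1 − √|R²test − R0²|)` with their average and absolute
   difference; MAE criteria (`MAE ≤ 0.1·range`,
   `MAE + 3σ ≤ 0.2·range`, population σ); Pareto ranking of candidate
   models; and progressive y-scrambling with the extrapolated Q² at
   r²yy′ = 0.85.

A synthetic-data module generates aligned pseudo-molecule series with a
known sparse linear activity model so the whole pipeline is testable
offline, and the package ships the 35-compound CDK2 purine-inhibitor
reference prediction tables (three models, 28 train / 7 test) used by the
validation tests.

## Worked example

Validate the packaged CoMFA reference predictions:

```r
library(qsar3d)
tab  <- paper_fixture("comfa")          # 35 rows, 28 train / 7 test
rep_ <- validation_report(tab, q2 = 0.743)
print(rep_)
```

```
r2pred         0.991
R2test         0.991
R02            0.999
R02_prime      0.999
rel_R02        -0.008
rel_R02_prime  -0.008
k              0.994
k_prime        1.006
MAE_test       0.127
MAE_train      0.151
sigma_test     0.054
sigma_train    0.121
rm2            0.902
rm2_prime      0.901
rm2_avg        0.901
delta_rm2      0.000
rm2 guideline  pass
GT overall     pass
```

r²pred = 0.991 means the model explains 99.1 % of the test-set variance
around the training mean; k/k′ within [0.85, 1.15] and R0² ≈ R²test mean
predictions track the identity line; MAE(test) = 0.127 log units is far
below 10 % of the 5.903-unit training range; rm²(avg) > 0.5 with
Δrm² < 0.2 passes the rm² guideline.

End-to-end on synthetic data (command line):

```sh
qsar3d simulate --out-prefix demo --n 30 --seed 7
qsar3d fit --structures demo.mol2 --activities demo_activities.csv \
           --out demo_model.json
# fit: onc=5 q2=0.995 r2=0.998 SEE=0.104 F=1652.174
```

The same is available in R via `qsar3d_cli(c("simulate", ...))`, or
programmatically: `generate_toy_series()` → `generate_activities()` →
`compute_fields()` → `assemble_descriptors()` → `fit_qsar()` →
`validation_report()`.

## Scope notes

Docking, molecular dynamics, and the proprietary topomer fragment
machinery are out of scope; topomer predictions enter only as packaged
numbers for the validation layer.  Partial charges are σ-PEOE
(Gasteiger) only — no π-Hückel component.  Maximum-common-substructure
detection is not implemented; rigid alignment consumes an externally
supplied atom mapping.  See `vignettes/qsar3d-methods.Rmd` for the full
methods discussion.
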