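# mutstab

Structure-based prediction of protein stability changes upon missense
mutation.

## The problem

A single amino-acid substitution changes a protein's unfolding Gibbs
free energy by ΔΔG (kcal/mol; positive = destabilizing under this
package's convention).  Estimating ΔΔG from a 3D structure matters for
variant prioritisation and protein design, but most predictors share
two weaknesses: poor accuracy on *stabilizing* mutations and a broken
thermodynamic anti-symmetry — for a forward mutation and its reverse,
ΔΔG_F + ΔΔG_R = 0 must hold, yet many methods predict both directions
as destabilizing.

`mutstab` addresses both by training a random-forest regression
(ntree = 500, mtry = 3) on a *symmetric* dataset: every measured
forward mutation is augmented with its reverse partner carrying the
negated ΔΔG, and the two are never separated by any cross-validation
split.  The scoring function uses ten features in six categories:

| feature | meaning |
|---|---|
| `PSSM` | PSI-BLAST log-odds change at the site (mut − wt) |
| `dCS` | conservation-score change (PROVEAN-style provider) |
| `dOMH` | hydrophobicity change, OMH scale (mut − wt) |
| `SASA_pro` | solvent accessible surface area of the mutated residue in the protein (Å², Shrake–Rupley) |
| `SASA_sol` | reference SASA of the wild-type residue in an extended tripeptide (Å²) |
| `P_FWY`, `P_RKDE`, `P_L` | fraction of aromatic / charged / leucine residues buried in the core (relative SASA < 0.2) |
| `N_Hydro`, `N_Charg` | hydrophobic and charged residues within the 23-site sequence window centred on the site |

The package also implements the full evaluation machinery: Pearson
R / RMSE / slope, MCC with max-MCC threshold search, ROC/AUC, the
forward/reverse anti-symmetry audit (R_FR), Fisher-z and DeLong
comparisons, five cross-validation protocols (random 80% and 50%
splits, per-protein-capped subsampling, leave-one-protein-out,
leave-one-protein-cluster-out at >25% sequence identity), dataset
curation (reverse augmentation, conflict resolution, structure
ranking, sequence clustering), and a synthetic-fixture generator so
everything builds and tests offline.

## Worked example

```r
library(mutstab)

# a self-contained synthetic study: toy structures, PSSMs,
# conservation tables, and ddG values from a known antisymmetric
# generating function
spec   <- synthetic_spec(n_proteins = 4, mutations_per_protein = 30, seed = 42)
bundle <- make_training_bundle(spec)

model <- train_ddg_model(bundle$features, bundle$dataset$ddg_exp,
                         ddg_model_params(seed = 42))
model
#> ddG random-forest scoring function
#>   trees: 500  mtry: 3  min leaf: 5  seed: 42
#>   features: PSSM, dCS, dOMH, SASA_pro, SASA_sol, P_FWY, P_RKDE, P_L, N_Hydro, N_Charg
#>   PSSM convention: difference
#>   trained on 240 mutations (ddG -5.74 .. 5.74 kcal/mol)

# predict one mutation with its per-feature contributions
fc <- feature_contributions(model, bundle$features[5, ])
round(fc$prediction, 2)       # +1.07 kcal/mol (experimental +1.14):
                              # destabilizing, mostly evolutionary signal
round(fc$contributions, 3)
#>     PSSM      dCS     dOMH SASA_pro SASA_sol    P_FWY   P_RKDE      P_L
#>    0.437    0.462   -0.043    0.060    0.228   -0.051   -0.012   -0.007
#>  N_Hydro  N_Charg
#>   -0.039    0.038

# leave-one-protein-out validation; pairs stay on one side of the split
cv <- run_cv(bundle$dataset, bundle$features, cv_scheme("CV4", seed = 1),
             ddg_model_params(n_trees = 200))
cv
#> CV4 cross-validation, 4 round(s)
#>   mean R = 0.949, mean RMSE = 0.969 kcal/mol
#>   pooled out-of-fold R = 0.943, RMSE = 0.992
```

`ddg_pred > 0` means the substitution is predicted destabilizing; the
contributions (plus a bias term) sum exactly to the prediction.  A
site is reported `COR` (core) when its relative SASA is below 0.2,
otherwise `SUR` (surface).

A command-line interface wrapping the same functions lives in
`inst/cli/mutstab` with subcommands `predict` (mutation list, inline
specifiers like `A:L104D`, or a whole-chain alanine scan), `train`,
`evaluate`, `fixtures` and `demo`:

```sh
Rscript inst/cli/mutstab demo --out /tmp/demo --seed 3
```

## Scope

The package consumes PSSM files and conservation scores as inputs; it
does not run PSI-BLAST or PROVEAN, fetch PDB entries, or build
side-chain-optimised mutant models (a naive Cβ-truncating mutator is
the default; externally built mutant structures are accepted through
the same PDB interface).  See `vignettes/mutstab-methods.Rmd` for the
model, its assumptions, and what the synthetic benchmark does and does
not demonstrate.
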