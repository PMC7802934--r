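---
title: "mutstab: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mutstab: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`mutstab` predicts the unfolding free-energy change ΔΔG (kcal/mol,
positive = destabilizing) of a single missense mutation with a random
forest regressed on ten features in six categories: two evolutionary
(`PSSM`, `dCS`), one physicochemical (`dOMH`), two accessibility
(`SASA_pro`, `SASA_sol`), three buried-composition fractions
(`P_FWY`, `P_RKDE`, `P_L`) and two sequence-window counts (`N_Hydro`,
`N_Charg`).  The forest uses 500 trees with 3 features considered per
split; the minimum terminal node size is 5, the reference default for
random-forest regression (the published configuration is silent on
node size, so the default is kept and is configurable through
`ddg_model_params()`).

Two modelling commitments do most of the work:

* **Symmetric training.**  Each measured forward mutation is paired
  with a constructed reverse mutation carrying the exactly negated
  ΔΔG.  Reverse records are featurised on a *mutant* structure and the
  mutant sequence — never by simply negating forward features — so the
  model sees both directions as genuine inputs.  This is what drives
  the anti-symmetry audit statistic R_FR (Pearson correlation of
  paired forward/reverse predictions) toward −1.
* **Pair integrity in validation.**  In every cross-validation scheme
  a forward record and its reverse partner land on the same side of
  the split.  Splitting them leaks the answer: the reverse target is
  minus the forward target.

## Feature definitions and their assumptions

* `PSSM`: the package consumes a PSI-BLAST ASCII PSSM and, by default,
  extracts the mutant-minus-wild-type log-odds difference at the
  mutated position.  The extracted quantity is genuinely ambiguous in
  the method lineage (wild-type score, mutant score, or difference all
  have precedent), so the convention is a parameter and is embedded in
  saved model metadata; trained models refuse feature vectors built
  under a different convention only insofar as the metadata documents
  the mismatch.  The difference convention was chosen as the default
  because it is the only one that is exactly antisymmetric, matching
  the symmetric-training design.  For reverse mutations the wild-type
  protein's profile is reused with the roles of the two residues
  swapped; a mutant-sequence profile is rarely available in practice
  and the swap preserves exact antisymmetry.
* `dCS` is consumed from a tabular provider (protein, chain, position,
  wt, mut, score), emulating PROVEAN output.  Running the homology
  pipeline that produces such scores is out of scope; the synthetic
  generator writes antisymmetric tables by construction.
* `dOMH` uses the optimal matching hydrophobicity scale (Sweet &
  Eisenberg 1983) bundled as code (`omh_scale()`), overridable per
  call.
* `SASA_pro` is computed by a Shrake–Rupley implementation (below);
  `SASA_sol` is the extended Gly-X-Gly tripeptide reference
  (`max_asa_reference()`, Miller et al. 1987 lineage).  A residue is
  core (`COR`) when `SASA_pro / SASA_sol < 0.2`, strictly: a ratio of
  exactly 0.2 is surface.  The original pipeline used DSSP for both
  numbers; DSSP's radius set and chain-break handling are
  provider-specific, so absolute SASA values here are comparable
  between mutstab runs but not bit-comparable with DSSP output.
* Burial fractions are computed over all assigned chains (multi-chain
  proteins are treated as one unit), with `N_All` the total residue
  count of those chains.
* Window counts scan the 23 positions centred on the site on the
  concatenated chain sequence, truncated at termini without
  renormalisation; hydrophobic = {V,I,L,F,M,W,Y,C}, charged =
  {R,K,D,E}, disjoint sets, so `N_Hydro + N_Charg <= 23` always.

## Structure handling

PDB parsing (via bio3d) keeps ATOM records of the 20 standard residues
plus MSE (normalised to MET, SE→SD); waters and other heteroatoms are
excluded; only the first NMR model is read.  Alternate locations keep
the highest-occupancy conformer, ties broken by file order.  Residues
are addressed by author numbering plus insertion code, never by
sequential index, so positions map exactly as in curated mutation
tables.  Experimental method and resolution are captured from the
header when present.

The naive mutant builder changes the residue identity and truncates
the side chain beyond Cβ (beyond Cα for glycine targets).  It is a
deliberate simplification — no side-chain repacking is attempted — and
the interface accepts an externally built mutant structure (e.g. from
a side-chain optimisation tool) through `parse_pdb()` wherever a
structure is consumed.

## Numerical choices

* **SASA**: Shrake–Rupley with a deterministic Fibonacci lattice,
  probe 1.4 Å, element radii C 1.70 / N 1.55 / O 1.52 / S 1.80 Å
  (1.80 otherwise), hydrogens ignored, 960 points per atom by default.
  Against analytic one- and two-sphere oracles the error is well under
  2% at 960 points (the test suite checks this at several
  separations).  The fixed lattice makes results exactly reproducible
  and translation-invariant to floating-point accuracy, but only
  approximately rotation-invariant: rotated coordinates change
  per-residue SASA by up to ~1.5% at 960 points.  The tests therefore
  assert translation invariance at 1e-6 relative and rotation
  invariance of the COR/SUR labels with SASA drift bounded at 2%.
  Raise `sphere_points` for tighter rotational stability.
* **MCC**: when any factor of the denominator is zero on a non-empty
  confusion matrix the value is defined as 0; the all-zero matrix is
  an error.  Counts are accumulated in double precision (the naive
  integer product overflows near n ≈ 1300).
* **ROC**: thresholds sweep the unique scores (positive when score ≥
  threshold), AUC by the trapezoid rule; this reproduces the
  concordant-pair (Mann–Whitney) statistic exactly, ties counting
  half, which the tests verify against brute force and against pROC.
* **Clustering**: proteins are single-linkage clustered over pairs
  with global-alignment identity > 25% and ≥ 50% coverage of both
  sequences.  Identity is identical residues over the full alignment
  length (gap columns included) — the robust choice, since
  matches-over-aligned-columns lets a short gappy core inflate a pair
  over the threshold; coverage is jointly aligned columns over each
  sequence length.  BLOSUM62, gap open 10, extend 0.5.  The partition
  is order-independent; clusters are numbered by smallest member.
* **Conflict resolution** when merging test sets: a mutation measured
  k times is kept at the mean iff max−min < 1.0 kcal/mol, strictly;
  boundary spreads drop.  ΔΔG = 0 counts as destabilizing.
* **CV3** samples per protein up to 20 mutations without replacement,
  treating a forward/reverse pair as one jointly sampled unit; a
  parity swap (drop a lone unpaired record for a skipped pair)
  reaches the cap exactly whenever attainable.  The published
  protocol does not state the sampling unit; sampling pairs is the
  only choice consistent with the pairing invariant.
* **Seeds**: every stochastic routine takes one integer seed and
  derives sub-seeds through `sample.int` draws from it, so a whole
  table (all CV rounds, all proteins of a bundle) reproduces from a
  single number.  Generator functions restore the caller's RNG state.

## The synthetic benchmark

`make_training_bundle()` materialises everything the real pipeline
reads — PDB structures, PSSM files, a conservation table, a mutation
CSV — for a study of, by default, 12 proteins × 60 residues with 84
forward mutations each (2016 records after augmentation).  Sizes were
chosen to exercise multi-protein cross-validation at a cost of tens of
seconds on one CPU; the acceptance script uses them unchanged.

Toy structures are ideal α-helices (3.6 residues/turn, 1.5 Å rise, Cβ
at standard geometry).  From 20 residues upward the chain is emitted
as two packed antiparallel helices ~8.5 Å apart, because a single
straight helix has no interior: the dimer arrangement gives genuinely
buried (RSA < 0.2) inner-facing residues alongside exposed ones while
keeping consecutive intra-chain Cα–Cα at 3.80 Å.

Forward ΔΔG values are a linear function of the *computed* ten
features plus Gaussian noise (0.5 kcal/mol); reverse values are exact
negations.  The coefficient vector puts its weight on the exactly
antisymmetric features (dOMH −1.2, dCS −0.3, PSSM −0.15 in their
native units) with small weights on the structural and composition
features.  That choice is a signal-to-noise design made once, up
front: it yields a ΔΔG spread of roughly 1.3–2 kcal/mol, similar to
curated thermodynamic datasets, and it reflects the physical fact
that the structural features of a forward/reverse pair are nearly
equal while their targets are opposite — a generator dominated by
those features would be internally inconsistent with thermodynamic
anti-symmetry, not merely harder to fit.

What passing the synthetic benchmark shows: the plumbing is correct
end to end (features computed where the generator computed them, pairs
kept together, forests trained and audited as specified), parameter
recovery works at realistic noise, and the symmetric-training design
produces near-perfectly antisymmetric predictors *when the generating
process is antisymmetric*.  What it does not show: accuracy on real
proteins.  Real structures have packed cores, side chains, and
feature–target relationships that are nonlinear and noisier; real
PSSMs and conservation scores are correlated with structure in ways
the generator does not emulate.  Published-scale accuracy claims
require the external curated datasets and providers, which this
package deliberately does not fetch.

## Limitations

* No PSI-BLAST/PROVEAN execution, PDB retrieval, homology modelling,
  or side-chain optimisation; all are consumed as inputs.
* mmCIF is not parsed; NMR ensembles beyond the first model and
  biological-assembly generation are out of scope (supply the
  assembly file).
* The naive mutant structure underestimates repacking effects around
  the mutation site; for accuracy-critical work supply externally
  built mutant models.
* MMseqs2 cluster files can be imported as the cluster table for
  exact reproduction of published clusterings; the built-in
  alignment-based clustering preserves the thresholds but is not
  guaranteed to reproduce MMseqs2's heuristics protein by protein.
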