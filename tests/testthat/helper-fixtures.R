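# Shared fixtures, built in code and cached for the test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# a single-atom "structure" for SASA oracles
atom_structure <- function(x, y, z, element = "C", aa = "G") {
  n <- length(x)
  structure(list(
    id = "toy",
    atoms = data.frame(chain = "A", resno = seq_len(n), icode = "",
                       aa = rep_len(aa, n), elety = "CA",
                       element = rep_len(element, n),
                       x = x, y = y, z = z, occ = 1,
                       stringsAsFactors = FALSE),
    meta = list()), class = "ddg_structure")
}

# analytic SASA of two equal spheres of expanded radius R at distance d
two_sphere_exact <- function(R, d) {
  if (d >= 2 * R) return(c(4 * pi * R^2, 4 * pi * R^2))
  h <- R - d / 2
  rep(4 * pi * R^2 - 2 * pi * R * h, 2)
}

# hand-written 3-residue PDB (chain A), with optional altloc site
tiny_pdb_text <- function(altloc = FALSE) {
  lines <- c(
    "HEADER    TEST PROTEIN                            01-JAN-20   TST1",
    "EXPDTA    X-RAY DIFFRACTION",
    "REMARK   2 RESOLUTION.    2.10 ANGSTROMS.",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  N   GLY A   2       3.332   1.536   0.000  1.00  0.00           N",
    "ATOM      5  CA  GLY A   2       4.021   2.794   0.000  1.00  0.00           C",
    "ATOM      6  C   GLY A   2       5.532   2.626   0.000  1.00  0.00           C")
  if (altloc) {
    lines <- c(lines,
      "ATOM      7  N   LEU A   3       6.232   3.745   0.000  1.00  0.00           N",
      "ATOM      8  CA ALEU A   3       7.689   3.752   0.000  0.60  0.00           C",
      "ATOM      9  CA BLEU A   3       7.700   3.900   0.100  0.40  0.00           C")
  } else {
    lines <- c(lines,
      "ATOM      7  N   LEU A   3       6.232   3.745   0.000  1.00  0.00           N",
      "ATOM      8  CA  LEU A   3       7.689   3.752   0.000  1.00  0.00           C")
  }
  c(lines, "TER", "END")
}

# minimal pair-linked dataset built directly (no file I/O)
toy_dataset <- function(proteins, muts_per_protein, seed = 1,
                        paired = TRUE) {
  set.seed(seed)
  rows <- do.call(rbind, lapply(proteins, function(p) {
    data.frame(protein_id = p, structure_id = p, chain = "A",
               position = seq_len(muts_per_protein), icode = "",
               wt = "L", mut = "A",
               ddg_exp = round(rnorm(muts_per_protein), 3),
               direction = "forward", pair_id = NA_integer_,
               stringsAsFactors = FALSE)
  }))
  d <- mutstab:::as_ddg_dataset(rows, "toy")
  if (paired) augment_with_reverse(d) else d
}

# small synthetic bundle shared across test files
small_bundle <- function() {
  cached("small_bundle", make_training_bundle(
    synthetic_spec(n_proteins = 4, residues_per_protein = 40,
                   mutations_per_protein = 25, seed = 73),
    sphere_points = 480))
}

# brute-force AUC: concordant-pair (Mann-Whitney) statistic
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
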