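# Synthetic fixtures: toy structures, PSSMs, conservation tables and
# ddG values from a known antisymmetric generating function, so the
# whole pipeline builds and tests offline.

# ideal alpha-helix cylindrical parameters per backbone atom:
# radius (A), phase offset (deg) relative to CA, z offset (A)
HELIX_GEOM <- list(
  N  = c(1.56, -28.1, -0.90),
  CA = c(2.28,   0.0,  0.00),
  C  = c(1.68,  26.4,  1.06),
  O  = c(2.00,  42.0,  1.20),
  CB = c(3.30, -25.0, -0.55)
)

helix_coords <- function(n, phase0 = 0) {
  per_res <- 100 * pi / 180   # 3.6 residues/turn
  rise <- 1.5
  out <- list()
  for (i in seq_len(n)) {
    for (at in names(HELIX_GEOM)) {
      g <- HELIX_GEOM[[at]]
      th <- phase0 + (i - 1) * per_res + g[2] * pi / 180
      out[[length(out) + 1]] <- data.frame(
        res = i, elety = at,
        x = g[1] * cos(th), y = g[1] * sin(th),
        z = (i - 1) * rise + g[3], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

format_atom <- function(serial, elety, res3, chain, resno, x, y, z) {
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, paste0(" ", elety), res3, chain, resno, x, y, z,
          1.0, 0.0, substring(elety, 1, 1))
}

#' Generate a toy protein structure in PDB format
#'
#' Builds an ideal alpha-helical backbone (3.6 residues/turn, 1.5 A
#' rise, C-beta at standard geometry).  For `n_residues >= 20` the chain
#' is split into two packed antiparallel helices (chains A and B,
#' ~8.5 A apart) so that inner-facing residues are genuinely buried
#' (relative SASA < 0.2) while exposed residues remain; smaller toys are
#' a single chain A.  Glycine residues get no C-beta.
#'
#' @param n_residues Total residue count (>= 3).
#' @param sequence Optional amino-acid string of length `n_residues`;
#'   random when omitted.
#' @param seed Integer seed (used only when `sequence` is omitted).
#' @return Character vector of PDB lines (invisibly parseable by
#'   [parse_pdb()]).
#' @export
make_toy_structure <- function(n_residues, sequence = NULL, seed = 1) {
  if (n_residues < 3)
    stop_mutstab("need at least 3 residues", "mutstab_value_error")
  if (is.null(sequence)) {
    rs <- .mutstab_rng(seed)
    on.exit(.mutstab_rng_restore(rs))
    sequence <- paste(sample(AA1, n_residues, replace = TRUE),
                      collapse = "")
  }
  aa <- strsplit(sequence, "")[[1]]
  if (length(aa) != n_residues)
    stop_mutstab("sequence length must equal n_residues",
                 "mutstab_value_error")
  if (!all(aa %in% AA1))
    stop_mutstab("unknown residue in sequence", "mutstab_value_error")

  two_chains <- n_residues >= 20
  n_a <- if (two_chains) ceiling(n_residues / 2) else n_residues
  lines <- c("HEADER    SYNTHETIC TOY PROTEIN                   01-JAN-20   TOYP",
             "EXPDTA    X-RAY DIFFRACTION",
             "REMARK   2 RESOLUTION.    1.50 ANGSTROMS.")
  serial <- 0
  emit_chain <- function(chain, aa_chain, transform) {
    co <- helix_coords(length(aa_chain))
    xyz <- transform(as.matrix(co[, c("x", "y", "z")]))
    out <- character(0)
    for (k in seq_len(nrow(co))) {
      i <- co$res[k]
      if (co$elety[k] == "CB" && aa_chain[i] == "G") next
      serial <<- serial + 1
      out <- c(out, format_atom(serial, co$elety[k],
                                AA1TO3[aa_chain[i]], chain, i,
                                xyz[k, 1], xyz[k, 2], xyz[k, 3]))
    }
    out
  }
  if (two_chains) {
    len_a <- n_a * 1.5
    lines <- c(lines,
               emit_chain("A", aa[1:n_a], identity),
               "TER",
               # antiparallel partner: flip z, shift x by packing distance
               emit_chain("B", aa[(n_a + 1):n_residues], function(m) {
                 cbind(8.5 - m[, 1], m[, 2], len_a - 1.5 - m[, 3])
               }),
               "TER")
  } else {
    lines <- c(lines, emit_chain("A", aa, identity), "TER")
  }
  c(lines, "END")
}

# seed scoping helpers: save/restore the caller's RNG state
.mutstab_rng <- function(seed) {
  rs <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  rs
}
.mutstab_rng_restore <- function(rs) {
  if (is.null(rs)) {
    if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", rs, globalenv())
}

#' Generate a synthetic PSI-BLAST ASCII PSSM
#'
#' Writes a standard ASCII PSSM whose log-odds rows are integer noise
#' with the native residue's score raised by `conservation_strength`.
#'
#' @param sequence Amino-acid string.
#' @param conservation_strength Added to the native residue's score at
#'   every position (0 = null profile).
#' @param seed Integer seed.
#' @param trailing Include the trailing weighted-percentage and
#'   information columns of the full PSI-BLAST dialect.
#' @return Character vector of file lines.
#' @export
make_synthetic_pssm <- function(sequence, conservation_strength = 6,
                                seed = 1, trailing = TRUE) {
  aa <- strsplit(sequence, "")[[1]]
  if (!all(aa %in% AA1))
    stop_mutstab("unknown residue in sequence", "mutstab_value_error")
  rs <- .mutstab_rng(seed)
  on.exit(.mutstab_rng_restore(rs))
  L <- length(aa)
  scores <- matrix(as.integer(round(stats::rnorm(L * 20, 0, 2))), L, 20)
  colnames(scores) <- PSSM_ALPHABET
  for (i in seq_len(L))
    scores[i, aa[i]] <- scores[i, aa[i]] +
      as.integer(round(conservation_strength))
  header <- paste0("           ",
                   paste(sprintf("%3s", PSSM_ALPHABET), collapse = ""),
                   if (trailing)
                     paste0(" ", paste(sprintf("%3s", PSSM_ALPHABET),
                                       collapse = "")))
  lines <- c("", "Last position-specific scoring matrix computed, weight ratios, information per position", header)
  for (i in seq_len(L)) {
    row <- paste0(sprintf("%5d %s ", i, aa[i]),
                  paste(sprintf("%3d", scores[i, ]), collapse = ""))
    if (trailing) {
      pct <- as.integer(round(stats::runif(20, 0, 100)))
      row <- paste0(row, " ", paste(sprintf("%3d", pct), collapse = ""),
                    sprintf("  %4.2f %4.2f", stats::runif(1, 0, 2),
                            stats::runif(1, 0, 2)))
    }
    lines <- c(lines, row)
  }
  c(lines, "", "                      K         Lambda", "Standard Ungapped    0.1347     0.3179")
}

#' Default synthetic study specification
#'
#' Defines the conditions of the synthetic benchmark: 12 proteins of 60
#' residues, ~2000 mutations after reverse augmentation, Gaussian noise
#' of 0.5 kcal/mol, and a generating coefficient vector dominated by the
#' exactly antisymmetric features (dOMH, PSSM, dCS) with small weights
#' on the structural/composition features, giving a realistic ddG
#' spread of ~1.3 kcal/mol.
#'
#' @param n_proteins,residues_per_protein,mutations_per_protein Sizes.
#' @param coefficients Named vector over the ten features.
#' @param noise_sd Gaussian noise on forward ddG (kcal/mol).
#' @param conservation_strength Passed to [make_synthetic_pssm()].
#' @param seed Integer master seed.
#' @return List of class `ddg_synthetic_spec`.
#' @export
synthetic_spec <- function(n_proteins = 12, residues_per_protein = 60,
                           mutations_per_protein = 84,
                           coefficients = c(PSSM = -0.15, dCS = -0.3,
                                            dOMH = -1.2, SASA_pro = -0.004,
                                            SASA_sol = 0.002, P_FWY = 0.5,
                                            P_RKDE = -0.5, P_L = 0.5,
                                            N_Hydro = 0.03,
                                            N_Charg = -0.03),
                           noise_sd = 0.5, conservation_strength = 6,
                           seed = 1) {
  if (n_proteins < 1)
    stop_mutstab("need at least one protein", "mutstab_value_error")
  if (noise_sd < 0 || any(!is.finite(coefficients)))
    stop_mutstab("invalid spec", "mutstab_value_error")
  stopifnot(setequal(names(coefficients), FEATURE_NAMES))
  structure(list(n_proteins = n_proteins,
                 residues_per_protein = residues_per_protein,
                 mutations_per_protein = mutations_per_protein,
                 coefficients = coefficients[FEATURE_NAMES],
                 noise_sd = noise_sd,
                 conservation_strength = conservation_strength,
                 seed = as.integer(seed)),
            class = "ddg_synthetic_spec")
}

#' Generate a complete synthetic training bundle
#'
#' Materialises everything the real pipeline consumes: toy PDB
#' structures, synthetic PSSM files, a conservation table, and a
#' pair-linked mutation dataset whose forward ddG values are
#' `coefficients . features + N(0, noise_sd)` and whose reverse ddG
#' values are the exact negations.  Reverse-record features are computed
#' on naively mutated structures and mutant sequences, exactly as the
#' prediction pipeline does.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Directory to write the file tree (`structures/`, `pssm/`,
#'   `conservation.tsv`, `mutations.csv`); created if needed.
#' @param sphere_points SASA resolution used for features.
#' @return List with `dataset` (augmented `ddg_dataset`), `features`
#'   (aligned matrix), `structures`, `pssms`, `conservation`, `spec`,
#'   `dir`.
#' @export
make_training_bundle <- function(spec = synthetic_spec(),
                                 dir = tempfile("bundle"),
                                 sphere_points = 960) {
  rs <- .mutstab_rng(spec$seed)
  on.exit(.mutstab_rng_restore(rs))
  dir.create(file.path(dir, "structures"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "pssm"), showWarnings = FALSE)

  prot_seeds <- sample.int(.Machine$integer.max - 1, spec$n_proteins)
  structures <- list()
  pssms <- list()
  cons_rows <- list()
  fwd_rows <- list()
  fwd_feats <- list()

  for (p in seq_len(spec$n_proteins)) {
    set.seed(prot_seeds[p])
    pid <- sprintf("SYN%02d", p)
    seq_p <- paste(sample(AA1, spec$residues_per_protein, replace = TRUE),
                   collapse = "")
    pdb_lines <- make_toy_structure(spec$residues_per_protein, seq_p)
    pdb_path <- file.path(dir, "structures", paste0(pid, ".pdb"))
    writeLines(pdb_lines, pdb_path)
    st <- parse_pdb(pdb_path)
    st$id <- pid
    structures[[pid]] <- st

    pssm_lines <- make_synthetic_pssm(seq_p, spec$conservation_strength,
                                      seed = prot_seeds[p])
    pssm_path <- file.path(dir, "pssm", paste0(pid, ".pssm"))
    writeLines(pssm_lines, pssm_path)
    pssms[[pid]] <- read_psiblast_pssm(pssm_path)

    res <- residues(st)
    # draw unique (position, mutant) substitutions
    n_mut <- spec$mutations_per_protein
    seen <- character(0)
    pos <- integer(0); mut <- character(0)
    while (length(pos) < n_mut) {
      pp <- sample.int(spec$residues_per_protein, 1)
      mm <- sample(setdiff(AA1, res$aa[pp]), 1)
      key <- paste(pp, mm)
      if (!key %in% seen) {
        seen <- c(seen, key)
        pos <- c(pos, pp); mut <- c(mut, mm)
      }
    }
    dcs <- stats::rnorm(n_mut, 0, 2)
    cons_rows[[pid]] <- data.frame(
      protein = pid,
      chain = c(res$chain[pos], res$chain[pos]),
      pos = c(res$resno[pos], res$resno[pos]),
      wt = c(res$aa[pos], mut), mut = c(mut, res$aa[pos]),
      score = c(dcs, -dcs), stringsAsFactors = FALSE)
    fwd_rows[[pid]] <- data.frame(
      protein_id = pid, structure_id = pid,
      chain = res$chain[pos], position = res$resno[pos], icode = "",
      wt = res$aa[pos], mut = mut, ddg_exp = NA_real_,
      direction = "forward", pair_id = NA_integer_,
      stringsAsFactors = FALSE)
  }

  conservation <- do.call(rbind, cons_rows)
  class(conservation) <- c("ddg_conservation", "data.frame")
  cons_path <- file.path(dir, "conservation.tsv")
  utils::write.table(conservation, cons_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  fwd <- as_ddg_dataset(do.call(rbind, fwd_rows), "synthetic")

  # forward features on wild-type structures
  wt_profiles <- lapply(structures, sasa_profile,
                        sphere_points = sphere_points)
  feats_fwd <- matrix(NA_real_, nrow(fwd), 10,
                      dimnames = list(NULL, FEATURE_NAMES))
  for (i in seq_len(nrow(fwd))) {
    pid <- fwd$protein_id[i]
    feats_fwd[i, ] <- build_feature_vector(
      fwd[i, ], structures[[pid]], wt_profiles[[pid]], pssms[[pid]],
      conservation)
  }
  fwd$ddg_exp <- as.vector(feats_fwd %*% spec$coefficients) +
    stats::rnorm(nrow(fwd), 0, spec$noise_sd)

  dataset <- augment_with_reverse(fwd)

  # reverse features on naively mutated structures
  n_f <- nrow(fwd)
  feats <- rbind(feats_fwd,
                 matrix(NA_real_, n_f, 10,
                        dimnames = list(NULL, FEATURE_NAMES)))
  for (j in seq_len(n_f)) {
    rec <- dataset[n_f + j, ]
    pid <- rec$protein_id
    # the mutant structure carries the reverse record's wild type
    mut_st <- mutate_structure_naive(structures[[pid]], rec$chain,
                                     rec$position, wt = rec$mut,
                                     mut = rec$wt, icode = rec$icode)
    mut_prof <- sasa_profile(mut_st, sphere_points = sphere_points)
    feats[n_f + j, ] <- build_feature_vector(
      rec, mut_st, mut_prof, pssms[[pid]], conservation)
  }

  write_mutation_table(dataset, file.path(dir, "mutations.csv"))
  list(dataset = dataset, features = feats, structures = structures,
       pssms = pssms, conservation = conservation, spec = spec,
       dir = dir)
}
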