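#' Hydrophobicity change of a substitution
#'
#' Difference of the OMH hydrophobicity scale between mutant and
#' wild-type residue: `scale(mut) - scale(wt)`.  Antisymmetric by
#' construction.
#'
#' @param wt,mut One-letter amino-acid codes (vectorised).
#' @param scale Named hydrophobicity table; defaults to [omh_scale()].
#' @return Numeric.
#' @export
delta_omh <- function(wt, mut, scale = omh_scale()) {
  if (any(is.na(scale[wt])) || any(is.na(scale[mut])))
    stop_mutstab("residue not in hydrophobicity scale",
                 "mutstab_lookup_error")
  unname(scale[mut] - scale[wt])
}

#' Read a conservation-change table
#'
#' Tab-separated table of per-mutation conservation-change scores (a
#' PROVEAN-style delta alignment score), columns: protein, chain, pos,
#' wt, mut, score.
#'
#' @param path File path.
#' @return Data frame of class `ddg_conservation`.
#' @export
read_conservation_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("protein", "chain", "pos", "wt", "mut", "score")
  if (!all(need %in% names(tab)))
    stop_mutstab(paste0("conservation table must have columns: ",
                        paste(need, collapse = ", ")),
                 "mutstab_schema_error")
  if (any(!is.finite(tab$score)))
    stop_mutstab("non-finite conservation scores", "mutstab_value_error")
  class(tab) <- c("ddg_conservation", "data.frame")
  tab
}

# score lookup; NULL when absent
conservation_score <- function(cons, protein, chain, pos, wt, mut) {
  i <- which(cons$protein == protein & cons$chain == chain &
             cons$pos == pos & cons$wt == wt & cons$mut == mut)
  if (!length(i)) return(NULL)
  cons$score[i[1]]
}

#' Buried-residue composition of a structure
#'
#' Counts and fractions of aromatic (F/W/Y), charged (R/K/D/E) and
#' leucine residues buried in the protein core (relative SASA < 0.2),
#' relative to the total residue count of the assigned chains.
#'
#' @param structure A `ddg_structure`.
#' @param sasa A `ddg_sasa_profile` covering all residues of `structure`.
#' @return List with `N_All`, `N_FWY`, `N_RKDE`, `N_L`, `P_FWY`,
#'   `P_RKDE`, `P_L`.
#' @export
burial_composition <- function(structure, sasa) {
  r <- residues(structure)
  key_r <- paste(r$chain, r$resno, r$icode)
  key_s <- paste(sasa$chain, sasa$resno, sasa$icode)
  m <- match(key_r, key_s)
  if (any(is.na(m)))
    stop_mutstab("SASA profile does not cover all residues",
                 "mutstab_coverage_error")
  buried <- sasa$location[m] == "COR"
  aa <- r$aa
  n_all <- nrow(r)
  n_fwy <- sum(buried & aa %in% AA_AROMATIC)
  n_rkde <- sum(buried & aa %in% AA_CHARGED)
  n_l <- sum(buried & aa == "L")
  list(N_All = n_all, N_FWY = n_fwy, N_RKDE = n_rkde, N_L = n_l,
       P_FWY = n_fwy / n_all, P_RKDE = n_rkde / n_all, P_L = n_l / n_all)
}

#' Hydrophobic and charged counts in the sequence window
#'
#' Counts hydrophobic (V/I/L/F/M/W/Y/C) and charged (R/K/D/E) residues
#' over the 23-site window centred on the mutated position (11 either
#' side, the site itself included), truncated at the termini.
#'
#' @param sequence Amino-acid string.
#' @param position 1-based position of the mutated site.
#' @return Named integer vector `c(N_Hydro=, N_Charg=)`.
#' @export
window_counts <- function(sequence, position) {
  n <- nchar(sequence)
  if (position < 1 || position > n)
    stop_mutstab("position out of sequence range", "mutstab_index_error")
  lo <- max(1, position - 11)
  hi <- min(n, position + 11)
  win <- strsplit(substring(sequence, lo, hi), "")[[1]]
  c(N_Hydro = sum(win %in% AA_HYDROPHOBIC),
    N_Charg = sum(win %in% AA_CHARGED))
}

#' Naive in-place mutation of a structure
#'
#' Replaces the residue identity at the mutation site and truncates its
#' side chain: atoms beyond C-beta are removed (beyond C-alpha when the
#' target is glycine); backbone and all other residues are untouched.
#' A stand-in for full side-chain rebuilding: an externally built mutant
#' structure can always be supplied instead via [parse_pdb()].
#'
#' @param structure A `ddg_structure`.
#' @param chain,resno,icode Mutation site (author numbering).
#' @param wt,mut One-letter wild-type and mutant residues.
#' @return Mutated `ddg_structure`.
#' @export
mutate_structure_naive <- function(structure, chain, resno, wt, mut,
                                   icode = "") {
  idx <- residue_atom_idx(structure, chain, resno, icode)
  a <- structure$atoms
  if (a$aa[idx[1]] != wt)
    stop_mutstab(sprintf("wild-type mismatch at %s:%s%s: structure has %s",
                         chain, resno, icode, a$aa[idx[1]]),
                 "mutstab_consistency_error")
  if (wt == mut) return(structure)
  keep_names <- c("N", "CA", "C", "O", "OXT")
  if (mut != "G") keep_names <- c(keep_names, "CB")
  drop <- idx[!(a$elety[idx] %in% keep_names)]
  a$aa[idx] <- mut
  if (length(drop)) a <- a[-drop, , drop = FALSE]
  structure$atoms <- a
  structure
}

# map a mutation site to its index in the concatenated chain sequence
sequence_position <- function(structure, chain, resno, icode = "") {
  r <- residues(structure)
  i <- which(r$chain == chain & r$resno == resno & r$icode == icode)
  if (!length(i))
    stop_mutstab(sprintf("residue %s:%s%s not found", chain, resno, icode),
                 "mutstab_index_error")
  i[1]
}

#' Assemble the ten-feature vector for a mutation
#'
#' Combines the evolutionary, hydrophobicity, accessibility and
#' composition features into the model's feature vector.  For a forward
#' mutation, `structure` is the wild-type structure; for a reverse
#' mutation it is the mutant structure and `wt`/`mut` are already
#' swapped.  The PSSM profile is always the wild-type protein's profile;
#' for reverse mutations its sequence therefore matches `mut` (the
#' original wild type) at the site, and the score difference is taken
#' with swapped roles.
#'
#' @param mutation List or one-row data frame with `protein_id`, `chain`,
#'   `position`, `icode` (optional), `wt`, `mut`, and optionally
#'   `direction` (`"forward"` default).
#' @param structure `ddg_structure` the features are measured on.
#' @param sasa `ddg_sasa_profile` of `structure`.
#' @param pssm `ddg_pssm` of the wild-type protein.
#' @param cons `ddg_conservation` table.
#' @param pssm_convention Passed to [pssm_feature()].
#' @return Named numeric vector of the ten features (`PSSM`, `dCS`,
#'   `dOMH`, `SASA_pro`, `SASA_sol`, `P_FWY`, `P_RKDE`, `P_L`,
#'   `N_Hydro`, `N_Charg`).
#' @export
build_feature_vector <- function(mutation, structure, sasa, pssm, cons,
                                 pssm_convention = "difference") {
  m <- as.list(mutation)
  icode <- m$icode %||% ""
  if (is.na(icode)) icode <- ""
  direction <- m$direction %||% "forward"
  for (p in c("structure", "sasa", "pssm", "cons")) {
    if (is.null(get(p)))
      stop_mutstab(paste0("missing feature provider: ", p),
                   "mutstab_missing_feature_error")
  }
  seq_pos <- sequence_position(structure, m$chain, m$position, icode)
  seqs <- structure_sequence(structure)
  site_aa <- substring(seqs, seq_pos, seq_pos)
  if (site_aa != m$wt)
    stop_mutstab(sprintf("wild-type mismatch at %s:%s%s: structure has %s",
                         m$chain, m$position, icode, site_aa),
                 "mutstab_consistency_error")

  # PSSM: wild-type protein profile; roles swapped for reverse records
  if (identical(direction, "reverse")) {
    prof_aa <- substring(pssm$sequence, seq_pos, seq_pos)
    if (prof_aa != m$mut)
      stop_mutstab(sprintf(
        "PSSM profile mismatch at position %d: profile has %s", seq_pos,
        prof_aa), "mutstab_consistency_error")
    s_src <- pssm$scores[seq_pos, m$wt]
    s_tgt <- pssm$scores[seq_pos, m$mut]
    pssm_val <- switch(pssm_convention,
                       difference = unname(s_tgt - s_src),
                       wt = unname(s_src),
                       mut = unname(s_tgt))
  } else {
    pssm_val <- pssm_feature(pssm, seq_pos, m$wt, m$mut,
                             convention = pssm_convention)
  }

  dcs <- conservation_score(cons, m$protein_id, m$chain, m$position,
                            m$wt, m$mut)
  if (is.null(dcs))
    stop_mutstab(sprintf(
      "missing feature provider: conservation score for %s %s:%s %s>%s",
      m$protein_id, m$chain, m$position, m$wt, m$mut),
      "mutstab_missing_feature_error")

  i <- profile_row(sasa, m$chain, m$position, icode)
  comp <- burial_composition(structure, sasa)
  wc <- window_counts(seqs, seq_pos)

  out <- c(PSSM = pssm_val,
           dCS = dcs,
           dOMH = delta_omh(m$wt, m$mut),
           SASA_pro = sasa$sasa_A2[i],
           SASA_sol = unname(max_asa_reference()[m$wt]),
           P_FWY = comp$P_FWY, P_RKDE = comp$P_RKDE, P_L = comp$P_L,
           N_Hydro = unname(wc["N_Hydro"]),
           N_Charg = unname(wc["N_Charg"]))
  if (any(!is.finite(out)))
    stop_mutstab("non-finite feature value", "mutstab_validation_error")
  out
}
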