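#' Per-residue solvent accessible surface area (Shrake-Rupley)
#'
#' Computes absolute SASA for every residue of a structure by the
#' Shrake-Rupley method: test points on each solvent-expanded atomic
#' sphere (deterministic Fibonacci lattice) are counted as accessible when
#' they fall outside all other expanded spheres.  Hydrogens are ignored.
#' Van der Waals radii are assigned by element (C 1.70, N 1.55, O 1.52,
#' S 1.80 A; 1.80 otherwise).
#'
#' @param structure A `ddg_structure`.
#' @param probe_radius Solvent probe radius in Angstrom (default 1.4).
#' @param sphere_points Number of test points per atom (default 960).
#' @return Numeric vector of per-residue SASA (A^2), named
#'   `chain:resno[icode]`, in residue file order.
#' @export
compute_sasa <- function(structure, probe_radius = 1.4, sphere_points = 960) {
  a <- structure$atoms
  a <- a[a$element != "H", , drop = FALSE]
  if (nrow(a) == 0)
    stop_mutstab("no heavy atoms", "mutstab_validation_error")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  if (any(!is.finite(xyz)))
    stop_mutstab("non-finite coordinates", "mutstab_validation_error")
  radii <- VDW_RADII[a$element]
  radii[is.na(radii)] <- VDW_DEFAULT
  atom_sasa <- .sasa_shrake_rupley(xyz, unname(radii), probe_radius,
                                   as.integer(sphere_points))
  key <- paste0(a$chain, ":", a$resno, a$icode)
  res_key <- unique(key)
  out <- vapply(split(atom_sasa, factor(key, levels = res_key)), sum,
                numeric(1))
  out[res_key]
}

#' Relative solvent accessibility
#'
#' Ratio of a residue's absolute SASA to its SASA in an extended
#' Gly-X-Gly tripeptide.
#'
#' @param abs_sasa Absolute SASA (A^2), vectorised.
#' @param aa One-letter amino-acid code(s), recycled against `abs_sasa`.
#' @param reference_table Named per-residue reference SASA; defaults to
#'   [max_asa_reference()].
#' @return Relative SASA (dimensionless, >= 0, may exceed 1).
#' @export
relative_sasa <- function(abs_sasa, aa, reference_table = max_asa_reference()) {
  ref <- reference_table[aa]
  if (any(is.na(ref)))
    stop_mutstab(paste0("no reference SASA for: ",
                        paste(unique(aa[is.na(ref)]), collapse = ", ")),
                 "mutstab_lookup_error")
  unname(abs_sasa / ref)
}

#' Core/surface classification of a residue
#'
#' A residue is buried in the protein core (`"COR"`) when its relative
#' SASA is strictly below the burial threshold, otherwise it is on the
#' surface (`"SUR"`).
#'
#' @param ratio Relative SASA value(s).
#' @param threshold Burial threshold (default 0.2; strict `<`).
#' @return Character vector of `"COR"` / `"SUR"`.
#' @export
classify_location <- function(ratio, threshold = 0.2) {
  if (any(!is.finite(ratio)) || any(ratio < 0))
    stop_mutstab("relative SASA must be finite and >= 0",
                 "mutstab_validation_error")
  ifelse(ratio < threshold, "COR", "SUR")
}

#' Full SASA profile of a structure
#'
#' Convenience wrapper combining [compute_sasa()], [relative_sasa()] and
#' [classify_location()].
#'
#' @inheritParams compute_sasa
#' @param reference_table Passed to [relative_sasa()].
#' @return Data frame (class `ddg_sasa_profile`) with columns chain,
#'   resno, icode, aa, sasa_A2, rsa, location.
#' @export
sasa_profile <- function(structure, probe_radius = 1.4, sphere_points = 960,
                         reference_table = max_asa_reference()) {
  r <- residues(structure)
  abs_sasa <- compute_sasa(structure, probe_radius, sphere_points)
  rsa <- relative_sasa(unname(abs_sasa), r$aa, reference_table)
  out <- data.frame(chain = r$chain, resno = r$resno, icode = r$icode,
                    aa = r$aa, sasa_A2 = unname(abs_sasa), rsa = rsa,
                    location = classify_location(rsa),
                    stringsAsFactors = FALSE)
  class(out) <- c("ddg_sasa_profile", "data.frame")
  out
}

#' Write a SASA profile as TSV
#'
#' @param profile A `ddg_sasa_profile`.
#' @param path Output file path.
#' @export
write_sasa_profile <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# profile row lookup for one residue
profile_row <- function(profile, chain, resno, icode = "") {
  i <- which(profile$chain == chain & profile$resno == resno &
             profile$icode == icode)
  if (!length(i))
    stop_mutstab(sprintf("residue %s:%s%s missing from SASA profile",
                         chain, resno, icode),
                 "mutstab_coverage_error")
  i[1]
}
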