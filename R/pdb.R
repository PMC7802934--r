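#' Parse a protein structure from PDB format
#'
#' Reads ATOM records for the 20 standard amino acids (selenomethionine MSE
#' is normalised to MET), resolving alternate locations by keeping the
#' highest-occupancy conformer (ties broken by file order).  Waters and all
#' other heteroatoms are excluded.  For multi-model (NMR) files only the
#' first model is used.  Experimental method and resolution are captured
#' from the header when present.
#'
#' @param source Path to a PDB file, or a character vector of PDB-format
#'   lines (a single string with embedded newlines is also accepted).
#' @param chains Optional character vector of chain identifiers to keep.
#' @return An object of class `ddg_structure`: a list with `id`, `atoms`
#'   (data frame: chain, resno, icode, aa, elety, element, x, y, z, occ)
#'   and `meta` (list with `method` and `resolution`).
#' @export
parse_pdb <- function(source, chains = NULL) {
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    path <- source
    lines <- readLines(source, warn = FALSE)
    id <- sub("\\.(pdb|ent)$", "", basename(source))
  } else {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE))
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(lines, path)
    id <- "structure"
  }

  meta <- list(method = NULL, resolution = NULL)
  expdta <- grep("^EXPDTA", lines, value = TRUE)
  if (length(expdta)) meta$method <- trimws(substring(expdta[1], 11))
  rem2 <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(rem2)) {
    res <- suppressWarnings(as.numeric(
      sub(".*RESOLUTION\\.?\\s+([0-9.]+).*", "\\1", rem2[1])))
    if (!is.na(res) && res > 0) meta$resolution <- res
  }
  hdr <- grep("^HEADER", lines, value = TRUE)
  if (length(hdr) && nchar(hdr[1]) >= 66) {
    code <- trimws(substring(hdr[1], 63, 66))
    if (nzchar(code)) id <- code
  }

  pdb <- tryCatch({
    utils::capture.output(
      p <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE,
                                            verbose = FALSE)))
    p
  }, error = function(e) stop_mutstab(
    paste0("cannot parse PDB input: ", conditionMessage(e)),
    "mutstab_format_error"))

  at <- pdb$atom
  keep <- (at$type == "ATOM" & at$resid %in% names(AA3TO1)) |
          (at$type == "HETATM" & at$resid == "MSE")
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0)
    stop_mutstab("no standard amino-acid ATOM records found",
                 "mutstab_empty_structure_error")

  # MSE -> MET normalisation (SE atom becomes SD)
  mse <- at$resid == "MSE"
  if (any(mse)) {
    at$resid[mse] <- "MET"
    at$elety[mse & at$elety == "SE"] <- "SD"
    at$elesy[mse & at$elesy %in% c("SE", "Se")] <- "S"
  }

  if (!is.null(chains)) {
    missing <- setdiff(chains, unique(at$chain))
    if (length(missing))
      stop_mutstab(paste0("chain(s) not present: ",
                          paste(missing, collapse = ", ")),
                   "mutstab_lookup_error")
    at <- at[at$chain %in% chains, , drop = FALSE]
  }

  # altloc policy: per atom site keep the highest-occupancy conformer,
  # ties broken by first listed
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (any(nzchar(alt))) {
    occ <- at$o
    occ[is.na(occ)] <- 1
    key <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert),
                 at$elety, sep = "|")
    ord <- seq_len(nrow(at))
    keep_idx <- vapply(split(ord, key), function(idx) {
      idx[which.max(occ[idx])]  # which.max returns first on ties
    }, integer(1))
    at <- at[sort(keep_idx), , drop = FALSE]
  }

  element <- at$elesy
  bad <- is.na(element) | !nzchar(trimws(element))
  if (any(bad)) {
    guess <- toupper(substring(gsub("[0-9]", "", trimws(at$elety[bad])), 1, 1))
    element[bad] <- guess
  }
  element <- toupper(trimws(element))

  atoms <- data.frame(
    chain = at$chain,
    resno = at$resno,
    icode = ifelse(is.na(at$insert), "", at$insert),
    aa = unname(AA3TO1[at$resid]),
    elety = trimws(at$elety),
    element = element,
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop_mutstab("non-finite atom coordinates", "mutstab_validation_error")

  structure(list(id = id, atoms = atoms, meta = meta),
            class = "ddg_structure")
}

#' Residue table of a structure
#'
#' @param structure A `ddg_structure`.
#' @return Data frame with one row per residue (chain, resno, icode, aa),
#'   in file order.
#' @export
residues <- function(structure) {
  a <- structure$atoms
  key <- paste(a$chain, a$resno, a$icode, sep = "|")
  first <- !duplicated(key)
  data.frame(chain = a$chain[first], resno = a$resno[first],
             icode = a$icode[first], aa = a$aa[first],
             stringsAsFactors = FALSE)
}

#' Amino-acid sequence of a structure
#'
#' Residue sequence of the selected chains concatenated in chain order;
#' this is the sequence used for the window-composition features.
#'
#' @param structure A `ddg_structure`.
#' @param chains Optional chain selection (default: all chains, file order).
#' @return Single character string of one-letter codes.
#' @export
structure_sequence <- function(structure, chains = NULL) {
  r <- residues(structure)
  if (!is.null(chains)) r <- r[r$chain %in% chains, , drop = FALSE]
  paste(r$aa, collapse = "")
}

#' @export
print.ddg_structure <- function(x, ...) {
  r <- residues(x)
  cat("Protein structure", x$id, "\n")
  cat("  chains:", paste(unique(r$chain), collapse = ", "), "\n")
  cat("  residues:", nrow(r), "  atoms:", nrow(x$atoms), "\n")
  if (!is.null(x$meta$method))
    cat("  method:", x$meta$method,
        if (!is.null(x$meta$resolution))
          paste0("(", x$meta$resolution, " A)"), "\n")
  invisible(x)
}

# locate a residue's atom rows; errors if absent
residue_atom_idx <- function(structure, chain, resno, icode = "") {
  a <- structure$atoms
  idx <- which(a$chain == chain & a$resno == resno & a$icode == icode)
  if (!length(idx))
    stop_mutstab(sprintf("residue %s:%s%s not found", chain, resno, icode),
                 "mutstab_index_error")
  idx
}
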