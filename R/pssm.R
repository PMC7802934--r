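#' Read a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Parses the standard ASCII PSSM produced by PSI-BLAST
#' (`-out_ascii_pssm`): a header line carrying the 20-letter alphabet
#' followed by one row per query position with the position index, the
#' query residue and 20 integer log-odds scores.  Trailing columns
#' (weighted percentages, information content, gapless match weight) are
#' tolerated and ignored, so both dialects (with and without the extra
#' columns) parse identically.
#'
#' @param source Path to a PSSM file or character vector of its lines.
#' @return Object of class `ddg_pssm`: list with `sequence` (query
#'   string) and `scores` (L x 20 integer matrix, columns in the fixed
#'   alphabet A R N D C Q E G H I L K M F P S T W Y V).
#' @export
read_psiblast_pssm <- function(source) {
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
  } else {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE))
  }
  # locate the alphabet header: first line whose tokens start with the
  # 20 standard letters in PSSM order
  header_at <- NA_integer_
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) >= 20 && identical(tok[1:20], PSSM_ALPHABET)) {
      header_at <- i
      break
    }
  }
  if (is.na(header_at))
    stop_mutstab("not a PSI-BLAST ASCII PSSM (alphabet header not found)",
                 "mutstab_format_error")

  seq_chars <- character(0)
  rows <- list()
  for (i in seq(header_at + 1, length(lines))) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) break
    tok <- strsplit(ln, "\\s+")[[1]]
    if (length(tok) < 22) {
      if (grepl("^[0-9]+$", tok[1]))
        stop_mutstab(sprintf("truncated PSSM row at line %d", i),
                     "mutstab_format_error")
      break  # footer (K/Lambda block)
    }
    if (!grepl("^[0-9]+$", tok[1])) break
    pos <- as.integer(tok[1])
    if (pos != length(seq_chars) + 1)
      stop_mutstab(sprintf("non-consecutive PSSM position %d", pos),
                   "mutstab_format_error")
    scores <- suppressWarnings(as.integer(tok[3:22]))
    if (any(is.na(scores)))
      stop_mutstab(sprintf("malformed PSSM scores at position %d", pos),
                   "mutstab_format_error")
    seq_chars <- c(seq_chars, tok[2])
    rows[[pos]] <- scores
  }
  if (!length(rows))
    stop_mutstab("PSSM contains no score rows", "mutstab_format_error")
  scores <- do.call(rbind, rows)
  colnames(scores) <- PSSM_ALPHABET
  structure(list(sequence = paste(seq_chars, collapse = ""),
                 scores = scores),
            class = "ddg_pssm")
}

#' @export
print.ddg_pssm <- function(x, ...) {
  cat("PSI-BLAST PSSM,", nrow(x$scores), "positions\n")
  invisible(x)
}

#' PSSM feature of a mutation
#'
#' Extracts the evolutionary feature of a substitution from a PSSM.
#' The default convention is the mutant-minus-wild-type log-odds
#' difference at the mutated position; the single-residue scores are
#' available as alternative conventions.  The convention in force is
#' recorded in trained model metadata.
#'
#' @param profile A `ddg_pssm`.
#' @param position 1-based position in the profile sequence.
#' @param wt,mut One-letter wild-type and mutant residues.
#' @param convention `"difference"` (default), `"wt"` or `"mut"`.
#' @return Numeric score.
#' @export
pssm_feature <- function(profile, position, wt, mut,
                         convention = c("difference", "wt", "mut")) {
  convention <- match.arg(convention)
  if (position < 1 || position > nrow(profile$scores))
    stop_mutstab("PSSM position out of range", "mutstab_index_error")
  seq_wt <- substring(profile$sequence, position, position)
  if (seq_wt != wt)
    stop_mutstab(sprintf(
      "wild-type mismatch at position %d: profile has %s, mutation says %s",
      position, seq_wt, wt), "mutstab_consistency_error")
  s_wt <- profile$scores[position, wt]
  s_mut <- profile$scores[position, mut]
  switch(convention,
         difference = unname(s_mut - s_wt),
         wt = unname(s_wt),
         mut = unname(s_mut))
}
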