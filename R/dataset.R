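# Mutation/ddG dataset representation and curation.
#
# A dataset is a data frame (class ddg_dataset) with columns:
#   protein_id, structure_id, chain, position, icode, wt, mut,
#   ddg_exp (kcal/mol, positive = destabilizing; NA allowed for
#   prediction-only records), direction ("forward"/"reverse"), pair_id
#   (links a forward record to its reverse partner).

DATASET_COLS <- c("protein_id", "structure_id", "chain", "position",
                  "icode", "wt", "mut", "ddg_exp", "direction", "pair_id")

record_key <- function(d, with_direction = TRUE) {
  k <- paste(d$protein_id, d$chain, d$position, d$icode, d$wt, d$mut,
             sep = "|")
  if (with_direction) k <- paste(k, d$direction, sep = "|")
  k
}

as_ddg_dataset <- function(df, name = "dataset") {
  df <- df[, DATASET_COLS]
  rownames(df) <- NULL
  attr(df, "name") <- name
  class(df) <- c("ddg_dataset", "data.frame")
  df
}

#' @export
print.ddg_dataset <- function(x, ...) {
  cat("Mutation dataset", attr(x, "name") %||% "", "\n")
  cat(" ", nrow(x), "records,", length(unique(x$protein_id)), "proteins;",
      sum(x$direction == "forward"), "forward /",
      sum(x$direction == "reverse"), "reverse\n")
  invisible(x)
}

#' Read a mutation/ddG table
#'
#' Ingests a CSV/TSV mutation table into a normalised dataset.  The
#' sign convention of the ddG column is positive = destabilizing; tables
#' using the opposite convention can be flipped on ingest.
#'
#' @param source File path (delimiter inferred from extension, or set
#'   `sep`).
#' @param column_map Named character vector mapping the canonical names
#'   `protein`, `structure`, `chain`, `pos`, `wt`, `mut`, `ddg` (and
#'   optionally `icode`) to the file's column names.
#' @param sign_flip If `TRUE`, negate the ddG column on ingest.
#' @param duplicates `"error"` (default) rejects duplicate mutation keys;
#'   `"mean"` collapses them to their mean ddG.
#' @param sep Field separator; default `","` for `.csv`, `"\t"` otherwise.
#' @param name Dataset name for provenance.
#' @return A `ddg_dataset` of forward records.
#' @export
read_mutation_table <- function(source, column_map = NULL, sign_flip = FALSE,
                                duplicates = c("error", "mean"),
                                sep = NULL, name = NULL) {
  duplicates <- match.arg(duplicates)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", source)) "," else "\t"
  tab <- utils::read.table(source, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"")
  cmap <- c(protein = "protein", structure = "structure", chain = "chain",
            pos = "pos", wt = "wt", mut = "mut", ddg = "ddg",
            icode = "icode")
  if (!is.null(column_map)) cmap[names(column_map)] <- column_map
  need <- c("protein", "structure", "chain", "pos", "wt", "mut", "ddg")
  missing <- need[!cmap[need] %in% names(tab)]
  if (length(missing))
    stop_mutstab(paste0("missing required column(s): ",
                        paste(cmap[missing], collapse = ", ")),
                 "mutstab_schema_error")
  ddg <- suppressWarnings(as.numeric(tab[[cmap["ddg"]]]))
  if (any(is.na(ddg) & !is.na(tab[[cmap["ddg"]]]) &
          nzchar(trimws(tab[[cmap["ddg"]]]))))
    stop_mutstab("unparseable ddG value", "mutstab_value_error")
  if (sign_flip) ddg <- -ddg
  icode <- if (cmap["icode"] %in% names(tab))
    as.character(tab[[cmap["icode"]]]) else ""
  icode[is.na(icode)] <- ""
  d <- data.frame(protein_id = as.character(tab[[cmap["protein"]]]),
                  structure_id = as.character(tab[[cmap["structure"]]]),
                  chain = as.character(tab[[cmap["chain"]]]),
                  position = as.integer(tab[[cmap["pos"]]]),
                  icode = icode,
                  wt = toupper(tab[[cmap["wt"]]]),
                  mut = toupper(tab[[cmap["mut"]]]),
                  ddg_exp = ddg,
                  direction = "forward", pair_id = NA_integer_,
                  stringsAsFactors = FALSE)
  if (any(d$wt == d$mut))
    stop_mutstab("wild-type equals mutant in some record(s)",
                 "mutstab_value_error")
  key <- record_key(d)
  if (anyDuplicated(key)) {
    if (duplicates == "error")
      stop_mutstab("duplicate mutation keys in table",
                   "mutstab_schema_error")
    agg <- tapply(d$ddg_exp, key, mean)
    d <- d[!duplicated(key), , drop = FALSE]
    d$ddg_exp <- unname(agg[record_key(d)])
  }
  as_ddg_dataset(d, name %||% sub("\\.[^.]+$", "", basename(source)))
}

#' Write a dataset as CSV
#' @param dataset A `ddg_dataset`.
#' @param path Output path.
#' @export
write_mutation_table <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Augment a forward dataset with reverse mutations
#'
#' For every forward record adds its reverse counterpart (wild-type and
#' mutant swapped, ddG negated), pair-linked through `pair_id`, doubling
#' the dataset.  The thermodynamic identity ddG_F + ddG_R = 0 holds
#' exactly by construction.
#'
#' @param dataset A `ddg_dataset` of forward records only.
#' @return Symmetric `ddg_dataset` (forward records first).
#' @export
augment_with_reverse <- function(dataset) {
  if (nrow(dataset) == 0) return(dataset)
  if (any(dataset$direction != "forward"))
    stop_mutstab("dataset already contains reverse records",
                 "mutstab_state_error")
  fwd <- dataset
  fwd$pair_id <- seq_len(nrow(fwd))
  rev <- fwd
  rev$wt <- fwd$mut
  rev$mut <- fwd$wt
  rev$ddg_exp <- -fwd$ddg_exp
  rev$direction <- "reverse"
  as_ddg_dataset(rbind(as.data.frame(fwd), as.data.frame(rev)),
                 paste0(attr(dataset, "name") %||% "dataset", "+reverse"))
}

#' Partition a dataset by stability effect
#'
#' Destabilizing mutations have `ddg_exp >= 0`; stabilizing `< 0`.
#'
#' @param dataset A `ddg_dataset` with ddG for every record.
#' @return List with elements `destabilizing` and `stabilizing`.
#' @export
split_by_sign <- function(dataset) {
  if (any(is.na(dataset$ddg_exp)))
    stop_mutstab("ddG missing for some records", "mutstab_value_error")
  de <- dataset$ddg_exp >= 0
  list(destabilizing = as_ddg_dataset(as.data.frame(dataset)[de, ],
                                      "destabilizing"),
       stabilizing = as_ddg_dataset(as.data.frame(dataset)[!de, ],
                                    "stabilizing"))
}

#' Merge test sets with conflict resolution and training overlap removal
#'
#' Takes the union of several mutation sets; a mutation measured several
#' times is kept at the mean ddG when the spread (max - min) is strictly
#' below `conflict_window`, otherwise all its entries are dropped.
#' Every mutation whose key appears in `training` is removed.
#'
#' @param sets List of `ddg_dataset` objects.
#' @param training `ddg_dataset` whose mutations must be excluded.
#' @param conflict_window Spread threshold in kcal/mol (default 1.0,
#'   strict).
#' @return Merged `ddg_dataset`.
#' @export
merge_test_sets <- function(sets, training, conflict_window = 1.0) {
  all <- do.call(rbind, lapply(sets, as.data.frame))
  if (is.null(all) || nrow(all) == 0)
    return(as_ddg_dataset(as.data.frame(training)[0, ], "merged"))
  key <- record_key(all, with_direction = FALSE)
  spread <- tapply(all$ddg_exp, key, function(v) max(v) - min(v))
  mn <- tapply(all$ddg_exp, key, mean)
  keep_keys <- names(spread)[spread < conflict_window]
  out <- all[!duplicated(key) & key %in% keep_keys, , drop = FALSE]
  out$ddg_exp <- unname(mn[record_key(out, with_direction = FALSE)])
  train_keys <- unique(record_key(as.data.frame(training),
                                  with_direction = FALSE))
  out <- out[!record_key(out, with_direction = FALSE) %in% train_keys, ,
             drop = FALSE]
  as_ddg_dataset(out, "merged")
}

#' Cluster proteins by sequence identity
#'
#' Single-linkage clustering over protein pairs whose pairwise global
#' alignment (BLOSUM62) shows more than `identity_threshold` sequence
#' identity with the aligned region covering at least
#' `coverage_threshold` of both sequences.  Identity is the fraction of
#' identical residues over aligned (both non-gap) columns.  The
#' partition is independent of input order; clusters are numbered by
#' their lexicographically smallest member.
#'
#' @param sequences Named character vector of protein sequences.
#' @param identity_threshold Identity above which two proteins are
#'   "similar" (default 0.25, strict `>`).
#' @param coverage_threshold Minimum alignment coverage of both
#'   sequences (default 0.5).
#' @return Data frame with columns `protein`, `cluster`.
#' @export
cluster_proteins <- function(sequences, identity_threshold = 0.25,
                             coverage_threshold = 0.5) {
  if (length(sequences) == 0 || any(!nzchar(sequences)))
    stop_mutstab("empty sequence(s)", "mutstab_value_error")
  if (is.null(names(sequences)))
    names(sequences) <- paste0("protein", seq_along(sequences))
  nm <- sort(names(sequences))
  n <- length(nm)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    data("BLOSUM62", package = "Biostrings", envir = environment())
    B62 <- get("BLOSUM62", envir = environment())
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      si <- sequences[[nm[i]]]; sj <- sequences[[nm[j]]]
      aln <- Biostrings::pairwiseAlignment(
        si, sj, type = "global", substitutionMatrix = B62,
        gapOpening = 10, gapExtension = 0.5)
      p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
      s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
      both <- p != "-" & s != "-"
      n_aln <- sum(both)
      if (n_aln == 0) next
      # identity over the full alignment length, coverage over the
      # jointly aligned region of each sequence
      identity <- sum(p[both] == s[both]) / length(p)
      cov_ok <- n_aln / nchar(si) >= coverage_threshold &&
                n_aln / nchar(sj) >= coverage_threshold
      if (identity > identity_threshold && cov_ok) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  cluster <- match(root, sort(unique(root)))
  data.frame(protein = nm, cluster = cluster, stringsAsFactors = FALSE)
}

#' Rank candidate structures for a protein
#'
#' Orders candidate structures by the documented selection criteria:
#' monomer/homomer preferred over heteromer; wild type over mutant;
#' fewer bound ligands; crystal structure over NMR; higher resolution.
#' Crystal structures worse than 3 A are excluded.
#'
#' @param candidates Data frame with columns `structure_id`, `multimer`
#'   (`"monomer"`/`"homomer"`/`"heteromer"`), `is_wild_type` (logical),
#'   `n_ligands`, `method` (`"xray"`/`"nmr"`), `resolution` (A, NA for
#'   NMR).
#' @return The input rows, filtered and ordered best first.
#' @export
rank_structures <- function(candidates) {
  c0 <- candidates
  drop <- c0$method == "xray" & !is.na(c0$resolution) & c0$resolution > 3
  c0 <- c0[!drop, , drop = FALSE]
  ord <- order(c0$multimer == "heteromer",        # FALSE first
               !c0$is_wild_type,
               c0$n_ligands,
               c0$method != "xray",
               ifelse(is.na(c0$resolution), Inf, c0$resolution))
  c0[ord, , drop = FALSE]
}
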