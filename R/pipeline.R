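# End-to-end pipeline: feature computation over a dataset and the
# command-level operations behind the command-line tool (predict,
# train, evaluate).

#' Compute the feature matrix for a mutation dataset
#'
#' Forward records are featurised on the wild-type structure and
#' sequence; reverse records on a naively mutated structure and the
#' mutant sequence (an externally built mutant structure can be
#' supplied per structure id via `mutant_structures`).  Rows whose
#' providers fail are reported, not fatal.
#'
#' @param dataset A `ddg_dataset`.
#' @param structures Named list of `ddg_structure` (by structure id) or
#'   a directory of `<structure_id>.pdb` files.
#' @param pssms Named list of `ddg_pssm` (by protein id) or a directory
#'   of `<protein_id>.pssm` files.
#' @param conservation A `ddg_conservation` table or its file path.
#' @param sphere_points SASA resolution.
#' @param pssm_convention Passed to [build_feature_vector()].
#' @return List with `features` (matrix aligned with `dataset`; failed
#'   rows are NA), `ok` (logical), `reasons` (character).
#' @export
compute_features <- function(dataset, structures, pssms, conservation,
                             sphere_points = 960,
                             pssm_convention = "difference") {
  if (is.character(structures) && length(structures) == 1) {
    paths <- list.files(structures, pattern = "\\.pdb$", full.names = TRUE)
    structures <- lapply(paths, parse_pdb)
    names(structures) <- sub("\\.pdb$", "", basename(paths))
  }
  if (is.character(pssms) && length(pssms) == 1) {
    paths <- list.files(pssms, pattern = "\\.pssm$", full.names = TRUE)
    pssms <- lapply(paths, read_psiblast_pssm)
    names(pssms) <- sub("\\.pssm$", "", basename(paths))
  }
  if (is.character(conservation))
    conservation <- read_conservation_table(conservation)

  n <- nrow(dataset)
  feats <- matrix(NA_real_, n, 10, dimnames = list(NULL, FEATURE_NAMES))
  ok <- logical(n)
  reasons <- character(n)
  prof_cache <- new.env(parent = emptyenv())
  wt_profile <- function(sid) {
    if (is.null(prof_cache[[sid]]))
      prof_cache[[sid]] <- sasa_profile(structures[[sid]],
                                        sphere_points = sphere_points)
    prof_cache[[sid]]
  }
  for (i in seq_len(n)) {
    rec <- dataset[i, ]
    res <- tryCatch({
      st <- structures[[rec$structure_id]]
      if (is.null(st))
        stop_mutstab(paste0("missing structure: ", rec$structure_id),
                     "mutstab_missing_feature_error")
      pm <- pssms[[rec$protein_id]]
      if (is.null(pm))
        stop_mutstab(paste0("missing PSSM: ", rec$protein_id),
                     "mutstab_missing_feature_error")
      if (rec$direction == "reverse") {
        st <- mutate_structure_naive(st, rec$chain, rec$position,
                                     wt = rec$mut, mut = rec$wt,
                                     icode = rec$icode)
        prof <- sasa_profile(st, sphere_points = sphere_points)
      } else {
        prof <- wt_profile(rec$structure_id)
      }
      build_feature_vector(rec, st, prof, pm, conservation,
                           pssm_convention = pssm_convention)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      reasons[i] <- conditionMessage(res)
    } else {
      feats[i, ] <- res
      ok[i] <- TRUE
    }
  }
  list(features = feats, ok = ok, reasons = reasons)
}

#' Parse a mutation specifier string
#'
#' Grammar: `CHAIN ":" WT POS [ICODE] MUT`, e.g. `"A:L104D"` (chain A,
#' Leu104 to Asp); an insertion code is appended to the position
#' (`"A:L104AD"` = Leu at 104A to Asp).
#'
#' @param spec Character vector of specifiers.
#' @return Data frame with chain, wt, position, icode, mut.
#' @export
parse_mutation_spec <- function(spec) {
  m <- regmatches(spec,
                  regexec("^([A-Za-z0-9]):([A-Z])([0-9]+)([A-Z]?)([A-Z])$",
                          spec))
  bad <- vapply(m, length, integer(1)) == 0
  if (any(bad))
    stop_mutstab(paste0("malformed mutation spec: ",
                        paste(spec[bad], collapse = ", ")),
                 "mutstab_format_error")
  data.frame(chain = vapply(m, `[`, "", 2),
             wt = vapply(m, `[`, "", 3),
             position = as.integer(vapply(m, `[`, "", 4)),
             icode = vapply(m, `[`, "", 5),
             mut = vapply(m, `[`, "", 6),
             stringsAsFactors = FALSE)
}

#' Predict ddG for mutations of one protein structure
#'
#' The command behind `predict`: takes a structure, one mutation source
#' (a mutation data frame / specifier vector, a mutation-list file, or
#' an alanine scan over the selected chains), and the feature
#' providers, and returns one row per mutation with the predicted ddG,
#' the core/surface location of the site, the ten feature values and
#' their per-feature contributions.  Rows that fail (e.g. wild-type
#' mismatch) are flagged with a reason and do not abort the run.
#'
#' @param structure_path PDB file of the (wild-type) protein.
#' @param model A `ddg_model` or path to a saved model file.
#' @param mutations Data frame (chain, position, wt, mut, optional
#'   icode) or character vector of specifiers like `"A:L104D"`.
#' @param mutation_file Path to a file of one specifier per line.
#' @param alanine_scan If `TRUE`, scan every non-alanine residue of the
#'   selected chains to alanine.
#' @param chains Optional chain selection.
#' @param pssm_path PSI-BLAST ASCII PSSM of the protein.
#' @param conservation_path Conservation table (TSV).
#' @param protein_id Protein identifier used in the conservation table;
#'   defaults to the structure id.
#' @param out Optional TSV output path.
#' @param sphere_points SASA resolution.
#' @return Data frame of predictions (invisibly written to `out`).
#' @export
cmd_predict <- function(structure_path, model, mutations = NULL,
                        mutation_file = NULL, alanine_scan = FALSE,
                        chains = NULL, pssm_path, conservation_path,
                        protein_id = NULL, out = NULL,
                        sphere_points = 960) {
  n_sources <- (!is.null(mutations)) + (!is.null(mutation_file)) +
    isTRUE(alanine_scan)
  if (n_sources != 1)
    stop_mutstab("exactly one mutation source must be given",
                 "mutstab_config_error")
  if (is.character(model)) model <- load_model(model)
  st <- parse_pdb(structure_path, chains = chains)
  if (is.null(protein_id)) protein_id <- st$id
  pssm <- read_psiblast_pssm(pssm_path)
  cons <- read_conservation_table(conservation_path)
  prof <- sasa_profile(st, sphere_points = sphere_points)

  if (!is.null(mutation_file))
    mutations <- readLines(mutation_file, warn = FALSE)
  if (is.character(mutations))
    mutations <- parse_mutation_spec(mutations[nzchar(trimws(mutations))])
  if (isTRUE(alanine_scan)) {
    r <- residues(st)
    r <- r[r$aa != "A", , drop = FALSE]  # skip native alanines
    mutations <- data.frame(chain = r$chain, position = r$resno,
                            icode = r$icode, wt = r$aa, mut = "A",
                            stringsAsFactors = FALSE)
  }
  if (is.null(mutations$icode)) mutations$icode <- ""

  n <- nrow(mutations)
  res_rows <- vector("list", n)
  for (i in seq_len(n)) {
    mu <- mutations[i, ]
    label <- sprintf("%s:%s%s%s%s", mu$chain, mu$wt, mu$position,
                     mu$icode, mu$mut)
    base <- data.frame(mutation = label, chain = mu$chain,
                       position = mu$position, icode = mu$icode,
                       wt = mu$wt, mut = mu$mut, stringsAsFactors = FALSE)
    row <- tryCatch({
      fv <- build_feature_vector(
        list(protein_id = protein_id, chain = mu$chain,
             position = mu$position, icode = mu$icode,
             wt = mu$wt, mut = mu$mut),
        st, prof, pssm, cons,
        pssm_convention = model$pssm_convention)
      fc <- feature_contributions(model, fv)
      loc <- prof$location[profile_row(prof, mu$chain, mu$position,
                                       mu$icode)]
      cbind(base,
            data.frame(ddg_pred = fc$prediction, location = loc,
                       status = "ok", reason = "",
                       stringsAsFactors = FALSE),
            as.data.frame(as.list(fv)),
            stats::setNames(as.data.frame(as.list(fc$contributions)),
                            paste0("contrib_", names(fc$contributions))))
    }, error = function(e) {
      cbind(base, data.frame(ddg_pred = NA_real_, location = NA_character_,
                             status = "failed",
                             reason = conditionMessage(e),
                             stringsAsFactors = FALSE))
    })
    res_rows[[i]] <- row
  }
  all_cols <- Reduce(union, lapply(res_rows, names))
  res_rows <- lapply(res_rows, function(r) {
    r[setdiff(all_cols, names(r))] <- NA
    r[all_cols]
  })
  result <- do.call(rbind, res_rows)
  if (!is.null(out))
    utils::write.table(result, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  result
}

read_dataset_file <- function(path) {
  head1 <- readLines(path, n = 1)
  if (all(c("protein_id", "direction", "pair_id") %in%
          strsplit(head1, ",")[[1]])) {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    d$icode[is.na(d$icode)] <- ""
    d$pair_id <- as.integer(d$pair_id)
    as_ddg_dataset(d, sub("\\.[^.]+$", "", basename(path)))
  } else {
    read_mutation_table(path)
  }
}

#' Train a model from a dataset and provider tree
#'
#' Computes features for every usable record, trains the scoring
#' function, saves it, and writes a training report (rows dropped and
#' why, parameters, fingerprint).
#'
#' @param mutations_path Mutation table (either a plain forward table
#'   or a full dataset CSV with direction/pair columns).
#' @param structures_dir Directory of `<structure_id>.pdb` files.
#' @param pssm_dir Directory of `<protein_id>.pssm` files.
#' @param conservation_path Conservation TSV.
#' @param out_path Where to save the model.
#' @param params A [ddg_model_params()].
#' @param report_path Optional JSON training-report path.
#' @param sphere_points SASA resolution.
#' @return The trained `ddg_model`, invisibly.
#' @export
cmd_train <- function(mutations_path, structures_dir, pssm_dir,
                      conservation_path, out_path,
                      params = ddg_model_params(), report_path = NULL,
                      sphere_points = 960) {
  dataset <- read_dataset_file(mutations_path)
  fx <- compute_features(dataset, structures_dir, pssm_dir,
                         conservation_path,
                         sphere_points = sphere_points)
  usable <- fx$ok & !is.na(dataset$ddg_exp)
  if (sum(usable) < 10)
    stop_mutstab("fewer than 10 usable training rows",
                 "mutstab_data_error")
  model <- train_ddg_model(fx$features[usable, , drop = FALSE],
                           dataset$ddg_exp[usable], params)
  save_model(model, out_path)
  if (!is.null(report_path)) {
    dropped <- which(!usable)
    jsonlite::write_json(
      list(n_records = nrow(dataset), n_used = sum(usable),
           dropped = lapply(dropped, function(i) list(
             row = i, reason = if (nzchar(fx$reasons[i])) fx$reasons[i]
                               else "missing experimental ddG")),
           params = unclass(params), fingerprint = model$fingerprint),
      report_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(model)
}

#' Cross-validate a dataset and write report files
#'
#' @inheritParams cmd_train
#' @param scheme A [cv_scheme()] (or a kind string).
#' @param out_prefix Report prefix passed to [write_cv_report()].
#' @param clusters_path Optional two-column TSV (protein, cluster) for
#'   CV5; computed from structure sequences when absent.
#' @return The `ddg_cv` result, invisibly.
#' @export
cmd_evaluate <- function(mutations_path, structures_dir, pssm_dir,
                         conservation_path, scheme, out_prefix,
                         params = ddg_model_params(),
                         clusters_path = NULL, sphere_points = 960) {
  if (is.character(scheme)) scheme <- cv_scheme(scheme)
  dataset <- read_dataset_file(mutations_path)
  fx <- compute_features(dataset, structures_dir, pssm_dir,
                         conservation_path,
                         sphere_points = sphere_points)
  if (!all(fx$ok))
    stop_mutstab(paste0("feature computation failed for ",
                        sum(!fx$ok), " record(s), e.g.: ",
                        fx$reasons[which(!fx$ok)[1]]),
                 "mutstab_data_error")
  clusters <- NULL
  if (scheme$kind == "CV5") {
    if (!is.null(clusters_path)) {
      clusters <- utils::read.table(clusters_path, header = TRUE,
                                    sep = "\t", stringsAsFactors = FALSE)
    } else {
      paths <- list.files(structures_dir, pattern = "\\.pdb$",
                          full.names = TRUE)
      seqs <- vapply(paths, function(p) structure_sequence(parse_pdb(p)),
                     "")
      names(seqs) <- sub("\\.pdb$", "", basename(paths))
      clusters <- cluster_proteins(seqs)
    }
  }
  cv <- run_cv(dataset, fx$features, scheme, params, clusters)
  write_cv_report(cv, out_prefix)
  invisible(cv)
}
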