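# Cross-validation protocols.  All schemes keep a forward mutation and
# its reverse partner on the same side of every split.

#' Cross-validation scheme
#'
#' Five protocols: `CV1`/`CV2` random splits training on 80%/50% of
#' mutations, repeated (default 100 times); `CV3` first subsamples up to
#' `cap` mutations per protein, then splits 80/20 (default 10 repeats);
#' `CV4` leave-one-protein-out; `CV5` leave-one-protein-cluster-out
#' (requires cluster assignments; all proteins similar to the held-out
#' one leave the training set together).
#'
#' @param kind One of `"CV1"`..`"CV5"`.
#' @param repeats Number of rounds (CV1-CV3; ignored for CV4/CV5).
#' @param fraction Training fraction for CV1/CV2 and the CV3 inner
#'   split.
#' @param cap Per-protein mutation cap for CV3.
#' @param seed Integer master seed; all round seeds derive from it.
#' @return List of class `ddg_cv_scheme`.
#' @export
cv_scheme <- function(kind = c("CV1", "CV2", "CV3", "CV4", "CV5"),
                      repeats = NULL, fraction = NULL, cap = 20,
                      seed = 1) {
  kind <- match.arg(kind)
  fraction <- fraction %||%
    switch(kind, CV1 = 0.8, CV2 = 0.5, CV3 = 0.8, 1)
  repeats <- repeats %||% switch(kind, CV1 = 100, CV2 = 100, CV3 = 10, 1)
  if (kind %in% c("CV1", "CV2") && (fraction <= 0 || fraction >= 1))
    stop_mutstab("fraction must be in (0,1)", "mutstab_value_error")
  if (cap < 1) stop_mutstab("cap must be >= 1", "mutstab_value_error")
  structure(list(kind = kind, repeats = as.integer(repeats),
                 fraction = fraction, cap = as.integer(cap),
                 seed = as.integer(seed)),
            class = "ddg_cv_scheme")
}

# sampling units: forward/reverse pairs move together; unpaired records
# are their own unit
pair_units <- function(dataset) {
  pid <- dataset$pair_id
  key <- ifelse(is.na(pid), paste0("solo", seq_len(nrow(dataset))),
                paste0("pair", pid))
  unname(split(seq_len(nrow(dataset)), factor(key, levels = unique(key))))
}

#' Train/test splits of a cross-validation scheme
#'
#' Materialises the splits without fitting any model; useful for
#' auditing the pairing invariant.  Every split keeps pair-linked
#' records on the same side.
#'
#' @param dataset A `ddg_dataset`.
#' @param scheme A [cv_scheme()].
#' @param clusters Cluster assignment data frame (`protein`, `cluster`)
#'   as from [cluster_proteins()]; required for CV5.
#' @return List of rounds, each a list with integer row indices `train`
#'   and `test` and the round `seed`.
#' @export
cv_splits <- function(dataset, scheme, clusters = NULL) {
  units <- pair_units(dataset)
  unit_protein <- vapply(units, function(i) dataset$protein_id[i[1]],
                         character(1))
  set.seed(scheme$seed)
  n_rounds <- switch(scheme$kind,
                     CV4 = length(unique(dataset$protein_id)),
                     CV5 = NA_integer_,
                     scheme$repeats)
  if (scheme$kind == "CV5") {
    if (is.null(clusters))
      stop_mutstab("CV5 requires cluster assignments",
                   "mutstab_config_error")
    missing <- setdiff(unique(dataset$protein_id), clusters$protein)
    if (length(missing))
      stop_mutstab(paste0("proteins without cluster assignment: ",
                          paste(missing, collapse = ", ")),
                   "mutstab_config_error")
    n_rounds <- length(unique(
      clusters$cluster[clusters$protein %in% dataset$protein_id]))
  }
  round_seeds <- sample.int(.Machine$integer.max - 1, n_rounds)

  splits <- vector("list", n_rounds)
  if (scheme$kind %in% c("CV1", "CV2")) {
    for (r in seq_len(n_rounds)) {
      set.seed(round_seeds[r])
      tr_units <- sample(seq_along(units),
                         round(scheme$fraction * length(units)))
      splits[[r]] <- list(train = unlist(units[tr_units]),
                          test = unlist(units[-tr_units]),
                          seed = round_seeds[r])
    }
  } else if (scheme$kind == "CV3") {
    by_protein <- split(seq_along(units), unit_protein)
    for (r in seq_len(n_rounds)) {
      set.seed(round_seeds[r])
      subset_units <- integer(0)
      for (pu in by_protein) {
        pu <- sample(pu)
        # greedy with skip: fill up to the cap, letting unpaired
        # records fill a one-mutation remainder a pair cannot
        lens <- lengths(units[pu])
        sel <- logical(length(pu))
        size <- 0L
        for (k in seq_along(pu)) {
          if (size + lens[k] <= scheme$cap) {
            sel[k] <- TRUE
            size <- size + lens[k]
          }
        }
        # parity fix: swap an included single for a skipped pair so the
        # subset reaches min(n, cap) exactly whenever attainable
        if (size == scheme$cap - 1L) {
          solo_in <- which(sel & lens == 1L)
          pair_out <- which(!sel & lens == 2L)
          if (length(solo_in) && length(pair_out)) {
            sel[solo_in[1]] <- FALSE
            sel[pair_out[1]] <- TRUE
          }
        }
        subset_units <- c(subset_units, pu[sel])
      }
      tr_units <- sample(subset_units,
                         round(scheme$fraction * length(subset_units)))
      te_units <- setdiff(subset_units, tr_units)
      splits[[r]] <- list(train = unlist(units[tr_units]),
                          test = unlist(units[te_units]),
                          seed = round_seeds[r])
    }
  } else if (scheme$kind == "CV4") {
    prots <- unique(dataset$protein_id)
    for (r in seq_along(prots)) {
      te_units <- which(unit_protein == prots[r])
      splits[[r]] <- list(train = unlist(units[-te_units]),
                          test = unlist(units[te_units]),
                          seed = round_seeds[r],
                          held_out = prots[r])
    }
  } else {  # CV5
    cl <- clusters$cluster[match(unit_protein, clusters$protein)]
    ids <- sort(unique(cl))
    for (r in seq_along(ids)) {
      te_units <- which(cl == ids[r])
      splits[[r]] <- list(train = unlist(units[-te_units]),
                          test = unlist(units[te_units]),
                          seed = round_seeds[r],
                          held_out = ids[r])
    }
  }
  splits
}

#' Run a cross-validation protocol
#'
#' Trains the scoring function on each round's training side and
#' evaluates on the held-out side, reporting per-round and mean R, RMSE
#' and slope.  For the exhaustive protocols (CV4/CV5, where every
#' mutation is tested exactly once) the pooled out-of-fold predictions
#' are returned, aligned with the dataset rows.
#'
#' @param dataset Pair-linked `ddg_dataset` with experimental ddG.
#' @param features Feature matrix, rows aligned with `dataset`.
#' @param scheme A [cv_scheme()].
#' @param params [ddg_model_params()] used for each round (the round
#'   seed overrides `params$seed`).
#' @param clusters Cluster assignments, required for CV5.
#' @return List of class `ddg_cv` with `scheme`, `rounds` (data frame:
#'   round, seed, n_train, n_test, R, RMSE, slope), `summary` (means),
#'   and `predictions` (CV4/CV5 only).
#' @export
run_cv <- function(dataset, features, scheme, params = ddg_model_params(),
                   clusters = NULL) {
  x <- as.matrix(features)
  if (nrow(x) != nrow(dataset))
    stop_mutstab("features and dataset differ in length",
                 "mutstab_shape_error")
  splits <- cv_splits(dataset, scheme, clusters)
  y <- dataset$ddg_exp
  exhaustive <- scheme$kind %in% c("CV4", "CV5")
  pooled <- if (exhaustive) rep(NA_real_, nrow(dataset))
  rounds <- data.frame(round = seq_along(splits),
                       seed = vapply(splits, `[[`, numeric(1), "seed"),
                       n_train = NA_integer_, n_test = NA_integer_,
                       R = NA_real_, RMSE = NA_real_, slope = NA_real_,
                       R_FR = NA_real_)
  for (r in seq_along(splits)) {
    sp <- splits[[r]]
    p <- params
    p$seed <- as.integer(sp$seed %% .Machine$integer.max)
    model <- train_ddg_model(x[sp$train, , drop = FALSE], y[sp$train], p)
    pred <- predict(model, x[sp$test, , drop = FALSE])
    rounds$n_train[r] <- length(sp$train)
    rounds$n_test[r] <- length(sp$test)
    if (exhaustive) pooled[sp$test] <- pred
    if (length(pred) >= 3 && stats::sd(pred) > 0 &&
        stats::sd(y[sp$test]) > 0) {
      rounds$R[r] <- pearson_r(pred, y[sp$test])
      rounds$slope[r] <- fit_slope(pred, y[sp$test])
    }
    rounds$RMSE[r] <- rmse(pred, y[sp$test])
    # anti-symmetry audit over the held-out pairs (the pairing rule
    # guarantees both members of a pair are in the test side together)
    te <- sp$test
    fwd <- te[dataset$direction[te] == "forward" &
                !is.na(dataset$pair_id[te])]
    if (length(fwd) >= 3) {
      rev_pos <- match(paste0("reverse", dataset$pair_id[fwd]),
                       paste0(dataset$direction[te], dataset$pair_id[te]))
      ok <- !is.na(rev_pos)
      if (sum(ok) >= 3) {
        pf <- pred[match(fwd[ok], te)]
        pr <- pred[rev_pos[ok]]
        if (stats::sd(pf) > 0 && stats::sd(pr) > 0)
          rounds$R_FR[r] <- antisymmetry_audit(pf, pr)$R_FR
      }
    }
  }
  out <- list(scheme = scheme, rounds = rounds,
              summary = list(mean_R = mean(rounds$R, na.rm = TRUE),
                             mean_RMSE = mean(rounds$RMSE, na.rm = TRUE),
                             mean_slope = mean(rounds$slope, na.rm = TRUE),
                             mean_R_FR = mean(rounds$R_FR, na.rm = TRUE),
                             n_rounds = nrow(rounds)))
  if (exhaustive) {
    out$predictions <- pooled
    out$summary$pooled_R <- pearson_r(pooled, y)
    out$summary$pooled_RMSE <- rmse(pooled, y)
    fwd <- which(dataset$direction == "forward" & !is.na(dataset$pair_id))
    rev <- match(dataset$pair_id[fwd],
                 ifelse(dataset$direction == "reverse", dataset$pair_id,
                        NA))
    ok <- !is.na(rev) & !is.na(pooled[fwd])
    if (sum(ok) >= 3)
      out$summary$pooled_R_FR <-
        antisymmetry_audit(pooled[fwd[ok]], pooled[rev[ok]])$R_FR
  }
  class(out) <- "ddg_cv"
  out
}

#' @export
print.ddg_cv <- function(x, ...) {
  cat(sprintf("%s cross-validation, %d round(s)\n", x$scheme$kind,
              nrow(x$rounds)))
  cat(sprintf("  mean R = %.3f, mean RMSE = %.3f kcal/mol\n",
              x$summary$mean_R, x$summary$mean_RMSE))
  if (!is.null(x$summary$pooled_R))
    cat(sprintf("  pooled out-of-fold R = %.3f, RMSE = %.3f\n",
                x$summary$pooled_R, x$summary$pooled_RMSE))
  invisible(x)
}

#' Write a cross-validation report
#'
#' Writes per-round metrics as TSV and the summary (with seeds) as JSON.
#'
#' @param cv A `ddg_cv`.
#' @param prefix Output path prefix; writes `<prefix>_rounds.tsv` and
#'   `<prefix>_summary.json`.
#' @export
write_cv_report <- function(cv, prefix) {
  utils::write.table(cv$rounds, paste0(prefix, "_rounds.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(kind = cv$scheme$kind, seed = cv$scheme$seed,
         R = cv$summary$mean_R, RMSE = cv$summary$mean_RMSE,
         R_FR = cv$summary$mean_R_FR, summary = cv$summary),
    paste0(prefix, "_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
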