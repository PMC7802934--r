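#' Random-forest model parameters
#'
#' Defaults follow the published configuration: 500 trees with 3
#' features considered per split; minimum terminal node size follows the
#' reference random-forest regression default (5).
#'
#' @param n_trees Number of trees (>= 1).
#' @param features_per_split Features sampled as split candidates
#'   (`mtry`).
#' @param min_leaf Minimum terminal node size.
#' @param seed Integer seed; training is deterministic given the seed.
#' @return List of class `ddg_model_params`.
#' @export
ddg_model_params <- function(n_trees = 500, features_per_split = 3,
                             min_leaf = 5, seed = 1) {
  stopifnot(n_trees >= 1, features_per_split >= 1)
  structure(list(n_trees = as.integer(n_trees),
                 features_per_split = as.integer(features_per_split),
                 min_leaf = as.integer(min_leaf),
                 seed = as.integer(seed)),
            class = "ddg_model_params")
}

#' Train the ddG scoring function
#'
#' Fits a random-forest regression of experimental ddG on the ten
#' evolutionary/structural features.  Intended to be trained on a
#' symmetric dataset (forward mutations plus their reverses with negated
#' ddG), which is what gives the predictor its low anti-symmetry bias.
#'
#' @param features Numeric matrix or data frame of feature values, one
#'   row per mutation; column names are recorded and enforced at
#'   prediction time.
#' @param targets Experimental ddG values (kcal/mol).
#' @param params A [ddg_model_params()].
#' @param pssm_convention PSSM feature convention the features were
#'   built with; stored as model metadata.
#' @return Object of class `ddg_model`.
#' @export
train_ddg_model <- function(features, targets, params = ddg_model_params(),
                            pssm_convention = "difference") {
  x <- as.matrix(features)
  if (nrow(x) != length(targets))
    stop_mutstab("features and targets differ in length",
                 "mutstab_shape_error")
  if (nrow(x) < 10)
    stop_mutstab("need at least 10 training samples", "mutstab_value_error")
  if (any(!is.finite(x)) || any(!is.finite(targets)))
    stop_mutstab("non-finite values in training data",
                 "mutstab_validation_error")
  if (is.null(colnames(x)))
    colnames(x) <- paste0("f", seq_len(ncol(x)))
  set.seed(params$seed)
  forest <- randomForest::randomForest(
    x = x, y = targets,
    ntree = params$n_trees,
    mtry = min(params$features_per_split, ncol(x)),
    nodesize = params$min_leaf,
    importance = FALSE)
  fp <- .data_fingerprint(x, targets)
  structure(list(forest = forest,
                 params = params,
                 feature_names = colnames(x),
                 pssm_convention = pssm_convention,
                 fingerprint = fp,
                 train_range = range(targets),
                 train_x = x, train_y = targets,
                 cache = new.env(parent = emptyenv()),
                 version = "1.0"),
            class = "ddg_model")
}

.data_fingerprint <- function(x, y) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(list(round(unname(x), 10), round(unname(y), 10)), f, version = 2)
  unname(tools::md5sum(f))
}

check_newdata <- function(model, features) {
  x <- as.matrix(features)
  if (is.null(dim(x)) || ncol(x) == 1 && length(model$feature_names) > 1)
    x <- matrix(x, nrow = 1)
  if (!is.null(colnames(x))) {
    if (!setequal(colnames(x), model$feature_names))
      stop_mutstab("feature names do not match the trained model",
                   "mutstab_schema_error")
    x <- x[, model$feature_names, drop = FALSE]
  } else if (ncol(x) != length(model$feature_names)) {
    stop_mutstab("feature count does not match the trained model",
                 "mutstab_schema_error")
  } else {
    colnames(x) <- model$feature_names
  }
  x
}

#' Predict ddG for feature vectors
#'
#' @param object A `ddg_model`.
#' @param newdata Feature vector (named), matrix or data frame.
#' @param ... Unused.
#' @return Numeric vector of predicted ddG (kcal/mol); positive =
#'   destabilizing.
#' @export
predict.ddg_model <- function(object, newdata, ...) {
  x <- check_newdata(object, newdata)
  unname(stats::predict(object$forest, x))
}

# per-tree node values: terminal nodes carry the forest's own node
# prediction; internal nodes the mean training target of rows routed
# through them.  The telescoping path sum then reproduces the forest
# prediction exactly.
tree_node_values <- function(tr, x, y) {
  nnode <- nrow(tr)
  sumv <- numeric(nnode)
  cnt <- numeric(nnode)
  node <- rep(1L, nrow(x))
  active <- seq_len(nrow(x))
  while (length(active)) {
    s <- rowsum(y[active], node[active])
    idx <- as.integer(rownames(s))
    sumv[idx] <- sumv[idx] + s[, 1]
    cnt[idx] <- cnt[idx] + as.vector(table(factor(node[active],
                                                  levels = idx)))
    term <- tr[node[active], 5] == -1
    active <- active[!term]
    if (!length(active)) break
    nd <- node[active]
    goleft <- x[cbind(active, tr[nd, 3])] <= tr[nd, 4]
    node[active] <- ifelse(goleft, tr[nd, 1], tr[nd, 2])
  }
  vals <- ifelse(cnt > 0, sumv / cnt, 0)
  is_term <- tr[, 5] == -1
  vals[is_term] <- tr[is_term, 6]
  vals
}

forest_tables <- function(model) {
  if (is.null(model$cache$trees)) {
    ntree <- model$params$n_trees
    trees <- vector("list", ntree)
    for (k in seq_len(ntree)) {
      # a constant-target forest grows rootless stumps getTree cannot
      # tabulate; represent them as a single terminal node
      tr <- tryCatch(randomForest::getTree(model$forest, k,
                                           labelVar = FALSE),
                     error = function(e) NULL)
      if (is.null(tr) || nrow(tr) == 0)
        tr <- matrix(c(0, 0, 0, 0, -1, mean(model$train_y)), 1, 6)
      trees[[k]] <- list(tree = tr,
                         values = tree_node_values(tr, model$train_x,
                                                   model$train_y))
    }
    model$cache$trees <- trees
  }
  model$cache$trees
}

#' Per-feature contributions of a prediction
#'
#' Decomposes a prediction into additive per-feature contributions by
#' tree-path attribution: along each tree's decision path the change in
#' node value at a split is credited to the split feature, then averaged
#' over trees.  `bias + sum(contributions)` equals the prediction.
#'
#' @param model A `ddg_model`.
#' @param features A single feature vector (named) or one-row matrix.
#' @return List with `prediction`, `bias` and `contributions` (named
#'   numeric, kcal/mol).
#' @export
feature_contributions <- function(model, features) {
  x <- check_newdata(model, features)
  if (nrow(x) != 1)
    stop_mutstab("feature_contributions takes a single feature vector",
                 "mutstab_shape_error")
  trees <- forest_tables(model)
  p <- length(model$feature_names)
  contrib <- numeric(p)
  bias <- 0
  pred <- 0
  for (tk in trees) {
    tr <- tk$tree
    vals <- tk$values
    node <- 1L
    bias <- bias + vals[1]
    while (tr[node, 5] != -1) {
      v <- tr[node, 3]
      nxt <- if (x[1, v] <= tr[node, 4]) tr[node, 1] else tr[node, 2]
      contrib[v] <- contrib[v] + vals[nxt] - vals[node]
      node <- nxt
    }
    pred <- pred + vals[node]
  }
  ntree <- length(trees)
  list(prediction = pred / ntree,
       bias = bias / ntree,
       contributions = setNames(contrib / ntree, model$feature_names))
}

#' Feature importance (impurity decrease)
#'
#' Total decrease in node impurity (residual sum of squares) from
#' splitting on each feature, averaged over all trees.
#'
#' @param model A `ddg_model`.
#' @return Named non-negative numeric vector.
#' @export
feature_importance <- function(model) {
  imp <- randomForest::importance(model$forest, type = 2)
  setNames(imp[, 1], rownames(imp))
}

#' Persist / restore a trained model
#'
#' The saved file embeds a format version, the model parameters, the
#' feature-name order, the PSSM convention and a training-set
#' fingerprint, so restored models are self-describing.
#'
#' @param model A `ddg_model`.
#' @param path File path.
#' @export
save_model <- function(model, path) {
  payload <- unclass(model)
  payload$cache <- NULL
  saveRDS(list(format = "mutstab_model", version = model$version,
               model = payload), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) NULL)
  if (is.null(obj) || !identical(obj$format, "mutstab_model") ||
      !identical(obj$version, "1.0"))
    stop_mutstab("not a compatible model file", "mutstab_compat_error")
  m <- obj$model
  m$cache <- new.env(parent = emptyenv())
  class(m) <- "ddg_model"
  m
}

#' @export
print.ddg_model <- function(x, ...) {
  cat("ddG random-forest scoring function\n")
  cat(sprintf("  trees: %d  mtry: %d  min leaf: %d  seed: %d\n",
              x$params$n_trees, x$params$features_per_split,
              x$params$min_leaf, x$params$seed))
  cat("  features:", paste(x$feature_names, collapse = ", "), "\n")
  cat("  PSSM convention:", x$pssm_convention, "\n")
  cat(sprintf("  trained on %d mutations (ddG %.2f .. %.2f kcal/mol)\n",
              nrow(x$train_x), x$train_range[1], x$train_range[2]))
  invisible(x)
}

#' @export
summary.ddg_model <- function(object, ...) {
  oob <- stats::predict(object$forest)
  r <- stats::cor(oob, object$train_y)
  cat("ddG random-forest scoring function\n")
  print(object)
  cat(sprintf("  out-of-bag: R = %.3f, RMSE = %.3f kcal/mol\n",
              r, sqrt(mean((oob - object$train_y)^2))))
  imp <- sort(feature_importance(object), decreasing = TRUE)
  cat("  importance (IncNodePurity):\n")
  for (nm in names(imp)) cat(sprintf("    %-9s %10.2f\n", nm, imp[nm]))
  invisible(list(oob_r = r, importance = imp))
}

#' @export
residuals.ddg_model <- function(object, ...) {
  object$train_y - stats::predict(object$forest)  # out-of-bag residuals
}

#' @export
plot.ddg_model <- function(x, ...) {
  imp <- sort(feature_importance(x))
  graphics::barplot(imp, horiz = TRUE, las = 1,
                    xlab = "IncNodePurity",
                    main = "Feature importance", ...)
  invisible(x)
}
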