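#' Configure a deep forest cascade
#'
#' Defaults follow deep-forest convention where the method description is
#' silent: two forest groups per layer (one predictive-clustering, one
#' per-label Gini) of `n_trees = 40` trees each, 5-fold internal
#' cross-fitting for the augmented representation, at most 20 layers, and
#' layer growth stopped once the tracked measure has not improved (beyond
#' `tol`) for `patience = 3` consecutive layers.
#'
#' @param n_trees trees per forest group.
#' @param n_folds internal cross-fitting folds for the out-of-fold
#'   representation.
#' @param max_layers hard cap on cascade depth.
#' @param patience consecutive non-improving layers before growth exits.
#' @param tracked_measure one of [tracked_measures()].
#' @param threshold label decision cut on the final scores.
#' @param conf_quantile quantile of first-layer confidences used as the
#'   feature-reuse threshold.
#' @param tol minimum improvement that counts as progress.
#' @param mtry,min_node,max_depth,bootstrap forwarded to [ml_forest()].
#' @param seed integer seed controlling every random choice in the cascade.
#' @return a `cascade_config` list.
#' @export
cascade_config <- function(n_trees = 40, n_folds = 5, max_layers = 20,
                           patience = 3, tracked_measure = "average_precision",
                           threshold = 0.5, conf_quantile = 0.3, tol = 1e-6,
                           mtry = NULL, min_node = 1, max_depth = 0,
                           bootstrap = TRUE, seed = 1) {
  stopifnot(tracked_measure %in% tracked_measures(),
            n_folds >= 2, max_layers >= 1, patience >= 1,
            threshold > 0, threshold < 1)
  structure(list(n_trees = n_trees, n_folds = n_folds,
                 max_layers = max_layers, patience = patience,
                 tracked_measure = tracked_measure, threshold = threshold,
                 conf_quantile = conf_quantile, tol = tol, mtry = mtry,
                 min_node = min_node, max_depth = max_depth,
                 bootstrap = bootstrap, seed = seed),
            class = "cascade_config")
}

# deterministic k-fold assignment from an integer seed (local RNG state)
kfold_assign <- function(n, k, seed) {
  k <- min(k, n)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed %% .Machine$integer.max)
  sample(rep_len(seq_len(k), n))
}

#' Fit one cascade layer
#'
#' Fits the two multi-label forest groups on the augmented input and builds
#' the layer's representation `H` (n x 2m: the rfpct block then the mlrf
#' block) from out-of-fold predictions under internal k-fold cross-fitting,
#' so no row's representation comes from forests trained on that row. The
#' per-fold forests are retained: at prediction time a group's output is the
#' mean over its fold forests.
#'
#' @param X_aug numeric matrix: original features, plus the previous layer's
#'   reused representation after the first layer.
#' @param Y binary label matrix.
#' @param config a [cascade_config()].
#' @param layer_seed integer seed for this layer.
#' @return a `cascade_layer` with `groups` (fitted fold forests per kind),
#'   `folds`, and `H`.
#' @export
layer_fit <- function(X_aug, Y, config = cascade_config(), layer_seed = 1) {
  X_aug <- as.matrix(X_aug)
  Y <- as.matrix(Y)
  n <- nrow(X_aug)
  m <- ncol(Y)
  k <- config$n_folds
  if (n < k) {
    warning("layer_fit: n = ", n, " < ", k, " folds; reducing to ", n)
    k <- n
  }
  folds <- kfold_assign(n, k, layer_seed)
  kinds <- c("rfpct", "mlrf")
  H <- matrix(NA_real_, n, 2 * m)
  groups <- list()
  for (gi in seq_along(kinds)) {
    kind <- kinds[gi]
    fold_models <- vector("list", k)
    for (fold in seq_len(k)) {
      tr <- folds != fold
      fm <- ml_forest(X_aug[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                      kind = kind, n_trees = config$n_trees,
                      mtry = config$mtry, min_node = config$min_node,
                      max_depth = config$max_depth,
                      bootstrap = config$bootstrap,
                      seed = layer_seed * 1000 + gi * 100 + fold)
      fold_models[[fold]] <- fm
      H[!tr, (gi - 1) * m + seq_len(m)] <-
        predict(fm, X_aug[!tr, , drop = FALSE])
    }
    groups[[kind]] <- fold_models
  }
  structure(list(groups = groups, folds = folds, H = H, m = m,
                 n_features_in = ncol(X_aug)),
            class = "cascade_layer")
}

# full-data prediction of one layer: per group, mean over fold forests
layer_predict <- function(layer, X_aug) {
  m <- layer$m
  H <- matrix(0, nrow(X_aug), 2 * m)
  for (gi in seq_along(layer$groups)) {
    preds <- lapply(layer$groups[[gi]], predict, newdata = X_aug)
    H[, (gi - 1) * m + seq_len(m)] <- Reduce(`+`, preds) / length(preds)
  }
  H
}

# averaged m-column score block of a 2m-column representation
rep_scores <- function(H) {
  m <- ncol(H) / 2
  (H[, seq_len(m), drop = FALSE] + H[, m + seq_len(m), drop = FALSE]) / 2
}

# per-instance confidence of a representation: mean over labels of
# max(score, 1 - score) on the averaged block
rep_confidence <- function(H) {
  s <- rep_scores(H)
  rowMeans(pmax(s, 1 - s))
}

#' Measure-aware feature reuse
#'
#' Per instance, the current layer's representation row `H_t` is kept only
#' when its confidence — the mean over labels of `max(score, 1 - score)` on
#' the averaged score block — reaches `conf_threshold`; low-confidence rows
#' retain the previous layer's reused representation `G_prev`, so a layer
#' cannot degrade an instance it is unsure about. At the first layer
#' (`G_prev = NULL`) the representation passes through unchanged.
#'
#' @param H_t current-layer representation (n x 2m).
#' @param G_prev previous reused representation of identical shape, or NULL.
#' @param conf_threshold confidence cut; rows below it keep `G_prev`.
#' @return `G_t`, with the per-instance confidences in
#'   `attr(, "confidence")`.
#' @export
measure_reuse <- function(H_t, G_prev = NULL, conf_threshold = 0) {
  conf <- rep_confidence(H_t)
  if (is.null(G_prev)) {
    return(structure(H_t, confidence = conf))
  }
  stopifnot(all(dim(H_t) == dim(G_prev)))
  keep <- conf >= conf_threshold
  G <- H_t
  G[!keep, ] <- G_prev[!keep, ]
  structure(G, confidence = conf)
}

#' Should layer growth stop?
#'
#' Growth exits once the tracked measure has failed to improve on its best
#' value (beyond `tol`) for `patience` consecutive layers. Improvement is
#' judged in the measure's own direction.
#'
#' @param history numeric vector of per-layer measure values so far.
#' @param direction `"lower"` or `"higher"`.
#' @param patience consecutive non-improving layers tolerated (default 3).
#' @param tol strict-improvement margin (default 1e-6).
#' @return TRUE when growth should exit.
#' @export
growth_stopped <- function(history, direction = c("higher", "lower"),
                           patience = 3, tol = 1e-6) {
  direction <- match.arg(direction)
  if (length(history) <= 1) return(FALSE)
  sgn <- if (direction == "higher") 1 else -1
  h <- sgn * history
  best <- h[1]
  since <- 0L
  for (v in h[-1]) {
    if (v > best + tol) {
      best <- v
      since <- 0L
    } else {
      since <- since + 1L
    }
    if (since >= patience) return(TRUE)
  }
  since >= patience
}

#' Best cascade depth from a measure history
#'
#' @inheritParams growth_stopped
#' @return index of the best layer (first occurrence on ties).
#' @export
best_depth <- function(history, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  if (direction == "higher") which.max(history) else which.min(history)
}

#' Fit a multi-label deep forest cascade
#'
#' Grows cascade layers on the feature matrix. Each layer's input is the
#' original features concatenated with the previous layer's reused
#' representation; each layer contributes an out-of-fold representation `H`
#' (see [layer_fit()]) which [measure_reuse()] turns into the reused
#' representation `G` carried forward. After every layer the tracked measure
#' is evaluated on the out-of-fold scores; growth exits when it has not
#' improved for `patience` layers (or at `max_layers`), and the selected
#' depth is the best layer in the history. The confidence threshold for
#' reuse is fixed at the `conf_quantile` quantile of the first layer's
#' confidences.
#'
#' @param X numeric feature matrix or a `feature_space`.
#' @param Y binary label matrix or a `label_matrix`.
#' @param config a [cascade_config()].
#' @return a `cascade_forest` model: `layers`, `history`, `best_depth`,
#'   `conf_threshold`, `threshold`, `config`.
#' @export
cascade_fit <- function(X, Y, config = cascade_config()) {
  if (inherits(X, "feature_space")) X <- X$X
  if (inherits(Y, "label_matrix")) Y <- Y$Y
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  dir <- measure_direction(config$tracked_measure)
  layers <- list()
  history <- numeric(0)
  G <- NULL
  conf_threshold <- NA_real_
  repeat {
    t0 <- Sys.time()
    X_aug <- if (is.null(G)) X else cbind(X, unclass_mat(G))
    layer_seed <- config$seed * 10000 + length(layers) + 1
    layer <- layer_fit(X_aug, Y, config, layer_seed)
    if (is.null(G)) {
      conf_threshold <- as.numeric(
        quantile(rep_confidence(layer$H), config$conf_quantile))
    }
    G <- measure_reuse(layer$H, G, conf_threshold)
    layers[[length(layers) + 1]] <- layer
    val <- eval_tracked(config$tracked_measure, Y, rep_scores(layer$H),
                        config$threshold)
    history <- c(history, val)
    sf_log("cascade layer ", length(layers), ": ",
           config$tracked_measure, " = ", signif(val, 5), " (",
           round(as.numeric(Sys.time() - t0, units = "secs"), 2), "s)")
    if (length(layers) >= config$max_layers ||
        growth_stopped(history, dir, config$patience, config$tol)) break
  }
  structure(list(layers = layers, history = history,
                 best_depth = best_depth(history, dir),
                 tracked_measure = config$tracked_measure,
                 conf_threshold = conf_threshold,
                 threshold = config$threshold,
                 n_features = ncol(X), m = ncol(Y),
                 label_names = colnames(Y), config = config),
            class = "cascade_forest")
}

unclass_mat <- function(G) {
  attr(G, "confidence") <- NULL
  G
}

#' Predict syndrome scores and label decisions from a fitted cascade
#'
#' Representations are propagated through layers 1..`best_depth` with the
#' stored reuse threshold; the final scores are the mean of the two forest
#' groups' outputs at the selected depth. A label is on when its score
#' exceeds `threshold`; a record whose every score falls below the threshold
#' gets its top-scoring label promoted (every case carries at least one
#' syndrome by the task's definition).
#'
#' @param object a `cascade_forest`.
#' @param newdata numeric matrix with the training feature count.
#' @param ... unused.
#' @return list with `scores` (n x m) and `labels` (binary n x m).
#' @export
predict.cascade_forest <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features) {
    stop("feature count mismatch: model fitted on ", object$n_features,
         " features, newdata has ", ncol(newdata))
  }
  G <- NULL
  H <- NULL
  for (d in seq_len(object$best_depth)) {
    X_aug <- if (is.null(G)) newdata else cbind(newdata, unclass_mat(G))
    H <- layer_predict(object$layers[[d]], X_aug)
    G <- measure_reuse(H, G, object$conf_threshold)
  }
  scores <- rep_scores(H)
  colnames(scores) <- object$label_names
  labels <- (scores > object$threshold) * 1L
  zero <- rowSums(labels) == 0
  if (any(zero)) {
    top <- apply(scores[zero, , drop = FALSE], 1, which.max)
    labels[cbind(which(zero), top)] <- 1L
  }
  list(scores = scores, labels = labels)
}

#' @export
print.cascade_forest <- function(x, ...) {
  cat("<cascade_forest> ", length(x$layers), " layers grown, depth ",
      x$best_depth, " selected by ", x$tracked_measure, " (history: ",
      paste(signif(x$history, 4), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Serialize / restore a fitted cascade
#'
#' Writes a JSON manifest (config, measure history, selected depth,
#' thresholds, label names) plus one RDS blob per layer. [load_cascade()]
#' restores a model whose predictions are bitwise-identical.
#'
#' @param model a `cascade_forest`; @param dir target directory.
#' @return `dir` (save) / the model (load), invisibly for save.
#' @export
save_cascade <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(model$config),
                   history = model$history,
                   best_depth = model$best_depth,
                   tracked_measure = model$tracked_measure,
                   conf_threshold = model$conf_threshold,
                   threshold = model$threshold,
                   n_features = model$n_features, m = model$m,
                   label_names = model$label_names,
                   n_layers = length(model$layers))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (i in seq_along(model$layers)) {
    saveRDS(model$layers[[i]], file.path(dir, sprintf("layer%03d.rds", i)))
  }
  invisible(dir)
}

#' @rdname save_cascade
#' @param dir directory written by [save_cascade()].
#' @export
load_cascade <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  layers <- lapply(seq_len(mf$n_layers), function(i) {
    readRDS(file.path(dir, sprintf("layer%03d.rds", i)))
  })
  cfg <- do.call(cascade_config, mf$config[names(mf$config) %in%
                                             names(formals(cascade_config))])
  structure(list(layers = layers, history = mf$history,
                 best_depth = mf$best_depth,
                 tracked_measure = mf$tracked_measure,
                 conf_threshold = mf$conf_threshold,
                 threshold = mf$threshold,
                 n_features = mf$n_features, m = mf$m,
                 label_names = mf$label_names, config = cfg),
            class = "cascade_forest")
}

#' Write per-record prediction scores and decisions
#'
#' TSV with record id, then per-label score columns and per-label decision
#' columns.
#'
#' @param pred result of [predict.cascade_forest()].
#' @param ids record ids; @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(pred, ids, path) {
  s <- pred$scores
  l <- pred$labels
  df <- data.frame(record_id = ids, check.names = FALSE)
  for (j in seq_len(ncol(s))) {
    df[[paste0("score.", colnames(s)[j])]] <- s[, j]
  }
  for (j in seq_len(ncol(l))) {
    df[[paste0("label.", colnames(s)[j])]] <- l[, j]
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
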