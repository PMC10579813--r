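#' Fit a multi-label random forest
#'
#' Grows an ensemble of multi-label decision trees whose leaves store mean
#' label vectors. Two node-generation methods are available — the two forest
#' groups a cascade layer pairs:
#' * `kind = "rfpct"`: predictive-clustering splits maximizing the total
#'   variance reduction of the label matrix across labels;
#' * `kind = "mlrf"`: splits maximizing per-label-averaged Gini reduction.
#'
#' Both use bootstrap resampling and `mtry = floor(sqrt(f))` feature
#' subsampling by default. Split ties break toward the lowest feature index,
#' then the lowest threshold; an impure node admitting no impurity-reducing
#' split (e.g. XOR label structure) is force-partitioned so deeper splits can
#' resolve it. Fitting is bitwise-deterministic for a given `seed` (the
#' forest uses its own RNG stream, not R's).
#'
#' @param X numeric feature matrix (n x f).
#' @param Y binary label matrix (n x m).
#' @param kind `"rfpct"` or `"mlrf"`.
#' @param n_trees trees per forest (default 40).
#' @param mtry features tried per split; default `floor(sqrt(f))`.
#' @param min_node minimum samples per leaf (default 1).
#' @param max_depth depth cap, 0 = unlimited.
#' @param bootstrap bootstrap-resample per tree (default TRUE).
#' @param seed integer seed.
#' @return an `ml_forest` object.
#' @export
ml_forest <- function(X, Y, kind = c("rfpct", "mlrf"), n_trees = 40,
                      mtry = NULL, min_node = 1, max_depth = 0,
                      bootstrap = TRUE, seed = 1) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  storage.mode(X) <- "double"
  storage.mode(Y) <- "double"
  stopifnot(nrow(X) == nrow(Y), nrow(X) >= 1, n_trees >= 1)
  if (nrow(X) < 2) {
    # degenerate single-sample input: every tree is the root leaf
  }
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  trees <- grow_forest_cpp(X, Y, as.integer(n_trees), as.integer(mtry),
                           criterion = if (kind == "rfpct") 0L else 1L,
                           as.integer(min_node), as.integer(max_depth),
                           isTRUE(bootstrap), as.double(seed))
  structure(list(kind = kind, trees = trees, n_trees = n_trees,
                 n_features = ncol(X), m = ncol(Y),
                 label_names = colnames(Y)),
            class = "ml_forest")
}

#' Fit a single multi-label decision tree
#'
#' Convenience wrapper for a one-tree forest with bootstrap off and all
#' features tried at each split — the deterministic base learner.
#'
#' @inheritParams ml_forest
#' @return an `ml_forest` with one tree.
#' @export
ml_tree <- function(X, Y, kind = c("rfpct", "mlrf"), min_node = 1,
                    max_depth = 0, seed = 1) {
  ml_forest(X, Y, kind = match.arg(kind), n_trees = 1, mtry = ncol(X),
            min_node = min_node, max_depth = max_depth, bootstrap = FALSE,
            seed = seed)
}

#' Predict label score vectors from a multi-label forest
#'
#' The forest score for a record is the arithmetic mean of the leaf label
#' vectors the record reaches across trees; entries lie in \[0, 1\].
#'
#' @param object an `ml_forest`.
#' @param newdata numeric matrix with the training feature count.
#' @param ... unused.
#' @return score matrix (n x m).
#' @export
predict.ml_forest <- function(object, newdata, ...) {
  if (is.null(object$trees) || !length(object$trees)) {
    stop("unfitted forest")
  }
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (ncol(newdata) != object$n_features) {
    stop("feature count mismatch: forest was fitted on ", object$n_features,
         " features, newdata has ", ncol(newdata))
  }
  out <- predict_forest_cpp(object$trees, newdata, object$m)
  colnames(out) <- object$label_names
  out
}

#' @export
print.ml_forest <- function(x, ...) {
  cat("<ml_forest kind=", x$kind, "> ", x$n_trees, " trees, ",
      x$n_features, " features, ", x$m, " labels\n", sep = "")
  invisible(x)
}
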