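#' @name multilabel-measures
#' @rdname multilabel-measures
#' @title Ranking- and label-based multi-label measures
#'
#' @description
#' The six classic multi-label measures over a binary truth matrix `Y`
#' (n x m), a binary prediction matrix `H`, and a confidence-score matrix
#' `F`. Throughout, rank 1 is the highest score and score ties are broken
#' toward the lower label index, so every measure is deterministic.
#'
#' * `hamming_loss(Y, H)` (lower better): mean per-cell disagreement.
#' * `one_error(Y, F)` (lower better): fraction of records whose top-scored
#'   label is not a true label.
#' * `coverage(Y, F)` (lower better): mean over records of (worst rank among
#'   true labels - 1). The default normalizer is `1/(n m)` — the form this
#'   method family reports; `conventional = TRUE` gives the textbook `1/n`
#'   form for cross-library comparison.
#' * `ranking_loss(Y, F)` (lower better): mean fraction of
#'   (positive, negative) label pairs with the positive scored `<=` the
#'   negative. Ties count fully against the model (`ties = "strict"`, the
#'   reported convention) or half (`ties = "half"`).
#' * `average_precision(Y, F)` (higher better): mean over records of the mean
#'   over true labels `j` of (number of true labels ranked at or above `j`) /
#'   rank(`j`).
#' * `macro_auc(Y, F)` (higher better): per-label pairwise AUC — the fraction
#'   of (positive instance, negative instance) pairs with the positive scored
#'   strictly higher (ties per `ties`) — macro-averaged over labels having
#'   both classes; single-class labels are excluded with a warning. Returns
#'   the macro average with the per-label vector attached as
#'   `attr(, "per_label")`.
#'
#' @param Y binary truth matrix.
#' @param H binary prediction matrix.
#' @param F numeric confidence-score matrix.
#' @param conventional use the `1/n` coverage normalizer instead of `1/(n m)`.
#' @param ties `"strict"` (ties fully penalized, the reported convention) or
#'   `"half"` (half credit).
#' @return a single numeric value (see each measure).
NULL

check_shapes <- function(Y, ...) {
  Y <- as.matrix(Y)
  if (nrow(Y) == 0 || ncol(Y) == 0) stop("empty input")
  for (M in list(...)) {
    if (!all(dim(as.matrix(M)) == dim(Y))) stop("shape mismatch")
  }
  Y
}

# rank vector of one score row: rank 1 = highest, ties -> lower label index
score_ranks <- function(fr) {
  m <- length(fr)
  ord <- order(-fr, seq_len(m))
  r <- integer(m)
  r[ord] <- seq_len(m)
  r
}

#' @rdname multilabel-measures
#' @export
hamming_loss <- function(Y, H) {
  Y <- check_shapes(Y, H)
  mean(as.matrix(H) != Y)
}

#' @rdname multilabel-measures
#' @export
one_error <- function(Y, F) {
  Y <- check_shapes(Y, F)
  F <- as.matrix(F)
  if (any(rowSums(Y) == 0)) stop("one_error: row without a true label")
  mean(vapply(seq_len(nrow(Y)), function(i) {
    top <- which.max(F[i, ]) # first max = lowest index on ties
    as.numeric(Y[i, top] != 1)
  }, numeric(1)))
}

#' @rdname multilabel-measures
#' @export
coverage <- function(Y, F, conventional = FALSE) {
  Y <- check_shapes(Y, F)
  F <- as.matrix(F)
  if (any(rowSums(Y) == 0)) stop("coverage: row without a true label")
  terms <- vapply(seq_len(nrow(Y)), function(i) {
    max(score_ranks(F[i, ])[Y[i, ] == 1]) - 1
  }, numeric(1))
  denom <- if (conventional) nrow(Y) else nrow(Y) * ncol(Y)
  sum(terms) / denom
}

#' @rdname multilabel-measures
#' @export
ranking_loss <- function(Y, F, ties = c("strict", "half")) {
  ties <- match.arg(ties)
  Y <- check_shapes(Y, F)
  F <- as.matrix(F)
  if (any(rowSums(Y) == 0)) stop("ranking_loss: row without a true label")
  terms <- vapply(seq_len(nrow(Y)), function(i) {
    pos <- F[i, Y[i, ] == 1]
    neg <- F[i, Y[i, ] == 0]
    if (length(neg) == 0) return(NA_real_)
    cmp <- outer(pos, neg, `-`)
    bad <- if (ties == "strict") sum(cmp <= 0) else
      sum(cmp < 0) + 0.5 * sum(cmp == 0)
    bad / (length(pos) * length(neg))
  }, numeric(1))
  if (anyNA(terms)) {
    warning("ranking_loss: ", sum(is.na(terms)),
            " row(s) without negative labels skipped")
  }
  mean(terms, na.rm = TRUE)
}

#' @rdname multilabel-measures
#' @export
average_precision <- function(Y, F) {
  Y <- check_shapes(Y, F)
  F <- as.matrix(F)
  if (any(rowSums(Y) == 0)) stop("average_precision: row without a true label")
  mean(vapply(seq_len(nrow(Y)), function(i) {
    r <- score_ranks(F[i, ])
    pr <- r[Y[i, ] == 1]
    mean(vapply(pr, function(rj) sum(pr <= rj) / rj, numeric(1)))
  }, numeric(1)))
}

#' @rdname multilabel-measures
#' @export
macro_auc <- function(Y, F, ties = c("strict", "half")) {
  ties <- match.arg(ties)
  Y <- check_shapes(Y, F)
  F <- as.matrix(F)
  per <- vapply(seq_len(ncol(Y)), function(j) {
    pos <- F[Y[, j] == 1, j]
    neg <- F[Y[, j] == 0, j]
    if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
    cmp <- outer(pos, neg, `-`)
    good <- if (ties == "strict") sum(cmp > 0) else
      sum(cmp > 0) + 0.5 * sum(cmp == 0)
    good / (length(pos) * length(neg))
  }, numeric(1))
  names(per) <- colnames(Y)
  if (anyNA(per)) {
    warning("macro_auc: ", sum(is.na(per)),
            " single-class label(s) excluded")
  }
  structure(mean(per, na.rm = TRUE), per_label = per)
}

#' Instance-based set-overlap measures
#'
#' The five set measures over true label sets `Y_i` and predicted sets `H_i`:
#' `mlACC` = mean Jaccard overlap `|Y_i ∩ H_i| / |Y_i ∪ H_i|`; `mlPRE` and
#' `mlREC` the mean per-instance precision `|Y_i ∩ H_i| / |H_i|` (an empty
#' predicted set contributes 0) and recall `|Y_i ∩ H_i| / |Y_i|`; `mlF1` the
#' harmonic mean of the aggregate `mlPRE` and `mlREC` (not instance-wise);
#' `ACC` the exact-match rate.
#'
#' @param Y binary truth matrix, every row with >= 1 one.
#' @param H binary prediction matrix of the same shape.
#' @return named numeric vector `mlACC`, `mlPRE`, `mlREC`, `mlF1`, `ACC`.
#' @export
set_measures <- function(Y, H) {
  Y <- check_shapes(Y, H)
  H <- as.matrix(H)
  if (any(rowSums(Y) == 0)) stop("set_measures: row without a true label")
  inter <- rowSums(Y == 1 & H == 1)
  uni <- rowSums(Y == 1 | H == 1)
  hsz <- rowSums(H == 1)
  mlacc <- mean(inter / uni)
  mlpre <- mean(ifelse(hsz == 0, 0, inter / hsz))
  mlrec <- mean(inter / rowSums(Y == 1))
  mlf1 <- if (mlpre + mlrec == 0) 0 else 2 * mlpre * mlrec / (mlpre + mlrec)
  acc <- mean(vapply(seq_len(nrow(Y)), function(i) {
    as.numeric(all(Y[i, ] == H[i, ]))
  }, numeric(1)))
  c(mlACC = mlacc, mlPRE = mlpre, mlREC = mlrec, mlF1 = mlf1, ACC = acc)
}

#' Optimization direction of a measure
#'
#' @param name measure name.
#' @return `"lower"` or `"higher"`.
#' @export
measure_direction <- function(name) {
  lower <- c("hamming_loss", "one_error", "coverage", "ranking_loss")
  higher <- c("average_precision", "macro_auc",
              "mlACC", "mlPRE", "mlREC", "mlF1", "ACC")
  if (name %in% lower) return("lower")
  if (name %in% higher) return("higher")
  stop("unknown measure: ", name)
}

#' The six tracked ranking/label measures
#' @return character vector of measure names usable as a cascade's tracked
#'   measure.
#' @export
tracked_measures <- function() {
  c("hamming_loss", "one_error", "coverage", "ranking_loss",
    "average_precision", "macro_auc")
}

# evaluate one tracked measure from scores (binary decisions at `threshold`
# where the measure needs them)
eval_tracked <- function(name, Y, scores, threshold = 0.5) {
  switch(name,
    hamming_loss = hamming_loss(Y, scores > threshold),
    one_error = one_error(Y, scores),
    coverage = coverage(Y, scores),
    ranking_loss = suppressWarnings(ranking_loss(Y, scores)),
    average_precision = average_precision(Y, scores),
    macro_auc = as.numeric(suppressWarnings(macro_auc(Y, scores))),
    stop("unknown tracked measure: ", name))
}

#' Compute all eleven measures at once
#'
#' @param Y binary truth matrix; @param H binary predictions; @param F score
#'   matrix.
#' @return data.frame with `measure`, `value`, `direction`.
#' @export
evaluate_all <- function(Y, H, F) {
  vals <- c(
    hamming_loss = hamming_loss(Y, H),
    one_error = one_error(Y, F),
    coverage = coverage(Y, F),
    ranking_loss = suppressWarnings(ranking_loss(Y, F)),
    average_precision = average_precision(Y, F),
    macro_auc = as.numeric(suppressWarnings(macro_auc(Y, F))),
    set_measures(Y, H))
  data.frame(measure = names(vals), value = unname(vals),
             direction = vapply(names(vals), measure_direction, character(1)),
             row.names = NULL)
}
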