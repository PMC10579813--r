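#' Multi-label cross-validation folds
#'
#' `method = "iterative"` implements iterative stratification: labels are
#' processed from rarest to commonest and each positive record is assigned
#' to the fold with the greatest remaining demand for that label (ties to
#' the fold with most remaining capacity, then lowest fold index), so rare
#' syndromes are spread across folds instead of landing in one. `"shuffle"`
#' is a plain random partition.
#'
#' @param Y binary label matrix or `label_matrix`.
#' @param k folds (default 5).
#' @param seed integer seed.
#' @param method `"iterative"` or `"shuffle"`.
#' @return integer fold assignment of length n.
#' @export
make_folds <- function(Y, k = 5, seed = 1,
                       method = c("iterative", "shuffle")) {
  method <- match.arg(method)
  if (inherits(Y, "label_matrix")) Y <- Y$Y
  Y <- as.matrix(Y)
  n <- nrow(Y)
  stopifnot(k >= 2, n >= k)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  if (method == "shuffle") {
    return(sample(rep_len(seq_len(k), n)))
  }
  fold <- rep(NA_integer_, n)
  capacity <- rep(n / k, k)
  # per-fold demand for each label, proportional to label frequency
  demand <- outer(rep(1 / k, k), colSums(Y))
  remaining <- function() which(is.na(fold))
  while (length(remaining()) > 0) {
    idx <- remaining()
    counts <- colSums(Y[idx, , drop = FALSE])
    active <- which(counts > 0)
    if (!length(active)) { # label-free rows (shouldn't occur post-cleaning)
      for (i in idx) {
        f <- which.max(capacity)
        fold[i] <- f
        capacity[f] <- capacity[f] - 1
      }
      break
    }
    lab <- active[which.min(counts[active])]
    for (i in idx[Y[idx, lab] == 1]) {
      d <- demand[, lab]
      best <- which(d == max(d))
      if (length(best) > 1) {
        best <- best[order(-capacity[best], best)][1]
      }
      fold[i] <- best
      pos <- which(Y[i, ] == 1)
      demand[best, pos] <- demand[best, pos] - 1
      capacity[best] <- capacity[best] - 1
    }
  }
  fold
}

#' Configure an end-to-end pipeline run
#'
#' @param records a [record_set()] or a records file path.
#' @param dialect a [record_dialect()] (used when `records` is a path).
#' @param synonyms optional synonym dictionary (named vector or TSV path).
#' @param scheme vectorization scheme, `"tfidf"` or `"binary"`.
#' @param k ReliefF neighbor count.
#' @param n_select features kept per fold; default `ceiling(f / 4)`.
#' @param similarity ReliefF similarity, `"pearson"` or `"cosine"`.
#' @param select run the feature-selection stage (FALSE = the ablation arm
#'   that feeds all features to the cascade).
#' @param cascade a [cascade_config()].
#' @param folds CV folds (default 5).
#' @param stratify fold method, `"iterative"` or `"shuffle"`.
#' @param seed integer seed for fold assignment and cascade seeds.
#' @param out_dir optional output directory for report files.
#' @return a `run_config` list.
#' @export
run_config <- function(records, dialect = record_dialect(), synonyms = NULL,
                       scheme = "tfidf", k = 10, n_select = NULL,
                       similarity = "pearson", select = TRUE,
                       cascade = cascade_config(), folds = 5,
                       stratify = "iterative", seed = 1, out_dir = NULL) {
  stopifnot(folds >= 2,
            cascade$tracked_measure %in% tracked_measures())
  structure(list(records = records, dialect = dialect, synonyms = synonyms,
                 scheme = scheme, k = k, n_select = n_select,
                 similarity = similarity, select = isTRUE(select),
                 cascade = cascade, folds = folds, stratify = stratify,
                 seed = seed, out_dir = out_dir),
            class = "run_config")
}

load_corpus <- function(cfg) {
  rs <- cfg$records
  if (is.character(rs)) rs <- read_records(rs, cfg$dialect)
  dict <- cfg$synonyms
  if (is.character(dict) && length(dict) == 1 && file.exists(dict)) {
    dict <- read_synonyms(dict)
  }
  if (!is.null(dict) && length(dict)) rs <- standardize_records(rs, dict)
  clean_records(rs)
}

#' Run the cross-validated pipeline
#'
#' Executes the full chain — preprocessing, vectorization, per-fold feature
#' selection (fitted on training rows only, so no test-fold leakage),
#' cascade fitting, thresholded prediction, evaluation — and reports every
#' fold's eleven measures plus their across-fold mean and sample standard
#' deviation. A feature-weight report fitted on the full corpus and the
#' pooled per-label AUC table are written alongside when `out_dir` is set.
#'
#' @param cfg a [run_config()].
#' @return list with `per_fold` (measure x fold data.frame), `summary`
#'   (measure, mean, sd), `fold_assign`, `selected` (per-fold feature-index
#'   lists), `per_label_auc`, and `weights` (full-corpus
#'   [feature_weights()]).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    sf_log("stage ", name, ": ",
           round(as.numeric(Sys.time() - t0, units = "secs"), 2), "s")
    out
  }
  rs <- stage("preprocess", load_corpus(cfg))
  vec <- stage("vectorize", vectorize_records(rs, cfg$scheme))
  fs <- vec$features
  lmx <- vec$labels
  n <- nrow(fs$X)
  f <- ncol(fs$X)
  n_select <- if (is.null(cfg$n_select)) ceiling(f / 4) else cfg$n_select
  fold_assign <- make_folds(lmx$Y, cfg$folds, cfg$seed, cfg$stratify)

  per_fold <- list()
  selected <- list()
  pooled_scores <- matrix(NA_real_, n, ncol(lmx$Y),
                          dimnames = list(NULL, lmx$label_names))
  for (fold in seq_len(cfg$folds)) {
    tr <- which(fold_assign != fold)
    te <- which(fold_assign == fold)
    fs_tr <- subset_feature_space(fs, tr)
    lm_tr <- subset_label_matrix(lmx, tr)
    if (cfg$select) {
      fw <- stage(paste0("select_fold", fold),
                  ml_relieff(fs_tr, lm_tr, k = cfg$k,
                             similarity = cfg$similarity))
      sel <- select_features(fw, min(n_select, f))
    } else {
      sel <- seq_len(f)
    }
    selected[[fold]] <- sel
    ccfg <- cfg$cascade
    ccfg$seed <- cfg$cascade$seed * 100 + fold
    model <- stage(paste0("fit_fold", fold),
                   cascade_fit(fs_tr$X[, sel, drop = FALSE], lm_tr$Y, ccfg))
    pred <- predict(model, fs$X[te, sel, drop = FALSE])
    pooled_scores[te, ] <- pred$scores
    evals <- evaluate_all(lmx$Y[te, , drop = FALSE], pred$labels,
                          pred$scores)
    per_fold[[fold]] <- evals$value
    measures <- evals$measure
  }
  pf <- do.call(cbind, per_fold)
  colnames(pf) <- paste0("fold", seq_len(cfg$folds))
  per_fold_df <- data.frame(measure = measures, pf, row.names = NULL)
  summary_df <- data.frame(measure = measures,
                           mean = rowMeans(pf),
                           sd = apply(pf, 1, sd), row.names = NULL)
  weights <- ml_relieff(fs, lmx, k = cfg$k, similarity = cfg$similarity)
  auc_pooled <- suppressWarnings(macro_auc(lmx$Y, pooled_scores))
  per_label_auc <- data.frame(label = lmx$label_names,
                              frequency = colSums(lmx$Y),
                              auc = as.numeric(attr(auc_pooled, "per_label")),
                              row.names = NULL)

  out <- list(per_fold = per_fold_df, summary = summary_df,
              fold_assign = fold_assign, selected = selected,
              per_label_auc = per_label_auc, weights = weights,
              n_select = n_select, features = fs, labels = lmx)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(per_fold_df, file.path(cfg$out_dir, "metrics_per_fold.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(summary_df, file.path(cfg$out_dir, "metrics_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_feature_weights(weights,
                          file.path(cfg$out_dir, "feature_weights.tsv"))
    write.table(per_label_auc, file.path(cfg$out_dir, "per_label_auc.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Paired ablation: cascade with vs without feature selection
#'
#' Runs the pipeline twice on identical folds and cascade seeds — once with
#' the ReliefF selection stage, once feeding every feature to the cascade —
#' and reports the paired table of the five tracked ranking measures, the
#' layout an ablation table uses.
#'
#' @param cfg a [run_config()] (its `select` field is overridden per arm).
#' @return list with `with_selection`, `without_selection` (full
#'   [run_pipeline()] results) and `table` (paired mean ± sd data.frame).
#' @export
run_ablation <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  cfg_with <- cfg
  cfg_with$select <- TRUE
  cfg_without <- cfg
  cfg_without$select <- FALSE
  if (!is.null(cfg$out_dir)) {
    cfg_with$out_dir <- file.path(cfg$out_dir, "with_selection")
    cfg_without$out_dir <- file.path(cfg$out_dir, "without_selection")
  }
  res_with <- run_pipeline(cfg_with)
  res_without <- run_pipeline(cfg_without)
  show <- c("hamming_loss", "one_error", "coverage", "ranking_loss",
            "average_precision")
  fmt <- function(res, arm) {
    s <- res$summary[res$summary$measure %in% show, ]
    data.frame(arm = arm, measure = s$measure, mean = s$mean, sd = s$sd,
               row.names = NULL)
  }
  tab <- rbind(fmt(res_without, "cascade_all_features"),
               fmt(res_with, "relieff_plus_cascade"))
  if (!is.null(cfg$out_dir)) {
    write.table(tab, file.path(cfg$out_dir, "ablation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(with_selection = res_with, without_selection = res_without,
       table = tab)
}
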