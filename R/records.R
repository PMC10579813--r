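#' Construct a record set
#'
#' A `record_set` holds parsed clinical records: one record is a unique id, a
#' set of symptom terms and a set of syndrome labels. Sets are stored as
#' character vectors without duplicates; empty sets are permitted at this
#' stage (cleaning is a separate step, see [clean_records()]).
#'
#' @param ids character vector of unique record ids.
#' @param symptoms list of character vectors (one per record).
#' @param labels list of character vectors (one per record).
#' @return an object of class `record_set`.
#' @seealso [read_records()], [clean_records()], [vectorize_records()]
#' @export
record_set <- function(ids, symptoms, labels) {
  ids <- as.character(ids)
  stopifnot(length(ids) == length(symptoms), length(ids) == length(labels))
  if (anyDuplicated(ids)) {
    stop("duplicate record ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  records <- lapply(seq_along(ids), function(i) {
    list(id = ids[[i]],
         symptoms = unique(as.character(symptoms[[i]])),
         labels = unique(as.character(labels[[i]])))
  })
  structure(list(records = records), class = "record_set")
}

#' @export
length.record_set <- function(x) length(x$records)

#' @export
print.record_set <- function(x, ...) {
  n <- length(x)
  cat("<record_set> ", n, " records, ",
      length(unique(unlist(lapply(x$records, `[[`, "symptoms")))),
      " distinct symptom terms, ",
      length(unique(unlist(lapply(x$records, `[[`, "labels")))),
      " distinct syndrome labels\n", sep = "")
  invisible(x)
}

record_ids <- function(rs) vapply(rs$records, `[[`, character(1), "id")

#' Describe the on-disk record dialect
#'
#' Records are delimited text with one record per line: a symptoms cell and a
#' labels cell (optionally preceded by an id cell), each cell holding terms
#' joined by `term_sep`.
#'
#' @param sep column separator (default tab).
#' @param term_sep separator between terms inside one cell (default `"|"`).
#' @param has_id does the file carry an explicit leading id column?
#' @param header does the file carry a header line?
#' @return a `record_dialect` list.
#' @export
record_dialect <- function(sep = "\t", term_sep = "|", has_id = FALSE,
                           header = FALSE) {
  stopifnot(is.character(sep), nchar(sep) == 1L,
            is.character(term_sep), nchar(term_sep) == 1L)
  structure(list(sep = sep, term_sep = term_sep, has_id = isTRUE(has_id),
                 header = isTRUE(header)), class = "record_dialect")
}

split_terms <- function(cell, term_sep) {
  if (is.na(cell) || !nzchar(trimws(cell))) return(character(0))
  out <- trimws(strsplit(cell, term_sep, fixed = TRUE)[[1]])
  out[nzchar(out)]
}

#' Read clinical records from delimited text
#'
#' Parses every row verbatim: records with empty symptom or label cells are
#' retained (cleaning is [clean_records()]'s job).
#'
#' @param path path to the records file.
#' @param dialect a [record_dialect()].
#' @return a [record_set()].
#' @export
read_records <- function(path, dialect = record_dialect()) {
  if (!inherits(dialect, "record_dialect")) {
    stop("unknown dialect: pass a record_dialect() object")
  }
  if (!file.exists(path)) stop("records file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (dialect$header && length(lines)) lines <- lines[-1]
  lines_keep <- nzchar(trimws(lines))
  offset <- if (dialect$header) 1L else 0L
  lineno <- which(lines_keep) + offset
  lines <- lines[lines_keep]
  ncol_expect <- if (dialect$has_id) 3L else 2L
  parts <- strsplit(lines, dialect$sep, fixed = TRUE)
  ids <- character(length(lines))
  symptoms <- vector("list", length(lines))
  labels <- vector("list", length(lines))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    # trailing empty cells are dropped by strsplit; pad them back
    if (length(p) < ncol_expect) p <- c(p, rep("", ncol_expect - length(p)))
    if (length(p) != ncol_expect) {
      stop("malformed row at line ", lineno[i], ": expected ", ncol_expect,
           " columns, found ", length(p))
    }
    if (dialect$has_id) {
      ids[i] <- p[1]
      symptoms[[i]] <- split_terms(p[2], dialect$term_sep)
      labels[[i]] <- split_terms(p[3], dialect$term_sep)
    } else {
      ids[i] <- paste0("r", i)
      symptoms[[i]] <- split_terms(p[1], dialect$term_sep)
      labels[[i]] <- split_terms(p[2], dialect$term_sep)
    }
  }
  record_set(ids, symptoms, labels)
}

#' Write a record set in the same dialect [read_records()] parses
#'
#' @param rs a [record_set()].
#' @param path output path.
#' @param dialect a [record_dialect()].
#' @return `path`, invisibly.
#' @export
write_records <- function(rs, path, dialect = record_dialect()) {
  stopifnot(inherits(rs, "record_set"), inherits(dialect, "record_dialect"))
  rows <- vapply(rs$records, function(r) {
    cells <- c(paste(r$symptoms, collapse = dialect$term_sep),
               paste(r$labels, collapse = dialect$term_sep))
    if (dialect$has_id) cells <- c(r$id, cells)
    paste(cells, collapse = dialect$sep)
  }, character(1))
  if (dialect$header) {
    hdr <- c("symptoms", "labels")
    if (dialect$has_id) hdr <- c("id", hdr)
    rows <- c(paste(hdr, collapse = dialect$sep), rows)
  }
  writeLines(rows, path, useBytes = TRUE)
  invisible(path)
}

#' Remove degenerate records and merge identical presentations
#'
#' Cleaning drops records lacking symptoms or labels, then merges records
#' whose symptom sets are identical into one record whose label set is the
#' union — the step that turns separately-recorded single-syndrome cases of
#' the same presentation into genuinely multi-label records. The merge key is
#' the symptom set (after standardization); patient identity is not available
#' in this data model. Idempotent.
#'
#' @param rs a [record_set()].
#' @return a cleaned [record_set()]; errors if nothing survives.
#' @export
clean_records <- function(rs) {
  stopifnot(inherits(rs, "record_set"))
  keep <- vapply(rs$records, function(r) {
    length(r$symptoms) > 0 && length(r$labels) > 0
  }, logical(1))
  n_dropped <- sum(!keep)
  recs <- rs$records[keep]
  if (!length(recs)) stop("cleaning removed every record")
  key <- vapply(recs, function(r) {
    paste(sort(r$symptoms), collapse = "\r")
  }, character(1))
  groups <- split(seq_along(recs), key)
  # preserve first-appearance order of each merged group
  groups <- groups[order(vapply(groups, min, integer(1)))]
  merged <- lapply(groups, function(ix) {
    list(id = recs[[ix[1]]]$id,
         symptoms = recs[[ix[1]]]$symptoms,
         labels = sort(unique(unlist(lapply(recs[ix], `[[`, "labels")))))
  })
  n_merged <- length(recs) - length(merged)
  sf_log("clean_records: dropped ", n_dropped, " empty record(s), merged ",
         n_merged, " duplicate presentation(s); ", length(merged), " remain")
  structure(list(records = unname(merged)), class = "record_set")
}

#' Read a synonym dictionary (variant -> standard term)
#'
#' Two-column tab-separated text: first column the variant spelling, second
#' the standard term. The mapping must be idempotent under one application
#' (no chains `a -> b`, `b -> c`); chained entries trigger a warning and are
#' applied once only, per [standardize_records()]'s apply-once semantics.
#'
#' @param path path to the TSV file.
#' @return a named character vector (names = variants, values = standards).
#' @export
read_synonyms <- function(path) {
  if (!file.exists(path)) stop("synonym dictionary not found: ", path)
  df <- read.delim(path, header = FALSE, sep = "\t",
                   colClasses = "character", quote = "", comment.char = "")
  if (ncol(df) != 2L) stop("synonym dictionary must have exactly 2 columns")
  dict <- stats::setNames(trimws(df[[2]]), trimws(df[[1]]))
  check_synonyms(dict)
  dict
}

check_synonyms <- function(dict) {
  if (!length(dict)) return(invisible(dict))
  chained <- names(dict)[dict %in% names(dict) & dict != names(dict) &
                           dict[dict] != dict]
  chained <- chained[!is.na(chained)]
  if (length(chained)) {
    warning("synonym dictionary is not idempotent (chained entries: ",
            paste(chained, collapse = ", "),
            "); terms are mapped once only", call. = FALSE)
  }
  invisible(dict)
}

#' Map symptom terms to standard names
#'
#' Each symptom term is replaced by its dictionary standard when present and
#' kept as-is otherwise (a single application — no chasing of chains); the
#' per-record symptom set is deduplicated after mapping, so two variants of
#' one standard term collapse to a single feature.
#'
#' @param rs a [record_set()].
#' @param dict named character vector as from [read_synonyms()]; may be empty.
#' @return the standardized [record_set()].
#' @export
standardize_records <- function(rs, dict = character(0)) {
  stopifnot(inherits(rs, "record_set"))
  if (!length(dict)) return(rs)
  check_synonyms(dict)
  unmapped <- 0L
  recs <- lapply(rs$records, function(r) {
    hit <- r$symptoms %in% names(dict)
    unmapped <<- unmapped + sum(!hit)
    mapped <- r$symptoms
    mapped[hit] <- unname(dict[mapped[hit]])
    r$symptoms <- unique(mapped)
    r
  })
  sf_log("standardize_records: ", unmapped, " term occurrence(s) passed ",
         "through unmapped")
  structure(list(records = recs), class = "record_set")
}

#' Vectorize records into a feature matrix and a label matrix
#'
#' Builds the design matrix `X` (n records x f symptom terms) and the binary
#' label matrix `Y` (n x m syndromes). Under `scheme = "binary"`, `X[i, p]`
#' is a presence indicator. Under `"tfidf"`, term frequency is the presence
#' indicator (symptoms are findings, not tokens: duplicates collapse to 1),
#' idf = ln((1 + n) / (1 + df)) + 1 (smoothed, so ubiquitous symptoms keep a
#' positive weight), and rows are L2-normalized.
#'
#' @param rs a cleaned [record_set()] (every record needs >= 1 symptom and
#'   >= 1 label; see [clean_records()]).
#' @param scheme `"tfidf"` (default) or `"binary"`.
#' @return list with components `features` (a `feature_space`: `X`,
#'   `feature_names`, `feature_min`, `feature_max`) and `labels` (a
#'   `label_matrix`: `Y`, `label_names`, `priors`).
#' @export
vectorize_records <- function(rs, scheme = c("tfidf", "binary")) {
  stopifnot(inherits(rs, "record_set"))
  scheme <- match.arg(scheme)
  ok <- vapply(rs$records, function(r) {
    length(r$symptoms) > 0 && length(r$labels) > 0
  }, logical(1))
  if (!all(ok)) stop("records must be cleaned before vectorization")
  n <- length(rs)
  vocab <- sort(unique(unlist(lapply(rs$records, `[[`, "symptoms"))))
  labs <- sort(unique(unlist(lapply(rs$records, `[[`, "labels"))))
  X <- matrix(0, n, length(vocab), dimnames = list(record_ids(rs), vocab))
  Y <- matrix(0L, n, length(labs), dimnames = list(record_ids(rs), labs))
  for (i in seq_len(n)) {
    X[i, match(rs$records[[i]]$symptoms, vocab)] <- 1
    Y[i, match(rs$records[[i]]$labels, labs)] <- 1L
  }
  if (scheme == "tfidf") {
    df <- colSums(X > 0)
    idf <- log((1 + n) / (1 + df)) + 1
    X <- sweep(X, 2, idf, `*`)
    X <- X / sqrt(rowSums(X^2)) # every row has >= 1 symptom, norm > 0
  }
  list(features = feature_space(X, scheme = scheme),
       labels = label_matrix(Y))
}

#' Bundle a design matrix with its feature index and per-feature ranges
#'
#' @param X numeric matrix (records x features) with column names.
#' @param scheme vectorization scheme tag, kept for provenance.
#' @return a `feature_space`.
#' @export
feature_space <- function(X, scheme = "binary") {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (ncol(X) > 0 && any(colSums(X != 0) == 0)) {
    stop("feature_space: all-zero feature column(s): ",
         paste(colnames(X)[colSums(X != 0) == 0], collapse = ", "))
  }
  structure(list(X = X, feature_names = colnames(X),
                 feature_min = apply(X, 2, min),
                 feature_max = apply(X, 2, max),
                 scheme = scheme), class = "feature_space")
}

#' Bundle a binary label matrix with its label index and priors
#'
#' @param Y binary matrix (records x labels) with column names; every row and
#'   column must contain at least one 1.
#' @return a `label_matrix` with `priors` = per-label column means `P(C)`.
#' @export
label_matrix <- function(Y) {
  Y <- as.matrix(Y)
  storage.mode(Y) <- "integer"
  if (is.null(colnames(Y))) colnames(Y) <- paste0("L", seq_len(ncol(Y)))
  if (!all(Y %in% c(0L, 1L))) stop("label matrix must be binary")
  if (any(rowSums(Y) == 0)) stop("label matrix has unlabeled record row(s)")
  if (any(colSums(Y) == 0)) stop("label matrix has empty label column(s)")
  structure(list(Y = Y, label_names = colnames(Y), priors = colMeans(Y)),
            class = "label_matrix")
}

# row subset that recomputes per-feature ranges / per-label priors, used to
# confine every fitted quantity to the training fold
subset_feature_space <- function(fs, idx) {
  X <- fs$X[idx, , drop = FALSE]
  structure(list(X = X, feature_names = fs$feature_names,
                 feature_min = apply(X, 2, min),
                 feature_max = apply(X, 2, max),
                 scheme = fs$scheme), class = "feature_space")
}

subset_label_matrix <- function(lm, idx) {
  Y <- lm$Y[idx, , drop = FALSE]
  structure(list(Y = Y, label_names = lm$label_names, priors = colMeans(Y)),
            class = "label_matrix")
}

#' Export matrices in sparse triplet text with a JSON sidecar
#'
#' Writes `X.triplet.tsv`, `Y.triplet.tsv` (1-based `row	col	value`),
#' `features.tsv`, `labels.tsv` name indices, and `matrices.json` with
#' dimensions and the vectorization scheme.
#'
#' @param fs a `feature_space`; @param lm a `label_matrix`;
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_matrices <- function(fs, lm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  triplet <- function(M, path) {
    nz <- which(M != 0, arr.ind = TRUE)
    df <- data.frame(row = nz[, 1], col = nz[, 2], value = M[nz])
    df <- df[order(df$row, df$col), ]
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  triplet(fs$X, file.path(dir, "X.triplet.tsv"))
  triplet(lm$Y, file.path(dir, "Y.triplet.tsv"))
  write.table(data.frame(index = seq_along(fs$feature_names),
                         feature = fs$feature_names),
              file.path(dir, "features.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(index = seq_along(lm$label_names),
                         label = lm$label_names),
              file.path(dir, "labels.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(n = nrow(fs$X), f = ncol(fs$X), m = ncol(lm$Y),
         scheme = fs$scheme),
    file.path(dir, "matrices.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Record/feature/label counts of a deposited dataset
#'
#' Reads a records file, applies the preprocessing chain (optional synonym
#' standardization, cleaning, merging) and reports the counts a dataset
#' summary table prints: record count, distinct symptom features, distinct
#' syndrome labels.
#'
#' @param path records file; @param dialect a [record_dialect()];
#' @param synonyms optional synonym dictionary path.
#' @return named list `n_records`, `n_features`, `n_labels`.
#' @export
dataset_statistics <- function(path, dialect = record_dialect(),
                               synonyms = NULL) {
  rs <- read_records(path, dialect)
  if (!is.null(synonyms)) rs <- standardize_records(rs, read_synonyms(synonyms))
  rs <- clean_records(rs)
  list(n_records = length(rs),
       n_features = length(unique(unlist(lapply(rs$records, `[[`,
                                                "symptoms")))),
       n_labels = length(unique(unlist(lapply(rs$records, `[[`, "labels")))))
}
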