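#' Configure the synthetic clinical-record generator
#'
#' The generator emulates the structure of preprocessed syndrome-record
#' corpora: sparse binary symptom features, several co-occurring syndrome
#' labels per record, long-tailed label frequencies (Zipf marginals), and a
#' minority of label-informative features among many noise features.
#' Defaults mimic the scale of a real outpatient stomach-disease corpus
#' (n = 436 records, 323 features of which ~10% are informative, 49 labels);
#' unit tests use much smaller configurations.
#'
#' @param n records.
#' @param f_informative,f_noise informative / pure-noise feature counts.
#' @param m syndrome labels.
#' @param labels_per_record mean label-set cardinality (drives the Zipf
#'   marginal scale).
#' @param label_correlation pairwise co-occurrence strength in \[0, 1\]:
#'   probability that a correlated label pair is drawn comonotonically.
#' @param signal added occurrence probability of an informative feature when
#'   its assigned label is present (effect size).
#' @param base_rate baseline occurrence probability of every feature.
#' @param tail Zipf exponent of the label marginals (larger = longer tail).
#' @param seed integer seed.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n = 436, f_informative = 33, f_noise = 290, m = 49,
                         labels_per_record = 2, label_correlation = 0.3,
                         signal = 0.6, base_rate = 0.1, tail = 1.2,
                         seed = 1) {
  stopifnot(n >= 1, f_informative >= 1, f_noise >= 0, m >= 1,
            signal >= 0, base_rate > 0, base_rate + signal <= 1,
            label_correlation >= 0, label_correlation <= 1)
  if (labels_per_record > m) stop("labels_per_record > m is infeasible")
  structure(list(n = n, f_informative = f_informative, f_noise = f_noise,
                 m = m, labels_per_record = labels_per_record,
                 label_correlation = label_correlation, signal = signal,
                 base_rate = base_rate, tail = tail, seed = seed),
            class = "synth_config")
}

#' Generate a synthetic multi-label record corpus with known ground truth
#'
#' Label marginals are Zipf-distributed, `P(l) ∝ l^(-tail)`, scaled so the
#' expected cardinality is `labels_per_record` (capped at 0.95). Consecutive
#' label pairs (1,2), (3,4), ... are correlated: with probability
#' `label_correlation` the pair is drawn from a comonotone coupling (one
#' shared uniform), which preserves both marginals exactly while inducing
#' positive co-occurrence; otherwise the two labels are independent. Records
#' left label-free are given one label drawn from the marginals. Each
#' informative feature is assigned a label round-robin and occurs with
#' probability `base_rate + signal` when that label is present, `base_rate`
#' otherwise; noise features occur with `base_rate` independently of the
#' labels, so at `signal = 0` informative and noise features are
#' exchangeable. Records left symptom-free get one uniformly drawn feature
#' switched on, so cleaning never drops a synthetic record.
#'
#' @param cfg a [synth_config()].
#' @return list with `records` (a [record_set()]), `features` (binary
#'   `feature_space` from [vectorize_records()]), `labels` (`label_matrix`),
#'   `truth` (names of the informative features) and `truth_idx` (their
#'   column indices in `features`).
#' @export
synth_generate <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  n <- cfg$n
  m <- cfg$m
  p <- (seq_len(m))^(-cfg$tail)
  p <- pmin(cfg$labels_per_record * p / sum(p), 0.95)

  Y <- matrix(0L, n, m)
  pair_starts <- seq(1, m - 1, by = 2)
  for (i in seq_len(n)) {
    for (a in pair_starts) {
      b <- a + 1
      if (stats::runif(1) < cfg$label_correlation) {
        v <- stats::runif(1)
        Y[i, a] <- as.integer(v < p[a])
        Y[i, b] <- as.integer(v < p[b])
      } else {
        Y[i, a] <- stats::rbinom(1, 1, p[a])
        Y[i, b] <- stats::rbinom(1, 1, p[b])
      }
    }
    if (m %% 2 == 1) Y[i, m] <- stats::rbinom(1, 1, p[m])
    if (sum(Y[i, ]) == 0) Y[i, sample.int(m, 1, prob = p)] <- 1L
  }

  f <- cfg$f_informative + cfg$f_noise
  fnames <- sprintf("sym%04d", seq_len(f))
  lnames <- sprintf("synd%03d", seq_len(m))
  assigned <- rep_len(seq_len(m), cfg$f_informative)
  X <- matrix(0L, n, f)
  for (j in seq_len(f)) {
    if (j <= cfg$f_informative) {
      pr <- cfg$base_rate + cfg$signal * Y[, assigned[j]]
    } else {
      pr <- rep(cfg$base_rate, n)
    }
    X[, j] <- stats::rbinom(n, 1, pr)
  }
  empty <- rowSums(X) == 0
  if (any(empty)) {
    X[cbind(which(empty), sample.int(f, sum(empty), replace = TRUE))] <- 1L
  }

  rs <- record_set(sprintf("syn_r%05d", seq_len(n)),
                   symptoms = lapply(seq_len(n), function(i) {
                     fnames[X[i, ] == 1L]
                   }),
                   labels = lapply(seq_len(n), function(i) {
                     lnames[Y[i, ] == 1L]
                   }))
  vec <- vectorize_records(rs, "binary")
  truth <- fnames[seq_len(cfg$f_informative)]
  list(records = rs, features = vec$features, labels = vec$labels,
       truth = truth,
       truth_idx = match(intersect(truth, vec$features$feature_names),
                         vec$features$feature_names))
}

#' Introduce spelling variants and the dictionary that undoes them
#'
#' Replaces a fraction of per-record term occurrences by synthetic variant
#' strings (`term~v1` / `term~v2`) and returns the synonym dictionary mapping
#' every introduced variant back to its standard term, so
#' `standardize_records(textualize(...))` reproduces the original
#' vectorization exactly. Deterministic for a fixed seed.
#'
#' @param rs a [record_set()].
#' @param variant_rate fraction of term occurrences to vary, in \[0, 1\].
#' @param seed integer seed.
#' @return list with `records` (varied [record_set()]) and `dictionary`
#'   (named character vector, variant -> standard).
#' @export
textualize <- function(rs, variant_rate = 0.3, seed = 1) {
  stopifnot(inherits(rs, "record_set"),
            variant_rate >= 0, variant_rate <= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  dict <- character(0)
  recs <- lapply(rs$records, function(r) {
    vary <- stats::runif(length(r$symptoms)) < variant_rate
    if (any(vary)) {
      variants <- paste0(r$symptoms[vary], "~v",
                         sample(1:2, sum(vary), replace = TRUE))
      dict[variants] <<- r$symptoms[vary]
      r$symptoms <- unique(c(r$symptoms[!vary], variants))
    }
    r
  })
  list(records = structure(list(records = recs), class = "record_set"),
       dictionary = dict)
}
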