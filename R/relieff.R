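#' Pearson correlation of two sample vectors
#'
#' Plain product-moment correlation,
#' \eqn{\rho = \sum (x_i-\bar x)(y_i-\bar y) / \sqrt{\sum (x_i-\bar x)^2
#' \sum (y_i-\bar y)^2}}. Unlike [stats::cor()], a zero-variance input is an
#' error here: the similarity layer above substitutes a floor instead (see
#' [sample_similarity()]).
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return correlation in \[-1, 1\].
#' @export
pcc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  dx <- x - mean(x)
  dy <- y - mean(y)
  vx <- sum(dx^2)
  vy <- sum(dy^2)
  if (vx == 0 || vy == 0) stop("pcc: zero-variance vector")
  sum(dx * dy) / sqrt(vx * vy)
}

#' Similarity between two sample vectors
#'
#' The method's sample similarity is the reciprocal of the Pearson distance,
#' `sim = 1 / (1 - rho)`: the Pearson distance lives in the open interval
#' (0, 2), so `sim` ranges over (0.5, Inf), reaching 0.5 at perfect
#' anticorrelation and growing without bound as samples align. Because
#' duplicate-direction samples do occur in sparse clinical data, `rho` is
#' clamped at `1 - epsilon` so the similarity tops out at `1/epsilon`. A
#' zero-variance vector yields the floor value `epsilon` (logged, not an
#' error). `similarity = "cosine"` gives the ablation baseline
#' `(1 + cos)/2 + epsilon`, likewise strictly positive.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @param similarity `"pearson"` (default) or `"cosine"`.
#' @param epsilon clamp/floor constant, default `1e-6`.
#' @return a similarity > 0.
#' @export
sample_similarity <- function(x, y, similarity = c("pearson", "cosine"),
                              epsilon = 1e-6) {
  similarity <- match.arg(similarity)
  stopifnot(epsilon > 0)
  if (similarity == "pearson") {
    rho <- tryCatch(pcc(x, y), error = function(e) NA_real_)
    if (is.na(rho)) {
      sf_log("sample_similarity: zero-variance vector, using floor ", epsilon)
      return(epsilon)
    }
    1 / (1 - min(rho, 1 - epsilon))
  } else {
    nx <- sqrt(sum(x^2))
    ny <- sqrt(sum(y^2))
    if (nx == 0 || ny == 0) {
      sf_log("sample_similarity: zero-norm vector, using floor ", epsilon)
      return(epsilon)
    }
    (1 + sum(x * y) / (nx * ny)) / 2 + epsilon
  }
}

# full n x n similarity matrix over the rows of X; vectorized but must agree
# with sample_similarity() entrywise
similarity_matrix <- function(X, similarity = "pearson", epsilon = 1e-6) {
  n <- nrow(X)
  if (similarity == "pearson") {
    sds <- apply(X, 1, stats::sd)
    R <- suppressWarnings(stats::cor(t(X)))
    R[is.na(R)] <- NA_real_
    S <- 1 / (1 - pmin(R, 1 - epsilon))
    bad <- sds == 0
    if (any(bad)) S[bad, ] <- S[, bad] <- epsilon
    S[is.na(S)] <- epsilon
  } else {
    nrm <- sqrt(rowSums(X^2))
    nrm_safe <- ifelse(nrm == 0, 1, nrm)
    C <- tcrossprod(X / nrm_safe)
    C <- pmin(pmax(C, -1), 1)
    S <- (1 + C) / 2 + epsilon
    bad <- nrm == 0
    if (any(bad)) S[bad, ] <- S[, bad] <- epsilon
  }
  S
}

#' Hit and miss neighborhoods of one probe record
#'
#' For probe `t` with label set `LS_t`: `hit` holds the up-to-`k`
#' highest-similarity records whose label set equals `LS_t` exactly; for each
#' syndrome class `C` outside `LS_t`, `miss[[C]]` holds the up-to-`k`
#' highest-similarity records whose label set contains `C`. The probe itself
#' is excluded everywhere; similarity ties break toward the lower record
#' index. A probe with a unique label set has an empty hit list (its hit term
#' contributes nothing to the weight update).
#'
#' @param t probe row index.
#' @param fs a `feature_space`; @param lm a `label_matrix`.
#' @param k neighbor count (default 10).
#' @inheritParams sample_similarity
#' @return list with `t`, `label_set`, `hit` (data.frame `index`, `sim`) and
#'   `miss` (named list of such data.frames).
#' @export
find_neighbors <- function(t, fs, lm, k = 10,
                           similarity = c("pearson", "cosine"),
                           epsilon = 1e-6) {
  similarity <- match.arg(similarity)
  X <- fs$X
  Y <- lm$Y
  stopifnot(nrow(X) >= 2, t >= 1, t <= nrow(X), k >= 1)
  sims <- vapply(seq_len(nrow(X)), function(j) {
    if (j == t) return(-Inf)
    sample_similarity(X[t, ], X[j, ], similarity, epsilon)
  }, numeric(1))
  keys <- label_keys(Y)
  ctx <- neighbor_context(t, sims, keys, Y, k)
  names(ctx$miss) <- lm$label_names[as.integer(names(ctx$miss))]
  ctx
}

label_keys <- function(Y) {
  apply(Y, 1, function(r) paste(which(r == 1L), collapse = ","))
}

# shared neighbor logic given a precomputed similarity row (probe at -Inf).
# Ranking quantizes similarity to 12 significant digits: mathematically tied
# similarities (ubiquitous in low-dimensional or duplicated records, where
# correlations hit +/-1 exactly) then break by record index irrespective of
# the float path that produced them. Weight terms keep full precision.
neighbor_context <- function(t, sims, keys, Y, k) {
  ord <- order(-signif(sims, 12), seq_along(sims)) # ties -> lower index
  ord <- ord[is.finite(sims[ord])]
  hit_idx <- ord[keys[ord] == keys[t]]
  hit_idx <- hit_idx[seq_len(min(k, length(hit_idx)))]
  ls <- which(Y[t, ] == 1L)
  out_classes <- setdiff(seq_len(ncol(Y)), ls)
  miss <- lapply(out_classes, function(C) {
    mi <- ord[Y[ord, C] == 1L]
    mi <- mi[seq_len(min(k, length(mi)))]
    data.frame(index = mi, sim = sims[mi])
  })
  names(miss) <- out_classes
  list(t = t, label_set = ls,
       hit = data.frame(index = hit_idx, sim = sims[hit_idx]),
       miss = miss)
}

#' Range-scaled per-feature difference between two records
#'
#' `|X[i, p] - X[j, p]|` scaled by the feature's observed range, so every
#' feature contributes on a common \[0, 1\] scale; a constant feature (zero
#' range) contributes 0.
#'
#' @param p feature index; @param i,j record indices; @param fs a
#'   `feature_space`.
#' @return difference in \[0, 1\].
#' @export
feature_diff <- function(p, i, j, fs) {
  rng <- unname(fs$feature_max[p] - fs$feature_min[p])
  if (rng == 0) return(0)
  unname(abs(fs$X[i, p] - fs$X[j, p])) / rng
}

#' Multi-label ReliefF feature weights with similarity weighting
#'
#' Scores each symptom feature by its power to separate records with
#' different syndrome label sets. Every record is visited once as the probe
#' (traversal, not random sampling, so low-frequency presentations are never
#' missed). For probe `t` and feature `p`, the weight update subtracts the
#' similarity-weighted mean range-scaled difference to the hit neighbors
#' (same label set — a discriminative feature should be locally constant
#' there) and adds, for every class `C` outside the probe's label set, the
#' prior-ratio-weighted similarity-weighted mean difference to the `C`-miss
#' neighbors:
#' \deqn{W_p \mathrel{-}= \frac{\sum_j sim(t, Hit_j)\, d(p, x_t, Hit_j)}
#'   {n \sum_j sim(t, Hit_j)} ;\quad
#'   W_p \mathrel{+}= \sum_{C \notin LS_t} \frac{P(C)}{1 - P(C_{x_t})}
#'   \frac{\sum_j sim(t, Miss_{Cj})\, d(p, x_t, Miss_{Cj})}
#'   {n \sum_j sim(t, Miss_{Cj})}}
#' with `P(C)` the label priors and `P(C_{x_t})` taken as the mean prior of
#' the probe's labels (this reduces to the classic ReliefF prior ratio for
#' single-label probes), clamped below `1 - 1e-12`. Empty hit or miss
#' neighborhoods contribute 0. Deterministic for a fixed input ordering.
#'
#' @param fs a `feature_space`; @param lm a `label_matrix`.
#' @param k neighbor count (default 10, the conventional ReliefF
#'   neighborhood).
#' @inheritParams sample_similarity
#' @return a `feature_weights` object: `W` (named weight vector) and `order`
#'   (feature indices by descending weight, ties toward the lower index).
#' @export
ml_relieff <- function(fs, lm, k = 10, similarity = c("pearson", "cosine"),
                       epsilon = 1e-6) {
  similarity <- match.arg(similarity)
  X <- fs$X
  Y <- lm$Y
  n <- nrow(X)
  f <- ncol(X)
  if (f == 0) stop("ml_relieff: no features")
  if (n < 2) stop("ml_relieff: need at least 2 records")
  stopifnot(nrow(Y) == n, k >= 1)
  priors <- lm$priors
  rng <- fs$feature_max - fs$feature_min
  rng_safe <- ifelse(rng == 0, 1, rng) # constant feature -> diff 0 anyway
  S <- similarity_matrix(X, similarity, epsilon)
  keys <- label_keys(Y)
  W <- numeric(f)
  for (t in seq_len(n)) {
    sims <- S[t, ]
    sims[t] <- -Inf
    ctx <- neighbor_context(t, sims, keys, Y, k)
    d_to <- function(idx) { # |x_t - x_j| / range, rows = neighbors
      abs(X[idx, , drop = FALSE] -
            matrix(X[t, ], length(idx), f, byrow = TRUE)) /
        matrix(rng_safe, length(idx), f, byrow = TRUE)
    }
    if (nrow(ctx$hit) > 0) {
      hs <- ctx$hit$sim
      W <- W - colSums(d_to(ctx$hit$index) * hs) / (n * sum(hs))
    }
    p_ls <- min(mean(priors[ctx$label_set]), 1 - 1e-12)
    for (Cname in names(ctx$miss)) {
      mdf <- ctx$miss[[Cname]]
      if (nrow(mdf) == 0) next
      C <- as.integer(Cname)
      ratio <- priors[C] / (1 - p_ls)
      ms <- mdf$sim
      W <- W + ratio * colSums(d_to(mdf$index) * ms) / (n * sum(ms))
    }
  }
  names(W) <- fs$feature_names
  feature_weights(W)
}

#' Construct a feature-weight object
#'
#' @param W named numeric weight vector.
#' @return a `feature_weights` with the descending-weight ordering (`order`),
#'   ties broken toward the lower feature index.
#' @export
feature_weights <- function(W) {
  ord <- order(-W, seq_along(W))
  structure(list(W = W, order = ord), class = "feature_weights")
}

#' @export
print.feature_weights <- function(x, n = 10, ...) {
  cat("<feature_weights> ", length(x$W), " features; top ", n, ":\n", sep = "")
  top <- x$order[seq_len(min(n, length(x$W)))]
  print(round(x$W[top], 5))
  invisible(x)
}

#' Keep the top-weighted features
#'
#' @param fw a [feature_weights()] object.
#' @param n_select how many features to keep (1..f).
#' @return integer vector of feature indices in descending-weight order.
#' @export
select_features <- function(fw, n_select) {
  stopifnot(inherits(fw, "feature_weights"))
  f <- length(fw$W)
  if (!is.numeric(n_select) || n_select < 1 || n_select > f) {
    stop("n_select must be in 1..", f)
  }
  fw$order[seq_len(as.integer(n_select))]
}

#' Write the ranked feature-weight report
#'
#' TSV with rank, feature name and weight in descending order — the table
#' behind a "top features" importance figure.
#'
#' @param fw a [feature_weights()]; @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_weights <- function(fw, path) {
  ord <- fw$order
  df <- data.frame(rank = seq_along(ord),
                   feature = names(fw$W)[ord],
                   weight = unname(fw$W[ord]))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
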