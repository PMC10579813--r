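# Independent brute-force oracles. These are deliberately naive, loop-based
# transcriptions of the defining formulas, written before and apart from the
# package implementations they check.

options(syndforest.verbose = FALSE)

# ---- similarity / weight-update oracle --------------------------------------

oracle_pcc <- function(x, y) {
  n <- length(x)
  sx <- sum(x) / n
  sy <- sum(y) / n
  num <- 0
  dx2 <- 0
  dy2 <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - sx) * (y[i] - sy)
    dx2 <- dx2 + (x[i] - sx)^2
    dy2 <- dy2 + (y[i] - sy)^2
  }
  if (dx2 == 0 || dy2 == 0) return(NA_real_)
  num / sqrt(dx2 * dy2)
}

oracle_sim <- function(x, y, epsilon = 1e-6) {
  rho <- oracle_pcc(x, y)
  if (is.na(rho)) return(epsilon)
  if (rho > 1 - epsilon) rho <- 1 - epsilon
  1 / (1 - rho)
}

# term-by-term transcription of the similarity-weighted multi-label ReliefF
# weight update, with traversal probe selection
oracle_relieff <- function(X, Y, k, epsilon = 1e-6) {
  n <- nrow(X)
  f <- ncol(X)
  m <- ncol(Y)
  priors <- colMeans(Y)
  fmin <- apply(X, 2, min)
  fmax <- apply(X, 2, max)
  d <- function(p, i, j) {
    if (fmax[p] == fmin[p]) return(0)
    abs(X[i, p] - X[j, p]) / (fmax[p] - fmin[p])
  }
  S <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) if (i != j) S[i, j] <- oracle_sim(X[i, ],
                                                                  X[j, ],
                                                                  epsilon)
  W <- numeric(f)
  for (t in 1:n) {
    ls <- which(Y[t, ] == 1)
    others <- setdiff(1:n, t)
    # neighbor ranking contract: similarity quantized to 12 significant
    # digits, exact ties broken by ascending record index
    ord <- others[order(-signif(S[t, others], 12), others)]
    same <- ord[vapply(ord, function(j) identical(which(Y[j, ] == 1), ls),
                       logical(1))]
    hit <- same[seq_len(min(k, length(same)))]
    p_ls <- min(mean(priors[ls]), 1 - 1e-12)
    for (p in 1:f) {
      if (length(hit) > 0) {
        num <- 0
        den <- 0
        for (j in hit) {
          num <- num + S[t, j] * d(p, t, j)
          den <- den + S[t, j]
        }
        W[p] <- W[p] - num / (n * den)
      }
      for (C in setdiff(1:m, ls)) {
        cand <- ord[Y[ord, C] == 1]
        miss <- cand[seq_len(min(k, length(cand)))]
        if (length(miss) == 0) next
        num <- 0
        den <- 0
        for (j in miss) {
          num <- num + S[t, j] * d(p, t, j)
          den <- den + S[t, j]
        }
        W[p] <- W[p] + (priors[C] / (1 - p_ls)) * num / (n * den)
      }
    }
  }
  W
}

# ---- metric oracles ---------------------------------------------------------

# rank of each label: 1 = highest score, ties -> lower label index
oracle_ranks <- function(fr) {
  m <- length(fr)
  r <- integer(m)
  for (j in 1:m) {
    r[j] <- 1 + sum(fr > fr[j]) + sum(fr[seq_len(j - 1)] == fr[j])
  }
  r
}

oracle_hamming <- function(Y, H) {
  bad <- 0
  for (i in seq_len(nrow(Y))) for (j in seq_len(ncol(Y))) {
    if (H[i, j] != Y[i, j]) bad <- bad + 1
  }
  bad / (nrow(Y) * ncol(Y))
}

oracle_one_error <- function(Y, F) {
  bad <- 0
  for (i in seq_len(nrow(Y))) {
    top <- which(oracle_ranks(F[i, ]) == 1)
    if (Y[i, top] != 1) bad <- bad + 1
  }
  bad / nrow(Y)
}

oracle_coverage <- function(Y, F, conventional = FALSE) {
  tot <- 0
  for (i in seq_len(nrow(Y))) {
    r <- oracle_ranks(F[i, ])
    tot <- tot + max(r[Y[i, ] == 1]) - 1
  }
  tot / (nrow(Y) * if (conventional) 1 else ncol(Y))
}

oracle_ranking_loss <- function(Y, F) {
  terms <- numeric(0)
  for (i in seq_len(nrow(Y))) {
    pos <- which(Y[i, ] == 1)
    neg <- which(Y[i, ] == 0)
    if (length(neg) == 0) next
    bad <- 0
    for (u in pos) for (v in neg) if (F[i, u] <= F[i, v]) bad <- bad + 1
    terms <- c(terms, bad / (length(pos) * length(neg)))
  }
  mean(terms)
}

oracle_average_precision <- function(Y, F) {
  terms <- numeric(0)
  for (i in seq_len(nrow(Y))) {
    r <- oracle_ranks(F[i, ])
    pos <- which(Y[i, ] == 1)
    s <- 0
    for (j in pos) {
      s <- s + sum(r[pos] <= r[j]) / r[j]
    }
    terms <- c(terms, s / length(pos))
  }
  mean(terms)
}

oracle_macro_auc <- function(Y, F) {
  per <- numeric(0)
  for (j in seq_len(ncol(Y))) {
    pos <- which(Y[, j] == 1)
    neg <- which(Y[, j] == 0)
    if (length(pos) == 0 || length(neg) == 0) next
    good <- 0
    for (a in pos) for (b in neg) if (F[a, j] > F[b, j]) good <- good + 1
    per <- c(per, good / (length(pos) * length(neg)))
  }
  mean(per)
}

oracle_set_measures <- function(Y, H) {
  n <- nrow(Y)
  mlacc <- mlpre <- mlrec <- acc <- 0
  for (i in 1:n) {
    Yi <- which(Y[i, ] == 1)
    Hi <- which(H[i, ] == 1)
    inter <- length(intersect(Yi, Hi))
    mlacc <- mlacc + inter / length(union(Yi, Hi))
    mlpre <- mlpre + if (length(Hi) == 0) 0 else inter / length(Hi)
    mlrec <- mlrec + inter / length(Yi)
    acc <- acc + as.numeric(setequal(Yi, Hi) &&
                              length(Yi) == length(Hi))
  }
  mlacc <- mlacc / n
  mlpre <- mlpre / n
  mlrec <- mlrec / n
  acc <- acc / n
  mlf1 <- if (mlpre + mlrec == 0) 0 else 2 * mlpre * mlrec / (mlpre + mlrec)
  c(mlACC = mlacc, mlPRE = mlpre, mlREC = mlrec, mlF1 = mlf1, ACC = acc)
}

# ---- random-instance generators for property tests --------------------------

# random binary label matrix with every row and column populated
rand_Y <- function(n, m) {
  repeat {
    Y <- matrix(rbinom(n * m, 1, 0.45), n, m)
    if (all(rowSums(Y) >= 1) && all(colSums(Y) >= 1)) return(Y)
  }
}

rand_instance <- function(n_max = 8, f_max = 4, m_max = 3) {
  n <- sample(3:n_max, 1)
  f <- sample(2:f_max, 1)
  m <- sample(2:m_max, 1)
  # continuous features: distinct sample pairs are almost surely untied in
  # similarity, so neighbor sets are unambiguous (tie-breaking has its own
  # deterministic unit tests on exactly tied inputs)
  X <- matrix(runif(n * f), n, f)
  Y <- rand_Y(n, m)
  list(X = X, Y = Y, n = n, f = f, m = m)
}

# small labelled corpus as matrices + package containers
as_spaces <- function(X, Y) {
  colnames(X) <- sprintf("p%02d", seq_len(ncol(X)))
  colnames(Y) <- sprintf("L%02d", seq_len(ncol(Y)))
  keep <- colSums(X != 0) > 0
  list(fs = feature_space(X[, keep, drop = FALSE]),
       lm = label_matrix(Y),
       keep = which(keep))
}

# strip the confidence attribute measure_reuse attaches
unclass_mat2 <- function(G) {
  attr(G, "confidence") <- NULL
  G
}
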