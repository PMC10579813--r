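test_that("pcc matches its closed forms and rejects zero variance", {
  expect_equal(pcc(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pcc(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pcc(c(1, 2, 3), c(1, 2, 4)), 9 / sqrt(84))
  expect_error(pcc(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
  expect_error(pcc(1, 1), NULL)
})

test_that("sample_similarity follows 1/(1 - rho) with clamp and floor", {
  # rho = -1 -> 0.5; rho = 0 -> 1; rho = 1 clamped -> 1/epsilon
  expect_equal(sample_similarity(c(1, 2, 3), c(3, 2, 1)), 0.5)
  x <- c(1, 2, 1, 2)
  y <- c(1, 1, 2, 2) # orthogonal after centering -> rho = 0
  expect_equal(sample_similarity(x, y), 1)
  expect_equal(sample_similarity(c(1, 2, 3), c(2, 4, 6), epsilon = 1e-6),
               1e6)
  # zero-variance vector: floor, not an exception
  expect_equal(sample_similarity(c(1, 1, 1), c(1, 2, 3), epsilon = 1e-6),
               1e-6)
})

test_that("sample_similarity is symmetric and strictly positive", {
  set.seed(11)
  for (rep in 1:25) {
    x <- round(runif(5), 3)
    y <- round(runif(5), 3)
    for (mode in c("pearson", "cosine")) {
      s1 <- sample_similarity(x, y, mode)
      s2 <- sample_similarity(y, x, mode)
      expect_identical(s1, s2)
      expect_gt(s1, 0)
    }
  }
})

test_that("find_neighbors builds hit/miss lists per the label-set rules", {
  # 3 samples, labels {L1},{L1},{L2}: probe 0 forced
  X <- matrix(c(1, 2, 3,
                1, 2, 4,
                9, 1, 2), 3, 3, byrow = TRUE)
  colnames(X) <- c("a", "b", "c")
  Y <- matrix(c(1L, 1L, 0L, 0L, 0L, 1L), 3, 2)
  colnames(Y) <- c("L1", "L2")
  ctx <- find_neighbors(1, feature_space(X), label_matrix(Y), k = 1)
  expect_equal(ctx$hit$index, 2)
  expect_equal(ctx$miss$L2$index, 3)
  expect_false(1 %in% c(ctx$hit$index, ctx$miss$L2$index))

  # probe with a unique label set has an empty hit list
  Y2 <- matrix(c(1L, 0L, 0L, 0L, 1L, 1L), 3, 2)
  colnames(Y2) <- c("L1", "L2")
  ctx2 <- find_neighbors(1, feature_space(X), label_matrix(Y2), k = 2)
  expect_equal(nrow(ctx2$hit), 0)

  # 6-sample case with K = 2 matches an exhaustive similarity-sort oracle
  set.seed(7)
  X6 <- matrix(runif(24), 6, 4,
               dimnames = list(NULL, paste0("p", 1:4)))
  Y6 <- rand_Y(6, 3)
  colnames(Y6) <- paste0("L", 1:3)
  fs <- feature_space(X6)
  lm <- label_matrix(Y6)
  for (t in 1:6) {
    ctx <- find_neighbors(t, fs, lm, k = 2)
    sims <- vapply(1:6, function(j) if (j == t) -Inf else
      oracle_sim(X6[t, ], X6[j, ]), numeric(1))
    ord <- setdiff(order(-signif(sims, 12), 1:6), t)
    key <- apply(Y6, 1, paste, collapse = "")
    same <- ord[key[ord] == key[t]]
    expect_equal(ctx$hit$index, same[seq_len(min(2, length(same)))])
    for (C in setdiff(1:3, which(Y6[t, ] == 1))) {
      cand <- ord[Y6[ord, C] == 1]
      expect_equal(ctx$miss[[paste0("L", C)]]$index,
                   cand[seq_len(min(2, length(cand)))])
    }
  }
})

test_that("feature_diff is range-scaled with a zero-range guard", {
  X <- cbind(a = c(1, 1, 3, 0),       # identical values in rows 1, 2
             b = c(0.5, 1.5, 0, 2),   # range (0, 2)
             cst = c(7, 7, 7, 7))     # zero range
  fs <- feature_space(X)
  expect_equal(feature_diff(1, 1, 2, fs), 0)
  expect_equal(feature_diff(2, 1, 2, fs), 0.5)
  expect_equal(feature_diff(3, 1, 2, fs), 0)
})

test_that("ml_relieff matches the straight-line weight-update oracle", {
  # fixed 4-sample, 2-feature, 2-label toy set with K = 1
  X <- matrix(c(0.1, 0.9,
                0.2, 0.8,
                0.9, 0.1,
                0.8, 0.3), 4, 2, byrow = TRUE,
              dimnames = list(NULL, c("p1", "p2")))
  Y <- matrix(c(1L, 1L, 0L, 0L,
                0L, 0L, 1L, 1L), 4, 2,
              dimnames = list(NULL, c("L1", "L2")))
  fw <- ml_relieff(feature_space(X), label_matrix(Y), k = 1)
  expect_equal(unname(fw$W), oracle_relieff(X, Y, k = 1), tolerance = 1e-12)

  # a feature constant across samples keeps weight exactly 0
  X2 <- cbind(X, p3 = 0.4)
  fw2 <- ml_relieff(feature_space(X2), label_matrix(Y), k = 1)
  expect_identical(unname(fw2$W[3]), 0)
})

test_that("ml_relieff equals the oracle on random small instances", {
  set.seed(202)
  for (rep in 1:60) {
    inst <- rand_instance(n_max = 8, f_max = 4, m_max = 3)
    k <- sample(1:3, 1)
    fw <- ml_relieff(feature_space(inst$X, scheme = "binary")
                     , label_matrix(inst$Y), k = k)
    expect_equal(unname(fw$W), oracle_relieff(inst$X, inst$Y, k = k),
                 tolerance = 1e-10)
  }
})

test_that("ml_relieff is deterministic and feature-permutation covariant", {
  set.seed(5)
  X <- matrix(runif(30 * 6), 30, 6,
              dimnames = list(NULL, paste0("p", 1:6)))
  Y <- rand_Y(30, 3)
  colnames(Y) <- paste0("L", 1:3)
  fs <- feature_space(X)
  lm <- label_matrix(Y)
  w1 <- ml_relieff(fs, lm, k = 3)
  w2 <- ml_relieff(fs, lm, k = 3)
  expect_identical(w1$W, w2$W)

  perm <- c(4, 1, 6, 3, 2, 5)
  fsp <- feature_space(X[, perm])
  wp <- ml_relieff(fsp, lm, k = 3)
  expect_equal(unname(wp$W), unname(w1$W[perm]), tolerance = 1e-12)
})

test_that("select_features keeps the top weights with index tie-breaks", {
  fw <- feature_weights(c(a = 0.2, b = 0.9, c = 0.1))
  expect_equal(select_features(fw, 2), c(2, 1))
  expect_equal(sort(select_features(fw, 3)), 1:3)
  expect_equal(select_features(feature_weights(c(0.5, 0.5)), 1), 1)
  expect_error(select_features(fw, 0), "n_select")
  expect_error(select_features(fw, 4), "n_select")
})

test_that("the feature-weight report ranks descending", {
  fw <- feature_weights(c(a = 0.2, b = 0.9, c = 0.1))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_feature_weights(fw, f)
  rep <- read.delim(f)
  expect_equal(rep$feature, c("b", "a", "c"))
  expect_true(all(diff(rep$weight) <= 0))
})
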