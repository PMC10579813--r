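sep_data <- function(n_per = 10) {
  # separable: three presentations with disjoint feature support
  X <- rbind(matrix(rep(c(1, 1, 0, 0, 0, 0), n_per), ncol = 6, byrow = TRUE),
             matrix(rep(c(0, 0, 1, 1, 0, 0), n_per), ncol = 6, byrow = TRUE),
             matrix(rep(c(0, 0, 0, 0, 1, 1), n_per), ncol = 6, byrow = TRUE))
  Y <- rbind(matrix(rep(c(1L, 0L, 0L), n_per), ncol = 3, byrow = TRUE),
             matrix(rep(c(0L, 1L, 1L), n_per), ncol = 3, byrow = TRUE),
             matrix(rep(c(0L, 0L, 1L), n_per), ncol = 3, byrow = TRUE))
  colnames(X) <- paste0("p", 1:6)
  colnames(Y) <- paste0("L", 1:3)
  list(X = X, Y = Y)
}

small_cfg <- function(...) {
  args <- list(n_trees = 8, n_folds = 3, max_layers = 3, seed = 4)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(cascade_config, args)
}

test_that("layer_fit produces an out-of-fold n x 2m representation", {
  d <- sep_data(7)
  ly <- layer_fit(d$X, d$Y, small_cfg(), layer_seed = 2)
  expect_equal(dim(ly$H), c(nrow(d$X), 2 * ncol(d$Y)))
  expect_false(anyNA(ly$H))
  expect_true(all(ly$H >= 0 & ly$H <= 1))

  # fold-assignment audit: each row's H comes from forests fitted without it
  for (i in seq_len(nrow(d$X))) {
    fold <- ly$folds[i]
    for (gi in 1:2) {
      fm <- ly$groups[[gi]][[fold]]
      block <- (gi - 1) * ncol(d$Y) + seq_len(ncol(d$Y))
      expect_equal(unname(ly$H[i, block]),
                   unname(predict(fm, d$X[i, , drop = FALSE])[1, ]))
    }
  }
  # rebuilding the fold model from the complement reproduces it exactly,
  # proving the held-out row took no part in fitting
  fold1_rows <- ly$folds != 1
  refit <- ml_forest(d$X[fold1_rows, ], d$Y[fold1_rows, ], kind = "rfpct",
                     n_trees = 8, seed = 2 * 1000 + 1 * 100 + 1)
  expect_identical(predict(refit, d$X), predict(ly$groups$rfpct[[1]], d$X))
})

test_that("layer_fit reduces folds with a warning when n < k", {
  X <- matrix(runif(8), 4, 2)
  Y <- cbind(c(1L, 1L, 0L, 1L), c(0L, 1L, 1L, 0L))
  expect_warning(ly <- layer_fit(X, Y, small_cfg(n_folds = 5)), "folds")
  expect_equal(dim(ly$H), c(4, 4))
})

test_that("layer_fit is deterministic for a fixed seed", {
  d <- sep_data(5)
  l1 <- layer_fit(d$X, d$Y, small_cfg(), layer_seed = 9)
  l2 <- layer_fit(d$X, d$Y, small_cfg(), layer_seed = 9)
  expect_identical(l1$H, l2$H)
})

test_that("measure_reuse splices rows by confidence", {
  H <- rbind(c(0.9, 0.1, 0.95, 0.05), # confident row
             c(0.5, 0.5, 0.5, 0.5))   # maximally unsure row
  G_prev <- matrix(0.25, 2, 4)
  # first layer passes through
  expect_equal(unclass_mat2(measure_reuse(H)), H)
  # all confidences high -> take H; all low -> keep G_prev
  expect_equal(unclass_mat2(measure_reuse(H, G_prev, conf_threshold = 0)), H)
  expect_equal(unclass_mat2(measure_reuse(H, G_prev, conf_threshold = 1.1)),
               G_prev)
  # mixed: row 1 (confidence 0.925) kept, row 2 (0.5) reverts
  G <- measure_reuse(H, G_prev, conf_threshold = 0.6)
  expect_equal(unname(attr(G, "confidence")), c(0.925, 0.5))
  expect_equal(unclass_mat2(G), rbind(H[1, ], G_prev[2, ]))
})

test_that("growth stopping and depth selection follow the patience rule", {
  # traced history: improvement at layer 2, then three flat layers
  h <- c(0.40, 0.45, 0.45, 0.45, 0.45)
  expect_false(growth_stopped(h[1:2], "higher"))
  expect_false(growth_stopped(h[1:4], "higher"))
  expect_true(growth_stopped(h, "higher"))
  expect_equal(best_depth(h, "higher"), 2)
  # direction matters: same numbers as a loss keep improving... downward
  expect_false(growth_stopped(c(0.5, 0.4, 0.3, 0.2, 0.1), "lower"))
  expect_true(growth_stopped(c(0.1, 0.1, 0.1, 0.1), "lower"))
  expect_equal(best_depth(c(0.3, 0.1, 0.1), "lower"), 2)
  # sub-tolerance wiggles do not count as progress
  expect_true(growth_stopped(c(0.4, 0.4 + 1e-9, 0.4, 0.4), "higher"))
})

test_that("cascade_fit terminates, caps layers, and tracks its measure", {
  d <- sep_data(6)
  m1 <- cascade_fit(d$X, d$Y, small_cfg(max_layers = 1))
  expect_length(m1$layers, 1)
  expect_equal(m1$best_depth, 1)

  m <- cascade_fit(d$X, d$Y, small_cfg(max_layers = 6))
  expect_lte(length(m$layers), 6)
  expect_equal(length(m$history), length(m$layers))
  # the selected depth is the best in history
  expect_equal(m$history[m$best_depth], max(m$history))
})

test_that("cascade interpolates a separable toy set at training time", {
  d <- sep_data(10)
  m <- cascade_fit(d$X, d$Y, small_cfg())
  p <- predict(m, d$X)
  expect_true(all(p$scores >= 0 & p$scores <= 1))
  expect_equal(hamming_loss(d$Y, p$labels), 0)
})

test_that("cascade predictions are bitwise reproducible and serializable", {
  d <- sep_data(5)
  m1 <- cascade_fit(d$X, d$Y, small_cfg())
  m2 <- cascade_fit(d$X, d$Y, small_cfg())
  expect_identical(predict(m1, d$X)$scores, predict(m2, d$X)$scores)

  dir <- withr::local_tempdir()
  save_cascade(m1, dir)
  m3 <- load_cascade(dir)
  expect_identical(predict(m1, d$X)$scores, predict(m3, d$X)$scores)
  expect_equal(m3$history, m1$history)
  expect_equal(m3$best_depth, m1$best_depth)
})

test_that("thresholding and top-label promotion shape the decisions", {
  d <- sep_data(5)
  m <- cascade_fit(d$X, d$Y, small_cfg())
  # fabricate score rows through the exported decision logic by predicting
  # then checking the rule directly on the returned scores
  p <- predict(m, d$X)
  expect_true(all(rowSums(p$labels) >= 1))
  expect_true(all(p$labels[p$scores > m$threshold] == 1))
  expect_error(predict(m, d$X[, 1:3]), "mismatch")
})
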