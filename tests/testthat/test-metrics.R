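test_that("each measure matches its defining example", {
  Y <- rbind(c(1, 0, 1), c(0, 1, 0))
  H <- rbind(c(1, 1, 1), c(0, 1, 0))
  expect_equal(hamming_loss(Y, Y), 0)
  expect_equal(hamming_loss(Y, H), 1 / 6)
  expect_equal(hamming_loss(Y, 1 - Y), 1)

  F1 <- rbind(c(0.9, 0.1), c(0.1, 0.9), c(0.6, 0.4))
  Yo <- rbind(c(1, 0), c(1, 0), c(0, 1))
  expect_equal(one_error(Yo, F1), 3 / 3 - 1 / 3) # rows 2 and 3 err
  expect_equal(one_error(rbind(c(1, 0)), rbind(c(0.9, 0.1))), 0)
  expect_equal(one_error(rbind(c(1, 0)), rbind(c(0.1, 0.9))), 1)

  # coverage, printed 1/(nm) normalization: worst true rank 3 -> (3-1)/3
  Yc <- rbind(c(1, 0, 1))
  Fc <- rbind(c(0.9, 0.8, 0.1))
  expect_equal(coverage(Yc, Fc), 2 / 3)
  expect_equal(coverage(Yc, Fc, conventional = TRUE), 2)
  # tight packing: true labels hold the top ranks
  expect_equal(coverage(rbind(c(1, 1, 0)), rbind(c(0.9, 0.8, 0.1))), 1 / 3)
  # all labels true -> m - 1, normalized
  expect_equal(coverage(rbind(c(1, 1, 1)), rbind(c(0.5, 0.1, 0.9))), 2 / 3)

  # perfectly separated scores -> 0; fully reversed -> 1
  expect_equal(ranking_loss(Yc, rbind(c(0.9, 0.1, 0.8))), 0)
  expect_equal(ranking_loss(rbind(c(0, 1, 0)), rbind(c(0.9, 0.1, 0.5))), 1)
  # ties count fully against the model under the printed convention
  expect_equal(ranking_loss(rbind(c(1, 0)), rbind(c(0.5, 0.5))), 1)
  expect_equal(ranking_loss(rbind(c(1, 0)), rbind(c(0.5, 0.5)),
                            ties = "half"), 0.5)

  # all true labels outrank all false labels -> 1
  expect_equal(average_precision(Yc, rbind(c(0.9, 0.1, 0.8))), 1)
  expect_equal(average_precision(rbind(c(1, 0)), rbind(c(0.1, 0.9))), 0.5)

  auc <- macro_auc(rbind(c(1, 0), c(0, 1)),
                   rbind(c(0.9, 0.2), c(0.3, 0.7)))
  expect_equal(as.numeric(auc), 1)
  # identical scores for one label: 0 under the printed rule, 0.5 half-credit
  Ft <- rbind(c(0.5), c(0.5))
  Yt <- rbind(1, 0)
  expect_equal(as.numeric(macro_auc(Yt, Ft)), 0)
  expect_equal(as.numeric(macro_auc(Yt, Ft, ties = "half")), 0.5)

  sm <- set_measures(rbind(c(1, 0, 1)), rbind(c(1, 1, 1)))
  expect_equal(unname(sm["mlACC"]), 2 / 3)
  expect_equal(unname(sm["mlPRE"]), 2 / 3)
  expect_equal(unname(sm["mlREC"]), 1)
  expect_equal(unname(sm["ACC"]), 0)
  expect_equal(unname(set_measures(Y, Y)), rep(1, 5))
  expect_equal(unname(set_measures(rbind(c(1, 0)), rbind(c(0, 1)))),
               rep(0, 5))
})

test_that("all eleven measures match brute-force oracles on random inputs", {
  set.seed(404)
  for (rep in 1:200) {
    n <- sample(2:6, 1)
    m <- sample(2:5, 1)
    Y <- rand_Y(n, m)
    F <- matrix(sample(seq(0, 1, 0.25), n * m, replace = TRUE), n, m)
    H <- matrix(rbinom(n * m, 1, 0.5), n, m)
    expect_equal(hamming_loss(Y, H), oracle_hamming(Y, H),
                 tolerance = 1e-12)
    expect_equal(one_error(Y, F), oracle_one_error(Y, F), tolerance = 1e-12)
    expect_equal(coverage(Y, F), oracle_coverage(Y, F), tolerance = 1e-12)
    expect_equal(suppressWarnings(ranking_loss(Y, F)),
                 oracle_ranking_loss(Y, F), tolerance = 1e-12)
    expect_equal(average_precision(Y, F), oracle_average_precision(Y, F),
                 tolerance = 1e-12)
    expect_equal(as.numeric(suppressWarnings(macro_auc(Y, F))),
                 oracle_macro_auc(Y, F), tolerance = 1e-12)
    expect_equal(set_measures(Y, H), oracle_set_measures(Y, H),
                 tolerance = 1e-12)
  }
})

test_that("every measure is invariant under label permutation", {
  set.seed(77)
  for (rep in 1:20) {
    n <- 5
    m <- 4
    Y <- rand_Y(n, m)
    F <- matrix(runif(n * m), n, m) # continuous scores: no rank ties moved
    H <- matrix(rbinom(n * m, 1, 0.5), n, m)
    perm <- sample(m)
    expect_equal(hamming_loss(Y, H), hamming_loss(Y[, perm], H[, perm]))
    expect_equal(one_error(Y, F), one_error(Y[, perm], F[, perm]))
    expect_equal(coverage(Y, F), coverage(Y[, perm], F[, perm]))
    expect_equal(suppressWarnings(ranking_loss(Y, F)),
                 suppressWarnings(ranking_loss(Y[, perm], F[, perm])))
    expect_equal(average_precision(Y, F),
                 average_precision(Y[, perm], F[, perm]))
    expect_equal(as.numeric(suppressWarnings(macro_auc(Y, F))),
                 as.numeric(suppressWarnings(macro_auc(Y[, perm],
                                                       F[, perm]))))
    expect_equal(unname(set_measures(Y, H)),
                 unname(set_measures(Y[, perm], H[, perm])))
  }
})

test_that("subset relations and the AP/RL equivalence hold", {
  set.seed(88)
  for (rep in 1:30) {
    Y <- rand_Y(5, 4)
    H <- matrix(rbinom(20, 1, 0.5), 5, 4)
    sm <- set_measures(Y, H)
    expect_gte(sm["mlREC"], sm["ACC"])
    expect_gte(sm["mlACC"], sm["ACC"])

    F <- matrix(runif(20), 5, 4)
    both <- rowSums(Y) > 0 & rowSums(Y) < 4
    if (any(both)) {
      Yb <- Y[both, , drop = FALSE]
      Fb <- F[both, , drop = FALSE]
      ap1 <- isTRUE(all.equal(average_precision(Yb, Fb), 1))
      rl0 <- isTRUE(all.equal(ranking_loss(Yb, Fb), 0))
      expect_equal(ap1, rl0)
    }
  }
})

test_that("error and warning contracts hold", {
  expect_error(hamming_loss(matrix(0, 0, 0), matrix(0, 0, 0)), "empty")
  expect_error(one_error(rbind(c(0, 0)), rbind(c(0.1, 0.2))), "true label")
  expect_error(hamming_loss(rbind(c(1, 0)), rbind(c(1, 0, 1))), "shape")
  # rows without negatives are skipped with a warning
  expect_warning(rl <- ranking_loss(rbind(c(1, 1), c(1, 0)),
                                    rbind(c(0.5, 0.5), c(0.9, 0.1))),
                 "skipped")
  expect_equal(rl, 0)
  # single-class labels are excluded from macro-AUC with a warning
  expect_warning(a <- macro_auc(rbind(c(1, 1), c(0, 1)),
                                rbind(c(0.8, 0.5), c(0.2, 0.6))),
                 "excluded")
  expect_equal(as.numeric(a), 1)
})

test_that("evaluate_all assembles the full report with directions", {
  Y <- rand_Y(6, 3)
  F <- matrix(runif(18), 6, 3)
  H <- (F > 0.5) * 1
  H[rowSums(H) == 0, 1] <- 1
  ev <- suppressWarnings(evaluate_all(Y, H, F))
  expect_equal(nrow(ev), 11)
  expect_setequal(ev$measure[ev$direction == "lower"],
                  c("hamming_loss", "one_error", "coverage", "ranking_loss"))
  expect_true(all(ev$value >= 0 & ev$value <= 1))
})
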