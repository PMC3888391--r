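test_that("perplexity profile reproduces the archetype classifiers", {
  p <- perplexity_profile(diag(2) * 10)
  expect_equal(p$k_X, 2)
  expect_equal(p$k_Y, 2)
  expect_equal(p$mu, 2)
  expect_equal(p$k_XgY, 1)
  expect_equal(p$ema, 1)
  expect_equal(p$nit, 1)
  expect_equal(p$acc, 1)

  # fully skewed task: perfect accuracy, floor NIT
  ps <- perplexity_profile(matrix(c(20, 0, 0, 0), 2))
  expect_equal(ps$k_X, 1)
  expect_equal(ps$mu, 1)
  expect_equal(ps$k_XgY, 1)
  expect_equal(ps$ema, 1)
  expect_equal(ps$acc, 1)
  expect_equal(ps$nit, 0.5)

  expect_error(perplexity_profile(matrix(0, 2, 2)), "empty")
})

test_that("perplexity decomposition identities hold on random tables", {
  set.seed(11)
  for (rep in 1:100) {
    n <- sample(2:6, 1)
    m <- sample(2:6, 1)
    p <- perplexity_profile(rand_table(n, m))
    expect_equal(p$k_X, p$mu * p$k_XgY, tolerance = 1e-9)
    expect_equal(p$k_Y, p$mu * p$k_YgX, tolerance = 1e-9)
    # inequality chains
    expect_true(1 - 1e-9 <= p$k_XgY && p$k_XgY <= p$k_X + 1e-9)
    expect_lte(p$k_X, n + 1e-9)
    expect_true(1 - 1e-9 <= p$mu && p$mu <= min(p$k_X, p$k_Y) + 1e-9)
    # NIT floor/ceiling and its relation to EMA
    expect_true(1 / n - 1e-12 <= p$nit && p$nit <= 1 + 1e-12)
    expect_lte(p$nit, p$ema + 1e-12)
    expect_equal(p$nit, p$ema * p$k_X / n, tolerance = 1e-9)
  }
})

test_that("accuracy is the trace fraction and needs matching labels", {
  expect_equal(accuracy(diag(2) * 10), 1)
  expect_equal(accuracy(matrix(5, 2, 2)), 0.5)
  expect_equal(accuracy(matrix(c(4, 2, 1, 3), 2)), 0.7)
  # alignment by label, not position
  ct <- confusion_table(matrix(c(0, 10, 10, 0), 2),
                        row_labels = c("a", "b"), col_labels = c("b", "a"))
  expect_equal(accuracy(ct), 1)
  bad <- confusion_table(matrix(1:4, 2), row_labels = c("a", "b"),
                         col_labels = c("c", "d"))
  expect_error(accuracy(bad), "labels differ")
  expect_silent(ema(bad))
  expect_silent(nit(bad))
})

test_that("EMA and NIT reproduce the published MEG algebra", {
  meg <- meg_fixture()
  # ema = 1/k_X|Y and nit = mu/n reproduce every published row to 3 decimals
  expect_equal(round(1 / meg$k_XgY, 3), meg$ema_published)
  expect_equal(round(meg$mu / 5, 3), meg$nit_published)
  # spot values: best-accuracy entrant and the weakest one
  expect_equal(round(1 / 2.562, 3), 0.390)
  expect_equal(round(1 / 4.801, 3), 0.208)
  expect_equal(round(1.932 / 5, 3), 0.386)
  expect_equal(round(1.031 / 5, 3), 0.206)
  # reconstructed task perplexity k_X = mu * k_X|Y is constant across rows
  k_X <- meg$mu * meg$k_XgY
  expect_lt(max(k_X) - min(k_X), 0.01)
})

test_that("EMA rewards the cross-labeled perfect classifier, accuracy does not", {
  anti <- matrix(c(0, 10, 10, 0), 2)
  expect_equal(ema(anti), 1)
  expect_equal(accuracy(anti), 0)
  expect_equal(nit(matrix(5, 2, 2)), 0.5)
  expect_equal(ema(matrix(5, 2, 2)), 0.5)
})

test_that("clueless bound flags label-permutation pathologies", {
  expect_equal(clueless_bound(5, 5), 0.2)
  expect_equal(clueless_bound(2, 2), 0.5)
  expect_equal(clueless_bound(3, 6), 1 / 6)
  expect_true(flag_permutation(matrix(c(0, 10, 10, 0), 2)))
  expect_false(flag_permutation(diag(2) * 10))
})

test_that("best label permutation maximizes the trace exactly", {
  swap <- best_label_permutation(matrix(c(0, 10, 10, 0), 2))
  expect_equal(swap$permutation, c(2L, 1L))
  expect_equal(swap$accuracy, 1)

  ident <- best_label_permutation(diag(2) * 10)
  expect_equal(ident$permutation, c(1L, 2L))
  expect_equal(ident$accuracy, 1)

  keep <- best_label_permutation(matrix(c(4, 2, 1, 3), 2))
  expect_equal(keep$permutation, c(1L, 2L))
  expect_equal(keep$accuracy, 0.7)

  expect_error(best_label_permutation(matrix(1, 2, 3)), "square")
})

test_that("assignment route agrees with exhaustive search and never hurts", {
  set.seed(33)
  for (rep in 1:20) {
    counts <- rand_table(5, 5)
    bp <- best_label_permutation(counts)        # exhaustive (5 <= 8)
    alt <- entropytriangle:::assignment_permutation(counts)
    expect_equal(sum(counts[cbind(1:5, alt)]),
                 sum(counts[cbind(1:5, bp$permutation)]))
    expect_gte(bp$accuracy, sum(diag(counts)) / sum(counts))
    # EMA and NIT are invariant under the returned remapping
    expect_equal(ema(bp$table), ema(counts), tolerance = 1e-12)
    expect_equal(nit(bp$table), nit(counts), tolerance = 1e-12)
  }
  # large-table route recovers a planted optimal permutation
  set.seed(34)
  k <- 10
  planted <- sample.int(k)
  big <- matrix(stats::rpois(k * k, 2), k, k)
  for (i in 1:k) big[i, planted[i]] <- big[i, planted[i]] + 50L
  bp <- best_label_permutation(big)
  expect_equal(bp$permutation, planted)
})
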