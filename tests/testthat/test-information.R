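test_that("joint distribution is the normalized count table", {
  J <- joint_distribution(matrix(c(10, 0, 0, 10), 2))
  expect_equal(J$p, matrix(c(0.5, 0, 0, 0.5), 2), ignore_attr = TRUE)
  expect_equal(unname(J$p_X), c(0.5, 0.5))

  # delta distribution from a fully skewed table
  Jd <- joint_distribution(matrix(c(20, 0, 0, 0), 2))
  expect_equal(Jd$p, matrix(c(1, 0, 0, 0), 2), ignore_attr = TRUE)
  expect_equal(unname(Jd$p_X), c(1, 0))
  expect_equal(unname(Jd$p_Y), c(1, 0))

  # hand normalization by N = 10
  Jh <- joint_distribution(matrix(c(4, 2, 1, 3), 2))
  expect_equal(Jh$p, matrix(c(0.4, 0.2, 0.1, 0.3), 2), ignore_attr = TRUE)
  expect_equal(unname(Jh$p_Y), c(0.6, 0.4))
  expect_equal(sum(Jh$p), 1)
})

test_that("additive smoothing perturbs cells before normalization", {
  J <- joint_distribution(matrix(c(1, 0, 0, 1), 2), smoothing = 0.5)
  expect_equal(sum(J$p), 1)
  expect_equal(J$p[1, 2], 0.5 / 4)
  expect_error(joint_distribution(matrix(0, 2, 2)), "empty confusion table")
  expect_error(joint_distribution(matrix(1, 2, 2), smoothing = -1),
               "non-negative")
})

test_that("entropy balance matches closed-form corner cases", {
  B <- entropy_balance(matrix(c(0.5, 0, 0, 0.5), 2))
  expect_equal(B$H_PX, 1)
  expect_equal(B$H_PY, 1)
  expect_equal(B$H_XY, 1)
  expect_equal(B$MI, 1)
  expect_equal(B$VI, 0)
  expect_equal(B$dH, 0)
  expect_equal(B$H_UX, 1)
  expect_equal(B$H_UY, 1)

  Bi <- entropy_balance(matrix(0.25, 2, 2))
  expect_equal(Bi$MI, 0)
  expect_equal(Bi$VI, 2)
  expect_equal(Bi$dH, 0)
})

test_that("mutual information agrees with the direct-summation oracle", {
  counts <- matrix(c(4, 2, 1, 3), 2)
  expect_equal(entropy_balance(counts)$MI, mi_direct(counts),
               tolerance = 1e-12)
  # frozen from the oracle on p = [[.4,.1],[.2,.3]]
  expect_equal(entropy_balance(counts)$MI, 0.1245112498, tolerance = 1e-9)
})

test_that("triangle coordinates land on the canonical vertices", {
  expect_equal(unlist(triangle_coordinates(diag(2) * 10)[1:3]),
               c(dH_norm = 0, mi2_norm = 1, vi_norm = 0))
  expect_equal(unlist(triangle_coordinates(matrix(5, 2, 2))[1:3]),
               c(dH_norm = 0, mi2_norm = 0, vi_norm = 1))
  expect_equal(unlist(triangle_coordinates(matrix(c(1, 0, 0, 0), 2))[1:3]),
               c(dH_norm = 1, mi2_norm = 0, vi_norm = 0))
  expect_error(triangle_coordinates(matrix(5, 1, 1)),
               "degenerate single-class task")
})

test_that("split coordinates decompose per variable and recombine", {
  sp <- split_coordinates(diag(2) * 10)
  expect_equal(unlist(sp$X[1:3]), c(dH_norm = 0, mi2_norm = 1, vi_norm = 0))
  expect_equal(unlist(sp$Y[1:3]), c(dH_norm = 0, mi2_norm = 1, vi_norm = 0))

  # constant-output classifier: X side pure noise, Y side pure specialization
  spc <- split_coordinates(matrix(c(10, 10, 0, 0), 2))
  expect_equal(unlist(spc$X[1:3]), c(dH_norm = 0, mi2_norm = 0, vi_norm = 1))
  expect_equal(unlist(spc$Y[1:3]), c(dH_norm = 1, mi2_norm = 0, vi_norm = 0))

  counts <- matrix(c(4, 2, 1, 3), 2)
  B <- entropy_balance(counts)
  sph <- split_coordinates(B)
  for (side in sph) {
    expect_equal(side$dH_norm + side$mi2_norm + side$vi_norm, 1,
                 tolerance = 1e-12)
  }
  # H_U-weighted mean of split triples returns the joint point
  jt <- triangle_coordinates(B)
  w <- c(B$H_UX, B$H_UY) / (B$H_UX + B$H_UY)
  expect_equal(w[1] * sph$X$dH_norm + w[2] * sph$Y$dH_norm, jt$dH_norm,
               tolerance = 1e-12)
  expect_equal(w[1] * sph$X$mi2_norm + w[2] * sph$Y$mi2_norm,
               jt$mi2_norm, tolerance = 1e-12)
  expect_equal(w[1] * sph$X$vi_norm + w[2] * sph$Y$vi_norm, jt$vi_norm,
               tolerance = 1e-12)
})

test_that("balance equation and MI consistency hold on random tables", {
  set.seed(421)
  for (rep in 1:200) {
    n <- sample(2:6, 1)
    m <- sample(2:6, 1)
    counts <- rand_table(n, m)
    B <- entropy_balance(counts)
    expect_lt(abs(B$dH + 2 * B$MI + B$VI - (B$H_UX + B$H_UY)), 1e-9)
    expect_lt(abs(B$MI - (B$H_PX - B$H_XgY)), 1e-9)
    expect_lt(abs(B$MI - mi_direct(counts)), 1e-9)
    # non-negativity and MI bound
    for (f in c("H_PX", "H_PY", "H_XY", "H_XgY", "H_YgX", "MI", "VI", "dH")) {
      expect_gte(B[[f]], 0)
    }
    expect_lte(B$MI, min(B$H_PX, B$H_PY) + 1e-12)
    tc <- triangle_coordinates(B)
    expect_lt(abs(tc$dH_norm + tc$mi2_norm + tc$vi_norm - 1), 1e-9)
  }
})

test_that("transposition swaps the axes and preserves the joint summary", {
  set.seed(99)
  for (rep in 1:25) {
    counts <- rand_table(sample(2:5, 1), sample(2:5, 1))
    B <- entropy_balance(counts)
    Bt <- entropy_balance(t(counts))
    expect_equal(Bt$H_PX, B$H_PY, tolerance = 1e-12)
    expect_equal(Bt$H_PY, B$H_PX, tolerance = 1e-12)
    expect_equal(Bt$H_XgY, B$H_YgX, tolerance = 1e-12)
    expect_equal(Bt$MI, B$MI, tolerance = 1e-12)
    expect_equal(Bt$VI, B$VI, tolerance = 1e-12)
    expect_equal(Bt$dH, B$dH, tolerance = 1e-12)
    expect_equal(unlist(triangle_coordinates(Bt)[1:3]),
                 unlist(triangle_coordinates(B)[1:3]), tolerance = 1e-12)
  }
})

test_that("row and column permutations leave every balance field unchanged", {
  set.seed(7)
  fields <- c("H_PX", "H_PY", "H_XY", "H_XgY", "H_YgX", "MI", "VI", "dH")
  for (rep in 1:25) {
    n <- sample(3:5, 1)
    counts <- rand_table(n, n)
    B <- entropy_balance(counts)
    perm <- sample.int(n)
    Br <- entropy_balance(counts[perm, , drop = FALSE])
    Bc <- entropy_balance(counts[, perm, drop = FALSE])
    for (f in fields) {
      expect_equal(Br[[f]], B[[f]], tolerance = 1e-12)
      expect_equal(Bc[[f]], B[[f]], tolerance = 1e-12)
    }
  }
})
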