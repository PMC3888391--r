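# Shared fixtures and independent oracles for the test suite.

# random non-negative integer table; occasionally zeroes out a row or column
# to exercise the 0 log 0 convention
rand_table <- function(n, m, lambda = 3) {
  repeat {
    counts <- matrix(stats::rpois(n * m, lambda), n, m)
    if (stats::runif(1) < 0.15) counts[sample.int(n, 1L), ] <- 0L
    if (stats::runif(1) < 0.15) counts[, sample.int(m, 1L)] <- 0L
    if (sum(counts) > 0) return(counts)
  }
}

# direct-summation mutual information oracle (bits)
mi_direct <- function(counts) {
  p <- counts / sum(counts)
  px <- rowSums(p)
  py <- colSums(p)
  total <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0) {
        total <- total + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
      }
    }
  }
  total
}

# plain entropy oracle (bits)
h_direct <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# independent brute-force count of the canonical matrix space: enumerate all
# n x n matrices by picking each row from the weak compositions of every
# possible row total, keep total == N and non-increasing row sums
brute_count_space <- function(n, N) {
  row_opts <- do.call(rbind, lapply(0:N, function(t) compositions_oracle(t, n)))
  row_tot <- rowSums(row_opts)
  k <- nrow(row_opts)
  idx <- do.call(expand.grid, rep(list(seq_len(k)), n))
  tot <- Reduce(`+`, lapply(idx, function(col) row_tot[col]))
  ok <- tot == N
  if (n > 1L) {
    for (r in seq_len(n - 1L)) {
      ok <- ok & row_tot[idx[[r]]] >= row_tot[idx[[r + 1L]]]
    }
  }
  sum(ok)
}

# test-side weak compositions, written independently of the package's
compositions_oracle <- function(m, parts) {
  if (parts == 1L) return(matrix(m, 1L, 1L))
  grid <- do.call(expand.grid, rep(list(0:m), parts - 1L))
  rest <- m - rowSums(grid)
  keep <- rest >= 0
  as.matrix(cbind(grid[keep, , drop = FALSE], rest[keep]))
}

# the published MEG mind-reading perplexity table (accuracy order)
meg_fixture <- function() meg_mindreading()
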