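#' Generate a synthetic confusion table
#'
#' Builds confusion matrices with controllable structure for testing and
#' demonstration: class skew of the true-class marginal, fidelity (the
#' probability mass a row places on its own class), and an optional
#' majority-classifier mode that funnels every sample into one predicted
#' column. These emulate the archetypes of the entropy triangle — balanced
#' faithful classifiers (apex), noisy ones (variation-of-information
#' vertex), and specialized majority classifiers (divergence vertex).
#'
#' @param n,m numbers of true and predicted classes.
#' @param N total sample count.
#' @param skew concentration of the symmetric Dirichlet from which the
#'   true-class marginal is drawn; `Inf` (the default) gives an exactly
#'   uniform marginal via largest-remainder rounding. Small values (< 1)
#'   give strongly skewed class distributions.
#' @param fidelity probability mass each row places on its matching
#'   predicted class (rows beyond `m` have no match and spread uniformly);
#'   the rest is spread evenly over the other columns. `fidelity = 1` with
#'   a uniform marginal yields the balanced diagonal table.
#' @param specialize_to optional column index: every sample is predicted as
#'   that class, overriding `fidelity` (a majority classifier; its mutual
#'   information is 0 and its NIT factor is the floor 1/n).
#' @param seed integer seed; the same spec and seed give an identical table.
#' @return a [confusion_table()].
#' @examples
#' generate_fixture(2, 2, 20, fidelity = 1)      # [[10,0],[0,10]]
#' generate_fixture(2, 2, 20, specialize_to = 1) # all mass in column 1
#' @export
generate_fixture <- function(n, m = n, N, skew = Inf, fidelity = 1,
                             specialize_to = NULL, seed = 1L) {
  if (n < 1 || m < 1 || N < 1) stop("need n, m, N >= 1")
  if (fidelity < 0 || fidelity > 1) stop("fidelity must lie in [0, 1]")
  if (!is.infinite(skew) && skew <= 0) stop("skew must be positive (or Inf)")
  if (!is.null(specialize_to) &&
      (specialize_to < 1 || specialize_to > m)) {
    stop("specialize_to must index a predicted class in 1..", m)
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))

  # true-class marginal counts
  if (is.infinite(skew)) {
    if (fidelity == 1 && is.null(specialize_to) && N < n) {
      stop("infeasible: cannot place ", N,
           " samples faithfully over ", n, " classes")
    }
    row_counts <- largest_remainder(rep(1 / n, n), N)
  } else {
    w <- stats::rgamma(n, shape = skew)
    if (sum(w) == 0) w <- rep(1, n)
    row_counts <- largest_remainder(w / sum(w), N)
  }

  counts <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    if (row_counts[i] == 0L) next
    if (!is.null(specialize_to)) {
      counts[i, specialize_to] <- row_counts[i]
    } else {
      probs <- rep((1 - fidelity) / max(1L, m - 1L), m)
      if (i <= m) probs[i] <- fidelity else probs <- rep(1 / m, m)
      if (fidelity == 1 && i <= m) {
        counts[i, i] <- row_counts[i]
      } else {
        counts[i, ] <- stats::rmultinom(1L, row_counts[i], probs)[, 1L]
      }
    }
  }
  confusion_table(counts,
                  row_labels = paste0("c", seq_len(n)),
                  col_labels = paste0("c", seq_len(m)))
}

# deterministic apportionment of N among probabilities p
largest_remainder <- function(p, N) {
  raw <- p * N
  base <- floor(raw)
  left <- N - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}
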