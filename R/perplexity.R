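#' Perplexity profile of a classifier
#'
#' Perplexity, \eqn{k = 2^H}, is the effective number of equally likely
#' outcomes behind a distribution with entropy \eqn{H} bits. A classifier's
#' confusion table yields the marginal perplexities \eqn{k_X = 2^{H(P_X)}}
#' and \eqn{k_Y = 2^{H(P_Y)}}, the remaining perplexities
#' \eqn{k_{X|Y} = 2^{H(X|Y)}} and \eqn{k_{Y|X} = 2^{H(Y|X)}}, and the
#' information transfer factor \eqn{\mu = 2^{MI}}, linked by the
#' decomposition chains \eqn{k_X = \mu \, k_{X|Y}} and
#' \eqn{k_Y = \mu \, k_{Y|X}}.
#'
#' From these come the two performance measures:
#' \itemize{
#'   \item EMA, the entropy-modulated accuracy
#'     \eqn{a' = 2^{-H(X|Y)} = 1/k_{X|Y}}: the expected accuracy of an
#'     equivalent classifier facing \eqn{k_{X|Y}} equally likely classes.
#'   \item the NIT factor \eqn{q = \mu / n = 2^{MI - \log_2 n}}: EMA
#'     corrected for non-uniform input priors; the fraction of the maximal
#'     possible information transfer achieved, with floor \eqn{1/n}.
#' }
#'
#' @param table a [confusion_table()] or non-negative count matrix.
#' @param smoothing passed to [joint_distribution()].
#' @return An object of class `perplexity_profile`: named list with fields
#'   `k_X`, `k_Y`, `k_XgY`, `k_YgX`, `mu`, `acc` (accuracy, `NA` when the
#'   label sets differ), `ema`, `nit`, `n`, `m`, `N`.
#' @examples
#' perplexity_profile(diag(2) * 10)            # perfect balanced: ema = nit = 1
#' perplexity_profile(matrix(c(20, 0, 0, 0), 2))  # skewed: acc = 1, nit = 1/2
#' @export
perplexity_profile <- function(table, smoothing = 0) {
  table <- as_confusion_table(table)
  B <- entropy_balance(table, smoothing = smoothing)
  acc <- tryCatch(accuracy(table), error = function(e) NA_real_)
  structure(
    list(k_X = 2^B$H_PX, k_Y = 2^B$H_PY,
         k_XgY = 2^B$H_XgY, k_YgX = 2^B$H_YgX,
         mu = 2^B$MI, acc = acc,
         ema = 2^(-B$H_XgY), nit = 2^B$MI / B$n,
         n = B$n, m = B$m, N = attr(table, "N")),
    class = "perplexity_profile"
  )
}

#' @export
print.perplexity_profile <- function(x, digits = 3, ...) {
  cat(sprintf("Perplexity profile (n = %d true, m = %d predicted, N = %s)\n",
              x$n, x$m, format(x$N)))
  cat(sprintf("  k_X = %.*f  k_Y = %.*f  k_X|Y = %.*f  k_Y|X = %.*f  mu = %.*f\n",
              digits, x$k_X, digits, x$k_Y, digits, x$k_XgY,
              digits, x$k_YgX, digits, x$mu))
  cat(sprintf("  accuracy = %s  EMA = %.*f  NIT = %.*f\n",
              if (is.na(x$acc)) "NA (label sets differ)"
              else formatC(x$acc, digits = digits, format = "f"),
              digits, x$ema, digits, x$nit))
  invisible(x)
}

#' @export
as.data.frame.perplexity_profile <- function(x, ...) {
  data.frame(k_X = x$k_X, k_Y = x$k_Y, k_XgY = x$k_XgY, k_YgX = x$k_YgX,
             mu = x$mu, acc = x$acc, ema = x$ema, nit = x$nit,
             n = x$n, m = x$m, N = x$N)
}

#' Classification accuracy
#'
#' Fraction of correctly classified instances: the trace of the confusion
#' table (after aligning predicted-class columns with true-class rows by
#' label) divided by the total count.
#'
#' @param table a [confusion_table()] or square count matrix.
#' @return accuracy in \[0, 1\].
#' @seealso [ema()], [nit()] which remain defined when label sets differ.
#' @export
accuracy <- function(table) {
  table <- as_confusion_table(table)
  m <- ct_counts(table)
  rl <- rownames(m)
  cl <- colnames(m)
  if (!setequal(rl, cl)) {
    stop("accuracy undefined; labels differ between rows and columns")
  }
  m <- m[, match(rl, cl), drop = FALSE]
  total <- sum(m)
  if (total <= 0) stop("empty confusion table")
  sum(diag(m)) / total
}

#' Entropy-modulated accuracy (EMA)
#'
#' \eqn{a' = 2^{-H(X|Y)} = 1/k_{X|Y}}: a pessimistic accuracy estimate for a
#' classifier that still has to distinguish \eqn{k_{X|Y}} equally likely
#' input classes after seeing its own prediction. Invariant under any
#' permutation of the output labels, unlike accuracy.
#'
#' @inheritParams perplexity_profile
#' @return EMA in (0, 1\].
#' @export
ema <- function(table, smoothing = 0) {
  perplexity_profile(table, smoothing = smoothing)$ema
}

#' Normalized information transfer (NIT) factor
#'
#' \eqn{q = \mu/n = 2^{MI - \log_2 n}}, the EMA corrected for deviation from
#' uniformity of the input prior. Equals EMA exactly when the input marginal
#' is uniform; always satisfies \eqn{1/n \le q \le 1}, with the floor
#' \eqn{1/n} attained by any classifier transferring no information — even
#' one with accuracy 1 on fully skewed data.
#'
#' @inheritParams perplexity_profile
#' @return NIT factor in \[1/n, 1\].
#' @export
nit <- function(table, smoothing = 0) {
  perplexity_profile(table, smoothing = smoothing)$nit
}

#' Accuracy floor of a clueless classifier
#'
#' The expected accuracy of the uniform count matrix: a balanced test set
#' spread uniformly over all output classes. Any observed accuracy below
#' this bound indicates that a permutation of the output labels would score
#' higher — the class names, not the classes, are mismatched.
#'
#' @param n,m true/predicted class counts.
#' @param N sample count (the bound does not depend on it; accepted for
#'   interface symmetry).
#' @return `1 / max(n, m)`.
#' @seealso [flag_permutation()], [best_label_permutation()]
#' @export
clueless_bound <- function(n, m = n, N = NULL) {
  if (n < 1 || m < 1) stop("class counts must be at least 1")
  1 / max(n, m)
}

#' Flag a label-permutation pathology
#'
#' `TRUE` when the observed accuracy falls below the clueless-classifier
#' bound [clueless_bound()], so that remapping output labels is guaranteed
#' to improve accuracy.
#'
#' @inheritParams accuracy
#' @export
flag_permutation <- function(table) {
  table <- as_confusion_table(table)
  accuracy(table) < clueless_bound(nrow(table), ncol(table))
}

#' Best output-label permutation
#'
#' Finds the column permutation of a square confusion table that maximizes
#' the trace, i.e. the relabelling of the classifier's outputs with the
#' highest achievable accuracy. EMA, NIT and all entropy terms are invariant
#' under this remapping. Exhaustive search is used for up to 8 classes;
#' larger tables are solved exactly as a maximum-weight bipartite assignment.
#'
#' @inheritParams accuracy
#' @return list with `permutation` (integer vector: new column order, so
#'   column `permutation[j]` moves to position `j`), `accuracy` (the
#'   remapped accuracy), and `table` (the permuted confusion table).
#' @examples
#' best_label_permutation(matrix(c(0, 10, 10, 0), 2))  # swap, accuracy 1
#' @export
best_label_permutation <- function(table) {
  table <- as_confusion_table(table)
  m <- ct_counts(table)
  k <- nrow(m)
  if (k != ncol(m)) stop("label permutation requires a square table")
  if (k <= 8L) {
    perms <- permutations_of(k)
    traces <- vapply(perms,
                     function(p) sum(m[cbind(seq_len(k), p)]), numeric(1))
    best <- perms[[which.max(traces)]]
  } else {
    best <- assignment_permutation(m)
  }
  total <- sum(m)
  if (total <= 0) stop("empty confusion table")
  permuted <- confusion_table(m[, best, drop = FALSE],
                              row_labels = rownames(m),
                              col_labels = colnames(m))
  list(permutation = best,
       accuracy = sum(m[cbind(seq_len(k), best)]) / total,
       table = permuted)
}

# all permutations of 1..k (k small)
permutations_of <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- permutations_of(k - 1L)
  out <- vector("list", k * length(sub))
  idx <- 1L
  for (p in sub) {
    for (pos in seq_len(k)) {
      out[[idx]] <- append(p, k, after = pos - 1L)
      idx <- idx + 1L
    }
  }
  out
}

# exact maximum-weight assignment via weighted bipartite matching
assignment_permutation <- function(m) {
  k <- nrow(m)
  g <- igraph::make_empty_graph(n = 2L * k, directed = FALSE)
  edges <- as.vector(t(cbind(rep(seq_len(k), each = k),
                             k + rep(seq_len(k), times = k))))
  # strictly positive weights so the matching is perfect
  w <- as.vector(t(m)) + 1
  g <- igraph::add_edges(g, edges, weight = w)
  igraph::V(g)$type <- rep(c(FALSE, TRUE), each = k)
  match <- igraph::max_bipartite_match(g, weights = igraph::E(g)$weight)
  as.integer(match$matching[seq_len(k)]) - k
}
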