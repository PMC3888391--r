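#' @keywords internal
"_PACKAGE"

# Shannon entropy in bits with the 0 log 0 := 0 convention.
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Joint distribution of true and predicted classes
#'
#' Maximum-likelihood estimate of the joint probability table from a
#' confusion table: `p = counts / N`, with optional additive smoothing
#' applied to every cell before normalization.
#'
#' @param table a [confusion_table()] or non-negative matrix, or an already
#'   normalized probability matrix (then `N` is its total, 1).
#' @param smoothing non-negative constant added to every cell before
#'   normalizing (0, the default, gives the pure maximum-likelihood
#'   estimate).
#' @return An object of class `joint_distribution` with elements `p` (the
#'   joint probability matrix), `p_X` (row marginal over true classes),
#'   `p_Y` (column marginal over predictions), and cardinalities `n`, `m`.
#' @examples
#' joint_distribution(matrix(c(4, 2, 1, 3), 2))
#' @export
joint_distribution <- function(table, smoothing = 0) {
  if (inherits(table, "joint_distribution")) return(table)
  m <- ct_counts(table)
  if (length(smoothing) != 1L || is.na(smoothing) || smoothing < 0) {
    stop("smoothing must be a single non-negative number")
  }
  m <- m + smoothing
  total <- sum(m)
  if (total <= 0) stop("empty confusion table")
  p <- m / total
  structure(
    list(p = p, p_X = rowSums(p), p_Y = colSums(p),
         n = nrow(p), m = ncol(p)),
    class = "joint_distribution"
  )
}

#' @export
print.joint_distribution <- function(x, digits = 4, ...) {
  cat(sprintf("Joint distribution over %d true x %d predicted classes\n",
              x$n, x$m))
  print(round(x$p, digits), ...)
  invisible(x)
}

#' Entropy balance of a joint distribution
#'
#' Computes every term of the entropy balance of a joint distribution
#' \eqn{P_{XY}} of true classes \eqn{X} and predictions \eqn{Y}, in bits:
#' the uniform reference entropies \eqn{H(U_X) = \log_2 n},
#' \eqn{H(U_Y) = \log_2 m}; the marginal entropies \eqn{H(P_X)},
#' \eqn{H(P_Y)}; the joint entropy \eqn{H(P_{XY})}; the conditional
#' entropies \eqn{H(X|Y)}, \eqn{H(Y|X)}; the mutual information
#' \eqn{MI = H(P_X) + H(P_Y) - H(P_{XY})}; the variation of information
#' \eqn{VI = H(X|Y) + H(Y|X)}; and the divergence from uniformity
#' \eqn{\Delta H = (H(U_X) - H(P_X)) + (H(U_Y) - H(P_Y))}.
#'
#' These satisfy the balance equation
#' \deqn{\Delta H + 2\,MI + VI = H(U_X) + H(U_Y),}
#' the identity behind the entropy triangle.
#'
#' @param x a [confusion_table()], count matrix, or [joint_distribution()].
#' @param smoothing passed to [joint_distribution()] when `x` is a table.
#' @return An object of class `entropy_balance`: a named list with fields
#'   `H_UX`, `H_UY`, `H_PX`, `H_PY`, `H_XY`, `H_XgY`, `H_YgX`, `MI`, `VI`,
#'   `dH`, and cardinalities `n`, `m`. All values in bits.
#' @examples
#' entropy_balance(diag(2) * 10)           # perfect 2-class classifier
#' entropy_balance(matrix(0.25, 2, 2))     # independent uniform
#' @export
entropy_balance <- function(x, smoothing = 0) {
  J <- joint_distribution(x, smoothing = smoothing)
  H_PX <- entropy_bits(J$p_X)
  H_PY <- entropy_bits(J$p_Y)
  H_XY <- entropy_bits(J$p)
  MI <- H_PX + H_PY - H_XY
  # clamp tiny negative round-off; true MI is non-negative
  if (MI < 0 && MI > -1e-12) MI <- 0
  H_XgY <- H_XY - H_PY
  H_YgX <- H_XY - H_PX
  if (H_XgY < 0 && H_XgY > -1e-12) H_XgY <- 0
  if (H_YgX < 0 && H_YgX > -1e-12) H_YgX <- 0
  H_UX <- log2(J$n)
  H_UY <- log2(J$m)
  structure(
    list(H_UX = H_UX, H_UY = H_UY, H_PX = H_PX, H_PY = H_PY,
         H_XY = H_XY, H_XgY = H_XgY, H_YgX = H_YgX,
         MI = MI, VI = H_XgY + H_YgX,
         dH = (H_UX - H_PX) + (H_UY - H_PY),
         n = J$n, m = J$m),
    class = "entropy_balance"
  )
}

#' @export
print.entropy_balance <- function(x, digits = 4, ...) {
  cat("Entropy balance (bits)\n")
  cat(sprintf("  H(U_X) = %.*f   H(U_Y) = %.*f\n",
              digits, x$H_UX, digits, x$H_UY))
  cat(sprintf("  H(P_X) = %.*f   H(P_Y) = %.*f   H(P_XY) = %.*f\n",
              digits, x$H_PX, digits, x$H_PY, digits, x$H_XY))
  cat(sprintf("  H(X|Y) = %.*f   H(Y|X) = %.*f\n",
              digits, x$H_XgY, digits, x$H_YgX))
  cat(sprintf("  MI = %.*f   VI = %.*f   dH = %.*f\n",
              digits, x$MI, digits, x$VI, digits, x$dH))
  cat(sprintf("  balance: dH + 2 MI + VI = %.*f = H(U_X) + H(U_Y)\n",
              digits, x$dH + 2 * x$MI + x$VI))
  invisible(x)
}

new_triangle_coordinates <- function(dH_norm, mi2_norm, vi_norm, variant) {
  structure(
    list(dH_norm = dH_norm, mi2_norm = mi2_norm, vi_norm = vi_norm,
         variant = variant),
    class = "triangle_coordinates"
  )
}

#' Entropy-triangle coordinates
#'
#' Normalizes the entropy balance to barycentric coordinates on the
#' 2-simplex: \eqn{(\Delta H', 2MI', VI')}, each term divided by
#' \eqn{H(U_X) + H(U_Y)}. The triple sums to 1 and locates the classifier on
#' the De Finetti (ternary) diagram: the apex (maximal \eqn{2MI'}) holds the
#' best classifiers, the right vertex (maximal \eqn{\Delta H'}) the
#' specialized majority classifiers, the left vertex (maximal \eqn{VI'}) the
#' worst, uninformative ones.
#'
#' @param x an [entropy_balance()], or anything [entropy_balance()] accepts.
#' @param ... passed to [entropy_balance()].
#' @return An object of class `triangle_coordinates` with fields `dH_norm`,
#'   `mi2_norm`, `vi_norm` (fractions summing to 1) and
#'   `variant = "joint"`.
#' @examples
#' triangle_coordinates(diag(2) * 10)   # apex: (0, 1, 0)
#' @export
triangle_coordinates <- function(x, ...) {
  B <- if (inherits(x, "entropy_balance")) x else entropy_balance(x, ...)
  denom <- B$H_UX + B$H_UY
  if (denom <= 0) stop("degenerate single-class task")
  new_triangle_coordinates(B$dH / denom, 2 * B$MI / denom, B$VI / denom,
                           "joint")
}

#' Split entropy-triangle coordinates
#'
#' The balance equation splits into one equation per variable:
#' \deqn{H(U_X) = (H(U_X) - H(P_X)) + MI + H(X|Y)}
#' and analogously for \eqn{Y}. Dividing each by its own uniform entropy
#' gives one barycentric triple per variable, so the input and output sides
#' of one classifier can be placed separately on the same triangle. The
#' average of the two triples weighted by \eqn{H(U_X)} and \eqn{H(U_Y)}
#' recovers the joint coordinates.
#'
#' @inheritParams triangle_coordinates
#' @return A list with elements `X` and `Y`, each a `triangle_coordinates`
#'   object (`variant` `"split_X"` / `"split_Y"`).
#' @examples
#' split_coordinates(matrix(c(10, 10, 0, 0), 2))  # constant-output classifier
#' @export
split_coordinates <- function(x, ...) {
  B <- if (inherits(x, "entropy_balance")) x else entropy_balance(x, ...)
  if (B$H_UX <= 0 || B$H_UY <= 0) stop("degenerate single-class task")
  list(
    X = new_triangle_coordinates((B$H_UX - B$H_PX) / B$H_UX, B$MI / B$H_UX,
                                 B$H_XgY / B$H_UX, "split_X"),
    Y = new_triangle_coordinates((B$H_UY - B$H_PY) / B$H_UY, B$MI / B$H_UY,
                                 B$H_YgX / B$H_UY, "split_Y")
  )
}

#' @export
print.triangle_coordinates <- function(x, digits = 4, ...) {
  cat(sprintf("Entropy-triangle coordinates (%s): dH' = %.*f, 2MI' = %.*f, VI' = %.*f\n",
              x$variant, digits, x$dH_norm, digits, x$mi2_norm,
              digits, x$vi_norm))
  invisible(x)
}

#' @export
as.data.frame.triangle_coordinates <- function(x, ...) {
  data.frame(dH_norm = x$dH_norm, mi2_norm = x$mi2_norm,
             vi_norm = x$vi_norm, variant = x$variant,
             stringsAsFactors = FALSE)
}
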