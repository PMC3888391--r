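#' Integer partitions with a fixed number of parts
#'
#' All partitions of `N` into at most `n` non-negative parts, returned as
#' non-increasing rows zero-padded to length `n`. These enumerate every
#' possible input class distribution of `N` samples over `n` classes, up to
#' reordering of the classes — from uniform to fully skewed.
#'
#' @param N total count to partition (\eqn{\ge 0}).
#' @param n number of parts (\eqn{\ge 1}).
#' @return integer matrix with `n` columns, one partition per row, rows in
#'   lexicographically decreasing order.
#' @examples
#' integer_partitions(4, 2)  # (4,0), (3,1), (2,2)
#' @export
integer_partitions <- function(N, n) {
  if (N < 0 || n < 1) stop("need N >= 0 and n >= 1")
  parts <- partitions_rec(as.integer(N), as.integer(n), as.integer(N))
  out <- do.call(rbind, parts)
  storage.mode(out) <- "integer"
  out
}

# partitions of total into exactly n parts, each <= cap, non-increasing
partitions_rec <- function(total, n, cap) {
  if (n == 1L) {
    if (total <= cap) return(list(total)) else return(list())
  }
  out <- list()
  for (first in min(total, cap):0L) {
    if (total - first > first * (n - 1L)) break  # remaining can't fit
    for (rest in partitions_rec(total - first, n - 1L, first)) {
      out[[length(out) + 1L]] <- c(first, rest)
    }
  }
  out
}

#' Weak compositions of an integer
#'
#' All ordered tuples of `n` non-negative integers summing to `m`: the
#' possible count vectors for one row of a confusion matrix. There are
#' `choose(m + n - 1, n - 1)` of them.
#'
#' @param m total count (\eqn{\ge 0}).
#' @param n number of parts (\eqn{\ge 1}).
#' @return integer matrix with `n` columns, one composition per row, no
#'   duplicates, in lexicographically decreasing order of the first part.
#' @examples
#' weak_compositions(2, 3)  # 6 rows
#' @export
weak_compositions <- function(m, n) {
  if (m < 0 || n < 1) stop("need m >= 0 and n >= 1")
  m <- as.integer(m)
  n <- as.integer(n)
  if (n == 1L) return(matrix(m, 1L, 1L))
  blocks <- lapply(m:0L, function(first) {
    cbind(first, weak_compositions(m - first, n - 1L), deparse.level = 0)
  })
  out <- do.call(rbind, blocks)
  storage.mode(out) <- "integer"
  out
}

#' Count the confusion-matrix space
#'
#' Closed-form size of the space enumerated by [enumerate_matrices()]:
#' summed over the partitions \eqn{N_1 \ge \dots \ge N_n \ge 0} of `N`, the
#' product of `choose(N_i + n - 1, n - 1)` row choices.
#'
#' @param n class count.
#' @param N sample count.
#' @return the number of canonical `n x n` matrices with total `N`.
#' @examples
#' count_matrices(2, 4)  # 22
#' @export
count_matrices <- function(n, N) {
  if (n < 1 || N < 0) stop("need n >= 1 and N >= 0")
  parts <- integer_partitions(N, n)
  sum(apply(parts, 1L, function(p) prod(choose(p + n - 1, n - 1))))
}

#' Enumerate the space of confusion matrices
#'
#' Generates every `n x n` non-negative integer matrix with total `N`, one
#' representative per row-permutation class: the row-sum vector (the input
#' class distribution) is taken non-increasing, since reordering rows only
#' renames the input classes. Construction follows partitions of `N` into
#' `n` row sums, then the Cartesian product of the weak compositions of
#' each row sum into `n` cells.
#'
#' @param n class count.
#' @param N sample count.
#' @param decimation either an integer stride \eqn{\ge 1} (keep one matrix
#'   in every `decimation` along the enumeration order) or a fraction in
#'   (0, 1) (keep a seeded uniform subset of that expected size).
#' @param seed integer seed for fractional decimation (required then).
#' @param max_count refuse to materialize more than this many matrices when
#'   no decimation is requested (resource guard).
#' @return list of [confusion_table()] objects, with attributes
#'   `space_size` (full count), `decimation` and `seed` recording how the
#'   subset was drawn. Enumeration order is fixed and reproducible:
#'   partitions in decreasing lexicographic order, row compositions
#'   likewise, rightmost row varying fastest.
#' @examples
#' length(enumerate_matrices(2, 4))  # 22
#' @export
enumerate_matrices <- function(n, N, decimation = 1, seed = NULL,
                               max_count = 2e5) {
  if (n < 1 || N < 1) stop("need n >= 1 and N >= 1")
  total <- count_matrices(n, N)
  fractional <- decimation > 0 && decimation < 1
  if (!fractional && (decimation < 1 || decimation != round(decimation))) {
    stop("decimation must be an integer stride >= 1 or a fraction in (0,1)")
  }
  if (!fractional && decimation == 1 && total > max_count) {
    stop(sprintf(
      "space holds %s matrices, above the cap of %s; decimate or raise max_count",
      format(total), format(max_count)))
  }
  keep <- if (fractional) {
    if (is.null(seed)) stop("fractional decimation needs a seed")
    k <- max(1L, floor(decimation * total))
    sort(sample_with_seed(total, k, seed))
  } else {
    seq(1L, total, by = as.integer(decimation))
  }
  keep_set <- logical(total)
  keep_set[keep] <- TRUE

  out <- vector("list", length(keep))
  filled <- 0L
  idx <- 0L
  parts <- integer_partitions(N, n)
  for (pi in seq_len(nrow(parts))) {
    rows <- lapply(parts[pi, ], weak_compositions, n = n)
    sizes <- vapply(rows, nrow, integer(1))
    block <- prod(sizes)
    counter <- rep(1L, n)
    for (b in seq_len(block)) {
      idx <- idx + 1L
      if (keep_set[idx]) {
        m <- do.call(rbind, lapply(seq_len(n),
                                   function(i) rows[[i]][counter[i], ]))
        filled <- filled + 1L
        out[[filled]] <- confusion_table(m)
      }
      # odometer, rightmost row fastest
      for (pos in n:1L) {
        counter[pos] <- counter[pos] + 1L
        if (counter[pos] <= sizes[pos]) break
        counter[pos] <- 1L
      }
    }
  }
  out <- out[seq_len(filled)]
  attr(out, "space_size") <- total
  attr(out, "decimation") <- decimation
  attr(out, "seed") <- seed
  out
}

# local-RNG sampling that leaves .Random.seed alone
sample_with_seed <- function(total, k, seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(total, k)
}

#' Sweep the confusion-matrix space onto the entropy triangle
#'
#' Evaluates every matrix of the space (or a decimated subset) and records
#' its accuracy, entropy-triangle coordinates, EMA and NIT factor. Plotting
#' the records colored by accuracy reproduces the accuracy-paradox picture:
#' matrices of the same accuracy scatter over a wide range of information
#' transfer, and perfect accuracy occurs both at the apex (balanced
#' faithful classifier) and at the majority-classifier vertex.
#'
#' @inheritParams enumerate_matrices
#' @return data frame of class `accuracy_sweep` with columns `id`,
#'   `accuracy`, `dH_norm`, `mi2_norm`, `vi_norm`, `ema`, `nit`; attributes
#'   as in [enumerate_matrices()].
#' @examples
#' sw <- accuracy_sweep(2, 4)
#' nrow(sw)  # 22
#' @export
accuracy_sweep <- function(n, N, decimation = 1, seed = NULL,
                           max_count = 2e5) {
  mats <- enumerate_matrices(n, N, decimation = decimation, seed = seed,
                             max_count = max_count)
  recs <- lapply(seq_along(mats), function(i) {
    m <- mats[[i]]
    B <- entropy_balance(m)
    tc <- triangle_coordinates(B)
    cnt <- ct_counts(m)
    data.frame(id = i, accuracy = sum(diag(cnt)) / sum(cnt),
               dH_norm = tc$dH_norm, mi2_norm = tc$mi2_norm,
               vi_norm = tc$vi_norm,
               ema = 2^(-B$H_XgY), nit = 2^B$MI / B$n)
  })
  out <- do.call(rbind, recs)
  attr(out, "space_size") <- attr(mats, "space_size")
  attr(out, "decimation") <- attr(mats, "decimation")
  attr(out, "seed") <- attr(mats, "seed")
  class(out) <- c("accuracy_sweep", "data.frame")
  out
}

#' Write sweep records to CSV
#'
#' @param sweep an [accuracy_sweep()] result.
#' @param path output CSV file.
#' @return `path`, invisibly. Decimation metadata goes into a leading
#'   comment line.
#' @export
write_sweep <- function(sweep, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# space_size=%s decimation=%s seed=%s",
                     format(attr(sweep, "space_size")),
                     format(attr(sweep, "decimation")),
                     if (is.null(attr(sweep, "seed"))) "NA"
                     else format(attr(sweep, "seed"))), con)
  utils::write.csv(as.data.frame(sweep), con, row.names = FALSE)
  invisible(path)
}
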