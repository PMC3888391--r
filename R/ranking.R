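#' Rank a population of classifiers by EMA
#'
#' Implements the population-assessment protocol: estimate the effective
#' number of classes of the task from \eqn{k_X}, rank the classifiers by
#' entropy-modulated accuracy (EMA), and judge from the best NIT factor
#' whether the population has effectively solved the task. On a shared task
#' (identical input marginal) EMA and NIT induce the same ranking, which can
#' differ sharply from the accuracy ranking on skewed data.
#'
#' @param tables a named list of confusion tables (or count matrices), all
#'   sharing the same true-class label set. Unnamed lists get ids `C1..Ck`.
#' @param smoothing passed to [perplexity_profile()].
#' @return An [evaluation_report()] object.
#' @examples
#' faithful <- diag(2) * 10
#' majority <- matrix(c(10, 10, 0, 0), 2)
#' rank_classifiers(list(faithful = faithful, majority = majority))
#' @export
rank_classifiers <- function(tables, smoothing = 0) {
  if (length(tables) == 0L) stop("no confusion tables to rank")
  tables <- lapply(tables, as_confusion_table)
  ids <- names(tables)
  if (is.null(ids)) ids <- paste0("C", seq_along(tables))
  ref <- sort(rownames(tables[[1L]]))
  for (i in seq_along(tables)) {
    if (!identical(sort(rownames(tables[[i]])), ref)) {
      stop("classifier '", ids[i], "' has a different true-class label set")
    }
  }
  profs <- lapply(tables, perplexity_profile, smoothing = smoothing)
  evaluation_report(do.call(rbind, lapply(profs, as.data.frame)), ids = ids)
}

#' Evaluation report from perplexity profiles
#'
#' Builds the ranked report directly from per-classifier profiles — either
#' [perplexity_profile()] objects or a data frame with columns `k_XgY`,
#' `mu`, `acc` (and optionally `n`, needed to recover `nit = mu / n` when an
#' `nit` column is absent). This is the entry point when only the published
#' perplexity table of a competition is available, not the raw confusion
#' matrices.
#'
#' Ranking is by descending EMA, ties broken by descending accuracy then by
#' id order.
#'
#' @param profiles data frame of profile rows (see above).
#' @param ids classifier identifiers; defaults to row names or `C1..Ck`.
#' @param n input cardinality used when `profiles` lacks both `nit` and `n`.
#' @return object of class `evaluation_report`: list with `rows` (data frame
#'   in EMA rank order with columns `id`, `k_XgY`, `mu`, `acc`, `ema`,
#'   `nit`, `rank_ema`, `rank_acc`), `ranking` (ids in EMA order),
#'   `task_perplexity` (median reconstructed \eqn{k_X = \mu k_{X|Y}}), and
#'   `solved_flag` (qualitative verdict from the best NIT factor).
#' @export
evaluation_report <- function(profiles, ids = NULL, n = NULL) {
  profiles <- as.data.frame(profiles)
  if (nrow(profiles) == 0L) stop("no profiles to rank")
  need <- c("k_XgY", "mu", "acc")
  missing_cols <- setdiff(need, names(profiles))
  if (length(missing_cols)) {
    stop("profiles lack columns: ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(ids)) {
    ids <- rownames(profiles)
    if (is.null(ids) || identical(ids, as.character(seq_len(nrow(profiles))))) {
      ids <- paste0("C", seq_len(nrow(profiles)))
    }
  }
  if (!("ema" %in% names(profiles))) profiles$ema <- 1 / profiles$k_XgY
  if (!("nit" %in% names(profiles))) {
    card <- if (!is.null(n)) n else profiles$n
    if (is.null(card)) stop("need 'n' to derive the NIT factor as mu / n")
    profiles$nit <- profiles$mu / card
  }
  rows <- data.frame(id = as.character(ids),
                     k_XgY = profiles$k_XgY, mu = profiles$mu,
                     acc = profiles$acc, ema = profiles$ema,
                     nit = profiles$nit, stringsAsFactors = FALSE)
  ord <- order(-rows$ema, -rows$acc, rows$id)
  rows <- rows[ord, , drop = FALSE]
  rows$rank_ema <- seq_len(nrow(rows))
  rows$rank_acc <- rank(-rows$acc, ties.method = "first")
  rownames(rows) <- NULL
  k_task <- stats::median(rows$mu * rows$k_XgY)
  best_nit <- rows$nit[1L]
  solved <- if (best_nit >= 0.9) {
    sprintf("task effectively solved (best NIT = %.3f)", best_nit)
  } else {
    sprintf("task not effectively solved (best NIT = %.3f)", best_nit)
  }
  structure(list(rows = rows, ranking = rows$id,
                 task_perplexity = k_task, solved_flag = solved),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, digits = 3, ...) {
  cat(sprintf("Classifier evaluation: %d classifiers, task perplexity k_X = %.*f\n",
              nrow(x$rows), digits, x$task_perplexity))
  cat(" ", x$solved_flag, "\n", sep = "")
  out <- x$rows
  num <- c("k_XgY", "mu", "acc", "ema", "nit")
  out[num] <- lapply(out[num], function(v) round(v, digits))
  print(out, row.names = FALSE, ...)
  invisible(x)
}

#' @export
as.data.frame.evaluation_report <- function(x, ...) x$rows

#' @export
summary.evaluation_report <- function(object, ...) {
  cat("Winner by EMA:      ", object$ranking[1L], "\n")
  acc_first <- object$rows$id[object$rows$rank_acc == 1L]
  cat("Winner by accuracy: ", acc_first, "\n")
  cat("Task perplexity k_X:", format(object$task_perplexity), "\n")
  cat(object$solved_flag, "\n")
  invisible(object)
}

#' Write an evaluation report to disk
#'
#' @param report an [evaluation_report()].
#' @param path output file.
#' @param format one of `"csv"`, `"json"`, `"markdown"`.
#' @param digits decimals for the numeric columns (default 3, matching the
#'   conventional presentation of perplexity tables).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "json", "markdown"),
                         digits = 3) {
  if (!inherits(report, "evaluation_report")) {
    stop("'report' must be an evaluation_report")
  }
  format <- match.arg(format)
  rows <- report$rows
  num <- c("k_XgY", "mu", "acc", "ema", "nit")
  rounded <- rows
  rounded[num] <- lapply(rounded[num], function(v) round(v, digits))
  if (format == "csv") {
    utils::write.csv(rounded, path, row.names = FALSE, quote = FALSE)
  } else if (format == "json") {
    jsonlite::write_json(
      list(task_perplexity = report$task_perplexity,
           solved_flag = report$solved_flag, rows = rounded),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    fmt <- function(v) formatC(v, digits = digits, format = "f")
    header <- "| rank | id | k_X|Y | mu | acc | ema | nit | acc rank |"
    sepr <- "|---|---|---|---|---|---|---|---|"
    body <- vapply(seq_len(nrow(rows)), function(i) {
      r <- rows[i, ]
      sprintf("| %d | %s | %s | %s | %s | %s | %s | %d |",
              r$rank_ema, r$id, fmt(r$k_XgY), fmt(r$mu), fmt(r$acc),
              fmt(r$ema), fmt(r$nit), r$rank_acc)
    }, character(1))
    writeLines(c(header, sepr, body), path)
  }
  invisible(path)
}
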