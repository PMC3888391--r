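#' Published perplexity table of the MEG mind-reading competition
#'
#' Per-classifier summary of the ten entrants of the PASCAL MEG
#' mind-reading challenge, a 5-class video-stimulus decoding task: the
#' remaining input perplexity `k_XgY`, the information transfer factor
#' `mu`, the official accuracy `acc`, and the published EMA and NIT values
#' (`ema_published`, `nit_published`), in the order of the official accuracy
#' ranking. The raw confusion matrices of the competition were never
#' released numerically; this summary is what the measures need
#' (`ema = 1/k_XgY`, `nit = mu/5`).
#'
#' @return data frame of 10 rows with an `n` attribute (5 classes) and row
#'   ids `M1..M10`.
#' @examples
#' meg <- meg_mindreading()
#' evaluation_report(meg, ids = meg$exp, n = attr(meg, "n"))
#' @export
meg_mindreading <- function() {
  path <- system.file("extdata", "meg_mindreading_table.csv",
                      package = "entropytriangle", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  attr(df, "n") <- 5L
  df
}
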