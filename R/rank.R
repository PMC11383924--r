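#' Rank candidate complex models
#'
#' Two selection strategies over an ensemble of scored models:
#' \describe{
#'   \item{confidence}{descending model confidence — the standard pick.}
#'   \item{xl_first}{first by crosslink satisfaction, ties broken by model
#'     confidence — the crosslink-aware pick that rescues targets where
#'     confidence alone is not discriminative.}
#' }
#' Remaining ties are broken by `model_id`, so the ranking is a stable
#' permutation of the input, invariant to input order.
#'
#' @param ensemble data.frame with columns `model_id`, `confidence`, and
#'   (for `xl_first`) `satisfaction`.
#' @param strategy `"confidence"` or `"xl_first"`.
#' @return The ensemble data.frame reordered best-first, with a `rank`
#'   column prepended.
#' @export
rank_models <- function(ensemble, strategy = c("confidence", "xl_first")) {
  strategy <- match.arg(strategy)
  ensemble <- as.data.frame(ensemble)
  if (!all(c("model_id", "confidence") %in% names(ensemble)))
    stop("ensemble needs model_id and confidence columns")
  if (anyDuplicated(ensemble$model_id))
    stop("model_id values must be unique within an ensemble")
  if (strategy == "xl_first") {
    if (!"satisfaction" %in% names(ensemble) ||
        anyNA(ensemble$satisfaction))
      stop("strategy xl_first requires crosslink satisfaction for every model")
    ord <- order(-ensemble$satisfaction, -ensemble$confidence,
                 ensemble$model_id)
  } else {
    if (anyNA(ensemble$confidence))
      stop("strategy confidence requires a confidence for every model")
    ord <- order(-ensemble$confidence, ensemble$model_id)
  }
  out <- ensemble[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}
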