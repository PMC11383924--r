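#' Crosslink satisfaction and noise rejection of a model
#'
#' A link is satisfied when its CA-CA distance in the model is within the
#' crosslinker cutoff. In `"labelled"` mode satisfaction is computed over
#' true (non-decoy) links and noise rejection is the fraction of decoys the
#' model places beyond the cutoff; in `"blind"` mode satisfaction covers
#' all links and noise rejection is `NA`. `"auto"` picks labelled when
#' decoy flags are available. Links whose residues cannot be resolved in
#' the model count as violated (reported via a message).
#'
#' @param model An `xl_structure`.
#' @param xs An `xl_crosslink_set`.
#' @param cutoff CA-CA cutoff in Angstrom (the crosslinker bound).
#' @param mode `"auto"`, `"labelled"` or `"blind"`.
#' @return An `xl_link_score`: list with `satisfaction`,
#'   `noise_rejection`, `n_links`, `n_unresolved`, `distances`.
#' @export
link_scores <- function(model, xs, cutoff = 25,
                        mode = c("auto", "labelled", "blind")) {
  mode <- match.arg(mode)
  links <- xs$links
  if (nrow(links) == 0L) stop("link scores undefined for an empty set")
  labelled <- !anyNA(links$is_decoy)
  if (mode == "auto") mode <- if (labelled) "labelled" else "blind"
  if (mode == "labelled" && !labelled)
    stop("decoy labels absent: labelled scoring impossible")
  d <- vapply(seq_len(nrow(links)), function(k) {
    tryCatch(ca_distance(model,
                         residue_ref(links$chain1[k], links$res1[k]),
                         residue_ref(links$chain2[k], links$res2[k])),
             error = function(e) NA_real_)
  }, numeric(1))
  unresolved <- is.na(d)
  if (any(unresolved))
    message(sum(unresolved), " link(s) unresolvable in the model; ",
            "counted as violated")
  sat_of <- function(idx) {
    if (!length(idx)) return(NA_real_)
    mean(!unresolved[idx] & d[idx] <= cutoff)
  }
  if (mode == "labelled") {
    satisfaction <- sat_of(which(!links$is_decoy))
    dec <- which(links$is_decoy)
    noise_rejection <- if (length(dec))
      mean(unresolved[dec] | d[dec] > cutoff) else NA_real_
  } else {
    satisfaction <- sat_of(seq_len(nrow(links)))
    noise_rejection <- NA_real_
  }
  structure(list(satisfaction = satisfaction,
                 noise_rejection = noise_rejection,
                 n_links = nrow(links), n_unresolved = sum(unresolved),
                 distances = d, cutoff = cutoff, mode = mode),
            class = "xl_link_score")
}

#' @export
print.xl_link_score <- function(x, ...) {
  cat(sprintf(
    "xl_link_score (%s): satisfaction %.3f, noise rejection %s over %d links (cutoff %g A)\n",
    x$mode, x$satisfaction,
    if (is.na(x$noise_rejection)) "NA" else sprintf("%.3f", x$noise_rejection),
    x$n_links, x$cutoff))
  invisible(x)
}

#' Combined model confidence
#'
#' The standard weighting of the predictor's interface and global TM-score
#' estimates: `0.8 * ipTM + 0.2 * pTM`.
#'
#' @param iptm Interface predicted TM-score in [0, 1].
#' @param ptm Predicted TM-score in [0, 1].
#' @return An `xl_confidence`: list with `iptm`, `ptm`, `confidence`.
#' @export
model_confidence <- function(iptm, ptm) {
  if (any(iptm < 0 | iptm > 1 | ptm < 0 | ptm > 1))
    stop("ipTM and pTM must lie in [0, 1]")
  structure(list(iptm = iptm, ptm = ptm,
                 confidence = 0.8 * iptm + 0.2 * ptm),
            class = "xl_confidence")
}
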