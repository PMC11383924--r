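#' Crosslinker chemistry profiles
#'
#' A profile names the reactive residue types of each reaction side and the
#' maximum CA-CA distance compatible with the reagent. Built-ins:
#' \describe{
#'   \item{SDA}{sulfo-SDA, heterobifunctional: NHS-ester side reacts with
#'     Lys/Ser/Thr/Tyr, the diazirine photo-side with any surface residue;
#'     bound 25 Angstrom CA-CA.}
#'   \item{DSSO}{homobifunctional, MS-cleavable; primarily Lys but also
#'     Ser/Thr/Tyr on both sides; bound 25 Angstrom (default, overridable).}
#'   \item{photo-AA}{photo-activatable amino acids (photo-Leu/photo-Met)
#'     reacting with any surface residue; bound 15 Angstrom.}
#' }
#'
#' @param name One of `"SDA"`, `"DSSO"`, `"photo-AA"`, or `"custom"`.
#' @param side1,side2 Character vectors of one-letter reactive residue
#'   types, or the wildcard `"surface"` (any surface residue). Used only
#'   when `name = "custom"`.
#' @param max_ca Maximum CA-CA distance in Angstrom; overrides the
#'   built-in default if given.
#' @return An `xl_profile`: list with `name`, `side1`, `side2`, `max_ca`.
#' @export
crosslinker_profile <- function(name = c("SDA", "DSSO", "photo-AA", "custom"),
                                side1 = NULL, side2 = NULL, max_ca = NULL) {
  name <- match.arg(name)
  p <- switch(name,
    "SDA"      = list(side1 = c("K", "S", "T", "Y"), side2 = "surface",
                      max_ca = 25),
    "DSSO"     = list(side1 = c("K", "S", "T", "Y"),
                      side2 = c("K", "S", "T", "Y"), max_ca = 25),
    "photo-AA" = list(side1 = c("L", "M"), side2 = "surface", max_ca = 15),
    "custom"   = list(side1 = side1, side2 = side2, max_ca = max_ca))
  if (!is.null(max_ca)) p$max_ca <- max_ca
  if (is.null(p$side1) || is.null(p$side2) || length(p$side1) == 0L ||
      length(p$side2) == 0L)
    stop("profile sides must be non-empty")
  if (is.null(p$max_ca) || p$max_ca <= 0)
    stop("max_ca must be positive")
  structure(c(list(name = name), p), class = "xl_profile")
}

#' Crosslinkable residues of one reaction side
#'
#' A residue can carry a crosslink when (i) its type is in the reactive set
#' of the side (any type for the `"surface"` wildcard), (ii) it is
#' observable after tryptic digestion, and (iii) it belongs to the
#' solvent-accessible surface.
#'
#' @param s An `xl_structure`.
#' @param side Character vector of reactive one-letter types, or
#'   `"surface"`.
#' @param digest Named list of [digest_trypsin()] results, one per chain.
#' @param sasa A [shrake_rupley()] result on the same structure.
#' @return data.frame with `chain`, `resno` (may be empty).
#' @export
crosslinkable_residues <- function(s, side, digest, sasa) {
  out <- lapply(chain_ids(s), function(ch) {
    res <- chain_residues(s, ch)
    seq1 <- strsplit(chain_sequence(s, ch), "")[[1]]
    ok_type <- if (identical(side, "surface")) rep(TRUE, nrow(res))
               else seq1 %in% side
    ok_obs <- seq_len(nrow(res)) %in% digest[[ch]]$observable
    ok_surf <- paste(ch, res$resno) %in%
      paste(sasa$surface$chain, sasa$surface$resno)
    res[ok_type & ok_obs & ok_surf & res$has_ca, c("resno"), drop = FALSE]
  })
  data.frame(
    chain = rep(chain_ids(s), vapply(out, nrow, integer(1))),
    resno = unlist(lapply(out, `[[`, "resno"), use.names = FALSE),
    stringsAsFactors = FALSE)
}
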