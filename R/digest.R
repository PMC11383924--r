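#' In-silico tryptic digestion
#'
#' Cleaves a protein sequence C-terminal to Lys or Arg, except when the next
#' residue is Pro, and enumerates peptides carrying up to `max_missed`
#' internal missed cleavage sites. A residue is *observable* if it lies on at
#' least one peptide whose length falls within the detectability window
#' (`min_len` to `max_len` residues, defaults typical of MS acquisition).
#' The default `max_missed = 2` reflects that a crosslinked lysine itself
#' suppresses cleavage.
#'
#' @param sequence One-letter amino-acid string (standard alphabet; `X`
#'   allowed, never cleaved).
#' @param max_missed Maximum missed cleavages per peptide.
#' @param min_len,max_len Observability window in residues.
#' @return An `xl_digest`: list with `peptides` (data.frame `start`, `end`
#'   — 1-based inclusive positions — `sequence`, `missed_cleavages`) and
#'   `observable` (sorted integer vector of residue positions).
#' @export
digest_trypsin <- function(sequence, max_missed = 2L,
                           min_len = 5L, max_len = 50L) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n == 0L) {
    return(structure(list(
      peptides = data.frame(start = integer(), end = integer(),
                            sequence = character(),
                            missed_cleavages = integer(),
                            stringsAsFactors = FALSE),
      observable = integer()), class = "xl_digest"))
  }
  aa <- strsplit(sequence, "")[[1]]
  if (!all(aa %in% c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")))
    stop("sequence contains characters outside the amino-acid alphabet")
  # cut after position i when aa[i] is K/R and aa[i+1] is not P
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after == n | aa[pmin(cut_after + 1L, n)] != "P"]
  bounds <- c(0L, cut_after[cut_after < n], n)  # fragment boundaries
  starts <- bounds[-length(bounds)] + 1L
  ends   <- bounds[-1]
  nfrag  <- length(starts)
  pep <- list()
  for (m in 0:max_missed) {
    i <- seq_len(max(0L, nfrag - m))
    if (length(i) == 0L) break
    pep[[m + 1L]] <- data.frame(
      start = starts[i], end = ends[i + m],
      missed_cleavages = m, stringsAsFactors = FALSE)
  }
  pep <- do.call(rbind, pep)
  pep <- pep[order(pep$start, pep$end), , drop = FALSE]
  pep$sequence <- substring(sequence, pep$start, pep$end)
  pep <- pep[, c("start", "end", "sequence", "missed_cleavages")]
  rownames(pep) <- NULL
  len <- pep$end - pep$start + 1L
  obs <- pep[len >= min_len & len <= max_len, , drop = FALSE]
  observable <- sort(unique(unlist(
    mapply(seq.int, obs$start, obs$end, SIMPLIFY = FALSE))))
  structure(list(peptides = pep, observable = as.integer(observable)),
            class = "xl_digest")
}

#' @export
print.xl_digest <- function(x, ...) {
  cat("xl_digest: ", nrow(x$peptides), " peptides, ",
      length(x$observable), " observable residues\n", sep = "")
  invisible(x)
}
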