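#' Build the soft-label contact map from a crosslink set
#'
#' Encodes a crosslink set as a symmetric `N_total x N_total` matrix over
#' the concatenated chains (in declared chain order), where each link
#' contributes the value `1 - link_fdr` at its residue-pair cell (and its
#' transpose). When several links fall on one cell the maximum value is
#' kept; all other cells are zero. This is the restraint feature a
#' restraint-aware predictor consumes.
#'
#' @param xs An `xl_crosslink_set`.
#' @param chain_order Character vector: chain ids in prediction-job order.
#' @param chain_lengths Named integer vector of chain lengths. Residue
#'   numbers are then assumed sequential from 1. Alternatively supply
#'   `structure` to map author numbering through each chain's residue
#'   index table.
#' @param structure Optional `xl_structure` providing the residue index
#'   tables (takes precedence for index resolution).
#' @return An `xl_restraint_map`: list with `matrix`, `chain_offsets`
#'   (0-based first global index per chain), `chain_order`,
#'   `chain_lengths`.
#' @export
build_soft_contact_map <- function(xs, chain_order, chain_lengths = NULL,
                                   structure = NULL) {
  if (!is.null(structure)) {
    chain_lengths <- vapply(chain_order, function(ch)
      chain_length(structure, ch), integer(1))
    index_of <- function(ch, resno) {
      i <- match(resno, chain_residues(structure, ch)$resno)
      i
    }
  } else {
    if (is.null(chain_lengths) || !all(chain_order %in% names(chain_lengths)))
      stop("chain_lengths must name every chain in chain_order")
    chain_lengths <- chain_lengths[chain_order]
    index_of <- function(ch, resno)
      ifelse(resno >= 1L & resno <= chain_lengths[[ch]], resno, NA_integer_)
  }
  offs <- c(0L, cumsum(as.integer(chain_lengths)))[seq_along(chain_order)]
  names(offs) <- chain_order
  n_total <- sum(chain_lengths)
  m <- matrix(0, n_total, n_total)
  links <- xs$links
  for (k in seq_len(nrow(links))) {
    l <- links[k, ]
    if (!(l$chain1 %in% chain_order) || !(l$chain2 %in% chain_order))
      stop("link ", k, " (", l$chain1, ":", l$res1, " - ", l$chain2, ":",
           l$res2, ") references a chain outside the declared order")
    i <- index_of(l$chain1, l$res1)
    j <- index_of(l$chain2, l$res2)
    if (is.na(i) || is.na(j))
      stop("link ", k, " (", l$chain1, ":", l$res1, " - ", l$chain2, ":",
           l$res2, ") has an out-of-range residue")
    gi <- offs[[l$chain1]] + i
    gj <- offs[[l$chain2]] + j
    v  <- 1 - l$link_fdr
    m[gi, gj] <- max(m[gi, gj], v)
    m[gj, gi] <- m[gi, gj]
  }
  structure(list(matrix = m, chain_offsets = offs,
                 chain_order = chain_order,
                 chain_lengths = as.integer(chain_lengths)),
            class = "xl_restraint_map")
}

#' Write / read a crosslink restraint file
#'
#' Tab-separated UTF-8 dialect:
#' `chain1<TAB>res1<TAB>chain2<TAB>res2<TAB>fdr[<TAB>decoy]` with residue
#' numbers in author numbering, the link-level FDR printed with 4 decimals,
#' and an optional 0/1 decoy column. Lines starting with `#` are comments;
#' the writer records the simulation parameters in the header. Writing the
#' same set twice yields byte-identical files.
#'
#' @param xs An `xl_crosslink_set`.
#' @param path Output (input) file path.
#' @return `write_restraints`: `path`, invisibly. `read_restraints`: an
#'   `xl_crosslink_set`.
#' @export
write_restraints <- function(xs, path) {
  p <- xs$params
  hdr <- c("# xlcomplex crosslink restraints",
           paste0("# source=", xs$source),
           if (!is.null(p$coverage))
             sprintf("# coverage=%g fdr=%g seed=%d scope=%s",
                     p$coverage, p$fdr, p$seed, p$scope),
           "# chain1\tres1\tchain2\tres2\tfdr\tdecoy")
  l <- xs$links
  rows <- sprintf("%s\t%d\t%s\t%d\t%.4f\t%d",
                  l$chain1, l$res1, l$chain2, l$res2, l$link_fdr,
                  as.integer(l$is_decoy))
  con <- file(path, open = "wb")  # LF endings on every platform
  on.exit(close(con))
  writeLines(c(hdr, rows), con, sep = "\n")
  invisible(path)
}

#' @rdname write_restraints
#' @export
read_restraints <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lineno <- which(keep)
  rows <- strsplit(raw[keep], "\t", fixed = TRUE)
  if (length(rows) == 0L)
    return(new_crosslink_set(empty_links(), NULL, path))
  nf <- lengths(rows)
  if (any(nf < 5L | nf > 6L))
    stop("malformed restraint line ", lineno[which(nf < 5L | nf > 6L)[1]],
         " in ", path, " (expected 5 or 6 tab-separated fields)")
  f <- function(i) vapply(rows, `[`, character(1), i)
  res1 <- suppressWarnings(as.integer(f(2)))
  res2 <- suppressWarnings(as.integer(f(4)))
  fdr  <- suppressWarnings(as.numeric(f(5)))
  bad  <- is.na(res1) | is.na(res2) | is.na(fdr) | fdr < 0 | fdr > 1
  if (any(bad))
    stop("malformed restraint line ", lineno[which(bad)[1]], " in ", path)
  decoy <- rep(NA, length(rows))
  has6 <- nf == 6L
  decoy[has6] <- vapply(rows[has6], `[`, character(1), 6) == "1"
  links <- data.frame(chain1 = f(1), res1 = res1, chain2 = f(3),
                      res2 = res2, is_decoy = decoy, link_fdr = fdr,
                      stringsAsFactors = FALSE)
  new_crosslink_set(links, NULL, path)
}

#' Serialize a restraint map as NPY with a JSON sidecar
#'
#' Writes the soft-label matrix as a NumPy `.npy` file (version 1.0,
#' little-endian float64, C order) and the chain bookkeeping (order,
#' lengths, 0-based offsets) as `<path>.json`.
#'
#' @param map An `xl_restraint_map`.
#' @param path Output `.npy` path.
#' @return `path`, invisibly.
#' @export
write_restraint_map <- function(map, path) {
  write_npy(map$matrix, path)
  jsonlite::write_json(
    list(chain_order = map$chain_order,
         chain_lengths = map$chain_lengths,
         chain_offsets = as.integer(map$chain_offsets)),
    paste0(path, ".json"), auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Minimal NPY writer / reader for numeric matrices
#'
#' NumPy binary format version 1.0, dtype `<f8`, C (row-major) order.
#'
#' @param m Numeric matrix.
#' @param path File path.
#' @return `write_npy`: `path`, invisibly. `read_npy`: a numeric matrix.
#' @export
write_npy <- function(m, path) {
  m <- as.matrix(m)
  dict <- sprintf("{'descr': '<f8', 'fortran_order': False, 'shape': (%d, %d), }",
                  nrow(m), ncol(m))
  pad <- (64L - (10L + nchar(dict) + 1L) %% 64L) %% 64L
  dict <- paste0(dict, strrep(" ", pad), "\n")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, utf8ToInt("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(dict)), con, size = 2, endian = "little")
  writeChar(dict, con, eos = NULL)
  writeBin(as.vector(t(m)), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_npy
#' @export
read_npy <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8)
  if (!identical(magic[1:6], as.raw(c(0x93, utf8ToInt("NUMPY")))))
    stop("not an NPY file: ", path)
  hlen <- readBin(con, "integer", 1, size = 2, endian = "little",
                  signed = FALSE)
  hdr <- rawToChar(readBin(con, "raw", hlen))
  shape <- regmatches(hdr, regexpr("\\(([0-9, ]+)\\)", hdr))
  dims <- as.integer(strsplit(gsub("[() ]", "", shape), ",")[[1]])
  if (!grepl("'<f8'", hdr) || grepl("True", hdr))
    stop("unsupported NPY dtype/order in ", path)
  v <- readBin(con, "double", prod(dims), size = 8, endian = "little")
  if (length(dims) == 1L) return(v)
  matrix(v, nrow = dims[1], ncol = dims[2], byrow = TRUE)
}
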