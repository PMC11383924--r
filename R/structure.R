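#' Protein structure container
#'
#' An `xl_structure` holds a hierarchical chain/residue/atom model as a flat
#' atom table (bio3d style): one row per atom with chain id, author residue
#' number, 3-letter residue name, atom name, element symbol and Cartesian
#' coordinates in Angstrom. Chains keep their file order; residue numbers are
#' author numbers (1-based, gaps permitted) and must be strictly increasing
#' within a chain. Residues lacking a CA atom are retained but flagged
#' incomplete and excluded from all geometric computations.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resid`, `elety`
#'   (atom name), `element`, `x`, `y`, `z`.
#' @return An object of class `xl_structure`.
#' @export
xl_structure <- function(atoms) {
  need <- c("chain", "resno", "resid", "elety", "element", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms)[need]
  atoms$chain   <- as.character(atoms$chain)
  atoms$resno   <- as.integer(atoms$resno)
  atoms$resid   <- as.character(atoms$resid)
  atoms$elety   <- as.character(atoms$elety)
  atoms$element <- toupper(as.character(atoms$element))
  if (nrow(atoms) == 0L)
    stop("empty structure: no protein atoms")
  for (ch in unique(atoms$chain)) {
    rn <- unique(atoms$resno[atoms$chain == ch])
    if (any(diff(rn) <= 0L))
      stop("residue numbers not strictly increasing in chain ", ch)
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "xl_structure")
}

#' @export
print.xl_structure <- function(x, ...) {
  ch <- chain_ids(x)
  n  <- vapply(ch, function(c) chain_length(x, c), integer(1))
  cat("xl_structure: ", length(ch), " chain(s), ",
      sum(n), " residues, ", nrow(x$atoms), " atoms\n", sep = "")
  cat(paste0("  ", ch, ": ", n, " residues"), sep = "\n")
  invisible(x)
}

#' Chain identifiers in declared (file) order
#' @param s An `xl_structure`.
#' @return Character vector of chain ids.
#' @export
chain_ids <- function(s) unique(s$atoms$chain)

#' Residue table of one chain
#'
#' @param s An `xl_structure`.
#' @param chain Chain id.
#' @return data.frame with `resno`, `resid`, `has_ca` in chain order.
#' @export
chain_residues <- function(s, chain) {
  a <- s$atoms[s$atoms$chain == chain, , drop = FALSE]
  if (nrow(a) == 0L) stop("unknown chain: ", chain)
  rn <- unique(a$resno)
  data.frame(
    resno  = rn,
    resid  = a$resid[match(rn, a$resno)],
    has_ca = rn %in% a$resno[a$elety == "CA"],
    stringsAsFactors = FALSE
  )
}

#' Number of residues in a chain
#' @inheritParams chain_residues
#' @export
chain_length <- function(s, chain) nrow(chain_residues(s, chain))

#' One-letter amino-acid sequence of a chain
#'
#' Unknown 3-letter codes map to `X`.
#' @inheritParams chain_residues
#' @return Single string.
#' @export
chain_sequence <- function(s, chain) {
  r   <- chain_residues(s, chain)
  one <- suppressWarnings(bio3d::aa321(r$resid))
  one[is.na(one)] <- "X"
  paste(one, collapse = "")
}

#' Reference to a single residue
#'
#' @param chain Chain id.
#' @param resno Author residue number.
#' @return An object of class `xl_residue_ref`.
#' @export
residue_ref <- function(chain, resno) {
  structure(list(chain = as.character(chain), resno = as.integer(resno)),
            class = "xl_residue_ref")
}

# Resolve a residue reference to its atom rows; errors if absent.
resolve_residue <- function(s, ref) {
  idx <- which(s$atoms$chain == ref$chain & s$atoms$resno == ref$resno)
  if (length(idx) == 0L)
    stop("residue ", ref$chain, ":", ref$resno, " not found in structure")
  s$atoms[idx, , drop = FALSE]
}

#' CA coordinate matrix of a chain
#'
#' n x 3 matrix of CA coordinates in chain order, rows named by author
#' residue number. Residues without a CA atom are skipped.
#' @inheritParams chain_residues
#' @return Numeric matrix with one row per CA-bearing residue.
#' @export
ca_matrix <- function(s, chain) {
  a <- s$atoms[s$atoms$chain == chain & s$atoms$elety == "CA", , drop = FALSE]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- a$resno
  m
}

water_resids <- c("HOH", "WAT", "DOD", "H2O")

#' Read a protein structure from PDB or mmCIF
#'
#' Parsing is delegated to \pkg{bio3d}. Only standard-polymer `ATOM` records
#' are kept: HETATM entries and waters are discarded. Alternate locations are
#' resolved deterministically to the highest-occupancy conformer, ties broken
#' by altloc letter order.
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @param format One of `"auto"` (by extension), `"pdb"`, `"mmcif"`.
#' @return An `xl_structure`.
#' @export
load_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "mmcif") bio3d::read.cif(path, verbose = FALSE,
                                           rm.alt = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e))
  )
  at <- pdb$atom
  at <- at[at$type == "ATOM" & !(at$resid %in% water_resids), , drop = FALSE]
  if (nrow(at) == 0L)
    stop("empty structure: ", path, " contains no protein ATOM records")
  # altloc resolution: highest occupancy, ties by altloc letter
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  key <- paste(at$chain, at$resno, at$elety, sep = "\r")
  ord <- order(key, -at$o, at$alt)
  at  <- at[ord, , drop = FALSE]
  at  <- at[!duplicated(key[ord]), , drop = FALSE]
  at  <- at[order(match(at$chain, unique(pdb$atom$chain)), at$resno, at$eleno), ,
            drop = FALSE]
  el <- toupper(at$elesy)
  bad <- is.na(el) | el == ""
  if (any(bad)) el[bad] <- toupper(substr(gsub("[0-9]", "", at$elety[bad]), 1, 1))
  xl_structure(data.frame(
    chain = at$chain, resno = at$resno, resid = at$resid,
    elety = at$elety, element = el,
    x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE
  ))
}

#' Write a structure to PDB or mmCIF
#'
#' The PDB writer emits fixed-width wwPDB v3.3 columns with occupancy 1.00
#' and B-factor 0.00; the mmCIF writer emits a minimal `_atom_site` loop.
#' Both round-trip through [load_structure()] at PDB coordinate precision
#' (1e-3 Angstrom).
#'
#' @param s An `xl_structure`.
#' @param path Output path.
#' @param format One of `"auto"` (by extension), `"pdb"`, `"mmcif"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  a <- s$atoms
  if (format == "pdb") {
    name4 <- ifelse(nchar(a$elety) < 4L, paste0(" ", a$elety), a$elety)
    name4 <- formatC(name4, width = -4)
    lines <- sprintf(
      "ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(a)), name4, a$resid, a$chain, a$resno,
      a$x, a$y, a$z, 1, 0, a$element)
    writeLines(c(lines, "END"), path)
  } else {
    hdr <- c("data_xlcomplex", "#", "loop_",
             paste0("_atom_site.",
                    c("group_PDB", "id", "type_symbol", "label_atom_id",
                      "label_alt_id", "label_comp_id", "label_asym_id",
                      "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                      "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                      "B_iso_or_equiv", "auth_seq_id", "auth_comp_id",
                      "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num")))
    rows <- sprintf(
      "ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 %d %s %s %s 1",
      seq_len(nrow(a)), a$element, a$elety, a$resid, a$chain, a$resno,
      a$x, a$y, a$z, a$resno, a$resid, a$chain, a$elety)
    writeLines(c(hdr, rows, "#"), path)
  }
  invisible(path)
}
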