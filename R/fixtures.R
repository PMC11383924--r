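# Ideal alpha-helix atom placement: radius (A), phase offset (deg) and
# axial offset (A) relative to the CA trace (rise 1.5 A, twist 100 deg per
# residue). Fixtures are geometric, not energetic: CB is a proxy so
# heavy-atom contact definitions are non-degenerate without side chains.
helix_atom_params <- data.frame(
  elety   = c("N",  "CA", "C",  "O",  "CB"),
  element = c("N",  "C",  "C",  "O",  "C"),
  radius  = c(1.60, 2.30, 2.00, 2.00, 3.30),
  phase   = c(-28,  0,    26,   30,   -8),
  dz      = c(-0.90, 0,   0.55, 1.70, -0.60),
  stringsAsFactors = FALSE)

helix_rise  <- 1.5   # A per residue
helix_twist <- 100   # degrees per residue

#' Ideal alpha-helix fixture
#'
#' Builds a deterministic ideal-geometry helix along the z axis (rise 1.5
#' Angstrom and twist 100 degrees per residue, CA radius 2.3 Angstrom) with
#' N, CA, C, O atoms and a CB proxy for every non-Gly residue.
#'
#' @param sequence One-letter amino-acid sequence.
#' @param chain_id Chain id for the output chain.
#' @param resno_start First author residue number.
#' @return An `xl_structure`.
#' @export
make_ideal_helix <- function(sequence, chain_id = "A", resno_start = 1L) {
  aa1 <- strsplit(toupper(sequence), "")[[1]]
  aa3 <- suppressWarnings(bio3d::aa123(aa1))
  aa3[is.na(aa3) | aa3 == "NA"] <- "UNK"
  rows <- lapply(seq_along(aa1), function(i) {
    p <- helix_atom_params
    if (aa1[i] == "G") p <- p[p$elety != "CB", ]
    ang <- ((i - 1) * helix_twist + p$phase) * pi / 180
    data.frame(chain = chain_id, resno = resno_start + i - 1L,
               resid = aa3[i], elety = p$elety, element = p$element,
               x = p$radius * cos(ang), y = p$radius * sin(ang),
               z = (i - 1) * helix_rise + p$dz,
               stringsAsFactors = FALSE)
  })
  xl_structure(do.call(rbind, rows))
}

#' Two-chain complex fixture
#'
#' Chain A is an ideal helix at the origin; chain B is an ideal helix under
#' a rigid transform (rotation about an axis through the origin, then
#' translation). Used as a synthetic "native" complex; geometry may clash —
#' fixtures need not be physical.
#'
#' @param seq_a,seq_b One-letter sequences of the two chains.
#' @param angle Rotation of chain B in degrees.
#' @param axis Rotation axis (length-3).
#' @param translation Translation of chain B in Angstrom (length-3); the
#'   default places two parallel helices close enough for a 5 Angstrom
#'   heavy-atom interface.
#' @param chain_ids Ids for the two chains.
#' @return An `xl_structure` with two chains.
#' @export
make_two_chain_complex <- function(seq_a, seq_b, angle = 0,
                                   axis = c(0, 0, 1),
                                   translation = c(10, 0, 0),
                                   chain_ids = c("A", "B")) {
  a <- make_ideal_helix(seq_a, chain_id = chain_ids[1])
  b <- make_ideal_helix(seq_b, chain_id = chain_ids[2])
  tf <- list(rotation = rotation_matrix(angle, axis),
             translation = translation)
  b$atoms[, c("x", "y", "z")] <-
    apply_transform(as.matrix(b$atoms[, c("x", "y", "z")]), tf)
  xl_structure(rbind(a$atoms, b$atoms))
}

#' Decoy-model ladder fixture
#'
#' Generates candidate models of a two-chain native with increasing
#' interface deviation: at each step the last chain (the "ligand") is
#' rotated about the z axis through its centroid and translated along +x,
#' optionally with per-atom Gaussian coordinate noise. Ladder index tracks
#' expected DockQ ordering (step 0/0 reproduces the native).
#'
#' @param native A two-chain `xl_structure`.
#' @param steps data.frame (or list of length-2 vectors) with per-model
#'   `rotation` (degrees) and `translation` (Angstrom).
#' @param noise_sd Per-atom Gaussian sigma in Angstrom (0 disables).
#' @param seed Seed for the noise.
#' @return List of `xl_structure` models, one per step.
#' @export
make_decoy_ladder <- function(native, steps, noise_sd = 0, seed = 1L) {
  if (!is.data.frame(steps))
    steps <- as.data.frame(do.call(rbind, steps)) |>
      stats::setNames(c("rotation", "translation"))
  ch <- chain_ids(native)
  lig <- ch[length(ch)]
  with_seed(seed, lapply(seq_len(nrow(steps)), function(k) {
    m <- native
    sel <- m$atoms$chain == lig
    xyz <- as.matrix(m$atoms[sel, c("x", "y", "z")])
    ctr <- colMeans(xyz)
    R <- rotation_matrix(steps$rotation[k], c(0, 0, 1))
    xyz <- sweep(sweep(xyz, 2, ctr) %*% t(R), 2, ctr, "+")
    xyz[, 1] <- xyz[, 1] + steps$translation[k]
    if (noise_sd > 0)
      xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = noise_sd),
                          ncol = 3)
    m$atoms[sel, c("x", "y", "z")] <- xyz
    m
  }))
}

#' Deterministic fixture sequence
#'
#' Repeats a 10-residue motif containing the SDA-reactive types (K, S, T,
#' Y) and tryptic cleavage sites (K, R), truncated to the requested length.
#'
#' @param n Sequence length in residues.
#' @param motif Repeating unit.
#' @return One-letter string of length `n`.
#' @export
fixture_sequence <- function(n, motif = "AKSTYELGIR") {
  substr(strrep(motif, ceiling(n / nchar(motif))), 1, n)
}
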