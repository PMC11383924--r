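# Van der Waals radii (Angstrom) for common protein elements (Bondi set).
vdw_radii <- c(H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52,
               S = 1.80, P = 1.80, SE = 1.90)
vdw_default <- 1.8

# Tien et al. (2013) theoretical maximal accessible surface areas (Gly-X-Gly)
# used to normalise per-residue SASA to relative SASA.
max_asa_gxg <- c(
  ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
  GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
  LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
  SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)

# Deterministic golden-spiral unit sphere points (n x 3).
golden_spiral_points <- function(n) {
  i   <- seq_len(n) - 0.5
  z   <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r   <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Estimates per-atom SASA by placing a deterministic golden-spiral point set
#' on each atom's solvent-expanded sphere (van der Waals radius plus probe)
#' and counting points not buried inside any neighbouring sphere. Atom areas
#' are summed per residue and normalised by Gly-X-Gly theoretical maxima to
#' give relative SASA; residues at or above `rel_cutoff` form the surface
#' set. Results are reproducible bit-for-bit for a fixed `n_points`.
#'
#' @param s An `xl_structure` with element assignments.
#' @param probe_radius Solvent probe radius in Angstrom (water: 1.4).
#' @param n_points Sphere sampling points per atom.
#' @param rel_cutoff Relative-SASA threshold defining surface residues.
#' @return An `xl_sasa`: list with `atoms` (per-atom areas, Angstrom^2),
#'   `residues` (data.frame `chain`, `resno`, `resid`, `sasa`, `rel_sasa`)
#'   and `surface` (data.frame `chain`, `resno`).
#' @export
shrake_rupley <- function(s, probe_radius = 1.4, n_points = 960L,
                          rel_cutoff = 0.25) {
  a   <- s$atoms
  n   <- nrow(a)
  el  <- a$element
  unknown <- setdiff(unique(el), names(vdw_radii))
  if (length(unknown))
    warning("unknown element(s) ", paste(unknown, collapse = ", "),
            "; using van der Waals radius ", vdw_default, " A")
  rad <- unname(vdw_radii[el])
  rad[is.na(rad)] <- vdw_default
  ext <- rad + probe_radius
  xyz <- as.matrix(a[, c("x", "y", "z")])
  pts <- golden_spiral_points(n_points)

  # pairwise neighbour lists within touching distance of expanded spheres
  d2 <- as.matrix(stats::dist(xyz))^2
  touch <- outer(ext, ext, "+")^2
  area <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < touch[i, ] & seq_len(n) != i)
    p  <- sweep(pts * ext[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
            (p[, 3] - xyz[j, 3])^2
      acc <- acc & (dj > ext[j]^2)
      if (!any(acc)) break
    }
    area[i] <- sum(acc) / n_points * 4 * pi * ext[i]^2
  }

  key <- paste(a$chain, a$resno, sep = "\r")
  res_sasa <- tapply(area, key, sum)
  first <- !duplicated(key)
  res <- data.frame(chain = a$chain[first], resno = a$resno[first],
                    resid = a$resid[first], stringsAsFactors = FALSE)
  res$sasa <- as.numeric(res_sasa[paste(res$chain, res$resno, sep = "\r")])
  ref <- max_asa_gxg[res$resid]
  ref[is.na(ref)] <- stats::median(max_asa_gxg)
  res$rel_sasa <- res$sasa / unname(ref)
  res <- res[order(match(res$chain, chain_ids(s)), res$resno), ]
  rownames(res) <- NULL
  surf <- res[res$rel_sasa >= rel_cutoff, c("chain", "resno")]
  rownames(surf) <- NULL
  structure(list(atoms = area, residues = res, surface = surf,
                 probe_radius = probe_radius, n_points = n_points,
                 rel_cutoff = rel_cutoff),
            class = "xl_sasa")
}

#' @export
print.xl_sasa <- function(x, ...) {
  cat("xl_sasa: ", nrow(x$residues), " residues, ",
      nrow(x$surface), " on surface (rel SASA >= ",
      x$rel_cutoff, ")\n", sep = "")
  invisible(x)
}
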