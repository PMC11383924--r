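#' Distance between two CA atoms
#'
#' Euclidean distance in Angstrom between the CA atoms of two residues,
#' the metric against which crosslinker-specific bounds (e.g. 25 Angstrom
#' for sulfo-SDA) are applied.
#'
#' @param s An `xl_structure`.
#' @param a,b `xl_residue_ref` objects (see [residue_ref()]).
#' @return Distance in Angstrom.
#' @export
ca_distance <- function(s, a, b) {
  ca <- function(ref) {
    at <- resolve_residue(s, ref)
    at <- at[at$elety == "CA", , drop = FALSE]
    if (nrow(at) == 0L)
      stop("residue ", ref$chain, ":", ref$resno, " has no CA atom")
    c(at$x[1], at$y[1], at$z[1])
  }
  sqrt(sum((ca(a) - ca(b))^2))
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of one point set onto another via singular
#' value decomposition of the cross-covariance matrix, constrained to a
#' proper rotation (det = +1, no reflection).
#'
#' @param mobile,target Numeric n x 3 matrices of matched points (n >= 3,
#'   non-collinear).
#' @return List with `rotation` (3 x 3), `translation` (length 3) and
#'   `rmsd` (Angstrom). The fitted points are
#'   `mobile \%*\% t(rotation) + translation` (see [apply_transform()]).
#' @export
superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!identical(dim(mobile), dim(target)))
    stop("point sets differ in size: ", nrow(mobile), " vs ", nrow(target))
  n <- nrow(mobile)
  if (n < 3L) stop("superposition needs at least 3 points, got ", n)
  cm <- colMeans(mobile); ct <- colMeans(target)
  X <- sweep(mobile, 2, cm); Y <- sweep(target, 2, ct)
  if (qr(X)$rank < 2L || qr(Y)$rank < 2L)
    stop("degenerate point set (collinear or coincident points)")
  sv <- svd(crossprod(X, Y))     # X^T Y = U D V^T
  d  <- sign(det(sv$v %*% t(sv$u)))
  R  <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- ct - as.vector(R %*% cm)
  fit <- sweep(mobile %*% t(R), 2, tr, "+")
  list(rotation = R, translation = tr,
       rmsd = sqrt(mean(rowSums((fit - target)^2))))
}

#' Apply a rigid transform to coordinates
#'
#' @param xyz Numeric n x 3 matrix.
#' @param transform List with `rotation` and `translation` as returned by
#'   [superpose()].
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, transform) {
  sweep(as.matrix(xyz) %*% t(transform$rotation), 2,
        transform$translation, "+")
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues' formula for a rotation of `angle` degrees about `axis`.
#'
#' @param angle Rotation angle in degrees.
#' @param axis Length-3 axis vector (normalised internally).
#' @return 3 x 3 rotation matrix.
#' @export
rotation_matrix <- function(angle, axis = c(0, 0, 1)) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
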