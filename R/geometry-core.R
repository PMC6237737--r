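## Elementary vector geometry shared by the torsion, pairing, helix and
## trajectory code. Coordinates are plain numeric xyz triples in angstrom.

.vnorm <- function(v) sqrt(sum(v^2))
.vunit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("cannot normalize a near-zero vector")
  v / n
}
.vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Torsion angle of four points
#'
#' Dihedral about the p2-p3 axis in degrees on `(-180, 180]`, IUPAC sign
#' convention (positive clockwise looking from p2 towards p3).
#'
#' @param p1,p2,p3,p4 Numeric xyz triples (angstrom).
#' @return Angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .vcross(b1, b2)
  n2 <- .vcross(b2, b3)
  if (.vnorm(n1) < 1e-9 || .vnorm(n2) < 1e-9)
    stop("undefined torsion: three of the four points are collinear")
  x <- sum(n1 * n2)
  y <- sum(.vcross(n1, n2) * .vunit(b2))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Bond angle of three points
#'
#' @param p1,p2,p3 Numeric xyz triples; the angle is at `p2`.
#' @return Angle in degrees on `[0, 180]`.
#' @export
bond_angle <- function(p1, p2, p3) {
  u <- .vunit(p1 - p2)
  v <- .vunit(p3 - p2)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

## Place a new atom at distance r from c, bond angle theta (deg) at c with
## respect to b, and torsion phi (deg) about the b-c axis with respect to a
## (standard NeRF internal-to-cartesian step).
.nerf_place <- function(a, b, c, r, theta, phi) {
  th <- theta * pi / 180
  ph <- phi * pi / 180
  bc <- .vunit(c - b)
  n <- .vunit(.vcross(b - a, bc))
  m <- .vcross(n, bc)
  d <- c(-r * cos(th), r * sin(th) * cos(ph), r * sin(th) * sin(ph))
  c + d[1] * bc + d[2] * m + d[3] * n
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation `Rmat` and translation minimizing the RMSD of
#' `Rmat %*% x + t` onto `y` over paired rows. Reflections are excluded:
#' degenerate cases resolve to determinant +1.
#'
#' @param x,y Numeric matrices, n x 3, corresponding rows paired.
#' @param weights Optional non-negative row weights.
#' @return List with `rotation` (3x3), `translation` (length 3), `rmsd`,
#'   and `transform(p)` applying the fit to an n x 3 matrix.
#' @export
superpose <- function(x, y, weights = NULL) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  stopifnot(ncol(x) == 3, ncol(y) == 3, nrow(x) == nrow(y), nrow(x) >= 3)
  w <- weights %||% rep(1, nrow(x))
  w <- w / sum(w)
  cx <- colSums(x * w)
  cy <- colSums(y * w)
  xc <- sweep(x, 2, cx)
  yc <- sweep(y, 2, cy)
  H <- t(xc * w) %*% yc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  Rm <- sv$v %*% D %*% t(sv$u)
  tr <- cy - as.numeric(Rm %*% cx)
  xfit <- t(Rm %*% t(x)) + matrix(tr, nrow(x), 3, byrow = TRUE)
  rmsd <- sqrt(sum(w * rowSums((xfit - y)^2)))
  list(rotation = Rm, translation = tr, rmsd = rmsd,
       transform = function(p) {
         p <- as.matrix(p)
         t(Rm %*% t(p)) + matrix(tr, nrow(p), 3, byrow = TRUE)
       })
}

#' Heavy-atom RMSD after optimal superposition
#'
#' @param x,y n x 3 coordinate matrices with paired rows.
#' @return RMSD in angstrom.
#' @export
rmsd_superposed <- function(x, y) superpose(x, y)$rmsd

## Rotation matrix about an arbitrary unit axis (degrees).
.rot_axis <- function(axis, angle_deg) {
  u <- .vunit(axis)
  a <- angle_deg * pi / 180
  ca <- cos(a)
  sa <- sin(a)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(ca + ux^2 * (1 - ca), ux * uy * (1 - ca) - uz * sa, ux * uz * (1 - ca) + uy * sa,
           uy * ux * (1 - ca) + uz * sa, ca + uy^2 * (1 - ca), uy * uz * (1 - ca) - ux * sa,
           uz * ux * (1 - ca) - uy * sa, uz * uy * (1 - ca) + ux * sa, ca + uz^2 * (1 - ca)),
         3, 3, byrow = TRUE)
}

.rot_z <- function(angle_deg) .rot_axis(c(0, 0, 1), angle_deg)
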