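# 3-D vector helpers -----------------------------------------------------

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-10) stop("cannot normalise a zero-length vector", call. = FALSE)
  a / n
}

#' Wrap angles onto the (-180, 180] degree domain
#'
#' All torsions in the package live on `(-180, 180]`; in particular a raw
#' value of -180 maps to +180 so that the fully extended conformation is
#' reported as (180, 180).
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector wrapped onto `(-180, 180]`.
#' @export
wrap_angle <- function(x) {
  w <- ((x + 180) %% 360) - 180
  w[!is.na(w) & w == -180] <- 180
  w
}

#' Smallest circular difference between two angles
#'
#' @param a,b angles in degrees.
#' @return absolute angular difference in `[0, 180]`.
#' @export
angle_diff <- function(a, b) {
  d <- abs(((a - b + 180) %% 360) - 180)
  d
}

#' Bond angle defined by three points
#'
#' @param p1,p2,p3 numeric xyz coordinates; the angle is taken at `p2`.
#' @return angle in degrees in `[0, 180]`.
#' @export
bond_angle <- function(p1, p2, p3) {
  u <- vunit(p1 - p2)
  v <- vunit(p3 - p2)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

#' Torsion angle defined by four points
#'
#' Computes the dihedral about the `p2`-`p3` axis with the IUPAC sign
#' convention (right-handed; the cis arrangement is 0, trans is 180).
#'
#' @param p1,p2,p3,p4 numeric xyz coordinates (angstroms).
#' @return angle in degrees on `(-180, 180]`.
#' @export
#' @examples
#' # trans (planar zig-zag) arrangement
#' dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-8 || vnorm(n2) < 1e-8) {
    stop("degenerate geometry: three consecutive points are collinear",
         call. = FALSE)
  }
  ang <- atan2(sum(vcross(n1, n2) * b2) / vnorm(b2),
               sum(n1 * n2)) * 180 / pi
  wrap_angle(ang)
}

# Internal-coordinate (NeRF-style) placement ------------------------------

# Place atom D bonded to C, with bond length `bond`, angle B-C-D `theta`
# (degrees) and torsion A-B-C-D `tau` (degrees).
place_atom <- function(a, b, c_, bond, theta, tau) {
  th <- theta * pi / 180
  ta <- tau * pi / 180
  bc <- vunit(c_ - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- c(-bond * cos(th),
          bond * sin(th) * cos(ta),
          bond * sin(th) * sin(ta))
  c_ + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Rotation matrix from a rotation vector (axis * angle in radians).
rotation_matrix <- function(rv) {
  th <- sqrt(sum(rv^2))
  if (th < 1e-12) return(diag(3))
  k <- rv / th
  K <- matrix(c(0, -k[3], k[2],
                k[3], 0, -k[1],
                -k[2], k[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Least-squares rigid superposition (Kabsch). Returns a function mapping
# coordinates from the `from` frame into the `to` frame.
kabsch_transform <- function(from, to) {
  cf <- colMeans(from)
  ct <- colMeans(to)
  A <- t(sweep(from, 2, cf)) %*% sweep(to, 2, ct)
  s <- svd(A)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  function(x) {
    x <- if (is.matrix(x)) x else matrix(x, ncol = 3)
    sweep(sweep(x, 2, cf) %*% t(R), 2, ct, "+")
  }
}
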