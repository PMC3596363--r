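# Independent oracles and shared fixtures for the test suite.

# Brute-force torsion via the two-plane-normal definition: magnitude from
# the normals' angle, sign from the scalar triple product.
oracle_dihedral <- function(p1, p2, p3, p4) {
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(max(-1, min(1, cosang))) * 180 / pi
  s <- sum(cr(n1, n2) * b2)
  out <- if (s < 0) -ang else ang
  if (out <= -180) out + 360 else out
}

# Direct arithmetic evaluation of the four-term Coulomb sum.
oracle_coulomb <- function(q_s, q_o, q_h, q_x, r_sh, r_sx, r_oh, r_ox) {
  332 * (q_s * q_h / r_sh + q_s * q_x / r_sx +
           q_o * q_h / r_oh + q_o * q_x / r_ox)
}

# Independent canonical-pattern definition, evaluated on a list of
# per-oxygen donor sets: exactly two non-empty oxygens, one containing
# both Calpha_m1 and N_0, the other exactly {N_p1}.
oracle_canonical <- function(sets) {
  nonempty <- Filter(length, sets)
  if (length(nonempty) != 2) return(FALSE)
  a <- nonempty[[1]]; b <- nonempty[[2]]
  ok <- function(br, so) {
    all(c("Calpha_m1", "N_0") %in% br) && setequal(so, "N_p1")
  }
  ok(a, b) || ok(b, a)
}

# Build an N-H ... O probe geometry with exact H-O distance and X-H-O
# angle (degrees), in the xy-plane.
hbond_probe <- function(d_ho, angle, d_xh = 1.01) {
  x <- c(0, 0, 0)
  h <- c(d_xh, 0, 0)
  th <- angle * pi / 180
  o <- h + d_ho * c(cos(pi - th), sin(pi - th), 0)
  list(x = x, h = h, o = o)
}

# A random rigid motion as a coordinate-mapping function.
random_rigid_motion <- function() {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  tr <- stats::rnorm(3, 0, 5)
  function(v) as.numeric(R %*% v + tr)
}
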