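# Low-level vector geometry shared by the structure, filter and design code.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Angle at `b` formed by points `a`-`b`-`c`
#' @param a,b,c numeric 3-vectors (Angstrom)
#' @return angle in degrees in [0, 180]
#' @keywords internal
point_angle <- function(a, b, c) {
  u <- unitv(a - b)
  v <- unitv(c - b)
  acos(pmin(1, pmax(-1, sum(u * v)))) * 180 / pi
}

#' Signed dihedral angle defined by four points
#'
#' IUPAC convention: looking down the `p2`-`p3` axis, the angle from the
#' `p1` branch to the `p4` branch, positive clockwise, in (-180, 180].
#' @param p1,p2,p3,p4 numeric 3-vectors
#' @return dihedral in degrees
#' @keywords internal
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unitv(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Place an atom from internal coordinates (natural extension reference frame)
#'
#' Returns the position `d` such that |c-d| = `bond`, the angle b-c-d equals
#' `angle` and the dihedral a-b-c-d equals `torsion`.
#' @param a,b,c numeric 3-vectors of the three preceding atoms
#' @param bond bond length (Angstrom); `angle`, `torsion` in degrees
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- unitv(c - b)
  n <- unitv(vcross(b - a, bc))
  m <- vcross(n, bc)
  d <- c(-bond * cos(ang),
         bond * sin(ang) * cos(tor),
         -bond * sin(ang) * sin(tor))
  c + d[1] * bc + d[2] * m + d[3] * n
}

# Ideal C-beta from backbone N/CA/C (tetrahedral L-amino-acid geometry).
ideal_cb <- function(n, ca, c) {
  place_atom(c, n, ca, bond = 1.521, angle = 110.4, torsion = 122.55)
}

#' Quasi-uniform unit sphere points (golden-spiral / Fibonacci lattice)
#' @param n number of points (>= 1)
#' @return an n x 3 matrix of unit vectors; deterministic
#' @keywords internal
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Rotation matrix about an arbitrary axis
#' @param axis numeric 3-vector (need not be unit)
#' @param theta angle in radians
#' @keywords internal
rotation_matrix <- function(axis, theta) {
  u <- unitv(axis)
  ct <- cos(theta); st <- sin(theta)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct),      ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),      uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}

# Apply a rigid transform to an N x 3 coordinate matrix.
rigid_transform <- function(coords, rot = diag(3), trans = c(0, 0, 0)) {
  sweep(coords %*% t(rot), 2, -trans, "-")
}

# Evaluate code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}
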