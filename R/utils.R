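#' @keywords internal
"_PACKAGE"

# Deterministic fan-out of a single user seed into named component seeds.
# Keeps every derived seed in [0, 2^31 - 2] so it is a valid R integer seed.
derive_seed <- function(seed, what, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(what)) * seq_along(utf8ToInt(as.character(what))))
  x <- (as.double(seed) * 48271 + h * 8191 + as.double(index) * 131071) %% 2147483647
  as.integer(x)
}

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v, eps = 1e-12) {
  n <- vnorm(v)
  if (n < eps) return(rep(0, length(v)))
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Dihedral angle of four points
#'
#' Signed torsion angle (radians, in (-pi, pi]) defined by atoms p1-p2-p3-p4,
#' using the standard atan2 formulation. Returns NA for degenerate
#' (collinear) configurations.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors (Angstrom).
#' @return numeric scalar angle in radians, or NA if undefined.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-8 || vnorm(n2) < 1e-8) return(NA_real_)
  # IUPAC sign convention (matches bio3d::torsion.xyz)
  y <- sum(cross3(n1, n2) * unit(b2))
  atan2(y, sum(n1 * n2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
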