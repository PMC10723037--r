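# Attributed k-NN residue graph: local frames, SE(3)-invariant spatial edge
# features (RBF distance + direction + quaternion orientation) and sinusoidal
# sequence-gap encodings.

#' Directed k-nearest-neighbour edges over C-alpha coordinates
#'
#' For each node i, edges i -> j from its k nearest other nodes by Euclidean
#' distance (all others when n - 1 < k) plus the self-loop i -> i. Ties are
#' broken by the smaller residue index; output is deterministic. Edges are
#' grouped by target node, self-loop first, then neighbours by increasing
#' distance, so every node owns a contiguous block of min(k, n-1) + 1 edges.
#'
#' @param X n x 3 coordinate matrix.
#' @param k neighbour count (default 30).
#' @return list with integer vectors `target`, `source`, scalar `deg`
#'   (edges per node) and `k_eff`.
#' @export
build_knn_edges <- function(X, k = 30L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 residues to build a graph")
  if (!all(is.finite(X))) stop("non-finite coordinates")
  if (k < 1L) stop("k must be positive")
  k_eff <- min(as.integer(k), n - 1L)
  # distances are rounded to 1e-6 A before sorting so that the
  # smaller-index tie-break is stable under rigid-body transforms
  D <- round(as.matrix(stats::dist(X)), 6)
  target <- integer(0); source <- integer(0)
  nb <- matrix(0L, n, k_eff)
  for (i in seq_len(n)) {
    ord <- order(D[i, -i], (seq_len(n))[-i])
    nb[i, ] <- ((seq_len(n))[-i])[ord][seq_len(k_eff)]
  }
  deg <- k_eff + 1L
  target <- rep(seq_len(n), each = deg)
  source <- as.integer(t(cbind(seq_len(n), nb)))
  list(target = target, source = source, deg = deg, k_eff = k_eff)
}

#' Per-residue local reference frames
#'
#' Builds a right-handed orthonormal basis O_i = \[b_i, n_i, b_i x n_i\]
#' from adjacent C-alpha directions: v_i = unit(x_i - x_(i-1)),
#' b_i = unit(v_i - v_(i+1)) (the negative bisector of the backbone angle),
#' n_i = unit(v_i x v_(i+1)). Terminal residues copy the frame of the
#' nearest interior residue; collinear interior triples fall back to the
#' nearest valid interior frame with a warning.
#'
#' @param X n x 3 coordinate matrix, n >= 3.
#' @return list with `O` (n x 3 x 3 array; O\[i,,\] has columns b, n, b x n).
#' @export
local_frames <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 residues for local frames")
  O <- array(NA_real_, c(n, 3, 3))
  valid <- rep(FALSE, n)
  for (i in 2:(n - 1)) {
    v_i <- unit(X[i, ] - X[i - 1, ])
    v_n <- unit(X[i + 1, ] - X[i, ])
    cr <- cross3(v_i, v_n)
    if (vnorm(cr) < 1e-8) next  # collinear triple
    b <- unit(v_i - v_n)
    nv <- unit(cr)
    O[i, , ] <- cbind(b, nv, cross3(b, nv))
    valid[i] <- TRUE
  }
  if (!any(valid)) stop("fully collinear chain: no local frame definable")
  if (!all(valid[2:(n - 1)]))
    warning("collinear residue triple(s); copying nearest valid frame")
  vidx <- which(valid)
  for (i in seq_len(n)) {
    if (!valid[i]) O[i, , ] <- O[vidx[which.min(abs(vidx - i))], , ]
  }
  list(O = O)
}

#' Gaussian radial basis encoding of a distance
#'
#' 16 Gaussian bumps with centers equally spaced on \[0, 20\] Angstrom and
#' width sigma equal to the center spacing (20/15 A by default).
#'
#' @param dist non-negative distance(s), Angstrom.
#' @param n_centers number of basis functions (default 16).
#' @param d_min,d_max center range (default 0 to 20 A).
#' @param sigma Gaussian width; defaults to the center spacing.
#' @return length(dist) x n_centers matrix with entries in (0, 1\].
#' @export
rbf_encode <- function(dist, n_centers = 16L, d_min = 0, d_max = 20,
                       sigma = NULL) {
  if (any(!is.finite(dist)) || any(dist < 0)) stop("distances must be finite and >= 0")
  mu <- seq(d_min, d_max, length.out = n_centers)
  if (is.null(sigma)) sigma <- (d_max - d_min) / (n_centers - 1L)
  exp(-outer(dist, mu, "-")^2 / (2 * sigma^2))
}

#' Unit quaternion of a rotation matrix
#'
#' Standard extraction branching on the largest of trace and diagonal
#' elements for numerical stability. The sign is canonicalised so that
#' w >= 0 (if w == 0, the first nonzero component is positive), making the
#' representation a single-valued function of the rotation.
#'
#' @param R 3 x 3 rotation matrix (orthonormal, det +1 within 1e-4).
#' @return numeric (w, x, y, z) with unit norm.
#' @export
quaternion_from_rotation <- function(R) {
  if (max(abs(crossprod(R) - diag(3))) > 1e-4 || abs(det(R) - 1) > 1e-4)
    stop("input is not a proper rotation matrix")
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > max(R[1, 1], R[2, 2], R[3, 3])) {
    s <- 2 * sqrt(tr + 1)
    q <- c(s / 4,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- 2 * sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3])
    q <- c((R[3, 2] - R[2, 3]) / s,
           s / 4,
           (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- 2 * sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3])
    q <- c((R[1, 3] - R[3, 1]) / s,
           (R[1, 2] + R[2, 1]) / s,
           s / 4,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- 2 * sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2])
    q <- c((R[2, 1] - R[1, 2]) / s,
           (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s,
           s / 4)
  }
  q <- q / vnorm(q)
  nz <- which(abs(q) > 1e-12)
  flip <- if (abs(q[1]) > 1e-12) q[1] < 0 else length(nz) && q[nz[1]] < 0
  if (flip) q <- -q
  q
}

rotation_from_quaternion <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Rotation- and translation-invariant spatial edge features
#'
#' For each edge i -> j: 16 RBF components of the C-alpha distance, the
#' direction of x_j relative to frame O_i (unit 3-vector), and the unit
#' quaternion of the relative orientation O_i' O_j. The self-loop is encoded
#' as \[rbf(0), zero direction, identity quaternion\].
#'
#' @param X n x 3 coordinates.
#' @param frames result of [local_frames()].
#' @param edges result of [build_knn_edges()].
#' @return n_edge x 23 matrix.
#' @export
spatial_edge_features <- function(X, frames, edges) {
  X <- as.matrix(X)
  ne <- length(edges$target)
  out <- matrix(0, ne, 23)
  i <- edges$target; j <- edges$source
  dx <- X[j, , drop = FALSE] - X[i, , drop = FALSE]
  dist <- sqrt(rowSums(dx^2))
  loop <- i == j
  if (any(dist[!loop] < 1e-6)) {
    bad <- which(!loop & dist < 1e-6)[1]
    stop("coincident residues on edge ", i[bad], " -> ", j[bad])
  }
  out[, 1:16] <- rbf_encode(dist)
  for (e in which(!loop)) {
    Oi <- frames$O[i[e], , ]
    Oj <- frames$O[j[e], , ]
    out[e, 17:19] <- crossprod(Oi, dx[e, ]) / dist[e]
    out[e, 20:23] <- quaternion_from_rotation(crossprod(Oi, Oj))
  }
  out[loop, 20] <- 1  # identity quaternion on self-loops
  out
}

#' Sinusoidal encoding of the signed sequence gap
#'
#' Standard transformer positional encoding of delta = j - i: pairs
#' (sin(delta / 10000^(2m/dim)), cos(delta / 10000^(2m/dim))) for
#' m = 0 .. dim/2 - 1.
#'
#' @param i,j residue index vectors (equal length).
#' @param dim even encoding dimension >= 2 (default 16).
#' @return length(i) x dim matrix.
#' @export
positional_edge_encoding <- function(i, j, dim = 16L) {
  if (dim %% 2L != 0L || dim < 2L) stop("dim must be even and >= 2")
  delta <- as.numeric(j - i)
  m <- 0:(dim / 2L - 1L)
  freq <- 1 / 10000^(2 * m / dim)
  ang <- outer(delta, freq)
  out <- matrix(0, length(delta), dim)
  out[, seq(1, dim, by = 2)] <- sin(ang)
  out[, seq(2, dim, by = 2)] <- cos(ang)
  out
}

#' Build the full attributed protein graph
#'
#' Combines k-NN edges, local frames, spatial edge features and positional
#' encodings into one graph object ready for the Graph Transformer. Options
#' `complete` (complete graph instead of k-NN) and `zero_spatial` (zero out
#' the 23 spatial components) configure the geometry-agnostic baseline.
#'
#' @param record a [protein_record()].
#' @param node_features `node_features` object ([assemble_node_features()]).
#' @param k neighbour count (default 30).
#' @param pos_dim positional encoding dimension (default 16).
#' @param complete use a complete graph (baseline).
#' @param zero_spatial zero the spatial edge features (baseline).
#' @return object of class `protein_graph`.
#' @export
build_protein_graph <- function(record, node_features, k = 30L, pos_dim = 16L,
                                complete = FALSE, zero_spatial = FALSE) {
  X <- record$ca_coords
  n <- nrow(X)
  if (nrow(node_features$H) != n) stop("node feature rows != residues")
  kk <- if (complete) n - 1L else k
  edges <- build_knn_edges(X, kk)
  frames <- local_frames(X)
  es <- spatial_edge_features(X, frames, edges)
  if (zero_spatial) es[] <- 0
  ep <- positional_edge_encoding(edges$target, edges$source, pos_dim)
  structure(list(
    id = record$id,
    H = node_features$H,
    block_spans = node_features$block_spans,
    coords = X,
    target = edges$target,
    source = edges$source,
    deg = edges$deg,
    k = kk,
    E = cbind(es, ep),
    labels = record$labels,
    cache = new.env(parent = emptyenv())),
    class = "protein_graph")
}

#' @export
print.protein_graph <- function(x, ...) {
  cat("ProteinGraph", x$id, "-", nrow(x$H), "nodes,",
      length(x$target), "directed edges (deg", x$deg, "),",
      ncol(x$H), "node features,", ncol(x$E), "edge features\n")
  invisible(x)
}
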