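# Per-residue node features: min-max normalised embeddings plus the
# 14-dimensional structural group (RSA + 9-state secondary-structure one-hot
# + torsion sin/cos).

#' Fit per-column min-max statistics on training embeddings
#'
#' @param M_list list of n_i x d embedding matrices from the training set.
#' @return list with numeric vectors `x_min`, `x_max` (length d).
#' @export
fit_minmax_stats <- function(M_list) {
  if (is.matrix(M_list)) M_list <- list(M_list)
  M <- do.call(rbind, M_list)
  list(x_min = apply(M, 2, min), x_max = apply(M, 2, max))
}

#' Min-max normalise an embedding matrix
#'
#' Maps each entry to (x - x_min) / (x_max - x_min) using statistics fitted
#' on the training set, clipping values outside the training range to
#' \[0, 1\]. Constant columns (x_max == x_min) map to 0.
#'
#' @param M n x d numeric matrix.
#' @param stats list with `x_min`, `x_max` from [fit_minmax_stats()].
#' @return n x d matrix with entries in \[0, 1\].
#' @export
minmax_normalize <- function(M, stats) {
  M <- as.matrix(M)
  if (ncol(M) != length(stats$x_min) || ncol(M) != length(stats$x_max))
    stop("column count mismatch between matrix (", ncol(M),
         ") and stats (", length(stats$x_min), ")")
  if (any(stats$x_max < stats$x_min)) stop("x_max < x_min in stats")
  rng <- stats$x_max - stats$x_min
  rng_safe <- ifelse(rng == 0, 1, rng)
  out <- sweep(sweep(M, 2, stats$x_min, "-"), 2, rng_safe, "/")
  out[, rng == 0] <- 0
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Backbone torsion angles as sin/cos
#'
#' phi_i is the dihedral C(i-1)-N(i)-CA(i)-C(i); psi_i is
#' N(i)-CA(i)-C(i)-N(i+1). Undefined angles (chain termini, missing atoms,
#' collinear quadruples) are encoded as (0, 0) for the affected pair.
#'
#' @param backbone list with n x 3 matrices `N`, `CA`, `C` (as in a
#'   [protein_record()] backbone slot).
#' @return n x 4 matrix with columns sin(phi), cos(phi), sin(psi), cos(psi).
#' @export
backbone_torsions <- function(backbone) {
  N <- backbone$N; CA <- backbone$CA; C <- backbone$C
  n <- nrow(CA)
  out <- matrix(0, n, 4,
                dimnames = list(NULL, c("sin_phi", "cos_phi", "sin_psi", "cos_psi")))
  ok <- function(p) all(is.finite(p))
  degen <- FALSE
  for (i in seq_len(n)) {
    if (i > 1L && ok(C[i - 1, ]) && ok(N[i, ]) && ok(CA[i, ]) && ok(C[i, ])) {
      phi <- dihedral_angle(C[i - 1, ], N[i, ], CA[i, ], C[i, ])
      if (is.na(phi)) degen <- TRUE else out[i, 1:2] <- c(sin(phi), cos(phi))
    }
    if (i < n && ok(N[i, ]) && ok(CA[i, ]) && ok(C[i, ]) && ok(N[i + 1, ])) {
      psi <- dihedral_angle(N[i, ], CA[i, ], C[i, ], N[i + 1, ])
      if (is.na(psi)) degen <- TRUE else out[i, 3:4] <- c(sin(psi), cos(psi))
    }
  }
  if (degen) warning("degenerate (collinear) torsion quadruple(s) encoded as (0,0)")
  out
}

# Deterministic near-uniform sphere point set (golden-section spiral).
sphere_points <- function(m) {
  i <- seq_len(m) - 0.5
  phi <- acos(1 - 2 * i / m)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Deterministic canonical orientation (principal axes, sign-fixed,
# right-handed). Sphere sampling is done in this frame so that accessible
# surface areas are invariant under rigid-body motion of the input.
canonicalize_coords <- function(X) {
  Xc <- sweep(X, 2, colMeans(X), "-")
  if (nrow(Xc) < 3L) return(round(Xc, 6))
  ev <- eigen(stats::cov(Xc), symmetric = TRUE)
  V <- ev$vectors
  Y <- Xc %*% V
  for (a in 1:3) {
    m <- which.max(abs(Y[, a]))
    if (Y[m, a] < 0) { Y[, a] <- -Y[, a]; V[, a] <- -V[, a] }
  }
  if (det(V) < 0) Y[, 3] <- -Y[, 3]
  round(Y, 6)
}

# Shrake-Rupley accessible surface area per atom.
# atoms: m x 3 coordinates; radii: m vdW radii.
shrake_rupley_asa <- function(atoms, radii, probe = 1.4, n_points = 100L) {
  atoms <- canonicalize_coords(atoms)
  m <- nrow(atoms)
  pts <- sphere_points(n_points)
  r_ext <- radii + probe
  asa <- numeric(m)
  for (a in seq_len(m)) {
    surf <- sweep(pts * r_ext[a], 2, atoms[a, ], "+")
    others <- setdiff(seq_len(m), a)
    if (length(others)) {
      d0 <- sqrt(colSums((t(atoms[others, , drop = FALSE]) - atoms[a, ])^2))
      near <- others[d0 < r_ext[a] + r_ext[others]]
    } else near <- integer(0)
    acc <- rep(TRUE, n_points)
    for (b in near) {
      db <- sqrt(rowSums(sweep(surf, 2, atoms[b, ], "-")^2))
      acc <- acc & (db >= r_ext[b])
      if (!any(acc)) break
    }
    asa[a] <- 4 * pi * r_ext[a]^2 * mean(acc)
  }
  asa
}

#' Relative solvent accessibility
#'
#' Per-residue solvent-accessible surface area from an internal
#' Shrake-Rupley sphere-sampling computation (probe 1.4 A, 100 sphere points
#' by default), divided by the theoretical maximal ASA of the residue type
#' (Tien et al. table) and clipped to \[0, 1\]. Uses backbone N/CA/C/O atoms
#' when present, otherwise a C-alpha pseudo-atom per residue (a documented
#' coarse approximation for C-alpha-only traces).
#'
#' @param record a [protein_record()].
#' @param probe probe radius in Angstrom.
#' @param n_points sphere sample points per atom (>= 100 recommended).
#' @param max_asa_table named vector of per-amino-acid maximal ASA values.
#' @return numeric n-vector in \[0, 1\].
#' @export
relative_solvent_accessibility <- function(record, probe = 1.4,
                                           n_points = 100L,
                                           max_asa_table = MAX_ASA_TIEN) {
  n <- nrow(record$ca_coords)
  bb <- record$backbone
  have_bb <- !is.null(bb) &&
    all(is.finite(bb$N)) && all(is.finite(bb$C)) && all(is.finite(bb$O))
  if (have_bb) {
    atoms <- rbind(bb$N, bb$CA, bb$C, bb$O)
    radii <- rep(VDW_RADII[c("N", "CA", "C", "O")], each = n)
    resmap <- rep(seq_len(n), times = 4)
  } else {
    atoms <- record$ca_coords
    radii <- rep(CA_PSEUDO_RADIUS, n)
    resmap <- seq_len(n)
  }
  asa_atom <- shrake_rupley_asa(atoms, radii, probe = probe, n_points = n_points)
  asa <- as.numeric(rowsum(asa_atom, resmap))
  aa <- strsplit(record$sequence, "")[[1]]
  rsa <- asa / max_asa_for(aa, max_asa_table)
  pmin(pmax(rsa, 0), 1)
}

DSSP_STATES <- c("H", "B", "E", "G", "I", "T", "S", "-", "unassigned")

ss_to_onehot <- function(ss) {
  n <- length(ss)
  ss[!ss %in% DSSP_STATES] <- "unassigned"
  out <- matrix(0, n, 9, dimnames = list(NULL, DSSP_STATES))
  out[cbind(seq_len(n), match(ss, DSSP_STATES))] <- 1
  out
}

# Classic fixed-column DSSP output reader: returns the per-residue
# secondary-structure character ('-' for blank) for one chain.
read_dssp_ss <- function(path, chain = NULL) {
  lines <- readLines(path)
  start <- grep("^  #  RESIDUE", lines)
  if (length(start) != 1L) stop("malformed DSSP file (no residue header): ", path)
  body <- lines[(start + 1L):length(lines)]
  body <- body[nchar(body) >= 17]
  aa <- substr(body, 14, 14)
  body <- body[aa != "!"]  # chain-break markers carry no residue
  ch <- substr(body, 12, 12)
  if (!is.null(chain)) body <- body[ch == chain]
  if (length(body) == 0L) stop("no DSSP residues", if (!is.null(chain)) paste0(" for chain ", chain))
  ss <- substr(body, 17, 17)
  ss[ss == " "] <- "-"
  ss
}

# Coarse torsion-based assigner: alpha-helical and extended Ramachandran
# regions mapped to H / E, anything else defined to '-', undefined torsions
# (both sin and cos zero, i.e. termini or CA-only traces) to 'unassigned'.
assign_ss_from_torsions <- function(torsions) {
  phi <- atan2(torsions[, 1], torsions[, 2]) * 180 / pi
  psi <- atan2(torsions[, 3], torsions[, 4]) * 180 / pi
  undef <- (torsions[, 1] == 0 & torsions[, 2] == 0) |
           (torsions[, 3] == 0 & torsions[, 4] == 0)
  ss <- rep("-", nrow(torsions))
  ss[phi >= -100 & phi <= -30 & psi >= -80 & psi <= 0] <- "H"
  ss[phi >= -180 & phi <= -90 & (psi >= 90 | psi <= -160)] <- "E"
  ss[undef] <- "unassigned"
  ss
}

#' Secondary-structure one-hot encoding
#'
#' Nine columns: the eight DSSP states (H, B, E, G, I, T, S, '-') plus an
#' explicit "unassigned" column, exactly one 1 per row. The source is either
#' a classic-format DSSP output file or, as a fallback requiring no external
#' tool, a coarse torsion-based assigner covering {H, E, -, unassigned}.
#'
#' @param n residue count (checked against the source).
#' @param dssp_path optional DSSP output file.
#' @param chain optional chain filter for the DSSP file.
#' @param torsions optional n x 4 sin/cos torsion matrix for the fallback.
#' @return n x 9 one-hot matrix.
#' @export
secondary_structure_onehot <- function(n, dssp_path = NULL, chain = NULL,
                                       torsions = NULL) {
  if (!is.null(dssp_path)) {
    ss <- read_dssp_ss(dssp_path, chain)
    if (length(ss) != n)
      stop("DSSP residue count (", length(ss), ") != expected (", n, ")")
  } else if (!is.null(torsions)) {
    if (nrow(torsions) != n) stop("torsion row count mismatch")
    ss <- assign_ss_from_torsions(torsions)
  } else {
    ss <- rep("unassigned", n)
  }
  ss_to_onehot(ss)
}

#' Compute the 14-dimensional structural feature group
#'
#' RSA (1) + secondary-structure one-hot (9) + torsion sin/cos (4). For
#' C-alpha-only records the torsions are (0,0,0,0), the secondary structure
#' is "unassigned" and RSA comes from C-alpha pseudo-atoms.
#'
#' @param record a [protein_record()].
#' @param dssp_path optional DSSP output file for the secondary structure.
#' @param n_points Shrake-Rupley sphere points.
#' @return n x 14 matrix.
#' @export
dssp_feature_group <- function(record, dssp_path = NULL, n_points = 100L) {
  n <- nrow(record$ca_coords)
  bb <- record$backbone
  have_bb <- !is.null(bb) && all(is.finite(bb$N)) && all(is.finite(bb$C))
  tor <- if (have_bb) backbone_torsions(bb) else matrix(0, n, 4)
  ss <- if (!is.null(dssp_path)) {
    secondary_structure_onehot(n, dssp_path = dssp_path)
  } else if (have_bb) {
    secondary_structure_onehot(n, torsions = tor)
  } else {
    secondary_structure_onehot(n)
  }
  rsa <- relative_solvent_accessibility(record, n_points = n_points)
  out <- cbind(rsa = rsa, ss, tor)
  stopifnot(ncol(out) == 14L)
  out
}

#' Assemble the node feature matrix
#'
#' Column-wise concatenation of the (already normalised) embedding block and
#' the 14-dimensional structural group, with block spans recorded.
#'
#' @param embeddings n x d_emb matrix, entries in \[0, 1\].
#' @param dssp_group n x 14 matrix from [dssp_feature_group()].
#' @return object of class `node_features`: list(H, block_spans).
#' @export
assemble_node_features <- function(embeddings, dssp_group) {
  embeddings <- as.matrix(embeddings)
  dssp_group <- as.matrix(dssp_group)
  if (nrow(embeddings) != nrow(dssp_group))
    stop("row mismatch: embeddings ", nrow(embeddings),
         ", structural group ", nrow(dssp_group))
  if (ncol(dssp_group) != 14L) stop("structural group must have 14 columns")
  d_emb <- ncol(embeddings)
  H <- unname(cbind(embeddings, dssp_group))
  structure(list(
    H = H,
    block_spans = list(embedding = seq_len(d_emb),
                       dssp = d_emb + seq_len(14L))),
    class = "node_features")
}
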