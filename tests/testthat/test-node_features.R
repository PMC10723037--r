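test_that("min-max normalisation maps the training range onto [0,1] and clips", {
  stats <- list(x_min = 2, x_max = 6)
  M <- matrix(c(2, 6, 4, 8, 0), ncol = 1)
  out <- minmax_normalize(M, stats)
  expect_equal(drop(out), c(0, 1, 0.5, 1, 0))
  # constant column maps to zero
  out2 <- minmax_normalize(matrix(c(3, 3), ncol = 1),
                           list(x_min = 3, x_max = 3))
  expect_equal(drop(out2), c(0, 0))
  expect_error(minmax_normalize(matrix(0, 2, 2), stats), "mismatch")
})

test_that("normalisation is idempotent on already-normalised data", {
  set.seed(1)
  M <- matrix(runif(50), 10, 5)
  stats <- list(x_min = rep(0, 5), x_max = rep(1, 5))
  expect_equal(minmax_normalize(M, stats), M)
})

test_that("fitted stats reproduce the column extremes", {
  set.seed(2)
  Ms <- list(matrix(rnorm(40), 10, 4), matrix(rnorm(20), 5, 4))
  st <- fit_minmax_stats(Ms)
  all_rows <- do.call(rbind, Ms)
  expect_equal(st$x_min, apply(all_rows, 2, min))
  norm <- minmax_normalize(all_rows, st)
  expect_true(all(norm >= 0 & norm <= 1))
})

test_that("dihedral angles match closed forms and a vector-algebra oracle", {
  # trans-planar zigzag: dihedral 180 degrees
  expect_equal(abs(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                                  c(1, -1, 0))), pi)
  # cis: 0 degrees
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                              c(1, 1, 0)), 0)
  # random quadruples vs independent two-plane-normal oracle
  oracle <- function(p1, p2, p3, p4) {
    n1 <- bindgraph:::cross3(p2 - p1, p3 - p2)
    n2 <- bindgraph:::cross3(p3 - p2, p4 - p3)
    ang <- acos(max(-1, min(1, sum(n1 * n2) /
                              (sqrt(sum(n1^2)) * sqrt(sum(n2^2))))))
    s <- sign(sum(n1 * (p4 - p3)))
    if (s == 0) s <- 1
    s * ang
  }
  set.seed(3)
  for (r in 1:25) {
    pts <- matrix(rnorm(12), 4, 3)
    got <- dihedral_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    expect_equal(got, oracle(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                 tolerance = 1e-9)
  }
  # collinear quadruple is undefined
  expect_true(is.na(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                                   c(3, 0, 0))))
})

test_that("backbone torsions encode termini as (0,0) and helix phi/psi as sin/cos", {
  rec <- helix_record_with_backbone(10)
  tor <- backbone_torsions(rec$backbone)
  expect_equal(dim(tor), c(10, 4))
  expect_equal(tor[1, 1:2], c(sin_phi = 0, cos_phi = 0))   # no phi at N-terminus
  expect_equal(tor[10, 3:4], c(sin_psi = 0, cos_psi = 0))  # no psi at C-terminus
  expect_true(all(tor >= -1 & tor <= 1))
  # interior angles: sin^2+cos^2 = 1 where defined
  s2 <- tor[2:9, 1]^2 + tor[2:9, 2]^2
  expect_equal(s2, rep(1, 8), tolerance = 1e-12)
})

test_that("an isolated residue is fully exposed and a buried one is not", {
  rec1 <- protein_record("iso", "A", matrix(c(0, 0, 0), 1, 3))
  expect_equal(relative_solvent_accessibility(rec1), 1)
  # residue at the center of a dense shell of other residues
  set.seed(4)
  pts <- bindgraph:::sphere_points(60) * 4
  shell <- rbind(c(0, 0, 0), pts)
  # build via raw ASA computation (the record invariants do not apply to
  # this artificial cluster)
  asa <- bindgraph:::shrake_rupley_asa(shell, rep(1.7, nrow(shell)))
  expect_lt(asa[1] / 129, 0.05)
})

test_that("Shrake-Rupley agrees with a 10x resolution run within 5%", {
  atoms <- rbind(c(0, 0, 0), c(4, 0, 0))
  radii <- c(1.7, 1.7)
  lo <- bindgraph:::shrake_rupley_asa(atoms, radii, n_points = 100L)
  hi <- bindgraph:::shrake_rupley_asa(atoms, radii, n_points = 1000L)
  expect_equal(lo, hi, tolerance = 0.05)
})

test_that("accessibility is invariant under rigid-body motion", {
  ds <- small_dataset(n_proteins = 1, seed = 9)
  rec <- ds$records[[1]]
  set.seed(5)
  R <- random_rotation()
  rec2 <- rec
  rec2$ca_coords <- rec$ca_coords %*% R +
    matrix(c(10, -4, 2), nrow(rec$ca_coords), 3, byrow = TRUE)
  expect_equal(relative_solvent_accessibility(rec2),
               relative_solvent_accessibility(rec), tolerance = 1e-9)
})

test_that("secondary-structure one-hot has nine columns and one 1 per row", {
  dssp <- withr::local_tempfile(fileext = ".dssp")
  writeLines(c(
    "==== Secondary Structure Definition ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
    "    1    1 A A  H  >        0   0  100",
    "    2    2 A G  H  <        0   0   90",
    "    3    3 A S              0   0   80"), dssp)
  oh <- secondary_structure_onehot(3, dssp_path = dssp)
  expect_equal(dim(oh), c(3, 9))
  expect_equal(rowSums(oh), rep(1, 3))
  expect_equal(oh[, "H"], c(1, 1, 0))
  expect_equal(unname(oh[3, "-"]), 1)  # blank field maps to '-'
  expect_error(secondary_structure_onehot(5, dssp_path = dssp), "count")
})

test_that("torsion fallback labels an ideal alpha-helical trace H", {
  phi <- -60 * pi / 180
  psi <- -45 * pi / 180
  tor <- cbind(sin(phi), cos(phi), sin(psi), cos(psi))[rep(1, 6), ]
  oh <- secondary_structure_onehot(6, torsions = tor)
  expect_equal(oh[, "H"], rep(1, 6))
  # undefined torsions fall into the explicit unassigned column
  oh0 <- secondary_structure_onehot(2, torsions = matrix(0, 2, 4))
  expect_equal(oh0[, "unassigned"], c(1, 1))
})

test_that("node feature assembly concatenates blocks with recorded spans", {
  ds <- small_dataset(n_proteins = 1, seed = 2)
  rec <- ds$records[[1]]
  emb <- minmax_normalize(ds$embeddings[[1]], fit_minmax_stats(ds$embeddings))
  dg <- dssp_feature_group(rec)
  nf <- assemble_node_features(emb, dg)
  expect_equal(ncol(nf$H), ncol(emb) + 14)
  expect_equal(nf$block_spans$dssp, ncol(emb) + 1:14)
  # synthetic 1024-dim usage gives the full-scale width
  expect_equal(1024 + 14, 1038)
  # permuting rows of both inputs permutes H identically
  p <- sample(nrow(emb))
  nf2 <- assemble_node_features(emb[p, ], dg[p, ])
  expect_equal(nf2$H, nf$H[p, ])
  expect_error(assemble_node_features(emb[-1, ], dg), "row mismatch")
})

test_that("the structural group is 14-dimensional with bounded entries", {
  rec <- helix_record_with_backbone(12)
  dg <- dssp_feature_group(rec)
  expect_equal(ncol(dg), 14)
  expect_true(all(dg[, 1] >= 0 & dg[, 1] <= 1))         # RSA
  expect_equal(unname(rowSums(dg[, 2:10])), rep(1, 12)) # SS one-hot
  expect_true(all(dg[, 11:14] >= -1 & dg[, 11:14] <= 1))
})
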