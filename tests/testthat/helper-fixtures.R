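# Shared fixture builders for the test suite. Everything is generated in
# code; no binary data.

# A minimal hand-written PDB with three residues on a line, CA spacing 3.8 A.
write_toy_pdb <- function(path, drop_residue = NULL, extra_chain = FALSE) {
  res <- c("ALA", "GLY", "SER")
  x <- c(0, 3.8, 7.6)
  lines <- character(0)
  serial <- 0L
  for (r in 1:3) {
    if (!is.null(drop_residue) && r == drop_residue) next
    serial <- serial + 1L
    lines <- c(lines, sprintf(
      "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      serial, res[r], r, x[r], 0, 0))
  }
  if (extra_chain) {
    for (r in 1:2) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  %3s B%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial, "LEU", r, 20 + 3.8 * r, 0, 0))
    }
  }
  writeLines(c(lines, "TER", "END"), path)
  path
}

# Full-backbone ideal helix record (exercises torsion / SS / RSA paths).
helix_record_with_backbone <- function(n = 12) {
  ca <- generate_backbone(n, "helix")
  # place N and C plausibly between consecutive CAs; O off the C atom
  N <- ca; C <- ca; O <- ca
  for (i in seq_len(n)) {
    prev <- if (i > 1) ca[i - 1, ] else ca[i, ] - c(3.8, 0, 0)
    nxt <- if (i < n) ca[i + 1, ] else ca[i, ] + c(3.8, 0, 0)
    N[i, ] <- ca[i, ] + 0.4 * (prev - ca[i, ]) + c(0, 0.3, 0)
    C[i, ] <- ca[i, ] + 0.4 * (nxt - ca[i, ]) + c(0.2, 0, 0.1)
    O[i, ] <- C[i, ] + c(0, 0, 1.2)
  }
  protein_record(id = "HLX_A",
                 sequence = paste(rep("A", n), collapse = ""),
                 ca_coords = ca,
                 backbone = list(N = N, CA = ca, C = C, O = O))
}

random_rotation <- function() {
  R <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

rigid_transform_dataset <- function(dataset, R, t) {
  for (p in seq_along(dataset$records)) {
    X <- dataset$records[[p]]$ca_coords
    dataset$records[[p]]$ca_coords <-
      X %*% R + matrix(t, nrow(X), 3, byrow = TRUE)
  }
  dataset
}

small_dataset <- function(n_proteins = 4, seed = 11, lengths = c(28, 40),
                          mode = "structure_only", pn = 0.18) {
  make_dataset(synthetic_spec(n_proteins = n_proteins, length_range = lengths,
                              pn_ratio_target = pn, embed_dim = 8,
                              signal_mode = mode, seed = seed))
}

small_graphs <- function(dataset, k = 8, pos_dim = 8, ...) {
  dataset_graphs(dataset, fit_minmax_stats(dataset$embeddings),
                 k = k, pos_dim = pos_dim, ...)
}

small_config <- function(graphs, seed = 3, num_layers = 2, num_heads = 2,
                         hidden_dim = 16, ...) {
  bindgraph_config(num_layers = num_layers, num_heads = num_heads,
                   hidden_dim = hidden_dim,
                   input_dim = ncol(graphs[[1]]$H),
                   edge_dim = ncol(graphs[[1]]$E), seed = seed, ...)
}
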