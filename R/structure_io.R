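# Structure input/output: PDB reading via bio3d, prediction tables, FASTA.

#' Construct a ProteinRecord
#'
#' A ProteinRecord bundles everything downstream code needs about one chain:
#' identifier, one-letter sequence, the n x 3 C-alpha coordinate matrix
#' (Angstrom), optional full-backbone N/CA/C/O coordinates, optional binary
#' binding labels and author residue numbers.
#'
#' @param id character identifier, e.g. "4L3O_A".
#' @param sequence one-letter amino-acid string of length n.
#' @param ca_coords n x 3 numeric matrix of C-alpha coordinates (Angstrom).
#' @param backbone optional list with n x 3 matrices `N`, `CA`, `C`, `O`
#'   (rows may be NA where an atom is missing).
#' @param labels optional integer vector of 0/1 binding labels, length n.
#' @param resnums integer vector of author residue numbers, length n.
#' @param chain_breaks integer indices i such that a chain break lies between
#'   residues i and i+1.
#' @return an object of class `protein_record`.
#' @export
protein_record <- function(id, sequence, ca_coords, backbone = NULL,
                           labels = NULL, resnums = NULL,
                           chain_breaks = integer(0)) {
  ca_coords <- as.matrix(ca_coords)
  n <- nrow(ca_coords)
  if (n == 0L) stop("protein_record: zero residues")
  if (ncol(ca_coords) != 3L) stop("ca_coords must be n x 3")
  if (nchar(sequence) != n)
    stop("sequence length (", nchar(sequence), ") != coordinate rows (", n, ")")
  if (is.null(resnums)) resnums <- seq_len(n)
  if (length(resnums) != n) stop("resnums length mismatch")
  if (!is.null(labels)) {
    if (length(labels) != n) stop("labels length mismatch")
    if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
    labels <- as.integer(labels)
  }
  rec <- structure(
    list(id = id, sequence = sequence, ca_coords = unname(ca_coords),
         backbone = backbone, labels = labels,
         resnums = as.integer(resnums),
         chain_breaks = as.integer(chain_breaks)),
    class = "protein_record")
  validate_record(rec)
  rec
}

# Consecutive C-alpha distances outside (2.5, 4.5) A are only legal across a
# flagged chain break.
validate_record <- function(rec) {
  n <- nrow(rec$ca_coords)
  if (n >= 2L) {
    d <- sqrt(rowSums((rec$ca_coords[-1, , drop = FALSE] -
                       rec$ca_coords[-n, , drop = FALSE])^2))
    bad <- which(d <= 2.5 | d >= 4.5)
    unflagged <- setdiff(bad, rec$chain_breaks)
    if (length(unflagged))
      stop("unphysical consecutive CA distance at position(s) ",
           paste(unflagged, collapse = ","), " without a chain-break flag")
  }
  invisible(rec)
}

#' @export
print.protein_record <- function(x, ...) {
  cat("ProteinRecord", x$id, "-", nrow(x$ca_coords), "residues")
  if (length(x$chain_breaks)) cat(",", length(x$chain_breaks), "chain break(s)")
  if (!is.null(x$labels)) cat(",", sum(x$labels), "positive labels")
  cat("\n  sequence:", substr(x$sequence, 1, 60),
      if (nchar(x$sequence) > 60) "..." else "", "\n")
  invisible(x)
}

#' Read one chain of a PDB file as a ProteinRecord
#'
#' Parses ATOM records (HETATM ignored) of the requested chain, first model
#' only. Residues are taken in file order; a residue without a C-alpha atom
#' is dropped and a chain break flagged between its neighbours. Alternate
#' locations are resolved to the highest occupancy, ties to the
#' first-listed. Non-standard residues with a standard parent (e.g. MSE) map
#' to the parent one-letter code, otherwise to "X". Chain breaks are also
#' flagged wherever consecutive surviving C-alphas are closer than 2.5 A or
#' farther than 4.5 A.
#'
#' @param path PDB file path.
#' @param chain single chain identifier (default: first chain present).
#' @return a [protein_record()] with backbone coordinates where N/C/O atoms
#'   are present.
#' @export
read_structure <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain %in% chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("chain '", chain, "' not found in ", path)

  # residue identity: resno + insertion code, ordered by file appearance
  ins <- at$insert
  ins[is.na(ins)] <- ""
  rkey <- paste(at$resno, ins, sep = "|")
  rlev <- unique(rkey)  # file order

  pick_atom <- function(sub, elety) {
    s <- sub[sub$elety == elety, , drop = FALSE]
    if (nrow(s) == 0L) return(NULL)
    if (nrow(s) > 1L) {
      occ <- s$o
      occ[is.na(occ)] <- 1
      s <- s[which.max(occ), , drop = FALSE]  # ties -> first listed
    }
    c(s$x, s$y, s$z)
  }

  n_all <- length(rlev)
  ca <- matrix(NA_real_, n_all, 3)
  bbN <- bbC <- bbO <- matrix(NA_real_, n_all, 3)
  seq3 <- character(n_all)
  resno <- integer(n_all)
  for (r in seq_len(n_all)) {
    sub <- at[rkey == rlev[r], , drop = FALSE]
    seq3[r] <- sub$resid[1]
    resno[r] <- sub$resno[1]
    p <- pick_atom(sub, "CA"); if (!is.null(p)) ca[r, ] <- p
    p <- pick_atom(sub, "N");  if (!is.null(p)) bbN[r, ] <- p
    p <- pick_atom(sub, "C");  if (!is.null(p)) bbC[r, ] <- p
    p <- pick_atom(sub, "O");  if (!is.null(p)) bbO[r, ] <- p
  }

  keep <- which(!is.na(ca[, 1]))
  if (length(keep) == 0L)
    stop("no residues with a CA atom in chain '", chain, "' of ", path)
  dropped <- setdiff(seq_len(n_all), keep)
  # a dropped residue induces a break between its surviving neighbours
  breaks <- integer(0)
  for (d in dropped) {
    before <- keep[keep < d]
    if (length(before)) breaks <- c(breaks, match(max(before), keep))
  }

  ca <- ca[keep, , drop = FALSE]
  n <- nrow(ca)
  if (n >= 2L) {
    dd <- sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-n, , drop = FALSE])^2))
    breaks <- sort(unique(c(breaks, which(dd <= 2.5 | dd >= 4.5))))
  }
  backbone <- list(N = bbN[keep, , drop = FALSE], CA = ca,
                   C = bbC[keep, , drop = FALSE], O = bbO[keep, , drop = FALSE])
  protein_record(
    id = paste0(sub("\\.(pdb|ent)$", "", basename(path)), "_", chain),
    sequence = paste(aa_three_to_one(seq3[keep]), collapse = ""),
    ca_coords = ca, backbone = backbone,
    resnums = resno[keep], chain_breaks = breaks)
}

#' Write per-residue predictions as TSV
#'
#' Writes a tab-separated table with columns `residue_index` (1-based),
#' `resnum`, `amino_acid`, `probability` (6 decimal places) and
#' `predicted_label`. Output is byte-deterministic for identical inputs.
#'
#' @param record a [protein_record()].
#' @param scores numeric vector of probabilities in \[0, 1\], length n.
#' @param binary integer vector of 0/1 calls, length n.
#' @param path output file path.
#' @export
write_predictions <- function(record, scores, binary, path) {
  n <- nrow(record$ca_coords)
  if (length(scores) != n || length(binary) != n)
    stop("write_predictions: length mismatch (n=", n, ", scores=",
         length(scores), ", binary=", length(binary), ")")
  if (any(scores < 0 | scores > 1)) stop("scores outside [0,1]")
  if (!all(binary %in% c(0L, 1L))) stop("binary calls must be 0/1")
  aa <- strsplit(record$sequence, "")[[1]]
  lines <- c("residue_index\tresnum\tamino_acid\tprobability\tpredicted_label",
             sprintf("%d\t%d\t%s\t%.6f\t%d", seq_len(n), record$resnums,
                     aa, scores, as.integer(binary)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a prediction TSV written by [write_predictions()]
#' @param path file path.
#' @return data.frame with the five table columns.
#' @export
read_predictions <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a FASTA file (bookkeeping only)
#' @param path FASTA file path.
#' @return named character vector of sequences keyed by record id.
#' @export
read_fasta <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA headers in ", path)
  id <- sub("^>", "", lines[hdr])
  id <- sub("\\s.*$", "", id)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, "", collapse = "")
  stats::setNames(unname(seqs), id)
}

# Minimal deterministic PDB writer for C-alpha traces (synthetic fixtures).
write_ca_pdb <- function(record, path) {
  aa1 <- strsplit(record$sequence, "")[[1]]
  one_to_three <- stats::setNames(names(AA_THREE_TO_ONE)[1:20],
                                  unname(AA_THREE_TO_ONE[1:20]))
  res3 <- one_to_three[aa1]
  res3[is.na(res3)] <- "UNK"
  X <- record$ca_coords
  lines <- sprintf(
    "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(X)), res3, record$resnums, X[, 1], X[, 2], X[, 3])
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}
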