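# Confusion-matrix metrics, ROC/PR areas, max-MCC threshold selection,
# nonlocal-contact stratification and paired bound/unbound comparison.

check_labels_scores <- function(labels, scores) {
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (any(!is.finite(scores)) || any(scores < 0 | scores > 1))
    stop("scores must lie in [0, 1]")
  if (length(labels) != length(scores)) stop("labels/scores length mismatch")
}

#' Confusion counts and threshold metrics
#'
#' Binary calls are score >= threshold. Accuracy, precision, recall,
#' specificity, F1 and MCC are computed from the confusion counts
#' (MCC = (TP*TN - FN*FP) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))). Any metric
#' with a zero denominator is reported as 0 and flagged in `degenerate`.
#'
#' @param labels 0/1 vector.
#' @param scores probabilities in \[0, 1\].
#' @param threshold decision threshold.
#' @return object of class `metrics_report`: confusion counts, the six
#'   threshold metrics, the threshold, and a character vector of degenerate
#'   metric names.
#' @export
confusion_and_metrics <- function(labels, scores, threshold = 0.5) {
  check_labels_scores(labels, scores)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  degenerate <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) { degenerate <<- c(degenerate, name); return(0) }
    num / den
  }
  acc <- safe(tp + tn, tp + tn + fp + fn, "ACC")
  pre <- safe(tp, tp + fp, "Pre")
  rec <- safe(tp, tp + fn, "Rec")
  spe <- safe(tn, tn + fp, "Spe")
  f1 <- safe(2 * pre * rec, pre + rec, "F1")
  mcc_den <- sqrt(as.double(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mcc_den == 0) { degenerate <- c(degenerate, "MCC"); 0 } else
    (as.double(tp) * tn - as.double(fn) * fp) / mcc_den
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn,
                 ACC = acc, Pre = pre, Rec = rec, Spe = spe,
                 F1 = f1, MCC = mcc, threshold = threshold,
                 degenerate = degenerate),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("TP=%d TN=%d FP=%d FN=%d (threshold %.4f)\n",
              x$TP, x$TN, x$FP, x$FN, x$threshold))
  cat(sprintf("ACC=%.4f Pre=%.4f Rec=%.4f Spe=%.4f F1=%.4f MCC=%.4f\n",
              x$ACC, x$Pre, x$Rec, x$Spe, x$F1, x$MCC))
  if (!is.null(x$AUC)) cat(sprintf("AUC=%.4f AUPRC=%.4f\n", x$AUC, x$AUPRC))
  if (length(x$degenerate))
    cat("degenerate metrics (reported as 0):",
        paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}

#' Area under the ROC curve (tie-averaged rank statistic)
#'
#' @param labels 0/1 vector containing both classes.
#' @param scores probabilities.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, scores) {
  check_labels_scores(labels, scores)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) stop("ROC AUC undefined: one class absent")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve (step integration)
#'
#' Scores are swept from high to low over distinct values; tied scores enter
#' as one group. The area is the step-wise sum of precision times recall
#' increment (no linear interpolation between operating points).
#'
#' @param labels 0/1 vector containing both classes.
#' @param scores probabilities.
#' @return AUPRC in \[0, 1\].
#' @export
pr_auc <- function(labels, scores) {
  check_labels_scores(labels, scores)
  np <- sum(labels == 1)
  if (np == 0 || np == length(labels)) stop("PR AUC undefined: one class absent")
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  grp_end <- which(diff(s) != 0)
  grp_end <- c(grp_end, length(s))
  ctp <- cumsum(y)[grp_end]
  cn <- grp_end
  prec <- ctp / cn
  rec <- ctp / np
  sum(prec * diff(c(0, rec)))
}

#' MCC-maximising decision threshold
#'
#' Scans the midpoints between consecutive distinct sorted scores plus the
#' boundary candidates 0 and 1, and returns the smallest threshold attaining
#' the maximal MCC (deterministic).
#'
#' @param labels 0/1 vector containing both classes.
#' @param scores probabilities.
#' @return list with `threshold` and the attained `mcc`.
#' @export
optimal_threshold_by_mcc <- function(labels, scores) {
  check_labels_scores(labels, scores)
  if (length(unique(labels)) < 2L) stop("threshold selection needs both classes")
  s <- sort(unique(scores))
  cands <- unique(c(0, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, 1))
  mccs <- vapply(cands, function(t) confusion_and_metrics(labels, scores, t)$MCC, 0)
  best <- max(mccs)
  list(threshold = cands[which(mccs >= best - 1e-15)[1]], mcc = best)
}

#' Nonlocal contact counts
#'
#' For each residue i, the number of residues j with sequence separation
#' |i - j| > 20 and C-alpha distance strictly below 12 Angstrom.
#'
#' @param X n x 3 C-alpha coordinate matrix.
#' @param min_separation sequence-separation cut (default 20, strict >).
#' @param max_distance distance cut in Angstrom (default 12, strict <).
#' @return integer n-vector.
#' @export
nonlocal_contact_counts <- function(X, min_separation = 20L, max_distance = 12) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite coordinates")
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  as.integer(rowSums(sep > min_separation & D < max_distance))
}

#' Metrics stratified by nonlocal-contact count
#'
#' Residues are assigned to half-open count bins (default 0-9, 10-19, >=20)
#' and the threshold metrics are recomputed per bin with one global
#' threshold. Bins that are empty or contain a single class are flagged,
#' not dropped.
#'
#' @param labels,scores as in [confusion_and_metrics()].
#' @param counts nonlocal-contact counts per residue.
#' @param threshold global decision threshold.
#' @param bins data.frame with columns `lo`, `hi` (inclusive; `Inf` allowed)
#'   partitioning the non-negative integers.
#' @return data.frame with one row per bin: bin label, n, n_pos, metrics,
#'   and a `flag` column ("" / "empty" / "one_class").
#' @export
stratified_metrics <- function(labels, scores, counts, threshold,
                               bins = data.frame(lo = c(0, 10, 20),
                                                 hi = c(9, 19, Inf))) {
  if (length(counts) != length(labels)) stop("counts length mismatch")
  bins <- bins[order(bins$lo), , drop = FALSE]
  if (bins$lo[1] != 0 || any(bins$lo[-1] != bins$hi[-nrow(bins)] + 1) ||
      !is.infinite(bins$hi[nrow(bins)]))
    stop("bins must partition the non-negative integers (gap or overlap found)")
  out <- lapply(seq_len(nrow(bins)), function(b) {
    idx <- counts >= bins$lo[b] & counts <= bins$hi[b]
    lab <- if (is.infinite(bins$hi[b])) paste0(">=", bins$lo[b]) else
      paste0(bins$lo[b], "-", bins$hi[b])
    if (!any(idx)) {
      return(data.frame(bin = lab, n = 0L, n_pos = 0L, ACC = NA, Pre = NA,
                        Rec = NA, Spe = NA, F1 = NA, MCC = NA, AUC = NA,
                        flag = "empty"))
    }
    m <- confusion_and_metrics(labels[idx], scores[idx], threshold)
    one_class <- length(unique(labels[idx])) < 2L
    auc <- if (one_class) NA else roc_auc(labels[idx], scores[idx])
    data.frame(bin = lab, n = sum(idx), n_pos = sum(labels[idx]),
               ACC = m$ACC, Pre = m$Pre, Rec = m$Rec, Spe = m$Spe,
               F1 = m$F1, MCC = m$MCC, AUC = auc,
               flag = if (one_class) "one_class" else "")
  })
  do.call(rbind, out)
}

#' Full evaluation of scores against labels
#'
#' Convenience wrapper: max-MCC threshold (or a supplied one), confusion
#' metrics, AUC and AUPRC in one report.
#'
#' @param labels,scores as in [confusion_and_metrics()].
#' @param threshold optional fixed threshold; when NULL the MCC-maximising
#'   threshold is selected on these scores.
#' @return `metrics_report` with AUC, AUPRC and threshold filled in.
#' @export
evaluate_predictions <- function(labels, scores, threshold = NULL) {
  if (is.null(threshold)) threshold <- optimal_threshold_by_mcc(labels, scores)$threshold
  rep <- confusion_and_metrics(labels, scores, threshold)
  rep$AUC <- roc_auc(labels, scores)
  rep$AUPRC <- pr_auc(labels, scores)
  rep
}

#' Paired bound/unbound structure comparison
#'
#' Runs the same fitted ensemble on two structure sets paired by id (e.g.
#' bound and unbound conformations of the same proteins) against the same
#' labels, and reports per-set metrics plus the relative change of each.
#'
#' @param fit a `bindgraph_fit` ensemble.
#' @param dataset_a,dataset_b `bindgraph_dataset` objects paired by protein
#'   id with equal residue counts per pair; labels are taken from
#'   `dataset_a`.
#' @return list with `report_a`, `report_b` and `relative_change` (named
#'   vector over ACC/Pre/Rec/Spe/F1/MCC/AUC/AUPRC).
#' @export
paired_structure_comparison <- function(fit, dataset_a, dataset_b) {
  ids_a <- vapply(dataset_a$records, function(r) r$id, "")
  ids_b <- vapply(dataset_b$records, function(r) r$id, "")
  if (!setequal(ids_a, ids_b))
    stop("unpaired ids: ", paste(symdiff <- union(setdiff(ids_a, ids_b),
                                                  setdiff(ids_b, ids_a)),
                                 collapse = ","))
  ord_b <- match(ids_a, ids_b)
  for (k in seq_along(ids_a)) {
    na <- nrow(dataset_a$records[[k]]$ca_coords)
    nb <- nrow(dataset_b$records[[ord_b[k]]]$ca_coords)
    if (na != nb) stop("length mismatch within pair ", ids_a[k],
                       " (", na, " vs ", nb, ")")
  }
  labels <- unlist(lapply(dataset_a$records, function(r) r$labels))
  sa <- unlist(predict(fit, dataset_a))
  sb <- unlist(predict(fit, dataset_b)[ord_b])
  ra <- evaluate_predictions(labels, sa)
  rb <- evaluate_predictions(labels, sb, threshold = ra$threshold)
  keys <- c("ACC", "Pre", "Rec", "Spe", "F1", "MCC", "AUC", "AUPRC")
  va <- unlist(ra[keys]); vb <- unlist(rb[keys])
  rel <- ifelse(va == 0, ifelse(vb == 0, 0, Inf), (vb - va) / abs(va))
  list(report_a = ra, report_b = rb, relative_change = stats::setNames(rel, keys))
}

#' Serialise a metrics report to a flat key-value text file
#' @param report a `metrics_report`.
#' @param path output path.
#' @export
write_metrics_report <- function(report, path) {
  keys <- c("TP", "TN", "FP", "FN", "ACC", "Pre", "Rec", "Spe", "F1", "MCC",
            "AUC", "AUPRC", "threshold")
  lines <- character(0)
  for (k in keys) {
    v <- report[[k]]
    if (is.null(v)) next
    lines <- c(lines, if (k %in% c("TP", "TN", "FP", "FN"))
      sprintf("%s\t%d", k, v) else sprintf("%s\t%.6f", k, v))
  }
  if (length(report$degenerate))
    lines <- c(lines, paste0("degenerate\t", paste(report$degenerate, collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}
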