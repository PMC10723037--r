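# End-to-end pipeline: dataset -> attributed graphs -> cross-validated
# ensemble fit -> predictions. The fit is the package's central S3 object.

#' Build attributed graphs for every protein in a dataset
#'
#' Normalises the embedding block with the supplied min-max statistics,
#' computes the 14-dimensional structural group, and assembles the k-NN
#' graph with spatial and positional edge features for each record.
#'
#' @param dataset a `bindgraph_dataset`.
#' @param norm_stats statistics from [fit_minmax_stats()] (fitted on
#'   training data).
#' @param k neighbour count (default 30).
#' @param pos_dim positional encoding dimension (default 16).
#' @param complete,zero_spatial geometry-agnostic baseline switches.
#' @param rsa_points Shrake-Rupley sphere points (default 100).
#' @return list of `protein_graph` objects.
#' @export
dataset_graphs <- function(dataset, norm_stats, k = 30L, pos_dim = 16L,
                           complete = FALSE, zero_spatial = FALSE,
                           rsa_points = 100L) {
  lapply(seq_along(dataset$records), function(p) {
    rec <- dataset$records[[p]]
    emb <- minmax_normalize(dataset$embeddings[[p]], norm_stats)
    nf <- assemble_node_features(emb, dssp_feature_group(rec, n_points = rsa_points))
    build_protein_graph(rec, nf, k = k, pos_dim = pos_dim,
                        complete = complete, zero_spatial = zero_spatial)
  })
}

#' Fit the binding-site prediction ensemble
#'
#' The main fitting function: fits embedding normalisation statistics on the
#' training data, builds the attributed residue graphs, runs protein-level
#' 5-fold cross-validation of the edge-aware Graph Transformer, and returns
#' the fold ensemble with its median MCC-maximising validation threshold.
#'
#' @param dataset a labelled `bindgraph_dataset` (from [make_dataset()] or
#'   [read_dataset()]).
#' @param model a [bindgraph_config()]; `input_dim`/`edge_dim` are derived
#'   from the data when left at their defaults.
#' @param training a [train_config()].
#' @param k neighbour count (default 30).
#' @param pos_dim positional edge-encoding dimension (default 16).
#' @param baseline fit the geometry-agnostic baseline (complete graph,
#'   zeroed spatial edge features) instead of the graph model.
#' @param verbose print per-fold progress.
#' @return object of class `bindgraph_fit`.
#' @export
bindgraph_fit <- function(dataset, model = NULL, training = train_config(),
                          k = 30L, pos_dim = 16L, baseline = FALSE,
                          verbose = FALSE) {
  d_emb <- ncol(dataset$embeddings[[1]])
  norm_stats <- fit_minmax_stats(dataset$embeddings)
  if (is.null(model)) model <- bindgraph_config()
  model$input_dim <- d_emb + 14L
  model$edge_dim <- 23L + as.integer(pos_dim)
  graphs <- dataset_graphs(dataset, norm_stats, k = k, pos_dim = pos_dim,
                           complete = baseline, zero_spatial = baseline)
  cv <- cross_validate(graphs, model, training, verbose = verbose)
  structure(list(members = cv$members, norm_stats = norm_stats,
                 model_cfg = model, train_cfg = training,
                 threshold = cv$threshold, cv_table = cv$cv_table,
                 fold_assignment = cv$fold_assignment,
                 k = as.integer(k), pos_dim = as.integer(pos_dim),
                 baseline = isTRUE(baseline)),
            class = "bindgraph_fit")
}

#' Predict binding probabilities with a fitted ensemble
#'
#' @param object a `bindgraph_fit`.
#' @param newdata a `bindgraph_dataset` (labels optional).
#' @param type "prob" for probabilities, "class" for 0/1 calls at the fit's
#'   threshold.
#' @param ... unused.
#' @return named list (by protein id) of per-residue vectors.
#' @export
predict.bindgraph_fit <- function(object, newdata, type = c("prob", "class"),
                                  ...) {
  type <- match.arg(type)
  d_emb <- ncol(newdata$embeddings[[1]])
  if (d_emb + 14L != object$model_cfg$input_dim)
    stop("embedding dimension mismatch: checkpoint expects d_emb = ",
         object$model_cfg$input_dim - 14L, ", got ", d_emb)
  graphs <- dataset_graphs(newdata, object$norm_stats, k = object$k,
                           pos_dim = object$pos_dim,
                           complete = object$baseline,
                           zero_spatial = object$baseline)
  out <- lapply(graphs, function(g)
    ensemble_predict(object$members, g, object$model_cfg))
  names(out) <- vapply(newdata$records, function(r) r$id, "")
  if (type == "class")
    out <- lapply(out, function(p) as.integer(p >= object$threshold))
  out
}

#' @export
print.bindgraph_fit <- function(x, ...) {
  cat("Edge-aware Graph Transformer binding-site ensemble",
      if (x$baseline) "(geometry-agnostic baseline)" else "", "\n")
  cat(sprintf("  %d fold members | %d layers, %d heads, d=%d | k=%d%s\n",
              length(x$members), x$model_cfg$num_layers,
              x$model_cfg$num_heads, x$model_cfg$hidden_dim, x$k,
              if (x$baseline) " (complete graph, spatial features zeroed)" else ""))
  cat(sprintf("  decision threshold (median max-MCC over folds): %.4f\n",
              x$threshold))
  invisible(x)
}

#' @export
summary.bindgraph_fit <- function(object, ...) {
  print(object)
  tab <- object$cv_table
  cat("\nCross-validation (protein-level folds):\n")
  print(tab, row.names = FALSE)
  cat(sprintf("\n  AUPRC %.4f +/- %.4f | AUC %.4f +/- %.4f | MCC %.4f +/- %.4f\n",
              mean(tab$AUPRC), stats::sd(tab$AUPRC),
              mean(tab$AUC), stats::sd(tab$AUC),
              mean(tab$MCC), stats::sd(tab$MCC)))
  invisible(object)
}

CHECKPOINT_VERSION <- 1L

#' Save a fitted ensemble as a versioned JSON checkpoint
#'
#' @param fit a `bindgraph_fit`.
#' @param path output file.
#' @export
save_checkpoint <- function(fit, path) {
  obj <- list(version = CHECKPOINT_VERSION,
              model_cfg = unclass(fit$model_cfg),
              norm_stats = fit$norm_stats,
              threshold = fit$threshold,
              k = fit$k, pos_dim = fit$pos_dim, baseline = fit$baseline,
              cv_table = fit$cv_table,
              member_vectors = lapply(fit$members, function(m)
                unlist(m$params, use.names = FALSE)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#'
#' Fails loudly when the stored parameter vectors do not match the stored
#' architecture configuration.
#'
#' @param path checkpoint file.
#' @return a `bindgraph_fit` (without training history).
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(as.integer(obj$version), CHECKPOINT_VERSION))
    stop("unsupported checkpoint version: ", obj$version)
  cfg <- do.call(bindgraph_config, obj$model_cfg[
    c("num_layers", "num_heads", "hidden_dim", "dropout", "input_dim",
      "edge_dim", "ffn_multiplier", "use_ffn", "head_hidden", "seed")])
  skeleton <- init_model(cfg)
  nexp <- length(unlist(skeleton, use.names = FALSE))
  mv <- obj$member_vectors
  if (is.matrix(mv)) mv <- lapply(seq_len(nrow(mv)), function(r) mv[r, ])
  members <- lapply(mv, function(v) {
    if (length(v) != nexp)
      stop("checkpoint/config mismatch: expected ", nexp,
           " parameters, found ", length(v))
    list(params = relist_params(as.numeric(v), skeleton))
  })
  structure(list(members = members,
                 norm_stats = list(x_min = as.numeric(obj$norm_stats$x_min),
                                   x_max = as.numeric(obj$norm_stats$x_max)),
                 model_cfg = cfg, train_cfg = NULL,
                 threshold = obj$threshold,
                 cv_table = obj$cv_table,
                 k = as.integer(obj$k), pos_dim = as.integer(obj$pos_dim),
                 baseline = isTRUE(obj$baseline)),
            class = "bindgraph_fit")
}
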