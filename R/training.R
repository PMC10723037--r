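# Optimisation protocol: residue-level binary cross-entropy with Adam,
# per-epoch resampling with replacement, Gaussian feature-noise
# augmentation, early stopping on validation AUPRC, 5-fold cross-validation
# and ensemble-mean inference.

#' Training configuration
#'
#' @param batch_size graphs per optimisation step (default 32).
#' @param proteins_per_epoch proteins drawn with replacement per epoch
#'   (default 5000; scale down for desk-size datasets).
#' @param max_epochs maximum epochs (default 30).
#' @param patience early-stopping patience in epochs (default 8).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param adam_beta1,adam_beta2,adam_eps Adam moments (0.9, 0.98, 1e-9).
#' @param noise_sigma Gaussian feature-noise s.d. on the node features
#'   during training (default 0.1).
#' @param n_folds cross-validation folds (default 5).
#' @param monitor_metric validation metric for early stopping ("AUPRC").
#' @param seed RNG seed.
#' @return object of class `train_config`.
#' @export
train_config <- function(batch_size = 32L, proteins_per_epoch = 5000L,
                         max_epochs = 30L, patience = 8L,
                         learning_rate = 1e-3, adam_beta1 = 0.9,
                         adam_beta2 = 0.98, adam_eps = 1e-9,
                         noise_sigma = 0.1, n_folds = 5L,
                         monitor_metric = "AUPRC", seed = 1L) {
  if (patience > max_epochs) stop("patience must be <= max_epochs")
  if (n_folds < 2L) stop("n_folds must be >= 2")
  structure(list(batch_size = as.integer(batch_size),
                 proteins_per_epoch = as.integer(proteins_per_epoch),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 learning_rate = learning_rate,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 adam_eps = adam_eps, noise_sigma = noise_sigma,
                 n_folds = as.integer(n_folds),
                 monitor_metric = monitor_metric, seed = as.integer(seed)),
            class = "train_config")
}

#' Add Gaussian feature noise
#'
#' Returns H + elementwise Normal(0, sigma^2) noise drawn from the current
#' RNG state; used on node features during training only.
#'
#' @param H n x d matrix.
#' @param sigma noise standard deviation (>= 0).
#' @return perturbed matrix.
#' @export
add_feature_noise <- function(H, sigma) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(H)
  H + matrix(stats::rnorm(length(H), 0, sigma), nrow(H), ncol(H))
}

# ---- Adam over flattened parameters ---------------------------------------

adam_init <- function(params) {
  theta <- unlist(params, use.names = FALSE)
  list(m = numeric(length(theta)), v = numeric(length(theta)), t = 0L)
}

adam_step <- function(params, grads, state, cfg) {
  theta <- unlist(params, use.names = FALSE)
  g <- unlist(grads, use.names = FALSE)
  state$t <- state$t + 1L
  state$m <- cfg$adam_beta1 * state$m + (1 - cfg$adam_beta1) * g
  state$v <- cfg$adam_beta2 * state$v + (1 - cfg$adam_beta2) * g^2
  mhat <- state$m / (1 - cfg$adam_beta1^state$t)
  vhat <- state$v / (1 - cfg$adam_beta2^state$t)
  theta <- theta - cfg$learning_rate * mhat / (sqrt(vhat) + cfg$adam_eps)
  list(params = relist_params(theta, params), state = state)
}

eval_metric <- function(params, graphs, config, metric = "AUPRC") {
  y <- unlist(lapply(graphs, function(g) g$labels))
  s <- unlist(lapply(graphs, function(g) model_forward(g, params, config)))
  switch(metric,
         AUPRC = pr_auc(y, s),
         AUC = roc_auc(y, s),
         stop("unknown monitor metric: ", metric))
}

#' Train one model on a train/validation split
#'
#' Each epoch draws `proteins_per_epoch` proteins with replacement from the
#' training set, iterates over them in batches of `batch_size` graphs with
#' fresh Gaussian feature noise per presentation, and minimises residue
#' binary cross-entropy with Adam. The validation monitor metric is
#' evaluated each epoch; training stops after `patience` epochs without
#' improvement or at `max_epochs`, returning the best-epoch parameters.
#'
#' @param train_graphs,val_graphs lists of labelled `protein_graph` objects
#'   (disjoint protein sets).
#' @param model_cfg a [bindgraph_config()].
#' @param train_cfg a [train_config()].
#' @param verbose print per-epoch progress.
#' @return list(params, history) where history is a data.frame with epoch,
#'   loss and validation metric.
#' @export
train_fold <- function(train_graphs, val_graphs, model_cfg, train_cfg,
                       verbose = FALSE) {
  if (length(train_graphs) == 0L || length(val_graphs) == 0L)
    stop("empty train or validation set")
  vy <- unlist(lapply(val_graphs, function(g) g$labels))
  if (length(unique(vy)) < 2L)
    stop("validation labels are one-class; the monitor metric is undefined ",
         "- use a different split")
  set.seed(derive_seed(train_cfg$seed, "train"))
  params <- init_model(model_cfg)
  state <- adam_init(params)
  best <- list(metric = -Inf, params = params, epoch = 0L)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_metric = numeric(0))
  stale <- 0L
  npp <- min(train_cfg$proteins_per_epoch, max(length(train_graphs),
                                               train_cfg$batch_size))
  for (epoch in seq_len(train_cfg$max_epochs)) {
    idx <- sample.int(length(train_graphs), npp, replace = TRUE)
    nb <- ceiling(length(idx) / train_cfg$batch_size)
    ep_loss <- 0
    for (b in seq_len(nb)) {
      bidx <- idx[((b - 1L) * train_cfg$batch_size + 1L):
                    min(b * train_cfg$batch_size, length(idx))]
      graphs <- train_graphs[bidx]
      H_list <- lapply(graphs, function(g)
        add_feature_noise(g$H, train_cfg$noise_sigma))
      lg <- model_loss_grad(params, graphs, model_cfg, train_mode = TRUE,
                            H_list = H_list)
      st <- adam_step(params, lg$grads, state, train_cfg)
      params <- st$params; state <- st$state
      ep_loss <- ep_loss + lg$loss * length(bidx)
    }
    ep_loss <- ep_loss / length(idx)
    vm <- eval_metric(params, val_graphs, model_cfg, train_cfg$monitor_metric)
    history <- rbind(history, data.frame(epoch = epoch, loss = ep_loss,
                                         val_metric = vm))
    if (verbose)
      message(sprintf("epoch %3d  loss %.5f  val %s %.4f", epoch, ep_loss,
                      train_cfg$monitor_metric, vm))
    if (vm > best$metric + 1e-12) {
      best <- list(metric = vm, params = params, epoch = epoch)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= train_cfg$patience) break
    }
  }
  list(params = best$params, history = history, best_epoch = best$epoch,
       best_metric = best$metric)
}

#' Protein-level cross-validation fold assignment
#'
#' @param ids character vector of protein ids.
#' @param n_folds number of folds.
#' @param seed RNG seed; assignment is a deterministic function of
#'   (ids, seed).
#' @return integer fold index per protein, each in 1..n_folds.
#' @export
assign_folds <- function(ids, n_folds, seed) {
  n <- length(ids)
  if (n < n_folds) stop("fewer proteins (", n, ") than folds (", n_folds, ")")
  set.seed(derive_seed(seed, "folds"))
  folds <- rep(seq_len(n_folds), length.out = n)
  sample(folds)
}

#' Cross-validated training of the full ensemble
#'
#' Assigns proteins (not residues) to `n_folds` folds, trains one model per
#' fold with [train_fold()], and returns the ensemble together with
#' per-fold validation metrics (mean and standard deviation) and the
#' median of the per-fold MCC-maximising validation thresholds.
#'
#' @param graphs list of labelled `protein_graph` objects.
#' @param model_cfg a [bindgraph_config()].
#' @param train_cfg a [train_config()].
#' @param verbose print progress.
#' @return list(members, fold_assignment, cv_table, threshold).
#' @export
cross_validate <- function(graphs, model_cfg, train_cfg, verbose = FALSE) {
  ids <- vapply(graphs, function(g) g$id, "")
  folds <- assign_folds(ids, train_cfg$n_folds, train_cfg$seed)
  members <- vector("list", train_cfg$n_folds)
  rows <- list()
  thresholds <- numeric(train_cfg$n_folds)
  for (f in seq_len(train_cfg$n_folds)) {
    tr <- graphs[folds != f]
    va <- graphs[folds == f]
    fold_cfg <- train_cfg
    fold_cfg$seed <- derive_seed(train_cfg$seed, "fold_seed", f)
    fit <- train_fold(tr, va, model_cfg, fold_cfg, verbose = verbose)
    vy <- unlist(lapply(va, function(g) g$labels))
    vs <- unlist(lapply(va, function(g) model_forward(g, fit$params, model_cfg)))
    thr <- optimal_threshold_by_mcc(vy, vs)
    thresholds[f] <- thr$threshold
    rows[[f]] <- data.frame(fold = f, AUPRC = pr_auc(vy, vs),
                            AUC = roc_auc(vy, vs), MCC = thr$mcc,
                            best_epoch = fit$best_epoch)
    members[[f]] <- list(params = fit$params, fold = f, history = fit$history)
    if (verbose) message(sprintf("fold %d: val AUPRC %.4f AUC %.4f", f,
                                 rows[[f]]$AUPRC, rows[[f]]$AUC))
  }
  cv_table <- do.call(rbind, rows)
  list(members = members, fold_assignment = folds, cv_table = cv_table,
       threshold = stats::median(thresholds))
}

#' Ensemble-mean prediction for one graph
#'
#' @param members list of fold members (each with `$params`).
#' @param graph a `protein_graph` whose node features were normalised with
#'   the ensemble's stored statistics.
#' @param model_cfg the [bindgraph_config()].
#' @return numeric n-vector of probabilities (arithmetic member mean).
#' @export
ensemble_predict <- function(members, graph, model_cfg) {
  if (length(members) == 0L) stop("empty ensemble")
  preds <- lapply(members, function(m) model_forward(graph, m$params, model_cfg))
  Reduce(`+`, preds) / length(preds)
}
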