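# Edge-aware Graph Transformer: multi-head attention in which the key and
# value of every neighbour are concatenated with the edge features, a
# position-wise feed-forward block with pre-layer normalisation, and a
# sigmoid head producing per-residue binding probabilities. Forward and
# backward passes are implemented in vectorised base R; gradients are
# validated by finite differences in the test suite.

#' Model configuration
#'
#' @param num_layers number of Graph Transformer layers (default 4).
#' @param num_heads attention heads (default 4); must divide `hidden_dim`.
#' @param hidden_dim hidden width d (default 64).
#' @param dropout dropout rate in \[0, 1) (default 0.2), applied to attention
#'   weights and the feed-forward output during training.
#' @param input_dim node feature dimension (embedding dim + 14).
#' @param edge_dim edge feature dimension (23 spatial + positional dim).
#' @param ffn_multiplier feed-forward expansion factor (default 4).
#' @param use_ffn include the position-wise feed-forward block.
#' @param head_hidden optional hidden width of the prediction head
#'   (0 = single linear layer + sigmoid, the default).
#' @param seed RNG seed for parameter initialisation.
#' @return object of class `bindgraph_config`.
#' @export
bindgraph_config <- function(num_layers = 4L, num_heads = 4L, hidden_dim = 64L,
                             dropout = 0.2, input_dim = 1038L, edge_dim = 39L,
                             ffn_multiplier = 4L, use_ffn = TRUE,
                             head_hidden = 0L, seed = 1L) {
  if (hidden_dim %% num_heads != 0L) stop("hidden_dim must be divisible by num_heads")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(list(num_layers = as.integer(num_layers),
                 num_heads = as.integer(num_heads),
                 hidden_dim = as.integer(hidden_dim),
                 dropout = dropout,
                 input_dim = as.integer(input_dim),
                 edge_dim = as.integer(edge_dim),
                 ffn_multiplier = as.integer(ffn_multiplier),
                 use_ffn = isTRUE(use_ffn),
                 head_hidden = as.integer(head_hidden),
                 seed = as.integer(seed)),
            class = "bindgraph_config")
}

glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

#' Initialise model parameters
#'
#' Weights are drawn with fan-in/fan-out scaled uniform initialisation from
#' the seed in the config; the same seed always yields identical parameters.
#'
#' @param config a [bindgraph_config()].
#' @return nested list of parameter arrays (class `bindgraph_params`).
#' @export
init_model <- function(config) {
  set.seed(config$seed)
  d <- config$hidden_dim
  h <- config$num_heads
  ed <- config$edge_dim
  fd <- d * config$ffn_multiplier
  layer <- function() {
    lp <- list(ln1_g = rep(1, d), ln1_b = rep(0, d),
               W_Q = glorot(d, d),
               W_K = glorot(d + ed, d),
               W_V = glorot(d, d),
               W_O = glorot(d + h * ed, d), b_O = rep(0, d))
    if (config$use_ffn) {
      lp <- c(lp, list(ln2_g = rep(1, d), ln2_b = rep(0, d),
                       W_F1 = glorot(d, fd), b_F1 = rep(0, fd),
                       W_F2 = glorot(fd, d), b_F2 = rep(0, d)))
    }
    lp
  }
  params <- list(w_in = glorot(config$input_dim, d), b_in = rep(0, d),
                 layers = lapply(seq_len(config$num_layers), function(l) layer()),
                 ln_f_g = rep(1, d), ln_f_b = rep(0, d))
  if (config$head_hidden > 0L) {
    params$w_h1 <- glorot(d, config$head_hidden)
    params$b_h1 <- rep(0, config$head_hidden)
    params$w_head <- glorot(config$head_hidden, 1L)
  } else {
    params$w_head <- glorot(d, 1L)
  }
  params$b_head <- 0
  class(params) <- "bindgraph_params"
  params
}

# ---- layer normalisation --------------------------------------------------

ln_fwd <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + 1e-5)
  xhat <- xc * inv
  Y <- sweep(xhat, 2, g, "*")
  Y <- sweep(Y, 2, b, "+")
  list(Y = Y, xhat = xhat, inv = inv)
}

ln_bwd <- function(dY, cache, g) {
  xhat <- cache$xhat
  dxhat <- sweep(dY, 2, g, "*")
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dX <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * cache$inv
  list(dX = dX, dg = dg, db = db)
}

# Sum a ne x m matrix over each target node's contiguous block of deg rows,
# returning n x m. Sets dim in place on the freshly allocated input.
block_rowsum <- function(x, deg, n, m) {
  dim(x) <- c(deg, n, m)
  colSums(x, dims = 1)
}

# Per-graph constants shared by every layer of a forward/backward pass.
graph_workspace <- function(graph, config) {
  d <- config$hidden_dim
  h <- config$num_heads
  d_h <- d %/% h
  ed <- ncol(graph$E)
  if (ed != config$edge_dim)
    stop("graph edge feature dim (", ed, ") != config edge_dim (", config$edge_dim, ")")
  Bv <- matrix(0, d, h)
  Bv[cbind(seq_len(d), rep(seq_len(h), each = d_h))] <- 1
  Be <- matrix(0, h * ed, h)
  Be[cbind(seq_len(h * ed), rep(seq_len(h), each = ed))] <- 1
  list(i = graph$target, j = graph$source, deg = graph$deg,
       n = nrow(graph$H), h = h, d = d, d_h = d_h, ed = ed,
       E = graph$E, EE = graph$E[, rep(seq_len(ed), times = h), drop = FALSE],
       Bv = Bv, Be = Be,
       headV = rep(seq_len(h), each = d_h),
       headE = rep(seq_len(h), each = ed))
}

# Workspace memoised per graph (reference-semantics cache environment),
# keyed on the head/width geometry so a config change rebuilds it.
get_workspace <- function(graph, config) {
  env <- graph$cache
  key <- paste(config$num_heads, config$hidden_dim, config$edge_dim, sep = "/")
  if (is.environment(env)) {
    if (identical(env$key, key)) return(env$ws)
    ws <- graph_workspace(graph, config)
    env$ws <- ws
    env$key <- key
    return(ws)
  }
  graph_workspace(graph, config)
}

colmax_blocks <- function(M) {
  # column maxima of a (deg x m) matrix without apply() overhead
  do.call(pmax, lapply(seq_len(nrow(M)), function(r) M[r, ]))
}

#' One edge-aware attention layer
#'
#' Applies pre-layer normalisation, multi-head attention in which keys and
#' values are the concatenation of the neighbour's hidden state and the edge
#' features (scores scaled by 1/sqrt(d_h), softmax over each node's
#' in-neighbourhood including the self-loop), a residual connection, and an
#' optional position-wise feed-forward block with its own residual.
#'
#' @param H n x d hidden state matrix.
#' @param graph a `protein_graph`.
#' @param layer_params one element of `params$layers` from [init_model()].
#' @param config the [bindgraph_config()].
#' @param train_mode apply dropout (uses the current RNG state).
#' @return updated n x d matrix.
#' @export
attention_layer <- function(H, graph, layer_params, config, train_mode = FALSE) {
  ws <- graph_workspace(graph, config)
  layer_fwd(H, layer_params, ws, config, train_mode)$H
}

layer_fwd <- function(H, lp, ws, config, train_mode) {
  p <- if (train_mode) config$dropout else 0
  i <- ws$i; j <- ws$j; deg <- ws$deg; n <- ws$n
  d <- ws$d; h <- ws$h; d_h <- ws$d_h; ed <- ws$ed

  l1 <- ln_fwd(H, lp$ln1_g, lp$ln1_b)
  Hn <- l1$Y
  Q <- Hn %*% lp$W_Q
  Hnj <- Hn[j, , drop = FALSE]
  # key of edge (i,j) is W_K applied to [h_j || e_ij]; computed as a split
  # product to avoid materialising the concatenation
  K <- Hnj %*% lp$W_K[seq_len(d), , drop = FALSE] +
    ws$E %*% lp$W_K[d + seq_len(ed), , drop = FALSE]
  V <- Hn %*% lp$W_V
  VE <- V[j, , drop = FALSE]
  Qi <- Q[i, , drop = FALSE]
  scores <- ((Qi * K) %*% ws$Bv) / sqrt(d_h)
  dim(scores) <- c(deg, n * h)
  sc2 <- scores
  mx <- colmax_blocks(sc2)
  ex <- exp(sc2 - rep(mx, each = deg))
  alpha2 <- ex / rep(colSums(ex), each = deg)
  alpha <- alpha2
  dim(alpha) <- c(deg * n, h)
  if (p > 0) {
    mask_a <- matrix(stats::runif(length(alpha)) >= p, nrow = nrow(alpha)) / (1 - p)
    alpha_d <- alpha * mask_a
  } else {
    mask_a <- NULL
    alpha_d <- alpha
  }
  aExpV <- alpha_d[, ws$headV, drop = FALSE]
  MV <- block_rowsum(VE * aExpV, deg, n, d)
  aExpE <- alpha_d[, ws$headE, drop = FALSE]
  ME <- block_rowsum(ws$EE * aExpE, deg, n, h * ed)
  M <- cbind(MV, ME)
  A <- sweep(M %*% lp$W_O, 2, lp$b_O, "+")
  H1 <- H + A

  cache <- list(l1 = l1, Hn = Hn, Q = Q, Qi = Qi, Hnj = Hnj, K = K, VE = VE,
                alpha2 = alpha2, mask_a = mask_a, aExpV = aExpV,
                aExpE = aExpE, M = M, H1 = H1)
  if (config$use_ffn) {
    l2 <- ln_fwd(H1, lp$ln2_g, lp$ln2_b)
    Z1 <- sweep(l2$Y %*% lp$W_F1, 2, lp$b_F1, "+")
    F1 <- pmax(Z1, 0)
    F2 <- sweep(F1 %*% lp$W_F2, 2, lp$b_F2, "+")
    if (p > 0) {
      mask_f <- matrix(stats::runif(length(F2)) >= p, nrow = n) / (1 - p)
      F2 <- F2 * mask_f
    } else mask_f <- NULL
    Hout <- H1 + F2
    cache <- c(cache, list(l2 = l2, Z1 = Z1, F1 = F1, mask_f = mask_f))
  } else {
    Hout <- H1
  }
  if (!all(is.finite(Hout))) stop("non-finite activations in attention layer")
  list(H = Hout, cache = cache)
}

layer_bwd <- function(dHout, lp, cache, ws, config) {
  i <- ws$i; j <- ws$j; deg <- ws$deg; n <- ws$n
  d <- ws$d; h <- ws$h; d_h <- ws$d_h; ed <- ws$ed
  g <- list()

  if (config$use_ffn) {
    dF2 <- if (!is.null(cache$mask_f)) dHout * cache$mask_f else dHout
    g$W_F2 <- crossprod(cache$F1, dF2)
    g$b_F2 <- colSums(dF2)
    dZ1 <- tcrossprod(dF2, lp$W_F2) * (cache$Z1 > 0)
    g$W_F1 <- crossprod(cache$l2$Y, dZ1)
    g$b_F1 <- colSums(dZ1)
    lb2 <- ln_bwd(tcrossprod(dZ1, lp$W_F1), cache$l2, lp$ln2_g)
    g$ln2_g <- lb2$dg; g$ln2_b <- lb2$db
    dH1 <- dHout + lb2$dX
  } else {
    dH1 <- dHout
  }

  dA <- dH1
  g$W_O <- crossprod(cache$M, dA)
  g$b_O <- colSums(dA)
  dM <- tcrossprod(dA, lp$W_O)
  dMV <- dM[, seq_len(d), drop = FALSE]
  dME <- dM[, d + seq_len(h * ed), drop = FALSE]
  dMVi <- dMV[i, , drop = FALSE]
  dMEi <- dME[i, , drop = FALSE]
  # dalpha per head sums the per-column products over each head's block
  dalpha_d <- (dMVi * cache$VE) %*% ws$Bv + (dMEi * ws$EE) %*% ws$Be
  dVE <- dMVi * cache$aExpV
  dalpha <- if (!is.null(cache$mask_a)) dalpha_d * cache$mask_a else dalpha_d
  dim(dalpha) <- c(deg, n * h)
  ssum <- colSums(cache$alpha2 * dalpha)
  dscores <- cache$alpha2 * (dalpha - rep(ssum, each = deg)) / sqrt(d_h)
  dim(dscores) <- c(deg * n, h)
  dS <- dscores[, ws$headV, drop = FALSE]
  dQ <- block_rowsum(dS * cache$K, deg, n, d)
  dK <- dS * cache$Qi
  g$W_K <- rbind(crossprod(cache$Hnj, dK), crossprod(ws$E, dK))
  dHn_j <- unname(rowsum(
    tcrossprod(dK, lp$W_K[seq_len(d), , drop = FALSE]), j))
  dV <- unname(rowsum(dVE, j))
  g$W_V <- crossprod(cache$Hn, dV)
  g$W_Q <- crossprod(cache$Hn, dQ)
  dHn <- tcrossprod(dQ, lp$W_Q) + dHn_j + tcrossprod(dV, lp$W_V)
  lb1 <- ln_bwd(dHn, cache$l1, lp$ln1_g)
  g$ln1_g <- lb1$dg; g$ln1_b <- lb1$db
  list(dH = dH1 + lb1$dX, grads = g[names(lp)])
}

#' Forward pass of the full model
#'
#' Input projection, `num_layers` edge-aware attention layers, final layer
#' normalisation, and the sigmoid prediction head. Eval mode (the default)
#' is deterministic; train mode applies dropout using the current RNG state.
#'
#' @param graph a `protein_graph` from [build_protein_graph()].
#' @param params model parameters from [init_model()].
#' @param config the matching [bindgraph_config()].
#' @param train_mode apply dropout.
#' @param H optional replacement node feature matrix (used for Gaussian
#'   feature-noise augmentation during training).
#' @return numeric n-vector of probabilities strictly inside (0, 1).
#' @export
model_forward <- function(graph, params, config, train_mode = FALSE, H = NULL) {
  fw <- model_fwd_full(graph, params, config, train_mode, H)
  fw$prob
}

model_fwd_full <- function(graph, params, config, train_mode = FALSE, H = NULL) {
  X <- if (is.null(H)) graph$H else H
  if (ncol(X) != config$input_dim)
    stop("node feature dim (", ncol(X), ") != config input_dim (",
         config$input_dim, ")")
  ws <- get_workspace(graph, config)
  H0 <- sweep(X %*% params$w_in, 2, params$b_in, "+")
  caches <- vector("list", config$num_layers)
  Hc <- H0
  for (l in seq_len(config$num_layers)) {
    st <- layer_fwd(Hc, params$layers[[l]], ws, config, train_mode)
    caches[[l]] <- st$cache
    Hc <- st$H
  }
  lf <- ln_fwd(Hc, params$ln_f_g, params$ln_f_b)
  if (config$head_hidden > 0L) {
    Zh <- sweep(lf$Y %*% params$w_h1, 2, params$b_h1, "+")
    Ah <- pmax(Zh, 0)
    z <- drop(Ah %*% params$w_head) + params$b_head
    head_cache <- list(Zh = Zh, Ah = Ah)
  } else {
    z <- drop(lf$Y %*% params$w_head) + params$b_head
    head_cache <- NULL
  }
  if (!all(is.finite(z))) stop("non-finite model output")
  list(prob = stats::plogis(z), z = z, X = X, ws = ws, H0 = H0,
       caches = caches, lf = lf, head_cache = head_cache)
}

# Backward pass given dL/dz; returns gradients in the shape of params.
model_bwd_full <- function(fw, dz, params, config) {
  g <- list()
  n <- length(dz)
  if (config$head_hidden > 0L) {
    g$w_head <- crossprod(fw$head_cache$Ah, dz)
    g$b_head <- sum(dz)
    dAh <- matrix(dz, ncol = 1) %*% t(params$w_head) # n x m
    dZh <- dAh * (fw$head_cache$Zh > 0)
    g$w_h1 <- crossprod(fw$lf$Y, dZh)
    g$b_h1 <- colSums(dZh)
    dY <- tcrossprod(dZh, params$w_h1)
  } else {
    g$w_head <- crossprod(fw$lf$Y, matrix(dz, ncol = 1))
    g$b_head <- sum(dz)
    dY <- matrix(dz, ncol = 1) %*% t(params$w_head)
  }
  lbf <- ln_bwd(dY, fw$lf, params$ln_f_g)
  g$ln_f_g <- lbf$dg; g$ln_f_b <- lbf$db
  dH <- lbf$dX
  g$layers <- vector("list", config$num_layers)
  for (l in rev(seq_len(config$num_layers))) {
    bk <- layer_bwd(dH, params$layers[[l]], fw$caches[[l]], fw$ws, config)
    g$layers[[l]] <- bk$grads
    dH <- bk$dH
  }
  g$w_in <- crossprod(fw$X, dH)
  g$b_in <- colSums(dH)
  g[names(params)]
}

# Numerically stable binary cross-entropy from logits.
bce_from_logits <- function(z, y) {
  mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
}

#' Loss and gradients over a batch of graphs
#'
#' Mean residue-level binary cross-entropy across all residues of the batch,
#' with analytic gradients from the hand-derived backward pass.
#'
#' @param params model parameters.
#' @param graphs list of `protein_graph` objects with labels.
#' @param config the [bindgraph_config()].
#' @param train_mode apply dropout.
#' @param H_list optional list of replacement node feature matrices
#'   (noise-augmented copies), parallel to `graphs`.
#' @param compute_grads return gradients as well as the loss.
#' @return list(loss, grads) where `grads` mirrors the parameter structure.
#' @export
model_loss_grad <- function(params, graphs, config, train_mode = FALSE,
                            H_list = NULL, compute_grads = TRUE) {
  ntot <- sum(vapply(graphs, function(g) nrow(g$H), 0))
  loss <- 0
  grads <- NULL
  for (gi in seq_along(graphs)) {
    gr <- graphs[[gi]]
    y <- gr$labels
    if (is.null(y)) stop("graph ", gr$id, " has no labels")
    fw <- model_fwd_full(gr, params, config, train_mode,
                         H = if (is.null(H_list)) NULL else H_list[[gi]])
    ni <- length(y)
    loss <- loss + bce_from_logits(fw$z, y) * ni / ntot
    if (compute_grads) {
      dz <- (fw$prob - y) / ntot
      gb <- model_bwd_full(fw, dz, params, config)
      grads <- if (is.null(grads)) gb else add_params(grads, gb)
    }
  }
  list(loss = loss, grads = grads)
}

# ---- nested parameter-list arithmetic -------------------------------------

# Rebuild a nested parameter list from a flat numeric vector.
relist_params <- function(theta, skeleton) {
  p <- utils::relist(theta, unclass(skeleton))
  class(p) <- "bindgraph_params"
  p
}

add_params <- function(a, b) {
  if (is.list(a)) {
    out <- mapply(add_params, a, b, SIMPLIFY = FALSE)
    attributes(out) <- attributes(a)
    out
  } else a + b
}

#' @export
print.bindgraph_params <- function(x, ...) {
  npar <- length(unlist(x))
  cat("bindgraph model parameters:", npar, "weights\n")
  invisible(x)
}
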