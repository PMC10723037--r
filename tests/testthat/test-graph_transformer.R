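test_that("config validates architecture constraints and defaults match", {
  cfg <- bindgraph_config()
  expect_equal(cfg$num_layers, 4L)
  expect_equal(cfg$num_heads, 4L)
  expect_equal(cfg$hidden_dim, 64L)
  expect_equal(cfg$dropout, 0.2)
  expect_error(bindgraph_config(hidden_dim = 30, num_heads = 4), "divisible")
  expect_error(bindgraph_config(dropout = 1), "dropout")
})

test_that("initialisation is a deterministic function of the seed", {
  cfg <- bindgraph_config(num_layers = 2, num_heads = 2, hidden_dim = 8,
                          input_dim = 10, edge_dim = 12, seed = 5)
  p1 <- init_model(cfg)
  p2 <- init_model(cfg)
  expect_identical(unlist(p1), unlist(p2))
  cfg$seed <- 6L
  p3 <- init_model(cfg)
  expect_gt(max(abs(unlist(p1) - unlist(p3))), 0)
})

test_that("zero weights and bias give probability one half everywhere", {
  ds <- small_dataset(n_proteins = 1, seed = 31)
  g <- small_graphs(ds)[[1]]
  cfg <- small_config(list(g))
  params <- init_model(cfg)
  params <- bindgraph:::relist_params(0 * unlist(params), params)
  p <- model_forward(g, params, cfg)
  expect_equal(p, rep(0.5, nrow(g$H)))
})

test_that("attention rows are a softmax: weights sum to one per node and head", {
  ds <- small_dataset(n_proteins = 1, seed = 32)
  g <- small_graphs(ds)[[1]]
  cfg <- small_config(list(g))
  params <- init_model(cfg)
  # recompute attention weights by the definition and check normalisation
  ws <- bindgraph:::graph_workspace(g, cfg)
  H0 <- sweep(g$H %*% params$w_in, 2, params$b_in, "+")
  st <- bindgraph:::layer_fwd(H0, params$layers[[1]], ws, cfg, FALSE)
  alpha2 <- st$cache$alpha2  # deg x (n * heads)
  expect_equal(colSums(alpha2), rep(1, ncol(alpha2)), tolerance = 1e-6)
  # single node with only a self-loop: alpha = 1 exactly
  g1 <- g
  g1$target <- 1L; g1$source <- 1L; g1$deg <- 1L
  g1$E <- g$E[1, , drop = FALSE] * 0
  g1$H <- g$H[1, , drop = FALSE]
  g1$cache <- new.env(parent = emptyenv())
  ws1 <- bindgraph:::graph_workspace(g1, cfg)
  st1 <- bindgraph:::layer_fwd(H0[1, , drop = FALSE], params$layers[[1]],
                               ws1, cfg, FALSE)
  expect_equal(as.vector(st1$cache$alpha2), rep(1, cfg$num_heads))
})

test_that("the forward pass is permutation-equivariant", {
  ds <- small_dataset(n_proteins = 1, seed = 33)
  g <- small_graphs(ds)[[1]]
  cfg <- small_config(list(g))
  params <- init_model(cfg)
  p0 <- model_forward(g, params, cfg)
  n <- nrow(g$H)
  set.seed(1)
  perm <- sample(n)
  inv <- order(perm)
  # relabel nodes: node i becomes position inv[i]
  gp <- g
  gp$H <- g$H[perm, , drop = FALSE]
  gp$labels <- g$labels[perm]
  # rebuild edge list in the permuted labelling, keeping block layout
  new_of_old <- inv
  ord <- order(new_of_old[g$target])
  gp$target <- new_of_old[g$target][ord]
  gp$source <- new_of_old[g$source][ord]
  gp$E <- g$E[ord, , drop = FALSE]
  gp$cache <- new.env(parent = emptyenv())
  pp <- model_forward(gp, params, cfg)
  expect_equal(pp, p0[perm], tolerance = 1e-10)
})

test_that("predictions are SE(3)-invariant end to end", {
  ds <- small_dataset(n_proteins = 2, seed = 34)
  graphs <- small_graphs(ds)
  cfg <- small_config(graphs)
  params <- init_model(cfg)
  p0 <- lapply(graphs, function(g) model_forward(g, params, cfg))
  set.seed(2)
  for (r in 1:3) {
    ds2 <- rigid_transform_dataset(ds, random_rotation(), rnorm(3) * 15)
    g2 <- small_graphs(ds2)
    for (k in 1:2) {
      expect_equal(model_forward(g2[[k]], params, cfg), p0[[k]],
                   tolerance = 1e-5)
    }
  }
})

test_that("eval mode is deterministic; train mode dropout is stochastic", {
  ds <- small_dataset(n_proteins = 1, seed = 35)
  g <- small_graphs(ds)[[1]]
  cfg <- small_config(list(g), dropout = 0.3)
  params <- init_model(cfg)
  expect_identical(model_forward(g, params, cfg),
                   model_forward(g, params, cfg))
  set.seed(7)
  a <- model_forward(g, params, cfg, train_mode = TRUE)
  b <- model_forward(g, params, cfg, train_mode = TRUE)
  expect_gt(max(abs(a - b)), 0)
  # same RNG state gives identical dropout
  set.seed(7)
  a2 <- model_forward(g, params, cfg, train_mode = TRUE)
  expect_identical(a, a2)
})

test_that("analytic gradients agree with central finite differences", {
  ds <- small_dataset(n_proteins = 1, seed = 36, lengths = c(25, 25))
  graphs <- small_graphs(ds, k = 6, pos_dim = 4)
  cfg <- small_config(graphs, num_layers = 2, num_heads = 2, hidden_dim = 8)
  params <- init_model(cfg)
  lg <- model_loss_grad(params, graphs, cfg)
  theta <- unlist(params)
  gvec <- unlist(lg$grads)
  expect_equal(length(theta), length(gvec))
  set.seed(8)
  idx <- sample(length(theta), 50)
  h <- 1e-5
  rel_err <- vapply(idx, function(k) {
    tp <- theta; tp[k] <- tp[k] + h
    tm <- theta; tm[k] <- tm[k] - h
    lp <- model_loss_grad(bindgraph:::relist_params(tp, params), graphs, cfg,
                          compute_grads = FALSE)$loss
    lm <- model_loss_grad(bindgraph:::relist_params(tm, params), graphs, cfg,
                          compute_grads = FALSE)$loss
    num <- (lp - lm) / (2 * h)
    abs(num - gvec[k]) / max(1e-6, abs(num) + abs(gvec[k]))
  }, 0)
  expect_lt(max(rel_err), 1e-4)
})

test_that("dimension mismatches fail loudly", {
  ds <- small_dataset(n_proteins = 1, seed = 37)
  g <- small_graphs(ds)[[1]]
  cfg <- small_config(list(g))
  cfg$input_dim <- cfg$input_dim + 1L
  params <- bindgraph_config(num_layers = 1, num_heads = 2, hidden_dim = 8,
                             input_dim = 5, edge_dim = ncol(g$E))
  expect_error(model_forward(g, init_model(params), params), "input_dim")
})

test_that("the optional hidden head layer is exercised when configured", {
  ds <- small_dataset(n_proteins = 1, seed = 38)
  g <- small_graphs(ds)[[1]]
  cfg <- small_config(list(g), head_hidden = 6L)
  params <- init_model(cfg)
  p <- model_forward(g, params, cfg)
  expect_true(all(p > 0 & p < 1))
  # gradient check through the hidden head
  lg <- model_loss_grad(params, list(g), cfg)
  theta <- unlist(params); gvec <- unlist(lg$grads)
  set.seed(9); idx <- sample(length(theta), 15); h <- 1e-5
  rel_err <- vapply(idx, function(k) {
    tp <- theta; tp[k] <- tp[k] + h
    tm <- theta; tm[k] <- tm[k] - h
    num <- (model_loss_grad(bindgraph:::relist_params(tp, params), list(g),
                            cfg, compute_grads = FALSE)$loss -
            model_loss_grad(bindgraph:::relist_params(tm, params), list(g),
                            cfg, compute_grads = FALSE)$loss) / (2 * h)
    abs(num - gvec[k]) / max(1e-6, abs(num) + abs(gvec[k]))
  }, 0)
  expect_lt(max(rel_err), 1e-4)
})
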