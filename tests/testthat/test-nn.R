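# Network primitives: gated update contract, pooling menu, and analytic
# gradients verified against numerical differentiation.

tiny_graphs <- function() {
  gs <- cached_graphs(8, seed = 41)
  for (i in seq_along(gs)) gs[[i]]$dG <- gs[[i]]$dG  # labelled already
  gs
}

tiny_setup <- function(pooling, d = 5L, layers = 2L, seed = 7L) {
  cfg <- model_config(embedding = d, conv_layers = layers, pooling = pooling,
                      head_hidden = 4L, seed = 3L)
  dims <- feature_dims()
  set.seed(seed)
  params <- hydrolyzer:::init_params(cfg, dims$atom, dims$bond + 3L, dims$global)
  list(cfg = cfg, params = params)
}

test_that("a layer with zero candidate weights is the identity map", {
  gs <- tiny_graphs()
  st <- tiny_setup("mean")
  batch <- batch_graphs(gs[1:3])
  p0 <- st$params
  d <- st$cfg$embedding
  for (l in seq_along(p0$layers)) {
    for (blk in c("bond", "atom", "glob")) {
      p0$layers[[l]][[blk]]$W[, d + seq_len(d)] <- 0   # candidate half
      p0$layers[[l]][[blk]]$b[d + seq_len(d)] <- 0
    }
  }
  fw <- hydrolyzer:::nn_forward(p0, batch, st$cfg)
  # with tanh(0) candidates every gated residual vanishes: the node states
  # after L layers equal the raw embeddings
  embA <- sweep(batch$A %*% p0$embed$Wa, 2, p0$embed$ba, `+`)
  expect_equal(fw$HA, embA, tolerance = 1e-12)
})

test_that("analytic gradients match numerical differentiation for every pooling", {
  gs <- tiny_graphs()
  batch <- batch_graphs(gs[1:4])
  for (pool in c("mean", "weighted_mean", "self_attention", "set2set")) {
    st <- tiny_setup(pool)
    params <- st$params; cfg <- st$cfg
    loss_fn <- function(flat, skel) {
      p <- hydrolyzer:::unflatten_params(flat, skel)
      fw <- hydrolyzer:::nn_forward(p, batch, cfg)
      mean((fw$yhat - batch$y)^2)
    }
    skel <- hydrolyzer:::param_skeleton(params)
    flat <- hydrolyzer:::flatten_params(params)
    fw <- hydrolyzer:::nn_forward(params, batch, cfg)
    dy <- 2 * (fw$yhat - batch$y) / length(batch$y)
    gr <- hydrolyzer:::flatten_params(
      hydrolyzer:::nn_backward(params, batch, cfg, fw, dy))
    set.seed(5)
    idx <- sample(length(flat), 40L)
    num <- vapply(idx, function(i) {
      e <- 1e-4
      f1 <- flat; f1[i] <- f1[i] + e
      f2 <- flat; f2[i] <- f2[i] - e
      (loss_fn(f1, skel) - loss_fn(f2, skel)) / (2 * e)
    }, numeric(1))
    denom <- pmax(1e-3, abs(num), abs(gr[idx]))
    expect_lt(max(abs(num - gr[idx]) / denom), 1e-4)
  }
})

test_that("pooling obeys its defining arithmetic", {
  # two-node mean: (f1 + f2) / 2
  H <- rbind(c(1, 2, 3), c(5, 6, 7))
  batchish <- list(ga = c(1L, 1L), gb = integer(0))
  pf <- hydrolyzer:::pool_forward(list(), "mean", H, matrix(0, 0, 3), batchish, 1L)
  expect_equal(as.numeric(pf$p), c(3, 4, 5))

  # weighted mean with equal weights (u = 0) equals mean pooling
  pf2 <- hydrolyzer:::pool_forward(list(u = matrix(0, 3, 1), c = 0),
                                   "weighted_mean", H, matrix(0, 0, 3),
                                   batchish, 1L)
  expect_equal(pf2$p, pf$p, tolerance = 1e-12)

  # uniform self-attention (u = 0) also reduces to the mean
  pf3 <- hydrolyzer:::pool_forward(list(u = matrix(0, 3, 1), c = 0),
                                   "self_attention", H, matrix(0, 0, 3),
                                   batchish, 1L)
  expect_equal(pf3$p, pf$p, tolerance = 1e-12)
})

test_that("set2set on a single node matches a step-by-step oracle", {
  d <- 3L
  set.seed(21)
  pp <- list(Wl = matrix(rnorm(2 * d * 4 * d, sd = 0.3), 2 * d, 4 * d),
             Ul = matrix(rnorm(d * 4 * d, sd = 0.3), d, 4 * d),
             bl = rnorm(4 * d, sd = 0.1))
  H <- matrix(c(0.5, -1, 2), 1, d)
  batchish <- list(ga = 1L, gb = integer(0))
  pf <- hydrolyzer:::pool_forward(pp, "set2set", H, matrix(0, 0, d), batchish, 1L)

  # independent re-implementation: explicit scalar LSTM + attention; with a
  # single node the softmax weight is exactly 1 and r_t = H
  sig <- function(x) 1 / (1 + exp(-x))
  h <- rep(0, d); cs <- rep(0, d); qstar <- rep(0, 2 * d)
  for (t in 1:3) {
    zi <- as.numeric(qstar %*% pp$Wl) + as.numeric(h %*% pp$Ul) + pp$bl
    i_ <- sig(zi[1:d]); f_ <- sig(zi[d + 1:d])
    o_ <- sig(zi[2 * d + 1:d]); g_ <- tanh(zi[3 * d + 1:d])
    cs <- f_ * cs + i_ * g_
    h <- o_ * tanh(cs)
    qstar <- c(h, as.numeric(H))
  }
  expect_equal(as.numeric(pf$p), qstar, tolerance = 1e-12)
})

test_that("the forward pass is invariant under node relabeling", {
  gs <- cached_graphs(6, seed = 41)
  for (pool in c("mean", "set2set")) {
    st <- tiny_setup(pool, d = 6L)
    ref <- hydrolyzer:::nn_forward(st$params, batch_graphs(gs), st$cfg)$yhat
    for (k in 1:10) {
      perm <- lapply(seq_along(gs), function(i) permute_graph(gs[[i]], seed = k * 17 + i))
      out <- hydrolyzer:::nn_forward(st$params, batch_graphs(perm), st$cfg)$yhat
      expect_equal(out, ref, tolerance = 1e-10)
    }
  }
})

test_that("batched and one-at-a-time forward passes agree", {
  gs <- cached_graphs(5, seed = 41)
  st <- tiny_setup("mean", d = 6L)
  all_at_once <- hydrolyzer:::nn_forward(st$params, batch_graphs(gs), st$cfg)$yhat
  one_by_one <- vapply(gs, function(g)
    hydrolyzer:::nn_forward(st$params, batch_graphs(list(g)), st$cfg)$yhat,
    numeric(1))
  expect_equal(all_at_once, one_by_one, tolerance = 1e-10)
})
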