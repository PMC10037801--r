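test_that("convolutional fusion is the stated linear map of the channel tensor", {
  set.seed(71)
  v1 <- random_view(10, "mirna", "functional")
  v2 <- random_view(10, "mirna", "gip")
  tens <- build_proximity_tensor(list(v1, v2), alpha = 0.9, K = 3)
  W <- matrix(rnorm(10 * 4), 10, 4)
  b <- rnorm(4)
  out <- conv_fuse(tens, W, b)
  expect_equal(dim(out), c(10L, 4L))

  # all-zero tensor with zero bias gives zero output (linearity)
  zt <- tens
  zt$channels <- lapply(zt$channels, function(ch) ch * 0)
  expect_equal(conv_fuse(zt, W, rep(0, 4)), matrix(0, 10, 4))

  # one channel, one-hot filter selecting column j: output = column j + bias
  t1 <- build_proximity_tensor(list(v1), alpha = 0.9, K = 1)
  W1 <- matrix(0, 10, 1); W1[3, 1] <- 1
  expect_equal(conv_fuse(t1, W1, 0.25)[, 1], t1$channels[[1]][, 3] + 0.25,
               tolerance = 1e-12)

  # explicit oracle: filter responses summed over channels
  oracle <- matrix(b, 10, 4, byrow = TRUE)
  for (ch in tens$channels) oracle <- oracle + ch %*% W
  expect_equal(out, oracle, tolerance = 1e-12)
  expect_error(conv_fuse(t1, matrix(rnorm(32), 8, 4), b), "mismatch")
})

test_that("structure embeddings concatenate first-order and high-order blocks", {
  v1 <- random_view(5, "mirna", "functional")
  v2 <- random_view(5, "mirna", "gip")
  H <- matrix(rnorm(15), 5, 3)
  X <- concat_structure(v1, v2, H)
  expect_equal(ncol(X), 13L)                       # 5 + 5 + 3
  expect_equal(X[, 1:5], unclass(v1), ignore_attr = TRUE)
  expect_equal(X[, 11:13], H, ignore_attr = TRUE)
  expect_equal(ncol(concat_structure(v1, v2)), 10L)  # no high-order block
  X0 <- concat_structure(v1, v2, H * 0)
  expect_equal(X0[, 1:10], X[, 1:10])
  expect_error(concat_structure(v1, random_view(4, "mirna", "gip"), H),
               "mismatch")
})

test_that("node transformation stacks the two per-type projections", {
  set.seed(73)
  Xm <- matrix(rnorm(12), 3, 4)
  Yd <- matrix(rnorm(10), 2, 5)
  Wm <- matrix(rnorm(8), 4, 2)
  Wd <- matrix(rnorm(10), 5, 2)
  h <- transform_nodes(Xm, Yd, Wm, Wd)
  expect_equal(h, rbind(Xm %*% Wm, Yd %*% Wd))
  expect_equal(transform_nodes(Xm * 0, Yd * 0, Wm, Wd), matrix(0, 5, 2))
})

test_that("attention aggregation matches brute-force enumeration on toys", {
  # single neighbor: coefficient 1, output = activation of the neighbor
  h <- matrix(c(1, 0.5, -0.3, 0.2, 0.1, 0.8), 3, 2, byrow = TRUE)
  G <- matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 0), 3, 3)   # node 3 isolated
  out <- attention_aggregate(h, G, slope = 0.2, activation = "elu")
  expect_equal(out[1, ], ifelse(h[2, ] > 0, h[2, ], exp(h[2, ]) - 1),
               tolerance = 1e-12)
  expect_equal(attr(out, "attention")[1, 2], 1)
  expect_equal(out[3, ], c(0, 0))                   # isolated -> zero

  # two neighbors with equal scores get 0.5 / 0.5
  h2 <- rbind(c(1, 0), c(0, 1), c(0, 1))
  G2 <- matrix(0, 3, 3); G2[1, 2:3] <- 1; G2[2:3, 1] <- 1
  a2 <- attr(attention_aggregate(h2, G2), "attention")
  expect_equal(a2[1, 2:3], c(0.5, 0.5))

  # 3-node toy against explicit softmax-weighted sum
  set.seed(75)
  h3 <- matrix(rnorm(6), 3, 2)
  G3 <- matrix(0, 3, 3); G3[1, 2:3] <- 1; G3[2:3, 1] <- 1; G3[2, 3] <- 1; G3[3, 2] <- 1
  out3 <- attention_aggregate(h3, G3, slope = 0.2, activation = "elu")
  for (i in 1:3) {
    nb <- which(G3[i, ] == 1)
    e <- sapply(nb, function(j) {
      s <- sum(h3[i, ] * h3[j, ]); if (s > 0) s else 0.2 * s
    })
    a <- exp(e) / sum(exp(e))
    agg <- colSums(a * h3[nb, , drop = FALSE])
    expect_equal(out3[i, ], ifelse(agg > 0, agg, exp(agg) - 1),
                 tolerance = 1e-10)
    expect_equal(sum(attr(out3, "attention")[i, nb]), 1, tolerance = 1e-6)
  }
})

test_that("attention coefficients sum to one per connected node for every head", {
  set.seed(77)
  inst <- six_node_instance()
  cfg <- tiny_config()
  st <- init_model_state(cfg, 4, 2)
  pre <- mdapred:::.prepare_inputs(inst$A, list(inst$Fm, inst$gm),
                                   list(inst$Ds, inst$gd), cfg)
  G <- build_heterogeneous_adjacency(inst$A)
  for (l in seq_len(cfg$L)) {
    hp <- st$params$heads[[l]]
    Xt_m <- cbind(pre$F_m, sweep(pre$Xsum_m %*% st$params$conv_m$W, 2,
                                 -st$params$conv_m$b))
    Xt_d <- cbind(pre$F_d, sweep(pre$Xsum_d %*% st$params$conv_d$W, 2,
                                 -st$params$conv_d$b))
    h <- transform_nodes(Xt_m, Xt_d, hp$Wm, hp$Wd)
    attn <- attr(attention_aggregate(h, G), "attention")
    connected <- rowSums(G) > 0
    expect_equal(unname(rowSums(attn)[connected]),
                 rep(1, sum(connected)), tolerance = 1e-6)
    expect_true(all(rowSums(attn)[!connected] == 0))
  }
})

test_that("the neural aggregator concatenates its two affine branches", {
  set.seed(79)
  h <- matrix(rnorm(12), 4, 3)
  hN <- matrix(rnorm(12), 4, 3)
  W1 <- matrix(rnorm(18), 6, 3); b1 <- rnorm(3)
  W2 <- matrix(rnorm(9), 3, 3); b2 <- rnorm(3)
  Z <- neural_aggregate(h, hN, W1, b1, W2, b2)
  expect_equal(Z, cbind(cbind(h, hN) %*% W1 + matrix(b1, 4, 3, byrow = TRUE),
                        (h + hN) %*% W2 + matrix(b2, 4, 3, byrow = TRUE)),
               tolerance = 1e-12)
  expect_equal(neural_aggregate(h, hN, W1 * 0, b1 * 0, W2 * 0, b2 * 0),
               matrix(0, 4, 6))
  # hN = 0, identity W2, zero bias: branch 2 returns h
  expect_equal(neural_aggregate(h, hN * 0, W1, b1, diag(3), rep(0, 3))[, 4:6],
               h)
})

test_that("multi-head concatenation orders blocks by head and splits by type", {
  Z1 <- matrix(1, 5, 4); Z2 <- matrix(2, 5, 4)
  out <- multi_head_concat(list(Z1, Z2), nm = 3)
  expect_equal(dim(out$Zm), c(3L, 8L))
  expect_equal(dim(out$Zd), c(2L, 8L))
  expect_true(all(out$Zm[, 1:4] == 1) && all(out$Zm[, 5:8] == 2))
  one <- multi_head_concat(list(Z1), nm = 3)
  expect_equal(one$Zm, Z1[1:3, ])
  # permuting heads permutes column blocks only
  sw <- multi_head_concat(list(Z2, Z1), nm = 3)
  expect_equal(sw$Zm[, 1:4], out$Zm[, 5:8])
})

test_that("the decoder and loss follow their closed forms", {
  expect_true(all(decode(matrix(0, 2, 3), matrix(0, 4, 3)) == 0.5))
  # orthogonal unit rows decode to 0.5
  Zm <- rbind(c(1, 0)); Zd <- rbind(c(0, 1))
  expect_equal(decode(Zm, Zd)[1, 1], 0.5)
  set.seed(81)
  Zm2 <- matrix(rnorm(4), 2, 2); Zd2 <- matrix(rnorm(4), 2, 2)
  expect_equal(unclass(decode(Zm2, Zd2)),
               1 / (1 + exp(-Zm2 %*% t(Zd2))), tolerance = 1e-12)
  expect_true(all(decode(Zm2, Zd2) > 0 & decode(Zm2, Zd2) < 1))

  expect_equal(bce_loss(0.5, 1), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(0.5, 0), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(0.9, 1), -log(0.9), tolerance = 1e-12)
  # clamping keeps the loss finite at degenerate probabilities
  expect_true(is.finite(bce_loss(1, 0)))
  expect_true(is.finite(bce_loss(0, 1)))
})

test_that("training is deterministic given the seed and reduces the loss", {
  inst <- six_node_instance()
  cfg <- tiny_config(epochs = 2L)
  mv <- list(inst$Fm, inst$gm); dv <- list(inst$Ds, inst$gd)
  m1 <- mda_train(inst$A, mv, dv, cfg)
  m2 <- mda_train(inst$A, mv, dv, cfg)
  expect_identical(m1$log$loss, m2$log$loss)
  expect_identical(m1$state$params, m2$state$params)

  # sustained training on planted synthetic data reduces the loss
  d <- generate_dataset(synthetic_spec(nm = 20L, nd = 20L, rank = 2L,
                                       seed = 3L))
  cfg2 <- model_config(K = 2, C_out = 4, f_tran = 4, L = 2, epochs = 200L,
                       seed = 3L)
  m <- mda_train(d$A, list(d$mirna_functional,
                           gip_kernel(d$A, node_type = "mirna")),
                 list(d$disease_semantic,
                      gip_kernel(t(unclass(d$A)), node_type = "disease")),
                 cfg2)
  expect_lt(m$log$loss[200], m$log$loss[1])
})

test_that("analytic gradients agree with central differences on a 6-node instance", {
  inst <- six_node_instance()
  pairs <- cbind(c(1L, 2L, 3L, 4L, 1L), c(1L, 2L, 2L, 1L, 2L))
  labels <- c(1, 1, 1, 0, 0)
  for (variant in c("full", "no_high_order", "plain_gat")) {
    cfg <- tiny_config(variant = variant, seed = 3L)
    st <- init_model_state(cfg, 4, 2)
    pre <- mdapred:::.prepare_inputs(inst$A, list(inst$Fm, inst$gm),
                                     list(inst$Ds, inst$gd), cfg)
    res <- mdapred:::.loss_grad(st, pre, pairs, labels, cfg)
    paths <- mdapred:::.param_paths(st$params)
    set.seed(83)
    checked <- 0L
    for (p in paths) {
      g <- mdapred:::.pluck(res$grads, p)
      for (idx in sample(length(g), min(2, length(g)))) {
        num <- numeric_grad_at(st, pre, pairs, labels, cfg, p, idx)
        denom <- max(abs(num), abs(g[idx]), 1e-8)
        expect_lt(abs(num - g[idx]) / denom, 1e-4)
        checked <- checked + 1L
      }
    }
    expect_gte(checked, 10L)
  }
})

test_that("forward is deterministic and respects the variant widths", {
  inst <- six_node_instance()
  for (variant in c("full", "no_high_order", "integrated_similarity",
                    "plain_gat")) {
    cfg <- tiny_config(variant = variant)
    st <- init_model_state(cfg, 4, 2)
    A1 <- mda_forward(inst$A, list(inst$Fm, inst$gm), list(inst$Ds, inst$gd),
                      st, cfg)
    A2 <- mda_forward(inst$A, list(inst$Fm, inst$gm), list(inst$Ds, inst$gd),
                      st, cfg)
    expect_identical(unclass(A1), unclass(A2))
    expect_equal(dim(A1), c(4L, 2L))
    expect_true(all(A1 > 0 & A1 < 1))
  }
  # variant-implied embedding widths
  cfg <- tiny_config()
  expect_equal(mdapred:::.embed_widths(cfg, 5, 4)$pm, 2 * 5 + cfg$C_out)
  expect_equal(mdapred:::.embed_widths(tiny_config(variant = "no_high_order"),
                                       5, 4)$pm, 10)
  expect_equal(mdapred:::.embed_widths(tiny_config(variant = "integrated_similarity"),
                                       5, 4)$pm, 5 + cfg$C_out)
})

test_that("plain attention and the full aggregator coincide under pass-through weights", {
  inst <- six_node_instance()
  f <- 3L
  cfg_full <- tiny_config(variant = "full", L = 1L)
  cfg_gat <- tiny_config(variant = "plain_gat", L = 1L)
  st_full <- init_model_state(cfg_full, 4, 2)
  st_gat <- init_model_state(cfg_gat, 4, 2)
  # share the conv and transformation weights
  st_gat$params$conv_m <- st_full$params$conv_m
  st_gat$params$conv_d <- st_full$params$conv_d
  st_gat$params$heads[[1]]$Wm <- st_full$params$heads[[1]]$Wm
  st_gat$params$heads[[1]]$Wd <- st_full$params$heads[[1]]$Wd
  # full: branch 1 passes hN through, branch 2 zeroed -> Z = [hN, 0]
  st_full$params$heads[[1]]$W1 <- rbind(matrix(0, f, f), diag(f))
  st_full$params$heads[[1]]$b1 <- rep(0, f)
  st_full$params$heads[[1]]$W2 <- matrix(0, f, f)
  st_full$params$heads[[1]]$b2 <- rep(0, f)
  # plain GAT: project hN to [hN, 0]
  st_gat$params$heads[[1]]$Wp <- cbind(diag(f), matrix(0, f, f))
  st_gat$params$heads[[1]]$bp <- rep(0, 2 * f)
  mv <- list(inst$Fm, inst$gm); dv <- list(inst$Ds, inst$gd)
  expect_equal(unclass(mda_forward(inst$A, mv, dv, st_full, cfg_full)),
               unclass(mda_forward(inst$A, mv, dv, st_gat, cfg_gat)),
               tolerance = 1e-12)
})

test_that("checkpoints round-trip the trained model", {
  inst <- six_node_instance()
  m <- mda_train(inst$A, list(inst$Fm, inst$gm), list(inst$Ds, inst$gd),
                 tiny_config(epochs = 3L))
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(m$state$params, m2$state$params)
  expect_identical(m$log, m2$log)
})
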