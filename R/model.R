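# The trainable predictor: learned convolutional fusion of the PPMI
# channel tensor, structure-embedding concatenation, multi-head graph
# attention over the bipartite association network with a neural
# aggregator, sigmoid inner-product decoding, and full-batch Adam
# training of the cross-entropy loss. Forward pass and analytic
# gradients are implemented directly in matrix form.

#' Model configuration
#'
#' Defaults follow the reference hyperparameter setting: `K = 3` RWR
#' steps, 256 convolution filters, transformed width 256, 2 attention
#' heads, learning rate 1e-4. The RWR continuation probability
#' (`alpha = 0.9`), the negative slope of the attention LeakyReLU (0.2)
#' and the neighbor-aggregation nonlinearity (ELU) are exposed here as
#' well.
#'
#' @param K Number of RWR transition steps.
#' @param C_out Number of convolution filters (high-order feature width).
#' @param f_tran Transformed per-head feature width.
#' @param L Number of attention heads.
#' @param learning_rate Adam learning rate.
#' @param epochs Training epochs (full-batch).
#' @param alpha RWR continuation probability in (0, 1).
#' @param variant `"full"`, `"no_high_order"` (drop the PPMI/convolution
#'   block), `"integrated_similarity"` (one merged view per node type:
#'   functional/semantic values where present, GIP elsewhere), or
#'   `"plain_gat"` (standard graph attention output only, projected to
#'   the full embedding width).
#' @param seed Integer seed controlling initialisation and any negative
#'   sampling done by [mda_train()].
#' @param leaky_slope Negative slope of the attention LeakyReLU.
#' @param activation Nonlinearity applied to the aggregated neighbor
#'   representation (`"elu"` by default).
#' @param clamp Probability clamp inside the loss, `[clamp, 1 - clamp]`.
#' @return A list of class `model_config`.
#' @export
model_config <- function(K = 3L, C_out = 256L, f_tran = 256L, L = 2L,
                         learning_rate = 1e-4, epochs = 1000L,
                         alpha = 0.9,
                         variant = c("full", "no_high_order",
                                     "integrated_similarity", "plain_gat"),
                         seed = 1L, leaky_slope = 0.2,
                         activation = c("elu", "relu"),
                         clamp = 1e-7) {
  variant <- match.arg(variant)
  activation <- match.arg(activation)
  .stop_if(K < 1 || C_out < 1 || f_tran < 1 || L < 1,
           "K, C_out, f_tran and L must all be >= 1")
  .stop_if(learning_rate <= 0, "learning_rate must be positive")
  .stop_if(alpha <= 0 || alpha >= 1, "alpha must lie in (0, 1)")
  structure(list(K = as.integer(K), C_out = as.integer(C_out),
                 f_tran = as.integer(f_tran), L = as.integer(L),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 alpha = alpha, variant = variant, seed = as.integer(seed),
                 leaky_slope = leaky_slope, activation = activation,
                 clamp = clamp),
            class = "model_config")
}

# number of similarity views per node type under a variant
.n_views <- function(config) {
  if (config$variant == "integrated_similarity") 1L else 2L
}

# structure-embedding widths implied by the variant
.embed_widths <- function(config, nm, nd) {
  S <- .n_views(config)
  extra <- if (config$variant == "no_high_order") 0L else config$C_out
  list(pm = S * nm + extra, pd = S * nd + extra,
       C_in_m = S * config$K, C_in_d = S * config$K)
}

#' Initialise trainable parameters
#'
#' Transformation and aggregator weights use Xavier normal
#' initialisation, biases start at zero; the draw is controlled by
#' `config$seed`. Convolution filters optionally take an explicit
#' standard deviation (`conv_sd`): [mda_train()] supplies one that
#' variance-matches the high-order block to the first-order similarity
#' features at initialisation, so neither block swamps the structure
#' embedding before training starts.
#'
#' @param config A [model_config()].
#' @param nm,nd Numbers of miRNA and disease nodes.
#' @param conv_sd Optional length-2 numeric (miRNA, disease) init sd for
#'   the convolution filters; default is Xavier with the convolutional
#'   fan-in (input channels x receptive field).
#' @return A list of class `model_state` with elements `params` (the
#'   trainable matrices) and `dims`.
#' @export
init_model_state <- function(config, nm, nd, conv_sd = NULL) {
  w <- .embed_widths(config, nm, nd)
  f <- config$f_tran
  if (is.null(conv_sd)) {
    conv_sd <- c(sqrt(2 / (w$C_in_m * nm + config$C_out)),
                 sqrt(2 / (w$C_in_d * nd + config$C_out)))
  }
  withr::with_seed(config$seed, {
    params <- list()
    if (config$variant != "no_high_order") {
      params$conv_m <- list(W = matrix(stats::rnorm(nm * config$C_out, 0,
                                                    conv_sd[[1L]]),
                                       nm, config$C_out),
                            b = rep(0, config$C_out))
      params$conv_d <- list(W = matrix(stats::rnorm(nd * config$C_out, 0,
                                                    conv_sd[[2L]]),
                                       nd, config$C_out),
                            b = rep(0, config$C_out))
    }
    params$heads <- lapply(seq_len(config$L), function(l) {
      h <- list(Wm = .xavier(w$pm, f), Wd = .xavier(w$pd, f))
      if (config$variant == "plain_gat") {
        h$Wp <- .xavier(f, 2L * f)
        h$bp <- rep(0, 2L * f)
      } else {
        h$W1 <- .xavier(2L * f, f)
        h$b1 <- rep(0, f)
        h$W2 <- .xavier(f, f)
        h$b2 <- rep(0, f)
      }
      h
    })
  })
  structure(list(params = params,
                 dims = c(list(nm = nm, nd = nd), w),
                 variant = config$variant),
            class = "model_state")
}

# ---- individual forward operations (also used by tests) ------------------

#' Fuse a proximity tensor with learned filters
#'
#' Each of the `C_out` filters spans the full feature width of one
#' channel (a length-n kernel, no channel index), slides over nodes with
#' stride 1, and its responses are summed across the input channels:
#' the high-order representation is
#' `(sum of channels) %*% W + b` (n x C_out), linear in the input
#' tensor.
#'
#' @param tensor A `proximity_tensor`.
#' @param W Weight matrix `n x C_out` (one column per filter).
#' @param b Bias vector of length `C_out`.
#' @return Matrix `n x C_out`.
#' @export
conv_fuse <- function(tensor, W, b) {
  Xsum <- Reduce(`+`, tensor$channels)
  .stop_if(ncol(Xsum) != nrow(W),
           "channel width mismatch: channels are %d wide, filters expect %d",
           ncol(Xsum), nrow(W))
  sweep(Xsum %*% W, 2L, -b)
}

#' Concatenate first-order views with the high-order representation
#'
#' @param view1,view2 First-order similarity views (`view2` may be `NULL`
#'   for the integrated-similarity variant).
#' @param high_order High-order representation (n x C_out) or `NULL` for
#'   the no-high-order variant.
#' @return The structure embedding, rows = nodes.
#' @export
concat_structure <- function(view1, view2 = NULL, high_order = NULL) {
  parts <- list(unclass(view1))
  if (!is.null(view2)) {
    .stop_if(nrow(view2) != nrow(view1), "view shape mismatch")
    parts <- c(parts, list(unclass(view2)))
  }
  if (!is.null(high_order)) {
    .stop_if(nrow(high_order) != nrow(view1),
             "high-order representation shape mismatch")
    parts <- c(parts, list(high_order))
  }
  do.call(cbind, parts)
}

#' Map both node types into a shared feature space
#'
#' @param Xm Structure embedding of miRNAs (nm x pm).
#' @param Yd Structure embedding of diseases (nd x pd).
#' @param Wm,Wd Per-head transformation matrices (pm x f, pd x f).
#' @return `(nm + nd) x f` matrix, miRNA rows first.
#' @export
transform_nodes <- function(Xm, Yd, Wm, Wd) {
  rbind(Xm %*% Wm, Yd %*% Wd)
}

# internal attention forward keeping intermediates for backprop
.attention_forward <- function(h, mask, slope, activation) {
  Sc <- tcrossprod(h)
  E <- .leaky_relu(Sc, slope)
  # stabilised masked softmax over each node's neighbor set
  Emask <- ifelse(mask > 0, E, -Inf)
  rmax <- apply(Emask, 1L, max)
  rmax[!is.finite(rmax)] <- 0   # isolated nodes
  W <- exp(Emask - rmax)        # exp(-Inf) = 0 kills non-neighbors
  rs <- rowSums(W)
  attn <- W / ifelse(rs > 0, rs, 1)
  u <- attn %*% h
  hN <- if (activation == "elu") .elu(u) else pmax(u, 0)
  list(hN = hN, u = u, attn = attn, Sc = Sc)
}

#' Attention-weighted aggregation of heterogeneous neighbors
#'
#' Attention scores are inner products of transformed node features
#' passed through LeakyReLU, computed only over edges of the association
#' network; softmax-normalised per node; the aggregated neighbor
#' representation is the nonlinearity applied to the attention-weighted
#' sum. Isolated nodes receive a zero neighbor representation.
#'
#' @param h Transformed node features `(nm + nd) x f`.
#' @param G_A Heterogeneous adjacency (binary, from the training fold).
#' @param slope LeakyReLU negative slope.
#' @param activation `"elu"` or `"relu"`.
#' @return `(nm + nd) x f` matrix with the per-node attention
#'   coefficient matrix attached as attribute `"attention"`.
#' @export
attention_aggregate <- function(h, G_A, slope = 0.2, activation = "elu") {
  .stop_if(nrow(G_A) != nrow(h), "h/G_A dimension mismatch")
  fwd <- .attention_forward(h, unclass(G_A), slope, activation)
  hN <- fwd$hN
  iso <- rowSums(G_A) == 0
  hN[iso, ] <- 0
  attr(hN, "attention") <- fwd$attn
  hN
}

#' Neural aggregation of a node with its neighbor representation
#'
#' Two fully connected branches, concatenated: branch 1 maps the
#' concatenation `(h || h_N)` through `W1, b1`; branch 2 maps the sum
#' `(h + h_N)` through `W2, b2`. Output width is `2 * f_tran`.
#'
#' @param h,hN Node and aggregated-neighbor features, `n x f` each.
#' @param W1 `2f x f` weight, `b1` length-f bias (concatenation branch).
#' @param W2 `f x f` weight, `b2` length-f bias (additive branch).
#' @return `n x 2f` enhanced representation.
#' @export
neural_aggregate <- function(h, hN, W1, b1, W2, b2) {
  .stop_if(!all(dim(h) == dim(hN)), "h and hN must have equal shape")
  Z1 <- sweep(cbind(h, hN) %*% W1, 2L, -b1)
  Z2 <- sweep((h + hN) %*% W2, 2L, -b2)
  cbind(Z1, Z2)
}

#' Concatenate per-head embeddings and split by node type
#'
#' @param Z_list List of per-head matrices `(nm + nd) x w`.
#' @param nm Number of miRNA rows.
#' @return List with `Zm` (first `nm` rows) and `Zd`.
#' @export
multi_head_concat <- function(Z_list, nm) {
  Z <- do.call(cbind, Z_list)
  list(Zm = Z[seq_len(nm), , drop = FALSE],
       Zd = Z[-seq_len(nm), , drop = FALSE])
}

#' Sigmoid inner-product decoder
#'
#' @param Zm,Zd Final embeddings of miRNAs and diseases.
#' @return Matrix of pair scores in (0, 1), class `prediction_matrix`.
#' @export
decode <- function(Zm, Zd) {
  .stop_if(ncol(Zm) != ncol(Zd), "embedding widths differ")
  A <- .sigmoid(tcrossprod(Zm, Zd))
  class(A) <- c("prediction_matrix", class(matrix()))
  A
}

#' Binary cross-entropy loss
#'
#' `-(y * log(p) + (1 - y) * log(1 - p))` averaged over the supplied
#' pairs, with probabilities clamped away from 0/1 for numerical safety.
#'
#' @param p Predicted probabilities.
#' @param y Binary labels.
#' @param clamp Clamping epsilon.
#' @return Mean loss (scalar).
#' @export
bce_loss <- function(p, y, clamp = 1e-7) {
  .stop_if(length(p) != length(y), "score/label length mismatch")
  p <- .clamp(p, clamp)
  mean(-(y * log(p) + (1 - y) * log(1 - p)))
}

# ---- input preparation ---------------------------------------------------

# Merge functional/semantic with GIP: keep the primary similarity where it
# is non-zero, fill the remaining entries from the GIP kernel.
.integrate_views <- function(primary, gip) {
  M <- ifelse(unclass(primary) != 0, unclass(primary), unclass(gip))
  diag(M) <- 1
  similarity_view(M, node_type = attr(primary, "node_type"),
                  view_tag = "integrated")
}

# Precompute everything the training loop reuses across epochs: the
# first-order blocks, the flattened PPMI channel tensors, and the
# neighbor mask from the training-fold adjacency.
.prepare_inputs <- function(A_graph, mirna_views, disease_views, config) {
  .stop_if(length(mirna_views) != 2L || length(disease_views) != 2L,
           "expected two views per node type (primary similarity, GIP)")
  if (config$variant == "integrated_similarity") {
    mv <- list(.integrate_views(mirna_views[[1L]], mirna_views[[2L]]))
    dv <- list(.integrate_views(disease_views[[1L]], disease_views[[2L]]))
  } else {
    mv <- mirna_views
    dv <- disease_views
  }
  F_m <- do.call(cbind, lapply(mv, unclass))
  F_d <- do.call(cbind, lapply(dv, unclass))
  out <- list(F_m = F_m, F_d = F_d, mask = unclass(build_heterogeneous_adjacency(A_graph)))
  if (config$variant != "no_high_order") {
    tm <- build_proximity_tensor(mv, alpha = config$alpha, K = config$K)
    td <- build_proximity_tensor(dv, alpha = config$alpha, K = config$K)
    .stop_if(length(tm$channels) != length(mv) * config$K,
             "channel count mismatch for miRNA tensor")
    out$Xsum_m <- Reduce(`+`, tm$channels)
    out$Xsum_d <- Reduce(`+`, td$channels)
  }
  out
}

# Variance-matched filter init: choose the conv sd so that the
# high-order block has the same per-entry scale as the first-order
# similarity features at initialisation (Xhat entry = <channel-sum row,
# filter>, so Var = ||row||^2 * sd^2 ~ n * rms(X)^2 * sd^2).
.matched_conv_sd <- function(pre) {
  if (is.null(pre$Xsum_m)) return(NULL)
  sd_one <- function(Xsum, F1) {
    rms_x <- sqrt(mean(Xsum^2))
    if (rms_x == 0) return(sqrt(2 / sum(dim(Xsum))))
    sqrt(mean(F1^2)) / (rms_x * sqrt(ncol(Xsum)))
  }
  c(sd_one(pre$Xsum_m, pre$F_m), sd_one(pre$Xsum_d, pre$F_d))
}

# ---- full forward + analytic backward ------------------------------------

# pairs: 2-column integer matrix (miRNA index, disease index); labels in
# {0,1}. Returns loss, the full prediction matrix, and (optionally)
# gradients mirroring state$params.
.loss_grad <- function(state, pre, pairs, labels, config, want_grad = TRUE) {
  pm <- state$params
  nm <- state$dims$nm; nd <- state$dims$nd
  f <- config$f_tran
  has_conv <- config$variant != "no_high_order"
  plain <- config$variant == "plain_gat"

  if (has_conv) {
    Xhat_m <- sweep(pre$Xsum_m %*% pm$conv_m$W, 2L, -pm$conv_m$b)
    Xhat_d <- sweep(pre$Xsum_d %*% pm$conv_d$W, 2L, -pm$conv_d$b)
    Xt_m <- cbind(pre$F_m, Xhat_m)
    Xt_d <- cbind(pre$F_d, Xhat_d)
  } else {
    Xt_m <- pre$F_m
    Xt_d <- pre$F_d
  }

  iso <- rowSums(pre$mask) == 0
  heads <- vector("list", config$L)
  for (l in seq_len(config$L)) {
    hp <- pm$heads[[l]]
    h <- rbind(Xt_m %*% hp$Wm, Xt_d %*% hp$Wd)
    fwd <- .attention_forward(h, pre$mask, config$leaky_slope,
                              config$activation)
    hN <- fwd$hN
    hN[iso, ] <- 0
    Z <- if (plain) {
      sweep(hN %*% hp$Wp, 2L, -hp$bp)
    } else {
      cbind(sweep(cbind(h, hN) %*% hp$W1, 2L, -hp$b1),
            sweep((h + hN) %*% hp$W2, 2L, -hp$b2))
    }
    heads[[l]] <- list(h = h, fwd = fwd, hN = hN, Z = Z)
  }
  Ztil <- do.call(cbind, lapply(heads, `[[`, "Z"))
  Zm <- Ztil[seq_len(nm), , drop = FALSE]
  Zd <- Ztil[-seq_len(nm), , drop = FALSE]
  scores <- tcrossprod(Zm, Zd)
  Ahat <- .sigmoid(scores)
  p <- .clamp(Ahat[pairs], config$clamp)
  loss <- mean(-(labels * log(p) + (1 - labels) * log(1 - p)))

  if (!want_grad) {
    return(list(loss = loss, Ahat = Ahat))
  }

  npair <- nrow(pairs)
  dS <- matrix(0, nm, nd)
  dS[pairs] <- dS[pairs] + (p - labels) / npair
  dZm <- dS %*% Zd
  dZd <- crossprod(dS, Zm)
  dZtil <- rbind(dZm, dZd)

  grads <- list()
  if (has_conv) {
    grads$conv_m <- list(W = matrix(0, nrow(pm$conv_m$W), ncol(pm$conv_m$W)),
                         b = rep(0, length(pm$conv_m$b)))
    grads$conv_d <- list(W = matrix(0, nrow(pm$conv_d$W), ncol(pm$conv_d$W)),
                         b = rep(0, length(pm$conv_d$b)))
  }
  grads$heads <- vector("list", config$L)
  dXt_m <- matrix(0, nrow(Xt_m), ncol(Xt_m))
  dXt_d <- matrix(0, nrow(Xt_d), ncol(Xt_d))
  wZ <- 2L * f                  # per-head embedding width in both modes
  for (l in seq_len(config$L)) {
    hp <- pm$heads[[l]]
    st <- heads[[l]]
    dZ <- dZtil[, ((l - 1L) * wZ + 1L):(l * wZ), drop = FALSE]
    h <- st$h; hN <- st$hN
    if (plain) {
      gWp <- crossprod(hN, dZ)
      gbp <- colSums(dZ)
      dh <- matrix(0, nrow(h), ncol(h))
      dhN <- dZ %*% t(hp$Wp)
      ghead <- list(Wm = NULL, Wd = NULL, Wp = gWp, bp = gbp)
    } else {
      dZ1 <- dZ[, seq_len(f), drop = FALSE]
      dZ2 <- dZ[, f + seq_len(f), drop = FALSE]
      gW1 <- crossprod(cbind(h, hN), dZ1)
      gb1 <- colSums(dZ1)
      gW2 <- crossprod(h + hN, dZ2)
      gb2 <- colSums(dZ2)
      dC <- dZ1 %*% t(hp$W1)              # gradient w.r.t. (h || hN)
      dT <- dZ2 %*% t(hp$W2)              # gradient w.r.t. (h + hN)
      dh <- dC[, seq_len(f), drop = FALSE] + dT
      dhN <- dC[, f + seq_len(f), drop = FALSE] + dT
      ghead <- list(Wm = NULL, Wd = NULL, W1 = gW1, b1 = gb1,
                    W2 = gW2, b2 = gb2)
    }
    dhN[iso, ] <- 0
    # through the aggregation nonlinearity
    du <- dhN * (if (config$activation == "elu") .elu_grad(st$fwd$u)
                 else (st$fwd$u > 0) * 1)
    attn <- st$fwd$attn
    dh <- dh + crossprod(attn, du)
    dAttn <- du %*% t(h)
    # softmax backward, rows restricted to neighbor sets via attn's zeros
    dE <- attn * (dAttn - rowSums(attn * dAttn))
    dSc <- dE * .leaky_relu_grad(st$fwd$Sc, config$leaky_slope)
    dh <- dh + (dSc + t(dSc)) %*% h
    dh_m <- dh[seq_len(nm), , drop = FALSE]
    dh_d <- dh[-seq_len(nm), , drop = FALSE]
    ghead$Wm <- crossprod(Xt_m, dh_m)
    ghead$Wd <- crossprod(Xt_d, dh_d)
    grads$heads[[l]] <- ghead
    dXt_m <- dXt_m + dh_m %*% t(hp$Wm)
    dXt_d <- dXt_d + dh_d %*% t(hp$Wd)
  }
  if (has_conv) {
    cm <- ncol(pre$F_m)
    cd <- ncol(pre$F_d)
    dXhat_m <- dXt_m[, (cm + 1L):ncol(dXt_m), drop = FALSE]
    dXhat_d <- dXt_d[, (cd + 1L):ncol(dXt_d), drop = FALSE]
    grads$conv_m$W <- crossprod(pre$Xsum_m, dXhat_m)
    grads$conv_m$b <- colSums(dXhat_m)
    grads$conv_d$W <- crossprod(pre$Xsum_d, dXhat_d)
    grads$conv_d$b <- colSums(dXhat_d)
  }
  list(loss = loss, Ahat = Ahat, grads = grads)
}

# ---- parameter traversal + Adam ------------------------------------------

# paths of numeric leaves inside state$params, as lists of keys
.param_paths <- function(params) {
  paths <- list()
  walk <- function(x, prefix) {
    if (is.numeric(x)) {
      paths[[length(paths) + 1L]] <<- prefix
    } else if (is.list(x)) {
      for (nm in seq_along(x)) {
        key <- if (is.null(names(x)) || names(x)[nm] == "") nm else names(x)[nm]
        walk(x[[nm]], c(prefix, list(key)))
      }
    }
  }
  walk(params, list())
  paths
}

.pluck <- function(x, path) {
  for (k in path) x <- x[[k]]
  x
}

.poke <- function(x, path, value) {
  if (length(path) == 1L) {
    x[[path[[1L]]]] <- value
    return(x)
  }
  x[[path[[1L]]]] <- .poke(x[[path[[1L]]]], path[-1L], value)
  x
}

.adam_init <- function(params, paths) {
  zeros <- lapply(paths, function(p) {
    v <- .pluck(params, p)
    v * 0
  })
  list(m = zeros, v = zeros, t = 0L)
}

.adam_step <- function(params, grads, opt, paths, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  for (i in seq_along(paths)) {
    g <- .pluck(grads, paths[[i]])
    opt$m[[i]] <- beta1 * opt$m[[i]] + (1 - beta1) * g
    opt$v[[i]] <- beta2 * opt$v[[i]] + (1 - beta2) * g^2
    mhat <- opt$m[[i]] / (1 - beta1^opt$t)
    vhat <- opt$v[[i]] / (1 - beta2^opt$t)
    p <- .pluck(params, paths[[i]]) - lr * mhat / (sqrt(vhat) + eps)
    params <- .poke(params, paths[[i]], p)
  }
  list(params = params, opt = opt)
}

# ---- training and prediction ---------------------------------------------

#' Train the association predictor
#'
#' Full-graph, full-batch training of the cross-entropy loss over the
#' supplied positive/negative pairs with Adam. All inputs (similarity
#' views, PPMI tensors, the message-passing adjacency) must derive from
#' `A_train` only — test-fold positives are expected to be zeroed before
#' calling. If no pair set is given, positives are all ones of
#' `A_train` and an equal number of negatives is sampled from the zero
#' pairs under `config$seed`.
#'
#' @param A_train Fold-masked [association_matrix()] (also defines the
#'   attention neighborhoods).
#' @param mirna_views List of two miRNA views (functional, GIP).
#' @param disease_views List of two disease views (semantic, GIP).
#' @param config A [model_config()].
#' @param train_pairs Optional 2-column matrix of (miRNA, disease)
#'   indices.
#' @param train_labels Optional binary labels matching `train_pairs`.
#' @return List of class `mda_model`: `state`, `log` (epoch, loss),
#'   `config`.
#' @export
mda_train <- function(A_train, mirna_views, disease_views, config,
                      train_pairs = NULL, train_labels = NULL) {
  nm <- nrow(A_train); nd <- ncol(A_train)
  if (is.null(train_pairs)) {
    pos <- which(unclass(A_train) == 1)
    neg_pool <- which(unclass(A_train) == 0)
    .stop_if(length(neg_pool) < length(pos),
             "not enough unknown pairs for negative sampling")
    neg <- withr::with_seed(config$seed, sample(neg_pool, length(pos)))
    idx <- c(pos, neg)
    train_pairs <- cbind(((idx - 1L) %% nm) + 1L, ((idx - 1L) %/% nm) + 1L)
    train_labels <- rep(c(1, 0), c(length(pos), length(neg)))
  }
  train_pairs <- cbind(as.integer(train_pairs[, 1L]),
                       as.integer(train_pairs[, 2L]))
  pre <- .prepare_inputs(A_train, mirna_views, disease_views, config)
  state <- init_model_state(config, nm, nd, conv_sd = .matched_conv_sd(pre))
  paths <- .param_paths(state$params)
  opt <- .adam_init(state$params, paths)
  log <- data.frame(epoch = integer(config$epochs),
                    loss = numeric(config$epochs))
  for (ep in seq_len(config$epochs)) {
    res <- .loss_grad(state, pre, train_pairs, train_labels, config)
    .stop_if(!is.finite(res$loss),
             "training diverged: non-finite loss at epoch %d", ep)
    step <- .adam_step(state$params, res$grads, opt, paths,
                       config$learning_rate)
    state$params <- step$params
    opt <- step$opt
    log$epoch[ep] <- ep
    log$loss[ep] <- res$loss
  }
  structure(list(state = state, log = log, config = config),
            class = "mda_model")
}

#' Full forward pass: score every miRNA-disease pair
#'
#' Recomputes the proximity tensors from the supplied views, applies the
#' fusion/attention/aggregation stack under the given parameters, and
#' decodes pair probabilities.
#'
#' @param A_graph Association matrix defining the message-passing
#'   adjacency (training edges only).
#' @param mirna_views,disease_views Similarity views as in [mda_train()].
#' @param state A `model_state`.
#' @param config The matching [model_config()].
#' @return A `prediction_matrix` (nm x nd) with entries in (0, 1).
#' @export
mda_forward <- function(A_graph, mirna_views, disease_views, state, config) {
  pre <- .prepare_inputs(A_graph, mirna_views, disease_views, config)
  res <- .loss_grad(state, pre, cbind(1L, 1L), 0, config, want_grad = FALSE)
  A <- res$Ahat
  dimnames(A) <- dimnames(A_graph)
  class(A) <- c("prediction_matrix", class(matrix()))
  A
}

#' Predict from a trained model
#'
#' @param model An `mda_model` from [mda_train()].
#' @param A_graph,mirna_views,disease_views Inputs as used for training.
#' @return A `prediction_matrix`.
#' @export
mda_predict <- function(model, A_graph, mirna_views, disease_views) {
  mda_forward(A_graph, mirna_views, disease_views, model$state, model$config)
}

#' Save a trained model checkpoint
#'
#' Serialises state, config and training log with `saveRDS` (fixed
#' serialisation version, so identical models give identical files).
#'
#' @param model An `mda_model`.
#' @param path Output path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path, version = 3L)
  invisible(path)
}

#' Load a model checkpoint written by [save_checkpoint()]
#'
#' @param path Checkpoint path.
#' @return The `mda_model`.
#' @export
load_checkpoint <- function(path) {
  readRDS(path)
}
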