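# Shared fixtures and small independent oracles used across the suite.

# tiny model configuration so unit tests run in milliseconds
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(K = 2L, C_out = 3L, f_tran = 3L, L = 2L,
                   learning_rate = 5e-3, epochs = 10L, seed = 7L)
  do.call(model_config, utils::modifyList(defaults, args))
}

# 4 x 2 instance (6 nodes) with both similarity views, for model tests
six_node_instance <- function() {
  A <- association_matrix(matrix(c(1, 0,
                                   1, 1,
                                   0, 1,
                                   0, 0), 4, 2, byrow = TRUE,
                                 dimnames = list(paste0("m", 1:4),
                                                 paste0("d", 1:2))))
  Fm <- worked_micro_example()$mirna_functional
  Ds <- similarity_view(matrix(c(1, 0.4, 0.4, 1), 2, 2,
                               dimnames = list(c("d1", "d2"),
                                               c("d1", "d2"))),
                        "disease", "semantic")
  list(A = A, Fm = Fm, Ds = Ds,
       gm = gip_kernel(A, node_type = "mirna"),
       gd = gip_kernel(t(unclass(A)), node_type = "disease"))
}

# random row-stochastic matrix
random_stochastic <- function(n) {
  W <- matrix(stats::runif(n * n, 0.05, 1), n, n)
  W / rowSums(W)
}

# random similarity view with unit diagonal
random_view <- function(n, node_type = "mirna", view_tag = "functional") {
  M <- matrix(stats::runif(n * n, 0.05, 0.95), n, n)
  M <- (M + t(M)) / 2
  diag(M) <- 1
  nms <- paste0(substr(node_type, 1, 1), seq_len(n))
  dimnames(M) <- list(nms, nms)
  similarity_view(M, node_type, view_tag)
}

# independent AUC oracle: all positive-negative pairs, ties counted 0.5
pairwise_auc <- function(scores, labels) {
  ps <- scores[labels == 1]
  ns <- scores[labels == 0]
  cmp <- outer(ps, ns, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# closed-form RWR oracle: P_k = a^k G^k + (1 - a) sum_{t<k} a^t G^t
rwr_closed_form <- function(G, alpha, k) {
  n <- nrow(G)
  mat_pow <- function(M, p) {
    R <- diag(n)
    for (i in seq_len(p)) R <- R %*% M
    R
  }
  acc <- matrix(0, n, n)
  for (t in 0:(k - 1)) acc <- acc + alpha^t * mat_pow(G, t)
  alpha^k * mat_pow(G, k) + (1 - alpha) * acc
}

# direct elementwise PPMI oracle
ppmi_direct <- function(P) {
  total <- sum(P)
  out <- matrix(0, nrow(P), ncol(P))
  for (i in seq_len(nrow(P))) {
    for (j in seq_len(ncol(P))) {
      if (P[i, j] > 0) {
        out[i, j] <- max(0, log2(P[i, j] * total /
                                   (sum(P[i, ]) * sum(P[, j]))))
      }
    }
  }
  out
}

# central-difference gradient of the training loss w.r.t. one parameter
numeric_grad_at <- function(state, pre, pairs, labels, config, path, idx,
                            eps = 1e-5) {
  base <- mdapred:::.pluck(state$params, path)
  perturbed <- function(delta) {
    v <- base
    v[idx] <- v[idx] + delta
    st <- state
    st$params <- mdapred:::.poke(state$params, path, v)
    mdapred:::.loss_grad(st, pre, pairs, labels, config,
                         want_grad = FALSE)$loss
  }
  (perturbed(eps) - perturbed(-eps)) / (2 * eps)
}
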