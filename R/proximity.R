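# Multi-order proximity features: random walk with restart on each
# row-normalised similarity view, then a shifted PPMI transform per step,
# stacked into the channel tensor consumed by the convolutional fuser.

#' Row-normalise a non-negative square matrix
#'
#' @param W Square non-negative matrix; every row must have positive sum.
#' @return Row-stochastic matrix (zero entries stay zero).
#' @export
row_normalize <- function(W) {
  .stop_if(any(W < 0), "row_normalize requires non-negative entries")
  rs <- rowSums(W)
  bad <- which(rs == 0)
  if (length(bad) > 0L) {
    nm <- rownames(W)[bad[1L]]
    stop(sprintf("all-zero row for node %s",
                 if (is.null(nm)) as.character(bad[1L]) else nm),
         call. = FALSE)
  }
  unclass(W) / rs
}

#' Random walk with restart transition sequence
#'
#' Iterates `P_k = alpha * P_{k-1} %*% G_hat + (1 - alpha) * P_0` with
#' `P_0 = I`: at every step the walk continues along the graph with
#' probability `alpha` and restarts at its origin node with probability
#' `1 - alpha`. The closed form is
#' `P_k = alpha^k G^k + (1 - alpha) * sum_{t < k} alpha^t G^t`.
#'
#' @param G_hat Row-stochastic transition matrix.
#' @param alpha Continuation probability in (0, 1).
#' @param K Number of steps (>= 1).
#' @return List of `K` row-stochastic matrices `P_1 .. P_K` with
#'   attributes `alpha` and `K`.
#' @export
rwr_sequence <- function(G_hat, alpha, K) {
  .stop_if(alpha <= 0 || alpha >= 1, "alpha must lie in (0, 1)")
  .stop_if(K < 1, "K must be >= 1")
  .stop_if(any(G_hat < 0) || max(abs(rowSums(G_hat) - 1)) > 1e-8,
           "G_hat must be row-stochastic")
  n <- nrow(G_hat)
  P0 <- diag(n)
  P <- P0
  out <- vector("list", K)
  for (k in seq_len(K)) {
    P <- alpha * (P %*% G_hat) + (1 - alpha) * P0
    out[[k]] <- P
  }
  attr(out, "alpha") <- alpha
  attr(out, "K") <- K
  out
}

#' Shifted positive pointwise mutual information transform
#'
#' `X[i, j] = max(0, log2(P[i, j] * sum(P) / (rowsum_i * colsum_j)))`:
#' how much more often the walk co-locates `i` with `j` than the product
#' of the margins predicts, floored at 0. Entries with `P[i, j] = 0` map
#' to 0. Invariant under global rescaling of `P`.
#'
#' @param P Non-negative matrix with positive total sum.
#' @return Non-negative matrix of the same shape.
#' @export
ppmi <- function(P) {
  .stop_if(any(P < 0), "ppmi requires non-negative entries")
  P <- unclass(P)
  total <- sum(P)
  .stop_if(total <= 0, "ppmi requires a positive total sum")
  rs <- rowSums(P)
  cs <- colSums(P)
  X <- matrix(0, nrow(P), ncol(P), dimnames = dimnames(P))
  pos <- which(P > 0)
  if (length(pos) > 0L) {
    ri <- ((pos - 1L) %% nrow(P)) + 1L
    cj <- ((pos - 1L) %/% nrow(P)) + 1L
    X[pos] <- pmax(0, log2(P[pos] * total / (rs[ri] * cs[cj])))
  }
  X
}

#' Stack multi-order PPMI features across similarity views
#'
#' Each view is row-normalised, diffused for `K` RWR steps, and every
#' step's transition matrix is converted to a PPMI matrix. Channels are
#' ordered view-major, step-minor: view 1 steps `1..K`, then view 2, ...
#'
#' @param views List of [similarity_view()]s, all of the same node type
#'   and shape.
#' @param alpha RWR continuation probability.
#' @param K Number of RWR steps.
#' @return A `proximity_tensor`: list with `channels` (length
#'   `length(views) * K`), `meta` (view index/tag and step per channel)
#'   and `node_type`.
#' @export
build_proximity_tensor <- function(views, alpha = 0.9, K = 3) {
  .stop_if(length(views) == 0L, "at least one view required")
  types <- vapply(views, function(v) attr(v, "node_type"), character(1))
  .stop_if(length(unique(types)) != 1L,
           "all views must share one node type")
  dims <- vapply(views, nrow, integer(1))
  .stop_if(length(unique(dims)) != 1L, "all views must share one shape")
  channels <- list()
  meta <- data.frame(view = integer(0), view_tag = character(0),
                     step = integer(0), stringsAsFactors = FALSE)
  for (s in seq_along(views)) {
    Ps <- rwr_sequence(row_normalize(views[[s]]), alpha = alpha, K = K)
    for (k in seq_len(K)) {
      channels[[length(channels) + 1L]] <- ppmi(Ps[[k]])
      meta <- rbind(meta, data.frame(
        view = s, view_tag = attr(views[[s]], "view_tag"), step = k,
        stringsAsFactors = FALSE))
    }
  }
  structure(list(channels = channels, meta = meta,
                 node_type = types[[1L]], alpha = alpha, K = K),
            class = "proximity_tensor")
}
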