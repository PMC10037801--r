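# Balanced 5-fold cross-validation with per-fold GIP recomputation,
# classification/ranking metrics, and the two case-study protocols.

#' Build balanced cross-validation folds
#'
#' All known pairs are positives; an equal number of negatives is
#' sampled once from the unknown pairs. Both sets are then partitioned
#' into `n_folds` near-equal parts, so train/test negatives never
#' overlap and test positives partition the positives.
#'
#' @param A An [association_matrix()].
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed; identical seeds give identical folds.
#' @return A list of class `fold_spec`: per fold, 2-column index
#'   matrices `train_pos`, `train_neg`, `test_pos`, `test_neg`.
#' @export
make_folds <- function(A, n_folds = 5L, seed = 1L) {
  nm <- nrow(A)
  pos <- which(unclass(A) == 1)
  neg_pool <- which(unclass(A) == 0)
  .stop_if(length(pos) < n_folds, "need at least n_folds positive pairs")
  .stop_if(length(neg_pool) < length(pos),
           "not enough unknown pairs for balanced negative sampling")
  withr::with_seed(seed, {
    neg <- sample(neg_pool, length(pos))
    pos_fold <- sample(rep_len(seq_len(n_folds), length(pos)))
    neg_fold <- sample(rep_len(seq_len(n_folds), length(neg)))
  })
  to_pairs <- function(idx) {
    cbind(mirna = ((idx - 1L) %% nm) + 1L,
          disease = ((idx - 1L) %/% nm) + 1L)
  }
  folds <- lapply(seq_len(n_folds), function(k) {
    list(train_pos = to_pairs(pos[pos_fold != k]),
         train_neg = to_pairs(neg[neg_fold != k]),
         test_pos = to_pairs(pos[pos_fold == k]),
         test_neg = to_pairs(neg[neg_fold == k]))
  })
  structure(list(folds = folds, n_folds = n_folds, seed = seed),
            class = "fold_spec")
}

#' Fold-masked inputs: training matrix and recomputed GIP views
#'
#' Test-fold positives are zeroed out of the association matrix; the GIP
#' kernels for both node types (and, downstream, the message-passing
#' adjacency) are recomputed from that masked matrix. Semantic and
#' functional views stay fold-independent.
#'
#' @param A The full [association_matrix()].
#' @param fold One element of `make_folds(...)$folds`.
#' @return List: `A_train`, `gip_mirna`, `gip_disease`.
#' @export
fold_views <- function(A, fold) {
  A_train <- unclass(A)
  if (nrow(fold$test_pos) > 0L) A_train[fold$test_pos] <- 0
  A_train <- association_matrix(A_train)
  list(A_train = A_train,
       gip_mirna = gip_kernel(A_train, node_type = "mirna"),
       gip_disease = gip_kernel(t(unclass(A_train)), node_type = "disease"))
}

# own trapezoidal ROC-AUC (ties handled by grouping equal scores, which
# matches the pairwise estimator with ties counted 0.5)
.roc_auc <- function(scores, labels) {
  o <- order(-scores)
  s <- scores[o]; y <- labels[o]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / sum(y))
  fpr <- c(0, fp[last] / sum(1 - y))
  .trapz(fpr, tpr)
}

.pr_auc <- function(scores, labels) {
  o <- order(-scores)
  s <- scores[o]; y <- labels[o]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(grp, fromLast = TRUE)
  recall <- tp[last] / sum(y)
  prec <- tp[last] / (tp[last] + fp[last])
  .trapz(c(0, recall), c(prec[1L], prec))
}

#' Threshold and ranking metrics for a score vector
#'
#' AUC and AUPR are computed by trapezoidal integration over score
#' thresholds; accuracy, precision, recall and F1 at the given
#' probability threshold.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (must contain both classes).
#' @param threshold Classification threshold (default 0.5).
#' @return Named list: `auc`, `aupr`, `accuracy`, `precision`, `recall`,
#'   `f1`.
#' @export
classification_metrics <- function(scores, labels, threshold = 0.5) {
  .stop_if(length(scores) != length(labels), "score/label length mismatch")
  .stop_if(!.is_binary(labels), "labels must be binary")
  .stop_if(length(unique(labels)) < 2L,
           "AUC undefined: labels contain a single class")
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(auc = .roc_auc(scores, labels),
       aupr = .pr_auc(scores, labels),
       accuracy = (tp + tn) / length(labels),
       precision = precision, recall = recall, f1 = f1)
}

#' True-positive-rate-at-k curve and its normalised area
#'
#' For every cutoff `k`, the fraction of all positives ranked in the top
#' `k` by score (ties broken by stable input order). The area is the
#' trapezoid over `k` with the k-axis rescaled to `[0, 1]`.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @param k_grid Integer cutoffs (default every `1..n`).
#' @return List: `k`, `tpr`, `autpr`.
#' @export
tpr_at_k_curve <- function(scores, labels, k_grid = seq_along(scores)) {
  n <- length(scores)
  .stop_if(any(k_grid < 1 | k_grid > n), "k_grid must lie in [1, n]")
  o <- order(-scores, seq_along(scores))
  cum_pos <- cumsum(labels[o])
  tpr <- cum_pos[k_grid] / sum(labels)
  autpr <- if (length(k_grid) > 1L) {
    .trapz((k_grid - 1) / (max(k_grid) - 1), tpr)
  } else tpr
  list(k = k_grid, tpr = tpr, autpr = autpr)
}

# train on one fold and score its held-out pairs
.run_fold <- function(A, fold, mirna_functional, disease_semantic, config) {
  fv <- fold_views(A, fold)
  pairs <- rbind(fold$train_pos, fold$train_neg)
  labels <- rep(c(1, 0), c(nrow(fold$train_pos), nrow(fold$train_neg)))
  model <- mda_train(fv$A_train,
                     list(mirna_functional, fv$gip_mirna),
                     list(disease_semantic, fv$gip_disease),
                     config, train_pairs = pairs, train_labels = labels)
  Ahat <- mda_predict(model, fv$A_train,
                      list(mirna_functional, fv$gip_mirna),
                      list(disease_semantic, fv$gip_disease))
  test_pairs <- rbind(fold$test_pos, fold$test_neg)
  test_labels <- rep(c(1, 0), c(nrow(fold$test_pos), nrow(fold$test_neg)))
  list(model = model, scores = Ahat[test_pairs], labels = test_labels)
}

#' Cross-validated evaluation of the full pipeline
#'
#' Trains one model per fold on fold-masked data (GIP views and the
#' message-passing adjacency recomputed from training edges only) and
#' evaluates on the held-out positive/negative pairs.
#'
#' @param A The full [association_matrix()].
#' @param mirna_functional miRNA functional [similarity_view()]
#'   (fold-independent).
#' @param disease_semantic Disease semantic [similarity_view()]
#'   (fold-independent).
#' @param config A [model_config()].
#' @param n_folds Number of folds (default 5).
#' @return A `metrics_report`: data frame `per_fold`, plus `mean` and
#'   `sd` rows over folds.
#' @export
run_cross_validation <- function(A, mirna_functional, disease_semantic,
                                 config, n_folds = 5L) {
  folds <- make_folds(A, n_folds = n_folds, seed = config$seed)
  rows <- vector("list", n_folds)
  for (k in seq_len(n_folds)) {
    res <- .run_fold(A, folds$folds[[k]], mirna_functional,
                     disease_semantic, config)
    cm <- classification_metrics(res$scores, res$labels)
    tk <- tpr_at_k_curve(res$scores, res$labels)
    rows[[k]] <- data.frame(fold = k, auc = cm$auc, aupr = cm$aupr,
                            autpr_at_k = tk$autpr, accuracy = cm$accuracy,
                            precision = cm$precision, recall = cm$recall,
                            f1 = cm$f1)
  }
  per_fold <- do.call(rbind, rows)
  metric_cols <- setdiff(names(per_fold), "fold")
  structure(list(per_fold = per_fold,
                 mean = colMeans(per_fold[metric_cols]),
                 sd = vapply(per_fold[metric_cols], stats::sd, numeric(1)),
                 folds = folds),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Cross-validation metrics (", nrow(x$per_fold), " folds)\n", sep = "")
  print(round(x$per_fold, 4), row.names = FALSE)
  cat("mean:\n")
  print(round(x$mean, 4))
  cat("sd:\n")
  print(round(x$sd, 4))
  invisible(x)
}

# shared helper for the two case-study protocols
.rank_candidates <- function(Ahat, A_known, disease_idx, candidates, top_n) {
  scores <- Ahat[, disease_idx]
  ord <- order(-scores[candidates], candidates)   # stable tie-break
  sel <- candidates[ord][seq_len(min(top_n, length(candidates)))]
  data.frame(rank = seq_along(sel),
             mirna = rownames(A_known)[sel],
             score = scores[sel],
             stringsAsFactors = FALSE)
}

#' Case study: rank novel candidates for a disease with known associations
#'
#' Trains on all known pairs plus an equal number of negatives sampled
#' from unknown pairs not involving the target disease, then ranks the
#' disease's unknown pairs by predicted score.
#'
#' @param A The full [association_matrix()].
#' @param disease Disease name (a column of `A`).
#' @param mirna_functional,disease_semantic Fold-independent views.
#' @param config A [model_config()].
#' @param top_n Number of candidates to return (default 20).
#' @return Data frame `rank`, `mirna`, `score`.
#' @export
case_study_novel <- function(A, disease, mirna_functional, disease_semantic,
                             config, top_n = 20L) {
  j <- match(disease, colnames(A))
  .stop_if(is.na(j), "unknown disease '%s'", disease)
  nm <- nrow(A)
  pos <- which(unclass(A) == 1)
  pool <- which(unclass(A) == 0)
  pool <- pool[((pool - 1L) %/% nm) + 1L != j]   # exclude the disease's unknowns
  .stop_if(length(pool) < length(pos),
           "not enough unknown pairs outside the target disease")
  neg <- withr::with_seed(config$seed, sample(pool, length(pos)))
  idx <- c(pos, neg)
  pairs <- cbind(((idx - 1L) %% nm) + 1L, ((idx - 1L) %/% nm) + 1L)
  labels <- rep(c(1, 0), c(length(pos), length(neg)))
  gm <- gip_kernel(A, node_type = "mirna")
  gd <- gip_kernel(t(unclass(A)), node_type = "disease")
  model <- mda_train(A, list(mirna_functional, gm),
                     list(disease_semantic, gd), config,
                     train_pairs = pairs, train_labels = labels)
  Ahat <- mda_predict(model, A, list(mirna_functional, gm),
                      list(disease_semantic, gd))
  candidates <- which(unclass(A)[, j] == 0)
  .rank_candidates(Ahat, A, j, candidates, top_n)
}

#' Case study: rank miRNAs for a disease treated as entirely new
#'
#' All of the disease's pairs are removed from training (its column is
#' zeroed; the GIP kernels are recomputed from the masked matrix), the
#' model is trained on the remaining positives plus an equal number of
#' sampled negatives involving other diseases, and every miRNA is ranked
#' for the target disease.
#'
#' @inheritParams case_study_novel
#' @return Data frame `rank`, `mirna`, `score` over all miRNAs (top_n).
#' @export
case_study_new_disease <- function(A, disease, mirna_functional,
                                   disease_semantic, config, top_n = 20L) {
  j <- match(disease, colnames(A))
  .stop_if(is.na(j), "unknown disease '%s'", disease)
  nm <- nrow(A)
  A_train <- unclass(A)
  A_train[, j] <- 0
  A_train <- association_matrix(A_train)
  pos <- which(unclass(A_train) == 1)
  pool <- which(unclass(A_train) == 0)
  pool <- pool[((pool - 1L) %/% nm) + 1L != j]
  neg <- withr::with_seed(config$seed, sample(pool, length(pos)))
  idx <- c(pos, neg)
  pairs <- cbind(((idx - 1L) %% nm) + 1L, ((idx - 1L) %/% nm) + 1L)
  labels <- rep(c(1, 0), c(length(pos), length(neg)))
  gm <- gip_kernel(A_train, node_type = "mirna")
  gd <- gip_kernel(t(unclass(A_train)), node_type = "disease")
  model <- mda_train(A_train, list(mirna_functional, gm),
                     list(disease_semantic, gd), config,
                     train_pairs = pairs, train_labels = labels)
  Ahat <- mda_predict(model, A_train, list(mirna_functional, gm),
                      list(disease_semantic, gd))
  .rank_candidates(Ahat, A, j, seq_len(nm), top_n)
}
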