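# The four similarity views: disease semantic similarity (two variants,
# averaged), miRNA functional similarity (best-match average over
# associated disease sets), and Gaussian interaction profile kernels.

#' Construct a validated similarity view
#'
#' A similarity view is a square symmetric matrix with entries in
#' `[0, 1]` and unit diagonal, tagged with the node type and the kind of
#' similarity it encodes.
#'
#' @param values Square numeric matrix.
#' @param node_type `"mirna"` or `"disease"`.
#' @param view_tag One of `"functional"`, `"semantic"`, `"gip"`,
#'   `"integrated"`.
#' @param tol Symmetry/range tolerance (small numeric noise is folded
#'   back; genuine violations error).
#' @return A matrix of class `similarity_view`.
#' @export
similarity_view <- function(values,
                            node_type = c("mirna", "disease"),
                            view_tag = c("functional", "semantic", "gip",
                                         "integrated"),
                            tol = 1e-8) {
  node_type <- match.arg(node_type)
  view_tag <- match.arg(view_tag)
  .stop_if(!is.matrix(values) || nrow(values) != ncol(values),
           "similarity view must be a square matrix")
  .stop_if(max(abs(values - t(values))) > tol,
           "similarity view is not symmetric within %g", tol)
  .stop_if(max(abs(diag(values) - 1)) > tol,
           "similarity view diagonal must be 1")
  .stop_if(min(values) < -tol || max(values) > 1 + tol,
           "similarity values must lie in [0, 1]")
  values <- (values + t(values)) / 2
  values <- pmin(pmax(values, 0), 1)
  diag(values) <- 1
  attr(values, "node_type") <- node_type
  attr(values, "view_tag") <- view_tag
  class(values) <- c("similarity_view", class(matrix()))
  values
}

#' Semantic contribution of ancestor terms, decay variant
#'
#' The disease itself contributes 1; each ancestor contributes
#' `delta^depth`, i.e. the maximum over all DAG paths of `delta` applied
#' once per edge (the max over paths of `delta^len` is `delta` to the
#' minimal depth).
#'
#' @param dag Named integer vector term -> minimal depth for one disease
#'   (an element of `disease_dag_set$dags`).
#' @param delta Decay factor in (0, 1); default 0.5.
#' @return Named numeric vector of contributions.
#' @export
semantic_contribution_v1 <- function(dag, delta = 0.5) {
  .stop_if(length(dag) == 0L, "empty DAG")
  .stop_if(delta <= 0 || delta >= 1, "delta must lie in (0, 1)")
  .stop_if(any(dag < 0), "DAG depths must be non-negative")
  out <- delta^as.numeric(dag)
  names(out) <- names(dag)
  out
}

#' Semantic contribution of ancestor terms, frequency variant
#'
#' Terms appearing in fewer descriptor trees are more specific and
#' contribute more: `-log(count / n_diseases)` (natural log; any fixed
#' base rescales numerator and denominator of the pairwise similarity
#' jointly, so the similarity itself is base-invariant).
#'
#' @param term_counts Named integer vector term -> number of DAGs
#'   containing it; every queried count must be >= 1.
#' @param n_diseases Total number of DAGs.
#' @return Named numeric vector of contributions (>= 0).
#' @export
semantic_contribution_v2 <- function(term_counts, n_diseases) {
  .stop_if(any(term_counts < 1), "term count of 0 for a queried term")
  .stop_if(any(term_counts > n_diseases),
           "term count exceeds the number of DAGs")
  out <- -log(as.numeric(term_counts) / n_diseases)
  names(out) <- names(term_counts)
  out
}

#' Disease semantic similarity from descriptor DAGs
#'
#' For diseases `a`, `b` with ancestor sets `T_a`, `T_b` and per-disease
#' contribution maps `D_a`, `D_b`, the similarity is
#' `sum over shared terms of (D_a(t) + D_b(t))` divided by
#' `DV(a) + DV(b)` where `DV` is the sum of all contributions. Variant
#' `"v1"` uses the depth-decay contributions, `"v2"` the frequency-based
#' ones (identical for both diseases), normalised the same way.
#'
#' @param dags A `disease_dag_set`.
#' @param variant `"v1"` or `"v2"`.
#' @param delta Decay factor for variant v1.
#' @return A disease [similarity_view()] tagged `"semantic"`.
#' @export
disease_semantic_similarity <- function(dags, variant = c("v1", "v2"),
                                        delta = 0.5) {
  variant <- match.arg(variant)
  .stop_if(!inherits(dags, "disease_dag_set"), "dags must be a disease_dag_set")
  .stop_if(any(lengths(dags$dags) == 0L), "disease with empty DAG")
  diseases <- names(dags$dags)
  terms <- names(dags$term_counts)
  nd <- length(diseases)
  C <- matrix(0, nd, length(terms), dimnames = list(diseases, terms))
  if (variant == "v2") {
    contrib <- semantic_contribution_v2(dags$term_counts, dags$n_diseases)
  }
  for (i in seq_len(nd)) {
    dag <- dags$dags[[i]]
    C[i, names(dag)] <- if (variant == "v1") {
      semantic_contribution_v1(dag, delta)
    } else {
      contrib[names(dag)]
    }
  }
  B <- (C > 0) * 1
  # presence matrix for shared-term sums; v2 contributions can be exactly 0
  # for universal terms, which then add nothing either way
  P <- matrix(0, nd, length(terms), dimnames = dimnames(C))
  for (i in seq_len(nd)) P[i, names(dags$dags[[i]])] <- 1
  N1 <- C %*% t(P)            # sum_t D_i(t) * [t in T_j]
  num <- N1 + t(N1)
  DV <- rowSums(C)
  den <- outer(DV, DV, `+`)
  S <- ifelse(den > 0, num / den, 0)
  diag(S) <- 1
  similarity_view(S, node_type = "disease", view_tag = "semantic")
}

#' Average two semantic similarity views
#'
#' @param s1,s2 Two disease [similarity_view()]s on the same node order.
#' @return Their elementwise mean as a `"semantic"` view.
#' @export
average_semantic_views <- function(s1, s2) {
  .stop_if(!identical(dim(s1), dim(s2)), "shape mismatch between views")
  .stop_if(!identical(rownames(s1), rownames(s2)),
           "node order mismatch between views")
  similarity_view((unclass(s1) + unclass(s2)) / 2,
                  node_type = attr(s1, "node_type"), view_tag = "semantic")
}

#' miRNA functional similarity by best-match average
#'
#' Two miRNAs are functionally similar if their associated disease sets
#' are semantically similar: with disease sets `D1`, `D2`,
#' `S = (sum_{d in D1} max_{d' in D2} dss(d, d') +
#'       sum_{d in D2} max_{d' in D1} dss(d, d')) / (|D1| + |D2|)`.
#' A miRNA with no associated disease (possible inside cross-validation
#' folds) gets similarity 0 to all others and 1 to itself.
#'
#' @param A An [association_matrix()].
#' @param dss A disease [similarity_view()] (semantic) on `colnames(A)`.
#' @return A miRNA [similarity_view()] tagged `"functional"`.
#' @export
mirna_functional_similarity <- function(A, dss) {
  .stop_if(ncol(A) != nrow(dss), "association/dss dimension mismatch")
  nm <- nrow(A); nd <- ncol(A)
  sizes <- rowSums(A)
  # BM[d, i] = best match of disease d against miRNA i's disease set
  BM <- matrix(0, nd, nm)
  for (i in seq_len(nm)) {
    Di <- which(A[i, ] == 1)
    if (length(Di) > 0L) {
      BM[, i] <- apply(unclass(dss)[, Di, drop = FALSE], 1L, max)
    }
  }
  N1 <- unclass(A) %*% BM     # [i, j] = sum_{d in Di} max_{d' in Dj}
  num <- N1 + t(N1)
  den <- outer(sizes, sizes, `+`)
  S <- matrix(0, nm, nm)
  ok <- outer(sizes > 0, sizes > 0, `&`)
  S[ok] <- (num / den)[ok]
  diag(S) <- 1
  dimnames(S) <- list(rownames(A), rownames(A))
  similarity_view(S, node_type = "mirna", view_tag = "functional")
}

#' Gaussian interaction profile kernel similarity
#'
#' Similarity of binary interaction profiles under a Gaussian kernel:
#' `K(i, j) = exp(-gamma * ||IP(i) - IP(j)||^2)` with bandwidth
#' `gamma = gamma_prime / mean_i ||IP(i)||^2`. For miRNAs the profiles
#' are the rows of the (fold-masked) association matrix, for diseases
#' its columns.
#'
#' @param profiles Binary matrix, one profile per row.
#' @param gamma_prime Bandwidth scale (> 0), default 1.
#' @param node_type Passed to [similarity_view()].
#' @return A [similarity_view()] tagged `"gip"`.
#' @export
gip_kernel <- function(profiles, gamma_prime = 1,
                       node_type = c("mirna", "disease")) {
  node_type <- match.arg(node_type)
  .stop_if(gamma_prime <= 0, "gamma_prime must be positive")
  P <- unclass(profiles)
  norms <- rowSums(P^2)
  .stop_if(all(norms == 0), "all profiles are zero: GIP bandwidth undefined")
  gamma <- gamma_prime / mean(norms)
  D2 <- outer(norms, norms, `+`) - 2 * tcrossprod(P)
  D2 <- pmax(D2, 0)
  K <- exp(-gamma * D2)
  dimnames(K) <- list(rownames(profiles), rownames(profiles))
  similarity_view(K, node_type = node_type, view_tag = "gip")
}

#' Write a similarity view as a square TSV with name headers
#'
#' First row holds an empty cell then column names; each following row a
#' node name then `%.17g`-formatted values (exact double round trip).
#'
#' @param view A [similarity_view()].
#' @param path Output path.
#' @export
write_similarity_view <- function(view, path) {
  nms <- rownames(view)
  .stop_if(is.null(nms), "similarity view must carry node names")
  lines <- c(paste(c("", nms), collapse = "\t"),
             vapply(seq_along(nms), function(i) {
               paste(c(nms[i], .fmt_num(view[i, ])), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a similarity view written by [write_similarity_view()]
#'
#' @param path Input path.
#' @param node_type,view_tag Metadata to attach (not stored in the file).
#' @return A [similarity_view()].
#' @export
read_similarity_view <- function(path, node_type = c("mirna", "disease"),
                                 view_tag = c("functional", "semantic",
                                              "gip", "integrated")) {
  lines <- readLines(path, warn = FALSE)
  .stop_if(length(lines) < 2L, "similarity file '%s' is empty", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]][-1L]
  n <- length(header)
  vals <- matrix(0, n, n, dimnames = list(header, header))
  for (i in seq_len(n)) {
    f <- strsplit(lines[[i + 1L]], "\t", fixed = TRUE)[[1L]]
    .stop_if(length(f) != n + 1L, "malformed similarity row %d", i)
    vals[i, ] <- as.numeric(f[-1L])
  }
  similarity_view(vals, node_type = match.arg(node_type),
                  view_tag = match.arg(view_tag))
}
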