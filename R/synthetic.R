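# Self-contained synthetic benchmark: sparse binary association matrix
# with planted block structure, similarity views correlated with the
# blocks, and a small descriptor-tree forest whose ancestor overlap also
# carries the block signal.

#' Specification for a synthetic dataset
#'
#' The defaults define the benchmark condition used throughout the test
#' suite: 60 x 60 nodes, 4 latent blocks, 10% association density, 2%
#' label noise.
#'
#' @param nm,nd Numbers of miRNAs and diseases.
#' @param rank Number of latent blocks (<= min(nm, nd)).
#' @param density Target fraction of positive pairs, in (0, 0.5).
#' @param noise Probability of flipping each entry, in [0, 0.5).
#' @param dag_depth Depth of each block's descriptor chain.
#' @param dag_branching Extra sampled ancestors per disease DAG.
#' @param p_ratio Between-block over within-block association probability.
#' @param base_sim Between-block baseline similarity of the views.
#' @param sim_noise Standard deviation of the symmetric view noise.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(nm = 60L, nd = 60L, rank = 4L, density = 0.1,
                           noise = 0.02, dag_depth = 4L, dag_branching = 2L,
                           p_ratio = 0, base_sim = 0.2, sim_noise = 0.05,
                           seed = 1L) {
  .stop_if(density <= 0 || density >= 0.5, "density must lie in (0, 0.5)")
  .stop_if(noise < 0 || noise >= 0.5, "noise must lie in [0, 0.5)")
  .stop_if(rank > min(nm, nd), "rank must be <= min(nm, nd)")
  .stop_if(rank < 1, "rank must be >= 1")
  structure(list(nm = as.integer(nm), nd = as.integer(nd),
                 rank = as.integer(rank), density = density, noise = noise,
                 dag_depth = as.integer(dag_depth),
                 dag_branching = as.integer(dag_branching),
                 p_ratio = p_ratio, base_sim = base_sim,
                 sim_noise = sim_noise, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# block-membership kernel + symmetric noise, clipped, unit diagonal
.block_view <- function(blocks, base, sd, node_type, view_tag) {
  n <- length(blocks)
  M <- ifelse(outer(blocks, blocks, `==`), 1, base)
  E <- matrix(stats::rnorm(n * n, 0, sd), n, n)
  E <- (E + t(E)) / 2
  M <- pmin(pmax(M + E, 0), 1)
  diag(M) <- 1
  dimnames(M) <- list(names(blocks), names(blocks))
  similarity_view(M, node_type = node_type, view_tag = view_tag)
}

#' Generate a synthetic dataset with planted block structure
#'
#' Each node is assigned to one of `rank` blocks; associations appear
#' with probability `p_in` inside matched blocks and `p_in * p_ratio`
#' otherwise, with `p_in` calibrated so the expected density matches the
#' spec; every entry is then flipped with probability `noise`. Similarity
#' views are the block-membership kernel plus symmetric Gaussian noise.
#' The descriptor forest gives every disease a chain of block-specific
#' ancestors down to a shared root (plus `dag_branching` extra sampled
#' ancestors from its own block chain), so semantic similarity computed
#' from the DAGs also recovers the block signal.
#'
#' @param spec A [synthetic_spec()].
#' @return List: `A` ([association_matrix()]), `mirna_functional` and
#'   `disease_semantic` ([similarity_view()]s), `dags`
#'   (`disease_dag_set`), `blocks` (per-type assignments), `spec`.
#' @export
generate_dataset <- function(spec) {
  .stop_if(!inherits(spec, "synthetic_spec"), "spec must be a synthetic_spec")
  withr::with_seed(spec$seed, {
    mirnas <- sprintf("mir-%03d", seq_len(spec$nm))
    diseases <- sprintf("disease-%03d", seq_len(spec$nd))
    bm <- rep_len(seq_len(spec$rank), spec$nm)
    bd <- rep_len(seq_len(spec$rank), spec$nd)
    names(bm) <- mirnas; names(bd) <- diseases
    match_frac <- mean(outer(bm, bd, `==`))
    p_in <- min(spec$density / (match_frac + (1 - match_frac) * spec$p_ratio),
                0.9)
    P <- ifelse(outer(bm, bd, `==`), p_in, p_in * spec$p_ratio)
    A <- matrix(as.numeric(stats::runif(spec$nm * spec$nd) < P),
                spec$nm, spec$nd, dimnames = list(mirnas, diseases))
    if (spec$noise > 0) {
      flip <- stats::runif(spec$nm * spec$nd) < spec$noise
      A[flip] <- 1 - A[flip]
    }
    Fm <- .block_view(bm, spec$base_sim, spec$sim_noise, "mirna", "functional")
    # descriptor forest: root -> per-block chains; disease DAG = its own
    # block chain (plus sampled extra ancestors from deeper chain levels)
    records <- list()
    for (i in seq_len(spec$nd)) {
      b <- bd[[i]]
      chain <- c(sprintf("B%dL%d", b, seq(spec$dag_depth, 1L)), "root")
      child <- c(diseases[[i]], chain[-length(chain)])
      parent <- chain
      if (spec$dag_branching > 0L && spec$dag_depth > 1L) {
        extra <- sample(seq_len(spec$dag_depth - 1L),
                        min(spec$dag_branching, spec$dag_depth - 1L))
        for (e in extra) {
          # a second edge from the disease into a shallower chain level,
          # creating diamond-shaped multi-path ancestry
          child <- c(child, diseases[[i]])
          parent <- c(parent, sprintf("B%dL%d", b, e))
        }
      }
      records[[diseases[[i]]]] <- data.frame(child = child, parent = parent,
                                             stringsAsFactors = FALSE)
    }
    dags <- .build_dag_set(records)
    Ds <- .block_view(bd, spec$base_sim, spec$sim_noise, "disease", "semantic")
  })
  list(A = association_matrix(A), mirna_functional = Fm,
       disease_semantic = Ds, dags = dags,
       blocks = list(mirna = bm, disease = bd), spec = spec)
}

#' Fixed hand-checkable micro instance
#'
#' A 4-miRNA x 3-disease instance with hard-coded associations, views
#' and descriptor trees, small enough that RWR, PPMI, attention and
#' decoder values can be verified by hand. Used throughout the oracle
#' tests.
#'
#' @return List with the same layout as [generate_dataset()].
#' @export
worked_micro_example <- function() {
  mirnas <- c("m1", "m2", "m3", "m4")
  diseases <- c("d1", "d2", "d3")
  A <- matrix(c(1, 1, 0,
                1, 0, 0,
                0, 1, 1,
                0, 0, 1), 4, 3, byrow = TRUE,
              dimnames = list(mirnas, diseases))
  Fm <- matrix(c(1.0, 0.8, 0.2, 0.1,
                 0.8, 1.0, 0.3, 0.2,
                 0.2, 0.3, 1.0, 0.7,
                 0.1, 0.2, 0.7, 1.0), 4, 4, byrow = TRUE,
               dimnames = list(mirnas, mirnas))
  Ds <- matrix(c(1.0, 0.6, 0.2,
                 0.6, 1.0, 0.3,
                 0.2, 0.3, 1.0), 3, 3, byrow = TRUE,
               dimnames = list(diseases, diseases))
  records <- list(
    d1 = data.frame(child = "d1", parent = "r", stringsAsFactors = FALSE),
    d2 = data.frame(child = "d2", parent = "r", stringsAsFactors = FALSE),
    d3 = data.frame(child = c("d3", "s"), parent = c("s", "r"),
                    stringsAsFactors = FALSE))
  list(A = association_matrix(A),
       mirna_functional = similarity_view(Fm, "mirna", "functional"),
       disease_semantic = similarity_view(Ds, "disease", "semantic"),
       dags = .build_dag_set(records),
       blocks = NULL, spec = NULL)
}
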