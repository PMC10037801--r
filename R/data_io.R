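# Reading/writing association lists, similarity matrices and disease
# descriptor trees, plus assembly of the heterogeneous adjacency.

#' Construct a binary miRNA-disease association matrix
#'
#' The association matrix `A` (nm x nd) is the supervision signal of the
#' whole pipeline: `A[i, j] = 1` records an experimentally supported
#' association between miRNA `i` and disease `j`, 0 an unobserved pair.
#'
#' @param values Numeric matrix with entries in `{0, 1}`.
#' @param mirna_names Character vector of row (miRNA) identifiers.
#' @param disease_names Character vector of column (disease) identifiers.
#' @return A matrix of class `association_matrix` with dimnames set.
#' @export
association_matrix <- function(values,
                               mirna_names = rownames(values),
                               disease_names = colnames(values)) {
  .stop_if(!is.matrix(values) || !is.numeric(values),
           "values must be a numeric matrix")
  .stop_if(!.is_binary(values), "association matrix entries must be 0 or 1")
  .stop_if(is.null(mirna_names) || is.null(disease_names),
           "miRNA and disease names are required")
  mirna_names <- trimws(as.character(mirna_names))
  disease_names <- trimws(as.character(disease_names))
  .stop_if(length(mirna_names) != nrow(values),
           "mirna_names length (%d) != nrow(values) (%d)",
           length(mirna_names), nrow(values))
  .stop_if(length(disease_names) != ncol(values),
           "disease_names length (%d) != ncol(values) (%d)",
           length(disease_names), ncol(values))
  .stop_if(anyDuplicated(mirna_names) > 0, "duplicate miRNA names")
  .stop_if(anyDuplicated(disease_names) > 0, "duplicate disease names")
  values <- matrix(as.numeric(values), nrow(values), ncol(values),
                   dimnames = list(mirna_names, disease_names))
  class(values) <- c("association_matrix", class(matrix()))
  values
}

#' Load known associations from a two-column delimited file
#'
#' Each non-empty line holds one known pair, `miRNA <TAB> disease`.
#' Duplicate lines are idempotent; identifier order is the order of first
#' occurrence in the file. Names are whitespace-trimmed and case-sensitive.
#'
#' @param path Path to the pair list.
#' @return An [association_matrix()].
#' @export
load_associations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  .stop_if(length(lines) == 0L, "association file '%s' is empty", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    f <- trimws(fields[[i]])
    .stop_if(length(f) != 2L || any(!nzchar(f)),
             "malformed association line %d: '%s'", i, lines[[i]])
    fields[[i]] <- f
  }
  m <- vapply(fields, `[[`, character(1), 1L)
  d <- vapply(fields, `[[`, character(1), 2L)
  mirnas <- unique(m)
  diseases <- unique(d)
  A <- matrix(0, length(mirnas), length(diseases),
              dimnames = list(mirnas, diseases))
  A[cbind(match(m, mirnas), match(d, diseases))] <- 1
  association_matrix(A)
}

#' Write an association matrix as a pair list
#'
#' Pairs are emitted sorted by (miRNA, disease) name in C-locale order, so
#' the file depends only on the content of the matrix and write/read/write
#' cycles are byte-identical.
#'
#' @param A An [association_matrix()].
#' @param path Output path.
#' @export
write_associations <- function(A, path) {
  idx <- which(A == 1, arr.ind = TRUE)
  m <- rownames(A)[idx[, 1L]]
  d <- colnames(A)[idx[, 2L]]
  o <- order(m, d, method = "radix")
  writeLines(paste(m[o], d[o], sep = "\t"), path)
  invisible(path)
}

#' Build the heterogeneous association network adjacency
#'
#' Stacks miRNA and disease nodes into one graph with adjacency
#' `rbind(cbind(0, A), cbind(t(A), 0))`: miRNAs occupy indices
#' `1..nm`, diseases `nm+1..nm+nd`. Only known associations become edges;
#' there are no miRNA-miRNA or disease-disease edges.
#'
#' @param A An [association_matrix()].
#' @return A symmetric binary matrix of class `heterogeneous_adjacency`.
#' @export
build_heterogeneous_adjacency <- function(A) {
  nm <- nrow(A); nd <- ncol(A)
  G <- rbind(cbind(matrix(0, nm, nm), unclass(A)),
             cbind(t(unclass(A)), matrix(0, nd, nd)))
  nodes <- c(rownames(A), colnames(A))
  dimnames(G) <- list(nodes, nodes)
  attr(G, "n_mirna") <- nm
  attr(G, "n_disease") <- nd
  class(G) <- c("heterogeneous_adjacency", class(matrix()))
  G
}

# ---- disease descriptor trees -------------------------------------------

# Shared constructor: records is a named list, one element per disease,
# each a data.frame(child, parent) of edges (possibly 0 rows). Computes the
# ancestor closure with minimal depths (BFS from the disease along
# child -> parent edges) and the global term -> #DAGs counts.
.build_dag_set <- function(records) {
  dags <- vector("list", length(records))
  names(dags) <- names(records)
  for (dz in names(records)) {
    ed <- records[[dz]]
    nodes <- unique(c(dz, ed$child, ed$parent))
    if (nrow(ed) > 0L) {
      .stop_if(!(dz %in% c(ed$child, ed$parent)),
               "disease '%s' is absent from its own DAG", dz)
      # Kahn's algorithm on the record's edges to reject cycles
      indeg <- table(factor(ed$parent, levels = nodes))
      adj <- split(ed$parent, factor(ed$child, levels = nodes))
      queue <- nodes[indeg == 0L]
      seen <- 0L
      indeg <- as.integer(indeg); names(indeg) <- nodes
      while (length(queue) > 0L) {
        v <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
        for (p in adj[[v]]) {
          indeg[[p]] <- indeg[[p]] - 1L
          if (indeg[[p]] == 0L) queue <- c(queue, p)
        }
      }
      .stop_if(seen < length(nodes), "cycle detected in DAG of disease '%s'", dz)
    }
    # BFS from the disease itself: minimal layer depth of every ancestor
    parents <- split(ed$parent, factor(ed$child, levels = nodes))
    depth <- c(0L); names(depth) <- dz
    frontier <- dz
    while (length(frontier) > 0L) {
      nxt <- character(0)
      for (v in frontier) {
        for (p in parents[[v]]) {
          if (!(p %in% names(depth))) {
            depth[[p]] <- depth[[v]] + 1L
            nxt <- c(nxt, p)
          }
        }
      }
      frontier <- unique(nxt)
    }
    dags[[dz]] <- depth
  }
  terms <- unlist(lapply(dags, names), use.names = FALSE)
  counts <- table(terms)
  term_counts <- as.integer(counts); names(term_counts) <- names(counts)
  structure(list(dags = dags,
                 term_counts = term_counts,
                 n_diseases = length(dags),
                 edges = records),
            class = "disease_dag_set")
}

#' Load per-disease descriptor DAGs
#'
#' File dialect: FASTA-like records. A line `>diseaseID` opens the record
#' for one disease; following `child <TAB> parent` lines give the directed
#' edges of its descriptor tree (child points toward the more general
#' term). A record with no edges describes a root-only DAG containing just
#' the disease. For every disease the ancestor closure reachable from the
#' disease itself is computed, each ancestor annotated with its minimal
#' layer depth (0 = the disease); terms are counted across all DAGs.
#'
#' @param path Path to a DAG file.
#' @return A `disease_dag_set`: `dags` (per disease, named integer vector
#'   term -> minimal depth), `term_counts`, `n_diseases`, and the raw
#'   `edges` used for round-tripping.
#' @export
load_disease_dags <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  .stop_if(length(lines) == 0L, "DAG file '%s' is empty", path)
  .stop_if(!startsWith(lines[[1L]], ">"),
           "DAG file must start with a '>disease' header line")
  records <- list()
  current <- NULL
  child <- parent <- character(0)
  flush <- function() {
    records[[current]] <<- data.frame(child = child, parent = parent,
                                      stringsAsFactors = FALSE)
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (startsWith(ln, ">")) {
      if (!is.null(current)) flush()
      current <- trimws(substring(ln, 2L))
      .stop_if(!nzchar(current), "empty disease id in header at line %d", i)
      .stop_if(current %in% names(records),
               "duplicate DAG record for disease '%s'", current)
      child <- parent <- character(0)
    } else {
      f <- trimws(strsplit(ln, "\t", fixed = TRUE)[[1L]])
      .stop_if(length(f) != 2L || any(!nzchar(f)),
               "malformed DAG edge at line %d: '%s'", i, ln)
      child <- c(child, f[[1L]]); parent <- c(parent, f[[2L]])
    }
  }
  flush()
  .build_dag_set(records)
}

#' Write a disease DAG set back to the file dialect
#'
#' Diseases and their edge lists are sorted (C locale) so output depends
#' only on content.
#'
#' @param dags A `disease_dag_set`.
#' @param path Output path.
#' @export
write_disease_dags <- function(dags, path) {
  out <- character(0)
  for (dz in sort(names(dags$edges), method = "radix")) {
    out <- c(out, paste0(">", dz))
    ed <- dags$edges[[dz]]
    if (nrow(ed) > 0L) {
      o <- order(ed$child, ed$parent, method = "radix")
      out <- c(out, paste(ed$child[o], ed$parent[o], sep = "\t"))
    }
  }
  writeLines(out, path)
  invisible(path)
}
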