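#' Build and validate an ontology DAG
#'
#' @param dag data.frame of \code{is_a} edges with columns \code{child},
#'   \code{parent}.
#' @return an \code{igraph} graph (edges child -> parent), validated to be
#'   acyclic with a single root reachable from every term.
#' @export
ontology_graph <- function(dag) {
  g <- igraph::graph_from_data_frame(dag[, c("child", "parent")],
                                     directed = TRUE)
  if (!igraph::is_dag(g))
    stop("ontology contains a cycle", call. = FALSE)
  roots <- names(which(igraph::degree(g, mode = "out") == 0L))
  if (length(roots) != 1L)
    stop("ontology must have exactly one root, found ",
         length(roots), call. = FALSE)
  g
}

#' True-path propagation of direct annotations
#'
#' A gene annotated to a term is implicitly annotated to every ancestor of
#' that term (the true-path rule).  Idempotent: propagating an already
#' propagated annotation set changes nothing.
#'
#' @param dag edge data.frame (\code{child}, \code{parent}) or an
#'   \code{\link{ontology_graph}}.
#' @param gene2term data.frame with columns \code{gene_id}, \code{term}
#'   (direct annotations).
#' @return data.frame \code{gene_id}, \code{term} including all implied
#'   ancestor annotations (unique rows).
#' @export
propagate_annotations <- function(dag, gene2term) {
  g <- if (inherits(dag, "igraph")) dag else ontology_graph(dag)
  terms <- unique(gene2term$term)
  unknown <- setdiff(terms, igraph::V(g)$name)
  if (length(unknown))
    stop("unknown term(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  anc <- lapply(setNames(terms, terms), function(t)
    names(igraph::subcomponent(g, t, mode = "out")))  # includes t itself
  out <- do.call(rbind, lapply(seq_len(nrow(gene2term)), function(i)
    data.frame(gene_id = gene2term$gene_id[i],
               term = anc[[gene2term$term[i]]],
               stringsAsFactors = FALSE)))
  unique(out)
}

# gene sets per term from a propagated annotation table
term_gene_sets <- function(annotations) {
  split(annotations$gene_id, annotations$term)
}

enrichment_row <- function(id, annotated, significant, expected, p) {
  data.frame(id = id, annotated = annotated, significant = significant,
             expected = expected, p_value = p, stringsAsFactors = FALSE)
}

#' One-sided Fisher (hypergeometric) overrepresentation test
#'
#' Per term, the upper-tail hypergeometric p-value of the overlap between
#' the study set and the term's (propagated) gene set inside the universe;
#' \code{expected = annotated * |study| / |universe|}.
#'
#' @param study_set character vector, subset of \code{universe}.
#' @param annotations propagated annotation data.frame (\code{gene_id},
#'   \code{term}) or a named list of term gene sets.
#' @param universe character vector of all genes eligible for the test.
#' @return data.frame with columns \code{id}, \code{annotated},
#'   \code{significant}, \code{expected}, \code{p_value}, sorted by
#'   ascending p.
#' @export
fisher_classic <- function(study_set, annotations, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  sets <- if (is.data.frame(annotations)) term_gene_sets(annotations)
          else annotations
  study_set <- intersect(unique(study_set), universe)
  n <- length(study_set)
  N <- length(universe)
  rows <- lapply(names(sets), function(term) {
    term_genes <- intersect(unique(sets[[term]]), universe)
    K <- length(term_genes)
    k <- length(intersect(term_genes, study_set))
    p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    enrichment_row(term, K, k, K * n / N, p)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res[order(res$p_value, res$id), , drop = FALSE]
}

#' GO overrepresentation with elim decorrelation
#'
#' Tests terms leaves-to-root; whenever a term's one-sided p-value is at or
#' below \code{elim_cutoff}, the study-set genes annotated to that term are
#' removed from all of its ancestors before those ancestors are tested, so
#' a parent is not called significant merely because a significant child
#' feeds it genes.  \code{elim_cutoff = 0} disables elimination and
#' reproduces \code{\link{fisher_classic}}.  The reported \code{annotated}
#' count is always the true propagated count; only \code{significant} (and
#' hence p) can shrink.
#'
#' @param dag edge data.frame or \code{\link{ontology_graph}}.
#' @param study_set character vector of study genes.
#' @param annotations \emph{propagated} annotation data.frame.
#' @param universe character vector of eligible genes.
#' @param elim_cutoff p-value at or below which a term's genes are
#'   eliminated from its ancestors (default 0.01).
#' @return data.frame as in \code{\link{fisher_classic}}.
#' @export
go_elim <- function(dag, study_set, annotations, universe,
                    elim_cutoff = 0.01) {
  g <- if (inherits(dag, "igraph")) dag else ontology_graph(dag)
  universe <- unique(universe)
  study_set <- intersect(unique(study_set), universe)
  n <- length(study_set)
  N <- length(universe)
  sets <- lapply(term_gene_sets(annotations), function(s)
    intersect(unique(s), universe))
  # leaves-to-root: reverse topological order on child->parent edges
  topo <- igraph::topo_sort(g, mode = "out")$name
  topo <- topo[topo %in% names(sets)]
  removed <- setNames(vector("list", length(sets)), names(sets))
  rows <- list()
  for (term in topo) {
    term_genes <- sets[[term]]
    K_true <- length(term_genes)
    kept <- setdiff(intersect(term_genes, study_set), removed[[term]])
    k <- length(kept)
    p <- phyper(k - 1L, K_true, N - K_true, n, lower.tail = FALSE)
    rows[[term]] <- enrichment_row(term, K_true, k, K_true * n / N, p)
    if (elim_cutoff > 0 && p <= elim_cutoff) {
      anc <- setdiff(names(igraph::subcomponent(g, term, mode = "out")),
                     term)
      elim_genes <- intersect(term_genes, study_set)
      for (a in intersect(anc, names(sets)))
        removed[[a]] <- union(removed[[a]], elim_genes)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res[order(res$p_value, res$id), , drop = FALSE]
}

#' Two-sided Fisher test for gene-family misrepresentation
#'
#' Per family, the two-sided Fisher exact p-value of the 2x2 table
#' (in-family x in-study) by the minimum-likelihood convention: the sum of
#' hypergeometric outcome probabilities not exceeding the observed one
#' (within a 1e-7 relative tie tolerance, the convention of common
#' statistical software).  Detects depletion as well as enrichment.
#'
#' @param study_set character vector of study genes.
#' @param family_sets named list of family gene sets, each a subset of
#'   \code{universe}.
#' @param universe character vector of eligible genes.
#' @return data.frame as in \code{\link{fisher_classic}}.
#' @export
fisher_two_sided <- function(study_set, family_sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  study_set <- intersect(unique(study_set), universe)
  n <- length(study_set)
  N <- length(universe)
  rows <- lapply(names(family_sets), function(fam) {
    fg <- unique(family_sets[[fam]])
    if (length(setdiff(fg, universe)))
      stop("family '", fam, "' not contained in universe", call. = FALSE)
    K <- length(fg)
    k <- length(intersect(fg, study_set))
    p <- two_sided_hyper_p(k, K, n, N)
    enrichment_row(fam, K, k, K * n / N, p)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res[order(res$p_value, res$id), , drop = FALSE]
}

# minimum-likelihood two-sided hypergeometric p for overlap k of a study
# of size n with a family of size K in a universe of size N
two_sided_hyper_p <- function(k, K, n, N) {
  support <- max(0L, n + K - N):min(K, n)
  d <- dhyper(support, K, N - K, n)
  obs <- d[match(k, support)]
  min(1, sum(d[d <= obs * (1 + 1e-7)]))
}
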