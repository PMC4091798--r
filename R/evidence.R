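#' Parse a declarative expression-evidence rule
#'
#' Rules are data, not code: a rule string is a flat conjunction or
#' disjunction of clauses of the form \code{var op number} with variables
#' \code{array_P} (number of arrays calling the gene Present) and
#' \code{reads} (mapped read count), operators \code{>=}, \code{>},
#' \code{<=}, \code{<}, \code{==}, joined by \code{AND} or \code{OR} (one
#' connective kind per rule, no parentheses).
#'
#' Shipped presets mirror the canonical per-cell-type rules of the
#' cross-species comparison design:
#' \describe{
#'   \item{\code{aic}}{\code{"array_P >= 2 OR reads >= 5"} - the founder
#'     cell of the apomictic germline, profiled on two arrays: Present on
#'     both arrays, or expressed by RNA-seq.}
#'   \item{\code{gamete}}{\code{"array_P >= 1 OR reads >= 5"} - egg and
#'     central cell, one array each.}
#'   \item{\code{aic_exclusive}}{\code{"reads >= 5 AND array_P >= 1"} - the
#'     stricter conjunction used when calling genes expressed in the
#'     apomictic founder cell but not its sexual counterpart.}
#'   \item{\code{rnaseq}}{\code{"reads >= 5"} - RNA-seq-only evidence.}
#' }
#'
#' @param rule rule string or preset name.
#' @return an \code{evidence_rule} object: a predicate taking an evidence
#'   data.frame (columns \code{array_P}, \code{reads}) and returning a
#'   logical vector.
#' @examples
#' r <- evidence_rule("aic")
#' r(data.frame(array_P = 2, reads = 0))  # TRUE
#' @export
evidence_rule <- function(rule) {
  presets <- c(aic = "array_P >= 2 OR reads >= 5",
               gamete = "array_P >= 1 OR reads >= 5",
               aic_exclusive = "reads >= 5 AND array_P >= 1",
               rnaseq = "reads >= 5")
  if (rule %in% names(presets)) rule <- presets[[rule]]
  has_and <- grepl("\\bAND\\b", rule)
  has_or <- grepl("\\bOR\\b", rule)
  if (has_and && has_or)
    stop("rule may use AND or OR, not both: ", rule, call. = FALSE)
  clauses <- trimws(strsplit(rule, "\\bAND\\b|\\bOR\\b")[[1]])
  parsed <- lapply(clauses, function(cl) {
    m <- regmatches(cl, regexec("^(array_P|reads)\\s*(>=|<=|==|>|<)\\s*([0-9.]+)$",
                                cl))[[1]]
    if (length(m) != 4L)
      stop("cannot parse rule clause: '", cl, "'", call. = FALSE)
    list(var = m[2], op = m[3], val = as.numeric(m[4]))
  })
  combine <- if (has_and) `&` else `|`
  f <- function(evidence) {
    vals <- lapply(parsed, function(cl) {
      if (!cl$var %in% names(evidence))
        stop("evidence table lacks column '", cl$var, "'", call. = FALSE)
      do.call(cl$op, list(evidence[[cl$var]], cl$val))
    })
    Reduce(combine, vals)
  }
  structure(f, class = "evidence_rule", rule = rule)
}

#' @export
print.evidence_rule <- function(x, ...) {
  cat("<evidence_rule> ", attr(x, "rule"), "\n", sep = "")
  invisible(x)
}

#' Build the per-gene, per-cell-type evidence table
#'
#' Combines array Present calls and RNA-seq counts into one record per
#' (homologue-anchored gene, cell type): \code{array_P} counts how many of
#' the cell type's arrays call the gene Present, and \code{reads} is the
#' maximum mapped read count over the cell type's RNA-seq samples.  Array
#' probesets and RNA-seq genes are mapped onto a common (target-species)
#' gene id space through the homologue map; ids without a homologue are
#' kept as species-local ids and can therefore only ever appear in
#' species-exclusive sets.
#'
#' @param calls presence-call matrix from \code{\link{pa_calls}} (probesets
#'   x arrays), or \code{NULL}.
#' @param counts gene-level count matrix (RNA-seq), or \code{NULL}.
#' @param design data.frame with columns \code{sample}, \code{cell_type},
#'   \code{platform} (\code{"array"} or \code{"rnaseq"}); every array /
#'   count column must appear exactly once.
#' @param homology optional data.frame (\code{query_gene},
#'   \code{target_gene}) used to translate RNA-seq gene ids to the anchored
#'   id space; many-to-one homology collapses by the union of evidence
#'   (maximum read count over supporting variants).
#' @param probeset2gene optional named vector translating probeset ids to
#'   anchored gene ids (identity when omitted).
#' @return data.frame with columns \code{gene}, \code{cell_type},
#'   \code{array_P}, \code{n_arrays}, \code{reads}.
#' @export
build_evidence <- function(calls = NULL, counts = NULL, design,
                           homology = NULL, probeset2gene = NULL) {
  need <- c("sample", "cell_type", "platform")
  if (!all(need %in% names(design)))
    stop("design needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  known <- c(colnames(calls), colnames(counts))
  missing <- setdiff(design$sample, known)
  if (length(missing))
    stop("design sample(s) not found in data: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(design$sample))
    stop("sample(s) assigned more than once in design", call. = FALSE)

  recs <- list()
  for (ct in unique(design$cell_type)) {
    arr <- design$sample[design$cell_type == ct &
                           design$platform == "array"]
    rna <- design$sample[design$cell_type == ct &
                           design$platform == "rnaseq"]
    gene_p <- NULL
    if (length(arr) && !is.null(calls)) {
      sub <- calls[, arr, drop = FALSE]
      ids <- rownames(sub)
      if (!is.null(probeset2gene)) {
        mapped <- probeset2gene[ids]
        ids <- ifelse(is.na(mapped), ids, mapped)
      }
      gene_p <- rowsum(rowSums(sub == "P") + 0, ids)[, 1L]
      gene_p <- pmin(gene_p, length(arr))  # cap at arrays available
    }
    gene_r <- NULL
    if (length(rna) && !is.null(counts)) {
      sub <- counts[, rna, drop = FALSE]
      reads <- apply(sub, 1L, max)
      ids <- rownames(sub)
      if (!is.null(homology)) {
        tg <- homology$target_gene[match(ids, homology$query_gene)]
        ids <- ifelse(is.na(tg), ids, tg)
      }
      gene_r <- tapply(reads, ids, max)  # union of evidence over variants
    }
    genes <- sort(union(names(gene_p), names(gene_r)))
    recs[[ct]] <- data.frame(
      gene = genes,
      cell_type = ct,
      array_P = as.integer(ifelse(genes %in% names(gene_p),
                                  gene_p[genes], 0L)),
      n_arrays = length(arr),
      reads = as.numeric(ifelse(genes %in% names(gene_r),
                                gene_r[genes], 0)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, recs)
  rownames(res) <- NULL
  res
}

#' Venn region counts for two or three sets
#'
#' @param sets named list of 2 or 3 character vectors over a shared id
#'   space.
#' @return named integer vector of region cardinalities (3 regions for two
#'   sets, 7 for three); the regions partition the union.
#' @examples
#' overlap_counts(list(A = c("x", "y"), B = c("y", "z")))
#' @export
overlap_counts <- function(sets) {
  if (!length(sets) %in% 2:3)
    stop("overlap_counts needs 2 or 3 sets", call. = FALSE)
  sets <- lapply(sets, unique)
  nm <- names(sets)
  if (is.null(nm)) nm <- LETTERS[seq_along(sets)]
  u <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) u %in% s, logical(length(u)))
  if (length(u) == 0L)
    member <- matrix(logical(0), 0L, length(sets))
  patterns <- apply(member, 1L, function(b) paste(ifelse(b, "1", "0"),
                                                  collapse = ""))
  combos <- expand.grid(rep(list(c("0", "1")), length(sets)))[-1L, ,
                                                              drop = FALSE]
  combos <- combos[, rev(seq_len(ncol(combos))), drop = FALSE]
  keys <- apply(combos, 1L, paste, collapse = "")
  labels <- apply(combos, 1L, function(b)
    paste(nm[b == "1"], collapse = "&"))
  counts <- vapply(keys, function(k) sum(patterns == k), integer(1))
  setNames(counts, labels)
}

#' Species-exclusive and shared expressed-gene sets
#'
#' Applies each species' cell-type rule to its evidence records and splits
#' the union of expressed genes into A-only, B-only and shared; the three
#' sets partition that union.
#'
#' @param evidence_a,evidence_b evidence data.frames (one cell type each)
#'   on the shared anchored id space.
#' @param rule_a,rule_b rules (strings, preset names, or
#'   \code{\link{evidence_rule}} objects).
#' @return list with \code{a_only}, \code{b_only}, \code{shared}.
#' @export
exclusive_sets <- function(evidence_a, evidence_b,
                           rule_a = "gamete", rule_b = "gamete") {
  if (!inherits(rule_a, "evidence_rule")) rule_a <- evidence_rule(rule_a)
  if (!inherits(rule_b, "evidence_rule")) rule_b <- evidence_rule(rule_b)
  exp_a <- evidence_a$gene[rule_a(evidence_a)]
  exp_b <- evidence_b$gene[rule_b(evidence_b)]
  list(a_only = setdiff(exp_a, exp_b),
       b_only = setdiff(exp_b, exp_a),
       shared = intersect(exp_a, exp_b))
}

#' Genes with evidence of expression in at least k samples of a cell type
#'
#' Each array on which the gene is called Present counts as one supporting
#' sample, as does each RNA-seq sample reaching the read threshold.
#'
#' @param evidence evidence data.frame for one cell type (columns
#'   \code{gene}, \code{array_P}, \code{reads}); the \code{reads} column is
#'   taken per RNA-seq sample when \code{rnaseq_counts} is supplied.
#' @param min_samples minimum supporting samples (default 2).
#' @param min_reads read threshold per RNA-seq sample (default 5).
#' @param rnaseq_counts optional matrix of the cell type's RNA-seq samples
#'   (genes x samples, anchored ids) so several RNA-seq samples can each
#'   contribute; otherwise the single \code{reads} column contributes at
#'   most one sample.
#' @return character vector of gene ids.
#' @export
multi_sample_expressed <- function(evidence, min_samples = 2L,
                                   min_reads = 5L, rnaseq_counts = NULL) {
  n_possible <- evidence$n_arrays[1L] %||% 0L
  rna_samples <- if (is.null(rnaseq_counts)) 1L else ncol(rnaseq_counts)
  if (n_possible + rna_samples < 2L)
    stop("cell type has fewer than 2 samples", call. = FALSE)
  support <- evidence$array_P
  if (is.null(rnaseq_counts)) {
    support <- support + (evidence$reads >= min_reads)
  } else {
    extra <- rowSums(rnaseq_counts >= min_reads)
    support <- support + ifelse(evidence$gene %in% names(extra),
                                extra[evidence$gene], 0L)
  }
  sort(evidence$gene[support >= min_samples])
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a
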