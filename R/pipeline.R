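#' Load and validate a pipeline configuration
#'
#' The configuration is a single declarative YAML file (or an equivalent
#' named list).  Recognized keys, all optional except \code{seed}:
#' simulation parameters (any \code{\link{sim_config}} argument), and the
#' stage parameters \code{n_probesets}, \code{probes_per_set},
#' \code{off_target_fraction}, \code{n_arrays}, \code{max_mismatches},
#' \code{p_present}, \code{p_marginal}, \code{min_negatives},
#' \code{min_total_len}, \code{min_reads}, \code{q}, \code{fdr_cut},
#' \code{raw_cut}, \code{n_terms}, \code{dag_depth}, \code{n_families},
#' \code{elim_cutoff}.
#'
#' @param config path to a YAML file or a named list.
#' @return validated configuration list with defaults filled in (class
#'   \code{pipeline_config}).
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    seed = 42L, n_probesets = 150L, probes_per_set = 11L,
    off_target_fraction = 0.3, n_arrays = 2L,
    max_mismatches = 3L, p_present = 0.02, p_marginal = 0.04,
    min_negatives = 20L, min_total_len = 100L, min_reads = 5L,
    q = 0.9, fdr_cut = 0.05, raw_cut = 0.001,
    n_terms = 40L, dag_depth = 3L, n_families = 10L, elim_cutoff = 0.01,
    psl_divergence = 0.05)
  sim_keys <- names(formals(sim_config))
  unknown <- setdiff(names(config), union(names(defaults), sim_keys))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  stage <- utils::modifyList(defaults,
                             config[intersect(names(config),
                                              names(defaults))])
  sim_args <- config[intersect(names(config), setdiff(sim_keys, "seed"))]
  stage$sim <- do.call(sim_config, c(sim_args, list(seed = stage$seed)))
  structure(stage, class = "pipeline_config")
}

#' Run the full cross-species analysis pipeline on synthetic fixtures
#'
#' Generates the synthetic study (transcriptomes, probe library, array
#' intensities, counts, alignments, annotations), then runs every analysis
#' stage in dependency order: probe mapping and the negative probeset list;
#' quantile normalization, median-polish summarization, PANP p-values and
#' P/M/A calls; homologue assignment; variant-to-gene aggregation,
#' expressed-gene sets and TMM / median-of-ratios factors; NOISeq-style and
#' exact-NB differential expression with the all-pairwise enrichment rules;
#' evidence harmonization with Venn and exclusive-set counts; GO (classic
#' and elim) and family enrichment; and hierarchical clustering of the
#' display-normalized counts of the enriched genes.  All randomness derives
#' from the configured seed, so identical config implies identical outputs.
#'
#' @param config a \code{\link{pipeline_config}}, a path to a YAML config,
#'   or a named list.
#' @param out_dir directory for stage outputs and the JSON report (created
#'   if needed); \code{NULL} computes everything in memory only.
#' @param quiet suppress progress messages (default TRUE).
#' @return a report list: per-stage summary statistics plus the resolved
#'   configuration (invisibly also written to \code{report.json} under
#'   \code{out_dir}).
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = TRUE) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  say <- function(...) if (!quiet) message("[", format(Sys.time(), "%H:%M:%S"),
                                           "] ", ...)
  cfg <- config$sim

  say("simulating fixtures")
  tx <- gen_transcriptome(cfg)
  lib <- gen_probesets(tx, n_probesets = config$n_probesets,
                       probes_per_set = config$probes_per_set,
                       divergence_rate = cfg$probe_divergence_rate,
                       off_target_fraction = config$off_target_fraction,
                       seed = cfg$seed)
  intens <- gen_array_intensities(lib, tx$truth, cfg,
                                  n_arrays = config$n_arrays)
  counts_var <- gen_counts(tx$truth, cfg, variants = tx$variants)
  cfg_t <- cfg; cfg_t$seed <- cfg$seed + 1L
  tx_target <- gen_transcriptome(cfg_t)
  # target gene models carry distinct ids
  names(tx_target$sequences) <- sub("^comp", "tg", names(tx_target$sequences))
  tx_target$variants$variant_id <- sub("^comp", "tg",
                                       tx_target$variants$variant_id)
  tx_target$variants$gene_id <- sub("^comp", "tg",
                                    tx_target$variants$gene_id)
  psl <- gen_homolog_psl(tx, tx_target, divergence = config$psl_divergence,
                         seed = cfg$seed)
  ann <- gen_annotations(unique(tx$variants$gene_id),
                         n_terms = config$n_terms,
                         dag_depth = config$dag_depth,
                         n_families = config$n_families,
                         seed = cfg$seed)

  say("probe mapping")
  aln <- align_probes(lib$probes, tx$sequences,
                      max_mismatches = config$max_mismatches)
  negatives <- classify_negative(lib$probes, aln)

  say("array presence calls")
  normalized <- quantile_normalize(log2(intens))
  expr <- summarize_probesets(normalized, lib$probes)
  pvals <- panp_pvalues(expr, negatives,
                        min_negatives = config$min_negatives)
  calls <- pa_calls(pvals, p_present = config$p_present,
                    p_marginal = config$p_marginal)

  say("homologue assignment")
  homology <- assign_homologues(psl$psl,
                                min_total_len = config$min_total_len)

  say("counts and normalization")
  counts <- gene_counts(counts_var)
  expressed <- expressed_genes(counts, min_reads = config$min_reads)
  tmm <- tmm_factors(counts)
  sf <- size_factors_median_ratio(counts)

  say("differential expression")
  focal <- cfg$samples[1L]
  others <- cfg$samples[-1L]
  noiseq <- lapply(setNames(others, others), function(s)
    noiseq_sim(counts, focal, s, norm_factors = tmm,
               seed = cfg$seed)$results)
  noiseq_set <- noiseq_enriched(noiseq, q = config$q)
  nb_contrast <- function(a, b) {
    p <- exact_nb_test(counts[, a], counts[, b],
                       sum(counts[, a]) * tmm[[a]],
                       sum(counts[, b]) * tmm[[b]],
                       dispersion = cfg$dispersion)
    data.frame(gene = rownames(counts),
               logFC = log2((counts[, a] + 0.5) / (sum(counts[, a]) * tmm[[a]])) -
                 log2((counts[, b] + 0.5) / (sum(counts[, b]) * tmm[[b]])),
               p = p, fdr = bh_adjust(p),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  focal_contrasts <- lapply(setNames(others, paste(focal, others,
                                                   sep = "_vs_")),
                            function(s) nb_contrast(focal, s))
  gam <- utils::combn(others, 2L)
  other_contrasts <- lapply(setNames(seq_len(ncol(gam)),
                                     paste(gam[1L, ], gam[2L, ],
                                           sep = "_vs_")),
                            function(i) nb_contrast(gam[1L, i], gam[2L, i]))
  special <- paste(others[1L], others[2L], sep = "_vs_")
  exact_sets <- exact_test_enriched(focal_contrasts, other_contrasts,
                                    fdr_cut = config$fdr_cut,
                                    raw_cut = config$raw_cut,
                                    special_pair = special)

  say("evidence harmonization")
  design <- data.frame(
    sample = c(colnames(calls), cfg$samples),
    cell_type = c(rep(focal, ncol(calls)), cfg$samples),
    platform = c(rep("array", ncol(calls)), rep("rnaseq",
                                                length(cfg$samples))),
    stringsAsFactors = FALSE)
  ps2gene <- setNames(lib$probeset_truth$gene_id,
                      lib$probeset_truth$probeset_id)
  ps2gene <- ps2gene[!is.na(ps2gene)]
  evidence <- build_evidence(calls = calls, counts = counts,
                             design = design, probeset2gene = ps2gene)
  ev_focal <- evidence[evidence$cell_type == focal, , drop = FALSE]
  ev_b <- evidence[evidence$cell_type == others[1L], , drop = FALSE]
  excl <- exclusive_sets(ev_focal, ev_b,
                         rule_a = "aic", rule_b = "rnaseq")
  venn <- overlap_counts(list(array_P = ev_focal$gene[ev_focal$array_P >= 1],
                              rnaseq = expressed[[focal]]))
  multi <- multi_sample_expressed(ev_focal, min_samples = 2L,
                                  min_reads = config$min_reads)

  say("enrichment")
  propagated <- propagate_annotations(ann$dag, ann$gene2term)
  universe <- unique(propagated$gene_id)
  study <- intersect(noiseq_set, universe)
  go_classic <- fisher_classic(study, propagated, universe)
  go_elim_res <- go_elim(ann$dag, study, propagated, universe,
                         elim_cutoff = config$elim_cutoff)
  fam_sets <- split(ann$families$gene_id, ann$families$family)
  fam_sets <- lapply(fam_sets, intersect, universe)
  fam_res <- fisher_two_sided(study, fam_sets, universe)

  say("clustering")
  heat_genes <- head(union(noiseq_set, exact_sets$enriched), 500L)
  clust <- NULL
  if (length(heat_genes) >= 2L) {
    hm <- row_scale_log2(counts[heat_genes, , drop = FALSE], sf)
    clust <- hcluster(hm)
  }

  report <- list(
    config = unclass(config)[setdiff(names(config), "sim")],
    sim_config = unclass(cfg),
    package_version = as.character(utils::packageVersion("crossgerm")),
    summary = list(
      n_genes = length(unique(tx$variants$gene_id)),
      n_variants = nrow(tx$variants),
      n_probesets = config$n_probesets,
      n_probe_alignments = nrow(aln),
      n_negative_probesets = length(negatives),
      n_present_calls = sum(calls == "P"),
      n_homolog_assigned = sum(!is.na(homology$target_gene)),
      n_expressed_per_sample = lengths(expressed),
      tmm_factors = as.list(tmm),
      size_factors = as.list(sf),
      n_noiseq_enriched = length(noiseq_set),
      n_exact_enriched = length(exact_sets$enriched),
      n_exact_de_union = length(exact_sets$de_union),
      venn = as.list(venn),
      n_exclusive_a = length(excl$a_only),
      n_exclusive_b = length(excl$b_only),
      n_shared = length(excl$shared),
      n_multi_sample_expressed = length(multi),
      top_go_elim = go_elim_res$id[1L],
      min_go_classic_p = min(go_classic$p_value),
      min_family_p = min(fam_res$p_value),
      leaf_order = if (is.null(clust)) character(0) else clust$order_ids))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(...) file.path(out_dir, ...)
    write_fasta(tx$sequences, w("transcriptome.fasta"))
    write_probe_library(lib$probes, w("probes.tsv"))
    write_matrix_tsv(intens, w("intensities.tsv"), "probe_id")
    write_matrix_tsv(counts_var, w("variant_counts.tsv"), "variant_id")
    write_psl(psl$psl, w("alignments.psl"))
    write.table(aln, w("probe_alignments.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_set_file(negatives, w("negative_probesets.txt"))
    write_matrix_tsv(expr, w("expression.tsv"), "probeset_id")
    write_matrix_tsv(pvals, w("panp_pvalues.tsv"), "probeset_id")
    write_matrix_tsv(calls, w("pa_calls.tsv"), "probeset_id")
    write.table(homology, w("homologues.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_matrix_tsv(counts, w("gene_counts.tsv"), "gene_id")
    write.table(data.frame(sample = names(tmm), factor = unname(tmm),
                           method = "tmm"),
                w("norm_factors.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_set_file(noiseq_set, w("noiseq_enriched.txt"))
    write_set_file(exact_sets$enriched, w("exact_enriched.txt"))
    write.table(evidence, w("evidence.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(go_elim_res, w("go_elim.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(fam_res, w("family_enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, w("report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(report)
}

#' Self-consistency audit of a pipeline output directory
#'
#' Recomputes the headline counts of \code{report.json} from the emitted
#' stage files and compares.
#'
#' @param out_dir directory written by \code{\link{run_pipeline}}.
#' @return TRUE invisibly if every audited number matches; otherwise an
#'   error describing the first mismatch.
#' @export
audit_report <- function(out_dir) {
  rep <- jsonlite::read_json(file.path(out_dir, "report.json"),
                             simplifyVector = TRUE)
  s <- rep$summary
  chk <- function(label, got, want) {
    if (!isTRUE(all.equal(as.numeric(got), as.numeric(want))))
      stop("audit mismatch for ", label, ": report ", want,
           ", recomputed ", got, call. = FALSE)
  }
  negatives <- read_set_file(file.path(out_dir, "negative_probesets.txt"))
  chk("n_negative_probesets", length(negatives), s$n_negative_probesets)
  aln <- read.delim(file.path(out_dir, "probe_alignments.tsv"))
  chk("n_probe_alignments", nrow(aln), s$n_probe_alignments)
  calls <- read_matrix_tsv(file.path(out_dir, "pa_calls.tsv"))
  chk("n_present_calls", sum(calls == "P"), s$n_present_calls)
  hom <- read.delim(file.path(out_dir, "homologues.tsv"))
  chk("n_homolog_assigned", sum(!is.na(hom$target_gene)),
      s$n_homolog_assigned)
  counts <- read_matrix_tsv(file.path(out_dir, "gene_counts.tsv"))
  vc <- read_matrix_tsv(file.path(out_dir, "variant_counts.tsv"))
  chk("count conservation", colSums(vc), colSums(counts))
  noiseq_set <- read_set_file(file.path(out_dir, "noiseq_enriched.txt"))
  chk("n_noiseq_enriched", length(noiseq_set), s$n_noiseq_enriched)
  exact_set <- read_set_file(file.path(out_dir, "exact_enriched.txt"))
  chk("n_exact_enriched", length(exact_set), s$n_exact_enriched)
  chk("venn partition",
      sum(unlist(s$venn)),
      length(union(
        read.delim(file.path(out_dir, "evidence.tsv"))$gene[
          read.delim(file.path(out_dir, "evidence.tsv"))$array_P >= 1],
        rownames(counts)[counts[, 1L] >= 5])))
  invisible(TRUE)
}

#' Hierarchical clustering with a deterministic leaf order
#'
#' Agglomerative clustering of matrix rows (euclidean distance, complete
#' linkage by default) as used for expression heatmaps.  Rows are sorted by
#' id before clustering so that ties in the merge sequence break
#' deterministically.
#'
#' @param m numeric matrix (>= 2 rows, finite values).
#' @param metric distance metric for \code{\link[stats]{dist}}.
#' @param linkage agglomeration method for \code{\link[stats]{hclust}}.
#' @return list with \code{tree} (an \code{hclust} object), \code{order_ids}
#'   (leaf labels in dendrogram order) and \code{heights} (merge heights).
#' @export
hcluster <- function(m, metric = "euclidean", linkage = "complete") {
  if (nrow(m) < 2L) stop("need at least 2 rows to cluster", call. = FALSE)
  if (any(!is.finite(m))) stop("matrix must be finite", call. = FALSE)
  m <- m[order(rownames(m)), , drop = FALSE]
  tree <- hclust(dist(m, method = metric), method = linkage)
  list(tree = tree, order_ids = rownames(m)[tree$order],
       heights = tree$height)
}

#' Display-path log2 normalization of counts
#'
#' \code{log2(count / size_factor + pseudocount)}, the transformation
#' applied to read counts before heatmap clustering; optionally centers
#' each row (per-row colour scaling).
#'
#' @param counts count matrix (genes x samples).
#' @param size_factors named positive factors (e.g.
#'   \code{\link{size_factors_median_ratio}}).
#' @param pseudocount offset inside the log (default 1).
#' @param center_rows subtract row means after the transform.
#' @return transformed numeric matrix.
#' @export
row_scale_log2 <- function(counts, size_factors, pseudocount = 1,
                           center_rows = FALSE) {
  if (any(size_factors <= 0)) stop("size factors must be > 0",
                                   call. = FALSE)
  f <- size_factors[colnames(counts)]
  if (anyNA(f)) stop("missing size factor for some sample", call. = FALSE)
  m <- log2(sweep(counts, 2L, f, "/") + pseudocount)
  if (center_rows) m <- m - rowMeans(m)
  m
}
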