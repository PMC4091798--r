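#' Generate a synthetic reference transcriptome with ground truth
#'
#' Emits a de-novo-assembly-style transcriptome: gene models named
#' \code{comp<i>_c0} carrying one or more transcript variants named
#' \code{comp<i>_c0_seq<j>}, with random ACGT sequences whose lengths follow
#' a normal distribution floored at \code{min_length}.  Alongside the
#' sequences a truth table records, per gene, whether it is expressed,
#' whether it is differentially expressed, the sample it is upregulated in,
#' and its fold change - the ground truth every downstream stage is tested
#' against.
#'
#' @param config a \code{\link{sim_config}}.
#' @return a list with components \code{sequences} (a named
#'   \code{\link[Biostrings]{DNAStringSet}}), \code{variants} (data.frame:
#'   \code{variant_id}, \code{gene_id}, \code{length}) and \code{truth}
#'   (data.frame: \code{gene_id}, \code{expressed}, \code{de},
#'   \code{de_sample}, \code{fold_change}, \code{expressed_in}).
#' @examples
#' tx <- gen_transcriptome(sim_config(seed = 1, n_genes = 10))
#' length(tx$sequences) >= 10
#' @export
gen_transcriptome <- function(config) {
  config <- validate_sim_config(config)
  with_stage_seed(config$seed, 1L, {
    n <- config$n_genes
    gene_ids <- sprintf("comp%d_c0", seq_len(n))
    nvar <- if (length(config$variants_per_gene) == 1L)
      rep(config$variants_per_gene, n)
    else
      sample(config$variants_per_gene, n, replace = TRUE)
    variant_gene_id <- rep(gene_ids, nvar)
    variant_id <- paste0(variant_gene_id, "_seq",
                         unlist(lapply(nvar, seq_len), use.names = FALSE))
    lens <- pmax(config$min_length,
                 as.integer(round(rnorm(length(variant_id),
                                        config$mean_length,
                                        config$sd_length))))
    seqs <- vapply(lens, random_dna, character(1))
    sequences <- Biostrings::DNAStringSet(seqs)
    names(sequences) <- variant_id

    expressed <- runif(n) < config$expressed_fraction
    de <- rep(FALSE, n)
    n_de <- round(config$de_fraction * n)
    if (n_de > 0) {
      de_pool <- which(expressed)
      de[sample(de_pool, min(n_de, length(de_pool)))] <- TRUE
    }
    truth <- data.frame(
      gene_id = gene_ids,
      expressed = expressed,
      de = de,
      de_sample = ifelse(de, config$samples[1L], NA_character_),
      fold_change = ifelse(de, config$fold_change, 1),
      expressed_in = ifelse(expressed,
                            paste(config$samples, collapse = ","), ""),
      stringsAsFactors = FALSE)
    list(sequences = sequences,
         variants = data.frame(variant_id = variant_id,
                               gene_id = variant_gene_id,
                               length = lens,
                               stringsAsFactors = FALSE),
         truth = truth)
  })
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic probe library with per-probe divergence truth
#'
#' On-target probesets copy \code{probes_per_set} probes of length
#' \code{probe_length} from randomly chosen transcripts and then mutate each
#' base independently with probability \code{divergence_rate}, emulating
#' cross-species probe/target divergence (0 to 3+ mismatches per probe).
#' A fraction \code{off_target_fraction} of probesets instead receive fully
#' random sequences; these are the expected negative probesets.
#'
#' @param transcriptome a list as returned by \code{\link{gen_transcriptome}}.
#' @param n_probesets number of probesets.
#' @param probes_per_set probes per probeset (ATH1-style default 11).
#' @param divergence_rate per-base substitution probability for on-target
#'   probes.
#' @param off_target_fraction fraction of probesets given random sequences.
#' @param seed integer seed.
#' @param probe_length probe length in bp (default 25).
#' @return list with \code{probes} (data.frame \code{probeset_id},
#'   \code{probe_id}, \code{sequence}), \code{probe_truth} (source variant,
#'   start, introduced mismatch count per probe; \code{NA} for off-target)
#'   and \code{probeset_truth} (\code{probeset_id}, \code{gene_id},
#'   \code{off_target}).
#' @export
gen_probesets <- function(transcriptome, n_probesets,
                          probes_per_set = 11L,
                          divergence_rate = 0.02,
                          off_target_fraction = 0.2,
                          seed = 42L,
                          probe_length = 25L) {
  with_stage_seed(seed, 2L, {
    seqs <- as.character(transcriptome$sequences)
    usable <- names(seqs)[nchar(seqs) >= probe_length]
    if (length(usable) < length(seqs))
      warning(length(seqs) - length(usable),
              " transcript(s) shorter than ", probe_length, " bp skipped")
    if (length(usable) == 0L)
      stop("no transcript long enough to host a probe", call. = FALSE)
    var2gene <- structure(transcriptome$variants$gene_id,
                          names = transcriptome$variants$variant_id)

    n_off <- round(off_target_fraction * n_probesets)
    off <- seq_len(n_probesets) <= n_off   # deterministic partition
    probeset_id <- sprintf("ps%04d", seq_len(n_probesets))

    probes <- vector("list", n_probesets)
    truths <- vector("list", n_probesets)
    for (i in seq_len(n_probesets)) {
      pid <- paste0(probeset_id[i], "_p", seq_len(probes_per_set))
      if (off[i]) {
        sq <- vapply(rep(probe_length, probes_per_set), random_dna,
                     character(1))
        truths[[i]] <- data.frame(probe_id = pid,
                                  probeset_id = probeset_id[i],
                                  source_variant = NA_character_,
                                  start = NA_integer_,
                                  mismatches = NA_integer_,
                                  stringsAsFactors = FALSE)
      } else {
        v <- sample(usable, 1L)
        tlen <- nchar(seqs[[v]])
        starts <- sample.int(tlen - probe_length + 1L, probes_per_set,
                             replace = tlen - probe_length + 1L < probes_per_set)
        raw <- substring(seqs[[v]], starts, starts + probe_length - 1L)
        mut <- mutate_sequences(raw, divergence_rate)
        sq <- mut$sequences
        truths[[i]] <- data.frame(probe_id = pid,
                                  probeset_id = probeset_id[i],
                                  source_variant = v,
                                  start = starts - 1L,  # 0-based
                                  mismatches = mut$n_sub,
                                  stringsAsFactors = FALSE)
      }
      probes[[i]] <- data.frame(probeset_id = probeset_id[i],
                                probe_id = pid,
                                sequence = sq,
                                stringsAsFactors = FALSE)
    }
    probe_truth <- do.call(rbind, truths)
    gene_of_set <- ifelse(off, NA_character_,
                          unname(var2gene[probe_truth$source_variant[
                            match(probeset_id, probe_truth$probeset_id)]]))
    list(probes = do.call(rbind, probes),
         probe_truth = probe_truth,
         probeset_truth = data.frame(probeset_id = probeset_id,
                                     gene_id = gene_of_set,
                                     off_target = off,
                                     stringsAsFactors = FALSE))
  })
}

# Substitute each base independently with probability `rate`, always to a
# different base; returns sequences and per-sequence substitution counts.
mutate_sequences <- function(seqs, rate) {
  bases <- c("A", "C", "G", "T")
  n_sub <- integer(length(seqs))
  if (rate <= 0)
    return(list(sequences = seqs, n_sub = n_sub))
  out <- vapply(seq_along(seqs), function(i) {
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    hit <- runif(length(ch)) < rate
    if (any(hit)) {
      ch[hit] <- vapply(ch[hit], function(b)
        sample(setdiff(bases, b), 1L), character(1))
      n_sub[i] <<- sum(hit)
    }
    paste(ch, collapse = "")
  }, character(1))
  list(sequences = out, n_sub = n_sub)
}

#' Generate probe-level array intensities
#'
#' Probesets targeting an expressed gene draw log2 intensities from the
#' signal distribution; all other probesets (unexpressed targets and
#' off-target sets) draw from the background distribution.  Each probe
#' additionally carries a fixed additive affinity effect (mean 0, SD
#' \code{probe_effect_sd}) shared across arrays, giving median-polish
#' summarization realistic structure to remove.  Intensities are returned on
#' the linear scale (\code{2^log2value}); the array-processing stage applies
#' the log2 transform itself.
#'
#' @param probe_library result of \code{\link{gen_probesets}}.
#' @param truth gene-level truth table from \code{\link{gen_transcriptome}}.
#' @param config a \code{\link{sim_config}}.
#' @param n_arrays number of array columns to simulate.
#' @param array_ids optional column names.
#' @return numeric matrix, probes x arrays, rownames = probe ids.
#' @export
gen_array_intensities <- function(probe_library, truth, config,
                                  n_arrays = 2L,
                                  array_ids = paste0("array", seq_len(n_arrays))) {
  config <- validate_sim_config(config)
  with_stage_seed(config$seed, 3L, {
    pr <- probe_library$probes
    pst <- probe_library$probeset_truth
    expressed_genes <- truth$gene_id[truth$expressed]
    set_expressed <- !pst$off_target & pst$gene_id %in% expressed_genes
    probe_set_expressed <- set_expressed[match(pr$probeset_id,
                                               pst$probeset_id)]
    n_probes <- nrow(pr)
    probe_effect <- rnorm(n_probes, 0, config$probe_effect_sd)
    mu <- ifelse(probe_set_expressed, config$signal_mean,
                 config$background_mean)
    sdv <- ifelse(probe_set_expressed, config$signal_sd,
                  config$background_sd)
    m <- matrix(0, n_probes, n_arrays,
                dimnames = list(pr$probe_id, array_ids))
    for (j in seq_len(n_arrays))
      m[, j] <- 2 ^ (rnorm(n_probes, mu, sdv) + probe_effect)
    m
  })
}

#' Generate a negative-binomial count table with known fold changes
#'
#' Per-gene baseline means are log-normal; differentially expressed genes are
#' multiplied by their truth fold change in the sample they are upregulated
#' in.  Column means are scaled so that expected column sums equal the
#' configured library sizes, then counts are drawn from a negative binomial
#' with dispersion \code{config$dispersion} (variance \code{mu + phi mu^2});
#' \code{dispersion = 0} gives Poisson counts.
#'
#' @param truth gene-level truth table from \code{\link{gen_transcriptome}}.
#' @param config a \code{\link{sim_config}}.
#' @param variants optional variant table (\code{variant_id}, \code{gene_id});
#'   when supplied, gene means are split across variants by random Dirichlet
#'   proportions and counts are emitted per variant, exercising the
#'   variant-to-gene aggregation stage.
#' @return integer matrix of counts (genes or variants x samples).
#' @export
gen_counts <- function(truth, config, variants = NULL) {
  config <- validate_sim_config(config)
  if (config$dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  with_stage_seed(config$seed, 4L, {
    n <- nrow(truth)
    baseline <- ifelse(truth$expressed,
                       exp(rnorm(n, log(50), config$baseline_sd)),
                       0.05)
    mu <- matrix(baseline, n, length(config$samples),
                 dimnames = list(truth$gene_id, config$samples))
    for (j in seq_along(config$samples)) {
      up <- !is.na(truth$de_sample) & truth$de_sample == config$samples[j]
      mu[up, j] <- mu[up, j] * truth$fold_change[up]
    }
    if (!is.null(variants)) {
      k <- table(variants$gene_id)[truth$gene_id]
      w <- unlist(lapply(k, function(m) {
        g <- rgamma(m, shape = 2)
        g / sum(g)
      }), use.names = FALSE)
      idx <- match(variants$gene_id, truth$gene_id)
      ord <- order(idx)  # variants grouped by gene in truth order
      mu <- mu[idx[ord], , drop = FALSE] * w
      rownames(mu) <- variants$variant_id[ord]
    }
    # scale expected column sums to library sizes
    mu <- sweep(mu, 2L, colSums(mu), "/")
    mu <- sweep(mu, 2L, as.numeric(config$library_sizes), "*")
    counts <- mu
    for (j in seq_len(ncol(mu))) {
      counts[, j] <- if (config$dispersion == 0)
        rpois(nrow(mu), mu[, j])
      else
        rnbinom(nrow(mu), mu = mu[, j], size = 1 / config$dispersion)
    }
    storage.mode(counts) <- "integer"
    counts
  })
}

#' Generate an is_a ontology DAG, gene annotations and gene families
#'
#' Terms are arranged in \code{dag_depth} levels under a single root; every
#' non-root term has one parent in the level above and, with probability
#' 0.25, a second parent (making a genuine DAG rather than a tree).  The
#' emitted gene annotations are direct only - true-path propagation is a
#' pipeline stage, not a generator feature.  Families are free to overlap:
#' a gene may belong to several.
#'
#' @param genes character vector of gene ids.
#' @param n_terms total number of terms including the root.
#' @param dag_depth number of levels below the root (>= 1).
#' @param n_families number of gene families.
#' @param seed integer seed.
#' @param terms_per_gene average number of direct term annotations per gene.
#' @return list with \code{dag} (data.frame \code{child}, \code{parent}),
#'   \code{gene2term} (data.frame \code{gene_id}, \code{term}) and
#'   \code{families} (data.frame \code{gene_id}, \code{family}).
#' @export
gen_annotations <- function(genes, n_terms = 50L, dag_depth = 3L,
                            n_families = 10L, seed = 42L,
                            terms_per_gene = 2) {
  if (dag_depth < 1L) stop("dag_depth must be >= 1", call. = FALSE)
  if (n_terms < 1L) stop("n_terms must be >= 1", call. = FALSE)
  with_stage_seed(seed, 5L, {
    term_ids <- sprintf("T%04d", seq_len(n_terms))
    root <- term_ids[1L]
    if (n_terms == 1L) {
      dag <- data.frame(child = character(0), parent = character(0),
                        stringsAsFactors = FALSE)
      levels <- list(root)
    } else {
      rest <- term_ids[-1L]
      lev <- sort(sample.int(dag_depth, length(rest), replace = TRUE))
      levels <- c(list(root), split(rest, lev))
      edges <- list()
      for (d in seq_along(levels)[-1L]) {
        parents_pool <- levels[[d - 1L]]
        ch <- levels[[d]]
        p1 <- sample(parents_pool, length(ch), replace = TRUE)
        edges[[length(edges) + 1L]] <-
          data.frame(child = ch, parent = p1, stringsAsFactors = FALSE)
        extra <- runif(length(ch)) < 0.25
        if (any(extra)) {
          p2 <- sample(parents_pool, sum(extra), replace = TRUE)
          keep <- p2 != p1[extra]
          if (any(keep))
            edges[[length(edges) + 1L]] <-
              data.frame(child = ch[extra][keep], parent = p2[keep],
                         stringsAsFactors = FALSE)
        }
      }
      dag <- do.call(rbind, edges)
    }
    leafish <- setdiff(term_ids, root)
    if (length(leafish) == 0L) leafish <- root
    g2t <- do.call(rbind, lapply(genes, function(g) {
      k <- max(1L, rpois(1L, terms_per_gene))
      data.frame(gene_id = g,
                 term = sample(leafish, min(k, length(leafish))),
                 stringsAsFactors = FALSE)
    }))
    fam_ids <- sprintf("FAM%03d", seq_len(n_families))
    fam <- do.call(rbind, lapply(genes, function(g) {
      k <- rbinom(1L, 2L, 0.4)
      if (k == 0L) return(NULL)
      data.frame(gene_id = g, family = sample(fam_ids, k),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(fam))
      fam <- data.frame(gene_id = character(0), family = character(0),
                        stringsAsFactors = FALSE)
    list(dag = dag, gene2term = g2t, families = fam)
  })
}

#' Generate a synthetic PSL alignment file with known homologue pairs
#'
#' Pairs each query-species gene with at most one distinct target-species
#' gene and emits one single-block PSL record per query variant against a
#' variant of the paired target gene, with \code{matches} set to
#' \code{round(L * (1 - divergence))} of the aligned length \code{L}.  Decoy
#' records pointing at a wrong target gene are added for a fraction of query
#' genes at \code{decoy_score_frac} of the true match count, exercising the
#' argmax over score sums.
#'
#' @param transcriptome_q query-species transcriptome
#'   (\code{\link{gen_transcriptome}} result).
#' @param transcriptome_t target-species transcriptome.
#' @param divergence per-base mismatch fraction of true alignments.
#' @param seed integer seed.
#' @param decoy_fraction fraction of query genes receiving a decoy record.
#' @param decoy_score_frac decoy match count relative to the true record.
#' @return list with \code{psl} (21-column data.frame in standard order)
#'   and \code{pairs} (data.frame \code{query_gene}, \code{target_gene}).
#' @export
gen_homolog_psl <- function(transcriptome_q, transcriptome_t,
                            divergence = 0.05, seed = 42L,
                            decoy_fraction = 0.5,
                            decoy_score_frac = 0.5) {
  if (divergence < 0 || divergence >= 1)
    stop("divergence must lie in [0, 1)", call. = FALSE)
  with_stage_seed(seed, 6L, {
    qv <- transcriptome_q$variants
    tv <- transcriptome_t$variants
    q_genes <- unique(qv$gene_id)
    t_genes <- unique(tv$gene_id)
    n_pairs <- min(length(q_genes), length(t_genes))
    target_for <- structure(sample(t_genes, n_pairs),
                            names = q_genes[seq_len(n_pairs)])
    rec <- list()
    mk_rec <- function(qvar, qlen, tvar, tlen, frac_match) {
      L <- min(qlen, tlen)
      m <- as.integer(round(L * frac_match))
      mm <- L - m
      data.frame(matches = m, misMatches = mm, repMatches = 0L, nCount = 0L,
                 qNumInsert = 0L, qBaseInsert = 0L,
                 tNumInsert = 0L, tBaseInsert = 0L,
                 strand = "+", qName = qvar, qSize = qlen,
                 qStart = 0L, qEnd = L,
                 tName = tvar, tSize = tlen, tStart = 0L, tEnd = L,
                 blockCount = 1L, blockSizes = paste0(L, ","),
                 qStarts = "0,", tStarts = "0,",
                 stringsAsFactors = FALSE)
    }
    for (qg in names(target_for)) {
      tg <- target_for[[qg]]
      qvars <- qv[qv$gene_id == qg, , drop = FALSE]
      tvars <- tv[tv$gene_id == tg, , drop = FALSE]
      for (i in seq_len(nrow(qvars))) {
        tpick <- tvars[sample.int(nrow(tvars), 1L), , drop = FALSE]
        rec[[length(rec) + 1L]] <- mk_rec(qvars$variant_id[i],
                                          qvars$length[i],
                                          tpick$variant_id,
                                          tpick$length,
                                          1 - divergence)
      }
      if (runif(1) < decoy_fraction && length(t_genes) > 1L) {
        wrong <- sample(setdiff(t_genes, tg), 1L)
        wv <- tv[tv$gene_id == wrong, , drop = FALSE]
        wpick <- wv[sample.int(nrow(wv), 1L), , drop = FALSE]
        # decoy at decoy_score_frac of the true PSL score: with a single
        # block of length L, score = matches - misMatches = 2m - L, so the
        # decoy match count solves 2m' - L = f (2m - L)
        L <- min(qvars$length[1L], wpick$length)
        true_score <- 2 * round(L * (1 - divergence)) - L
        m2 <- as.integer(round((decoy_score_frac * true_score + L) / 2))
        m2 <- max(0L, min(L, m2))
        rec[[length(rec) + 1L]] <- mk_rec(qvars$variant_id[1L],
                                          qvars$length[1L],
                                          wpick$variant_id,
                                          wpick$length,
                                          m2 / L)
      }
    }
    list(psl = do.call(rbind, rec),
         pairs = data.frame(query_gene = names(target_for),
                            target_gene = unname(target_for),
                            stringsAsFactors = FALSE))
  })
}
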