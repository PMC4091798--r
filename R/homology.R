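psl_columns <- c("matches", "misMatches", "repMatches", "nCount",
                 "qNumInsert", "qBaseInsert", "tNumInsert", "tBaseInsert",
                 "strand", "qName", "qSize", "qStart", "qEnd",
                 "tName", "tSize", "tStart", "tEnd",
                 "blockCount", "blockSizes", "qStarts", "tStarts")
psl_int_cols <- setdiff(psl_columns,
                        c("strand", "qName", "tName",
                          "blockSizes", "qStarts", "tStarts"))

#' Read a 21-column PSL alignment file
#'
#' Auto-detects and skips the 5-line \code{psLayout} header.  Records are
#' validated against the PSL invariants (0-based half-open coordinates,
#' \code{qStart < qEnd <= qSize}, block sizes summing to
#' \code{matches + misMatches + repMatches + nCount}); offending records are
#' dropped with a warning, a wrong column count is an error naming the line.
#'
#' @param path PSL file path.
#' @return data.frame with the 21 standard PSL columns (empty for an empty
#'   file).
#' @export
read_psl <- function(path) {
  lines <- readLines(path)
  if (length(lines) && startsWith(lines[1L], "psLayout")) {
    if (length(lines) < 5L)
      stop("truncated psLayout header in ", path, call. = FALSE)
    lines <- lines[-(1:5)]
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(empty_psl())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 21L))
    stop("PSL line ", which(nf != 21L)[1L], ": expected 21 columns, got ",
         nf[nf != 21L][1L], call. = FALSE)
  df <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(df) <- psl_columns
  for (col in psl_int_cols) df[[col]] <- as.integer(df[[col]])
  ok <- validate_psl_records(df)
  if (!all(ok)) {
    warning(sum(!ok), " PSL record(s) violating format invariants dropped")
    df <- df[ok, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

empty_psl <- function() {
  df <- as.data.frame(setNames(rep(list(character(0)), 21L), psl_columns),
                      stringsAsFactors = FALSE)
  for (col in psl_int_cols) df[[col]] <- integer(0)
  df
}

validate_psl_records <- function(df) {
  block_sum <- vapply(strsplit(df$blockSizes, ",", fixed = TRUE),
                      function(x) sum(as.integer(x)), numeric(1))
  df$qStart < df$qEnd & df$qEnd <= df$qSize &
    df$tStart < df$tEnd & df$tEnd <= df$tSize &
    block_sum == df$matches + df$misMatches + df$repMatches + df$nCount
}

#' @rdname read_psl
#' @param psl PSL data.frame.
#' @param header write the 5-line psLayout header (default FALSE).
#' @export
write_psl <- function(psl, path, header = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  if (header) {
    writeLines(c("psLayout version 3", "",
                 paste(psl_columns[1:9], collapse = "\t"), "",
                 paste(rep("-", 60), collapse = "")), con)
  }
  write.table(psl[, psl_columns], con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Score a PSL alignment record
#'
#' The standard BLAT alignment score derivable from PSL fields:
#' \code{matches + repMatches - misMatches - qNumInsert - tNumInsert}.
#' Used as the per-alignment score that is summed per gene pair when
#' assigning closest homologues.
#'
#' @param psl PSL data.frame (one or more records).
#' @return numeric vector of scores.
#' @examples
#' psl_score(data.frame(matches = 90, repMatches = 0, misMatches = 5,
#'                      qNumInsert = 1, tNumInsert = 1))
#' @export
psl_score <- function(psl) {
  psl$matches + psl$repMatches - psl$misMatches -
    psl$qNumInsert - psl$tNumInsert
}

#' Collapse a transcript-variant id to its gene id
#'
#' De-novo-assembly variant ids of the form \code{comp<i>_c<j>_seq<k>} are
#' collapsed to the gene model \code{comp<i>_c<j>} by stripping the
#' \code{_seq<k>} suffix.  Ids not matching the pattern pass through
#' unchanged with a warning (each is treated as its own gene).
#'
#' @param ids character vector of variant ids.
#' @param pattern regex whose removal yields the gene id.
#' @param warn warn on non-matching ids (default TRUE).
#' @return character vector of gene ids.
#' @examples
#' variant_gene("comp76373_c0_seq1")  # "comp76373_c0"
#' @export
variant_gene <- function(ids, pattern = "_seq[0-9]+$", warn = TRUE) {
  hit <- grepl(pattern, ids)
  if (warn && !all(hit))
    warning(sum(!hit), " id(s) without a variant suffix kept as-is")
  out <- ids
  out[hit] <- sub(pattern, "", ids[hit])
  out
}

#' Assign closest homologues from summed alignment scores
#'
#' Collapses both sides of the PSL records to genes, sums the per-record
#' scores (\code{\link{psl_score}}) and aligned lengths over every
#' (query gene, target gene) pair, and assigns each query gene the target
#' with the highest score sum among pairs whose total aligned length reaches
#' \code{min_total_len} (default 100 bp); otherwise the homologue is
#' \code{NA}.  Ties break to the lexicographically smallest target gene id.
#'
#' @param psl PSL data.frame.
#' @param min_total_len minimum summed aligned length in bp (default 100).
#' @param length_side side on which aligned length is summed:
#'   \code{"query"} (default, \code{qEnd - qStart}) or \code{"target"}.
#' @param collapse_variants collapse variant ids to genes on both sides
#'   (default TRUE).
#' @return data.frame with \code{query_gene}, \code{target_gene} (\code{NA}
#'   when no pair passes the floor), \code{score_sum},
#'   \code{aligned_length}.
#' @export
assign_homologues <- function(psl, min_total_len = 100L,
                              length_side = c("query", "target"),
                              collapse_variants = TRUE) {
  length_side <- match.arg(length_side)
  if (nrow(psl) == 0L)
    return(data.frame(query_gene = character(0), target_gene = character(0),
                      score_sum = numeric(0), aligned_length = integer(0),
                      stringsAsFactors = FALSE))
  qg <- if (collapse_variants) variant_gene(psl$qName, warn = FALSE)
        else psl$qName
  tg <- if (collapse_variants) variant_gene(psl$tName, warn = FALSE)
        else psl$tName
  score <- psl_score(psl)
  alen <- if (length_side == "query") psl$qEnd - psl$qStart
          else psl$tEnd - psl$tStart
  key <- paste(qg, tg, sep = "\r")
  ssum <- tapply(score, key, sum)
  lsum <- tapply(alen, key, sum)
  parts <- strsplit(names(ssum), "\r", fixed = TRUE)
  pair_q <- vapply(parts, `[[`, character(1), 1L)
  pair_t <- vapply(parts, `[[`, character(1), 2L)
  out <- lapply(split(seq_along(pair_q), pair_q), function(ix) {
    elig <- ix[lsum[ix] >= min_total_len]
    if (length(elig) == 0L)
      return(data.frame(query_gene = pair_q[ix[1L]],
                        target_gene = NA_character_,
                        score_sum = NA_real_, aligned_length = NA_integer_,
                        stringsAsFactors = FALSE))
    best <- max(ssum[elig])
    cand <- elig[ssum[elig] == best]
    pick <- cand[order(pair_t[cand])][1L]  # deterministic tie-break
    data.frame(query_gene = pair_q[pick], target_gene = pair_t[pick],
               score_sum = unname(ssum[pick]),
               aligned_length = as.integer(lsum[pick]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$query_gene), , drop = FALSE]
}
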