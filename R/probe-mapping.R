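#' Align short probes to a transcriptome allowing mismatches
#'
#' Exhaustive, full-length, ungapped search of every probe against both
#' strands of every transcript, reporting all loci within
#' \code{max_mismatches} Hamming distance.  Uses seed-and-filter: any hit
#' with at most k mismatches must contain one of k+1 disjoint probe
#' segments exactly, so exact segment hits (found with
#' \code{\link[Biostrings]{matchPDict}} over a concatenated subject) yield
#' candidate loci that are then verified by a vectorized Hamming check.
#' Ambiguity codes in the target never match; probes containing non-ACGT
#' characters are skipped with a warning and count as unaligned.
#'
#' Reported coordinates are 0-based offsets of the matched window on the
#' forward strand of the transcript; a \code{"-"} hit means the reverse
#' complement of the probe matches there.
#'
#' @param probes probe library data.frame with columns \code{probeset_id},
#'   \code{probe_id}, \code{sequence} (see \code{\link{read_probe_library}}).
#' @param transcriptome a named \code{DNAStringSet} (or named character
#'   vector) of transcript variants.
#' @param max_mismatches maximum Hamming distance (default 3).
#' @return data.frame with columns \code{probe_id}, \code{variant_id},
#'   \code{start} (0-based), \code{strand} (\code{"+"}/\code{"-"}),
#'   \code{mismatches}; zero rows if nothing aligns.
#' @examples
#' tx <- Biostrings::DNAStringSet(c(t1 = "ACGTACGTACGTACGTACGTACGTACGT"))
#' pr <- data.frame(probeset_id = "ps1", probe_id = "p1",
#'                  sequence = "ACGTACGTACGTACGTACGTACGTA")
#' align_probes(pr, tx, max_mismatches = 0)
#' @export
align_probes <- function(probes, transcriptome, max_mismatches = 3L) {
  if (!inherits(transcriptome, "DNAStringSet"))
    transcriptome <- Biostrings::DNAStringSet(transcriptome)
  if (is.null(names(transcriptome)))
    stop("transcriptome sequences must be named", call. = FALSE)
  k <- as.integer(max_mismatches)
  bad <- grepl("[^ACGT]", probes$sequence)
  if (any(bad)) {
    warning(sum(bad), " probe(s) with non-ACGT characters skipped ",
            "(treated as unaligned)")
    probes <- probes[!bad, , drop = FALSE]
  }
  if (nrow(probes) == 0L) return(empty_alignments())

  # concatenated subject: transcripts joined by runs of N longer than any
  # probe, so no verified window can span two transcripts
  seqs <- as.character(transcriptome)
  max_len <- max(nchar(probes$sequence))
  sep <- strrep("N", max_len + 1L)
  big_chr <- paste(seqs, collapse = sep)
  big <- Biostrings::DNAString(big_chr)
  big_int <- utf8ToInt(big_chr)  # N differs from A/C/G/T: never matches
  tx_start <- cumsum(c(1L, head(nchar(seqs) + nchar(sep), -1L)))  # 1-based
  tx_end <- tx_start + nchar(seqs) - 1L

  out <- list()
  for (len in sort(unique(nchar(probes$sequence)))) {
    grp <- probes[nchar(probes$sequence) == len, , drop = FALSE]
    for (strand in c("+", "-")) {
      pats <- if (strand == "+") grp$sequence
              else as.character(Biostrings::reverseComplement(
                Biostrings::DNAStringSet(grp$sequence)))
      hits <- seeded_hits(pats, big, big_int, len, k)
      if (is.null(hits)) next
      tx_idx <- findInterval(hits$start, tx_start)
      inside <- hits$start >= tx_start[tx_idx] &
        hits$start + len - 1L <= tx_end[tx_idx]
      hits <- hits[inside, , drop = FALSE]
      tx_idx <- tx_idx[inside]
      if (nrow(hits) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        probe_id = grp$probe_id[hits$pattern],
        variant_id = names(transcriptome)[tx_idx],
        start = hits$start - tx_start[tx_idx],  # 0-based in transcript
        strand = strand,
        mismatches = hits$mismatches,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty_alignments()
  res <- res[order(res$probe_id, res$variant_id, res$start, res$strand), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_alignments <- function() {
  data.frame(probe_id = character(0), variant_id = character(0),
             start = integer(0), strand = character(0),
             mismatches = integer(0), stringsAsFactors = FALSE)
}

# verified <=k-mismatch hits of patterns (equal length `len`) on `big`;
# returns data.frame(pattern = index into pats, start = 1-based in big,
# mismatches) or NULL
seeded_hits <- function(pats, big, big_int, len, k) {
  n_seg <- k + 1L
  widths <- rep(len %/% n_seg, n_seg)
  if (len %% n_seg) widths[seq_len(len %% n_seg)] <-
      widths[seq_len(len %% n_seg)] + 1L
  if (any(widths < 1L))
    stop("max_mismatches too large for probe length ", len, call. = FALSE)
  seg_off <- cumsum(c(0L, head(widths, -1L)))  # 0-based segment offsets
  cand <- vector("list", n_seg)
  for (j in seq_len(n_seg)) {
    segs <- substring(pats, seg_off[j] + 1L, seg_off[j] + widths[j])
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(segs))
    m <- Biostrings::matchPDict(pd, big)
    starts <- Biostrings::startIndex(m)
    hit_n <- lengths(starts)
    if (sum(hit_n) == 0L) next
    cand[[j]] <- data.frame(
      pattern = rep.int(seq_along(pats), hit_n),
      start = unlist(starts, use.names = FALSE) - seg_off[j],
      stringsAsFactors = FALSE)
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand) || nrow(cand) == 0L) return(NULL)
  keep <- cand$start >= 1L & cand$start + len - 1L <= length(big)
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  # verify candidates per pattern with a vectorized Hamming check
  by_pat <- split(cand$start, cand$pattern)
  offs <- 0:(len - 1L)
  res <- list()
  for (nm in names(by_pat)) {
    i <- as.integer(nm)
    st <- unique(by_pat[[nm]])
    p_int <- utf8ToInt(pats[i])
    win <- matrix(big_int[rep(st, each = len) + offs], nrow = len)
    mm <- colSums(win != p_int)
    ok <- mm <= k
    if (any(ok))
      res[[length(res) + 1L]] <- data.frame(pattern = i, start = st[ok],
                                            mismatches = as.integer(mm[ok]),
                                            stringsAsFactors = FALSE)
  }
  if (length(res)) do.call(rbind, res) else NULL
}

#' Derive the negative probeset list
#'
#' A probeset none of whose probes aligns anywhere to the target species'
#' transcriptome is a \emph{negative probeset}: on a heterologous
#' (cross-species) hybridization it measures pure background, which is what
#' presence/absence calling (\code{\link{panp_pvalues}}) requires.  Under
#' the default (strictest) rule a probeset is negative iff none of its
#' probes has any alignment; \code{min_unaligned_frac} relaxes this to "at
#' least that fraction of probes unaligned".
#'
#' @param probes probe library data.frame.
#' @param alignments data.frame from \code{\link{align_probes}} run on the
#'   full library.
#' @param min_unaligned_frac fraction of probes that must be unaligned
#'   (default 1 = all).
#' @return sorted character vector of negative probeset ids.
#' @export
classify_negative <- function(probes, alignments, min_unaligned_frac = 1) {
  n_probes <- table(probes$probeset_id)
  if (any(n_probes == 0L))
    stop("probeset with zero probes", call. = FALSE)
  aligned_probe <- unique(alignments$probe_id)
  unaligned <- !(probes$probe_id %in% aligned_probe)
  frac_unaligned <- tapply(unaligned, probes$probeset_id, mean)
  sort(names(frac_unaligned)[frac_unaligned >= min_unaligned_frac])
}
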