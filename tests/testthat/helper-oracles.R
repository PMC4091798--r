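# Independent brute-force oracles used to validate the package's
# implementations.  Each is written by definition, without sharing code
# with the functions under test.

revcomp_chr <- function(s) {
  vapply(s, function(x)
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE)[[1]]),
          collapse = ""), character(1), USE.NAMES = FALSE)
}

# naive both-strand sliding-window Hamming scan over every transcript
naive_probe_scan <- function(probes, seqs, k) {
  if (inherits(seqs, "DNAStringSet")) {
    nm <- names(seqs)
    seqs <- as.character(seqs)
    names(seqs) <- nm
  }
  out <- list()
  tx_int <- lapply(seqs, utf8ToInt)
  for (i in seq_len(nrow(probes))) {
    pseq <- probes$sequence[i]
    if (grepl("[^ACGT]", pseq)) next
    L <- nchar(pseq)
    for (strand in c("+", "-")) {
      p_int <- utf8ToInt(if (strand == "+") pseq else revcomp_chr(pseq))
      for (tx in names(seqs)) {
        t_int <- tx_int[[tx]]
        n_win <- length(t_int) - L + 1L
        if (n_win < 1L) next
        mm <- integer(n_win)
        for (j in seq_len(L))
          mm <- mm + (t_int[j:(n_win + j - 1L)] != p_int[j])
        hit <- which(mm <= k)
        if (length(hit))
          out[[length(out) + 1L]] <- data.frame(
            probe_id = probes$probe_id[i], variant_id = tx,
            start = hit - 1L, strand = strand,
            mismatches = mm[hit], stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(probe_id = character(0), variant_id = character(0),
               start = integer(0), strand = character(0),
               mismatches = integer(0), stringsAsFactors = FALSE)
  res[order(res$probe_id, res$variant_id, res$start, res$strand), ,
      drop = FALSE]
}

# canonical string form of an alignment table for set comparison
aln_key <- function(df) {
  sort(paste(df$probe_id, df$variant_id, df$start, df$strand,
             df$mismatches, sep = "|"))
}

# iterative two-way median polish, explicit loops
median_polish_oracle <- function(m, max_iter = 10L, tol = 0.01) {
  nr <- nrow(m); nc <- ncol(m)
  res <- m
  overall <- 0
  row_eff <- rep(0, nr)
  col_eff <- rep(0, nc)
  for (sweep in seq_len(max_iter)) {
    change <- 0
    for (r in seq_len(nr)) {
      d <- median(res[r, ])
      res[r, ] <- res[r, ] - d
      row_eff[r] <- row_eff[r] + d
      change <- change + abs(d)
    }
    d <- median(row_eff)
    row_eff <- row_eff - d
    overall <- overall + d
    change <- change + abs(d)
    for (cc in seq_len(nc)) {
      d <- median(res[, cc])
      res[, cc] <- res[, cc] - d
      col_eff[cc] <- col_eff[cc] + d
      change <- change + abs(d)
    }
    d <- median(col_eff)
    col_eff <- col_eff - d
    overall <- overall + d
    change <- change + abs(d)
    if (change < tol) break
  }
  list(overall = overall, row = row_eff, col = col_eff, residuals = res)
}

# empirical survivor function p-value, interpolation by hand
survivor_oracle <- function(x, bg) {
  u <- sort(unique(bg))
  pk <- sapply(u, function(v) mean(bg >= v))
  vapply(x, function(xx) {
    if (xx <= u[1]) return(1)
    if (xx > u[length(u)]) return(0)
    i <- max(which(u <= xx))
    if (u[i] == xx) return(pk[i])
    pk[i] + (pk[i + 1] - pk[i]) * (xx - u[i]) / (u[i + 1] - u[i])
  }, numeric(1))
}

# exact NB conditional test by full-support enumeration from the pmf formula
nb_enum_oracle <- function(y1, y2, phi) {
  s <- y1 + y2
  if (s == 0) return(1)
  a <- 0:s
  if (phi == 0) {
    lp <- lchoose(s, a) - s * log(2)
  } else {
    r <- 1 / phi
    m <- s / 2
    lnb <- function(z) lgamma(z + r) - lgamma(r) - lfactorial(z) +
      r * log(r / (r + m)) + z * log(m / (r + m))
    lp <- lnb(a) + lnb(s - a)
  }
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  min(1, sum(pr[pr <= pr[y1 + 1] * (1 + 1e-10)]))
}

# BH step-up by the closed form
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# hypergeometric upper tail by summation of the pmf formula
hyper_tail_oracle <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

# two-sided minimum-likelihood hypergeometric p by support enumeration
two_sided_enum_oracle <- function(k, K, n, N) {
  j <- max(0, n + K - N):min(K, n)
  pr <- exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n))
  obs <- pr[match(k, j)]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

# true-path propagation by repeated parent lookup until fixpoint
propagate_oracle <- function(dag, gene2term) {
  parents_of <- split(dag$parent, dag$child)
  close_up <- function(terms) {
    repeat {
      extra <- unique(unlist(parents_of[intersect(terms,
                                                  names(parents_of))]))
      new <- setdiff(extra, terms)
      if (length(new) == 0L) return(terms)
      terms <- c(terms, new)
    }
  }
  out <- lapply(split(gene2term$term, gene2term$gene_id), function(t)
    close_up(unique(t)))
  df <- do.call(rbind, lapply(names(out), function(g)
    data.frame(gene_id = g, term = out[[g]], stringsAsFactors = FALSE)))
  df[order(df$gene_id, df$term), ]
}

# brute-force complete-linkage agglomeration; returns the cophenetic matrix
complete_linkage_oracle <- function(m) {
  n <- nrow(m)
  d <- as.matrix(dist(m))
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < best_h) { best_h <- h; best <- c(i, j) }
    }
    ci <- clusters[[best[1]]]; cj <- clusters[[best[2]]]
    coph[ci, cj] <- best_h
    coph[cj, ci] <- best_h
    clusters[[best[1]]] <- c(ci, cj)
    clusters[[best[2]]] <- NULL
  }
  dimnames(coph) <- list(rownames(m), rownames(m))
  coph
}

# noise-cloud dominance recount by explicit double loop
dominance_oracle <- function(absM, D, noise_absM, noise_D) {
  vapply(seq_along(absM), function(g)
    mean(noise_absM <= absM[g] & noise_D <= D[g]), numeric(1))
}

# exhaustive argmax homologue assignment over all (query, target) pairs
assign_oracle <- function(psl, min_total_len = 100) {
  qg <- sub("_seq[0-9]+$", "", psl$qName)
  tg <- sub("_seq[0-9]+$", "", psl$tName)
  score <- psl$matches + psl$repMatches - psl$misMatches -
    psl$qNumInsert - psl$tNumInsert
  alen <- psl$qEnd - psl$qStart
  res <- list()
  for (q in sort(unique(qg))) {
    rows <- which(qg == q)
    targets <- unique(tg[rows])
    ss <- sapply(targets, function(t) sum(score[rows][tg[rows] == t]))
    ll <- sapply(targets, function(t) sum(alen[rows][tg[rows] == t]))
    ok <- which(ll >= min_total_len)
    if (length(ok) == 0L) {
      res[[q]] <- NA_character_
    } else {
      cand <- targets[ok][ss[ok] == max(ss[ok])]
      res[[q]] <- sort(cand)[1]
    }
  }
  unlist(res)
}
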