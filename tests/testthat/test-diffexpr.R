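null_counts <- function(seed, n = 200L, mu = 80, phi = 0.5,
                        samples = c("a", "b")) {
  set.seed(seed)
  m <- matrix(rnbinom(n * length(samples), mu = mu, size = 1 / phi),
              n, length(samples),
              dimnames = list(paste0("g", seq_len(n)), samples))
  m
}

test_that("noiseq probabilities are reproducible and equal a recount", {
  m <- null_counts(90)
  m[1:20, "a"] <- m[1:20, "a"] * 8L  # planted up-in-a genes
  r1 <- noiseq_sim(m, "a", "b", seed = 5L)
  r2 <- noiseq_sim(m, "a", "b", seed = 5L)
  expect_identical(r1$results$prob, r2$results$prob)

  recount <- dominance_oracle(abs(r1$results$M), r1$results$D,
                              r1$noise$absM, r1$noise$D)
  expect_equal(r1$results$prob, recount, tolerance = 1e-12)
})

test_that("noiseq dominance is monotone in |M| and D", {
  m <- null_counts(91)
  r <- noiseq_sim(m, "a", "b", seed = 6L)
  noise <- r$noise
  base_prob <- function(am, d)
    mean(noise$absM <= am & noise$D <= d)
  am <- quantile(noise$absM, c(0.2, 0.5, 0.8))
  d <- quantile(noise$D, c(0.2, 0.5, 0.8))
  for (i in 1:2) for (j in 1:3) {
    expect_lte(base_prob(am[i], d[j]), base_prob(am[i + 1], d[j]))
    expect_lte(base_prob(am[j %% 3 + 1], d[i]),
               base_prob(am[j %% 3 + 1], d[i + 1]))
  }
})

test_that("a gene with identical normalized values has probability zero", {
  m <- null_counts(92)
  m["g1", ] <- c(50L, 50L)  # equal counts, equal libraries up to factors
  # force exactly equal normalized expression by equalizing library sums
  diffsum <- sum(m[, "a"]) - sum(m[, "b"])
  if (diffsum > 0) m["g2", "b"] <- m["g2", "b"] + diffsum
  else m["g2", "a"] <- m["g2", "a"] - diffsum
  r <- noiseq_sim(m, "a", "b", seed = 7L)
  g1 <- r$results[r$results$gene == "g1", ]
  expect_equal(g1$M, 0)
  expect_equal(g1$D, 0)
  expect_lt(g1$prob, 0.05)  # only noise points exactly at the origin count
})

test_that("enrichment in the focal cell type needs all three contrasts", {
  res <- function(prob, M)
    data.frame(gene = "g1", M = M, D = 1, prob = prob)
  three_up <- list(b = res(0.95, 2), c = res(0.95, 1), d = res(0.95, 3))
  expect_identical(noiseq_enriched(three_up, q = 0.9), "g1")
  two_up <- list(b = res(0.95, 2), c = res(0.95, -1), d = res(0.95, 3))
  expect_identical(noiseq_enriched(two_up, q = 0.9), character(0))
  low_prob <- list(b = res(0.91, 2), c = res(0.89, 1), d = res(0.95, 3))
  expect_identical(noiseq_enriched(low_prob, q = 0.9), character(0))
  expect_error(noiseq_enriched(three_up[1:2], n_required = 3),
               "missing contrast")
})

test_that("planted fold changes are recovered by the noiseq path", {
  cfg <- sim_config(seed = 95L, n_genes = 600L, variants_per_gene = 1L,
                    de_fraction = 0.1, fold_change = 4)
  tx <- gen_transcriptome(cfg)
  counts <- gen_counts(tx$truth, cfg)
  tmm <- tmm_factors(counts)
  others <- cfg$samples[-1L]
  contrasts <- lapply(setNames(others, others), function(s)
    noiseq_sim(counts, cfg$samples[1L], s, norm_factors = tmm,
               seed = 95L)$results)
  got <- noiseq_enriched(contrasts, q = 0.9)
  planted <- tx$truth$gene_id[tx$truth$de]
  # simulated-replicate noise is conservative, so recall is partial but
  # the enriched set must be dominated by planted genes
  precision <- length(intersect(got, planted)) / max(1, length(got))
  recall <- length(intersect(got, planted)) / length(planted)
  cat(sprintf("\nnoiseq planted-DE recovery: recall %.2f precision %.2f\n",
              recall, precision))
  expect_gt(precision, 0.5)
  expect_gt(recall, 0.3)
  # and equals its own set-algebra recomputation
  manual <- Reduce(intersect, lapply(contrasts, function(r)
    r$gene[r$prob > 0.9 & r$M > 0]))
  expect_setequal(got, manual)
})

test_that("exact NB test matches full-support enumeration", {
  expect_equal(exact_nb_test(10, 10, 1e5, 1e5), 1)
  expect_equal(nb_enum_oracle(11, 11, 0.64), 1)

  cases <- rbind(c(20, 2), c(0, 15), c(7, 3), c(100, 60), c(250, 200),
                 c(1, 0), c(3, 3))
  for (i in seq_len(nrow(cases))) {
    y1 <- cases[i, 1]; y2 <- cases[i, 2]
    for (phi in c(0, 0.2, 0.64)) {
      got <- exact_nb_test(y1, y2, 1e6, 1e6, dispersion = phi)
      want <- nb_enum_oracle(y1, y2, phi)
      expect_equal(got, want, tolerance = 1e-12,
                   label = sprintf("p(%d,%d|phi=%g)", y1, y2, phi))
    }
  }
  # symmetry in the two samples at equal library size
  expect_equal(exact_nb_test(20, 2, 1e6, 1e6),
               exact_nb_test(2, 20, 1e6, 1e6))
})

test_that("the phi=0 limit is the conditional binomial test", {
  for (pair in list(c(12, 4), c(30, 30), c(9, 0))) {
    got <- exact_nb_test(pair[1], pair[2], 1e6, 1e6, dispersion = 0)
    s <- sum(pair)
    d <- dbinom(0:s, s, 0.5)
    want <- sum(d[d <= d[pair[1] + 1] * (1 + 1e-10)])
    expect_equal(got, min(1, want), tolerance = 1e-12)
  }
})

test_that("unequal library sizes are equalized by pseudo-counts", {
  # x2 observed in a library 4x deeper: y2 = x2 / 2 at the geometric mean
  expect_equal(exact_nb_test(10, 40, 1e6, 4e6),
               nb_enum_oracle(round(10 * 2), round(40 / 2), 0.64))
  expect_error(exact_nb_test(-1, 5, 1e6, 1e6), "counts")
  expect_error(exact_nb_test(1, 5, 1e6, 1e6, dispersion = -0.1),
               "dispersion")
})

test_that("BH adjustment equals the closed-form step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(100)
  p <- runif(100)
  got <- bh_adjust(p)
  expect_equal(got, bh_oracle(p), tolerance = 1e-14)
  # monotone in the order statistics of the input
  expect_true(all(diff(got[order(p)]) >= 0))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("exact-test enrichment applies FDR and raw-p rules per pair", {
  mk <- function(genes, lfc, p) {
    data.frame(gene = genes, logFC = lfc, p = p, fdr = bh_adjust(p))
  }
  genes <- paste0("g", 1:4)
  f1 <- mk(genes, c(2, 2, -1, 2), c(0.0001, 0.0002, 0.0001, 0.5))
  f2 <- mk(genes, c(1, 2, 1, 2), c(0.0001, 0.0003, 0.0001, 0.6))
  f3 <- mk(genes, c(3, -2, 1, 2), c(0.0002, 0.0001, 0.0001, 0.7))
  sp <- mk(genes, c(1, 1, 1, 1), c(0.0005, 0.002, 0.9, 0.9))
  out <- exact_test_enriched(list(c1 = f1, c2 = f2, c3 = f3),
                             list(sp = sp), special_pair = "sp")
  # g1: up with small fdr everywhere; g2 fails direction in c3;
  # g3 fails direction in c1; g4 fails fdr
  expect_identical(out$enriched, "g1")
  # special pair uses raw p < 0.001: only g1 qualifies there
  expect_true("g1" %in% out$de_union)
  expect_false("g2" %in% setdiff(out$de_union,
                                 unlist(lapply(list(f1, f2, f3),
                                               function(d)
                                                 d$gene[d$fdr < 0.05]))))
  expect_error(exact_test_enriched(list(c1 = f1[, 1:2])), "columns")
})
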