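# small hand-built DAG:        root
#                             /    \
#                            A      B
#                           / \    /
#                          A1  A2 B1
toy_dag <- data.frame(
  child = c("A", "B", "A1", "A2", "B1"),
  parent = c("root", "root", "A", "A", "B"),
  stringsAsFactors = FALSE)

test_that("true-path propagation reaches the root and is idempotent", {
  g2t <- data.frame(gene_id = c("g1", "g2"),
                    term = c("A1", "B1"), stringsAsFactors = FALSE)
  full <- propagate_annotations(toy_dag, g2t)
  g1_terms <- full$term[full$gene_id == "g1"]
  expect_setequal(g1_terms, c("A1", "A", "root"))
  again <- propagate_annotations(toy_dag, full)
  expect_setequal(paste(again$gene_id, again$term),
                  paste(full$gene_id, full$term))
  expect_error(propagate_annotations(toy_dag,
                                     data.frame(gene_id = "g",
                                                term = "nope")),
               "unknown term")
})

test_that("propagation equals the repeated-parent-lookup oracle", {
  for (seed in c(120L, 121L)) {
    ann <- gen_annotations(paste0("g", 1:40), n_terms = 30L,
                           dag_depth = 4L, seed = seed)
    got <- propagate_annotations(ann$dag, ann$gene2term)
    got <- got[order(got$gene_id, got$term), ]
    want <- propagate_oracle(ann$dag, ann$gene2term)
    expect_identical(paste(got$gene_id, got$term),
                     paste(want$gene_id, want$term))
  }
})

test_that("cyclic or multi-root ontologies are rejected", {
  cyc <- rbind(toy_dag,
               data.frame(child = "root", parent = "A1"))
  expect_error(ontology_graph(cyc), "cycle")
  two_roots <- data.frame(child = c("A", "B"),
                          parent = c("r1", "r2"))
  expect_error(ontology_graph(two_roots), "root")
})

test_that("one-sided Fisher equals the hypergeometric tail", {
  universe <- paste0("g", 1:1000)
  term <- list(T1 = universe[1:10])
  study <- universe[1:100]  # all 10 annotated genes inside
  res <- fisher_classic(study, term, universe)
  expect_equal(res$p_value, hyper_tail_oracle(10, 10, 100, 1000),
               tolerance = 1e-12)
  expect_equal(res$expected, 1.0)
  expect_identical(res$annotated, 10L)
  expect_identical(res$significant, 10L)

  # study = universe: p = 1 for every term
  res2 <- fisher_classic(universe, term, universe)
  expect_equal(res2$p_value, 1)

  set.seed(130)
  for (rep in 1:5) {
    K <- sample(5:50, 1); n <- sample(20:200, 1)
    study_r <- sample(universe, n)
    term_r <- list(T = sample(universe, K))
    k <- length(intersect(term_r$T, study_r))
    got <- fisher_classic(study_r, term_r, universe)$p_value
    expect_equal(got, hyper_tail_oracle(k, K, n, 1000), tolerance = 1e-12)
  }
  expect_error(fisher_classic("g1", term, character(0)), "universe")
})

test_that("classic Fisher p-values are conservative under the null", {
  set.seed(131)
  universe <- paste0("g", 1:400)
  term <- list(T = sample(universe, 40))
  p <- replicate(2000, {
    fisher_classic(sample(universe, 60), term, universe)$p_value
  })
  # super-uniform: empirical CDF never exceeds uniform by a clear margin
  for (alpha in c(0.01, 0.05, 0.2, 0.5))
    expect_lte(mean(p <= alpha), alpha + 3 * sqrt(alpha / 2000))
})

test_that("elim removes significant children's genes from ancestors", {
  # genes annotated directly: leaf A1 carries the entire signal
  universe <- paste0("g", 1:100)
  direct <- data.frame(
    gene_id = c(paste0("g", 1:10), paste0("g", 11:20)),
    term = c(rep("A1", 10), rep("B1", 10)),
    stringsAsFactors = FALSE)
  full <- propagate_annotations(toy_dag, direct)
  study <- paste0("g", 1:10)  # exactly the A1 genes
  classic <- fisher_classic(study, full, universe)
  elim <- go_elim(toy_dag, study, full, universe, elim_cutoff = 0.01)
  pc <- function(df, t) df$p_value[df$id == t]
  expect_lt(pc(classic, "A1"), 0.01)
  expect_equal(pc(elim, "A1"), pc(classic, "A1"))
  # A's overlap was exhausted by A1 -> p rises to 1
  expect_lt(pc(classic, "A"), 0.01)
  expect_equal(pc(elim, "A"), 1)
  # annotated counts never shrink
  expect_identical(elim$annotated[order(elim$id)],
                   classic$annotated[order(classic$id)])
})

test_that("elim with cutoff zero reproduces the classic test", {
  for (seed in c(140L, 141L)) {
    ann <- gen_annotations(paste0("g", 1:60), n_terms = 25L,
                           dag_depth = 3L, seed = seed)
    full <- propagate_annotations(ann$dag, ann$gene2term)
    universe <- unique(full$gene_id)
    set.seed(seed)
    study <- sample(universe, 15)
    classic <- fisher_classic(study, full, universe)
    elim0 <- go_elim(ann$dag, study, full, universe, elim_cutoff = 0)
    m <- match(classic$id, elim0$id)
    expect_equal(classic$p_value, elim0$p_value[m], tolerance = 1e-12)
  }
})

test_that("a three-level elimination cascade matches a manual oracle", {
  universe <- paste0("g", 1:60)
  direct <- data.frame(
    gene_id = c(paste0("g", 1:6), paste0("g", 7:9)),
    term = c(rep("A1", 6), rep("A2", 3)),
    stringsAsFactors = FALSE)
  full <- propagate_annotations(toy_dag, direct)
  study <- paste0("g", 1:8)  # all of A1, two of A2
  elim <- go_elim(toy_dag, study, full, universe, elim_cutoff = 0.01)
  # manual: A1 tested first (leaf), p = hyper tail of (6,6,8,60) -> signif;
  # A2: overlap 2 of 3 -> p = tail(2,3,8,60);
  # A: annotated 9, but A1's 6 study genes removed if A1 significant
  p_A1 <- hyper_tail_oracle(6, 6, 8, 60)
  expect_equal(elim$p_value[elim$id == "A1"], p_A1, tolerance = 1e-12)
  p_A2 <- hyper_tail_oracle(2, 3, 8, 60)
  expect_equal(elim$p_value[elim$id == "A2"], p_A2, tolerance = 1e-12)
  a1_sig <- p_A1 <= 0.01
  a2_sig <- p_A2 <= 0.01
  removed <- c(if (a1_sig) paste0("g", 1:6), if (a2_sig) paste0("g", 7:8))
  k_A <- length(setdiff(intersect(paste0("g", 1:9), study), removed))
  expect_equal(elim$p_value[elim$id == "A"],
               hyper_tail_oracle(k_A, 9, 8, 60), tolerance = 1e-12)
})

test_that("two-sided Fisher equals support enumeration", {
  universe <- paste0("g", 1:29000)
  fam <- list(F1 = universe[1:50])
  study <- c(universe[1:8], universe[10000:10892])  # n = 901, overlap 8
  res <- fisher_two_sided(study, fam, universe)
  expect_equal(res$p_value, two_sided_enum_oracle(8, 50, 901, 29000),
               tolerance = 1e-12)
  expect_equal(res$expected, 50 * 901 / 29000)

  # overlap at the mode of a symmetric table -> p = 1
  u2 <- paste0("g", 1:100)
  fam2 <- list(F = u2[1:50])
  study2 <- c(u2[1:25], u2[51:75])  # k = 25 = mode
  expect_equal(fisher_two_sided(study2, fam2, u2)$p_value, 1)

  # depletion: k = 0 with a large expected count gives a small p
  fam3 <- list(F = universe[1:500])
  study3 <- universe[20000:20900]
  p_dep <- fisher_two_sided(study3, fam3, universe)$p_value
  expect_lt(p_dep, 0.01)
  expect_equal(p_dep, two_sided_enum_oracle(0, 500, 901, 29000),
               tolerance = 1e-12)

  expect_error(fisher_two_sided(study2, list(F = c(u2[1], "zzz")), u2),
               "not contained")
})

test_that("two-sided Fisher agrees with fisher.test on random tables", {
  set.seed(150)
  for (rep in 1:10) {
    N <- sample(50:300, 1)
    K <- sample(5:(N / 2), 1)
    n <- sample(5:(N / 2), 1)
    u <- paste0("g", 1:N)
    fam <- list(F = u[1:K])
    study <- sample(u, n)
    k <- length(intersect(fam$F, study))
    got <- fisher_two_sided(study, fam, u)$p_value
    tab <- matrix(c(k, K - k, n - k, N - K - n + k), 2)
    want <- stats::fisher.test(tab)$p.value
    expect_equal(got, want, tolerance = 1e-9)
  }
})
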