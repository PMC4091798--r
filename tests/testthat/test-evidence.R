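test_that("rule strings parse into working predicates", {
  r <- evidence_rule("array_P >= 2 OR reads >= 5")
  ev <- data.frame(array_P = c(2, 1, 0, 0), reads = c(0, 0, 5, 4))
  expect_identical(r(ev), c(TRUE, FALSE, TRUE, FALSE))

  strict <- evidence_rule("aic_exclusive")  # reads >= 5 AND array_P >= 1
  expect_identical(strict(ev), c(FALSE, FALSE, FALSE, FALSE))
  ev2 <- data.frame(array_P = 1, reads = 5)
  expect_true(strict(ev2))

  expect_error(evidence_rule("array_P >= 1 AND reads >= 5 OR reads >= 9"),
               "not both")
  expect_error(evidence_rule("foo >= 1"), "cannot parse")
})

make_design <- function(calls, counts) {
  data.frame(
    sample = c(colnames(calls), colnames(counts)),
    cell_type = c(rep("aic", ncol(calls)), rep("aic", 1),
                  rep("egg", ncol(counts) - 1)),
    platform = c(rep("array", ncol(calls)), rep("rnaseq", ncol(counts))),
    stringsAsFactors = FALSE)
}

test_that("evidence records combine array calls and read counts", {
  calls <- matrix(c("P", "P", "A",
                    "P", "A", "A"), 3, 2,
                  dimnames = list(c("g1", "g2", "g3"),
                                  c("arr1", "arr2")))
  counts <- matrix(c(10L, 0L, 3L,
                     0L, 7L, 0L), 3, 2,
                   dimnames = list(c("g1", "g2", "g3"), c("rna1", "rna2")))
  design <- make_design(calls, counts)
  ev <- build_evidence(calls = calls, counts = counts, design = design)
  aic <- ev[ev$cell_type == "aic", ]
  expect_identical(aic$array_P[aic$gene == "g1"], 2L)
  expect_identical(aic$array_P[aic$gene == "g2"], 1L)
  expect_identical(aic$reads[aic$gene == "g1"], 10)
  egg <- ev[ev$cell_type == "egg", ]
  expect_identical(egg$reads[egg$gene == "g2"], 7)
  # independent recomputation per gene
  for (g in rownames(calls)) {
    expect_identical(aic$array_P[aic$gene == g],
                     sum(calls[g, ] == "P"))
    expect_identical(aic$reads[aic$gene == g], unname(counts[g, "rna1"]) + 0)
  }
  expect_error(build_evidence(calls, counts,
                              rbind(design, design[1, ])),
               "assigned more than once")
  bad <- design
  bad$sample[1] <- "ghost"
  expect_error(build_evidence(calls, counts, bad), "not found")
})

test_that("homologue anchoring translates RNA-seq gene ids", {
  counts <- matrix(c(9L, 6L), 2, 1,
                   dimnames = list(c("compA_c0", "compB_c0"), "rna1"))
  design <- data.frame(sample = "rna1", cell_type = "egg",
                       platform = "rnaseq", stringsAsFactors = FALSE)
  hom <- data.frame(query_gene = c("compA_c0", "compB_c0"),
                    target_gene = c("AT1", NA), stringsAsFactors = FALSE)
  ev <- build_evidence(counts = counts, design = design, homology = hom)
  expect_setequal(ev$gene, c("AT1", "compB_c0"))  # no homologue: local id
  # many-to-one homology takes the union (max) of read support
  hom2 <- data.frame(query_gene = c("compA_c0", "compB_c0"),
                     target_gene = c("AT1", "AT1"), stringsAsFactors = FALSE)
  ev2 <- build_evidence(counts = counts, design = design, homology = hom2)
  expect_identical(ev2$reads[ev2$gene == "AT1"], 9)
})

test_that("Venn regions partition the union", {
  two <- overlap_counts(list(A = c("x", "y"), B = c("y", "z")))
  expect_identical(unname(two[c("A", "B", "A&B")]), c(1L, 1L, 1L))

  same <- overlap_counts(list(A = letters[1:4], B = letters[1:4]))
  expect_identical(unname(same["A&B"]), 4L)
  expect_identical(unname(same["A"] + same["B"]), 0L)

  disj <- overlap_counts(list(A = c("a"), B = c("b")))
  expect_identical(unname(disj["A&B"]), 0L)

  set.seed(110)
  for (rep in 1:3) {
    sets <- lapply(1:3, function(i) sample(letters, sample(5:20, 1)))
    names(sets) <- c("A", "B", "C")
    v <- overlap_counts(sets)
    expect_length(v, 7L)
    expect_identical(sum(v), length(Reduce(union, sets)))
    # brute-force membership enumeration
    u <- Reduce(union, sets)
    brute <- table(vapply(u, function(g)
      paste(names(sets)[vapply(sets, function(s) g %in% s, logical(1))],
            collapse = "&"), character(1)))
    for (nm in names(brute))
      expect_identical(unname(v[nm]), as.integer(brute[[nm]]))
  }
})

test_that("exclusive and shared sets partition the expressed union", {
  ev_a <- data.frame(gene = paste0("g", 1:6),
                     array_P = c(2, 1, 0, 0, 2, 0),
                     reads = c(0, 0, 9, 0, 9, 0))
  ev_b <- data.frame(gene = paste0("g", 1:6),
                     array_P = 0,
                     reads = c(9, 0, 9, 9, 0, 0))
  out <- exclusive_sets(ev_a, ev_b, rule_a = "aic", rule_b = "rnaseq")
  # A-rule: P>=2 or reads>=5 -> g1, g3, g5; B-rule: reads>=5 -> g1, g3, g4
  expect_setequal(out$a_only, "g5")
  expect_setequal(out$b_only, "g4")
  expect_setequal(out$shared, c("g1", "g3"))
  union_all <- c(out$a_only, out$b_only, out$shared)
  expect_identical(anyDuplicated(union_all), 0L)
  expect_setequal(union_all, c("g1", "g3", "g4", "g5"))
})

test_that("the strict conjunction rule shapes the exclusive comparison", {
  # >= 5 reads AND P on at least one array
  ev <- data.frame(gene = c("g1", "g2", "g3"),
                   array_P = c(1L, 0L, 1L),
                   reads = c(9, 9, 2))
  r <- evidence_rule("aic_exclusive")
  expect_identical(ev$gene[r(ev)], "g1")
})

test_that("adding evidence never removes a gene from an expressed set", {
  set.seed(111)
  ev <- data.frame(gene = paste0("g", 1:50),
                   array_P = sample(0:2, 50, TRUE),
                   reads = sample(0:10, 50, TRUE))
  for (rule in c("aic", "gamete", "aic_exclusive", "rnaseq")) {
    r <- evidence_rule(rule)
    before <- ev$gene[r(ev)]
    more <- ev
    more$array_P <- pmin(more$array_P + 1L, 2L)
    more$reads <- more$reads + 5
    expect_true(all(before %in% more$gene[r(more)]), label = rule)
  }
})

test_that("multi-sample expression needs support from k samples", {
  ev <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                   cell_type = "aic",
                   array_P = c(2L, 1L, 1L, 0L),
                   n_arrays = 2L,
                   reads = c(0, 0, 8, 9))
  got <- multi_sample_expressed(ev, min_samples = 2L)
  expect_setequal(got, c("g1", "g3"))  # two arrays, or array + rnaseq
  # brute-force tally
  tally <- ev$array_P + (ev$reads >= 5)
  expect_setequal(got, ev$gene[tally >= 2])
  expect_error(multi_sample_expressed(
    data.frame(gene = "g", array_P = 0L, n_arrays = 0L, reads = 0),
    rnaseq_counts = NULL), "fewer than 2")
})
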