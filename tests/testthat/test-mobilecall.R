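# FPKM quantification and the mobile-call set logic.

toy_genes <- function() {
  gene_models(data.frame(
    gene_id = c("g1", "g2", "g3"), contig = "c1", strand = "+",
    start = c(1L, 2001L, 6001L), end = c(1000L, 4000L, 6500L)))
}

test_that("FPKM follows its definition exactly", {
  genes <- toy_genes()
  out <- compute_fpkm(c(g1 = 10), genes, 1e6)
  expect_equal(out$fpkm, 10)                       # 10 / 1kb / 1M
  expect_equal(compute_fpkm(c(g2 = 1), genes, 4e6)$fpkm, 0.125)
  expect_equal(compute_fpkm(c(g1 = 0), genes, 1e6)$fpkm, 0)
  expect_error(compute_fpkm(c(nope = 3), genes, 1e6), "nope")
})

test_that("FPKM normalization identity holds on random tables", {
  set.seed(41)
  genes <- toy_genes()
  for (i in 1:20) {
    counts <- setNames(rpois(3, 50), c("g1", "g2", "g3"))
    total <- sample(1e4:1e6, 1L)
    fp <- compute_fpkm(counts, genes, total)
    lens <- exonic_lengths(genes)[fp$gene_id]
    back <- sum(fp$fpkm * (lens / 1000) * (total / 1e6))
    expect_equal(back, sum(counts), tolerance = 1e-6)
  }
})

test_that("expressed gene set uses a strict threshold and replicate modes", {
  expr <- data.frame(gene_id = c("g1", "g2", "g3", "g1", "g2", "g3"),
                     replicate = rep(1:2, each = 3),
                     fpkm = c(0.06, 0.05, 0, 0.01, 0.2, 0))
  expect_equal(expressed_gene_set(expr), c("g1", "g2"))
  # all-replicates: g1 fails in rep2, g2 passes only rep2
  expect_equal(expressed_gene_set(expr, mode = "all-replicates"),
               character(0))
  expect_warning(out <- expressed_gene_set(expr[0, ]), "empty")
  expect_equal(out, character(0))
})

test_that("mobile replicate calls apply the A minus B minus C rule with FPKM gate", {
  genes <- toy_genes()
  # FPKM with total 1e6: count/len_kb
  out <- call_mobile_replicate(c(g1 = 8, g2 = 5), B_genes = "g2",
                               C_genes = character(0), genes, 1e6)
  expect_equal(out$gene_id, "g1")
  out2 <- call_mobile_replicate(c(g3 = 100), B_genes = character(0),
                                C_genes = "g3", genes, 1e6)
  expect_equal(nrow(out2), 0L)
  # missing control is a hard error
  expect_error(call_mobile_replicate(c(g1 = 3), NULL, character(0),
                                     genes, 1e6), "mandatory")
  # FPKM threshold is strict: 0.05 exactly is excluded
  # g1 len 1kb: count 0.05 * total/1e6 gives fpkm 0.05
  out3 <- call_mobile_replicate(c(g1 = 1), character(0), character(0),
                                genes, 2e7)
  expect_equal(nrow(out3), 0L)
})

test_that("mobile replicate calls equal a brute-force rule oracle", {
  set.seed(42)
  lens <- c(300L, 800L, 1500L, 2500L, 5000L)
  rows <- lapply(seq_along(lens), function(i)
    data.frame(gene_id = sprintf("g%02d", i), contig = "c1", strand = "+",
               start = 10000L * i, end = 10000L * i + lens[i] - 1L))
  genes <- gene_models(do.call(rbind, rows))
  ids <- sprintf("g%02d", seq_along(lens))
  for (rep in 1:200) {
    A <- setNames(rpois(5, 2), ids)
    B <- ids[stats::runif(5) < 0.3]
    C <- ids[stats::runif(5) < 0.3]
    total <- sample(c(1e4, 1e5, 1e6), 1L)
    got <- call_mobile_replicate(A, B, C, genes, total)$gene_id
    # oracle: evaluate the rule gene by gene, straight from the text
    want <- character(0)
    for (g in ids) {
      fpkm <- A[[g]] / (lens[match(g, ids)] / 1000) / (total / 1e6)
      if (A[[g]] > 0 && !(g %in% B) && !(g %in% C) && fpkm > 0.05)
        want <- c(want, g)
    }
    expect_identical(got, sort(want))
  }
})

test_that("replicate intersection is strict and guarded", {
  expect_equal(intersect_replicates(list(c("a", "b"), c("b", "c"))), "b")
  expect_equal(intersect_replicates(list(c("a", "b"), c("a", "b"))),
               c("a", "b"))
  expect_equal(intersect_replicates(list("a", "b")), character(0))
  expect_error(intersect_replicates(list(c("a", "b"))), "replicates")
  expect_warning(out <- intersect_replicates(list(c("a", "b")),
                                             allow_single = TRUE),
                 "NOT applied")
  expect_equal(out, c("a", "b"))
})

test_that("call-set monotonicity: stricter filters never enlarge the set", {
  set.seed(43)
  genes <- toy_genes()
  A <- c(g1 = 6, g2 = 9, g3 = 4)
  base <- call_mobile_replicate(A, character(0), character(0), genes, 1e5)
  withB <- call_mobile_replicate(A, "g2", character(0), genes, 1e5)
  withC <- call_mobile_replicate(A, character(0), c("g1", "g3"), genes, 1e5)
  strict <- call_mobile_replicate(A, character(0), character(0), genes,
                                  1e5, min_fpkm = 50)
  expect_true(all(withB$gene_id %in% base$gene_id))
  expect_true(all(withC$gene_id %in% base$gene_id))
  expect_true(all(strict$gene_id %in% base$gene_id))
})

test_that("condition summaries partition into shared and exclusive sets", {
  calls <- data.frame(
    gene_id = c("a", "b", "c", "b", "c", "d", "e"),
    direction = "upward",
    condition = c(rep("24C", 3L), rep("6C", 4L)))
  s <- summarize_calls(calls)
  expect_equal(s$venn$shared, 2L)
  expect_equal(s$venn$exclusive_a, 1L)
  expect_equal(s$venn$exclusive_b, 2L)
  expect_equal(s$venn$exclusive_a + s$venn$shared, s$venn$total_a)
  expect_equal(s$venn$exclusive_b + s$venn$shared, s$venn$total_b)
  # identical sets share everything; disjoint sets share nothing
  same <- summarize_calls(data.frame(gene_id = rep(c("x", "y"), 2L),
                                     direction = "downward",
                                     condition = rep(c("24C", "6C"),
                                                     each = 2L)))
  expect_equal(same$venn$shared, 2L)
  expect_equal(same$venn$exclusive_a + same$venn$exclusive_b, 0L)
})

test_that("low-expression fraction recounts the donor table", {
  expr <- data.frame(gene_id = c("a", "b", "c", "d"),
                     fpkm = c(0.2, 5, 0.9, 1.0))
  expect_equal(low_expression_fraction(c("a", "b", "c", "d"), expr), 0.5)
  expect_equal(low_expression_fraction(c("a", "c"), expr), 1)
  # absent genes count as FPKM 0; empty mobile set is a no-value marker
  expect_equal(low_expression_fraction(c("a", "zz"), expr), 1)
  expect_true(is.na(low_expression_fraction(character(0), expr)))
  # replicate rows are averaged; agrees with a direct recount
  set.seed(44)
  genes <- sprintf("g%02d", 1:30)
  tab <- data.frame(gene_id = rep(genes, 2L),
                    fpkm = stats::rlnorm(60, meanlog = -0.5))
  got <- low_expression_fraction(genes, tab)
  m <- tapply(tab$fpkm, tab$gene_id, mean)
  expect_equal(got, mean(m[genes] < 1))
})
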