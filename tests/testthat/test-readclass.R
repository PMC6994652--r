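# Read partitioning and fragment-to-gene assignment.

mk_hit <- function(read_id, contig, pos, end, score, evalue = NA_real_) {
  data.frame(
    read_id = read_id, mate = NA_integer_, mapped = TRUE, contig = contig,
    pos = pos, end = end, strand = "+", cigar = NA_character_,
    aligned_length = end - pos + 1L, mismatches = 0L, score = score,
    seq = NA_character_, qual = NA_character_, evalue = evalue,
    source = "tabular-hit", target = NA_character_,
    stringsAsFactors = FALSE)
}

mk_resident <- function(ids, mapped) {
  data.frame(read_id = ids, mapped = mapped,
             contig = ifelse(mapped, "c1", NA_character_),
             pos = ifelse(mapped, 100L, NA_integer_),
             end = ifelse(mapped, 199L, NA_integer_),
             strand = ifelse(mapped, "+", NA_character_),
             cigar = ifelse(mapped, "100M", NA_character_),
             aligned_length = ifelse(mapped, 100L, NA_integer_),
             mismatches = 0L, score = ifelse(mapped, 100, NA_real_),
             seq = NA_character_, qual = NA_character_,
             evalue = NA_real_, source = "builtin",
             stringsAsFactors = FALSE)
}

test_that("fragments are partitioned by best-score adjudication", {
  res <- mk_resident(c("f1/1", "f1/2", "f2/1", "f3/1", "f4/1", "f5/1"),
                     c(TRUE, FALSE, rep(FALSE, 4L)))
  own <- rbind(mk_hit("f2/1", "c1", 1, 80, 60),
               mk_hit("f3/1", "c1", 1, 80, 70),
               mk_hit("f4/1", "c1", 1, 80, 55))
  fgn <- rbind(mk_hit("f2/1", "p1", 1, 80, 80),
               mk_hit("f3/1", "p1", 1, 80, 70),
               mk_hit("f4/1", "p1", 1, 80, 54.5))
  p <- partition_reads("lib1", res, own, fgn, min_hit_length = 50)
  # mapped mate makes the whole fragment resident
  expect_equal(p$resident_frags, "f1")
  # foreign 80 vs own 60 wins; equal scores are ambiguous; own 55 vs 54.5 wins
  expect_equal(p$foreign$frag_id, "f2")
  expect_equal(p$ambiguous_frags, "f3")
  expect_equal(p$own$frag_id, "f4")
  # f5 hit nothing
  expect_equal(p$no_hit_frags, "f5")
})

test_that("every fragment lands in exactly one class", {
  set.seed(31)
  n <- 120L
  ids <- sprintf("f%03d", seq_len(n))
  mapped <- stats::runif(n) < 0.5
  res <- mk_resident(paste0(ids, "/1"), mapped)
  unm <- ids[!mapped]
  pick <- function(v, p) v[stats::runif(length(v)) < p]
  own_ids <- pick(unm, 0.5)
  fgn_ids <- pick(unm, 0.5)
  own <- if (length(own_ids)) do.call(rbind, lapply(own_ids, function(i)
    mk_hit(paste0(i, "/1"), "c1", 1, 80, sample(50:90, 1L)))) else NULL
  fgn <- if (length(fgn_ids)) do.call(rbind, lapply(fgn_ids, function(i)
    mk_hit(paste0(i, "/1"), "p1", 1, 80, sample(50:90, 1L)))) else NULL
  p <- partition_reads("lib", res, own, fgn)
  classes <- c(p$resident_frags, p$own$frag_id, p$foreign$frag_id,
               p$ambiguous_frags, p$no_hit_frags)
  expect_equal(sort(classes), sort(ids))
  expect_equal(anyDuplicated(classes), 0L)
  s <- partition_summary(p)
  expect_equal(s$resident + s$own + s$foreign + s$ambiguous + s$no_hit, n)
})

test_that("a fragment in both resident-mapped and hit lists is a contract error", {
  res <- mk_resident("f1/1", TRUE)
  expect_error(
    partition_reads("lib", res, NULL, mk_hit("f1/2", "p1", 1, 80, 60)),
    "two-pass")
})

test_that("hit quality gate drops weak and short hits", {
  res <- mk_resident(c("f1/1", "f2/1", "f3/1"), c(FALSE, FALSE, FALSE))
  fgn <- rbind(mk_hit("f1/1", "p1", 1, 80, 60, evalue = 1e-10),
               mk_hit("f2/1", "p1", 1, 80, 60, evalue = 1e-3),
               mk_hit("f3/1", "p1", 1, 40, 60, evalue = 1e-10))
  p <- partition_reads("lib", res, NULL, fgn)
  expect_equal(p$foreign$frag_id, "f1")       # e-value and length gates
  expect_equal(sort(p$no_hit_frags), c("f2", "f3"))
})

test_that("margin widens the ambiguous zone", {
  res <- mk_resident(c("f1/1", "f2/1"), FALSE)
  own <- rbind(mk_hit("f1/1", "c1", 1, 80, 60), mk_hit("f2/1", "c1", 1, 80, 60))
  fgn <- rbind(mk_hit("f1/1", "p1", 1, 80, 63), mk_hit("f2/1", "p1", 1, 80, 70))
  p <- partition_reads("lib", res, own, fgn, min_margin = 5)
  expect_equal(p$foreign$frag_id, "f2")       # wins by > 5
  expect_equal(p$ambiguous_frags, "f1")       # wins by only 3
})

test_that("fragments increment the gene with maximal exon overlap", {
  genes <- gene_models(data.frame(
    gene_id = c("gX", "gX", "gY"), contig = "c1", strand = "+",
    start = c(100L, 300L, 380L), end = c(200L, 360L, 500L)))
  hits <- data.frame(frag_id = c("a", "b", "c"), contig = "c1",
                     pos = c(120L, 340L, 600L), end = c(180L, 430L, 680L),
                     score = 1, stringsAsFactors = FALSE)
  out <- assign_fragments_to_genes(hits, genes)
  expect_equal(out$counts[["gX"]], 1L)   # inside one exon
  # b overlaps gX by 21 bases (340..360) and gY by 51 (380..430)
  expect_equal(out$counts[["gY"]], 1L)
  expect_equal(out$unassigned, 1L)       # intergenic hit
  expect_equal(sum(out$counts) + out$unassigned, nrow(hits))
})

test_that("overlap ties go to the lexicographically smallest gene id", {
  genes <- gene_models(data.frame(
    gene_id = c("gB", "gA"), contig = "c1", strand = "+",
    start = c(100L, 200L), end = c(150L, 250L)))
  hits <- data.frame(frag_id = "t", contig = "c1", pos = 130L, end = 220L,
                     score = 1, stringsAsFactors = FALSE)
  expect_message(out <- assign_fragments_to_genes(hits, genes), "tie")
  expect_equal(out$counts[["gA"]], 1L)
  expect_equal(out$counts[["gB"]], 0L)
})

test_that("count conservation holds on random assignments", {
  set.seed(32)
  genes <- gene_models(data.frame(
    gene_id = rep(sprintf("g%02d", 1:20), each = 2),
    contig = "c1", strand = "+",
    start = seq(1, by = 500, length.out = 40),
    end = seq(1, by = 500, length.out = 40) + sample(100:300, 40, TRUE)))
  n <- 500L
  hits <- data.frame(frag_id = sprintf("f%03d", 1:n), contig = "c1",
                     pos = sample.int(20000L, n), score = 1,
                     stringsAsFactors = FALSE)
  hits$end <- hits$pos + 99L
  out <- assign_fragments_to_genes(hits, genes)
  expect_equal(sum(out$counts) + out$unassigned, n)
})

test_that("gene models survive a GFF3 write/read round trip", {
  genes <- gene_models(data.frame(
    gene_id = c("g1", "g1", "g2"), contig = c("c1", "c1", "c2"),
    strand = c("+", "+", "-"), start = c(10L, 200L, 50L),
    end = c(100L, 320L, 400L)))
  path <- tempfile(fileext = ".gff3")
  write_gene_models(genes, path)
  back <- read_gene_models(path)
  expect_equal(back[order(back$gene_id, back$start), ]$start,
               genes$start)
  expect_equal(exonic_lengths(back), exonic_lengths(genes))
})
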