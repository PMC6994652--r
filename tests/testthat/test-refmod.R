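# Reference modification: pileup calling, variant filtering, genome
# rewriting, scaffold assembly.

test_that("pileup emits candidates only where reads disagree with the reference", {
  ref <- genome_sequence(c(chrA = strrep("ACGTACGTAC", 10)))
  mk_aln <- function(seqs, pos) {
    data.frame(read_id = sprintf("r%d", seq_along(seqs)), mapped = TRUE,
               contig = "chrA", pos = pos,
               cigar = paste0(nchar(seqs), "M"), seq = seqs,
               qual = strrep("I", nchar(seqs)), stringsAsFactors = FALSE)
  }
  # 10 reads all matching the reference: nothing called
  aln <- mk_aln(rep(substr(strrep("ACGTACGTAC", 10), 11, 40), 10), 11)
  expect_equal(nrow(call_pileup_variants(aln, ref)), 0L)

  # unanimous T over reference C (position 12, offset 2 of the read)
  rseq <- substr(strrep("ACGTACGTAC", 10), 11, 40)
  substr(rseq, 2, 2) <- "T"
  v <- call_pileup_variants(mk_aln(rep(rseq, 10), 11), ref)
  expect_equal(nrow(v), 1L)
  expect_equal(v$pos, 12L)
  expect_equal(v$ref, "C")
  expect_equal(v$alt, "T")
  expect_equal(v$depth, 10L)
  expect_equal(v$alt_support, 10L)
  expect_equal(v$zygosity, 1)

  # mixed column 5 ref / 5 alt: zygosity 0.5 (for filter_variants to drop)
  aln <- rbind(mk_aln(rep(substr(strrep("ACGTACGTAC", 10), 11, 40), 5), 11),
               mk_aln(rep(rseq, 5), 11))
  v <- call_pileup_variants(aln, ref)
  expect_equal(v$zygosity, 0.5)
  expect_equal(v$depth, 10L)
})

test_that("pileup rejects alignments off the reference", {
  ref <- genome_sequence(c(chrA = strrep("ACGT", 25)))
  aln <- data.frame(read_id = "r1", mapped = TRUE, contig = "chrZ",
                    pos = 1L, cigar = "4M", seq = "ACGT", qual = "IIII",
                    stringsAsFactors = FALSE)
  expect_error(call_pileup_variants(aln, ref), "chrZ")
  aln$contig <- "chrA"; aln$pos <- 500L
  expect_error(call_pileup_variants(aln, ref), "bounds")
})

test_that("variant filter enforces depth, zygosity and strict quality", {
  v <- variant_table(contig = rep("c", 4), pos = 1:4,
                     ref = rep("A", 4), alt = rep("T", 4),
                     depth = c(5L, 6L, 10L, 10L),
                     alt_support = c(5L, 6L, 10L, 10L),
                     quality = c(40, 21, 20, 40))
  out <- filter_variants(v)
  # depth 5 fails >=6; quality exactly 20 fails the strict > 20
  expect_equal(out$pos, c(2L, 4L))
  # zygosity boundary: 0.9 passes, 0.89 fails
  v2 <- variant_table(contig = c("c", "c"), pos = c(1L, 2L),
                      ref = c("A", "A"), alt = c("T", "T"),
                      depth = c(100L, 100L), alt_support = c(90L, 89L),
                      quality = 40)
  expect_equal(filter_variants(v2)$pos, 1L)
  # empty in, empty out
  expect_equal(nrow(filter_variants(variant_table())), 0L)
})

test_that("apply_variants performs exact edits with a consistent map", {
  g <- genome_sequence(c(c1 = "ACGT"))
  out <- apply_variants(g, variant_table("c1", 2, "C", "T"))
  expect_equal(as.character(out$genome), c(c1 = "ATGT"))
  expect_equal(genome_role(out$genome), "modified")
  # input untouched, empty list is a byte-identical no-op
  expect_equal(as.character(g), c(c1 = "ACGT"))
  noop <- apply_variants(g, variant_table())
  expect_identical(as.character(noop$genome), as.character(g))
  expect_equal(lift_position(noop$map, "c1", 1:4), 1:4)
})

test_that("length arithmetic matches an independent right-to-left edit oracle", {
  set.seed(77)
  s <- random_seq(1000)
  g <- genome_sequence(c(c1 = s))
  # 3 insertions totalling +7, 2 deletions totalling -4, well separated
  v <- variant_table(
    contig = rep("c1", 5), pos = c(100L, 300L, 500L, 700L, 900L),
    ref = c(substr(s, 100, 100), substr(s, 300, 300), substr(s, 500, 502),
            substr(s, 700, 700), substr(s, 900, 902)),
    alt = c(paste0(substr(s, 100, 100), "AA"),
            paste0(substr(s, 300, 300), "CCC"),
            substr(s, 500, 500),
            paste0(substr(s, 700, 700), "GG"),
            substr(s, 900, 900)))
  out <- apply_variants(g, v)
  expect_equal(Biostrings::width(out$genome)[[1L]], 1003L)

  # oracle: plain string splicing applied right to left
  oracle <- s
  for (i in rev(seq_len(nrow(v)))) {
    p <- v$pos[i]
    oracle <- paste0(substr(oracle, 1, p - 1), v$alt[i],
                     substr(oracle, p + nchar(v$ref[i]), nchar(oracle)))
  }
  expect_identical(as.character(out$genome)[[1L]], oracle)
})

test_that("ref-allele mismatches are hard errors and overlaps are skipped", {
  g <- genome_sequence(c(c1 = "AAACCCGGGTTT"))
  expect_error(apply_variants(g, variant_table("c1", 2, "G", "T")),
               "c1:2")
  # overlapping deletion + SNP inside it: first by coordinate wins
  v <- variant_table(contig = c("c1", "c1"), pos = c(4L, 5L),
                     ref = c("CCC", "C"), alt = c("C", "A"))
  expect_warning(out <- apply_variants(g, v), "overlap")
  expect_equal(nrow(out$applied), 1L)
  expect_equal(out$applied$pos, 4L)
  expect_equal(nrow(out$rejected), 1L)
  expect_equal(out$rejected$pos, 5L)
})

test_that("coordinate map is monotone and round-trips outside deleted intervals", {
  fx <- small_reseq_fixture()
  av <- apply_variants(fx$pair$scion$genome, fx$geno$variants)
  map <- av$map
  for (ct in names(fx$pair$scion$genome)) {
    anc <- map$anchors[map$anchors$contig == ct, ]
    expect_true(all(diff(anc$original_pos) > 0))
    expect_true(all(diff(anc$modified_pos) > 0))
    set.seed(404)
    pos <- sample.int(Biostrings::width(fx$pair$scion$genome)[[
      match(ct, names(fx$pair$scion$genome))]], 1000L)
    fwd <- lift_position(map, ct, pos)
    live <- !is.na(fwd)
    back <- lift_position(map, ct, fwd[live], direction = "backward")
    expect_equal(back, pos[live])
    # deleted original positions have no forward image
    del <- map$deleted[map$deleted$contig == ct, ]
    if (nrow(del) > 0L)
      expect_true(all(is.na(lift_position(map, ct, del$start))))
  }
})

test_that("modified contig lengths differ by the summed allele-length deltas", {
  fx <- small_reseq_fixture()
  av <- apply_variants(fx$pair$scion$genome, fx$geno$variants)
  for (ct in names(fx$pair$scion$genome)) {
    vv <- av$applied[av$applied$contig == ct, ]
    delta <- sum(nchar(vv$alt) - nchar(vv$ref))
    expect_equal(
      Biostrings::width(av$genome)[[match(ct, names(av$genome))]],
      Biostrings::width(fx$pair$scion$genome)[[
        match(ct, names(fx$pair$scion$genome))]] + delta)
  }
})

test_that("variant normalization left-aligns indels into repeat runs", {
  g <- genome_sequence(c(c1 = "GATTTTACGT"))
  # deletion of one T written at the right edge of the run
  v <- variant_table("c1", 5, "TT", "T")
  n <- normalize_variants(v, g)
  expect_equal(n$pos, 2L)
  expect_equal(n$ref, "AT")
  expect_equal(n$alt, "A")
  # SNPs unchanged
  v2 <- variant_table("c1", 3, "T", "C")
  expect_identical(normalize_variants(v2, g)[, 1:4], v2[, 1:4])
})

test_that("de Bruijn assembly reconstructs an unrepeated source sequence", {
  set.seed(88)
  src <- random_seq(500)
  starts <- seq(1, 401, by = 20)  # 100bp reads, 80bp overlap
  reads <- substring(src, starts, starts + 99)
  # mix strands: assembly must be strand-agnostic
  flip <- seq_along(reads) %% 2 == 0
  reads[flip] <- revcomp_chr(reads[flip])
  sc <- assemble_unmapped(reads, k = 31, min_scaffold_len = 200)
  expect_equal(length(sc$scaffolds), 1L)
  got <- as.character(sc$scaffolds)[[1L]]
  expect_true(got == src || got == revcomp_chr(src))
})

test_that("assembly terminates unitigs at repeated k-mers", {
  set.seed(89)
  a <- random_seq(150); rep_unit <- random_seq(31); b <- random_seq(150)
  # the repeated 31-mer creates a branch; no chimeric join across it
  src <- paste0(a, rep_unit, b, rep_unit, random_seq(150))
  starts <- seq(1, nchar(src) - 99, by = 10)
  reads <- substring(src, starts, starts + 99)
  sc <- assemble_unmapped(reads, k = 31, min_scaffold_len = 50)
  expect_true(length(sc$scaffolds) > 1L)
  expect_false(any(as.character(sc$scaffolds) == src))
})

test_that("assembly edge cases: no reads, k longer than every read", {
  expect_equal(length(assemble_unmapped(character(0))$scaffolds), 0L)
  expect_warning(sc <- assemble_unmapped(c("ACGTACGT"), k = 31),
                 "exceeds")
  expect_equal(length(sc$scaffolds), 0L)
})

test_that("build_modified_reference concatenates retained scaffolds only", {
  g <- genome_sequence(c(c1 = strrep("ACGT", 100),
                         c2 = strrep("GGCA", 100)))
  sc <- structure(list(
    scaffolds = genome_sequence(
      c(scaffold_0001 = random_seq(300), scaffold_0002 = random_seq(300),
        scaffold_0003 = random_seq(300)),
      name = "gx", role = "scaffold-extra"),
    provenance = "gx", excluded_ids = character(0)),
    class = "scaffold_set")
  out <- build_modified_reference(g, variant_table(), sc,
                                  exclusion_ids = "scaffold_0002")
  expect_equal(length(out$genome), 4L)
  expect_equal(out$scaffold_ids, c("scaffold_0001", "scaffold_0003"))
  # excluding everything leaves the modified contigs only
  out2 <- build_modified_reference(g, variant_table(), sc,
                                   exclusion_ids = names(sc$scaffolds))
  expect_equal(names(out2$genome), c("c1", "c2"))
  # id collision is a hard error
  clash <- sc; names(clash$scaffolds)[1L] <- "c1"
  expect_error(build_modified_reference(g, variant_table(), clash), "collide")
})

test_that("contaminant exclusion hook reads a tabular hit table", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("scaffold_0001\tnt_hit\t99.2\t280\t2\t0\t1\t280\t5\t284\t1e-80\t500",
               "scaffold_0002\tnt_hit\t88.0\t60\t7\t1\t1\t60\t9\t68\t0.02\t48"),
             tsv)
  hits <- read_alignments(tsv, "tabular")
  expect_equal(exclusion_ids_from_hits(hits), "scaffold_0001")
})

test_that("variants imported from VCF carry QUAL and apply cleanly", {
  skip_if_not_installed("VariantAnnotation")
  g <- genome_sequence(c(c1 = strrep("ACGTAGGCTA", 10)))
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=c1,length=100>",
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="depth">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "c1\t2\t.\tC\tT\t55\tPASS\tDP=20",
    "c1\t11\t.\tAC\tA\t33\tPASS\tDP=14",
    "c1\t26\t.\tG\tGTT\t18\tPASS\tDP=9"), vcf)
  v <- read_variants_vcf(vcf)
  expect_equal(v$kind, c("SNP", "DEL", "INS"))
  expect_equal(v$quality, c(55, 33, 18))
  expect_equal(v$depth, c(20L, 14L, 9L))
  # the VCF QUAL feeds the strict > 20 filter directly
  expect_equal(filter_variants(v)$pos, c(2L, 11L))
  out <- apply_variants(g, v)
  expect_equal(Biostrings::width(out$genome)[[1L]], 101L)
  expect_equal(substr(as.character(out$genome)[[1L]], 1, 12), "ATGTAGGCTAAG")
})
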