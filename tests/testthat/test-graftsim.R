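# Synthetic grafting experiment generator.

test_that("genome pair simulation is deterministic and divergence-controlled", {
  cfg <- sim_config(seed = 601, contig_length = 20000,
                    genes_per_species = 15)
  a <- simulate_genome_pair(cfg)
  b <- simulate_genome_pair(cfg)
  expect_identical(as.character(a$scion$genome),
                   as.character(b$scion$genome))
  expect_identical(as.character(a$rootstock$genome),
                   as.character(b$rootstock$genome))
  expect_identical(a$divergence, b$divergence)
  # zero divergence gives an identical (renamed) genome
  cfg0 <- sim_config(seed = 602, contig_length = 10000,
                     genes_per_species = 5,
                     interspecies_snp_rate = 0, interspecies_indel_rate = 0)
  p0 <- simulate_genome_pair(cfg0)
  expect_identical(unname(as.character(p0$scion$genome)),
                   unname(as.character(p0$rootstock$genome)))
})

test_that("planted interspecies SNP counts follow the binomial model", {
  # rate 0.01 over 100 kb: count within 3 sigma of Binomial(1e5, 0.01)
  cfg <- sim_config(seed = 603, contigs_per_species = 1,
                    contig_length = 100000, genes_per_species = 10,
                    interspecies_snp_rate = 0.01,
                    interspecies_indel_rate = 0.002)
  p <- simulate_genome_pair(cfg)
  n_snp <- sum(p$divergence$kind == "SNP")
  expect_lt(abs(n_snp - 1000), 3 * sqrt(1e5 * 0.01 * 0.99) + 1)
})

test_that("experimental genotype truth round-trips through apply_variants", {
  fx <- small_reseq_fixture()
  av <- apply_variants(fx$pair$scion$genome, fx$geno$variants)
  rebuilt <- as.character(av$genome)
  exp_core <- as.character(fx$geno$genome)[names(fx$pair$scion$genome)]
  expect_identical(rebuilt, exp_core)
  # truth bookkeeping: requested counts are delivered (minus rare
  # footprint collisions)
  expect_equal(sum(fx$geno$variants$kind == "SNP"), fx$cfg$genotype_snps,
               tolerance = 0.02)
  # zero-divergence genotype: identical genome, empty truth
  cfg0 <- sim_config(seed = 604, contig_length = 10000,
                     genes_per_species = 5, genotype_snps = 0,
                     genotype_insertions = 0, genotype_deletions = 0,
                     genotype_segments = 0)
  p0 <- simulate_genome_pair(cfg0)
  g0 <- derive_experimental_genotype(p0$scion$genome, cfg0, "g0")
  expect_identical(as.character(g0$genome),
                   as.character(p0$scion$genome))
  expect_equal(nrow(g0$variants), 0L)
})

test_that("expression tables honour the unexpressed fraction and the seed", {
  genes <- gene_models(data.frame(
    gene_id = sprintf("g%04d", 1:1000), contig = "c1", strand = "+",
    start = seq(1, by = 10, length.out = 1000),
    end = seq(5, by = 10, length.out = 1000)))
  cfg <- sim_config(seed = 605, unexpressed_fraction = 0.3)
  e1 <- simulate_expression(genes, cfg, "leaf", seed = 606)
  e2 <- simulate_expression(genes, cfg, "leaf", seed = 606)
  expect_identical(e1, e2)
  n0 <- sum(e1$level == 0)
  expect_lt(abs(n0 - 300), 3 * sqrt(1000 * 0.3 * 0.7))
  # sigma 0: every expressed gene shares one value
  cfg2 <- sim_config(seed = 607, expression_sdlog = 0)
  e3 <- simulate_expression(genes, cfg2, "leaf", seed = 608)
  expect_equal(length(unique(e3$level[e3$level > 0])), 1L)
})

test_that("read simulation respects transmission and provenance bookkeeping", {
  exp <- small_graft_fixture()
  # every emitted fragment has exactly one provenance label
  for (lib in names(exp$libraries)) {
    frags <- unique(fragment_id(exp$libraries[[lib]]$read_id))
    prov <- exp$truth_reads[exp$truth_reads$library_id == lib, ]
    expect_setequal(frags, prov$frag_id)
    expect_equal(anyDuplicated(prov$frag_id), 0L)
  }
  # homograft controls carry no foreign-provenance reads
  ctl <- exp$truth_reads[grepl("_(sh|rh)_", exp$truth_reads$library_id), ]
  expect_true(all(ctl$origin == "resident"))
  # heterograft recipients do carry foreign reads
  het <- exp$truth_reads[grepl("_(hs|hr)_", exp$truth_reads$library_id), ]
  expect_true(any(het$origin == "foreign"))
  # foreign reads come only from planted mobile genes of the direction
  up <- het[grepl("_hs_", het$library_id) & het$origin == "foreign", ]
  expect_true(all(up$gene_id %in%
    exp$mobile_truth$gene_id[exp$mobile_truth$direction == "upward"]))
})

test_that("zero transmission yields zero foreign reads", {
  cfg <- sim_config(seed = 609, contig_length = 20000,
                    genes_per_species = 20, mobile_per_direction = 4,
                    fragments_per_library = 1500, transmission_scale = 0,
                    genotype_segments = 0)
  exp <- simulate_graft_experiment(cfg)
  expect_true(all(exp$truth_reads$origin == "resident"))
})

test_that("foreign read counts track the target abundances", {
  exp <- small_graft_fixture()
  cfg <- exp$config
  prov <- exp$truth_reads
  mt <- exp$mobile_truth[exp$mobile_truth$direction == "upward", ]
  fgn <- prov[grepl("_hs_r1$", prov$library_id) & prov$origin == "foreign", ]
  lens <- exonic_lengths(exp$genes$rootstock)
  for (i in seq_len(nrow(mt))) {
    lambda <- mt$target_fpkm[i] * (lens[[mt$gene_id[i]]] / 1000) *
      cfg$fragments_per_library / 1e6
    got <- sum(fgn$gene_id == mt$gene_id[i])
    expect_lt(abs(got - lambda), 4 * sqrt(lambda) + 2)
  }
})

test_that("whole experiments are byte-deterministic per seed", {
  cfg <- sim_config(seed = 610, contig_length = 15000,
                    genes_per_species = 12, mobile_per_direction = 3,
                    fragments_per_library = 800)
  a <- simulate_graft_experiment(cfg)
  b <- simulate_graft_experiment(cfg)
  expect_identical(a$libraries, b$libraries)
  expect_identical(a$reseq, b$reseq)
  expect_identical(a$mobile_truth, b$mobile_truth)
  expect_identical(as.character(a$genotypes$scion$genome),
                   as.character(b$genotypes$scion$genome))
})

test_that("call evaluation does confusion-matrix arithmetic with NA markers", {
  u <- sprintf("g%02d", 1:20)
  same <- evaluate_calls(u[1:5], u[1:5], u)
  expect_equal(same$precision, 1)
  expect_equal(same$recall, 1)
  e <- evaluate_calls(character(0), u[1:5], u)
  expect_equal(e$recall, 0)
  expect_true(is.na(e$precision))
  m <- evaluate_calls(u[1:4], u[c(1:3, 5)], u)
  expect_equal(m$tp, 3L)
  expect_equal(m$fp, 1L)
  expect_equal(m$fn, 1L)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_error(evaluate_calls("not_in_universe", u[1], u))
})
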