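# Shared fixtures. Heavy simulations are memoized so several test files
# can reuse one object without re-simulating.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# small genome pair + experimental genotype + resequencing reads
small_reseq_fixture <- function() {
  fixture("small_reseq", function() {
    cfg <- sim_config(seed = 401, contig_length = 30000,
                      genes_per_species = 25, genotype_snps = 60,
                      genotype_insertions = 8, genotype_deletions = 8,
                      genotype_segments = 1,
                      genotype_segment_length = 1200,
                      fragments_per_library = 2000)
    pair <- simulate_genome_pair(cfg)
    geno <- derive_experimental_genotype(pair$scion$genome, cfg, "gx",
                                         seed = 402)
    reads <- simulate_resequencing_reads(geno$genome, cfg, seed = 403)
    list(cfg = cfg, pair = pair, geno = geno, reads = reads)
  })
}

# small full graft experiment with clearly detectable mobile abundance
small_graft_fixture <- function() {
  fixture("small_graft", function() {
    cfg <- sim_config(seed = 501, contig_length = 40000,
                      genes_per_species = 50, genotype_snps = 80,
                      genotype_insertions = 8, genotype_deletions = 8,
                      genotype_segments = 1,
                      genotype_segment_length = 1200,
                      mobile_per_direction = 6,
                      foreign_fpkm_range = c(600, 4000),
                      fragments_per_library = 6000)
    simulate_graft_experiment(cfg)
  })
}

variant_key <- function(v) paste(v$contig, v$pos, v$ref, v$alt)

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}
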