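#' Simulation configuration for a synthetic grafting experiment
#'
#' Collects every parameter of the synthetic heterografting experiment:
#' two diverged species genomes, a genotype layer separating the
#' experimental plants from their published references, gene models,
#' tissue expression, planted mobile transcripts and sequencing. All
#' randomness is driven by the mandatory `seed`.
#'
#' @param seed integer seed (mandatory; there is no implicit randomness).
#' @param contigs_per_species,contig_length genome shape per species.
#' @param genes_per_species number of genes per species.
#' @param exons_per_gene,exon_length,intron_length,intergenic_gap integer
#'   ranges (`c(min, max)`) for gene structure.
#' @param interspecies_snp_rate,interspecies_indel_rate per-base divergence
#'   rates used to derive species 2 from species 1, so homologous regions
#'   exist and cross-mapping is a real failure mode.
#' @param max_indel_length largest planted indel (bases).
#' @param genotype_snps,genotype_insertions,genotype_deletions counts of
#'   variants separating each experimental genotype from its reference.
#' @param genotype_segments,genotype_segment_length genotype-specific
#'   sequence absent from the reference (count and length in bases).
#' @param expression_meanlog,expression_sdlog log-normal expression model.
#' @param unexpressed_fraction fraction of genes with zero expression in a
#'   tissue (these feed the unexpressed-gene false-positive sets).
#' @param mobile_per_direction planted mobile genes per direction.
#' @param foreign_fpkm_range target foreign-FPKM window for planted mobile
#'   transcripts in the recipient tissue (log-uniform draw).
#' @param transmission_scale global multiplier on mobile transmission
#'   (0 gives a zero-mobility null experiment).
#' @param read_length,fragment_length,fragments_per_library,error_rate
#'   RNA-seq read simulation parameters.
#' @param replicates biological replicates per library role.
#' @param conditions character vector of growth conditions.
#' @param reseq_coverage,reseq_error_rate genomic resequencing depth and
#'   per-base error rate.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed,
                       contigs_per_species = 2,
                       contig_length = 200000,
                       genes_per_species = 200,
                       exons_per_gene = c(1, 4),
                       exon_length = c(200, 600),
                       intron_length = c(60, 200),
                       intergenic_gap = c(200, 800),
                       interspecies_snp_rate = 0.10,
                       interspecies_indel_rate = 0.005,
                       max_indel_length = 10,
                       genotype_snps = 500,
                       genotype_insertions = 50,
                       genotype_deletions = 50,
                       genotype_segments = 2,
                       genotype_segment_length = 3000,
                       expression_meanlog = 1,
                       expression_sdlog = 1.5,
                       unexpressed_fraction = 0.2,
                       mobile_per_direction = 20,
                       foreign_fpkm_range = c(0.2, 5),
                       transmission_scale = 1,
                       read_length = 100,
                       fragment_length = 250,
                       fragments_per_library = 50000,
                       error_rate = 0.01,
                       replicates = 2,
                       conditions = "24C",
                       reseq_coverage = 30,
                       reseq_error_rate = 0) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("a seed is mandatory")
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  rates <- c(cfg$interspecies_snp_rate, cfg$interspecies_indel_rate,
             cfg$unexpressed_fraction, cfg$error_rate, cfg$reseq_error_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  pos <- c(cfg$contigs_per_species, cfg$contig_length,
           cfg$genes_per_species, cfg$read_length, cfg$fragment_length,
           cfg$fragments_per_library, cfg$replicates, cfg$reseq_coverage)
  if (any(pos <= 0)) stop("counts and sizes must be positive")
  if (cfg$transmission_scale < 0) stop("transmission_scale must be >= 0")
  structure(cfg, class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

runif_int <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

other_base <- function(base) {
  vapply(base, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
         character(1L), USE.NAMES = FALSE)
}

# Random variant set over a genome: n_snp SNPs, n_ins insertions, n_del
# deletions in anchored VCF style. Positions are drawn uniformly (distinct
# within each kind, away from contig ends); the rare footprint collisions
# between events are resolved by dropping the later event, so planted
# counts stay within sampling noise of the requested counts.
random_variants <- function(genome, n_snp, n_ins, n_del, max_indel,
                            edge = 150L) {
  lens <- Biostrings::width(genome)
  names(lens) <- names(genome)
  seqs <- as.character(genome)
  ntot <- n_snp + n_ins + n_del
  if (ntot == 0L) return(variant_table())
  draw_kind <- function(n, kind) {
    if (n == 0L) return(NULL)
    ct <- sample(names(lens), n, replace = TRUE, prob = lens)
    rows <- lapply(names(lens), function(c1) {
      k <- sum(ct == c1)
      if (k == 0L) return(NULL)
      span <- lens[[c1]] - 2L * edge - max_indel
      data.frame(contig = c1,
                 pos = sample.int(span, min(k, span)) + edge,
                 kind = kind, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  v <- rbind(draw_kind(n_snp, "SNP"), draw_kind(n_ins, "INS"),
             draw_kind(n_del, "DEL"))
  v$len <- ifelse(v$kind == "SNP", 0L, sample.int(max_indel, nrow(v),
                                                  replace = TRUE))
  v$footprint_end <- v$pos + ifelse(v$kind == "DEL", v$len, 0L)
  v <- v[order(v$contig, v$pos, v$kind, method = "radix"), , drop = FALSE]
  keep <- logical(nrow(v))
  prev_contig <- ""; prev_end <- 0L
  for (i in seq_len(nrow(v))) {
    if (v$contig[i] != prev_contig || v$pos[i] > prev_end + 1L) {
      keep[i] <- TRUE
      prev_contig <- v$contig[i]; prev_end <- v$footprint_end[i]
    }
  }
  v <- v[keep, , drop = FALSE]
  ref <- alt <- character(nrow(v))
  for (i in seq_len(nrow(v))) {
    s <- seqs[[v$contig[i]]]
    p <- v$pos[i]
    anchor <- substr(s, p, p)
    if (v$kind[i] == "SNP") {
      ref[i] <- anchor
      alt[i] <- other_base(anchor)
    } else if (v$kind[i] == "INS") {
      ref[i] <- anchor
      alt[i] <- paste0(anchor, random_dna(v$len[i]))
    } else {
      ref[i] <- substr(s, p, p + v$len[i])
      alt[i] <- anchor
    }
  }
  out <- variant_table(contig = v$contig, pos = v$pos, ref = ref,
                       alt = alt)
  rownames(out) <- NULL
  out
}

place_genes <- function(genome, n_genes, cfg, prefix) {
  lens <- Biostrings::width(genome)
  rows <- list(); gi <- 0L
  per_contig <- ceiling(n_genes / length(genome))
  for (ci in seq_along(genome)) {
    ct <- names(genome)[ci]
    pos <- sample(seq(cfg$intergenic_gap[1], cfg$intergenic_gap[2]), 1L)
    placed <- 0L
    while (placed < per_contig && gi < n_genes) {
      nex <- runif_int(1L, cfg$exons_per_gene)
      exl <- runif_int(nex, cfg$exon_length)
      inl <- if (nex > 1L) runif_int(nex - 1L, cfg$intron_length)
             else integer(0)
      span <- sum(exl) + sum(inl)
      if (pos + span > lens[ci] - 500L) break
      gi <- gi + 1L; placed <- placed + 1L
      gene <- sprintf("%s_g%04d", prefix, gi)
      strand <- sample(c("+", "-"), 1L)
      st <- pos
      for (e in seq_len(nex)) {
        rows[[length(rows) + 1L]] <-
          data.frame(gene_id = gene, contig = ct, strand = strand,
                     start = st, end = st + exl[e] - 1L,
                     stringsAsFactors = FALSE)
        st <- st + exl[e] + if (e < nex) inl[e] else 0L
      }
      pos <- pos + span + runif_int(1L, cfg$intergenic_gap)
    }
  }
  gene_models(do.call(rbind, rows))
}

#' Simulate a diverged pair of species reference genomes
#'
#' Species 1 is random sequence with planted gene models; species 2 is
#' derived from species 1 by an interspecies divergence process (SNPs and
#' short indels), so homologous regions exist between the two genomes and
#' cross-genome mis-mapping is a realistic failure mode. Gene models are
#' lifted onto species 2 through the divergence coordinate map.
#' Deterministic for a given seed.
#'
#' @param config a [sim_config()].
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return list with `scion` and `rootstock`, each holding `genome`
#'   (role `"reference"`) and `genes`, plus the `divergence` variant table.
#' @export
simulate_genome_pair <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  contigs <- stats::setNames(
    vapply(seq_len(cfg$contigs_per_species),
           function(i) random_dna(cfg$contig_length), character(1L)),
    sprintf("scion_chr%d", seq_len(cfg$contigs_per_species)))
  g1 <- genome_sequence(contigs, name = "scionRef", role = "reference")
  genes1 <- place_genes(g1, cfg$genes_per_species, cfg, "SC")

  n_snp <- stats::rbinom(1L, cfg$contig_length * cfg$contigs_per_species,
                         cfg$interspecies_snp_rate)
  n_ind <- stats::rbinom(1L, cfg$contig_length * cfg$contigs_per_species,
                         cfg$interspecies_indel_rate)
  div <- random_variants(g1, n_snp, ceiling(n_ind / 2), floor(n_ind / 2),
                         cfg$max_indel_length)
  av <- apply_variants(g1, div)
  g2 <- av$genome
  genes2 <- if (nrow(div) > 0L)
    suppressWarnings(lift_gene_models(genes1, av$map)) else genes1
  names(g2) <- sub("^scion_", "rootstock_", names(g2))
  genes2$contig <- sub("^scion_", "rootstock_", genes2$contig)
  genes2$gene_id <- sub("^SC_", "RS_", genes2$gene_id)
  genes2 <- gene_models(genes2)
  g2 <- genome_sequence(as.character(g2), name = "rootstockRef",
                        role = "reference")
  list(scion = list(genome = g1, genes = genes1),
       rootstock = list(genome = g2, genes = genes2),
       divergence = div)
}

#' Derive an experimental genotype from a reference genome
#'
#' Emulates the gap the pipeline corrects: the genotype actually grafted
#' is not the genotype that was sequenced for the reference assembly. The
#' experimental genome differs from the reference by recorded SNPs and
#' indels (left-anchored, the convention the reference-modification stage
#' consumes) plus appended genotype-specific segments.
#'
#' @inheritParams simulate_genome_pair
#' @param reference reference genome `DNAStringSet`.
#' @param label genotype label for segment contig ids.
#' @return list with `genome` (experimental genotype, segments appended as
#'   extra contigs), `variants` (truth, normalized), `segments`, `map`.
#' @export
derive_experimental_genotype <- function(reference, config, label,
                                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  truth <- random_variants(reference, cfg$genotype_snps,
                           cfg$genotype_insertions, cfg$genotype_deletions,
                           cfg$max_indel_length)
  truth <- normalize_variants(truth, reference)
  av <- apply_variants(reference, truth)
  genome <- av$genome
  segs <- Biostrings::DNAStringSet(character(0))
  if (cfg$genotype_segments > 0L) {
    segs <- Biostrings::DNAStringSet(stats::setNames(
      vapply(seq_len(cfg$genotype_segments),
             function(i) random_dna(cfg$genotype_segment_length),
             character(1L)),
      sprintf("%s_seg%d", label, seq_len(cfg$genotype_segments))))
    meta <- S4Vectors::metadata(genome)
    genome <- c(genome, segs)
    S4Vectors::metadata(genome) <- meta
  }
  list(genome = genome, variants = truth, segments = segs, map = av$map)
}

#' Simulate tissue expression levels
#'
#' Independent log-normal relative abundances per gene, with a configurable
#' fraction of genes set to zero (unexpressed; these feed the C/C' sets).
#' Deterministic for a given seed.
#'
#' @inheritParams simulate_genome_pair
#' @param genes `gene_models` of the tissue's resident species.
#' @param tissue tissue label recorded in the output.
#' @return data frame `gene_id`, `tissue`, `level` (relative abundance).
#' @export
simulate_expression <- function(genes, config, tissue, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- sort(unique(genes$gene_id), method = "radix")
  n <- length(ids)
  expressed <- stats::runif(n) >= config$unexpressed_fraction
  level <- stats::rlnorm(n, config$expression_meanlog,
                         config$expression_sdlog) * expressed
  data.frame(gene_id = ids, tissue = tissue, level = level,
             stringsAsFactors = FALSE)
}

#' Extract transcript sequences from a genome
#'
#' Concatenates each gene's exon sequences in genomic order and
#' reverse-complements minus-strand genes, yielding the unspliced
#' transcript pool the read simulator samples from.
#'
#' @param genome genome `DNAStringSet`.
#' @param genes `gene_models` on that genome's coordinates.
#' @return named character vector of transcript sequences.
#' @export
transcript_sequences <- function(genome, genes) {
  seqs <- as.character(genome)
  ex <- genes[order(genes$gene_id, genes$start, method = "radix"), ,
              drop = FALSE]
  pieces <- substring(seqs[ex$contig], ex$start, ex$end)
  tx <- vapply(split(pieces, ex$gene_id), paste, character(1L),
               collapse = "")
  minus <- vapply(split(ex$strand, ex$gene_id), `[[`, character(1L), 1L)
  tx[minus == "-"] <- rc(tx[minus == "-"])
  tx
}

#' Plant mobile genes with target foreign abundances
#'
#' Chooses `mobile_per_direction` genes per direction among the donor
#' tissue's expressed genes and assigns each a target foreign FPKM drawn
#' log-uniformly from `foreign_fpkm_range`. The transmission fraction --
#' the share of the donor gene's transcript pool appearing in the
#' recipient read population -- is derived from the target FPKM, the
#' donor expression level and the recipient transcript pool, so mobility
#' is independent of donor abundance by construction.
#'
#' @inheritParams simulate_genome_pair
#' @param expression list with `scion` and `rootstock` tissue expression.
#' @param transcripts list with per-species transcript sequences.
#' @return data frame `gene_id`, `direction`, `condition`, `target_fpkm`,
#'   `transmission_fraction`, `donor_level`.
#' @export
plant_mobile_genes <- function(expression, transcripts, config,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  out <- list()
  pool_weight <- function(expr, tx) {
    lev <- stats::setNames(expr$level, expr$gene_id)
    lev <- lev[names(lev) %in% names(tx)]
    sum(lev * nchar(tx[names(lev)]) / 1000)
  }
  pools <- list(scion = pool_weight(expression$scion, transcripts$scion),
                rootstock = pool_weight(expression$rootstock,
                                        transcripts$rootstock))
  for (cond in cfg$conditions) {
    for (dir in c("upward", "downward")) {
      donor <- if (dir == "upward") "rootstock" else "scion"
      recipient <- if (dir == "upward") "scion" else "rootstock"
      expr <- expression[[donor]]
      cand <- intersect(expr$gene_id[expr$level > 0],
                        names(transcripts[[donor]]))
      if (cfg$mobile_per_direction > length(cand))
        stop("not enough expressed donor genes to plant mobile set")
      genes <- sort(sample(cand, cfg$mobile_per_direction),
                    method = "radix")
      lo <- log(cfg$foreign_fpkm_range[1]); hi <- log(cfg$foreign_fpkm_range[2])
      target <- exp(stats::runif(length(genes), lo, hi))
      lev <- stats::setNames(expr$level, expr$gene_id)[genes]
      # foreign pool weight giving E[FPKM] = target in the recipient:
      # w = target * len_kb * (recipient pool weight) / 1e6, and the
      # transmission fraction is w / (donor level * len_kb)
      frac <- target * pools[[recipient]] / (1e6 * lev)
      out[[length(out) + 1L]] <- data.frame(
        gene_id = genes, direction = dir, condition = cond,
        target_fpkm = target, transmission_fraction = frac,
        donor_level = as.numeric(lev), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Graft library design
#'
#' The four library roles of a grafting experiment (heterograft scion,
#' heterograft rootstock, scion homograft, rootstock homograft) for every
#' condition and replicate.
#'
#' @inheritParams simulate_genome_pair
#' @return data frame `library_id`, `role`, `condition`, `replicate`.
#' @export
graft_design <- function(config) {
  roles <- c("heterograft-scion", "heterograft-rootstock",
             "scion-homograft", "rootstock-homograft")
  short <- c("hs", "hr", "sh", "rh")
  rows <- expand.grid(role_i = seq_along(roles),
                      replicate = seq_len(config$replicates),
                      condition = config$conditions,
                      stringsAsFactors = FALSE)
  data.frame(library_id = sprintf("%s_%s_r%d", rows$condition,
                                  short[rows$role_i], rows$replicate),
             role = roles[rows$role_i], condition = rows$condition,
             replicate = rows$replicate, stringsAsFactors = FALSE)
}

add_sequencing_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  lens <- nchar(seqs)
  nerr <- stats::rbinom(length(seqs), lens, rate)
  hit <- which(nerr > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    p <- sample.int(lens[i], nerr[i])
    for (j in p) {
      alts <- bases[bases != substr(seqs[i], j, j)]
      substr(seqs[i], j, j) <- alts[sample.int(3L, 1L)]
    }
  }
  seqs
}

#' Simulate RNA-seq reads for every graft library
#'
#' Each library samples paired-end fragments from its resident transcript
#' pool (genes weighted by expression x transcript length). Heterograft
#' recipient libraries additionally sample foreign fragments of the
#' planted mobile genes at their transmission fractions; homograft control
#' libraries contain resident transcripts only. Per-base errors are
#' applied at the configured rate and every fragment's provenance is
#' recorded.
#'
#' @inheritParams simulate_genome_pair
#' @param design library design from [graft_design()].
#' @param transcripts list of per-species transcript sequence vectors.
#' @param expression list of per-tissue expression tables.
#' @param mobile_truth planted mobile set from [plant_mobile_genes()].
#' @return list with `libraries` (named list of read data frames) and
#'   `truth_reads` (per-fragment provenance labels).
#' @export
simulate_graft_reads <- function(design, transcripts, expression,
                                 mobile_truth, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  libs <- list(); prov <- list()
  for (li in seq_len(nrow(design))) {
    lib <- design[li, ]
    resident <- if (lib$role %in% c("heterograft-scion", "scion-homograft"))
      "scion" else "rootstock"
    donor <- if (resident == "scion") "rootstock" else "scion"
    expr <- expression[[resident]]
    tx_res <- transcripts[[resident]]
    lev <- stats::setNames(expr$level, expr$gene_id)
    lev <- lev[names(lev) %in% names(tx_res)]
    w_res <- lev * nchar(tx_res[names(lev)]) / 1000
    gene_pool <- names(w_res)
    w <- w_res
    origin <- rep("resident", length(w))
    tx_pool <- tx_res[gene_pool]
    if (startsWith(lib$role, "heterograft")) {
      dir <- if (resident == "scion") "upward" else "downward"
      mt <- mobile_truth[mobile_truth$direction == dir &
                           mobile_truth$condition == lib$condition, ,
                         drop = FALSE]
      if (nrow(mt) > 0L && cfg$transmission_scale > 0) {
        tx_don <- transcripts[[donor]]
        w_f <- mt$donor_level * mt$transmission_fraction *
          nchar(tx_don[mt$gene_id]) / 1000 * cfg$transmission_scale
        w <- c(w, stats::setNames(w_f, mt$gene_id))
        origin <- c(origin, rep("foreign", nrow(mt)))
        gene_pool <- c(gene_pool, mt$gene_id)
        tx_pool <- c(tx_pool, tx_don[mt$gene_id])
      }
    }
    live <- w > 0
    counts <- integer(length(w))
    if (any(live))
      counts[live] <- as.integer(stats::rmultinom(
        1L, cfg$fragments_per_library, w[live]))
    gene_of_frag <- rep(gene_pool, counts)
    origin_of_frag <- rep(origin, counts)
    n <- length(gene_of_frag)
    if (n == 0L) {
      libs[[lib$library_id]] <- data.frame(read_id = character(0),
                                           seq = character(0),
                                           qual = character(0))
      next
    }
    txs <- tx_pool[rep(seq_along(gene_pool), counts)]
    txlen <- nchar(txs)
    fl <- pmin(cfg$fragment_length, txlen)
    start <- floor(stats::runif(n) * (txlen - fl + 1)) + 1L
    frags <- substring(txs, start, start + fl - 1L)
    flip <- stats::runif(n) < 0.5
    frags[flip] <- rc(frags[flip])
    r1 <- substring(frags, 1L, pmin(cfg$read_length, fl))
    r2 <- rc(substring(frags, pmax(1L, fl - cfg$read_length + 1L), fl))
    r1 <- add_sequencing_errors(r1, cfg$error_rate)
    r2 <- add_sequencing_errors(r2, cfg$error_rate)
    frag_ids <- sprintf("%s:f%06d", lib$library_id, seq_len(n))
    reads <- data.frame(
      read_id = c(paste0(frag_ids, "/1"), paste0(frag_ids, "/2")),
      seq = c(r1, r2),
      qual = strrep("I", nchar(c(r1, r2))),
      stringsAsFactors = FALSE)
    ord <- order(rep(seq_len(n), 2L), rep(1:2, each = n))
    libs[[lib$library_id]] <- reads[ord, , drop = FALSE]
    prov[[lib$library_id]] <- data.frame(
      library_id = lib$library_id, frag_id = frag_ids,
      gene_id = gene_of_frag, origin = origin_of_frag,
      species_of_origin = ifelse(origin_of_frag == "resident", resident,
                                 donor),
      stringsAsFactors = FALSE)
  }
  truth_reads <- if (length(prov)) do.call(rbind, unname(prov)) else
    data.frame(library_id = character(0), frag_id = character(0),
               gene_id = character(0), origin = character(0),
               species_of_origin = character(0))
  rownames(truth_reads) <- NULL
  list(libraries = libs, truth_reads = truth_reads)
}

#' Simulate genomic resequencing reads
#'
#' Uniform single-end shotgun reads from an (experimental) genome at the
#' configured coverage, both strands, with optional per-base errors.
#'
#' @inheritParams simulate_genome_pair
#' @param genome genome to sequence.
#' @param label prefix for read ids.
#' @return read data frame (`read_id`, `seq`, `qual`).
#' @export
simulate_resequencing_reads <- function(genome, config, label = "rs",
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  widths <- Biostrings::width(genome)
  len <- cfg$read_length
  n <- ceiling(cfg$reseq_coverage * sum(widths) / len)
  ci <- sample.int(length(genome), n, replace = TRUE, prob = widths)
  seqs <- as.character(genome)
  start <- floor(stats::runif(n) * (widths[ci] - len + 1)) + 1L
  s <- substring(seqs[ci], start, start + len - 1L)
  minus <- stats::runif(n) < 0.5
  s[minus] <- rc(s[minus])
  s <- add_sequencing_errors(s, cfg$reseq_error_rate)
  data.frame(read_id = sprintf("%s:%07d", label, seq_len(n)),
             seq = s, qual = strrep("I", nchar(s)),
             stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic grafting experiment
#'
#' Runs the whole generative process in a fixed order under one seed:
#' reference genome pair with gene models, experimental genotypes (planted
#' variants + genotype-specific segments), tissue expression, planted
#' mobile genes, RNA-seq reads for every library and resequencing reads
#' for both genotypes. The returned truth tables cover every planted
#' variant, mobile gene and emitted fragment.
#'
#' @param config a [sim_config()].
#' @return a `graft_experiment` list; see the components in the source.
#' @export
simulate_graft_experiment <- function(config) {
  cfg <- config
  set.seed(cfg$seed)
  pair <- simulate_genome_pair(cfg, seed = NULL)
  geno_s <- derive_experimental_genotype(pair$scion$genome, cfg, "scionX")
  geno_r <- derive_experimental_genotype(pair$rootstock$genome, cfg,
                                         "rootstockX")
  genes_exp_s <- suppressWarnings(
    lift_gene_models(pair$scion$genes, geno_s$map))
  genes_exp_r <- suppressWarnings(
    lift_gene_models(pair$rootstock$genes, geno_r$map))
  transcripts <- list(
    scion = transcript_sequences(geno_s$genome, genes_exp_s),
    rootstock = transcript_sequences(geno_r$genome, genes_exp_r))
  expression <- list(
    scion = simulate_expression(pair$scion$genes, cfg, "scion-leaf"),
    rootstock = simulate_expression(pair$rootstock$genes, cfg,
                                    "rootstock-leaf"))
  mobile_truth <- plant_mobile_genes(expression, transcripts, cfg)
  design <- graft_design(cfg)
  rna <- simulate_graft_reads(design, transcripts, expression,
                              mobile_truth, cfg)
  reseq <- list(
    scion = simulate_resequencing_reads(geno_s$genome, cfg, "rs_scion"),
    rootstock = simulate_resequencing_reads(geno_r$genome, cfg,
                                            "rs_rootstock"))
  structure(list(
    config = cfg,
    references = list(scion = pair$scion$genome,
                      rootstock = pair$rootstock$genome),
    genes = list(scion = pair$scion$genes,
                 rootstock = pair$rootstock$genes),
    genotypes = list(scion = geno_s, rootstock = geno_r),
    expression = expression,
    mobile_truth = mobile_truth,
    design = design,
    libraries = rna$libraries,
    truth_reads = rna$truth_reads,
    reseq = reseq), class = "graft_experiment")
}

#' Score a call set against simulation truth
#'
#' Standard confusion-matrix arithmetic over a gene universe. Empty
#' denominators yield `NA` (an explicit no-value marker), never zero.
#'
#' @param called character vector of called gene ids (subset of universe).
#' @param truth character vector of truly mobile gene ids.
#' @param universe all genes over which calls were possible.
#' @return list with `tp`, `fp`, `fn`, `tn`, `precision`, `recall`, `f1`.
#' @export
evaluate_calls <- function(called, truth, universe) {
  stopifnot(all(called %in% universe))
  truth <- intersect(truth, universe)
  tp <- length(intersect(called, truth))
  fp <- length(setdiff(called, truth))
  fn <- length(setdiff(truth, called))
  tn <- length(universe) - tp - fp - fn
  precision <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  list(tp = tp, fp = fp, fn = fn, tn = tn, precision = precision,
       recall = recall, f1 = f1)
}
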