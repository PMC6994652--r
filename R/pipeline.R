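#' @keywords internal
write_manifest <- function(path, config, input_files = character(0),
                           counts = list()) {
  digests <- if (length(input_files))
    as.list(tools::md5sum(input_files[file.exists(input_files)]))
  else structure(list(), names = character(0))
  if (length(digests)) names(digests) <- basename(names(digests))
  manifest <- list(
    tool = "graftmobile",
    version = as.character(utils::packageVersion("graftmobile")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    input_digests = digests,
    counts = counts)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the simulation stage and write a synthetic experiment directory
#'
#' Emits reference and experimental genomes (FASTA), gene models (GFF3),
#' RNA-seq reads per library and resequencing reads per genotype (FASTQ),
#' complete truth tables (TSV), a config echo (JSON) and a run manifest.
#' Byte-identical for identical configs.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @return the `graft_experiment`, invisibly.
#' @export
run_simulate <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(outdir, "reads"), showWarnings = FALSE)
  exp <- simulate_graft_experiment(config)
  write_genome_fasta(exp$references$scion,
                     file.path(outdir, "ref_scion.fasta"))
  write_genome_fasta(exp$references$rootstock,
                     file.path(outdir, "ref_rootstock.fasta"))
  write_genome_fasta(exp$genotypes$scion$genome,
                     file.path(outdir, "experimental_scion.fasta"))
  write_genome_fasta(exp$genotypes$rootstock$genome,
                     file.path(outdir, "experimental_rootstock.fasta"))
  write_gene_models(exp$genes$scion, file.path(outdir, "genes_scion.gff3"))
  write_gene_models(exp$genes$rootstock,
                    file.path(outdir, "genes_rootstock.gff3"))
  for (lib in names(exp$libraries))
    write_fastq(exp$libraries[[lib]],
                file.path(outdir, "reads", paste0(lib, ".fastq")))
  write_fastq(exp$reseq$scion, file.path(outdir, "reseq_scion.fastq"))
  write_fastq(exp$reseq$rootstock,
              file.path(outdir, "reseq_rootstock.fastq"))
  write_variant_table(exp$genotypes$scion$variants,
                      file.path(outdir, "truth_variants_scion.tsv"))
  write_variant_table(exp$genotypes$rootstock$variants,
                      file.path(outdir, "truth_variants_rootstock.tsv"))
  write_tsv(exp$mobile_truth, file.path(outdir, "truth_mobile.tsv"))
  write_tsv(exp$truth_reads, file.path(outdir, "truth_reads.tsv"))
  write_tsv(exp$design, file.path(outdir, "design.tsv"))
  jsonlite::write_json(unclass(config),
                       file.path(outdir, "config_echo.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(file.path(outdir, "manifest.json"), unclass(config),
                 counts = list(
                   libraries = length(exp$libraries),
                   planted_variants_scion =
                     nrow(exp$genotypes$scion$variants),
                   planted_variants_rootstock =
                     nrow(exp$genotypes$rootstock$variants),
                   planted_mobile = nrow(exp$mobile_truth)))
  invisible(exp)
}

#' Run the reference-modification stage
#'
#' Aligns resequencing reads to the published reference (indel-aware
#' built-in matcher), calls and filters pileup variants, rewrites the
#' reference, assembles the leftover unmapped reads into extra scaffolds
#' and concatenates them (minus the exclusion list). Idempotent:
#' rerunning on unchanged inputs reproduces byte-identical outputs.
#'
#' @param reference reference genome (`DNAStringSet` or FASTA path).
#' @param reads resequencing reads (data frame or FASTQ path).
#' @param outdir output directory.
#' @param min_depth,min_zygosity,min_quality variant filters
#'   (see [filter_variants()]).
#' @param seed_len,max_mismatch_frac,max_indel matcher settings.
#' @param assembly_k,min_scaffold_len assembler settings.
#' @param exclusion_ids scaffold ids to drop (contaminant screen hook).
#' @param default_base_quality phred assumed for missing base qualities.
#' @param label genotype label for provenance.
#' @return list with `genome`, `map`, `applied`, `rejected`, `scaffolds`
#'   and stage `counts`.
#' @export
run_modref <- function(reference, reads, outdir,
                       min_depth = 6, min_zygosity = 0.9,
                       min_quality = 20, seed_len = 31,
                       max_mismatch_frac = 0.05, max_indel = 10,
                       assembly_k = 31, min_scaffold_len = 200,
                       exclusion_ids = character(0),
                       default_base_quality = 30, label = "genotype") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(reference)) reference <- read_genome_fasta(reference)
  if (is.character(reads)) reads <- read_fastq(reads)
  aln <- builtin_align(reads, reference, seed_len = seed_len,
                       max_mismatch_frac = max_mismatch_frac,
                       gapped = TRUE, max_indel = max_indel)
  candidates <- call_pileup_variants(aln, reference,
                                     default_base_quality)
  filtered <- filter_variants(candidates, min_depth, min_zygosity,
                              min_quality)
  unmapped <- reads[reads$read_id %in% aln$read_id[!aln$mapped], ,
                    drop = FALSE]
  scaffolds <- assemble_unmapped(unmapped, k = assembly_k,
                                 min_scaffold_len = min_scaffold_len,
                                 provenance = label)
  bm <- build_modified_reference(reference, filtered, scaffolds,
                                 exclusion_ids)
  write_genome_fasta(bm$genome, file.path(outdir, "genome_modified.fasta"))
  write_genome_fasta(scaffolds$scaffolds,
                     file.path(outdir, "scaffolds.fasta"))
  write_variant_table(candidates,
                      file.path(outdir, "variants_candidates.tsv"))
  write_variant_table(bm$applied, file.path(outdir, "variants_applied.tsv"))
  write_variant_table(bm$rejected,
                      file.path(outdir, "variants_rejected.tsv"))
  write_coordinate_map(bm$map, file.path(outdir, "coordinate_map.tsv"))
  counts <- list(reads_total = nrow(reads),
                 reads_mapped = sum(aln$mapped),
                 reads_unmapped = sum(!aln$mapped),
                 variants_called = nrow(candidates),
                 variants_filtered = nrow(filtered),
                 variants_applied = nrow(bm$applied),
                 variants_rejected = nrow(bm$rejected),
                 scaffolds_assembled = length(scaffolds$scaffolds),
                 scaffolds_retained = length(bm$scaffold_ids))
  write_manifest(file.path(outdir, "manifest.json"),
                 list(min_depth = min_depth, min_zygosity = min_zygosity,
                      min_quality = min_quality, seed_len = seed_len,
                      max_mismatch_frac = max_mismatch_frac,
                      max_indel = max_indel, assembly_k = assembly_k,
                      min_scaffold_len = min_scaffold_len,
                      default_base_quality = default_base_quality,
                      label = label),
                 input_files = c(file.path(outdir, "genome_modified.fasta")),
                 counts = counts)
  c(bm, list(scaffolds = scaffolds, counts = counts,
             alignments = NULL))
}

#' Run the mobile-mRNA detection stage
#'
#' Thin file-level wrapper over [detect_mobile_transcripts()]: accepts
#' genomes/annotations as objects or paths, library reads as data frames
#' or FASTQ paths, writes the mb-mRNA candidate and final tables, the
#' expression and partition tables, a structured run summary and a
#' manifest.
#'
#' @param scion_genome,rootstock_genome modified genomes or FASTA paths.
#' @param scion_genes,rootstock_genes `gene_models` or GFF3 paths.
#' @param libraries as in [detect_mobile_transcripts()]; each library's
#'   `reads` may be a FASTQ path.
#' @param outdir output directory.
#' @param ... thresholds passed to [detect_mobile_transcripts()].
#' @return the `mobile_call_result`, invisibly.
#' @export
run_detect <- function(scion_genome, rootstock_genome, scion_genes,
                       rootstock_genes, libraries, outdir, ...) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(scion_genome))
    scion_genome <- read_genome_fasta(scion_genome, role = "modified")
  if (is.character(rootstock_genome))
    rootstock_genome <- read_genome_fasta(rootstock_genome,
                                          role = "modified")
  if (is.character(scion_genes))
    scion_genes <- read_gene_models(scion_genes)
  if (is.character(rootstock_genes))
    rootstock_genes <- read_gene_models(rootstock_genes)
  libraries <- lapply(libraries, function(lib) {
    if (is.character(lib$reads)) lib$reads <- read_fastq(lib$reads)
    lib
  })
  res <- detect_mobile_transcripts(scion_genome, rootstock_genome,
                                   scion_genes, rootstock_genes,
                                   libraries, ...)
  write_tsv(res$calls, file.path(outdir, "mobile_candidates.tsv"))
  write_tsv(res$mobile, file.path(outdir, "mobile_calls.tsv"))
  write_tsv(res$expression, file.path(outdir, "expression.tsv"))
  write_tsv(res$partitions, file.path(outdir, "partitions.tsv"))
  s <- summarize_calls(res$mobile)
  jsonlite::write_json(
    list(counts = s$counts, venn = s$venn, params = res$params,
         tie_note = "fragments hitting both genomes equally are discarded"),
    file.path(outdir, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  write_manifest(file.path(outdir, "manifest.json"), res$params,
                 counts = list(
                   libraries = length(libraries),
                   candidates = nrow(res$calls),
                   mobile = nrow(res$mobile)))
  invisible(res)
}

#' Run the full synthetic pipeline end to end
#'
#' Chains the three stages on one synthetic experiment: simulate, rebuild
#' both modified references from the simulated resequencing reads, lift
#' the gene models onto the modified coordinates, detect mobile mRNAs and
#' score the calls against the planted truth.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (stage subdirectories are created).
#' @param write_simulation also write the full simulation directory
#'   (default `FALSE`: the experiment stays in memory).
#' @param ... thresholds forwarded to [detect_mobile_transcripts()].
#' @return list with `experiment`, `modref` (per species), `detect`
#'   (the `mobile_call_result`) and `evaluation` (per direction/condition
#'   precision/recall vs truth).
#' @export
run_all <- function(config, outdir, write_simulation = FALSE, ...) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  exp <- if (write_simulation)
    run_simulate(config, file.path(outdir, "simulate"))
  else simulate_graft_experiment(config)
  mod_s <- run_modref(exp$references$scion, exp$reseq$scion,
                      file.path(outdir, "modref_scion"),
                      label = "scionX")
  mod_r <- run_modref(exp$references$rootstock, exp$reseq$rootstock,
                      file.path(outdir, "modref_rootstock"),
                      label = "rootstockX")
  genes_s <- suppressWarnings(lift_gene_models(exp$genes$scion, mod_s$map))
  genes_r <- suppressWarnings(lift_gene_models(exp$genes$rootstock,
                                               mod_r$map))
  libraries <- lapply(seq_len(nrow(exp$design)), function(i) {
    d <- exp$design[i, ]
    list(library_id = d$library_id, role = d$role,
         condition = d$condition, replicate = d$replicate,
         reads = exp$libraries[[d$library_id]])
  })
  det <- run_detect(mod_s$genome, mod_r$genome, genes_s, genes_r,
                    libraries, file.path(outdir, "detect"), ...)
  evaluation <- list()
  for (cond in unique(exp$design$condition)) {
    for (dir in c("upward", "downward")) {
      donor <- if (dir == "upward") "rootstock" else "scion"
      truth <- exp$mobile_truth$gene_id[
        exp$mobile_truth$direction == dir &
          exp$mobile_truth$condition == cond]
      called <- det$mobile$gene_id[det$mobile$direction == dir &
                                     det$mobile$condition == cond]
      universe <- unique(exp$genes[[donor]]$gene_id)
      evaluation[[paste(dir, cond, sep = "_")]] <-
        evaluate_calls(called, truth, universe)
    }
  }
  jsonlite::write_json(evaluation, file.path(outdir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(experiment = exp, modref = list(scion = mod_s, rootstock = mod_r),
       detect = det, evaluation = evaluation)
}
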