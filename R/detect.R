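#' Detect mobile mRNAs in a grafting experiment
#'
#' Runs the full read-classification and mobile-calling workflow for both
#' directions and every condition. Per library, reads are aligned to the
#' library's resident (modified) genome; fragments that fail to map are
#' re-matched against both genomes at hit sensitivity and adjudicated by
#' best score ([partition_reads()]). Foreign fragments are assigned to the
#' partner genome's gene models; candidate mobile genes (set A/A') are
#' then filtered by homograft-control subtraction (B/B'),
#' donor-expression filtering (C/C'), a strict foreign-FPKM threshold per
#' replicate, and intersection across biological replicates.
#'
#' @param scion_genome,rootstock_genome modified genomes (`DNAStringSet`),
#'   or prebuilt [genome_index()] objects when running many detection
#'   rounds against fixed genomes.
#' @param scion_genes,rootstock_genes `gene_models` on those genomes.
#' @param libraries list of libraries; each element is a list with
#'   `library_id`, `role` (`heterograft-scion`, `heterograft-rootstock`,
#'   `scion-homograft`, `rootstock-homograft`), `condition`, `replicate`
#'   and `reads` (data frame `read_id`, `seq`, optionally `qual`).
#' @param min_fpkm mobility threshold, strict (default 0.05).
#' @param expression_mode donor-expression mode for [expressed_gene_set()].
#' @param b_mode homograft subtraction granularity: `"stringent"` excludes
#'   any gene with control foreign evidence; `"lenient"` only genes whose
#'   control foreign FPKM exceeds `min_fpkm`.
#' @param min_margin cross-genome score margin ([partition_reads()]).
#' @param seed_len,max_mismatch_frac resident-pass matcher settings.
#' @param hit_max_mismatch_frac mismatch tolerance of the more permissive
#'   cross-genome hit pass (default 0.10), mirroring the
#'   strict-mapper-then-sensitive-search structure of the workflow.
#' @param max_evalue,min_hit_length hit quality gate.
#' @param allow_single_replicate see [intersect_replicates()].
#' @return a `mobile_call_result`: list with `calls` (candidate table with
#'   filter flags), `mobile` (final calls), `expression` (per-library
#'   resident FPKM), `partitions` (per-library class counts), `params`.
#' @export
detect_mobile_transcripts <- function(scion_genome, rootstock_genome,
                                      scion_genes, rootstock_genes,
                                      libraries,
                                      min_fpkm = 0.05,
                                      expression_mode = "any-replicate",
                                      b_mode = c("stringent", "lenient"),
                                      min_margin = 0,
                                      seed_len = 31,
                                      max_mismatch_frac = 0.05,
                                      hit_max_mismatch_frac = 0.10,
                                      max_evalue = 1e-5,
                                      min_hit_length = 50,
                                      allow_single_replicate = FALSE) {
  b_mode <- match.arg(b_mode)
  roles <- vapply(libraries, `[[`, character(1L), "role")
  conds <- vapply(libraries, `[[`, character(1L), "condition")
  need <- c("heterograft-scion", "heterograft-rootstock",
            "scion-homograft", "rootstock-homograft")
  for (cond in unique(conds)) {
    have <- roles[conds == cond]
    missing <- setdiff(need, have)
    if (length(missing) > 0L)
      stop("condition ", cond, " lacks mandatory librar(ies): ",
           paste(missing, collapse = ", "),
           " (the homograft false-positive control is not optional)")
  }

  genes <- list(scion = scion_genes, rootstock = rootstock_genes)
  # one seed index per genome, shared by all libraries and passes;
  # callers running many detect rounds on fixed genomes can pass
  # prebuilt genome_index objects directly
  as_index <- function(g) if (inherits(g, "genome_index")) g
                          else genome_index(g, seed_len)
  genomes <- list(scion = as_index(scion_genome),
                  rootstock = as_index(rootstock_genome))

  # per-library two-pass classification
  lib_data <- lapply(libraries, function(lib) {
    resident <- if (lib$role %in% c("heterograft-scion", "scion-homograft"))
      "scion" else "rootstock"
    partner <- setdiff(c("scion", "rootstock"), resident)
    reads <- lib$reads
    res_aln <- builtin_align(reads, genomes[[resident]], seed_len,
                             max_mismatch_frac)
    frag <- fragment_id(res_aln$read_id)
    mapped_frags <- unique(frag[res_aln$mapped])
    todo <- reads[!(fragment_id(reads$read_id) %in% mapped_frags), ,
                  drop = FALSE]
    own_hits <- builtin_align(todo, genomes[[resident]], seed_len,
                              hit_max_mismatch_frac)
    foreign_hits <- builtin_align(todo, genomes[[partner]], seed_len,
                                  hit_max_mismatch_frac)
    part <- partition_reads(lib$library_id, res_aln, own_hits,
                            foreign_hits, min_margin = min_margin,
                            max_evalue = max_evalue,
                            min_hit_length = min_hit_length)
    res_assign <- assign_fragments_to_genes(part$resident,
                                            genes[[resident]])
    total_resident <- length(part$resident_frags)
    expr <- if (total_resident > 0L)
      compute_fpkm(res_assign$counts, genes[[resident]], total_resident)
    else data.frame(gene_id = names(res_assign$counts), count = 0,
                    fpkm = 0, stringsAsFactors = FALSE)
    fgn_assign <- assign_fragments_to_genes(part$foreign,
                                            genes[[partner]])
    list(lib = lib, resident = resident, partner = partner,
         partition = part, total_resident = total_resident,
         expression = expr, foreign_counts = fgn_assign$counts,
         foreign_unassigned = fgn_assign$unassigned)
  })
  names(lib_data) <- vapply(lib_data, function(x) x$lib$library_id,
                            character(1L))

  expression_long <- do.call(rbind, lapply(lib_data, function(x)
    cbind(x$expression,
          library_id = x$lib$library_id, role = x$lib$role,
          condition = x$lib$condition, replicate = x$lib$replicate,
          stringsAsFactors = FALSE)))
  rownames(expression_long) <- NULL
  partitions <- do.call(rbind, lapply(lib_data, function(x)
    cbind(partition_summary(x$partition), role = x$lib$role,
          condition = x$lib$condition, replicate = x$lib$replicate,
          total_resident = x$total_resident,
          foreign_unassigned = x$foreign_unassigned,
          stringsAsFactors = FALSE)))
  rownames(partitions) <- NULL

  pick <- function(role, cond)
    Filter(function(x) x$lib$role == role && x$lib$condition == cond,
           lib_data)

  all_calls <- list(); final <- list(); evidence <- list()
  for (cond in unique(conds)) {
    for (dir in c("upward", "downward")) {
      recipient_role <- if (dir == "upward") "heterograft-scion"
                        else "heterograft-rootstock"
      control_role <- if (dir == "upward") "scion-homograft"
                      else "rootstock-homograft"
      donor_role <- if (dir == "upward") "heterograft-rootstock"
                    else "heterograft-scion"
      donor_species <- if (dir == "upward") "rootstock" else "scion"
      donor_models <- genes[[donor_species]]
      donor_universe <- sort(unique(donor_models$gene_id),
                             method = "radix")

      recipients <- pick(recipient_role, cond)
      controls <- pick(control_role, cond)
      donors <- pick(donor_role, cond)

      # B / B': homograft foreign evidence on donor genes
      if (b_mode == "stringent") {
        B <- sort(unique(unlist(lapply(controls, function(x)
          names(x$foreign_counts)[x$foreign_counts > 0]))),
          method = "radix")
      } else {
        B <- sort(unique(unlist(lapply(controls, function(x) {
          if (x$total_resident == 0L) return(character(0))
          fp <- compute_fpkm(x$foreign_counts, donor_models,
                             x$total_resident)
          fp$gene_id[fp$fpkm > min_fpkm]
        }))), method = "radix")
      }
      # C / C': genes unexpressed in the donor tissue
      donor_expr <- do.call(rbind, lapply(donors, function(x)
        cbind(x$expression, replicate = x$lib$replicate,
              stringsAsFactors = FALSE)))
      expressed <- expressed_gene_set(donor_expr, min_fpkm,
                                      expression_mode)
      C <- setdiff(donor_universe, expressed)

      per_rep <- lapply(recipients, function(x)
        call_mobile_replicate(x$foreign_counts, B, C, donor_models,
                              max(x$total_resident, 1L), min_fpkm))
      names(per_rep) <- vapply(recipients, function(x)
        as.character(x$lib$replicate), character(1L))
      mobile <- intersect_replicates(lapply(per_rep, `[[`, "gene_id"),
                                     allow_single = allow_single_replicate)

      # candidate table with per-replicate evidence and filter flags
      cand_genes <- sort(unique(unlist(lapply(recipients, function(x)
        names(x$foreign_counts)[x$foreign_counts > 0]))),
        method = "radix")
      if (length(cand_genes) > 0L) {
        tab <- data.frame(gene_id = cand_genes, direction = dir,
                          condition = cond, stringsAsFactors = FALSE)
        pass_fpkm <- rep(TRUE, length(cand_genes))
        for (x in recipients) {
          fp <- compute_fpkm(x$foreign_counts, donor_models,
                             max(x$total_resident, 1L))
          rownames(fp) <- fp$gene_id
          rep_id <- x$lib$replicate
          tab[[paste0("count_rep", rep_id)]] <-
            fp[cand_genes, "count"]
          tab[[paste0("fpkm_rep", rep_id)]] <- fp[cand_genes, "fpkm"]
          pass_fpkm <- pass_fpkm & fp[cand_genes, "fpkm"] > min_fpkm
        }
        tab$passed_control_subtraction <- !(cand_genes %in% B)
        tab$passed_expression_filter <- !(cand_genes %in% C)
        tab$passed_fpkm_threshold <- pass_fpkm
        tab$passed_replicate_intersection <- cand_genes %in% mobile
        tab$mobile <- tab$passed_control_subtraction &
          tab$passed_expression_filter & tab$passed_fpkm_threshold &
          tab$passed_replicate_intersection
        all_calls[[paste(dir, cond)]] <- tab
      }
      if (length(mobile) > 0L)
        final[[paste(dir, cond)]] <- data.frame(
          gene_id = mobile, direction = dir, condition = cond,
          stringsAsFactors = FALSE)
      evidence[[paste(dir, cond)]] <-
        list(direction = dir, condition = cond, B_genes = B, C_genes = C,
             donor_universe = donor_universe, per_replicate = per_rep)
    }
  }
  calls <- if (length(all_calls)) do.call(rbind, unname(all_calls)) else
    data.frame(gene_id = character(0), direction = character(0),
               condition = character(0))
  mobile <- if (length(final)) do.call(rbind, unname(final)) else
    data.frame(gene_id = character(0), direction = character(0),
               condition = character(0))
  rownames(calls) <- rownames(mobile) <- NULL
  structure(list(calls = calls, mobile = mobile,
                 expression = expression_long, partitions = partitions,
                 evidence = evidence,
                 params = list(min_fpkm = min_fpkm,
                               expression_mode = expression_mode,
                               b_mode = b_mode, min_margin = min_margin,
                               seed_len = seed_len,
                               max_mismatch_frac = max_mismatch_frac,
                               hit_max_mismatch_frac = hit_max_mismatch_frac,
                               max_evalue = max_evalue,
                               min_hit_length = min_hit_length)),
            class = "mobile_call_result")
}

#' @export
print.mobile_call_result <- function(x, ...) {
  cat("mobile mRNA call set\n")
  s <- summarize_calls(x$mobile)
  if (nrow(x$mobile) == 0L) cat("  no mobile transcripts called\n")
  else print(s$counts, row.names = FALSE)
  invisible(x)
}
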