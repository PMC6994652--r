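#' FPKM quantification
#'
#' FPKM = fragments per kilobase of exonic transcript length per million
#' mapped fragments: `count / (exonic_length/1000) / (total_fragments/1e6)`.
#'
#' @param counts named numeric vector of fragment counts per gene.
#' @param genes `gene_models` supplying exonic lengths; every counted gene
#'   must have a model (missing model is a hard error).
#' @param total_fragments library-size denominator: the total number of
#'   mapped fragments in the library (must be > 0).
#' @return data frame with `gene_id`, `count`, `fpkm`.
#' @export
compute_fpkm <- function(counts, genes, total_fragments) {
  stopifnot(total_fragments > 0)
  lens <- exonic_lengths(genes)
  missing <- setdiff(names(counts), names(lens))
  if (length(missing) > 0L)
    stop("counted gene(s) without a model: ",
         paste(missing, collapse = ", "))
  data.frame(gene_id = names(counts),
             count = as.numeric(counts),
             fpkm = as.numeric(counts) / (lens[names(counts)] / 1000) /
               (total_fragments / 1e6),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Expressed gene set of a tissue
#'
#' Genes counted as expressed when their FPKM strictly exceeds `min_fpkm`
#' in at least one replicate (`"any-replicate"`, default) or in every
#' replicate (`"all-replicates"`). The complement of this set over the
#' donor gene universe is the unexpressed-gene false-positive set (C/C')
#' subtracted during mobile calling.
#'
#' @param expr expression data frame with `gene_id`, `fpkm` and (for
#'   all-replicates mode) a `replicate` column; rows from the donor-tissue
#'   libraries of one condition.
#' @param min_fpkm threshold, strict inequality (default 0.05).
#' @param mode `"any-replicate"` or `"all-replicates"`.
#' @return character vector of expressed gene ids.
#' @export
expressed_gene_set <- function(expr, min_fpkm = 0.05,
                               mode = c("any-replicate",
                                        "all-replicates")) {
  mode <- match.arg(mode)
  if (is.null(expr) || nrow(expr) == 0L) {
    warning("empty expression table: expressed gene set is empty")
    return(character(0))
  }
  if (mode == "any-replicate")
    return(sort(unique(expr$gene_id[expr$fpkm > min_fpkm]),
                method = "radix"))
  if (is.null(expr$replicate))
    stop("all-replicates mode needs a 'replicate' column")
  nrep <- length(unique(expr$replicate))
  hi <- expr[expr$fpkm > min_fpkm, , drop = FALSE]
  tab <- table(unique(hi[, c("gene_id", "replicate")])$gene_id)
  sort(names(tab)[tab == nrep], method = "radix")
}

#' Call mobile genes in one replicate
#'
#' The per-replicate set rule of the workflow: a donor gene is called
#' mobile in a replicate when it has foreign fragment evidence in the
#' heterograft recipient tissue (set A/A'), is not contaminated by
#' homograft-control foreign evidence (set B/B'), is expressed in the
#' donor tissue (not in set C/C'), and its foreign FPKM strictly exceeds
#' `min_fpkm`. The homograft control is mandatory: passing `NULL` for
#' `B_genes` is a hard error (pass `character(0)` for a control with no
#' foreign evidence).
#'
#' @param A_counts named numeric vector: foreign fragments assigned to
#'   each donor gene in the heterograft recipient tissue.
#' @param B_genes donor genes with homograft-control foreign evidence.
#' @param C_genes donor genes unexpressed in the donor tissue.
#' @param donor_genes `gene_models` of the donor genome.
#' @param recipient_total_fragments resident-mapped fragment total of the
#'   recipient library (FPKM denominator).
#' @param min_fpkm mobility threshold, strict (default 0.05).
#' @return data frame `gene_id`, `count`, `fpkm` of the replicate's calls.
#' @export
call_mobile_replicate <- function(A_counts, B_genes, C_genes, donor_genes,
                                  recipient_total_fragments,
                                  min_fpkm = 0.05) {
  if (is.null(B_genes) || is.null(C_genes))
    stop("homograft-control (B) and donor-expression (C) sets are ",
         "mandatory; pass character(0) for an empty set")
  A_counts <- A_counts[A_counts > 0]
  if (length(A_counts) == 0L)
    return(data.frame(gene_id = character(0), count = numeric(0),
                      fpkm = numeric(0), stringsAsFactors = FALSE))
  fp <- compute_fpkm(A_counts, donor_genes, recipient_total_fragments)
  keep <- !(fp$gene_id %in% B_genes) & !(fp$gene_id %in% C_genes) &
    fp$fpkm > min_fpkm
  out <- fp[keep, , drop = FALSE]
  out[order(out$gene_id, method = "radix"), , drop = FALSE]
}

#' Intersect per-replicate call sets
#'
#' Only genes called in every biological replicate are retained. A single
#' replicate is a hard error unless `allow_single = TRUE` (then passthrough
#' with a loud warning) -- replicate support is part of the method's
#' false-positive control.
#'
#' @param per_replicate_calls list of character vectors (one per replicate).
#' @param allow_single permit a single replicate (default `FALSE`).
#' @return character vector: the intersection.
#' @export
intersect_replicates <- function(per_replicate_calls, allow_single = FALSE) {
  if (length(per_replicate_calls) < 2L) {
    if (!allow_single)
      stop("at least two biological replicates are required")
    warning("single replicate: replicate-intersection filter NOT applied")
    return(sort(unique(per_replicate_calls[[1L]]), method = "radix"))
  }
  sort(Reduce(intersect, per_replicate_calls), method = "radix")
}

#' Summarize mobile calls across conditions
#'
#' Per-direction/per-condition totals plus the pairwise Venn partition
#' (shared and exclusive set sizes) across conditions within a direction.
#'
#' @param calls data frame with `gene_id`, `direction`, `condition` (one
#'   row per final call).
#' @return list with `counts` (direction x condition data frame) and
#'   `venn` (one row per direction and condition pair).
#' @export
summarize_calls <- function(calls) {
  if (is.null(calls) || nrow(calls) == 0L) {
    counts <- data.frame(direction = character(0),
                         condition = character(0), n = integer(0))
  } else {
    counts <- as.data.frame(table(direction = calls$direction,
                                  condition = calls$condition),
                            stringsAsFactors = FALSE)
    names(counts)[3L] <- "n"
  }
  venn <- list()
  for (dir in unique(calls$direction)) {
    sub <- calls[calls$direction == dir, , drop = FALSE]
    conds <- sort(unique(sub$condition))
    if (length(conds) < 2L) next
    for (i in seq_len(length(conds) - 1L)) for (j in (i + 1L):length(conds)) {
      a <- unique(sub$gene_id[sub$condition == conds[i]])
      b <- unique(sub$gene_id[sub$condition == conds[j]])
      venn[[length(venn) + 1L]] <- data.frame(
        direction = dir, condition_a = conds[i], condition_b = conds[j],
        shared = length(intersect(a, b)),
        exclusive_a = length(setdiff(a, b)),
        exclusive_b = length(setdiff(b, a)),
        total_a = length(a), total_b = length(b),
        stringsAsFactors = FALSE)
    }
  }
  venn <- if (length(venn)) do.call(rbind, venn) else
    data.frame(direction = character(0), condition_a = character(0),
               condition_b = character(0), shared = integer(0),
               exclusive_a = integer(0), exclusive_b = integer(0),
               total_a = integer(0), total_b = integer(0))
  list(counts = counts, venn = venn)
}

#' Fraction of mobile genes with low donor expression
#'
#' The share of mobile genes whose mean donor-tissue FPKM (across
#' replicates, absent genes counted as 0) lies strictly below `cutoff`.
#' Used to ask whether mobility is driven by abundance.
#'
#' @param mobile_genes character vector of mobile gene ids.
#' @param donor_expr donor expression data frame (`gene_id`, `fpkm`,
#'   optionally multiple replicates as rows).
#' @param cutoff FPKM cutoff (default 1).
#' @return fraction in \[0, 1\], or `NA` for an empty mobile set.
#' @export
low_expression_fraction <- function(mobile_genes, donor_expr, cutoff = 1) {
  if (length(mobile_genes) == 0L) return(NA_real_)
  mean_fpkm <- stats::setNames(rep(0, length(mobile_genes)), mobile_genes)
  sub <- donor_expr[donor_expr$gene_id %in% mobile_genes, , drop = FALSE]
  if (nrow(sub) > 0L) {
    m <- rowsum(sub$fpkm, sub$gene_id) / as.integer(table(sub$gene_id))
    mean_fpkm[rownames(m)] <- as.numeric(m)
  }
  mean(mean_fpkm < cutoff)
}
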