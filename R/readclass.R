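#' Gene models
#'
#' Gene models are stored as a data frame with one row per exon:
#' `gene_id`, `contig`, `strand`, `start`, `end` (1-based inclusive).
#' Exons of a gene must lie on one contig and must not overlap; they are
#' kept sorted by position.
#'
#' @param x data frame with the columns above.
#' @return a `gene_models` data frame.
#' @export
gene_models <- function(x) {
  stopifnot(all(c("gene_id", "contig", "strand", "start", "end") %in%
                  names(x)))
  x <- as.data.frame(x)[, c("gene_id", "contig", "strand", "start", "end")]
  x$start <- as.integer(x$start); x$end <- as.integer(x$end)
  if (any(x$end < x$start)) stop("exon(s) with end < start")
  x <- x[order(x$gene_id, x$start, method = "radix"), , drop = FALSE]
  rownames(x) <- NULL
  by_gene <- split(seq_len(nrow(x)), x$gene_id)
  for (idx in by_gene) {
    if (length(unique(x$contig[idx])) > 1L)
      stop("gene ", x$gene_id[idx[1L]], " spans multiple contigs")
    if (length(idx) > 1L &&
        any(x$start[idx][-1L] <= x$end[idx][-length(idx)]))
      stop("overlapping exons in gene ", x$gene_id[idx[1L]])
  }
  class(x) <- c("gene_models", "data.frame")
  x
}

#' @rdname gene_models
#' @param genes a `gene_models` data frame.
#' @return `exonic_lengths()`: named integer vector of summed exon lengths.
#' @export
exonic_lengths <- function(genes) {
  w <- genes$end - genes$start + 1L
  out <- rowsum(w, genes$gene_id)
  stats::setNames(as.integer(out), rownames(out))
}

#' Read / write gene models as GFF3
#'
#' Uses rtracklayer for parsing and serialization. On import, exons are
#' taken from `type == "exon"` features and their gene from the `Parent`
#' attribute (falling back to `ID` on gene features).
#'
#' @param path GFF3 file.
#' @return `read_gene_models()`: a `gene_models` data frame.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  ex <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(ex) == 0L) stop("no exon features in ", path)
  parent <- vapply(as.list(ex$Parent), function(p)
    if (length(p)) as.character(p[[1L]]) else NA_character_, character(1L))
  gene_models(data.frame(
    gene_id = sub("^(gene:|transcript:)", "", parent),
    contig = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    start = GenomicRanges::start(ex), end = GenomicRanges::end(ex),
    stringsAsFactors = FALSE))
}

#' @rdname read_gene_models
#' @param genes a `gene_models` data frame.
#' @export
write_gene_models <- function(genes, path) {
  spans <- do.call(rbind, lapply(split(genes, genes$gene_id), function(g)
    data.frame(gene_id = g$gene_id[1L], contig = g$contig[1L],
               strand = g$strand[1L], start = min(g$start),
               end = max(g$end), stringsAsFactors = FALSE)))
  spans <- spans[order(spans$contig, spans$start, method = "radix"), ]
  gene_gr <- GenomicRanges::GRanges(
    spans$contig, IRanges::IRanges(spans$start, spans$end),
    strand = spans$strand, type = "gene", ID = spans$gene_id)
  ex <- genes[order(genes$contig, genes$start, method = "radix"), ]
  exon_gr <- GenomicRanges::GRanges(
    ex$contig, IRanges::IRanges(ex$start, ex$end), strand = ex$strand,
    type = "exon", Parent = ex$gene_id)
  rtracklayer::export(c(gene_gr, exon_gr), path, format = "gff3")
  invisible(path)
}

exon_granges <- function(genes) {
  GenomicRanges::GRanges(genes$contig,
                         IRanges::IRanges(genes$start, genes$end),
                         gene_id = genes$gene_id)
}

fragment_id <- function(read_id) sub("/[12]$", "", read_id)

# best hit per fragment: highest score, ties by (contig, pos)
best_per_fragment <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$frag_id, -hits$score, hits$contig, hits$pos,
               method = "radix")
  hits <- hits[ord, , drop = FALSE]
  hits[!duplicated(hits$frag_id), , drop = FALSE]
}

#' Partition a library's fragments by mapping class
#'
#' Fragments (read pairs collapsed by read id; `/1`, `/2` suffixes are
#' stripped) are classified from the two-pass evidence of the workflow:
#' any fragment with a mapped alignment to its resident genome is
#' `resident`; the remaining fragments are adjudicated between their
#' best own-genome and best partner-genome (foreign) hits. A fragment is
#' `foreign` when its foreign score exceeds the own score by more than
#' `min_margin`, `own` in the mirrored case, `ambiguous` when neither side
#' wins by the margin, and `no_hit` when it hits nothing. Hits must first
#' pass the quality gate (`evalue <= max_evalue` where an e-value is
#' recorded, and aligned length `>= min_hit_length`). Ambiguous fragments
#' are discarded downstream: this is deliberately conservative against
#' homolog-driven cross-mapping, the dominant false-positive mode in
#' closely related graft partners.
#'
#' @param library_id library label.
#' @param resident_alignments alignment data frame vs the library's own
#'   genome covering every fragment of the library (unmapped rows
#'   included).
#' @param own_hits,foreign_hits hit data frames for the resident-unmapped
#'   fragments vs the own and partner genomes.
#' @param min_margin score margin a side must win by (default 0; ties are
#'   always ambiguous).
#' @param max_evalue,min_hit_length hit quality gate (defaults 1e-5, 50).
#' @return a `read_partition`: list with per-class fragment ids, the best
#'   resident alignment and best foreign/own hit per fragment, and counts.
#' @export
partition_reads <- function(library_id, resident_alignments,
                            own_hits = NULL, foreign_hits = NULL,
                            min_margin = 0, max_evalue = 1e-5,
                            min_hit_length = 50) {
  res <- resident_alignments
  res$frag_id <- fragment_id(res$read_id)
  mapped_frags <- unique(res$frag_id[res$mapped %in% TRUE])
  all_frags <- unique(res$frag_id)
  unmapped_frags <- setdiff(all_frags, mapped_frags)

  gate <- function(h, side) {
    if (is.null(h) || nrow(h) == 0L) {
      h <- empty_hit_df(); h$frag_id <- character(0); return(h)
    }
    h <- h[h$mapped %in% TRUE, , drop = FALSE]
    keep <- (is.na(h$evalue) | h$evalue <= max_evalue) &
      (!is.na(h$aligned_length) & h$aligned_length >= min_hit_length)
    h <- h[keep, , drop = FALSE]
    h$frag_id <- fragment_id(h$read_id)
    h
  }
  own <- gate(own_hits, "own")
  fgn <- gate(foreign_hits, "foreign")
  clash <- intersect(mapped_frags, unique(c(own$frag_id, fgn$frag_id)))
  if (length(clash) > 0L)
    stop("fragment(s) present both as resident-mapped and in hit lists ",
         "(two-pass contract violated), e.g. ", clash[1L])

  own_best <- best_per_fragment(own)
  fgn_best <- best_per_fragment(fgn)
  hit_frags <- union(own_best$frag_id, fgn_best$frag_id)
  unmapped_frags <- union(unmapped_frags, hit_frags)

  o <- stats::setNames(rep(-Inf, length(hit_frags)), hit_frags)
  o[own_best$frag_id] <- own_best$score
  f <- stats::setNames(rep(-Inf, length(hit_frags)), hit_frags)
  f[fgn_best$frag_id] <- fgn_best$score
  foreign_ids <- hit_frags[f - o > min_margin]
  own_ids <- hit_frags[o - f > min_margin]
  ambiguous <- setdiff(hit_frags, c(foreign_ids, own_ids))
  no_hit <- setdiff(unmapped_frags, hit_frags)

  resident_best <- best_per_fragment(
    res[res$mapped %in% TRUE, , drop = FALSE])
  structure(list(
    library_id = library_id,
    resident = resident_best,
    resident_frags = mapped_frags,
    unmapped_frags = unmapped_frags,
    foreign = fgn_best[fgn_best$frag_id %in% foreign_ids, , drop = FALSE],
    own = own_best[own_best$frag_id %in% own_ids, , drop = FALSE],
    ambiguous_frags = ambiguous,
    no_hit_frags = no_hit,
    params = list(min_margin = min_margin, max_evalue = max_evalue,
                  min_hit_length = min_hit_length,
                  tie_rule = "ambiguous fragments discarded")),
    class = "read_partition")
}

#' @rdname partition_reads
#' @param partition a `read_partition`.
#' @return `partition_summary()`: one-row data frame of per-class counts.
#' @export
partition_summary <- function(partition) {
  data.frame(library_id = partition$library_id,
             resident = length(partition$resident_frags),
             own = nrow(partition$own),
             foreign = nrow(partition$foreign),
             ambiguous = length(partition$ambiguous_frags),
             no_hit = length(partition$no_hit_frags),
             stringsAsFactors = FALSE)
}

#' Assign hit fragments to gene models
#'
#' Each fragment increments exactly one gene: the one whose exons overlap
#' the fragment's hit interval by the most bases (ties go to the
#' lexicographically smallest gene id and are counted in the output).
#' Fragments overlapping no exon are tallied as unassigned.
#'
#' @param hits data frame with `frag_id` (or `read_id`), `contig`, `pos`,
#'   `end` -- typically the `foreign` or `resident` slot of a
#'   [read_partition][partition_reads].
#' @param genes `gene_models` data frame on the same coordinates.
#' @return list with `counts` (named integer vector over all genes),
#'   `unassigned`, `n_ties` and the per-fragment `assignments` data frame.
#' @export
assign_fragments_to_genes <- function(hits, genes) {
  stopifnot(inherits(genes, "gene_models"))
  universe <- sort(unique(genes$gene_id), method = "radix")
  counts <- stats::setNames(integer(length(universe)), universe)
  if (is.null(hits$frag_id)) hits$frag_id <- fragment_id(hits$read_id)
  if (nrow(hits) == 0L)
    return(list(counts = counts, unassigned = 0L, n_ties = 0L,
                assignments = data.frame(frag_id = character(0),
                                         gene_id = character(0),
                                         overlap = integer(0))))
  if (anyDuplicated(hits$frag_id))
    hits <- best_per_fragment(hits)
  hg <- GenomicRanges::GRanges(hits$contig,
                               IRanges::IRanges(hits$pos, hits$end))
  eg <- exon_granges(genes)
  ov <- GenomicRanges::findOverlaps(hg, eg)
  n_ties <- 0L
  if (length(ov) == 0L) {
    assignments <- data.frame(frag_id = character(0),
                              gene_id = character(0), overlap = integer(0))
  } else {
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    w <- GenomicRanges::width(GenomicRanges::pintersect(hg[qh], eg[sh]))
    key <- paste(qh, eg$gene_id[sh], sep = "\r")
    tot <- rowsum(w, key)
    parts <- strsplit(rownames(tot), "\r", fixed = TRUE)
    cand <- data.frame(
      frag_idx = as.integer(vapply(parts, `[[`, character(1L), 1L)),
      gene_id = vapply(parts, `[[`, character(1L), 2L),
      overlap = as.integer(tot), stringsAsFactors = FALSE)
    cand <- cand[order(cand$frag_idx, -cand$overlap, cand$gene_id,
                       method = "radix"), , drop = FALSE]
    dup <- duplicated(cand$frag_idx)
    first <- cand[!dup, , drop = FALSE]
    # tie diagnostics: another gene with the same overlap for the fragment
    if (any(dup)) {
      alt <- cand[dup, , drop = FALSE]
      top <- stats::setNames(first$overlap, first$frag_idx)
      n_ties <- sum(!duplicated(alt$frag_idx) &
                      alt$overlap == top[as.character(alt$frag_idx)])
      if (n_ties > 0L)
        message(n_ties, " fragment(s) with tied gene overlap assigned to ",
                "the lexicographically smallest gene id")
    }
    assignments <- data.frame(frag_id = hits$frag_id[first$frag_idx],
                              gene_id = first$gene_id,
                              overlap = first$overlap,
                              stringsAsFactors = FALSE)
  }
  tab <- table(assignments$gene_id)
  counts[names(tab)] <- as.integer(tab)
  list(counts = counts,
       unassigned = nrow(hits) - nrow(assignments),
       n_ties = n_ties, assignments = assignments)
}
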