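#' Built-in k-mer seed-and-extend read matcher
#'
#' A desk-scale matcher so the pipeline runs without an external aligner:
#' exact k-mer seed lookup followed by ungapped extension on both strands.
#' A read is reported mapped at its best-scoring locus iff the mismatch
#' fraction is at most `max_mismatch_frac`; ties are broken
#' deterministically by (contig-id, position) in lexicographic contig
#' order, plus strand before minus. With `gapped = TRUE`, reads that fail
#' ungapped placement are additionally tested for a single internal indel
#' (up to `max_indel` bases) by anchoring exact k-mer seeds at both read
#' ends; this mode is used when aligning resequencing reads so that
#' genotype indels are recoverable from the pileup. It performs no spliced
#' or quality-aware alignment and is not a substitute for a production
#' aligner on real data.
#'
#' @param reads data frame with `read_id`, `seq` and optionally `qual`, or
#'   a named character vector, or a `DNAStringSet`.
#' @param genome genome `DNAStringSet`.
#' @param seed_len exact seed length (k-mer size, <= 31; default 31).
#' @param max_mismatch_frac maximum mismatch fraction for a mapped call
#'   (default 0.05).
#' @param gapped also attempt single-indel placement (default `FALSE`).
#' @param max_indel largest indel considered in gapped mode (default 10).
#' @return alignment data frame with one row per read: `read_id, mapped,
#'   contig, pos, end, strand, cigar, aligned_length, mismatches, score,
#'   seq, qual, evalue, source`. `seq`/`qual` are oriented to the forward
#'   genome strand for mapped reads. Score is the number of matching bases
#'   minus indel length.
#' @export
builtin_align <- function(reads, genome, seed_len = 31,
                          max_mismatch_frac = 0.05, gapped = FALSE,
                          max_indel = 10) {
  reads <- as_read_df(reads)
  idx <- if (inherits(genome, "genome_index")) genome
         else genome_index(genome, seed_len)
  qual <- reads$qual
  if (is.null(qual)) qual <- rep("", nrow(reads))
  qual[is.na(qual)] <- ""
  res <- .cpp_align(idx$ptr, as.character(reads$read_id),
                    as.character(reads$seq), as.character(qual),
                    max_mismatch_frac, isTRUE(gapped),
                    as.integer(max_indel))
  data.frame(read_id = res$read_id, mapped = res$mapped,
             contig = idx$contigs[res$contig_idx], pos = res$pos,
             end = res$pos + res$aligned_length - 1L,
             strand = res$strand, cigar = res$cigar,
             aligned_length = res$aligned_length,
             mismatches = res$mismatches, score = as.numeric(res$score),
             seq = res$seq, qual = res$qual, evalue = NA_real_,
             source = "builtin", stringsAsFactors = FALSE)
}

#' Prebuild a reusable seed index for a genome
#'
#' [builtin_align()] rebuilds its exact-k-mer index on every call; when
#' many libraries are matched against one genome, build the index once
#' and pass it in place of the genome.
#'
#' @param genome genome `DNAStringSet`.
#' @param seed_len k-mer size of the index (5-31; default 31).
#' @return a `genome_index` usable as the `genome` argument of
#'   [builtin_align()].
#' @export
genome_index <- function(genome, seed_len = 31) {
  if (seed_len > 31 || seed_len < 5)
    stop("seed_len must be in [5, 31]")
  g <- sort_contigs(genome)
  structure(list(ptr = .cpp_build_index(as.character(g),
                                        as.integer(seed_len)),
                 contigs = names(g), seed_len = as.integer(seed_len)),
            class = "genome_index")
}

as_read_df <- function(reads) {
  if (is.data.frame(reads)) {
    stopifnot(all(c("read_id", "seq") %in% names(reads)))
    return(reads)
  }
  if (methods::is(reads, "DNAStringSet"))
    return(data.frame(read_id = names(reads), seq = as.character(reads),
                      stringsAsFactors = FALSE))
  data.frame(read_id = if (is.null(names(reads)))
               sprintf("read_%06d", seq_along(reads)) else names(reads),
             seq = as.character(reads), stringsAsFactors = FALSE)
}

#' Read alignments or cross-genome hits from standard files
#'
#' Two dialects are supported: SAM (parsed through Rsamtools; unmapped
#' records, FLAG bit 0x4, yield `mapped = FALSE` rows) and the 12-column
#' BLAST tabular hit format (`qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore`). Subject coordinates of
#' tabular hits are normalized so `pos <= end` regardless of orientation.
#'
#' @param path input file.
#' @param dialect `"sam"` or `"tabular"`.
#' @param target optional genome identifier recorded on each record.
#' @return alignment data frame (columns as in [builtin_align()], plus
#'   `mate` for SAM input).
#' @export
read_alignments <- function(path, dialect = c("sam", "tabular"),
                            target = NA_character_) {
  dialect <- match.arg(dialect)
  if (dialect == "sam") read_sam_alignments(path, target)
  else read_tabular_hits(path, target)
}

read_sam_alignments <- function(path, target = NA_character_) {
  bam <- tryCatch(
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE),
    error = function(e) stop("malformed SAM file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  on.exit(unlink(bam))
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq", "qual",
             "mapq"),
    tag = c("AS", "NM"))
  x <- Rsamtools::scanBam(bam, param = p)[[1L]]
  n <- length(x$qname)
  if (n == 0L) {
    out <- empty_hit_df(target)
    return(out)
  }
  mapped <- !bitwAnd(x$flag, 4L)
  mate <- ifelse(bitwAnd(x$flag, 128L) > 0L, 2L, 1L)
  score <- as.numeric(x$tag$AS)
  if (all(is.na(score))) score <- as.numeric(x$mapq)
  nm <- as.integer(x$tag$NM)
  alen <- rep(NA_integer_, n)
  if (any(mapped))
    alen[mapped] <-
      GenomicAlignments::cigarWidthAlongReferenceSpace(x$cigar[mapped])
  data.frame(read_id = x$qname, mate = mate, mapped = mapped,
             contig = ifelse(mapped, as.character(x$rname), NA_character_),
             pos = ifelse(mapped, x$pos, NA_integer_),
             end = ifelse(mapped, x$pos + alen - 1L, NA_integer_),
             strand = ifelse(mapped,
                             ifelse(bitwAnd(x$flag, 16L) > 0L, "-", "+"),
                             NA_character_),
             cigar = ifelse(mapped, x$cigar, NA_character_),
             aligned_length = alen, mismatches = nm, score = score,
             seq = as.character(x$seq), qual = as.character(x$qual),
             evalue = NA_real_, source = "sam", target = target,
             stringsAsFactors = FALSE)
}

read_tabular_hits <- function(path, target = NA_character_) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  raw <- tryCatch(
    utils::read.delim(path, header = FALSE, comment.char = "#",
                      stringsAsFactors = FALSE),
    error = function(e) {
      lns <- tryCatch(readLines(path), error = function(e2) NULL)
      if (!is.null(lns) && all(grepl("^\\s*(#|$)", lns)))
        return(NULL)  # empty (or comment-only) file: no hits
      stop("cannot parse tabular hit file '", path, "': ",
           conditionMessage(e), call. = FALSE)
    })
  if (is.null(raw) || nrow(raw) == 0L)
    return(empty_hit_df(target))
  if (ncol(raw) != 12L)
    stop("tabular hit file '", path, "' has ", ncol(raw),
         " columns; expected the 12-column format (",
         paste(cols, collapse = " "), ")")
  names(raw) <- cols
  num <- c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
           "sstart", "send", "evalue", "bitscore")
  for (cn in num) {
    v <- suppressWarnings(as.numeric(raw[[cn]]))
    if (anyNA(v) && !anyNA(raw[[cn]]))
      stop("non-numeric value in column '", cn, "' of '", path,
           "' at line ", which(is.na(v))[1L])
    raw[[cn]] <- v
  }
  data.frame(read_id = as.character(raw$qseqid), mate = NA_integer_,
             mapped = TRUE, contig = as.character(raw$sseqid),
             pos = as.integer(pmin(raw$sstart, raw$send)),
             end = as.integer(pmax(raw$sstart, raw$send)),
             strand = ifelse(raw$send >= raw$sstart, "+", "-"),
             cigar = NA_character_,
             aligned_length = as.integer(raw$length),
             mismatches = as.integer(raw$mismatch), score = raw$bitscore,
             seq = NA_character_, qual = NA_character_,
             evalue = raw$evalue, source = "tabular-hit", target = target,
             stringsAsFactors = FALSE)
}

empty_hit_df <- function(target = NA_character_) {
  data.frame(read_id = character(0), mate = integer(0), mapped = logical(0),
             contig = character(0), pos = integer(0), end = integer(0),
             strand = character(0), cigar = character(0),
             aligned_length = integer(0), mismatches = integer(0),
             score = numeric(0), seq = character(0), qual = character(0),
             evalue = numeric(0), source = character(0),
             target = character(0), stringsAsFactors = FALSE)
}
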