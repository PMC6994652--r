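#' Build a sequence variant table
#'
#' Variants are plain data frames in left-anchored VCF style: indel alleles
#' carry one anchor base, so an insertion has `nchar(alt) > nchar(ref)` with
#' `ref` a prefix of length >= 1, and a deletion the reverse. `kind` is
#' derived from the alleles when not supplied.
#'
#' @param contig,pos,ref,alt vectors describing the variants (1-based).
#' @param depth,alt_support,quality read depth, reads supporting the
#'   alternate allele and a phred-like quality score.
#' @return data frame with columns `contig, pos, ref, alt, kind, depth,
#'   alt_support, zygosity, quality`.
#' @export
variant_table <- function(contig = character(0), pos = integer(0),
                          ref = character(0), alt = character(0),
                          depth = NA_integer_, alt_support = NA_integer_,
                          quality = NA_real_) {
  n <- length(pos)
  v <- data.frame(contig = as.character(contig), pos = as.integer(pos),
                  ref = toupper(as.character(ref)),
                  alt = toupper(as.character(alt)),
                  kind = character(n),
                  depth = rep_len(as.integer(depth), n),
                  alt_support = rep_len(as.integer(alt_support), n),
                  zygosity = rep(NA_real_, n),
                  quality = rep_len(as.numeric(quality), n),
                  stringsAsFactors = FALSE)
  v$kind <- ifelse(nchar(v$ref) == nchar(v$alt), "SNP",
                   ifelse(nchar(v$alt) > nchar(v$ref), "INS", "DEL"))
  v$zygosity <- ifelse(is.na(v$depth) | v$depth == 0L, NA_real_,
                       v$alt_support / v$depth)
  bad <- nchar(v$ref) == 0L | nchar(v$alt) == 0L | v$ref == v$alt
  if (any(bad)) stop("malformed variant allele(s) at row(s): ",
                     paste(which(bad), collapse = ", "))
  v
}

#' Call candidate variants from a read pileup
#'
#' Accumulates aligned bases column by column over the reference and emits
#' one candidate per (contig, position, alternate allele): SNPs from
#' mismatching bases, insertions/deletions from I/D CIGAR operations,
#' anchored VCF-style. Columns where every base matches the reference emit
#' nothing. Depth is the number of base observations covering the column,
#' zygosity the fraction supporting the alternate allele, and quality the
#' mean phred base quality of the supporting observations (defaulting to
#' `default_base_quality` when reads carry no qualities).
#'
#' @param alignments alignment data frame (see [builtin_align()] /
#'   [read_alignments()]); must contain `contig`, `pos`, `cigar`, `seq` and
#'   optionally `qual` and `mapped`.
#' @param reference genome `DNAStringSet` the alignments refer to.
#' @param default_base_quality phred value assumed for missing qualities.
#' @param indel_flank aligned bases a read must have on each side of an
#'   indel for the read to count toward the indel's depth and support
#'   (default 20). Reads with less flanking context cannot reliably
#'   report an indel -- the matcher may score the event as tail
#'   mismatches instead -- so counting them would deflate indel zygosity
#'   and sink true homozygous indels at the filter.
#' @return a variant data frame (see [variant_table()]).
#' @export
call_pileup_variants <- function(alignments, reference,
                                 default_base_quality = 30,
                                 indel_flank = 20) {
  aln <- alignments
  if (!is.null(aln$mapped)) aln <- aln[aln$mapped %in% TRUE, , drop = FALSE]
  refnames <- names(reference)
  if (nrow(aln) == 0L)
    return(variant_table())
  idx <- match(aln$contig, refnames)
  if (anyNA(idx))
    stop("alignment(s) to contig(s) absent from the reference: ",
         paste(unique(aln$contig[is.na(idx)]), collapse = ", "))
  widths <- Biostrings::width(reference)
  oob <- aln$pos < 1L | aln$pos > widths[idx]
  if (any(oob))
    stop("alignment position out of contig bounds at ",
         aln$contig[which(oob)[1L]], ":", aln$pos[which(oob)[1L]])
  qual <- aln$qual
  if (is.null(qual)) qual <- rep("", nrow(aln))
  qual[is.na(qual)] <- ""
  res <- .cpp_pileup(as.character(reference), as.integer(idx),
                     as.integer(aln$pos), as.character(aln$cigar),
                     as.character(aln$seq), as.character(qual),
                     as.integer(default_base_quality),
                     as.integer(indel_flank))
  v <- variant_table(contig = refnames[res$contig_idx], pos = res$pos,
                     ref = res$ref, alt = res$alt, depth = res$depth,
                     alt_support = res$alt_support, quality = res$quality)
  v
}

#' Filter candidate variants
#'
#' Retains candidates with `depth >= min_depth`, `zygosity >= min_zygosity`
#' (the operational reading of "homozygous") and `quality > min_quality`
#' (strict). Input order is preserved. Rows with `NA` in a filtered field
#' are dropped with a warning.
#'
#' @param candidates variant data frame.
#' @param min_depth minimum supporting read depth (default 6).
#' @param min_zygosity minimum alternate-allele fraction (default 0.9).
#' @param min_quality phred-like score that must be strictly exceeded
#'   (default 20).
#' @return filtered variant data frame.
#' @export
filter_variants <- function(candidates, min_depth = 6, min_zygosity = 0.9,
                            min_quality = 20) {
  if (nrow(candidates) == 0L) return(candidates)
  na <- is.na(candidates$depth) | is.na(candidates$zygosity) |
    is.na(candidates$quality)
  if (any(na)) {
    warning(sum(na), " candidate(s) with missing filter fields dropped")
    candidates <- candidates[!na, , drop = FALSE]
  }
  keep <- candidates$depth >= min_depth &
    candidates$zygosity >= min_zygosity &
    candidates$quality > min_quality
  candidates[keep, , drop = FALSE]
}

#' Left-align indel variants
#'
#' Normalizes variants to the left-most anchored representation: identical
#' trailing bases of ref and alt are trimmed (extending with the preceding
#' reference base when an allele would empty), then identical leading bases
#' beyond the anchor are trimmed. SNPs pass through unchanged. Needed to
#' compare call sets from different sources for the same edit.
#'
#' @param variants variant data frame.
#' @param reference genome providing sequence context.
#' @return normalized variant data frame.
#' @export
normalize_variants <- function(variants, reference) {
  if (nrow(variants) == 0L) return(variants)
  seqs <- as.character(reference)
  for (i in seq_len(nrow(variants))) {
    r <- variants$ref[i]; a <- variants$alt[i]
    if (nchar(r) == nchar(a)) next
    p <- variants$pos[i]
    s <- seqs[[variants$contig[i]]]
    repeat {
      nr <- nchar(r); na_ <- nchar(a)
      if (nr > 0L && na_ > 0L &&
          substr(r, nr, nr) == substr(a, na_, na_) &&
          (nr > 1L || na_ > 1L)) {
        if (nr == 1L || na_ == 1L) {
          if (p == 1L) break
          prev <- substr(s, p - 1L, p - 1L)
          r <- paste0(prev, substr(r, 1L, nr - 1L))
          a <- paste0(prev, substr(a, 1L, na_ - 1L))
          p <- p - 1L
        } else {
          r <- substr(r, 1L, nr - 1L)
          a <- substr(a, 1L, na_ - 1L)
        }
      } else break
    }
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, 1L, 1L) == substr(a, 1L, 1L) &&
           substr(r, 2L, 2L) == substr(a, 2L, 2L)) {
      r <- substr(r, 2L, nchar(r)); a <- substr(a, 2L, nchar(a))
      p <- p + 1L
    }
    variants$ref[i] <- r; variants$alt[i] <- a; variants$pos[i] <- p
  }
  variants
}

#' Incorporate variants into a reference genome
#'
#' Substitutes, inserts and deletes exactly as specified, returning the
#' modified genome together with a [coordinate map][lift_position] relating
#' original and modified positions. Reference alleles are validated against
#' the genome (mismatch is a hard error naming contig and position).
#' Overlapping variants are resolved first-come by coordinate: the later
#' one is skipped with a warning and reported in the rejects. Edits are
#' applied so that earlier coordinates never shift. The input genome is not
#' modified.
#'
#' @param reference genome `DNAStringSet`.
#' @param variants variant data frame (pre-filtered).
#' @return list with `genome` (role `"modified"`), `map` (`coordinate_map`),
#'   `applied` and `rejected` variant data frames.
#' @export
apply_variants <- function(reference, variants) {
  refnames <- names(reference)
  if (nrow(variants) > 0L) {
    unknown <- setdiff(unique(variants$contig), refnames)
    if (length(unknown) > 0L)
      stop("variants on contig(s) absent from the reference: ",
           paste(unknown, collapse = ", "))
  }
  seqs <- as.character(reference)
  widths <- nchar(seqs)
  names(widths) <- refnames

  anchors <- list(); deleted <- list(); inserted <- list()
  applied <- list(); rejected <- list()
  out <- seqs
  for (ct in refnames) {
    v <- variants[variants$contig == ct, , drop = FALSE]
    anchors[[ct]] <- data.frame(contig = ct, original_pos = 1L,
                                modified_pos = 1L, stringsAsFactors = FALSE)
    if (nrow(v) == 0L) next
    v <- v[order(v$pos, nchar(v$ref), v$alt, method = "radix"), , drop = FALSE]
    s <- seqs[[ct]]
    ends <- v$pos + nchar(v$ref) - 1L
    if (any(v$pos < 1L | ends > widths[[ct]]))
      stop("variant outside contig bounds on ", ct)
    obs <- substring(s, v$pos, ends)
    if (any(obs != v$ref)) {
      bad <- which(obs != v$ref)[1L]
      stop("reference allele mismatch at ", ct, ":", v$pos[bad],
           " (expected ", v$ref[bad], ", found ", obs[bad], ")")
    }
    keep <- logical(nrow(v)); prev_end <- 0L
    for (i in seq_len(nrow(v))) {
      if (v$pos[i] > prev_end) {
        keep[i] <- TRUE
        prev_end <- ends[i]
      }
    }
    if (any(!keep)) rejected[[ct]] <- v[!keep, , drop = FALSE]
    v <- v[keep, , drop = FALSE]
    ends <- ends[keep]
    applied[[ct]] <- v

    # splice: segments between variants + alt alleles
    seg_start <- c(1L, ends + 1L)
    seg_end <- c(v$pos - 1L, widths[[ct]])
    segs <- substring(s, seg_start, pmax(seg_end, seg_start - 1L))
    pieces <- character(2L * nrow(v) + 1L)
    pieces[seq(1L, length(pieces), by = 2L)] <- segs
    pieces[seq(2L, length(pieces), by = 2L)] <- v$alt
    out[[ct]] <- paste(pieces, collapse = "")

    rl <- nchar(v$ref); al <- nchar(v$alt)
    delta <- cumsum(al - rl)
    anchors[[ct]] <- rbind(anchors[[ct]],
                           data.frame(contig = ct,
                                      original_pos = ends + 1L,
                                      modified_pos = ends + 1L + delta,
                                      stringsAsFactors = FALSE))
    m <- pmin(rl, al)
    isdel <- rl > al
    if (any(isdel))
      deleted[[ct]] <- data.frame(contig = ct,
                                  start = v$pos[isdel] + m[isdel],
                                  end = v$pos[isdel] + rl[isdel] - 1L,
                                  stringsAsFactors = FALSE)
    isins <- al > rl
    if (any(isins)) {
      shift <- delta - (al - rl)  # cumulative delta before each variant
      inserted[[ct]] <- data.frame(contig = ct,
                                   start = v$pos[isins] + shift[isins] +
                                     m[isins],
                                   end = v$pos[isins] + shift[isins] +
                                     al[isins] - 1L,
                                   stringsAsFactors = FALSE)
    }
  }
  rejected <- do.call(rbind, unname(rejected))
  if (is.null(rejected)) rejected <- variant_table()
  if (nrow(rejected) > 0L)
    warning(nrow(rejected), " overlapping variant(s) skipped")
  applied <- do.call(rbind, unname(applied))
  if (is.null(applied)) applied <- variant_table()

  genome <- genome_sequence(out, name = S4Vectors::metadata(reference)$name,
                            role = "modified")
  map <- new_coordinate_map(
    anchors = do.call(rbind, unname(anchors)),
    deleted = if (length(deleted)) do.call(rbind, unname(deleted))
              else empty_interval_df(),
    inserted = if (length(inserted)) do.call(rbind, unname(inserted))
               else empty_interval_df(),
    original_length = as.list(widths),
    modified_length = stats::setNames(as.list(nchar(out)), refnames))
  list(genome = genome, map = map, applied = applied, rejected = rejected)
}

#' Assemble unmapped reads into extra scaffolds
#'
#' A minimal de Bruijn assembler: the k-mer set of the reads is compacted
#' into maximal non-branching paths (unitigs); unitigs shorter than
#' `min_scaffold_len` are discarded. Unitigs are reported in canonical
#' orientation, longest first, and the result is deterministic for
#' identical input. This is an interface stand-in for a full assembler:
#' scaffold quality is not the point, concatenating genotype-specific
#' sequence to the genome is.
#'
#' @param reads data frame with `seq`, character vector or `DNAStringSet`.
#' @param k k-mer size (odd, 5-31; default 31).
#' @param min_scaffold_len minimum unitig length to keep (default 200).
#' @param provenance genotype label recorded on the scaffold set.
#' @return a `scaffold_set`: list with `scaffolds` (genome with role
#'   `"scaffold-extra"`), `provenance` and `excluded_ids`.
#' @export
assemble_unmapped <- function(reads, k = 31, min_scaffold_len = 200,
                              provenance = "unknown") {
  seqs <- if (is.data.frame(reads)) reads$seq
          else if (methods::is(reads, "DNAStringSet")) as.character(reads)
          else as.character(reads)
  empty <- genome_sequence(stats::setNames(character(0), character(0)),
                           name = provenance, role = "scaffold-extra")
  if (length(seqs) == 0L)
    return(structure(list(scaffolds = empty, provenance = provenance,
                          excluded_ids = character(0)),
                     class = "scaffold_set"))
  if (max(nchar(seqs)) < k) {
    warning("k = ", k, " exceeds every read length; no scaffolds assembled")
    return(structure(list(scaffolds = empty, provenance = provenance,
                          excluded_ids = character(0)),
                     class = "scaffold_set"))
  }
  unitigs <- .cpp_assemble(seqs, as.integer(k), as.integer(min_scaffold_len))
  if (length(unitigs) == 0L) scaff <- empty
  else {
    names(unitigs) <- sprintf("scaffold_%04d", seq_along(unitigs))
    scaff <- genome_sequence(unitigs, name = provenance,
                             role = "scaffold-extra")
  }
  structure(list(scaffolds = scaff, provenance = provenance,
                 excluded_ids = character(0)),
            class = "scaffold_set")
}

#' Build an exclusion list from a contaminant hit table
#'
#' The contaminant screen is an exclusion-list interface: scaffolds are
#' searched against a contaminant database outside the package and the hit
#' table (BLAST tabular, outfmt 6) is handed back here. Any scaffold with a
#' hit at `evalue <= max_evalue` is excluded.
#'
#' @param hits hit table from [read_alignments()] with `dialect="tabular"`.
#' @param max_evalue e-value cutoff (default 1e-5).
#' @return character vector of scaffold ids to exclude.
#' @export
exclusion_ids_from_hits <- function(hits, max_evalue = 1e-5) {
  unique(hits$read_id[!is.na(hits$evalue) & hits$evalue <= max_evalue])
}

#' Build the modified reference genome
#'
#' Applies pre-filtered variants to the published reference and concatenates
#' the retained extra scaffolds (those not on the exclusion list). Scaffold
#' contigs keep their `scaffold_` ids and are recorded in the genome
#' metadata so downstream gene assignment can distinguish them.
#'
#' @param reference genome `DNAStringSet`.
#' @param variants pre-filtered variant data frame.
#' @param scaffolds optional `scaffold_set` from [assemble_unmapped()].
#' @param exclusion_ids scaffold ids to drop (contaminant screen).
#' @return list with `genome`, `map`, `applied`, `rejected`, `scaffold_ids`.
#' @export
build_modified_reference <- function(reference, variants,
                                     scaffolds = NULL,
                                     exclusion_ids = character(0)) {
  av <- apply_variants(reference, variants)
  genome <- av$genome
  kept <- character(0)
  if (!is.null(scaffolds) && length(scaffolds$scaffolds) > 0L) {
    sc <- scaffolds$scaffolds
    sc <- sc[!names(sc) %in% exclusion_ids]
    clash <- intersect(names(sc), names(genome))
    if (length(clash) > 0L)
      stop("scaffold id(s) collide with contig id(s): ",
           paste(clash, collapse = ", "))
    if (length(sc) > 0L) {
      kept <- names(sc)
      meta <- S4Vectors::metadata(genome)
      genome <- c(genome, sc)
      S4Vectors::metadata(genome) <- meta
    }
  }
  meta <- S4Vectors::metadata(genome)
  meta$role <- "modified"
  meta$scaffold_ids <- kept
  S4Vectors::metadata(genome) <- meta
  list(genome = genome, map = av$map, applied = av$applied,
       rejected = av$rejected, scaffold_ids = kept)
}

#' Write a variant table as TSV
#' @param variants variant data frame.
#' @param path output file.
#' @export
write_variant_table <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read variants from a VCF file
#'
#' Optional entry point for variants called outside the package. The VCF
#' `QUAL` column is used directly as the variant quality; depth is taken
#' from `INFO/DP` when present. Requires the VariantAnnotation package.
#'
#' @param path VCF 4.x file.
#' @param zygosity assumed alternate-allele fraction when the file carries
#'   no genotype information (default 1: pre-filtered homozygous calls).
#' @return variant data frame.
#' @export
read_variants_vcf <- function(path, zygosity = 1) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_variants_vcf() requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- as.character(unlist(rr$ALT))
  dp <- tryCatch(VariantAnnotation::info(vcf)$DP,
                 error = function(e) NULL)
  n <- length(rr)
  if (is.null(dp)) dp <- rep(NA_integer_, n)
  v <- variant_table(contig = as.character(GenomicRanges::seqnames(rr)),
                     pos = GenomicRanges::start(rr),
                     ref = as.character(rr$REF), alt = alt,
                     depth = dp,
                     alt_support = as.integer(round(dp * zygosity)),
                     quality = as.numeric(rr$QUAL))
  v$zygosity[is.na(v$zygosity)] <- zygosity
  v
}
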