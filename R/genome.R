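#' Construct a genome sequence set
#'
#' A genome is stored as a [Biostrings::DNAStringSet] with a `name` and a
#' `role` kept in its metadata. Roles distinguish published references
#' (`"reference"`), genotype-corrected genomes (`"modified"`) and extra
#' scaffolds assembled from genotype-specific reads (`"scaffold-extra"`).
#'
#' @param contigs named character vector or `DNAStringSet`; contig ids must
#'   be unique, sequences non-empty and restricted to the A/C/G/T/N alphabet.
#' @param name genome label (e.g. the genotype).
#' @param role one of `"reference"`, `"modified"`, `"scaffold-extra"`.
#' @return a `DNAStringSet` with `name` and `role` metadata.
#' @export
genome_sequence <- function(contigs, name = "genome",
                            role = c("reference", "modified",
                                     "scaffold-extra")) {
  role <- match.arg(role)
  x <- if (methods::is(contigs, "DNAStringSet")) contigs
       else Biostrings::DNAStringSet(contigs)
  ids <- names(x)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("every contig must be named")
  if (anyDuplicated(ids))
    stop("duplicate contig ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(Biostrings::width(x) == 0L))
    stop("zero-length contig(s): ",
         paste(ids[Biostrings::width(x) == 0L], collapse = ", "))
  af <- Biostrings::alphabetFrequency(x)
  bad <- rowSums(af) - rowSums(af[, c("A", "C", "G", "T", "N"), drop = FALSE])
  if (any(bad > 0))
    stop("contig(s) with bases outside {A,C,G,T,N}: ",
         paste(ids[bad > 0], collapse = ", "))
  S4Vectors::metadata(x) <- list(name = name, role = role)
  x
}

#' @rdname genome_sequence
#' @param x a genome built by [genome_sequence()] or read from FASTA.
#' @export
genome_role <- function(x) {
  role <- S4Vectors::metadata(x)$role
  if (is.null(role)) "reference" else role
}

#' Read / write genome FASTA
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] and
#' [Biostrings::writeXStringSet()] that attach/keep the genome role and
#' write 60-column FASTA.
#'
#' @param path FASTA file path.
#' @param name,role see [genome_sequence()].
#' @return `read_genome_fasta()`: a genome `DNAStringSet`.
#' @export
read_genome_fasta <- function(path, name = basename(path),
                              role = "reference") {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  genome_sequence(x, name = name, role = role)
}

#' @rdname read_genome_fasta
#' @param genome genome to write.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 60L)
  invisible(path)
}

#' Read / write FASTQ reads
#'
#' Reads are handled as a plain data frame with columns `read_id`, `seq`
#' and `qual` (phred+33). [Biostrings::readDNAStringSet()] does the parsing.
#'
#' @param path FASTQ file path.
#' @return `read_fastq()`: data frame with `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(read_id = sub("\\s.*$", "", names(x)),
             seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}

#' @rdname read_fastq
#' @param reads data frame with `read_id`, `seq` and optionally `qual`.
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$qual
  if (is.null(qual)) qual <- strrep("I", nchar(reads$seq))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste0("@", reads$read_id, "\n", reads$seq, "\n+\n", qual),
             con, sep = "\n")
  invisible(path)
}

# contigs sorted lexicographically (C locale) -- the deterministic order the
# aligner's tie-break contract is defined over
sort_contigs <- function(genome) {
  ord <- order(names(genome), method = "radix")
  genome[ord]
}
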