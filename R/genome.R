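#' Genome assembly container
#'
#' A named list of contig sequences (alphabet ACGTN, upper-cased on input)
#' with unique names.
#'
#' @param contigs named character vector or list of DNA strings.
#' @return an object of class `genome_assembly` with elements `contigs`
#'   (named character vector) and `total_length`.
#' @export
#' @examples
#' genome_assembly(c(chr1 = "ACGTACGTAA"))
genome_assembly <- function(contigs) {
  contigs <- unlist(contigs)
  stopifnot(is.character(contigs), length(contigs) > 0)
  if (is.null(names(contigs)) || anyDuplicated(names(contigs)) ||
      any(!nzchar(names(contigs))))
    stop("contigs must have unique non-empty names", call. = FALSE)
  if (any(!nzchar(contigs))) stop("contig sequences must be non-empty",
                                  call. = FALSE)
  contigs <- toupper(contigs)
  .check_dna(contigs, allow_n = TRUE, what = "contig sequence")
  structure(list(contigs = contigs,
                 total_length = sum(nchar(contigs))),
            class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf("genome_assembly: %d contig(s), %d bp total\n",
              length(x$contigs), x$total_length))
  invisible(x)
}

#' Read a genome from FASTA
#'
#' @param path FASTA file (multi-contig, wrapped or unwrapped).
#' @return a [genome_assembly()].
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ## drop description after first whitespace, as aligners do
  nm <- sub("\\s.*$", "", names(ss))
  genome_assembly(setNames(as.character(ss), nm))
}

#' Write a genome (or any named sequence set) to FASTA
#'
#' Sequences are wrapped at 80 columns.
#'
#' @param seqs named character vector of sequences, or a [genome_assembly()].
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "genome_assembly")) seqs <- seqs$contigs
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

## Extract [start, end) (0-based half-open) from one contig, with bounds check.
.get_subseq <- function(genome, contig, start, end) {
  if (!contig %in% names(genome$contigs))
    stop("contig '", contig, "' not in genome", call. = FALSE)
  len <- nchar(genome$contigs[[contig]])
  if (start < 0 || end > len || start >= end)
    stop(sprintf("interval [%d,%d) outside contig '%s' (length %d)",
                 start, end, contig, len), call. = FALSE)
  substring(genome$contigs[[contig]], start + 1L, end)
}
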