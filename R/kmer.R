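## k-mer uniqueness screening: probes are required to be "genomically unique"
## at the resolution of their constituent k-mers.

#' Build a double-stranded k-mer occurrence index
#'
#' Counts every k-mer on both strands of every contig. k-mers containing N are
#' not indexed. Because both strands are indexed, looking up a k-mer directly
#' returns its total occurrence count across the double-stranded genome, and
#' `count(x) == count(revcomp(x))` by construction.
#'
#' @param genome a [genome_assembly()].
#' @param k k-mer size in bases, >= 8.
#' @return an object of class `kmer_index`.
#' @export
#' @examples
#' idx <- build_uniqueness_index(genome_assembly(c(c1 = "ACGTACGT")), k = 8)
#' kmer_count(idx, "ACGTACGT")
build_uniqueness_index <- function(genome, k) {
  stopifnot(inherits(genome, "genome_assembly"))
  k <- as.integer(k)
  if (k < 8L) stop("k must be >= 8", call. = FALSE)
  if (k > max(nchar(genome$contigs)))
    stop("k exceeds the longest contig", call. = FALSE)
  kmers <- character(0)
  for (seq in genome$contigs) {
    n <- nchar(seq)
    if (n < k) next
    fwd <- substring(seq, 1:(n - k + 1L), k:n)
    kmers <- c(kmers, fwd, revcomp(fwd))
  }
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  counts <- table(kmers)
  counts <- setNames(as.integer(counts), names(counts))
  ## hashed environment for O(1) lookup
  env <- new.env(hash = TRUE, size = max(29L, length(counts)))
  for (i in seq_along(counts)) assign(names(counts)[i], counts[[i]], env)
  structure(list(k = k, counts = counts, env = env), class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("kmer_index: k=%d, %d distinct k-mers\n",
              x$k, length(x$counts)))
  invisible(x)
}

#' Total genomic occurrence count of k-mers
#'
#' @param index a `kmer_index` from [build_uniqueness_index()].
#' @param kmers character vector of k-mers (length k each).
#' @return integer vector of counts across both strands (0 for absent k-mers).
#' @export
kmer_count <- function(index, kmers) {
  stopifnot(inherits(index, "kmer_index"))
  if (length(kmers) == 0L) return(integer(0))
  if (any(nchar(kmers) != index$k))
    stop("query k-mers must have length k = ", index$k, call. = FALSE)
  vapply(toupper(kmers), function(km) {
    v <- get0(km, envir = index$env, inherits = FALSE)
    if (is.null(v)) 0L else v
  }, integer(1), USE.NAMES = FALSE)
}

## Max occurrence count over all constituent k-mers of each window sequence,
## batched into a single lookup pass. Windows containing N report NA
## (callers reject those windows anyway).
.max_kmer_hits <- function(index, seqs) {
  k <- index$k
  n <- nchar(seqs)
  if (any(n < k)) stop("window shorter than uniqueness k", call. = FALSE)
  per <- n - k + 1L
  all_km <- unlist(lapply(seqs, function(s)
    substring(s, 1:(nchar(s) - k + 1L), k:nchar(s))), use.names = FALSE)
  cnt <- kmer_count(index, all_km)
  cnt[grepl("N", all_km, fixed = TRUE)] <- NA_integer_
  grp <- rep.int(seq_along(seqs), per)
  as.integer(vapply(split(cnt, grp), function(x)
    if (anyNA(x)) NA_integer_ else max(x), integer(1), USE.NAMES = FALSE))
}
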