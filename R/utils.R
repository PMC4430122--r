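## Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] for plain
#' character vectors (alphabet ACGTN).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTT")
revcomp <- function(x) {
  stopifnot(is.character(x))
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Fast scalar check used in hot loops; avoids DNAStringSet overhead.
.revcomp1 <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

.check_dna <- function(x, allow_n = FALSE, what = "sequence") {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop(sprintf("invalid %s: characters outside %s in %s", what,
                 if (allow_n) "ACGTN" else "ACGT",
                 paste(head(x[bad], 3), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

.gc_percent <- function(seqs) {
  n <- nchar(seqs)
  gc <- n - nchar(gsub("[GC]", "", seqs))
  100 * gc / n
}

## 0-based half-open interval overlap.
.overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

## Parse "chr:start-end" (1-based inclusive, as on the command line) into a
## 0-based half-open interval list(contig, start, end).
parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", region))[[1]]
  if (length(m) != 4L) stop("cannot parse region '", region,
                            "'; expected contig:start-end", call. = FALSE)
  start <- as.numeric(gsub(",", "", m[3])) - 1
  end <- as.numeric(gsub(",", "", m[4]))
  if (start < 0 || end <= start) stop("bad region bounds in '", region, "'",
                                      call. = FALSE)
  list(contig = m[2], start = start, end = end)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
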