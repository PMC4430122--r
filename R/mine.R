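#' Probe mining parameters
#'
#' Filter settings for candidate probe discovery. Defaults follow a widely
#' used 42-mer Oligopaint design: Tm 85-99 degC, GC 35-80%, homopolymer/
#' G-quartet motifs excluded, and a 16-mer uniqueness screen requiring every
#' constituent k-mer to occur at most once in the double-stranded genome.
#'
#' @param probe_length probe length in bases (common choices 32, 36, 42).
#' @param tm_min,tm_max melting-temperature bounds, degC.
#' @param gc_min,gc_max GC-content bounds, percent.
#' @param forbidden_motifs character vector of disallowed subsequences.
#' @param min_spacing minimum start-to-start distance (bases) between accepted
#'   probes; for equal-length probes this equals the centre-to-centre spacing.
#' @param max_probes_per_target maximum accepted probes per target
#'   (`Inf` = unlimited).
#' @param uniqueness_k k-mer size for the genomic uniqueness screen.
#' @param uniqueness_max_hits maximum allowed double-stranded genome
#'   occurrences for any constituent k-mer.
#' @return an object of class `mining_params`.
#' @export
mining_params <- function(probe_length = 42L,
                          tm_min = 85, tm_max = 99,
                          gc_min = 35, gc_max = 80,
                          forbidden_motifs = c("GGGG", "CCCC", "TTTTT", "AAAAA"),
                          min_spacing = 0L,
                          max_probes_per_target = Inf,
                          uniqueness_k = 16L,
                          uniqueness_max_hits = 1L) {
  probe_length <- as.integer(probe_length)
  uniqueness_k <- as.integer(uniqueness_k)
  stopifnot(tm_min <= tm_max, gc_min <= gc_max,
            probe_length >= uniqueness_k, uniqueness_k >= 8L,
            min_spacing >= 0, max_probes_per_target >= 0,
            uniqueness_max_hits >= 1)
  if (length(forbidden_motifs)) {
    forbidden_motifs <- toupper(forbidden_motifs)
    .check_dna(forbidden_motifs, what = "forbidden motif")
  }
  structure(list(probe_length = probe_length,
                 tm_min = tm_min, tm_max = tm_max,
                 gc_min = gc_min, gc_max = gc_max,
                 forbidden_motifs = forbidden_motifs,
                 min_spacing = as.integer(min_spacing),
                 max_probes_per_target = max_probes_per_target,
                 uniqueness_k = uniqueness_k,
                 uniqueness_max_hits = as.integer(uniqueness_max_hits)),
            class = "mining_params")
}

#' @export
print.mining_params <- function(x, ...) {
  cat(sprintf(paste0("mining_params: L=%d, Tm [%g,%g] degC, GC [%g,%g]%%, ",
                     "%d motif(s), spacing %d, cap %s, k=%d (max hits %d)\n"),
              x$probe_length, x$tm_min, x$tm_max, x$gc_min, x$gc_max,
              length(x$forbidden_motifs), x$min_spacing,
              if (is.finite(x$max_probes_per_target))
                format(x$max_probes_per_target) else "unlimited",
              x$uniqueness_k, x$uniqueness_max_hits))
  invisible(x)
}

.empty_candidates <- function() {
  data.frame(contig = character(0), start = integer(0), end = integer(0),
              strand = character(0), sequence = character(0),
              tm = numeric(0), gc = numeric(0), stringsAsFactors = FALSE)
}

.as_target <- function(target) {
  if (is.character(target)) target <- parse_region(target)
  stopifnot(is.list(target), !is.null(target$contig),
            !is.null(target$start), !is.null(target$end))
  target
}

## Core window filter shared by mine_candidates, HOP discovery and
## interstitial design. Applies every per-window predicate but NOT the greedy
## spacing/cap, and returns all passing windows sorted by start.
##
## require_overlap: 0-based positions; a window must contain at least one.
## exclude_points:  0-based positions; a window must contain none.
## exclude_intervals: data.frame(start, end), 0-based half-open; no overlap.
.filter_windows <- function(genome, contig, start, end, params, conditions,
                            index, require_overlap = NULL,
                            exclude_points = NULL, exclude_intervals = NULL) {
  L <- params$probe_length
  if (!contig %in% names(genome$contigs))
    stop("contig '", contig, "' not in genome", call. = FALSE)
  contig_seq <- genome$contigs[[contig]]
  clen <- nchar(contig_seq)
  if (start < 0 || end > clen || start > end)
    stop(sprintf("target [%s,%s) outside contig '%s'",
                 format(start), format(end), contig), call. = FALSE)
  if (end - start < L) return(.empty_candidates())

  starts <- start:(end - L)
  keep <- rep(TRUE, length(starts))

  if (!is.null(require_overlap)) {
    if (length(require_overlap) == 0L) return(.empty_candidates())
    hit <- rep(FALSE, length(starts))
    for (p in require_overlap) hit <- hit | (starts <= p & p < starts + L)
    keep <- keep & hit
  }
  if (!is.null(exclude_points) && length(exclude_points)) {
    for (p in exclude_points) keep <- keep & !(starts <= p & p < starts + L)
  }
  if (!is.null(exclude_intervals) && nrow(exclude_intervals)) {
    for (i in seq_len(nrow(exclude_intervals))) {
      keep <- keep & !.overlaps(starts, starts + L,
                                exclude_intervals$start[i],
                                exclude_intervals$end[i])
    }
  }
  if (!any(keep)) return(.empty_candidates())
  starts <- starts[keep]
  seqs <- substring(contig_seq, starts + 1L, starts + L)

  ok <- !grepl("N", seqs, fixed = TRUE)
  gc <- .gc_percent(seqs)
  ok <- ok & gc >= params$gc_min & gc <= params$gc_max
  for (m in params$forbidden_motifs) ok <- ok & !grepl(m, seqs, fixed = TRUE)
  if (!any(ok)) return(.empty_candidates())

  starts <- starts[ok]; seqs <- seqs[ok]; gc <- gc[ok]
  tm <- tm_nearest_neighbor(seqs, conditions)
  ok <- tm >= params$tm_min & tm <= params$tm_max
  if (!is.null(index) && any(ok)) {
    hits <- rep(NA_integer_, length(seqs))
    hits[ok] <- .max_kmer_hits(index, seqs[ok])
    ok <- ok & !is.na(hits) & hits <= params$uniqueness_max_hits
  }
  if (!any(ok)) return(.empty_candidates())

  out <- data.frame(contig = contig, start = starts[ok],
                    end = starts[ok] + L, strand = "+",
                    sequence = seqs[ok], tm = tm[ok], gc = gc[ok],
                    stringsAsFactors = FALSE)
  out[order(out$start), , drop = FALSE]
}

## Greedy left-to-right spacing selection: keep the first passing window, then
## every subsequent window whose start is >= min_spacing from the last kept.
.greedy_spacing <- function(cands, min_spacing, max_probes) {
  if (nrow(cands) == 0L || max_probes == 0) return(.empty_candidates())
  cands <- cands[order(cands$start), , drop = FALSE]
  keep <- logical(nrow(cands))
  last <- -Inf
  n_kept <- 0
  for (i in seq_len(nrow(cands))) {
    if (cands$start[i] - last >= min_spacing) {
      keep[i] <- TRUE
      last <- cands$start[i]
      n_kept <- n_kept + 1
      if (n_kept >= max_probes) break
    }
  }
  out <- cands[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mine candidate Oligopaint probes from a genomic interval
#'
#' Scans every window of `params$probe_length` within the target, applies the
#' composition (GC), melting-temperature, forbidden-motif and k-mer
#' uniqueness filters, rejects windows containing N, then selects accepted
#' probes greedily left-to-right under the minimum spacing and per-target cap.
#' Candidates are reported on the plus strand in start order. The module is
#' fully deterministic.
#'
#' @param genome a [genome_assembly()].
#' @param target interval as `list(contig, start, end)` (0-based half-open)
#'   or a `"contig:start-end"` string (1-based inclusive).
#' @param params a [mining_params()].
#' @param conditions a [thermo_conditions()].
#' @param index a `kmer_index` over `genome` (or `NULL` to skip the
#'   uniqueness screen).
#' @return data.frame with columns contig, start, end, strand, sequence,
#'   tm, gc.
#' @export
#' @examples
#' g <- synth_genome(synthetic_genome_spec(contig_length = 5000, seed = 1))$genome
#' idx <- build_uniqueness_index(g, 16)
#' p <- mining_params(tm_min = 0, tm_max = 200)
#' head(mine_candidates(g, list(contig = "contig1", start = 0, end = 5000),
#'                      p, thermo_conditions(), idx))
mine_candidates <- function(genome, target, params,
                            conditions = thermo_conditions(), index = NULL) {
  stopifnot(inherits(genome, "genome_assembly"),
            inherits(params, "mining_params"))
  target <- .as_target(target)
  cands <- .filter_windows(genome, target$contig, target$start, target$end,
                           params, conditions, index)
  .greedy_spacing(cands, params$min_spacing, params$max_probes_per_target)
}
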