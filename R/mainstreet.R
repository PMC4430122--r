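## MainStreet architecture: assembly of synthesis-ready oligos (secondary /
## DNA-PAINT docking sites + primers + genomic insert) and orthogonality
## screening of secondary oligos.

#' Primer pair
#'
#' @param forward,reverse primer sequences, 5'->3', alphabet ACGT.
#' @param label pair name.
#' @return an object of class `primer_pair`.
#' @export
primer_pair <- function(forward, reverse, label = "primer") {
  forward <- toupper(forward); reverse <- toupper(reverse)
  stopifnot(nzchar(forward), nzchar(reverse))
  .check_dna(c(forward, reverse), what = "primer")
  structure(list(forward = forward, reverse = reverse, label = label),
            class = "primer_pair")
}

#' Secondary oligo binding site
#'
#' Classic fluorophore-bearing secondary oligos bind 32-base sites; DNA-PAINT
#' docking strands use 9-base sites so the imager duplex is transient at room
#' temperature. Other lengths are allowed with a warning.
#'
#' @param id site name.
#' @param sequence site sequence, ACGT.
#' @param kind `"secondary"` (default length 32) or `"paint_docking"`
#'   (default length 9).
#' @return an object of class `secondary_site`.
#' @export
secondary_site <- function(id, sequence,
                           kind = c("secondary", "paint_docking")) {
  kind <- match.arg(kind)
  sequence <- toupper(sequence)
  .check_dna(sequence, what = "secondary site")
  expected <- if (kind == "secondary") 32L else 9L
  if (nchar(sequence) != expected)
    warning(sprintf("site '%s' has length %d; the conventional %s length is %d",
                    id, nchar(sequence), kind, expected), call. = FALSE)
  structure(list(id = id, sequence = sequence, kind = kind),
            class = "secondary_site")
}

#' Assemble a synthesis-ready Oligopaint oligo
#'
#' Concatenates, 5'->3': optional secondary/docking sites, the forward
#' primer, the genomic insert, and the reverse complement of the reverse
#' primer (so the synthesised strand is amplifiable by the primer pair).
#' `placement` controls where the sites go: 5' of the forward primer
#' (the canonical MainStreet layout), internal to either primer, or split
#' across both ends (first half 5', remainder 3').
#'
#' @param genomic genomic insert sequence (non-empty, ACGT).
#' @param primers a [primer_pair()].
#' @param sites list of [secondary_site()] (possibly empty).
#' @param placement one of `"five_prime_of_forward"`, `"internal_5p"`,
#'   `"internal_3p"`, `"both_ends"`.
#' @return an object of class `full_oligo`: list with `parts` (data.frame of
#'   role, sequence) and `full_sequence`.
#' @export
#' @examples
#' p <- primer_pair("ACTGACTGACTGACTGACTG", "GTCAGTCAGTCAGTCAGTCA")
#' o <- assemble_full_oligo(strrep("ACGT", 10), p, list())
#' nchar(o$full_sequence)
assemble_full_oligo <- function(genomic, primers, sites = list(),
                                placement = c("five_prime_of_forward",
                                              "internal_5p", "internal_3p",
                                              "both_ends")) {
  placement <- match.arg(placement)
  stopifnot(inherits(primers, "primer_pair"))
  genomic <- toupper(genomic)
  if (!nzchar(genomic)) stop("empty genomic insert", call. = FALSE)
  .check_dna(genomic, what = "genomic insert")
  site_seq <- vapply(sites, function(s) s$sequence, character(1))
  site_part <- function(seqs) {
    if (length(seqs) == 0L) return(NULL)
    data.frame(role = "secondary_site", sequence = seqs,
               stringsAsFactors = FALSE)
  }
  fwd <- data.frame(role = "forward_primer", sequence = primers$forward,
                    stringsAsFactors = FALSE)
  gen <- data.frame(role = "genomic", sequence = genomic,
                    stringsAsFactors = FALSE)
  rev_rc <- data.frame(role = "reverse_primer_rc",
                       sequence = revcomp(primers$reverse),
                       stringsAsFactors = FALSE)
  parts <- switch(placement,
    five_prime_of_forward = rbind(site_part(site_seq), fwd, gen, rev_rc),
    internal_5p = rbind(fwd, site_part(site_seq), gen, rev_rc),
    internal_3p = rbind(fwd, gen, site_part(site_seq), rev_rc),
    both_ends = {
      n5 <- ceiling(length(site_seq) / 2)
      rbind(site_part(site_seq[seq_len(n5)]), fwd, gen, rev_rc,
            site_part(site_seq[setdiff(seq_along(site_seq), seq_len(n5))]))
    })
  rownames(parts) <- NULL
  structure(list(parts = parts,
                 full_sequence = paste(parts$sequence, collapse = "")),
            class = "full_oligo")
}

#' Extract the genomic insert from an assembled oligo
#' @param oligo a `full_oligo`.
#' @return the genomic insert sequence.
#' @export
genomic_insert <- function(oligo) {
  stopifnot(inherits(oligo, "full_oligo"))
  oligo$parts$sequence[oligo$parts$role == "genomic"]
}

#' @export
print.full_oligo <- function(x, ...) {
  cat(sprintf("full_oligo (%d nt): %s\n", nchar(x$full_sequence),
              paste(x$parts$role, collapse = " | ")))
  invisible(x)
}

#' Longest common substring length between two DNA sequences
#'
#' Exact longest shared substring, optionally considering both strands of the
#' first sequence (the relevant question for hybridization cross-talk).
#' Binary search over match lengths with fixed-string lookup.
#'
#' @param a,b DNA strings.
#' @param both_strands also compare the reverse complement of `a` against `b`.
#' @return length in bases of the longest exact match.
#' @export
longest_common_substring <- function(a, b, both_strands = TRUE) {
  if (!nzchar(a) || !nzchar(b)) return(0L)
  one <- function(a, b) {
    na <- nchar(a)
    has_match <- function(L) {
      subs <- unique(substring(a, 1:(na - L + 1L), L:na))
      for (s in subs) if (grepl(s, b, fixed = TRUE)) return(TRUE)
      FALSE
    }
    lo <- 0L; hi <- min(na, nchar(b))
    while (lo < hi) {
      mid <- as.integer(ceiling((lo + hi) / 2))
      if (has_match(mid)) lo <- mid else hi <- mid - 1L
    }
    lo
  }
  res <- one(a, b)
  if (both_strands) res <- max(res, one(.revcomp1(a), b))
  res
}

#' Screen secondary oligo sites for mutual and genomic orthogonality
#'
#' Computes, for every site, the longest exact substring match (either
#' strand) against every other site, against each probe genomic insert and
#' against the genome. The screen passes iff every such match is shorter than
#' `lcs_threshold`.
#'
#' @param sites list of [secondary_site()].
#' @param probe_sequences character vector of probe genomic inserts
#'   (may be empty).
#' @param genome a [genome_assembly()] or NULL.
#' @param lcs_threshold minimum match length (bases, >= 8) that counts as a
#'   cross-hybridization risk.
#' @return an object of class `orthogonality_report`: list with `matrix`
#'   (site-by-site LCS lengths, NA diagonal), `vs_probes`, `vs_genome`
#'   (per-site maxima, NA when absent), `worst_offender` and `pass`.
#' @export
check_orthogonality <- function(sites, probe_sequences = character(0),
                                genome = NULL, lcs_threshold = 12L) {
  stopifnot(lcs_threshold >= 8)
  ids <- vapply(sites, function(s) s$id, character(1))
  seqs <- vapply(sites, function(s) s$sequence, character(1))
  ns <- length(sites)
  m <- matrix(NA_integer_, ns, ns, dimnames = list(ids, ids))
  if (ns >= 2) {
    for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
      l <- longest_common_substring(seqs[i], seqs[j])
      m[i, j] <- l; m[j, i] <- l
    }
  }
  vs_probes <- if (length(probe_sequences))
    vapply(seqs, function(s)
      max(vapply(probe_sequences, longest_common_substring, integer(1), a = s)),
      integer(1))
  else setNames(rep(NA_integer_, ns), ids)
  vs_genome <- if (!is.null(genome) && genome$total_length > 0)
    vapply(seqs, function(s)
      max(vapply(genome$contigs, longest_common_substring, integer(1), a = s)),
      integer(1))
  else setNames(rep(NA_integer_, ns), ids)
  names(vs_probes) <- ids; names(vs_genome) <- ids

  all_vals <- c(m[upper.tri(m)], vs_probes, vs_genome)
  worst_len <- suppressWarnings(max(all_vals, na.rm = TRUE))
  if (!is.finite(worst_len)) worst_len <- 0L
  worst <- list(ids = character(0), length = worst_len)
  if (ns >= 2 && any(!is.na(m) & m == worst_len)) {
    ij <- which(m == worst_len, arr.ind = TRUE)[1, ]
    worst$ids <- ids[ij]
  } else if (any(!is.na(vs_probes) & vs_probes == worst_len)) {
    worst$ids <- c(ids[which(vs_probes == worst_len)[1]], "<probes>")
  } else if (any(!is.na(vs_genome) & vs_genome == worst_len)) {
    worst$ids <- c(ids[which(vs_genome == worst_len)[1]], "<genome>")
  }
  pass <- worst_len < lcs_threshold
  structure(list(matrix = m, vs_probes = vs_probes, vs_genome = vs_genome,
                 worst_offender = worst, threshold = lcs_threshold,
                 pass = pass),
            class = "orthogonality_report")
}

#' @export
print.orthogonality_report <- function(x, ...) {
  cat(sprintf("orthogonality_report: %s (worst match %d nt%s, threshold %d)\n",
              if (x$pass) "PASS" else "FAIL", x$worst_offender$length,
              if (length(x$worst_offender$ids))
                paste0(": ", paste(x$worst_offender$ids, collapse = " vs "))
              else "", x$threshold))
  invisible(x)
}

#' Greedily select mutually orthogonal secondary oligos
#'
#' Walks the pool in order and keeps each site whose predicted perfect-duplex
#' melting temperature lies inside `tm_window` and whose longest
#' common substring (either strand) with every already-selected site is below
#' `lcs_threshold`, until `n` sites are selected.
#'
#' @param pool list of [secondary_site()].
#' @param n number of sites required.
#' @param conditions a [thermo_conditions()].
#' @param tm_window numeric length-2, degC.
#' @param lcs_threshold orthogonality threshold in bases.
#' @return list of `n` selected [secondary_site()] objects.
#' @export
select_secondaries <- function(pool, n, conditions = thermo_conditions(),
                               tm_window = c(-Inf, Inf), lcs_threshold = 12L) {
  stopifnot(length(pool) >= n, n >= 0)
  if (n == 0L) return(list())
  chosen <- list()
  for (s in pool) {
    tm <- tm_nearest_neighbor(s$sequence, conditions)
    if (tm < tm_window[1] || tm > tm_window[2]) next
    clash <- any(vapply(chosen, function(c0)
      longest_common_substring(s$sequence, c0$sequence) >= lcs_threshold,
      logical(1)))
    if (clash) next
    chosen[[length(chosen) + 1L]] <- s
    if (length(chosen) == n) return(chosen)
  }
  stop(sprintf(paste0("cannot select %d orthogonal sites from pool of %d; ",
                      "best attainable: %d (%s)"),
               n, length(pool), length(chosen),
               paste(vapply(chosen, `[[`, character(1), "id"),
                     collapse = ", ")), call. = FALSE)
}
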