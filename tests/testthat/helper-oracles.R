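## Independent oracles used across the suite. These deliberately use plain
## per-window / per-table loops, separate from the package's vectorised code
## paths.

## Brute-force probe mining: enumerate every window in the target, apply each
## predicate one window at a time, then an independent greedy spacing pass.
oracle_mine <- function(genome, target, params, conditions, index,
                        require_overlap = NULL, exclude_points = NULL,
                        exclude_intervals = NULL) {
  L <- params$probe_length
  seq <- genome$contigs[[target$contig]]
  rows <- list()
  for (s in target$start:(target$end - L)) {
    w <- substr(seq, s + 1, s + L)
    if (grepl("N", w, fixed = TRUE)) next
    if (!is.null(require_overlap) &&
        !any(require_overlap >= s & require_overlap < s + L)) next
    if (!is.null(exclude_points) &&
        any(exclude_points >= s & exclude_points < s + L)) next
    if (!is.null(exclude_intervals) && nrow(exclude_intervals) > 0) {
      bad <- FALSE
      for (r in seq_len(nrow(exclude_intervals)))
        if (s < exclude_intervals$end[r] && exclude_intervals$start[r] < s + L)
          bad <- TRUE
      if (bad) next
    }
    gc <- 100 * sum(strsplit(w, "")[[1]] %in% c("G", "C")) / L
    if (gc < params$gc_min || gc > params$gc_max) next
    motif_hit <- FALSE
    for (m in params$forbidden_motifs)
      if (grepl(m, w, fixed = TRUE)) motif_hit <- TRUE
    if (motif_hit) next
    tm <- tm_nearest_neighbor(w, conditions)
    if (tm < params$tm_min || tm > params$tm_max) next
    if (!is.null(index)) {
      kmers <- substring(w, 1:(L - index$k + 1), index$k:L)
      if (max(kmer_count(index, kmers)) > params$uniqueness_max_hits) next
    }
    rows[[length(rows) + 1]] <- data.frame(
      contig = target$contig, start = s, end = s + L, strand = "+",
      sequence = w, tm = tm, gc = gc, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      sequence = character(0), tm = numeric(0),
                      gc = numeric(0)))
  all <- do.call(rbind, rows)
  ## independent greedy spacing + cap
  kept <- list(); last <- -Inf
  for (i in seq_len(nrow(all))) {
    if (length(kept) >= params$max_probes_per_target) break
    if (all$start[i] - last >= params$min_spacing) {
      kept[[length(kept) + 1]] <- all[i, ]
      last <- all$start[i]
    }
  }
  out <- do.call(rbind, kept)
  rownames(out) <- NULL
  out
}

## Full-enumeration Fisher oracle via log-binomial coefficients (the package
## route goes through dhyper).
oracle_fisher_p <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  supp <- max(0, k - m2):min(k, m1)
  logp <- lchoose(m1, supp) + lchoose(m2, k - supp) - lchoose(m1 + m2, k)
  p <- exp(logp)
  p_obs <- exp(lchoose(m1, a) + lchoose(m2, k - a) - lchoose(m1 + m2, k))
  sum(p[p <= p_obs * (1 + 1e-7)])
}

## Quadratic-time DP longest common substring (single strand).
oracle_lcs_one <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  best <- 0L
  prev <- integer(nb)
  for (i in seq_len(na)) {
    cur <- integer(nb)
    for (j in seq_len(nb)) {
      if (ca[i] == cb[j]) {
        cur[j] <- if (j == 1L) 1L else prev[j - 1L] + 1L
        if (cur[j] > best) best <- cur[j]
      }
    }
    prev <- cur
  }
  best
}

oracle_lcs <- function(a, b) {
  max(oracle_lcs_one(a, b), oracle_lcs_one(revcomp(a), b))
}

## random DNA of given length
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
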