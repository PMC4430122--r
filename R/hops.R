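## Haplotype-specific Oligopaint (HOP) design: cognate probe pairs spanning
## identical genomic coordinates that differ only at SNP alleles, plus
## SNP-avoiding interstitial probes.

#' SNP record table
#'
#' @param contig contig name(s).
#' @param pos 0-based SNP position(s).
#' @param ref,alt reference and alternate alleles (single bases, ref != alt).
#' @param hap_a,hap_b alleles carried by the two haplotypes; default
#'   convention assigns ref to haplotype A and alt to haplotype B.
#' @return data.frame with columns contig, pos, ref, alt, hap_a, hap_b.
#' @export
snp_records <- function(contig, pos, ref, alt, hap_a = ref, hap_b = alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  hap_a <- toupper(hap_a); hap_b <- toupper(hap_b)
  stopifnot(all(ref %in% DNA_BASES), all(alt %in% DNA_BASES),
            all(hap_a %in% DNA_BASES), all(hap_b %in% DNA_BASES),
            all(ref != alt), all(pos >= 0))
  df <- data.frame(contig = as.character(contig), pos = as.integer(pos),
                   ref = ref, alt = alt, hap_a = hap_a, hap_b = hap_b,
                   stringsAsFactors = FALSE)
  df[order(df$contig, df$pos), , drop = FALSE]
}

.check_snp_refs <- function(genome, snps) {
  for (i in seq_len(nrow(snps))) {
    base <- .get_subseq(genome, snps$contig[i], snps$pos[i], snps$pos[i] + 1L)
    if (base != snps$ref[i])
      stop(sprintf("reference mismatch for SNP %s:%d: VCF says %s, genome has %s",
                   snps$contig[i], snps$pos[i] + 1L, snps$ref[i], base),
           call. = FALSE)
  }
  invisible(snps)
}

#' Extract SNP-centred sequence blocks
#'
#' For probe length L, each SNP yields the reference block
#' `[pos - (L - 1), pos + L)` (length 2L - 1) so that every possible L-mer
#' window containing the SNP lies within the block. Blocks are clipped at
#' contig edges and flagged as truncated.
#'
#' @param genome a [genome_assembly()].
#' @param snps a [snp_records()] table; every `ref` must match the genome.
#' @param probe_length probe length L in bases.
#' @return data.frame with columns contig, start, end, sequence, focal_pos,
#'   truncated, and a list-column `contained` holding, per block, the row
#'   indices (into `snps`) of every SNP inside the block.
#' @export
extract_snp_blocks <- function(genome, snps, probe_length) {
  stopifnot(inherits(genome, "genome_assembly"), nrow(snps) >= 0)
  L <- as.integer(probe_length)
  .check_snp_refs(genome, snps)
  n <- nrow(snps)
  start <- integer(n); end <- integer(n); trunc <- logical(n)
  seqs <- character(n); contained <- vector("list", n)
  for (i in seq_len(n)) {
    clen <- nchar(genome$contigs[[snps$contig[i]]])
    s <- snps$pos[i] - (L - 1L)
    e <- snps$pos[i] + L
    trunc[i] <- s < 0L || e > clen
    s <- max(s, 0L); e <- min(e, clen)
    start[i] <- s; end[i] <- e
    seqs[i] <- .get_subseq(genome, snps$contig[i], s, e)
    contained[[i]] <- which(snps$contig == snps$contig[i] &
                            snps$pos >= s & snps$pos < e)
  }
  out <- data.frame(contig = snps$contig, start = start, end = end,
                    sequence = seqs, focal_pos = snps$pos,
                    truncated = trunc, stringsAsFactors = FALSE)
  out$contained <- contained
  out
}

#' Discover HOP candidate probes within SNP blocks
#'
#' Runs the full probe-mining filter stack over every window of each
#' SNP-centred block and additionally requires each candidate to overlap the
#' block's focal SNP (so every candidate overlaps at least one SNP, and a SNP
#' is coverable iff some passing window contains it). At most `per_block`
#' candidates are accepted per block (the classic haplotype-specific design
#' uses 1); coordinate-identical candidates arising from overlapping blocks
#' are deduplicated.
#'
#' @param blocks output of [extract_snp_blocks()].
#' @param snps the [snp_records()] table the blocks were built from.
#' @param params a [mining_params()].
#' @param conditions a [thermo_conditions()].
#' @param index a `kmer_index` over the genome (or `NULL`).
#' @param per_block per-block candidate cap (default 1).
#' @return candidate data.frame as in [mine_candidates()].
#' @export
discover_hop_candidates <- function(blocks, snps, params,
                                    conditions = thermo_conditions(),
                                    index = NULL, per_block = 1L) {
  out <- .empty_candidates()
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    tmpg <- structure(list(contigs = setNames(b$sequence, b$contig),
                           total_length = nchar(b$sequence)),
                      class = "genome_assembly")
    cand <- .filter_windows(tmpg, b$contig, 0L, b$end - b$start,
                            params, conditions, index,
                            require_overlap = b$focal_pos - b$start)
    cand <- .greedy_spacing(cand, params$min_spacing, per_block)
    if (nrow(cand)) {
      cand$start <- cand$start + b$start
      cand$end <- cand$end + b$start
      out <- rbind(out, cand)
    }
  }
  out <- out[!duplicated(out[c("contig", "start", "end")]), , drop = FALSE]
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Insert haplotype alleles into a candidate to form a cognate HOP pair
#'
#' Both sequences of the pair span exactly the candidate's genomic
#' coordinates; they are identical to the reference (and to each other)
#' everywhere except at the offsets of overlapping SNPs, where each carries
#' its haplotype's allele. All SNPs overlapping the candidate are inserted.
#'
#' @param candidate one candidate row (data.frame or list with contig, start,
#'   end, sequence).
#' @param snps a [snp_records()] table; the rows overlapping the candidate
#'   are used.
#' @return an object of class `hop_pair`: list(contig, start, end,
#'   hap_a_sequence, hap_b_sequence, snp_offsets).
#' @export
#' @examples
#' s <- snp_records("c1", 3, "T", "C")
#' insert_variants(list(contig = "c1", start = 0, end = 8,
#'                      sequence = "ACGTACGT"), s)
insert_variants <- function(candidate, snps) {
  ov <- snps[snps$contig == candidate$contig &
             snps$pos >= candidate$start & snps$pos < candidate$end, ,
             drop = FALSE]
  if (nrow(ov) == 0L)
    stop("candidate overlaps no SNP; cannot build a HOP pair", call. = FALSE)
  offs <- ov$pos - candidate$start
  chars <- strsplit(candidate$sequence, "")[[1]]
  mism <- chars[offs + 1L] != ov$ref
  if (any(mism))
    stop(sprintf("reference mismatch at %s:%d: SNP ref %s vs candidate %s",
                 candidate$contig, ov$pos[which(mism)[1]] + 1L,
                 ov$ref[which(mism)[1]], chars[offs[which(mism)[1]] + 1L]),
         call. = FALSE)
  a <- chars; b <- chars
  a[offs + 1L] <- ov$hap_a
  b[offs + 1L] <- ov$hap_b
  structure(list(contig = candidate$contig,
                 start = candidate$start, end = candidate$end,
                 hap_a_sequence = paste(a, collapse = ""),
                 hap_b_sequence = paste(b, collapse = ""),
                 snp_offsets = as.integer(offs)),
            class = "hop_pair")
}

#' @export
print.hop_pair <- function(x, ...) {
  cat(sprintf("hop_pair %s:[%d,%d) offsets {%s}\n  A: %s\n  B: %s\n",
              x$contig, x$start, x$end,
              paste(x$snp_offsets, collapse = ","),
              x$hap_a_sequence, x$hap_b_sequence))
  invisible(x)
}

#' Design interstitial probes avoiding all SNPs, HOPs and excluded regions
#'
#' Mines probes over the target with the standard filter stack plus hard
#' exclusion of (a) every SNP position, (b) every HOP footprint and (c) any
#' user-supplied avoidance interval (e.g. a transcribed region kept free for
#' simultaneous RNA FISH). The result binds both haplotypes equally.
#'
#' @param genome a [genome_assembly()].
#' @param target interval as in [mine_candidates()].
#' @param snps a [snp_records()] table.
#' @param hop_footprints data.frame(start, end) of HOP pair coordinates
#'   (0-based half-open), or NULL.
#' @param avoid data.frame(start, end) of additional excluded intervals,
#'   or NULL.
#' @param params,conditions,index as in [mine_candidates()].
#' @return candidate data.frame as in [mine_candidates()].
#' @export
design_interstitial <- function(genome, target, snps, hop_footprints = NULL,
                                avoid = NULL, params = mining_params(),
                                conditions = thermo_conditions(),
                                index = NULL) {
  target <- .as_target(target)
  excl <- rbind(
    if (!is.null(hop_footprints) && nrow(hop_footprints))
      hop_footprints[c("start", "end")],
    if (!is.null(avoid) && nrow(avoid)) avoid[c("start", "end")]
  )
  snp_pos <- snps$pos[snps$contig == target$contig]
  cand <- .filter_windows(genome, target$contig, target$start, target$end,
                          params, conditions, index,
                          exclude_points = snp_pos,
                          exclude_intervals = excl)
  .greedy_spacing(cand, params$min_spacing, params$max_probes_per_target)
}

#' Full haplotype-specific probe design pipeline
#'
#' Composes [extract_snp_blocks()], [discover_hop_candidates()],
#' [insert_variants()] and [design_interstitial()] over one target interval.
#' The SNP suitability fraction is the fraction of SNPs inside the target
#' covered by at least one HOP pair (the denominator includes SNPs lost to
#' clipping or filtering).
#'
#' @param genome a [genome_assembly()].
#' @param target interval as in [mine_candidates()].
#' @param snps a [snp_records()] table (ref alleles must match the genome).
#' @param params a [mining_params()]; the per-block cap is `per_block`.
#' @param conditions a [thermo_conditions()].
#' @param index a `kmer_index`, or `NULL` to build one from the genome.
#' @param avoid optional data.frame(start, end) of excluded intervals.
#' @param per_block per-block HOP candidate cap (default 1).
#' @return an object of class `hop_design_result`: list with `pairs` (list of
#'   `hop_pair`), `interstitial` (candidate data.frame),
#'   `snp_suitability_fraction` (NA with `no_snps = TRUE` when the target
#'   contains no SNPs), `coverage` (per-SNP table with pos and n_pairs) and
#'   `n_snps`.
#' @export
design_hops <- function(genome, target, snps, params = mining_params(),
                        conditions = thermo_conditions(), index = NULL,
                        avoid = NULL, per_block = 1L) {
  target <- .as_target(target)
  if (is.null(index))
    index <- build_uniqueness_index(genome, params$uniqueness_k)
  in_target <- snps$contig == target$contig &
    snps$pos >= target$start & snps$pos < target$end
  snps_t <- snps[in_target, , drop = FALSE]
  if (!is.null(avoid) && nrow(avoid)) {
    keep <- rep(TRUE, nrow(snps_t))
    for (i in seq_len(nrow(avoid)))
      keep <- keep & !(snps_t$pos >= avoid$start[i] & snps_t$pos < avoid$end[i])
    snps_use <- snps_t[keep, , drop = FALSE]
  } else snps_use <- snps_t

  no_snps <- nrow(snps_t) == 0L
  pairs <- list()
  cands <- .empty_candidates()
  if (nrow(snps_use)) {
    blocks <- extract_snp_blocks(genome, snps_use, params$probe_length)
    cands <- discover_hop_candidates(blocks, snps_use, params, conditions,
                                     index, per_block = per_block)
    cands <- cands[cands$start >= target$start & cands$end <= target$end, ,
                   drop = FALSE]
    if (!is.null(avoid) && nrow(avoid)) {
      keep <- rep(TRUE, nrow(cands))
      for (i in seq_len(nrow(avoid)))
        keep <- keep & !.overlaps(cands$start, cands$end,
                                  avoid$start[i], avoid$end[i])
      cands <- cands[keep, , drop = FALSE]
    }
    pairs <- lapply(seq_len(nrow(cands)), function(i)
      insert_variants(cands[i, ], snps))
  }
  footprints <- if (length(pairs))
    data.frame(start = vapply(pairs, `[[`, integer(1), "start"),
               end = vapply(pairs, `[[`, integer(1), "end"))
  else data.frame(start = integer(0), end = integer(0))

  inter <- design_interstitial(genome, target, snps, footprints, avoid,
                               params, conditions, index)

  covered <- vapply(seq_len(nrow(snps_t)), function(i) {
    sum(footprints$start <= snps_t$pos[i] & snps_t$pos[i] < footprints$end)
  }, integer(1))
  suitability <- if (no_snps) NA_real_ else mean(covered > 0)

  structure(list(pairs = pairs, interstitial = inter,
                 snp_suitability_fraction = suitability,
                 no_snps = no_snps,
                 coverage = data.frame(contig = snps_t$contig,
                                       pos = snps_t$pos,
                                       n_pairs = covered,
                                       stringsAsFactors = FALSE),
                 n_snps = nrow(snps_t)),
            class = "hop_design_result")
}

#' @export
print.hop_design_result <- function(x, ...) {
  cat(sprintf(paste0("hop_design_result: %d HOP pair(s), %d interstitial ",
                     "probe(s), %d SNP(s) in target, suitability %s\n"),
              length(x$pairs), nrow(x$interstitial), x$n_snps,
              if (x$no_snps) "undefined (no SNPs)"
              else sprintf("%.1f%%", 100 * x$snp_suitability_fraction)))
  invisible(x)
}
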