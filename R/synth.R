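## Seeded synthetic fixtures: diploid genomes with SNPs at a configurable
## density, and nuclear spot fields with known pairing ground truth.

#' Specification for a synthetic genome with SNPs
#'
#' Defaults emulate a Drosophila-hybrid-like design target: GC content 42%
#' and 7 SNPs per kb (the density observed between two inbred fly lines;
#' mouse strain pairs run nearer 2-3 SNPs per kb).
#'
#' @param n_contigs number of contigs.
#' @param contig_length length of each contig, bases.
#' @param gc_content GC fraction in `[0, 1]`.
#' @param snp_density SNPs per kilobase (must not exceed 1000).
#' @param seed RNG seed.
#' @return an object of class `synthetic_genome_spec`.
#' @export
synthetic_genome_spec <- function(n_contigs = 1L, contig_length = 50000L,
                                  gc_content = 0.42, snp_density = 7,
                                  seed = NULL) {
  stopifnot(n_contigs >= 1, contig_length >= 1,
            gc_content >= 0, gc_content <= 1, snp_density >= 0)
  if (snp_density > 1000)
    stop("snp_density exceeds 1 SNP per base", call. = FALSE)
  structure(list(n_contigs = as.integer(n_contigs),
                 contig_length = as.integer(contig_length),
                 gc_content = gc_content, snp_density = snp_density,
                 seed = seed),
            class = "synthetic_genome_spec")
}

#' Generate a synthetic genome and SNP panel
#'
#' Draws each contig i.i.d. at the requested GC content, then places SNPs
#' uniformly without replacement at the requested density. Each SNP's ref
#' allele is the generated genome base and its alt allele is a uniform draw
#' from the other three bases; by default haplotype A carries ref and
#' haplotype B carries alt, emulating two inbred parental haplotypes
#' differing by point substitutions. Deterministic per seed.
#'
#' @param spec a [synthetic_genome_spec()].
#' @return list with `genome` (a [genome_assembly()]) and `snps`
#'   (a [snp_records()] table).
#' @export
#' @examples
#' fix <- synth_genome(synthetic_genome_spec(contig_length = 10000, seed = 1))
#' fix$genome
#' nrow(fix$snps)  # about 70 SNPs at 7/kb
synth_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  gc <- spec$gc_content
  base_prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  contigs <- character(spec$n_contigs)
  snp_list <- list()
  for (i in seq_len(spec$n_contigs)) {
    bases <- sample(DNA_BASES, spec$contig_length, replace = TRUE,
                    prob = base_prob)
    contigs[i] <- paste(bases, collapse = "")
    n_snps <- round(spec$snp_density * spec$contig_length / 1000)
    if (n_snps > 0) {
      pos <- sort(sample.int(spec$contig_length, n_snps)) - 1L
      ref <- bases[pos + 1L]
      alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1L),
                    character(1), USE.NAMES = FALSE)
      snp_list[[i]] <- data.frame(contig = paste0("contig", i), pos = pos,
                                  ref = ref, alt = alt,
                                  stringsAsFactors = FALSE)
    }
  }
  names(contigs) <- paste0("contig", seq_len(spec$n_contigs))
  snps <- if (length(snp_list)) {
    all <- do.call(rbind, snp_list)
    snp_records(all$contig, all$pos, all$ref, all$alt)
  } else {
    snp_records(character(0), integer(0), character(0), character(0))
  }
  list(genome = genome_assembly(contigs), snps = snps)
}

#' Specification for a synthetic two-channel spot field
#'
#' Ground-truth generator for the quantification pipeline. Defaults plant the
#' pairing frequency observed for a developmentally regulated fly locus in
#' 6-8 h embryos (32%) over 101 nuclei; paired loci sit within a few hundred
#' nanometres of each other while unpaired loci are separated by over 2 um.
#'
#' @param n_nuclei number of nuclei.
#' @param pairing_probability probability a nucleus is paired.
#' @param pair_offset_sd per-axis s.d. (nm) of the signal separation in
#'   paired nuclei.
#' @param false_negative_rate per-channel probability a spot is missed.
#' @param chromatic_offset length-3 nm vector added to channel B coordinates
#'   (simulated chromatic aberration).
#' @param seed RNG seed.
#' @return an object of class `spot_field_spec`.
#' @export
spot_field_spec <- function(n_nuclei = 101L, pairing_probability = 0.32,
                            pair_offset_sd = 200,
                            false_negative_rate = 0,
                            chromatic_offset = c(0, 0, 0), seed = NULL) {
  stopifnot(n_nuclei >= 1,
            pairing_probability >= 0, pairing_probability <= 1,
            pair_offset_sd >= 0,
            false_negative_rate >= 0, false_negative_rate <= 1,
            length(chromatic_offset) == 3)
  structure(list(n_nuclei = as.integer(n_nuclei),
                 pairing_probability = pairing_probability,
                 pair_offset_sd = pair_offset_sd,
                 false_negative_rate = false_negative_rate,
                 chromatic_offset = chromatic_offset, seed = seed),
            class = "spot_field_spec")
}

#' Generate a synthetic spot field with known pairing ground truth
#'
#' Per nucleus, a channel-A spot is placed uniformly in an 8 x 8 x 8 um
#' nuclear box. With probability `pairing_probability` the nucleus is paired
#' and the channel-B spot is offset by N(0, pair_offset_sd) per axis;
#' otherwise B is displaced by 2.5-5 um in a uniformly random direction.
#' Spots are then dropped independently per channel at
#' `false_negative_rate`, and the chromatic offset is added to channel B.
#'
#' @param spec a [spot_field_spec()].
#' @return list with `spots` (a [spot_table()]) and `truth`
#'   (data.frame nucleus_id, paired).
#' @export
#' @examples
#' f <- synth_spot_field(spot_field_spec(n_nuclei = 50, seed = 1))
#' table(f$truth$paired)
synth_spot_field <- function(spec) {
  stopifnot(inherits(spec, "spot_field_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_nuclei
  ids <- sprintf("nucleus%04d", seq_len(n))
  paired <- runif(n) < spec$pairing_probability
  ax <- runif(n, 0, 8000); ay <- runif(n, 0, 8000); az <- runif(n, 0, 8000)
  dx <- dy <- dz <- numeric(n)
  for (i in seq_len(n)) {
    if (paired[i]) {
      off <- rnorm(3, 0, spec$pair_offset_sd)
    } else {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      off <- u * runif(1, 2500, 5000)
    }
    dx[i] <- off[1]; dy[i] <- off[2]; dz[i] <- off[3]
  }
  spots_a <- spot_table(ids, "A", ax, ay, az)
  spots_b <- spot_table(ids, "B",
                        ax + dx + spec$chromatic_offset[1],
                        ay + dy + spec$chromatic_offset[2],
                        az + dz + spec$chromatic_offset[3])
  keep_a <- runif(n) >= spec$false_negative_rate
  keep_b <- runif(n) >= spec$false_negative_rate
  spots <- rbind(spots_a[keep_a, , drop = FALSE],
                 spots_b[keep_b, , drop = FALSE])
  rownames(spots) <- NULL
  list(spots = spots,
       truth = data.frame(nucleus_id = ids, paired = paired,
                          stringsAsFactors = FALSE))
}
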