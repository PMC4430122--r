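## File formats: VCF (SNP subset), BED, TSV probe/spot tables, FASTA probe
## output. All coordinates are 0-based half-open internally; VCF POS is
## converted from 1-based on read/write and BED output is 0-based half-open.

#' Read SNPs from a VCF file
#'
#' Consumes CHROM, POS, REF, ALT and (optionally) phased GT columns of a
#' VCF v4.x file. Only biallelic-style single-nucleotide records are kept:
#' indels and records whose first ALT is not a single base are dropped with
#' a warning. Haplotype assignment: with no `samples`, haplotype A carries
#' REF and haplotype B the first ALT; with one sample name, its GT `a|b`
#' assigns allele a to haplotype A and b to haplotype B; with two sample
#' names, haplotype A is the first allele of sample 1 and haplotype B the
#' first allele of sample 2.
#'
#' @param path VCF file path.
#' @param samples NULL, or 1-2 sample names carrying phased genotypes.
#' @return a [snp_records()] table (pos 0-based).
#' @export
read_snps_vcf <- function(path, samples = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0)
    return(snp_records(character(0), integer(0), character(0), character(0)))
  alt1 <- sub(",.*$", "", fix$ALT)
  is_snp <- nchar(fix$REF) == 1 & nchar(alt1) == 1 &
    fix$REF %in% DNA_BASES & alt1 %in% DNA_BASES
  if (any(!is_snp))
    warning(sum(!is_snp), " non-SNP record(s) dropped from ", path,
            call. = FALSE)
  fix <- fix[is_snp, , drop = FALSE]
  alt1 <- alt1[is_snp]
  pos0 <- as.integer(fix$POS) - 1L
  hap_a <- fix$REF; hap_b <- alt1
  if (!is.null(samples)) {
    gt <- vcfR::extract.gt(vcf, element = "GT")[is_snp, , drop = FALSE]
    missing <- setdiff(samples, colnames(gt))
    if (length(missing))
      stop("sample(s) not in VCF: ", paste(missing, collapse = ", "),
           call. = FALSE)
    pick <- function(gt_str, which_allele) {
      al <- strsplit(gt_str, "[|/]")[[1]]
      as.integer(al[min(which_allele, length(al))])
    }
    allele_base <- function(idx, ref, alt) ifelse(idx == 0, ref, alt)
    if (length(samples) == 1) {
      g <- gt[, samples]
      ia <- vapply(g, pick, integer(1), which_allele = 1)
      ib <- vapply(g, pick, integer(1), which_allele = 2)
    } else {
      ia <- vapply(gt[, samples[1]], pick, integer(1), which_allele = 1)
      ib <- vapply(gt[, samples[2]], pick, integer(1), which_allele = 1)
    }
    hap_a <- allele_base(ia, fix$REF, alt1)
    hap_b <- allele_base(ib, fix$REF, alt1)
  }
  snp_records(fix$CHROM, pos0, fix$REF, alt1, hap_a, hap_b)
}

#' Write SNPs as a minimal VCF v4.2 file
#'
#' Emits CHROM/POS/ID/REF/ALT plus a single diploid sample `HAPS` whose
#' phased GT encodes the haplotype assignment (`a|b` with 0 = REF,
#' 1 = ALT), so [read_snps_vcf()] round-trips the table.
#'
#' @param snps a [snp_records()] table.
#' @param path output path.
#' @param contig_lengths optional named vector for `##contig` header lines.
#' @export
write_snps_vcf <- function(snps, path, contig_lengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=oligohops",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), contig_lengths))
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", "HAPS", sep = "\t"))
  gt <- paste0(ifelse(snps$hap_a == snps$ref, 0L, 1L), "|",
               ifelse(snps$hap_b == snps$ref, 0L, 1L))
  body <- if (nrow(snps)) sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.\tGT\t%s",
                                  snps$contig, snps$pos + 1L,
                                  sprintf("snp%d", seq_len(nrow(snps))),
                                  snps$ref, snps$alt, gt)
          else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write probe candidates as TSV
#' @param cands candidate data.frame from [mine_candidates()].
#' @param path output path.
#' @export
write_probes_tsv <- function(cands, path) {
  write.table(cands, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe candidate TSV
#' @param path TSV path written by [write_probes_tsv()].
#' @return candidate data.frame.
#' @export
read_probes_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write probe candidates as BED6
#'
#' 0-based half-open coordinates; score = round(Tm x 10).
#'
#' @param cands candidate data.frame.
#' @param path output path.
#' @param name_prefix probe name prefix.
#' @export
write_probes_bed <- function(cands, path, name_prefix = "probe") {
  lines <- if (nrow(cands))
    sprintf("%s\t%d\t%d\t%s\t%d\t%s", cands$contig, cands$start, cands$end,
            sprintf("%s%d", name_prefix, seq_len(nrow(cands))),
            round(cands$tm * 10), cands$strand)
  else character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Write probe candidates as FASTA
#'
#' @param cands candidate data.frame.
#' @param path output path.
#' @param reverse_complement emit the reverse complement (for
#'   strand-specific ssDNA probe sets).
#' @export
write_probes_fasta <- function(cands, path, reverse_complement = FALSE) {
  seqs <- cands$sequence
  if (reverse_complement) seqs <- revcomp(seqs)
  names(seqs) <- sprintf("%s:%d-%d(%s)", cands$contig, cands$start,
                         cands$end, cands$strand)
  write_fasta(seqs, path)
}

#' Write HOP pairs as TSV (plus optional per-haplotype FASTA)
#'
#' @param pairs list of `hop_pair` objects.
#' @param path TSV output path.
#' @param fasta_prefix if non-NULL, also writes `<prefix>_hapA.fasta` and
#'   `<prefix>_hapB.fasta`.
#' @export
write_hop_pairs <- function(pairs, path, fasta_prefix = NULL) {
  df <- data.frame(
    contig = vapply(pairs, `[[`, character(1), "contig"),
    start = vapply(pairs, `[[`, integer(1), "start"),
    end = vapply(pairs, `[[`, integer(1), "end"),
    hapA_seq = vapply(pairs, `[[`, character(1), "hap_a_sequence"),
    hapB_seq = vapply(pairs, `[[`, character(1), "hap_b_sequence"),
    snp_offsets = vapply(pairs, function(p)
      paste(p$snp_offsets, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(fasta_prefix) && length(pairs)) {
    nm <- sprintf("%s:%d-%d", df$contig, df$start, df$end)
    write_fasta(setNames(df$hapA_seq, nm),
                paste0(fasta_prefix, "_hapA.fasta"))
    write_fasta(setNames(df$hapB_seq, nm),
                paste0(fasta_prefix, "_hapB.fasta"))
  }
  invisible(path)
}

#' Read a spot table from TSV
#'
#' Expected columns: nucleus_id, channel, x, y, z and optionally radius
#' (nm units; missing radius defaults to 0).
#'
#' @param path TSV path.
#' @return a [spot_table()].
#' @export
read_spots_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("nucleus_id", "channel", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("spot TSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  spot_table(df$nucleus_id, df$channel, df$x, df$y, df$z,
             radius = df$radius %||% 0)
}

#' Write a spot (or localization) table as TSV
#' @param df data.frame.
#' @param path output path.
#' @export
write_spots_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a quantification summary as JSON
#'
#' Serialises a [colocalize()] result, a [concordance_table()] result or a
#' [fisher_exact_two_tailed()] result (or any plain list of scalars/tables)
#' to a JSON summary file.
#'
#' @param x result object.
#' @param path output path.
#' @export
write_summary_json <- function(x, path) {
  to_plain <- function(v) {
    if (inherits(v, "contingency_table")) unclass(v)
    else if (inherits(v, "colocalization_result"))
      list(percent_colocalization = v$percent_colocalization,
           undefined = v$undefined,
           percent_labelling = as.list(v$percent_labelling),
           direction = v$direction, n_matches = nrow(v$matches),
           n_foci = as.list(v$n_foci))
    else if (inherits(v, "fisher_result"))
      list(p_two_tailed = v$p_two_tailed, odds_ratio = v$odds_ratio,
           table = unclass(v$table))
    else if (is.list(v)) lapply(v, to_plain)
    else v
  }
  jsonlite::write_json(to_plain(x), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
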