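cond1M <- thermo_conditions(1, 0)

test_that("SNP blocks are centred, clipped and annotated correctly", {
  set.seed(2)
  seq <- random_dna(100)
  seq <- paste0(substr(seq, 1, 49), "A", substr(seq, 51, 100))
  g <- genome_assembly(c(c1 = seq))
  s <- snp_records("c1", 49, "A", "G")
  b <- extract_snp_blocks(g, s, probe_length = 5)
  expect_identical(b$start, 45L)
  expect_identical(b$end, 54L)
  expect_identical(b$end - b$start, 9L)
  expect_false(b$truncated)
  expect_identical(b$focal_pos - b$start, 4L)
  expect_identical(b$sequence, substr(seq, 46, 54))

  ## clipping at the contig start
  s2 <- snp_records("c1", 1, substr(seq, 2, 2),
                    setdiff(c("A", "C", "G", "T"), substr(seq, 2, 2))[1])
  b2 <- extract_snp_blocks(g, s2, probe_length = 5)
  expect_identical(c(b2$start, b2$end), c(0L, 6L))
  expect_true(b2$truncated)

  ## two SNPs 3 bp apart with L = 32: each block contains both records
  pos <- c(60, 63)
  s3 <- snp_records("c1", pos, substring(seq, pos + 1, pos + 1),
                    vapply(substring(seq, pos + 1, pos + 1),
                           function(r) setdiff(c("A", "C", "G", "T"), r)[1],
                           character(1)))
  b3 <- extract_snp_blocks(g, s3, probe_length = 32)
  expect_identical(b3$contained[[1]], c(1L, 2L))
  expect_identical(b3$contained[[2]], c(1L, 2L))
})

test_that("a reference-mismatching SNP is rejected by name", {
  g <- genome_assembly(c(c1 = "ACGTACGTACGT"))
  s <- snp_records("c1", 3, "G", "A")  # genome has T at position 3
  expect_error(extract_snp_blocks(g, s, 5), "reference mismatch.*c1:4")
})

test_that("HOP discovery finds one candidate per planted SNP and matches brute force", {
  set.seed(31)
  g <- genome_assembly(c(c1 = random_dna(5000)))
  pos <- seq(200, 4700, by = 500)           # 10 well-separated SNPs
  ref <- substring(g$contigs[["c1"]], pos + 1, pos + 1)
  alt <- vapply(ref, function(r) setdiff(c("A", "C", "G", "T"), r)[1],
                character(1))
  snps <- snp_records("c1", pos, ref, alt)
  params <- mining_params(tm_min = 60, tm_max = 110, gc_min = 0,
                          gc_max = 100, forbidden_motifs = character(0))
  idx <- build_uniqueness_index(g, 16)
  blocks <- extract_snp_blocks(g, snps, params$probe_length)
  got <- discover_hop_candidates(blocks, snps, params, cond1M, idx)
  expect_identical(nrow(got), 10L)
  for (i in seq_len(nrow(got))) {
    cover <- snps$pos >= got$start[i] & snps$pos < got$end[i]
    expect_true(any(cover))
  }
  ## brute force per block: first passing window containing the focal SNP
  for (i in seq_len(nrow(blocks))) {
    want <- oracle_mine(g, list(contig = "c1", start = blocks$start[i],
                                end = blocks$end[i]),
                        params, cond1M, idx,
                        require_overlap = blocks$focal_pos[i])
    expect_identical(got$start[i], want$start[1])
  }
  ## lifting the cap can only add candidates
  uncapped <- discover_hop_candidates(blocks, snps, params, cond1M, idx,
                                      per_block = Inf)
  expect_gte(nrow(uncapped), nrow(got))
})

test_that("variant insertion builds cognate pairs and validates the reference", {
  snp <- snp_records("c1", 3, "T", "C")
  pr <- insert_variants(list(contig = "c1", start = 0, end = 8,
                             sequence = "ACGTACGT"), snp)
  expect_identical(pr$hap_a_sequence, "ACGTACGT")
  expect_identical(pr$hap_b_sequence, "ACGCACGT")
  expect_identical(pr$snp_offsets, 3L)

  two <- snp_records("c1", c(2, 6), c("G", "G"), c("A", "T"))
  pr2 <- insert_variants(list(contig = "c1", start = 0, end = 8,
                              sequence = "ACGTACGT"), two)
  diffs <- which(strsplit(pr2$hap_a_sequence, "")[[1]] !=
                 strsplit(pr2$hap_b_sequence, "")[[1]]) - 1L
  expect_identical(diffs, c(2L, 6L))

  bad <- snp_records("c1", 3, "G", "A")
  expect_error(insert_variants(list(contig = "c1", start = 0, end = 8,
                                    sequence = "ACGTACGT"), bad),
               "reference mismatch")
  none <- snp_records("c1", 100, "A", "G")
  expect_error(insert_variants(list(contig = "c1", start = 0, end = 8,
                                    sequence = "ACGTACGT"), none),
               "no SNP")
})

test_that("interstitial probes avoid SNPs, HOP footprints and avoid intervals", {
  fix <- synth_genome(synthetic_genome_spec(contig_length = 5000,
                                            snp_density = 4, seed = 13))
  g <- fix$genome; snps <- fix$snps
  params <- mining_params(tm_min = 70, tm_max = 99)
  target <- list(contig = "contig1", start = 0, end = 5000)

  ## fully covered by an avoid interval -> nothing
  all_avoid <- data.frame(start = 0L, end = 5000L)
  expect_identical(nrow(design_interstitial(g, target, snps,
                                            avoid = all_avoid,
                                            params = params,
                                            conditions = cond1M)), 0L)

  fp <- data.frame(start = c(1000L, 3000L), end = c(1042L, 3042L))
  avoid <- data.frame(start = 2000L, end = 2300L)
  out <- design_interstitial(g, target, snps, fp, avoid, params, cond1M)
  expect_gt(nrow(out), 0)
  snp_hit <- vapply(seq_len(nrow(out)), function(i)
    any(snps$pos >= out$start[i] & snps$pos < out$end[i]), logical(1))
  expect_false(any(snp_hit))
  excl <- rbind(fp, avoid)
  iv_hit <- vapply(seq_len(nrow(out)), function(i)
    any(out$start[i] < excl$end & excl$start < out$end[i]), logical(1))
  expect_false(any(iv_hit))
  ## interstitial probes never overlap each other at spacing >= length
  params2 <- mining_params(tm_min = 70, tm_max = 99, min_spacing = 42L)
  out2 <- design_interstitial(g, target, snps, fp, avoid, params2, cond1M)
  if (nrow(out2) > 1) expect_true(all(diff(out2$start) >= 42))
})

test_that("full HOP pipeline satisfies its invariants on a 7 SNP/kb fixture", {
  fix <- synth_genome(synthetic_genome_spec(contig_length = 20000,
                                            snp_density = 7, seed = 77))
  g <- fix$genome; snps <- fix$snps
  params <- mining_params(tm_min = 75, tm_max = 99)
  target <- list(contig = "contig1", start = 0, end = 20000)
  idx <- build_uniqueness_index(g, 16)
  res <- design_hops(g, target, snps, params, cond1M, idx)

  expect_gt(length(res$pairs), 0)
  ## cognate-pair invariants, aggregated over all pairs
  pair_ok <- vapply(res$pairs, function(p) {
    if (!inherits(p, "hop_pair")) return(FALSE)
    if (nchar(p$hap_a_sequence) != p$end - p$start ||
        nchar(p$hap_b_sequence) != p$end - p$start) return(FALSE)
    a <- strsplit(p$hap_a_sequence, "")[[1]]
    b <- strsplit(p$hap_b_sequence, "")[[1]]
    ov <- snps[snps$pos >= p$start & snps$pos < p$end, ]
    ## hamming distance == number of offsets where the hap alleles differ
    if (sum(a != b) != sum(ov$hap_a != ov$hap_b)) return(FALSE)
    if (!identical(which(a != b) - 1L,
                   p$snp_offsets[ov$hap_a != ov$hap_b])) return(FALSE)
    ## non-SNP positions match the reference
    ref <- strsplit(.get_subseq(g, p$contig, p$start, p$end), "")[[1]]
    non_snp <- setdiff(seq_along(ref), p$snp_offsets + 1L)
    identical(a[non_snp], ref[non_snp]) && identical(b[non_snp], ref[non_snp])
  }, logical(1))
  expect_true(all(pair_ok))
  ## interstitial probes overlap no SNP and no HOP footprint
  fp <- data.frame(start = vapply(res$pairs, `[[`, integer(1), "start"),
                   end = vapply(res$pairs, `[[`, integer(1), "end"))
  inter_ok <- vapply(seq_len(nrow(res$interstitial)), function(i) {
    s <- res$interstitial$start[i]; e <- res$interstitial$end[i]
    !any(snps$pos >= s & snps$pos < e) && !any(s < fp$end & fp$start < e)
  }, logical(1))
  expect_true(all(inter_ok))
  ## suitability equals the brute-force per-SNP passing-window fraction
  brute_cover <- vapply(seq_len(nrow(snps)), function(i) {
    pos <- snps$pos[i]
    w <- oracle_mine(g, list(contig = "contig1",
                             start = max(0, pos - params$probe_length + 1),
                             end = min(20000, pos + params$probe_length)),
                     params, cond1M, idx, require_overlap = pos)
    !is.null(w) && nrow(w) > 0
  }, logical(1))
  expect_equal(res$snp_suitability_fraction, mean(brute_cover))
  expect_identical(res$n_snps, nrow(snps))
  ## determinism
  res2 <- design_hops(g, target, snps, params, cond1M, idx)
  expect_equal(res$snp_suitability_fraction, res2$snp_suitability_fraction)
  expect_identical(length(res$pairs), length(res2$pairs))
})

test_that("degenerate SNP configurations are handled", {
  fix <- synth_genome(synthetic_genome_spec(contig_length = 3000,
                                            snp_density = 0, seed = 3))
  params <- mining_params(tm_min = 70, tm_max = 99)
  res <- design_hops(fix$genome, list(contig = "contig1", start = 0,
                                      end = 3000), fix$snps, params, cond1M)
  expect_identical(length(res$pairs), 0L)
  expect_true(res$no_snps)
  expect_true(is.na(res$snp_suitability_fraction))

  ## all SNPs inside avoid intervals -> zero pairs, suitability 0
  fix2 <- synth_genome(synthetic_genome_spec(contig_length = 3000,
                                             snp_density = 3, seed = 4))
  res2 <- design_hops(fix2$genome, list(contig = "contig1", start = 0,
                                        end = 3000), fix2$snps, params,
                      cond1M, avoid = data.frame(start = 0L, end = 3000L))
  expect_identical(length(res2$pairs), 0L)
  expect_false(res2$no_snps)
  expect_identical(res2$snp_suitability_fraction, 0)
})
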