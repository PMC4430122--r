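test_that("focus merging follows the edge-to-edge single-linkage rule", {
  two_close <- spot_table("n1", "red", c(0, 500), 0, 0)
  expect_identical(nrow(merge_foci(two_close)), 1L)
  expect_equal(merge_foci(two_close)$x, 250)

  two_far <- spot_table("n1", "red", c(0, 1200), 0, 0)
  expect_identical(nrow(merge_foci(two_far)), 2L)

  ## transitive closure: A-B 900, B-C 900, A-C 1800 -> one focus
  chain <- spot_table("n1", "red", c(0, 900, 1800), 0, 0)
  expect_identical(nrow(merge_foci(chain)), 1L)

  ## radii shrink the effective separation: centres 1500 apart with radii
  ## 300 are 900 edge-to-edge
  fat <- spot_table("n1", "red", c(0, 1500), 0, 0, radius = 300)
  expect_identical(nrow(merge_foci(fat)), 1L)
  ## but well-separated fat spots stay apart
  fat2 <- spot_table("n1", "red", c(0, 2500), 0, 0, radius = 300)
  expect_identical(nrow(merge_foci(fat2)), 2L)

  ## strict threshold: exactly 1000 nm apart stays two foci
  border <- spot_table("n1", "red", c(0, 1000), 0, 0)
  expect_identical(nrow(merge_foci(border)), 2L)
})

test_that("merging partitions the input and is order invariant", {
  set.seed(19)
  s <- spot_table(sample(c("n1", "n2"), 40, TRUE),
                  sample(c("red", "green"), 40, TRUE),
                  runif(40, 0, 6000), runif(40, 0, 6000), runif(40, 0, 2000))
  f <- merge_foci(s)
  ## every spot accounted for exactly once
  expect_identical(sum(f$n_spots),
                   nrow(s))
  perm <- s[sample(nrow(s)), ]
  f2 <- merge_foci(perm)
  o1 <- f[order(f$nucleus_id, f$channel, f$x), ]
  o2 <- f2[order(f2$nucleus_id, f2$channel, f2$x), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("chromatic correction is a tracked one-shot translation", {
  s <- spot_table("n1", c("green", "red"), c(0, 177), 0, 0)
  corr <- correct_chromatic(s, "red", c(177, 0, 0))
  expect_equal(corr$x, c(0, 0))
  expect_equal(correct_chromatic(s, "red", c(0, 0, 0))$x, s$x)
  expect_error(correct_chromatic(corr, "red", c(177, 0, 0)),
               "already applied")
})

test_that("co-localization applies the lateral and axial thresholds", {
  fA <- merge_foci(spot_table("n1", "A", 0, 0, 0))
  near <- merge_foci(spot_table("n1", "B", 200, 0, 0))
  farxy <- merge_foci(spot_table("n1", "B", 300, 0, 0))
  farz <- merge_foci(spot_table("n1", "B", 0, 0, 700))
  expect_identical(nrow(colocalize(fA, near)$matches), 1L)
  expect_identical(nrow(colocalize(fA, farxy)$matches), 0L)
  expect_identical(nrow(colocalize(fA, farz)$matches), 0L)
  expect_equal(colocalize(fA, near)$percent_colocalization, 100)
  expect_equal(colocalize(fA, farxy)$percent_colocalization, 0)
})

test_that("duplicated fields give 100% co-localization matching a brute-force recount", {
  set.seed(23)
  n <- 30
  sA <- spot_table(sprintf("n%02d", rep(1:10, 3)), "A",
                   runif(n, 0, 8000), runif(n, 0, 8000), runif(n, 0, 2000))
  fA <- merge_foci(sA)
  fB <- fA; fB$channel <- "B"
  res <- colocalize(fA, fB)
  expect_equal(res$percent_colocalization, 100)
  expect_equal(unname(res$percent_labelling), c(100, 100))
  ## brute-force recount of matches
  cnt <- 0L
  for (i in seq_len(nrow(fA))) for (j in seq_len(nrow(fB)))
    if (fA$nucleus_id[i] == fB$nucleus_id[j] &&
        sqrt((fA$x[i] - fB$x[j])^2 + (fA$y[i] - fB$y[j])^2) < 250 &&
        abs(fA$z[i] - fB$z[j]) < 600) cnt <- cnt + 1L
  expect_identical(nrow(res$matches), cnt)
  ## swapping channels with swapped direction preserves the match set
  swapped <- colocalize(fB, fA, direction = "B_in_A")
  expect_identical(nrow(swapped$matches), nrow(res$matches))
  expect_equal(swapped$percent_colocalization, res$percent_colocalization)
  ## empty numerator channel is flagged undefined
  empty <- fA[0, ]
  expect_true(colocalize(empty, fB)$undefined)
})

test_that("pairing calls use the inclusive 0.8 um edge-to-edge rule", {
  fA <- merge_foci(spot_table("n1", "A", 0, 0, 0))
  at800 <- merge_foci(spot_table("n1", "B", 800, 0, 0))
  at900 <- merge_foci(spot_table("n1", "B", 900, 0, 0))
  expect_identical(pairing_call(fA, at800)$call, "paired")
  expect_identical(pairing_call(fA, at900)$call, "unpaired")
  expect_identical(pairing_call(fA, at900[0, ])$call, "no_signal")
  ## radii count: centres 1000 apart, radii 150 + 150 -> edge 700 -> paired
  fat <- merge_foci(spot_table("n1", "B", 1000, 0, 0, radius = 150))
  fA2 <- merge_foci(spot_table("n1", "A", 0, 0, 0, radius = 150))
  expect_identical(pairing_call(fA2, fat)$call, "paired")
})

test_that("concordance reproduces the printed 92.1% and excludes no_signal nuclei", {
  mk_calls <- function(states) data.frame(
    nucleus_id = sprintf("n%03d", seq_along(states)), call = states,
    min_dist = NA_real_, stringsAsFactors = FALSE)
  ## reconstructed table: 29 both paired, 3 X-only, 5 Y-only, 64 both unpaired
  x <- mk_calls(c(rep("paired", 32), rep("unpaired", 69)))
  y <- mk_calls(c(rep("paired", 29), rep("unpaired", 3),
                  rep("paired", 5), rep("unpaired", 64)))
  res <- concordance_table(x, y)
  expect_identical(unlist(res$table[c("a", "b", "c", "d")],
                          use.names = FALSE), c(29L, 3L, 5L, 64L))
  expect_equal(round(100 * res$concordance, 1), 92.1)
  expect_identical(res$n_excluded, 0L)

  all_same <- concordance_table(x, x)
  expect_equal(all_same$concordance, 1)

  even <- concordance_table(
    mk_calls(rep(c("paired", "unpaired"), each = 20)),
    mk_calls(rep(c("paired", "unpaired"), times = 20)))
  expect_equal(even$concordance, 0.5)

  ## no_signal exclusion
  x2 <- mk_calls(c("paired", "no_signal", "unpaired"))
  y2 <- mk_calls(c("paired", "paired", "no_signal"))
  res2 <- concordance_table(x2, y2)
  expect_identical(res2$n_excluded, 2L)
  expect_identical(res2$table$a, 1L)
  expect_error(concordance_table(x2[0, ], y2), "no shared nuclei")
})

test_that("the exact test equals full enumeration and honours its symmetries", {
  r <- fisher_exact_two_tailed(contingency_table(5, 0, 0, 5))
  expect_equal(r$p_two_tailed, 2 / 252, tolerance = 1e-12)
  expect_identical(r$odds_ratio, Inf)

  set.seed(29)
  for (rep in 1:40) {
    t <- as.integer(rmultinom(1, sample(1:40, 1), rep(0.25, 4)))
    p <- fisher_exact_two_tailed(t)$p_two_tailed
    expect_equal(p, oracle_fisher_p(t[1], t[2], t[3], t[4]),
                 tolerance = 1e-12)
    expect_true(p >= 0 && p <= 1)
    ## transposition and simultaneous row+column swap invariance
    expect_equal(fisher_exact_two_tailed(c(t[1], t[3], t[2],
                                           t[4]))$p_two_tailed, p)
    expect_equal(fisher_exact_two_tailed(c(t[4], t[3], t[2],
                                           t[1]))$p_two_tailed, p)
    ## agreement with the stock implementation
    expect_equal(p, stats::fisher.test(matrix(t, 2))$p.value,
                 tolerance = 1e-9)
  }

  ## maximal point probability => p = 1
  expect_equal(fisher_exact_two_tailed(c(5, 5, 5, 5))$p_two_tailed, 1)
  ## odds-ratio conventions and error cases
  expect_identical(fisher_exact_two_tailed(c(0, 3, 2, 0))$odds_ratio, 0)
  expect_true(is.na(fisher_exact_two_tailed(c(0, 3, 0, 2))$odds_ratio))
  expect_error(fisher_exact_two_tailed(c(0, 0, 0, 0)), "all-zero")
})
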