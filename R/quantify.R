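## Quantification of FISH signals: focus merging, chromatic correction,
## co-localization, homologue-pairing calls, concordance and exact tests.

#' Spot table constructor / validator
#'
#' @param nucleus_id nucleus identifiers.
#' @param channel channel names.
#' @param x,y,z coordinates in nanometres.
#' @param radius spot radii in nanometres (default 0 = point signals).
#' @return data.frame with the canonical spot columns.
#' @export
spot_table <- function(nucleus_id, channel, x, y, z, radius = 0) {
  df <- data.frame(nucleus_id = as.character(nucleus_id),
                   channel = as.character(channel),
                   x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                   radius = as.numeric(radius), stringsAsFactors = FALSE)
  stopifnot(all(is.finite(df$x)), all(is.finite(df$y)), all(is.finite(df$z)),
            all(df$radius >= 0))
  df
}

## union-find for single-linkage clustering
.uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Merge nearby spots into foci
#'
#' Single-linkage clustering: two spots in the same nucleus and channel are
#' linked iff their edge-to-edge distance (euclidean centre distance minus
#' both radii) is strictly below `merge_dist`; the transitive closure of the
#' link relation defines the foci (so a chain of close signals is one
#' focus). The focus centroid is the unweighted mean of its members and the
#' effective radius is the radius of the smallest centroid-centred sphere
#' enclosing all member spheres.
#'
#' @param spots a [spot_table()].
#' @param merge_dist merge threshold in nanometres (default 1000 = 1 um).
#' @return data.frame of foci: nucleus_id, channel, x, y, z, radius,
#'   n_spots.
#' @export
#' @examples
#' s <- spot_table("n1", "red", c(0, 500), 0, 0)
#' merge_foci(s)  # one focus at x = 250
merge_foci <- function(spots, merge_dist = 1000) {
  stopifnot(merge_dist >= 0)
  out <- NULL
  for (key in unique(paste(spots$nucleus_id, spots$channel, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    g <- spots[spots$nucleus_id == parts[1] & spots$channel == parts[2], ,
               drop = FALSE]
    n <- nrow(g)
    parent <- seq_len(n)
    if (n > 1) {
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        d <- sqrt((g$x[i] - g$x[j])^2 + (g$y[i] - g$y[j])^2 +
                    (g$z[i] - g$z[j])^2) - g$radius[i] - g$radius[j]
        if (d < merge_dist) {
          ri <- .uf_find(parent, i); rj <- .uf_find(parent, j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
    comp <- vapply(seq_len(n), function(i) .uf_find(parent, i), integer(1))
    for (cc in unique(comp)) {
      m <- g[comp == cc, , drop = FALSE]
      cx <- mean(m$x); cy <- mean(m$y); cz <- mean(m$z)
      eff <- max(sqrt((m$x - cx)^2 + (m$y - cy)^2 + (m$z - cz)^2) + m$radius)
      out <- rbind(out, data.frame(nucleus_id = parts[1], channel = parts[2],
                                   x = cx, y = cy, z = cz, radius = eff,
                                   n_spots = nrow(m),
                                   stringsAsFactors = FALSE))
    }
  }
  out <- out %||% data.frame(nucleus_id = character(0), channel = character(0),
                             x = numeric(0), y = numeric(0), z = numeric(0),
                             radius = numeric(0), n_spots = integer(0))
  rownames(out) <- NULL
  out[order(out$nucleus_id, out$channel, out$x), , drop = FALSE]
}

#' Correct chromatic aberration between two channels
#'
#' Subtracts a constant measured offset vector from the coordinates of one
#' channel, registering it onto the other. The correction is tracked per
#' channel so accidentally applying it twice raises an error.
#'
#' @param spots a [spot_table()] (or foci table with the same columns).
#' @param channel the channel whose coordinates are shifted.
#' @param offset numeric length-3 offset vector in nanometres, subtracted
#'   from the channel's (x, y, z); e.g. `c(177, 0, 0)` for a 177 nm
#'   red/green lateral offset.
#' @return the corrected table, with the applied correction recorded in
#'   attribute `chromatic_corrected`.
#' @export
correct_chromatic <- function(spots, channel, offset) {
  stopifnot(length(offset) == 3, all(is.finite(offset)))
  done <- attr(spots, "chromatic_corrected") %||% character(0)
  if (channel %in% done)
    stop("chromatic correction already applied to channel '", channel, "'",
         call. = FALSE)
  sel <- spots$channel == channel
  spots$x[sel] <- spots$x[sel] - offset[1]
  spots$y[sel] <- spots$y[sel] - offset[2]
  spots$z[sel] <- spots$z[sel] - offset[3]
  attr(spots, "chromatic_corrected") <- c(done, channel)
  spots
}

#' Co-localization between two channels of foci
#'
#' Two foci co-localize iff their centre-to-centre lateral distance
#' satisfies `sqrt(dx^2 + dy^2) < xy_thresh` AND the axial distance
#' `|dz| < z_thresh` (both strict, approximating a diffraction-limited
#' signal). The headline percentage counts, in the numerator channel, foci
#' with at least one co-localizing partner; `direction = "A_in_B"` makes A
#' the numerator channel (e.g. A = secondary-oligo signals, B = primary
#' probe signals for the conventional secondary-in-primary reading).
#' `% labelling` per channel is the percentage of nuclei with at least one
#' focus in that channel.
#'
#' @param fociA,fociB foci tables (as from [merge_foci()]) for the two
#'   channels.
#' @param xy_thresh lateral threshold, nm (default 250).
#' @param z_thresh axial threshold, nm (default 600).
#' @param direction `"A_in_B"` or `"B_in_A"`: which channel is the numerator
#'   of the co-localization percentage.
#' @param nuclei optional character vector of all nucleus ids scored (for
#'   `% labelling`); defaults to the union of nuclei present in either
#'   table.
#' @return an object of class `colocalization_result`: list with `matches`
#'   (data.frame nucleus_id, a, b row indices), `percent_colocalization`
#'   (NA with `undefined = TRUE` when the numerator channel is empty),
#'   `percent_labelling` (named vector A/B), `direction`.
#' @export
colocalize <- function(fociA, fociB, xy_thresh = 250, z_thresh = 600,
                       direction = c("A_in_B", "B_in_A"), nuclei = NULL) {
  direction <- match.arg(direction)
  nuclei <- nuclei %||% union(fociA$nucleus_id, fociB$nucleus_id)
  matches <- data.frame(nucleus_id = character(0), a = integer(0),
                        b = integer(0))
  for (i in seq_len(nrow(fociA))) {
    js <- which(fociB$nucleus_id == fociA$nucleus_id[i])
    for (j in js) {
      dxy <- sqrt((fociA$x[i] - fociB$x[j])^2 + (fociA$y[i] - fociB$y[j])^2)
      dz <- abs(fociA$z[i] - fociB$z[j])
      if (dxy < xy_thresh && dz < z_thresh)
        matches <- rbind(matches,
                         data.frame(nucleus_id = fociA$nucleus_id[i],
                                    a = i, b = j, stringsAsFactors = FALSE))
    }
  }
  num_n <- if (direction == "A_in_B") nrow(fociA) else nrow(fociB)
  num_hit <- if (direction == "A_in_B") length(unique(matches$a))
             else length(unique(matches$b))
  undefined <- num_n == 0L
  pct <- if (undefined) NA_real_ else 100 * num_hit / num_n
  lab <- c(A = 100 * length(unique(fociA$nucleus_id)) / length(nuclei),
           B = 100 * length(unique(fociB$nucleus_id)) / length(nuclei))
  structure(list(matches = matches, percent_colocalization = pct,
                 undefined = undefined, percent_labelling = lab,
                 direction = direction,
                 n_foci = c(A = nrow(fociA), B = nrow(fociB))),
            class = "colocalization_result")
}

#' @export
print.colocalization_result <- function(x, ...) {
  cat(sprintf(paste0("colocalization_result (%s): %s co-localization; ",
                     "labelling A %.1f%%, B %.1f%%\n"),
              x$direction,
              if (x$undefined) "undefined"
              else sprintf("%.1f%%", x$percent_colocalization),
              x$percent_labelling["A"], x$percent_labelling["B"]))
  invisible(x)
}

#' Per-nucleus homologue pairing calls
#'
#' A nucleus is called `paired` iff the minimal edge-to-edge distance
#' (centre distance minus both effective radii) between any focus of channel
#' A and any focus of channel B is `<= pair_thresh` (inclusive);
#' `no_signal` if either channel has no focus in the nucleus.
#'
#' @param fociA,fociB foci tables for the two channels.
#' @param pair_thresh pairing threshold in nanometres (default 800 = 0.8 um).
#' @param nuclei optional vector of all nucleus ids; defaults to the union.
#' @return data.frame with nucleus_id, call (paired/unpaired/no_signal) and
#'   min_dist (NA for no_signal).
#' @export
pairing_call <- function(fociA, fociB, pair_thresh = 800, nuclei = NULL) {
  nuclei <- nuclei %||% union(fociA$nucleus_id, fociB$nucleus_id)
  call <- character(length(nuclei))
  mind <- rep(NA_real_, length(nuclei))
  for (k in seq_along(nuclei)) {
    a <- fociA[fociA$nucleus_id == nuclei[k], , drop = FALSE]
    b <- fociB[fociB$nucleus_id == nuclei[k], , drop = FALSE]
    if (nrow(a) == 0 || nrow(b) == 0) { call[k] <- "no_signal"; next }
    d <- Inf
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
      dij <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 +
                    (a$z[i] - b$z[j])^2) - a$radius[i] - b$radius[j]
      d <- min(d, dij)
    }
    mind[k] <- d
    call[k] <- if (d <= pair_thresh) "paired" else "unpaired"
  }
  data.frame(nucleus_id = nuclei, call = call, min_dist = mind,
             stringsAsFactors = FALSE)
}

#' 2x2 contingency table
#'
#' @param a,b,c,d non-negative cell counts: rows = condition X
#'   (paired/unpaired), columns = condition Y.
#' @return an object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  structure(as.list(counts), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("contingency_table: [%d %d; %d %d] (n=%d)\n",
              x$a, x$b, x$c, x$d, x$a + x$b + x$c + x$d))
  invisible(x)
}

#' Pairing concordance between two loci
#'
#' Cross-tabulates per-nucleus pairing calls of two loci over the nuclei
#' called in both (nuclei with `no_signal` at either locus are excluded and
#' counted): a = both paired, b = X paired / Y unpaired, c = X unpaired /
#' Y paired, d = both unpaired. Concordance = (a + d) / (a + b + c + d).
#'
#' @param callsX,callsY outputs of [pairing_call()] for the two loci.
#' @return list with `table` (a [contingency_table()]), `concordance`
#'   (fraction) and `n_excluded`.
#' @export
concordance_table <- function(callsX, callsY) {
  m <- merge(callsX[c("nucleus_id", "call")], callsY[c("nucleus_id", "call")],
             by = "nucleus_id", suffixes = c("_x", "_y"))
  if (nrow(m) == 0) stop("no shared nuclei between the two call sets",
                         call. = FALSE)
  excl <- m$call_x == "no_signal" | m$call_y == "no_signal"
  m <- m[!excl, , drop = FALSE]
  if (nrow(m) == 0) stop("all shared nuclei lack signal at one locus",
                         call. = FALSE)
  tab <- contingency_table(
    a = sum(m$call_x == "paired" & m$call_y == "paired"),
    b = sum(m$call_x == "paired" & m$call_y == "unpaired"),
    c = sum(m$call_x == "unpaired" & m$call_y == "paired"),
    d = sum(m$call_x == "unpaired" & m$call_y == "unpaired"))
  list(table = tab,
       concordance = (tab$a + tab$d) / (tab$a + tab$b + tab$c + tab$d),
       n_excluded = sum(excl))
}

#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Exact conditional test with fixed margins: the two-tailed p-value is the
#' sum of hypergeometric point probabilities of every table with the same
#' margins whose probability does not exceed that of the observed table
#' (ties resolved with a 1e-7 relative tolerance). The reported odds ratio
#' is the sample odds ratio ad/bc, with the conventions Inf when bc = 0
#' (and ad > 0) and 0 when ad = 0 (and bc > 0).
#'
#' @param table a [contingency_table()] or numeric length-4 vector
#'   (a, b, c, d).
#' @return an object of class `fisher_result`: list(p_two_tailed,
#'   odds_ratio).
#' @export
#' @examples
#' fisher_exact_two_tailed(contingency_table(29, 3, 5, 64))
fisher_exact_two_tailed <- function(table) {
  if (is.numeric(table) && length(table) == 4)
    table <- contingency_table(table[1], table[2], table[3], table[4])
  stopifnot(inherits(table, "contingency_table"))
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  n <- a + b + c + d
  if (n == 0) stop("all-zero contingency table", call. = FALSE)
  m1 <- a + b   # row 1 margin
  m2 <- c + d   # row 2 margin
  k <- a + c    # column 1 margin
  support <- max(0, k - m2):min(k, m1)
  probs <- dhyper(support, m1, m2, k)
  p_obs <- dhyper(a, m1, m2, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  p <- min(1, max(0, p))
  ad <- a * d; bc <- b * c
  or <- if (bc == 0 && ad == 0) NA_real_
        else if (bc == 0) Inf
        else ad / bc
  structure(list(p_two_tailed = p, odds_ratio = or, table = table),
            class = "fisher_result")
}

#' @export
print.fisher_result <- function(x, ...) {
  cat(sprintf("fisher_result: two-tailed P = %.3g, odds ratio = %.3g\n",
              x$p_two_tailed, x$odds_ratio))
  invisible(x)
}
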