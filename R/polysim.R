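## Simulation of STORM localizations on lattice polymer models: SAW growth,
## Monte-Carlo equilibration, exponential switching cycles, Gaussian
## localization noise, uniform background, subsampling and rendering.

#' Polymer chain on the simple cubic lattice
#'
#' @param coords integer matrix (n x 3) of monomer lattice coordinates; rows
#'   must be distinct (self-avoidance).
#' @return an object of class `polymer_chain`.
#' @export
polymer_chain <- function(coords) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  stopifnot(ncol(coords) == 3, nrow(coords) >= 1)
  if (anyDuplicated(as.data.frame(coords)))
    stop("chain is not self-avoiding", call. = FALSE)
  structure(list(coords = coords, n = nrow(coords)), class = "polymer_chain")
}

#' @export
print.polymer_chain <- function(x, ...) {
  cat(sprintf("polymer_chain: %d monomers, R_ee^2 = %.1f\n", x$n,
              sum((x$coords[x$n, ] - x$coords[1, ])^2)))
  invisible(x)
}

#' Grow a self-avoiding chain by random lattice addition
#'
#' Monomers are added one at a time to a uniformly chosen free neighbour
#' (of the 6 unit directions) of the growing end; occupied sites are
#' rejected. A chain stuck for more than 10 consecutive rejections has its
#' terminal 10 monomers (or all but the first) erased and growth resumes, so
#' the procedure always terminates.
#'
#' @param n number of monomers (>= 1).
#' @param seed optional RNG seed for reproducibility.
#' @return a [polymer_chain()] of exactly `n` monomers with unit bonds.
#' @export
#' @examples
#' chain <- grow_chain(600, seed = 1)
grow_chain <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  polymer_chain(.grow_chain_cpp(as.integer(n)))
}

#' Equilibrate a chain by bond-fluctuation and pivot Monte-Carlo moves
#'
#' Each sweep attempts `n` single-monomer displacements to a neighbouring
#' lattice site -- accepted iff the site is free and both adjacent bonds stay
#' within the allowed squared-length set \{1, 2, 3, 4, 5\} -- plus one pivot
#' move applying a random non-identity cubic point-group operation to the
#' chain segment beyond a random pivot, accepted iff the result is
#' self-avoiding. Chain length and self-avoidance are invariant.
#'
#' @param chain a [polymer_chain()].
#' @param n_sweeps number of sweeps (0 returns the chain unchanged).
#' @param seed optional RNG seed.
#' @return the equilibrated [polymer_chain()].
#' @export
equilibrate <- function(chain, n_sweeps, seed = NULL) {
  stopifnot(inherits(chain, "polymer_chain"), n_sweeps >= 0)
  if (n_sweeps == 0) return(chain)
  if (!is.null(seed)) set.seed(seed)
  polymer_chain(.equilibrate_cpp(chain$coords, as.integer(n_sweeps)))
}

#' Simulation parameters for STORM localization modelling
#'
#' Defaults follow standard dSTORM-style imaging of a Cy5-class dye: a mean
#' of 2 switching cycles (localizations) per monomer and a localization
#' precision of 1 monomer diameter.
#'
#' @param mean_cycles expected localizations per monomer (exponential mean).
#' @param sigma per-axis Gaussian localization noise, monomer diameters.
#' @param background_rate expected number of background localizations,
#'   uniform over the chain's bounding box expanded by 3 sigma; `NULL`
#'   defaults to 0.5% of the expected foreground count.
#' @param subsample_fraction fraction of localizations retained (in `[0,1]`).
#' @param seed optional RNG seed applied by [simulate_localizations()].
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(mean_cycles = 2, sigma = 1, background_rate = NULL,
                       subsample_fraction = 1, seed = NULL) {
  stopifnot(mean_cycles >= 0, sigma >= 0,
            subsample_fraction >= 0, subsample_fraction <= 1,
            is.null(background_rate) || background_rate >= 0)
  structure(list(mean_cycles = mean_cycles, sigma = sigma,
                 background_rate = background_rate,
                 subsample_fraction = subsample_fraction, seed = seed),
            class = "sim_params")
}

#' Simulate single-molecule localizations on a polymer chain
#'
#' Each monomer emits an integerised exponential number of localizations
#' (mean `mean_cycles`; the exponential draw is stochastically rounded,
#' `floor(x) + Bernoulli(x - floor(x))`, so the mean is preserved exactly).
#' Background localizations are placed uniformly over the chain's bounding
#' box expanded by 3 sigma. Independent Gaussian noise of s.d. `sigma` per
#' axis is then added to every localization. If
#' `params$subsample_fraction < 1` the retained subset is drawn by
#' [subsample_localizations()].
#'
#' @param chain a [polymer_chain()].
#' @param params a [sim_params()].
#' @return data.frame with columns x, y, z (monomer-diameter units) and
#'   origin (monomer index, NA for background events).
#' @export
#' @examples
#' chain <- grow_chain(100, seed = 1)
#' ev <- simulate_localizations(chain, sim_params(seed = 2))
#' nrow(ev) / 100  # about 2 localizations per monomer
simulate_localizations <- function(chain, params = sim_params()) {
  stopifnot(inherits(chain, "polymer_chain"), inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- chain$n
  if (params$mean_cycles > 0) {
    x <- rexp(n, rate = 1 / params$mean_cycles)
    counts <- floor(x) + (runif(n) < x - floor(x))
  } else counts <- integer(n)
  idx <- rep.int(seq_len(n), counts)
  ev <- data.frame(x = chain$coords[idx, 1], y = chain$coords[idx, 2],
                   z = chain$coords[idx, 3], origin = idx)
  bg_rate <- params$background_rate %||% (0.005 * n * params$mean_cycles)
  if (bg_rate > 0) {
    nb <- rpois(1, bg_rate)
    if (nb > 0) {
      lo <- apply(chain$coords, 2, min) - 3 * params$sigma
      hi <- apply(chain$coords, 2, max) + 3 * params$sigma
      bg <- data.frame(x = runif(nb, lo[1], hi[1]),
                       y = runif(nb, lo[2], hi[2]),
                       z = runif(nb, lo[3], hi[3]),
                       origin = NA_integer_)
      ev <- rbind(ev, bg)
    }
  }
  if (nrow(ev) && params$sigma > 0) {
    ev$x <- ev$x + rnorm(nrow(ev), 0, params$sigma)
    ev$y <- ev$y + rnorm(nrow(ev), 0, params$sigma)
    ev$z <- ev$z + rnorm(nrow(ev), 0, params$sigma)
  }
  rownames(ev) <- NULL
  if (params$subsample_fraction < 1)
    ev <- subsample_localizations(ev, params$subsample_fraction)
  ev
}

#' Randomly subsample localizations
#'
#' Retains a uniformly random subset of exactly `round(fraction * N)`
#' localizations (without replacement), preserving row order. Removing
#' two-thirds of localizations approximates the density obtained with a
#' single reporter dye instead of an activator-reporter pair.
#'
#' @param events localization data.frame (x, y, z, ...).
#' @param fraction fraction retained, in `[0, 1]`.
#' @param seed optional RNG seed.
#' @return subsampled data.frame.
#' @export
subsample_localizations <- function(events, fraction, seed = NULL) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(events)
  m <- round(fraction * n)
  if (m == n) return(events)
  out <- events[sort(sample.int(n, m)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Render localizations as a 2D density map
#'
#' Projects localizations onto (x, y) and renders either a plain 2D
#' histogram (pixel value = number of in-bounds localizations; grid sum is
#' conserved) or a sum of unit-mass Gaussian kernels of width `sigma_render`
#' (the conventional super-resolution display).
#'
#' @param events localization data.frame with columns x, y.
#' @param pixel_size pixel edge, monomer diameters (> 0).
#' @param mode `"histogram"` or `"gaussian"`.
#' @param extent optional list(xlim, ylim); default spans the events padded
#'   by one pixel.
#' @param sigma_render Gaussian kernel s.d. for `mode = "gaussian"`.
#' @return an object of class `density_map`: list(grid, pixel_size, mode,
#'   xlim, ylim). Grid rows index y, columns x.
#' @export
render_localizations <- function(events, pixel_size = 1,
                                 mode = c("histogram", "gaussian"),
                                 extent = NULL, sigma_render = 1) {
  mode <- match.arg(mode)
  stopifnot(pixel_size > 0)
  if (is.null(extent)) {
    if (nrow(events) == 0) extent <- list(xlim = c(0, pixel_size),
                                          ylim = c(0, pixel_size))
    else extent <- list(xlim = range(events$x) + c(-1, 1) * pixel_size,
                        ylim = range(events$y) + c(-1, 1) * pixel_size)
  }
  nx <- max(1L, ceiling(diff(extent$xlim) / pixel_size))
  ny <- max(1L, ceiling(diff(extent$ylim) / pixel_size))
  grid <- matrix(0, nrow = ny, ncol = nx)
  if (nrow(events)) {
    ix <- floor((events$x - extent$xlim[1]) / pixel_size) + 1L
    iy <- floor((events$y - extent$ylim[1]) / pixel_size) + 1L
    inb <- ix >= 1L & ix <= nx & iy >= 1L & iy <= ny
    if (mode == "histogram") {
      for (k in which(inb)) grid[iy[k], ix[k]] <- grid[iy[k], ix[k]] + 1
    } else {
      half <- max(1L, ceiling(5 * sigma_render / pixel_size))
      cx <- (seq_len(nx) - 0.5) * pixel_size + extent$xlim[1]
      cy <- (seq_len(ny) - 0.5) * pixel_size + extent$ylim[1]
      for (k in which(inb)) {
        jx <- max(1L, ix[k] - half):min(nx, ix[k] + half)
        jy <- max(1L, iy[k] - half):min(ny, iy[k] + half)
        d2 <- outer((cy[jy] - events$y[k])^2,
                    (cx[jx] - events$x[k])^2, "+")
        ## shift by the minimum so narrow kernels cannot underflow to 0/0
        kern <- exp(-(d2 - min(d2)) / (2 * sigma_render^2))
        grid[jy, jx] <- grid[jy, jx] + kern / sum(kern)
      }
    }
  }
  structure(list(grid = grid, pixel_size = pixel_size, mode = mode,
                 xlim = extent$xlim, ylim = extent$ylim),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("density_map (%s): %d x %d pixels of %g, total mass %.1f\n",
              x$mode, nrow(x$grid), ncol(x$grid), x$pixel_size,
              sum(x$grid)))
  invisible(x)
}

#' Count connected components of a thresholded density map
#'
#' Binarises the rendered grid at `threshold` and counts connected
#' foreground components (via EBImage). Used to quantify the fragmentation
#' of structures as localization density drops.
#'
#' @param map a `density_map`.
#' @param threshold pixels strictly above this value are foreground.
#' @return integer component count.
#' @export
count_components <- function(map, threshold = 0) {
  stopifnot(inherits(map, "density_map"))
  if (!requireNamespace("EBImage", quietly = TRUE))
    stop("count_components requires the EBImage package", call. = FALSE)
  bw <- map$grid > threshold
  if (!any(bw)) return(0L)
  max(EBImage::bwlabel(bw))
}
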