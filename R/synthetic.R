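#' Parameters for the synthetic fundus generator
#'
#' The generator emulates the properties that make fundus vessel
#' segmentation hard: low-contrast curvilinear vessel trees on a dark
#' reddish textured disc (the circular field of view) with imaging noise,
#' at a vessel:background pixel ratio of roughly 1:9. It makes no attempt
#' at physiological realism (no optic disc, fovea, or lesions).
#'
#' @param image_size square image side in pixels.
#' @param n_trees number of vessel trees seeded per attempt.
#' @param branch_prob per-step probability that a walker spawns a branch.
#' @param width_range `c(min, max)` stroke width in pixels; walkers start at
#'   the maximum and taper toward the minimum.
#' @param vessel_contrast fraction in `[0, 1)` by which vessels are darker
#'   than the local background (0 renders them invisible).
#' @param noise_sd Gaussian pixel noise standard deviation (intensity
#'   fraction).
#' @param fov_radius field-of-view radius as a fraction of half the image
#'   side.
#' @param vessel_fraction_band admissible vessel fraction of total pixels;
#'   the default 5-15% brackets the ~1:9.2 vessel:background ratio of real
#'   whole-frame fundus masks.
#' @param seed integer seed; all randomness derives from it.
#' @return A `vn_synth_params` list.
#' @export
synth_params <- function(image_size = 128L, n_trees = 4L,
                         branch_prob = 0.06, width_range = c(1L, 4L),
                         vessel_contrast = 0.55, noise_sd = 0.04,
                         fov_radius = 0.95,
                         vessel_fraction_band = c(0.05, 0.15), seed = 1L) {
  stopifnot(image_size >= 16, width_range[1] >= 1,
            width_range[2] >= width_range[1],
            vessel_contrast >= 0 && vessel_contrast < 1, noise_sd >= 0,
            fov_radius > 0 && fov_radius <= 1,
            vessel_fraction_band[1] < vessel_fraction_band[2])
  fov_area <- pi * (fov_radius / 2)^2  # fraction of total pixels
  if (vessel_fraction_band[1] >= fov_area)
    stop("infeasible vessel fraction band: lower bound exceeds the ",
         "field-of-view area fraction")
  structure(list(image_size = as.integer(image_size),
                 n_trees = as.integer(n_trees), branch_prob = branch_prob,
                 width_range = width_range,
                 vessel_contrast = vessel_contrast, noise_sd = noise_sd,
                 fov_radius = fov_radius,
                 vessel_fraction_band = vessel_fraction_band,
                 seed = as.integer(seed)), class = "vn_synth_params")
}

.fov_mask <- function(params) {
  s <- params$image_size
  ctr <- (s + 1) / 2
  r <- params$fov_radius * s / 2
  d2 <- outer((seq_len(s) - ctr)^2, (seq_len(s) - ctr)^2, `+`)
  d2 <= r^2
}

# Disc stamp offsets for a given stroke width (cached per call chain).
.disc_offsets <- function(width) {
  r <- max(0, (width - 1) / 2)
  k <- ceiling(r)
  g <- expand.grid(di = -k:k, dj = -k:k)
  g[g$di^2 + g$dj^2 <= (r + 0.5)^2, , drop = FALSE]
}

#' Generate a binary vessel-tree mask
#'
#' Vessel trees are biased random walks launched near the disc centre:
#' each walker steps outward with angular jitter, tapers in width, and
#' branches with probability `branch_prob`; strokes are dilated to the
#' walker width and clipped to the circular field of view. Trees are added
#' until the vessel fraction of total pixels enters the configured band
#' (generation stops as soon as it is exceeded, so the band is respected
#' from both sides).
#'
#' @param params a [synth_params()]; `params$seed` makes the mask
#'   bit-reproducible.
#' @return Binary matrix `image_size x image_size` (1 = vessel).
#' @export
generate_vessel_tree <- function(params) {
  stopifnot(inherits(params, "vn_synth_params"))
  s <- params$image_size
  fov <- .fov_mask(params)
  band <- params$vessel_fraction_band
  wmin <- params$width_range[1]; wmax <- params$width_range[2]
  mask <- matrix(0L, s, s)
  offs <- lapply(seq_len(wmax), .disc_offsets)
  ctr <- (s + 1) / 2
  n_set <- 0L
  stamp <- function(i, j, width) {
    o <- offs[[max(1L, round(width))]]
    ii <- pmin(pmax(i + o$di, 1L), s)
    jj <- pmin(pmax(j + o$dj, 1L), s)
    sel <- cbind(ii, jj)[fov[cbind(ii, jj)] & mask[cbind(ii, jj)] == 0L, ,
                         drop = FALSE]
    mask[sel] <<- 1L
    n_set <<- n_set + nrow(sel)
  }
  withr::with_seed(params$seed, {
    # stop stamping once the vessel fraction reaches a per-seed target
    # drawn from the interior of the admissible band
    target <- stats::runif(1, band[1] + 0.15 * diff(band),
                           band[2] - 0.15 * diff(band)) * s * s
    walkers <- list()
    launch <- function() {
      rad <- stats::runif(1, 0, 0.25) * s / 2
      th <- stats::runif(1, 0, 2 * pi)
      walkers[[length(walkers) + 1L]] <<- list(
        i = ctr + rad * sin(th), j = ctr + rad * cos(th),
        ang = stats::runif(1, 0, 2 * pi), width = wmax, depth = 1L)
    }
    for (t in seq_len(params$n_trees)) launch()
    launches <- params$n_trees
    max_launches <- 100L * params$n_trees
    while (n_set < target) {
      if (length(walkers) == 0L) {
        if (launches >= max_launches)
          stop("could not reach the vessel fraction band; increase ",
               "n_trees or width_range")
        launch()
        launches <- launches + 1L
      }
      w <- walkers[[length(walkers)]]
      walkers[[length(walkers)]] <- NULL
      for (step in seq_len(4L * s)) {
        stamp(round(w$i), round(w$j), w$width)
        if (n_set >= target) break
        w$i <- w$i + sin(w$ang); w$j <- w$j + cos(w$ang)
        w$ang <- w$ang + stats::rnorm(1, sd = 0.15)
        w$width <- max(wmin, w$width * 0.997)
        if ((w$i - ctr)^2 + (w$j - ctr)^2 >
              (params$fov_radius * s / 2)^2) break
        if (w$depth < 4L && stats::runif(1) < params$branch_prob)
          walkers[[length(walkers) + 1L]] <- list(
            i = w$i, j = w$j,
            ang = w$ang + sample(c(-1, 1), 1) * stats::runif(1, 0.4, 0.9),
            width = max(wmin, w$width * 0.8), depth = w$depth + 1L)
      }
    }
  })
  mask
}

#' Render a fundus-like RGB image for a vessel mask
#'
#' Dark reddish disc background with a radial falloff and smooth
#' low-frequency texture; vessel pixels are darkened by `vessel_contrast`;
#' Gaussian noise is added; everything outside the field of view is black.
#'
#' @param mask binary vessel mask from [generate_vessel_tree()].
#' @param params the matching [synth_params()] (rendering randomness derives
#'   from `params$seed`, offset so it is independent of the tree draw).
#' @return `H x W x 3` array in `[0, 1]`.
#' @export
render_fundus <- function(mask, params) {
  stopifnot(inherits(params, "vn_synth_params"))
  s <- params$image_size
  fov <- .fov_mask(params)
  ctr <- (s + 1) / 2
  r2 <- outer((seq_len(s) - ctr)^2, (seq_len(s) - ctr)^2, `+`)
  shade <- 0.85 - 0.45 * r2 / (s / 2)^2
  img <- array(0, dim = c(s, s, 3))
  withr::with_seed(params$seed + 1000003L, {
    # smooth texture: coarse white noise upsampled and box-blurred
    coarse <- matrix(stats::rnorm((s %/% 8)^2, sd = 0.08), s %/% 8)
    tex <- nn_resize(coarse, s, s)
    box <- matrix(1 / 9, 9, 1)
    for (k in 1:3)
      tex <- cpp_conv2d(array(tex, c(s, s, 1)), box, 0, 3, 3)[, , 1]
    vessel_factor <- 1 - params$vessel_contrast * mask
    base <- c(0.85, 0.42, 0.20)
    for (c in 1:3) {
      ch <- base[c] * (shade + tex) * vessel_factor
      if (params$noise_sd > 0)
        ch <- ch + stats::rnorm(s * s, sd = params$noise_sd)
      img[, , c] <- pmin(pmax(ch, 0), 1) * fov
    }
  })
  img
}

#' Generate a seeded synthetic dataset
#'
#' `n` image/mask pairs with disjoint per-pair seeds derived from the
#' master seed; identical master seed and parameters reproduce the dataset
#' bit-exactly.
#'
#' @param n number of pairs (>= 1).
#' @param params a [synth_params()]; `params$seed` is the master seed.
#' @return List of `n` [sample_pair()]s.
#' @export
generate_dataset <- function(n, params = synth_params()) {
  stopifnot(n >= 1)
  lapply(seq_len(n), function(k) {
    pk <- params
    pk$seed <- params$seed + 1000L * k
    mask <- generate_vessel_tree(pk)
    sample_pair(render_fundus(mask, pk), mask,
                provenance = sprintf("synth:%d", pk$seed))
  })
}
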