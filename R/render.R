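# Smooth low-frequency random field in [-1, 1] over an h x w grid, built
# from a handful of random plane waves. Used for intensity texture.
smooth_field <- function(h, w, n_waves = 3, min_period = 0.25) {
  rr <- matrix(seq_len(h), h, w) / h
  cc <- matrix(seq_len(w), h, w, byrow = TRUE) / w
  f <- matrix(0, h, w)
  for (i in seq_len(n_waves)) {
    k <- stats::runif(2, 0.5, 1 / min_period)
    phi <- stats::runif(1, 0, 2 * pi)
    f <- f + stats::runif(1, 0.5, 1) * cos(2 * pi * (k[1] * rr + k[2] * cc) + phi)
  }
  m <- max(abs(f))
  if (m > 0) f / m else f
}

# Union of filled interiors (centre + neighbours) as a 0/1 matrix.
all_interiors <- function(geometry) {
  h <- geometry$image_size[1]; w <- geometry$image_size[2]
  m <- fill_contour(geometry$center_outline, h, w)
  for (nb in geometry$neighbor_outlines)
    m <- pmax(m, fill_contour(nb, h, w))
  m
}

add_noise_clip <- function(img, noise_sd) {
  if (noise_sd > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                        nrow(img), ncol(img))
  clip01(img)
}

#' Render a fluorescence channel for a synthetic geometry
#'
#' Emulates the three marker classes: a cytoplasmic marker fills each cell up
#' to its boundary with smoothly varying intensity; a membrane marker forms a
#' bright band centred on each cell outline; a mitochondrial marker is a
#' speckle field confined strictly inside each cell, at least `mito_margin`
#' px away from the boundary (mitochondria do not reach the cell limits).
#'
#' @param geometry A [generate_cell_geometry()] result.
#' @param marker One of `"cyto"`, `"mem"`, `"mito"`.
#' @param config A [sim_config()]; controls noise, membrane width and the
#'   mitochondrial margin.
#' @param seed Integer seed.
#' @return An H x W intensity matrix in `[0, 1]`.
#' @export
render_fluorescence <- function(geometry, marker, config, seed = config$seed) {
  if (!marker %in% c("cyto", "mem", "mito"))
    stop_substacks(sprintf("unknown marker '%s' (use cyto, mem or mito)", marker),
                   "substacks_unknown_marker")
  h <- geometry$image_size[1]; w <- geometry$image_size[2]
  shapes <- c(list(geometry$center_shape), geometry$neighbor_shapes)
  with_rng(seed, {
    img <- matrix(0, h, w)
    if (marker == "cyto") {
      tex <- smooth_field(h, w)
      for (sh in shapes) {
        inside <- fill_contour(shape_outline(sh), h, w) == 1
        base <- stats::runif(1, 0.4, 0.95)   # expression varies per cell
        img[inside] <- pmax(img[inside], base * (0.8 + 0.2 * tex[inside]))
      }
      # membranes exclude cytoplasm: a shallow dark seam along every cell
      # outline, visible where neighbouring cells touch
      for (sh in shapes) {
        sf <- shape_signed_field(sh, h, w)
        img <- img * (1 - 0.3 * exp(-2 * (sf / 1.5)^2))
      }
    } else if (marker == "mem") {
      half <- config$membrane_width / 2
      for (sh in shapes) {
        sf <- shape_signed_field(sh, h, w)
        band <- stats::runif(1, 0.7, 0.95) * exp(-2 * (sf / half)^2)
        img <- pmax(img, band)
      }
    } else {
      for (sh in shapes) {
        # mitochondria cluster well inside the cell, and how far they
        # spread varies per cell, so the speckle hull does not determine
        # the boundary; the configured margin is only the lower bound
        margin <- max(config$mito_margin,
                      stats::runif(1, 0.2, 0.6) * sqrt(sh$a * sh$b))
        sigma <- stats::runif(1, 0.8, 1.5)
        sf <- shape_signed_field(sh, h, w)
        # candidate speckle centres: deep interior so that blob tails stay
        # at least `margin` px from the outline
        ok <- which(sf < -(margin + 3 * sigma), arr.ind = TRUE)
        if (nrow(ok) == 0) next
        area <- sum(sf < 0)
        n_spk <- max(3, round(area / 350 * stats::runif(1, 0.5, 1.5)))
        # perinuclear clustering: speckles concentrate towards a random
        # direction, so their hull does not simply trace the cell outline
        ang <- atan2(ok[, 1] - sh$cy, ok[, 2] - sh$cx)
        phi0 <- stats::runif(1, 0, 2 * pi)
        kappa <- stats::runif(1, 0.5, 2)
        wgt <- exp(kappa * cos(ang - phi0))
        pick <- ok[sample.int(nrow(ok), min(n_spk, nrow(ok)),
                              prob = wgt), , drop = FALSE]
        amp <- stats::runif(nrow(pick), 0.5, 0.95)
        win <- ceiling(3 * sigma)
        for (i in seq_len(nrow(pick))) {
          r0 <- pick[i, 1]; c0 <- pick[i, 2]
          rs <- max(1, r0 - win):min(h, r0 + win)
          cs <- max(1, c0 - win):min(w, c0 + win)
          d2 <- outer((rs - r0)^2, (cs - c0)^2, "+")
          img[rs, cs] <- pmax(img[rs, cs], amp[i] * exp(-d2 / (2 * sigma^2)))
        }
      }
    }
    add_noise_clip(img, config$noise_sd)
  })
}

# Difference-of-Gaussians rim profile across the boundary, normalised so the
# on-contour value is 1; side lobes emulate defocus under/overshoot.
dog_rim_profile <- function(signed_dist, sigma1, sigma2) {
  (exp(-signed_dist^2 / (2 * sigma1^2)) -
     0.6 * exp(-signed_dist^2 / (2 * sigma2^2))) / 0.4
}

#' Render a brightfield channel at a given focal offset
#'
#' The in-focus image is mid-gray with a faint interior texture. Defocus adds
#' a diffraction-like rim along each cell boundary whose signed amplitude is
#' `sign(offset) * rim_gain * |offset|`: positive offsets produce bright rims
#' (intensity peaks at the boundary), negative offsets dark rims (valleys),
#' and larger offsets produce stronger rims.
#'
#' @inheritParams render_fluorescence
#' @param focal_offset_um Signed focal offset in micrometres; must be one of
#'   `config$focal_offsets`.
#' @return An H x W intensity matrix in `[0, 1]`.
#' @export
render_brightfield <- function(geometry, focal_offset_um, config,
                               seed = config$seed) {
  if (!focal_offset_um %in% config$focal_offsets)
    stop_substacks(sprintf("focal offset %g um is not in the configured set (%s)",
                           focal_offset_um,
                           paste(config$focal_offsets, collapse = ", ")),
                   "substacks_invalid_offset")
  h <- geometry$image_size[1]; w <- geometry$image_size[2]
  shapes <- c(list(geometry$center_shape), geometry$neighbor_shapes)
  sigma1 <- max(1.5, config$image_size / 200)
  sigma2 <- 3 * sigma1
  with_rng(seed, {
    img <- matrix(0.5, h, w)
    tex <- smooth_field(h, w, n_waves = 4, min_period = 0.15)
    for (sh in shapes) {
      # cells are faintly visible in focus: a small per-cell brightness
      # offset plus low-contrast interior texture
      inside <- fill_contour(shape_outline(sh), h, w) == 1
      off <- stats::runif(1, 0.04, 0.1) * sample(c(-1, 1), 1)
      img[inside] <- 0.5 + off + 0.05 * tex[inside]
    }
    amp <- sign(focal_offset_um) * config$rim_gain * abs(focal_offset_um)
    if (amp != 0) {
      for (sh in shapes) {
        sf <- shape_signed_field(sh, h, w)
        img <- img + amp * dog_rim_profile(sf, sigma1, sigma2)
      }
    }
    add_noise_clip(img, config$noise_sd)
  })
}

#' Generate one synthetic hyper-labeled stack with its ground-truth mask
#'
#' Draws a field-of-view geometry and renders all ten canonical channels
#' (three fluorescence markers plus brightfield at every configured focal
#' offset). With probability `negative_fraction` the image is cell-free:
#' fluorescence channels contain camera noise only, brightfield is flat
#' mid-gray plus noise, and the mask is all background. Each fluorescence
#' marker is independently present with its `marker_presence_probs`
#' probability; absent markers render as dark (noise-only) channels. The
#' ground-truth mask covers the centre cell only, even when neighbours are
#' present.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A list with elements `stack` (a [hyperstack()]), `mask` (0/1
#'   integer matrix), `geometry` (`cell_geometry` or `NULL` for negatives),
#'   `is_negative`, and `markers_present` (character vector).
#' @export
generate_hyperstack <- function(config, seed = config$seed) {
  h <- w <- config$image_size
  is_negative <- with_rng(mix_seed(seed, 101),
                          stats::runif(1) < config$negative_fraction)
  probs <- config$marker_presence_probs
  present <- with_rng(mix_seed(seed, 102),
                      stats::runif(3) < probs[c("cyto", "mem", "mito")])
  names(present) <- c("cyto", "mem", "mito")

  blank_noise <- function(sd_seed)
    with_rng(sd_seed, add_noise_clip(matrix(0, h, w), config$noise_sd))

  channels <- list()
  if (is_negative) {
    geometry <- NULL
    for (i in 1:3)
      channels[[c("cyto", "mem", "mito")[i]]] <- blank_noise(mix_seed(seed, 200 + i))
    for (off in sort(config$focal_offsets))
      channels[[bf_channel_name(off)]] <- with_rng(
        mix_seed(seed, 300, round(off * 10)),
        add_noise_clip(matrix(0.5, h, w), config$noise_sd))
    mask <- matrix(0L, h, w)
  } else {
    geometry <- generate_cell_geometry(config, seed = mix_seed(seed, 103))
    for (i in 1:3) {
      m <- c("cyto", "mem", "mito")[i]
      channels[[m]] <- if (present[[m]])
        render_fluorescence(geometry, m, config, seed = mix_seed(seed, 200 + i))
      else blank_noise(mix_seed(seed, 200 + i))
    }
    for (off in sort(config$focal_offsets))
      channels[[bf_channel_name(off)]] <- render_brightfield(
        geometry, off, config, seed = mix_seed(seed, 300, round(off * 10)))
    mask <- fill_contour(geometry$center_outline, h, w)
  }
  list(stack = hyperstack(channels, source_id = sprintf("sim-%d", seed)),
       mask = mask,
       geometry = geometry,
       is_negative = is_negative,
       markers_present = names(present)[present])
}
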