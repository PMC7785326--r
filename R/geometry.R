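#' Simulation configuration
#'
#' Parameters of the synthetic microscopy generator. The defaults emulate the
#' structure of a real single-cell crop dataset: 400 x 400 px frames centred
#' on one fully annotated cell, roughly a quarter of cells isolated from
#' neighbours, three fluorescence markers always present, seven brightfield
#' focal planes, and a substantial fraction of cell-free negative frames.
#'
#' @param image_size Frame side length in px (square frames).
#' @param cell_radius_range Length-2 numeric, min/max mean cell radius in
#'   px. The default scales with the frame so the centre cell spans roughly
#'   half the crop, as in single-cell training crops.
#' @param boundary_roughness Amplitude of the smooth radial perturbation of
#'   the elliptical cell outline; 0 gives exact ellipses. Dimensionless,
#'   relative to the local ellipse radius; must be in `[0, 0.9]`.
#' @param isolated_fraction Probability that the centre cell has no adjacent
#'   neighbour (default 0.26).
#' @param marker_presence_probs Named numeric, probability that each
#'   fluorescence marker (`cyto`, `mem`, `mito`) is labeled in an image.
#' @param focal_offsets Brightfield focal offsets in micrometres; must
#'   include 0. Default `c(-10, -5, -3, 0, 3, 5, 10)`.
#' @param rim_gain Defocus rim amplitude per micrometre of defocus
#'   (intensity units, >= 0).
#' @param noise_sd Standard deviation of additive Gaussian camera noise.
#' @param negative_fraction Probability that a generated image is cell-free
#'   (default 175 / 450, the negative-control share of the emulated dataset).
#' @param membrane_width Membrane rim width in px.
#' @param mito_margin Minimum distance (px) of mitochondrial speckle support
#'   from the cell boundary; must be >= 3.
#' @param seed Default seed used when callers do not pass one.
#' @return A `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(image_size = 64, cell_radius_range = c(12, 18))
sim_config <- function(image_size = 400,
                       cell_radius_range = round(c(0.22, 0.33) * image_size),
                       boundary_roughness = 0.12,
                       isolated_fraction = 0.26,
                       marker_presence_probs = c(cyto = 1, mem = 1, mito = 1),
                       focal_offsets = c(-10, -5, -3, 0, 3, 5, 10),
                       rim_gain = 0.03,
                       noise_sd = 0.02,
                       negative_fraction = 175 / 450,
                       membrane_width = max(2, round(image_size / 100)),
                       mito_margin = max(3, round(image_size / 66)),
                       seed = 1L) {
  if (!is_prob(isolated_fraction) || !is_prob(negative_fraction))
    stop_substacks("isolated_fraction and negative_fraction must be in [0, 1]",
                   "substacks_invalid_config")
  if (!all(vapply(marker_presence_probs, is_prob, logical(1))))
    stop_substacks("marker_presence_probs must be probabilities in [0, 1]",
                   "substacks_invalid_config")
  if (!0 %in% focal_offsets)
    stop_substacks("focal_offsets must include 0", "substacks_invalid_config")
  if (rim_gain < 0)
    stop_substacks("rim_gain must be >= 0", "substacks_invalid_config")
  if (boundary_roughness < 0 || boundary_roughness > 0.9)
    stop_substacks("boundary_roughness must be in [0, 0.9]",
                   "substacks_invalid_config")
  if (mito_margin < 3)
    stop_substacks("mito_margin must be >= 3 px", "substacks_invalid_config")
  cfg <- list(image_size = as.integer(image_size),
              cell_radius_range = as.numeric(cell_radius_range),
              boundary_roughness = boundary_roughness,
              isolated_fraction = isolated_fraction,
              marker_presence_probs = marker_presence_probs,
              focal_offsets = as.numeric(focal_offsets),
              rim_gain = rim_gain,
              noise_sd = noise_sd,
              negative_fraction = negative_fraction,
              membrane_width = membrane_width,
              mito_margin = mito_margin,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_geometry(cfg)
  cfg
}

# The centre cell (radius plus a small margin) must fit inside the frame.
validate_sim_geometry <- function(config) {
  max_r <- max(config$cell_radius_range) * (1 + config$boundary_roughness)
  if (2 * (max_r + 2) > config$image_size)
    stop_substacks(sprintf(
      "cell radius up to %.1f px cannot fit in a %d px frame",
      max_r, config$image_size), "substacks_invalid_config")
  invisible(config)
}

# ---- star-shaped cell outlines ---------------------------------------------

# A cell shape is an ellipse with a smooth low-frequency radial perturbation:
# r(theta) = r_ellipse(theta) * (1 + roughness * s(theta)), where s is a sum
# of 2-6 Fourier harmonics with |s| <= 1.
random_cell_shape <- function(cx, cy, mean_radius, roughness) {
  aspect <- stats::runif(1, 0.65, 1)
  a <- mean_radius / sqrt(aspect)
  b <- mean_radius * sqrt(aspect)
  phi <- stats::runif(1, 0, pi)
  ks <- 2:6
  amp <- stats::runif(5)
  amp <- if (sum(amp) > 0) amp / sum(amp) else rep(0.2, 5)
  phase <- stats::runif(5, 0, 2 * pi)
  list(cx = cx, cy = cy, a = a, b = b, phi = phi,
       roughness = roughness, harm_k = ks, harm_amp = amp, harm_phase = phase)
}

# Radius of the outline in direction theta (vectorised over theta).
shape_radius <- function(shape, theta) {
  t2 <- theta - shape$phi
  re <- shape$a * shape$b /
    sqrt((shape$b * cos(t2))^2 + (shape$a * sin(t2))^2)
  s <- rep(0, length(theta))
  for (i in seq_along(shape$harm_k))
    s <- s + shape$harm_amp[i] *
      cos(shape$harm_k[i] * theta + shape$harm_phase[i])
  re * (1 + shape$roughness * s)
}

# Sample the outline as an n x 2 (row, col) matrix, counter-clockwise, open
# (last point differs from first; consumers treat it as closed).
shape_outline <- function(shape, n = 256) {
  theta <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- shape_radius(shape, theta)
  cbind(row = shape$cy + r * sin(theta), col = shape$cx + r * cos(theta))
}

# Max outline radius (upper bound, used for placement).
shape_max_radius <- function(shape)
  max(shape$a, shape$b) * (1 + shape$roughness)

#' Generate the geometry of one synthetic field of view
#'
#' Draws a centre cell (an ellipse perturbed by smooth low-frequency radial
#' noise) and, with probability `1 - isolated_fraction`, one to three
#' neighbouring cells placed in contact with it. The centre cell always lies
#' fully inside the frame; neighbours may extend beyond it.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed for this draw.
#' @return A `cell_geometry` object with elements `center_outline` (n x 2
#'   matrix of row/col coordinates), `neighbor_outlines` (list of matrices),
#'   `is_isolated`, `image_size`, and the underlying analytic shapes.
#' @export
#' @examples
#' g <- generate_cell_geometry(sim_config(image_size = 64,
#'                                        cell_radius_range = c(10, 14)), seed = 1)
#' g$is_isolated
generate_cell_geometry <- function(config, seed = config$seed) {
  validate_sim_geometry(config)
  with_rng(seed, {
    S <- config$image_size
    r_mean <- stats::runif(1, config$cell_radius_range[1],
                           config$cell_radius_range[2])
    max_r <- r_mean * (1 + config$boundary_roughness) / sqrt(0.65)
    slack <- max(0, (S / 2 - max_r - 2))
    jitter <- min(slack, S * 0.03)
    cx <- S / 2 + stats::runif(1, -jitter, jitter)
    cy <- S / 2 + stats::runif(1, -jitter, jitter)
    center <- random_cell_shape(cx, cy, r_mean, config$boundary_roughness)

    is_isolated <- stats::runif(1) < config$isolated_fraction
    neighbors <- list()
    if (!is_isolated) {
      n_nb <- sample(1:3, 1)
      for (i in seq_len(n_nb)) {
        theta0 <- stats::runif(1, 0, 2 * pi)
        nb_r <- stats::runif(1, 0.6, 1.1) * r_mean
        nb <- random_cell_shape(0, 0, nb_r, config$boundary_roughness)
        # contact: centres separated by the two directed radii plus a
        # hairline gap (cells touch but membranes keep them distinct)
        d <- shape_radius(center, theta0) +
          shape_radius(nb, theta0 + pi) + stats::runif(1, 0, 2)
        nb$cx <- cx + d * cos(theta0)
        nb$cy <- cy + d * sin(theta0)
        neighbors[[length(neighbors) + 1]] <- nb
      }
    } else if (stats::runif(1) < 0.5) {
      # isolated cells may still have a distant, non-adjacent neighbour
      theta0 <- stats::runif(1, 0, 2 * pi)
      nb_r <- stats::runif(1, 0.5, 0.9) * r_mean
      nb <- random_cell_shape(0, 0, nb_r, config$boundary_roughness)
      d <- shape_max_radius(center) + shape_max_radius(nb) +
        stats::runif(1, 8, 20)
      nb$cx <- cx + d * cos(theta0)
      nb$cy <- cy + d * sin(theta0)
      neighbors[[1]] <- nb
    }
    structure(list(
      center_outline = shape_outline(center),
      neighbor_outlines = lapply(neighbors, shape_outline),
      is_isolated = is_isolated,
      image_size = c(S, S),
      center_shape = center,
      neighbor_shapes = neighbors
    ), class = "cell_geometry")
  })
}

#' Rasterise a closed contour into a binary mask
#'
#' Even-odd scanline fill: a pixel (at integer row/col centres) is inside if
#' a horizontal ray from it crosses the polygon an odd number of times.
#'
#' @param outline n x 2 matrix of (row, col) vertices of a closed contour
#'   (last vertex implicitly joins the first).
#' @param h,w Output mask dimensions.
#' @return An `h` x `w` 0/1 integer matrix.
#' @export
fill_contour <- function(outline, h, w) {
  y1 <- outline[, 1]; x1 <- outline[, 2]
  y2 <- c(y1[-1], y1[1]); x2 <- c(x1[-1], x1[1])
  keep <- y1 != y2
  y1 <- y1[keep]; x1 <- x1[keep]; y2 <- y2[keep]; x2 <- x2[keep]
  mask <- matrix(0L, h, w)
  for (r in seq_len(h)) {
    crossing <- (y1 <= r & y2 > r) | (y2 <= r & y1 > r)
    if (!any(crossing)) next
    xi <- x1[crossing] + (r - y1[crossing]) *
      (x2[crossing] - x1[crossing]) / (y2[crossing] - y1[crossing])
    xi <- sort(xi)
    for (k in seq(1, length(xi) - 1, by = 2)) {
      c0 <- ceiling(xi[k] - 1e-9); c1 <- floor(xi[k + 1] + 1e-9)
      c0 <- max(1L, c0); c1 <- min(w, c1)
      if (c0 <= c1) mask[r, c0:c1] <- 1L
    }
  }
  mask
}

# Signed radial coordinate field for a shape: rho(pixel) - r_shape(theta),
# negative inside. Returned as an h x w matrix. Cheap proxy for the signed
# distance to a star-shaped outline, used to render rims and erosions.
shape_signed_field <- function(shape, h, w) {
  rr <- matrix(seq_len(h), h, w) - shape$cy
  cc <- matrix(seq_len(w), h, w, byrow = TRUE) - shape$cx
  rho <- sqrt(rr^2 + cc^2)
  theta <- atan2(rr, cc)
  rho - matrix(shape_radius(shape, as.vector(theta)), h, w)
}

# Minimum pairwise distance between two sampled contours.
contour_min_distance <- function(a, b) {
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  sqrt(min(d2))
}
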