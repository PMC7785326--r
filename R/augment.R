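#' Augmentation parameters
#'
#' Ranges of the training-time transforms: photometric (brightness,
#' contrast) applied to image channels only, and geometric (dihedral,
#' rotation, skew, perspective/symmetric warp, jitter) applied with identical
#' parameters to image and mask. Defaults are mild values that keep
#' synthetic cell images realistic; every range is configurable.
#'
#' @param brightness_range Additive brightness bounds (on `[0, 1]` scale).
#' @param contrast_range Multiplicative contrast bounds.
#' @param rotation_range Max absolute rotation in degrees.
#' @param skew_range Max absolute shear, as a tangent (dimensionless).
#' @param warp_magnitude Perspective warp strength (dimensionless, <= 0.5).
#' @param jitter_frac Max translation as a fraction of the image side.
#' @param dihedral,rotation,skew,warp,jitter,brightness,contrast Enable flags.
#' @param target_size Output side length in px after the final square crop +
#'   resize (default 400).
#' @return An `augment_params` list.
#' @export
augment_params <- function(brightness_range = c(-0.1, 0.1),
                           contrast_range = c(0.85, 1.15),
                           rotation_range = 180,
                           skew_range = 0.15,
                           warp_magnitude = 0.2,
                           jitter_frac = 0.05,
                           dihedral = TRUE, rotation = TRUE, skew = TRUE,
                           warp = TRUE, jitter = TRUE,
                           brightness = TRUE, contrast = TRUE,
                           target_size = 400) {
  if (target_size <= 0)
    stop_substacks("target_size must be positive", "substacks_invalid_config")
  structure(list(brightness_range = brightness_range,
                 contrast_range = contrast_range,
                 rotation_range = rotation_range,
                 skew_range = skew_range,
                 warp_magnitude = warp_magnitude,
                 jitter_frac = jitter_frac,
                 dihedral = dihedral, rotation = rotation, skew = skew,
                 warp = warp, jitter = jitter,
                 brightness = brightness, contrast = contrast,
                 target_size = as.integer(target_size)),
            class = "augment_params")
}

# Dihedral group element k in 0..7: k %% 4 quarter-turns, k >= 4 adds a flip.
dihedral_matrix <- function(k) {
  q <- k %% 4
  th <- q * pi / 2
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  if (k >= 4) R <- R %*% diag(c(-1, 1, 1))
  R
}

# Draw a random forward homography (centre-anchored) from the enabled
# geometric transforms. Coordinates are (x=col, y=row, 1).
draw_homography <- function(params, h, w) {
  M <- diag(3)
  if (params$dihedral)
    M <- M %*% dihedral_matrix(sample.int(8, 1) - 1L)
  if (params$rotation) {
    th <- stats::runif(1, -params$rotation_range, params$rotation_range) * pi / 180
    M <- M %*% matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  }
  if (params$skew) {
    sx <- stats::runif(1, -params$skew_range, params$skew_range)
    sy <- stats::runif(1, -params$skew_range, params$skew_range)
    M <- M %*% matrix(c(1, sy, 0, sx, 1, 0, 0, 0, 1), 3, 3)
  }
  if (params$warp) {
    g <- stats::runif(1, -params$warp_magnitude, params$warp_magnitude) / (w / 2)
    hh <- stats::runif(1, -params$warp_magnitude, params$warp_magnitude) / (h / 2)
    M <- M %*% matrix(c(1, 0, g, 0, 1, hh, 0, 0, 1), 3, 3)
  }
  if (params$jitter) {
    tx <- stats::runif(1, -1, 1) * params$jitter_frac * w
    ty <- stats::runif(1, -1, 1) * params$jitter_frac * h
    M <- matrix(c(1, 0, 0, 0, 1, 0, tx, ty, 1), 3, 3) %*% M
  }
  M
}

# Warp a matrix by the forward homography M (about the image centre) using
# nearest-neighbour sampling with zero fill. Nearest is used for image and
# mask alike so the two stay perfectly synchronised and binary channels stay
# binary (bilinear appears only in the final resize of image channels).
warp_matrix <- function(img, M) {
  h <- nrow(img); w <- ncol(img)
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  Minv <- solve(M)
  xo <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  yo <- matrix(seq_len(h), h, w) - cy
  d <- Minv[3, 1] * xo + Minv[3, 2] * yo + Minv[3, 3]
  xi <- (Minv[1, 1] * xo + Minv[1, 2] * yo + Minv[1, 3]) / d + cx
  yi <- (Minv[2, 1] * xo + Minv[2, 2] * yo + Minv[2, 3]) / d + cy
  matrix(nearest_sample(img, as.vector(yi), as.vector(xi)), h, w)
}

subimage_pixels <- function(sub) {
  if (inherits(sub, "subimage_stack")) sub$pixels
  else if (is.matrix(sub)) array(sub, dim = c(dim(sub), 1))
  else sub
}

rewrap_subimage <- function(sub, px) {
  if (inherits(sub, "subimage_stack")) { sub$pixels <- px; sub } else px
}

#' Augment a subimage stack and its mask jointly
#'
#' Applies the enabled geometric transforms with identical parameters to
#' every image channel and to the mask (zero fill outside the frame), then
#' photometric brightness/contrast to image channels only, then the final
#' centre square crop and resize to `params$target_size` (bilinear for image
#' channels, nearest for the mask). The mask is re-thresholded at 0.5 and is
#' guaranteed binary on output.
#'
#' @param sub A `subimage_stack` (or H x W x C array).
#' @param mask A 0/1 matrix of the same H x W.
#' @param params An [augment_params()].
#' @param seed Optional integer seed for this draw.
#' @return A list with `sub` and `mask`, both at `target_size`.
#' @export
augment_pair <- function(sub, mask, params = augment_params(), seed = NULL) {
  px <- subimage_pixels(sub)
  mask <- as_mask(mask)
  if (!all(dim(px)[1:2] == dim(mask)))
    stop_substacks("subimage and mask shapes differ",
                   "substacks_shape_mismatch")
  run <- function() {
    geom_on <- params$dihedral || params$rotation || params$skew ||
      params$warp || params$jitter
    if (geom_on) {
      M <- draw_homography(params, dim(px)[1], dim(px)[2])
      for (ch in seq_len(dim(px)[3])) px[, , ch] <- warp_matrix(px[, , ch], M)
      mask <- warp_matrix(mask, M)
    }
    if (params$brightness || params$contrast) {
      ct <- if (params$contrast)
        stats::runif(1, params$contrast_range[1], params$contrast_range[2]) else 1
      br <- if (params$brightness)
        stats::runif(1, params$brightness_range[1], params$brightness_range[2]) else 0
      px <- clip01(px * ct + br)
    }
    out <- crop_resize(px, mask, params$target_size)
    out$mask <- as_mask(1L * (out$mask >= 0.5))
    out
  }
  res <- if (is.null(seed)) run() else with_rng(seed, run())
  list(sub = rewrap_subimage(sub, res$px), mask = res$mask)
}

crop_resize <- function(px, mask, target) {
  C <- dim(px)[3]
  cm <- center_square_crop(mask)
  s <- nrow(cm)
  out_px <- array(0, dim = c(target, target, C))
  for (ch in seq_len(C))
    out_px[, , ch] <- resize_image(center_square_crop(px[, , ch]),
                                   target, target, "bilinear")
  list(px = out_px, mask = resize_image(cm, target, target, "nearest"))
}

#' Validation-time standardisation
#'
#' No augmentation beyond a deterministic centre square crop and resize to
#' `target_size` (bilinear for image channels, nearest for the mask).
#'
#' @inheritParams augment_pair
#' @param target_size Output side length in px.
#' @return A list with `sub` and `mask`.
#' @export
validation_transform <- function(sub, mask, target_size = 400) {
  px <- subimage_pixels(sub)
  mask <- as_mask(mask)
  if (!all(dim(px)[1:2] == dim(mask)))
    stop_substacks("subimage and mask shapes differ",
                   "substacks_shape_mismatch")
  out <- crop_resize(px, mask, target_size)
  list(sub = rewrap_subimage(sub, out$px), mask = as_mask(1L * (out$mask >= 0.5)))
}
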