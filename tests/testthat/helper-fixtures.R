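# Shared fixtures and independent oracles. Heavyweight synthetic datasets
# are generated once per session and cached.

fx_cache <- new.env(parent = emptyenv())

fx_once <- function(key, fn) {
  if (is.null(fx_cache[[key]])) fx_cache[[key]] <- fn()
  fx_cache[[key]]
}

# The scaled-down comparison world: 60 hyper-labeled stacks at 96 px.
fx_world96 <- function() fx_once("world96", function() {
  cfg <- sim_config(image_size = 96, seed = 1)
  list(config = cfg, dataset = simulate_dataset(cfg, 60, seed = 21))
})

# A small positive example (cell guaranteed) at 64 px.
fx_example64 <- function() fx_once("ex64", function() {
  cfg <- sim_config(image_size = 64, negative_fraction = 0, seed = 2)
  generate_hyperstack(cfg, seed = 4)
})

# Tiny constant-channel stack for loading-code arithmetic.
fx_const_stack <- function(vals = c(cyto = 0.2, mem = 0.6, mito = 0.4,
                                    bf0 = 0.5), n = 4) {
  hyperstack(lapply(vals, function(v) matrix(v, n, n)))
}

# Scaled-down training configuration used by the protocol tests: 12 epochs
# of the two-phase schedule with learning rates suited to a from-scratch
# reduced-width network.
fx_train_config <- function(code, target_size = 96, ...) {
  train_config(code, frozen_epochs = 1, unfrozen_epochs = 11,
               max_lr_phase1 = 1e-3, lr_range_phase2 = c(3e-4, 5e-3),
               batch_size = 4, split_seed = 5, run_seed = 7,
               augment = augment_params(target_size = target_size,
                                        rotation = FALSE, skew = FALSE,
                                        warp = FALSE, brightness = FALSE,
                                        contrast = FALSE),
               ...)
}

fx_model_cfg <- function() model_config(width_multiplier = 1/8)

# ---- independent oracles ----------------------------------------------------

# Point-in-polygon by ray crossing, coded independently of fill_contour.
oracle_in_polygon <- function(py, px, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(py))
  j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 1]; xi <- poly[i, 2]
    yj <- poly[j, 1]; xj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

oracle_fill <- function(poly, h, w) {
  g <- expand.grid(r = seq_len(h), c = seq_len(w))
  matrix(as.integer(oracle_in_polygon(g$r, g$c, poly)), h, w)
}

# Mean intensity profile along outward normals of a sampled contour:
# distances in px relative to the contour (negative = inside). Independent
# of the renderer's radial-field machinery.
oracle_normal_profile <- function(img, outline, distances) {
  n <- nrow(outline)
  nxt <- c(2:n, 1)
  tx <- outline[nxt, 2] - outline[, 2]
  ty <- outline[nxt, 1] - outline[, 1]
  len <- sqrt(tx^2 + ty^2)
  # outward normal of a counter-clockwise (in row-down coords) contour
  nx <- ty / len; ny <- -tx / len
  # orient away from the centroid
  cx <- mean(outline[, 2]); cy <- mean(outline[, 1])
  flip <- (outline[, 2] - cx) * nx + (outline[, 1] - cy) * ny < 0
  nx[flip] <- -nx[flip]; ny[flip] <- -ny[flip]
  vapply(distances, function(d) {
    r <- outline[, 1] + d * ny
    c <- outline[, 2] + d * nx
    ok <- r >= 1 & r <= nrow(img) & c >= 1 & c <= ncol(img)
    mean(img[cbind(round(r[ok]), round(c[ok]))])
  }, numeric(1))
}

# Rim contrast: on-contour mean minus the mean of the flanking bands.
oracle_rim_contrast <- function(img, outline) {
  prof <- oracle_normal_profile(img, outline, -8:8)
  prof[9] - mean(prof[c(1:3, 15:17)])
}

# Independent single-pixel weighted cross-entropy (naive direct form).
oracle_wce_pixel <- function(x, cls, w) w[cls] * (-x[cls] + log(sum(exp(x))))
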