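test_that("cell geometry respects isolation, roughness and frame limits", {
  cfg <- sim_config(image_size = 64, seed = 1)

  # degenerate probability: always isolated, no adjacent neighbour
  cfg_iso <- sim_config(image_size = 64, isolated_fraction = 1)
  for (s in 1:10) {
    g <- generate_cell_geometry(cfg_iso, seed = s)
    expect_true(g$is_isolated)
    for (nb in g$neighbor_outlines)
      expect_gt(substacks:::contour_min_distance(g$center_outline, nb), 2)
  }

  # centre cell fully inside the frame
  for (s in 1:10) {
    g <- generate_cell_geometry(cfg, seed = s)
    expect_true(all(g$center_outline >= 1 & g$center_outline <= 64))
  }

  # non-isolated cells have at least one neighbour within 2 px
  cfg_nb <- sim_config(image_size = 96, isolated_fraction = 0)
  for (s in 1:10) {
    g <- generate_cell_geometry(cfg_nb, seed = s)
    dmin <- min(vapply(g$neighbor_outlines, function(nb)
      substacks:::contour_min_distance(g$center_outline, nb), numeric(1)))
    expect_lte(dmin, 2)
  }

  # zero roughness gives an exact ellipse: radii from the centre obey the
  # ellipse equation to < 0.5 px radial deviation
  cfg0 <- sim_config(image_size = 64, boundary_roughness = 0)
  g0 <- generate_cell_geometry(cfg0, seed = 3)
  sh <- g0$center_shape
  th <- atan2(g0$center_outline[, 1] - sh$cy, g0$center_outline[, 2] - sh$cx)
  r_obs <- sqrt((g0$center_outline[, 1] - sh$cy)^2 +
                  (g0$center_outline[, 2] - sh$cx)^2)
  t2 <- th - sh$phi
  r_ell <- sh$a * sh$b / sqrt((sh$b * cos(t2))^2 + (sh$a * sin(t2))^2)
  expect_lt(max(abs(r_obs - r_ell)), 0.5)

  # invalid config: radius exceeding the frame
  expect_error(sim_config(image_size = 40, cell_radius_range = c(30, 40)),
               class = "substacks_invalid_config")
})

test_that("isolated fraction matches its binomial law over many draws", {
  # scaled draw count; the binomial oracle gives the central 99% interval
  cfg <- sim_config(image_size = 64, isolated_fraction = 0.26)
  n <- 600
  iso <- vapply(seq_len(n), function(s)
    generate_cell_geometry(cfg, seed = 10000 + s)$is_isolated, logical(1))
  lo <- qbinom(0.005, n, 0.26)
  hi <- qbinom(0.995, n, 0.26)
  expect_gte(sum(iso), lo)
  expect_lte(sum(iso), hi)
})

test_that("ground-truth mask equals the polygon-fill oracle", {
  cfg <- sim_config(image_size = 48, negative_fraction = 0)
  for (s in 1:5) {
    ex <- generate_hyperstack(cfg, seed = 100 + s)
    expect_identical(ex$mask,
                     oracle_fill(ex$geometry$center_outline, 48, 48))
  }
})

test_that("fluorescence renderers honour marker geometry", {
  cfg <- sim_config(image_size = 64, noise_sd = 0, negative_fraction = 0)
  g <- generate_cell_geometry(cfg, seed = 7)

  # cyto support equals the union of cell interiors exactly (noiseless)
  cyto <- render_fluorescence(g, "cyto", cfg, seed = 1)
  union <- substacks:::all_interiors(g)
  expect_identical(1L * (cyto > 0), union)

  # cyto covers the centre mask
  mask <- fill_contour(g$center_outline, 64, 64)
  expect_true(all(cyto[mask == 1] > 0))

  # mito support lies strictly inside, >= mito_margin px from any contour
  mito <- render_fluorescence(g, "mito", cfg, seed = 2)
  bright <- which(mito > 0.05, arr.ind = TRUE)
  expect_gt(nrow(bright), 0)
  contours <- c(list(g$center_outline), g$neighbor_outlines)
  dmin <- vapply(seq_len(nrow(bright)), function(i) {
    min(vapply(contours, function(ct)
      min(sqrt((ct[, 1] - bright[i, 1])^2 + (ct[, 2] - bright[i, 2])^2)),
      numeric(1)))
  }, numeric(1))
  inside_union <- union[bright] == 1
  expect_true(all(inside_union))
  expect_true(all(dmin >= cfg$mito_margin - 1))  # sampled-contour tolerance

  # membrane: contour intensity at least 2x the flanks at +-5 px
  mem <- render_fluorescence(g, "mem", cfg, seed = 3)
  prof <- oracle_normal_profile(mem, g$center_outline, c(-5, 0, 5))
  expect_gte(prof[2], 2 * prof[1])
  expect_gte(prof[2], 2 * prof[3])

  expect_error(render_fluorescence(g, "nucleus", cfg),
               class = "substacks_unknown_marker")
})

test_that("defocus rims flip sign and grow with |offset|", {
  cfg <- sim_config(image_size = 64, noise_sd = 0.01, negative_fraction = 0)
  for (s in 1:5) {
    g <- generate_cell_geometry(cfg, seed = 200 + s)
    rim <- function(off) oracle_rim_contrast(
      render_brightfield(g, off, cfg, seed = 9), g$center_outline)
    expect_gt(rim(5), 0)
    expect_lt(rim(-5), 0)
    expect_gt(abs(rim(10)), abs(rim(3)))
    expect_gt(abs(rim(-10)), abs(rim(-3)))
    expect_lt(abs(rim(0)), 3 * cfg$noise_sd)
  }
  g <- generate_cell_geometry(cfg, seed = 201)
  expect_error(render_brightfield(g, 7, cfg),
               class = "substacks_invalid_offset")
})

test_that("dataset generation is deterministic and structured", {
  cfg <- sim_config(image_size = 32, negative_fraction = 0.4, seed = 1)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- generate_dataset(cfg, 12, d1, seed = 5)
  m2 <- generate_dataset(cfg, 12, d2, seed = 5)

  # byte-identical images and identical manifests under a fixed seed
  strip_root <- function(m) { attr(m, "root") <- NULL; as.data.frame(m) }
  expect_equal(strip_root(m1), strip_root(m2))
  for (f in m1$image_path)
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))

  # different seed changes the data
  d3 <- withr::local_tempdir()
  m3 <- generate_dataset(cfg, 12, d3, seed = 6)
  expect_false(identical(
    readBin(file.path(d1, m1$image_path[1]), "raw", 1e6),
    readBin(file.path(d3, m3$image_path[1]), "raw", 1e6)))

  # negatives have empty masks; positives nonempty
  for (i in seq_len(nrow(m1))) {
    mk <- read_mask(file.path(d1, m1$mask_path[i]))
    if (m1$is_negative[i]) expect_equal(sum(mk), 0)
    else expect_gt(sum(mk), 0)
  }

  # no negatives requested -> every mask nonempty
  d4 <- withr::local_tempdir()
  m4 <- generate_dataset(sim_config(image_size = 32, negative_fraction = 0),
                         6, d4, seed = 2)
  expect_true(all(!m4$is_negative))

  # all markers present -> every fluorescence channel has variance
  for (i in which(!m1$is_negative)) {
    st <- read_hyperstack(file.path(d1, m1$image_path[i]))
    for (ch in c("cyto", "mem", "mito"))
      expect_gt(stats::var(as.vector(get_channel(st, ch))), 0)
  }
})
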