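#' Generate a synthetic hyper-labeled dataset on disk
#'
#' Writes `n_images` synthetic hyper-labeled stacks (multi-page TIFF), their
#' binary ground-truth masks (PNG) and a CSV manifest into `out_dir`. A
#' fraction `negative_fraction` of images are cell-free negatives with
#' all-background masks; fluorescence markers are independently present per
#' image according to `marker_presence_probs`. Fully deterministic given
#' `seed`: re-running with the same arguments reproduces the files
#' byte-for-byte.
#'
#' @param config A [sim_config()].
#' @param n_images Number of images to generate.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return The manifest tibble (invisibly also written to
#'   `out_dir/manifest.csv`), with its `root` attribute set.
#' @export
#' @examples
#' \donttest{
#' cfg <- sim_config(image_size = 48, cell_radius_range = c(8, 12))
#' man <- generate_dataset(cfg, n_images = 4, out_dir = tempfile(), seed = 1)
#' nrow(man)
#' }
generate_dataset <- function(config, n_images, out_dir, seed = config$seed) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop_substacks(sprintf("cannot create output directory: %s", out_dir),
                   "substacks_io_error")
  rows <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    ex <- generate_hyperstack(config, seed = mix_seed(seed, 7000, i))
    img_rel <- sprintf("img_%04d.tiff", i)
    mask_rel <- sprintf("mask_%04d.png", i)
    write_hyperstack(ex$stack, file.path(out_dir, img_rel))
    write_mask(ex$mask, file.path(out_dir, mask_rel))
    tag <- if (ex$is_negative) "" else
      with_rng(mix_seed(seed, 7500, i),
               sample(c("AD293", "INS1E"), 1, prob = c(106, 169)))
    rows[[i]] <- tibble::tibble(
      image_path = img_rel,
      mask_path = mask_rel,
      is_negative = ex$is_negative,
      cell_type_tag = tag,
      markers_present = paste(ex$markers_present, collapse = ";"))
  }
  manifest <- dplyr::bind_rows(rows)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  attr(manifest, "root") <- normalizePath(out_dir)
  invisible(manifest)
}
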