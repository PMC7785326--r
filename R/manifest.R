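#' Dataset manifests
#'
#' A manifest is a tibble with one row per image: `image_path`, `mask_path`
#' (relative to the manifest's directory), `is_negative`, `cell_type_tag`,
#' and `markers_present` (semicolon-separated). The manifest's directory is
#' carried in the `root` attribute so rows can be resolved to files.
#'
#' @param path CSV file path.
#' @param check_paths Verify at load time that every referenced file exists.
#' @return A tibble with attribute `root`.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path))
    stop_substacks(sprintf("manifest not found: %s", path),
                   "substacks_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(image_path = "character",
                                       mask_path = "character"))
  df <- tibble::as_tibble(df)
  root <- dirname(normalizePath(path))
  if (anyDuplicated(df$image_path))
    stop_substacks("duplicate image_path entries in manifest",
                   "substacks_bad_manifest")
  if (check_paths) {
    missing <- !file.exists(file.path(root, df$image_path)) |
      !file.exists(file.path(root, df$mask_path))
    if (any(missing))
      stop_substacks(sprintf("manifest references missing files, e.g. %s",
                             df$image_path[which(missing)[1]]),
                     "substacks_bad_manifest")
  }
  attr(df, "root") <- root
  df
}

#' @rdname read_manifest
#' @param manifest Manifest tibble.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE)
  invisible(path)
}

# Resolve a manifest row's files against its root.
manifest_paths <- function(manifest, i) {
  root <- attr(manifest, "root")
  if (is.null(root)) root <- "."
  list(image = file.path(root, manifest$image_path[i]),
       mask = file.path(root, manifest$mask_path[i]))
}
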