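#' Read and write binary ground-truth masks
#'
#' Masks are stored on disk as 8-bit grayscale PNG with values in
#' `{0, 255}` and held in memory as 0/1 integer matrices. Reading a PNG with
#' any other value is an error naming the offending values (on the 0-255
#' disk scale).
#'
#' @param path PNG file path.
#' @return `read_mask()`: an H x W 0/1 integer matrix.
#' @export
read_mask <- function(path) {
  if (!file.exists(path))
    stop_substacks(sprintf("file not found: %s", path), "substacks_io_error")
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  vals <- unique(as.vector(px))
  bad <- vals[!vals %in% c(0, 1)]
  if (length(bad) > 0)
    stop_substacks(sprintf("mask PNG is not binary; offending values: %s",
                           paste(round(utils::head(bad, 5) * 255),
                                 collapse = ", ")),
                   "substacks_nonbinary_mask")
  m <- matrix(as.integer(px), nrow(px), ncol(px))
  m
}

#' @rdname read_mask
#' @param mask H x W matrix with values in `{0, 1}`.
#' @return `write_mask()`: `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  mask <- as_mask(mask)
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}
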