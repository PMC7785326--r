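#' Hyper-labeled image stack
#'
#' A set of co-registered, named single-cell channel images: fluorescence
#' markers and brightfield focal planes sharing one field of view. Channels
#' are identified by NAME, never by index, so stacks with missing channels
#' remain usable; known canonical channels are stored in canonical order.
#'
#' @param channels Named list of H x W numeric matrices with values in
#'   `[0, 1]`.
#' @param pixel_size_um Optional pixel size in micrometres.
#' @param source_id Optional identifier of the source image.
#' @return A `hyperstack` object.
#' @export
#' @examples
#' hs <- hyperstack(list(cyto = matrix(0.5, 8, 8), bf0 = matrix(0.2, 8, 8)))
#' channel_names(hs)
hyperstack <- function(channels, pixel_size_um = NULL, source_id = "") {
  if (!is.list(channels) || length(channels) == 0)
    stop_substacks("a hyperstack needs at least one channel",
                   "substacks_empty_stack")
  nms <- names(channels)
  if (is.null(nms) || any(nms == ""))
    stop_substacks("all channels must be named", "substacks_bad_channel_names")
  if (anyDuplicated(nms))
    stop_substacks(sprintf("duplicate channel name(s): %s",
                           paste(unique(nms[duplicated(nms)]), collapse = ", ")),
                   "substacks_duplicate_channel")
  dims <- vapply(channels, function(m) dim(as.matrix(m)), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_substacks("all channels must share the same (H, W)",
                   "substacks_shape_mismatch")
  channels <- lapply(channels, as.matrix)
  # canonical channels first, in canonical order; any extras keep their order
  canon <- intersect(canonical_channels(), nms)
  channels <- channels[c(canon, setdiff(nms, canon))]
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 source_id = source_id),
            class = "hyperstack")
}

#' @export
print.hyperstack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<hyperstack> %d channel(s), %d x %d px\n",
              length(x$channels), d[1], d[2]))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  if (!is.null(x$pixel_size_um))
    cat(sprintf("  pixel size: %g um\n", x$pixel_size_um))
  invisible(x)
}

#' @rdname hyperstack
#' @param x A `hyperstack`.
#' @export
channel_names <- function(x) names(x$channels)

#' Extract one channel image from a hyperstack
#'
#' @param x A `hyperstack`.
#' @param name Channel name.
#' @param strict If `TRUE` (default) a missing channel is an error; otherwise
#'   an all-zero image of the stack's size is returned (blank substitute).
#' @return An H x W numeric matrix.
#' @export
get_channel <- function(x, name, strict = TRUE) {
  if (!name %in% names(x$channels)) {
    if (strict)
      stop_substacks(sprintf("channel '%s' not present (have: %s)", name,
                             paste(names(x$channels), collapse = ", ")),
                     "substacks_missing_channel")
    d <- dim(x$channels[[1]])
    return(matrix(0, d[1], d[2]))
  }
  x$channels[[name]]
}

stack_dim <- function(x) dim(x$channels[[1]])

#' Validate a binary mask
#'
#' @param pixels H x W matrix with values in `{0, 1}`.
#' @return The mask as an integer matrix, invisibly validated.
#' @export
as_mask <- function(pixels) {
  pixels <- as.matrix(pixels)
  bad <- setdiff(unique(as.vector(pixels)), c(0, 1))
  if (length(bad) > 0)
    stop_substacks(sprintf("mask is not binary; offending values: %s",
                           paste(utils::head(bad, 5), collapse = ", ")),
                   "substacks_nonbinary_mask")
  storage.mode(pixels) <- "integer"
  pixels
}
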