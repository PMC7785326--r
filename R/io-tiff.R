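# Minimal baseline TIFF 6.0 reader/writer (little-endian, uncompressed,
# single-sample grayscale, 8/16 bit), with per-page channel names in the
# PageName tag (285) and stack metadata as JSON in the first page's
# ImageDescription (270). No TIFF package exists in this R environment, so
# the subset needed for hyper-labeled stacks is implemented here.

TIFF_TYPE_SIZES <- c(`1` = 1, `2` = 1, `3` = 2, `4` = 4, `5` = 8)

# ---- writer -----------------------------------------------------------------

uint16_le <- function(x) {
  x <- as.integer(round(x))
  as.raw(c(rbind(x %% 256L, x %/% 256L)))
}

uint32_le <- function(x) {
  x <- as.numeric(x)
  as.raw(c(rbind(x %% 256, (x %/% 256) %% 256,
                 (x %/% 65536) %% 256, (x %/% 16777216) %% 256)))
}

# One 12-byte IFD entry. `value` is either an immediate value (fits in 4
# bytes) or an offset; caller decides.
ifd_entry <- function(tag, type, count, value4) {
  c(uint16_le(tag), uint16_le(type), uint32_le(count), value4)
}

entry_short <- function(tag, v) ifd_entry(tag, 3L, 1L, c(uint16_le(v), as.raw(c(0, 0))))
entry_long  <- function(tag, v) ifd_entry(tag, 4L, 1L, uint32_le(v))

#' Write a hyper-labeled stack as a multi-page TIFF
#'
#' One grayscale 16-bit page per channel, in the stack's (canonical) channel
#' order. Channel names go into each page's PageName tag; pixel size and
#' source id are stored as JSON in the first page's ImageDescription.
#' Intensities in `[0, 1]` are quantised to 16 bits, so a round trip through
#' [read_hyperstack()] preserves values to within 1/65535.
#'
#' @param stack A [hyperstack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hyperstack <- function(stack, path) {
  if (!inherits(stack, "hyperstack"))
    stack <- hyperstack(stack)
  nms <- names(stack$channels)
  n_pages <- length(nms)
  d <- stack_dim(stack); H <- d[1]; W <- d[2]

  meta <- jsonlite::toJSON(list(pixel_size_um = stack$pixel_size_um,
                                source_id = stack$source_id),
                           auto_unbox = TRUE, null = "null")
  meta_raw <- c(charToRaw(as.character(meta)), as.raw(0))
  if (length(meta_raw) %% 2 == 1) meta_raw <- c(meta_raw, as.raw(0))

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(c(charToRaw("II"), uint16_le(42)), con)

  # layout per page: [strip data][page name][description (page 1)][IFD]
  offset <- 8
  ifd_offsets <- numeric(n_pages)
  blocks <- vector("list", n_pages)
  for (p in seq_len(n_pages)) {
    img <- stack$channels[[p]]
    q <- round(clip01(img) * 65535)
    strip <- uint16_le(as.vector(t(q)))        # TIFF is row-major
    name_raw <- c(charToRaw(nms[p]), as.raw(0))
    if (length(name_raw) %% 2 == 1) name_raw <- c(name_raw, as.raw(0))
    # values of <= 4 bytes are stored inline in the IFD value field
    name_inline <- length(name_raw) <= 4
    name_block <- if (name_inline) raw(0) else name_raw

    strip_off <- offset
    name_off <- strip_off + length(strip)
    desc_off <- name_off + length(name_block)
    desc_raw <- if (p == 1) meta_raw else raw(0)
    ifd_off <- desc_off + length(desc_raw)

    entries <- list(
      entry_long(256, W),
      entry_long(257, H),
      entry_short(258, 16),
      entry_short(259, 1),                      # no compression
      entry_short(262, 1)                       # BlackIsZero
    )
    if (p == 1)
      entries <- c(entries, list(ifd_entry(270, 2L, length(desc_raw),
                                           uint32_le(desc_off))))
    entries <- c(entries, list(
      entry_long(273, strip_off),
      entry_short(277, 1),
      entry_long(278, H),
      entry_long(279, length(strip)),
      ifd_entry(285, 2L, length(name_raw),
                if (name_inline) c(name_raw, raw(4 - length(name_raw)))
                else uint32_le(name_off)),
      entry_short(339, 1)                       # unsigned integer samples
    ))
    ifd <- c(uint16_le(length(entries)), unlist(entries))
    ifd_offsets[p] <- ifd_off
    blocks[[p]] <- list(strip = strip, name = name_block, desc = desc_raw,
                        ifd = ifd)
    offset <- ifd_off + length(ifd) + 4         # + next-IFD pointer
  }
  writeBin(uint32_le(ifd_offsets[1]), con)
  for (p in seq_len(n_pages)) {
    b <- blocks[[p]]
    next_ptr <- if (p < n_pages) ifd_offsets[p + 1] else 0
    writeBin(c(b$strip, b$name, b$desc, b$ifd, uint32_le(next_ptr)), con)
  }
  invisible(path)
}

# ---- reader -----------------------------------------------------------------

rd_uint <- function(raw, off, n_bytes, little) {
  b <- as.integer(raw[off + seq_len(n_bytes)])
  if (!little) b <- rev(b)
  sum(b * 256^(seq_len(n_bytes) - 1))
}

#' Read a multi-page TIFF as a hyperstack
#'
#' Supports uncompressed grayscale baseline TIFF (8 or 16 bit, either byte
#' order, one or more strips per page). Channel names are taken from each
#' page's PageName tag (falling back to `channel_names` or `"page<k>"`);
#' intensities are mapped to `[0, 1]` by the sample dtype maximum.
#'
#' @param path TIFF file path.
#' @param channel_names Optional character vector overriding per-page names.
#' @return A [hyperstack()].
#' @export
read_hyperstack <- function(path, channel_names = NULL) {
  if (!file.exists(path))
    stop_substacks(sprintf("file not found: %s", path), "substacks_io_error")
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 8)
    stop_substacks(sprintf("not a TIFF file: %s", path), "substacks_io_error")
  order_tag <- rawToChar(raw[1:2])
  little <- order_tag == "II"
  if (!order_tag %in% c("II", "MM") || rd_uint(raw, 2, 2, little) != 42)
    stop_substacks(sprintf("not a TIFF file: %s", path), "substacks_io_error")

  read_tag_values <- function(entry_off) {
    tag <- rd_uint(raw, entry_off, 2, little)
    type <- rd_uint(raw, entry_off + 2, 2, little)
    count <- rd_uint(raw, entry_off + 4, 4, little)
    size <- TIFF_TYPE_SIZES[as.character(type)]
    if (is.na(size)) return(NULL)
    total <- size * count
    val_off <- if (total <= 4) entry_off + 8 else rd_uint(raw, entry_off + 8, 4, little)
    if (type == 2) {                            # ASCII
      bytes <- raw[val_off + seq_len(count)]
      nul <- which(bytes == as.raw(0))
      v <- rawToChar(bytes[seq_len(if (length(nul)) nul[1] - 1 else count)])
    } else {
      v <- vapply(seq_len(count) - 1, function(i)
        rd_uint(raw, val_off + i * size, size, little), numeric(1))
    }
    list(tag = tag, value = v)
  }

  pages <- list()
  meta <- NULL
  ifd_off <- rd_uint(raw, 4, 4, little)
  while (ifd_off != 0) {
    n_entries <- rd_uint(raw, ifd_off, 2, little)
    tags <- list()
    for (e in seq_len(n_entries)) {
      tv <- read_tag_values(ifd_off + 2 + (e - 1) * 12)
      if (!is.null(tv)) tags[[as.character(tv$tag)]] <- tv$value
    }
    W <- tags[["256"]]; H <- tags[["257"]]
    bits <- if (is.null(tags[["258"]])) 1 else tags[["258"]][1]
    comp <- if (is.null(tags[["259"]])) 1 else tags[["259"]]
    if (comp != 1)
      stop_substacks("only uncompressed TIFF is supported",
                     "substacks_io_error")
    if (!bits %in% c(8, 16))
      stop_substacks(sprintf("unsupported bit depth: %d", bits),
                     "substacks_io_error")
    offs <- tags[["273"]]; counts <- tags[["279"]]
    bpp <- bits / 8
    vals <- numeric(W * H)
    pos <- 0
    for (s in seq_along(offs)) {
      n_px <- counts[s] / bpp
      if (bpp == 1) {
        v <- as.integer(raw[offs[s] + seq_len(counts[s])])
      } else {
        b <- matrix(as.integer(raw[offs[s] + seq_len(counts[s])]), nrow = 2)
        v <- if (little) b[1, ] + 256 * b[2, ] else b[2, ] + 256 * b[1, ]
      }
      vals[pos + seq_len(n_px)] <- v
      pos <- pos + n_px
    }
    img <- matrix(vals / (2^bits - 1), nrow = H, ncol = W, byrow = TRUE)
    pages[[length(pages) + 1]] <- list(img = img, name = tags[["285"]])
    if (is.null(meta) && !is.null(tags[["270"]]))
      meta <- tryCatch(jsonlite::fromJSON(tags[["270"]]),
                       error = function(e) NULL)
    ifd_off <- rd_uint(raw, ifd_off + 2 + n_entries * 12, 4, little)
  }
  if (length(pages) == 0)
    stop_substacks(sprintf("TIFF has no pages: %s", path), "substacks_io_error")

  dims <- vapply(pages, function(p) dim(p$img), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_substacks("TIFF pages have mismatched shapes",
                   "substacks_shape_mismatch")

  nms <- if (!is.null(channel_names)) {
    if (length(channel_names) != length(pages))
      stop_substacks("channel_names length must match the page count",
                     "substacks_io_error")
    channel_names
  } else {
    vapply(seq_along(pages), function(i) {
      nm <- pages[[i]]$name
      if (is.null(nm) || !nzchar(nm)) sprintf("page%d", i) else nm
    }, character(1))
  }
  if (anyDuplicated(nms))
    stop_substacks(sprintf("duplicate channel name(s) in TIFF: %s",
                           paste(unique(nms[duplicated(nms)]), collapse = ", ")),
                   "substacks_duplicate_channel")
  channels <- stats::setNames(lapply(pages, `[[`, "img"), nms)
  hyperstack(channels,
             pixel_size_um = if (!is.null(meta)) meta$pixel_size_um else NULL,
             source_id = if (!is.null(meta) && !is.null(meta$source_id))
               meta$source_id else "")
}
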