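#' @importFrom Rcpp evalCpp
#' @useDynLib substacks, .registration = TRUE
NULL

# Classed condition helper: every user-facing error carries a subclass so
# callers (and tests) can branch on the failure mode, not on message text.
stop_substacks <- function(msg, class, call = NULL) {
  stop(errorCondition(msg, class = c(class, "substacks_error"),
                      call = call))
}

#' Evaluate an expression under a temporary RNG state
#'
#' Saves and restores `.Random.seed` so that seeded internals never disturb
#' the caller's random stream. All stochastic operations in the package draw
#' from explicit seeds through this helper.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic seed derivation: mixes a base seed with stream labels
# (epoch, sample index, ...) into a new seed < 2^31. SplitMix-style integer
# hash done in double precision to stay exact (values < 2^53).
mix_seed <- function(seed, ...) {
  x <- as.numeric(seed) %% 2147483647
  for (k in as.numeric(c(...))) {
    x <- (x * 48271 + k * 16807 + 12345) %% 2147483647
    x <- (x * 69621) %% 2147483647
  }
  as.integer(x %% 2147483629 + 1)
}

# Clip values into [lo, hi].
clip01 <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

is_prob <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x <= 1

#' Canonical channel names
#'
#' The ten channels of a hyper-labeled stack: three fluorescence markers
#' (cytoplasm, membrane, mitochondria) and seven brightfield focal planes at
#' -10, -5, -3, 0, +3, +5 and +10 um relative to manual focus.
#'
#' @return Character vector of the ten canonical channel names, in order.
#' @export
#' @examples
#' canonical_channels()
canonical_channels <- function() {
  c("cyto", "mem", "mito",
    "bf-10", "bf-5", "bf-3", "bf0", "bf+3", "bf+5", "bf+10")
}

# Map a focal offset in um to its canonical brightfield channel name.
bf_channel_name <- function(offset_um) {
  if (offset_um == 0) return("bf0")
  sprintf("bf%+d", as.integer(offset_um))
}

# ---- small image primitives shared by simulator / augmentation -------------

# Bilinear sample of matrix `img` at fractional (row, col) coordinates.
# Out-of-frame coordinates return `fill`.
bilinear_sample <- function(img, r, c, fill = 0) {
  H <- nrow(img); W <- ncol(img)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  get_px <- function(ri, ci) {
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    out <- rep(fill, length(ri))
    idx <- (ci[ok] - 1) * H + ri[ok]
    out[ok] <- img[idx]
    out
  }
  v00 <- get_px(r0,     c0)
  v01 <- get_px(r0,     c0 + 1)
  v10 <- get_px(r0 + 1, c0)
  v11 <- get_px(r0 + 1, c0 + 1)
  v00 * (1 - fr) * (1 - fc) + v01 * (1 - fr) * fc +
    v10 * fr * (1 - fc) + v11 * fr * fc
}

# Nearest-neighbour sample, zero fill outside the frame.
nearest_sample <- function(img, r, c, fill = 0) {
  H <- nrow(img); W <- ncol(img)
  ri <- round(r); ci <- round(c)
  ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
  out <- rep(fill, length(ri))
  out[ok] <- img[(ci[ok] - 1) * H + ri[ok]]
  out
}

# Resize a matrix to (h, w); method "bilinear" or "nearest".
resize_image <- function(img, h, w, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  H <- nrow(img); W <- ncol(img)
  if (H == h && W == w) return(img)
  # align-corners-false style mapping: output pixel centres onto input grid
  r <- (seq_len(h) - 0.5) * H / h + 0.5
  c <- (seq_len(w) - 0.5) * W / w + 0.5
  rc <- expand.grid(r = r, c = c)
  v <- if (method == "bilinear") {
    bilinear_sample(img, pmin(pmax(rc$r, 1), H), pmin(pmax(rc$c, 1), W))
  } else {
    nearest_sample(img, pmin(pmax(rc$r, 1), H), pmin(pmax(rc$c, 1), W))
  }
  matrix(v, nrow = h, ncol = w)
}

# Central square crop of a matrix.
center_square_crop <- function(img) {
  H <- nrow(img); W <- ncol(img)
  s <- min(H, W)
  r0 <- floor((H - s) / 2)
  c0 <- floor((W - s) / 2)
  img[(r0 + 1):(r0 + s), (c0 + 1):(c0 + s), drop = FALSE]
}
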