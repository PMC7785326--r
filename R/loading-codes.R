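#' Channel sources: the building blocks of a loading code
#'
#' A channel source says how one output channel of a subimage stack is built
#' from a hyper-labeled stack: `ch_simple()` loads a named channel directly;
#' `ch_random()` picks one channel uniformly at random from a candidate set;
#' `ch_merge()` averages several members (each itself simple or random) into
#' a single channel, optionally blanking individual members first ("merge
#' dropout").
#'
#' Merge semantics: with probability `merge_dropout`, each member is replaced
#' by an all-zero (blank) image *before* averaging, and the mean is always
#' taken over the full member count. Dropout therefore dims the merged
#' channel rather than renormalising it, and `merge_dropout = 1` yields an
#' all-black channel. Set `renormalize = TRUE` on [resolve_channel()] /
#' [assemble_subimage()] for the alternative mean-over-survivors semantics.
#'
#' @param name,candidates,members Channel name(s) from
#'   [canonical_channels()]; `members` may mix names and `ch_simple()` /
#'   `ch_random()` objects.
#' @param merge_dropout Per-member blanking probability in `[0, 1]`.
#' @return A `ch_source` object.
#' @export
ch_simple <- function(name) {
  check_channel_names(name)
  structure(list(kind = "simple", name = name),
            class = c("ch_simple", "ch_source"))
}

#' @rdname ch_simple
#' @export
ch_random <- function(candidates) {
  if (length(candidates) == 0)
    stop_substacks("random source needs at least one candidate",
                   "substacks_bad_code")
  check_channel_names(candidates)
  structure(list(kind = "random", candidates = unname(candidates)),
            class = c("ch_random", "ch_source"))
}

#' @rdname ch_simple
#' @export
ch_merge <- function(members, merge_dropout = 0) {
  if (length(members) == 0)
    stop_substacks("merge source needs at least one member",
                   "substacks_bad_code")
  if (!is_prob(merge_dropout))
    stop_substacks("merge_dropout must be a probability in [0, 1]",
                   "substacks_bad_code")
  members <- lapply(members, function(m) {
    if (inherits(m, "ch_merge"))
      stop_substacks("nested merges are not supported", "substacks_bad_code")
    if (inherits(m, "ch_source")) m else ch_simple(m)
  })
  structure(list(kind = "merge", members = members,
                 merge_dropout = merge_dropout),
            class = c("ch_merge", "ch_source"))
}

check_channel_names <- function(nms) {
  bad <- setdiff(nms, canonical_channels())
  if (length(bad) > 0)
    stop_substacks(sprintf("unknown channel name(s): %s (valid: %s)",
                           paste(bad, collapse = ", "),
                           paste(canonical_channels(), collapse = ", ")),
                   "substacks_unknown_channel")
  invisible(nms)
}

#' One output-channel specification of a loading code
#'
#' Pairs a [ch_simple()]/[ch_random()]/[ch_merge()] source with a channel
#' dropout rate: the probability that the fully resolved channel is replaced
#' by a blank (all-zero) channel, emulating an unlabeled cell.
#'
#' @param source A `ch_source`, or a channel name (treated as simple).
#' @param dropout Channel dropout probability in `[0, 1]`.
#' @return A `channel_spec` object.
#' @export
channel_spec <- function(source, dropout = 0) {
  if (!inherits(source, "ch_source")) source <- ch_simple(source)
  if (!is_prob(dropout))
    stop_substacks("dropout must be a probability in [0, 1]",
                   "substacks_bad_code")
  structure(list(source = source, dropout = dropout), class = "channel_spec")
}

#' Loading codes: per-channel assembly instructions
#'
#' A loading code is an ordered list of [channel_spec()]s, one per model
#' input channel (three by default), naming how each input channel of a
#' training subimage stack is assembled from a hyper-labeled stack.
#'
#' @param ... `channel_spec`s, `ch_source`s or channel names.
#' @param name Code name (used in comparison tables).
#' @return A `loading_code` object.
#' @export
#' @examples
#' code <- loading_code(
#'   channel_spec(ch_merge(c("cyto", "mem", "mito"), merge_dropout = 0.5)),
#'   "bf0",
#'   ch_random(c("bf+3", "bf+5", "bf+10")),
#'   name = "Merge+Br")
loading_code <- function(..., name = "code") {
  specs <- lapply(list(...), function(s)
    if (inherits(s, "channel_spec")) s else channel_spec(s))
  if (length(specs) < 1)
    stop_substacks("a loading code needs at least one channel spec",
                   "substacks_bad_code")
  structure(list(specs = specs, name = name), class = "loading_code")
}

#' @export
print.loading_code <- function(x, ...) {
  cat(sprintf("<loading_code> '%s' (%d channels)\n", x$name, length(x$specs)))
  for (i in seq_along(x$specs))
    cat(sprintf("  [%d] %s\n", i, describe_spec(x$specs[[i]])))
  invisible(x)
}

describe_source <- function(src) {
  switch(src$kind,
         simple = src$name,
         random = sprintf("random{%s}", paste(src$candidates, collapse = ",")),
         merge = sprintf("merge{%s; merge_dropout=%g}",
                         paste(vapply(src$members, describe_source,
                                      character(1)), collapse = ","),
                         src$merge_dropout))
}

describe_spec <- function(spec) {
  s <- describe_source(spec$source)
  if (spec$dropout > 0) s <- sprintf("%s | dropout=%g", s, spec$dropout)
  s
}

# ---- resolution -------------------------------------------------------------

blank_like <- function(stack) {
  d <- stack_dim(stack)
  matrix(0, d[1], d[2])
}

resolve_source <- function(src, stack, strict, renormalize) {
  if (src$kind == "simple") {
    list(img = get_channel(stack, src$name, strict = strict),
         desc = src$name)
  } else if (src$kind == "random") {
    pick <- src$candidates[[sample.int(length(src$candidates), 1)]]
    list(img = get_channel(stack, pick, strict = strict),
         desc = sprintf("random->%s", pick))
  } else {
    # draw dropout decisions in a canonical member order so that the merged
    # result is exactly invariant to the listed order of members
    descs <- vapply(src$members, describe_source, character(1))
    ord <- order(descs)
    n <- length(src$members)
    acc <- blank_like(stack)
    kept <- 0L
    member_desc <- character(n)
    for (j in seq_len(n)) {
      m <- src$members[[ord[j]]]
      res <- resolve_source(m, stack, strict, renormalize)
      dropped <- stats::runif(1) < src$merge_dropout
      if (!dropped) {
        acc <- acc + res$img
        kept <- kept + 1L
      }
      member_desc[j] <- paste0(res$desc, if (dropped) "[dropped]" else "")
    }
    denom <- if (renormalize) max(kept, 1L) else n
    img <- if (renormalize && kept == 0L) blank_like(stack) else acc / denom
    list(img = img,
         desc = sprintf("merge(%s)/%d", paste(member_desc, collapse = ","),
                        denom))
  }
}

#' Resolve one channel spec against a hyperstack
#'
#' Applies the source (simple load, uniform random choice, or merge with
#' per-member merge dropout), then the channel dropout test: with probability
#' `spec$dropout` the whole resolved channel is replaced by a blank
#' (all-zero) image.
#'
#' @param spec A [channel_spec()].
#' @param stack A [hyperstack()].
#' @param seed Optional integer seed; if `NULL`, draws from the current RNG
#'   stream (used when a caller seeds a whole assembly at once).
#' @param strict If `TRUE`, a referenced channel missing from the stack is an
#'   error; if `FALSE`, it resolves to a blank channel.
#' @param renormalize Merge semantics switch; see [ch_merge()].
#' @return A list with `img` (H x W matrix) and `provenance` (a one-line
#'   description of what was loaded and what was dropped).
#' @export
resolve_channel <- function(spec, stack, seed = NULL, strict = TRUE,
                            renormalize = FALSE) {
  run <- function() {
    res <- resolve_source(spec$source, stack, strict, renormalize)
    if (spec$dropout > 0 && stats::runif(1) < spec$dropout) {
      res$img <- blank_like(stack)
      res$desc <- paste0(res$desc, " -> blank[channel dropout]")
    }
    list(img = res$img, provenance = res$desc)
  }
  if (is.null(seed)) run() else with_rng(seed, run())
}

#' Assemble a subimage stack from a hyperstack via a loading code
#'
#' Resolves each channel spec of `code` independently and in order against
#' `stack`, producing the model's actual input: a C x H x W stack (stored as
#' an H x W x C array) with per-channel provenance. Deterministic given
#' `seed`.
#'
#' @inheritParams resolve_channel
#' @param code A [loading_code()].
#' @return A `subimage_stack`: list with `pixels` (H x W x C array in
#'   `[0, 1]`), `provenance` (character, one entry per channel) and
#'   `code_name`.
#' @export
assemble_subimage <- function(stack, code, seed = NULL, strict = TRUE,
                              renormalize = FALSE) {
  run <- function() {
    d <- stack_dim(stack)
    C <- length(code$specs)
    px <- array(0, dim = c(d[1], d[2], C))
    prov <- character(C)
    for (i in seq_len(C)) {
      res <- resolve_channel(code$specs[[i]], stack, seed = NULL,
                             strict = strict, renormalize = renormalize)
      px[, , i] <- res$img
      prov[i] <- res$provenance
    }
    structure(list(pixels = px, provenance = prov, code_name = code$name),
              class = "subimage_stack")
  }
  if (is.null(seed)) run() else with_rng(seed, run())
}

#' @export
print.subimage_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<subimage_stack> '%s' %d x %d x %d\n", x$code_name,
              d[1], d[2], d[3]))
  for (i in seq_len(d[3])) cat(sprintf("  [%d] %s\n", i, x$provenance[i]))
  invisible(x)
}

# ---- builtin codes ----------------------------------------------------------

oof_lower <- function() c("bf-10", "bf-5", "bf-3")
oof_upper <- function() c("bf+3", "bf+5", "bf+10")
oof_all <- function() c(oof_lower(), oof_upper())

#' The built-in model loading codes
#'
#' The named loading codes of the standard strategy comparison: single-marker
#' fluorescence models (`cytoplasm`, `membrane`, `mitochondria`), the
#' in-focus `brightfield` model, the three-marker `fluorescence` model, a
#' fully `random` model, the `all_black` negative control, fixed
#' symmetric-defocus brightfield trios (`Br3`, `Br5`, `Br10`), the
#' randomised-defocus `RAND_Br_A+B` model (one random lower out-of-focus
#' plane, the in-focus plane, one random upper plane), per-marker +
#' brightfield combinations (`cyto_br`, `mem_br`, `mito_br`), and the
#' `Merge+Br` model (merged fluorescence, in-focus brightfield, one random
#' out-of-focus brightfield).
#'
#' @param merge_dropout Merge dropout rate used by the `Merge+Br` code.
#' @param dropout Channel dropout rate applied to every fluorescence-bearing
#'   spec of the fluorescence-based codes (the dropout-robustness knob).
#' @param single_channel How single-channel models fill the three model
#'   inputs: `"replicate"` (default) repeats the one resolved channel on all
#'   three inputs; `"pad_blank"` pairs it with two always-blank channels.
#' @return Named list of [loading_code()]s.
#' @export
#' @examples
#' names(builtin_codes())
builtin_codes <- function(merge_dropout = 0, dropout = 0,
                          single_channel = c("replicate", "pad_blank")) {
  single_channel <- match.arg(single_channel)
  single <- function(nm, label) {
    sp <- channel_spec(ch_simple(nm), dropout = dropout)
    if (single_channel == "replicate")
      loading_code(sp, sp, sp, name = label)
    else
      loading_code(sp,
                   channel_spec(ch_simple(nm), dropout = 1),
                   channel_spec(ch_simple(nm), dropout = 1),
                   name = label)
  }
  single_bf <- function(nm, label) {
    sp <- channel_spec(ch_simple(nm), dropout = 0)  # brightfield: label-free
    if (single_channel == "replicate")
      loading_code(sp, sp, sp, name = label)
    else
      loading_code(sp, channel_spec(ch_simple(nm), dropout = 1),
                   channel_spec(ch_simple(nm), dropout = 1), name = label)
  }
  fl <- function(nm) channel_spec(ch_simple(nm), dropout = dropout)
  codes <- list(
    cytoplasm = single("cyto", "cytoplasm"),
    membrane = single("mem", "membrane"),
    mitochondria = single("mito", "mitochondria"),
    brightfield = single_bf("bf0", "brightfield"),
    fluorescence = loading_code(fl("cyto"), fl("mem"), fl("mito"),
                                name = "fluorescence"),
    random = loading_code(
      channel_spec(ch_random(canonical_channels()), dropout = dropout),
      channel_spec(ch_random(canonical_channels()), dropout = dropout),
      channel_spec(ch_random(canonical_channels()), dropout = dropout),
      name = "random"),
    all_black = loading_code(
      channel_spec(ch_simple("cyto"), dropout = 1),
      channel_spec(ch_simple("mem"), dropout = 1),
      channel_spec(ch_simple("mito"), dropout = 1),
      name = "all_black"),
    Br3 = loading_code("bf-3", "bf0", "bf+3", name = "Br3"),
    Br5 = loading_code("bf-5", "bf0", "bf+5", name = "Br5"),
    Br10 = loading_code("bf-10", "bf0", "bf+10", name = "Br10"),
    `RAND_Br_A+B` = loading_code(ch_random(oof_lower()), "bf0",
                                 ch_random(oof_upper()),
                                 name = "RAND_Br_A+B"),
    cyto_br = loading_code(fl("cyto"), "bf0", ch_random(oof_all()),
                           name = "cyto_br"),
    mem_br = loading_code(fl("mem"), "bf0", ch_random(oof_all()),
                          name = "mem_br"),
    mito_br = loading_code(fl("mito"), "bf0", ch_random(oof_all()),
                           name = "mito_br"),
    `Merge+Br` = loading_code(
      channel_spec(ch_merge(c("cyto", "mem", "mito"),
                            merge_dropout = merge_dropout),
                   dropout = dropout),
      "bf0", ch_random(oof_all()), name = "Merge+Br")
  )
  codes
}

# ---- dropout overrides (used by the sweep protocol) -------------------------

source_has_merge <- function(src) src$kind == "merge"

#' Override the dropout rates of a loading code
#'
#' Returns a copy of `code` with `merge_dropout` set on every merge source
#' and/or `channel_dropout` set on every spec whose source touches a
#' fluorescence channel (the label-dependent inputs). Used by the sweep
#' protocol to re-rate a template code.
#'
#' @param code A [loading_code()].
#' @param channel_dropout Optional new channel dropout rate.
#' @param merge_dropout Optional new merge dropout rate.
#' @return The modified `loading_code`.
#' @export
override_dropout <- function(code, channel_dropout = NULL,
                             merge_dropout = NULL) {
  fluo <- c("cyto", "mem", "mito")
  touches_fluo <- function(src) {
    switch(src$kind,
           simple = src$name %in% fluo,
           random = any(src$candidates %in% fluo),
           merge = any(vapply(src$members, touches_fluo, logical(1))))
  }
  code$specs <- lapply(code$specs, function(sp) {
    if (!is.null(merge_dropout) && sp$source$kind == "merge")
      sp$source$merge_dropout <- merge_dropout
    if (!is.null(channel_dropout) && touches_fluo(sp$source))
      sp$dropout <- channel_dropout
    sp
  })
  code
}

code_has_merge <- function(code)
  any(vapply(code$specs, function(sp) source_has_merge(sp$source), logical(1)))
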