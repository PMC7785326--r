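# Loading-code config grammar (YAML or JSON): a code is a list of channel
# entries, each one of
#   {simple: NAME}
#   {random: [NAMES]}
#   {merge: [NAMES or entries], merge_dropout: R}
# optionally carrying `dropout: R` (channel dropout) at the entry level.

parse_source_entry <- function(entry, where) {
  if (is.character(entry) && length(entry) == 1)
    return(ch_simple(entry))
  if (!is.list(entry))
    stop_substacks(sprintf("malformed loading-code entry at %s", where),
                   "substacks_bad_code")
  kinds <- intersect(names(entry), c("simple", "random", "merge"))
  if (length(kinds) != 1)
    stop_substacks(sprintf(
      "entry at %s must have exactly one of simple/random/merge", where),
      "substacks_bad_code")
  if (kinds == "simple") {
    ch_simple(entry$simple)
  } else if (kinds == "random") {
    ch_random(unlist(entry$random))
  } else {
    md <- entry$merge_dropout %||% 0
    if (!is_prob(md))
      stop_substacks(sprintf("merge_dropout at %s must be in [0, 1]", where),
                     "substacks_bad_code")
    members <- lapply(seq_along(entry$merge), function(j)
      parse_source_entry(entry$merge[[j]], sprintf("%s/merge[%d]", where, j)))
    ch_merge(members, merge_dropout = md)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse a loading code from config text or a config list
#'
#' Accepts YAML or JSON text (or a file path ending in .yaml/.yml/.json, or
#' an already-parsed list). Unknown channel names are rejected with a message
#' listing the valid canonical names. Round-trips with
#' [serialize_loading_code()].
#'
#' @param x Config text, file path, or list.
#' @param name Name for the resulting code; a top-level `name` field in the
#'   config takes precedence.
#' @return A [loading_code()].
#' @export
#' @examples
#' parse_loading_code(
#'   "[{merge: [cyto, mem, mito], merge_dropout: 0.5},
#'     {simple: bf0}, {random: [bf+3, bf+5, bf+10]}]", name = "Merge+Br")
parse_loading_code <- function(x, name = "code") {
  if (is.character(x) && length(x) == 1) {
    if (grepl("\\.(ya?ml|json)$", x) && file.exists(x))
      x <- paste(readLines(x, warn = FALSE), collapse = "\n")
    x <- tryCatch(yaml::yaml.load(x), error = function(e)
      stop_substacks(sprintf("loading-code config syntax error: %s",
                             conditionMessage(e)), "substacks_bad_code"))
  }
  if (!is.null(x$name)) { name <- x$name; x <- x$channels %||% x[setdiff(names(x), "name")] }
  if (!is.list(x) || length(x) == 0)
    stop_substacks("a loading-code config must be a nonempty list of entries",
                   "substacks_bad_code")
  # a single entry like {simple: cyto} parses as a named list; wrap it
  if (!is.null(names(x)) && any(names(x) %in% c("simple", "random", "merge")))
    x <- list(x)
  specs <- lapply(seq_along(x), function(i) {
    entry <- x[[i]]
    dropout <- 0
    if (is.list(entry) && !is.null(entry$dropout)) {
      dropout <- entry$dropout
      if (!is_prob(dropout))
        stop_substacks(sprintf("dropout at entry %d must be in [0, 1]", i),
                       "substacks_bad_code")
    }
    channel_spec(parse_source_entry(entry, sprintf("entry %d", i)),
                 dropout = dropout)
  })
  do.call(loading_code, c(specs, list(name = name)))
}

source_to_list <- function(src) {
  switch(src$kind,
         simple = list(simple = src$name),
         random = list(random = as.list(src$candidates)),
         merge = {
           out <- list(merge = lapply(src$members, source_to_list))
           if (src$merge_dropout > 0) out$merge_dropout <- src$merge_dropout
           out
         })
}

#' @rdname parse_loading_code
#' @param code A [loading_code()].
#' @return `serialize_loading_code()`: a YAML string in normalised form.
#' @export
serialize_loading_code <- function(code) {
  entries <- lapply(code$specs, function(sp) {
    out <- source_to_list(sp$source)
    if (sp$dropout > 0) out$dropout <- sp$dropout
    out
  })
  yaml::as.yaml(list(name = code$name, channels = entries))
}
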