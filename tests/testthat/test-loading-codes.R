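# helper: count blank resolutions over n draws from one seeded stream
with_seed_count <- function(spec, st, n) {
  substacks:::with_rng(7, {
    sum(vapply(seq_len(n), function(i)
      all(resolve_channel(spec, st)$img == 0), logical(1)))
  })
}

test_that("channel resolution follows the loading-code semantics", {
  st <- fx_const_stack()

  # identity: simple load without dropout is bit-identical
  r <- resolve_channel(channel_spec("cyto"), st, seed = 1)
  expect_identical(r$img, st$channels$cyto)

  # dropout 1 blanks any source
  for (src in list(ch_simple("cyto"), ch_random(c("cyto", "mem")),
                   ch_merge(c("cyto", "mem")))) {
    r <- resolve_channel(channel_spec(src, dropout = 1), st, seed = 2)
    expect_true(all(r$img == 0))
  }

  # merge arithmetic under the dilution semantics
  r <- resolve_channel(channel_spec(ch_merge(c("cyto", "mem"))), st, seed = 3)
  expect_equal(unique(as.vector(r$img)), 0.4)   # (0.2 + 0.6) / 2

  # with one member dropped the mean dims: constant 0.1 or 0.3
  seen <- character(0)
  for (s in 1:40) {
    r <- resolve_channel(channel_spec(
      ch_merge(c("cyto", "mem"), merge_dropout = 0.5)), st, seed = s)
    v <- unique(round(as.vector(r$img), 10))
    expect_length(v, 1)
    expect_true(v %in% c(0, 0.1, 0.3, 0.4))
    seen <- union(seen, v)
  }
  expect_setequal(round(as.numeric(seen), 10), c(0, 0.1, 0.3, 0.4))

  # renormalised alternative averages over survivors
  vals <- vapply(1:40, function(s) {
    unique(as.vector(resolve_channel(channel_spec(
      ch_merge(c("cyto", "mem"), merge_dropout = 0.5)), st, seed = s,
      renormalize = TRUE)$img))[1]
  }, numeric(1))
  expect_true(all(round(vals, 10) %in% c(0, 0.2, 0.6, 0.4)))

  # merge_dropout = 1 is an all-black channel
  r <- resolve_channel(channel_spec(
    ch_merge(c("cyto", "mem", "mito"), merge_dropout = 1)), st, seed = 4)
  expect_true(all(r$img == 0))

  # member order invariance, exact
  a <- resolve_channel(channel_spec(
    ch_merge(c("cyto", "mem", "mito"), merge_dropout = 0.3)), st, seed = 9)
  b <- resolve_channel(channel_spec(
    ch_merge(c("mito", "cyto", "mem"), merge_dropout = 0.3)), st, seed = 9)
  expect_identical(a$img, b$img)

  # strict policy errors on missing channels; blank policy substitutes
  expect_error(resolve_channel(channel_spec("bf+3"), st, seed = 1),
               class = "substacks_missing_channel")
  r <- resolve_channel(channel_spec("bf+3"), st, seed = 1, strict = FALSE)
  expect_true(all(r$img == 0))
})

test_that("dropout rates are statistically conformant (binomial oracle)", {
  st <- fx_const_stack(n = 2)
  n <- 2000
  for (rate in c(0.1, 0.5, 0.9)) {
    spec <- channel_spec("cyto", dropout = rate)
    blanks <- with_seed_count(spec, st, n)
    expect_gte(blanks, qbinom(0.0005, n, rate))
    expect_lte(blanks, qbinom(0.9995, n, rate))
  }
  # merge dropout per member follows the same law; the constant merged
  # value identifies how many members were blanked (0.4 -> 0, 0.1/0.3 -> 1,
  # 0 -> 2)
  spec <- channel_spec(ch_merge(c("cyto", "mem"), merge_dropout = 0.3))
  drops <- substacks:::with_rng(42, {
    vapply(seq_len(n), function(i) {
      v <- unique(round(as.vector(resolve_channel(spec, st)$img), 10))[1]
      c(`0.4` = 0, `0.1` = 1, `0.3` = 1, `0` = 2)[[format(v)]]
    }, numeric(1))
  })
  n_member_drops <- sum(drops)
  expect_gte(n_member_drops, qbinom(0.0005, 2 * n, 0.3))
  expect_lte(n_member_drops, qbinom(0.9995, 2 * n, 0.3))
})

test_that("random sources draw uniformly (chi-square oracle)", {
  st <- fx_const_stack(vals = c(cyto = 0.1, mem = 0.2, mito = 0.3,
                                bf0 = 0.4), n = 2)
  spec <- channel_spec(ch_random(c("cyto", "mem", "mito", "bf0")))
  n <- 4000
  picks <- substacks:::with_rng(11, {
    vapply(seq_len(n), function(i)
      resolve_channel(spec, st)$img[1, 1], numeric(1))
  })
  counts <- table(factor(picks, levels = c(0.1, 0.2, 0.3, 0.4)))
  p <- stats::chisq.test(counts, p = rep(0.25, 4))$p.value
  expect_gt(p, 0.001)
})

test_that("assembly is ordered, seeded and in range", {
  ex <- fx_example64()
  code <- builtin_codes()$fluorescence

  s1 <- assemble_subimage(ex$stack, code, seed = 5)
  s2 <- assemble_subimage(ex$stack, code, seed = 5)
  expect_identical(s1$pixels, s2$pixels)        # same seed, same bytes
  expect_identical(dim(s1$pixels), c(64L, 64L, 3L))
  expect_identical(s1$pixels[, , 1], get_channel(ex$stack, "cyto"))
  expect_identical(s1$pixels[, , 2], get_channel(ex$stack, "mem"))
  expect_identical(s1$pixels[, , 3], get_channel(ex$stack, "mito"))

  # RAND Br A+B picks lower / in-focus / upper planes
  rb <- assemble_subimage(ex$stack, builtin_codes()$`RAND_Br_A+B`, seed = 8)
  expect_match(rb$provenance[1], "bf-(10|5|3)")
  expect_identical(rb$pixels[, , 2], get_channel(ex$stack, "bf0"))
  expect_match(rb$provenance[3], "bf\\+(3|5|10)")

  # all-black assembles to a zero stack
  ab <- assemble_subimage(ex$stack, builtin_codes()$all_black, seed = 1)
  expect_true(all(ab$pixels == 0))

  # every builtin code assembles on a canonical stack, values in [0, 1]
  for (nm in names(builtin_codes())) {
    sub <- assemble_subimage(ex$stack, builtin_codes()[[nm]], seed = 3)
    expect_identical(dim(sub$pixels), c(64L, 64L, 3L))
    expect_true(all(sub$pixels >= 0 & sub$pixels <= 1), label = nm)
  }
})

test_that("builtin Merge+Br has the documented structure", {
  code <- builtin_codes(merge_dropout = 0.5)$`Merge+Br`
  expect_length(code$specs, 3)
  src1 <- code$specs[[1]]$source
  expect_s3_class(src1, "ch_merge")
  expect_setequal(vapply(src1$members, function(m) m$name, character(1)),
                  c("cyto", "mem", "mito"))
  expect_equal(src1$merge_dropout, 0.5)
  expect_identical(code$specs[[2]]$source$name, "bf0")
  expect_s3_class(code$specs[[3]]$source, "ch_random")
  expect_true(all(grepl("^bf", code$specs[[3]]$source$candidates)))
})

test_that("override_dropout re-rates fluorescence and merge specs", {
  code <- builtin_codes()$`Merge+Br`
  c2 <- override_dropout(code, merge_dropout = 0.7)
  expect_equal(c2$specs[[1]]$source$merge_dropout, 0.7)
  c3 <- override_dropout(builtin_codes()$fluorescence, channel_dropout = 0.4)
  for (sp in c3$specs) expect_equal(sp$dropout, 0.4)
  # brightfield specs are untouched by channel-dropout overrides
  c4 <- override_dropout(code, channel_dropout = 0.4)
  expect_equal(c4$specs[[2]]$dropout, 0)
})

test_that("loading-code configs parse, validate and round-trip", {
  code <- parse_loading_code(
    "[{merge: [cyto, mem, mito], merge_dropout: 0.5}, {simple: bf0},
      {random: [bf+3, bf+5, bf+10]}]", name = "Merge+Br")
  expect_s3_class(code$specs[[1]]$source, "ch_merge")
  expect_equal(code$specs[[1]]$source$merge_dropout, 0.5)
  expect_identical(code$specs[[2]]$source$name, "bf0")

  err <- expect_error(parse_loading_code("[{simple: nucleus}]"),
                      class = "substacks_unknown_channel")
  expect_match(conditionMessage(err), "cyto")   # lists valid names
  expect_error(parse_loading_code("[{simple: cyto, dropout: 1.5}]"),
               class = "substacks_bad_code")

  # serialisation round trip is a fixed point over random codes
  rand_code <- function(seed) substacks:::with_rng(seed, {
    mk_src <- function() {
      k <- sample(3, 1)
      if (k == 1) list(simple = sample(canonical_channels(), 1))
      else if (k == 2)
        list(random = as.list(sample(canonical_channels(),
                                     sample(2:4, 1))))
      else list(merge = lapply(sample(canonical_channels(), sample(2:3, 1)),
                               function(x) list(simple = x)),
                merge_dropout = round(runif(1), 2))
    }
    lapply(seq_len(sample(1:4, 1)), function(i) {
      e <- mk_src()
      if (runif(1) < 0.5) e$dropout <- round(runif(1), 2)
      e
    })
  })
  for (s in 1:50) {
    cfg <- rand_code(s)
    norm <- serialize_loading_code(parse_loading_code(cfg))
    expect_identical(serialize_loading_code(parse_loading_code(norm)), norm)
  }
})
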