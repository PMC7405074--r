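# Hierarchical compression: savings, greedy replacement, nesting, library,
# blocks and delta-compressibility.

test_that("savings follows W*N - (W + 1 + N)", {
  expect_equal(savings(2, 4), 1)
  expect_equal(savings(3, 5), 6)
  expect_equal(savings(1, 1), -2)
  expect_equal(savings(1, 7), -2)
  expect_equal(savings(1, 100), -2) # single symbols never compress
})

test_that("hand-run compressions match the heuristic", {
  # a b a b a b a b: (a b) x4 and (a b a b) x2 both save exactly 1; the
  # longer-motif tie-break picks the 4-gram, compressibility is 1/8 either way
  g <- compress_sequence(rep(c(1L, 2L), 4))
  expect_equal(nrow(g$rules), 1)
  expect_equal(g$rules$savings, 1)
  expect_equal(g$compressibility, 1 / 8)
  expect_true(identical(g$defs[[1]], c(1L, 2L, 1L, 2L)) ||
                identical(g$defs[[1]], c(1L, 2L)))

  expect_equal(compress_sequence(1:9)$compressibility, 0) # all distinct

  g3 <- compress_sequence(rep(1:3, 4)) # (a b c) x4 beats (a b)
  expect_equal(g3$defs[[1]], 1:3)
  expect_equal(g3$rules$savings[1], 4)
  expect_equal(g3$compressibility, 1 / 3)
})

test_that("tie-breaks prefer longer motifs then lexicographic order", {
  # the 4-gram (3 4 1 2) ties the bigrams at savings 1 -> longer wins
  g <- compress_sequence(c(3L, 4L, 1L, 2L, 3L, 4L, 1L, 2L))
  expect_equal(g$defs[[1]], c(3L, 4L, 1L, 2L))
  # only the bigrams (3 4) and (1 2) repeat (4 times each, separated so no
  # longer gram recurs): equal savings -> lexicographically smallest wins
  x <- c(3L, 4L, 20L, 1L, 2L, 21L, 3L, 4L, 22L, 1L, 2L, 23L,
         3L, 4L, 24L, 1L, 2L, 25L, 3L, 4L, 26L, 1L, 2L, 27L)
  g2 <- compress_sequence(x)
  expect_equal(g2$defs[[1]], c(1L, 2L))
})

test_that("candidate motifs never span break sentinels", {
  x <- c(1L, 2L, 0L, 1L, 2L, 0L, 1L, 2L, 0L, 1L, 2L)
  g <- compress_sequence(x)
  expect_equal(g$defs[[1]], c(1L, 2L))
  expect_equal(g$rules$count, 4)
  expect_equal(g$original_length, 8) # sentinels excluded from the length
  expect_identical(expand_sequence(g), x) # sentinels preserved
})

test_that("expansion inverts compression (round trip, fuzzed)", {
  expect_equal(expand_symbol(2L, compress_sequence(rep(1:2, 3))), 2L)
  # hand-built two-level grammar: X -> (1 2), Y -> (X X)
  g0 <- structure(list(
    rules = data.frame(symbol = c(10L, 11L), savings = c(1L, 1L),
                       count = c(2L, 2L), length = c(2L, 2L)),
    defs = list(c(1L, 2L), c(10L, 10L)), compressed = 11L,
    original_length = 4, compressibility = 0.25, first_new_symbol = 10L,
    tokens = FALSE), class = "grammar")
  expect_equal(expand_symbol(11L, g0), c(1L, 2L, 1L, 2L))
  expect_error(expand_symbol(999L, g0), "unknown symbol")

  # nesting arises from compression itself: (1 2) compresses first (N = 8,
  # savings 5), then the rules (X 3) and (X 4) reference it
  x <- c(rep(c(1L, 2L, 3L), 4), rep(c(1L, 2L, 4L), 4))
  g <- compress_sequence(x)
  expect_gte(nrow(g$rules), 2)
  expect_true(any(vapply(seq_len(nrow(g$rules)), function(r)
    any(g$defs[[r]] >= g$first_new_symbol), logical(1)))) # a nested rule
  expect_identical(expand_sequence(g), x)

  set.seed(61)
  for (i in 1:200) {
    x <- as.integer(sample(1:4, sample(5:60, 1), replace = TRUE))
    g <- compress_sequence(x)
    expect_identical(expand_sequence(g), x)
    expect_gte(g$compressibility, 0)
    expect_lt(g$compressibility, 1)
    if (nrow(g$rules)) expect_true(all(g$rules$savings > 0))
  }
})

test_that("the library merges and canonically sorts unique terminal motifs", {
  s1 <- rep(c("A1", "I1"), 6)                            # rule: A1 I1 A1 I1
  s2 <- c(rep(c("A1", "I1"), 4), rep(c("A2", "I2"), 4))  # same rule + A2 I2 A2 I2
  g1 <- compress_sequence(s1)
  g2 <- compress_sequence(s2)
  lib <- build_library(list(g1, g2))
  expect_equal(anyDuplicated(lib$tokens), 0)
  expect_true("A1 I1 A1 I1" %in% lib$tokens)
  expect_equal(sum(lib$tokens == "A1 I1 A1 I1"), 1) # shared motif kept once
  expect_equal(lib$sources[lib$tokens == "A1 I1 A1 I1"], 2L)
  o <- order(lib$length)
  expect_equal(lib$length, lib$length[o]) # sorted by length first

  empty <- build_library(list(compress_sequence(encode_tokens(
    c("A1", "I2", "A3", "I4")))))
  expect_length(empty$motifs, 0)
})

test_that("library round-trips through its text format", {
  g <- compress_sequence(rep(c("A1", "I1", "A2", "I2"), 5))
  lib <- build_library(list(g))
  path <- tempfile(fileext = ".txt")
  write_library(lib, path)
  lib2 <- read_library(path)
  expect_equal(lib2$tokens, lib$tokens)
  unlink(path)
})

test_that("block compressibility drops partial blocks and is 0 when unique", {
  x <- rep(c(1L, 2L), 500) # 1000 symbols
  b <- block_compressibility(x, block = 500)
  expect_equal(nrow(b), 2)
  expect_true(all(b$compressibility > 0))

  expect_warning(b0 <- block_compressibility(1:100, block = 500), "shorter")
  expect_equal(nrow(b0), 0)

  bu <- block_compressibility(as.integer(1:500), block = 500)
  expect_equal(bu$compressibility, 0)
})

test_that("periodic blocks compress more than shuffled blocks", {
  set.seed(71)
  periodic <- rep(c(1L, 2L, 3L, 4L), 125)
  shuffled <- sample(periodic)
  cp <- block_compressibility(periodic, 500)$compressibility
  cs <- block_compressibility(shuffled, 500)$compressibility
  expect_gt(cp, cs)
})

test_that("delta-compressibility contrasts real data with paired shuffles", {
  expect_error(delta_compressibility(c(0.1, 0.2), matrix(0, 3, 10)),
               "paired")
  # degenerate: shuffles identical to the real sequence -> exactly 0
  expect_equal(delta_compressibility(0.25, matrix(0.25, 1, 10)), 0)

  # a single-module-kind sequence shuffles to itself: delta exactly 0
  msp <- generate_module_sequence(tiny_spec(seed = 3), 600)
  real <- compress_sequence(msp)$compressibility
  sh <- vapply(shuffle_within_windows(msp, 10, seed = 9), function(s)
    compress_sequence(s)$compressibility, numeric(1))
  expect_equal(delta_compressibility(real, matrix(sh, 1)), 0)

  # a sequence that is one motif repeated: far more compressible than its
  # shuffles, which keep the module multiset but destroy the order
  ms2 <- make_repeated_ms(rep(c("A1", "I1", "A2", "I2"), 150))
  real2 <- compress_sequence(ms2)$compressibility
  sh2 <- vapply(shuffle_within_windows(ms2, 10, seed = 9), function(s)
    compress_sequence(s)$compressibility, numeric(1))
  expect_gt(delta_compressibility(real2, matrix(sh2, 1)), 0)
})

test_that("compressibility rises with the planted-motif rate", {
  rates <- c(0, 0.02, 0.05, 0.1, 0.2)
  comp <- vapply(rates, function(r) {
    spec <- simulation_spec(seed = 83, planted_motifs = list(
      list(motif = c("A2", "I1", "A3", "I1"),
           rate = c(day5 = r, day6 = r, night5 = r, night6 = r))))
    ms <- generate_module_sequence(spec, 3000)
    compress_sequence(ms)$compressibility
  }, numeric(1))
  expect_gt(cor(rates, comp, method = "spearman"), 0)
  expect_true(all(diff(comp) >= 0) || cor(rates, comp, method = "spearman") > 0.8)
})

test_that("block values are length-independent while full-sequence values are not", {
  set.seed(89)
  short <- as.integer(sample(1:6, 600, replace = TRUE))
  long <- as.integer(sample(1:6, 6000, replace = TRUE))
  cf_short <- compress_sequence(short)$compressibility
  cf_long <- compress_sequence(long)$compressibility
  expect_gt(cf_long, cf_short) # full-sequence value grows with length
  bs <- block_compressibility(short, 500)$compressibility
  bl <- block_compressibility(long, 500)$compressibility
  expect_lt(abs(mean(bl) - mean(bs)), 0.05) # block values comparable
})
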