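# Within-window shuffles, occurrence counting, enrichment/constraint scores
# and column normalization.

make_ms <- function(tokens, window = rep("w", length(tokens))) {
  kind <- ifelse(substr(tokens, 1, 1) == "A", "active", "inactive")
  structure(data.frame(token = tokens, kind = kind,
                       module = abs(encode_tokens(tokens)),
                       start_frame = seq_along(tokens) - 1L,
                       length_frames = 1L, window = window,
                       excluded = FALSE, stringsAsFactors = FALSE),
            frame_rate = 25, animal_id = "t",
            class = c("module_sequence", "data.frame"))
}

test_that("shuffles preserve per-window multisets and alternation", {
  ms <- make_ms(c("A1", "I2", "A1", "I2"))
  for (sh in shuffle_within_windows(ms, 5, seed = 3)) {
    expect_equal(sort(sh$token), sort(ms$token))
    expect_true(all(sh$kind[-1] != sh$kind[-4]))
  }
  # all-identical modules: shuffle is the identity
  ms2 <- make_ms(rep(c("A1", "I1"), 5))
  for (sh in shuffle_within_windows(ms2, 3, seed = 1)) {
    expect_equal(sh$token, ms2$token)
  }
  # a window with <= 1 module of a kind stays unchanged for that kind
  ms3 <- make_ms(c("A1", "I1", "A2"))
  sh3 <- shuffle_within_windows(ms3, 4, seed = 2)
  for (s in sh3) expect_equal(s$token[2], "I1")
})

test_that("shuffling is deterministic and window-local", {
  spec <- simulation_spec(seed = 7, planted_motifs = default_planted_motifs())
  ms <- generate_module_sequence(spec, 2000)
  a <- shuffle_within_windows(ms, 3, seed = 11)
  b <- shuffle_within_windows(ms, 3, seed = 11)
  expect_identical(a, b)
  for (sh in a) {
    for (w in unique(ms$window)) {
      for (k in c("active", "inactive")) {
        sel <- ms$window == w & ms$kind == k
        expect_equal(sort(sh$module[sel]), sort(ms$module[sel]))
      }
    }
  }
})

test_that("planted motifs are rarer in shuffles than in the real sequence", {
  spec <- simulation_spec(seed = 13, planted_motifs = list(
    list(motif = c("A2", "I1", "A2", "I1"),
         rate = c(day5 = 0.05, day6 = 0.05, night5 = 0, night6 = 0))))
  ms <- generate_module_sequence(spec, 4000)
  motif <- encode_tokens(c("A2", "I1", "A2", "I1"))
  real <- count_occurrences(ms, list(motif))
  sh <- vapply(shuffle_within_windows(ms, 10, seed = 5), function(s)
    count_occurrences(s, list(motif)), integer(1))
  expect_gt(real, mean(sh))
})

test_that("occurrence counting matches brute-force position scans", {
  x <- encode_tokens(rep(c("A1", "I1"), 3))
  expect_equal(count_occurrences(x, list(encode_tokens(c("A1", "I1")))), 3L)
  expect_equal(count_occurrences(x, list(encode_tokens(c("A2", "I1")))), 0L)
  # overlapping matches: A1 I1 A1 in A1 I1 A1 I1 A1 -> 2
  x5 <- encode_tokens(c("A1", "I1", "A1", "I1", "A1"))
  m3 <- encode_tokens(c("A1", "I1", "A1"))
  expect_equal(count_occurrences(x5, list(m3)), 2L)
  expect_equal(count_occurrences(x5, list(m3), overlap = FALSE), 1L)
  # motif longer than the sequence
  expect_equal(count_occurrences(x5[1:2], list(encode_tokens(
    c("A1", "I1", "A1", "I1")))), 0L)

  set.seed(17)
  for (i in 1:50) {
    x <- as.integer(sample(c(-2:-1, 1:2), 40, replace = TRUE))
    motif <- as.integer(sample(c(-2:-1, 1:2), sample(2:4, 1), replace = TRUE))
    expect_equal(count_occurrences(x, list(motif)),
                 count_overlap_oracle(x, motif))
    expect_equal(count_occurrences(x, list(motif), overlap = FALSE),
                 count_nonoverlap_oracle(x, motif))
  }
})

test_that("counts never cross excluded modules", {
  ms <- make_ms(rep(c("A1", "I1"), 4))
  expect_equal(count_occurrences(ms, list(encode_tokens(c("A1", "I1")))), 4L)
  ms$excluded[4] <- TRUE # match starting at row 3 now spans a break
  expect_equal(count_occurrences(ms, list(encode_tokens(c("A1", "I1")))), 3L)
})

test_that("the enrichment score implements the shuffle Z with infinity rule", {
  sh <- c(rep(4.5 + 1.58, 5), rep(4.5 - 1.58, 5)) # mean 4.5, pop SD 1.58
  expect_equal(enrichment_score(10, sh), (10 - 4.5) / 1.58, tolerance = 1e-12)
  expect_equal(round(enrichment_score(10, sh), 2), 3.48)
  expect_equal(enrichment_score(4.5, sh), 0)
  # zero shuffle SD: the infinity rule constant
  expect_equal(enrichment_score(9, rep(4, 10)), sqrt(11))
  expect_equal(enrichment_score(1, rep(4, 10)), -sqrt(11))
  expect_equal(enrichment_score(4, rep(4, 10)), 0)
  # vectorized over motifs
  z <- enrichment_score(c(10, 4, 9), rbind(sh, sh, rep(4, 10)))
  expect_equal(z, c((10 - 4.5) / 1.58, (4 - 4.5) / 1.58, sqrt(11)),
               tolerance = 1e-12)
})

test_that("leave-one-out shuffle self-scores match a brute-force oracle", {
  expect_equal(shuffle_self_scores(rep(3, 10)), rep(0, 10))
  loo_oracle <- function(counts, n_total = length(counts)) {
    vapply(seq_along(counts), function(j) {
      rest <- counts[-j]
      mu <- mean(rest)
      s <- sqrt(mean((rest - mu)^2))
      if (s == 0) sign(counts[j] - mu) * sqrt(1 + n_total) else
        (counts[j] - mu) / s
    }, numeric(1))
  }
  set.seed(19)
  for (i in 1:50) {
    counts <- rpois(10, sample(1:6, 1))
    expect_equal(shuffle_self_scores(counts), loo_oracle(counts),
                 tolerance = 1e-12)
  }
  expect_equal(shuffle_self_scores(c(rep(0, 9), 5)), loo_oracle(c(rep(0, 9), 5)))
})

test_that("self-scores of shuffles average near zero over many motifs", {
  set.seed(23)
  counts <- matrix(rpois(400 * 10, 5), 400, 10)
  z <- shuffle_self_scores(counts)
  expect_lt(abs(mean(z)), 0.1)
})

test_that("column normalization centers, scales and flags constants", {
  em <- structure(list(scores = cbind(c(-1, 1), c(3, 3)),
                       samples = data.frame(animal_id = c("a", "b"),
                                            window = "w", instance = 1:2),
                       motifs = c("m1", "m2"), inf_fraction = 0,
                       normalized = FALSE), class = "enrichment_matrix")
  out <- normalize_columns(em)
  expect_equal(out$scores[, 1], c(-1, 1)) # population SD of (-1, 1) is 1
  expect_equal(out$scores[, 2], c(0, 0))
  expect_equal(out$constant_columns, c(FALSE, TRUE))

  set.seed(29)
  emr <- em
  emr$scores <- matrix(rnorm(200), 20, 10)
  emr$samples <- data.frame(animal_id = letters[1:20], window = "w",
                            instance = 1:20)
  outr <- normalize_columns(emr)
  expect_lt(max(abs(colMeans(outr$scores))), 1e-10)
})

test_that("enrichment matrix separates planted day scores from night", {
  spec <- simulation_spec(seed = 31, planted_motifs = default_planted_motifs())
  ds <- synthesize_dataset(spec, n_animals = 3, n_modules = 12000, seed = 31)
  grams <- lapply(ds$sequences, compress_sequence)
  lib <- build_library(grams)
  em <- enrichment_matrix(ds$sequences, lib, drop_censored = TRUE, seed = 31)
  expect_equal(nrow(em$scores), nrow(em$samples))
  expect_true(all(is.finite(em$scores)))
  planted <- match(c("A2 I1 A2 I1", "A3 I2 A3 I2"), em$motifs)
  expect_false(anyNA(planted))
  day <- startsWith(em$samples$window, "day")
  for (p in planted) {
    expect_gt(min(em$scores[day, p]), max(em$scores[!day, p]))
  }
})

test_that("real score distributions are heavier-tailed than shuffle nulls", {
  spec <- simulation_spec(seed = 37, planted_motifs = default_planted_motifs())
  ds <- synthesize_dataset(spec, n_animals = 2, n_modules = 8000, seed = 37)
  grams <- lapply(ds$sequences, compress_sequence)
  lib <- build_library(grams)
  # real Z for every motif in the first animal's first day window, plus the
  # shuffles' leave-one-out null
  ms <- ds$sequences[[1]]
  day <- ms[ms$window == "day5", ]
  class(day) <- class(ms)
  shuffles <- shuffle_within_windows(day, 10, seed = 37)
  x <- count_occurrences(day, lib)
  sh <- vapply(shuffles, function(s) count_occurrences(s, lib),
               integer(length(lib$motifs)))
  zr <- enrichment_score(x, sh)
  zs <- shuffle_self_scores(sh)
  expect_gt(pop_kurtosis(zr), pop_kurtosis(as.numeric(zs)))
})
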