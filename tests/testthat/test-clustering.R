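# Per-animal z-scoring, PCA knee, evidence accumulation, maximum-lifetime
# cut, kNN assignment and relabeling.

test_that("per-animal z-scoring uses the population SD", {
  m <- matrix(c(1, 2, 3), ncol = 1)
  z <- zscore_per_animal(m, rep("a", 3))
  expect_equal(as.numeric(z), c(-1, 0, 1) * sqrt(1.5), tolerance = 1e-6)
  expect_equal(round(as.numeric(z), 3), c(-1.225, 0, 1.225))
})

test_that("z-scoring removes per-animal location and scale", {
  set.seed(5)
  base <- matrix(rnorm(40), 20, 2)
  m <- rbind(base, base * 3 + 10) # second animal: shifted and scaled copy
  z <- zscore_per_animal(m, rep(c("a", "b"), each = 20))
  expect_equal(z[1:20, ], z[21:40, ], tolerance = 1e-10)
  for (a in c(1, 21)) {
    blk <- z[a:(a + 19), ]
    expect_lt(max(abs(colMeans(blk))), 1e-10)
    expect_equal(sqrt(colMeans(sweep(blk, 2, colMeans(blk))^2)), c(1, 1),
                 tolerance = 1e-10)
  }
})

test_that("zero within-animal SD raises an error naming animal and feature", {
  m <- matrix(c(1, 1, 1, 2, 3, 4), ncol = 2,
              dimnames = list(NULL, c("flat", "ok")))
  expect_error(zscore_per_animal(m, rep("fishX", 3)), "fishX")
  expect_error(zscore_per_animal(m, rep("fishX", 3)), "flat")
})

test_that("PCA projection respects rank and preserves distances", {
  set.seed(7)
  basis <- qr.Q(qr(matrix(rnorm(36), 6, 6)))[, 1:2]
  m <- matrix(rnorm(400), 200, 2) %*% t(basis) # exactly planar in 6-D
  p <- center_and_project(m, n_components = "all")
  expect_lt(sum(p$scree[3:6]), 1e-10)
  d0 <- dist(scale(m, scale = FALSE))
  d1 <- dist(p$scores)
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-8)
  expect_error(center_and_project(m, 7), "exceeds")
})

test_that("the scree knee finds the true factor count", {
  set.seed(11)
  n <- 2000
  f <- matrix(rnorm(n * 3), n, 3)              # 3 factors, equal variance
  basis <- qr.Q(qr(matrix(rnorm(18), 6, 3)))   # orthonormal loadings
  m <- f %*% t(basis) + matrix(rnorm(n * 6, sd = 0.05), n, 6) # noise floor
  p <- center_and_project(m, "auto")
  expect_equal(p$n_components, 3L)
})

test_that("evidence accumulation tallies co-assignments correctly", {
  pts <- matrix(rep(c(0, 0), each = 12), ncol = 2) # all points identical
  ev <- accumulate_evidence(pts, n_probe = 6, n_models = 1, k_range = c(2, 2),
                            sample_range = c(8, 10), seed = 2)
  expect_true(all(ev$counts == 1))
  expect_equal(dim(ev$counts), c(6, 6))

  far <- rbind(matrix(0, 20, 2), matrix(100, 20, 2))
  far <- far + matrix(rnorm(80, sd = 1e-3), 40, 2)
  ev2 <- accumulate_evidence(far, n_probe = 20, n_models = 5,
                             k_range = c(2, 3), sample_range = c(20, 30),
                             seed = 3)
  grp <- ev2$probe_idx <= 20
  expect_true(all(ev2$counts[grp, !grp] == 0))
  expect_true(all(ev2$counts[grp, grp] == 5))
  expect_true(isSymmetric(ev2$counts))
  expect_true(all(diag(ev2$counts) == 5))

  expect_error(accumulate_evidence(far, n_probe = 100, n_models = 1,
                                   k_range = c(2, 2), sample_range = c(10, 20),
                                   seed = 1),
               "exceeds")
})

test_that("well-separated blobs leave almost no between-blob evidence", {
  set.seed(13)
  pts <- rbind(matrix(rnorm(600), ncol = 2),
               matrix(rnorm(600, mean = 10), ncol = 2)) # 10 SD apart
  ev <- accumulate_evidence(pts, n_probe = 100, n_models = 50,
                            k_range = c(2, 8), sample_range = c(200, 400),
                            seed = 17)
  blob <- ev$probe_idx <= 300
  between <- ev$counts[blob, !blob]
  expect_lt(mean(between) / ev$n_models, 0.05)
  cut <- cut_max_lifetime(ev)
  expect_equal(cut$k, 2L)
})

test_that("maximum-lifetime cut recovers block-diagonal structure", {
  n_models <- 10
  counts <- matrix(0, 9, 9)
  for (b in 0:2) counts[b * 3 + 1:3, b * 3 + 1:3] <- n_models
  ev <- structure(list(counts = counts, probe_idx = 1:9,
                       n_models = n_models), class = "evidence_matrix")
  cut <- cut_max_lifetime(ev)
  expect_equal(cut$k, 3L)
  expect_equal(length(unique(cut$labels)), 3)
  expect_true(all(tapply(cut$labels, rep(1:3, each = 3),
                         function(x) length(unique(x))) == 1))
})

test_that("degenerate and two-probe evidence matrices are handled", {
  allsame <- structure(list(counts = matrix(5, 4, 4), probe_idx = 1:4,
                            n_models = 5), class = "evidence_matrix")
  expect_warning(cut1 <- cut_max_lifetime(allsame), "single cluster")
  expect_equal(cut1$k, 1L)

  two <- structure(list(counts = matrix(c(5, 1, 1, 5), 2), probe_idx = 1:2,
                        n_models = 5), class = "evidence_matrix")
  cut2 <- cut_max_lifetime(two) # merge height 4 > n_models - 4: split wins
  expect_equal(cut2$k, 2L)
  two2 <- structure(list(counts = matrix(c(5, 4, 4, 5), 2), probe_idx = 1:2,
                         n_models = 5), class = "evidence_matrix")
  expect_equal(suppressWarnings(cut_max_lifetime(two2)$k), 1L)
})

test_that("kNN assignment honors templates and breaks ties low", {
  pts <- matrix(c(0, 0, 10, 10, 5), ncol = 1)
  # probes: the two extremes, labels 1 and 2
  asn <- normalize_and_assign(pts, probe_idx = c(1, 3), probe_labels = c(1, 2),
                              k_nn = 1, seed = 1)
  expect_equal(asn[1], 1L)
  expect_equal(asn[3], 2L)
  # an exactly equidistant point between two equal-size template clusters:
  # the k_nn = 2 vote ties and the lowest module id wins
  pts2 <- matrix(c(0, 10, 0, 10, 5), ncol = 1)
  asn2 <- normalize_and_assign(pts2, probe_idx = 1:4,
                               probe_labels = c(1, 2, 1, 2), k_nn = 2,
                               seed = 1)
  expect_equal(asn2[5], 1L)
})

test_that("kNN k is reduced with a warning when clusters are small", {
  pts <- matrix(c(rnorm(10), rnorm(10, 50)), ncol = 1)
  expect_warning(
    normalize_and_assign(pts, probe_idx = 1:20,
                         probe_labels = rep(1:2, each = 10), k_nn = 50,
                         seed = 2),
    "reduced")
})

test_that("relabeling orders modules by mean length with documented ties", {
  modules <- c(1, 1, 2, 2)
  lens <- c(50, 50, 5, 5)
  out <- relabel_by_length(modules, lens)
  expect_equal(out, c(2, 2, 1, 1))
  # equal mean lengths: tie broken by smaller mean total
  out2 <- relabel_by_length(c(1, 2), c(10, 10), total = c(100, 20))
  expect_equal(out2, c(2, 1))
  # idempotent
  expect_equal(relabel_by_length(out, lens), out)
})

test_that("five planted modules are recovered from bout features", {
  # 9000 modules span a day and a night window, so all five inactive
  # templates are well represented
  spec <- simulation_spec(seed = 29)
  ds <- synthesize_dataset(spec, n_animals = 2, n_modules = 9000, seed = 29)
  bouts <- bind_bouts(lapply(ds$recordings, function(r)
    segment_bouts(apply_masks(apply_artifact_ceiling(r)))))
  asn <- cluster_bouts(bouts, n_probe = 800, n_models = 30, k_range = c(2, 15),
                       sample_range = c(1000, 3000), k_nn = 25, seed = 29)
  truth_a <- unlist(lapply(ds$sequences, function(s)
    s$module[s$kind == "active"]))
  truth_i <- unlist(lapply(ds$sequences, function(s)
    s$module[s$kind == "inactive"]))
  expect_equal(asn$k_active, 5L)
  expect_equal(asn$k_inactive, 5L)
  expect_gte(best_label_agreement(truth_a, asn$active), 0.95)
  expect_gte(best_label_agreement(truth_i, asn$inactive), 0.95)
  # module ids are ordered by ascending mean length
  expect_true(all(diff(asn$summary_active$mean_length_frames) > 0))
  expect_true(all(diff(asn$summary_inactive$mean_length_frames) > 0))
})

test_that("the mixture fits agree with an independent GMM implementation", {
  skip_if_not_installed("mclust")
  mclustBIC <- mclust::mclustBIC # Mclust() resolves this in the caller
  set.seed(37)
  x <- rbind(matrix(rnorm(400), ncol = 2),
             matrix(rnorm(400, mean = 6), ncol = 2))
  fit <- ethomotif:::gmm_fit_best_cpp(x, 2L, 5L, 1e-6, 200L, 1e-8)
  mine <- ethomotif:::gmm_assign_cpp(x, fit$means, fit$covs, fit$weights)
  mc <- mclust::Mclust(x, G = 2, modelNames = "VVV", verbose = FALSE)
  agree <- max(mean(mine == mc$classification),
               mean(mine == 3 - mc$classification))
  expect_gte(agree, 0.99)
})

test_that("the clustering pipeline is deterministic given a seed", {
  set.seed(41)
  pts <- rbind(matrix(rnorm(300), ncol = 1), matrix(rnorm(300, 8), ncol = 1))
  ev1 <- accumulate_evidence(pts, 50, 10, c(2, 4), c(100, 200), seed = 5)
  ev2 <- accumulate_evidence(pts, 50, 10, c(2, 4), c(100, 200), seed = 5)
  expect_identical(ev1$counts, ev2$counts)
  ev3 <- accumulate_evidence(pts, 50, 10, c(2, 4), c(100, 200), seed = 6)
  expect_false(identical(ev3$counts, ev1$counts))
})
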