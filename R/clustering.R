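# Module clustering: per-animal z-scoring, PCA with scree-knee selection,
# evidence accumulation over an ensemble of Gaussian mixture models,
# maximum-lifetime dendrogram cut, size-normalized kNN assignment, and
# relabeling by mean bout length.

#' Per-animal z-scoring of a bout feature matrix
#'
#' Each animal's block of rows is normalized feature-wise: subtract that
#' animal's mean and divide by that animal's population SD, removing
#' per-animal location and scale before bouts are pooled for clustering.
#'
#' @param m numeric matrix (bouts x features).
#' @param animal character/factor vector, one entry per row.
#' @return matrix of the same shape with per-animal column means 0 and SDs 1.
#' @export
zscore_per_animal <- function(m, animal) {
  m <- as.matrix(m)
  stopifnot(nrow(m) == length(animal))
  for (a in unique(animal)) {
    idx <- which(animal == a)
    if (length(idx) < 2) {
      stop("animal ", a, " contributes fewer than 2 bouts")
    }
    for (j in seq_len(ncol(m))) {
      s <- sd_pop(m[idx, j])
      if (s == 0) {
        stop("zero within-animal SD for animal ", a, ", feature ",
             colnames(m)[j] %||% j)
      }
      m[idx, j] <- (m[idx, j] - mean(m[idx, j])) / s
    }
  }
  m
}

#' Center features and project onto principal components
#'
#' Columns are mean-centered across all bouts, then PCA rotates the data;
#' the retained dimensionality is either given or chosen automatically at
#' the scree knee, defined as the largest drop between successive
#' explained-variance fractions (a reproducible stand-in for reading the
#' scree plot by eye).
#'
#' @param m z-scored active feature matrix.
#' @param n_components number of components, `"auto"` (knee) or `"all"`.
#' @return list with `scores` (projected matrix), `scree` (variance
#'   fractions), `n_components`, and `rotation`.
#' @export
center_and_project <- function(m, n_components = "auto") {
  m <- as.matrix(m)
  p <- prcomp(m, center = TRUE, scale. = FALSE)
  frac <- p$sdev^2 / sum(p$sdev^2)
  k <- if (identical(n_components, "auto")) {
    if (length(frac) < 2) 1L else which.max(frac[-length(frac)] - frac[-1])
  } else if (identical(n_components, "all")) {
    ncol(m)
  } else {
    n_components
  }
  if (k > ncol(m)) stop("n_components exceeds the number of features")
  list(scores = p$x[, seq_len(k), drop = FALSE], scree = frac,
       n_components = as.integer(k),
       rotation = p$rotation[, seq_len(k), drop = FALSE])
}

#' Evidence accumulation over a Gaussian mixture ensemble
#'
#' Samples `n_probe` probe points, then fits `n_models` Gaussian mixture
#' models, each on an independently sampled subset of the data with a
#' uniformly random component count in `k_range` and sample size in
#' `sample_range`. Every fit is restarted `n_restarts` times (k-means++
#' initialization; full, per-component, diagonally regularized covariances)
#' keeping the best log-likelihood. Each model assigns every probe point to
#' its maximum-posterior component, and pairwise co-assignments are tallied.
#'
#' @param points numeric matrix (points x dims), the clustering space.
#' @param n_probe number of probe points (paper-scale default 40000).
#' @param n_models ensemble size (default 200).
#' @param k_range integer range of mixture components (default c(2, 20)).
#' @param sample_range range of per-model training sample sizes (default
#'   c(40000, 100000); capped at the number of points).
#' @param n_restarts EM restarts per model (default 5).
#' @param reg ridge added to each component covariance diagonal (default
#'   1e-6).
#' @param seed integer seed.
#' @return list of class `evidence_matrix`: `counts` (n_probe x n_probe
#'   co-assignment tallies, diagonal = `n_models`), `probe_idx` (row indices
#'   into `points`), `n_models`.
#' @export
accumulate_evidence <- function(points, n_probe = 40000, n_models = 200,
                                k_range = c(2, 20),
                                sample_range = c(40000, 100000),
                                n_restarts = 5, reg = 1e-6, seed = 1L) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n_probe > n) {
    stop("n_probe (", n_probe, ") exceeds the number of points (", n, ")")
  }
  sample_range <- pmin(sample_range, n)
  set.seed(seed)
  probe_idx <- sort(sample.int(n, n_probe))
  probes <- points[probe_idx, , drop = FALSE]
  counts <- matrix(0, n_probe, n_probe)
  for (m in seq_len(n_models)) {
    k <- sample(seq(k_range[1], k_range[2]), 1L)
    s <- if (sample_range[1] >= sample_range[2]) sample_range[2] else
      sample(seq(sample_range[1], sample_range[2]), 1L)
    train <- points[sample.int(n, s), , drop = FALSE]
    fit <- gmm_fit_best_cpp(train, k, n_restarts, reg, 200L, 1e-6)
    labels <- gmm_assign_cpp(probes, fit$means, fit$covs, fit$weights)
    accumulate_coassign_cpp(counts, labels)
  }
  structure(list(counts = counts, probe_idx = probe_idx,
                 n_models = n_models),
            class = "evidence_matrix")
}

#' Maximum-lifetime cut of the evidence dendrogram
#'
#' Average-link hierarchical clustering of the probe points under the
#' dissimilarity `n_models - counts`; the cluster count K is the one whose
#' cut persists over the largest gap between consecutive merge heights
#' (lifetimes for K = 1 use `n_models` as the ceiling and for K = n use 0 as
#' the floor). Ties prefer larger K.
#'
#' @param ev an `evidence_matrix` from [accumulate_evidence()].
#' @return list with `labels` (probe cluster ids 1..K) and `k`.
#' @export
cut_max_lifetime <- function(ev) {
  stopifnot(inherits(ev, "evidence_matrix"))
  d <- ev$n_models - ev$counts
  n <- nrow(d)
  hc <- hclust(as.dist(d), method = "average")
  h <- hc$height # ascending, length n-1
  bounds <- c(0, h, ev$n_models)          # heights bracketing each K
  lifetimes <- diff(bounds)               # lifetimes[i] = lifetime of K = n - i + 1
  ks <- seq(n, 1)
  best <- max(lifetimes)
  k <- max(ks[lifetimes == best])         # tie-break: larger K
  if (k == 1) warning("degenerate evidence matrix: a single cluster")
  labels <- if (k == n) seq_len(n) else cutree(hc, k = k)
  list(labels = as.integer(labels), k = as.integer(k))
}

#' Size-normalize clusters and assign every point by kNN mode
#'
#' Equal-sized template sets are drawn by sampling, from each probe cluster,
#' the number of points in the smallest cluster. Every point in the data is
#' then assigned the modal cluster of its `k_nn` nearest template points
#' (Euclidean distance in the clustering space); ties take the lowest module
#' id.
#'
#' @param points full data matrix (points x dims).
#' @param probe_idx probe row indices (as in the evidence matrix).
#' @param probe_labels probe cluster ids from [cut_max_lifetime()].
#' @param k_nn neighbors to vote (default 50; reduced with a warning when
#'   the template sets are smaller).
#' @param seed integer seed for the template sampling.
#' @return integer module ids, one per row of `points`.
#' @export
normalize_and_assign <- function(points, probe_idx, probe_labels, k_nn = 50,
                                 seed = 1L) {
  points <- as.matrix(points)
  set.seed(seed)
  sizes <- table(probe_labels)
  m <- min(sizes)
  if (m < k_nn) {
    warning("smallest cluster (", m, ") < k_nn (", k_nn, "); k_nn reduced")
    k_nn <- m
  }
  keep <- unlist(lapply(sort(unique(probe_labels)), function(cl) {
    idx <- which(probe_labels == cl)
    idx[sample.int(length(idx), m)]
  }))
  templates <- points[probe_idx[keep], , drop = FALSE]
  tpl_labels <- probe_labels[keep]
  n_cl <- max(probe_labels)

  n <- nrow(points)
  out <- integer(n)
  t2 <- rowSums(templates^2)
  block <- 2000L
  for (b in seq(1, n, by = block)) {
    idx <- b:min(b + block - 1L, n)
    x <- points[idx, , drop = FALSE]
    d2 <- outer(rowSums(x^2), t2, "+") - 2 * tcrossprod(x, templates)
    for (i in seq_along(idx)) {
      nn <- order(d2[i, ])[seq_len(k_nn)]
      votes <- tabulate(tpl_labels[nn], nbins = n_cl)
      out[idx[i]] <- which.max(votes) # ties -> lowest id
    }
  }
  out
}

#' Relabel modules by ascending mean bout length
#'
#' Module 1 becomes the cluster with the smallest mean bout length; ties are
#' broken by smaller mean total delta-pixels (0 where unavailable, e.g.
#' inactive bouts).
#'
#' @param modules integer module ids, one per bout.
#' @param length_frames bout lengths in frames.
#' @param total bout total delta-pixels (optional).
#' @return integer module ids, dense 1..K, ordered by mean length.
#' @export
relabel_by_length <- function(modules, length_frames, total = NULL) {
  ids <- sort(unique(modules))
  mean_len <- vapply(ids, function(k) mean(length_frames[modules == k]),
                     numeric(1))
  mean_tot <- if (is.null(total)) rep(0, length(ids)) else
    vapply(ids, function(k) mean(total[modules == k]), numeric(1))
  o <- order(mean_len, mean_tot)
  remap <- integer(max(ids))
  remap[ids[o]] <- seq_along(ids)
  remap[modules]
}

#' Cluster bouts into behavioral modules
#'
#' End-to-end clustering for one bout table (typically all animals pooled):
#' active bouts are per-animal z-scored on the six features, centered, and
#' PCA-projected to the scree knee; inactive bouts are clustered on
#' log10(length) (lengths are compared on a log axis; switch off with
#' `log_inactive = FALSE`). Both kinds then go through evidence
#' accumulation, the maximum-lifetime cut, size-normalized kNN assignment,
#' and relabeling by mean length.
#'
#' @param bouts a `bout_table` (see [bind_bouts()]); excluded bouts are
#'   still assigned a module but can be dropped downstream.
#' @param n_probe,n_models,k_range,sample_range,n_restarts,reg,k_nn ensemble
#'   parameters, see [accumulate_evidence()] and [normalize_and_assign()];
#'   `n_probe` and `sample_range` are capped at the available bout counts.
#' @param n_components PCA dimensionality for the active features
#'   (`"auto"` = scree knee).
#' @param log_inactive cluster inactive bouts on log10(length)?
#' @param seed integer seed.
#' @return list of class `module_assignment`: per-kind module ids
#'   (`active`, `inactive`, aligned to the bout-table rows of that kind),
#'   `k_active`, `k_inactive`, `scree`, `n_components`, and per-module
#'   summary tables.
#' @export
cluster_bouts <- function(bouts, n_probe = 40000, n_models = 200,
                          k_range = c(2, 20), sample_range = c(40000, 1e5),
                          n_restarts = 5, reg = 1e-6, k_nn = 50,
                          n_components = "auto", log_inactive = TRUE,
                          seed = 1L) {
  stopifnot(inherits(bouts, "bout_table"))
  act <- bouts[bouts$kind == "active", ]
  ina <- bouts[bouts$kind == "inactive", ]

  fit_kind <- function(points, tag) {
    n <- nrow(points)
    np <- min(n_probe, max(2L, floor(n / 2)))
    ev <- accumulate_evidence(points, n_probe = np, n_models = n_models,
                              k_range = k_range,
                              sample_range = pmin(sample_range, n),
                              n_restarts = n_restarts, reg = reg,
                              seed = derive_seed(seed, paste0("ea:", tag)))
    cut <- cut_max_lifetime(ev)
    modules <- normalize_and_assign(points, ev$probe_idx, cut$labels,
                                    k_nn = k_nn,
                                    seed = derive_seed(seed,
                                                       paste0("nn:", tag)))
    list(modules = modules, k = cut$k)
  }

  feats <- as.matrix(act[, c("length_s", "mean", "sd", "total", "min", "max")])
  z <- zscore_per_animal(feats, act$animal_id)
  proj <- center_and_project(z, n_components)
  fa <- fit_kind(proj$scores, "active")
  active_modules <- relabel_by_length(fa$modules, act$length_frames,
                                      act$total)

  ipts <- matrix(if (log_inactive) log10(ina$length_frames) else
    ina$length_frames, ncol = 1)
  fi <- fit_kind(ipts, "inactive")
  inactive_modules <- relabel_by_length(fi$modules, ina$length_frames)

  summarize <- function(tab, modules) {
    data.frame(module = sort(unique(modules)),
               count = as.integer(table(modules)),
               mean_length_frames = vapply(sort(unique(modules)), function(k)
                 mean(tab$length_frames[modules == k]), numeric(1)))
  }

  structure(list(active = active_modules, inactive = inactive_modules,
                 k_active = fa$k, k_inactive = fi$k, scree = proj$scree,
                 n_components = proj$n_components,
                 summary_active = summarize(act, active_modules),
                 summary_inactive = summarize(ina, inactive_modules)),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  cat("<module_assignment>", x$k_active, "active modules,", x$k_inactive,
      "inactive modules;", x$n_components, "PCA components\n")
  invisible(x)
}
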