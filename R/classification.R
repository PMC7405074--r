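# Supervised motif selection: mRMR ranking, incremental cross-validated
# linear discriminant classifiers, curve smoothing, and the majority-class
# and random-subset baselines.

# discretize columns into 3 states at mean +/- t population SDs
discretize3 <- function(m, t = 0.5) {
  mu <- colMeans(m)
  sdev <- sqrt(colMeans(sweep(m, 2, mu)^2))
  sdev[sdev == 0] <- 1
  lo <- mu - t * sdev
  hi <- mu + t * sdev
  d <- matrix(2L, nrow(m), ncol(m))
  d[sweep(m, 2, lo, "<")] <- 1L
  d[sweep(m, 2, hi, ">")] <- 3L
  d
}

# mutual information (nats) between discrete z (ints 1..kz) and every column
# of D (ints 1..3), vectorized over columns
mi_vs_columns <- function(D, z) {
  n <- nrow(D)
  kz <- max(z)
  p <- ncol(D)
  mi <- numeric(p)
  pz <- tabulate(z, kz) / n
  for (a in 1:3) {
    Da <- D == a
    pa <- colMeans(Da)
    for (b in seq_len(kz)) {
      pab <- colSums(Da & (z == b)) / n
      nz <- pab > 0
      mi[nz] <- mi[nz] + pab[nz] * log(pab[nz] / (pa[nz] * pz[b]))
    }
  }
  mi
}

#' mRMR ranking of motifs for a contrast
#'
#' Greedy maximum-relevance minimum-redundancy ranking (mutual-information
#' difference scheme): scores are discretized into 3 states at each column's
#' mean +/- `disc_t` SDs (default 0.5; a full 1-SD band would collapse
#' one-sided enrichment signals into the middle state and erase their
#' relevance); the first motif maximizes MI with the class labels, and
#' each subsequent motif maximizes relevance minus its mean MI with the
#' motifs already chosen. The quotient scheme (relevance / redundancy) is
#' available via `variant = "MIQ"`.
#'
#' @param em a column-normalized `enrichment_matrix` (or plain matrix).
#' @param labels class labels aligned to the rows.
#' @param top how many motifs to rank (default 250; capped at the number of
#'   motifs).
#' @param variant `"MID"` (difference, default) or `"MIQ"` (quotient).
#' @param disc_t discretization half-width in column SDs (default 0.5).
#' @return integer vector of column indices, best first.
#' @export
mrmr_rank <- function(em, labels, top = 250, variant = c("MID", "MIQ"),
                      disc_t = 0.5) {
  variant <- match.arg(variant)
  m <- if (inherits(em, "enrichment_matrix")) em$scores else as.matrix(em)
  stopifnot(nrow(m) == length(labels))
  D <- discretize3(m, disc_t)
  y <- as.integer(factor(labels))
  p <- ncol(m)
  top <- min(top, p)
  relevance <- mi_vs_columns(D, y)
  chosen <- integer(top)
  chosen[1] <- which.max(relevance)
  red_sum <- numeric(p)
  for (t in seq_len(top)[-1]) {
    red_sum <- red_sum + mi_vs_columns(D, D[, chosen[t - 1]])
    score <- if (variant == "MID") {
      relevance - red_sum / (t - 1)
    } else {
      relevance / pmax(red_sum / (t - 1), 1e-12)
    }
    score[chosen[seq_len(t - 1)]] <- -Inf
    chosen[t] <- which.max(score)
  }
  chosen
}

# pooled-covariance linear discriminant with a small ridge, needed when the
# motif count exceeds the training sample count
lda_pooled_fit <- function(X, y, ridge = 1e-6) {
  y <- factor(y)
  cls <- levels(y)
  d <- ncol(X)
  mm <- vapply(cls, function(cl) colMeans(X[y == cl, , drop = FALSE]),
               numeric(d))
  mus <- if (d == 1) matrix(mm, ncol = 1) else t(mm)
  S <- matrix(0, d, d)
  for (ci in seq_along(cls)) {
    Xc <- sweep(X[y == cls[ci], , drop = FALSE], 2, mus[ci, ])
    S <- S + crossprod(Xc)
  }
  S <- S / nrow(X)
  S <- S + diag(ridge * (mean(diag(S)) + 1), d)
  Sinv <- solve(S)
  priors <- as.numeric(table(y)[cls]) / length(y)
  list(classes = cls, means = mus, Sinv = Sinv, log_priors = log(priors))
}

lda_pooled_predict <- function(fit, X) {
  # delta_k(x) = x' Sinv mu_k - 0.5 mu_k' Sinv mu_k + log pi_k
  A <- fit$Sinv %*% t(fit$means)                      # d x K
  const <- -0.5 * colSums(t(fit$means) * A) + fit$log_priors
  scores <- X %*% A
  scores <- sweep(scores, 2, const, "+")
  fit$classes[max.col(scores, ties.method = "first")]
}

# stratified (optionally animal-grouped) fold ids
make_folds <- function(labels, folds, seed, groups = NULL) {
  set.seed(seed)
  n <- length(labels)
  fold_of <- integer(n)
  if (is.null(groups)) {
    for (c in unique(labels)) {
      idx <- which(labels == c)
      idx <- idx[sample.int(length(idx))]
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
  } else {
    gs <- unique(groups)
    gs <- gs[sample.int(length(gs))]
    g_fold <- rep_len(seq_len(folds), length(gs))
    fold_of <- g_fold[match(groups, gs)]
  }
  fold_of
}

#' Cross-validated error curve over mRMR prefixes
#'
#' Linear discriminant classifiers are trained with `folds`-fold
#' cross-validation as sequential ranked motifs are added; prefix k uses the
#' first k ranked motifs.
#'
#' @param em a column-normalized `enrichment_matrix` (or matrix).
#' @param labels class labels per row.
#' @param ranked ranked column indices from [mrmr_rank()].
#' @param folds folds (default 10; reduced with a warning if a class is
#'   smaller, or if grouping leaves fewer groups).
#' @param seed integer seed for the fold split.
#' @param groups optional grouping vector (e.g. animal id) keeping all rows
#'   of a group in the same fold, avoiding leakage between train and test;
#'   `NULL` gives the plain stratified row-wise split.
#' @param ridge covariance regularization for the discriminant.
#' @return data frame: `k`, `error` (mean misclassification %), `sd` (SD
#'   across folds, %).
#' @export
incremental_cv_error <- function(em, labels, ranked, folds = 10, seed = 1L,
                                 groups = NULL, ridge = 1e-6) {
  m <- if (inherits(em, "enrichment_matrix")) em$scores else as.matrix(em)
  labels <- as.character(labels)
  min_class <- min(table(labels))
  n_units <- if (is.null(groups)) min_class else length(unique(groups))
  if (folds > n_units) {
    warning("reducing folds from ", folds, " to ", n_units)
    folds <- n_units
  }
  fold_of <- make_folds(labels, folds, seed, groups)
  ks <- seq_along(ranked)
  err <- matrix(NA_real_, length(ks), folds)
  for (f in seq_len(folds)) {
    tr <- fold_of != f
    te <- !tr
    if (length(unique(labels[tr])) < 2) next
    for (k in ks) {
      cols <- ranked[seq_len(k)]
      fit <- lda_pooled_fit(m[tr, cols, drop = FALSE], labels[tr], ridge)
      pred <- lda_pooled_predict(fit, m[te, cols, drop = FALSE])
      err[k, f] <- 100 * mean(pred != labels[te])
    }
  }
  data.frame(k = ks, error = rowMeans(err, na.rm = TRUE),
             sd = apply(err, 1, function(r) sd(r[!is.na(r)])))
}

#' Choose the motif count from a smoothed error curve
#'
#' The error curve is smoothed with a running average `smooth_width` motifs
#' wide (symmetric windows that shrink to width 1 at the curve's ends) and
#' the first index attaining the minimum is returned.
#'
#' @param curve numeric error values per prefix (or the data frame from
#'   [incremental_cv_error()]).
#' @param smooth_width running-average width (default 3, odd).
#' @return list with `count` (chosen prefix) and `error` (raw error there).
#' @export
select_motif_count <- function(curve, smooth_width = 3) {
  err <- if (is.data.frame(curve)) curve$error else as.numeric(curve)
  n <- length(err)
  if (n < smooth_width) {
    i <- which.min(err)
    return(list(count = i, error = err[i]))
  }
  half <- (smooth_width - 1) %/% 2
  sm <- vapply(seq_len(n), function(i) {
    w <- min(half, i - 1, n - i) # symmetric shrink at the edges
    mean(err[(i - w):(i + w)])
  }, numeric(1))
  i <- which.min(sm) # first index on ties
  list(count = i, error = err[i])
}

#' Majority-class baseline
#'
#' Error of always predicting the most frequent class, with the standard
#' error of a proportion.
#'
#' @param labels class labels.
#' @return list with `error` (%) and `se` (% standard error of proportion,
#'   `100 * sqrt(p(1-p)/n)` with `p = error/100`).
#' @examples
#' majority_class_error(rep(c("a", "b"), c(1, 9))) # 10% error
#' @export
majority_class_error <- function(labels) {
  n <- length(labels)
  p <- 1 - max(table(labels)) / n
  list(error = 100 * p, se = 100 * sqrt(p * (1 - p) / n))
}

#' Random-subset baseline
#'
#' Repeats the cross-validation protocol on `count` motifs drawn uniformly
#' without replacement, `repeats` times.
#'
#' @param em a column-normalized `enrichment_matrix` (or matrix).
#' @param labels class labels per row.
#' @param count motifs per draw.
#' @param repeats draws (default 10).
#' @param folds,seed,groups,ridge as in [incremental_cv_error()].
#' @return list with `error` (mean % across repeats) and `sd` (% across
#'   repeats).
#' @export
random_subset_baseline <- function(em, labels, count, repeats = 10,
                                   folds = 10, seed = 1L, groups = NULL,
                                   ridge = 1e-6) {
  m <- if (inherits(em, "enrichment_matrix")) em$scores else as.matrix(em)
  if (count > ncol(m)) stop("count exceeds the number of motifs")
  labels <- as.character(labels)
  min_class <- min(table(labels))
  n_units <- if (is.null(groups)) min_class else length(unique(groups))
  if (folds > n_units) folds <- n_units
  # the fold split is held fixed across repeats (same CV protocol); only the
  # motif draw varies, so count = all motifs reproduces the full-matrix error
  fold_of <- make_folds(labels, folds, derive_seed(seed, "rmcv"), groups)
  errs <- vapply(seq_len(repeats), function(r) {
    set.seed(derive_seed(seed, paste0("rm:", r)))
    cols <- sample.int(ncol(m), count)
    fe <- vapply(seq_len(folds), function(f) {
      tr <- fold_of != f
      if (length(unique(labels[tr])) < 2) return(NA_real_)
      fit <- lda_pooled_fit(m[tr, cols, drop = FALSE], labels[tr], ridge)
      pred <- lda_pooled_predict(fit, m[!tr, cols, drop = FALSE])
      100 * mean(pred != labels[!tr])
    }, numeric(1))
    mean(fe, na.rm = TRUE)
  }, numeric(1))
  list(error = mean(errs), sd = sd_pop(errs))
}

#' Full classifier report for one contrast
#'
#' Runs the supervised motif-selection machinery end to end: mRMR ranking,
#' the incremental cross-validated LDA error curve, the smoothed-minimum
#' motif count, and the majority-class and random-subset baselines.
#'
#' @param em a column-normalized `enrichment_matrix`.
#' @param labels class labels aligned to the matrix rows (2+ classes).
#' @param top motifs to rank (default 250).
#' @param folds CV folds (default 10).
#' @param smooth_width error-curve smoothing (default 3).
#' @param repeats random-subset repeats (default 10).
#' @param seed integer seed.
#' @param groups optional grouping (e.g. animal id) for the fold split.
#' @param row_filter optional logical vector selecting the rows entering the
#'   contrast (e.g. to exclude control samples).
#' @param ridge discriminant regularization.
#' @return object of class `classifier_report`: `ranked` (motif column
#'   indices), `curve`, `count`, `cv_error`, `cv_sd`, `mc_error`, `mc_se`,
#'   `rm_error`, `rm_sd`, `best_motif` (first mRMR pick).
#' @export
classify_contrast <- function(em, labels, top = 250, folds = 10,
                              smooth_width = 3, repeats = 10, seed = 1L,
                              groups = NULL, row_filter = NULL,
                              ridge = 1e-6) {
  m <- if (inherits(em, "enrichment_matrix")) em$scores else as.matrix(em)
  motif_names <- colnames(m) %||% as.character(seq_len(ncol(m)))
  labels <- as.character(labels)
  if (!is.null(row_filter)) {
    m <- m[row_filter, , drop = FALSE]
    labels <- labels[row_filter]
    if (!is.null(groups)) groups <- groups[row_filter]
  }
  stopifnot(length(unique(labels)) >= 2)
  ranked <- mrmr_rank(m, labels, top)
  curve <- incremental_cv_error(m, labels, ranked, folds = folds,
                                seed = derive_seed(seed, "cv"),
                                groups = groups, ridge = ridge)
  sel <- select_motif_count(curve, smooth_width)
  cv_sd <- curve$sd[sel$count]
  mc <- majority_class_error(labels)
  rm_ <- random_subset_baseline(m, labels, sel$count, repeats = repeats,
                                folds = folds,
                                seed = derive_seed(seed, "rm"),
                                groups = groups, ridge = ridge)
  structure(list(ranked = ranked, curve = curve, count = sel$count,
                 cv_error = sel$error, cv_sd = cv_sd, mc_error = mc$error,
                 mc_se = mc$se, rm_error = rm_$error, rm_sd = rm_$sd,
                 best_motif = motif_names[ranked[1]]),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(paste0("<classifier_report> %d motifs: CV %.2f%% (sd %.2f), ",
                     "majority class %.2f%% (EP %.2f), random subsets ",
                     "%.2f%% (sd %.2f)\n"),
              x$count, x$cv_error, x$cv_sd, x$mc_error, x$mc_se,
              x$rm_error, x$rm_sd))
  cat(" best motif:", x$best_motif, "\n")
  invisible(x)
}
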