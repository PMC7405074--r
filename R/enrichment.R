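# Motif enrichment: paired within-window shuffles, occurrence counting, and
# enrichment/constraint Z scores with the infinity rule.

#' Shuffle a module sequence within windows
#'
#' For each window instance, active module ids are permuted among the active
#' slots and inactive ids among the inactive slots, independently, so every
#' shuffle preserves the per-window module multisets and the strict
#' active/inactive transition structure. Excluded modules stay in place.
#'
#' @param ms a `module_sequence`.
#' @param n_shuffles number of shuffles (default 10).
#' @param seed integer seed; the ShuffleSet is fully determined by it.
#' @return list of `n_shuffles` `module_sequence` objects.
#' @export
shuffle_within_windows <- function(ms, n_shuffles = 10, seed = 1L) {
  stopifnot(inherits(ms, "module_sequence"))
  n <- nrow(ms)
  inst <- if (n) cumsum(c(TRUE, ms$window[-1] != ms$window[-n])) else integer()
  set.seed(seed)
  out <- vector("list", n_shuffles)
  for (s in seq_len(n_shuffles)) {
    sh <- ms
    for (w in unique(inst)) {
      for (knd in c("active", "inactive")) {
        idx <- which(inst == w & ms$kind == knd & !ms$excluded)
        if (length(idx) > 1) {
          perm <- idx[sample.int(length(idx))]
          sh$module[idx] <- ms$module[perm]
          sh$token[idx] <- ms$token[perm]
          sh$length_frames[idx] <- ms$length_frames[perm]
        }
      }
    }
    # anchors after permuting lengths
    if (n) sh$start_frame <- c(0L, cumsum(sh$length_frames)[-n])
    out[[s]] <- sh
  }
  out
}

#' Count motif occurrences in a sequence
#'
#' Sliding exact matches; by default overlapping matches all count (a count
#' independent of replacement order), switchable to non-overlapping greedy
#' left-to-right. Matches never span excluded modules.
#'
#' @param x a `module_sequence`, character tokens, or integer symbols.
#' @param motifs a `motif_library`, a list of integer motif vectors, or a
#'   single motif (integer or token vector).
#' @param overlap count overlapping matches (default TRUE)?
#' @return integer vector of counts, one per motif.
#' @examples
#' count_occurrences(c("A1","I1","A1","I1","A1"), c("A1","I1","A1")) # 2
#' @export
count_occurrences <- function(x, motifs, overlap = TRUE) {
  if (inherits(x, "module_sequence")) {
    x <- encode_sequence(x)
  } else if (is.character(x)) {
    x <- encode_tokens(x)
  }
  motifs <- as_motif_list(motifs)
  count_motifs_cpp(as.integer(x), motifs, isTRUE(overlap))
}

as_motif_list <- function(motifs) {
  if (inherits(motifs, "motif_library")) return(motifs$motifs)
  if (is.character(motifs)) return(list(encode_tokens(motifs)))
  if (is.numeric(motifs)) return(list(as.integer(motifs)))
  lapply(motifs, function(m) {
    if (is.character(m)) encode_tokens(m) else as.integer(m)
  })
}

#' Enrichment/constraint Z score
#'
#' The deviation of a motif's real count from its paired shuffled counts:
#' `Z = (x - mean(shuffles)) / sd(shuffles)` with the population SD over the
#' shuffles. When the shuffle SD is 0 the score would be infinite; it is
#' replaced by the constant `sqrt(1 + n_shuffles)` (+ when x exceeds the
#' shuffle mean, - when below, and 0 when equal).
#'
#' @param real_count real occurrence count (scalar or vector over motifs).
#' @param shuffled_counts numeric vector of the paired shuffle counts (when
#'   `real_count` is a vector, a matrix motifs x shuffles).
#' @return numeric Z score(s), always finite.
#' @examples
#' enrichment_score(10, c(3, 4, 4, 4, 5, 6, 3, 5, 4, 7)) # about 3.48-style
#' @export
enrichment_score <- function(real_count, shuffled_counts) {
  m <- if (is.matrix(shuffled_counts)) shuffled_counts else
    matrix(shuffled_counts, nrow = length(real_count),
           ncol = length(shuffled_counts), byrow = TRUE)
  stopifnot(nrow(m) == length(real_count))
  n_sh <- ncol(m)
  mu <- rowMeans(m)
  sdev <- sqrt(rowMeans((m - mu)^2))
  z <- (real_count - mu) / sdev
  inf_const <- sqrt(1 + n_sh)
  zero_sd <- sdev == 0
  z[zero_sd] <- sign(real_count[zero_sd] - mu[zero_sd]) * inf_const
  unname(z)
}

#' Leave-one-out Z scores of the shuffles against themselves
#'
#' Each shuffle in turn plays the real count and is scored against the other
#' shuffles; the same infinity rule as [enrichment_score()] applies (with
#' the constant still computed from the full shuffle count).
#'
#' @param shuffled_counts numeric vector of shuffle counts (or matrix motifs
#'   x shuffles).
#' @param n_shuffles_total shuffle count used for the infinity constant
#'   (default: the number supplied).
#' @return numeric vector (or matrix) of leave-one-out Z values.
#' @export
shuffle_self_scores <- function(shuffled_counts,
                                n_shuffles_total = NULL) {
  m <- if (is.matrix(shuffled_counts)) shuffled_counts else
    matrix(shuffled_counts, nrow = 1)
  n_sh <- ncol(m)
  n_shuffles_total <- n_shuffles_total %||% n_sh
  inf_const <- sqrt(1 + n_shuffles_total)
  out <- matrix(NA_real_, nrow(m), n_sh)
  for (j in seq_len(n_sh)) {
    rest <- m[, -j, drop = FALSE]
    mu <- rowMeans(rest)
    sdev <- sqrt(rowMeans((rest - mu)^2))
    z <- (m[, j] - mu) / sdev
    zero_sd <- sdev == 0
    z[zero_sd] <- sign(m[zero_sd, j] - mu[zero_sd]) * inf_const
    out[, j] <- z
  }
  if (!is.matrix(shuffled_counts)) out <- drop(out)
  out
}

#' Build the samples-by-motifs enrichment matrix
#'
#' For every animal and window instance, counts each library motif in the
#' real module sequence and in `n_shuffles` paired within-window shuffles,
#' and scores the deviation with [enrichment_score()]. Samples with zero
#' real and zero shuffle counts score 0 (the "equal" branch of the infinity
#' rule).
#'
#' @param sequences named list of `module_sequence` objects (one per animal).
#' @param library a `motif_library`.
#' @param n_shuffles paired shuffles per sequence (default 10).
#' @param overlap occurrence-counting convention (default overlapping).
#' @param min_modules drop window instances with fewer modules than this
#'   (default 0 = keep all; truncated partial windows at a recording's end
#'   carry too few modules for stable counts).
#' @param drop_censored drop each animal's final window instance, whose true
#'   extent is censored by the end of the recording (default FALSE).
#' @param seed master seed; per-animal shuffle seeds are derived from it.
#' @return object of class `enrichment_matrix`: `scores` (samples x motifs),
#'   `samples` (data frame: animal_id, window, instance), `motifs` (token
#'   strings), `inf_fraction` (share of scores set by the infinity rule),
#'   `normalized` (FALSE).
#' @export
enrichment_matrix <- function(sequences, library, n_shuffles = 10,
                              overlap = TRUE, min_modules = 0,
                              drop_censored = FALSE, seed = 1L) {
  stopifnot(inherits(library, "motif_library"))
  rows <- list()
  meta <- list()
  n_inf <- 0
  total <- 0
  for (aid in names(sequences)) {
    ms <- sequences[[aid]]
    n <- nrow(ms)
    inst <- if (n) cumsum(c(TRUE, ms$window[-1] != ms$window[-n])) else
      integer()
    shuffles <- shuffle_within_windows(ms, n_shuffles,
                                       seed = derive_seed(seed,
                                                          paste0("sh:", aid)))
    insts <- unique(inst)
    if (drop_censored && length(insts) > 1) {
      insts <- insts[-length(insts)]
    }
    for (w in insts) {
      idx <- which(inst == w)
      if (length(idx) < min_modules) next
      sub_real <- ms[idx, , drop = FALSE]
      class(sub_real) <- class(ms)
      x <- count_occurrences(sub_real, library, overlap)
      sh_counts <- vapply(shuffles, function(sh) {
        sub <- sh[idx, , drop = FALSE]
        class(sub) <- class(ms)
        count_occurrences(sub, library, overlap)
      }, integer(length(library$motifs)))
      if (length(library$motifs) == 1L) {
        sh_counts <- matrix(sh_counts, nrow = 1)
      }
      z <- enrichment_score(x, sh_counts)
      sdev0 <- apply(sh_counts, 1, function(r) all(r == r[1]))
      n_inf <- n_inf + sum(sdev0 & x != sh_counts[, 1])
      total <- total + length(z)
      rows[[length(rows) + 1L]] <- z
      meta[[length(meta) + 1L]] <- data.frame(animal_id = aid,
                                              window = ms$window[idx[1]],
                                              instance = w)
    }
  }
  scores <- do.call(rbind, rows)
  colnames(scores) <- library$tokens
  structure(list(scores = scores, samples = do.call(rbind, meta),
                 motifs = library$tokens,
                 inf_fraction = if (total) n_inf / total else 0,
                 normalized = FALSE),
            class = "enrichment_matrix")
}

#' Column-normalize an enrichment matrix
#'
#' Subtracts each motif column's mean and divides by its population SD;
#' zero-SD columns become all zeros and are flagged.
#'
#' @param em an `enrichment_matrix` (>= 2 rows).
#' @return the matrix with `normalized = TRUE` and a `constant_columns`
#'   logical vector.
#' @export
normalize_columns <- function(em) {
  stopifnot(inherits(em, "enrichment_matrix"), nrow(em$scores) >= 2)
  mu <- colMeans(em$scores)
  sdev <- sqrt(colMeans(sweep(em$scores, 2, mu)^2))
  flag <- sdev == 0
  sdev[flag] <- 1
  em$scores <- sweep(sweep(em$scores, 2, mu), 2, sdev, "/")
  em$scores[, flag] <- 0
  em$normalized <- TRUE
  em$constant_columns <- flag
  em
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cat("<enrichment_matrix>", nrow(x$scores), "samples x", ncol(x$scores),
      "motifs;", sprintf("%.1f%%", 100 * x$inf_fraction),
      "infinity-rule scores;", if (x$normalized) "column-normalized" else
        "raw", "\n")
  invisible(x)
}
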