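# shared fixtures and small oracles, built in code at test time

# best label agreement over all permutations of cluster ids (K small)
best_label_agreement <- function(truth, assigned) {
  ids <- sort(unique(assigned))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- 0
  for (p in perms(ids)) {
    remap <- integer(max(ids))
    remap[ids] <- p
    best <- max(best, mean(remap[assigned] == truth))
  }
  best
}

# minimal two-module spec: one active, one inactive template, single window
tiny_spec <- function(seed = 1L, planted_motifs = list(), amp = 5,
                      amp_sd = 0, len_a = 3, len_a_sd = 0) {
  simulation_spec(
    frame_rate = 25,
    schedule = data.frame(label = "all", start_frame = 0, end_frame = 1e7),
    active_templates = list(list(length_mean = len_a, length_sd = len_a_sd,
                                 amp_mean = amp, amp_sd = amp_sd,
                                 amp_min = 1)),
    inactive_templates = list(list(length_mean = 2, length_spread = 0)),
    module_probs = list(all = list(active = 1, inactive = 1)),
    planted_motifs = planted_motifs,
    seed = seed
  )
}

# module_sequence from a plain token vector, one window, unit lengths
make_repeated_ms <- function(tokens) {
  kind <- ifelse(substr(tokens, 1, 1) == "A", "active", "inactive")
  structure(data.frame(token = tokens, kind = kind,
                       module = abs(encode_tokens(tokens)),
                       start_frame = seq_along(tokens) - 1L,
                       length_frames = 1L, window = "w", excluded = FALSE,
                       stringsAsFactors = FALSE),
            frame_rate = 25, animal_id = "t",
            class = c("module_sequence", "data.frame"))
}

# brute-force non-overlapping occurrence count (position scan oracle)
count_nonoverlap_oracle <- function(x, motif) {
  W <- length(motif)
  n <- length(x)
  cnt <- 0L
  i <- 1L
  while (i + W - 1L <= n) {
    if (all(x[i:(i + W - 1L)] == motif)) {
      cnt <- cnt + 1L
      i <- i + W
    } else i <- i + 1L
  }
  cnt
}

# brute-force overlapping count
count_overlap_oracle <- function(x, motif) {
  W <- length(motif)
  n <- length(x)
  if (W > n) return(0L)
  sum(vapply(seq_len(n - W + 1L), function(i)
    all(x[i:(i + W - 1L)] == motif), logical(1)))
}

# exhaustive maximal-savings motif(s) of a sequence
oracle_best_motif <- function(x, max_len = 10) {
  n <- length(x)
  best <- 0
  defs <- character()
  for (W in 2:max(2, min(max_len, n))) {
    if (W > n) break
    key <- vapply(seq_len(n - W + 1), function(i)
      paste(x[i:(i + W - 1)], collapse = ","), character(1))
    for (g in unique(key)) {
      pos <- which(key == g)
      N <- 0L
      last <- -W
      for (p in pos) if (p > last + W - 1L) { N <- N + 1L; last <- p }
      if (N < 2) next
      s <- W * N - (W + 1 + N)
      if (s > best) { best <- s; defs <- g }
      else if (s == best && s > 0) defs <- c(defs, g)
    }
  }
  list(savings = best, defs = defs)
}

pop_kurtosis <- function(x) {
  m <- mean(x)
  mean((x - m)^4) / mean((x - m)^2)^2
}
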