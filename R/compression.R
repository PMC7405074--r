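# Hierarchical compression: the offline most-compressive-motif heuristic,
# compressibility, the merged motif library, 500-module blocks and
# delta-compressibility.

#' Savings of replacing a motif
#'
#' A motif of length `W` symbols occurring `N` times (non-overlapping) saves
#' `W*N - (W + 1 + N)` symbols: the replaced occurrences minus the cost of
#' the dictionary entry (`W + 1`) and of the new symbol at each occurrence
#' (`N`). Single symbols never compress (`W = 1` gives `-2` regardless of
#' `N`).
#'
#' @param W motif length in symbols (>= 1).
#' @param N occurrence count (>= 1).
#' @return integer savings (vectorized).
#' @examples
#' savings(2, 4) # 1
#' savings(3, 5) # 6
#' @export
savings <- function(W, N) {
  stopifnot(all(W >= 1), all(N >= 1))
  W * N - (W + 1 + N)
}

# module sequence -> signed integer codes; excluded modules become the break
# sentinel 0 so motifs never span them
encode_sequence <- function(ms) {
  stopifnot(inherits(ms, "module_sequence"))
  codes <- encode_tokens(ms$token)
  codes[ms$excluded] <- 0L
  codes
}

#' Compress a symbol sequence by iterated motif replacement
#'
#' At each iteration every contiguous candidate motif of length 2..`max_len`
#' in the current sequence is enumerated, occurrences are counted
#' non-overlapping (greedy left-to-right), and the motif with the largest
#' [savings()] is replaced everywhere by a fresh symbol; iteration stops
#' when no candidate saves > 0. Because later candidates are scanned over
#' the partially compressed sequence, rules may contain earlier rule
#' symbols, which is how motifs longer than `max_len` arise by nesting.
#' Ties prefer larger savings, then longer motifs, then the
#' lexicographically smallest definition.
#'
#' @param x a `module_sequence`, a character vector of module tokens, or an
#'   integer symbol vector (0 = break sentinel that motifs never span).
#' @param max_len maximum motif length per iteration (default 10).
#' @return object of class `grammar`: `rules` (data frame: `symbol`,
#'   `savings`, `count`, `length`), `defs` (list of integer definitions),
#'   `compressed` (integer sequence), `original_length` (sentinel-free
#'   symbols), `compressibility` (total savings / original length),
#'   `first_new_symbol`, and `tokens` (TRUE when input was token-coded).
#' @export
compress_sequence <- function(x, max_len = 10) {
  tokens <- FALSE
  if (inherits(x, "module_sequence")) {
    x <- encode_sequence(x)
    tokens <- TRUE
  } else if (is.character(x)) {
    x <- encode_tokens(x)
    tokens <- TRUE
  }
  x <- as.integer(x)
  first_new <- if (length(x)) max(abs(x)) + 1L else 1L
  res <- compress_cpp(x, as.integer(max_len), first_new)
  comp <- if (res$original_length > 0) {
    res$total_savings / res$original_length
  } else 0
  structure(list(
    rules = data.frame(symbol = res$rule_symbols, savings = res$savings,
                       count = res$counts,
                       length = vapply(res$rule_defs, length, integer(1))),
    defs = res$rule_defs, compressed = res$compressed,
    original_length = res$original_length, compressibility = comp,
    first_new_symbol = first_new, tokens = tokens), class = "grammar")
}

#' @export
print.grammar <- function(x, ...) {
  cat("<grammar>", nrow(x$rules), "rules; compressibility",
      signif(x$compressibility, 4), "over", x$original_length, "symbols\n")
  invisible(x)
}

#' Expand a symbol to its terminal module sequence
#'
#' @param symbol integer symbol (terminal or rule symbol of `g`).
#' @param g a `grammar` from [compress_sequence()].
#' @return integer vector of terminal symbols.
#' @export
expand_symbol <- function(symbol, g) {
  stopifnot(inherits(g, "grammar"))
  defs <- g$defs
  syms <- g$rules$symbol
  rec <- function(s) {
    if (s < g$first_new_symbol) return(s)
    i <- match(s, syms)
    if (is.na(i)) stop("unknown symbol: ", s)
    unlist(lapply(defs[[i]], rec))
  }
  as.integer(rec(symbol))
}

#' Expand a compressed sequence back to terminals
#'
#' Round-trip check: `expand_sequence(g)` reproduces the original input of
#' [compress_sequence()] exactly.
#'
#' @param g a `grammar`.
#' @return integer vector of terminal symbols (0 sentinels preserved).
#' @export
expand_sequence <- function(g) {
  stopifnot(inherits(g, "grammar"))
  memo <- new.env(parent = emptyenv())
  syms <- g$rules$symbol
  rec <- function(s) {
    if (s < g$first_new_symbol) return(s)
    key <- as.character(s)
    if (!is.null(memo[[key]])) return(memo[[key]])
    i <- match(s, syms)
    if (is.na(i)) stop("unknown symbol: ", s)
    v <- unlist(lapply(g$defs[[i]], rec))
    memo[[key]] <- v
    v
  }
  as.integer(unlist(lapply(g$compressed, rec)))
}

#' Merge grammars into a unique motif library
#'
#' Every rule of every grammar is expanded to its terminal module sequence;
#' unique motifs are kept and sorted canonically by length, then
#' lexicographically on module tokens (actives before inactives, ids
#' ascending).
#'
#' @param grammars list of `grammar` objects from module sequences.
#' @return object of class `motif_library`: `motifs` (list of integer
#'   terminal sequences), `tokens` (space-separated token strings),
#'   `length` (modules per motif), `sources` (in how many grammars each
#'   motif was found).
#' @export
build_library <- function(grammars) {
  stopifnot(length(grammars) >= 1)
  all_motifs <- list()
  src <- character()
  for (gi in seq_along(grammars)) {
    g <- grammars[[gi]]
    for (r in seq_len(nrow(g$rules))) {
      m <- expand_symbol(g$rules$symbol[r], g)
      all_motifs[[length(all_motifs) + 1L]] <- m
      src <- c(src, paste0(gi, ":", r))
    }
  }
  if (!length(all_motifs)) {
    return(structure(list(motifs = list(), tokens = character(),
                          length = integer(), sources = integer()),
                     class = "motif_library"))
  }
  keys <- vapply(all_motifs, paste, character(1), collapse = " ")
  grams <- as.integer(sub(":.*", "", src))
  first <- !duplicated(keys)
  n_src <- tapply(grams, keys, function(g) length(unique(g)))
  sources <- as.integer(n_src[keys[first]])
  motifs <- all_motifs[first]
  # canonical sort: length, then token order (A1 < A2 < ... < I1 < I2 ...)
  sort_key <- vapply(motifs, function(m) {
    paste(sprintf("%d%06d", as.integer(m < 0), abs(m)), collapse = " ")
  }, character(1))
  o <- order(lengths(motifs), sort_key)
  structure(list(motifs = motifs[o],
                 tokens = vapply(motifs[o], function(m)
                   paste(decode_tokens(m), collapse = " "), character(1)),
                 length = lengths(motifs[o]),
                 sources = as.integer(sources[o])),
            class = "motif_library")
}

#' @export
print.motif_library <- function(x, ...) {
  cat("<motif_library>", length(x$motifs), "unique motifs, lengths",
      if (length(x$motifs)) paste(range(x$length), collapse = "-") else "-",
      "\n")
  invisible(x)
}

#' Write / read a motif library (one motif per line, space-separated tokens)
#'
#' @param lib a `motif_library`.
#' @param path file path.
#' @export
write_library <- function(lib, path) {
  writeLines(lib$tokens, path)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  motifs <- lapply(strsplit(lines, " +"), encode_tokens)
  sort_key <- vapply(motifs, function(m)
    paste(sprintf("%d%06d", as.integer(m < 0), abs(m)), collapse = " "),
    character(1))
  o <- order(lengths(motifs), sort_key)
  structure(list(motifs = motifs[o],
                 tokens = vapply(motifs[o], function(m)
                   paste(decode_tokens(m), collapse = " "), character(1)),
                 length = lengths(motifs[o]),
                 sources = rep(NA_integer_, length(motifs))),
            class = "motif_library")
}

#' Per-block compressibility
#'
#' Compressibility varies with input length, so comparable values are
#' computed on non-overlapping blocks of a fixed number of modules
#' (default 500); the trailing partial block is dropped.
#'
#' @param x a `module_sequence` or integer symbol vector.
#' @param block block length in modules (default 500).
#' @param max_len motif length cap per iteration (default 10).
#' @return data frame with `block`, `start_module`, `compressibility`, and
#'   `window` (label of the block's first module when available).
#' @export
block_compressibility <- function(x, block = 500, max_len = 10) {
  win <- NULL
  if (inherits(x, "module_sequence")) {
    win <- x$window
    x <- encode_sequence(x)
  }
  x <- as.integer(x)
  n <- length(x)
  nb <- floor(n / block)
  if (nb == 0) {
    warning("sequence shorter than one block")
    return(data.frame(block = integer(), start_module = integer(),
                      compressibility = numeric(), window = character()))
  }
  out <- data.frame(block = seq_len(nb),
                    start_module = (seq_len(nb) - 1L) * block + 1L,
                    compressibility = NA_real_,
                    window = NA_character_)
  for (b in seq_len(nb)) {
    idx <- ((b - 1L) * block + 1L):(b * block)
    out$compressibility[b] <- compress_sequence(x[idx], max_len)$compressibility
    if (!is.null(win)) out$window[b] <- win[idx[1]]
  }
  out
}

#' Delta-compressibility against paired shuffles
#'
#' The difference between each sample's real compressibility and the mean of
#' its paired shuffled values.
#'
#' @param real numeric vector of real compressibility values.
#' @param shuffled matrix with one row per sample and one column per shuffle.
#' @return numeric vector `real - rowMeans(shuffled)`.
#' @export
delta_compressibility <- function(real, shuffled) {
  shuffled <- as.matrix(shuffled)
  if (length(real) != nrow(shuffled)) {
    stop("real and shuffled values are not paired sample-for-sample")
  }
  real - rowMeans(shuffled)
}
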