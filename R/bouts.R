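# Bout segmentation: alternating active/inactive bouts and the six-feature
# description of every active bout.

#' Features of one active bout
#'
#' The six features describing an active bout: length in seconds, and the
#' mean, SD, total, minimum and maximum of its per-frame delta-pixel values.
#' The SD is the population SD (divide by n), so a one-frame bout has SD 0.
#'
#' @param values positive integer delta-pixel values of the bout's frames.
#' @param frame_rate frames per second.
#' @return named numeric vector `length_s`, `mean`, `sd`, `total`, `min`,
#'   `max`.
#' @examples
#' active_features(c(5, 3, 2), 25)
#' @export
active_features <- function(values, frame_rate) {
  if (any(values <= 0)) stop("active bouts contain only positive values")
  c(length_s = length(values) / frame_rate, mean = mean(values),
    sd = sd_pop(values), total = sum(values), min = min(values),
    max = max(values))
}

#' Segment a recording into alternating bouts
#'
#' Active bouts are maximal runs of frames with delta-pixels > 0; inactive
#' bouts are maximal runs of zeros. Together they partition the recording.
#' Call [apply_artifact_ceiling()] and [apply_masks()] first.
#'
#' Flags: `at_edge` marks the leading and trailing bouts (their true extent
#' is censored by the recording boundary); `excluded` marks bouts lying
#' wholly inside a mask and inactive bouts abutting or overlapping a mask
#' boundary (their zeros may be mask artifacts); `artifact_touched` marks
#' inactive bouts that absorbed frames zeroed by the artifact ceiling.
#'
#' @param rec an [activity_recording()].
#' @return a `bout_table` data frame: `animal_id`, `kind`, `start_frame`,
#'   `length_frames`, `length_s`, `mean`, `sd`, `total`, `min`, `max` (the
#'   last five `NA` for inactive bouts), `window` (schedule label of the
#'   bout's start frame), `window_instance`, and the logical flags above.
#' @export
segment_bouts <- function(rec) {
  stopifnot(inherits(rec, "activity_recording"))
  v <- rec$values
  n <- length(v)
  empty <- data.frame(animal_id = character(), kind = character(),
                      start_frame = integer(), length_frames = integer(),
                      length_s = numeric(), mean = numeric(), sd = numeric(),
                      total = numeric(), min = numeric(), max = numeric(),
                      window = character(), window_instance = integer(),
                      at_edge = logical(), excluded = logical(),
                      artifact_touched = logical())
  if (n == 0) {
    return(structure(empty, frame_rate = rec$frame_rate,
                     class = c("bout_table", "data.frame")))
  }
  r <- rle(v > 0)
  end <- cumsum(r$lengths)
  start <- end - r$lengths # 0-based
  kind <- ifelse(r$values, "active", "inactive")
  nb <- length(start)

  feats <- matrix(NA_real_, nb, 5,
                  dimnames = list(NULL, c("mean", "sd", "total", "min", "max")))
  act <- which(r$values)
  for (i in act) {
    x <- v[(start[i] + 1L):end[i]]
    feats[i, ] <- c(mean(x), sd_pop(x), sum(x), min(x), max(x))
  }

  win <- rep(NA_character_, nb)
  win_inst <- rep(NA_integer_, nb)
  if (nrow(rec$schedule)) {
    idx <- findInterval(start, rec$schedule$start_frame)
    win <- rec$schedule$label[idx]
    win_inst <- rec$schedule$instance[idx]
  }

  at_edge <- seq_len(nb) %in% c(1L, nb)
  excluded <- rep(FALSE, nb)
  artifact <- rep(FALSE, nb)
  if (nrow(rec$masks)) {
    for (i in seq_len(nrow(rec$masks))) {
      ms <- rec$masks$start_frame[i]
      me <- rec$masks$end_frame[i]
      inside <- start >= ms & end <= me
      touches <- kind == "inactive" & start <= me & end >= ms
      excluded <- excluded | inside | touches
    }
  }
  rep_art <- attr(rec, "artifact_report")
  if (!is.null(rep_art) && nrow(rep_art)) {
    for (i in seq_len(nrow(rep_art))) {
      as_ <- rep_art$start_frame[i]
      ae <- as_ + rep_art$length_frames[i]
      artifact <- artifact | (kind == "inactive" & start < ae & end > as_)
    }
  }

  out <- data.frame(animal_id = rec$animal_id, kind = kind,
                    start_frame = start, length_frames = r$lengths,
                    length_s = r$lengths / rec$frame_rate,
                    mean = feats[, "mean"], sd = feats[, "sd"],
                    total = feats[, "total"], min = feats[, "min"],
                    max = feats[, "max"], window = win,
                    window_instance = win_inst, at_edge = at_edge,
                    excluded = excluded, artifact_touched = artifact,
                    stringsAsFactors = FALSE)
  structure(out, frame_rate = rec$frame_rate,
            class = c("bout_table", "data.frame"))
}

#' Combine per-animal bout tables
#'
#' @param bout_tables list of `bout_table` data frames.
#' @return one `bout_table` with a `bout_index` column (row within animal).
#' @export
bind_bouts <- function(bout_tables) {
  fr <- attr(bout_tables[[1]], "frame_rate")
  out <- do.call(rbind, lapply(bout_tables, function(b) {
    b$bout_index <- seq_len(nrow(b))
    as.data.frame(b)
  }))
  rownames(out) <- NULL
  structure(out, frame_rate = fr, class = c("bout_table", "data.frame"))
}

#' Module sequence from clustered bouts
#'
#' Attaches module assignments to a bout table and returns the animal's
#' behavior as an alternating sequence of module tokens with frame anchors.
#' Excluded bouts keep their row but are flagged; downstream compression and
#' counting treat them as breaks that motifs never span.
#'
#' @param bouts a `bout_table` for one animal (in recording order).
#' @param active_modules integer module ids for the active bouts, in order.
#' @param inactive_modules integer module ids for the inactive bouts, in
#'   order.
#' @return a `module_sequence` data frame (see
#'   [generate_module_sequence()]).
#' @export
module_sequence_from_bouts <- function(bouts, active_modules,
                                       inactive_modules) {
  stopifnot(inherits(bouts, "bout_table"))
  act <- bouts$kind == "active"
  stopifnot(sum(act) == length(active_modules),
            sum(!act) == length(inactive_modules))
  module <- integer(nrow(bouts))
  module[act] <- active_modules
  module[!act] <- inactive_modules
  token <- ifelse(act, paste0("A", module), paste0("I", module))
  out <- data.frame(token = token, kind = bouts$kind, module = module,
                    start_frame = bouts$start_frame,
                    length_frames = bouts$length_frames,
                    window = bouts$window,
                    excluded = bouts$excluded,
                    stringsAsFactors = FALSE)
  structure(out, frame_rate = attr(bouts, "frame_rate"),
            animal_id = bouts$animal_id[1],
            class = c("module_sequence", "data.frame"))
}

#' Write a bout table to CSV
#'
#' @param bouts a `bout_table`.
#' @param path output file.
#' @param config_hash optional provenance hash written as a `#` comment line.
#' @export
write_bout_table <- function(bouts, path, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash)) {
    writeLines(paste0("# config_hash: ", config_hash), con)
  }
  utils::write.csv(as.data.frame(bouts), con, row.names = FALSE)
  invisible(path)
}
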