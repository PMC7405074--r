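# Activity recordings: container, artifact ceiling, water-change masks, CSV
# ingestion.

#' One animal's delta-pixel recording
#'
#' @param values non-negative integer vector, one delta-pixel count per frame.
#' @param frame_rate frames per second (default 25).
#' @param animal_id identifier.
#' @param schedule data frame (`label`, `start_frame`, `end_frame`), half-open
#'   0-based windows tiling the recording; defaults to one window labelled
#'   `"all"`.
#' @param masks data frame (`start_frame`, `end_frame`) of intervals to
#'   exclude (e.g. water changes); overlapping masks are merged with a
#'   warning.
#' @return an object of class `activity_recording`.
#' @export
activity_recording <- function(values, frame_rate = 25, animal_id = "a1",
                               schedule = NULL, masks = NULL) {
  values <- as.integer(values)
  if (anyNA(values) || any(values < 0)) {
    stop("delta-pixel values must be non-negative integers")
  }
  n <- length(values)
  if (is.null(schedule)) {
    schedule <- data.frame(label = "all", start_frame = 0L, end_frame = n)
    if (n == 0) schedule <- schedule[0, ]
  }
  if (nrow(schedule) && !"instance" %in% names(schedule)) {
    schedule$instance <- seq_len(nrow(schedule))
  }
  if (nrow(schedule)) {
    o <- order(schedule$start_frame)
    schedule <- schedule[o, ]
    if (schedule$start_frame[1] != 0 ||
        utils::tail(schedule$end_frame, 1) != n ||
        any(schedule$start_frame[-1] != schedule$end_frame[-nrow(schedule)])) {
      stop("schedule windows must tile the recording without gaps or overlap")
    }
  }
  if (is.null(masks)) {
    masks <- data.frame(start_frame = integer(), end_frame = integer())
  }
  if (nrow(masks)) {
    if (any(masks$start_frame < 0) || any(masks$end_frame > n) ||
        any(masks$end_frame <= masks$start_frame)) {
      stop("masks must be non-empty intervals inside the recording")
    }
    masks <- masks[order(masks$start_frame), , drop = FALSE]
    merged <- masks[1, , drop = FALSE]
    warned <- FALSE
    for (i in seq_len(nrow(masks))[-1]) {
      last <- nrow(merged)
      if (masks$start_frame[i] <= merged$end_frame[last]) {
        merged$end_frame[last] <- max(merged$end_frame[last],
                                      masks$end_frame[i])
        warned <- TRUE
      } else {
        merged <- rbind(merged, masks[i, ])
      }
    }
    if (warned) warning("overlapping masks merged")
    masks <- merged
    rownames(masks) <- NULL
  }
  structure(list(animal_id = animal_id, values = values,
                 frame_rate = frame_rate, schedule = schedule,
                 masks = masks),
            class = "activity_recording")
}

#' @export
print.activity_recording <- function(x, ...) {
  cat("<activity_recording>", x$animal_id, "-", length(x$values),
      "frames @", x$frame_rate, "Hz,", nrow(x$schedule), "windows,",
      nrow(x$masks), "masks\n")
  invisible(x)
}

# maximal non-zero runs as (start 0-based, length)
nonzero_runs <- function(values) {
  r <- rle(values > 0)
  end <- cumsum(r$lengths)
  start <- end - r$lengths
  data.frame(start_frame = start[r$values], length_frames = r$lengths[r$values])
}

#' Apply the artifact ceiling
#'
#' Any maximal non-zero run containing at least one frame above `ceiling` is
#' zeroed over its full extent (tracking artifacts masquerade as huge
#' delta-pixel values). The default of 200 delta-pixels suits 96-well
#' recordings where genuine movement stays well below it.
#'
#' @param rec an [activity_recording()].
#' @param ceiling positive delta-pixel threshold (default 200).
#' @return the recording with zeroed runs, plus an `artifact_report`
#'   attribute (data frame of zeroed runs: start, length, max value) used to
#'   flag the inactive bouts those frames merge into.
#' @export
apply_artifact_ceiling <- function(rec, ceiling = 200) {
  stopifnot(inherits(rec, "activity_recording"), ceiling > 0)
  runs <- nonzero_runs(rec$values)
  report <- runs[0, ]
  report$max_value <- integer()
  if (nrow(runs)) {
    mx <- vapply(seq_len(nrow(runs)), function(i) {
      idx <- runs$start_frame[i] + seq_len(runs$length_frames[i])
      max(rec$values[idx])
    }, numeric(1))
    bad <- which(mx > ceiling)
    if (length(bad)) {
      for (i in bad) {
        idx <- runs$start_frame[i] + seq_len(runs$length_frames[i])
        rec$values[idx] <- 0L
      }
      report <- cbind(runs[bad, , drop = FALSE], max_value = mx[bad])
      rownames(report) <- NULL
    }
  }
  attr(rec, "artifact_report") <- report
  rec
}

#' Zero masked intervals
#'
#' Frames inside the recording's masks are set to zero; the masks stay
#' attached so [segment_bouts()] can flag the affected bouts for exclusion.
#'
#' @param rec an [activity_recording()].
#' @return the recording with masked frames zeroed.
#' @export
apply_masks <- function(rec) {
  stopifnot(inherits(rec, "activity_recording"))
  if (nrow(rec$masks)) {
    for (i in seq_len(nrow(rec$masks))) {
      idx <- (rec$masks$start_frame[i] + 1L):rec$masks$end_frame[i]
      rec$values[idx] <- 0L
    }
  }
  rec
}

#' Read a frames-by-animals delta-pixel table
#'
#' @param path CSV/TSV file whose header holds animal ids and whose columns
#'   hold per-frame integer delta-pixel counts. Lines starting with `#` are
#'   skipped.
#' @param frame_rate frames per second.
#' @param schedule optional schedule data frame shared by all animals
#'   (defaults to a single `"all"` window).
#' @param masks optional named list of per-animal mask data frames.
#' @param sep field separator (`","` or `"\t"`); guessed from the extension.
#' @return named list of [activity_recording()] objects.
#' @export
read_activity_csv <- function(path, frame_rate = 25, schedule = NULL,
                              masks = NULL, sep = NULL) {
  sep <- sep %||% if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.csv(path, sep = sep, comment.char = "#",
                         check.names = FALSE)
  n <- nrow(tab)
  sched <- schedule
  if (!is.null(sched)) {
    sched <- sched[sched$start_frame < n, , drop = FALSE]
    sched$end_frame <- pmin(sched$end_frame, n)
  }
  out <- lapply(names(tab), function(id) {
    activity_recording(tab[[id]], frame_rate = frame_rate, animal_id = id,
                       schedule = sched,
                       masks = if (!is.null(masks)) masks[[id]] else NULL)
  })
  names(out) <- names(tab)
  out
}
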