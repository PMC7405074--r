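# Synthetic activity data: seeded generator for module sequences and
# delta-pixel traces with planted modules and motifs, used to validate every
# downstream stage without external recordings.

#' Parse / build module tokens
#'
#' Modules are written `A<k>` (active) or `I<k>` (inactive). Internally they
#' are encoded as signed integers (+k active, -k inactive, 0 reserved as a
#' break sentinel that candidate motifs never span).
#'
#' @param tokens character vector of module tokens.
#' @return `encode_tokens()` returns an integer vector; `decode_tokens()` its
#'   inverse.
#' @examples
#' encode_tokens(c("A1", "I2"))
#' decode_tokens(c(1L, -2L))
#' @export
encode_tokens <- function(tokens) {
  kind <- substr(tokens, 1, 1)
  if (!all(kind %in% c("A", "I"))) {
    stop("module tokens must look like 'A<k>' or 'I<k>'")
  }
  id <- as.integer(substring(tokens, 2))
  if (anyNA(id) || any(id < 1)) stop("module ids must be positive integers")
  ifelse(kind == "A", id, -id)
}

#' @rdname encode_tokens
#' @param codes integer vector of signed module codes.
#' @export
decode_tokens <- function(codes) {
  out <- ifelse(codes > 0, paste0("A", codes), paste0("I", -codes))
  out[codes == 0] <- NA_character_
  out
}

token_kind <- function(tokens) ifelse(substr(tokens, 1, 1) == "A",
                                      "active", "inactive")

#' Specification for a synthetic activity recording
#'
#' Defines the generative conditions for seeded synthetic data: per-module
#' templates for bout length and amplitude, per-window (e.g. day/night)
#' categorical module probabilities, a light schedule, and motifs planted at
#' given per-module rates. Defaults emulate a larval-zebrafish day/night
#' recording at 25 Hz with five active and five inactive modules whose
#' lengths and amplitudes are well separated, and day/night module
#' probabilities that favor short inactivity by day and long inactivity by
#' night.
#'
#' @param frame_rate frames per second (default 25).
#' @param schedule data frame with columns `label`, `start_frame`,
#'   `end_frame` (half-open, 0-based) describing one cycle of the light
#'   schedule; the cycle is recycled if generation runs past its end.
#' @param active_templates list of templates, each a list with `length_mean`,
#'   `length_sd` (frames, normal, rounded, clamped at 1), `amp_mean`,
#'   `amp_sd` (delta-pixel levels, normal, rounded) and `amp_min` (>= 1;
#'   active frames can never emit 0).
#' @param inactive_templates list of templates, each a list with
#'   `length_mean` (frames, geometric mean) and `length_spread` (SD on the
#'   log10 scale).
#' @param module_probs named list (one element per schedule label), each a
#'   list with numeric vectors `active` and `inactive` summing to 1.
#' @param planted_motifs list of planted motifs, each a list with `motif`
#'   (character vector of alternating module tokens) and `rate` (named
#'   numeric per window label: the probability that a kind-compatible module
#'   position in that window starts a planted occurrence; labels omitted get
#'   rate 0).
#' @param seed master integer seed; all randomness is derived from it.
#' @return an object of class `simulation_spec`.
#' @export
simulation_spec <- function(frame_rate = 25,
                            schedule = default_schedule(frame_rate),
                            active_templates = default_active_templates(),
                            inactive_templates = default_inactive_templates(),
                            module_probs = default_module_probs(),
                            planted_motifs = list(),
                            seed = 1L) {
  stopifnot(frame_rate > 0, is.data.frame(schedule),
            all(c("label", "start_frame", "end_frame") %in% names(schedule)))
  if (any(schedule$end_frame <= schedule$start_frame)) {
    stop("schedule windows must have end_frame > start_frame")
  }
  for (tpl in active_templates) {
    if (tpl$length_mean < 1) stop("active template length must be >= 1 frame")
    if ((tpl$amp_min %||% 1) < 1) {
      stop("active amplitude template can emit 0 inside an active run; ",
           "amp_min must be >= 1")
    }
    if (tpl$amp_mean < (tpl$amp_min %||% 1)) {
      stop("active template amplitude mean below its minimum")
    }
  }
  for (tpl in inactive_templates) {
    if (tpl$length_mean < 1) stop("inactive template length must be >= 1 frame")
  }
  labels <- unique(schedule$label)
  if (!all(labels %in% names(module_probs))) {
    stop("module_probs must name every schedule label")
  }
  for (lab in labels) {
    p <- module_probs[[lab]]
    if (length(p$active) != length(active_templates) ||
        length(p$inactive) != length(inactive_templates)) {
      stop("module_probs length mismatch with templates in window ", lab)
    }
    if (abs(sum(p$active) - 1) > 1e-8 || abs(sum(p$inactive) - 1) > 1e-8) {
      stop("module probabilities must sum to 1 in window ", lab)
    }
  }
  planted_motifs <- lapply(planted_motifs, function(m) {
    kinds <- token_kind(m$motif)
    if (length(m$motif) < 2) stop("planted motifs must have >= 2 modules")
    if (any(kinds[-1] == kinds[-length(kinds)])) {
      stop("planted motif must alternate active/inactive modules: ",
           paste(m$motif, collapse = " "))
    }
    ids <- abs(encode_tokens(m$motif))
    n_tpl <- ifelse(kinds == "active", length(active_templates),
                    length(inactive_templates))
    if (any(ids > n_tpl)) stop("planted motif uses an unknown module id")
    rate <- m$rate
    if (is.null(names(rate))) stop("motif rate must be named by window label")
    m$rate <- rate
    m
  })
  structure(list(frame_rate = frame_rate, schedule = schedule,
                 active_templates = active_templates,
                 inactive_templates = inactive_templates,
                 module_probs = module_probs,
                 planted_motifs = planted_motifs, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' @rdname simulation_spec
#' @param day_hours,night_hours default-schedule window durations in hours.
#' @export
default_schedule <- function(frame_rate = 25, day_hours = 7,
                             night_hours = 5) {
  # two developmental cycles, each 7 h "day" + 5 h "night" (the 14:10
  # light-cycle ratio, halved so a 20k-module animal spans about one full
  # two-day period; day/night segments then hold thousands / hundreds of
  # modules, as in multi-day recordings). Labels carry the cycle (dpf-style)
  # so module probabilities and motif rates may drift across development.
  day <- round(day_hours * 3600 * frame_rate)
  night <- round(night_hours * 3600 * frame_rate)
  cyc <- day + night
  data.frame(label = c("day5", "night5", "day6", "night6"),
             start_frame = c(0, day, cyc, cyc + day),
             end_frame = c(day, cyc, cyc + day, 2 * cyc))
}

#' @rdname simulation_spec
#' @export
default_active_templates <- function() {
  list(
    list(length_mean = 2,  length_sd = 0.5, amp_mean = 6,   amp_sd = 1, amp_min = 3),
    list(length_mean = 4,  length_sd = 1.0, amp_mean = 20,  amp_sd = 2, amp_min = 3),
    list(length_mean = 8,  length_sd = 1.5, amp_mean = 45,  amp_sd = 4, amp_min = 3),
    list(length_mean = 16, length_sd = 2.5, amp_mean = 90,  amp_sd = 6, amp_min = 3),
    list(length_mean = 32, length_sd = 4.0, amp_mean = 150, amp_sd = 8, amp_min = 3)
  )
}

#' @rdname simulation_spec
#' @export
default_inactive_templates <- function() {
  # geometric-mean lengths a factor 4 apart (5 SD on the log10 scale) and
  # long enough that integer frame quantization stays well below the spread
  list(
    list(length_mean = 6,    length_spread = 0.12),
    list(length_mean = 24,   length_spread = 0.12),
    list(length_mean = 96,   length_spread = 0.12),
    list(length_mean = 384,  length_spread = 0.12),
    list(length_mean = 1536, length_spread = 0.12)
  )
}

#' @rdname simulation_spec
#' @export
default_module_probs <- function() {
  day <- list(active = c(0.25, 0.25, 0.20, 0.20, 0.10),
              inactive = c(0.35, 0.30, 0.20, 0.10, 0.05))
  night <- list(active = c(0.10, 0.15, 0.20, 0.25, 0.30),
                inactive = c(0.05, 0.10, 0.20, 0.30, 0.35))
  list(day5 = day, night5 = night, day6 = day, night6 = night)
}

# window label for 0-based frames, recycling the schedule cycle
schedule_label <- function(schedule, frames) {
  period <- max(schedule$end_frame)
  f <- frames %% period
  idx <- findInterval(f, schedule$start_frame)
  schedule$label[idx]
}

# materialize the recycled schedule as instance windows covering n frames
schedule_instances <- function(schedule, n_frames) {
  if (n_frames <= 0) {
    return(data.frame(label = character(), start_frame = integer(),
                      end_frame = integer(), instance = integer()))
  }
  period <- max(schedule$end_frame)
  n_cycles <- ceiling(n_frames / period)
  out <- do.call(rbind, lapply(seq_len(n_cycles) - 1L, function(cy) {
    data.frame(label = schedule$label,
               start_frame = schedule$start_frame + cy * period,
               end_frame = schedule$end_frame + cy * period)
  }))
  out <- out[out$start_frame < n_frames, , drop = FALSE]
  out$end_frame <- pmin(out$end_frame, n_frames)
  out$instance <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

sample_active_length <- function(tpl, n) {
  pmax(1L, as.integer(round(rnorm(n, tpl$length_mean, tpl$length_sd))))
}

sample_inactive_length <- function(tpl, n) {
  pmax(1L, as.integer(round(10^rnorm(n, log10(tpl$length_mean),
                                     tpl$length_spread))))
}

#' Generate a ground-truthed module sequence
#'
#' Draws a strictly alternating active/inactive module sequence under a
#' [simulation_spec()]: the module identity is sampled from the categorical
#' probabilities of the window containing the module's start frame, and its
#' length in frames from that module's template. Planted motifs are spliced
#' in during generation: at every kind-compatible position, a motif whose
#' window rate is positive starts with that probability (so insertions are
#' non-overlapping, uniform over compatible positions, and consistent with
#' the frame anchors); ground truth is recorded.
#'
#' @param spec a [simulation_spec()].
#' @param n_modules number of modules to generate (>= 2).
#' @param animal_id identifier used to derive the per-animal seed.
#' @param seed optional override of the spec's master seed.
#' @return a `module_sequence` data frame with columns `token`, `kind`,
#'   `module`, `start_frame`, `length_frames`, `window`, `excluded`, and
#'   attributes `frame_rate`, `animal_id` and `motif_truth` (a data frame of
#'   planted occurrences: motif, start index, window).
#' @export
generate_module_sequence <- function(spec, n_modules, animal_id = "a1",
                                     seed = NULL) {
  stopifnot(inherits(spec, "simulation_spec"), n_modules >= 2)
  seed <- seed %||% spec$seed
  set.seed(derive_seed(seed, paste0("seq:", animal_id)))

  n_act <- length(spec$active_templates)
  n_ina <- length(spec$inactive_templates)
  kind <- rep_len(c("active", "inactive"), n_modules)
  module <- integer(n_modules)
  len <- integer(n_modules)
  window <- character(n_modules)
  truth <- list()

  motif_codes <- lapply(spec$planted_motifs, function(m) encode_tokens(m$motif))
  motif_kind1 <- vapply(spec$planted_motifs,
                        function(m) token_kind(m$motif[1]), character(1))

  sample_one <- function(i, lab) {
    p <- spec$module_probs[[lab]]
    if (kind[i] == "active") {
      mid <- sample.int(n_act, 1L, prob = p$active)
      c(mid, sample_active_length(spec$active_templates[[mid]], 1L))
    } else {
      mid <- sample.int(n_ina, 1L, prob = p$inactive)
      c(mid, sample_inactive_length(spec$inactive_templates[[mid]], 1L))
    }
  }

  cur <- 0
  i <- 1L
  while (i <= n_modules) {
    lab <- schedule_label(spec$schedule, cur)
    window[i] <- lab
    planted <- FALSE
    for (mi in seq_along(spec$planted_motifs)) {
      m <- spec$planted_motifs[[mi]]
      L <- length(motif_codes[[mi]])
      rate <- m$rate[lab]
      if (is.na(rate) || rate <= 0) next
      if (motif_kind1[mi] != kind[i] || i + L - 1L > n_modules) next
      if (runif(1) >= rate) next
      # splice the motif, sampling each module's length from its template
      for (j in seq_len(L)) {
        k <- i + j - 1L
        module[k] <- abs(motif_codes[[mi]][j])
        window[k] <- schedule_label(spec$schedule, cur)
        len[k] <- if (kind[k] == "active") {
          sample_active_length(spec$active_templates[[module[k]]], 1L)
        } else {
          sample_inactive_length(spec$inactive_templates[[module[k]]], 1L)
        }
        cur <- cur + len[k]
      }
      truth[[length(truth) + 1L]] <-
        data.frame(motif = paste(m$motif, collapse = " "),
                   motif_index = mi, start = i, window = lab)
      i <- i + L
      planted <- TRUE
      break
    }
    if (planted) next
    s <- sample_one(i, lab)
    module[i] <- s[1]
    len[i] <- s[2]
    cur <- cur + s[2]
    i <- i + 1L
  }
  start <- c(0L, cumsum(len)[-n_modules])

  token <- ifelse(kind == "active", paste0("A", module), paste0("I", module))
  out <- data.frame(token = token, kind = kind, module = module,
                    start_frame = start, length_frames = len,
                    window = window, excluded = FALSE,
                    stringsAsFactors = FALSE)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(motif = character(), motif_index = integer(),
               start = integer(), window = character())
  structure(out, frame_rate = spec$frame_rate, animal_id = animal_id,
            motif_truth = truth, class = c("module_sequence", "data.frame"))
}

#' Render a module sequence as a delta-pixel trace
#'
#' Inverse of bout segmentation: active modules become runs of positive
#' integer delta-pixel values drawn from their amplitude template, inactive
#' modules become runs of zeros.
#'
#' @param ms a `module_sequence` (from [generate_module_sequence()]).
#' @param spec the [simulation_spec()] that produced it.
#' @param seed optional override of the spec's master seed.
#' @return an [activity_recording()].
#' @export
render_deltapixels <- function(ms, spec, seed = NULL) {
  stopifnot(inherits(ms, "module_sequence"), inherits(spec, "simulation_spec"))
  animal_id <- attr(ms, "animal_id") %||% "a1"
  seed <- seed %||% spec$seed
  set.seed(derive_seed(seed, paste0("render:", animal_id)))

  total <- sum(ms$length_frames)
  values <- integer(total)
  act <- which(ms$kind == "active")
  if (length(act)) {
    lens <- ms$length_frames[act]
    mods <- ms$module[act]
    tpl_mean <- vapply(spec$active_templates, `[[`, numeric(1), "amp_mean")
    tpl_sd <- vapply(spec$active_templates, `[[`, numeric(1), "amp_sd")
    tpl_min <- vapply(spec$active_templates,
                      function(t) t$amp_min %||% 1, numeric(1))
    frame_mod <- rep(mods, lens)
    amps <- round(rnorm(length(frame_mod), tpl_mean[frame_mod],
                        tpl_sd[frame_mod]))
    amps <- pmax(amps, tpl_min[frame_mod])
    pos <- sequence(lens) - 1L + rep(ms$start_frame[act], lens)
    values[pos + 1L] <- as.integer(amps)
  }
  activity_recording(values, frame_rate = spec$frame_rate,
                     animal_id = animal_id,
                     schedule = schedule_instances(spec$schedule, total))
}

#' Generate a multi-animal synthetic dataset
#'
#' Runs [generate_module_sequence()] and [render_deltapixels()] for several
#' animals under one master seed. Per-animal, per-motif insertion rates are
#' scaled by independent log-normal multipliers (SD `rate_heterogeneity` on
#' the log scale) to emulate individual variability.
#'
#' @param spec a [simulation_spec()].
#' @param n_animals number of animals.
#' @param n_modules modules per animal.
#' @param rate_heterogeneity sdlog of the per-animal motif-rate multiplier
#'   (0 disables it).
#' @param seed master seed (defaults to the spec's).
#' @return list with `recordings`, `sequences` (both per-animal lists),
#'   `truth` (combined planted-motif table with an `animal_id` column) and
#'   the `spec`.
#' @export
synthesize_dataset <- function(spec, n_animals = 8, n_modules = 20000,
                               rate_heterogeneity = 0.3, seed = NULL) {
  seed <- seed %||% spec$seed
  ids <- sprintf("fish%02d", seq_len(n_animals))
  sequences <- vector("list", n_animals)
  recordings <- vector("list", n_animals)
  names(sequences) <- names(recordings) <- ids
  truth <- list()
  for (a in seq_len(n_animals)) {
    sp <- spec
    if (length(sp$planted_motifs) && rate_heterogeneity > 0) {
      for (mi in seq_along(sp$planted_motifs)) {
        set.seed(derive_seed(seed, paste0("het:", ids[a], ":", mi)))
        mult <- rlnorm(1, 0, rate_heterogeneity)
        sp$planted_motifs[[mi]]$rate <- sp$planted_motifs[[mi]]$rate * mult
      }
    }
    ms <- generate_module_sequence(sp, n_modules, animal_id = ids[a],
                                   seed = seed)
    sequences[[a]] <- ms
    recordings[[a]] <- render_deltapixels(ms, sp, seed = seed)
    tr <- attr(ms, "motif_truth")
    if (nrow(tr)) {
      tr$animal_id <- ids[a]
      truth[[length(truth) + 1L]] <- tr
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(motif = character(), motif_index = integer(),
               start = integer(), window = character(),
               animal_id = character())
  list(recordings = recordings, sequences = sequences, truth = truth,
       spec = spec)
}

#' Write a synthetic dataset to CSV files
#'
#' Emits the same frames-by-animals layout the ingestion functions read:
#' `deltapixels.csv` (header = animal ids; traces truncated to the shortest
#' animal so columns align), `metadata.csv` (animal_id, group) and
#' `schedule.csv` (label, start_frame, end_frame).
#'
#' @param ds result of [synthesize_dataset()].
#' @param dir output directory (created if needed).
#' @param group group label written for every animal.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir, group = "wt") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- min(vapply(ds$recordings, function(r) length(r$values), numeric(1)))
  mat <- vapply(ds$recordings, function(r) r$values[seq_len(n)],
                integer(n))
  utils::write.csv(as.data.frame(mat),
                   file.path(dir, "deltapixels.csv"), row.names = FALSE)
  meta <- data.frame(animal_id = names(ds$recordings), group = group)
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  sched <- schedule_instances(ds$spec$schedule, n)
  utils::write.csv(sched[, c("label", "start_frame", "end_frame")],
                   file.path(dir, "schedule.csv"), row.names = FALSE)
  invisible(dir)
}
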