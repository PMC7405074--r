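# Pipeline orchestration: config file, staged artifacts, provenance hash,
# structured logging, and a process-level parallel map over animals.

ALL_STAGES <- c("simulate", "segment", "cluster", "compress", "enrich",
                "classify")

# polynomial rolling hash of the config for artifact provenance headers
config_hash <- function(config) {
  h <- 104729
  for (b in utf8ToInt(paste(deparse(config), collapse = ""))) {
    h <- (h * 131 + b) %% 2147483647 # exact in doubles
  }
  sprintf("%08x", as.integer(h))
}

#' Default pipeline configuration
#'
#' Parameter defaults follow the method's reference values: 25 Hz frames,
#' 200 delta-pixel ceiling, 40000 probes / 200 mixture models / 2-20
#' components / 40000-100000 training samples / 50 nearest neighbors for
#' clustering (all capped at the available data), 10-module motif cap and
#' 500-module blocks for compression, 10 shuffles with overlapping counting
#' for enrichment, and top-250 mRMR / 10 folds / 3-wide smoothing / 10
#' random-subset repeats for classification.
#'
#' @param out_dir artifact directory.
#' @param seed master seed (mandatory for every stochastic stage).
#' @return nested config list; any entry can be overridden before
#'   [run_pipeline()], or supplied via a YAML file with the same keys.
#' @export
default_config <- function(out_dir = "ethomotif_out", seed = 1L) {
  list(
    seed = as.integer(seed),
    paths = list(out = out_dir),
    frame_rate = 25,
    ceiling = 200,
    simulate = list(n_animals = 8, n_modules = 20000,
                    rate_heterogeneity = 0.3, day_hours = 7,
                    night_hours = 5),
    cluster = list(n_probe = 40000, n_models = 200, k_range = c(2, 20),
                   sample_range = c(40000, 100000), n_restarts = 5,
                   reg = 1e-6, k_nn = 50, n_components = "auto",
                   log_inactive = TRUE),
    compress = list(max_len = 10, block = 500),
    enrich = list(n_shuffles = 10, overlap = TRUE),
    classify = list(top = 250, folds = 10, smooth_width = 3, repeats = 10,
                    label_by = "window_base", group_by_animal = TRUE),
    n_cores = 1
  )
}

#' Read a pipeline config from YAML
#'
#' @param path YAML file with keys matching [default_config()]; missing keys
#'   take the defaults.
#' @return config list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  merge_lists <- function(base, over) {
    for (k in names(over)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]])) {
        merge_lists(base[[k]], over[[k]])
      } else over[[k]]
    }
    base
  }
  cfg <- merge_lists(cfg, user)
  if (is.null(cfg$seed)) stop("config must set a seed")
  cfg
}

log_stage <- function(...) {
  message(format(Sys.time(), "%H:%M:%S"), " [ethomotif] ", ...)
}

write_artifact <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
}

read_artifact <- function(path, stage) {
  if (!file.exists(path)) {
    stop("stage '", stage, "' needs missing artifact ", path,
         "; run the preceding stage first")
  }
  utils::read.csv(path, comment.char = "#", check.names = FALSE)
}

# deterministic process-level parallel map over animals: results identical
# to serial execution because every task derives its own seed
animal_map <- function(ids, fn, n_cores = 1) {
  if (n_cores > 1) {
    parallel::mclapply(ids, fn, mc.cores = n_cores)
  } else {
    lapply(ids, fn)
  }
}

sequences_from_module_table <- function(tab, frame_rate) {
  lapply(split(tab, tab$animal_id), function(d) {
    d <- d[order(d$start_frame), ]
    out <- data.frame(token = d$token, kind = d$kind, module = d$module,
                      start_frame = d$start_frame,
                      length_frames = d$length_frames, window = d$window,
                      excluded = as.logical(d$excluded),
                      stringsAsFactors = FALSE)
    structure(out, frame_rate = frame_rate, animal_id = d$animal_id[1],
              class = c("module_sequence", "data.frame"))
  })
}

#' Run the analysis pipeline
#'
#' Orchestrates the stages simulate -> segment -> cluster -> compress ->
#' enrich -> classify over on-disk CSV artifacts. Each stage reads its
#' predecessor's artifact files, so a run can be resumed or re-run from any
#' stage; every artifact carries a `# config_hash:` provenance line and a
#' manifest records the config hash, seed, and per-stage row counts.
#'
#' @param config config list (see [default_config()] / [read_config()]).
#' @param stages subset of stages to run, in pipeline order.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, stages = ALL_STAGES) {
  stages <- match.arg(stages, ALL_STAGES, several.ok = TRUE)
  out <- config$paths$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  seed <- config$seed
  manifest <- list(config_hash = hash, seed = seed,
                   package_version = as.character(utils::packageVersion("ethomotif")),
                   stages = list())
  t_all <- Sys.time()

  if ("simulate" %in% stages) {
    log_stage("simulate")
    spec <- simulation_spec(
      frame_rate = config$frame_rate, seed = seed,
      schedule = default_schedule(config$frame_rate,
                                  day_hours = config$simulate$day_hours,
                                  night_hours = config$simulate$night_hours),
      planted_motifs = default_planted_motifs())
    ds <- synthesize_dataset(spec, n_animals = config$simulate$n_animals,
                             n_modules = config$simulate$n_modules,
                             rate_heterogeneity =
                               config$simulate$rate_heterogeneity,
                             seed = seed)
    write_dataset(ds, out)
    manifest$stages$simulate <- list(animals = config$simulate$n_animals)
  }

  if ("segment" %in% stages) {
    log_stage("segment")
    dp_path <- file.path(out, "deltapixels.csv")
    if (!file.exists(dp_path)) {
      stop("stage 'segment' needs missing artifact ", dp_path)
    }
    sched <- NULL
    sp <- file.path(out, "schedule.csv")
    if (file.exists(sp)) sched <- utils::read.csv(sp)
    recs <- read_activity_csv(dp_path, frame_rate = config$frame_rate,
                              schedule = sched)
    bouts <- animal_map(recs, function(r) {
      r <- apply_artifact_ceiling(r, config$ceiling)
      r <- apply_masks(r)
      segment_bouts(r)
    }, config$n_cores)
    bouts <- bind_bouts(bouts)
    write_artifact(as.data.frame(bouts), file.path(out, "bouts.csv"), hash)
    manifest$stages$segment <- list(bouts = nrow(bouts))
  }

  if ("cluster" %in% stages) {
    log_stage("cluster")
    tab <- read_artifact(file.path(out, "bouts.csv"), "cluster")
    bouts <- structure(tab, frame_rate = config$frame_rate,
                       class = c("bout_table", "data.frame"))
    cl <- config$cluster
    asn <- cluster_bouts(bouts, n_probe = cl$n_probe,
                         n_models = cl$n_models, k_range = cl$k_range,
                         sample_range = cl$sample_range,
                         n_restarts = cl$n_restarts, reg = cl$reg,
                         k_nn = cl$k_nn, n_components = cl$n_components,
                         log_inactive = cl$log_inactive,
                         seed = derive_seed(config$seed, "cluster"))
    module <- integer(nrow(bouts))
    module[bouts$kind == "active"] <- asn$active
    module[bouts$kind == "inactive"] <- asn$inactive
    tab$module <- module
    tab$token <- ifelse(bouts$kind == "active", paste0("A", module),
                        paste0("I", module))
    write_artifact(tab, file.path(out, "modules.csv"), hash)
    summ <- rbind(cbind(kind = "active", asn$summary_active),
                  cbind(kind = "inactive", asn$summary_inactive))
    write_artifact(summ, file.path(out, "module_summary.csv"), hash)
    manifest$stages$cluster <- list(k_active = asn$k_active,
                                    k_inactive = asn$k_inactive)
  }

  if ("compress" %in% stages) {
    log_stage("compress")
    tab <- read_artifact(file.path(out, "modules.csv"), "compress")
    seqs <- sequences_from_module_table(tab, config$frame_rate)
    grams <- animal_map(seqs, function(s)
      compress_sequence(s, config$compress$max_len), config$n_cores)
    lib <- build_library(grams)
    write_library(lib, file.path(out, "library.txt"))
    gr <- do.call(rbind, lapply(names(seqs), function(a) {
      g <- grams[[match(a, names(seqs))]]
      if (!nrow(g$rules)) return(NULL)
      data.frame(animal_id = a, rule = g$rules$symbol,
                 definition = vapply(seq_len(nrow(g$rules)), function(r)
                   paste(decode_tokens(expand_symbol(g$rules$symbol[r], g)),
                         collapse = " "), character(1)),
                 savings = g$rules$savings, occurrences = g$rules$count,
                 compressibility = g$compressibility)
    }))
    write_artifact(gr, file.path(out, "grammar.csv"), hash)
    blocks <- do.call(rbind, lapply(names(seqs), function(a) {
      b <- block_compressibility(seqs[[a]], config$compress$block,
                                 config$compress$max_len)
      if (nrow(b)) cbind(animal_id = a, b) else NULL
    }))
    if (is.null(blocks)) {
      blocks <- data.frame(animal_id = character(), block = integer(),
                           start_module = integer(),
                           compressibility = numeric(), window = character())
    }
    write_artifact(blocks, file.path(out, "blocks.csv"), hash)
    manifest$stages$compress <- list(motifs = length(lib$motifs))
  }

  if ("enrich" %in% stages) {
    log_stage("enrich")
    tab <- read_artifact(file.path(out, "modules.csv"), "enrich")
    lib_path <- file.path(out, "library.txt")
    if (!file.exists(lib_path)) {
      stop("stage 'enrich' needs missing artifact ", lib_path)
    }
    lib <- read_library(lib_path)
    seqs <- sequences_from_module_table(tab, config$frame_rate)
    em <- enrichment_matrix(seqs, lib,
                            n_shuffles = config$enrich$n_shuffles,
                            overlap = config$enrich$overlap,
                            seed = derive_seed(config$seed, "enrich"))
    out_df <- cbind(em$samples, as.data.frame(em$scores,
                                              check.names = FALSE))
    write_artifact(out_df, file.path(out, "enrichment.csv"), hash)
    manifest$stages$enrich <- list(samples = nrow(em$scores),
                                   motifs = ncol(em$scores),
                                   inf_fraction = em$inf_fraction)
  }

  if ("classify" %in% stages) {
    log_stage("classify")
    tab <- read_artifact(file.path(out, "enrichment.csv"), "classify")
    meta_cols <- c("animal_id", "window", "instance")
    scores <- as.matrix(tab[, setdiff(names(tab), meta_cols), drop = FALSE])
    em <- structure(list(scores = scores, samples = tab[, meta_cols],
                         motifs = colnames(scores), inf_fraction = NA,
                         normalized = FALSE), class = "enrichment_matrix")
    em <- normalize_columns(em)
    cc <- config$classify
    labels <- if (identical(cc$label_by, "window_base")) {
      sub("[0-9]+$", "", tab$window) # collapse developmental cycles
    } else {
      tab[[cc$label_by]]
    }
    groups <- if (isTRUE(cc$group_by_animal)) tab$animal_id else NULL
    rep_ <- classify_contrast(em, labels, top = cc$top, folds = cc$folds,
                              smooth_width = cc$smooth_width,
                              repeats = cc$repeats,
                              seed = derive_seed(config$seed, "classify"),
                              groups = groups)
    df <- data.frame(comparison = paste(sort(unique(labels)), collapse = "/"),
                     motifs = rep_$count, cv_error = rep_$cv_error,
                     cv_sd = rep_$cv_sd, mc_error = rep_$mc_error,
                     mc_ep = rep_$mc_se, rm_error = rep_$rm_error,
                     rm_sd = rep_$rm_sd, best_motif = rep_$best_motif)
    write_artifact(df, file.path(out, "report.csv"), hash)
    manifest$stages$classify <- list(cv_error = rep_$cv_error,
                                     motifs = rep_$count)
  }

  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t_all, units = "secs"))
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  log_stage("done in ", round(manifest$elapsed_s, 1), " s")
  invisible(manifest)
}

#' Default planted motifs for simulated runs
#'
#' Two day-enriched four-module motifs, `A2 I1 A2 I1` and `A3 I2 A3 I2`,
#' planted at kind-compatible positions of day windows and absent at night.
#' Even-length, active-initial motifs respect the natural pairing unit of an
#' alternating sequence, so hierarchical compression can recover them as
#' exact rules; building them from mid-frequency day modules gives their
#' paired shuffles a realistic, non-degenerate count spread.
#'
#' @return list suitable for `simulation_spec(planted_motifs = ...)`.
#' @export
default_planted_motifs <- function() {
  list(
    list(motif = c("A2", "I1", "A2", "I1"),
         rate = c(day5 = 0.015, day6 = 0.015, night5 = 0, night6 = 0)),
    list(motif = c("A3", "I2", "A3", "I2"),
         rate = c(day5 = 0.015, day6 = 0.015, night5 = 0, night6 = 0))
  )
}
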