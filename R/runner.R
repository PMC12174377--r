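# Configuration, orchestration and small analytic utilities.

#' Default study configuration
#'
#' Holds every fixed constant of the emulated protocol: sampling rates,
#' filter settings, the wavelet grid (4-90 Hz, 1 Hz steps, 3-13 cycles),
#' ROI electrode lists, frequency bands, movement periods, trial-rejection
#' thresholds, the 20 Hz stimulation frequency, statistics options and the
#' cluster-test settings (pixel alpha 0.05, 97.5th-percentile decision).
#'
#' @return Named list; see [generate_study()] and [run_pipeline()] for the
#'   fields each stage consumes.
#' @export
default_config <- function() {
  list(
    n_subjects = 20,
    intensities = c("sham", "0.5", "1.0", "1.5"),
    time_points = c("pre", "post1", "post2"),
    fs = 1000,
    force_fs = 5000,
    duration_rest_s = 180,
    n_trials = 60,
    iti_s = 10,
    channels = roi_montage(),
    force_threshold_n = 0.5,
    filter = list(band = c(0.5, 95), notch_hz = 50, fs_out = 500),
    wavelet = list(fmin = 4, fmax = 90, step = 1, c_min = 3, c_max = 13),
    rejection = list(ptp_threshold = 200, min_trials = 20,
                     exclude_below = 11),
    stim_hz = 20,
    stats = list(backend = "glmmTMB",
                 families = c("time_within_intensity",
                              "intensity_change_scores")),
    cluster = list(alpha = 0.05, n_permutations = 1000),
    effects = list(),
    seed = 1,
    out_dir = NULL,
    results_dir = NULL
  )
}

#' Read / write a study configuration as YAML
#'
#' Configurations round-trip exactly: `save_config()` then `load_config()`
#' returns an equivalent list (user fields merged over [default_config()]).
#'
#' @param path YAML file path.
#' @return `load_config()`: the merged configuration list.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), user)
  if (is.null(cfg$seed)) stop("config must set a seed")
  cfg
}

#' @rdname load_config
#' @param config Configuration list.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# plain-list effect representation (YAML-friendly) -> effect_spec
as_effect_spec <- function(x, intensity) {
  if (inherits(x, "effect_spec")) return(x)
  if (is.null(x)) return(effect_spec(intensity))
  rules <- lapply(x$rules %||% list(), function(r) {
    effect_rule(r$multiplier, r$time_point %||% NA, r$band %||% NA,
                r$region %||% NA, r$context %||% NA)
  })
  shift <- unlist(x$peak_shift_hz %||% list())
  effect_spec(intensity, rules, if (is.null(shift)) numeric() else shift)
}

#' Stimulation electrode current density
#'
#' Current density per electrode of an HD montage disc electrode:
#' `current / n_electrodes / area`, with the nominal disc area rounded to
#' two decimals (a 2 cm disc is treated as 3.14 cm^2) and the result
#' reported to three decimals.
#'
#' @param current_ma Total current in mA (> 0).
#' @param diameter_cm Electrode diameter in cm (default 2).
#' @param n_electrodes Number of electrodes sharing the current (1 for the
#'   centre electrode, 4 for the return ring).
#' @return Current density in mA/cm^2, rounded to 3 decimals.
#' @export
current_density <- function(current_ma, diameter_cm = 2, n_electrodes = 1) {
  if (any(c(current_ma, diameter_cm, n_electrodes) <= 0))
    stop("all arguments must be > 0")
  area <- round(pi * (diameter_cm / 2)^2, 2)
  round(current_ma / n_electrodes / area, 3)
}

.block_pairs <- list(pre_post1 = c("pre", "post1"),
                     pre_post2 = c("pre", "post2"),
                     post1_post2 = c("post1", "post2"))

.subset_trials <- function(power, kept) {
  power$values <- power$values[kept, , , , drop = FALSE]
  power
}

# preprocess + decompose one dataset directory; returns trial tables,
# peak-beta rows and trial-averaged ratio maps
.process_dataset <- function(dir, cfg, bank_rest, bank_event, key) {
  ps <- period_spec()
  out <- list(status = list())
  # resting
  raw <- read_edf(file.path(dir, "rest.edf"))
  raw <- condition_raw(raw, cfg$filter$fs_out, cfg$filter$band,
                       cfg$filter$notch_hz)
  ep <- make_epochs(raw, "resting")
  ep <- reject_epochs(ep, cfg$rejection$ptp_threshold,
                      cfg$rejection$min_trials, cfg$rejection$exclude_below)
  out$status$rest <- ep$status
  if (ep$status != "excluded") {
    pw <- wavelet_power(ep, bank_rest, ps$resting_grid)
    pw <- .subset_trials(roi_average(pw), ep$kept)
    out$rest_table <- aggregate_power(to_db(pw), pw, periods = "resting")
  }
  # event-related
  raw <- read_edf(file.path(dir, "task.edf"))
  force_df <- utils::read.csv(file.path(dir, "task_force.csv"))
  force <- structure(list(samples = force_df$newtons, fs = cfg$force_fs),
                     class = "force_trace")
  raw <- condition_raw(raw, cfg$filter$fs_out, cfg$filter$band,
                       cfg$filter$notch_hz)
  onsets <- detect_movement_onsets(force, cfg$force_threshold_n,
                                   eeg_fs = cfg$filter$fs_out)
  ep <- make_epochs(raw, "event", onsets)
  ep <- reject_epochs(ep, cfg$rejection$ptp_threshold,
                      cfg$rejection$min_trials, cfg$rejection$exclude_below)
  out$status$task <- ep$status
  if (ep$status != "excluded") {
    grid <- sort(unique(c(seq(ps$baseline[1], ps$baseline[2], by = 20),
                          ps$event_grid)))
    pw <- roi_average(wavelet_power(ep, bank_event, grid))
    dbb <- .subset_trials(baseline_db(pw, ps$baseline), ep$kept)
    ratio <- .subset_trials(baseline_ratio(pw, ps$baseline), ep$kept)
    periods <- ps[c("pre_movement", "movement", "post_movement")]
    out$task_table <- aggregate_power(dbb, ratio, periods = periods)
    out$peak_beta <- peak_beta_table(dbb, ps, cfg$stim_hz)
    out$maps <- list()
    for (region in c("C3", "C4")) {
      for (p in names(periods)) {
        out$maps[[paste(region, p, sep = "/")]] <-
          trial_average_map(ratio, region, periods[[p]])
      }
    }
  }
  out
}

#' Run the full study analysis pipeline
#'
#' Chains the stages: optional synthetic-study generation, preprocessing
#' (filter/downsample, onset detection, epoching, rejection),
#' time-frequency power with ROI/band/period aggregation, peak-beta
#' features and percent-change maps, mixed-model contrasts, and the
#' factorial cluster-correlation battery. Results (CSV/JSON) and a
#' manifest with seeds and file hashes are written to
#' `config$results_dir`.
#'
#' @param config Configuration list (see [default_config()]), or a path to
#'   a YAML file.
#' @param stages Character subset of
#'   `c("simulate", "preprocess", "stats", "clusters")`; later stages
#'   require the earlier ones in the same call.
#' @return Invisibly, a list with `trial_power`, `peak_beta`, `fits`,
#'   `contrasts`, `clusters`, `status` and the manifest path.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "preprocess", "stats",
                                    "clusters")) {
  if (is.character(config)) config <- load_config(config)
  cfg <- utils::modifyList(default_config(), config)
  if (is.null(cfg$out_dir)) stop("config$out_dir is required")
  if (is.null(cfg$results_dir)) cfg$results_dir <- file.path(cfg$out_dir,
                                                             "results")
  dir.create(cfg$results_dir, recursive = TRUE, showWarnings = FALSE)
  cfg$effects <- stats::setNames(
    lapply(cfg$intensities, function(i) as_effect_spec(cfg$effects[[i]], i)),
    cfg$intensities)
  if ("simulate" %in% stages) generate_study(cfg, cfg$seed)

  res <- list(status = list())
  if (!"preprocess" %in% stages) return(invisible(res))
  wl <- cfg$wavelet
  bank <- build_wavelet_bank(wl$fmin, wl$fmax, wl$step, wl$c_min, wl$c_max,
                             cfg$filter$fs_out)
  subjects <- sprintf("sub%02d", seq_len(cfg$n_subjects))
  rest_tables <- list(); task_tables <- list(); peak_rows <- list()
  maps_store <- list()
  for (s in subjects) {
    for (intensity in cfg$intensities) {
      for (tp in cfg$time_points) {
        key <- paste(s, intensity, tp, sep = "/")
        d <- file.path(cfg$out_dir, s, intensity, tp)
        pr <- withCallingHandlers(
          .process_dataset(d, cfg, bank, bank, key),
          warning = function(w) {
            tb_log(key, ": ", conditionMessage(w))
            invokeRestart("muffleWarning")
          })
        res$status[[key]] <- pr$status
        ids <- function(t) cbind(data.frame(subject = s,
                                            intensity = intensity,
                                            time_point = tp,
                                            stringsAsFactors = FALSE), t)
        if (!is.null(pr$rest_table)) {
          rest_tables[[key]] <- ids(pr$rest_table)
        }
        if (!is.null(pr$task_table)) {
          task_tables[[key]] <- ids(pr$task_table)
          peak_rows[[key]] <- ids(pr$peak_beta)
          maps_store[[key]] <- pr$maps
        }
      }
    }
  }
  res$trial_power <- list(resting = do.call(rbind, rest_tables),
                          event = do.call(rbind, task_tables))
  res$peak_beta <- do.call(rbind, peak_rows)
  rownames(res$peak_beta) <- NULL
  utils::write.csv(res$trial_power$resting,
                   file.path(cfg$results_dir, "trial_power_resting.csv"),
                   row.names = FALSE)
  utils::write.csv(res$trial_power$event,
                   file.path(cfg$results_dir, "trial_power_event.csv"),
                   row.names = FALSE)
  utils::write.csv(res$peak_beta,
                   file.path(cfg$results_dir, "peak_beta.csv"),
                   row.names = FALSE)

  if ("stats" %in% stages) {
    res$fits <- list(); res$contrasts <- list()
    if (!is.null(res$trial_power$resting)) {
      tab <- build_long_table(list(res$trial_power$resting),
                              check_cells = FALSE)
      res$fits$resting <- fit_power_model(tab,
                                          backend = cfg$stats$backend)
    }
    if (!is.null(res$trial_power$event)) {
      tab <- build_long_table(list(res$trial_power$event),
                              check_cells = FALSE)
      for (p in unique(tab$period)) {
        res$fits[[p]] <- fit_power_model(tab[tab$period == p, ],
                                         backend = cfg$stats$backend)
      }
    }
    for (nm in names(res$fits)) {
      for (fam in cfg$stats$families) {
        res$contrasts[[paste(nm, fam, sep = "/")]] <-
          cbind(model = nm, marginal_contrasts(res$fits[[nm]], fam))
      }
    }
    ct <- do.call(rbind, res$contrasts)
    if (!is.null(ct)) {
      rownames(ct) <- NULL
      utils::write.csv(ct, file.path(cfg$results_dir, "contrasts.csv"),
                       row.names = FALSE)
    }
    tt <- do.call(rbind, lapply(names(res$fits), function(nm) {
      cbind(model = nm, res$fits[[nm]]$term_tests)
    }))
    utils::write.csv(tt, file.path(cfg$results_dir, "term_tests.csv"),
                     row.names = FALSE)
  }

  if ("clusters" %in% stages && !is.null(res$peak_beta)) {
    inputs <- .cluster_inputs(res, maps_store, cfg)
    res$clusters <- run_cluster_analysis(inputs$scalars, inputs$maps,
                                         cfg$cluster$alpha,
                                         cfg$cluster$n_permutations,
                                         seed = cfg$seed)
    if (!is.null(res$clusters$summary)) {
      utils::write.csv(res$clusters$summary,
                       file.path(cfg$results_dir, "cluster_summary.csv"),
                       row.names = FALSE)
    }
  }

  files <- list.files(cfg$results_dir, pattern = "\\.csv$",
                      full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("tacsbeta")),
    seed = cfg$seed,
    status = res$status,
    hashes = as.list(tools::md5sum(files))
  )
  names(manifest$hashes) <- basename(files)
  manifest_path <- file.path(cfg$results_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  res$manifest <- manifest_path
  invisible(res)
}

# assemble cluster-test inputs: pre-stimulation endo-exo scalars and
# percent-change map stacks keyed period/region/intensity/block-pair
.cluster_inputs <- function(res, maps_store, cfg) {
  pb <- res$peak_beta
  pre <- pb[pb$time_point == "pre", ]
  agg <- stats::aggregate(endo_exo_diff_hz ~ subject + intensity + region +
                            period, data = pre, FUN = mean)
  scalars <- data.frame(subject = agg$subject, period = agg$period,
                        region = agg$region, intensity = agg$intensity,
                        value = agg$endo_exo_diff_hz,
                        stringsAsFactors = FALSE)
  maps <- list()
  periods <- c("pre_movement", "movement", "post_movement")
  subjects <- unique(pb$subject)
  for (p in periods) {
    for (region in c("C3", "C4")) {
      for (intensity in cfg$intensities) {
        for (bp in names(.block_pairs)) {
          tps <- .block_pairs[[bp]]
          mats <- list()
          for (s in subjects) {
            ka <- paste(s, intensity, tps[1], sep = "/")
            kb <- paste(s, intensity, tps[2], sep = "/")
            mk <- paste(region, p, sep = "/")
            if (is.null(maps_store[[ka]][[mk]]) ||
                is.null(maps_store[[kb]][[mk]])) next
            mats[[s]] <- delta_power(maps_store[[ka]][[mk]],
                                     maps_store[[kb]][[mk]])
          }
          if (length(mats) < 5) next
          arr <- array(0, c(length(mats), dim(mats[[1]])),
                       dimnames = list(names(mats), NULL, NULL))
          for (i in seq_along(mats)) arr[i, , ] <- mats[[i]]
          maps[[p]][[region]][[intensity]][[bp]] <- arr
        }
      }
    }
  }
  list(scalars = scalars, maps = maps)
}
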