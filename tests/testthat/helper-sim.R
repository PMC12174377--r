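# Shared simulation helpers and lazily-built fixtures.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# One movement-block dataset pushed through the preprocessing + wavelet
# stages: subject with peak beta 17 Hz and a 0.5 amplitude ERD, 12 trials.
movement_fixture <- function() {
  fixture("movement", function() {
    p <- make_subject_profile(1, overrides = list(peak_beta_hz = 17,
                                                  erd_depth = 0.5,
                                                  ers_gain = 0.3))
    set.seed(3)
    mv <- simulate_movement_block(p, n_trials = 12)
    rc <- condition_raw(mv$raw)
    onsets <- detect_movement_onsets(mv$force)
    ep <- suppressWarnings(reject_epochs(make_epochs(rc, "event", onsets)))
    bank <- build_wavelet_bank()
    ps <- period_spec()
    grid <- sort(unique(c(seq(ps$baseline[1], ps$baseline[2], 20),
                          ps$event_grid)))
    pw <- roi_average(wavelet_power(ep, bank, grid))
    list(profile = p, block = mv, conditioned = rc, onsets = onsets,
         epochs = ep, power = pw, db = baseline_db(pw),
         ratio = baseline_ratio(pw))
  })
}

# Trial-power tables drawn from the generative model the mixed stage
# assumes: lognormal subject intercepts, iid log-normal trial noise, a
# multiplicative effect on selected cells.
sim_trial_table <- function(n_subj = 8, n_trials = 20, effect_mult = 1,
                            effect_cells = function(g) rep(FALSE, nrow(g)),
                            subj_sd = 0.3, noise_sd = 0.4, seed = 1,
                            intensities = c("sham", "0.5", "1.0", "1.5"),
                            time_points = c("pre", "post1", "post2"),
                            bands = c("theta", "alpha", "beta", "gamma")) {
  set.seed(seed)
  subjects <- sprintf("s%02d", seq_len(n_subj))
  g <- expand.grid(subject = subjects, intensity = intensities,
                   time_point = time_points, band = bands,
                   region = c("C3", "C4"), trial = seq_len(n_trials),
                   stringsAsFactors = FALSE)
  b <- stats::rnorm(n_subj, 0, subj_sd)
  names(b) <- subjects
  mu <- b[g$subject] + log(ifelse(effect_cells(g), effect_mult, 1))
  g$value_linear <- exp(mu + stats::rnorm(nrow(g), 0, noise_sd))
  g$value_db <- 10 * log10(g$value_linear)
  attr(g, "subject_offsets") <- b
  g
}

# Feature-level inputs for the cluster battery: per-subject scalars and
# percent-change maps for every (period, region, intensity, block pair)
# cell, with an optional planted monotone association in one cell.
sim_cluster_battery <- function(n_subj = 20, nf = 12, nt = 15,
                                plant = NULL, plant_strength = 12,
                                seed = 1,
                                intensities = c("sham", "0.5", "1.0", "1.5")) {
  set.seed(seed)
  periods <- c("pre_movement", "movement", "post_movement")
  regions <- c("C3", "C4")
  pairs <- c("pre_post1", "pre_post2", "post1_post2")
  subjects <- sprintf("s%02d", seq_len(n_subj))
  scal <- expand.grid(subject = subjects, period = periods,
                      region = regions, intensity = intensities,
                      stringsAsFactors = FALSE)
  scal$value <- stats::rnorm(nrow(scal), 0, 2)
  maps <- list()
  for (p in periods) for (r in regions) for (i in intensities) {
    for (bp in pairs) {
      arr <- array(stats::rnorm(n_subj * nf * nt, 0, 10),
                   c(n_subj, nf, nt),
                   dimnames = list(subjects, NULL, NULL))
      if (!is.null(plant) && identical(plant, c(p, r, i, bp))) {
        x <- scal$value[scal$period == p & scal$region == r &
                          scal$intensity == i]
        x <- x[match(subjects, scal$subject[scal$period == p &
                                              scal$region == r &
                                              scal$intensity == i])]
        block_f <- 4:8; block_t <- 5:10
        for (s in seq_len(n_subj)) {
          arr[s, block_f, block_t] <- arr[s, block_f, block_t] -
            plant_strength * x[s]
        }
      }
      maps[[p]][[r]][[i]][[bp]] <- arr
    }
  }
  list(scalars = scal, maps = maps,
       plant_block = list(f = 4:8, t = 5:10))
}
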