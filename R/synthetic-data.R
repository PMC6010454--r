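#' Simulation configuration for synthetic BCI-FES sessions
#'
#' Bundles every knob of the synthetic EEG generator. Background activity is
#' 1/f (pink) noise plus channel-specific white sensor noise; sensorimotor
#' rhythms are narrow-band mu (~11 Hz) and beta (~21 Hz) oscillators with
#' random phase. Event-related desynchronisation (ERD) is a multiplicative
#' power reduction of the oscillator envelope on `erd_channels` during the
#' active period of movement-attempt trials: an `erd_depth` of `d` scales
#' band power by `1 - d`.
#'
#' @param seed integer seed; a fixed seed reproduces every sample bit-exactly.
#' @param n_channels,fs montage size and sampling rate (defaults 16 at 512 Hz).
#' @param n_trials_per_run,n_runs protocol size (15 trials/run, 3 runs).
#' @param erd_depth fraction in `[0, 1]`: relative mu/beta power drop during
#'   movement attempts.
#' @param noise_scale multiplier on the background (pink + white) noise.
#' @param group `"bci"` (closed-loop FES) or `"sham"` (random FES).
#' @param coupling_graph optional data frame `(from, to, strength)` of
#'   directed MVAR couplings between channels; must yield a stable process.
#' @param coupling_change multiplicative post/pre factor on the cue-locked
#'   coupling modulation (the group x time effect of the resting sessions).
#' @param erd_channels channels carrying the desynchronising rhythms.
#' @param mu_freq,beta_freq rhythm centre frequencies (Hz).
#' @param mu_amp,beta_amp oscillator amplitudes (uV) on `erd_channels`;
#'   other channels carry half-amplitude rhythms.
#' @param timing named list of protocol constants in seconds: `prep` (3),
#'   `cue` (1), `active` (4, calibration), `stop` (2), `iti` (range
#'   3-4.5), `timeout` (7, therapy).
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_channels = 16, fs = 512,
                       n_trials_per_run = 15, n_runs = 3,
                       erd_depth = 0.5, noise_scale = 1,
                       group = c("bci", "sham"),
                       coupling_graph = NULL, coupling_change = 1,
                       erd_channels = c("C3", "C1", "CP3", "CP1"),
                       mu_freq = 11, beta_freq = 21,
                       mu_amp = 4, beta_amp = 2,
                       timing = list(prep = 3, cue = 1, active = 4,
                                     stop = 2, iti = c(3, 4.5), timeout = 7)) {
  group <- match.arg(group)
  if (!is.numeric(erd_depth) || erd_depth < 0 || erd_depth > 1) {
    stop("`erd_depth` must lie in [0, 1]")
  }
  channels <- montage_16()[seq_len(n_channels)]
  if (n_channels > 16) {
    stop("built-in montage provides at most 16 channels")
  }
  if (!is.null(coupling_graph)) {
    ab <- mvar_from_graph(coupling_graph,
                          channels = union(coupling_graph$from, coupling_graph$to),
                          fs = fs)
    rad <- companion_radius(ab$A)
    if (rad >= 1) {
      stop(sprintf(
        "unstable coupling_graph: companion spectral radius %.3f >= 1", rad))
    }
  }
  structure(
    list(seed = as.integer(seed), n_channels = n_channels, fs = fs,
         n_trials_per_run = n_trials_per_run, n_runs = n_runs,
         erd_depth = erd_depth, noise_scale = noise_scale, group = group,
         coupling_graph = coupling_graph, coupling_change = coupling_change,
         erd_channels = toupper(erd_channels), mu_freq = mu_freq,
         beta_freq = beta_freq, mu_amp = mu_amp, beta_amp = beta_amp,
         timing = timing),
    class = "sim_config"
  )
}

montage_16 <- function() {
  c("FZ", "FC3", "FC1", "FCZ", "FC2", "FC4", "C3", "C1", "CZ", "C2", "C4",
    "CP3", "CP1", "CPZ", "CP2", "CP4")
}

# pink (1/f amplitude) noise, unit variance
pink_noise <- function(n) {
  m <- stats::nextn(n)
  x <- stats::rnorm(m)
  X <- stats::fft(x)
  f <- c(1, seq_len(m - 1))
  f <- pmin(f, m - f + 1)          # mirrored frequency index
  X <- X / sqrt(f)
  y <- Re(stats::fft(X, inverse = TRUE)) / m
  y <- y[seq_len(n)]
  y / stats::sd(y)
}

# narrow-band oscillator: random-walk phase around freq, unit amplitude
nb_oscillator <- function(n, freq, fs, phase_jitter = 0.05) {
  dphi <- 2 * pi * freq / fs + stats::rnorm(n, 0, phase_jitter)
  sin(cumsum(dphi) + stats::runif(1, 0, 2 * pi))
}

# background + rhythms for one continuous block; `mod` is a per-sample
# amplitude multiplier applied to the oscillators of ERD channels
synth_block <- function(cfg, n, mod) {
  k <- cfg$n_channels
  channels <- montage_16()[seq_len(k)]
  out <- matrix(0, k, n)
  is_erd <- channels %in% cfg$erd_channels
  for (j in seq_len(k)) {
    bg <- cfg$noise_scale * (3 * pink_noise(n) + stats::rnorm(n))
    amp_mu <- if (is_erd[j]) cfg$mu_amp else cfg$mu_amp / 2
    amp_beta <- if (is_erd[j]) cfg$beta_amp else cfg$beta_amp / 2
    m <- if (is_erd[j]) mod else rep(1, n)
    osc <- amp_mu * m * nb_oscillator(n, cfg$mu_freq, cfg$fs) +
      amp_beta * m * nb_oscillator(n, cfg$beta_freq, cfg$fs)
    out[j, ] <- bg + osc
  }
  rownames(out) <- channels
  out
}

#' Generate a calibration session with known ground truth
#'
#' Produces a continuous 16-channel recording of balanced, randomised
#' movement-attempt and rest trials following the standard protocol (3-s
#' preparation, 1-s cue, 4-s active period, 2-s stop, 3-4.5-s inter-trial
#' interval; times are relative to the "Start" cue at 0). During the active
#' period of attempt trials, mu/beta band power on the ERD channels drops by
#' the configured `erd_depth`.
#'
#' @param config a [sim_config] (`fs = 512`, `n_channels = 16` for the
#'   standard protocol).
#' @return A list with elements `recording` ([eeg_recording]), `events`
#'   (per-trial data frame: `trial`, `class`, `t_start`, `active_on`,
#'   `active_off`), and `ground_truth` (list: `true_labels`, `true_graph`,
#'   `true_erd_channels`, `fes_schedule`, `erd_power_ratio`).
#' @export
gen_calibration_session <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tm <- config$timing
  n_trials <- config$n_trials_per_run * config$n_runs
  labels <- sample(rep(c("attempt", "rest"), length.out = n_trials))
  fs <- config$fs
  itis <- stats::runif(n_trials, tm$iti[1], tm$iti[2])
  trial_len <- round((tm$prep + tm$cue + tm$active + tm$stop + itis) * fs)
  offsets <- cumsum(c(0, utils::head(trial_len, -1)))
  n_total <- sum(trial_len)
  # per-sample ERD envelope multiplier over the whole session
  mod <- rep(1, n_total)
  t_start <- (offsets + round(tm$prep * fs)) / fs
  active_on <- t_start + tm$cue
  active_off <- active_on + tm$active
  for (i in seq_len(n_trials)) {
    if (labels[i] == "attempt") {
      a <- round(active_on[i] * fs) + 1L
      b <- round(active_off[i] * fs)
      mod[a:b] <- sqrt(1 - config$erd_depth)
    }
  }
  samples <- synth_block(config, n_total, mod)
  samples <- add_coupling_component(config, samples)
  rec <- eeg_recording(samples, fs = fs,
                       channels = rownames(samples), lesion_side = "left",
                       reference = "mastoid")
  events <- data.frame(trial = seq_len(n_trials), class = labels,
                       t_start = t_start, active_on = active_on,
                       active_off = active_off)
  gt <- list(true_labels = labels, true_graph = config$coupling_graph,
             true_erd_channels = intersect(config$erd_channels, rec$channels),
             fes_schedule = rep(NA_real_, n_trials),
             erd_power_ratio = 1 - config$erd_depth)
  list(recording = rec, events = events, ground_truth = gt)
}

add_coupling_component <- function(cfg, samples) {
  if (is.null(cfg$coupling_graph)) return(samples)
  chans <- intersect(rownames(samples),
                     union(cfg$coupling_graph$from, cfg$coupling_graph$to))
  ab <- mvar_from_graph(cfg$coupling_graph, channels = chans, fs = cfg$fs)
  x <- simulate_mvar(ab$A, n = ncol(samples), innov_sd = 1)
  samples[chans, ] <- samples[chans, ] + x
  samples
}

#' Generate a therapy course (closed-loop BCI or sham arm)
#'
#' Simulates `n_runs` runs of `n_trials_per_run` movement-attempt trials. In
#' the `bci` arm the supplied decoder is applied online (62.5-ms steps,
#' leaky evidence accumulation) and FES is delivered if and only if the
#' accumulated attempt evidence crosses the confidence threshold before the
#' timeout. In the `sham` arm the full FES schedule (9-11 deliveries per
#' 15-trial run, delivery times uniform in 3.5-5.5 s after the "Start" cue)
#' is drawn *before* any EEG is synthesised, so it is independent of the
#' neural realisation by construction; the decoder still runs silently so
#' that decoder-FES contingency can be analysed.
#'
#' @param config a [sim_config]; `config$group` selects the arm.
#' @param decoder a `decoder_model` from [fit_classifier()]; required in both
#'   arms (sham patients also get a calibrated decoder for analysis).
#' @param trial_class class of the generated trials (`"attempt"`; `"rest"`
#'   yields ERD-free signals, e.g. for false-positive checks).
#' @return A `trial_log` data frame with one row per trial: `run`, `trial`,
#'   `true_class`, `t_fes` (s after "Start", `NA` if none), `decision`,
#'   `decision_time`, and list-columns `step_times`, `posterior`.
#' @export
gen_therapy_course <- function(config, decoder = NULL,
                               trial_class = c("attempt", "rest")) {
  stopifnot(inherits(config, "sim_config"))
  trial_class <- match.arg(trial_class)
  if (is.null(decoder)) {
    stop("a trained decoder is required (both arms run the decoder; ",
         "only the bci arm lets it drive FES)")
  }
  set.seed(config$seed)
  tm <- config$timing
  n_runs <- config$n_runs; n_tr <- config$n_trials_per_run
  sham_schedule <- NULL
  if (config$group == "sham") {
    # schedule drawn up-front: independent of the signals below
    sham_schedule <- sham_fes_schedule(n_runs, n_tr)
  }
  rows <- list()
  for (r in seq_len(n_runs)) {
    for (i in seq_len(n_tr)) {
      res <- simulate_therapy_trial(config, decoder, trial_class,
                                    sham_t_fes = if (!is.null(sham_schedule))
                                      sham_schedule[[r]][i] else NULL)
      rows[[length(rows) + 1L]] <- c(list(run = r, trial = i), res)
    }
  }
  log <- data.frame(
    run = vapply(rows, `[[`, 1L, "run"),
    trial = vapply(rows, `[[`, 1L, "trial"),
    true_class = vapply(rows, `[[`, "", "true_class"),
    t_fes = vapply(rows, `[[`, 1, "t_fes"),
    decision = vapply(rows, `[[`, "", "decision"),
    decision_time = vapply(rows, `[[`, 1, "decision_time")
  )
  log$step_times <- I(lapply(rows, `[[`, "step_times"))
  log$posterior <- I(lapply(rows, `[[`, "posterior"))
  class(log) <- c("trial_log", class(log))
  attr(log, "arm") <- config$group
  log
}

# one therapy trial: returns decision + posterior trace. Sham trials end at
# the scheduled FES, so the epoch is synthesised (and decoded) only up to
# that point; trials without FES run to the timeout.
simulate_therapy_trial <- function(config, decoder, trial_class, sham_t_fes) {
  tm <- config$timing
  fs <- config$fs
  active_len <- tm$timeout
  if (!is.null(sham_t_fes) && !is.na(sham_t_fes)) {
    active_len <- min(active_len, sham_t_fes - tm$cue + 2 * decoder$step_s)
  }
  epoch_s <- tm$prep + tm$cue + active_len
  n <- round(epoch_s * fs)
  t_start <- tm$prep
  active_on <- t_start + tm$cue
  active_off <- active_on + active_len
  mod <- rep(1, n)
  if (trial_class == "attempt") {
    mod[(round(active_on * fs) + 1L):round(active_off * fs)] <-
      sqrt(1 - config$erd_depth)
  }
  samples <- synth_block(config, n, mod)
  rec <- eeg_recording(samples, fs = fs, channels = rownames(samples),
                       lesion_side = "left", reference = "mastoid")
  events <- data.frame(trial = 1L, class = trial_class, t_start = t_start,
                       active_on = active_on, active_off = active_off)
  post <- decode_posteriors(decoder, rec, events)[[1]]
  times <- attr(post, "times")
  if (config$group == "bci") {
    tr <- accumulate_evidence(post, alpha = decoder$alpha, th = decoder$th,
                              times = times, two_sided = FALSE)
    t_fes <- if (tr$decision == "attempt") tr$decision_time else NA_real_
    n_keep <- if (!is.na(t_fes)) which(times >= t_fes)[1] else length(post)
    list(true_class = trial_class, t_fes = t_fes, decision = tr$decision,
         decision_time = tr$decision_time,
         step_times = times[seq_len(n_keep)],
         posterior = as.numeric(post)[seq_len(n_keep)])
  } else {
    t_fes <- if (is.null(sham_t_fes) || is.na(sham_t_fes)) NA_real_ else sham_t_fes
    n_keep <- if (!is.na(t_fes)) max(1L, sum(times <= t_fes)) else length(post)
    list(true_class = trial_class, t_fes = t_fes, decision = "none",
         decision_time = NA_real_,
         step_times = times[seq_len(n_keep)],
         posterior = as.numeric(post)[seq_len(n_keep)])
  }
}

#' Draw a sham-arm FES schedule
#'
#' Random (not neurally driven) FES: each 15-trial run receives a number of
#' deliveries drawn uniformly from {9, 10, 11} (the observed per-run range
#' of closed-loop therapy), assigned to random trials, with delivery times
#' uniform in 3.5-5.5 s after the "Start" cue. Uses the current RNG state;
#' [gen_therapy_course()] draws the whole schedule before synthesising any
#' EEG.
#'
#' @param n_runs number of runs.
#' @param n_trials_per_run trials per run.
#' @param seed optional seed (left untouched if `NULL`).
#' @return List of length `n_runs`; each element is a vector of per-trial
#'   FES onset times (s after the cue), `NA` for trials without FES.
#' @export
sham_fes_schedule <- function(n_runs, n_trials_per_run = 15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_runs), function(r) {
    n_fes <- sample(9:11, 1)
    fes_trials <- sort(sample(seq_len(n_trials_per_run), n_fes))
    t_fes <- rep(NA_real_, n_trials_per_run)
    t_fes[fes_trials] <- stats::runif(n_fes, 3.5, 5.5)
    t_fes
  })
}

#' Generate a synthetic clinical cohort with a known recovery model
#'
#' Per-patient recovery is generated as
#' `dFMA = effect * 1[group = bci] + link_slope * accuracy + cell effects + noise`,
#' where `accuracy` is the patient's decoder-FES contingency accuracy
#' (fraction in `[0, 1]`) and the optional `cell_weights` add contributions
#' of the individual contingency cells (percent scale). Pre scores are drawn
#' uniformly from the moderate-to-severe range (5-40 FMA-UE points) and post
#' scores are clipped to the 0-66 scale (clipping is flagged).
#'
#' @param n_per_group patients per arm (>= 3).
#' @param effect group effect on `dFMA` in FMA-UE points.
#' @param noise_sd residual standard deviation in points.
#' @param link_slope points of recovery per unit of contingency accuracy.
#' @param seed integer seed.
#' @param cell_weights optional named vector `c(TP =, TN =, FP =, FN =)` of
#'   points per percent of each contingency cell.
#' @return A `clinical_table` data frame (`id`, `group`, `score`,
#'   `timepoint`, `value`) with attributes `accuracy`, `cells` (per-patient
#'   contingency percentages), `dfma` and `clipped`.
#' @export
gen_clinical_cohort <- function(n_per_group, effect = 0, noise_sd = 3,
                                link_slope = 0, seed = 1L,
                                cell_weights = NULL) {
  if (n_per_group < 3) stop("need at least 3 patients per group")
  set.seed(seed)
  n <- 2L * n_per_group
  group <- rep(c("bci", "sham"), each = n_per_group)
  # contingency cells emulating closed-loop vs random FES structure
  tp <- ifelse(group == "bci", stats::rnorm(n, 72, 10), stats::rnorm(n, 42, 11))
  fp <- ifelse(group == "bci", 0, pmax(0, stats::rnorm(n, 21, 8)))
  tn <- pmax(0, ifelse(group == "bci", stats::rnorm(n, 13, 7),
                       stats::rnorm(n, 12, 7)))
  tp <- pmin(pmax(tp, 5), 95)
  sc <- 100 / (tp + fp + tn + pmax(5, 100 - tp - fp - tn))
  cells <- data.frame(TP = tp * sc, FP = fp * sc, TN = tn * sc)
  cells$FN <- 100 - cells$TP - cells$FP - cells$TN
  accuracy <- (cells$TP + cells$TN) / 100
  dfma <- effect * (group == "bci") + link_slope * accuracy +
    stats::rnorm(n, 0, noise_sd)
  if (!is.null(cell_weights)) {
    dfma <- dfma + as.matrix(cells[, names(cell_weights)]) %*% cell_weights
  }
  pre <- sample(5:40, n, replace = TRUE)
  post_raw <- pre + dfma
  post <- pmin(pmax(post_raw, 0), 66)
  clipped <- post != post_raw
  if (any(clipped)) {
    message(sum(clipped), " post score(s) clipped to the 0-66 FMA-UE range")
  }
  id <- sprintf("%s%02d", group, stats::ave(seq_len(n), group, FUN = seq_along))
  tab <- data.frame(
    id = rep(id, 2), group = rep(group, 2), score = "FMA-UE",
    timepoint = rep(c("pre", "post"), each = n), value = c(pre, post)
  )
  class(tab) <- c("clinical_table", class(tab))
  attr(tab, "accuracy") <- stats::setNames(accuracy, id)
  attr(tab, "cells") <- cbind(id = id, group = group, cells)
  attr(tab, "dfma") <- stats::setNames(as.numeric(post - pre), id)
  attr(tab, "clipped") <- stats::setNames(clipped, id)
  tab
}

# ---- resting-state sessions for connectivity --------------------------------

#' Generate a resting-session trial ensemble with cue-locked coupling change
#'
#' Emulates the pre/post high-density resting recordings at region-of-
#' interest scale: channels are generated directly as a time-varying MVAR
#' process (identity mixing, no volume conduction). Directed couplings of
#' `coupling_graph` run at their base strength before the "Start" cue and
#' are multiplied by `1 + mod` within the post-cue analysis window; for post
#' sessions of the `bci` group the modulation `mod` is further multiplied by
#' `config$coupling_change`, which is the injected group x time effect.
#'
#' @param config a [sim_config]; `coupling_graph` must be set. The relevant
#'   fields are `seed`, `group`, `coupling_graph`, `coupling_change`,
#'   `noise_scale` and `fs` (the resting generator accepts any `fs`).
#' @param session `"pre"` or `"post"`.
#' @param n_trials number of resting trials (epochs).
#' @param epoch time range of each epoch in seconds relative to the cue.
#' @param mod base cue-locked modulation of coupling strength.
#' @param channels channel labels of the generated process.
#' @return List with `trials` (array channel x time x trial), `times`
#'   (seconds relative to the cue) and `fs`.
#' @export
gen_resting_session <- function(config, session = c("pre", "post"),
                                n_trials = 20, epoch = c(-3.5, 2.5),
                                mod = 0.4,
                                channels = c("C5", "C3", "C1", "C2", "C4", "C6")) {
  stopifnot(inherits(config, "sim_config"))
  session <- match.arg(session)
  if (is.null(config$coupling_graph)) stop("config$coupling_graph must be set")
  set.seed(config$seed + 1000L * (session == "post"))
  fs <- config$fs
  m <- mod * if (session == "post" && config$group == "bci")
    config$coupling_change else 1
  g <- config$coupling_graph
  g_active <- g
  g_active$strength <- g$strength * (1 + m)
  ab_base <- mvar_from_graph(g, channels = channels, fs = fs)
  ab_act <- mvar_from_graph(g_active, channels = channels, fs = fs)
  if (companion_radius(ab_act$A) >= 1) {
    stop("modulated coupling graph is unstable")
  }
  times <- seq(epoch[1], epoch[2] - 1 / fs, by = 1 / fs)
  active <- times >= 0
  trials <- simulate_mvar_switch(ab_base$A, ab_act$A, n = length(times),
                                 burn = round(fs), active = active,
                                 innov_sd = config$noise_scale,
                                 n_trials = n_trials)
  list(trials = trials, times = times, fs = fs)
}

#' Simulate a full connectivity cohort and return ROI-level values
#'
#' For each synthetic subject, generates pre and post resting sessions with
#' [gen_resting_session()], runs the sliding-window SdDTF pipeline
#' ([sddtf_sliding()], [baseline_reference()], [roi_average()]) and returns
#' the per-subject ROI/band/session table that the clinical statistics
#' consume. Subjects vary in their base coupling strength (10% jitter).
#'
#' @param n_per_group subjects per arm.
#' @param coupling_change multiplicative post/pre coupling-modulation factor
#'   for the bci arm (1 = null).
#' @param seed integer seed.
#' @param n_trials,fs,p,mod,base_strength generator and estimator sizes.
#' @param freqs frequency grid (Hz) for the spectral estimation.
#' @param epoch,baseline,analysis epoch range and referencing intervals (s).
#' @param bands named list of frequency bands (Hz ranges).
#' @return Data frame: `id`, `group`, `session`, `roi`, `band`, `value`.
#' @export
simulate_connectivity_cohort <- function(n_per_group, coupling_change = 2.5,
                                         seed = 1L, n_trials = 20, fs = 128,
                                         p = 3, mod = 0.4,
                                         base_strength = 0.2,
                                         freqs = seq(2, 48, by = 2),
                                         epoch = c(-3.5, 2.5),
                                         baseline = c(-3.5, -1),
                                         analysis = c(0, 2.5),
                                         bands = list(mu = c(10, 12),
                                                      beta = c(18, 24))) {
  set.seed(seed)
  channels <- c("C5", "C3", "C1", "C2", "C4", "C6")
  rois <- list(aff_sm = c("C5", "C3", "C1"),
               unaff_sm = c("C2", "C4", "C6"))
  out <- list()
  subj_seeds <- sample.int(2^30, 2L * n_per_group)
  groups <- rep(c("bci", "sham"), each = n_per_group)
  jitter <- stats::runif(2L * n_per_group, 0.9, 1.1)
  for (s in seq_along(groups)) {
    graph <- data.frame(from = "C5", to = "C3",
                        strength = base_strength * jitter[s])
    cfg <- sim_config(seed = subj_seeds[s], fs = fs, group = groups[s],
                      coupling_graph = graph,
                      coupling_change = coupling_change)
    for (session in c("pre", "post")) {
      ses <- gen_resting_session(cfg, session, n_trials = n_trials,
                                 epoch = epoch, mod = mod,
                                 channels = channels)
      ct <- sddtf_sliding(ses$trials, times = ses$times, fs = fs,
                          p = p, freqs = freqs)
      ref <- baseline_reference(ct, baseline = baseline, analysis = analysis)
      roi <- roi_average(ref, rois = rois, bands = bands)
      roi$id <- sprintf("%s%02d", groups[s], ((s - 1) %% n_per_group) + 1)
      roi$group <- groups[s]
      roi$session <- session
      out[[length(out) + 1L]] <- roi
    }
  }
  do.call(rbind, out)
}
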