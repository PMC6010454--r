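# shared fixtures built in code

# tiny deterministic recording
toy_recording <- function(k = 16, n = 1000, fs = 512, seed = 1) {
  set.seed(seed)
  eeg_recording(matrix(rnorm(k * n), k, n), fs = fs,
                channels = bcifes:::montage_16()[seq_len(k)],
                lesion_side = "left")
}

# hand-built feature tensor: n_trials x n_steps x k x nf with labels
toy_feature_tensor <- function(n_trials = 20, n_steps = 4, k = 3, nf = 2,
                               labels = rep(c("attempt", "rest"),
                                            length.out = n_trials),
                               seed = 1) {
  set.seed(seed)
  arr <- array(abs(rnorm(n_trials * n_steps * k * nf)),
               c(n_trials, n_steps, k, nf))
  structure(arr, freqs = seq(10, by = 2, length.out = nf),
            step = 0.0625, times = seq_len(n_steps) * 0.0625,
            labels = labels, channels = bcifes:::montage_16()[seq_len(k)],
            class = c("feature_tensor", "array"))
}

# hand-built trial log with explicit posteriors / FES times
toy_trial_log <- function(posterior, t_fes, arm = "bci") {
  n <- length(posterior)
  log <- data.frame(run = rep(1L, n), trial = seq_len(n),
                    true_class = rep("attempt", n),
                    t_fes = t_fes, decision = rep("none", n),
                    decision_time = rep(NA_real_, n))
  log$step_times <- I(lapply(posterior, function(p) seq_along(p) * 0.0625 + 1))
  log$posterior <- I(posterior)
  class(log) <- c("trial_log", class(log))
  attr(log, "arm") <- arm
  log
}

# long clinical table from a wide matrix of values (subjects x timepoints)
toy_clinical_table <- function(values, group, score = "FMA-UE",
                               timepoints = colnames(values)) {
  n <- nrow(values)
  ids <- sprintf("S%02d", seq_len(n))
  out <- do.call(rbind, lapply(seq_along(timepoints), function(j) {
    data.frame(id = ids, group = group, score = score,
               timepoint = timepoints[j], value = values[, j])
  }))
  class(out) <- c("clinical_table", class(out))
  out
}

# ROI table -> clinical-table shape for the mixed ANOVA
roi_to_table <- function(roi, which_roi = "within:aff_sm", band = "mu") {
  sub <- roi[roi$roi == which_roi & roi$band == band, ]
  tab <- data.frame(id = sub$id, group = sub$group, score = "conn",
                    timepoint = sub$session, value = sub$value)
  class(tab) <- c("clinical_table", class(tab))
  tab
}

interaction_p <- function(roi, ...) {
  suppressMessages(mixed_anova(roi_to_table(roi, ...), "conn",
                               c("pre", "post")))$p
}
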