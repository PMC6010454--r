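#' Rank PSD features by two-class discriminant power
#'
#' For each (channel, frequency) feature, pools all time-step samples of all
#' trials and computes the canonical discriminant ratio of the two classes
#' (between-class variance over within-class variance, the two-class special
#' case of canonical variate analysis). Features are ordered by decreasing
#' score; ties break lexicographically on (channel, frequency). An optional
#' user mask restricts the candidates (the "prior neurophysiological
#' knowledge" override).
#'
#' @param features a `feature_tensor` from [welch_psd_features()].
#' @param mask optional logical matrix channel x frequency of admissible
#'   features.
#' @return A `feature_ranking`: data frame `channel`, `freq`, `score`,
#'   ordered by rank.
#' @export
rank_features <- function(features, mask = NULL) {
  labels <- attr(features, "labels")
  channels <- attr(features, "channels")
  freqs <- attr(features, "freqs")
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop("both classes must be present")
  if (min(table(labels)) < 2) stop("need >= 2 trials per class")
  d <- dim(features)
  scores <- matrix(0, d[3], d[4])
  x_by_class <- lapply(classes, function(cl) {
    features[labels == cl, , , , drop = FALSE]
  })
  n_c <- vapply(x_by_class, function(x) prod(dim(x)[1:2]), 1)
  warned <- FALSE
  for (ch in seq_len(d[3])) {
    for (fb in seq_len(d[4])) {
      v <- lapply(x_by_class, function(x) as.numeric(x[, , ch, fb]))
      m_c <- vapply(v, mean, 1)
      grand <- sum(n_c * m_c) / sum(n_c)
      ssb <- sum(n_c * (m_c - grand)^2)
      ssw <- sum(vapply(v, function(x) sum((x - mean(x))^2), 1))
      if (ssw <= .Machine$double.eps * sum(n_c)) {
        scores[ch, fb] <- Inf
        warned <- TRUE
      } else {
        scores[ch, fb] <- ssb / ssw
      }
    }
  }
  if (warned) warning("zero within-class variance; score capped at +Inf")
  rk <- data.frame(
    channel = rep(channels, times = length(freqs)),
    freq = rep(freqs, each = length(channels)),
    score = as.numeric(scores)
  )
  if (!is.null(mask)) {
    rk <- rk[as.logical(mask), ]   # mask is channel x freq, column-major
  }
  ord <- order(-rk$score, match(rk$channel, channels), rk$freq)
  rk <- rk[ord, ]
  rownames(rk) <- NULL
  class(rk) <- c("feature_ranking", class(rk))
  rk
}

#' Fit the two-class Gaussian decoder
#'
#' One Gaussian prototype per class (movement attempt vs rest) on the
#' selected feature subspace, diagonal covariance, equal priors. The
#' posterior for a sample `x` is `N_a(x) / (N_a(x) + N_r(x))`.
#'
#' @param features a `feature_tensor` with per-trial labels.
#' @param ranking a `feature_ranking`; the top `n_features` rows are used.
#' @param n_features number of features to keep (at most 10 by convention).
#' @param alpha,th,timeout evidence-accumulation parameters stored with the
#'   model: integration coefficient per 62.5-ms step, confidence threshold,
#'   and trial timeout in seconds.
#' @param var_floor variance floor as a fraction of the feature's pooled
#'   variance (guards against singular class variances).
#' @return A `decoder_model`.
#' @export
fit_classifier <- function(features, ranking, n_features = 10,
                           alpha = 0.96, th = 0.8, timeout = 7,
                           var_floor = 1e-8) {
  stopifnot(inherits(ranking, "feature_ranking"))
  labels <- attr(features, "labels")
  classes <- c("attempt", "rest")
  if (!all(classes %in% labels)) stop("both classes must be present")
  if (min(table(labels)) < 5) stop("need >= 5 trials per class")
  sel <- utils::head(ranking, n_features)
  channels <- attr(features, "channels")
  freqs <- attr(features, "freqs")
  ch_i <- match(sel$channel, channels)
  fb_i <- match(sel$freq, freqs)
  pull <- function(cl) {
    x <- features[labels == cl, , , , drop = FALSE]
    sapply(seq_len(nrow(sel)), function(j) as.numeric(x[, , ch_i[j], fb_i[j]]))
  }
  xa <- pull("attempt"); xr <- pull("rest")
  floor_ <- var_floor * apply(rbind(xa, xr), 2, stats::var)
  va <- pmax(apply(xa, 2, stats::var), floor_)
  vr <- pmax(apply(xr, 2, stats::var), floor_)
  if (any(va == floor_) || any(vr == floor_)) {
    warning("singular class variance floored")
  }
  structure(
    list(features = sel[, c("channel", "freq")],
         mean_attempt = colMeans(xa), mean_rest = colMeans(xr),
         var_attempt = va, var_rest = vr,
         alpha = alpha, th = th, timeout = timeout,
         window_s = 1.0, step_s = attr(features, "step") %||% 0.0625,
         log_features = FALSE),
    class = "decoder_model"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Posterior probability of "movement attempt" for feature samples
#'
#' @param model a `decoder_model`.
#' @param x numeric matrix (samples x selected features) or vector.
#' @return Numeric vector of posteriors in `[0, 1]`; attempt and rest
#'   posteriors sum to one.
#' @export
predict_posterior <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  ll <- function(mu, v) {
    -0.5 * rowSums(sweep(sweep(x, 2, mu)^2, 2, v, "/")) -
      0.5 * sum(log(2 * pi * v))
  }
  la <- ll(model$mean_attempt, model$var_attempt)
  lr <- ll(model$mean_rest, model$var_rest)
  1 / (1 + exp(lr - la))
}

# per-trial posterior traces for a recording + events, using the model's
# stored feature definition; the recording gets the same Laplacian
# derivation the decoder was calibrated on
decode_posteriors <- function(model, rec, events, laplacian = TRUE) {
  if (laplacian) rec <- apply_laplacian(rec)
  ft <- welch_psd_features(rec, events, window_s = model$window_s,
                           step_s = model$step_s)
  channels <- attr(ft, "channels"); freqs <- attr(ft, "freqs")
  ch_i <- match(model$features$channel, channels)
  fb_i <- match(model$features$freq, freqs)
  if (anyNA(ch_i) || anyNA(fb_i)) {
    stop("recording does not provide the model's feature space")
  }
  lapply(seq_len(dim(ft)[1]), function(tr) {
    x <- sapply(seq_along(ch_i), function(j) ft[tr, , ch_i[j], fb_i[j]])
    p <- predict_posterior(model, x)
    attr(p, "times") <- attr(ft, "times")
    p
  })
}

#' Accumulate posterior evidence to a confidence threshold
#'
#' Exponential (leaky) integration of the per-step attempt posteriors:
#' `p_acc(t) = alpha p_acc(t-1) + (1 - alpha) p(t)` starting from 0.5. A
#' decision "attempt" is taken at the first step where `p_acc >= th`; in
#' two-sided mode (offline evaluation) a decision "rest" is taken where
#' `p_acc <= 1 - th`. If the sequence ends without a crossing the trial is a
#' no-decision.
#'
#' @param posteriors numeric vector of attempt posteriors in `[0, 1]`.
#' @param alpha integration coefficient in `[0, 1)`.
#' @param th confidence threshold in `(0.5, 1]`.
#' @param times optional per-step timestamps (s); defaults to the step index.
#' @param two_sided also allow rest decisions (used offline; online only
#'   attempt crossings trigger FES).
#' @return An `evidence_trace` list: `values`, `decision` (`"attempt"`,
#'   `"rest"` or `"none"`), `decision_time`, `decision_step`.
#' @export
accumulate_evidence <- function(posteriors, alpha, th, times = NULL,
                                two_sided = FALSE) {
  if (!is.numeric(alpha) || alpha < 0 || alpha >= 1) {
    stop("`alpha` must lie in [0, 1)")
  }
  if (th <= 0.5 || th > 1) stop("`th` must lie in (0.5, 1]")
  if (any(posteriors < 0 | posteriors > 1)) {
    stop("posteriors must lie in [0, 1]")
  }
  if (is.null(times)) times <- seq_along(posteriors)
  p_acc <- numeric(length(posteriors))
  prev <- 0.5
  decision <- "none"; d_step <- NA_integer_
  for (t in seq_along(posteriors)) {
    prev <- alpha * prev + (1 - alpha) * posteriors[t]
    p_acc[t] <- prev
    if (prev >= th) {
      decision <- "attempt"; d_step <- t; break
    }
    if (two_sided && prev <= 1 - th) {
      decision <- "rest"; d_step <- t; break
    }
  }
  structure(list(values = p_acc[seq_len(if (is.na(d_step)) length(posteriors) else d_step)],
                 decision = decision,
                 decision_time = if (is.na(d_step)) NA_real_ else times[d_step],
                 decision_step = d_step),
            class = "evidence_trace")
}

#' Offline single-trial decoder performance
#'
#' Replays evidence accumulation over every labelled calibration trial
#' (two-sided crossings) and tabulates, with the decided-trials denominator:
#' `TPR` = attempt trials decided "attempt" / attempt trials with any
#' decision, `FPR` = rest trials decided "attempt" / rest trials with any
#' decision, and `ND` = no-decision trials / all trials. Because printed
#' conventions differ, all-trials-denominator variants (`TPR_all`,
#' `FPR_all`) are reported alongside.
#'
#' @param model a `decoder_model`.
#' @param features a labelled `feature_tensor`.
#' @return List `TPR`, `FPR`, `ND`, `TPR_all`, `FPR_all`, `n_attempt`,
#'   `n_rest`. Rates over an empty class are `NA`.
#' @export
evaluate_offline <- function(model, features) {
  labels <- attr(features, "labels")
  if (!length(labels)) stop("empty feature tensor")
  channels <- attr(features, "channels"); freqs <- attr(features, "freqs")
  ch_i <- match(model$features$channel, channels)
  fb_i <- match(model$features$freq, freqs)
  decisions <- character(dim(features)[1])
  for (tr in seq_len(dim(features)[1])) {
    x <- sapply(seq_along(ch_i), function(j) features[tr, , ch_i[j], fb_i[j]])
    p <- predict_posterior(model, x)
    decisions[tr] <- accumulate_evidence(p, model$alpha, model$th,
                                         two_sided = TRUE)$decision
  }
  att <- labels == "attempt"; rst <- labels == "rest"
  if (!any(att) && !any(rst)) stop("no labelled trials")
  dec <- decisions != "none"
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  list(
    TPR = rate(sum(att & decisions == "attempt"), sum(att & dec)),
    FPR = rate(sum(rst & decisions == "attempt"), sum(rst & dec)),
    ND = mean(!dec),
    TPR_all = rate(sum(att & decisions == "attempt"), sum(att)),
    FPR_all = rate(sum(rst & decisions == "attempt"), sum(rst)),
    n_attempt = sum(att), n_rest = sum(rst),
    decisions = decisions
  )
}

#' Adapt the confidence threshold between runs
#'
#' Therapist-style shaping keeping the task hard but feasible: if the last
#' run delivered more than `target[2]` FES the threshold is raised by
#' `delta`; if fewer than `target[1]`, lowered by `delta`; otherwise kept.
#' The threshold is clamped to `(0.5, 0.99]`.
#'
#' @param run_history numeric vector of per-run FES counts, or a
#'   `trial_log` (counts are derived from `t_fes`).
#' @param th current threshold.
#' @param delta adjustment step.
#' @param target acceptable band of FES per 15-trial run.
#' @return The updated threshold.
#' @export
shape_threshold <- function(run_history, th, delta = 0.02,
                            target = c(10, 12)) {
  if (inherits(run_history, "trial_log")) {
    run_history <- tapply(!is.na(run_history$t_fes), run_history$run, sum)
  }
  if (!length(run_history)) stop("need at least one completed run")
  last <- utils::tail(as.numeric(run_history), 1)
  th_new <- th
  if (last > target[2]) th_new <- th + delta
  if (last < target[1]) th_new <- th - delta
  min(max(th_new, 0.5 + 1e-6), 0.99)
}

#' Serialize / deserialize a decoder model as JSON
#'
#' @param model a `decoder_model`.
#' @param path file path.
#' @return `path` (writer) or a `decoder_model` (reader).
#' @export
write_decoder <- function(model, path) {
  stopifnot(inherits(model, "decoder_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_decoder
#' @export
read_decoder <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$features <- as.data.frame(m$features)
  for (f in c("mean_attempt", "mean_rest", "var_attempt", "var_rest")) {
    m[[f]] <- as.numeric(m[[f]])
  }
  structure(m, class = "decoder_model")
}

#' Calibrate a decoder from a recording and its events
#'
#' Convenience wrapper: Laplacian filter, Welch features, discriminant
#' ranking, Gaussian fit.
#'
#' @param rec calibration [eeg_recording].
#' @param events trial event table (see [welch_psd_features()]).
#' @param n_features,alpha,th,timeout passed to [fit_classifier()].
#' @param neighbor_map passed to [apply_laplacian()].
#' @return A `decoder_model`.
#' @export
calibrate_decoder <- function(rec, events, n_features = 10, alpha = 0.96,
                              th = 0.8, timeout = 7,
                              neighbor_map = default_neighbor_map()) {
  lap <- apply_laplacian(rec, neighbor_map)
  ft <- welch_psd_features(lap, events)
  rk <- rank_features(ft)
  fit_classifier(ft, rk, n_features = n_features, alpha = alpha, th = th,
                 timeout = timeout)
}
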