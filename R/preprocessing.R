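#' Orthogonal-neighbour map for the 16-channel sensorimotor montage
#'
#' The decoding montage covers the sensorimotor strip with Fz, FC3, FC1, FCz,
#' FC2, FC4, C3, C1, Cz, C2, C4, CP3, CP1, CPz, CP2 and CP4. Channels are
#' arranged on a grid (Fz above FCz; three rows FC / C / CP by five columns)
#' and each channel's Laplacian neighbours are its orthogonal (cross)
#' neighbours on that grid. Boundary channels use whatever orthogonal
#' neighbours exist, with equal weights summing to one.
#'
#' @return A data frame with columns `channel`, `neighbor`, `weight`.
#' @export
default_neighbor_map <- function() {
  grid <- rbind(
    c(NA,    NA,    "FZ",  NA,    NA),
    c("FC3", "FC1", "FCZ", "FC2", "FC4"),
    c("C3",  "C1",  "CZ",  "C2",  "C4"),
    c("CP3", "CP1", "CPZ", "CP2", "CP4")
  )
  rows <- nrow(grid); cols <- ncol(grid)
  out <- list()
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      ch <- grid[r, c]
      if (is.na(ch)) next
      nb <- c(
        if (r > 1) grid[r - 1, c] else NA,
        if (r < rows) grid[r + 1, c] else NA,
        if (c > 1) grid[r, c - 1] else NA,
        if (c < cols) grid[r, c + 1] else NA
      )
      nb <- nb[!is.na(nb)]
      out[[ch]] <- data.frame(channel = ch, neighbor = nb,
                              weight = 1 / length(nb))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Surface Laplacian spatial filter
#'
#' Subtracts from every channel the weighted sum of its neighbours' voltages:
#' `out_j = x_j - sum_i w_ij x_i`. This acts as a spatial high-pass that
#' sharpens focal sensorimotor rhythms before feature extraction.
#'
#' @param rec an [eeg_recording].
#' @param neighbor_map data frame with columns `channel`, `neighbor`,
#'   `weight`; weights must sum to 1 within each channel. Defaults to the
#'   orthogonal map of [default_neighbor_map()].
#' @return The filtered [eeg_recording] (reference tag `"laplacian"`).
#' @export
apply_laplacian <- function(rec, neighbor_map = default_neighbor_map()) {
  stopifnot(inherits(rec, "eeg_recording"))
  map <- neighbor_map
  map$channel <- toupper(map$channel)
  map$neighbor <- toupper(map$neighbor)
  unknown <- setdiff(unique(c(map$channel, map$neighbor)), rec$channels)
  if (length(unknown)) {
    stop("neighbor map refers to unknown channel(s): ",
         paste(unknown, collapse = ", "))
  }
  sums <- tapply(map$weight, map$channel, sum)
  if (any(abs(sums - 1) > 1e-8)) {
    stop("neighbor weights must sum to 1 per channel; offending: ",
         paste(names(sums)[abs(sums - 1) > 1e-8], collapse = ", "))
  }
  k <- length(rec$channels)
  W <- matrix(0, k, k, dimnames = list(rec$channels, rec$channels))
  for (i in seq_len(nrow(map))) {
    W[map$channel[i], map$neighbor[i]] <- map$weight[i]
  }
  out <- rec
  out$samples <- (diag(k) - W) %*% rec$samples
  rownames(out$samples) <- rec$channels
  out$reference <- "laplacian"
  out
}

#' Welch power spectral density of a single signal
#'
#' Hann-tapered, overlapping segments, one-sided density scaling. With 500-ms
#' segments the bin spacing is exactly `1/seg_s` Hz, so no zero padding is
#' needed.
#'
#' @param x numeric vector.
#' @param fs sampling frequency (Hz).
#' @param seg_s segment length in seconds; `fs * seg_s` must be an integer.
#' @param seg_overlap fractional overlap between consecutive segments.
#' @return Data frame with columns `freq` (Hz) and `psd` (uV^2/Hz).
#' @export
welch_psd <- function(x, fs, seg_s = 0.5, seg_overlap = 0.75) {
  seg_len <- fs * seg_s
  if (abs(seg_len - round(seg_len)) > 1e-9) {
    stop("fs * seg_s must be an integer number of samples")
  }
  seg_len <- as.integer(round(seg_len))
  step <- as.integer(round(seg_len * (1 - seg_overlap)))
  if (step < 1L) stop("segment overlap too large")
  if (length(x) < seg_len) stop("signal shorter than one segment")
  starts <- seq(1L, length(x) - seg_len + 1L, by = step)
  P <- welch_periodograms(matrix(x[outer(seq_len(seg_len) - 1L, starts, "+")],
                                 nrow = seg_len), fs)
  data.frame(freq = (seq_len(nrow(P)) - 1L) * fs / seg_len,
             psd = rowMeans(P))
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

# One-sided Hann periodograms of the columns of `segs` (seg_len x n_segs).
# Density scaling: 2 |X|^2 / (fs * sum(w^2)), halved at DC and Nyquist.
welch_periodograms <- function(segs, fs) {
  seg_len <- nrow(segs)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(seg_len) - 1L) / (seg_len - 1L))
  X <- stats::mvfft(segs * w)
  nf <- seg_len %/% 2L + 1L
  P <- 2 * abs(X[seq_len(nf), , drop = FALSE])^2 / (fs * sum(w^2))
  P[1L, ] <- P[1L, ] / 2
  if (seg_len %% 2L == 0L) P[nf, ] <- P[nf, ] / 2
  P
}

#' Welch PSD feature tensor over trial active periods
#'
#' Computes, every `step_s` seconds of each trial's active period, the Welch
#' PSD of the trailing `window_s` seconds of every channel (five Hann
#' segments of `seg_s` seconds at `seg_overlap` overlap for the defaults),
#' retaining the bins from `f_lo` to `f_hi` Hz at `f_res` Hz spacing. At the
#' standard 16-channel, 4-40 Hz configuration this yields 304 candidate
#' features per time step.
#'
#' @param rec an [eeg_recording] (typically Laplacian-filtered).
#' @param events trial event table with columns `trial`, `class`, `t_start`
#'   (time of the "Start" cue, s), `active_on`, `active_off` (s, absolute).
#' @param window_s,step_s,seg_s,seg_overlap,f_lo,f_hi,f_res see Details.
#' @return A `feature_tensor`: array `[trial, step, channel, freq]` with
#'   attributes `freqs`, `step` (s), `times` (step times relative to
#'   `t_start`), `labels` (per-trial class), `channels`.
#' @export
welch_psd_features <- function(rec, events, window_s = 1.0, step_s = 0.0625,
                               seg_s = 0.5, seg_overlap = 0.75,
                               f_lo = 4, f_hi = 40, f_res = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  seg_len <- as.integer(round(fs * seg_s))
  win_len <- as.integer(round(fs * window_s))
  step_len <- as.integer(round(fs * step_s))
  seg_step <- as.integer(round(seg_len * (1 - seg_overlap)))
  if (abs(fs * seg_s - seg_len) > 1e-9 || abs(fs * step_s - step_len) > 1e-9) {
    stop("fs must give integer segment and step lengths")
  }
  n_seg <- (win_len - seg_len) / seg_step + 1
  if (abs(n_seg - round(n_seg)) > 1e-9) {
    stop("window does not hold an integer number of segments at this overlap")
  }
  n_seg <- as.integer(round(n_seg))
  freqs_all <- (seq_len(seg_len %/% 2L + 1L) - 1L) / seg_s
  freqs <- seq(f_lo, f_hi, by = f_res)
  bin_idx <- match(freqs, freqs_all)
  if (anyNA(bin_idx)) stop("requested bins not on the Welch frequency grid")

  keep <- rep(TRUE, nrow(events))
  per_trial <- vector("list", nrow(events))
  rel_times <- NULL
  for (i in seq_len(nrow(events))) {
    a_on <- events$active_on[i]; a_off <- events$active_off[i]
    if (a_off - a_on < step_s || a_on * fs < win_len) {
      warning("trial ", events$trial[i], " shorter than the analysis window; skipped")
      keep[i] <- FALSE
      next
    }
    step_samp <- seq(as.integer(round(a_on * fs)),
                     as.integer(round(a_off * fs)), by = step_len)
    step_samp <- step_samp[step_samp <= n_samples(rec)]
    # all segment starts needed by any step live on one arithmetic grid
    g <- gcd2(step_len, seg_step)
    first <- min(step_samp) - win_len + 1L
    last <- max(step_samp) - win_len + seg_step * (n_seg - 1L) + 1L
    grid <- seq(first, last, by = g)
    idx <- outer(seq_len(seg_len) - 1L, grid, "+")
    k <- length(rec$channels)
    vals <- array(NA_real_, c(length(step_samp), k, length(freqs)))
    base_col <- (step_samp - win_len + 1L - first) %/% g + 1L
    for (ch in seq_len(k)) {
      P <- welch_periodograms(matrix(rec$samples[ch, idx], nrow = seg_len), fs)
      Pb <- P[bin_idx, , drop = FALSE]
      acc <- Pb[, base_col, drop = FALSE]
      for (j in seq_len(n_seg - 1L)) {
        acc <- acc + Pb[, base_col + j * (seg_step %/% g), drop = FALSE]
      }
      vals[, ch, ] <- t(acc / n_seg)
    }
    per_trial[[i]] <- vals
    if (is.null(rel_times)) rel_times <- step_samp / fs - events$t_start[i]
  }
  per_trial <- per_trial[keep]
  if (!length(per_trial)) stop("no trial long enough for the analysis window")
  n_steps <- min(vapply(per_trial, function(v) dim(v)[1], 1L))
  tensor <- array(NA_real_,
                  c(length(per_trial), n_steps, length(rec$channels), length(freqs)))
  for (i in seq_along(per_trial)) {
    tensor[i, , , ] <- per_trial[[i]][seq_len(n_steps), , ]
  }
  structure(tensor,
            freqs = freqs, step = step_s, times = rel_times[seq_len(n_steps)],
            labels = events$class[keep], channels = rec$channels,
            class = c("feature_tensor", "array"))
}

#' Preprocess a high-density recording for connectivity analysis
#'
#' Band-pass filters with a 4th-order non-causal (forward-backward)
#' Butterworth between 1 and 50 Hz, decimates to 512 Hz, and re-references
#' to the common average of the retained channels. Channels flagged noisy
#' are dropped before re-referencing.
#'
#' @param rec an [eeg_recording]; `fs` must be an integer multiple of 512.
#' @param noisy character vector of channels to exclude (manual detection).
#' @param f_lo,f_hi band edges in Hz.
#' @return The preprocessed [eeg_recording] at 512 Hz, reference `"CAR"`.
#' @export
preprocess_hd <- function(rec, noisy = character(), f_lo = 1, f_hi = 50) {
  stopifnot(inherits(rec, "eeg_recording"))
  fac <- rec$fs / 512
  if (abs(fac - round(fac)) > 1e-9 || fac < 1) {
    stop("fs must be an integer multiple of 512 Hz (got ", rec$fs, ")")
  }
  fac <- as.integer(round(fac))
  noisy <- toupper(noisy)
  keep <- !(rec$channels %in% noisy)
  if (!any(keep)) stop("all channels flagged noisy")
  x <- rec$samples[keep, , drop = FALSE]
  bf <- signal::butter(4, c(f_lo, f_hi) / (rec$fs / 2), type = "pass")
  filt <- t(apply(x, 1, function(v) signal::filtfilt(bf, v)))
  dec <- filt[, seq(1, ncol(filt), by = fac), drop = FALSE]
  dec <- sweep(dec, 2, colMeans(dec))
  eeg_recording(dec, fs = 512, channels = rec$channels[keep],
                lesion_side = rec$lesion_side, reference = "CAR")
}

#' Flip a montage so the lesioned hemisphere is on the left
#'
#' For recordings with a right-hemisphere lesion, the data of homologous
#' left/right channel pairs (odd/even 10/20 indices) are exchanged; midline
#' channels are untouched. Left-lesion recordings pass through unchanged.
#' Applying the flip twice restores the original recording.
#'
#' @param rec an [eeg_recording].
#' @return The hemisphere-aligned [eeg_recording].
#' @export
flip_montage <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$lesion_side == "left") return(rec)
  pairs <- homologous_pairs(rec$channels)
  out <- rec
  for (i in seq_len(nrow(pairs))) {
    li <- match(pairs$left[i], rec$channels)
    ri <- match(pairs$right[i], rec$channels)
    out$samples[li, ] <- rec$samples[ri, ]
    out$samples[ri, ] <- rec$samples[li, ]
  }
  out$flipped <- !isTRUE(rec$flipped)
  out
}
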