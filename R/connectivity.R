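#' Build MVAR coefficient matrices from a directed coupling graph
#'
#' Each channel follows an oscillatory AR(2) (poles at radius `rho` and
#' frequency `osc_freq`); a graph edge `(from, to, strength)` adds a lag-1
#' cross-coefficient `A1[to, from] = strength`.
#'
#' @param graph data frame with columns `from`, `to`, `strength`.
#' @param channels channel labels of the process (superset of the graph's).
#' @param fs sampling rate (Hz).
#' @param rho,osc_freq pole radius and oscillation frequency of the
#'   per-channel dynamics.
#' @return List with `A` (array `k x k x 2`) and `channels`.
#' @keywords internal
mvar_from_graph <- function(graph, channels, fs, rho = 0.85, osc_freq = 11) {
  channels <- toupper(channels)
  k <- length(channels)
  A <- array(0, c(k, k, 2), dimnames = list(channels, channels, NULL))
  diag(A[, , 1]) <- 2 * rho * cos(2 * pi * osc_freq / fs)
  diag(A[, , 2]) <- -rho^2
  for (i in seq_len(nrow(graph))) {
    from <- toupper(graph$from[i]); to <- toupper(graph$to[i])
    if (!(from %in% channels) || !(to %in% channels)) {
      stop("coupling edge refers to unknown channel: ", from, " -> ", to)
    }
    A[to, from, 1] <- A[to, from, 1] + graph$strength[i]
  }
  list(A = A, channels = channels)
}

# spectral radius of the MVAR companion matrix
companion_radius <- function(A) {
  k <- dim(A)[1]; p <- dim(A)[3]
  C <- matrix(0, k * p, k * p)
  for (l in seq_len(p)) C[seq_len(k), (l - 1) * k + seq_len(k)] <- A[, , l]
  if (p > 1) {
    C[(k + 1):(k * p), seq_len(k * (p - 1))] <- diag(k * (p - 1))
  }
  max(Mod(eigen(C, only.values = TRUE)$values))
}

# simulate a stationary MVAR with Gaussian innovations
simulate_mvar <- function(A, n, innov_sd = 1, burn = 200) {
  k <- dim(A)[1]; p <- dim(A)[3]
  nt <- n + burn
  x <- matrix(0, k, nt)
  e <- matrix(stats::rnorm(k * nt, 0, innov_sd), k, nt)
  for (t in (p + 1):nt) {
    acc <- e[, t]
    for (l in seq_len(p)) acc <- acc + A[, , l] %*% x[, t - l]
    x[, t] <- acc
  }
  out <- x[, (burn + 1):nt, drop = FALSE]
  rownames(out) <- dimnames(A)[[1]]
  out
}

# time-varying simulation of a whole trial ensemble at once: coefficients
# switch to A_active where active[t]; returns array k x n x n_trials
simulate_mvar_switch <- function(A_base, A_active, n, burn, active,
                                 innov_sd = 1, n_trials = 1) {
  k <- dim(A_base)[1]; p <- dim(A_base)[3]
  nt <- n + burn
  act <- c(rep(FALSE, burn), active)
  x <- array(0, c(k, n_trials, nt))
  e <- array(stats::rnorm(k * n_trials * nt, 0, innov_sd), c(k, n_trials, nt))
  for (t in (p + 1):nt) {
    A <- if (act[t]) A_active else A_base
    acc <- e[, , t, drop = FALSE]
    dim(acc) <- c(k, n_trials)
    for (l in seq_len(p)) acc <- acc + A[, , l] %*% x[, , t - l]
    x[, , t] <- acc
  }
  out <- aperm(x[, , (burn + 1):nt, drop = FALSE], c(1, 3, 2))
  dimnames(out) <- list(dimnames(A_base)[[1]], NULL, NULL)
  out
}

#' Fit a multivariate autoregressive model over a trial ensemble
#'
#' Pools the lagged regressors of all trials (no cross-trial continuity) and
#' solves the least-squares problem jointly, which is what makes short-window
#' estimates possible: the effective sample size is `n_trials x window`.
#' Ill-conditioned normal equations fall back to a small ridge penalty.
#'
#' @param trials list of channel x time matrices, or an array
#'   channel x time x trial, sharing window alignment.
#' @param p model order.
#' @return An `mvar_model`: `A` (array `k x k x p`), `sigma` (innovation
#'   covariance), `p`, `channels`, `residuals`, `ridge` (0 when unused).
#' @export
fit_mvar <- function(trials, p) {
  if (is.array(trials) && length(dim(trials)) == 3L) {
    trials <- lapply(seq_len(dim(trials)[3]), function(i) trials[, , i])
  }
  stopifnot(is.list(trials), length(trials) >= 1, p >= 1)
  k <- nrow(trials[[1]])
  channels <- rownames(trials[[1]])
  if (is.null(channels)) channels <- paste0("ch", seq_len(k))
  n_tot <- sum(vapply(trials, ncol, 1L))
  if (n_tot < 10 * p * k) {
    stop("too few samples for a stable fit: need >= ", 10 * p * k,
         " pooled samples, got ", n_tot)
  }
  Xs <- list(); Ys <- list()
  for (tr in trials) {
    T_ <- ncol(tr)
    if (T_ <= p) next
    idx <- (p + 1):T_
    Ys[[length(Ys) + 1L]] <- t(tr[, idx, drop = FALSE])
    X <- matrix(0, length(idx), k * p)
    for (l in seq_len(p)) {
      X[, (l - 1) * k + seq_len(k)] <- t(tr[, idx - l, drop = FALSE])
    }
    Xs[[length(Xs) + 1L]] <- X
  }
  X <- do.call(rbind, Xs); Y <- do.call(rbind, Ys)
  XtX <- crossprod(X)
  ridge <- 0
  kappa_ <- kappa(XtX, exact = FALSE)
  if (!is.finite(kappa_) || kappa_ > 1e12) {
    ridge <- 1e-8 * mean(diag(XtX))
    message("ill-conditioned MVAR normal equations; ridge lambda = ",
            format(ridge))
  }
  B <- solve(XtX + diag(ridge, ncol(X)), crossprod(X, Y))
  res <- Y - X %*% B
  dof <- max(nrow(X) - ncol(X), 1L)
  sigma <- crossprod(res) / dof
  A <- array(0, c(k, k, p), dimnames = list(channels, channels, NULL))
  for (l in seq_len(p)) A[, , l] <- t(B[(l - 1) * k + seq_len(k), , drop = FALSE])
  structure(list(A = A, sigma = sigma, p = p, channels = channels,
                 residuals = res, ridge = ridge, n_obs = nrow(X)),
            class = "mvar_model")
}

#' Select the MVAR order by the Schwarz (Bayesian) criterion
#'
#' @param trials as in [fit_mvar()].
#' @param p_grid candidate orders.
#' @return The order minimising `log det(Sigma) + log(N) p k^2 / N`.
#' @export
select_order <- function(trials, p_grid = 3:12) {
  sbc <- vapply(p_grid, function(p) {
    m <- fit_mvar(trials, p)
    k <- length(m$channels)
    n <- m$n_obs
    determinant(m$sigma, logarithm = TRUE)$modulus + log(n) * p * k^2 / n
  }, 1)
  p_grid[which.min(sbc)]
}

#' Spectral transfer matrix and cross-spectrum of an MVAR model
#'
#' `H(f) = (I - sum_k A_k e^(-i 2 pi f k / fs))^-1` and
#' `S(f) = H(f) Sigma_w H(f)*`.
#'
#' @param model an `mvar_model`.
#' @param freqs frequencies (Hz) at which to evaluate.
#' @param fs sampling rate (Hz) of the data the model was fit on.
#' @return A `spectral_matrices` list: `H`, `S` (complex arrays
#'   `k x k x n_freq`), `freqs`, `channels`.
#' @export
spectral_transfer <- function(model, freqs, fs) {
  if (!inherits(model, "mvar_model")) stop("`model` must be an mvar_model")
  k <- length(model$channels); p <- model$p
  H <- array(complex(real = 0), c(k, k, length(freqs)),
             dimnames = list(model$channels, model$channels, NULL))
  S <- H; Abar <- H
  I_k <- diag(k) + 0i
  for (fi in seq_along(freqs)) {
    Af <- I_k
    for (l in seq_len(p)) {
      Af <- Af - model$A[, , l] * exp(-2i * pi * freqs[fi] * l / fs)
    }
    Hf <- tryCatch(solve(Af), error = function(e) {
      stop("singular spectral matrix at f = ", freqs[fi], " Hz")
    })
    H[, , fi] <- Hf
    S[, , fi] <- Hf %*% model$sigma %*% Conj(t(Hf))
    Abar[, , fi] <- Af
  }
  structure(list(H = H, S = S, Abar = Abar,
                 sigma_inv = tryCatch(solve(model$sigma),
                                      error = function(e) NULL),
                 freqs = freqs, fs = fs, channels = model$channels),
            class = "spectral_matrices")
}

#' Short-time direct directed transfer function (single window)
#'
#' Combines the full-frequency DTF `eta` (transfer magnitudes normalised
#' per target over all sources *and* frequencies, so that
#' `sum_(source, f) eta^2 = 1` per target) with the partial coherence `chi`
#' (computed from the inverse cross-spectrum, suppressing indirect cascade
#' paths): `delta_ij(f) = eta_ij(f) chi_ij(f)`, quantifying direct flow from
#' source `j` to target `i`.
#'
#' @param spec a `spectral_matrices` object.
#' @param loading diagonal loading factor (times `trace(S)/k`) applied before
#'   inverting `S` for the partial coherence.
#' @return A `connectivity_tensor`: array `[target, source, freq]` of `delta`
#'   values with attributes `eta`, `chi`, `freqs`, `referenced = FALSE`.
#' @export
sddtf <- function(spec, loading = 1e-10) {
  if (!inherits(spec, "spectral_matrices")) {
    stop("`spec` must come from spectral_transfer()")
  }
  k <- length(spec$channels); nf <- length(spec$freqs)
  absH2 <- abs(spec$H)^2
  denom <- sqrt(apply(absH2, 1, sum))            # per target, over sources+freqs
  eta <- absH2
  for (i in seq_len(k)) {
    eta[i, , ] <- sqrt(matrix(absH2[i, , ], k, nf)) / denom[i]
  }
  chi <- array(0, dim(eta))
  clamp_count <- 0L
  diag_idx <- seq(1, k * k, by = k + 1)
  # inverse cross-spectrum: directly as Abar^H Sigma^-1 Abar when the MVAR
  # factorisation is available (exact and well conditioned), otherwise by
  # inverting S with a small diagonal loading
  use_factor <- !is.null(spec$Abar) && !is.null(spec$sigma_inv)
  for (fi in seq_len(nf)) {
    if (use_factor) {
      Af <- spec$Abar[, , fi]
      P <- Conj(t(Af)) %*% spec$sigma_inv %*% Af
    } else {
      Sf <- spec$S[, , fi]
      lam <- loading * Re(sum(Sf[diag_idx])) / k
      P <- solve(Sf + diag(lam, k))
    }
    d <- Re(P[diag_idx])
    chi2 <- abs(P)^2 / outer(d, d)
    neg <- chi2 < 0
    if (any(neg)) {
      chi2[neg] <- 0
      clamp_count <- clamp_count + sum(neg)
    }
    chi[, , fi] <- sqrt(chi2)
  }
  if (clamp_count > 0) {
    warning(clamp_count, " negative partial-coherence value(s) clamped to 0")
  }
  delta <- eta * chi
  dimnames(delta) <- list(spec$channels, spec$channels, NULL)
  structure(delta, eta = eta, chi = chi, freqs = spec$freqs,
            channels = spec$channels, referenced = FALSE,
            class = c("connectivity_tensor", "array"))
}

#' Sliding-window SdDTF over a trial ensemble
#'
#' Fits one multi-trial MVAR per window (1-s windows overlapping 0.8 s by
#' default, i.e. a 200-ms step) and stacks the per-window SdDTF values.
#' Window timestamps are window centres.
#'
#' @param trials array channel x time x trial (epochs sharing alignment).
#' @param times vector of epoch times in seconds (relative to the cue).
#' @param fs sampling rate (Hz).
#' @param p MVAR order, or `"auto"` for Schwarz-criterion selection on the
#'   full-epoch ensemble (selected once and held fixed across windows).
#' @param freqs frequency grid (Hz); default 2-48 Hz in 2-Hz steps.
#' @param window_s,overlap_s window length and overlap in seconds.
#' @param min_trials minimum ensemble size.
#' @return A `connectivity_tensor`: array `[target, source, freq, window]`
#'   with attributes `freqs`, `window_centers`, `referenced = FALSE`.
#' @export
sddtf_sliding <- function(trials, times, fs, p = "auto",
                          freqs = seq(2, 48, by = 2),
                          window_s = 1.0, overlap_s = 0.8, min_trials = 5) {
  stopifnot(length(dim(trials)) == 3L, dim(trials)[2] == length(times))
  if (dim(trials)[3] < min_trials) {
    stop("need at least ", min_trials, " trials, got ", dim(trials)[3])
  }
  step_s <- window_s - overlap_s
  win_len <- round(window_s * fs)
  n_t <- dim(trials)[2]
  # window starts on the time grid (floor((T - window)/step) + 1 windows)
  n_win <- floor((n_t / fs - window_s) / step_s + 1e-9) + 1
  if (n_win < 1) stop("epoch shorter than one window")
  starts <- round((seq_len(n_win) - 1) * step_s * fs) + 1L
  starts <- starts[starts + win_len - 1L <= n_t]
  if (identical(p, "auto")) {
    p <- select_order(trials, p_grid = 3:12)
  }
  k <- dim(trials)[1]
  n_tr <- dim(trials)[3]
  channels <- dimnames(trials)[[1]]
  if (is.null(channels)) channels <- paste0("ch", seq_len(k))
  # one lagged design over the whole epoch; every window is a row subset
  t_idx <- (p + 1):n_t
  Y <- matrix(aperm(trials[, t_idx, , drop = FALSE], c(2, 3, 1)),
              length(t_idx) * n_tr, k)
  X <- matrix(0, length(t_idx) * n_tr, k * p)
  for (l in seq_len(p)) {
    X[, (l - 1) * k + seq_len(k)] <-
      matrix(aperm(trials[, t_idx - l, , drop = FALSE], c(2, 3, 1)),
             length(t_idx) * n_tr, k)
  }
  row_time <- rep(t_idx, times = n_tr)   # epoch sample of each design row
  out <- array(0, c(k, k, length(freqs), length(starts)))
  centers <- numeric(length(starts))
  for (w in seq_along(starts)) {
    idx <- starts[w]:(starts[w] + win_len - 1L)
    rows <- row_time >= starts[w] + p & row_time <= starts[w] + win_len - 1L
    Xw <- X[rows, , drop = FALSE]; Yw <- Y[rows, , drop = FALSE]
    XtX <- crossprod(Xw)
    B <- tryCatch(solve(XtX, crossprod(Xw, Yw)), error = function(e) {
      lam <- 1e-8 * mean(diag(XtX))
      message("ill-conditioned window ", w, "; ridge lambda = ", format(lam))
      solve(XtX + diag(lam, ncol(Xw)), crossprod(Xw, Yw))
    })
    resid <- Yw - Xw %*% B
    sigma <- crossprod(resid) / max(nrow(Xw) - ncol(Xw), 1L)
    A <- array(0, c(k, k, p), dimnames = list(channels, channels, NULL))
    for (l in seq_len(p)) A[, , l] <- t(B[(l - 1) * k + seq_len(k), , drop = FALSE])
    m <- structure(list(A = A, sigma = sigma, p = p, channels = channels),
                   class = "mvar_model")
    ct <- sddtf(spectral_transfer(m, freqs, fs))
    out[, , , w] <- ct
    centers[w] <- mean(times[idx])
  }
  dimnames(out) <- list(dimnames(trials)[[1]], dimnames(trials)[[1]],
                        NULL, NULL)
  structure(out, freqs = freqs, window_centers = centers, p = p,
            channels = dimnames(trials)[[1]], referenced = FALSE,
            class = c("connectivity_tensor", "array"))
}

#' Baseline-reference a sliding-window connectivity tensor
#'
#' Subtracts, per (target, source, frequency), the mean over baseline
#' windows from the mean over analysis windows (window membership by window
#' centre). The result is a single cue-locked modulation value per edge and
#' frequency.
#'
#' @param tensor 4-d `connectivity_tensor` from [sddtf_sliding()].
#' @param baseline,analysis time intervals in seconds relative to the cue.
#' @return 3-d `connectivity_tensor` `[target, source, freq]` with
#'   `referenced = TRUE`.
#' @export
baseline_reference <- function(tensor, baseline = c(-3.5, -1),
                               analysis = c(0, 2.5)) {
  stopifnot(inherits(tensor, "connectivity_tensor"))
  if (isTRUE(attr(tensor, "referenced"))) {
    stop("tensor is already baseline-referenced")
  }
  centers <- attr(tensor, "window_centers")
  if (is.null(centers)) stop("tensor carries no window timestamps")
  in_base <- centers >= baseline[1] & centers <= baseline[2]
  in_ana <- centers >= analysis[1] & centers <= analysis[2]
  if (!any(in_base)) stop("no window centre falls in the baseline interval")
  if (!any(in_ana)) stop("no window centre falls in the analysis interval")
  ref <- apply(tensor[, , , in_ana, drop = FALSE], c(1, 2, 3), mean) -
    apply(tensor[, , , in_base, drop = FALSE], c(1, 2, 3), mean)
  dimnames(ref) <- dimnames(tensor)[1:3]
  structure(ref, freqs = attr(tensor, "freqs"),
            channels = attr(tensor, "channels"), referenced = TRUE,
            class = c("connectivity_tensor", "array"))
}

#' Average connectivity over regions of interest and frequency bands
#'
#' Within-ROI values average the ordered channel pairs `i != j` inside the
#' ROI; between-ROI values `A->B` average over sources in A and targets in
#' B. Band values average the frequency bins falling inside the band.
#'
#' @param tensor 3-d `connectivity_tensor` (typically baseline-referenced).
#' @param rois named list of channel vectors.
#' @param bands named list of `c(lo, hi)` frequency ranges in Hz; defaults
#'   to mu (10-12 Hz) and beta (18-24 Hz).
#' @param exclude character vector of channels removed as noisy; their pairs
#'   are excluded (counts are reported in a message).
#' @return Data frame `roi`, `band`, `value` with one row per
#'   (ROI-or-ROI-pair, band). Within-ROI rows are named `"within:<roi>"`,
#'   between rows `"<A>-><B>"`.
#' @export
roi_average <- function(tensor, rois, bands = list(mu = c(10, 12),
                                                   beta = c(18, 24)),
                        exclude = character()) {
  stopifnot(inherits(tensor, "connectivity_tensor"),
            length(dim(tensor)) == 3L)
  channels <- attr(tensor, "channels")
  freqs <- attr(tensor, "freqs")
  exclude <- toupper(exclude)
  rois <- lapply(rois, function(r) {
    r <- toupper(r)
    missing <- setdiff(r, channels)
    if (length(missing)) stop("ROI channel(s) absent: ",
                              paste(missing, collapse = ", "))
    kept <- setdiff(r, exclude)
    if (length(kept) < length(r)) {
      message(length(r) - length(kept), " ROI channel(s) excluded as noisy")
    }
    kept
  })
  rows <- list()
  add <- function(label, sources, targets, within) {
    for (b in names(bands)) {
      fb <- freqs >= bands[[b]][1] & freqs <= bands[[b]][2]
      si <- match(sources, channels); ti <- match(targets, channels)
      sub <- tensor[ti, si, fb, drop = FALSE]
      if (within) {
        keep <- outer(targets, sources, "!=")
        vals <- apply(sub, 3, function(m) mean(m[keep]))
      } else {
        vals <- apply(sub, 3, mean)
      }
      rows[[length(rows) + 1L]] <<- data.frame(
        roi = label, band = b, value = mean(vals))
    }
  }
  for (a in names(rois)) {
    add(paste0("within:", a), rois[[a]], rois[[a]], within = TRUE)
  }
  for (a in names(rois)) for (b in names(rois)) {
    if (a != b) add(paste0(a, "->", b), rois[[a]], rois[[b]], within = FALSE)
  }
  do.call(rbind, rows)
}
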