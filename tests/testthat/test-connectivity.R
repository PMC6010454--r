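ar_model <- function(A, sigma = NULL) {
  k <- dim(A)[1]
  if (is.null(sigma)) sigma <- diag(k)
  structure(list(A = A, sigma = sigma, p = dim(A)[3],
                 channels = dimnames(A)[[1]] %||% paste0("ch", seq_len(k))),
            class = "mvar_model")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("multi-trial MVAR fit recovers known coefficients", {
  set.seed(10)
  A <- array(0, c(3, 3, 2))
  A[, , 1] <- matrix(c(0.5, 0, 0, 0.4, 0.4, 0, 0, 0.4, 0.3), 3, byrow = TRUE)
  A[, , 2] <- diag(-0.2, 3)
  trials <- lapply(1:100, function(i) bcifes:::simulate_mvar(A, 512))
  fit <- fit_mvar(trials, 2)
  expect_lt(max(abs(fit$A - A)), 0.05)
  # residuals pass a whiteness check on every channel
  for (ch in 1:3) {
    expect_gt(Box.test(fit$residuals[, ch], lag = 20, type = "Ljung-Box")$p.value,
              0.01)
  }
})

test_that("independent white noise yields near-zero cross-coefficients", {
  set.seed(11)
  trials <- lapply(1:50, function(i) matrix(rnorm(3 * 256), 3))
  fit <- fit_mvar(trials, 2)
  off <- fit$A
  for (l in 1:2) diag(off[, , l]) <- 0
  expect_lt(max(abs(off)), 0.05)
  expect_error(fit_mvar(trials[1], 20), "too few samples")
})

test_that("spectral transfer matches closed forms", {
  # order zero: H = I at every frequency
  A0 <- array(0, c(2, 2, 0))
  m0 <- structure(list(A = A0, sigma = diag(2), p = 0,
                       channels = c("A", "B")), class = "mvar_model")
  sp0 <- spectral_transfer(m0, c(1, 7, 31), 128)
  for (fi in 1:3) {
    expect_equal(Re(sp0$H[, , fi]), diag(2), tolerance = 1e-14,
                 ignore_attr = TRUE)
  }

  # univariate AR(1), a = 0.5: S(f) = 1 / |1 - 0.5 e^(-i 2 pi f / fs)|^2
  A1 <- array(0.5, c(1, 1, 1)); dimnames(A1) <- list("X", "X", NULL)
  sp1 <- spectral_transfer(ar_model(A1, matrix(1)), seq(2, 40, 2), 128)
  closed <- sapply(seq(2, 40, 2),
                   function(f) 1 / abs(1 - 0.5 * exp(-2i * pi * f / 128))^2)
  expect_equal(as.numeric(Re(sp1$S[1, 1, ])), closed, tolerance = 1e-12)

  # diagonal coefficients -> diagonal H
  Ad <- array(0, c(3, 3, 2))
  Ad[, , 1] <- diag(c(0.4, 0.5, 0.6)); Ad[, , 2] <- diag(-0.3, 3)
  spd <- spectral_transfer(ar_model(Ad), c(4, 10), 128)
  offdiag <- abs(spd$H)
  for (fi in 1:2) diag(offdiag[, , fi]) <- 0
  expect_lt(max(offdiag), 1e-14)
})

test_that("SdDTF of decoupled channels is exactly zero off-diagonal", {
  Ad <- array(0, c(2, 2, 1))
  Ad[, , 1] <- diag(c(0.5, -0.3))
  ct <- sddtf(spectral_transfer(ar_model(Ad), seq(2, 40, 2), 128))
  expect_lt(max(abs(ct[1, 2, ]), abs(ct[2, 1, ])), 1e-10)
})

test_that("ffDTF normalization holds to 1e-10 on estimated fits", {
  set.seed(12)
  g <- data.frame(from = "A", to = "B", strength = 0.4)
  ab <- bcifes:::mvar_from_graph(g, c("A", "B", "C"), fs = 128)
  trials <- lapply(1:30, function(i) bcifes:::simulate_mvar(ab$A, 128))
  ct <- sddtf(spectral_transfer(fit_mvar(trials, 3), seq(2, 48, 2), 128))
  eta <- attr(ct, "eta")
  expect_lt(max(abs(apply(eta^2, 1, sum) - 1)), 1e-10)
})

test_that("partial coherence suppresses the indirect edge of a chain", {
  set.seed(13)
  g <- data.frame(from = c("A", "B"), to = c("B", "C"), strength = 0.5)
  ab <- bcifes:::mvar_from_graph(g, c("A", "B", "C"), fs = 128)
  trials <- lapply(1:60, function(i) bcifes:::simulate_mvar(ab$A, 256))
  ct <- sddtf(spectral_transfer(fit_mvar(trials, 3), seq(2, 48, 2), 128))
  eta <- attr(ct, "eta")   # non-partialized ffDTF: the oracle
  ratio_indirect <- mean(ct["C", "A", ]) / mean(eta[3, 1, ])
  ratio_direct <- mean(ct["B", "A", ]) / mean(eta[2, 1, ])
  expect_lt(ratio_indirect, 0.5)
  expect_gt(ratio_direct, ratio_indirect * 2)
  expect_gt(mean(ct["B", "A", ]), 5 * mean(ct["C", "A", ]))
})

test_that("SdDTF is equivariant under channel permutation", {
  set.seed(14)
  g <- data.frame(from = "A", to = "B", strength = 0.4)
  ab <- bcifes:::mvar_from_graph(g, c("A", "B", "C"), fs = 128)
  X <- lapply(1:20, function(i) bcifes:::simulate_mvar(ab$A, 256))
  perm <- c(3, 1, 2)
  Xp <- lapply(X, function(m) m[perm, ])
  ct <- sddtf(spectral_transfer(fit_mvar(X, 2), seq(4, 40, 4), 128))
  ctp <- sddtf(spectral_transfer(fit_mvar(Xp, 2), seq(4, 40, 4), 128))
  expect_equal(ctp[dimnames(ct)[[1]], dimnames(ct)[[2]], ],
               ct[, , ], tolerance = 1e-8)
})

test_that("sliding windows: count arithmetic and stationarity", {
  set.seed(15)
  fs <- 160
  g <- data.frame(from = "A", to = "B", strength = 0.4)
  ab <- bcifes:::mvar_from_graph(g, c("A", "B", "C"), fs = fs)
  n <- 6 * fs
  arr <- array(0, c(3, n, 15), dimnames = list(c("A", "B", "C"), NULL, NULL))
  for (i in 1:15) arr[, , i] <- bcifes:::simulate_mvar(ab$A, n)
  times <- seq(-3.5, 2.5 - 1 / fs, by = 1 / fs)
  ct <- sddtf_sliding(arr, times, fs, p = 3)
  # 6-s epoch, 1-s window, 0.8-s overlap -> floor((6-1)/0.2) + 1 = 26
  expect_equal(dim(ct)[4], 26)
  expect_equal(length(attr(ct, "window_centers")), 26)
  # stationary process: window-to-window variation stays small
  edge <- apply(ct["B", "A", attr(ct, "freqs") >= 8 &
                   attr(ct, "freqs") <= 14, ], 2, mean)
  expect_lt(sd(edge) / mean(edge), 0.3)
  expect_error(sddtf_sliding(arr[, , 1:2], times, fs, p = 3), "trials")
  # each window equals the explicit fit_mvar + sddtf route
  w_start <- 1 + 5 * round(0.2 * fs)   # window 6
  ens <- arr[, w_start:(w_start + fs - 1), ]
  ref <- sddtf(spectral_transfer(fit_mvar(ens, 3), attr(ct, "freqs"), fs))
  expect_equal(unname(ct[, , , 6]), unname(as.array(ref)[, , ]),
               tolerance = 1e-8)
})

test_that("baseline referencing is centred, detects changes, and guards", {
  set.seed(16)
  fs <- 128
  cfg0 <- sim_config(seed = 21, fs = fs, group = "bci", coupling_change = 1,
                     coupling_graph = data.frame(from = "C5", to = "C3",
                                                 strength = 0.35))
  # stationary: modulation 0 -> referenced values near zero
  ses0 <- gen_resting_session(cfg0, "pre", n_trials = 15, mod = 0)
  ct0 <- sddtf_sliding(ses0$trials, ses0$times, fs, p = 3)
  ref0 <- baseline_reference(ct0)
  expect_lt(abs(mean(ref0)), 2 * sd(ref0) / sqrt(length(ref0)) + 0.005)
  # injected post-cue coupling increase -> positive value on the true edge
  ses1 <- gen_resting_session(cfg0, "pre", n_trials = 15, mod = 0.8)
  ct1 <- sddtf_sliding(ses1$trials, ses1$times, fs, p = 3)
  ref1 <- baseline_reference(ct1)
  mu <- attr(ref1, "freqs") >= 10 & attr(ref1, "freqs") <= 12
  expect_gt(mean(ref1["C3", "C5", mu]), 0)
  # double referencing is refused; empty interval is refused
  expect_error(baseline_reference(ref1), "already")
  expect_error(baseline_reference(ct1, baseline = c(-9, -8)), "baseline")
})

test_that("ROI averaging: pair combinatorics and uniform tensors", {
  k <- 6
  channels <- c("C5", "C3", "C1", "C2", "C4", "C6")
  freqs <- seq(2, 48, 2)
  arr <- array(0.3, c(k, k, length(freqs)),
               dimnames = list(channels, channels, NULL))
  tens <- structure(arr, freqs = freqs, channels = channels,
                    referenced = TRUE,
                    class = c("connectivity_tensor", "array"))
  rois <- list(aff = c("C5", "C3", "C1"), unaff = c("C2", "C4", "C6"))
  out <- roi_average(tens, rois)
  expect_true(all(abs(out$value - 0.3) < 1e-12))   # diagonal excluded
  # distinct diagonal must not leak into within-ROI averages
  for (f in seq_along(freqs)) diag(arr[, , f]) <- 99
  tens2 <- structure(arr, freqs = freqs, channels = channels,
                     referenced = TRUE,
                     class = c("connectivity_tensor", "array"))
  out2 <- roi_average(tens2, rois)
  w <- out2$value[out2$roi == "within:aff" & out2$band == "mu"]
  expect_equal(w, 0.3, tolerance = 1e-12)          # 6 ordered pairs only
  # noisy-channel exclusion drops that channel's pairs
  expect_message(out3 <- roi_average(tens2, rois, exclude = "C5"), "excluded")
  expect_equal(out3$value[out3$roi == "within:aff" & out3$band == "mu"], 0.3,
               tolerance = 1e-12)
  expect_error(roi_average(tens2, list(bad = c("C5", "ZZ"))), "absent")
})

test_that("order selection picks a plausible order for a known process", {
  set.seed(17)
  g <- data.frame(from = "A", to = "B", strength = 0.4)
  ab <- bcifes:::mvar_from_graph(g, c("A", "B"), fs = 128)
  trials <- lapply(1:40, function(i) bcifes:::simulate_mvar(ab$A, 256))
  p_hat <- select_order(trials, p_grid = 1:6)
  expect_true(p_hat >= 2 && p_hat <= 4)   # true order 2
})
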