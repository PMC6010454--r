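#' Decoder-FES contingency table of a therapy log
#'
#' Per trial, the last PSD sample at or before FES onset (or the final
#' active-period sample when no FES was delivered) is classified as
#' "attempt" if its attempt posterior is at least 0.5. Cells: TP = attempt
#' sample with FES, FP = rest sample with FES, FN = attempt sample without
#' FES, TN = rest sample without FES, expressed as percentages of the
#' trials. In closed-loop (bci) logs FP is structurally zero, because FES
#' follows only an attempt-evidence crossing.
#'
#' @param logs a `trial_log` (see [gen_therapy_course()]); per-step
#'   posteriors must be present.
#' @param offset time offset in seconds added to the FES onset before
#'   picking the classified sample (0 = at onset; negative/positive values
#'   probe contingency before/after delivery).
#' @return A `contingency_table` list: `TP`, `TN`, `FP`, `FN` (percent),
#'   `n_trials`, `n_excluded`.
#' @export
build_contingency <- function(logs, offset = 0) {
  stopifnot(inherits(logs, "trial_log"))
  cells <- c(TP = 0, TN = 0, FP = 0, FN = 0)
  n_used <- 0L; n_excl <- 0L
  for (i in seq_len(nrow(logs))) {
    post <- logs$posterior[[i]]
    times <- logs$step_times[[i]]
    if (!length(post)) {
      n_excl <- n_excl + 1L
      next
    }
    t_fes <- logs$t_fes[i]
    idx <- if (!is.na(t_fes)) {
      cand <- which(times <= t_fes + offset)
      if (!length(cand)) 1L else max(cand)
    } else {
      length(post)
    }
    sample_attempt <- post[idx] >= 0.5
    fes <- !is.na(t_fes)
    cell <- if (sample_attempt && fes) "TP" else if (!sample_attempt && fes)
      "FP" else if (sample_attempt && !fes) "FN" else "TN"
    cells[cell] <- cells[cell] + 1
    n_used <- n_used + 1L
  }
  if (n_excl > 0) {
    message(n_excl, " trial(s) without posterior trace excluded")
  }
  if (n_used == 0L) stop("no usable trials")
  out <- as.list(100 * cells / n_used)
  out$n_trials <- n_used
  out$n_excluded <- n_excl
  structure(out, class = "contingency_table")
}

#' Standard metrics of a contingency table
#'
#' `TPR = TP/(TP+FN)`, `TNR = TN/(TN+FP)`, `PPV = TP/(TP+FP)`,
#' `NPV = TN/(TN+FN)`, `Accuracy = (TP+TN)/(TP+TN+FP+FN)`. Ratios with a
#' zero denominator are reported as `NA`, never imputed.
#'
#' @param table a `contingency_table` (cells must sum to 100 +- 0.5).
#' @return A `contingency_metrics` list of the five ratios in `[0, 1]`.
#' @export
compute_metrics <- function(table) {
  cells <- c(table$TP, table$TN, table$FP, table$FN)
  if (any(cells < 0)) stop("negative contingency cell")
  if (abs(sum(cells) - 100) > 0.5) {
    stop("cells must sum to 100% (got ", round(sum(cells), 2), ")")
  }
  rate <- function(num, den) if (den <= 0) NA_real_ else num / den
  structure(list(
    TPR = rate(table$TP, table$TP + table$FN),
    TNR = rate(table$TN, table$TN + table$FP),
    PPV = rate(table$TP, table$TP + table$FP),
    NPV = rate(table$TN, table$TN + table$FN),
    Accuracy = sum(cells[1:2]) / sum(cells)
  ), class = "contingency_metrics")
}

# internal: leave-one-out cross-validated r^2 of a linear model
loocv_r2 <- function(X, y) {
  n <- length(y)
  pred <- numeric(n)
  X <- as.matrix(X)
  for (i in seq_len(n)) {
    fit <- stats::lm.fit(cbind(1, X[-i, , drop = FALSE]), y[-i])
    pred[i] <- sum(c(1, X[i, ]) * fit$coefficients)
  }
  1 - sum((y - pred)^2) / sum((y - mean(y))^2)
}

#' Leave-one-out regression of recovery on contingency cells
#'
#' Fits `dFMA = w1 TP + w2 TN + w3 FP + w4 FN` by ordinary least squares.
#' Because the four cells sum to 100%, FN is dropped from the design matrix
#' (with an intercept) and the weights of the full form are recovered by
#' back-substitution (`w4 = intercept/100`, `wi = bi + w4`). The reported
#' explained variance is leave-one-out cross-validated:
#' `r2 = 1 - SS_pred / SS_tot` over held-out predictions (it can be
#' negative).
#'
#' @param cells data frame with columns `TP`, `TN`, `FP`, `FN` (percent),
#'   one row per patient.
#' @param dfma per-patient FMA-UE change (post minus pre).
#' @return A `contingency_regression` list: `weights` (w1..w4), `r2`
#'   (LOOCV), `r2_insample`, `n`, `note`.
#' @export
loocv_regression <- function(cells, dfma) {
  n <- length(dfma)
  if (n < 5) stop("need at least 5 patients")
  stopifnot(nrow(cells) == n, all(c("TP", "TN", "FP", "FN") %in% names(cells)))
  X <- as.matrix(cells[, c("TP", "TN", "FP")])
  fit <- stats::lm.fit(cbind(1, X), dfma)
  b <- fit$coefficients
  w4 <- b[1] / 100
  weights <- c(TP = unname(b[2] + w4), TN = unname(b[3] + w4),
               FP = unname(b[4] + w4), FN = unname(w4))
  r2_in <- 1 - sum(fit$residuals^2) / sum((dfma - mean(dfma))^2)
  structure(list(
    weights = weights,
    r2 = loocv_r2(X, dfma),
    r2_insample = r2_in,
    n = n,
    note = "FN dropped from the design (cells sum to 100%); full weights by back-substitution"
  ), class = "contingency_regression")
}

#' Leave-one-out explained variance of an accuracy-only model
#'
#' The single-predictor benchmark `dFMA ~ Accuracy`, cross-validated the
#' same way as [loocv_regression()].
#'
#' @param accuracy per-patient contingency accuracy.
#' @param dfma per-patient FMA-UE change.
#' @return LOOCV `r^2`.
#' @export
loocv_accuracy_r2 <- function(accuracy, dfma) {
  loocv_r2(matrix(accuracy, ncol = 1), dfma)
}

#' Single-sample detection rate of a therapy log
#'
#' Fraction of all active-period posterior samples classified as movement
#' attempt (posterior >= 0.5; ties count as attempt). `NA` when no samples
#' are available.
#'
#' @param logs a `trial_log`.
#' @return Fraction in `[0, 1]`, or `NA`.
#' @export
single_sample_rate <- function(logs) {
  stopifnot(inherits(logs, "trial_log"))
  post <- unlist(logs$posterior)
  if (!length(post)) return(NA_real_)
  mean(post >= 0.5)
}
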