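#' Statistical result container
#'
#' Uniform return type of the clinical battery: a named statistic, its
#' value, degrees of freedom, p-value, confidence bounds and correction tag.
#'
#' @param statistic name of the statistic ("F", "t", "W", "V", "r", "OR",
#'   "d", "D", ...).
#' @param value numeric value.
#' @param df degrees of freedom (scalar or length-2).
#' @param p p-value.
#' @param ci length-2 confidence bounds.
#' @param correction `"none"` or `"bonferroni"`.
#' @param note free-text annotation.
#' @return An object of class `stat_result`.
#' @export
stat_result <- function(statistic, value, df = NULL, p = NULL, ci = NULL,
                        correction = "none", note = NULL) {
  if (!is.null(p)) stopifnot(p >= 0, p <= 1)
  structure(list(statistic = statistic, value = value, df = df, p = p,
                 ci = ci, correction = correction, note = note),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s = %.4g", x$statistic, x$value))
  if (!is.null(x$df)) cat(sprintf(" (df = %s)", paste(round(x$df, 2), collapse = ", ")))
  if (!is.null(x$p)) cat(sprintf(", p = %.4g", x$p))
  if (!is.null(x$ci)) cat(sprintf(", 95%% CI [%.4g, %.4g]", x$ci[1], x$ci[2]))
  if (x$correction != "none") cat(" [", x$correction, "-corrected]", sep = "")
  cat("\n")
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

# long clinical table -> wide matrix of one score (rows = patients)
score_wide <- function(table, score, timepoints) {
  sub <- table[table$score == score & table$timepoint %in% timepoints, ]
  if (!nrow(sub)) stop("no rows for score ", score)
  ids <- unique(sub$id)
  wide <- sapply(timepoints, function(tp) {
    s <- sub[sub$timepoint == tp, ]
    s$value[match(ids, s$id)]
  })
  rownames(wide) <- ids
  grp <- sub$group[match(ids, sub$id)]
  list(values = wide, group = grp, ids = ids)
}

#' Mixed-design two-way ANOVA on a clinical score
#'
#' One within-subjects factor (TIME over the requested timepoints) and one
#' between-subjects factor (GROUP). Patients missing any requested timepoint
#' are removed listwise (logged). Sphericity is assumed (as per a Mauchly
#' check at two or three levels); classical univariate F tests are computed
#' via [stats::aov()] with an `Error(id)` stratum.
#'
#' @param table a long `clinical_table` (`id`, `group`, `score`,
#'   `timepoint`, `value`).
#' @param score which score to analyse.
#' @param timepoints within-subject levels, in order.
#' @return A `stat_result` for the TIME x GROUP interaction, with an
#'   `effects` attribute holding the full effect table (GROUP, TIME,
#'   TIME:GROUP).
#' @export
mixed_anova <- function(table, score, timepoints = c("pre", "post")) {
  w <- score_wide(table, score, timepoints)
  complete <- stats::complete.cases(w$values)
  if (sum(!complete) > 0) {
    message(sum(!complete), " patient(s) dropped listwise (missing timepoint)")
  }
  vals <- w$values[complete, , drop = FALSE]
  grp <- factor(w$group[complete])
  if (any(table(grp) < 2)) stop("need >= 2 subjects per group")
  n <- nrow(vals)
  long <- data.frame(
    id = factor(rep(rownames(vals), times = length(timepoints))),
    group = factor(rep(as.character(grp), times = length(timepoints))),
    time = factor(rep(timepoints, each = n), levels = timepoints),
    value = as.numeric(vals)
  )
  fit <- stats::aov(value ~ group * time + Error(id), data = long)
  sm <- summary(fit)
  between <- sm[["Error: id"]][[1]]
  within <- sm[["Error: Within"]][[1]]
  eff <- rbind(
    data.frame(effect = "GROUP", F = between["group", "F value"],
               df1 = between["group", "Df"],
               df2 = between["Residuals", "Df"],
               p = between["group", "Pr(>F)"]),
    data.frame(effect = "TIME", F = within["time", "F value"],
               df1 = within["time", "Df"], df2 = within["Residuals", "Df"],
               p = within["time", "Pr(>F)"]),
    data.frame(effect = "TIME:GROUP", F = within["group:time", "F value"],
               df1 = within["group:time", "Df"],
               df2 = within["Residuals", "Df"],
               p = within["group:time", "Pr(>F)"])
  )
  res <- stat_result("F", eff$F[3], df = c(eff$df1[3], eff$df2[3]),
                     p = eff$p[3],
                     note = sprintf("TIME x GROUP interaction, %s over (%s); sphericity assumed; n = %d",
                                    score, paste(timepoints, collapse = ", "), n))
  attr(res, "effects") <- eff
  res
}

#' Wilcoxon rank-sum / signed-rank tests with Bonferroni correction
#'
#' Exact null distributions are used for n <= 25 without ties; the
#' tie-corrected normal approximation (with continuity correction)
#' otherwise. All-zero paired differences give p = 1 with a note.
#'
#' @param x,y numeric samples (`y` omitted or paired partner).
#' @param paired signed-rank (TRUE) or rank-sum (FALSE).
#' @param bonferroni_m number of post-hoc comparisons in the family; the
#'   reported `p` is multiplied by `m` (capped at 1).
#' @return A `stat_result` (`W` for rank-sum, `V` for signed-rank).
#' @export
wilcoxon_battery <- function(x, y = NULL, paired = FALSE, bonferroni_m = 1) {
  if (length(x) < 3 || (!is.null(y) && length(y) < 3)) {
    stop("need n >= 3 per sample")
  }
  if (paired && !is.null(y)) {
    d <- x - y
    if (all(d == 0)) {
      return(stat_result("V", 0, p = 1,
                         correction = if (bonferroni_m > 1) "bonferroni" else "none",
                         note = "all paired differences zero"))
    }
  }
  n_eff <- if (paired) sum((x - y) != 0) else length(x) + length(y)
  exact_ok <- n_eff <= 25
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, paired = paired, exact = exact_ok,
                       correct = TRUE)
  )
  p <- min(1, wt$p.value * bonferroni_m)
  stat_result(names(wt$statistic), unname(wt$statistic), p = p,
              correction = if (bonferroni_m > 1) "bonferroni" else "none",
              note = if (exact_ok) "exact where untied" else "normal approximation")
}

#' Odds ratio with a Woolf (log-normal) confidence interval
#'
#' `OR = (a d) / (b c)` for the 2 x 2 table `[[a, b], [c, d]]`; the 95%
#' interval is `exp(ln OR +- z sqrt(1/a + 1/b + 1/c + 1/d))`. Zero cells
#' receive the Haldane 0.5 correction (flagged). A Fisher exact p-value
#' accompanies the estimate.
#'
#' @param counts 2 x 2 integer matrix (e.g. responders/non-responders by
#'   group).
#' @param conf confidence level.
#' @return A `stat_result` with `value` = OR, `ci`, and Fisher `p`.
#' @export
odds_ratio <- function(counts, conf = 0.95) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2, 2)), all(counts >= 0))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("empty margin in 2x2 table")
  }
  note <- NULL
  cc <- counts
  if (any(cc == 0)) {
    cc <- cc + 0.5
    note <- "Haldane 0.5 correction applied (zero cell)"
  }
  or <- (cc[1, 1] * cc[2, 2]) / (cc[1, 2] * cc[2, 1])
  se <- sqrt(sum(1 / cc))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- exp(log(or) + c(-1, 1) * z * se)
  p <- stats::fisher.test(round(counts))$p.value
  stat_result("OR", or, p = p, ci = ci, note = note)
}

#' Pearson correlation with t-distribution p-value
#'
#' `t = r sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom,
#' two-sided.
#'
#' @param x,y numeric vectors.
#' @return A `stat_result` with `value` = r, `df`, `p` and the Fisher-z CI.
#' @export
pearson_corr <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need n >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  stat_result("r", unname(ct$estimate), df = unname(ct$parameter),
              p = ct$p.value,
              ci = if (!is.null(ct$conf.int)) as.numeric(ct$conf.int))
}

#' Cohen's d with pooled standard deviation
#'
#' `d = (mean_x - mean_y) / s_p` with
#' `s_p = sqrt(((n_x - 1) s_x^2 + (n_y - 1) s_y^2) / (n_x + n_y - 2))`.
#'
#' @param x,y numeric samples (n >= 2 each).
#' @return A `stat_result` with `value` = d.
#' @export
effect_size_d <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) stop("need n >= 2 per group")
  sp <- sqrt(((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
               (length(x) + length(y) - 2))
  stat_result("d", (mean(x) - mean(y)) / sp)
}

#' Group descriptives of a clinical score
#'
#' Mean, standard deviation, minimum and maximum of one score at one
#' timepoint within one group, with missing values removed; values print at
#' one decimal place.
#'
#' @param table a long `clinical_table`.
#' @param group,score,timepoint selectors.
#' @return List `mean`, `sd`, `min`, `max`, `n`.
#' @export
descriptives <- function(table, group, score, timepoint) {
  v <- table$value[table$group == group & table$score == score &
                     table$timepoint == timepoint]
  v <- v[!is.na(v)]
  if (!length(v)) stop("no observations for the requested cell")
  structure(list(mean = mean(v), sd = stats::sd(v), min = min(v),
                 max = max(v), n = length(v)),
            class = "score_descriptives")
}

#' @export
print.score_descriptives <- function(x, ...) {
  cat(sprintf("%.1f +- %.1f [%g, %g] (n = %d)\n",
              x$mean, x$sd, x$min, x$max, x$n))
  invisible(x)
}

#' Lilliefors-corrected Kolmogorov-Smirnov normality check
#'
#' @param x numeric sample, n >= 4, non-constant (constant input is an
#'   error).
#' @return A `stat_result` with the Lilliefors `D` statistic and p.
#' @export
normality_check <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 4) stop("need n >= 4")
  if (stats::sd(x) == 0) stop("constant sample: normality undefined")
  lt <- nortest::lillie.test(x)
  stat_result("D", unname(lt$statistic), p = lt$p.value)
}

#' Per-patient change scores from a long clinical table
#'
#' @param table a `clinical_table`.
#' @param score score name.
#' @param from,to timepoints; the change is `to - from`. Patients missing
#'   either timepoint get `NA`.
#' @return Data frame `id`, `group`, `delta`.
#' @export
delta_scores <- function(table, score, from = "pre", to = "post") {
  w <- score_wide(table, score, c(from, to))
  data.frame(id = w$ids, group = w$group,
             delta = w$values[, 2] - w$values[, 1])
}

#' Responder counts and odds ratio for clinically relevant recovery
#'
#' Counts patients gaining at least `threshold` points (default: the
#' 5-point FMA-UE minimal clinically important difference) per group and
#' forms the 2 x 2 responders table (rows: bci, sham; columns: responder,
#' non-responder).
#'
#' @param table a `clinical_table` containing `score`.
#' @param score score name.
#' @param threshold responder cut-off in points.
#' @return List `counts` (2 x 2 matrix) and `or` (a `stat_result` from
#'   [odds_ratio()]).
#' @export
fma_responders <- function(table, score = "FMA-UE", threshold = 5) {
  d <- delta_scores(table, score)
  d <- d[!is.na(d$delta), ]
  counts <- rbind(
    bci = c(sum(d$group == "bci" & d$delta >= threshold),
            sum(d$group == "bci" & d$delta < threshold)),
    sham = c(sum(d$group == "sham" & d$delta >= threshold),
             sum(d$group == "sham" & d$delta < threshold))
  )
  colnames(counts) <- c("responder", "non_responder")
  list(counts = counts, or = odds_ratio(counts))
}

#' Run the full clinical battery on a clinical table
#'
#' Reproduces the standard analysis of a two-arm pre/post(/follow-up)
#' trial: mixed ANOVA on the primary score, within- and between-group
#' Wilcoxon tests on the secondary scores, responder odds ratio, effect
#' size, and group descriptives.
#'
#' @param table a long `clinical_table` with at least an `"FMA-UE"` score.
#' @return A tidy data frame: `analysis`, `score`, `statistic`, `value`,
#'   `p`, `ci_lo`, `ci_hi`, `note`.
#' @export
clinical_battery <- function(table) {
  rows <- list()
  push <- function(analysis, score, sr) {
    rows[[length(rows) + 1L]] <<- data.frame(
      analysis = analysis, score = score, statistic = sr$statistic,
      value = sr$value, p = if (is.null(sr$p)) NA_real_ else sr$p,
      ci_lo = if (is.null(sr$ci)) NA_real_ else sr$ci[1],
      ci_hi = if (is.null(sr$ci)) NA_real_ else sr$ci[2],
      note = if (is.null(sr$note)) "" else sr$note
    )
  }
  tps <- intersect(c("pre", "post", "followup"), unique(table$timepoint))
  an <- mixed_anova(table, "FMA-UE", timepoints = tps)
  push("mixed_anova_interaction", "FMA-UE", an)
  d <- delta_scores(table, "FMA-UE")
  d <- d[!is.na(d$delta), ]
  push("effect_size", "FMA-UE",
       effect_size_d(d$delta[d$group == "bci"], d$delta[d$group == "sham"]))
  resp <- fma_responders(table)
  push("responders_odds_ratio", "FMA-UE", resp$or)
  for (sc in setdiff(unique(table$score), "FMA-UE")) {
    ds <- delta_scores(table, sc)
    ds <- ds[!is.na(ds$delta), ]
    if (nrow(ds) < 6) next
    push("between_group_ranksum", sc,
         wilcoxon_battery(ds$delta[ds$group == "bci"],
                          ds$delta[ds$group == "sham"]))
    w <- score_wide(table, sc, c("pre", "post"))
    for (g in c("bci", "sham")) {
      sel <- w$group == g & stats::complete.cases(w$values)
      push(paste0("within_group_signedrank_", g), sc,
           wilcoxon_battery(w$values[sel, 2], w$values[sel, 1],
                            paired = TRUE, bonferroni_m = 2))
    }
  }
  do.call(rbind, rows)
}
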