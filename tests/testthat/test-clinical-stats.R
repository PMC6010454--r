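# hand-computed repeated-measures sums of squares for a 2-group design
manual_mixed_f <- function(values, group, timepoints = colnames(values)) {
  n <- nrow(values); t <- ncol(values)
  grand <- mean(values)
  subj_means <- rowMeans(values)
  grp_levels <- unique(group)
  grp_means <- sapply(grp_levels, function(g) mean(values[group == g, ]))
  time_means <- colMeans(values)
  cell_means <- sapply(seq_len(t), function(j)
    sapply(grp_levels, function(g) mean(values[group == g, j])))
  n_g <- sapply(grp_levels, function(g) sum(group == g))
  ss_group <- t * sum(n_g * (grp_means - grand)^2)
  ss_subj <- t * sum((subj_means - grand)^2)
  ss_time <- n * sum((time_means - grand)^2)
  ss_cells <- sum(sapply(seq_len(t), function(j)
    n_g * (cell_means[, j] - grand)^2))
  ss_int <- ss_cells - ss_group - ss_time
  ss_tot <- sum((values - grand)^2)
  ss_err_within <- ss_tot - ss_subj - ss_time - ss_int
  df_int <- (t - 1) * (length(grp_levels) - 1)
  df_err <- (n - length(grp_levels)) * (t - 1)
  (ss_int / df_int) / (ss_err_within / df_err)
}

test_that("mixed ANOVA interaction F equals hand-computed sums of squares", {
  set.seed(30)
  vals <- matrix(rnorm(12 * 3, mean = 20, sd = 4), 12, 3,
                 dimnames = list(NULL, c("pre", "post", "followup")))
  grp <- rep(c("bci", "sham"), each = 6)
  vals[grp == "bci", 2] <- vals[grp == "bci", 2] + 3
  tab <- toy_clinical_table(vals, grp)
  res <- mixed_anova(tab, "FMA-UE", c("pre", "post", "followup"))
  expect_equal(res$value, manual_mixed_f(vals, grp), tolerance = 1e-10)
  expect_equal(res$df, c(2, 20))

  # tiny balanced design (2 groups x 2 subjects x 3 times)
  vals2 <- matrix(c(1, 2, 3, 2, 3, 4, 1, 1, 1, 2, 2, 3), 4, 3, byrow = TRUE,
                  dimnames = list(NULL, c("pre", "post", "followup")))
  grp2 <- c("bci", "bci", "sham", "sham")
  res2 <- mixed_anova(toy_clinical_table(vals2, grp2), "FMA-UE",
                      c("pre", "post", "followup"))
  expect_equal(res2$value, manual_mixed_f(vals2, grp2), tolerance = 1e-10)
})

test_that("mixed ANOVA null and power behaviour on synthetic groups", {
  # the same set of (distinct) time profiles in both groups: interaction
  # sum of squares exactly zero, subject-by-time variation feeds the error
  prof <- matrix(c(10, 14, 13, 20, 21, 26, 30, 34, 31), 3, byrow = TRUE,
                 dimnames = list(NULL, c("pre", "post", "followup")))
  vals <- rbind(prof, prof + 2)   # constant shift: group effect only
  tab <- toy_clinical_table(vals, rep(c("bci", "sham"), each = 3))
  res <- mixed_anova(tab, "FMA-UE", c("pre", "post", "followup"))
  expect_gt(res$p, 0.5)
  expect_lt(res$value, 1e-10)

  # strong interaction: +10 points post for one group, sd 2, n = 10/group
  set.seed(31)
  v <- matrix(rnorm(20 * 2, 20, 2), 20, 2,
              dimnames = list(NULL, c("pre", "post")))
  g <- rep(c("bci", "sham"), each = 10)
  v[g == "bci", 2] <- v[g == "bci", 2] + 10
  res2 <- mixed_anova(toy_clinical_table(v, g), "FMA-UE", c("pre", "post"))
  expect_lt(res2$p, 0.001)

  # listwise deletion is logged
  v[1, 2] <- NA
  expect_message(mixed_anova(toy_clinical_table(v, g), "FMA-UE",
                             c("pre", "post")), "listwise")
})

test_that("Wilcoxon exact p equals sign-assignment enumeration for n = 5", {
  x <- c(3.1, -0.7, 2.4, 1.6, 0.9)
  y <- rep(0, 5)
  got <- wilcoxon_battery(x, y, paired = TRUE)
  # enumeration oracle over all 2^5 sign assignments of the ranked |d|
  d <- x - y
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), 5))
  v_all <- as.matrix(signs) %*% r
  p_enum <- mean(v_all >= v_obs) * 2
  expect_equal(got$p, min(1, p_enum), tolerance = 1e-12)

  # identical samples: p = 1 with note
  same <- wilcoxon_battery(c(1, 2, 3), c(1, 2, 3), paired = TRUE)
  expect_equal(same$p, 1)
  expect_match(same$note, "zero")
})

test_that("MRC gain is significant for the BCI arm after Bonferroni", {
  t1 <- load_table1()
  w <- subset(t1, score == "MRC" & group == "bci")
  pre <- w$value[w$timepoint == "pre"]
  post <- w$value[w$timepoint == "post"]
  res <- wilcoxon_battery(post, pre, paired = TRUE, bonferroni_m = 2)
  expect_lt(res$p, 0.05)
  expect_equal(res$correction, "bonferroni")
  # sham arm does not reach significance
  ws <- subset(t1, score == "MRC" & group == "sham")
  res_s <- wilcoxon_battery(ws$value[ws$timepoint == "post"],
                            ws$value[ws$timepoint == "pre"],
                            paired = TRUE, bonferroni_m = 2)
  expect_gt(res_s$p, 0.05)
})

test_that("odds ratio and Woolf interval match the closed-form oracle", {
  or <- odds_ratio(rbind(c(8, 6), c(2, 11)))
  expect_equal(or$value, 88 / 12, tolerance = 1e-12)
  se <- sqrt(1 / 8 + 1 / 6 + 1 / 2 + 1 / 11)
  expect_equal(or$ci[2], exp(log(88 / 12) + qnorm(0.975) * se),
               tolerance = 1e-12)
  expect_equal(round(or$value, 2), 7.33)
  expect_equal(round(or$ci, 2), c(1.16, 46.23))

  sym <- odds_ratio(matrix(4, 2, 2))
  expect_equal(sym$value, 1)
  expect_true(sym$ci[1] < 1 && sym$ci[2] > 1)

  hald <- odds_ratio(rbind(c(5, 0), c(2, 7)))
  expect_match(hald$note, "Haldane")
  expect_error(odds_ratio(rbind(c(0, 0), c(2, 7))), "margin")
})

test_that("Pearson p equals the t-distribution CDF oracle", {
  set.seed(33)
  x <- rnorm(24); y <- 0.4 * x + rnorm(24)
  res <- pearson_corr(x, y)
  r <- cor(x, y)
  tstat <- r * sqrt(22) / sqrt(1 - r^2)
  # independent numerical integration of the t density
  p_oracle <- 2 * integrate(function(u) dt(u, 22), abs(tstat), Inf,
                            rel.tol = 1e-12)$value
  expect_equal(res$p, p_oracle, tolerance = 1e-9)
  expect_equal(res$df, 22)

  exact <- pearson_corr(1:10, 2 * (1:10))
  expect_equal(exact$value, 1)
  expect_lt(exact$p, 1e-12)
  x0 <- c(-1, 1, -1, 1); y0 <- c(1, 1, -1, -1)   # constructed orthogonal
  res0 <- pearson_corr(x0, y0)
  expect_equal(res0$value, 0)
  expect_equal(res0$p, 1)
  expect_error(pearson_corr(rep(1, 5), 1:5), "variance")
})

test_that("effect size d: boundary cases and the trial's recovery contrast", {
  expect_equal(effect_size_d(c(1, 2, 3), c(1, 2, 3))$value, 0)
  set.seed(34)
  expect_equal(effect_size_d(rnorm(4000, 1), rnorm(4000, 0))$value, 1,
               tolerance = 0.05)
  t1 <- load_table1()
  d <- delta_scores(t1, "FMA-UE"); d <- d[!is.na(d$delta), ]
  res <- effect_size_d(d$delta[d$group == "bci"], d$delta[d$group == "sham"])
  expect_lt(abs(res$value - 1.03), 0.1)
  expect_error(effect_size_d(1, c(1, 2)), "n >= 2")
})

test_that("Lilliefors check calibrates on Gaussian and flags bimodal data", {
  gauss <- sapply(1:40, function(s) {
    set.seed(s); normality_check(rnorm(100))$p > 0.05
  })
  expect_gte(mean(gauss), 0.9)
  bimod <- sapply(1:40, function(s) {
    set.seed(s)
    normality_check(c(rnorm(25, -4, 0.5), rnorm(25, 4, 0.5)))$p < 0.05
  })
  expect_gte(mean(bimod), 0.9)
  expect_error(normality_check(rep(2, 10)), "constant")
  expect_error(normality_check(c(1, 2, 3)), "n >= 4")
})

test_that("statistics are invariant to patient order", {
  t1 <- load_table1()
  set.seed(35)
  perm <- sample(nrow(t1))
  t1p <- t1[perm, ]
  class(t1p) <- class(t1)
  a <- suppressMessages(mixed_anova(t1, "FMA-UE", c("pre", "post")))
  b <- suppressMessages(mixed_anova(t1p, "FMA-UE", c("pre", "post")))
  expect_equal(a$value, b$value, tolerance = 1e-12)
  da <- delta_scores(t1, "FMA-UE"); db <- delta_scores(t1p, "FMA-UE")
  expect_equal(sort(da$delta), sort(db$delta))
  expect_equal(fma_responders(t1)$or$value, fma_responders(t1p)$or$value)
})

test_that("type-I error of the battery stays nominal on null cohorts", {
  ps <- sapply(1:500, function(s) {
    tab <- suppressMessages(
      gen_clinical_cohort(10, effect = 0, link_slope = 0, noise_sd = 3,
                          seed = 7000 + s))
    d <- attr(tab, "dfma")
    g <- rep(c("bci", "sham"), each = 10)
    t.test(d[g == "bci"], d[g == "sham"], var.equal = TRUE)$p.value
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.02)
})

test_that("descriptives reproduce the printed group summaries", {
  t1 <- load_table1()
  checks <- list(
    list("bci", "FMA-UE", "pre", 21.6, 10.8),
    list("bci", "FMA-UE", "post", 28.3, 14.5),
    list("bci", "FMA-UE", "followup", 28.5, 12.2),
    list("sham", "FMA-UE", "pre", 19.9, 11.2),
    list("sham", "FMA-UE", "post", 22.0, 12.2),
    list("bci", "MRC", "post", 2.6, 1.2),
    list("bci", "ESS", "pre", 66.2, 12.6),
    list("sham", "ESS", "followup", 66.2, 11.0)
  )
  for (ck in checks) {
    ds <- descriptives(t1, ck[[1]], ck[[2]], ck[[3]])
    expect_equal(round(ds$mean, 1), ck[[4]])
    expect_equal(round(ds$sd, 1), ck[[5]])
  }
})
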