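test_that("fit_linear recovers exact fits and validates input", {
  x <- 1:10
  f <- fit_linear(x, 2 * x + 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r_squared, 1)

  # cross-check against stats::lm on noisy data (independent route)
  set.seed(5)
  xx <- rnorm(40); yy <- 0.3 * xx + rnorm(40)
  g <- fit_linear(xx, yy)
  lm_fit <- summary(stats::lm(yy ~ xx))
  expect_equal(g$slope, unname(coef(lm_fit)[2, 1]), tolerance = 1e-12)
  expect_equal(g$r_squared, lm_fit$r.squared, tolerance = 1e-12)
  expect_equal(g$p_value, coef(lm_fit)[2, 4], tolerance = 1e-12)

  expect_error(fit_linear(rep(1, 10), rnorm(10)), "constant")
  expect_error(fit_linear(1:2, 1:2), "at least 3")
})

test_that("anova_oneway matches the classical F test and handles degeneracy", {
  g1 <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  r <- anova_oneway(g1)
  expect_equal(r$f_statistic, 0)
  expect_equal(r$p_value, 1)

  # degenerate: zero within-variance, separated means
  rd <- anova_oneway(list(c(0, 0), c(1, 1)))
  expect_true(is.infinite(rd$f_statistic))
  expect_equal(rd$p_value, 0)
  expect_true(rd$degenerate)

  # oracle: stats::oneway.test with pooled variance on random groups
  set.seed(9)
  vals <- rnorm(60); grp <- factor(rep(1:3, each = 20))
  mine <- anova_oneway(split(vals, grp))
  ref <- stats::oneway.test(vals ~ grp, var.equal = TRUE)
  expect_equal(mine$f_statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)

  expect_error(anova_oneway(list(1:3)), "at least 2 groups")
  expect_error(anova_oneway(list(1:3, 5)), ">= 2 values")
})

test_that("pairwise_t covers all pairs, both variants, and matches a permutation oracle", {
  gs <- list(g1 = c(1, 2, 3, 4), g2 = c(1, 2, 3, 4), g3 = c(10, 11, 12, 13))
  pw <- pairwise_t(gs)
  expect_named(pw, c("g1_vs_g2", "g1_vs_g3", "g2_vs_g3"))
  expect_equal(pw$g1_vs_g2$t_statistic, 0)
  expect_equal(pw$g1_vs_g2$p_value, 1)
  expect_lt(pw$g1_vs_g3$p_value, 1e-4)

  # Welch p approximates the permutation distribution of the Welch statistic
  set.seed(31)
  a <- rnorm(8, 0.3); b <- rnorm(8)
  p_welch <- pairwise_t(list(a = a, b = b))$a_vs_b$p_value
  tobs <- abs(t.test(a, b)$statistic)
  pool <- c(a, b)
  perm <- replicate(4000, {
    idx <- sample(16, 8)
    abs(t.test(pool[idx], pool[-idx])$statistic)
  })
  p_perm <- mean(perm >= tobs)
  expect_lt(abs(p_welch - p_perm), 0.05)

  # pooled variant equals var.equal t.test
  pp <- pairwise_t(list(a = a, b = b), var_equal = TRUE)$a_vs_b
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(pp$p_value, ref$p.value, tolerance = 1e-12)

  # Holm adjustment is monotone and >= raw
  ph <- pairwise_t(gs, adjust = "holm")
  expect_true(all(vapply(ph, function(e) e$p_adjusted >= e$p_value, TRUE)))
})

test_that("roc_curve: separation, direction reversal, tie handling, CI machinery", {
  # perfect separation, lower scores positive
  r <- roc_curve(c(0.7, 0.6, 0.4, 0.5), c(FALSE, FALSE, TRUE, TRUE),
                 direction = "lower_is_positive", ci = "none")
  expect_equal(r$auroc, 1.0)
  cut <- select_cutoff(r)
  expect_gt(cut$threshold, 0.5)
  expect_lte(cut$threshold, 0.6)
  expect_equal(cut$sensitivity, 1.0)
  expect_equal(cut$specificity, 1.0)
  expect_equal(cut$comparison, "<")

  # reversing the direction maps AUROC to 1 - AUROC
  set.seed(2)
  sc <- rnorm(40); lb <- runif(40) > 0.5
  a1 <- roc_curve(sc, lb, "lower_is_positive", ci = "none")$auroc
  a2 <- roc_curve(sc, lb, "higher_is_positive", ci = "none")$auroc
  expect_equal(a1 + a2, 1.0, tolerance = 1e-12)

  # ROC sweep is monotone
  p <- roc_curve(sc, lb, "lower_is_positive", ci = "none")$points
  expect_true(all(diff(p$sensitivity) >= 0))
  expect_true(all(diff(p$specificity) <= 0))

  # all-tied scores: flagged, AUROC 0.5
  rt <- roc_curve(rep(1, 10), rep(c(TRUE, FALSE), 5), ci = "none")
  expect_true(rt$all_tied)
  expect_equal(rt$auroc, 0.5)
  expect_true(select_cutoff(rt)$noninformative)

  expect_error(roc_curve(1:5, rep(TRUE, 5)), "both classes")

  # bootstrap CI: deterministic for a seed, brackets the point estimate here
  rb1 <- roc_curve(sc, lb, ci = "bootstrap", boot_reps = 200, seed = 4)
  rb2 <- roc_curve(sc, lb, ci = "bootstrap", boot_reps = 200, seed = 4)
  expect_identical(rb1$ci95, rb2$ci95)
  expect_true(rb1$ci95[1] <= rb1$auroc && rb1$auroc <= rb1$ci95[2])

  # DeLong CI has positive width and brackets the estimate
  rd <- roc_curve(sc, lb, ci = "delong")
  expect_true(rd$ci95[1] < rd$auroc && rd$auroc < rd$ci95[2])
})

test_that("trapezoid AUROC equals the pairwise Mann-Whitney count (dual route)", {
  set.seed(12)
  for (i in 1:50) {
    n1 <- sample(3:25, 1); n0 <- sample(3:25, 1)
    # integer-ish scores force plenty of ties
    pos <- sample(0:10, n1, replace = TRUE) + rbinom(n1, 1, 0.5) * 0.5
    neg <- sample(0:10, n0, replace = TRUE) + rbinom(n0, 1, 0.5) * 0.5
    lab <- c(rep(TRUE, n1), rep(FALSE, n0))
    r <- roc_curve(c(pos, neg), lab, "lower_is_positive", ci = "none")
    expect_equal(r$auroc, auroc_pairwise(pos, neg, TRUE), tolerance = 1e-12)
    r2 <- roc_curve(c(pos, neg), lab, "higher_is_positive", ci = "none")
    expect_equal(r2$auroc, auroc_pairwise(pos, neg, FALSE), tolerance = 1e-12)
  }
})

test_that("run_grading_analysis produces the full report and validates input", {
  coh <- simulate_cohort(cohort_spec(seed = 4))
  rep <- run_grading_analysis(coh, ci = "none")
  expect_s3_class(rep, "grading_report")
  expect_named(rep$features, c("surface_regularity", "sphericity",
                               "elongation", "flatness"))
  for (f in rep$features) {
    expect_named(f$pairwise, c("g1_vs_g2", "g1_vs_g3", "g2_vs_g3"))
    expect_named(f$roc, c("g1_vs_g3", "g12_vs_g3", "g1_vs_g23"))
    expect_true(f$regression$r_squared >= 0 && f$regression$r_squared <= 1)
    expect_gte(f$anova$f_statistic, 0)
  }
  # grade-1 cutoff calls high values grade 1; grade-3 cutoff calls low values grade 3
  expect_equal(rep$features$surface_regularity$cutoff_grade1$comparison, ">")
  expect_equal(rep$features$surface_regularity$cutoff_grade3$comparison, "<")
  # config echo
  expect_equal(rep$config$ci, "none")
  expect_true(nzchar(rep$package_version))

  tab <- coh$table
  expect_error(run_grading_analysis(tab[setdiff(names(tab), "mitotic_rate")]),
               "mitotic_rate")
  expect_error(run_grading_analysis(tab[tab$who_grade != 3, ]), "absent")
  tiny <- tab[c(1, 63, 134), ]
  expect_error(run_grading_analysis(tiny), "insufficient group sizes")
})

test_that("permuted grade labels behave like a null (few significant pairwise tests)", {
  hits <- 0; total <- 0
  for (seed in 1:10) {
    coh <- simulate_cohort(cohort_spec(seed = seed))$table
    set.seed(seed + 1000)
    coh$who_grade <- sample(coh$who_grade)
    rep <- run_grading_analysis(coh, ci = "none")
    for (f in rep$features) for (pw in f$pairwise) {
      total <- total + 1
      if (pw$p_value < 0.05) hits <- hits + 1
    }
  }
  expect_lte(hits / total, 0.15)   # expected 0.05 under the null
})

test_that("cohort-level regression R^2 sits in the calibrated band on average", {
  r2 <- vapply(1:15, function(s) {
    coh <- simulate_cohort(cohort_spec(seed = s))
    fit_linear(coh$table$mitotic_rate, coh$table$surface_regularity)$r_squared
  }, 1)
  expect_gt(mean(r2), 0.02)
  expect_lt(mean(r2), 0.12)
})
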