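# End-to-end grading analysis of a cohort table: per feature, regression on
# mitotic rate, one-way ANOVA across WHO grades, the three pairwise t-tests,
# three ROC contrasts and operating cutoffs.

.required_cols <- c("case_id", "who_grade", "mitotic_rate", .feature_names)

#' Run the full grading analysis on a cohort
#'
#' For each of the four markers: OLS regression against mitotic rate; one-way
#' ANOVA across WHO grades 1/2/3; pairwise two-tailed t-tests (1 vs 2, 1 vs
#' 3, 2 vs 3); ROC for the contrasts grade 1 vs 3, grades {1,2} vs 3 and
#' grade 1 vs {2,3}; and Youden cutoffs for grade-1 identification (higher
#' marker calls grade 1) and grade-3 identification (lower marker calls
#' grade 3).
#'
#' @param cohort A cohort `data.frame` (or a `cohort` object from
#'   [simulate_cohort()]) with columns `case_id`, `who_grade` (1/2/3),
#'   `mitotic_rate` and the four feature columns.
#' @param features Feature columns to analyze.
#' @param ttest `"welch"` (default) or `"pooled"` pairwise t-test variant.
#' @param adjust Pairwise p-value adjustment, `"none"` (default, raw p) or
#'   `"holm"`.
#' @param ci AUROC CI method: `"bootstrap"`, `"delong"` or `"none"`.
#' @param boot_reps Bootstrap resamples for the AUROC CI.
#' @param seed Seed for the bootstrap CIs.
#' @return A list of class `grading_report`: per-feature results plus the
#'   resolved configuration and package version.
#' @export
run_grading_analysis <- function(cohort, features = .feature_names,
                                 ttest = c("welch", "pooled"),
                                 adjust = c("none", "holm"),
                                 ci = c("bootstrap", "delong", "none"),
                                 boot_reps = 2000L, seed = 1L) {
  ttest <- match.arg(ttest); adjust <- match.arg(adjust); ci <- match.arg(ci)
  if (inherits(cohort, "cohort")) cohort <- cohort$table
  miss <- setdiff(c("case_id", "who_grade", "mitotic_rate", features),
                  names(cohort))
  if (length(miss) > 0)
    stop("cohort is missing required column(s): ", paste(miss, collapse = ", "))
  if (!all(cohort$who_grade %in% 1:3))
    stop("who_grade must be 1, 2 or 3")
  ng <- table(factor(cohort$who_grade, levels = 1:3))
  if (any(ng == 0))
    stop("grade ", paste(names(ng)[ng == 0], collapse = ", "),
         " absent from the cohort")
  if (any(ng < 2)) stop("insufficient group sizes: every grade needs >= 2 cases")
  if (any(cohort$mitotic_rate < 0)) stop("mitotic_rate must be >= 0")

  per_feature <- list()
  for (f in features) {
    v <- cohort[[f]]
    groups <- split(v, factor(cohort$who_grade, levels = 1:3))
    names(groups) <- c("g1", "g2", "g3")

    is3 <- cohort$who_grade == 3
    is1 <- cohort$who_grade == 1
    not2 <- cohort$who_grade != 2
    roc_1v3 <- roc_curve(v[not2], is3[not2],
                         direction = "lower_is_positive", ci = ci,
                         boot_reps = boot_reps, seed = seed)
    roc_12v3 <- roc_curve(v, is3, direction = "lower_is_positive", ci = ci,
                          boot_reps = boot_reps, seed = seed)
    roc_1v23 <- roc_curve(v, is1, direction = "higher_is_positive", ci = ci,
                          boot_reps = boot_reps, seed = seed)

    per_feature[[f]] <- list(
      group_means = vapply(groups, mean, 1),
      group_sd = vapply(groups, sd, 1),
      regression = fit_linear(cohort$mitotic_rate, v),
      anova = anova_oneway(groups),
      pairwise = pairwise_t(groups, var_equal = (ttest == "pooled"),
                            adjust = adjust),
      roc = list(g1_vs_g3 = roc_1v3, g12_vs_g3 = roc_12v3,
                 g1_vs_g23 = roc_1v23),
      cutoff_grade1 = select_cutoff(roc_1v23),
      cutoff_grade3 = select_cutoff(roc_12v3)
    )
  }
  structure(list(
    features = per_feature,
    n_per_grade = as.integer(ng),
    config = list(features = features, ttest = ttest, adjust = adjust,
                  ci = ci, boot_reps = as.integer(boot_reps),
                  seed = as.integer(seed)),
    package_version = as.character(packageVersion("shapegrade"))
  ), class = "grading_report")
}

#' @export
print.grading_report <- function(x, ...) {
  cat("<grading_report> n per grade: ",
      paste(x$n_per_grade, collapse = "/"), "\n", sep = "")
  for (f in names(x$features)) {
    r <- x$features[[f]]
    cat(sprintf("%-19s means %.3f/%.3f/%.3f | ANOVA F=%.1f p=%.2g | R2=%.3f | AUROC 1v3 %.2f, 12v3 %.2f, 1v23 %.2f\n",
                f, r$group_means[1], r$group_means[2], r$group_means[3],
                r$anova$f_statistic, r$anova$p_value,
                r$regression$r_squared,
                r$roc$g1_vs_g3$auroc, r$roc$g12_vs_g3$auroc,
                r$roc$g1_vs_g23$auroc))
  }
  invisible(x)
}

#' Write a grading report as JSON
#'
#' Serializes everything except the per-threshold ROC sweeps, which go to
#' separate CSV files via [write_roc_points()].
#'
#' @param report A `grading_report`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "grading_report"))
  strip <- report
  for (f in names(strip$features)) {
    for (ct in names(strip$features[[f]]$roc)) {
      strip$features[[f]]$roc[[ct]]$points <- NULL
    }
  }
  jsonlite::write_json(unclass(strip), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Write per-contrast ROC sweeps as CSV
#'
#' One `roc_points_<feature>_<contrast>.csv` per feature/contrast pair.
#'
#' @param report A `grading_report`.
#' @param dir Output directory (created if needed).
#' @return The written paths, invisibly.
#' @export
write_roc_points <- function(report, dir) {
  stopifnot(inherits(report, "grading_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (f in names(report$features)) {
    for (ct in names(report$features[[f]]$roc)) {
      p <- file.path(dir, paste0("roc_points_", f, "_", ct, ".csv"))
      write.csv(report$features[[f]]$roc[[ct]]$points, p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
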