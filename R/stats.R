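# Grading statistics: OLS regression of features on mitotic rate, one-way
# ANOVA and pairwise t-tests across WHO grades, ROC/AUROC with bootstrap or
# DeLong confidence intervals, and Youden cutoff selection.

#' Ordinary least-squares regression of a feature on mitotic rate
#'
#' @param x Predictor (mitotic rates), length >= 3, not constant.
#' @param y Response (feature values), same length.
#' @return A list with `slope`, `intercept`, `r_squared`, `p_value`
#'   (two-sided t test of zero slope) and `n`.
#' @export
fit_linear <- function(x, y) {
  x <- as.double(x); y <- as.double(y)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete observations")
  if (var(x) == 0) stop("predictor is constant")
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  res <- y - intercept - slope * x
  ss_res <- sum(res^2); ss_tot <- sum((y - my)^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  se <- sqrt(ss_res / (n - 2) / sxx)
  p <- if (se > 0) 2 * pt(abs(slope / se), df = n - 2, lower.tail = FALSE) else 0
  list(slope = slope, intercept = intercept, r_squared = r2,
       p_value = max(p, .Machine$double.xmin), n = n)
}

#' One-way ANOVA
#'
#' Classical (equal-variance) one-way analysis of variance.
#'
#' If the within-group variance is exactly zero while group means differ, the
#' F statistic is infinite; the result carries `f_statistic = Inf`,
#' `p_value = 0` and `degenerate = TRUE` rather than erroring.
#'
#' @param groups List (>= 2 entries) of numeric vectors, each of length >= 2.
#' @return A list with `f_statistic`, `p_value`, `df` (between, within) and
#'   `degenerate`.
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2L)) stop("each group needs >= 2 values")
  k <- length(groups)
  n <- vapply(groups, length, 1L)
  m <- vapply(groups, mean, 1)
  gm <- sum(n * m) / sum(n)
  ssb <- sum(n * (m - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  df1 <- k - 1L; df2 <- sum(n) - k
  if (ssw == 0) {
    if (ssb == 0) return(list(f_statistic = 0, p_value = 1,
                              df = c(df1, df2), degenerate = FALSE))
    return(list(f_statistic = Inf, p_value = 0,
                df = c(df1, df2), degenerate = TRUE))
  }
  f <- (ssb / df1) / (ssw / df2)
  list(f_statistic = f, p_value = pf(f, df1, df2, lower.tail = FALSE),
       df = c(df1, df2), degenerate = FALSE)
}

#' Pairwise two-tailed t-tests between groups
#'
#' Welch (unequal variance, the default) or pooled two-sample two-tailed
#' t-test for every pair of groups. P-values are raw by default; Holm
#' adjustment is available via `adjust`.
#'
#' @param groups Named list of numeric vectors, each of length >= 2.
#' @param var_equal Use the pooled-variance test instead of Welch.
#' @param adjust `"none"` (raw p, default) or `"holm"`.
#' @return A list, one entry per pair (named `"a_vs_b"`), each with
#'   `groups`, `t_statistic`, `p_value` (and `p_adjusted` if requested).
#' @export
pairwise_t <- function(groups, var_equal = FALSE, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  if (!is.list(groups) || length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2L)) stop("each group needs >= 2 values")
  nm <- names(groups)
  if (is.null(nm)) nm <- as.character(seq_along(groups))
  prs <- utils::combn(seq_along(groups), 2)
  out <- list()
  for (c in seq_len(ncol(prs))) {
    i <- prs[1, c]; j <- prs[2, c]
    a <- groups[[i]]; b <- groups[[j]]
    if (sd(a) == 0 && sd(b) == 0) {
      tt <- list(statistic = c(t = if (mean(a) == mean(b)) 0 else Inf),
                 p.value = if (mean(a) == mean(b)) 1 else 0)
    } else {
      tt <- t.test(a, b, var.equal = var_equal)
    }
    out[[paste0(nm[i], "_vs_", nm[j])]] <-
      list(groups = c(nm[i], nm[j]),
           t_statistic = unname(tt$statistic),
           p_value = tt$p.value)
  }
  if (adjust == "holm") {
    p <- vapply(out, `[[`, 1, "p_value")
    pa <- stats::p.adjust(p, method = "holm")
    for (k in seq_along(out)) out[[k]]$p_adjusted <- unname(pa[k])
  }
  out
}

# trapezoid AUROC over the empirical ROC polyline; with vertices at every
# unique score this equals the Mann-Whitney estimate with ties counted 1/2
.auroc_trapezoid <- function(pos, neg, lower_is_positive) {
  if (!lower_is_positive) { pos <- -pos; neg <- -neg }
  u <- sort(unique(c(pos, neg)))
  tpr <- c(0, vapply(u, function(s) mean(pos <= s), 1))
  fpr <- c(0, vapply(u, function(s) mean(neg <= s), 1))
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' ROC curve and AUROC
#'
#' Sweeps classification thresholds at midpoints between consecutive unique
#' scores. With `direction = "lower_is_positive"` a case is called positive
#' when its score is `<=` the threshold (the convention for shape markers,
#' which decrease with grade). The AUROC is the trapezoid area under the
#' empirical ROC polyline, which equals the Mann-Whitney probability estimate
#' with ties counted 1/2. The 95% CI comes from a stratified bootstrap
#' (default) or DeLong's method; the p-value (AUROC vs 0.5) from the
#' two-sided Mann-Whitney test.
#'
#' @param scores Numeric marker values.
#' @param labels Logical (or 0/1) vector; `TRUE` = positive class.
#' @param direction `"lower_is_positive"` or `"higher_is_positive"`.
#' @param ci `"bootstrap"`, `"delong"` or `"none"`.
#' @param boot_reps Bootstrap resamples (default 2000).
#' @param seed Seed for the bootstrap (local to this call).
#' @return An object of class `roc_result`: `direction`, `points`
#'   (data.frame threshold/sensitivity/specificity), `auroc`, `ci95`,
#'   `p_value`, `n_pos`, `n_neg`, `all_tied`.
#' @export
roc_curve <- function(scores, labels,
                      direction = c("lower_is_positive", "higher_is_positive"),
                      ci = c("bootstrap", "delong", "none"),
                      boot_reps = 2000L, seed = 1L) {
  direction <- match.arg(direction)
  ci <- match.arg(ci)
  labels <- as.logical(labels)
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  if (!any(labels) || all(labels)) stop("both classes must be present")
  pos <- scores[labels]; neg <- scores[!labels]
  lower <- direction == "lower_is_positive"

  all_tied <- length(unique(scores)) == 1L
  u <- sort(unique(scores))
  thr <- if (length(u) > 1)
    c(u[1] - diff(range(u)) * 1e-6, (u[-1] + u[-length(u)]) / 2,
      u[length(u)] + diff(range(u)) * 1e-6)
  else c(u - 1, u + 1)
  sens <- vapply(thr, function(t) if (lower) mean(pos <= t) else mean(pos >= t), 1)
  spec <- vapply(thr, function(t) if (lower) mean(neg > t) else mean(neg < t), 1)
  pts <- data.frame(threshold = thr, sensitivity = sens, specificity = spec)
  if (!lower) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  rownames(pts) <- NULL

  auroc <- if (all_tied) 0.5 else .auroc_trapezoid(pos, neg, lower)
  p <- if (all_tied) 1 else
    suppressWarnings(wilcox.test(pos, neg, exact = FALSE)$p.value)

  ci95 <- c(NA_real_, NA_real_)
  if (!all_tied && ci == "bootstrap") {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
    bs <- vapply(seq_len(boot_reps), function(r) {
      .auroc_trapezoid(sample(pos, replace = TRUE),
                       sample(neg, replace = TRUE), lower)
    }, 1)
    ci95 <- unname(quantile(bs, c(0.025, 0.975), type = 7))
  } else if (!all_tied && ci == "delong") {
    ci95 <- .delong_ci(pos, neg, lower, auroc)
  }
  structure(list(direction = direction, points = pts, auroc = auroc,
                 ci95 = ci95, p_value = p, n_pos = length(pos),
                 n_neg = length(neg), all_tied = all_tied,
                 ci_method = ci),
            class = "roc_result")
}

# DeLong structural-components variance for a single AUROC
.delong_ci <- function(pos, neg, lower, auroc) {
  if (lower) { pos <- -pos; neg <- -neg }  # make higher = positive
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  v10 <- vapply(pos, function(x) mean(psi(x, neg)), 1)
  v01 <- vapply(neg, function(y) mean(psi(pos, y)), 1)
  v <- var(v10) / length(pos) + var(v01) / length(neg)
  se <- sqrt(max(v, 0))
  pmin(pmax(auroc + c(-1, 1) * 1.96 * se, 0), 1)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUROC %.3f (95%% CI %.3f-%.3f, %s), p = %.3g; %d pos / %d neg, %s\n",
              x$auroc, x$ci95[1], x$ci95[2], x$ci_method, x$p_value,
              x$n_pos, x$n_neg, x$direction))
  invisible(x)
}

#' Select an operating cutoff from a ROC curve
#'
#' Maximizes Youden's J = sensitivity + specificity - 1 over the threshold
#' sweep; exact ties are broken toward higher specificity. A flat curve
#' (J = 0 everywhere) is flagged non-informative.
#'
#' @param roc A [roc_curve()] result.
#' @param criterion Selection rule; only `"youden"` is implemented.
#' @return A list with `threshold`, `comparison` (`"<"` when lower scores
#'   call positive, else `">"`), `sensitivity`, `specificity`, `youden_j`,
#'   `criterion` and `noninformative`.
#' @export
select_cutoff <- function(roc, criterion = c("youden")) {
  stopifnot(inherits(roc, "roc_result"))
  criterion <- match.arg(criterion)
  p <- roc$points
  j <- p$sensitivity + p$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[order(p$specificity[best], decreasing = TRUE)][1]
  list(threshold = p$threshold[best],
       comparison = if (roc$direction == "lower_is_positive") "<" else ">",
       sensitivity = p$sensitivity[best],
       specificity = p$specificity[best],
       youden_j = j[best],
       criterion = criterion,
       noninformative = max(j) <= 1e-9)
}
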