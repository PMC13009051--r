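# Synthetic cohorts with the statistical structure the grading analysis
# assumes: three WHO grades with grade-dependent feature means, a right-
# skewed (log-normal) mitotic rate per grade, and a latent per-case
# "irregularity" that couples low shape-feature values to high mitotic rates.
#
# Default calibration (the stated world):
#   n per grade        62 / 71 / 19
#   surface regularity 0.59 / 0.55 / 0.45
#   sphericity         0.69 / 0.63 / 0.55
#   flatness           0.66 / 0.65 / 0.52
#   elongation         0.85 / 0.84 / 0.73
#   mitotic-rate means 0.83 / 2.73 / 24.84
# Within-grade feature SDs are not reported with the means; the defaults
# (0.076, 0.085, 0.099, 0.081) are derived from the reported one-way ANOVA F
# statistics (24.9, 21.7, 15.7, 17.1) at those means and group sizes — see
# the methods vignette for the derivation.

.feature_names <- c("surface_regularity", "sphericity", "elongation", "flatness")

#' Specification of a synthetic grading cohort
#'
#' @param n_per_grade Integer vector `c(n1, n2, n3)` of cases per WHO grade.
#' @param feature_means Named list (one entry per feature in
#'   `surface_regularity`, `sphericity`, `elongation`, `flatness`) of
#'   per-grade target means, each in (0,1).
#' @param feature_sd Named numeric vector of within-grade SDs per feature.
#' @param mitotic_means Per-grade means of the log-normal mitotic rate.
#' @param mitotic_sdlog Log-scale SD of the mitotic rate (scalar or per
#'   grade).
#' @param coupling Correlation strength in `[0, 1]` between the latent
#'   irregularity that drives the features and the log mitotic rate. Note
#'   that the grade structure alone (low features + high mitotic rate in
#'   grade 3) already induces most of the cohort-level feature-mitosis
#'   association; the default 0.15 adds a small within-grade component,
#'   calibrated so the regression of surface regularity on mitotic rate has
#'   mean R^2 near 0.06 at the default n.
#' @param latent_loading Loading of each feature on the shared latent
#'   irregularity (within-grade feature coherence).
#' @param base_radius,spacing,harmonic_degree_max Geometric-mode phantom
#'   parameters (see [perturbed_ball_spec()]).
#' @param eps_means Geometric mode: per-grade mean perturbation amplitude.
#' @param eps_sd Geometric mode: SD of the per-case amplitude.
#' @param stretch_sd Geometric mode: SD of the per-case axis-stretch draws
#'   around the elongation/flatness targets.
#' @param seed Master integer seed; per-case seeds are derived as
#'   `(seed * 100003 + case_index) mod (2^31 - 1)`.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_grade = c(62L, 71L, 19L),
                        feature_means = list(
                          surface_regularity = c(0.59, 0.55, 0.45),
                          sphericity         = c(0.69, 0.63, 0.55),
                          elongation         = c(0.85, 0.84, 0.73),
                          flatness           = c(0.66, 0.65, 0.52)),
                        feature_sd = c(
                          surface_regularity = 0.076,
                          sphericity         = 0.085,
                          elongation         = 0.081,
                          flatness           = 0.099),
                        mitotic_means = c(0.83, 2.73, 24.84),
                        mitotic_sdlog = 1.3,
                        coupling = 0.15,
                        latent_loading = 0.6,
                        base_radius = 15, spacing = 1,
                        harmonic_degree_max = 8,
                        eps_means = c(0.35, 0.45, 0.65),
                        eps_sd = 0.08,
                        stretch_sd = 0.05,
                        seed = 1L) {
  n_per_grade <- as.integer(n_per_grade)
  if (length(n_per_grade) != 3L || any(is.na(n_per_grade)) || any(n_per_grade <= 0L))
    stop("n_per_grade must be three positive integers")
  if (!setequal(names(feature_means), .feature_names))
    stop("feature_means must name exactly: ", paste(.feature_names, collapse = ", "))
  for (f in .feature_names) {
    m <- feature_means[[f]]
    if (length(m) != 3L || any(m <= 0) || any(m >= 1))
      stop("infeasible calibration: means for ", f, " must be three values in (0,1)")
  }
  if (!setequal(names(feature_sd), .feature_names) || any(feature_sd <= 0))
    stop("feature_sd must be positive and named per feature")
  if (length(mitotic_means) != 3L || any(mitotic_means <= 0))
    stop("mitotic_means must be three positive values")
  mitotic_sdlog <- rep_len(as.double(mitotic_sdlog), 3L)
  if (any(mitotic_sdlog <= 0)) stop("mitotic_sdlog must be > 0")
  if (coupling < 0 || coupling > 1) stop("coupling must be in [0, 1]")
  if (latent_loading < 0 || latent_loading > 1) stop("latent_loading must be in [0, 1]")
  if (length(eps_means) != 3L || any(eps_means < 0) || any(eps_means >= 1))
    stop("eps_means must be three values in [0, 1)")
  structure(list(
    n_per_grade = n_per_grade, feature_means = feature_means,
    feature_sd = feature_sd, mitotic_means = mitotic_means,
    mitotic_sdlog = mitotic_sdlog, coupling = coupling,
    latent_loading = latent_loading, base_radius = base_radius,
    spacing = spacing, harmonic_degree_max = as.integer(harmonic_degree_max),
    eps_means = eps_means, eps_sd = eps_sd, stretch_sd = stretch_sd,
    seed = as.integer(seed)), class = "cohort_spec")
}

.case_seed <- function(master, index) {
  as.integer((as.double(master) * 100003 + index) %% 2147483647)
}

# truncated-normal draw on (lo, hi) by rejection (bounded), vectorized length 1
.rtrunc <- function(mean, sd, lo = 0, hi = 1) {
  for (i in 1:200) {
    x <- rnorm(1, mean, sd)
    if (x > lo && x < hi) return(x)
  }
  min(max(mean, lo + 1e-3), hi - 1e-3)
}

#' Simulate a synthetic grading cohort
#'
#' Two modes. `"tabular"` draws the four shape features directly from
#' grade-conditional truncated-normal distributions around the target means,
#' with a shared latent irregularity per case that also raises the (log)
#' mitotic rate — fast, and calibrated so sample means match the targets.
#' `"geometric"` builds an actual perturbed-ball phantom per case (amplitude
#' and axis stretch grade-dependent) and measures the features from the
#' voxel mask, so the whole image pipeline is exercised; its feature means
#' follow the same grade ordering but are not numerically calibrated.
#'
#' Fully deterministic for a fixed `spec$seed` (case-by-case: each case uses
#' a seed derived from the master seed and its index).
#'
#' @param spec A [cohort_spec()].
#' @param mode `"tabular"` or `"geometric"`.
#' @param keep_masks Geometric mode: return the per-case masks.
#' @return A list of class `cohort` with `table` (data.frame: `case_id`,
#'   `who_grade`, `mitotic_rate`, the four features and, in geometric mode,
#'   `volume_mm3`/`surface_mm2`), `masks` (list or NULL), `mode`, `spec`.
#' @export
simulate_cohort <- function(spec = cohort_spec(),
                            mode = c("tabular", "geometric"),
                            keep_masks = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  mode <- match.arg(mode)
  n <- spec$n_per_grade
  grades <- rep(1:3, times = n)
  ntot <- sum(n)
  ids <- sprintf("case_%03d", seq_len(ntot))

  old <- .save_rng(); on.exit(.restore_rng(old))

  rows <- vector("list", ntot)
  masks <- if (mode == "geometric" && keep_masks) vector("list", ntot) else NULL
  for (i in seq_len(ntot)) {
    g <- grades[i]
    set.seed(.case_seed(spec$seed, i))
    z <- rnorm(1)          # latent irregularity (high = irregular)
    w <- rnorm(1)          # independent mitotic noise
    mu_log <- log(spec$mitotic_means[g]) - spec$mitotic_sdlog[g]^2 / 2
    mit <- exp(mu_log + spec$mitotic_sdlog[g] *
                 (spec$coupling * z + sqrt(1 - spec$coupling^2) * w))

    if (mode == "tabular") {
      lam <- spec$latent_loading
      vals <- vapply(.feature_names, function(f) {
        .rtrunc(spec$feature_means[[f]][g] -
                  spec$feature_sd[[f]] * lam * z,
                spec$feature_sd[[f]] * sqrt(1 - lam^2))
      }, numeric(1))
      rows[[i]] <- data.frame(case_id = ids[i], who_grade = g,
                              mitotic_rate = mit, t(vals))
    } else {
      # amplitude driven by the same latent z so that mitotic coupling and
      # surface irregularity agree case by case
      eps <- min(max(spec$eps_means[g] + spec$eps_sd * z, 0), 0.85)
      b <- .rtrunc(spec$feature_means$elongation[g], spec$stretch_sd, 0.3, 1)
      cs <- .rtrunc(spec$feature_means$flatness[g], spec$stretch_sd, 0.2, b)
      rot <- random_rotation()
      pb <- perturbed_ball_spec(base_radius = spec$base_radius,
                                amplitude = eps,
                                harmonic_degree_max = spec$harmonic_degree_max,
                                spacing = spec$spacing,
                                seed = .case_seed(spec$seed, i))
      msk <- .make_stretched_perturbed_ball(pb, stretch = c(1, b, cs),
                                            rotation = rot)
      ft <- compute_features(msk)
      rows[[i]] <- data.frame(case_id = ids[i], who_grade = g,
                              mitotic_rate = mit,
                              surface_regularity = ft$surface_regularity,
                              sphericity = ft$sphericity,
                              elongation = ft$elongation,
                              flatness = ft$flatness,
                              volume_mm3 = ft$volume,
                              surface_mm2 = ft$surface_area)
      if (keep_masks) masks[[i]] <- msk
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, masks = masks, mode = mode, spec = spec),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", nrow(x$table), " cases (",
      paste(x$spec$n_per_grade, collapse = "/"), " per grade), mode ",
      x$mode, "\n", sep = "")
  print(aggregate(x$table[.feature_names],
                  by = list(who_grade = x$table$who_grade), mean))
  invisible(x)
}

# perturbed ball composed with an axis stretch and rotation: a point p is
# foreground iff q = diag(1/stretch) R^T p satisfies |q| <= R0 (1 + eps P(q/|q|))
.make_stretched_perturbed_ball <- function(spec, stretch = c(1, 1, 1),
                                           rotation = diag(3)) {
  stopifnot(inherits(spec, "perturbed_ball_spec"))
  R0 <- spec$base_radius; eps <- spec$amplitude; sp <- spec$spacing
  ax <- .grid_axes(R0 * (1 + eps) * max(stretch), sp)
  g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  q <- sweep(g %*% rotation, 2, stretch, `/`)
  r <- sqrt(rowSums(q^2))
  inside <- r <= R0 * (1 - eps)
  shell <- !inside & r <= R0 * (1 + eps) & r > 0
  if (eps > 0 && any(shell)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(spec$seed)
    lmax <- spec$harmonic_degree_max
    ldeg <- unlist(lapply(1:lmax, function(l) rep(l, 2 * l + 1)))
    coef <- rnorm((lmax + 1L)^2 - 1L) / ldeg
    qs <- q[shell, , drop = FALSE]; rs <- r[shell]
    pert <- drop(.real_sh_basis(qs[, 3] / rs, atan2(qs[, 2], qs[, 1]), lmax) %*% coef)
    pert <- pert / max(abs(pert))
    inside[shell] <- rs <= R0 * (1 + eps * pert)
  }
  vox <- array(inside * 1L, dim = rep(length(ax), 3))
  if (sum(vox) == 0L) stop("perturbation emptied the mask")
  segmentation_mask(vox, spacing = rep(sp, 3), origin = rep(ax[1], 3))
}
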