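# Voxelized phantom lesions with controllable surface irregularity.
#
# The irregular phantom is a star-convex region r(theta, phi) <=
# R0 * (1 + eps * P(theta, phi)) where P is a random band-limited angular
# function: a zero-mean combination of real spherical harmonics up to a
# maximum degree, rescaled to max|P| = 1. Radial perturbation keeps the
# eps = 0 identity with the plain ball exact and makes enclosed volume and
# area smooth in eps, so surface regularity decreases smoothly with eps.

.grid_axes <- function(half_extent, spacing) {
  n <- as.integer(ceiling(half_extent / spacing)) + 2L
  (-n:n) * spacing
}

#' Digital ball phantom
#'
#' Voxelizes a ball: voxel centers within `radius` of the grid center are
#' foreground. The grid carries a 2-voxel background margin and is centered
#' so that `origin` is the physical position of the first voxel center.
#'
#' @param radius Ball radius in mm (>= `spacing`).
#' @param spacing Isotropic voxel spacing in mm.
#' @return A `seg_mask`.
#' @export
make_ball <- function(radius, spacing = 1) {
  if (!is.finite(radius) || radius < spacing)
    stop("radius below resolution: need radius >= spacing")
  ax <- .grid_axes(radius, spacing)
  r2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  segmentation_mask((r2 <= radius^2) * 1L, spacing = rep(spacing, 3),
                    origin = rep(ax[1], 3))
}

#' Digital ellipsoid phantom
#'
#' Voxel centers inside the (optionally rotated) ellipsoid
#' \eqn{(x/a)^2 + (y/b)^2 + (z/c)^2 \le 1} are foreground. Ground truth for
#' elongation (b/a) and flatness (c/a).
#'
#' @param semi_axes Semi-axes `c(a, b, c)` in mm, `a >= b >= c >= spacing`.
#' @param spacing Isotropic voxel spacing in mm.
#' @param rotation 3x3 rotation matrix applied to the ellipsoid (default
#'   identity); see [random_rotation()].
#' @return A `seg_mask`.
#' @export
make_ellipsoid <- function(semi_axes, spacing = 1, rotation = diag(3)) {
  if (length(semi_axes) != 3L || is.unsorted(rev(semi_axes)))
    stop("semi_axes must be c(a, b, c) with a >= b >= c")
  if (semi_axes[3] < spacing) stop("smallest semi-axis below resolution")
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation must be orthonormal")
  ax <- .grid_axes(semi_axes[1], spacing)
  g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  q <- g %*% rotation                       # rotate points into ellipsoid frame
  inside <- (q[, 1] / semi_axes[1])^2 + (q[, 2] / semi_axes[2])^2 +
    (q[, 3] / semi_axes[3])^2 <= 1
  vox <- array(inside * 1L, dim = rep(length(ax), 3))
  segmentation_mask(vox, spacing = rep(spacing, 3), origin = rep(ax[1], 3))
}

#' Uniform random 3D rotation
#'
#' Rotation matrix from a uniformly random unit quaternion.
#'
#' @param seed Optional integer seed (local to this call).
#' @return A 3x3 rotation matrix.
#' @export
random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Specification of a perturbed-ball phantom
#'
#' @param base_radius Unperturbed radius R0 in mm (default 15 mm, a typical
#'   meningioma scale).
#' @param amplitude Relative radial perturbation eps in `[0, 1)`.
#' @param harmonic_degree_max Maximum spherical-harmonic degree of the
#'   angular perturbation (>= 1); higher degrees give finer surface detail.
#' @param spacing Isotropic voxel spacing in mm.
#' @param seed Integer seed; output is deterministic per seed.
#' @return An object of class `perturbed_ball_spec`.
#' @export
perturbed_ball_spec <- function(base_radius = 15, amplitude = 0.3,
                                harmonic_degree_max = 8, spacing = 1,
                                seed = 1L) {
  if (!is.finite(base_radius) || base_radius <= 0) stop("base_radius must be > 0")
  if (!is.finite(amplitude) || amplitude < 0 || amplitude >= 1)
    stop("amplitude must be in [0, 1)")
  if (harmonic_degree_max < 1) stop("harmonic_degree_max must be >= 1")
  if (spacing <= 0) stop("spacing must be > 0")
  structure(list(base_radius = base_radius, amplitude = amplitude,
                 harmonic_degree_max = as.integer(harmonic_degree_max),
                 spacing = spacing, seed = as.integer(seed)),
            class = "perturbed_ball_spec")
}

# Real spherical harmonics (orthonormal, Condon-Shortley phase absorbed) for
# l = 1..lmax evaluated at directions given by cos(theta) and phi.
# Returns a matrix [n_points x n_basis].
.real_sh_basis <- function(costheta, phi, lmax) {
  x <- costheta
  npt <- length(x)
  somx2 <- sqrt(pmax(1 - x^2, 0))
  # associated Legendre P_l^m by standard recurrences, per m
  nb <- (lmax + 1L)^2 - 1L
  out <- matrix(0, npt, nb)
  col <- 0L
  P <- vector("list", lmax + 1L)  # P[[l+1]][[m+1]]
  for (l in 0:lmax) P[[l + 1L]] <- vector("list", l + 1L)
  P[[1L]][[1L]] <- rep(1, npt)
  for (m in 0:lmax) {
    if (m > 0) {
      # P_m^m = (2m-1)!! * somx2^m (Condon-Shortley (-1)^m dropped; sign is
      # irrelevant for a random zero-mean combination)
      P[[m + 1L]][[m + 1L]] <- prod(seq(1, 2 * m - 1, by = 2)) * somx2^m
    }
    if (m < lmax) P[[m + 2L]][[m + 1L]] <- (2 * m + 1) * x * P[[m + 1L]][[m + 1L]]
    if (m + 2L <= lmax) for (l in (m + 2L):lmax) {
      P[[l + 1L]][[m + 1L]] <- ((2 * l - 1) * x * P[[l]][[m + 1L]] -
                                  (l + m - 1) * P[[l - 1L]][[m + 1L]]) / (l - m)
    }
  }
  for (l in 1:lmax) {
    for (m in (-l):l) {
      am <- abs(m)
      nrm <- sqrt((2 * l + 1) / (4 * pi) *
                    exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      plm <- P[[l + 1L]][[am + 1L]]
      col <- col + 1L
      out[, col] <- if (m > 0) sqrt(2) * nrm * plm * cos(m * phi)
      else if (m < 0) sqrt(2) * nrm * plm * sin(am * phi)
      else nrm * plm
    }
  }
  out
}

#' Perturbed-ball phantom with controllable surface irregularity
#'
#' Voxelizes the star-convex region \eqn{r \le R_0 (1 + \varepsilon
#' P(\theta,\phi))} where P is a seeded random combination of real spherical
#' harmonics of degree 1..`harmonic_degree_max` (coefficients N(0,1) damped
#' by 1/l, zero mean over the sphere, rescaled to max |P| = 1 over the
#' evaluated directions). `amplitude = 0` reproduces
#' `make_ball(base_radius, spacing)` exactly.
#'
#' @param spec A [perturbed_ball_spec()].
#' @return A `seg_mask`.
#' @export
make_perturbed_ball <- function(spec) {
  stopifnot(inherits(spec, "perturbed_ball_spec"))
  R0 <- spec$base_radius; eps <- spec$amplitude; sp <- spec$spacing
  if (eps == 0) return(make_ball(R0, sp))
  ax <- .grid_axes(R0 * (1 + eps), sp)
  n <- length(ax)
  g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  r <- sqrt(rowSums(g^2))
  inside <- r <= R0 * (1 - eps)            # trivially inside
  shell <- !inside & r <= R0 * (1 + eps) & r > 0
  if (any(shell)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(spec$seed)
    lmax <- spec$harmonic_degree_max
    ncoef <- (lmax + 1L)^2 - 1L
    ldeg <- unlist(lapply(1:lmax, function(l) rep(l, 2 * l + 1)))
    coef <- rnorm(ncoef) / ldeg
    gs <- g[shell, , drop = FALSE]
    rs <- r[shell]
    pert <- drop(.real_sh_basis(gs[, 3] / rs, atan2(gs[, 2], gs[, 1]), lmax) %*% coef)
    pert <- pert / max(abs(pert))
    inside[shell] <- rs <= R0 * (1 + eps * pert)
  }
  vox <- array(inside * 1L, dim = rep(n, 3))
  if (sum(vox) == 0L) stop("perturbation emptied the mask")
  segmentation_mask(vox, spacing = rep(sp, 3), origin = rep(ax[1], 3))
}
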