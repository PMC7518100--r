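#' Quality metrics and the synthetic phantom generator
#'
#' PSNR and two SSIM variants measure restoration quality against a
#' ground-truth volume.  The phantom generator produces a deterministic
#' piecewise-smooth 3D volume (nested ellipsoids, thin sheets, optional
#' edge smoothing) that stands in for downloadable brain phantoms at
#' desk scale.  It emulates piecewise-constant anatomy with curved
#' boundaries and thin structures; it does not emulate MR texture,
#' bias fields, or anatomical realism.
#'
#' @name evaluation
NULL

#' Peak signal-to-noise ratio
#'
#' `10*log10(MAX^2 / MSE)` in dB, with MSE the voxel-wise mean squared
#' error.  Identical volumes return `Inf`.  `MAX` is a convention: the
#' nominal dynamic range of the ground truth, not of the test volume.
#'
#' @param ref ground-truth array.
#' @param test array of the same shape.
#' @param max_intensity nominal maximum intensity (default `max(ref)`).
#' @return PSNR in dB.
#' @export
psnr <- function(ref, test, max_intensity = max(ref)) {
  if (!identical(dim(ref), dim(test)))
    stop("`ref` and `test` must have identical shapes", call. = FALSE)
  mse <- mean((ref - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(max_intensity^2 / mse)
}

#' Global-moment structural similarity index
#'
#' The single-window form
#' `(2*mu_x*mu_y + c1)*(2*s_x*s_y + c2) /
#'  ((mu_x^2 + mu_y^2 + c1)*(s_x^2 + s_y^2 + c2))`
#' with means and standard deviations taken over the whole volume and
#' the product of standard deviations (not the covariance) in the
#' second factor.  Always `<= 1` (AM-GM), equal to 1 when the global
#' moments agree; being global, it cannot detect spatial scrambling —
#' use [ssim_standard()] for the conventional windowed index.
#'
#' @param ref,test arrays of the same shape.
#' @param max_intensity nominal dynamic range; stabilizers default to
#'   `c1 = (0.01*MAX)^2`, `c2 = (0.03*MAX)^2`.
#' @param c1,c2 positive stabilizing constants.
#' @return similarity in \[-1, 1\].
#' @export
ssim_paper <- function(ref, test, max_intensity = max(ref),
                       c1 = (0.01 * max_intensity)^2,
                       c2 = (0.03 * max_intensity)^2) {
  if (!identical(dim(ref), dim(test)))
    stop("`ref` and `test` must have identical shapes", call. = FALSE)
  if (c1 <= 0 || c2 <= 0) stop("`c1`, `c2` must be positive", call. = FALSE)
  mx <- mean(ref); my <- mean(test)
  sx <- sqrt(mean((ref - mx)^2)); sy <- sqrt(mean((test - my)^2))
  (2 * mx * my + c1) * (2 * sx * sy + c2) /
    ((mx^2 + my^2 + c1) * (sx^2 + sy^2 + c2))
}

# mean filter with a cube window via a banded row-stochastic matrix per axis
.axis_filter <- function(n, radius) {
  k <- outer(seq_len(n), seq_len(n),
             function(i, j) as.numeric(abs(i - j) <= radius))
  k / rowSums(k)
}

.apply_axis <- function(vol, K, axis) {
  d <- dim(vol)
  perm <- c(axis, setdiff(1:3, axis))
  m <- K %*% matrix(aperm(vol, perm), nrow = d[axis])
  aperm(array(m, dim = d[perm]), order(perm))
}

#' Windowed structural similarity index (conventional form)
#'
#' Mean over voxels of the standard SSIM map computed with a cubic
#' moving window (uniform weights, edges renormalized) and the
#' covariance in the cross term.
#'
#' @inheritParams ssim_paper
#' @param window odd cube window edge, default 7.
#' @return mean SSIM over the volume.
#' @export
ssim_standard <- function(ref, test, max_intensity = max(ref),
                          c1 = (0.01 * max_intensity)^2,
                          c2 = (0.03 * max_intensity)^2, window = 7L) {
  if (!identical(dim(ref), dim(test)))
    stop("`ref` and `test` must have identical shapes", call. = FALSE)
  r <- (window - 1L) %/% 2L
  Ks <- lapply(dim(ref), .axis_filter, radius = r)
  sm <- function(v) {
    for (ax in 1:3) v <- .apply_axis(v, Ks[[ax]], ax)
    v
  }
  mx <- sm(ref); my <- sm(test)
  vx <- pmax(sm(ref^2) - mx^2, 0)
  vy <- pmax(sm(test^2) - my^2, 0)
  cxy <- sm(ref * test) - mx * my
  mean((2 * mx * my + c1) * (2 * cxy + c2) /
         ((mx^2 + my^2 + c1) * (vx + vy + c2)))
}

.gauss_filter <- function(n, width) {
  radius <- max(1L, ceiling(3 * width))
  k <- outer(seq_len(n), seq_len(n),
             function(i, j) exp(-(i - j)^2 / (2 * width^2)) *
               (abs(i - j) <= radius))
  k / rowSums(k)
}

#' Synthetic piecewise-smooth 3D phantom
#'
#' Deterministic-for-seed stand-in for a brain phantom: a large "head"
#' ellipsoid containing randomly placed overlapping ellipsoids at the
#' given intensity levels plus two one-voxel-thick sheets, optionally
#' blurred by a separable Gaussian of the given width to emulate
#' partial-volume edges.  With `smoothing_width = 0` the set of voxel
#' values is a subset of `c(0, intensity_levels)`.
#'
#' @param shape integer 3-vector, each `>= 16`; default 64^3.
#' @param n_ellipsoids number of interior ellipsoids, default 6.
#' @param intensity_levels tissue intensity levels; the nominal dynamic
#'   range of the phantom is `max(intensity_levels)`.
#' @param smoothing_width Gaussian edge-smoothing width in voxels
#'   (0 = hard edges).
#' @param seed integer seed; fixed seed gives a bit-identical phantom.
#' @return 3-way numeric array in `[0, max(intensity_levels)]`.
#' @export
make_phantom <- function(shape = c(64, 64, 64), n_ellipsoids = 6,
                         intensity_levels = c(45, 105, 160, 220, 255),
                         smoothing_width = 0.8, seed = 1) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 16L))
    stop("`shape` must be a 3-vector with all dimensions >= 16", call. = FALSE)
  if (any(intensity_levels < 0)) stop("intensities must be >= 0", call. = FALSE)
  .local_seed(seed, {
    g1 <- array(rep(seq_len(shape[1]), times = prod(shape[2:3])), dim = shape)
    g2 <- array(rep(rep(seq_len(shape[2]), each = shape[1]), times = shape[3]),
                dim = shape)
    g3 <- array(rep(seq_len(shape[3]), each = prod(shape[1:2])), dim = shape)
    vol <- array(0, dim = shape)
    ctr <- (shape + 1) / 2
    ax0 <- 0.42 * shape
    head <- ((g1 - ctr[1]) / ax0[1])^2 + ((g2 - ctr[2]) / ax0[2])^2 +
      ((g3 - ctr[3]) / ax0[3])^2 <= 1
    k <- length(intensity_levels)
    vol[head] <- intensity_levels[1]
    for (i in seq_len(n_ellipsoids)) {
      c_i <- ctr + (stats::runif(3) - 0.5) * 0.5 * shape
      a_i <- pmax(2, (0.08 + 0.17 * stats::runif(3)) * shape)
      inside <- ((g1 - c_i[1]) / a_i[1])^2 + ((g2 - c_i[2]) / a_i[2])^2 +
        ((g3 - c_i[3]) / a_i[3])^2 <= 1
      vol[inside & head] <- intensity_levels[(i %% k) + 1]
    }
    # two one-voxel-thick sheets inside the head, to exercise thin structures
    for (sheet in 1:2) {
      axis <- sample.int(3, 1)
      pos <- sample(seq.int(round(shape[axis] * 0.3),
                            round(shape[axis] * 0.7)), 1)
      idx <- list(g1, g2, g3)[[axis]] == pos
      vol[idx & head] <- intensity_levels[k]
    }
    if (smoothing_width > 0) {
      Ks <- lapply(shape, .gauss_filter, width = smoothing_width)
      for (ax in 1:3) vol <- .apply_axis(vol, Ks[[ax]], ax)
      vol <- pmin(pmax(vol, 0), max(intensity_levels))
    }
    vol
  })
}
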