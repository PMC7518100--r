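#' Adaptive multilinear rank shrinkage
#'
#' Core mathematics of the denoiser: the proximal (threshold) operator of
#' the parameterized logarithmic nonconvex penalty
#' `pen(x) = lam * (1/a) * log(1 + a*x)` applied to mode singular values,
#' the adaptive multilinear rank rule (rank = number of singular values
#' surviving the threshold), and the truncated-HOSVD group denoiser.
#'
#' Although the log penalty is nonconvex, the scalar objective
#' `0.5*(y - x)^2 + pen(x)` is strictly convex whenever `0 <= a < 1/lam`,
#' so the threshold operator below is its unique global minimizer.
#'
#' @name shrinkage
NULL

#' Shrinkage parameter bundle
#'
#' @param lam positive threshold.
#' @param a nonconvexity parameter; must satisfy `0 < a < 1/lam` so the
#'   proximal objective stays strictly convex.  Defaults to `0.5/lam`,
#'   which guarantees `a * lam = 0.5 < 1` for any `lam`.
#' @param tau optional record of the universal-threshold constant
#'   `2*log(p^3*m)` the threshold was derived from (diagnostic only).
#' @return Object of class `shrinkage_params`.
#' @export
shrinkage_params <- function(lam, a = 0.5 / lam, tau = NULL) {
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) || lam <= 0)
    stop("`lam` must be a positive number", call. = FALSE)
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("`a` must be a positive number", call. = FALSE)
  if (a >= 1 / lam)
    stop("`a` must satisfy a < 1/lam (strict convexity condition)",
         call. = FALSE)
  structure(list(lam = lam, a = a, tau = tau), class = "shrinkage_params")
}

#' Threshold operator of the logarithmic penalty
#'
#' Closed-form minimizer of `0.5*(y - x)^2 + lam*(1/a)*log(1 + a*|x|)`:
#' zero below the threshold `lam`, and
#' `sign(y) * (|y|/2 - 1/(2a) + sqrt((|y|/2 + 1/(2a))^2 - lam/a))`
#' at or above it.  The two branches meet continuously at `|y| = lam`.
#' Shrinks less than the soft threshold but more than the identity:
#' `max(|y| - lam, 0) <= |log_prox(y)| <= |y|`.
#'
#' @param y numeric vector of observations.
#' @param lam positive threshold.
#' @param a nonconvexity parameter, `0 < a < 1/lam`.
#' @return numeric vector, same length as `y`.
#' @export
log_prox <- function(y, lam, a) {
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) || lam <= 0)
    stop("`lam` must be a positive number", call. = FALSE)
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("`a` must be a positive number", call. = FALSE)
  if (a >= 1 / lam)
    stop("`a` must satisfy a < 1/lam (strict convexity condition)",
         call. = FALSE)
  ay <- abs(y)
  # radicand is (lam/2 - 1/(2a))^2 at |y| = lam and increases with |y|
  rad <- pmax((ay / 2 + 1 / (2 * a))^2 - lam / a, 0)
  out <- sign(y) * (ay / 2 - 1 / (2 * a) + sqrt(rad))
  out[ay < lam] <- 0
  out
}

#' Soft-threshold operator (convex-relaxation baseline)
#'
#' `max(delta - lam, 0)` element-wise; this is both the singular-value
#' thresholding rule of the nuclear-norm relaxation and the `a -> 0`
#' limit of [log_prox()].
#'
#' @param delta nonnegative numeric vector.
#' @param lam nonnegative threshold.
#' @return numeric vector.
#' @export
soft_threshold <- function(delta, lam) {
  if (any(!is.finite(delta)) || !is.finite(lam))
    stop("inputs must be finite", call. = FALSE)
  pmax(delta - lam, 0)
}

#' Shrink a singular-value spectrum and estimate its rank
#'
#' Applies [log_prox()] element-wise to a nonincreasing nonnegative
#' spectrum; the multilinear rank estimate is the count of strictly
#' positive shrunk values, floored at 1 so a group never collapses to
#' the zero tensor (the leading singular vector carries the group mean).
#'
#' @param delta nonincreasing nonnegative numeric vector.
#' @param params a [shrinkage_params()] object.
#' @return list with `values` (shrunk spectrum) and `rank` (integer).
#' @export
shrink_spectrum <- function(delta, params) {
  stopifnot(inherits(params, "shrinkage_params"))
  if (any(delta < 0) || any(!is.finite(delta)))
    stop("`delta` must be finite and nonnegative", call. = FALSE)
  if (is.unsorted(rev(delta), strictly = FALSE))
    stop("`delta` must be sorted in nonincreasing order", call. = FALSE)
  values <- log_prox(delta, params$lam, params$a)
  list(values = values, rank = max(1L, sum(values > 0)))
}

#' Truncated HOSVD of a cube group with adaptive multilinear ranks
#'
#' For each mode n, takes the SVD of the mode-n unfolding, shrinks the
#' singular values with the log-penalty threshold operator, sets the
#' mode rank to the number of survivors (floored at 1), and keeps the
#' first `r_n` left singular vectors.  The core is the projection of the
#' group onto the retained factors.  Shrunk singular values are used
#' only for rank counting; they are never substituted into the
#' reconstruction.
#'
#' @param group 4-way numeric array (p x p x p x m cube stack).
#' @param params a [shrinkage_params()] object.
#' @return `hosvd_factors` object with truncated factors and full
#'   (untruncated) spectra stored for diagnostics.
#' @export
estimate_truncation <- function(group, params) {
  .check_tensor4(group)
  if (!all(is.finite(group))) stop("group has non-finite entries", call. = FALSE)
  stopifnot(inherits(params, "shrinkage_params"))
  dims <- dim(group)
  factors <- vector("list", 4L)
  spectra <- vector("list", 4L)
  ranks <- integer(4L)
  for (n in 1:4) {
    m <- unfold(group, n)
    sv <- svd(m, nu = min(dim(m)), nv = 0)
    d <- sv$d
    if (length(d) < dims[n]) d <- c(d, rep(0, dims[n] - length(d)))
    spectra[[n]] <- d[seq_len(dims[n])]
    r <- shrink_spectrum(spectra[[n]], params)$rank
    r <- min(r, ncol(sv$u))
    factors[[n]] <- .fix_signs(sv$u[, seq_len(r), drop = FALSE])
    ranks[n] <- r
  }
  core <- group
  for (n in 1:4) core <- ttm(core, t(factors[[n]]), n)
  structure(list(core = core, factors = factors, spectra = spectra,
                 ranks = ranks),
            class = "hosvd_factors")
}

#' Denoise one cube group by truncated-core HOSVD
#'
#' Computes the adaptive truncation with [estimate_truncation()] and
#' reconstructs; the result is the orthogonal projection of the group
#' onto the retained multilinear subspace, so
#' `||group||^2 = ||out||^2 + ||group - out||^2`.
#'
#' @inheritParams estimate_truncation
#' @return 4-way array, same shape as `group`.
#' @export
denoise_group <- function(group, params) {
  reconstruct(estimate_truncation(group, params))
}
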