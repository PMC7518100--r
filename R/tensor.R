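#' Tensor algebra primitives for fourth-order tensors
#'
#' The denoiser stacks matched image cubes into fourth-order tensors
#' (p x p x p x m) and factorizes them by higher-order SVD.  This file
#' provides the minimal tensor toolbox: mode-n unfolding and folding,
#' the n-mode matrix product, and the full (untruncated) HOSVD.
#'
#' Unfolding convention: in the mode-n unfolding the rows are indexed by
#' the mode-n index and the columns enumerate the mode-n fibers with the
#' lowest-numbered remaining index varying fastest.  Any consistent
#' convention yields the same singular values and reconstructions; this
#' one is fixed so factor matrices are reproducible bit-for-bit.
#'
#' @name tensor-tools
NULL

.check_tensor4 <- function(x, arg = "x") {
  if (!is.array(x) || length(dim(x)) != 4L)
    stop(sprintf("`%s` must be a 4-way array", arg), call. = FALSE)
  invisible(x)
}

.check_mode <- function(mode) {
  if (length(mode) != 1L || !mode %in% 1:4)
    stop("`mode` must be a single integer in 1..4", call. = FALSE)
  as.integer(mode)
}

#' Mode-n unfolding (matricization) of a fourth-order tensor
#'
#' Rearranges a 4-way array into a matrix whose rows are indexed by the
#' chosen mode and whose columns enumerate the mode-n fibers, with the
#' lowest-numbered remaining index varying fastest.
#'
#' @param x 4-way numeric array.
#' @param mode integer in 1..4.
#' @return A numeric matrix of shape `dim(x)[mode]` by
#'   `prod(dim(x)[-mode])`, with attributes `mode` and `origin_shape`.
#' @examples
#' t4 <- array(rnorm(24), dim = c(2, 3, 2, 2))
#' dim(unfold(t4, 2))  # 3 x 8
#' @export
unfold <- function(x, mode) {
  .check_tensor4(x)
  mode <- .check_mode(mode)
  perm <- c(mode, setdiff(1:4, mode))
  m <- matrix(aperm(x, perm), nrow = dim(x)[mode])
  attr(m, "mode") <- mode
  attr(m, "origin_shape") <- dim(x)
  m
}

#' Fold a mode-n unfolding back into a fourth-order tensor
#'
#' Exact inverse of [unfold()] under the package's fixed column ordering.
#'
#' @param m numeric matrix (a mode-`mode` unfolding).
#' @param mode integer in 1..4.
#' @param shape integer 4-vector, the target tensor shape.
#' @return A 4-way array of dimension `shape`.
#' @export
fold <- function(m, mode, shape) {
  mode <- .check_mode(mode)
  if (!is.matrix(m)) stop("`m` must be a matrix", call. = FALSE)
  shape <- as.integer(shape)
  if (length(shape) != 4L || any(shape < 1L))
    stop("`shape` must be a positive integer 4-vector", call. = FALSE)
  if (nrow(m) != shape[mode] || ncol(m) != prod(shape[-mode]))
    stop(sprintf(
      "matrix of shape (%d, %d) is inconsistent with tensor shape (%s) at mode %d",
      nrow(m), ncol(m), paste(shape, collapse = ","), mode), call. = FALSE)
  perm <- c(mode, setdiff(1:4, mode))
  a <- array(m, dim = shape[perm])
  aperm(a, order(perm))
}

#' n-mode product of a fourth-order tensor with a matrix
#'
#' Multiplies tensor `x` along dimension `mode` by matrix `v` (K x Jn),
#' replacing that dimension by K.  Equivalent to
#' `fold(v %*% unfold(x, mode), ...)`.
#'
#' @param x 4-way numeric array with `dim(x)[mode] == ncol(v)`.
#' @param v numeric matrix.
#' @param mode integer in 1..4.
#' @return 4-way array with dimension `mode` replaced by `nrow(v)`.
#' @export
ttm <- function(x, v, mode) {
  .check_tensor4(x)
  mode <- .check_mode(mode)
  if (!is.matrix(v)) v <- as.matrix(v)
  if (ncol(v) != dim(x)[mode])
    stop(sprintf("matrix has %d columns but tensor mode %d has size %d",
                 ncol(v), mode, dim(x)[mode]), call. = FALSE)
  shape <- dim(x)
  shape[mode] <- nrow(v)
  fold(v %*% unfold(x, mode), mode, shape)
}

#' Fix SVD sign indeterminacy
#'
#' Flips each column of `u` so its largest-magnitude entry is positive
#' (ties broken by lowest row index); applied to factor matrices so that
#' the whole pipeline is reproducible across runs.
#' @noRd
.fix_signs <- function(u) {
  for (j in seq_len(ncol(u))) {
    i <- which.max(abs(u[, j]))
    if (u[i, j] < 0) u[, j] <- -u[, j]
  }
  u
}

#' Full higher-order SVD of a fourth-order tensor
#'
#' Computes, for each mode n, the left singular vectors and singular
#' values of the mode-n unfolding, and the core tensor
#' `S = x ×1 U1' ×2 U2' ×3 U3' ×4 U4'`.  The full-rank reconstruction
#' `S ×1 U1 ×2 U2 ×3 U3 ×4 U4` reproduces `x` up to round-off.
#'
#' @param x 4-way numeric array with finite entries.
#' @return An object of class `hosvd_factors`: a list with elements
#'   `core` (4-way array), `factors` (list of 4 orthonormal matrices),
#'   `spectra` (list of 4 nonincreasing singular-value vectors) and
#'   `ranks` (integer 4-vector of retained column counts).
#' @export
hosvd <- function(x) {
  .check_tensor4(x)
  if (!all(is.finite(x))) stop("tensor has non-finite entries", call. = FALSE)
  dims <- dim(x)
  factors <- vector("list", 4L)
  spectra <- vector("list", 4L)
  for (n in 1:4) {
    m <- unfold(x, n)
    sv <- svd(m, nu = dims[n], nv = 0)
    factors[[n]] <- .fix_signs(sv$u)
    # pad spectrum to Jn when the unfolding is tall in the other direction
    d <- sv$d
    if (length(d) < dims[n]) d <- c(d, rep(0, dims[n] - length(d)))
    spectra[[n]] <- d[seq_len(dims[n])]
  }
  core <- x
  for (n in 1:4) core <- ttm(core, t(factors[[n]]), n)
  structure(list(core = core, factors = factors, spectra = spectra,
                 ranks = dims),
            class = "hosvd_factors")
}

#' Reconstruct a tensor from (possibly truncated) HOSVD factors
#'
#' Applies `core ×1 U1 ×2 U2 ×3 U3 ×4 U4`.  With full factors this is the
#' identity; with truncated factors it is the orthogonal projection of
#' the original tensor onto the retained multilinear subspace.
#'
#' @param f an object of class `hosvd_factors`.
#' @return 4-way array.
#' @export
reconstruct <- function(f) {
  if (!inherits(f, "hosvd_factors"))
    stop("`f` must be an `hosvd_factors` object", call. = FALSE)
  x <- f$core
  for (n in 1:4) x <- ttm(x, f$factors[[n]], n)
  x
}

#' @export
print.hosvd_factors <- function(x, ...) {
  cat("HOSVD factors\n")
  cat("  core:", paste(dim(x$core), collapse = " x "), "\n")
  cat("  ranks:", paste(x$ranks, collapse = ", "), "\n")
  invisible(x)
}
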