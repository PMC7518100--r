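#' Nonlocal cube matching and aggregation
#'
#' Reference cubes of edge `p` are placed on a regular grid over the
#' volume; for each reference, the `m` most similar cubes (squared
#' Euclidean distance over voxels) inside an `L x L x L` search window
#' centred on the reference are stacked into a fourth-order tensor.
#' After group-wise denoising, cubes are aggregated back by uniform
#' averaging of all contributions at each voxel.
#'
#' Corners are 0-based throughout; a cube with corner `c` occupies
#' voxels `[c, c+p)` along each axis.  This file holds the plain R
#' implementation; the full pipeline uses an equivalent compiled path
#' (see [denoise_stabilized()]).
#'
#' @name block-matching
NULL

.check_volume <- function(vol, arg = "vol") {
  if (!is.array(vol) || length(dim(vol)) != 3L)
    stop(sprintf("`%s` must be a 3-way array", arg), call. = FALSE)
  invisible(vol)
}

.axis_positions <- function(dim, p, stride) {
  pos <- seq.int(0L, dim - p, by = stride)
  if (pos[length(pos)] != dim - p) pos <- c(pos, dim - p)
  pos
}

#' Reference-cube corner grid
#'
#' Regular grid with step `stride`, the last position per axis snapped
#' to `dim - p` so the whole volume is covered by reference cubes
#' whenever `stride <= p`.
#'
#' @param shape integer 3-vector (volume dimensions).
#' @param p cube edge length in voxels.
#' @param stride grid step, `>= 1`.
#' @return integer matrix with one 0-based corner per row, rows in
#'   lexicographic order.
#' @export
reference_positions <- function(shape, p, stride) {
  shape <- as.integer(shape)
  if (length(shape) != 3L) stop("`shape` must have length 3", call. = FALSE)
  if (p > min(shape))
    stop("cube edge `p` exceeds a volume dimension", call. = FALSE)
  if (stride < 1L) stop("`stride` must be >= 1", call. = FALSE)
  ax <- lapply(shape, .axis_positions, p = p, stride = stride)
  g <- expand.grid(c3 = ax[[3]], c2 = ax[[2]], c1 = ax[[1]],
                   KEEP.OUT.ATTRS = FALSE)
  out <- as.matrix(g[, c("c1", "c2", "c3")])
  dimnames(out) <- NULL
  storage.mode(out) <- "integer"
  out
}

.cube_at <- function(vol, corner, p) {
  vol[corner[1] + seq_len(p), corner[2] + seq_len(p),
      corner[3] + seq_len(p), drop = FALSE]
}

#' Match similar cubes inside a local search window
#'
#' Candidates are all in-volume corners within `(L-1)/2` of the
#' reference corner per axis (window clipped at borders, no padding).
#' The reference itself is always ranked first; the remaining candidates
#' are ordered by squared-distance with ties broken by lexicographic
#' corner order, and the best `m - 1` are kept.
#'
#' @param vol 3-way numeric array.
#' @param ref_corner integer 3-vector, 0-based corner of the reference.
#' @param p cube edge.
#' @param m maximum number of cubes in the group (including reference).
#' @param L odd search-window edge.
#' @return Object of class `cube_group`: list with `tensor`
#'   (p x p x p x m_eff array, reference in slot 1), `corners`
#'   (m_eff x 3 integer matrix) and `distances`.
#' @export
match_cubes <- function(vol, ref_corner, p, m, L) {
  .check_volume(vol)
  if (L %% 2L != 1L) stop("`L` must be odd", call. = FALSE)
  dims <- dim(vol)
  ref_corner <- as.integer(ref_corner)
  if (any(ref_corner < 0L) || any(ref_corner + p > dims))
    stop("reference cube falls outside the volume", call. = FALSE)
  half <- (L - 1L) %/% 2L
  lo <- pmax(0L, ref_corner - half)
  hi <- pmin(dims - p, ref_corner + half)
  cand <- as.matrix(expand.grid(c3 = lo[3]:hi[3], c2 = lo[2]:hi[2],
                                c1 = lo[1]:hi[1],
                                KEEP.OUT.ATTRS = FALSE))[, 3:1, drop = FALSE]
  ref_cube <- .cube_at(vol, ref_corner, p)
  d <- vapply(seq_len(nrow(cand)), function(i) {
    sum((.cube_at(vol, cand[i, ], p) - ref_cube)^2)
  }, numeric(1))
  is_ref <- cand[, 1] == ref_corner[1] & cand[, 2] == ref_corner[2] &
    cand[, 3] == ref_corner[3]
  others <- which(!is_ref)
  ord <- others[order(d[others], others)]    # stable: ties by lexicographic corner
  keep <- c(which(is_ref), ord)[seq_len(min(m, nrow(cand)))]
  m_eff <- length(keep)
  tensor <- array(0, dim = c(p, p, p, m_eff))
  for (j in seq_len(m_eff)) tensor[, , , j] <- .cube_at(vol, cand[keep[j], ], p)
  structure(list(tensor = tensor,
                 corners = matrix(as.integer(cand[keep, , drop = FALSE]),
                                  ncol = 3),
                 distances = d[keep]),
            class = "cube_group")
}

#' Aggregate denoised cube groups into a volume
#'
#' Each voxel becomes the uniform average of every cube value covering
#' it.  Errors if any voxel receives no contribution (broken stride
#' contract upstream).
#'
#' @param groups list of `cube_group` objects whose `tensor` slots hold
#'   denoised cubes.
#' @param shape integer 3-vector, the output volume dimensions.
#' @return 3-way numeric array.
#' @export
aggregate_groups <- function(groups, shape) {
  shape <- as.integer(shape)
  num <- array(0, dim = shape)
  den <- array(0, dim = shape)
  for (g in groups) {
    p <- dim(g$tensor)[1]
    for (j in seq_len(dim(g$tensor)[4])) {
      i1 <- g$corners[j, 1] + seq_len(p)
      i2 <- g$corners[j, 2] + seq_len(p)
      i3 <- g$corners[j, 3] + seq_len(p)
      num[i1, i2, i3] <- num[i1, i2, i3] + g$tensor[, , , j]
      den[i1, i2, i3] <- den[i1, i2, i3] + 1
    }
  }
  if (any(den == 0))
    stop("some voxels received no cube contribution", call. = FALSE)
  num / den
}
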