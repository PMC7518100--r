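# Independent brute-force oracles used to freeze expected values.
# These deliberately avoid the package's own unfold/fold/ttm code paths.

rand_tensor <- function(dims, seed) {
  set.seed(seed)
  array(rnorm(prod(dims)), dim = dims)
}

# direct evaluation of the n-mode product definition:
# (X x_n V)[j1..k..j4] = sum_{jn} x[j1..jn..j4] * v[k, jn]
oracle_mode_product <- function(x, v, mode) {
  d <- dim(x)
  dn <- d
  dn[mode] <- nrow(v)
  out <- array(0, dim = dn)
  for (j1 in seq_len(dn[1])) for (j2 in seq_len(dn[2]))
    for (j3 in seq_len(dn[3])) for (j4 in seq_len(dn[4])) {
      acc <- 0
      for (jn in seq_len(d[mode])) {
        idx <- c(j1, j2, j3, j4)
        k <- idx[mode]
        idx[mode] <- jn
        acc <- acc + x[idx[1], idx[2], idx[3], idx[4]] * v[k, jn]
      }
      out[j1, j2, j3, j4] <- acc
    }
  out
}

# grid minimization of the scalar proximal objective
# 0.5*(y - x)^2 + lam*(1/a)*log(1 + a*x) over x in [0, y]
oracle_prox_grid <- function(y, lam, a, step = 1e-5) {
  x <- seq(0, y, by = step)
  obj <- 0.5 * (y - x)^2 + (lam / a) * log1p(a * x)
  x[which.min(obj)]
}

# random tensor with exact multilinear rank (r1, r2, r3, r4):
# orthonormal factors applied to a full-rank random core
rand_lowrank_tensor <- function(dims, ranks, seed, scale = 1) {
  set.seed(seed)
  core <- array(rnorm(prod(ranks)), dim = ranks)
  x <- core
  for (n in 1:4) {
    u <- qr.Q(qr(matrix(rnorm(dims[n] * ranks[n]), dims[n], ranks[n])))
    x <- ttm(x, u, n)
  }
  x * scale
}

# smallest nonzero singular value across the four mode unfoldings
min_mode_sv <- function(x, ranks) {
  mn <- Inf
  for (n in 1:4) {
    d <- svd(unfold(x, n), nu = 0, nv = 0)$d
    mn <- min(mn, d[ranks[n]])
  }
  mn
}
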