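test_that("reference_positions tiles exactly and snaps the last position", {
  pos <- reference_positions(c(8, 8, 8), p = 4, stride = 4)
  expect_identical(nrow(pos), 8L)
  expect_setequal(unique(pos[, 1]), c(0L, 4L))

  pos <- reference_positions(c(9, 9, 9), p = 4, stride = 4)
  expect_identical(nrow(pos), 27L)
  expect_setequal(unique(pos[, 1]), c(0L, 4L, 5L))

  expect_error(reference_positions(c(3, 8, 8), p = 4, stride = 2), "exceeds")
})

test_that("every voxel is covered by a reference cube when stride <= p", {
  set.seed(20)
  for (i in 1:5) {
    shape <- sample(7:15, 3, replace = TRUE)
    p <- sample(2:4, 1)
    stride <- sample(seq_len(p), 1)
    pos <- reference_positions(shape, p, stride)
    cov <- array(0L, dim = shape)
    for (r in seq_len(nrow(pos))) {
      i1 <- pos[r, 1] + seq_len(p); i2 <- pos[r, 2] + seq_len(p)
      i3 <- pos[r, 3] + seq_len(p)
      cov[i1, i2, i3] <- cov[i1, i2, i3] + 1L
    }
    expect_true(all(cov >= 1L))
  }
})

test_that("match_cubes is deterministic on constant volumes (lexicographic ties)", {
  vol <- array(7, dim = c(8, 8, 8))
  g <- match_cubes(vol, c(2, 2, 2), p = 2, m = 4, L = 5)
  expect_identical(g$corners[1, ], c(2L, 2L, 2L))   # reference first
  expect_true(all(g$distances[-1] == 0))
  # remaining corners are the lexicographically smallest window corners
  expect_identical(g$corners[2, ], c(0L, 0L, 0L))
  expect_identical(g$corners[3, ], c(0L, 0L, 1L))
  expect_identical(g$corners[4, ], c(0L, 0L, 2L))
})

test_that("a planted duplicate outranks all non-identical cubes", {
  set.seed(21)
  vol <- array(runif(12^3, 0, 10), dim = c(12, 12, 12))
  p <- 3
  ref <- c(4L, 4L, 4L)
  dup <- c(7L, 5L, 2L)
  vol[dup[1] + 1:p, dup[2] + 1:p, dup[3] + 1:p] <-
    vol[ref[1] + 1:p, ref[2] + 1:p, ref[3] + 1:p]
  g <- match_cubes(vol, ref, p = p, m = 3, L = 9)
  expect_identical(g$corners[2, ], dup)
  # brute-force scan of the whole window confirms no closer candidate
  half <- 4
  best <- Inf
  rc <- vol[ref[1] + 1:p, ref[2] + 1:p, ref[3] + 1:p]
  for (c1 in max(0, ref[1] - half):min(12 - p, ref[1] + half))
    for (c2 in max(0, ref[2] - half):min(12 - p, ref[2] + half))
      for (c3 in max(0, ref[3] - half):min(12 - p, ref[3] + half)) {
        if (all(c(c1, c2, c3) == ref) || all(c(c1, c2, c3) == dup)) next
        best <- min(best, sum((vol[c1 + 1:p, c2 + 1:p, c3 + 1:p] - rc)^2))
      }
  expect_gt(best, 0)
})

test_that("match_cubes contracts: m = 1, shift invariance, reference fiber", {
  set.seed(22)
  vol <- array(rnorm(10^3), dim = c(10, 10, 10))
  g1 <- match_cubes(vol, c(3, 3, 3), p = 3, m = 1, L = 5)
  expect_identical(dim(g1$tensor)[4], 1L)
  expect_identical(g1$corners, matrix(c(3L, 3L, 3L), 1))

  g <- match_cubes(vol, c(3, 3, 3), p = 3, m = 6, L = 5)
  gs <- match_cubes(vol + 100, c(3, 3, 3), p = 3, m = 6, L = 5)
  expect_identical(g$corners, gs$corners)

  expect_identical(g$tensor[, , , 1],
                   vol[3 + 1:3, 3 + 1:3, 3 + 1:3])
  expect_error(match_cubes(vol, c(3, 3, 3), p = 3, m = 6, L = 4), "odd")
  expect_error(match_cubes(vol, c(9, 9, 9), p = 3, m = 2, L = 5), "outside")
})

test_that("aggregation averages cube contributions uniformly", {
  g <- structure(list(tensor = array(5, dim = c(4, 4, 4, 1)),
                      corners = matrix(0L, 1, 3)), class = "cube_group")
  expect_identical(aggregate_groups(list(g), c(4, 4, 4)),
                   array(5, dim = c(4, 4, 4)))

  # two cubes overlapping on one voxel with values 1 and 3 -> mean 2
  g2 <- structure(list(tensor = array(c(1, 3), dim = c(1, 1, 1, 2)),
                       corners = rbind(c(0L, 0L, 0L), c(0L, 0L, 0L))),
                  class = "cube_group")
  expect_identical(aggregate_groups(list(g2), c(1, 1, 1)),
                   array(2, dim = c(1, 1, 1)))

  expect_error(aggregate_groups(list(g), c(5, 4, 4)), "no cube contribution")

  # random cubes against an independent numerator/denominator accumulation
  set.seed(23)
  shape <- c(6, 6, 6)
  groups <- list()
  num <- array(0, shape); den <- array(0, shape)
  for (k in 1:5) {
    p <- sample(2:3, 1)
    nc <- sample(1:3, 1)
    corners <- t(replicate(nc, sapply(shape, function(s) sample(0:(s - p), 1))))
    tens <- array(rnorm(p^3 * nc), dim = c(p, p, p, nc))
    groups[[k]] <- structure(list(tensor = tens,
                                  corners = matrix(as.integer(corners), ncol = 3)),
                             class = "cube_group")
    for (j in seq_len(nc)) {
      i1 <- corners[j, 1] + 1:p; i2 <- corners[j, 2] + 1:p; i3 <- corners[j, 3] + 1:p
      num[i1, i2, i3] <- num[i1, i2, i3] + tens[, , , j]
      den[i1, i2, i3] <- den[i1, i2, i3] + 1
    }
  }
  # ensure coverage with one full-volume cube
  big <- array(0, dim = c(6, 6, 6, 1))
  groups[[6]] <- structure(list(tensor = big, corners = matrix(0L, 1, 3)),
                           class = "cube_group")
  num <- num + big[, , , 1]; den <- den + 1
  expect_equal(aggregate_groups(groups, shape), num / den, tolerance = 1e-12)
})

test_that("identity-denoised groups aggregate back to the input volume", {
  set.seed(24)
  vol <- array(runif(8^3), dim = c(8, 8, 8))
  refs <- reference_positions(dim(vol), p = 3, stride = 2)
  groups <- lapply(seq_len(nrow(refs)), function(i)
    match_cubes(vol, refs[i, ], p = 3, m = 5, L = 5))
  expect_equal(aggregate_groups(groups, dim(vol)), vol, tolerance = 1e-12)
})
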