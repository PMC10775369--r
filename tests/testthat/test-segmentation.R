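test_that("tiling follows the stride and last-tile anchoring rules", {
  one <- tileImage(matrix(0, 300, 300), 300, 0.2)
  expect_length(one, 1L)
  expect_equal(c(one[[1]]$row_offset, one[[1]]$col_offset), c(0L, 0L))

  four <- tileImage(matrix(0, 540, 540), 300, 0.2) # stride 240
  expect_length(four, 4L)
  expect_setequal(vapply(four, `[[`, numeric(1), "row_offset"), c(0, 240))

  anch <- tileImage(matrix(0, 310, 300), 300, 0.2)
  expect_length(anch, 2L)
  expect_setequal(vapply(anch, `[[`, numeric(1), "row_offset"), c(0, 10))
})

test_that("every pixel is covered by at least one tile", {
  set.seed(5)
  for (rep in 1:20) {
    nr <- sample(40:700, 1); nc <- sample(40:700, 1)
    ts <- sample(c(64, 100, 300), 1)
    tiles <- tileImage(matrix(0, nr, nc), ts, 0.2)
    cov <- matrix(0L, nr, nc)
    for (t in tiles)
      cov[t$row_offset + seq_len(t$valid_rows),
          t$col_offset + seq_len(t$valid_cols)] <- 1L
    expect_true(all(cov == 1L), info = sprintf("%dx%d ts=%d", nr, nc, ts))
  }
})

test_that("rasterized labels have a boundary ring separating interiors", {
  expect_true(all(rasterizeLabels(matrix(0L, 10, 10)) == 0L))

  lab <- diskLabels(c(40, 40), cbind(20, 20), 8)
  mask <- rasterizeLabels(lab, 2L)
  ring <- sum(mask == 2)
  # ring area ~ perimeter x width (2 pi r w); generous band for discreteness
  expect_gt(ring, 0.6 * 2 * pi * 8 * 2)
  expect_lt(ring, 1.6 * 2 * pi * 8 * 2)
  # interior strictly inside the instance (morphological erosion oracle)
  interior <- which(mask == 1, arr.ind = TRUE)
  d <- sqrt((interior[, 1] - 20)^2 + (interior[, 2] - 20)^2)
  expect_true(all(d <= 8 - 1))
  expect_true(all(mask[lab == 0] == 0))

  # touching disks: a class-2 ridge keeps the interiors 4-disconnected
  two <- diskLabels(c(40, 60), rbind(c(20, 20), c(20, 32)), c(6, 6))
  m2 <- rasterizeLabels(two, 2L)
  inst <- extractInstances(m2, min_area = 5)
  expect_equal(max(inst), 2L)
})

test_that("weighted cross-entropy matches hand evaluation", {
  w <- lossWeights()
  # perfect one-hot prediction: loss vanishes
  target <- matrix(sample(0:2, 25, TRUE), 5, 5)
  perfect <- array(0, c(5, 5, 3))
  for (k in 0:2) perfect[, , k + 1][target == k] <- 1
  expect_lt(weightedCrossEntropy(perfect, target, w), 1e-6)

  # single interior pixel, p = (.2, .5, .3): 3 x (-ln .5)
  p1 <- array(c(0.2, 0.5, 0.3), c(1, 1, 3))
  expect_equal(weightedCrossEntropy(p1, matrix(1L, 1, 1), w), 3 * -log(0.5))

  # boundary pixel predicted interior, p = (.1, .6, .3): 3 x 2 x (-ln .3)
  p2 <- array(c(0.1, 0.6, 0.3), c(1, 1, 3))
  expect_equal(weightedCrossEntropy(p2, matrix(2L, 1, 1), w),
               3 * 2 * -log(0.3))
})

test_that("soft Jaccard matches closed forms and the loop oracle", {
  target <- matrix(sample(0:2, 64, TRUE), 8, 8)
  perfect <- array(0, c(8, 8, 3))
  for (k in 0:2) perfect[, , k + 1][target == k] <- 1
  expect_lt(jaccardLoss(perfect, target), 1e-6)

  # half-overlap: intersection a, union 3a, per-class Jaccard 1/3
  y <- matrix(0L, 8, 8); y[1:4, ] <- 1L
  p <- array(0, c(8, 8, 3))
  p[, , 2][3:6, ] <- 1; p[, , 1][c(1:2, 7:8), ] <- 1
  expect_equal(jaccardLoss(p, y), (2 / 3 + 2 / 3 + 0) / 3, tolerance = 1e-6)

  # brute-force triple-loop oracle on random probabilities
  set.seed(11)
  for (rep in 1:5) {
    z <- array(rexp(8 * 8 * 3), c(8, 8, 3))
    pr <- z / array(rep(apply(z, c(1, 2), sum), 3), c(8, 8, 3))
    tg <- matrix(sample(0:2, 64, TRUE), 8, 8)
    loss <- 0
    for (k in 0:2) {
      inter <- 0; psum <- 0; ysum <- 0
      for (r in 1:8) for (c in 1:8) {
        yk <- as.numeric(tg[r, c] == k)
        inter <- inter + pr[r, c, k + 1] * yk
        psum <- psum + pr[r, c, k + 1]
        ysum <- ysum + yk
      }
      loss <- loss + 1 - (inter + 1e-7) / (psum + ysum - inter + 1e-7)
    }
    expect_equal(jaccardLoss(pr, tg), loss / 3, tolerance = 1e-6)
  }
})

test_that("count, autoencode and total losses combine linearly", {
  expect_equal(countLoss(0, matrix(0L, 4, 4)), 0)
  three <- diskLabels(c(30, 90), rbind(c(15, 15), c(15, 45), c(15, 75)),
                      c(5, 5, 5))
  expect_equal(countLoss(5, three), 4)
  x <- array(runif(32), c(4, 4, 2))
  expect_equal(autoencodeLoss(x, x), 0)

  expect_equal(totalLoss(0, 0, 0, 0, 0), 0)
  expect_equal(totalLoss(1, 1, 1, 1, 1), 2001.5001) # reference weights
  w2 <- totalLoss(2, 2, 2, 2, 2)
  expect_equal(w2, 2 * 2001.5001)
})

test_that("instances are extracted by seeded expansion with an area filter", {
  expect_equal(max(extractInstances(matrix(0L, 20, 20))), 0L)

  two <- diskLabels(c(40, 60), rbind(c(20, 20), c(20, 33)), c(6, 6))
  m <- rasterizeLabels(two, 2L)
  inst <- extractInstances(m, min_area = 10)
  expect_equal(max(inst), 2L)
  # labels contiguous, instance pixels cover interior + claimed boundary
  expect_setequal(unique(as.vector(inst)), 0:2)

  # a tiny interior blob is removed by the area filter
  small <- matrix(0L, 20, 20); small[10, 9:11] <- 1L # interior area 3
  mm <- rasterizeLabels(small, 1L)
  expect_equal(max(extractInstances(mm, min_area = 20)), 0L)
})

test_that("rasterize/extract round trip preserves instance counts", {
  set.seed(23)
  for (rep in 1:20) {
    lay <- randomLayout(c(96, 96), sample(3:8, 1), touching_pairs = 2)
    lab <- diskLabels(c(96, 96), lay$centers, lay$radii)
    k <- length(unique(lab[lab > 0]))
    inst <- extractInstances(rasterizeLabels(lab, 2L), min_area = 5)
    expect_equal(max(inst), k)
  }
})
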