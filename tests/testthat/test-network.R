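test_that("the three heads satisfy their shape contracts", {
  m <- buildNetwork(depth = 2, base_filters = 4, in_channels = 2, seed = 1)
  x <- array(runif(32 * 32 * 2), c(32, 32, 2))
  out <- forwardNetwork(m, x)
  expect_equal(dim(out$probs), c(32, 32, 3))
  sums <- apply(out$probs, c(1, 2), sum)
  expect_equal(max(abs(sums - 1)), 0, tolerance = 1e-9)
  expect_length(out$count, 1L)
  expect_equal(dim(out$recon), dim(x))
  expect_gt(out$l2, 0)
  # tile size incompatible with the pooling depth is rejected
  expect_error(forwardNetwork(m, array(0, c(30, 30, 2))), "pooling depth")
})

test_that("analytic gradients match finite differences", {
  set.seed(4)
  m <- buildNetwork(depth = 2, base_filters = 2, in_channels = 1, seed = 7)
  # move biases off the ReLU kink so central differences are valid
  for (li in seq_along(m$convs))
    m$convs[[li]]$b[] <- rnorm(length(m$convs[[li]]$b), 0, 0.3)
  x <- array(runif(8 * 8), c(8, 8, 1))
  y <- matrix(sample(0:2, 64, TRUE), 8, 8)
  w <- lossWeights(alpha = 2, lambda_c = 0.5, lambda_a = 1.5, beta = 1e-3)
  g <- cycmif:::.unet_lossgrad_cpp(unclass(m), x, y, 3, unclass(w))
  fd <- function(mod)
    cycmif:::.unet_lossgrad_cpp(unclass(mod), x, y, 3, unclass(w))$total
  eps <- 1e-6
  for (li in seq_along(m$convs)) {
    W <- m$convs[[li]]$W
    for (i in sample(length(W), min(3, length(W)))) {
      mp <- m; mp$convs[[li]]$W[i] <- W[i] + eps
      mm <- m; mm$convs[[li]]$W[i] <- W[i] - eps
      num <- (fd(mp) - fd(mm)) / (2 * eps)
      expect_equal(g$grads[[li]]$W[i], num, tolerance = 1e-3)
    }
    i <- sample(length(m$convs[[li]]$b), 1)
    mp <- m; mp$convs[[li]]$b[i] <- m$convs[[li]]$b[i] + eps
    mm <- m; mm$convs[[li]]$b[i] <- m$convs[[li]]$b[i] - eps
    num <- (fd(mp) - fd(mm)) / (2 * eps)
    expect_equal(g$grads[[li]]$b[i], num, tolerance = 1e-3)
  }
})

test_that("the composite loss decreases on a learnable toy problem", {
  set.seed(6)
  cfg <- syntheticConfig(n_cycles = 2L, n_fovs = 2L,
                         image_shape = c(96L, 96L), n_cells = 10L,
                         max_shift = 0L, noise_sd = 0.01, seed = 16L)
  g <- generateDataset(cfg)
  pp <- preprocessDataset(g$dataset)
  cd45 <- lapply(1:2, function(i) getImage(pp, i, 1, 2))
  dapi <- lapply(1:2, function(i) getImage(pp, i, 1, 1))
  tt <- makeTrainingTiles(cd45, dapi, g$truth$instance_maps,
                          tile_size = 32L, overlap = 0.2)
  fit <- trainNetwork(tt$tiles, tt$labels, tt$counts, fov = tt$fov,
                      config = trainConfig(tile_size = 32L, epochs = 6L,
                                           batch_size = 8L,
                                           learning_rate = 7e-4, seed = 2L),
                      depth = 2L, base_filters = 4L)
  h <- fit$history
  expect_lt(h[nrow(h), "total"], h[1, "total"])
  expect_true(all(is.finite(h)))
})

test_that("training refuses a dataset of empty tiles", {
  empty <- replicate(5, array(0, c(16, 16, 2)), simplify = FALSE)
  labs <- replicate(5, matrix(0L, 16, 16), simplify = FALSE)
  expect_error(
    trainNetwork(empty, labs, counts = rep(0, 5),
                 config = trainConfig(epochs = 1L, seed = 1L),
                 depth = 2L, base_filters = 2L),
    "no non-empty")
})

test_that("stitched prediction equals the single-tile forward pass", {
  m <- buildNetwork(depth = 2, base_filters = 4, in_channels = 2, seed = 5)
  cd45 <- matrix(runif(64 * 64), 64, 64)
  dapi <- matrix(runif(64 * 64), 64, 64)
  pf <- predictFov(m, cd45, dapi, tile_size = 64L)
  x <- array(0, c(64, 64, 2)); x[, , 1] <- cd45; x[, , 2] <- dapi
  direct <- forwardNetwork(m, x)
  expect_equal(pf$probs, direct$probs)
  expect_equal(dim(pf$mask), dim(cd45))
  expect_true(all(pf$mask %in% 0:2))
  # overlapping tiles still cover and classify every pixel
  big <- predictFov(m, matrix(runif(96 * 80), 96, 80),
                    matrix(runif(96 * 80), 96, 80), tile_size = 64L)
  expect_equal(dim(big$mask), c(96L, 80L))
  expect_error(predictFov(m, cd45, matrix(0, 10, 10)), "shape")
})
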