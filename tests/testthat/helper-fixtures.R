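# Shared fixtures: all synthetic, built in code.

# a matrix with disk-shaped objects at given centers/radii
diskImage <- function(shape, centers, radii, value = 1, background = 0) {
  img <- matrix(background, shape[1], shape[2])
  rg <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cg <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  for (k in seq_len(nrow(centers))) {
    d <- sqrt((rg - centers[k, 1])^2 + (cg - centers[k, 2])^2)
    img[d <= radii[k]] <- value
  }
  img
}

# instance label map of disks (later disks never overwrite earlier ones)
diskLabels <- function(shape, centers, radii) {
  lab <- matrix(0L, shape[1], shape[2])
  rg <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cg <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  for (k in seq_len(nrow(centers))) {
    d <- sqrt((rg - centers[k, 1])^2 + (cg - centers[k, 2])^2)
    lab[d <= radii[k] & lab == 0L] <- k
  }
  lab
}

# a random non-touching disk layout within a margin
randomLayout <- function(shape, n, rmin = 4, rmax = 7, gap = 2,
                         touching_pairs = 0) {
  centers <- matrix(numeric(0), 0, 2)
  radii <- numeric(0)
  tries <- 0
  addAt <- function(row, col, r) {
    centers <<- rbind(centers, c(row, col)); radii <<- c(radii, r)
  }
  while (nrow(centers) < n && tries < 3000) {
    tries <- tries + 1
    r <- runif(1, rmin, rmax)
    row <- runif(1, rmax + 3, shape[1] - rmax - 3)
    col <- runif(1, rmax + 3, shape[2] - rmax - 3)
    if (!nrow(centers) ||
        all(sqrt((centers[, 1] - row)^2 + (centers[, 2] - col)^2) >=
            radii + r + gap))
      addAt(row, col, r)
  }
  k <- 0
  while (k < touching_pairs && nrow(centers) >= 1 && tries < 6000) {
    tries <- tries + 1
    i <- nrow(centers)
    r <- runif(1, rmin, rmax)
    th <- runif(1, 0, 2 * pi)
    row <- centers[i, 1] + (radii[i] + r) * cos(th)
    col <- centers[i, 2] + (radii[i] + r) * sin(th)
    ok <- row > rmax + 3 && col > rmax + 3 && row < shape[1] - rmax - 3 &&
      col < shape[2] - rmax - 3
    if (ok && all(sqrt((centers[-i, 1] - row)^2 + (centers[-i, 2] - col)^2) >=
                  radii[-i] + r + gap)) {
      addAt(row, col, r)
      k <- k + 1
    }
  }
  list(centers = centers, radii = radii)
}

# small synthetic dataset shared by several tests
tinyConfig <- function(...) {
  syntheticConfig(n_cycles = 2L, n_fovs = 1L, n_channels = 2L,
                  image_shape = c(128L, 128L), n_cells = 12L,
                  max_shift = 6L, noise_sd = 0.005, seed = 42L, ...)
}

# equal-intensity marker map: every marker identical, no per-cell variation
flatIntensityMap <- function(level = 0.5) {
  data.frame(marker = ".default", mean_on = level, mean_off = level, sd = 0,
             stringsAsFactors = FALSE)
}
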