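test_that("planted shifts respect the reference and the bound", {
  expect_equal(plantShifts(1, 10, 3), cbind(dy = 0, dx = 0))
  s0 <- plantShifts(5, 0, 3)
  expect_true(all(s0 == 0))
  s <- plantShifts(4, 15, 7)
  expect_equal(s[1, ], c(dy = 0, dx = 0))
  expect_true(all(abs(s) <= 15))
  expect_true(all(s == round(s)))
  # uniform-integer sampler: many draws cover negative and positive values
  many <- plantShifts(500, 15, 11)[-1, ]
  expect_true(min(many) < -10 && max(many) > 10)
})

test_that("zero-shift zero-noise dataset has identical matched channels", {
  cfg <- syntheticConfig(n_cycles = 3L, n_fovs = 1L, n_channels = 2L,
                         image_shape = c(96L, 96L), n_cells = 8L,
                         max_shift = 0L, noise_sd = 0,
                         marker_intensity_map = flatIntensityMap(),
                         seed = 5L)
  g <- generateDataset(cfg)
  # cycles 2 and 3 carry generically rendered markers (full-disk footprint);
  # cycle 1 holds DAPI (nuclear) and CD45 (membrane), whose footprints differ
  for (c in 1:2)
    expect_identical(getImage(g$dataset, 1, 2, c),
                     getImage(g$dataset, 1, 3, c))
})

test_that("planted cell count is conserved in ground truth", {
  cfg <- syntheticConfig(n_cycles = 2L, n_fovs = 2L,
                         image_shape = c(320L, 320L), n_cells = 50L,
                         max_shift = 4L, seed = 8L)
  g <- generateDataset(cfg)
  for (i in 1:2) {
    expect_equal(sum(g$truth$cell_table$fov == i), 50L)
    expect_equal(max(g$truth$instance_maps[[i]]), 50L)
    expect_setequal(unique(as.vector(g$truth$instance_maps[[i]])), 0:50)
  }
})

test_that("generation is deterministic under a fixed seed", {
  a <- generateDataset(tinyConfig())
  b <- generateDataset(tinyConfig())
  expect_identical(a$dataset@images, b$dataset@images)
  expect_identical(a$truth, b$truth)
})

test_that("rendering follows the additive background + footprint model", {
  cfg <- syntheticConfig(n_cycles = 2L, image_shape = c(64L, 64L),
                         n_cells = 1L, noise_sd = 0,
                         background_level = 0.05, seed = 1L)
  # no cells: stain equals quench equals the constant background
  none <- renderFov(data.frame(row = numeric(0), col = numeric(0),
                               r = numeric(0)),
                    c(0, 0), "CD3", cfg)
  expect_true(all(none[[1]]$stain == 0.05))
  expect_identical(none[[1]]$stain, none[[1]]$quench)

  # one disk, marker on: mean inside the hard footprint = background + mean_on
  cells <- data.frame(row = 32, col = 32, r = 6, mean_CD3 = 0.4,
                      mean_CD4 = 0)
  on <- renderFov(cells, c(0, 0), "CD3", cfg)[[1]]$stain
  d <- sqrt(outer((1:64 - 32)^2, rep(1, 64)) +
            outer(rep(1, 64), (1:64 - 32)^2))
  inside <- d <= 6
  expect_equal(mean(on[inside]), 0.05 + 0.4, tolerance = 1e-12)

  # off marker contributes nothing inside the cell
  off <- renderFov(cells, c(0, 0), "CD4", cfg)[[1]]
  expect_equal(max(abs(off$stain - off$quench)), 0, tolerance = 1e-12)
})

test_that("rule set applied to true marker means reproduces planted phenotypes", {
  cfg <- syntheticConfig(n_cycles = 4L, n_fovs = 1L,
                         image_shape = c(320L, 320L), n_cells = 60L,
                         noise_sd = 0, seed = 21L)
  g <- generateDataset(cfg)
  tab <- g$truth$cell_table
  rules <- phenotypeRuleTable()
  markers <- sub("^mean_", "", grep("^mean_", names(tab), value = TRUE))
  # positivity from true means at the midpoint of the on/off levels
  pos <- as.matrix(tab[, paste0("mean_", markers)]) > 0.28
  colnames(pos) <- markers
  called <- apply(pos, 1, function(p) {
    for (r in seq_len(nrow(rules))) {
      if (all(p[rules$positive[[r]]]) && !any(p[rules$negative[[r]]]))
        return(rules$name[r])
    }
    "unassigned"
  })
  expect_identical(unname(called), tab$phenotype)
})

test_that("datasets round-trip through disk", {
  g <- generateDataset(tinyConfig())
  dir <- withr::local_tempdir()
  writeDataset(g, dir, sample = "t")
  ds <- groupImages(dir)
  expect_equal(nFov(ds), 1L)
  expect_equal(nCycles(ds), 2L)
  expect_equal(nChannels(ds), 2L)
  for (j in 1:2) for (c in 1:2) {
    a <- getImage(g$dataset, 1, j, c)
    b <- getImage(ds, 1, j, c)
    expect_lt(max(abs(pmin(a, 1) - b)), 1.1 / 65535)
  }
  # label TIFF round trip is exact
  lab <- readLabelTiff(file.path(dir, "t_f01_labels.tif"))
  expect_identical(lab, g$truth$instance_maps[[1]])
})
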