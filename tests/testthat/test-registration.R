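test_that("maximum projection is the per-pixel maximum", {
  a <- matrix(c(0, 3, 5, 2), 1)
  expect_identical(maxProject(list(a)), a)
  expect_identical(maxProject(list(matrix(c(0, 5), 1), matrix(c(3, 2), 1))),
                   matrix(c(3, 5), 1))
  set.seed(1)
  imgs <- replicate(5, matrix(runif(60), 6, 10), simplify = FALSE)
  brute <- matrix(0, 6, 10)
  for (r in 1:6) for (c in 1:10)
    brute[r, c] <- max(vapply(imgs, function(m) m[r, c], numeric(1)))
  expect_equal(maxProject(imgs), brute)
  expect_error(maxProject(list()), "no channel")
})

test_that("foreground mask keeps only cell-sized objects", {
  blank <- matrix(0, 64, 64)
  fm <- foregroundMask(blank, c(50, 500))
  expect_equal(fm$count, 0L)
  expect_true(!any(fm$mask))

  one <- diskImage(c(64, 64), cbind(32, 32), 6, value = 0.9)
  fm1 <- foregroundMask(one, c(50, 500))
  expect_equal(fm1$count, 1L)
  # the retained component is the planted disk (connected-component oracle)
  expect_gt(sum(fm1$mask & one > 0) / sum(one > 0), 0.8)

  small <- diskImage(c(64, 64), cbind(32, 32), 1.7, value = 0.9) # area ~10
  fm2 <- foregroundMask(small, c(50, 500))
  expect_equal(fm2$count, 0L)
})

test_that("estimateShift recovers planted translations", {
  set.seed(3)
  lay <- randomLayout(c(128, 128), 15)
  ref <- diskImage(c(128, 128), lay$centers, lay$radii, value = 0.8)
  cfg <- registrationConfig(size_band = c(20, 2000), seed = 2)

  same <- estimateShift(ref, ref, cfg)
  expect_false(same$failed)
  expect_equal(unname(same$final_shift), c(0, 0))

  mov <- applyShift(ref, -c(6, -4)) # content displaced by (+6, -4)
  est <- estimateShift(ref, mov, cfg)
  expect_false(est$failed)
  expect_equal(unname(est$final_shift), c(6, -4))

  blank <- estimateShift(ref, matrix(0, 128, 128), cfg)
  expect_true(blank$failed)
  expect_match(blank$reason, "low cellularity")
})

test_that("shift estimation is anti-symmetric and translation-equivariant", {
  set.seed(7)
  lay <- randomLayout(c(128, 128), 15)
  ref <- diskImage(c(128, 128), lay$centers, lay$radii, value = 0.8)
  cfg <- registrationConfig(size_band = c(20, 2000), seed = 5)
  for (s in list(c(4, 8), c(-6, 2), c(10, -10))) {
    mov <- applyShift(ref, -s)
    ab <- estimateShift(ref, mov, cfg)$final_shift
    ba <- estimateShift(mov, ref, cfg)$final_shift
    expect_equal(unname(ab), s)
    expect_equal(unname(ba), -s)
  }
})

test_that("applyShift inverts cleanly on the interior", {
  x <- matrix(runif(400), 20, 20)
  expect_identical(applyShift(x, c(0, 0)), x)
  y <- applyShift(applyShift(x, c(3, -2)), c(-3, 2))
  expect_equal(y[5:15, 5:15], x[5:15, 5:15])
})

test_that("one FOV aligns the whole cycle set and honors the reference", {
  cfg <- syntheticConfig(n_cycles = 3L, n_fovs = 3L, n_channels = 2L,
                         image_shape = c(192L, 192L), n_cells = 25L,
                         max_shift = 8L, noise_sd = 0.005,
                         marker_intensity_map = flatIntensityMap(0.5),
                         seed = 14L)
  g <- generateDataset(cfg)
  pp <- preprocessDataset(g$dataset)
  rcfg <- registrationConfig(size_band = c(20, 3000), seed = 3)
  res <- alignCycleSet(pp, 1, rcfg)
  expect_s4_class(res, "RegistrationResult")
  expect_true(all(abs(cycleShifts(res) - g$truth$shifts) <= 1))
  # the same cycle shift applies to every FOV: cycles 2 and 3 carry
  # identically rendered scenes, so after alignment they coincide
  aligned <- applyShiftToDataset(pp, res)
  for (i in 1:3) {
    a <- getImage(aligned, i, 2, 1)
    r <- getImage(aligned, i, 3, 1)
    interior <- 30:160
    expect_gt(cor(as.vector(a[interior, interior]),
                  as.vector(r[interior, interior])), 0.9)
  }
  # reference convention: choosing cycle 2 zeroes its shift
  res2 <- alignCycleSet(pp, 1, registrationConfig(reference_cycle = 2L,
                                                  size_band = c(20, 3000),
                                                  seed = 3))
  expect_equal(unname(cycleShifts(res2)[2, ]), c(0, 0))
  rel <- sweep(g$truth$shifts, 2, g$truth$shifts[2, ])
  expect_true(all(abs(cycleShifts(res2) - rel) <= 1))
})

test_that("trial crops are seeded: estimation is deterministic", {
  cfg <- syntheticConfig(n_cycles = 3L, n_fovs = 1L, n_channels = 2L,
                         image_shape = c(160L, 160L), n_cells = 20L,
                         max_shift = 10L, noise_sd = 0.01, seed = 31L)
  g <- generateDataset(cfg)
  pp <- preprocessDataset(g$dataset)
  rcfg <- registrationConfig(size_band = c(20, 3000), seed = 9)
  r1 <- alignCycleSet(pp, 1, rcfg)
  r2 <- alignCycleSet(pp, 1, rcfg)
  expect_identical(cycleShifts(r1), cycleShifts(r2))
  expect_identical(r1@trialShifts, r2@trialShifts)
})
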