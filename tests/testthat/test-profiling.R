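test_that("per-cell aggregation matches brute-force pixel loops", {
  lab <- diskLabels(c(40, 40), rbind(c(12, 12), c(28, 28)), c(5, 6))
  uniform <- matrix(0, 40, 40); uniform[lab == 1] <- 7
  tab <- aggregateCellSignals(lab, list(M1 = uniform))
  expect_equal(unname(intensityMatrix(tab)["M1", 1]), 7)

  set.seed(13)
  imgs <- list(A = matrix(runif(1600), 40, 40),
               B = matrix(rexp(1600), 40, 40))
  tab2 <- aggregateCellSignals(lab, imgs)
  for (k in 1:2) for (m in c("A", "B")) {
    px <- imgs[[m]][lab == k]
    expect_equal(unname(intensityMatrix(tab2)[m, k]), mean(px),
                 tolerance = 1e-9)
  }
  cd <- SummarizedExperiment::colData(tab2)
  expect_equal(cd$area, c(sum(lab == 1), sum(lab == 2)))
  expect_error(aggregateCellSignals(lab, list(A = matrix(0, 10, 10))),
               "shape")
})

test_that("aggregation is mask-additive", {
  lab <- diskLabels(c(30, 30), cbind(15, 15), 7)
  set.seed(2)
  img <- matrix(runif(900), 30, 30)
  whole <- mean(img[lab == 1])
  # split the pixel set arbitrarily in two
  idx <- which(lab == 1)
  half <- idx[seq_len(floor(length(idx) / 2))]
  rest <- setdiff(idx, half)
  recombined <- (mean(img[half]) * length(half) +
                 mean(img[rest]) * length(rest)) / length(idx)
  expect_equal(whole, recombined, tolerance = 1e-9)
})

test_that("MAD outlier removal drops only the high side", {
  mk <- function(v) SingleCellTable(
    matrix(v, 1, dimnames = list("M1", NULL)),
    data.frame(cell_id = seq_along(v), fov = 1, area = 10,
               centroid_row = 1, centroid_col = 1))
  # hand computation: median 3, MAD 1, cutoff 3 + 5 = 8
  t1 <- removeOutliersMAD(mk(c(1, 2, 3, 4, 100)), k = 5)
  expect_equal(ncol(t1), 4L)
  expect_equal(attr(t1, "removed"), 5L)
  # symmetric data with no extremes is unchanged
  t2 <- removeOutliersMAD(mk(c(2, 3, 4, 5, 6)), k = 5)
  expect_equal(ncol(t2), 5L)
  # all-equal values: MAD = 0 guard, no removals
  t3 <- removeOutliersMAD(mk(rep(4, 6)), k = 5)
  expect_equal(ncol(t3), 6L)
  # removal count is monotone non-increasing in k
  v <- c(rexp(20), 50, 80)
  removed <- vapply(c(2, 4, 6, 10),
                    function(k) length(attr(removeOutliersMAD(mk(v), k),
                                            "removed")), numeric(1))
  expect_true(all(diff(removed) <= 0))
  expect_error(removeOutliersMAD(mk(c(1, 2))), "3 cells")
})

test_that("log transform is a one-way state transition", {
  tab <- SingleCellTable(
    matrix(c(exp(1) - 1e-6, 0, 5), 1, dimnames = list("M1", NULL)),
    data.frame(cell_id = 1:3, fov = 1, area = 1,
               centroid_row = 1, centroid_col = 1))
  lt <- logTransform(tab)
  expect_equal(transformState(lt), "log")
  expect_equal(unname(intensityMatrix(lt)[1, 1]), 1)
  expect_equal(unname(intensityMatrix(lt)[1, 2]), log(1e-6))
  expect_true(all(diff(order(intensityMatrix(tab))) ==
                  diff(order(intensityMatrix(lt))))) # monotone
  expect_error(logTransform(lt), "raw state")
})

test_that("positivity thresholds sit 3 SD below the marker mean", {
  set.seed(8)
  v <- rnorm(400, 2, 0.5)
  v <- (v - mean(v)) / sd(v) * 0.5 + 2 # exact mean 2, sd 0.5
  tab <- SingleCellTable(
    matrix(v, 1, dimnames = list("M1", NULL)),
    data.frame(cell_id = seq_along(v), fov = 1, area = 1,
               centroid_row = 1, centroid_col = 1), transformState = "log")
  thr <- positivityThresholds(tab)
  expect_equal(unname(thr["M1"]), 0.5)
  # shifting all values shifts the threshold, positivity unchanged
  tab2 <- SingleCellTable(
    matrix(v + 3, 1, dimnames = list("M1", NULL)),
    data.frame(cell_id = seq_along(v), fov = 1, area = 1,
               centroid_row = 1, centroid_col = 1), transformState = "log")
  expect_equal(unname(positivityThresholds(tab2)["M1"]), 3.5)
  expect_identical(positivity(callPositivity(tab)),
                   positivity(callPositivity(tab2)))
  # constant marker: threshold = mean, strict > makes all cells negative
  tabc <- SingleCellTable(
    matrix(2, 1, 5, dimnames = list("M1", NULL)),
    data.frame(cell_id = 1:5, fov = 1, area = 1,
               centroid_row = 1, centroid_col = 1), transformState = "log")
  expect_true(all(!positivity(callPositivity(tabc))))
  one <- tabc[, 1]
  one <- methods::as(one, "SingleCellTable")
  expect_error(positivityThresholds(one), "single cell")
})

test_that("the rule engine reproduces the reference gating table", {
  markers <- c("CD45", "CD3", "CD4", "CD8", "CD56", "CD20", "CD11b",
               "CD66b", "CD68", "CD11c", "CK56")
  mkPos <- function(on) {
    p <- matrix(FALSE, 1, length(markers), dimnames = list(NULL, markers))
    p[, on] <- TRUE
    p
  }
  callOne <- function(on) {
    tab <- SingleCellTable(
      matrix(0, length(markers), 1, dimnames = list(markers, NULL)),
      data.frame(cell_id = 1, fov = 1, area = 1, centroid_row = 1,
                 centroid_col = 1), transformState = "log")
    S4Vectors::metadata(tab)$positivity <- mkPos(on)
    phenotypes(assignPhenotypes(tab))
  }
  expect_equal(callOne(c("CD45", "CD3", "CD4")), "CD4+ T cells")
  expect_equal(callOne(c("CD45", "CD3", "CD8")), "CD8+ T cells")
  expect_equal(callOne(c("CD45", "CD56")), "Natural killer cells")
  expect_equal(callOne(c("CD45", "CD20")), "B cells")
  expect_equal(callOne(c("CD45", "CD11b", "CD66b")), "Neutrophils")
  expect_equal(callOne(c("CD45", "CD11b", "CD68")), "Macrophages")
  expect_equal(callOne(c("CD45", "CD11b", "CD11c")), "Dendritic cells")
  expect_equal(callOne("CD45"), "Immune cells")
  expect_equal(callOne(c("CD56", "CK56")), "unassigned") # CD45-negative
  # first match wins on overlapping gates
  expect_equal(callOne(c("CD45", "CD11b", "CD66b", "CD68")), "Neutrophils")
  # a rule naming an absent marker is a configuration error
  tab <- SingleCellTable(
    matrix(0, 2, 1, dimnames = list(c("CD45", "CD3"), NULL)),
    data.frame(cell_id = 1, fov = 1, area = 1, centroid_row = 1,
               centroid_col = 1), transformState = "log")
  S4Vectors::metadata(tab)$positivity <-
    matrix(TRUE, 1, 2, dimnames = list(NULL, c("CD45", "CD3")))
  expect_error(assignPhenotypes(tab), "absent from the panel")
})

test_that("z-scoring standardizes each marker", {
  set.seed(3)
  x <- rbind(A = rnorm(50, 5), B = rnorm(50, -2, 3), C = rep(1, 50))
  tab <- SingleCellTable(x, data.frame(cell_id = 1:50, fov = 1, area = 1,
                                       centroid_row = 1, centroid_col = 1),
                         transformState = "log")
  z <- zscoreMatrix(tab)
  expect_equal(unname(colMeans(z)[1:2]), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)[1:2]), c(1, 1), tolerance = 1e-12)
  expect_true(all(z[, "C"] == 0))
  # 3-cell hand example
  tab3 <- SingleCellTable(matrix(c(1, 2, 6), 1, dimnames = list("M", NULL)),
                          data.frame(cell_id = 1:3, fov = 1, area = 1,
                                     centroid_row = 1, centroid_col = 1),
                          transformState = "log")
  expect_equal(unname(zscoreMatrix(tab3)[, 1]),
               (c(1, 2, 6) - 3) / sd(c(1, 2, 6)))
})

test_that("rule files round-trip through CSV and YAML", {
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "rules.csv")
  write.csv(data.frame(name = c("X cells", "Y cells"),
                       positive = c("CD45;CD3", "CD45"),
                       negative = c("CD8", "")), csv, row.names = FALSE)
  r <- readPhenotypeRules(csv)
  expect_equal(r$name, c("X cells", "Y cells"))
  expect_equal(r$positive[[1]], c("CD45", "CD3"))
  expect_equal(r$negative[[2]], character(0))
  yml <- file.path(dir, "rules.yaml")
  yaml::write_yaml(list(list(name = "Z", positive = list("CD20"),
                             negative = list("CD3", "CD11b"))), yml)
  ry <- readPhenotypeRules(yml)
  expect_equal(ry$negative[[1]], c("CD3", "CD11b"))
  expect_error(phenotypeRule("bad", "CD3", "CD3"), "both positive")
})
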