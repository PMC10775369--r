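#' Configuration for the synthetic cyclic-imaging generator
#'
#' Describes a fully ground-truthed synthetic acquisition: disk-like cells
#' with nuclear (DAPI) and membrane (CD45) signal, phenotype-driven marker
#' intensities, per-cycle rigid translations, additive background plus
#' Gaussian noise, and paired quench exposures.
#'
#' Intensities are on the unit fluorescence scale of a 16-bit camera
#' (1.0 = saturation). Defaults emulate a moderately dense FNA-style field:
#' 40 cells of 5--9 px radius in a 256 x 256 FOV, remounting shifts up to
#' 10 px, background 0.05 and noise sd 0.01.
#'
#' @param n_cycles number of staining cycles N (>= 2).
#' @param n_fovs number of fields of view M.
#' @param n_channels channels per cycle C.
#' @param image_shape c(rows, cols) in pixels.
#' @param n_cells cells planted per FOV.
#' @param cell_radius_range c(min, max) cell radius in pixels.
#' @param max_shift largest per-cycle translation component (px); must be
#'   below a quarter of the smaller image dimension.
#' @param phenotype_mixture named numeric vector of mixture proportions over
#'   rule names in \code{rules}; must sum to 1.
#' @param rules phenotype rule table ([phenotypeRuleTable()] by default).
#' @param marker_intensity_map data.frame(marker, mean_on, mean_off, sd) in
#'   unit fluorescence; markers absent from the map fall back to the map row
#'   named \code{".default"}.
#' @param background_level constant background added to every exposure.
#' @param noise_sd sd of additive Gaussian pixel noise.
#' @param min_gap minimum edge-to-edge gap between planted cells (px).
#' @param touching_fraction fraction of cells planted as touching pairs
#'   (edge-to-edge distance 0), for boundary-class stress tests.
#' @param subpixel if TRUE translations are real-valued; integer otherwise.
#' @param seed RNG seed.
#' @return validated config (list with class "mifSyntheticConfig").
#' @export
syntheticConfig <- function(n_cycles = 4L, n_fovs = 2L, n_channels = 3L,
                            image_shape = c(256L, 256L), n_cells = 40L,
                            cell_radius_range = c(5, 9), max_shift = 10L,
                            phenotype_mixture = NULL,
                            rules = phenotypeRuleTable(),
                            marker_intensity_map = NULL,
                            background_level = 0.05, noise_sd = 0.01,
                            min_gap = 2, touching_fraction = 0,
                            subpixel = FALSE, seed = 1L) {
  if (is.null(phenotype_mixture))
    phenotype_mixture <- c("CD4+ T cells" = 0.18, "CD8+ T cells" = 0.14,
                           "Natural killer cells" = 0.06, "B cells" = 0.10,
                           "Neutrophils" = 0.20, "Macrophages" = 0.16,
                           "Dendritic cells" = 0.06, "Immune cells" = 0.10)
  if (is.null(marker_intensity_map))
    marker_intensity_map <- data.frame(
      marker = c("DAPI", ".default"),
      mean_on = c(0.70, 0.55), mean_off = c(0.0, 0.02),
      sd = c(0.05, 0.05), stringsAsFactors = FALSE)

  if (n_cycles < 2L) stop("n_cycles must be >= 2")
  if (abs(sum(phenotype_mixture) - 1) > 1e-9)
    stop("phenotype mixture proportions must sum to 1")
  if (max_shift >= min(image_shape) / 4)
    stop("max_shift must be below min(image_shape)/4")
  if (any(c(marker_intensity_map$mean_on, marker_intensity_map$mean_off,
            background_level) < 0))
    stop("intensities must be non-negative")
  unknown <- setdiff(names(phenotype_mixture), c(rules$name, "Tumor cells"))
  if (length(unknown))
    stop("phenotype mixture names not in the rule table: ",
         paste(unknown, collapse = ", "))

  structure(list(
    n_cycles = as.integer(n_cycles), n_fovs = as.integer(n_fovs),
    n_channels = as.integer(n_channels),
    image_shape = as.integer(image_shape), n_cells = as.integer(n_cells),
    cell_radius_range = cell_radius_range, max_shift = max_shift,
    phenotype_mixture = phenotype_mixture, rules = rules,
    marker_intensity_map = marker_intensity_map,
    background_level = background_level, noise_sd = noise_sd,
    min_gap = min_gap, touching_fraction = touching_fraction,
    subpixel = subpixel, seed = as.integer(seed)
  ), class = "mifSyntheticConfig")
}

# canonical marker panel order used to fill the manifest
.panelMarkers <- c("DAPI", "CD45", "CD3", "CD4", "CD8", "CD56", "CD20",
                   "CD11b", "CD66b", "CD68", "CD11c", "CK56")

#' Default marker manifest for a synthetic panel
#'
#' Assigns the canonical immune panel (DAPI and CD45 first, so the
#' segmentation input channels always exist) to (cycle, channel) slots;
#' slots beyond the panel get generic markers "M13", "M14", ...
#'
#' @param n_cycles,n_channels manifest dimensions.
#' @return data.frame(cycle, channel, marker).
#' @export
defaultManifest <- function(n_cycles, n_channels) {
  n <- n_cycles * n_channels
  markers <- .panelMarkers
  if (n > length(markers))
    markers <- c(markers, paste0("M", seq(length(markers) + 1L, n)))
  markers <- markers[seq_len(n)]
  data.frame(cycle = rep(seq_len(n_cycles), each = n_channels),
             channel = rep(seq_len(n_channels), times = n_cycles),
             marker = markers, stringsAsFactors = FALSE)
}

#' Plant per-cycle rigid translations
#'
#' Emulates the spatial offsets introduced when a slide is removed and
#' remounted between staining cycles. The reference cycle (index 1) gets
#' (0, 0); the others are drawn uniformly on the integers in
#' \code{[-max_shift, max_shift]^2}.
#'
#' @param n_cycles number of cycles (>= 1).
#' @param max_shift bound on each component (px).
#' @param seed RNG seed.
#' @param subpixel draw real-valued shifts instead of integers.
#' @return n_cycles x 2 matrix, columns \code{dy}, \code{dx}.
#' @export
plantShifts <- function(n_cycles, max_shift, seed, subpixel = FALSE) {
  stopifnot(n_cycles >= 1)
  set.seed(seed)
  draw <- function(n) {
    if (subpixel) runif(n, -max_shift, max_shift)
    else sample(seq(-max_shift, max_shift), n, replace = TRUE)
  }
  s <- cbind(dy = c(0, draw(n_cycles - 1L)),
             dx = c(0, draw(n_cycles - 1L)))
  if (max_shift == 0) s[] <- 0
  s
}

# Per-cell realized marker means given its phenotype rule.
# A marker is "on" when listed positive in the cell's rule (DAPI is always
# on); otherwise "off". The special non-immune phenotype "Tumor cells" is
# CK56+ CD45- (an epithelial population, useful to make every gated marker
# bimodal across a specimen). Realized mean ~ N(mean_on/off, sd), clipped
# at 0.
.cellMarkerMeans <- function(phenotype, markers, rules, imap) {
  onset <- if (identical(phenotype, "Tumor cells")) c("DAPI", "CK56") else {
    rule <- rules[rules$name == phenotype, ]
    unique(c("DAPI", rule$positive[[1L]]))
  }
  vapply(markers, function(m) {
    row <- imap[match(m, imap$marker), ]
    if (is.na(row$marker)) row <- imap[match(".default", imap$marker), ]
    mu <- if (m %in% onset) row$mean_on else row$mean_off
    max(0, rnorm(1L, mu, row$sd))
  }, numeric(1))
}

# Sample non-overlapping cell geometry for one FOV. Touching pairs (if
# requested) are planted first at exact edge contact.
.placeCells <- function(config) {
  shape <- config$image_shape; n <- config$n_cells
  rr <- config$cell_radius_range
  margin <- rr[2] + 4
  cells <- data.frame(row = numeric(0), col = numeric(0), r = numeric(0))
  nPairs <- floor(config$touching_fraction * n / 2)
  ok <- function(row, col, r, gap) {
    if (row < margin || col < margin ||
        row > shape[1] - margin || col > shape[2] - margin) return(FALSE)
    if (!nrow(cells)) return(TRUE)
    d <- sqrt((cells$row - row)^2 + (cells$col - col)^2)
    all(d >= cells$r + r + gap)
  }
  addOne <- function(gap) {
    for (it in seq_len(2000L)) {
      r <- runif(1, rr[1], rr[2])
      row <- runif(1, margin, shape[1] - margin)
      col <- runif(1, margin, shape[2] - margin)
      if (ok(row, col, r, gap)) {
        cells[nrow(cells) + 1L, ] <<- c(row, col, r)
        return(TRUE)
      }
    }
    FALSE
  }
  planted <- 0L
  while (planted + 2L <= 2L * nPairs) {
    if (!addOne(config$min_gap)) break
    a <- cells[nrow(cells), ]
    done <- FALSE
    for (it in seq_len(200L)) {
      r2 <- runif(1, rr[1], rr[2])
      th <- runif(1, 0, 2 * pi)
      row2 <- a$row + (a$r + r2) * cos(th)
      col2 <- a$col + (a$r + r2) * sin(th)
      # touching partner: contact with a, normal gap to everyone else
      if (row2 >= margin && col2 >= margin && row2 <= shape[1] - margin &&
          col2 <= shape[2] - margin) {
        others <- cells[-nrow(cells), , drop = FALSE]
        if (!nrow(others) ||
            all(sqrt((others$row - row2)^2 + (others$col - col2)^2) >=
                others$r + r2 + config$min_gap)) {
          cells[nrow(cells) + 1L, ] <- c(row2, col2, r2)
          done <- TRUE; break
        }
      }
    }
    if (!done) cells <- cells[-nrow(cells), , drop = FALSE]
    planted <- nrow(cells)
  }
  while (nrow(cells) < n) if (!addOne(config$min_gap)) break
  if (nrow(cells) < n)
    warning("placed only ", nrow(cells), " of ", n, " requested cells")
  cells
}

# Soft-edged footprint weight of a cell at distance d from its center:
# 1 inside the hard footprint (d <= r), linear falloff over 1 px outside.
# CD45 is membrane-localized (annulus outside 0.55 r); DAPI nuclear
# (disk of radius 0.55 r).
.footprintWeights <- function(dist, r, marker) {
  soft <- function(edge) pmin(1, pmax(0, edge + 1 - dist)) # ramp outside edge
  if (identical(marker, "DAPI")) {
    soft(0.55 * r)
  } else if (identical(marker, "CD45")) {
    outer_w <- soft(r)
    inner <- 0.55 * r
    ring <- pmin(1, pmax(0, dist - inner)) # 0 at the nucleus, 1 past it
    outer_w * ring
  } else {
    soft(r)
  }
}

#' Render the stain and quench images of one FOV for one cycle
#'
#' The stain image is \code{background + sum(cell footprints x realized
#' marker mean) + N(0, noise_sd)}, clipped at zero; the quench image is
#' background plus an independent noise draw (a separate exposure).
#'
#' @param cells data.frame of cell geometry and marker means for the FOV
#'   (as produced inside [generateDataset()]), with columns row, col, r and
#'   one \code{mean_<marker>} column per panel marker.
#' @param shift numeric (dy, dx) applied to all cell centers for this cycle.
#' @param markers character vector of markers for this cycle's channels.
#' @param config a [syntheticConfig()].
#' @return list of length \code{length(markers)}; each element is
#'   \code{list(stain=, quench=)} matrices.
#' @export
renderFov <- function(cells, shift, markers, config) {
  shape <- config$image_shape
  rowg <- matrix(seq_len(shape[1]), shape[1], shape[2])
  colg <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  out <- vector("list", length(markers))
  for (ci in seq_along(markers)) {
    m <- markers[ci]
    img <- matrix(config$background_level, shape[1], shape[2])
    if (nrow(cells)) for (k in seq_len(nrow(cells))) {
      cr <- cells$row[k] + shift[1]; cc <- cells$col[k] + shift[2]
      r <- cells$r[k]
      # only touch a local window around the cell
      r0 <- max(1L, floor(cr - r - 2)); r1 <- min(shape[1], ceiling(cr + r + 2))
      c0 <- max(1L, floor(cc - r - 2)); c1 <- min(shape[2], ceiling(cc + r + 2))
      if (r0 > r1 || c0 > c1) next
      d <- sqrt((rowg[r0:r1, c0:c1] - cr)^2 + (colg[r0:r1, c0:c1] - cc)^2)
      w <- .footprintWeights(d, r, m)
      img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] +
        w * cells[[paste0("mean_", m)]][k]
    }
    if (config$noise_sd > 0)
      img <- img + matrix(rnorm(length(img), 0, config$noise_sd),
                          shape[1], shape[2])
    quench <- matrix(config$background_level, shape[1], shape[2])
    if (config$noise_sd > 0)
      quench <- quench + matrix(rnorm(length(quench), 0, config$noise_sd),
                                shape[1], shape[2])
    out[[ci]] <- list(stain = pmax(img, 0), quench = pmax(quench, 0))
  }
  out
}

# Hard instance map in the reference frame: pixel belongs to the nearest
# cell whose hard footprint (d <= r) covers it.
.instanceMap <- function(cells, shape) {
  lab <- matrix(0L, shape[1], shape[2])
  best <- matrix(Inf, shape[1], shape[2])
  if (!nrow(cells)) return(lab)
  rowg <- matrix(seq_len(shape[1]), shape[1], shape[2])
  colg <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  for (k in seq_len(nrow(cells))) {
    d <- sqrt((rowg - cells$row[k])^2 + (colg - cells$col[k])^2)
    claim <- d <= cells$r[k] & (d - cells$r[k]) < best
    lab[claim] <- k
    best[claim] <- (d - cells$r[k])[claim]
  }
  # relabel contiguously in case a cell was fully occluded
  ids <- sort(unique(lab[lab > 0]))
  lab[] <- match(lab, c(0L, ids)) - 1L
  lab
}

#' Generate a fully ground-truthed synthetic cyclic dataset
#'
#' Produces a [CyclicDataset-class] of stain/quench pairs over
#' (FOV, cycle, channel) together with the planted ground truth: per-cycle
#' shifts, per-FOV instance label maps (reference frame), and a cell table
#' with phenotype, centroid, area and realized per-marker means.
#'
#' Cycle j's images are the cycle-1 scene translated by \code{shifts[j, ]}
#' with an independent noise realization.
#'
#' @param config a [syntheticConfig()].
#' @return list with elements \code{dataset} ([CyclicDataset-class]) and
#'   \code{truth} (list: shifts, instance_maps, cell_table).
#' @export
generateDataset <- function(config) {
  stopifnot(inherits(config, "mifSyntheticConfig"))
  manifest <- defaultManifest(config$n_cycles, config$n_channels)
  shifts <- plantShifts(config$n_cycles, config$max_shift, config$seed,
                        config$subpixel)
  set.seed(config$seed + 1L)
  markers <- manifest$marker
  phenos <- names(config$phenotype_mixture)

  images <- list()
  instance_maps <- vector("list", config$n_fovs)
  tabs <- list()
  next_id <- 1L
  for (i in seq_len(config$n_fovs)) {
    geom <- .placeCells(config)
    ph <- sample(phenos, nrow(geom), replace = TRUE,
                 prob = config$phenotype_mixture)
    means <- t(vapply(ph, .cellMarkerMeans, numeric(length(markers)),
                      markers = markers, rules = config$rules,
                      imap = config$marker_intensity_map))
    colnames(means) <- paste0("mean_", markers)
    cells <- cbind(geom, as.data.frame(means))
    lab <- .instanceMap(cells, config$image_shape)
    instance_maps[[i]] <- lab
    kept <- sort(unique(lab[lab > 0]))
    area <- tabulate(lab[lab > 0], nbins = max(lab))
    tabs[[i]] <- data.frame(
      cell_id = seq(next_id, length.out = length(kept)),
      fov = i, label = kept, phenotype = ph[kept],
      centroid_row = cells$row[kept], centroid_col = cells$col[kept],
      radius = cells$r[kept], area = area[kept],
      as.data.frame(means[kept, , drop = FALSE]),
      stringsAsFactors = FALSE)
    next_id <- next_id + length(kept)
    for (j in seq_len(config$n_cycles)) {
      mk <- manifest$marker[manifest$cycle == j]
      rend <- renderFov(cells, shifts[j, ], mk, config)
      for (c in seq_len(config$n_channels))
        images[[imageKey(i, j, c)]] <- rend[[c]]
    }
  }
  dataset <- CyclicDataset(images, manifest, config$n_fovs,
                           config$n_cycles, config$n_channels)
  truth <- list(shifts = shifts, instance_maps = instance_maps,
                cell_table = do.call(rbind, tabs))
  list(dataset = dataset, truth = truth)
}

#' Write a synthetic dataset to disk
#'
#' Stain/quench images as 16-bit grayscale TIFF named
#' \code{\{sample\}_f\{fov\}_c\{cycle\}_ch\{channel\}_\{stain|quench\}.tif},
#' instance labels as one 16-bit TIFF per FOV, the cell table as CSV, the
#' manifest as CSV and the planted shifts as JSON.
#'
#' @param gen output of [generateDataset()].
#' @param dir output directory (created if needed).
#' @param sample sample name prefix.
#' @return dir, invisibly.
#' @export
writeDataset <- function(gen, dir, sample = "synthetic") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ds <- gen$dataset
  for (i in seq_len(nFov(ds))) for (j in seq_len(nCycles(ds)))
    for (c in seq_len(nChannels(ds))) {
      el <- ds@images[[imageKey(i, j, c)]]
      for (kind in c("stain", "quench")) {
        f <- file.path(dir, sprintf("%s_f%02d_c%02d_ch%d_%s.tif",
                                    sample, i, j, c, kind))
        tiff::writeTIFF(pmin(pmax(el[[kind]], 0), 1), f,
                        bits.per.sample = 16L)
      }
    }
  for (i in seq_along(gen$truth$instance_maps)) {
    lab <- gen$truth$instance_maps[[i]]
    tiff::writeTIFF(lab / 65535, file.path(dir,
      sprintf("%s_f%02d_labels.tif", sample, i)), bits.per.sample = 16L)
  }
  utils::write.csv(gen$truth$cell_table,
                   file.path(dir, paste0(sample, "_cells.csv")),
                   row.names = FALSE)
  utils::write.csv(markerManifest(ds),
                   file.path(dir, paste0(sample, "_manifest.csv")),
                   row.names = FALSE)
  jsonlite::write_json(
    lapply(seq_len(nrow(gen$truth$shifts)), function(j)
      list(dy = gen$truth$shifts[j, 1], dx = gen$truth$shifts[j, 2])),
    file.path(dir, paste0(sample, "_shifts.json")), auto_unbox = TRUE)
  invisible(dir)
}

#' Read an instance label TIFF written by [writeDataset()]
#' @param path label TIFF path.
#' @return integer matrix of instance labels.
#' @export
readLabelTiff <- function(path) {
  x <- tiff::readTIFF(path)
  matrix(as.integer(round(x * 65535)), nrow(x), ncol(x))
}
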