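#' Build the three-head segmentation network
#'
#' A U-Net style encoder-decoder with \code{depth} 2x2 max-poolings and
#' \code{base_filters} channels at the first level, doubling per level.
#' Three heads share the encoder: (a) a 3-class softmax decoder at input
#' resolution with skip connections, (b) a scalar cell-count regressor on the
#' globally pooled bottleneck, and (c) an auto-encoding decoder
#' reconstructing the input from the bottleneck. Tiles fed to the network
#' must be divisible by \code{2^depth}.
#'
#' @param depth number of pooling levels.
#' @param base_filters channels of the first encoder level.
#' @param in_channels input channels (2: CD45 + DAPI).
#' @param seed weight-initialization seed.
#' @return model object (list of layer weights, class "mifUNet").
#' @export
buildNetwork <- function(depth = 3L, base_filters = 8L, in_channels = 2L,
                         seed = 1L) {
  stopifnot(depth >= 1, base_filters >= 1, in_channels >= 1)
  model <- .unet_init_cpp(as.integer(depth), as.integer(base_filters),
                          as.integer(in_channels), as.integer(seed))
  class(model) <- "mifUNet"
  model
}

#' @export
print.mifUNet <- function(x, ...) {
  npar <- sum(vapply(x$convs, function(l) length(l$W) + length(l$b),
                     numeric(1))) + length(x$countW) + 1
  cat("Three-head U-Net: depth", x$depth, ", base", x$base, "filters,",
      x$cin, "input channels,", format(npar, big.mark = ","),
      "parameters\n")
  invisible(x)
}

#' Forward pass of the network on one tile
#'
#' @param model a [buildNetwork()] model.
#' @param input H x W x C array (C = model input channels); H, W divisible
#'   by \code{2^depth}.
#' @return list: \code{probs} (H x W x 3 softmax array), \code{count}
#'   (scalar), \code{recon} (H x W x C), \code{l2} (parameter L2 norm,
#'   the regularization component).
#' @export
forwardNetwork <- function(model, input) {
  stopifnot(inherits(model, "mifUNet"), length(dim(input)) == 3)
  .unet_forward_cpp(unclass(model), input)
}

#' Assemble training tiles from images and instance maps
#'
#' Tiles the CD45/DAPI channel pair and the matching instance map of each
#' FOV, rasterizes instance labels to the three-class mask, and records the
#' number of instances intersecting each tile.
#'
#' @param cd45_images,dapi_images,instance_maps parallel lists over FOVs.
#' @param tile_size,overlap tiling parameters (see [tileImage()]).
#' @param boundary_width ring width for [rasterizeLabels()].
#' @return list with parallel lists \code{tiles} (H x W x 2 arrays),
#'   \code{labels} (integer class masks), \code{counts}, and \code{fov} ids.
#' @export
makeTrainingTiles <- function(cd45_images, dapi_images, instance_maps,
                              tile_size = 64L, overlap = 0.2,
                              boundary_width = 2L) {
  stopifnot(length(cd45_images) == length(dapi_images),
            length(cd45_images) == length(instance_maps))
  tiles <- list(); labels <- list(); counts <- numeric(0); fovs <- integer(0)
  for (i in seq_along(cd45_images)) {
    mask <- rasterizeLabels(instance_maps[[i]], boundary_width)
    tc <- tileImage(cd45_images[[i]], tile_size, overlap)
    td <- tileImage(dapi_images[[i]], tile_size, overlap)
    tm <- tileImage(mask, tile_size, overlap)
    ti <- tileImage(instance_maps[[i]], tile_size, overlap)
    for (k in seq_along(tc)) {
      x <- array(0, c(tile_size, tile_size, 2L))
      x[, , 1] <- tc[[k]]$tile
      x[, , 2] <- td[[k]]$tile
      tiles[[length(tiles) + 1L]] <- x
      labels[[length(labels) + 1L]] <-
        matrix(as.integer(tm[[k]]$tile), tile_size, tile_size)
      counts <- c(counts,
                  length(setdiff(unique(as.vector(ti[[k]]$tile)), 0)))
      fovs <- c(fovs, i)
    }
  }
  list(tiles = tiles, labels = labels, counts = counts, fov = fovs)
}

# mean per-class pixel F1 between predicted and true class masks
.pixelF1 <- function(pred, truth, classes = 0:2) {
  f1 <- vapply(classes, function(k) {
    tp <- sum(pred == k & truth == k)
    fp <- sum(pred == k & truth != k)
    fn <- sum(pred != k & truth == k)
    if (tp == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}

# pixel classification accuracy of a model over a list of tiles
.tileAccuracy <- function(model, tiles, labels) {
  correct <- 0; total <- 0
  for (k in seq_along(tiles)) {
    p <- forwardNetwork(model, tiles[[k]])$probs
    pred <- apply(p, c(1, 2), which.max) - 1L
    correct <- correct + sum(pred == labels[[k]])
    total <- total + length(labels[[k]])
  }
  correct / total
}

#' Train the segmentation network
#'
#' Tiles with no labeled cells are removed from the training split (class
#' balance); the train/validation split is by FOV when FOV ids are given.
#' With \code{restarts > 1}, training is repeated from different random
#' initializations and the model with the best validation pixel
#' classification accuracy is kept.
#'
#' @param tiles list of H x W x 2 input arrays.
#' @param labels list of matching integer class masks.
#' @param counts numeric vector of per-tile instance counts.
#' @param fov optional integer FOV id per tile (FOV-wise split).
#' @param model optional starting model; by default built to match the data.
#' @param config a [trainConfig()].
#' @param weights a [lossWeights()].
#' @param depth,base_filters architecture of the default model.
#' @param restarts number of random restarts.
#' @return list: \code{model}, \code{history} (per-epoch loss components of
#'   the retained run), \code{val_accuracy}, \code{val_idx} (indices of
#'   held-out tiles).
#' @export
trainNetwork <- function(tiles, labels, counts, fov = NULL, model = NULL,
                         config = trainConfig(), weights = lossWeights(),
                         depth = 3L, base_filters = 8L, restarts = 1L) {
  stopifnot(length(tiles) == length(labels), length(tiles) == length(counts))
  set.seed(config$seed)
  n <- length(tiles)
  if (is.null(fov)) fov <- seq_len(n)
  ufov <- unique(fov)
  nval <- max(1L, round(config$validation_fraction * length(ufov)))
  valFov <- sample(ufov, nval)
  val_idx <- which(fov %in% valFov)
  train_idx <- setdiff(seq_len(n), val_idx)
  # drop empty tiles from the training split only
  train_idx <- train_idx[counts[train_idx] > 0]
  if (!length(train_idx)) stop("no non-empty training tiles")

  best <- NULL
  for (r in seq_len(restarts)) {
    m0 <- if (!is.null(model) && restarts == 1L) model else
      buildNetwork(depth, base_filters, dim(tiles[[1]])[3],
                   seed = config$seed + r - 1L)
    cfg <- config
    cfg$seed <- config$seed + 1000L * (r - 1L)
    fit <- .unet_train_cpp(unclass(m0), tiles[train_idx],
                           labels[train_idx], counts[train_idx],
                           unclass(weights), unclass(cfg))
    mod <- fit$model
    class(mod) <- "mifUNet"
    acc <- if (length(val_idx))
      .tileAccuracy(mod, tiles[val_idx], labels[val_idx]) else NA_real_
    if (is.null(best) || (!is.na(acc) && acc > best$val_accuracy))
      best <- list(model = mod, history = fit$history, val_accuracy = acc,
                   val_idx = val_idx)
  }
  best
}

#' Predict the class mask of a full field of view
#'
#' Tiles the aligned, pre-processed CD45 and DAPI images, runs the network
#' on each tile, stitches per-class probabilities by averaging over overlap
#' regions, and takes the per-pixel argmax.
#'
#' @param model a trained [buildNetwork()] model.
#' @param cd45_img,dapi_img equal-shape matrices.
#' @param tile_size,overlap tiling parameters.
#' @return list: \code{mask} (integer matrix in \{0, 1, 2\}), \code{probs}
#'   (H x W x 3 stitched probability array), \code{count} (sum of tile count
#'   heads, a coarse FOV cell-count estimate).
#' @export
predictFov <- function(model, cd45_img, dapi_img, tile_size = 64L,
                       overlap = 0.2) {
  if (!identical(dim(cd45_img), dim(dapi_img)))
    stop("CD45 and DAPI images differ in shape")
  H <- nrow(cd45_img); W <- ncol(cd45_img)
  tc <- tileImage(cd45_img, tile_size, overlap)
  td <- tileImage(dapi_img, tile_size, overlap)
  acc <- array(0, c(H, W, 3))
  cov <- matrix(0, H, W)
  countSum <- 0
  for (k in seq_along(tc)) {
    x <- array(0, c(tile_size, tile_size, 2L))
    x[, , 1] <- tc[[k]]$tile; x[, , 2] <- td[[k]]$tile
    out <- forwardNetwork(model, x)
    r <- tc[[k]]$row_offset; c <- tc[[k]]$col_offset
    vr <- tc[[k]]$valid_rows; vc <- tc[[k]]$valid_cols
    acc[r + seq_len(vr), c + seq_len(vc), ] <-
      acc[r + seq_len(vr), c + seq_len(vc), , drop = FALSE] +
      out$probs[seq_len(vr), seq_len(vc), , drop = FALSE]
    cov[r + seq_len(vr), c + seq_len(vc)] <-
      cov[r + seq_len(vr), c + seq_len(vc)] + 1
    countSum <- countSum + out$count
  }
  for (k in 1:3) acc[, , k] <- acc[, , k] / cov
  mask <- matrix(apply(acc, c(1, 2), which.max) - 1L, H, W)
  list(mask = mask, probs = acc, count = countSum)
}
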