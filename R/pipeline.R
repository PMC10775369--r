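#' Save / load a trained segmentation model
#'
#' The checkpoint bundles the layer weights with the architecture
#' description (depth, base filters, input channels), so a saved model is
#' self-contained.
#'
#' @param model a [buildNetwork()] model.
#' @param path checkpoint file (.rds).
#' @return path (write) or the model (read).
#' @export
writeModel <- function(model, path) {
  stopifnot(inherits(model, "mifUNet"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  model <- readRDS(path)
  class(model) <- "mifUNet"
  model
}

# md5 content hash of a set of files plus a config fingerprint
.hashOf <- function(files, extra = NULL) {
  files <- sort(files[file.exists(files)])
  parts <- c(unname(tools::md5sum(files)),
             if (!is.null(extra))
               jsonlite::toJSON(unclass(extra), auto_unbox = TRUE,
                                force = TRUE))
  # hash of hashes via a temp file (base R has no in-memory md5)
  tf <- tempfile()
  writeLines(paste(parts, collapse = "\n"), tf)
  on.exit(unlink(tf))
  unname(tools::md5sum(tf))
}

.stageFresh <- function(outdir, stage, hash, artifacts) {
  hf <- file.path(outdir, paste0(".", stage, ".hash"))
  file.exists(hf) && identical(readLines(hf, warn = FALSE)[1], hash) &&
    all(file.exists(artifacts))
}

.stageDone <- function(outdir, stage, hash) {
  writeLines(hash, file.path(outdir, paste0(".", stage, ".hash")))
}

#' Default pipeline configuration
#'
#' @param input_dir directory of raw TIFFs (see [groupImages()]).
#' @param output_dir directory for stage artifacts.
#' @param naming_pattern file naming regex.
#' @param fov_for_alignment FOV used for shift estimation.
#' @param registration a [registrationConfig()].
#' @param checkpoint path to a trained model (.rds), or NULL.
#' @param train a [trainConfig()] to train from scratch, or NULL. Exactly
#'   one of \code{checkpoint}/\code{train} must be supplied unless
#'   \code{use_ground_truth} is TRUE.
#' @param use_ground_truth bypass the network and read planted instance
#'   label TIFFs (\code{*_f<ii>_labels.tif}) from \code{input_dir};
#'   decouples profiling/clustering from training stochasticity.
#' @param tile_size,seg_depth,seg_base network/tiling geometry.
#' @param min_area smallest accepted instance (px^2).
#' @param mad_k outlier-removal multiplier.
#' @param rules phenotype rule table.
#' @param n_neighbors,min_dist,min_cluster_size clustering parameters.
#' @param supervised_embedding use phenotype labels in the projection.
#' @param seed master seed.
#' @return config list (class "mifPipelineConfig").
#' @export
pipelineConfig <- function(input_dir, output_dir,
                           naming_pattern = NULL, fov_for_alignment = 1L,
                           registration = registrationConfig(),
                           checkpoint = NULL, train = NULL,
                           use_ground_truth = FALSE,
                           tile_size = 64L, seg_depth = 3L, seg_base = 8L,
                           min_area = 20L, mad_k = 5,
                           rules = phenotypeRuleTable(),
                           n_neighbors = 15, min_dist = 0.1,
                           min_cluster_size = NULL,
                           supervised_embedding = FALSE, seed = 1L) {
  if (!use_ground_truth && is.null(checkpoint) == is.null(train))
    stop("supply exactly one of 'checkpoint' or 'train' for segmentation")
  if (!is.null(checkpoint) && !file.exists(checkpoint))
    stop("checkpoint file does not exist: ", checkpoint)
  structure(as.list(environment()), class = "mifPipelineConfig")
}

#' Run the full analysis pipeline
#'
#' Orchestrates group -> preprocess -> register -> segment -> profile ->
#' cluster with per-stage artifacts under \code{output_dir} (shifts JSON,
#' instance label TIFFs, cell CSV, cluster CSVs). Stages whose inputs are
#' unchanged (content hash) and whose artifacts exist are skipped. A stage
#' failure stops downstream stages and is reported.
#'
#' @param config a [pipelineConfig()].
#' @return run report (list): per-stage status and timing, cell/FOV counts,
#'   failed FOVs or cycles.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "mifPipelineConfig"))
  outdir <- config$output_dir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(stages = list(), counts = list())
  t_all <- Sys.time()
  inputFiles <- list.files(config$input_dir, full.names = TRUE,
                           pattern = "\\.(tiff?|csv|json)$")

  stage <- function(name, fun) {
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e) e)
    el <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    if (inherits(res, "error")) {
      report$stages[[name]] <<- list(status = "failed",
                                     error = conditionMessage(res),
                                     seconds = el)
      return(FALSE)
    }
    status <- if (isTRUE(attr(res, "skipped"))) "skipped" else "completed"
    report$stages[[name]] <<- list(status = status, seconds = el)
    TRUE
  }

  env <- new.env()

  okGroup <- stage("group", function() {
    args <- list(config$input_dir)
    if (!is.null(config$naming_pattern))
      args$naming_pattern <- config$naming_pattern
    mf <- list.files(config$input_dir, pattern = "_manifest\\.csv$",
                     full.names = TRUE)
    if (length(mf) == 1L)
      args$manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
    env$raw <- do.call(groupImages, args)
    report$counts$fovs <<- nFov(env$raw)
    report$counts$cycles <<- nCycles(env$raw)
    invisible(NULL)
  })
  if (!okGroup) return(.finishReport(report, t_all))

  okPre <- stage("preprocess", function() {
    env$pp <- preprocessDataset(env$raw)
    invisible(NULL)
  })
  if (!okPre) return(.finishReport(report, t_all))

  shiftsFile <- file.path(outdir, "shifts.json")
  regHash <- .hashOf(inputFiles, config$registration)
  okReg <- stage("register", function() {
    if (.stageFresh(outdir, "register", regHash, shiftsFile)) {
      sj <- jsonlite::read_json(shiftsFile, simplifyVector = TRUE)
      sh <- cbind(dy = sj$dy, dx = sj$dx)
      env$reg <- new("RegistrationResult", shifts = sh,
                     trialShifts = rep(list(matrix(0, 0, 2)), nrow(sh)),
                     failed = sj$failed, reason = as.character(sj$reason),
                     objectsFound = as.integer(sj$objects),
                     referenceCycle = config$registration$reference_cycle)
      env$aligned <- applyShiftToDataset(env$pp, env$reg)
      return(structure(list(), skipped = TRUE))
    }
    env$reg <- alignCycleSet(env$pp, config$fov_for_alignment,
                             config$registration)
    sh <- cycleShifts(env$reg)
    jsonlite::write_json(
      data.frame(cycle = seq_len(nrow(sh)), dy = sh[, 1], dx = sh[, 2],
                 failed = registrationFailed(env$reg),
                 reason = env$reg@reason, objects = env$reg@objectsFound),
      shiftsFile, auto_unbox = TRUE, digits = NA)
    .stageDone(outdir, "register", regHash)
    env$aligned <- applyShiftToDataset(env$pp, env$reg)
    report$counts$failed_cycles <<- sum(registrationFailed(env$reg))
    invisible(NULL)
  })
  if (!okReg) return(.finishReport(report, t_all))

  segFiles <- file.path(outdir, sprintf("instances_f%02d.tif",
                                        seq_len(nFov(env$pp))))
  segHash <- .hashOf(c(inputFiles, config$checkpoint),
                     list(gt = config$use_ground_truth,
                          tile = config$tile_size, reg = regHash))
  okSeg <- stage("segment", function() {
    if (.stageFresh(outdir, "segment", segHash, segFiles)) {
      env$instances <- lapply(segFiles, readLabelTiff)
      return(structure(list(), skipped = TRUE))
    }
    mf <- markerManifest(env$aligned)
    findChannel <- function(marker) {
      hit <- mf[mf$marker == marker, ]
      if (!nrow(hit)) stop("panel lacks required marker: ", marker)
      hit[1, ]
    }
    if (config$use_ground_truth) {
      labFiles <- list.files(config$input_dir,
                             pattern = "_f[0-9]+_labels\\.tiff?$",
                             full.names = TRUE)
      if (length(labFiles) != nFov(env$pp))
        stop("ground-truth bypass: expected ", nFov(env$pp),
             " label TIFFs, found ", length(labFiles))
      env$instances <- lapply(sort(labFiles), readLabelTiff)
    } else {
      model <- if (!is.null(config$checkpoint)) readModel(config$checkpoint)
        else {
          cd45c <- findChannel("CD45"); dapic <- findChannel("DAPI")
          cd45 <- lapply(seq_len(nFov(env$aligned)), function(i)
            getImage(env$aligned, i, cd45c$cycle, cd45c$channel))
          dapi <- lapply(seq_len(nFov(env$aligned)), function(i)
            getImage(env$aligned, i, dapic$cycle, dapic$channel))
          labFiles <- list.files(config$input_dir,
                                 pattern = "_f[0-9]+_labels\\.tiff?$",
                                 full.names = TRUE)
          if (length(labFiles) != nFov(env$pp))
            stop("training requires instance label TIFFs in input_dir")
          gtmaps <- lapply(sort(labFiles), readLabelTiff)
          tt <- makeTrainingTiles(cd45, dapi, gtmaps,
                                  tile_size = config$tile_size)
          fit <- trainNetwork(tt$tiles, tt$labels, tt$counts, fov = tt$fov,
                              config = config$train,
                              depth = config$seg_depth,
                              base_filters = config$seg_base)
          writeModel(fit$model, file.path(outdir, "model.rds"))
          fit$model
        }
      cd45c <- findChannel("CD45"); dapic <- findChannel("DAPI")
      env$instances <- lapply(seq_len(nFov(env$aligned)), function(i) {
        pf <- predictFov(model,
                         getImage(env$aligned, i, cd45c$cycle, cd45c$channel),
                         getImage(env$aligned, i, dapic$cycle, dapic$channel),
                         tile_size = config$tile_size)
        extractInstances(pf$mask, config$min_area)
      })
    }
    for (i in seq_along(env$instances))
      tiff::writeTIFF(env$instances[[i]] / 65535, segFiles[i],
                      bits.per.sample = 16L)
    .stageDone(outdir, "segment", segHash)
    report$counts$cells_segmented <<-
      sum(vapply(env$instances, max, numeric(1)))
    invisible(NULL)
  })
  if (!okSeg) return(.finishReport(report, t_all))

  cellsFile <- file.path(outdir, "cells.csv")
  okProf <- stage("profile", function() {
    mf <- markerManifest(env$aligned)
    tables <- list()
    for (i in seq_len(nFov(env$aligned))) {
      if (max(env$instances[[i]]) == 0) next
      stack <- list()
      for (r in seq_len(nrow(mf)))
        stack[[mf$marker[r]]] <-
          getImage(env$aligned, i, mf$cycle[r], mf$channel[r])
      tables[[length(tables) + 1L]] <-
        aggregateCellSignals(env$instances[[i]], stack, fov = i)
    }
    if (!length(tables)) stop("no cells found in any FOV")
    tab <- combineCellTables(tables)
    report$counts$cells_total <<- ncol(tab)
    tab <- removeOutliersMAD(tab, k = config$mad_k)
    report$counts$cells_filtered <<- length(attr(tab, "removed"))
    tab <- logTransform(tab)
    tab <- callPositivity(tab)
    tab <- assignPhenotypes(tab, config$rules)
    env$cells <- tab
    writeCellTable(tab, cellsFile)
    invisible(NULL)
  })
  if (!okProf) return(.finishReport(report, t_all))

  okClust <- stage("cluster", function() {
    tab <- env$cells
    labels <- if (config$supervised_embedding) phenotypes(tab) else NULL
    emb <- embedCells(tab, n_neighbors = config$n_neighbors,
                      min_dist = config$min_dist,
                      phenotype_labels = labels, seed = config$seed)
    cl <- clusterCells(emb, min_cluster_size = config$min_cluster_size)
    report$counts$n_clusters <<- cl$n_clusters
    df <- asCellFrame(tab)
    df$umap1 <- emb$coords[, 1]; df$umap2 <- emb$coords[, 2]
    df$cluster <- cl$cluster
    utils::write.csv(df, file.path(outdir, "cells_clustered.csv"),
                     row.names = FALSE)
    prof <- clusterProfiles(tab, cl)
    utils::write.csv(as.data.frame(prof),
                     file.path(outdir, "cluster_profiles.csv"))
    comp <- composition(cl, phenotypes(tab))
    utils::write.csv(as.data.frame(comp$counts),
                     file.path(outdir, "composition.csv"), row.names = FALSE)
    invisible(NULL)
  })
  .finishReport(report, t_all)
}

.finishReport <- function(report, t_all) {
  report$seconds_total <- as.numeric(difftime(Sys.time(), t_all,
                                              units = "secs"))
  failed <- names(Filter(function(s) s$status == "failed", report$stages))
  report$ok <- length(failed) == 0L
  report$failed_stage <- if (length(failed)) failed[1] else NA_character_
  class(report) <- "mifRunReport"
  report
}

#' @export
print.mifRunReport <- function(x, ...) {
  cat("Pipeline run:", if (x$ok) "OK" else
      paste0("FAILED at '", x$failed_stage, "'"), "\n")
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    cat(sprintf("  %-10s %-9s %6.1fs%s\n", nm, s$status, s$seconds,
                if (!is.null(s$error)) paste0("  [", s$error, "]") else ""))
  }
  for (nm in names(x$counts))
    cat(sprintf("  %s: %s\n", nm, x$counts[[nm]]))
  invisible(x)
}
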