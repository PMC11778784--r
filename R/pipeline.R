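## pipeline: batch driver tying the modules into the segmentation ->
## morphometry workflow, with a JSON run config, per-stage artifacts and a
## machine-readable manifest. One config describes one specimen; heatmaps
## of many specimens are averaged separately (averageHeatmapFiles).

#' Read and validate a run configuration
#'
#' JSON fields: `stack` (TIFF path), `output_dir`, `spacing` (dz, dy, dx),
#' `channels` (`outer`, `inner` layer names in stack order), `threshold`
#' (`policy`, optional `level`, `min_area`), `poles` (`A`, `B` xyz),
#' `disc` (`centre`, `normal`, `radius`, optional `atrial_side`),
#' `dorsal_ref`, optional `triad` (3 x 3 rows), `unroll` (`n_planes`,
#' `n_angle_bins`, `extension_frac`), `cells` (`nuclei_csv`,
#' `k_neighbours`), `seed`. Vectors are normalized on load; referenced
#' input files must exist.
#'
#' @param path JSON config path.
#' @return validated config list (class `cardiomorph_config`).
#' @export
readRunConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validateRunConfig(cfg)
}

#' @rdname readRunConfig
#' @param cfg a config list (as from JSON).
#' @export
validateRunConfig <- function(cfg) {
  if (is.null(cfg$stack)) stop("config field 'stack' is required")
  if (!file.exists(cfg$stack)) stop("stack file not found: ", cfg$stack)
  if (is.null(cfg$output_dir)) stop("config field 'output_dir' is required")
  err <- .checkSpacing(cfg$spacing)
  if (!is.null(err)) stop("config spacing: ", err)
  if (is.null(cfg$channels$outer) || is.null(cfg$channels$inner))
    stop("config must name the outer and inner channel")
  if (!is.null(cfg$dorsal_ref)) cfg$dorsal_ref <- .normalize(as.numeric(cfg$dorsal_ref))
  if (!is.null(cfg$disc))
    cfg$disc_obj <- CutDisc(as.numeric(cfg$disc$centre),
                            as.numeric(cfg$disc$normal),
                            as.numeric(cfg$disc$radius))
  if (!is.null(cfg$triad)) {
    cfg$triad <- do.call(rbind, lapply(seq_len(3), function(r)
      .normalize(as.numeric(unlist(cfg$triad[r, ])))))
  }
  if (!is.null(cfg$cells$nuclei_csv) && !file.exists(cfg$cells$nuclei_csv))
    stop("nuclei CSV not found: ", cfg$cells$nuclei_csv)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  class(cfg) <- "cardiomorph_config"
  cfg
}

#' Write a run configuration as JSON
#'
#' @param cfg config list.
#' @param path output path.
#' @export
writeRunConfig <- function(cfg, path) {
  cfg$disc_obj <- NULL
  class(cfg) <- NULL
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.stageOrder <- c("segment", "ecm", "mesh", "centreline", "partition",
                 "morphometry", "unroll", "cells")

#' Run the analysis pipeline
#'
#' Executes the requested stages in canonical order, writing per-stage
#' artifacts (masks, meshes, CSVs) under `output_dir` and a manifest JSON
#' listing parameters and MD5 hashes of every output. Stage dependencies
#' must be satisfied either by including the upstream stage or by artifacts
#' of a previous run in the same `output_dir`; otherwise a dependency error
#' names the missing stage. Rerunning an identical config reproduces
#' hash-identical outputs for all deterministic stages.
#'
#' @param config a config list from [readRunConfig()].
#' @param stages subset of `c("segment", "ecm", "mesh", "centreline",
#'   "partition", "morphometry", "unroll", "cells")`.
#' @return (invisibly) the manifest list.
#' @export
runPipeline <- function(config, stages = .stageOrder) {
  if (!inherits(config, "cardiomorph_config"))
    config <- validateRunConfig(config)
  bad <- setdiff(stages, .stageOrder)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- .stageOrder[.stageOrder %in% stages]
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  store <- new.env(parent = emptyenv())
  manifest <- list(config = unclass(config)[setdiff(names(config), "disc_obj")],
                   package_version = as.character(utils::packageVersion("cardiomorph")),
                   stages = list())
  chO <- config$channels$outer
  chI <- config$channels$inner

  need <- function(what) {
    got <- get0(what, envir = store, ifnotfound = NULL)
    if (!is.null(got)) return(got)
    # fall back to artifacts of a previous run
    loaded <- switch(what,
      centreline = {
        f <- file.path(out, "centreline", "centreline.csv")
        if (file.exists(f)) {
          df <- utils::read.csv(f)
          Centreline(as.matrix(df[, c("x", "y", "z")]), df$arclength,
                     df$inscribed_radius,
                     anchors = rbind(as.numeric(config$poles$A),
                                     as.numeric(config$poles$B)))
        } else NULL
      },
      mesh_outer_ext = .loadPLY(file.path(out, "mesh", "outer_external.ply")),
      mesh_outer_int = .loadPLY(file.path(out, "mesh", "outer_internal.ply")),
      mesh_inner_ext = .loadPLY(file.path(out, "mesh", "inner_external.ply")),
      thickness_mesh = .loadPLY(file.path(out, "morphometry", "thickness_outer.ply")),
      NULL)
    if (is.null(loaded))
      stop("dependency not satisfied: stage producing '", what,
           "' has not run and no artifact was found under ", out)
    store[[what]] <- loaded
    loaded
  }

  addFiles <- function(stage, files) {
    h <- tools::md5sum(files)
    manifest$stages[[stage]] <<- list(files = as.list(h))
  }

  for (st in stages) {
    sdir <- file.path(out, st)
    dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
    files <- character(0)
    if (st == "segment") {
      stack <- readStack(config$stack, spacing = config$spacing,
                         channelNames = c(chO, chI))
      pol <- list(threshold = config$threshold$policy %||% "auto",
                  level = config$threshold$level,
                  minArea = config$threshold$min_area %||% 4)
      ov <- if (!is.null(config$overrides) && file.exists(config$overrides))
        readContourOverrides(config$overrides) else NULL
      lib <- buildContourLibrary(stack, policy = pol, overrides = ov)
      writeContourLibrary(lib, sdir)
      store$lib <- lib
      files <- list.files(sdir, full.names = TRUE)
      files <- files[!grepl("\\.json$", files) | TRUE]
    } else if (st == "ecm") {
      lib <- store$lib %||% stop("dependency not satisfied: run 'segment' first")
      ecm <- ecmMask(libraryMask(lib, chO, "filled_internal"),
                     libraryMask(lib, chI, "filled_external"))
      store$ecm <- ecm
      mst <- IntensityStack(array(as.integer(maskVoxels(ecm)),
                                  dim(maskVoxels(ecm))),
                            spacing = spacing(ecm), channelNames = "ECM",
                            origin = origin(ecm))
      writeStack(mst, file.path(sdir, "ecm.tif"), bits = 8L)
      vols <- compartmentVolumes(lib, ecm, chO, chI)
      writeVolumesCsv(vols, file.path(sdir, "compartment_volumes_um3.csv"))
      files <- list.files(sdir, full.names = TRUE)
    } else if (st == "mesh") {
      lib <- store$lib %||% stop("dependency not satisfied: run 'segment' first")
      for (spec in list(c("outer", "filled_external", "outer_external"),
                        c("outer", "filled_internal", "outer_internal"),
                        c("inner", "filled_external", "inner_external"),
                        c("inner", "filled_internal", "inner_internal"))) {
        ch <- if (spec[1] == "outer") chO else chI
        m <- maskToMesh(libraryMask(lib, ch, spec[2]))
        store[[paste0("mesh_", spec[1], "_",
                      substr(spec[2], 8, 10))]] <- m
        writePLY(m, file.path(sdir, paste0(spec[3], ".ply")))
      }
      files <- list.files(sdir, full.names = TRUE)
    } else if (st == "centreline") {
      lib <- store$lib %||% stop("dependency not satisfied: run 'segment' first")
      if (is.null(config$poles)) stop("config field 'poles' is required")
      lumen <- libraryMask(lib, chO, "filled_internal")
      cl <- extractCentreline(lumen, as.numeric(config$poles$A),
                              as.numeric(config$poles$B))
      store$centreline <- cl
      writeCentrelineCsv(cl, file.path(sdir, "centreline.csv"))
      writeCentrelineVTK(cl, file.path(sdir, "centreline.vtk"))
      lm <- loopingMetrics(cl)
      utils::write.csv(data.frame(metric = names(lm),
                                  value = unlist(lm),
                                  units = c("um", "um", "dimensionless")),
                       file.path(sdir, "looping_metrics.csv"),
                       row.names = FALSE)
      files <- list.files(sdir, full.names = TRUE)
    } else if (st == "partition") {
      lib <- store$lib %||% stop("dependency not satisfied: run 'segment' first")
      if (is.null(config$disc_obj)) stop("config field 'disc' is required")
      heart <- libraryMask(lib, chO, "filled_external")
      part <- splitByDisc(heart, config$disc_obj,
                          atrialSide = config$disc$atrial_side %||% "positive")
      store$partition <- part
      vv <- prod(spacing(heart))
      utils::write.csv(data.frame(
        chamber = c("atrium", "ventricle"),
        volume_um3 = c(sum(part@labels == 1L) * vv,
                       sum(part@labels == 2L) * vv),
        cut_area_um2 = part@cutArea),
        file.path(sdir, "chamber_volumes_um3.csv"), row.names = FALSE)
      files <- list.files(sdir, full.names = TRUE)
    } else if (st == "morphometry") {
      mOuterExt <- need("mesh_outer_ext")
      mOuterInt <- need("mesh_outer_int")
      cl <- need("centreline")
      triad <- config$triad %||% diag(3)
      fit <- fitEllipsoid(mOuterExt, triad)
      utils::write.csv(data.frame(
        quantity = c("width_um", "length_um", "depth_um", "asphericity"),
        value = c(semiAxes(fit), asphericity(fit))),
        file.path(sdir, "ellipsoid.csv"), row.names = FALSE)
      bal <- ballooningMap(mOuterExt, cl)
      writePLY(bal, file.path(sdir, "ballooning_external.ply"))
      writeScalarCsv(bal, file.path(sdir, "ballooning_external.csv"))
      thk <- thicknessMap(mOuterInt, mOuterExt, carrier = "outer")
      store$thickness_mesh <- thk
      writePLY(thk, file.path(sdir, "thickness_outer.ply"))
      writeScalarCsv(thk, file.path(sdir, "thickness_outer.csv"))
      files <- list.files(sdir, full.names = TRUE)
    } else if (st == "unroll") {
      thk <- need("thickness_mesh")
      cl <- need("centreline")
      if (is.null(config$dorsal_ref))
        stop("config field 'dorsal_ref' is required")
      up <- config$unroll %||% list()
      ext <- extendCentreline(cl, (up$extension_frac %||% 0.05) *
                                    max(clArclength(cl)))
      hm <- unrollHeatmap(thk, ext, config$dorsal_ref,
                          nPlanes = up$n_planes %||% 100L,
                          nAngleBins = up$n_angle_bins %||% 72L)
      exportHeatmapCsv(hm, file.path(sdir, "thickness_heatmap.csv"))
      files <- list.files(sdir, full.names = TRUE)
    } else if (st == "cells") {
      if (is.null(config$cells$nuclei_csv))
        stop("config field 'cells$nuclei_csv' is required")
      nuc <- loadNuclei(config$cells$nuclei_csv)
      if (is.null(config$disc_obj)) stop("config field 'disc' is required")
      nuc <- assignChambers(nuc, config$disc_obj,
                            atrialSide = config$disc$atrial_side %||% "positive")
      cl <- need("centreline")
      nuc <- assignRegions(nuc, cl, config$dorsal_ref)
      res <- internuclearDistance(nuc, k = config$cells$k_neighbours %||% 4L)
      writeNucleiCsv(res$nuclei, file.path(sdir, "nuclei.csv"))
      utils::write.csv(res$per_chamber,
                       file.path(sdir, "ind_per_chamber_um.csv"),
                       row.names = FALSE)
      utils::write.csv(res$per_region,
                       file.path(sdir, "ind_per_region_um.csv"),
                       row.names = FALSE)
      files <- list.files(sdir, full.names = TRUE)
    }
    addFiles(st, files)
  }

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

.loadPLY <- function(path) if (file.exists(path)) readPLY(path) else NULL

#' Average heatmap CSVs across specimens
#'
#' @param paths character vector of heatmap CSVs from [exportHeatmapCsv()].
#' @param outPrefix output path prefix; writes `<prefix>_mean.csv`,
#'   `<prefix>_sd.csv`, `<prefix>_count.csv`.
#' @return the averaged [Heatmap2D-class], invisibly.
#' @export
averageHeatmapFiles <- function(paths, outPrefix) {
  maps <- lapply(paths, readHeatmapCsv)
  avg <- averageHeatmaps(maps)
  exportHeatmapCsv(avg, paste0(outPrefix, "_mean.csv"))
  sdMap <- avg; sdMap@values <- avg@sd
  exportHeatmapCsv(sdMap, paste0(outPrefix, "_sd.csv"))
  cntMap <- avg; cntMap@values <- avg@count + 0
  exportHeatmapCsv(cntMap, paste0(outPrefix, "_count.csv"))
  invisible(avg)
}
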