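# Batch orchestration: configuration, staged per-image processing with
# idempotent re-runs, and tabular/JSON exports of per-cell foci statistics.

PIPELINE_STAGES <- c("segment", "preprocess", "detect", "classify", "coloc",
                     "export")

#' Build a pipeline run configuration
#'
#' All physical parameters are denominated in nm and converted to px via
#' `pixel_size`, so one configuration transfers between images of equal
#' magnification. The resolved configuration is hashed
#' ([config_hash()]) and the hash is stamped into every output file name's
#' sidecar marker, making runs reproducible and re-runs skippable.
#'
#' @param images list of image entries, each a list with `id`, `brightfield`
#'   (TIFF/PNG path), `stack` (multi-page TIFF path), optional `stack2`
#'   (second channel) and optional `mask` (precomputed label/binary mask
#'   TIFF bypassing segmentation).
#' @param out_dir output directory.
#' @param pixel_size nm/px.
#' @param segmentation overrides for [segmentation_params()].
#' @param nlm list with `patch_size`, `patch_distance`, `strength`.
#' @param foci list with `L_min_nm`, `L_max_nm`, `n_levels`, `n_eval`,
#'   `area_scale`.
#' @param classifier list with either `model` (path to a saved model) or
#'   `thresholds` (named list of feature bounds), plus `seed`.
#' @return a `run_config` list.
#' @export
run_config <- function(images, out_dir, pixel_size = 40.7,
                       segmentation = list(), nlm = list(),
                       foci = list(), classifier = list()) {
  seg <- do.call(segmentation_params, c(list(pixel_size = pixel_size), segmentation))
  nlm_def <- list(patch_size = 5L, patch_distance = 6L, strength = 0.05)
  nlm_def[names(nlm)] <- nlm
  foci_def <- list(L_min_nm = 250, L_max_nm = 2500, n_levels = 64L,
                   n_eval = 32L, area_scale = 1)
  foci_def[names(foci)] <- foci
  cls_def <- list(model = NULL, thresholds = NULL, seed = 1L)
  cls_def[names(classifier)] <- classifier
  structure(list(images = images, out_dir = out_dir, pixel_size = pixel_size,
                 segmentation = seg, nlm = nlm_def, foci = foci_def,
                 classifier = cls_def),
            class = "run_config")
}

#' Read a configuration file (YAML or JSON)
#' @param path file path; `.json` is parsed as JSON, anything else as YAML.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' Hash of a resolved configuration
#'
#' Covers the inputs and every analysis parameter but not `out_dir`, so two
#' runs of the same analysis into different directories share a hash (and
#' must produce byte-identical JSON/CSV outputs).
#'
#' @param config a `run_config`.
#' @return md5 string.
#' @export
config_hash <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL
  md5_of(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                          null = "null", force = TRUE))
}

read_image_any <- function(path) {
  img <- if (grepl("\\.png$", path)) png::readPNG(path)
  else tiff::readTIFF(path, all = FALSE)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

read_stack <- function(path) {
  sl <- tiff::readTIFF(path, all = TRUE)
  sl <- lapply(sl, function(s) if (length(dim(s)) == 3) s[, , 1] else s)
  array(unlist(sl), c(dim(sl[[1]]), length(sl)))
}

marker_path <- function(dir, stage) file.path(dir, paste0(".done_", stage))

stage_done <- function(dir, stage, hash) {
  mp <- marker_path(dir, stage)
  file.exists(mp) && identical(readLines(mp, warn = FALSE)[1], hash)
}

mark_stage <- function(dir, stage, hash) writeLines(hash, marker_path(dir, stage))

outlines_to_json <- function(outlines) {
  lapply(outlines, function(ol) list(
    polygon = unname(apply(ol$polygon - 1, 1, function(r) r, simplify = FALSE)),
    centroid = ol$centroid - 1, area_px2 = ol$area,
    equivalent_radius_px = ol$equivalent_radius))
}

foci_to_json <- function(foci, features, region, pixel_size) {
  lapply(seq_along(foci), function(i) {
    fo <- foci[[i]]
    off <- region$offset - 1  # to full-image coordinates
    list(polygon = unname(apply(sweep(fo$contour$vertices, 2, -(off - 1), "-") - 1,
                                1, function(r) r, simplify = FALSE)),
         level = fo$level,
         area_px2 = fo$area, area_nm2 = fo$area * pixel_size^2,
         centroid = fo$centroid + off - 1,
         intensity_max = fo$intensity_max, intensity_min = fo$intensity_min,
         intensity_mean = fo$intensity_mean,
         features = as.list(features[i, ]))
  })
}

write_json_det <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
}

# Process one channel of one image: regions + detections + features.
detect_channel <- function(image, outlines, cfg) {
  proj <- denoise_nlm(image, cfg$nlm$patch_size, cfg$nlm$patch_distance,
                      cfg$nlm$strength)
  regions <- extract_cells(proj, outlines, cfg$pixel_size)
  dets <- lapply(regions, function(rg)
    detect_foci(rg, cfg$foci$L_min_nm, cfg$foci$L_max_nm,
                cfg$foci$n_levels, cfg$foci$n_eval, cfg$foci$area_scale))
  feats <- vector("list", length(regions))
  for (i in seq_along(regions)) {
    fm <- extract_features_cell(dets[[i]]$foci, regions[[i]])
    dets[[i]]$foci <- dets[[i]]$foci[attr(fm, "kept")]
    feats[[i]] <- fm
  }
  list(regions = regions, detections = dets, features = feats)
}

#' Run the staged batch pipeline
#'
#' Stages (prefix-closed): segment, preprocess, detect, classify, coloc,
#' export. Per image, a subdirectory of `config$out_dir` receives the label
#' mask (16-bit TIFF), outlines JSON, projected/denoised channel TIFFs, foci
#' JSON (with features), label CSV, and colocalization CSV; `export` writes
#' batch-level statistics tables. Completed stages are skipped on re-runs
#' with an identical configuration hash unless `force = TRUE`. Per-image
#' failures are logged and skipped; the run fails only if every image fails.
#'
#' @param config a `run_config` (or path, see [read_config()]).
#' @param stages character vector, a prefix of the stage list.
#' @param force recompute even when markers are up to date.
#' @return invisibly, the run directory.
#' @export
run_pipeline <- function(config, stages = PIPELINE_STAGES, force = FALSE) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  if (!identical(stages, PIPELINE_STAGES[seq_along(stages)]))
    stop("stages must form a prefix of: ", paste(PIPELINE_STAGES, collapse = " -> "))
  hash <- config_hash(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(hash, file.path(config$out_dir, "config.hash"))
  write_json_det(unclass(config), file.path(config$out_dir, "config.json"))
  failures <- 0L
  all_stats <- list()
  for (entry in config$images) {
    res <- tryCatch(
      run_pipeline_image(entry, config, stages, hash, force),
      error = function(e) {
        message("image ", entry$id, " failed: ", conditionMessage(e))
        structure(list(), class = "pipeline_failure")
      })
    if (inherits(res, "pipeline_failure")) failures <- failures + 1L
    else if (!is.null(res)) all_stats[[entry$id]] <- res
  }
  if (length(config$images) && failures == length(config$images))
    stop("all images failed")
  if ("export" %in% stages) {
    st <- export_stats(all_stats)
    write.csv(st$per_focus, file.path(config$out_dir, "stats_per_focus.csv"),
              row.names = FALSE)
    write.csv(st$per_cell, file.path(config$out_dir, "stats_per_cell.csv"),
              row.names = FALSE)
    write.csv(st$summary, file.path(config$out_dir, "stats_summary.csv"),
              row.names = FALSE)
  }
  invisible(config$out_dir)
}

run_pipeline_image <- function(entry, cfg, stages, hash, force) {
  dir <- file.path(cfg$out_dir, entry$id)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # --- segment ---
  mask_path <- file.path(dir, "cellmask.tif")
  if (force || !stage_done(dir, "segment", hash)) {
    outlines <- if (!is.null(entry$mask)) {
      outlines_from_mask(round(read_image_any(entry$mask) * 65535))
    } else {
      segment_cells(read_image_any(entry$brightfield), cfg$segmentation)
    }
    img_dim <- if (length(outlines)) dim(outlines[[1]]$mask) else
      dim(read_image_any(entry$brightfield %||% entry$mask))
    lab <- matrix(0L, img_dim[1], img_dim[2])
    for (i in seq_along(outlines)) lab[outlines[[i]]$mask] <- i
    tiff::writeTIFF(lab / 65535, mask_path, bits.per.sample = 16L)
    write_json_det(outlines_to_json(outlines), file.path(dir, "outlines.json"))
    mark_stage(dir, "segment", hash)
  }
  if (!"preprocess" %in% stages) return(NULL)
  outlines <- outlines_from_mask(round(read_image_any(mask_path) * 65535))
  # --- preprocess ---
  proj_path <- file.path(dir, "projected_ch0.tif")
  if (force || !stage_done(dir, "preprocess", hash)) {
    proj <- max_project(read_stack(entry$stack))
    tiff::writeTIFF(pmin(pmax(proj, 0), 1), proj_path)
    if (!is.null(entry$stack2)) {
      proj2 <- max_project(read_stack(entry$stack2))
      tiff::writeTIFF(pmin(pmax(proj2, 0), 1),
                      file.path(dir, "projected_ch1.tif"))
    }
    mark_stage(dir, "preprocess", hash)
  }
  if (!"detect" %in% stages) return(NULL)
  # --- detect (+features) ---
  ch0 <- detect_channel(read_image_any(proj_path), outlines, cfg)
  if (!stage_done(dir, "detect", hash) || force) {
    json <- lapply(seq_along(ch0$regions), function(i)
      list(cell = i - 1L,
           n_candidates = length(ch0$detections[[i]]$candidates),
           foci = foci_to_json(ch0$detections[[i]]$foci, ch0$features[[i]],
                               ch0$regions[[i]], cfg$pixel_size)))
    write_json_det(json, file.path(dir, "foci_ch0.json"))
    mark_stage(dir, "detect", hash)
  }
  if (!"classify" %in% stages) return(NULL)
  # --- classify ---
  feats <- do.call(rbind, ch0$features)
  index <- do.call(rbind, lapply(seq_along(ch0$features), function(i)
    if (nrow(ch0$features[[i]]))
      data.frame(cell = i, focus = seq_len(nrow(ch0$features[[i]])))))
  labels <- if (!is.null(feats) && nrow(feats)) {
    if (!is.null(cfg$classifier$model)) {
      predict_foci(load_model(cfg$classifier$model), feats)
    } else if (!is.null(cfg$classifier$thresholds)) {
      threshold_classify(feats, cfg$classifier$thresholds)
    } else rep(1L, nrow(feats))
  } else integer(0)
  if (!stage_done(dir, "classify", hash) || force) {
    lab_df <- if (length(labels))
      cbind(image = entry$id, index, label = labels)
    else data.frame(image = character(0), cell = integer(0),
                    focus = integer(0), label = integer(0))
    write.csv(lab_df, file.path(dir, "labels.csv"), row.names = FALSE)
    mark_stage(dir, "classify", hash)
  }
  # --- coloc ---
  coloc <- NULL
  if ("coloc" %in% stages && !is.null(entry$stack2)) {
    ch1 <- detect_channel(read_image_any(file.path(dir, "projected_ch1.tif")),
                          outlines, cfg)
    recs <- lapply(seq_along(ch0$regions), function(i)
      coloc_cell(ch0$regions[[i]], ch1$regions[[i]],
                 ch0$detections[[i]]$foci, ch1$detections[[i]]$foci, i))
    pairs <- do.call(rbind, lapply(recs, function(r)
      if (nrow(r$pairs)) cbind(image = entry$id, cell = r$cell, r$pairs)))
    cells <- data.frame(image = entry$id,
                        cell = vapply(recs, `[[`, numeric(1), "cell"),
                        pearson = vapply(recs, `[[`, numeric(1), "pearson"))
    if (!stage_done(dir, "coloc", hash) || force) {
      write.csv(cells, file.path(dir, "coloc_cells.csv"), row.names = FALSE)
      if (!is.null(pairs))
        write.csv(pairs, file.path(dir, "coloc_pairs.csv"), row.names = FALSE)
      mark_stage(dir, "coloc", hash)
    }
    coloc <- list(cells = cells, pairs = pairs)
  }
  list(image = entry$id, regions = ch0$regions, detections = ch0$detections,
       features = ch0$features, labels = labels, index = index, coloc = coloc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-cell and summary statistics of classified foci
#'
#' Builds three tables from pipeline results: per focus (area in px^2/nm^2
#' and raw min/mean/max brightness — raw, unnormalized microscope values),
#' per cell (focus count), and a batch summary (mean foci per cell,
#' percentage of cells with at least one classified focus).
#'
#' @param results named list of per-image results as produced inside
#'   [run_pipeline()] (fields `regions`, `detections`, `labels`, `index`).
#' @return list of data.frames `per_focus`, `per_cell`, `summary`.
#' @export
export_stats <- function(results) {
  pf <- list(); pc <- list()
  for (res in results) {
    if (is.null(res)) next
    ncells <- length(res$regions)
    counts <- integer(ncells)
    for (ci in seq_len(ncells)) {
      rows <- which(res$index$cell == ci)
      foci <- res$detections[[ci]]$foci
      for (k in seq_along(rows)) {
        if (res$labels[rows[k]] != 1L) next
        fo <- foci[[k]]
        counts[ci] <- counts[ci] + 1L
        px2 <- fo$area
        pf[[length(pf) + 1L]] <- data.frame(
          image = res$image, cell = ci, focus = k,
          area_px2 = px2,
          area_nm2 = px2 * res$regions[[ci]]$pixel_size^2,
          brightness_max = fo$intensity_max,
          brightness_min = fo$intensity_min,
          brightness_mean = fo$intensity_mean)
      }
      pc[[length(pc) + 1L]] <- data.frame(image = res$image, cell = ci,
                                          n_foci = counts[ci])
    }
  }
  per_focus <- if (length(pf)) do.call(rbind, pf) else
    data.frame(image = character(0), cell = integer(0), focus = integer(0),
               area_px2 = numeric(0), area_nm2 = numeric(0),
               brightness_max = numeric(0), brightness_min = numeric(0),
               brightness_mean = numeric(0))
  per_cell <- if (length(pc)) do.call(rbind, pc) else
    data.frame(image = character(0), cell = integer(0), n_foci = integer(0))
  summary <- data.frame(
    n_cells = nrow(per_cell),
    n_foci = sum(per_cell$n_foci),
    mean_foci_per_cell = if (nrow(per_cell)) mean(per_cell$n_foci) else 0,
    pct_cells_with_foci = if (nrow(per_cell))
      100 * mean(per_cell$n_foci >= 1) else 0)
  list(per_focus = per_focus, per_cell = per_cell, summary = summary)
}
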