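# Pipeline configuration and file-level orchestration. These functions back
# the `veinmap` command-line tool (inst/cli/veinmap) and are usable directly.

#' Pipeline configuration
#'
#' Nested list of every tunable knob, with validated keys: unknown keys are
#' rejected so a typo cannot silently fall back to a default. The structure
#' round-trips through YAML ([load_config()] / [save_config()]).
#'
#' @param ... named overrides, either nested lists (`clahe = list(clip =
#'   0.02)`) or dotted keys (`"clahe.clip" = 0.02`).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    version = "1",
    io = list(bit_depth = 14L, amplitude_floor = 0),
    preprocess = list(invert = FALSE),
    otsu = list(bins = 0L),   # 0 = native 2^bit_depth levels
    mask = list(widths = c(10L, 15L)),
    clahe = list(tiles = c(8L, 8L), clip = 0.01, bins = 256L),
    adjust = list(saturation = 0.01),
    extract = list(method = "kmeans"),
    maxcurv = list(sigma = 2),
    kmeans = list(K = 3L, seed = 1L, tol = 1e-6, max_iter = 100L),
    ransac = list(epsilon = 2, iterations = 2000L, seed = 1L),
    register = list(fill_radius = 4),
    eval = list(roi = "intersection")
  )
  overrides <- list(...)
  if (length(overrides) == 1L && is.list(overrides[[1L]]) &&
      is.null(names(overrides))) {
    overrides <- overrides[[1L]]
  }
  for (key in names(overrides)) {
    if (grepl(".", key, fixed = TRUE)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
      vm_assert(length(parts) == 2L && parts[1L] %in% names(cfg) &&
                  parts[2L] %in% names(cfg[[parts[1L]]]),
                "veinmap_config_error", sprintf("unknown config key: %s", key))
      cfg[[parts[1L]]][[parts[2L]]] <- overrides[[key]]
    } else {
      vm_assert(key %in% names(cfg), "veinmap_config_error",
                sprintf("unknown config key: %s", key))
      if (is.list(cfg[[key]])) {
        sub <- overrides[[key]]
        vm_assert(is.list(sub), "veinmap_config_error",
                  sprintf("config section '%s' must be a list", key))
        for (sk in names(sub)) {
          vm_assert(sk %in% names(cfg[[key]]), "veinmap_config_error",
                    sprintf("unknown config key: %s.%s", key, sk))
          cfg[[key]][[sk]] <- sub[[sk]]
        }
      } else {
        cfg[[key]] <- overrides[[key]]
      }
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
load_config <- function(path) {
  vm_assert(file.exists(path), "veinmap_io_error",
            sprintf("config not found: %s", path))
  pipeline_config(yaml::read_yaml(path))
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run vein detection on a SWIR image file
#'
#' Reads the image, runs [detect_veins()], writes the binary vein mask as an
#' 8-bit PNG and a JSON report (threshold, per-stage mask areas, timing).
#'
#' @param config a [pipeline_config()].
#' @param swir_path input SWIR image (TIFF/PNG).
#' @param mask_path output mask PNG.
#' @param report_path optional output report JSON.
#' @return the report, invisibly.
#' @export
run_detect <- function(config, swir_path, mask_path,
                       report_path = NULL) {
  t0 <- proc.time()[["elapsed"]]
  img <- read_swir(swir_path, bit_depth = config$io$bit_depth)
  det <- detect_veins(img, method = config$extract$method, config = config)
  write_mask(det$mask, mask_path)
  report <- list(
    input = swir_path,
    method = det$method,
    threshold = det$threshold,
    foreground_px = sum(det$roi$foreground),
    mask_narrow_px = sum(det$roi$mask_narrow),
    mask_wide_px = sum(det$roi$mask_wide),
    vein_px = sum(det$mask),
    elapsed_s = proc.time()[["elapsed"]] - t0
  )
  if (!is.null(report_path)) {
    jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}

#' Fit the TOF-to-SWIR transform from a control-point file
#'
#' Reads `x1,y1,x2,y2` pairs, optionally undistorts the TOF side with the
#' given intrinsics, runs [ransac_register()] and writes the transform JSON.
#'
#' @param config a [pipeline_config()] (RANSAC knobs under `ransac`).
#' @param pairs_path control-point CSV.
#' @param transform_path output transform JSON.
#' @param intrinsics_path optional TOF intrinsics JSON; when given, the F1
#'   side is distortion-corrected before fitting.
#' @return the fitted [linear_map2d()], invisibly.
#' @export
run_calibrate <- function(config, pairs_path, transform_path,
                          intrinsics_path = NULL) {
  pairs <- read_control_points(pairs_path)
  if (!is.null(intrinsics_path)) {
    pairs <- undistort_pairs(pairs, read_intrinsics(intrinsics_path))
  }
  map <- ransac_register(pairs,
                         epsilon = config$ransac$epsilon,
                         iterations = config$ransac$iterations,
                         seed = config$ransac$seed)
  write_transform(map, transform_path)
  invisible(map)
}

#' Localize detected veins in 3D
#'
#' Loads the SWIR image, vein mask, TOF frame and fitted transform, fuses
#' depth into the SWIR grid ([register_tof_to_swir()]), exports the
#' registered depth raster (text) and the labelled vein point cloud (PLY),
#' plus a JSON report.
#'
#' @param config a [pipeline_config()].
#' @param swir_path SWIR image path.
#' @param mask_path vein-mask PNG from [run_detect()].
#' @param depth_path,amplitude_path TOF rasters.
#' @param intrinsics_path TOF intrinsics JSON.
#' @param transform_path transform JSON from [run_calibrate()].
#' @param out_prefix output path prefix; writes `<prefix>_depth.txt`,
#'   `<prefix>_veins.ply`, `<prefix>_report.json`.
#' @return the report, invisibly.
#' @export
run_locate <- function(config, swir_path, mask_path, depth_path,
                       amplitude_path, intrinsics_path, transform_path,
                       out_prefix) {
  t0 <- proc.time()[["elapsed"]]
  img <- read_swir(swir_path, bit_depth = config$io$bit_depth)
  mask <- read_mask(mask_path)
  intr <- read_intrinsics(intrinsics_path)
  tof <- read_tof(depth_path, amplitude_path, intr,
                  amplitude_floor = config$io$amplitude_floor)
  map <- read_transform(transform_path)
  fused <- register_tof_to_swir(tof, map, img,
                                fill_radius = config$register$fill_radius)
  pts <- map_veins_3d(mask, fused)
  depth_out <- fused$depth_reg
  depth_out[!fused$valid] <- -1
  write_raster_text(depth_out, paste0(out_prefix, "_depth.txt"))
  write_pointcloud(pts, paste0(out_prefix, "_veins.ply"),
                   labels = attr(pts, "label"))
  report <- list(
    vein_px = sum(mask),
    vein_points = nrow(pts),
    registered_px = sum(fused$valid),
    depth_range_mm = if (any(fused$valid))
      range(fused$depth_reg[fused$valid]) else c(NA_real_, NA_real_),
    elapsed_s = proc.time()[["elapsed"]] - t0
  )
  jsonlite::write_json(report, paste0(out_prefix, "_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' Score a detection against ground truth
#'
#' Evaluation ROI follows `config$eval$roi`: `"intersection"` restricts the
#' counts to the same region the detector could mark (the intersection of
#' the two segmentation masks, recomputed from the SWIR image);
#' `"image"` uses every pixel.
#'
#' @param config a [pipeline_config()].
#' @param pred_path,truth_path binary mask PNGs.
#' @param swir_path SWIR image used to rebuild the ROI masks (required for
#'   `roi = "intersection"`).
#' @param report_path optional output JSON.
#' @return list with `tp_rate`, `accuracy`, `error_rate` and `counts`.
#' @export
run_eval <- function(config, pred_path, truth_path, swir_path = NULL,
                     report_path = NULL) {
  pred <- read_mask(pred_path)
  truth <- read_mask(truth_path)
  roi <- NULL
  if (identical(config$eval$roi, "intersection")) {
    vm_assert(!is.null(swir_path), "veinmap_config_error",
              "eval roi 'intersection' needs the SWIR image")
    img <- read_swir(swir_path, bit_depth = config$io$bit_depth)
    seg <- segment_foreground(img, invert = config$preprocess$invert)
    masks <- build_masks(seg$foreground, widths = config$mask$widths)
    roi <- masks$mask_narrow & masks$mask_wide
  }
  cc <- confusion_counts(pred, truth, roi)
  report <- list(tp_rate = tp_rate(cc), accuracy = accuracy(cc),
                 error_rate = error_rate(cc),
                 counts = list(tp = cc$tp, fp = cc$fp, tn = cc$tn,
                               fn = cc$fn, total = cc$total))
  if (!is.null(report_path)) {
    jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA)
  }
  report
}

#' Write a full synthetic fixture bundle to a directory
#'
#' Generates one scene from a [phantom_spec()] and writes everything a
#' pipeline run needs: SWIR image (TIFF), truth and foreground masks (PNG),
#' TOF depth/amplitude rasters (text), control-point CSV, TOF intrinsics and
#' planted-transform JSON, and the spec echoed as JSON (the bundle's single
#' source of truth).
#'
#' @param spec a [phantom_spec()].
#' @param dir output directory (created if missing).
#' @return named character vector of written paths, invisibly.
#' @export
run_synth <- function(spec, dir) {
  stopifnot(inherits(spec, "phantom_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scene <- generate_tof_scene(spec)
  p <- c(swir = file.path(dir, "swir.tif"),
         truth = file.path(dir, "truth.png"),
         foreground = file.path(dir, "foreground.png"),
         depth = file.path(dir, "tof_depth.txt"),
         amplitude = file.path(dir, "tof_amplitude.txt"),
         pairs = file.path(dir, "control_points.csv"),
         intrinsics = file.path(dir, "tof_intrinsics.json"),
         transform = file.path(dir, "planted_transform.json"),
         spec = file.path(dir, "spec.json"))
  write_swir(scene$phantom$image, p[["swir"]])
  write_mask(scene$phantom$truth, p[["truth"]])
  write_mask(scene$phantom$foreground, p[["foreground"]])
  write_raster_text(scene$tof$depth, p[["depth"]])
  write_raster_text(scene$tof$amplitude, p[["amplitude"]])
  write_control_points(scene$pairs, p[["pairs"]])
  write_intrinsics(spec$tof_intrinsics, p[["intrinsics"]])
  write_transform(scene$map, p[["transform"]])
  sp <- unclass(spec)
  sp$tof_intrinsics <- unclass(sp$tof_intrinsics)
  sp$map <- list(R = lapply(1:2, function(i) spec$map$R[i, ]), T = spec$map$T)
  jsonlite::write_json(sp, p[["spec"]], auto_unbox = TRUE, digits = NA)
  invisible(p)
}
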