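# End-to-end orchestration: inverted green channel -> enhancement ->
# multi-scale detection -> fusion -> threshold -> (optional) evaluation.

#' Fused multi-scale vessel response
#'
#' Runs the detector over all scales and fuses the standardized responses.
#' In `split` mode, small scales (`< 9`) are detected on the locally enhanced
#' image and large scales (`>= 9`) on the globally enhanced image, then fused
#' with the un-enhanced inverted green channel. In `baseline` mode every
#' scale is detected on the inverted green channel itself (the classic
#' all-scales detector).
#'
#' @param igc inverted green channel matrix (see [inverted_green()]).
#' @param fov logical FOV mask (default whole frame).
#' @param mode `"split"` or `"baseline"`.
#' @param detector a [detector_params()] list (its `scales` drive baseline
#'   mode).
#' @param split a [scale_split()] (split mode).
#' @param local a [local_enhance_params()] list (split mode).
#' @param c_g global enhancement gain (split mode, default 1).
#' @return fused numeric matrix (see [fuse_split()] / [fuse_baseline()]).
#' @export
vessel_response <- function(igc, fov = NULL, mode = c("split", "baseline"),
                            detector = detector_params(),
                            split = scale_split(),
                            local = local_enhance_params(), c_g = 1) {
  mode <- match.arg(mode)
  check_image(igc, "inverted green channel")
  if (is.null(fov)) fov <- matrix(TRUE, nrow(igc), ncol(igc))
  respond <- function(img, scales)
    lapply(scales, function(L)
      standardize_response(single_scale_response(img, L, fov, detector), fov))
  if (mode == "baseline")
    return(fuse_baseline(respond(igc, detector$scales), igc, fov))
  i1 <- local_enhance(igc, local)
  small <- respond(i1, split$small)
  large <- if (length(split$large)) {
    i2 <- global_enhance(igc, fov, c_g)
    respond(i2, split$large)
  } else list()
  fuse_split(small, large, igc, fov, split)
}

#' Segment retinal vessels in one image
#'
#' The full pipeline on an in-memory image: invert the green channel, build
#' the fused multi-scale response, threshold it into a vessel mask.
#'
#' @param img `H x W x 3` RGB array in `[0, 1]`, or a green-channel matrix.
#' @param fov logical FOV mask; `NULL` derives one with
#'   [fov_mask()]`(mode = "threshold")` for RGB input, or uses the whole
#'   frame for matrix input.
#' @param mode `"split"` (default) or `"baseline"`.
#' @param threshold_method,threshold_value see [threshold_map()].
#' @param skeleton also compute the 1-px skeleton of the mask?
#' @inheritParams vessel_response
#' @return a `vessel_segmentation` list: `mask`, `fused`, `igc`, `fov`,
#'   optionally `skeleton`, and the parameters used.
#' @export
segment_vessels <- function(img, fov = NULL, mode = c("split", "baseline"),
                            threshold_method = "quantile",
                            threshold_value = 0.104,
                            detector = detector_params(),
                            split = scale_split(),
                            local = local_enhance_params(), c_g = 1,
                            skeleton = FALSE) {
  mode <- match.arg(mode)
  if (is.null(fov)) {
    fov <- if (is.matrix(img)) matrix(TRUE, nrow(img), ncol(img))
           else fov_mask(img, mode = "threshold")
  }
  igc <- inverted_green(img)
  fused <- vessel_response(igc, fov, mode, detector, split, local, c_g)
  mask <- threshold_map(fused, fov, threshold_method, threshold_value)
  out <- list(mask = mask, fused = fused, igc = igc, fov = fov,
              mode = mode, threshold_method = threshold_method,
              threshold_value = threshold_value,
              threshold = attr(mask, "threshold"))
  if (skeleton) out$skeleton <- skeletonize_mask(mask)
  structure(out, class = "vessel_segmentation")
}

#' @export
print.vessel_segmentation <- function(x, ...) {
  cat(sprintf("vessel segmentation (%s mode): %dx%d, %d vessel px (%.1f%% of FOV), threshold %.4f (%s)\n",
              x$mode, nrow(x$mask), ncol(x$mask), sum(x$mask),
              100 * sum(x$mask) / sum(x$fov), x$threshold, x$threshold_method))
  invisible(x)
}

#' File-based segmentation run
#'
#' Loads an image (and optional FOV/truth masks), runs [segment_vessels()],
#' and writes all artifacts into `out_dir`: `fused.tif` (+ range sidecar),
#' `mask.png`, `skeleton.png`, `metrics.json` (when truth is given),
#' `config.json` (the resolved configuration) and `run.log` with per-stage
#' timings.
#'
#' @param image_path input photograph.
#' @param out_dir output directory, created if needed.
#' @param fov_path optional FOV mask file; when absent the FOV is derived by
#'   red-channel thresholding.
#' @param truth_path optional ground-truth vessel mask file.
#' @param skeleton write the skeletonized mask as well?
#' @inheritParams segment_vessels
#' @return the metrics list (or `NULL` without truth), invisibly.
#' @export
run_segmentation <- function(image_path, out_dir, fov_path = NULL,
                             truth_path = NULL,
                             mode = c("split", "baseline"),
                             threshold_method = "quantile",
                             threshold_value = 0.104,
                             detector = detector_params(),
                             split = scale_split(),
                             local = local_enhance_params(), c_g = 1,
                             skeleton = FALSE) {
  mode <- match.arg(mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  t_all <- proc.time()[["elapsed"]]
  logln <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                             append = TRUE)
  cat(sprintf("run started %s\n", format(Sys.time())), file = log_path)

  timed <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      logln("stage %s FAILED: %s", stage, conditionMessage(e))
      stopf("stage %s failed: %s", stage, conditionMessage(e))
    })
    logln("stage %-10s %.2fs", stage, proc.time()[["elapsed"]] - t0)
    res
  }

  img <- timed("load", load_image(image_path))
  fov <- timed("fov", if (!is.null(fov_path))
    fov_mask(img, mode = "file", path = fov_path)
    else fov_mask(img, mode = "threshold"))
  seg <- timed("segment",
               segment_vessels(img, fov, mode, threshold_method,
                               threshold_value, detector, split, local, c_g,
                               skeleton = skeleton))
  timed("write", {
    save_response(seg$fused, file.path(out_dir, "fused.tif"))
    save_mask(seg$mask, file.path(out_dir, "mask.png"))
    if (skeleton) save_mask(seg$skeleton, file.path(out_dir, "skeleton.png"))
  })

  metrics <- NULL
  if (!is.null(truth_path)) {
    metrics <- timed("evaluate", {
      truth <- fov_mask(img, mode = "file", path = truth_path)
      m <- segmentation_metrics(confusion_counts(seg$mask, truth, fov))
      jsonlite::write_json(unclass(m), file.path(out_dir, "metrics.json"),
                           auto_unbox = TRUE, digits = NA)
      m
    })
  }
  config <- list(image = image_path, fov = fov_path, truth = truth_path,
                 mode = mode,
                 threshold = list(method = threshold_method,
                                  value = threshold_value),
                 detector = unclass(detector), split = unclass(split),
                 local = unclass(local), c_g = c_g, skeleton = skeleton)
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  logln("total %.2fs", proc.time()[["elapsed"]] - t_all)
  invisible(metrics)
}
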