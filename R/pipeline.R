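#' Read a frame stack
#'
#' Accepts a multi-page TIFF or a directory of lexicographically sorted
#' PNG/TIFF frames; 8-bit and 16-bit inputs are rescaled to 0..255.
#'
#' @param path TIFF file or directory.
#' @return list of numeric matrices (0..255).
#' @export
read_frames <- function(path) {
  to255 <- function(m) {
    if (length(dim(m)) == 3) m <- m[, , 1]
    m * 255
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stop("no PNG/TIFF frames found in ", path)
    lapply(files, function(f) {
      if (grepl("\\.png$", f, ignore.case = TRUE)) to255(png::readPNG(f))
      else to255(tiff::readTIFF(f))
    })
  } else if (file.exists(path)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (is.matrix(pages)) pages <- list(pages)
    lapply(pages, to255)
  } else stop("input not found: ", path)
}

#' Write a frame stack as a multi-page 8-bit TIFF
#'
#' @param frames list of matrices (0..255).
#' @param path output TIFF path.
#' @export
write_frames <- function(frames, path) {
  tiff::writeTIFF(lapply(frames, function(f) f / 255), path,
                  bits.per.sample = 8)
  invisible(path)
}

#' Full pipeline configuration
#'
#' Bundles the per-stage configurations; every field has the package
#' default and any can be overridden from a YAML file via
#' [read_pipeline_config()].
#'
#' @param flattening [flattening_config()].
#' @param tracker [tracker_config()].
#' @param flow [flow_config()].
#' @param crop_size single-cell crop side (odd px).
#' @param frame_buffer_size frames retained for crop acquisition.
#' @param scale_range,response_threshold blob-segmenter parameters.
#' @param seed RNG seed for any stochastic stage.
#' @export
pipeline_config <- function(flattening = flattening_config(),
                            tracker = tracker_config(),
                            flow = flow_config(),
                            crop_size = 21, frame_buffer_size = 32,
                            scale_range = c(1.4, 5.5),
                            response_threshold = 0.06,
                            seed = 1) {
  as.list(environment())
}

#' @rdname pipeline_config
#' @param path YAML file whose top-level keys override default fields
#'   (nested keys override fields of the stage configs).
#' @export
read_pipeline_config <- function(path) {
  ov <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  for (k in names(ov)) {
    if (k %in% c("flattening", "tracker", "flow") && is.list(ov[[k]])) {
      base <- switch(k, flattening = flattening_config,
                     tracker = tracker_config, flow = flow_config)
      cfg[[k]] <- do.call(base, ov[[k]])
    } else cfg[[k]] <- ov[[k]]
  }
  cfg
}

#' Run the streaming pipeline over a frame stack
#'
#' Per frame: segment (density map), flatten (detections), tracker step;
#' on each exit event, the clearest buffered frame is selected and a
#' single-cell crop acquired, then classified if a model is attached.
#' Per-stage wall-clock latency is recorded for every frame
#' (informational; useful for judging real-time feasibility on given
#' hardware).
#'
#' @param frames list of frame matrices (see [read_frames()]).
#' @param config a [pipeline_config()].
#' @param segmenter `function(frame, frame_index) -> density map`;
#'   defaults to the blob segmenter. Use [oracle_segmenter()] to isolate
#'   downstream stages.
#' @param classifier optional `ifc_classifier`.
#' @return list with `detections`, `tracks` (table), `count`, `crops`,
#'   `predictions`, `events`, `latency_ms` (per-stage mean/max), and
#'   `summary` (a run summary, see below). The summary reports total
#'   frames, total count (last issued track id), per-class counts and the
#'   ratio normalized to 100, and the actual throughput
#'   `count / (frames / frame_rate)`.
#' @export
run_pipeline <- function(frames, config = pipeline_config(),
                         segmenter = NULL, classifier = NULL) {
  if (is.null(segmenter)) {
    # default blob segmenter with a running in-focus amplitude estimate
    # (95th percentile of recent blob depths) for mass-based radii
    amp_env <- new.env(parent = emptyenv())
    amp_env$depths <- numeric()
    segmenter <- function(frame, frame_index) {
      amp <- if (length(amp_env$depths) >= 30)
        max(stats::quantile(amp_env$depths, 0.85), 0.05) else NULL
      ann <- blob_segment(frame, config$scale_range,
                          config$response_threshold, amplitude = amp,
                          return_annotations = TRUE)
      if (nrow(ann))
        amp_env$depths <- c(utils::tail(amp_env$depths, 470), ann$depth)
      build_density_map(ann[, c("row", "col", "radius", "class", "object_id")],
                        dim(frame))
    }
  }
  state <- new_tracker(config$tracker)
  buf <- frame_buffer(config$frame_buffer_size)
  detections <- NULL
  crops <- list()
  predictions <- NULL
  events <- list()
  lat <- list(segment = numeric(), flatten = numeric(), track = numeric(),
              acquire = numeric())
  shape <- if (length(frames)) dim(frames[[1]]) else config$tracker$frame_shape
  for (f in seq_along(frames) - 1L) {
    frame <- frames[[f + 1]]
    if (!all(dim(frame) == shape))
      stop("frame ", f, " has shape ", paste(dim(frame), collapse = "x"),
           ", expected ", paste(shape, collapse = "x"))
    buffer_push(buf, f, frame)
    t0 <- proc.time()[3]
    dm <- segmenter(frame, f)
    t1 <- proc.time()[3]
    det <- flatten(dm, config$flattening, frame_index = f)
    t2 <- proc.time()[3]
    st <- tracker_step(state, det, f)
    state <- st$state
    t3 <- proc.time()[3]
    for (ev in st$events) {
      events[[length(events) + 1]] <- ev
      if (ev$type %in% c("out", "stale_out")) {
        sc <- acquire_on_exit(ev, buf, config$crop_size)
        if (!is.null(sc)) {
          crops[[length(crops) + 1]] <- sc
          if (!is.null(classifier)) {
            pr <- predict_cell(classifier, sc)
            predictions <- rbind(predictions, data.frame(
              track_id = sc$track_id, class = pr$label,
              probability = max(pr$prob)))
          }
        }
      }
    }
    t4 <- proc.time()[3]
    detections <- rbind(detections, det)
    lat$segment <- c(lat$segment, (t1 - t0) * 1000)
    lat$flatten <- c(lat$flatten, (t2 - t1) * 1000)
    lat$track <- c(lat$track, (t3 - t2) * 1000)
    lat$acquire <- c(lat$acquire, (t4 - t3) * 1000)
  }
  if (is.null(detections))
    detections <- data.frame(frame = integer(), row = integer(),
                             col = integer(), radius = numeric(),
                             score = numeric())
  count <- state$next_id - 1L
  frame_rate <- config$flow$frame_rate_hz
  per_class <- if (!is.null(predictions)) table(predictions$class) else table(character())
  ratio <- if (length(per_class)) {
    pc <- as.numeric(per_class)
    round(100 * pc / max(pc))
  } else numeric()
  summary <- list(
    total_frames = length(frames),
    total_count = count,
    per_class_counts = as.list(per_class),
    number_ratio = ratio,
    actual_throughput_per_s = if (length(frames))
      round(count / (length(frames) / frame_rate)) else 0,
    latency_ms = lapply(lat, function(x)
      if (length(x)) list(mean = mean(x), max = max(x)) else list(mean = NA, max = NA)))
  list(detections = detections, tracks = tracks_table(state), count = count,
       crops = crops, predictions = predictions, events = events,
       state = state, latency_ms = summary$latency_ms, summary = summary)
}

#' Simulate a recording and write it to disk
#'
#' @param out_dir output directory (created if needed): `frames.tif`,
#'   `truth.csv`, `objects.csv`, `config.yaml`.
#' @param ... passed to [simulate_sequence()].
#' @export
simulate_recording <- function(out_dir, ...) {
  sim <- simulate_sequence(...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_frames(sim$frames, file.path(out_dir, "frames.tif"))
  utils::write.csv(sim$truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  utils::write.csv(sim$objects, file.path(out_dir, "objects.csv"),
                   row.names = FALSE)
  yaml::write_yaml(list(flow = sim$config, seed = sim$seed),
                   file.path(out_dir, "config.yaml"))
  invisible(sim)
}

#' Evaluate a pipeline run against ground truth
#'
#' Computes mAP at the IoU threshold (detection classes from the
#' classifier when predictions exist, otherwise by radius binning against
#' the known class radii), the counting report, localization error, and
#' the tracking report; optionally written as a JSON report.
#'
#' Objects whose centers fall within `edge_margin_px` of the left or right
#' frame edge are excluded from both ground truth and detections: they are
#' only partially imaged, so neither their boxes nor their classes are
#' well defined.
#'
#' @param run result of [run_pipeline()].
#' @param truth simulator ground truth (per-frame annotations).
#' @param iou_threshold IoU threshold for detection scoring.
#' @param frame_shape `c(H, W)` of the frames.
#' @param edge_margin_px boundary exclusion margin.
#' @param json_path optional output path for the JSON report.
#' @export
evaluate_run <- function(run, truth, iou_threshold = 0.4,
                         frame_shape = c(100, 500), edge_margin_px = 5,
                         json_path = NULL) {
  W <- frame_shape[2]
  inb <- function(x) x$col >= edge_margin_px & x$col <= W - 1 - edge_margin_px
  gt <- truth[inb(truth), , drop = FALSE]
  det <- run$detections[inb(run$detections), , drop = FALSE]
  class_radii <- tapply(gt$radius, gt$class, stats::median)
  det$class <- bin_radius_class(det$radius, class_radii)
  # occluded instants are scored as don't-care (identity through occlusion
  # is the tracker's job, not the single-frame detector's); the fully
  # strict score is reported alongside
  ign <- if ("occluded" %in% names(gt)) gt$occluded else NULL
  ap <- average_precision(det, gt, iou_threshold, ignore = ign)
  ap_strict <- if (is.null(ign)) ap else average_precision(det, gt, iou_threshold)
  n_true <- length(unique(gt$object_id))
  cnt <- counting_report(run$count, max(1, n_true))
  loc <- localization_error(det, gt, iou_threshold)
  trk <- tracking_report(run, gt)
  report <- list(per_class_ap = as.list(ap$per_class), mAP = ap$mAP,
                 mAP_strict_all_instants = ap_strict$mAP,
                 counting = cnt, localization = loc, tracking = trk)
  if (!is.null(json_path))
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  report
}
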