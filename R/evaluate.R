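#' Intersection over union of two axis-aligned boxes
#'
#' @param a,b boxes as vectors or one-row data frames with
#'   `col_min,row_min,col_max,row_max`.
#' @return IoU in \[0, 1\].
#' @export
iou <- function(a, b) {
  a <- unlist(a); b <- unlist(b)
  if (a["col_max"] <= a["col_min"] || a["row_max"] <= a["row_min"] ||
      b["col_max"] <= b["col_min"] || b["row_max"] <= b["row_min"])
    stop("degenerate box")
  iw <- min(a["col_max"], b["col_max"]) - max(a["col_min"], b["col_min"])
  ih <- min(a["row_max"], b["row_max"]) - max(a["row_min"], b["row_min"])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  areaA <- (a["col_max"] - a["col_min"]) * (a["row_max"] - a["row_min"])
  areaB <- (b["col_max"] - b["col_min"]) * (b["row_max"] - b["row_min"])
  unname(inter / (areaA + areaB - inter))
}

# vectorized IoU of one box against many (columns col_min,row_min,col_max,row_max)
.iou_many <- function(a, B) {
  iw <- pmin(a$col_max, B$col_max) - pmax(a$col_min, B$col_min)
  ih <- pmin(a$row_max, B$row_max) - pmax(a$row_min, B$row_min)
  inter <- pmax(iw, 0) * pmax(ih, 0)
  areaA <- (a$col_max - a$col_min) * (a$row_max - a$row_min)
  areaB <- (B$col_max - B$col_min) * (B$row_max - B$row_min)
  inter / (areaA + areaB - inter)
}

#' Assign class labels to detections by radius binning
#'
#' Maps each detection to the nearest known class radius; the evaluation
#' protocol uses this when no classifier is attached to the pipeline.
#'
#' @param radius numeric vector of detected radii (px).
#' @param class_radii named numeric vector of reference radii per class.
#' @return character vector of class labels.
#' @export
bin_radius_class <- function(radius, class_radii) {
  names(class_radii)[apply(abs(outer(radius, class_radii, `-`)), 1, which.min)]
}

#' Average precision and mAP at a fixed IoU threshold
#'
#' Score-descending greedy matching of detections to ground truth within
#' each frame and class at the given IoU threshold (each ground-truth
#' object is matched at most once); AP is the area under the
#' precision-recall curve with all-point (monotone envelope)
#' interpolation, and mAP is the unweighted mean over classes that have
#' ground truth.
#'
#' Ground-truth rows flagged by `ignore` are scored as don't-care regions,
#' the standard treatment of instants a single-frame annotator or detector
#' cannot resolve (here: occlusions, where several objects project onto
#' one image blob and identity is carried by the tracker instead): they are
#' excluded from the ground-truth count, and detections that would
#' otherwise be false positives are discarded without penalty when they
#' overlap an ignored object at the IoU threshold.
#'
#' @param detections `data.frame` with `frame,row,col,radius,score,class`.
#' @param truth `data.frame` with `frame,row,col,radius,class`.
#' @param iou_threshold IoU above which a detection counts as a true
#'   positive (the evaluation protocol uses 0.4).
#' @param ignore optional logical vector along `truth`: don't-care rows.
#' @return list with `per_class` (named AP vector), `mAP`, and `matches`
#'   (per-detection TP/FP flags and matched ground-truth row indices).
#' @export
average_precision <- function(detections, truth, iou_threshold = 0.4,
                              ignore = NULL) {
  if (is.null(ignore)) ignore <- rep(FALSE, nrow(truth))
  stopifnot(length(ignore) == nrow(truth))
  dontcare <- truth[ignore, , drop = FALSE]
  dc_boxes <- if (nrow(dontcare))
    cbind(dontcare, detection_to_box(dontcare)) else NULL
  truth <- truth[!ignore, , drop = FALSE]
  classes <- sort(unique(truth$class))
  skipped <- setdiff(unique(detections$class), classes)
  if (length(skipped))
    warning("no ground truth for class(es): ", paste(skipped, collapse = ", "))
  tb <- cbind(truth, detection_to_box(truth))
  db <- cbind(detections, detection_to_box(detections))
  ap <- numeric(0)
  match_rows <- NULL
  for (cl in classes) {
    gt <- tb[tb$class == cl, , drop = FALSE]
    dd <- db[db$class == cl, , drop = FALSE]
    n_gt <- nrow(gt)
    if (nrow(dd) == 0) { ap[cl] <- 0; next }
    dd <- dd[order(-dd$score), , drop = FALSE]
    used <- logical(n_gt)
    tp <- logical(nrow(dd)); gt_idx <- rep(NA_integer_, nrow(dd))
    drop_dc <- logical(nrow(dd))
    for (i in seq_len(nrow(dd))) {
      cand <- which(gt$frame == dd$frame[i] & !used)
      if (length(cand)) {
        ious <- .iou_many(dd[i, ], gt[cand, , drop = FALSE])
        j <- which.max(ious)
        if (ious[j] >= iou_threshold) {
          tp[i] <- TRUE; used[cand[j]] <- TRUE; gt_idx[i] <- cand[j]
          next
        }
      }
      if (!is.null(dc_boxes)) {
        dc <- dc_boxes[dc_boxes$frame == dd$frame[i], , drop = FALSE]
        if (nrow(dc) && max(.iou_many(dd[i, ], dc)) >= iou_threshold)
          drop_dc[i] <- TRUE
      }
    }
    dd <- dd[!drop_dc, , drop = FALSE]; tp <- tp[!drop_dc]
    if (nrow(dd) == 0) { ap[cl] <- 0; next }
    cum_tp <- cumsum(tp); cum_fp <- cumsum(!tp)
    recall <- cum_tp / n_gt
    precision <- cum_tp / (cum_tp + cum_fp)
    # all-point interpolation: precision envelope from the right
    penv <- rev(cummax(rev(precision)))
    r_prev <- c(0, recall[-length(recall)])
    ap[cl] <- sum((recall - r_prev) * penv)
    match_rows <- rbind(match_rows,
                        data.frame(class = cl, frame = dd$frame, row = dd$row,
                                   col = dd$col, score = dd$score, tp = tp))
  }
  list(per_class = ap, mAP = mean(ap), matches = match_rows)
}

#' Counting error report
#'
#' @param predicted predicted object count.
#' @param reference reference (e.g. manual) count, > 0.
#' @return list with `difference` (absolute) and `relative_error_percent`.
#' @export
counting_report <- function(predicted, reference) {
  if (reference <= 0) stop("reference count must be positive")
  list(difference = abs(predicted - reference),
       relative_error_percent = 100 * abs(predicted - reference) / reference)
}

#' Localization error of matched detections
#'
#' Matches detections to ground truth greedily by score at the IoU
#' threshold (class-agnostic) and reports the Euclidean center distance
#' over matched pairs.
#'
#' @param detections `frame,row,col,radius,score`.
#' @param truth `frame,row,col,radius`.
#' @param iou_threshold matching threshold.
#' @return list with `mean_px`, `max_px`, `n_matched`.
#' @export
localization_error <- function(detections, truth, iou_threshold = 0.4) {
  db <- cbind(detections, detection_to_box(detections))
  tb <- cbind(truth, detection_to_box(truth))
  db <- db[order(-db$score), , drop = FALSE]
  used <- logical(nrow(tb))
  dists <- numeric(0)
  for (i in seq_len(nrow(db))) {
    cand <- which(tb$frame == db$frame[i] & !used)
    if (!length(cand)) next
    ious <- .iou_many(db[i, ], tb[cand, , drop = FALSE])
    j <- which.max(ious)
    if (ious[j] >= iou_threshold) {
      used[cand[j]] <- TRUE
      dists <- c(dists, sqrt((db$row[i] - tb$row[cand[j]])^2 +
                             (db$col[i] - tb$col[cand[j]])^2))
    }
  }
  list(mean_px = if (length(dists)) mean(dists) else NA_real_,
       max_px = if (length(dists)) max(dists) else NA_real_,
       n_matched = length(dists))
}

#' Tracking quality report against simulator ground truth
#'
#' Associates each emitted track with the ground-truth object that is
#' nearest to its observed positions over shared frames, then reports the
#' count error, the duplicate rate (tracks beyond the first mapping to
#' the same object), identity switches within tracks, and the fraction of
#' ground-truth objects with an occlusion episode that still end up with
#' exactly one track (occlusion recovery).
#'
#' @param tracker_result result of [run_tracker()] (or a tracker state).
#' @param truth per-frame ground-truth annotations
#'   (`frame,object_id,row,col,occluded`).
#' @param match_radius_px maximum center distance for a per-frame
#'   track-to-truth association.
#' @return list of metrics.
#' @export
tracking_report <- function(tracker_result, truth, match_radius_px = 12) {
  tt <- tracks_table(tracker_result)
  n_true <- length(unique(truth$object_id))
  count <- if (!is.null(tracker_result$count)) tracker_result$count else
    length(unique(tt$track_id))
  if (nrow(tt) == 0 || n_true == 0)
    return(list(count = count, true_count = n_true,
                count_error = abs(count - n_true), duplicate_rate = 0,
                id_switches = 0, occlusion_recovery_rate = NA_real_))
  obs <- tt[tt$state %in% c("IN", "ASSIGNED", "APPEAR"), , drop = FALSE]
  assigned <- integer(0)
  switches <- 0L
  for (id in unique(obs$track_id)) {
    h <- obs[obs$track_id == id, , drop = FALSE]
    ids <- rep(NA_integer_, nrow(h))
    for (i in seq_len(nrow(h))) {
      g <- truth[truth$frame == h$frame[i], , drop = FALSE]
      if (!nrow(g)) next
      dd <- sqrt((g$row - h$row[i])^2 + (g$col - h$col[i])^2)
      j <- which.min(dd)
      if (dd[j] <= match_radius_px) ids[i] <- g$object_id[j]
    }
    ids_ok <- ids[!is.na(ids)]
    if (length(ids_ok)) {
      maj <- as.integer(names(sort(table(ids_ok), decreasing = TRUE))[1])
      assigned <- c(assigned, maj)
      if (length(ids_ok) > 1)
        switches <- switches + sum(ids_ok[-1] != ids_ok[-length(ids_ok)])
    }
  }
  dup <- sum(duplicated(assigned))
  occl_ids <- unique(truth$object_id[truth$occluded])
  recov <- if (length(occl_ids))
    mean(vapply(occl_ids, function(o) sum(assigned == o) == 1, TRUE))
  else NA_real_
  list(count = count, true_count = n_true,
       count_error = abs(count - n_true),
       duplicate_rate = dup / max(1, length(assigned)),
       id_switches = switches,
       occlusion_recovery_rate = recov)
}
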