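#' Tracker configuration
#'
#' Defaults are calibrated to the imaging regime of a 50 x 100 um channel
#' viewed as a 100 x 500 px region of interest at 500 frames/s with flow
#' rates of roughly 6-18 uL/min, i.e. axial displacements of ~40-90
#' px/frame.
#'
#' @param gate_px maximum admissible prediction-to-detection distance.
#' @param lateral_weight multiplier on the lateral (row) residual in the
#'   assignment cost; objects in Poiseuille flow barely move laterally, so
#'   lateral jumps are penalized more than axial ones.
#' @param entry_margin_px detections at `col` below this margin may start
#'   new tracks.
#' @param exit_margin_px unmatched tracks predicted within this margin of
#'   the right edge are considered to have left the region of interest.
#' @param nominal_velocity_px axial velocity (px/frame) assumed for tracks
#'   with a single observation.
#' @param max_occlusion_frames occlusions persisting longer are forced out
#'   as stale.
#' @param appear_lateral_tol_px lateral tolerance when re-associating a
#'   detection with an occluded track.
#' @param velocity_bounds_px admissible range for the per-frame axial
#'   velocity estimate; flow is strictly forward, so a displacement
#'   estimate corrupted by a bad association is clamped into this range
#'   instead of being allowed to predict backwards.
#' @param frame_shape `c(H, W)` of the frames in pixels.
#' @param track_buffer capacity of the completed-track circular buffer.
#' @export
tracker_config <- function(gate_px = 60, lateral_weight = 5,
                           entry_margin_px = 100, exit_margin_px = 100,
                           nominal_velocity_px = 40,
                           max_occlusion_frames = 10,
                           appear_lateral_tol_px = 6,
                           velocity_bounds_px = c(5, 150),
                           frame_shape = c(100, 500),
                           track_buffer = 256) {
  stopifnot(gate_px > 0, lateral_weight >= 1, entry_margin_px > 0,
            exit_margin_px > 0, nominal_velocity_px > 0,
            max_occlusion_frames >= 1, appear_lateral_tol_px > 0,
            entry_margin_px + exit_margin_px < frame_shape[2])
  as.list(environment())
}

#' Create an empty tracker state
#'
#' @param config a [tracker_config()].
#' @return tracker state: active tracks, next sequential id, completed-track
#'   circular buffer.
#' @export
new_tracker <- function(config = tracker_config()) {
  list(config = config, tracks = list(), next_id = 1L, last_frame = -Inf,
       completed = list())
}

.clamp_velocity <- function(v, config) {
  min(max(v, config$velocity_bounds_px[1]), config$velocity_bounds_px[2])
}

.new_track <- function(id, frame, det, config) {
  list(id = id,
       history = data.frame(frame = frame, row = det$row, col = det$col,
                            radius = det$radius, state = "IN",
                            stringsAsFactors = FALSE),
       state = "IN", velocity = config$nominal_velocity_px, n_obs = 1L,
       active = TRUE,
       occl_count = 0L, last_row = det$row, last_col = det$col,
       last_obs_row = det$row, last_obs_col = det$col, last_obs_frame = frame)
}

#' Predict a track's next position
#'
#' Constant-velocity extrapolation along the flow axis: the column advances
#' by the last observed per-frame displacement (or the nominal velocity if
#' only one observation exists); the row never changes, reflecting the
#' negligible lateral motion of objects in Poiseuille flow.
#'
#' @param track a track object held in the tracker state.
#' @return numeric `c(row, col)`.
#' @export
predict_position <- function(track) {
  if (!isTRUE(track$active)) stop("cannot predict an inactive track")
  c(track$last_row, track$last_col + track$velocity)
}

#' Gated assignment cost matrix between tracks and detections
#'
#' Cost is the Euclidean distance between the predicted track position and
#' the detection center, with the lateral residual scaled by
#' `lateral_weight`; pairs farther apart than `gate_px` are forbidden
#' (`Inf`) and can never be matched. For tracks with a single observation
#' the axial velocity is only known to lie within the Poiseuille range
#' (`velocity_bounds_px`), so the axial residual is measured against that
#' whole admissible displacement interval rather than a point prediction —
#' the cost is then dominated by the lateral residual, which is the
#' reliable coordinate for a newborn track.
#'
#' @param tracks list of active track objects.
#' @param detections detection table (`row`, `col`).
#' @param config a [tracker_config()].
#' @export
build_cost_matrix <- function(tracks, detections, config) {
  nr <- length(tracks); nc <- nrow(detections)
  C <- matrix(Inf, nr, nc)
  if (nr == 0 || nc == 0) return(C)
  vb <- config$velocity_bounds_px
  for (i in seq_len(nr)) {
    t <- tracks[[i]]
    p <- predict_position(t)
    if (t$n_obs <= 1L) {
      dcol <- detections$col - t$last_col
      ax <- pmax(0, vb[1] - dcol, dcol - vb[2])
    } else {
      ax <- abs(detections$col - p[2])
    }
    d <- sqrt(ax^2 + (config$lateral_weight * (detections$row - p[1]))^2)
    d[d > config$gate_px] <- Inf
    C[i, ] <- d
  }
  C
}

.append_history <- function(track, frame, row, col, radius, state) {
  track$history <- rbind(track$history,
                         data.frame(frame = frame, row = row, col = col,
                                    radius = radius, state = state,
                                    stringsAsFactors = FALSE))
  track$state <- state
  track
}

.complete_track <- function(state, track, frame, event_type, events) {
  track$active <- FALSE
  state$completed <- c(state$completed, list(track))
  if (length(state$completed) > state$config$track_buffer)
    state$completed <- state$completed[-1]
  events[[length(events) + 1]] <- list(type = event_type, frame = frame,
                                       track = track)
  list(state = state, events = events)
}

#' Advance the tracker by one frame
#'
#' Matched detections extend their tracks (`ASSIGNED`). An unmatched
#' detection either starts a new sequentially-numbered track (`IN`) if it
#' lies within the entry margin, is re-associated with an occluded track
#' whose lateral position and forward displacement are plausible
#' (`APPEAR`), or starts a new track flagged as an anomaly. An unmatched
#' track is closed (`OUT`) if its prediction has reached the exit margin,
#' and otherwise coasts on its predicted position (`OCCLUSION`); an
#' occlusion persisting beyond `max_occlusion_frames` is forced out as
#' stale. Exit events carry the completed track.
#'
#' @param state tracker state from [new_tracker()] or a previous step.
#' @param detections detections for frame `frame` (`row`, `col`, `radius`).
#' @param frame frame index, strictly increasing across calls.
#' @return list with updated `state` and a list of `events`
#'   (`type` in `out`, `stale_out`, `anomaly_in`; `frame`; `track`).
#' @export
tracker_step <- function(state, detections, frame) {
  if (frame <= state$last_frame) stop("frame index must be strictly increasing")
  cfg <- state$config
  W <- cfg$frame_shape[2]
  events <- list()
  active_idx <- which(vapply(state$tracks, function(t) isTRUE(t$active), TRUE))
  tracks <- state$tracks[active_idx]
  if (is.null(detections))
    detections <- data.frame(row = numeric(), col = numeric(), radius = numeric())

  C <- build_cost_matrix(tracks, detections, cfg)
  res <- solve_assignment(C)

  # matched pairs -> ASSIGNED
  if (nrow(res$matches)) {
    for (k in seq_len(nrow(res$matches))) {
      ti <- res$matches[k, 1]; di <- res$matches[k, 2]
      tr <- tracks[[ti]]
      det <- detections[di, ]
      if (frame > tr$last_obs_frame)
        tr$velocity <- .clamp_velocity(
          (det$col - tr$last_obs_col) / (frame - tr$last_obs_frame), cfg)
      tr <- .append_history(tr, frame, det$row, det$col, det$radius, "ASSIGNED")
      tr$last_row <- det$row; tr$last_col <- det$col
      tr$last_obs_row <- det$row; tr$last_obs_col <- det$col
      tr$last_obs_frame <- frame
      tr$occl_count <- 0L
      tr$n_obs <- tr$n_obs + 1L
      tracks[[ti]] <- tr
    }
  }

  # unmatched detections -> IN / APPEAR / anomaly IN
  for (di in res$unmatched_detections) {
    det <- detections[di, ]
    appear_ti <- NA_integer_
    if (det$col >= cfg$entry_margin_px) {
      cand <- which(vapply(tracks, function(t) {
        isTRUE(t$active) && t$state == "OCCLUSION" &&
          abs(t$last_row - det$row) <= cfg$appear_lateral_tol_px &&
          (det$col - t$last_obs_col) > 0 &&
          (det$col - t$last_obs_col) <= cfg$gate_px * (t$occl_count + 1) &&
          det$col <= t$last_col + t$velocity + cfg$gate_px
      }, TRUE))
      if (length(cand))
        appear_ti <- cand[which.min(vapply(cand, function(i)
          abs(tracks[[i]]$last_row - det$row), 0))]
    }
    if (!is.na(appear_ti)) {
      tr <- tracks[[appear_ti]]
      if (frame > tr$last_obs_frame)
        tr$velocity <- .clamp_velocity(
          (det$col - tr$last_obs_col) / (frame - tr$last_obs_frame), cfg)
      tr <- .append_history(tr, frame, det$row, det$col, det$radius, "APPEAR")
      tr$last_row <- det$row; tr$last_col <- det$col
      tr$last_obs_row <- det$row; tr$last_obs_col <- det$col
      tr$last_obs_frame <- frame
      tr$occl_count <- 0L
      tr$n_obs <- tr$n_obs + 1L
      tracks[[appear_ti]] <- tr
    } else {
      tr <- .new_track(state$next_id, frame, det, cfg)
      state$next_id <- state$next_id + 1L
      tracks[[length(tracks) + 1]] <- tr
      if (det$col >= cfg$entry_margin_px)
        events[[length(events) + 1]] <- list(type = "anomaly_in",
                                             frame = frame, track = tr)
    }
  }

  # unmatched tracks -> OUT / OCCLUSION / stale OUT
  for (ti in res$unmatched_tracks) {
    tr <- tracks[[ti]]
    p <- predict_position(tr)
    last_radius <- tr$history$radius[nrow(tr$history)]
    # exit only when the object was last *observed* inside the exit zone;
    # a mid-channel miss coasts as OCCLUSION instead of being closed early
    # (it either re-matches, re-appears, or goes stale). The zone scales
    # with the track's own velocity: a slow near-wall object is only "out"
    # once it is within its next displacement of the right edge, while a
    # fast object may jump the whole configured margin between frames.
    margin_eff <- min(cfg$exit_margin_px, max(1.5 * tr$velocity, 15))
    if (p[2] >= W - margin_eff && tr$last_obs_col >= W - margin_eff) {
      tr <- .append_history(tr, frame, p[1], p[2], last_radius, "OUT")
      tr$active <- FALSE
      done <- .complete_track(state, tr, frame, "out", events)
      state <- done$state; events <- done$events
      tracks[[ti]] <- tr
    } else {
      tr <- .append_history(tr, frame, p[1], p[2], last_radius, "OCCLUSION")
      tr$last_row <- p[1]; tr$last_col <- p[2]
      tr$occl_count <- tr$occl_count + 1L
      if (tr$occl_count > cfg$max_occlusion_frames) {
        tr <- .append_history(tr, frame, p[1], p[2], last_radius, "OUT")
        tr$active <- FALSE
        done <- .complete_track(state, tr, frame, "stale_out", events)
        state <- done$state; events <- done$events
      }
      tracks[[ti]] <- tr
    }
  }

  state$tracks[active_idx] <- tracks[seq_along(active_idx)]
  if (length(tracks) > length(active_idx))
    state$tracks <- c(state$tracks, tracks[(length(active_idx) + 1):length(tracks)])
  state$last_frame <- frame
  list(state = state, events = events)
}

#' Run the tracker over a detection stream
#'
#' Folds [tracker_step()] over frames `0 .. n_frames - 1` (frames with no
#' detections still advance the state machine, which is how exits and
#' occlusions progress). The total object count is the last issued track
#' id, which is what prevents objects imaged in many consecutive frames
#' from being counted more than once.
#'
#' @param detections detection table with a `frame` column.
#' @param config a [tracker_config()].
#' @param n_frames number of frames in the stream.
#' @return list with `state`, `count` (last issued id), `events`, and
#'   `completed` (the completed-track buffer contents).
#' @export
run_tracker <- function(detections, config = tracker_config(),
                        n_frames = max(detections$frame) + 1L) {
  state <- new_tracker(config)
  events <- list()
  for (f in seq_len(n_frames) - 1L) {
    step <- tracker_step(state, detections[detections$frame == f, , drop = FALSE], f)
    state <- step$state
    events <- c(events, step$events)
  }
  list(state = state, count = state$next_id - 1L, events = events,
       completed = state$completed)
}

#' Flatten tracker state into a per-frame table
#'
#' @param state tracker state (or result of [run_tracker()]).
#' @return `data.frame` with `track_id,frame,row,col,radius,state`.
#' @export
tracks_table <- function(state) {
  if (!is.null(state$state)) state <- state$state
  rows <- lapply(state$tracks, function(t)
    cbind(track_id = t$id, t$history))
  if (!length(rows))
    return(data.frame(track_id = integer(), frame = integer(), row = numeric(),
                      col = numeric(), radius = numeric(), state = character()))
  do.call(rbind, rows)
}
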