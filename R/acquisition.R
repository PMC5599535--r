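#' Fixed-size circular frame buffer
#'
#' Holds the most recent `capacity` frames, keyed by frame index; lookups
#' of evicted frames fail cleanly with `NULL`. This is the memory that the
#' streaming pipeline keeps instead of storing whole recordings.
#'
#' @param capacity number of frames retained.
#' @export
frame_buffer <- function(capacity = 32) {
  stopifnot(capacity >= 1)
  env <- new.env(parent = emptyenv())
  env$capacity <- as.integer(capacity)
  env$frames <- vector("list", capacity)
  env$indices <- rep(NA_integer_, capacity)
  class(env) <- "frame_buffer"
  env
}

#' @rdname frame_buffer
#' @param buf a frame buffer.
#' @param frame_index integer frame index.
#' @param frame frame image matrix.
#' @export
buffer_push <- function(buf, frame_index, frame) {
  slot <- (frame_index %% buf$capacity) + 1L
  buf$frames[[slot]] <- frame
  buf$indices[slot] <- as.integer(frame_index)
  invisible(buf)
}

#' @rdname frame_buffer
#' @export
buffer_get <- function(buf, frame_index) {
  slot <- (frame_index %% buf$capacity) + 1L
  if (is.na(buf$indices[slot]) || buf$indices[slot] != frame_index) return(NULL)
  buf$frames[[slot]]
}

#' Select the clearest buffered frame of a completed track
#'
#' Scans the track's state history for frames that (a) are still in the
#' buffer, (b) were direct observations (`IN`, `ASSIGNED`, `APPEAR` —
#' never `OCCLUSION`, whose positions are predictions), and (c) whose crop
#' window lies fully inside the frame; among those, the frame whose column
#' is nearest the axial midline of the region of interest is returned as
#' the least edge-truncated, best-framed view.
#'
#' @param track a completed track (state `OUT`).
#' @param buf a [frame_buffer()].
#' @param crop_size crop side length in px (odd).
#' @return the selected frame index, or `NULL` if no history entry
#'   qualifies (e.g. the track was occluded for its whole buffered life).
#' @export
select_clear_frame <- function(track, buf, crop_size = 21) {
  h <- track$history
  stopifnot("OUT" %in% h$state)
  half <- (crop_size - 1) / 2
  cand <- h[h$state %in% c("IN", "ASSIGNED", "APPEAR"), , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  ok <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    f <- buffer_get(buf, cand$frame[i])
    if (is.null(f)) next
    H <- nrow(f); W <- ncol(f)
    r <- round(cand$row[i]); cc <- round(cand$col[i])
    ok[i] <- r - half >= 0 && r + half <= H - 1 &&
             cc - half >= 0 && cc + half <= W - 1
  }
  cand <- cand[ok, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  f0 <- buffer_get(buf, cand$frame[1])
  mid <- (ncol(f0) - 1) / 2
  cand$frame[which.min(abs(cand$col - mid))]
}

#' Crop a fixed-size single-cell image
#'
#' @param frame image matrix.
#' @param center `c(row, col)` in 0-based pixels (rounded to integers).
#' @param size odd crop side length (21 px holds objects up to ~15 um at
#'   1 um/px; configurable for larger cells).
#' @return list with `pixels` (`size x size` matrix), `center`, and
#'   `padded` (`TRUE` if out-of-bounds pixels were filled with the frame's
#'   median background).
#' @export
crop_cell <- function(frame, center, size = 21) {
  if (size %% 2 != 1 || size < 1) stop("crop size must be odd and positive")
  half <- (size - 1) / 2
  r <- round(center[1]); cc <- round(center[2])
  H <- nrow(frame); W <- ncol(frame)
  out <- matrix(stats::median(frame), size, size)
  ri <- (r - half):(r + half); ci <- (cc - half):(cc + half)
  rok <- ri >= 0 & ri <= H - 1; cok <- ci >= 0 & ci <= W - 1
  padded <- !all(rok) || !all(cok)
  if (any(rok) && any(cok))
    out[which(rok), which(cok)] <- frame[ri[rok] + 1, ci[cok] + 1]
  list(pixels = out, center = c(r, cc), padded = padded)
}

#' Acquire the single-cell image of an exiting track
#'
#' Composition of [select_clear_frame()] and [crop_cell()]: called once per
#' exit event, it yields at most one crop per physical object.
#'
#' @param event an exit event from the tracker (`track`, `frame`).
#' @param buf a [frame_buffer()].
#' @param crop_size odd crop side length.
#' @return a single-cell image: list with `pixels`, `track_id`,
#'   `source_frame_index`, `center`, `padded`; or `NULL` when no clear
#'   buffered frame exists.
#' @export
acquire_on_exit <- function(event, buf, crop_size = 21) {
  track <- event$track
  fsel <- select_clear_frame(track, buf, crop_size)
  if (is.null(fsel)) return(NULL)
  h <- track$history
  entry <- h[h$frame == fsel & h$state %in% c("IN", "ASSIGNED", "APPEAR"), ][1, ]
  cr <- crop_cell(buffer_get(buf, fsel), c(entry$row, entry$col), crop_size)
  list(pixels = cr$pixels, track_id = track$id, source_frame_index = fsel,
       center = cr$center, padded = cr$padded)
}
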