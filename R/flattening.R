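#' Configuration for the flattening detector
#'
#' @param stop_threshold minimum admissible peak density. The default is 30%
#'   of the peak of the faintest legitimate object, i.e.
#'   `0.3 / (2 * pi * (r_max / 3)^2)` — a scale-aware floor that rejects
#'   residual ripple without dropping large, dim objects.
#' @param zero_radius_factor radius of the zero-out disk in units of the
#'   extracted component's sigma; 4 covers the truncation extent used when
#'   maps are built.
#' @param max_detections hard cap on extracted components per map.
#' @param r_max largest expected object radius in px (sets the default
#'   `stop_threshold`).
#' @export
flattening_config <- function(stop_threshold = NULL, zero_radius_factor = 4,
                              max_detections = 200, r_max = 21) {
  if (is.null(stop_threshold))
    stop_threshold <- 0.3 / (2 * pi * (r_max / 3)^2)
  stopifnot(stop_threshold > 0, zero_radius_factor >= 3, max_detections >= 1)
  list(stop_threshold = stop_threshold,
       zero_radius_factor = zero_radius_factor,
       max_detections = as.integer(max_detections))
}

#' Extract all Gaussian components from a density map ("flattening")
#'
#' Iteratively (1) finds the global maximum `p_max` of the map and its pixel
#' index, (2) records a detection with that center, the variance
#' `1 / (2 * pi * p_max)` and radius `3 * sigma`, and (3) zeroes all pixels
#' within `zero_radius_factor * sigma` of the center, until the remaining
#' maximum falls below `stop_threshold` or `max_detections` is reached.
#' Because the global maximum always belongs to the smallest-variance
#' component still present, detections come out in descending peak order.
#' Ties on the maximum are broken toward the smallest (row, col) in
#' lexicographic order for determinism. Centers are integer pixels (the
#' argmax index); no sub-pixel refinement is applied.
#'
#' @param map nonnegative density map matrix.
#' @param config a [flattening_config()].
#' @param frame_index frame index stored on each detection.
#' @return a `data.frame` with columns `frame`, `row`, `col` (0-based
#'   integer pixels), `radius`, `score` (the peak density), in extraction
#'   order (scores non-increasing).
#' @export
flatten <- function(map, config = flattening_config(), frame_index = 0L) {
  if (!is.matrix(map)) stop("map must be a matrix")
  if (any(map < 0)) stop("density map must be nonnegative")
  H <- nrow(map); W <- ncol(map)
  out <- vector("list", config$max_detections)
  n <- 0L
  while (n < config$max_detections) {
    p_max <- max(map)
    if (p_max < config$stop_threshold) break
    idx <- which(map == p_max)
    r0 <- (idx - 1L) %% H
    c0 <- (idx - 1L) %/% H
    o <- order(r0, c0)[1L]  # smallest (row, col) lexicographically
    ri <- r0[o]; ci <- c0[o]
    s2 <- peak_to_variance(p_max)
    s <- sqrt(s2)
    n <- n + 1L
    out[[n]] <- c(ri, ci, 3 * s, p_max)
    zr <- config$zero_radius_factor * s
    i0 <- max(0L, as.integer(floor(ri - zr))); i1 <- min(H - 1L, as.integer(ceiling(ri + zr)))
    j0 <- max(0L, as.integer(floor(ci - zr))); j1 <- min(W - 1L, as.integer(ceiling(ci + zr)))
    ii <- i0:i1; jj <- j0:j1
    d2 <- outer((ii - ri)^2, (jj - ci)^2, `+`)
    blk <- map[ii + 1L, jj + 1L, drop = FALSE]
    blk[d2 <= zr^2] <- 0
    map[ii + 1L, jj + 1L] <- blk
  }
  if (n == 0L)
    return(data.frame(frame = integer(), row = integer(), col = integer(),
                      radius = numeric(), score = numeric()))
  m <- do.call(rbind, out[seq_len(n)])
  data.frame(frame = as.integer(frame_index), row = as.integer(m[, 1]),
             col = as.integer(m[, 2]), radius = m[, 3], score = m[, 4])
}

#' Axis-aligned square box of a detection
#'
#' The box side is twice the detection radius, centered on the detection;
#' used by the IoU-based evaluation protocol.
#'
#' @param d detection table (rows from [flatten()] or any table with
#'   `row`, `col`, `radius`).
#' @return `data.frame` with columns `col_min`, `row_min`, `col_max`,
#'   `row_max`.
#' @export
detection_to_box <- function(d) {
  data.frame(col_min = d$col - d$radius, row_min = d$row - d$radius,
             col_max = d$col + d$radius, row_max = d$row + d$radius)
}

#' @rdname flatten
#' @param detections detection table.
#' @param path CSV path (`frame,row,col,radius,score`).
#' @export
write_detections <- function(detections, path) {
  utils::write.csv(detections, path, row.names = FALSE)
  invisible(path)
}
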