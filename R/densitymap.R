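#' Build a Gaussian-mixture density map from annotations
#'
#' Each annotated object contributes one normalized isotropic bivariate
#' Gaussian with mean at its center and standard deviation `radius / 3`
#' (no mixing coefficient, so the map integrates to approximately the number
#' of objects whose footprint lies inside the grid). Components are truncated
#' to zero beyond 4 standard deviations of their center; the discarded mass
#' is below 0.04% per component.
#'
#' @param ann annotation table (see [annotations()]); may have zero rows.
#' @param shape integer vector `c(H, W)` of the output grid in pixels.
#' @return an `H x W` numeric matrix of nonnegative densities. Pixel (i, j)
#'   in 0-based coordinates is element `[i + 1, j + 1]`.
#' @examples
#' m <- build_density_map(annotations(50, 250, 9), c(100, 500))
#' max(m)  # ~ 1 / (2 * pi * 9)
#' @export
build_density_map <- function(ann, shape) {
  stopifnot(length(shape) == 2, all(shape >= 1))
  validate_annotations(ann)
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  Y <- matrix(0, H, W)
  if (nrow(ann) == 0) return(Y)
  for (k in seq_len(nrow(ann))) {
    mu_r <- ann$row[k]; mu_c <- ann$col[k]
    s <- ann$radius[k] / 3
    ext <- 4 * s
    i0 <- max(0L, as.integer(floor(mu_r - ext)))
    i1 <- min(H - 1L, as.integer(ceiling(mu_r + ext)))
    j0 <- max(0L, as.integer(floor(mu_c - ext)))
    j1 <- min(W - 1L, as.integer(ceiling(mu_c + ext)))
    if (i0 > i1 || j0 > j1) next
    ii <- i0:i1; jj <- j0:j1
    d2 <- outer((ii - mu_r)^2, (jj - mu_c)^2, `+`)
    g <- exp(-d2 / (2 * s^2)) / (2 * pi * s^2)
    g[d2 > ext^2] <- 0
    Y[ii + 1L, jj + 1L] <- Y[ii + 1L, jj + 1L] + g
  }
  Y
}

#' Variance of a Gaussian component from its peak density
#'
#' The peak of a normalized isotropic bivariate Gaussian with variance
#' `sigma^2` is `p_max = 1 / (2 * pi * sigma^2)`; inverting gives the
#' variance from the observed global maximum of a density map. Larger
#' objects therefore have lower peaks, which is why iterative peak
#' extraction always removes the smallest-variance component first.
#'
#' @param p_max positive peak density value.
#' @return the variance `sigma^2 = 1 / (2 * pi * p_max)` in px^2.
#' @export
peak_to_variance <- function(p_max) {
  if (any(!is.finite(p_max) | p_max <= 0))
    stop("p_max must be positive and finite")
  1 / (2 * pi * p_max)
}

#' Perfect segmenter backed by ground-truth annotations
#'
#' Renders the density map that an ideal image-to-density-map regressor
#' would output for a frame, directly from ground-truth annotations. Used
#' to isolate downstream stages (flattening, tracking, acquisition) from
#' detector error in tests and experiments.
#'
#' @param ann ground-truth annotations for one frame.
#' @param shape `c(H, W)` frame shape in pixels.
#' @export
oracle_segment <- function(ann, shape) build_density_map(ann, shape)

#' Make a segmenter function from per-frame ground truth
#'
#' @param truth per-frame annotation table with a `frame` column.
#' @param shape frame shape `c(H, W)`.
#' @return a function `(frame_image, frame_index) -> density map` that
#'   ignores the pixels and renders the truth for `frame_index`.
#' @export
oracle_segmenter <- function(truth, shape) {
  force(truth); force(shape)
  function(frame, frame_index) {
    oracle_segment(truth[truth$frame == frame_index, , drop = FALSE], shape)
  }
}

# fraction of a disk of radius r centered at column c that lies within
# columns [0, W-1] (circular-segment area; row truncation cannot occur)
.disk_visible_frac <- function(c0, r, W) {
  seg <- function(d) {  # area fraction beyond a chord at distance d from center
    if (d >= r) return(0)
    if (d <= -r) return(1)
    (r^2 * acos(d / r) - d * sqrt(r^2 - d^2)) / (pi * r^2)
  }
  1 - seg(c0) - seg(W - 1 - c0)
}

# 3x3-neighbourhood strict-or-equal local maxima above a threshold.
# Returns an H x W logical matrix. Plateaus are handled downstream by
# non-maximum suppression.
.local_max_3x3 <- function(m, thr) {
  H <- nrow(m); W <- ncol(m)
  p <- matrix(-Inf, H + 2, W + 2)
  p[2:(H + 1), 2:(W + 1)] <- m
  ok <- m >= thr
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ok <- ok & (m >= p[(2 + di):(H + 1 + di), (2 + dj):(W + 1 + dj)])
  }
  ok
}

#' Classical blob-based segmenter for bright-field frames
#'
#' A drop-in implementation of the image-to-density-map contract using
#' multi-scale Laplacian-of-Gaussian (LoG) blob detection: the frame is
#' inverted (bright-field objects are dark), normalized by its median
#' background, and the scale-normalized LoG response is maximized over
#' position and scale. Each blob becomes an annotation with radius
#' `sqrt(2) * sigma_LoG` (the conventional LoG scale-radius relation) and
#' the set is rendered with [build_density_map()], so the output obeys the
#' same Gaussian-mixture convention as the oracle segmenter.
#'
#' @param frame single-channel numeric matrix (0..255 or 0..1).
#' @param scale_range `c(sigma_min, sigma_max)` LoG scales in px; the
#'   default covers object radii of roughly 2 to 10 px.
#' @param response_threshold minimum scale-normalized LoG response, in
#'   units of fractional contrast against the background.
#' @param amplitude in-focus darkness amplitude (fraction of background)
#'   used for the blur-invariant mass-based radius estimate; when `NULL`
#'   it is estimated from the darkest blobs of this frame. The streaming
#'   pipeline supplies a running estimate across frames.
#' @param return_annotations if `TRUE`, return the blob annotation table
#'   (with `depth` and `mass` columns) instead of the rendered density map.
#' @return density map matrix of the same shape as `frame` (or the
#'   annotation table).
#' @export
blob_segment <- function(frame, scale_range = c(1.4, 5.5),
                         response_threshold = 0.06,
                         amplitude = NULL,
                         return_annotations = FALSE) {
  if (!is.matrix(frame) || length(frame) == 0)
    stop("frame must be a non-empty single-channel matrix")
  if (length(scale_range) != 2 || any(scale_range <= 0) ||
      scale_range[2] < scale_range[1])
    stop("degenerate scale range")
  f <- frame / if (max(frame) > 1) 255 else 1
  bg <- stats::median(f)
  work <- (bg - f) / max(bg, 1e-6)  # dark objects -> positive contrast

  sigmas <- exp(seq(log(scale_range[1]), log(scale_range[2]),
                    length.out = max(3, ceiling(log(scale_range[2] / scale_range[1]) / log(1.22)) + 1)))
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  resp <- lapply(sigmas, function(s) {
    sm <- EBImage::gblur(work, sigma = s, boundary = "replicate")
    -s^2 * EBImage::filter2(sm, lap, boundary = "replicate")
  })

  cand <- NULL
  for (si in seq_along(sigmas)) {
    r <- resp[[si]]
    ok <- .local_max_3x3(r, response_threshold)
    # border pixels carry boundary-padding artifacts; never seed blobs there
    ok[c(1, nrow(ok)), ] <- FALSE
    ok[, c(1, ncol(ok))] <- FALSE
    if (si > 1) ok <- ok & (r >= resp[[si - 1]])
    if (si < length(sigmas)) ok <- ok & (r >= resp[[si + 1]])
    idx <- which(ok)
    if (length(idx)) {
      cand <- rbind(cand, data.frame(
        row = (idx - 1) %% nrow(r), col = (idx - 1) %/% nrow(r),
        sigma = sigmas[si], resp = r[idx]))
    }
  }
  ann <- annotations()
  if (!is.null(cand) && nrow(cand) > 0) {
    cand <- cand[order(-cand$resp), , drop = FALSE]
    keep <- logical(0); krow <- numeric(0); kcol <- numeric(0)
    for (i in seq_len(nrow(cand))) {
      if (length(krow) == 0 ||
          all((krow - cand$row[i])^2 + (kcol - cand$col[i])^2 >
              pmax(2, sqrt(2) * cand$sigma[i])^2)) {
        keep <- c(keep, i); krow <- c(krow, cand$row[i]); kcol <- c(kcol, cand$col[i])
      }
    }
    cand <- cand[keep, , drop = FALSE]
    # Radius refinement from integrated darkness ("mass"). Blur
    # redistributes but conserves the darkness of an absorbing disk, so
    # M = amplitude * pi * r^2 holds regardless of defocus, unlike the raw
    # LoG scale, which inflates with blur. The in-focus amplitude is
    # self-calibrated from the darkest blobs when not supplied; windows of
    # close neighbours are apportioned by nearest blob so they do not
    # double-count each other's darkness.
    n <- nrow(cand)
    win <- vector("list", n)
    depth <- numeric(n)
    for (i in seq_len(n)) {
      r0 <- sqrt(2) * cand$sigma[i]
      ext <- ceiling(2 * r0 + 3)
      i0 <- max(0, cand$row[i] - ext); i1 <- min(nrow(frame) - 1, cand$row[i] + ext)
      j0 <- max(0, cand$col[i] - ext); j1 <- min(ncol(frame) - 1, cand$col[i] + ext)
      u <- bg - f[(i0:i1) + 1, (j0:j1) + 1, drop = FALSE]
      d2w <- outer(((i0:i1) - cand$row[i])^2, ((j0:j1) - cand$col[i])^2, `+`)
      inside <- d2w <= ext^2
      nb <- which(seq_len(n) != i &
                  (cand$row - cand$row[i])^2 + (cand$col - cand$col[i])^2 <
                    (2 * ext)^2)
      for (j in nb) {
        d2j <- outer(((i0:i1) - cand$row[j])^2, ((j0:j1) - cand$col[j])^2, `+`)
        inside <- inside & d2w <= d2j
      }
      depth[i] <- max(u[d2w <= max(4, r0^2)])
      win[[i]] <- list(mass = sum(u[inside]), r0 = r0)
    }
    amp <- amplitude
    if (is.null(amp)) amp <- max(stats::quantile(depth, 0.85), 0.05)
    rad <- numeric(n); stacked <- integer(n)
    for (i in seq_len(n)) {
      w <- win[[i]]
      # objects entering/leaving the frame are truncated along the column
      # axis only (rows are walls, excluded by the object radius)
      vis_frac <- .disk_visible_frac(cand$col[i], w$r0, ncol(frame))
      m <- w$mass / max(vis_frac, 0.3)
      # darkness much deeper than one absorbing object can produce means
      # two objects stacked in depth (an occlusion): the blob's mass then
      # belongs to k objects, so the single-object radius shrinks by sqrt(k)
      k <- max(1, min(2, round(depth[i] / amp)))
      stacked[i] <- k
      rad[i] <- min(max(sqrt(pmax(m, 1) / (pi * amp * k)), 1.5), 15)
    }
    ann <- annotations(cand$row, cand$col, radius = rad)
    ann$depth <- depth; ann$n_stacked <- stacked
  }
  if (return_annotations) return(ann)
  build_density_map(ann[, c("row", "col", "radius", "class", "object_id")],
                    dim(frame))
}

#' Write a density map as a 32-bit float TIFF (debug output)
#'
#' @param map density map matrix.
#' @param path output file path.
#' @export
write_density_map <- function(map, path) {
  tiff::writeTIFF(pmin(map, 1), path, bits.per.sample = 32)
  invisible(path)
}
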