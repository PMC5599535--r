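#' Extract a feature vector from a single-cell crop
#'
#' Hand-crafted features for size-based bead/cell discrimination, computed
#' on the background-subtracted darkness image `u = bg - x` with `bg` the
#' median of the crop border (so the vector is invariant to an additive
#' intensity offset). The radial profile uses the *median* darkness per
#' concentric ring about the patch center: an off-center second object (a
#' doublet) occupies a limited angular sector of any ring, so ring medians
#' — and everything derived from them — follow the centered object.
#' Second-moment features use a tight center weight for the same reason.
#'
#' Features: central depth (peak of the two innermost ring medians), the
#' 9 ring medians themselves (rings of width 1.25 px), the equivalent
#' radius of the half-depth dark core, and center-weighted second central
#' moments (row, col, cross).
#'
#' @param crop numeric matrix (square, odd side, e.g. 21 x 21) or a
#'   single-cell image list with a `pixels` element.
#' @return named numeric vector of length 14.
#' @export
extract_features <- function(crop) {
  x <- if (is.list(crop)) crop$pixels else crop
  if (!is.matrix(x) || nrow(x) != ncol(x) || nrow(x) %% 2 != 1)
    stop("crop must be a square matrix with odd side length")
  n <- nrow(x); c0 <- (n - 1) / 2
  border <- c(x[1, ], x[n, ], x[, 1], x[, n])
  bg <- stats::median(border)
  u <- bg - x
  d <- sqrt(outer((seq_len(n) - 1 - c0)^2, (seq_len(n) - 1 - c0)^2, `+`))
  ring <- pmin(floor(d / 1.25), 8)
  med <- vapply(0:8, function(k) stats::median(u[ring == k]), 0)
  names(med) <- paste0("ring", 0:8)
  depth <- max(med[1:2], 0)
  dark_rings <- med > depth / 2 & depth > 3
  eq_radius <- if (any(dark_rings)) 1.25 * max(which(dark_rings)) else 0
  w <- pmax(u, 0) * exp(-(d / 4)^2)
  sw <- sum(w)
  mom <- if (sw > 1e-9) {
    rr <- row(x) - 1 - c0; cc <- col(x) - 1 - c0
    c(m_rr = sum(w * rr^2) / sw, m_cc = sum(w * cc^2) / sw,
      m_rc = sum(w * rr * cc) / sw)
  } else c(m_rr = 0, m_cc = 0, m_rc = 0)
  c(depth = depth, eq_radius = eq_radius, med, mom)
}

#' Train the baseline single-cell classifier
#'
#' Multinomial logistic regression (via [nnet::multinom()]) on
#' [extract_features()], with standardized features. The classifier is a
#' pluggable seam: any model mapping a crop to a probability vector over
#' classes can replace it.
#'
#' @param crops list of crop matrices (or single-cell image lists).
#' @param labels character/factor class labels, one per crop.
#' @param seed RNG seed (training is reproducible given data and seed).
#' @return an object of class `ifc_classifier`.
#' @export
train_classifier <- function(crops, labels, seed = 0) {
  labels <- as.character(labels)
  stopifnot(length(crops) == length(labels))
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("training requires at least 2 classes")
  if (min(table(labels)) < 10) stop("need at least 10 crops per class")
  X <- t(vapply(crops, extract_features, numeric(14)))
  ctr <- colMeans(X); scl <- apply(X, 2, stats::sd); scl[scl < 1e-9] <- 1
  Xs <- scale(X, ctr, scl)
  df <- data.frame(Xs)
  df$.label <- factor(labels, levels = classes)
  set.seed(seed)
  fit <- nnet::multinom(.label ~ ., df, trace = FALSE, maxit = 400,
                        MaxNWts = 5000)
  structure(list(fit = fit, classes = classes, center = ctr, scale = scl,
                 feature_names = colnames(X)),
            class = "ifc_classifier")
}

#' Classify a single-cell crop
#'
#' @param model an `ifc_classifier` (or any object with a compatible
#'   `predict_cell` method).
#' @param crop crop matrix or single-cell image list.
#' @return list with `label` (argmax class) and `prob` (named probability
#'   vector summing to 1).
#' @export
predict_cell <- function(model, crop) {
  stopifnot(inherits(model, "ifc_classifier"))
  x <- extract_features(crop)
  xs <- as.data.frame(t((x - model$center) / model$scale))
  pr <- stats::predict(model$fit, newdata = xs, type = "probs")
  if (length(model$classes) == 2) pr <- c(1 - pr, pr)
  pr <- as.numeric(pr); names(pr) <- model$classes
  list(label = model$classes[which.max(pr)], prob = pr)
}

#' Save / load a trained classifier
#'
#' @param model an `ifc_classifier`.
#' @param path file path.
#' @export
save_classifier <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) readRDS(path)

#' 2-D embedding of crop features for population scatter plots
#'
#' Principal-component projection of the feature vectors to two
#' dimensions, for presentation of class populations (the cytometric
#' scatter view). Deterministic: component signs are fixed so the largest
#' loading of each axis is positive.
#'
#' @param crops list of crops (or a precomputed feature matrix).
#' @return n x 2 matrix of embedding coordinates.
#' @export
embed_scatter <- function(crops) {
  X <- if (is.matrix(crops)) crops else
    t(vapply(crops, extract_features, numeric(14)))
  keep <- apply(X, 2, stats::sd) > 1e-9
  if (sum(keep) < 2) return(matrix(0, nrow(X), 2))
  pc <- stats::prcomp(X[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  k <- min(2, ncol(pc$x))
  Y <- pc$x[, seq_len(k), drop = FALSE]
  if (k < 2) Y <- cbind(Y, 0)
  for (j in 1:2) if (max(Y[, j]) < -min(Y[, j])) Y[, j] <- -Y[, j]
  unname(Y)
}

#' Simulate labeled single-cell crops
#'
#' Renders particles of the given diameters with the same camera model as
#' the video simulator (defocus, motion blur, sensor noise) and crops them
#' to the standard single-cell size; used to train and benchmark the
#' classifier with known labels. With `doublet = TRUE` each crop also
#' contains a second, off-center particle of a random class.
#'
#' @param diameters_um particle diameters (one class per diameter).
#' @param n_per_class crops per class.
#' @param seed RNG seed.
#' @param config a [flow_config()] (supplies the optical/flow regime).
#' @param render [render_params()].
#' @param crop_size crop side length.
#' @param doublet add an off-center second particle to every crop.
#' @return list with `crops` (list of matrices), `labels`, and `meta`
#'   (per-crop depth, jitter, and doublet class).
#' @export
simulate_crop_dataset <- function(diameters_um = c(7, 10, 15),
                                  n_per_class = 300, seed = 0,
                                  config = flow_config(),
                                  render = render_params(),
                                  crop_size = 21, doublet = FALSE) {
  set.seed(seed)
  side <- crop_size + 10
  local_cfg <- config
  local_cfg$roi_px <- c(side, side)
  c0 <- (side - 1) / 2
  crops <- list(); labels <- character(); meta <- NULL
  for (d in diameters_um) {
    r_um <- d / 2
    for (i in seq_len(n_per_class)) {
      depth <- stats::runif(1, r_um, config$channel_height_um - r_um)
      lat <- stats::runif(1, r_um, config$channel_width_um - r_um)
      v_px <- axial_velocity(lat, depth, config) / config$frame_rate_hz /
        config$um_per_px
      jr <- stats::runif(1, -1, 1); jc <- stats::runif(1, -1, 1)
      parts <- data.frame(row = c0 + jr, col = c0 + jc,
                          radius_px = r_um / config$um_per_px,
                          depth_um = depth, velocity_px = v_px)
      dcls <- NA_character_
      if (doublet) {
        d2 <- sample(diameters_um, 1)
        ang <- stats::runif(1, 0, 2 * pi)
        off_lo <- (d + d2) / 2 / config$um_per_px + 1
        off <- stats::runif(1, off_lo, max(off_lo + 1, 12))
        dep2 <- stats::runif(1, d2 / 2, config$channel_height_um - d2 / 2)
        parts <- rbind(parts, data.frame(
          row = c0 + jr + off * sin(ang), col = c0 + jc + off * cos(ang),
          radius_px = d2 / 2 / config$um_per_px, depth_um = dep2,
          velocity_px = v_px))
        dcls <- paste0(d2, "um")
      }
      frame <- render_frame(parts, local_cfg, render)
      cr <- crop_cell(frame, c(c0 + jr, c0 + jc), crop_size)
      crops[[length(crops) + 1]] <- cr$pixels
      labels <- c(labels, paste0(d, "um"))
      meta <- rbind(meta, data.frame(class = paste0(d, "um"), depth_um = depth,
                                     jitter_row = jr, jitter_col = jc,
                                     doublet_class = dcls))
    }
  }
  list(crops = crops, labels = labels, meta = meta)
}
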