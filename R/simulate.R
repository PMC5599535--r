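#' Suspension specification
#'
#' Describes a mixed suspension of polystyrene micro-particles: one stock
#' per diameter at a given mass fraction, mixed in equal volumes.
#'
#' @param diameters_um distinct particle diameters in micrometers.
#' @param mass_fraction_percent mass fraction of each stock in % w/w.
#' @param particle_density_g_per_ml particle material density
#'   (polystyrene ~ 1.05 g/mL).
#' @param n_stocks_mixed number of stocks mixed in equal volumes (defaults
#'   to the number of diameters).
#' @export
suspension_spec <- function(diameters_um = c(7, 10, 15),
                            mass_fraction_percent = 0.3,
                            particle_density_g_per_ml = 1.05,
                            n_stocks_mixed = length(diameters_um)) {
  stopifnot(all(diameters_um > 0), anyDuplicated(diameters_um) == 0,
            mass_fraction_percent > 0, particle_density_g_per_ml > 0,
            n_stocks_mixed >= 1)
  as.list(environment())
}

#' Flow / imaging configuration
#'
#' @param channel_height_um,channel_width_um microchannel cross-section
#'   (depth direction and lateral/imaged direction) in micrometers.
#' @param roi_px imaged region of interest `c(rows, cols)`; rows span the
#'   channel width, cols the flow direction.
#' @param um_per_px image scale.
#' @param flow_rate_ul_per_min volumetric flow rate.
#' @param frame_rate_hz camera frame rate.
#' @param shutter_s exposure time per frame in seconds.
#' @export
flow_config <- function(channel_height_um = 50, channel_width_um = 100,
                        roi_px = c(100, 500), um_per_px = 1,
                        flow_rate_ul_per_min = 6, frame_rate_hz = 500,
                        shutter_s = 1e-4) {
  stopifnot(channel_height_um > 0, channel_width_um > 0, all(roi_px > 0),
            um_per_px > 0, flow_rate_ul_per_min >= 0, frame_rate_hz > 0,
            shutter_s > 0, roi_px[1] * um_per_px <= channel_width_um + 1e-9)
  as.list(environment())
}

#' Number concentration of a mixed suspension
#'
#' Converts mass concentrations to particle number concentrations: after
#' equal-volume mixing of `n_stocks_mixed` stocks, each class has mass
#' concentration `mass_fraction/100 * 1 g/mL / n_stocks_mixed`, and its
#' number concentration is that mass divided by the single-particle mass
#' `rho * pi/6 * d^3`. Because the stocks share the same mass fraction,
#' counts scale as `d^-3`.
#'
#' @param spec a [suspension_spec()].
#' @return list with `per_class` (particles/uL per diameter), `total`, and
#'   `ratio` (rounded, normalized to 100 for the smallest diameter).
#' @export
number_concentration <- function(spec) {
  d_cm <- spec$diameters_um * 1e-4
  mass_per_particle <- spec$particle_density_g_per_ml * (pi / 6) * d_cm^3  # g
  c_g_per_ml <- (spec$mass_fraction_percent / 100) * 1 / spec$n_stocks_mixed
  per_ml <- c_g_per_ml / mass_per_particle
  per_ul <- per_ml / 1e3
  names(per_ul) <- paste0(spec$diameters_um, "um")
  ref <- per_ul[which.min(spec$diameters_um)]
  list(per_class = per_ul, total = sum(per_ul),
       ratio = round(100 * per_ul / ref))
}

#' Estimated throughput from flow rate and concentration
#'
#' `Throughput [count/s] = Flow rate [uL/s] x concentration [count/uL]`,
#' rounded to the nearest integer for reporting.
#'
#' @param flow_rate_ul_per_min flow rate in uL/min.
#' @param concentration_per_ul number concentration in particles/uL.
#' @export
estimated_throughput <- function(flow_rate_ul_per_min, concentration_per_ul) {
  stopifnot(flow_rate_ul_per_min >= 0, concentration_per_ul >= 0)
  round(flow_rate_ul_per_min / 60 * concentration_per_ul)
}

#' Axial velocity of the Poiseuille-like channel flow
#'
#' Product-of-parabolas profile over the rectangular cross-section:
#' `u = U_max (1 - (2 y'/W)^2) (1 - (2 z'/H)^2)` with `y'`, `z'` offsets
#' from the channel center and `U_max = 9/4 * Q/A`, so the cross-sectional
#' mean equals `Q/A`. Fastest mid-channel, zero at the walls; two objects
#' at different depths therefore travel at different speeds, which is what
#' makes image-plane occlusions transient.
#'
#' @param lateral_um position across the channel width, in (0, W).
#' @param depth_um position across the channel height, in (0, H).
#' @param config a [flow_config()].
#' @return axial velocity in um/s.
#' @export
axial_velocity <- function(lateral_um, depth_um, config) {
  W <- config$channel_width_um; H <- config$channel_height_um
  if (any(lateral_um <= 0 | lateral_um >= W | depth_um <= 0 | depth_um >= H))
    stop("position must be strictly inside the channel")
  Q <- config$flow_rate_ul_per_min * 1e9 / 60  # um^3/s
  A <- W * H
  u_max <- 9 / 4 * Q / A
  u_max * (1 - (2 * (lateral_um - W / 2) / W)^2) *
          (1 - (2 * (depth_um - H / 2) / H)^2)
}

# separable Gaussian blur of a small matrix (edge-replicated)
.sep_blur <- function(m, sigma) {
  if (sigma < 0.15) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma); k <- k / sum(k)
  n <- nrow(m); p <- ncol(m)
  pad <- function(x, r) c(rep(x[1], r), x, rep(x[length(x)], r))
  conv1 <- function(x) stats::filter(pad(x, r), k, sides = 2)[(r + 1):(r + length(x))]
  m <- apply(m, 2, conv1)
  t(apply(t(m), 2, conv1))
}

#' Render one bright-field frame of the microchannel
#'
#' Particles are drawn as darkened disks with anti-aliased edges, motion-
#' blurred by averaging 5 sub-exposure positions spanning the streak
#' `velocity x shutter`, defocus-blurred by a Gaussian PSF whose width
#' grows linearly with distance from the mid-channel focal plane, then
#' sensor noise is added and the image is clipped and quantized to 8 bits.
#'
#' @param particles `data.frame` with `row`, `col` (px), `radius_px`,
#'   `depth_um`, `velocity_px` (per frame).
#' @param config a [flow_config()].
#' @param render list of rendering parameters, see [render_params()].
#' @return integer matrix (0..255) of shape `roi_px`.
#' @export
render_frame <- function(particles, config, render = render_params()) {
  H <- config$roi_px[1]; W <- config$roi_px[2]
  img <- matrix(render$background, H, W)
  if (abs(render$gradient) > 0)
    img <- img + render$gradient * (col(img) - (W + 1) / 2) / W
  if (!is.null(particles) && nrow(particles) > 0) {
    for (k in seq_len(nrow(particles))) {
      p <- particles[k, ]
      z_off <- abs(p$depth_um - config$channel_height_um / 2)
      s_psf <- render$psf_sigma0 + render$defocus_px_per_um * z_off
      streak <- p$velocity_px * config$shutter_s * config$frame_rate_hz
      ext <- ceiling(p$radius_px + 3 * s_psf + streak / 2 + 2)
      i0 <- max(0, floor(p$row - ext)); i1 <- min(H - 1, ceiling(p$row + ext))
      j0 <- max(0, floor(p$col - ext)); j1 <- min(W - 1, ceiling(p$col + ext))
      if (i0 > i1 || j0 > j1) next
      ii <- i0:i1; jj <- j0:j1
      acc <- matrix(0, length(ii), length(jj))
      offs <- if (streak > 0.01) seq(-streak / 2, streak / 2, length.out = 5) else 0
      for (o in offs) {
        d <- sqrt(outer((ii - p$row)^2, (jj - (p$col + o))^2, `+`))
        acc <- acc + pmin(pmax(p$radius_px - d + 0.5, 0), 1)
      }
      acc <- acc / length(offs)
      acc <- .sep_blur(acc, s_psf)
      img[ii + 1, jj + 1] <- img[ii + 1, jj + 1] - render$contrast * acc
    }
  }
  img <- img + matrix(stats::rnorm(H * W, 0, render$noise_sd), H, W)
  matrix(as.integer(pmin(pmax(round(img), 0), 255)), H, W)
}

#' Construct a two-particle occlusion episode
#'
#' Builds the canonical occlusion scenario: two particles on the same
#' lateral line but at different depths, so the deeper/more central one
#' travels faster, catches up with the other inside the region of
#' interest, overlaps it for a few frames, and escapes. Used to exercise
#' the tracker's occlusion / appear states with known ground truth.
#'
#' @param seed RNG seed (randomizes diameters, rows, depths, meeting
#'   point).
#' @param config a [flow_config()].
#' @param render [render_params()].
#' @param n_frames frames to simulate (default covers both transits).
#' @return same structure as [simulate_sequence()].
#' @export
simulate_occlusion_pair <- function(seed = 1, config = flow_config(),
                                    render = render_params(),
                                    n_frames = 24) {
  set.seed(seed)
  d_um <- sample(c(7, 10, 15), 2, replace = TRUE)
  r_px <- d_um / 2 / config$um_per_px
  row <- stats::runif(1, max(r_px) + 2, config$roi_px[1] - max(r_px) - 2)
  lat <- row * config$um_per_px
  # slow particle near a wall, fast one near mid-depth
  H <- config$channel_height_um
  z_slow <- stats::runif(1, d_um[1] / 2 + 1, d_um[1] / 2 + 6)
  z_fast <- stats::runif(1, H / 2 - 6, H / 2 + 6)
  v <- c(axial_velocity(lat, z_slow, config),
         axial_velocity(lat, z_fast, config)) / config$frame_rate_hz /
    config$um_per_px
  meet_col <- stats::runif(1, 180, 320)
  meet_t <- 8
  arrival <- meet_t - (meet_col + r_px) / v  # col(t) = -r + (t - arrival) v
  objects <- data.frame(
    object_id = 1:2, arrival_time = arrival, class = paste0(d_um, "um"),
    radius_px = r_px, row = c(row, row + stats::runif(1, -1, 1)),
    depth_um = c(z_slow, z_fast), velocity_px = v)
  sim_from_objects(objects, config, render, n_frames, seed)
}

#' Simulate frames from an explicit object table
#'
#' Lower-level entry point shared by [simulate_sequence()] and
#' [simulate_occlusion_pair()]: renders a caller-constructed set of
#' trajectories (one row per object: `object_id`, `arrival_time`, `class`,
#' `radius_px`, `row`, `depth_um`, `velocity_px`) and derives per-frame
#' ground truth, letting tests build exact scenarios such as guaranteed
#' occlusion-free streams.
#'
#' @param objects object table as above.
#' @param config a [flow_config()].
#' @param render [render_params()].
#' @param n_frames number of frames.
#' @param seed recorded in the output (the caller controls the RNG state).
#' @return same structure as [simulate_sequence()].
#' @export
sim_from_objects <- function(objects, config = flow_config(),
                             render = render_params(), n_frames = 50,
                             seed = NA) {
  W_px <- config$roi_px[2]
  frames <- vector("list", n_frames)
  truth_rows <- vector("list", n_frames)
  for (f in seq_len(n_frames) - 1L) {
    col_f <- -objects$radius_px + (f - objects$arrival_time) * objects$velocity_px
    # rendering covers partially-entered/exited disks; the truth table only
    # lists objects whose center is inside the imaged region (others are
    # not countable or localizable in that frame)
    vis <- which(f >= objects$arrival_time & col_f < W_px + objects$radius_px)
    ann <- NULL
    if (length(vis))
      ann <- data.frame(frame = f, object_id = objects$object_id[vis],
                        row = objects$row[vis], col = col_f[vis],
                        radius = objects$radius_px[vis],
                        class = objects$class[vis],
                        depth_um = objects$depth_um[vis],
                        velocity_px = objects$velocity_px[vis])
    occl <- logical(if (is.null(ann)) 0 else nrow(ann))
    if (!is.null(ann) && nrow(ann) > 1) {
      for (a in seq_len(nrow(ann) - 1)) for (b in (a + 1):nrow(ann)) {
        dd <- sqrt((ann$row[a] - ann$row[b])^2 + (ann$col[a] - ann$col[b])^2)
        if (dd < ann$radius[a] + ann$radius[b]) occl[c(a, b)] <- TRUE
      }
    }
    if (!is.null(ann)) ann$occluded <- occl
    frames[[f + 1]] <- render_frame(
      if (is.null(ann)) NULL else
        data.frame(row = ann$row, col = ann$col, radius_px = ann$radius,
                   depth_um = ann$depth_um, velocity_px = ann$velocity_px),
      config, render)
    if (!is.null(ann))
      ann <- ann[ann$col >= 0 & ann$col <= W_px - 1, , drop = FALSE]
    truth_rows[[f + 1]] <- if (!is.null(ann) && nrow(ann)) ann else NULL
  }
  truth <- do.call(rbind, truth_rows[!vapply(truth_rows, is.null, TRUE)])
  if (is.null(truth))
    truth <- data.frame(frame = integer(), object_id = integer(),
                        row = numeric(), col = numeric(), radius = numeric(),
                        class = character(), depth_um = numeric(),
                        velocity_px = numeric(), occluded = logical())
  seen <- unique(truth$object_id)
  list(frames = frames, truth = truth,
       objects = objects[objects$object_id %in% seen, , drop = FALSE],
       occlusions = NULL, config = config, seed = seed)
}

#' Rendering parameters for the synthetic camera model
#'
#' @param background background gray level (8-bit).
#' @param contrast darkening amplitude of an in-focus particle (gray
#'   levels).
#' @param psf_sigma0 in-focus PSF sigma in px.
#' @param defocus_px_per_um PSF sigma growth per um of defocus.
#' @param noise_sd additive Gaussian sensor noise sigma (gray levels).
#' @param gradient linear illumination gradient amplitude across the frame.
#' @export
render_params <- function(background = 200, contrast = 90, psf_sigma0 = 0.6,
                          defocus_px_per_um = 0.08, noise_sd = 2.5,
                          gradient = 0) {
  as.list(environment())
}

#' Simulate a microchannel recording with full ground truth
#'
#' Particles arrive as a Poisson process at the analytically estimated
#' throughput, with class proportions from the suspension's number
#' concentrations; each particle gets a uniform lateral and depth position
#' (excluded from the walls by its radius) and the constant axial velocity
#' of the Poiseuille-like profile at that position. Frames are rendered
#' with [render_frame()]; the ground truth records every particle's
#' per-frame position and pairwise occlusion intervals (image-plane center
#' distance below the sum of radii).
#'
#' @param config a [flow_config()].
#' @param spec a [suspension_spec()].
#' @param n_frames number of frames to simulate.
#' @param seed RNG seed; identical inputs give bit-identical output.
#' @param render [render_params()].
#' @param rate_per_s optional override of the arrival rate (objects/s).
#' @return list with `frames` (list of 8-bit matrices), `truth` (per-frame
#'   annotations: `frame,object_id,row,col,radius,class,occluded`),
#'   `objects` (per-object entry frame, positions, velocity, class), and
#'   `occlusions` (object-id pairs with frame ranges).
#' @export
simulate_sequence <- function(config = flow_config(),
                              spec = suspension_spec(),
                              n_frames = 100, seed = 1,
                              render = render_params(),
                              rate_per_s = NULL) {
  stopifnot(n_frames >= 1)
  set.seed(seed)
  conc <- number_concentration(spec)
  if (is.null(rate_per_s))
    rate_per_s <- config$flow_rate_ul_per_min / 60 * conc$total
  lambda <- rate_per_s / config$frame_rate_hz  # arrivals per frame
  W_px <- config$roi_px[2]

  objects <- NULL
  n_arrivals <- if (lambda > 0) stats::rpois(1, lambda * n_frames) else 0
  if (n_arrivals > 0) {
    arrival <- sort(stats::runif(n_arrivals, 0, n_frames))
    cls_idx <- sample(seq_along(spec$diameters_um), n_arrivals, replace = TRUE,
                      prob = conc$per_class / conc$total)
    d_um <- spec$diameters_um[cls_idx]
    r_um <- d_um / 2
    lat <- stats::runif(n_arrivals, r_um, config$channel_width_um - r_um)
    dep <- stats::runif(n_arrivals, r_um, config$channel_height_um - r_um)
    v_px <- axial_velocity(lat, dep, config) / config$frame_rate_hz /
      config$um_per_px
    objects <- data.frame(
      object_id = seq_len(n_arrivals), arrival_time = arrival,
      class = paste0(d_um, "um"), radius_px = r_um / config$um_per_px,
      row = lat / config$um_per_px, depth_um = dep, velocity_px = v_px)
  }

  if (is.null(objects))
    objects <- data.frame(object_id = integer(), arrival_time = numeric(),
                          class = character(), radius_px = numeric(),
                          row = numeric(), depth_um = numeric(),
                          velocity_px = numeric())
  out <- sim_from_objects(objects, config, render, n_frames, seed)
  occlusions <- NULL
  if (nrow(out$truth)) {
    otr <- out$truth[out$truth$occluded, ]
    if (nrow(otr)) {
      sp <- split(otr$frame, otr$object_id)
      occlusions <- data.frame(object_id = as.integer(names(sp)),
                               first_frame = vapply(sp, min, 0),
                               last_frame = vapply(sp, max, 0))
    }
  }
  out$occlusions <- occlusions
  out$spec <- spec
  out
}
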