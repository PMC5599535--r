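# shared oracles and fixture builders

# all permutations of a vector (exhaustive assignment oracle)
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  out
}

# brute-force minimum assignment cost on a (possibly rectangular, possibly
# gated) cost matrix; forbidden pairs cost `big`, dummies cost 0
brute_force_assignment <- function(C, big = 1e7) {
  n <- nrow(C); m <- ncol(C)
  nn <- max(n, m)
  Cp <- matrix(0, nn, nn)
  Cp[seq_len(n), seq_len(m)] <- ifelse(is.finite(C), C, big)
  best <- Inf
  for (p in all_perms(seq_len(nn))) {
    s <- sum(Cp[cbind(seq_len(nn), p)])
    if (s < best) best <- s
  }
  best
}

# well-separated random annotations: pairwise distance > 3 * (sigma_i + sigma_j)
random_separated_annotations <- function(k, shape = c(100, 500),
                                         radii_range = c(6, 21)) {
  ann <- NULL
  tries <- 0
  while ((is.null(ann) || nrow(ann) < k) && tries < 2000) {
    tries <- tries + 1
    r <- stats::runif(1, radii_range[1], radii_range[2])
    s <- r / 3
    row <- stats::runif(1, 4 * s, shape[1] - 1 - 4 * s)
    col <- stats::runif(1, 4 * s, shape[2] - 1 - 4 * s)
    if (!is.null(ann)) {
      d <- sqrt((ann$row - row)^2 + (ann$col - col)^2)
      if (any(d <= 3 * (ann$radius / 3 + s) + 2)) next
    }
    ann <- rbind(ann, annotations(row, col, r))
  }
  ann
}

# deterministic detection stream for a set of ideal linear trajectories
ideal_detection_stream <- function(objects, n_frames, width = 500) {
  rows <- NULL
  for (f in seq_len(n_frames) - 1L) {
    col_f <- objects$col0 + f * objects$velocity_px
    vis <- which(col_f >= 0 & col_f <= width - 1 & f >= objects$start_frame)
    if (length(vis))
      rows <- rbind(rows, data.frame(
        frame = f, row = objects$row[vis], col = col_f[vis],
        radius = objects$radius[vis], score = 0.02))
  }
  rows
}
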