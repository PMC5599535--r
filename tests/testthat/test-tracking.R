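mk_track <- function(col_hist, row = 50, config = tracker_config()) {
  st <- new_tracker(config)
  for (i in seq_along(col_hist)) {
    det <- data.frame(row = row, col = col_hist[i], radius = 5)
    st <- tracker_step(st, det, i - 1L)$state
  }
  st$tracks[[1]]
}

test_that("prediction extrapolates the axial velocity and freezes the row", {
  t1 <- mk_track(c(100, 140))
  expect_equal(predict_position(t1), c(50, 180))
  t2 <- mk_track(100)
  expect_equal(predict_position(t2), c(50, 140))  # nominal velocity 40
  t3 <- mk_track(c(100, 160, 220))
  expect_equal(predict_position(t3)[1], 50)
  t3$active <- FALSE
  expect_error(predict_position(t3), "inactive")
})

test_that("cost matrix uses weighted Euclidean distance with gating", {
  cfg <- tracker_config(lateral_weight = 1, gate_px = 60,
                        nominal_velocity_px = 40)
  st <- new_tracker(cfg)
  st <- tracker_step(st, data.frame(row = 50, col = 60, radius = 5), 0)$state
  st <- tracker_step(st, data.frame(row = 50, col = 100, radius = 5), 1)$state
  tr <- st$tracks[[1]]  # established: predicts (50, 140)
  C <- build_cost_matrix(list(tr),
                         data.frame(row = c(50, 53, 50), col = c(140, 144, 300)),
                         cfg)
  expect_equal(C[1, 1], 0)
  expect_equal(C[1, 2], 5)  # 3-4-5 triangle
  expect_true(is.infinite(C[1, 3]))  # beyond the gate
})

test_that("a gated-out pair is never matched even if unique", {
  cfg <- tracker_config(gate_px = 10)
  st <- new_tracker(cfg)
  st <- tracker_step(st, data.frame(row = 50, col = 50, radius = 5), 0)$state
  st <- tracker_step(st, data.frame(row = 50, col = 90, radius = 5), 1)$state
  res <- tracker_step(st, data.frame(row = 10, col = 131, radius = 5), 2)
  # detection is far laterally: old track coasts, new track born
  expect_equal(res$state$next_id, 3L)
})

test_that("one particle traversing gives one track: IN, ASSIGNED..., OUT", {
  cfg <- tracker_config()
  obj <- data.frame(row = 50, col0 = 10, velocity_px = 60, radius = 5,
                    start_frame = 0)
  det <- ideal_detection_stream(obj, 12)
  out <- run_tracker(det, cfg, n_frames = 12)
  expect_equal(out$count, 1L)
  tt <- tracks_table(out)
  expect_equal(tt$state[1], "IN")
  expect_true(all(tt$state[2:(nrow(tt) - 1)] == "ASSIGNED"))
  expect_equal(tt$state[nrow(tt)], "OUT")
  expect_equal(length(out$events), 1L)
  expect_equal(out$events[[1]]$type, "out")
})

test_that("occlusion-free multi-particle streams are counted exactly", {
  set.seed(31)
  for (rep in 1:3) {
    n <- 20
    objs <- data.frame(row = seq(10, 90, length.out = n),
                       col0 = runif(n, -300, 0),
                       velocity_px = runif(n, 35, 85),
                       radius = sample(c(3.5, 5, 7.5), n, TRUE),
                       start_frame = 0)
    n_frames <- 25
    det <- ideal_detection_stream(objs, n_frames)
    out <- run_tracker(det, tracker_config(), n_frames = n_frames)
    n_seen <- length(unique(paste(round(objs$row, 3))[
      objs$col0 + (n_frames - 1) * objs$velocity_px >= 0]))
    expect_equal(out$count, n_seen)
  }
})

test_that("track ids increase monotonically and are never reused", {
  set.seed(8)
  objs <- data.frame(row = c(20, 40, 60, 80), col0 = c(0, -80, -160, -240),
                     velocity_px = 50, radius = 5, start_frame = 0)
  det <- ideal_detection_stream(objs, 20)
  out <- run_tracker(det, tracker_config(), n_frames = 20)
  tt <- tracks_table(out)
  first_frames <- tapply(tt$frame, tt$track_id, min)
  expect_true(all(diff(first_frames[order(as.integer(names(first_frames)))]) >= 0))
  expect_equal(out$count, 4L)
})

test_that("frame indices must increase strictly", {
  st <- new_tracker(tracker_config())
  st <- tracker_step(st, data.frame(row = 50, col = 10, radius = 5), 0)$state
  expect_error(tracker_step(st, data.frame(row = 50, col = 50, radius = 5), 0),
               "increasing")
})

test_that("a depth-separated overlap is resolved into two identities", {
  # both particles share a lateral line; the deeper one is faster and
  # briefly occludes the slower one mid-channel
  sim <- simulate_occlusion_pair(seed = 4)
  seg <- oracle_segmenter(sim$truth, dim(sim$frames[[1]]))
  det <- NULL
  for (f in sort(unique(sim$truth$frame)))
    det <- rbind(det, flatten(seg(NULL, f), frame_index = f))
  out <- run_tracker(det, tracker_config(), n_frames = length(sim$frames))
  expect_equal(out$count, 2L)
  rep <- tracking_report(out, sim$truth)
  expect_equal(rep$count_error, 0)
  expect_equal(rep$duplicate_rate, 0)
})

test_that("stale occlusions are forced out", {
  cfg <- tracker_config(max_occlusion_frames = 3)
  det <- data.frame(frame = 0, row = 50, col = 50, radius = 5, score = 1)
  out <- run_tracker(det, cfg, n_frames = 10)
  tt <- tracks_table(out)
  expect_equal(sum(tt$state == "OCCLUSION"), 4)  # 3 allowed + the stale one
  expect_equal(tt$state[nrow(tt)], "OUT")
  expect_equal(out$events[[1]]$type, "stale_out")
})
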