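box <- function(cmin, rmin, cmax, rmax)
  data.frame(col_min = cmin, row_min = rmin, col_max = cmax, row_max = rmax)

test_that("iou covers the standard cases", {
  expect_equal(iou(box(0, 0, 2, 2), box(0, 0, 2, 2)), 1)
  expect_equal(iou(box(0, 0, 1, 1), box(5, 5, 6, 6)), 0)
  expect_equal(iou(box(0, 0, 1, 1), box(0.5, 0, 1.5, 1)), 1 / 3)
  expect_error(iou(box(0, 0, 0, 1), box(0, 0, 1, 1)), "degenerate")
})

mk_det <- function(frame, row, col, radius, score, class)
  data.frame(frame = frame, row = row, col = col, radius = radius,
             score = score, class = class, stringsAsFactors = FALSE)

test_that("average precision on perfect and empty detections", {
  gt <- data.frame(frame = c(0, 0, 1), row = c(20, 60, 40),
                   col = c(100, 300, 200), radius = c(5, 7.5, 5),
                   class = c("a", "b", "a"))
  perfect <- mk_det(gt$frame, gt$row, gt$col, gt$radius, 1, gt$class)
  ap <- average_precision(perfect, gt)
  expect_equal(unname(ap$per_class), c(1, 1))
  expect_equal(ap$mAP, 1)
  none <- average_precision(perfect[0, ], gt)
  expect_equal(none$mAP, 0)
})

test_that("score order decides the PR curve (hand-walked two-detection case)", {
  gt <- data.frame(frame = 0, row = 50, col = 100, radius = 5, class = "a")
  # matching detection outranks the spurious one -> AP 1
  d1 <- mk_det(c(0, 0), c(50, 20), c(100, 400), c(5, 5), c(0.9, 0.1), "a")
  expect_equal(average_precision(d1, gt)$mAP, 1)
  # scores swapped -> the false positive eats the first precision point
  d2 <- mk_det(c(0, 0), c(50, 20), c(100, 400), c(5, 5), c(0.1, 0.9), "a")
  expect_equal(average_precision(d2, gt)$mAP, 0.5)
})

test_that("each ground-truth object is matched at most once", {
  gt <- data.frame(frame = 0, row = 50, col = 100, radius = 5, class = "a")
  d <- mk_det(c(0, 0), c(50, 50), c(100, 101), c(5, 5), c(0.9, 0.8), "a")
  ap <- average_precision(d, gt)
  expect_equal(sum(ap$matches$tp), 1)
})

test_that("counting report reproduces the reference arithmetic", {
  r <- counting_report(2346, 2343)
  expect_equal(r$difference, 3)
  expect_equal(r$relative_error_percent, 0.128, tolerance = 0.002)
  expect_equal(unlist(counting_report(10, 10)), c(0, 0),
               ignore_attr = TRUE)
  r0 <- counting_report(0, 50)
  expect_equal(r0$relative_error_percent, 100)
  expect_error(counting_report(5, 0), "positive")
})

test_that("localization error measures matched center distances", {
  gt <- data.frame(frame = 0, row = c(20, 60), col = c(100, 300),
                   radius = c(5, 5))
  d <- data.frame(frame = 0, row = c(20, 61), col = c(100, 300),
                  radius = c(5, 5), score = c(1, 1))
  le <- localization_error(d, gt)
  expect_equal(le$n_matched, 2)
  expect_equal(le$mean_px, 0.5)
  expect_equal(le$max_px, 1)
  perfect <- localization_error(d[1, ], gt[1, ])
  expect_equal(perfect$mean_px, 0)
})

test_that("flattening on oracle maps localizes to within a pixel", {
  set.seed(13)
  ann <- random_separated_annotations(8, radii_range = c(6, 15))
  gt <- data.frame(frame = 0, row = ann$row, col = ann$col,
                   radius = ann$radius)
  det <- flatten(build_density_map(ann, c(100, 500)), frame_index = 0)
  le <- localization_error(det, gt)
  expect_equal(le$n_matched, 8)
  expect_lte(le$mean_px, 1)
})

test_that("tracking report is clean on an ideal run and empty input", {
  objs <- data.frame(row = c(20, 50, 80), col0 = c(0, -100, -200),
                     velocity_px = 50, radius = 5, start_frame = 0)
  det <- ideal_detection_stream(objs, 18)
  out <- run_tracker(det, tracker_config(), n_frames = 18)
  truth <- data.frame(frame = det$frame, object_id = match(det$row, objs$row),
                      row = det$row, col = det$col, occluded = FALSE)
  rep <- tracking_report(out, truth)
  expect_equal(rep$count_error, 0)
  expect_equal(rep$duplicate_rate, 0)
  expect_equal(rep$id_switches, 0)
  empty <- tracking_report(out, truth[0, ])
  expect_equal(empty$true_count, 0)
})

test_that("radius binning maps to the nearest class", {
  cr <- c("7um" = 3.5, "10um" = 5, "15um" = 7.5)
  expect_equal(bin_radius_class(c(3.4, 4.4, 6.4, 9), cr),
               c("7um", "10um", "15um", "15um"))
})
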