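disk_crop <- function(r, bg = 200, depth = 90, n = 21, offset = c(0, 0)) {
  c0 <- (n - 1) / 2
  d <- sqrt(outer((0:(n - 1) - c0 - offset[1])^2,
                  (0:(n - 1) - c0 - offset[2])^2, `+`))
  bg - depth * pmin(pmax(r - d + 0.5, 0), 1)
}

test_that("features of a uniform patch are flat", {
  f <- extract_features(matrix(120, 21, 21))
  expect_equal(unname(f["eq_radius"]), 0)
  expect_true(all(abs(f[grep("ring", names(f))]) < 1e-9))
})

test_that("equivalent radius grows with disk size", {
  f7 <- extract_features(disk_crop(3.5))
  f15 <- extract_features(disk_crop(7.5))
  expect_gt(f15["eq_radius"], f7["eq_radius"])
  expect_gt(f15["ring4"], f7["ring4"])
})

test_that("features are invariant to an additive intensity offset", {
  cr <- disk_crop(5)
  expect_equal(extract_features(cr), extract_features(cr + 17))
})

test_that("wrong crop sizes are rejected", {
  expect_error(extract_features(matrix(0, 20, 20)), "odd")
  expect_error(extract_features(matrix(0, 21, 19)), "square")
})

test_that("the baseline classifier separates bead sizes", {
  set <- simulate_crop_dataset(n_per_class = 60, seed = 5)
  idx <- seq_along(set$labels)
  test_i <- unlist(lapply(split(idx, set$labels), function(v) v[1:15]))
  train_i <- setdiff(idx, test_i)
  model <- train_classifier(set$crops[train_i], set$labels[train_i], seed = 1)
  pred <- vapply(test_i, function(i)
    predict_cell(model, set$crops[[i]])$label, "")
  expect_gt(mean(pred == set$labels[test_i]), 0.9)
  # probabilities are a distribution
  pr <- predict_cell(model, set$crops[[1]])$prob
  expect_equal(sum(pr), 1, tolerance = 1e-6)
  expect_true(all(pr >= 0))
})

test_that("training is reproducible and rejects degenerate inputs", {
  set <- simulate_crop_dataset(n_per_class = 15, seed = 2)
  m1 <- train_classifier(set$crops, set$labels, seed = 3)
  m2 <- train_classifier(set$crops, set$labels, seed = 3)
  expect_equal(coef(m1$fit), coef(m2$fit))
  expect_error(train_classifier(set$crops, rep("a", length(set$crops))),
               "2 classes")
  expect_error(train_classifier(set$crops[1:12], c(rep("a", 6), rep("b", 6))),
               "10 crops")
})

test_that("permuted labels give chance-level accuracy", {
  set <- simulate_crop_dataset(n_per_class = 40, seed = 9)
  set.seed(4)
  perm <- sample(set$labels)
  idx <- seq_along(perm)
  test_i <- unlist(lapply(split(idx, perm), function(v) v[1:10]))
  train_i <- setdiff(idx, test_i)
  model <- train_classifier(set$crops[train_i], perm[train_i], seed = 1)
  pred <- vapply(test_i, function(i)
    predict_cell(model, set$crops[[i]])$label, "")
  expect_lt(mean(pred == perm[test_i]), 0.65)  # ~1/3 expected
})

test_that("small translations do not change the predicted class", {
  set <- simulate_crop_dataset(n_per_class = 60, seed = 6)
  model <- train_classifier(set$crops, set$labels, seed = 1)
  cfg <- flow_config(); cfg$roi_px <- c(31, 31)
  mk <- function(dr, dc) {
    set.seed(9)
    fr <- render_frame(data.frame(row = 15 + dr, col = 15 + dc,
                                  radius_px = 7.5, depth_um = 25,
                                  velocity_px = 40), cfg)
    crop_cell(fr, c(15, 15))$pixels
  }
  p0 <- predict_cell(model, mk(0, 0))$label
  p2 <- predict_cell(model, mk(2, 1))$label
  expect_equal(p0, "15um")
  expect_equal(p0, p2)
})

test_that("classifier round trips through serialization", {
  set <- simulate_crop_dataset(n_per_class = 12, seed = 11)
  model <- train_classifier(set$crops, set$labels, seed = 1)
  f <- tempfile(fileext = ".rds")
  save_classifier(model, f)
  m2 <- load_classifier(f)
  expect_equal(predict_cell(model, set$crops[[1]]),
               predict_cell(m2, set$crops[[1]]))
  unlink(f)
})

test_that("embedding separates classes and handles degenerate input", {
  set <- simulate_crop_dataset(n_per_class = 30, seed = 8)
  Y <- embed_scatter(set$crops)
  expect_equal(dim(Y), c(length(set$crops), 2))
  # silhouette-style check: mean within-class distance < between-class
  lab <- set$labels
  d <- as.matrix(dist(Y))
  sil <- vapply(seq_along(lab), function(i) {
    a <- mean(d[i, lab == lab[i]][-1])
    b <- min(vapply(setdiff(unique(lab), lab[i]), function(cl)
      mean(d[i, lab == cl]), 0))
    (b - a) / max(a, b)
  }, 0)
  expect_gt(mean(sil), 0)
  # single class, constant crops: no error
  Y2 <- embed_scatter(replicate(5, matrix(100, 21, 21), simplify = FALSE))
  expect_equal(dim(Y2), c(5, 2))
  # reproducible
  expect_equal(Y, embed_scatter(set$crops))
})
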