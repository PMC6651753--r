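test_that("the central-window label rule matches the patch convention", {
  m <- matrix(0L, 96, 96)
  expect_identical(label_from_annotation(m), 0L)
  # 0-based pixel (32, 32) -> 1-based [33, 33]: inside the window
  m[33, 33] <- 1L
  expect_identical(label_from_annotation(m), 1L)
  # 0-based (31, 31) is just outside; tumor there does not set the label
  m2 <- matrix(0L, 96, 96); m2[32, 32] <- 1L
  expect_identical(label_from_annotation(m2), 0L)
  # corners of the window, 0-based rows/cols in [32, 64)
  m3 <- matrix(0L, 96, 96); m3[64, 64] <- 1L
  expect_identical(label_from_annotation(m3), 1L)
  m4 <- matrix(0L, 96, 96); m4[65, 65] <- 1L
  expect_identical(label_from_annotation(m4), 0L)
  expect_error(label_from_annotation(matrix(0L, 20, 20)), "32")
})

test_that("generated patches are deterministic and label-consistent", {
  a <- generate_patch(1, synth_params(seed = 5))
  b <- generate_patch(1, synth_params(seed = 5))
  expect_identical(a$image, b$image)
  expect_identical(a$annotation, b$annotation)
  c <- generate_patch(1, synth_params(seed = 6))
  expect_false(identical(a$image, c$image))

  # class 0: no annotation at all; class 1: annotation touches the window
  for (seed in 0:99) {
    p0 <- generate_patch(0, synth_params(seed = seed))
    expect_true(all(p0$annotation == 0L))
    p1 <- generate_patch(1, synth_params(seed = seed))
    expect_identical(label_from_annotation(p1$annotation), 1L)
    win <- p1$annotation[33:64, 33:64]
    expect_gt(sum(win), 0)
  }
})

test_that("patch geometry and palette invariants hold", {
  p <- generate_patch(1, synth_params(seed = 2))
  expect_identical(dim(p$image), c(96L, 96L, 3L))
  expect_identical(dim(p$annotation), c(96L, 96L))
  expect_true(min(p$image) >= 0 && max(p$image) <= 255)
  expect_error(synth_params(tumor_radius_range = c(2, 3)), "strictly larger")
  expect_error(synth_params(tumor_radius_range = c(50, 60)), "too large")
})

test_that("the linear mock follows its closed form on the mask cube", {
  img <- gradient_image(12, 12)
  sm <- squaregrid_segments(12, 12, 9)
  cf <- seq(0.01, 0.09, by = 0.01)
  clf <- linear_mock_classifier(img, sm, cf, intercept = 0.05)

  p_full <- clf$predict(list(img))
  expect_equal(p_full[1, 2], 0.05 + sum(cf), tolerance = 1e-12)
  black <- apply_mask(img, sm, rep(0, 9))
  p_black <- clf$predict(list(black))
  expect_equal(p_black[1, 2], 0.05, tolerance = 1e-12)

  expect_error(linear_mock_classifier(img, sm, cf[1:3], 0.05), "length")
  expect_error(linear_mock_classifier(img, sm, rep(0.2, 9), 0.5), "\\[0, 1\\]")
})

test_that("the tumor detector sees only visible annotated central pixels", {
  p <- generate_patch(1, synth_params(seed = 4))
  clf <- tumor_detector_classifier(p$annotation, steepness = 8)

  black <- array(0L, dim = dim(p$image))
  expect_equal(clf$predict(list(black))[1, 1], plogis(-4), tolerance = 1e-12)

  # closed form on the unperturbed patch
  central <- p$annotation[33:64, 33:64]
  expect_equal(clf$predict(list(p$image))[1, 1],
               plogis(8 * (sum(central) / 1024 - 0.5)), tolerance = 1e-12)

  # hiding a segment disjoint from the annotation leaves p1 unchanged
  sm <- squaregrid_segments(96, 96, 36)
  overlap <- vapply(0:35, function(j) {
    sum(p$annotation[sm$labels == j]) }, integer(1))
  j_off <- which(overlap == 0)[1] - 1L
  hidden <- apply_mask(p$image, sm, replace(rep(1, 36), j_off + 1L, 0))
  expect_equal(clf$predict(list(hidden))[1, 1], clf$predict(list(p$image))[1, 1],
               tolerance = 1e-12)
  expect_error(tumor_detector_classifier(p$annotation, steepness = 0),
               "steepness")
})

test_that("explanations localize on the annotation for the tumor detector", {
  hits <- 0L
  trials <- 12L
  for (seed in seq_len(trials)) {
    p <- generate_patch(1, synth_params(seed = seed))
    clf <- tumor_detector_classifier(p$annotation)
    ex <- explain(p$image, clf, segmenter_params("squaregrid", n_squares = 36),
                  class_index = 1, n_samples = 400, seed = seed)
    top <- which.max(ex$weights) - 1L
    if (sum(p$annotation[ex$segments$labels == top]) > 0) hits <- hits + 1L
  }
  expect_identical(hits, trials)
})

test_that("unannotated segments never dominate the annotated maximum", {
  p <- generate_patch(1, synth_params(seed = 8))
  clf <- tumor_detector_classifier(p$annotation)
  ex <- explain(p$image, clf, segmenter_params("squaregrid", n_squares = 36),
                class_index = 1, n_samples = 2000, seed = 3)
  overlap <- vapply(0:35, function(j) {
    sum(p$annotation[ex$segments$labels == j]) }, integer(1))
  max_annotated <- max(ex$weights[overlap > 0])
  expect_true(all(abs(ex$weights[overlap == 0]) < max_annotated))
})

test_that("the smooth mock deviates from linearity by at most its amplitude", {
  setup <- stability_setup()
  masks <- sample_masks(36, 200, seed = 1)
  probs <- predict_perturbations(setup$image, setup$segments, masks,
                                 setup$classifier)
  s <- setup$intercept + as.vector(masks %*% setup$coefficients)
  expect_equal(probs[, 2], s + 0.01 * sin(2 * pi * s), tolerance = 1e-12)
  expect_true(all(abs(probs[, 2] - s) <= 0.01 + 1e-12))
})
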