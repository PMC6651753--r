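test_that("a constant classifier explains to an identically zero heat map", {
  img <- gradient_image(12, 12)
  ex <- explain(img, constant_classifier(), segmenter_params("squaregrid",
                n_squares = 9), n_samples = 60, seed = 1)
  expect_equal(ex$weights, rep(0, 9), tolerance = 1e-12)
  expect_equal(max(abs(ex$heatmap$values)), 0, tolerance = 1e-12)
})

test_that("explanations recover a linear mock's coefficients and localize them", {
  img <- gradient_image(12, 12)
  sm <- squaregrid_segments(12, 12, 9)
  cf <- rep(0, 9); cf[4] <- 0.7       # segment 3 carries all the signal
  clf <- linear_mock_classifier(img, sm, cf, intercept = 0.1)
  ex <- explain(img, clf, segmenter_params("squaregrid", n_squares = 9),
                class_index = 1, n_samples = 200, seed = 2)
  expect_equal(ex$weights, cf, tolerance = 1e-9)
  expect_equal(ex$intercept, 0.1, tolerance = 1e-9)
  on_segment <- sm$labels == 3L
  expect_equal(unique(ex$heatmap$values[on_segment]), 0.7, tolerance = 1e-9)
  expect_equal(max(abs(ex$heatmap$values[!on_segment])), 0, tolerance = 1e-9)
})

test_that("explain is bit-exact under a fixed seed and varies across seeds", {
  setup <- stability_setup()
  p <- segmenter_params("squaregrid", n_squares = 36)
  a <- explain(setup$image, setup$classifier, p, class_index = 1,
               n_samples = 300, seed = 11)
  b <- explain(setup$image, setup$classifier, p, class_index = 1,
               n_samples = 300, seed = 11)
  expect_identical(a$weights, b$weights)
  expect_identical(a$heatmap$values, b$heatmap$values)
  c <- explain(setup$image, setup$classifier, p, class_index = 1,
               n_samples = 300, seed = 12)
  expect_false(identical(a$weights, c$weights))
})

test_that("the default explained class is the classifier's argmax prediction", {
  img <- gradient_image(12, 12)
  ex <- explain(img, constant_classifier(c(0.3, 0.7)),
                segmenter_params("squaregrid", n_squares = 4),
                n_samples = 30, seed = 1)
  expect_identical(ex$class_index, 1L)
})

test_that("heat-map mass equals the weight-times-size sum over segments", {
  setup <- stability_setup()
  ex <- explain(setup$image, setup$classifier,
                segmenter_params("squaregrid", n_squares = 36),
                class_index = 1, n_samples = 300, seed = 5)
  mass <- sum(ex$heatmap$values)
  by_segment <- sum(ex$weights * segment_sizes(ex$segments))
  expect_equal(mass, by_segment, tolerance = 1e-9)
})

test_that("the squaregrid final map is exactly the sum of its level maps", {
  setup <- stability_setup()
  sq <- squaregrid_explain(setup$image, setup$classifier, class_index = 1,
                           n_samples = 700, seed = 3)
  expect_identical(sq$levels, c(9L, 16L, 36L, 64L, 144L, 256L, 576L))
  ks <- vapply(sq$level_explanations, function(e) e$segments$k, integer(1))
  expect_identical(ks, sq$levels)
  resum <- Reduce(`+`, lapply(sq$level_explanations,
                              function(e) e$heatmap$values))
  expect_identical(sq$heatmap$values, resum)
  expect_identical(sq$heatmap$provenance, "squaregrid-sum")

  # per-level runs are reproducible independently: level i uses seed + i - 1
  lvl3 <- explain(setup$image, setup$classifier,
                  segmenter_params("squaregrid", n_squares = 36),
                  class_index = 1, n_samples = 700, seed = 5)
  expect_identical(sq$level_explanations[[3]]$weights, lvl3$weights)
})

test_that("a constant classifier yields a zero squaregrid map at every level", {
  img <- gradient_image(24, 24)
  sq <- squaregrid_explain(img, constant_classifier(), class_index = 1,
                           levels = c(9, 16), n_samples = 40, seed = 1)
  expect_equal(max(abs(sq$heatmap$values)), 0, tolerance = 1e-12)
})

test_that("averaging heat maps is the elementwise arithmetic mean", {
  m1 <- heat_map(matrix(1:12 / 10, 3, 4), "a")
  expect_equal(average_heatmaps(list(m1, m1, m1))$values, m1$values)
  m2 <- heat_map(-m1$values, "b")
  expect_equal(average_heatmaps(list(m1, m2))$values, matrix(0, 3, 4))

  maps <- lapply(1:3, function(s) gridlime:::with_seed(s,
    heat_map(matrix(stats::rnorm(12), 3, 4), "r")))
  avg <- average_heatmaps(maps)
  # brute-force pixel loop oracle
  for (r in 1:3) for (c in 1:4) {
    expect_equal(avg$values[r, c],
                 mean(c(maps[[1]]$values[r, c], maps[[2]]$values[r, c],
                        maps[[3]]$values[r, c])))
  }
  expect_identical(avg$provenance, "avg")
  expect_error(average_heatmaps(list()), "non-empty")
  expect_error(average_heatmaps(list(m1, heat_map(matrix(0, 2, 2)))),
               "dimensions")
})

test_that("stability is zero under identical seeds and shrinks with sample size", {
  setup <- stability_setup()
  p <- segmenter_params("squaregrid", n_squares = 36)
  runs <- lapply(1:3, function(i) {
    explain(setup$image, setup$classifier, p, class_index = 1,
            n_samples = 250, seed = 7)$weights
  })
  expect_identical(runs[[1]], runs[[2]])
  expect_identical(runs[[1]], runs[[3]])

  small <- stability_check(setup$image, setup$classifier, p, class_index = 1,
                           n_samples = 120, repeats = 3, base_seed = 0)
  large <- stability_check(setup$image, setup$classifier, p, class_index = 1,
                           n_samples = 2000, repeats = 3, base_seed = 0)
  expect_gt(small, large)
  expect_error(stability_check(setup$image, setup$classifier, p,
                               repeats = 1), "repeats")
})

test_that("fitted model methods expose the surrogate coherently", {
  setup <- stability_setup()
  ex <- explain(setup$image, setup$classifier,
                segmenter_params("squaregrid", n_squares = 36),
                class_index = 1, n_samples = 300, seed = 9)
  cf <- coef(ex)
  expect_length(cf, 37)
  expect_identical(names(cf)[1], "(intercept)")
  expect_equal(unname(cf[-1]), ex$weights)

  pred <- predict(ex, rep(1, 36))
  expect_equal(pred, ex$intercept + sum(ex$weights))
  expect_equal(fitted(ex), predict(ex, ex$masks))
  res <- residuals(ex)
  expect_equal(res, ex$probabilities[, 2] - fitted(ex))
  expect_lt(sd(res), 0.011)           # residual scale set by the mock's nonlinearity

  out <- capture.output(print(ex))
  expect_true(any(grepl("fit score", out)))
  s <- summary(ex)
  expect_s3_class(s, "summary.lime_explanation")
  expect_identical(nrow(s$weight_table), 36L)
})
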