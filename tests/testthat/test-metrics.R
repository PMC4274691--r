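test_that("region matching enforces a one-to-one mapping", {
  gt <- four_fibre_gt()

  # identical masks: every fibre matched
  m <- match_regions(gt, gt)
  expect_identical(nrow(m$pairs), 4L)
  expect_length(m$unmatched_gt, 0)
  expect_length(m$unmatched_pred, 0)

  # two fragments inside one gt fibre: larger intersection wins the pair
  split <- four_fibre_split_pred()
  ms <- match_regions(split, gt)
  expect_identical(nrow(ms$pairs), 4L)
  expect_length(ms$unmatched_pred, 1)
  won <- ms$pairs[ms$pairs$gt == 1L, ]
  expect_identical(won$pred, 5L)   # the larger (right) fragment

  # a region straddling two fibres at < 50% each matches neither
  straddle <- matrix(0L, 40, 40)
  straddle[3:18, 11:30] <- 1L      # 40% in fibre 1, 40% in fibre 2
  mm <- match_regions(label_mask(straddle), gt)
  expect_identical(nrow(mm$pairs), 0L)
  expect_identical(mm$unmatched_pred, 1L)

  expect_error(match_regions(label_mask(matrix(0L, 5, 5)), gt), "shape")
})

test_that("accuracy counts TP / (TP + FP + FN) and is label-permutation invariant", {
  gt <- four_fibre_gt()
  expect_identical(fibre_accuracy(match_regions(gt, gt)), 1)

  # TP = 3, FN = 1, FP = 0
  pred3 <- unclass(gt); attributes(pred3) <- list(dim = dim(gt))
  pred3[pred3 == 4L] <- 0L
  expect_identical(fibre_accuracy(match_regions(label_mask(pred3), gt)), 0.75)

  # TP = 3, FN = 1, FP = 2 (two background blobs large enough to be regions)
  pred5 <- pred3
  pred5[19:22, 2:6] <- 5L
  pred5[19:22, 30:34] <- 6L
  pred5 <- label_mask(label_renumber_for_tests(pred5))
  expect_identical(fibre_accuracy(match_regions(pred5, gt)), 0.5)

  # permuting labels changes nothing
  perm <- unclass(gt); attributes(perm) <- list(dim = dim(gt))
  perm[] <- c(0L, 4L, 3L, 1L, 2L)[perm + 1L]
  expect_identical(fibre_accuracy(match_regions(label_mask(perm), gt)), 1)

  expect_error(fibre_accuracy(match_regions(label_mask(matrix(0L, 40, 40)),
                                            label_mask(matrix(0L, 40, 40)))),
               "undefined")
})

test_that("fragmentation is p/n over gt fibres with multiple pred components", {
  gt <- four_fibre_gt()
  full <- binary_mask(unclass(gt) > 0L, "fibre")
  expect_identical(fragmentation(full, gt), 0)

  split <- four_fibre_split_pred()
  expect_identical(fragmentation(binary_mask(unclass(split) > 0L, "fibre"), gt),
                   0.25)

  # every fibre split in two -> 1.0
  allsplit <- unclass(gt) > 0L
  allsplit[, c(10, 30)] <- FALSE
  expect_identical(fragmentation(binary_mask(allsplit, "fibre"), gt), 1)

  # sliver guard: a 2-px crumb does not count as a fragment
  crumb <- matrix(FALSE, 40, 40)
  crumb[3:18, 3:16] <- TRUE      # bulk of fibre 1
  crumb[4, 18] <- TRUE           # 1-px crumb, separated by a gap
  expect_identical(fragmentation(binary_mask(crumb, "fibre"),
                                 label_mask((unclass(gt) == 1L) * 1L)), 0)

  expect_error(fragmentation(full, label_mask(matrix(0L, 40, 40))), "no fibres")
})

test_that("congealment is q/n over gt fibres merged inside one pred region", {
  gt <- four_fibre_gt()
  expect_identical(congealment(gt, gt), 0)

  merge <- four_fibre_merge_pred()
  expect_identical(congealment(merge, gt), 0.5)

  # one region covering everything congeals all fibres
  one <- label_mask(matrix(1L, 40, 40))
  expect_identical(congealment(one, gt), 1)
})

test_that("misclassification percentage is the XOR pixel rate", {
  a <- binary_mask(matrix(TRUE, 20, 20), "fibre")
  expect_identical(misclassification_percentage(a, a), 0)
  b <- binary_mask(matrix(FALSE, 20, 20), "fibre")
  expect_identical(misclassification_percentage(a, b), 100)
  half <- binary_mask(cbind(matrix(TRUE, 20, 10), matrix(FALSE, 20, 10)), "fibre")
  expect_identical(misclassification_percentage(half, b), 50)
  expect_error(misclassification_percentage(a, binary_mask(matrix(TRUE, 5, 5),
                                                           "fibre")), "shape")
})

test_that("the smoothed misclassification CDF behaves like a distribution", {
  # single value: midpoint of the rise sits at that value
  cdf1 <- cdf_estimate(30)
  mid <- cdf1$grid[which.min(abs(cdf1$values - 0.5))]
  expect_lt(abs(mid - 30), 0.5)
  expect_true(all(diff(cdf1$values) >= -1e-12))
  expect_gte(cdf1$values[1], 0)
  expect_lte(cdf1$values[length(cdf1$values)], 1 + 1e-9)
  expect_equal(cdf1$values[length(cdf1$values)], 1, tolerance = 1e-3)

  # stochastically smaller set dominates pointwise
  withr::with_seed(31, S <- runif(40, 10, 60))
  a <- cdf_estimate(S)
  b <- cdf_estimate(S + 10)
  expect_true(all(a$values >= b$values - 1e-9))

  # with a tiny bandwidth the smoothed CDF approaches the empirical CDF
  Sint <- c(10, 20, 20, 40, 70)
  small <- cdf_estimate(Sint, grid_points = 2048, bandwidth = 0.01)
  emp <- stats::ecdf(Sint)
  probe <- c(15, 30, 55, 90)
  expect_equal(small$values[vapply(probe, function(p)
    which.min(abs(small$grid - p)), 1L)], emp(probe), tolerance = 0.01)

  expect_error(cdf_estimate(numeric(0)), "at least one")
})

test_that("minor-axis diameters match analytic discs and ellipses", {
  scale <- 0.899
  for (r in c(10, 20, 35, 60)) {
    H <- 4 * r + 9
    m <- disc_mask(H, H, list(c(2 * r + 5, 2 * r + 5)), r)
    d <- fibre_diameters(label_mask(m * 1L, px_scale_um = scale))
    expect_equal(d, 2 * r * scale, tolerance = 0.03)
  }
  # axis-aligned ellipse, semi-axes 40 x 15 px
  e <- ellipse_mask(120, 160, c(60, 80), a = 40, b = 15)
  d <- fibre_diameters(label_mask(e * 1L, px_scale_um = 1))
  expect_equal(d, 30, tolerance = 0.03)
  # rotation invariance
  e30 <- ellipse_mask(160, 160, c(80, 80), a = 40, b = 15, theta = pi / 6)
  d30 <- fibre_diameters(label_mask(e30 * 1L, px_scale_um = 1))
  expect_equal(d30, d, tolerance = 0.03)

  expect_error(fibre_diameters(label_mask(matrix(0L, 10, 10))), "no fibres")
})

test_that("the variability coefficient uses the sample sd and is scale-free", {
  expect_identical(variability_coefficient(c(50, 50, 50)), 0)
  expect_equal(variability_coefficient(c(40, 60)), 1000 * sqrt(200) / 50,
               tolerance = 1e-12)
  expect_equal(variability_coefficient(c(40, 60)), 282.8427, tolerance = 1e-4)
  expect_identical(variability_coefficient(c(40, 60)),
                   variability_coefficient(c(80, 120)))
  expect_error(variability_coefficient(55), "at least two")
  expect_error(variability_coefficient(c(0, 0)), "positive")
})

test_that("evaluate_segmentation aggregates the hand fixtures correctly", {
  gt <- four_fibre_gt()
  perfect <- evaluate_segmentation(gt, gt)
  expect_identical(perfect$accuracy, 1)
  expect_identical(perfect$fragmentation, 0)
  expect_identical(perfect$congealment, 0)
  expect_identical(perfect$misclassification_pct, 0)

  # one split: F = 0.25; one merge: C = 0.5
  expect_identical(evaluate_segmentation(four_fibre_split_pred(), gt)$fragmentation,
                   0.25)
  expect_identical(evaluate_segmentation(four_fibre_merge_pred(), gt)$congealment,
                   0.5)

  td <- tidy(perfect)
  expect_s3_class(td, "tbl_df")
  expect_identical(td$value[td$metric == "accuracy"], 1)
  gl <- glance(perfect)
  expect_identical(gl$tp, 4L)
})

test_that("metrics reports round-trip through JSON", {
  gt <- four_fibre_gt()
  rep1 <- evaluate_segmentation(four_fibre_split_pred(), gt)
  path <- withr::local_tempfile(fileext = ".json")
  write_metrics_json(rep1, path)
  back <- read_metrics_json(path)
  expect_s3_class(back, "metrics_report")
  for (f in c("accuracy", "fragmentation", "congealment",
              "misclassification_pct", "mean_diameter_um", "vc"))
    expect_equal(back[[f]], rep1[[f]], tolerance = 1e-12)
  expect_equal(back$diameters_um, rep1$diameters_um, tolerance = 1e-12)

  batch <- evaluate_batch(list(gt, four_fibre_split_pred()), list(gt, gt))
  path2 <- withr::local_tempfile(fileext = ".json")
  write_metrics_json(batch, path2)
  back2 <- read_metrics_json(path2)
  expect_equal(back2$pooled$accuracy, batch$pooled$accuracy, tolerance = 1e-12)
  expect_equal(back2$S, batch$S, tolerance = 1e-12)
})

test_that("batch evaluation pools counts and reports both VC conventions", {
  gt <- four_fibre_gt()
  batch <- evaluate_batch(list(a = gt, b = four_fibre_split_pred()),
                          list(a = gt, b = gt))
  # pooled accuracy = (4 + 4) / (4 + 4 + 1 unmatched fragment)
  expect_equal(batch$pooled$accuracy, 8 / 9, tolerance = 1e-12)
  expect_equal(batch$pooled$fragmentation, 1 / 8, tolerance = 1e-12)
  expect_identical(length(batch$S), 2L)
  expect_s3_class(batch$cdf, "cdf_estimate")
  expect_identical(nrow(tidy(batch)), 2L)
  expect_true(all(c("vc_pooled", "vc_per_image_mean") %in%
                  names(glance(batch))))
})
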