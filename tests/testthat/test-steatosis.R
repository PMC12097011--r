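test_that("feature extraction obeys its contract", {
  d <- c(20, 20, 20)
  const <- voxel_grid(array(0.5, d))
  fs <- extract_features(const, c(2, 4))
  expect_equal(ncol(fs$features), 5L)               # 2 scales x 2 + range
  expect_equal(nrow(fs$features), prod(d))
  expect_true(all(abs(fs$features[, "localsd_2"]) < 1e-8))
  expect_true(all(abs(fs$features[, "range_1vox"]) < 1e-8))

  # checkerboard has higher local sd than a flat region
  chk <- array(0.2, d)
  idx <- arrayInd(seq_len(prod(d)), d)
  chk[(rowSums(idx) %% 2) == 0] <- 0.8
  mixed <- array(0.2, d); mixed[1:10, , ] <- chk[1:10, , ]
  fm <- extract_features(voxel_grid(mixed), 2)
  sd_feat <- array(fm$features[, "localsd_2"], d)
  expect_gt(mean(sd_feat[3:8, , ]), 10 * mean(sd_feat[13:18, , ]))

  expect_error(extract_features(const, numeric(0)), "nonempty")
  expect_error(extract_features(voxel_grid(array(0.5, d), c(2, 2, 2)), 1),
               "voxel spacing")
})

test_that("training on a linearly separable phantom reaches >= 99% accuracy", {
  d <- c(40, 40, 40)
  set.seed(6)
  img <- array(0.3, d)
  img[21:40, , ] <- 0.7
  img <- img + array(stats::rnorm(prod(d), 0, 0.02), d)
  g <- voxel_grid(img)
  lab <- array(0L, d)
  lab[1:18, , ] <- 2L      # background annotation
  lab[23:40, , ] <- 1L     # target annotation
  ann <- voxel_grid(lab, kind = "labels")
  fs <- extract_features(g, 1)
  fit <- train_classifier(fs, ann, iterations = 150, seed = 1)
  final <- utils::tail(fit$curves, 1)
  expect_gte(final$val_accuracy, 0.99)
  expect_gte(final$val_iou, 0.95)
  # monotone sanity and the curves' invariants
  expect_gte(final$val_accuracy, fit$curves$val_accuracy[1])
  expect_true(all(diff(fit$curves$iteration) > 0))
  expect_true(all(fit$curves$val_iou >= 0 & fit$curves$val_iou <= 1))

  # determinism: same seed, identical curves
  fit2 <- train_classifier(fs, ann, iterations = 150, seed = 1)
  expect_identical(fit$curves, fit2$curves)

  expect_error(train_classifier(fs, ann, iterations = 0), "iterations")
  one_class <- voxel_grid(array(c(1L, rep(0L, prod(d) - 1)), d),
                          kind = "labels")
  expect_error(train_classifier(fs, one_class, 10), "both target")
})

test_that("prediction post-processing: raw threshold, closing, size filter", {
  d <- c(40, 40, 40)
  set.seed(6)
  img <- array(0.3, d); img[21:40, , ] <- 0.7
  img <- img + array(stats::rnorm(prod(d), 0, 0.02), d)
  g <- voxel_grid(img)
  lab <- array(0L, d); lab[1:18, , ] <- 2L; lab[23:40, , ] <- 1L
  fs <- extract_features(g, 1)
  fit <- train_classifier(fs, voxel_grid(lab, kind = "labels"), 150, seed = 1)

  raw <- predict_steatosis(fit$classifier, fs, 0, 0)
  # score away from the class boundary plane (1-voxel transition zone)
  expect_gt(mean(raw$data[23:40, , ]), 0.99)
  expect_lt(mean(raw$data[1:18, , ]), 0.01)

  gone <- predict_steatosis(fit$classifier, fs, 0,
                            min_component_um3 = prod(d) * 2)
  expect_false(any(gone$data))

  other <- extract_features(g, c(1, 2))
  expect_error(predict_steatosis(fit$classifier, other), "specification")
})

test_that("overlap metrics follow set arithmetic and are symmetric", {
  d <- c(10, 10, 10)
  a <- array(FALSE, d); a[1:4, 1, 1] <- TRUE
  b <- array(FALSE, d); b[3:6, 1, 1] <- TRUE
  ga <- voxel_grid(a, kind = "labels"); gb <- voxel_grid(b, kind = "labels")

  same <- evaluate_overlap(ga, ga)
  expect_equal(same$iou, 1); expect_equal(same$dice, 1)
  expect_equal(same$accuracy, 1)

  disj <- array(FALSE, d); disj[7:9, 1, 1] <- TRUE
  expect_equal(evaluate_overlap(ga, voxel_grid(disj, kind = "labels"))$iou, 0)

  # |pred| = |truth| = 4 with overlap 2: iou 1/3, dice 1/2
  half <- evaluate_overlap(ga, gb)
  expect_equal(half$iou, 1 / 3)
  expect_equal(half$dice, 1 / 2)
  rev <- evaluate_overlap(gb, ga)
  expect_equal(half$iou, rev$iou)
  expect_equal(half$dice, rev$dice)

  empty <- voxel_grid(array(FALSE, d), kind = "labels")
  expect_equal(evaluate_overlap(empty, empty)$iou, 1)
  expect_error(evaluate_overlap(ga, voxel_grid(array(FALSE, c(5, 5, 5)),
                                               kind = "labels")), "share")
})

test_that("apply_mask multiplies label by grayscale exactly", {
  ph <- small_phantom()
  mask <- truth_mask(ph, "steatosis")
  out <- apply_mask(ph$gray, mask)
  expect_identical(sum(out$data), sum(ph$gray$data[mask$data]))
  full <- voxel_grid(array(TRUE, dim(mask$data)), mask$spacing,
                     kind = "labels")
  expect_identical(apply_mask(ph$gray, full)$data, ph$gray$data)
  none <- voxel_grid(array(FALSE, dim(mask$data)), mask$spacing,
                     kind = "labels")
  expect_true(all(apply_mask(ph$gray, none)$data == 0))
})

test_that("classifier recovers the phantom steatosis mask and band profile", {
  ph <- quiet_phantom()
  g <- quiet_normalized()
  fs <- extract_features(g, c(1, 2, 4))
  ann <- annotate_from_truth(ph, 0.05, seed = 1)
  fit <- train_classifier(fs, ann, iterations = 300, seed = 1)
  pred <- predict_steatosis(fit$classifier, fs, closing_radius_um = 2,
                            min_component_um3 = 100)
  ov <- evaluate_overlap(pred, truth_mask(ph, "steatosis"))
  expect_gte(ov$iou, 0.85)

  # end-to-end: programmed band fractions recovered within +/- 0.07
  cv <- truth_mask(ph, "central_vein")
  lab <- ph$truth$labels$data
  other_lumens <- voxel_grid(array(lab %in% 2:4, dim(lab)), cv$spacing,
                             kind = "labels")
  br <- band_quantify(surface_distance_field(cv), pred, c(0, 30, 60),
                      exclude_mask = other_lumens)
  prog <- ph$truth$programmed_band_fractions
  expect_true(all(abs(br$percent / 100 - prog) <= 0.07))
})
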