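test_that("region growing equals the flood-fill oracle on random volumes", {
  for (case in 1:4) {
    set.seed(case)
    d <- c(20, 18, 16)
    gray <- array(stats::runif(prod(d)), d)
    conn <- sample(c(6, 18, 26), 1)
    lo <- stats::runif(1, 0.2, 0.4)
    hi <- stats::runif(1, 0.6, 0.9)
    ok <- which(gray >= lo & gray <= hi)
    seeds_lin <- sample(ok, 3)
    idx <- arrayInd(seeds_lin, d)
    g <- voxel_grid(gray)
    sp <- seed_points(idx[, 1] - 1, idx[, 2] - 1, idx[, 3] - 1)
    got <- region_grow(g, sp, lo, hi, conn)$data
    want <- flood_oracle(gray, idx, lo, hi, conn)
    expect_identical(as.integer(got), as.integer(want))
  }
})

test_that("region growing semantics: exact cylinders, connectivity, errors", {
  d <- c(60, 30, 30)
  gray <- array(0.1, d)
  cyl <- rasterize_tree(data.frame(x1 = 5, y1 = 15, z1 = 15, x2 = 55,
                                   y2 = 15, z2 = 15, radius = 5), d)$data
  cyl2 <- rasterize_tree(data.frame(x1 = 5, y1 = 15, z1 = 5, x2 = 55,
                                    y2 = 15, z2 = 5, radius = 3), d)$data
  gray[cyl | cyl2] <- 0.9
  g <- voxel_grid(gray)
  out <- region_grow(g, seed_points(30, 15, 15), 0.5, 1)
  expect_identical(out$data > 0, cyl)   # only the seeded tube

  # constant volume with low = high = seed intensity labels everything
  cg <- voxel_grid(array(0.4, c(8, 8, 8)))
  all_lab <- region_grow(cg, seed_points(4, 4, 4), 0.4, 0.4)
  expect_true(all(all_lab$data == 1L))

  expect_error(region_grow(g, seed_points(0, 0, 0), 0.5, 1),
               "seed 1 has intensity")
  expect_error(region_grow(g, seed_points(30, 15, 15), 0.5, 1,
                           connectivity = 4), "connectivity")
})

test_that("enlarging the intensity window never shrinks the grown region", {
  set.seed(8)
  d <- c(24, 24, 24)
  gray <- array(stats::runif(prod(d)), d)
  gray[12, 12, 12] <- 0.5
  g <- voxel_grid(gray)
  s <- seed_points(11, 11, 11)
  narrow <- region_grow(g, s, 0.45, 0.55)$data > 0
  wide <- region_grow(g, s, 0.35, 0.7)$data > 0
  expect_true(all(wide[narrow]))
})

test_that("sinusoid segmentation subtracts vessels and filters by size", {
  d <- c(30, 30, 30)
  gray <- array(0.1, d)
  gray[5:10, 5:10, 5:10] <- 0.9       # a 216-voxel blob
  gray[20, 20, 20] <- 0.9             # a single bright voxel
  g <- voxel_grid(gray)
  thr <- voxel_grid(gray >= 0.5, kind = "labels")

  expect_false(any(segment_sinusoids(g, 0.5, 1, thr)$data))

  empty_vm <- voxel_grid(array(FALSE, d), kind = "labels")
  expect_false(any(segment_sinusoids(g, 0.5, 1, empty_vm,
                                     min_volume_um3 = 1e4)$data))

  out <- segment_sinusoids(g, 0.5, 1, empty_vm, min_volume_um3 = 10)
  expect_equal(sum(out$data), 216)     # the speck is filtered out

  expect_error(segment_sinusoids(g, 0.5, 1,
                                 voxel_grid(array(FALSE, c(10, 10, 10)),
                                            kind = "labels")), "share")
})

test_that("phantom sinusoids are recovered with IoU >= 0.9 at low noise", {
  ph <- quiet_phantom()
  g <- quiet_normalized()
  lab <- ph$truth$labels$data
  vm_truth <- voxel_grid(array(lab %in% 1:4, dim(lab)), g$spacing,
                         kind = "labels")
  sin <- segment_sinusoids(g, 0.68, 1, vm_truth, 150)
  ov <- evaluate_overlap(sin, truth_mask(ph, "sinusoid"))
  expect_gte(ov$iou, 0.9)
  expect_false(any(sin$data & vm_truth$data))  # disjoint by construction
})

test_that("vein branches are classified central vs portal by companion proximity", {
  # a vein tree with artery/bile-duct tubes running parallel at ~20 um is
  # portal; the same tree with only a distant companion blob is central
  d <- c(200, 120, 120)
  set.seed(17)
  cfg <- phantom_config(shape = d,
                        tree_params = list(root_radius = 10, depth = 2,
                                           root_length = 70,
                                           n_central = 1, n_portal = 1))
  tr <- generate_vessel_tree(cfg, "portal")
  vein <- rasterize_tree(tr, d)
  off <- 20
  comp_tubes <- rbind(
    transform(tr, y1 = y1 + off, y2 = y2 + off, radius = 3),
    transform(tr, y1 = y1 - off, y2 = y2 - off, radius = 3))
  comp <- rasterize_tree(comp_tubes, d)
  graph <- build_graph(skeletonize(vein), prune_below_um = 8)

  cls_portal <- classify_vein_branches(graph, comp, 40, 0.5)
  expect_gte(mean(cls_portal == "portal"), 0.95)

  far <- array(FALSE, d)
  far[1:4, 1:4, 1:4] <- TRUE
  cls_central <- classify_vein_branches(
    graph, voxel_grid(far, kind = "labels"), 40, 0.5)
  expect_gte(mean(cls_central == "central"), 0.95)

  empty <- voxel_grid(array(FALSE, d), kind = "labels")
  expect_true(all(classify_vein_branches(graph, empty, 40) == "central"))

  # threshold 0: any nearby companion voxel makes a branch portal
  cls0 <- classify_vein_branches(graph, comp, 40, 0)
  frac <- attr(cls0, "companion_fraction")
  expect_identical(unname(cls0 == "portal"), unname(frac > 0))
})

test_that("split_by_seed assigns components wholly, with conflict/orphan errors", {
  ph <- quiet_phantom()
  cv <- truth_mask(ph, "central_vein")
  pv <- truth_mask(ph, "portal_vein")
  both <- voxel_grid(cv$data | pv$data, cv$spacing, kind = "labels")
  seeds <- phantom_seeds(ph)
  halves <- split_by_seed(both, seeds)
  expect_identical(halves$central$data, cv$data)
  expect_identical(halves$portal$data, pv$data)

  conflicting <- seeds
  conflicting$type <- c("central", "central")
  expect_error({
    s2 <- conflicting; s2$type <- c("portal", "central")
    # put both seeds into the same (central) component
    s2[2, c("x", "y", "z")] <- s2[1, c("x", "y", "z")] + c(2, 0, 0)
    split_by_seed(both, s2)
  }, "both central and portal")

  expect_error(split_by_seed(both, seeds[1, ]), "without a seed")
})
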