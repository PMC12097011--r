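cfg_for_trees <- function(...) {
  phantom_config(shape = c(400, 400, 400),
                 tree_params = list(...))
}

test_that("vessel tree branching follows the radius-ratio recursion", {
  set.seed(1)
  t0 <- generate_vessel_tree(cfg_for_trees(depth = 0, root_radius = 50),
                             "central")
  expect_equal(nrow(t0), 1L)

  set.seed(1)
  tr <- generate_vessel_tree(
    cfg_for_trees(depth = 2, branch_count = 2, radius_ratio = 0.8,
                  root_radius = 50, min_radius = 1), "central")
  expect_equal(nrow(tr), 7L)           # 1 + 2 + 4
  expect_equal(sort(unique(tr$radius)), c(32, 40, 50))  # 50 * 0.8^g
  expect_equal(sum(tr$generation == 2), 4L)

  # degenerate root: emitted once, clamped up to min_radius
  set.seed(1)
  td <- generate_vessel_tree(
    cfg_for_trees(depth = 2, root_radius = 10, min_radius = 20), "central")
  expect_equal(nrow(td), 1L)
  expect_equal(td$radius, 20)
})

test_that("branch count never exceeds the geometric bound and stays in bounds", {
  for (seed in 1:4) {
    set.seed(seed)
    cfg <- cfg_for_trees(depth = 3, branch_count = 3, root_radius = 30,
                         radius_ratio = 0.7, min_radius = 5)
    tr <- generate_vessel_tree(cfg, sample(c("central", "portal"), 1))
    expect_lte(nrow(tr), 1 + 3 + 9 + 27)
    ends <- as.matrix(tr[, c("x2", "y2", "z2")])
    expect_true(all(ends >= 0 & ends <= 400))
  }
})

test_that("tube rasterization reproduces analytic cylinder and sphere volumes", {
  cyl <- data.frame(x1 = 10, y1 = 20, z1 = 20, x2 = 110, y2 = 20, z2 = 20,
                    radius = 5)
  m <- rasterize_tree(cyl, c(130, 40, 40))
  expect_lt(abs(sum(m$data) - pi * 25 * 100) / (pi * 25 * 100), 0.05)

  sph <- data.frame(x1 = 20, y1 = 20, z1 = 20, x2 = 20, y2 = 20, z2 = 20,
                    radius = 10)
  ms <- rasterize_tree(sph, c(40, 40, 40))
  expect_lt(abs(sum(ms$data) - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.05)

  empty <- rasterize_tree(cyl[0, ], c(10, 10, 10))
  expect_false(any(empty$data))
  expect_error(rasterize_tree(cyl, c(0, 10, 10)), "empty grid")
})

test_that("sinusoid synthesis: edge cases, determinism and volume expectation", {
  expect_false(any(synthesize_sinusoids(
    c(30, 30, 30), c(1, 1, 1),
    list(node_density = 0, tube_radius = 3))$data))

  set.seed(5)
  full <- voxel_grid(array(TRUE, c(40, 40, 40)), kind = "labels")
  s1 <- synthesize_sinusoids(c(40, 40, 40), c(1, 1, 1),
                             list(node_density = 5e5, tube_radius = 2), full)
  expect_false(any(s1$data))

  set.seed(7)
  a <- synthesize_sinusoids(c(60, 60, 60), c(1, 1, 1),
                            list(node_density = 5e5, tube_radius = 2))
  set.seed(7)
  b <- synthesize_sinusoids(c(60, 60, 60), c(1, 1, 1),
                            list(node_density = 5e5, tube_radius = 2))
  expect_identical(a$data, b$data)

  expected <- pi * 4 * attr(a, "total_length") # pi r^2 L
  expect_lt(abs(sum(a$data) - expected) / expected, 0.30)

  # the mesh is a single connected network
  lab <- connected_components(a)
  expect_equal(max(lab$data), 1L)
})

test_that("steatosis droplet placement honours the programmed band profile", {
  sphere <- rasterize_tree(
    data.frame(x1 = 64, y1 = 64, z1 = 64, x2 = 64, y2 = 64, z2 = 64,
               radius = 20), c(128, 128, 128))

  expect_error(place_steatosis(
    voxel_grid(array(FALSE, c(10, 10, 10)), kind = "labels"),
    list(band_edges = c(0, 10), band_probabilities = 0.5,
         droplet_radius = c(2, 3))), "empty")

  set.seed(1)
  none <- place_steatosis(sphere, list(band_edges = c(0, 15, 30),
                                       band_probabilities = c(0, 0),
                                       droplet_radius = c(2, 4)))
  expect_false(any(none$data))

  # saturated acceptance: fractions approach 1 in every band
  set.seed(2)
  sat <- place_steatosis(sphere, list(band_edges = c(0, 15, 30),
                                      band_probabilities = c(1, 1),
                                      droplet_radius = c(3, 6)))
  dist <- surface_distance_field(sphere)
  br <- band_quantify(dist, sat, c(0, 15, 30))
  expect_true(all(br$percent > 90))
})

test_that("intensity rendering is exact without noise and statistically calibrated with it", {
  ph <- small_phantom()
  lab <- ph$truth$labels
  im0 <- list(parenchyma_mean = 0.35, lumen_mean = 0.75,
              steatosis_mean = 0.55, noise_sd = 0, bias_amplitude = 0,
              stripe_period = 24, stripe_amplitude = 0)
  g0 <- render_intensity(lab, im0)
  expect_equal(sort(unique(as.vector(g0$data))), c(0.35, 0.55, 0.75))
  expect_true(all(g0$data[lab$data == 0] == 0.35))

  # CLT bound on the lumen ROI mean
  set.seed(9)
  im1 <- utils::modifyList(im0, list(noise_sd = 0.05))
  g1 <- render_intensity(lab, im1)
  lumen <- g1$data[lab$data %in% 1:5]
  expect_lt(abs(mean(lumen) - 0.75), 5 * 0.05 / sqrt(length(lumen)))

  # stripes: spectral peak of the slice-mean profile at 1/period
  set.seed(9)
  im2 <- utils::modifyList(im0, list(stripe_amplitude = 0.05,
                                     stripe_period = 16))
  g2 <- render_intensity(lab, im2)
  prof <- apply(g2$data, 3, mean)
  f <- Mod(stats::fft(prof - mean(prof)))[2:(length(prof) / 2)]
  expect_equal(which.max(f) + 1, length(prof) / 16 + 1)
})

test_that("the phantom is deterministic and its tissue classes are exclusive", {
  ph <- small_phantom()
  ph2 <- generate_phantom(ph$config)
  expect_identical(ph$truth$labels$data, ph2$truth$labels$data)
  expect_identical(ph$gray$data, ph2$gray$data)

  lab <- ph$truth$labels$data
  expect_true(all(lab %in% 0:6))
  vessels <- lab %in% 1:4
  expect_false(any(vessels & ph$truth$steatosis_mask$data))
  expect_false(any((lab == 5) & (lab == 6)))
  # every labelled class is populated in this phantom
  expect_setequal(sort(unique(as.vector(lab))), 0:6)
})
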