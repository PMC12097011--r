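cyl_mask <- function() fixture("cyl_mask", function() {
  rasterize_tree(data.frame(x1 = 15, y1 = 20, z1 = 20, x2 = 115, y2 = 20,
                            z2 = 20, radius = 5), c(130, 40, 40))
})

ball_in_corner <- function() {
  m <- array(FALSE, c(130, 40, 40))
  m[120:126, 30:36, 30:36] <- TRUE
  m
}

test_that("skeletonization preserves topology on canonical solids", {
  # straight cylinder: centreline spans [95, 110] um
  sk <- skeletonize(cyl_mask())
  gr <- build_graph(sk)
  expect_gte(max(vapply(gr$edges, `[[`, numeric(1), "length")), 95)
  expect_lte(max(vapply(gr$edges, `[[`, numeric(1), "length")), 110)
  expect_true(all(sk$data[!cyl_mask()$data] == FALSE))  # skeleton inside mask

  # solid ball collapses to a small cluster near the centre
  ball <- rasterize_tree(data.frame(x1 = 15, y1 = 15, z1 = 15, x2 = 15,
                                    y2 = 15, z2 = 15, radius = 10),
                         c(30, 30, 30))
  skb <- skeletonize(ball)
  expect_lte(sum(skb$data), 27)
  ctr <- arrayInd(which(skb$data), dim(skb$data))
  # the curve skeleton of a ball is a short chord through the centre
  expect_true(all(skb$data[!ball$data] == FALSE))
  expect_true(all(abs(colMeans(ctr) - 16) <= 1))

  # solid torus keeps exactly one cycle (a single self-edge)
  d <- c(60, 60, 20)
  tor <- array(FALSE, d)
  for (k in 1:20) for (j in 1:60) for (i in 1:60) {
    rho <- sqrt((i - 30)^2 + (j - 30)^2)
    tor[i, j, k] <- (rho - 18)^2 + (k - 10)^2 <= 25
  }
  skt <- skeletonize(voxel_grid(tor, kind = "labels"))
  grt <- build_graph(skt, prune_below_um = 10)
  expect_equal(length(grt$edges), 1L)
  expect_equal(grt$edges[[1]]$node_a, grt$edges[[1]]$node_b)

  # skeleton components match mask components
  two <- voxel_grid(cyl_mask()$data | ball_in_corner(), kind = "labels")
  sk2 <- skeletonize(two)
  expect_equal(max(connected_components(sk2)$data),
               max(connected_components(two)$data))

  aniso <- voxel_grid(array(TRUE, c(5, 5, 5)), spacing = c(1, 1, 2),
                      kind = "labels")
  expect_error(skeletonize(aniso), "isotropic")
})

test_that("build_graph decomposes paths, junctions and prunes spurs", {
  mk_skel <- function(coords, d = c(40, 40, 40)) {
    m <- array(FALSE, d)
    m[coords] <- TRUE
    voxel_grid(m, kind = "labels")
  }
  lin <- function(pts, d = c(40, 40, 40))
    pts[, 1] + d[1] * (pts[, 2] - 1) + d[1] * d[2] * (pts[, 3] - 1)

  # straight path: 2 end nodes, 1 edge
  path <- cbind(5:25, 20, 20)
  g1 <- build_graph(mk_skel(lin(path)))
  expect_equal(nrow(g1$nodes), 2L)
  expect_equal(length(g1$edges), 1L)
  expect_equal(g1$edges[[1]]$length, 20)

  # Y: one branch cluster, three end nodes, three edges
  y <- rbind(cbind(10:20, 20, 20),        # stem
             cbind(21:30, 21:30, 20),     # diagonal arm
             cbind(21:30, 19:10, 20))     # other diagonal arm
  g2 <- build_graph(mk_skel(lin(y)))
  expect_equal(length(g2$edges), 3L)
  expect_equal(sum(g2$nodes$kind == "branch"), 1L)
  expect_equal(sum(g2$nodes$kind == "end"), 3L)

  # Y with a 3-um spur, pruned at 5 um, merges into a single edge
  y3 <- rbind(cbind(10:30, 20, 20), cbind(20, 21:23, 20))
  g3 <- build_graph(mk_skel(lin(y3)), prune_below_um = 5)
  expect_equal(length(g3$edges), 1L)
  total <- sum(vapply(g3$edges, `[[`, numeric(1), "length"))
  expect_gte(total, 20)
  expect_lte(total, 21)

  # empty skeleton: empty graph, not an error
  g0 <- build_graph(mk_skel(integer(0)))
  expect_equal(length(g0$edges), 0L)
  expect_equal(nrow(g0$nodes), 0L)
})

test_that("edge splitting leaves total length unchanged", {
  pts <- cbind(seq(0, 30, by = 1), 0, 0)
  full <- sum(sqrt(rowSums(diff(pts)^2)))
  a <- pts[1:13, ]; b <- pts[13:31, ]
  split_sum <- sum(sqrt(rowSums(diff(a)^2))) + sum(sqrt(rowSums(diff(b)^2)))
  expect_equal(split_sum, full)
})

test_that("EDT radii code tube diameter correctly", {
  mask <- cyl_mask()
  gr <- attach_radii(build_graph(skeletonize(mask)), mask)
  diam <- unlist(lapply(gr$edges, function(e) 2 * e$radius))
  # interior points (exclude extended tips where the tube is cut)
  core <- diam[diam > quantile(diam, 0.2)]
  expect_true(all(core >= 9 & core <= 11))

  # doubling the radius doubles the median coded diameter within 10%
  fat <- rasterize_tree(data.frame(x1 = 15, y1 = 25, z1 = 25, x2 = 115,
                                   y2 = 25, z2 = 25, radius = 10),
                        c(130, 50, 50))
  grf <- attach_radii(build_graph(skeletonize(fat)), fat)
  dfat <- unlist(lapply(grf$edges, function(e) 2 * e$radius))
  expect_lt(abs(median(dfat) / median(diam) - 2), 0.2)

  # a skeleton point outside the mask is a hard error
  bad <- build_graph(skeletonize(mask))
  bad$edges[[1]]$points[1, ] <- c(1, 1, 1)
  expect_error(attach_radii(bad, mask), "outside the mask")

  # single-voxel mask: radius at most one voxel
  one <- voxel_grid(array(c(TRUE, rep(FALSE, 26)), c(3, 3, 3)),
                    kind = "labels")
  sk1 <- skeletonize(one)
  g1 <- attach_radii(build_graph(sk1), one)
  expect_lte(max(unlist(lapply(g1$edges, `[[`, "radius")), 0), 1)
})

test_that("the morphometry panel matches analytic expectations", {
  mask <- cyl_mask()
  gr <- build_graph(skeletonize(mask))
  rep <- summarize_morphometry(gr, mask, 1e6)
  expect_equal(rep$n_segments, 1L)
  expect_lt(abs(rep$volume_fraction - 7.854e-3) / 7.854e-3, 0.05)
  expect_lt(abs(rep$length_density_m_per_mm3 - 0.1) / 0.1, 0.11)
  # conservation: total volume is exactly voxel count x voxel volume
  expect_identical(rep$total_volume_um3, sum(mask$data) * voxel_volume(mask))

  empty <- voxel_grid(array(FALSE, c(10, 10, 10)), kind = "labels")
  rep0 <- summarize_morphometry(build_graph(skeletonize(empty)), empty, 1e3)
  expect_equal(rep0$n_segments, 0L)
  expect_equal(rep0$total_length_um, 0)
  expect_equal(rep0$mean_diameter_um, 0)
})

test_that("phantom tree length and diameter are recovered from the skeleton", {
  set.seed(42)
  cfg <- phantom_config(shape = c(200, 200, 200),
                        tree_params = list(root_radius = 8, depth = 2,
                                           root_length = 80,
                                           branch_angle = c(25, 45),
                                           n_central = 1, n_portal = 1))
  tr <- generate_vessel_tree(cfg, "central")
  mask <- rasterize_tree(tr, c(200, 200, 200))
  gr <- attach_radii(build_graph(skeletonize(mask), prune_below_um = 10), mask)
  rep <- summarize_morphometry(gr, mask, 8e6)
  L_true <- tree_total_length(tr)
  expect_lt(abs(rep$total_length_um - L_true) / L_true, 0.1)
  d_true <- 2 * weighted.mean(tr$radius, tr$length)
  expect_lt(abs(rep$mean_diameter_um - d_true), 1)
})

test_that("a fibrotic phantom shows thinner, denser central veins than control", {
  mk <- function(seed, tree) {
    set.seed(seed)
    cfg <- phantom_config(shape = c(200, 200, 200), tree_params = tree)
    tr <- generate_vessel_tree(cfg, "central")
    mask <- rasterize_tree(tr, c(200, 200, 200))
    gr <- attach_radii(build_graph(skeletonize(mask), prune_below_um = 10),
                       mask)
    summarize_morphometry(gr, mask, 8e6)
  }
  control <- mk(1, list(root_radius = 10, depth = 2, root_length = 80,
                        n_central = 1, n_portal = 1))
  fibrotic <- mk(1, list(root_radius = 7, depth = 3, radius_ratio = 0.7,
                         root_length = 80, branch_count = 2,
                         n_central = 1, n_portal = 1))
  expect_lt(fibrotic$mean_diameter_um, control$mean_diameter_um)
  expect_gt(fibrotic$length_density_m_per_mm3,
            control$length_density_m_per_mm3)
})

test_that("group comparison reproduces the pooled t-test exactly", {
  expect_error(compare_groups(1, c(1, 2)), "at least 2")

  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)

  a <- c(2.1, 2.5, 2.3); b <- c(3.1, 3.3, 3.5)
  got <- compare_groups(a, b)
  want <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(got$t_statistic, unname(want$statistic), tolerance = 1e-6)
  expect_equal(got$p_value, want$p.value, tolerance = 1e-6)
  expect_equal(got$sem_a, stats::sd(a) / sqrt(3))

  welch <- compare_groups(a, c(b, 4.9), welch = TRUE)
  want_w <- stats::t.test(a, c(b, 4.9))
  expect_equal(welch$t_statistic, unname(want_w$statistic), tolerance = 1e-6)
  expect_equal(welch$p_value, want_w$p.value, tolerance = 1e-6)

  # documented zero-variance guard
  guard <- compare_groups(c(1, 1, 1), c(2, 2, 2))
  expect_true(is.infinite(guard$t_statistic))
  expect_equal(guard$p_value, 0)
})
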