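test_that("surface distance field: adjacency, analytic sphere, sentinels", {
  d <- c(20, 20, 20)
  m <- array(FALSE, d); m[8:12, 8:12, 8:12] <- TRUE
  g <- voxel_grid(m, kind = "labels")
  df <- surface_distance_field(g)
  expect_true(all(is.na(df$data[m])))              # interior excluded
  expect_equal(df$data[13, 10, 10], 1)             # face-adjacent voxel
  expect_equal(df$data[14, 10, 10], 2)

  sph <- rasterize_tree(data.frame(x1 = 30, y1 = 30, z1 = 30, x2 = 30,
                                   y2 = 30, z2 = 30, radius = 10),
                        c(60, 60, 60))
  dfs <- surface_distance_field(sph)
  # at exterior radius rho the distance is ~ rho - r within one voxel
  for (rho in c(15, 20, 25)) {
    got <- dfs$data[30 + rho + 1, 31, 31]
    expect_lt(abs(got - (rho - 10)), 1)
  }

  allfg <- voxel_grid(array(TRUE, c(5, 5, 5)), kind = "labels")
  expect_true(all(is.na(surface_distance_field(allfg)$data)))
  expect_error(surface_distance_field(
    voxel_grid(array(FALSE, d), kind = "labels")), "empty")
})

test_that("band assignment agrees with brute-force nearest-voxel search", {
  set.seed(3)
  d <- c(24, 22, 20)
  m <- array(FALSE, d)
  m[sample(prod(d), 5)] <- TRUE
  g <- voxel_grid(m, kind = "labels")
  df <- surface_distance_field(g)
  want <- edt_oracle(m, c(1, 1, 1))
  edges <- c(0, 3, 6, 9, 12)
  ext <- !m
  band_got <- findInterval(df$data[ext], edges)
  band_want <- findInterval(want[ext], edges)
  expect_identical(band_got, band_want)
})

test_that("band quantification partitions the shell exactly", {
  ph <- small_phantom()
  cv <- truth_mask(ph, "central_vein")
  df <- surface_distance_field(cv)
  steat <- truth_mask(ph, "steatosis")
  edges <- c(0, 20, 40)
  br <- band_quantify(df, steat, edges)

  # conservation: band region volumes sum to the shell volume exactly
  shell <- sum(!is.na(df$data) & df$data < max(edges)) * voxel_volume(cv)
  expect_identical(sum(br$region_volume_um3), shell)
  # nesting: cumulative volumes increase with distance
  expect_true(all(diff(cumsum(br$region_volume_um3)) > 0))
  expect_true(all(br$steatotic_volume_um3 <= br$region_volume_um3))

  none <- voxel_grid(array(FALSE, dim(cv$data)), cv$spacing, kind = "labels")
  expect_true(all(band_quantify(df, none, edges)$percent == 0))

  allshell <- voxel_grid(!is.na(df$data) & df$data < max(edges),
                         cv$spacing, kind = "labels")
  expect_true(all(band_quantify(df, allshell, edges)$percent == 100))

  expect_error(band_quantify(df, steat, c(10, 20)), "from 0")
})

test_that("band_report arithmetic validates and computes percentages", {
  br <- band_report(c(0, 30, 60), c(100, 200), c(50, 30))
  expect_equal(br$percent, c(50, 15))
  expect_error(band_report(c(0, 30, 60), c(100, 200), c(150, 30)),
               "exceeds")
  expect_error(band_report(c(5, 30), 10, 1), "start at 0")
})

test_that("shell dilation matches the analytic spherical shell", {
  sph <- rasterize_tree(data.frame(x1 = 55, y1 = 55, z1 = 55, x2 = 55,
                                   y2 = 55, z2 = 55, radius = 20),
                        c(110, 110, 110))
  sh <- dilate_shell(sph, 30)
  want <- 4 / 3 * pi * (50^3 - 20^3)
  expect_lt(abs(sum(sh$data) - want) / want, 0.05)
  expect_false(any(sh$data & sph$data))       # disjoint from the branch

  rind <- dilate_shell(sph, 0.9)              # sub-voxel radius: 1-voxel rind
  expect_gt(sum(rind$data), 0)
  expect_true(all(distance_transform(sph)$data[rind$data] <= 1))
  expect_error(dilate_shell(sph, 0), "positive")
})

test_that("diameter-class stratification bins branches and respects overlap rules", {
  d <- c(120, 60, 60)
  thin <- rasterize_tree(data.frame(x1 = 10, y1 = 30, z1 = 30, x2 = 50,
                                    y2 = 30, z2 = 30, radius = 4), d)
  fat <- rasterize_tree(data.frame(x1 = 70, y1 = 30, z1 = 30, x2 = 110,
                                   y2 = 30, z2 = 30, radius = 8), d)
  # steatosis: the y < 30 half-space
  half <- array(FALSE, d); half[, 1:30, ] <- TRUE
  steat <- voxel_grid(half, kind = "labels")

  rep1 <- diameter_class_report(list(thin), 8, steat,
                                class_edges_um = c(100, 150),
                                shell_radius_um = 15)
  expect_equal(nrow(rep1), 1L)                # unpopulated classes absent
  expect_equal(rep1$class, "<100")
  expect_lt(abs(rep1$percent - 50), 3)        # half the shell is steatotic

  # two branches in different classes; overlapping shells go to the larger
  rep2 <- diameter_class_report(list(thin, fat), c(90, 160), steat,
                                class_edges_um = c(100, 150),
                                shell_radius_um = 25)
  expect_setequal(rep2$class, c("<100", ">150"))
  sh_thin <- dilate_shell(thin, 25)$data & !fat$data
  sh_fat <- dilate_shell(fat, 25)$data & !thin$data
  overlap <- sum(sh_thin & sh_fat)
  expect_gt(overlap, 0)
  expect_equal(rep2$shell_volume_um3[rep2$class == ">150"], sum(sh_fat))
  expect_equal(rep2$shell_volume_um3[rep2$class == "<100"],
               sum(sh_thin) - overlap)

  expect_error(diameter_class_report(list(thin), NA_real_, steat),
               "diameter")
})
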