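mk_gray <- function(data, spacing = c(1, 1, 1))
  voxel_grid(data, spacing, kind = "grayscale")

test_that("bias correction flattens smooth fields and preserves structure", {
  d <- c(48, 48, 48)
  expect_error(correct_bias(mk_gray(array(0, d))), "all-zero")
  expect_error(correct_bias(mk_gray(array(1, d)), sigma_um = 0.5), "exceed")

  # constant volume: identity up to rescale
  const <- correct_bias(mk_gray(array(0.5, d)), 16)
  expect_equal(as.vector(const$data), rep(0.5, prod(d)), tolerance = 1e-8)

  # pure smooth bias (peaks inside the field of view), no structure:
  # CV reduced >= 90%
  bx <- 1 + 0.3 * cos(2 * pi * (seq_len(d[1]) - 0.5) / d[1])
  bias <- outer(outer(bx, bx), bx)
  bgrid <- mk_gray(0.5 * bias / mean(bias))
  cv0 <- stats::sd(bgrid$data) / mean(bgrid$data)
  corr <- correct_bias(bgrid, 8)
  cv1 <- stats::sd(corr$data) / mean(corr$data)
  expect_lt(cv1, 0.1 * cv0)

  # piecewise-constant phantom (uniformly scattered bright blobs, so the
  # local structure density is homogeneous) times bias: label-wise means
  # restored to 2%
  dph <- c(96, 96, 96)
  set.seed(11)
  centers <- cbind(stats::runif(60, 8, 88), stats::runif(60, 8, 88),
                   stats::runif(60, 8, 88))
  blobs <- rasterize_tree(
    data.frame(x1 = centers[, 1], y1 = centers[, 2], z1 = centers[, 3],
               x2 = centers[, 1], y2 = centers[, 2], z2 = centers[, 3],
               radius = 6), dph)$data
  clean <- array(0.35, dph); clean[blobs] <- 0.75
  bx <- 1 + 0.15 * cos(2 * pi * (seq_len(dph[1]) - 0.5) / dph[1])
  by <- 1 + 0.15 * cos(2 * pi * (seq_len(dph[2]) - 0.5) / dph[2] + 1)
  bfield <- outer(outer(bx, by), rep(1, dph[3]))
  biased <- mk_gray(clean * bfield / mean(bfield))  # gain-normalized bias
  fixed <- correct_bias(biased, 16)
  for (lvl in c(FALSE, TRUE)) {
    m_true <- mean(clean[blobs == lvl])
    m_fix <- mean(fixed$data[blobs == lvl])
    expect_lt(abs(m_fix - m_true) / m_true, 0.02)
  }

  # approximate idempotence
  twice <- correct_bias(fixed, 16)
  rel_rms <- sqrt(mean((twice$data - fixed$data)^2)) /
    sqrt(mean(fixed$data^2))
  expect_lt(rel_rms, 0.01)
})

test_that("stripe removal notches the programmed axial frequency", {
  d <- c(40, 40, 96)
  base <- array(0.5, d)
  set.seed(4)
  base <- base + array(stats::rnorm(prod(d), 0, 0.01), d)
  g <- mk_gray(base)

  # stripe-free volume passes through nearly unchanged
  out0 <- remove_stripes(g, 3, period_voxels = 24)
  expect_lt(sqrt(mean((out0$data - g$data)^2)) / sqrt(mean(g$data^2)), 0.01)

  stripe <- 0.05 * sin(2 * pi * (seq_len(d[3]) - 1) / 24)
  gs <- mk_gray(base + rep(stripe, each = d[1] * d[2]))
  out <- remove_stripes(gs, 3)               # auto period detection
  expect_equal(attr(out, "period"), 24)

  prof <- function(x) apply(x, 3, mean)
  amp_at <- function(x, k) Mod(stats::fft(prof(x) - mean(prof(x))))[k + 1]
  k0 <- d[3] / 24
  expect_lt(amp_at(out$data, k0), 0.1 * amp_at(gs$data, k0))
  # total energy changed by <= 5%
  e0 <- sum(gs$data^2); e1 <- sum(out$data^2)
  expect_lt(abs(e1 - e0) / e0, 0.05)

  expect_error(remove_stripes(g, 5), "axis")
  expect_error(remove_stripes(g, 3, period_voxels = 1), ">= 2")
})

test_that("denoise_and_normalize maps the stated percentiles to [0, 1]", {
  set.seed(2)
  d <- c(24, 24, 24)
  g <- mk_gray(array(stats::runif(prod(d), 0.2, 0.8), d))
  out <- denoise_and_normalize(g, 0, 5, 95)
  q <- stats::quantile(out$data, c(0.05, 0.95), names = FALSE)
  expect_equal(q[1], 0, tolerance = 1e-6)
  expect_equal(q[2], 1, tolerance = 1e-6)
  expect_true(all(out$data >= 0 & out$data <= 1))

  # radius-1 median removes a single-voxel impulse
  imp <- array(0.5, d); imp[12, 12, 12] <- 1
  expect_equal(length(unique(as.vector(
    cpp_median_filter(as.vector(imp), d, 1L)))), 1L)
  expect_error(denoise_and_normalize(mk_gray(array(1, d)), 0, 0, 100),
               "degenerate")

  expect_error(denoise_and_normalize(g, 1, 60, 40), "p_low")
})

test_that("isotropic resampling preserves extent, volume and label integrity", {
  # the instrument geometry: 0.35 x 0.35 x 1 um at (200, 200, 70)
  g <- mk_gray(array(stats::runif(200 * 200 * 70), c(200, 200, 70)),
               spacing = c(0.35, 0.35, 1))
  out <- resample_isotropic(g, 1)
  expect_identical(dim(out$data), c(70L, 70L, 70L))
  expect_equal(out$spacing, c(1, 1, 1))

  # already isotropic: untouched
  iso <- voxel_grid(array(1:8, c(2, 2, 2)), kind = "labels")
  expect_identical(resample_isotropic(iso, 1)$data, iso$data)

  # a 20-um-diameter sphere keeps its volume within 10% across resampling
  sph <- rasterize_tree(
    data.frame(x1 = 20, y1 = 20, z1 = 20, x2 = 20, y2 = 20, z2 = 20,
               radius = 10), c(115, 115, 40), spacing = c(0.35, 0.35, 1))
  vol0 <- sum(sph$data) * voxel_volume(sph)
  rs <- resample_isotropic(sph, 1)
  vol1 <- sum(rs$data) * voxel_volume(rs)
  expect_lt(abs(vol1 - vol0) / vol0, 0.10)
  expect_true(is.logical(rs$data))

  expect_error(resample_isotropic(g, 500), "extent")
  expect_error(resample_isotropic(g, -1), "positive")
})
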