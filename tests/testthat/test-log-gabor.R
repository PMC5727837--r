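test_that("analytic transfer values hit the filter center and bandwidth points", {
  p <- log_gabor_params()
  for (s in seq_len(p$n_scales)) {
    f0 <- 1 / (p$min_wave * p$mult^(s - 1))
    for (k in seq_len(p$n_orientations)) {
      th0 <- (k - 1) * pi / p$n_orientations
      expect_equal(log_gabor_response(p, s, f0, th0, th0), 1, tolerance = 1e-13)
      expect_equal(log_gabor_response(p, s, f0, th0 + p$sigma_theta, th0),
                   exp(-0.5), tolerance = 1e-13)
      expect_equal(log_gabor_response(p, s, f0, th0 - p$sigma_theta, th0),
                   exp(-0.5), tolerance = 1e-13)
    }
  }
  # DC is zero by convention
  expect_identical(log_gabor_response(p, 1, 0, 0, 0), 0)
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(log_gabor_params(n_scales = 0), "n_scales")
  expect_error(log_gabor_params(min_wave = 2), "min_wave")
  expect_error(log_gabor_params(mult = 1), "mult")
  expect_error(log_gabor_params(sigma_theta = 0), "sigma_theta")
  expect_error(build_log_gabor_bank(log_gabor_params(), 4, 64), ">= 8")
})

test_that("bank grids are nonnegative, zero at DC, and peak near (f0, theta0)", {
  p <- log_gabor_params(n_scales = 3)
  bank <- build_log_gabor_bank(p, 64, 64)
  for (s in seq_len(p$n_scales)) for (o in seq_len(p$n_orientations)) {
    g <- bank$transfer[[s]][[o]]
    expect_gte(min(g), 0)
    expect_identical(g[1, 1], 0)   # DC bin
    expect_lte(max(g), 1 + 1e-12)
  }
  # peak location: scale 1 (wavelength 6 px => f0 ~ 0.167), orientation 0
  # (theta0 = 0 points along the column-frequency axis)
  g <- bank$transfer[[1]][[1]]
  peak <- arrayInd(which.max(g), dim(g))
  fy <- wcesaliency:::fft_freqs(64)[peak[1]]
  fx <- wcesaliency:::fft_freqs(64)[peak[2]]
  expect_lt(abs(sqrt(fx^2 + fy^2) - bank$center_freqs[1]), 0.02)
  expect_lt(abs(atan2(fy, fx)), 0.1)
  # reflected half-plane is suppressed (analytic one-sided filter)
  refl_theta <- pi
  expect_lt(log_gabor_response(p, 1, bank$center_freqs[1], refl_theta, 0),
            1e-5)
})

test_that("vectorized PC equals the per-pixel loop oracle on seeded images", {
  p <- log_gabor_params()
  bank <- build_log_gabor_bank(p, 32, 32)
  set.seed(0)
  for (rep in 1:3) {
    img <- matrix(runif(32 * 32), 32, 32)
    for (o in c(1L, 4L)) {
      qr <- quadrature_responses(img, bank, o)
      expected <- pc_loop_oracle(qr$even, qr$odd, p$epsilon)
      got <- pc_orientation_map(img, bank, o)
      expect_equal(max(abs(got - expected)), 0, tolerance = 1e-9)
      expect_gte(min(got), 0)
      expect_lte(max(got), 1)
    }
  }
})

test_that("PC of a constant image vanishes", {
  p <- log_gabor_params()
  bank <- build_log_gabor_bank(p, 32, 32)
  img <- matrix(0.5, 32, 32)
  pc <- pc_orientation_map(img, bank, 1)
  expect_lt(max(pc), 1e-8)
})

test_that("PC localizes a vertical step edge at the step column", {
  img <- matrix(0.2, 64, 64)
  img[, 33:64] <- 0.8
  bank <- build_log_gabor_bank(log_gabor_params(), 64, 64)
  # orientation with theta0 = 0 is tuned to horizontal frequency variation,
  # i.e. vertical edges
  pc <- pc_orientation_map(img, bank, 1)
  col_mean <- colMeans(pc)
  # exclude the wrap-around edge at the frame border
  expect_lte(abs(which.max(col_mean[5:60]) + 4 - 32.5), 1.5)
})

test_that("PC is insensitive to brightness/contrast rescaling", {
  set.seed(0)
  img <- matrix(runif(128 * 128), 128, 128)
  p <- log_gabor_params()
  pc1 <- pc_maps(img, p)
  pc2 <- pc_maps(0.5 + 0.4 * img, p)
  d <- mapply(function(a, b) mean(abs(a - b)), pc1, pc2)
  expect_lt(mean(d), 0.05)
})

test_that("edge moment equals the larger eigenvalue of the orientation matrix", {
  set.seed(1)
  img <- matrix(runif(32 * 32), 32, 32)
  pcs <- pc_maps(img)
  ors <- attr(pcs, "orientations")
  got <- edge_moment(pcs)
  for (i in seq(1, 32, by = 3)) for (j in seq(1, 32, by = 3)) {
    cx <- sum(sapply(seq_along(pcs), function(o) (pcs[[o]][i, j] * sin(ors[o]))^2))
    cy <- sum(sapply(seq_along(pcs), function(o) (pcs[[o]][i, j] * cos(ors[o]))^2))
    cxy <- sum(sapply(seq_along(pcs), function(o)
      pcs[[o]][i, j]^2 * sin(ors[o]) * cos(ors[o])))
    ev <- max(eigen(matrix(c(cy, cxy, cxy, cx), 2, 2), symmetric = TRUE)$values)
    expect_equal(got[i, j], ev, tolerance = 1e-9)
  }
})

test_that("a single-orientation unit PC pixel has moment 1", {
  pcs <- replicate(6, matrix(0, 8, 8), simplify = FALSE)
  ors <- (0:5) * pi / 6
  pcs[[3]][4, 4] <- 1
  m <- edge_moment(pcs, ors)
  expect_equal(m[4, 4], 1, tolerance = 1e-12)
  expect_equal(sum(m), 1, tolerance = 1e-12)
})

test_that("edge saliency is normalized to [0,1] and zero maps pass through", {
  z <- edge_saliency(matrix(0.3, 32, 32))
  expect_lt(max(z), 1e-12)      # constant image: zero moment, unnormalized
  d <- disc_image(64, 64, radius = 20)
  s1 <- edge_saliency(d$gray)
  expect_equal(max(s1), 1)
  expect_gte(min(s1), 0)
})

test_that("high edge saliency concentrates at a disc boundary", {
  d <- disc_image(64, 64, radius = 20)
  s1 <- edge_saliency(d$gray)
  top <- s1 >= quantile(s1, 0.99)
  expect_true(all(abs(d$r[top] - 20) <= 2))
})
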