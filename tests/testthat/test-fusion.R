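test_that("fusion averages pixel-wise and respects weights", {
  m <- matrix(0.4, 3, 3)
  f <- fuse_maps(m, m, m)
  expect_equal(f$values, m)

  e <- matrix(1, 1, 1); i <- matrix(0.5, 1, 1); c0 <- matrix(0, 1, 1)
  expect_equal(fuse_maps(e, i, c0)$values[1, 1], 0.5)
  e2 <- matrix(0.8, 1, 1); i2 <- matrix(0.4, 1, 1); c2 <- matrix(0.9, 1, 1)
  expect_equal(fuse_maps(e2, i2, c2, weights = c(0.5, 0.5, 0))$values[1, 1],
               0.6)
})

test_that("fusion rejects bad shapes and weights", {
  m <- matrix(0.5, 2, 2)
  expect_error(fuse_maps(m, m, matrix(0.5, 3, 3)), "shape")
  expect_error(fuse_maps(m, m, m, weights = c(0.5, 0.5, 0.5)), "sum to 1")
  expect_error(fuse_maps(m * 3, m, m), "outside")
})

test_that("fused values stay within the component envelope", {
  set.seed(5)
  e <- matrix(runif(64), 8, 8); i <- matrix(runif(64), 8, 8)
  c0 <- matrix(runif(64), 8, 8)
  f <- fuse_maps(e, i, c0)$values
  expect_true(all(f >= pmin(e, i, c0) - 1e-12))
  expect_true(all(f <= pmax(e, i, c0) + 1e-12))
})

test_that("mean thresholding picks strict exceedances", {
  m <- matrix(0.7, 4, 4)
  mask <- threshold_mask(m)
  expect_false(any(mask))                       # constant map -> empty
  m2 <- matrix(c(0.1, 0.1, 0.1, 0.9), 2, 2)
  mask2 <- threshold_mask(m2)
  expect_equal(sum(mask2), 1)
  expect_equal(attr(mask2, "threshold"), 0.3)
})

test_that("thresholding is invariant to adding a constant", {
  set.seed(6)
  m <- matrix(runif(100, 0, 0.5), 10, 10)
  expect_identical(as.vector(threshold_mask(m)),
                   as.vector(threshold_mask(m + 0.3)))
})

test_that("field-of-view restriction confines threshold and mask", {
  m <- matrix(0.2, 8, 8); m[3, 3] <- 0.9
  fov <- matrix(FALSE, 8, 8); fov[1:4, 1:4] <- TRUE
  mask <- threshold_mask(m, fov)
  expect_false(any(mask & !fov))
  expect_equal(attr(mask, "threshold"), mean(m[fov]))
})

test_that("region extraction finds 8-connected components and filters by area", {
  mask <- matrix(FALSE, 12, 12)
  expect_equal(nrow(extract_regions(mask)), 0)

  mask[2:4, 2:4] <- TRUE
  mask[8:10, 8:10] <- TRUE
  regs <- extract_regions(mask)
  expect_equal(nrow(regs), 2)
  expect_equal(regs$area, c(9L, 9L))

  # diagonal touch merges under 8-connectivity
  mask2 <- matrix(FALSE, 6, 6)
  mask2[1:2, 1:2] <- TRUE; mask2[3, 3] <- TRUE
  expect_equal(nrow(extract_regions(mask2)), 1)

  mask3 <- matrix(FALSE, 20, 20)
  mask3[1:5, 1] <- TRUE              # 5 px
  mask3[10:14, 10:13] <- TRUE        # 20 px
  regs3 <- extract_regions(mask3, min_area = 10)
  expect_equal(nrow(regs3), 1)
  expect_equal(regs3$area, 20L)
})

test_that("region areas partition the mask", {
  set.seed(7)
  mask <- matrix(runif(32 * 32) < 0.3, 32, 32)
  regs <- extract_regions(mask)
  expect_equal(sum(regs$area), sum(mask))
  px <- do.call(rbind, regs$pixels)
  expect_equal(nrow(px), sum(mask))
  expect_equal(nrow(unique(as.data.frame(px))), sum(mask))  # disjoint
})

test_that("overlay paints exactly the mask boundary green", {
  img <- flat_rgb(16, 16, c(0.5, 0.5, 0.5))
  expect_identical(overlay_mask(img, matrix(FALSE, 16, 16)), img)

  full <- matrix(TRUE, 16, 16)
  ov <- overlay_mask(img, full)
  border <- matrix(FALSE, 16, 16)
  border[c(1, 16), ] <- TRUE; border[, c(1, 16)] <- TRUE
  expect_true(all(ov[, , 2][border] == 1))
  expect_identical(ov[2:15, 2:15, ], img[2:15, 2:15, ])

  blk <- matrix(FALSE, 16, 16); blk[4:13, 6:15] <- TRUE
  ov2 <- overlay_mask(img, blk)
  # loop oracle: boundary = true pixel with a non-true 8-neighbour
  bnd <- matrix(FALSE, 16, 16)
  for (i in 1:16) for (j in 1:16) {
    if (!blk[i, j]) next
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > 16 || jj < 1 || jj > 16 || !blk[ii, jj])
        bnd[i, j] <- TRUE
    }
  }
  expect_identical(ov2[, , 2] == 1 & ov2[, , 1] == 0, bnd)
})
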