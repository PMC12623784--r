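test_that("synthetic scenes are deterministic with consistent ground truth", {
  sc1 <- generate_scene(n_cells = 4, seed = 12, noise_sd = 0)
  sc2 <- generate_scene(n_cells = 4, seed = 12, noise_sd = 0)
  expect_identical(sc1$cluster_channel, sc2$cluster_channel)
  expect_identical(sc1$mask, sc2$mask)
  expect_identical(nrow(sc1$truth), 4L)
  # noise-free: rendered cluster pixels equal the stored ground truth
  for (i in 1:4) {
    cellpix <- sc1$mask == i
    bright <- sc1$cluster_channel > sc1$background + 1
    expect_identical(sum(bright & cellpix), as.integer(sc1$truth$cluster_area_px[i]))
  }
})

test_that("cluster-area quantification recovers discs and picks the largest", {
  skip_if_not_installed("EBImage")
  nx <- 128; ny <- 128
  mask <- matrix(0L, nx, ny); mask[10:110, 10:110] <- 1L
  img <- matrix(100, nx, ny)
  # flat image: sd = 0, strict threshold leaves nothing
  out <- cdc42_cluster_area_image(img, mask)
  expect_equal(out$cluster_area_px, 0)
  # bright disc of known size
  xx <- matrix(seq_len(nx), nx, ny); yy <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  disc <- (xx - 50)^2 + (yy - 50)^2 <= 8^2
  img2 <- img; img2[disc] <- 1000
  target <- sum(disc)
  out2 <- cdc42_cluster_area_image(img2, mask, imaging_config(sigma = 0.5))
  expect_lt(abs(out2$cluster_area_px - target) / target, 0.15)
  # two discs: only the largest is counted
  disc2 <- (xx - 85)^2 + (yy - 85)^2 <= 4^2
  img3 <- img2; img3[disc2] <- 1000
  out3 <- cdc42_cluster_area_image(img3, mask, imaging_config(sigma = 0.5))
  expect_lt(abs(out3$cluster_area_px - target) / target, 0.15)
  expect_lt(out3$cluster_area_px, target * 1.2)
  expect_error(cdc42_cluster_area_image(img, matrix(0L, nx, ny) + 0L,
                                        labels = 3L),
               "empty cell mask")
})

test_that("ring diameter from images matches the rendered annulus", {
  skip_if_not_installed("EBImage")
  sc <- generate_scene(n_cells = 2, canvas = c(220, 220),
                       ring_diameter = c(20, 20), seed = 3, noise_sd = 0)
  cfg <- imaging_config()
  for (i in 1:2) {
    tr <- sc$truth[i, ]
    res <- ring_diameter_image(sc$ring_channel, sc$mask, tr$label,
                               neck = c(tr$neck_x, tr$neck_y), config = cfg)
    expect_false(res$discarded)
    expect_lt(abs(res$diameter - tr$ring_outer_diameter), 2.0)
  }
  # a uniform zero channel yields a discarded flag
  res0 <- ring_diameter_image(matrix(0, 220, 220), sc$mask, 1,
                              neck = c(sc$truth$neck_x[1], sc$truth$neck_y[1]),
                              config = cfg)
  expect_true(res0$discarded)
})

test_that("objects overlapping the neck ellipse too little are excluded", {
  skip_if_not_installed("EBImage")
  nx <- 160; ny <- 160
  mask <- matrix(0L, nx, ny); mask[20:140, 40:120] <- 1L
  img <- matrix(0, nx, ny)
  # a blob far from the neck: overlaps the thin neck ellipse < 50 percent
  xx <- matrix(seq_len(nx), nx, ny); yy <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  img[(xx - 120)^2 + (yy - 80)^2 <= 10^2] <- 100
  res <- ring_diameter_image(img, mask, 1, neck = c(60, 80),
                             config = imaging_config())
  expect_true(res$discarded)
})

test_that("FWHM estimates match analytic pulses", {
  # rectangular pulse of width w
  prof <- c(rep(0, 20), rep(10, 15), rep(0, 20))
  expect_equal(ring_diameter_fwhm(prof), 15, tolerance = 1.0)
  # triangular pulse: peak 10, base 0, half-width 8 -> FWHM 8
  tri <- c(rep(0, 10), seq(0, 10, length.out = 9), seq(10, 0, length.out = 9)[-1],
           rep(0, 10))
  expect_equal(ring_diameter_fwhm(tri), 8, tolerance = 0.1)
  # two equal peaks: widest crossing reported with a warning
  two <- c(rep(0, 5), rep(10, 3), rep(0, 5), rep(10, 6), rep(0, 5))
  expect_warning(w <- ring_diameter_fwhm(two), "widest")
  expect_equal(w, 6, tolerance = 1.0)
  expect_error(ring_diameter_fwhm(rep(2, 30)), "flat")
})

test_that("phalloidin actin-cluster quantification honours the 80 percent rule", {
  skip_if_not_installed("EBImage")
  nx <- 200; ny <- 200
  xx <- matrix(seq_len(nx), nx, ny); yy <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  neck <- c(100, 100)
  # realistic geometry: constant cytoplasmic background, bright cluster
  # occupying a minority of the neck ellipse (the mean + 2 sd threshold
  # presumes the cluster is not most of the reference region)
  img <- matrix(100, nx, ny)
  blob <- (xx - 100)^2 + (yy - 100)^2 <= 5^2   # fully inside the ellipse
  img[blob] <- 500
  cfg <- imaging_config(sigma = 0.5)
  a <- actin_cluster_area_phalloidin(img, neck, config = cfg)
  expect_gt(a, 0)
  expect_lt(abs(a - sum(blob)) / sum(blob), 0.35)
  # blob mostly outside the ellipse: dropped entirely
  img2 <- matrix(100, nx, ny)
  img2[(xx - 100)^2 + (yy - 140)^2 <= 5^2] <- 500
  expect_equal(actin_cluster_area_phalloidin(img2, neck, config = cfg), 0)
  # flat image: nothing above threshold
  expect_equal(actin_cluster_area_phalloidin(matrix(1, nx, ny), neck,
                                             config = cfg), 0)
})

test_that("rotational-symmetry volumes match closed forms", {
  skip_if_not_installed("EBImage")
  nx <- 120; ny <- 120
  xx <- matrix(seq_len(nx), nx, ny); yy <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  # circle radius 25 -> sphere volume
  circ <- (xx - 60)^2 + (yy - 60)^2 <= 25^2
  v <- cell_volume_from_mask(circ)
  expect_lt(abs(v - 4 / 3 * pi * 25^3) / (4 / 3 * pi * 25^3), 0.03)
  # ellipse semi-axes (40, 22) -> prolate spheroid 4/3 pi a b^2
  ell <- ((xx - 60) / 40)^2 + ((yy - 60) / 22)^2 <= 1
  v2 <- cell_volume_from_mask(ell)
  expect_lt(abs(v2 - 4 / 3 * pi * 40 * 22^2) / (4 / 3 * pi * 40 * 22^2), 0.03)
  # doubling the mask scale multiplies the volume by ~8
  ell_half <- ((xx - 60) / 20)^2 + ((yy - 60) / 11)^2 <= 1
  v3 <- cell_volume_from_mask(ell_half)
  expect_lt(abs(v2 / v3 - 8), 8 * 0.1)
  # disconnected masks are rejected
  two <- circ; two[100:110, 100:110] <- TRUE
  expect_error(cell_volume_from_mask(two), "one connected")
})

test_that("measured ring diameter grows with the rendered diameter", {
  skip_if_not_installed("EBImage")
  d_meas <- vapply(c(14, 19, 24), function(dd) {
    sc <- generate_scene(n_cells = 1, canvas = c(140, 140),
                         ring_diameter = c(dd, dd), seed = 5, noise_sd = 2)
    tr <- sc$truth[1, ]
    ring_diameter_image(sc$ring_channel, sc$mask, 1,
                        neck = c(tr$neck_x, tr$neck_y))$diameter
  }, numeric(1))
  expect_true(all(diff(d_meas) > 0))
})
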