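test_that("cluster area counts the published threshold band", {
  m <- get_mesh(2.5, 642)
  # two-level field: max on exactly 10 percent of nodes
  n10 <- round(0.10 * m$n_nodes)
  f <- rep(1, m$n_nodes)
  ord <- order(-m$nodes[, 3])
  f[ord[seq_len(n10)]] <- 5
  cm <- cluster_area(f, m)
  expect_equal(cm$fraction, n10 / m$n_nodes)
  expect_equal(cm$area, cm$fraction * m$A_m)
  expect_identical(cm$n_clusters, 1L)
})

test_that("cluster area equals an independent brute-force recount", {
  m <- get_mesh(2.5, 642)
  f <- gaussian_cap_field(m, width = 1.2)
  cm <- cluster_area(f, m, threshold = 0.2)
  # independent recount straight from the definition
  brute <- sum(abs(max(f) - f) < 0.2 * (max(f) - min(f))) / length(f)
  expect_equal(cm$fraction, brute)
  # threshold 0 keeps only nodes equal to the maximum
  cm0 <- cluster_area(f, m, threshold = 0)
  expect_equal(cm0$fraction, 0)
  expect_error(cluster_area(rep(1, m$n_nodes), m), "degenerate")
})

test_that("disjoint caps are flagged as multiple clusters", {
  m <- get_mesh(2.5, 642)
  f <- gaussian_cap_field(m, width = 0.7)
  s_bottom <- acos(pmin(1, pmax(-1, -m$nodes[, 3] / m$R))) * m$R
  f <- f + 100 * exp(-(s_bottom / 0.7)^2)
  cm <- cluster_area(f, m, threshold = 0.3)
  expect_gte(cm$n_clusters, 2L)
})

test_that("ring point filtering keeps the argmax and annulus support", {
  m <- get_mesh(2.5, 642)
  # uniform positive field: everything is retained
  expect_length(ring_points(rep(2, m$n_nodes)), m$n_nodes)
  # synthetic annulus around z = 0
  band <- abs(m$nodes[, 3]) < 0.4
  P <- ifelse(band, 10, 0.1)
  idx <- ring_points(P, threshold = 0.2)
  expect_setequal(idx, which(band))
  expect_true(which.max(P) %in% ring_points(P))
  expect_error(ring_points(rep(0, 5)), "positive")
})

test_that("ring diameter is exact on circles and averages annulus rims", {
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  circ <- cbind(1.3 * cos(th), 1.3 * sin(th), 0.7)
  expect_equal(ring_diameter(circ)$diameter, 2.6, tolerance = 1e-12)
  # ideal annulus: inner diameter 1, outer 2, dense uniform radial sampling
  set.seed(7)
  r <- runif(4000, 0.5, 1.0)
  ph <- runif(4000, 0, 2 * pi)
  ann <- cbind(r * cos(ph), r * sin(ph), 1)
  rm <- ring_diameter(ann)
  expect_equal(rm$diameter, 1.5, tolerance = 0.02)
  expect_lt(rm$d_inner, rm$d_outer)
})

test_that("ring diameter is invariant to rotation and permutation, linear in scale", {
  set.seed(1)
  th <- runif(200, 0, 2 * pi)
  r <- runif(200, 0.8, 1.0)
  pts <- cbind(r * cos(th), r * sin(th), 0.5)
  d0 <- ring_diameter(pts)$diameter
  # rigid rotation about a skew axis
  ang <- 0.83
  Rx <- rbind(c(1, 0, 0), c(0, cos(ang), -sin(ang)), c(0, sin(ang), cos(ang)))
  Rz <- rbind(c(cos(0.4), -sin(0.4), 0), c(sin(0.4), cos(0.4), 0), c(0, 0, 1))
  expect_equal(ring_diameter(pts %*% t(Rx %*% Rz))$diameter, d0,
               tolerance = 1e-9)
  expect_equal(ring_diameter(pts[sample.int(200), ])$diameter, d0,
               tolerance = 1e-12)
  expect_equal(ring_diameter(3 * pts)$diameter, 3 * d0, tolerance = 1e-9)
  expect_error(ring_diameter(pts[1:4, ]), "at least 6")
})

test_that("ring formation time finds the recovery after the dip", {
  # monotone increasing trace: first sample
  expect_equal(ring_formation_time(0:10, seq(1, 2, length.out = 11)), 1)
  # dip then rise, first exceeding the initial value at t = 37
  t <- seq(0, 60, by = 1)
  v <- c(10, 10 - 0.4 * (1:30), 10 - 12 + 2 * (1:30))
  v[t == 37] <- 10.5  # crosses at t = 37
  v[t > 37] <- pmax(v[t > 37], 10.5)
  expect_equal(ring_formation_time(t, v), 37)
  # monotone decreasing: never formed
  expect_true(is.na(ring_formation_time(0:10, seq(5, 1, length.out = 11))))
})

test_that("log-log slope fitting matches closed-form OLS", {
  V <- c(65, 130, 270)
  # exact power law area = c V^(1/3)
  res <- suppressWarnings(fit_loglog_slope(V, 2.7 * V^(1 / 3)))
  expect_equal(res$slope, 1 / 3, tolerance = 1e-12)
  expect_equal(res$r_squared, 1)
  # constant metric: slope 0
  expect_equal(suppressWarnings(fit_loglog_slope(V, rep(4, 3)))$slope, 0)
  # hand-computed three-point OLS
  x <- log(c(1, 2, 4)); y <- log(c(2, 3, 7))
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(fit_loglog_slope(c(1, 2, 4), c(2, 3, 7))$slope, beta)
  expect_error(fit_loglog_slope(c(65, 130), c(1, 2)), "n >= 3")
  expect_error(fit_loglog_slope(V, c(-1, 2, 3)), "positive")
  expect_error(fit_loglog_slope(c(65, 65, 65), c(1, 2, 3)), "undefined|volume")
})
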