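test_that("the post-fusion radius follows the area-addition formula", {
  expect_equal(displaced_radius(2.5, 0), 2.5)
  e <- exo_params()
  expect_equal(displaced_radius(2.5, e$A_exo),
               sqrt(2.5^2 + 4 * pi * 0.05^2 / (4 * pi)))
  expect_equal(displaced_radius(2.5, e$A_exo), 2.50050, tolerance = 1e-5)
  expect_true(all(displaced_radius(c(1, 2, 3), 0.1) > c(1, 2, 3)))
  expect_error(displaced_radius(-1, 0), "positive")
})

test_that("the displacement map has the right limits and monotonicities", {
  R <- 2.5
  e0 <- exo_params(r_exo = 0)
  s <- seq(0, pi * R, length.out = 50)
  expect_true(all(exo_displacement(s, R, e0) == 0))
  e <- exo_params()   # alpha 0.5, gamma 1, r_exo 0.05
  dr <- exo_displacement(s, R, e)
  expect_true(all(dr >= 0))
  # decays to (essentially) zero at the antipode: the exact terminal value
  # is pi (R' - R), about one percent of the displacement at the origin
  expect_lt(dr[length(dr)], 0.02 * dr[1])
  expect_gt(dr[1], dr[length(dr)])
  # halving the mobile fraction increases the displacement at small s
  e_half <- exo_params(alpha = 0.25)
  expect_gt(exo_displacement(0.1, R, e_half), exo_displacement(0.1, R, e))
  # the forward map s + dr(s) is non-decreasing everywhere (bijective up
  # to the saturated terminal cap) and strictly increasing before it
  g <- s + dr
  expect_true(all(diff(g) > -1e-12))
  expect_true(all(diff(g[s < 0.9 * pi * R]) > 0))
  expect_error(exo_displacement(-0.5, R, e), "0, pi R")
})

test_that("event times form a seeded homogeneous Poisson process", {
  expect_length(sample_event_times(0, 100), 0)
  t1 <- sample_event_times(0.4, 1e4, seed = 11)
  t2 <- sample_event_times(0.4, 1e4, seed = 11)
  expect_identical(t1, t2)
  # count within 3 sigma of rate * horizon
  expect_lt(abs(length(t1) - 4000), 3 * sqrt(4000))
  # exponential gaps: mean within 3 sigma
  gaps <- diff(t1)
  expect_lt(abs(mean(gaps) - 1 / 0.4), 3 * (1 / 0.4) / sqrt(length(gaps)))
  expect_true(all(diff(t1) > 0))
})

test_that("eligible nodes follow the epsilon threshold rule", {
  m <- get_mesh(2.5, 642)
  f <- gaussian_cap_field(m, width = 1.0)
  # epsilon = 1 keeps only the arg-max node(s)
  expect_identical(sort(eligible_nodes(f, 1 - 1e-12)),
                   which(f > (1 - 1e-12) * max(f)))
  expect_true(which.max(f) %in% eligible_nodes(f, 1 - 1e-12))
  # epsilon -> 0 keeps every node with positive signal
  expect_length(eligible_nodes(f, 1e-12), m$n_nodes)
  # eligible fraction is monotone non-increasing in epsilon
  eps <- c(0.01, 0.1, 0.3, 0.5, 0.7, 0.9)
  fr <- vapply(eps, function(e) attr(eligible_nodes(f, e), "fraction"),
               numeric(1))
  expect_true(all(diff(fr) <= 0))
  expect_error(eligible_nodes(rep(0, 10), 0.5), "all zero")
})

test_that("the exocytosis remap conserves mass and pushes material outward", {
  m <- get_mesh(2.5, 2562)
  model <- septin_model()
  N <- m$n_nodes
  F <- matrix(0, N, 10, dimnames = list(NULL, model$species))
  F[, "Cdc42T"] <- gaussian_cap_field(m, width = 0.8, amplitude = 150)
  F[, "S"] <- gaussian_cap_field(m, width = 0.5, amplitude = 20)
  F[, "Cdc42D"] <- 40
  st <- membrane_state(F, c(Cdc42I = 1, BemGEFc = 0.01, GapSc = 0.1,
                            Axl2c = 0.1, Sc = 1))
  hit <- which.max(F[, "Cdc42T"])
  e <- exo_params()
  # pure displacement (delivery off) conserves each surface integral;
  # the raw interpolation error removed by the flux correction is small
  s1 <- apply_exocytosis(st, m, hit, e, deliver = FALSE)
  m0 <- colSums(st$fields * m$node_area)
  m1 <- colSums(s1$fields * m$node_area)
  expect_lt(max(abs(m1 - m0) / pmax(m0, 1e-300)), 1e-10)
  err <- attr(s1, "mass_error")
  expect_lt(max(abs(err), na.rm = TRUE), 0.03)
  # zero vesicle area: identity
  s0 <- apply_exocytosis(st, m, hit, exo_params(r_exo = 0))
  expect_identical(s0$fields, st$fields)
  # material moves outward: field-weighted mean distance from the hit
  # centre grows
  sdist <- geodesic_distance(m, seq_len(N), rep(hit, N))
  wmean0 <- sum(st$fields[, "S"] * sdist * m$node_area) /
    sum(st$fields[, "S"] * m$node_area)
  s2 <- st
  for (k in 1:10) s2 <- apply_exocytosis(s2, m, hit, e, deliver = FALSE)
  wmean2 <- sum(s2$fields[, "S"] * sdist * m$node_area) /
    sum(s2$fields[, "S"] * m$node_area)
  expect_gt(wmean2, wmean0)
})

test_that("vesicle delivery dilutes the pole with Cdc42D and X cargo", {
  m <- get_mesh(2.5, 2562)
  model <- septin_model()
  N <- m$n_nodes
  F <- matrix(0, N, 10, dimnames = list(NULL, model$species))
  F[, "Cdc42T"] <- gaussian_cap_field(m, width = 0.8, amplitude = 180)
  F[, "Cdc42D"] <- 5
  st <- membrane_state(F, c(Cdc42I = 1, BemGEFc = 0.01, GapSc = 0.1,
                            Axl2c = 0.1, Sc = 1))
  hit <- which.max(F[, "Cdc42T"])
  e <- exo_params()
  s1 <- apply_exocytosis(st, m, hit, e, deliver_X = TRUE)
  # the hit node now carries vesicle membrane: delivered Cdc42D and X
  expect_equal(unname(s1$fields[hit, "Cdc42D"]), e$deliver_Cdc42D)
  expect_equal(unname(s1$fields[hit, "X"]), e$deliver_X)
  expect_equal(unname(s1$fields[hit, "Cdc42T"]), 0)
  # SBE mode: no X delivered
  s2 <- apply_exocytosis(st, m, hit, e, deliver_X = FALSE)
  expect_equal(unname(s2$fields[hit, "X"]), 0)
})
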