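test_that("hit-site sampling concentrates with increasing beta", {
  p <- particle_params()
  set.seed(21)
  cand <- septring:::.cap_points(10000, p$R, p$Omega)
  d <- septring:::.geo_to_center(cand, p$R)
  # beta = 0: uniform over candidates
  set.seed(1)
  pick0 <- replicate(2000, attr(sample_hit_site(cand, 0, p$R), "index"))
  expect_lt(abs(mean(d[pick0]) - mean(d)), 3 * sd(d) / sqrt(2000))
  # large beta concentrates near the centre
  set.seed(2)
  pick3 <- replicate(2000, attr(sample_hit_site(cand, 3, p$R), "index"))
  set.seed(3)
  pick01 <- replicate(2000, attr(sample_hit_site(cand, 0.1, p$R), "index"))
  expect_lt(mean(d[pick3]), mean(d[pick01]))
  # seeded determinism
  h1 <- sample_hit_site(cand, 1, p$R, seed = 5)
  h2 <- sample_hit_site(cand, 1, p$R, seed = 5)
  expect_identical(h1, h2)
  expect_error(sample_hit_site(cand[0, , drop = FALSE], 1, p$R), "candidate")
})

test_that("the simple particle model displaces without loss", {
  # degenerate vesicle: nothing moves
  p0 <- particle_params(r_exo = 0)
  tr0 <- run_simple_particle_sim(p0, seed = 9)
  expect_identical(tr0$positions[[1]], tr0$positions[[21]])
  # particles live on the sphere and are never created or destroyed
  p <- particle_params(beta = 3)
  tr <- run_simple_particle_sim(p, seed = 9)
  expect_length(tr$positions, 21L)
  for (k in c(1, 11, 21)) {
    pos <- tr$positions[[k]]
    expect_equal(nrow(pos), p$n_init)
    expect_lt(max(abs(sqrt(rowSums(pos^2)) - p$R)) / p$R, 1e-9)
  }
  # focused exocytosis pushes the cloud outward on average
  expect_true(all(diff(tr$mean_dist) > -1e-9))
  expect_gt(tr$mean_dist[21], tr$mean_dist[1])
  # reproducibility
  tr2 <- run_simple_particle_sim(p, seed = 9)
  expect_identical(tr$positions[[21]], tr2$positions[[21]])
})

test_that("displacement alone spreads most under focused central exocytosis", {
  # hits at the pole centre (large beta) displace every particle radially
  # outward, while diffused hits (small beta) also push particles inward
  # toward the centre: a displacement-only model therefore does NOT
  # produce a wider pole under diffused exocytosis, which is what
  # motivates exocytosis-aided septin recruitment as the enlargement
  # mechanism
  spreads <- vapply(c(0.1, 1, 3), function(b) {
    m <- vapply(1:6, function(i) {
      tr <- run_simple_particle_sim(particle_params(beta = b),
                                    seed = round(b * 100) + i)
      tr$mean_dist[21]
    }, numeric(1))
    mean(m)
  }, numeric(1))
  expect_gte(spreads[3], spreads[1])
})

test_that("the complex particle model is a birth-death process on the sphere", {
  # no recruitment, empty start: stays empty
  p0 <- particle_params(k_rec = 0)
  tr0 <- run_complex_particle_sim(p0, duration = 2, exo_rate = 0, seed = 1)
  expect_true(all(tr0$counts == 0))
  # steady-state count ~ k_rec / k_off = 120 within 3 sigma
  p <- particle_params(k_rec = 60, k_off = 0.5)
  tr <- run_complex_particle_sim(p, duration = 30, exo_rate = 0.4, seed = 2)
  burn <- tr$times > 5 / p$k_off
  mean_count <- mean(tr$counts[burn])
  expect_lt(abs(mean_count - 120), 3 * sqrt(120))
  # all particles on the sphere
  expect_lt(max(abs(sqrt(rowSums(tr$positions^2)) - p$R)) / p$R, 1e-9)
  # measured lifetimes have mean 1 / k_off
  p2 <- particle_params(k_rec = 200, k_off = 1, Dm = 0)
  tr2 <- run_complex_particle_sim(p2, duration = 25, exo_rate = 0, seed = 3)
  lt <- tr2$lifetimes
  expect_gt(length(lt), 3000)
  expect_lt(abs(mean(lt) - 1), 3 * 1 / sqrt(length(lt)))
  # determinism
  tr3 <- run_complex_particle_sim(p, duration = 5, exo_rate = 0.4, seed = 2)
  tr4 <- run_complex_particle_sim(p, duration = 5, exo_rate = 0.4, seed = 2)
  expect_identical(tr3$positions, tr4$positions)
})

test_that("Brownian surface steps have the planar mean-square displacement", {
  # recruit many immortal particles, diffuse briefly, compare MSD to 4 D t
  p <- particle_params(k_rec = 1e5, k_off = 0, Dm = 0.0045, dt = 0.01,
                       Omega = 0.05)
  tr1 <- run_complex_particle_sim(p, duration = 0.01, exo_rate = 0, seed = 4,
                                  record_every = 1L)
  # positions after exactly one diffusion step of the recruited batch
  # (recruited uniformly in the cap, then one Gaussian tangent step)
  p_nod <- particle_params(k_rec = 1e5, k_off = 0, Dm = 0, dt = 0.01,
                           Omega = 0.05)
  tr0 <- run_complex_particle_sim(p_nod, duration = 0.01, exo_rate = 0,
                                  seed = 4, record_every = 1L)
  # same seed: identical recruitment, so displacement is diffusion only
  n <- min(nrow(tr0$positions), nrow(tr1$positions))
  dd <- acos(pmin(1, pmax(-1, rowSums(tr0$positions[seq_len(n), ] *
                                        tr1$positions[seq_len(n), ]) /
                            p$R^2))) * p$R
  msd <- mean(dd^2)
  expect_lt(abs(msd - 4 * p$Dm * p$dt) / (4 * p$Dm * p$dt), 0.15)
})

test_that("particle snapshots serialise to CSV", {
  tr <- run_simple_particle_sim(particle_params(n_init = 10), n_iter = 2,
                                seed = 1)
  f <- tempfile(fileext = ".csv")
  write_particle_csv(tr, f)
  d <- read.csv(f)
  expect_identical(nrow(d), 30L)
  expect_named(d, c("iteration", "particle", "x", "y", "z"))
  unlink(f)
})
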