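# Zero-reaction model used to probe the diffusion part of the splitting.
.diffusion_only_model <- function(D) {
  septring:::.make_model(
    "diffusion_only", "u", "c0",
    f = function(F, cyto, p) F * 0,
    jac = function(F, cyto, p) array(0, c(1, 1, nrow(F))),
    cyto_rhs = function(cyto, means, p, eta) c(c0 = 0),
    pools = list(),
    diffusion = function(p) c(u = D)
  )
}

test_that("surface operators have the Laplace-Beltrami structure", {
  m <- get_mesh(2.5, 642)
  ops <- assemble_surface_operators(m)
  # constant fields are in the null space
  expect_lt(max(abs(ops$K %*% rep(3.7, m$n_nodes))), 1e-10)
  # symmetry
  expect_lt(max(abs(ops$K - Matrix::t(ops$K))), 1e-14)
  # lumped mass equals the node areas
  expect_equal(ops$M, m$node_area)
  # degree-1 spherical harmonic: Rayleigh quotient gives the
  # Laplace-Beltrami eigenvalue lambda_1 = l(l+1)/R^2 = 2/R^2
  y <- m$nodes[, 3] / m$R
  lam <- as.numeric((y %*% (ops$K %*% y)) / sum(ops$M * y^2))
  expect_equal(lam, 2 / 2.5^2, tolerance = 0.01)
  # refinement tightens the estimate
  m2 <- get_mesh(2.5, 2562)
  ops2 <- assemble_surface_operators(m2)
  y2 <- m2$nodes[, 3] / m2$R
  lam2 <- as.numeric((y2 %*% (ops2$K %*% y2)) / sum(ops2$M * y2^2))
  expect_lt(abs(lam2 - 2 / 2.5^2), abs(lam - 2 / 2.5^2))
})

test_that("a pure diffusion step damps harmonics by the implicit factor", {
  m <- get_mesh(2.5, 642)
  ops <- assemble_surface_operators(m)
  model <- .diffusion_only_model(D = 0.1)
  cfg <- solver_config()
  y1 <- m$nodes[, 3] / m$R
  st <- membrane_state(matrix(5 + y1, dimnames = list(NULL, "u")),
                       c(c0 = 1))
  dt <- 2
  s1 <- imex_step(st, dt, model, list(), m, 0.01, ops, cfg)
  lam1 <- 2 / 2.5^2
  expected <- 5 + y1 / (1 + dt * 0.1 * lam1)
  expect_equal(as.numeric(s1$fields), expected, tolerance = 5e-3)
  # zero diffusion and zero reactions leave the state untouched
  model0 <- .diffusion_only_model(D = 0)
  s0 <- imex_step(st, dt, model0, list(), m, 0.01, ops, cfg)
  expect_identical(s0$fields[, 1], st$fields[, 1])
})

test_that("one coupled step conserves every pool to near machine precision", {
  m <- get_mesh(2.5, 642)
  ops <- assemble_surface_operators(m)
  params <- positive_feedback_params()
  model <- positive_feedback_model()
  eta <- membrane_cytosol_ratio(2.5)
  st <- perturbed_initial_state(params, m, eta, delta = 0.2, seed = 4)
  tot0 <- conserved_totals(st, m, eta, model)
  cfg <- solver_config()
  s <- st
  for (k in 1:5) s <- imex_step(s, 0.1, model, params, m, eta, ops, cfg)
  tot1 <- conserved_totals(s, m, eta, model)
  expect_lt(max(abs(tot1 - tot0) / tot0), 1e-8)
})

test_that("the cytosolic midpoint substep matches its closed form", {
  # linear decay dc/dt = -k c over one step: c (1 - k dt + (k dt)^2 / 2)
  k <- 0.8; dt <- 0.3
  model <- septring:::.make_model(
    "decay", character(0), "c",
    f = NULL, jac = NULL,
    cyto_rhs = function(cyto, means, p, eta) c(c = -p$k * cyto[["c"]]),
    pools = list(), diffusion = function(p) numeric(0))
  out <- ode_substep(c(c = 2), c(), dt, model, list(k = k), eta = 1)
  expect_equal(unname(out[["c"]]), 2 * (1 - k * dt + (k * dt)^2 / 2))
  # zero derivative: unchanged
  out0 <- ode_substep(c(c = 2), c(), dt, model, list(k = 0), eta = 1)
  expect_equal(unname(out0[["c"]]), 2)
})

test_that("perturbed initial states are seeded, bounded and renormalised", {
  m <- get_mesh(2.5, 642)
  params <- positive_feedback_params()
  eta <- membrane_cytosol_ratio(2.5)
  wm <- well_mixed_steady_state(params, eta)
  # delta = 0: exactly homogeneous
  s0 <- perturbed_initial_state(params, m, eta, delta = 0, wm = wm)
  expect_true(all(apply(s0$fields, 2, function(v) diff(range(v))) == 0))
  # determinism in the seed
  s1 <- perturbed_initial_state(params, m, eta, delta = 0.05, seed = 7, wm = wm)
  s2 <- perturbed_initial_state(params, m, eta, delta = 0.05, seed = 7, wm = wm)
  expect_identical(s1$fields, s2$fields)
  s3 <- perturbed_initial_state(params, m, eta, delta = 0.05, seed = 8, wm = wm)
  expect_false(identical(s1$fields, s3$fields))
  # totals conserved by the renormalisation
  model <- positive_feedback_model()
  tot <- conserved_totals(s1, m, eta, model)
  expect_rel_equal(tot[["Cdc42I"]], params$Cdc42_tot, 1e-10)
  expect_rel_equal(tot[["BemGEFc"]], params$BemGEF_tot, 1e-10)
})

test_that("an unperturbed homogeneous state stays homogeneous", {
  m <- get_mesh(2.5, 162)
  params <- positive_feedback_params()
  eta <- membrane_cytosol_ratio(2.5)
  st <- perturbed_initial_state(params, m, eta, delta = 0)
  model <- positive_feedback_model()
  cfg <- solver_config(t_end = 20, ss_rate_tol = 0)
  traj <- integrate_model(model, params, m, eta, st, cfg)
  spread <- apply(traj$state$fields, 2, function(v) diff(range(v)))
  expect_lt(max(spread / pmax(colMeans(traj$state$fields), 1e-12)), 1e-8)
})

test_that("trajectories are deterministic given config and seed", {
  m <- get_mesh(2.5, 162)
  params <- positive_feedback_params()
  eta <- membrane_cytosol_ratio(2.5)
  st <- perturbed_initial_state(params, m, eta, delta = 0.05, seed = 3)
  model <- positive_feedback_model()
  cfg <- solver_config(t_end = 15, ss_rate_tol = 0)
  t1 <- integrate_model(model, params, m, eta, st, cfg)
  t2 <- integrate_model(model, params, m, eta, st, cfg)
  expect_identical(t1$state$fields, t2$state$fields)
  expect_identical(t1$summary, t2$summary)
})

test_that("the splitting is first order: one-step defect halves with dt", {
  m <- get_mesh(2.5, 162)
  ops <- assemble_surface_operators(m)
  params <- positive_feedback_params()
  model <- positive_feedback_model()
  eta <- membrane_cytosol_ratio(2.5)
  st <- perturbed_initial_state(params, m, eta, delta = 0.2, seed = 2)
  cfg <- solver_config()
  # reference: many tiny steps
  fine <- st
  for (k in 1:128) fine <- imex_step(fine, 1 / 128, model, params, m, eta,
                                     ops, cfg)
  defect <- function(nsub) {
    s <- st
    for (k in seq_len(nsub)) s <- imex_step(s, 1 / nsub, model, params, m,
                                            eta, ops, cfg)
    max(abs(s$fields - fine$fields))
  }
  d1 <- defect(8)
  d2 <- defect(16)
  d3 <- defect(32)
  expect_gt(d1 / d2, 1.6)
  expect_lt(d1 / d2, 2.6)
  expect_gt(d2 / d3, 1.6)
  expect_lt(d2 / d3, 3.0)
})

test_that("negative-feedback trajectories with the feedback off reproduce positive-feedback runs exactly", {
  m <- get_mesh(2.5, 162)
  eta <- membrane_cytosol_ratio(2.5)
  p_pf <- positive_feedback_params()
  p_nf <- negative_feedback_params(k8max = 0, k9max = 0)
  wm_pf <- well_mixed_steady_state(p_pf, eta)
  st_pf <- perturbed_initial_state(p_pf, m, eta, delta = 0.05, seed = 6,
                                   wm = wm_pf)
  wm_nf <- well_mixed_steady_state(p_nf, eta)
  st_nf <- perturbed_initial_state(p_nf, m, eta, delta = 0.05, seed = 6,
                                   wm = wm_nf)
  expect_identical(unname(st_nf$fields[, 1:4]), unname(st_pf$fields))
  cfg <- solver_config(t_end = 10, ss_rate_tol = 0)
  tr_pf <- integrate_model(positive_feedback_model(), p_pf, m, eta, st_pf, cfg)
  tr_nf <- integrate_model(negative_feedback_model(), p_nf, m, eta, st_nf, cfg)
  expect_identical(unname(tr_nf$state$fields[, 1:4]),
                   unname(tr_pf$state$fields))
  expect_true(all(tr_nf$state$fields[, 5:6] == 0))
})
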