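test_that("all-zero states have zero reaction derivatives", {
  mesh1 <- unit_mesh()
  for (make in list(positive_feedback_model, negative_feedback_model)) {
    model <- make()
    params <- if (identical(model$name, "negative_feedback"))
      negative_feedback_params() else positive_feedback_params()
    st <- uniform_state(model, setNames(numeric(length(model$species)),
                                        model$species),
                        setNames(numeric(length(model$cyto)), model$cyto))
    d <- reaction_rhs(st, params, mesh1, eta = 0.01, model = model)
    expect_true(all(d$fields == 0))
    expect_true(all(d$cyto == 0))
  }
})

test_that("the well-mixed fixed point annihilates the derivatives", {
  eta <- membrane_cytosol_ratio(volume_to_radius(65))
  params <- positive_feedback_params()
  wm <- well_mixed_steady_state(params, eta)
  model <- positive_feedback_model()
  st <- uniform_state(model, wm$fields, wm$cyto)
  d <- reaction_rhs(st, params, unit_mesh(), eta, model)
  expect_lt(max(abs(d$fields)), 1e-10)
  expect_lt(max(abs(d$cyto)), 1e-10)
  # pool totals match the configured amounts
  expect_rel_equal(wm$cyto[["Cdc42I"]] +
                     eta * sum(wm$fields[c("Cdc42T", "Cdc42D", "BemGEF42")]),
                   params$Cdc42_tot, 1e-9)

  # negative feedback: the unphosphorylated state is stationary except for
  # the dynamically frozen phospho-gates (orders of magnitude below k8max)
  params_nf <- negative_feedback_params()
  wm_nf <- well_mixed_steady_state(params_nf, eta)
  expect_true(all(wm_nf$fields[c("BemGEF42s", "BemGEFms")] == 0))
  model_nf <- negative_feedback_model()
  st_nf <- uniform_state(model_nf, wm_nf$fields, wm_nf$cyto)
  d_nf <- reaction_rhs(st_nf, params_nf, unit_mesh(), eta, model_nf)
  expect_lt(max(abs(d_nf$fields)), 1e-7)
  expect_equal(unname(wm_nf$fields[1:4]), unname(wm$fields),
               tolerance = 1e-8)
})

test_that("reaction Jacobians match numerical differentiation", {
  set.seed(11)
  for (fam in c("pf", "nf", "sep")) {
    model <- switch(fam, pf = positive_feedback_model(),
                    nf = negative_feedback_model(),
                    sep = septin_model())
    params <- switch(fam, pf = positive_feedback_params(),
                     nf = negative_feedback_params(), sep = septin_params())
    n <- length(model$species)
    F <- matrix(runif(3 * n, 0.1, 5), 3, n,
                dimnames = list(NULL, model$species))
    cyto <- setNames(runif(length(model$cyto), 0.01, 2), model$cyto)
    J <- model$jac(F, cyto, params)
    h <- 1e-6
    for (j in seq_len(n)) {
      Fp <- F; Fm <- F
      Fp[, j] <- Fp[, j] + h
      Fm[, j] <- Fm[, j] - h
      num <- (model$f(Fp, cyto, params) - model$f(Fm, cyto, params)) / (2 * h)
      for (i in seq_len(n))
        expect_equal(J[i, j, ], unname(num[, i]), tolerance = 1e-5)
    }
  }
})

test_that("compiled reaction kernels agree with the R networks", {
  set.seed(3)
  cfg <- solver_config()
  for (fam in c("pf", "nf", "sep")) {
    model <- switch(fam, pf = positive_feedback_model(),
                    nf = negative_feedback_model(),
                    sep = septin_model())
    params <- switch(fam, pf = positive_feedback_params(),
                     nf = negative_feedback_params(), sep = septin_params())
    n <- length(model$species)
    F <- matrix(runif(20 * n, 0, 4), 20, n,
                dimnames = list(NULL, model$species))
    cyto <- setNames(runif(length(model$cyto), 0.01, 2), model$cyto)
    r_cpp <- septring:::.reaction_be_cpp(F, model$kernel_id, params,
                                         as.numeric(cyto[model$cyto]),
                                         0.05, 1e-12, 50)
    model_r <- model
    model_r$kernel_id <- NULL
    r_R <- septring:::.reaction_be(F, cyto, params, model_r, 0.05, cfg)
    expect_equal(unname(r_cpp), unname(r_R), tolerance = 1e-9)
  }
})

test_that("switching the negative feedback off reduces to positive feedback", {
  params_nf <- negative_feedback_params(k8max = 0, k9max = 0)
  params_pf <- positive_feedback_params()
  mesh1 <- unit_mesh()
  eta <- 0.012
  set.seed(5)
  vals <- runif(4, 0.1, 10)
  model_nf <- negative_feedback_model()
  model_pf <- positive_feedback_model()
  st_nf <- uniform_state(model_nf, setNames(c(vals, 0, 0), model_nf$species),
                         c(Cdc42I = 2, BemGEFc = 0.01, BemGEFcs = 0))
  st_pf <- uniform_state(model_pf, setNames(vals, model_pf$species),
                         c(Cdc42I = 2, BemGEFc = 0.01))
  d_nf <- reaction_rhs(st_nf, params_nf, mesh1, eta, model_nf)
  d_pf <- reaction_rhs(st_pf, params_pf, mesh1, eta, model_pf)
  expect_identical(unname(d_nf$fields[, 1:4]), unname(d_pf$fields))
  expect_true(all(d_nf$fields[, 5:6] == 0))
  # with feedback on, starred species decay to zero only in the cytosol
  # (dephosphorylation is cytosolic): phosphorylation gate at high activity
  # approaches k8max
  expect_equal(hill_gate(1e9, 0.0063, 6, 10), 0.0063, tolerance = 1e-9)
  expect_equal(hill_gate(6, 0.0063, 6, 10), 0.0063 / 2)
  expect_equal(hill_gate(0, 0.0063, 6, 10), 0)
})

test_that("septin network: inert septin pools give zero septin derivatives", {
  model <- septin_model()
  params <- septin_params()
  mesh1 <- unit_mesh()
  # Cdc42 cycle active, septin species and cytosolic septin pools all zero
  st <- uniform_state(model,
                      setNames(c(2, 1, 0.5, 0.01, rep(0, 6)), model$species),
                      c(Cdc42I = 2, BemGEFc = 0.005, GapSc = 0,
                        Axl2c = 0, Sc = 0))
  d <- reaction_rhs(st, params, mesh1, 0.012, model)
  sep_cols <- c("Axl2", "Axl2S", "S", "P", "X", "GapS")
  expect_true(all(d$fields[, sep_cols] == 0))
  expect_true(all(d$cyto[c("GapSc", "Axl2c", "Sc")] == 0))
})

test_that("GapS-catalysed hydrolysis adds to the basal k2b pathway", {
  model <- septin_model()
  params <- septin_params()
  mesh1 <- unit_mesh()
  base <- setNames(c(3, 1, 0, 0, 0, 0, 0, 0, 0, 0), model$species)
  cy <- c(Cdc42I = 0, BemGEFc = 0, GapSc = 0, Axl2c = 0, Sc = 0)
  d0 <- reaction_rhs(uniform_state(model, base, cy), params, mesh1, 0.01,
                     model)
  # with GapS = 0 the Cdc42T decay is k2b only
  expect_equal(unname(d0$fields[1, "Cdc42T"]), -params$k2b * 3)
  withG <- base; withG[["GapS"]] <- 2
  d1 <- reaction_rhs(uniform_state(model, withG, cy), params, mesh1, 0.01,
                     model)
  expect_equal(unname(d1$fields[1, "Cdc42T"]),
               -(params$k2b + params$k13 * 2) * 3)
})

test_that("reaction networks conserve every pool instantaneously", {
  # for each conserved pool, the derivative of cyto + eta <members> is zero
  set.seed(9)
  mesh1 <- unit_mesh()
  eta <- 0.015
  for (fam in c("pf", "nf", "sep")) {
    model <- switch(fam, pf = positive_feedback_model(),
                    nf = negative_feedback_model(),
                    sep = septin_model())
    params <- switch(fam, pf = positive_feedback_params(),
                     nf = negative_feedback_params(), sep = septin_params())
    vals <- setNames(runif(length(model$species), 0.1, 3), model$species)
    cyto <- setNames(runif(length(model$cyto), 0.01, 1), model$cyto)
    st <- uniform_state(model, vals, cyto)
    d <- reaction_rhs(st, params, mesh1, eta, model)
    pools <- model$pools
    if (fam == "nf") {
      # merge the phospho-split BemGEF pools: k8/k9 cross between them
      pools <- list(pools[[1]],
                    list(cyto = c("BemGEFc", "BemGEFcs"),
                         members = c("BemGEFm", "BemGEF42", "BemGEFms",
                                     "BemGEF42s")))
    }
    for (pl in pools) {
      ddt <- sum(d$cyto[pl$cyto]) +
        eta * sum(d$fields[1, pl$members])
      if (fam == "sep" && identical(pl$cyto, "Sc"))
        ddt <- ddt - eta * params$k25 * 0  # X-delivery handled by events
      expect_lt(abs(ddt), 1e-12 * max(1, sum(abs(d$fields))))
    }
  }
})
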