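## Reaction networks of the model families. Each model object bundles the
## membrane species list, diffusion coefficients, the reaction right-hand
## side and its node-local Jacobian (for the implicit reaction update),
## membrane/cytosol exchange pools, and slow conservative transfers handled
## outside the stiff solve (phospho-cycling of the negative feedback).
##
## Membrane fields are stored as an N x n_species matrix (uM in the membrane
## compartment); cytosolic species are named scalars (uM). Surface integrals
## use lumped node areas; `eta` converts membrane fluxes to cytosolic
## concentration changes.

.w_mean <- function(mesh, v) sum(mesh$node_area * v) / mesh$A_m

#' Construct a membrane/cytosol state
#'
#' @param fields N x n matrix of membrane concentrations (uM), columns named.
#' @param cyto Named numeric of cytosolic concentrations (uM).
#' @param t Time (s).
#' @return Object of class `membrane_state`.
#' @export
membrane_state <- function(fields, cyto, t = 0) {
  if (is.null(colnames(fields))) stop("fields must have column names", call. = FALSE)
  if (any(fields < 0) || any(cyto < 0))
    stop("negative concentrations in state", call. = FALSE)
  if (any(!is.finite(fields)) || any(!is.finite(cyto)))
    stop("non-finite concentrations in state", call. = FALSE)
  structure(list(fields = fields, cyto = cyto, t = t), class = "membrane_state")
}

#' @export
print.membrane_state <- function(x, ...) {
  cat(sprintf("membrane_state at t = %.4g s: %d nodes\n", x$t, nrow(x$fields)))
  rng <- apply(x$fields, 2, range)
  for (j in seq_len(ncol(x$fields)))
    cat(sprintf("  %-8s [%.4g, %.4g] uM\n", colnames(x$fields)[j], rng[1, j], rng[2, j]))
  cat("  cytosol:", paste(sprintf("%s = %.4g", names(x$cyto), x$cyto), collapse = ", "), "\n")
  invisible(x)
}

## ---- positive feedback model ---------------------------------------------

.pf_species <- c("Cdc42T", "Cdc42D", "BemGEF42", "BemGEFm")
.pf_cyto <- c("Cdc42I", "BemGEFc")

.pf_f <- function(F, cyto, p) {
  T <- F[, 1L]; D <- F[, 2L]; B42 <- F[, 3L]; Bm <- F[, 4L]
  I <- cyto[["Cdc42I"]]; Bc <- cyto[["BemGEFc"]]
  act <- (p$k2a * Bm + p$k3 * B42) * D
  cbind(
    act - (p$k2b + p$k4a * Bm + p$k7 * Bc) * T + p$k4b * B42,
    p$k2b * T - act - p$k5b * D + p$k5a * I,
    (p$k4a * Bm + p$k7 * Bc) * T - p$k4b * B42,
    p$k1a * Bc - p$k1b * Bm + p$k4b * B42 - p$k4a * Bm * T
  )
}

.pf_jac <- function(F, cyto, p) {
  T <- F[, 1L]; D <- F[, 2L]; B42 <- F[, 3L]; Bm <- F[, 4L]
  Bc <- cyto[["BemGEFc"]]
  N <- nrow(F)
  J <- array(0, c(4L, 4L, N))
  J[1, 1, ] <- -(p$k2b + p$k4a * Bm + p$k7 * Bc)
  J[1, 2, ] <- p$k2a * Bm + p$k3 * B42
  J[1, 3, ] <- p$k3 * D + p$k4b
  J[1, 4, ] <- p$k2a * D - p$k4a * T
  J[2, 1, ] <- p$k2b
  J[2, 2, ] <- -(p$k2a * Bm + p$k3 * B42) - p$k5b
  J[2, 3, ] <- -p$k3 * D
  J[2, 4, ] <- -p$k2a * D
  J[3, 1, ] <- p$k4a * Bm + p$k7 * Bc
  J[3, 3, ] <- -p$k4b
  J[3, 4, ] <- p$k4a * T
  J[4, 1, ] <- -p$k4a * Bm
  J[4, 3, ] <- p$k4b
  J[4, 4, ] <- -p$k1b - p$k4a * T
  J
}

# d(cyto)/dt given area-weighted surface means of the membrane fields.
.pf_cyto_rhs <- function(cyto, means, p, eta) {
  c(Cdc42I = eta * (p$k5b * means[["Cdc42D"]] - p$k5a * cyto[["Cdc42I"]]),
    BemGEFc = eta * (p$k1b * means[["BemGEFm"]] - p$k1a * cyto[["BemGEFc"]] -
                       p$k7 * cyto[["BemGEFc"]] * means[["Cdc42T"]]))
}

## ---- negative feedback model ---------------------------------------------

.nf_species <- c("Cdc42T", "Cdc42D", "BemGEF42", "BemGEFm", "BemGEF42s", "BemGEFms")
.nf_cyto <- c("Cdc42I", "BemGEFc", "BemGEFcs")

.nf_f <- function(F, cyto, p) {
  T <- F[, 1L]; D <- F[, 2L]; B42 <- F[, 3L]; Bm <- F[, 4L]
  B42s <- F[, 5L]; Bms <- F[, 6L]
  I <- cyto[["Cdc42I"]]; Bc <- cyto[["BemGEFc"]]; Bcs <- cyto[["BemGEFcs"]]
  act <- (p$k2a * Bm + p$k3 * B42) * D
  cbind(
    act - (p$k2b + p$k4a * (Bm + Bms) + p$k7 * (Bc + Bcs)) * T + p$k4b * (B42 + B42s),
    p$k2b * T - act - p$k5b * D + p$k5a * I,
    (p$k4a * Bm + p$k7 * Bc) * T - p$k4b * B42,
    p$k1a * Bc - p$k1b * Bm + p$k4b * B42 - p$k4a * Bm * T,
    (p$k4a * Bms + p$k7 * Bcs) * T - p$k4b * B42s,
    p$k1a * Bcs - p$k1b * Bms + p$k4b * B42s - p$k4a * Bms * T
  )
}

.nf_jac <- function(F, cyto, p) {
  T <- F[, 1L]; D <- F[, 2L]; B42 <- F[, 3L]; Bm <- F[, 4L]
  B42s <- F[, 5L]; Bms <- F[, 6L]
  Bc <- cyto[["BemGEFc"]]; Bcs <- cyto[["BemGEFcs"]]
  N <- nrow(F)
  J <- array(0, c(6L, 6L, N))
  J[1, 1, ] <- -(p$k2b + p$k4a * (Bm + Bms) + p$k7 * (Bc + Bcs))
  J[1, 2, ] <- p$k2a * Bm + p$k3 * B42
  J[1, 3, ] <- p$k3 * D + p$k4b
  J[1, 4, ] <- p$k2a * D - p$k4a * T
  J[1, 5, ] <- p$k4b
  J[1, 6, ] <- -p$k4a * T
  J[2, 1, ] <- p$k2b
  J[2, 2, ] <- -(p$k2a * Bm + p$k3 * B42) - p$k5b
  J[2, 3, ] <- -p$k3 * D
  J[2, 4, ] <- -p$k2a * D
  J[3, 1, ] <- p$k4a * Bm + p$k7 * Bc
  J[3, 3, ] <- -p$k4b
  J[3, 4, ] <- p$k4a * T
  J[4, 1, ] <- -p$k4a * Bm
  J[4, 3, ] <- p$k4b
  J[4, 4, ] <- -p$k1b - p$k4a * T
  J[5, 1, ] <- p$k4a * Bms + p$k7 * Bcs
  J[5, 5, ] <- -p$k4b
  J[5, 6, ] <- p$k4a * T
  J[6, 1, ] <- -p$k4a * Bms
  J[6, 5, ] <- p$k4b
  J[6, 6, ] <- -p$k1b - p$k4a * T
  J
}

.nf_cyto_rhs <- function(cyto, means, p, eta) {
  Bc <- cyto[["BemGEFc"]]; Bcs <- cyto[["BemGEFcs"]]
  c(Cdc42I = eta * (p$k5b * means[["Cdc42D"]] - p$k5a * cyto[["Cdc42I"]]),
    BemGEFc = eta * (p$k1b * means[["BemGEFm"]] - p$k1a * Bc -
                       p$k7 * Bc * means[["Cdc42T"]]),
    BemGEFcs = eta * (p$k1b * means[["BemGEFms"]] - p$k1a * Bcs -
                        p$k7 * Bcs * means[["Cdc42T"]]))
}

#' Hill activation gate
#'
#' `hill(x, max, h, n) = max * x^n / (h^n + x^n)`, the sigmoidal gate used by
#' the delayed negative feedback.
#'
#' @param x Input concentration (uM).
#' @param vmax Maximal rate.
#' @param h Half-activation constant (uM).
#' @param n Hill exponent.
#' @return Gated rate, same shape as `x`.
#' @export
hill_gate <- function(x, vmax, h, n) {
  xn <- pmax(x, 0)^n
  vmax * xn / (h^n + xn)
}

# Slow conservative transfers of the negative-feedback model, applied
# explicitly over dt. Phosphorylation BemGEF42 -> BemGEF42* on the
# membrane is Hill-ACTIVATED by the local total complex concentration
# BemGEF42_t = BemGEF42 + BemGEF42* (it switches on where activity is
# high). Dephosphorylation BemGEFc* -> BemGEFc in the cytosol is
# Hill-REPRESSED by the surface-averaged BemGEF42_t: it switches on once
# activity has fallen. The repressive form is required for the published
# behaviour - the feedback must release the scaffold again when the
# cluster weakens, enabling the reported oscillations; an activating gate
# would trap the entire scaffold pool in the phosphorylated state after
# one activity burst. Rates are << 1/s, so explicit treatment is accurate;
# transfers move mass between species of one pool and conserve totals
# exactly.
.nf_transfer <- function(F, cyto, p, dt, mesh, eta) {
  if (p$k8max > 0) {
    B42t <- F[, 3L] + F[, 5L]
    phi8 <- pmin(dt * hill_gate(B42t, p$k8max, p$k8h, p$k8n) * F[, 3L], F[, 3L])
    F[, 3L] <- F[, 3L] - phi8
    F[, 5L] <- F[, 5L] + phi8
  }
  if (p$k9max > 0) {
    b42t_bar <- .w_mean(mesh, F[, 3L] + F[, 5L])
    k9 <- p$k9max - hill_gate(b42t_bar, p$k9max, p$k9h, p$k9n)
    phi9 <- min(dt * k9 * cyto[["BemGEFcs"]], cyto[["BemGEFcs"]])
    cyto[["BemGEFcs"]] <- cyto[["BemGEFcs"]] - phi9
    cyto[["BemGEFc"]] <- cyto[["BemGEFc"]] + phi9
  }
  list(fields = F, cyto = cyto)
}

## ---- septin ring model (SBE / SBER) --------------------------------------

.sep_species <- c("Cdc42T", "Cdc42D", "BemGEF42", "BemGEFm",
                  "Axl2", "Axl2S", "S", "P", "X", "GapS")
.sep_cyto <- c("Cdc42I", "BemGEFc", "GapSc", "Axl2c", "Sc")

.sep_f <- function(F, cyto, p) {
  T <- F[, 1L]; D <- F[, 2L]; B42 <- F[, 3L]; Bm <- F[, 4L]
  A <- F[, 5L]; AS <- F[, 6L]; S <- F[, 7L]; P <- F[, 8L]
  X <- F[, 9L]; G <- F[, 10L]
  I <- cyto[["Cdc42I"]]; Bc <- cyto[["BemGEFc"]]; Gc <- cyto[["GapSc"]]
  Ac <- cyto[["Axl2c"]]; Sc <- cyto[["Sc"]]
  act <- (p$k2a * Bm + p$k3 * B42) * D
  poly <- (2 * p$k16 * S - p$k17 * P) * S       # net S -> P polymerisation flux
  cbind(
    act - (p$k2b + p$k4a * Bm + p$k7 * Bc) * T - p$k13 * G * T + p$k4b * B42,
    p$k2b * T + p$k13 * G * T - act - p$k5b * D + p$k5a * I,
    (p$k4a * Bm + p$k7 * Bc) * T - p$k4b * B42,
    p$k1a * Bc - p$k1b * Bm + p$k4b * B42 - p$k4a * Bm * T,
    p$k15 * AS - p$k19 * A * S - p$k20 * A * Sc - p$k22 * A + p$k23 * Ac * B42,
    p$k19 * A * S + p$k20 * A * Sc - p$k15 * AS,
    p$k15 * AS - poly - p$k21 * S - p$k19 * A * S + p$k18 * P + p$k25 * Sc * X,
    poly - p$k18 * P,
    -p$k24 * X,
    p$k12a * Gc * P - p$k12b * G
  )
}

.sep_jac <- function(F, cyto, p) {
  T <- F[, 1L]; D <- F[, 2L]; B42 <- F[, 3L]; Bm <- F[, 4L]
  A <- F[, 5L]; AS <- F[, 6L]; S <- F[, 7L]; P <- F[, 8L]
  X <- F[, 9L]; G <- F[, 10L]
  Bc <- cyto[["BemGEFc"]]; Gc <- cyto[["GapSc"]]
  Ac <- cyto[["Axl2c"]]; Sc <- cyto[["Sc"]]
  N <- nrow(F)
  J <- array(0, c(10L, 10L, N))
  J[1, 1, ] <- -(p$k2b + p$k4a * Bm + p$k7 * Bc) - p$k13 * G
  J[1, 2, ] <- p$k2a * Bm + p$k3 * B42
  J[1, 3, ] <- p$k3 * D + p$k4b
  J[1, 4, ] <- p$k2a * D - p$k4a * T
  J[1, 10, ] <- -p$k13 * T
  J[2, 1, ] <- p$k2b + p$k13 * G
  J[2, 2, ] <- -(p$k2a * Bm + p$k3 * B42) - p$k5b
  J[2, 3, ] <- -p$k3 * D
  J[2, 4, ] <- -p$k2a * D
  J[2, 10, ] <- p$k13 * T
  J[3, 1, ] <- p$k4a * Bm + p$k7 * Bc
  J[3, 3, ] <- -p$k4b
  J[3, 4, ] <- p$k4a * T
  J[4, 1, ] <- -p$k4a * Bm
  J[4, 3, ] <- p$k4b
  J[4, 4, ] <- -p$k1b - p$k4a * T
  J[5, 3, ] <- p$k23 * Ac
  J[5, 5, ] <- -p$k19 * S - p$k20 * Sc - p$k22
  J[5, 6, ] <- p$k15
  J[5, 7, ] <- -p$k19 * A
  J[6, 5, ] <- p$k19 * S + p$k20 * Sc
  J[6, 6, ] <- -p$k15
  J[6, 7, ] <- p$k19 * A
  J[7, 5, ] <- -p$k19 * S
  J[7, 6, ] <- p$k15
  J[7, 7, ] <- -4 * p$k16 * S + p$k17 * P - p$k21 - p$k19 * A
  J[7, 8, ] <- p$k17 * S + p$k18
  J[7, 9, ] <- p$k25 * Sc
  J[8, 7, ] <- 4 * p$k16 * S - p$k17 * P
  J[8, 8, ] <- -p$k17 * S - p$k18
  J[9, 9, ] <- -p$k24
  J[10, 8, ] <- p$k12a * Gc
  J[10, 10, ] <- -p$k12b
  J
}

.sep_cyto_rhs <- function(cyto, means, p, eta) {
  Bc <- cyto[["BemGEFc"]]; Gc <- cyto[["GapSc"]]
  Ac <- cyto[["Axl2c"]]; Sc <- cyto[["Sc"]]
  c(Cdc42I = eta * (p$k5b * means[["Cdc42D"]] - p$k5a * cyto[["Cdc42I"]]),
    BemGEFc = eta * (p$k1b * means[["BemGEFm"]] - p$k1a * Bc -
                       p$k7 * Bc * means[["Cdc42T"]]),
    GapSc = eta * (p$k12b * means[["GapS"]] - p$k12a * Gc * means[["P"]]),
    Axl2c = eta * (p$k22 * means[["Axl2"]] -
                     p$k23 * Ac * means[["BemGEF42"]]),
    Sc = eta * (p$k21 * means[["S"]] -
                  p$k20 * means[["Axl2"]] * Sc - p$k25 * means[["X"]] * Sc))
}

## ---- model objects --------------------------------------------------------

.make_model <- function(name, species, cyto, f, jac, cyto_rhs, pools,
                        diffusion, transfer = NULL, kernel_id = NULL) {
  structure(list(name = name, species = species, cyto = cyto, f = f,
                 jac = jac, cyto_rhs = cyto_rhs, pools = pools,
                 diffusion = diffusion, transfer = transfer,
                 kernel_id = kernel_id),
            class = "septring_model")
}

#' @export
print.septring_model <- function(x, ...) {
  cat(sprintf("septring_model '%s': %d membrane species (%s), %d cytosolic (%s)\n",
              x$name, length(x$species), paste(x$species, collapse = ", "),
              length(x$cyto), paste(x$cyto, collapse = ", ")))
  invisible(x)
}

#' Model family constructors
#'
#' Build the model object used by the solver for a given parameter set:
#' the positive-feedback Cdc42 cycle, the negative-feedback extension with
#' phospho-cycled scaffold species, or the septin ring model (SBE/SBER;
#' identical networks, SBE omits every reaction of the vesicle-delivered
#' species X). Membrane/cytosol exchange pools declare which membrane
#' species exchange with which cytosolic scalar; the solver uses them for
#' exactly conservative bookkeeping.
#'
#' @param params Matching parameter object.
#' @return A `septring_model`.
#' @export
positive_feedback_model <- function(params = positive_feedback_params()) {
  .make_model(
    "positive_feedback", .pf_species, .pf_cyto, .pf_f, .pf_jac, .pf_cyto_rhs,
    pools = list(
      list(cyto = "Cdc42I", members = c("Cdc42T", "Cdc42D", "BemGEF42"),
           total = "Cdc42_tot"),
      list(cyto = "BemGEFc", members = c("BemGEFm", "BemGEF42"),
           total = "BemGEF_tot")),
    diffusion = function(p) setNames(rep(p$Dm, 4L), .pf_species),
    kernel_id = 1L
  )
}

#' @rdname positive_feedback_model
#' @export
negative_feedback_model <- function(params = negative_feedback_params()) {
  .make_model(
    "negative_feedback", .nf_species, .nf_cyto, .nf_f, .nf_jac, .nf_cyto_rhs,
    pools = list(
      list(cyto = "Cdc42I",
           members = c("Cdc42T", "Cdc42D", "BemGEF42", "BemGEF42s"),
           total = "Cdc42_tot"),
      list(cyto = "BemGEFc", members = c("BemGEFm", "BemGEF42"), total = NA),
      list(cyto = "BemGEFcs", members = c("BemGEFms", "BemGEF42s"), total = NA)),
    diffusion = function(p) setNames(rep(p$Dm, 6L), .nf_species),
    transfer = .nf_transfer, kernel_id = 2L
  )
}

#' @rdname positive_feedback_model
#' @param mode `"SBER"` (with vesicle-delivered recruiter X) or `"SBE"`.
#' @export
septin_model <- function(params = septin_params(), mode = c("SBER", "SBE")) {
  mode <- match.arg(mode)
  m <- .make_model(
    paste0("septin_", mode), .sep_species, .sep_cyto, .sep_f, .sep_jac,
    .sep_cyto_rhs,
    pools = list(
      list(cyto = "Cdc42I", members = c("Cdc42T", "Cdc42D", "BemGEF42"),
           total = "Cdc42_tot"),
      list(cyto = "BemGEFc", members = c("BemGEFm", "BemGEF42"),
           total = "BemGEF_tot"),
      list(cyto = "GapSc", members = "GapS", total = "GapS_tot"),
      list(cyto = "Axl2c", members = c("Axl2", "Axl2S"), total = "Axl2_tot"),
      list(cyto = "Sc", members = c("S", "P", "Axl2S"), total = "Septin_tot")),
    diffusion = function(p) {
      d <- setNames(rep(p$Dm, 10L), .sep_species)
      d[c("P", "X")] <- p$Dp
      d
    },
    kernel_id = 3L
  )
  m$mode <- mode
  m
}

#' Reaction right-hand sides (diffusion excluded)
#'
#' Evaluate the reaction time-derivatives of all membrane fields and
#' cytosolic scalars for a state, including the slow transfer reactions
#' (phospho-cycling). Diffusion is handled by the solver, not here.
#'
#' @param state A `membrane_state`.
#' @param params Parameter object.
#' @param mesh A `surface_mesh` (for surface averages).
#' @param eta Membrane/cytosol volume ratio.
#' @param model Optional pre-built model object.
#' @return List with `fields` (N x n matrix of d/dt) and `cyto`
#'   (named numeric of d/dt).
#' @export
reaction_rhs <- function(state, params, mesh, eta, model = NULL) {
  if (is.null(model)) model <- .model_for(params)
  F <- state$fields
  if (any(!is.finite(F)) || any(F < -1e-12))
    stop("reaction_rhs: NaN or negative concentrations", call. = FALSE)
  dF <- model$f(F, state$cyto, params)
  colnames(dF) <- model$species
  means <- setNames(vapply(seq_len(ncol(F)), function(j) .w_mean(mesh, F[, j]),
                           numeric(1)), model$species)
  dc <- model$cyto_rhs(state$cyto, means, params, eta)
  # slow transfers contribute their instantaneous rates too
  if (identical(model$name, "negative_feedback")) {
    B42t <- F[, "BemGEF42"] + F[, "BemGEF42s"]
    r8 <- hill_gate(B42t, params$k8max, params$k8h, params$k8n) * F[, "BemGEF42"]
    dF[, "BemGEF42"] <- dF[, "BemGEF42"] - r8
    dF[, "BemGEF42s"] <- dF[, "BemGEF42s"] + r8
    r9 <- (params$k9max -
             hill_gate(.w_mean(mesh, B42t), params$k9max, params$k9h,
                       params$k9n)) * state$cyto[["BemGEFcs"]]
    dc[["BemGEFcs"]] <- dc[["BemGEFcs"]] - r9
    dc[["BemGEFc"]] <- dc[["BemGEFc"]] + r9
  }
  list(fields = dF, cyto = dc)
}

#' @rdname reaction_rhs
#' @export
positive_feedback_rhs <- function(state, params, mesh, eta)
  reaction_rhs(state, params, mesh, eta, positive_feedback_model(params))

#' @rdname reaction_rhs
#' @export
negative_feedback_rhs <- function(state, params, mesh, eta)
  reaction_rhs(state, params, mesh, eta, negative_feedback_model(params))

#' @rdname reaction_rhs
#' @param mode SBE or SBER (see [septin_model()]).
#' @export
sber_rhs <- function(state, params, mesh, eta, mode = "SBER") {
  if (identical(mode, "SBE")) params <- .sbe_params(params)
  reaction_rhs(state, params, mesh, eta, septin_model(params, mode))
}

# SBE mode: all reactions of species X are switched off.
.sbe_params <- function(p) { p$k24 <- 0; p$k25 <- 0; p }

.model_for <- function(params) {
  if (inherits(params, "negative_feedback_params")) return(negative_feedback_model(params))
  if (inherits(params, "septin_params")) return(septin_model(params))
  if (inherits(params, "positive_feedback_params")) return(positive_feedback_model(params))
  stop("no model for parameter class ", paste(class(params), collapse = "/"),
       call. = FALSE)
}

## ---- conserved totals & well-mixed state ----------------------------------

#' Conserved pool totals of a state
#'
#' Cytosol-equivalent totals: `cyto + eta * <sum of member fields>` for each
#' conserved pool (X is excluded: it is vesicle-delivered and decays).
#'
#' @param state A `membrane_state`.
#' @param mesh A `surface_mesh`.
#' @param eta Membrane/cytosol volume ratio.
#' @param model Model object.
#' @return Named numeric of pool totals (uM).
#' @export
conserved_totals <- function(state, mesh, eta, model) {
  pools <- model$pools
  # starred/unstarred BemGEF pools of the negative-feedback model merge
  out <- c()
  done <- c()
  for (pl in pools) {
    memb <- rowSums(state$fields[, pl$members, drop = FALSE])
    out <- c(out, state$cyto[[pl$cyto]] + eta * .w_mean(mesh, memb))
    done <- c(done, pl$cyto)
  }
  names(out) <- done
  if (all(c("BemGEFc", "BemGEFcs") %in% names(out))) {
    out <- c(out[setdiff(names(out), c("BemGEFc", "BemGEFcs"))],
             BemGEF = unname(out["BemGEFc"] + out["BemGEFcs"]))
  }
  # septin pool counts Axl2S once in both Axl2 and septin pools by design
  out
}

#' Well-mixed (homogeneous) steady state
#'
#' Integrates the spatially homogeneous reaction system to equilibrium and
#' polishes the root with a damped Newton iteration. This is the unstable
#' uniform state from which polarization simulations start.
#'
#' For the negative-feedback model the unphosphorylated fixed point is
#' returned (phospho-species zero): at basal complex activity both Hill
#' gates are many orders of magnitude below their maximal rates, so the
#' phospho-cycle is dynamically frozen on simulation timescales and an
#' unpolarized cell carries no phosphorylated scaffold.
#'
#' @param params Parameter object (positive- or negative-feedback family, or
#'   septin parameters for the polarization module of the septin model).
#' @param eta Membrane/cytosol volume ratio.
#' @param t_relax Integration horizon used to approach the fixed point (s).
#' @return A list with `fields` (named membrane concentrations) and `cyto`.
#' @export
well_mixed_steady_state <- function(params, eta, t_relax = 2e4) {
  model <- .model_for(params)
  frozen_phospho <- inherits(params, "negative_feedback_params")
  params_run <- params
  if (frozen_phospho) { params_run$k8max <- 0; params_run$k9max <- 0 }
  nb <- length(model$species)
  mesh1 <- list(node_area = 1, A_m = 1)   # single-node quadrature
  fun <- function(y) {
    F <- matrix(y[seq_len(nb)], nrow = 1, dimnames = list(NULL, model$species))
    cyto <- setNames(y[nb + seq_along(model$cyto)], model$cyto)
    st <- list(fields = F, cyto = cyto)
    d <- reaction_rhs(st, params_run, mesh1, eta, model)
    c(as.numeric(d$fields), as.numeric(d$cyto))
  }
  rhs <- function(t, y, parms) list(fun(y))
  cyto0 <- setNames(numeric(length(model$cyto)), model$cyto)
  cyto0[["Cdc42I"]] <- params$Cdc42_tot
  cyto0[["BemGEFc"]] <- params$BemGEF_tot
  if ("GapSc" %in% model$cyto) cyto0[["GapSc"]] <- params$GapS_tot
  if ("Axl2c" %in% model$cyto) cyto0[["Axl2c"]] <- params$Axl2_tot
  if ("Sc" %in% model$cyto) cyto0[["Sc"]] <- params$Septin_tot
  y0 <- c(numeric(nb), cyto0)
  out <- deSolve::lsoda(y0, c(0, t_relax / 4, t_relax), rhs, NULL,
                        rtol = 1e-12, atol = 1e-14)
  y <- out[nrow(out), -1]
  # damped Newton polish with a numerical Jacobian
  m <- length(y)
  for (it in 1:40) {
    d <- fun(y)
    if (max(abs(d)) < 1e-13 * max(1, max(abs(y)))) break
    J <- matrix(0, m, m)
    h <- pmax(1e-7 * abs(y), 1e-10)
    for (j in seq_len(m)) {
      yp <- y; yp[j] <- yp[j] + h[j]
      J[, j] <- (fun(yp) - d) / h[j]
    }
    step <- tryCatch(solve(J, -d), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      yn <- y + lam * step
      if (all(yn >= 0) && max(abs(fun(yn))) <= max(abs(d))) break
      lam <- lam / 2
      if (lam < 1e-4) { yn <- y; break }
    }
    if (identical(yn, y)) break
    y <- yn
  }
  d <- fun(y)
  if (max(abs(d)) > 1e-8)
    stop("well-mixed steady state did not converge (max |dc/dt| = ",
         format(max(abs(d))), ")", call. = FALSE)
  list(fields = setNames(y[seq_len(nb)], model$species),
       cyto = setNames(y[nb + seq_along(model$cyto)], model$cyto))
}
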