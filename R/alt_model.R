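## Alternative positive-feedback model with finite cytosolic diffusion:
## the cytosol is a bulk compartment (a ball), discretised as radial
## shells times the surface mesh (finite volumes: radial fluxes between
## shells, cotangent-weighted angular fluxes within each shell). Membrane
## Cdc42T/Cdc42D live on the outermost surface; a Robin-type boundary flux
## couples bulk Cdc42I to the membrane, with recruitment saturating at the
## membrane packing limit kmax.

#' Build the bulk (cytosol) discretisation for the alternative model
#'
#' @param mesh A `surface_mesh` (the outer boundary).
#' @param n_shells Number of radial shells.
#' @return List: `n_shells`, `r_faces`, `r_centers`, `vol` (N x L control
#'   volumes, um^3), `face_area_over_dr` (N x (L-1) radial coupling
#'   coefficients), `shell_thickness`.
#' @export
bulk_shells <- function(mesh, n_shells = 6) {
  R <- mesh$R
  L <- n_shells
  rf <- seq(0, R, length.out = L + 1)        # shell faces
  rc <- (rf[-1] + rf[-(L + 1)]) / 2          # shell centers
  omega <- mesh$node_area / R^2              # solid angles, sum = 4 pi
  vol <- outer(omega, diff(rf^3) / 3)        # N x L
  dr <- diff(rc)
  fa <- outer(omega, rf[2:L]^2) / matrix(dr, mesh$n_nodes, L - 1, byrow = TRUE)
  list(n_shells = L, r_faces = rf, r_centers = rc, vol = vol,
       face_area_over_dr = fa, shell_thickness = diff(rf))
}

#' Reaction and flux right-hand side of the alternative model
#'
#' Membrane: `dT/dt = k2 D - km2 T + k3 T^2 D (+ diffusion)`,
#' `dD/dt = -k2 D + km2 T - k3 T^2 D + J (+ diffusion)` with the boundary
#' exchange flux `J = k1 I_R (kmax - (T + D)) - km1 D` (recruitment
#' saturates when the membrane is packed: `T + D = kmax` shuts it off).
#' Bulk: pure diffusion; the outermost shell loses `J` (converted by the
#' shell thickness).
#'
#' @param state List with `T`, `D` (membrane nodal vectors, uM) and `I`
#'   (N x L bulk matrix, uM; column L is the subsurface shell).
#' @param params An [alt_model_params()].
#' @param mesh A `surface_mesh`.
#' @param shells From [bulk_shells()].
#' @return List of derivatives `T`, `D`, `I` (reaction/flux only; membrane
#'   and bulk diffusion are handled by the integrator) plus `J` (um
#'   uM / s, the exchange flux per membrane area).
#' @export
alternative_model_rhs <- function(state, params, mesh, shells) {
  T <- state$T; D <- state$D
  IR <- state$I[, shells$n_shells]
  sat <- params$kmax - (T + D)
  J <- params$k1 * IR * sat - params$km1 * D     # uM um / s per area
  act <- params$k2 * D + params$k3 * T^2 * D
  dT <- act - params$km2 * T
  dD <- -act + params$km2 * T + J
  dI <- matrix(0, nrow(state$I), ncol(state$I))
  # exact flux pairing: the membrane gains J per unit boundary area, the
  # subsurface shell loses the same amount per control volume
  dI[, shells$n_shells] <- -J * mesh$node_area / shells$vol[, shells$n_shells]
  list(T = dT, D = dD, I = dI, J = J)
}

#' Integrate the alternative positive-feedback model
#'
#' First-order splitting: explicit reaction/flux update (all rates of this
#' model family are of order 1/s or below), then implicit diffusion for
#' the membrane fields (surface FEM) and the bulk (radial + angular finite
#' volumes).
#'
#' @param params An [alt_model_params()].
#' @param mesh A `surface_mesh`.
#' @param n_shells Radial shells for the bulk.
#' @param init Optional initial state (list `T`, `D`, `I`); default: all
#'   Cdc42 in the bulk at concentration `Cdc42_tot`, with multiplicative
#'   noise `delta` on the membrane seed fields.
#' @param t_end Horizon (s).
#' @param dt Fixed step (s).
#' @param delta Initial perturbation of the membrane fields.
#' @param seed RNG seed.
#' @param record_every Record summary every this many steps.
#' @return List of class `alt_trajectory`: final `state`, `summary`
#'   (t, max/mean T, total), `total0` (initial total Cdc42 amount, uM um^3).
#' @export
integrate_alt_model <- function(params = alt_model_params(), mesh,
                                n_shells = 6, init = NULL, t_end = 200,
                                dt = 0.05, delta = 0.01, seed = 1L,
                                record_every = 50L) {
  shells <- bulk_shells(mesh, n_shells)
  N <- mesh$n_nodes; L <- shells$n_shells
  if (is.null(init)) {
    set.seed(seed)
    init <- list(T = 0.05 * params$kmax * (1 + runif(N, -delta, delta)),
                 D = 0.05 * params$kmax * (1 + runif(N, -delta, delta)),
                 I = matrix(params$Cdc42_tot, N, L))
  }
  state <- init
  total_of <- function(s)
    sum(s$I * shells$vol) + sum((s$T + s$D) * mesh$node_area)
  total0 <- total_of(state)
  ops <- assemble_surface_operators(mesh)
  # membrane diffusion operators (backward Euler)
  chT <- Matrix::Cholesky(Matrix::Diagonal(x = ops$M) + dt * params$DT * ops$K,
                          LDL = FALSE)
  chD <- Matrix::Cholesky(Matrix::Diagonal(x = ops$M) + dt * params$DD * ops$K,
                          LDL = FALSE)
  # bulk diffusion: block system over shells; build sparse matrix once
  # unknown ordering: node i, shell l -> (l-1) * N + i
  idx <- function(i, l) (l - 1L) * N + i
  trips_i <- c(); trips_j <- c(); trips_x <- c()
  add <- function(i, j, x) {
    trips_i <<- c(trips_i, i); trips_j <<- c(trips_j, j); trips_x <<- c(trips_x, x)
  }
  # radial couplings
  for (l in seq_len(L - 1)) {
    cfl <- params$DI * shells$face_area_over_dr[, l]
    add(idx(seq_len(N), l), idx(seq_len(N), l), cfl)
    add(idx(seq_len(N), l + 1), idx(seq_len(N), l + 1), cfl)
    add(idx(seq_len(N), l), idx(seq_len(N), l + 1), -cfl)
    add(idx(seq_len(N), l + 1), idx(seq_len(N), l), -cfl)
  }
  # angular couplings: stiffness h_r * K_unit per shell (cot weights are
  # scale free)
  Ku <- ops$K
  tk <- Matrix::summary(Ku)
  for (l in seq_len(L)) {
    sc <- params$DI * shells$shell_thickness[l]
    add(idx(tk$i, l), idx(tk$j, l), sc * tk$x)
  }
  Kb <- Matrix::sparseMatrix(i = trips_i, j = trips_j, x = trips_x,
                             dims = c(N * L, N * L))
  Mb <- as.numeric(shells$vol)            # control volumes in idx order?
  # shells$vol is N x L with column l = shell l -> as.numeric matches idx
  Ab <- Matrix::Diagonal(x = Mb) + dt * Matrix::forceSymmetric(Kb)
  chB <- Matrix::Cholesky(Ab, LDL = FALSE)
  nsteps <- ceiling(t_end / dt)
  rows <- list(); ri <- 0L
  for (k in seq_len(nsteps)) {
    d <- alternative_model_rhs(state, params, mesh, shells)
    Tn <- state$T + dt * d$T
    Dn <- state$D + dt * d$D
    In <- state$I + dt * d$I
    if (min(Tn, Dn) < -1e-9 * params$kmax || min(In) < -1e-6 * params$Cdc42_tot)
      stop("negative concentrations; reduce dt", call. = FALSE)
    Tn <- as.numeric(Matrix::solve(chT, ops$M * Tn))
    Dn <- as.numeric(Matrix::solve(chD, ops$M * Dn))
    In <- matrix(as.numeric(Matrix::solve(chB, Mb * as.numeric(In))), N, L)
    state <- list(T = Tn, D = Dn, I = In)
    if (k %% record_every == 0L || k == nsteps) {
      ri <- ri + 1L
      rows[[ri]] <- c(t = k * dt, maxT = max(Tn), meanT = mean(Tn),
                      total = total_of(state))
    }
  }
  structure(list(state = state, summary = as.data.frame(do.call(rbind, rows)),
                 total0 = total0, shells = shells, params = params),
            class = "alt_trajectory")
}
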