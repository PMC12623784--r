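## Stochastic exocytosis: event timing, hit-site selection, radial
## displacement of membrane species away from the fusion site, and vesicle
## cargo delivery.

#' Sphere radius after vesicle fusion
#'
#' Adding the vesicle surface area `A_exo` to the sphere gives
#' `R' = sqrt(R^2 + A_exo / 4 pi)`.
#'
#' @param R Cell radius (um).
#' @param A_exo Vesicle surface area (um^2).
#' @return `R'` in um.
#' @export
displaced_radius <- function(R, A_exo) {
  if (any(R <= 0)) stop("`R` must be positive", call. = FALSE)
  if (any(A_exo < 0)) stop("`A_exo` must be >= 0", call. = FALSE)
  sqrt(R^2 + A_exo / (4 * pi))
}

#' Radial displacement caused by one exocytosis event
#'
#' A molecule at arc length (geodesic distance) `s` from the centre of
#' exocytosis is displaced outward by
#' `dr(s) = (1/gamma) * (R' * acos(1 - (R^2/R'^2) (1 - cos(s/R)) -
#' A_exo / (2 pi R'^2 alpha)) - s)`, with `R'` from [displaced_radius()].
#' The acos argument is clamped to `[-1, 1]`.
#'
#' @param s Arc length(s) from the exocytosis centre, in `[0, pi R]` (um).
#' @param R Cell radius (um).
#' @param params An [exo_params()] object (uses `A_exo`, `alpha`, `gamma`).
#' @return Displacement(s) in um (>= 0).
#' @export
exo_displacement <- function(s, R, params) {
  if (any(s < -1e-12) || any(s > pi * R + 1e-9))
    stop("`s` must lie in [0, pi R]", call. = FALSE)
  s <- pmin(pmax(s, 0), pi * R)
  if (params$A_exo == 0) return(rep(0, length(s)))
  Rp <- displaced_radius(R, params$A_exo)
  arg <- 1 - (R^2 / Rp^2) * (1 - cos(s / R)) -
    params$A_exo / (2 * pi * Rp^2 * params$alpha)
  arg <- pmin(1, pmax(-1, arg))
  pmax((Rp * acos(arg) - s) / params$gamma, 0)
}

#' Sample exocytosis event times
#'
#' Homogeneous Poisson process: inter-event times are Exponential(rate).
#'
#' @param rate Event rate lambda (events/s).
#' @param horizon Simulation horizon (s).
#' @param seed RNG seed; the same seed gives an identical event list.
#' @return Increasing vector of event times in `(0, horizon]` (possibly
#'   empty).
#' @export
sample_event_times <- function(rate, horizon, seed = 1L) {
  if (rate < 0) stop("`rate` must be >= 0", call. = FALSE)
  if (rate == 0 || horizon <= 0) return(numeric(0))
  set.seed(seed)
  # draw in blocks until the horizon is passed
  times <- numeric(0)
  t <- 0
  repeat {
    n <- max(16L, ceiling(rate * (horizon - t) * 1.2))
    gaps <- rexp(n, rate)
    tt <- t + cumsum(gaps)
    times <- c(times, tt[tt <= horizon])
    t <- tt[length(tt)]
    if (t > horizon) break
  }
  times
}

#' Nodes eligible for exocytosis
#'
#' Exocytosis is targeted towards the Cdc42-GTP cluster: eligible nodes are
#' those with `Cdc42T > epsilon * max(Cdc42T)`. A smaller `epsilon` makes
#' exocytosis more diffused. The fraction of all mesh nodes that is
#' eligible is attached as attribute `"fraction"` (and is the quantity
#' reported as "% of nodes that can be hit").
#'
#' @param field Non-negative nodal field (Cdc42-GTP).
#' @param epsilon Threshold in (0, 1].
#' @return Integer vector of eligible node indices with attribute
#'   `fraction`.
#' @export
eligible_nodes <- function(field, epsilon) {
  if (any(field < 0)) stop("field must be non-negative", call. = FALSE)
  mx <- max(field)
  if (mx <= 0) stop("cannot target exocytosis: field is all zero", call. = FALSE)
  idx <- which(field > epsilon * mx)
  attr(idx, "fraction") <- length(idx) / length(field)
  idx
}

# Sample one hit node among the eligible set (uniformly), deterministically
# in the seed.
.sample_exo_hit <- function(field, epsilon, seed) {
  idx <- eligible_nodes(field, epsilon)
  set.seed(seed)
  hit <- idx[sample.int(length(idx), 1L)]
  attr(hit, "eligible_frac") <- attr(idx, "fraction")
  hit
}

# Node -> incident triangle list (computed once per mesh and memoised on the
# mesh's environment-free list via attribute).
.node_triangles <- function(mesh) {
  inc <- attr(mesh, "node_tri")
  if (!is.null(inc)) return(inc)
  f <- mesh$triangles
  split(rep(seq_len(nrow(f)), 3L), c(f[, 1], f[, 2], f[, 3]))
}

# Barycentric interpolation of nodal values at unit-sphere points.
# pts: m x 3 unit vectors; returns m x ncol(vals) matrix.
.interp_on_mesh <- function(mesh, pts, vals) {
  V <- mesh$nodes / mesh$R
  f <- mesh$triangles
  inc <- .node_triangles(mesh)
  m <- nrow(pts)
  out <- matrix(NA_real_, m, ncol(vals))
  dots <- pts %*% t(V)               # m x N
  nearest <- max.col(dots)
  for (q in seq_len(m)) {
    cand <- inc[[nearest[q]]]
    best_tri <- NA_integer_; best_min <- -Inf; best_b <- NULL
    p <- pts[q, ]
    for (tr in cand) {
      vid <- f[tr, ]
      Tm <- t(V[vid, , drop = FALSE])          # 3 x 3
      b <- tryCatch(solve(Tm, p), error = function(e) NULL)
      if (is.null(b)) next
      ssum <- sum(b)
      if (ssum <= 0) next
      b <- b / ssum                            # gnomonic barycentric
      if (min(b) > best_min) { best_min <- min(b); best_tri <- tr; best_b <- b }
    }
    if (is.na(best_tri) || best_min < -0.05) {
      out[q, ] <- vals[nearest[q], ]           # fallback: nearest node
    } else {
      b <- pmax(best_b, 0); b <- b / sum(b)
      out[q, ] <- b %*% vals[f[best_tri, ], , drop = FALSE]
    }
  }
  out
}

#' Apply one exocytosis event to a membrane state
#'
#' Every membrane species is remapped radially away from the hit node by
#' value transport: the new value at arc length `s` is the old value at the
#' pre-image arc `s_pre` solving `s_pre + dr(s_pre) = s`. A final uniform
#' per-species flux correction removes the slight mass inflation of the
#' outward stretch so the pure displacement conserves each surface
#' integral exactly; the raw inflation is recorded in attribute
#' `mass_error`.
#' The area vacated at the centre is new vesicle membrane: it carries
#' Cdc42-GDP at `params$deliver_Cdc42D` (and X at `params$deliver_X` when
#' `deliver_X = TRUE`), and zero concentration of every other species,
#' diluting the pole. The vesicle footprint (area `A_exo`) is mixed into
#' the nodes nearest the hit site by area fraction.
#'
#' @param state A `membrane_state`.
#' @param mesh A `surface_mesh`.
#' @param hit_node Index of the hit node (must be eligible at call time).
#' @param params An [exo_params()].
#' @param deliver_X Deliver the septin recruiter X (SBER mode)?
#' @param deliver Apply cargo delivery at all (set `FALSE` to study the
#'   pure displacement map).
#' @return Updated `membrane_state` with attribute `mass_error` (named
#'   relative surface-integral changes of the displacement step).
#' @export
apply_exocytosis <- function(state, mesh, hit_node, params,
                             deliver_X = TRUE, deliver = TRUE) {
  F <- state$fields
  if (params$A_exo == 0) return(state)
  R <- mesh$R
  N <- mesh$n_nodes
  cvec <- mesh$nodes[hit_node, ] / R
  s <- .geodesic_from_point(mesh, cvec)
  # forward map g(s) = s + dr(s) on a fine grid (monotone)
  grid <- seq(0, pi * R, length.out = 4000L)
  dr <- exo_displacement(grid, R, params)
  g <- grid + dr
  # the forward map is non-decreasing; it is exactly flat (= pi R') on the
  # terminal region where the acos argument saturates (the far cap all maps
  # to the antipode). A tiny ramp makes the inverse interpolation
  # well-defined there.
  if (any(diff(g) < -1e-9 * R))
    stop("displacement map is not monotone; check exocytosis parameters",
         call. = FALSE)
  g <- cummax(g) + seq_along(g) * (1e-12 * R)
  s_active_max <- if (any(dr > 1e-10)) grid[max(which(dr > 1e-10))] else 0
  void_edge <- g[1]                      # image of the centre
  affected <- which(s <= min(s_active_max + 0.05 * R, pi * R * 0.999) & s > 0)
  affected <- affected[affected != hit_node]
  masses0 <- colSums(F * mesh$node_area)
  Fnew <- F
  if (length(affected)) {
    s_aff <- s[affected]
    invoid <- s_aff <= void_edge
    s_pre <- approx(g, grid, xout = s_aff, rule = 2)$y
    # value transport (semi-Lagrangian): the new value at arc s is the old
    # value at the pre-image point along the great circle towards the node
    xs <- mesh$nodes[affected, , drop = FALSE] / R
    proj <- as.numeric(xs %*% cvec)
    e <- xs - proj %o% cvec
    elen <- sqrt(rowSums(e^2))
    ok <- elen > 1e-12
    e[ok, ] <- e[ok, ] / elen[ok]
    a <- s_pre / R
    pts <- cos(a) * matrix(cvec, length(affected), 3, byrow = TRUE) +
      sin(a) * e
    pts <- pts / sqrt(rowSums(pts^2))
    vals <- .interp_on_mesh(mesh, pts[!invoid & ok, , drop = FALSE], F)
    Fnew[affected[!invoid & ok], ] <- vals
  }
  # centre of exocytosis: the hit node itself maps into the void
  void_nodes <- c(hit_node, affected[s[affected] <= void_edge])
  delivered <- setNames(numeric(ncol(F)), colnames(F))
  if (deliver) {
    if ("Cdc42D" %in% names(delivered))
      delivered[["Cdc42D"]] <- params$deliver_Cdc42D
    if (deliver_X && "X" %in% names(delivered))
      delivered[["X"]] <- params$deliver_X
  }
  Fnew[void_nodes, ] <- 0
  # the raw value transport stretches outward-moving annuli and so inflates
  # each surface integral slightly; the inflation (reported as a
  # diagnostic) is removed by a uniform per-species flux correction so the
  # pure displacement conserves each surface integral exactly
  masses1 <- colSums(Fnew * mesh$node_area)
  mass_err <- (masses1 - masses0) / pmax(masses0, 1e-300)
  fix <- ifelse(masses1 > 0, masses0 / masses1, 1)
  Fnew <- Fnew * rep(fix, each = N)
  # cargo concentrations are diluted by the vesicle/footprint area ratio
  # when the mesh cannot resolve a full vesicle in the vacated nodes
  a_void <- sum(mesh$node_area[void_nodes])
  f_cargo <- min(1, params$A_exo / a_void)
  Fnew[void_nodes, ] <- matrix(delivered * f_cargo, length(void_nodes),
                               ncol(F), byrow = TRUE)
  # footprint mixing: make sure a full vesicle area's worth of membrane
  # carries the delivered composition
  if (deliver) {
    if (a_void < params$A_exo) {
      rest <- setdiff(order(s), void_nodes)
      need <- params$A_exo - a_void
      for (i in rest) {
        fmix <- min(1, need / mesh$node_area[i])
        Fnew[i, ] <- (1 - fmix) * Fnew[i, ] + fmix * delivered
        need <- need - fmix * mesh$node_area[i]
        if (need <= 0) break
      }
    }
  }
  out <- structure(list(fields = Fnew, cyto = state$cyto, t = state$t),
                   class = "membrane_state")
  attr(out, "mass_error") <- mass_err
  out
}
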