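## Particle-based models of exocytosis-driven displacement on a sphere:
## a simple displacement-only model and a complex model with tau-leaping
## recruitment, Brownian surface diffusion and SSA-drawn membrane lifetimes.

# Uniform random points in the geodesic cap of area Omega * 4 pi R^2 around
# +z (cos(theta) uniform in [1 - 2 Omega, 1]).
.cap_points <- function(n, R, Omega) {
  cosmin <- 1 - 2 * Omega
  ct <- runif(n, cosmin, 1)
  st <- sqrt(pmax(0, 1 - ct^2))
  phi <- runif(n, 0, 2 * pi)
  R * cbind(st * cos(phi), st * sin(phi), ct)
}

.geo_to_center <- function(pts, R) {
  R * acos(pmin(1, pmax(-1, pts[, 3] / R)))
}

#' Sample an exocytosis hit site within the pole
#'
#' Samples one of the pre-generated candidate points, with candidate `i`
#' weighted by `1 / (d_i + 1e-8)^beta` where `d_i` is its geodesic distance
#' to the pole centre. Small `beta` spreads exocytosis across the pole;
#' large `beta` concentrates it at the centre.
#'
#' @param candidates m x 3 matrix of candidate positions (um, on the
#'   sphere).
#' @param beta Concentration exponent.
#' @param R Sphere radius (um).
#' @param seed Optional seed (set for standalone reproducibility; leave
#'   `NULL` inside simulations that manage the RNG stream).
#' @return The chosen position (3-vector) with attribute `index`.
#' @export
sample_hit_site <- function(candidates, beta, R, seed = NULL) {
  if (!is.matrix(candidates) || nrow(candidates) == 0L)
    stop("no candidate hit sites", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  d <- .geo_to_center(candidates, R)
  w <- 1 / (d + 1e-8)^beta
  i <- sample.int(nrow(candidates), 1L, prob = w)
  structure(candidates[i, ], index = i)
}

# Displace particle positions radially away from a hit site by the
# exocytosis displacement map.
.displace_particles <- function(pos, hit, R, exo) {
  if (exo$A_exo == 0) return(pos)
  h <- hit / sqrt(sum(hit^2))
  xu <- pos / R
  cosang <- pmin(1, pmax(-1, as.numeric(xu %*% h)))
  s <- R * acos(cosang)
  dr <- exo_displacement(s, R, exo)
  s2 <- pmin(s + dr, pi * R * (1 - 1e-12))
  e <- xu - cosang %o% h
  el <- sqrt(rowSums(e^2))
  ok <- el > 1e-14
  e[ok, ] <- e[ok, ] / el[ok]
  out <- pos
  a <- s2 / R
  out[ok, ] <- R * (cos(a[ok]) * matrix(h, sum(ok), 3, byrow = TRUE) +
                      sin(a[ok]) * e[ok, , drop = FALSE])
  out
}

#' Simple particle model of exocytosis-driven spreading
#'
#' `n_init` particles start uniformly distributed in a pole (geodesic cap)
#' occupying fraction `Omega` of the sphere surface. For 20 iterations one
#' exocytosis event is applied per iteration: a hit site is sampled from a
#' fixed set of `n_candidates` pre-generated points (weighted by the
#' `beta` rule) and every particle is displaced radially away from it.
#' Particles neither diffuse nor dissociate.
#'
#' @param params A [particle_params()].
#' @param n_iter Number of iterations (default 20).
#' @param seed RNG seed.
#' @return List of class `particle_trajectory`: `positions` (list of
#'   n x 3 matrices, one per iteration incl. initial), `mean_dist`
#'   (mean geodesic distance from the pole centre per iteration), `hits`
#'   (hit positions), `params`.
#' @export
run_simple_particle_sim <- function(params, n_iter = 20L, seed = 1L) {
  set.seed(seed)
  R <- params$R
  exo <- exo_params(r_exo = params$r_exo, alpha = params$alpha,
                    gamma = params$gamma)
  pos <- .cap_points(params$n_init, R, params$Omega)
  cand <- .cap_points(params$n_candidates, R, params$Omega)
  positions <- vector("list", n_iter + 1L)
  positions[[1L]] <- pos
  hits <- matrix(NA_real_, n_iter, 3L)
  for (it in seq_len(n_iter)) {
    hit <- sample_hit_site(cand, params$beta, R)
    hits[it, ] <- hit
    pos <- .displace_particles(pos, hit, R, exo)
    positions[[it + 1L]] <- pos
  }
  md <- vapply(positions, function(p) mean(.geo_to_center(p, R)), numeric(1))
  structure(list(positions = positions, mean_dist = md, hits = hits,
                 params = params),
            class = "particle_trajectory")
}

#' Complex particle model with recruitment, diffusion and dissociation
#'
#' Per time step `dt`: `Poisson(k_rec dt)` new particles are recruited
#' uniformly within the pole, each with a membrane lifetime drawn once as
#' `Exponential(k_off)` (the Gillespie/SSA draw for independent particles);
#' all particles take a Brownian surface step with coefficient `Dm`
#' (tangent-plane Gaussian, reprojected to the sphere); particles whose
#' lifetime has elapsed are removed; exocytosis events arrive as a Poisson
#' process with rate `exo_rate` and displace all particles.
#'
#' @param params A [particle_params()].
#' @param duration Simulated time (s).
#' @param exo_rate Exocytosis event rate (events/s; 0 disables).
#' @param seed RNG seed.
#' @param record_every Record summary every this many steps.
#' @return List of class `particle_trajectory`: `times`, `counts`,
#'   `mean_dist`, final `positions`, `lifetimes` (of all removed
#'   particles), `n_events`, `params`.
#' @export
run_complex_particle_sim <- function(params, duration = 60, exo_rate = 0.4,
                                     seed = 1L, record_every = 10L) {
  set.seed(seed)
  R <- params$R
  dt <- params$dt
  exo <- exo_params(r_exo = params$r_exo, alpha = params$alpha,
                    gamma = params$gamma)
  cand <- .cap_points(params$n_candidates, R, params$Omega)
  nsteps <- ceiling(duration / dt)
  ev_times <- if (exo_rate > 0) {
    gaps <- rexp(max(16L, ceiling(exo_rate * duration * 2)), exo_rate)
    tt <- cumsum(gaps); tt[tt <= duration]
  } else numeric(0)
  pos <- matrix(numeric(0), 0L, 3L)
  death <- numeric(0)
  removed_life <- numeric(0)
  born <- numeric(0)
  times <- c(); counts <- c(); mean_dist <- c()
  ev_i <- 1L
  sd_step <- sqrt(2 * params$Dm * dt)
  for (k in seq_len(nsteps)) {
    t <- k * dt
    # recruitment (tau-leaping)
    nrec <- rpois(1L, params$k_rec * dt)
    if (nrec > 0L) {
      newp <- .cap_points(nrec, R, params$Omega)
      pos <- rbind(pos, newp)
      life <- if (params$k_off > 0) rexp(nrec, params$k_off) else rep(Inf, nrec)
      death <- c(death, t + life)
      born <- c(born, rep(t, nrec))
    }
    # Brownian surface step
    n <- nrow(pos)
    if (n > 0L && params$Dm > 0) {
      xu <- pos / R
      a <- matrix(0, n, 3L); a[, 1L] <- 1
      swap <- abs(xu[, 1L]) > 0.9
      if (any(swap)) a[swap, ] <- matrix(c(0, 1, 0), sum(swap), 3L,
                                         byrow = TRUE)
      t1 <- cbind(xu[, 2] * a[, 3] - xu[, 3] * a[, 2],
                  xu[, 3] * a[, 1] - xu[, 1] * a[, 3],
                  xu[, 1] * a[, 2] - xu[, 2] * a[, 1])
      t1 <- t1 / sqrt(rowSums(t1^2))
      t2 <- cbind(xu[, 2] * t1[, 3] - xu[, 3] * t1[, 2],
                  xu[, 3] * t1[, 1] - xu[, 1] * t1[, 3],
                  xu[, 1] * t1[, 2] - xu[, 2] * t1[, 1])
      step <- rnorm(n, 0, sd_step) * t1 + rnorm(n, 0, sd_step) * t2
      xn <- xu + step / R
      xn <- xn / sqrt(rowSums(xn^2))
      pos <- R * xn
    }
    # dissociation
    if (n > 0L) {
      gone <- death <= t
      if (any(gone)) {
        removed_life <- c(removed_life, death[gone] - born[gone])
        pos <- pos[!gone, , drop = FALSE]
        death <- death[!gone]; born <- born[!gone]
      }
    }
    # exocytosis
    while (ev_i <= length(ev_times) && ev_times[ev_i] <= t) {
      if (nrow(pos) > 0L) {
        hit <- sample_hit_site(cand, params$beta, R)
        pos <- .displace_particles(pos, hit, R, exo)
      }
      ev_i <- ev_i + 1L
    }
    if (k %% record_every == 0L) {
      times <- c(times, t)
      counts <- c(counts, nrow(pos))
      mean_dist <- c(mean_dist,
                     if (nrow(pos)) mean(.geo_to_center(pos, R)) else NA_real_)
    }
  }
  structure(list(times = times, counts = counts, mean_dist = mean_dist,
                 positions = pos, lifetimes = removed_life,
                 n_events = ev_i - 1L, params = params),
            class = "particle_trajectory")
}

#' @export
print.particle_trajectory <- function(x, ...) {
  if (!is.null(x$counts))
    cat(sprintf("particle_trajectory: %d particles at end, %d recorded times\n",
                utils::tail(x$counts, 1), length(x$times)))
  else
    cat(sprintf("particle_trajectory: %d iterations, %d particles\n",
                length(x$positions) - 1L, nrow(x$positions[[1]])))
  invisible(x)
}

#' Write particle snapshots as CSV
#'
#' @param traj A `particle_trajectory` from [run_simple_particle_sim()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_particle_csv <- function(traj, file) {
  rows <- do.call(rbind, lapply(seq_along(traj$positions), function(i) {
    p <- traj$positions[[i]]
    data.frame(iteration = i - 1L, particle = seq_len(nrow(p)),
               x = p[, 1], y = p[, 2], z = p[, 3])
  }))
  write.csv(rows, file, row.names = FALSE)
  invisible(file)
}
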