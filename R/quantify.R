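## Quantification of simulation outputs: cluster area, septin ring
## diameter, ring formation time, and log-log scaling exponents.

#' Is a field polarized?
#'
#' A field counts as polarized when its maximum clearly exceeds the mean
#' and its minimum is depleted well below it: `max > 2 mean` and
#' `min < 0.2 mean`. (A ratio test against the maximum alone misclassifies
#' broad flat-topped clusters.)
#'
#' @param field Nodal concentrations.
#' @return Logical.
#' @export
is_polarized <- function(field) {
  m <- mean(field)
  m > 0 && max(field) > 2 * m && min(field) < 0.2 * m
}

#' Cdc42-GTP cluster area of a nodal field
#'
#' A node belongs to the cluster when
#' `|max(field) - field| < threshold * (max(field) - min(field))`.
#' The cluster area is the (unweighted) node fraction times the membrane
#' area; an area-weighted variant is also reported. Connected components of
#' the cluster node set (mesh edge adjacency) flag multi-cluster states.
#'
#' @param field Nodal concentrations (uM); must be polarized
#'   (`max > min`).
#' @param mesh A `surface_mesh`.
#' @param threshold Relative band below the maximum (default 0.2).
#' @return Object of class `cluster_metrics`: `fraction`, `area` (um^2),
#'   `area_weighted` (um^2), `n_clusters`, `nodes`, `max`, `mean`, `min`.
#' @export
cluster_area <- function(field, mesh, threshold = 0.2) {
  if (any(!is.finite(field))) stop("field must be finite", call. = FALSE)
  mx <- max(field); mn <- min(field)
  if (mx <= mn)
    stop("degenerate field: max == min (unpolarized)", call. = FALSE)
  inside <- abs(mx - field) < threshold * (mx - mn)
  fraction <- mean(inside)
  nodes <- which(inside)
  structure(list(
    fraction = fraction,
    area = fraction * mesh$A_m,
    area_weighted = sum(mesh$node_area[nodes]),
    n_clusters = .count_components(mesh, nodes),
    nodes = nodes,
    max = mx, mean = mean(field), min = mn,
    threshold = threshold
  ), class = "cluster_metrics")
}

#' @export
print.cluster_metrics <- function(x, ...) {
  cat(sprintf("cluster_metrics: area = %.4g um^2 (fraction %.4g), %d cluster(s), max = %.4g uM\n",
              x$area, x$fraction, x$n_clusters, x$max))
  invisible(x)
}

# Connected components of a node subset under mesh edge adjacency.
.count_components <- function(mesh, nodes) {
  if (length(nodes) == 0L) return(0L)
  e <- .mesh_edges(mesh)
  keep <- e[e[, 1] %in% nodes & e[, 2] %in% nodes, , drop = FALSE]
  comp <- seq_along(nodes)
  names(comp) <- nodes
  idx <- function(v) match(v, nodes)
  # union-find
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  if (nrow(keep)) for (r in seq_len(nrow(keep))) {
    a <- find(idx(keep[r, 1])); b <- find(idx(keep[r, 2]))
    if (a != b) comp[a] <- b
  }
  length(unique(vapply(seq_along(nodes), find, integer(1))))
}

#' Septin ring point set
#'
#' Filters the polymerised-septin field: nodes with
#' `|max(P) - P| > threshold * max(P)` are discarded; the rest constitute
#' the ring. The node attaining the maximum is always retained.
#'
#' @param P Nodal polymerised-septin concentrations; `max(P) > 0` required.
#' @param threshold Relative band (default 0.2).
#' @return Integer node indices.
#' @export
ring_points <- function(P, threshold = 0.2) {
  mx <- max(P)
  if (mx <= 0) stop("P has no positive maximum", call. = FALSE)
  which(abs(mx - P) <= threshold * mx)
}

#' Septin ring diameter from a point set
#'
#' Fits the ring axis as the mean direction of the points, projects every
#' point onto the plane normal to the axis and computes per-point diameters
#' (twice the in-plane radial distance). Points with radius at or below the
#' median form the inner rim, points at or above form the outer rim; the
#' reported diameter is the mean of the inner-rim mean and outer-rim mean,
#' which equals `2 r` on a perfect circle and `(d_inner + d_outer) / 2` on
#' an ideal annulus.
#'
#' @param points m x 3 matrix of ring coordinates (um), m >= 6.
#' @param axis Optional fixed axis (unit 3-vector); default: mean direction.
#' @return Object of class `ring_metrics`: `diameter` (um), `d_inner`,
#'   `d_outer`, `axis`, per-point diameters `d`.
#' @export
ring_diameter <- function(points, axis = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < 6L)
    stop("need at least 6 ring points", call. = FALSE)
  if (is.null(axis)) {
    axis <- colMeans(points / sqrt(rowSums(points^2)))
    na <- sqrt(sum(axis^2))
    if (!is.finite(na) || na < 1e-6)
      stop("degenerate ring axis: points are not an annular band", call. = FALSE)
    axis <- axis / na
  }
  proj <- as.numeric(points %*% axis)
  inplane <- points - proj %o% axis
  r <- sqrt(rowSums(inplane^2))
  med <- median(r)
  inner <- r <= med + 1e-12
  outer <- r >= med - 1e-12
  d <- 2 * r
  d_inner <- mean(d[inner]); d_outer <- mean(d[outer])
  structure(list(diameter = (d_inner + d_outer) / 2,
                 d_inner = d_inner, d_outer = d_outer,
                 axis = axis, d = d, n = nrow(points)),
            class = "ring_metrics")
}

#' @export
print.ring_metrics <- function(x, ...) {
  cat(sprintf("ring_metrics: diameter = %.4g um (inner %.4g, outer %.4g), n = %d points\n",
              x$diameter, x$d_inner, x$d_outer, x$n))
  invisible(x)
}

#' Ring diameter of a simulated septin field
#'
#' [ring_points()] on the polymerised-septin field, coordinates from the
#' mesh, then [ring_diameter()]. At coarse desk-scale resolutions
#' individual vesicle deliveries leave single-node spikes on top of the
#' ring; `smooth` passes of mass-conservative mesh-scale smoothing (an
#' implicit diffusion solve with length scale of one mesh spacing) are
#' applied first so the band filter sees the ring crest rather than the
#' most recent delivery. `smooth = 0` reproduces the raw filter.
#'
#' @param P Nodal polymerised-septin field.
#' @param mesh A `surface_mesh`.
#' @param threshold Relative band (default 0.2).
#' @param smooth Number of smoothing passes (default 4, about two mesh
#'   spacings of smoothing length).
#' @return A `ring_metrics` object.
#' @export
ring_diameter_field <- function(P, mesh, threshold = 0.2, smooth = 4L) {
  P <- smooth_field(P, mesh, passes = smooth)
  idx <- ring_points(P, threshold)
  ring_diameter(mesh$nodes[idx, , drop = FALSE])
}

#' Mass-conservative mesh-scale smoothing of a nodal field
#'
#' Each pass solves `(M + tau K) u = M u0` with `tau = A_m / N` (smoothing
#' length of about one mesh spacing); the surface integral is preserved.
#'
#' @param field Nodal values.
#' @param mesh A `surface_mesh`.
#' @param passes Number of passes (0 returns the field unchanged).
#' @return Smoothed nodal values.
#' @export
smooth_field <- function(field, mesh, passes = 1L) {
  if (passes < 1L) return(field)
  ops <- assemble_surface_operators(mesh)
  tau <- mesh$A_m / mesh$n_nodes
  U <- matrix(field, ncol = 1)
  for (k in seq_len(passes))
    U <- .diffusion_solve(ops, 1, tau, U, 1e-9)
  as.numeric(U)
}

#' Ring formation time from a Cdc42-GTP trace
#'
#' Upon septin recruitment the maximal Cdc42-GTP concentration first dips
#' and then recovers; the time at which it first exceeds its initial value
#' is the ring-formation-speed metric.
#'
#' @param t Times (s), starting at the septin-module start (t\[1\] = 0).
#' @param value Max-node Cdc42-GTP concentrations at `t`.
#' @param margin Relative excess over the initial value required to count
#'   as a crossing (filters numerical noise on flat starts; default 0.1
#'   percent).
#' @return First `t > 0` at or after the trace minimum with
#'   `value > value[1] * (1 + margin)`, or `NA_real_` when the trace never
#'   exceeds its initial value ("not formed"). Requiring the crossing to
#'   follow the minimum makes the metric insensitive to sub-margin drift
#'   before septin suppression sets in; for a monotone increasing trace
#'   the minimum is the first sample, so the first sample is returned.
#' @export
ring_formation_time <- function(t, value, margin = 1e-3) {
  if (length(t) != length(value) || length(t) < 2L)
    stop("need matching t/value vectors of length >= 2", call. = FALSE)
  dip <- which.min(value)
  idx <- which(value > value[1] * (1 + margin) & t > 0 &
                 seq_along(t) >= dip)
  if (!length(idx)) return(NA_real_)
  t[idx[1]]
}

#' Log-log scaling exponent
#'
#' Ordinary least squares of `log(metric)` on `log(volume)`: the fitted
#' slope is the allometric scaling exponent, reported with its standard
#' error, the two-sided t-test p-value of the slope, and R^2.
#'
#' @param volumes Cell volumes (fL), positive, length >= 3.
#' @param metrics Measured quantities (e.g. cluster areas, um^2), positive.
#' @return Object of class `scaling_result`: `slope`, `se`, `p_value`,
#'   `r_squared`, `n`, `fit` (the `lm` object), `data`.
#' @export
fit_loglog_slope <- function(volumes, metrics) {
  ok <- is.finite(volumes) & is.finite(metrics)
  volumes <- volumes[ok]; metrics <- metrics[ok]
  if (length(volumes) < 3L) stop("need n >= 3 for a fit", call. = FALSE)
  if (any(volumes <= 0) || any(metrics <= 0))
    stop("volumes and metrics must be positive", call. = FALSE)
  if (length(unique(volumes)) < 2L)
    stop("slope undefined: a single repeated volume was supplied", call. = FALSE)
  fit <- lm(log(metrics) ~ log(volumes))
  sm <- summary(fit)
  structure(list(slope = unname(coef(fit)[2]),
                 se = unname(sm$coefficients[2, 2]),
                 p_value = unname(sm$coefficients[2, 4]),
                 r_squared = sm$r.squared,
                 n = length(volumes),
                 fit = fit,
                 data = data.frame(volume = volumes, metric = metrics)),
            class = "scaling_result")
}

#' @export
print.scaling_result <- function(x, ...) {
  cat(sprintf("scaling_result: slope = %.4g +/- %.4g (p = %.3g, R^2 = %.3f, n = %d)\n",
              x$slope, x$se, x$p_value, x$r_squared, x$n))
  invisible(x)
}
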