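# Shared fixtures: small meshes are expensive enough to build once.

mesh_cache <- new.env()

get_mesh <- function(R = 2.5, nodes = 642) {
  key <- sprintf("%g_%d", R, nodes)
  if (is.null(mesh_cache[[key]]))
    mesh_cache[[key]] <- build_sphere_mesh(R, nodes)
  mesh_cache[[key]]
}

# Gaussian cap field centred on +z: exp(-(s/width)^2) scaled.
gaussian_cap_field <- function(mesh, width = 0.5, amplitude = 100,
                               floor = 1) {
  s <- acos(pmin(1, pmax(-1, mesh$nodes[, 3] / mesh$R))) * mesh$R
  floor + amplitude * exp(-(s / width)^2)
}

# Homogeneous membrane state for a model at given uniform values.
uniform_state <- function(model, values, cyto, N = 10L) {
  F <- matrix(rep(values, each = N), N,
              dimnames = list(NULL, model$species))
  membrane_state(F, cyto)
}

# Trivial quadrature consistent with an N-node uniform state.
unit_mesh <- function(N = 10L) list(node_area = rep(1 / N, N), A_m = 1)

# Shared septin-model polarization checkpoint (expensive; reused across
# the acceptance blocks).
checkpoint_cache <- new.env()

get_checkpoint <- function(gap_factor = 1) {
  key <- sprintf("gf_%g", gap_factor)
  if (is.null(checkpoint_cache[[key]]))
    checkpoint_cache[[key]] <- septin_checkpoint(
      septin_params(gap_factor = gap_factor), volume = 33,
      target_nodes = 642, seed = 1, t_end = 1500)
  checkpoint_cache[[key]]
}

expect_rel_equal <- function(actual, expected, tol = 1e-6) {
  expect_lt(abs(actual - expected) / max(abs(expected), 1e-300), tol)
}
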