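## Parameter sets for the model families, with published kinetic constants as
## defaults. Units: first-order rates s^-1, second-order rates uM^-1 s^-1,
## diffusion um^2/s, concentrations uM (cytosol-equivalent for totals).

.check_nonneg <- function(p, fields) {
  bad <- fields[vapply(fields, function(f) !is.finite(p[[f]]) || p[[f]] < 0, logical(1))]
  if (length(bad))
    stop("negative or non-finite rate(s): ", paste(bad, collapse = ", "), call. = FALSE)
}

#' Parameters of the positive-feedback polarization model
#'
#' The Cdc42 GTPase cycle with scaffold-mediated positive feedback: Cdc42-GTP
#' recruits its own activator (the Bem1-Cdc24 GEF complex). Kinetic constants
#' default to the published reaction table for this model family. The total
#' concentrations (cytosol-equivalent) are calibration choices of this
#' package, set to the magnitudes used by the source models of this family;
#' see the methods vignette.
#'
#' @param k1a,k1b BemGEF cytosol/membrane exchange (s^-1).
#' @param k2a GEF-catalysed Cdc42 activation (uM^-1 s^-1).
#' @param k2b Basal Cdc42-GTP hydrolysis, includes GAP background (s^-1).
#' @param k3 BemGEF42-catalysed activation (uM^-1 s^-1).
#' @param k4a,k4b BemGEFm + Cdc42T complex association/dissociation.
#' @param k5a,k5b GDI-mediated Cdc42 membrane on/off rates (s^-1).
#' @param k7 Direct BemGEFc + Cdc42T association (uM^-1 s^-1).
#' @param Dm Membrane diffusion coefficient (um^2/s). The published
#'   reaction tables of this family do not print it; the default is the
#'   source model's value, which also reproduces the published pole
#'   concentration (see the methods vignette).
#' @param Cdc42_tot,BemGEF_tot Total pools, cytosol-equivalent uM.
#' @param gap_factor Multiplier on `k2b` emulating altered GAP activity
#'   (default 1).
#' @return Object of class `c("positive_feedback_params", "septring_params")`.
#' @export
positive_feedback_params <- function(k1a = 10, k1b = 10, k2a = 0.16, k2b = 0.35,
                                     k3 = 0.35, k4a = 10, k4b = 10,
                                     k5a = 36, k5b = 0.65, k7 = 10,
                                     Dm = 0.036,
                                     Cdc42_tot = 5, BemGEF_tot = 0.017,
                                     gap_factor = 1) {
  p <- list(k1a = k1a, k1b = k1b, k2a = k2a, k2b = k2b * gap_factor, k3 = k3,
            k4a = k4a, k4b = k4b, k5a = k5a, k5b = k5b, k7 = k7, Dm = Dm,
            Cdc42_tot = Cdc42_tot, BemGEF_tot = BemGEF_tot)
  .check_nonneg(p, names(p))
  if (Cdc42_tot <= 0 || BemGEF_tot <= 0) stop("totals must be positive", call. = FALSE)
  structure(p, class = c("positive_feedback_params", "septring_params"))
}

#' Parameters of the negative-feedback polarization model
#'
#' Extends [positive_feedback_params()] with a delayed negative feedback:
#' at high BemGEF42 activity the complex autophosphorylates (Hill-gated rate
#' `k8`), the phosphorylated scaffold cannot activate Cdc42, and
#' dephosphorylation (`k9`) occurs only in the cytosol.
#'
#' @inheritParams positive_feedback_params
#' @param k8max,k8h,k8n Maximal rate (s^-1), half-activation (uM) and Hill
#'   exponent of the phosphorylation gate.
#' @param k9max,k9h,k9n Same for the cytosolic dephosphorylation gate. The
#'   default exponent 10.003 is loaded verbatim from the published table.
#' @param ... Passed to [positive_feedback_params()].
#' @return Object of class `c("negative_feedback_params", "septring_params")`.
#' @export
negative_feedback_params <- function(k8max = 0.0063, k8h = 6, k8n = 10,
                                     k9max = 0.0044, k9h = 6, k9n = 10.003,
                                     ...) {
  base <- positive_feedback_params(...)
  p <- c(unclass(base),
         list(k8max = k8max, k8h = k8h, k8n = k8n,
              k9max = k9max, k9h = k9h, k9n = k9n))
  if (k8n <= 0 || k9n <= 0) stop("Hill exponents must be positive", call. = FALSE)
  .check_nonneg(p, c("k8max", "k8h", "k9max", "k9h"))
  structure(p, class = c("negative_feedback_params", "septring_params"))
}

#' Parameters of the alternative positive-feedback model
#'
#' A minimal three-species Cdc42 cycle in which the positive feedback is
#' collapsed into a single third-order reaction, cytosolic diffusion is finite
#' and the cytosol is part of the geometry. Membrane recruitment saturates at
#' a maximal packing `kmax` per node.
#'
#' @param k1 Bulk-to-membrane attachment (uM^-1 s^-1, paired with `kmax`).
#' @param kmax Membrane saturation level (uM).
#' @param km1 Membrane detachment of Cdc42D (s^-1).
#' @param k2,km2 Activation / deactivation (s^-1).
#' @param k3 Cooperative feedback (uM^-2 s^-1).
#' @param DT,DD Membrane diffusion of Cdc42T / Cdc42D (um^2/s).
#' @param DI Cytosolic (bulk) diffusion (um^2/s).
#' @param Cdc42_tot Total Cdc42, bulk-equivalent uM (calibration choice).
#' @return Object of class `c("alt_model_params", "septring_params")`.
#' @export
alt_model_params <- function(k1 = 0.28, kmax = 2.54, km1 = 0.133,
                             k2 = 0.001368, km2 = 0.028, k3 = 1,
                             DT = 0.011, DD = 1.21, DI = 10,
                             Cdc42_tot = 1.0) {
  p <- list(k1 = k1, kmax = kmax, km1 = km1, k2 = k2, km2 = km2, k3 = k3,
            DT = DT, DD = DD, DI = DI, Cdc42_tot = Cdc42_tot)
  .check_nonneg(p, names(p))
  structure(p, class = c("alt_model_params", "septring_params"))
}

#' Parameters of the septin ring models (SBE / SBER)
#'
#' The septin module couples the Cdc42 polarization cycle (with a
#' pole-hardened parameterisation: faster hydrolysis and GDI cycling than the
#' cluster-scaling variant) to Axl2-mediated septin recruitment, septin
#' polymerisation, septin-recruited GAPs, and - in SBER mode - a
#' vesicle-delivered septin recruiter X. `SPR` (septin / polarity-factor
#' binding rate) aliases `k19`; `PSR` (polarity-factor septin recruitment
#' rate) aliases `k20`.
#'
#' Total pool concentrations are calibration choices of this package (see
#' methods vignette); the kinetic constants default to the published table.
#'
#' @param k1a,k1b,k2a,k2b,k3,k4a,k4b,k5a,k5b,k7 Cdc42 cycle constants.
#' @param k12a,k12b GapS recruitment by polymerised septin / release.
#' @param k13 GapS-catalysed Cdc42T hydrolysis (uM^-1 s^-1).
#' @param k15 Axl2S complex release: Axl2S -> Axl2 + S (s^-1).
#' @param k16,k17,k18 Septin polymerisation (S+S -> 2P, S+P -> 2P) and
#'   depolymerisation (P -> S).
#' @param k19 SPR: membrane septin binding to Axl2 (Axl2 + S -> Axl2S).
#' @param k20 PSR: cytosolic septin recruitment by Axl2 (Axl2 + Sc -> Axl2S).
#' @param k21 Septin membrane detachment S -> Sc (s^-1).
#' @param k22 Axl2 (and Axl2S) membrane detachment (s^-1).
#' @param k23 Axl2 recruitment by BemGEF42 (uM^-1 s^-1).
#' @param k24 Decay of the vesicle-delivered recruiter X (s^-1).
#' @param k25 X-catalysed septin recruitment (uM^-1 s^-1).
#' @param Dm Membrane diffusion (um^2/s) of monomeric species.
#' @param Dp Membrane diffusion of P and X (um^2/s).
#' @param Cdc42_tot,BemGEF_tot,GapS_tot,Axl2_tot,Septin_tot Total pools
#'   (cytosol-equivalent uM).
#' @param SPR,PSR Optional aliases overriding `k19` / `k20`.
#' @param gap_factor Multiplier on `k2b` (reduced-GAP perturbations).
#' @return Object of class `c("septin_params", "septring_params")`.
#' @export
septin_params <- function(k1a = 10, k1b = 10, k2a = 0.16, k2b = 0.63,
                          k3 = 0.35, k4a = 10, k4b = 10,
                          k5a = 144, k5b = 20.8, k7 = 10,
                          k12a = 10, k12b = 10, k13 = 1.5,
                          k15 = 1.0, k16 = 0.05, k17 = 0.125, k18 = 0.1,
                          k19 = 4.5, k20 = 0.2, k21 = 0.65, k22 = 10.5,
                          k23 = 26, k24 = 0.1, k25 = 5.5,
                          Dm = 0.036, Dp = 0.00025,
                          Cdc42_tot = 5, BemGEF_tot = 0.017,
                          GapS_tot = 0.2, Axl2_tot = 0.2, Septin_tot = 5.0,
                          SPR = NULL, PSR = NULL, gap_factor = 1) {
  if (!is.null(SPR)) k19 <- SPR
  if (!is.null(PSR)) k20 <- PSR
  p <- list(k1a = k1a, k1b = k1b, k2a = k2a, k2b = k2b * gap_factor, k3 = k3,
            k4a = k4a, k4b = k4b, k5a = k5a, k5b = k5b, k7 = k7,
            k12a = k12a, k12b = k12b, k13 = k13, k15 = k15, k16 = k16,
            k17 = k17, k18 = k18, k19 = k19, k20 = k20, k21 = k21,
            k22 = k22, k23 = k23, k24 = k24, k25 = k25,
            Dm = Dm, Dp = Dp,
            Cdc42_tot = Cdc42_tot, BemGEF_tot = BemGEF_tot,
            GapS_tot = GapS_tot, Axl2_tot = Axl2_tot, Septin_tot = Septin_tot)
  .check_nonneg(p, names(p))
  structure(p, class = c("septin_params", "septring_params"))
}

#' Exocytosis parameters
#'
#' @param r_exo Vesicle radius (um; default 0.05 = 50 nm).
#' @param alpha Mobile (fluid) membrane fraction, in (0, 1].
#' @param gamma Ratio of lipid to protein velocity, in (0, 1].
#' @param rate Exocytosis event rate lambda (events/s).
#' @param epsilon Hit-region threshold: nodes with
#'   `Cdc42T > epsilon * max(Cdc42T)` are eligible. Smaller `epsilon` means
#'   more diffused exocytosis.
#' @param deliver_Cdc42D Cdc42-GDP concentration delivered by a vesicle (uM).
#' @param deliver_X Concentration of the septin recruiter X delivered (uM;
#'   used in SBER mode only).
#' @return Object of class `exo_params`.
#' @export
exo_params <- function(r_exo = 0.05, alpha = 0.5, gamma = 1.0, rate = 0.4,
                       epsilon = 0.5, deliver_Cdc42D = 100, deliver_X = 20) {
  if (alpha <= 0 || alpha > 1) stop("`alpha` must be in (0, 1]", call. = FALSE)
  if (gamma <= 0 || gamma > 1) stop("`gamma` must be in (0, 1]", call. = FALSE)
  if (rate < 0) stop("`rate` must be >= 0", call. = FALSE)
  if (epsilon <= 0 || epsilon > 1) stop("`epsilon` must be in (0, 1]", call. = FALSE)
  structure(
    list(r_exo = r_exo, A_exo = 4 * pi * r_exo^2, alpha = alpha, gamma = gamma,
         rate = rate, epsilon = epsilon,
         deliver_Cdc42D = deliver_Cdc42D, deliver_X = deliver_X),
    class = "exo_params"
  )
}

#' Particle simulator parameters
#'
#' @param R Sphere radius (um).
#' @param r_exo Vesicle radius (um).
#' @param Omega Pole fraction of the sphere surface, in (0, 1).
#' @param alpha,gamma Displacement-map hydrodynamic parameters.
#' @param beta Hit-site concentration exponent; small values spread
#'   exocytosis across the pole, large values focus it at the centre.
#' @param k_rec Recruitment rate into the pole (particles/s, complex model).
#' @param k_off Membrane dissociation rate (s^-1, complex model).
#' @param Dm Particle surface diffusion coefficient (um^2/s).
#' @param dt Time step for the tau-leaping / diffusion loop (s).
#' @param n_init Initial particle count (simple model).
#' @param n_candidates Number of pre-generated candidate hit sites.
#' @return Object of class `particle_params`.
#' @export
particle_params <- function(R = 2.5, r_exo = 0.05, Omega = 0.03,
                            alpha = 0.5, gamma = 1.0, beta = 1.0,
                            k_rec = 60, k_off = 0.5, Dm = 0.0045,
                            dt = 0.01, n_init = 1000, n_candidates = 10000) {
  if (Omega <= 0 || Omega >= 1) stop("`Omega` must be in (0, 1)", call. = FALSE)
  if (any(c(k_rec, k_off, Dm, dt) < 0)) stop("rates must be >= 0", call. = FALSE)
  structure(
    list(R = R, r_exo = r_exo, A_exo = 4 * pi * r_exo^2, Omega = Omega,
         alpha = alpha, gamma = gamma, beta = beta, k_rec = k_rec,
         k_off = k_off, Dm = Dm, dt = dt, n_init = n_init,
         n_candidates = n_candidates),
    class = "particle_params"
  )
}

#' Protein-slope scaling configuration
#'
#' The protein slope is the slope of log concentration versus log cell
#' volume: slope 0 keeps concentrations constant (amounts scale linearly
#' with volume); slope -1 keeps amounts constant (concentration dilutes as
#' 1/V). GAP activity is never rescaled.
#'
#' @param protein_slope Dimensionless slope (typically in `[-1, 0]`).
#' @param V0 Reference volume (fL) at which the tabulated concentrations
#'   apply (default 65, the smallest simulated volume).
#' @param species Character vector of total-pool names to rescale.
#' @return Object of class `scaling_config`.
#' @export
scaling_config <- function(protein_slope = 0, V0 = 65,
                           species = c("Cdc42_tot", "BemGEF_tot")) {
  if (V0 <= 0) stop("`V0` must be positive", call. = FALSE)
  if (protein_slope < -1 || protein_slope > 0)
    warning("protein slope outside [-1, 0]; proceeding", call. = FALSE)
  structure(list(protein_slope = protein_slope, V0 = V0, species = species),
            class = "scaling_config")
}

#' Rescale total protein amounts with cell volume
#'
#' Applies `c(V) = c(V0) * (V / V0)^slope` to the totals named in the
#' scaling configuration; all other entries (in particular GAP-related
#' rates and pools) are unchanged.
#'
#' @param params A `septring_params` object.
#' @param V Cell volume (fL).
#' @param config A [scaling_config()].
#' @return Parameters with rescaled totals.
#' @examples
#' p <- scale_amounts_with_volume(positive_feedback_params(), 270,
#'                                scaling_config(protein_slope = -0.44))
#' @export
scale_amounts_with_volume <- function(params, V, config = scaling_config()) {
  if (V <= 0) stop("`V` must be positive", call. = FALSE)
  fac <- (V / config$V0)^config$protein_slope
  for (sp in config$species) {
    if (!is.null(params[[sp]])) params[[sp]] <- params[[sp]] * fac
  }
  params
}

#' Read / write parameter sets as JSON
#'
#' Parameter sets serialise to a JSON object with a `model` tag so that
#' experiment configurations are plain text files.
#'
#' @param params A `septring_params` object.
#' @param file Path.
#' @return `write_params`: `file` invisibly. `read_params`: the parameter
#'   object.
#' @export
write_params <- function(params, file) {
  model <- class(params)[1]
  jsonlite::write_json(c(list(model = model), unclass(params)), file,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

#' @rdname write_params
#' @export
read_params <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  model <- x$model
  x$model <- NULL
  ctor <- switch(model,
    positive_feedback_params = positive_feedback_params,
    negative_feedback_params = negative_feedback_params,
    alt_model_params = alt_model_params,
    septin_params = septin_params,
    stop("unknown model tag: ", model, call. = FALSE))
  args <- x[names(x) %in% names(formals(ctor))]
  # derived / stored fields not in the constructor signature are reapplied
  p <- do.call(ctor, args)
  for (nm in setdiff(names(x), names(p))) p[[nm]] <- x[[nm]]
  p
}
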