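## estimators: the binding-free-energy estimator family built on decomposed
## end-state terms, and the two-valued interior-dielectric rescaling.
##
## All regimes are affine in their coefficients -- the property the fitting
## module exploits -- and every score decomposes exactly into gas-phase,
## polar-solvation, nonpolar-solvation and entropy-surrogate contributions.

REGIMES <- c("sasa_only", "sav_only", "sav_disp", "spt",
             "pbsa_e", "pbsa_ex",
             "ani_one_term", "ani_sav_disp", "ani_spt", "ani_pbsae")

REGIME_COEFS <- list(
  sasa_only    = c("gamma", "b"),
  sav_only     = c("gamma", "b"),
  sav_disp     = c("gamma", "b"),
  spt          = c("gamma", "p", "b"),
  pbsa_e       = c("a1", "a2", "a3", "a4", "gamma"),
  pbsa_ex      = c("a1", "a2", "a3", "a4", "a5"),
  ani_one_term = c("a", "gamma", "b"),
  ani_sav_disp = c("a", "gamma", "b"),
  ani_spt      = c("a", "gamma", "p", "b"),
  ani_pbsae    = c("a1", "a2", "a3", "a4")
)

#' Estimator model specification
#'
#' Bundles an estimator regime with its coefficient vector. Regimes:
#' `sasa_only`/`sav_only` (one-term nonpolar model `gamma*x + b` on the area
#' or volume difference), `sav_disp` (two-term cavity-dispersion model, the
#' dispersion coefficient fixed at 1), `spt` (scaled-particle-theory model
#' using both area and volume), `pbsa_e` (empirical rescoring with a shared
#' electrostatic coefficient and a rotatable-bond entropy surrogate),
#' `pbsa_ex` (its fully empirical five-coefficient extension), and the
#' `ani_*` analogues in which a scaled single-point interaction energy
#' `a * dE_sp` replaces the molecular-mechanics gas-phase terms.
#'
#' @param regime One of the regimes above.
#' @param coefficients Named numeric vector; required names depend on the
#'   regime (`gamma` kcal/mol/A^2, `p` kcal/mol/A^3, `b` kcal/mol, `a`
#'   dimensionless, `a1..a5` dimensionless empirical weights).
#' @param geometry_source Metadata: `"amber_style"` when dSASA/dSAV come from
#'   the usual solvent-accessible surface machinery, `"mc_style"` when the
#'   Monte-Carlo ASA/PCAV (or ASA/POAV) values are fed into the same columns.
#' @param term_map Optional named character vector re-mapping the empirical
#'   coefficients of `pbsa_e`/`ani_pbsae` onto terms, absorbing the ambiguity
#'   of their published layout. Term keys: `dE_vdW`, `dE_ele`, `dG_PB`,
#'   `polar_shared` (electrostatic + polar solvation, dielectric-scaled),
#'   `gamma_dSASA`, `dSASA`, `dSAV`, `N_rot`, `dE_sp`.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(regime, coefficients,
                       geometry_source = c("amber_style", "mc_style"),
                       term_map = NULL) {
  regime <- match.arg(regime, REGIMES)
  geometry_source <- match.arg(geometry_source)
  need <- REGIME_COEFS[[regime]]
  miss <- setdiff(need, names(coefficients))
  if (length(miss) > 0) {
    mmp_stop("mmpbsar_config_error",
             "regime '%s' requires coefficient(s): %s", regime,
             paste(miss, collapse = ", "))
  }
  if (any(!is.finite(coefficients[need]))) {
    mmp_stop("mmpbsar_config_error", "coefficients must be finite")
  }
  if (is.null(term_map)) {
    term_map <- switch(regime,
      pbsa_e = c(a1 = "dE_vdW", a2 = "polar_shared", a3 = "gamma_dSASA",
                 a4 = "N_rot"),
      ani_pbsae = c(a1 = "dE_sp", a2 = "dG_PB", a3 = "dSASA", a4 = "dSAV"),
      NULL)
  }
  structure(list(regime = regime,
                 coefficients = coefficients[need],
                 geometry_source = geometry_source,
                 term_map = term_map),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model_spec: regime '%s' (%s geometry)\n", x$regime,
              x$geometry_source))
  cat("  coefficients:",
      paste(sprintf("%s = %g", names(x$coefficients), x$coefficients),
            collapse = ", "), "\n")
  invisible(x)
}

## published coefficient presets (one-term defaults from the standard PB/GB
## parameterisations; the fitted columns from the 54-complex study)
PRESETS <- list(
  `one-term-classic` = list(regime = "sasa_only",
                            coefficients = c(gamma = 0.00542, b = 0.92)),
  `one-term-gb`      = list(regime = "sasa_only",
                            coefficients = c(gamma = 0.005, b = 0)),
  `one-term-pb`      = list(regime = "sasa_only",
                            coefficients = c(gamma = 0.0072, b = 0)),
  `sav-disp-amber`   = list(regime = "sav_disp",
                            coefficients = c(gamma = 0.0378, b = -0.5692)),
  `pbsae-original`   = list(regime = "pbsa_e",
                            coefficients = c(a1 = 0.03037, a2 = 0.07791,
                                             a3 = 1.2193, a4 = 0.1854,
                                             gamma = 0.0072)),
  `sasa-fit-a`       = list(regime = "sasa_only",
                            coefficients = c(gamma = 0.0836, b = 0)),
  `spt-fit-a`        = list(regime = "spt",
                            coefficients = c(gamma = 0.1394, p = 0.0163,
                                             b = 0))
)

#' Bundled coefficient presets
#'
#' @param name Preset name; `model_preset()` with no argument lists them.
#' @return A [model_spec()] (or a character vector of preset names).
#' @export
model_preset <- function(name = NULL) {
  if (is.null(name)) return(names(PRESETS))
  if (!name %in% names(PRESETS)) {
    mmp_stop("mmpbsar_config_error", "unknown preset '%s' (available: %s)",
             name, paste(names(PRESETS), collapse = ", "))
  }
  p <- PRESETS[[name]]
  model_spec(p$regime, p$coefficients)
}

#' One-term nonpolar solvation model
#'
#' `gamma * x + b`, the empirical surface-tension form applied to a surface
#' area (Angstrom^2) or volume (Angstrom^3) difference.
#'
#' @param x Area or volume (difference) value.
#' @param gamma Surface-tension (or pressure) coefficient.
#' @param b Correction offset, kcal/mol.
#' @return kcal/mol.
#' @export
gnp_one_term <- function(x, gamma, b) {
  stopifnot(is.finite(gamma), is.finite(b))
  gamma * x + b
}

#' Scaled-particle-theory nonpolar model
#'
#' `gamma * area + p * volume + b`; using both the area and volume captures
#' the crossover between volume-dominated (small cavity) and area-dominated
#' (large cavity) repulsive solvation. Reduces to [gnp_one_term()] when
#' either coefficient is zero.
#'
#' @param area,volume Area (A^2) and volume (A^3) differences.
#' @param gamma,p,b Surface, pressure and offset coefficients.
#' @return kcal/mol.
#' @export
gnp_spt <- function(area, volume, gamma, p, b) {
  stopifnot(is.finite(gamma), is.finite(p), is.finite(b))
  gamma * area + p * volume + b
}

#' Two-term (cavity + dispersion) nonpolar model
#'
#' `(gamma * volume + b) + e_disp`: a repulsive cavity term plus an
#' attractive dispersion energy whose coefficient is fixed at 1. When the
#' dispersion energy is an exactly linear function of the volume this model
#' collapses onto [gnp_spt()] with transformed coefficients.
#'
#' @param volume Volume difference (A^3).
#' @param e_disp Dispersion energy difference (kcal/mol).
#' @param gamma,b Cavity coefficients.
#' @return kcal/mol.
#' @export
gnp_two_term <- function(volume, e_disp, gamma, b) {
  stopifnot(is.finite(gamma), is.finite(b))
  (gamma * volume + b) + e_disp
}

#' Two-valued interior dielectric pair
#'
#' The interior (solute) dielectric constant enters the estimators twice:
#' in the protein-ligand Coulombic term and in the polar-solvation term.
#' The two-valued scheme decouples them: `eps_ele` divides `dE_ele` and
#' `eps_pb` divides `dG_PB`. `(1, 1)` is the identity; a single-valued
#' interior dielectric is the diagonal `eps_ele == eps_pb`.
#'
#' @param eps_ele,eps_pb Dielectric constants, both >= 1.
#' @return An object of class `dielectric_pair`.
#' @export
dielectric_pair <- function(eps_ele = 1, eps_pb = 1) {
  if (!is.finite(eps_ele) || !is.finite(eps_pb) ||
      eps_ele < 1 || eps_pb < 1) {
    mmp_stop("mmpbsar_domain_error",
             "dielectric constants must be finite and >= 1")
  }
  structure(list(eps_ele = eps_ele, eps_pb = eps_pb),
            class = "dielectric_pair")
}

#' Rescale delta terms to a new interior dielectric
#'
#' Algebraic shortcut for terms computed at an interior dielectric of 1:
#' the Coulombic difference is divided by `eps_ele` and the polar-solvation
#' difference by `eps_pb`; all other terms are unchanged. This reproduces a
#' dielectric change without re-solving the Poisson-Boltzmann equation and
#' is exact for the Coulombic term, an approximation for the PB term.
#'
#' @param delta A `delta_terms` table computed at interior dielectric 1.
#' @param pair A [dielectric_pair()].
#' @return The rescaled `delta_terms` table.
#' @export
rescale_dielectric <- function(delta, pair) {
  stopifnot(inherits(pair, "dielectric_pair"))
  delta$dE_ele <- delta$dE_ele / pair$eps_ele
  delta$dG_PB <- delta$dG_PB / pair$eps_pb
  delta
}

## term values used by the configurable empirical mappings; dielectric
## scaling is already applied where the term is electrostatic
empirical_term_value <- function(key, delta, pair, gamma) {
  switch(key,
    dE_vdW = delta$dE_vdW,
    dE_ele = delta$dE_ele / pair$eps_ele,
    dG_PB = delta$dG_PB / pair$eps_pb,
    polar_shared = delta$dE_ele / pair$eps_ele + delta$dG_PB / pair$eps_pb,
    gamma_dSASA = gamma * delta$dSASA,
    dSASA = delta$dSASA,
    dSAV = delta$dSAV,
    N_rot = delta$N_rot,
    dE_sp = delta$dE_sp,
    mmp_stop("mmpbsar_config_error", "unknown term key '%s' in term_map", key)
  )
}

## contribution bucket for an empirical term key
empirical_term_bucket <- function(key) {
  switch(key,
    dE_vdW = "gas", dE_ele = "gas", dE_sp = "gas",
    dG_PB = "polar",
    gamma_dSASA = "nonpolar", dSASA = "nonpolar", dSAV = "nonpolar",
    N_rot = "entropy",
    polar_shared = "mixed")
}

require_terms <- function(delta, cols, regime) {
  for (cn in cols) {
    if (is.null(delta[[cn]]) || anyNA(delta[[cn]])) {
      mmp_stop("mmpbsar_config_error",
               "regime '%s' requires term '%s' (missing or NA)", regime, cn)
    }
  }
}

#' Score complexes with an estimator model
#'
#' Applies the regime formula to each complex's delta terms at the given
#' interior-dielectric pair. The per-complex score decomposes exactly into
#' gas-phase (`contrib_gas`: vdW + Coulombic, or the scaled single-point
#' interaction energy), polar solvation (`contrib_polar`), nonpolar
#' solvation (`contrib_nonpolar`) and entropy surrogate (`contrib_entropy`)
#' contributions, and `dG_pred` equals their sum to machine precision.
#' Conformational entropy beyond the rotatable-bond surrogate of the
#' empirical regimes is set to zero.
#'
#' @param delta A `delta_terms` table ([average_deltas()], [delta_terms()]);
#'   terms must have been computed at interior dielectric 1.
#' @param model A [model_spec()] or preset name.
#' @param pair A [dielectric_pair()].
#' @return data.frame of class `scored_complexes`.
#' @export
score <- function(delta, model, pair = dielectric_pair(1, 1)) {
  if (is.character(model)) model <- model_preset(model)
  stopifnot(inherits(model, "model_spec"), inherits(pair, "dielectric_pair"))
  cf <- as.list(model$coefficients)
  rg <- model$regime
  n <- nrow(delta)
  gas <- polar <- np <- ent <- rep(0, n)

  mm_gas <- function() delta$dE_vdW + delta$dE_ele / pair$eps_ele
  pb <- function() delta$dG_PB / pair$eps_pb

  if (rg %in% c("sasa_only", "sav_only", "sav_disp", "spt")) {
    require_terms(delta, c("dE_vdW", "dE_ele", "dG_PB"), rg)
    gas <- mm_gas(); polar <- pb()
    np <- switch(rg,
      sasa_only = { require_terms(delta, "dSASA", rg)
                    gnp_one_term(delta$dSASA, cf$gamma, cf$b) },
      sav_only  = { require_terms(delta, "dSAV", rg)
                    gnp_one_term(delta$dSAV, cf$gamma, cf$b) },
      sav_disp  = { require_terms(delta, c("dSAV", "dE_disp"), rg)
                    gnp_two_term(delta$dSAV, delta$dE_disp, cf$gamma, cf$b) },
      spt       = { require_terms(delta, c("dSASA", "dSAV"), rg)
                    gnp_spt(delta$dSASA, delta$dSAV, cf$gamma, cf$p, cf$b) })
  } else if (rg %in% c("ani_one_term", "ani_sav_disp", "ani_spt")) {
    require_terms(delta, c("dE_sp", "dG_PB"), rg)
    gas <- cf$a * delta$dE_sp; polar <- pb()
    np <- switch(rg,
      ani_one_term = { require_terms(delta, "dSASA", rg)
                       gnp_one_term(delta$dSASA, cf$gamma, cf$b) },
      ani_sav_disp = { require_terms(delta, c("dSAV", "dE_disp"), rg)
                       gnp_two_term(delta$dSAV, delta$dE_disp,
                                    cf$gamma, cf$b) },
      ani_spt      = { require_terms(delta, c("dSASA", "dSAV"), rg)
                       gnp_spt(delta$dSASA, delta$dSAV,
                               cf$gamma, cf$p, cf$b) })
  } else {
    ## empirical regimes, configurable coefficient-to-term mapping
    tm <- model$term_map
    if (rg == "pbsa_ex") {
      tm <- c(a1 = "dE_vdW", a2 = "dE_ele", a3 = "dG_PB",
              a4 = "dSASA", a5 = "dSAV")
    }
    needed <- unique(unlist(lapply(unname(tm), function(k) switch(k,
      polar_shared = c("dE_ele", "dG_PB"),
      gamma_dSASA = "dSASA",
      dE_ele = "dE_ele", dG_PB = "dG_PB", dE_vdW = "dE_vdW",
      dSASA = "dSASA", dSAV = "dSAV", dE_sp = "dE_sp", N_rot = "N_rot"))))
    require_terms(delta, needed, rg)
    for (an in names(tm)) {
      key <- tm[[an]]
      val <- cf[[an]] * empirical_term_value(key, delta, pair, cf$gamma)
      bucket <- empirical_term_bucket(key)
      if (bucket == "mixed") {
        gas <- gas + cf[[an]] * delta$dE_ele / pair$eps_ele
        polar <- polar + cf[[an]] * delta$dG_PB / pair$eps_pb
      } else {
        switch(bucket,
               gas = gas <- gas + val,
               polar = polar <- polar + val,
               nonpolar = np <- np + val,
               entropy = ent <- ent + val)
      }
    }
  }
  out <- data.frame(complex_id = delta$complex_id,
                    dG_pred = gas + polar + np + ent,
                    contrib_gas = gas, contrib_polar = polar,
                    contrib_nonpolar = np, contrib_entropy = ent,
                    stringsAsFactors = FALSE)
  attr(out, "model") <- model
  attr(out, "pair") <- pair
  class(out) <- c("scored_complexes", "data.frame")
  out
}
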