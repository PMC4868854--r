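#' Convert a solution-phase nitrite-oxidation flux to soil units
#'
#' Bridges the model's volumetric flux (uM s^-1 in soil solution) to the
#' field unit of potential nitrite oxidation (ng-N per g dry soil per hour):
#' `flux * 1e-6 mol/L/s * water_content L/g * 14e9 ng-N/mol * 3600 s/h`,
#' weighted by the compartment's share of soil mass and summed over
#' compartments.
#'
#' @param flux Per-compartment NO2- oxidation flux, uM s^-1 (vector).
#' @param water_content Soil water content, L per g dry soil (default
#'   2.1e-4, i.e. 0.21 g H2O per g dry soil).
#' @param mass_fraction Per-compartment mass fraction (same length as
#'   `flux`).
#' @return Soil-level nitrite oxidation, ng-N g^-1 h^-1.
#' @export
#' @examples
#' nitrite_oxidation_to_soil_units(1, 2.1e-4, 1)  # ~1.06e4 ng-N/g/h
nitrite_oxidation_to_soil_units <- function(flux, water_content = 2.1e-4,
                                            mass_fraction = 1) {
  if (any(c(flux, water_content, mass_fraction) < 0))
    stop("nitrite_oxidation_to_soil_units: arguments must be >= 0")
  sum(flux * 1e-6 * water_content * 14e9 * 3600 * mass_fraction)
}

#' Run global-change treatment scenarios
#'
#' For each driver row: build the two-compartment environment, run each
#' compartment to steady state (all types seeded everywhere; persistence in
#' the bulk is emergent), aggregate per-type biomass over compartments
#' weighted by mass fraction, and convert the total NO2- oxidation flux to
#' soil units.
#'
#' @param drivers Data.frame with columns `treatment`, `ammonification`,
#'   `respiration` (one row per treatment; see [read_drivers()]). Rows with
#'   missing driver values are skipped with a warning.
#' @param typeset A [type_set()].
#' @param config A [nob_model_config()].
#' @param water_content Soil water content, L per g dry soil.
#' @param hotspot_mass_fraction,oc_mapping Passed to [build_environment()].
#' @return A data.frame of class `nob_scenario_table`: per treatment the
#'   per-type relative abundances (`rel.<type>`, biomass fractions summing
#'   to 1, or 0 if all extinct), aggregate biomass `biomass.<type>`
#'   (mass-fraction weighted, M), `oxidation_ng_N_g_h`, `n_types` and a
#'   `converged` flag (all compartments).
#' @export
run_scenarios <- function(drivers, typeset, config = nob_model_config(),
                          water_content = 2.1e-4,
                          hotspot_mass_fraction = 0.055,
                          oc_mapping = "scaled") {
  stopifnot(inherits(typeset, "nob_typeset"))
  nms <- names(typeset$profiles)
  ok <- stats::complete.cases(drivers[, c("ammonification", "respiration")])
  if (any(!ok))
    warning("run_scenarios: skipping treatment(s) with missing drivers: ",
            paste(drivers$treatment[!ok], collapse = ", "))
  drivers <- drivers[ok, , drop = FALSE]
  ## the bulk compartment is prescribed, hence shared by all treatments
  bulk_env <- build_environment(list(ammonification = 1, respiration = 1),
                                hotspot_mass_fraction)$bulk
  bulk_ss <- run_to_steady_state(typeset, bulk_env, config = config)
  memo <- new.env(parent = emptyenv())   # replicate rows often share drivers
  rows <- lapply(seq_len(nrow(drivers)), function(i) {
    env2 <- build_environment(drivers[i, ], hotspot_mass_fraction,
                              oc_mapping = oc_mapping)
    key <- paste(format(c(drivers$ammonification[i], drivers$respiration[i]),
                        digits = 15), collapse = "|")
    hot_ss <- memo[[key]] %||% {
      ss <- run_to_steady_state(typeset, env2$hotspot, config = config)
      memo[[key]] <- ss
      ss
    }
    f <- env2$hotspot_mass_fraction
    biomass <- f * hot_ss$biomass + (1 - f) * bulk_ss$biomass
    tot <- sum(biomass)
    rel <- if (tot > 0) biomass / tot else biomass * 0
    ox <- nitrite_oxidation_to_soil_units(
      c(hot_ss$total_no2_flux, bulk_ss$total_no2_flux),
      water_content, c(f, 1 - f))
    out <- data.frame(treatment = drivers$treatment[i],
                      oxidation_ng_N_g_h = ox,
                      n_types = typeset$n_types,
                      converged = hot_ss$converged && bulk_ss$converged)
    out[paste0("rel.", nms)] <- as.list(rel)
    out[paste0("biomass.", nms)] <- as.list(biomass)
    out
  })
  structure(do.call(rbind, rows),
            class = c("nob_scenario_table", "data.frame"))
}

#' Percent effect of an elevated treatment relative to ambient
#'
#' `100 * (elevated - ambient) / ambient`.
#'
#' @param elevated,ambient Treatment means; `ambient` must be nonzero.
#' @return Percent effect.
#' @export
percent_effect <- function(elevated, ambient) {
  if (any(ambient == 0))
    stop("percent_effect: undefined for ambient = 0")
  100 * (elevated - ambient) / ambient
}

#' Compare predicted with observed per-treatment values
#'
#' Ordinary least-squares regression of observed on predicted plus the
#' Pearson correlation. Treatments are matched by label.
#'
#' @param pred,obs Named numeric vectors (names = treatment labels), or a
#'   data.frame each with columns `treatment` and `value`.
#' @return A list of class `nob_comparison`: `pairs` (data.frame),
#'   `slope`, `intercept`, `r`, `p_value` (of the slope), `n`.
#' @export
compare_predicted_observed <- function(pred, obs) {
  as_pairs <- function(x, nm) {
    if (is.data.frame(x)) stats::setNames(x$value, x$treatment)
    else if (!is.null(names(x))) x
    else stop("compare_predicted_observed: '", nm, "' must be named")
  }
  pred <- as_pairs(pred, "pred"); obs <- as_pairs(obs, "obs")
  shared <- intersect(names(pred), names(obs))
  if (length(shared) < 3L)
    stop("compare_predicted_observed: need >= 3 matched treatments, got ",
         length(shared))
  pairs <- data.frame(treatment = shared,
                      predicted = unname(pred[shared]),
                      observed = unname(obs[shared]))
  fit <- stats::lm(observed ~ predicted, data = pairs)
  ## summary.lm warns on zero-residual (identity) fits; that case is valid
  co <- suppressWarnings(summary(fit))$coefficients
  structure(list(pairs = pairs,
                 slope = unname(co["predicted", "Estimate"]),
                 intercept = unname(co["(Intercept)", "Estimate"]),
                 r = stats::cor(pairs$predicted, pairs$observed),
                 p_value = unname(co["predicted", "Pr(>|t|)"]),
                 n = nrow(pairs)),
            class = "nob_comparison")
}

#' @export
print.nob_comparison <- function(x, ...) {
  cat(sprintf("Predicted vs observed (n = %d): slope %.3g, intercept %.3g, r = %.3f, p = %.3g\n",
              x$n, x$slope, x$intercept, x$r, x$p_value))
  invisible(x)
}

#' Model-complexity ablation over 1-4 functional types
#'
#' Re-runs the scenario pipeline under each requested number of functional
#' types and summarizes how predictions change: per-treatment nitrite
#' oxidation per configuration, and the composition distance of each
#' configuration from the 3-type reference (mean absolute difference of the
#' relative abundances of the shared genus-level groups: Nitrospira-like
#' vs Nitrobacter-like).
#'
#' @param drivers Driver table (see [run_scenarios()]).
#' @param n_types_list Integer subset of 1:4.
#' @param ... Passed to [run_scenarios()].
#' @return A list of class `nob_ablation`: `scenarios` (named list of
#'   scenario tables), `oxidation` (treatments x configurations data.frame)
#'   and `composition_distance` (named numeric, vs the 3-type reference;
#'   `NA` when 3 is not in `n_types_list`).
#' @export
complexity_ablation <- function(drivers, n_types_list = 1:4, ...) {
  if (!all(n_types_list %in% 1:4))
    stop("complexity_ablation: 'n_types_list' must be a subset of 1:4")
  runs <- lapply(n_types_list, function(k)
    run_scenarios(drivers, build_type_set(k), ...))
  names(runs) <- paste0("n", n_types_list)
  ox <- data.frame(treatment = runs[[1]]$treatment)
  for (nm in names(runs)) ox[[nm]] <- runs[[nm]]$oxidation_ng_N_g_h
  dist <- rep(NA_real_, length(runs))
  names(dist) <- names(runs)
  if ("n3" %in% names(runs)) {
    ref <- genus_shares(runs$n3)
    for (nm in names(runs))
      dist[nm] <- mean(abs(genus_shares(runs[[nm]]) - ref))
    if ("n1" %in% names(dist))
      dist["n1"] <- NA_real_  # a single average type resolves no genus axis
  }
  structure(list(scenarios = runs, oxidation = ox,
                 composition_distance = dist),
            class = "nob_ablation")
}

## collapse relative abundances to the Nitrospira-like share (the
## genus-level axis every configuration resolves)
genus_shares <- function(scen) {
  rel <- scen[, grep("^rel\\.", names(scen)), drop = FALSE]
  spira <- grep("Nitrospira", names(rel))
  rowSums(rel[, spira, drop = FALSE])
}
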