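#' Map gross ammonification to hotspot nitrite concentration
#'
#' Nitrite supply to NOB scales steeply with gross ammonification (the proxy
#' of N availability to nitrifiers), following the empirical power law
#' NO2- (M) = 2e-16 * ammonification^5.35 with ammonification in
#' ng-N g^-1 h^-1.
#'
#' @param a Gross ammonification, ng-N g^-1 h^-1 (scalar or vector, >= 0).
#' @return NO2- concentration, M.
#' @export
#' @examples
#' ammonification_to_no2(100)  # ~1e-5 M
ammonification_to_no2 <- function(a) {
  if (any(a < 0)) stop("ammonification_to_no2: 'a' must be >= 0")
  2e-16 * a^5.35
}

#' Map soil respiration to hotspot organic-carbon concentration
#'
#' Soil respiration measured without OC supply indexes native OC
#' availability. The empirical relation is linear in respiration with a zero
#' crossing at r0 = 1.55 mg-C g^-1 h^-1. Two interpretations of its slope
#' are supported:
#' \describe{
#'   \item{`"scaled"` (default)}{the linear shape and zero crossing are kept
#'     but the slope is rescaled so that the observed range of field
#'     respiration rates (up to `r_max` = 2.70 mg-C g^-1 h^-1) spans the
#'     model's OC domain `[0, oc_max]`. This keeps treatment contrasts inside
#'     the regime where the niche model is defined.}
#'   \item{`"literal"`}{OC = 10*r - 15.5 taken at face value in M, clamped
#'     into `[0, oc_max]`; saturates for any r >= (15.5 + oc_max)/10.}
#' }
#'
#' @param r Soil respiration, mg-C g^-1 h^-1 (> 0).
#' @param mapping `"scaled"` or `"literal"`.
#' @param oc_max Upper clamp, M (default 5e-3, the top of the simulated OC
#'   gradient, equivalent to 150 ppm CH2O).
#' @param r_max Respiration mapped to `oc_max` under the scaled
#'   interpretation.
#' @return OC concentration, M, in `[0, oc_max]`.
#' @export
respiration_to_oc <- function(r, mapping = c("scaled", "literal"),
                              oc_max = 5e-3, r_max = 2.70) {
  mapping <- match.arg(mapping)
  if (any(r <= 0)) stop("respiration_to_oc: 'r' must be > 0")
  r0 <- 1.55                      # zero crossing of the printed relation
  oc <- if (mapping == "literal") 10 * r - 15.5
        else oc_max * (r - r0) / (r_max - r0)
  pmin(pmax(oc, 0), oc_max)
}

#' Map soil respiration to hotspot oxygen concentration
#'
#' High respiratory activity depletes soil-solution O2:
#' O2 (M) = -0.019 * ln(r) + 0.0137, clamped into the physically plausible
#' range `[1e-4, 1e-2]` M (the simulated O2 gradient).
#'
#' @param r Soil respiration, mg-C g^-1 h^-1 (> 0).
#' @param o2_min,o2_max Clamp bounds, M.
#' @return O2 concentration, M; nonincreasing in `r`.
#' @export
respiration_to_o2 <- function(r, o2_min = 1e-4, o2_max = 1e-2) {
  if (any(r <= 0)) stop("respiration_to_o2: 'r' must be > 0")
  pmin(pmax(-0.019 * log(r) + 0.0137, o2_min), o2_max)
}

#' Convert parts-per-million (mg/L of soil solution) to molar
#'
#' @param ppm Concentration, mg L^-1 (>= 0).
#' @param molar_mass Molar mass, g mol^-1 (> 0). CH2O = 30, O2 = 32.
#' @return Concentration, M.
#' @export
#' @examples
#' ppm_to_molar(150, 30)  # 5e-3 M CH2O
#' ppm_to_molar(3.2, 32)  # 1e-4 M O2
ppm_to_molar <- function(ppm, molar_mass) {
  if (any(ppm < 0)) stop("ppm_to_molar: 'ppm' must be >= 0")
  if (any(molar_mass <= 0)) stop("ppm_to_molar: 'molar_mass' must be > 0")
  ppm / (1000 * molar_mass)
}

#' Substrate concentrations of one homogeneous soil compartment
#'
#' @param no2,oc,o2 Concentrations, M (>= 0).
#' @param co2 Dissolved CO2, M; defaults to a non-limiting 1e-5 M.
#' @return An object of class `nob_environment_state`.
#' @export
environment_state <- function(no2, oc, o2, co2 = 1e-5) {
  v <- c(no2 = no2, oc = oc, o2 = o2, co2 = co2)
  if (any(!is.finite(v)) || any(v < 0))
    stop("environment_state: concentrations must be finite and >= 0")
  structure(as.list(v), class = "nob_environment_state")
}

#' @export
print.nob_environment_state <- function(x, ...) {
  cat(sprintf("Soil solution: NO2- %.3g M | OC %.3g M | O2 %.3g M | CO2 %.3g M\n",
              x$no2, x$oc, x$o2, x$co2))
  invisible(x)
}

#' One treatment's environmental driver record
#'
#' @param treatment Treatment label (e.g. CTRL, N, W, NW, CO2, CO2N, CO2W,
#'   CO2NW).
#' @param ammonification Gross ammonification, ng-N g^-1 h^-1 (>= 0).
#' @param respiration Soil respiration, mg-C g^-1 h^-1 (> 0).
#' @param replicate Optional replicate index.
#' @return A one-row data.frame of class `nob_driver`.
#' @export
driver_record <- function(treatment, ammonification, respiration,
                          replicate = NA_integer_) {
  if (ammonification < 0) stop("driver_record: 'ammonification' must be >= 0")
  if (respiration <= 0) stop("driver_record: 'respiration' must be > 0")
  structure(data.frame(treatment = as.character(treatment),
                       ammonification = ammonification,
                       respiration = respiration,
                       replicate = replicate),
            class = c("nob_driver", "data.frame"))
}

#' Read a per-treatment driver table from CSV
#'
#' Expected columns: `treatment`, `ammonification_ng_N_g_h`,
#' `respiration_mg_C_g_h` and optionally `replicate`. A synthetic example
#' table ships at `system.file("extdata", "drivers_synthetic.csv",
#' package = "nobsim")`.
#'
#' @param path CSV path.
#' @return A data.frame with columns `treatment`, `ammonification`,
#'   `respiration`, `replicate`.
#' @export
read_drivers <- function(path) {
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("treatment", "ammonification_ng_N_g_h", "respiration_mg_C_g_h")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("read_drivers: missing column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(treatment = as.character(d$treatment),
                    ammonification = as.numeric(d$ammonification_ng_N_g_h),
                    respiration = as.numeric(d$respiration_mg_C_g_h),
                    replicate = if ("replicate" %in% names(d))
                      d$replicate else NA_integer_)
  if (any(out$ammonification < 0) || any(out$respiration <= 0))
    stop("read_drivers: drivers out of range (ammonification >= 0, respiration > 0)")
  out
}

#' Assemble the two-compartment soil environment for one driver record
#'
#' The soil is represented by two homogeneous compartments. The *hotspot*
#' (default 5.5% of soil mass) collects the microhabitats with highest O2
#' and N availability; its substrate concentrations follow the measured
#' drivers through [ammonification_to_no2()], [respiration_to_oc()] and
#' [respiration_to_o2()]. The *bulk* compartment represents the remaining
#' habitats, with O2 and NO2- prescribed at low values (5e-4 M and 1e-5 M)
#' and no organic carbon.
#'
#' @param driver A [driver_record()] or any list/one-row data.frame with
#'   `ammonification` and `respiration`.
#' @param hotspot_mass_fraction Mass fraction of the hotspot compartment,
#'   in (0, 1).
#' @param co2 Dissolved CO2 in both compartments, M.
#' @param oc_mapping Passed to [respiration_to_oc()].
#' @return An object of class `nob_two_compartment` with elements `hotspot`,
#'   `bulk` (both [environment_state()]) and `hotspot_mass_fraction`.
#' @export
#' @examples
#' build_environment(driver_record("CTRL", 100, 1.8))
build_environment <- function(driver, hotspot_mass_fraction = 0.055,
                              co2 = 1e-5, oc_mapping = "scaled") {
  if (!(hotspot_mass_fraction > 0 && hotspot_mass_fraction < 1))
    stop("build_environment: 'hotspot_mass_fraction' must lie in (0, 1)")
  a <- driver$ammonification
  r <- driver$respiration
  structure(list(
    treatment = driver$treatment %||% NA_character_,
    hotspot = environment_state(
      no2 = ammonification_to_no2(a),
      oc = respiration_to_oc(r, mapping = oc_mapping),
      o2 = respiration_to_o2(r),
      co2 = co2),
    bulk = environment_state(no2 = 1e-5, oc = 0, o2 = 5e-4, co2 = co2),
    hotspot_mass_fraction = hotspot_mass_fraction
  ), class = "nob_two_compartment")
}

#' @export
print.nob_two_compartment <- function(x, ...) {
  cat(sprintf("Two-compartment soil (hotspot %.1f%% of mass)\n",
              100 * x$hotspot_mass_fraction))
  cat("  hotspot: "); print(x$hotspot)
  cat("  bulk:    "); print(x$bulk)
  invisible(x)
}
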