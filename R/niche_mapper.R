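#' Specification of a NO2- x OC x O2 gradient grid
#'
#' Default ranges follow the simulated gradients used to reconstruct the NOB
#' niches: NO2- from 7.4e-6 to 3.7e-2 M (log-spaced; spans soil and culture
#' conditions), OC from 0 to 5e-3 M (linear, includes 0), O2 from 1e-4 to
#' 1e-2 M (log-spaced; high-respiration/moist to air-intruded soil).
#'
#' @param no2_range,oc_range,o2_range Length-2 numeric ranges, M.
#' @param points_per_axis Number of grid points per axis (>= 2), recycled to
#'   length 3 (NO2-, OC, O2).
#' @param spacing Character vector of `"log"`/`"linear"` per axis; an axis
#'   starting at 0 must be linear.
#' @return A list of class `nob_gradient_spec` with an `axes` element
#'   (named list of grid coordinate vectors).
#' @export
gradient_spec <- function(no2_range = c(7.4e-6, 3.7e-2),
                          oc_range = c(0, 5e-3),
                          o2_range = c(1e-4, 1e-2),
                          points_per_axis = 12L,
                          spacing = c("log", "linear", "log")) {
  pts <- rep_len(as.integer(points_per_axis), 3L)
  if (any(pts < 2L)) stop("gradient_spec: 'points_per_axis' must be >= 2")
  spacing <- rep_len(spacing, 3L)
  ranges <- list(no2 = no2_range, oc = oc_range, o2 = o2_range)
  axes <- Map(function(rng, n, sp) {
    if (any(diff(rng) <= 0) || any(rng < 0))
      stop("gradient_spec: ranges must be nonnegative and increasing")
    if (sp == "log") {
      if (rng[1] <= 0)
        stop("gradient_spec: log spacing requires a positive lower bound")
      exp(seq(log(rng[1]), log(rng[2]), length.out = n))
    } else seq(rng[1], rng[2], length.out = n)
  }, ranges, as.list(pts), as.list(spacing))
  structure(list(axes = axes, points_per_axis = pts, spacing = spacing),
            class = "nob_gradient_spec")
}

#' Reconstruct NOB niches by sweeping steady states over a gradient grid
#'
#' Runs [run_to_steady_state()] independently in every cell of the
#' NO2- x OC x O2 grid and collects per-type steady-state biomass. Cells are
#' independent, so the map is deterministic and invariant to evaluation
#' order.
#'
#' @param typeset A [type_set()].
#' @param spec A [gradient_spec()].
#' @param config A [nob_model_config()].
#' @param co2 Dissolved CO2 in every cell, M.
#' @return A `nob_niche_map`: tidy data.frame with one row per cell and
#'   type - columns `no2_M`, `oc_M`, `o2_M`, `type`, `biomass_M`,
#'   `log10_biomass` (`NA` for extinct types), `dominant` (logical),
#'   `converged`. Attribute `n_unconverged` counts flagged cells.
#' @export
niche_sweep <- function(typeset, spec = gradient_spec(),
                        config = nob_model_config(), co2 = 1e-5) {
  stopifnot(inherits(typeset, "nob_typeset"),
            inherits(spec, "nob_gradient_spec"))
  grid <- expand.grid(no2 = spec$axes$no2, oc = spec$axes$oc,
                      o2 = spec$axes$o2, KEEP.OUT.ATTRS = FALSE)
  nms <- names(typeset$profiles)
  n <- length(nms)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    env <- environment_state(no2 = grid$no2[i], oc = grid$oc[i],
                             o2 = grid$o2[i], co2 = co2)
    ss <- run_to_steady_state(typeset, env, config = config)
    rows[[i]] <- data.frame(
      no2_M = grid$no2[i], oc_M = grid$oc[i], o2_M = grid$o2[i],
      type = nms, biomass_M = unname(ss$biomass),
      total_no2_flux = ss$total_no2_flux,
      converged = ss$converged, row.names = NULL)
  }
  map <- do.call(rbind, rows)
  map$log10_biomass <- ifelse(map$biomass_M > 0, log10(map$biomass_M), NA_real_)
  map <- classify_dominance(map)
  structure(map, class = c("nob_niche_map", "data.frame"),
            n_types = n, n_unconverged = sum(!map$converged) / n)
}

#' Label the dominant type of every niche-map cell
#'
#' The dominant type of a cell is the one with maximal steady-state biomass;
#' ties are broken by type order (first listed wins) and flagged. Cells
#' where every type is extinct are labelled `"none"`.
#'
#' @param map A `nob_niche_map` (or its underlying data.frame).
#' @return The map with per-row logical `dominant`, and per-cell columns
#'   `dominant_type` and `tie`.
#' @export
classify_dominance <- function(map) {
  key <- interaction(map$no2_M, map$oc_M, map$o2_M, drop = TRUE)
  map$dominant <- FALSE
  map$dominant_type <- NA_character_
  map$tie <- FALSE
  for (cell in split(seq_len(nrow(map)), key)) {
    b <- map$biomass_M[cell]
    if (all(b <= 0)) { map$dominant_type[cell] <- "none"; next }
    top <- which.max(b)
    map$dominant[cell[top]] <- TRUE
    map$dominant_type[cell] <- map$type[cell[top]]
    map$tie[cell] <- sum(b == b[top]) > 1L
  }
  map
}

#' Summarize a niche map by dominance counts
#'
#' @param map A `nob_niche_map`.
#' @return Table of cell counts per dominant type.
#' @export
dominance_table <- function(map) {
  cells <- !duplicated(interaction(map$no2_M, map$oc_M, map$o2_M, drop = TRUE))
  table(map$dominant_type[cells])
}

#' Write a niche map to tidy CSV
#'
#' @param map A `nob_niche_map`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_niche_map <- function(map, path) {
  utils::write.csv(as.data.frame(map)[, c("no2_M", "oc_M", "o2_M", "type",
                                          "biomass_M", "log10_biomass",
                                          "dominant")],
                   path, row.names = FALSE)
  invisible(path)
}
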