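#' Split-plot factorial study design
#'
#' The emulated field layout: three global-change factors each at two
#' levels - CO2 (applied at whole-plot level), N addition and precipitation
#' W (applied at quadrant level) - in full factorial combination (8
#' treatments), replicated in `n_blocks` blocks, i.e. 48 experimental units
#' by default.
#'
#' @param n_blocks Number of replicate blocks (default 6).
#' @return A list of class `nob_study_design` with a `units` data.frame
#'   (block, treatment, factor levels) and `treatments`.
#' @export
study_design <- function(n_blocks = 6L) {
  lev <- expand.grid(CO2 = c(0L, 1L), N = c(0L, 1L), W = c(0L, 1L),
                     KEEP.OUT.ATTRS = FALSE)
  lev$treatment <- ifelse(
    lev$CO2 + lev$N + lev$W == 0, "CTRL",
    paste0(ifelse(lev$CO2 == 1, "CO2", ""), ifelse(lev$N == 1, "N", ""),
           ifelse(lev$W == 1, "W", "")))
  units <- merge(data.frame(block = seq_len(n_blocks)), lev, by = NULL)
  units$unit <- seq_len(nrow(units))
  structure(list(units = units, treatments = lev$treatment,
                 n_blocks = n_blocks),
            class = "nob_study_design")
}

#' Default factorial effect multipliers of the driver generator
#'
#' Illustrative treatment effects on the two environmental drivers, chosen
#' to reproduce the qualitative effect directions of the field study
#' (N raises ammonification and hence Nitrobacter; W raises respiration and
#' lowers ammonification; CO2 raises respiration/OC and hence nitrite
#' oxidation):
#' N multiplies ammonification by 1.8; W multiplies respiration by 1.15 and
#' ammonification by 0.9; CO2 multiplies respiration by 1.3.
#'
#' @return Nested list `list(ammonification = ..., respiration = ...)` of
#'   per-factor multipliers.
#' @export
default_effect_multipliers <- function() {
  list(ammonification = c(CO2 = 1, N = 1.8, W = 0.9),
       respiration = c(CO2 = 1.3, N = 1, W = 1.15))
}

#' Generate per-unit environmental drivers for a factorial design
#'
#' Multiplicative factorial model: each unit's drivers are the baseline
#' times the product of its elevated factors' multipliers, times unit-mean
#' lognormal noise with coefficient of variation `noise_cv`.
#'
#' @param design A [study_design()].
#' @param effect_multipliers As [default_effect_multipliers()].
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (>= 0; 0 gives identical replicates).
#' @param seed Integer RNG seed; the whole generator chain is reproducible
#'   from it.
#' @param baseline_ammonification Baseline gross ammonification,
#'   ng-N g^-1 h^-1.
#' @param baseline_respiration Baseline soil respiration, mg-C g^-1 h^-1.
#' @return Driver data.frame (one row per unit): `unit`, `block`,
#'   `treatment`, `ammonification`, `respiration`, `replicate`.
#' @export
generate_drivers <- function(design = study_design(),
                             effect_multipliers = default_effect_multipliers(),
                             noise_cv = 0.2, seed = 1L,
                             baseline_ammonification = 100,
                             baseline_respiration = 1.8) {
  if (!is.numeric(noise_cv) || noise_cv < 0)
    stop("generate_drivers: 'noise_cv' must be >= 0")
  if (any(unlist(effect_multipliers) <= 0))
    stop("generate_drivers: multipliers must be > 0")
  u <- design$units
  mult_for <- function(driver) {
    m <- effect_multipliers[[driver]]
    m["CO2"]^u$CO2 * m["N"]^u$N * m["W"]^u$W
  }
  withr_seed(seed, {
    noise <- function(n) {
      if (noise_cv == 0) return(rep(1, n))
      sdlog <- sqrt(log(1 + noise_cv^2))     # unit-mean lognormal
      stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    data.frame(unit = u$unit, block = u$block, treatment = u$treatment,
               ammonification = baseline_ammonification *
                 mult_for("ammonification") * noise(nrow(u)),
               respiration = baseline_respiration *
                 mult_for("respiration") * noise(nrow(u)),
               replicate = u$block)
  })
}

## evaluate expr under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Forward-simulate noisy field observations from a driver table
#'
#' For every experimental unit the scenario pipeline supplies the *true*
#' model outputs (soil nitrite oxidation, per-type biomass and relative
#' abundance); observations are then corrupted the way the field assays
#' would be: potential-nitrite-oxidation (PNO) measurements get unit-mean
#' lognormal noise, genus abundances get a copies-per-biomass conversion
#' plus lognormal noise (qPCR-like), and the composition of the
#' Nitrobacter-like community is observed as a 30-clone multinomial library
#' over the Nitrobacter types.
#'
#' @param drivers Per-unit driver table from [generate_drivers()].
#' @param typeset A [type_set()]; the 3-type reference by default.
#' @param noise_model List: `pno_cv`, `abundance_cv` (lognormal CVs),
#'   `copies_per_biomass` (gene copies per g soil per M biomass-C),
#'   `n_clones` (library size).
#' @param seed Integer RNG seed.
#' @param config A [nob_model_config()].
#' @param scenario Optional precomputed [run_scenarios()] table for exactly
#'   these drivers (one row per unit); lets repeated-noise experiments skip
#'   re-simulating the deterministic truth.
#' @param ... Passed to [run_scenarios()].
#' @return A list of class `nob_synthetic_dataset`: `observations` (per
#'   unit: drivers, `pno_observed`, per-genus `copies.*`, clone counts
#'   `clones.*`), `truth` (per unit: true oxidation and per-type relative
#'   abundances) and `meta` (seed, noise model, typeset provenance).
#' @export
generate_observations <- function(drivers, typeset = build_type_set(3),
                                  noise_model = list(),
                                  seed = 1L,
                                  config = nob_model_config(),
                                  scenario = NULL, ...) {
  nm <- utils::modifyList(list(pno_cv = 0.2, abundance_cv = 0.3,
                               copies_per_biomass = 1e12, n_clones = 30L),
                          noise_model)
  scen <- scenario %||% run_scenarios(drivers, typeset, config = config, ...)
  ## run_scenarios keys rows by the treatment column; here one row per unit
  stopifnot(nrow(scen) == nrow(drivers))
  nms <- names(typeset$profiles)
  rel <- as.matrix(scen[, paste0("rel.", nms), drop = FALSE])
  bio <- as.matrix(scen[, paste0("biomass.", nms), drop = FALSE])
  colnames(rel) <- colnames(bio) <- nms
  nbac <- grep("Nitrobacter", nms, value = TRUE)
  withr_seed(seed, {
    lnoise <- function(n, cv) {
      if (cv == 0) return(rep(1, n))
      s <- sqrt(log(1 + cv^2))
      stats::rlnorm(n, -s^2 / 2, s)
    }
    n <- nrow(drivers)
    obs <- data.frame(unit = drivers$unit, block = drivers$block,
                      treatment = drivers$treatment,
                      ammonification = drivers$ammonification,
                      respiration = drivers$respiration,
                      pno_observed = scen$oxidation_ng_N_g_h *
                        lnoise(n, nm$pno_cv))
    ## qPCR-like genus abundances (copies per g dry soil)
    spira <- grep("Nitrospira", nms)
    obs$copies.Nitrobacter <- rowSums(bio[, setdiff(seq_along(nms), spira),
                                          drop = FALSE]) *
      nm$copies_per_biomass * lnoise(n, nm$abundance_cv)
    obs$copies.Nitrospira <- rowSums(bio[, spira, drop = FALSE]) *
      nm$copies_per_biomass * lnoise(n, nm$abundance_cv)
    ## 30-clone nxrA libraries over the Nitrobacter-like types
    if (length(nbac) >= 1L) {
      pb <- bio[, nbac, drop = FALSE]
      for (cl in nbac) obs[[paste0("clones.", cl)]] <- 0L
      for (i in seq_len(n)) {
        tot <- sum(pb[i, ])
        pr <- if (tot > 0) pb[i, ] / tot else rep(1 / length(nbac),
                                                  length(nbac))
        draw <- stats::rmultinom(1, nm$n_clones, pr)[, 1]
        for (j in seq_along(nbac))
          obs[[paste0("clones.", nbac[j])]][i] <- draw[j]
      }
    }
    truth <- data.frame(unit = drivers$unit, treatment = drivers$treatment,
                        oxidation_ng_N_g_h = scen$oxidation_ng_N_g_h)
    truth[paste0("rel.", nms)] <- as.data.frame(rel)
    structure(list(observations = obs, truth = truth,
                   meta = list(seed = seed, noise_model = nm,
                               typeset = typeset$provenance,
                               n_types = typeset$n_types)),
              class = "nob_synthetic_dataset")
  })
}

#' Recovery diagnostics of the pipeline against stored truth
#'
#' Regresses observed on true PNO per treatment ([compare_predicted_observed()])
#' and reports bias and RMSE of the observed treatment means against truth,
#' plus the recovered percent effect of each factor on PNO alongside the
#' true one.
#'
#' @param dataset A [generate_observations()] result.
#' @return A list of class `nob_recovery_report`: `pno_comparison`,
#'   `pno_bias`, `pno_rmse`, `effects` (data.frame: factor, true and
#'   recovered percent effect on PNO).
#' @export
recovery_report <- function(dataset) {
  if (is.null(dataset$truth))
    stop("recovery_report: dataset carries no truth metadata")
  obs <- dataset$observations
  tru <- dataset$truth
  obs_mean <- tapply(obs$pno_observed, obs$treatment, mean)
  tru_mean <- tapply(tru$oxidation_ng_N_g_h, tru$treatment, mean)
  shared <- intersect(names(obs_mean), names(tru_mean))
  cmp <- compare_predicted_observed(tru_mean[shared], obs_mean[shared])
  err <- obs_mean[shared] - tru_mean[shared]
  ## treatment labels encode elevated factors by letter (CTRL has none)
  fac_effect <- function(x) {
    vapply(c(CO2 = "CO2", N = "N", W = "W"), function(pat) {
      hi <- grepl(pat, names(x), fixed = TRUE)
      percent_effect(mean(x[hi]), mean(x[!hi]))
    }, 0)
  }
  structure(list(pno_comparison = cmp,
                 pno_bias = mean(err), pno_rmse = sqrt(mean(err^2)),
                 effects = data.frame(
                   factor = c("CO2", "N", "W"),
                   true_percent_effect = unname(fac_effect(tru_mean[shared])),
                   recovered_percent_effect = unname(fac_effect(obs_mean[shared])))),
            class = "nob_recovery_report")
}

#' @export
print.nob_recovery_report <- function(x, ...) {
  cat("Synthetic-data recovery report\n")
  print(x$pno_comparison)
  cat(sprintf("  PNO bias %.3g, RMSE %.3g ng-N/g/h\n", x$pno_bias, x$pno_rmse))
  print(x$effects, row.names = FALSE)
  invisible(x)
}
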