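#' Model configuration for the NOB community simulator
#'
#' Bundles the numerical and physiological closure parameters of the
#' dynamical system. Defaults are chosen for soil NOB at the scales of the
#' simulated gradients; all are overridable.
#'
#' @param q_min_c,q_min_n Minimum (subsistence) cellular quotas of stored C
#'   and N, mol per mol biomass-C. Growth ceases at the minimum quota
#'   (Droop).
#' @param f_n_assim Fraction of oxidized NO2--N routed to biomass N
#'   (assimilation); the remainder leaves as NO3-.
#' @param density_mortality Density-dependent loss coefficient m_q,
#'   (M biomass-C)^-1 s^-1: each type's per-capita loss is
#'   `mortality + m_q * B_guild`, where `B_guild` sums the biomass of the
#'   type's *crowding guild* (types sharing the same strategy class: the two
#'   K-strategist Nitrospira-like types form one guild; every other strategy
#'   is its own guild). The quadratic term is the standard trait-model
#'   closure that permits stable coexistence of several types on few
#'   resources while trait-redundant types partition, rather than inflate,
#'   their guild's niche; set it to 0 to recover purely first-order
#'   mortality (then equilibrium competition for one resource is
#'   winner-takes-all).
#' @param renewal_rate Resource renewal rate rho, s^-1, of the semi-chemostat
#'   boundary used by [run_to_steady_state()]: ambient concentrations relax
#'   toward the prescribed environment at rho while being depleted by
#'   consumption, so the prescribed values act as constant supply points.
#' @param o2_per_no2 Mol O2 consumed per mol NO2- oxidized (0.5 for
#'   NO2- + 1/2 O2 -> NO3-).
#' @param o2_per_oc Mol O2 consumed per mol CH2O oxidized.
#' @param seed_biomass Initial biomass per type, M biomass-C.
#' @param extinction_threshold Biomass below which a type is reported
#'   extinct, M biomass-C.
#' @param residual_tol Steady-state criterion on max_i |dB_i/dt|/B_i over
#'   surviving types, s^-1.
#' @param horizon_cap Maximum integration horizon, s (default 10 years).
#' @param atol,rtol Absolute (M) and relative solver tolerances.
#' @return A list of class `nob_model_config`.
#' @export
nob_model_config <- function(q_min_c = 0.05, q_min_n = 0.005,
                             f_n_assim = 0.02,
                             density_mortality = 0.003,
                             renewal_rate = 1e-3,
                             o2_per_no2 = 0.5, o2_per_oc = 1,
                             seed_biomass = 1e-6,
                             extinction_threshold = 1e-12,
                             residual_tol = 1e-10,
                             horizon_cap = 10 * 365.25 * 86400,
                             atol = 1e-14, rtol = 1e-8) {
  structure(as.list(environment()), class = "nob_model_config")
}

#' Dual-Monod substrate oxidation rate (energy acquisition)
#'
#' Rate of NO2- (or OC) oxidation by one type:
#' `V = V_max * S/(K_S + S) * O2/(K_O2 + O2) * B`, with the oxygen
#' half-saturation evaluated at the ambient O2 via [evaluate_k_m_o2()] for
#' profiles with a flexible oxygen response.
#'
#' @param profile A [trait_profile()].
#' @param s Substrate concentration, M.
#' @param o2 O2 concentration, M.
#' @param biomass Biomass, M biomass-C.
#' @param substrate `"no2"` or `"oc"` (selects V_max and K_M).
#' @return Oxidation rate, uM s^-1.
#' @export
substrate_oxidation_rate <- function(profile, s, o2, biomass,
                                     substrate = c("no2", "oc")) {
  substrate <- match.arg(substrate)
  if (any(c(s, o2, biomass) < 0))
    stop("substrate_oxidation_rate: arguments must be >= 0")
  v_max <- if (substrate == "no2") profile$v_max_no2 else profile$v_max_oc
  k_m <- if (substrate == "no2") profile$k_m_no2 else profile$k_m_oc
  k_o2 <- evaluate_k_m_o2(profile, o2)
  s_um <- s * 1e6                       # M -> uM, to match K_M units
  o2_um <- o2 * 1e6
  v_max * monod(s_um, k_m) * monod(o2_um, k_o2) * biomass
}

monod <- function(s, k) ifelse(s <= 0, 0, s / (k + s))

#' Energy-coupled carbon fixation rate
#'
#' C assimilation follows Michaelis-Menten kinetics in the available C, with
#' an effective maximal rate set by the energy yielded by concurrent
#' NO2-/OC oxidation: `V_C = yield * energy_rate * C/(K_C + C)`. No
#' oxidation, no fixation.
#'
#' @param profile A [trait_profile()].
#' @param c_conc Available C concentration, M (CO2 for chemolithotrophs,
#'   CO2 + OC for mixotrophs).
#' @param biomass Biomass, M biomass-C (kept for interface symmetry; the
#'   energy rate is already extensive).
#' @param energy_rate Total substrate oxidation rate of the type, uM s^-1.
#' @return C fixation rate, uM s^-1.
#' @export
carbon_fixation_rate <- function(profile, c_conc, biomass, energy_rate) {
  if (any(c(c_conc, biomass, energy_rate) < 0))
    stop("carbon_fixation_rate: arguments must be >= 0")
  profile$growth_yield * energy_rate * monod(c_conc * 1e6, profile$k_m_c)
}

#' Droop growth limitation factor
#'
#' `min_e (1 - q_min_e / q_e)` over the stored elements (C, N), clipped to
#' `[0, 1]`. Growth stops when either quota falls to its minimum.
#'
#' @param q_c,q_n Cellular quotas, mol per mol biomass-C.
#' @param config A [nob_model_config()] (supplies the minimum quotas).
#' @return Limitation factor in `[0, 1]`.
#' @export
growth_limitation <- function(q_c, q_n, config = nob_model_config()) {
  d <- pmin(1 - config$q_min_c / pmax(q_c, config$q_min_c),
            1 - config$q_min_n / pmax(q_n, config$q_min_n))
  pmin(pmax(d, 0), 1)
}

#' Initial community state
#'
#' @param typeset A [type_set()].
#' @param biomass Initial biomass per type, M biomass-C (recycled).
#' @param q_c,q_n Initial quotas, mol per mol biomass-C; default to twice the
#'   subsistence quotas (replete enough to start growing).
#' @param config A [nob_model_config()].
#' @return A named list of class `nob_community_state` with vectors
#'   `biomass_c`, `quota_c`, `quota_n` and scalar `time`.
#' @export
community_state <- function(typeset, biomass = NULL, q_c = NULL, q_n = NULL,
                            config = nob_model_config()) {
  n <- typeset$n_types
  biomass <- rep_len(biomass %||% config$seed_biomass, n)
  q_c <- rep_len(q_c %||% (2 * config$q_min_c), n)
  q_n <- rep_len(q_n %||% (2 * config$q_min_n), n)
  if (any(biomass < 0)) stop("community_state: biomass must be >= 0")
  if (any(q_c < config$q_min_c) || any(q_n < config$q_min_n))
    stop("community_state: quotas must be >= their minimum")
  structure(list(biomass_c = stats::setNames(biomass, names(typeset$profiles)),
                 quota_c = q_c, quota_n = q_n, time = 0),
            class = "nob_community_state")
}

## ---- the ODE right-hand side ------------------------------------------
## State layout: [B_1..B_n, qC_1..qC_n, qN_1..qN_n,
##                no2, oc, o2, no3, n_assim]
## Concentrations in M; B in M biomass-C; quotas dimensionless (mol/mol).
## boundary: "clamped"  - resource pools pinned at the environment values;
##           "renewal"  - semi-chemostat relaxation toward them at rho;
##           "batch"    - closed system (no resupply; NO3- accumulates).
nob_derivs <- function(t, y, pars) {
  n <- pars$n
  cfg <- pars$config
  B <- pmax(y[seq_len(n)], 0)
  qc <- pmax(y[n + seq_len(n)], cfg$q_min_c)
  qn <- pmax(y[2L * n + seq_len(n)], cfg$q_min_n)
  no2 <- max(y[3L * n + 1L], 0); oc <- max(y[3L * n + 2L], 0)
  o2 <- max(y[3L * n + 3L], 0)

  ## flexible traits: piecewise-linear in the ambient concentration
  k_o2 <- pars$k_m_o2
  for (i in pars$which_flex_ko2)
    k_o2[i] <- interp1(pars$flex_ko2[[i]], o2)
  mu_max <- pars$mu_max
  for (i in pars$which_flex_mu)
    mu_max[i] <- interp1(pars$flex_mu[[i]], oc)

  m_o2 <- (o2 * 1e6) / (k_o2 + o2 * 1e6)
  v_no2 <- pars$v_max_no2 * ((no2 * 1e6) / (pars$k_m_no2 + no2 * 1e6)) * m_o2
  v_oc <- pars$v_max_oc * ((oc * 1e6) / (pars$k_m_oc + oc * 1e6)) * m_o2
  energy <- v_no2 + v_oc                   # uM/(M biomass)/s, per capita

  c_avail <- pars$co2 + pars$mixo_num * oc
  m_c <- (c_avail * 1e6) / (pars$k_m_c + c_avail * 1e6)
  u_c <- pars$yield * energy * m_c * 1e-6                               # s^-1
  u_n <- cfg$f_n_assim * v_no2 * 1e-6                                   # s^-1

  d_fac <- pmin(pmax(1 - cfg$q_min_c / qc, 0), pmax(1 - cfg$q_min_n / qn, 0))
  d_fac <- pmin(d_fac, 1)
  mu <- mu_max * d_fac

  crowd <- cfg$density_mortality * drop(pars$crowd_mat %*% B)
  dB <- (mu - pars$mortality - crowd) * B
  dqc <- u_c - mu * qc
  dqn <- u_n - mu * qn

  cons_no2 <- sum(v_no2 * B) * 1e-6        # M/s
  cons_oc_ox <- sum(v_oc * B) * 1e-6
  ## mixotroph C assimilation draws on OC in proportion to its share of C
  assim_oc <- sum(pars$yield * energy * m_c * B * pars$mixo_num *
                    (oc / (c_avail + (c_avail <= 0)))) * 1e-6
  cons_o2 <- cfg$o2_per_no2 * cons_no2 + cfg$o2_per_oc * cons_oc_ox

  if (pars$boundary == "clamped") {
    dres <- c(0, 0, 0)
  } else if (pars$boundary == "renewal") {
    rho <- cfg$renewal_rate
    dres <- c(rho * (pars$env$no2 - no2) - cons_no2,
              rho * (pars$env$oc - oc) - cons_oc_ox - assim_oc,
              rho * (pars$env$o2 - o2) - cons_o2)
  } else {                                  # batch
    dres <- c(-cons_no2, -(cons_oc_ox + assim_oc), -cons_o2)
  }
  dno3 <- (1 - cfg$f_n_assim) * cons_no2
  dnassim <- cfg$f_n_assim * cons_no2
  list(c(dB, dqc, dqn, dres, dno3, dnassim),
       c(mu = mu, v_no2 = v_no2 * B, v_oc = v_oc * B))
}

## linear interpolation on a 2-column anchor matrix, constant beyond ends
interp1 <- function(a, x) {
  n <- nrow(a)
  if (x <= a[1, 1]) return(a[1, 2])
  if (x >= a[n, 1]) return(a[n, 2])
  j <- findInterval(x, a[, 1])
  a[j, 2] + (a[j + 1, 2] - a[j, 2]) * (x - a[j, 1]) / (a[j + 1, 1] - a[j, 1])
}

build_ode_pars <- function(typeset, env, config, boundary) {
  pr <- typeset$profiles
  flex_mu <- lapply(pr, `[[`, "flexible_mu_max")
  flex_ko2 <- lapply(pr, `[[`, "flexible_k_m_o2")
  list(
    n = typeset$n_types, config = config, env = env, boundary = boundary,
    v_max_no2 = vapply(pr, `[[`, 0, "v_max_no2"),
    k_m_no2 = vapply(pr, `[[`, 0, "k_m_no2"),
    v_max_oc = vapply(pr, `[[`, 0, "v_max_oc"),
    k_m_oc = vapply(pr, `[[`, 0, "k_m_oc"),
    k_m_o2 = vapply(pr, `[[`, 0, "k_m_o2"),
    k_m_c = vapply(pr, `[[`, 0, "k_m_c"),
    yield = vapply(pr, `[[`, 0, "growth_yield"),
    mu_max = vapply(pr, `[[`, 0, "mu_max"),
    mortality = vapply(pr, `[[`, 0, "mortality"),
    mixo = vapply(pr, is_mixotroph, TRUE),
    mixo_num = as.numeric(vapply(pr, is_mixotroph, TRUE)),
    flex_mu = flex_mu, flex_ko2 = flex_ko2,
    which_flex_mu = which(!vapply(flex_mu, is.null, TRUE)),
    which_flex_ko2 = which(!vapply(flex_ko2, is.null, TRUE)),
    crowd_mat = crowding_matrix(pr),
    co2 = env$co2
  )
}

## guild-sharing matrix for the density-dependent loss: K-strategist
## (Nitrospira-like) types crowd each other; every other strategy class is
## its own guild; averaged types never share.
crowding_matrix <- function(profiles) {
  strat <- vapply(profiles, `[[`, "", "strategy")
  guild <- ifelse(strat %in% c("K_chemolithotroph", "K_mixotroph"),
                  "K", paste0(strat, ".", seq_along(strat)))
  guild[strat == "r_chemolithotroph"] <- "r_chemo"
  guild[strat == "r_mixotroph"] <- "r_mixo"
  outer(guild, guild, `==`) * 1
}

state_vector <- function(state, env) {
  c(state$biomass_c, state$quota_c, state$quota_n,
    env$no2, env$oc, env$o2, 0, 0)
}

#' Integrate the NOB community dynamics
#'
#' Solves the coupled biomass-quota-resource system with a stiff-capable
#' implicit solver ([deSolve::lsoda()]). Three boundary conditions are
#' available: `"clamped"` (substrate concentrations held fixed at the
#' environment values - a pure forcing, useful for analytic limits),
#' `"renewal"` (semi-chemostat: ambient pools relax toward the environment
#' values at `config$renewal_rate` while being consumed) and `"batch"`
#' (closed system; substrates deplete and NO3- accumulates, used for
#' stoichiometric conservation checks).
#'
#' @param typeset A [type_set()].
#' @param env An [environment_state()].
#' @param initial A [community_state()]; defaults to equal seeding at
#'   `config$seed_biomass`.
#' @param horizon Integration horizon, s (> 0).
#' @param boundary `"clamped"`, `"renewal"` or `"batch"`.
#' @param config A [nob_model_config()].
#' @param n_out Number of output times (regular grid including 0 and
#'   `horizon`).
#' @return A data.frame of class `nob_trajectory`: `time`, per-type
#'   `biomass.<name>`, `quota_c.<name>`, `quota_n.<name>`, resource pools
#'   (`no2`, `oc`, `o2`, M), cumulative `no3` and `n_assim` (M), per-type
#'   growth rates `mu.<name>` (s^-1) and oxidation fluxes (uM s^-1).
#' @export
nob_integrate <- function(typeset, env, initial = NULL, horizon,
                          boundary = c("renewal", "clamped", "batch"),
                          config = nob_model_config(), n_out = 101L) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(typeset, "nob_typeset"),
            inherits(env, "nob_environment_state"), horizon > 0)
  initial <- initial %||% community_state(typeset, config = config)
  pars <- build_ode_pars(typeset, env, config, boundary)
  y0 <- state_vector(initial, env)
  times <- seq(0, horizon, length.out = max(2L, n_out))
  sol <- deSolve::lsoda(y0, times, nob_derivs, pars,
                        atol = config$atol, rtol = config$rtol,
                        maxsteps = 100000L)
  if (attr(sol, "istate")[1] < 0)
    stop("nob_integrate: solver failure (istate = ",
         attr(sol, "istate")[1], ") at t ~ ", max(sol[, 1]))
  out <- as.data.frame(sol)
  n <- typeset$n_types
  nms <- names(typeset$profiles)
  names(out) <- c("time",
                  paste0("biomass.", nms), paste0("quota_c.", nms),
                  paste0("quota_n.", nms),
                  "no2", "oc", "o2", "no3", "n_assim",
                  paste0("mu.", nms), paste0("v_no2.", nms),
                  paste0("v_oc.", nms))
  bcol <- paste0("biomass.", nms)
  if (any(out[, bcol] < 0)) {
    warning("nob_integrate: negative biomass excursion clipped to 0")
    out[, bcol][out[, bcol] < 0] <- 0
  }
  structure(out, class = c("nob_trajectory", "data.frame"))
}

#' Run the community to steady state under constant resource supply
#'
#' Integrates the semi-chemostat system (boundary `"renewal"`) in stages of
#' increasing horizon until the per-capita biomass rate of change of every
#' surviving type falls below `config$residual_tol`, or the horizon cap is
#' reached. Types whose biomass drops below the extinction threshold are
#' reported with biomass 0. Deterministic for fixed inputs.
#'
#' @param typeset A [type_set()].
#' @param env An [environment_state()] giving the constant supply-point
#'   concentrations.
#' @param seed_biomass Initial biomass per type, M biomass-C (> 0; equal
#'   seeding by default).
#' @param config A [nob_model_config()].
#' @return An object of class `nob_steady_state`: list with `biomass`
#'   (named, M, extinct types 0), `quota_c`, `quota_n`, `mu` (realized
#'   growth rates, s^-1), `fluxes` (data.frame per type: `no2_oxidation`,
#'   `oc_oxidation`, `c_fixation` in uM/s, `growth_rate` in s^-1,
#'   `mortality_loss` in uM/s), `resources` (ambient no2/oc/o2, M),
#'   `total_no2_flux` (uM/s), `converged`, `residual` (s^-1), `time` (s).
#' @export
run_to_steady_state <- function(typeset, env, seed_biomass = NULL,
                                config = nob_model_config()) {
  stopifnot(inherits(typeset, "nob_typeset"),
            inherits(env, "nob_environment_state"))
  seed_biomass <- seed_biomass %||% config$seed_biomass
  if (any(seed_biomass <= 0))
    stop("run_to_steady_state: 'seed_biomass' must be > 0")
  n <- typeset$n_types
  state <- community_state(typeset, biomass = seed_biomass, config = config)
  pars <- build_ode_pars(typeset, env, config, "renewal")
  y <- state_vector(state, env)
  t_now <- 0
  residual <- Inf
  n_partial <- 0L
  ## stage horizons: geometric schedule up to the cap
  stage_end <- 4e6
  while (t_now < config$horizon_cap) {
    stage_end <- min(max(stage_end, t_now * 4), config$horizon_cap)
    times <- c(t_now, stage_end)
    sol <- suppressWarnings(
      deSolve::lsoda(y, times, nob_derivs, pars,
                     atol = config$atol, rtol = config$rtol,
                     maxsteps = 100000L))
    istate <- attr(sol, "istate")[1]
    t_reached <- sol[nrow(sol), 1]
    if (istate < 0 && !(istate == -1 && t_reached > t_now))
      stop("run_to_steady_state: solver failure (istate = ", istate,
           ") at t ~ ", t_now)
    ## istate -1: step budget exhausted mid-stage; the partial trajectory is
    ## still accurate, so resume from where the solver stopped
    y <- sol[nrow(sol), 1L + seq_len(3L * n + 5L)]  # drop time and aux cols
    t_now <- t_reached
    if (istate == -1) {
      n_partial <- n_partial + 1L
      if (n_partial >= 4L) break   # persistent step-budget exhaustion:
    }                              # report the state as unconverged
    ## clip extinct types so they stop influencing the residual
    B <- y[seq_len(n)]
    B[B < config$extinction_threshold] <- 0
    y[seq_len(n)] <- B
    d <- nob_derivs(t_now, y, pars)[[1]]
    alive <- B > 0
    residual <- if (any(alive)) max(abs(d[seq_len(n)][alive] / B[alive])) else 0
    if (residual < config$residual_tol) break
  }
  finalize_steady_state(typeset, env, y, t_now, residual, config, pars)
}

finalize_steady_state <- function(typeset, env, y, time, residual, config,
                                  pars) {
  n <- typeset$n_types
  nms <- names(typeset$profiles)
  B <- y[seq_len(n)]
  B[B < config$extinction_threshold] <- 0
  qc <- y[n + seq_len(n)]; qn <- y[2L * n + seq_len(n)]
  res <- stats::setNames(pmax(y[3L * n + 1:3], 0), c("no2", "oc", "o2"))
  aux <- nob_derivs(time, c(B, qc, qn, res, 0, 0), pars)[[2]]
  mu <- aux[seq_len(n)]
  v_no2 <- aux[n + seq_len(n)]
  v_oc <- aux[2L * n + seq_len(n)]
  c_fix <- vapply(seq_len(n), function(i)
    carbon_fixation_rate(typeset$profiles[[i]],
                         res["oc"] * pars$mixo[i] + pars$co2,
                         B[i], v_no2[i] + v_oc[i]), 0)
  fluxes <- data.frame(
    type = nms,
    no2_oxidation = unname(v_no2),
    oc_oxidation = unname(v_oc),
    c_fixation = c_fix,
    growth_rate = unname(mu),
    mortality_loss = unname((pars$mortality + config$density_mortality *
                               drop(pars$crowd_mat %*% B)) * B * 1e6),
    row.names = NULL)
  structure(list(
    biomass = stats::setNames(unname(B), nms),
    quota_c = unname(qc), quota_n = unname(qn),
    mu = stats::setNames(unname(mu), nms),
    fluxes = fluxes, resources = res,
    total_no2_flux = sum(v_no2),
    converged = residual < config$residual_tol,
    residual = unname(residual), time = time,
    env = env
  ), class = "nob_steady_state")
}

#' @export
print.nob_steady_state <- function(x, ...) {
  cat(sprintf("NOB steady state (t = %.3g s, converged: %s, residual %.2g /s)\n",
              x$time, x$converged, x$residual))
  for (nm in names(x$biomass))
    cat(sprintf("  %-24s B = %.4g M biomass-C, mu = %.3g /s\n",
                nm, x$biomass[[nm]], x$mu[[nm]]))
  cat(sprintf("  ambient NO2- %.3g M, OC %.3g M, O2 %.3g M | total NO2- flux %.3g uM/s\n",
              x$resources["no2"], x$resources["oc"], x$resources["o2"],
              x$total_no2_flux))
  invisible(x)
}

#' Analytic break-even (R*) nitrite concentration of a single type
#'
#' Closed-form break-even concentration `S* = Delta K / (mu - Delta)` of
#' classical resource-competition theory, evaluated with the type's
#' effective maximum growth rate at the given O2 and OC (flexible traits
#' honoured, oxygen Monod factor applied). The lowest-S* type excludes its
#' competitors at equilibrium when mortality is purely first-order.
#'
#' @param profile A [trait_profile()].
#' @param o2 Ambient O2, M.
#' @param oc Ambient OC, M.
#' @return Break-even NO2- concentration, uM; `Inf` when the type cannot
#'   break even at any NO2-.
#' @export
break_even_no2 <- function(profile, o2 = 1e-2, oc = 0) {
  mu_eff <- evaluate_mu_max(profile, oc) *
    monod(o2 * 1e6, evaluate_k_m_o2(profile, o2))
  if (mu_eff <= profile$mortality) return(Inf)
  profile$mortality * profile$k_m_no2 / (mu_eff - profile$mortality)
}
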