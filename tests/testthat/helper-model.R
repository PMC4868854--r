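## Shared test fixtures: minimal trait profiles and an independent
## brute-force integrator used as oracle for the package's solver.

## single-resource chemolithotroph with oxidation capacity tied to growth
## requirement (v_max = mu_max * q_min_c / (yield * 1e-6))
simple_chemo <- function(name = "T", mu_max = 7e-6, k_m_no2 = 15,
                         k_m_o2 = 10, yield = 0.1, mortality = 3e-7,
                         vmax_factor = 1) {
  trait_profile(name, "K_chemolithotroph",
                v_max_no2 = vmax_factor * mu_max * 0.05 / (yield * 1e-6),
                k_m_no2 = k_m_no2, k_m_o2 = k_m_o2,
                mu_max = mu_max, growth_yield = yield, mortality = mortality)
}

## Explicit-Euler reimplementation of the model equations (biomass, quotas,
## resources), written directly from the documented rate laws. Independent
## of the package's deSolve path.
euler_integrate <- function(typeset, env, horizon, dt,
                            boundary = "clamped",
                            config = nob_model_config(),
                            biomass0 = config$seed_biomass) {
  pr <- typeset$profiles
  n <- length(pr)
  B <- rep(biomass0, n)
  qc <- rep(2 * config$q_min_c, n); qn <- rep(2 * config$q_min_n, n)
  no2 <- env$no2; oc <- env$oc; o2 <- env$o2
  mm <- function(s, k) if (s <= 0) 0 else s / (k + s)
  steps <- ceiling(horizon / dt)
  for (step in seq_len(steps)) {
    vno2 <- vapply(seq_len(n), function(i) {
      p <- pr[[i]]
      p$v_max_no2 * mm(no2 * 1e6, p$k_m_no2) *
        mm(o2 * 1e6, evaluate_k_m_o2(p, o2))
    }, 0)
    voc <- vapply(seq_len(n), function(i) {
      p <- pr[[i]]
      p$v_max_oc * mm(oc * 1e6, p$k_m_oc) *
        mm(o2 * 1e6, evaluate_k_m_o2(p, o2))
    }, 0)
    uc <- vapply(seq_len(n), function(i) {
      p <- pr[[i]]
      cav <- env$co2 + if (nobsim:::is_mixotroph(p)) oc else 0
      p$growth_yield * (vno2[i] + voc[i]) * mm(cav * 1e6, p$k_m_c) * 1e-6
    }, 0)
    un <- config$f_n_assim * vno2 * 1e-6
    mu <- vapply(seq_len(n), function(i) {
      d <- min(1 - config$q_min_c / qc[i], 1 - config$q_min_n / qn[i])
      evaluate_mu_max(pr[[i]], oc) * min(max(d, 0), 1)
    }, 0)
    mort <- vapply(pr, `[[`, 0, "mortality")
    B2 <- B + dt * (mu - mort - config$density_mortality * B) * B
    qc <- qc + dt * (uc - mu * qc)
    qn <- qn + dt * (un - mu * qn)
    if (boundary == "renewal") {
      rho <- config$renewal_rate
      no2 <- no2 + dt * (rho * (env$no2 - no2) - sum(vno2 * B) * 1e-6)
      oc <- oc + dt * (rho * (env$oc - oc) - sum(voc * B) * 1e-6)
      o2 <- o2 + dt * (rho * (env$o2 - o2) -
                         (0.5 * sum(vno2 * B) + sum(voc * B)) * 1e-6)
    }
    B <- pmax(B2, 0)
  }
  list(biomass = B, quota_c = qc, quota_n = qn, no2 = no2)
}
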