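test_that("dual-Monod oxidation rate obeys its closed-form identities", {
  p <- simple_chemo(k_m_no2 = 50, k_m_o2 = 10)
  # zero substrate, oxygen or biomass each nullify the rate
  expect_equal(substrate_oxidation_rate(p, 0, 1e-2, 1e-5), 0)
  expect_equal(substrate_oxidation_rate(p, 1e-3, 0, 1e-5), 0)
  expect_equal(substrate_oxidation_rate(p, 1e-3, 1e-2, 0), 0)
  # half-saturation identity: s = K_M, O2 -> saturation
  o2_sat <- 1e6 * 10 * 1e-6   # 1e6 x K_M(O2), in M
  v <- substrate_oxidation_rate(p, 50e-6, o2_sat, 1e-5)
  expect_equal(v, p$v_max_no2 * 1e-5 / 2, tolerance = 1e-5)
  # random draws equal the direct formula evaluation
  set.seed(11)
  for (i in 1:20) {
    s <- runif(1, 0, 1e-2); o2 <- runif(1, 0, 1e-2); B <- runif(1, 0, 1e-3)
    expected <- p$v_max_no2 * (s * 1e6 / (p$k_m_no2 + s * 1e6)) *
      (o2 * 1e6 / (p$k_m_o2 + o2 * 1e6)) * B
    expect_equal(substrate_oxidation_rate(p, s, o2, B), expected,
                 tolerance = 1e-12)
  }
})

test_that("carbon fixation is energy-coupled Michaelis-Menten", {
  p <- simple_chemo()
  expect_equal(carbon_fixation_rate(p, 0, 1e-5, 1), 0)
  expect_equal(carbon_fixation_rate(p, 1e-3, 1e-5, 0), 0)
  # c = K_M(C): half of the energy-limited maximum
  c_half <- p$k_m_c * 1e-6
  expect_equal(carbon_fixation_rate(p, c_half, 1e-5, 2),
               p$growth_yield * 2 / 2)
})

test_that("Droop limitation clips between minimum quota and saturation", {
  cfg <- nob_model_config()
  expect_equal(growth_limitation(cfg$q_min_c, 1, cfg), 0)
  expect_equal(growth_limitation(1, cfg$q_min_n, cfg), 0)
  expect_equal(growth_limitation(1e9, 1e9, cfg), 1, tolerance = 1e-8)
  # min rule over elements
  qc <- 2 * cfg$q_min_c          # C term = 0.5
  qn <- 5 * cfg$q_min_n          # N term = 0.8
  expect_equal(growth_limitation(qc, qn, cfg), 0.5)
})

test_that("clamped saturating conditions give exponential growth at mu_max", {
  p <- trait_profile("E", "K_chemolithotroph", v_max_no2 = 4e4, k_m_no2 = 10,
                     k_m_o2 = 5, mu_max = 1e-5, growth_yield = 0.5,
                     mortality = 1e-30)
  ts <- type_set(list(p))
  cfg <- nob_model_config(density_mortality = 0)
  horizon <- 5 * log(2) / 1e-5   # five doublings
  tr <- nob_integrate(ts, environment_state(1e-2, 0, 1e-2),
                      horizon = horizon, boundary = "clamped", config = cfg)
  expect_equal(tr$biomass.E[nrow(tr)], cfg$seed_biomass * exp(1e-5 * horizon),
               tolerance = 0.01)
})

test_that("zero initial biomass is an absorbing state", {
  ts <- type_set(list(simple_chemo()))
  st <- community_state(ts, biomass = 0)
  tr <- nob_integrate(ts, environment_state(1e-3, 0, 1e-2), st,
                      horizon = 1e6, boundary = "clamped")
  expect_true(all(tr$biomass.T == 0))
})

test_that("solver agrees with a small-step explicit-Euler oracle", {
  cfg <- nob_model_config(density_mortality = 0)
  ts <- build_type_set(3)
  env <- environment_state(5e-4, 1e-3, 1e-3)
  horizon <- 2e5
  tr <- nob_integrate(ts, env, horizon = horizon, boundary = "clamped",
                      config = cfg)
  eul <- euler_integrate(ts, env, horizon, dt = 20, boundary = "clamped",
                         config = cfg)
  got <- unlist(tr[nrow(tr), paste0("biomass.", names(ts$profiles))])
  expect_equal(unname(got), unname(eul$biomass), tolerance = 1e-4)
})

test_that("biomass and resources never go negative over random draws", {
  set.seed(99)
  cfg <- nob_model_config()
  for (i in 1:60) {
    p <- simple_chemo(mu_max = runif(1, 1e-6, 3e-5),
                      k_m_no2 = runif(1, 5, 800),
                      k_m_o2 = runif(1, 5, 200),
                      yield = runif(1, 0.01, 0.5),
                      vmax_factor = runif(1, 0.2, 5))
    env <- environment_state(10^runif(1, -6, -2), runif(1, 0, 5e-3),
                             10^runif(1, -4, -2))
    tr <- nob_integrate(type_set(list(p)), env, horizon = 1e6,
                        boundary = sample(c("clamped", "renewal", "batch"), 1),
                        config = cfg, n_out = 11L)
    expect_true(all(tr$biomass.T >= 0))
    expect_true(all(tr[, grep("^quota", names(tr))] >= 0))
    expect_true(all(tr[, c("no2", "oc", "o2")] >= -1e-12))
  }
})

test_that("a type below break-even washes out; above it settles at flux balance", {
  cfg <- nob_model_config(density_mortality = 0)
  # mu(env) < mortality everywhere: washout
  weak <- trait_profile("W", "K_chemolithotroph", v_max_no2 = 1,
                        k_m_no2 = 500, k_m_o2 = 10, mu_max = 1e-6,
                        growth_yield = 0.1)
  ss <- run_to_steady_state(type_set(list(weak)),
                            environment_state(1e-6, 0, 1e-4), config = cfg)
  expect_equal(unname(ss$biomass), 0)
  # substrate-rich: survivor's realized growth balances mortality
  strong <- simple_chemo("S")
  ss2 <- run_to_steady_state(type_set(list(strong)),
                             environment_state(1e-4, 0, 1e-2), config = cfg)
  expect_true(ss2$converged)
  expect_gt(ss2$biomass[["S"]], 0)
  expect_equal(unname(ss2$mu), strong$mortality, tolerance = 1e-4)
})

test_that("steady state balances growth against losses per surviving type", {
  cfg <- nob_model_config()
  ts <- build_type_set(3)
  ss <- run_to_steady_state(ts, environment_state(2e-4, 2e-3, 1e-3),
                            config = cfg)
  expect_true(ss$converged)
  alive <- ss$biomass > 0
  loss <- ss$fluxes$mortality_loss[alive] # uM/s
  growth <- ss$mu[alive] * ss$biomass[alive] * 1e6
  expect_equal(unname(growth), loss, tolerance = 1e-6)
})

test_that("run_to_steady_state equals the long-horizon trajectory endpoint", {
  cfg <- nob_model_config()
  ts <- build_type_set(3)
  envs <- list(environment_state(1e-5, 0, 5e-4),
               environment_state(2e-4, 5e-3, 1e-4),
               environment_state(3.7e-2, 0, 1e-2))
  for (env in envs) {
    ss <- run_to_steady_state(ts, env, config = cfg)
    tr <- nob_integrate(ts, env, horizon = ss$time, boundary = "renewal",
                        config = cfg, n_out = 2L)
    endpoint <- unlist(tr[nrow(tr), paste0("biomass.", names(ts$profiles))])
    endpoint[endpoint < cfg$extinction_threshold] <- 0
    expect_equal(unname(endpoint), unname(ss$biomass), tolerance = 1e-3)
  }
})

test_that("closed-batch nitrogen ledger is conserved", {
  ts <- build_type_set(3)
  tr <- nob_integrate(ts, environment_state(5e-4, 1e-3, 1e-3),
                      horizon = 2e6, boundary = "batch")
  consumed <- tr$no2[1] - tr$no2[nrow(tr)]
  accounted <- tr$no3[nrow(tr)] + tr$n_assim[nrow(tr)]
  expect_gt(consumed, 0)
  expect_equal(accounted, consumed, tolerance = 1e-6)
})

test_that("break-even concentration follows the closed form", {
  p <- simple_chemo(mu_max = 1e-5, k_m_no2 = 100, k_m_o2 = 10,
                    mortality = 3e-7)
  # saturating O2: S* = Delta K / (mu_eff - Delta)
  o2 <- 1e-2
  mu_eff <- 1e-5 * (o2 * 1e6) / (10 + o2 * 1e6)
  expect_equal(break_even_no2(p, o2 = o2), 3e-7 * 100 / (mu_eff - 3e-7))
  # a type that cannot break even at any nitrite level
  weak <- trait_profile("W", "K_chemolithotroph", v_max_no2 = 1,
                        k_m_no2 = 100, k_m_o2 = 10, mu_max = 2e-7,
                        growth_yield = 0.1)
  expect_equal(break_even_no2(weak), Inf)
})

test_that("steady-state runs are deterministic", {
  ts <- build_type_set(3)
  env <- environment_state(1e-4, 1e-3, 1e-3)
  s1 <- run_to_steady_state(ts, env)
  s2 <- run_to_steady_state(ts, env)
  expect_identical(s1$biomass, s2$biomass)
})
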