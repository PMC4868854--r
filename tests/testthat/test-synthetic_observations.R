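test_that("the study design lays out 48 split-plot units", {
  des <- study_design()
  expect_equal(nrow(des$units), 48)
  expect_equal(length(unique(des$units$treatment)), 8)
  expect_equal(as.vector(table(des$units$treatment)), rep(6L, 8))
  # every unit carries exactly one treatment, nested in a block
  expect_equal(anyDuplicated(des$units[, c("block", "treatment")]), 0)
  expect_setequal(unique(des$units$treatment),
                  c("CTRL", "N", "W", "NW", "CO2", "CO2N", "CO2W", "CO2NW"))
})

test_that("driver generation honours the factorial model and the seed", {
  des <- study_design()
  # zero noise: replicates within a treatment are identical
  d0 <- generate_drivers(des, noise_cv = 0, seed = 3)
  spread <- tapply(d0$ammonification, d0$treatment, function(x) diff(range(x)))
  expect_true(all(spread == 0))
  # null multipliers: all treatments share the baseline
  null <- list(ammonification = c(CO2 = 1, N = 1, W = 1),
               respiration = c(CO2 = 1, N = 1, W = 1))
  dn <- generate_drivers(des, null, noise_cv = 0, seed = 3)
  expect_true(all(dn$ammonification == 100) && all(dn$respiration == 1.8))
  # multiplicative structure: N treatment = baseline x1.8 on ammonification
  expect_equal(unique(d0$ammonification[d0$treatment == "N"]), 180)
  expect_equal(unique(d0$respiration[d0$treatment == "CO2NW"]),
               1.8 * 1.3 * 1.15)
  # same seed -> identical table; different seed -> different noise
  d1 <- generate_drivers(des, noise_cv = 0.2, seed = 11)
  d2 <- generate_drivers(des, noise_cv = 0.2, seed = 11)
  d3 <- generate_drivers(des, noise_cv = 0.2, seed = 12)
  expect_identical(d1, d2)
  expect_false(identical(d1$ammonification, d3$ammonification))
  expect_error(generate_drivers(des, noise_cv = -1), "noise_cv")
})

test_that("forward-simulated observations respect their constraints", {
  des <- study_design(n_blocks = 1L)
  drv <- generate_drivers(des, noise_cv = 0, seed = 5)
  ds <- generate_observations(drv, seed = 5)
  obs <- ds$observations
  expect_equal(nrow(obs), 8)
  clone_cols <- grep("^clones\\.", names(obs))
  expect_equal(unname(rowSums(obs[, clone_cols])), rep(30, 8))
  expect_true(all(obs$pno_observed >= 0))
  expect_true(all(obs[, grep("^copies\\.", names(obs))] >= 0))
  # same-seed determinism across the whole chain
  ds2 <- generate_observations(drv, seed = 5)
  expect_identical(ds$observations, ds2$observations)
  expect_identical(ds$truth, ds2$truth)
})

test_that("noise-free datasets recover the truth exactly", {
  des <- study_design(n_blocks = 1L)
  drv <- generate_drivers(des, noise_cv = 0, seed = 7)
  ds <- generate_observations(drv, seed = 7,
                              noise_model = list(pno_cv = 0,
                                                 abundance_cv = 0))
  expect_equal(ds$observations$pno_observed, ds$truth$oxidation_ng_N_g_h)
  rep <- recovery_report(ds)
  expect_equal(rep$pno_bias, 0)
  expect_equal(rep$pno_rmse, 0)
  expect_equal(rep$pno_comparison$slope, 1)
  expect_equal(rep$effects$true_percent_effect,
               rep$effects$recovered_percent_effect)
  # clone libraries match expected proportions up to multinomial rounding
  nb <- ds$truth$rel.Nitrobacter_chemolitho + ds$truth$rel.Nitrobacter_mixo
  pr_true <- ifelse(nb > 0, ds$truth$rel.Nitrobacter_mixo / nb, NA)
  pr_obs <- ds$observations$clones.Nitrobacter_mixo / 30
  ok <- !is.na(pr_true)
  expect_lt(max(abs(pr_obs[ok] - pr_true[ok])), 0.2)
})

test_that("noisier observations degrade recovery monotonically", {
  des <- study_design(n_blocks = 2L)
  drv <- generate_drivers(des, noise_cv = 0, seed = 21)
  scen <- run_scenarios(drv, build_type_set(3))
  rmse_at <- function(cv) {
    r <- vapply(1:12, function(s) {
      ds <- generate_observations(drv, seed = 100 + s, scenario = scen,
                                  noise_model = list(pno_cv = cv))
      recovery_report(ds)$pno_rmse
    }, 0)
    mean(r)
  }
  rmses <- vapply(c(0.1, 0.2, 0.4), rmse_at, 0)
  expect_true(all(diff(rmses) > 0))
})

test_that("recovery_report requires truth metadata", {
  expect_error(recovery_report(list(observations = data.frame())), "truth")
})
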