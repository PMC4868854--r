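test_that("reference 3-type set has the expected members and structure", {
  ts <- build_type_set(3)
  expect_s3_class(ts, "nob_typeset")
  expect_equal(ts$n_types, 3)
  expect_setequal(names(ts$profiles),
                  c("Nitrospira", "Nitrobacter_chemolitho", "Nitrobacter_mixo"))
  expect_false(is_any_mixo <- nobsim:::is_mixotroph(ts$profiles$Nitrospira))
  expect_true(nobsim:::is_mixotroph(ts$profiles$Nitrobacter_mixo))
  # K/r contrast of the half-saturation constants
  expect_lt(ts$profiles$Nitrospira$k_m_no2,
            ts$profiles$Nitrobacter_chemolitho$k_m_no2)
})

test_that("trait profile invariants are enforced", {
  expect_error(simple_chemo(k_m_no2 = -5), "k_m_no2")
  expect_error(trait_profile("X", "K_chemolithotroph", v_max_no2 = 1,
                             k_m_no2 = 10, k_m_o2 = 10, mu_max = 1e-6,
                             growth_yield = 1.5), "growth_yield")
  expect_error(trait_profile("X", "K_chemolithotroph", v_max_no2 = 1,
                             k_m_no2 = 10, k_m_o2 = 10, mu_max = 1e-6,
                             growth_yield = 0.1, mortality = 0), "mortality")
  # non-mixotrophs cannot oxidize OC
  expect_error(trait_profile("X", "K_chemolithotroph", v_max_no2 = 1,
                             k_m_no2 = 10, k_m_o2 = 10, mu_max = 1e-6,
                             growth_yield = 0.1, v_max_oc = 5), "v_max_oc")
  # anchors must be strictly ordered
  expect_error(trait_profile("X", "r_mixotroph", v_max_no2 = 1,
                             k_m_no2 = 10, k_m_o2 = 10, growth_yield = 0.1,
                             flexible_mu_max = rbind(c(1e-3, 1e-6),
                                                     c(1e-3, 2e-6))),
               "strictly increasing")
})

test_that("flexible growth rate interpolates the printed anchors", {
  mixo <- build_type_set(3)$profiles$Nitrobacter_mixo
  expect_equal(evaluate_mu_max(mixo, 0), 6.9e-6)
  expect_equal(evaluate_mu_max(mixo, 5e-3), 2.78e-5)   # 150 ppm CH2O
  # midpoint of the two anchors under linear interpolation
  expect_equal(evaluate_mu_max(mixo, 2.5e-3), 1.735e-5)
  # constant beyond the last anchor
  expect_equal(evaluate_mu_max(mixo, 1), 2.78e-5)
  expect_error(evaluate_mu_max(mixo, -1), ">= 0")
  # non-flexible profile returns its constant
  spira <- build_type_set(3)$profiles$Nitrospira
  expect_equal(evaluate_mu_max(spira, 5e-3), spira$mu_max)
})

test_that("flexible oxygen half-saturation interpolates the printed anchors", {
  mixo <- build_type_set(3)$profiles$Nitrobacter_mixo
  expect_equal(evaluate_k_m_o2(mixo, 1e-4), 25.1)      # ~3.2 ppm O2
  expect_equal(evaluate_k_m_o2(mixo, 6.25e-3), 125)    # >= 200 ppm O2
  expect_equal(evaluate_k_m_o2(mixo, 1e-2), 125)
  expect_error(evaluate_k_m_o2(mixo, -1e-6), ">= 0")
  spira <- build_type_set(3)$profiles$Nitrospira
  expect_equal(evaluate_k_m_o2(spira, 0), 10)
  expect_equal(evaluate_k_m_o2(spira, 1e-2), 10)
})

test_that("flexible trait evaluation is monotone nondecreasing", {
  set.seed(42)
  for (rep in 1:25) {
    n_anchor <- sample(2:5, 1)
    xs <- sort(runif(n_anchor, 0, 1))
    ys <- cumsum(runif(n_anchor, 0, 1e-5))
    p <- trait_profile("F", "r_mixotroph", v_max_no2 = 1, k_m_no2 = 10,
                       k_m_o2 = 10, growth_yield = 0.1,
                       flexible_mu_max = cbind(xs, ys),
                       flexible_k_m_o2 = cbind(xs, 1 + ys * 1e6))
    grid <- seq(0, 1, length.out = 101)
    expect_true(all(diff(evaluate_mu_max(p, grid)) >= -1e-15))
    expect_true(all(diff(evaluate_k_m_o2(p, grid)) >= -1e-12))
  }
})

test_that("averaging traits is an arithmetic mean and is idempotent", {
  a <- simple_chemo("A", k_m_no2 = 10)
  b <- simple_chemo("B", k_m_no2 = 500)
  avg <- average_traits(list(a, b), name = "AB")
  expect_equal(avg$k_m_no2, 255)
  expect_equal(avg$mu_max, a$mu_max)
  # n copies of one profile average to that profile
  same <- average_traits(list(a, a, a), name = "A")
  for (f in c("v_max_no2", "k_m_no2", "k_m_o2", "mu_max", "growth_yield",
              "mortality", "v_max_c", "k_m_c"))
    expect_equal(same[[f]], a[[f]], info = f)
  expect_error(average_traits(list(), "X"), "empty")
  expect_error(average_traits(list(a), "X"), ">= 2")
})

test_that("averaging evaluates flexible traits on the union of anchors", {
  ref <- build_type_set(3)$profiles
  avg <- average_traits(ref, name = "NOB_avg")
  # pointwise mean of the member responses
  for (oc in c(0, 1e-3, 5e-3))
    expect_equal(evaluate_mu_max(avg, oc),
                 mean(vapply(ref, evaluate_mu_max, 0, oc = oc)))
  for (o2 in c(1e-4, 2e-3, 6.25e-3))
    expect_equal(evaluate_k_m_o2(avg, o2),
                 mean(vapply(ref, evaluate_k_m_o2, 0, o2 = o2)))
})

test_that("ablation type sets are built as documented", {
  expect_error(build_type_set(5), "1, 2, 3, 4")
  ts1 <- build_type_set(1); ts2 <- build_type_set(2)
  ts3 <- build_type_set(3); ts4 <- build_type_set(4)
  expect_equal(ts1$n_types, 1)
  expect_equal(names(ts2$profiles), c("Nitrospira", "Nitrobacter_avg"))
  # 4-type set extends the reference set without altering it
  expect_identical(ts4$profiles[1:3], ts3$profiles)
  # the averaged Nitrobacter keeps a (weak) flexible OC response
  expect_false(is.null(ts2$profiles$Nitrobacter_avg$flexible_mu_max))
  expect_gt(evaluate_mu_max(ts2$profiles$Nitrobacter_avg, 5e-3),
            evaluate_mu_max(ts2$profiles$Nitrobacter_avg, 0))
  # 1-type average equals the mean of the three reference profiles
  expect_equal(ts1$profiles[[1]]$k_m_no2,
               mean(vapply(ts3$profiles, `[[`, 0, "k_m_no2")))
})

test_that("trait configs survive a save/load round trip field-by-field", {
  ts <- build_type_set(4)
  f <- withr::local_tempfile(fileext = ".yaml")
  save_trait_config(ts, f)
  ts2 <- load_trait_config(f)
  expect_equal(ts2$profiles, ts$profiles, tolerance = 0)
  # packaged reference config loads to the reference set
  ref <- load_trait_config(system.file("extdata", "traits_reference.yaml",
                                       package = "nobsim"))
  expect_equal(ref$profiles[1:3], build_type_set(3)$profiles, tolerance = 0)
})

test_that("malformed configs fail with informative errors", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("types:\n- name: X\n  strategy: K_chemolithotroph\n  bogus_key: 1", f)
  expect_error(load_trait_config(f), "bogus_key")
  f2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines("nothing: here", f2)
  expect_error(load_trait_config(f2), "types")
  expect_error(load_trait_config("/nonexistent/file.yaml"), "no such file")
})
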