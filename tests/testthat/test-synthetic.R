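# synthetic cohort generator: archetypes, mixing, determinism, outcomes

test_that("generator parameters are validated", {
  expect_error(generator_params(n = 0), "positive")
  expect_error(generator_params(mixture = c(monophasic = 0.6, biphasic = 0.6,
                                            monotonic = 0, flat = 0)), "sum to 1")
  expect_error(generator_params(noise_sd_glucose = -1), ">= 0")
  expect_error(generator_params(followup_fraction = 1.2), "\\[0, 1\\]")
})

test_that("archetype mixture frequencies land near their weights at n = 1000", {
  coh <- generate_cohort(generator_params(n = 1000, seed = 1))
  freq <- table(attr(coh, "truth")$archetype) / 1000
  expect_lt(abs(freq[["monophasic"]] - 0.547), 0.03)
  expect_lt(abs(freq[["biphasic"]] - 0.420), 0.03)
  expect_lt(abs(freq[["monotonic"]] - 0.025), 0.03)
})

test_that("generation is deterministic and stable under cohort enlargement", {
  a <- generate_cohort(generator_params(n = 5, seed = 99))
  b <- generate_cohort(generator_params(n = 5, seed = 99))
  expect_identical(a, b)
  big <- generate_cohort(generator_params(n = 20, seed = 99))
  shared <- setdiff(names(a), grep("^fu_", names(a), value = TRUE))
  expect_identical(a[shared], big[1:5, shared])
})

test_that("every generated profile satisfies the OGTT invariants", {
  coh <- generate_cohort(generator_params(n = 300, seed = 4))
  G <- as.matrix(coh[paste0("glucose_", c(0, 30, 60, 90, 120))])
  I <- as.matrix(coh[paste0("insulin_", c(0, 30, 60, 90, 120))])
  expect_true(all(is.finite(G)) && all(G >= 40))
  expect_true(all(is.finite(I)) && all(I >= 1))
  expect_true(all(coh$bmi_percentile >= 85))
  labs <- coh[c("hba1c", "total_chol", "ldl", "hdl", "triglycerides")]
  expect_true(all(as.matrix(labs) >= 0, na.rm = TRUE))
})

test_that("zero-noise single-archetype cohorts classify into their own class", {
  intended <- c(monophasic = "monophasic", biphasic = "biphasic",
                monotonic = "monotonically_increasing", flat = "inconclusive")
  for (arch in names(intended)) {
    mix <- c(monophasic = 0, biphasic = 0, monotonic = 0, flat = 0)
    mix[arch] <- 1
    coh <- generate_cohort(generator_params(n = 40, mixture = mix,
                                            noise_sd_glucose = 0, seed = 8))
    labs <- classify_shapes(as.matrix(coh[paste0("glucose_", c(0, 30, 60, 90, 120))]))
    expect_true(all(labs == intended[arch]),
                label = sprintf("archetype %s", arch))
  }
})

test_that("flat archetype with zero noise is constant; monotonic is strictly increasing", {
  set.seed(1)
  flat <- generate_profile(ogtt_archetype("flat", 85, 0), insulin_gain = 1,
                           noise_sd_glucose = 0)
  expect_true(all(flat$glucose == 85))
  mono <- generate_profile(ogtt_archetype("monotonic", 85, 50), insulin_gain = 1,
                           noise_sd_glucose = 0)
  expect_true(all(diff(mono$glucose) > 0))
})

test_that("insulin is exactly linear in the gain before flooring", {
  a <- ogtt_archetype("monophasic", 85, 50)
  set.seed(123)
  p1 <- generate_profile(a, insulin_gain = 2, insulin_basal = 20)
  set.seed(123)
  p2 <- generate_profile(a, insulin_gain = 4, insulin_basal = 20)
  # basal high enough that the 1 uU/mL floor never engages
  expect_true(all(p1$insulin > 1))
  expect_equal(p2$insulin, 2 * p1$insulin, tolerance = 1e-12)
  expect_identical(p1$glucose, p2$glucose)
})

test_that("intercept-only outcome model calibrates follow-up dysglycemia to 7.3%", {
  params <- generator_params(n = 4000, followup_fraction = 1,
                             outcome = list(beta_height = 0, beta_g120 = 0,
                                            prevalence = 0.073),
                             seed = 6)
  coh <- generate_cohort(params)
  tr <- attr(coh, "truth")
  # with zero coefficients every participant gets exactly the target probability
  expect_true(all(abs(tr$event_prob - 0.073) < 1e-12))
  rate <- mean(tr$fu_event)
  expect_lt(abs(rate - 0.073), 2 * sqrt(0.073 * 0.927 / 4000) + 1e-9)
  # follow-up labels recomputed from the drawn glucose values agree
  lab <- label_dysglycemia(coh$fu_glucose_0, coh$fu_glucose_120)
  expect_equal(unname(lab), tr$fu_event)
})

test_that("a large negative outcome intercept yields zero events", {
  # beta = 0 and prevalence ~ 0 drives the calibrated intercept to -inf analog
  params <- generator_params(n = 300, followup_fraction = 1,
                             outcome = list(beta_height = 0, beta_g120 = 0,
                                            prevalence = 1e-9),
                             seed = 2)
  coh <- generate_cohort(params)
  expect_equal(sum(attr(coh, "truth")$fu_event), 0L)
})

test_that("a strong curve-height coefficient raises glucose FPC1 in the event group", {
  params <- generator_params(n = 2000, followup_fraction = 1,
                             outcome = list(beta_height = 2, beta_g120 = 0,
                                            prevalence = 0.15),
                             seed = 10)
  coh <- generate_cohort(params)
  tr <- attr(coh, "truth")
  G <- as.matrix(coh[paste0("glucose_", c(0, 30, 60, 90, 120))])
  cs <- fit_curves(G, default_basis, lambda = 10, analyte = "glucose")
  z1 <- fpc_scores(fit_fpca(cs), cs)[, 1]
  expect_gt(mean(z1[tr$fu_event]) - mean(z1[!tr$fu_event]), 0)
  # and the latent driver separates cleanly
  expect_gt(mean(tr$latent_height[tr$fu_event]),
            mean(tr$latent_height[!tr$fu_event]))
})

test_that("follow-up outcome is independent of baseline fasting glucose by construction", {
  coh <- generate_cohort(generator_params(n = 3000, followup_fraction = 1, seed = 20))
  tr <- attr(coh, "truth")
  auc <- roc_auc(coh$glucose_0, tr$fu_event)$auc
  expect_lt(abs(auc - 0.5), 0.05)
})
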