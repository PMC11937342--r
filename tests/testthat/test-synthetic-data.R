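test_that("the reference panel honours its factor structure, bounds and
           seed", {
  one <- gen_reference_panel(K = 6, n_ref = 400, n_factors = 1,
                             loadings = matrix(8, 6, 1), noise_sd = 2,
                             seed = 111)
  sm <- build_similarity_matrix(one)
  off <- sm$entries[upper.tri(sm$entries)]
  expect_true(all(off > 0.8))  # single strong factor ties all traits

  p1 <- gen_reference_panel(K = 10, n_ref = 50, seed = 112)
  p2 <- gen_reference_panel(K = 10, n_ref = 50, seed = 112)
  expect_identical(p1$values, p2$values)
  expect_true(all(p1$values >= 1 & p1$values <= 100))
  expect_error(gen_reference_panel(K = 3, n_factors = 5, seed = 1),
               "more factors")

  # default settings give a usable mix of signed similarities
  pd <- gen_reference_panel(seed = 113)
  smd <- build_similarity_matrix(pd)
  offd <- smd$entries[upper.tri(smd$entries)]
  expect_gt(sum(offd > 0), 10)
  expect_gt(sum(offd < 0), 10)
})

test_that("survey cohorts expose their generative ground truth", {
  z <- gen_survey_cohort(n_subjects = 30, K = 12,
                         offset_scale_meanlog = -10, noise_sd = 0,
                         blocks = character(0), seed = 114)
  # vanishing offsets force SUD to zero for every subject
  sud <- discrepancy_table(z$tables$self, z$tables$utility)$value
  expect_true(all(sud == 0))

  co <- gen_survey_cohort(n_subjects = 400, seed = 115)
  sud <- discrepancy_table(co$tables$self, co$tables$utility)$value
  # measured SUD tracks the continuous generative truth (rounding and
  # clipping perturb it only slightly)
  expect_gt(cor(sud, co$truth$true_sud), 0.95)
  # every generated table passes the shared validation by construction
  expect_s3_class(co$tables$ideal, "rating_table")
  expect_true(all(co$scores$SCC >= 12 & co$scores$SCC <= 60))
  expect_true(all(co$scores$SE >= 10 & co$scores$SE <= 40))
})

test_that("the survey link is calibrated and switches off cleanly", {
  big <- gen_survey_cohort(n_subjects = 10000, seed = 116)
  sud <- discrepancy_table(big$tables$self, big$tables$utility)$value
  r <- cor(sud, big$scores$SCC)
  expect_equal(r, -0.55, tolerance = 0.05)
  r_se <- cor(big$scores$SE, big$scores$SCC)
  expect_equal(r_se, 0.59, tolerance = 0.06)

  null <- gen_survey_cohort(n_subjects = 10000, a_sud = 0,
                            rho_se_sud = 0, seed = 117)
  sud0 <- discrepancy_table(null$tables$self, null$tables$utility)$value
  expect_lt(abs(cor(sud0, null$scores$SCC)), 0.03)
})

test_that("learning cohorts store their truth and reproduce bit-for-bit", {
  panel <- gen_reference_panel(K = 15, n_ref = 60, seed = 118)
  c1 <- gen_learning_cohort(n_subjects = 5, model_id = 4, panel = panel,
                            n_trials = 15, seed = 119)
  c2 <- gen_learning_cohort(n_subjects = 5, model_id = 4, panel = panel,
                            n_trials = 15, seed = 119)
  expect_identical(lapply(c1$sessions, `[[`, "U"),
                   lapply(c2$sessions, `[[`, "U"))
  expect_equal(colnames(c1$true_params)[-1], c("alpha", "gamma", "sigma"))

  # the no-learning generator at the identity transform copies S
  idsampler <- function(n) cbind(beta0 = rep(0, n), beta1 = rep(1, n),
                                 sigma = rep(1e-12, n))
  c3 <- gen_learning_cohort(n_subjects = 3, model_id = 1, panel = panel,
                            n_trials = 15, param_sampler = idsampler,
                            seed = 120)
  for (s in c3$sessions) expect_equal(s$U, s$S)

  # injected missingness flows through the exclusion rules
  c4 <- gen_learning_cohort(n_subjects = 6, model_id = 2, panel = panel,
                            n_trials = 15, miss_prob = 0.3, seed = 121)
  rep <- apply_exclusions(do.call(rbind, lapply(c4$sessions, `[[`, "U")),
                          threshold = 0.2)
  expect_true(any(!rep$retained))
})
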