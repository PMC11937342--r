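test_that("similarity matrix reproduces column correlations with forced
           unit diagonal", {
  set.seed(31)
  a <- round(runif(40, 20, 80))
  v <- cbind(a = a, b = a, c = 101 - a, d = round(runif(40, 1, 100)))
  rt <- rating_table(v, block = "reference")
  sm <- build_similarity_matrix(rt)
  expect_equal(sm$entries["a", "b"], 1)
  expect_equal(sm$entries["a", "c"], -1)
  expect_equal(unname(diag(sm$entries)), rep(1, 4))
  expect_equal(sm$entries, t(sm$entries))

  # Monte-Carlo under independence: near-zero similarity at n = 5000
  set.seed(32)
  big <- rating_table(matrix(round(runif(10000, 1, 100)), 5000, 2),
                      block = "reference")
  expect_lt(abs(build_similarity_matrix(big)$entries[1, 2]), 0.05)

  const <- rating_table(cbind(x = rep(50, 10), y = 1:10), block = "reference")
  expect_error(build_similarity_matrix(const), "zero-variance.*'x'")
})

test_that("feedback is the panel column mean rounded half-up", {
  rt <- rating_table(cbind(a = c(60, 70, 80), b = c(60, 61, NA),
                           c = c(50, NA, 70)), block = "reference")
  fb <- compute_feedback(rt)
  expect_equal(unname(fb), c(70, 61, 60))  # 60.5 rounds up, NA dropped
  allna <- rating_table(cbind(a = c(NA_real_, NA_real_)), block = "reference")
  expect_error(compute_feedback(allna), "no non-missing")
})

test_that("prediction-error spread follows the worked similarity example", {
  sm <- toy_sim(c("a", "b"), 0.5)
  ses <- learning_session(c("a", "b"), S = c(50, 50), U = c(30, NA),
                          F_fb = c(60, 70))
  tr <- predict_trajectory(2, c(alpha = 1 - 1e-12, sigma = 10), ses, sm)
  expect_equal(tr$PE[1], 30)
  expect_equal(tr$Pm[2], 80 + 30 * 0.5, tolerance = 1e-6)
})

test_that("trajectories agree with the independent plain-R reference for
           all five models", {
  for (seed in 1:4) {
    fx <- random_session(n_trials = 15, seed = seed, miss = 2)
    sim_tt <- fx$sim$entries
    cases <- list(
      list(1, c(beta0 = 12, beta1 = 0.6, sigma = 8)),
      list(2, c(alpha = 0.35, sigma = 8)),
      list(3, c(alpha_plus = 0.4, alpha_minus = 0.15, sigma = 8)),
      list(4, c(alpha = 0.3, gamma = 0.45, sigma = 8)),
      list(5, c(alpha_plus = 0.45, alpha_minus = 0.1, gamma = 0.3,
                sigma = 8)))
    for (cs in cases) {
      got <- predict_trajectory(cs[[1]], cs[[2]], fx$session, fx$sim)
      want <- ref_predict(cs[[1]], cs[[2]], fx$session$S, fx$session$F_fb,
                          fx$session$U, sim_tt, fx$session$p_init_vec)
      expect_equal(got$P, want$P, tolerance = 1e-10)
      expect_equal(got$Pm, want$Pm, tolerance = 1e-10)
      ll <- model_loglik(cs[[1]], cs[[2]], fx$session, fx$sim)
      expect_equal(ll, ref_loglik(cs[[1]], cs[[2]], fx$session, sim_tt),
                   tolerance = 1e-10)
    }
  }
})

test_that("nested models reduce to one another exactly", {
  fx <- random_session(n_trials = 20, seed = 7, miss = 1)
  t2 <- predict_trajectory(2, c(alpha = 0.28, sigma = 9), fx$session, fx$sim)
  t3 <- predict_trajectory(3, c(alpha_plus = 0.28, alpha_minus = 0.28,
                                sigma = 9), fx$session, fx$sim)
  expect_equal(t3$P, t2$P)
  t4 <- predict_trajectory(4, c(alpha = 0.28, gamma = 1e-14, sigma = 9),
                           fx$session, fx$sim)
  expect_equal(t4$P, t2$P, tolerance = 1e-9)
  t5 <- predict_trajectory(5, c(alpha_plus = 0.28, alpha_minus = 0.28,
                                gamma = 1e-14, sigma = 9),
                           fx$session, fx$sim)
  expect_equal(t5$P, t2$P, tolerance = 1e-9)
  t4b <- predict_trajectory(4, c(alpha = 0.31, gamma = 0.4, sigma = 9),
                            fx$session, fx$sim)
  t5b <- predict_trajectory(5, c(alpha_plus = 0.31, alpha_minus = 0.31,
                                 gamma = 0.4, sigma = 9),
                            fx$session, fx$sim)
  expect_equal(t5b$P, t4b$P)
})

test_that("learning boundaries behave as designed", {
  fx <- random_session(n_trials = 10, seed = 5)
  # alpha -> 0: no learning, every Pm stays at the initial prediction
  t0 <- predict_trajectory(2, c(alpha = 1e-14, sigma = 5), fx$session,
                           fx$sim)
  expect_equal(t0$Pm, rep(80, 10), tolerance = 1e-9)
  # gamma -> 1: prediction copies the self-rating
  t1 <- predict_trajectory(4, c(alpha = 0.3, gamma = 1 - 1e-14, sigma = 5),
                           fx$session, fx$sim)
  expect_equal(t1$P, fx$session$S, tolerance = 1e-9)
  # identity similarity: no spread before a trait's own trial
  id_sim <- toy_sim(fx$session$trait, 0)
  tid <- predict_trajectory(2, c(alpha = 0.5, sigma = 5), fx$session, id_sim)
  expect_equal(tid$Pm, rep(80, 10))
  # self-rating initialisation: alpha = 0 pins Pm at the self profile
  ses_self <- learning_session(fx$session$trait, fx$session$S,
                               fx$session$U, fx$session$F_fb,
                               p_init = "self")
  tself <- predict_trajectory(2, c(alpha = 1e-14, sigma = 5), ses_self,
                              fx$sim)
  expect_equal(tself$Pm, fx$session$S, tolerance = 1e-9)
})

test_that("trajectories are invariant to consistent trait relabeling", {
  fx <- random_session(n_trials = 12, seed = 13)
  tr <- predict_trajectory(4, c(alpha = 0.3, gamma = 0.2, sigma = 6),
                           fx$session, fx$sim)
  perm <- sample(12)
  relab <- setNames(paste0("q", seq_len(12)), fx$session$trait)
  sim2 <- fx$sim
  sim2$trait_labels <- unname(relab[sim2$trait_labels])
  dimnames(sim2$entries) <- list(sim2$trait_labels, sim2$trait_labels)
  sim2$entries <- sim2$entries[perm, perm]
  sim2$trait_labels <- sim2$trait_labels[perm]
  ses2 <- learning_session(unname(relab[fx$session$trait]), fx$session$S,
                           fx$session$U, fx$session$F_fb)
  tr2 <- predict_trajectory(4, c(alpha = 0.3, gamma = 0.2, sigma = 6),
                            ses2, sim2)
  expect_equal(tr2$P, tr$P)
})

test_that("log-likelihood matches a hand-computed Gaussian sum and is
           additive over trials", {
  sm <- toy_sim(c("a", "b", "c"), 0)
  ses <- learning_session(c("a", "b", "c"), S = c(40, 60, 50),
                          U = c(70, 85, 90), F_fb = c(50, 50, 50))
  # alpha = 0 so P = 80 on every trial; sigma = 10
  want <- sum(-0.5 * log(2 * pi * 100) - (c(70, 85, 90) - 80)^2 / 200)
  expect_equal(model_loglik(2, c(alpha = 1e-14, sigma = 10), ses, sm),
               want, tolerance = 1e-9)
  # zero residuals: -(T/2) log(2 pi sigma^2)
  ses0 <- learning_session(c("a", "b", "c"), S = c(40, 60, 50),
                           U = c(80, 80, 80), F_fb = c(50, 50, 50))
  expect_equal(model_loglik(2, c(alpha = 1e-14, sigma = 10), ses0, sm),
               -(3 / 2) * log(2 * pi * 100), tolerance = 1e-9)
  # dropping a response removes exactly that trial's term
  ses1 <- learning_session(c("a", "b", "c"), S = c(40, 60, 50),
                           U = c(70, NA, 90), F_fb = c(50, 50, 50))
  gain <- model_loglik(2, c(alpha = 1e-14, sigma = 10), ses1, sm) -
    model_loglik(2, c(alpha = 1e-14, sigma = 10), ses, sm)
  expect_equal(gain, -(-0.5 * log(2 * pi * 100) - 25 / 200),
               tolerance = 1e-9)
})

test_that("closed-loop simulation is reproducible and honours limits", {
  fx <- random_session(n_trials = 10, seed = 3)
  frame <- list(trait = fx$session$trait, S = fx$session$S,
                F_fb = fx$session$F_fb)
  s1 <- simulate_subject(2, c(alpha = 0.3, sigma = 8), frame, fx$sim,
                         seed = 42)
  s2 <- simulate_subject(2, c(alpha = 0.3, sigma = 8), frame, fx$sim,
                         seed = 42)
  s3 <- simulate_subject(2, c(alpha = 0.3, sigma = 8), frame, fx$sim,
                         seed = 43)
  expect_identical(s1$U, s2$U)
  expect_false(identical(s1$U, s3$U))
  expect_true(all(s1$U >= 1 & s1$U <= 100 & s1$U == round(s1$U)))

  # sigma = 0 under model 2: responses equal the clipped rounded P
  s0 <- simulate_subject(2, c(alpha = 0.3, sigma = 1e-12), frame, fx$sim,
                         seed = 1)
  tr <- attr(s0, "trace")
  expect_equal(s0$U, pmin(pmax(round(tr$P), 1), 100))
  # gamma = 1 self-copy limit
  sg <- simulate_subject(4, c(alpha = 0.3, gamma = 1 - 1e-13,
                              sigma = 1e-12), frame, fx$sim, seed = 1)
  expect_equal(sg$U, frame$S)
})

test_that("session CSVs round-trip", {
  fx1 <- random_session(8, seed = 61, miss = 1)
  fx2 <- random_session(8, seed = 62)
  s1 <- fx1$session; s1$subject_id <- "p1"
  s2 <- fx2$session; s2$subject_id <- "p2"
  path <- withr::local_tempfile(fileext = ".csv")
  write_sessions(list(s1, s2), path)
  back <- read_sessions(path)
  expect_equal(back$p1$U, s1$U)
  expect_equal(back$p2$trait, s2$trait)
  sp <- withr::local_tempfile(fileext = ".csv")
  write_similarity_matrix(fx1$sim, sp)
  simback <- read_similarity_matrix(sp)
  expect_equal(simback$entries, fx1$sim$entries, tolerance = 1e-12)
})
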