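test_that("Fisher-z interval behaves at the boundaries and narrows with n", {
  expect_warning(res <- pearson_with_ci(x = 1:10, y = 1:10), "degenerate")
  expect_equal(c(res$ci_lower, res$ci_upper), c(1, 1))
  sym <- pearson_with_ci(r = 0, n = 103)
  expect_equal(sym$ci_lower, -sym$ci_upper, tolerance = 1e-12)
  widths <- sapply(c(20, 50, 200, 1000), function(n) {
    ci <- pearson_with_ci(r = 0.4, n = n)
    ci$ci_upper - ci$ci_lower
  })
  expect_true(all(diff(widths) < 0))
})

test_that("Fisher interval covers the true correlation at the nominal
           rate", {
  set.seed(101)
  rho <- 0.45; n <- 40; reps <- 10000
  covered <- logical(reps)
  for (i in seq_len(reps)) {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    ci <- pearson_with_ci(x, y)
    covered[i] <- ci$ci_lower <= rho && rho <= ci$ci_upper
  }
  expect_equal(mean(covered), 0.95, tolerance = 0.011)
})

test_that("hierarchical regression from raw data matches the
           correlation-matrix mode and the normal equations", {
  set.seed(102)
  n <- 120
  x1 <- rnorm(n); x2 <- 0.5 * x1 + rnorm(n)
  y <- 0.8 * x1 - 0.4 * x2 + rnorm(n)
  d <- data.frame(y = y, x1 = x1, x2 = x2)
  raw <- hierarchical_regression(d, "y", base = "x1", added = "x2")
  R <- cor(d)
  mat <- hierarchical_regression(outcome = "y", base = "x1", added = "x2",
                                 cormat = R, n = n)
  expect_equal(raw$full$r_squared, mat$full$r_squared, tolerance = 1e-10)
  expect_equal(raw$f_change, mat$f_change, tolerance = 1e-10)
  expect_equal(raw$full$coefficients$beta, mat$full$coefficients$beta,
               tolerance = 1e-10)

  # normal-equation oracle on standardized variables
  Z <- scale(as.matrix(d))
  beta_ref <- solve(crossprod(Z[, 2:3]), crossprod(Z[, 2:3], Z[, 1]))
  expect_equal(raw$full$coefficients$beta, as.numeric(beta_ref),
               tolerance = 1e-10)

  # an orthogonal useless addition yields a zero R2 change
  x3 <- residuals(lm(rnorm(n) ~ y + x1))
  d$x3 <- x3
  null_add <- hierarchical_regression(d, "y", base = "x1", added = "x3")
  expect_lt(null_add$delta_r2, 1e-12)
})

test_that("commonality components sum to the full R2 and vanish for
           orthogonal predictors", {
  # brute-force subset oracle on a random 3-predictor instance
  set.seed(103)
  n <- 90
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- X %*% c(0.5, -0.3, 0.2) + rnorm(n)
  d <- data.frame(y = y, X)
  cm <- commonality(d, "y", c("a", "b", "c"))
  expect_equal(nrow(cm$components), 7)
  expect_equal(sum(cm$components$component), cm$total_r2,
               tolerance = 1e-10)
  r2_full <- summary(lm(y ~ a + b + c, d))$r.squared
  r2_wo_a <- summary(lm(y ~ b + c, d))$r.squared
  expect_equal(unname(cm$unique["a"]), r2_full - r2_wo_a,
               tolerance = 1e-10)

  # exactly uncorrelated predictors: no common variance
  R <- diag(3); dimnames(R) <- list(c("y", "p", "q"), c("y", "p", "q"))
  R["y", "p"] <- R["p", "y"] <- 0.5
  R["y", "q"] <- R["q", "y"] <- -0.3
  cm0 <- commonality(outcome = "y", predictors = c("p", "q"),
                     cormat = R, n = 200)
  expect_equal(unname(cm0$unique), c(0.25, 0.09), tolerance = 1e-12)
  expect_equal(cm0$components$component[cm0$components$size == 2], 0,
               tolerance = 1e-12)
})

test_that("variance inflation factors match the closed form and flag
           collinearity", {
  expect_equal(unname(vif(cormat = diag(3))), rep(1, 3))
  set.seed(107)
  X <- qr.Q(qr(matrix(rnorm(300), 100, 3)))  # near-orthogonal columns
  expect_equal(unname(vif(X)), rep(1, 3), tolerance = 1e-3)

  R <- matrix(c(1, 0.71, 0.71, 1), 2)
  expect_equal(unname(vif(cormat = R)), rep(1 / (1 - 0.71^2), 2),
               tolerance = 1e-12)

  set.seed(104)
  Xd <- cbind(a = rnorm(50), b = rnorm(50))
  Xd <- cbind(Xd, c = Xd[, "a"])
  expect_warning(v <- vif(Xd), "collinearity")
  expect_true(is.infinite(v[["a"]]) && is.infinite(v[["c"]]))
})

test_that("BIC subset selection finds the generating predictor and
           punishes pure noise", {
  set.seed(105)
  hits <- 0L
  for (i in 1:10) {
    n <- 300
    d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
    d$y <- 0.8 * d$x1 + rnorm(n)
    rank <- best_subset_bic(d, "y", c("x1", "x2", "x3"))
    if (rank$predictors[1] == "x1") hits <- hits + 1L
    with_true <- rank$bic[rank$predictors == "x1"]
    with_noise <- rank$bic[rank$predictors == "x1 + x2"]
    expect_gt(with_noise, with_true)
  }
  expect_gte(hits, 9L)
  d0 <- data.frame(y = rnorm(30))
  expect_equal(best_subset_bic(d0, "y", character(0))$predictors,
               "(intercept only)")
})

test_that("the prediction-error trend test detects learning and stays
           calibrated under permutation", {
  set.seed(106)
  make_sessions <- function(decreasing, n_sub = 20, T_ = 50) {
    lapply(seq_len(n_sub), function(i) {
      mu <- if (decreasing) 25 - 0.3 * seq_len(T_) else rep(12, T_)
      U <- pmin(pmax(round(50 + mu * sample(c(-1, 1), T_, TRUE) +
                             rnorm(T_, 0, 4)), 1), 100)
      learning_session(paste0("t", seq_len(T_)),
                       S = rep(50, T_), U = U, F_fb = rep(50, T_),
                       subject_id = paste0("s", i))
    })
  }
  trend <- pe_trend_test(make_sessions(TRUE))
  expect_lt(trend$p, 0.01)
  expect_equal(trend$slope_sign, -1)

  # permutation null: p-values approximately uniform across seeds
  base <- make_sessions(TRUE, n_sub = 8, T_ = 40)
  pvals <- sapply(1:60, function(k) {
    perm <- lapply(base, function(s) {
      idx <- sample(s$n_trials)
      learning_session(s$trait, s$S, s$U[idx], s$F_fb,
                       subject_id = s$subject_id)
    })
    pe_trend_test(perm)$p
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)

  flat <- lapply(1:4, function(i)
    learning_session(paste0("t", 1:20), rep(50, 20),
                     U = rep(60, 20), F_fb = rep(50, 20),
                     subject_id = paste0("s", i)))
  expect_equal(pe_trend_test(flat)$p, 1)
})
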