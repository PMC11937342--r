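test_that("profile distances match hand arithmetic and handle missingness", {
  expect_equal(profile_distance(c(10, 40, 70), c(20, 20, 100))$value, 20)
  expect_equal(profile_distance(c(5, 5), c(5, 5))$value, 0)
  expect_equal(profile_distance(c(5, 5), c(5, 5), "euclidean")$value, 0)

  res <- profile_distance(c(10, NA, 30), c(20, 50, NA))
  expect_equal(res$value, 10)
  expect_equal(res$n_pairs_used, 1)
  expect_error(profile_distance(c(NA, NA), c(1, 2)), "no usable")
  expect_error(profile_distance(c(1, 2), c(5, 5), "pearson"),
               "zero-variance")
})

test_that("distance metrics are symmetric, translation-sensitive, and only
           the correlation variant is scale-free", {
  set.seed(11)
  s <- round(runif(20, 1, 100)); u <- round(runif(20, 1, 100))
  expect_equal(profile_distance(s, u)$value, profile_distance(u, s)$value)
  expect_equal(profile_distance(s, u, "euclidean")$value,
               profile_distance(u, s, "euclidean")$value)
  # shifting the dominating profile up by c raises the mean |diff| by c
  u2 <- pmax(s, u)
  expect_equal(profile_distance(s, pmin(u2 + 7, 1e9))$value,
               profile_distance(s, u2)$value + 7)
  # positive affine transform: correlation invariant, distances not
  expect_equal(profile_distance(s, 0.5 * u + 10, "pearson")$value,
               profile_distance(s, u, "pearson")$value)
  expect_false(isTRUE(all.equal(profile_distance(s, 0.5 * u + 10)$value,
                                profile_distance(s, u)$value)))
})

test_that("table-level discrepancies respect alignment and known offsets", {
  set.seed(21)
  self <- matrix(sample(30:70, 40, TRUE), 4, 10)
  delta <- matrix(sample(c(-12, -5, 0, 4, 9), 40, TRUE), 4, 10)
  t_self <- rating_table(self, block = "self")
  t_util <- rating_table(self + delta, subject_ids = t_self$subject_ids,
                         trait_labels = t_self$trait_labels,
                         block = "utility")
  res <- discrepancy_table(t_self, t_util)
  expect_equal(res$value, rowMeans(abs(delta)))  # oracle: stored offsets

  # identical tables: all zero
  expect_true(all(discrepancy_table(t_self, t_self)$value == 0))

  # consistent column permutation leaves values unchanged
  perm <- sample(10)
  t_self_p <- rating_table(self[, perm],
                           subject_ids = t_self$subject_ids,
                           trait_labels = t_self$trait_labels[perm],
                           block = "self")
  t_util_p <- rating_table((self + delta)[, perm],
                           subject_ids = t_self$subject_ids,
                           trait_labels = t_self$trait_labels[perm],
                           block = "utility")
  expect_equal(discrepancy_table(t_self_p, t_util_p)$value, res$value)

  bad <- rating_table(self, trait_labels = paste0("x", 1:10), block = "utility")
  expect_error(discrepancy_table(t_self, bad), "trait labels")

  # a degenerate subject yields NA with a reason, not an error
  v <- self
  v[2, ] <- NA
  t_na <- rating_table(v, subject_ids = t_self$subject_ids,
                       trait_labels = t_self$trait_labels, block = "self")
  res2 <- discrepancy_table(t_na, t_util)
  expect_true(is.na(res2$value[2]) && !is.na(res2$note[2]))
})
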