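#' Pearson correlation with Fisher-z confidence interval
#'
#' Computes r (from raw data or from a reported summary `r`, `n`), a
#' two-sided t-test p-value, and the Fisher-z confidence interval
#' `tanh(atanh(r) +/- z * / sqrt(n - 3))`.
#'
#' @param x,y Raw numeric vectors, or `NULL` when summary input is used.
#' @param r,n Summary input: a correlation and its sample size.
#' @param level Confidence level (default 0.95).
#' @return One-row data frame: `r`, `n`, `df`, `ci_lower`, `ci_upper`,
#'   `p`.
#' @examples
#' pearson_with_ci(r = -0.566, n = 155)
#' @export
pearson_with_ci <- function(x = NULL, y = NULL, r = NULL, n = NULL,
                            level = 0.95) {
  if (!is.null(x) && !is.null(y)) {
    ok <- complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 4L) stop("need at least 4 complete pairs", call. = FALSE)
    if (sd(x) == 0 || sd(y) == 0) stop("zero-variance input", call. = FALSE)
    r <- cor(x, y)
  } else if (is.null(r) || is.null(n)) {
    stop("supply raw vectors x, y or summary r, n", call. = FALSE)
  }
  if (abs(r) >= 1 - 1e-12) {
    warning("|r| = 1: degenerate confidence interval", call. = FALSE)
    r <- sign(r)
    return(data.frame(r = r, n = n, df = n - 2L, ci_lower = r,
                      ci_upper = r, p = 0))
  }
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- qnorm(1 - (1 - level) / 2)
  ci <- tanh(z + c(-1, 1) * q * se)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  data.frame(r = r, n = n, df = n - 2L, ci_lower = ci[1L],
             ci_upper = ci[2L], p = p)
}

# ---- internal: standardized OLS either from raw data or a correlation
# matrix ----

# R2 and standardized coefficients for `outcome ~ predictors` given the
# full correlation matrix.
ols_from_cormat <- function(R, n, outcome, predictors) {
  stopifnot(outcome %in% rownames(R), all(predictors %in% rownames(R)))
  p <- length(predictors)
  if (p == 0L) {
    return(list(beta = numeric(0), r2 = 0, predictors = character(0),
                n = n, p = 0L))
  }
  Rxx <- R[predictors, predictors, drop = FALSE]
  rxy <- R[predictors, outcome]
  Rinv <- tryCatch(solve(Rxx), error = function(e)
    stop("singular predictor correlation matrix (exact collinearity?)",
         call. = FALSE))
  beta <- as.numeric(Rinv %*% rxy)
  r2 <- sum(beta * rxy)
  se <- sqrt((1 - r2) / (n - p - 1) * diag(Rinv))
  tt <- beta / se
  list(beta = setNames(beta, predictors), se = setNames(se, predictors),
       t = setNames(tt, predictors),
       p_coef = setNames(2 * pt(-abs(tt), n - p - 1), predictors),
       r2 = r2, n = n, p = p, predictors = predictors)
}

cormat_from_raw <- function(data, vars) {
  m <- as.matrix(data[, vars, drop = FALSE])
  if (anyNA(m)) {
    keep <- complete.cases(m)
    m <- m[keep, , drop = FALSE]
  }
  list(R = cor(m), n = nrow(m))
}

summarise_model <- function(fitted, level = 0.95) {
  q <- qnorm(1 - (1 - level) / 2)
  n <- fitted$n; p <- fitted$p; r2 <- fitted$r2
  adj <- if (p > 0) 1 - (1 - r2) * (n - 1) / (n - p - 1) else 0
  Fstat <- if (p > 0) (r2 / p) / ((1 - r2) / (n - p - 1)) else NA_real_
  list(coefficients = if (p > 0) data.frame(
         predictor = fitted$predictors, beta = unname(fitted$beta),
         se = unname(fitted$se),
         ci_lower = unname(fitted$beta - q * fitted$se),
         ci_upper = unname(fitted$beta + q * fitted$se),
         t = unname(fitted$t), p = unname(fitted$p_coef),
         stringsAsFactors = FALSE) else NULL,
       r_squared = r2, adj_r_squared = adj, f = Fstat,
       df1 = p, df2 = n - p - 1, n = n,
       p_value = if (p > 0) pf(Fstat, p, n - p - 1, lower.tail = FALSE)
                 else NA_real_)
}

#' Hierarchical regression with R-squared change test
#'
#' Fits a base model `outcome ~ base` and a full model
#' `outcome ~ base + added` on standardized variables (both outcome and
#' predictors standardized), and tests the improvement with
#' `F_change = dR2 / ((1 - R2_full) / (n - p_full - 1))` on
#' `(k_added, n - p_full - 1)` degrees of freedom. Accepts either raw
#' data or a printed correlation matrix with its sample size, in which
#' case every quantity is computed from the matrix alone.
#'
#' @param data Data frame containing the variables (raw mode).
#' @param outcome Outcome variable name.
#' @param base Character vector of base-model predictors.
#' @param added Character vector of predictors added in the full model.
#' @param cormat Correlation matrix with variable names (matrix mode).
#' @param n Sample size (matrix mode).
#' @param level Confidence level for coefficient intervals.
#' @return List of class `hierarchical_regression`: `base` and `full`
#'   model summaries (standardized coefficients, R2, adjusted R2, F,
#'   VIF for the full model), `delta_r2`, `f_change`, `df_change`,
#'   `p_change`.
#' @export
hierarchical_regression <- function(data = NULL, outcome, base, added,
                                    cormat = NULL, n = NULL,
                                    level = 0.95) {
  vars <- c(outcome, base, added)
  if (is.null(cormat)) {
    if (is.null(data)) stop("supply data or cormat + n", call. = FALSE)
    cc <- cormat_from_raw(data, vars)
    cormat <- cc$R; n <- cc$n
  }
  p_full <- length(base) + length(added)
  if (n <= p_full + 1) stop("too few observations", call. = FALSE)
  fit_base <- ols_from_cormat(cormat, n, outcome, base)
  fit_full <- ols_from_cormat(cormat, n, outcome, c(base, added))
  d_r2 <- fit_full$r2 - fit_base$r2
  k <- length(added)
  df2 <- n - p_full - 1
  f_change <- (d_r2 / k) / ((1 - fit_full$r2) / df2)
  out <- list(base = summarise_model(fit_base, level),
              full = summarise_model(fit_full, level),
              delta_r2 = d_r2, f_change = f_change,
              df_change = c(k, df2),
              p_change = pf(f_change, k, df2, lower.tail = FALSE),
              vif = vif(cormat = cormat[c(base, added), c(base, added),
                                        drop = FALSE]))
  class(out) <- "hierarchical_regression"
  out
}

#' @export
print.hierarchical_regression <- function(x, ...) {
  cat(sprintf("Base model:  R2 = %.3f (adj %.3f), F(%d, %d) = %.2f\n",
              x$base$r_squared, x$base$adj_r_squared, x$base$df1,
              x$base$df2, x$base$f))
  cat(sprintf("Full model:  R2 = %.3f (adj %.3f), F(%d, %d) = %.2f\n",
              x$full$r_squared, x$full$adj_r_squared, x$full$df1,
              x$full$df2, x$full$f))
  cat(sprintf("Change:      dR2 = %.3f, F(%d, %d) = %.3f, p = %.3g\n",
              x$delta_r2, x$df_change[1L], x$df_change[2L], x$f_change,
              x$p_change))
  invisible(x)
}

#' Commonality analysis (variance partitioning)
#'
#' Decomposes the full-model R-squared into unique components (one per
#' predictor) and common components (one per predictor subset of size
#' >= 2) via the all-subsets inclusion--exclusion identity
#' \deqn{C(A) = -\sum_{X \subseteq A} (-1)^{|A| - |X|} R^2(U \setminus X),}
#' so that all `2^p - 1` components sum exactly to the full R-squared.
#' Accepts raw data or a printed correlation matrix.
#'
#' @inheritParams hierarchical_regression
#' @param predictors Character vector of predictor names (p >= 2,
#'   p <= 12 for the exhaustive enumeration).
#' @return List of class `commonality_result`: `components` data frame
#'   (`subset`, `size`, `component`), `unique` named vector,
#'   `total_r2`, `adj_r2`, `n`.
#' @export
commonality <- function(data = NULL, outcome, predictors, cormat = NULL,
                        n = NULL) {
  p <- length(predictors)
  if (p < 2L) stop("commonality needs at least 2 predictors", call. = FALSE)
  if (p > 12L) stop("exhaustive enumeration capped at 12 predictors",
                    call. = FALSE)
  vars <- c(outcome, predictors)
  if (is.null(cormat)) {
    if (is.null(data)) stop("supply data or cormat + n", call. = FALSE)
    cc <- cormat_from_raw(data, vars)
    cormat <- cc$R; n <- cc$n
  }
  ev <- eigen(cormat[predictors, predictors], symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) <= 1e-12) stop("predictor correlation matrix is not positive definite",
                             call. = FALSE)

  n_sets <- bitwShiftL(1L, p) - 1L
  r2 <- numeric(n_sets + 1L)  # r2[mask + 1]; empty set = 0
  for (mask in seq_len(n_sets)) {
    sel <- predictors[bitwAnd(bitwShiftR(mask, seq_len(p) - 1L), 1L) == 1L]
    r2[mask + 1L] <- ols_from_cormat(cormat, n, outcome, sel)$r2
  }
  full_mask <- n_sets
  comp <- numeric(n_sets)
  subset_label <- character(n_sets)
  subset_size <- integer(n_sets)
  for (a in seq_len(n_sets)) {
    bits_a <- which(bitwAnd(bitwShiftR(a, seq_len(p) - 1L), 1L) == 1L)
    acc <- 0
    # iterate over submasks x of a
    x <- a
    repeat {
      sgn <- (-1)^(length(bits_a) - sum(bitwAnd(bitwShiftR(x, seq_len(p) - 1L), 1L)))
      acc <- acc + sgn * r2[bitwAnd(full_mask, bitwNot(x)) + 1L]
      if (x == 0L) break
      x <- bitwAnd(x - 1L, a)
    }
    comp[a] <- -acc
    subset_label[a] <- paste(predictors[bits_a], collapse = " & ")
    subset_size[a] <- length(bits_a)
  }
  total <- r2[full_mask + 1L]
  uniq <- comp[bitwShiftL(1L, seq_len(p) - 1L)]
  names(uniq) <- predictors
  out <- list(components = data.frame(subset = subset_label,
                                      size = subset_size,
                                      component = comp,
                                      stringsAsFactors = FALSE),
              unique = uniq, total_r2 = total,
              adj_r2 = 1 - (1 - total) * (n - 1) / (n - p - 1), n = n)
  class(out) <- "commonality_result"
  out
}

#' @export
print.commonality_result <- function(x, ...) {
  cat(sprintf("Commonality analysis: total R2 = %.4f (adj %.4f), n = %d\n",
              x$total_r2, x$adj_r2, x$n))
  print(transform(x$components, component = round(component, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` regresses predictor j on the
#' remaining predictors. Exactly collinear predictors are reported as
#' `Inf`.
#'
#' @param X Numeric matrix or data frame of predictors, or `NULL`.
#' @param cormat Predictor correlation matrix (alternative input).
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(X = NULL, cormat = NULL) {
  if (is.null(cormat)) {
    if (is.null(X)) stop("supply X or cormat", call. = FALSE)
    X <- as.matrix(X)
    if (ncol(X) < 2L) stop("need at least 2 predictors", call. = FALSE)
    sds <- apply(X, 2L, sd)
    if (any(sds == 0)) stop("constant predictor column", call. = FALSE)
    cormat <- cor(X)
  }
  p <- ncol(cormat)
  if (p < 2L) stop("need at least 2 predictors", call. = FALSE)
  labs <- colnames(cormat)
  if (is.null(labs)) labs <- paste0("x", seq_len(p))
  out <- setNames(numeric(p), labs)
  inv <- tryCatch(solve(cormat), error = function(e) NULL)
  if (!is.null(inv) && all(diag(inv) > 0) && min(eigen(cormat, symmetric = TRUE,
      only.values = TRUE)$values) > 1e-10) {
    out[] <- diag(inv)
  } else {
    warning("exact collinearity: infinite VIF flagged", call. = FALSE)
    for (j in seq_len(p)) {
      r2j <- ols_from_cormat_safe(cormat, j)
      out[j] <- if (r2j >= 1 - 1e-10) Inf else 1 / (1 - r2j)
    }
  }
  out
}

# R2 of predictor j on the others, tolerant of singular blocks
# (minimum-norm solution via the pseudo-inverse).
ols_from_cormat_safe <- function(R, j) {
  others <- setdiff(seq_len(ncol(R)), j)
  Rxx <- R[others, others, drop = FALSE]
  rxy <- R[others, j]
  sv <- svd(Rxx)
  pos <- sv$d > 1e-10 * sv$d[1L]
  beta <- sv$v[, pos, drop = FALSE] %*%
    (crossprod(sv$u[, pos, drop = FALSE], rxy) / sv$d[pos])
  min(sum(beta * rxy), 1)
}

#' Best-subset regression ranked by BIC
#'
#' Exhaustively fits OLS for every subset of candidate predictors
#' (intercept always included) and ranks by
#' `BIC = n log(RSS / n) + k log(n)` with `k` counting the predictors,
#' the intercept and the error variance.
#'
#' @param data Data frame with outcome and candidates.
#' @param outcome Outcome variable name.
#' @param candidates Character vector of candidate predictors (<= 15).
#' @return Data frame ranked by BIC: `predictors`, `size`, `bic`, `r2`,
#'   `adj_r2`.
#' @export
best_subset_bic <- function(data, outcome, candidates) {
  p <- length(candidates)
  if (p > 15L) stop("exhaustive enumeration capped at 15 candidates",
                    call. = FALSE)
  df <- data[complete.cases(data[, c(outcome, candidates), drop = FALSE]), ,
             drop = FALSE]
  y <- df[[outcome]]
  n <- length(y)
  rows <- list()
  for (mask in 0:(bitwShiftL(1L, p) - 1L)) {
    sel <- if (p > 0L) {
      candidates[bitwAnd(bitwShiftR(mask, seq_len(p) - 1L), 1L) == 1L]
    } else character(0)
    k <- length(sel) + 2L  # predictors + intercept + error variance
    if (n <= k) next
    X <- cbind(1, as.matrix(df[, sel, drop = FALSE]))
    fit <- lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    r2 <- 1 - rss / sum((y - mean(y))^2)
    rows[[length(rows) + 1L]] <- data.frame(
      predictors = if (length(sel)) paste(sel, collapse = " + ")
                   else "(intercept only)",
      size = length(sel),
      bic = n * log(rss / n) + k * log(n),
      r2 = r2,
      adj_r2 = 1 - (1 - r2) * (n - 1) / (n - length(sel) - 1),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(out$bic), , drop = FALSE]
}

#' Temporal trend test on absolute prediction errors
#'
#' Checks whether |PE| changes over the course of the learning session —
#' the signature of learning — by regressing |PE| on a cubic B-spline
#' basis of trial number (interior knots at trial quantiles) with
#' subject fixed intercepts, and F-testing the spline block against the
#' intercepts-only model. This is a fixed-knot simplification of a
#' penalized smooth-trend (GAM) analysis.
#'
#' @param sessions List of [learning_session()]s with responses.
#' @param n_knots Number of interior knots (default 3).
#' @return One-row data frame: `f`, `df1`, `df2`, `p`, `n_obs`, plus
#'   `slope_sign` (sign of the linear trend, for direction).
#' @export
pe_trend_test <- function(sessions, n_knots = 3) {
  rows <- lapply(sessions, function(s) {
    pe <- s$F_fb - s$U
    ok <- !is.na(pe)
    data.frame(subject = s$subject_id, trial = which(ok),
               abs_pe = abs(pe[ok]), stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  if (nrow(d) < 10L) stop("need at least 10 trials with defined |PE|",
                          call. = FALSE)
  if (var(d$abs_pe) == 0) {
    return(data.frame(f = 0, df1 = NA_real_, df2 = NA_real_, p = 1,
                      n_obs = nrow(d), slope_sign = 0))
  }
  knots <- unique(quantile(d$trial, probs = seq_len(n_knots) / (n_knots + 1)))
  B <- splines::bs(d$trial, knots = knots, degree = 3)
  multi <- length(unique(d$subject)) > 1L
  m0 <- if (multi) lm(abs_pe ~ factor(subject), data = d)
        else lm(abs_pe ~ 1, data = d)
  m1 <- if (multi) lm(abs_pe ~ factor(subject) + B, data = d)
        else lm(abs_pe ~ B, data = d)
  a <- anova(m0, m1)
  slope <- coef(lm(abs_pe ~ trial, data = d))[["trial"]]
  data.frame(f = a$F[2L], df1 = a$Df[2L], df2 = a$Res.Df[2L],
             p = a$`Pr(>F)`[2L], n_obs = nrow(d),
             slope_sign = sign(slope))
}
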