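# Variational Dirichlet update for random-effects model comparison.
# Given an n x M log-evidence matrix, iterates responsibilities
# u_nm ∝ exp(logev_nm + E[log f_m]) and concentrations alpha = alpha0 +
# colSums(u) to convergence, and returns the variational free energy of
# the random-effects model (used for the Bayes omnibus risk).
vb_dirichlet <- function(logev, alpha0 = 1, tol = 1e-8, max_iter = 500) {
  logev <- clamp_logev(logev)
  n <- nrow(logev); M <- ncol(logev)
  a0 <- rep_len(alpha0, M)
  alpha <- a0 + n / M
  for (it in seq_len(max_iter)) {
    elogf <- digamma(alpha) - digamma(sum(alpha))
    w <- sweep(logev, 2L, elogf, "+")
    w <- w - apply(w, 1L, max)
    u <- exp(w)
    u <- u / rowSums(u)
    alpha_new <- a0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  elogf <- digamma(alpha) - digamma(sum(alpha))
  # free energy of the random-effects model
  u_safe <- pmax(u, 1e-300)
  F1 <- sum(u * logev) + sum(u %*% elogf) - sum(u * log(u_safe)) +
    lgamma(sum(a0)) - sum(lgamma(a0)) + sum((a0 - 1) * elogf) -
    (lgamma(sum(alpha)) - sum(lgamma(alpha)) + sum((alpha - 1) * elogf))
  list(alpha = alpha, u = u, free_energy = F1)
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Failed subject fits report -Inf evidence; map them to a value far
# below the worst finite evidence so the Dirichlet layer stays finite.
clamp_logev <- function(logev) {
  bad <- !is.finite(logev)
  if (any(bad)) {
    floor_val <- if (all(bad)) -1e6 else min(logev[!bad]) - 1000
    logev[bad] <- floor_val
  }
  logev
}

#' Exceedance and protected exceedance probabilities
#'
#' Given the Dirichlet posterior over population model frequencies, the
#' exceedance probability `EP_m` is the posterior probability that model
#' m is the most frequent, estimated from Monte-Carlo Dirichlet draws.
#' The Bayes omnibus risk `BOR` is the posterior probability of the null
#' hypothesis that all models are equally frequent, obtained by
#' comparing the free energy of the random-effects model against the
#' equal-frequency null on the same subject-level evidences. The
#' protected exceedance probability shrinks EP towards chance:
#' `PXP_m = EP_m (1 - BOR) + BOR / M`.
#'
#' @param concentrations Positive Dirichlet concentration vector
#'   (length M >= 2).
#' @param logev Optional n x M matrix of subject-level log evidences;
#'   required for `BOR`/`PXP`.
#' @param n_draws Monte-Carlo sample size for EP (default 1e5).
#' @param seed Optional seed for the draws.
#' @param alpha0 Prior concentration (default 1 per model).
#' @return List with `ep`, `bor`, `pxp` (and the draws' `n_draws`).
#' @examples
#' protected_exceedance(c(3, 1))$ep[1]  # ~ 1 - 0.5^3 = 0.875
#' @export
protected_exceedance <- function(concentrations, logev = NULL,
                                 n_draws = 1e5, seed = NULL, alpha0 = 1) {
  M <- length(concentrations)
  if (M < 2L) stop("need at least two models", call. = FALSE)
  if (any(concentrations <= 0)) stop("concentrations must be positive",
                                     call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  g <- matrix(rgamma(n_draws * M, shape = rep(concentrations,
                                              each = n_draws)),
              nrow = n_draws)
  ep <- tabulate(max.col(g, ties.method = "random"), nbins = M) / n_draws
  bor <- NA_real_
  pxp <- rep(NA_real_, M)
  if (!is.null(logev)) {
    logev <- clamp_logev(as.matrix(logev))
    if (ncol(logev) != M) stop("logev has the wrong number of models",
                               call. = FALSE)
    f1 <- vb_dirichlet(logev, alpha0 = alpha0)$free_energy
    f0 <- sum(apply(logev, 1L, log_sum_exp) - log(M))
    bor <- 1 / (1 + exp(f1 - f0))
    pxp <- ep * (1 - bor) + bor / M
  }
  list(ep = ep, bor = bor, pxp = pxp, n_draws = n_draws)
}

#' Hierarchical (random-effects) fit across subjects and models
#'
#' Empirical-Bayes scheme approximating hierarchical Bayesian inference
#' with model identity as a random effect:
#'
#' 1. Fit every subject under every model by MAP with a wide Gaussian
#'    prior in transformed space; obtain Laplace log evidences.
#' 2. E-step: responsibilities of each model for each subject,
#'    proportional to `exp(log-evidence + E[log model frequency])`, with
#'    Dirichlet concentrations `alpha_m = alpha0 + sum_n u_nm`. The
#'    evidences entering this step are the ones obtained under the
#'    shared wide prior: comparing models on a common fixed prior keeps
#'    the complexity penalty between nested models intact (a group
#'    prior re-tuned on the same data would let the richer model evade
#'    it).
#' 3. M-step: each model's group prior mean and variance are updated as
#'    responsibility-weighted moments of the subject-level posteriors
#'    (MAP plus Laplace variance), regularised by one pseudo-subject at
#'    the initial wide prior; subjects are then refit under the updated
#'    group priors (warm-started), which regularises the individual
#'    parameter estimates.
#' 4. Iterate the refit/M-step sweep to convergence of the group means,
#'    then compute exceedance and protected exceedance probabilities
#'    from the Dirichlet posterior.
#'
#' @param models Vector of model ids or list of [model_spec()]s.
#' @param sessions List of [learning_session()]s (>= 2 subjects).
#' @param sim Similarity matrix shared by all sessions.
#' @param config List overriding defaults: `max_iter` (8), `mean_tol`
#'   (0.02 on transformed group means), `n_restarts` (10, first sweep),
#'   `n_restarts_refit` (2, later sweeps), `prior_mean` (0),
#'   `prior_var` (6.25), `alpha0` (1), `n_draws` (1e5), `sigma_fixed`
#'   (NA), `compare_at` ("emitted"), `seed`, `verbose`.
#' @return An object of class `group_fit`: per-model group priors,
#'   subject fits, responsibilities, Dirichlet concentrations, model
#'   frequencies, `ep`, `bor`, `pxp`, log-evidence matrix, convergence
#'   info.
#' @export
fit_hierarchical <- function(models, sessions, sim = NULL,
                             config = list()) {
  cfg <- modifyList(list(max_iter = 8L, mean_tol = 0.02,
                         n_restarts = 10L, n_restarts_refit = 2L,
                         prior_mean = 0, prior_var = 6.25, alpha0 = 1,
                         n_draws = 1e5, sigma_fixed = NA_real_,
                         compare_at = "emitted", seed = NULL,
                         verbose = FALSE), config)
  specs <- lapply(models, as_model_spec)
  M <- length(specs)
  n <- length(sessions)
  if (n < 2L) stop("need at least two subjects", call. = FALSE)
  if (M < 1L) stop("need at least one model", call. = FALSE)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  wide <- lapply(specs, function(sp)
    default_prior(sp, cfg$prior_mean, cfg$prior_var))
  priors <- wide
  fits <- vector("list", M)
  logev <- matrix(NA_real_, n, M)
  group_mean_prev <- NULL
  converged <- FALSE
  iters <- 0L
  u <- NULL

  for (iter in seq_len(cfg$max_iter)) {
    iters <- iter
    restarts <- if (iter == 1L) cfg$n_restarts else cfg$n_restarts_refit
    for (m in seq_len(M)) {
      fits[[m]] <- lapply(seq_len(n), function(i) {
        fit_subject_map(specs[[m]], sessions[[i]], sim = sim,
                        prior = priors[[m]], n_restarts = restarts,
                        sigma_fixed = cfg$sigma_fixed,
                        warm_start = if (iter > 1L) fits[[m]][[i]]$map_z,
                        compare_at = cfg$compare_at)
      })
      if (iter == 1L) {
        logev[, m] <- vapply(fits[[m]], `[[`, numeric(1), "log_evidence")
      }
    }
    if (iter == 1L) {
      # model-identity layer: wide-prior evidences, held fixed afterwards
      if (M > 1L) {
        vb <- vb_dirichlet(logev, alpha0 = cfg$alpha0)
        u <- vb$u
        conc <- vb$alpha
      } else {
        u <- matrix(1, n, 1L)
        conc <- cfg$alpha0 + n
      }
      freq <- conc / sum(conc)
    }

    # M-step: responsibility-weighted group moments, regularised by one
    # pseudo-subject at the wide prior.
    group_mean <- vector("list", M)
    for (m in seq_len(M)) {
      d <- length(fits[[m]][[1L]]$map_z)
      Z <- t(vapply(fits[[m]], `[[`, numeric(d), "map_z"))
      V <- t(vapply(fits[[m]], function(f) {
        v <- f$post_var_z
        # unidentified directions report huge Laplace variances; treat
        # them as prior-width uncertainty
        v[!is.finite(v) | v > cfg$prior_var] <- cfg$prior_var
        v
      }, numeric(d)))
      if (d == 1L) { Z <- t(Z); V <- t(V) }
      w <- u[, m]
      sw <- sum(w) + 1
      mu0 <- rep_len(cfg$prior_mean, d)
      v0 <- rep_len(cfg$prior_var, d)
      mu <- (colSums(Z * w) + mu0) / sw
      vv <- (colSums((sweep(Z, 2L, mu))^2 * w) + colSums(V * w) +
               v0 + (mu0 - mu)^2) / sw
      # keep the group prior between a small floor and the initial wide
      # prior: empirical-Bayes shrinkage only ever tightens it
      vv <- pmin(pmax(vv, 1e-3), cfg$prior_var)
      sp <- specs[[m]]
      pnames <- sp$par_names[fits[[m]][[1L]]$free]
      priors[[m]] <- list(mean = setNames(mu, pnames),
                          sd = setNames(sqrt(vv), pnames))
      group_mean[[m]] <- mu
    }

    dm <- if (is.null(group_mean_prev)) Inf else {
      max(unlist(Map(function(a, b) max(abs(a - b)),
                     group_mean, group_mean_prev)))
    }
    if (cfg$verbose) {
      message(sprintf("iter %d: max|dmean| = %.4f, freq = %s", iter, dm,
                      paste(sprintf("%.3f", freq), collapse = " ")))
    }
    group_mean_prev <- group_mean
    if (iter > 1L && dm < cfg$mean_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("hierarchical fit did not fully converge in ", cfg$max_iter,
            " iterations; returning last iterate", call. = FALSE)
  }

  if (M > 1L) {
    pe <- protected_exceedance(conc, logev, n_draws = cfg$n_draws,
                               alpha0 = cfg$alpha0)
  } else {
    pe <- list(ep = 1, bor = NA_real_, pxp = 1)
  }

  rownames(u) <- rownames(logev) <-
    vapply(sessions, `[[`, character(1), "subject_id")
  model_ids <- vapply(specs, `[[`, integer(1), "model_id")
  colnames(u) <- colnames(logev) <- paste0("model_", model_ids)

  structure(list(model_ids = model_ids, specs = specs,
                 group_priors = priors, subject_fits = fits,
                 responsibilities = u, concentrations = conc,
                 frequencies = freq, ep = pe$ep, bor = pe$bor,
                 pxp = pe$pxp, log_evidence = logev,
                 converged = converged, n_iterations = iters,
                 config = cfg),
            class = "group_fit")
}

#' @export
print.group_fit <- function(x, ...) {
  cat(sprintf("<group_fit> %d subjects, models %s (%d iterations%s)\n",
              nrow(x$responsibilities),
              paste(x$model_ids, collapse = ", "), x$n_iterations,
              if (x$converged) "" else ", not converged"))
  tab <- data.frame(model = x$model_ids,
                    frequency = round(x$frequencies, 4),
                    ep = round(x$ep, 4), pxp = round(x$pxp, 4))
  print(tab, row.names = FALSE)
  if (is.finite(x$bor)) cat(sprintf("  BOR = %.4f\n", x$bor))
  invisible(x)
}

#' Per-subject natural-space parameter estimates from a group fit
#'
#' @param fit A `group_fit`.
#' @param model_id Which model's estimates to extract.
#' @return Data frame: `subject_id` plus one column per parameter.
#' @export
subject_parameters <- function(fit, model_id) {
  m <- match(model_id, fit$model_ids)
  if (is.na(m)) stop("model not present in fit", call. = FALSE)
  sp <- fit$specs[[m]]
  rows <- lapply(fit$subject_fits[[m]], function(f) {
    as.data.frame(c(list(subject_id = f$subject_id), as.list(f$map_par)),
                  stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
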