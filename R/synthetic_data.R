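#' Generate a synthetic reference panel
#'
#' Emulates the independent rater panel (232 raters in the study design)
#' whose utility ratings supply both the feedback schedule and the
#' inter-trait similarity matrix. Ratings follow a latent-factor model:
#' `rating = clip(round(50 + loadings %*% factors + noise), 1, 100)`,
#' which yields a similarity matrix with a realistic spread of positive
#' and negative entries.
#'
#' @param K Number of traits (default 50).
#' @param n_ref Panel size (default 232).
#' @param n_factors Number of latent factors (default 4).
#' @param loading_sd SD of the Gaussian factor loadings (default 8).
#' @param noise_sd SD of the rater-level noise (default 6).
#' @param loadings Optional explicit K x n_factors loading matrix.
#' @param trait_labels Optional labels (default from [trait_lexicon()]
#'   when K = 50).
#' @param seed Integer seed (mandatory for reproducibility).
#' @return A [rating_table()] with block `"reference"`; the loadings are
#'   attached as attribute `"loadings"`.
#' @export
gen_reference_panel <- function(K = 50, n_ref = 232, n_factors = 4,
                                loading_sd = 8, noise_sd = 6,
                                loadings = NULL, trait_labels = NULL,
                                seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (n_ref < 10) stop("panel needs at least 10 raters", call. = FALSE)
  if (n_factors > K) stop("more factors than traits", call. = FALSE)
  set.seed(seed)
  if (is.null(loadings)) {
    loadings <- matrix(rnorm(K * n_factors, sd = loading_sd), K, n_factors)
  }
  stopifnot(nrow(loadings) == K, ncol(loadings) == n_factors)
  if (is.null(trait_labels)) {
    trait_labels <- if (K == 50) trait_lexicon()$label
                    else paste0("trait_", seq_len(K))
  }
  f <- matrix(rnorm(n_ref * n_factors), n_ref, n_factors)
  v <- 50 + f %*% t(loadings) + matrix(rnorm(n_ref * K, sd = noise_sd),
                                       n_ref, K)
  v <- pmin(pmax(round(v), 1), 100)
  rt <- rating_table(v, subject_ids = paste0("ref_", seq_len(n_ref)),
                     trait_labels = trait_labels, block = "reference")
  attr(rt, "loadings") <- loadings
  rt
}

#' Generate a synthetic survey cohort
#'
#' Emulates the survey studies' structure: self / utility (and
#' optionally ideal / ought) rating blocks with known per-trait
#' generative offsets, plus Self-Concept Clarity and Self-Esteem scores
#' produced by a specified linear link, so that the ground-truth SUD and
#' the SUD--SCC association are known by construction.
#'
#' The utility profile is `self + delta`, where `delta_ik =
#' scale_i * e_ik` with standard-normal `e` and a log-normal per-subject
#' scale, so `SUD_i` is close to `scale_i * sqrt(2/pi)` before rounding.
#' A latent esteem factor correlates `rho_se_sud` with the standardised
#' negative SUD; SCC is a linear combination of both plus noise. Latents
#' are discretised to the questionnaire sum-score ranges (12--60 for
#' SCC, 10--40 for Self-Esteem).
#'
#' Default link coefficients (`a_sud` 0.37, `a_se` 0.42, `noise_sd`
#' 0.7376, `rho_se_sud` -0.46) were calibrated once, from the implied
#' latent correlation algebra, to reproduce the magnitude of the
#' published survey associations (SUD--SCC about -0.56, SE--SCC about
#' 0.59, SUD--SE about -0.46).
#'
#' @param n_subjects Cohort size (default 155).
#' @param K Number of traits (default 50).
#' @param offset_scale_meanlog,offset_scale_sdlog Log-normal parameters
#'   of the per-subject offset scale.
#' @param self_mean,self_sd Moments of the self-rating draw.
#' @param a0,a_sud,a_se,noise_sd Survey link: `SCC_latent = a0 +
#'   a_sud * (-SUD_std) + a_se * esteem + Normal(0, noise_sd)`.
#' @param rho_se_sud Correlation between the esteem latent and the
#'   standardised negative SUD.
#' @param blocks Which comparison blocks to generate besides self and
#'   utility (`"ideal"`, `"ought"`).
#' @param miss_prob Per-cell probability of a missing rating.
#' @param seed Integer seed (mandatory).
#' @return List: `tables` (named rating tables), `scores` (data frame
#'   with `subject_id`, `SCC`, `SE`), `truth` (per-subject true offset
#'   scale, true SUD of the continuous offsets, latent esteem), and the
#'   offset matrices under `offsets`.
#' @export
gen_survey_cohort <- function(n_subjects = 155, K = 50,
                              offset_scale_meanlog = log(14),
                              offset_scale_sdlog = 0.45,
                              self_mean = 55, self_sd = 20,
                              a0 = 0, a_sud = 0.37, a_se = 0.42,
                              noise_sd = 0.7376, rho_se_sud = -0.46,
                              blocks = c("ideal", "ought"),
                              miss_prob = 0, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(seed)
  labels <- if (K == 50) trait_lexicon()$label else paste0("trait_", seq_len(K))
  ids <- paste0("s", seq_len(n_subjects))
  clip100 <- function(m) pmin(pmax(round(m), 1), 100)

  self <- matrix(rnorm(n_subjects * K, self_mean, self_sd), n_subjects, K)
  self <- clip100(self)

  scale_i <- exp(rnorm(n_subjects, offset_scale_meanlog, offset_scale_sdlog))
  e <- matrix(rnorm(n_subjects * K), n_subjects, K)
  delta <- e * scale_i
  utility <- clip100(self + delta)
  true_sud <- rowMeans(abs(delta))

  offsets <- list(utility = delta)
  tables <- list(
    self = rating_table(self, ids, labels, "self"),
    utility = rating_table(utility, ids, labels, "utility"))
  for (b in intersect(blocks, c("ideal", "ought"))) {
    db <- matrix(rnorm(n_subjects * K), n_subjects, K) *
      scale_i * runif(n_subjects, 0.8, 1.2)
    tables[[b]] <- rating_table(clip100(self + db), ids, labels, b)
    offsets[[b]] <- db
  }

  sud_std <- as.numeric(scale(true_sud))
  esteem <- rho_se_sud * sud_std +
    sqrt(1 - rho_se_sud^2) * rnorm(n_subjects)
  scc_latent <- a0 + a_sud * (-sud_std) + a_se * esteem +
    rnorm(n_subjects, 0, noise_sd)
  scc <- pmin(pmax(round(36 + 8 * scc_latent), 12), 60)
  se <- pmin(pmax(round(25 + 5 * esteem), 10), 40)

  if (miss_prob > 0) {
    for (b in names(tables)) {
      v <- tables[[b]]$values
      v[matrix(runif(length(v)) < miss_prob, nrow(v))] <- NA_real_
      tables[[b]] <- rating_table(v, ids, labels, tables[[b]]$block)
    }
  }

  list(tables = tables,
       scores = data.frame(subject_id = ids, SCC = scc, SE = se,
                           stringsAsFactors = FALSE),
       truth = data.frame(subject_id = ids, offset_scale = scale_i,
                          true_sud = true_sud, esteem = esteem,
                          stringsAsFactors = FALSE),
       offsets = offsets)
}

#' Default true-parameter samplers for recovery studies
#'
#' Natural-space samplers bracketing the fitted population values:
#' learning rates `alpha ~ U(0.02, 0.5)`, mixture weight
#' `gamma ~ U(0.05, 0.6)`, response noise `sigma ~ U(5, 15)`; model 1's
#' regression uses `beta0 ~ U(10, 40)`, `beta1 ~ U(0.3, 0.9)`.
#'
#' @param model_id Model id 1..5.
#' @return Function of `n` returning an n x d matrix of named draws.
#' @export
default_param_sampler <- function(model_id) {
  spec <- model_spec(model_id)
  function(n) {
    draws <- vapply(spec$par_names, function(p) {
      switch(sub("_(plus|minus)$", "", p),
             alpha = runif(n, 0.02, 0.5),
             gamma = runif(n, 0.05, 0.6),
             sigma = runif(n, 5, 15),
             beta0 = runif(n, 10, 40),
             beta1 = runif(n, 0.3, 0.9))
    }, numeric(n))
    if (n == 1L) draws <- matrix(draws, nrow = 1L,
                                 dimnames = list(NULL, spec$par_names))
    draws
  }
}

#' Generate a closed-loop learning cohort with known ground truth
#'
#' Per subject: a random trait order over the panel's traits, a fresh
#' self-rating profile, true parameters drawn from `param_sampler`, and
#' a closed-loop simulated session via [simulate_subject()] using the
#' panel-derived similarity matrix and feedback schedule.
#'
#' @param n_subjects Cohort size (default 85).
#' @param model_id Generating model (1..5).
#' @param panel Reference panel [rating_table()] (default: a fresh
#'   [gen_reference_panel()] at a seed derived from `seed`).
#' @param n_trials Trials per session; must not exceed the panel's trait
#'   count (default: all panel traits).
#' @param param_sampler Function of n returning true natural-space
#'   parameters (default [default_param_sampler()]).
#' @param p_init Initial prediction (80, or `"self"`).
#' @param self_mean,self_sd Self-profile draw moments.
#' @param miss_prob Per-trial missed-response probability.
#' @param compare_at Dual-rate comparison convention (models 3, 5).
#' @param seed Integer seed (mandatory).
#' @return List: `sessions`, `true_params` (data frame), `sim`,
#'   `feedback`, `panel`, `model_id`.
#' @export
gen_learning_cohort <- function(n_subjects = 85, model_id = 4,
                                panel = NULL, n_trials = NULL,
                                param_sampler = default_param_sampler(model_id),
                                p_init = 80, self_mean = 55, self_sd = 20,
                                miss_prob = 0, compare_at = "emitted",
                                seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(seed)
  if (is.null(panel)) {
    panel <- gen_reference_panel(seed = sample.int(.Machine$integer.max, 1))
  }
  sim <- build_similarity_matrix(panel)
  fb <- compute_feedback(panel)
  K <- length(sim$trait_labels)
  if (is.null(n_trials)) n_trials <- K
  stopifnot(n_trials <= K)

  truth <- param_sampler(n_subjects)
  colnames(truth) <- model_spec(model_id)$par_names
  sessions <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    ord <- sample(sim$trait_labels, n_trials)
    S <- pmin(pmax(round(rnorm(n_trials, self_mean, self_sd)), 1), 100)
    frame <- list(trait = ord, S = S, F_fb = unname(fb[ord]),
                  subject_id = paste0("s", i), p_init = p_init)
    sessions[[i]] <- simulate_subject(model_id, truth[i, ], frame,
                                      sim = sim, compare_at = compare_at,
                                      miss_prob = miss_prob)
  }
  list(sessions = sessions,
       true_params = data.frame(subject_id = paste0("s", seq_len(n_subjects)),
                                truth, stringsAsFactors = FALSE),
       sim = sim, feedback = fb, panel = panel, model_id = model_id)
}
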