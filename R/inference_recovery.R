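#' Parameter recovery study
#'
#' Simulates a cohort from a chosen model with known parameters, refits
#' the same model hierarchically, and reports the Pearson correlation
#' between true and recovered values per parameter, computed in the
#' natural (untransformed) space.
#'
#' @param model_id Generating/fitted model (1..5).
#' @param n_subjects Cohort size (default 85).
#' @param n_trials Trials per session (default 50, the session length
#'   of the study design).
#' @param panel Optional reference panel; generated if `NULL`.
#' @param param_sampler True-parameter sampler
#'   (default [default_param_sampler()]).
#' @param seed Integer seed (mandatory).
#' @param config Passed to [fit_hierarchical()].
#' @return An object of class `recovery_report`: data frame `summary`
#'   (`parameter`, `r`, `n`), plus `true` and `recovered` data frames.
#' @export
parameter_recovery <- function(model_id = 4, n_subjects = 85,
                               n_trials = 50, panel = NULL,
                               param_sampler = default_param_sampler(model_id),
                               seed, config = list()) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, 2)
  if (is.null(panel)) {
    panel <- gen_reference_panel(K = n_trials, seed = seeds[1L])
  }
  cohort <- gen_learning_cohort(n_subjects = n_subjects,
                                model_id = model_id, panel = panel,
                                n_trials = n_trials,
                                param_sampler = param_sampler,
                                seed = seeds[2L])
  fit <- fit_hierarchical(model_id, cohort$sessions, sim = cohort$sim,
                          config = config)
  rec <- subject_parameters(fit, model_id)
  pnames <- model_spec(model_id)$par_names
  rs <- vapply(pnames, function(p) {
    tv <- cohort$true_params[[p]]
    if (sd(tv) == 0) return(NA_real_)
    cor(tv, rec[[p]])
  }, numeric(1))
  structure(list(summary = data.frame(parameter = pnames, r = rs,
                                      n = n_subjects,
                                      stringsAsFactors = FALSE),
                 true = cohort$true_params, recovered = rec,
                 fit = fit, model_id = model_id, seed = seed),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> model %d, n = %d\n", x$model_id,
              x$summary$n[1L]))
  print(transform(x$summary, r = round(r, 3)), row.names = FALSE)
  invisible(x)
}

#' Model confusion (model-recovery) study
#'
#' For each generating model, simulates cohorts with known parameters,
#' fits the full model set hierarchically, and records which model wins
#' by protected exceedance probability. Reported as a confusion matrix
#' (rows: generating model; columns: selected model).
#'
#' @param model_ids Models in the comparison set (default 1:5).
#' @param n_subjects Subjects per simulated cohort.
#' @param n_reps Cohorts per generating model.
#' @param n_trials Trials per session.
#' @param panel Optional shared reference panel; generated if `NULL`.
#' @param samplers Optional named list of parameter samplers per model
#'   id (defaults to [default_param_sampler()] per model).
#' @param seed Integer seed (mandatory).
#' @param config Passed to [fit_hierarchical()].
#' @return An object of class `confusion_report`: `counts` and
#'   row-normalised `proportions` matrices, plus the per-cell winners
#'   and PXP tables.
#' @export
model_confusion <- function(model_ids = 1:5, n_subjects = 40,
                            n_reps = 2, n_trials = 50, panel = NULL,
                            samplers = NULL, seed, config = list()) {
  if (length(model_ids) < 2L) stop("need at least two models", call. = FALSE)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(seed)
  if (is.null(panel)) {
    panel <- gen_reference_panel(K = n_trials,
                                 seed = sample.int(.Machine$integer.max, 1))
  }
  M <- length(model_ids)
  counts <- matrix(0L, M, M,
                   dimnames = list(generated = paste0("model_", model_ids),
                                   selected = paste0("model_", model_ids)))
  details <- list()
  for (gi in seq_len(M)) {
    g <- model_ids[gi]
    sampler <- if (!is.null(samplers) && !is.null(samplers[[as.character(g)]]))
      samplers[[as.character(g)]] else default_param_sampler(g)
    for (rep in seq_len(n_reps)) {
      cohort <- gen_learning_cohort(
        n_subjects = n_subjects, model_id = g, panel = panel,
        n_trials = n_trials, param_sampler = sampler,
        seed = sample.int(.Machine$integer.max, 1))
      fit <- fit_hierarchical(model_ids, cohort$sessions,
                              sim = cohort$sim, config = config)
      win <- which.max(fit$pxp)
      counts[gi, win] <- counts[gi, win] + 1L
      details[[length(details) + 1L]] <-
        data.frame(generated = g, rep = rep,
                   selected = model_ids[win],
                   pxp_winner = fit$pxp[win],
                   stringsAsFactors = FALSE)
    }
  }
  props <- counts / rowSums(counts)
  structure(list(counts = counts, proportions = props,
                 details = do.call(rbind, details),
                 model_ids = model_ids, seed = seed),
            class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, ...) {
  cat("<confusion_report> row-normalised selection proportions\n")
  print(round(x$proportions, 3))
  invisible(x)
}
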