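#' Run a configured analysis stage end-to-end
#'
#' Configuration-driven orchestration of the package's study pipelines.
#' The config is a named list (or path to a YAML/JSON file) with a
#' mandatory `stage` and per-stage fields:
#'
#' * `"synth"` — generate synthetic data; fields: `what`
#'   (`"panel"`, `"survey"`, `"learning"`), `seed`, generator arguments,
#'   `out_dir` for CSV output.
#' * `"study1"` / `"study2"` — survey association analysis; fields:
#'   either `paths` (named CSV paths per block plus `scores`) or
#'   `synthetic = TRUE` with `seed`; `metric` (default
#'   `"manhattan_mean"`).
#' * `"study3_fit"` — hierarchical model comparison; fields: `sessions`
#'   (CSV path) or `synthetic = TRUE` + `seed`, `models` (default 1:5),
#'   `sim` (CSV path, optional when synthetic), `init` (80 or
#'   `"self"`), `fit_config`.
#' * `"recover"` — parameter recovery; fields: `model_id`, `n_subjects`,
#'   `seed`, `fit_config`.
#' * `"confuse"` — model confusion; fields: `model_ids`, `n_subjects`,
#'   `n_reps`, `seed`, `fit_config`.
#'
#' Every stochastic stage requires a `seed`; the summary records the
#' package version, the seed, and a config hash, and re-running the same
#' config reproduces the summary exactly.
#'
#' @param config Named list, or path to a YAML or JSON config file.
#' @param out_dir Optional output directory; when given, a
#'   `summary.json` plus stage CSV tables are written there.
#' @return The stage summary (named list), invisibly also written to
#'   `out_dir` when requested.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$stage)) stop("config$stage is required", call. = FALSE)
  stage <- match.arg(config$stage,
                     c("study1", "study2", "study3_fit", "recover",
                       "confuse", "synth"))
  needs_seed <- stage %in% c("recover", "confuse", "synth") ||
    isTRUE(config$synthetic)
  if (needs_seed && is.null(config$seed)) {
    stop("seed is mandatory for stochastic stages", call. = FALSE)
  }
  if (!is.null(config$models)) {
    bad <- setdiff(as.integer(unlist(config$models)), 1:5)
    if (length(bad)) stop("unknown model id ", bad[1L], call. = FALSE)
  }
  summary <- switch(stage,
                    study1 = pipeline_survey(config, with_sdt = FALSE),
                    study2 = pipeline_survey(config, with_sdt = TRUE),
                    study3_fit = pipeline_fit(config),
                    recover = pipeline_recover(config),
                    confuse = pipeline_confuse(config),
                    synth = pipeline_synth(config, out_dir))
  summary$meta <- list(stage = stage,
                       package_version = as.character(packageVersion("sudlearn")),
                       seed = config$seed,
                       config_hash = config_hash(config))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE, na = "null")
  }
  invisible(summary)
}

# Deterministic 64-bit-ish FNV-1a hash of the serialised config.
config_hash <- function(config) {
  bytes <- as.integer(serialize(config, NULL, version = 2L))
  h <- 2166136261
  for (b in bytes) h <- ((bitwXor(as.integer(h %% 2^31), b)) * 16777619) %% 2^32
  sprintf("%08x", as.integer(h %% 2^31))
}

survey_inputs <- function(config, with_sdt) {
  blocks <- c("self", "utility", if (with_sdt) c("ideal", "ought"))
  if (isTRUE(config$synthetic)) {
    cohort <- gen_survey_cohort(
      n_subjects = config$n_subjects %||% if (with_sdt) 323 else 155,
      blocks = if (with_sdt) c("ideal", "ought") else character(0),
      seed = config$seed)
    list(tables = cohort$tables[blocks], scores = cohort$scores)
  } else {
    paths <- config$paths
    if (is.null(paths)) stop("survey stages need paths or synthetic = TRUE",
                             call. = FALSE)
    tables <- lapply(blocks, function(b) read_rating_table(paths[[b]], b))
    names(tables) <- blocks
    scores <- read.csv(paths$scores, stringsAsFactors = FALSE)
    list(tables = tables, scores = scores)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipeline_survey <- function(config, with_sdt) {
  metric <- config$metric %||% "manhattan_mean"
  inp <- survey_inputs(config, with_sdt)
  tables <- inp$tables
  scores <- inp$scores
  d <- data.frame(subject_id = scores$subject_id, SCC = scores$SCC,
                  SE = scores$SE, stringsAsFactors = FALSE)
  d$SUD <- discrepancy_table(tables$self, tables$utility, metric)$value
  if (with_sdt) {
    d$ISD <- discrepancy_table(tables$self, tables$ideal, metric)$value
    d$OSD <- discrepancy_table(tables$self, tables$ought, metric)$value
  }
  cors <- list(
    sud_scc = pearson_with_ci(d$SUD, d$SCC),
    scc_se = pearson_with_ci(d$SCC, d$SE),
    sud_se = pearson_with_ci(d$SUD, d$SE))
  if (with_sdt) {
    hier <- hierarchical_regression(d, "SCC", base = c("ISD", "OSD"),
                                    added = "SUD")
    bic <- best_subset_bic(d, "SCC", c("SUD", "ISD", "OSD", "SE"))
    comm <- NULL
  } else {
    hier <- hierarchical_regression(d, "SCC", base = "SE", added = "SUD")
    comm <- commonality(d, "SCC", c("SUD", "SE"))
    bic <- NULL
  }
  list(scores = d, correlations = cors, regression = unclass(hier),
       commonality = if (!is.null(comm)) unclass(comm),
       bic = bic)
}

pipeline_fit <- function(config) {
  models <- as.integer(config$models %||% 1:5)
  init <- config$init %||% 80
  if (isTRUE(config$synthetic)) {
    cohort <- gen_learning_cohort(
      n_subjects = config$n_subjects %||% 20,
      model_id = config$generating_model %||% 4,
      n_trials = config$n_trials %||% 50, p_init = init,
      seed = config$seed)
    sessions <- cohort$sessions
    sim <- cohort$sim
  } else {
    sessions <- read_sessions(config$sessions, p_init = init)
    sim <- read_similarity_matrix(config$sim)
  }
  fit <- fit_hierarchical(models, sessions, sim = sim,
                          config = config$fit_config %||% list())
  list(models = models,
       frequencies = fit$frequencies, ep = fit$ep, bor = fit$bor,
       pxp = fit$pxp,
       winner = models[which.max(fit$pxp)],
       group_means = lapply(fit$group_priors, `[[`, "mean"),
       converged = fit$converged)
}

pipeline_recover <- function(config) {
  rep <- parameter_recovery(model_id = config$model_id %||% 4,
                            n_subjects = config$n_subjects %||% 85,
                            n_trials = config$n_trials %||% 50,
                            seed = config$seed,
                            config = config$fit_config %||% list())
  list(recovery = rep$summary, model_id = rep$model_id)
}

pipeline_confuse <- function(config) {
  rep <- model_confusion(model_ids = as.integer(config$model_ids %||% 1:5),
                         n_subjects = config$n_subjects %||% 40,
                         n_reps = config$n_reps %||% 2,
                         n_trials = config$n_trials %||% 50,
                         seed = config$seed,
                         config = config$fit_config %||% list())
  list(counts = rep$counts, proportions = rep$proportions,
       details = rep$details)
}

pipeline_synth <- function(config, out_dir) {
  what <- match.arg(config$what %||% "survey",
                    c("panel", "survey", "learning"))
  out <- switch(what,
    panel = {
      panel <- gen_reference_panel(K = config$K %||% 50,
                                   n_ref = config$n_ref %||% 232,
                                   seed = config$seed)
      if (!is.null(out_dir)) {
        dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
        write_rating_table(panel, file.path(out_dir, "panel.csv"))
      }
      list(what = what, n_ref = nrow(panel$values), K = ncol(panel$values))
    },
    survey = {
      cohort <- gen_survey_cohort(n_subjects = config$n_subjects %||% 155,
                                  seed = config$seed)
      if (!is.null(out_dir)) {
        dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
        for (b in names(cohort$tables)) {
          write_rating_table(cohort$tables[[b]],
                             file.path(out_dir, paste0(b, ".csv")))
        }
        write.csv(cohort$scores, file.path(out_dir, "scores.csv"),
                  row.names = FALSE)
      }
      list(what = what, n_subjects = nrow(cohort$scores))
    },
    learning = {
      cohort <- gen_learning_cohort(n_subjects = config$n_subjects %||% 85,
                                    model_id = config$generating_model %||% 4,
                                    n_trials = config$n_trials %||% 50,
                                    seed = config$seed)
      if (!is.null(out_dir)) {
        dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
        write_sessions(cohort$sessions, file.path(out_dir, "sessions.csv"))
        write_similarity_matrix(cohort$sim, file.path(out_dir, "sim.csv"))
        write.csv(cohort$true_params,
                  file.path(out_dir, "true_params.csv"), row.names = FALSE)
      }
      list(what = what, n_subjects = length(cohort$sessions),
           model_id = cohort$model_id)
    })
  out
}
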