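#' Construct a learning session
#'
#' One subject's ordered feedback-learning block: on each of the T trials
#' (50 in the study design) a trait is shown, the subject holds a
#' self-rating `S` for it, states a utility estimate `U` (possibly
#' missed), and then sees the reference group's feedback `F`. Each trait
#' appears exactly once.
#'
#' @param trait Character or integer vector of trait labels in trial
#'   order (no repeats).
#' @param S Self-ratings per trial, in `[1, 100]`.
#' @param U Utility responses per trial (`NA` = missed).
#' @param F_fb Feedback values per trial, in `[1, 100]`.
#' @param subject_id Identifier.
#' @param p_init Initial prediction: a single value (default 80) shared
#'   by all traits, or `"self"` for the variant that initialises each
#'   trait's prediction at the subject's own self-rating.
#' @return An object of class `learning_session`.
#' @export
learning_session <- function(trait, S, U, F_fb, subject_id = "s1",
                             p_init = 80) {
  trait <- as.character(trait)
  T_ <- length(trait)
  if (anyDuplicated(trait)) stop("each trait must appear exactly once",
                                 call. = FALSE)
  stopifnot(length(S) == T_, length(U) == T_, length(F_fb) == T_)
  if (anyNA(S) || any(S < 1 | S > 100)) {
    stop("self-ratings must be non-missing and in [1, 100]", call. = FALSE)
  }
  if (anyNA(F_fb) || any(F_fb < 1 | F_fb > 100)) {
    stop("feedback must be non-missing and in [1, 100]", call. = FALSE)
  }
  if (any(!is.na(U) & (U < 1 | U > 100))) {
    stop("utility responses must be in [1, 100]", call. = FALSE)
  }
  p_init_vec <- resolve_p_init(p_init, S)
  structure(list(subject_id = as.character(subject_id), trait = trait,
                 S = as.numeric(S), U = as.numeric(U),
                 F_fb = as.numeric(F_fb), p_init = p_init,
                 p_init_vec = p_init_vec, n_trials = T_),
            class = "learning_session")
}

resolve_p_init <- function(p_init, S) {
  if (identical(p_init, "self")) return(as.numeric(S))
  p <- as.numeric(p_init)
  if (length(p) == 1L) p <- rep(p, length(S))
  if (anyNA(p) || any(p < 1 | p > 100)) {
    stop("p_init must lie in [1, 100]", call. = FALSE)
  }
  p
}

#' @export
print.learning_session <- function(x, ...) {
  cat(sprintf("<learning_session> subject '%s': %d trials, %d missed\n",
              x$subject_id, x$n_trials, sum(is.na(x$U))))
  invisible(x)
}

#' Read / write learning sessions in long CSV form
#'
#' Columns: `subject_id`, `trial`, `trait`, `S`, `U` (empty when the
#' response was missed), `F`.
#'
#' @param path CSV path.
#' @param p_init Initial-prediction setting forwarded to
#'   [learning_session()].
#' @return `read_sessions()` returns a list of `learning_session`
#'   objects; `write_sessions()` writes one CSV for a list of sessions.
#' @export
read_sessions <- function(path, p_init = 80) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("subject_id", "trial", "trait", "S", "U", "F")
  if (!all(need %in% names(df))) {
    stop("session CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lapply(split(df, df$subject_id), function(d) {
    d <- d[order(d$trial), ]
    learning_session(d$trait, d$S, as.numeric(d$U), d$F,
                     subject_id = d$subject_id[1L], p_init = p_init)
  })
}

#' @rdname read_sessions
#' @param sessions List of `learning_session` objects.
#' @export
write_sessions <- function(sessions, path) {
  rows <- lapply(sessions, function(s) {
    data.frame(subject_id = s$subject_id, trial = seq_len(s$n_trials),
               trait = s$trait, S = s$S, U = s$U, F = s$F_fb,
               stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Inter-trait similarity matrix from a reference panel
#'
#' Entry (j, k) is the Pearson correlation between the panel's rating
#' columns for traits j and k (pairwise-complete observations); the
#' diagonal is forced to exactly 1. Signed similarities are kept as-is:
#' negatively related traits spread sign-flipped updates.
#'
#' @param reference A [rating_table()] from the reference panel.
#' @param min_pairs Minimum complete rater pairs required per entry.
#' @return A `similarity_matrix`: list with `trait_labels` and the
#'   K x K `entries` matrix.
#' @export
build_similarity_matrix <- function(reference, min_pairs = 3L) {
  stopifnot(inherits(reference, "rating_table"))
  v <- reference$values
  sds <- apply(v, 2L, sd, na.rm = TRUE)
  if (any(is.na(sds) | sds == 0)) {
    bad <- reference$trait_labels[which(is.na(sds) | sds == 0)[1L]]
    stop(sprintf("zero-variance reference column for trait '%s'", bad),
         call. = FALSE)
  }
  npair <- crossprod(!is.na(v))
  if (any(npair < min_pairs)) {
    stop(sprintf("fewer than %d complete rater pairs for some trait pair",
                 min_pairs), call. = FALSE)
  }
  m <- cor(v, use = "pairwise.complete.obs")
  diag(m) <- 1
  dimnames(m) <- list(reference$trait_labels, reference$trait_labels)
  structure(list(trait_labels = reference$trait_labels, entries = m),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  off <- x$entries[upper.tri(x$entries)]
  cat(sprintf("<similarity_matrix> %d traits; off-diagonal range [%.2f, %.2f]\n",
              length(x$trait_labels), min(off), max(off)))
  invisible(x)
}

#' Read / write a similarity matrix CSV (labelled K x K grid)
#' @param path CSV path.
#' @return `read_similarity_matrix()` returns a `similarity_matrix`.
#' @export
read_similarity_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE, row.names = 1L)
  m <- as.matrix(df)
  if (!isTRUE(all.equal(rownames(m), colnames(m)))) {
    stop("similarity CSV must have matching row/column labels", call. = FALSE)
  }
  structure(list(trait_labels = colnames(m), entries = m),
            class = "similarity_matrix")
}

#' @rdname read_similarity_matrix
#' @param sim A `similarity_matrix`.
#' @export
write_similarity_matrix <- function(sim, path) {
  write.csv(sim$entries, path, row.names = TRUE)
  invisible(path)
}

#' Feedback schedule: panel-average utility per trait
#'
#' The feedback shown after each utility response is the reference
#' panel's mean utility rating for that trait, rounded half-up to an
#' integer on the 1--100 display scale. Missing panel ratings are
#' dropped per column.
#'
#' @param reference A [rating_table()] of panel utility ratings.
#' @return Named integer-valued numeric vector of feedback per trait.
#' @examples
#' rt <- rating_table(cbind(a = c(60, 61)), block = "reference")
#' compute_feedback(rt)  # 61: round-half-up of 60.5
#' @export
compute_feedback <- function(reference) {
  stopifnot(inherits(reference, "rating_table"))
  mu <- colMeans(reference$values, na.rm = TRUE)
  if (anyNA(mu) || any(!is.finite(mu))) {
    stop("a trait column has no non-missing reference ratings", call. = FALSE)
  }
  fb <- floor(mu + 0.5)  # round half-up, not banker's rounding
  pmin(pmax(fb, 1), 100)
}

# Similarity sub-matrix in session trial order.
session_sim <- function(session, sim) {
  idx <- match(session$trait, sim$trait_labels)
  if (anyNA(idx)) stop("session traits missing from similarity matrix",
                       call. = FALSE)
  sim$entries[idx, idx, drop = FALSE]
}

#' Trial-wise model predictions for a session
#'
#' Runs a learning model forward through a session and returns the
#' emitted prediction `P(t)`, the learning component `Pm(t)` (identical
#' to `P` except for the self-adjusted models 4--5), and the prediction
#' error `PE(t) = F(t) - U(t)` on answered trials. Every trial strictly
#' before `t` with an answered response contributes
#' `alpha_eff(i) * PE(i) * SIM(trait_i, trait_t)` to `Pm(t)` on top of
#' the initial prediction.
#'
#' @param model A [model_spec()] or model id 1..5.
#' @param params Natural-space parameters (named or canonical order).
#' @param session A [learning_session()].
#' @param sim A `similarity_matrix` covering the session's traits
#'   (ignored by model 1).
#' @param compare_at For the dual-rate models 3 and 5: whether the
#'   rate-selection condition |F - S| < |P - S| compares feedback against
#'   the `"emitted"` prediction (default) or the `"learning"` component.
#' @return Data frame with columns `trial`, `trait`, `S`, `U`, `F`,
#'   `P`, `Pm`, `PE`.
#' @export
predict_trajectory <- function(model, params, session, sim = NULL,
                               compare_at = c("emitted", "learning")) {
  spec <- as_model_spec(model)
  compare_at <- match.arg(compare_at)
  par <- canonical_par(spec, params)
  sim_tt <- trajectory_sim(spec, session, sim)
  tr <- .traj_cpp(spec$model_id, par, session$S, session$F_fb, session$U,
                  sim_tt, session$p_init_vec,
                  compare_at == "learning")
  data.frame(trial = seq_len(session$n_trials), trait = session$trait,
             S = session$S, U = session$U, F = session$F_fb,
             P = tr$P, Pm = tr$Pm, PE = tr$PE, stringsAsFactors = FALSE)
}

trajectory_sim <- function(spec, session, sim) {
  if (spec$model_id == 1L) {
    return(matrix(0, session$n_trials, session$n_trials))
  }
  if (is.null(sim)) stop("models 2-5 need a similarity matrix", call. = FALSE)
  session_sim(session, sim)
}

#' Gaussian log-likelihood of a session under a model
#'
#' Responses are modelled as `U(t) ~ Normal(P(t), sigma)` on answered
#' trials; missed trials are skipped. The 1--100 response bounds are not
#' treated as censoring.
#'
#' @inheritParams predict_trajectory
#' @return Log-likelihood (scalar).
#' @export
model_loglik <- function(model, params, session, sim = NULL,
                         compare_at = c("emitted", "learning")) {
  spec <- as_model_spec(model)
  compare_at <- match.arg(compare_at)
  par <- canonical_par(spec, params)
  if (all(is.na(session$U))) stop("session has no answered trials",
                                  call. = FALSE)
  sim_tt <- trajectory_sim(spec, session, sim)
  .loglik_cpp(spec$model_id, par, session$S, session$F_fb, session$U,
              sim_tt, session$p_init_vec, compare_at == "learning")
}

#' Simulate a subject closed-loop from a learning model
#'
#' At each trial the model emits `P(t)` from the history of *simulated*
#' responses, draws `U(t) = P(t) + Normal(0, sigma)`, then rounds and
#' clips to the integer 1--100 slider scale; the resulting prediction
#' error feeds subsequent trials.
#'
#' @inheritParams predict_trajectory
#' @param frame List with `trait` (trial order), `S` (self-ratings),
#'   `F_fb` (feedback per trial), optional `subject_id` and `p_init`.
#' @param sim Similarity matrix over the frame's traits.
#' @param seed Optional integer seed (response noise only).
#' @param miss_prob Per-trial probability of a missed response.
#' @return A [learning_session()] with simulated responses; the emitted
#'   predictions are attached as attribute `"trace"`.
#' @export
simulate_subject <- function(model, params, frame, sim = NULL, seed = NULL,
                             compare_at = c("emitted", "learning"),
                             miss_prob = 0) {
  spec <- as_model_spec(model)
  compare_at <- match.arg(compare_at)
  par <- canonical_par(spec, params)
  if (!is.null(seed)) set.seed(seed)
  T_ <- length(frame$trait)
  stopifnot(length(frame$S) == T_, length(frame$F_fb) == T_)
  p_init <- if (is.null(frame$p_init)) 80 else frame$p_init
  p_init_vec <- resolve_p_init(p_init, frame$S)
  sim_tt <- if (spec$model_id == 1L) matrix(0, T_, T_) else {
    if (is.null(sim)) stop("models 2-5 need a similarity matrix",
                           call. = FALSE)
    idx <- match(as.character(frame$trait), sim$trait_labels)
    if (anyNA(idx)) stop("frame traits missing from similarity matrix",
                         call. = FALSE)
    sim$entries[idx, idx, drop = FALSE]
  }
  eps <- rnorm(T_)
  out <- .simulate_cpp(spec$model_id, par, frame$S, frame$F_fb, sim_tt,
                       p_init_vec, eps, compare_at == "learning")
  U <- out$U
  if (miss_prob > 0) U[runif(T_) < miss_prob] <- NA_real_
  ses <- learning_session(frame$trait, frame$S, U, frame$F_fb,
                          subject_id = if (is.null(frame$subject_id)) "sim"
                                       else frame$subject_id,
                          p_init = p_init)
  attr(ses, "trace") <- data.frame(trial = seq_len(T_), P = out$P,
                                   Pm = out$Pm, PE = out$PE)
  ses
}
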