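#' Specification of a trait-utility learning model
#'
#' The package implements five generative models of how people produce
#' trait-utility ratings during a feedback-learning session:
#'
#' * **Model 1 (no learning)** — utility responses are a linear
#'   transformation of self-ratings, \eqn{P(t) = \beta_0 + \beta_1 S(t)}.
#' * **Model 2 (fine granularity)** — a Rescorla--Wagner learner whose
#'   prediction errors spread to upcoming traits in proportion to
#'   inter-trait similarity.
#' * **Model 3** — Model 2 with asymmetric learning rates: one rate for
#'   feedback that moves the utility estimate towards the self-rating,
#'   another for feedback that moves it away.
#' * **Model 4 (self-adjusted)** — Model 2 whose emitted prediction mixes
#'   the learning component with the trait's self-rating,
#'   \eqn{P(t) = \gamma S(t) + (1-\gamma) P^m(t)}.
#' * **Model 5** — Model 4 with the asymmetric rates of Model 3.
#'
#' All models share a Gaussian observation model with free standard
#' deviation `sigma`. Parameters live on their natural scales
#' (`alpha`, `gamma` in (0,1); `sigma` > 0; `beta` unbounded); fitting
#' happens in a transformed space (logit / log / identity).
#'
#' @param model_id Integer in 1..5.
#' @return An object of class `model_spec`: a list with `model_id`,
#'   `name`, `par_names` (canonical parameter order), and `transforms`
#'   (`"identity"`, `"logistic"` or `"log"` per parameter).
#' @examples
#' model_spec(4)
#' @export
model_spec <- function(model_id) {
  model_id <- as.integer(model_id)
  if (length(model_id) != 1L || is.na(model_id) ||
      model_id < 1L || model_id > 5L) {
    stop("model_id must be a single integer in 1..5", call. = FALSE)
  }
  info <- switch(model_id,
    list(name = "no_learning",
         par_names = c("beta0", "beta1", "sigma"),
         transforms = c("identity", "identity", "log")),
    list(name = "fine_granularity",
         par_names = c("alpha", "sigma"),
         transforms = c("logistic", "log")),
    list(name = "fine_granularity_dual",
         par_names = c("alpha_plus", "alpha_minus", "sigma"),
         transforms = c("logistic", "logistic", "log")),
    list(name = "self_adjusted",
         par_names = c("alpha", "gamma", "sigma"),
         transforms = c("logistic", "logistic", "log")),
    list(name = "self_adjusted_dual",
         par_names = c("alpha_plus", "alpha_minus", "gamma", "sigma"),
         transforms = c("logistic", "logistic", "logistic", "log"))
  )
  structure(c(list(model_id = model_id), info), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Learning model %d (%s)\n", x$model_id, x$name))
  cat("  parameters:", paste(x$par_names, collapse = ", "), "\n")
  invisible(x)
}

as_model_spec <- function(model) {
  if (inherits(model, "model_spec")) model else model_spec(model)
}

transform_codes <- function(spec) {
  match(spec$transforms, c("identity", "logistic", "log")) - 1L
}

#' Convert parameters between natural and transformed space
#'
#' Fitting operates on an unconstrained transformed space: unit-interval
#' parameters through the logit, positive parameters through the log,
#' unbounded parameters untouched.
#'
#' @param spec A [model_spec()] (or model id).
#' @param par Named or ordered numeric vector in natural space.
#' @param z Numeric vector in transformed space.
#' @return The vector in the other space, named by parameter.
#' @export
par_to_z <- function(spec, par) {
  spec <- as_model_spec(spec)
  par <- canonical_par(spec, par)
  z <- par
  for (j in seq_along(par)) {
    z[j] <- switch(spec$transforms[j],
                   identity = par[j],
                   logistic = qlogis(par[j]),
                   log = log(par[j]))
  }
  setNames(z, spec$par_names)
}

#' @rdname par_to_z
#' @export
z_to_par <- function(spec, z) {
  spec <- as_model_spec(spec)
  par <- z
  for (j in seq_along(z)) {
    par[j] <- switch(spec$transforms[j],
                     identity = z[j],
                     logistic = plogis(z[j]),
                     log = exp(z[j]))
  }
  setNames(par, spec$par_names)
}

# Accepts a named vector in any order, or an ordered unnamed vector, and
# returns the canonical order; validates bounds.
canonical_par <- function(spec, par) {
  d <- length(spec$par_names)
  if (!is.null(names(par)) && all(spec$par_names %in% names(par))) {
    par <- par[spec$par_names]
  } else if (length(par) != d) {
    stop(sprintf("model %d expects %d parameters (%s)", spec$model_id, d,
                 paste(spec$par_names, collapse = ", ")), call. = FALSE)
  }
  par <- as.numeric(par)
  for (j in seq_len(d)) {
    ok <- switch(spec$transforms[j],
                 identity = is.finite(par[j]),
                 logistic = is.finite(par[j]) && par[j] > 0 && par[j] < 1,
                 log = is.finite(par[j]) && par[j] > 0)
    if (!ok) {
      stop(sprintf("parameter '%s' out of bounds for model %d",
                   spec$par_names[j], spec$model_id), call. = FALSE)
    }
  }
  setNames(par, spec$par_names)
}
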