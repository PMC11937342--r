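# Plain-R reference implementation of the learning models, kept
# deliberately independent of the package's compiled engine: a slow
# trial-by-trial loop used to cross-check trajectories and to drive the
# grid-integration evidence oracle.
ref_predict <- function(model_id, par, S, F_fb, U, sim_tt, p_init,
                        compare = "emitted") {
  T_ <- length(S)
  P <- Pm <- numeric(T_)
  for (t in seq_len(T_)) {
    if (model_id == 1) {
      P[t] <- Pm[t] <- par[["beta0"]] + par[["beta1"]] * S[t]
      next
    }
    acc <- 0
    if (t > 1) {
      for (i in seq_len(t - 1)) {
        if (is.na(U[i])) next
        pe <- F_fb[i] - U[i]
        a <- if (model_id %in% c(2, 4)) par[["alpha"]] else {
          refp <- if (compare == "emitted") P[i] else Pm[i]
          if (abs(F_fb[i] - S[i]) < abs(refp - S[i])) par[["alpha_plus"]]
          else par[["alpha_minus"]]
        }
        acc <- acc + a * pe * sim_tt[i, t]
      }
    }
    Pm[t] <- p_init[t] + acc
    P[t] <- if (model_id >= 4) {
      par[["gamma"]] * S[t] + (1 - par[["gamma"]]) * Pm[t]
    } else Pm[t]
  }
  list(P = P, Pm = Pm)
}

ref_loglik <- function(model_id, par, ses, sim_tt, compare = "emitted") {
  tr <- ref_predict(model_id, par, ses$S, ses$F_fb, ses$U, sim_tt,
                    ses$p_init_vec, compare)
  ok <- !is.na(ses$U)
  sum(dnorm(ses$U[ok], tr$P[ok], par[["sigma"]], log = TRUE))
}

# small helper fixtures ------------------------------------------------

toy_sim <- function(labels, entries) {
  m <- matrix(entries, length(labels), length(labels),
              dimnames = list(labels, labels))
  diag(m) <- 1
  structure(list(trait_labels = labels, entries = m),
            class = "similarity_matrix")
}

random_session <- function(n_trials = 12, seed = 1, miss = 0) {
  set.seed(seed)
  labels <- paste0("t", seq_len(n_trials))
  S <- round(runif(n_trials, 1, 100))
  U <- round(runif(n_trials, 1, 100))
  if (miss > 0) U[sample(n_trials, miss)] <- NA
  F_fb <- round(runif(n_trials, 1, 100))
  e <- matrix(rnorm(n_trials^2, sd = 0.4), n_trials)
  sm <- toy_sim(labels, pmin(pmax((e + t(e)) / 2, -0.95), 0.95))
  list(session = learning_session(labels, S, U, F_fb), sim = sm)
}
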