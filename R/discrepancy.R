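#' Discrepancy between a self profile and a comparison profile
#'
#' Self-Utility Distance (SUD) and its relatives quantify how far a
#' person's self-concept profile sits from a comparison profile over the
#' same traits. The primary metric is the mean absolute difference
#' (`"manhattan_mean"`), i.e. a Manhattan distance normalised by the
#' number of usable trait pairs so that scores remain comparable under
#' missing responses. `"euclidean"` is the plain root-sum-of-squares
#' control metric; `"pearson"` is the correlation control and is a
#' *similarity* (larger = more aligned), not a distance.
#'
#' Pairs where either profile is missing are dropped (pairwise deletion).
#'
#' @param s,u Numeric rating vectors of equal length (1--100 scale,
#'   `NA` allowed).
#' @param metric `"manhattan_mean"`, `"euclidean"`, or `"pearson"`.
#' @param subject_id Identifier stored with the result.
#' @return One-row data frame: `subject_id`, `metric`, `value`,
#'   `n_pairs_used`.
#' @examples
#' profile_distance(c(10, 40, 70), c(20, 20, 100))$value  # 20
#' @export
profile_distance <- function(s, u,
                             metric = c("manhattan_mean", "euclidean",
                                        "pearson"),
                             subject_id = "s1") {
  metric <- match.arg(metric)
  if (length(s) != length(u)) stop("profiles differ in length", call. = FALSE)
  ok <- !is.na(s) & !is.na(u)
  n <- sum(ok)
  s <- s[ok]; u <- u[ok]
  value <- switch(metric,
    manhattan_mean = {
      if (n < 1L) stop("no usable trait pairs", call. = FALSE)
      mean(abs(s - u))
    },
    euclidean = {
      if (n < 1L) stop("no usable trait pairs", call. = FALSE)
      sqrt(sum((s - u)^2))
    },
    pearson = {
      if (n < 2L) stop("pearson needs at least 2 usable pairs", call. = FALSE)
      if (sd(s) == 0 || sd(u) == 0) {
        stop("pearson undefined for a zero-variance profile", call. = FALSE)
      }
      cor(s, u)
    })
  data.frame(subject_id = subject_id, metric = metric, value = value,
             n_pairs_used = n, stringsAsFactors = FALSE)
}

#' Per-subject discrepancies between two rating tables
#'
#' Applies [profile_distance()] row-wise to two aligned rating tables
#' (e.g. self vs utility for SUD, self vs ideal for Ideal-Self
#' Discrepancy). Subjects whose profiles fail the metric's preconditions
#' (e.g. no usable pairs) get a missing value; the reason is recorded in
#' the `note` column instead of aborting the cohort.
#'
#' @param self_table,other_table [rating_table()]s with identical
#'   subjects and trait labels.
#' @inheritParams profile_distance
#' @return Data frame with one row per subject: `subject_id`, `metric`,
#'   `value`, `n_pairs_used`, `note`.
#' @export
discrepancy_table <- function(self_table, other_table,
                              metric = c("manhattan_mean", "euclidean",
                                         "pearson")) {
  metric <- match.arg(metric)
  stopifnot(inherits(self_table, "rating_table"),
            inherits(other_table, "rating_table"))
  if (!identical(self_table$trait_labels, other_table$trait_labels)) {
    stop("trait labels differ between tables", call. = FALSE)
  }
  if (!identical(self_table$subject_ids, other_table$subject_ids)) {
    stop("subject ids differ between tables", call. = FALSE)
  }
  res <- lapply(seq_along(self_table$subject_ids), function(i) {
    out <- tryCatch(
      cbind(profile_distance(self_table$values[i, ],
                             other_table$values[i, ], metric,
                             subject_id = self_table$subject_ids[i]),
            note = NA_character_, stringsAsFactors = FALSE),
      error = function(e) {
        data.frame(subject_id = self_table$subject_ids[i], metric = metric,
                   value = NA_real_, n_pairs_used = NA_integer_,
                   note = conditionMessage(e), stringsAsFactors = FALSE)
      })
    out
  })
  do.call(rbind, res)
}
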