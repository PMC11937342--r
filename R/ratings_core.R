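#' Construct a validated trait-rating table
#'
#' A rating table holds one block of adjective ratings (self, utility,
#' ideal, ought, or reference-panel utility): one row per subject, one
#' column per trait adjective, values on the 1--100 slider scale with
#' missing responses allowed.
#'
#' @param values Numeric matrix (subjects x traits); `NA` marks a
#'   missing response.
#' @param subject_ids Unique subject identifiers (default: rownames or
#'   `s1..sn`).
#' @param trait_labels Unique trait labels (default: colnames).
#' @param block One of `"self"`, `"utility"`, `"ideal"`, `"ought"`,
#'   `"reference"`.
#' @return An object of class `rating_table`.
#' @examples
#' rt <- rating_table(matrix(50, 2, 3), block = "self")
#' dim(rt$values)
#' @export
rating_table <- function(values, subject_ids = NULL, trait_labels = NULL,
                         block = c("self", "utility", "ideal", "ought",
                                   "reference")) {
  block <- match.arg(block)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(subject_ids)) {
    subject_ids <- rownames(values)
    if (is.null(subject_ids)) subject_ids <- paste0("s", seq_len(nrow(values)))
  }
  if (is.null(trait_labels)) {
    trait_labels <- colnames(values)
    if (is.null(trait_labels)) trait_labels <- paste0("trait_", seq_len(ncol(values)))
  }
  subject_ids <- as.character(subject_ids)
  trait_labels <- as.character(trait_labels)
  if (anyDuplicated(subject_ids)) stop("duplicate subject ids", call. = FALSE)
  if (anyDuplicated(trait_labels)) stop("duplicate trait labels", call. = FALSE)
  if (length(subject_ids) != nrow(values) ||
      length(trait_labels) != ncol(values)) {
    stop("id/label lengths do not match the value matrix", call. = FALSE)
  }
  bad <- which(!is.na(values) & (values < 1 | values > 100), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("rating out of [1, 100] for subject '%s', trait '%s'",
                 subject_ids[bad[1L, 1L]], trait_labels[bad[1L, 2L]]),
         call. = FALSE)
  }
  dimnames(values) <- list(subject_ids, trait_labels)
  structure(list(subject_ids = subject_ids, trait_labels = trait_labels,
                 block = block, values = values),
            class = "rating_table")
}

#' @export
print.rating_table <- function(x, ...) {
  cat(sprintf("<rating_table> block '%s': %d subjects x %d traits, %d missing\n",
              x$block, nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' Read / write a wide rating-table CSV
#'
#' The wide format has `subject_id` in the first column and one column
#' per trait label; empty cells encode missing responses.
#'
#' @param path CSV file path.
#' @param block Block label passed to [rating_table()].
#' @return `read_rating_table()` returns a validated [rating_table()];
#'   `write_rating_table()` writes one and returns `path` invisibly.
#' @export
read_rating_table <- function(path, block = "self") {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("rating CSV needs subject_id plus trait columns",
                          call. = FALSE)
  ids <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  rating_table(vals, subject_ids = ids,
               trait_labels = colnames(df)[-1L], block = block)
}

#' @rdname read_rating_table
#' @param table A `rating_table`.
#' @export
write_rating_table <- function(table, path) {
  stopifnot(inherits(table, "rating_table"))
  df <- data.frame(subject_id = table$subject_ids,
                   table$values, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' The 50-adjective trait lexicon scaffold
#'
#' Returns placeholder labels with a balanced valence split (25 positive
#' and 25 negative), mirroring the structure of the adjective set used in
#' the rating tasks. Supply real adjectives via `labels` if available.
#'
#' @param labels Optional character vector of 50 labels.
#' @return Data frame with `label` and `valence` columns.
#' @export
trait_lexicon <- function(labels = NULL) {
  if (is.null(labels)) {
    labels <- c(sprintf("pos_%02d", 1:25), sprintf("neg_%02d", 1:25))
  }
  if (length(labels) != 50L || anyDuplicated(labels)) {
    stop("the lexicon needs 50 unique labels", call. = FALSE)
  }
  data.frame(label = labels,
             valence = rep(c("positive", "negative"), each = 25L),
             stringsAsFactors = FALSE)
}

#' Score a Likert questionnaire with reverse-coded items
#'
#' Computes per-subject sum scores after reflecting reverse-keyed items
#' (`item_min + item_max - x`). Intended for the 12-item Self-Concept
#' Clarity scale (5-point) and the 10-item Self-Esteem scale (4-point).
#' Subjects with any missing item get a missing score (no imputation).
#'
#' @param items Integer matrix (subjects x items) or data frame.
#' @param reverse_keys Integer indices of reverse-coded items.
#' @param item_min,item_max Response bounds of the scale.
#' @param scale_name Label stored with the result (e.g. `"SCC"`, `"RSES"`).
#' @param subject_ids Optional identifiers.
#' @return Data frame: `subject_id`, `scale_name`, `n_items`, `score`.
#' @examples
#' score_scale(matrix(4, 3, 10), integer(), 1, 4, "RSES")$score
#' @export
score_scale <- function(items, reverse_keys = integer(), item_min, item_max,
                        scale_name = "scale", subject_ids = NULL) {
  items <- as.matrix(items)
  storage.mode(items) <- "double"
  if (any(!is.na(items) & (items < item_min | items > item_max))) {
    stop(sprintf("item response outside [%d, %d]", item_min, item_max),
         call. = FALSE)
  }
  if (length(reverse_keys)) {
    if (any(reverse_keys < 1 | reverse_keys > ncol(items))) {
      stop("reverse_keys out of range", call. = FALSE)
    }
    items[, reverse_keys] <- item_min + item_max - items[, reverse_keys]
  }
  if (is.null(subject_ids)) subject_ids <- paste0("s", seq_len(nrow(items)))
  score <- rowSums(items)  # NA if any item missing
  data.frame(subject_id = as.character(subject_ids),
             scale_name = scale_name, n_items = ncol(items),
             score = score, stringsAsFactors = FALSE)
}

#' Default reverse-key sets for the bundled questionnaires
#'
#' The published standard keys: items 1, 2, 3, 8, 9, 10, 11 and 12 of
#' the 12-item Self-Concept Clarity scale, and items 2, 5, 6, 8 and 9 of
#' the 10-item Rosenberg Self-Esteem scale. Override per study if a
#' different key set was used.
#'
#' @param scale `"SCC"` or `"RSES"`.
#' @return Integer vector of reverse-coded item indices.
#' @export
default_reverse_keys <- function(scale = c("SCC", "RSES")) {
  switch(match.arg(scale),
         SCC = c(1L, 2L, 3L, 8L, 9L, 10L, 11L, 12L),
         RSES = c(2L, 5L, 6L, 8L, 9L))
}

#' Apply the missing-response exclusion rule
#'
#' Subjects missing more than `threshold` (default 20%) of their expected
#' responses are excluded; the inequality is strict, so a subject at
#' exactly the threshold is retained.
#'
#' @param responses Either a numeric matrix / data frame of responses
#'   (`NA` = missing, one row per subject), a list of response vectors,
#'   or a data frame with columns `subject_id`, `n_missing`, `n_total`.
#' @param threshold Maximum tolerated missing fraction.
#' @param subject_ids Optional identifiers (matrix/list input).
#' @return Data frame: `subject_id`, `n_missing`, `n_total`,
#'   `missing_fraction`, `retained`.
#' @examples
#' m <- rbind(c(1, NA, 3, 4, 5), c(1, 2, 3, 4, 5))
#' apply_exclusions(m, threshold = 0.2)
#' @export
apply_exclusions <- function(responses, threshold = 0.20,
                             subject_ids = NULL) {
  if (is.data.frame(responses) &&
      all(c("n_missing", "n_total") %in% names(responses))) {
    ids <- if ("subject_id" %in% names(responses)) {
      as.character(responses$subject_id)
    } else paste0("s", seq_len(nrow(responses)))
    n_missing <- responses$n_missing
    n_total <- responses$n_total
  } else if (is.list(responses) && !is.data.frame(responses)) {
    ids <- if (is.null(names(responses))) {
      paste0("s", seq_along(responses))
    } else names(responses)
    n_missing <- vapply(responses, function(v) sum(is.na(v)), integer(1))
    n_total <- lengths(responses)
  } else {
    m <- as.matrix(responses)
    ids <- if (!is.null(subject_ids)) as.character(subject_ids)
           else if (!is.null(rownames(m))) rownames(m)
           else paste0("s", seq_len(nrow(m)))
    n_missing <- rowSums(is.na(m))
    n_total <- rep(ncol(m), nrow(m))
  }
  if (any(n_total <= 0)) stop("zero expected responses", call. = FALSE)
  frac <- n_missing / n_total
  data.frame(subject_id = ids, n_missing = as.integer(n_missing),
             n_total = as.integer(n_total), missing_fraction = frac,
             retained = frac <= threshold, stringsAsFactors = FALSE)
}
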