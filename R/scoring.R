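#' Estimate argument applicability scores
#'
#' For every (item, position, concern) cell, the applicability score is
#' the proportion of respondents to the item who ticked an argument of
#' that concern as applying to that position. Both perspectives are
#' pooled by default: each respondent to an item contributes exactly one
#' judgment per cell, whether they judged the position as their own side
#' or as the other side.
#'
#' @param judgments Judgment tibble from [derive_judgments()].
#' @param participants Optional participant tibble, needed when
#'   `participant_filter` is given.
#' @param participant_filter Optional predicate: a function taking the
#'   participant tibble and returning a logical vector selecting the
#'   subpopulation to score.
#' @param participant_ids Optional character vector of participant ids
#'   to restrict to (alternative to `participant_filter`).
#' @param perspective Which judgments to count: `"both"` (default,
#'   the score's definition), `"own"` or `"other"` (used by the
#'   opinion-based analysis).
#' @param min_judgments Cells with fewer judgments are omitted.
#' @param population_label Label stored on the result.
#' @return A tibble (class `score_table`) with columns `item_id`,
#'   `position`, `concern`, `ticks`, `judgments`, `score`, in
#'   deterministic (item, position, concern) order.
#' @export
applicability_scores <- function(judgments,
                                 participants = NULL,
                                 participant_filter = NULL,
                                 participant_ids = NULL,
                                 perspective = c("both", "own", "other"),
                                 min_judgments = 1,
                                 population_label = "all") {
  perspective <- match.arg(perspective)
  if (!is.null(participant_filter)) {
    if (is.null(participants)) {
      stop("participant_filter requires a participants table", call. = FALSE)
    }
    keep <- participant_filter(participants)
    keep[is.na(keep)] <- FALSE
    participant_ids <- participants$participant_id[keep]
  }
  x <- judgments
  if (!is.null(participant_ids)) {
    x <- x[x$participant_id %in% participant_ids, ]
  }
  if (perspective != "both") {
    x <- x[x$perspective == perspective, ]
  }
  if (nrow(x) == 0) {
    warning("no judgments match the participant filter; empty score table",
            call. = FALSE)
  }
  out <- x |>
    dplyr::group_by(.data$item_id, .data$position, .data$concern) |>
    dplyr::summarise(ticks = sum(.data$applies),
                     judgments = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$judgments >= min_judgments) |>
    dplyr::mutate(score = .data$ticks / .data$judgments) |>
    dplyr::arrange(.data$item_id, .data$position, .data$concern)
  attr(out, "population_label") <- population_label
  class(out) <- c("score_table", class(out))
  out
}

#' Pair two populations' score tables
#'
#' Intersects the populated cells of two score tables built against the
#' same item set and taxonomy, yielding one row per shared
#' (item, position, concern) cell in deterministic order
#' (pairwise-complete: cells missing from either table are dropped).
#'
#' @param table_1,table_2 Score tables from [applicability_scores()].
#' @return A tibble (class `paired_scores`) with columns `item_id`,
#'   `position`, `concern`, `score_1`, `score_2`, `n_1`, `n_2`.
#' @export
pair_scores <- function(table_1, table_2) {
  a <- tibble::as_tibble(table_1)[, c("item_id", "position", "concern",
                                      "score", "judgments")]
  b <- tibble::as_tibble(table_2)[, c("item_id", "position", "concern",
                                      "score", "judgments")]
  out <- dplyr::inner_join(a, b, by = c("item_id", "position", "concern"),
                           suffix = c("_1", "_2")) |>
    dplyr::rename(n_1 = "judgments_1", n_2 = "judgments_2") |>
    dplyr::select("item_id", "position", "concern",
                  "score_1", "score_2", "n_1", "n_2") |>
    dplyr::arrange(.data$item_id, .data$position, .data$concern)
  if (nrow(out) == 0) {
    warning("score tables share no populated cells; empty pairing",
            call. = FALSE)
  }
  attr(out, "labels") <- c(attr(table_1, "population_label") %||% "1",
                           attr(table_2, "population_label") %||% "2")
  class(out) <- c("paired_scores", class(out))
  out
}
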