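#' Column order for a response table
#'
#' Responses are stored in long format, one row per (participant, item)
#' judgment pair, with per-concern 0/1 tick columns for the respondent's
#' own position (`own_<concern>`) and the opposite position
#' (`other_<concern>`), catch-all flags, and the index (1..k) of the
#' argument wording shown for each concern (`shown_<concern>`).
#'
#' @param taxonomy A `concern_taxonomy`.
#' @return Character vector of column names in canonical order.
#' @export
response_columns <- function(taxonomy) {
  cons <- taxonomy$concerns
  c(
    "participant_id", "item_id", "own_answer",
    paste0("own_", cons), paste0("other_", cons),
    "other_reason_own", "other_reason_other",
    paste0("shown_", cons)
  )
}

participant_columns <- function() {
  c("participant_id", "sex", "age", "ideology", "ideology_score",
    "education", "verbal_ability", "country", "population_label")
}

validate_responses <- function(responses, taxonomy) {
  required <- response_columns(taxonomy)
  missing_cols <- setdiff(required, names(responses))
  if (length(missing_cols)) {
    stop("response table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_pos <- !responses$own_answer %in% POSITIONS
  if (any(bad_pos)) {
    stop("invalid own_answer at row(s) ",
         paste(head(which(bad_pos), 5), collapse = ", "),
         " (must be 'affirmative' or 'negative')", call. = FALSE)
  }
  dup <- duplicated(responses[c("participant_id", "item_id")])
  if (any(dup)) {
    stop("duplicate (participant, item) pair at row(s) ",
         paste(head(which(dup), 5), collapse = ", "), call. = FALSE)
  }
  for (con in taxonomy$concerns) {
    for (side in c("own_", "other_")) {
      v <- responses[[paste0(side, con)]]
      if (!all(v %in% c(0L, 1L))) {
        stop("column ", side, con, " must be 0/1; offending row(s): ",
             paste(head(which(!v %in% c(0L, 1L)), 5), collapse = ", "),
             call. = FALSE)
      }
    }
    s <- responses[[paste0("shown_", con)]]
    k <- length(taxonomy$arguments[[con]])
    if (!all(s %in% seq_len(k))) {
      stop("column shown_", con, " must index an argument 1..", k,
           "; offending row(s): ",
           paste(head(which(!s %in% seq_len(k)), 5), collapse = ", "),
           call. = FALSE)
    }
  }
  # tick columns referring to concerns outside the taxonomy
  tick_cols <- grep("^(own|other)_", names(responses), value = TRUE)
  tick_cols <- setdiff(
    tick_cols,
    c(paste0("own_", taxonomy$concerns), paste0("other_", taxonomy$concerns),
      "own_answer", "other_reason_own", "other_reason_other")
  )
  if (length(tick_cols)) {
    unknown <- unique(sub("^(own|other)_", "", tick_cols))
    stop("tick column(s) for unknown concern label(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  invisible(responses)
}

#' Read survey responses from a delimited file
#'
#' @param path File path (TSV by default).
#' @param taxonomy A `concern_taxonomy` the ticks are validated against.
#' @param delim Field delimiter, `"\t"` or `","`.
#' @return A tibble of validated responses in canonical column order.
#' @export
read_responses <- function(path, taxonomy, delim = "\t") {
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE)
  x <- tibble::as_tibble(x)
  validate_responses(x, taxonomy)
  x[, response_columns(taxonomy)]
}

#' Write survey responses to a delimited file
#'
#' Columns are written in the canonical order given by
#' [response_columns()] so repeated exports are byte-identical.
#'
#' @param responses Response tibble.
#' @param path Output path.
#' @inheritParams read_responses
#' @return `path`, invisibly.
#' @export
write_responses <- function(responses, path, taxonomy, delim = "\t") {
  validate_responses(responses, taxonomy)
  readr::write_delim(responses[, response_columns(taxonomy)], path,
                     delim = delim, progress = FALSE)
  invisible(path)
}

#' Read a participant demographics table
#'
#' @inheritParams read_responses
#' @return A tibble, one row per participant.
#' @export
read_participants <- function(path, delim = "\t") {
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE)
  x <- tibble::as_tibble(x)
  if (!"participant_id" %in% names(x)) {
    stop("participants file lacks a participant_id column", call. = FALSE)
  }
  if (anyDuplicated(x$participant_id)) {
    stop("duplicate participant_id at row(s) ",
         paste(head(which(duplicated(x$participant_id)), 5), collapse = ", "),
         call. = FALSE)
  }
  if ("ideology_score" %in% names(x)) {
    bad <- !is.na(x$ideology_score) &
      (x$ideology_score < 0 | x$ideology_score > 10)
    if (any(bad)) {
      stop("ideology_score outside 0-10 at row(s) ",
           paste(head(which(bad), 5), collapse = ", "), call. = FALSE)
    }
  }
  x
}

#' Write a participant demographics table
#'
#' @param participants Participant tibble.
#' @inheritParams write_responses
#' @return `path`, invisibly.
#' @export
write_participants <- function(participants, path, delim = "\t") {
  cols <- intersect(participant_columns(), names(participants))
  cols <- c(cols, setdiff(names(participants), cols))
  readr::write_delim(participants[, cols], path, delim = delim,
                     progress = FALSE)
  invisible(path)
}

#' Export a score table
#'
#' Writes one row per (item, position, concern) cell with exact tick and
#' judgment counts and the score printed to 6 decimals.
#'
#' @param table A score table from [applicability_scores()].
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(table, path, delim = "\t") {
  out <- table
  out$score <- sprintf("%.6f", out$score)
  readr::write_delim(out, path, delim = delim, progress = FALSE)
  invisible(path)
}
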