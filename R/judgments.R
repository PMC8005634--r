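#' Expand two-sided responses into per-(opinion, concern) judgments
#'
#' Each response row records one participant's ticks for their own
#' position and for the opposite position. This normalizes those ticks
#' into one row per (participant, item, position, concern): the
#' `applies` flag is the tick, and `perspective` records whether the
#' judged position was the respondent's own side or the other side.
#' Every response expands to exactly `2 * length(taxonomy$concerns)`
#' judgments; the catch-all "some other reason" flags are not judgments
#' of any concern and are dropped here.
#'
#' @param responses Validated response tibble (see [read_responses()]).
#' @param taxonomy A `concern_taxonomy`.
#' @return A tibble with columns `participant_id`, `item_id`, `position`,
#'   `concern`, `applies` (logical), `perspective` ("own" or "other").
#' @export
derive_judgments <- function(responses, taxonomy) {
  validate_responses(responses, taxonomy)
  cons <- taxonomy$concerns
  expand_side <- function(prefix, perspective) {
    ticks <- as.matrix(responses[paste0(prefix, cons)])
    pos <- if (perspective == "own") {
      responses$own_answer
    } else {
      opposite_position(responses$own_answer)
    }
    tibble::tibble(
      participant_id = rep(responses$participant_id, times = length(cons)),
      item_id = rep(responses$item_id, times = length(cons)),
      position = rep(pos, times = length(cons)),
      concern = rep(cons, each = nrow(responses)),
      applies = as.vector(ticks) == 1L,
      perspective = perspective
    )
  }
  out <- dplyr::bind_rows(expand_side("own_", "own"),
                          expand_side("other_", "other"))
  dplyr::arrange(out, .data$participant_id, .data$item_id,
                 .data$position, .data$concern)
}
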