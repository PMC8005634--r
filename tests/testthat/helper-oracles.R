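# Independent oracle for the concordance correlation coefficient, built
# on stats::cov/var (bias-corrected estimators rescaled to 1/n moments)
# rather than the package's own moment computation.
ccc_oracle <- function(x, y) {
  n <- length(x)
  cxy <- cov(x, y) * (n - 1) / n
  vx <- var(x) * (n - 1) / n
  vy <- var(y) * (n - 1) / n
  2 * cxy / (vx + vy + (mean(x) - mean(y))^2)
}

# Naive per-cell scoring by explicit aggregation, independent of the
# package's grouped-summarise path.
scores_oracle <- function(judgments) {
  agg <- aggregate(applies ~ item_id + position + concern,
                   data = as.data.frame(judgments),
                   FUN = function(v) c(ticks = sum(v), n = length(v)))
  out <- data.frame(agg[1:3],
                    ticks = agg$applies[, "ticks"],
                    judgments = agg$applies[, "n"])
  out$score <- out$ticks / out$judgments
  out[order(out$item_id, out$position, out$concern), ]
}

# A small two-group study used throughout the tests.
tiny_study <- function(seed = 42, n_items = 8, n_per_group = 30,
                       items_pp = 4, tau = 0, kappa = 0, ...) {
  cfg <- sim_config(
    n_items,
    list(sim_group("a", n_per_group, tau = tau),
         sim_group("b", n_per_group, tau = tau)),
    items_per_participant = items_pp,
    kappa = kappa, seed = seed, ...
  )
  simulate_study(cfg)
}

group_ids <- function(study, label) {
  study$participants$participant_id[
    study$participants$population_label == label
  ]
}

# Hand-built response table: one row per participant x item with
# explicit tick sets (lists of concern labels).
manual_responses <- function(rows, taxonomy = default_taxonomy()) {
  cons <- taxonomy$concerns
  out <- lapply(rows, function(r) {
    rec <- list(participant_id = r$participant_id,
                item_id = r$item_id,
                own_answer = r$own_answer)
    for (co in cons) {
      rec[[paste0("own_", co)]] <- as.integer(co %in% (r$own_ticks %||% c()))
      rec[[paste0("other_", co)]] <-
        as.integer(co %in% (r$other_ticks %||% c()))
    }
    rec$other_reason_own <- r$other_reason_own %||% 0L
    rec$other_reason_other <- r$other_reason_other %||% 0L
    for (co in cons) rec[[paste0("shown_", co)]] <- r$shown %||% 1L
    tibble::as_tibble(rec)
  })
  dplyr::bind_rows(out)[, response_columns(taxonomy)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
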