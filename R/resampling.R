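# Internal matrix form of a judgment table: one row per participant, one
# column per (item, position, concern) cell; `ticks` holds 0/1 ticks and
# `judged` marks which cells the participant actually judged.
judgment_matrices <- function(judgments) {
  pids <- sort(unique(judgments$participant_id))
  cell_key <- paste(judgments$item_id, judgments$position,
                    judgments$concern, sep = "\r")
  cells <- sort(unique(cell_key))
  pidx <- match(judgments$participant_id, pids)
  cidx <- match(cell_key, cells)
  ticks <- matrix(0, length(pids), length(cells))
  judged <- matrix(0, length(pids), length(cells))
  ticks[cbind(pidx, cidx)] <- as.numeric(judgments$applies)
  judged[cbind(pidx, cidx)] <- 1
  parts <- strsplit(cells, "\r", fixed = TRUE)
  list(
    participants = pids,
    ticks = ticks,
    judged = judged,
    cell_item = vapply(parts, `[[`, "", 1L),
    cell_position = vapply(parts, `[[`, "", 2L),
    cell_concern = vapply(parts, `[[`, "", 3L)
  )
}

# CCC between the score vectors of two disjoint participant row sets,
# over cells populated with at least `min_judgments` judgments per side.
split_ccc_rows <- function(jm, rows1, rows2, min_judgments = 1) {
  t1 <- colSums(jm$ticks[rows1, , drop = FALSE])
  j1 <- colSums(jm$judged[rows1, , drop = FALSE])
  t2 <- colSums(jm$ticks[rows2, , drop = FALSE])
  j2 <- colSums(jm$judged[rows2, , drop = FALSE])
  keep <- j1 >= min_judgments & j2 >= min_judgments & j1 > 0 & j2 > 0
  if (sum(keep) < 2) return(NA_real_)
  ccc(t1[keep] / j1[keep], t2[keep] / j2[keep])
}

new_null_result <- function(observed, splits, B_requested, n1, n2, seed,
                            conservative, extra = list()) {
  splits <- splits[!is.na(splits)]
  n_eff <- length(splits)
  n_discarded <- B_requested - n_eff
  if (n_discarded > 0.01 * B_requested) {
    stop("more than 1% of split replicates produced an empty pairing (",
         n_discarded, " of ", B_requested, "); check min_judgments and ",
         "split sizes", call. = FALSE)
  }
  r <- sum(splits < observed)
  p <- if (conservative) (r + 1) / (n_eff + 1) else r / n_eff
  structure(
    c(list(
      observed_ccc = observed,
      expected_ccc = mean(splits),
      split_cccs = splits,
      p_value = p,
      B = n_eff,
      n_1 = n1, n_2 = n2,
      seed = seed,
      n_discarded = n_discarded,
      conservative = conservative
    ), extra),
    class = "null_result"
  )
}

#' @export
print.null_result <- function(x, ...) {
  cat("<null_result> observed CCC ", sprintf("%.4f", x$observed_ccc),
      "; expected CCC under perfect agreement ",
      sprintf("%.4f", x$expected_ccc),
      " (", x$B, " random splits, sizes ", x$n_1, "/", x$n_2, ")\n",
      "p = ", format(x$p_value), sep = "")
  if (x$n_discarded > 0) cat("  (", x$n_discarded, " replicates discarded)\n")
  cat("\n")
  invisible(x)
}

#' Random-split test of perfect population-level agreement
#'
#' The null hypothesis is that the two populations are in perfect
#' agreement (population CCC = 1), so the observed between-sample CCC
#' falls short of 1 only through sampling error. Under this null the two
#' samples are exchangeable draws from one population: the test pools
#' them and repeatedly (`B` times) re-splits the pooled participants at
#' random into two subsamples of the original sizes, recomputing the
#' between-split CCC each time. The mean of these split CCCs is the
#' *expected CCC under perfect agreement* (the proper reference value in
#' place of 1), and the p-value is the proportion of split CCCs strictly
#' below the observed CCC.
#'
#' Splits are at participant level: all of a participant's judgments
#' move together.
#'
#' @param judgments Judgment tibble from [derive_judgments()].
#' @param ids_1,ids_2 Disjoint character vectors of participant ids
#'   forming the two observed samples; their union is the pooled sample.
#' @param B Number of random splits (default 1000).
#' @param seed Integer seed; results are reproducible given it.
#' @param min_judgments Cells with fewer judgments on either side of a
#'   split are dropped from that split's pairing.
#' @param conservative If `TRUE`, use the (r + 1) / (B + 1) p-value
#'   instead of the plain proportion r / B.
#' @return A `null_result` list: `observed_ccc`, `expected_ccc`,
#'   `split_cccs`, `p_value`, `B`, `n_1`, `n_2`, `seed`, `n_discarded`.
#' @export
random_split_null <- function(judgments, ids_1, ids_2, B = 1000,
                              seed = 1L, min_judgments = 1,
                              conservative = FALSE) {
  B <- assert_count(B, "B")
  if (length(intersect(ids_1, ids_2))) {
    stop("ids_1 and ids_2 must be disjoint", call. = FALSE)
  }
  pooled <- c(ids_1, ids_2)
  jm <- judgment_matrices(
    judgments[judgments$participant_id %in% pooled, ]
  )
  rows1 <- match(intersect(ids_1, jm$participants), jm$participants)
  rows2 <- match(intersect(ids_2, jm$participants), jm$participants)
  n1 <- length(rows1)
  n2 <- length(rows2)
  if (n1 < 2 || n2 < 2) {
    stop("each sample needs at least two participants with judgments",
         call. = FALSE)
  }
  observed <- split_ccc_rows(jm, rows1, rows2, min_judgments)
  if (is.na(observed)) {
    stop("observed pairing is empty; nothing to test", call. = FALSE)
  }
  np <- n1 + n2
  splits <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      r1 <- sample.int(np, n1)
      split_ccc_rows(jm, r1, setdiff(seq_len(np), r1), min_judgments)
    }, numeric(1))
  })
  new_null_result(observed, splits, B, n1, n2, seed, conservative)
}

# Internal: per-item structures for stratified splitting. `item_sides`
# assigns every respondent of every item to side 1 or 2.
stratified_structures <- function(judgments, item_sides) {
  jm <- judgment_matrices(judgments)
  items <- sort(unique(item_sides$item_id))
  lapply(items, function(it) {
    cells <- which(jm$cell_item == it)
    side_tab <- item_sides[item_sides$item_id == it, ]
    rows <- match(side_tab$participant_id, jm$participants)
    ok <- !is.na(rows)
    side_tab <- side_tab[ok, ]
    rows <- rows[ok]
    list(
      item_id = it,
      ticks = jm$ticks[rows, cells, drop = FALSE],
      side = side_tab$side,
      n1 = sum(side_tab$side == 1L),
      n2 = sum(side_tab$side == 2L),
      cell_position = jm$cell_position[cells],
      cell_concern = jm$cell_concern[cells]
    )
  })
}

# Scores for one item under a side assignment, oriented per `orient`.
# Returns a 2-column matrix (vec1, vec2) over the item's cells.
item_side_scores <- function(st, side, orient) {
  s1 <- colMeans(st$ticks[side == 1L, , drop = FALSE])
  s2 <- colMeans(st$ticks[side == 2L, , drop = FALSE])
  if (orient == "opinion") {
    # side 1 holds the affirmative position: for affirmative cells the
    # holders' vector is s1, for negative cells it is s2
    neg <- st$cell_position == "negative"
    v1 <- ifelse(neg, s2, s1)
    v2 <- ifelse(neg, s1, s2)
    cbind(v1, v2)
  } else {
    cbind(s1, s2)
  }
}

#' Stratified (per-item) random-split null
#'
#' Like [random_split_null()], but respondents are re-split
#' independently *within each item*, preserving each item's two
#' original side sizes. This is the appropriate null when the observed
#' partition itself varies by item, as in the opinion-based analysis
#' where each item's respondents are divided by their own answer.
#'
#' @param judgments Judgment tibble.
#' @param item_sides Tibble with columns `item_id`, `participant_id`,
#'   `side` (1 or 2): the observed per-item partition.
#' @param B Number of replicates.
#' @param seed Integer seed.
#' @param orient `"population"`: side 1 is always score vector 1.
#'   `"opinion"`: side 1 holds the affirmative position, so for
#'   negative-position cells the roles swap — vector 1 is always "the
#'   side that holds the judged opinion", mirroring the observed
#'   supporter/opponent construction.
#' @param min_side Items where either side has fewer respondents are
#'   dropped (with a message) before the analysis.
#' @param conservative See [random_split_null()].
#' @return A `null_result` with extra elements `n_items_used` and
#'   `dropped_items`.
#' @export
stratified_split_null <- function(judgments, item_sides, B = 1000,
                                  seed = 1L,
                                  orient = c("population", "opinion"),
                                  min_side = 2, conservative = FALSE) {
  orient <- match.arg(orient)
  B <- assert_count(B, "B")
  if (!all(item_sides$side %in% c(1L, 2L))) {
    stop("side must be 1 or 2", call. = FALSE)
  }
  structures <- stratified_structures(judgments, item_sides)
  sizes_ok <- vapply(structures, function(st) {
    st$n1 >= min_side && st$n2 >= min_side
  }, logical(1))
  dropped <- vapply(structures[!sizes_ok], `[[`, "", "item_id")
  if (length(dropped)) {
    message("dropping ", length(dropped),
            " item(s) with fewer than ", min_side,
            " respondents on a side: ",
            paste(head(dropped, 10), collapse = ", "))
  }
  structures <- structures[sizes_ok]
  if (!length(structures)) {
    stop("no items left after dropping under-sized sides", call. = FALSE)
  }

  pooled_ccc <- function(score_fun) {
    sc <- do.call(rbind, lapply(structures, score_fun))
    ccc(sc[, 1], sc[, 2])
  }
  observed <- pooled_ccc(function(st) {
    item_side_scores(st, st$side, orient)
  })
  splits <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      pooled_ccc(function(st) {
        item_side_scores(st, sample(st$side), orient)
      })
    }, numeric(1))
  })
  n1 <- sum(vapply(structures, `[[`, 0L, "n1"))
  n2 <- sum(vapply(structures, `[[`, 0L, "n2"))
  new_null_result(observed, splits, B, n1, n2, seed, conservative,
                  extra = list(n_items_used = length(structures),
                               dropped_items = unname(dropped)))
}

#' Participant-level bootstrap interval for the CCC
#'
#' Resamples participants with replacement within each of the two
#' samples, recomputes both score tables and the between-sample CCC,
#' and returns a percentile interval. An alternative to the asymptotic
#' [ccc_ci()] that respects the participant-level dependence of the
#' score cells.
#'
#' @inheritParams random_split_null
#' @param level Confidence level.
#' @return Named numeric vector `c(lower, upper)` with attribute
#'   `"boot_cccs"` holding the replicate values.
#' @export
ccc_ci_boot <- function(judgments, ids_1, ids_2, B = 500, seed = 1L,
                        level = 0.95, min_judgments = 1) {
  B <- assert_count(B, "B")
  jm <- judgment_matrices(
    judgments[judgments$participant_id %in% c(ids_1, ids_2), ]
  )
  rows1 <- match(intersect(ids_1, jm$participants), jm$participants)
  rows2 <- match(intersect(ids_2, jm$participants), jm$participants)
  reps <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      split_ccc_rows(jm,
                     sample(rows1, length(rows1), replace = TRUE),
                     sample(rows2, length(rows2), replace = TRUE),
                     min_judgments)
    }, numeric(1))
  })
  reps <- reps[!is.na(reps)]
  alpha <- (1 - level) / 2
  out <- quantile(reps, c(alpha, 1 - alpha), names = FALSE, type = 7)
  out <- c(lower = out[1], upper = out[2])
  attr(out, "boot_cccs") <- reps
  out
}
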