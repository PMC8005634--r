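#' Specify a two-way participant split
#'
#' Defines how a participant pool is partitioned into the two
#' subpopulations whose applicability scores are compared:
#' \describe{
#'   \item{sex}{women vs men.}
#'   \item{age}{sample-median split, younger vs older; participants at
#'     the median go to the younger side (deterministic rule).}
#'   \item{ideology}{the binary liberal vs conservative attribute.}
#'   \item{ideology_scale}{left (0 to `left_max`) vs right (`right_min`
#'     to 10) on the 11-point left-right scale; the moderates in
#'     between are excluded.}
#'   \item{education}{higher vs lower.}
#'   \item{verbal_ability}{Wordsum score `>= wordsum_cut` (higher) vs
#'     below it (lower).}
#'   \item{country, population}{two named levels of the `country` or
#'     `population_label` attribute.}
#' }
#' Participants missing the attribute are excluded from the split.
#'
#' @param attribute Which attribute to split on.
#' @param label Display label for the comparison.
#' @param levels Length-2 character vector naming the two sides, for
#'   `country` and `population` splits.
#' @param left_max,right_min Scale thresholds for `ideology_scale`
#'   (defaults 3 and 7: left 0-3, moderate 4-6, right 7-10).
#' @param wordsum_cut Verbal-ability threshold (default 8: higher is 8
#'   or above, lower is 7 or below).
#' @return A `split_spec` list.
#' @export
split_spec <- function(attribute = c("sex", "age", "ideology",
                                     "ideology_scale", "education",
                                     "verbal_ability", "country",
                                     "population"),
                       label = NULL, levels = NULL,
                       left_max = 3, right_min = 7, wordsum_cut = 8) {
  attribute <- match.arg(attribute)
  if (attribute %in% c("country", "population") &&
      (is.null(levels) || length(levels) != 2)) {
    stop("country/population splits need exactly two levels", call. = FALSE)
  }
  structure(
    list(attribute = attribute,
         label = label %||% attribute,
         levels = levels,
         left_max = left_max, right_min = right_min,
         wordsum_cut = wordsum_cut),
    class = "split_spec"
  )
}

#' Partition participants according to a split specification
#'
#' @param participants Participant tibble.
#' @param spec A [split_spec()].
#' @return A list with `ids_1`, `ids_2` (disjoint participant id
#'   vectors), `labels` (the two side labels) and `n_1`, `n_2`.
#' @export
demographic_split <- function(participants, spec) {
  p <- participants
  col <- switch(spec$attribute,
    sex = "sex", age = "age", ideology = "ideology",
    ideology_scale = "ideology_score", education = "education",
    verbal_ability = "verbal_ability", country = "country",
    population = "population_label"
  )
  if (!col %in% names(p)) {
    stop("participants lack attribute ", sQuote(col), call. = FALSE)
  }
  p <- p[!is.na(p[[col]]), ]
  v <- p[[col]]
  sides <- switch(spec$attribute,
    sex = list(v == "female", v == "male", c("women", "men")),
    age = {
      med <- median(v)
      list(v <= med, v > med, c("younger", "older"))
    },
    ideology = list(v == "liberal", v == "conservative",
                    c("liberals", "conservatives")),
    ideology_scale = list(v <= spec$left_max, v >= spec$right_min,
                          c("left-wing", "right-wing")),
    education = list(v == "higher", v == "lower",
                     c("higher education", "lower education")),
    verbal_ability = list(v >= spec$wordsum_cut, v < spec$wordsum_cut,
                          c("higher verbal ability",
                            "lower verbal ability")),
    country = ,
    population = list(v == spec$levels[1], v == spec$levels[2], spec$levels)
  )
  ids_1 <- p$participant_id[sides[[1]]]
  ids_2 <- p$participant_id[sides[[2]]]
  if (length(ids_1) < 2 || length(ids_2) < 2) {
    stop("split ", sQuote(spec$label), " leaves a side with fewer than ",
         "two participants (", length(ids_1), " vs ", length(ids_2), ")",
         call. = FALSE)
  }
  list(ids_1 = ids_1, ids_2 = ids_2, labels = sides[[3]],
       n_1 = length(ids_1), n_2 = length(ids_2))
}

#' Supporter-vs-opponent agreement on argument applicability
#'
#' Splits each item's respondents by their own answer and compares, for
#' every opinion, the applicability scores implied by its holders'
#' own-side ticks (vector 1) with those implied by the opposite
#' answer's holders judging it from the other side (vector 2). Because
#' the partition differs across items, the perfect-agreement null
#' re-splits respondents within each item ([stratified_split_null()]
#' with the opinion orientation).
#'
#' Opinions where either side has fewer than `min_holders` holders are
#' dropped; the dropped items are reported.
#'
#' @param responses Validated response tibble.
#' @param taxonomy A `concern_taxonomy`.
#' @param min_holders Minimum holders required on each side of an item.
#' @param B Number of null replicates.
#' @param seed Integer seed.
#' @param level Confidence level for the CCC interval.
#' @param conservative See [random_split_null()].
#' @return A list with `agreement` (one-row tibble as [agreement()],
#'   plus `n_opinions_used`), `null` (a `null_result`), `paired`
#'   (the supporter/opponent paired scores) and `dropped_items`.
#' @export
opinion_split_analysis <- function(responses, taxonomy,
                                   min_holders = 5, B = 1000, seed = 1L,
                                   level = 0.95, conservative = FALSE) {
  validate_responses(responses, taxonomy)
  judgments <- derive_judgments(responses, taxonomy)
  counts <- responses |>
    dplyr::count(.data$item_id, .data$own_answer) |>
    tidyr::pivot_wider(names_from = "own_answer", values_from = "n",
                       values_fill = 0L)
  for (pos in POSITIONS) if (!pos %in% names(counts)) counts[[pos]] <- 0L
  retained <- counts$item_id[counts$affirmative >= min_holders &
                               counts$negative >= min_holders]
  dropped <- setdiff(counts$item_id, retained)
  if (!length(retained)) {
    stop("no opinions retained at min_holders = ", min_holders,
         call. = FALSE)
  }
  keep_resp <- responses[responses$item_id %in% retained, ]
  keep_judg <- judgments[judgments$item_id %in% retained, ]

  # own-perspective judgments of opinion P come exactly from P's
  # holders; other-perspective ones from the opposite answer's holders
  t_own <- applicability_scores(keep_judg, perspective = "own",
                                population_label = "supporters")
  t_other <- applicability_scores(keep_judg, perspective = "other",
                                  population_label = "opponents")
  paired <- pair_scores(t_own, t_other)
  agr <- agreement(paired, level = level)
  agr$n_opinions_used <- dplyr::n_distinct(paired$item_id, paired$position)

  item_sides <- tibble::tibble(
    item_id = keep_resp$item_id,
    participant_id = keep_resp$participant_id,
    side = ifelse(keep_resp$own_answer == "affirmative", 1L, 2L)
  )
  null <- stratified_split_null(keep_judg, item_sides, B = B, seed = seed,
                                orient = "opinion",
                                min_side = max(2, min_holders),
                                conservative = conservative)
  list(agreement = agr, null = null, paired = paired,
       dropped_items = dropped)
}

#' Run a full between-population agreement study
#'
#' End-to-end pipeline: derive judgments, then for each requested
#' comparison partition the participants, estimate both sides'
#' applicability score tables, pair them, summarize agreement (CCC with
#' confidence interval, Pearson, regression line) and run the
#' random-split test of perfect agreement. Also computes the
#' full-sample score table and its per-concern boxplot summary.
#'
#' @param study A `sim_study` from [simulate_study()], or any list with
#'   elements `participants` and `responses` (canonical schemas).
#' @param comparisons List of [split_spec()] objects.
#' @param taxonomy Taxonomy; defaults to the study's configured one.
#' @param B Number of random-split replicates per comparison.
#' @param seed Integer base seed; comparison i uses `seed + i`.
#' @param min_judgments Minimum judgments per cell and side.
#' @param level Confidence level for CCC intervals.
#' @return A `study_report` list: `results` (one row per comparison:
#'   sizes, `n_pairs`, `ccc`, CI, `expected_ccc`, `p_value`, `pearson`,
#'   OLS line), `boxplot`, `scores_full`, `paired` (named list of
#'   paired score tables), `nulls` (named list of `null_result`s),
#'   `B`, `seed`.
#' @export
run_study <- function(study, comparisons, taxonomy = NULL, B = 1000,
                      seed = 1L, min_judgments = 1, level = 0.95) {
  taxonomy <- taxonomy %||% study$config$taxonomy %||% default_taxonomy()
  if (inherits(comparisons, "split_spec")) comparisons <- list(comparisons)
  judgments <- derive_judgments(study$responses, taxonomy)
  scores_full <- applicability_scores(judgments,
                                      min_judgments = min_judgments,
                                      population_label = "all")
  rows <- list()
  paired_list <- list()
  nulls <- list()
  for (i in seq_along(comparisons)) {
    spec <- comparisons[[i]]
    sides <- demographic_split(study$participants, spec)
    t1 <- applicability_scores(judgments, participant_ids = sides$ids_1,
                               min_judgments = min_judgments,
                               population_label = sides$labels[1])
    t2 <- applicability_scores(judgments, participant_ids = sides$ids_2,
                               min_judgments = min_judgments,
                               population_label = sides$labels[2])
    paired <- pair_scores(t1, t2)
    agr <- agreement(paired, level = level)
    null <- random_split_null(judgments, sides$ids_1, sides$ids_2,
                              B = B, seed = seed + i,
                              min_judgments = min_judgments)
    rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(comparison = spec$label,
                     n_1 = sides$n_1, n_2 = sides$n_2),
      agr,
      tibble::tibble(expected_ccc = null$expected_ccc,
                     p_value = null$p_value)
    )
    paired_list[[spec$label]] <- paired
    nulls[[spec$label]] <- null
  }
  structure(
    list(results = dplyr::bind_rows(rows),
         boxplot = boxplot_summary(scores_full),
         scores_full = scores_full,
         paired = paired_list,
         nulls = nulls,
         B = B, seed = seed),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> ", nrow(x$results), " comparison(s), B = ", x$B,
      ", seed = ", x$seed, "\n\n", sep = "")
  df <- as.data.frame(x$results)
  df$ccc <- sprintf("%.3f [%.3f, %.3f]", df$ccc, df$ci_lower, df$ci_upper)
  print(df[, c("comparison", "n_1", "n_2", "n_pairs", "ccc",
               "expected_ccc", "p_value")], row.names = FALSE)
  invisible(x)
}

#' Write a study report to delimited files
#'
#' Writes `results`, `boxplot` (outlier lists collapsed to
#' comma-separated strings) and one tidy scatter file per comparison
#' (`scatter_<label>`), all with deterministic column order.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed).
#' @param delim Field delimiter.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, delim = "\t") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (delim == ",") ".csv" else ".tsv"
  readr::write_delim(report$results, file.path(dir, paste0("results", ext)),
                     delim = delim, progress = FALSE)
  bp <- report$boxplot
  bp$outliers <- vapply(bp$outliers,
                        function(v) paste(sprintf("%.6f", v), collapse = ","),
                        "")
  bp$extreme_outliers <- vapply(bp$extreme_outliers,
                                function(v) paste(sprintf("%.6f", v),
                                                  collapse = ","), "")
  readr::write_delim(bp, file.path(dir, paste0("boxplot", ext)),
                     delim = delim, progress = FALSE)
  for (label in names(report$paired)) {
    safe <- gsub("[^A-Za-z0-9_-]+", "_", label)
    readr::write_delim(tibble::as_tibble(report$paired[[label]]),
                       file.path(dir, paste0("scatter_", safe, ext)),
                       delim = delim, progress = FALSE)
  }
  invisible(dir)
}
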