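paired_xy <- function(x, y) {
  if (is.null(y)) {
    if (!is.data.frame(x) || !all(c("score_1", "score_2") %in% names(x))) {
      stop("supply either two numeric vectors or a paired_scores table",
           call. = FALSE)
    }
    list(x = as.numeric(x$score_1), y = as.numeric(x$score_2))
  } else {
    list(x = as.numeric(x), y = as.numeric(y))
  }
}

#' Lin's concordance correlation coefficient
#'
#' Measures agreement between two paired score vectors as
#' `2 * s_xy / (s_x^2 + s_y^2 + (m_x - m_y)^2)`, with means `m` and
#' biased (1/n) moment estimators `s`. Unlike the Pearson correlation it
#' penalizes departures from the 45-degree identity line, not just
#' departures from linearity, so it is 1 only under perfect agreement.
#'
#' Degenerate cases: if both vectors are constant and equal the CCC is
#' 1 by convention; if both are constant but unequal the numerator is 0
#' and the denominator positive, giving 0.
#'
#' @param x A `paired_scores` table, or a numeric vector.
#' @param y A numeric vector when `x` is numeric.
#' @return A single number in `[-1, 1]`.
#' @examples
#' ccc(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9))  # 1
#' ccc(c(0, 1), c(1, 0))                    # -1
#' @export
ccc <- function(x, y = NULL) {
  v <- paired_xy(x, y)
  x <- v$x
  y <- v$y
  n <- length(x)
  if (n < 2 || length(y) != n) {
    stop("need at least two complete pairs", call. = FALSE)
  }
  mx <- mean(x)
  my <- mean(y)
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0) {
    return(1)
  }
  2 * sxy / denom
}

#' Pearson correlation of paired scores
#'
#' Plain product-moment correlation; measures deviation from linearity
#' only (it is blind to slope and intercept shifts). Returns `NA` with
#' a warning if either vector is constant.
#'
#' @inheritParams ccc
#' @return A single number in `[-1, 1]`, or `NA`.
#' @export
pearson_cor <- function(x, y = NULL) {
  v <- paired_xy(x, y)
  if (sd(v$x) == 0 || sd(v$y) == 0) {
    warning("constant vector: Pearson correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  cor(v$x, v$y)
}

#' Confidence interval for the CCC
#'
#' Lin's asymptotic interval: the CCC is mapped through the inverse
#' hyperbolic tangent (Fisher-type z transform), a normal interval is
#' built with Lin's asymptotic standard error, and the endpoints are
#' back-transformed, which keeps the interval inside `[-1, 1]`. When
#' the CCC is exactly +/-1 the interval degenerates to a point.
#'
#' @inheritParams ccc
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
ccc_ci <- function(x, y = NULL, level = 0.95) {
  v <- paired_xy(x, y)
  x <- v$x
  y <- v$y
  n <- length(x)
  if (n < 4) stop("need at least four pairs for the asymptotic CI",
                  call. = FALSE)
  C <- ccc(x, y)
  if (abs(C) >= 1) {
    return(c(lower = C, upper = C))
  }
  r <- pearson_cor(x, y)
  if (is.na(r) || r == 0) {
    stop("CCC confidence interval undefined for constant or uncorrelated",
         " data", call. = FALSE)
  }
  sx2 <- mean((x - mean(x))^2)
  sy2 <- mean((y - mean(y))^2)
  u <- (mean(x) - mean(y)) / sqrt(sqrt(sx2 * sy2))  # location shift, u^2 scale
  u2 <- u^2
  se_z2 <- ((1 - r^2) * C^2 / ((1 - C^2) * r^2) +
              2 * C^3 * (1 - C) * u2 / (r * (1 - C^2)^2) -
              C^4 * u2^2 / (2 * r^2 * (1 - C^2)^2)) / (n - 2)
  se_z <- sqrt(max(se_z2, 0))
  z <- atanh(C)
  q <- qnorm(1 - (1 - level) / 2)
  c(lower = tanh(z - q * se_z), upper = tanh(z + q * se_z))
}

#' Least-squares line through paired scores
#'
#' Fits `score_2 ~ score_1` by ordinary least squares; under perfect
#' agreement the fitted line coincides with the identity line
#' (slope 1, intercept 0).
#'
#' @inheritParams ccc
#' @return Named numeric vector `c(slope, intercept)`.
#' @export
ols_line <- function(x, y = NULL) {
  v <- paired_xy(x, y)
  if (sd(v$x) == 0) stop("regressor is constant; no line defined",
                         call. = FALSE)
  fit <- lm(v$y ~ v$x)
  c(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]))
}

#' Per-concern score variances and their ratio
#'
#' For each concern, the biased (1/n) variance of each population's
#' scores across opinions, and the ratio `var_2 / var_1`. A ratio well
#' below 1 for every concern indicates that population 2 distinguishes
#' less sharply between opinions than population 1.
#'
#' @param paired A `paired_scores` table.
#' @param by_concern If `FALSE`, a single row over all cells instead.
#' @return A tibble with columns `concern`, `var_1`, `var_2`, `ratio`
#'   (`NA` where `var_1` is 0).
#' @export
variance_ratio <- function(paired, by_concern = TRUE) {
  biased_var <- function(z) mean((z - mean(z))^2)
  grp <- if (by_concern) dplyr::group_by(paired, .data$concern) else
    dplyr::mutate(paired, concern = "all") |> dplyr::group_by(.data$concern)
  out <- grp |>
    dplyr::summarise(
      n = dplyr::n(),
      var_1 = biased_var(.data$score_1),
      var_2 = biased_var(.data$score_2),
      .groups = "drop"
    )
  if (any(out$n < 2)) {
    stop("need at least two pairs per concern for a variance ratio",
         call. = FALSE)
  }
  out$ratio <- ifelse(out$var_1 == 0, NA_real_, out$var_2 / out$var_1)
  dplyr::select(out, "concern", "var_1", "var_2", "ratio")
}

#' Per-concern boxplot summary of applicability scores
#'
#' Five-number summary per concern with Tukey-style fences: the box is
#' the interquartile range (quartiles by linear interpolation,
#' `quantile()` type 7), the whiskers reach the minimum and maximum
#' values lying within 1.5 box heights of the box edges, values between
#' 1.5 and 3 box heights outside the box are outliers, and values more
#' than 3 box heights outside are extreme outliers.
#'
#' @param table A `score_table`.
#' @return A tibble, one row per concern, with columns `concern`, `n`,
#'   `median`, `q1`, `q3`, `whisker_low`, `whisker_high` and
#'   list-columns `outliers`, `extreme_outliers`.
#' @export
boxplot_summary <- function(table) {
  summarise_one <- function(s) {
    if (length(s) < 5) {
      stop("need at least five scores per concern for a boxplot summary",
           call. = FALSE)
    }
    q <- quantile(s, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    inner_lo <- q[1] - 1.5 * iqr
    inner_hi <- q[3] + 1.5 * iqr
    outer_lo <- q[1] - 3 * iqr
    outer_hi <- q[3] + 3 * iqr
    inside <- s[s >= inner_lo & s <= inner_hi]
    tibble::tibble(
      n = length(s),
      median = q[2], q1 = q[1], q3 = q[3],
      whisker_low = min(inside), whisker_high = max(inside),
      outliers = list(sort(s[(s < inner_lo & s >= outer_lo) |
                               (s > inner_hi & s <= outer_hi)])),
      extreme_outliers = list(sort(s[s < outer_lo | s > outer_hi]))
    )
  }
  tibble::as_tibble(table) |>
    dplyr::group_by(.data$concern) |>
    dplyr::reframe(summarise_one(.data$score)) |>
    dplyr::arrange(.data$concern)
}

#' Full agreement summary for a paired score table
#'
#' Combines the CCC, its confidence interval, the Pearson correlation
#' and the fitted regression line into one row.
#'
#' @param paired A `paired_scores` table.
#' @param level Confidence level for the CCC interval.
#' @return A one-row tibble with columns `n_pairs`, `ccc`, `ci_lower`,
#'   `ci_upper`, `pearson`, `ols_slope`, `ols_intercept`.
#' @export
agreement <- function(paired, level = 0.95) {
  ci <- ccc_ci(paired, level = level)
  line <- ols_line(paired)
  tibble::tibble(
    n_pairs = nrow(paired),
    ccc = ccc(paired),
    ci_lower = ci[["lower"]],
    ci_upper = ci[["upper"]],
    pearson = pearson_cor(paired),
    ols_slope = line[["slope"]],
    ols_intercept = line[["intercept"]]
  )
}
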