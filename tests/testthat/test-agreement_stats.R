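test_that("the CCC matches hand-computed values on toy vectors", {
  expect_equal(ccc(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9)), 1)
  expect_equal(ccc(c(0, 1), c(1, 0)), -1)
  # means equal (0.4), s12 = 0.04/3, s1^2 = 0.08/3, s2^2 = 0.02/3:
  # 2 * 0.04 / (0.08 + 0.02) = 0.8
  expect_equal(ccc(c(0.2, 0.4, 0.6), c(0.3, 0.4, 0.5)), 0.8,
               tolerance = 1e-12)
  # degenerate conventions
  expect_equal(ccc(c(0.3, 0.3), c(0.3, 0.3)), 1)
  expect_equal(ccc(c(0.3, 0.3), c(0.6, 0.6)), 0)
  expect_error(ccc(0.5, 0.5), "at least two")
})

test_that("Pearson is 1 for affine relations and ~0 for independent noise", {
  expect_equal(pearson_cor(c(0.2, 0.4, 0.6), c(0.3, 0.4, 0.5)), 1)
  x <- c(0.1, 0.7, 0.4)
  expect_equal(pearson_cor(x, x), 1)
  withr::with_seed(101, {
    a <- rnorm(10000)
    b <- rnorm(10000)
    expect_lt(abs(pearson_cor(a, b)), 0.05)
  })
  expect_warning(r <- pearson_cor(c(1, 1, 1), c(0, 1, 2)), "constant")
  expect_true(is.na(r))
})

test_that("CCC obeys its structural properties on fuzzed vectors", {
  withr::with_seed(77, {
    for (i in 1:300) {
      n <- sample(2:50, 1)
      x <- runif(n)
      y <- runif(n)
      C <- ccc(x, y)
      r <- suppressWarnings(pearson_cor(x, y))
      expect_gte(C, -1)
      expect_lte(C, 1)
      if (!is.na(r)) expect_lte(abs(C), abs(r) + 1e-12)
      expect_equal(C, ccc(y, x), tolerance = 1e-12)
      perm <- sample.int(n)
      expect_equal(C, ccc(x[perm], y[perm]), tolerance = 1e-12)
    }
  })
})

test_that("adding a constant offset strictly lowers the CCC", {
  x <- c(0.1, 0.3, 0.5, 0.8)
  vals <- vapply(c(0, 0.05, 0.1, 0.3, 0.6), function(d) ccc(x, x + d),
                 numeric(1))
  expect_equal(vals[1], 1)
  expect_true(all(diff(vals) < 0))
})

test_that("the asymptotic CI brackets the estimate and narrows with n", {
  st <- tiny_study(seed = 47)
  j <- derive_judgments(st$responses, st$config$taxonomy)
  p <- pair_scores(
    applicability_scores(j, participant_ids = group_ids(st, "a")),
    applicability_scores(j, participant_ids = group_ids(st, "b"))
  )
  ci <- ccc_ci(p)
  C <- ccc(p)
  expect_lte(ci[["lower"]], C)
  expect_gte(ci[["upper"]], C)
  expect_true(all(abs(ci) <= 1))

  # width shrinks as the number of paired cells grows under the same
  # generative scores (SE ~ 1/sqrt(n))
  width <- function(n_pairs, seed) {
    withr::with_seed(seed, {
      theta <- rbeta(n_pairs, 0.8, 1.6)
      x <- rbinom(n_pairs, 50, theta) / 50
      y <- rbinom(n_pairs, 50, theta) / 50
      ci <- ccc_ci(x, y)
      ci[["upper"]] - ci[["lower"]]
    })
  }
  expect_lt(width(1568, 3), width(100, 3))

  expect_identical(ccc_ci(c(0.1, 0.2, 0.3, 0.4), c(0.1, 0.2, 0.3, 0.4)),
                   c(lower = 1, upper = 1))
})

test_that("the 95% CI attains nominal coverage on bivariate-normal data", {
  # population CCC in closed form for a bivariate normal
  rho <- 0.9
  s1 <- 1
  s2 <- 1.2
  mu_d <- 0.3
  true_ccc <- 2 * rho * s1 * s2 / (s1^2 + s2^2 + mu_d^2)
  withr::with_seed(2024, {
    covered <- vapply(1:500, function(i) {
      z1 <- rnorm(200)
      z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(200)
      x <- z1 * s1
      y <- z2 * s2 + mu_d
      ci <- ccc_ci(x, y)
      ci[["lower"]] <= true_ccc && true_ccc <= ci[["upper"]]
    }, logical(1))
  })
  expect_gte(mean(covered), 0.92)
  expect_lte(mean(covered), 0.98)
})

test_that("the fitted line recovers exact and shrunken relations", {
  x <- c(0.1, 0.2, 0.5, 0.9)
  expect_equal(ols_line(x, x), c(slope = 1, intercept = 0))
  expect_equal(ols_line(x, 0.5 * x + 0.1), c(slope = 0.5, intercept = 0.1))
  expect_error(ols_line(rep(0.4, 5), x), "constant")

  # group 2 pulled toward its mean by 0.7 with binomial noise
  withr::with_seed(55, {
    theta <- rbeta(1568, 0.8, 1.6)
    shrunk <- mean(theta) + 0.7 * (theta - mean(theta))
    x <- rbinom(1568, 100, theta) / 100
    y <- rbinom(1568, 100, shrunk) / 100
    sl <- ols_line(x, y)[["slope"]]
  })
  expect_lt(abs(sl - 0.7), 0.05)
})

test_that("variance ratios detect compressed score dispersion", {
  st <- tiny_study(seed = 53)
  j <- derive_judgments(st$responses, st$config$taxonomy)
  tab <- applicability_scores(j)
  same <- pair_scores(tab, tab)
  vr <- variance_ratio(same)
  expect_equal(nrow(vr), 8)
  expect_true(all(vr$ratio == 1))

  half <- same
  half$score_2 <- mean(half$score_2) + 0.5 * (half$score_2 - mean(half$score_2))
  vr_all <- variance_ratio(half, by_concern = FALSE)
  expect_equal(vr_all$ratio, 0.25, tolerance = 1e-12)

  flat <- same
  flat$score_1 <- 0.4
  expect_true(all(is.na(variance_ratio(flat)$ratio)))
})

test_that("boxplot summaries apply the whisker and outlier fences", {
  tax1 <- load_taxonomy(NULL)
  mk_table <- function(scores) {
    tibble::tibble(item_id = sprintf("i%02d", seq_along(scores)),
                   position = "affirmative", concern = "harm",
                   ticks = 0L, judgments = 1L, score = scores)
  }
  even <- boxplot_summary(mk_table(seq(0.1, 0.9, by = 0.1)))
  expect_equal(even$whisker_low, 0.1)
  expect_equal(even$whisker_high, 0.9)
  expect_equal(even$median, 0.5)
  expect_length(even$outliers[[1]], 0)
  expect_length(even$extreme_outliers[[1]], 0)

  # quartiles by linear interpolation: (0.1, 0.2, 0.3, 0.4, 1.0) has
  # q1 = 0.2, median = 0.3, q3 = 0.4, so 1.0 sits exactly at the outer
  # fence (q3 + 3 * IQR) and is an ordinary outlier
  skew <- boxplot_summary(mk_table(c(0.1, 0.2, 0.3, 0.4, 1.0)))
  expect_equal(skew$q1, 0.2)
  expect_equal(skew$q3, 0.4)
  expect_equal(skew$whisker_high, 0.4)
  expect_equal(skew$outliers[[1]], 1.0)

  far <- boxplot_summary(mk_table(c(0.1, 0.2, 0.3, 0.4, 0.2, 0.25, 2.5)))
  expect_true(2.5 %in% far$extreme_outliers[[1]])

  expect_error(boxplot_summary(mk_table(c(0.1, 0.2))), "at least five")
})

test_that("offset-configured studies rank fairness and liberty highest", {
  cfg <- sim_preset("shared_27", scale = 0.6, seed = 63,
                    concern_offsets = c(fairness = 1.2, liberty = 1.2))
  st <- simulate_study(cfg)
  tab <- applicability_scores(derive_judgments(st$responses, cfg$taxonomy))
  bp <- boxplot_summary(tab)
  top2 <- bp$concern[order(bp$median, decreasing = TRUE)][1:2]
  expect_setequal(top2, c("fairness", "liberty"))
})

test_that("agreement() assembles a consistent one-row summary", {
  st <- tiny_study(seed = 59)
  j <- derive_judgments(st$responses, st$config$taxonomy)
  p <- pair_scores(
    applicability_scores(j, participant_ids = group_ids(st, "a")),
    applicability_scores(j, participant_ids = group_ids(st, "b"))
  )
  a <- agreement(p)
  expect_equal(a$n_pairs, nrow(p))
  expect_equal(a$ccc, ccc(p))
  expect_lte(abs(a$ccc), abs(a$pearson))
  expect_true(a$ci_lower <= a$ccc && a$ccc <= a$ci_upper)
})
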