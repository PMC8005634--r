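test_that("true-score draws honour the prior and the seed", {
  cfg_point <- sim_config(4, sim_group("a", 10),
                          items_per_participant = 2,
                          theta_prior = list(dist = "point", value = 0.5),
                          seed = 1)
  th <- draw_true_scores(cfg_point)
  expect_equal(nrow(th), 4 * 2 * 8)
  expect_true(all(th$theta == 0.5))

  cfg <- sim_config(20, sim_group("a", 10), items_per_participant = 5,
                    seed = 99)
  expect_identical(draw_true_scores(cfg), draw_true_scores(cfg))

  # Monte-Carlo check of the Beta(2, 2) prior mean against its closed
  # form (0.5); 10,000+ cells
  cfg_mc <- sim_config(320, sim_group("a", 10), items_per_participant = 5,
                       theta_prior = list(dist = "beta", shape1 = 2,
                                          shape2 = 2),
                       seed = 7)
  th_mc <- draw_true_scores(cfg_mc)  # 320 * 2 * 8 = 5,120 cells
  expect_gt(nrow(th_mc), 5000)
  expect_lt(abs(mean(th_mc$theta) - 0.5), 0.01)
})

test_that("concern offsets shift the configured concerns' medians up", {
  cfg <- sim_config(120, sim_group("a", 10), items_per_participant = 5,
                    concern_offsets = c(fairness = 1.5, liberty = 1.5),
                    seed = 21)
  th <- draw_true_scores(cfg)
  med <- tapply(th$theta, th$concern, median)
  shifted <- sort(med, decreasing = TRUE)[1:2]
  expect_setequal(names(shifted), c("fairness", "liberty"))
})

test_that("log-odds perturbation is unbiased in scale and monotone in tau", {
  cfg <- sim_config(320, sim_group("a", 10), items_per_participant = 5,
                    theta_prior = list(dist = "point", value = 0.5),
                    seed = 3)
  base <- draw_true_scores(cfg)

  expect_identical(perturb_group_scores(base, 0, seed = 5), base)

  # tau = 5 around logit 0: compare the empirical variance of theta'
  # with numerical integration of the logit-normal second moment
  big <- base[rep(1, 10000), ]
  pert <- perturb_group_scores(big, 5, seed = 8)
  m2 <- integrate(function(x) plogis(x)^2 * dnorm(x, 0, 5), -Inf, Inf)$value
  m1 <- integrate(function(x) plogis(x) * dnorm(x, 0, 5), -Inf, Inf)$value
  expect_lt(abs(var(pert$theta) - (m2 - m1^2)), 0.01)

  for (seed in 1:3) {
    devs <- vapply(c(0, 0.3, 1.0), function(tau) {
      mean(abs(perturb_group_scores(base, tau, seed = seed)$theta -
                 base$theta))
    }, numeric(1))
    expect_true(all(diff(devs) > 0))
  }
})

test_that("simulated studies are deterministic and correctly shaped", {
  st1 <- tiny_study(seed = 17)
  st2 <- tiny_study(seed = 17)
  expect_identical(st1$responses, st2$responses)
  expect_identical(st1$participants, st2$participants)
  expect_identical(st1$truth, st2$truth)
  expect_false(identical(st1$responses, tiny_study(seed = 18)$responses))

  # byte-identical files under an identical config
  tax <- st1$config$taxonomy
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_responses(st1$responses, f1, tax)
  write_responses(st2$responses, f2, tax)
  expect_identical(readLines(f1), readLines(f2))

  expect_equal(nrow(st1$responses),
               nrow(st1$participants) * st1$config$items_per_participant)
  expect_error(sim_config(5, sim_group("a", 10), items_per_participant = 6),
               "cannot exceed")
  expect_error(sim_group("a", 0), "n_participants")
})

test_that("a saturated generator ticks every concern", {
  cfg <- sim_config(4, sim_group("a", 20), items_per_participant = 2,
                    theta_prior = list(dist = "point", value = 1), seed = 2)
  st <- simulate_study(cfg)
  tick_cols <- c(paste0("own_", cfg$taxonomy$concerns),
                 paste0("other_", cfg$taxonomy$concerns))
  expect_true(all(as.matrix(st$responses[tick_cols]) == 1L))
})

test_that("a 98-item study covers 196 distinct opinions", {
  cfg <- sim_preset("us_like", scale = 0.35, seed = 5)
  st <- simulate_study(cfg)
  j <- derive_judgments(st$responses, cfg$taxonomy)
  expect_equal(dplyr::n_distinct(j$item_id, j$position), 196)
})

test_that("empirical scores converge to the latent truth when tau = kappa = 0", {
  # single item, theta = 0.3 everywhere, 5,000 raters: binomial SE ~ 0.0065
  cfg <- sim_config(1, sim_group("a", 5000), items_per_participant = 1,
                    theta_prior = list(dist = "point", value = 0.3),
                    seed = 31)
  st <- simulate_study(cfg)
  tab <- applicability_scores(derive_judgments(st$responses, cfg$taxonomy))
  expect_true(all(abs(tab$score - 0.3) < 0.02))

  # heterogeneous truth, 5 items fully crossed: max deviation below 0.03
  cfg2 <- sim_config(5, sim_group("a", 5000), items_per_participant = 5,
                     seed = 32)
  st2 <- simulate_study(cfg2)
  tab2 <- applicability_scores(derive_judgments(st2$responses,
                                                cfg2$taxonomy))
  truth <- st2$truth$a
  merged <- dplyr::inner_join(
    tibble::as_tibble(tab2), truth,
    by = c("item_id", "position", "concern")
  )
  expect_equal(nrow(merged), 5 * 16)
  expect_lt(max(abs(merged$score - merged$theta)), 0.03)
})

test_that("judgments per item match the sampling design", {
  st <- tiny_study(seed = 13, n_items = 10, n_per_group = 100, items_pp = 4)
  n <- 200
  p <- 4 / 10
  raters <- dplyr::count(st$responses, item_id)
  expect_equal(sum(raters$n), n * 4)
  z <- (raters$n - n * p) / sqrt(n * p * (1 - p))
  expect_true(all(abs(z) < 3))
})

test_that("preset designs reproduce the three studies' arithmetic", {
  us <- sim_preset("us_like")
  expect_equal(us$n_items, 98)
  expect_equal(us$groups[[1]]$n_participants * us$items_per_participant /
                 us$n_items, 110, tolerance = 0.01)
  uk <- sim_preset("uk_like")
  expect_equal(uk$n_items, 108)
  expect_equal(uk$groups[[1]]$n_participants * uk$items_per_participant /
                 uk$n_items, 100, tolerance = 0.01)
  sh <- sim_preset("shared_27", n_groups = 2)
  expect_equal(sh$n_items, 27)
  expect_length(sh$groups, 2)
})
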