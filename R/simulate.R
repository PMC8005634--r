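#' Specify one simulated population group
#'
#' @param label Group label (used as `population_label` and in ids).
#' @param n_participants Number of participants in the group.
#' @param tau Group-discrepancy parameter: standard deviation of the
#'   zero-mean normal perturbation applied to the latent applicability
#'   scores on the log-odds scale. `tau = 0` means the group shares the
#'   base truth exactly (the null of perfect agreement).
#' @param compress Distinctiveness factor in (0, 1]: the group's latent
#'   scores are pulled toward their grand mean by this factor
#'   (`theta_g = m + compress * (theta - m)`). `compress = 1` leaves
#'   them unchanged; values below 1 emulate a group that distinguishes
#'   less sharply between opinions.
#' @param country Country string recorded for each participant.
#' @param demographics Optional function `function(n)` returning a
#'   tibble of demographic columns overriding the built-in generator.
#' @return A `sim_group` list.
#' @export
sim_group <- function(label, n_participants, tau = 0, compress = 1,
                      country = label, demographics = NULL) {
  stopifnot(tau >= 0, compress > 0, compress <= 1)
  n_participants <- assert_count(n_participants, "n_participants")
  structure(
    list(label = label, n_participants = n_participants, tau = tau,
         compress = compress, country = country,
         demographics = demographics),
    class = "sim_group"
  )
}

#' Configure a synthetic argument-attribution survey
#'
#' The generator emulates the study design of the argument-applicability
#' surveys: `n_items` dichotomous moral questions, each participant
#' judging `items_per_participant` randomly drawn items, answering
#' yes/no, then ticking which of the taxonomy's concerns apply to their
#' own position and to the opposite position. Ticks are Bernoulli draws
#' governed by a latent true score matrix theta over
#' (opinion, concern) cells.
#'
#' @param n_items Number of dichotomous items (98 US-like, 108 UK-like,
#'   27 shared cross-country set).
#' @param groups List of [sim_group()] specifications.
#' @param items_per_participant Items judged by each participant
#'   (default 19, the Study-1 average; fixed per participant).
#' @param taxonomy A `concern_taxonomy`.
#' @param theta_prior Distribution spec for the baseline latent scores:
#'   `list(dist = "beta", shape1, shape2)`,
#'   `list(dist = "uniform", min, max)` or
#'   `list(dist = "point", value)`. Default Beta(0.8, 1.6), right-skewed
#'   with most mass below 0.5.
#' @param concern_offsets Optional named numeric vector of per-concern
#'   log-odds shifts applied to the baseline scores (e.g. to make
#'   fairness and liberty the most applicable concerns).
#' @param opinion_prevalence Distribution spec for each item's
#'   probability of an affirmative own answer. Default Beta(2, 2).
#' @param kappa Perspective-discrepancy parameter: standard deviation of
#'   extra zero-mean log-odds noise applied per judgment when a
#'   respondent judges the side opposite their own. `kappa = 0` means
#'   opponents use the same latent scores as supporters.
#' @param within_concern_argument_sd Standard deviation of per-argument
#'   wording effects on the log-odds scale (0 disables them).
#' @param seed Integer seed; all generator output is deterministic
#'   given the full configuration including the seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_items,
                       groups,
                       items_per_participant = 19,
                       taxonomy = default_taxonomy(),
                       theta_prior = list(dist = "beta", shape1 = 0.8,
                                          shape2 = 1.6),
                       concern_offsets = NULL,
                       opinion_prevalence = list(dist = "beta", shape1 = 2,
                                                 shape2 = 2),
                       kappa = 0,
                       within_concern_argument_sd = 0,
                       seed = 1L) {
  n_items <- assert_count(n_items, "n_items")
  items_per_participant <- assert_count(items_per_participant,
                                        "items_per_participant")
  if (items_per_participant > n_items) {
    stop("items_per_participant cannot exceed n_items", call. = FALSE)
  }
  if (inherits(groups, "sim_group")) groups <- list(groups)
  if (!length(groups) || !all(vapply(groups, inherits, TRUE, "sim_group"))) {
    stop("groups must be a list of sim_group() specifications",
         call. = FALSE)
  }
  labels <- vapply(groups, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("group labels must be unique", call. = FALSE)
  stopifnot(kappa >= 0, within_concern_argument_sd >= 0)
  if (!is.null(concern_offsets)) {
    bad <- setdiff(names(concern_offsets), taxonomy$concerns)
    if (length(bad)) {
      stop("concern_offsets for unknown concern(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(
      n_items = n_items, groups = groups,
      items_per_participant = items_per_participant,
      taxonomy = taxonomy, theta_prior = theta_prior,
      concern_offsets = concern_offsets,
      opinion_prevalence = opinion_prevalence,
      kappa = kappa,
      within_concern_argument_sd = within_concern_argument_sd,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Ready-made study-design presets
#'
#' Three presets mirror the design arithmetic of the original surveys:
#' `"us_like"` (98 items, 568 participants, 19 items each, roughly 110
#' raters per item), `"uk_like"` (108 items, 903 participants, 12 items
#' each, roughly 100 raters per item) and `"shared_27"` (the 27-item
#' cross-country set, 223 participants, 12 items each, roughly 99
#' raters per item).
#'
#' @param name Preset name.
#' @param n_groups Number of equal-sized groups the participant pool is
#'   divided into (participants per group = total / n_groups, rounded).
#' @param tau Group discrepancy passed to every group.
#' @param scale Multiplier on the participant counts, to run smaller
#'   studies with the same items/ratings structure.
#' @param ... Further arguments passed to [sim_config()] (e.g. `kappa`,
#'   `seed`, `concern_offsets`).
#' @return A `sim_config`.
#' @export
sim_preset <- function(name = c("us_like", "uk_like", "shared_27"),
                       n_groups = 1, tau = 0, scale = 1, ...) {
  name <- match.arg(name)
  des <- switch(name,
    us_like   = list(n_items = 98L, n_total = 568L, ipp = 19L),
    uk_like   = list(n_items = 108L, n_total = 903L, ipp = 12L),
    shared_27 = list(n_items = 27L, n_total = 223L, ipp = 12L)
  )
  per_group <- max(2L, as.integer(round(des$n_total * scale / n_groups)))
  groups <- lapply(seq_len(n_groups), function(g) {
    sim_group(paste0("g", g), per_group, tau = tau)
  })
  sim_config(n_items = des$n_items, groups = groups,
             items_per_participant = des$ipp, ...)
}

draw_dist <- function(spec, n) {
  switch(spec$dist,
    beta = rbeta(n, spec$shape1, spec$shape2),
    uniform = runif(n, spec$min %||% 0, spec$max %||% 1),
    point = rep(spec$value, n),
    stop("unknown distribution spec: ", spec$dist, call. = FALSE)
  )
}

item_ids <- function(n_items) sprintf("item%03d", seq_len(n_items))

theta_grid <- function(config) {
  tidyr::expand_grid(
    item_id = item_ids(config$n_items),
    position = POSITIONS,
    concern = config$taxonomy$concerns
  )
}

.draw_true_scores <- function(config) {
  grid <- theta_grid(config)
  theta <- draw_dist(config$theta_prior, nrow(grid))
  if (!is.null(config$concern_offsets)) {
    off <- config$concern_offsets[grid$concern]
    off[is.na(off)] <- 0
    theta <- inv_logit(logit(clamp_unit(theta)) + off)
  }
  grid$theta <- theta
  grid
}

#' Draw a latent true score matrix
#'
#' One latent probability theta per (opinion, concern) cell, drawn from
#' the configured prior and shifted by any per-concern log-odds
#' offsets. Deterministic given the configuration seed.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `item_id`, `position`, `concern`,
#'   `theta`.
#' @export
draw_true_scores <- function(config) {
  withr::with_seed(config$seed, .draw_true_scores(config))
}

.perturb_group_scores <- function(base, tau, compress = 1) {
  theta <- base$theta
  if (compress < 1) {
    m <- mean(theta)
    theta <- m + compress * (theta - m)
  }
  if (tau > 0) {
    theta <- inv_logit(logit(clamp_unit(theta)) +
                         rnorm(length(theta), 0, tau))
  }
  out <- base
  out$theta <- theta
  out
}

#' Perturb a true score matrix on the log-odds scale
#'
#' Adds independent zero-mean normal noise with standard deviation
#' `tau` to each cell's log-odds. Scores exactly 0 or 1 are clamped to
#' `[1e-6, 1 - 1e-6]` before the transform. `tau = 0` returns the input
#' unchanged.
#'
#' @param base A true score tibble from [draw_true_scores()].
#' @param tau Non-negative perturbation standard deviation.
#' @param seed Integer seed.
#' @return A perturbed true score tibble of the same shape.
#' @export
perturb_group_scores <- function(base, tau, seed = 1L) {
  stopifnot(tau >= 0)
  if (tau == 0) return(base)
  withr::with_seed(seed, .perturb_group_scores(base, tau))
}

default_demographics <- function(n) {
  score <- sample(0:10, n, TRUE)
  ideology <- ifelse(score <= 4, "liberal",
                     ifelse(score >= 6, "conservative",
                            sample(c("liberal", "conservative"), n, TRUE)))
  tibble::tibble(
    sex = sample(c("female", "male"), n, TRUE, prob = c(0.59, 0.41)),
    age = pmin(pmax(round(rnorm(n, 39.2, 12)), 18), 80),
    ideology = ideology,
    ideology_score = score,
    education = sample(c("higher", "lower"), n, TRUE, prob = c(0.53, 0.47)),
    verbal_ability = rbinom(n, 10, 0.75)
  )
}

#' Simulate a full argument-attribution study
#'
#' Draws a base true score matrix, derives each group's matrix (optional
#' compression toward the grand mean, then tau log-odds perturbation),
#' and simulates every participant's item draws, own answers and
#' two-sided concern ticks. Other-side ticks receive extra per-judgment
#' log-odds noise with standard deviation `kappa`; per-argument wording
#' effects are applied when `within_concern_argument_sd > 0`.
#'
#' @param config A [sim_config()].
#' @return A `sim_study` list with elements `participants` (tibble),
#'   `responses` (tibble in the canonical response schema), `truth`
#'   (named list of per-group true score tibbles, plus `"base"`), and
#'   `config`.
#' @export
simulate_study <- function(config) {
  withr::with_seed(config$seed, .simulate_study(config))
}

.simulate_study <- function(config) {
  tax <- config$taxonomy
  cons <- tax$concerns
  nc <- length(cons)
  ids <- item_ids(config$n_items)

  base <- .draw_true_scores(config)
  prevalence <- draw_dist(config$opinion_prevalence, config$n_items)

  # per-argument wording effects, fixed for the study
  arg_delta <- lapply(tax$arguments, function(a) {
    if (config$within_concern_argument_sd > 0) {
      rnorm(length(a), 0, config$within_concern_argument_sd)
    } else {
      rep(0, length(a))
    }
  })
  names(arg_delta) <- cons

  truth <- list(base = base)
  participants <- list()
  responses <- list()

  for (grp in config$groups) {
    theta_g <- .perturb_group_scores(base, grp$tau, grp$compress)
    truth[[grp$label]] <- theta_g
    # array lookup: [item, position, concern], rows of theta_g are
    # ordered item x position x concern (expand_grid order)
    th <- array(theta_g$theta,
                dim = c(nc, 2L, config$n_items))  # concern fastest
    n <- grp$n_participants
    pid <- sprintf("%s_p%04d", grp$label, seq_len(n))

    demo <- if (is.null(grp$demographics)) {
      default_demographics(n)
    } else {
      grp$demographics(n)
    }
    demo$participant_id <- pid
    demo$country <- grp$country
    demo$population_label <- grp$label
    participants[[grp$label]] <-
      demo[, intersect(participant_columns(), names(demo))]

    ipp <- config$items_per_participant
    item_idx <- as.vector(vapply(
      seq_len(n), function(i) sample.int(config$n_items, ipp),
      integer(ipp)
    ))
    nr <- n * ipp
    row_pid <- rep(pid, each = ipp)
    own_aff <- runif(nr) < prevalence[item_idx]
    own_pos_idx <- ifelse(own_aff, 1L, 2L)
    opp_pos_idx <- 3L - own_pos_idx

    shown <- matrix(0L, nr, nc)
    delta <- matrix(0, nr, nc)
    for (j in seq_len(nc)) {
      k <- length(tax$arguments[[cons[j]]])
      shown[, j] <- sample.int(k, nr, replace = TRUE)
      delta[, j] <- arg_delta[[cons[j]]][shown[, j]]
    }

    tick_probs <- function(pos_idx, extra_sd) {
      p <- matrix(0, nr, nc)
      for (j in seq_len(nc)) {
        p[, j] <- th[cbind(j, pos_idx, item_idx)]
      }
      shift <- delta
      if (extra_sd > 0) {
        shift <- shift + matrix(rnorm(nr * nc, 0, extra_sd), nr, nc)
      }
      if (any(shift != 0)) {
        p <- inv_logit(logit(clamp_unit(p)) + shift)
      }
      p
    }
    own_ticks <- 1L * (matrix(runif(nr * nc), nr, nc) <
                         tick_probs(own_pos_idx, 0))
    other_ticks <- 1L * (matrix(runif(nr * nc), nr, nc) <
                           tick_probs(opp_pos_idx, config$kappa))

    resp <- tibble::tibble(
      participant_id = row_pid,
      item_id = ids[item_idx],
      own_answer = POSITIONS[own_pos_idx]
    )
    for (j in seq_len(nc)) resp[[paste0("own_", cons[j])]] <- own_ticks[, j]
    for (j in seq_len(nc)) resp[[paste0("other_", cons[j])]] <- other_ticks[, j]
    resp$other_reason_own <- rbinom(nr, 1, 0.1)
    resp$other_reason_other <- rbinom(nr, 1, 0.1)
    for (j in seq_len(nc)) resp[[paste0("shown_", cons[j])]] <- shown[, j]
    responses[[grp$label]] <- resp
  }

  participants <- dplyr::bind_rows(participants)
  responses <- dplyr::bind_rows(responses)
  responses <- responses[, response_columns(tax)]
  structure(
    list(participants = participants, responses = responses,
         truth = truth, config = config),
    class = "sim_study"
  )
}

#' @export
print.sim_study <- function(x, ...) {
  cat("<sim_study> ", length(x$config$groups), " group(s), ",
      nrow(x$participants), " participants, ",
      x$config$n_items, " items, ",
      nrow(x$responses), " responses\n", sep = "")
  invisible(x)
}
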