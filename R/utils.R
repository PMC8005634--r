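#' @importFrom rlang %||% .data
#' @importFrom stats cor lm coef median quantile rbeta rbinom rnorm runif
#'   sd setNames var qnorm
#' @importFrom utils head
NULL

POSITIONS <- c("affirmative", "negative")

opposite_position <- function(position) {
  unname(c(affirmative = "negative", negative = "affirmative")[position])
}

logit <- function(p) log(p / (1 - p))

inv_logit <- function(x) 1 / (1 + exp(-x))

# clamp away from {0, 1} so the log-odds transform stays finite
clamp_unit <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1 || !is.finite(x) || x < min || x != round(x)) {
    stop(name, " must be a single integer >= ", min, call. = FALSE)
  }
  as.integer(x)
}
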