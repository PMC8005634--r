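#' The built-in moral-concern taxonomy
#'
#' Eight moral concerns, each represented by three specific argument
#' wordings (24 arguments in total), plus a catch-all "some other reason"
#' option. The concerns are harm, fairness, ingroup loyalty, authority,
#' purity, liberty, violence and governmental overreach.
#'
#' @return A `concern_taxonomy` object: a list with elements
#'   `concerns` (ordered character vector of concern labels),
#'   `arguments` (named list mapping each concern to its argument texts)
#'   and `catch_all_label`.
#' @examples
#' tax <- default_taxonomy()
#' length(tax$concerns)                  # 8
#' sum(lengths(tax$arguments))           # 24
#' @export
default_taxonomy <- function() {
  arguments <- list(
    harm = c(
      "Someone suffers emotionally",
      "Someone cares for someone weak or vulnerable",
      "Someone is cruel"
    ),
    fairness = c(
      "Some people are treated differently from others",
      "Someone acts unfairly",
      "Someone is denied his or her rights"
    ),
    ingroup = c(
      "Someone's action shows love for his or her country",
      "Someone does something to betray his or her group",
      "Someone shows a lack of loyalty"
    ),
    authority = c(
      "Someone shows a lack of respect for authority",
      "Someone conforms to the traditions of society",
      "Someone creates disruption to the order in our country"
    ),
    purity = c(
      "Someone violates standards of purity and decency",
      "Someone does something disgusting",
      "Someone acts in a way that God would approve of"
    ),
    liberty = c(
      "Everyone is free to do as they wanted",
      "Someone's freedom of choice is restricted",
      "Everyone is free to decide what group norms or traditions they want to follow"
    ),
    violence = c(
      "Violence is used",
      "Someone is killed",
      "Someone is physically harmed"
    ),
    government = c(
      "It goes beyond what the government's responsibility should be",
      "It is expensive for the government",
      "The government would handle it poorly"
    )
  )
  new_taxonomy(names(arguments), arguments, "some other reason")
}

new_taxonomy <- function(concerns, arguments, catch_all_label) {
  tax <- structure(
    list(
      concerns = as.character(concerns),
      arguments = arguments,
      catch_all_label = catch_all_label
    ),
    class = "concern_taxonomy"
  )
  validate_taxonomy(tax)
}

validate_taxonomy <- function(tax) {
  if (length(tax$concerns) < 1) {
    stop("taxonomy must define at least one concern", call. = FALSE)
  }
  if (anyDuplicated(tax$concerns)) {
    stop(
      "duplicate concern labels: ",
      paste(unique(tax$concerns[duplicated(tax$concerns)]), collapse = ", "),
      call. = FALSE
    )
  }
  if (!setequal(names(tax$arguments), tax$concerns)) {
    stop("argument list must cover exactly the concern labels", call. = FALSE)
  }
  all_args <- unlist(tax$arguments, use.names = FALSE)
  if (anyDuplicated(all_args)) {
    stop(
      "duplicate argument text across the taxonomy: ",
      paste(sQuote(all_args[duplicated(all_args)]), collapse = ", "),
      call. = FALSE
    )
  }
  if (any(lengths(tax$arguments) < 1)) {
    stop("every concern needs at least one argument", call. = FALSE)
  }
  tax
}

#' Load a concern taxonomy from a YAML file
#'
#' The file maps each concern label to a list of argument wordings;
#' an optional `catch_all_label` key names the catch-all option
#' (default "some other reason"). With `path = NULL` the built-in
#' taxonomy from [default_taxonomy()] is returned.
#'
#' @param path Path to a YAML taxonomy file, or `NULL` for the default.
#' @return A `concern_taxonomy` object.
#' @export
load_taxonomy <- function(path = NULL) {
  if (is.null(path)) {
    return(default_taxonomy())
  }
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) {
      stop("cannot parse taxonomy file ", sQuote(path), ": ",
           conditionMessage(e), call. = FALSE)
    }
  )
  if (!is.list(raw) || is.null(names(raw))) {
    stop("taxonomy file must be a mapping of concern -> argument list",
         call. = FALSE)
  }
  catch_all <- raw[["catch_all_label"]] %||% "some other reason"
  raw[["catch_all_label"]] <- NULL
  arguments <- lapply(raw, function(x) as.character(unlist(x)))
  new_taxonomy(names(arguments), arguments, catch_all)
}

#' @export
print.concern_taxonomy <- function(x, ...) {
  cat("<concern_taxonomy> ", length(x$concerns), " concerns, ",
      sum(lengths(x$arguments)), " arguments\n", sep = "")
  for (con in x$concerns) {
    cat("  ", format(con, width = 12), " (",
        length(x$arguments[[con]]), " arguments)\n", sep = "")
  }
  invisible(x)
}

#' Write a taxonomy to a YAML file
#'
#' @param tax A `concern_taxonomy`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(tax, path) {
  out <- tax$arguments
  out$catch_all_label <- tax$catch_all_label
  yaml::write_yaml(out, path)
  invisible(path)
}
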