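#' Define a growth environment
#'
#' An environment is a named set of open uptake (exchange) reactions. By the
#' usual constraint-based convention, positive exchange flux is secretion;
#' uptake is modelled by giving the exchange reaction a negative lower bound
#' whose magnitude is the uptake bound stored here, so the environment type
#' itself is sign-free. Secretion through any exchange is always permitted.
#'
#' @param name environment name.
#' @param uptakes named numeric vector: exchange reaction id -> uptake bound
#'   (finite, non-negative magnitude).
#' @param element which elemental source (`"C"`, `"N"`, `"P"`, `"S"`) was
#'   swapped relative to the base medium, or `"none"`.
#' @param nutrient metabolite id of the swapped nutrient, or `NA`.
#' @param sources named character vector mapping element -> exchange reaction
#'   id of that element's source in this medium (used when deriving
#'   single-swap environments from a base medium).
#' @return a one-row tibble with columns `name`, `element`, `nutrient` and
#'   list-columns `uptakes` and `sources`. Environment collections are just
#'   row-bound tibbles of this shape.
#' @export
growth_env <- function(name, uptakes, element = "none", nutrient = NA_character_,
                       sources = NULL) {
  stopifnot(is.numeric(uptakes), !is.null(names(uptakes)))
  if (any(!is.finite(uptakes)) || any(uptakes < 0))
    stop("uptake bounds must be finite and non-negative", call. = FALSE)
  stopifnot(element %in% c("C", "N", "P", "S", "none"))
  tibble::tibble(name = name, element = element, nutrient = nutrient,
                 uptakes = list(uptakes),
                 sources = list(sources %||% character()))
}

# Coerce env argument (one-row env tibble or bare named numeric) to the
# named uptake vector.
env_uptakes <- function(env) {
  if (is.numeric(env) && !is.null(names(env))) return(env)
  if (is.data.frame(env)) {
    if (nrow(env) != 1L)
      stop("expected a single environment (one row); got ", nrow(env), call. = FALSE)
    return(env$uptakes[[1]])
  }
  stop("cannot interpret environment argument", call. = FALSE)
}

env_name <- function(env) {
  if (is.data.frame(env)) env$name else "env"
}

#' Read environment definitions
#'
#' Accepts either a JSON array of objects or a TSV, one environment per
#' record, with fields `name`, `element`, `nutrient`, and either an
#' `uptakes` object (JSON: exchange id -> bound) or `exchange` + `bound`
#' columns (TSV, one row per open uptake, grouped by `name`).
#'
#' @param path file path (`.json` or `.tsv`).
#' @return environment tibble as produced by [growth_env()].
#' @export
read_environments <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    return(purrr::map_dfr(recs, function(r) {
      growth_env(r$name, unlist(r$uptakes),
                 element = r$element %||% "none",
                 nutrient = r$nutrient %||% NA_character_)
    }))
  }
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("name", "exchange", "bound") %in% names(tab)))
  tab |>
    dplyr::group_by(.data$name) |>
    dplyr::group_map(function(g, key) {
      growth_env(key$name,
                 stats::setNames(g$bound, g$exchange),
                 element = if ("element" %in% names(g)) g$element[1] else "none",
                 nutrient = if ("nutrient" %in% names(g)) g$nutrient[1] else NA_character_)
    }) |>
    dplyr::bind_rows()
}

#' Write environments as JSON
#'
#' @param envs environment tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_environments <- function(envs, path) {
  recs <- purrr::pmap(envs, function(name, element, nutrient, uptakes, ...) {
    list(name = name, element = element, nutrient = nutrient,
         uptakes = as.list(uptakes))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
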