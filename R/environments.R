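#' Generate single-swap nutrient environments
#'
#' Starting from a base minimal medium that declares exactly one source per
#' element among C, N, P and S, produces one environment per (element,
#' candidate nutrient) pair by closing the base source of that element and
#' opening the candidate's exchange reaction at the default uptake bound.
#' All non-swapped base components stay open. The base environment itself is
#' included first. A candidate equal to the base source of its element is
#' suppressed as a duplicate; a candidate whose exchange reaction is absent
#' from `network` (when supplied) is skipped with a warning.
#'
#' @param base base environment (one-row tibble from [growth_env()]) whose
#'   `sources` field names the exchange reaction of each element's source.
#' @param candidates data frame with columns `element` (`"C"`, `"N"`,
#'   `"P"`, `"S"`), `nutrient` (metabolite id) and `exchange` (exchange
#'   reaction id); a nutrient usable for two elements appears once per
#'   element role.
#' @param network optional `metabolic_network` used to validate candidate
#'   exchanges (typically the universal network).
#' @param uptake_bound uptake bound given to the opened candidate exchange
#'   (default 10 flux units).
#' @return environment tibble (base environment first).
#' @export
generate_environments <- function(base, candidates, network = NULL,
                                  uptake_bound = 10) {
  stopifnot(is.data.frame(base), nrow(base) == 1)
  sources <- base$sources[[1]]
  stopifnot(all(c("C", "N", "P", "S") %in% names(sources)))
  stopifnot(all(c("element", "nutrient", "exchange") %in% names(candidates)))
  base_up <- base$uptakes[[1]]

  if (!is.null(network)) {
    ex_ids <- network$reactions$id[network$reactions$is_exchange]
    missing <- !(candidates$exchange %in% ex_ids)
    if (any(missing)) {
      warning("skipping candidate(s) without an exchange reaction: ",
              paste(candidates$nutrient[missing], collapse = ", "),
              call. = FALSE)
      candidates <- candidates[!missing, ]
    }
  }

  envs <- purrr::pmap(candidates, function(element, nutrient, exchange, ...) {
    if (exchange == sources[[element]]) return(NULL)  # base source itself
    up <- base_up[names(base_up) != sources[[element]]]
    up[exchange] <- uptake_bound
    src <- sources; src[[element]] <- exchange
    growth_env(paste0(element, ":", nutrient), up,
               element = element, nutrient = nutrient, sources = src)
  })
  dplyr::bind_rows(c(list(base), envs))
}

#' Screen environments for novel growth phenotypes
#'
#' Runs FBA viability of the host and of the expanded universal network in
#' every environment. An environment is *novel* when the host cannot grow
#' but the universal network can — the set of conditions the host could
#' reach by acquiring reactions from the pool.
#'
#' @param host host `metabolic_network`.
#' @param universal merged (host + pool) `metabolic_network`; must contain
#'   every host reaction.
#' @param envs environment tibble.
#' @param tol viability tolerance on biomass flux.
#' @return `envs` with logical columns `host_viable`, `universal_viable`,
#'   `novel` appended (class `environment_screen`).
#' @export
screen_novel <- function(host, universal, envs, tol = VIABILITY_TOL) {
  if (!all(host$reactions$id %in% universal$reactions$id))
    stop("universal network must contain every host reaction", call. = FALSE)
  res <- purrr::map(seq_len(nrow(envs)), function(i) {
    e <- envs[i, ]
    # environments may open exchanges that exist only in the universal
    # network; for the host those uptakes cannot be imported at all
    up <- e$uptakes[[1]]
    host_up <- up[names(up) %in% host$reactions$id[host$reactions$is_exchange]]
    c(host = is_viable(host, host_up, tol = tol),
      universal = is_viable(universal, e, tol = tol))
  })
  out <- envs
  out$host_viable <- vapply(res, `[[`, logical(1), "host")
  out$universal_viable <- vapply(res, `[[`, logical(1), "universal")
  out$novel <- !out$host_viable & out$universal_viable
  class(out) <- c("environment_screen", class(out))
  out
}

#' Write an environment screen as TSV
#'
#' Columns `env`, `element`, `nutrient`, `host_viable`, `universal_viable`,
#' `novel`.
#'
#' @param screen result of [screen_novel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_screen_tsv <- function(screen, path) {
  out <- data.frame(env = screen$name, element = screen$element,
                    nutrient = screen$nutrient,
                    host_viable = screen$host_viable,
                    universal_viable = screen$universal_viable,
                    novel = screen$novel)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
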