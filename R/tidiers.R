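#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an environment screen
#'
#' @param x an `environment_screen` from [screen_novel()].
#' @param ... unused.
#' @return tibble with one row per environment.
#' @export
tidy.environment_screen <- function(x, ...) {
  tibble::tibble(env = x$name, element = x$element, nutrient = x$nutrient,
                 host_viable = x$host_viable,
                 universal_viable = x$universal_viable, novel = x$novel)
}

#' @rdname tidy.environment_screen
#' @export
glance.environment_screen <- function(x, ...) {
  tibble::tibble(n_envs = nrow(x), n_host_viable = sum(x$host_viable),
                 n_universal_viable = sum(x$universal_viable),
                 n_novel = sum(x$novel))
}

#' Tidy a minimal-set enumeration
#'
#' @param x a `minimal_set_enumeration` from [enumerate_minimal_sets()].
#' @param ... unused.
#' @return tibble with columns `env`, `set_index`, `size`, `reaction_ids`
#'   (semicolon-joined).
#' @export
tidy.minimal_set_enumeration <- function(x, ...) {
  tibble::tibble(env = x$env,
                 set_index = seq_along(x$sets),
                 size = vapply(x$sets, `[[`, integer(1), "size"),
                 reaction_ids = vapply(x$sets, function(s)
                   paste(s$active_set, collapse = ";"), character(1)))
}

#' @rdname tidy.minimal_set_enumeration
#' @export
glance.minimal_set_enumeration <- function(x, ...) {
  tibble::tibble(env = x$env, minimal_size = x$minimal_size,
                 n_sets = length(x$sets), exhausted = x$exhausted)
}

#' Tidy a gap-fill solution
#'
#' @param x a `gapfill_solution`.
#' @param ... unused.
#' @return one-row tibble with `env`, `size`, `reaction_ids`,
#'   `biomass_flux`.
#' @export
tidy.gapfill_solution <- function(x, ...) {
  tibble::tibble(env = x$env, size = x$size,
                 reaction_ids = paste(x$active_set, collapse = ";"),
                 biomass_flux = x$biomass_flux)
}

#' Tidy a pair classification
#'
#' @param x a `pair_classification` from [screen_pairs()].
#' @param ... unused.
#' @return tibble with list-columns flattened to semicolon-joined strings.
#' @export
tidy.pair_classification <- function(x, ...) {
  join <- function(col) vapply(col, paste, character(1), collapse = ";")
  tibble::tibble(reaction_a = x$reaction_a, reaction_b = x$reaction_b,
                 envs = join(x$beneficial_envs), category = x$category,
                 stepping_stone_ids = join(x$stepping_stones))
}

#' Tidy / summarise contingent-gain test results
#'
#' @param x a `contingent_gain_test`.
#' @param ... unused.
#' @return one-row tibble.
#' @export
glance.contingent_gain_test <- function(x, ...) {
  tibble::tibble(mean_f = x$mean_f, n_used = x$n_used,
                 n_excluded = x$n_excluded, p_value = x$p_value)
}

#' @rdname glance.contingent_gain_test
#' @param x a `cogain_randomization`.
#' @export
glance.cogain_randomization <- function(x, ...) {
  tibble::tibble(observed_mean = x$observed_mean, reps = x$reps,
                 p_value = x$p_value)
}
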