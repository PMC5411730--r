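# LP bounds with every candidate closed except `open_ids`; returns max
# biomass flux. Used by the single- and pair-activation screens.
activate_and_grow <- function(network, env, cand_idx, open_idx) {
  bb <- fba_bounds(network, env)
  lb <- bb$lb; ub <- bb$ub
  closed <- setdiff(cand_idx, open_idx)
  lb[closed] <- 0; ub[closed] <- 0
  obj <- as.numeric(network$reactions$id == network$biomass)
  res <- lp_solve(obj, network$S, rep(0, length(network$metabolites)),
                  lb, ub, maximize = TRUE)
  if (res$status == "optimal") res$objective else 0
}

default_candidates <- function(network) {
  rx <- network$reactions
  sort(rx$id[rx$origin == "universal" & !rx$is_exchange])
}

#' Fitness effect of single reaction additions
#'
#' Adds each universal candidate reaction alone to the host (all other
#' candidates inactivated) and evaluates growth by FBA across the novel
#' environments.
#'
#' @param universal merged `metabolic_network`.
#' @param novel_envs environment tibble of host-inviable environments.
#' @param candidates candidate ids (default: all universal-origin,
#'   non-exchange reactions); passing a host-origin reaction is an error.
#' @param tol growth tolerance on biomass flux.
#' @return long tibble with columns `reaction`, `env`: one row per
#'   (reaction, environment) where the single addition enables growth.
#'   Reactions beneficial nowhere contribute no rows.
#' @export
screen_singles <- function(universal, novel_envs, candidates = NULL,
                           tol = VIABILITY_TOL) {
  rx <- universal$reactions
  candidates <- candidates %||% default_candidates(universal)
  idx <- match(candidates, rx$id)
  if (anyNA(idx)) stop("unknown candidate(s): ",
                       paste(candidates[is.na(idx)], collapse = ", "),
                       call. = FALSE)
  if (any(rx$origin[idx] != "universal"))
    stop("host-origin reactions cannot be screened as candidates: ",
         paste(candidates[rx$origin[idx] != "universal"], collapse = ", "),
         call. = FALSE)
  cand_idx <- match(default_candidates(universal), rx$id)
  out <- purrr::map(seq_len(nrow(novel_envs)), function(i) {
    e <- novel_envs[i, ]
    hits <- candidates[vapply(idx, function(j) {
      activate_and_grow(universal, e, cand_idx, j) > tol
    }, logical(1))]
    if (length(hits) == 0) return(NULL)
    tibble::tibble(reaction = hits, env = e$name)
  })
  dplyr::bind_rows(out) |>
    (\(d) if (nrow(d) == 0)
       tibble::tibble(reaction = character(), env = character()) else d)() |>
    dplyr::arrange(.data$reaction, .data$env)
}

#' Classify growth-promoting reaction pairs
#'
#' Activates two universal candidate reactions at a time (all others
#' inactivated) and tests growth by FBA across the novel environments.
#' Pairs beneficial in at least one environment are kept and classified:
#' `"beneficial_with_combined_and_individual_effect"` when at least one
#' member also enables growth on its own somewhere (that member is a
#' stepping stone), otherwise `"beneficial_without_individual_effect"`.
#'
#' By default the quadratic scan is restricted to candidates that appear in
#' an enumerated minimal set or are beneficial alone — a restriction that
#' provably loses no size-2 minimal pair; set `exhaustive = TRUE` to test
#' every candidate pair.
#'
#' @inheritParams screen_singles
#' @param enumerations optional list of [enumerate_minimal_sets()] results
#'   used to restrict the candidate set.
#' @param singles optional precomputed [screen_singles()] table.
#' @param exhaustive test all candidate pairs.
#' @return tibble of class `pair_classification`: `reaction_a`,
#'   `reaction_b`, `beneficial_envs`, `solo_envs_a`, `solo_envs_b`
#'   (list-columns), `category`, `stepping_stones` (list-column of members
#'   beneficial alone).
#' @export
screen_pairs <- function(universal, novel_envs, enumerations = NULL,
                         candidates = NULL, singles = NULL,
                         exhaustive = FALSE, tol = VIABILITY_TOL) {
  rx <- universal$reactions
  all_cand <- default_candidates(universal)
  if (is.null(singles))
    singles <- screen_singles(universal, novel_envs, tol = tol)
  if (is.null(candidates)) {
    if (exhaustive) {
      candidates <- all_cand
    } else {
      in_sets <- unique(unlist(purrr::map(enumerations %||% list(),
                                          function(en) {
        unlist(purrr::map(en$sets, "active_set"))
      })))
      candidates <- sort(union(in_sets, unique(singles$reaction)))
    }
  }
  if (length(candidates) < 2)
    return(structure(tibble::tibble(reaction_a = character(),
                                    reaction_b = character(),
                                    beneficial_envs = list(),
                                    solo_envs_a = list(), solo_envs_b = list(),
                                    category = character(),
                                    stepping_stones = list()),
                     class = c("pair_classification", "tbl_df", "tbl", "data.frame")))

  cand_idx <- match(all_cand, rx$id)
  pair_tab <- utils::combn(sort(candidates), 2)
  solo_of <- function(r) sort(singles$env[singles$reaction == r])
  rows <- purrr::map(seq_len(ncol(pair_tab)), function(k) {
    a <- pair_tab[1, k]; b <- pair_tab[2, k]
    open <- match(c(a, b), rx$id)
    envs <- novel_envs$name[vapply(seq_len(nrow(novel_envs)), function(i) {
      activate_and_grow(universal, novel_envs[i, ], cand_idx, open) > tol
    }, logical(1))]
    if (length(envs) == 0) return(NULL)
    sa <- solo_of(a); sb <- solo_of(b)
    stones <- c(if (length(sa) > 0) a, if (length(sb) > 0) b)
    tibble::tibble(reaction_a = a, reaction_b = b,
                   beneficial_envs = list(envs),
                   solo_envs_a = list(sa), solo_envs_b = list(sb),
                   category = if (length(stones) > 0)
                     "beneficial_with_combined_and_individual_effect"
                   else "beneficial_without_individual_effect",
                   stepping_stones = list(stones %||% character()))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0)
    out <- tibble::tibble(reaction_a = character(), reaction_b = character(),
                          beneficial_envs = list(), solo_envs_a = list(),
                          solo_envs_b = list(), category = character(),
                          stepping_stones = list())
  class(out) <- c("pair_classification", class(out))
  out
}

#' Accessibility of two-step environments through adaptive walks
#'
#' An environment whose minimal added-reaction sets have size 2 is
#' *accessible* when at least one of its minimal pairs contains a member
#' that enables growth alone in some other environment (a stepping stone):
#' the two-reaction innovation can then be reached by two successive
#' single-reaction adaptive steps under changing environments.
#'
#' @param pairs a [screen_pairs()] classification.
#' @param enumerations list of [enumerate_minimal_sets()] results covering
#'   every two-step environment.
#' @return list of class `accessibility_result`: `two_step_envs`,
#'   `accessible_envs`, `fraction_accessible`.
#' @export
accessibility <- function(pairs, enumerations) {
  sizes <- vapply(enumerations, `[[`, numeric(1), "minimal_size")
  envs <- vapply(enumerations, `[[`, character(1), "env")
  two_step <- envs[sizes == 2]
  # reactions beneficial alone anywhere, per the pair screen's solo lists
  solo <- unique(c(
    unlist(purrr::map2(pairs$reaction_a, pairs$solo_envs_a,
                       function(r, e) if (length(e) > 0) r)),
    unlist(purrr::map2(pairs$reaction_b, pairs$solo_envs_b,
                       function(r, e) if (length(e) > 0) r))))
  accessible <- vapply(two_step, function(e) {
    en <- enumerations[[which(envs == e)[1]]]
    any(vapply(en$sets, function(s) any(s$active_set %in% solo), logical(1)))
  }, logical(1))
  structure(list(two_step_envs = two_step,
                 accessible_envs = two_step[accessible],
                 fraction_accessible = if (length(two_step) > 0)
                   mean(accessible) else NA_real_),
            class = "accessibility_result")
}

#' @export
print.accessibility_result <- function(x, ...) {
  cat("<accessibility_result> ", length(x$accessible_envs), " of ",
      length(x$two_step_envs), " two-step environments accessible",
      if (length(x$two_step_envs) > 0)
        paste0(" (", format(100 * x$fraction_accessible), "%)"),
      "\n", sep = "")
  invisible(x)
}

#' Exaptation overlap of minimal reaction sets across environments
#'
#' For each environment, the fraction of its minimal added-reaction sets
#' that are entirely contained in at least one minimal set of a *different*
#' environment — reaction sets adaptive in one environment later co-opted
#' as parts of larger growth-promoting sets elsewhere.
#'
#' @param enumerations list of at least two [enumerate_minimal_sets()]
#'   results.
#' @return list with `per_env` (tibble: `env`, `n_sets`, `fraction`) and
#'   `mean` (mean of the per-environment fractions).
#' @export
exaptation_overlap <- function(enumerations) {
  if (length(enumerations) < 2)
    stop("exaptation overlap needs at least two environments", call. = FALSE)
  envs <- vapply(enumerations, `[[`, character(1), "env")
  sets_of <- purrr::map(enumerations, function(en)
    purrr::map(en$sets, "active_set"))
  per <- purrr::map2(seq_along(enumerations), envs, function(i, e) {
    own <- sets_of[[i]]
    others <- unlist(sets_of[-i], recursive = FALSE)
    covered <- vapply(own, function(s) {
      any(vapply(others, function(s2) all(s %in% s2), logical(1)))
    }, logical(1))
    tibble::tibble(env = e, n_sets = length(own), fraction = mean(covered))
  })
  per <- dplyr::bind_rows(per)
  list(per_env = per, mean = mean(per$fraction))
}
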