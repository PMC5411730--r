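#' Solve a bounded linear program
#'
#' Thin wrapper around the package's dense bounded-variable simplex. Solves
#' `min/max c'x` subject to `A x = b` and `lb <= x <= ub`. All bounds must be
#' finite; callers model "unbounded" fluxes with the conventional cap of
#' 1000 flux units.
#'
#' @param obj numeric objective coefficients (length `ncol(A)`).
#' @param A constraint matrix (dense or `Matrix` sparse; coerced to dense).
#' @param b right-hand side (length `nrow(A)`).
#' @param lb,ub variable bounds, finite.
#' @param maximize if `TRUE`, maximise the objective.
#' @param maxiter simplex iteration cap.
#'
#' @return A list with `status` (`"optimal"`, `"infeasible"`, or
#'   `"failed"`), `x` (primal solution or `NULL`), and `objective`.
#' @keywords internal
lp_solve <- function(obj, A, b, lb, ub, maximize = FALSE, maxiter = 20000L) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == nrow(A),
            length(lb) == n, length(ub) == n)
  if (!all(is.finite(lb)) || !all(is.finite(ub)))
    stop("lp_solve requires finite variable bounds", call. = FALSE)
  if (any(lb > ub + 1e-12))
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  cc <- if (maximize) -as.numeric(obj) else as.numeric(obj)
  res <- simplex_lp(A, as.numeric(b), cc, as.numeric(lb), as.numeric(ub),
                    as.integer(maxiter))
  status <- switch(as.character(res$status),
                   "0" = "optimal", "1" = "infeasible", "failed")
  objective <- if (status == "optimal") {
    if (maximize) -res$obj else res$obj
  } else NA_real_
  list(status = status,
       x = if (status == "optimal") as.numeric(res$x) else NULL,
       objective = objective)
}
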