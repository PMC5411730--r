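#' @importFrom rlang %||% .data
#' @importFrom Rcpp sourceCpp
#' @useDynLib stepstone, .registration = TRUE
NULL

# Conventional cap for "unbounded" fluxes (mmol / gDW / h by convention only).
FLUX_CAP <- 1000

# Viability tolerance: strictly between LP solver noise and the 1e-4 growth
# floor used by the gap-fill MILP.
VIABILITY_TOL <- 1e-6

#' Parse a reaction equation string
#'
#' Understands the tab-delimited dialect's equation syntax, e.g.
#' `"1 A + 2 B <-> 1 C"`, `"A -> B"`, or the exchange form `"A <->"`
#' (single metabolite, empty product side). Coefficients default to 1.
#'
#' @param eq equation string; `"->"` marks an irreversible and `"<->"` a
#'   reversible reaction.
#' @return list with `metabolites`, `coefficients` (negative = consumed),
#'   and `reversible`.
#' @export
parse_equation <- function(eq) {
  stopifnot(is.character(eq), length(eq) == 1L)
  rev <- grepl("<->", eq, fixed = TRUE)
  sides <- if (rev) strsplit(eq, "<->", fixed = TRUE)[[1]]
           else strsplit(eq, "->", fixed = TRUE)[[1]]
  if (!grepl("<->|->", eq)) stop("equation lacks an arrow: ", eq, call. = FALSE)
  lhs <- if (length(sides) >= 1) sides[1] else ""
  rhs <- if (length(sides) >= 2) sides[2] else ""
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (side == "") return(list(mets = character(), coefs = numeric()))
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    terms <- terms[terms != ""]
    mets <- character(length(terms)); coefs <- numeric(length(terms))
    for (k in seq_along(terms)) {
      parts <- strsplit(terms[k], "\\s+")[[1]]
      if (length(parts) == 1L) { mets[k] <- parts; coefs[k] <- sign }
      else {
        cf <- suppressWarnings(as.numeric(parts[1]))
        if (is.na(cf)) stop("bad coefficient in term '", terms[k], "'", call. = FALSE)
        mets[k] <- paste(parts[-1], collapse = " "); coefs[k] <- sign * cf
      }
    }
    list(mets = mets, coefs = coefs)
  }
  l <- parse_side(lhs, -1); r <- parse_side(rhs, +1)
  mets <- c(l$mets, r$mets); coefs <- c(l$coefs, r$coefs)
  if (anyDuplicated(mets)) {
    agg <- tapply(coefs, mets, sum)
    mets <- names(agg); coefs <- as.numeric(agg)
    keep <- abs(coefs) > 0
    mets <- mets[keep]; coefs <- coefs[keep]
  }
  list(metabolites = mets, coefficients = coefs, reversible = rev)
}

#' Format a reaction equation string
#'
#' Inverse of [parse_equation()]; used when networks are built
#' programmatically from stoichiometry.
#'
#' @param metabolites metabolite ids.
#' @param coefficients signed stoichiometric coefficients (negative = consumed).
#' @param reversible write `"<->"` instead of `"->"`.
#' @return equation string.
#' @export
make_equation <- function(metabolites, coefficients, reversible = FALSE) {
  fmt <- function(m, cf) {
    if (length(m) == 0) return("")
    paste(paste(format(cf, trim = TRUE, scientific = FALSE), m), collapse = " + ")
  }
  neg <- coefficients < 0
  lhs <- fmt(metabolites[neg], -coefficients[neg])
  rhs <- fmt(metabolites[!neg], coefficients[!neg])
  arrow <- if (reversible) "<->" else "->"
  trimws(paste(lhs, arrow, rhs))
}

#' Construct a metabolic network
#'
#' Builds the constraint-based network object that every other function in
#' the package consumes: a reaction table, the metabolite universe, a sparse
#' stoichiometric matrix `S` (metabolites x reactions), and the identity of
#' the biomass reaction.
#'
#' @param reactions a data frame with columns `id` and `equation`; optional
#'   columns `lower`, `upper`, `origin` (`"host"` or `"universal"`) and
#'   `gpr` (boolean gene expression string). Missing bounds default to
#'   `[0, 1000]` for irreversible and `[-1000, 1000]` for reversible
#'   reactions.
#' @param biomass_reaction id of the biomass reaction; must exist and be
#'   irreversible forward. May be `NULL` for pure reaction pools that are
#'   only ever merged into a host network.
#' @return an object of class `metabolic_network` with elements `reactions`
#'   (tibble), `metabolites`, `S` (sparse `dgCMatrix`), `biomass`.
#' @export
metabolic_network <- function(reactions, biomass_reaction = NULL) {
  rx <- tibble::as_tibble(reactions)
  stopifnot(all(c("id", "equation") %in% names(rx)))
  if (anyDuplicated(rx$id)) stop("reaction ids must be unique", call. = FALSE)
  parsed <- lapply(rx$equation, parse_equation)
  rev_eq <- vapply(parsed, `[[`, logical(1), "reversible")
  if (!"lower" %in% names(rx)) rx$lower <- ifelse(rev_eq, -FLUX_CAP, 0)
  if (!"upper" %in% names(rx)) rx$upper <- FLUX_CAP
  rx$lower[is.na(rx$lower)] <- ifelse(rev_eq[is.na(rx$lower)], -FLUX_CAP, 0)
  rx$upper[is.na(rx$upper)] <- FLUX_CAP
  if (any(rx$lower > rx$upper))
    stop("lower bound exceeds upper bound for: ",
         paste(rx$id[rx$lower > rx$upper], collapse = ", "), call. = FALSE)
  rx$reversible <- rx$lower < 0
  if (!"origin" %in% names(rx)) rx$origin <- "host"
  rx$origin[is.na(rx$origin)] <- "host"
  if (!all(rx$origin %in% c("host", "universal")))
    stop("origin must be 'host' or 'universal'", call. = FALSE)
  if (!"gpr" %in% names(rx)) rx$gpr <- NA_character_
  rx$gpr <- as.character(rx$gpr)

  n_met <- vapply(parsed, function(p) length(p$metabolites), integer(1))
  rx$is_exchange <- n_met == 1L

  mets <- unique(unlist(lapply(parsed, `[[`, "metabolites")))
  ii <- unlist(lapply(parsed, function(p) match(p$metabolites, mets)))
  jj <- rep(seq_along(parsed), n_met)
  vv <- unlist(lapply(parsed, `[[`, "coefficients"))
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = vv,
                            dims = c(length(mets), nrow(rx)),
                            dimnames = list(mets, rx$id))

  if (!is.null(biomass_reaction)) {
    if (!biomass_reaction %in% rx$id)
      stop("biomass reaction '", biomass_reaction, "' not in network", call. = FALSE)
    if (rx$lower[rx$id == biomass_reaction] < 0)
      stop("biomass reaction must be irreversible forward", call. = FALSE)
  }

  rx <- rx[, c("id", "equation", "lower", "upper", "reversible",
               "is_exchange", "origin", "gpr")]
  structure(list(reactions = rx, metabolites = mets, S = S,
                 biomass = biomass_reaction),
            class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("<metabolic_network> ", nrow(x$reactions), " reactions (",
      sum(x$reactions$origin == "universal"), " universal, ",
      sum(x$reactions$is_exchange), " exchange), ",
      length(x$metabolites), " metabolites; biomass: ",
      x$biomass %||% "<none>", "\n",
      sep = "")
  invisible(x)
}

#' Read / write the tab-delimited network dialect
#'
#' Plain TSV with columns `id`, `equation`, `lower`, `upper`, `origin`,
#' `gpr`. Files written by [write_network_tsv()] round-trip bit-exactly
#' through [read_network_tsv()].
#'
#' @param path file path.
#' @param biomass_reaction biomass reaction id (read only).
#' @return [read_network_tsv()] returns a `metabolic_network`;
#'   [write_network_tsv()] returns `path` invisibly.
#' @export
read_network_tsv <- function(path, biomass_reaction) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           na.strings = "", quote = "", comment.char = "")
  metabolic_network(tab, biomass_reaction)
}

#' @rdname read_network_tsv
#' @param network a `metabolic_network`.
#' @export
write_network_tsv <- function(network, path) {
  rx <- network$reactions
  out <- data.frame(id = rx$id, equation = rx$equation,
                    lower = format(rx$lower, trim = TRUE, scientific = FALSE),
                    upper = format(rx$upper, trim = TRUE, scientific = FALSE),
                    origin = rx$origin,
                    gpr = ifelse(is.na(rx$gpr), "", rx$gpr))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an SBML Level 3 model (fbc flux bounds and GPRs)
#'
#' Minimal reader for SBML L3 documents that use the `fbc` package for flux
#' bounds and gene-product associations, as distributed with genome-scale
#' reconstructions. Species, reactions, stoichiometry, bound parameters and
#' GPR expressions are extracted; compartments and annotations are ignored.
#'
#' @param path SBML file path.
#' @param biomass_reaction biomass reaction id; if `NULL`, the first reaction
#'   whose id contains "biomass" (case-insensitive) is used.
#' @return a `metabolic_network`.
#' @export
read_network_sbml <- function(path, biomass_reaction = NULL) {
  doc <- xml2::read_xml(path)
  ns_all <- xml2::xml_ns(doc)
  # parameters hold the fbc bound values
  params <- xml2::xml_find_all(doc, ".//*[local-name()='parameter']")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  rx_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='reaction']")
  get_species <- function(node, tag) {
    refs <- xml2::xml_find_all(node, paste0(".//*[local-name()='", tag,
                                            "']/*[local-name()='speciesReference']"))
    sp <- xml2::xml_attr(refs, "species")
    st <- xml2::xml_attr(refs, "stoichiometry")
    st <- ifelse(is.na(st), 1, as.numeric(st))
    stats::setNames(st, sp)
  }
  parse_gpr_node <- function(node) {
    gpa <- xml2::xml_find_first(node, ".//*[local-name()='geneProductAssociation']")
    if (is.na(gpa) || inherits(gpa, "xml_missing")) return(NA_character_)
    walk <- function(n) {
      nm <- xml2::xml_name(n)
      kids <- xml2::xml_children(n)
      if (nm == "geneProductRef") return(xml2::xml_attr(n, "geneProduct"))
      sub <- vapply(kids, walk, character(1))
      if (nm == "and") paste0("(", paste(sub, collapse = " AND "), ")")
      else if (nm == "or") paste0("(", paste(sub, collapse = " OR "), ")")
      else if (length(sub) == 1) sub else NA_character_
    }
    kids <- xml2::xml_children(gpa)
    if (length(kids) == 0) return(NA_character_)
    walk(kids[[1]])
  }
  rows <- lapply(rx_nodes, function(node) {
    id <- xml2::xml_attr(node, "id")
    reactants <- get_species(node, "listOfReactants")
    products <- get_species(node, "listOfProducts")
    attrs <- xml2::xml_attrs(node)
    lb_ref <- attrs[grepl("lowerFluxBound$", names(attrs))]
    ub_ref <- attrs[grepl("upperFluxBound$", names(attrs))]
    lb <- if (length(lb_ref)) unname(pval[lb_ref[1]]) else NA_real_
    ub <- if (length(ub_ref)) unname(pval[ub_ref[1]]) else NA_real_
    rev_attr <- xml2::xml_attr(node, "reversible")
    rev <- isTRUE(tolower(rev_attr) == "true")
    if (is.na(lb)) lb <- if (rev) -FLUX_CAP else 0
    if (is.na(ub)) ub <- FLUX_CAP
    lb <- max(lb, -FLUX_CAP); ub <- min(ub, FLUX_CAP)
    eq <- make_equation(c(names(reactants), names(products)),
                        c(-unname(reactants), unname(products)),
                        reversible = lb < 0)
    tibble::tibble(id = id, equation = eq, lower = lb, upper = ub,
                   origin = "host", gpr = parse_gpr_node(node))
  })
  tab <- dplyr::bind_rows(rows)
  if (is.null(biomass_reaction)) {
    hit <- grep("biomass", tab$id, ignore.case = TRUE, value = TRUE)
    if (length(hit) == 0) stop("no biomass reaction found; supply biomass_reaction",
                               call. = FALSE)
    biomass_reaction <- hit[1]
  }
  metabolic_network(tab, biomass_reaction)
}
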