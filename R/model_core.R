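#' Constraint-based metabolic models and flux balance analysis
#'
#' A `metabolic_model` holds a stoichiometric network with flux bounds
#' (mmol/gDW/h), a biomass objective reaction (gDW/gDW/h) and a set of
#' exchange reactions. Exchange reactions follow the AGORA/VMH sign
#' convention: negative flux is uptake, positive flux is secretion.
#'
#' @param id model identifier.
#' @param metabolites data.frame with columns `id`, `name`, `compartment`
#'   (missing `name`/`compartment` are filled from `id` / `"e"`).
#' @param reactions list of reactions, each a list with elements `id`,
#'   `stoich` (named numeric, metabolite -> coefficient), `lb`, `ub`.
#' @param objective reaction id of the biomass objective.
#' @param exchanges character vector of exchange reaction ids, or `NULL` to
#'   auto-detect single-metabolite boundary reactions.
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, metabolites, reactions, objective,
                            exchanges = NULL) {
  stopifnot(is.character(id), length(id) == 1)
  if (is.character(metabolites)) {
    metabolites <- data.frame(id = metabolites)
  }
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$compartment)) metabolites$compartment <- "e"
  metabolites <- metabolites[, c("id", "name", "compartment")]
  rxn_ids <- vapply(reactions, function(r) r$id, character(1))
  names(reactions) <- rxn_ids
  if (is.null(exchanges)) {
    # boundary = touches exactly one metabolite, and that metabolite is
    # extracellular (compartment "e"); intracellular sinks are not exchanges
    comp <- setNames(metabolites$compartment, metabolites$id)
    exchanges <- rxn_ids[vapply(reactions, function(r) {
      st <- r$stoich[r$stoich != 0]
      length(st) == 1L && identical(unname(comp[names(st)]), "e")
    }, logical(1))]
  }
  m <- structure(
    list(id = id, metabolites = metabolites, reactions = reactions,
         objective = objective, exchanges = exchanges),
    class = "metabolic_model")
  validate_model(m)
}

#' Validate a metabolic model's structural invariants
#'
#' Checks that every stoichiometry entry names a declared metabolite, that
#' `lb <= ub` for every reaction, that the objective reaction exists, and
#' that each exchange reaction touches exactly one metabolite.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly usable; errors describe the offending element.
#' @export
validate_model <- function(model) {
  mets <- model$metabolites$id
  if (anyDuplicated(mets)) stop("duplicated metabolite ids")
  rxn_ids <- names(model$reactions)
  if (anyDuplicated(rxn_ids)) stop("duplicated reaction ids")
  for (r in model$reactions) {
    bad <- setdiff(names(r$stoich), mets)
    if (length(bad) > 0) {
      stop(sprintf("reaction '%s' references undeclared metabolite(s): %s",
                   r$id, paste(bad, collapse = ", ")))
    }
    if (!is.finite(r$lb) || !is.finite(r$ub)) {
      stop(sprintf("reaction '%s' has non-finite bounds", r$id))
    }
    if (r$lb > r$ub) {
      stop(sprintf("reaction '%s' has lb > ub", r$id))
    }
  }
  if (!model$objective %in% rxn_ids) {
    stop(sprintf("objective reaction '%s' not found in model '%s'",
                 model$objective, model$id))
  }
  bad_ex <- setdiff(model$exchanges, rxn_ids)
  if (length(bad_ex) > 0) {
    stop(sprintf("unknown exchange reaction(s): %s",
                 paste(bad_ex, collapse = ", ")))
  }
  for (ex in model$exchanges) {
    st <- model$reactions[[ex]]$stoich
    if (sum(st != 0) != 1L) {
      stop(sprintf("exchange reaction '%s' must touch exactly one metabolite", ex))
    }
  }
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %s: %d metabolites, %d reactions (%d exchange), objective '%s'\n",
              x$id, nrow(x$metabolites), length(x$reactions),
              length(x$exchanges), x$objective))
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @return dense matrix, metabolites x reactions.
#' @export
model_matrix <- function(model) {
  mets <- model$metabolites$id
  rxns <- names(model$reactions)
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (r in model$reactions) {
    st <- r$stoich
    S[names(st), r$id] <- unname(st)
  }
  S
}

model_bounds <- function(model) {
  lb <- vapply(model$reactions, function(r) r$lb, numeric(1))
  ub <- vapply(model$reactions, function(r) r$ub, numeric(1))
  list(lb = lb, ub = ub)
}

#' Read a metabolic model
#'
#' Reads either the package's JSON dialect (`{id, metabolites[], reactions[{id,
#' stoich{}, lb, ub}], objective, exchanges?}`) or an SBML Level 3 + FBC file.
#' Exchange reactions are auto-detected as single-metabolite boundary
#' reactions when not annotated.
#'
#' @param path file path.
#' @param dialect `"json"` or `"sbml"`; default guesses from the extension.
#' @return a validated `metabolic_model`.
#' @export
read_model <- function(path, dialect = c("auto", "json", "sbml")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  if (dialect == "sbml") return(read_sbml_model(path))
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed model JSON in '", path,
                                           "': ", conditionMessage(e)))
  for (f in c("id", "metabolites", "reactions", "objective")) {
    if (is.null(obj[[f]])) stop("model JSON missing field '", f, "'")
  }
  mets <- data.frame(
    id = vapply(obj$metabolites, function(m) m$id, character(1)),
    name = vapply(obj$metabolites, function(m) m$name %||% m$id, character(1)),
    compartment = vapply(obj$metabolites, function(m) m$compartment %||% "e",
                         character(1)))
  rxns <- lapply(obj$reactions, function(r) {
    if (is.null(r$id)) stop("reaction without id in '", path, "'")
    list(id = r$id, stoich = unlist(r$stoich), lb = as.numeric(r$lb),
         ub = as.numeric(r$ub))
  })
  exch <- if (!is.null(obj$exchanges)) unlist(obj$exchanges) else NULL
  metabolic_model(obj$id, mets, rxns, obj$objective, exch)
}

#' Write a metabolic model in the JSON dialect
#'
#' `read_model(write_model(m, path))` is the identity on the JSON dialect.
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  obj <- list(
    id = model$id,
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      as.list(model$metabolites[i, ])
    }),
    reactions = lapply(unname(model$reactions), function(r) {
      list(id = r$id, stoich = as.list(r$stoich), lb = r$lb, ub = r$ub)
    }),
    objective = model$objective,
    exchanges = as.list(model$exchanges))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Solve flux balance analysis for a model
#'
#' Maximizes the objective (biomass) flux subject to steady state
#' \eqn{S v = 0} and flux bounds. Returns an infeasible status rather than
#' raising when no feasible flux distribution exists.
#'
#' @param model a `metabolic_model`.
#' @param extra_bounds named list of `c(lb, ub)` pairs overriding reaction
#'   bounds (e.g. diet-derived uptake limits); names must be reaction ids.
#' @param tol primal feasibility tolerance of the solver.
#' @return an object of class `fba_solution`: list with `status`
#'   (`"optimal"`/`"infeasible"`), `objective_value` (1/h) and `fluxes`
#'   (named, mmol/gDW/h).
#' @export
solve_fba <- function(model, extra_bounds = NULL, tol = 1e-9) {
  S <- model_matrix(model)
  bounds <- model_bounds(model)
  lb <- bounds$lb
  ub <- bounds$ub
  if (!is.null(extra_bounds)) {
    bad <- setdiff(names(extra_bounds), colnames(S))
    if (length(bad) > 0) {
      stop("unknown reaction id(s) in extra_bounds: ", paste(bad, collapse = ", "))
    }
    for (id in names(extra_bounds)) {
      eb <- extra_bounds[[id]]
      lb[id] <- eb[1]
      ub[id] <- eb[2]
    }
    if (any(lb > ub)) stop("merged bounds violate lb <= ub")
  }
  cvec <- as.numeric(colnames(S) == model$objective)
  res <- .lp_solve_cpp(S, rep(0, nrow(S)), cvec, lb, ub, tol)
  out <- list(status = res$status,
              objective_value = if (res$status == "optimal") res$objective else NA_real_,
              fluxes = if (res$status == "optimal")
                setNames(as.numeric(res$fluxes), colnames(S)) else NULL)
  class(out) <- "fba_solution"
  out
}

#' @export
print.fba_solution <- function(x, ...) {
  cat(sprintf("<fba_solution> status=%s objective=%s\n", x$status,
              format(x$objective_value)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
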