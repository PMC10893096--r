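#' Initialize a spatial arena from a community, models and a diet
#'
#' Places `round(abundance * n_init)` individuals per species (at least one
#' each) at distinct uniformly random grid cells and seeds every cell with
#' `diet mM * cell_volume` mmol of each diet metabolite. The default grid is
#' 60 x 60 = 3600 cells and the default inoculum 400 individuals (the
#' simulated communities in the source protocol start with 300-500
#' individuals; a warning is raised outside that range).
#'
#' @param community a `community` (model id -> relative abundance) from
#'   [build_community()], or a named abundance vector.
#' @param models named list of `metabolic_model`s covering the community.
#' @param diet named numeric vector, metabolite -> mM (see
#'   [diet_to_constraints()], [blend_diets()]).
#' @param n_init total initial individuals.
#' @param shape `c(rows, cols)` of the grid.
#' @param seed RNG seed for agent placement.
#' @param b0 initial biomass per individual, gDW.
#' @param arena_volume total arena volume, L (each cell holds
#'   `arena_volume / prod(shape)`).
#' @param dt time step, h.
#' @param p_move per-step movement probability.
#' @param diffusion dimensionless diffusion ratio `D*dt/h^2` per metabolite
#'   (scalar or named vector), must be <= 0.25 for stability of the explicit
#'   sweep.
#' @return an object of class `arena`.
#' @export
init_arena <- function(community, models, diet, n_init = 400,
                       shape = c(60, 60), seed = NULL, b0 = 1e-6,
                       arena_volume = 0.01, dt = 1, p_move = 1,
                       diffusion = 0.1) {
  ab <- if (inherits(community, "community")) community$abundance else community
  if (length(ab) == 0) stop("community is empty")
  if (abs(sum(ab) - 1) > 1e-9) stop("community abundances must sum to 1")
  ncell <- prod(shape)
  if (n_init < 1 || n_init > ncell) {
    stop("n_init must be in [1, ", ncell, "]")
  }
  if (n_init < 300 || n_init > 500) {
    warning("n_init = ", n_init, " is outside the protocol range [300, 500]")
  }
  missing_models <- setdiff(names(ab), names(models))
  if (length(missing_models) > 0) {
    stop("no metabolic model for: ", paste(missing_models, collapse = ", "))
  }
  models <- models[names(ab)]

  counts <- pmax(1L, as.integer(round(ab * n_init)))
  n_agents <- sum(counts)
  if (n_agents > ncell) stop("more initial agents than grid cells")

  mets <- unique(c(unlist(lapply(models, exchange_metabolites)), names(diet)))
  substrate <- matrix(0, ncell, length(mets), dimnames = list(NULL, mets))
  cell_volume <- arena_volume / ncell
  if (length(diet) > 0) {
    substrate[, names(diet)] <- matrix(rep(diet * cell_volume, each = ncell),
                                       ncell)
  }

  cells <- with_seed(seed, sample.int(ncell, n_agents))
  agents <- data.frame(
    species = rep(names(ab), counts),
    biomass = b0,
    cell = cells)

  if (length(diffusion) == 1 && is.null(names(diffusion))) {
    alpha <- setNames(rep(diffusion, length(mets)), mets)
  } else {
    alpha <- setNames(rep(0, length(mets)), mets)
    alpha[names(diffusion)] <- diffusion
  }
  if (any(alpha > 0.25)) stop("diffusion ratio D*dt/h^2 must be <= 0.25")

  structure(list(shape = shape, cell_volume = cell_volume,
                 metabolites = mets, substrate = substrate, agents = agents,
                 models = models, dt = dt, b0 = b0, p_move = p_move,
                 alpha = alpha, seed = seed),
            class = "arena")
}

#' @export
print.arena <- function(x, ...) {
  cat(sprintf("<arena> %d x %d cells, %d agents (%d species), %d metabolites, occupancy %.3f\n",
              x$shape[1], x$shape[2], nrow(x$agents),
              length(unique(x$agents$species)), length(x$metabolites),
              nrow(x$agents) / prod(x$shape)))
  invisible(x)
}

exchange_metabolites <- function(model) {
  vapply(model$reactions[model$exchanges],
         function(r) names(r$stoich)[r$stoich != 0], character(1))
}

# compile models into the flat arrays the C++ stepping loop consumes
.cpp_models <- function(models, mets) {
  lapply(models, function(m) {
    S <- model_matrix(m)
    bounds <- model_bounds(m)
    ex <- match(m$exchanges, colnames(S))
    exmet <- match(vapply(m$exchanges, function(e) {
      st <- m$reactions[[e]]$stoich
      names(st)[st != 0]
    }, character(1)), mets)
    list(S = S, lb = bounds$lb, ub = bounds$ub,
         obj = as.numeric(colnames(S) == m$objective),
         ex_rxn = as.integer(ex), ex_met = as.integer(exmet))
  })
}

.run_arena_cpp <- function(arena, steps, lptol = 1e-9) {
  sp_idx <- match(arena$agents$species, names(arena$models))
  .arena_run_cpp(.cpp_models(arena$models, arena$metabolites),
                 as.integer(sp_idx), arena$agents$biomass,
                 as.integer(arena$agents$cell), arena$substrate,
                 as.integer(arena$shape[1]), as.integer(arena$shape[2]),
                 as.integer(steps), arena$dt, arena$b0, arena$p_move,
                 as.numeric(arena$alpha), lptol)
}

#' Advance an arena by one time step
#'
#' One step of the individual-based loop: agents (in seeded shuffled order)
#' cap exchange uptake by local substrate, solve FBA, grow by
#' `biomass * (1 + mu * dt)`, exchange metabolites with their cell, divide
#' into a free 8-neighbor cell once biomass reaches `2 * b0`, move with
#' probability `p_move`; each substrate field then diffuses by one explicit
#' zero-flux Laplacian sweep. Infeasible agents persist with zero growth.
#' Uses the current RNG state; wrap in `set.seed()` for reproducibility.
#'
#' @param arena an `arena`.
#' @param steps number of steps to advance.
#' @return the advanced `arena`, with a `"diagnostics"` attribute holding
#'   per-step mass bookkeeping (exchange totals, pre/post-diffusion totals).
#' @export
step_arena <- function(arena, steps = 1) {
  res <- .run_arena_cpp(arena, steps)
  arena$substrate <- res$substrate
  colnames(arena$substrate) <- arena$metabolites
  arena$agents <- data.frame(
    species = names(arena$models)[res$species],
    biomass = res$biomass,
    cell = res$cell)
  attr(arena, "diagnostics") <- res[c("counts", "secretion", "uptake",
                                      "flux_delta", "env_pre_diff",
                                      "env_post", "env0", "clamp_total",
                                      "n_infeasible")]
  arena
}

#' Run a replicated community simulation
#'
#' Runs `hours / dt` steps per replicate with independent seeds and collects
#' end-point metabolite concentrations (total mmol across cells divided by
#' total arena volume, i.e. mM), per-species abundance trajectories,
#' per-species cumulative uptake/secretion, and grid occupancy.
#'
#' @param arena an `arena` from [init_arena()].
#' @param hours simulated time, h (default 12).
#' @param replicates number of independent replicates (default 10).
#' @param seeds integer vector of per-replicate seeds; defaults to
#'   `arena$seed + 1:replicates` (or `1:replicates`).
#' @return an object of class `simulation_result` with elements
#'   `end_concentrations` (replicates x metabolites, mM), `species_counts`
#'   (list of (steps+1) x species matrices), `secretion`/`uptake` (lists of
#'   species x metabolite mmol matrices), `occupancy`, `n_infeasible`,
#'   `diagnostics`, plus the run settings.
#' @export
run_simulation <- function(arena, hours = 12, replicates = 10, seeds = NULL) {
  steps <- hours / arena$dt
  if (abs(steps - round(steps)) > 1e-9 || steps <= 0) {
    stop("hours/dt must be a positive integer number of steps")
  }
  steps <- as.integer(round(steps))
  if (is.null(seeds)) {
    base <- if (is.null(arena$seed)) 0L else as.integer(arena$seed)
    seeds <- base + seq_len(replicates)
  }
  if (length(seeds) != replicates) stop("need one seed per replicate")

  ncell <- prod(arena$shape)
  total_volume <- ncell * arena$cell_volume
  species <- names(arena$models)
  mets <- arena$metabolites

  end_conc <- matrix(NA_real_, replicates, length(mets),
                     dimnames = list(NULL, mets))
  counts_l <- vector("list", replicates)
  secretion_l <- vector("list", replicates)
  uptake_l <- vector("list", replicates)
  diag_l <- vector("list", replicates)
  occupancy <- numeric(replicates)
  n_infeasible <- integer(replicates)

  for (r in seq_len(replicates)) {
    res <- with_seed(seeds[r], .run_arena_cpp(arena, steps))
    end_conc[r, ] <- colSums(res$substrate) / total_volume
    cn <- res$counts
    dimnames(cn) <- list(NULL, species)
    counts_l[[r]] <- cn
    sec <- res$secretion
    upt <- res$uptake
    dimnames(sec) <- dimnames(upt) <- list(species, mets)
    secretion_l[[r]] <- sec
    uptake_l[[r]] <- upt
    occupancy[r] <- length(res$species) / ncell
    n_infeasible[r] <- res$n_infeasible
    diag_l[[r]] <- res[c("flux_delta", "env_pre_diff", "env_post", "env0",
                         "clamp_total")]
  }
  structure(list(end_concentrations = end_conc, species_counts = counts_l,
                 secretion = secretion_l, uptake = uptake_l,
                 occupancy = occupancy, n_infeasible = n_infeasible,
                 diagnostics = diag_l, hours = hours, dt = arena$dt,
                 replicates = replicates, seeds = seeds,
                 total_volume = total_volume),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %d replicates x %g h, %d metabolites, mean occupancy %.3f\n",
              x$replicates, x$hours, ncol(x$end_concentrations),
              mean(x$occupancy)))
  invisible(x)
}

#' Attribute metabolite production and consumption to species
#'
#' Sums cumulative exchange over replicates and reports, per species and
#' metabolite, the produced and consumed amounts (mmol) and each producer's
#' percentage of that metabolite's total production. Metabolites never
#' exchanged are omitted; production percentages sum to 100 within each
#' produced metabolite.
#'
#' @param result a `simulation_result`.
#' @return data.frame with columns `species`, `metabolite`, `produced_mmol`,
#'   `consumed_mmol`, `production_pct`.
#' @export
flux_attribution <- function(result) {
  sec <- Reduce(`+`, result$secretion) / result$replicates
  upt <- Reduce(`+`, result$uptake) / result$replicates
  keep <- colSums(sec) + colSums(upt) > 0
  sec <- sec[, keep, drop = FALSE]
  upt <- upt[, keep, drop = FALSE]
  out <- expand.grid(species = rownames(sec), metabolite = colnames(sec),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$produced_mmol <- as.numeric(sec)
  out$consumed_mmol <- as.numeric(upt)
  tot <- colSums(sec)[out$metabolite]
  out$production_pct <- ifelse(tot > 0, 100 * out$produced_mmol / tot, NA_real_)
  out <- out[out$produced_mmol > 0 | out$consumed_mmol > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}
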