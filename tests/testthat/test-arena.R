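# helpers building small arenas quickly
toy2 <- function(motif = "independent") make_toy_models(2, motif)
plentiful <- function(truth, mM = 1e5) {
  setNames(rep(mM, nrow(truth)), truth$substrate)
}

test_that("initial per-species counts follow the rounding rule", {
  toy <- make_toy_models(3, "independent")
  comm <- setNames(c(0.5, 0.3, 0.2), names(toy$models))
  diet <- plentiful(toy$truth)
  a <- init_arena(comm, toy$models, diet, n_init = 400, shape = c(60, 60),
                  seed = 1)
  tab <- table(a$agents$species)
  expect_equal(as.integer(tab[c("sp01", "sp02", "sp03")]), c(200, 120, 80))
  expect_equal(prod(a$shape), 3600)
  expect_equal(nrow(a$agents) / prod(a$shape), 400 / 3600)
  # distinct cells, all inside the grid
  expect_equal(anyDuplicated(a$agents$cell), 0L)
  expect_true(all(a$agents$cell >= 1 & a$agents$cell <= 3600))
})

test_that("every species keeps at least one founder and warnings flag the inoculum range", {
  toy <- make_toy_models(2, "independent")
  comm <- setNames(c(0.999, 0.001), names(toy$models))
  a <- suppressWarnings(init_arena(comm, toy$models, plentiful(toy$truth),
                                   n_init = 100, shape = c(20, 20), seed = 1))
  expect_true(all(c("sp01", "sp02") %in% a$agents$species))
  expect_warning(
    init_arena(comm, toy$models, plentiful(toy$truth), n_init = 100,
               shape = c(20, 20), seed = 1),
    "outside the protocol range")
  expect_error(
    init_arena(comm, toy$models, plentiful(toy$truth), n_init = 0),
    "n_init")
})

test_that("substrate seeding converts diet mM to per-cell amounts", {
  toy <- make_toy_models(1, "independent")
  comm <- setNames(1, names(toy$models))
  a <- suppressWarnings(init_arena(comm, toy$models, c(nut01_e = 50),
                                   n_init = 10, shape = c(10, 10), seed = 1,
                                   arena_volume = 0.01))
  expect_equal(unique(a$substrate[, "nut01_e"]), 50 * 0.01 / 100)
  # total amount / total volume recovers the diet concentration
  expect_equal(sum(a$substrate[, "nut01_e"]) / 0.01, 50)
})

test_that("a lone agent with substrate at hand grows at its analytic rate", {
  toy <- make_toy_models(1, "independent")  # uptake 10, yield 0.1 -> mu = 1
  comm <- setNames(1, names(toy$models))
  a <- suppressWarnings(init_arena(comm, toy$models, plentiful(toy$truth),
                                   n_init = 1, shape = c(5, 5), seed = 2))
  set.seed(7)
  a1 <- step_arena(a)
  # biomass doubled, so the agent divided into two cells of b0 each
  expect_equal(sum(a1$agents$biomass), 2e-6, tolerance = 1e-12)
  expect_equal(nrow(a1$agents), 2L)
})

test_that("agents without usable substrate neither grow nor deplete anything", {
  toy <- make_toy_models(1, "independent")
  comm <- setNames(1, names(toy$models))
  a <- suppressWarnings(init_arena(comm, toy$models, c(nut01_e = 0),
                                   n_init = 5, shape = c(5, 5), seed = 3))
  set.seed(8)
  a1 <- step_arena(a, steps = 3)
  expect_equal(a1$agents$biomass, rep(1e-6, 5))
  expect_equal(sum(a1$substrate), 0)
})

test_that("infeasible agents persist with zero growth and are counted", {
  # biomass reaction forced positive with no substrate available: infeasible
  mets <- data.frame(id = c("s_e", "p_c"))
  rxns <- list(
    list(id = "EX_s", stoich = c(s_e = -1), lb = 0, ub = 0),
    list(id = "trans", stoich = c(s_e = -1, p_c = 1), lb = 0, ub = 1000),
    list(id = "bio", stoich = c(p_c = -1), lb = 0.5, ub = 1000))
  m <- metabolic_model("stuck", mets, rxns, "bio")
  a <- suppressWarnings(init_arena(setNames(1, "stuck"), list(stuck = m),
                                   c(s_e = 100), n_init = 4, shape = c(4, 4),
                                   seed = 4))
  set.seed(9)
  a1 <- step_arena(a)
  d <- attr(a1, "diagnostics")
  expect_equal(nrow(a1$agents), 4L)
  expect_equal(a1$agents$biomass, rep(1e-6, 4))
  expect_equal(d$n_infeasible, 4L)
})

test_that("diffusion leaves a uniform field unchanged and conserves mass", {
  toy <- make_toy_models(1, "independent")
  comm <- setNames(1, names(toy$models))
  a <- suppressWarnings(init_arena(comm, toy$models, c(nut01_e = 40),
                                   n_init = 1, shape = c(8, 8), seed = 5,
                                   diffusion = 0.25))
  # remove the agent's own consumption by bounding uptake to zero
  a$models$sp01$reactions$EX_nut01_e$lb <- 0
  set.seed(10)
  a1 <- step_arena(a)
  expect_equal(a1$substrate[, "nut01_e"], a$substrate[, "nut01_e"],
               tolerance = 1e-14)
  expect_error(
    suppressWarnings(init_arena(comm, toy$models, c(nut01_e = 1), n_init = 1,
                                shape = c(8, 8), diffusion = 0.3)),
    "0.25")
})

test_that("per-step mass bookkeeping closes and diffusion conserves totals", {
  toy <- make_toy_models(3, "chain")
  comm <- setNames(c(0.4, 0.35, 0.25), names(toy$models))
  diet <- c(nut01_e = 100)
  a <- init_arena(comm, toy$models, diet, n_init = 400, shape = c(60, 60),
                  seed = 6)
  set.seed(11)
  a1 <- step_arena(a, steps = 12)
  d <- attr(a1, "diagnostics")
  env_start <- rbind(d$env0, d$env_post[-nrow(d$env_post), , drop = FALSE])
  scale <- pmax(abs(d$env_pre_diff), abs(env_start), 1e-12)
  rel_err <- abs(d$env_pre_diff - env_start - d$flux_delta) / scale
  expect_lt(max(rel_err), 1e-8)
  diff_rel <- abs(d$env_post - d$env_pre_diff) /
    pmax(abs(d$env_pre_diff), 1e-12)
  expect_lt(max(diff_rel), 1e-12)
  expect_true(all(a1$substrate >= 0))
})

test_that("monoculture biomass gain equals yield times substrate consumed", {
  toy <- make_toy_models(1, "independent", uptake_bound = 10, yield = 0.1,
                         byproduct_stoich = 0)
  comm <- setNames(1, names(toy$models))
  a <- suppressWarnings(init_arena(comm, toy$models, c(nut01_e = 30),
                                   n_init = 50, shape = c(15, 15), seed = 7))
  b0_total <- sum(a$agents$biomass)
  sub0 <- sum(a$substrate[, "nut01_e"])
  set.seed(12)
  a1 <- step_arena(a, steps = 12)
  gained <- sum(a1$agents$biomass) - b0_total
  consumed <- sub0 - sum(a1$substrate[, "nut01_e"])
  expect_gt(gained, 0)
  expect_equal(gained, 0.1 * consumed, tolerance = 1e-6)
})

test_that("an obligate cross-feeder grows iff its producer is present", {
  toy <- make_toy_models(2, "cross_feeding")
  diet <- c(nut01_e = 1000)  # substrate for sp01 only
  both <- suppressWarnings(init_arena(
    setNames(c(0.5, 0.5), names(toy$models)), toy$models, diet,
    n_init = 60, shape = c(15, 15), seed = 8))
  alone <- suppressWarnings(init_arena(
    setNames(1, "sp02"), toy$models["sp02"], diet,
    n_init = 30, shape = c(15, 15), seed = 9))
  biomass_of <- function(arena, sp) {
    sum(arena$agents$biomass[arena$agents$species == sp])
  }
  b0_both <- biomass_of(both, "sp02")
  set.seed(21)
  end_both <- step_arena(both, steps = 12)
  b0_alone <- biomass_of(alone, "sp02")
  set.seed(22)
  end_alone <- step_arena(alone, steps = 12)
  expect_gt(biomass_of(end_both, "sp02"), b0_both)
  expect_equal(biomass_of(end_alone, "sp02"), b0_alone)
})

test_that("replicates with equal seeds reproduce bit-identical trajectories", {
  toy <- make_toy_models(2, "independent")
  comm <- setNames(c(0.6, 0.4), names(toy$models))
  a <- suppressWarnings(init_arena(comm, toy$models, plentiful(toy$truth, 500),
                                   n_init = 50, shape = c(12, 12), seed = 10))
  s1 <- run_simulation(a, hours = 6, replicates = 2, seeds = c(5, 5))
  expect_identical(s1$end_concentrations[1, ], s1$end_concentrations[2, ])
  s2 <- run_simulation(a, hours = 6, replicates = 1, seeds = 5)
  expect_identical(s2$end_concentrations[1, ], s1$end_concentrations[1, ])
})

test_that("hours must be an integer multiple of the time step", {
  toy <- make_toy_models(1, "independent")
  a <- suppressWarnings(init_arena(setNames(1, "sp01"), toy$models,
                                   c(nut01_e = 10), n_init = 5,
                                   shape = c(5, 5), seed = 11))
  expect_error(run_simulation(a, hours = 2.5), "positive integer")
})

test_that("population growth respects space and occupancy stays within [0, 1]", {
  toy <- make_toy_models(1, "independent")
  comm <- setNames(1, names(toy$models))
  a <- suppressWarnings(init_arena(comm, toy$models, plentiful(toy$truth),
                                   n_init = 10, shape = c(6, 6), seed = 12))
  sim <- run_simulation(a, hours = 12, replicates = 2)
  totals <- rowSums(sim$species_counts[[1]])
  expect_true(all(diff(totals) >= 0))
  expect_true(all(totals <= 36))
  expect_true(all(sim$occupancy >= 0 & sim$occupancy <= 1))
})

test_that("flux attribution splits production percentages correctly", {
  toy <- make_toy_models(2, "cross_feeding")
  comm <- setNames(c(0.5, 0.5), names(toy$models))
  a <- suppressWarnings(init_arena(comm, toy$models, c(nut01_e = 1000),
                                   n_init = 40, shape = c(12, 12), seed = 13))
  sim <- run_simulation(a, hours = 12, replicates = 2)
  fa <- flux_attribution(sim)
  by1 <- fa[fa$metabolite == "by01_e", ]
  expect_equal(by1$production_pct[by1$species == "sp01"], 100)
  consumer <- by1[by1$species == "sp02", ]
  expect_equal(consumer$produced_mmol, 0)
  expect_gt(consumer$consumed_mmol, 0)
  # percentages sum to 100 per produced metabolite
  for (met in unique(fa$metabolite)) {
    pct <- fa$production_pct[fa$metabolite == met]
    if (any(!is.na(pct))) expect_equal(sum(pct, na.rm = TRUE), 100)
  }
})
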