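#' Generate toy genome-scale metabolic models with known yields
#'
#' Every species gets an uptake -> transport -> biomass backbone: an
#' exchange reaction for its substrate (uptake bound `uptake_bound`), a
#' transport into an internal pool, and a biomass reaction consuming
#' `1/yield` internal units per unit biomass flux, so the analytic optimal
#' growth rate is `uptake_bound * yield`. With `byproduct_stoich > 0` the
#' biomass reaction additionally secretes a byproduct through its own
#' exchange. Motifs wire the substrates: `independent` species consume
#' private nutrients; `chain`/`cross_feeding` species i > 1 consume species
#' i-1's byproduct (species 1 consumes the diet nutrient), giving an obligate
#' producer/consumer chain.
#'
#' @param n_species number of models.
#' @param motif `"independent"`, `"chain"` or `"cross_feeding"`.
#' @param uptake_bound substrate uptake bound, mmol/gDW/h.
#' @param yield biomass yield, gDW per mmol substrate.
#' @param byproduct_stoich mmol byproduct secreted per unit biomass flux
#'   (0 disables secretion; must be > 0 for chained motifs).
#' @return list with `models` (named list of `metabolic_model`s) and
#'   `truth` (data.frame: species, substrate, byproduct, mu_max, yield).
#' @export
make_toy_models <- function(n_species, motif = c("independent", "chain",
                                                 "cross_feeding"),
                            uptake_bound = 10, yield = 0.1,
                            byproduct_stoich = 5) {
  motif <- match.arg(motif)
  if (n_species < 1) stop("n_species must be >= 1")
  chained <- motif %in% c("chain", "cross_feeding")
  if (chained && byproduct_stoich <= 0) {
    stop("chained motifs need byproduct_stoich > 0")
  }
  ids <- sprintf("sp%02d", seq_len(n_species))
  models <- vector("list", n_species)
  truth <- data.frame(species = ids, substrate = NA_character_,
                      byproduct = NA_character_, mu_max = uptake_bound * yield,
                      yield = yield)
  for (i in seq_len(n_species)) {
    sub <- if (chained && i > 1) sprintf("by%02d_e", i - 1) else
      sprintf("nut%02d_e", if (chained) 1L else i)
    prod <- if (byproduct_stoich > 0) sprintf("by%02d_e", i) else NULL
    cyt <- sprintf("pool%02d_c", i)
    mets <- data.frame(id = c(sub, cyt, prod),
                       name = c(sub, cyt, prod),
                       compartment = c("e", "c", if (!is.null(prod)) "e"))
    bio_stoich <- setNames(-1 / yield, cyt)
    if (!is.null(prod)) bio_stoich[prod] <- byproduct_stoich
    rxns <- list(
      list(id = paste0("EX_", sub), stoich = setNames(-1, sub),
           lb = -uptake_bound, ub = 1000),
      list(id = sprintf("trans%02d", i),
           stoich = setNames(c(-1, 1), c(sub, cyt)), lb = 0, ub = 1000),
      list(id = sprintf("biomass%02d", i), stoich = bio_stoich,
           lb = 0, ub = 1000))
    if (!is.null(prod)) {
      rxns <- c(rxns, list(list(id = paste0("EX_", prod),
                                stoich = setNames(-1, prod),
                                lb = 0, ub = 1000)))
    }
    models[[i]] <- metabolic_model(ids[i], mets, rxns,
                                   sprintf("biomass%02d", i))
    truth$substrate[i] <- sub
    truth$byproduct[i] <- if (is.null(prod)) NA_character_ else prod
  }
  names(models) <- ids
  list(models = models, truth = truth)
}

#' Simulate a group-structured zOTU count table
#'
#' Negative-binomial counts with log-normal library sizes and planted
#' differential taxa: planted taxa have expected counts differing between
#' the two groups by `2^planted_lfc`.
#'
#' @param n_taxa number of taxa.
#' @param n_per_group samples per group (cohort default 25 per group).
#' @param depth_mean mean library size.
#' @param nb_dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param planted_taxa indices or names of differential taxa.
#' @param planted_lfc log2 fold change (group 2 over group 1), recycled
#'   along `planted_taxa`.
#' @param groups the two group labels.
#' @param base_weights optional fixed relative taxon weights (length
#'   `n_taxa`); default draws log-normal weights, giving realistically
#'   skewed abundance profiles.
#' @param seed RNG seed.
#' @return list with `table` (an [abundance_table()] whose metadata holds
#'   the group labels) and `truth` (data.frame of planted taxa and lfc).
#' @export
simulate_counts <- function(n_taxa, n_per_group = 25, depth_mean = 20000,
                            nb_dispersion = 0.5, planted_taxa = integer(0),
                            planted_lfc = numeric(0),
                            groups = c("control", "PD"),
                            base_weights = NULL, seed = NULL) {
  stopifnot(n_taxa >= 1, n_per_group >= 1, depth_mean > 0, nb_dispersion >= 0)
  taxa <- sprintf("zotu%03d", seq_len(n_taxa))
  if (is.character(planted_taxa)) planted_taxa <- match(planted_taxa, taxa)
  planted_lfc <- if (length(planted_taxa) > 0) {
    rep_len(planted_lfc, length(planted_taxa))
  } else {
    numeric(0)
  }
  n <- 2 * n_per_group
  samples <- sprintf("s%03d", seq_len(n))
  grp <- rep(groups, each = n_per_group)
  with_seed(seed, {
    base <- if (is.null(base_weights)) {
      rlnorm(n_taxa, meanlog = 0, sdlog = 1)
    } else {
      rep_len(base_weights, n_taxa)
    }
    w1 <- base / sum(base)
    w2raw <- base
    w2raw[planted_taxa] <- w2raw[planted_taxa] * 2^planted_lfc
    w2 <- w2raw / sum(base)  # planted ratio stays exactly 2^lfc
    lib <- rlnorm(n, meanlog = log(depth_mean), sdlog = 0.25)
    mu <- outer(w1, lib)
    mu[, grp == groups[2]] <- outer(w2, lib[grp == groups[2]])
    counts <- matrix(
      if (nb_dispersion > 0) {
        rnbinom(length(mu), mu = mu, size = 1 / nb_dispersion)
      } else {
        rpois(length(mu), lambda = mu)
      },
      n_taxa, n, dimnames = list(taxa, samples))
    list(table = abundance_table(counts,
                                 metadata = data.frame(sample = samples,
                                                       group = grp)),
         truth = data.frame(taxon = taxa[planted_taxa], lfc = planted_lfc))
  })
}

.random_dna <- function(n, length) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
  }, character(1))
}

# substitute exactly round(rate * length) sites (positions random), so a
# query's divergence from its source is the stated fraction, not a draw
.mutate_dna <- function(seq, rate) {
  s <- strsplit(seq, "")[[1]]
  k <- round(rate * length(s))
  if (k > 0) {
    hit <- sample(length(s), k)
    for (i in hit) {
      s[i] <- sample(setdiff(c("A", "C", "G", "T"), s[i]), 1)
    }
  }
  paste(s, collapse = "")
}

#' Generate 16S-like reference and query sequences
#'
#' One random reference sequence per model; each query is a point-mutated
#' copy of its assigned reference with exactly `round(divergence * length)`
#' substituted sites at random positions, so the intended nearest neighbor
#' and the realized divergence are both known exactly.
#'
#' @param model_ids reference (model) ids.
#' @param query_assignment named character vector: query id -> model id.
#' @param divergence per-site substitution rate per query (scalar or named
#'   by query), in \[0, 1).
#' @param length sequence length, bp (420 ~ a V4-V5 amplicon).
#' @param seed RNG seed.
#' @return list with `references`, `queries` (named character vectors) and
#'   `truth` (data.frame: query, reference, divergence).
#' @export
synth_sequences <- function(model_ids, query_assignment,
                            divergence = 0.02, length = 420, seed = NULL) {
  if (any(divergence < 0 | divergence >= 1)) {
    stop("divergence must be in [0, 1)")
  }
  stopifnot(all(query_assignment %in% model_ids))
  div <- rep_len(divergence, length(query_assignment))
  if (!is.null(names(divergence))) {
    div <- divergence[names(query_assignment)]
  }
  with_seed(seed, {
    refs <- setNames(.random_dna(length(model_ids), length), model_ids)
    queries <- setNames(vapply(seq_along(query_assignment), function(k) {
      .mutate_dna(refs[[query_assignment[k]]], div[k])
    }, character(1)), names(query_assignment))
    list(references = refs, queries = queries,
         truth = data.frame(query = names(query_assignment),
                            reference = unname(query_assignment),
                            divergence = unname(div)))
  })
}

#' Generate per-participant diets with group-shifted nutrients
#'
#' Log-normal gram intakes; nutrients named in `group_shifts` have their
#' group-2 median multiplied by the stated factor. Optionally generates one
#' clinical variable with a target Spearman correlation to a chosen
#' nutrient (Gaussian copula), emulating diet-clinical coupling.
#'
#' @param n_per_group participants per group.
#' @param nutrients nutrient names.
#' @param mean_grams median intake per nutrient (scalar or named), g/day.
#' @param group_shifts named multiplicative shifts for group 2.
#' @param groups the two group labels.
#' @param clinical optional list `list(nutrient =, rho =, name =)` planting
#'   a correlated clinical variable.
#' @param seed RNG seed.
#' @return list with `diets` (named list of data.frames `nutrient`,
#'   `grams`), `metadata` (participant, group, clinical variable if any) and
#'   `truth`.
#' @export
synth_diets <- function(n_per_group, nutrients, mean_grams = 5,
                        group_shifts = numeric(0),
                        groups = c("control", "PD"), clinical = NULL,
                        seed = NULL) {
  n <- 2 * n_per_group
  ids <- sprintf("s%03d", seq_len(n))
  grp <- rep(groups, each = n_per_group)
  med <- setNames(rep_len(mean_grams, length(nutrients)), nutrients)
  with_seed(seed, {
    z <- matrix(rnorm(length(nutrients) * n), length(nutrients), n,
                dimnames = list(nutrients, ids))
    grams <- med * exp(0.4 * z)
    for (nu in names(group_shifts)) {
      grams[nu, grp == groups[2]] <- grams[nu, grp == groups[2]] * group_shifts[[nu]]
    }
    meta <- data.frame(participant = ids, group = grp)
    truth <- list(group_shifts = group_shifts)
    if (!is.null(clinical)) {
      rho <- clinical$rho
      zc <- rho * z[clinical$nutrient, ] + sqrt(1 - rho^2) * rnorm(n)
      meta[[clinical$name %||% "clinical1"]] <- 50 + 10 * zc
      truth$clinical <- clinical
    }
    diets <- lapply(ids, function(id) {
      data.frame(nutrient = nutrients, grams = unname(grams[, id]))
    })
    names(diets) <- ids
    list(diets = diets, metadata = meta, truth = truth)
  })
}

#' Generate a random rooted phylogeny over a taxon set
#'
#' Random bifurcating rooted tree with exponential branch lengths; every
#' taxon appears as exactly one leaf.
#'
#' @param taxa leaf labels (>= 2).
#' @param seed RNG seed.
#' @return an `ape` `phylo` object.
#' @export
synth_tree <- function(taxa, seed = NULL) {
  if (length(taxa) < 2) stop("need at least two taxa")
  with_seed(seed, {
    tr <- ape::rtree(length(taxa), rooted = TRUE,
                     br = function(n) rexp(n, rate = 5) + 1e-4)
    tr$tip.label <- sample(taxa)
    tr
  })
}

#' Nutrient map linking synthetic nutrients to toy-model substrates
#'
#' One nutrient per diet-consumed toy substrate plus optional unmapped
#' extras, with plausible molecular weights.
#'
#' @param truth the `truth` table from [make_toy_models()].
#' @param extra_nutrients names of nutrients without an exchange metabolite.
#' @param seed RNG seed for molecular weights.
#' @return data.frame `nutrient`, `metabolite`, `mol_weight` (extras get
#'   `NA` metabolite and are excluded; they exercise the unmapped path).
#' @export
synth_nutrient_map <- function(truth, extra_nutrients = character(0),
                               seed = NULL) {
  subs <- unique(grep("^nut", truth$substrate, value = TRUE))
  with_seed(seed, {
    data.frame(nutrient = paste0("nutrient_", sub("_e$", "", subs)),
               metabolite = subs,
               mol_weight = round(rlnorm(length(subs), log(180), 0.3), 2))
  })
}
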