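#' Default pipeline configuration
#'
#' Parameter defaults reproduce the source protocol's stated settings:
#' 97% mapping identity, 2% community abundance cutoff, 20% prevalence
#' filter, 60 x 60 = 3600-cell arena, 400 initial microbes, 12 h in 1 h
#' steps, 10 replicates, 9999 permutations, 99%/1% personal/reference diet
#' blending, alpha 0.05. Synthetic-cohort defaults are the scaled desk-size
#' cohort: 2 x 10 samples, 60 taxa, 6 toy models.
#'
#' @param ... overrides (name = value).
#' @return a named list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    # mapping / community
    identity_threshold = 0.97, min_abundance = 0.02,
    # ecology
    rarefy_depth = NULL,  # NULL = 0.9 quantile of library sizes
    prevalence = 0.20, permutations = 9999, alpha = 0.05,
    # diet
    w_personal = 0.99, diet_volume = 1.0,
    # arena
    grid = c(60, 60), n_init = 400, hours = 12, dt = 1, replicates = 10,
    b0 = 1e-6, arena_volume = 0.01, p_move = 1, diffusion = 0.1,
    # synthetic cohort
    n_models = 6, motif = "independent", uptake_bound = 10, yield = 0.1,
    byproduct_stoich = 5, n_taxa = 60, n_per_group = 10, depth_mean = 20000,
    nb_dispersion = 0.5, seq_length = 420, divergence_max = 0.02,
    frac_unmapped = 0.15, mean_grams = 20, taxa_weights = "lognormal",
    planted_species = NULL, planted_lfc = 0, diet_shifts = numeric(0),
    seed = 1)
  override <- list(...)
  bad <- setdiff(names(override), names(cfg))
  if (length(bad) > 0) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(override)] <- override
  .validate_config(structure(cfg, class = "run_config"))
}

#' @rdname default_config
#' @description `scaled_config()` additionally shrinks the arena (20 x 20
#'   cells, 100 initial microbes, 999 permutations) so that full pipeline
#'   runs complete in seconds; used for power/calibration experiments.
#' @export
scaled_config <- function(...) {
  default_config(grid = c(20, 20), n_init = 100, permutations = 999, ...)
}

.validate_config <- function(cfg) {
  stopifnot(cfg$identity_threshold > 0, cfg$identity_threshold <= 1,
            cfg$min_abundance >= 0, cfg$min_abundance < 1,
            cfg$prevalence >= 0, cfg$prevalence <= 1,
            cfg$w_personal >= 0, cfg$w_personal <= 1,
            length(cfg$grid) == 2, all(cfg$grid >= 1),
            cfg$n_init >= 1, cfg$hours > 0, cfg$dt > 0, cfg$replicates >= 1,
            cfg$permutations >= 1, cfg$diffusion <= 0.25)
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys override [default_config()].
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(default_config, vals)
}

#' Generate a complete synthetic cohort
#'
#' Produces every input the pipeline consumes, with known ground truth: toy
#' metabolic models, a group-structured zOTU table, 16S-like reference and
#' query sequences (taxa assigned to models round-robin, a fraction left
#' divergent enough to stay unmapped), a phylogeny, per-participant diets
#' and a nutrient map. When `planted_species` is set, the taxa assigned to
#' that model are planted as differential with `planted_lfc`.
#'
#' @param cfg a `run_config` (see [default_config()]).
#' @return list with `models`, `model_truth`, `table`, `count_truth`,
#'   `sequences`, `tree`, `diets`, `diet_metadata`, `nutrient_map`,
#'   `reference_diet`.
#' @export
synth_cohort <- function(cfg = default_config()) {
  seed <- cfg$seed
  toy <- make_toy_models(cfg$n_models, cfg$motif, cfg$uptake_bound,
                         cfg$yield, cfg$byproduct_stoich)
  taxa <- sprintf("zotu%03d", seq_len(cfg$n_taxa))
  assignment <- setNames(names(toy$models)[(seq_len(cfg$n_taxa) - 1) %%
                                             cfg$n_models + 1], taxa)
  div <- with_seed(seed + 1, {
    d <- runif(cfg$n_taxa, 0, cfg$divergence_max)
    unmapped <- runif(cfg$n_taxa) < cfg$frac_unmapped
    d[unmapped] <- 0.10
    setNames(d, taxa)
  })
  seqs <- synth_sequences(names(toy$models), assignment, divergence = div,
                          length = cfg$seq_length, seed = seed + 2)
  planted_taxa <- character(0)
  if (!is.null(cfg$planted_species)) {
    planted_taxa <- names(assignment)[assignment == cfg$planted_species &
                                        div < 0.05]
  }
  cts <- simulate_counts(cfg$n_taxa, cfg$n_per_group, cfg$depth_mean,
                         cfg$nb_dispersion, planted_taxa = planted_taxa,
                         planted_lfc = cfg$planted_lfc,
                         base_weights = if (identical(cfg$taxa_weights,
                                                      "uniform")) 1 else NULL,
                         seed = seed + 3)
  tree <- synth_tree(taxa, seed = seed + 4)
  nmap <- synth_nutrient_map(toy$truth,
                             seed = seed + 5)
  dts <- synth_diets(cfg$n_per_group, nutrients = nmap$nutrient,
                     mean_grams = cfg$mean_grams,
                     group_shifts = cfg$diet_shifts,
                     clinical = list(nutrient = nmap$nutrient[1], rho = -0.6,
                                     name = "disease_duration"),
                     seed = seed + 6)
  # reference diet: shipped synthetic Western-style table restricted/extended
  # to the toy nutrient panel so every substrate has a trace background
  ref <- setNames(rep(10, nrow(nmap)), nmap$metabolite)
  list(models = toy$models, model_truth = toy$truth, table = cts$table,
       count_truth = cts$truth, sequences = seqs, tree = tree,
       diets = dts$diets, diet_metadata = dts$metadata, nutrient_map = nmap,
       reference_diet = ref)
}

#' Run the full community-reconstruction pipeline
#'
#' Stages: `synth` (or user-supplied inputs) -> sequence mapping ->
#' per-sample model communities -> diet constraint sets (grams -> mM,
#' 99%/1% blending) -> replicated arena simulations -> ecology statistics
#' (rarefaction, prevalence filter, alpha diversity, Bray-Curtis and
#' UniFrac with ANOSIM/PERMANOVA, diet-clinical Spearman/FDR) -> end-point
#' metabolite group comparison. With `out_dir` set, per-stage TSV/JSON
#' outputs and a reproducibility manifest are written.
#'
#' @param cfg a `run_config`.
#' @param inputs optional cohort list as returned by [synth_cohort()]
#'   (generated from `cfg` when `NULL`).
#' @param out_dir optional output directory.
#' @param stages character subset of
#'   `c("map", "communities", "diet", "simulate", "ecology", "endpoints")`;
#'   later stages require earlier ones.
#' @return list with per-stage results (`mapping`, `communities`, `diets`,
#'   `simulations`, `ecology`, `endpoints`, `attribution`, `config`).
#' @export
run_pipeline <- function(cfg = scaled_config(), inputs = NULL, out_dir = NULL,
                         stages = c("map", "communities", "diet", "simulate",
                                    "ecology", "endpoints")) {
  if (is.null(inputs)) inputs <- synth_cohort(cfg)
  res <- list(config = cfg)
  samples <- colnames(inputs$table$counts)
  groups <- inputs$table$metadata$group[match(samples,
                                              inputs$table$metadata$sample)]

  if ("map" %in% stages) {
    res$mapping <- map_sequences(inputs$sequences$queries,
                                 inputs$sequences$references,
                                 threshold = cfg$identity_threshold)
  }

  if ("communities" %in% stages) {
    res$communities <- lapply(samples, function(s) {
      build_community(inputs$table, res$mapping, s,
                      min_abundance = cfg$min_abundance)
    })
    names(res$communities) <- samples
  }

  if ("diet" %in% stages) {
    res$diets <- lapply(samples, function(s) {
      personal <- diet_to_constraints(inputs$diets[[s]], inputs$nutrient_map,
                                      volume = cfg$diet_volume)
      blend_diets(personal, inputs$reference_diet, cfg$w_personal)
    })
    names(res$diets) <- samples
  }

  if ("simulate" %in% stages) {
    res$simulations <- lapply(seq_along(samples), function(k) {
      s <- samples[k]
      arena <- init_arena(res$communities[[s]], inputs$models, res$diets[[s]],
                          n_init = cfg$n_init, shape = cfg$grid,
                          seed = cfg$seed + 7 + k, b0 = cfg$b0,
                          arena_volume = cfg$arena_volume, dt = cfg$dt,
                          p_move = cfg$p_move, diffusion = cfg$diffusion)
      run_simulation(arena, hours = cfg$hours, replicates = cfg$replicates,
                     seeds = cfg$seed + 1000 + k * cfg$replicates +
                       seq_len(cfg$replicates))
    })
    names(res$simulations) <- samples
  }

  if ("ecology" %in% stages) {
    depth <- cfg$rarefy_depth
    if (is.null(depth)) {
      depth <- floor(quantile(colSums(inputs$table$counts), 0.1))
    }
    tab <- rarefy(inputs$table, depth, seed = cfg$seed + 50)
    tab <- prevalence_filter(tab, cfg$prevalence)
    kept <- colnames(tab$counts)
    kept_groups <- groups[match(kept, samples)]
    bc <- bray_curtis(tab)
    uf_u <- unifrac(tab, inputs$tree, weighted = FALSE)
    uf_w <- unifrac(tab, inputs$tree, weighted = TRUE)
    nutr <- sapply(inputs$diets[kept], function(d) d$grams)
    rownames(nutr) <- inputs$diets[[1]]$nutrient
    clin_cols <- setdiff(names(inputs$diet_metadata), c("participant", "group"))
    sp <- NULL
    if (length(clin_cols) > 0 && length(kept) >= 4) {
      clin <- t(as.matrix(inputs$diet_metadata[
        match(kept, inputs$diet_metadata$participant), clin_cols, drop = FALSE]))
      rownames(clin) <- clin_cols
      sp <- spearman_fdr(nutr, clin)
    }
    res$ecology <- list(
      rarefied_depth = depth,
      table = tab,
      alpha = alpha_diversity(tab),
      bray_curtis = bc,
      unifrac_unweighted = uf_u,
      unifrac_weighted = uf_w,
      anosim_bc = .beta_test(anosim_test, bc, kept_groups, cfg, 60),
      permanova_bc = .beta_test(permanova_test, bc, kept_groups, cfg, 61),
      anosim_wuf = .beta_test(anosim_test, uf_w, kept_groups, cfg, 62),
      permanova_wuf = .beta_test(permanova_test, uf_w, kept_groups, cfg, 63),
      spearman = sp)
  }

  if ("endpoints" %in% stages) {
    res$endpoints <- compare_endpoints(res$simulations, groups)
    res$attribution <- lapply(res$simulations, flux_attribution)
  }

  if (!is.null(out_dir)) .write_pipeline_outputs(res, inputs, out_dir)
  res
}

# beta-diversity tests need >= 2 samples per group after rarefaction; on
# degenerate cohorts report NULL instead of aborting the whole run
.beta_test <- function(fun, d, groups, cfg, seed_offset) {
  if (any(table(groups) < 2) || length(unique(groups)) < 2) {
    message("skipping beta-diversity test: a group has < 2 samples")
    return(NULL)
  }
  fun(d, groups, cfg$permutations, seed = cfg$seed + seed_offset)
}

.write_pipeline_outputs <- function(res, inputs, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(res$mapping)) tsv(res$mapping, "mapping.tsv")
  if (!is.null(res$communities)) {
    jsonlite::write_json(lapply(res$communities, function(cm) {
      list(sample = cm$sample, abundance = as.list(cm$abundance),
           mapped_fraction = cm$mapped_fraction)
    }), file.path(out_dir, "communities.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(res$diets)) {
    jsonlite::write_json(lapply(res$diets, as.list),
                         file.path(out_dir, "diets_mM.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(res$simulations)) {
    conc <- do.call(rbind, lapply(names(res$simulations), function(s) {
      m <- res$simulations[[s]]$end_concentrations
      data.frame(sample = s, replicate = seq_len(nrow(m)), m,
                 check.names = FALSE)
    }))
    tsv(conc, "end_concentrations.tsv")
  }
  if (!is.null(res$ecology)) {
    tsv(res$ecology$alpha, "alpha_diversity.tsv")
    tsv(data.frame(sample = rownames(res$ecology$bray_curtis),
                   res$ecology$bray_curtis, check.names = FALSE),
        "bray_curtis.tsv")
    tests <- lapply(Filter(Negate(is.null),
                           res$ecology[c("anosim_bc", "permanova_bc",
                                         "anosim_wuf", "permanova_wuf")]),
                    function(t) {
      list(statistic = unname(t$statistic), R2 = t$R2, p = t$p,
           permutations = t$permutations)
    })
    jsonlite::write_json(tests, file.path(out_dir, "beta_tests.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(res$ecology$spearman)) tsv(res$ecology$spearman, "spearman.tsv")
  }
  if (!is.null(res$endpoints)) {
    tsv(res$endpoints, "endpoints.tsv")
    tsv(do.call(rbind, lapply(names(res$attribution), function(s) {
      cbind(sample = s, res$attribution[[s]])
    })), "attribution.tsv")
  }
  files <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(
    package = "commfba",
    version = as.character(utils::packageVersion("commfba")),
    r_version = R.version.string,
    config = unclass(res$config),
    checksums = as.list(tools::md5sum(file.path(out_dir, files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
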