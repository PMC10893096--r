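#' Taxa-by-samples abundance table with metadata
#'
#' Container for a zOTU/taxon count matrix plus optional taxonomy labels and
#' per-sample metadata (group labels, clinical variables).
#'
#' @param counts non-negative integer matrix, taxa x samples, with
#'   dimnames.
#' @param taxonomy optional data.frame keyed by column `taxon`.
#' @param metadata optional data.frame keyed by column `sample`, typically
#'   with a `group` column.
#' @return an object of class `abundance_table`.
#' @export
abundance_table <- function(counts, taxonomy = NULL, metadata = NULL) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have taxon rownames and sample colnames")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (anyDuplicated(colnames(counts))) stop("sample ids must be unique")
  if (!is.null(metadata)) {
    if (!"sample" %in% names(metadata)) stop("metadata needs a 'sample' column")
    missing <- setdiff(colnames(counts), metadata$sample)
    if (length(missing) > 0) {
      stop("metadata missing sample(s): ", paste(missing, collapse = ", "))
    }
  }
  structure(list(counts = counts, taxonomy = taxonomy, metadata = metadata),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d taxa x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

.get_counts <- function(table) {
  if (inherits(table, "abundance_table")) table$counts else as.matrix(table)
}

.wrap_like <- function(table, counts) {
  if (!inherits(table, "abundance_table")) return(counts)
  table$counts <- counts
  if (!is.null(table$metadata)) {
    table$metadata <- table$metadata[table$metadata$sample %in% colnames(counts), ,
                                     drop = FALSE]
  }
  table
}

#' Rarefy samples to an even sequencing depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`;
#' samples with fewer total reads than `depth` are dropped with a warning.
#'
#' @param table `abundance_table` or counts matrix (taxa x samples).
#' @param depth target depth (reads per sample).
#' @param seed RNG seed.
#' @return the rarefied table (every remaining column sums to `depth`).
#' @export
rarefy <- function(table, depth, seed = NULL) {
  if (depth <= 0) stop("depth must be positive")
  counts <- .get_counts(table)
  totals <- colSums(counts)
  drop <- totals < depth
  if (any(drop)) {
    warning("dropping ", sum(drop), " sample(s) below depth ", depth, ": ",
            paste(colnames(counts)[drop], collapse = ", "))
    counts <- counts[, !drop, drop = FALSE]
  }
  if (ncol(counts) == 0) stop("no sample reaches the rarefaction depth")
  # vegan::rrarefy warns whenever the smallest nonzero count exceeds 1,
  # which is routine for deep samples; that advisory is muffled
  out <- with_seed(seed, withCallingHandlers(
    t(vegan::rrarefy(t(counts), depth)),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }))
  storage.mode(out) <- "integer"
  .wrap_like(table, out)
}

#' Filter taxa by prevalence
#'
#' Keeps taxa with nonzero counts in at least
#' `ceiling(min_prevalence * n_samples)` samples (default: present in at
#' least 20% of samples).
#'
#' @param table `abundance_table` or counts matrix.
#' @param min_prevalence fraction of samples, in (0, 1].
#' @return the filtered table.
#' @export
prevalence_filter <- function(table, min_prevalence = 0.20) {
  if (min_prevalence < 0 || min_prevalence > 1) {
    stop("min_prevalence must be in [0, 1]")
  }
  counts <- .get_counts(table)
  need <- ceiling(min_prevalence * ncol(counts))
  keep <- rowSums(counts > 0) >= need
  .wrap_like(table, counts[keep, , drop = FALSE])
}

#' Alpha diversity indices of one sample
#'
#' Observed richness, Shannon index (natural log) and inverse Simpson index.
#'
#' @param counts non-negative count (or abundance) vector for one sample, or
#'   a table, in which case all samples are returned as a data.frame.
#' @return named vector `c(observed, shannon, inv_simpson)` for a vector
#'   input; data.frame with a `sample` column for a table input.
#' @export
alpha_diversity <- function(counts) {
  if (is.matrix(counts) || inherits(counts, "abundance_table")) {
    m <- .get_counts(counts)
    out <- t(apply(m, 2, alpha_diversity))
    return(data.frame(sample = colnames(m), out, row.names = NULL))
  }
  if (all(counts == 0)) stop("all-zero sample has undefined diversity")
  c(observed = sum(counts > 0),
    shannon = unname(vegan::diversity(counts, index = "shannon")),
    inv_simpson = unname(vegan::diversity(counts, index = "invsimpson")))
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{d(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)} between all sample
#' pairs.
#'
#' @param table `abundance_table` or counts matrix (taxa x samples).
#' @return symmetric samples x samples matrix with zero diagonal, values in
#'   \[0, 1\].
#' @export
bray_curtis <- function(table) {
  x <- .get_counts(table)
  if (ncol(x) < 2) stop("need at least two samples")
  if (any(colSums(x) == 0)) {
    stop("Bray-Curtis undefined for all-zero sample(s): ",
         paste(colnames(x)[colSums(x) == 0], collapse = ", "))
  }
  n <- ncol(x)
  d <- matrix(0, n, n, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- sum(abs(x[, i] - x[, j])) / sum(x[, i] + x[, j])
    }
  }
  d
}

#' UniFrac phylogenetic beta diversity
#'
#' Unweighted UniFrac is the tree branch length unique to one of the two
#' communities divided by the branch length covered by either. Weighted
#' UniFrac is \eqn{\sum_i b_i |A_i - B_i|} over branches, where \eqn{A_i}
#' and \eqn{B_i} are the fractions of each sample's reads descending branch
#' \eqn{i}; the normalized variant (default) divides by
#' \eqn{\sum_i b_i (A_i + B_i)}.
#'
#' @param table `abundance_table` or counts matrix; every taxon must be a
#'   tip of `tree`.
#' @param tree rooted `phylo` tree with branch lengths.
#' @param weighted logical.
#' @param normalized divide weighted distances by their maximum attainable
#'   value (ignored for unweighted).
#' @return symmetric samples x samples distance matrix.
#' @export
unifrac <- function(table, tree, weighted = FALSE, normalized = TRUE) {
  x <- .get_counts(table)
  missing <- setdiff(rownames(x), tree$tip.label)
  if (length(missing) > 0) {
    stop("taxa missing from tree: ", paste(missing, collapse = ", "))
  }
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  n <- ncol(x)
  p <- sweep(x, 2, colSums(x), "/")  # read fractions per sample

  # fraction of each sample's reads descending every edge (postorder sweep)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  node_frac <- matrix(0, ntip + nnode, n)
  node_frac[match(rownames(x), tree$tip.label), ] <- p
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    node_frac[po$edge[k, 1], ] <- node_frac[po$edge[k, 1], ] +
      node_frac[po$edge[k, 2], ]
  }
  edge_frac <- node_frac[tree$edge[, 2], , drop = FALSE]
  b <- tree$edge.length

  d <- matrix(0, n, n, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      A <- edge_frac[, i]
      B <- edge_frac[, j]
      if (weighted) {
        num <- sum(b * abs(A - B))
        if (normalized) {
          den <- sum(b * (A + B))
          d[i, j] <- if (den > 0) num / den else 0
        } else {
          d[i, j] <- num
        }
      } else {
        pa <- A > 0
        pb <- B > 0
        den <- sum(b[pa | pb])
        d[i, j] <- if (den > 0) sum(b[xor(pa, pb)]) / den else 0
      }
      d[j, i] <- d[i, j]
    }
  }
  d
}

.pair_index <- function(n) {
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(2:n, function(k) k:n))
  list(i = i, j = j)
}

.check_groups <- function(groups, n) {
  groups <- as.factor(groups)
  if (length(groups) != n) stop("one group label per sample required")
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("every group needs at least two samples")
  groups
}

#' Analysis of similarities (ANOSIM)
#'
#' Clarke's rank-based permutation test:
#' \eqn{R = (\bar r_B - \bar r_W) / (n(n-1)/4)} on the ranked distances,
#' with the permutation p-value \eqn{(1 + \#\{R^* \ge R\}) / (perm + 1)}
#' under random relabeling of samples.
#'
#' @param d distance matrix (samples x samples) or `dist`.
#' @param groups group label per sample.
#' @param permutations number of label permutations (protocol default 9999).
#' @param seed RNG seed for the permutations.
#' @return object of class `permutation_test` with `statistic` (R), `p`,
#'   `permutations`.
#' @export
anosim_test <- function(d, groups, permutations = 9999, seed = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  groups <- .check_groups(groups, n)
  pr <- .pair_index(n)
  r <- rank(d[cbind(pr$i, pr$j)])
  denom <- n * (n - 1) / 4
  stat_fun <- function(g) {
    within <- g[pr$i] == g[pr$j]
    (mean(r[!within]) - mean(r[within])) / denom
  }
  obs <- stat_fun(groups)
  perm <- with_seed(seed, vapply(seq_len(permutations),
                                 function(k) stat_fun(sample(groups)),
                                 numeric(1)))
  structure(list(method = "ANOSIM", statistic = c(R = obs),
                 p = (1 + sum(perm >= obs)) / (permutations + 1),
                 permutations = permutations),
            class = "permutation_test")
}

#' Permutational multivariate analysis of variance (PERMANOVA / Adonis)
#'
#' Partitions squared distances:
#' \eqn{SS_T = \frac{1}{n}\sum_{i<j} d_{ij}^2},
#' \eqn{SS_W = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d_{ij}^2},
#' pseudo-F \eqn{= (SS_B/(a-1)) / (SS_W/(n-a))} and \eqn{R^2 = SS_B/SS_T},
#' with the same permutation p-value convention as [anosim_test()].
#'
#' @inheritParams anosim_test
#' @return object of class `permutation_test` with `statistic` (pseudo-F),
#'   `R2`, `p`, `permutations`.
#' @export
permanova_test <- function(d, groups, permutations = 9999, seed = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  groups <- .check_groups(groups, n)
  a <- nlevels(groups)
  pr <- .pair_index(n)
  d2 <- d[cbind(pr$i, pr$j)]^2
  ss_total <- sum(d2) / n
  stat_fun <- function(g) {
    gi <- g[pr$i]
    within <- gi == g[pr$j]
    sw <- tapply(d2[within], gi[within], sum)
    ng <- table(g)[names(sw)]
    ss_within <- sum(sw / as.numeric(ng))
    ss_between <- ss_total - ss_within
    f <- (ss_between / (a - 1)) / (ss_within / (n - a))
    c(f, ss_between / ss_total)
  }
  obs <- stat_fun(groups)
  perm <- with_seed(seed, vapply(seq_len(permutations),
                                 function(k) stat_fun(sample(groups))[1],
                                 numeric(1)))
  structure(list(method = "PERMANOVA", statistic = c(F = obs[1]),
                 R2 = obs[2],
                 p = (1 + sum(perm >= obs[1])) / (permutations + 1),
                 permutations = permutations),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("<%s> %s = %.4f%s, p = %.4g (%d permutations)\n", x$method,
              names(x$statistic), x$statistic,
              if (!is.null(x$R2)) sprintf(", R2 = %.4f", x$R2) else "",
              x$p, x$permutations))
  invisible(x)
}

#' Pairwise Spearman correlations with FDR correction
#'
#' Spearman's rho (mid-ranks) between every row of `X` and every row of `Y`,
#' two-sided p-values (exact for n <= 9 without ties, t-approximation
#' otherwise) and Benjamini-Hochberg adjustment across all pairs. Pairs with
#' a constant variable have undefined rho and are reported as `NA`.
#'
#' @param X,Y numeric matrices, variables x samples, with matching samples.
#' @param exact_max_n largest n for the exact null distribution.
#' @return data.frame with `var_x`, `var_y`, `rho`, `p`, `p_adj`.
#' @export
spearman_fdr <- function(X, Y, exact_max_n = 9) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y)) stop("X and Y must share samples (columns)")
  if (ncol(X) < 4) stop("need at least 4 paired observations")
  if (is.null(rownames(X))) rownames(X) <- paste0("x", seq_len(nrow(X)))
  if (is.null(rownames(Y))) rownames(Y) <- paste0("y", seq_len(nrow(Y)))
  out <- expand.grid(var_x = rownames(X), var_y = rownames(Y),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- ncol(X)
  res <- mapply(function(vx, vy) {
    x <- X[vx, ]
    y <- Y[vy, ]
    if (sd(x) == 0 || sd(y) == 0) return(c(NA_real_, NA_real_))
    exact <- n <= exact_max_n && !anyDuplicated(x) && !anyDuplicated(y)
    ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = exact))
    c(unname(ct$estimate), ct$p.value)
  }, out$var_x, out$var_y)
  out$rho <- res[1, ]
  out$p <- res[2, ]
  out$p_adj <- p.adjust(out$p, method = "BH")
  out
}
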