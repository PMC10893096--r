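#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration of the null distribution when both groups have at most
#' `exact_max_n` observations and there are no ties; otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param x,y numeric vectors (the two groups).
#' @param exact_max_n largest per-group n for the exact distribution.
#' @return list with `U` (Mann-Whitney statistic of `x`) and `p`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max_n = 8) {
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  if (length(unique(c(x, y))) == 1L) {
    return(list(U = length(x) * length(y) / 2, p = 1))
  }
  exact <- length(x) <= exact_max_n && length(y) <= exact_max_n &&
    !anyDuplicated(c(x, y))
  ht <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  list(U = unname(ht$statistic), p = ht$p.value)
}

#' Gaussian-identity GLM group test
#'
#' Fits `value ~ group (+ covariates)` with a Gaussian identity link and
#' reports the Wald test on the group coefficient. With no covariates this
#' is numerically the pooled-variance two-sample t-test.
#'
#' @param values numeric response.
#' @param groups two-level factor (or coercible).
#' @param covariates optional data.frame of additional regressors.
#' @return list with `coefficient` (effect of the second group level) and
#'   `p`; errors name the collinear column on a singular design.
#' @export
glm_group_test <- function(values, groups, covariates = NULL) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  if (any(table(groups) < 3)) stop("need at least 3 observations per group")
  df <- data.frame(value = values, group = groups)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  fit <- glm(value ~ ., data = df, family = gaussian())
  if (any(is.na(coef(fit)))) {
    stop("singular design; collinear column(s): ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  term <- paste0("group", levels(groups)[2])
  pv <- sm[term, "Pr(>|t|)"]
  if (is.nan(pv)) pv <- 1  # zero residual variance (constant response)
  list(coefficient = unname(sm[term, "Estimate"]), p = unname(pv))
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' p is the sum of hypergeometric probabilities of all tables (with the
#' observed margins) no more probable than the observed one.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return the two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers")
  }
  fisher.test(table)$p.value
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement, capped at 1. Adjusted
#' values never fall below the raw p-values.
#'
#' @param p vector of p-values in (0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Compare simulation end-point metabolites between groups
#'
#' Summarizes each sample's replicate end-point concentrations (mean by
#' default), restricts to the metabolites common to every sample's output,
#' and tests each metabolite between the two groups with the Wilcoxon
#' rank-sum test and the Gaussian GLM, adjusting each p-value family across
#' metabolites with Benjamini-Hochberg. Results are invariant to sample and
#' replicate ordering.
#'
#' @param results named list (one element per sample) of
#'   `simulation_result`s, or of replicate x metabolite concentration
#'   matrices.
#' @param groups group label per sample (named or in `results` order).
#' @param summary replicate summary statistic, `"mean"` or `"median"`.
#' @param covariates optional data.frame (samples x covariates) passed to
#'   the GLM.
#' @return data.frame, one row per common metabolite: `metabolite`,
#'   group means, `wilcoxon_U`, `p_wilcoxon`, `p_adj_wilcoxon`,
#'   `glm_coefficient`, `p_glm`, `p_adj_glm`, `direction` (group with the
#'   larger mean), ordered by `p_wilcoxon`.
#' @export
compare_endpoints <- function(results, groups, summary = c("mean", "median"),
                              covariates = NULL) {
  summary <- match.arg(summary)
  mats <- lapply(results, function(r) {
    if (inherits(r, "simulation_result")) r$end_concentrations else as.matrix(r)
  })
  reps <- vapply(mats, nrow, integer(1))
  if (length(unique(reps)) != 1) {
    stop("every sample must be simulated with the same replicate count")
  }
  common <- Reduce(intersect, lapply(mats, colnames))
  if (length(common) == 0) stop("no metabolite common to all samples")
  sfun <- if (summary == "mean") colMeans else function(m) apply(m, 2, median)
  value <- t(vapply(mats, function(m) sfun(m[, common, drop = FALSE]),
                    numeric(length(common))))
  colnames(value) <- common
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  lv <- levels(groups)

  rows <- lapply(common, function(met) {
    v <- value[, met]
    w <- wilcoxon_rank_sum(v[groups == lv[1]], v[groups == lv[2]])
    g <- glm_group_test(v, groups, covariates)
    m1 <- mean(v[groups == lv[1]])
    m2 <- mean(v[groups == lv[2]])
    data.frame(metabolite = met, mean_1 = m1, mean_2 = m2,
               wilcoxon_U = w$U, p_wilcoxon = w$p,
               glm_coefficient = g$coefficient, p_glm = g$p,
               direction = if (m1 >= m2) lv[1] else lv[2])
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "mean_1"] <- paste0("mean_", lv[1])
  names(out)[names(out) == "mean_2"] <- paste0("mean_", lv[2])
  out$p_adj_wilcoxon <- bh_adjust(out$p_wilcoxon)
  out$p_adj_glm <- bh_adjust(out$p_glm)
  out <- out[order(out$p_wilcoxon, out$metabolite), , drop = FALSE]
  rownames(out) <- NULL
  out
}
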