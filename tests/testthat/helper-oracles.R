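# Independent oracles used across the suite. These deliberately take naive
# routes (enumeration, brute force) distinct from the package's own code.

# --- LP oracle: brute-force vertex enumeration ------------------------------
# max c'v s.t. S v = 0, lb <= v <= ub (finite bounds). Every vertex of the
# bounded polytope has >= n - rank(S) variables at a bound; enumerate all
# basic/nonbasic splits and bound assignments, keep feasible points.
lp_enumerate <- function(S, c_vec, lb, ub, tol = 1e-9) {
  S <- as.matrix(S)
  n <- ncol(S)
  r <- qr(S)$rank
  best <- -Inf
  feasible <- FALSE
  nonbasic_sets <- utils::combn(n, n - r, simplify = FALSE)
  if (n - r == 0) nonbasic_sets <- list(integer(0))
  for (N in nonbasic_sets) {
    B <- setdiff(seq_len(n), N)
    SB <- S[, B, drop = FALSE]
    if (qr(SB)$rank < length(B)) next
    grid <- if (length(N) > 0) {
      expand.grid(rep(list(c(FALSE, TRUE)), length(N)))
    } else {
      data.frame(row.names = 1)
    }
    for (g in seq_len(nrow(grid))) {
      v <- numeric(n)
      if (length(N) > 0) {
        at_ub <- as.logical(grid[g, ])
        v[N] <- ifelse(at_ub, ub[N], lb[N])
      }
      rhs <- -S[, N, drop = FALSE] %*% v[N]
      vb <- tryCatch(qr.solve(SB, rhs), error = function(e) NULL)
      if (is.null(vb)) next
      v[B] <- vb
      if (max(abs(S %*% v)) > 1e-7) next
      if (any(v < lb - 1e-7) || any(v > ub + 1e-7)) next
      feasible <- TRUE
      best <- max(best, sum(c_vec * v))
    }
  }
  list(feasible = feasible, objective = best)
}

# random small metabolic network as raw LP pieces; bounds always contain 0
# so v = 0 is feasible and the LP is bounded
random_lp <- function(n_mets, n_rxns, seed) {
  set.seed(seed)
  S <- matrix(sample(-2:2, n_mets * n_rxns, replace = TRUE,
                     prob = c(.1, .2, .4, .2, .1)), n_mets, n_rxns)
  lb <- -round(runif(n_rxns, 0, 10), 2)
  ub <- round(runif(n_rxns, 0, 10), 2)
  k <- sample(n_rxns, 1)
  c_vec <- as.numeric(seq_len(n_rxns) == k)
  list(S = S, lb = lb, ub = ub, c_vec = c_vec, objective_rxn = k)
}

# wrap raw LP pieces as a metabolic_model (exchanges unused by solve_fba)
lp_as_model <- function(lp, id = "rnd") {
  mets <- sprintf("m%02d", seq_len(nrow(lp$S)))
  rxns <- lapply(seq_len(ncol(lp$S)), function(j) {
    st <- lp$S[, j]
    names(st) <- mets
    st <- st[st != 0]
    if (length(st) == 0) st <- setNames(0, mets[1])
    list(id = sprintf("r%02d", j), stoich = st, lb = lp$lb[j], ub = lp$ub[j])
  })
  metabolic_model(id, mets, rxns, sprintf("r%02d", lp$objective_rxn),
                  exchanges = character(0))
}

# --- UniFrac oracle: naive per-branch computation via phangorn --------------
unifrac_naive <- function(x, tree, weighted = FALSE, normalized = TRUE) {
  p <- sweep(x, 2, colSums(x), "/")
  n <- ncol(x)
  ntip <- length(tree$tip.label)
  desc <- phangorn::Descendants(tree, tree$edge[, 2], type = "tips")
  A <- vapply(seq_len(n), function(s) {
    vapply(desc, function(tips) {
      sum(p[match(tree$tip.label[tips], rownames(x)), s], na.rm = TRUE)
    }, numeric(1))
  }, numeric(nrow(tree$edge)))
  b <- tree$edge.length
  d <- matrix(0, n, n, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (weighted) {
        num <- sum(b * abs(A[, i] - A[, j]))
        d[i, j] <- if (normalized) num / sum(b * (A[, i] + A[, j])) else num
      } else {
        pa <- A[, i] > 0
        pb <- A[, j] > 0
        d[i, j] <- sum(b[xor(pa, pb)]) / sum(b[pa | pb])
      }
      d[j, i] <- d[i, j]
    }
  }
  d
}

# --- Wilcoxon oracle: full enumeration of rank splits -----------------------
wilcox_enumerate <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  u_all <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  p <- sum(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9) / ncol(combs)
  list(U = u_obs, p = min(1, p))
}

# --- Fisher oracle: hypergeometric enumeration ------------------------------
fisher_enumerate <- function(tab) {
  r1 <- sum(tab[1, ])
  c1 <- sum(tab[, 1])
  n <- sum(tab)
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(ks, r1, n - r1, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# --- small toy fixtures -----------------------------------------------------
chain_toy <- function(uptake = 10, yield = 0.1) {
  make_toy_models(1, "independent", uptake_bound = uptake, yield = yield,
                  byproduct_stoich = 0)$models[[1]]
}

expect_no_warning_arena <- function(...) suppressWarnings(init_arena(...))
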