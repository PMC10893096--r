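random_table <- function(n_taxa, n_samples, seed, lambda = 40) {
  set.seed(seed)
  matrix(rpois(n_taxa * n_samples, lambda), n_taxa, n_samples,
         dimnames = list(paste0("t", seq_len(n_taxa)),
                         paste0("s", seq_len(n_samples))))
}

# exhaustive two-group label enumeration of a permutation statistic
enumerate_labels <- function(n, n1, stat_fun) {
  apply(utils::combn(n, n1), 2, function(idx) {
    g <- rep("b", n)
    g[idx] <- "a"
    stat_fun(factor(g))
  })
}

test_that("rarefaction conserves depth and drops shallow samples", {
  x <- random_table(30, 6, seed = 51)
  x[, 6] <- 0
  x[1, 6] <- 5
  expect_warning(out <- rarefy(x, depth = 100, seed = 1), "dropping 1 sample")
  expect_equal(unname(colSums(out)), rep(100, 5))
  # a sample exactly at depth is returned unchanged
  y <- matrix(c(3L, 7L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(rarefy(y, 10, seed = 1), y)
  expect_error(rarefy(y, 0), "positive")
})

test_that("rarefied counts have the hypergeometric mean", {
  x <- matrix(c(30L, 50L, 20L), 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
  depth <- 40
  draws <- vapply(1:1000, function(s) rarefy(x, depth, seed = s)["a", 1],
                  numeric(1))
  mu <- depth * 30 / 100
  v <- depth * 0.3 * 0.7 * (100 - depth) / 99
  expect_lt(abs(mean(draws) - mu), 3 * sqrt(v / 1000))
})

test_that("prevalence filtering uses the ceiling boundary", {
  x <- matrix(0L, 3, 50, dimnames = list(c("rare", "edge", "common"),
                                         paste0("s", 1:50)))
  x["rare", 1:9] <- 1L
  x["edge", 1:10] <- 1L
  x["common", ] <- 2L
  out <- prevalence_filter(x, 0.20)
  expect_setequal(rownames(out), c("edge", "common"))
  expect_equal(rownames(prevalence_filter(x, 0)), rownames(x))
})

test_that("alpha diversity matches closed forms", {
  uniform <- rep(5, 8)
  a <- alpha_diversity(uniform)
  expect_equal(unname(a["shannon"]), log(8))
  expect_equal(unname(a["inv_simpson"]), 8)
  expect_equal(unname(a["observed"]), 8)
  single <- c(10, 0, 0)
  expect_equal(unname(alpha_diversity(single)), c(1, 0, 1))
  expect_equal(unname(alpha_diversity(c(1, 2, 3))["shannon"]),
               -sum((1:3) / 6 * log((1:3) / 6)))
  expect_error(alpha_diversity(c(0, 0)), "all-zero")
})

test_that("Bray-Curtis matches its formula and vegan", {
  x <- cbind(s1 = c(6, 0, 2), s2 = c(2, 2, 0), s3 = c(6, 0, 2))
  rownames(x) <- paste0("t", 1:3)
  d <- bray_curtis(x)
  expect_equal(d["s1", "s2"], 8 / 12)
  expect_equal(d["s1", "s3"], 0)
  expect_equal(d, t(d))
  disjoint <- cbind(s1 = c(5, 0), s2 = c(0, 7))
  rownames(disjoint) <- c("a", "b")
  expect_equal(bray_curtis(disjoint)["s1", "s2"], 1)
  y <- random_table(25, 8, seed = 52)
  dv <- as.matrix(vegan::vegdist(t(y), method = "bray"))
  expect_equal(unname(bray_curtis(y)), unname(dv), tolerance = 1e-12)
})

test_that("UniFrac equals the naive per-branch oracle on random trees", {
  skip_if_not_installed("phangorn")
  for (k in 1:20) {
    taxa <- paste0("t", 1:8)
    tr <- synth_tree(taxa, seed = 500 + k)
    x <- random_table(8, 4, seed = 600 + k, lambda = 3)
    rownames(x) <- taxa
    x[x > 0 & matrix(runif(32) < 0.3, 8, 4)] <- 0  # some absences
    if (any(colSums(x) == 0)) next
    for (w in c(FALSE, TRUE)) {
      ours <- unifrac(x, tr, weighted = w)
      oracle <- unifrac_naive(x, tr, weighted = w)
      expect_equal(ours, oracle, tolerance = 1e-10)
    }
  }
})

test_that("unweighted UniFrac spans [0, 1] with the star-tree extremes", {
  taxa <- paste0("t", 1:4)
  star <- ape::read.tree(text = "(t1:1,t2:1,t3:1,t4:1);")
  x <- cbind(s1 = c(1, 1, 0, 0), s2 = c(0, 0, 1, 1), s3 = c(1, 1, 0, 0))
  rownames(x) <- taxa
  d <- unifrac(x, star, weighted = FALSE)
  expect_equal(d["s1", "s2"], 1)
  expect_equal(d["s1", "s3"], 0)
})

test_that("UniFrac agrees with picante on presence data", {
  skip_if_not_installed("picante")
  taxa <- paste0("t", 1:10)
  tr <- synth_tree(taxa, seed = 61)
  x <- random_table(10, 5, seed = 62, lambda = 2)
  rownames(x) <- taxa
  d <- unifrac(x, tr, weighted = FALSE)
  pd <- as.matrix(picante::unifrac(t(x), tr))
  expect_equal(unname(d[rownames(pd), colnames(pd)]), unname(pd),
               tolerance = 1e-10)
})

test_that("UniFrac requires every taxon in the tree", {
  tr <- synth_tree(c("a", "b"), seed = 63)
  x <- cbind(s1 = c(1, 1), s2 = c(1, 0))
  rownames(x) <- c("a", "zz")
  expect_error(unifrac(x, tr), "missing from tree")
})

test_that("ANOSIM R is 1 under complete separation and matches vegan", {
  # two tight clusters far apart
  set.seed(64)
  y <- cbind(matrix(rnorm(12, 0, 0.1), 3), matrix(rnorm(12, 10, 0.1), 3))
  colnames(y) <- paste0("s", 1:8)
  rownames(y) <- paste0("t", 1:3)
  d <- as.matrix(dist(t(y)))
  g <- rep(c("a", "b"), each = 4)
  res <- anosim_test(d, g, permutations = 199, seed = 1)
  expect_equal(unname(res$statistic), 1)
  expect_lte(res$p, 0.05)
  van <- vegan::anosim(as.dist(d), g, permutations = 99)
  expect_equal(unname(res$statistic), unname(van$statistic), tolerance = 1e-12)
})

test_that("ANOSIM/PERMANOVA p-values match exhaustive enumeration at n = 6", {
  x <- random_table(12, 6, seed = 65)
  d <- bray_curtis(x)
  g <- rep(c("a", "b"), each = 3)
  res_a <- anosim_test(d, g, permutations = 999, seed = 2)
  res_p <- permanova_test(d, g, permutations = 999, seed = 3)
  pr <- commfba:::.pair_index(6)
  r <- rank(d[cbind(pr$i, pr$j)])
  stat_a <- function(gg) {
    w <- gg[pr$i] == gg[pr$j]
    (mean(r[!w]) - mean(r[w])) / (6 * 5 / 4)
  }
  d2 <- d[cbind(pr$i, pr$j)]^2
  sst <- sum(d2) / 6
  stat_f <- function(gg) {
    w <- gg[pr$i] == gg[pr$j]
    ssw <- sum(tapply(d2[w], gg[pr$i][w], sum) / 3)
    ((sst - ssw) / 1) / (ssw / 4)
  }
  ex_a <- enumerate_labels(6, 3, stat_a)
  ex_f <- enumerate_labels(6, 3, stat_f)
  p_ex_a <- mean(ex_a >= stat_a(factor(g)) - 1e-12)
  p_ex_f <- mean(ex_f >= stat_f(factor(g)) - 1e-12)
  se <- function(p) sqrt(p * (1 - p) / 999)
  expect_lt(abs(res_a$p - p_ex_a), 3 * se(p_ex_a) + 1e-3)
  expect_lt(abs(res_p$p - p_ex_f), 3 * se(p_ex_f) + 1e-3)
})

test_that("PERMANOVA statistics match vegan::adonis2 and classical ANOVA", {
  x <- random_table(20, 10, seed = 66)
  d <- bray_curtis(x)
  g <- rep(c("a", "b"), each = 5)
  res <- permanova_test(d, g, permutations = 499, seed = 4)
  ad <- vegan::adonis2(as.dist(d) ~ g, permutations = 99)
  expect_equal(unname(res$statistic), ad$F[1], tolerance = 1e-10)
  expect_equal(res$R2, ad$R2[1], tolerance = 1e-10)
  # univariate Euclidean distances: pseudo-F equals the one-way ANOVA F
  set.seed(67)
  y <- rnorm(10, mean = rep(c(0, 1), each = 5))
  de <- as.matrix(dist(y))
  res_e <- permanova_test(de, g, permutations = 99, seed = 5)
  f_classic <- summary(aov(y ~ factor(g)))[[1]]$`F value`[1]
  expect_equal(unname(res_e$statistic), f_classic, tolerance = 1e-10)
})

test_that("permutation tests are invariant to relabeling but only ANOSIM to distance shifts", {
  x <- random_table(15, 8, seed = 68)
  d <- bray_curtis(x)
  g1 <- rep(c("a", "b"), each = 4)
  g2 <- rep(c("PD", "control"), each = 4)
  expect_equal(anosim_test(d, g1, 199, seed = 6)$p,
               anosim_test(d, g2, 199, seed = 6)$p)
  expect_equal(permanova_test(d, g1, 199, seed = 6)$p,
               permanova_test(d, g2, 199, seed = 6)$p)
  dsh <- d + 0.5
  diag(dsh) <- 0
  expect_equal(anosim_test(dsh, g1, 199, seed = 7)$statistic,
               anosim_test(d, g1, 199, seed = 7)$statistic)
  expect_false(isTRUE(all.equal(permanova_test(dsh, g1, 199, seed = 7)$statistic,
                                permanova_test(d, g1, 199, seed = 7)$statistic)))
})

test_that("group preconditions are enforced", {
  d <- bray_curtis(random_table(10, 5, seed = 69))
  expect_error(anosim_test(d, c("a", "a", "a", "a", "b"), permutations = 99),
               "at least two samples")
  expect_error(anosim_test(d, rep("a", 5), 99), "at least two groups")
  expect_error(permanova_test(d, c("a", "a", "a", "a", "b"), 99),
               "at least two samples")
})

test_that("Spearman correlations recover monotone pairs with BH adjustment", {
  X <- rbind(up = 1:8, down = 8:1, flat = rep(1, 8))
  Y <- rbind(y1 = (1:8)^2)
  out <- spearman_fdr(X, Y)
  expect_equal(out$rho[out$var_x == "up"], 1)
  expect_equal(out$rho[out$var_x == "down"], -1)
  expect_true(is.na(out$rho[out$var_x == "flat"]))
  expect_true(all(out$p_adj >= out$p, na.rm = TRUE))
})
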