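test_that("H statistic matches hand-worked values and kruskal.test", {
  expect_equal(kruskal_wallis_statistic(c(1.2, 3.4, 5.6, 7.8),
                                        c("a", "a", "b", "b")), 2.4)
  expect_equal(kruskal_wallis_statistic(c(1, 1, 2, 2, 3, 3),
                                        c("a", "a", "a", "b", "b", "b")),
               10 / 3, tolerance = 1e-12)
  set.seed(7)
  for (i in 1:20) {
    v <- sample(1:8, 15, replace = TRUE)  # heavy ties
    g <- sample(c("x", "y", "z"), 15, replace = TRUE)
    if (length(unique(g)) < 2) next
    expect_equal(kruskal_wallis_statistic(v, g),
                 unname(kruskal.test(v, factor(g))$statistic),
                 tolerance = 1e-12)
  }
  # all-identical values: guarded H = 0
  expect_equal(kruskal_wallis_statistic(rep(2, 6), rep(c("a", "b"), 3)), 0)
  # two singleton groups still computable
  expect_true(is.finite(kruskal_wallis_statistic(c(1, 2), c("a", "b"))))
})

test_that("empirical p has the add-one floor and seed determinism", {
  set.seed(1)
  v <- c(rnorm(10), rnorm(10) + 50)  # overwhelming separation
  g <- rep(c("a", "b"), each = 10)
  r <- permutation_test(v, g, n_perm = 2000, seed = 3)
  expect_equal(r$p_empirical, 1 / 2001)
  r2 <- permutation_test(v, g, n_perm = 2000, seed = 3)
  expect_identical(r$p_empirical, r2$p_empirical)
})

test_that("empirical p agrees with full enumeration on a 6-sample design", {
  set.seed(5)
  for (i in 1:3) {
    v <- rnorm(6)
    g <- rep(c("a", "b"), each = 3)
    exact <- oracle_perm_kw_exact(v, g)
    r <- permutation_test(v, g, n_perm = 2000, seed = 10 + i)
    expect_lt(abs(r$p_empirical - exact), 2 / sqrt(2000))
  }
})

test_that("type-I error is controlled under a simulated null", {
  set.seed(99)
  alpha <- 0.05
  n_rep <- 500
  rejections <- 0
  for (b in seq_len(n_rep)) {
    v <- rnorm(24)
    g <- rep(c("a", "b", "c"), 8)
    r <- permutation_test(v, g, n_perm = 200, seed = b)
    if (r$p_empirical <= alpha) rejections <- rejections + 1
  }
  rate <- rejections / n_rep
  ci <- 2.576 * sqrt(alpha * (1 - alpha) / n_rep)
  expect_lt(abs(rate - alpha), ci)
})

test_that("empirical p is valid across an alpha grid", {
  set.seed(123)
  pvals <- replicate(300, {
    v <- rnorm(12)
    g <- rep(c("a", "b"), 6)
    permutation_test(v, g, n_perm = 99,
                     seed = sample.int(1e6, 1))$p_empirical
  })
  for (alpha in c(0.01, 0.05, 0.1, 0.2)) {
    eps <- 2.576 * sqrt(alpha * (1 - alpha) / 300)
    expect_lte(mean(pvals <= alpha), alpha + eps)
  }
})

test_that("stratified permutations preserve per-stratum group counts", {
  set.seed(6)
  v <- rnorm(20)
  g <- rep(c("a", "b"), 10)
  s <- rep(c("s1", "s2"), each = 10)
  r <- permutation_test(v, g, "stratified", strata = s, n_perm = 300,
                        seed = 2)
  expect_s3_class(r, "association_result")
  expect_identical(r$variant, "stratified")
  # a stratum-confounded shift is nullified by within-stratum permutation
  v_conf <- rnorm(20) + ifelse(s == "s1", 0, 5)
  g_conf <- ifelse(s == "s1", "a", "b")  # group == stratum
  expect_error(permutation_test(v_conf, g_conf, "stratified",
                                strata = s, n_perm = 10, seed = 1),
               NA)
})

test_that("adjusted variant with no covariates equals the plain variant", {
  set.seed(8)
  v <- rnorm(18)
  g <- rep(c("a", "b", "c"), 6)
  p1 <- permutation_test(v, g, "plain", n_perm = 500, seed = 11)
  p2 <- permutation_test(v, g, "adjusted", adjust = NULL, n_perm = 500,
                         seed = 11)
  p3 <- permutation_test(v, g, "adjusted",
                         adjust = data.frame()[seq_along(v), , drop = FALSE],
                         n_perm = 500, seed = 11)
  expect_identical(p1$p_empirical, p2$p_empirical)
  expect_identical(p1$p_empirical, p3$p_empirical)
  expect_identical(p1$statistic, p2$statistic)
})

test_that("Freedman-Lane adjustment absorbs a nuisance covariate", {
  set.seed(31)
  n <- 60
  nuisance <- rep(c("u", "v"), each = n / 2)
  g <- sample(c("a", "b"), n, replace = TRUE)
  v <- rnorm(n) + ifelse(nuisance == "u", 0, 3)  # effect only via nuisance
  r <- permutation_test(v, g, "adjusted",
                        adjust = data.frame(nu = nuisance),
                        n_perm = 500, seed = 9)
  expect_gt(r$p_empirical, 0.01)
})

test_that("subset mask and level checks behave", {
  v <- rnorm(10)
  g <- c(rep("a", 5), rep("b", 5))
  keep <- c(rep(TRUE, 5), rep(FALSE, 5))
  expect_error(permutation_test(v, g, include = keep), "2 group levels")
  expect_error(permutation_test(v, g, n_perm = 0), "n_perm")
  r <- permutation_test(v, g, include = rep(TRUE, 10), n_perm = 50, seed = 1)
  expect_identical(r$n_used, 10L)
})

test_that("the panel runs every signature x variant cell", {
  W0 <- simulate_signatures(3, seed = 5)
  sim <- simulate_catalog(W0, 30, mutations_mean = 500, seed = 44)
  ex <- estimate_exposures(sim$catalog, W0)
  set.seed(12)
  cov <- data.frame(sample_id = colnames(ex$percent),
                    meno = sample(c("pre", "post"), 30, TRUE),
                    subtype = sample(c("LumA", "TN"), 30, TRUE),
                    src = sample(c("A", "B"), 30, TRUE),
                    is_pre = TRUE)
  variants <- list(
    menopausal = list(group = "meno"),
    subtype = list(group = "subtype"),
    meno_by_subtype = list(group = "meno", variant = "stratified",
                           strata = "subtype"),
    meno_adj_subtype = list(group = "meno", variant = "adjusted",
                            adjust = "subtype"),
    source_in_pre = list(group = "src", adjust = "subtype",
                         variant = "adjusted", include = "is_pre"))
  res <- run_panel(ex, cov, variants, n_perm = 99, seed = 7)
  expect_identical(nrow(res), 15L)
  expect_true(all(res$p_empirical >= 1 / 100 & res$p_empirical <= 1))
  expect_error(run_panel(ex, cov[-1, ], variants, n_perm = 9, seed = 1),
               "absent")
})

test_that("planted group shifts are detected, constants are not", {
  W0 <- simulate_signatures(2, seed = 3)
  n <- 60
  set.seed(77)
  g <- rep(c("a", "b"), each = n / 2)
  e1 <- pmin(pmax(rbeta(n, 2, 2) + ifelse(g == "a", 0, 0.3), 0), 1)
  E <- rbind(e1, 1 - e1)
  V <- sapply(seq_len(n), function(j)
    rmultinom(1, 800, W0 %*% E[, j, drop = FALSE]))
  rownames(V) <- trinuc_channels(); colnames(V) <- paste0("s", seq_len(n))
  ex <- estimate_exposures(V, W0)
  r <- permutation_test(ex$percent[1, ], g, n_perm = 500, seed = 5)
  expect_lt(r$p_empirical, 0.05)
  r0 <- permutation_test(rep(5, n), g, n_perm = 500, seed = 5)
  expect_gt(r0$p_empirical, 0.5)
})
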