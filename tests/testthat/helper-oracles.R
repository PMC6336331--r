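# Independent oracles used across tests: direct enumerations kept separate
# from the implementation paths they check.

# Two-sided Fisher p for a 2x2 table by explicit hypergeometric enumeration
# over all tables with the observed margins ("probability at most observed",
# relative tolerance against float ties).
oracle_fisher_2x2 <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  if (m == 0 || n == 0 || k == 0 || (c + d) == 0) return(1)
  x <- max(0, k - n):min(k, m)
  probs <- dhyper(x, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact permutation p of the Kruskal-Wallis statistic by full enumeration of
# all label arrangements (small n only); proportion of arrangements with
# H >= observed, identity included.
oracle_perm_kw_exact <- function(values, groups) {
  n <- length(values)
  perms <- all_permutations(n)
  h_obs <- sigcohort::kruskal_wallis_statistic(values, groups)
  h_all <- apply(perms, 1, function(p)
    sigcohort::kruskal_wallis_statistic(values[p], groups))
  mean(h_all >= h_obs)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) cbind(i, sub + (sub >= i))))
}

# Monte-Carlo oracle for the over-representation tail probability: draw the
# query without replacement from the universe and count overlaps >= k.
oracle_ora_resample <- function(N, K, n, k, reps = 1e5, seed = 1) {
  set.seed(seed)
  hits <- rhyper(reps, K, N - K, n)
  mean(hits >= k)
}

rc <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  unname(comp[x])
}

small_catalog_sim <- function(k = 3, n_samples = 20, mean_mut = 800,
                              seed = 5) {
  W <- sigcohort::simulate_signatures(k, seed = seed)
  sim <- sigcohort::simulate_catalog(W, n_samples,
                                     mutations_mean = mean_mut,
                                     alpha = 0.3, seed = seed + 1)
  list(W = W, sim = sim)
}
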