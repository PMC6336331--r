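#' Non-negative matrix factorization by multiplicative KL updates
#'
#' Factorizes a non-negative catalog `V` (channels x samples) as `W %*% H`
#' by minimizing the generalized Kullback-Leibler divergence
#' `D(V || WH) = sum(V * log(V / WH) - V + WH)` with Brunet-style
#' multiplicative updates. The objective is non-increasing at every
#' iteration; iteration stops when the relative objective change falls below
#' `tol` or after `max_iter` iterations. On return `W` is column-normalized
#' (columns sum to 1) with the scale moved into `H`.
#'
#' @param V Non-negative matrix (or a `trinuc_catalog`).
#' @param rank Number of signatures; must be below the number of samples.
#' @param seed Integer seed for the uniform random initialization.
#' @param max_iter,tol Stopping controls.
#' @param objective `"kl"` (default) or `"frobenius"`.
#' @return List with `W` (column-stochastic), `H`, `objective` (final),
#'   `trace` (objective per recorded iteration), `iterations`, `converged`.
#' @export
nmf_factorize <- function(V, rank, seed = 1L, max_iter = 2000L, tol = 1e-6,
                          objective = c("kl", "frobenius")) {
  if (inherits(V, "trinuc_catalog")) V <- V$counts
  V <- as.matrix(V) * 1.0
  objective <- match.arg(objective)
  if (any(V < 0)) stop("V must be non-negative")
  n <- nrow(V); s <- ncol(V)
  if (rank >= s) stop("rank must be smaller than the number of samples")
  zero_col <- colSums(V) == 0
  if (any(zero_col)) {
    stop("all-zero sample column(s): ",
         paste(colnames(V)[zero_col], collapse = ", "),
         "; drop them before factorizing")
  }
  eps <- 1e-12
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  scale <- sqrt(mean(V) / rank)
  W <- matrix(stats::runif(n * rank), n, rank) * scale
  H <- matrix(stats::runif(rank * s), rank, s) * scale
  kl_obj <- function(W, H) {
    WH <- W %*% H + eps
    pos <- V > 0
    sum(V[pos] * log(V[pos] / WH[pos])) - sum(V) + sum(WH)
  }
  fr_obj <- function(W, H) 0.5 * sum((V - W %*% H)^2)
  obj_fun <- if (objective == "kl") kl_obj else fr_obj
  trace <- numeric(0)
  prev <- obj_fun(W, H)
  trace <- prev
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (objective == "kl") {
      WH <- W %*% H + eps
      H <- H * (crossprod(W, V / WH)) / (colSums(W) + eps)
      WH <- W %*% H + eps
      W <- W * ((V / WH) %*% t(H)) / rep(rowSums(H) + eps, each = n)
    } else {
      H <- H * crossprod(W, V) / (crossprod(W) %*% H + eps)
      W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    }
    cur <- obj_fun(W, H)
    trace <- c(trace, cur)
    if (is.finite(prev) && abs(prev - cur) <= tol * max(abs(prev), eps)) {
      converged <- TRUE
      prev <- cur
      break
    }
    prev <- cur
  }
  cs <- colSums(W)
  cs[cs == 0] <- 1
  W <- sweep(W, 2, cs, "/")
  H <- H * cs
  dimnames(W) <- list(rownames(V), paste0("S", seq_len(rank)))
  dimnames(H) <- list(paste0("S", seq_len(rank)), colnames(V))
  list(W = W, H = H, objective = prev, trace = trace,
       iterations = iter, converged = converged)
}

#' Multi-start NMF with consensus clustering
#'
#' Runs `n_runs` random restarts at a fixed rank. Each run clusters samples
#' by the signature with maximal contribution; the consensus matrix is the
#' mean connectivity matrix over runs, and its stability is summarized by the
#' cophenetic correlation coefficient between the consensus-derived distances
#' (1 - consensus) and the cophenetic distances of their average-linkage
#' hierarchical clustering.
#'
#' @param V Catalog matrix or `trinuc_catalog`.
#' @param rank Factorization rank.
#' @param n_runs Number of random restarts (>= 2).
#' @param seed Root seed; run r uses `seed + r`.
#' @param ... Passed to [nmf_factorize()].
#' @return List of class `nmf_consensus` with `rank`, `consensus`,
#'   `cophenetic`, `best_run` (the factorization with lowest objective), and
#'   `objectives`.
#' @export
run_multistart <- function(V, rank, n_runs = 50L, seed = 1L, ...) {
  if (inherits(V, "trinuc_catalog")) V <- V$counts
  stopifnot(n_runs >= 2)
  s <- ncol(V)
  consensus <- matrix(0, s, s)
  best <- NULL
  objectives <- numeric(n_runs)
  n_clusters_best <- NA_integer_
  for (r in seq_len(n_runs)) {
    fit <- nmf_factorize(V, rank, seed = seed + r, ...)
    objectives[r] <- fit$objective
    cl <- apply(fit$H, 2, which.max)
    conn <- outer(cl, cl, "==") * 1
    consensus <- consensus + conn
    if (is.null(best) || fit$objective < best$objective) {
      best <- fit
      n_clusters_best <- length(unique(cl))
    }
  }
  consensus <- consensus / n_runs
  diag(consensus) <- 1
  structure(list(rank = rank, consensus = consensus,
                 cophenetic = cophenetic_coefficient(consensus),
                 best_run = best, objectives = objectives,
                 n_clusters_best = n_clusters_best),
            class = "nmf_consensus")
}

#' Cophenetic correlation coefficient of a consensus matrix
#'
#' Pearson correlation between the distances `1 - consensus` and the
#' cophenetic distances from their average-linkage hierarchical clustering.
#' Degenerate consensus matrices with zero distance variance (all samples
#' always co-cluster, or rank 1) are perfectly stable: the coefficient is 1.
#'
#' @param consensus Symmetric S x S matrix in `[0, 1]` with unit diagonal.
#' @return Coefficient in `[-1, 1]`.
#' @export
cophenetic_coefficient <- function(consensus) {
  d <- stats::as.dist(1 - consensus)
  if (length(d) < 2 || stats::sd(d) == 0) return(1)
  hc <- stats::hclust(d, method = "average")
  cd <- stats::cophenetic(hc)
  if (stats::sd(cd) == 0) return(1)
  stats::cor(d, cd)
}

#' Choose the factorization rank by consensus stability
#'
#' Runs [run_multistart()] across a range of ranks and returns the rank with
#' the highest cophenetic coefficient. Exact ties are resolved by effective
#' rank: among the tied ranks, the largest *saturated* one wins, where a rank
#' is saturated when every signature of its best factorization dominates at
#' least one sample. When consensus clustering stays perfectly reproducible
#' as the rank grows, the larger rank exposes finer structure that is still
#' stable (the usual reading of consensus stability curves); a tied rank
#' whose extra signatures dominate no sample is redundant, so degenerate
#' catalogs (e.g. identical duplicate samples) still resolve to rank 1. If no
#' tied rank is saturated the smallest wins.
#'
#' @param V Catalog matrix or `trinuc_catalog`.
#' @param rank_range Integer vector of candidate ranks.
#' @param n_runs Restarts per rank.
#' @param seed Root seed; rank k uses `seed + 1000 * k` as its root.
#' @param ... Passed to [nmf_factorize()].
#' @return List with `rank` (chosen), `curve` (data frame rank, cophenetic,
#'   best_objective), and `fits` (named list of `nmf_consensus`).
#' @export
select_rank <- function(V, rank_range, n_runs = 50L, seed = 1L, ...) {
  if (!length(rank_range)) stop("empty rank range")
  rank_range <- sort(unique(as.integer(rank_range)))
  fits <- lapply(rank_range, function(k) {
    run_multistart(V, k, n_runs = n_runs, seed = seed + 1000L * k, ...)
  })
  names(fits) <- rank_range
  coph <- vapply(fits, `[[`, numeric(1), "cophenetic")
  curve <- data.frame(rank = rank_range, cophenetic = coph,
                      best_objective = vapply(fits, function(f)
                        f$best_run$objective, numeric(1)))
  tied <- which(coph == max(coph))
  saturated <- vapply(fits, function(f)
    f$n_clusters_best == f$rank, logical(1))
  chosen <- if (any(saturated[tied])) {
    max(rank_range[tied][saturated[tied]])
  } else {
    min(rank_range[tied])
  }
  list(rank = chosen, curve = curve, fits = fits)
}
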