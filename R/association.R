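#' Tie-corrected Kruskal-Wallis H statistic
#'
#' `H = [12 / (N (N + 1)) * sum(R_i^2 / n_i) - 3 (N + 1)] / C` with mid-ranks
#' and tie correction `C = 1 - sum(t^3 - t) / (N^3 - N)`. When all values are
#' identical (`C = 0`), H is 0 by convention.
#'
#' @param values Numeric vector.
#' @param groups Group labels (>= 2 non-empty groups).
#' @return The H statistic.
#' @export
#' @examples
#' kruskal_wallis_statistic(c(1.2, 3.4, 5.6, 7.8), c(1, 1, 2, 2))  # 2.4
kruskal_wallis_statistic <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(tabulate(groups) == 0)) stop("every group must be non-empty")
  r <- rank(values)
  .kw_from_ranks(r, groups, .tie_correction(values))
}

.tie_correction <- function(values) {
  n <- length(values)
  t <- table(values)
  1 - sum(t^3 - t) / (n^3 - n)
}

.kw_from_ranks <- function(r, groups, C) {
  n <- length(r)
  Ri <- tapply(r, groups, sum)
  ni <- tabulate(groups)
  h0 <- 12 / (n * (n + 1)) * sum(Ri^2 / ni) - 3 * (n + 1)
  if (C <= 0) return(0)
  h0 / C
}

#' Permutation Kruskal-Wallis test of a contribution vector
#'
#' Tests association between per-sample values (e.g. signature
#' contributions) and a categorical grouping by comparing the observed
#' tie-corrected H against its permutation distribution. Variants:
#' \describe{
#'   \item{plain}{values permuted freely across samples;}
#'   \item{stratified}{values permuted only within strata, so per-stratum
#'     group composition is preserved exactly;}
#'   \item{adjusted}{Freedman-Lane: values are regressed on the indicator
#'     design of the adjustment covariates, residuals are permuted and added
#'     back to the fitted values before recomputing H — with no adjustment
#'     covariates this reduces exactly to the plain variant.}
#' }
#' An optional logical `include` mask subsets the samples first. The
#' empirical p uses the add-one estimator
#' `p = (1 + #(H_perm >= H_obs)) / (1 + n_perm)`, so `p >= 1/(n_perm + 1)`.
#'
#' @param values Per-sample numeric vector.
#' @param groups Grouping factor of interest.
#' @param variant `"plain"`, `"stratified"` or `"adjusted"`.
#' @param strata Stratification factor (stratified variant).
#' @param adjust Data frame (or vector) of categorical nuisance covariates
#'   (adjusted variant); `NULL` or zero columns means no adjustment.
#' @param include Optional logical subset mask.
#' @param n_perm Number of permutations (default 2000).
#' @param seed Integer seed; the same seed reproduces the same p exactly.
#' @return List of class `association_result`: `statistic`, `p_empirical`,
#'   `n_perm`, `variant`, `seed`, `n_used`.
#' @export
permutation_test <- function(values, groups,
                             variant = c("plain", "stratified", "adjusted"),
                             strata = NULL, adjust = NULL, include = NULL,
                             n_perm = 2000L, seed = 1L) {
  variant <- match.arg(variant)
  if (n_perm < 1) stop("n_perm must be at least 1")
  n0 <- length(values)
  if (!is.null(include)) {
    stopifnot(is.logical(include), length(include) == n0)
    keep <- include & !is.na(include)
  } else keep <- rep(TRUE, n0)
  values <- values[keep]
  groups <- droplevels(factor(groups[keep]))
  if (nlevels(groups) < 2) {
    stop("fewer than 2 group levels remain after subsetting")
  }
  if (variant == "stratified") {
    if (is.null(strata)) stop("stratified variant needs strata")
    strata <- droplevels(factor(strata[keep]))
    if (any(tabulate(strata) < 2)) {
      stop("every stratum must contain at least 2 samples")
    }
  }
  design <- NULL
  if (variant == "adjusted" && !is.null(adjust)) {
    adjust <- as.data.frame(adjust)[keep, , drop = FALSE]
    if (ncol(adjust) > 0) {
      adjust[] <- lapply(adjust, factor)
      design <- stats::model.matrix(~ ., data = adjust)
    }
  }
  n <- length(values)
  h_obs <- kruskal_wallis_statistic(values, groups)
  if (is.null(design)) {
    fitted <- rep(mean(values), n)
  } else {
    fit <- stats::lm.fit(design, values)
    fitted <- fit$fitted.values
  }
  resid <- values - fitted

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  h_perm <- numeric(n_perm)
  strata_idx <- if (variant == "stratified") split(seq_len(n), strata)
  # without adjustment covariates a permuted response is just a permutation
  # of the values, so ranks and tie correction can be precomputed
  plain_path <- is.null(design)
  r0 <- rank(values)
  C0 <- .tie_correction(values)
  for (b in seq_len(n_perm)) {
    idx <- if (variant == "stratified") {
      out <- integer(n)
      for (ix in strata_idx) out[ix] <- ix[sample.int(length(ix))]
      out
    } else sample.int(n)
    h_perm[b] <- if (plain_path) {
      .kw_from_ranks(r0[idx], groups, C0)
    } else {
      kruskal_wallis_statistic(fitted + resid[idx], groups)
    }
  }
  p <- (1 + sum(h_perm >= h_obs)) / (1 + n_perm)
  structure(list(statistic = h_obs, p_empirical = p, n_perm = n_perm,
                 variant = variant, seed = seed, n_used = n),
            class = "association_result")
}

#' Run the permutation panel over all signatures and test variants
#'
#' One permutation test per signature per requested variant; p-values are
#' reported without multiplicity adjustment.
#'
#' @param exposures `exposure_matrix` (or K x S matrix); rows are
#'   signatures, columns samples.
#' @param covariates Data frame with `sample_id` plus the columns named by
#'   the variant specs.
#' @param variants Named list of variant specifications, each a list with
#'   `group` (column name), `variant`, and optionally `strata`, `adjust`
#'   (character vector of column names), `include` (column name of a logical
#'   mask).
#' @param n_perm,seed Passed to [permutation_test()]; test t of signature k
#'   is seeded `seed + 97 * k + t` for reproducibility.
#' @return Data frame: signature, variant name, statistic, p_empirical,
#'   n_perm, seed.
#' @export
run_panel <- function(exposures, covariates, variants, n_perm = 2000L,
                      seed = 1L) {
  H <- if (inherits(exposures, "exposure_matrix")) exposures$percent
       else as.matrix(exposures)
  ids <- colnames(H)
  if (is.null(ids) || !("sample_id" %in% names(covariates))) {
    stop("exposures need sample column names and covariates a sample_id")
  }
  missing_ids <- setdiff(ids, covariates$sample_id)
  if (length(missing_ids)) {
    stop("sample id(s) absent from covariates: ",
         paste(missing_ids, collapse = ", "))
  }
  cov <- covariates[match(ids, covariates$sample_id), , drop = FALSE]
  res <- list()
  for (k in seq_len(nrow(H))) {
    for (t in seq_along(variants)) {
      v <- variants[[t]]
      r <- permutation_test(
        values = H[k, ],
        groups = cov[[v$group]],
        variant = if (is.null(v$variant)) "plain" else v$variant,
        strata = if (!is.null(v$strata)) cov[[v$strata]],
        adjust = if (!is.null(v$adjust)) cov[v$adjust],
        include = if (!is.null(v$include)) cov[[v$include]],
        n_perm = n_perm, seed = seed + 97L * k + t)
      res[[length(res) + 1L]] <- data.frame(
        signature = rownames(H)[k], variant = names(variants)[t],
        statistic = r$statistic, p_empirical = r$p_empirical,
        n_perm = r$n_perm, seed = r$seed, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}
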