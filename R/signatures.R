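#' Cosine similarity between two non-negative vectors
#'
#' @param u,v Numeric vectors of equal length; neither may be all-zero.
#' @return `dot(u, v) / (|u| |v|)`; in `[0, 1]` for non-negative inputs.
#' @export
#' @examples
#' cosine_similarity(c(1, 1, 0), c(1, 0, 1))  # 0.5
cosine_similarity <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for zero vectors")
  sum(u * v) / (nu * nv)
}

#' Match extracted signatures to a reference catalog
#'
#' For each extracted signature, reports the reference signature with maximal
#' cosine similarity (independent best hits, not a global assignment) and
#' flags matches below `threshold`.
#'
#' @param extracted Channels x K matrix of extracted signatures; rownames are
#'   channel labels.
#' @param reference Channels x R matrix of named reference signatures with
#'   identical rownames in identical order.
#' @param threshold Cosine below which a match is flagged unmatched.
#' @return Data frame: `signature`, `best_match`, `cosine`, `matched`.
#' @export
match_signatures <- function(extracted, reference, threshold = 0.75) {
  extracted <- as.matrix(extracted); reference <- as.matrix(reference)
  if (is.null(rownames(extracted)) || is.null(rownames(reference)) ||
      !identical(rownames(extracted), rownames(reference))) {
    stop("channel orders differ between extracted and reference matrices; ",
         "no silent reordering is done")
  }
  sim <- matrix(NA_real_, ncol(extracted), ncol(reference))
  for (i in seq_len(ncol(extracted)))
    for (j in seq_len(ncol(reference)))
      sim[i, j] <- cosine_similarity(extracted[, i], reference[, j])
  best <- apply(sim, 1, which.max)
  cos <- sim[cbind(seq_along(best), best)]
  data.frame(signature = colnames(extracted),
             best_match = colnames(reference)[best],
             cosine = cos,
             matched = cos >= threshold,
             stringsAsFactors = FALSE)
}

#' Optimal one-to-one column matching between two signature sets
#'
#' Exhaustive search over column permutations maximizing the total cosine
#' similarity; intended for simulation recovery checks at small K.
#'
#' @param A,B Channels x K matrices with equal K (K <= 8).
#' @return List with `perm` (column j of `B` matched to column `perm[j]` of
#'   `A`) and per-pair `cosines`.
#' @export
match_columns <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  k <- ncol(A)
  stopifnot(ncol(B) == k, k <= 8)
  sim <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    sim[i, j] <- cosine_similarity(A[, i], B[, j])
  perms <- .permutations(k)
  tot <- apply(perms, 1, function(p) sum(sim[cbind(p, seq_len(k))]))
  best <- perms[which.max(tot), ]
  list(perm = best, cosines = sim[cbind(best, seq_len(k))])
}

.permutations <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- .permutations(k - 1)
  out <- matrix(0L, 0, k)
  for (i in seq_len(k)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  out
}

#' Estimate per-sample signature exposures by non-negative least squares
#'
#' Each catalog column is regressed on the column-stochastic signature matrix
#' under non-negativity (Lawson-Hanson NNLS), which keeps contributions
#' well-defined for samples not used in training. Samples with zero mutations
#' get all-zero exposures and are flagged.
#'
#' @param V Catalog matrix (channels x samples) or `trinuc_catalog`.
#' @param W Channels x K column-stochastic signature matrix.
#' @return List of class `exposure_matrix` with `H` (K x S mutation counts
#'   attributed to each signature), `percent` (columns sum to 100, all-zero
#'   for empty samples), `zero_samples`.
#' @export
estimate_exposures <- function(V, W) {
  if (inherits(V, "trinuc_catalog")) V <- V$counts
  V <- as.matrix(V) * 1.0
  W <- as.matrix(W)
  stopifnot(nrow(V) == nrow(W))
  cs <- colSums(W)
  if (any(abs(cs - 1) > 1e-6)) stop("signature matrix must be column-stochastic")
  k <- ncol(W); s <- ncol(V)
  H <- matrix(0, k, s, dimnames = list(colnames(W), colnames(V)))
  zero <- colSums(V) == 0
  for (j in which(!zero)) {
    H[, j] <- pracma::lsqnonneg(W, V[, j])$x
  }
  tot <- colSums(H)
  percent <- H
  pos <- tot > 0
  percent[, pos] <- sweep(H[, pos, drop = FALSE], 2, tot[pos], "/") * 100
  percent[, !pos] <- 0
  structure(list(H = H, percent = percent, zero_samples = colnames(V)[zero]),
            class = "exposure_matrix")
}
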