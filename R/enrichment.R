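#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then gene symbols, tab-separated.
#' Symbols are uppercased for matching; empty sets are rejected.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors with a `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fields, length, integer(1)) < 3
  if (any(bad)) stop("GMT line(s) without genes: ", paste(which(bad), collapse = ", "))
  sets <- lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  names(sets) <- vapply(fields, `[[`, character(1), 1)
  attr(sets, "description") <- vapply(fields, `[[`, character(1), 2)
  sets
}

#' Gene-set over-representation analysis (hypergeometric)
#'
#' For each set, the upper hypergeometric tail probability of observing at
#' least the seen overlap between the query list and the set within the
#' universe. Sets overlapping the query in fewer than `min_overlap` genes are
#' removed before Benjamini-Hochberg adjustment over the surviving sets.
#' Query genes outside the universe are reported and dropped.
#'
#' @param query Character vector of gene symbols of interest.
#' @param sets Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Background gene symbols; defaults to the union of all set
#'   members.
#' @param min_overlap Minimum query/set overlap for a set to be scored.
#' @param q_max Report filter on adjusted q (use `1` to keep everything).
#' @return List with `results` (data frame: set, set_size, overlap, p, q,
#'   overlap_genes), `n_query_used`, `dropped_query`.
#' @export
ora_hypergeometric <- function(query, sets, universe = NULL,
                               min_overlap = 3, q_max = 0.05) {
  if (!length(query)) stop("empty query gene list")
  query <- unique(toupper(query))
  sets <- lapply(sets, toupper)
  if (any(!vapply(sets, length, integer(1)))) stop("empty gene set supplied")
  if (is.null(universe)) universe <- unique(unlist(sets))
  universe <- unique(toupper(universe))
  if (!length(universe)) stop("empty universe")
  dropped <- setdiff(query, universe)
  query <- intersect(query, universe)
  if (!length(query)) stop("no query genes in the universe")
  N <- length(universe); n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    su <- intersect(sets[[nm]], universe)
    ov <- intersect(query, su)
    k <- length(ov); K <- length(su)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, set_size = K, overlap = k, p = p,
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[res$overlap >= min_overlap, , drop = FALSE]
  if (nrow(res)) {
    res$q <- bh_adjust(res$p)
    res <- res[order(res$p), , drop = FALSE]
    if (q_max < 1) res <- res[res$q < q_max, , drop = FALSE]
  } else {
    res$q <- numeric(0)
  }
  rownames(res) <- NULL
  list(results = res, n_query_used = n, dropped_query = dropped,
       universe_size = N)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}
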