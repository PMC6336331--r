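#' Marker-positivity thresholds for IHC calls
#'
#' Defaults follow the St Gallen convention used for clinical breast-cancer
#' subtyping: ER and PR are positive when more than 1% of cells stain, Ki67
#' when more than 14% stain. Inequalities are strict at the boundary.
#'
#' @param er_min,pr_min,ki67_min Positivity thresholds in percent of stained
#'   cells; a marker is positive when its staining score is strictly greater.
#' @return A list of class `ihc_thresholds`.
#' @export
ihc_thresholds <- function(er_min = 1, pr_min = 1, ki67_min = 14) {
  stopifnot(er_min >= 0, er_min <= 100, pr_min >= 0, pr_min <= 100,
            ki67_min >= 0, ki67_min <= 100)
  structure(list(er_min = er_min, pr_min = pr_min, ki67_min = ki67_min),
            class = "ihc_thresholds")
}

.check_pct <- function(x, what) {
  bad <- !is.na(x) & (x < 0 | x > 100)
  if (any(bad)) stop(what, " percentages must lie in [0, 100]")
}

#' Call per-marker positivity from IHC staining scores
#'
#' @param ihc Data frame with one row per case and columns `case_id`,
#'   `er_pct`, `pr_pct`, `her2` (one of `"negative"`, `"equivocal"`,
#'   `"positive"`), `ki67_pct` (may be `NA`), and optionally `egfr_pos`,
#'   `ck56_pos` (logical, may be `NA`).
#' @param thresholds An [ihc_thresholds()] object.
#' @return The input with logical columns `er_pos`, `pr_pos`, `ki67_pos`
#'   appended (`ki67_pos` is `NA` where `ki67_pct` is missing).
#' @export
#' @examples
#' ihc <- data.frame(case_id = "c1", er_pct = 1, pr_pct = 50,
#'                   her2 = "negative", ki67_pct = 14)
#' call_positivity(ihc)[, c("er_pos", "pr_pos", "ki67_pos")]
call_positivity <- function(ihc, thresholds = ihc_thresholds()) {
  stopifnot(is.data.frame(ihc),
            all(c("case_id", "er_pct", "pr_pct", "her2") %in% names(ihc)))
  .check_pct(ihc$er_pct, "ER"); .check_pct(ihc$pr_pct, "PR")
  her2 <- as.character(ihc$her2)
  bad <- !is.na(her2) & !(her2 %in% c("negative", "equivocal", "positive"))
  if (any(bad)) stop("her2 must be one of negative/equivocal/positive")
  ihc$er_pos <- ihc$er_pct > thresholds$er_min
  ihc$pr_pos <- ihc$pr_pct > thresholds$pr_min
  if (!is.null(ihc$ki67_pct)) {
    .check_pct(ihc$ki67_pct, "Ki67")
    ihc$ki67_pos <- ihc$ki67_pct > thresholds$ki67_min
  } else {
    ihc$ki67_pos <- NA
  }
  ihc
}

#' Assign IHC subtypes from marker positivity
#'
#' Applies the clinical ER/PR/HER2 rules: luminal A is ER+/HER2-, luminal B
#' ER+/HER2+, HER2-enriched ER-/HER2+, triple-negative ER-/PR-/HER2-.
#' HER2-equivocal cases without confirmatory FISH, and residual combinations
#' such as ER-/PR+/HER2-, are Undetermined. Triple-negative tumors are
#' additionally labeled basal when EGFR and/or CK5/6 stain positive.
#'
#' @param ihc Data frame as for [call_positivity()]; a `fish_confirmed`
#'   logical column resolves equivocal HER2 (treated as positive when
#'   confirmed), missing/FALSE leaves those cases Undetermined.
#' @param thresholds An [ihc_thresholds()] object.
#' @return Data frame with columns `case_id`, `subtype` (factor over
#'   LuminalA, LuminalB, HER2enriched, TripleNegative, Undetermined), `basal`
#'   (`"basal"`/`"non-basal"` for triple-negatives, `"not-applicable"`
#'   otherwise) and `ki67_pos`.
#' @export
assign_subtype <- function(ihc, thresholds = ihc_thresholds()) {
  calls <- call_positivity(ihc, thresholds)
  her2 <- as.character(calls$her2)
  fish <- if (!is.null(calls$fish_confirmed)) {
    !is.na(calls$fish_confirmed) & calls$fish_confirmed
  } else rep(FALSE, nrow(calls))
  n <- nrow(calls)
  subtype <- rep("Undetermined", n)
  her2_pos <- her2 == "positive" | (her2 == "equivocal" & fish)
  her2_neg <- her2 == "negative"
  unresolved <- her2 == "equivocal" & !fish
  er <- calls$er_pos
  pr <- calls$pr_pos
  subtype[!unresolved & er & her2_neg] <- "LuminalA"
  subtype[!unresolved & er & her2_pos] <- "LuminalB"
  subtype[!unresolved & !er & her2_pos] <- "HER2enriched"
  subtype[!unresolved & !er & !pr & her2_neg] <- "TripleNegative"
  egfr <- if (!is.null(calls$egfr_pos)) calls$egfr_pos else rep(NA, n)
  ck56 <- if (!is.null(calls$ck56_pos)) calls$ck56_pos else rep(NA, n)
  basal_pos <- (!is.na(egfr) & egfr) | (!is.na(ck56) & ck56)
  basal <- rep("not-applicable", n)
  tn <- subtype == "TripleNegative"
  basal[tn] <- ifelse(basal_pos[tn], "basal", "non-basal")
  lev <- c("LuminalA", "LuminalB", "HER2enriched", "TripleNegative",
           "Undetermined")
  data.frame(case_id = calls$case_id,
             subtype = factor(subtype, levels = lev),
             basal = basal,
             ki67_pos = calls$ki67_pos,
             stringsAsFactors = FALSE)
}

#' Cross-tabulate two categorical case variables
#'
#' Rows with a missing value in either variable are dropped; the number of
#' dropped rows is reported in the result.
#'
#' @param calls Data frame of per-case calls.
#' @param row_var,col_var Column names to tabulate.
#' @return List with `counts` (integer matrix with dimnames), `n_dropped`.
#' @export
tabulate_calls <- function(calls, row_var, col_var) {
  stopifnot(row_var %in% names(calls), col_var %in% names(calls))
  r <- calls[[row_var]]
  c_ <- calls[[col_var]]
  keep <- !is.na(r) & !is.na(c_)
  n_dropped <- sum(!keep)
  if (!any(keep)) stop("no complete cases to tabulate")
  counts <- table(droplevels(factor(r[keep])), droplevels(factor(c_[keep])),
                  dnn = c(row_var, col_var))
  list(counts = unclass(as.matrix(counts)), n_dropped = n_dropped)
}

.check_table <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("contingency table must hold non-negative integers")
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Two-sided p-value under the "probability at most that of the observed
#' table" rule over the hypergeometric distribution with fixed margins (the
#' convention of mainstream statistics environments). A table with a zero
#' margin has p = 1 by convention.
#'
#' @param counts 2x2 matrix of non-negative integers.
#' @return The two-sided p-value.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(96, 47, 38, 1), 2, 2))
fisher_exact_2x2 <- function(counts) {
  counts <- .check_table(counts)
  stopifnot(nrow(counts) == 2, ncol(counts) == 2)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) return(1)
  stats::fisher.test(counts)$p.value
}

#' Fisher exact test for an r x c table (Freeman-Halton)
#'
#' Small tables (total count at or below `enum_cap`) are tested exactly by
#' enumeration of all tables with the observed margins; larger tables fall
#' back to a Monte-Carlo estimate over `mc_reps` margin-preserving samples
#' when `mc_reps` is given, and error otherwise.
#'
#' @param counts r x c matrix of non-negative integers.
#' @param enum_cap Largest total count handled by full enumeration.
#' @param mc_reps Number of Monte-Carlo table samples for large tables.
#' @param seed Seed for the Monte-Carlo path.
#' @return List with `p.value` and `method` (`"enumeration"` or
#'   `"monte-carlo"`).
#' @export
fisher_exact_rxc <- function(counts, enum_cap = 300, mc_reps = NULL,
                             seed = 1L) {
  counts <- .check_table(counts)
  stopifnot(nrow(counts) >= 2, ncol(counts) >= 2)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    return(list(p.value = 1, method = "enumeration"))
  }
  if (sum(counts) <= enum_cap) {
    p <- stats::fisher.test(counts, workspace = 2e7)$p.value
    return(list(p.value = p, method = "enumeration"))
  }
  if (is.null(mc_reps)) {
    stop("table total ", sum(counts), " exceeds the enumeration cap (",
         enum_cap, "); supply mc_reps for a Monte-Carlo estimate")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  p <- stats::fisher.test(counts, simulate.p.value = TRUE,
                          B = mc_reps)$p.value
  list(p.value = p, method = "monte-carlo")
}

# save/restore the global RNG state so seeded helpers do not perturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
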