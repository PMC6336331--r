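#' Somatic-mutation filter settings
#'
#' Defaults mirror the filtering used for FFPE tumor duplicates sequenced
#' alongside matched blood: a variant must be called in both tumor duplicates
#' with a variant allele fraction of at least 4% in each, must be absent from
#' every blood sample in the cohort, must not be a known polymorphism
#' (population allele frequency above 0.001), and must belong to a
#' potentially deleterious effect class.
#'
#' @param vaf_min Minimum variant allele fraction per tumor duplicate.
#' @param popaf_max Variants with population allele frequency strictly above
#'   this are removed as known SNPs.
#' @param require_both_duplicates Demand presence in both tumor duplicates.
#' @param exclude_in_blood Remove variants seen in any blood sample of the
#'   cohort.
#' @param effects_kept Effect classes retained.
#' @return List of class `somatic_filter_config`.
#' @export
somatic_filter_config <- function(vaf_min = 0.04,
                                  popaf_max = 0.001,
                                  require_both_duplicates = TRUE,
                                  exclude_in_blood = TRUE,
                                  effects_kept = c("splice", "indel-coding",
                                                   "nonsense", "stop-loss",
                                                   "non-synonymous")) {
  stopifnot(vaf_min >= 0, vaf_min <= 1, popaf_max >= 0, popaf_max <= 1)
  structure(list(vaf_min = vaf_min, popaf_max = popaf_max,
                 require_both_duplicates = require_both_duplicates,
                 exclude_in_blood = exclude_in_blood,
                 effects_kept = effects_kept),
            class = "somatic_filter_config")
}

.variant_key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")

#' Filter raw variant calls down to somatic mutations
#'
#' @param calls Data frame of mutation records with columns `sample_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `gene`, `effect`, `vaf`, `source` (one of
#'   `tumor_dup1`, `tumor_dup2`, `blood`).
#' @param cfg A [somatic_filter_config()].
#' @param popaf Optional population allele-frequency table with columns
#'   `chrom`, `pos`, `ref`, `alt`, `af`.
#' @return One record per case per retained variant (taken from the first
#'   tumor duplicate), as a data frame.
#' @export
filter_somatic <- function(calls, cfg = somatic_filter_config(),
                           popaf = NULL) {
  req <- c("sample_id", "chrom", "pos", "ref", "alt", "effect", "vaf",
           "source")
  stopifnot(is.data.frame(calls), all(req %in% names(calls)))
  bad_src <- !(calls$source %in% c("tumor_dup1", "tumor_dup2", "blood"))
  if (any(bad_src)) stop("unknown source label(s): ",
                         paste(unique(calls$source[bad_src]), collapse = ", "))
  if (cfg$require_both_duplicates) {
    tum <- calls[calls$source != "blood", , drop = FALSE]
    src_per_case <- tapply(tum$source, tum$sample_id,
                           function(s) length(unique(s)))
    short <- names(src_per_case)[src_per_case < 2]
    if (length(short)) {
      stop("duplicate concordance required but case(s) lack a second tumor ",
           "duplicate: ", paste(short, collapse = ", "))
    }
  }
  key <- .variant_key(calls)
  blood_keys <- unique(key[calls$source == "blood"])
  pop_drop <- character(0)
  if (!is.null(popaf) && nrow(popaf)) {
    pk <- .variant_key(popaf)
    pop_drop <- unique(pk[popaf$af > cfg$popaf_max])
  }
  tum <- calls[calls$source %in% c("tumor_dup1", "tumor_dup2"), , drop = FALSE]
  tkey <- .variant_key(tum)
  ckey <- paste(tum$sample_id, tkey, sep = "|")
  keep_idx <- integer(0)
  for (g in split(seq_len(nrow(tum)), ckey)) {
    rows <- tum[g, , drop = FALSE]
    srcs <- unique(rows$source)
    if (cfg$require_both_duplicates &&
        !all(c("tumor_dup1", "tumor_dup2") %in% srcs)) next
    vafs <- rows$vaf
    if (any(!is.na(vafs) & vafs < cfg$vaf_min)) next
    k <- .variant_key(rows[1, ])
    if (cfg$exclude_in_blood && k %in% blood_keys) next
    if (k %in% pop_drop) next
    if (!(rows$effect[1] %in% cfg$effects_kept)) next
    keep_idx <- c(keep_idx, g[order(rows$source)][1])
  }
  out <- tum[sort(keep_idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}
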