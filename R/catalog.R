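.is_snv <- function(ref, alt) nchar(ref) == 1L & nchar(alt) == 1L &
  ref %in% .BASES & alt %in% .BASES

#' Fetch trinucleotide contexts from a reference
#'
#' @param mutations Data frame with `chrom` and 1-based `pos`.
#' @param reference Named character vector of contig sequences, or a
#'   `Biostrings::DNAStringSet`, or a path to a FASTA file.
#' @return Data frame `ctx5`, `ctx3` (uppercase bases).
#' @export
fetch_context <- function(mutations, reference) {
  seqs <- .as_contigs(reference)
  miss <- setdiff(unique(mutations$chrom), names(seqs))
  if (length(miss)) stop("contig(s) absent from reference: ",
                         paste(miss, collapse = ", "))
  lens <- nchar(seqs)
  bad <- mutations$pos < 2 | mutations$pos + 1 > lens[mutations$chrom]
  if (any(bad)) {
    stop("position(s) outside contig for context lookup: ",
         paste(utils::head(paste0(mutations$chrom[bad], ":",
                                  mutations$pos[bad]), 5), collapse = ", "))
  }
  s <- unname(seqs[mutations$chrom])
  data.frame(
    ctx5 = toupper(substr(s, mutations$pos - 1L, mutations$pos - 1L)),
    ctx3 = toupper(substr(s, mutations$pos + 1L, mutations$pos + 1L)),
    stringsAsFactors = FALSE)
}

.as_contigs <- function(reference) {
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference)) {
    ss <- Biostrings::readDNAStringSet(reference)
    seqs <- toupper(as.character(ss))
    names(seqs) <- sub("\\s.*$", "", names(ss))
    return(seqs)
  }
  if (inherits(reference, "DNAStringSet")) {
    seqs <- toupper(as.character(reference))
    names(seqs) <- sub("\\s.*$", "", names(reference))
    return(seqs)
  }
  if (is.character(reference) && !is.null(names(reference))) {
    return(toupper(reference))
  }
  stop("reference must be a FASTA path, DNAStringSet, or named character ",
       "vector of contig sequences")
}

#' Build the 96-channel trinucleotide catalog for a set of samples
#'
#' Single-nucleotide variants are classified into the fixed 96-channel layout
#' ([trinuc_channels()]); indels and multi-nucleotide records do not enter
#' the catalog and are counted separately.
#'
#' @param mutations Data frame with `sample_id`, `chrom`, `pos`, `ref`,
#'   `alt`.
#' @param reference Reference accepted by [fetch_context()].
#' @param samples Optional ordered sample ids (defaults to order of first
#'   appearance); samples without mutations yield all-zero columns.
#' @return List of class `trinuc_catalog` with `counts` (96 x S integer
#'   matrix, rownames the channel labels), `samples`, and `n_excluded`
#'   (non-SNV records per sample).
#' @export
build_catalog96 <- function(mutations, reference, samples = NULL) {
  if (is.null(samples)) samples <- unique(mutations$sample_id)
  counts <- matrix(0L, nrow = 96, ncol = length(samples),
                   dimnames = list(trinuc_channels(), samples))
  n_excluded <- stats::setNames(integer(length(samples)), samples)
  if (nrow(mutations)) {
    stopifnot(all(mutations$sample_id %in% samples))
    snv <- .is_snv(toupper(mutations$ref), toupper(mutations$alt))
    ex <- table(factor(mutations$sample_id[!snv], levels = samples))
    n_excluded[] <- as.integer(ex)
    m <- mutations[snv, , drop = FALSE]
    if (nrow(m)) {
      ctx <- fetch_context(m, reference)
      ch <- classify_channel(m$ref, m$alt, ctx$ctx5, ctx$ctx3)
      tab <- table(factor(ch, levels = 1:96),
                   factor(m$sample_id, levels = samples))
      counts[] <- as.integer(tab)
    }
  }
  structure(list(counts = counts, samples = samples,
                 n_excluded = n_excluded),
            class = "trinuc_catalog")
}

#' Eight-category strand-symmetric mutation spectrum
#'
#' SNVs are assigned to the six pair-notation classes, with G:C>A:T split by
#' CpG context; indels and multi-nucleotide records fall into the `indel`
#' category, so the eight categories partition every record.
#'
#' @param mutations Data frame with `ref`, `alt` and either `ctx5`/`ctx3`
#'   columns or a `reference` to look them up.
#' @param reference Optional reference for context lookup.
#' @return List of class `pair_spectrum` with integer `counts` over the 8
#'   fixed categories and `fractions`.
#' @export
build_pair_spectrum <- function(mutations, reference = NULL) {
  cats <- pair_spectrum_categories()
  counts <- stats::setNames(integer(8), cats)
  if (nrow(mutations)) {
    ref <- toupper(mutations$ref); alt <- toupper(mutations$alt)
    snv <- .is_snv(ref, alt)
    counts["indel"] <- sum(!snv)
    if (any(snv)) {
      m <- mutations[snv, , drop = FALSE]
      if (!all(c("ctx5", "ctx3") %in% names(m))) {
        if (is.null(reference)) {
          stop("mutations lack ctx5/ctx3 columns and no reference given")
        }
        m <- cbind(m, fetch_context(m, reference))
      }
      pair <- to_pair_notation(m$ref, m$alt)
      cpg <- is_cpg(m$ref, m$alt, m$ctx5, m$ctx3)
      lab <- ifelse(pair == "G:C>A:T",
                    ifelse(cpg, "G:C>A:T at CpG", "G:C>A:T other"), pair)
      tab <- table(factor(lab, levels = cats))
      counts <- counts + as.integer(tab)
    }
  }
  total <- sum(counts)
  structure(list(counts = counts,
                 fractions = if (total > 0) counts / total else counts * 0),
            class = "pair_spectrum")
}

#' The fixed eight spectrum categories
#' @return Character vector of the 8 labels.
#' @export
pair_spectrum_categories <- function() {
  c("G:C>A:T at CpG", "G:C>A:T other", "G:C>T:A", "G:C>C:G",
    "A:T>G:C", "A:T>T:A", "A:T>C:G", "indel")
}

#' Compare one spectrum category between two datasets
#'
#' Two-sided Fisher exact test of category-vs-rest counts between the two
#' spectra.
#'
#' @param spec_a,spec_b `pair_spectrum` objects.
#' @param category One of [pair_spectrum_categories()].
#' @return Two-sided p-value.
#' @export
spectrum_compare <- function(spec_a, spec_b, category) {
  stopifnot(category %in% pair_spectrum_categories())
  ka <- spec_a$counts[category]; na <- sum(spec_a$counts)
  kb <- spec_b$counts[category]; nb <- sum(spec_b$counts)
  if (na == 0 || nb == 0) stop("both spectra must be non-empty")
  if (ka + kb == 0) return(1)
  fisher_exact_2x2(matrix(c(ka, na - ka, kb, nb - kb), 2, 2, byrow = TRUE))
}

#' Per-sample mutation rates per megabase
#'
#' @param mutations Data frame with `sample_id`; one row per retained
#'   mutation.
#' @param capture_mb Size of the captured territory in Mb (e.g. 47 for a
#'   medical-exome capture).
#' @param samples Optional ordered sample ids including zero-count samples.
#' @return List with per-sample `rates` and their `mean`.
#' @export
mutation_rate_per_mb <- function(mutations, capture_mb, samples = NULL) {
  stopifnot(capture_mb > 0)
  if (is.null(samples)) samples <- unique(mutations$sample_id)
  if (!length(samples)) stop("no samples supplied")
  n <- table(factor(mutations$sample_id, levels = samples))
  rates <- as.numeric(n) / capture_mb
  names(rates) <- samples
  list(rates = rates, mean = mean(rates))
}
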