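# Plain-text readers/writers for the tabular interchange formats used by the
# pipeline. All tables are TSV with a header; missing values are empty cells.

#' Read a per-case IHC marker table
#'
#' Expected columns: case_id, er_pct, pr_pct, her2, ki67_pct, egfr_pos,
#' ck56_pos, p53_stain, fish_confirmed (extra columns pass through).
#'
#' @param path TSV path.
#' @return Data frame suitable for [call_positivity()].
#' @export
read_ihc_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  req <- c("case_id", "er_pct", "pr_pct", "her2")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("IHC table lacks column(s): ", paste(miss, collapse = ", "))
  for (col in c("egfr_pos", "ck56_pos", "fish_confirmed")) {
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  }
  df
}

#' Read a MAF-like mutation table
#'
#' Expected columns: sample_id, chrom, pos, ref, alt, gene, effect, vaf,
#' source.
#'
#' @param path TSV path.
#' @return Data frame of mutation records.
#' @export
read_mutation_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""),
                          colClasses = c(chrom = "character"))
  req <- c("sample_id", "chrom", "pos", "ref", "alt", "effect", "source")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("mutation table lacks column(s): ",
                         paste(miss, collapse = ", "))
  df$pos <- as.integer(df$pos)
  df
}

#' Read a population allele-frequency table
#' @param path TSV with columns chrom, pos, ref, alt, af.
#' @return Data frame.
#' @export
read_popaf_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  stopifnot(all(c("chrom", "pos", "ref", "alt", "af") %in% names(df)))
  df
}

#' Write / read a 96-channel catalog as TSV
#'
#' 96 labeled rows (column `channel`), one column per sample.
#'
#' @param catalog A `trinuc_catalog` or a 96 x S matrix with channel
#'   rownames.
#' @param path Output TSV path.
#' @export
write_catalog_tsv <- function(catalog, path) {
  m <- if (inherits(catalog, "trinuc_catalog")) catalog$counts else as.matrix(catalog)
  stopifnot(identical(rownames(m), trinuc_channels()))
  df <- data.frame(channel = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog_tsv
#' @return `read_catalog_tsv`: a `trinuc_catalog`.
#' @export
read_catalog_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(names(df)[1] == "channel")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$channel
  if (!identical(rownames(m), trinuc_channels())) {
    stop("catalog channels are not in the fixed 96-channel order")
  }
  storage.mode(m) <- "integer"
  structure(list(counts = m, samples = colnames(m),
                 n_excluded = stats::setNames(integer(ncol(m)), colnames(m))),
            class = "trinuc_catalog")
}

#' Read a signature or reference catalog TSV (96 labeled rows x named columns)
#'
#' @param path TSV with first column `channel` and one column per signature.
#' @param normalize Rescale columns to sum to 1.
#' @return Numeric matrix with channel rownames.
#' @export
read_signature_tsv <- function(path, normalize = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(names(df)[1] == "channel")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$channel
  if (!identical(rownames(m), trinuc_channels())) {
    stop("signature channels are not in the fixed 96-channel order")
  }
  if (any(m < 0)) stop("signatures must be non-negative")
  if (normalize) m <- sweep(m, 2, colSums(m), "/")
  m
}
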