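#' Fixed 96-channel trinucleotide layout
#'
#' Single-base substitutions are reduced to the pyrimidine strand and indexed
#' by substitution class (C>A, C>G, C>T, T>A, T>C, T>G) and the 5'/3' flanking
#' bases (alphabetical A, C, G, T), giving the conventional 96-channel layout
#' of published signature catalogs (COSMIC v2 ordering). Channel i (1-based)
#' is `class*16 + idx5*4 + idx3 + 1` with all indices 0-based.
#'
#' @return Character vector of 96 labels such as `"A[C>A]A"`, in fixed order.
#' @export
#' @examples
#' trinuc_channels()[c(1, 96)]
trinuc_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  out <- character(96)
  k <- 1L
  for (s in subs) for (b5 in bases) for (b3 in bases) {
    out[k] <- paste0(b5, "[", s, "]", b3)
    k <- k + 1L
  }
  out
}

.BASES <- c("A", "C", "G", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A")
.SUBS6 <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

.check_bases <- function(x, what) {
  bad <- !(x %in% .BASES)
  if (any(bad)) {
    stop("ambiguous or invalid ", what, " base(s): ",
         paste(unique(x[bad]), collapse = ", "))
  }
}

#' Classify single-base substitutions into the 96 trinucleotide channels
#'
#' Substitutions with a purine reference base are reverse-complemented
#' (alleles complemented, flanks complemented and swapped) onto the
#' pyrimidine strand before indexing, so the classification is strand
#' symmetric.
#'
#' @param ref,alt Single reference/alternate bases (vectorized).
#' @param ctx5,ctx3 Bases immediately 5' and 3' of the substituted position,
#'   read on the same strand as `ref`.
#' @return Integer vector of 1-based channel indices into
#'   [trinuc_channels()].
#' @export
#' @examples
#' classify_channel("C", "A", "A", "A")  # A[C>A]A -> 1
#' classify_channel("G", "T", "A", "C")  # revcomp -> G[C>A]T -> 12
classify_channel <- function(ref, alt, ctx5, ctx3) {
  n <- length(ref)
  stopifnot(length(alt) == n, length(ctx5) == n, length(ctx3) == n)
  ref <- toupper(ref); alt <- toupper(alt)
  ctx5 <- toupper(ctx5); ctx3 <- toupper(ctx3)
  .check_bases(ref, "reference"); .check_bases(alt, "alternate")
  .check_bases(ctx5, "5' context"); .check_bases(ctx3, "3' context")
  if (any(ref == alt)) stop("ref and alt must differ")
  # collapse purine-reference records onto the pyrimidine strand
  pur <- ref %in% c("A", "G")
  r <- ifelse(pur, .COMP[ref], ref)
  a <- ifelse(pur, .COMP[alt], alt)
  f5 <- ifelse(pur, .COMP[ctx3], ctx5)
  f3 <- ifelse(pur, .COMP[ctx5], ctx3)
  cls <- match(paste0(r, ">", a), .SUBS6) - 1L
  i5 <- match(f5, .BASES) - 1L
  i3 <- match(f3, .BASES) - 1L
  cls * 16L + i5 * 4L + i3 + 1L
}

#' Strand-symmetric pair notation for single-base substitutions
#'
#' Maps a substitution to one of the six strand-equivalent classes, labeled
#' purine-first (e.g. a C>A on either strand is reported as G:C>T:A).
#'
#' @param ref,alt Single bases (vectorized).
#' @return Character vector over the six labels
#'   `G:C>T:A, G:C>C:G, G:C>A:T, A:T>T:A, A:T>G:C, A:T>C:G`.
#' @export
#' @examples
#' to_pair_notation(c("G", "C", "T"), c("T", "A", "C"))
to_pair_notation <- function(ref, alt) {
  stopifnot(length(ref) == length(alt))
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(nchar(ref) != 1L | nchar(alt) != 1L)) {
    stop("pair notation is defined for single-base substitutions only; ",
         "route indels to the indel category upstream")
  }
  .check_bases(ref, "reference"); .check_bases(alt, "alternate")
  if (any(ref == alt)) stop("ref and alt must differ")
  pur <- ref %in% c("A", "G")
  r <- ifelse(pur, .COMP[ref], ref)
  a <- ifelse(pur, .COMP[alt], alt)
  # pyrimidine-strand class -> purine-first label
  lab <- c("C>A" = "G:C>T:A", "C>G" = "G:C>C:G", "C>T" = "G:C>A:T",
           "T>A" = "A:T>T:A", "T>C" = "A:T>G:C", "T>G" = "A:T>C:G")
  unname(lab[paste0(r, ">", a)])
}

#' Is a substitution at a CpG site?
#'
#' After reduction to the pyrimidine strand, a substitution is at CpG when the
#' mutated base is a C immediately followed by a G (3' flank G).
#'
#' @inheritParams classify_channel
#' @return Logical vector.
#' @export
is_cpg <- function(ref, alt, ctx5, ctx3) {
  ref <- toupper(ref); alt <- toupper(alt)
  ctx5 <- toupper(ctx5); ctx3 <- toupper(ctx3)
  .check_bases(ref, "reference")
  pur <- ref %in% c("A", "G")
  r <- ifelse(pur, .COMP[ref], ref)
  f3 <- ifelse(pur, .COMP[ctx5], ctx3)
  r == "C" & f3 == "G"
}

#' Reverse complement of a base vector
#' @param x Character vector of bases.
#' @return Complemented bases (element-wise; use `rev()` for sequences).
#' @keywords internal
complement_base <- function(x) unname(.COMP[toupper(x)])
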