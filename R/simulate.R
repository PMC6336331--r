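# Seeded generators for synthetic cohorts with known ground truth. Defaults
# encode the cohort structure the analysis modules are built for: the IHC
# subtype mixture and per-subtype Ki67-positivity of a 233-case
# premenopausal breast-cancer series, an 8-gene panel mutated in 63.5% of
# 126 sequenced cases (TP53 32.5%, PIK3CA 21.4%, AKT1 9.5%), a TP53 spectrum
# with 27% G:C>T:A, and exome catalogs drawn from known signature mixtures.

#' Default synthetic-cohort configuration
#'
#' Central defaults for the generators. Subtype probabilities and
#' per-subtype Ki67-positivity follow the reference cohort's subtype table
#' (134/26/11/48/14 luminal A / luminal B / HER2-enriched / triple-negative /
#' undetermined out of 233, Ki67-positive 96/23/10/47/13 of those). The
#' 8-gene panel model draws the number of mutated genes per case from the
#' observed multiplicity (46 none, 59 one, 21 more than one, of 126) and the
#' genes from their observed marginal counts (TP53 41, PIK3CA 27, AKT1 12,
#' remainder spread over the other five panel genes).
#'
#' @param seed Mandatory integer seed.
#' @param n_cases Cohort size for IHC simulation.
#' @param n_panel_cases Cases with panel sequencing.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed, n_cases = 233L, n_panel_cases = 126L) {
  if (missing(seed)) stop("a seed is mandatory for every generator")
  structure(list(
    seed = as.integer(seed),
    n_cases = as.integer(n_cases),
    n_panel_cases = as.integer(n_panel_cases),
    subtype_probs = c(LuminalA = 134, LuminalB = 26, HER2enriched = 11,
                      TripleNegative = 48, Undetermined = 14) / 233,
    ki67_pos_rate = c(LuminalA = 96 / 134, LuminalB = 23 / 26,
                      HER2enriched = 10 / 11, TripleNegative = 47 / 48,
                      Undetermined = 13 / 14),
    basal_rate = 45 / 48,
    panel_genes = c("TP53", "PIK3CA", "AKT1", "CDH1", "PTEN", "RB1",
                    "ERBB2", "NOTCH1"),
    gene_weights = c(TP53 = 41, PIK3CA = 27, AKT1 = 12, CDH1 = 5,
                     PTEN = 4, RB1 = 4, ERBB2 = 4, NOTCH1 = 4) / 101,
    multiplicity_probs = c(none = 46, one = 59, multi = 21) / 126,
    tp53_spectrum = c("G:C>A:T at CpG" = 0.13, "G:C>A:T other" = 0.12,
                      "G:C>T:A" = 0.27, "G:C>C:G" = 0.08,
                      "A:T>G:C" = 0.10, "A:T>T:A" = 0.06,
                      "A:T>C:G" = 0.04, "indel" = 0.20),
    vaf_shape = c(5, 15), vaf_min = 0.04,
    artifact_rates = c(single_dup = 0.5, blood = 0.3, popaf = 0.3,
                       low_vaf = 0.3)
  ), class = "sim_config")
}

.dirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = alpha), nrow = k)
  sweep(g, 2, colSums(g), "/")
}

.rvaf <- function(n, shape = c(5, 15), vaf_min = 0.04) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rbeta(n, shape[1], shape[2])
    out <- c(out, x[x >= vaf_min])
  }
  out[seq_len(n)]
}

#' Simulate a reference genome
#'
#' I.i.d. uniform bases per contig; deterministic per seed.
#'
#' @param contigs Character vector of contig names.
#' @param length Length of each contig (recycled), at least 3.
#' @param seed Integer seed.
#' @param path Optional FASTA path to write.
#' @return Named character vector of sequences (invisibly writes FASTA when
#'   `path` given).
#' @export
simulate_reference <- function(contigs, length, seed, path = NULL) {
  if (any(length < 3)) stop("contig length must be at least 3")
  len <- rep_len(length, base::length(contigs))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  seqs <- vapply(len, function(L)
    paste(sample(.BASES, L, replace = TRUE), collapse = ""), character(1))
  names(seqs) <- contigs
  if (!is.null(path)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  }
  invisible(seqs)
}

#' Simulate an IHC cohort with known subtype truth
#'
#' Draws a subtype per case and marker values consistent with its
#' definition, so that [assign_subtype()] recovers the drawn subtype for
#' every determined case. Ki67 percentages are drawn above/below the 14%
#' threshold at the per-subtype positivity rates. Menopausal status and
#' study source are independent covariate columns for association studies.
#'
#' @param cfg A [sim_config()].
#' @return List with `ihc` (marker table), `truth` (per-case subtype, basal
#'   and Ki67 truth).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  n <- cfg$n_cases
  subtype <- sample(names(cfg$subtype_probs), n, replace = TRUE,
                    prob = cfg$subtype_probs)
  case_id <- sprintf("case%03d", seq_len(n))
  er_pct <- pr_pct <- ki67_pct <- numeric(n)
  her2 <- character(n); egfr <- ck56 <- rep(FALSE, n)
  fish <- rep(FALSE, n)
  basal <- rep("not-applicable", n)
  for (i in seq_len(n)) {
    st <- subtype[i]
    er_pos <- st %in% c("LuminalA", "LuminalB")
    er_pct[i] <- if (er_pos) stats::runif(1, 10, 100) else stats::runif(1, 0, 1)
    pr_pct[i] <- switch(st,
      LuminalA = , LuminalB = if (stats::runif(1) < 0.9)
        stats::runif(1, 10, 100) else stats::runif(1, 0, 1),
      HER2enriched = if (stats::runif(1) < 0.2)
        stats::runif(1, 10, 100) else stats::runif(1, 0, 1),
      stats::runif(1, 0, 1))
    her2[i] <- switch(st,
      LuminalA = "negative", LuminalB = "positive",
      HER2enriched = "positive", TripleNegative = "negative",
      Undetermined = "equivocal")
    if (st == "Undetermined" && stats::runif(1) < 1 / 14) {
      # the rarer undetermined mode: ER-/PR+/HER2- with weak PR positivity
      her2[i] <- "negative"
      er_pct[i] <- stats::runif(1, 0, 1)
      pr_pct[i] <- stats::runif(1, 1.5, 10)
    }
    if (st == "TripleNegative") {
      if (stats::runif(1) < cfg$basal_rate) {
        basal[i] <- "basal"
        which_m <- sample(1:3, 1)  # EGFR, CK5/6, or both
        egfr[i] <- which_m %in% c(1, 3)
        ck56[i] <- which_m %in% c(2, 3)
      } else basal[i] <- "non-basal"
    }
    ki_pos <- stats::runif(1) < cfg$ki67_pos_rate[st]
    ki67_pct[i] <- if (ki_pos) stats::runif(1, 15, 80) else stats::runif(1, 0, 14)
  }
  ihc <- data.frame(case_id = case_id, er_pct = er_pct, pr_pct = pr_pct,
                    her2 = her2, ki67_pct = ki67_pct, egfr_pos = egfr,
                    ck56_pos = ck56, p53_stain = NA_character_,
                    fish_confirmed = fish,
                    menopausal = sample(c("pre", "post"), n, replace = TRUE),
                    source = sample(c("cohortA", "cohortB"), n,
                                    replace = TRUE),
                    stringsAsFactors = FALSE)
  truth <- data.frame(case_id = case_id, subtype = subtype, basal = basal,
                      ki67_positive = ki67_pct > 14,
                      stringsAsFactors = FALSE)
  list(ihc = ihc, truth = truth)
}

#' Simulate per-case panel variant call sets (tumor duplicates + blood)
#'
#' True somatic variants appear in both tumor duplicates with VAF at or
#' above the calling threshold and nowhere else. Injected artifacts each
#' violate exactly one somatic-filter rule (present in a single duplicate,
#' present in blood, population allele frequency above the SNP cutoff, or
#' sub-threshold VAF) and are labeled in the truth table. All variant
#' positions are distinct so truth labels stay unambiguous.
#'
#' @param cfg A [sim_config()].
#' @param artifact_rates Named per-case Poisson rates for the four artifact
#'   types (defaults from `cfg`; set to zeros for a clean cohort).
#' @return List with `calls` (mutation records across sources), `popaf`
#'   (population AF table covering the popaf artifacts), `reference` (named
#'   contig sequences: one contig per panel gene), `truth` (all variants
#'   with a `class` of `"somatic"` or the artifact type).
#' @export
simulate_callsets <- function(cfg, artifact_rates = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(artifact_rates)) artifact_rates <- cfg$artifact_rates
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed + 1L)
  genes <- cfg$panel_genes
  gene_len <- 2000L
  ref <- simulate_reference(genes, gene_len, seed = cfg$seed + 2L)
  n <- cfg$n_panel_cases
  case_id <- sprintf("pcase%03d", seq_len(n))
  used_pos <- lapply(genes, function(g) integer(0))
  names(used_pos) <- genes
  draw_pos <- function(gene) {
    repeat {
      p <- sample(2:(gene_len - 1L), 1L)
      if (!(p %in% used_pos[[gene]])) {
        used_pos[[gene]] <<- c(used_pos[[gene]], p)
        return(p)
      }
    }
  }
  mut_rows <- list(); truth_rows <- list(); popaf_rows <- list()
  deleterious <- c("non-synonymous", "nonsense", "splice", "indel-coding",
                   "stop-loss")
  eff_probs <- c(0.75, 0.08, 0.05, 0.10, 0.02)
  new_variant <- function(gene) {
    pos <- draw_pos(gene)
    effect <- sample(deleterious, 1, prob = eff_probs)
    r <- substr(ref[[gene]], pos, pos)
    if (effect == "indel-coding") {
      alt <- paste0(r, sample(.BASES, 1))
    } else {
      alt <- sample(setdiff(.BASES, r), 1)
    }
    list(gene = gene, pos = pos, ref = r, alt = alt, effect = effect)
  }
  emit <- function(case, v, sources, vafs) {
    for (j in seq_along(sources)) {
      mut_rows[[length(mut_rows) + 1L]] <<- data.frame(
        sample_id = case, chrom = v$gene, pos = v$pos, ref = v$ref,
        alt = v$alt, gene = v$gene, effect = v$effect, vaf = vafs[j],
        source = sources[j], stringsAsFactors = FALSE)
    }
  }
  record_truth <- function(case, v, class) {
    truth_rows[[length(truth_rows) + 1L]] <<- data.frame(
      sample_id = case, chrom = v$gene, pos = v$pos, ref = v$ref,
      alt = v$alt, gene = v$gene, effect = v$effect, class = class,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    mult <- sample(names(cfg$multiplicity_probs), 1,
                   prob = cfg$multiplicity_probs)
    n_genes <- switch(mult, none = 0L, one = 1L, multi = 2L)
    gsel <- if (n_genes > 0) {
      sample(names(cfg$gene_weights), n_genes, prob = cfg$gene_weights)
    } else character(0)
    for (g in gsel) {
      v <- new_variant(g)
      emit(case_id[i], v, c("tumor_dup1", "tumor_dup2"),
           .rvaf(2, cfg$vaf_shape, cfg$vaf_min))
      record_truth(case_id[i], v, "somatic")
    }
    # artifacts: each violates exactly one filter rule
    for (type in names(artifact_rates)) {
      for (a in seq_len(stats::rpois(1, artifact_rates[type]))) {
        v <- new_variant(sample(genes, 1))
        switch(type,
          single_dup = {
            emit(case_id[i], v, "tumor_dup1",
                 .rvaf(1, cfg$vaf_shape, cfg$vaf_min))
          },
          blood = {
            emit(case_id[i], v, c("tumor_dup1", "tumor_dup2", "blood"),
                 c(.rvaf(2, cfg$vaf_shape, cfg$vaf_min), stats::runif(1, 0.3, 0.6)))
          },
          popaf = {
            emit(case_id[i], v, c("tumor_dup1", "tumor_dup2"),
                 .rvaf(2, cfg$vaf_shape, cfg$vaf_min))
            popaf_rows[[length(popaf_rows) + 1L]] <- data.frame(
              chrom = v$gene, pos = v$pos, ref = v$ref, alt = v$alt,
              af = stats::runif(1, 0.002, 0.05), stringsAsFactors = FALSE)
          },
          low_vaf = {
            emit(case_id[i], v, c("tumor_dup1", "tumor_dup2"),
                 stats::runif(2, 0.005, 0.035))
          })
        record_truth(case_id[i], v, type)
      }
    }
    # every case carries a synonymous passenger (both duplicates) and a
    # blood-only germline record, so all three sources are represented for
    # every case regardless of its somatic/artifact draw
    v <- new_variant(sample(genes, 1))
    v$effect <- "synonymous"
    v$alt <- if (nchar(v$alt) > 1) sample(setdiff(.BASES, v$ref), 1) else v$alt
    emit(case_id[i], v, c("tumor_dup1", "tumor_dup2"),
         .rvaf(2, cfg$vaf_shape, cfg$vaf_min))
    v <- new_variant(sample(genes, 1))
    emit(case_id[i], v, "blood", stats::runif(1, 0.4, 0.6))
  }
  calls <- do.call(rbind, mut_rows)
  truth <- do.call(rbind, truth_rows)
  popaf <- if (length(popaf_rows)) do.call(rbind, popaf_rows) else
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), af = numeric(0))
  list(calls = calls, popaf = popaf, reference = ref, truth = truth)
}

#' Simulate sparse random signatures over the 96 channels
#'
#' Columns drawn from a symmetric Dirichlet; low concentration gives sparse,
#' well-separated signatures. Redrawn until all pairwise cosines fall below
#' `max_cosine`.
#'
#' @param k Number of signatures.
#' @param seed Integer seed.
#' @param concentration Dirichlet concentration per channel.
#' @param max_cosine Maximum allowed pairwise cosine similarity.
#' @return 96 x k column-stochastic matrix with channel rownames.
#' @export
simulate_signatures <- function(k, seed, concentration = 0.1,
                                max_cosine = 0.6) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  repeat {
    W <- .dirichlet(k, rep(concentration, 96))
    ok <- TRUE
    if (k > 1) {
      for (i in seq_len(k - 1)) for (j in (i + 1):k) {
        if (cosine_similarity(W[, i], W[, j]) >= max_cosine) ok <- FALSE
      }
    }
    if (ok) break
  }
  dimnames(W) <- list(trinuc_channels(), paste0("true", seq_len(k)))
  W
}

#' Simulate a 96-channel catalog from a known signature mixture
#'
#' Per sample, the mutation total is Poisson, the exposure vector is drawn
#' from a symmetric Dirichlet over the true signatures, and channel counts
#' are multinomial with probabilities `W %*% exposures`.
#'
#' @param W True 96 x K column-stochastic signature matrix.
#' @param n_samples Number of samples.
#' @param mutations_mean Poisson mean of per-sample mutation totals.
#' @param alpha Symmetric Dirichlet concentration of exposures (low values
#'   give a dominant signature per sample).
#' @param seed Integer seed.
#' @return List with `catalog` (`trinuc_catalog`), `exposures` (true K x S
#'   fractions), `totals`.
#' @export
simulate_catalog <- function(W, n_samples, mutations_mean = 1000,
                             alpha = 0.3, seed = 1L) {
  stopifnot(nrow(W) == 96, all(abs(colSums(W) - 1) < 1e-9))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  k <- ncol(W)
  E <- .dirichlet(n_samples, rep(alpha, k))
  totals <- stats::rpois(n_samples, mutations_mean)
  counts <- matrix(0L, 96, n_samples,
                   dimnames = list(trinuc_channels(),
                                   sprintf("s%03d", seq_len(n_samples))))
  for (j in seq_len(n_samples)) {
    if (totals[j] > 0) {
      counts[, j] <- stats::rmultinom(1, totals[j], W %*% E[, j, drop = FALSE])
    }
  }
  dimnames(E) <- list(colnames(W), colnames(counts))
  cat96 <- structure(list(counts = counts, samples = colnames(counts),
                          n_excluded = stats::setNames(
                            integer(n_samples), colnames(counts))),
                     class = "trinuc_catalog")
  list(catalog = cat96, exposures = E, totals = totals)
}

#' Simulate a TP53-style mutation list with a fixed 8-category spectrum
#'
#' Categories are drawn from the configured spectrum probabilities (default
#' headline weight 0.27 on G:C>T:A, indels second at 0.20). Each record is
#' emitted with reference/alternate alleles and flanking contexts consistent
#' with its category on a randomly chosen strand, so the spectrum builder
#' recovers the generating probabilities up to sampling error.
#'
#' @param cfg A [sim_config()] (supplies `tp53_spectrum` and the seed).
#' @param n_mutations Number of records to draw.
#' @return Data frame of mutation records with `ctx5`/`ctx3` columns and a
#'   `category` truth column.
#' @export
simulate_tp53_spectrum <- function(cfg, n_mutations) {
  stopifnot(inherits(cfg, "sim_config"))
  probs <- cfg$tp53_spectrum
  stopifnot(abs(sum(probs) - 1) < 1e-9)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed + 3L)
  cats <- sample(names(probs), n_mutations, replace = TRUE, prob = probs)
  # pyrimidine-strand representation per category: ref, alt, ctx3 constraint
  pyr <- list("G:C>A:T at CpG" = list(ref = "C", alt = "T", ctx3 = "G"),
              "G:C>A:T other" = list(ref = "C", alt = "T",
                                     ctx3 = c("A", "C", "T")),
              "G:C>T:A" = list(ref = "C", alt = "A", ctx3 = .BASES),
              "G:C>C:G" = list(ref = "C", alt = "G", ctx3 = .BASES),
              "A:T>G:C" = list(ref = "T", alt = "C", ctx3 = .BASES),
              "A:T>T:A" = list(ref = "T", alt = "A", ctx3 = .BASES),
              "A:T>C:G" = list(ref = "T", alt = "G", ctx3 = .BASES))
  rows <- lapply(seq_len(n_mutations), function(i) {
    cat_i <- cats[i]
    if (cat_i == "indel") {
      r <- sample(.BASES, 1)
      df <- data.frame(ref = r, alt = paste0(r, sample(.BASES, 1)),
                       ctx5 = sample(.BASES, 1), ctx3 = sample(.BASES, 1),
                       effect = "indel-coding", stringsAsFactors = FALSE)
    } else {
      p <- pyr[[cat_i]]
      ctx5 <- sample(.BASES, 1)
      ctx3 <- if (length(p$ctx3) == 1) p$ctx3 else sample(p$ctx3, 1)
      if (stats::runif(1) < 0.5) {
        df <- data.frame(ref = p$ref, alt = p$alt, ctx5 = ctx5, ctx3 = ctx3,
                         effect = "non-synonymous", stringsAsFactors = FALSE)
      } else {
        # emit on the purine strand: complement alleles, swap+complement flanks
        df <- data.frame(ref = complement_base(p$ref),
                         alt = complement_base(p$alt),
                         ctx5 = complement_base(ctx3),
                         ctx3 = complement_base(ctx5),
                         effect = "non-synonymous", stringsAsFactors = FALSE)
      }
    }
    df
  })
  out <- do.call(rbind, rows)
  data.frame(sample_id = "tp53set", chrom = "TP53",
             pos = seq_len(n_mutations) * 3L, out,
             gene = "TP53", category = cats, stringsAsFactors = FALSE)
}

#' Simulate an exome-scale coding mutation table
#'
#' Per-sample coding mutation totals are Poisson around
#' `coding_total / n_samples`; a fixed fraction are non-synonymous SNVs or
#' indels and the rest synonymous. Defaults emulate a 12-exome series with
#' 2634 coding mutations of which 2128 are non-synonymous SNVs/indels over a
#' 47 Mb capture.
#'
#' @param n_samples Number of exomes.
#' @param coding_total Expected total coding mutations across samples.
#' @param nonsyn_frac Fraction of coding mutations that are non-synonymous
#'   SNVs or indels.
#' @param seed Integer seed.
#' @return Data frame with `sample_id`, `effect` and a `coding` flag.
#' @export
simulate_exome_counts <- function(n_samples = 12L, coding_total = 2634,
                                  nonsyn_frac = 2128 / 2634, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  per <- stats::rpois(n_samples, coding_total / n_samples)
  ids <- rep(sprintf("ex%02d", seq_len(n_samples)), per)
  eff <- ifelse(stats::runif(length(ids)) < nonsyn_frac,
                sample(c("non-synonymous", "nonsense", "indel-coding"),
                       length(ids), replace = TRUE, prob = c(0.8, 0.1, 0.1)),
                "synonymous")
  data.frame(sample_id = ids, effect = eff, coding = TRUE,
             stringsAsFactors = FALSE)
}
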