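test_that("catalog construction counts SNVs per channel and sample", {
  ref <- c(chr1 = "AACAT")
  empty <- build_catalog96(data.frame(sample_id = character(0),
                                      chrom = character(0), pos = integer(0),
                                      ref = character(0), alt = character(0)),
                           ref)
  expect_identical(dim(empty$counts), c(96L, 0L))
  mut <- data.frame(sample_id = "s1", chrom = "chr1", pos = 3L, ref = "C",
                    alt = "A", stringsAsFactors = FALSE)
  cat1 <- build_catalog96(mut, ref)
  expect_identical(cat1$counts["A[C>A]A", "s1"], 1L)
  expect_identical(sum(cat1$counts), 1L)
})

test_that("catalog column sums equal per-sample SNV counts on simulation", {
  cfg <- sim_config(seed = 17, n_panel_cases = 30)
  cs <- simulate_callsets(cfg)
  som <- filter_somatic(cs$calls, popaf = cs$popaf)
  snv <- nchar(som$ref) == 1 & nchar(som$alt) == 1
  cat96 <- build_catalog96(som, cs$reference, samples = unique(som$sample_id))
  tallies <- table(factor(som$sample_id[snv], levels = unique(som$sample_id)))
  expect_identical(as.integer(colSums(cat96$counts)), as.integer(tallies))
  expect_identical(unname(cat96$n_excluded),
                   as.integer(table(factor(som$sample_id[!snv],
                                           levels = unique(som$sample_id)))))
})

test_that("catalog construction commutes with sample concatenation", {
  cfg <- sim_config(seed = 19, n_panel_cases = 12)
  cs <- simulate_callsets(cfg, artifact_rates = c(single_dup = 0, blood = 0,
                                                  popaf = 0, low_vaf = 0))
  som <- filter_somatic(cs$calls, popaf = cs$popaf)
  ids <- unique(som$sample_id)
  half <- ids[seq_len(floor(length(ids) / 2))]
  a <- build_catalog96(som[som$sample_id %in% half, ], cs$reference,
                       samples = half)
  b <- build_catalog96(som[!som$sample_id %in% half, ], cs$reference,
                       samples = setdiff(ids, half))
  full <- build_catalog96(som, cs$reference, samples = ids)
  expect_identical(cbind(a$counts, b$counts), full$counts)
})

test_that("out-of-contig positions and unknown contigs are rejected", {
  ref <- c(chr1 = "ACGTA")
  mut <- data.frame(sample_id = "s", chrom = "chr1", pos = 5L, ref = "A",
                    alt = "T")
  expect_error(build_catalog96(mut, ref), "outside contig")
  mut$chrom <- "chrX"
  expect_error(build_catalog96(mut, ref), "absent from reference")
})

test_that("context lookup is case-insensitive and FASTA round-trips", {
  ref <- c(chr1 = "aacat")
  mut <- data.frame(sample_id = "s1", chrom = "chr1", pos = 3L, ref = "C",
                    alt = "A")
  expect_identical(fetch_context(mut, ref),
                   data.frame(ctx5 = "A", ctx3 = "A", stringsAsFactors = FALSE))
  fa <- tempfile(fileext = ".fa")
  simulate_reference(c("c1", "c2"), 50, seed = 3, path = fa)
  seqs <- simulate_reference(c("c1", "c2"), 50, seed = 3)
  mut2 <- data.frame(sample_id = "s", chrom = "c2", pos = 10L, ref = "A",
                     alt = "T")
  expect_identical(fetch_context(mut2, fa), fetch_context(mut2, seqs))
})

test_that("pair spectrum partitions all records into the 8 categories", {
  mut <- data.frame(
    sample_id = "s", chrom = "g", pos = 1:2,
    ref = c("G", "C"), alt = c("T", "CA"),
    ctx5 = c("A", "A"), ctx3 = c("A", "A"), stringsAsFactors = FALSE)
  sp <- build_pair_spectrum(mut)
  expect_identical(unname(sp$counts["G:C>T:A"]), 1L)
  expect_identical(unname(sp$counts["indel"]), 1L)
  expect_identical(sum(sp$counts), 2L)
  # C>T with 3' G lands in the CpG split
  cpg <- data.frame(sample_id = "s", chrom = "g", pos = 1L, ref = "C",
                    alt = "T", ctx5 = "A", ctx3 = "G")
  expect_identical(unname(build_pair_spectrum(cpg)$counts["G:C>A:T at CpG"]), 1L)
  expect_equal(sum(sp$fractions), 1)
})

test_that("simulated spectra are partitioned completely and recover weights", {
  cfg <- sim_config(seed = 29)
  mut <- simulate_tp53_spectrum(cfg, 4000)
  sp <- build_pair_spectrum(mut)
  expect_identical(sum(sp$counts), 4000L)
  # each category frequency within 3 binomial sigmas of its weight
  for (cat_i in names(cfg$tp53_spectrum)) {
    p <- cfg$tp53_spectrum[[cat_i]]
    se <- sqrt(p * (1 - p) / 4000)
    expect_lt(abs(sp$fractions[[cat_i]] - p), 3 * se + 1e-9)
  }
  # truth labels agree with the spectrum builder record by record
  expect_identical(unname(sp$counts[names(cfg$tp53_spectrum)]),
                   as.integer(table(factor(mut$category,
                                           levels = names(cfg$tp53_spectrum)))))
})

test_that("spectrum comparison delegates to the exact 2x2 test", {
  cfg <- sim_config(seed = 37)
  sp <- build_pair_spectrum(simulate_tp53_spectrum(cfg, 500))
  expect_equal(spectrum_compare(sp, sp, "G:C>T:A"), 1, tolerance = 1e-9)
  a <- sp; b <- sp
  a$counts[] <- 0L; a$counts["G:C>T:A"] <- 10L; a$counts["indel"] <- 10L
  b$counts[] <- 0L; b$counts["indel"] <- 20L
  expect_equal(spectrum_compare(a, b, "G:C>T:A"),
               oracle_fisher_2x2(10, 10, 0, 20), tolerance = 1e-9)
  a$counts["G:C>T:A"] <- 0L
  expect_equal(spectrum_compare(a, b, "G:C>T:A"), 1)
})

test_that("mutation rates per Mb are counts over capture size", {
  mut <- data.frame(sample_id = rep(c("a", "b"), c(94, 94)))
  r <- mutation_rate_per_mb(mut, 47)
  expect_equal(unname(r$rates), c(2, 2))
  expect_equal(r$mean, 2)
  r0 <- mutation_rate_per_mb(mut[0, , drop = FALSE], 47, samples = "a")
  expect_equal(unname(r0$rates), 0)
  expect_error(mutation_rate_per_mb(mut[0, , drop = FALSE], 47), "no samples")
})

test_that("catalog TSV writer/reader round-trips", {
  sim <- small_catalog_sim(n_samples = 4, mean_mut = 100)
  path <- tempfile(fileext = ".tsv")
  write_catalog_tsv(sim$sim$catalog, path)
  back <- read_catalog_tsv(path)
  expect_identical(back$counts, sim$sim$catalog$counts)
})
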