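---
title: "Methods and design choices in sigcohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in sigcohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigcohort)
```

`sigcohort` packages the downstream genomics analyses used in pilot-scale
tumor cohort studies of premenopausal breast cancer: clinical subtype calling
from immunohistochemistry (IHC), somatic mutation filtering for
FFPE-derived sequencing, mutation spectra and 96-channel catalogs, de novo
mutational signature inference, permutation association testing, and gene-set
over-representation. Every stage can be exercised on seeded synthetic cohorts
with known ground truth, which is how the package validates itself.

## IHC subtyping and exact contingency tests

Markers are called positive by strict thresholds: ER and PR at staining
score > 1% and Ki67 at > 14% (the St Gallen convention). The thresholds live
in `ihc_thresholds()` so a cohort with different clinical cutoffs can
override them; the boundary is always exclusive (`er_pct = 1` is negative).
Subtypes follow the ER/PR/HER2 rules — luminal A (ER+/HER2−), luminal B
(ER+/HER2+), HER2-enriched (ER−/HER2+), triple-negative (ER−/PR−/HER2−),
with EGFR/CK5/6 splitting triple-negatives into basal/non-basal. Two
situations yield `Undetermined`: an equivocal HER2 result without
confirmatory FISH, and marker combinations outside the four definitions
(e.g. ER−/PR+/HER2−). The mapping is total: every input row receives exactly
one label.

Association between categorical case variables uses Fisher's exact test.
The 2×2 p-value is the two-sided "probability at most that of the observed
table" sum over the hypergeometric distribution (the convention of mainstream
statistical software, with a `1 + 1e-7` relative guard against floating-point
ties); r×c tables use the exact Freeman–Halton test when the table total is at
most the enumeration cap (300 by default) and a seeded Monte-Carlo estimate
beyond it, with the path taken reported alongside the p-value.

One analysis choice deserves a note. For the cohort-level test of Ki67
positivity against IHC subtype we tabulate *all* subtype rows including the
`Undetermined` group. On the reference cohort counts (96/38, 23/3, 10/1,
47/1, 13/1) this five-row table gives p ≈ 1.9×10⁻⁴; restricting to the four
assigned subtypes gives p ≈ 1.2×10⁻⁴. Both are one function call
(`fisher_exact_rxc`), but the inclusive table is the default analysis because
undetermined cases still carry a valid Ki67 measurement and discarding a
row of a marginal table changes the question being asked, not just its
power.

```{r fisher}
fisher_exact_2x2(matrix(c(96, 38, 47, 1), 2, 2, byrow = TRUE))
fisher_exact_rxc(matrix(c(96, 38, 23, 3, 10, 1, 47, 1, 13, 1),
                        ncol = 2, byrow = TRUE))$p.value
```

## Somatic filtering for FFPE duplicates

Formalin fixation introduces artefactual low-frequency variants. The filter
therefore demands that a variant be called in **both** tumor duplicates of a
case with a variant allele fraction of at least 4% in each; that it be absent
from every blood sample of the whole cohort; that its population allele
frequency not exceed 0.001 (known polymorphisms are removed, strictly-greater
rule); and that its effect class be potentially deleterious (splice, coding
indel, nonsense, stop-loss, or non-synonymous substitution). All cutoffs are
configuration (`somatic_filter_config()`) with those defaults. A case that
is subject to the duplicate-concordance rule but has calls from only one
tumor source is an error naming the case, not a silent pass. Retained
records are deduplicated to one row per case per variant, which makes the
filter idempotent.

## Mutation spectra and the 96-channel catalog

Single-base substitutions are reduced to the pyrimidine strand (purine
references are reverse-complemented together with their flanks) and indexed
by the six substitution classes C>A, C>G, C>T, T>A, T>C, T>G crossed with the
4×4 flanking bases in alphabetical order — the fixed channel order of
published signature catalogs (COSMIC v2 layout), so reference signature
tables can be joined row-for-row without reordering. Strand invariance is
tested exhaustively over all 192 raw substitution–context combinations.
Trinucleotide contexts come from a reference FASTA (1-based positions;
lookup reads `pos − 1` and `pos + 1`; parsing is case-insensitive). Indels
and multi-nucleotide substitutions never enter the catalog; they are counted
separately, and in the eight-category strand-symmetric spectrum (six pair
classes with G:C>A:T split by CpG context, plus `indel`) they form the
eighth category, so the spectrum partitions every record. Spectrum labels use
the purine-first style (G:C>T:A) throughout.

## Signature inference

The factorization engine minimizes the generalized Kullback–Leibler
divergence `D(V‖WH)` with Brunet-style multiplicative updates (Frobenius
updates are available behind a flag). Defaults: `max_iter = 2000`,
`tol = 1e-6` relative objective change, `1e-12` added to update denominators
against division by zero; initial entries are i.i.d. uniform scaled by the
data mean and seeded per run, so a seed reproduces a factorization
bit-for-bit. The objective trace is retained and is non-increasing up to
floating-point resolution (the tests allow `1e-8` relative slack for the
epsilon guards). After convergence `W` is column-normalized with the scale
moved into `H`.

Rank selection follows consensus stability. Each of `n_runs` restarts (50 by
default; validation workloads in this package use 20, which was sufficient
for stable curves at the simulated sizes) clusters samples by their dominant
signature; the consensus matrix is the mean connectivity, and its cophenetic
correlation coefficient — the Pearson correlation between `1 − consensus`
distances and the cophenetic distances of their average-linkage
dendrogram — measures how reproducible the clustering is across restarts.
Degenerate consensus matrices with zero distance variance are perfectly
stable by definition (coefficient 1), which also covers rank 1.

The chosen rank maximizes the cophenetic coefficient. Exact ties occur in
practice: a catalog generated from three well-separated signatures usually
also clusters perfectly stably at rank 2 (two of the clusters merge the same
way in every restart), so "smallest tied rank" would systematically
under-fit. Ties are therefore resolved by *effective rank*: among tied ranks
the largest **saturated** one wins, where a rank is saturated when every
signature of its best run is the dominant signature of at least one sample.
An unsaturated tied rank means the extra signatures dominate nothing — the
classic symptom of over-fitting a degenerate catalog (e.g. identical
duplicated samples), in which case the smallest tied rank is returned. On
simulated three-signature catalogs (30 samples, ~1000 mutations each,
pairwise signature cosine < 0.6) this recovers rank 3 across seeds while
identical-duplicate catalogs resolve to rank 1.

Matching to a reference catalog reports, for each extracted signature
independently, the reference entry with maximal cosine similarity and flags
hits below 0.75 — deliberately *not* a one-to-one assignment, since two
extracted signatures may legitimately resemble the same reference process.
The one-to-one matcher (`match_columns`, exhaustive over permutations at
small K) exists for simulation recovery checks only. Channel order between
extracted and reference matrices must be identical; mismatches are an
error, never a silent reorder.

Per-sample contributions are re-estimated by non-negative least squares of
each catalog column on the normalized signatures rather than read off the
training `H`, so exposures are equally well-defined for held-out samples;
percentage contributions rescale each column to 100 (all-zero and flagged
for empty samples). At 10⁴ mutations per sample, recovered percentages are
within ~1.5 points of the generating truth in the package's own acceptance
run (3 points is the tested bound).

## Permutation association testing

Signature contributions are compared across categorical covariates with the
tie-corrected Kruskal–Wallis H statistic (all-identical values give H = 0 by
convention, guarding the tie-correction denominator). Because the cohorts of
interest are small, significance comes from an empirical permutation
distribution (2000 permutations by default) with the add-one estimator
`p = (1 + #{H* ≥ H}) / (1 + n_perm)`, which never returns 0 and is valid by
construction. Three schemes cover the analysis variants: free label
permutation; within-stratum permutation (per-stratum group composition is
preserved exactly); and Freedman–Lane residual permutation for adjustment —
values are regressed on the indicator design of the nuisance covariates,
residuals are permuted and added back to the fitted values, and H is
recomputed. Freedman–Lane was chosen because it is the standard
permutation-valid treatment of nuisance covariates; with an empty adjustment
set the fitted values are a constant and the procedure reduces *exactly*
(same seed, same permutations, same p) to the plain variant, which the tests
assert. `run_panel()` runs every signature × variant cell with
deterministic per-cell seeds and applies no multiple-testing correction,
mirroring how such exploratory panels are reported.

## Over-representation analysis

Gene-set enrichment of a mutated-gene list is the upper hypergeometric tail
of the query/set overlap within an explicit universe. There is no hidden
background: the universe defaults to the union of all set members and its
size is reported. Sets overlapping the query in fewer than 3 genes are
removed before Benjamini–Hochberg adjustment, and the default report keeps
q < 0.05 — both filters are configuration. Query genes outside the universe
are dropped and reported. Gene sets load from standard GMT files with
symbols uppercased for matching.

## The synthetic cohorts: what they emulate and what they do not

`sim_config(seed)` fixes the study conditions; every generator is a pure
function of it (same seed, byte-identical output, caller's RNG untouched).

* **IHC cohort** (`simulate_cohort`): subtype mixture 134/26/11/48/14
  (luminal A / luminal B / HER2-enriched / triple-negative / undetermined)
  out of 233; per-subtype Ki67 positivity 96/134, 23/26, 10/11, 47/48,
  13/14; 45/48 of triple-negatives basal. Marker percentages are drawn
  consistently with the drawn subtype (e.g. luminal A gets ER > 1% and
  negative HER2), so the subtype caller recovers the truth for every
  determined case. The continuous staining distributions (uniform ranges
  above/below each threshold) are plausible rather than estimated — only
  the positivity rates are cohort-calibrated.
* **Panel call sets** (`simulate_callsets`): 126 cases; the number of
  mutated panel genes per case is drawn from the observed multiplicity
  (46 none / 59 one / 21 more than one) and genes from marginal weights
  TP53 41, PIK3CA 27, AKT1 12, the remaining five genes 21 jointly (of 101
  mutation slots), reproducing the case-level frequencies 63.5% any,
  32.5% TP53, 21.4% PIK3CA in expectation. True somatic VAFs are drawn from
  Beta(5, 15) truncated at 0.04 — plausible FFPE tumor fractions that
  respect the calling threshold by construction. Artifact records each
  violate exactly one filter rule and are placed at positions distinct from
  true variants so truth labels stay unambiguous.
* **TP53 spectrum** (`simulate_tp53_spectrum`): category weights 0.27
  G:C>T:A, 0.20 indel, 0.13 G:C>A:T at CpG, 0.12 G:C>A:T other, 0.10
  A:T>G:C, 0.08 G:C>C:G, 0.06 A:T>T:A, 0.04 A:T>C:G — the headline fraction
  and the observed ordering (G:C>T:A most frequent, indels second) anchor
  the two largest weights; the remainder is a fixed plausible allocation.
  Records are emitted on a random strand with context consistent with their
  category, so the spectrum builder round-trips the weights.
* **Signature catalogs** (`simulate_signatures`/`simulate_catalog`): true
  signatures are sparse Dirichlet draws (concentration 0.1) redrawn until
  pairwise cosines fall below 0.6; exposures are Dirichlet(0.3), totals
  Poisson (1000 per sample in the standard validation, 10⁴ for exposure
  recovery), channels multinomial.
* **Exome counts** (`simulate_exome_counts`): 12 exomes, 2634 expected
  coding mutations of which 2128 non-synonymous SNVs/indels, over a 47 Mb
  capture — giving a mean non-synonymous rate of ~3.8/Mb.

What the generators deliberately do **not** emulate: read-level sequencing
error, realistic genome composition (references are i.i.d. uniform bases),
linkage between markers beyond the subtype definitions, correlated
mutational processes across genes, or inter-gene differences in length and
mutability. Passing the round-trip tests therefore demonstrates that the
pipeline's logic is correct under its stated model, not that the model
captures every property of real FFPE exomes.

## Problem sizes used in validation

The package's own acceptance computations use: the published 233-case
subtype table for the exact tests; one synthetic 126-case panel cohort; 2000
spectrum draws; 12 synthetic exomes; rank selection over ranks 2–6 with 20
restarts on a 30-sample catalog of ~1000 mutations per sample; exposure
recovery at 10⁴ mutations per sample; and 500 null cohorts of 24 samples at
200 permutations each for type-I calibration. These sizes give sampling
errors comfortably inside the tolerances asserted (binomial/multinomial
3-sigma bands), and each stage completes in seconds on a single CPU.

## Known limitations

* The multiplicative-update NMF finds local optima; multi-start with the
  lowest-objective run mitigates but does not eliminate this, and KL-NMF is
  only identifiable up to permutation and only when the data are close to
  separable (the recovery tests anchor identifiability with sparse
  exposures).
* The Monte-Carlo r×c Fisher path estimates, rather than bounds, the exact
  p; its error is reported only through the number of replicates chosen.
* The enrichment module's q-values depend entirely on the user-supplied
  gene-set collection and universe; results are not comparable across
  collections.
* Cophenetic-based rank selection can plateau at 1.0 over several ranks for
  very clean catalogs; the saturation tie-break addresses the common case
  but very small cohorts (fewer samples than plausible ranks) remain hard.
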