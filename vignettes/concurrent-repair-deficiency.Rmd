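---
title: "Methods: mutational signatures of concurrent proofreading and MMR loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutational signatures of concurrent proofreading and MMR loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repairsigs)
```

## Background

Replication fidelity rests on two partially redundant mechanisms: the
exonuclease (proofreading) domains of the replicative polymerases
epsilon (*POLE*, leading strand) and delta (*POLD1*, lagging strand),
and the post-replicative mismatch repair (MMR) pathway. Tumors that
lose either mechanism are hypermutated with characteristic mutational
signatures; tumors that lose *both* acquire signatures that are not the
additive mixture of the individual ones, because a class of replication
errors is repairable by either mechanism and only surfaces when both
are gone. `repairsigs` implements the computational pipeline for
characterizing such tumors end to end:

1. a pentanucleotide + indel **mutation catalog** (1536 SNV channels,
   8 indel size channels),
2. **signature discovery** by Bayesian NMF with automatic relevance
   determination (ARD) and multi-run consensus,
3. **signature comparison** against a reference database by a
   cosine-maximizing two-signature combination fit, with a pairwise
   background and a channel-shuffling permutation null,
4. **genomic covariates**: replication-timing enrichment and
   leading/lagging replicative strand asymmetry, both with bootstrap
   errors, and
5. an **event-ordering test** that uses mutation clonality to ask
   whether the proofreading or the MMR defect came first.

Because the real tumor cohorts behind these analyses are controlled-
access, the package ships a first-class synthetic cohort generator
whose ground truth exercises every stage.

## The channel space

SNVs are encoded by their substitution and the two bases on each side
of the mutated site. With substitutions pyrimidine-centered there are
6 substitution types and 256 four-base flank combinations: 1536
channels. Purine-centered records are reverse-complemented on encoding,
so a mutation and its opposite-strand description always land in the
same channel (`encode_snv_channel("AACGA", "T")` equals
`encode_snv_channel("TCGTT", "A")`). Insertions and deletions occupy
eight further channels by size (1, 2, 3, >= 4 bases). The wide SNV
space exists to separate signatures that collide in the conventional
96-channel trinucleotide space; `collapse_to_trimer()` projects
catalogs and signatures down to 96 channels (summing the 16 pentamer
preimages of each trinucleotide channel) for display and for database
comparison.

Channel ordering is a convention, not biology: substitutions are
ordered C>A, C>G, C>T, T>A, T>C, T>G and contexts lexicographically by
the (-2, -1, +1, +2) flanks. Records with ambiguous bases, or indels
without a usable length, are excluded and counted in the catalog's
`qc` attribute rather than failing the run. Microsatellite-locus
calling for indels is out of scope; an optional per-sample
microsatellite-indel count is consumed as an annotation.

Coordinates are 1-based inclusive everywhere in memory — the R and
Bioconductor convention — while the BED-like track files on disk use
0-based half-open intervals and the tabular mutation format is 1-based.

## The synthetic cohort generator

`simulate_cohort()` draws a cohort from a `cohort_config()`:

* **Genotypes.** Samples are assigned to six genotype classes (MSS,
  MSI, POLE-MSS, POLE-MSI, POLD1-MSI, POLD1-MSS) with configurable
  fractions. The defaults loosely mirror an endometrial cohort: mostly
  MSS and MSI tumors, a minority with proofreading mutations, and a
  small concurrent-deficiency group.
* **Burdens.** Total mutation counts are drawn log-uniformly within a
  per-genotype range. Defaults span roughly 10^2 (MSS) to 10^5
  (POLE-MSI) — hypermutation is the phenomenon, so the generator must
  cover orders of magnitude. These ranges are free parameters of the
  simulation, not a calibration to any published count distribution.
* **Signatures.** Mutations are drawn channel-wise from the genotype's
  mixture over ground-truth signatures. The bundled truth set
  (`synthetic_truth_signatures()`) is deterministic and sparse: each
  signature concentrates ~90% of its mass on one or two trinucleotide
  motifs, spread unevenly over the 16 pentamer preimages so the wide
  channel space carries signal, plus indel mass for the MMR-related
  signatures. Sparse peaked vectors keep the test suite free of any
  external signature database; `read_signature_table()` loads a
  user-supplied table in the standard 96-channel text layout when real
  references are available.
* **Placement.** Each SNV is placed at a reference position whose
  pentamer matches its channel, so re-extraction of context from the
  FASTA always agrees with the record. Optional placement weights per
  timing bin (`timing_bias`) and per substitution on the leading
  template (`strand_bias`) create known enrichment and asymmetry for
  the covariate modules to recover.
* **Clonality.** Clonal mutations receive CCF ~ 1 with narrow 95%
  intervals, subclonal ones CCF ~ U(0.1, 0.5) with wider intervals,
  both truncated to [0, 1]. This makes the interval-based
  clonal/subclonal partition mostly unambiguous while still producing
  an ambiguous band that straddles the 0.75 cut.
* **Event order.** Under `order_scenario = "pole_first"`, a fraction
  (default 0.3) of each POLE-MSI sample's burden is emitted from the
  pure proofreading signature with clonal CCFs only — the mutations
  accumulated between the first event and the second — while the rest
  follows the genotype mixture with the usual clonal fraction.
  `"msi_first"` does the same with the MMR signature.

All randomness flows from one integer seed; identical configurations
yield byte-identical cohorts.

What the generator does **not** emulate: human genome composition and
size (the toy reference is a ~50 kb i.i.d. sequence), exome capture,
germline variation, mutation clustering, or realistic
replication-timing structure (the timing track is a simple positional
partition). Passing tests therefore demonstrate correctness of the
computations under the stated generative model, not performance on
real tumor data.

## Bayesian NMF with automatic relevance determination

`bayes_nmf()` factorizes the catalog `V` (channels x samples) as
`V ~ Poisson(W H)` and minimizes the KL (Poisson) divergence by
multiplicative updates, with exponential (L1-type) priors on each
component's column of `W` and row of `H`. Each component has a
relevance scale `lambda_k`, updated in closed form each iteration as

```
lambda_k = (||w_k||_1 + ||h_k||_1 + b) / (F + N + a + 1)
```

with `F` channels, `N` samples, shape hyperparameter `a = 10`, and `b`
set from the data scale as `sqrt((a - 1) (a - 2) mean(V) / K_max)`.
Superfluous components see their relevance collapse, which feeds back
into the updates as a strong shrinkage (the `1/lambda_k` term) and
drives their mass to zero; at convergence, components whose mass falls
below `1e-8` of the largest are pruned, giving the effective rank
`K_effective`. The full MAP objective is monotone non-increasing under
these updates (asserted in the tests), and convergence is declared when
its relative change falls below `tol` (default `1e-7`, checked every 10
iterations) or after `max_iter` (default 100,000) iterations.

Two numerical notes. First, the MAP solution shrinks activities
slightly relative to raw counts; the deficit scales like
`(F + N + a + 1) / sum(V)`, i.e. it is visible on toy catalogs with a
few thousand mutations and negligible at realistic burdens. Second,
because the likelihood is Poisson on raw counts, hyper-mutated samples
carry proportionally more weight; the wide 1536+8 channel space is the
mechanism that keeps their signatures separable, and no per-sample
reweighting is applied.

`consensus_extraction()` runs the factorization from independent seeds
(default 10 runs), tallies `K_effective` across runs, and returns the
run with the modal rank, breaking ties among modal runs by the lowest
final objective. `fit_activities()` re-estimates `H` for fixed,
externally supplied signatures — the attribution step used when
projecting a catalog onto known or ground-truth signatures.

Per-mutation attribution follows
`P(i | c, p) = w_{c,i} h_{i,p} / sum_j w_{c,j} h_{j,p}`; channels with
zero weight under every signature receive a uniform vector with a
warning.

## Comparing signatures to a reference

`cosine_sim()` compares 96-channel profiles. For a composite process
split across two discovered signatures, `fit_combination()` finds
non-negative coefficients `(alpha1, alpha2)` maximizing the cosine of
`alpha1 C1 + alpha2 C2` against a target. Only the coefficient ratio is
identified; results are normalized to `alpha1 + alpha2 = 1`. The
default solver projects the target onto the plane spanned by the two
components (2x2 normal equations) and clamps to the better single
component whenever the unconstrained optimum would need a negative
coefficient; a golden-section search over the mixing fraction is
available as an alternative, and both are tested against a dense grid.
Non-negativity is enforced by default because signatures are densities
that are summed, but `nonneg = FALSE` gives the unconstrained subspace
fit.

Judging whether a good combination match could arise by chance uses
two backgrounds:

* `pairwise_background()` fits every pair of discovered signatures
  against every reference profile, excluding per-signature lists of
  known true-positive matches. The exclusion lists are a required user
  input — which matches count as "true positives" is a judgment about
  the particular signature set, not something the package can decide.
* `permutation_null()` shuffles each signature's 96 channel values
  (preserving its sorted value set, hence its sparsity), fits all
  pairs against the full reference, and records the best cosine per
  iteration, for 10,000 iterations by default. This estimates how well
  randomized signatures of equivalent sparsity can be made to match by
  two-component overfitting.

## Replication timing and strand asymmetry

For the timing profile, per-channel burdens come from the fitted model,
`lambda_{c,p} = sum_i w_{c,i} h_{i,p}`, and the flat-rate expectation
for substitution type S in a timing bin is

```
n_exp = sum_{c in S} lambda_{c,p} / N_c_global * N_c_bin
```

where the opportunity counts `N_c` are tallied from the supplied
reference and timing track (`opportunity_track()`). Summed over bins
the expectation recovers `sum_{c in S} lambda_{c,p}` exactly — an
identity the tests assert to machine precision. Observed and expected
counts are summed across the selected samples before the ratio
(ratio-of-sums), matching the patient-bootstrap design: patients are
resampled with replacement (default 1000 times) and the SD of the
recomputed ratio reported per cell. Sample selection for genotype
groups uses `select_dominated_samples()`, by default requiring >= 75%
summed activity fraction of the group's signatures. The timing track
is an input; the package does not derive replication timing from
sequencing data.

Strand asymmetry counts the 12 stranded substitution classes by the
template role (leading/lagging) of the strand carrying the A-or-C base
of the mutated pair — the C of a C:G pair for C>N changes, the paired
A for T>N changes. Densities are normalized per channel by the
stranded opportunity counts and then summed within substitution type.
This per-channel normalization is a deliberate choice: normalizing by
the pooled base content of each strand class biases peaked signatures
whenever context composition differs between leading- and
lagging-template regions, whereas the per-channel form is exactly
symmetric under an unbiased mutation process (and exactly recovers a
2:1 placement bias as log2 ratio 1). Errors come from resampling
mutations with replacement (default 1000 times), implemented as a
multinomial redraw over the stranded channel counts. Flipping every
strand label negates all six log2 ratios exactly. Strand labels are
consumed from a BED-like leading-template track; deriving such a track
from replication-timing gradients is left to the user.

## Ordering the two repair-deficiency events

If one defect preceded the other, the first defect's signature had time
to deposit mutations before the second arrived, after which the
concurrent-deficiency signature dominates — so the early signature
should be over-represented among *clonal* mutations. The test:

1. **Clonality.** A mutation is clonal when its 95% CCF interval lies
   entirely above 0.75 (`ccf_lo > 0.75`), subclonal when entirely
   below, ambiguous otherwise. "95% confidence of CCF > 0.75" is
   interpreted through the supplied interval bounds — the closest
   executable reading; ambiguous mutations (including any with missing
   intervals) are excluded.
2. **Eligibility.** Samples qualify when the concurrent-signature
   group contributes at least 100 attributed mutations and at least
   35% of the attributed total (both bounds inclusive).
3. **Masses.** Per-mutation signature probabilities are summed within
   groups (E = proofreading, M = MMR, C = concurrent), separately over
   the clonal and subclonal subsets, giving the four masses of each
   hypothesis.
4. **Resampling.** `ordering_pvalue()` draws 10^6 independent Poisson
   counts around the four masses and reports the fraction of draws in
   which the clonal ratio `n_E*/n_C*` fails to exceed the subclonal
   ratio. Ties count toward that fraction (conservative), and draws
   with a zero reference count in either compartment — where the ratio
   is undefined — are redrawn and tallied. Zero *observed* reference
   mass makes the test inapplicable (`NA`).
5. **Correction.** Both the E-first and M-first hypotheses of every
   eligible sample enter one Benjamini-Hochberg family; significance
   is called at q < 0.1.

Note that when several samples carry very strong signals (p near 0),
BH mechanically lowers the q-values of the remaining hypotheses in the
family; the type-I calibration of the procedure refers to the global
null, which the synthetic `"simultaneous"` scenario realizes.

## Cohort-level statistics

`classify_exo_status()` applies the exonuclease-domain filter (POLE
codons 268–471, POLD1 codons 304–517): only in-domain *missense*
mutations count; splice-site, truncating, and out-of-domain records
are discounted, and POLE hotspots P286R/V411L are labelled. Codons are
taken from the input table as given; no transcript mapping is
performed. Fisher's exact tests use the two-sided minimum-likelihood
convention of `stats::fisher.test` — the sidedness is a convention
choice, made explicit in `fisher_exact(sided = ...)` — and group
comparisons of signature fractions use one-tailed Wilcoxon rank-sum
tests via `stats::wilcox.test` (exact for small untied samples,
continuity-corrected normal approximation otherwise).

## Problem sizes and verification

The test and acceptance suites run entirely on synthetic cohorts sized
for quick, deterministic verification: signature recovery uses 60
samples with burdens 500–20,000 and a 10-run consensus; the covariate
calibrations use 10-sample cohorts with a few thousand mutations each;
ordering calibration uses 200 null samples and 50 `pole_first` samples
at 10^5 Monte-Carlo draws per test, with the symmetric-input anchor
and the oracle comparison at the full 10^6. Monte-Carlo checks are
framed in units of their own standard errors. Brute-force oracles back
the closed-form pieces: a dense grid for the combination fit, full
hypergeometric enumeration for Fisher's test, an independent
re-simulation for the ordering p-value, and exhaustive enumeration for
the channel space.

## Known limitations

* The synthetic reference is tiny and unstructured; opportunity
  counts, timing bins and strand segments are correspondingly simple.
  Real analyses should supply genome-scale tracks.
* ARD hyperparameters (`a`, the derived `b`, and the pruning
  threshold) are standard choices, exposed as arguments; rank
  recovery on real cohorts can be sensitive to them.
* The ordering test's power depends on the attribution model: when
  the early signature's contexts overlap the concurrent signature's,
  clonal mass leaks between groups and power drops — visible in the
  synthetic cohorts as reduced (but still high) detection rates.
* Activities from tiny catalogs are shrunk by the ARD prior (see
  above); compare totals only at realistic burdens.
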