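# Small shared fixtures, built once per test run.

tiny_tracks <- simulate_reference_tracks(2000, 4, seed = 7)

# Single-genotype cohort used by several covariate/ordering tests.
small_cohort <- function(genotype = "POLE-MSS", sigs = c("BKG", "E"),
                         n_samples = 6, burden = c(1000, 4000), seed = 17,
                         ...) {
  mix <- stats::setNames(1, genotype)
  br <- stats::setNames(list(burden), genotype)
  simulate_cohort(cohort_config(
    n_samples = n_samples, genotype_mix = mix, burden_range = br,
    truth_signatures = synthetic_truth_signatures(sigs),
    ref_length = 30000, seed = seed, ...))
}

expect_sums_to <- function(x, total, tol = 1e-8) {
  expect_lt(abs(sum(x) - total), tol * max(1, abs(total)))
}
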