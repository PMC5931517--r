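test_that("opportunity counting partitions exactly across timing bins", {
  tr <- tiny_tracks
  opp <- opportunity_track(tr$reference, tr$timing_track)
  expect_equal(rowSums(opp$N_bin), opp$N_global)
  expect_true(all(opp$N_bin >= 0))
  # channels sharing a pentamer share opportunities (alt plays no role)
  info <- snv_channel_info()
  split_counts <- split(opp$N_global, info$pentamer)
  expect_true(all(vapply(split_counts, function(x) {
    length(unique(x)) == 1
  }, logical(1))))
  # total pentamer windows = positions with full context, double-stranded
  expect_equal(sum(opp$N_global) / 3, nchar(tr$reference) - 4)
})

test_that("lambda burdens follow the W*H arithmetic and conserve totals", {
  W <- matrix(c(0.5, 0.5, 0, 0.2, 0.3, 0.5), ncol = 2)
  H <- matrix(c(100, 40), nrow = 2, dimnames = list(NULL, "p"))
  m <- signature_model(W, H)
  lam <- lambda_channel_burden(m, "p")
  expect_equal(unname(lam),
               c(0.5 * 100 + 0.2 * 40, 0.5 * 100 + 0.3 * 40, 0.5 * 40))
  expect_equal(sum(lam), sum(H))
  # uniform single signature spreads burden evenly
  mu <- signature_model(matrix(1 / 1536, 1536, 1),
                        matrix(100, 1, 1, dimnames = list(NULL, "q")))
  expect_equal(unname(lambda_channel_burden(mu, "q")),
               rep(100 / 1536, 1536))
})

test_that("expected bin counts implement the opportunity-weighted formula", {
  tr <- tiny_tracks
  opp <- opportunity_track(tr$reference, tr$timing_track)
  info <- snv_channel_info()
  set.seed(2)
  lam <- runif(1536) * (opp$N_global > 0)
  for (s in c("C>A", "T>C")) {
    e <- expected_bin_counts(lam, opp, s)
    expect_equal(sum(e), sum(lam[info$substitution == s &
                                   opp$N_global > 0]))
  }
  # a one-bin track puts all expectation in that bin
  one_bin <- tibble::tibble(chrom = "chr1", start = 1,
                            end = nchar(tr$reference), timing_q = "Q1")
  opp1 <- opportunity_track(tr$reference, one_bin)
  e1 <- expected_bin_counts(lam, opp1, "C>T")
  expect_equal(unname(e1), sum(lam[info$substitution == "C>T"]))
  # hand-computed two-channel skew
  opp_toy <- structure(list(
    N_global = stats::setNames(rep(0, 1536), info$label),
    N_bin = matrix(0, 1536, 2, dimnames = list(info$label, c("Q1", "Q2"))),
    bin_labels = c("Q1", "Q2")), class = "opportunity_track")
  opp_toy$N_global[1] <- 10; opp_toy$N_bin[1, ] <- c(7, 3)
  opp_toy$N_global[2] <- 20; opp_toy$N_bin[2, ] <- c(5, 15)
  lam_toy <- numeric(1536); lam_toy[1] <- 30; lam_toy[2] <- 40
  e_toy <- expected_bin_counts(lam_toy, opp_toy, "C>A")
  expect_equal(unname(e_toy), c(30 * 0.7 + 40 * 0.25, 30 * 0.3 + 40 * 0.75))
  # inconsistent reference: burden where no opportunity exists
  lam_bad <- numeric(1536); lam_bad[3] <- 1
  expect_error(expected_bin_counts(lam_bad, opp_toy, "C>A"),
               "zero global opportunity")
})

test_that("flat-placement cohorts give enrichment 1 within bootstrap error", {
  co <- small_cohort(n_samples = 8, burden = c(2000, 6000), seed = 44)
  W <- co$truth$signatures
  model <- fit_activities(build_catalog(co$mutations), W)
  opp <- opportunity_track(co$reference, co$timing_track)
  tp <- timing_profile(co$mutations, model, opp, n_boot = 300, seed = 2)
  expect_equal(nrow(tp), 8)
  mm <- co$mutations[co$mutations$substitution %in% c("C>A", "C>T") &
                       !is.na(co$mutations$timing_bin), ]
  recount <- as.vector(table(mm$timing_bin, mm$substitution))
  expect_equal(tp$observed, recount)
  z <- abs(tp$enrichment - 1) / tp$boot_sd
  expect_lt(max(z), 3)
  # per-substitution conservation of observed counts
  tot <- tapply(tp$observed, tp$substitution, sum)
  muts <- co$mutations[!is.na(co$mutations$timing_bin), ]
  expect_equal(unname(tot["C>A"]),
               sum(muts$substitution == "C>A", na.rm = TRUE))
})

test_that("a late-bin rate bias appears at its expected enrichment", {
  # placement weights (2/3, 2/3, 2/3, 2) have mean 1, so the late bin
  # should sit near enrichment 2 and the early bins near 2/3
  co <- small_cohort(n_samples = 8, burden = c(2000, 6000), seed = 45,
                     timing_bias = c(2 / 3, 2 / 3, 2 / 3, 2))
  model <- fit_activities(build_catalog(co$mutations), co$truth$signatures)
  opp <- opportunity_track(co$reference, co$timing_track)
  tp <- timing_profile(co$mutations, model, opp, n_boot = 300, seed = 2)
  late <- tp$enrichment[tp$timing_bin == "Q4"]
  early <- tp$enrichment[tp$timing_bin == "Q1"]
  expect_true(all(abs(late - 2) < 0.15))
  expect_true(all(abs(early - 2 / 3) < 0.1))
  ft <- timing_slope_ftest(tp)
  expect_true(all(ft$slope > 0))
})

test_that("patient bootstrap SDs behave at the degenerate and convergent ends", {
  O <- matrix(c(5, 10, 20, 40), ncol = 2)
  E <- matrix(c(4, 12, 18, 44), ncol = 2)
  # single patient: resampling a singleton is deterministic
  sd1 <- bootstrap_patients(O[1, , drop = FALSE], E[1, , drop = FALSE],
                            n_boot = 50, seed = 1)
  expect_equal(sd1, c(0, 0))
  # fixed seed reproducibility
  expect_identical(bootstrap_patients(O, E, n_boot = 100, seed = 3),
                   bootstrap_patients(O, E, n_boot = 100, seed = 3))
  # convergence: a 200-rep SD is within 20% of a 5000-rep SD
  set.seed(9)
  O2 <- matrix(rpois(40, 30), ncol = 2)
  E2 <- matrix(rep(30, 40), ncol = 2)
  s_small <- bootstrap_patients(O2, E2, n_boot = 200, seed = 5)
  s_big <- bootstrap_patients(O2, E2, n_boot = 5000, seed = 6)
  expect_true(all(abs(s_small - s_big) / s_big < 0.2))
})

test_that("strand asymmetry is null for symmetric cohorts and scales with bias", {
  co <- small_cohort(n_samples = 8, burden = c(3000, 8000), seed = 46)
  sa <- strand_asymmetry(co$mutations, co$reference, co$strand_track,
                         n_boot = 300, seed = 4)
  expect_equal(nrow(sa), 6)
  expect_true(all(abs(sa$log2_ratio) < 3 * sa$log2_sd))
  # stranded counts conserve the labelled SNV total
  labelled <- sum(!is.na(co$mutations$strand_label) &
                    co$mutations$variant_class == "SNV")
  expect_equal(sum(sa$n_leading + sa$n_lagging), labelled)

  bias <- stats::setNames(c(2, 1, 1, 1, 1, 1),
                          c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"))
  co2 <- small_cohort(n_samples = 8, burden = c(3000, 8000), seed = 47,
                      strand_bias = bias)
  sa2 <- strand_asymmetry(co2$mutations, co2$reference, co2$strand_track,
                          n_boot = 300, seed = 4)
  expect_lt(abs(sa2$log2_ratio[sa2$substitution == "C>A"] - 1),
            3 * sa2$log2_sd[sa2$substitution == "C>A"])

  # antisymmetry: flipping every strand role negates the ratios
  m3 <- co2$mutations
  m3$strand_label <- ifelse(m3$strand_label == "leading",
                            "lagging", "leading")
  st3 <- co2$strand_track
  st3$leading_template <- ifelse(st3$leading_template == "+", "-", "+")
  sa3 <- strand_asymmetry(m3, co2$reference, st3, n_boot = 10, seed = 4)
  expect_equal(sa3$log2_ratio, -sa2$log2_ratio, tolerance = 1e-12)
})

test_that("sample selection by dominant signature honors the fraction cut", {
  H <- matrix(c(80, 20, 60, 40, 99, 1), nrow = 2,
              dimnames = list(c("E", "BKG"), c("a", "b", "c")))
  m <- signature_model(matrix(1 / 1544, 1544, 2), H)
  expect_setequal(select_dominated_samples(m, "E", 0.75), c("a", "c"))
  expect_setequal(select_dominated_samples(m, c("E", "BKG"), 0.75),
                  c("a", "b", "c"))
})
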