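test_that("rank-1 catalogs collapse to a single component recovering the profile", {
  set.seed(4)
  profile <- numeric(1544)
  profile[sample(1536, 12)] <- runif(12)
  profile <- profile / sum(profile)
  burdens <- round(runif(12, 500, 5000))
  V <- round(profile %o% burdens)
  rownames(V) <- all_channels()
  colnames(V) <- paste0("P", seq_along(burdens))
  m <- bayes_nmf(V, k_max = 6, max_iter = 3000, seed = 2)
  expect_equal(m$K_effective, 1L)
  expect_gt(cosine_sim(m$W[, 1], profile), 0.999)
  # the ARD prior shrinks activities slightly on small catalogs
  expect_equal(unname(colSums(m$H)), unname(colSums(V)), tolerance = 0.05)
})

test_that("the MAP objective trace is non-increasing", {
  co <- small_cohort(genotype = "MSI", sigs = c("BKG", "M"),
                     n_samples = 8, burden = c(300, 2000), seed = 6)
  V <- build_catalog(co$mutations)
  m <- bayes_nmf(V, k_max = 6, max_iter = 1500, seed = 3)
  tr <- m$objective_trace
  expect_true(all(diff(tr) <= 1e-6 * abs(tr[-length(tr)])))
})

test_that("degenerate NMF inputs are rejected or clamped", {
  V <- matrix(0, 10, 3)
  expect_error(bayes_nmf(V), "all zero")
  V2 <- matrix(rpois(30, 5), 10, 3)
  expect_warning(m <- bayes_nmf(V2, k_max = 8, max_iter = 200, seed = 1),
                 "clamping")
  expect_lte(m$K_effective, 3)
})

test_that("consensus picks the modal rank, breaking ties by objective", {
  co <- small_cohort(genotype = "MSI", sigs = c("BKG", "M"),
                     n_samples = 10, burden = c(500, 3000), seed = 8)
  V <- build_catalog(co$mutations)
  cf <- consensus_extraction(V, n_runs = 3, k_max = 5, max_iter = 1500,
                             seed = 40)
  expect_s3_class(cf, "consensus_fit")
  ks <- cf$report$K_effective
  tab <- table(ks)
  expect_true(cf$modal_k %in% as.integer(names(tab)[tab == max(tab)]))
  in_modal <- cf$report$K_effective == cf$modal_k
  expect_equal(cf$report$final_objective[cf$report$chosen],
               min(cf$report$final_objective[in_modal]))
  expect_equal(cf$model$K_effective, cf$modal_k)
  # single-run consensus returns that run
  cf1 <- consensus_extraction(V, n_runs = 1, k_max = 5, max_iter = 800,
                              seed = 41)
  expect_true(cf1$report$chosen[1])
})

test_that("per-mutation probabilities follow the w*h normalization", {
  W <- matrix(c(2, 1, 0, 1,
                0, 1, 0, 2), ncol = 2)   # channel 3 unseen by both
  H <- matrix(c(10, 2,
                5, 5), nrow = 2, byrow = TRUE)
  colnames(H) <- c("p1", "p2")
  m <- signature_model(W, H)
  # the W-column normalization cancels in the ratio, so the expected
  # probability is W[c, ] * H[, p] renormalized — small-integer arithmetic:
  # channel 2, sample p1: (1*10, 1*5) / 15
  p <- mutation_signature_probabilities(m, 2, "p1")
  expect_equal(unname(p[1, ]), c(10, 5) / 15)
  # channel 4, sample p2: (1*2, 2*5) / 12
  expect_equal(unname(mutation_signature_probabilities(m, 4, "p2")[1, ]),
               c(2, 10) / 12)
  expect_equal(rowSums(mutation_signature_probabilities(
    m, c(1, 2, 4), c("p1", "p2", "p1"))), rep(1, 3),
    ignore_attr = TRUE)
  # K = 1: probability 1
  m1 <- signature_model(W[, 1, drop = FALSE], H[1, , drop = FALSE])
  expect_equal(unname(mutation_signature_probabilities(m1, 2, "p2")[1, ]), 1)
  # channel unseen under all signatures -> uniform with warning
  expect_warning(pu <- mutation_signature_probabilities(m, 3, "p1"),
                 "unseen")
  expect_equal(unname(pu[1, ]), c(0.5, 0.5))
})

test_that("activity fractions sum to one per sample and flag zero burdens", {
  W <- synthetic_truth_signatures(c("BKG", "E"))
  H <- matrix(c(100, 0, 0,
                300, 50, 0), nrow = 2, byrow = TRUE,
              dimnames = list(c("BKG", "E"), c("a", "b", "c")))
  m <- signature_model(W, H)
  af <- activity_fractions(m)
  sums <- tapply(af$fraction, af$sample, sum)
  expect_equal(as.vector(sums[c("a", "b")]), c(1, 1))
  expect_true(all(is.na(af$fraction[af$sample == "c"])))
  expect_equal(af$fraction[af$sample == "b" & af$signature == "E"], 1)
})

test_that("fixed-signature activity fitting recovers known mixtures", {
  W <- synthetic_truth_signatures(c("BKG", "E", "M"))
  H <- matrix(c(200, 800, 100,
                50, 100, 900), nrow = 3,
              dimnames = list(colnames(W), c("x", "y")))
  V <- W %*% H
  m <- fit_activities(V, W, n_iter = 800)
  expect_equal(unname(m$H), unname(H), tolerance = 0.02)
})

test_that("genotype groups show elevated fractions of their generating signature", {
  W <- synthetic_truth_signatures(c("BKG", "E", "M"))
  cfg <- cohort_config(
    n_samples = 24,
    genotype_mix = c(MSS = 1 / 3, MSI = 1 / 3, `POLE-MSS` = 1 / 3),
    burden_range = list(MSS = c(300, 1000), MSI = c(300, 1000),
                        `POLE-MSS` = c(300, 1000)),
    truth_signatures = W, ref_length = 30000, seed = 25)
  co <- simulate_cohort(cfg)
  m <- fit_activities(build_catalog(co$mutations), W)
  af <- activity_fractions(m) |>
    dplyr::left_join(co$annotations[, c("sample", "genotype")], by = "sample")
  e_pole <- af$fraction[af$signature == "E" & af$genotype == "POLE-MSS"]
  e_mss <- af$fraction[af$signature == "E" & af$genotype == "MSS"]
  m_msi <- af$fraction[af$signature == "M" & af$genotype == "MSI"]
  m_mss <- af$fraction[af$signature == "M" & af$genotype == "MSS"]
  expect_lt(rank_sum_test(e_pole, e_mss), 0.01)
  expect_lt(rank_sum_test(m_msi, m_mss), 0.01)
})

test_that("tidiers expose profiles and fit summaries", {
  co <- small_cohort(n_samples = 3, burden = c(200, 500), seed = 13)
  m <- bayes_nmf(build_catalog(co$mutations), k_max = 3, max_iter = 500,
                 seed = 1)
  td <- tidy(m)
  expect_named(td, c("channel", "signature", "weight"))
  expect_equal(nrow(td), 1544 * m$K_effective)
  gl <- glance(m)
  expect_equal(gl$K_effective, m$K_effective)
  expect_equal(nrow(gl), 1)
})
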