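test_that("reference tracks partition the sequence without overlap", {
  tr <- simulate_reference_tracks(400, 4, seed = 2)
  tt <- tr$timing_track
  expect_equal(nrow(tt), 4)
  expect_equal(tt$start[1], 1)
  expect_equal(tt$end[4], 400)
  expect_true(all(tt$start[-1] == tt$end[-4] + 1))
  expect_equal(sum(tt$end - tt$start + 1), 400)
  st <- tr$strand_track
  expect_true(all(st$start[-1] == st$end[-nrow(st)] + 1))
  expect_equal(sum(st$end - st$start + 1), 400)
  expect_setequal(unique(st$leading_template), c("+", "-"))

  expect_error(simulate_reference_tracks(0, 4), "positive")
  expect_error(simulate_reference_tracks(10, 4), "5 \\* n_bins")
  # determinism of base composition
  tr2 <- simulate_reference_tracks(400, 4, seed = 2)
  expect_identical(tr$reference, tr2$reference)
})

test_that("cohort generation is deterministic and conserves burdens", {
  cfg <- cohort_config(n_samples = 4, genotype_mix = c(MSS = 0.5, MSI = 0.5),
                       burden_range = list(MSS = c(100, 300),
                                           MSI = c(200, 500)),
                       ref_length = 20000, seed = 5)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1$mutations, co2$mutations)
  expect_identical(co1$annotations, co2$annotations)
  # conservation: emitted mutations per sample equal realized draws
  expect_equal(colSums(co1$truth$realized_counts),
               colSums(co1$truth$realized_signature_counts))
  tallies <- table(co1$mutations$sample)
  expect_equal(as.vector(tallies[colnames(co1$truth$realized_counts)]),
               unname(colSums(co1$truth$realized_counts)))
})

test_that("an empty cohort is valid", {
  cfg <- cohort_config(n_samples = 0, seed = 1)
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co$mutations), 0)
  expect_equal(nrow(co$annotations), 0)
  expect_identical(dim(co$truth$realized_counts), c(1544L, 0L))
  d <- withr::local_tempdir()
  write_cohort(co, d)
  expect_true(all(file.exists(file.path(d, c("mutations.tsv",
                                             "annotations.tsv",
                                             "reference.fa",
                                             "timing.bed", "strand.bed",
                                             "truth.json")))))
})

test_that("single-signature draws match a brute-force multinomial recount", {
  W1 <- synthetic_truth_signatures("E")
  cfg <- cohort_config(n_samples = 1, genotype_mix = c(`POLE-MSS` = 1),
                       burden_range = list(`POLE-MSS` = c(1000, 1000)),
                       truth_signatures = W1,
                       genotype_signature_weights =
                         matrix(1, 1, 1, dimnames = list("POLE-MSS", "E")),
                       ref_length = 30000, seed = 9)
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co$mutations), 1000)
  recount <- table(factor(co$mutations$channel, levels = 1:1544))
  expect_equal(unname(co$truth$realized_counts[, 1]), as.vector(recount))
})

test_that("config validation rejects inconsistent inputs", {
  expect_error(cohort_config(genotype_mix = c(MSS = 0.5, MSI = 0.4)),
               "sum to 1")
  expect_error(cohort_config(genotype_mix = c(XXX = 1)), "unknown genotype")
  W <- synthetic_truth_signatures()
  Wbad <- W * 2
  expect_error(cohort_config(truth_signatures = Wbad), "sum to 1")
  expect_error(
    cohort_config(genotype_mix = c(MSS = 1),
                  burden_range = list(MSS = c(500, 100))),
    "burden_range")
})

test_that("annotations reflect genotypes and generator truth fractions", {
  cfg <- cohort_config(n_samples = 40,
                       genotype_mix = c(MSS = 0.5, `POLE-MSI` = 0.25,
                                        MSI = 0.25),
                       burden_range = list(MSS = c(50, 100),
                                           `POLE-MSI` = c(200, 400),
                                           MSI = c(100, 200)),
                       ref_length = 20000, seed = 12)
  co <- simulate_cohort(cfg)
  tab <- table(co$annotations$genotype)
  expect_equal(unname(tab[c("MSS", "POLE-MSI", "MSI")]),
               as.vector(c(20L, 10L, 10L)), ignore_attr = TRUE)
  ct <- crosstab(co$annotations, "genotype", "msi_status")
  expect_equal(sum(ct[["MSI-H"]], ct[["MSS"]]), 40)
  expect_true(all(co$annotations$pole_exo_status[
    co$annotations$genotype == "POLE-MSI"] == "exo*"))
})

test_that("pole_first cohorts enrich signature E among clonal mutations", {
  co <- small_cohort(genotype = "POLE-MSI", sigs = c("BKG", "E", "M", "C"),
                     n_samples = 6, burden = c(1000, 2000), seed = 31,
                     order_scenario = "pole_first")
  mm <- partition_clonality(co$mutations)
  cl <- mm$clonality == "clonal"
  sc <- mm$clonality == "subclonal"
  f_cl <- mean(mm$true_signature[cl] == "E")
  f_sc <- mean(mm$true_signature[sc] == "E")
  expect_gt(f_cl, f_sc)
  # under the simultaneous scenario there is no such excess
  co0 <- small_cohort(genotype = "POLE-MSI", sigs = c("BKG", "E", "M", "C"),
                      n_samples = 6, burden = c(1000, 2000), seed = 31)
  mm0 <- partition_clonality(co0$mutations)
  f0_cl <- mean(mm0$true_signature[mm0$clonality == "clonal"] == "E")
  f0_sc <- mean(mm0$true_signature[mm0$clonality == "subclonal"] == "E")
  expect_lt(abs(f0_cl - f0_sc), 0.05)
})

test_that("CCF intervals give mostly unambiguous clonality labels", {
  co <- small_cohort(n_samples = 4, burden = c(500, 1000), seed = 3)
  mm <- partition_clonality(co$mutations)
  expect_true(all(co$mutations$ccf_lo <= co$mutations$ccf))
  expect_true(all(co$mutations$ccf <= co$mutations$ccf_hi))
  expect_gt(mean(mm$clonality != "ambiguous"), 0.9)
  # truth labels drive the partition
  agree <- mm$clonality == ifelse(mm$clonal_truth, "clonal", "subclonal")
  expect_gt(mean(agree[mm$clonality != "ambiguous"]), 0.95)
})
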