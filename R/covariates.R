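#' Count mutation opportunities per channel, globally and per timing bin
#'
#' For each of the 1536 pentanucleotide channels, counts the positions
#' of the reference whose pyrimidine-centered pentamer (on either
#' strand) matches the channel's context — the number of sites where a
#' mutation of that channel could occur. Counts are computed per timing
#' interval; the global count is the sum over bins, so the partition
#' identity holds exactly.
#'
#' @param reference character sequence, [Biostrings::DNAString] or
#'   single-sequence [Biostrings::DNAStringSet].
#' @param timing_track tibble with `start`, `end` (1-based inclusive)
#'   and `timing_q` labels partitioning the sequence.
#' @return object of class `opportunity_track`: `N_global` (named
#'   1536-vector), `N_bin` (1536 x bins matrix), `bin_labels`.
#' @export
opportunity_track <- function(reference, timing_track) {
  seqchr <- reference_as_character(reference)
  dna <- Biostrings::DNAString(seqchr)
  L <- length(dna)
  bins <- unique(timing_track$timing_q)
  info <- snv_channel_info()
  counts <- matrix(0, nrow = 1536L, ncol = length(bins),
                   dimnames = list(info$label, bins))
  for (i in seq_len(nrow(timing_track))) {
    s <- timing_track$start[i]; e <- timing_track$end[i]
    lo <- max(1L, s - 2L); hi <- min(L, e + 2L)
    if (hi - lo + 1L < 5L) next
    pf <- Biostrings::oligonucleotideFrequency(
      Biostrings::subseq(dna, lo, hi), width = 5)
    pyr <- pf[info$pentamer] + pf[revcomp(info$pentamer)]
    counts[, timing_track$timing_q[i]] <-
      counts[, timing_track$timing_q[i]] + pyr
  }
  structure(list(N_global = rowSums(counts), N_bin = counts,
                 bin_labels = bins), class = "opportunity_track")
}

#' Per-channel expected mutation burden of a sample
#'
#' `lambda[c] = sum_i W[c, i] * H[i, p]` — the model-attributed burden
#' of channel `c` in sample `p`. Summed over channels this recovers the
#' sample's total attributed mutation count.
#'
#' @param model a `signature_model`.
#' @param sample a sample id (column of `model$H`).
#' @return named numeric vector over the model's channels.
#' @export
lambda_channel_burden <- function(model, sample) {
  p <- match(sample, colnames(model$H))
  if (is.na(p)) stop("unknown sample id: ", sample)
  drop(model$W %*% model$H[, p])
}

#' Expected per-bin mutation counts under a flat background rate
#'
#' Distributes a sample's per-channel burden over timing bins in
#' proportion to the channel's opportunity counts:
#' `n_exp[bin] = sum_{c in S} lambda[c] / N_global[c] * N_bin[c, bin]`.
#' Summed over bins this equals `sum_{c in S} lambda[c]` exactly.
#'
#' @param lambda per-channel burden vector (at least the 1536 SNV
#'   channels, e.g. from [lambda_channel_burden()]).
#' @param opportunities an [opportunity_track()].
#' @param substitution substitution type, e.g. `"C>A"`.
#' @return named numeric vector over timing bins.
#' @export
expected_bin_counts <- function(lambda, opportunities, substitution) {
  info <- snv_channel_info()
  idx <- which(info$substitution == substitution)
  lam <- lambda[idx]
  Ng <- opportunities$N_global[idx]
  if (any(lam > 0 & Ng == 0)) {
    stop("positive burden on channels with zero global opportunity; ",
         "reference and catalog are inconsistent")
  }
  ok <- Ng > 0
  drop(crossprod(opportunities$N_bin[idx[ok], , drop = FALSE],
                 lam[ok] / Ng[ok]))
}

#' Replication-timing mutation-density enrichment profile
#'
#' For each substitution type and timing bin, aggregates observed
#' mutation counts and flat-rate expected counts
#' ([expected_bin_counts()]) over the selected samples
#' (ratio-of-sums), and reports the enrichment `observed / expected`
#' with a patient-bootstrap standard deviation. Enrichment is 1 in
#' every bin when mutations fall proportionally to opportunity.
#'
#' @param mutations annotated mutation tibble (needs `channel`,
#'   `substitution`, `timing_bin`, `sample`; see
#'   [annotate_mutations()]).
#' @param model a `signature_model` providing per-channel burdens.
#' @param opportunities an [opportunity_track()].
#' @param samples samples to aggregate (default: all model samples).
#' @param substitutions substitution types to profile; the default
#'   covers the two most frequent types in proofreading/MMR-deficient
#'   tumors.
#' @param n_boot patient-bootstrap replicates for the SD.
#' @param seed integer seed for the bootstrap.
#' @return tibble of class `enrichment_profile`: one row per
#'   (substitution, bin) with `observed`, `expected`, `enrichment`,
#'   `boot_sd`, `n_samples`.
#' @export
timing_profile <- function(mutations, model, opportunities,
                           samples = colnames(model$H),
                           substitutions = c("C>A", "C>T"),
                           n_boot = 1000, seed = 1) {
  if (!length(samples)) stop("no samples selected")
  bins <- opportunities$bin_labels
  mm <- mutations |>
    dplyr::filter(.data$sample %in% samples,
                  .data$substitution %in% substitutions,
                  !is.na(.data$timing_bin))
  O <- table(factor(mm$sample, levels = samples),
             factor(mm$substitution, levels = substitutions),
             factor(mm$timing_bin, levels = bins))
  E <- array(0, dim = dim(O), dimnames = dimnames(O))
  for (p in seq_along(samples)) {
    lam <- lambda_channel_burden(model, samples[p])
    for (s in substitutions) {
      E[p, s, ] <- expected_bin_counts(lam, opportunities, s)
    }
  }
  nS <- length(substitutions); nB <- length(bins)
  Om <- matrix(O, nrow = length(samples))
  Em <- matrix(E, nrow = length(samples))
  point <- colSums(Om) / colSums(Em)
  sds <- bootstrap_patients(Om, Em, n_boot = n_boot, seed = seed)
  tibble::tibble(
    substitution = rep(substitutions, times = nB),
    timing_bin = rep(bins, each = nS),
    observed = colSums(Om),
    expected = colSums(Em),
    enrichment = point,
    boot_sd = sds,
    n_samples = length(samples)
  ) |>
    dplyr::arrange(.data$substitution, .data$timing_bin) |>
    structure(class = c("enrichment_profile", "tbl_df", "tbl", "data.frame"))
}

#' Patient-bootstrap standard deviations of an observed/expected ratio
#'
#' Resamples patients (rows) with replacement `n_boot` times and
#' returns the SD of the recomputed ratio-of-sums for each column. A
#' single patient yields SD 0 everywhere.
#'
#' @param observed,expected patients x cells numeric matrices.
#' @param n_boot number of bootstrap replicates.
#' @param seed integer seed.
#' @return numeric vector of SDs, one per column.
#' @export
bootstrap_patients <- function(observed, expected, n_boot = 1000, seed = 1) {
  P <- nrow(observed)
  stopifnot(P >= 1, all(dim(observed) == dim(expected)))
  withr::with_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(P, P, replace = TRUE)
      colSums(observed[idx, , drop = FALSE]) /
        colSums(expected[idx, , drop = FALSE])
    }, numeric(ncol(observed)))
  })
  if (ncol(observed) == 1L) reps <- matrix(reps, nrow = 1)
  apply(reps, 1, stats::sd)
}

#' Per-channel stranded opportunity counts for replicative asymmetry
#'
#' For each of the 1536 pentanucleotide channels, counts the reference
#' positions matching the channel's pyrimidine-centered context whose
#' A-or-C base (the C of a C:G pair for C>N channels, the paired A for
#' T>N channels) sits on the leading vs the lagging strand template.
#' These are the denominators for stranded mutational densities;
#' normalizing per channel — rather than by the pooled base content of
#' each strand class — keeps the densities symmetric under an unbiased
#' mutation process even when context composition differs between
#' leading- and lagging-template regions.
#'
#' @param reference sequence (character or Biostrings).
#' @param strand_track tibble with `start`, `end`, `leading_template`
#'   (`"+"`/`"-"`).
#' @return 1536 x 2 matrix (`"leading"`, `"lagging"` columns), rows
#'   aligned with [snv_channels()].
#' @export
strand_opportunities <- function(reference, strand_track) {
  seqchr <- reference_as_character(reference)
  L <- nchar(seqchr)
  pos <- 3:(L - 2)
  pent <- substring(seqchr, pos - 2L, pos + 2L)
  center <- substr(pent, 3, 3)
  strand <- ifelse(center %in% c("C", "T"), "+", "-")
  pent_pyr <- ifelse(strand == "+", pent, revcomp(pent))
  lead <- strand_track$leading_template[interval_lookup(pos, strand_track)]
  keep <- !is.na(lead) & !grepl("[^ACGT]", pent)
  # A-or-C strand: the pyrimidine strand for C-centered contexts, the
  # opposite strand for T-centered contexts (tracking the paired A)
  pyr_center <- substr(pent_pyr, 3, 3)
  ac_strand <- ifelse(pyr_center == "C", strand,
                      ifelse(strand == "+", "-", "+"))
  label <- ifelse(ac_strand == lead, "leading", "lagging")
  tab <- table(factor(pent_pyr[keep], levels = sort(unique(snv_channel_info()$pentamer))),
               factor(label[keep], levels = c("leading", "lagging")))
  info <- snv_channel_info()
  out <- unclass(tab)[info$pentamer, , drop = FALSE]
  rownames(out) <- info$label
  out
}

#' Replicative strand asymmetry profile
#'
#' Computes the 12 stranded mutational densities (6 substitution types x
#' leading/lagging template position of the mutated pair's A-or-C base)
#' and the 6 `log2(leading / lagging)` asymmetry ratios, with
#' mutation-bootstrap standard deviations. Each substitution type's
#' stranded density is the sum over its channels of the per-channel
#' count divided by that channel's stranded opportunity
#' ([strand_opportunities()]); channels lacking opportunity on either
#' strand are excluded from both sides. A ratio is reported `NA` when
#' either strand has zero mutations (no pseudo-counts).
#'
#' @param mutations annotated mutation tibble with `channel` and
#'   `strand_label` (see [annotate_mutations()]).
#' @param reference,strand_track inputs for [strand_opportunities()].
#' @param samples samples to include (default all).
#' @param n_boot mutation-bootstrap replicates.
#' @param seed integer seed.
#' @return tibble of class `asymmetry_profile`: per substitution type,
#'   stranded counts and densities, `log2_ratio`, `log2_sd`.
#' @export
strand_asymmetry <- function(mutations, reference, strand_track,
                             samples = unique(mutations$sample),
                             n_boot = 1000, seed = 1) {
  mm <- mutations |>
    dplyr::filter(.data$sample %in% samples,
                  .data$variant_class == "SNV",
                  !is.na(.data$strand_label),
                  !is.na(.data$channel))
  if (!nrow(mm)) stop("no stranded SNVs among the selected samples")
  opp <- strand_opportunities(reference, strand_track)
  valid <- opp[, 1] > 0 & opp[, 2] > 0
  cnt <- table(factor(mm$channel, levels = 1:1536),
               factor(mm$strand_label, levels = c("leading", "lagging")))
  cnt <- unclass(cnt)
  sub_of <- snv_channel_info()$substitution
  grp <- factor(sub_of, levels = SUBSTITUTIONS)
  dens_chan <- (cnt / opp) * valid          # n_c / N_c per side
  dens_chan[!is.finite(dens_chan)] <- 0
  dens <- rowsum(dens_chan, grp)
  n_side <- rowsum(cnt * valid, grp)
  ratio <- ifelse(n_side[, 1] > 0 & n_side[, 2] > 0,
                  log2(dens[, 1] / dens[, 2]), NA_real_)
  # mutation bootstrap: resampling mutation rows is a multinomial
  # redraw over the 1536 x 2 stranded channel counts
  N <- sum(cnt)
  withr::with_seed(seed, {
    B <- stats::rmultinom(n_boot, N, as.vector(cnt) / N)
  })
  wl <- ifelse(valid, 1 / opp[, 1], 0)
  wg <- ifelse(valid, 1 / opp[, 2], 0)
  Bl <- B[1:1536, , drop = FALSE] * wl
  Bg <- B[1537:3072, , drop = FALSE] * wg
  dl <- rowsum(Bl, grp); dg <- rowsum(Bg, grp)
  lr <- log2(dl / dg)
  lr[!is.finite(lr)] <- NA
  tibble::tibble(
    substitution = SUBSTITUTIONS,
    n_leading = as.vector(n_side[, 1]), n_lagging = as.vector(n_side[, 2]),
    leading_density = as.vector(dens[, 1]),
    lagging_density = as.vector(dens[, 2]),
    leading_sd = apply(dl, 1, stats::sd),
    lagging_sd = apply(dg, 1, stats::sd),
    log2_ratio = as.vector(ratio),
    log2_sd = apply(lr, 1, stats::sd, na.rm = TRUE)
  ) |>
    structure(class = c("asymmetry_profile", "tbl_df", "tbl", "data.frame"))
}

#' F-test on the slope of a timing enrichment profile
#'
#' Regresses enrichment on the timing-bin index and reports the F-test
#' for a non-zero slope, per substitution type. A diagnostic utility
#' for synthetic profiles (four points per substitution).
#'
#' @param profile an [timing_profile()] result.
#' @return tibble with `substitution`, `slope`, `f_statistic`,
#'   `p_value`.
#' @export
timing_slope_ftest <- function(profile) {
  profile |>
    dplyr::group_by(.data$substitution) |>
    dplyr::reframe({
      idx <- seq_along(.data$enrichment)
      fit <- stats::lm(.data$enrichment ~ idx)
      an <- stats::anova(fit)
      tibble::tibble(slope = stats::coef(fit)[2],
                     f_statistic = an$`F value`[1],
                     p_value = an$`Pr(>F)`[1])
    })
}

#' Select samples whose spectra are dominated by a signature group
#'
#' Mirrors the ">75\% contribution" style selection used when profiling
#' genotype groups: a sample qualifies when the summed activity
#' fraction of the named signatures reaches `min_fraction`.
#'
#' @param model a `signature_model`.
#' @param signatures character vector of signature names (rows of
#'   `model$H`).
#' @param min_fraction minimum summed fraction (default 0.75).
#' @return character vector of sample ids.
#' @export
select_dominated_samples <- function(model, signatures,
                                     min_fraction = 0.75) {
  H <- model$H
  frac <- colSums(H[signatures, , drop = FALSE]) / colSums(H)
  colnames(H)[!is.na(frac) & frac >= min_fraction]
}
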