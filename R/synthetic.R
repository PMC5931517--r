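GENOTYPES <- c("MSS", "MSI", "POLE-MSS", "POLE-MSI", "POLD1-MSI", "POLD1-MSS")

#' Ground-truth signatures for synthetic cohorts
#'
#' Sparse, peaked signature vectors over the 1544-channel space
#' (1536 pentanucleotide SNV channels + 8 indel size channels), built
#' deterministically so tests carry no external signature database:
#' \describe{
#'   \item{BKG}{flat background over all SNV channels (aging/noise).}
#'   \item{E}{proofreading-deficient polymerase epsilon: peaks at the
#'     pentamer preimages of T\[C>A\]T and T\[C>T\]G.}
#'   \item{M}{mismatch-repair deficiency: C>T at CpG-like contexts plus
#'     1-base indel mass.}
#'   \item{C}{concurrent proofreading + MMR loss: G\[C>A\]T and
#'     T\[C>T\]T peaks with some 1-base deletions.}
#'   \item{D}{POLD1-proofreading + MMR loss: C\[C>T\]T peak with heavy
#'     1-base deletion mass.}
#' }
#' Within each peaked trimer motif, mass is spread unevenly over the 16
#' pentamer preimages so the -2/+2 context carries real signal.
#'
#' @param which subset of signature names to return.
#' @return numeric matrix, 1544 channels x signatures, columns sum to 1.
#' @export
synthetic_truth_signatures <- function(which = c("BKG", "E", "M", "C", "D")) {
  info <- snv_channel_info()
  n <- 1544L
  pent_weights <- exp(-(0:15) / 3)          # uneven spread over preimages
  pent_weights <- pent_weights / sum(pent_weights)
  peak <- function(trimer, mass) {
    v <- numeric(n)
    idx <- which(info$trimer == trimer)
    v[idx] <- mass * pent_weights
    v
  }
  indel_mass <- function(ch, mass) {
    v <- numeric(n)
    v[1536L + match(ch, indel_channels())] <- mass
    v
  }
  flat_snv <- c(rep(1 / 1536, 1536), numeric(8))
  sigs <- list(
    BKG = flat_snv,
    E   = peak("T[C>A]T", 0.50) + peak("T[C>T]G", 0.44) + 0.06 * flat_snv,
    M   = peak("A[C>T]G", 0.28) + peak("G[C>T]G", 0.22) + peak("T[C>T]G", 0.12) +
          indel_mass(c("DEL1", "INS1"), c(0.20, 0.10)) + 0.08 * flat_snv,
    C   = peak("G[C>A]T", 0.48) + peak("T[C>T]T", 0.32) +
          indel_mass("DEL1", 0.12) + 0.08 * flat_snv,
    D   = peak("C[C>T]T", 0.46) + indel_mass("DEL1", 0.30) +
          peak("T[A>G]T", 0.16) + 0.08 * flat_snv
  )
  W <- vapply(sigs[which], function(v) v / sum(v), numeric(n))
  rownames(W) <- all_channels()
  W
}

default_genotype_weights <- function(sig_names = c("BKG", "E", "M", "C", "D")) {
  w <- rbind(
    `MSS`       = c(BKG = 1.00, E = 0,    M = 0,    C = 0,    D = 0),
    `MSI`       = c(BKG = 0.25, E = 0,    M = 0.75, C = 0,    D = 0),
    `POLE-MSS`  = c(BKG = 0.15, E = 0.85, M = 0,    C = 0,    D = 0),
    `POLE-MSI`  = c(BKG = 0.05, E = 0.12, M = 0.08, C = 0.75, D = 0),
    `POLD1-MSI` = c(BKG = 0.05, E = 0,    M = 0.25, C = 0,    D = 0.70),
    `POLD1-MSS` = c(BKG = 0.70, E = 0,    M = 0,    C = 0,    D = 0.30)
  )
  w <- w[, sig_names, drop = FALSE]
  sweep(w, 1, rowSums(w), "/")
}

#' Configuration of a synthetic tumor cohort
#'
#' Bundles every knob of the generator: genotype composition, per-sample
#' mutation burdens (drawn log-uniformly within `burden_range`, spanning
#' the orders of magnitude seen across MSS, MSI and
#' proofreading-deficient tumors), ground-truth signatures and their
#' per-genotype mixtures, microsatellite-indel summary rates, clonality
#' structure, and the event-order scenario.
#'
#' @param n_samples number of tumors.
#' @param genotype_mix named fractions over the six genotype labels
#'   (must sum to 1).
#' @param burden_range named list of `c(min, max)` total mutation counts
#'   per genotype.
#' @param ms_indel_rate named per-genotype mean microsatellite-indel
#'   count (annotation summary only).
#' @param truth_signatures channels x signatures matrix, columns
#'   non-negative and summing to 1 (default
#'   [synthetic_truth_signatures()]).
#' @param genotype_signature_weights genotype x signature mixing matrix,
#'   rows summing to 1.
#' @param clonal_fraction fraction of ordinary mutations drawn clonal.
#' @param ccf_noise_sd spread of the CCF interval half-width.
#' @param order_scenario `"simultaneous"`, `"pole_first"` or
#'   `"msi_first"`; the *_first scenarios emit an extra clonal-only
#'   mutation mass from signature E (or M) in POLE-MSI samples,
#'   emulating mutations accumulated between the first and second
#'   repair-loss events.
#' @param early_mass_fraction fraction of a POLE-MSI sample's burden
#'   emitted as that clonal-only early mass under a *_first scenario.
#' @param timing_bias length-4 relative mutation rate per replication
#'   timing quartile (flat by default).
#' @param strand_bias named per-substitution leading:lagging placement
#'   ratio for the A-or-C base (1 = symmetric).
#' @param ref_length,n_timing_bins toy reference geometry.
#' @param seed single integer; all randomness flows from it.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 60,
                          genotype_mix = c(`MSS` = 0.40, `MSI` = 0.28,
                                           `POLE-MSS` = 0.14, `POLE-MSI` = 0.10,
                                           `POLD1-MSI` = 0.05, `POLD1-MSS` = 0.03),
                          burden_range = list(
                            `MSS` = c(100, 1000), `MSI` = c(1000, 8000),
                            `POLE-MSS` = c(5000, 50000), `POLE-MSI` = c(10000, 100000),
                            `POLD1-MSI` = c(3000, 30000), `POLD1-MSS` = c(1000, 10000)),
                          ms_indel_rate = c(`MSS` = 3, `MSI` = 300,
                                            `POLE-MSS` = 10, `POLE-MSI` = 250,
                                            `POLD1-MSI` = 200, `POLD1-MSS` = 8),
                          truth_signatures = synthetic_truth_signatures(),
                          genotype_signature_weights =
                            default_genotype_weights(colnames(truth_signatures)),
                          clonal_fraction = 0.8,
                          ccf_noise_sd = 0.03,
                          order_scenario = c("simultaneous", "pole_first", "msi_first"),
                          early_mass_fraction = 0.3,
                          timing_bias = c(1, 1, 1, 1),
                          strand_bias = stats::setNames(rep(1, 6), SUBSTITUTIONS),
                          ref_length = 50000,
                          n_timing_bins = 4,
                          seed = 1) {
  order_scenario <- match.arg(order_scenario)
  genotype_mix <- genotype_mix[genotype_mix > 0]
  if (n_samples > 0 && abs(sum(genotype_mix) - 1) > 1e-8) {
    stop("genotype_mix fractions must sum to 1")
  }
  if (!all(names(genotype_mix) %in% GENOTYPES)) {
    stop("unknown genotype label in genotype_mix")
  }
  if (is.null(colnames(truth_signatures)) || ncol(truth_signatures) == 0) {
    stop("truth_signatures must be a named, non-empty signature matrix")
  }
  if (any(truth_signatures < 0) ||
      any(abs(colSums(truth_signatures) - 1) > 1e-6)) {
    stop("truth signatures must be non-negative and sum to 1")
  }
  for (g in names(genotype_mix)) {
    br <- burden_range[[g]]
    if (is.null(br) || br[1] > br[2] || br[1] < 1) {
      stop("invalid burden_range for genotype ", g)
    }
  }
  structure(list(
    n_samples = n_samples, genotype_mix = genotype_mix,
    burden_range = burden_range, ms_indel_rate = ms_indel_rate,
    truth_signatures = truth_signatures,
    genotype_signature_weights = genotype_signature_weights,
    clonal_fraction = clonal_fraction, ccf_noise_sd = ccf_noise_sd,
    order_scenario = order_scenario, early_mass_fraction = early_mass_fraction,
    timing_bias = timing_bias, strand_bias = strand_bias,
    ref_length = ref_length, n_timing_bins = n_timing_bins, seed = seed
  ), class = "cohort_config")
}

#' Generate a toy reference sequence with timing and strand tracks
#'
#' The timing track partitions the sequence into `n_bins` contiguous
#' intervals labelled `Q1..Qn` (replication-timing quartiles when
#' `n_bins = 4`); the strand track halves each timing interval and
#' alternates which reference strand acts as the leading-strand
#' template.
#'
#' @param length sequence length (>= 5 * n_bins).
#' @param n_bins number of timing intervals.
#' @param seed integer seed.
#' @return list with `reference` (character sequence), `timing_track`
#'   and `strand_track` tibbles (1-based inclusive `start`/`end`).
#' @export
simulate_reference_tracks <- function(length, n_bins = 4, seed = 1) {
  if (length <= 0) stop("length must be positive")
  if (length < 5 * n_bins) stop("length must be at least 5 * n_bins")
  withr::with_seed(seed, {
    seq <- paste(sample(BASES, length, replace = TRUE,
                        prob = c(0.30, 0.20, 0.20, 0.30)), collapse = "")
    cuts <- round(seq_len(n_bins - 1) * length / n_bins)
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, length)
    timing <- tibble::tibble(
      chrom = "chr1", start = as.integer(starts), end = as.integer(ends),
      timing_q = paste0("Q", seq_len(n_bins))
    )
    mids <- floor((starts + ends) / 2)
    strand <- tibble::tibble(
      chrom = "chr1",
      start = as.integer(c(rbind(starts, mids + 1L))),
      end = as.integer(c(rbind(mids, ends))),
      leading_template = rep_len(c("+", "-"), 2L * n_bins)
    )
    list(reference = seq, timing_track = timing, strand_track = strand)
  })
}

# Index every position of the reference by its pyrimidine-centered
# pentamer, with the strand the pyrimidine sits on, the timing bin, and
# the strand label the position would receive for C-centered vs
# T-centered substitutions.
build_position_index <- function(reference, timing_track, strand_track) {
  L <- nchar(reference)
  pos <- 3:(L - 2)
  pent <- substring(reference, pos - 2L, pos + 2L)
  center <- substr(pent, 3, 3)
  strand <- ifelse(center %in% c("C", "T"), "+", "-")
  pent_pyr <- ifelse(strand == "+", pent, revcomp(pent))
  bin <- timing_track$timing_q[interval_lookup(pos, timing_track)]
  lead <- strand_track$leading_template[interval_lookup(pos, strand_track)]
  # A-or-C strand: C-centered channels -> pyrimidine strand; T-centered
  # channels -> the paired A, i.e. the opposite strand.
  opp <- ifelse(strand == "+", "-", "+")
  label_c <- ifelse(strand == lead, "leading", "lagging")
  label_t <- ifelse(opp == lead, "leading", "lagging")
  df <- data.frame(pos = pos, strand = strand, pent_pyr = pent_pyr,
                   bin = bin, label_c = label_c, label_t = label_t,
                   stringsAsFactors = FALSE)
  split(df, df$pent_pyr)
}

draw_ccfs <- function(n, clonal, noise_sd) {
  ccf <- numeric(n); hw <- numeric(n)
  nc <- sum(clonal)
  ccf[clonal] <- pmin(1, stats::rnorm(nc, 0.95, 0.03))
  hw[clonal] <- abs(stats::rnorm(nc, 0.06, noise_sd)) + 0.01
  ns <- n - nc
  ccf[!clonal] <- stats::runif(ns, 0.10, 0.50)
  hw[!clonal] <- abs(stats::rnorm(ns, 0.10, noise_sd)) + 0.02
  tibble::tibble(ccf = ccf,
                 ccf_lo = pmax(0, ccf - hw),
                 ccf_hi = pmin(1, ccf + hw))
}

#' Generate a synthetic cohort with full ground truth
#'
#' Draws per-sample burdens, realizes mutations channel-wise from each
#' genotype's signature mixture, places SNVs at reference positions
#' matching their pentamer context (honoring any timing/strand placement
#' bias), attaches CCF point estimates and 95\% intervals with a
#' clonal/subclonal structure, and emits per-sample annotations plus a
#' POLE/POLD1 gene-mutation table consistent with each genotype. Under
#' `order_scenario = "pole_first"` an extra clonal-only mass of
#' signature-E mutations is emitted in POLE-MSI samples (symmetrically
#' for `"msi_first"` and signature M).
#'
#' @param config a [cohort_config()].
#' @return object of class `synthetic_cohort`: list with `mutations`,
#'   `annotations`, `gene_mutations`, `reference`, `timing_track`,
#'   `strand_track`, and `truth` (the config, realized channel counts,
#'   and realized per-sample signature counts).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  tracks <- simulate_reference_tracks(config$ref_length, config$n_timing_bins,
                                      seed = config$seed + 1000L)
  withr::with_seed(config$seed, {
    W <- config$truth_signatures
    sig_names <- colnames(W)
    n <- config$n_samples
    if (n == 0) {
      return(empty_cohort(config, tracks, sig_names))
    }
    # genotype assignment by largest remainder, then sample order shuffled
    mix <- config$genotype_mix
    counts <- floor(mix * n)
    rem <- n - sum(counts)
    if (rem > 0) {
      extra <- order(mix * n - counts, decreasing = TRUE)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1
    }
    genotype <- sample(rep(names(mix), counts))
    samples <- sprintf("S%03d", seq_len(n))

    br <- config$burden_range
    burden <- vapply(genotype, function(g) {
      r <- br[[g]]
      round(exp(stats::runif(1, log(r[1]), log(r[2]))))
    }, numeric(1))

    idx <- build_position_index(tracks$reference, tracks$timing_track,
                                tracks$strand_track)
    info <- snv_channel_info()

    per_sample <- vector("list", n)
    sig_counts <- matrix(0, nrow = length(sig_names), ncol = n,
                         dimnames = list(sig_names, samples))
    gw <- config$genotype_signature_weights
    scenario <- config$order_scenario
    early_sig <- switch(scenario, pole_first = "E", msi_first = "M", NULL)
    for (s in seq_len(n)) {
      g <- genotype[s]
      B <- burden[s]
      weights <- gw[g, ]
      n_early <- 0L
      if (!is.null(early_sig) && g == "POLE-MSI" && early_sig %in% sig_names) {
        n_early <- round(config$early_mass_fraction * B)
      }
      k_sig <- as.vector(stats::rmultinom(1, B - n_early, weights))
      names(k_sig) <- sig_names
      sig_of <- rep(rep(sig_names, k_sig))
      clonal <- stats::runif(B - n_early) < config$clonal_fraction
      if (n_early > 0) {
        sig_of <- c(rep(early_sig, n_early), sig_of)
        clonal <- c(rep(TRUE, n_early), clonal)
        k_sig[early_sig] <- k_sig[early_sig] + n_early
      }
      sig_counts[, s] <- k_sig
      # channel draw per mutation, grouped by generating signature
      channel <- integer(length(sig_of))
      for (sg in sig_names[k_sig > 0]) {
        rows <- which(sig_of == sg)
        channel[rows] <- sample.int(1544L, length(rows), replace = TRUE,
                                    prob = W[, sg])
      }
      per_sample[[s]] <- tibble::tibble(
        sample = samples[s], channel = channel,
        true_signature = sig_of, clonal_truth = clonal
      )
    }
    muts <- dplyr::bind_rows(per_sample)

    muts <- materialize_mutations(muts, idx, info, tracks, config)
    ccfs <- draw_ccfs(nrow(muts), muts$clonal_truth, config$ccf_noise_sd)
    muts <- dplyr::bind_cols(muts, ccfs)
    muts <- annotate_mutations(muts, tracks$timing_track, tracks$strand_track)

    ann <- make_annotations(samples, genotype, muts, config)
    gene_muts <- make_gene_mutations(samples, genotype, ann)

    realized <- build_catalog(muts, include_indels = TRUE, samples = samples)
    structure(list(
      mutations = muts, annotations = ann, gene_mutations = gene_muts,
      reference = tracks$reference, timing_track = tracks$timing_track,
      strand_track = tracks$strand_track,
      truth = list(config = config, signatures = W,
                   realized_counts = realized,
                   realized_signature_counts = sig_counts)
    ), class = "synthetic_cohort")
  })
}

empty_cohort <- function(config, tracks, sig_names) {
  structure(list(
    mutations = tibble::tibble(
      sample = character(), chrom = character(), pos = integer(),
      ref = character(), alt = character(), variant_class = character(),
      pentamer = character(), indel_len = integer(), ccf = numeric(),
      ccf_lo = numeric(), ccf_hi = numeric()
    ),
    annotations = tibble::tibble(
      sample = character(), genotype = character(),
      pole_exo_status = character(), pold1_exo_status = character(),
      msi_status = character(), mlh1_silenced = logical(),
      ms_indel_count = integer(), total_snv = integer()
    ),
    gene_mutations = tibble::tibble(
      sample = character(), gene = character(), codon = integer(),
      consequence = character(), protein_change = character()
    ),
    reference = tracks$reference, timing_track = tracks$timing_track,
    strand_track = tracks$strand_track,
    truth = list(config = config, signatures = config$truth_signatures,
                 realized_counts = build_catalog(
                   tibble::tibble(sample = character(),
                                  variant_class = character(),
                                  pentamer = character(), alt = character(),
                                  indel_len = integer()),
                   samples = character()),
                 realized_signature_counts =
                   matrix(0, length(sig_names), 0,
                          dimnames = list(sig_names, NULL)))
  ), class = "synthetic_cohort")
}

materialize_mutations <- function(muts, idx, info, tracks, config) {
  L <- nchar(tracks$reference)
  is_snv <- muts$channel <= 1536L
  out <- muts
  out$chrom <- "chr1"
  out$pos <- NA_integer_
  out$ref <- NA_character_
  out$alt <- NA_character_
  out$pentamer <- NA_character_
  out$variant_class <- ifelse(is_snv, "SNV",
                              ifelse(muts$channel <= 1540L, "INS", "DEL"))
  out$indel_len <- NA_integer_

  tb <- stats::setNames(config$timing_bias,
                        paste0("Q", seq_along(config$timing_bias)))
  sb <- config$strand_bias
  flat <- all(tb == tb[1]) && all(sb == 1)

  snv_rows <- which(is_snv)
  if (length(snv_rows)) {
    ch <- muts$channel[snv_rows]
    pent <- info$pentamer[ch]
    sub <- info$substitution[ch]
    alt_pyr <- substr(sub, 3, 3)
    grp <- split(seq_along(snv_rows), paste(pent, sub))
    for (g in grp) {
      cand <- idx[[pent[g[1]]]]
      if (is.null(cand)) {
        # pentamer absent from a very short toy reference: fall back to a
        # present context with the same center base and re-encode, so the
        # emitted tally still matches the drawn burden exactly
        center <- substr(pent[g[1]], 3, 3)
        avail <- names(idx)[substr(names(idx), 3, 3) == center]
        repl <- avail[1]
        pent[g] <- repl
        cand <- idx[[repl]]
        out$channel[snv_rows[g]] <- encode_snv_channel(rep(repl, length(g)),
                                                       alt_pyr[g])
      }
      prob <- NULL
      if (!flat) {
        lab <- if (substr(sub[g[1]], 1, 1) == "C") cand$label_c else cand$label_t
        prob <- tb[cand$bin] * ifelse(lab == "leading", sb[[sub[g[1]]]], 1)
      }
      pick <- cand[sample.int(nrow(cand), length(g), replace = TRUE,
                              prob = prob), ]
      rows <- snv_rows[g]
      out$pos[rows] <- pick$pos
      plus <- pick$strand == "+"
      out$ref[rows] <- ifelse(plus, substr(pent[g], 3, 3),
                              comp_base(substr(pent[g], 3, 3)))
      out$alt[rows] <- ifelse(plus, alt_pyr[g], comp_base(alt_pyr[g]))
      out$pentamer[rows] <- ifelse(plus, pent[g], revcomp(pent[g]))
    }
  }

  ind_rows <- which(out$variant_class != "SNV")
  if (length(ind_rows)) {
    ch <- out$channel[ind_rows] - 1536L
    size_class <- ifelse(ch > 4L, ch - 4L, ch)
    len <- ifelse(size_class < 4L, size_class,
                  pmin(4L + stats::rpois(length(ind_rows), 1), 12L))
    pos <- sample(3:(L - 20L), length(ind_rows), replace = TRUE)
    anchor <- extract_pentamer(tracks$reference, pos)
    anchor1 <- substr(anchor, 3, 3)
    is_ins <- out$variant_class[ind_rows] == "INS"
    ins_seq <- vapply(len, function(k) {
      paste(sample(BASES, k, replace = TRUE), collapse = "")
    }, character(1))
    out$pos[ind_rows] <- pos
    out$indel_len[ind_rows] <- as.integer(len)
    out$ref[ind_rows] <- ifelse(is_ins, anchor1,
                                substring(tracks$reference, pos, pos + len))
    out$alt[ind_rows] <- ifelse(is_ins, paste0(anchor1, ins_seq), anchor1)
    out$pentamer[ind_rows] <- NA_character_
  }
  out
}

make_annotations <- function(samples, genotype, muts, config) {
  snv_tab <- muts |>
    dplyr::filter(.data$variant_class == "SNV") |>
    dplyr::count(.data$sample)
  total_snv <- stats::setNames(rep(0L, length(samples)), samples)
  total_snv[snv_tab$sample] <- snv_tab$n
  is_msi <- grepl("MSI", genotype)
  pole <- grepl("^POLE", genotype)
  pold1 <- grepl("^POLD1", genotype)
  hotspot <- ifelse(pole,
                    sample(c("P286R", "V411L", "other"), length(samples),
                           replace = TRUE, prob = c(0.5, 0.25, 0.25)),
                    NA_character_)
  mlh1 <- rep(NA, length(samples))
  mlh1[is_msi] <- stats::runif(sum(is_msi)) <
    ifelse(pole[is_msi], 0.4, 0.75)
  tibble::tibble(
    sample = samples, genotype = genotype,
    pole_exo_status = ifelse(pole, "exo*", "WT"),
    pole_hotspot = hotspot,
    pold1_exo_status = ifelse(pold1, "exo*", "WT"),
    msi_status = ifelse(is_msi, "MSI-H", "MSS"),
    mlh1_silenced = mlh1,
    ms_indel_count = stats::rpois(length(samples),
                                  config$ms_indel_rate[genotype]),
    total_snv = as.integer(total_snv)
  )
}

# A small POLE/POLD1 mutation table consistent with each genotype, plus
# decoy records (out-of-domain missense, in-domain truncating) that a
# correct exonuclease-domain classifier must ignore.
make_gene_mutations <- function(samples, genotype, ann) {
  rows <- list()
  for (s in seq_along(samples)) {
    g <- genotype[s]
    if (grepl("^POLE", g)) {
      codon <- switch(ann$pole_hotspot[s], P286R = 286L, V411L = 411L,
                      sample(c(297L, 305L, 368L, 424L, 459L), 1))
      pc <- switch(ann$pole_hotspot[s], P286R = "P286R", V411L = "V411L",
                   paste0("X", codon, "Y"))
      rows[[length(rows) + 1]] <- tibble::tibble(
        sample = samples[s], gene = "POLE", codon = codon,
        consequence = "missense", protein_change = pc)
    }
    if (grepl("^POLD1", g)) {
      codon <- sample(c(316L, 318L, 402L, 478L), 1)
      rows[[length(rows) + 1]] <- tibble::tibble(
        sample = samples[s], gene = "POLD1", codon = codon,
        consequence = "missense", protein_change = paste0("X", codon, "Y"))
    }
    # decoys
    if (stats::runif(1) < 0.08) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        sample = samples[s], gene = "POLE", codon = 500L,
        consequence = "missense", protein_change = "A500B")
    }
    if (stats::runif(1) < 0.05) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        sample = samples[s], gene = "POLE", codon = 300L,
        consequence = "nonsense", protein_change = "E300*")
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(sample = character(), gene = character(),
                          codon = integer(), consequence = character(),
                          protein_change = character()))
  }
  dplyr::bind_rows(rows)
}
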