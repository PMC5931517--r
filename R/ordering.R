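#' Partition mutations into clonal / subclonal / ambiguous
#'
#' A mutation is clonal when its 95\% CCF interval lies entirely above
#' 0.75 (`ccf_lo > 0.75`), subclonal when entirely below
#' (`ccf_hi < 0.75`), and ambiguous otherwise (interval straddles 0.75,
#' or missing bounds). Ambiguous mutations are excluded from the
#' ordering test.
#'
#' @param mutations tibble with `ccf_lo` and `ccf_hi` columns.
#' @param threshold CCF cut point (default 0.75).
#' @return the tibble with a `clonality` factor column added.
#' @export
partition_clonality <- function(mutations, threshold = 0.75) {
  lo <- mutations$ccf_lo
  hi <- mutations$ccf_hi
  if (anyNA(lo) || anyNA(hi)) {
    warning(sum(is.na(lo) | is.na(hi)),
            " mutation(s) with missing CCF interval treated as ambiguous")
  }
  cl <- dplyr::case_when(
    is.na(lo) | is.na(hi) ~ "ambiguous",
    lo > threshold ~ "clonal",
    hi < threshold ~ "subclonal",
    TRUE ~ "ambiguous"
  )
  mutations$clonality <- factor(cl, levels = c("clonal", "subclonal",
                                               "ambiguous"))
  mutations
}

#' Samples eligible for the event-ordering test
#'
#' A sample qualifies when the reference signature group (the
#' concurrent-deficiency signatures) contributes at least
#' `min_mutations` attributed mutations and at least `min_fraction` of
#' its total attributed burden; both bounds are inclusive.
#'
#' @param model a `signature_model`.
#' @param group_c character vector of reference-group signature names
#'   (rows of `model$H`).
#' @param min_mutations minimum attributed mutation count (default
#'   100).
#' @param min_fraction minimum attributed fraction (default 0.35).
#' @return character vector of eligible sample ids.
#' @export
select_ordering_candidates <- function(model, group_c,
                                       min_mutations = 100,
                                       min_fraction = 0.35) {
  H <- model$H
  mass <- colSums(H[group_c, , drop = FALSE])
  frac <- mass / colSums(H)
  colnames(H)[mass >= min_mutations & !is.na(frac) & frac >= min_fraction]
}

#' Clonal and subclonal signature-group masses of a sample
#'
#' Sums per-mutation signature probabilities
#' ([mutation_signature_probabilities()]) within each signature group,
#' separately over the clonal and subclonal mutation subsets (ambiguous
#' mutations are dropped).
#'
#' @param mutations annotated, clonality-partitioned mutation tibble
#'   for one or more samples (`channel`, `sample`, `clonality`).
#' @param model a `signature_model`.
#' @param groups named list mapping group label to signature names,
#'   e.g. `list(E = c("E1","E2","E3"), M = c("M1","M2"), C = c("C1","C2"))`.
#' @return tibble with one row per (sample, group): `clonal_mass`,
#'   `subclonal_mass`.
#' @export
signature_group_masses <- function(mutations, model, groups) {
  mm <- mutations |>
    dplyr::filter(!is.na(.data$channel),
                  .data$clonality %in% c("clonal", "subclonal"))
  if (!nrow(mm)) {
    return(tibble::tibble(sample = character(), group = character(),
                          clonal_mass = numeric(),
                          subclonal_mass = numeric()))
  }
  probs <- mutation_signature_probabilities(model, mm$channel, mm$sample)
  gm <- vapply(groups, function(g) {
    rowSums(probs[, g, drop = FALSE])
  }, numeric(nrow(mm)))
  df <- tibble::as_tibble(gm)
  df$sample <- mm$sample
  df$clonality <- mm$clonality
  df |>
    tidyr::pivot_longer(dplyr::all_of(names(groups)), names_to = "group",
                        values_to = "p") |>
    dplyr::group_by(.data$sample, .data$group) |>
    dplyr::summarise(
      clonal_mass = sum(.data$p[.data$clonality == "clonal"]),
      subclonal_mass = sum(.data$p[.data$clonality == "subclonal"]),
      .groups = "drop"
    )
}

#' Poisson ratio-resampling p-value for clonal signature enrichment
#'
#' Tests whether a target signature group's mutations are enriched
#' among clonal relative to subclonal mutations, against the reference
#' (concurrent-deficiency) group. Draws `n_draws` independent Poisson
#' counts around the four observed masses and reports the fraction of
#' draws in which the clonal ratio fails to exceed the subclonal ratio
#' (`x_c / y_c <= x_s / y_s`, evaluated by cross-multiplication). Small
#' p indicates the target signature's mutations are clonally enriched —
#' evidence its causal event came first. Draws with a zero reference
#' count in either compartment (undefined ratio) are redrawn and
#' counted.
#'
#' @param n_target_clonal,n_ref_clonal,n_target_subclonal,n_ref_subclonal
#'   observed (probability-summed) mutation masses.
#' @param n_draws Monte-Carlo sample size (default 1e6).
#' @param seed integer seed.
#' @return list: `p_value`, `n_draws`, `n_redrawn`.
#' @export
ordering_pvalue <- function(n_target_clonal, n_ref_clonal,
                            n_target_subclonal, n_ref_subclonal,
                            n_draws = 1e6, seed = 1) {
  if (n_ref_clonal <= 0 || n_ref_subclonal <= 0) {
    return(list(p_value = NA_real_, n_draws = n_draws, n_redrawn = 0L))
  }
  n_redrawn <- 0L
  withr::with_seed(seed, {
    xc <- stats::rpois(n_draws, n_target_clonal)
    yc <- stats::rpois(n_draws, n_ref_clonal)
    xs <- stats::rpois(n_draws, n_target_subclonal)
    ys <- stats::rpois(n_draws, n_ref_subclonal)
    bad <- which(yc == 0L | ys == 0L)
    while (length(bad)) {
      n_redrawn <- n_redrawn + length(bad)
      xc[bad] <- stats::rpois(length(bad), n_target_clonal)
      yc[bad] <- stats::rpois(length(bad), n_ref_clonal)
      xs[bad] <- stats::rpois(length(bad), n_target_subclonal)
      ys[bad] <- stats::rpois(length(bad), n_ref_subclonal)
      bad <- bad[yc[bad] == 0L | ys[bad] == 0L]
    }
    p <- mean(as.numeric(xc) * as.numeric(ys) <=
                as.numeric(xs) * as.numeric(yc))
  })
  list(p_value = p, n_draws = n_draws, n_redrawn = n_redrawn)
}

#' Order repair-deficiency events from mutation clonality
#'
#' Full ordering pipeline: partitions mutations by clonality, selects
#' samples with substantial reference-group (concurrent-signature)
#' contributions, computes clonal/subclonal signature-group masses, and
#' runs the Poisson ratio-resampling test for both the
#' "target-E-first" and "target-M-first" hypotheses. Both hypotheses of
#' every eligible sample enter a single Benjamini-Hochberg family;
#' significance is called at `q < q_threshold`.
#'
#' @param mutations annotated mutation tibble (`channel`, `sample`,
#'   `ccf_lo`, `ccf_hi`).
#' @param model a `signature_model`.
#' @param groups named list with entries `E`, `M` (target groups) and
#'   `C` (reference group), each a character vector of signature names.
#' @param min_mutations,min_fraction eligibility thresholds
#'   ([select_ordering_candidates()]).
#' @param n_draws Monte-Carlo draws per test.
#' @param seed integer seed; per-test seeds are derived from it.
#' @param q_threshold significance threshold on the BH-adjusted q.
#' @return tibble of class `ordering_result`: one row per (sample,
#'   hypothesis) with the four masses, `p_value`, `q_value`,
#'   `significant`.
#' @export
order_events <- function(mutations, model,
                         groups = list(E = "E", M = "M", C = "C"),
                         min_mutations = 100, min_fraction = 0.35,
                         n_draws = 1e6, seed = 1, q_threshold = 0.1) {
  stopifnot(all(c("E", "M", "C") %in% names(groups)))
  eligible <- select_ordering_candidates(model, groups$C,
                                         min_mutations, min_fraction)
  if (!length(eligible)) {
    return(structure(tibble::tibble(
      sample = character(), hypothesis = character(),
      n_target_clonal = numeric(), n_ref_clonal = numeric(),
      n_target_subclonal = numeric(), n_ref_subclonal = numeric(),
      p_value = numeric(), q_value = numeric(), significant = logical()
    ), class = c("ordering_result", "tbl_df", "tbl", "data.frame"),
    q_threshold = q_threshold, n_draws = n_draws))
  }
  mm <- mutations |> dplyr::filter(.data$sample %in% eligible)
  mm <- partition_clonality(mm)
  masses <- signature_group_masses(mm, model, groups) |>
    tidyr::pivot_wider(names_from = "group",
                       values_from = c("clonal_mass", "subclonal_mass"))
  rows <- list()
  for (i in seq_len(nrow(masses))) {
    for (target in c("E", "M")) {
      tc <- masses[[paste0("clonal_mass_", target)]][i]
      ts <- masses[[paste0("subclonal_mass_", target)]][i]
      rc <- masses[["clonal_mass_C"]][i]
      rs <- masses[["subclonal_mass_C"]][i]
      test_seed <- (seed + 7L * i + ifelse(target == "E", 0L, 1L)) %% .Machine$integer.max
      pv <- ordering_pvalue(tc, rc, ts, rs, n_draws = n_draws,
                            seed = test_seed)
      rows[[length(rows) + 1]] <- tibble::tibble(
        sample = masses$sample[i],
        hypothesis = paste0(target, "_first"),
        n_target_clonal = tc, n_ref_clonal = rc,
        n_target_subclonal = ts, n_ref_subclonal = rs,
        p_value = pv$p_value
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out$q_value <- NA_real_
  ok <- !is.na(out$p_value)
  out$q_value[ok] <- stats::p.adjust(out$p_value[ok], method = "BH")
  out$significant <- !is.na(out$q_value) & out$q_value < q_threshold
  structure(out, class = c("ordering_result", "tbl_df", "tbl", "data.frame"),
            q_threshold = q_threshold, n_draws = n_draws)
}

#' Clonal vs subclonal 96-channel spectra
#'
#' Trinucleotide spectra of the clonal and subclonal mutation subsets
#' of each sample, for inspecting which signature dominates each
#' compartment.
#'
#' @param mutations clonality-partitioned, annotated mutation tibble.
#' @return tibble with `sample`, `clonality`, `channel` (96-space
#'   label), `count`.
#' @export
clonality_spectra <- function(mutations) {
  mm <- mutations |>
    dplyr::filter(.data$variant_class == "SNV", !is.na(.data$channel),
                  .data$clonality %in% c("clonal", "subclonal"))
  map <- trimer_collapse_map()
  mm$trimer <- trimer_channels()[map[mm$channel]]
  mm |>
    dplyr::count(.data$sample, .data$clonality, .data$trimer,
                 name = "count") |>
    dplyr::rename(channel = "trimer")
}
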