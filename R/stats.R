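POLE_EXO_DOMAIN <- c(268L, 471L)
POLD1_EXO_DOMAIN <- c(304L, 517L)

#' Classify polymerase exonuclease-domain status from a mutation table
#'
#' A sample is called `exo*` for a gene when it carries at least one
#' missense mutation inside that polymerase's exonuclease (proofreading)
#' domain — POLE codons 268-471, POLD1 codons 304-517. Out-of-domain
#' mutations, splice-site mutations and loss-of-function (nonsense /
#' frameshift) mutations are discounted. POLE hotspot labels P286R and
#' V411L are attached when seen.
#'
#' @param gene_mutations tibble with `sample`, `gene`, `codon`,
#'   `consequence` (and optionally `protein_change`). Recognised
#'   consequences: `missense`, `nonsense`, `frameshift`, `splice_site`,
#'   `synonymous`; others are skipped with a warning.
#' @param samples character vector of all sample ids (so mutation-free
#'   samples are reported WT).
#' @param gene `"POLE"` or `"POLD1"`.
#' @param domain codon interval; defaults to the gene's exonuclease
#'   domain.
#' @return tibble with `sample`, `status` (`"exo*"`/`"WT"`), `hotspot`
#'   (`"P286R"`, `"V411L"` or `NA`).
#' @export
classify_exo_status <- function(gene_mutations, samples,
                                gene = c("POLE", "POLD1"),
                                domain = NULL) {
  gene <- match.arg(gene)
  if (is.null(domain)) {
    domain <- if (gene == "POLE") POLE_EXO_DOMAIN else POLD1_EXO_DOMAIN
  }
  gm <- gene_mutations |> dplyr::filter(.data$gene == !!gene)
  known <- c("missense", "nonsense", "frameshift", "splice_site",
             "synonymous")
  unknown <- !gm$consequence %in% known
  if (any(unknown)) {
    warning(sum(unknown), " record(s) with unrecognised consequence skipped")
    gm <- gm[!unknown, , drop = FALSE]
  }
  hits <- gm |>
    dplyr::filter(.data$consequence == "missense",
                  .data$codon >= domain[1], .data$codon <= domain[2])
  status <- tibble::tibble(sample = samples,
                           status = ifelse(samples %in% hits$sample,
                                           "exo*", "WT"),
                           hotspot = NA_character_)
  if (gene == "POLE" && nrow(hits)) {
    hs <- hits |>
      dplyr::mutate(hotspot = dplyr::case_when(
        .data$codon == 286L ~ "P286R",
        .data$codon == 411L ~ "V411L",
        TRUE ~ NA_character_)) |>
      dplyr::filter(!is.na(.data$hotspot)) |>
      dplyr::distinct(.data$sample, .data$hotspot)
    status$hotspot[match(hs$sample, status$sample)] <- hs$hotspot
  }
  status
}

#' Fisher's exact test on a 2x2 table
#'
#' Thin wrapper over [stats::fisher.test()] with the sidedness
#' vocabulary used throughout this package. The two-sided p-value uses
#' the minimum-likelihood method (summing hypergeometric outcomes no
#' more probable than the observed table).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param sided `"two"`, `"greater"` or `"less"`.
#' @return the p-value.
#' @export
fisher_exact <- function(table, sided = c("two", "greater", "less")) {
  sided <- match.arg(sided)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  alt <- switch(sided, two = "two.sided", greater = "greater",
                less = "less")
  stats::fisher.test(table, alternative = alt)$p.value
}

#' One-tailed Wilcoxon rank-sum comparison of signature fractions
#'
#' Tests whether `group` values are stochastically greater (or less)
#' than `reference` values. Delegates to [stats::wilcox.test()], which
#' uses exact enumeration for small untied samples and a
#' continuity-corrected normal approximation otherwise (ties handled by
#' midranks).
#'
#' @param group,reference numeric vectors.
#' @param direction `"greater"` (default) or `"less"`, for the group
#'   relative to the reference.
#' @return the p-value.
#' @export
rank_sum_test <- function(group, reference,
                          direction = c("greater", "less")) {
  direction <- match.arg(direction)
  stopifnot(length(group) > 0, length(reference) > 0)
  suppressWarnings(
    stats::wilcox.test(group, reference, alternative = direction,
                       correct = TRUE)$p.value
  )
}

#' Cross-tabulate two annotation variables
#'
#' Counts sample combinations of two closed-vocabulary variables, with
#' an explicit `(missing)` category so marginals always sum to the
#' cohort size.
#'
#' @param annotations per-sample annotation tibble.
#' @param row_var,col_var column names to tabulate.
#' @return tibble in wide form: one row per `row_var` level, one count
#'   column per `col_var` level.
#' @export
crosstab <- function(annotations, row_var, col_var) {
  r <- as.character(annotations[[row_var]])
  c_ <- as.character(annotations[[col_var]])
  r[is.na(r)] <- "(missing)"
  c_[is.na(c_)] <- "(missing)"
  tab <- table(r, c_)
  out <- tibble::as_tibble(as.data.frame.matrix(tab), rownames = row_var)
  out
}
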