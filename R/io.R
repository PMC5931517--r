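#' Read / write the MAF-like mutation TSV dialect
#'
#' Columns: `sample`, `chrom`, `pos` (1-based), `ref`, `alt`,
#' `variant_class` (`SNV`/`INS`/`DEL`), `context5` (forward-strand
#' pentamer, SNVs only), `ccf`, `ccf_lo`, `ccf_hi`. Internally the
#' context column is named `pentamer`; indel lengths are reconstructed
#' from `ref`/`alt` on read.
#'
#' @param path file path.
#' @param mutations mutation tibble (e.g. from [simulate_cohort()]).
#' @return `read_maf` returns a mutation tibble ready for
#'   [annotate_mutations()] / [build_catalog()].
#' @export
read_maf <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          chrom = readr::col_character(),
                          ref = readr::col_character(),
                          alt = readr::col_character()))
  df |>
    dplyr::rename(pentamer = "context5") |>
    dplyr::mutate(
      indel_len = dplyr::case_when(
        .data$variant_class == "INS" ~ nchar(.data$alt) - nchar(.data$ref),
        .data$variant_class == "DEL" ~ nchar(.data$ref) - nchar(.data$alt),
        TRUE ~ NA_integer_
      )
    )
}

#' @rdname read_maf
#' @export
write_maf <- function(mutations, path) {
  mutations |>
    dplyr::select(dplyr::all_of(c("sample", "chrom", "pos", "ref", "alt",
                                  "variant_class")),
                  context5 = "pentamer",
                  dplyr::all_of(c("ccf", "ccf_lo", "ccf_hi"))) |>
    readr::write_tsv(path)
  invisible(mutations)
}

#' Read / write BED-like interval tracks
#'
#' On disk the tracks are BED-like (0-based half-open `start`/`end`,
#' tab-separated, with one label column); in memory intervals are
#' 1-based inclusive.
#'
#' @param path file path.
#' @param track tibble with `chrom`, `start`, `end` and one label
#'   column.
#' @param label name of the label column (`"timing_q"` or
#'   `"leading_template"`).
#' @return `read_track` returns the track tibble (1-based inclusive).
#' @export
read_track <- function(path, label) {
  df <- readr::read_tsv(path, col_names = c("chrom", "start", "end", label),
                        show_col_types = FALSE)
  df$start <- df$start + 1L   # BED 0-based half-open -> 1-based inclusive
  df
}

#' @rdname read_track
#' @export
write_track <- function(track, path, label) {
  out <- track
  out$start <- out$start - 1L
  readr::write_tsv(out[, c("chrom", "start", "end", label)], path,
                   col_names = FALSE)
  invisible(track)
}

#' Write a synthetic cohort to a directory
#'
#' Emits `mutations.tsv` (MAF-like dialect), `annotations.tsv`,
#' `gene_mutations.tsv`, `reference.fa`, `timing.bed`, `strand.bed` and
#' `truth.json` (generator configuration scalars plus realized
#' per-sample signature counts).
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_maf(cohort$mutations, file.path(dir, "mutations.tsv"))
  readr::write_tsv(cohort$annotations, file.path(dir, "annotations.tsv"))
  readr::write_tsv(cohort$gene_mutations,
                   file.path(dir, "gene_mutations.tsv"))
  ref <- Biostrings::DNAStringSet(cohort$reference)
  names(ref) <- "chr1"
  Biostrings::writeXStringSet(ref, file.path(dir, "reference.fa"))
  write_track(cohort$timing_track, file.path(dir, "timing.bed"), "timing_q")
  write_track(cohort$strand_track, file.path(dir, "strand.bed"),
              "leading_template")
  cfg <- cohort$truth$config
  truth <- list(
    seed = cfg$seed,
    n_samples = cfg$n_samples,
    genotype_mix = as.list(cfg$genotype_mix),
    order_scenario = cfg$order_scenario,
    clonal_fraction = cfg$clonal_fraction,
    signature_names = colnames(cohort$truth$signatures),
    realized_signature_counts =
      apply(cohort$truth$realized_signature_counts, 2, as.list)
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
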