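#' Extract the 5-base reference context around a position
#'
#' Returns the forward-strand reference bases at `pos - 2 ... pos + 2`.
#' Positions are 1-based. Vectorized over `pos`.
#'
#' @param reference a [Biostrings::DNAString], [Biostrings::DNAStringSet]
#'   of length one, or plain character sequence.
#' @param pos integer positions of the mutated base.
#' @return character vector of pentamers; `NA` where the window runs off
#'   either end of the sequence.
#' @export
extract_pentamer <- function(reference, pos) {
  seq <- reference_as_character(reference)
  len <- nchar(seq)
  ok <- !is.na(pos) & pos >= 3 & pos <= len - 2
  out <- rep(NA_character_, length(pos))
  if (any(ok)) out[ok] <- substring(seq, pos[ok] - 2L, pos[ok] + 2L)
  out
}

reference_as_character <- function(reference) {
  if (inherits(reference, "DNAStringSet")) reference <- reference[[1]]
  if (inherits(reference, "DNAString")) {
    return(as.character(reference))
  }
  as.character(reference)[1]
}

#' Build a channels x samples mutation count matrix
#'
#' Encodes each record into the 1536-channel pentanucleotide SNV space
#' (plus the 8 indel size channels unless `include_indels = FALSE`) and
#' tallies counts per sample. Records that cannot be encoded (ambiguous
#' bases, missing contexts, non-positive indel lengths) are excluded and
#' tallied in the `qc` attribute rather than raising an error.
#'
#' @param mutations tibble of mutation records with columns `sample`,
#'   `variant_class` (`"SNV"`, `"INS"`, `"DEL"`), `pentamer` and `alt`
#'   (SNVs), and `indel_len` (indels). [read_maf()] and
#'   [simulate_cohort()] produce this layout.
#' @param include_indels include the 8 indel channels (rows 1537:1544).
#' @param samples optional character vector fixing the column set and
#'   order; samples without mutations get all-zero columns.
#' @return integer matrix with channel labels as rownames and sample ids
#'   as colnames, with attribute `qc` (named excluded-record counts).
#' @export
build_catalog <- function(mutations, include_indels = TRUE, samples = NULL) {
  channels <- all_channels(include_indels)
  n_chan <- length(channels)
  if (is.null(samples)) {
    samples <- if (nrow(mutations)) sort(unique(mutations$sample)) else character()
  }
  mat <- matrix(0L, nrow = n_chan, ncol = length(samples),
                dimnames = list(channels, samples))
  qc <- c(ambiguous_snv = 0L, bad_indel_length = 0L,
          unknown_class = 0L, unknown_sample = 0L)
  if (nrow(mutations)) {
    is_snv <- mutations$variant_class == "SNV"
    is_ind <- mutations$variant_class %in% c("INS", "DEL")
    qc["unknown_class"] <- sum(!is_snv & !is_ind)
    idx <- rep(NA_integer_, nrow(mutations))
    idx[is_snv] <- encode_snv_channel(mutations$pentamer[is_snv],
                                      mutations$alt[is_snv])
    qc["ambiguous_snv"] <- sum(is_snv & is.na(idx))
    if (include_indels) {
      ind_idx <- encode_indel_channel(mutations$indel_len[is_ind],
                                      mutations$variant_class[is_ind] == "INS")
      qc["bad_indel_length"] <- sum(is.na(ind_idx))
      idx[is_ind] <- ind_idx + 1536L
    }
    col <- match(mutations$sample, samples)
    qc["unknown_sample"] <- sum(!is.na(idx) & is.na(col))
    keep <- !is.na(idx) & !is.na(col)
    if (any(keep)) {
      tab <- table(factor(idx[keep], levels = seq_len(n_chan)),
                   factor(col[keep], levels = seq_along(samples)))
      mat[] <- as.integer(tab)
    }
  }
  attr(mat, "qc") <- qc
  mat
}

#' Write / read a catalog as TSV (channels as rows, samples as columns)
#'
#' @param catalog matrix from [build_catalog()].
#' @param path file path.
#' @return `read_catalog` returns the matrix; `write_catalog` its input,
#'   invisibly.
#' @export
write_catalog <- function(catalog, path) {
  df <- tibble::as_tibble(catalog, rownames = "channel")
  readr::write_tsv(df, path)
  invisible(catalog)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}

#' Annotate mutation records with channel, timing bin and strand label
#'
#' Adds `channel` (index into [all_channels()]), `substitution`,
#' `timing_bin` from a timing track, and `strand_label` (role of the
#' template strand carrying the A-or-C base of the mutated pair) from a
#' replication-strand track. SNVs whose pentamer centers on a purine are
#' understood as their pyrimidine-strand complement, so the strand label
#' accounts for which reference strand carries the C (for C>N) or the A
#' (for T>N, tracked through its paired A).
#'
#' @param mutations mutation tibble (see [build_catalog()]); SNV rows
#'   additionally need `ref` to determine the pyrimidine strand.
#' @param timing_track tibble with `start`, `end` (1-based inclusive)
#'   and `timing_q`; `NULL` to skip.
#' @param strand_track tibble with `start`, `end` and `leading_template`
#'   (`"+"` or `"-"`, the reference strand serving as leading-strand
#'   template); `NULL` to skip.
#' @return the mutation tibble with annotation columns added.
#' @export
annotate_mutations <- function(mutations, timing_track = NULL,
                               strand_track = NULL) {
  out <- mutations
  is_snv <- out$variant_class == "SNV"
  ch <- rep(NA_integer_, nrow(out))
  ch[is_snv] <- encode_snv_channel(out$pentamer[is_snv], out$alt[is_snv])
  is_ind <- out$variant_class %in% c("INS", "DEL")
  ch[is_ind] <- encode_indel_channel(out$indel_len[is_ind],
                                     out$variant_class[is_ind] == "INS") + 1536L
  out$channel <- ch
  subs <- rep(NA_character_, nrow(out))
  subs[which(ch <= 1536L)] <- SUBSTITUTIONS[(ch[which(ch <= 1536L)] - 1L) %/% 256L + 1L]
  out$substitution <- subs
  if (!is.null(timing_track)) {
    bin_at <- interval_lookup(out$pos, timing_track)
    out$timing_bin <- timing_track$timing_q[bin_at]
  }
  if (!is.null(strand_track)) {
    seg <- interval_lookup(out$pos, strand_track)
    lead <- strand_track$leading_template[seg]
    # strand holding the A-or-C base: for a reference pyrimidine C or T,
    # the C sits on "+" iff ref == C; the A paired with a reference T
    # also sits on "-" of the T, i.e. on "+" iff ref == A.
    ac_strand <- dplyr::case_when(
      !is_snv ~ NA_character_,
      out$ref %in% c("C", "A") ~ "+",
      out$ref %in% c("G", "T") ~ "-",
      TRUE ~ NA_character_
    )
    out$strand_label <- dplyr::if_else(
      is.na(ac_strand) | is.na(lead), NA_character_,
      dplyr::if_else(ac_strand == lead, "leading", "lagging")
    )
  }
  out
}

interval_lookup <- function(pos, track) {
  i <- findInterval(pos, track$start)
  i[i == 0L] <- NA_integer_
  bad <- !is.na(i) & pos > track$end[i]
  i[bad] <- NA_integer_
  i
}
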