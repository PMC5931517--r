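#' @importFrom rlang .data
#' @import dplyr
NULL

BASES <- c("A", "C", "G", "T")

# Substitutions are pyrimidine-centered and fixed in this order; pentamer
# contexts are ordered lexicographically by the (-2, -1, +1, +2) flanks.
SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

INDEL_CHANNELS <- c("INS1", "INS2", "INS3", "INS4+",
                    "DEL1", "DEL2", "DEL3", "DEL4+")

comp_base <- function(x) chartr("ACGT", "TGCA", x)

#' Reverse-complement a vector of DNA strings
#'
#' Thin vectorized helper for short fixed-width contexts; for anything
#' longer use [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA strings over A/C/G/T.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  n <- nchar(x)
  if (length(unique(n)) == 1L && n[1] == 5L) {
    # fast path for pentamers
    cc <- comp_base(x)
    paste0(substr(cc, 5, 5), substr(cc, 4, 4), substr(cc, 3, 3),
           substr(cc, 2, 2), substr(cc, 1, 1))
  } else {
    vapply(x, function(s) {
      paste(rev(strsplit(comp_base(s), "")[[1]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
}

base_digit <- function(x) match(x, BASES) - 1L

#' SNV channel labels in the 1536-channel pentanucleotide space
#'
#' Channels are substitution-major: all 256 contexts of C>A first, then
#' C>G, and so on. The label for substitution `r>a` in context
#' `b2 b1 [r] p1 p2` is `"b2b1[r>a]p1p2"`, e.g. `"AA[C>T]GA"`.
#'
#' @return character vector of length 1536.
#' @export
snv_channels <- function() {
  ctx <- expand.grid(p2 = BASES, p1 = BASES, m1 = BASES, m2 = BASES,
                     stringsAsFactors = FALSE)
  # expand.grid varies the first column fastest; reorder so that the
  # (-2,-1,+1,+2) tuple is lexicographic
  ctx <- ctx[order(ctx$m2, ctx$m1, ctx$p1, ctx$p2), ]
  unlist(lapply(SUBSTITUTIONS, function(s) {
    ref <- substr(s, 1, 1)
    alt <- substr(s, 3, 3)
    paste0(ctx$m2, ctx$m1, "[", ref, ">", alt, "]", ctx$p1, ctx$p2)
  }), use.names = FALSE)
}

#' Indel size-class channel labels
#'
#' Insertions and deletions of 1, 2, 3, and >= 4 bases, in that order.
#'
#' @return character vector of length 8.
#' @export
indel_channels <- function() INDEL_CHANNELS

#' Trinucleotide channel labels in the conventional 96-channel space
#'
#' @return character vector of length 96, substitution-major with
#'   lexicographic (-1, +1) contexts, e.g. `"A[C>A]A"`.
#' @export
trimer_channels <- function() {
  ctx <- expand.grid(p1 = BASES, m1 = BASES, stringsAsFactors = FALSE)
  ctx <- ctx[order(ctx$m1, ctx$p1), ]
  unlist(lapply(SUBSTITUTIONS, function(s) {
    ref <- substr(s, 1, 1)
    alt <- substr(s, 3, 3)
    paste0(ctx$m1, "[", ref, ">", alt, "]", ctx$p1)
  }), use.names = FALSE)
}

#' Full channel label set used for signature extraction
#'
#' @param include_indels append the 8 indel channels after the 1536 SNV
#'   channels (the default, giving 1544 channels).
#' @return character vector.
#' @export
all_channels <- function(include_indels = TRUE) {
  if (include_indels) c(snv_channels(), indel_channels()) else snv_channels()
}

#' Encode an SNV into its pentanucleotide channel
#'
#' Purine-centered records are reverse-complemented so every stored
#' channel is centered on a pyrimidine (C or T). Vectorized.
#'
#' @param pentamer 5-base reference context centered on the mutated base.
#' @param alt alternate allele observed at the center position.
#' @return integer channel index in `1:1536` (indices follow
#'   [snv_channels()]); `NA` for records with ambiguous bases or where
#'   `alt` equals the reference base.
#' @export
encode_snv_channel <- function(pentamer, alt) {
  pentamer <- toupper(pentamer)
  alt <- toupper(alt)
  bad <- is.na(pentamer) | is.na(alt) | nchar(pentamer) != 5L |
    grepl("[^ACGT]", pentamer) | !alt %in% BASES
  pentamer[bad] <- "AACAA"  # placeholder, masked below
  alt[bad] <- "G"
  center <- substr(pentamer, 3, 3)
  flip <- center %in% c("A", "G")
  pentamer[flip] <- revcomp(pentamer[flip])
  alt[flip] <- comp_base(alt[flip])
  center <- substr(pentamer, 3, 3)
  bad <- bad | alt == center
  sub_idx <- ifelse(center == "C",
                    match(alt, c("A", "G", "T")) - 1L,
                    match(alt, c("A", "C", "G")) + 2L)
  ctx_idx <- base_digit(substr(pentamer, 1, 1)) * 64L +
    base_digit(substr(pentamer, 2, 2)) * 16L +
    base_digit(substr(pentamer, 4, 4)) * 4L +
    base_digit(substr(pentamer, 5, 5))
  idx <- sub_idx * 256L + ctx_idx + 1L
  idx[bad] <- NA_integer_
  as.integer(idx)
}

#' Encode an indel into its size-class channel
#'
#' @param indel_len inserted/deleted length in bases (>= 1).
#' @param is_insertion logical; `FALSE` for deletions.
#' @return integer index in `1:8` into [indel_channels()]; `NA` for
#'   non-positive or missing lengths.
#' @export
encode_indel_channel <- function(indel_len, is_insertion) {
  bad <- is.na(indel_len) | indel_len < 1L
  size <- pmin(as.integer(indel_len), 4L)
  idx <- size + ifelse(rep_len(is_insertion, length(size)), 0L, 4L)
  idx[bad] <- NA_integer_
  as.integer(idx)
}

#' Map pentamer channels onto their trinucleotide channel
#'
#' Every 96-space channel has exactly 16 pentamer preimages (the 4 x 4
#' choices of the -2 and +2 flanks).
#'
#' @return integer vector of length 1536 with values in `1:96`,
#'   positionally aligned with [snv_channels()].
#' @export
trimer_collapse_map <- function() {
  info <- snv_channel_info()
  m1 <- substr(info$pentamer, 2, 2)
  p1 <- substr(info$pentamer, 4, 4)
  sub_idx <- match(info$substitution, SUBSTITUTIONS) - 1L
  as.integer(sub_idx * 16L + base_digit(m1) * 4L + base_digit(p1) + 1L)
}

#' Per-channel annotation table for the 1536 SNV channels
#'
#' @return tibble with columns `channel` (index), `label`,
#'   `substitution`, `pentamer` (pyrimidine-centered context) and
#'   `trimer` (96-space label).
#' @export
snv_channel_info <- function() {
  labels <- snv_channels()
  pent <- paste0(substr(labels, 1, 2), substr(labels, 4, 4),
                 substr(labels, 8, 9))
  sub <- substr(labels, 4, 6)
  tibble::tibble(
    channel = seq_along(labels),
    label = labels,
    substitution = sub,
    pentamer = pent,
    trimer = paste0(substr(labels, 2, 2), "[", sub, "]", substr(labels, 8, 8))
  )
}

#' Collapse a pentanucleotide catalog or signature into 96-channel space
#'
#' Each trinucleotide channel receives the sum of its 16 pentamer
#' preimages; indel rows (if present) are dropped, so only SNV mass is
#' conserved.
#'
#' @param x numeric vector of length 1536/1544, or a matrix with that
#'   many rows (channels x samples).
#' @param drop_indels drop trailing indel rows when `x` covers the full
#'   1544-channel space.
#' @return object of the same kind over the 96 trinucleotide channels,
#'   rows named by [trimer_channels()].
#' @export
collapse_to_trimer <- function(x, drop_indels = TRUE) {
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, ncol = 1) else as.matrix(x)
  if (nrow(m) == 1544L && drop_indels) m <- m[1:1536, , drop = FALSE]
  if (nrow(m) != 1536L) {
    stop("input must cover the 1536 SNV channels (got ", nrow(m), " rows)")
  }
  map <- trimer_collapse_map()
  out <- rowsum(m, group = map, reorder = TRUE)
  rownames(out) <- trimer_channels()
  if (vec) out[, 1] else out
}
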