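#' Cosine similarity between two non-negative spectra
#'
#' @param a,b numeric vectors of equal length (e.g. 96-channel
#'   signatures); must be non-zero.
#' @return number in \[0, 1\] for non-negative inputs.
#' @export
cosine_sim <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for zero vectors")
  sum(a * b) / (na * nb)
}

#' Cosine-maximizing non-negative combination of two signatures
#'
#' Finds coefficients `(alpha1, alpha2)` maximizing
#' `cosine(alpha1 * c1 + alpha2 * c2, target)`. Only the ratio
#' `alpha1 : alpha2` is identified; coefficients are returned normalized
#' to sum 1 (the mixing fraction `t = alpha1`).
#'
#' Two solvers: `"closed"` projects the target onto the plane spanned by
#' `c1`, `c2` (2x2 normal equations) and clamps to the better endpoint
#' when the unconstrained optimum needs a negative coefficient;
#' `"golden"` runs golden-section search on the mixing fraction over
#' \[0, 1\]. Both enforce non-negative coefficients by default because
#' signatures are densities that are summed; set `nonneg = FALSE` for
#' the unconstrained subspace fit.
#'
#' @param c1,c2 component spectra (equal-length non-negative vectors).
#' @param target spectrum to match.
#' @param method `"closed"` (exact) or `"golden"`.
#' @param nonneg constrain coefficients to be non-negative.
#' @return list of class `combination_fit`: `alpha` (length 2, sums to
#'   1), `cosine`, `method`.
#' @export
fit_combination <- function(c1, c2, target, method = c("closed", "golden"),
                            nonneg = TRUE) {
  method <- match.arg(method)
  stopifnot(length(c1) == length(c2), length(c1) == length(target))
  if (sum(target^2) == 0) stop("zero target spectrum")
  if (sum(c1^2) == 0 || sum(c2^2) == 0) stop("zero component spectrum")
  if (method == "closed") {
    fit <- combo_fit_closed(c1, c2, target, nonneg = nonneg)
  } else {
    g <- function(t) cosine_sim(t * c1 + (1 - t) * c2 + 1e-300, target)
    opt <- stats::optimize(g, c(0, 1), maximum = TRUE,
                           tol = .Machine$double.eps^0.5)
    # compare against the endpoints, which optimize() can miss
    cands <- c(opt$maximum, 0, 1)
    vals <- vapply(cands, g, numeric(1))
    t <- cands[which.max(vals)]
    fit <- list(alpha = c(t, 1 - t), cosine = max(vals))
  }
  structure(list(alpha = fit$alpha, cosine = fit$cosine, method = method),
            class = "combination_fit")
}

combo_fit_closed <- function(c1, c2, target, nonneg = TRUE) {
  g11 <- sum(c1 * c1); g22 <- sum(c2 * c2); g12 <- sum(c1 * c2)
  b1 <- sum(c1 * target); b2 <- sum(c2 * target)
  nt <- sqrt(sum(target^2))
  det <- g11 * g22 - g12^2
  end1 <- b1 / (sqrt(g11) * nt)
  end2 <- b2 / (sqrt(g22) * nt)
  interior <- FALSE
  if (det > 1e-300) {
    a1 <- (g22 * b1 - g12 * b2) / det
    a2 <- (g11 * b2 - g12 * b1) / det
    interior <- !nonneg || (a1 >= 0 && a2 >= 0)
  }
  if (interior) {
    q <- a1 * b1 + a2 * b2   # = b' G^{-1} b = ||projection||^2
    cosine <- sqrt(max(q, 0)) / nt
    alpha <- c(a1, a2)
    if (sum(abs(alpha)) == 0) alpha <- c(0.5, 0.5)
    alpha <- alpha / sum(alpha)
  } else if (end1 >= end2) {
    alpha <- c(1, 0); cosine <- end1
  } else {
    alpha <- c(0, 1); cosine <- end2
  }
  list(alpha = alpha, cosine = min(cosine, 1))
}

#' @export
print.combination_fit <- function(x, ...) {
  cat(sprintf("<combination_fit> cosine = %.4f, alpha = (%.3f, %.3f) [%s]\n",
              x$cosine, x$alpha[1], x$alpha[2], x$method))
  invisible(x)
}

#' Background distribution of best pairwise combination matches
#'
#' For every unordered pair of discovered signatures, fits the
#' cosine-maximizing two-signature combination against every reference
#' profile (minus any per-signature exclusions of known true-positive
#' matches) and records the best match. The resulting distribution is
#' the empirical background for judging whether an observed combination
#' match could arise between unrelated signatures.
#'
#' @param signatures channels x K matrix (K >= 2) of discovered
#'   signatures (96-space; use [collapse_to_trimer()] first if needed).
#' @param reference channels x M matrix of reference profiles.
#' @param exclusions named list: for signature name `s`,
#'   `exclusions[[s]]` is a character vector of reference names never
#'   allowed as the best match for any pair involving `s`.
#' @return tibble with one row per pair: `sig1`, `sig2`, `best_ref`,
#'   `cosine`, `alpha1`, `alpha2`.
#' @export
pairwise_background <- function(signatures, reference, exclusions = list()) {
  S <- as.matrix(signatures); R <- as.matrix(reference)
  if (ncol(S) < 2) stop("need at least two signatures")
  sn <- colnames(S) %||% paste0("S", seq_len(ncol(S)))
  rn <- colnames(R) %||% paste0("R", seq_len(ncol(R)))
  pairs <- utils::combn(ncol(S), 2)
  out <- vector("list", ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    excl <- union(exclusions[[sn[i1]]], exclusions[[sn[i2]]])
    use <- setdiff(seq_len(ncol(R)), which(rn %in% excl))
    if (!length(use)) stop("no reference profiles left after exclusions for ",
                           sn[i1], " + ", sn[i2])
    best <- list(cosine = -Inf)
    for (r in use) {
      f <- combo_fit_closed(S[, i1], S[, i2], R[, r])
      if (f$cosine > best$cosine) best <- c(f, ref = r)
    }
    out[[j]] <- tibble::tibble(
      sig1 = sn[i1], sig2 = sn[i2], best_ref = rn[best$ref],
      cosine = best$cosine, alpha1 = best$alpha[1], alpha2 = best$alpha[2]
    )
  }
  dplyr::bind_rows(out)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Channel-shuffling permutation null for combination matches
#'
#' Each iteration independently permutes the channel values of every
#' signature (preserving each signature's sorted value set, i.e. its
#' sparsity), fits all signature pairs against the full reference with
#' the combination fit, and records the best cosine across pairs and
#' references. The resulting distribution estimates how well randomized
#' signatures of equivalent sparsity can be made to match the reference
#' by two-component overfitting.
#'
#' @inheritParams pairwise_background
#' @param n_perm number of permutation iterations.
#' @param seed integer seed.
#' @param threshold report the empirical probability of a best match at
#'   or above this cosine.
#' @return list of class `permutation_null`: `values` (length
#'   `n_perm`), `p_exceed`, `threshold`, `n_perm`, `seed`.
#' @export
permutation_null <- function(signatures, reference, n_perm = 10000,
                             seed = 1, threshold = 0.99) {
  S <- as.matrix(signatures); R <- as.matrix(reference)
  if (ncol(S) < 2) stop("need at least two signatures")
  stopifnot(n_perm >= 1)
  nc <- nrow(S)
  rnorms <- sqrt(colSums(R^2))
  pairs <- utils::combn(ncol(S), 2)
  vals <- numeric(n_perm)
  withr::with_seed(seed, {
    for (it in seq_len(n_perm)) {
      P <- apply(S, 2, sample)
      best <- -Inf
      for (j in seq_len(ncol(pairs))) {
        c1 <- P[, pairs[1, j]]; c2 <- P[, pairs[2, j]]
        best <- max(best, combo_best_over_refs(c1, c2, R, rnorms))
      }
      vals[it] <- best
    }
  })
  structure(list(values = vals, p_exceed = mean(vals >= threshold),
                 threshold = threshold, n_perm = n_perm, seed = seed),
            class = "permutation_null")
}

# Vectorized over all reference columns: best achievable non-negative
# combination cosine of (c1, c2) against each reference, maximized.
combo_best_over_refs <- function(c1, c2, R, rnorms) {
  g11 <- sum(c1 * c1); g22 <- sum(c2 * c2); g12 <- sum(c1 * c2)
  det <- g11 * g22 - g12^2
  b1 <- as.vector(crossprod(c1, R))
  b2 <- as.vector(crossprod(c2, R))
  end <- pmax(b1 / sqrt(g11), b2 / sqrt(g22))
  if (det > 1e-300) {
    a1 <- (g22 * b1 - g12 * b2) / det
    a2 <- (g11 * b2 - g12 * b1) / det
    interior <- a1 >= 0 & a2 >= 0
    q <- a1 * b1 + a2 * b2
    num <- ifelse(interior, sqrt(pmax(q, 0)), end)
  } else {
    num <- end
  }
  max(pmin(num / rnorms, 1))
}

#' @export
print.permutation_null <- function(x, ...) {
  q <- stats::quantile(x$values, c(0.5, 0.95, 0.99))
  cat(sprintf(
    "<permutation_null> %d iterations; P(best >= %.2f) = %.4g\n",
    x$n_perm, x$threshold, x$p_exceed))
  cat(sprintf("  best-match cosine quantiles: 50%% %.3f, 95%% %.3f, 99%% %.3f\n",
              q[1], q[2], q[3]))
  invisible(x)
}

#' Synthetic 96-channel reference signature table
#'
#' A deterministic stand-in for an external signature database: peaked
#' random profiles over the 96 trinucleotide channels. Intended for
#' tests and examples; real comparisons should load a user-supplied
#' table with [read_signature_table()].
#'
#' @param n number of profiles.
#' @param n_peaks dominant channels per profile.
#' @param peak_mass total mass on the dominant channels.
#' @param seed integer seed.
#' @return 96 x `n` matrix, columns named `REF1..REFn`, summing to 1.
#' @export
synthetic_reference_signatures <- function(n = 30, n_peaks = 4,
                                           peak_mass = 0.75, seed = 99) {
  withr::with_seed(seed, {
    R <- vapply(seq_len(n), function(i) {
      v <- rep((1 - peak_mass) / 96, 96)
      pk <- sample.int(96, n_peaks)
      v[pk] <- v[pk] + peak_mass * as.vector(stats::rmultinom(1, 1000, rep(1, n_peaks))) / 1000
      v / sum(v)
    }, numeric(96))
  })
  dimnames(R) <- list(trimer_channels(), paste0("REF", seq_len(n)))
  R
}

#' Read / write a 96-channel signature table
#'
#' Text layout: a `channel` column of trinucleotide labels
#' (`"A[C>A]A"` style) followed by one numeric column per signature.
#' Rows are reordered to the canonical [trimer_channels()] order on
#' read.
#'
#' @param path file path.
#' @param x channels x signatures matrix.
#' @return `read_signature_table` returns a 96 x K matrix.
#' @export
read_signature_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  labs <- df[[1]]
  ord <- match(trimer_channels(), labs)
  if (anyNA(ord)) stop("signature table is missing trinucleotide channels")
  mat <- as.matrix(df[ord, -1, drop = FALSE])
  rownames(mat) <- trimer_channels()
  mat
}

#' @rdname read_signature_table
#' @export
write_signature_table <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(as.matrix(x), rownames = "channel"), path)
  invisible(x)
}
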