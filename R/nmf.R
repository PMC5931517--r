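#' Bayesian NMF with automatic relevance determination
#'
#' Factorizes a non-negative mutation count matrix `V` (channels x
#' samples) as `V ~ Poisson(W H)` by multiplicative updates minimizing
#' the KL (Poisson) divergence, with exponential (L1-type) priors on the
#' columns of `W` and rows of `H` whose scales are per-component
#' relevance hyperparameters updated in closed form. Components whose
#' relevance (total mass `||w_k||_1 + ||h_k||_1`) collapses below
#' `prune_rel` times the largest component's are pruned at convergence,
#' so the effective rank is learned rather than fixed.
#'
#' @param catalog non-negative channels x samples matrix (from
#'   [build_catalog()]).
#' @param k_max maximum number of components; clamped with a warning to
#'   `min(dim(catalog))`.
#' @param max_iter,tol iteration cap and relative-objective convergence
#'   tolerance (checked every 10 iterations).
#' @param a shape hyperparameter of the inverse-gamma hyperprior on the
#'   relevance scales; larger values prune more aggressively.
#' @param prune_rel relative relevance threshold below which a component
#'   is discarded at convergence.
#' @param seed integer seed for the random initialization.
#' @return object of class `signature_model`: `W` (channels x K, columns
#'   normalized to sum 1), `H` (K x samples, carrying the magnitudes so
#'   `W %*% H` reconstructs the catalog), `K_effective`, `relevance`,
#'   `objective_trace`, `final_objective`, `n_iter`, `converged`,
#'   `run_seed`.
#' @export
bayes_nmf <- function(catalog, k_max = 25, max_iter = 100000, tol = 1e-7,
                      a = 10, prune_rel = 1e-8, seed = 1) {
  V <- as.matrix(catalog)
  if (any(V < 0)) stop("catalog must be non-negative")
  if (sum(V) == 0) stop("catalog is all zero; nothing to factorize")
  F_ <- nrow(V); N <- ncol(V)
  if (k_max > min(F_, N)) {
    warning("k_max exceeds min(dim(catalog)); clamping to ", min(F_, N))
    k_max <- min(F_, N)
  }
  K <- as.integer(k_max)
  vbar <- mean(V)
  b <- sqrt((a - 1) * (a - 2) * vbar / K)
  C <- F_ + N + a + 1
  eps <- .Machine$double.xmin
  nz <- V > 0
  Vnz <- V[nz]

  withr::with_seed(seed, {
    W <- matrix(stats::runif(F_ * K), F_, K) * sqrt(vbar)
    H <- matrix(stats::runif(K * N), K, N) * sqrt(vbar)
  })
  lambda <- (colSums(W) + rowSums(H) + b) / C

  objective <- function(WH) {
    kl <- sum(Vnz * log(Vnz / WH[nz])) - sum(V) + sum(WH)
    kl + sum((colSums(W) + rowSums(H) + b) / lambda) + C * sum(log(lambda))
  }

  trace <- numeric(0)
  prev <- Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    WH <- W %*% H
    W <- W * ((V / (WH + eps)) %*% t(H)) /
      (rep(1, F_) %o% (rowSums(H) + 1 / lambda) + eps)
    WH <- W %*% H
    H <- H * (crossprod(W, V / (WH + eps))) /
      ((colSums(W) + 1 / lambda) %o% rep(1, N) + eps)
    lambda <- (colSums(W) + rowSums(H) + b) / C
    if (it %% 10L == 0L || it == max_iter) {
      obj <- objective(W %*% H + eps)
      trace <- c(trace, obj)
      if (is.finite(prev) && abs(prev - obj) < tol * abs(prev)) {
        converged <- TRUE
        break
      }
      prev <- obj
    }
  }

  relevance <- colSums(W) + rowSums(H)
  keep <- relevance > prune_rel * max(relevance)
  W <- W[, keep, drop = FALSE]
  H <- H[keep, , drop = FALSE]
  scale <- colSums(W)
  W <- sweep(W, 2, scale, "/")
  H <- H * scale
  k_eff <- sum(keep)
  dimnames(W) <- list(rownames(V), paste0("S", seq_len(k_eff)))
  dimnames(H) <- list(colnames(W), colnames(V))
  structure(list(
    W = W, H = H, K_effective = k_eff,
    relevance = relevance[keep], lambda = lambda[keep],
    objective_trace = trace, final_objective = trace[length(trace)],
    n_iter = it, converged = converged, run_seed = seed
  ), class = "signature_model")
}

#' Construct a signature model from known factors
#'
#' Useful for building a model from ground-truth signatures and
#' activities, or from externally fitted factors.
#'
#' @param W channels x K non-negative matrix; columns are rescaled to
#'   sum to 1 and the scale absorbed into `H`.
#' @param H K x samples non-negative activity matrix.
#' @return a `signature_model`.
#' @export
signature_model <- function(W, H) {
  W <- as.matrix(W); H <- as.matrix(H)
  stopifnot(ncol(W) == nrow(H), all(W >= 0), all(H >= 0))
  scale <- colSums(W)
  W <- sweep(W, 2, scale, "/")
  H <- H * scale
  if (is.null(colnames(W))) {
    colnames(W) <- rownames(H) %||% paste0("S", seq_len(ncol(W)))
  }
  rownames(H) <- colnames(W)
  structure(list(W = W, H = H, K_effective = ncol(W),
                 relevance = colSums(H), lambda = NULL,
                 objective_trace = numeric(0), final_objective = NA_real_,
                 n_iter = 0L, converged = NA, run_seed = NA_integer_),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat("<signature_model> ", nrow(x$W), " channels, K_effective = ",
      x$K_effective, ", ", ncol(x$H), " samples\n", sep = "")
  invisible(x)
}

#' Broom-style tidiers for signature models
#'
#' `tidy()` returns the signature profiles in long form; `glance()`
#' one-row fit summary.
#'
#' @param x a `signature_model`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.signature_model <- function(x, ...) {
  tibble::as_tibble(x$W, rownames = "channel") |>
    tidyr::pivot_longer(-"channel", names_to = "signature",
                        values_to = "weight")
}

#' @rdname tidy.signature_model
#' @export
glance.signature_model <- function(x, ...) {
  tibble::tibble(K_effective = x$K_effective, n_iter = x$n_iter,
                 converged = x$converged,
                 final_objective = x$final_objective,
                 total_activity = sum(x$H))
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Multi-run consensus signature extraction
#'
#' Runs [bayes_nmf()] independently from `n_runs` seeds, tallies the
#' effective rank across runs, and returns the run with the modal
#' `K_effective` (ties among modal runs broken by the lowest final
#' objective).
#'
#' @param catalog channels x samples count matrix.
#' @param n_runs number of independent runs.
#' @param seeds optional integer vector of run seeds (default
#'   `seed + 0:(n_runs-1)`).
#' @param seed base seed used when `seeds` is not given.
#' @param ... passed on to [bayes_nmf()].
#' @return list of class `consensus_fit` with elements `model` (the
#'   chosen `signature_model`) and `report` (one row per run: seed,
#'   `K_effective`, final objective, chosen flag).
#' @export
consensus_extraction <- function(catalog, n_runs = 10, seeds = NULL,
                                 seed = 1, ...) {
  stopifnot(n_runs >= 1)
  if (is.null(seeds)) seeds <- seed + seq_len(n_runs) - 1L
  runs <- lapply(seeds, function(s) bayes_nmf(catalog, seed = s, ...))
  ks <- vapply(runs, `[[`, integer(1), "K_effective")
  objs <- vapply(runs, `[[`, numeric(1), "final_objective")
  tab <- table(ks)
  modal_ks <- as.integer(names(tab)[tab == max(tab)])
  if (length(modal_ks) > 1) {
    best_by_k <- vapply(modal_ks, function(k) min(objs[ks == k]), numeric(1))
    modal_k <- modal_ks[which.min(best_by_k)]
  } else {
    modal_k <- modal_ks
  }
  in_modal <- ks == modal_k
  chosen <- which(in_modal)[which.min(objs[in_modal])]
  report <- tibble::tibble(
    run = seq_along(runs), seed = seeds, K_effective = ks,
    final_objective = objs, chosen = seq_along(runs) == chosen
  )
  structure(list(model = runs[[chosen]], report = report,
                 modal_k = modal_k), class = "consensus_fit")
}

#' @export
print.consensus_fit <- function(x, ...) {
  cat("<consensus_fit> modal K =", x$modal_k, "over",
      nrow(x$report), "runs\n")
  print(x$report)
  invisible(x)
}

#' Fit activities for fixed signatures
#'
#' Estimates `H` for a known signature matrix `W` by multiplicative KL
#' updates with `W` held fixed — the attribution step used when a
#' catalog is projected onto previously discovered or ground-truth
#' signatures.
#'
#' @param catalog channels x samples count matrix.
#' @param W channels x K signature matrix (columns rescaled to sum 1).
#' @param n_iter number of multiplicative updates.
#' @return a `signature_model` with the supplied `W` and fitted `H`.
#' @export
fit_activities <- function(catalog, W, n_iter = 500) {
  V <- as.matrix(catalog)
  W <- as.matrix(W)
  stopifnot(nrow(V) == nrow(W))
  W <- sweep(W, 2, colSums(W), "/")
  K <- ncol(W); N <- ncol(V)
  eps <- .Machine$double.xmin
  H <- matrix(rep(colSums(V) / K, each = K), K, N)
  for (i in seq_len(n_iter)) {
    WH <- W %*% H
    H <- H * crossprod(W, V / (WH + eps))   # colSums(W) == 1
  }
  m <- signature_model(W, H)
  m$n_iter <- n_iter
  m
}

#' Per-mutation signature attribution probabilities
#'
#' For a mutation of channel `c` in sample `p`, the probability it was
#' generated by signature `i` is
#' `w[c,i] h[i,p] / sum_j w[c,j] h[j,p]`.
#'
#' @param model a `signature_model`.
#' @param channel integer channel indices (rows of `model$W`).
#' @param sample sample ids (columns of `model$H`), recycled against
#'   `channel`.
#' @return matrix `length(channel)` x K of probabilities, rows summing
#'   to 1. Channels unseen under every signature get a uniform row (with
#'   one warning).
#' @export
mutation_signature_probabilities <- function(model, channel, sample) {
  n <- max(length(channel), length(sample))
  channel <- rep_len(channel, n)
  sample <- rep_len(sample, n)
  p_col <- match(sample, colnames(model$H))
  if (anyNA(p_col)) stop("unknown sample id")
  num <- model$W[channel, , drop = FALSE] *
    t(model$H)[p_col, , drop = FALSE]
  den <- rowSums(num)
  zero <- den == 0
  if (any(zero)) {
    warning(sum(zero), " mutation(s) in channels unseen under all ",
            "signatures; assigned uniform probabilities")
    num[zero, ] <- 1
    den[zero] <- ncol(model$W)
  }
  num / den
}

#' Per-sample signature activity fractions
#'
#' @param model a `signature_model`.
#' @return tibble with one row per (sample, signature):  `activity`
#'   (attributed mutation count) and `fraction` of the sample's total;
#'   zero-burden samples get `NA` fractions.
#' @export
activity_fractions <- function(model) {
  H <- model$H
  tot <- colSums(H)
  frac <- sweep(H, 2, tot, "/")
  frac[, tot == 0] <- NA_real_
  tibble::as_tibble(t(H), rownames = "sample") |>
    tidyr::pivot_longer(-"sample", names_to = "signature",
                        values_to = "activity") |>
    dplyr::left_join(
      tibble::as_tibble(t(frac), rownames = "sample") |>
        tidyr::pivot_longer(-"sample", names_to = "signature",
                            values_to = "fraction"),
      by = c("sample", "signature")
    )
}

#' Match discovered signatures to a reference set by cosine similarity
#'
#' Greedy one-to-one assignment: the globally most similar
#' (discovered, reference) pair is matched first, then removed, until
#' one side is exhausted.
#'
#' @param W discovered channels x K matrix.
#' @param truth reference channels x K' matrix on the same channel set.
#' @return tibble with `signature`, `matched`, `cosine`.
#' @export
match_signatures <- function(W, truth) {
  cs <- crossprod(
    sweep(as.matrix(W), 2, sqrt(colSums(W^2)), "/"),
    sweep(as.matrix(truth), 2, sqrt(colSums(truth^2)), "/")
  )
  out <- list()
  while (nrow(cs) > 0 && ncol(cs) > 0) {
    ij <- arrayInd(which.max(cs), dim(cs))
    out[[length(out) + 1]] <- tibble::tibble(
      signature = rownames(cs)[ij[1]], matched = colnames(cs)[ij[2]],
      cosine = cs[ij[1], ij[2]]
    )
    cs <- cs[-ij[1], -ij[2], drop = FALSE]
  }
  dplyr::bind_rows(out)
}
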