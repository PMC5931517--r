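#' @import ggplot2
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a 96-channel mutational spectrum
#'
#' @param spectrum named numeric vector over [trimer_channels()] (or a
#'   1536/1544 vector, collapsed automatically).
#' @param title optional plot title.
#' @return a ggplot.
#' @export
plot_spectrum <- function(spectrum, title = NULL) {
  if (length(spectrum) %in% c(1536L, 1544L)) {
    spectrum <- collapse_to_trimer(spectrum)
  }
  stopifnot(length(spectrum) == 96L)
  df <- tibble::tibble(channel = trimer_channels(),
                       substitution = substr(trimer_channels(), 3, 5),
                       value = as.numeric(spectrum))
  df$channel <- factor(df$channel, levels = trimer_channels())
  ggplot(df, aes(x = .data$channel, y = .data$value,
                 fill = .data$substitution)) +
    geom_col(width = 0.8) +
    facet_grid(~substitution, scales = "free_x") +
    labs(x = NULL, y = "fraction", title = title) +
    theme_minimal(base_size = 9) +
    theme(axis.text.x = element_blank(), legend.position = "none")
}

#' @rdname autoplot_methods
#' @export
autoplot.signature_model <- function(object, ...) {
  w96 <- collapse_to_trimer(object$W)
  w96 <- sweep(w96, 2, colSums(w96), "/")
  df <- tibble::as_tibble(w96, rownames = "channel") |>
    tidyr::pivot_longer(-"channel", names_to = "signature",
                        values_to = "weight")
  df$channel <- factor(df$channel, levels = trimer_channels())
  df$substitution <- substr(as.character(df$channel), 3, 5)
  ggplot(df, aes(x = .data$channel, y = .data$weight,
                 fill = .data$substitution)) +
    geom_col(width = 0.8) +
    facet_grid(signature ~ substitution, scales = "free_x") +
    labs(x = NULL, y = "channel weight") +
    theme_minimal(base_size = 8) +
    theme(axis.text.x = element_blank(), legend.position = "none")
}

#' autoplot methods for result objects
#'
#' Quick diagnostic plots: signature spectra for `signature_model`,
#' per-bin enrichment with 2-SD error bars for `enrichment_profile`,
#' leading/lagging log2 ratios for `asymmetry_profile`, and per-sample
#' q-values for `ordering_result`.
#'
#' @param object the result object.
#' @param ... unused.
#' @return a ggplot.
#' @name autoplot_methods
#' @export
autoplot.enrichment_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$timing_bin, y = .data$enrichment,
                     group = .data$substitution)) +
    geom_hline(yintercept = 1, linetype = 2, color = "grey50") +
    geom_line() +
    geom_pointrange(aes(ymin = .data$enrichment - 2 * .data$boot_sd,
                        ymax = .data$enrichment + 2 * .data$boot_sd)) +
    facet_wrap(~substitution) +
    labs(x = "replication timing bin (early → late)",
         y = "observed / expected mutation density") +
    theme_minimal()
}

#' @rdname autoplot_methods
#' @export
autoplot.asymmetry_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$substitution, y = .data$log2_ratio)) +
    geom_hline(yintercept = 0, linetype = 2, color = "grey50") +
    geom_pointrange(aes(ymin = .data$log2_ratio - 2 * .data$log2_sd,
                        ymax = .data$log2_ratio + 2 * .data$log2_sd)) +
    labs(x = NULL,
         y = "log2( leading / lagging template density )") +
    theme_minimal()
}

#' @rdname autoplot_methods
#' @export
autoplot.ordering_result <- function(object, ...) {
  ggplot(object, aes(x = .data$sample, y = -log10(.data$q_value),
                     color = .data$hypothesis,
                     shape = .data$significant)) +
    geom_point(size = 2) +
    geom_hline(yintercept = -log10(attr(object, "q_threshold")),
               linetype = 2, color = "grey50") +
    labs(x = NULL, y = "-log10 q") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5))
}
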