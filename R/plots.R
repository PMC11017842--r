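# ggplot2 visualizations for each result type.

#' Plot a miRNA ranking
#'
#' Bar chart of validated, predicted and net evidence per ranked miRNA.
#'
#' @param object A `mirna_ranking`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mirna_ranking <- function(object, ...) {
  d <- tidy(object)
  d <- tidyr::pivot_longer(
    d, c("validated_score", "predicted_score", "net_evidence"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$mirna_id, .data$rank),
    y = .data$value, fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "count",
                  title = "miRNA multi-gene coverage ranking") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}

#' Plot replicate fold changes from a 2^-ddCt analysis
#'
#' @param object A `ddct_result`.
#' @param ... Unused.
#' @return A ggplot on a log2 fold-change axis with the control baseline
#'   at 1.
#' @export
autoplot.ddct_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$fold)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_jitter(width = 0.08, height = 0, size = 2) +
    ggplot2::stat_summary(fun = function(x) exp(mean(log(x))),
                          geom = "crossbar", width = 0.3,
                          colour = "steelblue") +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::labs(title = sprintf("%s relative expression (2^-ddCt vs %s)",
                                  object$assay, object$reference),
                  y = "fold change", x = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a fitted DNA-content histogram
#'
#' Histogram of the intensities used for fitting, with the fitted G0/G1
#' and G2/M Gaussians and the S-phase plateau overlaid.
#'
#' @param object A `phase_fit`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.phase_fit <- function(object, bins = 100, ...) {
  x <- object$intensity
  d <- tibble::tibble(intensity = x)
  grid <- seq(min(x), max(x), length.out = 400)
  s1 <- object$cv; mu1 <- object$mu1; mu2 <- object$mu2
  # densities on the intensity scale (the model lives in log space)
  comp <- dplyr::bind_rows(
    tibble::tibble(intensity = grid, phase = "G0/G1",
                   dens = object$g0g1 *
                     stats::dnorm(log(grid), log(mu1), max(s1, 1e-6)) / grid),
    tibble::tibble(intensity = grid, phase = "G2/M",
                   dens = object$g2m *
                     stats::dnorm(log(grid), log(mu2), max(s1, 1e-6)) / grid),
    tibble::tibble(intensity = grid, phase = "S",
                   dens = ifelse(grid > mu1 & grid < mu2,
                                 object$s / (mu2 - mu1), 0)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$intensity)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80", colour = "grey60") +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(y = .data$dens, colour = .data$phase),
                       linewidth = 0.8) +
    ggplot2::labs(title = "DNA-content histogram and fitted phases",
                  x = "PI intensity", y = "density") +
    ggplot2::theme_minimal()
}

#' Plot over-representation results
#'
#' @param results Tibble from [enrich()].
#' @param max_terms Terms shown (most significant first).
#' @return A ggplot of -log10 FDR per term.
#' @export
plot_enrichment <- function(results, max_terms = 15L) {
  d <- head(results, max_terms)
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$term_id, -.data$fdr),
    y = -log10(.data$fdr), fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(-log[10] ~ FDR),
                  title = "Over-representation of the candidate gene set") +
    ggplot2::theme_minimal()
}
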