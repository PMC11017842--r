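# broom-style tidiers for the package's result objects.

#' Tidy a miRNA ranking
#'
#' @param x A `mirna_ranking` from [rank_mirnas()].
#' @param ... Unused.
#' @return A plain tibble of the ranking rows.
#' @export
tidy.mirna_ranking <- function(x, ...) {
  tibble::as_tibble(unclass(x)[seq_along(x)])
}

#' @rdname tidy.mirna_ranking
#' @export
glance.mirna_ranking <- function(x, ...) {
  key <- attr(x, "ranking_key")
  tibble::tibble(n_ranked = nrow(x),
                 min_coverage = key$filter$min_coverage,
                 top_k = key$top_k,
                 sort_key = paste(key$sort, collapse = ", "))
}

#' Tidy a 2^-ddCt result
#'
#' `tidy()` returns the per-replicate fold changes; `glance()` the one-row
#' summary with the test battery.
#'
#' @param x A `ddct_result` from [delta_delta_ct()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ddct_result <- function(x, ...) {
  dplyr::mutate(x$folds, assay = x$assay, .before = 1L)
}

#' @rdname tidy.ddct_result
#' @export
glance.ddct_result <- function(x, ...) {
  tibble::tibble(assay = x$assay, reference = x$reference,
                 mean_fold_change = x$mean_fold_change,
                 p_anova = x$p_anova, normality_p = x$normality_p,
                 significant = x$significant)
}

#' Tidy a cell-cycle phase fit
#'
#' `tidy()` returns one row per phase; `glance()` the fitted mixture
#' parameters.
#'
#' @param x A `phase_fit` from [fit_phases()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.phase_fit <- function(x, ...) {
  tibble::tibble(phase = c("g0g1", "s", "g2m"),
                 fraction = c(x$g0g1, x$s, x$g2m))
}

#' @rdname tidy.phase_fit
#' @export
glance.phase_fit <- function(x, ...) {
  tibble::tibble(mu1 = x$mu1, mu2 = x$mu2, peak_ratio = x$mu2 / x$mu1,
                 cv = x$cv, n = x$n, em_iterations = length(x$loglik),
                 loglik = if (length(x$loglik)) x$loglik[length(x$loglik)]
                          else NA_real_,
                 degenerate = x$degenerate)
}
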