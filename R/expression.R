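# qRT-PCR relative quantification (2^-ddCt) and the accompanying
# statistical battery: Kolmogorov-Smirnov normality, one-way ANOVA and
# Tukey HSD.

#' Default reference-assay map
#'
#' Gene assays are normalized against GAPDH and miRNA assays against
#' SNORD-47, the conventional small-RNA control.
#'
#' @param assays Character vector of assay names.
#' @return Named character vector assay -> reference assay.
#' @export
default_reference_map <- function(assays) {
  ref <- ifelse(grepl("^hsa-|-mir-|^mir", tolower(assays)), "SNORD-47", "GAPDH")
  setNames(ref, assays)
}

#' Relative expression by the 2^-ddCt method
#'
#' For each replicate, dCt = Ct(assay) - Ct(reference assay, same sample);
#' ddCt = dCt - mean dCt of the control group; fold change = 2^-ddCt. The
#' summary fold change per group is the geometric mean of its replicate
#' fold changes (fold changes live on a log scale). Group differences in
#' dCt are tested by one-way ANOVA with Tukey HSD contrasts, and normality
#' of the group-centered dCt residuals by the Kolmogorov-Smirnov test.
#'
#' @param ct Ct tibble with columns `sample_id`, `group`, `assay`, `ct`
#'   (see [read_ct_table()]).
#' @param assay Target assay to quantify.
#' @param reference Reference assay name; defaults to
#'   [default_reference_map()] of `assay`.
#' @param control Label of the baseline group (default `"control"`).
#' @param alpha Significance level for the `significant` flag (default
#'   0.05).
#' @return Object of class `ddct_result`: a list with the per-replicate
#'   fold-change tibble (`folds`), per-group geometric-mean fold changes
#'   (`group_means`), `mean_fold_change` (treated groups pooled), `p_anova`,
#'   `p_tukey`, `normality_p`, and `significant` (`p_anova < alpha`).
#' @export
delta_delta_ct <- function(ct, assay, reference = NULL,
                           control = "control", alpha = 0.05) {
  ct <- validate_ct(ct)
  reference <- reference %||% unname(default_reference_map(assay)[assay])
  tgt <- dplyr::filter(ct, .data$assay == !!assay)
  ref <- dplyr::filter(ct, .data$assay == !!reference)
  if (!nrow(tgt)) stop_input("no measurements for assay %s", assay)
  miss <- setdiff(tgt$sample_id, ref$sample_id)
  if (length(miss)) {
    stop_input("missing reference (%s) measurement for sample(s): %s",
               reference, paste(miss, collapse = ", "))
  }
  d <- dplyr::inner_join(tgt, ref[, c("sample_id", "ct")],
                         by = "sample_id", suffix = c("", "_ref"))
  d <- dplyr::mutate(d, delta_ct = .data$ct - .data$ct_ref)
  if (!control %in% d$group) stop_input("control group '%s' absent", control)
  tab <- table(d$group)
  if (any(tab < 2L)) {
    stop_input("group(s) with fewer than 2 replicates: %s",
               paste(names(tab)[tab < 2L], collapse = ", "))
  }
  baseline <- mean(d$delta_ct[d$group == control])
  d <- dplyr::mutate(d, ddct = .data$delta_ct - baseline,
                     fold = 2^(-.data$ddct))
  folds <- dplyr::select(d, "sample_id", "group", "delta_ct", "ddct", "fold")

  geo <- function(x) exp(mean(log(x)))
  group_means <- dplyr::summarise(
    dplyr::group_by(folds, .data$group),
    mean_fold_change = geo(.data$fold), n = dplyr::n(), .groups = "drop")

  treated_folds <- folds$fold[folds$group != control]
  mean_fc <- if (length(treated_folds)) geo(treated_folds) else NA_real_

  groups <- split(d$delta_ct, d$group)
  at <- anova_tukey(groups)
  resid <- unlist(lapply(groups, function(x) x - mean(x)), use.names = FALSE)
  norm_p <- if (length(resid) >= 3 && sd(resid) > 0) ks_normality(resid)
            else NA_real_

  structure(list(assay = assay, reference = reference, control = control,
                 folds = folds, group_means = group_means,
                 mean_fold_change = mean_fc,
                 p_anova = at$p_anova, p_tukey = at$p_tukey,
                 normality_p = norm_p,
                 significant = is.finite(at$p_anova) && at$p_anova < alpha),
            class = "ddct_result")
}

#' @export
print.ddct_result <- function(x, ...) {
  cat(sprintf("2^-ddCt: %s (reference %s, baseline group '%s')\n",
              x$assay, x$reference, x$control))
  cat(sprintf("  mean fold change (treated): %.4g\n", x$mean_fold_change))
  cat(sprintf("  ANOVA p = %.4g; KS normality p = %.4g; significant: %s\n",
              x$p_anova, x$normality_p, x$significant))
  invisible(x)
}

#' One-sample Kolmogorov-Smirnov normality test
#'
#' Tests the values against a normal distribution with the sample mean and
#' standard deviation, returning the asymptotic p-value
#' `2 * sum (-1)^(k-1) exp(-2 k^2 n D^2)`. This is the plain KS variant
#' with estimated parameters (as in the SPSS one-sample KS dialog); it is
#' conservative because no Lilliefors correction is applied.
#'
#' @param values Numeric vector, n >= 3, non-constant.
#' @return p-value, with the statistic in `attr(, "statistic")`.
#' @export
ks_normality <- function(values) {
  n <- length(values)
  if (n < 3L) stop_input("need at least 3 values for the KS test")
  s <- sd(values)
  if (s == 0) stop_input("values are constant (zero standard deviation)")
  x <- sort(values)
  f <- pnorm(x, mean = mean(values), sd = s)
  i <- seq_len(n)
  d <- max(pmax(i / n - f, f - (i - 1) / n))
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * n * d^2))
  p <- min(1, max(0, p))
  structure(p, statistic = d)
}

#' One-way ANOVA with Tukey HSD post hoc contrasts
#'
#' Classical fixed-effects one-way ANOVA (via `stats::aov`) plus Tukey
#' honestly-significant-difference p-values from the studentized-range
#' distribution for all pairwise group contrasts. When all observations are
#' identical the F statistic is 0/0 and the p-value is 1 by convention.
#'
#' @param groups Named list of numeric vectors, >= 2 groups with >= 2
#'   observations each.
#' @return List with `p_anova`, `f` (the F statistic), and `p_tukey`, a
#'   named vector of contrast p-values (`"B-A"` style names).
#' @export
anova_tukey <- function(groups) {
  if (length(groups) < 2L) stop_input("need at least 2 groups")
  if (any(lengths(groups) < 2L)) {
    stop_input("every group needs at least 2 observations")
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  df <- data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(names(groups), lengths(groups)), levels = names(groups)))
  if (sd(df$y) == 0) {
    cn <- utils::combn(names(groups), 2, function(p) paste(p[2], p[1], sep = "-"))
    return(list(p_anova = 1, f = 0,
                p_tukey = setNames(rep(1, length(cn)), cn)))
  }
  fit <- aov(y ~ g, data = df)
  an <- summary(fit)[[1]]
  f <- an[["F value"]][1]
  p <- an[["Pr(>F)"]][1]
  if (!is.finite(f)) { f <- 0; p <- 1 }
  tk <- TukeyHSD(fit)$g
  p_tukey <- setNames(tk[, "p adj"], rownames(tk))
  # zero residual variance makes Tukey p NaN; resolve by the mean contrast
  bad <- !is.finite(p_tukey)
  if (any(bad)) p_tukey[bad] <- ifelse(tk[bad, "diff"] == 0, 1, 0)
  list(p_anova = unname(p), f = unname(f), p_tukey = p_tukey)
}
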