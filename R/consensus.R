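#' Tally per-miRNA evidence over a candidate gene set
#'
#' For each miRNA, counts distinct evidence sources, genes with at least one
#' predicted-class record, genes with at least one validated-class record,
#' and positive/negative validated evidence records, restricted to the
#' candidate gene set. Records for genes outside the set are ignored. The
#' validated score is the number of validated genes and the predicted score
#' the number of predicted genes — i.e. the miRNA's simultaneous coverage of
#' the candidate set under each evidence class. The integrated score is a
#' multi-source confidence aggregate: the sum over covered genes of the
#' maximum per-source confidence (see Details).
#'
#' @details Gene and miRNA identifiers are matched case-insensitively;
#' reported miRNA ids keep the spelling of their first occurrence. The
#' integrated score is this package's reproducible aggregate (databases that
#' publish an "integrated score" do not disclose their formula); it lies in
#' \[0, number of genes\] and is order-compatible with coverage.
#'
#' @param evidence Evidence tibble (see [read_evidence_table()]).
#' @param genes Candidate gene set (character vector; canonicalized).
#' @param mirna Optional character vector of miRNA ids to summarize; defaults
#'   to every miRNA in the table. Ids absent from the table yield all-zero
#'   rows.
#' @return Tibble with one row per miRNA: `mirna_id`, `integrated_score`,
#'   `n_sources`, `n_predicted_genes`, `positive_evidence`,
#'   `negative_evidence`, `net_evidence`, `n_validated_genes`,
#'   `validated_score`, `predicted_score`, `coverage` (genes with evidence of
#'   either class).
#' @export
#' @examples
#' ev <- tibble::tibble(
#'   mirna_id = "hsa-miR-16-5p", gene_id = c("AR", "MET"),
#'   source_name = "tarbase", source_class = "validated",
#'   direction = "positive", confidence = 1)
#' summarize_mirnas(ev, c("AR", "MET", "EGFR"))
summarize_mirnas <- function(evidence, genes, mirna = NULL) {
  evidence <- validate_evidence(evidence)
  genes <- gene_set(genes)

  ev <- evidence
  ev$gene_id <- canon_gene(ev$gene_id)
  ev$.key <- canon_mirna_key(ev$mirna_id)
  ev <- dplyr::filter(ev, .data$gene_id %in% genes)

  if (is.null(mirna)) {
    ids <- evidence$mirna_id[!duplicated(canon_mirna_key(evidence$mirna_id))]
  } else {
    ids <- mirna
  }
  keys <- canon_mirna_key(ids)

  per <- dplyr::group_by(ev, .data$.key)
  per <- dplyr::summarise(
    per,
    n_sources = dplyr::n_distinct(.data$source_name),
    n_predicted_genes = dplyr::n_distinct(
      .data$gene_id[.data$source_class == "predicted"]),
    n_validated_genes = dplyr::n_distinct(
      .data$gene_id[.data$source_class == "validated"]),
    positive_evidence = sum(.data$source_class == "validated" &
                              .data$direction == "positive"),
    negative_evidence = sum(.data$source_class == "validated" &
                              .data$direction == "negative"),
    coverage = dplyr::n_distinct(.data$gene_id),
    integrated_score = sum(vapply(
      split(.data$confidence, .data$gene_id), max, numeric(1))),
    .groups = "drop")

  out <- tibble::tibble(mirna_id = ids, .key = keys)
  out <- dplyr::left_join(out, per, by = ".key")
  out <- dplyr::mutate(
    out,
    dplyr::across(c("n_sources", "n_predicted_genes", "n_validated_genes",
                    "positive_evidence", "negative_evidence", "coverage"),
                  ~ as.integer(tidyr::replace_na(.x, 0L))),
    integrated_score = tidyr::replace_na(.data$integrated_score, 0),
    net_evidence = net_evidence(.data$positive_evidence,
                                .data$negative_evidence),
    validated_score = .data$n_validated_genes,
    predicted_score = .data$n_predicted_genes)
  dplyr::select(out, "mirna_id", "integrated_score", "n_sources",
                "n_predicted_genes", "positive_evidence", "negative_evidence",
                "net_evidence", "n_validated_genes", "validated_score",
                "predicted_score", "coverage")
}

#' Summarize a single miRNA
#'
#' Convenience wrapper around [summarize_mirnas()] for one id.
#'
#' @inheritParams summarize_mirnas
#' @param mirna_id A single miRNA id.
#' @return One-row tibble (all-zero when the id is absent from the table).
#' @export
summarize_mirna <- function(evidence, genes, mirna_id) {
  stopifnot(length(mirna_id) == 1L)
  summarize_mirnas(evidence, genes, mirna = mirna_id)
}

#' Net validated evidence
#'
#' Positive minus negative validated-evidence record counts; may be
#' negative.
#'
#' @param positive,negative Non-negative record counts (vectorized).
#' @return Integer vector `positive - negative`.
#' @export
#' @examples
#' net_evidence(15, 1)  # 14
net_evidence <- function(positive, negative) {
  if (any(positive < 0) || any(negative < 0)) {
    stop_input("evidence counts must be non-negative")
  }
  as.integer(positive) - as.integer(negative)
}

#' Integrated evidence score for one miRNA
#'
#' Sum over candidate genes of the maximum per-source confidence among the
#' miRNA's records for that gene (either evidence class); 0 when the miRNA
#' has no records over the set.
#'
#' @inheritParams summarize_mirna
#' @return A single number in \[0, `length(genes)`\].
#' @export
integrated_score <- function(evidence, genes, mirna_id) {
  summarize_mirna(evidence, genes, mirna_id)$integrated_score
}

#' Rank miRNAs by simultaneous multi-gene coverage
#'
#' Filters to miRNAs whose coverage (candidate genes with evidence of either
#' class) reaches `min_coverage`, then sorts by validated score, predicted
#' score, net evidence and integrated score (all descending) with a final
#' lexicographic tie-break on the miRNA id, and keeps the first `top_k`.
#'
#' @inheritParams summarize_mirnas
#' @param min_coverage Minimum number of covered candidate genes (>= 1).
#' @param top_k Number of top miRNAs to return (>= 1).
#' @return A tibble of class `mirna_ranking` with the [summarize_mirnas()]
#'   columns plus `rank`; the filter and sort criteria are recorded in
#'   `attr(, "ranking_key")`. Empty (zero rows) when nothing passes the
#'   filter.
#' @export
rank_mirnas <- function(evidence, genes, min_coverage = 2L, top_k = 3L) {
  min_coverage <- assert_count(min_coverage, "min_coverage", min = 1L)
  top_k <- assert_count(top_k, "top_k", min = 0L)
  summ <- summarize_mirnas(evidence, genes)
  summ <- dplyr::filter(summ, .data$coverage >= min_coverage)
  summ <- dplyr::arrange(
    summ,
    dplyr::desc(.data$validated_score), dplyr::desc(.data$predicted_score),
    dplyr::desc(.data$net_evidence), dplyr::desc(.data$integrated_score),
    canon_mirna_key(.data$mirna_id))
  summ <- head(summ, top_k)
  summ <- dplyr::mutate(summ, rank = dplyr::row_number(), .before = 1L)
  structure(summ,
            class = c("mirna_ranking", class(summ)),
            ranking_key = list(
              filter = list(min_coverage = min_coverage),
              sort = c("validated_score desc", "predicted_score desc",
                       "net_evidence desc", "integrated_score desc",
                       "mirna_id asc"),
              top_k = top_k))
}
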