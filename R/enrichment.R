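# Over-representation analysis: exact hypergeometric upper tail computed in
# log space, Benjamini-Hochberg step-up control, and a tidy per-term driver.

#' Hypergeometric upper-tail probability
#'
#' P\[X >= count\] for X ~ Hypergeometric(universe_size, term_size,
#' query_size): the probability that a random query of `query_size` genes
#' drawn from a universe of `universe_size` overlaps a term of `term_size`
#' genes in at least `count` members. Terms are accumulated in log space
#' (log-binomials and log-sum-exp), so small tail masses do not underflow.
#'
#' @param count Observed overlap (non-negative integer).
#' @param query_size,term_size,universe_size Set sizes.
#' @return A probability in \[0, 1\].
#' @export
#' @examples
#' hypergeom_upper_tail(4, 6, 10, 50)
hypergeom_upper_tail <- function(count, query_size, term_size, universe_size) {
  count <- assert_count(count, "count")
  query_size <- assert_count(query_size, "query_size")
  term_size <- assert_count(term_size, "term_size")
  universe_size <- assert_count(universe_size, "universe_size")
  if (query_size > universe_size || term_size > universe_size ||
      count > query_size || count > term_size) {
    stop_input("inconsistent counts: need count <= query_size <= universe_size and count <= term_size <= universe_size")
  }
  if (count == 0L) return(1)
  kmax <- min(term_size, query_size)
  kmin <- max(0L, query_size - (universe_size - term_size))
  if (count <= kmin) return(1)
  k <- count:kmax
  logp <- lchoose(term_size, k) + lchoose(universe_size - term_size,
                                          query_size - k) -
    lchoose(universe_size, query_size)
  mx <- max(logp)
  min(1, exp(mx + log(sum(exp(logp - mx)))))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: p-values are ranked, scaled by
#' m/rank, made monotone by a cumulative minimum from the largest rank down,
#' clipped to \[0, 1\], and returned in the input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order as `p`.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(is.na(p) | p < 0 | p > 1)) stop_input("p-values must lie in [0,1]")
  m <- length(p)
  ord <- order(p)
  scaled <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Over-representation of a gene set against term annotations
#'
#' Tests each annotation term for over-representation of the query genes by
#' the exact hypergeometric upper tail, adjusts across the tested terms with
#' Benjamini-Hochberg, and flags terms with FDR below `threshold` as
#' significant. Annotation genes are intersected with the universe before
#' counting; only terms overlapping the query are reported.
#'
#' @param query Query gene set (character vector).
#' @param annotation Named list of character vectors (term -> genes), as
#'   returned by [read_gmt()].
#' @param universe Background gene set; defaults to the union of all
#'   annotated genes. Every query gene must be in the universe.
#' @param threshold FDR significance cutoff (default 0.05).
#' @return Tibble with one row per overlapping term: `term_id`, `term_name`,
#'   `count`, `term_size`, `universe_size`, `query_size`, `p_value`, `fdr`,
#'   `significant`; sorted by `fdr` then `term_id`.
#' @export
enrich <- function(query, annotation, universe = NULL, threshold = 0.05) {
  query <- gene_set(query)
  if (!length(annotation) || is.null(names(annotation))) {
    stop_input("annotation must be a named list of gene vectors")
  }
  ann <- lapply(annotation, canon_gene)
  if (is.null(universe)) {
    universe <- gene_set(unique(unlist(ann, use.names = FALSE)))
  } else {
    universe <- gene_set(universe)
  }
  outside <- setdiff(query, universe)
  if (length(outside)) {
    stop_input("query gene(s) outside the universe: %s",
               paste(outside, collapse = ", "))
  }
  desc <- attr(annotation, "description") %||%
    setNames(names(annotation), names(annotation))

  rows <- purrr::imap(ann, function(genes, term) {
    genes <- intersect(genes, universe)
    ov <- length(intersect(genes, query))
    if (ov == 0L) return(NULL)
    tibble::tibble(
      term_id = term,
      term_name = unname(desc[term] %||% term),
      count = ov,
      term_size = length(genes),
      universe_size = length(universe),
      query_size = length(query),
      p_value = hypergeom_upper_tail(ov, length(query), length(genes),
                                     length(universe)))
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    return(tibble::tibble(term_id = character(0), term_name = character(0),
                          count = integer(0), term_size = integer(0),
                          universe_size = integer(0), query_size = integer(0),
                          p_value = numeric(0), fdr = numeric(0),
                          significant = logical(0)))
  }
  out$fdr <- bh_fdr(out$p_value)
  out$significant <- out$fdr < threshold
  dplyr::arrange(out, .data$fdr, .data$term_id)
}
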