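# Independent oracles: deliberately naive re-implementations (set
# comprehension over raw rows, exhaustive scans, plain DP, combinatorial
# sums) used to cross-check the package's vectorized code paths.

# --- consensus ---------------------------------------------------------

# Brute-force per-miRNA recount by looping over raw rows.
oracle_summary <- function(evidence, genes, id) {
  genes <- toupper(trimws(genes))
  rows <- evidence[tolower(evidence$mirna_id) == tolower(id) &
                     toupper(trimws(evidence$gene_id)) %in% genes, ,
                   drop = FALSE]
  val <- rows[rows$source_class == "validated", , drop = FALSE]
  pred <- rows[rows$source_class == "predicted", , drop = FALSE]
  best <- 0
  for (g in unique(toupper(rows$gene_id))) {
    best <- best + max(rows$confidence[toupper(rows$gene_id) == g])
  }
  list(
    n_sources = length(unique(rows$source_name)),
    n_predicted_genes = length(unique(toupper(pred$gene_id))),
    n_validated_genes = length(unique(toupper(val$gene_id))),
    positive_evidence = sum(val$direction == "positive"),
    negative_evidence = sum(val$direction == "negative"),
    net_evidence = sum(val$direction == "positive") -
      sum(val$direction == "negative"),
    coverage = length(unique(toupper(rows$gene_id))),
    integrated_score = best)
}

# Brute-force ranking: recount every miRNA, filter, order().
oracle_rank <- function(evidence, genes, min_coverage, top_k) {
  ids <- unique(evidence$mirna_id)
  summ <- lapply(ids, function(id) oracle_summary(evidence, genes, id))
  keep <- vapply(summ, function(s) s$coverage >= min_coverage, logical(1))
  ids <- ids[keep]; summ <- summ[keep]
  if (!length(ids)) return(character(0))
  vs <- vapply(summ, `[[`, numeric(1), "n_validated_genes")
  ps <- vapply(summ, `[[`, numeric(1), "n_predicted_genes")
  ne <- vapply(summ, `[[`, numeric(1), "net_evidence")
  is <- vapply(summ, `[[`, numeric(1), "integrated_score")
  ord <- order(-vs, -ps, -ne, -is, tolower(ids))
  utils::head(ids[ord], top_k)
}

# Random well-formed evidence table over <=10 miRNAs x 6 genes x 12 sources.
random_evidence <- function(n_rows = 200) {
  mirnas <- sprintf("hsa-miR-%d-5p", 1:10)
  genes <- c("AR", "PIK3CA", "PIK3CB", "MET", "FGFR4", "EGFR")
  sources <- sprintf("db%02d", 1:12)
  combos <- expand.grid(m = mirnas, g = genes, s = sources,
                        stringsAsFactors = FALSE)
  pick <- combos[sample(nrow(combos), min(n_rows, nrow(combos))), ]
  tibble::tibble(
    mirna_id = pick$m, gene_id = pick$g, source_name = pick$s,
    source_class = sample(c("validated", "predicted"), nrow(pick), TRUE),
    direction = sample(c("positive", "negative"), nrow(pick), TRUE,
                       prob = c(0.85, 0.15)),
    confidence = round(runif(nrow(pick)), 3))
}

# --- duplex ------------------------------------------------------------

rc <- function(x) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", x), "")[[1]]), collapse = "")
}

# Exhaustive per-offset scan testing the four site patterns directly.
oracle_seed_scan <- function(mirna, utr) {
  pat <- list(
    "8mer" = paste0(chartr("ACGU", "UGCA", substr(mirna, 8, 8)),
                    rc(substr(mirna, 2, 7)), "A"),
    "7mer-m8" = paste0(chartr("ACGU", "UGCA", substr(mirna, 8, 8)),
                       rc(substr(mirna, 2, 7))),
    "7mer-A1" = paste0(rc(substr(mirna, 2, 7)), "A"),
    "6mer" = rc(substr(mirna, 2, 7)))
  n <- nchar(utr)
  hits <- list()
  for (p in 0:(n - 1)) {                       # 0-based start
    for (tp in names(pat)) {                   # most specific first
      w <- nchar(pat[[tp]])
      if (p + w > n) next
      if (substr(utr, p + 1, p + w) != pat[[tp]]) next
      # suppress the less specific variants of the same core match
      core0 <- if (tp %in% c("8mer", "7mer-m8")) p + 1 else p
      already <- vapply(hits, function(h) h$core0 == core0, logical(1))
      if (any(already)) next
      hits[[length(hits) + 1]] <- list(start = p, end = p + w,
                                       site_type = tp, core0 = core0)
    }
  }
  if (!length(hits)) {
    return(tibble::tibble(start = integer(0), end = integer(0),
                          site_type = character(0)))
  }
  out <- tibble::tibble(
    start = vapply(hits, `[[`, numeric(1), "start"),
    end = vapply(hits, `[[`, numeric(1), "end"),
    site_type = vapply(hits, `[[`, character(1), "site_type"))
  out$start <- as.integer(out$start); out$end <- as.integer(out$end)
  out[order(out$start, out$end), ]
}

# Plain quadratic-time Gotoh DP recomputing only the optimal score.
oracle_align_score <- function(mirna, window) {
  a <- strsplit(paste(rev(strsplit(mirna, "")[[1]]), collapse = ""), "")[[1]]
  b <- strsplit(window, "")[[1]]
  sc <- function(x, y) {
    k <- paste0(x, y)
    if (k %in% c("AU", "UA", "GC", "CG")) 5
    else if (k %in% c("GU", "UG")) 1 else -3
  }
  n <- length(a); m <- length(b); NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (j in 1:m) Y[1, j + 1] <- -8 - 2 * (j - 1)
  for (i in 1:n) X[i + 1, 1] <- -8 - 2 * (i - 1)
  for (i in 1:n) for (j in 1:m) {
    M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + sc(a[i], b[j])
    X[i + 1, j + 1] <- max(M[i, j + 1] - 8, X[i, j + 1] - 2, Y[i, j + 1] - 8)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - 8, Y[i + 1, j] - 2, X[i + 1, j] - 8)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

random_rna_str <- function(len, first = NULL) {
  s <- sample(c("A", "C", "G", "U"), len, replace = TRUE)
  if (!is.null(first)) s[1] <- first
  paste(s, collapse = "")
}

# --- enrichment --------------------------------------------------------

# Tail mass by direct combinatorial sum (plain choose(), no logs).
oracle_hypergeom <- function(count, q, t, u) {
  if (count == 0) return(1)
  k <- count:min(t, q)
  sum(choose(t, k) * choose(u - t, q - k)) / choose(u, q)
}

# Hand-applied BH step-up rule.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, p[ord[i]] * m / i)
    adj[ord[i]] <- min(1, running)
  }
  adj
}

# --- expression / cell cycle ------------------------------------------

# Brute-force KS statistic: sup |empirical - model CDF| over sorted points.
oracle_ks_stat <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  f <- pnorm(xs, mean(x), sd(x))
  m <- 0
  for (i in 1:n) m <- max(m, abs(i / n - f[i]), abs((i - 1) / n - f[i]))
  m
}
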