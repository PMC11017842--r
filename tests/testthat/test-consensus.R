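genes6 <- c("AR", "PIK3CA", "PIK3CB", "MET", "FGFR4", "EGFR")

# Build an evidence table realizing given validated positive/negative record
# counts spread over `n_genes` genes, plus predicted records.
make_candidate <- function(id, n_pos, n_neg, n_val_genes,
                           n_pred_genes = n_val_genes) {
  val_genes <- rep(genes6[seq_len(n_val_genes)], length.out = n_pos + n_neg)
  validated <- tibble::tibble(
    mirna_id = id, gene_id = val_genes,
    source_name = paste0("valdb", stats::ave(seq_along(val_genes), val_genes,
                                             FUN = seq_along)),
    source_class = "validated",
    direction = rep(c("positive", "negative"), c(n_pos, n_neg)),
    confidence = 1)
  predicted <- tibble::tibble(
    mirna_id = id, gene_id = genes6[seq_len(n_pred_genes)],
    source_name = "targetscan", source_class = "predicted",
    direction = "positive", confidence = 0.9)
  dplyr::bind_rows(validated, predicted)
}

test_that("summaries reproduce the candidate miRNA tally shapes", {
  # 15 positive + 1 negative validated records over 6 genes -> net 14
  ev <- make_candidate("Hsa-miR-16-5p", 15, 1, 6)
  s <- summarize_mirna(ev, genes6, "hsa-miR-16-5p")
  expect_equal(s$n_validated_genes, 6L)
  expect_equal(s$positive_evidence, 15L)
  expect_equal(s$negative_evidence, 1L)
  expect_equal(s$net_evidence, 14L)
  expect_equal(s$validated_score, 6L)
})

test_that("net evidence is positive minus negative and rejects negatives", {
  expect_equal(net_evidence(7, 2), 5L)
  expect_equal(net_evidence(6, 2), 4L)
  expect_equal(net_evidence(0, 0), 0L)
  expect_equal(net_evidence(1, 4), -3L)
  expect_error(net_evidence(-1, 0), "non-negative")
})

test_that("empty and absent miRNAs give all-zero summaries", {
  ev <- make_candidate("m1", 2, 0, 2)
  s <- summarize_mirna(ev[0, ], genes6, "m1")
  expect_equal(s$net_evidence, 0L)
  expect_equal(s$coverage, 0L)
  s2 <- summarize_mirna(ev, genes6, "never-seen")
  expect_equal(s2$integrated_score, 0)
  expect_equal(s2$n_sources, 0L)
})

test_that("integrated score sums per-gene maxima of confidence", {
  ev <- tibble::tibble(
    mirna_id = "m1", gene_id = c("AR", "AR"), source_name = c("a", "b"),
    source_class = "predicted", direction = "positive",
    confidence = c(0.4, 0.9))
  expect_equal(integrated_score(ev, genes6, "m1"), 0.9)
  expect_equal(integrated_score(ev[1, ], genes6, "m1"), 0.4)

  withr::local_seed(42)
  for (rep_i in 1:20) {
    ev <- random_evidence(150)
    id <- sample(unique(ev$mirna_id), 1)
    expect_equal(integrated_score(ev, genes6, id),
                 oracle_summary(ev, genes6, id)$integrated_score,
                 tolerance = 1e-12)
  }
})

test_that("records for genes outside the candidate set are ignored", {
  ev <- make_candidate("m1", 4, 0, 4)
  extra <- tibble::tibble(mirna_id = "m1", gene_id = "TP53",
                          source_name = "tarbase", source_class = "validated",
                          direction = "positive", confidence = 1)
  s1 <- summarize_mirna(ev, genes6, "m1")
  s2 <- summarize_mirna(dplyr::bind_rows(ev, extra), genes6, "m1")
  expect_equal(s1, s2)
})

test_that("summaries are permutation invariant and conserve record counts", {
  withr::local_seed(99)
  for (rep_i in 1:10) {
    ev <- random_evidence(180)
    ids <- unique(ev$mirna_id)
    perm <- ev[sample(nrow(ev)), ]
    a <- summarize_mirnas(ev, genes6, mirna = sort(ids))
    b <- summarize_mirnas(perm, genes6, mirna = sort(ids))
    expect_equal(a, b)
    # conservation: positive + negative = validated record count
    for (id in ids) {
      s <- a[a$mirna_id == id, ]
      expect_equal(s$positive_evidence + s$negative_evidence,
                   sum(ev$source_class == "validated" & ev$mirna_id == id))
    }
    expect_identical(
      tidy(rank_mirnas(ev, genes6, 1, 99))$mirna_id,
      tidy(rank_mirnas(perm, genes6, 1, 99))$mirna_id)
  }
})

test_that("adding records moves scores in the documented direction", {
  ev <- make_candidate("m1", 3, 0, 3)
  base <- summarize_mirna(ev, genes6, "m1")
  new_val <- tibble::tibble(mirna_id = "m1", gene_id = "EGFR",
                            source_name = "newdb", source_class = "validated",
                            direction = "positive", confidence = 1)
  up <- summarize_mirna(dplyr::bind_rows(ev, new_val), genes6, "m1")
  expect_gte(up$validated_score, base$validated_score)

  neg <- tibble::tibble(mirna_id = "m1", gene_id = "AR",
                        source_name = "negdb", source_class = "validated",
                        direction = "negative", confidence = 1)
  dn <- summarize_mirna(dplyr::bind_rows(ev, neg), genes6, "m1")
  expect_equal(dn$net_evidence, base$net_evidence - 1L)
})

test_that("ranking filters by coverage, sorts hierarchically, breaks ties by id", {
  ev <- dplyr::bind_rows(
    make_candidate("Hsa-miR-16-5p", 15, 1, 6),
    make_candidate("Hsa-miR-124-3p", 7, 2, 6),
    make_candidate("Hsa-miR-27a-3p", 6, 2, 5, n_pred_genes = 4),
    make_candidate("distractor-mir", 1, 0, 1))
  r <- rank_mirnas(ev, genes6, min_coverage = 2, top_k = 3)
  expect_equal(r$mirna_id,
               c("Hsa-miR-16-5p", "Hsa-miR-124-3p", "Hsa-miR-27a-3p"))
  expect_false("distractor-mir" %in% r$mirna_id)
  expect_equal(attr(r, "ranking_key")$filter$min_coverage, 2L)

  tie <- dplyr::bind_rows(make_candidate("mir-b", 3, 0, 3),
                          make_candidate("mir-a", 3, 0, 3))
  expect_equal(rank_mirnas(tie, genes6, 1, 5)$mirna_id, c("mir-a", "mir-b"))
})

test_that("planted hub miRNAs always outrank sparse background", {
  withr::local_seed(7)
  for (rep_i in 1:5) {
    sim <- simulate_evidence(seed = sample.int(1e6, 1))
    hubs <- sim$truth$mirna_id[sim$truth$is_hub]
    r <- rank_mirnas(sim$evidence, sim$genes, min_coverage = 2,
                     top_k = length(hubs))
    expect_setequal(r$mirna_id, hubs)
  }
})

test_that("tidiers and plot return the documented shapes", {
  ev <- make_candidate("m1", 3, 0, 3)
  r <- rank_mirnas(ev, genes6, 1, 5)
  expect_s3_class(tidy(r), "tbl_df")
  expect_equal(glance(r)$n_ranked, 1L)
  expect_s3_class(autoplot(r), "ggplot")
})
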