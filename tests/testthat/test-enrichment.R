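test_that("hypergeometric tail: trivial and degenerate cases", {
  expect_equal(hypergeom_upper_tail(0, 6, 10, 50), 1)
  expect_equal(hypergeom_upper_tail(3, 6, 50, 50), 1)   # term = universe
  expect_error(hypergeom_upper_tail(7, 6, 10, 50), "inconsistent")
  expect_error(hypergeom_upper_tail(4, 6, 10, 5), "inconsistent")
})

test_that("hypergeometric tail matches enumeration and the reference CDF", {
  expect_equal(hypergeom_upper_tail(4, 6, 10, 50),
               oracle_hypergeom(4, 6, 10, 50), tolerance = 1e-12)
  withr::local_seed(61)
  for (rep_i in 1:60) {
    u <- sample(10:60, 1)
    t <- sample(1:u, 1)
    q <- sample(1:u, 1)
    k <- sample(0:min(t, q), 1)
    mine <- hypergeom_upper_tail(k, q, t, u)
    expect_equal(mine, oracle_hypergeom(k, q, t, u), tolerance = 1e-10)
    expect_equal(mine, phyper(k - 1, t, u - t, q, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("adding a non-query gene to a term never lowers the p-value", {
  withr::local_seed(62)
  for (rep_i in 1:20) {
    u <- sample(20:60, 1)
    q <- sample(2:8, 1)
    t <- sample(q:(u - 1), 1)
    k <- sample(1:min(t, q), 1)
    expect_gte(hypergeom_upper_tail(k, q, t + 1, u),
               hypergeom_upper_tail(k, q, t, u) - 1e-12)
  }
})

test_that("BH follows the step-up rule and is order equivariant", {
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(numeric(0)), numeric(0))

  withr::local_seed(63)
  for (rep_i in 1:20) {
    p <- runif(sample(1:30, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
    expect_equal(bh_fdr(p), p.adjust(p, "BH"), tolerance = 1e-12)
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm]), bh_fdr(p)[perm])
  }
  expect_error(bh_fdr(c(0.1, 1.7)), "\\[0,1\\]")
})

test_that("enrich counts overlaps, ranks by FDR and flags significance", {
  genes6 <- c("AR", "PIK3CA", "PIK3CB", "MET", "FGFR4", "EGFR")
  universe <- c(genes6, sprintf("BG%05d", seq_len(19994)))
  ann <- list(hit_term = genes6,
              partial = c("AR", "MET", "BG00001", "BG00002"),
              unrelated = c("BG00003", "BG00004"))
  res <- enrich(genes6, ann, universe = universe)
  expect_equal(res$term_id[1], "hit_term")
  expect_equal(res$count[res$term_id == "hit_term"], 6L)
  expect_equal(min(res$p_value), res$p_value[res$term_id == "hit_term"])
  expect_true(res$significant[1])
  expect_false("unrelated" %in% res$term_id)

  expect_equal(nrow(enrich(c("AR"), list(t = c("MET")),
                           universe = c("AR", "MET"))), 0)
  expect_error(enrich(c("AR", "NOPE"), ann, universe = universe), "NOPE")
})

test_that("enrich agrees with a per-term oracle on a toy annotation", {
  withr::local_seed(64)
  universe <- sprintf("G%02d", 1:40)
  ann <- lapply(1:5, function(i) sample(universe, sample(4:12, 1)))
  names(ann) <- paste0("T", 1:5)
  query <- sample(universe, 6)
  res <- enrich(query, ann, universe = universe)
  for (i in seq_len(nrow(res))) {
    tg <- ann[[res$term_id[i]]]
    ov <- length(intersect(tg, query))
    expect_equal(res$count[i], ov)
    expect_equal(res$p_value[i],
                 oracle_hypergeom(ov, length(query), length(tg), 40),
                 tolerance = 1e-10)
  }
  expect_equal(res$fdr, oracle_bh(res$p_value), tolerance = 1e-12)
  expect_equal(res$fdr, sort(res$fdr))
})

test_that("the universe defaults to the union of annotated genes", {
  ann <- list(a = c("AR", "MET"), b = c("MET", "EGFR", "FGFR4"))
  res <- enrich(c("AR", "MET"), ann)
  expect_equal(unique(res$universe_size), 4L)
})
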