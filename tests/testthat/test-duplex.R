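test_that("seed sites: planted and negative cases", {
  withr::local_seed(11)
  m <- random_rna_str(22, first = "U")
  # full reverse complement of positions 1-8 embedded at offset 10 is an
  # 8mer (position 1 is U, so its complement is the required A1 adenine)
  insert <- rc(substr(m, 1, 8))
  utr <- paste0(random_rna_str(10), insert, random_rna_str(20))
  hits <- find_seed_sites(m, utr)
  hit8 <- hits[hits$site_type == "8mer", ]
  expect_equal(nrow(hit8), 1)
  expect_equal(hit8$start, 10L)
  expect_equal(hit8$end, 18L)

  # a UTR with no pyrimidine/purine partner for the seed at all
  m2 <- paste0("U", strrep("A", 21))
  expect_equal(nrow(find_seed_sites(m2, strrep("C", 50))), 0)
  expect_error(find_seed_sites("ACGUACG", "ACGU"), "at least 8")
})

test_that("seed sites equal the exhaustive per-offset oracle", {
  withr::local_seed(21)
  for (rep_i in 1:40) {
    m <- random_rna_str(22)
    utr <- random_rna_str(300)
    got <- find_seed_sites(m, utr)
    want <- oracle_seed_scan(m, utr)
    expect_equal(got, want)
  }
  # repetitive seed: overlapping core matches must all be reported
  m <- paste0("UGCGCGCG", random_rna_str(14))
  utr <- strrep("CGCGCGCG", 6)
  expect_equal(find_seed_sites(m, utr), oracle_seed_scan(m, utr))
})

test_that("duplex alignment handles perfect, degenerate and empty input", {
  m <- "UAGCAGCACGUAAAUAUUGGCG"
  a <- align_duplex(m, rc(m))
  expect_equal(nchar(a$mirna), 22)
  expect_equal(a$bars, strrep("|", 22))
  expect_false(grepl("-", a$mirna, fixed = TRUE))
  expect_equal(a$score, 22 * 5)

  deg <- align_duplex(m, "A")
  expect_equal(sum(strsplit(deg$utr, "")[[1]] == "-"), 21)
  expect_equal(nchar(deg$mirna), 22)

  expect_error(align_duplex(m, ""), "empty")
})

test_that("alignment score matches an independent DP and is reproducible", {
  withr::local_seed(31)
  for (rep_i in 1:40) {
    m <- random_rna_str(sample(16:24, 1))
    w <- random_rna_str(sample(8:30, 1))
    a <- align_duplex(m, w)
    expect_equal(a$score, oracle_align_score(m, w))
    b <- align_duplex(m, w)
    expect_identical(a, b)
    # the three strings always share one length; bars only at real pairs
    expect_equal(nchar(a$mirna), nchar(a$bars))
    expect_equal(nchar(a$utr), nchar(a$bars))
    cols <- cbind(strsplit(a$mirna, "")[[1]], strsplit(a$bars, "")[[1]],
                  strsplit(a$utr, "")[[1]])
    for (k in seq_len(nrow(cols))) {
      paired <- cols[k, 2] != " "
      if (paired) {
        key <- paste0(cols[k, 1], cols[k, 3])
        expect_true(key %in% c("AU", "UA", "GC", "CG", "GU", "UG"))
      }
    }
  }
})

test_that("free energy reproduces a hand-summed helix from the shipped table", {
  par <- duplex_energy_params()
  # 5'GCGC3' UTR against miRNA GCGC: stacks GC/CG, CG/GC, GC/CG
  a <- align_duplex("GCGC", "GCGC")
  expect_equal(a$bars, "||||")
  expect_equal(duplex_free_energy(a),
               par[["GC/CG"]] + par[["CG/GC"]] + par[["GC/CG"]] +
                 par[["initiation"]])
})

test_that("free energy: empty helix, monotone extension, translation invariance", {
  par <- duplex_energy_params()
  none <- align_duplex("AAAA", "CCCC")  # no possible pair
  dg0 <- duplex_free_energy(none)
  expect_equal(as.numeric(dg0), par[["initiation"]])
  expect_true(attr(dg0, "non_binding"))

  # extending a helix by one stacked WC pair strictly lowers delta G
  short <- align_duplex("GCG", "CGC")
  long <- align_duplex("GCGC", "GCGC")
  expect_lt(duplex_free_energy(long), duplex_free_energy(short))

  # any hit with at least one WC stack is below zero
  expect_lt(duplex_free_energy(align_duplex("GC", "GC")), 0)
  expect_lt(duplex_free_energy(align_duplex("AU", "AU")), 0)

  # same site with identical local context at different UTR offsets:
  # identical delta G (the energy has no positional dependence)
  withr::local_seed(41)
  m <- "UAGCAGCACGUAAAUAUUGGCG"
  site <- rc(substr(m, 1, 8))
  ctx <- random_rna_str(22)
  u1 <- paste0(ctx, site, random_rna_str(10))
  u2 <- paste0(random_rna_str(12), ctx, site, random_rna_str(25))
  r1 <- report_sites(c(m1 = m), c(u1 = u1), top_n = 1)
  r2 <- report_sites(c(m1 = m), c(u1 = u2), top_n = 1)
  expect_equal(r2$start, r1$start + 12L)
  expect_equal(r1$delta_g, r2$delta_g)
})

test_that("wobble pairs score as pairs but use the generic stack entry", {
  par <- duplex_energy_params()
  a <- align_duplex("GG", "UU")   # two G:U wobbles
  expect_equal(a$bars, "::")
  expect_equal(duplex_free_energy(a), par[["wobble"]] + par[["initiation"]])
})

test_that("report_sites ranks planted sites by binding strength", {
  withr::local_seed(51)
  m <- random_rna_str(22, first = "U")
  strong_site <- rc(m)                     # full-length complement
  weak_site <- paste0(rc(substr(m, 1, 8))) # seed only, scrambled flank
  utr <- paste0(random_rna_str(15), strong_site, random_rna_str(15),
                weak_site, random_rna_str(15))
  r <- report_sites(c(mir = m), c(u = utr), top_n = 5)
  expect_gte(nrow(r), 2)
  expect_equal(r$delta_g, sort(r$delta_g))
  expect_equal(r$start[1], 15L + 14L)      # 8mer begins at site offset + 14

  expect_equal(nrow(report_sites(c(mir = m), c(u = utr), top_n = 0)), 0)

  # permuting record order changes nothing
  m2 <- random_rna_str(22, first = "U")
  r1 <- report_sites(c(a = m, b = m2), c(x = utr, y = rev(utr)[1]), top_n = 3)
  r2 <- report_sites(c(b = m2, a = m), c(y = rev(utr)[1], x = utr), top_n = 3)
  expect_equal(r1, r2)
})
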