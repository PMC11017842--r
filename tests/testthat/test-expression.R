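make_ct <- function(trt_dct, ctl_dct, assay = "AR", ref = "GAPDH",
                    base_ref = 18) {
  n <- length(trt_dct)
  tibble::tibble(
    sample_id = rep(c(paste0("t", seq_len(n)), paste0("c", seq_len(n))),
                    each = 2),
    group = rep(c("treated", "control"), each = 2 * n),
    assay = rep(c(assay, ref), 2 * n),
    ct = as.vector(rbind(base_ref + c(trt_dct, ctl_dct),
                         rep(base_ref, 2 * n))))
}

test_that("ddCt: null, forced two-fold, and error cases", {
  ct <- make_ct(c(2, 2, 2), c(2, 2, 2))
  r <- delta_delta_ct(ct, "AR")
  expect_equal(r$mean_fold_change, 1)
  expect_equal(r$folds$fold, rep(1, 6))

  # treated dCt exactly one cycle below control -> fold 2
  r2 <- delta_delta_ct(make_ct(c(1, 1, 1), c(2, 2, 2)), "AR")
  expect_equal(r2$mean_fold_change, 2)

  bad <- make_ct(c(1, 1), c(2, 2))
  bad <- bad[!(bad$sample_id == "t1" & bad$assay == "GAPDH"), ]
  expect_error(delta_delta_ct(bad, "AR"), "t1")

  one_rep <- make_ct(1, 2)
  expect_error(delta_delta_ct(one_rep, "AR"), "fewer than 2")
})

test_that("ddCt is invariant to per-sample Ct offsets and reciprocal on swap", {
  withr::local_seed(71)
  ct <- simulate_ct(fold_changes = c(AR = 0.4), seed = 5)$ct
  r <- delta_delta_ct(ct, "AR")
  # add a sample-specific constant to every Ct of that sample
  shift <- ct
  offs <- setNames(runif(length(unique(ct$sample_id)), -3, 3),
                   unique(ct$sample_id))
  shift$ct <- shift$ct + offs[shift$sample_id]
  r2 <- delta_delta_ct(shift, "AR")
  expect_equal(r2$folds$fold, r$folds$fold, tolerance = 1e-10)

  swapped <- ct
  swapped$group <- ifelse(ct$group == "treated", "control", "treated")
  r3 <- delta_delta_ct(swapped, "AR")
  expect_equal(r3$mean_fold_change, 1 / r$mean_fold_change, tolerance = 1e-10)
})

test_that("KS statistic equals the brute-force sup difference", {
  withr::local_seed(72)
  for (rep_i in 1:10) {
    x <- rnorm(sample(5:60, 1), sample(-3:3, 1), runif(1, 0.5, 2))
    p <- ks_normality(x)
    expect_equal(as.numeric(attr(p, "statistic")), oracle_ks_stat(x),
                 tolerance = 1e-12)
    # same statistic as the stats::ks.test implementation
    ref <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
    expect_equal(as.numeric(attr(p, "statistic")),
                 unname(ref$statistic), tolerance = 1e-12)
    expect_true(p >= 0 && p <= 1)
  }
  expect_error(ks_normality(c(1, 2)), "at least 3")
  expect_error(ks_normality(rep(1, 5)), "constant")
})

test_that("KS p-values are calibrated for genuinely normal data", {
  withr::local_seed(73)
  reject <- vapply(1:200, function(i) ks_normality(rnorm(1000)) <= 0.05,
                   logical(1))
  expect_gte(mean(!reject), 0.94)
})

test_that("ANOVA/Tukey: identity, separation, and the two-group t-test link", {
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  r <- anova_tukey(same)
  expect_equal(r$f, 0)
  expect_equal(r$p_anova, 1)

  allsame <- list(a = c(5, 5), b = c(5, 5))
  expect_equal(anova_tukey(allsame)$p_anova, 1)
  expect_equal(unname(anova_tukey(allsame)$p_tukey), 1)

  withr::local_seed(74)
  far <- list(a = rnorm(3, 0, 1e-4), b = rnorm(3, 10, 1e-4))
  expect_lt(anova_tukey(far)$p_anova, 1e-6)

  for (rep_i in 1:10) {
    g <- list(a = rnorm(sample(3:8, 1)), b = rnorm(sample(3:8, 1), 0.5))
    expect_equal(anova_tukey(g)$p_anova,
                 t.test(g$a, g$b, var.equal = TRUE)$p.value,
                 tolerance = 1e-10)
  }

  r3 <- anova_tukey(list(a = rnorm(4), b = rnorm(4), c = rnorm(4)))
  expect_setequal(names(r3$p_tukey), c("b-a", "c-a", "c-b"))
  expect_error(anova_tukey(list(a = 1:3)), "at least 2 groups")
  expect_error(anova_tukey(list(a = 1:3, b = 2)), "at least 2 observations")
})

test_that("ddct result tidiers and plot expose the documented fields", {
  ct <- simulate_ct(fold_changes = c(AR = 0.4), seed = 9)$ct
  r <- delta_delta_ct(ct, "AR")
  expect_s3_class(tidy(r), "tbl_df")
  g <- glance(r)
  expect_named(g, c("assay", "reference", "mean_fold_change", "p_anova",
                    "normality_p", "significant"))
  expect_equal(g$reference, "GAPDH")
  expect_s3_class(autoplot(r), "ggplot")
})
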