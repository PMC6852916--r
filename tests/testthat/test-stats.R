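test_that("the {4,5} vs {1,2,3} rank configuration gives exact two-sided p = 0.2", {
  res <- mw_test(c(4, 5), c(1, 2, 3))
  expect_equal(res$u, 6)
  expect_equal(res$p_value, 0.2)
  expect_true(res$exact)
  expect_true(res$z > 0)
})

test_that("identical group multisets give Z = 0 and p = 1", {
  res <- mw_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$z, 0)
  expect_equal(res$p_value, 1)
  res2 <- mw_test(c(2, 2), c(2, 2, 2), exact = FALSE)
  expect_equal(res2$z, 0)
  expect_equal(res2$p_value, 1)
})

test_that("exact MW p matches enumeration for every group-size split of n <= 10", {
  set.seed(31)
  for (n in 4:10) {
    for (n1 in 1:(n - 1)) {
      vals <- sample(1:5, n, replace = TRUE)  # heavy ties on purpose
      x <- vals[seq_len(n1)]
      y <- vals[-seq_len(n1)]
      expect_equal(mw_test(x, y)$p_value, oracle_mw_exact_p(x, y),
                   tolerance = 1e-12,
                   info = sprintf("n1=%d n2=%d", n1, n - n1))
    }
  }
})

test_that("untied exact MW p agrees with wilcox.test's exact distribution", {
  set.seed(32)
  for (i in 1:10) {
    n1 <- sample(2:5, 1)
    n2 <- sample(2:5, 1)
    vals <- sample.int(1000, n1 + n2)  # distinct => no ties
    x <- vals[seq_len(n1)]
    y <- vals[-seq_len(n1)]
    expect_equal(mw_test(x, y)$p_value,
                 wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("large-sample MW agrees with wilcox.test's tie-corrected normal p", {
  set.seed(33)
  x <- round(rnorm(60, 0.3), 1)
  y <- round(rnorm(150), 1)
  res <- mw_test(x, y, exact = FALSE)
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(res$u, unname(ref$statistic))
})

test_that("per-tissue MW splits by tissue membership with a signed Z", {
  set.seed(34)
  n <- 400
  ann <- make_annotated(runif(n))
  # tissue A eQTLs get inflated significance; tissue B eQTLs stay at the null
  a_ids <- ann$snp_id[1:40]
  b_ids <- ann$snp_id[41:80]
  ann[1:40, `:=`(p_value = p_value / 50, neglog10p = -log10(p_value / 50))]
  ann[1:80, `:=`(is_eqtl = TRUE, tissue_count = 1L)]
  assoc <- data.frame(snp_id = c(a_ids, b_ids),
                      tissue = rep(c("A", "B"), each = 40),
                      adjusted_q = 0.01)
  cat <- eqtl_catalog(assoc, data.frame(snp_id = c(a_ids, b_ids),
                                        chrom = "chr1",
                                        pos = seq_len(80)))
  res <- mann_whitney_by_tissue(ann, cat)
  expect_identical(res$tissue, c("A", "B"))
  expect_identical(res$n_eqtl, c(40L, 40L))
  expect_identical(res$n_non_eqtl, c(360L, 360L))
  expect_true(res$mw_z[res$tissue == "A"] > 2)
  # cross-check each tissue against the standalone test
  for (tt in c("A", "B")) {
    ids <- if (tt == "A") a_ids else b_ids
    ref <- mw_test(ann$neglog10p[ann$snp_id %in% ids],
                   ann$neglog10p[!ann$snp_id %in% ids], exact = FALSE)
    expect_equal(res$mw_z[res$tissue == tt], ref$z, tolerance = 1e-12)
    expect_equal(res$mw_p[res$tissue == tt], ref$p_value, tolerance = 1e-12)
  }
})

test_that("gray-zone restriction drops SNPs outside (5e-8, 0.05) before testing", {
  ann <- make_annotated(c(0.5, 0.06, 0.04, 1e-6, 1e-9))
  ann[3, `:=`(is_eqtl = TRUE, tissue_count = 1L)]
  assoc <- data.frame(snp_id = ann$snp_id[3], tissue = "A", adjusted_q = 0.01)
  cat <- eqtl_catalog(assoc, data.frame(snp_id = ann$snp_id[3],
                                        chrom = "chr1", pos = 3L))
  res <- mann_whitney_by_tissue(ann, cat, gray_zone_only = TRUE)
  # gray zone keeps p in {0.04, 1e-6}: 1 eQTL vs 1 non-eQTL
  expect_identical(res$n_eqtl + res$n_non_eqtl, 2L)
})

test_that("category means and SEs follow sd/sqrt(n), degenerate cases flagged", {
  ann <- make_annotated(c(0.1, 0.01, 0.001, 0.5),
                        tissue_count = c(1L, 1L, 1L, 0L))
  ann[1:3, neglog10p := c(1, 2, 3)]
  res <- mean_by_tissue_count_category(ann)
  expect_identical(res$tissue_count_category, c("0", "1", "2", "3", ">3"))
  r1 <- res[res$tissue_count_category == "1", ]
  expect_equal(r1$mean_neglog10p, 2)
  expect_equal(r1$se, 0.5774, tolerance = 1e-4)
  expect_identical(res$n[res$tissue_count_category == "2"], 0L)
  # single-value category: SE flagged as NA
  ann2 <- make_annotated(c(0.1, 0.2), tissue_count = c(2L, 0L))
  res2 <- mean_by_tissue_count_category(ann2)
  expect_true(is.na(res2$se[res2$tissue_count_category == "2"]))
})

test_that("window-count means pool the tail and split by anchor status", {
  ann <- make_annotated(runif(50), window_count = c(rep(0L, 20), rep(3L, 10),
                                                    rep(40L, 20)))
  res <- mean_by_window_count(ann, max_count_bin = 18L)
  expect_identical(res$window_count_bin, c(0L, 3L, 18L))
  expect_true(res$pooled[res$window_count_bin == 18L])
  expect_identical(res$n, c(20L, 10L, 20L))

  allzero <- make_annotated(runif(30))
  r0 <- mean_by_window_count(allzero)
  expect_identical(nrow(r0), 1L)
  expect_equal(r0$mean_neglog10p, mean(allzero$neglog10p))

  ann[, is_eqtl := rep(c(TRUE, FALSE), 25)]
  split <- mean_by_window_count(ann, split_by_anchor_eqtl_status = TRUE)
  expect_identical(sort(unique(split$anchor_group)), c("eqtl", "non_eqtl"))
  expect_identical(sum(split$n), 50L)
})

test_that("zone classification matches the published definitions and boundary rule", {
  expect_identical(as.character(zone_classify(c(0.06, 1e-6, 0.5, 0.01, 1e-9))),
                   c("white_noise", "dark_gray", "white_noise", "light_gray",
                     "genome_wide"))
  # boundary values belong to the less extreme zone
  expect_identical(as.character(zone_classify(c(0.05, 5e-5, 5e-8))),
                   c("white_noise", "light_gray", "dark_gray"))
  expect_error(zone_classify(0), class = "ez_data_error")
  expect_error(zone_classify(1.2), class = "ez_data_error")
})

test_that("zone proportions use the binomial SE and partition the SNP set", {
  set.seed(36)
  ann <- make_annotated(runif(100), is_eqtl = c(rep(TRUE, 2), rep(FALSE, 98)),
                        best_q = c(2, 3, rep(NA, 98)),
                        tissue_count = c(1L, 1L, rep(0L, 98)))
  res <- eqtl_proportion_by_zone(ann)
  expect_identical(sum(res$n), 100L)
  wn <- res[res$zone == "white_noise", ]
  # spot-check the SE formula on the white-noise zone
  expect_equal(wn$se_prop, sqrt(wn$prop_eqtl * (1 - wn$prop_eqtl) / wn$n))
  expect_equal(res$se_prop^2 * res$n,
               res$prop_eqtl * (1 - res$prop_eqtl),
               tolerance = 1e-12, ignore_attr = TRUE)
  # frozen example: 2 eQTLs of 100 SNPs in one zone
  one_zone <- make_annotated(runif(100, 0.06, 0.9),
                             is_eqtl = c(rep(TRUE, 2), rep(FALSE, 98)))
  rz <- eqtl_proportion_by_zone(one_zone)
  expect_equal(rz$prop_eqtl[rz$zone == "white_noise"], 0.02)
  expect_equal(rz$se_prop[rz$zone == "white_noise"], 0.0140, tolerance = 1e-3)
  empty <- rz[rz$zone == "genome_wide", ]
  expect_identical(empty$n, 0L)
  expect_true(is.na(empty$prop_eqtl))
})

test_that("binned curve uses half-open 0.5 bins with terminal pooling at the GW boundary", {
  ann <- make_annotated(c(0.05012, 1e-9, 10^-7.2, 1, 0.99))
  bins <- binned_eqtl_curve(ann)
  expect_identical(nrow(bins), 16L)
  expect_identical(sum(bins$n), 5L)
  # -log10 p = 1.3 falls in [1.0, 1.5)
  expect_identical(bins$n[bins$bin_low == 1.0], 1L)
  # 1e-9 (neglog10p = 9) pools into the terminal bin
  expect_identical(bins$n[is.infinite(bins$bin_high)], 1L)
  # 10^-7.2 is below the GW boundary: penultimate bin [7.0, 7.301)
  expect_identical(bins$n[15], 1L)
  expect_equal(bins$bin_high[15], -log10(5e-8))
  # p = 1 and p = 0.99 land in the first bin
  expect_identical(bins$n[1], 2L)
})

test_that("gray-zone trend runs over the 12 gray bins and flags degenerate input", {
  set.seed(37)
  p <- 10^(-runif(20000, 0, 7.29))
  ann <- make_annotated(p, is_eqtl = runif(20000) < 0.3 * (-log10(p)) / 7)
  bins <- binned_eqtl_curve(ann)
  tr <- gray_zone_trend(bins)
  expect_identical(tr$n_bins_used, 12L)
  expect_true(tr$estimate > 0.8)

  flat <- data.table::data.table(bin_low = seq(0, 5.5, 0.5),
                                 bin_high = seq(0.5, 6, 0.5),
                                 bin_mid = seq(0.25, 5.75, 0.5),
                                 n = 10L, prop_eqtl = 0.5)
  tr2 <- gray_zone_trend(flat, zone_bounds = c(1.3, 6))
  expect_true(tr2$degenerate)
  expect_error(gray_zone_trend(flat[1:2, ], zone_bounds = c(0, 6)),
               class = "ez_data_error")
})

test_that("strictly increasing proportions over the gray bins give R = 1", {
  bins <- data.table::data.table(
    bin_low = c(seq(0, 7, 0.5), -log10(5e-8)),
    bin_high = c(seq(0.5, 7, 0.5), -log10(5e-8), Inf),
    n = 10L)
  bins[, bin_mid := (bin_low + ifelse(is.finite(bin_high), bin_high, bin_low + 0.5)) / 2]
  bins[, prop_eqtl := seq(0.01, 0.16, length.out = 16)]
  tr <- gray_zone_trend(bins)
  expect_equal(tr$estimate, 1)
  expect_identical(tr$n_bins_used, 12L)
})

test_that("co-localization proportions by density class carry binomial SEs", {
  ann <- make_annotated(runif(100),
                        window_count = c(rep(0L, 40), rep(3L, 30), rep(9L, 30)),
                        is_eqtl = rep(c(TRUE, FALSE), 50))
  ann[, in_tf_site := c(rep(FALSE, 70), rep(TRUE, 9), rep(FALSE, 21))]
  res <- colocalization_by_density(ann)
  hi <- res[res$feature_class == "tf" & res$group == "high", ]
  expect_equal(hi$prop, 0.3)
  expect_equal(hi$se, sqrt(0.3 * 0.7 / 30))
  expect_identical(res$n[res$feature_class == "tf" & res$group == "all_eqtl"], 50L)
  # no features at all: every proportion zero
  none <- make_annotated(runif(10))
  rn <- colocalization_by_density(none)
  expect_true(all(rn$prop[rn$n > 0] == 0))
})

test_that("statistics are invariant to input row order", {
  inst <- random_instance(808, n_snps = 150, n_eqtls = 120)
  ann <- annotate_snps(inst$snps, inst$catalog, inst$features)
  perm <- ann[sample.int(nrow(ann)), ]
  expect_equal(as.data.frame(mean_by_tissue_count_category(ann)),
               as.data.frame(mean_by_tissue_count_category(perm)))
  expect_equal(as.data.frame(eqtl_proportion_by_zone(ann)),
               as.data.frame(eqtl_proportion_by_zone(perm)))
  expect_equal(as.data.frame(binned_eqtl_curve(ann)),
               as.data.frame(binned_eqtl_curve(perm)))
  expect_equal(as.data.frame(mann_whitney_by_tissue(ann, inst$catalog)),
               as.data.frame(mann_whitney_by_tissue(perm, inst$catalog)))
})
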