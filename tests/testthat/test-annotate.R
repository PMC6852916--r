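test_that("tissue-breadth categories follow the published cut points", {
  expect_identical(as.character(tissue_count_category(c(0, 1, 2, 3, 4, 48))),
                   c("0", "1", "2", "3", ">3", ">3"))
  expect_error(tissue_count_category(-1), class = "ez_data_error")
})

test_that("density categories follow the published cut points", {
  expect_identical(as.character(density_category(c(0, 1, 7, 8, 117))),
                   c("low", "intermediate", "intermediate", "high", "high"))
  expect_error(density_category(-2), class = "ez_data_error")
})

test_that("eQTL status annotation matches a per-SNP scan of the association list", {
  inst <- random_instance(101, n_snps = 50, n_eqtls = 40)
  ann <- annotate_eqtl_status(inst$snps, inst$catalog)
  sig <- inst$catalog$associations[inst$catalog$associations$significant == TRUE, ]
  for (i in seq_len(nrow(ann))) {
    rows <- sig[sig$snp_id == ann$snp_id[i], ]
    expect_identical(ann$tissue_count[i], length(unique(rows$tissue)))
    expect_identical(ann$is_eqtl[i], nrow(rows) > 0)
    if (nrow(rows)) {
      expect_equal(ann$best_neglog10q[i], max(-log10(rows$adjusted_q)))
    } else {
      expect_true(is.na(ann$best_neglog10q[i]))
    }
  }
})

test_that("SNPs absent from the catalog get zero counts; known sets count correctly", {
  snps <- make_annotated(rep(0.5, 3))[, 1:6]
  assoc <- data.frame(snp_id = c("s00001", "s00001"),
                      tissue = c("Lung", "Thyroid"),
                      adjusted_q = c(0.01, 0.02))
  cat <- eqtl_catalog(assoc, data.frame(snp_id = "s00001", chrom = "chr1",
                                        pos = 1))
  ann <- annotate_eqtl_status(snps, cat)
  expect_identical(ann$tissue_count[ann$snp_id == "s00001"], 2L)
  expect_identical(ann$tissue_count[ann$snp_id == "s00002"], 0L)
  expect_identical(sort(eqtl_tissues(cat, "s00001")[[1]]),
                   c("Lung", "Thyroid"))
  expect_identical(eqtl_tissues(cat, "s00002")[[1]], character(0))
})

test_that("restrict_to_overlap needs a tested universe and drops outsiders", {
  snps <- make_annotated(rep(0.5, 3))[, 1:6]
  assoc <- data.frame(snp_id = "s00001", tissue = "Lung", adjusted_q = 0.01)
  pos <- data.frame(snp_id = "s00001", chrom = "chr1", pos = 1)
  cat_nouniv <- eqtl_catalog(assoc, pos)
  expect_error(annotate_eqtl_status(snps, cat_nouniv, restrict_to_overlap = TRUE),
               class = "ez_config_error")
  cat_univ <- eqtl_catalog(assoc, pos,
                           tested_snps = c("s00001", "s00003"))
  ann <- annotate_eqtl_status(snps, cat_univ, restrict_to_overlap = TRUE)
  expect_identical(sort(ann$snp_id), c("s00001", "s00003"))
})

test_that("window counting respects the closed +/-5 kb boundary and anchor exclusion", {
  snps <- data.table::data.table(snp_id = "a", chrom = "chr1", pos = 10000L,
                                 p_value = 0.5, neglog10p = -log10(0.5),
                                 backbone = FALSE)
  cat <- eqtl_catalog(
    data.frame(snp_id = c("e1", "e2"), tissue = "Lung",
               adjusted_q = c(0.01, 0.01)),
    data.frame(snp_id = c("e1", "e2"), chrom = "chr1",
               pos = c(5000L, 15001L)))
  expect_identical(count_window_eqtls(snps, cat, 5000L), 1L)

  # an anchor that is itself the only eQTL around
  cat2 <- eqtl_catalog(data.frame(snp_id = "a", tissue = "Lung",
                                  adjusted_q = 0.01),
                       data.frame(snp_id = "a", chrom = "chr1", pos = 10000L))
  expect_identical(count_window_eqtls(snps, cat2, 5000L), 0L)
  expect_identical(count_window_eqtls(snps, cat2, 5000L,
                                      exclude_anchor = FALSE), 1L)
})

test_that("window counts match the all-pairs oracle on random instances", {
  inst <- random_instance(202, n_snps = 200, n_eqtls = 500)
  got <- count_window_eqtls(inst$snps, inst$catalog, 5000L)
  want <- oracle_window_counts(inst$snps, inst$eq, 5000L)
  expect_identical(got, want)
})

test_that("window counting is symmetric and monotone in half_width", {
  inst <- random_instance(303, n_snps = 100, n_eqtls = 100)
  # symmetry: count B in A's window iff A in B's window, over eQTL anchors
  eq <- inst$eq
  for (hw in c(1000L, 5000L)) {
    for (i in seq_len(min(20, nrow(eq)))) {
      within_i <- eq$chrom == eq$chrom[i] & abs(eq$pos - eq$pos[i]) <= hw
      for (j in which(within_i)) {
        expect_true(abs(eq$pos[j] - eq$pos[i]) <= hw)
      }
    }
  }
  c1 <- count_window_eqtls(inst$snps, inst$catalog, 2500L)
  c2 <- count_window_eqtls(inst$snps, inst$catalog, 5000L)
  expect_true(all(c2 >= c1))
})

test_that("window counts count distinct eQTL SNPs and ignore row order", {
  assoc <- data.frame(snp_id = c("e1", "e1", "e1"),
                      tissue = c("A", "B", "C"), adjusted_q = 0.01)
  pos <- data.frame(snp_id = "e1", chrom = "chr1", pos = 1200L)
  cat <- eqtl_catalog(assoc, pos)
  snps <- make_annotated(0.5)[, 1:6]
  snps$chrom <- "chr1"; snps$pos <- 1000L
  expect_identical(count_window_eqtls(snps, cat, 5000L), 1L)

  inst <- random_instance(404, n_snps = 80, n_eqtls = 60)
  shuffled <- eqtl_catalog(
    inst$catalog$associations[sample.int(nrow(inst$catalog$associations)), ],
    inst$catalog$positions[sample.int(nrow(inst$catalog$positions)), ])
  expect_identical(count_window_eqtls(inst$snps, inst$catalog, 5000L),
                   count_window_eqtls(inst$snps, shuffled, 5000L))
})

test_that("colocalization flags match the all-pairs oracle, boundaries inclusive", {
  inst <- random_instance(505, n_snps = 100, n_eqtls = 20, n_features = 50)
  fl <- colocalize(inst$snps, inst$features)
  expect_identical(fl$in_tf_site, oracle_coloc(inst$snps, inst$features, "tf"))
  expect_identical(fl$in_mirna_site,
                   oracle_coloc(inst$snps, inst$features, "mirna"))

  snps <- make_annotated(0.5)[, 1:6]
  snps$pos <- 1010L
  feats <- data.table::data.table(chrom = "chr1", start = 990L, end = 1010L,
                                  feature_class = "tf")
  expect_true(colocalize(snps, feats)$in_tf_site)
  expect_false(colocalize(snps, NULL)$in_tf_site)
})

test_that("annotation of a partitioned SNP set equals annotation of the union", {
  inst <- random_instance(606, n_snps = 90, n_eqtls = 80)
  full <- annotate_snps(inst$snps, inst$catalog, inst$features)
  idx <- sample(rep(1:3, length.out = nrow(inst$snps)))
  parts <- lapply(1:3, function(k)
    annotate_snps(inst$snps[idx == k, ], inst$catalog, inst$features))
  merged <- data.table::rbindlist(parts)
  data.table::setkey(merged, snp_id)
  full_sorted <- data.table::copy(full)
  data.table::setkey(full_sorted, snp_id)
  expect_equal(as.data.frame(full_sorted), as.data.frame(merged))
})
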