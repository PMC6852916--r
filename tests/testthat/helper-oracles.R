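# Independent brute-force oracles. Each recomputes a quantity by the most
# direct O(n*m) route, sharing no code with the package implementation.

oracle_window_counts <- function(snps, eq, half_width, exclude_anchor = TRUE) {
  vapply(seq_len(nrow(snps)), function(i) {
    hit <- eq$chrom == snps$chrom[i] &
      abs(eq$pos - snps$pos[i]) <= half_width
    if (exclude_anchor) hit <- hit & eq$snp_id != snps$snp_id[i]
    sum(hit)
  }, integer(1))
}

oracle_coloc <- function(snps, features, class) {
  f <- features[features$feature_class == class, ]
  vapply(seq_len(nrow(snps)), function(i) {
    any(f$chrom == snps$chrom[i] & f$start <= snps$pos[i] &
          snps$pos[i] <= f$end)
  }, logical(1))
}

oracle_fragment_aggregates <- function(fragments, snps, eq, gw_threshold = 5e-8) {
  res <- lapply(seq_len(nrow(fragments)), function(i) {
    in_frag <- snps$chrom == fragments$chrom[i] &
      snps$pos >= fragments$start[i] & snps$pos <= fragments$end[i]
    eq_in <- eq$chrom == fragments$chrom[i] &
      eq$pos >= fragments$start[i] & eq$pos <= fragments$end[i]
    list(snp_count = sum(in_frag),
         mean_neglog10p = if (any(in_frag)) mean(snps$neglog10p[in_frag]) else NA_real_,
         has_gw_snp = any(snps$p_value[in_frag] < gw_threshold),
         eqtl_count = sum(eq_in))
  })
  data.frame(snp_count = vapply(res, `[[`, numeric(1), "snp_count"),
             mean_neglog10p = vapply(res, `[[`, numeric(1), "mean_neglog10p"),
             has_gw_snp = vapply(res, `[[`, logical(1), "has_gw_snp"),
             eqtl_count = vapply(res, `[[`, numeric(1), "eqtl_count"))
}

# Exact two-sided Mann-Whitney p by direct enumeration over all subsets of
# the pooled sample, built recursively (no utils::combn).
oracle_mw_exact_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled)
  mu <- n1 * (n - n1) / 2
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  subsets <- function(from, k) {
    if (k == 0L) return(list(integer(0)))
    if (from > n) return(list())
    c(lapply(subsets(from + 1L, k - 1L), function(s) c(from, s)),
      subsets(from + 1L, k))
  }
  us <- vapply(subsets(1L, n1),
               function(s) sum(r[s]) - n1 * (n1 + 1) / 2, numeric(1))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Spearman R by the direct definition: Pearson correlation of average ranks.
oracle_spearman_r <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# small random instance on 3 chromosomes for interval oracles
random_instance <- function(seed, n_snps = NULL, n_eqtls = NULL,
                            n_features = 30L, chrom_len = 50000L) {
  set.seed(seed)
  if (is.null(n_snps)) n_snps <- sample(20:500, 1)
  if (is.null(n_eqtls)) n_eqtls <- sample(10:1000, 1)
  chroms <- c("chr1", "chr2", "chr3")
  snps <- data.table::data.table(
    snp_id = sprintf("s%04d", seq_len(n_snps)),
    chrom = sample(chroms, n_snps, replace = TRUE),
    pos = sample.int(chrom_len, n_snps, replace = TRUE),
    p_value = runif(n_snps))
  snps[, neglog10p := -log10(p_value)]
  snps[, backbone := FALSE]
  # eQTL SNPs: a mix of GWAS SNPs and catalog-only SNPs, duplicate
  # associations across tissues
  eq_ids <- unique(c(sample(snps$snp_id, min(n_eqtls, n_snps) %/% 2),
                     sprintf("e%04d", seq_len(n_eqtls))))[seq_len(n_eqtls)]
  own <- !eq_ids %in% snps$snp_id
  eq_pos <- data.table::data.table(
    snp_id = eq_ids,
    chrom = ifelse(own, sample(chroms, n_eqtls, replace = TRUE),
                   snps$chrom[match(eq_ids, snps$snp_id)]),
    pos = ifelse(own, sample.int(chrom_len, n_eqtls, replace = TRUE),
                 snps$pos[match(eq_ids, snps$snp_id)]))
  n_assoc <- pmin(1L + rgeom(n_eqtls, 0.6), 5L)
  assoc <- data.table::data.table(
    snp_id = rep(eq_ids, n_assoc),
    tissue = unlist(lapply(n_assoc, function(k)
      sample(sprintf("t%02d", 1:8), k))),
    adjusted_q = runif(sum(n_assoc), 1e-6, 0.05))
  catalog <- eqtl_catalog(assoc, eq_pos, tested_snps = snps$snp_id)
  features <- data.table::data.table(
    chrom = sample(chroms, n_features, replace = TRUE),
    start = sample.int(chrom_len - 200L, n_features, replace = TRUE))
  features[, end := start + sample(1:200, n_features, replace = TRUE)]
  features[, feature_class := sample(c("tf", "mirna"), n_features,
                                     replace = TRUE)]
  list(snps = snps, catalog = catalog, features = features,
       eq = eqtl_snps(catalog))
}

# minimal annotated table for statistics tests
make_annotated <- function(p_value, is_eqtl = FALSE, window_count = 0L,
                           best_q = NA_real_, tissue_count = NULL,
                           in_tf = FALSE, in_mirna = FALSE) {
  n <- length(p_value)
  if (is.null(tissue_count)) tissue_count <- as.integer(is_eqtl)
  data.table::data.table(
    snp_id = sprintf("s%05d", seq_len(n)),
    chrom = "chr1",
    pos = seq_len(n),
    p_value = p_value,
    neglog10p = -log10(p_value),
    backbone = FALSE,
    is_eqtl = rep_len(is_eqtl, n),
    tissue_count = rep_len(tissue_count, n),
    tissue_count_category = tissue_count_category(rep_len(tissue_count, n)),
    best_neglog10q = rep_len(best_q, n),
    window_eqtl_count = rep_len(as.integer(window_count), n),
    density_category = density_category(rep_len(as.integer(window_count), n)),
    in_tf_site = rep_len(in_tf, n),
    in_mirna_site = rep_len(in_mirna, n))
}
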