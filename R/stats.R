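#' Mann-Whitney U test with signed, tie-corrected Z
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test comparing `x` (the eQTL
#' group) against `y` (the non-eQTL group). The Z statistic is signed so that
#' a positive value means the `x` group tends to have larger values. For
#' small samples (`n1 + n2 <= 10` by default) the two-sided p-value is
#' computed exactly by enumerating all assignments of the pooled values to
#' the two groups, which handles ties without approximation; otherwise the
#' tie-corrected normal approximation is used.
#'
#' @param x,y Numeric vectors (group values, e.g. -log10 p).
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact enumeration;
#'   `NULL` (default) selects it when `length(x) + length(y) <= 10`.
#' @return List with `u` (U statistic of the `x` group), `z` (signed,
#'   tie-corrected), `p_value` (two-sided), `exact`, `n1`, `n2`.
#' @export
mw_test <- function(x, y, exact = NULL) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 == 0L || n2 == 0L) ez_data_error("both groups must be non-empty")
  if (is.null(exact)) exact <- (n1 + n2) <= 10L
  pooled <- c(x, y)
  n <- n1 + n2
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2

  # tie-corrected variance of U
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  z <- if (sigma2 > 0) (u - mu) / sqrt(sigma2) else 0

  if (exact) {
    if (n > 12L) ez_config_error("exact enumeration limited to n1 + n2 <= 12")
    splits <- utils::combn(n, n1)
    us <- colSums(matrix(r[splits], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
  } else {
    p <- if (sigma2 > 0) 2 * stats::pnorm(-abs(z)) else 1
  }
  list(u = u, z = z, p_value = min(p, 1), exact = exact, n1 = n1, n2 = n2)
}

.gray_zone_filter <- function(annotated, thresholds = zone_thresholds()) {
  zones <- zone_classify(annotated$p_value, thresholds)
  annotated[zones %in% c("light_gray", "dark_gray"), ]
}

#' Per-tissue Mann-Whitney comparison of eQTL vs non-eQTL SNPs
#'
#' For each tissue, splits the SNPs by whether they are a significant eQTL in
#' that tissue and compares the two groups' `-log10 p` with a two-sided
#' Mann-Whitney test (tie-corrected normal approximation; Z signed so that a
#' positive value means the eQTL group is more significant in the GWAS).
#' Optionally restricts the analysis to gray-zone SNPs
#' (5e-8 <= p < 0.05) first. Tissues with an empty group are skipped with a
#' message. A Bonferroni-adjusted p-value column is emitted for convenience;
#' no decision in the package uses it.
#'
#' @param annotated Annotated SNP table ([annotate_snps()]).
#' @param catalog An [eqtl_catalog()].
#' @param gray_zone_only Restrict to gray-zone SNPs before testing.
#' @param thresholds Zone thresholds, see [zone_thresholds()].
#' @return `data.table` sorted by tissue: `tissue`, `n_non_eqtl`, `n_eqtl`,
#'   `mean_non`, `median_non`, `mean_eqtl`, `median_eqtl`, `mw_z`, `mw_p`,
#'   `mw_p_bonferroni`.
#' @export
mann_whitney_by_tissue <- function(annotated, catalog, gray_zone_only = FALSE,
                                   thresholds = zone_thresholds()) {
  dat <- data.table::as.data.table(annotated)
  if (gray_zone_only) dat <- .gray_zone_filter(dat, thresholds)
  if (nrow(dat) == 0L) ez_data_error("no SNPs to test")

  v <- dat$neglog10p
  n <- length(v)
  r <- rank(v)
  tie_tab <- table(v)
  tie_term <- sum(tie_tab^3 - tie_tab)

  sig <- catalog$associations[significant == TRUE, .(snp_id, tissue)]
  sig <- sig[snp_id %in% dat$snp_id]
  member <- split(match(sig$snp_id, dat$snp_id), sig$tissue)

  rows <- lapply(sort(catalog$tissues), function(tt) {
    idx <- member[[tt]]
    n1 <- length(idx)
    n2 <- n - n1
    if (n1 == 0L || n2 == 0L) {
      message("mann_whitney_by_tissue: skipping tissue '", tt,
              "' (empty group)")
      return(NULL)
    }
    u <- sum(r[idx]) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    z <- if (sigma2 > 0) (u - mu) / sqrt(sigma2) else 0
    p <- if (sigma2 > 0) 2 * stats::pnorm(-abs(z)) else 1
    x <- v[idx]
    y <- v[-idx]
    data.table::data.table(tissue = tt, n_non_eqtl = n2, n_eqtl = n1,
                           mean_non = mean(y), median_non = stats::median(y),
                           mean_eqtl = mean(x), median_eqtl = stats::median(x),
                           mw_z = z, mw_p = p)
  })
  out <- data.table::rbindlist(rows)
  if (nrow(out)) out[, mw_p_bonferroni := pmin(1, mw_p * length(catalog$tissues))]
  out[]
}

.mean_se <- function(v) {
  n <- length(v)
  list(n = n,
       mean = if (n >= 1L) mean(v) else NA_real_,
       se = if (n >= 2L) stats::sd(v) / sqrt(n) else NA_real_)
}

#' Mean GWAS significance by tissue-breadth category
#'
#' Mean and standard error of `-log10 p` for SNPs stratified by the number of
#' tissues in which they are an eQTL ("0", "1", "2", "3", ">3").
#'
#' @param annotated Annotated SNP table.
#' @return `data.table`: `tissue_count_category`, `n`, `mean_neglog10p`,
#'   `se` (`NA` when `n < 2`). All five categories are reported, empty ones
#'   with `n = 0`.
#' @export
mean_by_tissue_count_category <- function(annotated) {
  dat <- data.table::as.data.table(annotated)
  out <- data.table::rbindlist(lapply(.tissue_cat_levels, function(cat) {
    v <- dat$neglog10p[dat$tissue_count_category == cat]
    ms <- .mean_se(v)
    data.table::data.table(tissue_count_category = cat, n = ms$n,
                           mean_neglog10p = ms$mean, se = ms$se)
  }))
  out[]
}

#' Mean GWAS significance by window eQTL count
#'
#' Mean and standard error of `-log10 p` for SNPs stratified by the number of
#' eQTLs in their +/-5 kb neighborhood; counts at or above `max_count_bin`
#' are pooled into a terminal bin. Optionally computed separately for anchor
#' SNPs that are / are not themselves eQTLs.
#'
#' @param annotated Annotated SNP table.
#' @param split_by_anchor_eqtl_status Produce separate curves by the anchor
#'   SNP's own eQTL status.
#' @param max_count_bin Pooling threshold for the terminal bin (default 18).
#' @return `data.table`: `anchor_group` (`"all"`, `"eqtl"`, `"non_eqtl"`),
#'   `window_count_bin` (integer; the terminal bin holds all counts >=
#'   `max_count_bin`), `pooled` (logical), `n`, `mean_neglog10p`, `se`.
#' @export
mean_by_window_count <- function(annotated, split_by_anchor_eqtl_status = FALSE,
                                 max_count_bin = 18L) {
  dat <- data.table::as.data.table(annotated)
  groups <- if (split_by_anchor_eqtl_status) {
    list(non_eqtl = dat[is_eqtl == FALSE], eqtl = dat[is_eqtl == TRUE])
  } else {
    list(all = dat)
  }
  out <- data.table::rbindlist(lapply(names(groups), function(g) {
    gd <- groups[[g]]
    if (nrow(gd) == 0L) return(NULL)
    bin <- pmin(gd$window_eqtl_count, max_count_bin)
    agg <- data.table::data.table(bin = bin, v = gd$neglog10p)[
      , .(n = .N, mean_neglog10p = mean(v),
          se = if (.N >= 2L) stats::sd(v) / sqrt(.N) else NA_real_),
      by = bin]
    agg[, anchor_group := g]
    agg[, pooled := bin == max_count_bin]
    agg
  }))
  data.table::setnames(out, "bin", "window_count_bin")
  data.table::setorder(out, anchor_group, window_count_bin)
  data.table::setcolorder(out, c("anchor_group", "window_count_bin", "pooled",
                                 "n", "mean_neglog10p", "se"))
  out[]
}

#' Classify p-values into significance zones
#'
#' Partitions (0, 1] into four zones: white noise (`p >= 0.05`, not nominally
#' significant), light gray (`5e-5 <= p < 0.05`), dark gray
#' (`5e-8 <= p < 5e-5`), and genome-wide (`p < 5e-8`). Boundary values are
#' assigned to the less extreme zone.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param thresholds Named vector `c(nominal=, dark=, gw=)`, see
#'   [zone_thresholds()].
#' @return Factor with levels
#'   `"white_noise","light_gray","dark_gray","genome_wide"`.
#' @export
zone_classify <- function(p, thresholds = zone_thresholds()) {
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    ez_data_error("p-values must lie in (0, 1]")
  }
  out <- ifelse(p >= thresholds[["nominal"]], "white_noise",
         ifelse(p >= thresholds[["dark"]], "light_gray",
         ifelse(p >= thresholds[["gw"]], "dark_gray", "genome_wide")))
  factor(out, levels = .zone_levels)
}

#' eQTL proportion and significance by zone
#'
#' For each significance zone: the proportion of SNPs that are eQTLs with its
#' binomial standard error `sqrt(p(1-p)/n)`, and the mean (with SE) of the
#' eQTLs' best `-log10 q` — how significant the eQTLs themselves are.
#'
#' @param annotated Annotated SNP table.
#' @param thresholds See [zone_thresholds()].
#' @return `data.table`: `zone`, `n`, `n_eqtl`, `prop_eqtl`, `se_prop`,
#'   `mean_best_neglog10q`, `se_q`. Empty zones are reported with `n = 0`
#'   and `NA` statistics.
#' @export
eqtl_proportion_by_zone <- function(annotated, thresholds = zone_thresholds()) {
  dat <- data.table::as.data.table(annotated)
  zone <- zone_classify(dat$p_value, thresholds)
  out <- data.table::rbindlist(lapply(.zone_levels, function(zz) {
    sel <- zone == zz
    n <- sum(sel)
    if (n == 0L) {
      return(data.table::data.table(zone = zz, n = 0L, n_eqtl = 0L,
                                    prop_eqtl = NA_real_, se_prop = NA_real_,
                                    mean_best_neglog10q = NA_real_,
                                    se_q = NA_real_))
    }
    n_eqtl <- sum(dat$is_eqtl[sel])
    prop <- n_eqtl / n
    q <- dat$best_neglog10q[sel & dat$is_eqtl]
    ms <- .mean_se(q)
    data.table::data.table(zone = zz, n = n, n_eqtl = n_eqtl,
                           prop_eqtl = prop,
                           se_prop = sqrt(prop * (1 - prop) / n),
                           mean_best_neglog10q = ms$mean, se_q = ms$se)
  }))
  out[, zone := factor(zone, levels = .zone_levels)]
  out[]
}

# bin breaks: 0, 0.5, ..., up to the last full step below the genome-wide
# boundary, then the boundary itself, then Inf. With the defaults this gives
# 16 bins, the last one pooling everything at or beyond -log10(5e-8).
.bin_breaks <- function(bin_width = 0.5, n_bins = 16L,
                        gw_neglog10 = -log10(5e-8)) {
  lows <- seq(0, by = bin_width, length.out = n_bins - 1L)
  if (lows[n_bins - 1L] >= gw_neglog10) {
    ez_config_error("bin grid reaches past the genome-wide boundary; ",
                    "reduce n_bins or bin_width")
  }
  c(lows, gw_neglog10, Inf)
}

#' Binned eQTL-proportion curve
#'
#' Stratifies SNPs by `-log10 p` in `bin_width` increments. Bins are
#' half-open `[low, high)`; because genome-wide significant SNPs are few,
#' every SNP at or beyond the genome-wide boundary (`-log10 p >= 7.301`) is
#' pooled into the terminal bin. Per bin: the eQTL proportion with binomial
#' SE and the mean best `-log10 q` of the bin's eQTLs with its SE.
#'
#' @param annotated Annotated SNP table.
#' @param bin_width Bin width on the -log10 p scale (default 0.5).
#' @param n_bins Total number of bins including the terminal pooled bin
#'   (default 16).
#' @param thresholds See [zone_thresholds()]; fixes the pooling boundary.
#' @return `data.table`: `bin_low`, `bin_high`, `bin_mid`, `n`, `n_eqtl`,
#'   `prop_eqtl`, `se_prop`, `mean_best_neglog10q`, `se_q`.
#' @export
binned_eqtl_curve <- function(annotated, bin_width = 0.5, n_bins = 16L,
                              thresholds = zone_thresholds()) {
  dat <- data.table::as.data.table(annotated)
  breaks <- .bin_breaks(bin_width, n_bins, -log10(thresholds[["gw"]]))
  idx <- findInterval(dat$neglog10p, breaks, rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L  # p = 1 gives neglog10p = 0, bin 1
  out <- data.table::rbindlist(lapply(seq_len(n_bins), function(b) {
    sel <- idx == b
    n <- sum(sel)
    n_eqtl <- sum(dat$is_eqtl[sel])
    prop <- if (n > 0L) n_eqtl / n else NA_real_
    q <- dat$best_neglog10q[sel & dat$is_eqtl]
    ms <- .mean_se(q)
    data.table::data.table(
      bin_low = breaks[b], bin_high = breaks[b + 1L],
      bin_mid = if (is.finite(breaks[b + 1L])) (breaks[b] + breaks[b + 1L]) / 2
                else breaks[b] + bin_width / 2,
      n = n, n_eqtl = n_eqtl, prop_eqtl = prop,
      se_prop = if (n > 0L) sqrt(prop * (1 - prop) / n) else NA_real_,
      mean_best_neglog10q = ms$mean, se_q = ms$se)
  }))
  out[]
}

#' Gray-zone trend in the binned eQTL curve
#'
#' Spearman rank correlation between bin midpoint and eQTL proportion over
#' the bins lying fully inside the gray zone (on the -log10 p scale,
#' `[1.3, 7.301)` by default — 12 bins at width 0.5).
#'
#' @param bins Output of [binned_eqtl_curve()].
#' @param zone_bounds Lower and upper -log10 p bounds of the gray zone.
#' @return List with `estimate` (Spearman R), `p_value`, `n_bins_used`,
#'   `degenerate`.
#' @export
gray_zone_trend <- function(bins,
                            zone_bounds = c(-log10(0.05), -log10(5e-8))) {
  sel <- bins$bin_low >= zone_bounds[1L] - 1e-9 &
    bins$bin_high <= zone_bounds[2L] + 1e-9 &
    bins$n > 0L
  use <- bins[sel, ]
  if (nrow(use) < 3L) {
    ez_data_error("fewer than 3 populated bins inside the gray zone")
  }
  res <- spearman_cor(use$bin_mid, use$prop_eqtl)
  list(estimate = res$estimate, p_value = res$p_value,
       n_bins_used = res$n, degenerate = res$degenerate)
}

.prop_se <- function(flag) {
  n <- length(flag)
  if (n == 0L) return(list(n = 0L, prop = NA_real_, se = NA_real_))
  prop <- mean(flag)
  list(n = n, prop = prop, se = sqrt(prop * (1 - prop) / n))
}

#' Regulatory co-localization by eQTL-density class
#'
#' For each feature class (TF and miRNA binding sites): the proportion of
#' SNPs co-localizing with a feature among SNPs in low / intermediate / high
#' eQTL-density neighborhoods, plus two reference proportions computed over
#' all eQTL SNPs and all non-eQTL SNPs.
#'
#' @param annotated Annotated SNP table (with co-localization flags).
#' @return `data.table`: `feature_class`, `group` (the three density classes
#'   plus `"all_eqtl"`, `"all_non_eqtl"`), `n`, `prop`, `se`.
#' @export
colocalization_by_density <- function(annotated) {
  dat <- data.table::as.data.table(annotated)
  flag_col <- c(tf = "in_tf_site", mirna = "in_mirna_site")
  groups <- c(.density_levels, "all_eqtl", "all_non_eqtl")
  out <- data.table::rbindlist(lapply(.feature_classes, function(cl) {
    flags <- dat[[flag_col[[cl]]]]
    data.table::rbindlist(lapply(groups, function(g) {
      sel <- switch(g,
        all_eqtl = dat$is_eqtl,
        all_non_eqtl = !dat$is_eqtl,
        dat$density_category == g)
      ps <- .prop_se(flags[sel])
      data.table::data.table(feature_class = cl, group = g, n = ps$n,
                             prop = ps$prop, se = ps$se)
    }))
  }))
  out[]
}
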