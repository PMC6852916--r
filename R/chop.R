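#' Tile the genome into consecutive non-overlapping fragments
#'
#' Divides each chromosome into consecutive, non-overlapping fragments of
#' `size` bases starting from the first nucleotide; the last fragment of a
#' chromosome may be shorter. Fragment `i` spans
#' `[(i-1)*size + 1, min(i*size, L)]` (1-based inclusive), so fragments
#' partition `[1, L]` exactly.
#'
#' @param chrom_lengths Named numeric vector (or two-column `data.frame`) of
#'   chromosome lengths in bases.
#' @param size Fragment size in bases (default 5000).
#' @return `data.table` with columns `chrom`, `index`, `start`, `end`;
#'   attribute `fragment_size` records `size`.
#' @export
chop_genome <- function(chrom_lengths, size = 5000L) {
  if (is.data.frame(chrom_lengths)) {
    chrom_lengths <- stats::setNames(as.numeric(chrom_lengths[[2L]]),
                                     as.character(chrom_lengths[[1L]]))
  }
  if (length(size) != 1L || !is.finite(size) || size < 1) {
    ez_config_error("fragment size must be a positive integer")
  }
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    ez_config_error("chrom_lengths must be named by chromosome")
  }
  if (any(!is.finite(chrom_lengths) | chrom_lengths < 1)) {
    ez_config_error("chromosome lengths must be >= 1")
  }
  size <- as.integer(size)
  frags <- data.table::rbindlist(lapply(names(chrom_lengths), function(cc) {
    L <- chrom_lengths[[cc]]
    n <- as.integer(ceiling(L / size))
    idx <- seq_len(n)
    data.table::data.table(chrom = cc, index = idx,
                           start = (idx - 1L) * size + 1L,
                           end = as.integer(pmin(as.numeric(idx) * size, L)))
  }))
  data.table::setattr(frags, "fragment_size", size)
  frags[]
}

#' Aggregate SNPs and eQTLs into genome fragments
#'
#' Assigns every GWAS SNP and every distinct significant eQTL SNP of the
#' catalog to its unique fragment (`index = ceiling(pos / size)`) and fills
#' per-fragment aggregates: `snp_count`, `mean_neglog10p` (`NA` for fragments
#' without GWAS SNPs), `has_gw_snp` (any SNP with `p < gw_threshold`), and
#' `eqtl_count`.
#'
#' @param fragments Output of [chop_genome()].
#' @param snps GWAS SNP table.
#' @param catalog An [eqtl_catalog()].
#' @param gw_threshold Genome-wide significance threshold (default 5e-8).
#' @return The fragment table with aggregate columns added.
#' @export
assign_and_aggregate <- function(fragments, snps, catalog, gw_threshold = 5e-8) {
  size <- attr(fragments, "fragment_size")
  if (is.null(size)) ez_config_error("fragments must come from chop_genome()")
  frags <- data.table::copy(fragments)
  chrom_max <- frags[, .(n_frag = max(index)), by = chrom]

  check_positions <- function(chrom, pos, what) {
    missing <- setdiff(unique(chrom), chrom_max$chrom)
    if (length(missing)) {
      ez_data_error(what, " on chromosome(s) absent from the length table: ",
                    paste(missing, collapse = ", "))
    }
    nmax <- stats::setNames(chrom_max$n_frag, chrom_max$chrom)
    idx <- as.integer(ceiling(pos / size))
    if (any(idx > nmax[chrom] | pos < 1)) {
      ez_data_error(what, " position outside the stated chromosome length")
    }
    idx
  }

  snp_idx <- check_positions(snps$chrom, snps$pos, "GWAS SNP")
  snp_agg <- data.table::data.table(chrom = snps$chrom, index = snp_idx,
                                    neglog10p = snps$neglog10p,
                                    gw = snps$p_value < gw_threshold)[
    , .(snp_count = .N, mean_neglog10p = mean(neglog10p),
        has_gw_snp = any(gw)), by = .(chrom, index)]

  eq <- eqtl_snps(catalog)
  eq_idx <- check_positions(eq$chrom, eq$pos, "eQTL SNP")
  eq_agg <- data.table::data.table(chrom = eq$chrom, index = eq_idx)[
    , .(eqtl_count = .N), by = .(chrom, index)]

  out <- merge(frags, snp_agg, by = c("chrom", "index"), all.x = TRUE)
  out <- merge(out, eq_agg, by = c("chrom", "index"), all.x = TRUE)
  out[is.na(snp_count), snp_count := 0L]
  out[is.na(eqtl_count), eqtl_count := 0L]
  out[is.na(has_gw_snp), has_gw_snp := FALSE]
  data.table::setorder(out, chrom, index)
  data.table::setattr(out, "fragment_size", size)
  out[]
}

#' Spearman rank correlation
#'
#' Spearman correlation with average ranks for ties. The p-value uses the
#' large-sample t approximation by default; for `n <= 10` an exhaustive
#' permutation p-value is available (intended as a small-sample oracle).
#' Degenerate inputs (constant ranks) are flagged rather than reported as 0.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @param exact Use the exhaustive permutation p-value (requires `n <= 10`).
#' @return List with `estimate`, `p_value`, `n`, `degenerate`.
#' @export
spearman_cor <- function(x, y, exact = FALSE) {
  n <- length(x)
  if (n < 3L) ez_data_error("spearman_cor needs at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(estimate = NA_real_, p_value = NA_real_, n = n,
                degenerate = TRUE))
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (exact) {
    if (n > 10L) ez_config_error("exact permutation Spearman limited to n <= 10")
    perms <- .permutations(n)
    obs <- abs(rho)
    rhos <- apply(perms, 1L, function(pp) stats::cor(rx, ry[pp]))
    p <- mean(abs(rhos) >= obs - 1e-12)
  } else {
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    p <- ct$p.value
  }
  list(estimate = rho, p_value = p, n = n, degenerate = FALSE)
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Correlate fragment eQTL count with mean GWAS significance
#'
#' Spearman rank correlation between a fragment's eQTL count and the mean
#' `-log10 p` of the GWAS SNPs it contains, over fragments with at least one
#' GWAS SNP (the mean is undefined for empty fragments; their number is
#' reported). Optionally excludes fragments containing any genome-wide
#' significant SNP, the control for GW peaks driving the association.
#'
#' @param fragments Output of [assign_and_aggregate()].
#' @param exclude_gw_fragments Drop fragments with `has_gw_snp`.
#' @return List with `estimate` (Spearman R), `p_value`, `n_used`,
#'   `n_empty_excluded`, `degenerate` (TRUE when ranks are constant and the
#'   correlation is undefined).
#' @export
fragment_correlation <- function(fragments, exclude_gw_fragments = FALSE) {
  usable <- fragments[fragments$snp_count >= 1L, ]
  n_empty <- nrow(fragments) - nrow(usable)
  if (exclude_gw_fragments) usable <- usable[usable$has_gw_snp == FALSE, ]
  if (nrow(usable) < 3L) {
    ez_data_error("fewer than 3 usable fragments for the correlation")
  }
  res <- spearman_cor(usable$eqtl_count, usable$mean_neglog10p)
  list(estimate = res$estimate, p_value = res$p_value, n_used = res$n,
       n_empty_excluded = n_empty, degenerate = res$degenerate)
}
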