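#' Tissue-breadth category of an eQTL SNP
#'
#' SNPs are stratified by the number of tissues in which they show significant
#' eQTL activity into five categories: "0", "1", "2", "3", ">3".
#'
#' @param n Integer vector of tissue counts (>= 0).
#' @return Factor with levels `"0","1","2","3",">3"`.
#' @export
tissue_count_category <- function(n) {
  if (any(!is.finite(n) | n < 0)) ez_data_error("tissue count must be >= 0")
  factor(ifelse(n > 3, ">3", as.character(n)), levels = .tissue_cat_levels)
}

#' eQTL-density category of a SNP's neighborhood
#'
#' Neighborhood eQTL counts are classified as low density (no eQTLs in the
#' +/-5 kb region), intermediate density (1-7 eQTLs), or high density (8 or
#' more eQTLs).
#'
#' @param count Integer vector of window eQTL counts (>= 0).
#' @return Factor with levels `"low","intermediate","high"`.
#' @export
density_category <- function(count) {
  if (any(!is.finite(count) | count < 0)) ez_data_error("window count must be >= 0")
  factor(ifelse(count == 0, "low", ifelse(count <= 7, "intermediate", "high")),
         levels = .density_levels)
}

# Count, for each anchor (chrom, pos), the positions in (q_chrom, q_pos)
# within +/- half_width on the same chromosome. Closed window: |delta| <=
# half_width is inside. Binary search per chromosome via findInterval on the
# sorted query positions.
.window_counts <- function(chrom, pos, q_chrom, q_pos, half_width) {
  counts <- integer(length(pos))
  by_chrom <- split(q_pos, q_chrom)
  for (cc in names(by_chrom)) {
    idx <- which(chrom == cc)
    if (!length(idx)) next
    s <- sort(by_chrom[[cc]])
    hi <- findInterval(pos[idx] + half_width, s)
    lo <- findInterval(pos[idx] - half_width - 1L, s)
    counts[idx] <- hi - lo
  }
  counts
}

#' Count eQTLs in the +/- half_width window around each SNP
#'
#' For every anchor SNP, counts the distinct significant eQTL SNPs of the
#' catalog (unique `snp_id`, regardless of how many tissues each is active
#' in) lying on the same chromosome within the closed window
#' `|pos_eqtl - pos_anchor| <= half_width`. When `exclude_anchor` is `TRUE`
#' (default) an anchor that is itself a catalog eQTL is not counted in its
#' own window.
#'
#' @param snps GWAS SNP table ([read_gwas_summary()]).
#' @param catalog An [eqtl_catalog()].
#' @param half_width Window half-width in bases (default 5000, the typical
#'   haplotype-block size).
#' @param exclude_anchor Exclude the anchor SNP from its own count.
#' @return Integer vector of counts, parallel to `snps`.
#' @export
count_window_eqtls <- function(snps, catalog, half_width = 5000L,
                               exclude_anchor = TRUE) {
  if (half_width < 0) ez_config_error("half_width must be >= 0")
  eq <- eqtl_snps(catalog)
  counts <- .window_counts(snps$chrom, snps$pos, eq$chrom, eq$pos, half_width)
  if (exclude_anchor && nrow(eq)) {
    m <- match(snps$snp_id, eq$snp_id)
    hit <- !is.na(m)
    if (any(hit)) {
      same <- eq$chrom[m[hit]] == snps$chrom[hit] &
        abs(eq$pos[m[hit]] - snps$pos[hit]) <= half_width
      counts[hit] <- counts[hit] - as.integer(same)
    }
  }
  counts
}

#' Flag SNPs co-localizing with regulatory features
#'
#' A SNP co-localizes with a feature class if its position falls inside any
#' feature interval of that class on the same chromosome (closed interval:
#' `start <= pos <= end`).
#'
#' @param snps GWAS SNP table.
#' @param features Feature table from [read_bed_features()] (both classes may
#'   be row-bound); may be `NULL` or empty.
#' @return `data.table` with logical columns `in_tf_site`, `in_mirna_site`,
#'   parallel to `snps`.
#' @export
colocalize <- function(snps, features = NULL) {
  out <- data.table::data.table(in_tf_site = logical(nrow(snps)),
                                in_mirna_site = logical(nrow(snps)))
  if (is.null(features) || nrow(features) == 0L) return(out)
  for (cl in .feature_classes) {
    f <- features[features$feature_class == cl, ]
    if (!nrow(f)) next
    flag <- logical(nrow(snps))
    for (cc in unique(f$chrom)) {
      fi <- f[f$chrom == cc, ]
      idx <- which(snps$chrom == cc)
      if (!length(idx)) next
      flag[idx] <- IRanges::overlapsAny(
        IRanges::IRanges(snps$pos[idx], width = 1L),
        IRanges::IRanges(fi$start, fi$end))
    }
    out[[if (cl == "tf") "in_tf_site" else "in_mirna_site"]] <- flag
  }
  out
}

#' Annotate GWAS SNPs with eQTL status
#'
#' Joins a GWAS SNP table with a cis-eQTL catalog on `snp_id`, computing for
#' each SNP whether it is a significant eQTL in at least one tissue, in how
#' many tissues, the tissue-breadth category, and the best (largest)
#' `-log10 q` over its significant associations.
#'
#' @param snps GWAS SNP table.
#' @param catalog An [eqtl_catalog()].
#' @param restrict_to_overlap Drop SNPs absent from the catalog's tested-SNP
#'   universe (both studies must have assayed a SNP for its non-eQTL status
#'   to be meaningful). Requires the catalog to carry `tested_snps`.
#' @return `data.table`: the `snps` columns plus `is_eqtl`, `tissue_count`,
#'   `tissue_count_category`, `best_neglog10q` (`NA` for non-eQTLs).
#' @export
annotate_eqtl_status <- function(snps, catalog, restrict_to_overlap = FALSE) {
  out <- data.table::as.data.table(snps)
  if (restrict_to_overlap) {
    if (is.null(catalog$tested_snps)) {
      ez_config_error("restrict_to_overlap requires a catalog with a tested-SNP universe")
    }
    out <- out[snp_id %in% catalog$tested_snps]
  }
  sig <- catalog$associations[significant == TRUE,
                              .(tissue_count = data.table::uniqueN(tissue),
                                best_neglog10q = max(-log10(adjusted_q))),
                              by = snp_id]
  out <- merge(out, sig, by = "snp_id", all.x = TRUE, sort = FALSE)
  out[is.na(tissue_count), tissue_count := 0L]
  out[, is_eqtl := tissue_count >= 1L]
  out[, tissue_count_category := tissue_count_category(tissue_count)]
  out[]
}

#' Full per-SNP annotation
#'
#' Runs the complete annotation sequence: eQTL status and tissue breadth,
#' +/- `half_width` window eQTL counts, density category, and regulatory
#' co-localization flags.
#'
#' @inheritParams annotate_eqtl_status
#' @inheritParams count_window_eqtls
#' @param features Optional regulatory-feature table ([read_bed_features()]).
#' @return `data.table` with one row per retained SNP and columns `snp_id`,
#'   `chrom`, `pos`, `p_value`, `neglog10p`, `backbone`, `is_eqtl`,
#'   `tissue_count`, `tissue_count_category`, `best_neglog10q`,
#'   `window_eqtl_count`, `density_category`, `in_tf_site`, `in_mirna_site`.
#' @export
annotate_snps <- function(snps, catalog, features = NULL,
                          half_width = 5000L, exclude_anchor = TRUE,
                          restrict_to_overlap = FALSE) {
  ann <- annotate_eqtl_status(snps, catalog, restrict_to_overlap)
  ann[, window_eqtl_count := count_window_eqtls(ann, catalog, half_width,
                                                exclude_anchor)]
  ann[, density_category := density_category(window_eqtl_count)]
  flags <- colocalize(ann, features)
  ann[, in_tf_site := flags$in_tf_site]
  ann[, in_mirna_site := flags$in_mirna_site]
  data.table::setcolorder(ann, c("snp_id", "chrom", "pos", "p_value",
                                 "neglog10p", "backbone", "is_eqtl",
                                 "tissue_count", "tissue_count_category",
                                 "best_neglog10q", "window_eqtl_count",
                                 "density_category", "in_tf_site",
                                 "in_mirna_site"))
  ann[]
}
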