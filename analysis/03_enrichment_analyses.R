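#!/usr/bin/env Rscript
# The stratified enrichment analyses: per-tissue Mann-Whitney comparisons of
# -log10 p between eQTL and non-eQTL SNPs (all SNPs and gray-zone only),
# mean significance by tissue-breadth category and by window eQTL count,
# eQTL proportions by significance zone and in 0.5-increment bins with the
# gray-zone Spearman trend, and regulatory co-localization by density class.

library(eqtlzone)

ann <- data.table::fread("scratch/annotated.tsv")
catalog <- read_eqtl_catalog("scratch/simulated_inputs/eqtl_catalog.tsv",
                             mode = "pre_filtered")

mw_all <- mann_whitney_by_tissue(ann, catalog)
mw_gray <- mann_whitney_by_tissue(ann, catalog, gray_zone_only = TRUE)
write_result_table(mw_all, "results/03_tissue_comparisons.tsv")
write_result_table(mw_gray, "results/03_tissue_comparisons_gray.tsv")
message(sum(mw_all$mw_z > 0), " of ", nrow(mw_all),
        " tissues show higher -log10 p in eQTL SNPs (positive Z)")

tc <- mean_by_tissue_count_category(ann)
write_result_table(tc, "results/03_tissue_count_means.tsv")
message("mean -log10 p by tissue breadth: ",
        paste(sprintf("%s=%.2f", tc$tissue_count_category,
                      tc$mean_neglog10p), collapse = ", "))

wd <- mean_by_window_count(ann, split_by_anchor_eqtl_status = TRUE)
write_result_table(wd, "results/03_window_density_means.tsv")

zp <- eqtl_proportion_by_zone(ann)
write_result_table(zp, "results/03_zone_proportions.tsv")
message("eQTL proportion by zone (%): ",
        paste(sprintf("%s=%.2f", zp$zone, 100 * zp$prop_eqtl),
              collapse = ", "))

bins <- binned_eqtl_curve(ann)
trend <- gray_zone_trend(bins)
write_result_table(bins, "results/03_binned_curve.tsv")
message(sprintf("gray-zone trend: Spearman R = %.3f over %d bins (p = %.2g)",
                trend$estimate, trend$n_bins_used, trend$p_value))

cl <- colocalization_by_density(ann)
write_result_table(cl, "results/03_colocalization.tsv")
hi <- cl[cl$feature_class == "tf" & cl$group == "high", ]
lo <- cl[cl$feature_class == "tf" & cl$group == "low", ]
message(sprintf("TF co-localization: %.2f%% in high-density vs %.2f%% in low-density regions",
                100 * hi$prop, 100 * lo$prop))
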