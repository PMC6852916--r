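#!/usr/bin/env Rscript
# The genome-chopping control: windows centered on SNPs overlap, so eQTL-dense
# peaks would be over-represented in the window analysis. Tiling the genome
# into consecutive non-overlapping 5 kb fragments de-overlaps the question:
# does a fragment's eQTL count correlate with the mean -log10 p of its SNPs,
# and does the correlation survive removal of fragments containing a
# genome-wide significant SNP?

library(eqtlzone)

ann <- data.table::fread("scratch/annotated.tsv")
catalog <- read_eqtl_catalog("scratch/simulated_inputs/eqtl_catalog.tsv",
                             mode = "pre_filtered")
lens <- read_chrom_lengths("scratch/simulated_inputs/chrom_lengths.tsv")

frags <- assign_and_aggregate(chop_genome(lens, 5000), ann, catalog)
fc <- fragment_correlation(frags, exclude_gw_fragments = FALSE)
fc_no <- fragment_correlation(frags, exclude_gw_fragments = TRUE)

census <- data.frame(
  quantity = c("n_fragments", "n_fragments_no_eqtl", "n_fragments_no_snp",
               "max_eqtls_in_fragment", "mean_snps_per_fragment"),
  value = c(nrow(frags), sum(frags$eqtl_count == 0), sum(frags$snp_count == 0),
            max(frags$eqtl_count), round(mean(frags$snp_count), 2)))
write_result_table(census, "results/04_fragment_census.tsv")

correl <- data.frame(
  analysis = c("all_fragments", "excluding_gw_fragments"),
  spearman_r = c(fc$estimate, fc_no$estimate),
  p_value = c(fc$p_value, fc_no$p_value),
  n_used = c(fc$n_used, fc_no$n_used))
write_result_table(correl, "results/04_fragment_correlations.tsv")

message(sprintf("%d fragments (%.0f%% without eQTLs); max %d eQTLs in one fragment",
                nrow(frags), 100 * mean(frags$eqtl_count == 0),
                max(frags$eqtl_count)))
message(sprintf("fragment correlation: R = %.3f (p = %.2g); excluding GW fragments: R = %.3f (p = %.2g)",
                fc$estimate, fc$p_value, fc_no$estimate, fc_no$p_value))
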