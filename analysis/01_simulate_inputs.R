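#!/usr/bin/env Rscript
# Generates the synthetic study the downstream analyses consume: GWAS summary
# statistics for 200,000 SNPs on a 3 x 20 Mb genome, a 48-tissue cis-eQTL
# catalog (~2% of SNPs are eQTLs, >80% of them tissue-specific, spatially
# clustered), and TF/miRNA binding sites concentrated in the eQTL-dense
# regions. The full input files are large and go to scratch/; a compact
# summary goes to results/.

library(eqtlzone)

sim <- simulate_study(enriched_config(seed = 20260920L))
paths <- write_simulated_inputs(sim, "scratch/simulated_inputs")

tissue_counts <- table(sim$catalog$associations$snp_id)
summary <- data.frame(
  quantity = c("n_snps", "n_eqtl_snps", "eqtl_fraction_pct",
               "tissue_specific_pct", "n_associations", "n_tf_sites",
               "n_mirna_sites", "n_causal_snps"),
  value = c(nrow(sim$gwas), sum(sim$truth$is_eqtl),
            round(100 * mean(sim$truth$is_eqtl), 3),
            round(100 * mean(tissue_counts == 1), 2),
            nrow(sim$catalog$associations),
            sum(sim$features$feature_class == "tf"),
            sum(sim$features$feature_class == "mirna"),
            sum(sim$truth$causal)))
dir.create("results", showWarnings = FALSE)
write_result_table(summary, "results/01_simulation_summary.tsv")

message("simulated ", nrow(sim$gwas), " SNPs; ", sum(sim$truth$is_eqtl),
        " eQTLs (", round(100 * mean(sim$truth$is_eqtl), 2), "%), ",
        round(100 * mean(tissue_counts == 1), 1), "% tissue-specific")
message("inputs written under scratch/simulated_inputs/")
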