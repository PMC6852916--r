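#!/usr/bin/env Rscript
# Annotates every GWAS SNP with its eQTL status, tissue-breadth category,
# +/-5 kb eQTL density (and density class), and regulatory co-localization
# flags, reading the simulated inputs back through the package's file
# readers (the same path a real GWAS + eQTL catalog would take).

library(eqtlzone)

dir <- "scratch/simulated_inputs"
gwas <- read_gwas_summary(file.path(dir, "gwas.tsv"),
                          column_map = list(snp = "snp", chr = "chr",
                                            pos = "pos", p = "p",
                                            backbone = "backbone"))
catalog <- read_eqtl_catalog(file.path(dir, "eqtl_catalog.tsv"),
                             mode = "pre_filtered")
features <- rbind(read_bed_features(file.path(dir, "tf_sites.bed"), "tf"),
                  read_bed_features(file.path(dir, "mirna_sites.bed"), "mirna"))

ann <- annotate_snps(gwas, catalog, features)
write_result_table(ann, "scratch/annotated.tsv")

density_tab <- as.data.frame(table(ann$density_category))
names(density_tab) <- c("density_category", "n_snps")
breadth_tab <- as.data.frame(table(ann$tissue_count_category))
names(breadth_tab) <- c("tissue_count_category", "n_snps")
write_result_table(density_tab, "results/02_density_classes.tsv")
write_result_table(breadth_tab, "results/02_tissue_breadth.tsv")

message("annotated ", nrow(ann), " SNPs; density classes: ",
        paste(density_tab$n_snps, collapse = " / "),
        " (low/intermediate/high)")
message("full annotation in scratch/annotated.tsv")
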