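#' Pipeline run configuration
#'
#' Either a simulation preset (`sim`) or the four input paths must be
#' supplied, never both. All analysis parameters carry the package defaults:
#' +/-5 kb windows, 5 kb fragments, the standard zone thresholds, 0.5-wide
#' bins with 16 categories, and window-count pooling at 18.
#'
#' @param sim Optional [sim_config()]; when given, inputs are simulated.
#' @param gwas_path,eqtl_path,chrom_lengths_path Input paths (delimited text).
#' @param tf_bed_path,mirna_bed_path Optional BED paths for regulatory
#'   features.
#' @param eqtl_mode,test_counts,tested_snps Passed to [read_eqtl_catalog()].
#' @param gwas_column_map Passed to [read_gwas_summary()].
#' @param half_width Window half-width in bases.
#' @param fragment_size Genome-chopping fragment size in bases.
#' @param thresholds Zone thresholds, see [zone_thresholds()].
#' @param bin_width,n_bins Binned-curve parameters.
#' @param max_count_bin Window-count pooling threshold.
#' @param exclude_anchor Exclude the anchor SNP from its own window count.
#' @param backbone_only Restrict the analysis to backbone SNPs.
#' @param restrict_to_overlap Restrict to SNPs in the eQTL tested universe.
#' @return Object of class `run_config`.
#' @export
run_config <- function(sim = NULL,
                       gwas_path = NULL, eqtl_path = NULL,
                       chrom_lengths_path = NULL,
                       tf_bed_path = NULL, mirna_bed_path = NULL,
                       eqtl_mode = "pre_filtered", test_counts = NULL,
                       tested_snps = NULL,
                       gwas_column_map = list(snp = "snp", chr = "chr",
                                              pos = "pos", p = "p",
                                              backbone = "backbone"),
                       half_width = 5000L, fragment_size = 5000L,
                       thresholds = zone_thresholds(),
                       bin_width = 0.5, n_bins = 16L, max_count_bin = 18L,
                       exclude_anchor = TRUE,
                       backbone_only = FALSE, restrict_to_overlap = FALSE) {
  have_paths <- !is.null(gwas_path) || !is.null(eqtl_path)
  if (is.null(sim) && !have_paths) {
    ez_config_error("supply either a simulation preset or input paths")
  }
  if (!is.null(sim) && have_paths) {
    ez_config_error("supply a simulation preset or input paths, not both")
  }
  if (is.null(sim) && (is.null(gwas_path) || is.null(eqtl_path) ||
                       is.null(chrom_lengths_path))) {
    ez_config_error("file input requires gwas_path, eqtl_path and chrom_lengths_path")
  }
  structure(as.list(environment()), class = "run_config")
}

# Stage wrapper: failures are rethrown with the stage name; completion is
# recorded in the manifest. Timings go to the message log only, so that a
# fixed seed and config give a byte-identical manifest.
.stage <- function(manifest, name, quiet, expr) {
  t0 <- proc.time()[["elapsed"]]
  result <- tryCatch(force(expr), error = function(e) {
    stop(errorCondition(
      paste0("stage '", name, "' failed: ", conditionMessage(e)),
      class = c("ez_stage_error", class(e))))
  })
  elapsed <- proc.time()[["elapsed"]] - t0
  if (!quiet) message(sprintf("[%s] done in %.1fs", name, elapsed))
  manifest$stages <- c(manifest$stages, name)
  list(result = result, manifest = manifest)
}

#' Run the full enrichment pipeline
#'
#' Executes the complete analysis sequence on simulated or file inputs:
#' read/simulate, annotate (eQTL status, window counts, density class,
#' co-localization), per-tissue Mann-Whitney tests (all SNPs and gray-zone
#' only), tissue-count-category means, window-density curves, zone
#' proportions, the binned eQTL curve with the gray-zone trend, and the
#' genome-chopping control with fragment correlations computed with and
#' without genome-wide fragments. A manifest records the seed, parameters,
#' per-stage row counts, and every dropped row.
#'
#' @param config A [run_config()].
#' @param quiet Suppress stage progress messages (default `TRUE`).
#' @return A result bundle: list with `annotated`, `tissue_comparisons`,
#'   `tissue_comparisons_gray`, `tissue_count_means`, `window_density_means`,
#'   `zone_proportions`, `binned_curve`, `gray_zone_trend`, `fragments`,
#'   `fragment_correlation`, `fragment_correlation_no_gw`, `colocalization`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  manifest <- list(parameters = list(
    half_width = config$half_width, fragment_size = config$fragment_size,
    thresholds = as.list(config$thresholds), bin_width = config$bin_width,
    n_bins = config$n_bins, max_count_bin = config$max_count_bin,
    exclude_anchor = config$exclude_anchor,
    backbone_only = config$backbone_only,
    restrict_to_overlap = config$restrict_to_overlap,
    seed = if (!is.null(config$sim)) config$sim$seed else NA),
    stages = list(), counts = list())

  st <- .stage(manifest, "load_inputs", quiet, {
    if (!is.null(config$sim)) {
      sim <- simulate_study(config$sim)
      features <- sim$features
      list(gwas = sim$gwas, catalog = sim$catalog, features = features,
           chrom_lengths = config$sim$chrom_lengths, n_rejected = 0L,
           has_backbone = TRUE)
    } else {
      gwas <- read_gwas_summary(config$gwas_path,
                                column_map = config$gwas_column_map)
      catalog <- read_eqtl_catalog(config$eqtl_path, mode = config$eqtl_mode,
                                   test_counts = config$test_counts,
                                   tested_snps = config$tested_snps)
      features <- NULL
      if (!is.null(config$tf_bed_path)) {
        features <- read_bed_features(config$tf_bed_path, "tf")
      }
      if (!is.null(config$mirna_bed_path)) {
        features <- rbind(features,
                          read_bed_features(config$mirna_bed_path, "mirna"))
      }
      list(gwas = gwas, catalog = catalog, features = features,
           chrom_lengths = read_chrom_lengths(config$chrom_lengths_path),
           n_rejected = attr(gwas, "n_rejected") %||% 0L,
           has_backbone = !is.null(config$gwas_column_map$backbone))
    }
  })
  manifest <- st$manifest
  inputs <- st$result
  manifest$counts$n_gwas_read <- nrow(inputs$gwas)
  manifest$counts$n_rejected_p <- inputs$n_rejected

  gwas <- inputs$gwas
  if (config$backbone_only) {
    if (!isTRUE(inputs$has_backbone)) {
      ez_config_error("backbone_only requires a mapped backbone column")
    }
    gwas <- gwas[gwas$backbone == TRUE, ]
    manifest$counts$n_after_backbone <- nrow(gwas)
  }

  st <- .stage(manifest, "annotate", quiet, {
    annotate_snps(gwas, inputs$catalog, inputs$features,
                  half_width = config$half_width,
                  exclude_anchor = config$exclude_anchor,
                  restrict_to_overlap = config$restrict_to_overlap)
  })
  manifest <- st$manifest
  annotated <- st$result
  manifest$counts$n_analyzed <- nrow(annotated)

  st <- .stage(manifest, "tissue_tests", quiet, list(
    all = mann_whitney_by_tissue(annotated, inputs$catalog,
                                 gray_zone_only = FALSE,
                                 thresholds = config$thresholds),
    gray = mann_whitney_by_tissue(annotated, inputs$catalog,
                                  gray_zone_only = TRUE,
                                  thresholds = config$thresholds)))
  manifest <- st$manifest
  tissue_tests <- st$result

  st <- .stage(manifest, "tissue_count_means", quiet,
               mean_by_tissue_count_category(annotated))
  manifest <- st$manifest
  tissue_count_means <- st$result

  st <- .stage(manifest, "window_density_means", quiet,
               mean_by_window_count(annotated,
                                    split_by_anchor_eqtl_status = TRUE,
                                    max_count_bin = config$max_count_bin))
  manifest <- st$manifest
  window_density_means <- st$result

  st <- .stage(manifest, "zone_proportions", quiet,
               eqtl_proportion_by_zone(annotated, config$thresholds))
  manifest <- st$manifest
  zone_proportions <- st$result

  st <- .stage(manifest, "binned_curve", quiet, {
    bins <- binned_eqtl_curve(annotated, config$bin_width, config$n_bins,
                              config$thresholds)
    trend <- gray_zone_trend(bins)
    list(bins = bins, trend = trend)
  })
  manifest <- st$manifest
  curve <- st$result

  st <- .stage(manifest, "genome_chopping", quiet, {
    frags <- chop_genome(inputs$chrom_lengths, config$fragment_size)
    frags <- assign_and_aggregate(frags, annotated, inputs$catalog,
                                  gw_threshold = config$thresholds[["gw"]])
    list(fragments = frags,
         with_gw = fragment_correlation(frags, exclude_gw_fragments = FALSE),
         no_gw = fragment_correlation(frags, exclude_gw_fragments = TRUE))
  })
  manifest <- st$manifest
  chopping <- st$result
  manifest$counts$n_fragments <- nrow(chopping$fragments)
  manifest$counts$n_fragments_no_snp <- chopping$with_gw$n_empty_excluded

  st <- .stage(manifest, "colocalization", quiet,
               colocalization_by_density(annotated))
  manifest <- st$manifest
  coloc <- st$result

  manifest$n_stages <- length(manifest$stages)
  list(annotated = annotated,
       tissue_comparisons = tissue_tests$all,
       tissue_comparisons_gray = tissue_tests$gray,
       tissue_count_means = tissue_count_means,
       window_density_means = window_density_means,
       zone_proportions = zone_proportions,
       binned_curve = curve$bins,
       gray_zone_trend = curve$trend,
       fragments = chopping$fragments,
       fragment_correlation = chopping$with_gw,
       fragment_correlation_no_gw = chopping$no_gw,
       colocalization = coloc,
       manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a pipeline result bundle
#'
#' Writes every result table as tab-separated text plus the manifest and the
#' headline statistics (fragment correlations, gray-zone trend) as JSON, in a
#' fixed directory layout. Refuses to overwrite an existing non-empty
#' directory unless `overwrite = TRUE`.
#'
#' @param bundle Output of [run_pipeline()].
#' @param dir Output directory.
#' @param overwrite Allow writing into a non-empty directory.
#' @param annotated Also write the (large) per-SNP annotated table.
#' @return `dir`, invisibly.
#' @export
write_result_bundle <- function(bundle, dir, overwrite = FALSE,
                                annotated = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !overwrite) {
    ez_config_error("output directory is not empty (use overwrite = TRUE): ", dir)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("tissue_comparisons", "tissue_comparisons_gray",
              "tissue_count_means", "window_density_means",
              "zone_proportions", "binned_curve", "fragments",
              "colocalization")
  if (annotated) tables <- c("annotated", tables)
  for (tb in tables) {
    write_result_table(bundle[[tb]], file.path(dir, paste0(tb, ".tsv")))
  }
  summary <- list(gray_zone_trend = bundle$gray_zone_trend,
                  fragment_correlation = bundle$fragment_correlation,
                  fragment_correlation_no_gw = bundle$fragment_correlation_no_gw)
  jsonlite::write_json(summary, file.path(dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
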