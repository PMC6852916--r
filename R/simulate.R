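#' Simulation configuration
#'
#' Parameters of the synthetic GWAS + eQTL-catalog + regulatory-feature
#' generator. The generating model works on the z-scale: a causal SNP's
#' association z-score is Normal(mu, 1) with
#' `mu = effect_mean_base + effect_per_tissue * min(tissue_count,
#' tissue_effect_cap) + density_effect * min(local_eqtl_count,
#' density_effect_cap)`, a non-causal SNP's is Normal(0, 1), and the GWAS
#' p-value is the two-sided tail probability. The density effect saturates at
#' `density_effect_cap = 6` neighbors, so the density-significance curve has a
#' true plateau for the pipeline to find. eQTL positions are spatially
#' clustered around cluster centers, and regulatory features are placed near
#' those same centers with probability `cluster_strength / (1 +
#' cluster_strength)` (else uniformly), which ties high eQTL density to
#' regulatory content.
#'
#' @param seed Integer RNG seed; seeded runs are reproducible bit-for-bit.
#' @param chrom_lengths Named vector of chromosome lengths (default three
#'   chromosomes of 2e7 bases).
#' @param n_snps Number of GWAS SNPs (default 200,000).
#' @param n_tissues Number of tissues in the eQTL catalog (default 48).
#' @param eqtl_fraction Expected fraction of SNPs that are eQTLs (default
#'   0.02, the order of the eQTL proportion observed among real GWAS SNPs).
#' @param tissue_specific_fraction Probability that an eQTL is active in
#'   exactly one tissue (default 0.8; more than 80% of real eQTLs are
#'   tissue-specific).
#' @param tissue_count_tail Geometric parameter for pan-tissue eQTLs: their
#'   tissue count is `2 + Geometric(tissue_count_tail)`, capped at
#'   `n_tissues`.
#' @param causal_fraction_eqtl,causal_fraction_non_eqtl Fractions of
#'   eQTL / non-eQTL SNPs with a true disease association.
#' @param effect_mean_base Base mean z-shift of causal SNPs.
#' @param effect_per_tissue Additional shift per tissue of eQTL activity.
#' @param tissue_effect_cap Tissue count beyond which the tissue effect stops
#'   growing (default 4, mirroring the ">3" breadth category).
#' @param density_effect Additional shift per neighboring eQTL.
#' @param density_effect_cap Neighbor count at which the density effect
#'   saturates (default 6).
#' @param cluster_strength Propensity of eQTLs and regulatory features to
#'   co-locate around cluster centers (0 = uniform placement).
#' @param cluster_spacing Mean spacing of cluster centers in bases.
#' @param cluster_sd Gaussian width of a cluster in bases.
#' @param half_width Window half-width used for the generator's own
#'   local-density truth (matches the analysis default, 5000).
#' @param feature_width Width of a regulatory feature in bases.
#' @param n_tf_features,n_mirna_features Numbers of TF / miRNA binding sites.
#' @param backbone_fraction Fraction of SNPs flagged as array-backbone SNPs.
#' @return Object of class `sim_config` (a validated list).
#' @seealso [null_config()], [enriched_config()], [simulate_study()]
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chr1 = 2e7, chr2 = 2e7, chr3 = 2e7),
                       n_snps = 200000L,
                       n_tissues = 48L,
                       eqtl_fraction = 0.02,
                       tissue_specific_fraction = 0.8,
                       tissue_count_tail = 0.5,
                       causal_fraction_eqtl = 0.6,
                       causal_fraction_non_eqtl = 0.15,
                       effect_mean_base = 1.5,
                       effect_per_tissue = 0.4,
                       tissue_effect_cap = 4L,
                       density_effect = 0.5,
                       density_effect_cap = 6L,
                       cluster_strength = 60,
                       cluster_spacing = 4e5,
                       cluster_sd = 2000,
                       half_width = 5000L,
                       feature_width = 500L,
                       n_tf_features = 2000L,
                       n_mirna_features = 1000L,
                       backbone_fraction = 0.5) {
  cfg <- list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
              n_snps = as.integer(n_snps), n_tissues = as.integer(n_tissues),
              eqtl_fraction = eqtl_fraction,
              tissue_specific_fraction = tissue_specific_fraction,
              tissue_count_tail = tissue_count_tail,
              causal_fraction_eqtl = causal_fraction_eqtl,
              causal_fraction_non_eqtl = causal_fraction_non_eqtl,
              effect_mean_base = effect_mean_base,
              effect_per_tissue = effect_per_tissue,
              tissue_effect_cap = as.integer(tissue_effect_cap),
              density_effect = density_effect,
              density_effect_cap = as.integer(density_effect_cap),
              cluster_strength = cluster_strength,
              cluster_spacing = cluster_spacing,
              cluster_sd = cluster_sd,
              half_width = as.integer(half_width),
              feature_width = as.integer(feature_width),
              n_tf_features = as.integer(n_tf_features),
              n_mirna_features = as.integer(n_mirna_features),
              backbone_fraction = backbone_fraction)
  fracs <- c("eqtl_fraction", "tissue_specific_fraction", "tissue_count_tail",
             "causal_fraction_eqtl", "causal_fraction_non_eqtl",
             "backbone_fraction")
  for (f in fracs) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1) {
      ez_config_error(f, " must lie in [0, 1]")
    }
  }
  if (is.null(names(cfg$chrom_lengths)) || any(cfg$chrom_lengths < 1)) {
    ez_config_error("chrom_lengths must be a named vector of positive lengths")
  }
  if (cfg$n_snps > sum(cfg$chrom_lengths)) {
    ez_config_error("n_snps exceeds the number of available positions")
  }
  if (cfg$n_snps < 1L || cfg$n_tissues < 1L) {
    ez_config_error("n_snps and n_tissues must be positive")
  }
  structure(cfg, class = "sim_config")
}

#' Null simulation preset
#'
#' All effect parameters zero: no SNP carries a true association, so GWAS
#' p-values are exactly Uniform(0, 1) and independent of eQTL status. Used
#' for type-I calibration of the pipeline's tests.
#'
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
null_config <- function(...) {
  sim_config(causal_fraction_eqtl = 0, causal_fraction_non_eqtl = 0,
             effect_mean_base = 0, effect_per_tissue = 0, density_effect = 0,
             ...)
}

#' Enriched simulation preset
#'
#' The documented default effect sizes: eQTLs are four times as likely to be
#' causal as non-eQTLs, causal effects grow with tissue breadth (capped at 4
#' tissues) and with local eQTL density (saturating at 6 neighbors), and
#' regulatory features cluster where eQTLs cluster. A pipeline run on this
#' preset reproduces the qualitative enrichment patterns: eQTL SNPs more
#' significant than non-eQTLs in every tissue, pan-tissue above
#' tissue-specific, a density curve rising over 0-6 neighbors then
#' plateauing, and eQTL proportions rising across significance zones.
#'
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
enriched_config <- function(...) {
  sim_config(...)
}

#' Generate a synthetic GWAS + eQTL study
#'
#' Draws SNP positions uniformly per chromosome (without duplicates), selects
#' eQTL SNPs with spatial clustering around cluster centers, assigns each
#' eQTL a tissue count (tissue-specific with probability
#' `tissue_specific_fraction`, else `2 + Geometric`), draws per-association
#' adjusted q-values from the decreasing density `q = 0.05 * U^2` on
#' (0, 0.05], places regulatory features near cluster centers, and generates
#' GWAS p-values from the z-scale model described in [sim_config()].
#'
#' @param config A [sim_config()].
#' @return List with elements `gwas` (GWAS SNP table in [read_gwas_summary()]
#'   layout), `catalog` (an [eqtl_catalog()] whose tested universe is every
#'   simulated SNP), `features` (regulatory-feature table), `truth`
#'   (per-SNP generating truth: `snp_id`, `is_eqtl`, `tissue_count`,
#'   `local_eqtl_count`, `causal`, `mu`), and `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  lens <- config$chrom_lengths
  chroms <- names(lens)

  # positions: multinomial split across chromosomes, uniform within
  n_per <- as.vector(stats::rmultinom(1L, config$n_snps, prob = lens))
  pos_list <- lapply(seq_along(chroms), function(i) {
    sort(sample.int(as.integer(lens[[i]]), n_per[i]))
  })
  gwas <- data.table::data.table(
    chrom = rep(chroms, n_per),
    pos = as.integer(unlist(pos_list))
  )
  gwas[, snp_id := sprintf("snp%07d", .I)]
  gwas[, backbone := stats::runif(.N) < config$backbone_fraction]

  # cluster centers, one per ~cluster_spacing bases
  centers <- lapply(seq_along(chroms), function(i) {
    k <- max(1L, as.integer(round(lens[[i]] / config$cluster_spacing)))
    sort(stats::runif(k, 1, lens[[i]]))
  })
  names(centers) <- chroms

  # distance to the nearest cluster center, per SNP
  dist_to_center <- numeric(nrow(gwas))
  for (cc in chroms) {
    idx <- which(gwas$chrom == cc)
    ctr <- centers[[cc]]
    j <- findInterval(gwas$pos[idx], ctr)
    d_left <- ifelse(j >= 1L, gwas$pos[idx] - ctr[pmax(j, 1L)], Inf)
    d_right <- ifelse(j < length(ctr), ctr[pmin(j + 1L, length(ctr))] - gwas$pos[idx], Inf)
    dist_to_center[idx] <- pmin(abs(d_left), abs(d_right))
  }

  # eQTL selection: clustered Bernoulli with mean eqtl_fraction
  w <- 1 + config$cluster_strength *
    exp(-0.5 * (dist_to_center / config$cluster_sd)^2)
  p_eqtl <- pmin(1, config$eqtl_fraction * w / mean(w))
  is_eqtl <- stats::runif(nrow(gwas)) < p_eqtl

  # tissue counts and associations
  tissues <- sprintf("tissue_%02d", seq_len(config$n_tissues))
  n_eqtl <- sum(is_eqtl)
  tissue_count <- integer(nrow(gwas))
  if (n_eqtl > 0L) {
    specific <- stats::runif(n_eqtl) < config$tissue_specific_fraction
    k <- ifelse(specific, 1L,
                pmin(2L + stats::rgeom(n_eqtl, config$tissue_count_tail),
                     config$n_tissues))
    tissue_count[is_eqtl] <- k
    eqtl_ids <- gwas$snp_id[is_eqtl]
    assoc_tissues <- unlist(lapply(k, function(ki) sample(tissues, ki)))
    assoc <- data.table::data.table(
      snp_id = rep(eqtl_ids, k),
      tissue = assoc_tissues,
      raw_p = NA_real_,
      adjusted_q = 0.05 * pmax(stats::runif(sum(k)), .Machine$double.eps)^2,
      significant = TRUE
    )
  } else {
    assoc <- data.table::data.table(snp_id = character(0), tissue = character(0),
                                    raw_p = numeric(0), adjusted_q = numeric(0),
                                    significant = logical(0))
  }

  # local eQTL density truth (distinct eQTL neighbors within +/- half_width,
  # anchor excluded) — the same quantity the analysis measures
  eq_chrom <- gwas$chrom[is_eqtl]
  eq_pos <- gwas$pos[is_eqtl]
  local_count <- .window_counts(gwas$chrom, gwas$pos, eq_chrom, eq_pos,
                                config$half_width)
  local_count[is_eqtl] <- local_count[is_eqtl] - 1L

  # causal status and z-scale effects
  p_causal <- ifelse(is_eqtl, config$causal_fraction_eqtl,
                     config$causal_fraction_non_eqtl)
  causal <- stats::runif(nrow(gwas)) < p_causal
  mu <- ifelse(causal,
               config$effect_mean_base +
                 config$effect_per_tissue *
                   pmin(tissue_count, config$tissue_effect_cap) +
                 config$density_effect *
                   pmin(local_count, config$density_effect_cap),
               0)
  z <- stats::rnorm(nrow(gwas), mean = mu, sd = 1)
  gwas[, p_value := 2 * stats::pnorm(-abs(z))]
  gwas[, neglog10p := -log10(p_value)]

  # regulatory features: near cluster centers with probability
  # cluster_strength / (1 + cluster_strength), else uniform
  all_centers <- data.table::data.table(
    chrom = rep(chroms, lengths(centers)),
    center = unlist(centers))
  place_features <- function(n_feat, cls) {
    if (n_feat == 0L) {
      return(data.table::data.table(chrom = character(0), start = integer(0),
                                    end = integer(0), feature_class = character(0)))
    }
    clustered <- stats::runif(n_feat) < config$cluster_strength /
      (1 + config$cluster_strength)
    n_cl <- sum(clustered)
    ch <- character(n_feat)
    st <- numeric(n_feat)
    if (n_cl > 0L) {
      pick <- sample.int(nrow(all_centers), n_cl, replace = TRUE)
      ch[clustered] <- all_centers$chrom[pick]
      st[clustered] <- all_centers$center[pick] +
        stats::rnorm(n_cl, 0, 2 * config$cluster_sd)
    }
    if (n_feat - n_cl > 0L) {
      pick <- sample.int(length(chroms), n_feat - n_cl, replace = TRUE,
                         prob = lens)
      ch[!clustered] <- chroms[pick]
      st[!clustered] <- stats::runif(n_feat - n_cl, 1, lens[pick])
    }
    st <- pmax(1, pmin(round(st), lens[ch] - config$feature_width + 1))
    data.table::data.table(chrom = ch, start = as.integer(st),
                           end = as.integer(st + config$feature_width - 1L),
                           feature_class = cls)
  }
  features <- rbind(place_features(config$n_tf_features, "tf"),
                    place_features(config$n_mirna_features, "mirna"))

  catalog <- eqtl_catalog(
    assoc,
    positions = gwas[is_eqtl | snp_id %in% assoc$snp_id,
                     .(snp_id, chrom, pos)],
    tissues = tissues,
    tested_snps = gwas$snp_id)

  truth <- data.table::data.table(snp_id = gwas$snp_id, is_eqtl = is_eqtl,
                                  tissue_count = tissue_count,
                                  local_eqtl_count = local_count,
                                  causal = causal, mu = mu)
  data.table::setcolorder(gwas, c("snp_id", "chrom", "pos", "p_value",
                                  "neglog10p", "backbone"))
  list(gwas = gwas[], catalog = catalog, features = features, truth = truth,
       config = config)
}

#' Write simulated inputs to disk
#'
#' Writes a simulated study in the exact input formats the readers consume:
#' GWAS summary table, eQTL catalog (pre-filtered layout), one BED file per
#' feature class, a chromosome-length table, and the truth table.
#'
#' @param sim Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulated_inputs <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    gwas = file.path(dir, "gwas.tsv"),
    eqtl = file.path(dir, "eqtl_catalog.tsv"),
    tf = file.path(dir, "tf_sites.bed"),
    mirna = file.path(dir, "mirna_sites.bed"),
    chrom_lengths = file.path(dir, "chrom_lengths.tsv"),
    truth = file.path(dir, "truth.tsv"))
  write_gwas_summary(sim$gwas, paths[["gwas"]])
  write_eqtl_catalog(sim$catalog, paths[["eqtl"]])
  write_bed_features(sim$features[sim$features$feature_class == "tf", ],
                     paths[["tf"]])
  write_bed_features(sim$features[sim$features$feature_class == "mirna", ],
                     paths[["mirna"]])
  write_result_table(
    data.table::data.table(chrom = names(sim$config$chrom_lengths),
                           length = as.integer(sim$config$chrom_lengths)),
    paths[["chrom_lengths"]])
  write_result_table(sim$truth, paths[["truth"]])
  invisible(paths)
}
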