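#' Normalize chromosome labels
#'
#' Chromosome labels are opaque strings matched exactly across inputs
#' ("chr1" != "1"). This helper applies an explicit, reversible normalization
#' when inputs disagree on the "chr" prefix.
#'
#' @param chrom Character vector of chromosome labels.
#' @param normalize One of `"none"` (default), `"strip_chr"`, `"add_chr"`.
#' @return Character vector of normalized labels.
#' @export
normalize_chrom <- function(chrom, normalize = c("none", "strip_chr", "add_chr")) {
  normalize <- match.arg(normalize)
  switch(normalize,
    none = chrom,
    strip_chr = sub("^chr", "", chrom),
    add_chr = ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
  )
}

.read_delim <- function(path, delim = NULL) {
  if (!file.exists(path)) ez_config_error("input file does not exist: ", path)
  if (is.null(delim)) {
    # auto-detect from the header line: tab wins if present, else comma
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else "\t"
  }
  data.table::fread(path, sep = delim, header = TRUE, data.table = TRUE,
                    showProgress = FALSE)
}

.require_columns <- function(dt, cols, what) {
  missing <- setdiff(unlist(cols), names(dt))
  if (length(missing)) {
    ez_config_error(what, ": missing column(s) ", paste(missing, collapse = ", "))
  }
}

#' Read GWAS summary statistics
#'
#' Reads a delimited table of per-SNP GWAS association results. Rows with a
#' p-value outside (0, 1] are rejected (not clamped) and counted: -log10(0) is
#' undefined and silently clamping would inflate downstream enrichment. The
#' rejection count is attached as attribute `n_rejected` and reported via a
#' message.
#'
#' @param path Path to a delimited text file with a header.
#' @param column_map Named list mapping internal names `snp`, `chr`, `pos`,
#'   `p`, and optionally `backbone` to the file's column names.
#' @param delim Field separator; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @param chrom_normalize Chromosome-label normalization, see
#'   [normalize_chrom()].
#' @return A `data.table` with columns `snp_id`, `chrom`, `pos`, `p_value`,
#'   `neglog10p`, `backbone`, in file order; attribute `n_rejected` gives the
#'   number of rows dropped for out-of-range p.
#' @export
read_gwas_summary <- function(path,
                              column_map = list(snp = "snp", chr = "chr",
                                                pos = "pos", p = "p"),
                              delim = NULL,
                              chrom_normalize = "none") {
  dt <- .read_delim(path, delim)
  .require_columns(dt, column_map[c("snp", "chr", "pos", "p")], "GWAS summary table")
  has_backbone <- !is.null(column_map$backbone)
  if (has_backbone) .require_columns(dt, column_map["backbone"], "GWAS summary table")

  out <- data.table::data.table(
    snp_id = as.character(dt[[column_map$snp]]),
    chrom = normalize_chrom(as.character(dt[[column_map$chr]]), chrom_normalize),
    pos = as.integer(dt[[column_map$pos]]),
    p_value = as.numeric(dt[[column_map$p]]),
    backbone = if (has_backbone) as.logical(dt[[column_map$backbone]]) else FALSE
  )
  bad <- !is.finite(out$p_value) | out$p_value <= 0 | out$p_value > 1
  n_rejected <- sum(bad)
  if (n_rejected > 0) {
    message("read_gwas_summary: rejected ", n_rejected,
            " row(s) with p outside (0, 1]")
    out <- out[!bad]
  }
  if (anyDuplicated(out$snp_id)) {
    first_dup <- out$snp_id[duplicated(out$snp_id)][1L]
    ez_data_error("duplicate snp_id in GWAS summary table: ", first_dup)
  }
  if (any(out$pos < 1L, na.rm = TRUE)) {
    ez_data_error("GWAS summary table: position < 1")
  }
  out[, neglog10p := -log10(p_value)]
  data.table::setcolorder(out, c("snp_id", "chrom", "pos", "p_value",
                                 "neglog10p", "backbone"))
  data.table::setattr(out, "n_rejected", n_rejected)
  out[]
}

#' Write GWAS summary statistics
#'
#' Inverse of [read_gwas_summary()] with canonical column names; round-trips
#' field-by-field.
#'
#' @param gwas Table as returned by [read_gwas_summary()].
#' @param path Output path (tab-separated, with header).
#' @return `path`, invisibly.
#' @export
write_gwas_summary <- function(gwas, path) {
  # %.17g preserves every bit of the double, so read -> write -> read is exact
  out <- data.table::data.table(snp = gwas$snp_id, chr = gwas$chrom,
                                pos = gwas$pos,
                                p = sprintf("%.17g", gwas$p_value),
                                backbone = gwas$backbone)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Construct a cis-eQTL catalog
#'
#' The catalog holds significant SNP-by-tissue cis-eQTL associations, the
#' tissue panel, genomic positions for every catalog SNP, and (optionally) the
#' set of SNPs the eQTL study tested — needed to restrict a GWAS to the
#' overlap of both studies.
#'
#' @param associations `data.frame` with columns `snp_id`, `tissue`,
#'   `adjusted_q` (per-tissue multiple-testing-adjusted p), optionally `raw_p`
#'   and `significant`.
#' @param positions `data.frame` with columns `snp_id`, `chrom`, `pos`
#'   covering every association SNP.
#' @param tissues Character vector of tissue labels; defaults to the tissues
#'   observed in `associations`.
#' @param tested_snps Optional character vector: all SNP ids tested by the
#'   eQTL study.
#' @return An object of class `eqtl_catalog`.
#' @export
eqtl_catalog <- function(associations, positions, tissues = NULL,
                         tested_snps = NULL) {
  assoc <- data.table::as.data.table(associations)
  .require_columns(assoc, list("snp_id", "tissue", "adjusted_q"), "eQTL associations")
  assoc[, snp_id := as.character(snp_id)]
  assoc[, tissue := as.character(tissue)]
  if (!"raw_p" %in% names(assoc)) assoc[, raw_p := NA_real_]
  if (!"significant" %in% names(assoc)) assoc[, significant := adjusted_q <= 0.05]
  if (any(!is.finite(assoc$adjusted_q) | assoc$adjusted_q <= 0 | assoc$adjusted_q > 1)) {
    ez_data_error("eQTL associations: adjusted_q outside (0, 1]")
  }
  if (anyDuplicated(assoc, by = c("snp_id", "tissue"))) {
    dup <- assoc[duplicated(assoc, by = c("snp_id", "tissue"))][1L]
    ez_data_error("duplicate (snp_id, tissue) association: ",
                  dup$snp_id, " / ", dup$tissue)
  }
  pos <- data.table::as.data.table(positions)
  .require_columns(pos, list("snp_id", "chrom", "pos"), "eQTL positions")
  pos <- unique(pos[, .(snp_id = as.character(snp_id),
                        chrom = as.character(chrom), pos = as.integer(pos))])
  if (anyDuplicated(pos$snp_id)) {
    ez_data_error("conflicting positions for catalog SNP: ",
                  pos$snp_id[duplicated(pos$snp_id)][1L])
  }
  missing_pos <- setdiff(assoc$snp_id, pos$snp_id)
  if (length(missing_pos)) {
    ez_data_error("no position for catalog SNP(s): ",
                  paste(utils::head(missing_pos, 3), collapse = ", "))
  }
  if (is.null(tissues)) tissues <- sort(unique(assoc$tissue))
  if (!all(assoc$tissue %in% tissues)) {
    ez_data_error("association tissue not in tissue panel: ",
                  setdiff(assoc$tissue, tissues)[1L])
  }
  data.table::setkey(assoc, snp_id, tissue)
  data.table::setkey(pos, snp_id)
  structure(list(associations = assoc[], positions = pos[],
                 tissues = tissues,
                 tested_snps = if (is.null(tested_snps)) NULL else as.character(tested_snps)),
            class = "eqtl_catalog")
}

#' @export
print.eqtl_catalog <- function(x, ...) {
  sig <- x$associations[x$associations$significant == TRUE]
  cat("eqtl_catalog:", nrow(x$associations), "associations,",
      length(unique(sig$snp_id)), "unique eQTL SNPs,",
      length(x$tissues), "tissues",
      if (!is.null(x$tested_snps)) paste0("(tested universe: ",
                                          length(x$tested_snps), " SNPs)"),
      "\n")
  invisible(x)
}

#' Unique significant eQTL SNPs in a catalog
#'
#' @param catalog An [eqtl_catalog()].
#' @return `data.table` with `snp_id`, `chrom`, `pos`, one row per SNP with a
#'   significant association in at least one tissue.
#' @export
eqtl_snps <- function(catalog) {
  ids <- unique(catalog$associations[significant == TRUE, snp_id])
  catalog$positions[.(ids), .(snp_id, chrom, pos)]
}

#' Tissues in which SNPs are significant eQTLs
#'
#' @param catalog An [eqtl_catalog()].
#' @param snp_ids Character vector of SNP ids.
#' @return Named list mapping each requested id to the (possibly empty)
#'   character vector of tissues with a significant association.
#' @export
eqtl_tissues <- function(catalog, snp_ids) {
  sig <- catalog$associations[significant == TRUE, .(snp_id, tissue)]
  sets <- split(sig$tissue, sig$snp_id)
  out <- sets[snp_ids]
  out[vapply(out, is.null, logical(1))] <- list(character(0))
  names(out) <- snp_ids
  out
}

#' Read a cis-eQTL catalog
#'
#' Two modes mirror the two forms an eQTL release may take. In
#' `"raw_with_testcounts"` mode each row carries the raw association p-value
#' and a per-tissue number-of-tests table is supplied; per-tissue Bonferroni
#' adjustment `q = min(1, p * m_tissue)` is applied and only associations with
#' `q <= alpha` are retained. In `"pre_filtered"` mode the p column is the
#' already-adjusted q and rows are kept as-is.
#'
#' @param path Delimited file with header; columns (by default) `snp`,
#'   `tissue`, `p`, `chr`, `pos`.
#' @param mode `"pre_filtered"` or `"raw_with_testcounts"`.
#' @param test_counts Required in raw mode: a `data.frame` with columns
#'   `tissue`, `n_tests`, or a named numeric vector, giving the number of
#'   cis-eQTL tests performed per tissue.
#' @param alpha Significance level after adjustment (default 0.05).
#' @param column_map Named list mapping internal names to file columns.
#' @param tested_snps Optional character vector (or path to a one-column file)
#'   listing every SNP tested by the eQTL study.
#' @param delim,chrom_normalize As in [read_gwas_summary()].
#' @return An [eqtl_catalog()].
#' @export
read_eqtl_catalog <- function(path,
                              mode = c("pre_filtered", "raw_with_testcounts"),
                              test_counts = NULL,
                              alpha = 0.05,
                              column_map = list(snp = "snp", tissue = "tissue",
                                                p = "p", chr = "chr", pos = "pos"),
                              tested_snps = NULL,
                              delim = NULL,
                              chrom_normalize = "none") {
  mode <- match.arg(mode)
  dt <- .read_delim(path, delim)
  .require_columns(dt, column_map[c("snp", "tissue", "p", "chr", "pos")],
                   "eQTL catalog")
  assoc <- data.table::data.table(
    snp_id = as.character(dt[[column_map$snp]]),
    tissue = as.character(dt[[column_map$tissue]]),
    p_col = as.numeric(dt[[column_map$p]])
  )
  pos <- data.table::data.table(
    snp_id = assoc$snp_id,
    chrom = normalize_chrom(as.character(dt[[column_map$chr]]), chrom_normalize),
    pos = as.integer(dt[[column_map$pos]])
  )
  if (mode == "raw_with_testcounts") {
    if (is.null(test_counts)) {
      ez_config_error("raw_with_testcounts mode requires a per-tissue test_counts table")
    }
    if (is.numeric(test_counts) && !is.null(names(test_counts))) {
      m <- test_counts
    } else {
      tc <- data.table::as.data.table(test_counts)
      .require_columns(tc, list("tissue", "n_tests"), "test-count table")
      m <- stats::setNames(as.numeric(tc$n_tests), tc$tissue)
    }
    unknown <- setdiff(assoc$tissue, names(m))
    if (length(unknown)) {
      ez_config_error("tissue(s) missing from test-count table: ",
                      paste(unknown, collapse = ", "))
    }
    assoc[, raw_p := p_col]
    assoc[, adjusted_q := pmin(1, raw_p * m[tissue])]
    assoc <- assoc[adjusted_q <= alpha]
    assoc[, significant := TRUE]
  } else {
    assoc[, raw_p := NA_real_]
    assoc[, adjusted_q := p_col]
    n_bad <- sum(assoc$adjusted_q > alpha)
    if (n_bad > 0) {
      warning("pre_filtered eQTL catalog contains ", n_bad,
              " association(s) with adjusted q > ", alpha,
              "; marked not significant")
    }
    assoc[, significant := adjusted_q <= alpha]
  }
  assoc[, p_col := NULL]
  if (is.character(tested_snps) && length(tested_snps) == 1 &&
      file.exists(tested_snps)) {
    tested_snps <- .read_delim(tested_snps)[[1L]]
  }
  eqtl_catalog(assoc, pos[snp_id %in% assoc$snp_id],
               tested_snps = tested_snps)
}

#' Write a cis-eQTL catalog
#'
#' Writes the significant associations with positions in the `pre_filtered`
#' input layout, so that [read_eqtl_catalog()] round-trips the catalog.
#'
#' @param catalog An [eqtl_catalog()].
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_eqtl_catalog <- function(catalog, path) {
  out <- merge(catalog$associations[, .(snp_id, tissue, adjusted_q)],
               catalog$positions, by = "snp_id", sort = FALSE)
  data.table::setorder(out, snp_id, tissue)
  data.table::fwrite(out[, .(snp = snp_id, tissue,
                             p = sprintf("%.17g", adjusted_q),
                             chr = chrom, pos = pos)], path, sep = "\t")
  invisible(path)
}

#' Read regulatory features from BED
#'
#' BED coordinates are 0-based half-open on disk; they are converted to the
#' package's single internal convention, 1-based inclusive
#' (`start = start_bed + 1`, `end = end_bed`), on read. This is the only place
#' in the package where a coordinate convention changes.
#'
#' @param path BED3+ file (no header; extra columns ignored).
#' @param feature_class `"tf"` (transcription-factor binding site) or
#'   `"mirna"` (miRNA binding site).
#' @return `data.table` with columns `chrom`, `start`, `end`, `feature_class`
#'   (1-based inclusive coordinates).
#' @export
read_bed_features <- function(path, feature_class = c("tf", "mirna")) {
  feature_class <- match.arg(feature_class)
  if (!file.exists(path)) ez_config_error("BED file does not exist: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.table::data.table(chrom = character(0), start = integer(0),
                                  end = integer(0), feature_class = character(0)))
  }
  fields <- strsplit(lines, "[ \t]+")
  n_fields <- lengths(fields)
  if (any(n_fields < 3L)) {
    ez_data_error("malformed BED record at line ", which(n_fields < 3L)[1L],
                  ": fewer than 3 fields")
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start_bed <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end_bed <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  bad <- is.na(start_bed) | is.na(end_bed) | end_bed <= start_bed
  if (any(bad)) {
    ez_data_error("malformed BED record at line ", which(bad)[1L],
                  ": end <= start or non-numeric coordinates")
  }
  data.table::data.table(chrom = chrom, start = start_bed + 1L, end = end_bed,
                         feature_class = feature_class)
}

#' Write regulatory features to BED
#'
#' Inverse of [read_bed_features()]: internal 1-based inclusive intervals are
#' written back as 0-based half-open BED3.
#'
#' @param features Table with `chrom`, `start`, `end` (internal convention).
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_bed_features <- function(features, path) {
  out <- data.table::data.table(chrom = features$chrom,
                                start = features$start - 1L,
                                end = features$end)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a chromosome-length table
#'
#' @param path Two-column delimited file (chromosome, length), with header.
#' @param delim,chrom_normalize As in [read_gwas_summary()].
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_lengths <- function(path, delim = NULL, chrom_normalize = "none") {
  dt <- .read_delim(path, delim)
  if (ncol(dt) < 2L) ez_config_error("chromosome-length table needs 2 columns")
  lens <- as.numeric(dt[[2L]])
  names(lens) <- normalize_chrom(as.character(dt[[1L]]), chrom_normalize)
  if (any(!is.finite(lens) | lens < 1)) {
    ez_data_error("chromosome lengths must be >= 1")
  }
  lens
}

#' Write a result table
#'
#' All result tables are written as tab-separated text with a header, in a
#' deterministic column and row order.
#'
#' @param x Table to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(x, path) {
  data.table::fwrite(data.table::as.data.table(x), path, sep = "\t", na = "NA")
  invisible(path)
}
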