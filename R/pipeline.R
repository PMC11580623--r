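#' Run the full SDR discovery pipeline
#'
#' Chains every stage on in-memory inputs: call masking and site filtering,
#' per-site sex association (FET, allele-frequency LRT, BH-FDR,
#' Weir-Cockerham F_ST), sex-specific SNP detection with depth and LD
#' support, coverage scanning for sex-limited hemizygous regions, system
#' classification, SDR assembly with repeat content, gene census and
#' variant annotation of the hits.
#'
#' @param genotypes A `genotype_table` (raw; QC is applied here).
#' @param sexframe Sample sheet aligned with the genotype samples.
#' @param depth Optional `depth_matrix` for the coverage scan.
#' @param genes Optional `gene_models` (or GFF-style data frame).
#' @param repeats Optional repeat intervals (`chrom`, `start`, `end`,
#'   1-based).
#' @param reference Optional named sequence vector (needed for coding-effect
#'   annotation).
#' @param filter,rule,coverage,assembly Stage configurations.
#' @param alpha FDR level for the association scan.
#' @param flank_bp Annotation flank for upstream/downstream calls.
#' @return An object of class `sdr_scan` with elements `qc`, `assoc`,
#'   `hits`, `hit_depth`, `ld`, `haploid_regions`, `system_call`,
#'   `sex_linked_regions`, `sdr`, `repeat_content`, `sdr_genes`,
#'   `hit_annotation`.
#' @export
sdr_scan <- function(genotypes, sexframe, depth = NULL, genes = NULL,
                     repeats = NULL, reference = NULL,
                     filter = filter_config(), rule = sex_specific_rule(),
                     coverage = coverage_config(),
                     assembly = assembly_config(),
                     alpha = 0.05, flank_bp = 5000) {
  masked <- mask_low_quality_calls(genotypes, filter)
  filtered <- filter_sites(masked, sexframe, filter)
  assoc <- assoc_scan(filtered, sexframe, alpha = alpha)
  hits <- detect_sex_specific(filtered, sexframe, rule)
  hit_depth <- if (nrow(hits)) hit_depth_summary(hits, depth, sexframe) else NULL
  ld <- if (nrow(hits) >= 2) {
    idx <- match(paste(hits$chrom, hits$pos),
                 paste(filtered$sites$chrom, filtered$sites$pos))
    ld_r2(subset_sites(filtered, idx))
  } else NULL

  haploid <- list()
  if (!is.null(depth)) {
    cand <- scan_depth(depth, sexframe, coverage)
    haploid <- call_regions(cand, coverage)
  }
  system_call <- classify_system(
    hits, coverage_regions = haploid,
    depth_flag = if (!is.null(hit_depth)) !hit_depth$depth_comparable else NULL)

  chrom_lengths <- if (!is.null(reference))
    setNames(nchar(reference), names(reference)) else NULL
  sl_regions <- cluster_snps(hits, assembly, chrom_lengths)
  sdr <- assemble_sdr(sl_regions, haploid)

  repeat_content <- if (!is.null(repeats) && !is.null(sdr) &&
                        inherits(sdr, "sdr_call"))
    repeat_fraction(sdr$sdr, repeats) else NA_real_

  models <- if (is.data.frame(genes)) gene_models(genes) else genes
  sdr_genes <- if (!is.null(models) && inherits(sdr, "sdr_call"))
    genes_in_region(sdr$sdr, models) else NULL
  hit_annotation <- if (!is.null(models) && !is.null(reference) && nrow(hits)) {
    idx <- match(paste(hits$chrom, hits$pos),
                 paste(filtered$sites$chrom, filtered$sites$pos))
    annotate_variants(filtered$sites[idx, c("chrom", "pos", "ref", "alt")],
                      models, reference, flank_bp)
  } else NULL

  structure(list(qc = list(n_masked = attr(masked, "n_masked"),
                           drop_counts = attr(filtered, "drop_counts"),
                           n_sites = nrow(filtered$sites)),
                 filtered = filtered, assoc = assoc, hits = hits,
                 hit_depth = hit_depth, ld = ld, haploid_regions = haploid,
                 system_call = system_call,
                 sex_linked_regions = sl_regions, sdr = sdr,
                 repeat_content = repeat_content, sdr_genes = sdr_genes,
                 hit_annotation = hit_annotation),
            class = "sdr_scan")
}

#' @export
print.sdr_scan <- function(x, ...) {
  cat(sprintf("SDR scan: %d filtered sites, %d sex-specific SNPs, system %s (%s)\n",
              x$qc$n_sites, nrow(x$hits), x$system_call$system,
              x$system_call$confidence))
  cat(sprintf("  weighted F_ST = %.5f\n", x$assoc$fst_weighted))
  if (!is.null(x$ld))
    cat(sprintf("  mean LD r2 among hits = %.3f\n", x$ld$mean_r2))
  if (length(x$haploid_regions)) {
    cat(sprintf("  %d sex-limited hemizygous region(s):\n",
                length(x$haploid_regions)))
    for (r in x$haploid_regions) { cat("   "); print(r) }
  }
  if (inherits(x$sdr, "sdr_call")) print(x$sdr)
  if (!is.na(x$repeat_content))
    cat(sprintf("  SDR repeat content: %.0f%%\n", 100 * x$repeat_content))
  if (!is.null(x$sdr_genes))
    cat(sprintf("  genes in SDR: %s\n", paste(x$sdr_genes$gene, collapse = ", ")))
  invisible(x)
}

#' @export
summary.sdr_scan <- function(object, ...) {
  x <- object
  out <- list(
    n_sites = x$qc$n_sites,
    n_hits = nrow(x$hits),
    system = x$system_call$system,
    fst_weighted = x$assoc$fst_weighted,
    fet_threshold = x$assoc$fet_threshold,
    mean_ho = if (nrow(x$hits)) mean(x$hits$ho_focal) else NA_real_,
    mean_r2 = if (!is.null(x$ld)) x$ld$mean_r2 else NA_real_,
    sdr_length_bp = if (inherits(x$sdr, "sdr_call"))
      interval_length(x$sdr$sdr$start, x$sdr$sdr$end) else NA_integer_,
    repeat_content = x$repeat_content,
    n_sdr_genes = if (!is.null(x$sdr_genes)) nrow(x$sdr_genes) else NA_integer_)
  class(out) <- "summary.sdr_scan"
  out
}

#' @export
print.summary.sdr_scan <- function(x, ...) {
  cat(sprintf(paste0(
    "sites: %d | sex-specific SNPs: %d (mean Ho %.3f) | system: %s\n",
    "weighted F_ST: %.5f | FET p-line: %.3g | mean r2: %.3f\n",
    "SDR: %s bp (repeats %.0f%%), %s genes\n"),
    x$n_sites, x$n_hits, x$mean_ho, x$system, x$fst_weighted,
    x$fet_threshold, x$mean_r2,
    format(x$sdr_length_bp, big.mark = ","), 100 * x$repeat_content,
    x$n_sdr_genes))
  invisible(x)
}
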