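#' SNP filtering thresholds
#'
#' The six-criterion cascade applied to raw biallelic SNP calls:
#' (a) biallelic only; (b) site quality `Q >= min_site_q` and genotype
#' quality `GQ >= min_gq`; (c) per-call depth `DP >= min_dp`; (d) call rate
#' `>= min_callrate` overall and `>= min_called_per_sex` called individuals
#' in each sex; (e) global minor allele frequency `>= global_maf`, or
#' (f) rescue when the within-sex MAF reaches `rescue_local_maf` in either
#' sex. GQ/DP act per call (masking); the remaining criteria act per site.
#'
#' @param min_site_q,min_gq,min_dp,min_callrate,min_called_per_sex,global_maf,rescue_local_maf
#'   Thresholds; defaults 30, 20, 7, 0.90, 12, 0.05, 0.20. All comparisons
#'   are inclusive (`>=`).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_site_q = 30, min_gq = 20, min_dp = 7,
                          min_callrate = 0.90, min_called_per_sex = 12,
                          global_maf = 0.05, rescue_local_maf = 0.20) {
  stopifnot(min_site_q >= 0, min_gq >= 0, min_dp >= 0,
            min_callrate > 0, min_callrate <= 1,
            min_called_per_sex >= 0, global_maf >= 0, rescue_local_maf >= 0)
  structure(list(min_site_q = min_site_q, min_gq = min_gq, min_dp = min_dp,
                 min_callrate = min_callrate,
                 min_called_per_sex = min_called_per_sex,
                 global_maf = global_maf,
                 rescue_local_maf = rescue_local_maf),
            class = "filter_config")
}

#' Load genotypes from a VCF and a sample-sex table
#'
#' Parses a multi-sample VCF (plain or gzipped) into a `genotype_table` --
#' sites with REF/ALT/QUAL plus per-call genotype code, DP and GQ matrices --
#' and reads the sample sheet into a sex frame. Phasing is ignored
#' (`1|0` == `0/1`); any half-missing genotype (`./1`) is treated as
#' missing. Multi-allelic records are dropped (not split), as are non-SNP
#' records.
#'
#' @param vcf_path Path to a VCF v4.2+ file.
#' @param sex_path Path to a TSV with columns `sample_id` and `sex`
#'   (values `F`/`M`); an optional `genome_mean_depth` column is carried
#'   through.
#' @return List with `genotypes` (a `genotype_table`) and `sexframe`.
#' @export
load_genotypes <- function(vcf_path, sex_path) {
  sexframe <- read.delim(sex_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "sex") %in% names(sexframe)))
    stop("sex table needs columns sample_id and sex")
  if (anyDuplicated(sexframe$sample_id)) stop("duplicated sample IDs in sex table")
  if (!all(sexframe$sex %in% c("F", "M"))) stop("sex must be F or M")
  if (length(unique(sexframe$sex)) < 2) stop("both sexes must be represented")

  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  samples <- colnames(v@gt)[-1]
  missing_samples <- setdiff(samples, sexframe$sample_id)
  if (length(missing_samples))
    stop("VCF samples absent from sex table: ",
         paste(missing_samples, collapse = ", "))
  sexframe <- sexframe[match(samples, sexframe$sample_id), , drop = FALSE]
  rownames(sexframe) <- NULL
  if (!"genome_mean_depth" %in% names(sexframe))
    sexframe$genome_mean_depth <- NA_real_

  fix <- vcfR::getFIX(v)
  keep <- !is.na(fix[, "ALT"]) & !grepl(",", fix[, "ALT"], fixed = TRUE) &
    nchar(fix[, "REF"]) == 1 & nchar(fix[, "ALT"]) == 1
  gt_raw <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)[keep, , drop = FALSE]
  gq <- vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE)[keep, , drop = FALSE]
  code <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep(NA_integer_, length(g))
    out[g %in% c("0/0")] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g %in% c("1/1")] <- 2L
    out
  }
  gt <- matrix(code(gt_raw), nrow(gt_raw), ncol(gt_raw))
  sites <- data.frame(chrom = fix[keep, "CHROM"],
                      pos = as.integer(fix[keep, "POS"]),
                      ref = fix[keep, "REF"], alt = fix[keep, "ALT"],
                      qual = as.numeric(fix[keep, "QUAL"]),
                      stringsAsFactors = FALSE)
  table <- structure(list(sites = sites, gt = gt,
                          dp = dp, gq = gq, samples = samples),
                     class = "genotype_table")
  list(genotypes = table, sexframe = sexframe)
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d sites x %d samples (%.1f%% called)\n",
              nrow(x$sites), length(x$samples),
              100 * mean(!is.na(x$gt))))
  invisible(x)
}

#' Mask low-quality genotype calls
#'
#' Sets to missing every call with `GQ < min_gq` or `DP < min_dp`
#' (thresholds inclusive on retention). Masking individual calls -- rather
#' than dropping whole sites -- feeds naturally into the per-site call-rate
#' criteria applied afterwards by [filter_sites()].
#'
#' @param table A `genotype_table`.
#' @param cfg A [filter_config()].
#' @return The table with failing calls set to `NA`; the number of newly
#'   masked calls is stored in `attr(, "n_masked")`.
#' @export
mask_low_quality_calls <- function(table, cfg = filter_config()) {
  bad <- (!is.na(table$gt)) &
    (is.na(table$gq) | table$gq < cfg$min_gq |
       is.na(table$dp) | table$dp < cfg$min_dp)
  table$gt[bad] <- NA_integer_
  attr(table, "n_masked") <- sum(bad)
  table
}

# alt-allele frequency over called genotypes; folds to MAF
.maf <- function(gt_rows) {
  called <- rowSums(!is.na(gt_rows))
  alt <- rowSums(gt_rows, na.rm = TRUE)
  p <- ifelse(called > 0, alt / (2 * called), NA_real_)
  pmin(p, 1 - p)
}

#' Apply the per-site SNP filter cascade
#'
#' Retains a site iff it is biallelic, `QUAL >= min_site_q`, overall call
#' rate `>= min_callrate`, at least `min_called_per_sex` called individuals
#' in each sex, and either global MAF `>= global_maf` or within-sex MAF
#' `>= rescue_local_maf` in at least one sex. MAF is computed from allele
#' counts of called genotypes only (missing calls leave the denominator).
#' Call the function on a table already masked with
#' [mask_low_quality_calls()]; the per-sex called counts are therefore
#' post-masking counts.
#'
#' @param table A masked `genotype_table`.
#' @param sexframe Sample sheet aligned with `table$samples`.
#' @param cfg A [filter_config()].
#' @return The filtered table; `attr(, "drop_counts")` reports, in cascade
#'   order, how many sites each criterion removed among sites surviving the
#'   previous ones.
#' @export
filter_sites <- function(table, sexframe, cfg = filter_config()) {
  stopifnot(identical(sexframe$sample_id, table$samples))
  n <- length(table$samples)
  is_f <- sexframe$sex == "F"
  called <- rowSums(!is.na(table$gt))
  called_f <- rowSums(!is.na(table$gt[, is_f, drop = FALSE]))
  called_m <- called - called_f
  maf_all <- .maf(table$gt)
  maf_f <- .maf(table$gt[, is_f, drop = FALSE])
  maf_m <- .maf(table$gt[, !is_f, drop = FALSE])

  pass_q <- !is.na(table$sites$qual) & table$sites$qual >= cfg$min_site_q
  pass_cr <- called / n >= cfg$min_callrate
  pass_sex <- called_f >= cfg$min_called_per_sex &
    called_m >= cfg$min_called_per_sex
  pass_maf <- (!is.na(maf_all) & maf_all >= cfg$global_maf) |
    (!is.na(maf_f) & maf_f >= cfg$rescue_local_maf) |
    (!is.na(maf_m) & maf_m >= cfg$rescue_local_maf)

  keep <- pass_q & pass_cr & pass_sex & pass_maf
  drop_counts <- c(site_quality = sum(!pass_q),
                   call_rate = sum(pass_q & !pass_cr),
                   per_sex_calls = sum(pass_q & pass_cr & !pass_sex),
                   maf = sum(pass_q & pass_cr & pass_sex & !pass_maf))
  if (!any(keep)) warning("no sites survive filtering")
  out <- subset_sites(table, keep)
  attr(out, "drop_counts") <- drop_counts
  out
}

#' Subset a genotype table by site index
#' @param table A `genotype_table`.
#' @param i Logical or integer site index.
#' @return The subsetted table.
#' @export
subset_sites <- function(table, i) {
  out <- table
  out$sites <- table$sites[i, , drop = FALSE]
  rownames(out$sites) <- NULL
  out$gt <- table$gt[i, , drop = FALSE]
  out$dp <- table$dp[i, , drop = FALSE]
  out$gq <- table$gq[i, , drop = FALSE]
  dimnames(out$gt) <- dimnames(out$dp) <- dimnames(out$gq) <- NULL
  class(out) <- "genotype_table"
  out
}
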