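#' Sex-specific SNP detection rule
#'
#' A site is called sex-specific for a focal sex when that sex shows at
#' least `min_het_count` heterozygotes with observed heterozygosity at least
#' `min_ho`, while the other sex has no heterozygotes at all and every one
#' of its called genotypes is the same homozygote. With 24 focal-sex
#' individuals and an Ho floor of 0.75 the derived count floor is 18
#' (`ceiling(0.75 * 24)`); see [derive_min_het()].
#'
#' @param min_het_count Minimum heterozygote count in the focal sex; when
#'   `NULL`, derived per dataset as `ceiling(min_ho * n_focal)`.
#' @param min_ho Minimum observed heterozygosity (het/called) in the focal
#'   sex.
#' @param max_other_het Maximum heterozygotes tolerated in the other sex
#'   (0: fully sex-linked).
#' @return An object of class `sex_specific_rule`.
#' @export
sex_specific_rule <- function(min_het_count = 18L, min_ho = 0.75,
                              max_other_het = 0L) {
  stopifnot(is.null(min_het_count) || min_het_count >= 1,
            min_ho > 0, min_ho <= 1, max_other_het >= 0)
  structure(list(min_het_count = min_het_count, min_ho = min_ho,
                 max_other_het = as.integer(max_other_het)),
            class = "sex_specific_rule")
}

#' Heterozygote-count floor implied by an Ho threshold
#'
#' Generalises a fixed heterozygote-count requirement to any cohort size:
#' with `n_focal` individuals of the focal sex and an observed-heterozygosity
#' floor `min_ho`, the matching count floor is `ceiling(min_ho * n_focal)`.
#'
#' @param n_focal Number of focal-sex individuals.
#' @param min_ho Observed-heterozygosity floor.
#' @return Integer count floor.
#' @examples
#' derive_min_het(24, 0.75) # 18
#' @export
derive_min_het <- function(n_focal, min_ho = 0.75) {
  stopifnot(n_focal >= 1, min_ho > 0, min_ho <= 1)
  as.integer(ceiling(min_ho * n_focal))
}

#' Observed heterozygosity of one site within a sample subset
#'
#' Heterozygote count over called genotypes; missing calls leave the
#' denominator.
#'
#' @param gt Integer genotype codes (0/1/2, `NA` missing) for one site.
#' @param subset Optional logical/integer index of samples to use.
#' @return Proportion in `[0, 1]`, or `NA` if nothing is called.
#' @export
observed_heterozygosity <- function(gt, subset = NULL) {
  if (!is.null(subset)) gt <- gt[subset]
  called <- sum(!is.na(gt))
  if (called == 0) return(NA_real_)
  sum(gt == 1L, na.rm = TRUE) / called
}

#' Detect sex-specific SNPs by the heterozygosity-contrast rule
#'
#' Scans a filtered genotype table for sites heterozygous in one sex and
#' uniformly homozygous for a single allele in the other -- the expected
#' signature of a fully sex-linked site in the heterogametic sex. Both-sex
#' hits are impossible by construction (a focal sex needs heterozygotes, the
#' other sex none).
#'
#' @param table A filtered `genotype_table`.
#' @param sexframe Sample sheet aligned with `table$samples`.
#' @param rule A [sex_specific_rule()].
#' @return Data frame of hits: `chrom`, `pos`, `focal_sex`,
#'   `het_count_focal`, `called_focal`, `ho_focal`, `other_sex_allele`
#'   (`"ref"` or `"alt"`), and per-sex mean/sd depth at the site.
#' @export
detect_sex_specific <- function(table, sexframe, rule = sex_specific_rule()) {
  stopifnot(identical(sexframe$sample_id, table$samples))
  is_f <- sexframe$sex == "F"
  res <- list()
  for (focal in c("F", "M")) {
    foc <- if (focal == "F") is_f else !is_f
    gtf <- table$gt[, foc, drop = FALSE]
    gto <- table$gt[, !foc, drop = FALSE]
    het_f <- rowSums(gtf == 1L, na.rm = TRUE)
    called_f <- rowSums(!is.na(gtf))
    ho <- ifelse(called_f > 0, het_f / called_f, NA_real_)
    het_o <- rowSums(gto == 1L, na.rm = TRUE)
    n_homref_o <- rowSums(gto == 0L, na.rm = TRUE)
    n_homalt_o <- rowSums(gto == 2L, na.rm = TRUE)
    called_o <- rowSums(!is.na(gto))
    min_het <- if (is.null(rule$min_het_count))
      derive_min_het(sum(foc), rule$min_ho) else rule$min_het_count
    one_allele <- (n_homref_o == called_o | n_homalt_o == called_o) &
      called_o > 0
    hit <- het_f >= min_het & !is.na(ho) & ho >= rule$min_ho &
      het_o <= rule$max_other_het & one_allele
    if (!any(hit)) next
    idx <- which(hit)
    mdep <- .site_depth_by_sex(table, is_f, idx)
    res[[focal]] <- data.frame(
      chrom = table$sites$chrom[idx], pos = table$sites$pos[idx],
      focal_sex = focal, het_count_focal = het_f[idx],
      called_focal = called_f[idx], ho_focal = ho[idx],
      other_sex_allele = ifelse(n_homref_o[idx] > 0, "ref", "alt"),
      mean_depth_f = mdep$mean_f, sd_depth_f = mdep$sd_f,
      mean_depth_m = mdep$mean_m, sd_depth_m = mdep$sd_m,
      stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(chrom = character(), pos = integer(), focal_sex = character(),
               het_count_focal = integer(), called_focal = integer(),
               ho_focal = numeric(), other_sex_allele = character(),
               mean_depth_f = numeric(), sd_depth_f = numeric(),
               mean_depth_m = numeric(), sd_depth_m = numeric(),
               stringsAsFactors = FALSE)
  out <- out[order(match(out$chrom, unique(table$sites$chrom)), out$pos), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

.site_depth_by_sex <- function(table, is_f, idx) {
  dpf <- table$dp[idx, is_f, drop = FALSE]
  dpm <- table$dp[idx, !is_f, drop = FALSE]
  list(mean_f = rowMeans(dpf, na.rm = TRUE),
       sd_f = apply(dpf, 1, sd, na.rm = TRUE),
       mean_m = rowMeans(dpm, na.rm = TRUE),
       sd_m = apply(dpm, 1, sd, na.rm = TRUE))
}

#' Classify the sex-determination system from sex-specific SNPs
#'
#' Excess heterozygosity in one sex alone cannot separate a ZW from an XY
#' interpretation (all-female heterozygosity could reflect an XY system
#' viewed from segregating variation, or a ZW system); a definitive label
#' additionally requires coverage corroboration -- either comparable depth
#' between sexes at the hit sites (the hits sit on the shared gametolog) or
#' a co-located sex-limited hemizygous region.
#'
#' @param hits Data frame from [detect_sex_specific()].
#' @param coverage_regions Optional list of `genomic_region` objects of kind
#'   `sex_specific_haploid` (from [call_regions()]), used as corroborating
#'   evidence.
#' @param depth_flag Optional logical: `TRUE` when the hit-site depth
#'   comparison found a significant deficit in one sex (from
#'   [hit_depth_summary()]'s `depth_comparable == FALSE`).
#' @param minority_max Fraction of discordant focal sexes above which the
#'   call is `ambiguous`.
#' @return List with `system` (`"ZW"`, `"XY"` or `"ambiguous"`),
#'   `confidence` (`"corroborated"` or `"provisional"`) and `rationale`.
#' @export
classify_system <- function(hits, coverage_regions = NULL, depth_flag = NULL,
                            minority_max = 0.10) {
  if (is.null(hits) || nrow(hits) == 0)
    return(list(system = "ambiguous", confidence = "none",
                rationale = "no sex-specific SNPs"))
  tab <- table(factor(hits$focal_sex, levels = c("F", "M")))
  maj <- names(which.max(tab))
  minority <- min(tab) / sum(tab)
  if (minority > minority_max)
    return(list(system = "ambiguous", confidence = "none",
                rationale = sprintf("focal sexes conflict (%d F vs %d M)",
                                    tab[["F"]], tab[["M"]])))
  sys <- if (maj == "F") "ZW" else "XY"
  hap_sex <- vapply(coverage_regions %||% list(), function(r) r$sex, character(1))
  cochrom <- vapply(coverage_regions %||% list(), function(r) r$chrom, character(1))
  colocated <- any(hap_sex == maj & cochrom %in% unique(hits$chrom))
  contradicts <- length(hap_sex) > 0 && any(hap_sex == setdiff(c("F", "M"), maj))
  if (contradicts)
    return(list(system = "ambiguous", confidence = "none",
                rationale = "hemizygous region in the opposite sex contradicts the SNP signal"))
  depth_ok <- is.null(depth_flag) || !depth_flag
  if (colocated || (depth_ok && !is.null(depth_flag)))
    list(system = sys, confidence = "corroborated",
         rationale = paste0(if (colocated)
           sprintf("%s-limited hemizygous region co-locates with the hits; ", maj)
           else "",
           if (depth_ok && !is.null(depth_flag))
             "no depth deficit at hit sites" else ""))
  else
    list(system = sys, confidence = "provisional",
         rationale = "heterozygosity contrast only; no coverage corroboration")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Depth of sex-specific SNPs per individual and per sex
#'
#' Looks each hit up in the depth matrix (falling back to the VCF DP field
#' when a position is absent), summarises mean/sd depth per sex, and runs
#' Welch's t-test per hit. When no hit shows `p < 0.05` the summary carries
#' `depth_comparable = TRUE`: the hits sit on sequence present in both
#' sexes.
#'
#' @param hits Data frame from [detect_sex_specific()].
#' @param depth A `depth_matrix` (or `NULL` to use the VCF DP already in the
#'   hit table).
#' @param sexframe Sample sheet.
#' @return List with `per_hit` (means, sds, Welch p per hit), `pooled`
#'   (per-sex mean and sd over all hit-by-individual depths) and
#'   `depth_comparable`.
#' @export
hit_depth_summary <- function(hits, depth, sexframe) {
  is_f <- sexframe$sex == "F"
  n <- nrow(hits)
  mean_f <- sd_f <- mean_m <- sd_m <- p <- rep(NA_real_, n)
  pool_f <- list(); pool_m <- list()
  for (i in seq_len(n)) {
    row <- NULL
    if (!is.null(depth)) {
      j <- which(depth$positions$chrom == hits$chrom[i] &
                   depth$positions$pos == hits$pos[i])
      if (length(j)) row <- depth$depth[j[1], ]
    }
    if (is.null(row)) { # no depth at this position: flagged, not dropped
      mean_f[i] <- hits$mean_depth_f[i]; sd_f[i] <- hits$sd_depth_f[i]
      mean_m[i] <- hits$mean_depth_m[i]; sd_m[i] <- hits$sd_depth_m[i]
      next
    }
    df <- row[is_f]; dm <- row[!is_f]
    pool_f[[length(pool_f) + 1]] <- df; pool_m[[length(pool_m) + 1]] <- dm
    mean_f[i] <- mean(df); sd_f[i] <- sd(df)
    mean_m[i] <- mean(dm); sd_m[i] <- sd(dm)
    p[i] <- welch_t(df, dm)$p
  }
  per_hit <- data.frame(chrom = hits$chrom, pos = hits$pos,
                        mean_depth_f = mean_f, sd_depth_f = sd_f,
                        mean_depth_m = mean_m, sd_depth_m = sd_m,
                        welch_p = p, stringsAsFactors = FALSE)
  all_f <- as.numeric(unlist(pool_f)); all_m <- as.numeric(unlist(pool_m))
  pooled <- data.frame(sex = c("F", "M"),
                       mean_depth = c(mean(all_f), mean(all_m)),
                       sd_depth = c(sd(all_f), sd(all_m)))
  list(per_hit = per_hit, pooled = pooled,
       depth_comparable = all(is.na(p) | p >= 0.05))
}

#' Pairwise LD (r-squared) among sites
#'
#' Squared Pearson correlation of genotype dosage (0/1/2) across samples
#' called at both sites -- the genotype-r2 convention for unphased data.
#' Pairs sharing fewer than 4 called samples, or with zero dosage variance,
#' are undefined.
#'
#' @param table A `genotype_table` restricted to the sites of interest.
#' @param min_shared Minimum shared called samples per pair.
#' @return List with `r2` (symmetric matrix, `NA` diagonal-off undefined
#'   pairs, 1 on the diagonal) and `mean_r2` (mean of defined off-diagonal
#'   values).
#' @export
ld_r2 <- function(table, min_shared = 4L) {
  n <- nrow(table$sites)
  if (n < 2) stop("need at least 2 sites")
  g <- t(table$gt) # samples x sites
  r2 <- matrix(NA_real_, n, n)
  diag(r2) <- 1
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(g[, i]) & !is.na(g[, j])
      if (sum(ok) < min_shared) next
      if (sd(g[ok, i]) == 0 || sd(g[ok, j]) == 0) next
      r2[i, j] <- r2[j, i] <- cor(g[ok, i], g[ok, j])^2
    }
  }
  off <- r2[upper.tri(r2)]
  if (all(is.na(off))) warning("all site pairs undefined")
  list(r2 = r2, mean_r2 = mean(off, na.rm = TRUE))
}
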