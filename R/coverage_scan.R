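#' Welch's unequal-variance t-test
#'
#' Two-sided Welch t-test with Satterthwaite degrees of freedom, with
#' explicit handling of the degenerate constant-depth cases that arise in
#' coverage data: both groups constant and equal gives `p = 1`; both
#' constant but different gives `p = 0` flagged `degenerate`.
#'
#' @param a,b Numeric vectors (e.g. per-individual depths of the two sexes).
#' @return List with `t`, `df`, `p` and `degenerate`.
#' @export
welch_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop("need >= 2 values per group")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = NA_real_, p = 1,
                                        degenerate = FALSE))
    return(list(t = Inf, df = NA_real_, p = 0, degenerate = TRUE))
  }
  se2 <- va / length(a) + vb / length(b)
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / (va^2 / (length(a)^2 * (length(a) - 1)) +
                   vb^2 / (length(b)^2 * (length(b) - 1)))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), degenerate = FALSE)
}

#' Configuration for the coverage scan
#'
#' Thresholds for calling sex-limited hemizygous candidates: a position is a
#' candidate for (say) a female-limited region when the between-sex Welch
#' p-value falls below `welch_p_max`, the female depth ratio to each
#' individual's own genome-wide mean averages inside `half_depth_band`
#' (hemizygous = one copy instead of two), and mean male depth is at most
#' `absent_depth_max` (distinguishing true absence from a shared CNV).
#'
#' @param welch_p_max Significance threshold (default 1e-4).
#' @param half_depth_band Fraction-of-own-mean band for "approximately half
#'   depth" (default `c(0.35, 0.65)`), robust to between-individual depth
#'   variation.
#' @param absent_depth_max Maximum mean depth (X) in the sex lacking the
#'   region (default 2).
#' @param merge_gap Maximum gap (bp) between candidates merged into one
#'   region.
#' @param min_region_len Minimum reported region length (bp).
#' @return An object of class `coverage_config`.
#' @export
coverage_config <- function(welch_p_max = 1e-4,
                            half_depth_band = c(0.35, 0.65),
                            absent_depth_max = 2,
                            merge_gap = 200L, min_region_len = 1000L) {
  stopifnot(welch_p_max > 0, welch_p_max < 1,
            length(half_depth_band) == 2,
            half_depth_band[1] > 0, half_depth_band[2] < 1,
            half_depth_band[1] < half_depth_band[2],
            absent_depth_max >= 0, merge_gap >= 0, min_region_len >= 1)
  structure(list(welch_p_max = welch_p_max, half_depth_band = half_depth_band,
                 absent_depth_max = absent_depth_max,
                 merge_gap = as.integer(merge_gap),
                 min_region_len = as.integer(min_region_len)),
            class = "coverage_config")
}

#' Read a depth matrix from TSV
#'
#' Expects columns `chrom`, `pos`, then one numeric column per sample.
#'
#' @param path TSV path.
#' @return A `depth_matrix`.
#' @export
read_depth_matrix <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos") %in% names(d)))
    stop("depth TSV needs chrom and pos columns")
  samples <- setdiff(names(d), c("chrom", "pos"))
  structure(list(positions = d[, c("chrom", "pos")],
                 depth = as.matrix(d[, samples, drop = FALSE]),
                 samples = samples), class = "depth_matrix")
}

#' Scan per-position depth for sex-limited candidates
#'
#' Compares per-individual depth between sexes at every position and flags
#' hemizygous candidates per [coverage_config()]. Both sexes are scanned;
#' a candidate is tagged with the sex that carries the sequence.
#'
#' @param depth A `depth_matrix`.
#' @param sexframe Sample sheet; `genome_mean_depth` is used for the
#'   half-depth ratio (computed from the matrix itself when absent).
#' @param cfg A [coverage_config()].
#' @return Data frame: `chrom`, `pos`, `mean_f`, `mean_m`, `ratio_f`,
#'   `ratio_m` (mean depth ratio to own genome mean), `p`, `candidate`,
#'   `candidate_sex`.
#' @export
scan_depth <- function(depth, sexframe, cfg = coverage_config()) {
  stopifnot(identical(sexframe$sample_id, depth$samples))
  gm <- sexframe$genome_mean_depth
  if (is.null(gm) || all(is.na(gm))) gm <- colMeans(depth$depth)
  is_f <- sexframe$sex == "F"
  D <- depth$depth
  nf <- sum(is_f); nm <- sum(!is_f)
  mean_f <- rowMeans(D[, is_f, drop = FALSE])
  mean_m <- rowMeans(D[, !is_f, drop = FALSE])
  ratio <- sweep(D, 2, gm, "/")
  ratio_f <- rowMeans(ratio[, is_f, drop = FALSE])
  ratio_m <- rowMeans(ratio[, !is_f, drop = FALSE])
  # vectorised Welch test across rows
  vf <- apply(D[, is_f, drop = FALSE], 1, stats::var)
  vm <- apply(D[, !is_f, drop = FALSE], 1, stats::var)
  se2 <- vf / nf + vm / nm
  t <- (mean_f - mean_m) / sqrt(se2)
  df <- se2^2 / (vf^2 / (nf^2 * (nf - 1)) + vm^2 / (nm^2 * (nm - 1)))
  p <- 2 * stats::pt(-abs(t), df)
  p[se2 == 0 & mean_f == mean_m] <- 1
  p[se2 == 0 & mean_f != mean_m] <- 0
  band <- cfg$half_depth_band
  cand_f <- !is.na(p) & p < cfg$welch_p_max &
    ratio_f >= band[1] & ratio_f <= band[2] & mean_m <= cfg$absent_depth_max
  cand_m <- !is.na(p) & p < cfg$welch_p_max &
    ratio_m >= band[1] & ratio_m <= band[2] & mean_f <= cfg$absent_depth_max
  data.frame(chrom = depth$positions$chrom, pos = depth$positions$pos,
             mean_f = mean_f, mean_m = mean_m,
             ratio_f = ratio_f, ratio_m = ratio_m, p = p,
             candidate = cand_f | cand_m,
             candidate_sex = ifelse(cand_f, "F", ifelse(cand_m, "M", NA)),
             stringsAsFactors = FALSE)
}

#' Merge candidate positions into hemizygous regions
#'
#' Maximal runs of candidate positions (per chromosome and per carrying
#' sex) with inter-candidate gaps at most `merge_gap` become regions;
#' regions shorter than `min_region_len` are dropped.
#'
#' @param candidates Output of [scan_depth()].
#' @param cfg A [coverage_config()].
#' @return List of `genomic_region` objects of kind `sex_specific_haploid`,
#'   sorted and disjoint.
#' @export
call_regions <- function(candidates, cfg = coverage_config()) {
  cand <- candidates[candidates$candidate, , drop = FALSE]
  out <- list()
  for (sx in unique(cand$candidate_sex)) {
    for (cn in unique(cand$chrom[cand$candidate_sex == sx])) {
      pos <- cand$pos[cand$candidate_sex == sx & cand$chrom == cn]
      runs <- .merge_positions(pos, cfg$merge_gap)
      runs <- runs[runs$end - runs$start + 1 >= cfg$min_region_len, ,
                   drop = FALSE]
      for (k in seq_len(nrow(runs)))
        out[[length(out) + 1]] <- genomic_region(
          cn, runs$start[k], runs$end[k], "sex_specific_haploid", sex = sx,
          provenance = list(n_candidates = sum(pos >= runs$start[k] &
                                                 pos <= runs$end[k])))
    }
  }
  ord <- order(vapply(out, function(r) r$chrom, character(1)),
               vapply(out, function(r) r$start, integer(1)))
  out[ord]
}
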