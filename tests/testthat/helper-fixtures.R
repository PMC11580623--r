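# shared in-code fixtures; nothing is read from disk

# small, fast cohort for unit tests
small_config <- function(seed = 1, ...) {
  cohort_config(chrom_lengths = c(chr1 = 200000L, chr2 = 300000L),
                n_autosomal_snps = 1000, seed = seed, ...)
}

# memoised default-condition cohorts (shared by detector/coverage tests)
.cohorts <- new.env(parent = emptyenv())
cached_cohort <- function(seed) {
  key <- as.character(seed)
  if (is.null(.cohorts[[key]]))
    .cohorts[[key]] <- simulate_cohort(cohort_config(
      seed = seed, n_sexlinked_snps = 20))
  .cohorts[[key]]
}

# hand-built genotype table: gt is a sites x samples matrix of 0/1/2/NA
make_gt <- function(gt, dp = 30, gq = 99, qual = 100,
                    chrom = "chr1", pos = NULL,
                    ref = "A", alt = "G", n_f = NULL) {
  gt <- as.matrix(gt)
  n_sites <- nrow(gt); n <- ncol(gt)
  if (is.null(n_f)) n_f <- ceiling(n / 2)
  if (is.null(pos)) pos <- seq_len(n_sites) * 100L
  expand <- function(x) if (length(x) == 1) matrix(x, n_sites, n) else as.matrix(x)
  structure(list(
    sites = data.frame(chrom = rep(chrom, length.out = n_sites),
                       pos = pos, ref = rep(ref, length.out = n_sites),
                       alt = rep(alt, length.out = n_sites),
                       qual = rep(qual, length.out = n_sites),
                       stringsAsFactors = FALSE),
    gt = gt, dp = expand(dp), gq = expand(gq),
    samples = c(sprintf("F%02d", seq_len(n_f)),
                sprintf("M%02d", seq_len(n - n_f)))),
    class = "genotype_table")
}

make_sexframe <- function(n_f, n_m, mean_depth = 30) {
  data.frame(sample_id = c(sprintf("F%02d", seq_len(n_f)),
                           sprintf("M%02d", seq_len(n_m))),
             sex = c(rep("F", n_f), rep("M", n_m)),
             genome_mean_depth = mean_depth, stringsAsFactors = FALSE)
}

# sexframe matching make_gt column order (F first half, M second half)
sexframe_for <- function(table, n_f = NULL) {
  sex <- substr(table$samples, 1, 1)
  data.frame(sample_id = table$samples, sex = sex,
             genome_mean_depth = 30, stringsAsFactors = FALSE)
}

key_of <- function(d) paste(d$chrom, d$pos)
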