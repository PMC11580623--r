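test_that("VCF round trip preserves genotype codes, phasing ignored", {
  d <- withr::local_tempdir()
  gt <- rbind(c(0L, 1L, 2L, NA), c(1L, 1L, 0L, 0L))
  tab <- make_gt(gt, dp = 30, gq = 90)
  vcf <- file.path(d, "x.vcf")
  write_vcf(tab, vcf)
  # inject a phased genotype to check | handling
  lines <- readLines(vcf)
  lines <- sub("0/1:30:90", "0|1:30:90", lines, fixed = TRUE)
  writeLines(lines, vcf)
  sexfile <- file.path(d, "sex.tsv")
  write.table(sexframe_for(tab), sexfile, sep = "\t", quote = FALSE,
              row.names = FALSE)
  lg <- load_genotypes(vcf, sexfile)
  expect_equal(lg$genotypes$gt, gt, ignore_attr = TRUE)
  expect_equal(lg$genotypes$sites$pos, tab$sites$pos)
  expect_equal(lg$sexframe$sex, c("F", "F", "M", "M"))
})

test_that("samples missing from the sex table are reported by name", {
  d <- withr::local_tempdir()
  tab <- make_gt(rbind(c(0L, 1L, 2L, 0L)))
  vcf <- file.path(d, "x.vcf"); write_vcf(tab, vcf)
  sf <- sexframe_for(tab)[1:3, ]
  sexfile <- file.path(d, "sex.tsv")
  write.table(sf, sexfile, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_genotypes(vcf, sexfile), "M02")
})

test_that("multi-allelic and indel records are dropped on load", {
  d <- withr::local_tempdir()
  tab <- make_gt(rbind(c(0L, 1L, 1L, 0L), c(0L, 0L, 1L, 1L)))
  vcf <- file.path(d, "x.vcf"); write_vcf(tab, vcf)
  lines <- readLines(vcf)
  body <- grep("^chr", lines)
  lines[body[1]] <- sub("\tG\t", "\tG,T\t", lines[body[1]])
  writeLines(lines, vcf)
  sexfile <- file.path(d, "sex.tsv")
  write.table(sexframe_for(tab), sexfile, sep = "\t", quote = FALSE,
              row.names = FALSE)
  lg <- load_genotypes(vcf, sexfile)
  expect_equal(nrow(lg$genotypes$sites), 1)
  expect_equal(lg$genotypes$sites$pos, tab$sites$pos[2])
})

test_that("call masking applies GQ and DP thresholds inclusively", {
  gt <- matrix(1L, 1, 4)
  tab <- make_gt(gt,
                 dp = matrix(c(30, 7, 6, 30), 1),
                 gq = matrix(c(19, 20, 99, NA), 1))
  m <- mask_low_quality_calls(tab, filter_config())
  expect_equal(as.vector(m$gt), c(NA, 1L, NA, NA))
  expect_equal(attr(m, "n_masked"), 3)
  # already-missing calls stay missing and are not recounted
  m2 <- mask_low_quality_calls(m, filter_config())
  expect_equal(attr(m2, "n_masked"), 0)
})

test_that("site filter enforces quality, call rate, per-sex counts and MAF", {
  n_f <- 24; n_m <- 20; n <- n_f + n_m
  # site 1: clean common SNP      -> retained
  # site 2: QUAL 29               -> dropped (site quality)
  # site 3: 39/44 called (88.6%)  -> dropped (call rate)
  # site 4: global MAF 0.023      -> dropped (MAF, no rescue)
  g1 <- c(rep(1L, 10), rep(0L, n - 10))
  g2 <- g1
  g3 <- c(rep(NA, 5), rep(1L, 6), rep(0L, n - 11))
  g4 <- c(rep(1L, 2), rep(0L, n - 2))
  tab <- make_gt(rbind(g1, g2, g3, g4),
                 qual = c(100, 29, 100, 100), n_f = n_f)
  sf <- make_sexframe(n_f, n_m)
  stopifnot(identical(sf$sample_id, tab$samples))
  out <- filter_sites(tab, sf, filter_config())
  expect_equal(out$sites$pos, tab$sites$pos[1])
  expect_equal(as.vector(attr(out, "drop_counts")), c(1, 1, 0, 1))
  # with 24 F + 20 M at call rate 0.90 the per-sex >= 12 clause can never
  # bind (<= 4 missing calls leaves both sexes above 12); it bites once the
  # overall criterion is relaxed: 11 called females fail it
  g5 <- c(rep(NA, 13), rep(1L, n_f - 13), rep(0L, n_m))
  tab5 <- make_gt(rbind(g5), n_f = n_f)
  cfg_lax <- filter_config(min_callrate = 0.5)
  expect_warning(out5 <- filter_sites(tab5, sf, cfg_lax), "no sites")
  expect_equal(as.vector(attr(out5, "drop_counts")), c(0, 0, 1, 0))
})

test_that("local-MAF rescue retains a sex-skewed rare site", {
  # with near-balanced sexes the global MAF is always >= half the local MAF,
  # so the rescue needs unbalanced called counts: 4 F vs 40 M
  n_f <- 4; n_m <- 40; n <- n_f + n_m
  g <- c(rep(1L, 2), rep(0L, n - 2)) # 2 het females: MAF_F 0.25, global 0.023
  tab <- make_gt(rbind(g), n_f = n_f)
  sf <- make_sexframe(n_f, n_m)
  cfg <- filter_config(min_called_per_sex = 2)
  out <- filter_sites(tab, sf, cfg)
  expect_equal(nrow(out$sites), 1)
  # same table without the rescue criterion drops it
  cfg0 <- filter_config(min_called_per_sex = 2, rescue_local_maf = 1)
  expect_warning(out0 <- filter_sites(tab, sf, cfg0), "no sites")
  expect_equal(nrow(out0$sites), 0)
})

test_that("filtering is idempotent and preserves site order and genotypes", {
  co <- cached_cohort(101)
  cfg <- filter_config()
  m <- mask_low_quality_calls(co$genotypes, cfg)
  f1 <- filter_sites(m, co$sexframe, cfg)
  f2 <- filter_sites(f1, co$sexframe, cfg)
  expect_equal(f1$sites, f2$sites)
  expect_equal(f1$gt, f2$gt, ignore_attr = TRUE)
  expect_false(is.unsorted(f1$sites$pos[f1$sites$chrom == "chr1"]))
  # masking never rewrites a genotype to a different called value
  keep <- !is.na(m$gt)
  expect_true(all(m$gt[keep] == co$genotypes$gt[keep]))
})

test_that("a cohort planted without violations loses no site", {
  co <- simulate_cohort(small_config(seed = 31, genotype_error_rate = 0,
                                     missing_rate = 0,
                                     maf_dist = c(0.2, 0.5)))
  m <- mask_low_quality_calls(co$genotypes, filter_config())
  f <- filter_sites(m, co$sexframe, filter_config())
  # DP draws can still dip below 7 for low-coverage individuals; allow only
  # call-rate casualties of that stochastic masking, no MAF/quality drops
  dc <- attr(f, "drop_counts")
  expect_equal(dc[["site_quality"]], 0)
  expect_equal(dc[["maf"]], 0)
  expect_gt(nrow(f$sites) / nrow(co$genotypes$sites), 0.97)
})
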