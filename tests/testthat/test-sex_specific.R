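test_that("observed heterozygosity excludes missing calls from the denominator", {
  expect_equal(observed_heterozygosity(rep(1L, 24)), 1.0)
  expect_equal(observed_heterozygosity(c(rep(1L, 18), rep(0L, 6))), 0.75)
  expect_equal(observed_heterozygosity(c(rep(1L, 23), NA)), 1.0)
  expect_true(is.na(observed_heterozygosity(c(NA_integer_, NA_integer_))))
  expect_equal(observed_heterozygosity(c(1L, 1L, 0L, 2L, NA), subset = 1:3),
               2 / 3)
})

test_that("the heterozygote-count floor scales with cohort size", {
  expect_equal(derive_min_het(24, 0.75), 18L)
  expect_equal(derive_min_het(20, 0.75), 15L)
  expect_equal(derive_min_het(30, 0.9), 27L)
})

test_that("detector enforces the full contrast rule", {
  n_f <- 24; n_m <- 20
  sf <- make_sexframe(n_f, n_m)
  mk <- function(...) make_gt(rbind(...), n_f = n_f)
  fem_het <- rep(1L, n_f)
  # clean fully sex-linked site -> reported for females
  t1 <- mk(c(fem_het, rep(0L, n_m)))
  h1 <- detect_sex_specific(t1, sf)
  expect_equal(nrow(h1), 1)
  expect_equal(h1$focal_sex, "F")
  expect_equal(h1$ho_focal, 1)
  expect_equal(h1$other_sex_allele, "ref")
  # a single male heterozygote kills the site
  t2 <- mk(c(fem_het, 1L, rep(0L, n_m - 1)))
  expect_equal(nrow(detect_sex_specific(t2, sf)), 0)
  # males split between the two homozygotes: not one fixed allele
  t3 <- mk(c(fem_het, rep(0L, n_m - 5), rep(2L, 5)))
  expect_equal(nrow(detect_sex_specific(t3, sf)), 0)
  # 17 female hets: below the count floor
  t4 <- mk(c(rep(1L, 17), rep(0L, n_f - 17), rep(0L, n_m)))
  expect_equal(nrow(detect_sex_specific(t4, sf)), 0)
  # 18 of 24 called (Ho = 0.75 exactly, inclusive)
  t5 <- mk(c(rep(1L, 18), rep(0L, 6), rep(0L, n_m)))
  expect_equal(nrow(detect_sex_specific(t5, sf)), 1)
  # missing other-sex calls are tolerated (called ones all one homozygote)
  t6 <- mk(c(fem_het, rep(NA, 3), rep(2L, n_m - 3)))
  h6 <- detect_sex_specific(t6, sf)
  expect_equal(nrow(h6), 1)
  expect_equal(h6$other_sex_allele, "alt")
  # male-focal symmetry (XY-like signal) with a lower count floor
  t7 <- mk(c(rep(0L, n_f), rep(1L, n_m)))
  h7 <- detect_sex_specific(t7, sf, sex_specific_rule(min_het_count = NULL))
  expect_equal(h7$focal_sex, "M")
  expect_equal(h7$het_count_focal, 20)
})

test_that("detector output is invariant to sample and site order", {
  co <- cached_cohort(101)
  f <- filter_sites(mask_low_quality_calls(co$genotypes), co$sexframe)
  h0 <- detect_sex_specific(f, co$sexframe)
  set.seed(1)
  sp <- sample(length(f$samples))
  fp <- f
  fp$gt <- f$gt[, sp]; fp$dp <- f$dp[, sp]; fp$gq <- f$gq[, sp]
  fp$samples <- f$samples[sp]
  sfp <- co$sexframe[sp, ]
  h1 <- detect_sex_specific(fp, sfp)
  expect_equal(h1, h0)
  ss <- sample(nrow(f$sites))
  fs <- subset_sites(f, ss)
  h2 <- detect_sex_specific(fs, co$sexframe)
  expect_equal(h2[order(h2$chrom, h2$pos), ]$pos, h0$pos)
})

test_that("system classification needs coverage corroboration for certainty", {
  hits_f <- data.frame(chrom = "chr2", pos = 1:20 * 1000, focal_sex = "F")
  region_f <- genomic_region("chr2", 30000, 51000, "sex_specific_haploid",
                             sex = "F")
  r1 <- classify_system(hits_f, coverage_regions = list(region_f))
  expect_equal(r1$system, "ZW")
  expect_equal(r1$confidence, "corroborated")
  # comparable depth at hit sites corroborates too
  r2 <- classify_system(hits_f, depth_flag = FALSE)
  expect_equal(r2$system, "ZW")
  expect_equal(r2$confidence, "corroborated")
  # male-focal hits without coverage: provisional XY
  hits_m <- data.frame(chrom = "chr2", pos = 1:20 * 1000, focal_sex = "M")
  r3 <- classify_system(hits_m)
  expect_equal(r3$system, "XY")
  expect_equal(r3$confidence, "provisional")
  # conflicting focal sexes -> ambiguous
  hits_mix <- data.frame(chrom = "chr2", pos = 1:20 * 1000,
                         focal_sex = rep(c("F", "M"), 10))
  expect_equal(classify_system(hits_mix)$system, "ambiguous")
  # opposite-sex hemizygous region contradicts the SNP signal
  region_m <- genomic_region("chr2", 30000, 51000, "sex_specific_haploid",
                             sex = "M")
  expect_equal(classify_system(hits_f, list(region_m))$system, "ambiguous")
  expect_equal(classify_system(hits_f[0, ])$system, "ambiguous")
})

test_that("hit depths are comparable between sexes at segregating sex-linked sites", {
  co <- cached_cohort(101)
  f <- filter_sites(mask_low_quality_calls(co$genotypes), co$sexframe)
  hits <- detect_sex_specific(f, co$sexframe)
  hd <- hit_depth_summary(hits, co$depth, co$sexframe)
  mf <- hd$pooled$mean_depth[1]; mm <- hd$pooled$mean_depth[2]
  sdp <- max(hd$pooled$sd_depth)
  expect_lt(abs(mf - mm), 2 * sdp)
  # constant depth matrix: identical means, p = 1 everywhere
  const <- co$depth
  const$depth[] <- 30
  hdc <- hit_depth_summary(hits, const, co$sexframe)
  expect_true(all(hdc$per_hit$welch_p == 1, na.rm = TRUE))
  expect_true(hdc$depth_comparable)
})

test_that("LD r2 is dosage correlation squared with undefined degenerate pairs", {
  g <- rbind(c(1L, 1L, 1L, 0L, 0L, 2L),
             c(1L, 1L, 1L, 0L, 0L, 2L),  # identical -> r2 = 1
             c(0L, 0L, 0L, 0L, 0L, 0L))  # constant -> undefined
  tab <- make_gt(g)
  r <- ld_r2(tab)
  expect_equal(r$r2[1, 2], 1)
  expect_true(is.na(r$r2[1, 3]))
  expect_equal(r$r2, t(r$r2))
  # two planted fully sex-linked sites are in perfect LD
  co <- simulate_cohort(small_config(seed = 41, genotype_error_rate = 0,
                                     missing_rate = 0))
  planted <- match(key_of(co$truth$planted_snps), key_of(co$genotypes$sites))
  r2 <- ld_r2(subset_sites(co$genotypes, planted[1:2]))
  expect_equal(r2$r2[1, 2], 1)
  # pairs sharing < 4 called samples are undefined
  g2 <- rbind(c(1L, 0L, 2L, NA, NA, NA),
              c(NA, NA, 2L, 1L, 0L, 1L))
  expect_warning(r3 <- ld_r2(make_gt(g2)), "undefined")
  expect_true(is.na(r3$r2[1, 2]))
})
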