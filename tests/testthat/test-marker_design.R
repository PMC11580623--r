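rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

test_that("paralog scan finds exact and gapped duplicates, ignores noise", {
  set.seed(60)
  q <- rand_seq(600)
  genome <- c(chrA = paste0(rand_seq(2000), q, rand_seq(1500), q,
                            rand_seq(1000)),
              chrB = rand_seq(3000))
  hits <- paralog_scan(q, genome,
                       query_locus = list(chrom = "chrA", start = 2001))
  expect_equal(nrow(hits), 1) # the self-hit at 2001 is excluded
  expect_equal(hits$identity, 100)
  expect_equal(hits$total_gap_bp, 0)
  expect_equal(hits$start, 2001 + 600 + 1500)
  expect_equal(hits$end, hits$start + 599)
  # no hits in an unrelated genome
  expect_equal(nrow(paralog_scan(q, c(chrB = rand_seq(5000)))), 0)
})

test_that("gapped paralog reports gap count and summed gap length", {
  set.seed(61)
  q <- rand_seq(590)
  gapped <- paste0(substr(q, 1, 100), rand_seq(40),
                   substr(q, 101, 250), rand_seq(30),
                   substr(q, 251, 400), rand_seq(27),
                   substr(q, 401, 590))
  genome <- c(chrA = paste0(rand_seq(1000), gapped, rand_seq(1000)))
  hits <- paralog_scan(q, genome)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$n_gaps, 3)
  expect_equal(hits$total_gap_bp, 97)
  expect_equal(hits$end - hits$start + 1, 687)
  expect_gt(hits$identity, 80)
  # reverse-strand copies are found too
  genome_rc <- c(chrA = paste0(rand_seq(1000),
                               sdrscan:::.revcomp(q), rand_seq(1000)))
  h2 <- paralog_scan(q, genome_rc)
  expect_equal(h2$strand, "-")
  expect_equal(h2$identity, 100)
})

test_that("alignment scores match the full dynamic-programming oracle", {
  set.seed(62)
  for (i in 1:5) {
    q <- rand_seq(300)
    s <- paste0(substr(q, 1, 150), rand_seq(20), substr(q, 151, 300))
    # mutate a few bases
    s <- strsplit(s, "")[[1]]
    mut <- sample(length(s), 10)
    s[mut] <- sample(c("A", "C", "G", "T"), 10, TRUE)
    s <- paste(s, collapse = "")
    mine <- sdrscan:::.sw_affine(q, s)
    oracle <- Biostrings::pairwiseAlignment(
      q, s, type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -2, baseOnly = TRUE),
      gapOpening = 5, gapExtension = 2)
    expect_equal(mine$score, Biostrings::score(oracle), tolerance = 1e-9)
  }
})

test_that("scan is symmetric between the two copies of a pair", {
  set.seed(63)
  q <- rand_seq(590)
  gapped <- paste0(substr(q, 1, 200), rand_seq(97), substr(q, 201, 590))
  genome <- c(chrA = paste0(rand_seq(1000), q, rand_seq(800), gapped,
                            rand_seq(1000)))
  h1 <- paralog_scan(q, genome, query_locus = list(chrom = "chrA",
                                                   start = 1001))
  h2 <- paralog_scan(gapped, genome,
                     query_locus = list(chrom = "chrA", start = 2391))
  expect_equal(h2$start, 1001)
  expect_equal(h1$start, 2391)
  expect_lt(abs(h1$identity - h2$identity), 0.5)
})

test_that("marker selection requires one haploid copy and a resolvable difference", {
  hap <- list(genomic_region("chr2", 140000, 161325, "sex_specific_haploid",
                             sex = "F"))
  qloc <- list(chrom = "chr2", start = 141001, end = 141590)
  mk_hit <- function(gap, chrom = "chr2", start = 250001) {
    h <- data.frame(chrom = chrom, start = start, end = start + 589 + gap,
                    strand = "+", query_start = 1, query_end = 590,
                    identity = 86, n_gaps = (gap > 0) * 3,
                    total_gap_bp = gap, score = 400)
    attr(h, "alignments") <- list(list(
      qaligned = paste(rep("A", 590), collapse = ""),
      saligned = paste(rep("A", 590), collapse = ""), score = 400))
    h
  }
  sel <- select_marker_locus(mk_hit(97), qloc, hap)
  expect_equal(nrow(sel), 1)
  expect_true(nrow(sel$conserved_windows[[1]]) >= 1)
  # 5 bp difference: gel-unresolvable
  none <- select_marker_locus(mk_hit(5), qloc, hap)
  expect_equal(nrow(none), 0)
  expect_match(attr(none, "explanation"), "min_diff_bp")
  # both copies diploid (query outside the haploid region)
  qout <- list(chrom = "chr2", start = 200000, end = 200589)
  none2 <- select_marker_locus(mk_hit(97), qout, hap)
  expect_equal(nrow(none2), 0)
})

test_that("in-silico PCR reproduces the two-band geometry", {
  set.seed(64)
  fwd <- rand_seq(20)
  rev <- rand_seq(20)
  insert <- rand_seq(601) # 641 bp product: 20 (fwd) + 601 + 20 (rc rev)
  template_long <- paste0(rand_seq(100), fwd, insert,
                          sdrscan:::.revcomp(rev), rand_seq(100))
  # short template: same primers, 97 bp removed internally
  template_short <- paste0(rand_seq(50), fwd, substr(insert, 98, nchar(insert)),
                           sdrscan:::.revcomp(rev), rand_seq(50))
  genome <- c(dip = template_long, hap = template_short)
  amp <- in_silico_pcr(genome, list(forward = fwd, reverse = rev))
  expect_equal(nrow(amp), 2)
  expect_setequal(amp$length, c(641, 544))
  expect_equal(amp$start[amp$template == "dip"], 101)
  # primer sites in the same orientation (no convergent pair): nothing
  amp0 <- in_silico_pcr(c(x = paste0(rand_seq(100), fwd, rand_seq(200), rev,
                                     rand_seq(100))),
                        list(forward = fwd, reverse = rev))
  expect_equal(nrow(amp0), 0)
  # reversed layout (rc(rev) upstream of fwd): nothing either
  amp1 <- in_silico_pcr(c(x = paste0(rand_seq(100), sdrscan:::.revcomp(rev),
                                     rand_seq(200), fwd, rand_seq(100))),
                        list(forward = fwd, reverse = rev))
  expect_equal(nrow(amp1), 0)
})

test_that("band patterns follow per-sex copy number, with XY mirroring", {
  hapF <- list(genomic_region("hap", 1, 1000, "sex_specific_haploid",
                              sex = "F"))
  preds <- data.frame(template = c("dip", "hap"), start = c(101, 51),
                      end = c(741, 594), length = c(641, 544),
                      orientation = "+")
  bp <- band_pattern(preds, hapF)
  expect_true(bp$informative)
  f <- bp$bands[bp$bands$sex == "F", ]
  m <- bp$bands[bp$bands$sex == "M", ]
  expect_equal(f$length, c(641, 544))
  expect_equal(f$copy_number, c(2L, 1L))
  expect_equal(m$length, 641)
  expect_equal(m$copy_number, 2L)
  # female-unique band is 97 bp shorter than the shared band
  expect_equal(setdiff(f$length, m$length), 544)
  expect_equal(641 - 544, 97)
  # XY mirror: male-limited haploid region
  hapM <- list(genomic_region("hap", 1, 1000, "sex_specific_haploid",
                              sex = "M"))
  bpm <- band_pattern(preds, hapM)
  expect_equal(bpm$bands$length[bpm$bands$sex == "M"], c(641, 544))
  expect_equal(bpm$bands$length[bpm$bands$sex == "F"], 641)
  # no haploid amplicon: identical patterns, flagged uninformative
  bp0 <- band_pattern(preds[1, ], hapF)
  expect_false(bp0$informative)
})

test_that("simulated truth primers amplify the truth bands off the reference", {
  co <- cached_cohort(101)
  amp <- in_silico_pcr(co$reference, co$truth$primers)
  bp <- band_pattern(amp, list(co$truth$hemizygous_region))
  expect_setequal(bp$bands$length[bp$bands$sex == "F"],
                  co$truth$expected_bands$F)
  expect_setequal(bp$bands$length[bp$bands$sex == "M"],
                  co$truth$expected_bands$M)
  expect_equal(diff(sort(unique(amp$length))),
               co$truth$paralog$total_gap_bp)
})
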