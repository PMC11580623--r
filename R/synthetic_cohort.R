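#' Configuration for a synthetic sex-determination cohort
#'
#' Defines the study conditions for [simulate_cohort()]: a resequenced cohort
#' of genetically sexed individuals segregating a small sex-determining
#' region. Defaults emulate a ZW study of 24 females and 20 males at
#' 20-41X depth, with a sex chromosome carrying two sex-linked SNP segments
#' and, between them, a ~21.3 kb W-limited (hemizygous) insertion of which a
#' 590 bp stretch has a diploid paralog elsewhere on the same chromosome
#' differing by three internal gaps totalling 97 bp.
#'
#' @param n_females,n_males Cohort sizes (each >= 2).
#' @param system `"ZW"` (female heterogametic) or `"XY"`. XY mirrors ZW with
#'   the sex roles swapped; one code path serves both.
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#' @param n_autosomal_snps Number of autosomal SNPs planted on the first
#'   chromosome under Hardy-Weinberg equilibrium.
#' @param sdr_chrom Name of the sex chromosome.
#' @param sexlinked_intervals List of 1-based inclusive `c(start, end)`
#'   intervals on `sdr_chrom` holding fully sex-linked SNPs.
#' @param n_sexlinked_snps Total planted sex-linked SNPs; each interval gets
#'   its two endpoints plus a proportional share of interior positions.
#' @param hemizygous_interval `c(start, end)` of the heterogametic-sex-only
#'   insertion (present in the reference, which represents a heterogametic
#'   individual's assembly). Emitted as depth only -- a hemizygous region has
#'   no biallelic diploid genotypes, so no VCF records are placed inside it.
#' @param mean_depth_range `c(low, high)` X-coverage; each individual's
#'   genome-wide mean depth is drawn uniformly from this range.
#' @param depth_dispersion Negative-binomial size parameter for per-site
#'   depth around the individual mean (smaller = more overdispersed).
#' @param genotype_error_rate Mean per-call miscall probability. Each call
#'   draws a latent error probability (a small fraction of calls are dubious,
#'   the rest near-certain); miscalls are applied at that probability and the
#'   call's GQ is its Phred transform, so low-quality calls are the
#'   error-enriched ones, as in real variant calling.
#' @param missing_rate Per-call probability of a missing genotype.
#' @param maf_dist `c(min, max)` of the uniform autosomal minor-allele
#'   frequency distribution (a modelling choice; real site-frequency spectra
#'   are not claimed).
#' @param paralog_spec List with `source` (interval inside
#'   `hemizygous_interval`), `dest_chrom`, `dest_start`, `gaps` (lengths of
#'   sequence inserted into the diploid copy) and `gap_offsets` (positions in
#'   the source copy after which each gap is inserted).
#' @param depth_step_sdr,depth_step_other Spacing (bp) of depth-matrix
#'   positions on the sex chromosome and elsewhere.
#' @param seed Integer seed; identical seeds give byte-identical outputs.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_females = 24, n_males = 20,
                          system = c("ZW", "XY"),
                          chrom_lengths = c(chr1 = 1000000L, chr2 = 300000L),
                          n_autosomal_snps = 10000,
                          sdr_chrom = "chr2",
                          sexlinked_intervals = list(c(120000L, 129299L),
                                                     c(170000L, 172500L)),
                          n_sexlinked_snps = 46,
                          hemizygous_interval = c(140000L, 161325L),
                          mean_depth_range = c(20, 41),
                          depth_dispersion = 8,
                          genotype_error_rate = 0.005,
                          missing_rate = 0.02,
                          maf_dist = c(0.05, 0.5),
                          paralog_spec = list(source = c(141001L, 141590L),
                                              dest_chrom = "chr2",
                                              dest_start = 250001L,
                                              gaps = c(40L, 30L, 27L),
                                              gap_offsets = c(100L, 250L, 400L)),
                          depth_step_sdr = 50L,
                          depth_step_other = 200L,
                          seed = 1L) {
  system <- match.arg(system)
  if (n_females < 2 || n_males < 2) stop("need at least 2 individuals per sex")
  if (is.null(names(chrom_lengths))) stop("chrom_lengths must be named")
  if (!sdr_chrom %in% names(chrom_lengths)) stop("sdr_chrom not in chrom_lengths")
  L <- chrom_lengths[[sdr_chrom]]
  iv_ok <- function(iv) length(iv) == 2 && iv[1] >= 1 && iv[2] <= L && iv[1] <= iv[2]
  if (!all(vapply(sexlinked_intervals, iv_ok, logical(1))))
    stop("sexlinked_intervals outside ", sdr_chrom)
  if (!iv_ok(hemizygous_interval)) stop("hemizygous_interval outside ", sdr_chrom)
  for (iv in sexlinked_intervals)
    if (iv[1] <= hemizygous_interval[2] && hemizygous_interval[1] <= iv[2])
      stop("hemizygous_interval overlaps a sex-linked interval")
  ps <- paralog_spec
  if (ps$source[1] < hemizygous_interval[1] || ps$source[2] > hemizygous_interval[2])
    stop("paralog source must lie inside hemizygous_interval")
  if (length(ps$gaps) != length(ps$gap_offsets))
    stop("paralog gaps and gap_offsets must have equal length")
  if (length(ps$gaps) && any(ps$gaps <= 0)) stop("paralog gap lengths must be positive")
  src_len <- ps$source[2] - ps$source[1] + 1
  if (length(ps$gap_offsets) &&
      (any(ps$gap_offsets < 1) || any(ps$gap_offsets >= src_len)))
    stop("gap_offsets must fall strictly inside the source copy")
  dest_len <- src_len + sum(ps$gaps)
  if (ps$dest_chrom == sdr_chrom) {
    de <- ps$dest_start + dest_len - 1
    if (ps$dest_start <= hemizygous_interval[2] && hemizygous_interval[1] <= de)
      stop("paralog destination overlaps hemizygous_interval")
  }
  if (ps$dest_start + dest_len - 1 > chrom_lengths[[ps$dest_chrom]])
    stop("paralog destination outside chromosome")
  if (maf_dist[1] <= 0 || maf_dist[2] > 0.5 || maf_dist[1] > maf_dist[2])
    stop("maf_dist must satisfy 0 < min <= max <= 0.5")
  structure(list(
    n_females = as.integer(n_females), n_males = as.integer(n_males),
    system = system, chrom_lengths = chrom_lengths,
    n_autosomal_snps = as.integer(n_autosomal_snps), sdr_chrom = sdr_chrom,
    sexlinked_intervals = sexlinked_intervals,
    n_sexlinked_snps = as.integer(n_sexlinked_snps),
    hemizygous_interval = as.integer(hemizygous_interval),
    mean_depth_range = mean_depth_range,
    depth_dispersion = depth_dispersion,
    genotype_error_rate = genotype_error_rate, missing_rate = missing_rate,
    maf_dist = maf_dist, paralog_spec = ps,
    depth_step_sdr = as.integer(depth_step_sdr),
    depth_step_other = as.integer(depth_step_other),
    seed = as.integer(seed)), class = "cohort_config")
}

.rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.revcomp <- function(s) {
  chartr("ACGTN", "TGCAN",
         vapply(strsplit(s, "", fixed = TRUE),
                function(x) paste(rev(x), collapse = ""), character(1)))
}

#' Plant a diploid paralog of a haploid-region subsequence
#'
#' Copies a stretch of the (heterogametic-sex-limited) hemizygous region to a
#' destination locus, inserting gap sequences so the diploid copy is longer
#' than the haploid original by the summed gap length -- the raw material of
#' a paralog-length-polymorphism sexing marker.
#'
#' @param reference Named character vector of chromosome sequences.
#' @param spec `paralog_spec` list as in [cohort_config()] (fields `source`,
#'   `dest_chrom`, `dest_start`, `gaps`, `gap_offsets`); the source interval
#'   is addressed on `chrom`.
#' @param chrom Chromosome holding the source interval.
#' @param hemizygous_interval Optional interval the destination must avoid.
#' @return List with the modified `reference`, `haploid` and `diploid`
#'   interval records and `total_gap_bp`. Gap sequences are drawn from the
#'   current RNG stream.
#' @export
plant_paralog <- function(reference, spec, chrom,
                          hemizygous_interval = NULL) {
  src <- substr(reference[[chrom]], spec$source[1], spec$source[2])
  src_len <- nchar(src)
  dest_len <- src_len + sum(spec$gaps)
  if (!is.null(hemizygous_interval) && spec$dest_chrom == chrom) {
    de <- spec$dest_start + dest_len - 1
    if (spec$dest_start <= hemizygous_interval[2] &&
        hemizygous_interval[1] <= de)
      stop("paralog destination overlaps hemizygous_interval")
  }
  # build diploid copy: source with gap sequences inserted after each offset
  ord <- order(spec$gap_offsets)
  offs <- spec$gap_offsets[ord]; gaps <- spec$gaps[ord]
  pieces <- character(0); prev <- 1L
  for (g in seq_along(gaps)) {
    pieces <- c(pieces, substr(src, prev, offs[g]), .rand_seq(gaps[g]))
    prev <- offs[g] + 1L
  }
  pieces <- c(pieces, substr(src, prev, src_len))
  dip <- paste(pieces, collapse = "")
  stopifnot(nchar(dip) == dest_len)
  tgt <- reference[[spec$dest_chrom]]
  substr(tgt, spec$dest_start, spec$dest_start + dest_len - 1) <- dip
  reference[[spec$dest_chrom]] <- tgt
  list(reference = reference,
       haploid = list(chrom = chrom, start = spec$source[1],
                      end = spec$source[2], length = src_len),
       diploid = list(chrom = spec$dest_chrom, start = spec$dest_start,
                      end = spec$dest_start + dest_len - 1,
                      length = dest_len),
       n_gaps = length(gaps), total_gap_bp = sum(gaps))
}

# deterministic gene layout tied to the config geometry; returns a GFF-style
# data.frame (seqid, source, type, start, end, score, strand, phase,
# attributes) with gene/mRNA/exon/CDS/UTR rows
.cohort_genes <- function(config) {
  rows <- list()
  add_gene <- function(id, chrom, start, end, strand, nexons) {
    span <- end - start + 1
    bl <- (span %/% (2L * nexons - 1L))
    if (bl < 30L) return(invisible(NULL)) # no room, skip
    ex_start <- start + (seq_len(nexons) - 1L) * 2L * bl
    ex_end <- ex_start + bl - 1L
    gend <- ex_end[nexons]
    u5 <- min(45L, bl %/% 3L) # UTR allowance at each terminus
    cds_lo <- ex_start[1] + u5
    cds_hi <- ex_end[nexons] - u5
    # clip CDS to multiple of 3
    seg_lo <- pmax(ex_start, cds_lo); seg_hi <- pmin(ex_end, cds_hi)
    keep <- seg_lo <= seg_hi
    tot <- sum(seg_hi[keep] - seg_lo[keep] + 1L)
    rem <- tot %% 3L
    if (rem > 0L) { cds_hi <- cds_hi - rem; seg_hi <- pmin(ex_end, cds_hi) }
    keep <- seg_lo <= seg_hi
    seg_lo <- seg_lo[keep]; seg_hi <- seg_hi[keep]
    # phase along transcription direction
    lens <- seg_hi - seg_lo + 1L
    if (strand == "+") {
      cum <- c(0L, cumsum(lens))[seq_along(lens)]
    } else {
      cum <- rev(c(0L, cumsum(rev(lens)))[seq_along(lens)])
    }
    phase <- (3L - cum %% 3L) %% 3L
    g <- function(type, s, e, ph, attr)
      data.frame(seqid = chrom, source = "sdrscan", type = type,
                 start = s, end = e, score = ".", strand = strand,
                 phase = ifelse(is.na(ph), ".", as.character(ph)),
                 attributes = attr, stringsAsFactors = FALSE)
    mid <- paste0(id, ".t1")
    out <- rbind(
      g("gene", start, gend, NA, sprintf("ID=%s;Name=%s", id, id)),
      g("mRNA", start, gend, NA, sprintf("ID=%s;Parent=%s", mid, id)),
      g("exon", ex_start, ex_end, NA, sprintf("Parent=%s", mid)),
      g("CDS", seg_lo, seg_hi, phase, sprintf("Parent=%s", mid)))
    # UTR pieces: exon parts outside [cds_lo, cds_hi]
    utr <- list()
    for (i in seq_len(nexons)) {
      if (ex_start[i] < cds_lo)
        utr[[length(utr) + 1L]] <- c(ex_start[i], min(ex_end[i], cds_lo - 1L), 1L)
      if (ex_end[i] > cds_hi)
        utr[[length(utr) + 1L]] <- c(max(ex_start[i], cds_hi + 1L), ex_end[i], 3L)
    }
    for (u in utr) {
      side <- if (strand == "+") u[3] else (4L - u[3]) # swap 5'/3' on minus
      out <- rbind(out, g(if (side == 1L) "five_prime_UTR" else "three_prime_UTR",
                          u[1], u[2], NA, sprintf("Parent=%s", mid)))
    }
    rows[[length(rows) + 1L]] <<- out
    invisible(NULL)
  }

  sdr <- config$sdr_chrom
  A <- config$sexlinked_intervals[[1]]
  hz <- config$hemizygous_interval
  # four genes tiled over the first sex-linked segment and its inner flank
  wA <- A[2] - A[1] + 1
  gw <- max(600L, (wA * 2L) %/% 9L)
  s0 <- A[1] + 200L
  add_gene("cyp19b", sdr, s0, s0 + gw - 1L, "+", 3L)
  add_gene("myo5c", sdr, s0 + gw + 300L, s0 + 2L * gw - 1L, "-", 2L)
  add_gene("gnb5", sdr, s0 + 2L * gw + 300L, s0 + 3L * gw - 1L, "+", 2L)
  add_gene("ap4e1", sdr, A[2] + 500L, A[2] + 500L + gw, "-", 3L)
  # two degenerate piccolo-like genes inside the hemizygous insertion
  hw <- hz[2] - hz[1] + 1
  p0 <- hz[1] + max(2500L, hw %/% 10L)
  add_gene("pclol1", sdr, p0, p0 + 1500L, "+", 3L)
  add_gene("pclol2", sdr, p0 + 2500L, p0 + 4200L, "+", 3L)
  # one gene in the second sex-linked segment (if present)
  if (length(config$sexlinked_intervals) > 1) {
    B <- config$sexlinked_intervals[[2]]
    add_gene("clpx", sdr, B[1] + 400L, B[2] - 100L, "-", 2L)
  }
  # the diploid paralog host gene, outside the SDR
  ps <- config$paralog_spec
  dlen <- (ps$source[2] - ps$source[1] + 1) + sum(ps$gaps)
  add_gene("pclo", ps$dest_chrom, ps$dest_start - 2000L,
           ps$dest_start + dlen + 2000L, "+", 4L)
  # two autosomal genes on the first chromosome
  aut <- names(config$chrom_lengths)[1]
  add_gene("auta", aut, 10000L, 13000L, "+", 3L)
  add_gene("autb", aut, 50000L, 52000L, "-", 2L)
  do.call(rbind, rows)
}

# repeats tiling the expected SDR at 56% coverage (700 bp of every 1250 bp),
# plus a few autosomal repeats; 1-based inclusive
.cohort_repeats <- function(config, sdr_span) {
  starts <- seq(sdr_span[1], sdr_span[2] - 699L, by = 1250L)
  rep_sdr <- data.frame(chrom = config$sdr_chrom, start = starts,
                        end = starts + 699L)
  aut <- names(config$chrom_lengths)[1]
  rep_aut <- data.frame(chrom = aut, start = c(5000L, 200000L, 700000L),
                        end = c(6999L, 201499L, 702999L))
  rbind(rep_aut, rep_sdr)
}

#' Simulate a complete synthetic sex-determination study
#'
#' Generates, from a seeded [cohort_config()], every input the SDR pipeline
#' consumes -- reference genome, VCF genotypes, a per-position depth matrix,
#' sample sheet, gene models, repeat intervals, a planted haploid/diploid
#' paralog pair with a shared primer pair -- together with a `truth` record
#' of everything planted, for parameter-recovery testing.
#'
#' Heterogametic-sex individuals are heterozygous at every planted sex-linked
#' SNP (before error and missingness) and the other sex is homozygous for the
#' reference allele; autosomal genotypes are drawn per site from
#' Hardy-Weinberg proportions at a simulated allele frequency. Within the
#' hemizygous interval the heterogametic sex runs at half its genome-wide
#' mean depth and the other sex at ~0.3X background; no VCF records are
#' emitted there.
#'
#' @param config A [cohort_config()].
#' @param outdir Optional directory; when given, writes `ref.fa`,
#'   `cohort.vcf`, `depth.tsv`, `samples.tsv`, `genes.gff3`, `repeats.bed`,
#'   `primers.tsv` and `truth.json`.
#' @return An object of class `sdr_cohort`: list with `reference`,
#'   `genotypes` (a `genotype_table`), `sexframe`, `depth` (a
#'   `depth_matrix`), `genes`, `repeats`, `primers`, `truth`, `config`.
#' @export
simulate_cohort <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  hg <- if (config$system == "ZW") "F" else "M" # heterogametic sex
  n_f <- config$n_females; n_m <- config$n_males
  samples <- c(sprintf("F%02d", seq_len(n_f)), sprintf("M%02d", seq_len(n_m)))
  sex <- c(rep("F", n_f), rep("M", n_m))
  n <- n_f + n_m

  # --- reference genome + paralog -------------------------------------------
  reference <- vapply(config$chrom_lengths, .rand_seq, character(1))
  pp <- plant_paralog(reference, config$paralog_spec, config$sdr_chrom,
                      config$hemizygous_interval)
  reference <- pp$reference

  # --- SNP positions --------------------------------------------------------
  aut_chrom <- names(config$chrom_lengths)[1]
  aut_pos <- sort(sample.int(config$chrom_lengths[[1]],
                             config$n_autosomal_snps))
  sl_pos <- integer(0)
  ivlen <- vapply(config$sexlinked_intervals, function(iv) iv[2] - iv[1] + 1,
                  numeric(1))
  n_inner <- pmax(0L, round(config$n_sexlinked_snps * ivlen / sum(ivlen)) - 2L)
  for (k in seq_along(config$sexlinked_intervals)) {
    iv <- config$sexlinked_intervals[[k]]
    inner <- if (n_inner[k] > 0 && iv[2] - iv[1] > 1)
      sample(seq.int(iv[1] + 1L, iv[2] - 1L), min(n_inner[k], iv[2] - iv[1] - 1L))
    else integer(0)
    sl_pos <- c(sl_pos, iv[1], sort(inner), iv[2]) # endpoints always planted
  }

  # --- genotypes ------------------------------------------------------------
  chrom <- c(rep(aut_chrom, length(aut_pos)), rep(config$sdr_chrom, length(sl_pos)))
  pos <- c(aut_pos, sl_pos)
  n_sites <- length(pos)
  is_sl <- c(rep(FALSE, length(aut_pos)), rep(TRUE, length(sl_pos)))
  ref_base <- vapply(seq_len(n_sites),
                     function(i) substr(reference[[chrom[i]]], pos[i], pos[i]),
                     character(1))
  alt_base <- vapply(ref_base, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1), USE.NAMES = FALSE)
  maf <- runif(n_sites, config$maf_dist[1], config$maf_dist[2])
  gt <- matrix(0L, n_sites, n)
  aut_idx <- which(!is_sl)
  p_site <- maf[aut_idx]
  gt[aut_idx, ] <- matrix(
    rbinom(length(aut_idx) * n, 1L, rep(p_site, n)) +
      rbinom(length(aut_idx) * n, 1L, rep(p_site, n)),
    nrow = length(aut_idx))
  het_cols <- if (hg == "F") seq_len(n_f) else n_f + seq_len(n_m)
  gt[which(is_sl), het_cols] <- 1L # heterogametic sex heterozygous
  gt[which(is_sl), setdiff(seq_len(n), het_cols)] <- 0L
  truth_gt <- gt

  # --- error + quality model ------------------------------------------------
  ncall <- n_sites * n
  e <- config$genotype_error_rate
  # mixture: most calls near-certain (GQ ~70), a fraction 2e dubious with
  # uniform latent error, so the mean miscall probability is exactly e and
  # dubious calls are the error-enriched, low-GQ ones that QC masks
  bad_frac <- min(1, 2 * e)
  eps <- ifelse(runif(ncall) < bad_frac, runif(ncall), 1e-7)
  gq <- matrix(pmin(99L, pmax(3L, as.integer(round(-10 * log10(eps))))),
               n_sites, n)
  flip <- runif(ncall) < eps
  if (any(flip)) {
    cur <- gt[flip]
    alt1 <- ifelse(cur == 0L, 1L, ifelse(cur == 1L, 0L, 1L))
    alt2 <- ifelse(cur == 0L, 2L, ifelse(cur == 1L, 2L, 0L))
    gt[flip] <- ifelse(runif(sum(flip)) < 0.5, alt1, alt2)
  }
  miss <- matrix(runif(ncall) < config$missing_rate, n_sites, n)
  gt[miss] <- NA_integer_

  # --- depth ----------------------------------------------------------------
  indiv_mean <- runif(n, config$mean_depth_range[1], config$mean_depth_range[2])
  dp <- matrix(rnbinom(ncall, size = config$depth_dispersion,
                       mu = rep(indiv_mean, each = n_sites)), n_sites, n)
  qual <- round(30 + rowSums(dp) / 10)
  sites <- data.frame(chrom = chrom, pos = pos, ref = ref_base,
                      alt = alt_base, qual = qual, stringsAsFactors = FALSE)
  ord <- order(match(chrom, names(config$chrom_lengths)), pos)
  genotypes <- structure(list(sites = sites[ord, , drop = FALSE],
                              gt = gt[ord, , drop = FALSE],
                              dp = dp[ord, , drop = FALSE],
                              gq = gq[ord, , drop = FALSE],
                              samples = samples),
                         class = "genotype_table")
  rownames(genotypes$sites) <- NULL
  truth_gt <- truth_gt[ord, , drop = FALSE]
  is_sl <- is_sl[ord]

  # depth matrix over a genome-wide grid (finer on the sex chromosome)
  dpos <- lapply(names(config$chrom_lengths), function(cn) {
    step <- if (cn == config$sdr_chrom) config$depth_step_sdr else config$depth_step_other
    grid <- seq.int(1L, config$chrom_lengths[[cn]], by = step)
    if (cn == config$sdr_chrom) # depth of every SNP in every individual
      grid <- sort(unique(c(grid, sl_pos)))
    data.frame(chrom = cn, pos = grid)
  })
  dpos <- do.call(rbind, dpos)
  hz <- config$hemizygous_interval
  in_hz <- dpos$chrom == config$sdr_chrom & dpos$pos >= hz[1] & dpos$pos <= hz[2]
  mu <- outer(rep(1, nrow(dpos)), indiv_mean)
  hg_cols <- if (hg == "F") sex == "F" else sex == "M"
  mu[in_hz, hg_cols] <- mu[in_hz, hg_cols] * 0.5
  mu[in_hz, !hg_cols] <- 0.3
  depth_mat <- matrix(rnbinom(length(mu), size = config$depth_dispersion,
                              mu = as.vector(mu)), nrow = nrow(dpos))
  colnames(depth_mat) <- samples
  depth <- structure(list(positions = dpos, depth = depth_mat,
                          samples = samples), class = "depth_matrix")

  sexframe <- data.frame(sample_id = samples, sex = sex,
                         genome_mean_depth = colMeans(depth_mat),
                         stringsAsFactors = FALSE)
  rownames(sexframe) <- NULL

  # --- annotation tracks, primers, truth ------------------------------------
  genes <- .cohort_genes(config)
  flank <- 5000L
  sl_all <- sort(sl_pos)
  sdr_span <- c(max(1L, min(sl_all) - flank),
                min(config$chrom_lengths[[config$sdr_chrom]], max(sl_all) + flank))
  repeats <- .cohort_repeats(config, sdr_span)

  ps <- config$paralog_spec
  src_seq <- substr(reference[[config$sdr_chrom]], ps$source[1], ps$source[2])
  # shared primers in the conserved flanks of the duplicated segment:
  # product spans offsets 11..(10 + hap_product) of the haploid copy
  hap_product <- min(nchar(src_seq) - 46L, 544L)
  fwd <- substr(src_seq, 11L, 30L)
  rev_site <- substr(src_seq, 10L + hap_product - 19L, 10L + hap_product)
  primers <- data.frame(name = "sexmark1", forward = fwd,
                        reverse = .revcomp(rev_site), stringsAsFactors = FALSE)
  dip_product <- hap_product + pp$total_gap_bp
  bands_hg <- sort(c(dip_product, hap_product), decreasing = TRUE)
  gene_df <- genes[genes$type == "gene", ]
  sdr_genes <- gene_df$attributes[gene_df$seqid == config$sdr_chrom &
                                    gene_df$start <= sdr_span[2] &
                                    gene_df$end >= sdr_span[1]]
  sdr_genes <- sub("^ID=([^;]+);.*$", "\\1", sdr_genes)

  truth <- structure(list(
    system = config$system, heterogametic_sex = hg,
    planted_snps = data.frame(chrom = config$sdr_chrom, pos = sl_all),
    hemizygous_region = genomic_region(config$sdr_chrom, hz[1], hz[2],
                                       "sex_specific_haploid", sex = hg),
    expected_sdr = genomic_region(config$sdr_chrom, sdr_span[1], sdr_span[2], "sdr"),
    paralog = list(haploid = pp$haploid, diploid = pp$diploid,
                   n_gaps = pp$n_gaps, total_gap_bp = pp$total_gap_bp),
    primers = primers,
    expected_bands = setNames(list(bands_hg, bands_hg[1]),
                              c(hg, setdiff(c("F", "M"), hg))),
    sdr_genes = sdr_genes,
    indiv_mean_depth = setNames(indiv_mean, samples),
    truth_gt = truth_gt, sexlinked_site = is_sl), class = "truth_set")

  cohort <- structure(list(reference = reference, genotypes = genotypes,
                           sexframe = sexframe, depth = depth, genes = genes,
                           repeats = repeats, primers = primers, truth = truth,
                           config = config), class = "sdr_cohort")
  if (!is.null(outdir)) write_cohort(cohort, outdir)
  cohort
}

#' @export
print.sdr_cohort <- function(x, ...) {
  cat(sprintf("Synthetic %s cohort: %d F / %d M, %d SNP sites, %d depth positions\n",
              x$config$system, x$config$n_females, x$config$n_males,
              nrow(x$genotypes$sites), nrow(x$depth$positions)))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits the standard plain-text formats consumed by the pipeline: 60-column
#' FASTA, VCF v4.2 with GT:DP:GQ, a depth TSV (chrom, pos, one column per
#' sample), sample sheet, GFF3 gene models, 0-based half-open repeat BED,
#' primer TSV and a JSON truth record.
#'
#' @param cohort An `sdr_cohort` from [simulate_cohort()].
#' @param outdir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(ref = file.path(outdir, "ref.fa"),
             vcf = file.path(outdir, "cohort.vcf"),
             depth = file.path(outdir, "depth.tsv"),
             samples = file.path(outdir, "samples.tsv"),
             genes = file.path(outdir, "genes.gff3"),
             repeats = file.path(outdir, "repeats.bed"),
             primers = file.path(outdir, "primers.tsv"),
             truth = file.path(outdir, "truth.json"))
  write_fasta(cohort$reference, paths["ref"])
  write_vcf(cohort$genotypes, paths["vcf"],
            contig_lengths = cohort$config$chrom_lengths)
  dm <- cbind(cohort$depth$positions,
              as.data.frame(cohort$depth$depth, check.names = FALSE))
  write.table(dm, paths["depth"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort$sexframe, paths["samples"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(c("##gff-version 3",
               with(cohort$genes, paste(seqid, source, type, start, end,
                                        score, strand, phase, attributes,
                                        sep = "\t"))), paths["genes"])
  bed <- data.frame(cohort$repeats$chrom, cohort$repeats$start - 1L,
                    cohort$repeats$end)
  write.table(bed, paths["repeats"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(cohort$primers, paths["primers"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  tr <- cohort$truth
  jsonlite::write_json(list(
    system = tr$system, heterogametic_sex = tr$heterogametic_sex,
    planted_snps = tr$planted_snps,
    hemizygous_region = tr$hemizygous_region[c("chrom", "start", "end")],
    expected_sdr = tr$expected_sdr[c("chrom", "start", "end")],
    paralog = tr$paralog, expected_bands = tr$expected_bands,
    sdr_genes = tr$sdr_genes), paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Write sequences as 60-column wrapped FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq.int(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(path)
}

#' Write a genotype table as VCF v4.2 (GT:DP:GQ)
#' @param table A `genotype_table`.
#' @param path Output path.
#' @param contig_lengths Optional named lengths for `##contig` headers.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(table, path, contig_lengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=sdrscan",
           if (!is.null(contig_lengths))
             sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                     as.integer(contig_lengths)),
           '##INFO=<ID=NS,Number=1,Type=Integer,Description="Number of samples with data">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", table$samples), collapse = "\t"))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[table$gt + 1L],
                   nrow(table$gt), ncol(table$gt))
  gt_str[is.na(table$gt)] <- "./."
  cell <- matrix(paste(gt_str, table$dp, table$gq, sep = ":"),
                 nrow(table$gt), ncol(table$gt))
  cell[is.na(table$gt)] <- "./.:.:."
  body <- paste(table$sites$chrom, table$sites$pos, ".", table$sites$ref,
                table$sites$alt, table$sites$qual, "PASS",
                paste0("NS=", rowSums(!is.na(table$gt))), "GT:DP:GQ",
                apply(cell, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
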