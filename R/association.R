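#' Two-sided allelic Fisher's exact test
#'
#' Exact test of allele-count independence in a 2x2 table of minor/major
#' allele counts by sex. The two-sided p-value follows the
#' minimum-likelihood rule: the sum of hypergeometric probabilities of all
#' tables with the observed margins whose point probability does not exceed
#' the observed table's (within relative tolerance 1e-7, the conventional
#' guard against floating-point ties).
#'
#' @param a,b Minor- and major-allele counts in females.
#' @param c,d Minor- and major-allele counts in males.
#' @return The two-sided p-value. Monomorphic tables (a zero allele margin)
#'   return 1 with attribute `monomorphic = TRUE`.
#' @examples
#' fisher_exact_allelic(2, 0, 0, 2) # 1/3
#' @export
fisher_exact_allelic <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m1 <- a + c # minor-allele margin
  n1 <- a + b # female margin
  n2 <- c + d
  if (m1 == 0 || m1 == n1 + n2 || n1 == 0 || n2 == 0)
    return(structure(1, monomorphic = TRUE))
  lo <- max(0L, m1 - n2)
  hi <- min(n1, m1)
  x <- lo:hi
  logp <- stats::dhyper(x, n1, n2, m1, log = TRUE)
  obs <- logp[x == a]
  p <- sum(exp(logp[logp <= obs + log(1 + 1e-7)]))
  min(1, p)
}

#' Likelihood-ratio test of allele-frequency equality between sexes
#'
#' A count-based surrogate for genotype-likelihood allele-frequency tests:
#' compares two binomial likelihoods with free per-sex allele frequencies
#' against a pooled frequency, \eqn{G = 2[\ell(\hat p_F, \hat p_M) -
#' \ell(\hat p)]}, referred to a chi-square distribution with 1 df.
#'
#' @inheritParams fisher_exact_allelic
#' @return The upper-tail p-value; `attr(, "G")` holds the statistic
#'   (clipped at 0). Monomorphic tables return 1.
#' @export
lrt_allele_freq <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  nf <- a + b; nm <- c + d
  if (nf == 0 || nm == 0) stop("empty sex margin")
  if (a + c == 0 || b + d == 0) return(structure(1, G = 0))
  ll <- function(x, n, p) {
    t1 <- if (x > 0) x * log(p) else 0
    t2 <- if (n - x > 0) (n - x) * log(1 - p) else 0
    t1 + t2
  }
  pf <- a / nf; pm <- c / nm; pp <- (a + c) / (nf + nm)
  G <- max(0, 2 * (ll(a, nf, pf) + ll(c, nm, pm) -
                     ll(a, nf, pp) - ll(c, nm, pp)))
  if (G < 1e-10) G <- 0 # equal frequencies up to rounding
  structure(stats::pchisq(G, df = 1, lower.tail = FALSE), G = G)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j},
#' returned in the input order.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]` (NA passed through).
#' @return q-values, same length and order as the input.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  stopifnot(all(is.na(pvals) | (pvals >= 0 & pvals <= 1)))
  stats::p.adjust(pvals, method = "BH")
}

#' Raw p-value threshold achieving a target FDR
#'
#' The largest raw p-value whose BH q-value is at most `alpha` -- the
#' "genome-wide significance line" implied by the data.
#'
#' @param pvals Raw p-values.
#' @param alpha Target FDR, in (0, 1).
#' @return The threshold (an element of `pvals`), or `NA` if nothing is
#'   significant.
#' @export
fdr_threshold <- function(pvals, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  q <- bh_fdr(pvals)
  ok <- !is.na(q) & q <= alpha
  if (!any(ok)) return(NA_real_)
  max(pvals[ok])
}

#' Per-site Weir-Cockerham F_ST between the sexes
#'
#' The two-population (r = 2) variance-components estimator of Weir &
#' Cockerham (1984): components `a` (among populations), `b` (among
#' individuals within populations) and `c` (within individuals), with
#' \eqn{F_{ST} = a / (a + b + c)}. Negative estimates are reported as-is.
#'
#' @param n_f,n_m Called diploid sample sizes per sex.
#' @param p_f,p_m Alternate-allele frequencies per sex.
#' @param h_f,h_m Observed heterozygote proportions per sex.
#' @return List with `a`, `b`, `c` and `fst` (`NA` with all-zero components
#'   when the site is monomorphic across both sexes).
#' @export
wc_fst_site <- function(n_f, p_f, h_f, n_m, p_m, h_m) {
  stopifnot(n_f >= 1, n_m >= 1)
  n <- c(n_f, n_m); p <- c(p_f, p_m); h <- c(h_f, h_m)
  r <- 2
  nbar <- mean(n)
  pbar <- sum(n * p) / (r * nbar)
  if (pbar <= 0 || pbar >= 1)
    return(list(a = 0, b = 0, c = 0, fst = NA_real_))
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  list(a = a, b = b, c = cc,
       fst = if (denom > 0) a / denom else NA_real_)
}

#' Genome-wide weighted Weir-Cockerham F_ST
#'
#' Ratio-of-sums weighting across sites:
#' \eqn{\sum_i a_i / \sum_i (a_i + b_i + c_i)}; monomorphic sites contribute
#' nothing. This (not the mean of per-site ratios) is the conventional
#' "weighted" genome estimate and can legitimately be slightly negative in
#' the absence of differentiation.
#'
#' @param components Data frame or list of per-site components with elements
#'   `a`, `b`, `c` (as from [wc_fst_site()]).
#' @return The weighted F_ST (`NA` with a warning if the denominator is not
#'   positive).
#' @export
wc_fst_weighted <- function(components) {
  a <- sum(components$a, na.rm = TRUE)
  denom <- sum(components$a, na.rm = TRUE) + sum(components$b, na.rm = TRUE) +
    sum(components$c, na.rm = TRUE)
  if (!is.finite(denom) || denom <= 0) {
    warning("non-positive F_ST denominator")
    return(NA_real_)
  }
  a / denom
}

#' Per-site sex-association scan
#'
#' Runs the allelic Fisher's exact test, the allele-frequency LRT, BH-FDR
#' adjustment of both, and the per-site Weir-Cockerham estimator over every
#' site of a (filtered) genotype table, and computes the genome-wide
#' weighted F_ST.
#'
#' @param table A `genotype_table` (ideally post-QC).
#' @param sexframe Sample sheet aligned with `table$samples`.
#' @param alpha FDR level used for the reported significance thresholds.
#' @return An object of class `assoc_scan`: list with `stats` (one row per
#'   site: allele counts, `p_fet`, `q_fet`, `p_lrt`, `q_lrt`, `fst` and the
#'   `a`/`b`/`c` components), `fst_weighted`, `fet_threshold`,
#'   `lrt_threshold` and `alpha`.
#' @export
assoc_scan <- function(table, sexframe, alpha = 0.05) {
  stopifnot(identical(sexframe$sample_id, table$samples))
  is_f <- sexframe$sex == "F"
  gtf <- table$gt[, is_f, drop = FALSE]
  gtm <- table$gt[, !is_f, drop = FALSE]
  nf <- rowSums(!is.na(gtf)); nm <- rowSums(!is.na(gtm))
  altf <- rowSums(gtf, na.rm = TRUE); altm <- rowSums(gtm, na.rm = TRUE)
  hetf <- rowSums(gtf == 1L, na.rm = TRUE); hetm <- rowSums(gtm == 1L, na.rm = TRUE)
  # minor allele defined on the pooled called counts
  minor_is_alt <- (altf + altm) <= (nf + nm) # alt dosage <= half of 2(nf+nm)
  a <- ifelse(minor_is_alt, altf, 2 * nf - altf)
  b <- 2 * nf - a
  cc <- ifelse(minor_is_alt, altm, 2 * nm - altm)
  d <- 2 * nm - cc

  n_sites <- nrow(table$sites)
  p_fet <- p_lrt <- fst <- va <- vb <- vc <- rep(NA_real_, n_sites)
  for (i in seq_len(n_sites)) {
    if (nf[i] == 0 || nm[i] == 0) next
    p_fet[i] <- fisher_exact_allelic(a[i], b[i], cc[i], d[i])
    p_lrt[i] <- lrt_allele_freq(a[i], b[i], cc[i], d[i])
    w <- wc_fst_site(nf[i], altf[i] / (2 * nf[i]), hetf[i] / nf[i],
                     nm[i], altm[i] / (2 * nm[i]), hetm[i] / nm[i])
    fst[i] <- w$fst; va[i] <- w$a; vb[i] <- w$b; vc[i] <- w$c
  }
  stats <- data.frame(chrom = table$sites$chrom, pos = table$sites$pos,
                      minor_f = a, major_f = b, minor_m = cc, major_m = d,
                      p_fet = p_fet, q_fet = bh_fdr(p_fet),
                      p_lrt = p_lrt, q_lrt = bh_fdr(p_lrt),
                      fst = fst, a = va, b = vb, c = vc,
                      stringsAsFactors = FALSE)
  poly <- !is.na(fst)
  structure(list(stats = stats,
                 fst_weighted = if (any(poly))
                   wc_fst_weighted(stats[poly, c("a", "b", "c")]) else NA_real_,
                 fet_threshold = fdr_threshold(p_fet[!is.na(p_fet)], alpha),
                 lrt_threshold = fdr_threshold(p_lrt[!is.na(p_lrt)], alpha),
                 alpha = alpha), class = "assoc_scan")
}

#' @export
print.assoc_scan <- function(x, ...) {
  n_fet <- sum(x$stats$q_fet <= x$alpha, na.rm = TRUE)
  n_lrt <- sum(x$stats$q_lrt <= x$alpha, na.rm = TRUE)
  cat(sprintf("assoc_scan: %d sites; weighted F_ST = %.5f\n",
              nrow(x$stats), x$fst_weighted))
  cat(sprintf("  FDR %.2f: %d FET hits (p-line %.3g), %d LRT hits (p-line %.3g)\n",
              x$alpha, n_fet, x$fet_threshold, n_lrt, x$lrt_threshold))
  invisible(x)
}
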