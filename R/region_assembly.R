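#' SDR assembly parameters
#'
#' @param flank_bp Flank added to each sex-linked SNP cluster (default
#'   5000 bp on each side).
#' @param snp_cluster_gap Maximum distance between consecutive sex-specific
#'   SNPs sharing a cluster (default 10 kb).
#' @param clip_to_chrom Clip flanked clusters to `[1, chrom_length]`.
#' @return An object of class `assembly_config`.
#' @export
assembly_config <- function(flank_bp = 5000L, snp_cluster_gap = 10000L,
                            clip_to_chrom = TRUE) {
  stopifnot(flank_bp >= 0, snp_cluster_gap >= 0)
  structure(list(flank_bp = as.integer(flank_bp),
                 snp_cluster_gap = as.integer(snp_cluster_gap),
                 clip_to_chrom = clip_to_chrom), class = "assembly_config")
}

#' Cluster sex-specific SNPs into sex-linked regions
#'
#' Consecutive hits closer than `snp_cluster_gap` share a cluster; each
#' cluster span is extended by `flank_bp` both ways (clipped to the
#' chromosome). Flanked clusters that come to overlap are merged -- flanks
#' are annotation, not evidence, so overlap implies one segment.
#'
#' @param hits Data frame with `chrom` and `pos` (from
#'   [detect_sex_specific()]).
#' @param cfg An [assembly_config()].
#' @param chrom_lengths Optional named lengths used for clipping.
#' @return List of `genomic_region` objects of kind `sex_linked`, each with
#'   the contributing SNP positions in `provenance`.
#' @export
cluster_snps <- function(hits, cfg = assembly_config(), chrom_lengths = NULL) {
  if (is.null(hits) || nrow(hits) == 0) return(list())
  out <- list()
  for (cn in unique(hits$chrom)) {
    pos <- sort(hits$pos[hits$chrom == cn])
    runs <- .merge_positions(pos, cfg$snp_cluster_gap)
    runs$start <- runs$start - cfg$flank_bp
    runs$end <- runs$end + cfg$flank_bp
    if (cfg$clip_to_chrom) {
      runs$start <- pmax(1L, runs$start)
      if (!is.null(chrom_lengths) && cn %in% names(chrom_lengths))
        runs$end <- pmin(as.integer(chrom_lengths[[cn]]), runs$end)
    }
    # merge flanked clusters that now overlap or touch
    runs <- runs[order(runs$start), , drop = FALSE]
    merged <- runs[1, , drop = FALSE]
    for (k in seq_len(nrow(runs))[-1]) {
      last <- nrow(merged)
      if (runs$start[k] <= merged$end[last] + 1L)
        merged$end[last] <- max(merged$end[last], runs$end[k])
      else merged <- rbind(merged, runs[k, ])
    }
    for (k in seq_len(nrow(merged)))
      out[[length(out) + 1]] <- genomic_region(
        cn, merged$start[k], merged$end[k], "sex_linked",
        provenance = list(snps = pos[pos >= merged$start[k] &
                                       pos <= merged$end[k]]))
  }
  out
}

#' Assemble the sex-determining region
#'
#' Combines sex-linked SNP clusters with coverage-derived hemizygous
#' regions: the SDR spans from the first to the last sex-linked region, and
#' additionally absorbs any hemizygous region lying between them (or
#' overlapping them). Hemizygous regions outside the sex-linked span are
#' excluded and listed separately.
#'
#' @param sex_linked List of `sex_linked` regions from [cluster_snps()].
#' @param haploid List of `sex_specific_haploid` regions from
#'   [call_regions()].
#' @return An object of class `sdr_call`: list with `sdr` (a
#'   `genomic_region`, or a list of per-chromosome regions with a warning if
#'   the input spans chromosomes), `components` (data frame of contributing
#'   regions with lengths in bp and Kb) and `excluded` (haploid regions
#'   outside the span). `NULL` when there are no components.
#' @export
assemble_sdr <- function(sex_linked, haploid = list()) {
  if (length(sex_linked) == 0 && length(haploid) == 0) return(NULL)
  all_reg <- c(sex_linked, haploid)
  chroms <- unique(vapply(all_reg, function(r) r$chrom, character(1)))
  if (length(chroms) > 1) {
    warning("regions on multiple chromosomes; assembling per chromosome")
    calls <- lapply(chroms, function(cn) {
      assemble_sdr(Filter(function(r) r$chrom == cn, sex_linked),
                   Filter(function(r) r$chrom == cn, haploid))
    })
    names(calls) <- chroms
    return(calls)
  }
  if (length(sex_linked) == 0) {
    span <- c(min(vapply(haploid, `[[`, integer(1), "start")),
              max(vapply(haploid, `[[`, integer(1), "end")))
  } else {
    span <- c(min(vapply(sex_linked, `[[`, integer(1), "start")),
              max(vapply(sex_linked, `[[`, integer(1), "end")))
  }
  inside <- vapply(haploid, function(r) r$start <= span[2] && r$end >= span[1],
                   logical(1))
  comp <- c(sex_linked, haploid[inside])
  comp_df <- do.call(rbind, lapply(comp, function(r) {
    len <- interval_length(r$start, r$end)
    data.frame(chrom = r$chrom, start = r$start, end = r$end, kind = r$kind,
               length_bp = len, length_kb = .kb(len, 1),
               stringsAsFactors = FALSE)
  }))
  comp_df <- comp_df[order(comp_df$start), , drop = FALSE]
  rownames(comp_df) <- NULL
  sdr <- genomic_region(chroms, span[1], span[2], "sdr",
                        provenance = list(components = comp_df))
  structure(list(sdr = sdr, components = comp_df,
                 excluded = haploid[!inside]), class = "sdr_call")
}

#' @export
print.sdr_call <- function(x, ...) {
  len <- interval_length(x$sdr$start, x$sdr$end)
  cat(sprintf("SDR %s:%s-%s, ~%d Kb (%s bp)\n", x$sdr$chrom,
              format(x$sdr$start, big.mark = ","),
              format(x$sdr$end, big.mark = ","),
              round(.kb(len, 0)), format(len, big.mark = ",")))
  cat("components:\n")
  for (i in seq_len(nrow(x$components)))
    cat(sprintf("  %-22s %9d-%9d  ~%.1f kb\n", x$components$kind[i],
                x$components$start[i], x$components$end[i],
                x$components$length_kb[i]))
  if (length(x$excluded))
    cat(sprintf("  (%d haploid region(s) outside the span, excluded)\n",
                length(x$excluded)))
  invisible(x)
}

#' Fraction of a region covered by repeats
#'
#' Length of the union of repeat intervals intersected with the region,
#' divided by the region length. Overlapping repeats are collapsed first.
#'
#' @param region A `genomic_region` (or list with `chrom`, `start`, `end`).
#' @param repeats Data frame with `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @return Proportion in `[0, 1]`.
#' @export
repeat_fraction <- function(region, repeats) {
  r <- repeats[repeats$chrom == region$chrom, , drop = FALSE]
  if (nrow(r) == 0) return(0)
  ir <- IRanges::IRanges(start = r$start, end = r$end)
  ir <- IRanges::reduce(ir)
  reg <- IRanges::IRanges(start = region$start, end = region$end)
  ov <- IRanges::intersect(ir, reg)
  sum(IRanges::width(ov)) / interval_length(region$start, region$end)
}
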