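#' Length of a 1-based inclusive genomic interval
#'
#' All coordinates in sdrscan are 1-based and fully closed, the convention in
#' which published region positions are printed; the length of `[start, end]`
#' is therefore `end - start + 1`.
#'
#' @param start,end Integer positions, `start <= end`, both 1-based.
#' @return Interval length in bp (vectorised).
#' @examples
#' interval_length(2397919, 2419244) # 21326
#' interval_length(5, 5)             # 1
#' @export
interval_length <- function(start, end) {
  if (any(start < 1) || any(end < 1)) stop("coordinates are 1-based (>= 1)")
  if (any(start > end)) stop("start > end")
  end - start + 1
}

#' Construct a genomic region record
#'
#' A light-weight 1-based inclusive interval with a role tag used throughout
#' the pipeline: `sex_linked` (SNP-cluster derived), `sex_specific_haploid`
#' (coverage-derived hemizygous region), `sdr`, or `flank`.
#'
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive endpoints.
#' @param kind Role tag.
#' @param sex Optional sex tag for hemizygous regions (`"F"` or `"M"`).
#' @param provenance Optional record of contributing SNPs/regions.
#' @return An object of class `genomic_region`.
#' @export
genomic_region <- function(chrom, start, end,
                           kind = c("sex_linked", "sex_specific_haploid",
                                    "sdr", "flank"),
                           sex = NA_character_, provenance = NULL) {
  kind <- match.arg(kind)
  start <- as.integer(start); end <- as.integer(end)
  interval_length(start, end) # validates
  structure(list(chrom = chrom, start = start, end = end, kind = kind,
                 sex = sex, provenance = provenance),
            class = "genomic_region")
}

#' @export
print.genomic_region <- function(x, ...) {
  cat(sprintf("<%s> %s:%s-%s (%s bp)%s\n", x$kind, x$chrom,
              format(x$start, big.mark = ","), format(x$end, big.mark = ","),
              format(interval_length(x$start, x$end), big.mark = ","),
              if (!is.na(x$sex)) paste0(" [", x$sex, "]") else ""))
  invisible(x)
}

# merge sorted candidate positions into maximal runs with gap tolerance;
# returns data.frame(start, end) or empty
.merge_positions <- function(pos, merge_gap) {
  if (length(pos) == 0L) return(data.frame(start = integer(), end = integer()))
  pos <- sort(unique(as.integer(pos)))
  brk <- which(diff(pos) > merge_gap)
  starts <- pos[c(1L, brk + 1L)]
  ends <- pos[c(brk, length(pos))]
  data.frame(start = starts, end = ends)
}

# format bp as Kb, round half away from zero to `digits`
.kb <- function(bp, digits = 1) {
  x <- bp / 1000
  s <- sign(x)
  s * floor(abs(x) * 10^digits + 0.5) / 10^digits
}
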