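#' Scan a genome for paralogs of a query sequence
#'
#' Seed-and-extend homology search: exact k-mer seeds are grouped into
#' diagonal chains per chromosome and strand, and each chained window is
#' aligned to the query with an affine-gap local aligner (match +1,
#' mismatch -2, gap open -5, gap extend -2; a length-L gap costs
#' `5 + 2L`). Hits below `min_identity` percent or shorter than `min_len`
#' aligned query bases are dropped, as is the query's own locus.
#'
#' @param query Query sequence (ACGT string, length >= `min_len`).
#' @param genome Named character vector of chromosome sequences.
#' @param query_locus Optional `list(chrom=, start=)` giving the query's own
#'   position, used to exclude the self-hit and to report genomic query
#'   coordinates.
#' @param min_identity Minimum percent identity (matches over alignment
#'   columns).
#' @param min_len Minimum aligned query length (bp).
#' @param k Seed k-mer size.
#' @param min_seeds Minimum seeds per chain considered for extension.
#' @return Data frame of hits (`chrom`, `start`, `end`, `strand`,
#'   `query_start`, `query_end`, `identity`, `n_gaps`, `total_gap_bp`,
#'   `score`), ordered by score; the pairwise alignments are kept in
#'   `attr(, "alignments")`.
#' @export
paralog_scan <- function(query, genome, query_locus = NULL,
                         min_identity = 80, min_len = 200, k = 15,
                         min_seeds = 5) {
  query <- toupper(query)
  if (grepl("[^ACGT]", query)) stop("query contains non-ACGT symbols")
  if (nchar(query) < min_len) stop("query shorter than min_len")
  qlen <- nchar(query)
  hits <- list(); alns <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") query else .revcomp(query)
    starts <- seq_len(qlen - k + 1)
    kmers <- substring(q, starts, starts + k - 1)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers))
    for (cn in names(genome)) {
      m <- Biostrings::matchPDict(pd, Biostrings::DNAString(genome[[cn]]))
      sstart <- unlist(lapply(seq_along(m), function(i)
        Biostrings::start(m[[i]])), use.names = FALSE)
      qstart <- rep(starts, vapply(m, length, integer(1)))
      if (length(sstart) == 0) next
      ord <- order(sstart)
      sstart <- sstart[ord]; qstart <- qstart[ord]
      diag <- sstart - qstart
      # chain seeds: break when the subject jumps far or the diagonal shifts
      brk <- c(FALSE, diff(sstart) > qlen | abs(diff(diag)) > 200)
      chain <- cumsum(brk)
      for (ch in unique(chain)) {
        sel <- chain == ch
        if (sum(sel) < min_seeds) next
        ws <- max(1L, min(sstart[sel]) - min(qstart[sel]) - 50L)
        we <- min(nchar(genome[[cn]]),
                  max(sstart[sel]) + k + (qlen - min(qstart[sel])) + 50L)
        win <- substr(genome[[cn]], ws, we)
        al <- .sw_affine(q, win)
        cols <- nchar(al$qaligned)
        if (cols == 0) next
        qa <- strsplit(al$qaligned, "")[[1]]
        sa <- strsplit(al$saligned, "")[[1]]
        matches <- sum(qa == sa & qa != "-")
        identity <- 100 * matches / cols
        gap_run <- rle(qa == "-" | sa == "-")
        n_gaps <- sum(gap_run$values)
        q_span <- al$qend - al$qstart + 1
        s_span <- al$send - al$sstart + 1
        if (identity < min_identity || q_span < min_len) next
        gs <- ws + al$sstart - 1L; ge <- ws + al$send - 1L
        # query coordinates on the forward strand of the query
        if (strand == "+") { qs <- al$qstart; qe <- al$qend }
        else { qs <- qlen - al$qend + 1L; qe <- qlen - al$qstart + 1L }
        if (!is.null(query_locus) && cn == query_locus$chrom) {
          g0 <- query_locus$start
          ov <- min(ge, g0 + qlen - 1L) - max(gs, g0) + 1L
          if (ov > 0.5 * q_span) next # self-hit
        }
        hits[[length(hits) + 1]] <- data.frame(
          chrom = cn, start = gs, end = ge, strand = strand,
          query_start = qs, query_end = qe, identity = identity,
          n_gaps = n_gaps, total_gap_bp = abs(s_span - q_span),
          score = al$score, stringsAsFactors = FALSE)
        alns[[length(alns) + 1]] <- al[c("qaligned", "saligned", "score")]
      }
    }
  }
  if (length(hits) == 0) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), query_start = integer(),
                      query_end = integer(), identity = numeric(),
                      n_gaps = integer(), total_gap_bp = integer(),
                      score = numeric())
    attr(out, "alignments") <- list()
    return(out)
  }
  out <- do.call(rbind, hits)
  # collapse duplicate hits from adjacent chains
  key <- paste(out$chrom, out$start, out$end, out$strand)
  keep <- !duplicated(key)
  out <- out[keep, , drop = FALSE]
  alns <- alns[keep]
  ord <- order(-out$score)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alignments") <- alns[ord]
  out
}

#' Select paralog pairs usable as length-polymorphism sexing markers
#'
#' Keeps hits where exactly one copy lies inside a sex-limited haploid
#' region and the length difference is gel-resolvable
#' (`total_gap_bp >= min_diff_bp`); ranks by length difference then
#' identity, and reports conserved windows (runs of >= 20 identical
#' gap-free alignment columns) suitable for shared primers.
#'
#' @param hits Data frame from [paralog_scan()] (with its `alignments`
#'   attribute).
#' @param query_locus `list(chrom=, start=, end=)` of the query copy.
#' @param haploid_regions List of `sex_specific_haploid` `genomic_region`s.
#' @param min_diff_bp Minimum length difference (default 20).
#' @return Ranked data frame of qualifying hits with a `conserved_windows`
#'   list-column (each a data frame of query-coordinate windows); zero rows
#'   with an `explanation` attribute when nothing qualifies.
#' @export
select_marker_locus <- function(hits, query_locus, haploid_regions,
                                min_diff_bp = 20) {
  inside <- function(chrom, s, e) {
    any(vapply(haploid_regions, function(r)
      r$chrom == chrom && s >= r$start && e <= r$end, logical(1)))
  }
  q_in <- inside(query_locus$chrom, query_locus$start, query_locus$end)
  if (nrow(hits) == 0) {
    attr(hits, "explanation") <- "no paralog hits"
    return(hits)
  }
  s_in <- vapply(seq_len(nrow(hits)), function(i)
    inside(hits$chrom[i], hits$start[i], hits$end[i]), logical(1))
  ok <- xor(q_in, s_in) & hits$total_gap_bp >= min_diff_bp
  alns <- attr(hits, "alignments")
  out <- hits[ok, , drop = FALSE]
  if (nrow(out) == 0) {
    attr(out, "explanation") <- if (!any(xor(q_in, s_in)))
      "no hit with exactly one copy inside a haploid region"
    else sprintf("no qualifying hit reaches min_diff_bp = %d (gel-unresolvable)",
                 min_diff_bp)
    return(out)
  }
  out$conserved_windows <- lapply(which(ok), function(i) {
    .conserved_windows(alns[[i]], hits$query_start[i], min_len = 20)
  })
  ord <- order(-out$total_gap_bp, -out$identity)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# runs of identical gap-free columns, reported in query coordinates
.conserved_windows <- function(al, query_start, min_len = 20) {
  qa <- strsplit(al$qaligned, "")[[1]]
  sa <- strsplit(al$saligned, "")[[1]]
  same <- qa == sa & qa != "-"
  qpos <- cumsum(qa != "-") + query_start - 1L
  r <- rle(same)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values & r$lengths >= min_len
  data.frame(query_start = qpos[starts[sel]], query_end = qpos[ends[sel]],
             length = r$lengths[sel])
}

# primer occurrences on the plus strand; 3'-end mismatch disallowed
.primer_sites <- function(seq, primer, max_mismatch) {
  subj <- Biostrings::DNAString(seq)
  m <- Biostrings::matchPattern(Biostrings::DNAString(primer), subj,
                                max.mismatch = max_mismatch)
  st <- Biostrings::start(m); en <- Biostrings::end(m)
  if (max_mismatch > 0 && length(st)) {
    last <- substr(primer, nchar(primer), nchar(primer))
    keep <- substring(seq, en, en) == last
    st <- st[keep]; en <- en[keep]
  }
  data.frame(start = st, end = en)
}

#' In-silico PCR
#'
#' Predicts amplicons of a primer pair against a genome: the forward primer
#' matched on the plus strand with the reverse-complemented reverse primer
#' downstream (and the symmetric minus-strand orientation). Product length
#' is the inclusive span between the two primers' outer 5' ends. Primer
#' matches are exact by default; with `max_mismatch > 0`, mismatches at the
#' 3' terminus are still disallowed (they abolish extension).
#'
#' @param genome Named character vector of sequences.
#' @param primers List or one-row data frame with `forward` and `reverse`
#'   (both written 5' to 3' on their own strand), optionally `name`.
#' @param max_mismatch Mismatches tolerated per primer (default 0).
#' @param max_product Maximum product length (bp).
#' @return Data frame of class `amplicon_prediction`: `template`, `start`,
#'   `end`, `length`, `orientation`.
#' @export
in_silico_pcr <- function(genome, primers, max_mismatch = 0,
                          max_product = 3000) {
  fwd <- toupper(primers$forward[[1]]); rev <- toupper(primers$reverse[[1]])
  if (grepl("[^ACGT]", fwd) || grepl("[^ACGT]", rev))
    stop("primers must be ACGT only")
  if (nchar(fwd) < 15 || nchar(rev) < 15) stop("primers must be >= 15 nt")
  out <- list()
  for (cn in names(genome)) {
    seq <- genome[[cn]]
    # plus orientation: fwd reads plus strand, rc(rev) downstream
    f <- .primer_sites(seq, fwd, max_mismatch)
    r <- .primer_sites(seq, .revcomp(rev), max_mismatch)
    for (i in seq_len(nrow(f))) {
      down <- r$end[r$start > f$start[i]]
      for (e in down) {
        len <- e - f$start[i] + 1
        if (len <= max_product)
          out[[length(out) + 1]] <- data.frame(
            template = cn, start = f$start[i], end = e, length = len,
            orientation = "+", stringsAsFactors = FALSE)
      }
    }
    # minus orientation: rev reads plus strand, rc(fwd) downstream
    f2 <- .primer_sites(seq, rev, max_mismatch)
    r2 <- .primer_sites(seq, .revcomp(fwd), max_mismatch)
    for (i in seq_len(nrow(f2))) {
      down <- r2$end[r2$start > f2$start[i]]
      for (e in down) {
        len <- e - f2$start[i] + 1
        if (len <= max_product)
          out[[length(out) + 1]] <- data.frame(
            template = cn, start = f2$start[i], end = e, length = len,
            orientation = "-", stringsAsFactors = FALSE)
      }
    }
    if (length(out) > 100) stop("non-specific primers (> 100 products)")
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(template = character(), start = integer(), end = integer(),
               length = integer(), orientation = character())
  # the same physical amplicon is found in both orientations; deduplicate
  res <- res[!duplicated(res[, c("template", "start", "end")]), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("amplicon_prediction", "data.frame")
  res
}

#' Expected gel band pattern per genetic sex
#'
#' Maps each predicted amplicon's template locus to a per-sex copy number
#' (inside a sex-limited haploid region: 1 copy in the carrying sex, 0 in
#' the other; elsewhere: 2 in both) and reports the multiset of band
#' lengths per sex. A band at copy number 1 is annotated as reduced dosage
#' -- on a gel, visibly fainter than a 2-copy band of similar size.
#'
#' @param predictions Data frame from [in_silico_pcr()].
#' @param haploid_regions List of `sex_specific_haploid` `genomic_region`s
#'   (each carries its sex tag).
#' @return An object of class `band_pattern`: list with `bands` (data
#'   frame: `sex`, `length`, `copy_number`, `template`, `start`, `end`) and
#'   `informative` (`FALSE` when both sexes show identical patterns).
#' @export
band_pattern <- function(predictions, haploid_regions) {
  rows <- list()
  for (i in seq_len(nrow(predictions))) {
    cn <- c(F = 2L, M = 2L)
    for (r in haploid_regions) {
      if (r$chrom == predictions$template[i] &&
          predictions$start[i] >= r$start && predictions$end[i] <= r$end) {
        if (is.na(r$sex)) { cn <- c(F = NA_integer_, M = NA_integer_) }
        else {
          cn[r$sex] <- 1L
          cn[setdiff(c("F", "M"), r$sex)] <- 0L
        }
        break
      }
    }
    for (sx in c("F", "M")) {
      if (!is.na(cn[sx]) && cn[sx] == 0L) next
      rows[[length(rows) + 1]] <- data.frame(
        sex = sx, length = predictions$length[i], copy_number = cn[[sx]],
        template = predictions$template[i], start = predictions$start[i],
        end = predictions$end[i], stringsAsFactors = FALSE)
    }
  }
  bands <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sex = character(), length = integer(), copy_number = integer(),
               template = character(), start = integer(), end = integer())
  bands <- bands[order(bands$sex, -bands$length), , drop = FALSE]
  rownames(bands) <- NULL
  pat <- function(sx) sort(bands$length[bands$sex == sx])
  structure(list(bands = bands,
                 informative = !identical(pat("F"), pat("M"))),
            class = "band_pattern")
}

#' @export
print.band_pattern <- function(x, ...) {
  for (sx in c("F", "M")) {
    b <- x$bands[x$bands$sex == sx, , drop = FALSE]
    cat(sprintf("%s: %s\n", sx, if (nrow(b) == 0) "(no product)" else
      paste(sprintf("%d bp (x%s)", b$length,
                    ifelse(is.na(b$copy_number), "?", b$copy_number)),
            collapse = ", ")))
  }
  if (!x$informative) cat("marker uninformative: identical patterns\n")
  invisible(x)
}
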