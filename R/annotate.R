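#' Read a reference genome FASTA
#' @param path FASTA path.
#' @return Named character vector of sequences (upper case).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/exon/CDS/UTR features into the internal gene-model list
#' used by [classify_variant()] and [genes_in_region()].
#'
#' @param path GFF3 path.
#' @return An object of class `gene_models`.
#' @export
read_gene_models <- function(path) {
  g <- ape::read.gff(path, na.strings = c(".", "?"), GFF3 = TRUE)
  names(g) <- tolower(names(g))
  gene_models(data.frame(seqid = as.character(g$seqid), type = as.character(g$type),
                         start = g$start, end = g$end,
                         strand = as.character(g$strand),
                         phase = as.character(g$phase),
                         attributes = as.character(g$attributes),
                         stringsAsFactors = FALSE))
}

.gff_attr <- function(attr, key) {
  m <- regmatches(attr, regexec(paste0("(?:^|;)", key, "=([^;]+)"), attr))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
         character(1))
}

#' Build gene models from a GFF-style data frame
#'
#' @param gff Data frame with columns `seqid`, `type`, `start`, `end`,
#'   `strand`, `phase`, `attributes` (`ID=`/`Parent=` keys).
#' @return An object of class `gene_models`: a list of genes, each with
#'   `id`, `chrom`, `strand`, `start`, `end` and `transcripts` (each with
#'   ordered `exons`, `cds`, `utr5`, `utr3` data frames of genomic
#'   intervals).
#' @export
gene_models <- function(gff) {
  genes <- gff[gff$type == "gene", , drop = FALSE]
  mrnas <- gff[gff$type == "mRNA", , drop = FALSE]
  gene_ids <- .gff_attr(genes$attributes, "ID")
  mrna_ids <- .gff_attr(mrnas$attributes, "ID")
  mrna_parent <- .gff_attr(mrnas$attributes, "Parent")
  feat <- gff[gff$type %in% c("exon", "CDS", "five_prime_UTR",
                              "three_prime_UTR"), , drop = FALSE]
  feat_parent <- .gff_attr(feat$attributes, "Parent")
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    tix <- which(mrna_parent == gene_ids[i])
    transcripts <- lapply(tix, function(t) {
      fx <- feat[feat_parent == mrna_ids[t], , drop = FALSE]
      grab <- function(ty) {
        d <- fx[fx$type == ty, c("start", "end", "phase"), drop = FALSE]
        d <- d[order(d$start), , drop = FALSE]
        rownames(d) <- NULL
        d
      }
      list(id = mrna_ids[t], exons = grab("exon"), cds = grab("CDS"),
           utr5 = grab("five_prime_UTR"), utr3 = grab("three_prime_UTR"))
    })
    out[[i]] <- list(id = gene_ids[i], chrom = genes$seqid[i],
                     strand = genes$strand[i], start = genes$start[i],
                     end = genes$end[i], transcripts = transcripts)
  }
  structure(out, class = "gene_models")
}

# translate a codon string via the standard genetic code
.translate_codon <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

# coding-strand sequence of the CDS of a transcript, plus a map from
# genomic position to CDS coordinate (1-based along translation direction)
.cds_sequence <- function(tr, chrom_seq, strand) {
  segs <- tr$cds
  pieces <- substring(chrom_seq, segs$start, segs$end)
  if (strand == "+") {
    seq <- paste(pieces, collapse = "")
    gpos <- unlist(mapply(seq.int, segs$start, segs$end, SIMPLIFY = FALSE))
  } else {
    seq <- .revcomp(paste(pieces, collapse = ""))
    gpos <- rev(unlist(mapply(seq.int, segs$start, segs$end, SIMPLIFY = FALSE)))
  }
  list(seq = seq, gpos = gpos)
}

.in_any <- function(pos, segs) {
  nrow(segs) > 0 && any(pos >= segs$start & pos <= segs$end)
}

#' Classify a variant against gene models
#'
#' Assigns exactly one category per variant with within-transcript
#' precedence CDS > UTR > intron; variants outside every transcript are
#' `upstream`/`downstream` when within `flank_bp` of a gene span (side
#' resolved by gene strand, distance measured from the span boundary), else
#' `intergenic`. Single-base CDS substitutions are translated on the coding
#' strand via the standard genetic code to give
#' `exon_synonymous`/`exon_missense`/`exon_nonsense`. Overlapping genes are
#' resolved by the highest-precedence category, ties by smallest gene id.
#'
#' @param chrom,pos,ref,alt Variant (1-based; `ref`/`alt` single bases for
#'   coding-effect calls).
#' @param models A `gene_models` object.
#' @param reference Named character vector of chromosome sequences.
#' @param flank_bp Up/downstream window (default 5000).
#' @return List with `category`, `gene` (id or `NA`) and `distance`
#'   (bp to the gene span for up/downstream, else `NA`).
#' @export
classify_variant <- function(chrom, pos, ref, alt, models, reference,
                             flank_bp = 5000) {
  chrom_seq <- reference[[chrom]]
  if (is.null(chrom_seq)) stop("chromosome ", chrom, " not in reference")
  base <- substr(chrom_seq, pos, pos)
  if (nchar(ref) == 1 && base != ref)
    stop(sprintf("reference mismatch at %s:%d (VCF %s, FASTA %s)",
                 chrom, pos, ref, base))
  rank <- c(exon_nonsense = 1, exon_missense = 2, exon_synonymous = 3,
            five_utr = 4, three_utr = 4, intron = 5)
  best <- NULL
  best_rank <- Inf
  for (g in models) {
    if (g$chrom != chrom || pos < g$start || pos > g$end) next
    for (tr in g$transcripts) {
      cat_here <- NULL
      if (.in_any(pos, tr$cds)) {
        if (nchar(ref) == 1 && nchar(alt) == 1) {
          cs <- .cds_sequence(tr, chrom_seq, g$strand)
          ci <- match(pos, cs$gpos)
          codon_i <- (ci - 1) %/% 3
          cod <- substr(cs$seq, codon_i * 3 + 1, codon_i * 3 + 3)
          within <- ci - codon_i * 3
          sub_base <- if (g$strand == "+") alt else chartr("ACGT", "TGCA", alt)
          cod_alt <- cod
          substr(cod_alt, within, within) <- sub_base
          aa0 <- .translate_codon(cod); aa1 <- .translate_codon(cod_alt)
          cat_here <- if (is.na(aa0) || is.na(aa1)) "exon_missense"
          else if (aa0 == aa1) "exon_synonymous"
          else if (aa1 == "*") "exon_nonsense"
          else "exon_missense"
        } else cat_here <- "exon_missense" # indel in CDS: positional only
      } else if (.in_any(pos, tr$utr5)) cat_here <- "five_utr"
      else if (.in_any(pos, tr$utr3)) cat_here <- "three_utr"
      else if (.in_any(pos, tr$exons)) {
        # exonic but outside CDS and annotated UTRs: side of the CDS decides
        warning(sprintf("%s:%d exonic but outside CDS/UTR in %s; using nearest UTR side",
                        chrom, pos, tr$id))
        cds_lo <- min(tr$cds$start); cds_hi <- max(tr$cds$end)
        left <- pos < cds_lo
        cat_here <- if ((left && g$strand == "+") || (!left && g$strand == "-"))
          "five_utr" else "three_utr"
      } else cat_here <- "intron"
      r <- rank[[cat_here]]
      if (r < best_rank || (r == best_rank && g$id < best$gene)) {
        best <- list(category = cat_here, gene = g$id, distance = NA_real_)
        best_rank <- r
      }
    }
  }
  if (!is.null(best)) return(best)
  # outside all genes: nearest gene within flank_bp
  dists <- vapply(models, function(g) {
    if (g$chrom != chrom) return(NA_real_)
    if (pos < g$start) g$start - pos else if (pos > g$end) pos - g$end else 0
  }, numeric(1))
  ok <- which(!is.na(dists) & dists <= flank_bp & dists > 0)
  if (length(ok) == 0)
    return(list(category = "intergenic", gene = NA_character_,
                distance = NA_real_))
  ids <- vapply(models[ok], `[[`, character(1), "id")
  sel <- ok[order(dists[ok], ids)][1]
  g <- models[[sel]]
  before <- pos < g$start
  category <- if ((before && g$strand == "+") || (!before && g$strand == "-"))
    "upstream" else "downstream"
  list(category = category, gene = g$id, distance = dists[sel])
}

#' Annotate a set of variants
#'
#' Vectorised wrapper over [classify_variant()].
#'
#' @param sites Data frame with `chrom`, `pos`, `ref`, `alt`.
#' @param models A `gene_models` object.
#' @param reference Named character vector of sequences.
#' @param flank_bp Up/downstream window.
#' @return Data frame: the input plus `category`, `gene`, `distance`.
#' @export
annotate_variants <- function(sites, models, reference, flank_bp = 5000) {
  res <- lapply(seq_len(nrow(sites)), function(i)
    classify_variant(sites$chrom[i], sites$pos[i], sites$ref[i],
                     sites$alt[i], models, reference, flank_bp))
  cbind(sites,
        category = vapply(res, `[[`, character(1), "category"),
        gene = vapply(res, `[[`, character(1), "gene"),
        distance = vapply(res, `[[`, numeric(1), "distance"))
}

#' Genes overlapping a region
#'
#' Closed-interval intersection of gene spans with a region.
#'
#' @param region A `genomic_region` (or list with `chrom`, `start`, `end`).
#' @param models A `gene_models` object.
#' @return Data frame: `gene`, `start`, `end`, `strand`, `overlap_bp`.
#' @export
genes_in_region <- function(region, models) {
  rows <- lapply(models, function(g) {
    if (g$chrom != region$chrom) return(NULL)
    lo <- max(g$start, region$start); hi <- min(g$end, region$end)
    if (lo > hi) return(NULL)
    data.frame(gene = g$id, start = g$start, end = g$end, strand = g$strand,
               overlap_bp = hi - lo + 1, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(), start = integer(), end = integer(),
                      strand = character(), overlap_bp = integer())
  rownames(out) <- NULL
  out
}

#' Per-exon nucleotide identity between two transcripts
#'
#' Pairs exons by order from the 3' end (the conserved end of degenerating
#' paralogs) and computes, per pair, a global pairwise alignment identity:
#' matches over alignment columns, gap columns counting as mismatches. The
#' reported average is the unweighted mean over pairs.
#'
#' @param query_exons,subject_exons Character vectors of exon sequences in
#'   transcription order (5' to 3').
#' @return List with `pairs` (data frame: query/subject index, lengths,
#'   `identity` in percent) and `mean_identity`.
#' @export
exon_identity_table <- function(query_exons, subject_exons) {
  query_exons <- query_exons[nchar(query_exons) > 0]
  subject_exons <- subject_exons[nchar(subject_exons) > 0]
  k <- min(length(query_exons), length(subject_exons))
  if (k == 0) stop("no non-empty exons to pair")
  qi <- length(query_exons) - k + seq_len(k)
  si <- length(subject_exons) - k + seq_len(k)
  idents <- numeric(k)
  for (j in seq_len(k)) {
    al <- Biostrings::pairwiseAlignment(
      query_exons[qi[j]], subject_exons[si[j]], type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -2, baseOnly = TRUE),
      gapOpening = 5, gapExtension = 2)
    pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    idents[j] <- 100 * sum(pa == sa & pa != "-") / length(pa)
  }
  pairs <- data.frame(query_exon = qi, subject_exon = si,
                      query_len = nchar(query_exons[qi]),
                      subject_len = nchar(subject_exons[si]),
                      identity = idents)
  list(pairs = pairs, mean_identity = mean(idents))
}
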