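# toy single-transcript gene on a synthetic chromosome; plus or minus strand
toy_gene <- function(strand = "+", cds = c(111L, 170L),
                     exon = c(101L, 180L), gene = c(95L, 190L)) {
  gff <- data.frame(
    seqid = "c", source = "t",
    type = c("gene", "mRNA", "exon", "CDS", "five_prime_UTR",
             "three_prime_UTR"),
    start = c(gene[1], gene[1], exon[1], cds[1],
              if (strand == "+") exon[1] else cds[2] + 1L,
              if (strand == "+") cds[2] + 1L else exon[1]),
    end = c(gene[2], gene[2], exon[2], cds[2],
            if (strand == "+") cds[1] - 1L else exon[2],
            if (strand == "+") exon[2] else cds[1] - 1L),
    score = ".", strand = strand, phase = c(".", ".", ".", "0", ".", "."),
    attributes = c("ID=g1;Name=g1", "ID=g1.t1;Parent=g1",
                   rep("Parent=g1.t1", 4)),
    stringsAsFactors = FALSE)
  gene_models(gff)
}

chrom_with <- function(at, what, len = 10000) {
  s <- paste(rep("A", len), collapse = "")
  substr(s, at, at + nchar(what) - 1L) <- what
  c(c = s)
}

test_that("coding substitutions are classified via the standard genetic code", {
  models <- toy_gene("+")
  ref <- chrom_with(111, "GATTTT") # codon 1 GAT (Asp), codon 2 TTT (Phe)
  # third-position GAT -> GAC: synonymous
  r <- classify_variant("c", 113, "T", "C", models, ref)
  expect_equal(r$category, "exon_synonymous")
  expect_equal(r$gene, "g1")
  # GAT -> GCT: missense (Asp -> Ala)
  expect_equal(classify_variant("c", 112, "A", "C", models, ref)$category,
               "exon_missense")
  # second codon TGT (Cys) -> TGA: stop gained
  ref2 <- chrom_with(111, "GATTGT")
  expect_equal(classify_variant("c", 116, "T", "A", models, ref2)$category,
               "exon_nonsense")
})

test_that("nonsense and strand handling agree with direct translation", {
  models <- toy_gene("+")
  ref <- chrom_with(111, "TGCAAA") # TGC (Cys), AAA (Lys)
  # TGC -> TGA: stop gained at third position
  expect_equal(classify_variant("c", 113, "C", "A", models, ref)$category,
               "exon_nonsense")
  # minus strand: genomic CDS interval holds the reverse complement
  mm <- toy_gene("-")
  # coding codon GAT occupies genomic 168..170 as ATC on the plus strand
  refm <- chrom_with(168, "ATC")
  # genomic 168 A->G => coding third position T->C: GAT -> GAC synonymous
  expect_equal(classify_variant("c", 168, "A", "G", mm, refm)$category,
               "exon_synonymous")
})

test_that("positional categories follow precedence and the 5 kb flank rule", {
  models <- toy_gene("+")
  ref <- chrom_with(111, "GAT")
  expect_equal(classify_variant("c", 105, "A", "G", models, ref)$category,
               "five_utr")
  expect_equal(classify_variant("c", 175, "A", "G", models, ref)$category,
               "three_utr")
  # inside the gene span but outside the exon: intron-like
  expect_equal(classify_variant("c", 185, "A", "G", models, ref)$category,
               "intron")
  # 23 bp upstream of the gene span on the plus strand
  up <- classify_variant("c", 72, "A", "G", models, ref)
  expect_equal(up$category, "upstream")
  expect_equal(up$distance, 23)
  dn <- classify_variant("c", 200, "A", "G", models, ref)
  expect_equal(dn$category, "downstream")
  # beyond 5 kb: intergenic
  expect_equal(classify_variant("c", 5300, "A", "G", models, ref)$category,
               "intergenic")
  # reference mismatch is an error naming the site
  expect_error(classify_variant("c", 113, "G", "C", models, ref),
               "mismatch at c:113")
})

test_that("coding-effect calls agree with a brute-force translation oracle", {
  skip_if_not_installed("seqinr")
  set.seed(55)
  n_codons <- 50
  bases <- c("A", "C", "G", "T")
  codons <- replicate(n_codons, paste(sample(bases, 3, TRUE), collapse = ""))
  cds_seq <- paste(codons, collapse = "")
  cds_len <- nchar(cds_seq)
  models <- toy_gene("+", cds = c(111L, 110L + cds_len),
                     exon = c(101L, 120L + cds_len),
                     gene = c(95L, 130L + cds_len))
  ref <- chrom_with(111, cds_seq)
  for (ci in seq_len(n_codons)) {
    for (within in 1:3) {
      gpos <- 110L + (ci - 1L) * 3L + within
      refb <- substr(ref[["c"]], gpos, gpos)
      for (alt in setdiff(bases, refb)) {
        got <- classify_variant("c", gpos, refb, alt, models, ref)$category
        cod <- codons[ci]
        cod_alt <- cod
        substr(cod_alt, within, within) <- alt
        aa0 <- seqinr::translate(strsplit(cod, "")[[1]])
        aa1 <- seqinr::translate(strsplit(cod_alt, "")[[1]])
        want <- if (aa0 == aa1) "exon_synonymous"
        else if (aa1 == "*") "exon_nonsense" else "exon_missense"
        expect_equal(got, want,
                     label = sprintf("%s->%s at codon %d pos %d (got %s)",
                                     cod, cod_alt, ci, within, got))
      }
    }
  }
})

test_that("every variant receives exactly one category and counts partition", {
  co <- cached_cohort(101)
  models <- gene_models(co$genes)
  sl <- rbind(co$genotypes$sites[co$genotypes$sites$chrom == "chr2", ],
              co$genotypes$sites[co$genotypes$sites$chrom == "chr1", ][1:5, ])
  ann <- annotate_variants(sl, models, co$reference)
  expect_equal(nrow(ann), 25)
  expect_false(anyNA(ann$category))
  cats <- c("exon_synonymous", "exon_missense", "exon_nonsense", "five_utr",
            "three_utr", "intron", "upstream", "downstream", "intergenic")
  expect_true(all(ann$category %in% cats))
  expect_equal(sum(table(ann$category)), 25)
  up <- ann$category %in% c("upstream", "downstream")
  expect_true(all(ann$distance[up] <= 5000))
})

test_that("GFF3 written by the simulator round-trips through the reader", {
  co <- cached_cohort(101)
  d <- withr::local_tempdir()
  write_cohort(co, d)
  m1 <- read_gene_models(file.path(d, "genes.gff3"))
  m2 <- gene_models(co$genes)
  expect_equal(length(m1), length(m2))
  expect_equal(vapply(m1, `[[`, character(1), "id"),
               vapply(m2, `[[`, character(1), "id"))
  i <- which(vapply(m1, `[[`, character(1), "id") == "cyp19b")
  expect_equal(m1[[i]]$transcripts[[1]]$cds$start,
               m2[[i]]$transcripts[[1]]$cds$start)
})

test_that("gene census over a region uses closed-interval overlap", {
  models <- gene_models(data.frame(
    seqid = "c", source = "t", type = "gene",
    start = c(100L, 500L), end = c(200L, 700L), score = ".", strand = "+",
    phase = ".", attributes = c("ID=a", "ID=b"), stringsAsFactors = FALSE))
  reg <- genomic_region("c", 150, 499, "sdr", provenance = list(x = 1))
  g <- genes_in_region(reg, models)
  expect_equal(g$gene, "a") # gene b starts at end+1 -> excluded
  expect_equal(g$overlap_bp, 51)
  # the synthetic SDR carries its planted gene count
  co <- cached_cohort(101)
  g2 <- genes_in_region(co$truth$expected_sdr, gene_models(co$genes))
  expect_equal(sort(g2$gene), sort(co$truth$sdr_genes))
  expect_equal(nrow(g2), 7)
})

test_that("exon identity pairs from the 3' end and counts gap columns", {
  r <- exon_identity_table(c("ACGTACGT"), c("ACGTACGT"))
  expect_equal(r$mean_identity, 100)
  expect_equal(exon_identity_table("ACGT", "ACGA")$mean_identity, 75)
  # disjoint alphabets: near zero
  expect_lt(exon_identity_table("AAAAAAAA", "CCCCCCCC")$mean_identity, 10)
  # unequal exon counts: the trailing (3') exons are paired
  r2 <- exon_identity_table(c("TTTT", "ACGT", "GGGG"), c("ACGA", "GGGG"))
  expect_equal(r2$pairs$query_exon, c(2, 3))
  expect_equal(r2$pairs$identity, c(75, 100))
  expect_equal(r2$mean_identity, 87.5)
})
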