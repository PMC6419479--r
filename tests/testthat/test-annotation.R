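test_that("strand correction relabels substitutions into sense alphabet", {
  expect_equal(strand_correct_type("A", "G", "+"), "A-to-G")
  expect_equal(strand_correct_type("T", "C", "-"), "A-to-G")
  expect_equal(strand_correct_type("C", "T", "-"), "G-to-A")
  expect_equal(strand_correct_type("A", "G", c("+", "-")), "unassigned")
  expect_equal(strand_correct_type("A", "G", character()), "unassigned")
  expect_error(strand_correct_type("A", "A", "+"), "differ")
})

test_that("strand correction round-trips through reverse complement", {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (ref in names(comp)) for (alt in setdiff(names(comp), ref)) {
    plus <- strand_correct_type(ref, alt, "+")
    minus <- strand_correct_type(comp[[ref]], comp[[alt]], "-")
    expect_equal(plus, minus)
  }
})

test_that("region classification follows the stated precedence", {
  gm <- tiny_gene_models()
  # pos in gA's intron AND gB's CDS -> exonic, gene gB
  r <- classify_region("chr1", 300L, gm)
  expect_equal(r$region, "exonic")
  expect_equal(r$gene_ids, "gB")
  # plain CDS
  expect_equal(classify_region("chr1", 150L, gm)$region, "exonic")
  # UTRs
  expect_equal(classify_region("chr1", 110L, gm)$region, "UTR5")
  expect_equal(classify_region("chr1", 550L, gm)$region, "UTR3")
  # ncRNA exon
  expect_equal(classify_region("chr1", 2100L, gm)$region, "ncRNA")
  # deep intron of gA (away from gB and junctions)
  expect_equal(classify_region("chr1", 240L, gm)$region, "intronic")
  # near-junction intronic position classifies as splicing
  expect_equal(classify_region("chr1", 203L, gm)$region, "splicing")
  # no transcript
  r0 <- classify_region("chr1", 5000L, gm)
  expect_equal(r0$region, "intergenic")
  expect_length(r0$gene_ids, 0L)
})

test_that("codon consequences match a full-translation oracle for all 576 edits", {
  codons <- apply(expand.grid(BASES <- c("A", "C", "G", "T"),
                              BASES, BASES)[, 3:1], 1, paste, collapse = "")
  cds_seq <- paste(codons, collapse = "")
  n <- nchar(cds_seq)
  flank <- paste(rep("A", 10), collapse = "")
  genome <- Biostrings::DNAStringSet(c(chrT = paste0(flank, cds_seq, flank)))
  gm <- gene_models(
    data.frame(gene_id = "g1", transcript_id = "t1", chrom = "chrT",
               strand = "+", start = 11L, end = 10L + n,
               biotype = "protein_coding"),
    data.frame(transcript_id = "t1", type = c("exon", "CDS"), chrom = "chrT",
               start = 11L, end = 10L + n))
  aa_of <- function(s) as.character(Biostrings::translate(
    Biostrings::DNAString(s), no.init.codon = TRUE))
  checked <- 0L
  for (ci in seq_along(codons)) {
    for (off in 1:3) {
      idx <- (ci - 1L) * 3L + off
      ref <- substr(cds_seq, idx, idx)
      for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
        got <- coding_consequence("chrT", 10L + idx, ref, alt, gm, "t1",
                                  genome)
        mutated <- codons[ci]
        substr(mutated, off, off) <- alt
        aa_ref <- aa_of(codons[ci]); aa_alt <- aa_of(mutated)
        want <- if (aa_ref == aa_alt) "synonymous"
        else if (aa_alt == "*") "stopgain"
        else if (aa_ref == "*") "stoploss"
        else "nonsynonymous"
        expect_equal(got$consequence, want,
                     info = sprintf("%s pos %d -> %s", codons[ci], off, alt))
        expect_equal(got$aa_change, paste0(aa_ref, "→", aa_alt))
        checked <- checked + 1L
      }
    }
  }
  expect_equal(checked, 576L)
})

test_that("the hallmark Y-to-C and K-to-R recoding edits are reproduced", {
  genome <- Biostrings::DNAStringSet(c(chrT = "GTACAAAGG"))
  gm <- gene_models(
    data.frame(gene_id = "g1", transcript_id = "t1", chrom = "chrT",
               strand = "+", start = 2L, end = 7L, biotype = "protein_coding"),
    data.frame(transcript_id = "t1", type = c("exon", "CDS"), chrom = "chrT",
               start = 2L, end = 7L))
  # TAC (Tyr) edited A>G at codon position 2 -> TGC (Cys)
  yc <- coding_consequence("chrT", 3L, "A", "G", gm, "t1", genome)
  expect_equal(yc$consequence, "nonsynonymous")
  expect_equal(yc$aa_change, "Y→C")
  # AAA (Lys) edited A>G at codon position 2 -> AGA (Arg)
  genome2 <- Biostrings::DNAStringSet(c(chrT = "AAAAGG"))
  gm2 <- gene_models(
    data.frame(gene_id = "g1", transcript_id = "t1", chrom = "chrT",
               strand = "+", start = 1L, end = 3L, biotype = "protein_coding"),
    data.frame(transcript_id = "t1", type = c("exon", "CDS"), chrom = "chrT",
               start = 1L, end = 3L))
  kr <- coding_consequence("chrT", 2L, "A", "G", gm2, "t1", genome2)
  expect_equal(kr$consequence, "nonsynonymous")
  expect_equal(kr$aa_change, "K→R")
  # synonymous third-position edit: GGA -> GGG
  genome3 <- Biostrings::DNAStringSet(c(chrT = "GGATAA"))
  gm3 <- gene_models(
    data.frame(gene_id = "g1", transcript_id = "t1", chrom = "chrT",
               strand = "+", start = 1L, end = 6L, biotype = "protein_coding"),
    data.frame(transcript_id = "t1", type = c("exon", "CDS"), chrom = "chrT",
               start = 1L, end = 6L))
  gg <- coding_consequence("chrT", 3L, "A", "G", gm3, "t1", genome3)
  expect_equal(gg$consequence, "synonymous")
})

test_that("minus-strand consequences use the reverse-complemented codon", {
  # minus-strand CDS; genomic plus strand reads the reverse complement.
  # transcript sense CDS = TAC TAA? keep it simple: sense CDS "TACGGG"
  sense <- "TACGGG"
  plus <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(sense)))  # "CCCGTA"
  genome <- Biostrings::DNAStringSet(c(chrT = plus))
  gm <- gene_models(
    data.frame(gene_id = "g1", transcript_id = "t1", chrom = "chrT",
               strand = "-", start = 1L, end = 6L, biotype = "protein_coding"),
    data.frame(transcript_id = "t1", type = c("exon", "CDS"), chrom = "chrT",
               start = 1L, end = 6L))
  # sense TAC codon position 2 (A) sits at genomic pos 5 (plus base T);
  # sense A>G is genomic T>C
  cc <- coding_consequence("chrT", 5L, "T", "C", gm, "t1", genome)
  expect_equal(cc$consequence, "nonsynonymous")
  expect_equal(cc$aa_change, "Y→C")
})

test_that("consequence calling refuses positions outside the CDS", {
  gm <- tiny_gene_models()
  genome <- Biostrings::DNAStringSet(
    c(chr1 = paste(rep("A", 3000), collapse = "")))
  expect_error(coding_consequence("chr1", 110L, "A", "G", gm, "tA", genome),
               "not inside the CDS")
})

test_that("annotation recovers truth types, regions and strands end to end", {
  sim <- small_sim()
  cand <- detect_rdds(sim$dna, sim$rna[[1]], filter_config(),
                      sim$reference$models)
  pass <- cand[cand$pass, ]
  ann <- annotate_rdds(pass, sim$reference$models, sim$reference$sequences)
  truth <- sim$truth
  m <- match(paste(ann$chrom, ann$pos), paste(truth$chrom, truth$pos))
  expect_true(all(!is.na(m)))  # small_sim has no false passes
  typed <- ann$rdd_type != "unassigned"
  expect_true(all(ann$rdd_type[typed] == truth$rdd_type[m][typed]))
  # region classes agree with the generator's placement classes
  map <- c(exonic = "exonic", utr5 = "UTR5", utr3 = "UTR3",
           intronic = "intronic", ncRNA = "ncRNA", intergenic = "intergenic")
  expect_true(all(ann$region == unname(map[truth$region_class[m]])))
})
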