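# run the cascade on one hand-built RNA site over a clean hom-ref DNA site
detect_one <- function(rna_counts, dna_depth = 30L, ref = "A", pos = 100L,
                       gm = NULL, config = filter_config(), baseq = 40,
                       dna_counts = NULL) {
  dna <- if (is.null(dna_counts)) dna_row(pos = pos, ref = ref,
                                          depth = dna_depth)
  else pileup_row(pos = pos, ref = ref, counts = dna_counts,
                  sample_id = "DNA")
  rna <- pileup_row(pos = pos, ref = ref, counts = rna_counts,
                    sample_id = "RNA_rep1", mean_baseq = baseq)
  detect_rdds(pileup_table(dna), pileup_table(rna), config, gm)
}

test_that("edit_ratio is exact division with strict domain checks", {
  expect_equal(edit_ratio(12, 30), 0.4)
  expect_equal(edit_ratio(3, 30), 0.1)
  expect_equal(edit_ratio(29, 30), 29 / 30)
  expect_error(edit_ratio(1, 0), "total_reads")
  expect_error(edit_ratio(5, 3), "alt_reads")
})

test_that("splice distance follows intron-end geometry", {
  gm <- gene_models(
    data.frame(gene_id = "g1", transcript_id = "t1", chrom = "chr1",
               strand = "+", start = 50L, end = 260L,
               biotype = "ncRNA"),
    data.frame(transcript_id = "t1", type = "exon", chrom = "chr1",
               start = c(50L, 201L), end = c(100L, 260L)))
  # intron spans 101..200, junction bases are 101 and 200
  expect_equal(splice_proximity("chr1", 103L, gm), 2)
  expect_equal(splice_proximity("chr1", 106L, gm), 5)
  expect_equal(splice_proximity("chr1", 101L, gm), 0)
  expect_equal(splice_proximity("chr1", 1000L, gm), Inf)
})

test_that("edit-ratio band bounds are inclusive at 0.10 and 0.95", {
  cases <- list(
    list(alt = 999L, pass = FALSE),   # 0.0999 -> discarded
    list(alt = 1000L, pass = TRUE),   # 0.1000 -> retained
    list(alt = 9500L, pass = TRUE),   # 0.9500 -> retained
    list(alt = 9501L, pass = FALSE))  # 0.9501 -> discarded
  for (cs in cases) {
    counts <- list(A = split2(10000L - cs$alt), G = split2(cs$alt))
    cand <- detect_one(counts)
    expect_equal(nrow(cand), 1L)
    expect_equal(cand$pass, cs$pass, info = paste("alt =", cs$alt))
    if (!cs$pass) expect_equal(cand$filters_failed, "edit_ratio")
  }
})

test_that("the RNA read-depth threshold flips exactly at 10 reads", {
  fail9 <- detect_one(list(A = split2(5), G = split2(4)))
  expect_false(fail9$pass)
  expect_equal(fail9$filters_failed, "min_rna_reads")
  pass10 <- detect_one(list(A = split2(6), G = split2(4)))
  expect_true(pass10$pass)
})

test_that("the alternative-read threshold flips exactly at 2 reads", {
  one <- detect_one(list(A = split2(39), G = c(1, 0)))
  expect_match(one$filters_failed, "min_alt_reads")
  two <- detect_one(list(A = split2(38), G = c(1, 1)))
  expect_no_match(two$filters_failed, "min_alt_reads")
})

test_that("the DNA depth threshold flips exactly at 4 reads", {
  rna <- list(A = split2(28), G = split2(12))
  fail3 <- detect_one(rna, dna_depth = 3L)
  expect_false(fail3$pass)
  expect_match(fail3$filters_failed, "min_dna_reads")
  pass4 <- detect_one(rna, dna_depth = 4L)
  expect_true(pass4$pass)
})

test_that("the intronic splice window flips between 4 and 5 bp", {
  gm <- tiny_gene_models()  # tA intron spans 201..400
  rna <- list(A = split2(70), G = split2(30))
  at4 <- detect_one(rna, pos = 205L, gm = gm)
  expect_false(at4$pass)
  expect_equal(at4$filters_failed, "splice_window")
  at5 <- detect_one(rna, pos = 206L, gm = gm)
  expect_true(at5$pass)
  # exonic sites next to a junction are untouched by the splice filter
  exonic_near <- detect_one(rna, pos = 198L, gm = gm)
  expect_no_match(exonic_near$filters_failed, "splice_window")
})

test_that("a true heterozygous DNA site is rejected as not homozygous", {
  cand <- detect_one(list(A = split2(18), G = split2(12)),
                     dna_counts = list(A = split2(18), G = split2(2)))
  expect_false(cand$pass)
  expect_match(cand$filters_failed, "dna_not_homozygous")
})

test_that("strand-skewed alternative reads fail the Fisher strand filter", {
  cand <- detect_one(list(A = c(20, 20), G = c(15, 0)))
  expect_match(cand$filters_failed, "max_fs")
  expect_gt(cand$fs, 30)
})

test_that("multiple failures are all recorded without short-circuiting", {
  # depth 9 (min_rna_reads), alt 1 (min_alt_reads), low qual
  cand <- detect_one(list(A = split2(8), G = c(1, 0)))
  codes <- strsplit(cand$filters_failed, ";")[[1]]
  expect_true(all(c("min_rna_reads", "min_alt_reads", "min_site_qual")
                  %in% codes))
})

test_that("a third supported allele fails biallelicity", {
  cand <- detect_one(list(A = split2(24), G = split2(10), C = split2(6)))
  expect_match(cand$filters_failed, "not_biallelic")
})

test_that("repeat overlap is filtered exactly when repeats are supplied", {
  rna <- list(A = split2(28), G = split2(12))
  reps <- data.frame(chrom = "chr1", start = 90L, end = 110L)
  inside <- detect_one(rna, config = filter_config())
  expect_true(inside$pass)  # no repeat set supplied: filter off by default
  dna <- dna_row(pos = 100L); rnar <- pileup_row(pos = 100L, counts = rna,
                                                 sample_id = "RNA_rep1")
  with_rep <- detect_rdds(pileup_table(dna), pileup_table(rnar),
                          filter_config(), repeats = reps)
  expect_equal(with_rep$filters_failed, "repeat_region")
  outside <- detect_rdds(pileup_table(dna), pileup_table(rnar),
                         filter_config(),
                         repeats = data.frame(chrom = "chr1", start = 500L,
                                              end = 600L))
  expect_true(outside$pass)
})

test_that("conflicting reference bases between DNA and RNA error out", {
  dna <- dna_row(pos = 100L, ref = "A")
  rna <- pileup_row(pos = 100L, ref = "C",
                    counts = list(C = split2(20), T = split2(10)))
  expect_error(detect_rdds(pileup_table(dna), pileup_table(rna)),
               "conflicting reference")
})

test_that("unsorted input pileups error out", {
  dna <- pileup_table(dna_row(pos = 100L), dna_row(pos = 200L))
  rna <- data.table::rbindlist(list(
    pileup_row(pos = 200L, counts = list(A = split2(20), G = split2(10))),
    pileup_row(pos = 100L, counts = list(A = split2(20), G = split2(10)))))
  expect_error(detect_rdds(dna, rna), "sorted")
})

test_that("tightening thresholds never adds a PASS candidate", {
  sim <- small_sim()
  gm <- sim$reference$models
  base <- detect_rdds(sim$dna, sim$rna[[1]], filter_config(), gm)
  base_keys <- with(base[base$pass, ], paste(chrom, pos, ref, alt))
  stricter <- list(
    filter_config(min_rna_reads = 15L),
    filter_config(min_alt_reads = 4L),
    filter_config(min_site_qual = 200),
    filter_config(edit_ratio_min = 0.2, edit_ratio_max = 0.8))
  for (cfg in stricter) {
    cand <- detect_rdds(sim$dna, sim$rna[[1]], cfg, gm)
    keys <- with(cand[cand$pass, ], paste(chrom, pos, ref, alt))
    expect_true(all(keys %in% base_keys))
  }
})

test_that("no simulated heterozygous DNA SNV passes the cascade", {
  sim <- small_sim()
  het <- sim$snvs[sim$snvs$zygosity == "het", ]
  for (r in 1:3) {
    cand <- detect_rdds(sim$dna, sim$rna[[r]], filter_config(),
                        sim$reference$models)
    pk <- with(cand[cand$pass, ], paste(chrom, pos))
    expect_length(intersect(pk, paste(het$chrom, het$pos)), 0L)
  }
})
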