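# Shared in-code fixtures: hand-built pileup rows, tiny gene models and a
# small simulated dataset reused across test files.

# one pileup row with explicit per-strand counts; counts is a named list
# like list(A = c(10, 10), G = c(5, 5)) giving (fwd, rev) per base
pileup_row <- function(chrom = "chr1", pos = 100L, ref = "A", counts,
                       sample_id = "S", mean_baseq = 40, frac_mapq_ge = 1) {
  row <- list(sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
              ref = ref)
  cnt <- setNames(rep(0L, 8L),
                  as.vector(t(outer(c("A", "C", "G", "T"), c("fwd", "rev"),
                                    paste, sep = "_"))))
  for (b in names(counts)) {
    cnt[paste0(b, "_fwd")] <- counts[[b]][1]
    cnt[paste0(b, "_rev")] <- counts[[b]][2]
  }
  row$depth <- as.integer(sum(cnt))
  row <- c(row, setNames(as.list(as.integer(cnt)), names(cnt)))
  row$mean_baseq <- mean_baseq
  row$frac_mapq_ge <- frac_mapq_ge
  as.data.frame(row, stringsAsFactors = FALSE)
}

# a pileup table from several pileup_row() calls
pileup_table <- function(...) {
  dt <- data.table::rbindlist(list(...))
  data.table::setorder(dt, chrom, pos)
  dt[]
}

# balanced strand split helper: n reads -> c(ceiling, floor)
split2 <- function(n) c(ceiling(n / 2), floor(n / 2))

# a strong hom-ref DNA row at the same position
dna_row <- function(chrom = "chr1", pos = 100L, ref = "A", depth = 30L)
  pileup_row(chrom, pos, ref, setNames(list(split2(depth)), ref),
             sample_id = "DNA")

# two-gene hand model: gene gA (+, protein_coding, 2 exons with intron
# 201..400) and gene gB (-, protein_coding, single exon), plus an ncRNA gN.
# gB's CDS overlaps gA's intron so precedence can be exercised.
tiny_gene_models <- function() {
  tx <- data.frame(
    gene_id = c("gA", "gB", "gN"),
    transcript_id = c("tA", "tB", "tN"),
    chrom = "chr1",
    strand = c("+", "-", "+"),
    start = c(101L, 251L, 2001L),
    end = c(600L, 370L, 2300L),
    biotype = c("protein_coding", "protein_coding", "ncRNA"),
    stringsAsFactors = FALSE)
  ft <- rbind(
    data.frame(transcript_id = "tA", type = "exon", chrom = "chr1",
               start = c(101L, 401L), end = c(200L, 600L)),
    data.frame(transcript_id = "tA", type = "five_prime_UTR", chrom = "chr1",
               start = 101L, end = 130L),
    data.frame(transcript_id = "tA", type = "CDS", chrom = "chr1",
               start = c(131L, 401L), end = c(200L, 519L)),
    data.frame(transcript_id = "tA", type = "three_prime_UTR", chrom = "chr1",
               start = 520L, end = 600L),
    data.frame(transcript_id = "tB", type = "exon", chrom = "chr1",
               start = 251L, end = 370L),
    data.frame(transcript_id = "tB", type = "CDS", chrom = "chr1",
               start = 261L, end = 359L),
    data.frame(transcript_id = "tB", type = "five_prime_UTR", chrom = "chr1",
               start = 360L, end = 370L),
    data.frame(transcript_id = "tB", type = "three_prime_UTR", chrom = "chr1",
               start = 251L, end = 260L),
    data.frame(transcript_id = "tN", type = "exon", chrom = "chr1",
               start = 2001L, end = 2300L))
  gene_models(tx, ft)
}

# small, fast simulation shared across tests (memoised per session)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(seed = 7L, n_chroms = 1L,
                               chrom_length = 18000L, n_genes = 6L,
                               n_edit_sites = 40L)
      cache <<- simulate_rdd_dataset(cfg, dir = NULL, n_replicates = 3L)
    }
    cache
  }
})

# brute-force two-sided Fisher p-value by enumeration over all tables with
# the observed margins, using plain choose() products (independent of the
# log-space implementation)
fisher_oracle_fs <- function(ref_fwd, ref_rev, alt_fwd, alt_rev) {
  n <- ref_fwd + ref_rev + alt_fwd + alt_rev
  if (n == 0) return(0)
  ref_tot <- ref_fwd + ref_rev; alt_tot <- alt_fwd + alt_rev
  fwd_tot <- ref_fwd + alt_fwd
  denom <- choose(n, fwd_tot)
  ks <- max(0, fwd_tot - alt_tot):min(ref_tot, fwd_tot)
  probs <- choose(ref_tot, ks) * choose(alt_tot, fwd_tot - ks) / denom
  obs <- probs[ks == ref_fwd]
  p <- sum(probs[probs <= obs * (1 + 1e-7)])
  p <- min(1, max(p, 1e-300))
  max(0, -10 * log10(p))
}
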