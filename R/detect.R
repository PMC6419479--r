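#' Filter cascade configuration
#'
#' Thresholds of the RDD filter cascade. Defaults are the published cascade:
#' at least 4 genomic reads with the DNA completely homozygous; RNA variants
#' supported by at least 10 total and 2 alternative reads; all covering
#' reads passing mapping quality 20 at pileup construction; phred site
#' quality at least 95 on the RNA variant call; Fisher strand value at most
#' 30; intronic sites more than 4 bp from a splice junction; edit ratio kept
#' inside the inclusive band [0.10, 0.95].
#'
#' @param min_dna_reads minimum DNA depth.
#' @param min_rna_reads minimum RNA depth.
#' @param min_alt_reads minimum RNA reads on the alternative allele (also
#'   the support needed for a second non-reference allele to void
#'   biallelicity).
#' @param min_mapq mapping-quality threshold assumed at pileup construction;
#'   sites must report `frac_mapq_ge = 1`.
#' @param min_site_qual minimum phred site quality of the RNA variant call.
#' @param max_fs maximum phred-scaled Fisher strand value.
#' @param edit_ratio_min,edit_ratio_max inclusive edit-ratio band.
#' @param splice_window_bp intronic sites within this distance of a splice
#'   junction are removed.
#' @param max_dna_alt_reads non-reference DNA reads tolerated by the strict
#'   homozygosity test.
#' @param min_mean_baseq sanity floor on the mean base quality of the RNA
#'   site.
#' @param exclude_repeats `NA` enables repeat exclusion exactly when a
#'   repeat interval set is supplied; `TRUE`/`FALSE` force it.
#' @param genotype_error_rate per-read error for the genotype caller;
#'   `NULL` derives it per site from `mean_baseq`.
#' @return List of class `filter_config`.
#' @export
filter_config <- function(min_dna_reads = 4L, min_rna_reads = 10L,
                          min_alt_reads = 2L, min_mapq = 20L,
                          min_site_qual = 95, max_fs = 30,
                          edit_ratio_min = 0.10, edit_ratio_max = 0.95,
                          splice_window_bp = 4L, max_dna_alt_reads = 0L,
                          min_mean_baseq = 20, exclude_repeats = NA,
                          genotype_error_rate = NULL) {
  cfg <- list(min_dna_reads = min_dna_reads, min_rna_reads = min_rna_reads,
              min_alt_reads = min_alt_reads, min_mapq = min_mapq,
              min_site_qual = min_site_qual, max_fs = max_fs,
              edit_ratio_min = edit_ratio_min, edit_ratio_max = edit_ratio_max,
              splice_window_bp = splice_window_bp,
              max_dna_alt_reads = max_dna_alt_reads,
              min_mean_baseq = min_mean_baseq,
              exclude_repeats = exclude_repeats,
              genotype_error_rate = genotype_error_rate)
  if (!(cfg$edit_ratio_min > 0 && cfg$edit_ratio_min < cfg$edit_ratio_max &&
          cfg$edit_ratio_max < 1))
    stop("need 0 < edit_ratio_min < edit_ratio_max < 1")
  counts <- c(cfg$min_dna_reads, cfg$min_rna_reads, cfg$min_alt_reads,
              cfg$min_mapq, cfg$splice_window_bp, cfg$max_dna_alt_reads)
  if (any(counts < 0)) stop("count thresholds must be >= 0")
  structure(cfg, class = "filter_config")
}

#' Edit ratio
#'
#' Fraction of RNA reads carrying the edited allele at a site.
#'
#' @param alt_reads,total_reads read counts, `total_reads >= 1`.
#' @return `alt_reads / total_reads` as an exact double division.
#' @export
edit_ratio <- function(alt_reads, total_reads) {
  if (any(total_reads < 1L)) stop("total_reads must be >= 1")
  if (any(alt_reads < 0L | alt_reads > total_reads))
    stop("need 0 <= alt_reads <= total_reads")
  alt_reads / total_reads
}

#' Distance to the nearest splice junction
#'
#' Junctions are the first and last base of every intron of every transcript
#' overlapping the position (transcript span, introns included). Returns 0
#' if the position is itself a junction base and `Inf` when no transcript
#' overlaps the position.
#'
#' @param chrom,pos position (vectorised over `pos`).
#' @param gene_models a [gene_models()] object.
#' @return Numeric distances in bp (possibly `Inf`).
#' @export
splice_proximity <- function(chrom, pos, gene_models) {
  stopifnot(length(chrom) == 1L || length(chrom) == length(pos))
  chrom <- rep_len(chrom, length(pos))
  tx <- gene_models$transcripts
  jn <- gm_junctions(gene_models)
  vapply(seq_along(pos), function(i) {
    hit <- tx$chrom == chrom[i] & tx$start <= pos[i] & tx$end >= pos[i]
    if (!any(hit)) return(Inf)
    j <- jn$pos[jn$transcript_id %in% tx$transcript_id[hit]]
    if (!length(j)) return(Inf)
    min(abs(j - pos[i]))
  }, numeric(1))
}

FILTER_CODES <- c("min_dna_reads", "dna_not_homozygous", "not_biallelic",
                  "min_rna_reads", "min_alt_reads", "min_mapq",
                  "min_mean_baseq", "min_site_qual", "max_fs",
                  "splice_window", "edit_ratio", "repeat_region")

#' Detect RNA-DNA difference candidates for one RNA replicate
#'
#' Joins the DNA and RNA pileups on position and evaluates the full filter
#' cascade at every position where the RNA shows at least one non-reference
#' read, recording every failed filter (no short-circuiting). Sites with an
#' empty failure list are PASS candidates. Positions covered in both
#' samples but without any RNA alternative read cannot be differences and
#' are only counted (see attribute `n_covered`).
#'
#' @param dna,rna pileup tables (canonical schema), sorted by (chrom, pos).
#' @param config a [filter_config()].
#' @param gene_models optional [gene_models()]; required for the intronic
#'   splice-window filter (skipped with a warning when absent).
#' @param repeats optional repeat intervals: data.frame with chrom,
#'   start, end (1-based inclusive, e.g. from [read_bed()]).
#' @return data.frame of class `rdd_candidates` with per-site counts,
#'   edit ratio, quality metrics, `filters_failed` (semicolon-joined codes,
#'   empty string for PASS) and logical `pass`; attributes `n_covered`
#'   (positions covered in both samples) and `sample_id`.
#' @export
detect_rdds <- function(dna, rna, config = filter_config(),
                        gene_models = NULL, repeats = NULL) {
  dna <- data.table::as.data.table(dna)
  rna <- data.table::as.data.table(rna)
  validate_pileup(dna, "DNA pileup")
  validate_pileup(rna, "RNA pileup")
  exclude_repeats <- if (is.na(config$exclude_repeats))
    !is.null(repeats) else isTRUE(config$exclude_repeats)
  if (exclude_repeats && is.null(repeats))
    stop("exclude_repeats = TRUE but no repeat intervals supplied")

  key <- c("chrom", "pos")
  m <- merge(dna, rna, by = key, suffixes = c("_dna", "_rna"))
  if (nrow(m) && any(m$ref_dna != m$ref_rna))
    stop("conflicting reference bases between DNA and RNA pileups at ",
         paste(head(m[m$ref_dna != m$ref_rna,
                      paste(chrom, pos, sep = ":")], 3), collapse = ", "))
  n_covered <- nrow(m)
  if (n_covered == 0L) {
    out <- empty_candidates()
    attr(out, "n_covered") <- 0L
    return(out)
  }

  base_cols <- function(sfx) {
    cnt <- sapply(BASES, function(b)
      m[[paste0(b, "_fwd", sfx)]] + m[[paste0(b, "_rev", sfx)]])
    if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = nrow(m))
    cnt
  }
  rna_cnt <- base_cols("_rna")
  dna_cnt <- base_cols("_dna")
  ridx <- match(m$ref_dna, BASES)
  pick <- cbind(seq_len(nrow(m)), ridx)

  rna_ref_n <- rna_cnt[pick]
  rna_nonref <- rna_cnt; rna_nonref[pick] <- -1L
  alt_idx <- max.col(rna_nonref, ties.method = "first")
  rna_alt_n <- rna_nonref[cbind(seq_len(nrow(m)), alt_idx)]
  second <- rna_nonref
  second[cbind(seq_len(nrow(m)), alt_idx)] <- -1L
  rna_second_n <- apply(second, 1L, max)

  cand <- which(rna_alt_n >= 1L)
  if (!length(cand)) {
    out <- empty_candidates()
    attr(out, "n_covered") <- n_covered
    return(out)
  }
  mi <- m[cand]
  alt_base <- BASES[alt_idx[cand]]
  ref_base <- mi$ref_dna
  rna_depth <- mi$depth_rna
  dna_depth <- mi$depth_dna
  dna_nonref_n <- dna_depth - dna_cnt[cbind(cand, ridx[cand])]
  ratio <- rna_alt_n[cand] / rna_depth

  # RNA genotype: three-genotype ML caller on (ref, alt) counts
  eps_rna <- if (is.null(config$genotype_error_rate))
    eps_from_baseq(mi$mean_baseq_rna) else config$genotype_error_rate
  gl <- genotype_loglik(rna_ref_n[cand], rna_alt_n[cand], eps_rna)
  qual <- site_qual_from_loglik(gl)
  # DNA genotype for strict homozygosity
  eps_dna <- if (is.null(config$genotype_error_rate))
    eps_from_baseq(mi$mean_baseq_dna) else config$genotype_error_rate
  dna_alt_n <- dna_depth - dna_cnt[cbind(cand, ridx[cand])]
  gl_dna <- genotype_loglik(dna_depth - dna_alt_n, dna_alt_n, eps_dna)
  dna_hom <- max.col(gl_dna, ties.method = "first") == 1L &
    dna_nonref_n <= config$max_dna_alt_reads

  fs <- vapply(seq_along(cand), function(i) {
    r <- mi[i]
    fisher_strand(r[[paste0(ref_base[i], "_fwd_rna")]],
                  r[[paste0(ref_base[i], "_rev_rna")]],
                  r[[paste0(alt_base[i], "_fwd_rna")]],
                  r[[paste0(alt_base[i], "_rev_rna")]])
  }, numeric(1))

  in_band <- ratio >= config$edit_ratio_min & ratio <= config$edit_ratio_max
  is_biallelic <- rna_second_n[cand] < config$min_alt_reads

  intronic <- rep(FALSE, length(cand))
  splice_d <- rep(Inf, length(cand))
  if (!is.null(gene_models)) {
    intr <- gm_introns(gene_models)
    if (nrow(intr)) {
      for (ch in unique(mi$chrom)) {
        ii <- which(mi$chrom == ch)
        iv <- intr[intr$chrom == ch, , drop = FALSE]
        if (!nrow(iv)) next
        ov <- IRanges::findOverlaps(
          IRanges::IRanges(mi$pos[ii], mi$pos[ii]),
          IRanges::IRanges(iv$start, iv$end))
        intronic[ii[unique(S4Vectors::queryHits(ov))]] <- TRUE
      }
    }
    need <- which(intronic)
    if (length(need))
      splice_d[need] <- splice_proximity(mi$chrom[need], mi$pos[need],
                                         gene_models)
  }

  in_repeat <- rep(FALSE, length(cand))
  if (!is.null(repeats) && nrow(repeats)) {
    for (ch in unique(mi$chrom)) {
      ii <- which(mi$chrom == ch)
      rv <- repeats[repeats$chrom == ch, , drop = FALSE]
      if (!nrow(rv)) next
      ov <- IRanges::findOverlaps(IRanges::IRanges(mi$pos[ii], mi$pos[ii]),
                                  IRanges::IRanges(rv$start, rv$end))
      in_repeat[ii[unique(S4Vectors::queryHits(ov))]] <- TRUE
    }
  }

  fail <- list(
    min_dna_reads = dna_depth < config$min_dna_reads,
    dna_not_homozygous = !dna_hom,
    not_biallelic = !is_biallelic,
    min_rna_reads = rna_depth < config$min_rna_reads,
    min_alt_reads = rna_alt_n[cand] < config$min_alt_reads,
    min_mapq = mi$frac_mapq_ge_dna < 1 | mi$frac_mapq_ge_rna < 1,
    min_mean_baseq = mi$mean_baseq_rna < config$min_mean_baseq,
    min_site_qual = qual < config$min_site_qual,
    max_fs = fs > config$max_fs,
    splice_window = intronic & splice_d <= config$splice_window_bp,
    edit_ratio = !in_band,
    repeat_region = if (exclude_repeats) in_repeat else rep(FALSE, length(cand)))
  fmat <- do.call(cbind, fail)
  failed <- apply(fmat, 1L, function(f)
    paste(FILTER_CODES[f[FILTER_CODES]], collapse = ";"))

  out <- data.frame(
    sample_id = mi$sample_id_rna, chrom = mi$chrom, pos = mi$pos,
    ref = ref_base, alt = alt_base,
    rna_alt_reads = rna_alt_n[cand], rna_total_reads = rna_depth,
    edit_ratio = ratio, dna_depth = dna_depth,
    dna_alt_reads = dna_nonref_n, fs = fs, site_qual = qual,
    filters_failed = failed, pass = failed == "",
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rdd_candidates", "data.frame")
  attr(out, "n_covered") <- n_covered
  attr(out, "sample_id") <- unique(mi$sample_id_rna)
  out
}

empty_candidates <- function() {
  out <- data.frame(sample_id = character(), chrom = character(),
                    pos = integer(), ref = character(), alt = character(),
                    rna_alt_reads = integer(), rna_total_reads = integer(),
                    edit_ratio = numeric(), dna_depth = integer(),
                    dna_alt_reads = integer(), fs = numeric(),
                    site_qual = numeric(), filters_failed = character(),
                    pass = logical(), stringsAsFactors = FALSE)
  class(out) <- c("rdd_candidates", "data.frame")
  out
}

#' Per-filter attrition table
#'
#' Counts, for each filter code, how many candidates failed it (filters are
#' evaluated without short-circuiting, so counts overlap).
#'
#' @param candidates [detect_rdds()] output.
#' @return Named integer vector over filter codes plus `PASS`.
#' @export
filter_attrition <- function(candidates) {
  codes <- strsplit(candidates$filters_failed, ";", fixed = TRUE)
  n <- vapply(FILTER_CODES, function(cd)
    sum(vapply(codes, function(x) cd %in% x, logical(1))), integer(1))
  c(n, PASS = sum(candidates$pass))
}
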