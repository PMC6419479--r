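#' @name io_formats
#' @title On-disk formats
#' @description
#' The pipeline touches five plain-text formats. Pileup tables are
#' tab-separated with a single '#'-prefixed header line and the fixed column
#' order `sample_id, chrom, pos, ref, depth, A_fwd, A_rev, C_fwd, C_rev,
#' G_fwd, G_rev, T_fwd, T_rev, mean_baseq, frac_mapq_ge`; per-strand allele
#' counts are the minimal sufficient statistics for every downstream filter.
#' Coordinates are 1-based inclusive in FASTA/GFF3/pileup/VCF; BED input is
#' 0-based half-open and converted on read.
NULL

PILEUP_COLS <- c("sample_id", "chrom", "pos", "ref", "depth",
                 "A_fwd", "A_rev", "C_fwd", "C_rev",
                 "G_fwd", "G_rev", "T_fwd", "T_rev",
                 "mean_baseq", "frac_mapq_ge")

#' Read a per-site pileup table
#'
#' Validates the schema, the count invariant (depth equals the sum of the
#' eight per-allele-per-strand counts) and sorted (chrom, pos) order.
#'
#' @param path path to a pileup TSV written by [write_pileup_table()].
#' @return A `data.table` with the canonical pileup columns.
#' @export
read_pileup_table <- function(path) {
  if (!file.exists(path)) stop("pileup file not found: ", path)
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#"))
    stop("pileup file lacks '#'-prefixed header: ", path)
  cols <- strsplit(sub("^#", "", header), "\t", fixed = TRUE)[[1]]
  if (!identical(cols, PILEUP_COLS))
    stop("pileup header does not match schema in ", path, "\n  expected: ",
         paste(PILEUP_COLS, collapse = ","), "\n  found:    ",
         paste(cols, collapse = ","))
  n_lines <- length(readLines(path, n = 2L))
  if (n_lines < 2L) {
    dt <- data.table::data.table(
      sample_id = character(), chrom = character(), pos = integer(),
      ref = character(), depth = integer(), A_fwd = integer(),
      A_rev = integer(), C_fwd = integer(), C_rev = integer(),
      G_fwd = integer(), G_rev = integer(), T_fwd = integer(),
      T_rev = integer(), mean_baseq = numeric(), frac_mapq_ge = numeric())
    return(dt)
  }
  dt <- data.table::fread(path, skip = 1L, header = FALSE, sep = "\t",
                          col.names = PILEUP_COLS,
                          colClasses = list(character = c(1L, 2L, 4L)))
  validate_pileup(dt, path)
  dt
}

validate_pileup <- function(dt, path = "<pileup>") {
  if (nrow(dt) == 0L) return(invisible(dt))
  counts <- as.matrix(dt[, c("A_fwd", "A_rev", "C_fwd", "C_rev",
                             "G_fwd", "G_rev", "T_fwd", "T_rev"), with = FALSE])
  if (any(counts < 0)) {
    line <- which(rowSums(counts < 0) > 0)[1]
    stop(sprintf("%s: negative allele count at line %d", path, line + 1L))
  }
  bad <- which(dt$depth != rowSums(counts))
  if (length(bad))
    stop(sprintf("%s: depth != sum of allele counts at line %d (pos %s:%d)",
                 path, bad[1] + 1L, dt$chrom[bad[1]], dt$pos[bad[1]]))
  if (!all(dt$ref %in% BASES))
    stop(path, ": ref base must be one of A,C,G,T (uppercase)")
  o <- order(dt$chrom, dt$pos)
  if (!identical(o, seq_len(nrow(dt))))
    stop(path, ": rows are not sorted by (chrom, pos)")
  if (anyDuplicated(paste(dt$chrom, dt$pos)))
    stop(path, ": duplicated (chrom, pos) rows")
  invisible(dt)
}

#' Write a pileup table
#' @param dt pileup `data.table`/data.frame in the canonical schema.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_pileup_table <- function(dt, path) {
  dt <- data.table::as.data.table(dt)[, PILEUP_COLS, with = FALSE]
  writeLines(paste0("#", paste(PILEUP_COLS, collapse = "\t")), path)
  data.table::fwrite(dt, path, sep = "\t", append = TRUE, col.names = FALSE)
  invisible(path)
}

#' Read a reference FASTA
#' @param path FASTA path.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA not found: ", path)
  Biostrings::readDNAStringSet(path)
}

#' Read gene models from GFF3
#'
#' Builds one gene model per mRNA feature; exon/CDS/UTR children are grouped
#' through their `Parent` attribute. An mRNA without CDS children is typed
#' ncRNA. Errors on exons with unresolvable parents and on mRNAs with
#' unknown strand.
#'
#' @param path GFF3 path.
#' @return A [gene_models()] object.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  ty <- as.character(gr$type)
  mrna <- gr[ty == "mRNA"]
  if (any(as.character(BiocGenerics::strand(mrna)) %in% c("*", ".")))
    stop("mRNA with unknown strand '.' in ", path)
  mrna_id <- as.character(mrna$ID)
  genes <- gr[ty == "gene"]
  gene_of <- setNames(as.character(unlist(mrna$Parent)), mrna_id)
  kids <- gr[ty %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR")]
  parent <- as.character(S4Vectors::unstrsplit(
    as(kids$Parent, "CharacterList"), ","))
  if (length(kids) && any(parent == "" | !(parent %in% mrna_id)))
    stop("feature without resolvable mRNA parent in ", path)
  cds_parents <- unique(parent[as.character(kids$type) == "CDS"])
  transcripts <- data.frame(
    gene_id = unname(gene_of[mrna_id]),
    transcript_id = mrna_id,
    chrom = as.character(GenomicRanges::seqnames(mrna)),
    strand = as.character(BiocGenerics::strand(mrna)),
    start = BiocGenerics::start(mrna),
    end = BiocGenerics::end(mrna),
    biotype = ifelse(mrna_id %in% cds_parents, "protein_coding", "ncRNA"),
    stringsAsFactors = FALSE)
  features <- data.frame(
    transcript_id = parent,
    type = as.character(kids$type),
    chrom = as.character(GenomicRanges::seqnames(kids)),
    start = BiocGenerics::start(kids),
    end = BiocGenerics::end(kids),
    stringsAsFactors = FALSE)
  transcripts <- transcripts[order(transcripts$chrom, transcripts$start), ,
                             drop = FALSE]
  rownames(transcripts) <- NULL
  gene_models(transcripts, features)
}

#' Write gene models as GFF3
#' @param gm a [gene_models()] object.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_gff3 <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  tx <- gm$transcripts
  genes <- unique(tx$gene_id)
  lines <- character()
  for (g in genes) {
    gt <- tx[tx$gene_id == g, , drop = FALSE]
    lines <- c(lines, sprintf("%s\trddetect\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              gt$chrom[1], min(gt$start), max(gt$end),
                              gt$strand[1], g))
    for (i in seq_len(nrow(gt))) {
      tid <- gt$transcript_id[i]
      lines <- c(lines,
                 sprintf("%s\trddetect\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                         gt$chrom[i], gt$start[i], gt$end[i], gt$strand[i],
                         tid, g))
      ft <- gm$features[gm$features$transcript_id == tid, , drop = FALSE]
      ft <- ft[order(ft$start, ft$type), , drop = FALSE]
      phase <- ifelse(ft$type == "CDS", "0", ".")
      lines <- c(lines,
                 sprintf("%s\trddetect\t%s\t%d\t%d\t.\t%s\t%s\tParent=%s",
                         ft$chrom, ft$type, ft$start, ft$end, gt$strand[i],
                         phase, tid))
    }
  }
  writeLines(lines, con)
  invisible(path)
}

#' Read a BED file (0-based half-open), converting to 1-based inclusive
#'
#' @param path BED path (>= 3 columns; name and score kept when present).
#' @return data.frame with columns chrom, start, end (1-based inclusive)
#'   and, when present, name and score.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED not found: ", path)
  dt <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(dt) < 3L) stop("BED needs at least 3 columns: ", path)
  names(dt)[1:3] <- c("chrom", "start", "end")
  if (ncol(dt) >= 4L) names(dt)[4] <- "name"
  if (ncol(dt) >= 5L) names(dt)[5] <- "score"
  if (any(dt$end <= dt$start))
    stop("BED interval with end <= start in ", path)
  dt$start <- dt$start + 1L  # 0-based half-open -> 1-based inclusive
  dt
}

#' Write truth editing sites as BED (0-based half-open)
#' @param truth [place_truth_sites()] output.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_truth_bed <- function(truth, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   truth$chrom, truth$pos - 1L, truth$pos, truth$rdd_type,
                   round(1000 * truth$true_edit_ratio), truth$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Write annotated RDD candidates as a minimal VCF 4.2
#'
#' One record per candidate; FILTER is `PASS` or the semicolon-joined codes
#' of the failed filters; INFO carries the edit ratio, sense-strand type,
#' region class, amino-acid change and host-transcript strand.
#'
#' @param sites annotated candidate data.frame ([annotate_rdds()] output;
#'   plain [detect_rdds()] output is accepted, annotation fields then
#'   default to missing).
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_rdd_vcf <- function(sites, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=rddetect",
    "##INFO=<ID=EDITRATIO,Number=1,Type=Float,Description=\"Fraction of RNA reads carrying the edited allele\">",
    "##INFO=<ID=RDDTYPE,Number=1,Type=String,Description=\"Sense-strand substitution type\">",
    "##INFO=<ID=REGION,Number=1,Type=String,Description=\"Genic region class\">",
    "##INFO=<ID=AACHANGE,Number=1,Type=String,Description=\"Amino acid change for exonic sites\">",
    "##INFO=<ID=STRAND,Number=1,Type=String,Description=\"Host transcript strand(s)\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Phred-scaled Fisher strand p-value\">",
    "##INFO=<ID=DNADEPTH,Number=1,Type=Integer,Description=\"DNA read depth\">",
    paste0("##FILTER=<ID=", c("min_dna_reads", "dna_not_homozygous",
                              "not_biallelic", "min_rna_reads",
                              "min_alt_reads", "min_mapq", "min_mean_baseq",
                              "min_site_qual", "max_fs", "splice_window",
                              "edit_ratio", "repeat_region"),
           ",Description=\"Filter cascade code\">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(sites)) {
    filt <- ifelse(is.na(sites$filters_failed) | sites$filters_failed == "",
                   "PASS", sites$filters_failed)
    info <- sprintf("EDITRATIO=%.3f;RDDTYPE=%s;REGION=%s;AACHANGE=%s;STRAND=%s;FS=%.2f;DNADEPTH=%d",
                    sites$edit_ratio,
                    sites$rdd_type %||% rep(".", nrow(sites)),
                    sites$region %||% rep(".", nrow(sites)),
                    ifelse(is.na(sites$aa_change %||% rep(NA, nrow(sites))),
                           ".", sites$aa_change %||% rep(".", nrow(sites))),
                    sites$tx_strand %||% rep(".", nrow(sites)),
                    sites$fs, sites$dna_depth)
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t%.1f\t%s\t%s",
                       sites$chrom, sites$pos, sites$ref, sites$alt,
                       pmin(sites$site_qual, 9999), filt, info), con)
  }
  invisible(path)
}
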