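#' Gene model container
#'
#' Holds transcript-level gene models: one row per transcript plus a long
#' table of exon/CDS/UTR intervals. All coordinates are 1-based inclusive.
#' Transcripts without any CDS interval are ncRNA; protein-coding CDS lengths
#' must be divisible by three.
#'
#' @param transcripts data.frame with columns `gene_id`, `transcript_id`,
#'   `chrom`, `strand` ("+"/"-"), `start`, `end`, `biotype`
#'   ("protein_coding" or "ncRNA").
#' @param features data.frame with columns `transcript_id`, `type`
#'   ("exon", "CDS", "five_prime_UTR", "three_prime_UTR"), `chrom`,
#'   `start`, `end`.
#' @return An object of class `gene_models`.
#' @export
gene_models <- function(transcripts, features) {
  transcripts <- as.data.frame(transcripts, stringsAsFactors = FALSE)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  need_tx <- c("gene_id", "transcript_id", "chrom", "strand", "start", "end", "biotype")
  if (!all(need_tx %in% names(transcripts)))
    stop("transcripts must have columns: ", paste(need_tx, collapse = ", "))
  need_ft <- c("transcript_id", "type", "chrom", "start", "end")
  if (!all(need_ft %in% names(features)))
    stop("features must have columns: ", paste(need_ft, collapse = ", "))
  if (nrow(transcripts) && !all(transcripts$strand %in% c("+", "-")))
    stop("transcript strand must be '+' or '-'")
  if (nrow(features) && !all(features$transcript_id %in% transcripts$transcript_id))
    stop("feature with unknown transcript parent: ",
         paste(unique(setdiff(features$transcript_id, transcripts$transcript_id)),
               collapse = ", "))
  for (tx in transcripts$transcript_id) {
    ex <- features[features$transcript_id == tx & features$type == "exon", , drop = FALSE]
    if (nrow(ex) == 0L) stop("transcript without exons: ", tx)
    ex <- ex[order(ex$start), ]
    if (any(ex$end < ex$start)) stop("malformed exon interval in ", tx)
    if (nrow(ex) > 1L && any(ex$start[-1L] <= ex$end[-nrow(ex)]))
      stop("overlapping exons in transcript ", tx)
    cds <- features[features$transcript_id == tx & features$type == "CDS", , drop = FALSE]
    if (nrow(cds)) {
      in_exon <- vapply(seq_len(nrow(cds)), function(i)
        any(cds$start[i] >= ex$start & cds$end[i] <= ex$end), logical(1))
      if (!all(in_exon)) stop("CDS outside exons in transcript ", tx)
      bt <- transcripts$biotype[transcripts$transcript_id == tx]
      if (bt == "protein_coding" && sum(cds$end - cds$start + 1L) %% 3L != 0L)
        stop("CDS length not divisible by 3 in transcript ", tx)
    }
  }
  structure(list(transcripts = transcripts, features = features),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d transcripts (%d protein_coding, %d ncRNA), %d features\n",
              nrow(x$transcripts),
              sum(x$transcripts$biotype == "protein_coding"),
              sum(x$transcripts$biotype == "ncRNA"),
              nrow(x$features)))
  invisible(x)
}

# features of one or more types, joined with transcript strand/gene
gm_features <- function(gm, types) {
  ft <- gm$features[gm$features$type %in% types, , drop = FALSE]
  i <- match(ft$transcript_id, gm$transcripts$transcript_id)
  ft$strand <- gm$transcripts$strand[i]
  ft$gene_id <- gm$transcripts$gene_id[i]
  ft$biotype <- gm$transcripts$biotype[i]
  ft
}

# introns: gaps between consecutive exons of each transcript
gm_introns <- function(gm) {
  out <- lapply(seq_len(nrow(gm$transcripts)), function(i) {
    tx <- gm$transcripts$transcript_id[i]
    ex <- gm$features[gm$features$transcript_id == tx &
                        gm$features$type == "exon", , drop = FALSE]
    ex <- ex[order(ex$start), ]
    if (nrow(ex) < 2L) return(NULL)
    data.frame(transcript_id = tx,
               gene_id = gm$transcripts$gene_id[i],
               chrom = gm$transcripts$chrom[i],
               strand = gm$transcripts$strand[i],
               start = ex$end[-nrow(ex)] + 1L,
               end = ex$start[-1L] - 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(transcript_id = character(), gene_id = character(),
                      chrom = character(), strand = character(),
                      start = integer(), end = integer())
  out[out$end >= out$start, , drop = FALSE]
}

# splice junction bases: the first and the last base of every intron
gm_junctions <- function(gm) {
  intr <- gm_introns(gm)
  if (nrow(intr) == 0L)
    return(data.frame(transcript_id = character(), chrom = character(),
                      pos = integer()))
  data.frame(transcript_id = rep(intr$transcript_id, 2L),
             chrom = rep(intr$chrom, 2L),
             pos = c(intr$start, intr$end),
             stringsAsFactors = FALSE)
}

gm_granges <- function(df) {
  if (nrow(df) == 0L)
    return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = if ("strand" %in% names(df)) df$strand else "*")
}

# transcript spans as GRanges with transcript metadata
gm_tx_gr <- function(gm) {
  gr <- gm_granges(gm$transcripts)
  S4Vectors::mcols(gr)$transcript_id <- gm$transcripts$transcript_id
  S4Vectors::mcols(gr)$gene_id <- gm$transcripts$gene_id
  S4Vectors::mcols(gr)$biotype <- gm$transcripts$biotype
  gr
}
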