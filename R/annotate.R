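#' Strand-corrected substitution type
#'
#' Relabels a genomic plus-strand substitution into the transcript
#' sense-strand alphabet. On a plus-strand transcript the genomic bases are
#' the sense bases; on a minus-strand transcript both bases are
#' complemented (genomic T>C on a minus-strand gene is A-to-G editing).
#' Positions overlapped by transcripts on both strands, or by none, cannot
#' be assigned a single sense strand and are labelled "unassigned" -- they
#' are excluded from the 12-type spectrum.
#'
#' @param ref_base,alt_base genomic plus-strand bases, `ref != alt`.
#' @param strands character vector of the strands of transcripts
#'   overlapping the position (any subset of "+", "-").
#' @return One of the 12 labels (e.g. "A-to-G") or "unassigned".
#' @export
strand_correct_type <- function(ref_base, alt_base, strands) {
  if (ref_base == alt_base) stop("ref and alt must differ")
  s <- unique(strands[!is.na(strands)])
  if (length(s) != 1L) return("unassigned")
  if (s == "+") rdd_type_label(ref_base, alt_base)
  else rdd_type_label(comp_base(ref_base), comp_base(alt_base))
}

#' Region classification with precedence
#'
#' Classifies a position against all overlapping transcripts with the
#' conventional precedence
#' `exonic (CDS) > splicing > ncRNA exon > UTR5 > UTR3 > intronic >
#' intergenic`; "splicing" means within `splice_window_bp` of a splice
#' junction on either side. `gene_ids` lists every gene supporting the
#' winning class.
#'
#' @param chrom,pos position.
#' @param gene_models a [gene_models()] object.
#' @param splice_window_bp window around junctions for the splicing class.
#' @return list with elements `region` and `gene_ids` (character vector,
#'   empty for intergenic).
#' @export
classify_region <- function(chrom, pos, gene_models, splice_window_bp = 4L) {
  ctx <- region_context(gene_models)
  classify_at(ctx, chrom, pos, splice_window_bp)
}

# precomputed feature tables shared across many classify_at calls
region_context <- function(gm) {
  list(tx = gm$transcripts,
       cds = gm_features(gm, "CDS"),
       ex = gm_features(gm, "exon"),
       u5 = gm_features(gm, "five_prime_UTR"),
       u3 = gm_features(gm, "three_prime_UTR"),
       jn = gm_junctions(gm))
}

classify_at <- function(ctx, chrom, pos, splice_window_bp = 4L) {
  tx <- ctx$tx
  hit <- tx$chrom == chrom & tx$start <= pos & tx$end >= pos
  support <- list()
  add <- function(cls, genes) {
    if (length(genes))
      support[[cls]] <<- unique(c(support[[cls]], genes))
  }
  ft_at <- function(ft)
    ft[ft$chrom == chrom & ft$start <= pos & ft$end >= pos, , drop = FALSE]
  cds <- ft_at(ctx$cds)
  add("exonic", cds$gene_id[cds$biotype == "protein_coding"])
  jn <- ctx$jn[ctx$jn$chrom == chrom &
                 abs(ctx$jn$pos - pos) <= splice_window_bp, , drop = FALSE]
  if (nrow(jn)) {
    gi <- tx$gene_id[match(jn$transcript_id, tx$transcript_id)]
    add("splicing", unique(gi))
  }
  ex <- ft_at(ctx$ex)
  add("ncRNA", ex$gene_id[ex$biotype == "ncRNA"])
  add("UTR5", ft_at(ctx$u5)$gene_id)
  add("UTR3", ft_at(ctx$u3)$gene_id)
  if (any(hit)) {
    intr_tx <- tx$transcript_id[hit][!(tx$transcript_id[hit] %in%
                                         unique(ex$transcript_id))]
    add("intronic", tx$gene_id[match(intr_tx, tx$transcript_id)])
  }
  for (cls in c("exonic", "splicing", "ncRNA", "UTR5", "UTR3", "intronic")) {
    if (!is.null(support[[cls]]))
      return(list(region = cls, gene_ids = sort(support[[cls]])))
  }
  list(region = "intergenic", gene_ids = character())
}

#' Coding consequence of a substitution
#'
#' Builds the affected codon from the spliced CDS in transcript orientation
#' (reverse-complemented for minus-strand transcripts), substitutes the
#' edited base at its codon offset and translates both codons with the
#' standard genetic code.
#'
#' @param chrom,pos genomic position; must fall in the transcript's CDS.
#' @param ref_base,alt_base genomic plus-strand bases.
#' @param gene_models a [gene_models()] object.
#' @param transcript_id protein-coding transcript to evaluate.
#' @param sequences reference [Biostrings::DNAStringSet].
#' @return list with `consequence` ("synonymous", "nonsynonymous",
#'   "stopgain" or "stoploss"), `aa_change` (e.g. "Y→C"), `codon_ref`,
#'   `codon_alt` and `aa_pos` (codon index).
#' @export
coding_consequence <- function(chrom, pos, ref_base, alt_base, gene_models,
                               transcript_id, sequences) {
  gm <- gene_models
  i <- match(transcript_id, gm$transcripts$transcript_id)
  if (is.na(i)) stop("unknown transcript: ", transcript_id)
  strand <- gm$transcripts$strand[i]
  cds <- gm$features[gm$features$transcript_id == transcript_id &
                       gm$features$type == "CDS", , drop = FALSE]
  if (!nrow(cds)) stop("transcript has no CDS: ", transcript_id)
  cds <- cds[order(cds$start), , drop = FALSE]
  if (!any(cds$start <= pos & cds$end >= pos))
    stop(sprintf("position %s:%d is not inside the CDS of %s",
                 chrom, pos, transcript_id))
  # spliced CDS on the plus strand, then flip for minus-strand transcripts
  plus_seq <- paste(vapply(seq_len(nrow(cds)), function(k)
    as.character(Biostrings::subseq(sequences[[chrom]], cds$start[k],
                                    cds$end[k])), character(1)),
    collapse = "")
  L <- nchar(plus_seq)
  plus_idx <- genomic_to_tx(cds, "+", pos)
  if (strand == "+") {
    tx_seq <- plus_seq
    idx <- plus_idx
    ref_t <- ref_base; alt_t <- alt_base
  } else {
    tx_seq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(plus_seq)))
    idx <- L - plus_idx + 1L
    ref_t <- comp_base(ref_base); alt_t <- comp_base(alt_base)
  }
  have <- substr(tx_seq, idx, idx)
  if (have != ref_t)
    stop(sprintf("reference mismatch at %s:%d in %s: CDS has %s, site ref is %s",
                 chrom, pos, transcript_id, have, ref_t))
  aa_pos <- (idx - 1L) %/% 3L + 1L
  off <- (idx - 1L) %% 3L + 1L
  codon_ref <- substr(tx_seq, (aa_pos - 1L) * 3L + 1L, aa_pos * 3L)
  codon_alt <- codon_ref
  substr(codon_alt, off, off) <- alt_t
  aa_ref <- unname(Biostrings::GENETIC_CODE[codon_ref])
  aa_alt <- unname(Biostrings::GENETIC_CODE[codon_alt])
  consequence <- if (aa_ref == aa_alt) "synonymous"
  else if (aa_alt == "*") "stopgain"
  else if (aa_ref == "*") "stoploss"
  else "nonsynonymous"
  list(consequence = consequence,
       aa_change = paste0(aa_ref, "→", aa_alt),
       codon_ref = codon_ref, codon_alt = codon_alt, aa_pos = aa_pos)
}

#' Annotate RDD candidates with type, region and coding consequence
#'
#' Adds the strand-corrected substitution type (from the strands of all
#' transcripts overlapping each site), the region class with supporting
#' genes, and -- for exonic sites -- the codon-level consequence computed
#' on the first protein-coding transcript whose CDS contains the site.
#'
#' @param candidates [detect_rdds()] output (any subset of rows).
#' @param gene_models a [gene_models()] object.
#' @param sequences reference [Biostrings::DNAStringSet] (needed for coding
#'   consequences; `NULL` leaves them NA).
#' @param splice_window_bp window for the "splicing" region class.
#' @return The candidate table with columns `tx_strand`, `rdd_type`,
#'   `region`, `gene_ids` (comma-joined), `consequence`, `aa_change`;
#'   class `annotated_rdds`.
#' @export
annotate_rdds <- function(candidates, gene_models, sequences = NULL,
                          splice_window_bp = 4L) {
  n <- nrow(candidates)
  tx <- gene_models$transcripts
  out <- as.data.frame(candidates)
  out$tx_strand <- rep(".", n)
  out$rdd_type <- rep("unassigned", n)
  out$region <- rep("intergenic", n)
  out$gene_ids <- rep("", n)
  out$consequence <- rep(NA_character_, n)
  out$aa_change <- rep(NA_character_, n)
  ctx <- region_context(gene_models)
  cds <- ctx$cds
  for (i in seq_len(n)) {
    ch <- out$chrom[i]; p <- out$pos[i]
    hit <- tx$chrom == ch & tx$start <= p & tx$end >= p
    strands <- unique(tx$strand[hit])
    out$tx_strand[i] <- if (length(strands)) paste(strands, collapse = "") else "."
    out$rdd_type[i] <- strand_correct_type(out$ref[i], out$alt[i], strands)
    cls <- classify_at(ctx, ch, p, splice_window_bp)
    out$region[i] <- cls$region
    out$gene_ids[i] <- paste(cls$gene_ids, collapse = ",")
    if (cls$region == "exonic" && !is.null(sequences)) {
      host <- cds[cds$chrom == ch & cds$start <= p & cds$end >= p &
                    cds$biotype == "protein_coding", , drop = FALSE]
      if (nrow(host)) {
        tid <- sort(unique(host$transcript_id))[1]
        cc <- coding_consequence(ch, p, out$ref[i], out$alt[i], gene_models,
                                 tid, sequences)
        out$consequence[i] <- cc$consequence
        out$aa_change[i] <- cc$aa_change
      }
    }
  }
  class(out) <- c("annotated_rdds", "data.frame")
  attr(out, "n_covered") <- attr(candidates, "n_covered")
  out
}
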