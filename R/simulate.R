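#' Simulation configuration
#'
#' Parameters of the synthetic genome, gene models, diploid SNVs and RNA
#' editing events used for validation. Defaults describe a small two-
#' chromosome genome expressed at depths typical of a bulk RNA-seq tissue
#' replicate: DNA at ~25x, RNA at ~40x over exons, a per-base substitution
#' error of 1e-3 (phred 30), and 200 editing events with edit ratios drawn
#' uniformly from [0.15, 0.90]. The default substitution-type weights put
#' ~42% of events on A-to-G, mirroring the dominance of A-to-I deamination
#' in mammalian tissues, with C-to-T and the remaining non-canonical types
#' sharing the rest.
#'
#' @param seed integer seed driving every random draw downstream.
#' @param n_chroms,chrom_length number and length (bp) of chromosomes.
#' @param n_genes total genes placed (non-overlapping).
#' @param exons_per_gene integer range `c(lo, hi)` of exons per transcript.
#' @param dna_depth_mean,rna_depth_mean Poisson mean coverage (reads).
#' @param error_rate per-base substitution sequencing error in [0, 0.5).
#' @param het_snv_rate,hom_snv_rate per-bp probability of a true
#'   heterozygous / homozygous-alternative DNA SNV.
#' @param n_edit_sites number of true editing events to place.
#' @param edit_ratio_range `c(lo, hi)` fractions within (0, 1).
#' @param edit_type_weights named numeric over the 12 sense-strand
#'   substitution labels; must sum to 1.
#' @param frac_ncrna fraction of genes emitted without a CDS (ncRNA).
#' @param region_weights named weights over truth-site placement classes
#'   `exonic`, `utr5`, `utr3`, `intronic`, `ncRNA`, `intergenic`.
#' @param intron_depth_factor RNA coverage over introns relative to exons
#'   (pre-mRNA signal).
#' @param intergenic_bg_frac fraction of intergenic positions receiving
#'   background RNA coverage.
#' @param intergenic_depth_factor RNA background depth relative to exons.
#' @param splice_buffer_bp intronic truth sites are kept at least this far
#'   from splice junctions so that every placed site is detectable in
#'   principle.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chroms = 2L,
                              chrom_length = 50000L,
                              n_genes = 30L,
                              exons_per_gene = c(2L, 5L),
                              dna_depth_mean = 25,
                              rna_depth_mean = 40,
                              error_rate = 0.001,
                              het_snv_rate = 5e-4,
                              hom_snv_rate = 5e-4,
                              n_edit_sites = 200L,
                              edit_ratio_range = c(0.15, 0.90),
                              edit_type_weights = default_edit_type_weights(),
                              frac_ncrna = 0.2,
                              region_weights = c(exonic = 0.45, utr5 = 0.05,
                                                 utr3 = 0.15, intronic = 0.20,
                                                 ncRNA = 0.05, intergenic = 0.10),
                              intron_depth_factor = 0.4,
                              intergenic_bg_frac = 0.05,
                              intergenic_depth_factor = 0.25,
                              splice_buffer_bp = 4L) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              dna_depth_mean = dna_depth_mean, rna_depth_mean = rna_depth_mean,
              error_rate = error_rate, het_snv_rate = het_snv_rate,
              hom_snv_rate = hom_snv_rate, n_edit_sites = as.integer(n_edit_sites),
              edit_ratio_range = edit_ratio_range,
              edit_type_weights = edit_type_weights,
              frac_ncrna = frac_ncrna, region_weights = region_weights,
              intron_depth_factor = intron_depth_factor,
              intergenic_bg_frac = intergenic_bg_frac,
              intergenic_depth_factor = intergenic_depth_factor,
              splice_buffer_bp = as.integer(splice_buffer_bp))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

#' Default substitution-type weights (A-to-G dominant)
#' @return Named numeric vector over the 12 types summing to 1.
#' @export
default_edit_type_weights <- function() {
  w <- setNames(rep(0.30 / 8, 12L), RDD_TYPES)
  w["A-to-G"] <- 0.42
  w["C-to-T"] <- 0.10
  w["G-to-A"] <- 0.09
  w["T-to-C"] <- 0.09
  w
}

validate_simulation_config <- function(cfg) {
  stopifnot(length(cfg$exons_per_gene) == 2L,
            cfg$exons_per_gene[1] >= 1L,
            cfg$exons_per_gene[2] >= cfg$exons_per_gene[1])
  if (cfg$dna_depth_mean <= 0 || cfg$rna_depth_mean <= 0)
    stop("depth means must be > 0")
  if (cfg$error_rate < 0 || cfg$error_rate >= 0.5)
    stop("error_rate must lie in [0, 0.5)")
  r <- cfg$edit_ratio_range
  if (length(r) != 2L || r[1] <= 0 || r[2] >= 1 || r[1] > r[2])
    stop("edit_ratio_range must be within (0, 1) with low <= high")
  w <- cfg$edit_type_weights
  if (!all(RDD_TYPES %in% names(w)) || any(w < 0))
    stop("edit_type_weights must be a non-negative vector over the 12 types")
  if (abs(sum(w) - 1) > 1e-8)
    stop("edit_type_weights must sum to 1")
  if (any(!names(cfg$region_weights) %in%
            c("exonic", "utr5", "utr3", "intronic", "ncRNA", "intergenic")))
    stop("unknown region class in region_weights")
  invisible(cfg)
}

# ---- reference genome and gene models --------------------------------------

#' Generate a toy reference genome and gene annotation
#'
#' Draws random chromosome sequences and places non-overlapping genes with
#' alternating-ish strands and 1 intron or more whenever a transcript has
#' more than one exon. Protein-coding transcripts carry a CDS (length
#' divisible by 3) flanked by 5'/3' UTRs in transcript orientation; a
#' configurable fraction of genes is emitted as ncRNA (exons only).
#' Fully deterministic for a fixed `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return List of class `rdd_reference` with elements `sequences`
#'   (a [Biostrings::DNAStringSet]) and `models` (a [gene_models()]).
#' @export
generate_reference <- function(config) {
  validate_simulation_config(config)
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chroms))
  seqs <- vapply(chroms, function(ch)
    paste(sample(BASES, config$chrom_length, replace = TRUE), collapse = ""),
    character(1))
  sequences <- Biostrings::DNAStringSet(seqs)
  names(sequences) <- chroms

  tx_rows <- list(); ft_rows <- list()
  if (config$n_genes > 0L) {
    gene_chrom <- chroms[((seq_len(config$n_genes) - 1L) %% config$n_chroms) + 1L]
    cursor <- setNames(rep(1L, config$n_chroms), chroms)
    for (i in seq_len(config$n_genes)) {
      ch <- gene_chrom[i]
      n_ex_range <- config$exons_per_gene[1]:config$exons_per_gene[2]
      n_ex <- n_ex_range[sample.int(length(n_ex_range), 1L)]
      ex_len <- sample(150:300, n_ex, replace = TRUE)
      in_len <- if (n_ex > 1L) sample(80:400, n_ex - 1L, replace = TRUE) else integer()
      gap <- sample(200:800, 1L)
      start <- cursor[ch] + gap
      end <- start + sum(ex_len) + sum(in_len) - 1L
      if (end > config$chrom_length - 100L)
        stop(sprintf(paste0("chrom_length %d too small to place %d genes ",
                            "(gene %d would end at %d on %s)"),
                     config$chrom_length, config$n_genes, i, end, ch))
      cursor[ch] <- end
      strand <- sample(c("+", "-"), 1L)
      biotype <- if (runif(1) < config$frac_ncrna) "ncRNA" else "protein_coding"
      gid <- sprintf("g%03d", i); tid <- sprintf("t%03d", i)

      ex_start <- start + c(0L, cumsum(ex_len[-n_ex] + in_len))
      ex_end <- ex_start + ex_len - 1L
      exons <- data.frame(transcript_id = tid, type = "exon", chrom = ch,
                          start = ex_start, end = ex_end,
                          stringsAsFactors = FALSE)
      feats <- exons
      if (biotype == "protein_coding") {
        L <- sum(ex_len)
        utr5 <- sample(20:60, 1L); utr3 <- sample(30:90, 1L)
        if (L - utr5 - utr3 < 30L) { utr5 <- 20L; utr3 <- 30L }
        cds_len <- L - utr5 - utr3
        cds_len <- cds_len - (cds_len %% 3L)
        utr3 <- L - utr5 - cds_len
        mk <- function(a, b, type) {
          iv <- tx_to_genomic(exons, strand, a, b)
          if (is.null(iv)) return(NULL)
          data.frame(transcript_id = tid, type = type, chrom = ch,
                     start = iv$start, end = iv$end, stringsAsFactors = FALSE)
        }
        feats <- rbind(feats,
                       mk(1L, utr5, "five_prime_UTR"),
                       mk(utr5 + 1L, utr5 + cds_len, "CDS"),
                       mk(utr5 + cds_len + 1L, L, "three_prime_UTR"))
      }
      tx_rows[[i]] <- data.frame(gene_id = gid, transcript_id = tid, chrom = ch,
                                 strand = strand, start = start, end = end,
                                 biotype = biotype, stringsAsFactors = FALSE)
      ft_rows[[i]] <- feats
    }
  }
  transcripts <- if (length(tx_rows)) do.call(rbind, tx_rows) else
    data.frame(gene_id = character(), transcript_id = character(),
               chrom = character(), strand = character(), start = integer(),
               end = integer(), biotype = character())
  features <- if (length(ft_rows)) do.call(rbind, ft_rows) else
    data.frame(transcript_id = character(), type = character(),
               chrom = character(), start = integer(), end = integer())
  models <- gene_models(transcripts, features)
  structure(list(sequences = sequences, models = models, config = config),
            class = "rdd_reference")
}

# map a transcript-coordinate interval [a, b] onto genomic intervals.
# exons: data.frame sorted by genomic start; transcript order follows the
# strand (descending genomic order on "-").
tx_to_genomic <- function(exons, strand, a, b) {
  if (b < a) return(NULL)
  ex <- exons[order(exons$start), , drop = FALSE]
  if (strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  w <- ex$end - ex$start + 1L
  cum_before <- cumsum(c(0L, w[-length(w)]))
  out <- list()
  for (k in seq_len(nrow(ex))) {
    lo <- max(a, cum_before[k] + 1L); hi <- min(b, cum_before[k] + w[k])
    if (lo > hi) next
    if (strand == "+") {
      gs <- ex$start[k] + (lo - cum_before[k] - 1L)
      ge <- ex$start[k] + (hi - cum_before[k] - 1L)
    } else {
      ge <- ex$end[k] - (lo - cum_before[k] - 1L)
      gs <- ex$end[k] - (hi - cum_before[k] - 1L)
    }
    out[[length(out) + 1L]] <- c(gs, ge)
  }
  if (!length(out)) return(NULL)
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2])[order(m[, 1]), , drop = FALSE]
}

# genomic position -> transcript coordinate (1-based along the mature/spliced
# sequence defined by the given intervals), or NA if not inside them
genomic_to_tx <- function(intervals, strand, pos) {
  iv <- intervals[order(intervals$start), , drop = FALSE]
  if (strand == "-") iv <- iv[rev(seq_len(nrow(iv))), , drop = FALSE]
  w <- iv$end - iv$start + 1L
  cum_before <- cumsum(c(0L, w[-length(w)]))
  for (k in seq_len(nrow(iv))) {
    if (pos >= iv$start[k] && pos <= iv$end[k]) {
      off <- if (strand == "+") pos - iv$start[k] else iv$end[k] - pos
      return(cum_before[k] + off + 1L)
    }
  }
  NA_integer_
}

# ---- ground truth ----------------------------------------------------------

#' Place true editing events with known type, strand and edit ratio
#'
#' Draws `n_edit_sites` distinct positions across region classes according to
#' `region_weights`, assigns each a sense-strand substitution type from
#' `edit_type_weights` (the position must carry the type's reference base on
#' the host transcript's sense strand) and an edit ratio uniform over
#' `edit_ratio_range`. For minus-strand transcripts the recorded genomic
#' substitution is the reverse complement of the sense-strand type.
#' Intergenic sites are recorded in plus-strand alphabet with no transcript.
#'
#' @param config a [simulation_config()].
#' @param reference output of [generate_reference()].
#' @return data.frame of class `truth_sites`, sorted by (chrom, pos), with
#'   columns chrom, pos, transcript_id, gene_id, strand, region_class,
#'   rdd_type, sense_ref, sense_alt, ref_base, alt_base, true_edit_ratio.
#' @export
place_truth_sites <- function(config, reference) {
  validate_simulation_config(config)
  set.seed(config$seed + 1L)
  gm <- reference$models
  pools <- truth_position_pools(config, reference)
  weights <- setNames(rep(0, length(pools)), names(pools))
  weights[names(config$region_weights)] <- config$region_weights
  avail <- unlist(lapply(pools, nrow))
  classes <- names(pools)[avail > 0L & weights > 0]
  if (config$n_edit_sites > sum(avail[classes]))
    stop(sprintf("requested %d truth sites but only %d eligible positions exist",
                 config$n_edit_sites, sum(avail[classes])))
  w_cls <- weights[classes]
  if (!length(classes) || sum(w_cls) <= 0)
    stop("no eligible region class has positive weight")
  used <- character()
  rows <- vector("list", config$n_edit_sites)
  from_of <- substr(RDD_TYPES, 1L, 1L)
  for (i in seq_len(config$n_edit_sites)) {
    placed <- FALSE
    for (try in seq_len(400L)) {
      cls <- sample(classes, 1L, prob = w_cls)
      ty <- sample(RDD_TYPES, 1L, prob = config$edit_type_weights[RDD_TYPES])
      pool <- pools[[cls]]
      ok <- pool$sense_base == from_of[match(ty, RDD_TYPES)] &
        !(paste(pool$chrom, pool$pos) %in% used)
      if (!any(ok)) next
      j <- sample(which(ok), 1L)
      row <- pool[j, , drop = FALSE]
      used <- c(used, paste(row$chrom, row$pos))
      sense_ref <- substr(ty, 1L, 1L); sense_alt <- substr(ty, 6L, 6L)
      minus <- !is.na(row$strand) && row$strand == "-"
      rows[[i]] <- data.frame(
        chrom = row$chrom, pos = row$pos,
        transcript_id = row$transcript_id, gene_id = row$gene_id,
        strand = ifelse(is.na(row$strand), "+", row$strand),
        region_class = cls, rdd_type = ty,
        sense_ref = sense_ref, sense_alt = sense_alt,
        ref_base = if (minus) comp_base(sense_ref) else sense_ref,
        alt_base = if (minus) comp_base(sense_alt) else sense_alt,
        true_edit_ratio = runif(1, config$edit_ratio_range[1],
                                config$edit_ratio_range[2]),
        stringsAsFactors = FALSE)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("requested more truth sites than available eligible positions")
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("truth_sites", "data.frame")
  out
}

# candidate positions per region class, with host-transcript strand and the
# base each position shows on the transcript sense strand
truth_position_pools <- function(config, reference) {
  gm <- reference$models
  seqs <- reference$sequences
  base_at <- function(chrom, pos) {
    s <- as.character(seqs[[chrom]])
    substring(s, pos, pos)
  }
  expand <- function(df) {
    if (is.null(df) || nrow(df) == 0L)
      return(data.frame(chrom = character(), pos = integer(),
                        transcript_id = character(), gene_id = character(),
                        strand = character(), sense_base = character()))
    pos <- unlist(lapply(seq_len(nrow(df)), function(i) df$start[i]:df$end[i]))
    n_each <- df$end - df$start + 1L
    out <- data.frame(chrom = rep(df$chrom, n_each), pos = pos,
                      transcript_id = rep(df$transcript_id, n_each),
                      gene_id = rep(df$gene_id, n_each),
                      strand = rep(df$strand, n_each),
                      stringsAsFactors = FALSE)
    b <- character(nrow(out))
    for (ch in unique(out$chrom)) {
      idx <- out$chrom == ch
      b[idx] <- base_at(ch, out$pos[idx])
    }
    out$sense_base <- ifelse(out$strand == "-", comp_base(b), b)
    out
  }
  cds <- gm_features(gm, "CDS")
  utr5 <- gm_features(gm, "five_prime_UTR")
  utr3 <- gm_features(gm, "three_prime_UTR")
  nc <- gm_features(gm, "exon")
  nc <- nc[nc$biotype == "ncRNA", , drop = FALSE]
  intr <- gm_introns(gm)
  intr$biotype <- NA_character_
  pools <- list(exonic = expand(cds), utr5 = expand(utr5), utr3 = expand(utr3),
                ncRNA = expand(nc), intronic = expand(intr))
  # keep intronic sites clear of splice junctions
  if (nrow(pools$intronic)) {
    jn <- gm_junctions(gm)
    if (nrow(jn)) {
      d <- vapply(seq_len(nrow(pools$intronic)), function(i) {
        j <- jn[jn$chrom == pools$intronic$chrom[i], "pos"]
        if (!length(j)) return(Inf)
        min(abs(j - pools$intronic$pos[i]))
      }, numeric(1))
      pools$intronic <- pools$intronic[d > config$splice_buffer_bp, , drop = FALSE]
    }
  }
  # intergenic: outside every transcript span
  ig <- lapply(names(seqs), function(ch) {
    tx <- gm$transcripts[gm$transcripts$chrom == ch, , drop = FALSE]
    covered <- rep(FALSE, config$chrom_length)
    for (i in seq_len(nrow(tx))) covered[tx$start[i]:tx$end[i]] <- TRUE
    pos <- which(!covered)
    if (!length(pos)) return(NULL)
    data.frame(chrom = ch, pos = pos, transcript_id = NA_character_,
               gene_id = NA_character_, strand = NA_character_,
               stringsAsFactors = FALSE)
  })
  ig <- do.call(rbind, ig)
  if (!is.null(ig) && nrow(ig)) {
    b <- character(nrow(ig))
    for (ch in unique(ig$chrom)) {
      idx <- ig$chrom == ch
      b[idx] <- base_at(ch, ig$pos[idx])
    }
    ig$sense_base <- b
  } else {
    ig <- data.frame(chrom = character(), pos = integer(),
                     transcript_id = character(), gene_id = character(),
                     strand = character(), sense_base = character())
  }
  pools$intergenic <- ig
  pools
}

#' Place true diploid DNA SNVs (heterozygous and homozygous-alternative)
#'
#' Positions are drawn per base-pair at `het_snv_rate` / `hom_snv_rate`,
#' avoiding truth editing sites. Heterozygous SNVs exercise the
#' "heterozygous at DNA means not an RDD" rejection path; homozygous-
#' alternative SNVs appear identically in DNA and RNA and must likewise not
#' be called edits.
#'
#' @param config a [simulation_config()].
#' @param reference output of [generate_reference()].
#' @param truth optional [place_truth_sites()] output to avoid.
#' @return data.frame with columns chrom, pos, ref_base, alt_base, zygosity.
#' @export
place_snvs <- function(config, reference, truth = NULL) {
  set.seed(config$seed + 2L)
  seqs <- reference$sequences
  avoid <- if (!is.null(truth)) paste(truth$chrom, truth$pos) else character()
  rows <- list()
  for (ch in names(seqs)) {
    for (zyg in c("het", "hom")) {
      rate <- if (zyg == "het") config$het_snv_rate else config$hom_snv_rate
      n <- rbinom(1L, config$chrom_length, rate)
      if (n == 0L) next
      pos <- sample.int(config$chrom_length, n)
      keep <- !(paste(ch, pos) %in% c(avoid, unlist(lapply(rows, function(r)
        paste(r$chrom, r$pos)))))
      pos <- pos[keep]
      if (!length(pos)) next
      s <- as.character(seqs[[ch]])
      ref <- substring(s, pos, pos)
      alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1L), character(1))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, pos = pos, ref_base = ref, alt_base = unname(alt),
        zygosity = zyg, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), pos = integer(), ref_base = character(),
               alt_base = character(), zygosity = character())
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- pileup simulation -----------------------------------------------------

#' Simulate a per-site pileup table for one sample
#'
#' Per-position depth is Poisson; allele counts follow the diploid genotype
#' (hom-ref everywhere except SNV positions) for DNA, with edited-base counts
#' Binomial(depth, true edit ratio) added at truth sites for RNA. A uniform
#' substitution error then redirects each read to one of the three other
#' bases; reads split ~50/50 across strands. RNA coverage spans transcripts
#' (introns at `intron_depth_factor` of exonic depth) plus a random fraction
#' of intergenic background; DNA covers the whole genome.
#'
#' @param reference output of [generate_reference()].
#' @param truth_sites [place_truth_sites()] output (used for RNA only).
#' @param config a [simulation_config()].
#' @param sample_kind "DNA" or "RNA".
#' @param snvs optional [place_snvs()] output.
#' @param replicate replicate index (RNA); distinct replicates draw
#'   independent coverage and counts but share the truth.
#' @return A pileup `data.table` in the package's canonical schema, sorted
#'   by (chrom, pos); zero-depth positions are omitted.
#' @export
simulate_pileups <- function(reference, truth_sites = NULL, config,
                             sample_kind = c("DNA", "RNA"),
                             snvs = NULL, replicate = 1L) {
  sample_kind <- match.arg(sample_kind)
  validate_simulation_config(config)
  offset <- if (sample_kind == "DNA") 10L else 100L + as.integer(replicate)
  set.seed(config$seed + offset)
  gm <- reference$models
  seqs <- reference$sequences
  baseq <- if (config$error_rate <= 0) 60 else
    min(60, round(-10 * log10(config$error_rate), 1))

  pieces <- list()
  for (ch in names(seqs)) {
    len <- length(seqs[[ch]])
    if (sample_kind == "DNA") {
      pos <- seq_len(len)
      mu <- rep(config$dna_depth_mean, len)
    } else {
      mu <- rep(0, len)
      tx <- gm$transcripts[gm$transcripts$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(tx)))
        mu[tx$start[i]:tx$end[i]] <-
          config$rna_depth_mean * config$intron_depth_factor
      ex <- gm$features[gm$features$type == "exon" &
                          gm$features$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(ex)))
        mu[ex$start[i]:ex$end[i]] <- config$rna_depth_mean
      bg <- mu == 0 & runif(len) < config$intergenic_bg_frac
      mu[bg] <- config$rna_depth_mean * config$intergenic_depth_factor
      pos <- which(mu > 0)
      mu <- mu[pos]
    }
    if (!length(pos)) next
    depth <- rpois(length(pos), mu)
    keep <- depth > 0L
    pos <- pos[keep]; depth <- depth[keep]
    if (!length(pos)) next
    s <- as.character(seqs[[ch]])
    ref <- substring(s, pos, pos)

    f_alt <- rep(0, length(pos))
    alt_base <- rep(NA_character_, length(pos))
    if (!is.null(snvs)) {
      sv <- snvs[snvs$chrom == ch, , drop = FALSE]
      i <- match(pos, sv$pos)
      hit <- !is.na(i)
      f_alt[hit] <- ifelse(sv$zygosity[i[hit]] == "het", 0.5, 1)
      alt_base[hit] <- sv$alt_base[i[hit]]
    }
    if (sample_kind == "RNA" && !is.null(truth_sites)) {
      tr <- truth_sites[truth_sites$chrom == ch, , drop = FALSE]
      i <- match(pos, tr$pos)
      hit <- !is.na(i)
      f_alt[hit] <- tr$true_edit_ratio[i[hit]]
      alt_base[hit] <- tr$alt_base[i[hit]]
    }
    alt_n <- rbinom(length(pos), depth, f_alt)
    ref_n <- depth - alt_n

    counts <- matrix(0L, nrow = length(pos), ncol = 4L,
                     dimnames = list(NULL, BASES))
    ri <- match(ref, BASES)
    counts[cbind(seq_along(pos), ri)] <- ref_n
    ai <- match(alt_base, BASES)
    has_alt <- !is.na(ai) & alt_n > 0L
    counts[cbind(which(has_alt), ai[has_alt])] <-
      counts[cbind(which(has_alt), ai[has_alt])] + alt_n[has_alt]

    if (config$error_rate > 0) {
      for (b in seq_len(4L)) {
        e <- rbinom(length(pos), counts[, b], config$error_rate)
        idx <- which(e > 0L)
        if (!length(idx)) next
        counts[idx, b] <- counts[idx, b] - e[idx]
        others <- setdiff(seq_len(4L), b)
        for (k in idx) {
          add <- as.integer(rmultinom(1L, e[k], rep(1 / 3, 3L)))
          counts[k, others] <- counts[k, others] + add
        }
      }
    }
    fwd <- matrix(0L, nrow = length(pos), ncol = 4L)
    for (b in seq_len(4L)) fwd[, b] <- rbinom(length(pos), counts[, b], 0.5)
    rev <- counts - fwd
    depth_out <- rowSums(counts)
    keep <- depth_out > 0L
    sid <- if (sample_kind == "DNA") "DNA" else sprintf("RNA_rep%d", replicate)
    pieces[[ch]] <- data.table::data.table(
      sample_id = sid, chrom = ch, pos = as.integer(pos[keep]),
      ref = ref[keep], depth = as.integer(depth_out[keep]),
      A_fwd = fwd[keep, 1], A_rev = rev[keep, 1],
      C_fwd = fwd[keep, 2], C_rev = rev[keep, 2],
      G_fwd = fwd[keep, 3], G_rev = rev[keep, 3],
      T_fwd = fwd[keep, 4], T_rev = rev[keep, 4],
      mean_baseq = baseq, frac_mapq_ge = 1)
  }
  out <- data.table::rbindlist(pieces)
  data.table::setorder(out, chrom, pos)
  out[]
}

#' Simulate a complete matched DNA/RNA dataset and write it to disk
#'
#' Runs the full generator: reference and gene models, truth editing sites,
#' diploid SNVs, one DNA pileup and `n_replicates` RNA pileups, all
#' deterministic under `config$seed`. Files written: `reference.fa`,
#' `genes.gff3`, `truth.bed` (0-based half-open, name = type,
#' score = round(1000 x edit ratio)), `truth.tsv`, `snvs.tsv`,
#' `dna.pileup.tsv`, `rna_rep<k>.pileup.tsv`.
#'
#' @param config a [simulation_config()].
#' @param dir output directory (created if missing); NULL skips writing.
#' @param n_replicates number of RNA replicates.
#' @return Invisible list with the in-memory objects and file paths.
#' @export
simulate_rdd_dataset <- function(config, dir = NULL, n_replicates = 3L) {
  reference <- generate_reference(config)
  truth <- place_truth_sites(config, reference)
  snvs <- place_snvs(config, reference, truth)
  dna <- simulate_pileups(reference, truth, config, "DNA", snvs = snvs)
  rna <- lapply(seq_len(n_replicates), function(r)
    simulate_pileups(reference, truth, config, "RNA", snvs = snvs,
                     replicate = r))
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      reference = file.path(dir, "reference.fa"),
      gff3 = file.path(dir, "genes.gff3"),
      truth_bed = file.path(dir, "truth.bed"),
      truth_tsv = file.path(dir, "truth.tsv"),
      snvs = file.path(dir, "snvs.tsv"),
      dna = file.path(dir, "dna.pileup.tsv"),
      rna = file.path(dir, sprintf("rna_rep%d.pileup.tsv", seq_len(n_replicates))))
    Biostrings::writeXStringSet(reference$sequences, paths$reference)
    write_gff3(reference$models, paths$gff3)
    write_truth_bed(truth, paths$truth_bed)
    data.table::fwrite(truth, paths$truth_tsv, sep = "\t")
    data.table::fwrite(snvs, paths$snvs, sep = "\t")
    write_pileup_table(dna, paths$dna)
    for (r in seq_len(n_replicates))
      write_pileup_table(rna[[r]], paths$rna[r])
  }
  invisible(list(reference = reference, truth = truth, snvs = snvs,
                 dna = dna, rna = rna, config = config, paths = paths))
}
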