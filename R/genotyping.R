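#' @name genotyping
#' @title Diploid genotype calling from pileup counts
#' @description
#' A deliberately simple maximum-likelihood diploid caller over the three
#' genotypes ref/ref, ref/alt and alt/alt, where alt is the highest-count
#' non-reference base. Under a per-read substitution error `eps`, an
#' alternative read arises with probability `eps` from ref/ref, 0.5 from
#' ref/alt and `1 - eps` from alt/alt. The site quality is the phred-scaled
#' posterior probability of hom-ref under a flat genotype prior, capped at
#' 10000: large values mean the site is confidently variant. Note that a
#' truly edited site with a low edit ratio is penalised by the ref/alt
#' model's 50/50 expectation; this is the same behaviour joint diploid
#' callers show on editing data and is the binding constraint on sensitivity
#' at low edit ratios.
NULL

# per-site counts on each base (both strands)
pileup_base_counts <- function(site) {
  c(A = site$A_fwd + site$A_rev, C = site$C_fwd + site$C_rev,
    G = site$G_fwd + site$G_rev, T = site$T_fwd + site$T_rev)
}

# eps from a phred mean base quality, clipped to a sane range
eps_from_baseq <- function(baseq) {
  pmin(0.25, pmax(1e-6, 10^(-baseq / 10)))
}

#' Call a diploid genotype from one pileup site
#'
#' @param site a single pileup row (list or one-row data.frame in the
#'   canonical schema).
#' @param error_rate per-read substitution error `eps`; `NULL` derives it
#'   from the site's `mean_baseq` as `10^(-baseq/10)` clipped to
#'   `[1e-6, 0.25]`.
#' @param min_alt_reads read support needed for a second non-reference
#'   allele to make the site multi-allelic (`is_biallelic = FALSE`).
#' @return A `genotype_call`: list with `genotype` (two bases), `alt_base`
#'   (NA when hom-ref), `ref_reads`, `alt_reads`, `site_qual`, `fs`,
#'   `is_biallelic`, `depth`.
#' @export
call_genotype <- function(site, error_rate = 0.01, min_alt_reads = 2L) {
  counts <- pileup_base_counts(site)
  depth <- sum(counts)
  if (depth < 1L) stop("no-call: site has zero depth")
  eps <- if (is.null(error_rate)) eps_from_baseq(site$mean_baseq) else error_rate
  ref <- site$ref
  nonref <- sort(counts[setdiff(BASES, ref)], decreasing = TRUE)
  alt <- names(nonref)[1]
  ref_n <- unname(counts[ref]); alt_n <- unname(nonref[1])
  gl <- genotype_loglik(ref_n, alt_n, eps)
  g_idx <- which.max(gl)
  qual <- site_qual_from_loglik(gl)
  genotype <- switch(g_idx, c(ref, ref), sort(c(ref, alt)), c(alt, alt))
  is_biallelic <- !(length(nonref) > 1L && nonref[2] >= min_alt_reads)
  strand_of <- function(b, s) site[[paste0(b, "_", s)]]
  fs <- if (alt_n > 0L)
    fisher_strand(strand_of(ref, "fwd"), strand_of(ref, "rev"),
                  strand_of(alt, "fwd"), strand_of(alt, "rev")) else 0
  structure(list(genotype = genotype,
                 alt_base = if (g_idx == 1L && alt_n == 0L) NA_character_ else alt,
                 ref_reads = ref_n, alt_reads = alt_n,
                 site_qual = qual, fs = fs,
                 is_biallelic = is_biallelic, depth = depth,
                 map_genotype = c("hom_ref", "het", "hom_alt")[g_idx]),
            class = "genotype_call")
}

#' @export
print.genotype_call <- function(x, ...) {
  cat(sprintf("genotype %s/%s  qual %.1f  ref:alt %d:%d  FS %.2f  %s\n",
              x$genotype[1], x$genotype[2], x$site_qual, x$ref_reads,
              x$alt_reads, x$fs,
              if (x$is_biallelic) "biallelic" else "multi-allelic"))
  invisible(x)
}

# log-likelihoods of (hom_ref, het, hom_alt); vectorised over sites
genotype_loglik <- function(ref_n, alt_n, eps) {
  n <- ref_n + alt_n
  cbind(hom_ref = dbinom(alt_n, n, eps, log = TRUE),
        het = dbinom(alt_n, n, 0.5, log = TRUE),
        hom_alt = dbinom(alt_n, n, 1 - eps, log = TRUE))
}

# phred-scaled posterior of hom-ref under a flat prior, capped at 10000;
# accepts a vector (one site) or matrix (rows = sites)
site_qual_from_loglik <- function(gl) {
  if (is.null(dim(gl))) gl <- matrix(gl, nrow = 1L)
  lse <- .row_logsumexp(gl)
  q <- -10 / log(10) * (gl[, 1L] - lse)
  unname(pmin(q, 10000))
}

#' Phred-scaled Fisher strand-bias statistic
#'
#' Two-sided Fisher exact test on the 2x2 table of (ref, alt) x (forward,
#' reverse) read counts, using the standard convention of summing every
#' hypergeometric table probability not exceeding the observed one.
#' Computed with log-space factorials; the p-value is clamped to >= 1e-300
#' and `FS = -10*log10(p)`. An all-zero table returns 0 by convention.
#' Large values flag strand bias, a mapping-artifact signature.
#'
#' @param ref_fwd,ref_rev,alt_fwd,alt_rev non-negative read counts.
#' @return Non-negative phred-scaled value.
#' @export
fisher_strand <- function(ref_fwd, ref_rev, alt_fwd, alt_rev) {
  counts <- c(ref_fwd, ref_rev, alt_fwd, alt_rev)
  if (any(counts < 0)) stop("counts must be non-negative")
  n <- sum(counts)
  if (n == 0L) return(0)
  ref_tot <- ref_fwd + ref_rev
  alt_tot <- alt_fwd + alt_rev
  fwd_tot <- ref_fwd + alt_fwd
  k_min <- max(0L, fwd_tot - alt_tot)
  k_max <- min(ref_tot, fwd_tot)
  k <- k_min:k_max
  logp <- lchoose(ref_tot, k) + lchoose(alt_tot, fwd_tot - k) -
    lchoose(n, fwd_tot)
  obs <- logp[k == ref_fwd]
  p <- sum(exp(logp[logp <= obs + 1e-7]))
  p <- min(1, max(p, 1e-300))
  max(0, -10 * log10(p))
}

#' Strict homozygosity test for the DNA sample
#'
#' A position counts as strictly homozygous when the maximum-likelihood
#' genotype is hom-ref and the total non-reference read count does not
#' exceed `max_dna_alt_reads` (0 by default: "completely homozygous").
#'
#' @param site a single DNA pileup row.
#' @param call the [call_genotype()] result for that row.
#' @param max_dna_alt_reads tolerated non-reference reads.
#' @return Logical flag.
#' @export
is_strictly_homozygous <- function(site, call, max_dna_alt_reads = 0L) {
  counts <- pileup_base_counts(site)
  nonref <- sum(counts) - unname(counts[site$ref])
  call$map_genotype == "hom_ref" && nonref <= max_dna_alt_reads
}
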