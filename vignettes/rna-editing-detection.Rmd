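---
title: "Detecting RNA editing sites from matched DNA/RNA pileups"
author: "rddetect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting RNA editing sites from matched DNA/RNA pileups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rddetect)
```

## The problem

RNA editing enzymes (ADARs deaminating adenosine to inosine, APOBECs
deaminating cytidine to uridine) change single bases of a transcript after
it is copied from DNA. Because inosine pairs like guanosine, A-to-I editing
is observed in RNA-seq reads as an A>G mismatch against the genome on the
transcript's sense strand. The observable signature is therefore an
*RNA-DNA difference* (RDD): a position that is confidently homozygous in
genomic DNA from an individual but carries a second allele in RNA reads
from the same individual. Almost everything else that produces such a
mismatch — undetected heterozygosity, sequencing error, misalignment around
splice junctions and repeats, strand-biased mapping artifacts — must be
filtered away, which is why RDD calling is a cascade of conservative
filters rather than a single test.

`rddetect` implements that cascade on *per-site pileup count tables*
rather than on BAM files: for every position we require only the
per-allele, per-strand read counts, the mean base quality, and the fraction
of reads passing the mapping-quality cutoff used when the pileup was built.
Those counts are sufficient statistics for every filter below, which keeps
the package small, fast and easy to validate against simulations with known
ground truth.

## The filter cascade

For each position covered in both the DNA and one RNA replicate, with at
least one non-reference RNA read, the cascade evaluates **all** of the
following and records every failure (no short-circuiting), so that
per-filter attrition tables can be produced:

1. **DNA coverage** — at least `min_dna_reads = 4` genomic reads.
2. **Strict DNA homozygosity** — the maximum-likelihood DNA genotype is
   hom-ref *and* at most `max_dna_alt_reads = 0` non-reference reads are
   present ("completely homozygous"). This is deliberately strict: a single
   stray DNA read vetoes the site.
3. **Biallelic RNA site** — no second non-reference allele with
   `min_alt_reads` support; indels are excluded structurally (the pileup
   schema is SNV-only).
4. **RNA coverage** — at least `min_rna_reads = 10` RNA reads.
5. **Alternative support** — at least `min_alt_reads = 2` edited reads.
6. **Mapping quality** — every covering read passed MAPQ `min_mapq = 20`
   at pileup construction (`frac_mapq_ge = 1`).
7. **Site quality** — the phred-scaled posterior that the RNA site is
   *not* hom-ref is at least `min_site_qual = 95`, with a
   `min_mean_baseq = 20` sanity floor on mean base quality.
8. **Strand bias** — the phred-scaled two-sided Fisher exact test on the
   (ref, alt) × (forward, reverse) table is at most `max_fs = 30`.
9. **Splice proximity** — intronic sites within `splice_window_bp = 4` of
   a splice junction (the first or last base of any intron of any
   transcript overlapping the site) are removed; exonic sites adjacent to
   junctions are untouched. Junctions come from the supplied GFF3, the
   only junction source the pipeline has.
10. **Edit ratio** — the fraction of edited RNA reads must lie in the
    *inclusive* band `[0.10, 0.95]`; the rule discards strictly below 10%
    and strictly above 95%, so a site at exactly 0.10 or 0.95 is kept.
11. **Repeats** — if a repeat BED is supplied, sites inside repeat
    intervals are removed (repeat exclusion defaults to on exactly when a
    repeat set is given).

Candidates failing nothing are PASS sites. PASS sites detected in **every**
biological replicate of a tissue — matched on the full (chrom, pos, ref,
alt) key, so the same position edited to different bases is *not* one
site — are the tissue's *common editing sites*, the unit reported
downstream.

## Genotype model and the site quality

The caller is a deliberately simple maximum-likelihood diploid model over
\{ref/ref, ref/alt, alt/alt\}, where alt is the highest-count non-reference
base. With per-read error $\varepsilon$, an alternative read arises with
probability $\varepsilon$, $1/2$ and $1-\varepsilon$ under the three
genotypes, giving binomial likelihoods on the (ref, alt) counts. The site
quality is
$$\mathrm{QUAL} = -10\log_{10} P(\text{hom-ref}\mid \text{counts}),$$
the posterior under a flat genotype prior, capped at 10000. By default
$\varepsilon$ is derived per site from the pileup's mean base quality as
$10^{-q/10}$ (clipped to $[10^{-6}, 0.25]$), so the caller is
self-consistent with the data's own quality scores;
`filter_config(genotype_error_rate =)` overrides it.

Two consequences of this model are worth stating explicitly, because they
are properties of any calibrated caller, not implementation accidents:

* **Low edit ratios earn low site qualities.** With
  $\varepsilon = 10^{-3}$ the hom-ref/het likelihood crossover sits at an
  alt fraction of almost exactly 10%, and a phred-95 posterior requires
  roughly 8 edited reads at 40x. A true site edited at 15% therefore fails
  the `min_site_qual = 95` gate in a substantial fraction of replicates no
  matter how the caller is tuned: the probability of seeing $k$ errors in
  40 reads bounds the attainable confidence. The quality gate, not
  coverage, is the binding constraint on sensitivity below ~25% edit
  ratio. The acceptance script measures exactly this.
* **High edit ratios call hom-alt, not het.** Above an alt fraction of
  ~90% (at $\varepsilon = 10^{-3}$) the maximum-likelihood genotype is
  alt/alt. RNA editing is not constrained to 50/50 allele balance, so the
  cascade does not demand a het *label*: it demands a confidently
  non-reference, biallelic site (gate 7) with an edit ratio inside the
  band (gate 10). This choice also makes the band's inclusive upper bound
  at 0.95 meaningful; requiring a literal het call would silently empty
  it.

The Fisher strand statistic is computed exactly: all tables with the
observed margins are enumerated with log-space factorials, the two-sided
p-value is the sum of hypergeometric probabilities not exceeding the
observed table's (the standard convention, with a $1+10^{-7}$ relative tie
tolerance), clamped to $\ge 10^{-300}$ before the phred transform. An
all-zero table returns 0 by convention. The test suite checks it against a
brute-force enumeration oracle on every 2×2 table with total up to 40 and
against `stats::fisher.test`.

## Strand correction, regions and consequences

Because bulk RNA-seq is typically unstranded, the raw genomic substitution
confounds a type with its reverse complement (genomic T>C on a minus-strand
gene is A-to-G editing). Types are therefore assigned on the *transcript
sense strand*: if all transcripts overlapping a site lie on one strand the
genomic pair is relabelled (complemented for minus-strand hosts) into one
of the 12 substitution types; positions overlapped by transcripts on both
strands, or by none, are "unassigned" and excluded from the type spectrum.

Region classes follow the conventional annotation precedence when several
transcripts overlap: `exonic (CDS) > splicing > ncRNA exon > UTR5 > UTR3 >
intronic > intergenic`. "Splicing" is retained as a class even though such
intronic sites are usually already filtered — the classification window and
the detection window are configured independently. For exonic sites the
affected codon is rebuilt from the spliced CDS in transcript orientation
(reverse-complemented for minus-strand models), the edited base substituted
at its codon offset, and both codons translated with the standard genetic
code (table 1 only; no mitochondrial code). Stop-loss is classified for
completeness alongside stop-gain. Amino-acid changes are reported as
one-letter pairs ("Y→C") without a position index, since the toy
coordinates of the simulator carry no biological meaning.

## What the simulator emulates — and what it does not

The synthetic-data module generates: random chromosome sequences;
non-overlapping genes (~50/50 strands, 2-5 exons, a configurable ncRNA
fraction) with CDS/UTR structure; true editing events with per-site type,
host strand and edit ratio; true heterozygous and homozygous-alternative
DNA SNVs (so the "heterozygous at DNA, therefore not an RDD" rejection
path is exercised); and Poisson-depth pileups in which allele counts
follow the diploid genotype (DNA) or the binomial edit ratio (RNA), a
uniform substitution error redirects reads to the three other bases, and
reads split ~50/50 across strands. RNA coverage spans transcripts —
introns at a reduced pre-mRNA factor (default 0.4) — plus a random 5% of
intergenic background at low depth. Everything is deterministic given the
seed, byte for byte.

Default conditions were chosen once, as a realistic bulk study: DNA at
25x, RNA at 40x over exons, substitution error $10^{-3}$ (phred 30, also
the emitted mean base quality), heterozygous and homozygous SNV rates of
$5\times10^{-4}$/bp each, 200 editing events with ratios uniform on
[0.15, 0.90], and a type spectrum dominated by A-to-G (42%) with C-to-T,
G-to-A and T-to-C at ~10% each, mirroring mammalian tissue spectra.
Intronic truth sites are kept clear of the splice window by construction,
so every placed site is detectable in principle.

Deliberately *not* modelled: read-level artifacts (the input is counts,
not reads), PCR duplicates, splice-aware misalignment, expression-level
variation between genes, overlapping or bidirectionally transcribed genes
by default, and indels (the cascade's input schema is SNV-only). Passing
the injection-recovery tests therefore demonstrates the correctness of the
*cascade arithmetic and bookkeeping* under the stated statistical model —
it does not certify performance on real alignments, where misalignment
noise is structured rather than uniform.

## Numerical and design choices

* Coordinates are 1-based inclusive in every emitted file (FASTA, GFF3,
  pileup, VCF); BED is 0-based half-open and converted on read.
* Edit-ratio band bounds are inclusive (see gate 10).
* The published "base quality ≥ 95" threshold is interpreted as the
  phred-scaled *site* quality of the RNA variant call — per-base phred
  qualities cannot reach 95, and a GATK-style QUAL is the only quantity on
  that scale in the upstream workflow this package re-implements. The
  mean base quality keeps a separate ≥20 floor. This interpretation is a
  design decision, stated here rather than silently reinterpreted.
* Ties in the top non-reference allele are broken in A<C<G<T order;
  genotype-likelihood ties resolve to the earlier genotype in
  (hom-ref, het, hom-alt) order. Both are deterministic.
* The p-value clamp at $10^{-300}$ caps FS at 3000; site quality is capped
  at 10000.
* Degenerate inputs: zero-depth sites are no-calls; an all-zero Fisher
  table scores 0; an empty gene annotation disables the splice and typing
  logic (types become "unassigned", regions "intergenic"); conflicting
  reference bases between the DNA and RNA pileups at a position are an
  error, not a warning.
* The replicate-intersection key includes ref and alt. A per-site mean
  edit ratio across replicates is reported for common sites.
* Problem sizes in the shipped tests and the acceptance script (two 50 kb
  chromosomes, 30 genes, 200 truth sites, 3 replicates) were chosen so the
  full injection-recovery study runs in well under a minute while leaving
  every per-filter decision statistically visible.

## Known limitations

* Sensitivity below ~25% edit ratio is bounded by the phred-95 site
  quality gate at 40x coverage, as derived above; rescuing those sites
  requires either deeper RNA coverage or relaxing `min_site_qual`, both of
  which are configuration choices, not code changes.
* The strict homozygosity rule (`max_dna_alt_reads = 0`) vetoes a site
  whenever a single sequencing error lands on it in DNA (~2.5% of sites at
  25x with error $10^{-3}$); `max_dna_alt_reads` is configurable for
  users who prefer calibrated tolerance over the published strictness.
* One transcript model per gene; overlapping isoforms are supported by the
  data structures but not generated by the simulator.
* The consequence caller evaluates the first protein-coding transcript
  (by identifier) whose CDS contains the site; with the simulator's
  non-overlapping genes this is unique.
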