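---
title: "Methods: characterizing piRNA populations with planted-truth synthetic data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing piRNA populations with planted-truth synthetic data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis

Piwi-interacting RNAs (piRNAs) are ~23–29 nt small RNAs that guide
Piwi-family proteins, canonically to silence transposable elements. Two
properties make a piRNA population informative about its biogenesis route:
*where* the reads come from (transposon copies, satellite DNA, or gene
models — and, within genes, CDS-exons, introns or UTRs, on the sense or
antisense strand), and *how* sense and antisense reads relate positionally.
The germline ping-pong amplification loop cleaves a transcript opposite
nucleotides 10–11 of the guide, so reciprocal piRNA pairs share exactly 10
nt between their 5′ ends; an excess of 10-nt 5′–5′ overlaps over other
overlap lengths is the ping-pong signature. Somatic (e.g. brain) piRNA
populations typically lack this signature and can instead show a transposon
*sense* bias and a predominantly genic origin.

`pirnaflow` implements this characterization as separable stages —
screening, exact mapping, hierarchical category assignment, strand-bias
spectrum, ping-pong z-score, negative-binomial differential expression and
antisense/gene concordance — and pairs it with a generator that forges an
annotated genome and read populations in which every one of those signals
is planted with known value. The package's tests and acceptance script are
round trips: plant, run the full pipeline, compare the recovered quantity
with the plant at binomial-sampling tolerance.

## The synthetic genome

`genome_spec()`/`build_genome()` lay out non-overlapping feature blocks —
gene models (5′UTR, alternating CDS-exons and introns, 3′UTR, abutting
without gaps, random strand), transposon copies grouped in families of the
LTR and LINE classes (copies alternate strands so both orientations exist),
satellite loci, and tRNA/rRNA/snRNA/snoRNA blacklist loci — separated by
random spacers on a small number of contigs, with every sequence drawn
uniformly at random.

One deliberate departure from real genomes: every k-mer of length
`uniqueness_k` (default 18, i.e. below the minimum read length) occurs
exactly once genome-wide *up to reverse complement*. Duplicated canonical
k-mers are repaired by point mutations (bounded rounds; the build fails if
a spec is too dense to repair). This makes exact mapping of ≥ 23 nt reads
provably unambiguous, so classification logic is tested in isolation from
multimapping policy; multimapping behaviour itself is exercised by
dedicated fixtures that duplicate sequence on purpose. Consequently
satellite loci are *annotation-level* satellites (typed intervals), not
sequence-level tandem repeats, and transposon copies of a family share a
label, not a sequence.

## The read populations

`read_profile()` fixes the planted composition: the category mixture over
transposon/satellite/genic/blacklist, the genic part mixture, the
transposon sense fraction, a length distribution on 23–29 nt, and the
fraction of transposon reads drawn from planted ping-pong pairs. Two
presets encode the tissue contrast:

* `profile_brain()`: 87.8 % genic (exon .62 / intron .11 / utr5 .05 /
  utr3 .22), 10 % transposon with sense fraction 0.70, 0.2 % satellite,
  2 % blacklist, no ping-pong pairing.
* `profile_ovary()`: 90 % transposon with sense fraction 0.30 and 30 %
  ping-pong pairing, 2.3 % satellite, 5.7 % genic (intron-weighted:
  .12/.66/.15/.07), 2 % blacklist.

The exon/3′UTR and intron weights, the satellite shares and the 90 %/10 %
transposon split are the published tissue percentages; the brain
intron/5′UTR split, the numeric sense fractions, the blacklist share and
`genic_sense_fraction` (0.5) are this package's defaults, chosen once as
plausible values and flagged as such in the preset documentation.
`profile_tud_brain()` differs from the brain preset only in sense fraction
0.5 — the population whose parity the bias test should *not* reject.

Real small-RNA libraries concentrate their reads on a limited set of
distinct species, and the minimum-count filter presupposes that. The
simulator therefore works in two levels. Each mixture cell (category ×
gene part × orientation) receives a pool of *species* — fixed (locus,
length, strand) triples whose size is the cell's expected read count
divided by `mean_species_count` (default 25). Each of the `n_reads`
instances then draws its cell independently per the profile probabilities
and a species uniformly within the cell. Composition fractions are thus
exactly multinomial at the instance level (so binomial standard errors
apply to the round-trip targets), while every species accumulates ~25
pooled counts and survives the count filter with near certainty
(P(Poisson(25) < 10) ≈ 4×10⁻⁴).

Ping-pong pairing is planted without perturbing the mixture: a fraction of
transposon instances is drawn from pools of species *pairs* placed inside
one transposon copy with the + member's 5′ end at p and the − member's 5′
end at p + 9 — exactly 10 shared positions. Both members accumulate
counts, so O(10) receives a large product-weight excess while the total
read count stays exactly `n_reads`. Two side effects are documented rather
than hidden: the overall transposon sense fraction becomes
(1 − pp)·f + pp/2, and paired species exist only within transposons, as in
the germline mechanism.

`simulate_counts()` plants differential expression directly at the count
level: group-A mean `baseline_mean`, group-B mean shifted by
±`log2fc_magnitude` for a `de_fraction` of features (sign drawn so that
`down_fraction_among_de` go down), independent NB(μ, φ) replicates. The
presets carry the two direction mixtures (brain .85 down, ovary .39 down)
at de_fraction 0.3, |log2FC| 3, baseline 100, φ 0.1, 3+3 replicates.

What the generator does **not** emulate: sequencing errors, adapters,
quality-score structure, chimeras, genuine multimapping families, 1U/10A
nucleotide composition, or any coupling between a species' abundance and
its genomic context. Passing round trips therefore demonstrate that the
*measurement* stages are correct at realistic desk scale — not that the
pipeline is robust to artifacts the generator never produces.

## Stage conventions and numerical choices

* **Coordinates** are 0-based half-open internally; GFF3 (1-based
  inclusive) is converted at the boundary; BED6 is emitted natively. The
  5′ coordinate of an alignment is `start` on + and `end − 1` on −, and
  the 5′–5′ overlap is k = fp(−) − fp(+) + 1 (1-based inclusive: k = 10
  means ten shared positions).
* **Screening**: blacklist removal triggers on ≥ 1 nt overlap on either
  strand (the strictest contamination rule, since no overlap fraction is
  published); the minimum count of 10 is taken over the pooled sum of all
  samples, with a `per_group` scope available since the original pooling
  convention is not stated. Each filter is a pure per-read predicate, so
  the screen is order-independent and idempotent.
* **Assignment**: the transposon ≻ satellite ≻ genic hierarchy is decided
  across *all* of a read's alignments; qualifying overlaps must cover
  ≥ 50 % of the read (configurable) to prevent 1-nt grazing assignments;
  deciding-alignment ties go to the leftmost (contig, start); gene-part
  ties follow utr3 > utr5 > exon > intron; "exon" means CDS-exon, disjoint
  from the UTRs. Composition percentages weight each species by its pooled
  count by default (`weighting = "unique"` counts each species once; the
  published convention is unknown, so both exist).
* **Strand bias** uses the exact binomial rather than a normal
  approximation because desk-scale weighted totals can be small; weights
  are rounded to integers for the test.
* **Ping-pong**: pair weight is the product of the two read counts
  (`min` selectable); background window k ∈ [1,20] \ {10}; the z uses the
  n−1 sample standard deviation and raises an informative error when the
  background is degenerate (all bins equal). The pipeline computes the
  histogram over **all** retained piRNA alignments, not only
  transposon-assigned ones: planted pairs live only inside transposons, so
  the signal is unchanged, but a genic-dominated library (brain) retains a
  non-degenerate background at 20,000 reads.
* **NB differential expression**: both group means are fitted by Newton
  iteration on the NB likelihood at fixed φ (closed form under equal
  factors; gradient tolerance 1e-8, damped steps, bounded iterations), the
  LRT is referred to χ²₁, and log2FC uses a 1e-8 pseudo-mean floor so
  all-zero groups are finite. Two estimator choices matter at 2–3
  replicates and are the package's defaults after explicit calibration
  checks (the type-I suite in the tests): (i) *normalization* — total-count
  factors acquire composition bias when a large, direction-skewed fraction
  of features changes, so the default locates the mode of each sample's
  log-ratio density against a reference sample (the null cluster's peak),
  which stays centred where total-count and trimmed-mean factors drift;
  (ii) *dispersion* — the plain moment/median estimator underestimates φ at
  3+3, inflating the LRT, so the default maximizes a Cox–Reid-adjusted
  profile likelihood (each profiled group mean contributes half the log
  Fisher information). `size_factors()` (total-count) and
  `estimate_dispersion()` (moments) remain exported and selectable.
* **Concordance**: a pair requires significance on both sides; the
  antisense restriction is applied at the pairing step by default (a flag
  disables it); multi-target piRNAs contribute one pair per significant
  target unless `collapse_targets = TRUE`; zero-fold-change pairs are
  excluded and tallied; the headline fraction carries an exact binomial CI.

## Problem sizes and determinism

All simulation-backed checks run at deliberately modest scale — 20,000
reads per library over 4 samples against a ~60 kb genome, 2,000 features ×
3+3 replicates for DE, 100–200 repeats for the significance studies —
sizes at which every planted quantity is separated from its alternatives
by several standard errors while the whole suite stays fast. Every source
of randomness flows through an explicit seed (`withr::with_seed`), and
fixed seeds give byte-identical FASTA/GFF3/TSV outputs; the pipeline
manifest records per-stage row counts and file checksums so rerun identity
is checkable.

## Known limitations

Exact matching only (no mismatches or indels) — appropriate for error-free
synthetic reads, deliberate for isolating classification logic; SAM/BAM
ingestion is out of scope. The shared-dispersion NB-LRT is a fully
specified, oracle-checkable stand-in for exact-test/tagwise machinery and
is validated by simulation, not by agreement with any external
implementation. Published z-scores from real libraries depend on the
underlying data and database versions and are not reproduced here; the
package reproduces the *qualitative* tissue pattern (signature present vs.
absent) and the planted quantitative round trips.
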