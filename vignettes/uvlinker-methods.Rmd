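---
title: "Methods: simulated UV sex-chromosome discovery and molecular divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated UV sex-chromosome discovery and molecular divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvlinker)
```

# The problem

Dioecious bryophytes carry UV sex chromosomes: the dominant life stage is
haploid, females carry a U and males a V, and both are hemizygous for the
organism's whole life. Given whole-genome resequencing of one male and one
female genotype, three questions follow naturally:

1. Which parts of the assembly are sex-linked? A U-linked sequence receives
   reads only from the female sample and a V-linked sequence only from the
   male, so presence/absence shows up as an extreme male:female coverage
   ratio.
2. How fast are sex-linked genes diverging relative to autosomal and
   organellar genes? Pairwise dN/dS against orthologs of a related species
   answers this, with ω > 1 the signature of diversifying selection.
3. Do candidate stress-tolerance genes differ in copy number between the
   sexed genotypes, and are they expressed sex-specifically? A per-gene
   coverage-ratio scan plus qPCR relative quantification answers this.

Field samples of wild plants are never axenic, so a decontamination stage
precedes everything: host and microbial reads separate on GC content when
the host sits near 45% GC and the dominant contaminants near 65%.

`uvlinker` implements this pipeline over a synthetic-data generator that
emulates the statistical structure of such a study with exact truth labels,
so every stage has a recovery test. The `analysis/` scripts run the stages
in order (simulate, GC screen, coverage scan, marker cascade, divergence,
qPCR) and write their tables under `results/`.

# The synthetic study design

`sim_config()` fixes the study conditions; they are chosen once to mirror
the sequencing design the pipeline targets and are not tuned per analysis:

* genome: 3 autosomes of 100 kb, U and V segments of 50 kb, a mitochondrion
  (20 kb) and chloroplast (15 kb), and two 50 kb contaminant segments.
  Desk-scale stand-ins for a ~200 Mb assembly; windows, ratios and the
  estimators are all length-local, so recovery behaviour transfers.
* base composition: i.i.d. per site at 45% GC (host) and 65% GC
  (contaminants). Real genomes have isochore and repeat structure; i.i.d.
  composition is sufficient for testing threshold classifiers and k-mer
  peaks, and is the one structural simplification to keep in mind when
  reading the recovery rates below.
* reads: 100 bp error-free pairs, ~300 bp Gaussian inserts (SD 30), depth
  20x per sample, Poisson fragment counts, organelles at 10x the nuclear
  depth (organellar copy number is variable in vivo; the multiplier is a
  free simulation parameter, not a claim about any particular data set),
  contaminants at 30% of read pairs. Base qualities are constant because
  the analysis never uses them; an error process would only blur the GC
  classifier by well under its decision margin.
* ortholog pairs: a random sense-codon ancestor evolved along two branches
  of length t/2 by a Gillespie-style continuous-time codon process in which
  nonsynonymous changes have rate ω times synonymous ones, transitions are
  weighted κ, and stop-introducing events have rate zero. Rates are
  normalized so t is the expected number of substitutions per codon; the
  default t = 0.3 per codon (~0.1 per site) is deep enough to be
  informative and shallow enough that counting methods are unbiased.
* qPCR: 3 plants per sex, hydrated and dehydrated, baseline Cq per gene,
  per-gene dehydration shifts in cycles, Gaussian technical noise
  (SD 0.2-0.3 cycles, typical replicate scatter), and structural missingness:
  sex-specific genes never amplify in the opposite sex.

All generators are deterministic given a seed (byte-identical files), which
the test suite asserts by hashing.

# Stage-by-stage notes and numerical choices

## GC screening and k-mer coverage

Reads with GC strictly above 0.55 are discarded together with their mates
(pairs stay intact because assemblers require mated files); GC exactly at
the threshold is kept. GC is computed over unambiguous bases only. At 100 bp
the binomial scatter of read GC is ~0.05, so the 0.55 cut sits two standard
deviations from both the 0.45 host and 0.65 contaminant means — recall and
retention near 0.97 are the expected operating point, not a tuning result.

Scaffold-level diagnostics report the two highest-density modes of the
length-weighted GC distribution (Gaussian kernel, default bandwidth 0.02)
and the antimode between them.

k-mers are counted canonically (lexicographic minimum of k-mer and reverse
complement; any k-mer containing N is skipped because canonicalization over
ambiguity codes is undefined). The coverage peak is the global maximum of
the histogram beyond the first local minimum scanned from multiplicity 1
(ties toward lower multiplicity); the k-mer peak converts to base coverage
by read_len/(read_len − k + 1). With k = 31 on 100 bp reads the factor is
100/70, and peak quantization to integer multiplicities makes the estimate
step in units of ~1.4x.

## The coverage scan

Windows are fixed 500 bp tiles from position 0 of each segment; the
terminal partial window keeps its true width and is excluded from flagging
(its mean is noisier and the sex call there is unreliable). Normalization is
the median over baseline windows of cov_a/cov_b with both depths positive —
robust to sex-specific regions inflating one library, and restrictable to
putative autosomes.

The ratio is `log2((cov_a/sqrt(s) + p) / (cov_b*sqrt(s) + p))` with
pseudo-count p = 0.1. Splitting the scale factor symmetrically before adding
the pseudo-count is a deliberate choice: it is the only form that keeps two
exact contracts simultaneously — perfectly proportional samples give exactly
0, and swapping the samples while inverting the scale negates the ratio to
machine precision. Applying the scale to one sample only breaks one or the
other by O(p). At 20x and p = 0.1 a sex-specific window scores
|log2(20/0.1)| ≈ 7.6, far beyond the |ratio| > 4 flag threshold, and a
flagged window is called sample-specific (rather than merely enriched) when
the depleted sample's raw mean depth is ≤ 2.

Flagged windows with identical calls merge when adjacent (configurable gap);
regions report window counts, mean ratio and total bp. Coordinates are
0-based half-open throughout, converting at GFF3 boundaries.

## The marker cascade

Stages are cumulative: every region counts as `region_only`; regions on a
scaffold with a predicted gene reach `has_gene` (scaffold-wide by default,
with an optional distance limit); a gene with a best homology hit of known
chromosome class reaches `has_homolog`; and concordance — male-specific
coverage with a V homolog or female-specific coverage with a U homolog —
reaches `sex_concordant`. Best hits maximise bitscore with deterministic
ties (e-value, then subject id). Discordant combinations are kept and
annotated, never dropped. Chromosome classes of homologs come from an
explicit subject-to-class map rather than id parsing.

## NG86 dN/dS

The estimator is Nei–Gojobori (1986) counting with Jukes–Cantor correction:

* Sites: each codon position contributes a fraction of a synonymous site
  equal to the share of its point mutations (excluding those creating
  stops) that preserve the amino acid, and the complementary fraction of a
  nonsynonymous site. Every codon therefore contributes exactly 3 sites and
  S + N = 3L holds to machine precision — the convention under which the
  estimator is exactly brute-force verifiable. S and N are averaged over
  the two sequences.
* Differences: per codon pair, all orderings of the differing positions are
  enumerated (1, 2 or 6 pathways), pathways through stop codons are
  skipped, and synonymous/nonsynonymous step counts are averaged over the
  legal pathways (over all pathways in the degenerate case where every
  pathway is blocked). Sd + Nd equals the number of differing positions.
* Distances: dS = JC(Sd/S), dN = JC(Nd/N), each defined only below the
  0.75 saturation bound; ω = dN/dS when dS > 0. S can be exactly zero for
  degenerate inputs (e.g. a single ATG codon); this is recorded as a
  `dS_zero` flag with ω undefined.

The estimator is NG86 (κ = 1) rather than a ts/tv- and frequency-corrected
method because NG86 admits an independent exhaustive oracle (the test suite
compares every sense-codon pair and 10,000 random short alignments against
a separate pathway-enumeration brute force at 1e-9). Group-level
conclusions here are threshold-based (ω > 1, class contrasts) and robust to
this choice at simulated scales; recovery tests confirm the estimator is
unbiased within ±0.05 at ω ∈ {0.1, 0.5, 1.0} under its own model with
κ = 1.

Filtering follows the standard conventions: estimates with dS = 0, dN > 2
or ω > 10 are removed with itemised reasons. Retained ratios are
natural-log transformed for statistics; ω = 0 entries receive
log(ω + 1e-4) — the transform of exact zeros is a free choice, and
contrasts are invariant to the log base.

Codon alignments are built by back-translating a protein alignment:
aligned residue columns expand to their source codons, columns gapped in
either row and codon columns containing a stop are removed, and a mask
records the removals. Only the standard genetic code is supported.

## Group statistics

Class summaries report untransformed mean ω ± SE per class (as such results
are conventionally presented) while all testing happens on the log scale:
an omnibus F across classes and targeted contrasts of each class against
the autosomal baseline (treatment coding makes each coefficient exactly
that orthogonal contrast). When a scaffold column is present the model adds
a scaffold random intercept via `lmerTest` (genes on one scaffold share
history); otherwise an ordinary linear model is used and the output says
so. Contrast p-values are reported unadjusted, with a Holm-adjusted column
alongside.

The copy-number scan flags genes at |log2 ratio| > 4 — at 20x this requires
~16-fold difference, i.e. presence/absence or strong amplification, not
sampling noise. qPCR relative expression is efficiency^(Cq_control −
Cq_target) with efficiency fixed at 2 (perfect doubling) by default; the
factorial model tests gene, state, sex and interactions on the ratio, with
per-gene dehydrated-vs-hydrated contrasts via `emmeans`; missing ratios
(no amplification) are excluded listwise, which leaves sex-specific genes
with non-estimable contrasts rather than fabricated ones.

Completeness percentages round half-away-from-zero to one decimal so that
printed shares sum to 100.0 within rounding slack.

# What passing tests do and do not show

The recovery rates (U/V window sensitivity and precision ≥ 0.95 at 20x, GC
recall/retention ≥ 0.9, ω recovery ±0.05) are properties of the pipeline
under the simulator's assumptions: error-free reads, i.i.d. base
composition, no repeats, no paralogy, simple contaminant community, NG86's
own substitution model. Real data add mapping ambiguity in repeats,
coverage waviness, diverged-paralog cross-mapping and codon-frequency bias;
the thresholds are exposed as parameters precisely because those effects
shift operating points. What the tests do establish is that the
implementation computes the intended quantities exactly (oracle
equivalence, closed-form examples, exact invariants) and that the method
recovers truth when its assumptions hold.

# Problem sizes

Test and example problem sizes (genome of ~0.5 Mb, 2000-codon alignments,
100-200 replicate pairs per ω, 40 qPCR seeds) are the package's chosen
desk-scale study conditions: large enough that binomial/Poisson scatter is
far from the decision thresholds, small enough to iterate on quickly.
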