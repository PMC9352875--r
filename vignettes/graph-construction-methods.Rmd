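---
title: "Population-specific genome graph construction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-specific genome graph construction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graphref)
```

## The problem

A linear genome reference represents every individual by a single
haploid sequence, so reads from individuals carrying alleles absent
from that sequence align worse and their variants are called less
sensitively — an effect that grows with the genetic distance between
the sequenced population and the reference. A genome *graph* keeps the
linear sequence as a backbone and adds common population variants as
alternate paths, giving the aligner a choice of allele at each variant
site. The scientific questions `graphref` addresses are: *which*
variants should enter the graph, *how many samples* are needed for a
population's graph to be representative, and *how to remove* the
ambiguity that added variation can introduce.

## Population statistics

Two per-region statistics drive sample-size reasoning, both computed
locus-by-locus from diploid genotype calls against the backbone.

**Nucleotide diversity** is the mean per-base-pair edit distance
between two haplotypes drawn at random (without replacement) from the
population. At a variant locus with alleles $i$ carrying occurrence
counts $|i|$ out of $N$ called alleles, the contribution is
$\sum_{i, j \ne i} |i||j| \, \delta_{i,j} / (N(N-1))$, with
$\delta_{i,j}$ the Levenshtein distance between allele strings; the
region value is the summed contribution divided by the region width in
bp. **Absolute divergence** replaces the second haplotype with the
backbone itself: $\sum_i |i|\,\delta_{i,r} / N$ per locus. Diversity
measures how heterogeneous the population is internally (and is
invariant to which allele is labelled "reference" — a property the test
suite checks by relabelling); divergence measures how far the
population sits from the chosen backbone. The two are independent in
principle: a population can be internally homogeneous yet far from the
reference.

Implementation choices: $\delta$ is plain Levenshtein distance over the
full allele strings including the shared VCF anchor base (the anchor
contributes zero and is harmless); loci are treated independently, with
no phasing, exactly as the locus-wise formulas require; missing
genotypes are dropped from $N$ at their locus only, keeping the count
sums consistent. Loci with fewer than two called alleles contribute
nothing to diversity. We compute on the post-splitting biallelic
representation; a multiallelic site therefore appears as several loci.

## The binomial selection model

A graph is built from $N$ diploid samples by keeping variants whose
*observed* allele frequency reaches a cut-off $f_c$ (default 0.05,
boundary included). Because the builder sees a finite sample, the
observed frequency scatters around the true one: common variants can be
missed and rare ones can slip in. Treating each of the $2N$ sampled
alleles as an independent Bernoulli trial with success probability
equal to the variant's true frequency $f$, the observed occurrence
count is Binomial$(2N, f)$ and the probability that the variant enters
the graph is the upper tail at $k = \lceil 2N f_c \rceil$
(`prob_added()`), computed through the binomial survival function for
numerical stability. The exact-integer boundary $k = 2Nf_c$ is included,
matching the "observed AF $\ge f_c$" rule; note that because the
threshold is an integer count, the addition probability is only
asymptotically monotone in $N$ — it sawtooths where
$\lceil 2N f_c \rceil$ jumps.

Averaging over the population's allele-frequency density $p(f)$ gives
the expected representativeness of an $N$-sample graph. With the ideal
graph defined by the true frequencies, the true positive rate is the
captured fraction of truly-common mass,

$$\mathrm{TPR}(N) \;=\;
\frac{\int_{f_c}^{1} P(\text{added}\mid f)\, p(f)\, df}
     {\int_{f_c}^{1} p(f)\, df},$$

and the false positive rate integrates $P(\text{added}\mid f)\,p(f)$
*below* the cut-off against the same denominator, so it is a count of
wrongly-included variants relative to the ideal graph size (and can in
principle exceed 1 for densities concentrated almost entirely below the
cut-off). Both are evaluated by midpoint-rule quadrature on the density
histogram grid (512 equal bins by default): $p(f)$ is itself an
empirical histogram, so higher-order quadrature would be spurious
precision. A bin straddling $f_c$ is assigned by its midpoint; with 512
bins the resulting error is far below the Monte-Carlo noise of any
empirical comparison.

The empirical counterpart (`empirical_accrual()`) adds real (or
simulated) samples one at a time, selects variants at the observed
frequency, and labels each selected variant true or false by comparing
the *full-cohort* frequency to the same cut-off — complete population
information stands in for truth. Orderings are either seeded uniform
shuffles or "homogeneous" round-robin draws across subpopulation
strata (shuffled within each stratum by the seed), which spreads
consecutive picks evenly over subpopulations; other stratification
protocols can be expressed by supplying an explicit ordering.

## The synthetic population generator

`make_population()` emulates exactly the statistical structure the
model assumes: locus positions uniform along a contig, each locus's
true frequency drawn from a chosen `af_density`, and every one of the
$2N$ haplotypes carrying the alternate allele independently with that
probability. About 10% of loci are 1–3 bp indels so the edit-distance
machinery is exercised; truth tables of true frequencies are returned
so every downstream result can be scored. Three fixed Beta-shaped
spectra (`af_spectrum_presets()`) span the qualitative range seen
across human super-populations: a strongly rare-skewed spectrum
(Beta(0.3, 1.5)) paired with more loci models a high-diversity
population; a common-skewed spectrum (Beta(0.8, 0.8)) with fewer loci
models a low-diversity one. This reproduces the two features that drive
the sample-size result: diverse populations carry both more variant
sites and a larger rare fraction, so their accrual curves rise more
slowly — the acceptance suite checks that the more diverse synthetic
population needs at least as many samples to first reach TPR 0.9 in at
least 16 of 20 paired replicates.

What the generator deliberately does **not** model: linkage
disequilibrium, phasing structure, mutation-rate heterogeneity,
sequencing error, or genotype uncertainty. The locus-independence is a
feature for validating the locus-independent formulas, but it means
passing tests demonstrate correctness of the implemented model, not
robustness to LD-induced correlations in real cohorts.

The problem sizes used by the test and acceptance runs — 500-sample
populations with 1,500 loci for accrual, 60 kb contigs, 6 kb pipeline
genomes — were chosen as the smallest sizes at which Monte-Carlo noise
is comfortably below the tolerances being checked.

## Graph construction pipeline

`construct_graph()` runs five stages, each with explicit record
accounting (every input record is kept or logged with a removal reason;
the logs are part of the output):

1. **Harmonization.** Each source VCF passes a quality filter (keep
   FILTER `PASS` or missing, replaceable by a predicate), multiallelic
   splitting with per-allele AC/AF bookkeeping, and left normalization
   (trim shared trailing bases, extending left with the preceding
   backbone base when an allele would empty; then trim shared leading
   bases keeping one). Normalization is idempotent and
   haplotype-preserving; a record that would walk off the contig start
   stays at position 1 and is flagged.
2. **Alt-contig decomposition.** Alternate-haplotype contigs are
   removed from the assembly and their alignments to the primary
   chromosomes are decomposed into SNP/insertion/deletion records,
   left-normalized, so alternate sequence becomes graph paths in
   backbone coordinates. Alignments are *consumed*, not computed
   (assemblies ship them; fixtures generate them); the round trip —
   applying the records to the primary region reconstructs the aligned
   alt contig exactly — is asserted in the acceptance suite. These
   records carry no population frequency and therefore join the graph
   alongside the frequency-filtered set rather than being discarded by
   the AF filter.
3. **Merging and AF recalculation.** Records are keyed by
   (contig, pos, ref, alt). When every source carrying a record
   provides AC and AN, the merged frequency is $\sum AC / \sum AN$;
   otherwise the sample-count-weighted mean of the available AFs. This
   is the only estimator consistent under concatenation of sources.
   Merging is order-independent. Records with no frequency at all are
   dropped and logged by the subsequent AF filter (cut-off $f_c$,
   boundary included).
4. **SV filtering.** Structural variants (longer allele > 50 bp) can
   duplicate sequence present elsewhere, making read-length fragments
   ambiguous. "Similarity" is operationalized as an exact common
   substring of at least the read length $L$ (default 150 bp) — exact
   $L$-mer sharing is precisely what makes a read multi-map — found by
   k-mer anchoring (seed $k = \min(31, L/2)$, coalescing consecutive
   seeds per alignment diagonal), which is exact for matches at least
   $k$ long and is audited against quadratic dynamic programming in the
   tests. Insertion SVs sharing $\ge L$ with the non-decoy backbone are
   removed; of SV pairs sharing $\ge L$, the shorter alt is removed
   (ties keep the smaller coordinate), processed in sorted order to a
   fixpoint; matches on decoy contigs are N-masked on the decoy
   (union of match intervals) so decoys cannot absorb reads belonging
   on SV paths; finally alleles longer than `max_sv_len` are dropped.
   The 10 kb default for `max_sv_len` balances path-length cost against
   SV retention and is deliberately surfaced in the configuration
   rather than hard-coded. Deletion SVs participate in the
   length cap only, since only insertions introduce novel sequence.
5. **Multimap pruning.** See below.

`augment_graph()` implements the iterative loop: cohort calls at or
above the cut-off merge into the prior graph's variant set as a new
source (stamped with the next iteration index in the `ITER` INFO key),
and the SV and multimap filters re-run over the *union* — re-running
over the union rather than only the new records is what makes the
filter postconditions hold globally after every iteration. Prior edges
are never re-filtered by frequency; only the multimap stage may remove
them.

## Multimap detection and minimal pruning

As variants accumulate, distinct regions of the graph can spell
identical read-length sequences, making reads uninformative.
`simulate_reads()` enumerates, for every backbone anchor and every
compatible (non-overlapping) subset of nearby variants, the exact
$L$-mer a read starting there on that path would have — including reads
starting at every internal offset of an insertion allele, so
duplicated insertions are seen end to end. Two variants are considered
incompatible when their reference intervals (including indel anchor
bases) intersect; overlapping alternates are modelled as mutually
exclusive paths throughout — the conservative reading of VCF padding
semantics. Per anchor the enumeration
is capped (64 paths by default) with the reference path and every
single-variant path always retained and remaining slots filled
high-frequency-first, so every edge is exercised even under truncation.

A *placement* is a genomic position: (contig, anchor, allele-internal
offset). A read is **multi-mapped** when its sequence is spelled at two
or more distinct positions; alternate paths spelling the same read at a
single position are not multi-mapping — such a read still has exactly
one location, it merely fails to distinguish alleles there. Placement
lookup is a hash over every spelled $L$-mer of the graph, built by the
same exhaustive enumeration at stride 1, so it is complete for exact
matches by construction and is verified against brute-force spelling
enumeration on small graphs. Mismatch-tolerant multi-mapping, as a
scoring aligner would see it, is deliberately out of scope: exact
duplicate spelling keeps the filter deterministic and auditable.

An ambiguous read is *pruneable* when at most one of its positions is
reachable through the plain backbone (backbone repeats are immutable
and reported separately). The variants to remove are a hitting set over
the per-read implicated variant sets: exact branch-and-bound when at
most 20 candidate variants are implicated, greedy
(most-implicated-first, ties by lowest frequency then coordinate)
otherwise; the acceptance suite checks exact minimality against
exhaustive search on instances with up to 12 candidates. Two natural
objectives exist — fewest variants removed, or fewest base pairs
removed; the package optimizes set cardinality by default (it admits
the clean exact oracle), reports the base pairs removed, and exposes
`objective = "bp"` for the weighted alternative. After pruning, detection re-runs to a
fixpoint; since pruning only deletes spellings, the loop terminates and
cannot create new ambiguity.

The anchor stride defaults to 1 (complete coverage); for larger
backbones a coarser stride trades completeness of *detection* for time
while the placement index stays exhaustive. The read length default,
150 bp, matches the short-read technology the ambiguity argument is
about.

## Numerical and degenerate-input conventions

VCF records are 1-based; every internal interval is 0-based half-open,
converted only at I/O boundaries. Backbones are stored uppercase;
variants touching non-ACGT bases (e.g. the N runs written by decoy
masking) are rejected to a log rather than raising. When AC and AN are
both present the stored frequency is exactly their ratio; a supplied AF
is validated against it only to 1e-5, absorbing the 6-significant-digit
rounding of VCF serialization. Records whose ref disagrees with the
backbone, or that run past a contig end, are rejected to the build log,
never fatal. An empty variant set is a valid graph that spells the
backbone verbatim; an empty cohort is a valid augmentation that changes
nothing.

## Known limitations

- No linkage or phasing in the generator or the statistics; the
  locus-independent formulas are exact for the model, not for real LD
  structure.
- Exact-match multimap semantics understate the ambiguity a
  mismatch-tolerant aligner would experience.
- Site-level merging only: genotype-level conflicts between sources are
  out of scope.
- Database records with no usable frequency are dropped (and logged)
  rather than imputed.
- No breakend or inversion-specific SV handling; no cyclic graph
  structures; no succinct graph serialization (the graph is a FASTA
  backbone plus a sorted VCF of paths and a JSON summary).
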