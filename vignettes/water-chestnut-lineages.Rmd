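---
title: "Tracing water-chestnut maternal lineages with chloroplast INDELs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing water-chestnut maternal lineages with chloroplast INDELs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trapatools)
```

## The problem

Water chestnuts (*Trapa*) include one domesticated species, *T. bispinosa*,
whose seeds are several-fold larger than those of its wild relatives
*T. natans*, *T. japonica* (tetraploid, 2n = 96) and *T. incisa*. Two
questions drive the analysis this package implements: which wild species is
the maternal ancestor of the domesticate, and whether seed gigantism came
from polyploidization or from selection on a diploid genome. The chloroplast
is maternally inherited, so length polymorphisms in the plastome (cpINDELs)
typed by plain PCR identify maternal lineages; flow cytometry against an
internal standard measures genome size and hence ploidy; X-ray CT volumetry
quantifies the edible endosperm.

No sequencing, cytometry or CT raw data are redistributable here, so the
package pairs each analysis stage with a synthetic generator whose ground
truth is recorded, and ships the published summary tables (peak pairs,
marker panel, genotype matrix) as fixtures. Everything downstream of raw
data — variant screening, marker design, typing, distances, trees, sizes,
volumes — is computed, tested and reproducible.

## Synthetic study system

`simulate_reference_genome()` draws a uniform-random quadripartite circular
plastome, linearized at the LSC start: LSC, IRa, SSC, IRb with
IRb = reverse-complement(IRa), enforced as an object invariant. Default
region lengths (88,684 / 24,452 / 18,414 / 24,452 nt) follow the assembled
contig sizes of a domesticated water-chestnut plastome, totalling ~156 kb.

`simulate_lineages()` walks a rooted five-taxon tree (domesticate sister to
a natans-like taxon, japonica-like next, incisa-like and an outgroup more
distant) and plants per-branch variants on reference coordinates:

* **SNPs** under an HKY-like scheme (transition:transversion rate ratio
  `kappa`, default 2, uniform base frequencies). Default per-branch counts
  (10–60) give pairwise divergences of order 10^-3 at full genome size —
  the within-genus regime where composite-likelihood distances are nearly
  linear. SNPs falling in IRa are mirrored into IRb so every leaf keeps the
  quadripartite invariant.
* **INDELs** constructed to *guarantee* an intended motif class: inserted
  homopolymers of 8–12 nt (single-nucleotide repeats), duplications of the
  4–15 nt immediately left of the site (tandem), whole-unit deletions from
  pre-existing microsatellite arrays (SSR), and random non-repetitive
  insertions re-sampled until no class matches (no motif). Each candidate is
  left-normalized and re-classified before acceptance, so the truth labels
  are consistent with the classifier's definitions by construction. INDELs
  are restricted to single-copy regions, at least 300 nt apart (room for
  primers; published amplicons are 135–250 nt) and at least 300 nt from
  region boundaries.

Each leaf genome differs from the reference by exactly the union of variants
on its root path, and `apply_variants()` regenerates every leaf from the
truth record — the round-trip the test suite asserts.

What the generator does **not** emulate: read-level sequencing error,
assembly artifacts, rate heterogeneity across sites, recombination (absent
in plastomes anyway), IR boundary shifts, and INDEL hotspots. Passing tests
therefore demonstrate correctness of the algorithms under clean, known
truth — not robustness to mis-assembled genomes.

`simulate_pileup_candidates()` emulates the variant-screening input: every
true variant with Poisson coverage and allele fraction jittered around 1
(plastomes are effectively haploid), plus per-site false positives at a
configurable rate with fractions centered near 0.3. The screening defaults
(`filter_spec()`: coverage strictly greater than 200, allele fraction
strictly greater than 60%) mirror the study's screen; the fraction threshold
is interpreted per variant as an allele fraction, the natural pileup
reading. `simulate_flow_peaks()` puts multiplicative jitter on the
sample/internal peak ratio, so the ratio estimator is unbiased and its
Monte-Carlo error is the test statistic. `simulate_morphometry()` draws
per-taxon seed dimensions and capsule/endosperm volumes; endosperm fractions
are re-sampled into the observed 53–68.9% interval, and the default volume
presets are calibrated once so that domesticate/wild total-volume ratios sit
in the published 4.2–4.5 range and endosperm-volume ratios in 3.3–3.7, with
the highest fraction in the japonica-like taxon. These presets are study
conditions, not tuning knobs.

## Whole-genome alignment and INDEL discovery

`align_pair()` produces an end-to-end global alignment by anchor-and-chain:
k-mers (k = 21) occurring exactly once in both sequences are chained by a
longest strictly-increasing subsequence, thinned to a 400 nt stride, and the
short inter-anchor segments are solved by affine-gap dynamic programming
(match +1, mismatch −2, gap open 10, gap extend 0.5 — scores that favor one
long gap over scattered short ones, matching the discrete INDELs that
separate near-identical plastomes). Two shortcuts preserve exactness:
equal-length segments whose mismatch count is provably too small for any
gapped alternative to win are taken ungapped, and anchor-free segments
recurse with smaller k before direct DP. Inverted repeats defeat
genome-level k-mer uniqueness, but within an inter-anchor segment the IR
copy is unique again, which the recursion exploits. The contract — identical
output to full dynamic programming on the inter-anchor segments — is tested
directly against unrestricted DP on sequences small enough to afford it.

`extract_indels()` turns maximal gap runs into anchored (VCF-style) events
and left-normalizes them: an event is shifted left through repeat context
until shifting would change its alleles. Left normalization is idempotent
and placement-invariant (applying the original and the normalized event
yields the same sequence), both asserted property-style.

### Motif classification

`classify_motif()` examines an event under **every placement** equivalent to
its normalized position (gaps in repeats are degenerate) and reports all
matching classes plus a primary class with precedence
SSR > tandem > single-nucleotide repeat:

* *single-nucleotide repeat*: the gap allele is a homopolymer and merges
  with an adjacent run of the same base to >= 8 nt in total. The floor of 8
  is a deliberate, conservative choice: published homopolymer-associated
  INDELs sit in runs of ~10, and shorter runs are weak PCR markers.
* *tandem*: the gap allele equals the immediately adjacent substring, or
  starts/ends with one full copy (>= 4 nt, not itself a homopolymer) of it.
  The boundary-unit extension covers real tandem events whose gap spans one
  repeat unit plus adjacent unique sequence — duplications in nature are not
  obliged to align their breakpoints with the repeat unit. The 4 nt floor
  keeps chance 1-in-256 matches from flooding the class.
* *SSR*: the gap is a whole number of units of a microsatellite (unit
  2–6 nt, at least two distinct bases, >= 3 tandem copies, extending at
  least one unit beyond the gap), and the allele itself is periodic in that
  unit. Mononucleotide runs are excluded here — they are the
  single-nucleotide-repeat class.
* *no motif*: none of the above.

A brute-force scanner (exhaustive placement enumeration by string equality,
direct run/period scans) re-implements these definitions independently in
the test helpers; the two agree on 1,000 randomized events per run.

On the published 19-marker panel, the rows whose printed core-sequence pairs
are internally consistent classify to their printed motif column, including
the one double-labelled complex marker (tandem plus single-nucleotide
repeat). Several printed core cells are garbled as published — flanks
shifted by one base, a gap run one column too long, one cell missing
entirely — and those rows cannot match any crisp rule; the acceptance suite
reports them honestly rather than special-casing them.

## Markers and genotyping

`design_primers()` scans the variant flanks for the primer pair closest to
the variant such that both primers are 18–27 nt, bind exactly once
(forward on the + strand, reverse as a reverse complement), pass a Wallace
2AT+4GC melting screen (60 ± 5 °C), and bracket the variant within a
100–300 nt amplicon. Failure is a first-class *undesignable* result — real
marker panels lose candidates at exactly this step. `insilico_pcr()` uses
exact-match binding only: a deterministic model in which failed wet-lab
amplifications map onto the no-product and undesignable paths rather than
onto binding thermodynamics. Multiple possible products raise an error that
lists the sites. `call_genotypes()` codes distinct amplicon lengths 1, 2, …
ascending per locus — **code 1 is the shortest allele**; the published
matrix never states its coding order, so this convention is documented
rather than inferred.

## Plastid types

`assign_plastid_types()` partitions accessions by exact equality of their
code vectors over the marker panel; accessions with any missing call are
excluded and reported (partial-vector matching would silently merge
lineages). Labels are systematic (T01… in lexicographic vector order, hence
row-order invariant) with an optional alias map, because the published type
names encode taxon knowledge the algorithm does not have.

A data note: the published genotype matrix has 12 printed rows, but three
row pairs carry identical nine-locus vectors (the two region-split rows of
one widespread type deliberately so, two further pairs presumably not).
Grouping by vector — the definition of a maternal lineage — therefore yields
9 types from the printed digits, and the largest domesticate type absorbs
29 accessions where the printed layout shows 25. The package computes from
the data; it does not reproduce the printed row count, and the acceptance
suite records the discrepancy rather than hiding it.

## Distances and trees

`mcl_distances()` estimates TN93-family distances with substitution
parameters shared across all pairs, the composite-likelihood scheme:
pooled empirical base frequencies; shared transition/transversion rate
ratios `k1` (purines) and `k2` (pyrimidines) chosen to maximize the summed
pairwise log-likelihood, profiled over per-pair depths (outer L-BFGS-B,
projected-gradient tolerance 1e-8; inner per-pair 1-D maximization with a
Newton polish). Ambiguous positions are removed per pair (pairwise
deletion), and per-pair usable-site counts are reported alongside the
matrix. Fixing `k1 = k2 = 1` with uniform frequencies collapses the
estimator onto the Jukes–Cantor closed form to 1e-10 — the nesting test. A
pair whose maximum-likelihood depth reaches the saturation bound is flagged
with a diagnostic and NA rather than returned as a silent number.

`nj_tree()` is the standard agglomeration with two determinism rules: ties
in the rate-corrected criterion go to the lowest-index pair, and a negative
branch estimate is clamped to zero with the deficit moved to its sister so
the pair sum is preserved. On additive matrices the recovered path lengths
reproduce the input to 1e-9, and the topology matches an independent
reference implementation. `root_with_outgroup()` places the root at the
midpoint of the outgroup's pendant edge. `count_variable_sites()` exposes
both an all-variable and a parsimony-informative census (gapped cells
excluded per column), because "informative sites" is ambiguous in common
usage; the all-variable count is the default reading.

Problem sizes in the test suite are deliberate choices: 20.5 kb plastomes
(proportionally scaled regions) exercise every code path at a second or two
per run, and the 100-replicate five-taxon topology-recovery study runs on
6.8 kb genomes with SNP-only divergence, where the generating counts still
give every internal branch >= 10 substitutions — comfortably above the
recovery threshold, as the >= 95% criterion verifies. Full-size 156 kb
genomes run through the same code in a few seconds and are used in the
round-trip tests.

## Cytometry and morphometry

Genome size is the internal-standard ratio, `(peak / internal_peak) x
internal_size`, assuming fluorescence linear in DNA content with a single
calibration point — exactly the published computation, with rice
(1C = 373,245,519 bp) as the default standard. Ploidy is
`2 x round(size / diploid_baseline)` (half rounds up), reporting the raw
ratio; a ratio below 0.25 errors as an implausible standard. The published
peak pairs reproduce all printed sizes within 0.01% relative — the printed
peaks carry two decimals, so exact integer agreement is not forced.

Volumes from CT label masks are voxel counts times the voxel volume;
grayscale segmentation is out of scope (the original segmentation was
manual), so labeled masks are the input boundary. "Total volume" is defined
as pericarp plus interior — the capsule including endosperm. Interspecific
ratios are ratios of group means, not means of per-seed ratios: seeds are
not paired across species, and the published ranges are aggregate.

## Pipeline

`run_pipeline()` executes simulate → screen → discover → design → genotype →
type → tree → size → morphometry from one nested config (R list or YAML),
validated against the default schema at startup. Thresholds default to the
study's values (200x, 60%, rice internal size). Each stage appends a
provenance line with record counts (the screening stage logs counts before
and after the filter), outputs are plain text (FASTA, TSV/CSV, VCF, newick)
and byte-identical across reruns of the same config, and a failing stage
halts the run with its name while retaining completed outputs.

## Known limitations

* Circular genomes are linearized at the LSC start; events spanning the
  origin are out of scope (none occur in the published panel).
* Insertions relative to the reference are dropped when pairwise alignments
  are merged into the reference-projected multiple alignment; substitution
  distances are unaffected, but alignment-based INDEL analyses should use
  the pairwise events instead.
* Exact-match PCR cannot model partial primer mismatches; markers that
  would amplify weakly in practice appear as clean products or no products.
* The motif classes are crisp rules over a +/- 30 nt window; human repeat
  annotation is fuzzier, and borderline published calls (e.g. a 5 nt
  homopolymer insertion beside an unrelated run) fall outside them.
* The composite-likelihood estimator shares rate parameters across pairs;
  strongly heterogeneous pairs (saturation, extreme composition) are
  flagged, not modeled.
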