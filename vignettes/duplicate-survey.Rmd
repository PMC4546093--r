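---
title: "Surveying evolutionarily young gene duplicates: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveying evolutionarily young gene duplicates: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Gene duplication supplies the raw material for new genes, and the
structural state of a duplicate at birth — whether the whole ancestral ORF
was copied, whether the copy landed on the same chromosome, in which
orientation, and by what mechanism — shapes its subsequent evolution.
`dupliscan` implements a complete survey pipeline for *evolutionarily
young* duplicates (synonymous divergence Ks at most 0.1) in small gene
families (at most five members): paralog discovery by all-against-all
protein similarity, single-link family clustering, codon-level Ks
estimation, curation of annotation artifacts and redundant similarity
pairs, an outgroup-anchored screen for ectopic gene conversion,
anchor-chain alignment of genomic neighborhoods to delineate each
duplication tract, classification of structure (complete / partial /
chimeric), mechanism (DNA- vs RNA-mediated) and genomic geography, and a
battery of cohort-level statistics. A seeded synthetic-genome simulator
plants truth-labelled duplication events so that every stage is testable
end to end without any external download.

## Pipeline stages and their assumptions

### Similarity search and families

Canonical transcripts are the transcripts with the largest summed CDS
length per gene (ties broken by transcript id), because the search operates
in protein space and coding length is what matters there. The search is a
seeded Smith–Waterman: exact 4-residue words shared by two proteins are
grouped by alignment diagonal, and a pair becomes an alignment candidate
when two non-overlapping words lie on one diagonal within 40 residues (a
two-hit rule). Candidates are scored by full local dynamic programming
with BLOSUM62 and affine gaps (open 11, extend 1), and an expectation value
is computed from the Karlin–Altschul formula with the published gapped
constants (lambda = 0.267, K = 0.041). Hits require E <= 1e-10 and >= 40%
identity; identity is matches over all alignment columns, including gap
columns (the common local-alignment convention; the choice of denominator
is not prescribed by the method we follow, so the convention is stated
here once). No alignment-coverage filter is applied. Families are the
connected components of the hit graph (single link): one hit anywhere
merges two families, so the partition is invariant to input order, and
only families of two to five members proceed — the dynamics of large
multigene families differ and are out of scope.

Proteins shorter than the seed word are skipped with a warning; a
precomputed hit table (TSV) can be substituted for the internal engine.

### Ks estimation

Paralog pairs are aligned globally in protein space (Needleman–Wunsch,
BLOSUM62, 11/1) and the alignment is back-translated so that every
amino-acid column maps onto its source codon and every protein gap onto a
3-nt gap. Before estimation the codon alignment is trimmed to its
*well-aligned core*: scoring each column +1 for an amino-acid match and -1
otherwise, the maximal-scoring contiguous run of columns is kept. For
structurally homogeneous pairs this keeps everything; for chimeric pairs it
cuts, within a couple of columns, at the junction where the derived copy's
novel sequence begins — without the trim, a global aligner pairs the novel
tail with unrelated donor sequence and Ks is grossly inflated.

Divergence is estimated with the Nei–Gojobori (1986) counting method:
per-codon synonymous site fractions (a possible change to a stop codon
counts as nonsynonymous), pathway averaging for codons differing at two or
three positions (pathways through stop codons are excluded when any valid
pathway exists), sites averaged over the two sequences, and Jukes–Cantor
correction of the proportions. A synonymous proportion of 3/4 or more is
saturated and yields an undefined Ks; such pairs are dropped with a log
message. At Ks <= 0.1 the difference between this estimator and
maximum-likelihood codon models is second order, which is why a
self-contained counting method is used. Columns containing gaps, stops or
ambiguous bases are removed first and at least 10 codons must remain.

On sequences evolved under the estimator's own assumptions (uniform codon
usage, no transition bias, substitutions placed uniformly over synonymous
sites) the mean estimate stays within 0.005 of the true divergence for
true Ks in {0.01, 0.05, 0.1}; `analysis/05_estimator_calibration.R` and the
test suite recompute this.

### Curation

Three curation steps run between Ks estimation and the youth filter, in
this order: (i) *same-location* pairs — two gene ids on one chromosome
with byte-identical coding extents — are annotation artifacts, not
duplications, and are removed; (ii) within families of three to five
members, only n − 1 of the C(n, 2) similarity pairs reflect distinct
duplication events, so a UPGMA tree is built from the pairwise Ks matrix
and, for each internal node, the minimum-Ks pair spanning the two joined
clusters is retained (ties broken lexicographically by gene id — the tree
tells us *how many* events there were; the representative choice and
tie-break are our determinism decisions); the rest are *shadow* pairs;
(iii) neighboring pairs that duplicated together — collinear on both loci,
with consistent order and strand relation, at most one intervening gene —
merge into *linked sets* carrying the arithmetic mean Ks of their members
and counting as a single event. The one-gene adjacency window is the
smallest non-trivial choice (it is configurable); the merge condition is
purely positional. After curation, events with Ks <= 0.1 (inclusive)
are retained.

### Gene conversion

Ectopic gene conversion homogenizes paralogous sequence and resets the
apparent age of a pair, so every event is screened against an outgroup.
The three coding sequences (two paralogs, best-hit outgroup ortholog) are
aligned through the first paralog, the alignment is condensed to its
polymorphic columns, and candidate fragments are maximal runs of condensed
columns at which the paralogs agree. The fragment score is the run length
with no interior mismatch allowed — the simplest defensible statistic; a
mismatch penalty would add a parameter the data here cannot calibrate.
The observed maximum run is compared with its null distribution over
random permutations of condensed column order; the add-one estimator
p = (1 + #{perm >= obs}) / (1 + n_perm) guarantees p > 0, and Bonferroni
correction across the candidate pairs tested within a family controls the
family-wise call. Linked sets are tested per member ORF and flagged
converted when any member is significant. All downstream statistics are
computed twice: on all events and on the no-conversion subset; events
without an outgroup ortholog stay in both.

The test's power is governed by the number of informative (outgroup-
differing) columns inside the converted tract, roughly tract length times
outgroup divergence. With an outgroup at divergence 0.1 and 3%-divergent
pairs, 300-bp tracts are detected with sensitivity above 0.9 while the
empirical size stays at or below the nominal alpha = 0.05 (the discrete
max-run statistic makes the test slightly conservative); both numbers are
recomputed by the calibration script. Shorter tracts lose power quickly —
at 200 bp sensitivity drops well below 0.9 under the same conditions — and
an outgroup as close as Ks = 0.011 provides few informative sites, so
genome-scale runs with that outgroup detect only the longest tracts. That
is a property of the data, not the test.

### Duplication tract and classification

The genomic neighborhoods of the two paralogs (coding extent plus a 200-kb
flank, widened to 800 kb when a chain touches the window edge) are
compared by exact 31-mer anchors, collapsed into same-diagonal blocks
(joined across gaps up to 50 bp, with identity computed from the
sequences), and chained collinearly with gaps of at most 5 kb on both loci;
inverted copies chain with reversed collinearity. K-mers occurring more
than ten times in a window are treated as repeats and skipped. The
duplication tract is the highest-scoring chain overlapping both focal
genes; its outermost coordinates are the breakpoints, and the *span* is
the minimum of the two tract extents — conservative when the interior of
an old tract has decayed. Anchors cannot reach closer than about one
k-mer length to a true breakpoint, so recovered spans carry an edge error
up to about 2k.

Structure is classified jointly, without inferring which copy is
ancestral, by counting how many of the two coding extents protrude beyond
their tract by more than a 200-bp tolerance (absorbing the anchor edge
erosion): zero protrusions is a *complete* duplicate, one is *partial*
(the tract truncates an ORF and the truncated copy's ORF ends inside the
tract), two is *chimeric* (a breakpoint falls inside a CDS *and* the
derived ORF recruits coding sequence from outside the tract; both the
ancestral gene's continuation and the novel recruitment then protrude).
Unannotated read-through is not inferred.

Mechanism: a pair is RNA-mediated (retrotransposed) iff one paralog is
intronless while the partner has introns and the intronless locus lacks
alignable copies of the partner's introns; a poly-A run (>= 10 nt within
50 bp downstream) is recorded as supporting evidence but not required.
When the two paralogs are near neighbors, the partner's own locus is
excluded from the intron-remnant search window. Two single-exon genes
carry no intron-loss signal and default to DNA. Structural class is
reported as `retro` for RNA-mediated events; complete/partial/chimeric
apply to DNA-mediated events only.

Geography: intrachromosomal iff both paralogs are on one (placed)
chromosome; orientation is direct iff strands agree (defined only
intrachromosomally); distance is the unique sequence between the inner
tract breakpoints, zero when tracts touch. Genes on unplaced scaffolds are
searched but excluded from geography statistics.

### Cohort statistics

Events are stratified into three age cohorts — Ks = 0, 0 < Ks <= 0.025,
0.025 < Ks <= 0.1 (right-inclusive) — and characteristics are compared
across them with log-likelihood-ratio G-tests. The Williams correction
(goodness of fit: q = 1 + (k+1)/(6n); independence:
q = 1 + (nΣ1/R − 1)(nΣ1/C − 1)/(6n(r−1)(c−1))) is applied by default: it is
required to reproduce the reference values this package validates against,
and a flag disables it. When the two older cohorts do not differ for a
characteristic, the two-cohort comparison (Ks = 0 vs 0 < Ks <= 0.1) is
additionally reported. Chromosome frequencies are normalized by
protein-coding gene counts with half-event counting: an intrachromosomal
pair adds one event to its chromosome, an interchromosomal pair adds half
to each, because the ancestral copy cannot be identified. Centromere
analyses bin coding-extent midpoints by distance from the centromere
midpoint in 10-Mb bins, again with half counting when a pair straddles
bins; the bin width is configurable, and the synthetic-study workflow
uses 1-Mb bins because its desk-scale chromosomes span only a few Mb per
arm (a 10-Mb bin would be degenerate there). Trend statistics are Kendall's tau-b (span vs Ks, separately for
DNA- and RNA-mediated events), the Pearson correlation of Ks with
log10(distance) for intrachromosomal pairs (zero distances are excluded —
the log is undefined — and logged), and Wilcoxon rank-sum comparisons of
spans against gene lengths and coding extents. The rank-sum statistic W is
reported as the sum of ranks of the spans in the pooled sample; its
p-value comes from the normal approximation with tie correction and is
identical to the U-statistic convention's p (the two statistics differ by
the constant n1(n1+1)/2). Non-integer (half) counts enter the G formulas
as-is. No multiple-testing correction is applied across the report's many
tests. Sex-chromosome-excluded variants of every analysis are produced via
an `autosomes_only` switch.

## The simulator: what it emulates, and what it does not

`simulate_genome()` builds chromosomes of non-overlapping multi-exon
protein-coding genes. Coding extents are lognormal with median 25 kb and
mean 65 kb (meanlog = log 25000, sdlog = sqrt(2 log 2.6)), truncated to
[2 kb, 300 kb]; the upper truncation trims about 3.6% of the mass so the
realized median stays within a few percent of the target while keeping
desk-scale chromosomes. CDS lengths are uniform over 900–2400 nt, split
into exons of at least 10 codons at codon boundaries; intergenic spacers
are exponential (mean 25 kb, minimum 3 kb); a tenth of genes get a second,
shorter transcript so canonical selection is exercised. Intergenic
sequence is uniform random — no repeat landscape — which keeps the anchor
aligner's false-positive rate negligible; consequences for real, repeat-
rich genomes are discussed under limitations.

`plant_duplication_event()` copies a tract around a compatible donor to a
new location with controlled class, location, orientation, span and target
Ks; partial and chimeric breakpoints fall at codon boundaries beyond the
first intron (so a truncated copy keeps an intron and cannot mimic a
retrogene) and leave at least 900 nt of shared coding region; chimeric
copies gain a novel in-frame exon outside the tract;
retrocopies are the spliced CDS plus a 12-nt poly-A tract. Derived copies
are mutated synonymously — substitutions placed uniformly over NG86
synonymous sites — until the pair's Ks first reaches the target
(first-passage, so the realized Ks slightly overshoots by at most one
substitution step, about 0.005 on the shortest 900-nt shared region; the
study grid therefore targets up to ks_max − 0.006 so every realized value
stays within the youth filter), noncoding tract sequence receives 1%
substitutions, and optional conversion tracts are homogenized back to the
donor. The truth table records the *realized* NG86 Ks and final
coordinates; its schema mirrors the pipeline's events table so recovery
scoring is a join. The outgroup is the pre-duplication ancestor lineage
mutated to synonymous divergence 0.011 (the human–chimpanzee scale), with
noncoding sequence mutated at the matching proportion. Background
divergence is uniform Jukes–Cantor-like, matching the estimator's
assumptions so recovery tests are unconfounded.

Planted events are kept positionally distinct: every inserted copy must
lie outside the linked-set adjacency window of all previous events' genes,
since two independent events that happen to be perfectly collinear
neighbors are, by the curation rule's own definition, indistinguishable
from one linked event. Linked-set behavior itself is tested with
explicitly constructed collinear neighbor pairs.

Not emulated: repeat landscapes, indel evolution, codon-usage bias,
splice-site sequence, UTRs, selection on the copies. Passing recovery
tests therefore demonstrates the pipeline's correctness under its own
model assumptions — clean homology signal, neutral synonymous divergence —
not robustness to repeat-dense or alignment-hostile genomic contexts.

## Problem sizes and numerical choices

The end-to-end recovery experiment uses five chromosomes, 300 background
genes (about 27 Mb) and 60 planted events over the class x location x
orientation grid with Ks spread over [0, 0.094]; this size exercises every
code path while a full run (simulation + pipeline) completes in a few
minutes on one CPU. Permutation counts default to 10,000 per test (2,000
in the recovery run; the calibration experiments use 1,000 with 500
negative and 100 positive replicates). Other numerical decisions, in one
place: Ks saturation at proportion 3/4 returns NA and excludes the pair;
UPGMA ties and equal-length canonical transcripts break lexicographically;
the conversion p-value uses the add-one estimator; anchor k = 31 with
max 10 occurrences and 50-bp block joining; chain gaps at most 5 kb;
structural tolerance 200 bp (several times the typical anchor edge
erosion, far below the smallest real protrusion the simulator plants);
all randomness flows from one root seed per run.

## Known limitations

* The conversion screen needs informative sites: with a chimp-scale
  outgroup (Ks 0.011) only long tracts are detectable, and sensitivity at
  200-bp tracts falls below the 0.9 achieved at 300 bp.
* The anchor aligner assumes mostly unique sequence in the flanking
  windows; in repeat-rich regions the max-occurrence filter discards
  anchors and tracts may fragment (flagged, not silently misclassified).
* Chimeric-vs-partial classification trusts the annotation: an ORF
  extension that is real but unannotated is classified partial.
* The NG86/JC estimator is appropriate for Ks <= 0.1; it is not a
  substitute for ML codon models at larger divergences.
* Same-location removal requires exact coordinate identity; duplicated
  annotation with slightly offset coordinates would survive it.
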