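---
title: "Methods: codon usage, physicochemistry, phylogeny and expression in woxkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon usage, physicochemistry, phylogeny and expression in woxkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

woxkit implements the downstream characterization that is typically run on
a plant gene family — here, the WUSCHEL-related homeobox (WOX)
transcription factors of four Euphorbiaceae species — once the family
members have been identified and curated: codon-usage bias and
expression-host comparison, protein physicochemistry, distance-based
phylogeny with clade assignment, gene-structure and promoter-element
statistics, and relative expression. This vignette documents the models,
the rules and their parameters, the numerical choices, and what the
synthetic-data generators do and do not emulate.

## Codon usage bias

For codon $i$ in a synonymous family of size $k$ with counts $X$,

$$\mathrm{RSCU}_i = \frac{X_i\,k}{\sum_{j \in \mathrm{fam}} X_j},
\qquad
\mathrm{RFSC}_i = \frac{100\,X_i}{\sum_{j \in \mathrm{fam}} X_j},$$

so within every family with nonzero total, RSCU sums to $k$, RFSC sums to
100, and $\mathrm{RFSC} = \mathrm{RSCU} \cdot 100 / k$. A codon has
positive bias when RSCU > 1 and negative bias when RSCU < 1; on computed
values the comparison uses a tolerance of $10^{-9}$ around 1, while
printed two-decimal tables are classified verbatim, so a printed 1.00 is
"no bias". Counting is frame-0 over whole coding sequences; triplets
containing non-ACGT characters are skipped and tallied; the three stop
codons form a TER family of size 3 that participates in the 64-codon
universe, as codon-usage tables conventionally print them.

A codon is called *high-frequency* when its RFSC exceeds 60% or is at
least 1.5 times the family-average frequency $100/k$. Two operator
choices are deliberate and load-bearing:

* the $1.5\times$ clause is inclusive (`>=`): reference tables mark codons
  sitting exactly at the boundary (RFSC 37.50 in a four-codon family) as
  high-frequency, which forces `>=` there;
* the 60% clause is strict (`>`): no table row disambiguates 60 exactly,
  so strictness was fixed once and documented;
* single-codon families (Met, Trp) are never classified — their RFSC is
  trivially 100 and published tables do not mark them.

Codon frequencies are reported per 1,000 codons. Two gene sets are
compared per codon by the frequency ratio $r$; the similarity band is
$0.50 < r < 2.00$ with divergence *inclusive* at both ends
($r \le 0.50$ or $r \ge 2.00$), anchored by published table footnotes that
italicize ratios of exactly 0.50. The band is reciprocal-symmetric, so the
classification does not depend on which set is the numerator. Candidate
expression hosts are ranked by ascending divergent-codon count; ties are
broken by the mean $|\log_2 r|$ over defined non-stop codons, then by
label. The tie-break is this package's own deterministic rule — published
host preferences at equal divergent counts are not otherwise explained.

### The transcribed reference tables

The package ships transcriptions of a published four-species RSCU/RFSC
table and the corresponding codon-frequency-ratio table against four
reference genomes (`inst/extdata/`). `verify_fixtures()` recomputes from
them the cross-species bias partition (19 all-positive, 23 all-negative,
2 all-unbiased, 20 differing), the consensus high-frequency set
{GCA, GAU, CCA, AGA}, the divergent-codon counts of the four highlighted
host comparisons (6, 6, 5, 5), and the clade percentage summary.

Some printed cells are internally inconsistent: the RFSC column does not
equal $\mathrm{RSCU} \cdot 100/k$ for the three *J. curcas* stop-codon
rows and for sixteen *M. esculenta* cells (all of its two-codon families
plus two stop rows), where the printed RSCU values appear to be copied
from neighbouring rows. The transcription carries these values verbatim
with an `anomalous` flag computed from the identity itself
($|\mathrm{RFSC} - \mathrm{RSCU}\cdot 100/k| > 1.2$, i.e. beyond what
two-decimal rounding can explain); consistency tests exclude flagged
cells. The flagged cells do not affect any of the recomputed counts
above. The provenance of the reference-genome frequencies behind the
ratio table is not recoverable, so ratios are transcribed, not recomputed.

## Protein physicochemistry

Profiles follow the ExPASy-style definitions. Molecular weight is the sum
of average residue masses plus one water (18.01524 Da). The net charge at
a given pH is the Henderson–Hasselbalch sum over the N-terminus, H, K, R
(positive) and the C-terminus, D, E, C, Y (negative); cysteine is treated
as ionizable (reduced form). The theoretical pI is the bisection root of
the net charge on [0, 14] to a tolerance of $10^{-3}$ pH units — the root
exists and is unique because the charge is strictly decreasing. The
default pKa set is a documented Bjellqvist-style table
(`default_pka()`); the exact constants behind any particular published
ExPASy run are configuration, not ground truth, so alternative sets can
be supplied, and exact reproduction of published pI values would require
the original sequences. The instability index is the Guruprasad dipeptide
statistic $\mathrm{II} = (10/L)\sum \mathrm{DIWV}(x_i, x_{i+1})$ with the
published weight table; II of exactly 40 is classed unstable (the stable
class is II < 40). The aliphatic index is
$X_A + 2.9 X_V + 3.9(X_I + X_L)$ in mole percent, and GRAVY is the mean
Kyte–Doolittle hydropathy.

## Phylogeny and clade assignment

Distances on protein alignments use pairwise gap deletion; the default
model is the p-distance (the common default for protein NJ trees), with a
Poisson correction $-\ln(1-p)$ selectable. Tree construction is the
Saitou–Nei neighbor-joining algorithm. Two determinism choices:

* Q-matrix ties are broken by the lexicographically smallest pair of
  cluster labels (a cluster is labelled by its smallest leaf), making the
  output independent of input taxon order up to relabeling;
* negative branch lengths are clamped to zero with the deficit moved to
  the sister branch — the common tree-software convention — which changes
  printed lengths, never the topology.

On additive inputs the NJ tree reproduces the input distances exactly
(to $10^{-9}$); the test suite cross-checks the topology against an
exhaustive enumeration of unrooted topologies scored by ordinary least
squares on 5–6 taxa, where full enumeration is cheap, and against the
generating tree on 4–8 taxa (for an additive matrix from a tree with
positive branch lengths, the generating topology is the unique
least-squares optimum at zero residual).

Bootstrap supports resample alignment columns with replacement; the
support of an internal edge is the percentage of replicate trees
containing the same leaf bipartition, computed over the replicates that
yield a tree (a replicate in which some pair shares no comparable columns
is dropped with a warning). Clade assignment is by nearest anchor in the
distance matrix: each non-anchor gene takes the clade of its closest
anchor, with the margin defined as the gap to the best other clade; a
zero margin is reported as "ambiguous" rather than resolved arbitrarily.
Percentages are rounded half away from zero to one decimal, the
convention used for printed clade summaries (38/12/9 of 59 genes gives
64.4 / 20.3 / 15.3).

## Gene structure and promoters

Structure statistics are computed from GFF3 gene models (1-based
inclusive coordinates, segments sorted by genomic start regardless of
strand; one mRNA per gene is assumed, the first being used otherwise).
A gene is "long" when its span exceeds 3,000 bp, matching the "more than
3 kb" convention. The promoter is the 2,000 bp immediately upstream of
the start codon in transcript orientation — on the minus strand, the
reverse complement of the 3' flank of the CDS on the forward strand —
truncated (and flagged) at contig edges.

Cis-element scanning matches user-supplied IUPAC consensus strings on
both strands, reporting every match including overlaps, ordered by
(start, strand, name); a palindromic consensus therefore yields one hit
per strand at the same position. The widely used proprietary motif
dictionaries are not redistributed: the motif table is user input, and
`demo_motifs()` ships a small documented demonstration table (ARE, MYC,
MYB, LTR, ABRE, G-box, GT1 with stress / hormone / growth categories)
for tests and examples. Summaries count hits per gene × motif and per
gene × category, keeping genes with zero hits.

## Relative expression

The 2^-ΔΔCt method with two reference genes: per gene and sample, ΔCt is
the mean target Ct minus the arithmetic mean of the reference genes'
replicate-mean Ct (equivalent to the geometric mean of their linear
quantities); ΔΔCt subtracts the calibrator sample, and the fold change is
$2^{-\Delta\Delta Ct}$ with amplification efficiency fixed at 2, as no
efficiency correction is assumed. The construction makes the calibrator's
fold exactly 1 and the result invariant to a constant Ct shift of a whole
sample (a plate effect). Significance against the calibrator is a
two-sided Student's t-test on replicate-level ΔCt at α = 0.01, with no
multiple-testing correction — matching the convention of small qPCR
panels; with a single replicate the fold is reported and the test
skipped. Heatmap transforms are $\log_2(x+1)$ and, optionally, row
z-scores on the logged values; constant rows are set to zero and flagged
rather than producing NaN. The exact scaling behind any published heatmap
is unstated, so these are documented defaults, not reproductions.

## Synthetic data: what it emulates, and what it does not

Every generator is a pure function of its parameters and a seed, and
returns a truth object sufficient to predict the downstream output
exactly. `expand_seed()` derives disjoint per-generator substreams from
one pipeline seed so adding a generator never perturbs existing datasets.

* `simulate_cds_set()` draws codons iid within the synonymous families of
  a random amino-acid sequence (ATG first, one stop last — no internal
  stops by construction), with per-family codon probabilities given or
  Dirichlet-drawn. RSCU converges to $k \cdot p$; the suite verifies this
  at $4 \times 10^5$ codons, where the 0.05 bound on the maximal error is
  a comfortable three-sigma statement for six-codon families (the TER
  family, with one stop per gene, is far below that sample size and is
  excluded from the bound).
* `simulate_alignment_on_tree()` evolves a uniform-over-20 root sequence
  with Poisson(rate × branch length × columns) substitutions, replacement
  uniform over the other residues — a deliberately non-biological model
  (no empirical exchangeability, no rate heterogeneity, no indels) that
  is nevertheless sufficient for distance and topology recovery tests.
* `simulate_annotation_bundle()` lays out non-overlapping genes with 2–4
  exons, UTRs on terminal exons, alternating strands and intron lengths
  wide enough (60–1,500 bp) that some spans exceed 3 kb.
* `simulate_promoters()` plants motif instances at non-overlapping
  random positions and strands; with a background alphabet disjoint from
  the motif letters, scan counts equal planted counts exactly.
* `simulate_ct_table()` writes target Ct as
  $\mathrm{ref} + \Delta_{\mathrm{base}} - \log_2(\mathrm{fold}) +
  \mathcal{N}(0, \sigma)$ with the references at the reference level, in
  triplicate by default.

Passing on these generators demonstrates correctness of the computations,
not robustness to the many features of real data they do not model:
sequencing and annotation errors, isoforms, alignment uncertainty,
among-site rate variation, motif false positives on realistic
backgrounds, and qPCR efficiency differences.

## Problem sizes and determinism

The shipped test suite runs the published-table reproductions instantly
and sizes its simulations for tight feedback: 100 additive matrices of
4–8 taxa for the NJ checks, 500-column alignments for clade recovery,
$4 \times 10^5$ codons for estimator convergence, 200 seeded Ct tables
for fold recovery. `scripts/acceptance.R` recomputes the same quantities
from scratch at comparable sizes. All randomness flows from the supplied
seed, and re-running any pipeline configuration with the same seed
reproduces byte-identical outputs.

## Known limitations

Family identification (HMM/BLAST screening and domain verification),
alignment construction, de-novo motif discovery, read quantification and
figure rendering are out of scope — curated sequences, alignments, motif
tables and expression matrices are inputs. The ratio table's reference
frequencies and the motif dictionary are user-supplied; published counts
that depend on unavailable inputs (genome-scale protein ranges,
promoter-element totals, heatmap levels) are exercised only as
synthetic-truth round-trips.
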