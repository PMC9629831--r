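---
title: "Methods: mapping the oscillating pharyngeal cuticle secretome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping the oscillating pharyngeal cuticle secretome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`moltmap` reconstructs a spatiotemporal picture of cuticle-centric gene
expression in *C. elegans*: which genes peak at which hour of the ~8-hour
molting cycle, which of them are pharynx-enriched and secreted, how much
low-complexity and disordered sequence their products carry, and which
low-complexity families they form. This vignette records the models, the
parameter defaults and the numerical decisions, and what the synthetic
validation does and does not establish.

## Phase fitting and the temporal map

Each gene's hourly log2 expression series is fit by harmonic regression
at the molting period P (default 8 h):

    y(t) = mu + a cos(2*pi*t/P) + b sin(2*pi*t/P) + e

The fitted curve peaks at `t_peak = atan2(b, a) * P / (2*pi)`; the phase
in degrees is `t_peak / P * 360`, the amplitude is `sqrt(a^2 + b^2)`
(log2 units), and the oscillation p-value is the F-test of the two
harmonic terms against the intercept-only model. A gene is called
oscillating when p < 0.001 **and** the amplitude reaches a floor
(default 0.25 log2 units). The floor exists because at low noise the
F-test alone flags genes with biologically negligible amplitude; 0.25
log2 units (a ±19% swing) is the smallest oscillation we regard as
meaningful, half the smallest planted amplitude. A constant series is
not an error: it returns amplitude 0 and p = 1.

The 360-degree cycle is divided into eight half-open 45-degree bins,
`[45(k-1), 45k) -> hour k`, hour labels 1-based so the molt falls in
"the sixth hour". Half-open intervals ensure the bins partition the
circle with no gene counted twice; the choice of which edge is closed is
a convention, applied consistently everywhere (binning, overlay,
profiles). Sorting by phase and binning commute by construction.

The molt overlay counts, per bin, the oscillating genes that belong to
an independently derived molt-upregulated list; the peak molting hour is
the argmax bin, with ties resolved to the earliest tied bin (plus a
warning) so the result is deterministic. List members absent from the
map are logged and dropped rather than failing the run, since deposited
gene lists routinely contain retired identifiers.

Deposited master tables that already carry phases and annotations can be
consumed by `report_from_master()` (pass-through): phases are taken as
given, so no assumption about how the original study parameterised its
sinusoid is needed.

## Enrichment, secretome and abundance statistics

A gene is tissue-enriched when its TPM in the target tissue exceeds
`fold` (default 1.5) times its TPM in **every** other tissue and is at
least `min_tpm` (default 25). "Relative to all other tissues" could also
mean relative to their mean; the strict every-tissue reading is the
default because it is reproducible and conservative, and
`compare = "mean"` provides the laxer reading. The secretome cutoff is a
signal-peptide score of 0.45, inclusive ("0.45 or more"); genes without
a score are non-secreted with a warning, never dropped silently.

Per-bin abundance profiles report mean, SEM and a two-tailed one-sample
Student t-test of the bin's per-gene values against a global mean. By
default the global mean is computed over the profiled set itself (so the
n-weighted mean of bin means reproduces it exactly); a wider reference —
e.g. the mean over all map genes, the red-dashed-line convention — can
be supplied. Empty bins yield NA means and p = 1 with a warning;
single-gene bins p = 1; zero-spread bins p = 1 when the mean equals the
reference and 0 otherwise. No multiple-testing correction is applied
anywhere, matching the plain per-bin t-test convention of this kind of
chart. The lagged cell-type test compares bin b to bin b-2 with a
one-sided two-sample equal-variance t-test at p < 0.01; bins 1 and 2
have no comparator and are never flagged.

Cell-cluster summaries support two modes. "average" is the per-gene mean
over a cell type's clusters. "max-average" instead takes all values from
the one cluster whose mean over the gene set is highest — chosen once
per cell type, not per gene — because clusters of one cell type often
differ in developmental time, and averaging them dilutes the signal.

Network density is simply unique undirected in-set edges per node, with
self-loops and out-of-set edges dropped with a warning; edge lists are
ingested, not retrieved.

## SEG low-complexity detection

The SEG implementation follows the classic two-stage design at the
standard stringency (window W = 12, trigger K2 <= 2.2 bits, extension
K2 <= 2.5 bits). Stage one computes the Shannon entropy
`K2 = -sum (n_i/L) log2(n_i/L)` of every length-12 window; windows at or
below the trigger threshold seed maximal contiguous runs of windows at
or below the extension threshold, and overlapping residue spans of such
runs merge into candidate regions. Stage two refines each region to the
subsequence minimising the compositional probability

    P0 = Omega * F / 20^L,  Omega = L! / prod(n_i!),
    F = 20! / prod(r_k!)

where `r_k` are the multiplicities of identical residue counts (zeros
included). P0 is computed in log space with `lgamma` to avoid overflow,
incrementally in O(1) per extension so a region of length m costs
O(m^2). Ties within 1e-9 in log P0 go to the longer, then the leftmost
subsequence — deterministic and matching the brute-force oracle used in
the tests. Sequences shorter than the window return no segments with a
warning rather than inventing a short-window variant. Non-canonical
letters are an error by default; `on_noncanonical = "skip"` treats
windows containing them as high-complexity, for proteomes with
selenocysteine or ambiguity codes. Segment coordinates are 0-based
half-open (BED convention). %LCR is segment residues over protein
length.

## Disorder, composition and property waves

A residue is disordered when its track probability is at least 0.5 (the
native convention of per-residue disorder predictors whose output the
package ingests); IDRs are maximal disordered runs of >= 30 residues,
and %IDR is the residue fraction inside IDRs. The 30-residue rule is the
package's own computation; predictor internals are out of scope and
their scores (phase-separation propensity, prion-likeness, protofilament
and amyloid calls) are ingested as tables. PLAAC scores, which reach
down to -60, are shifted by +60 for charting.

Mean amino-acid composition is averaged per protein (each protein one
vector of 20 percentages summing to 100, then averaged unweighted), so
long proteins do not dominate a set's profile; a pooled length-weighted
mode is available. Group property statistics use the same one-sample
t-test machinery as the bin profiles, against the global mean over all
proteins carrying the property. Transcript-weighted property waves
multiply each gene's transcript count by its product's property value
and average within bins; the profile is exactly linear in the counts.

Signal-peptide trimming removes the first 20 residues and is gated on
the secreted flag, so leader hydrophobicity cannot inflate alignment
identity.

## Family discovery

Percent identity comes from global Needleman–Wunsch alignment with
BLOSUM62 and affine gaps (open 10, extend 0.5), implemented on top of
`Biostrings::pairwiseAlignment` so the package needs no external
aligner. Identity is identical pairs over columns where **both**
sequences carry a residue (gap-excluded), which is robust to terminal
gap inflation between proteins of different length; a gap-included mode
is provided.

Families are single-linkage components of the graph whose edges join
pairs at or above an identity threshold; components below
`min_family_size = 3` stay singletons. The default threshold is 55%.
This is deliberately far above the ~30% often quoted for homology:
between unrelated but similarly composition-biased low-complexity
proteins, gap-excluded identity reaches 30–40% by chance (the aligner
pairs the shared minor residues and the both-residue denominator is
small), while family members at realistic divergence (10–20% per-residue
substitution) stay above 60%. 55% sits between the two distributions;
it is an exposed parameter and is recorded in every report's provenance
block. Family labels are assigned by descending size, then by the
lexicographically smallest member, making the labelling invariant to
input order.

Each family is aligned by center-star MSA: the member with the highest
summed identity is the center, every member is aligned to it pairwise,
and the alignments merge under once-a-gap-always-a-gap. This is adequate
for the highly similar within-family sequences the pipeline feeds it and
is not a general MSA engine; degapping any output row reproduces the
input sequence exactly (a tested invariant). Position frequency matrices
give per-column residue frequencies plus the gap fraction (summing to
one); column occupancy is the logo stack width, and the residue
colouring partition (polar G,S,T,Y,C; neutral Q,N; basic K,R,H; acidic
D,E; hydrophobic A,V,L,I,P,W,F,M) is attached as metadata.

## The synthetic-data generator

The generator produces every pipeline input with planted truth, sized to
the study conditions the pipeline is built around (scaled to a 4000-gene
genome by default so the full suite runs in about a minute):

* 13.4% of genes oscillate (the genome-wide fraction behind a
  2716-gene map on a ~20,000-gene genome), with uniform phases, an
  8-hour period sampled at 16 hourly points, amplitudes uniform on
  0.5–2 log2 units and Gaussian noise of 0.25 log2 units. The amplitude
  distribution of real oscillating genes is not pinned down by the
  sources this emulates, so it is an exposed parameter rather than a
  fixed constant.
* 22% of oscillators are molt-upregulated, drawn with weights
  concentrated on the molt bin (1 : 0.25 : 0.02 for distance 0/1/>1
  bins), so the overlay peaks at the planted hour with realistic
  spill-over.
* 13.5% of oscillators are pharynx-enriched at 4-fold; secreted
  fractions are 62% (enriched oscillators), 39% (other oscillators) and
  17% (non-oscillating), the strata the map analysis is designed to
  expose.
* Secreted pharynx genes peaking at the molt hour carry a pharynx
  abundance of 30x the oscillating-set mean — the molt-hour transcript
  wave.
* Six low-complexity families (sizes 7,6,5,5,5,5) are planted among the
  secreted pharynx-enriched genes: each family is a consensus drawn from
  a strongly biased residue frequency (one dominant residue at 55%,
  e.g. Q-, C-, P-rich) mutated per residue at rate 0.15. Secreted
  proteins get a 20-residue hydrophobic leader and a signal-peptide
  score >= 0.45; disorder tracks are piecewise constant, high inside
  planted low-complexity tracts.

Two construction details matter numerically. First, tissue columns are
normalised to one million, and the target column carries the extra
enrichment and molt-wave mass; the generator therefore pre-scales the
planted pharynx values by the induced column-sum ratio (a closed-form
linear solve) so the planted ratios hold *after* normalisation.
Configurations whose planted mass exceeds what the column can carry
(e.g. a large enriched fraction combined with a 30-fold wave on a small
oscillating set) have no solution and are rejected with a configuration
error rather than silently degrading. Second, the 30-fold wave value is
solved self-consistently (the boosted genes themselves raise the global
mean they are defined against), so the measured bin-over-global ratio
equals the configured fold exactly in the noise-free limit.

The generator emulates the *shape* of the real datasets, not their full
texture: no single-cell dropout or count noise, no length/GC biases, no
retired gene identifiers, no partially disordered tracks, and unrelated
background proteins are uniform-random rather than realistically
composed. Passing recovery tests therefore demonstrate that the
pipeline's computations are correct and well-calibrated on data of this
structure — not that the biological classifications would reach the same
accuracy on real single-cell summaries.

## Problem sizes and determinism

Every generator consumes a single integer seed and is bit-for-bit
reproducible; the pipeline adds no randomness of its own, and all report
tables are deterministically ordered. The test suite validates SEG
against an exhaustive brute-force oracle on 200 sequences of length
<= 40, phase recovery on 200 simulated oscillators (mean absolute
circular error under 5 degrees at amplitude 1, noise 0.25), molt-hour
recovery across 100 seeded replicates of the default configuration,
exact noise-free recovery of enrichment and secretion, the ~30-fold
molt-bin wave within [25, 35], rediscovery of the six planted families
at adjusted Rand index >= 0.9, and calibration of the group t-test
(uniform null p-values over 1000 simulations). The molt-wave check
profiles over planted bins: bin-edge fitting noise is covered by the
phase-recovery check, and mixing it into the wave check would measure
two things at once.

## Known limitations

* SEG stage two is O(m^2) per candidate region; proteins consisting of
  thousands of contiguous low-complexity residues will be slow.
* Center-star alignment is a heuristic; for distantly related family
  members a profile-based MSA would be more faithful.
* The identity threshold that separates families is data-dependent; on
  real proteomes the discovered family count moves with it, which is why
  it is a parameter and recorded in the provenance block rather than a
  constant.
* `report_from_master()` trusts the ingested phases and annotations; it
  recomputes summary statistics, not the upstream calls.
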