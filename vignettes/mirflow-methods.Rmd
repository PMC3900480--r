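---
title: "Methods: small RNA-seq miRNA profiling with mirflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA-seq miRNA profiling with mirflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirflow)
```

`mirflow` is a desk-scale re-implementation of a classic pooled-library
small RNA-seq miRNA workflow: three stage libraries (E13/E19/E27-like) of
adaptered single-end reads are cleaned, collapsed, annotated, mined for
known and novel miRNAs, tested for pairwise differential expression, and
followed up with seed-rule target scanning and ΔΔCt qPCR arithmetic. This
vignette documents the models, the tunable parameters, the numerical
choices, and what the bundled synthetic data can and cannot show.

## Read cleaning

Raw reads pass a base-quality screen and are then categorized by a fixed
precedence: 3′-adapter-null → insert-null → 5′-adapter contaminant →
shorter-than-18-nt → polyA → retained. Retained inserts (18–30 nt, the gel
selection window of this library type) are collapsed to unique reads, the
currency of every later stage.

Choices the source protocol left open, fixed here and configurable:

* **Quality screen** (`quality_screen`): fail when more than `fmax = 0.5`
  of bases are below Phred `qmin = 20` or more than `nmax = 1` N calls —
  conventional small-RNA defaults.
* **Adapter matching** (`classify_and_trim`): exact match of the 3′
  adapter's first 12 nt anywhere in the read, with one fallback pass
  allowing a single mismatch. The default adapters are the classic Illumina
  small-RNA sequences; the protocol names the vendor but not the sequences.
* **polyA rule**: an insert with ≥ 80 % A after trimming; applied after the
  length rule so short inserts are counted as short, matching the summary
  table's ordering.
* **Percentages** are reported as count / high-quality × 100, rounded
  half-up to 2 decimals, reproducing the published table formatting. The
  published per-library tallies ship under `inst/extdata/` and the
  accounting identity (retained = high-quality − Σ discards) reproduces
  their retained rows exactly (98.55 %, 97.31 %, 99.09 %).

## Annotation hierarchy

Each unique read is assigned exactly one class with precedence
miRNA > rRNA > tRNA > snRNA > snoRNA > scRNA > repeat > exon_sense >
exon_antisense > intron_sense > intron_antisense > unannotated. The source
methods describe ncRNA screening and miRNA comparison but no total order
over all twelve classes; miRNA is placed first because the published class
table attributes 48–82 % of reads to miRNA, which a decoy-first order would
strip. miRNA matching tolerates ≤ 2 mismatches (ungapped, full length of
the shorter sequence); the other sequence classes require exact substring
matches; genomic-context classes come from the best exact genome hit
intersected with the BED-like tracks (repeat > exon > intron, sense =
hit strand `+`). Reads with a genome hit but no track overlap, and reads
with no genome hit, are both `unannotated` (the published accounting does
not separate them; the per-read table keeps `genome_hits` as a diagnostic).

One printed value did not survive recomputation: the E13 miRNA share is
listed as 48.41 % but its own counts give 7115935/14580115 = 48.81 %; the
package reports the arithmetic value.

## Known-miRNA identification

Three steps mirror the published criteria: (1) unique reads are assigned to
the reference mature with the fewest mismatches (≤ 2, ungapped; ties to the
lexicographically first name); (2) each family keeps its highest-expressed
member as representative, where "expression" is the summed raw count across
the three libraries (the simplest global basis; the source states "highest
expressed" without one) and families derive from names by stripping the
species prefix, arm suffix and paralog letters/numbers (`let-7f-5p` →
`let-7`, `miR-133a` → `miR-133`); (3) matures whose precursor does not fold
into a verifying hairpin are discarded, with "verifying" shared with the
novel-miRNA caller (below). Positional nucleotide bias is computed over
unique identified mature sequences, unweighted — whether the published
percentages are count-weighted is unstated, so the unweighted variant is
the default and a `weights` argument provides the other.

## The folding engine

`fold_mfe()` is a self-contained dynamic program over nested structures:
nearest-neighbor stacking energies for Watson–Crick and G:U pairs,
tabulated hairpin/bulge/internal-loop length penalties with logarithmic
extrapolation, an affine multiloop penalty, minimum hairpin loop 3 nt, and
interior loops capped at 30 unpaired nt. Energies are integer tenths of
kcal/mol; the model is deliberately compact (no terminal-mismatch or
special-loop bonuses) because the pipeline only needs minimum-free-energy
values and pairing topology, not chemical accuracy. The exact model is
exported by `fold_energy_model()` and an independent R-side evaluator
(`structure_energy()`) audits the optimizer: in the test suite the
traceback structure must evaluate to the reported minimum and exhaustive
enumeration of all nested structures on short sequences must not beat it.
An optional `backend = "vienna"` shells out to an `RNAfold` executable when
one is on the PATH; all package internals and tests use the bundled folder.

## Novel-miRNA calling

Candidate reads are those not assigned to a known small-RNA sequence class,
pooled across libraries and grouped by best-hit locus so 3′-trimmed isomiR
variants share their support. Cheap gates run first: per-library support
≥ `min_reads = 5` (the smallest per-library count in the published novel
table), ≤ `hit_cap = 10` exact genome hits, mature length 20–22 nt, and
intron or antisense-exon context. Surviving loci have their ±150 nt flank
folded and must satisfy:

* **mature in one arm**: ≥ 75 % of mature bases paired, all partners on one
  side, ends engaged within 2 nt, and the star at most `max_star_gap = 35`
  nt away — the compactness bound is what distinguishes a hairpin precursor
  from long-range pairing in a 320-nt flank;
* **2-nt 3′ overhang geometry**: the implied star (partners of the mature,
  extended 2 nt past the partner of the mature's 5′ end) lies inside the
  flank, does not overlap the mature, and mirrors the mature's span with
  net bulge asymmetry ≤ 2 nt — a Dicer duplex has sharp ends;
* **no large loops**: no unpaired run > 5 nt inside the mature or star span
  (the source gives no number; this is the Mireap-flavored default);
* **energy**: the refolded local precursor region (mature through star,
  ±2 nt) has MFE ≤ −18 kcal/mol, inclusive — the criterion is stated once
  as "lower than or equal to" and once as "lower than"; the inclusive form
  is used. The energy is evaluated on the local precursor rather than the
  whole flank because a random 320-mer almost always folds below −18,
  which would make the criterion vacuous.

Called candidates are merged by locus identity (the published per-library
lists were merged by an unstated rule; locus identity is implemented) and
named `novel-mir-<k>` by descending total count, ties by coordinate.

## Differential expression

Normalized expression is TPM; zero counts take a 0.01 TPM pseudocount for
ratio arithmetic (needed for finite extreme fold changes). The P-value is
the Audic–Claverie conditional: given count $x$ in one library, the count
in the other is negative binomial with size $x+1$ and probability
$N_1/(N_1+N_2)$; the two-sided P doubles the smaller tail. Because those
tails are not exchangeable in $(x, N_1) \leftrightarrow (y, N_2)$, the
statistic is evaluated in both orientations and the smaller value reported,
which restores exact swap symmetry while matching the closed-form value
$2 \cdot (1/2)^{11}$ at $x{=}10, y{=}0, N_1{=}N_2$. Significance classes
use $p < 0.01$ ("extremely significant") and $p < 0.05$ with an
$|\log_2 \mathrm{fc}| \ge 1$ gate — the published classes name no
thresholds; these are the conventional ones and are configurable. No
multiple-testing correction is applied by default, matching the source
analysis. The test suite checks the engine against direct term-by-term
summation (≤ 1e-10 relative over the $x+y \le 30$ grid) and a seeded
global-null simulation (type-I rate at $p<0.05$ ≤ 0.07 with $n = 2000$
Poisson species).

## Target scanning and qPCR

A target site is a transcript 9-mer pairing antiparallel with miRNA
positions 1–9 (5′ end), zero mismatches, at most three G:U wobbles; no 3′
supplementary pairing is required, and whether the source scanned full
transcripts or 3′ UTRs is unstated — the scanner takes whatever FASTA it is
given. An optional duplex-energy filter (off by default) scores the full
duplex with the bundled energy model. qPCR quantities are
$N = 2^{-\Delta\Delta C_t}$ with replicate Ct values averaged
arithmetically and a non-fatal flag when the replicate SD exceeds 0.5
cycles; the calibrator sample is an explicit argument because the source
plots imply but never name one.

## The synthetic-data generator

`simulate_genome()` builds a block-structured genome (exon / intron /
repeat / intergenic), plants novel-miRNA precursors inside introns, designs
a hairpin precursor for every known mature, draws per-class decoy ncRNA
references, and embeds seed-complement target sites in a transcript set.
Precursors are reverse-complement-palindromic stems (mature plus 4 extra
pairs, GC-rich) closed by 4–8 nt loops, re-verified against the folding
engine (MFE ≤ −18, mature in arm) and redesigned on failure. Decoy
"degradation" loci are the caller's negative controls and are verified
non-hairpins at generation time: a candidate placement whose ±90 nt window
already folds most of the locus into one nearby arm is re-sampled, the
mirror image of the positive-side guarantee — a random locus that genuinely
folds into a compact stem-loop carries no negative label.

`simulate_libraries()` draws per-library clean counts by gamma-perturbed
multinomial sampling: Dirichlet baseline abundances (gamma shape 2, so
every planted species stays detectably expressed), per-library fold-change
multipliers, and a per-species gamma factor with variance `dispersion`
(default 0.05; 0 degenerates to multinomial). This gives
negative-binomial-like marginals with exact library-size conservation, so
`expected counts + contaminants + quality failures = library size` holds as
an identity. Reads are insert + 3′ adapter padded to 44 nt; miRNA reads are
3′-trimmed isomiRs (1–2 nt) with probability 0.2, reflecting the fixed 5′
ends implied by the strong published first-position U bias (planted at
0.85); substitution errors default to 0.1 %. Contaminant classes and rates
default to the published per-category discard fractions, and the quality
-fail rate to the published raw-to-high-quality drop. `min_mirna_reads`
optionally floors the drawn count of each planted miRNA species — the
recovery analyses use 10, the support level their planted loci are
specified to have.

**What the simulation does not emulate:** quality-score realism, indels,
ligation and PCR bias, cross-mapping paralog families with near-identical
sequences, star-strand reads, and real genome repeat structure. Passing the
recovery suites therefore demonstrates that the algorithms are correct on
data satisfying their stated assumptions, not that the thresholds are
optimal for a real duck muscle library.

## Problem sizes

The default configuration is a 60 kb genome, 25 known matures, 8 novel
loci, and three libraries of 20,000 reads; the recovery analyses in the
test suite and acceptance script use 4,000–10,000-read libraries, an 80 kb
genome with 5 planted novel loci against 50 decoys, 500 matures for the
nucleotide-bias check, and the $x+y \le 30$ grid for the P-value oracle —
sizes chosen so the complete validation runs comfortably on a laptop while
every planted signal is still statistically decisive.
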