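---
title: "Models and methods in circpie"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in circpie}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circpie)
```

# The system being modelled

Group I introns are self-splicing catalytic RNAs: an exogenous GTP attacks
the 5' splice site, and a second transesterification excises the intron and
ligates the flanking exons E1 and E2. In the permuted intron–exon (PIE)
arrangement the intron is split inside its P6 helix and the two halves are
moved to opposite ends of a cargo cassette, giving a precursor

```
H1 | 3'intron + E2 | IRES | GOI | E1 + 5'intron | H2
```

(H1/H2 are homology arms that bring the intron halves together, the IRES
drives cap-independent translation, GOI is the gene of interest). If the
split intron retains catalytic activity, splicing of this precursor releases
a **circular RNA** E2–IRES–GOI–E1 whose only scar is the ligated E1–E2
junction. `circpie` models these constructs and implements the sequencing
analyses used to ask, for a panel of candidate introns: does the permuted
intron still fold like the native one, which intramolecular contacts form in
the precursor, how accurate is the junction, and which exon or IRES variants
circularize or translate best.

All coordinates in the package are 0-based half-open (SAM positions are
converted at the parser boundary, exactly once; BED input is already
0-based), and all sequence is handled in the uppercase DNA alphabet with
U→T on input — these match the conventions of the alignment formats the
pipeline consumes.

# Construct model

`intron_spec()` holds the native (GII) sequence with a domain annotation
(P1–P9 helices, loops, etc.) supplied by the user as a BED-like table —
base-exact domain boundaries come from structure models and are treated as
input, not inferred. The split point must fall inside the annotated P6
interval; when unspecified it defaults to the P6 midpoint, a neutral choice
given that the split is defined only to lie "in P6". `build_pie()` assembles
the precursor and records `gii_map`, the partial bijection from precursor
positions to native-intron positions over the intron and exon segments; the
map is the backbone of every GII-versus-PIE comparison. `predict_circle()`
returns the splicing product linearized from the first E2 base, so the
ligation junction sits between the last and first positions.

In `annotate_regions()` exon labels take precedence over P-domain labels
where the annotations overlap (E1/E2 participate in the terminal helices of
some introns): downstream interaction classification treats exon and
homology sequence as their own compartments, so the exon identity is the
informative label there.

# SHAPE-MaP reactivity

Chemical probing marks flexible nucleotides with an acylating reagent (NAI);
the adduct is read out as reverse-transcription mutations. Three channels
are sequenced: modified, untreated (DMSO), and a denatured control that
measures per-position mutability. The per-position reactivity is

$$\mathrm{raw}_i = \frac{r^{\mathrm{mod}}_i - r^{\mathrm{unt}}_i}{r^{\mathrm{den}}_i},
\qquad r = \frac{\text{mutation events}}{\text{effective depth}}.$$

Event placement follows mutational-profiling conventions: a mismatch counts
at its own position, an insertion or deletion counts once at the position
immediately 5' of the event, and events on one read within 2 nt of each
other are merged to the 5'-most position, since nearby mutations typically
arise from a single reverse-transcriptase encounter with an adduct.
Bit-exact parity with any particular profiling tool is a non-goal; the
placement rules are stated so they can be tested exactly.

Tunable parameters, with defaults:

* `depth_threshold = 500` reads per channel — positions below it in any
  channel are masked rather than estimated. 500 trades coverage breadth
  against rate precision (at depth 500 a 1% rate has a ~0.4% standard
  error).
* `min_mapq = 10` for counting reads — excludes multimapper artifacts.
* `merge_distance = 2` nt for event merging.

Normalization uses the 2–8% rule: the scale is the mean of raw values
between the 90th and 98th percentile of unmasked positions (the top 2% are
treated as outliers), and normalized reactivity is raw/scale. Negative raw
reactivities are retained — divergence analysis correlates reactivities,
and clamping would distort the correlations; clamping is available for
display only.

`domain_divergence()` computes, per annotated domain, the Pearson
correlation between GII and PIE reactivities over positions unmasked in
both profiles (mapped through `gii_map`); domains with fewer than
`min_positions = 5` usable positions give a null row. Correlations are
computed on raw reactivities by default: per-profile normalization is a
single positive scale, so Pearson r is unchanged either way (`use_norm`
exposes the choice regardless). `divergence_association()` then rank-
correlates per-intron divergence (1 − r) with circularization efficiency;
with n ≤ 8 introns the p-value is the exact permutation probability over
all n! rank orderings (enumerated), because asymptotic approximations are
meaningless at panel sizes of eight.

# SPLASH interactome

Psoralen cross-linking plus proximity ligation converts base-paired regions
into chimeric reads: a primary alignment carrying an `SA` tag whose
supplementary alignment is the second arm. The pipeline is:

1. **Dedup** — records sharing (reference, position, strand, CIGAR) collapse
   to one. The key deliberately includes position and strand, not CIGAR
   alone: identical CIGARs at different positions are unrelated reads, and
   collapsing them would destroy signal while doing nothing for PCR
   duplicates. Supplementary lines follow their primary's fate.
2. **Extraction** — mapped plus-strand primaries with exactly one same-
   reference, same-strand SA entry become two-arm chimeras; reads with two
   or more SA entries (3-arm chimeras) are discarded and counted, since the
   model is pairwise. Minus-strand primaries cannot be genuine contacts of a
   single-stranded transcript and are excluded, though they still count
   toward the mapped total. The chimera's mapping quality is the minimum of
   the two arms (SA entries lacking one are treated as passing).
3. **Filtering** — mapping quality strictly > 20 and arm span strictly > 10
   nt. "Arm span" is read as each arm's aligned reference length; the
   alternative reading (inter-arm gap) is implemented behind
   `span_mode = "gap"`. Chimeras whose arms abut the E1 3' end and the E2
   5' start within ±5 nt are removed: such reads are consistent with the
   ligated junction of the circular *product* and would otherwise masquerade
   as a long-range contact in the precursor.
4. **Binning** — each arm is assigned by its 5'-most coordinate to a 10-nt
   window (no multi-assignment of boundary-spanning arms, keeping counts
   integral), window pairs with a single supporting read are dropped as
   background, and counts are normalized by the total mapped reads of the
   construct so constructs of different library depth are comparable.

`classify_interactions()` labels windows by majority region and assigns each
pair one category with precedence homology-involved → intron–intron
(same/cross-domain) → intron–GOI → GOI–GOI → other; the categories partition
the pairs, so category aggregates conserve the total normalized signal.
`differential_interactions()` compares replicate groups per window pair or
per category with an independent two-sample pooled-variance t-test on
normalized counts, imputing an observed zero for keys absent from a
replicate (absence of a count is data, not missingness). Raw p-values are
reported with a significance flag at p < .05 and no multiplicity
correction, matching how such screens are typically read; the degenerate
all-equal case reports t = 0, p = 1 rather than erroring.

# Junction libraries, error profiling and variant selection

**N60 extraction.** In the randomized-exon libraries the E1+E2 sequence is
replaced by 60 random nucleotides; circularized molecules are amplified and
sequenced, and the insert is recovered from each read as the sequence
between the first exact match of the 8-nt 5' flank and the next exact match
of the 8-nt 3' flank, kept only if exactly 60 nt, then deduplicated. Flank
matching is exact by default (a `max_flank_mismatch` option exists) — with
8-mers, a single tolerated mismatch already admits appreciable spurious
anchoring. The bookkeeping identity retained + flank-failures +
length-failures + duplicates = reads scanned holds exactly and is asserted
in the tests. `build_pfm()` summarizes the retained inserts as per-position
frequencies with information content $IC = 2 + \sum_b f_b \log_2 f_b$ bits
against a uniform background.

**Junction errors.** `junction_error_profile()` computes per-position
insertion, deletion and mismatch rates from alignments against the
junction-centered circle reference. Insertions are anchored 5' of the
event; deletions are counted at each deleted reference position, with depth
there including the deletion-spanning reads, so a 3% deletion of one base
is reported as a 3% rate at that base. Error classes are mutually exclusive
per event; one read may contribute events at several positions.

**Variant selection.** `call_variant_frequencies()` reports every
non-reference base at frequency ≥ 0.001 with a one-sided exact binomial
tail p-value against a user-set error rate (default 0.001) — an explicit,
testable stand-in for a SNP caller's internal model; caller parity is a
non-goal. Two alphas exist deliberately: the permissive call-level
reporting threshold and the stricter selection-level `alpha = 0.05` used by
`intersect_enriched_variants()`, which keeps variants significant in
*every* replicate sample and ranks them by mean variant frequency.

# Synthetic data

The simulators generate every read-level input with planted ground truth so
the full pipeline is testable end to end without downloads. They emulate
the study conditions at desk scale: profiling channels with untreated rate
0.005, denatured rate 0.08 and unit modification gain at per-channel depth
5000; chimeric libraries of 500 reads over planted arm pairs with ±3-nt
start jitter, 15–35-nt arms, 10% uniform noise and 20% injected PCR
duplicates; N60 libraries of 10,000 reads with constrained positions and
10% length spike-ins; pileups with multinomial counts at depth 2000 and
0.001 error. Where a condition is not dictated by the protocol being
emulated the default is a value typical for such libraries, chosen once.
Every generator takes a mandatory seed and restores the RNG state, so
identical calls are byte-identical; all simulated reads are
substitution/indel-only with no quality modelling, and the parsers
accordingly never require quality strings.

What the simulators do **not** emulate — and hence what passing tests do
not show about real data: sequencing quality profiles and context-dependent
error, PCR amplification bias, psoralen cross-linking efficiency and its
sequence bias, reverse-transcription drop-off, partial-length reads, and
alignment ambiguity (simulated reads are emitted pre-aligned with known
CIGARs). Recovery results on simulated data bound the pipeline's
correctness, not the biology's noise.

# Numerical choices and degenerate inputs

* Reactivity positions failing depth or with a zero denatured rate are
  masked, never raised; normalization requires ≥ 20 unmasked positions and
  a strictly positive scale, otherwise it fails loudly.
* Ties in window majority labels resolve to the most frequent label, first
  seen; tie-break is deterministic.
* Zero-variance groups in the t-test: equal means give t = 0, p = 1;
  unequal constant means give |t| = ∞, p = 0.
* Degenerate PIE segments (empty IRES, GOI or homology arms) are legal
  zero-length segments; the tiling and length-conservation invariants still
  hold.
* Exact permutation p-values switch to the asymptotic t approximation above
  n = 8, where enumeration (n!) stops being worthwhile.

The test suite runs all simulation-based checks at the sizes above (150-nt
reference at depth 5000 for reactivity recovery; 500-read chimeric
libraries; 10,000-read N60 libraries; 100 random constructs and 100 random
SAM fixtures for the property and oracle-equivalence checks), sizes at
which the statistical tolerances asserted are comfortably discriminating.

# Known limitations

* The SAM subset parsed is what the pipeline needs (primary/supplementary
  flags, CIGAR, MD, SA); BAM input should be converted to SAM text first.
* Chimera extraction assumes single-end (merged) reads against a single
  precursor reference, as in the protocol modelled.
* Interaction-energy prediction for observed contacts (RNAcofold) and
  secondary-structure prediction from reactivities are outside the package's
  scope, as are basecalling, demultiplexing and alignment.
* Domain-level divergence inherits the user's domain annotation; the
  package does not infer helix boundaries.
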