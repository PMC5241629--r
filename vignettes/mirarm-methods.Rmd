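---
title: "Methods: arm-resolved miRNA profiling and target prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: arm-resolved miRNA profiling and target prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirarm)
```

This vignette is the package's own account of its models, parameters and
numerical choices. Coordinates are 0-based half-open everywhere inside the
package; 1-based positions appear only in prose about miRNA biology (seed
= positions 2–8 from the 5' end, by field convention).

## Read model and preprocessing

Small-RNA sequencing reads a short insert (a mature miRNA, canonically
~22 nt) plus the 3' sequencing adapter, truncated at the sequencer read
length. `trim_adapter()` therefore removes the read suffix at the
leftmost position where a prefix of the adapter matches with at most
`floor(rate × overlap)` mismatches (`rate` = 0.1); overlaps shorter than
`min_overlap` = 8 are admissible only where they reach the read's 3'
terminus. The floor in the allowance matters: rounding up would permit one
mismatch in a one-nucleotide terminal overlap, i.e. trim the last base of
every read, and trimming would no longer be idempotent on adapter-free
reads. A consequence of terminal matching worth knowing: a read that
genuinely ends with the adapter's first base loses that base. This is the
standard behaviour of adapter trimmers and is irrelevant after the length
filter. `length_filter()` keeps 19–24 nt, the canonical mature length
window; no base-quality filtering is applied because the pipeline's
decisions are all sequence-level.

## Mapping contract

`map_reads()` maps in hairpin space, not genome space: forward strand
only (matures are sense to their precursor), ungapped, all offsets with
Hamming distance ≤ `max_mismatch` (default 1, appropriate stringency for
≤ 24 nt reads). Only minimum-distance hits are retained, and a read
retained at k places contributes weight 1/k to each — a deterministic,
order-independent alternative to random single assignment. Indels are
excluded by design; the simulator likewise produces substitution errors
only (the dominant short-read error mode), which keeps the
aligner/simulator contract closed. A brute-force all-offsets scan is kept
in the test suite as the mapping oracle.

## Peak calling and the mature interval

Weighted read-start profiles are summed over all stage libraries, so a
mature "expressed in at least one stage" is detectable even if shallow in
every single stage; per-stage quantification happens downstream. Per arm
(arms are delimited by the hairpin loop: the region between the last
opening and first closing bracket of the structure; a pair-free structure
falls back to a flagged midpoint split), the peak is the maximum start
count, ties to the smallest position. The mature interval runs from the
peak over the modal read length among reads starting exactly at the peak;
modal ties resolve toward 22 nt, then shorter — the canonical Dicer
product length. Support is the weight starting within peak ± 1 nt: wide
enough to absorb 5' heterogeneity (the simulator's jitter is −1/0/+1 at
0.15/0.70/0.15, emulating Drosha/Dicer imprecision), narrow enough not to
merge distinct isomiRs. `min_support` = 10 weighted reads is this
package's declared detection threshold. Calls are verified to sit in the
stem (≥ 60% of mature positions paired) and flagged novel when no
annotated mature on the same precursor overlaps reciprocally ≥ 50%.

## Folding

`fold_hairpin()` is a base-pair-maximisation (Nussinov) dynamic program:
Watson–Crick plus G:U pairs, minimum hairpin loop of 3 nt, deterministic
traceback pairing each position with the smallest admissible partner. It
is a topological folder — adequate for locating the stem and loop of a
miRNA hairpin and for stem-localisation checks — not a thermodynamic MFE
folder; energy-parameterised folding exists only in the duplex model,
where it is needed. The DP is pinned by an exhaustive enumeration oracle
for all sequences ≤ 15 nt in the tests.

## Expression analytics

Counts per mature and stage are the summed weights of reads starting in
the call's peak ± 1 window; RPM rescales each stage column to 10⁶.
Dominance per precursor and stage compares arm RPM (not raw counts, since
stage depths differ): strictly larger wins, equality is a tie, and stages
with 5p + 3p RPM below `min_total_rpm` = 5 are "low" — a guard against
coin-flip dominance on one or two reads. A precursor switches arms when,
ignoring tie/low stages, each arm dominates at least one stage.

Shannon entropy H = −Σ pᵢ log pᵢ is computed per stage over mature
miRNAs by default (a precursor-level option sums arms first). The
logarithm base is a parameter (natural log default, base 2 available)
because diversity indices are reported in both units in the literature.

Stage clustering uses 1 − Pearson correlation of log₂(RPM + 1) vectors
with average linkage — a standard, monotone choice for expression
profiles; stages are ordered alphabetically before clustering so leaf
order is reproducible, and a zero-variance stage (undefined correlation)
gets distance 1 with a warning rather than an error.

## Duplex energetics and MRE prediction

Candidate sites are anchored where the UTR matches the reverse complement
of the seed (2–8; Watson–Crick, optionally with G:U wobble) or of the
3'-compensatory span (13–19, Watson–Crick). Each anchor is expanded to an
energy window of width ≈ miRNA length + 8 nt, oriented by which miRNA
span the anchor matches (the extra 8 nt is bulge allowance, 4 per side);
this keeps windows within the duplex DP's 40 nt bound.

`duplex_energy()` is an intermolecular-only DP: no intramolecular
structure, stacking free energies summed over contiguous paired columns,
and an affine penalty `loop_open + loop_ext × (unpaired nt)` for internal
loops and bulges; dangling ends are free, so ΔG of a single isolated pair
is 0 and ΔG ≤ 0 always. The stack table is the published Watson–Crick +
G:U wobble RNA/RNA stacking set at 37 °C (Turner-style parameters,
embedded as versioned data in `nn_stack_table()`). The loop penalty is
deliberately coarse — `loop_open` = 3.5 kcal/mol, `loop_ext` = 0.5
kcal/mol per unpaired nucleotide, in line with the magnitude of published
bulge/internal-loop costs. An early draft used 2.0 kcal/mol, which is far
below those magnitudes and let register-shifted tracebacks with spurious
bulges undercut the biologically planted register; 3.5 restores the
expected behaviour. Loop length is capped at 10 nt per strand. The DP is
pinned by a brute-force enumeration over all increasing pair chains for
windows ≤ 12 nt. Ties between co-optimal tracebacks are broken by a fixed
deterministic preference (stacked continuation, then smaller loops); with
real-valued parameters exact ties essentially never arise, and
determinism, not a particular co-optimum, is the contract.

Seed classes are read off the pairing string: canonical (2–8 all
Watson–Crick), G:U seed (2–8 all paired, ≥ 1 wobble), 3'-compensatory
(≥ 1 seed mismatch and 13–19 all paired), else seedless.

Significance is an empirical, assumption-free null: the UTR is shuffled
preserving dinucleotide counts exactly (Altschul–Erickson Eulerian-walk
shuffle), the best same-miRNA site energy is recorded per shuffle, and
p = (1 + #{null ≤ observed}) / (n + 1) with n = 100 shuffles by default
(n ≥ 19 is enforced so p < 0.05 is resolvable). An extreme-value fit
could be added behind a flag but is not the default. Filters are strict,
ΔG < −20 kcal/mol and p < 0.05; a hit at exactly −20 or exactly 0.05 is
removed. Note the inherent consequence: the p-filter admits false
positives at roughly its nominal rate, so an occasional strong background
duplex (typically G:U-rich) survives both filters; precision against
planted truth is therefore high but not structurally 1.

Cross-species conservation is gene-level: an edge (miRNA m, gene gA) is
conserved when m is shared and some ortholog of gA is also predicted for
m in the second species. Site-position conservation is not required —
co-prediction of the interaction is the criterion. Degree statistics
count conserved edges only, with sample (n − 1) SD, reported 0 and
flagged when only one miRNA is present.

The seed span is 2–8 by default; an alternative 2–9 convention seen in
conservation figures is available through the `seed_span` arguments.

## Alignment and conservation of mature sequences

`center_star_msa()` aligns mature homologs with a Needleman–Wunsch core
(match +1, mismatch −1, gap −2; deterministic tie order diagonal > up >
left) around the center sequence maximising summed pairwise scores, with
"once a gap, always a gap" merging. Mature miRNAs are ~22 nt and
near-identical, where center-star is effectively exact; it is not meant
for long or divergent sequences and no guide tree is built. Per-column
conservation is the modal non-gap base count over the number of
sequences; the consensus letter is uppercase only at fraction exactly 1,
lowercase at ≥ 0.5, else ".".

## qPCR quantification

`ddct()` implements 2^−ΔΔCt with replicate-averaged ΔCt and a calibrator
condition whose RQ is 1 by construction; log₂(RQ) = −ΔΔCt exactly.
`two_sample_ttest()` defaults to Welch (the safer choice when variances
are unknown; a pooled variant sits behind `var_equal = TRUE`) and uses a
strict p < 0.05 flag. Amplification-efficiency correction is out of
scope.

## What the simulator does and does not emulate

`gen_hairpin()` builds stem–loop–stem sequences whose 3' arm is the
reverse complement of the 5' arm except at bulged positions (substituted
with non-pairing bases at `bulge_rate`), with the construction's own
dot-bracket structure and 22-nt truth matures placed slightly inside the
arms so 5'-jitter stays on the precursor. `simulate_library()` draws per
read: arm (per-precursor, per-stage 5p fraction), 5' jitter, length from
19–24 nt (default weights peaked at 22: 0.02/0.05/0.15/0.55/0.15/0.08),
substitution errors, and adapter read-through at 36 sequencing cycles.
`gen_utr_with_mres()` plants target sites in uniform-random UTRs; each
planted site is the full reverse complement of the miRNA with
class-specific seed/3' edits. Full complements are intentionally
idealised: they guarantee the planted register is the duplex MFE (partial
sites with random filler admit alternative registers that scramble the
planted seed class) and they clear the −20 kcal/mol filter, which a bare
seed match never could. All generators are pure functions of their seed.

Consequently, passing tests demonstrate parameter recovery under this
generative model — two-arm pileups, independent substitution errors, flat
qualities, idealised MREs, uniform UTR background. They do not
demonstrate robustness to features real libraries have and the simulator
omits: other small-RNA classes (piRNA, tRFs), ligation and PCR biases,
indel errors, quality-score structure, isoform-rich 5' heterogeneity
beyond ±1 nt, composition-biased UTRs, or partial, bulged MREs typical of
animal targets. Headline counts from real libraries (numbers of expressed
matures, genome-wide interaction counts) additionally depend on genome
and annotation versions and are outside what synthetic cohorts can
reproduce.

## Problem sizes and degenerate inputs

The shipped tests and `scripts/acceptance.R` use cohorts the package
treats as its reference study scale: 50 hairpins × 4 stages × 10⁴
reads/stage at error rate 0.005 for arm recovery and switching
(5 planted switches among 50 precursors, 5p fractions 0.9 vs 0.1); 200
seeded instances ≤ 12–15 nt for each enumeration oracle; and ten 1000-nt
UTRs with 20 canonical + 10 compensatory planted sites at 100 shuffles
for MRE recovery. Degenerate inputs are defined, not fatal: empty
alignment sets give zero profiles and no calls; all-zero RPM columns warn;
an all-zero stage entropy is an error (undefined distribution); pair-free
structures fall back to a flagged midpoint split; empty networks report
zero degree statistics.
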