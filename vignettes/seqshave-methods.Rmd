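---
title: "Low-similarity segment filtering: model, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-similarity segment filtering: model, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqshave)
```

## The problem

Multiple sequence alignments carry two very different kinds of noise.
*Alignment errors* put genuine residues in the wrong columns and are the
target of block filters, which drop ambiguously aligned columns for all
sequences at once.  *Primary sequence errors* — sequencing mistakes,
assembly chimeras, mis-annotated intron/exon boundaries — corrupt the
residues of a single sequence.  A block filter is poorly suited to them:
it either misses the error (the surrounding columns look fine) or throws
away correct data from every other sequence.  seqshave targets exactly
this case, removing a *low-similarity segment* from one sequence while
leaving the rest of the alignment untouched.

## The model

The alignment is summarized as a profile: per match column, emission
frequencies of the 20 amino acids.  Two strategies are offered:
`complete` (one profile from all sequences; the default, and much
cheaper) and `leave_one_out` (for each sequence, a profile from all the
others).  On an alignment where one sequence duplicates another, the two
strategies give that sequence nearly identical annotations, since
removing one of two identical rows barely moves the column counts.

Each residue is then assigned one of four match categories against the
profile, and a cumulative similarity score

\[ S_0 = 1, \qquad S_k = \mathrm{clamp}_{[0,1]}(S_{k-1} + c(\sigma_k)) \]

is accumulated along the sequence, where \(\sigma_k\) is the category of
residue \(k\) and \(c\) maps the categories to the four elemental
scores \(c_1 < 0\) (blank mismatch), \(c_2 < 0\) (conservative
substitution), \(c_3 > 0\) (low-confidence consensus match) and
\(c_4 > 0\) (high-confidence consensus match).  A low-similarity segment
is a maximal run with \(S < 1\) containing at least one \(S = 0\); it
starts after the last position at 1 and ends at the last null position,
or at the sequence end when the run never recovers to 1.  Detected
segments are masked with gaps (or a visible character via `mask_char`),
never by deleting columns.

With the default matrix \((-0.15, -0.08, 0.15, 0.45)\) the score needs
at least \(\lceil 1/0.15 \rceil = 7\) consecutive blanks to fall from 1
to 0, which bounds the smallest detectable error in fully conserved
surroundings.  Four further presets trade sensitivity against
specificity (`matrix_preset()`); custom values are accepted with sign
validation.

### Segment boundary rule

Two readings of the segment end are defensible: the last null position
of the run, or the whole sub-1 run.  The last-null rule is the more
precise statement and is the default; the full-run alternative remains
selectable (`detect_segments(rule = "full_run")`) for experimentation.
When a trace begins below 1 there is no "last position at 1", and the
segment starts at position 1.

## The two annotation engines

The **internal engine** is a deterministic reference implementation that
makes the whole package testable with no external binaries.  Its rules:

* Match columns are those with gap fraction ≤ 0.5 (configurable,
  `match_gap_threshold`); residues in other (insert) columns are `B`.
* Emissions use unweighted counts with a Laplace +1 prior:
  \(e(r) = (\mathrm{count}(r) + 1) / (n_{\mathrm{obs}} + 20)\).
* The consensus is the residue maximizing \(e\) (alphabetic tie-break,
  so results are deterministic).
* A consensus-equal residue is `U` if \(e > 0.5\), else `L`; otherwise
  `P` when \(\log(e(r)/f(r)) > 0\) against the background composition
  \(f\), else `B`.  Unknown residues (`x`/`X`, e.g. translated STOPs)
  are always `B`.

The background \(f\) is the Robinson–Robinson (1991) amino-acid
composition, the standard null model of profile-HMM software; a uniform
1/20 option exists.  Note that under Laplace smoothing a consensus
emission exceeds 1/2 only when built from ≥ 21 observations, so small
alignments annotate conserved columns `L` rather than `U` — by design,
both are positive-scoring consensus matches.

The **external engine** (`engine = "hmmer"`) builds the profile with
`hmmbuild --fragthresh 0 --plaplace` (equal sequence weights, Laplace +1
prior) and scores each ungapped sequence with `hmmsearch` under default
options, parsing the per-domain match line: uppercase → `U`, lowercase →
`L`, `+` → `P`, space → `B`.  Residues outside every envelope are `B`
(a sequence without any hit is all-`B`, with a warning); where envelopes
overlap, the non-`B` symbol from the higher-scoring envelope wins.  The
internal rule is a documented approximation of these display categories,
not a claim of bit-level agreement; on high-identity alignments the two
engines agree on the match/mismatch dichotomy at well over 90% of
residues (tested), and categories — not posterior probabilities — drive
the score in both cases.

## The error simulator

`introduce_error()` plants a ground-truthed error in the ungapped coding
sequence of one alignment row:

* **frameshift** — one nucleotide deleted at the anchor codon boundary
  and one random nucleotide re-inserted after a set number of
  out-of-frame codons (or the insertion first, direction drawn at
  random), so CDS length is conserved and exactly the windowed codons
  are translated out of frame;
* **scramble** — a uniform permutation of the window's nucleotides;
* **insertion** — a shuffled copy of a random same-length window of the
  same sequence inserted at the anchor, preserving local composition.

Anchors are drawn uniformly among codon starts that keep the window
clear of the first and last codon.  In-frame STOP codons arising from an
error are kept and translated to `x`, never truncating.  Errors are
applied to degapped CDS, so gap collisions cannot arise.
`build_erroneous_msa()` translates everything and realigns: with MAFFT
L-INS-i when requested, or with a built-in deterministic aligner that
reuses the source gap pattern (exact for the length-conserving error
types) and opens sequence-specific gap columns for insertions.  True
error spans are tracked through realignment by residue index —
realignment moves gaps, never residues — and reported in both residue
and column coordinates.

## The synthetic fixture generator

`generate_fixture_msa()` evolves a random sense-codon root CDS along a
star tree: each nucleotide substitutes with probability `divergence`
per branch, and each codon is deleted or duplicated with probability
`indel_rate/2` each, insertions opening sequence-specific columns so the
returned codon alignment is exact by construction.  The defaults — 25
sequences, 200 codons, `divergence = 0.05`, `indel_rate = 0.01` — mirror
the study conditions the evaluation machinery is designed around:
25-sequence subsets of moderately divergent single-copy gene families,
with pairwise nucleotide identity near \((1-d)^2 + d^2/3 \approx 0.90\)
(a property the tests verify against simulation).

What the generator deliberately does *not* emulate: tree structure
(a star tree matches the profile's implicit assumption but real gene
families are hierarchically related), among-site rate variation,
selection on codons, and realistic indel length distributions.  Passing
tests on these fixtures therefore demonstrate the mechanics and the
broad sensitivity/specificity regime of the method, not its performance
on deeply divergent empirical families.

For the short-error property (errors of 1–6 residues must go
undetected), fixtures are generated with `divergence = 0`: the claim is
analytic and presupposes a full score at error onset, which holds
exactly in perfectly conserved regions; in divergent surroundings a
short error *can* be caught when the score is already below 1, which is
the documented trade-off of the method, not a defect.

## Evaluation and regions

`confusion()` scores at residue level: a residue is truth-positive iff
inside a true error span of its own sequence, call-positive iff inside a
detected segment of its own sequence — a detection in the wrong sequence
is never a true positive.  Pooled (micro) and per-replicate (macro)
averages are both available, since "mean sensitivity" is ambiguous
between the two; the acceptance-style gates use micro-averages.

`classify_columns()` partitions columns into unambiguously and
ambiguously aligned regions with an entropy/gap rule at three named
stringencies — strict (0.4, 0.05), medium (0.5, 0.2), loose (0.6, 0.4).
It is a self-contained stand-in for external block-filtering software,
keeping the named settings; entropy is normalized Shannon entropy over
the column's residues, smoothed with a running mean (window 3, odd by
construction) before thresholding.  `characterize_segment()` applies the
insertion rule (segment region with ≥ 70% gaps ⇒ insertion-linked) and
the two 10% computability thresholds for mean pairwise identity.

## Parameter optimization

`enumerate_grid()` materializes the 9 × 7 × 9 × 5 = 2835 scoring
matrices from integer thousandths (never repeated floating-point
addition), `c1` outermost and `c4` innermost.  `optimize_matrix()`
exploits the fact that annotation is matrix-independent: each simulated
alignment is annotated once and every matrix is scored on the shared
annotations, which makes the grid search cheap and — as the tests check
— exactly equivalent to recomputing from scratch.  The bi-objective
(mean sensitivity, mean specificity) has no canonical scalarization, so
`sum` (default), `min` and `product` are all computed and reported; the
chosen one only orders the table.

## Numerical choices

Scores are accumulated in double precision in a small compiled kernel.
The clamp writes literal `0` and `1`, and values within `1e-9` of a
bound are snapped to it: every score path built from 3-decimal matrix
entries is mathematically a multiple of 0.001, so a value that close to
a bound *is* that bound up to accumulation error.  This keeps the
`S == 0` and `S == 1` tests of the boundary rule exact in floating
point.  The independent reference accumulator used by the tests applies
the same contract but shares no code with the kernel.

## Problem sizes used by the shipped checks

The test-suite properties run at desk scale, chosen once: 30 replicates
for the scramble-recovery gate and for the length-monotonicity sign
test (lengths 5/10/20/40), 30 fixtures for short-error invisibility,
10,000 random traces for kernel/oracle equivalence.  The full published
designs are *enumerated*, not executed: `design_totals()` reproduces the
640,000-simulation / 4,960,000-error characterization arithmetic and
`optimization_design()` the 80,000 simulated MSAs of the grid
optimization.

## Known limitations

* The internal engine approximates profile-HMM display categories with
  column statistics; it has no insert-state emissions and no envelope
  heuristic, so agreement with HMMER degrades on gappy, divergent
  alignments.
* Sequences much shorter than the alignment (fragments) are annotated
  against all match columns they span; there is no fragment-specific
  weighting beyond the equal-weights profile.
* The star-tree generator understates the correlation structure of real
  gene families (see above).
* Very short errors (< 7 aa with the default matrix) are undetectable
  in conserved regions by construction; users needing sensitivity there
  must accept more false positives via a more permissive matrix.
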