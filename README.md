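# seqshave

Segment filtering for protein multiple sequence alignments: detection and
removal of **low-similarity segments** — contiguous residue stretches in a
single sequence that fit the rest of the alignment poorly and typically
betray *primary sequence errors* (sequencing errors, assembly errors, or
wrong structural annotations such as misplaced intron/exon boundaries).
Unlike block filters (BMGE, trimAl), which drop whole alignment columns,
seqshave removes a stretch from one sequence at a time, so correct
homologous residues in the other sequences are kept.

It is aimed at phylogenomics and comparative-genomics pipelines that feed
MSAs into tree inference or selection tests, where a single erroneous
segment can inflate branch lengths or mimic positive selection.

## Method

For an alignment of `n` sequences:

1. **Profile.** A profile is built from the MSA (either from all
   sequences — *complete* strategy — or from all but the sequence under
   scrutiny — *leave-one-out*), with equal sequence weights and a
   Laplace +1 prior on emission counts.
2. **Match annotation.** Every ungapped residue of every sequence is
   compared with the profile consensus and annotated with one of four
   categories: `U` (matches the consensus, emission probability > 50%),
   `L` (matches, ≤ 50%), `+`/`P` (differs but has positive log-odds
   against the background composition: a conservative substitution) and
   blank/`B` (negative log-odds, unknown residue, insert column, or
   outside every search envelope).
3. **Cumulative similarity score.** Walking left to right, a score *S*
   starts at 1 and is updated per residue with a four-parameter scoring
   matrix (c₁ for `B`, c₂ for `P` — both negative; c₃ for `L`, c₄ for
   `U` — both positive), clamped to `0 ≤ S ≤ 1`. The default matrix is
   (c₁, c₂, c₃, c₄) = (−0.15, −0.08, 0.15, 0.45); four further published
   presets are available via `matrix_preset()`.
4. **Segments.** A low-similarity segment is a maximal run of positions
   with `S < 1` containing at least one `S = 0`; it starts after the
   last position at 1 and ends at the last null position (or the
   sequence end if the run never recovers). Detected segments are masked
   with gaps in that sequence only; alignment geometry is untouched.

A direct consequence of the default matrix is that an error shorter than
⌈1/|c₁|⌉ = 7 residues cannot pull the score from 1 to 0 and is therefore
undetectable inside perfectly conserved regions.

The package also ships the surrounding characterization machinery: a
ground-truthed simulator of frameshift, scramble and insertion errors in
codon alignments (`error_spec()`, `build_erroneous_msa()`), a synthetic
star-tree codon-MSA generator (`generate_fixture_msa()`), residue-level
sensitivity/specificity scoring (`confusion()`), UAR/AAR
alignment-region classification (`classify_columns()`), and the
2835-point scoring-matrix grid search (`enumerate_grid()`,
`optimize_matrix()`).

Two annotation engines are provided: a deterministic internal reference
engine (default, no external binaries) and an adapter that shells out to
HMMER's `hmmbuild`/`hmmsearch` for fidelity with profile-HMM practice
(`profile_spec(engine = "hmmer")`). Likewise the simulator can realign
with MAFFT L-INS-i (`aligner = "mafft"`) or with a built-in
gap-pattern-preserving aligner.

## Worked example

```r
library(seqshave)

# a 25-sequence, 200-codon synthetic alignment; scramble 30 codons of seq05
nt  <- generate_fixture_msa(n_seqs = 25, n_codons = 200, seed = 42)
sim <- build_erroneous_msa(nt, list(error_spec("scramble", "seq05", 30, seed = 7)))
sim$truth
#>   seq_id error_type length_aa anchor start_res end_res start_col end_col
#> 1  seq05   scramble        30     43        43      72        47      78

res <- clean(sim$alignment)          # internal engine, default matrix
res$segments
#>   seq_id start_res end_res start_col end_col length
#> 1  seq05        46      72        50      78     27

confusion(res$segments, sim$truth, sim$alignment)[c("sensitivity", "specificity")]
#> $sensitivity
#> [1] 0.9
#> $specificity
#> [1] 1
```

The simulator injected a 30-residue scrambled block at residues 43–72 of
`seq05`; the cleaner recovered a segment covering 27 of the 30 erroneous
residues (sensitivity 0.90 on this replicate) and removed nothing
anywhere else (specificity 1). The first few scrambled residues escape
because the score needs several mismatches to fall from 1 — the
boundary behavior described above.

A shell interface with the same functionality is installed as
`exec/seqshave` (subcommands `clean`, `simulate`, `evaluate`,
`optimize`, `fixtures`).

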