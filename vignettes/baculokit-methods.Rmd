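---
title: "baculokit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{baculokit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(baculokit)
```

baculokit re-implements, as a reusable pipeline, the analyses that a
granulovirus genome project runs after assembly: ORF calling on a circular
chromosome, promoter motif classification, discovery of imperfect palindromes
and homologous regions (hrs), gene-content classification, gene-parity
synteny, and a concatenated core-gene distance phylogeny.  This vignette
documents the models, the parameters that matter, and the design decisions
that were genuinely open.

## Coordinates and the granulin anchor

All coordinates are 1-based inclusive (GenBank convention); BED output
converts to 0-based half-open on emission.  On a circular genome an interval
with `start > end` wraps the origin, and its span is computed modulo the
genome length.  Position 1 is, by the field's convention, the A of the
granulin start codon, with "clockwise" the granulin coding strand;
`numberFromAnchor()` rotates (and, for a minus-strand anchor, reflects) any
annotation into this frame.  Genomes without a granulin annotation keep
their native origin.

## ORF calling

`enumerateOrfs()` scans all six frames for ATG-initiated open reading frames
encoding at least `minAa = 50` amino acids (methionine counted, stop
excluded).  Because the source convention "at least 150 nt (50 aa)" is off by
one codon — 50 residues plus a stop occupy 153 nt — the default demands a
50-aa protein and the flag `countStopInMin = TRUE` restores the literal
150-nt reading.  Frames continue across the circular origin: the scan runs on
the doubled sequence and calls are deduplicated modulo the genome length.
Within each stop-to-stop segment the 5'-most ATG is the canonical candidate;
shorter in-frame variants are retained separately.

"Minimal overlapping of adjacent ORFs" is not a published algorithm, so
`selectMinimalOverlap()` makes the rule explicit: greedy longest-first
retention, keeping a candidate only while its nucleotide overlap with every
retained ORF stays within `maxOverlapNt = 75` (ties broken by smaller start,
then plus strand).  Published ORF catalogues typically involve curation
beyond any overlap rule, so exact reproduction of a deposited gene set is not
promised from the rule alone — `runAnnotate(gff =)` ingests a trusted
annotation instead, because genome-level statistics (coding fraction, strand
split) are properties of the annotation, not of the heuristic.

## Promoter classification

A flat window of 150 nt immediately 5' of each start codon, on the coding
strand only, is scanned for degenerate motifs: early promoters require a
TATA-box variant (TATAW, TATAWAW, TATAWTW) with a CAKT initiator whose start
lies 20–40 nt downstream of the TATA end (both bounds inclusive; the gap is
counted between the last TATA base and the first CAKT base, and a
configuration switch re-anchors it at the TATA start); late promoters
require DTAAG anywhere in the window; GATA motifs (WGATAR/WGATAY) are
reported but never change the call.  Summaries print both counting
conventions — ORFs with an early element regardless of late, and
early-only/late-only/both — because published "early" counts are ambiguous
about dual-promoter genes.

## Palindromes, hrs, and the non-hr ori

`findPalindromes()` (C++ core) reports maximal approximate inverted repeats:
at arm length *k* up to `ceil(k * rate)` mismatches are tolerated
(`rate = 0.2`), the reported arm is the largest budget-respecting arm ending
on a matched pair, and overlapping calls collapse to the best-scoring one
(longest arm, then fewest mismatches, then smallest start).  Defaults
(`minArm = 15`, `maxLoop = 40`) mirror the structures described for
tortricid-specific granulovirus hrs — ~58–76 bp imperfect palindromes with
conserved 15-bp ends — because the source describes structures, not
thresholds; all are configuration knobs.  A maximal reading absorbs any
self-complementary core into the arms, so two structurally different
(arm, loop) decompositions of the same span are the same call; spans, not
decompositions, are the stable quantity and the one tested.

hrs are single-linkage clusters of palindromes within `maxGap = 1000` nt
(circular adjacency honored); the hr interval is the envelope of its
members, unpadded.  The hairpin score in `hairpinDeltaG()` is a documented
approximation — unified nearest-neighbor stacking terms over consecutive
matched stem pairs, a hairpin-loop initiation table with a
Jacobson–Stockmayer extrapolation beyond 30 nt, a flat +1 kcal/mol per stem
mismatch, and loops shorter than 3 scored as the minimal loop (the cruciform
apex case).  It ranks hairpins; it does not reproduce Mfold free energies,
which depend on model and version and are therefore reported for comparison
only.

A non-hr-ori candidate (`flagNonHrOri()`) needs three pieces of evidence:
at least two direct-repeat pairs within 1 kb of an hr envelope, AT content
above 0.65 over the repeat region itself (the envelope of the direct-repeat
pairs — the hr supplies context, not composition), and the hr context;
AT-rich repeat regions without an hr nearby are reported at a second tier.  Direct repeats are found by
seed-and-extend without gaps, so the two units of a reported pair have equal
length — an imperfect 79/72-bp pair is recovered as its ~72-bp common core.

## Alignment and phylogeny

Pairwise global alignment is Needleman–Wunsch with affine gaps (a gap of
length L costs `open + extend * L`), BLOSUM62 with 10/0.1 for proteins and
+1/−1 with 2/1 for DNA; the BLOSUM series is available as presets.
`progressiveMsa()` builds a UPGMA guide tree from pairwise identities and
merges profiles bottom-up with profile-profile Needleman–Wunsch, returning
rows in input order.  Percent identity defaults to the aligned-columns
denominator; because published average-identity tables rarely state their
denominator, the mode is a flag and such tables are comparison output, not
assertions.

The phylogeny stage follows the classical distance recipe: per-gene
alignments are masked by complete deletion (every column containing any gap
or missing symbol in any row is removed), concatenated into a supermatrix
with recorded gene boundaries, and converted to distances with the
gamma-corrected proportion of differing sites,
d = a[(1 − p)^(−1/a) − 1] with shape a = 2.25, which tends to the Poisson
correction −ln(1 − p) as a grows.  A maximum-likelihood Dayhoff distance
(`model = "dayhoff_ml"`) is available as an alternative, because the exact
distance computed by the original analysis software cannot be recovered from
its description; the closed form is the default since it is exactly
testable.  `upgmaTree()` is deterministic average-linkage with merge height
d/2 and lexicographic tie-breaking; UPGMA is retained deliberately, despite
its molecular-clock assumption, to mirror the method being re-implemented.
`bootstrapUpgma()` resamples supermatrix columns (site bootstrap), rebuilds
the tree per replicate, and reports the percentage of replicates containing
each full-data clade.

## The synthetic-data generator

`simulateGenome()` builds circular genomes whose truth tables are exact:

* background bases are drawn i.i.d. to an AT target (0.585 by default);
* ORF cassettes carry a 150-nt promoter window constructed to satisfy the
  classifier for the planted class (rejection-sampled), an in-frame stop just
  5' of the ATG so the planted start is canonical, and a stop-free coding
  body;
* hr cassettes embed imperfect palindromes sharing a conserved 15-bp end
  block; each planted palindrome is a perfect palindrome over its whole span
  with the requested mismatches injected into one arm, flanked by 12-nt
  all-mismatch guards so the detector's maximal reading reproduces the
  planted span exactly;
* the optional ori cassette appends two identical 31-bp direct repeats and
  an imperfect 79/72-bp pair beside the first hr.

Two guarantees make recall/precision assertable at 1.0.  First, every
cassette is rejection-sampled until, scanned in isolation (with stop codons
padded onto both ends in all frames), it contains no feature beyond the
planted ones that the detectors would keep.  Second, the assembled background
is *sterilized*: spurious ORFs or palindromes that arise by chance in random
sequence are broken by point edits outside the planted cassettes (an
in-frame stop codon near the spurious ATG, or pair-breaking substitutions in
a spurious arm), iterating detection and editing to a fixpoint.  Sterilized
backgrounds are what make the truth table a truth table; they are also the
generator's main departure from real genomes, which owe no such guarantee.
Passing recall/precision tests therefore demonstrates correctness of the
detectors against a known standard, not expected accuracy on real data,
where overlapping weak features and curation judgment dominate the error
budget.

The flagship recipe (`epapRecipe()`) fixes the study conditions: 119,082 bp
at 58.5% AT; 40 ORF cassettes with early-only/late-only/both/none promoter
classes in the proportions 5/16/3/16 (the published 133-gene catalogue
scaled down, keeping its class proportions, because independent 150-nt
windows cannot tile 133 genes at 91% coding density); 16 hr cassettes
holding 26 palindromes (the published architecture); one ori cassette.
Protein families evolve along a known tree via a Dayhoff model with
4-category discrete-gamma rates (shape 2.25), so clade-recovery tests have
an exact topological truth.

## Problem sizes and numerical choices

The test suite and the acceptance script run at sizes chosen to exercise the
algorithms fully while staying desk-scale: oracle equivalence on 20 random
genomes up to 5 kb (ORFs) and 20 random 2-kb sequences (palindromes), 1000
random windows (IUPAC), 10 random ultrametric matrices (UPGMA), 20 simulated
8-taxon panels (clade recovery), and one full 119-kb flagship genome.
Distance ties in UPGMA break lexicographically; DP traceback ties prefer the
substitution state; palindrome dedup ties prefer fewer mismatches, then the
smaller start.  Degenerate inputs have defined behavior throughout: all-N
composition is an error, p = 1 distances name the offending taxon pair,
single-sequence MSAs warn and return the input, and empty candidate sets
propagate as empty tables, not exceptions.

## Known limitations

* The overlap-selection rule is a reasonable formalization, not the
  published curation; deposited gene sets should be ingested, not re-derived.
* The hairpin energy is a ranking score, not a folding prediction.
* Direct-repeat pairs are gap-free; diverged repeats with indels are found
  only via their longest common core.
* Real hr boundaries are operationally defined; the envelope definition here
  is one defensible choice among several.
* The phylogeny stage assumes a clock (UPGMA); for real data one would also
  run a clock-free method before drawing conclusions from branch order.
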