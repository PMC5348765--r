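---
title: "Mining archaeal-type RNase H retrotransposons: models and methods"
author: "retromine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining archaeal-type RNase H retrotransposons: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Type-I ribonucleases H fall into recognisable subgroups.  The
archaeal-type enzyme (aRNH) carries an arginine at the semiconservative
active-site position of the D-E-D-R/H-D catalytic constellation, the
Fungi/Metazoa-type enzyme (fmRNH) a histidine, and the original RNase H
of Ty3/Gypsy LTR retrotransposons (gRNH) has lost conservation at that
position.  In several eukaryotic lineages, retrotransposons have
independently captured aRNH domains: Ty3/Gypsy LTR elements acquired a
second ("dual") RNase H next to their degenerate gRNH, and some L1-type
non-LTR elements carry an aRNH at the C-terminal end of ORF2, with a
CCHC zinc knuckle upstream of it.  A chromodomain (CHD) fused after the
integrase distinguishes one of the Ty3/Gypsy groups.

`retromine` turns this observation into a reusable mining pipeline.
Given genome assemblies, it:

1. finds aRNH anchor domains in six-frame translations with an in-package
   profile search;
2. expands each anchor by 10,000 nt per side and looks for co-localized
   reverse-transcriptase (RT) evidence with LTR-type and non-LTR-type RT
   profiles;
3. splits anchored loci into LTR retrotransposons, non-LTR
   retrotransposons, and RT-free "individual" RNH loci (potential
   cellular genes or element remnants);
4. assigns RT-positive loci to element groups (Chronos and Archon for
   the two Ty3/Gypsy groups, L1, Utopia) by local protein alignment
   against reference coding sequences, with the chromodomain arbitrating
   between the two Ty3/Gypsy groups;
5. annotates element structure: ORFs, LTR pairs by flank self-alignment,
   CCHC motifs, the catalytic-residue audit, and the ordered domain
   architecture;
6. mines fmRNH genes separately with 1,000 nt flanks;
7. clusters the individual aRNHs against the retrotransposon aRNH
   references on a bootstrapped neighbor-joining tree; and
8. reports per-genome count tables with RT-associated groups and
   RT-free categories in separate column blocks.

Everything is testable at desk scale because the package also contains a
synthetic-genome generator that plants divergence-controlled element
copies with exact ground truth.

## The profile search model

The paper-scale pipelines in this field run `hmmsearch`; here the domain
search is implemented in the package so that the whole analysis is
self-contained and exactly reproducible.  The model is a deliberately
small Plan7-style profile:

* match states only for alignment columns with gap fraction < 0.5;
* per-state emissions estimated with a background-proportional
  pseudocount, `(counts + pc * bg) / (n + pc)` with `pc = 1`, stored as
  log-odds in bits against the background;
* one global insert/delete open probability (0.01) and extend
  probability (0.4), i.e. affine gap costs `log2(0.01)` and `log2(0.4)`
  bits;
* uniform, zero-cost local entry and exit at any match state
  (Smith-Waterman-style locality);
* `X` and `*` emit at background (log-odds 0), so raw frame translations
  of degenerate copies - stops included - are scanned directly.

Hits are decoded with exact Viterbi dynamic programming (C++), extracted
greedily best-first, masking each reported hit and rescanning until the
best score falls below the threshold.  Because no alignment may cross a
masked residue, only the sequence suffix from the mask onward needs
recomputation.  Correctness of the decoder is pinned by a brute-force
test oracle that enumerates every legal state path on small instances.

**Background frequencies are uniform** (1/20): the synthetic templates
are uniform-random proteins, so the uniform null is exactly right for
the shipped profiles; real-proteome backgrounds can be passed to
`build_profile()`.

**The score threshold is 30 bits** per profile.  The cutoff was chosen
by decoy calibration, not fitted to any recovery result: on random
200-residue targets the best local score of a 140-state profile reaches
~22 bits, and a six-frame scan of a 500 kb genome offers roughly 10^8
alignment start points, so a threshold in the mid-20s is the minimum
that keeps the expected number of false anchors per genome well below
one.  True hits in the regimes the pipeline addresses score hundreds of
bits (a 5%-diverged copy of a 140-state domain still scores ~350), so
the margin costs no sensitivity.  The decoy false-positive property test
(100 random 200-mers, required FPR <= 1%) validates the default.

## Windows, chaining, and adjacent elements

The mining contract is window-based: RT evidence anywhere within
±10,000 nt of the anchor makes a locus RT-positive.  Two refinements
proved necessary the moment genomes carry more than one element:

* **Anchor merging.**  The same domain seen in two frames (> 50%
  reciprocal overlap) is one locus.  In addition, two anchors in
  *different* frames within 600 nt whose profile-state coverages are
  complementary are fragments of one frameshifted domain and are merged;
  two nearby anchors in the same frame, or two anchors that each cover
  the whole profile, are distinct copies and stay separate.
* **Evidence chaining and window clipping.**  A ±10 kb window routinely
  contains a neighboring element.  Each locus window is first clipped at
  the midpoint toward the nearest neighboring anchor, and only domain
  hits chained to the anchor (inter-hit gaps <= 1,200 nt) count as this
  locus's evidence.  The 1,200 nt link gap covers the largest
  within-element gap that can arise when one domain of a pol fails to
  hit; anything further away is treated as a different locus.  Truly
  interleaved or nested insertions are still resolved as a single locus;
  this is a documented limitation.

## Group assignment

tBLASTn-by-seed is replaced by local protein alignment (BLOSUM62, affine
gaps 11/1) of the translated segments under the locus's domain hits
against one reference coding protein per group.  The best group wins if
alignment identity >= 0.35 and the best/second-best score ratio
>= 1.2.  Chronos and Archon differ by the INT-CHD fusion, so when those
two are the top candidates the chromodomain hit decides directly.

## Structural annotation

* **ORFs**: maximal ATG-to-stop frames on both strands, minimum 100
  residues.  The first ATG after the previous in-frame stop defines the
  ORF; nested later starts are not reported.
* **LTR pairs**: local Smith-Waterman alignment (match 2, mismatch -3,
  gap 5/2) of up to 5 kb of sequence upstream of the element ORF region
  against up to 5 kb downstream; reported when >= 100 nt long and
  >= 80% identical.
* **CCHC knuckle**: the pattern `C-x(2)-C-x(4)-H-x(4)-C`, the canonical
  retroviral spacing; spacings are configurable because only the motif
  name, not its geometry, is fixed by prior work.
* **Catalytic audit**: the RNH profiles carry the match-state indices of
  the five catalytic positions; the audit reads the target residues
  aligned to those states from the Viterbi trace (`-` for deletions) and
  flags any deviation from D-E-D-R/H-D as degenerate.  The
  semiconservative fourth position expects R for aRNH, H for fmRNH, and
  is unconstrained for gRNH.
* **Architecture**: domains of the dominant frame ordered by protein
  coordinate; dual-RNH means gRH immediately followed by aRH; INT-CHD
  fusion means CHD within 300 residues after the integrase.

## Phylogenetics

Maximum-likelihood and Bayesian reconstruction are out of scope; the
package's claims are about clade membership of simulated sequences, for
which distance methods suffice and stay within desk-scale budgets.

* Sequences are aligned implicitly by decoding each against the aRNH (or
  RT) profile and reading off the residue per match state - the
  package's analogue of aligning everything to a common HMM.  Insertions
  are dropped; unreached states are gaps.
* Distances are Poisson-corrected, `d = -ln(1 - p)` over columns where
  neither sequence is gapped, capped at 10; fragments with no shared
  columns take the cap inside tree construction (and are an error in the
  user-facing distance function, where silent saturation would hide a
  bug).
* Trees are Saitou-Nei neighbor joining (via `ape::nj`) after sorting
  taxa lexicographically, which makes the topology invariant to input
  order; negative branch estimates are clamped to zero.
* Support is the percentage of 100 column-resampling bootstrap
  replicates containing each original unrooted bipartition, seeded and
  reproducible.
* Individual aRNHs are labelled by the group of the smallest supported
  clade (bootstrap >= 60, the conventional highlight cutoff) containing
  the individual together with references of exactly one group; an
  individual with no such clade founds a novel clade - mirroring an
  aRNH lineage with no significant clustering to any RT-associated
  aRNH.

## The synthetic world

All templates are synthetic, generated once from a fixed internal seed
with the relevant motifs planted, so the package ships no third-party
sequence and every audit has an exact expectation:

* Domain templates: uniform-random proteins of realistic lengths (PR
  100, RT 240/260, gRNH 130, aRNH/fmRNH 140, INT 250, CHD 50, EN 200,
  RLE 150 residues) with D-E-D-R-D at fixed positions in aRNH,
  D-E-D-H-D in fmRNH, non-canonical residues in gRNH, a YVDD-like motif
  in both RTs, and a 14-residue CCHC knuckle.
* Architectures: Chronos = LTR + gag + PR-RT-gRH-aRH-IN-CHD + LTR;
  Archon = the same without CHD; L1 = ORF1 + ORF2(EN-RT-CCHC-aRH) with
  aRH C-terminal and a poly-A tail; Utopia = a single ORF RT-aRH-RLE
  (the exact internal order for this group is an assumption and flagged
  as such); cellular genes are lone aRNH or fmRNH ORFs.
* Group divergences: each group's aRNH and RT variants sit 18% (amino
  acid) from the family base template (catalytic/motif residues
  protected), so one family profile detects all groups while groups stay
  resolvable by alignment and phylogeny.  The cellular aRNH lineage sits
  at 28% and an unrelated outgroup aRNH at 30%: a cellular gene exactly
  as close to every retrotransposon lineage as the lineages are to each
  other would be unresolvable by construction.
* Copy mutation: substitutions uniform per site at the stated
  divergence; indels of length 1-3 at 1% of the substitution rate (so
  0% divergence means byte-identical copies); feature coordinates are
  projected through indels; catalytic codons can be protected or
  force-mutated to build degenerate-active-site cases.
* Genomes: i.i.d. background at 50% GC (oomycete-like assemblies sit
  near 50%), elements inserted at uniform points on random strands;
  final length = background + planted lengths.  Nesting and truncation
  are off by default.

What a green test does **not** establish: performance on real genome
assemblies with repeat families, compositional heterogeneity, solo
LTRs, nested insertions, or genuinely novel domain variants - the
generator does not emulate those.  The simulator measures whether the
algorithmic chain is correct, not whether the shipped profiles are
sensitive to real oomycete elements; for real data one would build
profiles from curated seed alignments via `read_seed_alignment()`.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally and 1-based closed in
  GFF3 output.
* Viterbi ties are broken deterministically (first-found best cell in
  scan order); with real-valued bit scores exact ties essentially only
  occur in constructed cases.
* `build_profile` normalises each column by its non-gap count (not the
  row count), otherwise gapped columns would not sum to one.
* Evaluation with zero predictions reports precision 1 with an explicit
  `precision_undefined` flag.
* Partial domain hits are projected to the full profile extent
  (3 nt per missing match state, orientation-aware) before span
  calculations, the analogue of envelope coordinates.
* All randomness flows through an internal seed-scoped RNG wrapper;
  library code never perturbs the caller's RNG state, and the same seed
  reproduces every artifact byte for byte.

## Known limitations

* Nested/interleaved insertions collapse into single loci.
* No E-value calibration; significance is a per-profile bit threshold.
* No cross-copy clustering into families: each locus is one element.
* The LTR detector reports the best repeat pair only, and its boundaries
  inherit local-alignment end trimming (~tens of nt at diverged ends).
* Group assignment requires references; unknown groups surface as
  `unassigned` rather than as new clusters.
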