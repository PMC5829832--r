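---
title: "Methods: profiling CcoA distribution, neighborhoods and copA frameshifts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profiling CcoA distribution, neighborhoods and copA frameshifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccoaprofiler)
```

`ccoaprofiler` answers a comparative-genomics question about copper
trafficking: does the MFS-type Cu importer CcoA track the *cbb*₃-type
cytochrome *c* oxidase (marker *ccoN*) more closely than the *aa*₃-type
oxidase (marker *cox1*), and what do the *copA* suppressor alleles that
bypass CcoA loss look like at the sequence level? This vignette documents
the models behind each stage, the tunable parameters with their defaults,
what the synthetic-data generator does and does not emulate, and the
design choices made where more than one reasonable convention exists.

## Homolog classification

A candidate protein is called **CcoA-like** when three criteria hold
jointly:

1. **Similarity.** Its Needleman–Wunsch global alignment score against
   the seed CcoA (BLOSUM62, gap open 10, gap extend 0.5), divided by the
   seed's self-alignment score, is at least `min_similarity = 0.3`. This
   normalized score replaces a database-search E-value cutoff: it is
   dimensionless, 1 for the seed itself, and near 0 for unrelated
   sequences. The package deliberately does not reproduce any particular
   database search.
2. **Motifs in context.** An `MXXXM` match lies entirely inside predicted
   transmembrane helix 7 and an `HXXXM` match inside helix 8. These
   Met/His pairs are the putative Cu-ligand motifs of the transporter;
   requiring both (a strict AND) is the conservative reading of the
   annotation rule. By default no flank tolerance is allowed around the
   helix span; `motif_flank` relaxes this by ±n residues if a user's
   topology caller places helix edges differently.
3. **Topology.** Twelve predicted helices give `ccoA_like`; exactly
   eleven give `ccoA_like_truncated`, the C-terminally truncated form
   that lacks helix 12 and occurs clustered with the *cbb*₃-Cox genes in
   Rhizobiales-like genomes. Any other helix count is negative.

Negative verdicts enumerate every failed criterion
(`low_similarity`, `missing_MXXXM_helix7`, `missing_HXXXM_helix8`,
`unexpected_helix_count`), so a profile can be audited per protein.

### Transmembrane topology prediction

Helices are called from Kyte–Doolittle hydropathy with a sliding window
of 19 residues (odd, centered), threshold 1.6, and minimum helix length
15 — standard values for hydropathy-based TM detection. Because a window
*center* only clears the threshold when most of the window is
hydrophobic, a maximal run of qualifying centers is systematically
shorter than the physical helix; each center run is therefore expanded
by half a window on both sides (clipped to the sequence), in the style of
classical candidate-extension callers. Expanded segments separated by
fewer than `merge_gap = 4` residues merge; segments shorter than
`min_len` are dropped. The ambiguity code `X` scores 0 hydropathy and
never satisfies a literal motif position; other non-standard residues
either score 0 or raise an error (`on_nonstandard`).

This caller is intentionally dependency-free and deterministic. It is
*not* an HMM topology predictor: on real proteomes, marginal helices with
interrupted hydrophobicity can be split or missed, which is why the
classifier records the full topology and reasons rather than a bare
verdict.

## Synthetic data: what is emulated and what is not

All validation rests on generators whose outputs carry exact ground
truth.

- **Reference backbone.** A deterministic canonical CcoA-like protein
  (549 aa): twelve 21-residue hydrophobic blocks (residues cycling
  L,I,V,F) separated by 25-residue polar/charged loops, with `MXXXM`
  spliced into the center of block 7 and `HXXXM` into block 8. Block
  residues all score ≥ 2.8 hydropathy, loops ≤ −0.4, so helix calls are
  unambiguous under the default parameters for every realization. Loops
  of 25 residues keep expanded helix segments ≥ 4 residues apart, so
  merging can never fuse planted helices. Homologs
  (`generate_ccoa_like`) substitute 10% of positions within their
  residue class, never touching the literal motif residues; truncated
  forms drop block 12. Decoys are either soluble polar 200-mers (no Met,
  no His, no helix) or five-helix membrane proteins without the motifs.
- **Cohorts.** `generate_cohort` realizes an exact requested Venn
  partition over {ccoA, cbb3, aa3}: one synthetic genome per cell
  occupant, a single contig, non-overlapping genes with filler genes
  between markers so neighborhood windows are non-trivial. Genomes with
  both ccoA and cbb3 that draw the Rhizobiales taxonomy label get the
  clustered layout *ccoNOQP–ccoGHIS–ccoA* on one strand with a truncated
  CcoA, emulating the observed arrangement. ccoA copy number is 1–3
  (probabilities 0.85/0.10/0.05 — multi-copy genomes are documented but
  rare); extra copies are placed un-clustered and full-length, a choice
  the generator makes because no empirical rule for multi-copy placement
  is established. All randomness flows from one integer seed; identical
  seeds give byte-identical FASTA/GFF3/TSV/JSON outputs.
- **copA alleles.** `generate_copa` builds a 300-codon CDS with the
  CXXC motif at codon 15, a nucleotide tandem repeat starting at codon
  80, DKTGT at 150 and CPC at 220 — tract before the catalytic motifs,
  after the metal-binding domain, as in P1B-type ATPase architecture.
  Tract bases are padded to the codon boundary with bases chosen so the
  tract cannot extend, and the flanking codon is swapped if it would
  extend the tract leftward; filler codons are varied to avoid spurious
  repeats. Indels are applied at the tract start (leftmost placement).

What the generator does **not** emulate: real alphaproteobacterial
amino-acid/GC composition, phylogenetic signal usable for tree building,
operon structure beyond gene order, or the paralog structure of real
MFS families. Green tests on synthetic cohorts therefore demonstrate the
*correctness of the algorithms against known truth*, not classifier
performance on diverged natural sequences, where similarity thresholds
and topology calls are the binding constraints.

## Profiling conventions

The presence/absence matrix counts a genome ccoA-positive when any of
its proteins is `ccoA_like` *or* `ccoA_like_truncated` — truncated forms
are genuine homologs. aa3 presence is keyed on the catalytic-subunit
marker *cox1* alone (*cox2*/*cox3* columns are accepted but optional);
cbb3 on *ccoN*. Percentages are rounded half up to integer percent and
always reported beside their numerator and denominator, because summary
percentages quoted without denominators are a recurring source of
irreproducible numbers in the literature; a zero denominator yields an
undefined (`NA`) percentage, never 0.

## Neighborhood rule

"Immediately downstream" is operationalized as: both the structural
(ccoNOQP) and assembly (ccoGHIS) clusters on one contig (allowing
`max_intervening = 1` unrelated gene inside a cluster; ccoQ optional by
default since small genes are inconsistently annotated), and a ccoA gene
3′ of the combined run — relative to the cluster's majority strand —
with at most `window = 2` intervening genes. Offsets count genes, not
nucleotides, which makes the rule invariant to contig flips
(coordinates and strands reversed) and to input row order; both
invariances are property-tested. Mixed-strand clusters are reported with
a warning flag rather than discarded.

## Similarity network

Edges connect protein pairs whose normalized alignment score
S(a,b)/√(S(a,a)·S(b,b)) reaches the threshold (default 0.5); clusters
are connected components, numbered by decreasing size with ties broken
by the lexicographically smallest member. The threshold is this scoring's
*analog* of a database alignment-score cutoff, not the same scale; what
the package tests is the network mechanism — exact pair counts, symmetry,
component labeling against a union-find oracle, and monotonicity of the
component count in the threshold — not absolute score values.

## Repeats, indels and frameshift consequences

`scan_ntr` reports all maximal tandem repeats with primitive units of
1–3 bp (defaults: ≥5 copies mononucleotide, ≥4 dinucleotide, ≥3
trinucleotide — monomeric G/C runs being the most slippage-prone, the
mono threshold is the strictest in copies but loosest in length).
Canonical reporting means smallest unit and leftmost phase: `CGCGCG` is
CG×3, never GC or CGCG. Non-ACGT characters break tracts (with a
warning) or raise an error.

Indel placement inside a repeat is inherently ambiguous, so
`locate_indel` fixes the VCF-style *leftmost* convention and validates
that alleles differ by exactly one contiguous block; applying the call
to the reference reconstructs the mutant byte-for-byte (round-trip
property). Under a frameshift (indel length ≢ 0 mod 3), a motif counts
as retained iff its full wild-type span ends strictly before the first
frameshifted codon — residues encoded after the shift are treated as
non-homologous even when coincidentally similar. For in-frame indels the
mutant translation is rescanned for the motif patterns instead.
Translation uses the standard genetic code; the input is assumed to be a
CDS starting at ATG, and `CPC` is matched literally (`CPX` is available
as an optional pattern for the generalized membrane metal-binding site).

## Problem sizes and determinism

The shipped test suite validates each operation against independent
brute-force oracles at these scales, chosen to exercise every code path
with comfortable statistical coverage while keeping a full run on a
single CPU to a few minutes: a 327-genome cohort for profiling, 200
generated homologs plus 200 decoys for the classifier round-trip, 1,000
random proteins for the motif scanner, 1,000 random ~2-kb sequences for
the repeat scanner, 100 random matrices for the Venn tally, 50 flipped
genomes for the neighborhood invariance, and a 100-protein two-family
network over an 11-point threshold grid. Full-pipeline determinism is
asserted by comparing output checksums of two runs with the same seed.

## Known limitations

- The hydropathy caller is a single-scale window method; it is adequate
  for the synthetic backbone and for well-behaved MFS topologies but is
  not a replacement for HMM-based predictors on real proteomes.
- The similarity threshold (0.3 of seed self-score) was chosen for clear
  separation between backbone-derived homologs and unrelated sequences;
  strongly diverged natural homologs near the twilight zone would
  require lowering it and relying more heavily on the motif/topology
  criteria.
- Cluster numbering in the similarity network depends on the input set;
  only the clustering mechanism, not any particular published cluster
  catalogue, is reproduced.
- The cohort generator draws taxonomy labels independently of marker
  content (except for the Rhizobiales clustered layout), so it does not
  model lineage-specific marker correlations.
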