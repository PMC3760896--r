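---
title: "Conservation-core analysis of nitrogenase Component 1: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conservation-core analysis of nitrogenase Component 1: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nifcore)
```

## The problem

Nitrogenase Component 1 (the MoFe-protein and its V- and Fe-only
homologues) is an alpha2-beta2 tetramer whose alpha- (NifD/AnfD/VnfD) and
beta-subunits (NifK/AnfK/VnfK) are encoded by three genotypes, *nif*,
*anf* and *vnf*. Across a diverse species panel the subunit sequences are
clearly homologous but highly variable; natural selection has retained
only a small core of invariant or nearly invariant residues, concentrated
around the P-cluster, the cofactor and the subunit interfaces. This
package implements the column-level machinery needed to identify that
core on a multiple sequence alignment, to partition families into groups
by their insertion/deletion patterns and group-exclusive residues, and to
project the conservation classes onto atomic coordinates.

The pipeline consumes an existing alignment (aligned FASTA or Clustal; it
does not run an aligner) with a sidecar metadata table assigning each
sequence a species, a gene family (`nif`/`anf`/`vnf`), a subunit (`D` or
`K`) and a group label over `I, II, III, IV, Anf, Vnf`.

## Reference numbering and the co-aligned core

All positions are reported in the numbering of a reference sequence
(`build_reference_map()`), chosen to match the residue numbering of the
crystal structures. Columns where the reference is gapped are *insertion
columns*: they carry no number, only the preceding reference number as an
anchor, until the register is re-established. This reproduces the
spreadsheet bookkeeping convention in which deletions are blank cells in
the other sequences and insertions are blank cells in the reference.

All column statistics are computed over the *co-aligned core*
(`coaligned_columns()`): the columns in which **no** sequence has a gap.
Terminal extensions are treated identically to internal indels — a
sequence that starts later than the reference simply removes its leading
columns from the core. We expose the raw maximal gap-free blocks; any
minimum-block-length smoothing is left to the caller, because no
principled block-size threshold exists and the downstream statistics do
not depend on the blocking, only on the column set.

## Conservation classes

Each core column is classified (`classify_column()`) from its residue
counts, in rule order:

| distinct residues | class |
|---|---|
| 1 | invariant |
| 2, minority count = 1 | single variant, outlier |
| 2, residues functionally similar | single variant, similar |
| 2, otherwise | single variant, dissimilar |
| 3 | double variant |
| >= 4, one residue in > 90% of sequences | dominant |
| otherwise | variable |

Design notes:

* **The similarity scheme is an input.** "Functionally similar" is not a
  uniquely determined notion; the default scheme (beta-branched {I,V},
  aliphatic {L,I,V,A,M}, aromatic {F,Y,W}, basic {K,R,H}, acidic {D,E},
  amide {N,Q}, small {G,A,S}, thiol/selenol {C,U}, {P}, {T}) is
  consistent with the canonical pairings seen in these families (R/K and
  I/V substitute freely; I/V never pairs with L at the same stringent
  sites) but is deliberately configurable
  (`read_similarity_scheme()`), and the scheme in force is recorded in
  every output header.
* **The outlier subtype takes precedence** over similar/dissimilar when
  the minority residue occurs exactly once. A 94-of-95 column is reported
  as an outlier column even when the pair is chemically similar; the
  subtype is purely count-based.
* **The dominant threshold is a strict fraction** (> 0.90) rather than a
  fixed count, so it scales to any family size. A consequence worth
  knowing: for families of about 30 sequences or fewer no column can be
  "dominant" (four distinct residues force at least three minority
  sequences, which already exceeds 10%).
* **Suspected sequencing-error outliers are not removed.** Columns are
  classified exactly as given in the translated gene database; flagging
  is the reader's job, not the classifier's.
* **Selenocysteine** is carried as `U` in the protein alphabet, and `X`
  is rejected outright rather than silently kept: a single ambiguous
  residue would silently corrupt invariance counts. The equivalence map
  (`sec_equivalence()`) merges `U` into `C` before counting — optionally
  only at designated reference positions — so a Cys/Sec column is
  invariant, matching the treatment of the P-cluster ligand position 62.

`summarize_conservation()` reports the class counts with percentages on
the co-aligned total; `aa_class_composition()` tabulates which amino
acids carry each class; `covariation()` reports the joint residue table
and both conditional distributions for a chosen pair of positions (the
Lys96/Tyr98 pattern). No significance test is attached to covariation:
with 95 strongly structured sequences a formal independence test would be
confounded by phylogeny, so the package reports the full table and leaves
inference to the reader.

## Groups, co-invariance, strong motifs

Groups are **input labels**, not the output of a clustering algorithm:
the six-group structure is defined by genetic origin plus indel
patterns, and the package takes it as given (from metadata or from
`assign_group()`). `indel_fingerprint()` reduces a sequence to its
(anchor, kind, length) chain-difference triples relative to the
reference — e.g. the 52-residue insertion after position 391 that marks
Group II.

`coinvariance_matrix()` counts, for each group pair, the core columns
invariant in both groups *with the same residue*; the diagonal counts
columns invariant within one group and deliberately **includes** the
universally invariant columns (the published diagonals are clearly
unrestricted — a three-member group's diagonal far exceeds the universal
count — so "beyond the universal residues" is narrative, not a filter).
Empty groups yield `NA` rows, not zeros: a count of zero is a statement
about sequences, `NA` a statement about the absence of sequences.

`strong_motifs()` returns the (column, residue) pairs invariant within a
group subset and absent from that column in every other sequence. With
the subset equal to all groups the exclusivity condition is vacuous and
the result is exactly the universal invariant set — a useful cross-module
consistency check that the test suite enforces. Motifs are computed over
co-aligned columns only (group-private columns inside indel regions are
not scanned); the output headers state this choice.

`assign_group()` scores a query against each group's motif list by a
simple vote — the number of motif sites where the query carries the motif
residue — because the published assignment practice is an ensemble
judgement with no formal score; the simplest auditable rule is used and
reported in full. Exact ties are broken by indel-fingerprint agreement
when that identifies a unique candidate, and are otherwise reported as
ties rather than silently resolved. A query gapped at every motif site is
flagged unassignable.

## Structure shells

`read_structure()` wraps the bio3d PDB parser, resolving alternate
locations to the highest-occupancy copy. `contact_shell()` includes a
residue iff the minimum inter-atomic distance to the target selection is
**less than or equal to** the cutoff (default 5.0 Å): "within 5 Å" is
read inclusively, and the boundary case is fixed so results are
reproducible to the digit. Distances are computed over non-hydrogen
atoms; hydrogen inclusion is a flag (`include_hydrogens`) since atomic-
resolution structures carry riding hydrogens that conventional contact
tables omit. Waters never appear in the direct shell; the target's own
residues are excluded while covalent protein ligands (the cluster
cysteines) are ordinary shell members.

`water_mediated_contacts()` implements a distance-only hydrogen-bond
rule: a residue contacts the target through water iff a polar (N/O)
residue atom is within 3.5 Å of a water oxygen that is itself within
3.5 Å of a target atom, and the residue is not already in the direct
shell. 3.5 Å is the conventional upper bound for an O/N–O hydrogen bond;
no angular term is applied because none is stated for the reference
tables we mirror, and a distance-only rule is reproducible from
coordinates alone.

Targets are named atom selections (`target_selection()`), by hetero
residue name or by explicit atom list — the beta–beta interface
mononuclear site (Asp353/Asp357 carboxylates, the 108 backbone carbonyl,
Glu109) is handled as a custom selection, not a special case. One
alpha-beta pair of the tetramer suffices (the two-fold symmetric copy is
redundant); a chain filter selects it. `annotate_shell()` joins shell
residues to conservation classes through the reference numbering
(assumed to match the structure's numbering, with a per-chain offset
option) and collapses to invariant / single-variant / multi-variant;
residues outside the co-aligned core are flagged `no_coverage`, never
dropped.

## Selenocysteine codon scan

`detect_amber_readthrough()` implements the sequence-level Sec
criterion only: the codon mapped to the scanned reference position is the
amber stop TAG, the protein carries U there, and translation continues
in frame to the annotated terminus. Genome-scale corroboration (selA/
selB/selD genes, the bSECIS stem-loop) is out of scope, and every report
carries a field saying those checks were not performed. Translation uses
the standard genetic code with TAG read-through permitted only at the
scanned position; a one-nucleotide frame shift breaks the cds/protein
consistency check, which the tests use as a negative control.
`codon_usage_at_position()` tallies the codons behind one reference
column across species — the degenerate-codon argument that invariant
residues are conserved by selection, not by codon inertia.

## The synthetic generator

`generate_family()` produces alignments with fully known ground truth so
that every pipeline stage is testable without downloads. Its defaults
*are* the study conditions: 95 sequences in six groups of 45/18/8/3/12/9,
a 422-column co-aligned core carrying 41 invariant and 39 single-variant
columns, double-variant/dominant/hypervariable columns for the rest,
strong-motif columns whose per-subset counts mirror the published
group-by-group motif table (diagonal 9/7/2/32/23/15 plus the off-diagonal
subsets), the 52-residue Group II insertion anchored after reference 391
and smaller group-characteristic indels, an invariant Arg at position 60,
an invariant Cys at position 62 carried as Sec (U) by three Group III
sequences, and the G/H/L *nif*/*anf*/*vnf* discriminator at position 69.

Construction guarantees, enforced by redraw during generation:

* planted class labels are exact — noise (`noise_rate`) only ever touches
  columns whose true class is *variable*, so recovery tests stay sharp;
* no non-planted column accidentally forms a strong motif: no residue's
  carrier set may coincide with a proper union of complete groups;
* the same seed reproduces the family byte-for-byte.

Background residues are drawn uniformly (hypervariable columns use 7–12
residue pools); a codon-frequency table can replace the uniform
synonymous-codon draw in `generate_cds_for()`. What the generator does
**not** emulate: phylogenetic correlation between sequences (no
tree-based substitution model), compositional bias, alignment error, or
the real data's correlation between indels and structural loops. Passing
recovery tests therefore demonstrates the correctness of the counting
machinery on data with the right marginal structure — not robustness to
aligner artefacts or phylogenetic non-independence, which the real
analysis inherits from its inputs.

`generate_toy_structure()` places pseudo-residues at known radial
distances around a compact cluster, with optional bridging waters, and
emits the expected shell computed by an independent brute-force all-pairs
scan alongside the coordinates.

## Validation strategy and problem sizes

The test suite validates every operation three ways: exact recovery of
planted truth on the full-size default family (95 x 422, under ten
seconds); equality with independent brute-force oracles on 100 random
20-sequence x 50-column alignments and 15 random 200-atom toy
structures; and property suites — shell monotonicity in the cutoff,
rigid-motion invariance, the closed 5.0 Å boundary, motif exclusivity
re-verified against the raw matrix, reference-map round-trip identity,
co-invariance symmetry and its min-diagonal bound, and monotone shrinkage
of motif sets as sequences are added. Group assignment is exercised with
200 replicate queries at 5% substitution noise. These sizes keep the
whole suite under half a minute while leaving each property attested on
at least a hundred independent instances.

## Known limitations

* Groups are taken as given; the package will not discover a seventh
  group, only report when a query matches none.
* Motif counts depend on the co-aligned-columns-only convention; a
  group-local column inside an indel region can be diagnostic in practice
  but is not scanned.
* The structure overlay assumes the coordinate residue numbering matches
  the reference numbering up to a constant per-chain offset; structures
  with renumbered loops need an explicit mapping.
* The amber scan is a necessary, not sufficient, Sec criterion; without
  the genomic machinery checks a TAG read-through call remains
  provisional.
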