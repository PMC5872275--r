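---
title: "In-silico PCR-RFLP typing of honey bee subspecies: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In-silico PCR-RFLP typing of honey bee subspecies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beeRFLP)
```

## The problem

Four *Apis mellifera* subspecies bred in Russia — the Central Russian bee
(*A. m. mellifera*), the Carpathian (*A. m. carpatica*), the Carniolan
(*A. m. carnica*) and the Grey Mountain Caucasian (*A. m. caucasica*) —
are conventionally told apart by morphometry, which needs trained
specialists. Their COX1 barcodes differ at a handful of stable positions
in the 658-bp Folmer region: an A/G polymorphism at position 99 separates
carnica and carpatica from the other two; a G/A change at 448 marks
carnica within that pair; and position 421 splits *A. m. mellifera* into
two haplogroups (C→T for haplogroup 1, which also carries several private
C↔T transitions plus one A→G and one T→A change; C→A for haplogroup 2).
The caucasica-type sequence carries the reference base at every key
position and is identified by exclusion.

None of these SNPs happens to create or destroy a natural restriction
site, so a plain CAPS assay is impossible. The typing panel instead uses
*mutagenic* (dCAPS) primers: oligos carrying one or two deliberate
mismatches near the 3' end. Because the polymerase extends the primer
itself, the primer sequence **replaces the template** at the product ends;
together with the diagnostic allele just beyond the primer, the
substitutions complete a restriction site that exists only in products of
the targeted haplotype. One short digestion per assay then reads the
genotype as a band pattern on a 3% agarose gel — no sequencing required.

This package is the in-silico counterpart of that workflow: virtual PCR
with primer overwrite, digestion over IUPAC-degenerate sites, a decision
matrix that converts cut/uncut patterns into subspecies calls, a
generalised assay-design search, and the K2P/neighbor-joining machinery
used to describe barcode variability.

## The amplification model

`find_primer_sites()` scans both strands of a concrete template and counts,
for every offset, the primer positions whose IUPAC code does not contain
the template base. A footprint with at most `max_mismatch` such positions
anneals. Three modelling decisions matter:

* **No 3'-clamp rule.** Classical primer design demands a matched 3'
  terminus; mutagenic primers violate it by construction and demonstrably
  still prime. Terminal mismatches therefore count like any other and
  the default budget is `max_mismatch = 3` over the whole oligo.
* **Primer overwrite.** `amplify()` builds the product as
  *resolved forward primer* + *template interior verbatim* + *reverse
  complement of the resolved reverse primer*. A degenerate primer position
  resolves to the template base when compatible (the polymerase copies the
  template); an incompatible position resolves to the lexicographically
  smallest base of its expansion, which for a concrete mismatch is the
  primer base itself — the overwrite that makes dCAPS work.
* **All pairings are reported.** Every forward-orientation hit is paired
  with every downstream reverse-orientation hit inside the size window;
  ambiguity is surfaced, never hidden. The general default window is
  100–1000 bp; the packaged diagnostic assays use 120–160 bp, the range in
  which short products still separate cleanly on 3% agarose.

`nested_amplify()` models the two-step rescue used for degraded DNA: a
long, highly specific outer pair first, then the assay pair on the outer
product. The outer round may run with its own, more permissive mismatch
budget (`outer_max_mismatch`), since rescue is exactly the situation in
which the inner primers fail on the raw template. Note that the published
primer tables reuse the names AmCarp-f/AmCar-r for both a long barcoding
pair and the short diagnostic pair; the packaged table keeps the
diagnostic sequences under the canonical names and ships the long pair as
`AmCarp-f_outer`/`AmCar-r_outer`.

## Digestion

Recognition sites are IUPAC strings (HinfI = GANTC) scanned on both
strands with zero mismatches; for the five packaged enzymes (AluI AG^CT,
HinfI G^ANTC, HspAI G^CGC, MspI C^CGG, DraI TTT^AAA) the sites are
self-complementary, so the two scans coincide. Only top-strand cut
positions define fragments — a gel reads double-stranded length, so
overhang geometry is irrelevant — and digestion is complete (a 2-h excess
digest; no partial-digest kinetics). Fragment lengths always sum to the
input length. `resolve_enzyme()` follows commercial isoschizomers
(HpaII→MspI, AluBI→AluI, ...); GlaI resolves but warns, because its
dependence on substrate methylation is not modelled.
`gel_resolvable()` applies two configurable thresholds, 20 bp minimum
visible fragment and 15 bp minimum separable difference; these are
deliberately below the smallest published diagnostic fragment (28 bp) and
split (107 vs 32), and are package defaults, not measured gel physics.

## The decision matrix and its honest edge cases

Each assay contributes one cut/uncut bit; the packaged matrix maps the
sixteen possible patterns onto five haplotype rows. Two cells need care:

* *carpatica vs carnica*: a minority of carnica specimens lack the
  position-448 SNP and produce the carpatica pattern (HspAI cut, MspI
  uncut). That pattern is therefore always called carpatica **with an
  ambiguity flag** (`carnica_carpatica_ambiguous`), never silently.
* *caucasica*: its row is all-uncut, so the call is by exclusion
  (`caucasica_by_exclusion`) and requires all four assays.

Patterns matching no row are reported `inconsistent`; the classifier
never coerces to the nearest row. The sequence-level key
(`assign_haplogroup()`) applies the same logic to a Folmer sequence
directly and returns `"unknown"` when a key position carries `N` or an
allele outside the key, rather than forcing a call.

## The synthetic haplotypes

`generate_fixtures()` builds the five haplotypes on a shared seeded
background (default GC 0.30 — the bee mitochondrial region is AT-rich)
and places each assay so that its uncut product length and its fragment
split equal the published values exactly: AluI 107+32 of 139, HinfI
122+28 of 150, HspAI 111+30 of 141, MspI 118+30 of 148.

Working out where the recognition sites can sit is instructive. The AluI
site completed by the haplogroup-1 T allele at 421 would need positions
418–420 to read AGC, while the HinfI site completed by the haplogroup-2 A
allele at the same position needs 420 to be G — the two sites cannot both
contain position 421 in the template. The published assays escape this
through primer-contributed bases, but with the printed primer sequences a
junction-spanning site yields splits one base off the printed ones
(108/31 instead of 107/32 for AluI, 29/121 instead of 122/28 for HinfI)
under every cut-offset convention. The generator therefore places each
site fully inside the template interior: HspAI keyed on position 99,
MspI on 448, HinfI on 421, and AluI on one of haplogroup 1's private C→T
transitions at a fixture-defined position (Folmer 533). This reproduces
every published cell exactly while keeping the diagnostic-allele logic —
each site is completed by the target allele and absent, anywhere in the
product, for every other haplotype.

The layout places the AmCarp amplicon at Folmer 70–210, AmEu2 at
299–448, AmCar at 329–476 and AmEu1 at 500–638. The AmEu2/AmCar overlap
forces three single-base compromises (one primer anneals with 1–2
tolerated mismatches at its outermost bases), which the mismatch budget
absorbs — a useful side effect, since it exercises the annealing model.
Haplogroup 1's additional divergence (eight C↔T transitions in total,
one A→G, one T→A) is drawn outside all four amplicons so intra-subspecies
variation can never perturb an assay product. Residual random-background
sites are removed by a deterministic scrub, and a fixture set is accepted
only after all twenty assay-by-haplotype cells re-simulate to the
published table — the generator is itself a test of the amplification and
digestion engines.

What the fixtures are **not**: they share only the combinatorial
structure of the real barcodes (coordinates, alleles, footprints,
products, splits), not their sequence. Passing tests demonstrate that the
machinery reproduces the method's logic, not that the real GenBank
haplotypes behave identically; translation realism (absence of internal
stop codons) is likewise not enforced.

## Assay design as a search

`design_assay()` generalises how the diagnostic primers were built. For
each enzyme, strand and placement of the recognition site over the SNP it
derives the mutagenic primer whose 3'-adjacent template allele completes
the site, subject to: at most `max_subs = 2` substitutions; substitutions
confined to the 3'-terminal half; the SNP itself always supplied by the
template (otherwise the assay is not allele-specific). Generated
mutagenic primers default to 30 nt — the cleaved-off fragment is about as
long as the mutagenic primer, which sizes it for a 3% gel — and the
opposite primer to 19 nt. Every candidate is validated by full
re-simulation on every haplotype, and the non-target check scans the
whole product on both strands, because primers alone are not
haplotype-specific — the restriction step carries all the specificity.
Ranking is deterministic: substitution count, then product length, then
enzyme name.

## Distances and trees

`k2p_distance()` counts transition and transversion proportions P and Q
over usable sites and evaluates d = −½·ln(1 − 2P − Q) − ¼·ln(1 − 2Q).
Pairwise deletion of gap/ambiguity sites is the default (complete
deletion is available at the matrix level); saturated pairs
(1 − 2P − Q ≤ 0 or 1 − 2Q ≤ 0) raise a typed error rather than returning
an arbitrary large distance, are reported as `NA` in matrices, and abort
tree building with a clear message. `mean_group_distance()` is the
package's variability statistic: the mean pairwise K2P distance within a
group (`NA` for singletons). The published variability figures do not
state whether they are K2P or p-distances; this package computes K2P
means and documents that choice. Neighbor joining is delegated to
`ape::nj()`, with negative branch estimates clamped to zero and flagged;
`bootstrap_support()` resamples alignment columns with replacement under
a caller-supplied seed, rebuilds the K2P/NJ tree per replicate, skips
and counts saturated replicates, and reports integer percentage supports
per internal bipartition. Trees round-trip through Newick via ape.

## Numerical and interface conventions

* Coordinates are 1-based and inclusive on the top strand; the Folmer
  frame is positions 1–658 of the trimmed barcode.
* Lowercase input is normalised; `U` is rejected (DNA only); `-` is
  tolerated in records and flagged by the translation QC.
* Translation QC uses the invertebrate mitochondrial code (NCBI table 5)
  by default; when no frame is given, the frame with fewest internal
  stops is chosen and flagged as heuristic, since the barcode's frame
  offset is not fixed by the method.
* All tie-breaks (degenerate-base resolution, design ranking) are
  lexicographic and documented, so identical inputs give identical
  outputs; all randomness flows through explicit seeds.

## Problem sizes used by the test suite

The suite validates the scanners against brute-force oracles on ~600
random instances (templates up to 300 bp), checks design soundness and
completeness against an exhaustive enumerator on fifteen 300-bp allele
pairs, recovers twenty random 5–8-taxon additive trees exactly, and
re-simulates all twenty assay-by-haplotype cells on several fixture
seeds. These sizes were chosen so the whole suite runs in about a minute
on a laptop while still exercising every code path; the fixture
construction itself is size-invariant, so nothing about the method
changes at larger scales.

## Known limitations

* No thermodynamics: melting temperature, secondary structure and primer
  dimers are out of scope, as the method never relies on them.
* Linear templates only; no circular digestion, star activity,
  methylation sensitivity or partial digests.
* The fixture generator reproduces the published fragment arithmetic, not
  the real COX1 sequences; analyses of real barcodes should load them as
  FASTA and use the same functions.
* Neighbor joining on COX1 barcodes separates these subspecies only
  weakly (low supports are expected); the tree tools are provided for
  describing variability, not as the identification method.
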