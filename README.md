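# beeRFLP

In-silico PCR-RFLP typing of honey bee (*Apis mellifera*) subspecies from
diagnostic SNPs in the COX1 Folmer region.

Four subspecies bred in Russia — *A. m. mellifera* (two mitochondrial
haplogroups), *A. m. carpatica*, *A. m. carnica* and *A. m. caucasica* —
differ at three stable positions of the 658-bp COX1 barcode: A/G at
position 99 (carnica + carpatica), C→T / C→A at 421 (mellifera
haplogroups 1 and 2) and G/A at 448 (carnica). None of these SNPs
creates a natural restriction site, so the typing method uses
**mutagenic (dCAPS) primers**: oligos with deliberate 3'-end mismatches
that, because the primer sequence overwrites the template in the PCR
product, complete a restriction site only when the diagnostic allele is
present. One digest per assay (AluI, HinfI, HspAI, MspI) then reads the
genotype as a band pattern on a 3% agarose gel:

| assay (primers + enzyme) | mell. H1 | mell. H2 | carpatica | carnica | caucasica |
|---|---|---|---|---|---|
| AmEu1-f/AmEu1-r + AluI  | 107, 32 | 139 | 139 | 139 | 139 |
| AmEu2-f/AmEu2-r + HinfI | 150 | 122, 28 | 150 | 150 | 150 |
| AmCarp-f/AmCarp-r + HspAI | 141 | 141 | 111, 30 | 111, 30 | 141 |
| AmCar-f/AmCar-r + MspI  | 148 | 148 | 148 | 118, 30 | 148 |

The package simulates this entire workflow for sequence analysts and
assay designers: degenerate-primer annealing with mismatch tolerance,
virtual amplification with primer overwrite, restriction digestion over
IUPAC sites with isoschizomer resolution, the cut/uncut decision matrix
(including the carnica/carpatica ambiguity and the caucasica
by-exclusion call), a generalised mutagenic-assay design search, Kimura
2-parameter distances with neighbor-joining trees and bootstrap, and a
seeded generator of 658-bp haplotype fixtures that reproduces the whole
fragment table above without any download.

## Worked example

Generate the fixture haplotypes, run the carpatica assay, and classify
every sample from its gel pattern:

```r
library(beeRFLP)

fx <- generate_fixtures(seed = 1)
validate_assay(fx$assays$AmCarp, fx$haplotypes)
#>     haplotype n_products product_len fragments   cut
#>  mellifera_H1          1         141       141 FALSE
#>  mellifera_H2          1         141       141 FALSE
#>     carpatica          1         141    111,30  TRUE
#>       carnica          1         141    111,30  TRUE
#>     caucasica          1         141       141 FALSE

classify_samples(fixture_patterns(fx))
#>        sample         call             confidence_note partial
#>  mellifera_H1 mellifera_H1                      unique   FALSE
#>  mellifera_H2 mellifera_H2                      unique   FALSE
#>     carpatica    carpatica carnica_carpatica_ambiguous   FALSE
#>       carnica      carnica                      unique   FALSE
#>     caucasica    caucasica      caucasica_by_exclusion   FALSE
```

The HspAI digest cuts the 141-bp carpatica and carnica products into
111 + 30 bp and leaves the other subspecies uncut; the classifier calls
every haplotype correctly and flags the two honest edge cases — the
carpatica pattern cannot exclude a carnica specimen lacking the
position-448 SNP, and caucasica is identified only by exclusion.

The same steps are available from a shell through the thin CLI:

```sh
exec/beerflp simulate --seed 1 --out run1
exec/beerflp classify --patterns run1/observed_patterns.tsv --out run1
exec/beerflp tree --in run1/haplotypes.fasta --reps 100 --seed 1 --out run1
```

See the vignette (`vignettes/bee-subspecies-typing.Rmd`) for the models,
parameter defaults and the reasoning behind the fixture geometry.

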