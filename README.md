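# intronforge

Build tabular databases of **group I introns** — self-splicing catalytic
RNAs — with reliable exon–intron boundaries, subtype classification,
structural-element annotation, and putative **homing endonuclease genes
(HEGs)**, starting from covariance-model search hits and GenBank
annotations.

Group I introns excise themselves from precursor transcripts through two
transesterifications; the last nucleotide of the 5′ exon is a strictly
conserved U that forms the catalytic U–G pair. Covariance-model searches
(Infernal `cmsearch`) find group I introns genome-wide but the raw hit
coordinates are not splice boundaries. `intronforge` refines them against
the annotation already present in the GenBank feature table, validates
the result against the conserved U, and layers subtype, structure and
HEG annotations on top. It is aimed at researchers compiling intron
catalogues for evolutionary analysis or ribozyme engineering.

## The method

For every hit the pipeline walks the target record's features and
collects candidate boundaries:

1. an `intron` feature whose span overlaps the hit range by **≥ 50
   positions**, or
2. for any compound-location feature (`join(...)` — e.g. the exons of a
   spliced gene), a gap between consecutive parts overlapping the hit by
   ≥ 50 positions (unannotated introns between annotated exons).

The candidate with the **largest overlap** wins. It is accepted only if
it does not touch either end of the entry (the flanking exonic context
must be known) and its first base is U (T in DNA) — the catalytic-pair
nucleotide. Accepted introns get up to **150 nt** of exonic context per
side, a subtype (argmax of per-subtype covariance-model bit scores from
`cmscan`), and structural elements (P1–P9, P5a–d, …) mapped from the
subtype alignment columns onto intron coordinates.

HEG detection translates each intron in all **six reading frames under
every NCBI genetic-code table**, keeps ORFs of **≥ 120 amino acids**
(valid start codon to first in-frame stop; nested ORFs pruned to the
largest), and calls an ORF a putative HEG when its InterProScan — or,
as a fallback, DELTA-BLAST — annotations contain one of the stems
`endonuc`, `homing`, `nuclease`. Each HEG records whether its genetic
code is the `expected` one for the intron's compartment, that of an
`other_location` in the same organism, or `foreign` — the signature of
lateral transfer or relic ORFs. External tools are never executed:
their tabular outputs are parsed (`external_command_templates()` shows
the invocations the readers expect).

A seeded fixture generator (`fixture_spec()` / `generate_fixtures()`)
emits synthetic GenBank records with planted introns and ORFs plus
matching mock tool outputs, so the whole pipeline runs and is tested
fully offline.

## Worked example

```r
library(intronforge)

spec <- fixture_spec(seed = 7, n_records = 8, plant_heg = TRUE,
                     boundary_pathway = "both")
fx <- generate_fixtures(spec, "fixtures")

cfg <- pipeline_config(
  genbank = fx$files$genbank, tblout = fx$files$tblout,
  out_dir = "db", taxonomy = fx$files$taxonomy,
  cmscan = fx$files$cmscan, interproscan = fx$files$interproscan,
  quiet = TRUE
)
db <- build_db(cfg)
db
#> <intron_db> 8 introns (8 with HEGs), 8 HEGs, 0 rejected hits

dplyr::select(tidy(db), intron_id, start_1based, end_1based,
              boundary_source, subtype, n_hegs)
#> # A tibble: 8 × 6
#>   intron_id     start_1based end_1based boundary_source subtype n_hegs
#>   <chr>                <int>      <int> <chr>           <chr>    <int>
#> 1 SYN000001.1_1          242       1216 intron_feature  IC3          1
#> 2 SYN000002.1_1          231        870 compound_gap    IA1          1
#> 3 SYN000003.1_1          279       1214 intron_feature  IC3          1
#> 4 SYN000004.1_1          328       1212 compound_gap    IC3          1
#> 5 SYN000005.1_1          337       1133 intron_feature  IC1          1
#> 6 SYN000006.1_1          393       1281 compound_gap    IC3          1
#> 7 SYN000007.1_1          224        908 intron_feature  IC1          1
#> 8 SYN000008.1_1          344       1112 compound_gap    IA1          1
```

All eight planted introns are recovered at their exact planted
coordinates — half via explicit `intron` features, half via
compound-location gaps — and every planted endonuclease ORF is called
from the mock InterProScan evidence (`n_hegs`). `tidy(db, "hegs")`
lists each HEG with its frame, genetic-code table and provenance class;
on random synthetic sequence the largest ORF covering a planted
cassette often arises under a permissive code table (few stop codons),
which the provenance column then reports honestly as `foreign` — see
the vignette for why real introns behave differently. Results land in
`db/introns.tsv` and `db/hegs.tsv` (escaped, round-trippable TSV), with
FASTA side files and a JSON run report.

A thin command-line front end wraps the same functions:

```sh
exec/intronforge make-fixtures --seed 7 --n 8 --plant-heg --out fixtures
exec/intronforge build-db --config pipeline.yaml
exec/intronforge summarize --introns db/introns.tsv --hegs db/hegs.tsv
```

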