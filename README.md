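# isoswap

Mining and querying bioisosteric fragment replacements from holo
protein–ligand complexes.

Medicinal chemists optimizing a hit or lead often need to swap one
functional group or scaffold for another that keeps the binding
interactions but improves properties (permeability, stability, novelty).
`isoswap` derives such replacement candidates from structural data: when
two similar binding pockets in different crystal structures hold
chemically different ligand fragments in the same region of space, those
fragments are recorded as a replaceable pair.

## Method in brief

* Binding sites (residues within 5 Å of a ligand) are reduced to labeled
  physico-chemical points and superposed by an exact maximum clique over
  the distance-consistent product graph, followed by Kabsch least-squares
  fitting. Alignments whose score is ≥ 2 standard deviations above the
  batch mean (Z-filter) are kept.
* Ligands are transposed between aligned sites and fragmented at
  rotatable bonds into *core* atoms plus *join* atoms (retained copies of
  the cross-bond partners, marking reattachment points).
* Fragment pairs are scored by the Hausdorff distance between their van
  der Waals surfaces,

  ```
  HD(A,B) = max{ oHD(A,B), oHD(B,A) },
  oHD(A,B) = max_{a in A} min_{b in B} ||a - b||,
  ```

  computed on Fibonacci-lattice sphere samples; pairs with Overall
  HD ≤ 1.50 Å are stored with Overall/Core/H-bonding HDs, corresponding
  join atoms, provenance and the SCOP family relation.
* Queries run by input molecule, core substructure or fragment
  descriptors, with *loose*/*rigorous* presets (common-core vs
  specific-structure matching, inter- vs intra-family, interchangeable
  join-atom hybridization classes), HD sorting and pagination. A chosen
  replacement can be grafted back into the query molecule under
  valence-aware closest-pair reconnection and exported as SMILES or MOL.

See `vignettes/bioisostere-mining.Rmd` for the full model, parameter
table, numerical conventions and limitations.

## Worked example

Fragment the shipped sulfonamide inhibitor (a synthetic reconstruction of
a MurF-inhibitor-like structure: benzothiophene-2-sulfonyl → NH →
dichlorophenyl → morpholine), then mine a generated fixture pair and ask
for ring replacements:

```r
library(isoswap)

murf <- read_mol(system.file("extdata", "murf_inhibitor_synthetic.mol",
                             package = "isoswap"))
query_by_molecule(murf)
#> <iso_fragment_menu> 5 fragments:
#>   [1] heavy 10 (core 9 + join 1), ring atoms 9
#>   [2] heavy 5 (core 3 + join 2), ring atoms 0
#>   [3] heavy 3 (core 1 + join 2), ring atoms 0
#>   [4] heavy 10 (core 8 + join 2), ring atoms 6
#>   [5] heavy 7 (core 6 + join 1), ring atoms 6
```

Five fragments: the benzothiophene (1), the sulfonyl linker (2), the
bridging NH (3), the dichlorobenzene (4) and the morpholine (5).

```r
d <- file.path(tempdir(), "fix")
write_fixture_set(d, seed = 7)               # two complexes, planted pair
cxa <- read_pdb_complex(file.path(d, "cpx7a.pdb"))
cxb <- read_pdb_complex(file.path(d, "cpx7b.pdb"))
db <- mine_pairs(list(cxa, cxb),
                 scop = read_scop_table(file.path(d, "families.tsv")))
#> mine_pairs: alignment batch too small for Z-scoring; using absolute
#> clique-score threshold 4
db
#> <iso_pairdb> v1: 4 pair records

frag <- query_by_molecule(read_smiles("CCc1ccccc1"))$fragments[[2]]
find_replacements(frag, db, query_options("rigorous"))
#> <iso_results> 2 rows in 1 page(s)
#>   rank  hd_overall     hd_core hd_hbond family_relation complex_a complex_b page
#> 1    1 0.001004845 0.001004845       NA           intra     cpx7a     cpx7b    1
#> 2    2 0.001004845 0.001004845       NA           intra     cpx7b     cpx7a    1
```

The planted benzene-core pair is recovered with an Overall HD of ~0.001 Å
(the two ring surfaces coincide up to sphere sampling), labeled
intra-family via the supplied `families.tsv`. H-bonding HD is absent
(`NA`) because neither fragment has donor or acceptor atoms.

## Command line

A thin wrapper over the same functions is installed at
`inst/scripts/isoswap`:

```sh
isoswap fixtures --out fix --seed 7
isoswap mine --out fix/out.db --scop fix/families.tsv fix/cpx7a.pdb fix/cpx7b.pdb
isoswap query --db fix/out.db --smiles 'CCc1ccccc1' --select-fragment 2 --preset rigorous
isoswap replace --mol query.mol --fragment 1 --with frag.sdf -o product.mol
```

Exit codes: 0 success, 2 validation/usage error, 1 runtime error. Options
may also come from a `key = value` config file via `--config`
(command line wins).

## Pair database

`save_db()`/`load_db()` persist a single versioned JSON file; records hold
both fragments (atoms, bonds, join flags), the three HDs, join-atom
correspondences, source complexes and the family relation, and both
orientations of every pair. `export_jsonl()` writes one JSON object per
record with canonical SMILES for interchange. Externally computed site
transforms (12 numbers per line: row-major rotation, then translation)
can be imported to drive mining in place of the built-in aligner
(`read_transforms()`, or `isoswap mine --transforms`).

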