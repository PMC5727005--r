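Package: isoswap
Title: Mining and Querying Bioisosteric Fragment Replacements from
    Protein-Ligand Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines bioisosteric and scaffold-hopping fragment replacements
    from holo protein-ligand complexes. Binding sites of different complexes
    are superimposed by a distance-consistent maximum-clique match of their
    physico-chemical site points followed by Kabsch superposition; alignments
    are retained by a Z-score criterion; co-crystallized ligands are
    transposed between aligned sites and fragmented at rotatable bonds into
    core/join-atom fragments; fragment pairs in high spatial overlap, scored
    by Hausdorff distances between their van der Waals surfaces, are stored
    in a queryable pair database. Query tools answer bioisostere searches by
    molecule, core substructure or fragment properties, with join-atom
    compatibility rules, family filters and Hausdorff-distance sorting, and a
    valence-aware reconnector grafts a chosen replacement back into the query
    molecule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    bio3d,
    ChemmineR,
    ChemmineOB,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
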