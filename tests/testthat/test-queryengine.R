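# the tests below run against mk_test_db() (helper-oracles.R): morpholine
# fragments paired with thiophene/benzene under intra/inter/unknown family
# relations plus a toluene-core single fragment

test_that("the loose and rigorous presets pin the documented options", {
  lo <- query_options("loose")
  expect_identical(lo$family, "both")
  expect_true(lo$common_core_query)
  expect_identical(lo$sort_key, "core")

  ri <- query_options("rigorous")
  expect_identical(ri$family, "intra")
  expect_false(ri$common_core_query)
  expect_false(ri$interchangeable_join_types)

  cu <- query_options("custom", family = "inter", hd_cutoff = 0.8)
  expect_identical(cu$family, "inter")
  expect_equal(cu$hd_cutoff, 0.8)
})

test_that("join-type compatibility follows the hybridization classes", {
  expect_true(join_types_compatible("N.2", "N.pl3", interchangeable = TRUE))
  expect_false(join_types_compatible("N.2", "N.pl3", interchangeable = FALSE))
  expect_false(join_types_compatible("N.2", "O.2", interchangeable = TRUE))
  expect_true(join_types_compatible("C.3", "C.3", interchangeable = FALSE))
  expect_false(join_types_compatible("C.3", "C.2", interchangeable = TRUE))
  expect_true(join_types_compatible("C.ar", "C.2", interchangeable = TRUE))
})

test_that("query by molecule presents the fragment menu", {
  menu <- query_by_molecule(make_ligand("benzene"))
  expect_length(menu$fragments, 1L)
  menu2 <- query_by_molecule(make_ligand("murf_mock"))
  expect_length(menu2$fragments, 5L)
  salt <- mk_mol(c("C", "C"), rbind(c(0, 0, 0), c(9, 0, 0)), NULL)
  expect_error(query_by_molecule(salt), "largest")
})

test_that("core-substructure queries match by labeled subgraph", {
  db <- mk_test_db()
  # benzene is contained in the toluene core, the only query-side
  # fragment of this database with an aromatic carbocycle
  hits <- query_by_core(db, make_ligand("benzene"))
  keys <- vapply(hits$fragments, isoswap:::core_key, character(1))
  tol <- db$records[[5]]$query_fragment
  expect_identical(keys, isoswap:::core_key(tol))

  # single aromatic N matches nothing here; single O matches morpholine
  lone_o <- perceive_and_type(iso_mol("O", matrix(0, 1, 3), NULL))
  hits_o <- query_by_core(db, lone_o)
  expect_gte(length(hits_o$fragments), 1L)
  lone_n_ar <- perceive_and_type(iso_mol("N", matrix(0, 1, 3), NULL))
  lone_n_ar$atoms$sybyl <- "N.ar"
  expect_length(query_by_core(db, lone_n_ar)$fragments, 0L)

  # a substructure larger than any stored fragment matches nothing
  expect_length(query_by_core(db, make_ligand("biphenyl"))$fragments, 0L)

  # linear-scan oracle: every reported hit really contains the substructure
  for (f in hits$fragments)
    expect_true(igraph::subgraph_isomorphic(
      isoswap:::color_pair(isoswap:::mol_core_style_graph(
        make_ligand("benzene")), core_graph(f))[[1]],
      isoswap:::color_pair(isoswap:::mol_core_style_graph(
        make_ligand("benzene")), core_graph(f))[[2]],
      method = "vf2"))
})

test_that("property queries apply closed-interval descriptor bounds", {
  db <- mk_test_db()
  hits <- query_by_properties(db, list(n_heavy = c(6, 8),
                                       n_ring_atoms = c(6, 6)))
  expect_gte(length(hits$fragments), 2L)
  for (f in hits$fragments) {
    d <- describe_fragment(f)
    expect_true(d$n_heavy >= 6 && d$n_heavy <= 8 && d$n_ring_atoms == 6)
  }
  expect_length(query_by_properties(db, list(n_heavy = c(50, 60)))$fragments,
                0L)
  expect_error(query_by_properties(db, list(n_heavy = c(6, 2))), "min <= max")
  expect_error(query_by_properties(db, list(bogus = c(0, 1))), "bogus")
  # multi-join (linker) fragments only
  sulf_db <- pair_db(list(mk_record(
    fragment_molecule(make_ligand("sulfonamide"))[[2]],
    fragment_molecule(make_ligand("sulfonamide"))[[2]], 0.1, 0.1)))
  expect_length(query_by_properties(sulf_db,
                                    list(n_join = c(2, Inf)))$fragments, 1L)
  expect_length(query_by_properties(db, list(n_join = c(2, Inf)))$fragments,
                0L)
})

test_that("replacement search respects presets, filters, sorting, paging", {
  db <- mk_test_db()
  fmorN <- single_fragment(mk_n_ethylmorpholine())[[1]]

  # rigorous: intra-family, strict join types -> thiophene + one benzene
  ri <- find_replacements(fmorN, db, query_options("rigorous"))
  expect_equal(nrow(ri$table), 2L)
  expect_true(all(ri$table$family_relation == "intra"))

  # loose: common-core -> all four morpholine records (both join variants)
  lo <- find_replacements(fmorN, db, query_options("loose"))
  expect_equal(nrow(lo$table), 4L)
  # rigorous results are a subset of loose results
  rid <- vapply(ri$rows, `[[`, integer(1), "record_id")
  lid <- vapply(lo$rows, `[[`, integer(1), "record_id")
  expect_true(all(rid %in% lid))

  # family custom filter: inter includes unknown
  inter <- find_replacements(fmorN, db,
                             query_options("custom", family = "inter",
                                           common_core_query = TRUE))
  expect_setequal(unique(inter$table$family_relation),
                  c("inter", "unknown"))

  # intra-only custom sits between rigorous and both
  intra <- find_replacements(fmorN, db,
                             query_options("custom", family = "intra",
                                           common_core_query = TRUE))
  expect_true(all(rid %in% vapply(intra$rows, `[[`, integer(1),
                                  "record_id")))
  expect_true(all(vapply(intra$rows, `[[`, integer(1), "record_id") %in%
                    lid))

  # hd cutoff honored post-hoc
  tight <- find_replacements(fmorN, db,
                             query_options("loose", hd_cutoff = 0.8))
  expect_true(all(tight$table$hd_overall <= 0.8))

  # duplicate bioisostere from two sources -> two rows, distinct HDs
  dup <- lo$table[lo$table$family_relation == "intra", ]
  expect_gte(nrow(lo$table), 2L)

  # sorting: asc/desc are exact reverses on distinct keys
  asc <- find_replacements(fmorN, db, query_options("loose",
                                                    sort_order = "asc"))
  desc <- find_replacements(fmorN, db, query_options("loose",
                                                     sort_order = "desc"))
  expect_equal(asc$table$hd_core, rev(desc$table$hd_core))
  expect_true(!is.unsorted(asc$table$hd_core))

  # pagination
  paged <- find_replacements(fmorN, db,
                             query_options("loose", page_size = 2L))
  expect_equal(max(paged$table$page), 2L)
  pg2 <- result_page(paged, 2L)
  expect_equal(nrow(pg2$table), 2L)

  # Rule 3: isomorphic-core queries retrieve identical record sets
  fmorC <- single_fragment(mk_c_ethylmorpholine())[[1]]
  loC <- find_replacements(fmorC, db, query_options("loose"))
  expect_setequal(vapply(loC$rows, `[[`, integer(1), "record_id"), lid)

  # specific mode requires a join selection on multi-join fragments
  linker <- fragment_molecule(make_ligand("sulfonamide"))[[2]]
  expect_error(find_replacements(linker, db, query_options("rigorous")),
               "select")
  # and a join atom at all
  ftol <- db$records[[5]]$query_fragment
  expect_error(find_replacements(ftol, db, query_options("rigorous")),
               "join atom")
})

test_that("common-core results are reduced to cores with remapped joins", {
  db <- mk_test_db()
  fmorN <- single_fragment(mk_n_ethylmorpholine())[[1]]
  sel <- which(fmorN$atoms$is_join)[1]
  lo <- find_replacements(fmorN, db, query_options("loose"),
                          selected_join = sel)
  row <- lo$rows[[1]]
  # replacement carries exactly one join atom: the remapped selection
  expect_equal(sum(row$replacement$atoms$is_join), 1L)
  expect_identical(row$replacement$atoms$sybyl[row$replacement$atoms$is_join],
                   fmorN$atoms$sybyl[sel])
})

test_that("Rule 1 widens specific-structure matches to similar join types", {
  # query fragment: morpholine joined through an aromatic carbon (C.ar);
  # database fragment: morpholine joined through an sp2 carbon (C.2):
  # same element, same trigonal class -> matched only when Rule 1 is on
  ring <- make_ligand("morpholine")
  aryl <- mk_mol(c(ring$atoms$element, rep("C", 6)),
                 rbind(as.matrix(ring$atoms[, c("x", "y", "z")]),
                       isoswap:::ring_xy(6, 1.39, center = c(-4.3, 0, 0),
                                         start = 0)),
                 rbind(ring$bonds[, c("i", "j", "order")],
                       isoswap:::ring_bonds(6, "ar", offset = 6L),
                       data.frame(i = 4, j = 7, order = "1")))
  vinyl <- mk_mol(c(ring$atoms$element, "C", "C"),
                  rbind(as.matrix(ring$atoms[, c("x", "y", "z")]),
                        c(-2.9, 0, 0), c(-3.6, 1.2, 0)),
                  rbind(ring$bonds[, c("i", "j", "order")],
                        data.frame(i = c(4, 7), j = c(7, 8),
                                   order = c("1", "2"))))
  fq <- single_fragment(aryl)[[1]]   # join C.ar
  fd <- single_fragment(vinyl)[[1]]  # join C.2
  fthio <- single_fragment(mk_ethylthiophene())[[1]]
  db <- pair_db(list(mk_record(fd, fthio, 0.5, 0.4, relation = "intra")))
  strict <- find_replacements(fq, db, query_options(
    "custom", family = "both", interchangeable_join_types = FALSE))
  relaxed <- find_replacements(fq, db, query_options(
    "custom", family = "both", interchangeable_join_types = TRUE))
  expect_equal(nrow(strict$table), 0L)
  expect_equal(nrow(relaxed$table), 1L)
})
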