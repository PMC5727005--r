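test_that("available valence counts heavy bonds only", {
  # propane middle carbon: 2 heavy bonds -> 2 left
  pr <- mk_mol(rep("C", 3),
               rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.2, 1.3, 0)),
               data.frame(i = c(1, 2), j = c(2, 3), order = "1"))
  expect_equal(available_valence(pr, 2), 2L)
  # carbon with four heavy neighbours is saturated
  ne <- mk_mol(rep("C", 5),
               rbind(c(0, 0, 0), c(1.5, 0, 0), c(-1.5, 0, 0),
                     c(0, 1.5, 0), c(0, -1.5, 0)),
               data.frame(i = 1, j = 2:5, order = "1"))
  expect_equal(available_valence(ne, 1), 0L)
  # hydrogens are ignored: CH2 with two explicit H keeps 2 heavy slots
  ch <- mk_mol(c("C", "C", "C", "H", "H"),
               rbind(c(0, 0, 0), c(1.5, 0, 0), c(-1.5, 0, 0),
                     c(0, 1.0, 0.3), c(0, -1.0, 0.3)),
               data.frame(i = 1, j = 2:5, order = "1"))
  expect_equal(available_valence(ch, 1), 2L)
  # oxygen of an ether is saturated
  et <- mk_mol(c("C", "O", "C"),
               rbind(c(0, 0, 0), c(1.4, 0, 0), c(2.1, 1.2, 0)),
               data.frame(i = c(1, 2), j = c(2, 3), order = "1"))
  expect_equal(available_valence(et, 2), 0L)
})

test_that("identity replacement is a graph-level no-op on fixtures", {
  for (tpl in c("biphenyl", "ethylbenzene", "murf_mock")) {
    m <- make_ligand(tpl)
    for (f in fragment_molecule(m)) {
      jr <- which(f$atoms$is_join)
      if (length(jr) == 0L) next
      prod <- replace_fragment(m, f, f,
                               list(new_join = jr[1],
                                    attach = f$broken$partner[1]))
      expect_true(same_molecule(prod, m))
      # heavy-atom bookkeeping
      expect_equal(nrow(prod$atoms), nrow(m$atoms))
    }
  }
})

test_that("a real swap grafts the new ring and stays valence-legal", {
  m <- mk_n_ethylmorpholine()
  frags <- fragment_molecule(m)
  fthio <- single_fragment(mk_ethylthiophene())[[1]]
  jr <- which(fthio$atoms$is_join)
  prod <- replace_fragment(m, frags[[1]], fthio,
                           list(new_join = jr[1],
                                attach = frags[[1]]$broken$partner[1]))
  expect_identical(to_smiles(prod), to_smiles(mk_ethylthiophene()))
  expect_equal(nrow(prod$atoms),
               nrow(m$atoms) - sum(!frags[[1]]$atoms$is_join) +
                 sum(!fthio$atoms$is_join))
})

test_that("secondary bonds go to the next closest valence-feasible atom", {
  # central linker with two attachments; the replacement's nearest atom to
  # the second attachment is saturated, so the bond falls through to the
  # next closest feasible atom
  mol <- mk_mol(c("C", "C", "C", "C", "C", "C"),
                rbind(c(-3.0, 0, 0), c(-1.5, 0, 0), c(0, 0, 0),
                      c(1.5, 0, 0), c(3.0, 0, 0), c(4.5, 0, 0)),
                data.frame(i = 1:5, j = 2:6, order = "1"))
  frags <- fragment_molecule(mol)
  mid <- frags[[2]]  # middle piece with two joins
  expect_equal(sum(mid$atoms$is_join), 2L)

  # replacement C-C-O-C chain (join on the first carbon): after placement
  # the ether oxygen lands exactly on the second attachment point but is
  # already valence-saturated, so the bond must fall through to the next
  # closest feasible atom (the carbon on the oxygen's far side)
  repl_mol <- mk_mol(c("C", "C", "O", "C"),
                     rbind(c(-4.4, 0, 0), c(-2.9, 0, 0), c(-1.4, 0, 0),
                           c(-1.4, 1.4, 0)),
                     data.frame(i = c(1, 2, 3), j = c(2, 3, 4),
                                order = "1"))
  ratoms <- repl_mol$atoms
  ratoms$orig <- NA_integer_
  ratoms$is_join <- c(TRUE, FALSE, FALSE, FALSE)
  rbonds <- repl_mol$bonds
  rbonds$in_ring <- FALSE
  repl <- structure(list(atoms = ratoms, bonds = rbonds, parent = "repl",
                         broken = data.frame(core = 2L,
                                             partner = NA_integer_)),
                    class = "iso_frag")

  prod <- replace_fragment(mol, mid, repl,
                           list(new_join = 1L, attach = mid$broken$partner[1]))
  expect_equal(igraph::components(isoswap:::mol_graph(prod))$no, 1L)
  # the oxygen kept its two original bonds; the severed atom bonded to
  # the fall-through carbon instead
  o_idx <- which(prod$atoms$element == "O")
  expect_equal(sum(prod$bonds$i == o_idx | prod$bonds$j == o_idx), 2L)
  for (a in seq_len(nrow(prod$atoms)))
    expect_gte(available_valence(prod, a), 0L)
})

test_that("impossible reconnections raise a reconnection failure", {
  mol <- mk_mol(c("C", "C", "C", "C", "C", "C"),
                rbind(c(-3.0, 0, 0), c(-1.5, 0, 0), c(0, 0, 0),
                      c(1.5, 0, 0), c(3.0, 0, 0), c(4.5, 0, 0)),
                data.frame(i = 1:5, j = 2:6, order = "1"))
  frags <- fragment_molecule(mol)
  mid <- frags[[2]]
  # replacement whose single core atom is a halogen: the primary bond
  # consumes its only valence slot, leaving none for the second attachment
  o_repl <- structure(list(
    atoms = data.frame(element = c("F", "C"), x = c(0, -1.4), y = 0, z = 0,
                       sybyl = c("F", "C.3"), vdw = c(1.47, 1.70),
                       is_donor = FALSE, is_acceptor = FALSE,
                       heavy_degree = 1L, orig = NA_integer_,
                       is_join = c(FALSE, TRUE)),
    bonds = data.frame(i = 2, j = 1, order = "1", in_ring = FALSE),
    parent = "fluoro", broken = data.frame(core = 1L, partner = NA_integer_)),
    class = "iso_frag")
  expect_error(replace_fragment(mol, mid, o_repl,
                                list(new_join = 2L,
                                     attach = mid$broken$partner[1])),
               "valence-feasible")
})

test_that("randomized replacements never break valence caps", {
  pool_mols <- list(mk_n_ethylmorpholine(), mk_ethylthiophene(),
                    make_ligand("ethylbenzene"), make_ligand("biphenyl"))
  pool <- unlist(lapply(pool_mols, function(m)
    Filter(function(f) sum(f$atoms$is_join) >= 1L, fragment_molecule(m))),
    recursive = FALSE)
  hosts <- list(make_ligand("murf_mock"), mk_n_ethylmorpholine(),
                make_ligand("biphenyl"))
  set.seed(2024)
  n_ok <- 0L
  for (k in 1:300) {
    host <- hosts[[sample(length(hosts), 1)]]
    frags <- fragment_molecule(host)
    f <- frags[[sample(length(frags), 1)]]
    if (sum(f$atoms$is_join) == 0L) next
    new <- pool[[sample(length(pool), 1)]]
    jr <- which(new$atoms$is_join)
    res <- try(replace_fragment(
      host, f, new,
      list(new_join = jr[sample(length(jr), 1)],
           attach = f$broken$partner[sample(nrow(f$broken), 1)])),
      silent = TRUE)
    if (inherits(res, "try-error")) next  # legal refusals are fine
    n_ok <- n_ok + 1L
    for (a in seq_len(nrow(res$atoms)))
      expect_gte(available_valence(res, a), 0L)
  }
  expect_gte(n_ok, 100L)
})

test_that("products export to SMILES and MOL and re-import", {
  m <- make_ligand("biphenyl")
  f <- fragment_molecule(m)[[1]]
  prod <- replace_fragment(m, f, f, list(new_join = which(f$atoms$is_join)[1],
                                         attach = f$broken$partner[1]))
  expect_identical(export_product(prod, "smiles"), to_smiles(m))
  path <- withr::local_tempfile(fileext = ".mol")
  export_product(prod, "mol", path)
  expect_true(same_molecule(read_mol(path), m))
})

test_that("three sequential swaps keep producing valid exports", {
  mol <- make_ligand("murf_mock")
  ring_repl <- list(
    single_fragment(mk_ethylthiophene())[[1]],
    fragment_molecule(make_ligand("ethylbenzene"))[[1]],
    single_fragment(mk_n_ethylmorpholine())[[1]]
  )
  # replace the three ring fragments one at a time, re-importing the MOL
  # export between steps (the workflow of repeated single replacements)
  ring_keys <- vapply(ring_repl, isoswap:::core_key, character(1))
  for (step in 1:3) {
    frags <- fragment_molecule(mol)
    ring_idx <- which(vapply(frags, function(f)
      describe_fragment(f)$n_ring_atoms >= 5L, logical(1)))
    expect_gte(length(ring_idx), 1L)
    target <- frags[[ring_idx[1]]]
    new <- ring_repl[[step]]
    prod <- replace_fragment(mol, target, new,
                             list(new_join = which(new$atoms$is_join)[1],
                                  attach = target$broken$partner[1]))
    smi <- export_product(prod, "smiles")
    expect_true(nzchar(smi))
    path <- withr::local_tempfile(fileext = ".mol")
    export_product(prod, "mol", path)
    mol <- read_mol(path)
  }
  expect_equal(igraph::components(isoswap:::mol_graph(mol))$no, 1L)
})
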