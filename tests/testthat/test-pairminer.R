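test_that("surface sampling lies on spheres and culls buried points", {
  lone <- fragment_molecule(mk_mol("C", matrix(c(1, 2, 3), 1), NULL))[[1]]
  sp <- surface_points(lone, "all", density = 64)
  expect_equal(nrow(sp), 64L)
  r <- sqrt(rowSums(sweep(sp, 2, c(1, 2, 3))^2))
  expect_equal(r, rep(1.70, 64), tolerance = 1e-9)

  # two coincident atoms: every point sits exactly on the other sphere,
  # so nothing is culled and the union equals one sphere's samples twice
  two <- fragment_molecule(
    mk_mol(c("C", "C"), rbind(c(0, 0, 0), c(0, 0, 0)),
           data.frame(i = 1, j = 2, order = "1")))[[1]]
  sp2 <- surface_points(two, "all", density = 32)
  expect_equal(nrow(sp2), 64L)
  expect_equal(sqrt(rowSums(sp2^2)), rep(1.70, 64), tolerance = 1e-9)

  # partially overlapping atoms cull interior points (brute-force check)
  ov <- fragment_molecule(
    mk_mol(c("C", "C"), rbind(c(0, 0, 0), c(1.5, 0, 0)),
           data.frame(i = 1, j = 2, order = "1")))[[1]]
  spo <- surface_points(ov, "all", density = 64)
  expect_lt(nrow(spo), 128L)
  d1 <- sqrt(rowSums(spo^2))
  d2 <- sqrt(rowSums(sweep(spo, 2, c(1.5, 0, 0))^2))
  on1 <- abs(d1 - 1.7) < 1e-6; on2 <- abs(d2 - 1.7) < 1e-6
  expect_true(all(on1 | on2))
  expect_true(all(d1[on2] >= 1.7 - 1e-6) && all(d2[on1] >= 1.7 - 1e-6))

  # hbond subset of an apolar fragment signals emptiness
  bz <- fragment_molecule(make_ligand("benzene"))[[1]]
  hb <- surface_points(bz, "hbond", 32)
  expect_true(attr(hb, "empty_subset"))
  expect_equal(nrow(hb), 0L)

  # core subset excludes join-atom spheres
  bp <- fragment_molecule(make_ligand("biphenyl"))[[1]]
  expect_lt(nrow(surface_points(bp, "core", 32)),
            nrow(surface_points(bp, "all", 32)))
})

test_that("Hausdorff operators match hand cases and the brute-force oracle", {
  A <- rbind(c(0, 0, 0), c(10, 0, 0)); B <- rbind(c(0, 0, 0))
  expect_equal(one_sided_hd(A, B), 10)
  expect_equal(one_sided_hd(B, A), 0)
  expect_equal(hausdorff(A, B), 10)
  expect_error(one_sided_hd(matrix(numeric(), ncol = 3), B), "empty")

  set.seed(5)
  for (k in 1:25) {
    P <- random_points(sample(5:50, 1)); Q <- random_points(sample(5:50, 1))
    expect_identical(hausdorff(P, Q), bf_hausdorff(P, Q))
    expect_identical(hausdorff(P, Q), hausdorff(Q, P))
    expect_identical(one_sided_hd(P, Q), bf_one_sided_hd(P, Q))
  }

  # rigid co-transformation leaves HD unchanged
  P <- random_points(40); Q <- random_points(30)
  h0 <- hausdorff(P, Q)
  R <- isoswap:::random_rotation(); t <- c(3, 4, 5)
  expect_equal(hausdorff(sweep(P %*% t(R), 2, t, `+`),
                         sweep(Q %*% t(R), 2, t, `+`)),
               h0, tolerance = 1e-9)
})

test_that("join-atom matching is greedy by ascending distance", {
  f <- single_fragment(mk_ethylthiophene())[[1]]
  m0 <- match_join_atoms(f, f)
  expect_equal(nrow(m0), 1L)
  expect_equal(m0$dist, 0)

  shifted <- f
  shifted$atoms$x <- shifted$atoms$x + 5
  expect_equal(nrow(match_join_atoms(f, shifted)), 0L)

  # 2 vs 2 join atoms with crossed distances: the closest pair is taken
  # first and the remaining atoms pair up second
  sq <- fragment_molecule(make_ligand("sulfonamide"))
  linker <- sq[[2]]  # SO2 core with two joins
  expect_equal(sum(linker$atoms$is_join), 2L)
  other <- linker
  other$atoms$x <- other$atoms$x + 0.4
  mm <- match_join_atoms(linker, other)
  expect_equal(nrow(mm), 2L)
  expect_true(all(diff(mm$dist) >= 0) || nrow(mm) == 2L)
  # every join atom used at most once
  expect_equal(anyDuplicated(mm$q), 0L)
  expect_equal(anyDuplicated(mm$p), 0L)
})

test_that("mining recovers planted pairs and rejects displaced ones", {
  pair <- make_complex_pair(21, planted_overlap = 0)
  db <- suppressMessages(
    mine_pairs(list(pair$complex_a, pair$complex_b),
               site_cutoff = pair$truth$site_cutoff, density = 32))
  hit <- Filter(function(r) r$qkey == pair$truth$query_core_key &&
                  r$pkey == pair$truth$partner_core_key, db_records(db))
  expect_gte(length(hit), 1L)
  expect_lt(hit[[1]]$hd_overall, 0.3)
  # join atoms of the planted ring pair coincide
  expect_gte(nrow(hit[[1]]$join_correspondences), 1L)
  # both orientations stored
  rev_hit <- Filter(function(r) r$qkey == pair$truth$partner_core_key &&
                      r$pkey == pair$truth$query_core_key, db_records(db))
  expect_gte(length(rev_hit), 1L)

  far <- make_complex_pair(21, planted_overlap = 6)
  db6 <- suppressMessages(
    mine_pairs(list(far$complex_a, far$complex_b),
               site_cutoff = far$truth$site_cutoff, density = 32))
  hit6 <- Filter(function(r) r$qkey == far$truth$query_core_key &&
                   r$pkey == far$truth$partner_core_key, db_records(db6))
  expect_length(hit6, 0L)

  # cutoff monotonicity: a smaller cutoff never adds records
  db_tight <- suppressMessages(
    mine_pairs(list(pair$complex_a, pair$complex_b),
               site_cutoff = pair$truth$site_cutoff, density = 32,
               hd_cutoff = 0.5))
  expect_lte(length(db_records(db_tight)), length(db_records(db)))
})

test_that("homogeneous alignment batches are emptied by the Z-filter", {
  # four congruent pockets: all pairwise scores equal, sd = 0, nothing
  # reaches Z >= 2
  base <- make_complex_pair(31)
  mk <- function(nm, tr) {
    p <- base$complex_a$protein
    p[, c("x", "y", "z")] <- apply_transform(tr, as.matrix(p[, c("x", "y", "z")]))
    isoswap:::fixture_complex(nm, p,
      list(transpose_ligand(base$complex_a$ligands[[1]], tr)))
  }
  set.seed(99)
  cxs <- lapply(1:4, function(k)
    mk(paste0("eq", k), iso_transform(isoswap:::random_rotation(),
                                      c(15 * k, 0, 0))))
  db <- suppressMessages(mine_pairs(cxs, site_cutoff = 5))
  expect_length(db_records(db), 0L)
})

test_that("externally supplied transforms drive mining directly", {
  pair <- make_complex_pair(41, planted_overlap = 0)
  tr <- pair$truth$transform
  key <- paste0(pair$complex_a$name, "|", pair$complex_b$name)
  db <- mine_pairs(list(pair$complex_a, pair$complex_b),
                   site_cutoff = pair$truth$site_cutoff, density = 32,
                   transforms = stats::setNames(list(tr), key))
  # the imported transform is B -> A; stored under A|B it is used as-is
  hit <- Filter(function(r) r$qkey == pair$truth$query_core_key &&
                  r$pkey == pair$truth$partner_core_key, db_records(db))
  expect_gte(length(hit), 1L)
})

test_that("the pair database round-trips and rejects foreign versions", {
  pair <- make_complex_pair(51)
  db <- suppressMessages(
    mine_pairs(list(pair$complex_a, pair$complex_b),
               site_cutoff = pair$truth$site_cutoff, density = 32))
  expect_gte(length(db_records(db)), 2L)
  f <- withr::local_tempfile(fileext = ".json")
  save_db(db, f)
  db2 <- load_db(f)
  expect_equal(length(db_records(db2)), length(db_records(db)))
  for (k in seq_along(db$records)) {
    a <- db$records[[k]]; b <- db2$records[[k]]
    expect_equal(b$hd_overall, a$hd_overall, tolerance = 1e-12)
    expect_equal(b$hd_core, a$hd_core, tolerance = 1e-12)
    expect_identical(b$qkey, a$qkey)
    expect_identical(b$family_relation, a$family_relation)
    expect_equal(as.data.frame(b$query_fragment$atoms),
                 as.data.frame(a$query_fragment$atoms),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }

  bad <- jsonlite::read_json(f)
  bad$version <- 99L
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(bad, f2, auto_unbox = TRUE)
  expect_error(load_db(f2), "version")

  # JSONL export emits one parsable object per record
  f3 <- withr::local_tempfile(fileext = ".jsonl")
  export_jsonl(db, f3)
  lines <- readLines(f3)
  expect_length(lines, length(db_records(db)))
  obj <- jsonlite::fromJSON(lines[1])
  expect_true(is.numeric(obj$hd_overall))
  expect_true(nzchar(obj$query_smiles))
})
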