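# Mining bioisosteric fragment pairs: for every pair of binding sites that
# passes the alignment Z-filter, the second ligand is transposed into the
# first site's frame, both ligands are fragmented, and fragment pairs in
# high spatial overlap (Overall Hausdorff distance at or below the cutoff)
# are recorded with Overall/Core/H-bonding HDs, corresponding join atoms
# and the SCOP family relation of the two proteins.

#' Match corresponding join atoms of two superposed fragments
#'
#' Greedy nearest-pair matching: candidate join-atom pairs are taken in
#' ascending distance order; each join atom is used at most once; pairs
#' farther apart than `tol` are never matched.
#'
#' @param q,p `iso_frag` objects in a common coordinate frame.
#' @param tol Maximum pairing distance in Angstrom.
#' @return Data frame with columns `q`, `p` (join-atom row indices in each
#'   fragment's `atoms`) and `dist`.
#' @export
match_join_atoms <- function(q, p, tol = 1.5) {
  qi <- which(q$atoms$is_join); pi <- which(p$atoms$is_join)
  empty <- data.frame(q = integer(), p = integer(), dist = numeric())
  if (length(qi) == 0L || length(pi) == 0L) return(empty)
  qc <- as.matrix(q$atoms[qi, c("x", "y", "z"), drop = FALSE])
  pc <- as.matrix(p$atoms[pi, c("x", "y", "z"), drop = FALSE])
  d <- cross_dist(qc, pc)
  cand <- which(d <= tol, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)
  cand <- cand[order(d[cand]), , drop = FALSE]
  used_q <- logical(length(qi)); used_p <- logical(length(pi))
  rows <- list()
  for (r in seq_len(nrow(cand))) {
    a <- cand[r, 1]; b <- cand[r, 2]
    if (used_q[a] || used_p[b]) next
    used_q[a] <- TRUE; used_p[b] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(q = qi[a], p = pi[b],
                                            dist = d[a, b])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Hausdorff distances between two fragments given precomputed surfaces.
frag_surfaces <- function(frag, density) {
  list(all = surface_points(frag, "all", density),
       core = surface_points(frag, "core", density),
       hbond = surface_points(frag, "hbond", density))
}

pair_hds <- function(sq, sp) {
  hb <- if (isTRUE(attr(sq$hbond, "empty_subset")) ||
            isTRUE(attr(sp$hbond, "empty_subset"))) NA_real_
        else hausdorff(sq$hbond, sp$hbond)
  list(overall = hausdorff(sq$all, sp$all),
       core = hausdorff(sq$core, sp$core),
       hbond = hb)
}

#' Read a chain-to-SCOP-family mapping
#'
#' Tab-separated file with columns `pdb_id`, `chain`, `family`. A chain
#' value of `*` applies to every chain of the entry.
#'
#' @param path TSV file.
#' @return Data frame usable as the `scop` argument of [mine_pairs()].
#' @export
read_scop_table <- function(path) {
  t <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("pdb_id", "chain", "family")
  if (!all(need %in% names(t)))
    stop("SCOP table must have columns pdb_id, chain, family", call. = FALSE)
  t
}

scop_family <- function(scop, pdb_id, chain) {
  if (is.null(scop)) return(NA_character_)
  hit <- scop$family[scop$pdb_id == pdb_id &
                     (scop$chain == chain | scop$chain == "*")]
  if (length(hit) == 0L) NA_character_ else hit[1]
}

family_relation <- function(fa, fb) {
  if (is.na(fa) || is.na(fb)) "unknown"
  else if (fa == fb) "intra" else "inter"
}

new_pair_record <- function(qfrag, pfrag, hds, joins, source, relation) {
  structure(list(
    query_fragment = qfrag, partner_fragment = pfrag,
    hd_overall = hds$overall, hd_core = hds$core, hd_hbond = hds$hbond,
    join_correspondences = joins, source = source,
    family_relation = relation,
    qkey = core_key(qfrag), pkey = core_key(pfrag)
  ), class = "iso_pair")
}

#' @export
print.iso_pair <- function(x, ...) {
  cat(sprintf(
    "<iso_pair> %s/%s HD overall %.3f core %.3f hbond %s [%s] %s->%s\n",
    x$source$ligand_a, x$source$ligand_b, x$hd_overall, x$hd_core,
    ifelse(is.na(x$hd_hbond), "-", sprintf("%.3f", x$hd_hbond)),
    x$family_relation, x$source$complex_a, x$source$complex_b))
  invisible(x)
}

#' Mine bioisosteric fragment pairs from a set of complexes
#'
#' For every cross-complex binding-site pair the sites are aligned with
#' [align_sites()]; the batch of alignment scores is reduced with
#' [zscore_filter()] at `zthr` (when the batch holds at least three
#' alignments with non-zero spread; smaller or degenerate batches fall back
#' to the absolute clique-size criterion `min_score`, since a standard
#' score is meaningless there). For every retained site pair the second
#' ligand is transposed into the first frame, both ligands fragmented, and
#' every cross fragment pair with Overall HD at or below `hd_cutoff` is
#' recorded in both orientations.
#'
#' @param complexes List of at least two `iso_complex` objects.
#' @param eps Distance-consistency tolerance of [align_sites()].
#' @param zthr Z-score threshold (default 2).
#' @param hd_cutoff Overall Hausdorff cutoff in Angstrom (default 1.50).
#' @param density Surface points per atom (default 64).
#' @param min_score Minimum clique size for an alignment.
#' @param site_cutoff Binding-site distance cutoff in Angstrom.
#' @param scop Optional data frame from [read_scop_table()].
#' @param transforms Optional named list of [iso_transform()]s keyed
#'   `"<nameA>|<nameB>"`; when a key matches a complex pair, the imported
#'   transform replaces the built-in aligner for that pair and the pair
#'   bypasses the Z-filter (externally validated alignment).
#' @param join_tol Join-atom correspondence tolerance in Angstrom.
#' @return An `iso_pairdb` database object (possibly with zero records).
#' @export
mine_pairs <- function(complexes, eps = 2.0, zthr = 2, hd_cutoff = 1.5,
                       density = 64L, min_score = 4L, site_cutoff = 5.0,
                       scop = NULL, transforms = NULL, join_tol = 1.5) {
  if (length(complexes) < 2L)
    stop("mining requires at least 2 complexes", call. = FALSE)
  stopifnot(all(vapply(complexes, inherits, logical(1), "iso_complex")))

  # one entry per (complex, ligand): site points + fragment/surface caches
  entries <- list()
  for (ci in seq_along(complexes)) {
    cx <- complexes[[ci]]
    for (li in seq_along(cx$ligands)) {
      pts <- tryCatch(
        describe_site(extract_binding_site(cx, li, cutoff = site_cutoff)),
        error = function(e) {
          warning("skipping ", cx$name, " ligand ", li, ": ",
                  conditionMessage(e), call. = FALSE)
          NULL
        })
      if (is.null(pts) || nrow(pts) == 0L) next
      entries[[length(entries) + 1L]] <- list(ci = ci, li = li, pts = pts)
    }
  }

  cand <- list()
  for (u in seq_along(entries)) {
    for (v in seq_along(entries)) {
      if (v <= u) next
      ea <- entries[[u]]; eb <- entries[[v]]
      if (ea$ci == eb$ci) next
      key <- paste0(complexes[[ea$ci]]$name, "|", complexes[[eb$ci]]$name)
      rkey <- paste0(complexes[[eb$ci]]$name, "|", complexes[[ea$ci]]$name)
      ext <- NULL
      if (!is.null(transforms)) {
        if (!is.null(transforms[[key]])) ext <- transforms[[key]]
        else if (!is.null(transforms[[rkey]]))
          ext <- invert_transform(transforms[[rkey]])
      }
      if (!is.null(ext)) {
        cand[[length(cand) + 1L]] <- list(a = ea, b = eb, transform = ext,
                                          score = NA_integer_,
                                          imported = TRUE)
      } else {
        al <- align_sites(ea$pts, eb$pts, eps = eps, min_score = min_score)
        if (!is.null(al))
          cand[[length(cand) + 1L]] <- list(a = ea, b = eb,
                                            transform = al$transform,
                                            score = al$score,
                                            imported = FALSE)
      }
    }
  }

  scores <- vapply(cand, function(x)
    if (x$imported) NA_real_ else as.numeric(x$score), numeric(1))
  native <- which(!is.na(scores))
  keep <- which(vapply(cand, `[[`, logical(1), "imported"))
  if (length(native) >= 3L) {
    kept <- zscore_filter(scores[native], threshold = zthr)
    z <- attr(kept, "zscores")
    for (k in seq_along(native)) cand[[native[k]]]$zscore <- z[k]
    keep <- c(keep, native[kept])
  } else if (length(native) > 0L) {
    message("mine_pairs: alignment batch too small for Z-scoring; using ",
            "absolute clique-score threshold ", min_score)
    keep <- c(keep, native[scores[native] >= min_score])
  }

  frag_cache <- new.env(parent = emptyenv())
  get_frags <- function(ci, li) {
    key <- paste(ci, li)
    if (is.null(frag_cache[[key]]))
      frag_cache[[key]] <- fragment_molecule(complexes[[ci]]$ligands[[li]])
    frag_cache[[key]]
  }

  records <- list()
  for (k in keep) {
    x <- cand[[k]]
    ca <- complexes[[x$a$ci]]; cb <- complexes[[x$b$ci]]
    liga <- ca$ligands[[x$a$li]]
    ligb <- transpose_ligand(cb$ligands[[x$b$li]], x$transform)
    fa <- get_frags(x$a$ci, x$a$li)
    fb <- fragment_molecule(ligb)
    sa <- lapply(fa, frag_surfaces, density = density)
    sb <- lapply(fb, frag_surfaces, density = density)
    fam_a <- scop_family(scop, ca$name, liga$source$chain %||% "A")
    fam_b <- scop_family(scop, cb$name, cb$ligands[[x$b$li]]$source$chain %||% "A")
    rel <- family_relation(fam_a, fam_b)
    for (i in seq_along(fa)) {
      for (j in seq_along(fb)) {
        hds <- pair_hds(sa[[i]], sb[[j]])
        if (hds$overall > hd_cutoff) next
        joins <- match_join_atoms(fa[[i]], fb[[j]], tol = join_tol)
        src <- list(complex_a = ca$name, complex_b = cb$name,
                    ligand_a = liga$name, ligand_b = ligb$name,
                    zscore = x$zscore %||% NA_real_)
        records[[length(records) + 1L]] <-
          new_pair_record(fa[[i]], fb[[j]], hds, joins, src, rel)
        rsrc <- list(complex_a = cb$name, complex_b = ca$name,
                     ligand_a = ligb$name, ligand_b = liga$name,
                     zscore = x$zscore %||% NA_real_)
        records[[length(records) + 1L]] <-
          new_pair_record(fb[[j]], fa[[i]], hds,
                          data.frame(q = joins$p, p = joins$q,
                                     dist = joins$dist),
                          rsrc, rel)
      }
    }
  }
  pair_db(records, params = list(eps = eps, zthr = zthr,
                                 hd_cutoff = hd_cutoff, density = density,
                                 min_score = min_score,
                                 site_cutoff = site_cutoff))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- pair database ----------------------------------------------------

.PAIRDB_FORMAT <- "isoswap-pairdb"
.PAIRDB_VERSION <- 1L

#' Construct a pair database
#' @param records List of pair records (as produced by [mine_pairs()]).
#' @param params Mining parameters to remember.
#' @return Object of class `iso_pairdb`.
#' @export
pair_db <- function(records, params = list()) {
  structure(list(format = .PAIRDB_FORMAT, version = .PAIRDB_VERSION,
                 records = records, params = params),
            class = "iso_pairdb")
}

#' @export
print.iso_pairdb <- function(x, ...) {
  cat(sprintf("<iso_pairdb> v%d: %d pair records\n", x$version,
              length(x$records)))
  invisible(x)
}

#' @rdname pair_db
#' @param db An `iso_pairdb`.
#' @export
db_records <- function(db) db$records

# index: qkey of each record (bucket prefilter for core queries)
db_qkeys <- function(db) vapply(db$records, `[[`, character(1), "qkey")

frag_to_list <- function(f) {
  list(atoms = f$atoms, bonds = f$bonds, parent = f$parent,
       broken = f$broken)
}

#' Save / load a pair database
#'
#' The database is a single versioned JSON file; loading a file with an
#' unknown format or version raises an explicit version error.
#'
#' @param db An `iso_pairdb`.
#' @param path File path.
#' @return `load_db` returns the `iso_pairdb`.
#' @export
save_db <- function(db, path) {
  stopifnot(inherits(db, "iso_pairdb"))
  payload <- list(
    format = db$format, version = db$version, params = db$params,
    records = lapply(db$records, function(r) list(
      query_fragment = frag_to_list(r$query_fragment),
      partner_fragment = frag_to_list(r$partner_fragment),
      hd_overall = r$hd_overall, hd_core = r$hd_core,
      hd_hbond = r$hd_hbond, join_correspondences = r$join_correspondences,
      source = r$source, family_relation = r$family_relation,
      qkey = r$qkey, pkey = r$pkey
    ))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null")
  invisible(path)
}

#' @rdname save_db
#' @export
load_db <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(payload$format, .PAIRDB_FORMAT) ||
      !identical(as.integer(payload$version), .PAIRDB_VERSION))
    stop("unsupported pair-database format/version: ",
         payload$format %||% "?", " v", payload$version %||% "?",
         call. = FALSE)
  records <- lapply(payload$records, function(r) {
    to_df <- function(l) {
      if (length(l) == 0L) return(data.frame())
      do.call(rbind, lapply(l, function(row)
        as.data.frame(lapply(row, function(v) if (is.null(v)) NA else v),
                      stringsAsFactors = FALSE)))
    }
    f1 <- r$query_fragment; f2 <- r$partner_fragment
    structure(list(
      query_fragment = structure(list(atoms = to_df(f1$atoms),
                                      bonds = to_df(f1$bonds),
                                      parent = f1$parent %||% "",
                                      broken = to_df(f1$broken)),
                                 class = "iso_frag"),
      partner_fragment = structure(list(atoms = to_df(f2$atoms),
                                        bonds = to_df(f2$bonds),
                                        parent = f2$parent %||% "",
                                        broken = to_df(f2$broken)),
                                   class = "iso_frag"),
      hd_overall = r$hd_overall, hd_core = r$hd_core,
      hd_hbond = if (is.null(r$hd_hbond)) NA_real_ else r$hd_hbond,
      join_correspondences = to_df(r$join_correspondences),
      source = r$source,
      family_relation = r$family_relation,
      qkey = r$qkey, pkey = r$pkey
    ), class = "iso_pair")
  })
  pair_db(records, params = payload$params)
}

#' Export a pair database as JSON Lines
#'
#' One JSON object per record with the pair's Hausdorff distances, family
#' relation, provenance and the canonical SMILES of both fragments.
#'
#' @param db An `iso_pairdb`.
#' @param path Output file.
#' @export
export_jsonl <- function(db, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (r in db$records) {
    obj <- list(
      query_smiles = to_smiles(fragment_to_mol(r$query_fragment)),
      partner_smiles = to_smiles(fragment_to_mol(r$partner_fragment)),
      hd_overall = r$hd_overall, hd_core = r$hd_core, hd_hbond = r$hd_hbond,
      family_relation = r$family_relation, source = r$source)
    writeLines(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE,
                                             digits = NA, na = "null")),
               con)
  }
  invisible(path)
}
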