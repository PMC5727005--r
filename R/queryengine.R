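# Query layer over the pair database: the three input modes (molecule,
# core substructure, descriptor properties), the join/core-atom search
# rules, the loose/rigorous presets, family filters, Hausdorff sorting
# and pagination.
#
# Rule 1: with interchangeable join types, fragments whose join atoms share
#   element and hybridization geometry class (e.g. N.2 vs N.pl3) match.
# Rules 3+4 (common-core queries): join atoms are stripped from the query,
#   any database fragment with an isomorphic core matches, and the selected
#   join atom is remapped onto the replacement by nearest core position.
# Rule 2 (join-to-core conversion) is deliberately not offered; join atoms
#   outside the selected reconnection pair are always ignored.
# Rule 5 (sequential combination) is implicit in the option set.

#' Query options
#'
#' The `loose` preset searches both family relations with common-core
#' queries (join atoms ignored); the `rigorous` preset restricts to
#' intra-family pairs, non-interchangeable join types and
#' specific-structure queries. `custom` takes each option as given.
#'
#' @param filtering `"custom"`, `"loose"` or `"rigorous"`.
#' @param interchangeable_join_types Rule 1 toggle.
#' @param common_core_query Rules 3+4 toggle.
#' @param family `"intra"`, `"inter"` or `"both"`; pairs with unspecified
#'   families count as inter.
#' @param hd_cutoff Overall Hausdorff cutoff in Angstrom (default 1.50).
#' @param sort_key `"overall"`, `"core"` or `"hbond"`; common-core queries
#'   always sort by core HD.
#' @param sort_order `"asc"` or `"desc"`.
#' @param page_size Rows per result page (default 10).
#' @return List of class `iso_query_options`.
#' @export
query_options <- function(filtering = c("custom", "loose", "rigorous"),
                          interchangeable_join_types = FALSE,
                          common_core_query = FALSE,
                          family = c("both", "intra", "inter"),
                          hd_cutoff = 1.5,
                          sort_key = c("overall", "core", "hbond"),
                          sort_order = c("asc", "desc"),
                          page_size = 10L) {
  filtering <- match.arg(filtering)
  family <- match.arg(family)
  sort_key <- match.arg(sort_key)
  sort_order <- match.arg(sort_order)
  if (filtering == "loose") {
    family <- "both"
    common_core_query <- TRUE
    interchangeable_join_types <- TRUE  # irrelevant: join atoms ignored
  } else if (filtering == "rigorous") {
    family <- "intra"
    common_core_query <- FALSE
    interchangeable_join_types <- FALSE
  }
  if (common_core_query) sort_key <- "core"
  structure(list(filtering = filtering,
                 interchangeable_join_types = interchangeable_join_types,
                 common_core_query = common_core_query,
                 family = family, hd_cutoff = hd_cutoff,
                 sort_key = sort_key, sort_order = sort_order,
                 page_size = as.integer(page_size)),
            class = "iso_query_options")
}

# Sybyl type -> hybridization geometry class
sybyl_geom_class <- function(type) {
  suffix <- ifelse(grepl("\\.", type), sub("^[^.]*\\.", "", type), "")
  cls <- unname(c(`3` = "sp3", `2` = "trigonal", pl3 = "trigonal",
                  ar = "trigonal", cat = "trigonal", am = "trigonal",
                  `1` = "linear", o = "sulfinyl", o2 = "sulfonyl",
                  `4` = "sp3")[suffix])
  cls[is.na(cls)] <- "terminal"
  cls
}

sybyl_element <- function(type) sub("\\..*$", "", type)

#' Are two join-atom types compatible?
#'
#' Strict mode requires equal Sybyl types; interchangeable mode (Rule 1)
#' requires the same element and the same hybridization geometry class,
#' so e.g. an N.2 join atom can be exchanged with N.pl3.
#'
#' @param t1,t2 Sybyl type strings.
#' @param interchangeable Rule 1 toggle.
#' @return Logical.
#' @export
join_types_compatible <- function(t1, t2, interchangeable = FALSE) {
  if (!interchangeable) return(t1 == t2)
  sybyl_element(t1) == sybyl_element(t2) &
    sybyl_geom_class(t1) == sybyl_geom_class(t2)
}

# full labeled graph over a fragment's heavy atoms; join-atom labels depend
# on the Rule 1 setting
frag_full_graph <- function(frag, interchangeable = FALSE) {
  heavy <- which(frag$atoms$element != "H")
  ar <- frag_aromatic(frag)
  lab <- character(length(heavy))
  for (k in seq_along(heavy)) {
    a <- heavy[k]
    lab[k] <- if (frag$atoms$is_join[a]) {
      if (interchangeable)
        paste0("j:", frag$atoms$element[a], ":",
               sybyl_geom_class(frag$atoms$sybyl[a]))
      else paste0("j:", frag$atoms$sybyl[a])
    } else {
      paste0("c:", frag$atoms$element[a], ifelse(ar[a], ":ar", ""))
    }
  }
  g <- igraph::make_empty_graph(n = length(heavy), directed = FALSE)
  b <- frag$bonds[frag$bonds$i %in% heavy & frag$bonds$j %in% heavy, ,
                  drop = FALSE]
  if (nrow(b))
    g <- igraph::add_edges(g, rbind(match(b$i, heavy), match(b$j, heavy)))
  igraph::V(g)$label <- lab
  if (nrow(b)) igraph::E(g)$order <- b$order else
    g <- igraph::set_edge_attr(g, "order", value = character(0))
  g
}

# exact specific-structure match: core + join atoms, join types compared
# under the Rule 1 setting
fragment_matches <- function(a, b, interchangeable = FALSE) {
  labeled_isomorphic(frag_full_graph(a, interchangeable),
                     frag_full_graph(b, interchangeable))
}

#' Fragment an input molecule for query-fragment selection
#'
#' First query mode: the molecule is fragmented and each fragment returned
#' with its descriptors, ready for selection.
#'
#' @param mol A typed, connected [iso_mol()]; disconnected input (e.g. a
#'   salt) raises an error advising selection of the largest component.
#' @return List of class `iso_fragment_menu` with `fragments` and
#'   `descriptors`.
#' @export
query_by_molecule <- function(mol) {
  g <- mol_graph(mol)
  if (igraph::components(g)$no != 1L)
    stop("input is disconnected (a salt or mixture?); select the largest ",
         "component and resubmit", call. = FALSE)
  frags <- fragment_molecule(mol)
  structure(list(fragments = frags,
                 descriptors = lapply(frags, describe_fragment)),
            class = "iso_fragment_menu")
}

#' @export
print.iso_fragment_menu <- function(x, ...) {
  cat(sprintf("<iso_fragment_menu> %d fragments:\n", length(x$fragments)))
  for (i in seq_along(x$fragments)) {
    d <- x$descriptors[[i]]
    cat(sprintf("  [%d] heavy %d (core %d + join %d), ring atoms %d\n",
                i, d$n_heavy, d$n_core, d$n_join, d$n_ring_atoms))
  }
  invisible(x)
}

# distinct query-side fragments of a database, with their record indices
db_distinct_query_fragments <- function(db) {
  sig <- vapply(db$records, function(r)
    paste(r$qkey, paste(sort(r$query_fragment$atoms$sybyl[
      r$query_fragment$atoms$is_join]), collapse = "+")), character(1))
  split(seq_along(db$records), sig)
}

#' Find database query fragments containing a core substructure
#'
#' Second query mode: returns the distinct database query fragments whose
#' core structure contains `sub` as a labeled subgraph.
#'
#' @param db An `iso_pairdb`.
#' @param sub The core substructure: a typed, connected [iso_mol()] (drawn
#'   without join atoms).
#' @return List of class `iso_fragment_hits`: `fragments` plus
#'   `record_ids` (per-fragment record indices into the database).
#' @export
query_by_core <- function(db, sub) {
  stopifnot(inherits(db, "iso_pairdb"), inherits(sub, "iso_mol"))
  gsub_ <- mol_core_style_graph(sub)
  if (igraph::components(gsub_)$no != 1L)
    stop("substructure must be connected", call. = FALSE)
  groups <- db_distinct_query_fragments(db)
  frags <- list(); ids <- list()
  for (grp in groups) {
    f <- db$records[[grp[1]]]$query_fragment
    gt <- core_graph(f)
    if (igraph::vcount(gsub_) > igraph::vcount(gt)) next
    gs <- color_pair(gsub_, gt)
    if (igraph::subgraph_isomorphic(gs[[1]], gs[[2]], method = "vf2")) {
      frags[[length(frags) + 1L]] <- f
      ids[[length(ids) + 1L]] <- grp
    }
  }
  structure(list(fragments = frags, record_ids = ids),
            class = "iso_fragment_hits")
}

# labeled graph of a whole molecule's heavy atoms, core-style labels
mol_core_style_graph <- function(mol) {
  heavy <- heavy_idx(mol)
  arb <- mol$bonds[mol$bonds$order == "ar", , drop = FALSE]
  ar <- logical(n_atoms(mol)); ar[unique(c(arb$i, arb$j))] <- TRUE
  # lone atoms drawn as part of an aromatic system carry it in their type
  ar <- ar | grepl("\\.ar$", mol$atoms$sybyl %||% "")
  g <- igraph::make_empty_graph(n = length(heavy), directed = FALSE)
  b <- mol$bonds[mol$bonds$i %in% heavy & mol$bonds$j %in% heavy, ,
                 drop = FALSE]
  if (nrow(b))
    g <- igraph::add_edges(g, rbind(match(b$i, heavy), match(b$j, heavy)))
  igraph::V(g)$label <- paste0(mol$atoms$element[heavy],
                               ifelse(ar[heavy], ":ar", ""))
  if (nrow(b)) igraph::E(g)$order <- b$order else
    g <- igraph::set_edge_attr(g, "order", value = character(0))
  g
}

#' @export
print.iso_fragment_hits <- function(x, ...) {
  cat(sprintf("<iso_fragment_hits> %d distinct query fragments\n",
              length(x$fragments)))
  invisible(x)
}

#' Find database query fragments by descriptor bounds
#'
#' Third query mode: closed-interval bounds on the fragment descriptors
#' (`n_heavy`, `n_donor`, `n_acceptor`, `n_ring_atoms`, `n_core`,
#' `n_join`).
#'
#' @param db An `iso_pairdb`.
#' @param bounds Named list of `c(min, max)` pairs (use `Inf` for an open
#'   upper end).
#' @return An `iso_fragment_hits` list, as for [query_by_core()].
#' @export
query_by_properties <- function(db, bounds) {
  stopifnot(inherits(db, "iso_pairdb"))
  legal <- c("n_heavy", "n_donor", "n_acceptor", "n_ring_atoms",
             "n_core", "n_join")
  if (!all(names(bounds) %in% legal))
    stop("unknown descriptor(s): ",
         paste(setdiff(names(bounds), legal), collapse = ", "),
         call. = FALSE)
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    if (length(b) != 2L || b[1] > b[2])
      stop("bounds for ", nm, " must be c(min, max) with min <= max",
           call. = FALSE)
  }
  groups <- db_distinct_query_fragments(db)
  frags <- list(); ids <- list()
  for (grp in groups) {
    f <- db$records[[grp[1]]]$query_fragment
    d <- describe_fragment(f)
    ok <- all(vapply(names(bounds), function(nm)
      d[[nm]] >= bounds[[nm]][1] && d[[nm]] <= bounds[[nm]][2],
      logical(1)))
    if (ok) {
      frags[[length(frags) + 1L]] <- f
      ids[[length(ids) + 1L]] <- grp
    }
  }
  structure(list(fragments = frags, record_ids = ids),
            class = "iso_fragment_hits")
}

#' Search the database for replacements of a fragment
#'
#' In specific-structure mode the query fragment must match a record's
#' query side exactly, join atoms included (join types compared under
#' Rule 1 per `opts$interchangeable_join_types`); a join atom must be
#' selected when the fragment has more than one. In common-core mode
#' (Rules 3+4) any record whose query core is isomorphic to the fragment's
#' core matches; results are reduced to their core structure, and the
#' selected join atom (if given) is remapped onto the replacement by
#' nearest matched core position.
#'
#' Rows are filtered by the family option (records with unspecified
#' families count as inter-family) and the Overall HD cutoff, sorted by
#' the active HD key with a deterministic tie-break, and paginated.
#'
#' @param frag The query `iso_frag`.
#' @param db An `iso_pairdb`.
#' @param opts An [query_options()] list.
#' @param selected_join Row index (in `frag$atoms`) of the join atom that
#'   will carry the reconnection; may be `NULL` for single-join fragments
#'   or common-core queries.
#' @return Object of class `iso_results`: `table` (one row per result with
#'   HDs, family relation, provenance and page number) and `rows` (the
#'   full per-result detail, including the replacement fragment).
#' @export
find_replacements <- function(frag, db, opts = query_options(),
                              selected_join = NULL) {
  stopifnot(inherits(frag, "iso_frag"), inherits(db, "iso_pairdb"),
            inherits(opts, "iso_query_options"))
  joins <- which(frag$atoms$is_join)
  if (!opts$common_core_query) {
    if (length(joins) == 0L)
      stop("specific-structure queries need a fragment with at least one ",
           "join atom; use a common-core query instead", call. = FALSE)
    if (is.null(selected_join)) {
      if (length(joins) > 1L)
        stop("fragment has ", length(joins), " join atoms; select the one ",
             "to reconnect through (selected_join)", call. = FALSE)
      selected_join <- joins
    }
  }
  if (!is.null(selected_join) && !(selected_join %in% joins))
    stop("selected_join must index a join atom of the fragment",
         call. = FALSE)

  fkey <- core_key(frag)
  keys <- db_qkeys(db)
  hits <- list()
  for (i in which(keys == fkey)) {
    r <- db$records[[i]]
    ok <- if (opts$common_core_query) same_core(r$query_fragment, frag)
          else fragment_matches(r$query_fragment, frag,
                                opts$interchangeable_join_types)
    if (!ok) next
    if (r$hd_overall > opts$hd_cutoff) next
    fam_ok <- switch(opts$family,
      both = TRUE,
      intra = r$family_relation == "intra",
      inter = r$family_relation %in% c("inter", "unknown"))
    if (!fam_ok) next
    hits[[length(hits) + 1L]] <- list(record = r, record_id = i)
  }
  if (length(hits) == 0L) {
    return(structure(list(table = data.frame(), rows = list(),
                          options = opts), class = "iso_results"))
  }

  rows <- lapply(hits, function(h) {
    r <- h$record
    repl <- r$partner_fragment
    remap <- NULL
    if (opts$common_core_query) {
      repl <- reduce_to_core(repl)
      if (!is.null(selected_join))
        remap <- remap_join_atom(frag, selected_join, r)
      if (!is.null(remap)) repl <- remap$fragment
    }
    list(record_id = h$record_id,
         query_fragment = r$query_fragment,
         replacement = repl,
         hd_overall = r$hd_overall, hd_core = r$hd_core,
         hd_hbond = r$hd_hbond,
         join_correspondences = if (opts$common_core_query)
           data.frame() else r$join_correspondences,
         family_relation = r$family_relation,
         source = r$source)
  })

  key <- vapply(rows, function(r) switch(opts$sort_key,
    overall = r$hd_overall, core = r$hd_core,
    hbond = if (is.na(r$hd_hbond)) Inf else r$hd_hbond), numeric(1))
  tie <- vapply(rows, function(r)
    paste(r$source$complex_a, r$source$complex_b,
          core_key(r$replacement)), character(1))
  ord <- order(if (opts$sort_order == "asc") key else -key, tie)
  rows <- rows[ord]

  tab <- data.frame(
    rank = seq_along(rows),
    hd_overall = vapply(rows, `[[`, numeric(1), "hd_overall"),
    hd_core = vapply(rows, `[[`, numeric(1), "hd_core"),
    hd_hbond = vapply(rows, `[[`, numeric(1), "hd_hbond"),
    family_relation = vapply(rows, `[[`, character(1), "family_relation"),
    complex_a = vapply(rows, function(r) r$source$complex_a, character(1)),
    complex_b = vapply(rows, function(r) r$source$complex_b, character(1)),
    stringsAsFactors = FALSE)
  tab$page <- ceiling(seq_along(rows) / opts$page_size)
  structure(list(table = tab, rows = rows, options = opts),
            class = "iso_results")
}

#' @export
print.iso_results <- function(x, ...) {
  cat(sprintf("<iso_results> %d rows in %d page(s)\n", nrow(x$table),
              if (nrow(x$table)) max(x$table$page) else 0L))
  if (nrow(x$table)) print(utils::head(x$table, 10L))
  invisible(x)
}

#' One page of a result set
#' @param results An `iso_results` object.
#' @param page Page number (1-based).
#' @return The subset `iso_results` for that page.
#' @export
result_page <- function(results, page = 1L) {
  sel <- which(results$table$page == page)
  structure(list(table = results$table[sel, , drop = FALSE],
                 rows = results$rows[sel], options = results$options),
            class = "iso_results")
}

# strip join atoms from a fragment (Rule 3 reduction of displayed results)
reduce_to_core <- function(frag) {
  core <- which(!frag$atoms$is_join)
  atoms <- frag$atoms[core, , drop = FALSE]
  rownames(atoms) <- NULL
  b <- frag$bonds[frag$bonds$i %in% core & frag$bonds$j %in% core, ,
                  drop = FALSE]
  structure(list(atoms = atoms,
                 bonds = data.frame(i = match(b$i, core),
                                    j = match(b$j, core),
                                    order = b$order, in_ring = b$in_ring),
                 parent = frag$parent,
                 broken = frag$broken[0, , drop = FALSE]),
            class = "iso_frag")
}

# Rule 4: map the selected query join atom onto the replacement core.
# The query fragment's core is matched onto the record's query core (they
# are isomorphic); the core atom carrying the selected join maps to a
# position in the record frame; the replacement core atom nearest to that
# position receives a new join atom of the selected join's type.
remap_join_atom <- function(frag, selected_join, record) {
  anchor_row <- frag$bonds$i[frag$bonds$j == selected_join]
  if (length(anchor_row) == 0L)
    anchor_row <- frag$bonds$j[frag$bonds$i == selected_join]
  if (length(anchor_row) == 0L) return(NULL)
  core_rows <- which(!frag$atoms$is_join)
  g1 <- core_graph(frag); g2 <- core_graph(record$query_fragment)
  gs <- color_pair(g1, g2)
  mp <- igraph::isomorphisms(gs[[1]], gs[[2]], method = "vf2")
  if (length(mp) == 0L) return(NULL)
  map <- as.integer(mp[[1]])
  rec_core_rows <- which(!record$query_fragment$atoms$is_join)
  anchor_pos_idx <- rec_core_rows[map[match(anchor_row, core_rows)]]
  p <- unlist(record$query_fragment$atoms[anchor_pos_idx,
                                          c("x", "y", "z")])
  repl <- reduce_to_core(record$partner_fragment)
  rc <- as.matrix(repl$atoms[, c("x", "y", "z"), drop = FALSE])
  tgt <- which.min(rowSums(sweep(rc, 2L, p)^2))
  # new join atom: copy of the selected join's identity, placed one bond
  # length out from the target core atom, away from the core centroid
  dirv <- rc[tgt, ] - colMeans(rc)
  if (sqrt(sum(dirv^2)) < 1e-9) dirv <- c(1, 0, 0)
  dirv <- dirv / sqrt(sum(dirv^2))
  ja <- frag$atoms[selected_join, , drop = FALSE]
  ja$x <- rc[tgt, 1] + 1.5 * dirv[1]
  ja$y <- rc[tgt, 2] + 1.5 * dirv[2]
  ja$z <- rc[tgt, 3] + 1.5 * dirv[3]
  ja$is_join <- TRUE
  ja$orig <- NA_integer_
  atoms <- rbind(repl$atoms, ja[, names(repl$atoms), drop = FALSE])
  bonds <- rbind(repl$bonds,
                 data.frame(i = tgt, j = nrow(atoms), order = "1",
                            in_ring = FALSE))
  frag_out <- structure(list(atoms = atoms, bonds = bonds,
                             parent = repl$parent,
                             broken = data.frame(core = tgt,
                                                 partner = NA_integer_)),
                        class = "iso_frag")
  list(fragment = frag_out, target_core_atom = tgt)
}
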