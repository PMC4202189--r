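#' Assign unique edge ids across a pathway collection
#'
#' Every distinct canonical gene pair appearing in any pathway receives
#' exactly one integer edge id. Ids are consecutive from 1 and assigned in
#' byte-lexicographic order of the canonical pairs, so the catalog is a
#' deterministic bijection independent of pathway input order.
#'
#' @param edge_lists List of `gene_edge_list` objects
#'   ([interpolate_gene_edges()], [read_pathway_collection()]).
#' @return List with `catalog` (class `edge_catalog`: data.frame
#'   `pairs(edge_id, gene_a, gene_b)` plus a pair-to-id lookup) and
#'   `pathways`, a list of `pathway_edge_set` objects (`pathway_id`, `name`,
#'   `source`, sorted integer `edge_ids`), ordered by pathway id. Pathways
#'   with no gene-gene edges are excluded with a warning.
#' @export
build_edge_catalog <- function(edge_lists) {
  empty <- vapply(edge_lists, function(e) nrow(e$pairs) == 0L, logical(1))
  if (any(empty)) {
    for (e in edge_lists[empty]) {
      warning(sprintf("pathway '%s' has no gene-gene edges and is excluded",
                      e$pathway_id), call. = FALSE)
    }
    edge_lists <- edge_lists[!empty]
  }
  all_a <- as.character(unlist(lapply(edge_lists, function(e) e$pairs$gene_a),
                               use.names = FALSE))
  all_b <- as.character(unlist(lapply(edge_lists, function(e) e$pairs$gene_b),
                               use.names = FALSE))
  key <- pair_key(all_a, all_b)
  first <- !duplicated(key)
  ord <- order(all_a[first], all_b[first], method = "radix")
  pairs <- data.frame(edge_id = seq_len(sum(first)),
                      gene_a = all_a[first][ord],
                      gene_b = all_b[first][ord],
                      stringsAsFactors = FALSE)
  lookup <- stats::setNames(pairs$edge_id, pair_key(pairs$gene_a, pairs$gene_b))
  catalog <- structure(list(pairs = pairs, lookup = lookup),
                       class = "edge_catalog")
  pw <- lapply(edge_lists, function(e) {
    ids <- unname(lookup[pair_key(e$pairs$gene_a, e$pairs$gene_b)])
    structure(list(pathway_id = e$pathway_id,
                   name = e$name %||% "",
                   source = e$source %||% "",
                   edge_ids = sort(ids)),
              class = "pathway_edge_set")
  })
  pw <- pw[order(vapply(pw, `[[`, character(1), "pathway_id"), method = "radix")]
  list(catalog = catalog, pathways = pw)
}

#' @export
print.edge_catalog <- function(x, ...) {
  cat(sprintf("Edge catalog: %d unique gene-gene edges over %d genes\n",
              nrow(x$pairs), length(unique(c(x$pairs$gene_a, x$pairs$gene_b)))))
  invisible(x)
}

# id -> canonical pair decode, with lookup error on unknown ids
catalog_decode <- function(catalog, edge_ids) {
  i <- match(edge_ids, catalog$pairs$edge_id)
  if (anyNA(i)) {
    stop_integrity("unknown edge_id: ", paste(edge_ids[is.na(i)], collapse = ", "))
  }
  catalog$pairs[i, c("gene_a", "gene_b"), drop = FALSE]
}

#' Build the edges-by-pathways bipartite incidence
#'
#' The two maps are transposes of one another: an edge is linked to exactly
#' the pathways whose edge set contains it.
#'
#' @param pathways List of `pathway_edge_set` objects
#'   (from [build_edge_catalog()]).
#' @return Object of class `bipartite_incidence`: `pathway_ids` (sorted),
#'   `pathway_to_edges` (named list of sorted integer vectors) and
#'   `edge_to_pathways` (named by edge id, sorted character vectors).
#' @export
build_incidence <- function(pathways) {
  if (length(pathways) == 0L) stop_input("empty pathway list")
  pids <- vapply(pathways, `[[`, character(1), "pathway_id")
  if (anyDuplicated(pids)) {
    stop_input("duplicate pathway_id '", pids[duplicated(pids)][1L], "'")
  }
  ord <- order(pids, method = "radix")
  pathways <- pathways[ord]
  pids <- pids[ord]
  p2e <- stats::setNames(lapply(pathways, function(p) sort(p$edge_ids)), pids)
  eid <- unlist(p2e, use.names = FALSE)
  epid <- rep(pids, lengths(p2e))
  sp <- split(epid, eid)
  e2p <- lapply(sp, sort_byte)
  structure(list(pathway_ids = pids,
                 pathway_to_edges = p2e,
                 edge_to_pathways = e2p),
            class = "bipartite_incidence")
}

#' @export
print.bipartite_incidence <- function(x, ...) {
  cat(sprintf("Bipartite incidence: %d edges x %d pathways\n",
              length(x$edge_to_pathways), length(x$pathway_ids)))
  invisible(x)
}

#' Enumerate all maximal bicliques of an incidence structure
#'
#' A biclique is a pair (edge set E, pathway set P) with every edge of E
#' present in every pathway of P; it is maximal when no further edge lies in
#' all of P and no further pathway contains all of E. The full set of
#' maximal bicliques is computed by closure-based (formal-concept style)
#' enumeration on the pathway side: the family of pathway sets obtained as
#' intersections of the per-edge pathway memberships is exactly the family
#' of closed pathway sets, and each closed set P pairs with
#' E = all edges contained in every pathway of P.
#'
#' @param incidence A `bipartite_incidence`.
#' @param min_pathways Keep bicliques spanning at least this many pathways.
#'   Default 2: a shared component involves more than one pathway.
#' @param min_edges Keep bicliques with at least this many edges (default 1).
#' @return Object of class `biclique_set`: a list of bicliques, each a list
#'   with sorted `edge_ids` (integer) and `pathway_ids` (character), sorted
#'   by (number of pathways desc, number of edges desc, pathway ids) and
#'   numbered `biclique_id` 1..k in that order.
#' @examples
#' pw <- list(
#'   structure(list(pathway_id = "P1", name = "", source = "",
#'                  edge_ids = c(1L, 2L, 3L)), class = "pathway_edge_set"),
#'   structure(list(pathway_id = "P2", name = "", source = "",
#'                  edge_ids = c(1L, 2L)), class = "pathway_edge_set"),
#'   structure(list(pathway_id = "P3", name = "", source = "",
#'                  edge_ids = c(1L, 4L)), class = "pathway_edge_set"))
#' bc <- enumerate_maximal_bicliques(build_incidence(pw), min_pathways = 2)
#' length(bc)  # 2: ({1}, {P1,P2,P3}) and ({1,2}, {P1,P2})
#' @export
enumerate_maximal_bicliques <- function(incidence, min_pathways = 2L,
                                        min_edges = 1L) {
  stopifnot(min_pathways >= 1L, min_edges >= 1L)
  e2p <- incidence$edge_to_pathways
  if (length(e2p) == 0L) return(new_biclique_set(list()))
  edge_ids <- as.integer(names(e2p))
  # group edges sharing the same pathway membership; work on pathway indices
  pids <- incidence$pathway_ids
  psets <- lapply(e2p, function(p) match(p, pids))
  gkey <- vapply(psets, set_key, character(1))
  grp <- match(gkey, unique(gkey))
  gsets <- psets[!duplicated(gkey)]
  gedges <- split(edge_ids, grp)  # group index -> member edge ids

  # incremental intersection closure over the distinct membership sets
  closed <- list()
  have <- new.env(hash = TRUE, parent = emptyenv())
  add <- function(s) {
    k <- set_key(s)
    if (length(s) > 0L && is.null(have[[k]])) {
      have[[k]] <- TRUE
      closed[[length(closed) + 1L]] <<- s
    }
  }
  for (s in gsets) {
    for (c in closed) add(intersect_sorted(c, s))
    add(s)
  }

  out <- list()
  for (P in closed) {
    if (length(P) < min_pathways) next
    in_all <- vapply(gsets, function(s) is_subset(P, s), logical(1))
    E <- sort(unlist(gedges[in_all], use.names = FALSE))
    if (length(E) >= min_edges) {
      out[[length(out) + 1L]] <- list(edge_ids = E, pathway_ids = pids[P])
    }
  }
  new_biclique_set(out)
}

new_biclique_set <- function(bicliques) {
  if (length(bicliques) > 0L) {
    np <- vapply(bicliques, function(b) length(b$pathway_ids), integer(1))
    ne <- vapply(bicliques, function(b) length(b$edge_ids), integer(1))
    pkey <- vapply(bicliques, function(b) set_key(b$pathway_ids), character(1))
    ord <- order(-np, -ne, pkey, method = "radix")
    bicliques <- bicliques[ord]
    for (i in seq_along(bicliques)) bicliques[[i]]$biclique_id <- i
  }
  structure(bicliques, class = "biclique_set")
}

#' @export
print.biclique_set <- function(x, n = 10L, ...) {
  cat(sprintf("Maximal biclique set: %d biclique(s)\n", length(x)))
  for (b in utils::head(x, n)) {
    cat(sprintf("  B%d: %d edge(s) shared by %d pathway(s) [%s]\n",
                b$biclique_id, length(b$edge_ids), length(b$pathway_ids),
                paste(utils::head(b$pathway_ids, 6L), collapse = ", ")))
  }
  if (length(x) > n) cat(sprintf("  ... and %d more\n", length(x) - n))
  invisible(x)
}

#' Brute-force maximal biclique enumeration (test oracle)
#'
#' Enumerates every nonempty subset of pathways, intersects their edge
#' sets, closes each candidate on the pathway side and deduplicates. Result
#' is the complete maximal biclique set by construction; cost is 2^p, so
#' the function refuses more than 15 pathways. Intended as the independent
#' correctness oracle for [enumerate_maximal_bicliques()].
#'
#' @inheritParams enumerate_maximal_bicliques
#' @return A `biclique_set`, sorted identically to the fast path.
#' @export
oracle_enumerate_bicliques <- function(incidence, min_pathways = 2L,
                                       min_edges = 1L) {
  p <- length(incidence$pathway_ids)
  if (p > 15L) stop_input("oracle refuses more than 15 pathways (got ", p, ")")
  p2e <- incidence$pathway_to_edges
  pids <- incidence$pathway_ids
  seen <- new.env(hash = TRUE, parent = emptyenv())
  out <- list()
  for (mask in seq_len(2^p - 1L)) {
    S <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
    E <- Reduce(intersect_sorted, p2e[S])
    if (length(E) == 0L) next
    Pfull <- pids[vapply(p2e, function(es) is_subset(E, es), logical(1))]
    if (length(Pfull) < min_pathways || length(E) < min_edges) next
    k <- set_key(Pfull)
    if (is.null(seen[[k]])) {
      seen[[k]] <- TRUE
      out[[length(out) + 1L]] <- list(edge_ids = E, pathway_ids = Pfull)
    }
  }
  new_biclique_set(out)
}
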