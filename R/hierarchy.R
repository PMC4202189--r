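#' Arrange maximal bicliques into a hierarchical similarity graph
#'
#' Bicliques are partially ordered by strict containment of their pathway
#' sets; by biclique maximality this is equivalent to the reverse strict
#' containment of their edge sets, so moving down the hierarchy trades
#' breadth of sharing for size of the shared subgraph. Arcs are the Hasse
#' diagram (transitive reduction) of that order; the roots are the
#' bicliques shared by the most pathways (the top nodes of aggregation),
#' and levels are longest-path depths so a node is always drawn strictly
#' below everything that contains its pathway set.
#'
#' @param bicliques A `biclique_set` (or plain list of bicliques with
#'   `edge_ids` and `pathway_ids`).
#' @return Object of class `hierarchy_graph`: list with `nodes` (the
#'   bicliques, re-sorted deterministically and numbered), `arcs` (integer
#'   matrix, columns `parent`, `child`), `levels` (integer vector, root
#'   depth 0) and `roots` (integer ids).
#' @export
build_hierarchy <- function(bicliques) {
  bicliques <- new_biclique_set(unclass(bicliques))
  n <- length(bicliques)
  if (n == 0L) {
    return(structure(list(nodes = list(), node_ids = integer(0),
                          arcs = matrix(integer(0), ncol = 2L,
                                        dimnames = list(NULL, c("parent", "child"))),
                          levels = integer(0), roots = integer(0)),
                     class = "hierarchy_graph"))
  }
  psets <- lapply(bicliques, `[[`, "pathway_ids")
  # strict containment: pathways(i) superset of pathways(j), i != j
  contains <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j &&
        length(psets[[i]]) > length(psets[[j]]) &&
        is_subset(psets[[j]], psets[[i]])) {
      contains[i, j] <- TRUE
    }
  }
  # Hasse: drop arcs implied through an intermediate node
  hasse <- contains
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (hasse[i, j] && any(contains[i, ] & contains[, j])) hasse[i, j] <- FALSE
  }
  arcs <- which(hasse, arr.ind = TRUE)
  arcs <- arcs[order(arcs[, 1L], arcs[, 2L]), , drop = FALSE]
  dimnames(arcs) <- list(NULL, c("parent", "child"))
  roots <- which(colSums(contains) == 0L)
  levels <- longest_path_levels(n, arcs, roots)
  structure(list(nodes = unclass(bicliques),
                 node_ids = seq_len(n),
                 arcs = arcs,
                 levels = stats::setNames(levels, seq_len(n)),
                 roots = roots),
            class = "hierarchy_graph")
}

# longest-path depth from the given roots over Hasse arcs (DAG)
longest_path_levels <- function(n, arcs, roots, start_level = 0L) {
  levels <- rep(NA_integer_, n)
  levels[roots] <- start_level
  indeg <- tabulate(arcs[, "child"], nbins = n)
  queue <- roots[order(roots)]
  while (length(queue) > 0L) {
    v <- queue[1L]
    queue <- queue[-1L]
    ch <- arcs[arcs[, "parent"] == v, "child"]
    for (c in ch) {
      lv <- levels[v] + 1L
      if (is.na(levels[c]) || lv > levels[c]) levels[c] <- lv
      indeg[c] <- indeg[c] - 1L
      if (indeg[c] == 0L) queue <- c(queue, c)
    }
  }
  levels
}

#' @export
print.hierarchy_graph <- function(x, ...) {
  cat(sprintf("Hierarchy graph: %d node(s), %d arc(s), %d root(s), depth %s\n",
              length(x$nodes), nrow(x$arcs), length(x$roots),
              if (length(x$levels)) max(x$levels) else 0L))
  invisible(x)
}

#' Extract the sub-hierarchy below a node
#'
#' Induces the hierarchy on a node and all of its descendants, with levels
#' recomputed from the new root (depth 0).
#'
#' @param h A `hierarchy_graph`.
#' @param root_id Biclique id of the new root.
#' @return A `hierarchy_graph` over the descendants; node ids keep their
#'   original numbering.
#' @export
subhierarchy <- function(h, root_id) {
  if (!root_id %in% h$node_ids) {
    stop_input("unknown biclique id: ", root_id)
  }
  keep <- descendants(h, root_id, include_self = TRUE)
  arcs <- h$arcs[h$arcs[, "parent"] %in% keep & h$arcs[, "child"] %in% keep, ,
                 drop = FALSE]
  levels <- longest_path_levels(max(h$node_ids), arcs, root_id)
  structure(list(nodes = h$nodes[match(keep, h$node_ids)],
                 node_ids = keep,
                 arcs = arcs,
                 levels = stats::setNames(levels[keep], keep),
                 roots = root_id),
            class = "hierarchy_graph")
}

# integer ids of descendants by BFS over arcs
descendants <- function(h, root_id, include_self = FALSE) {
  seen <- root_id
  frontier <- root_id
  while (length(frontier) > 0L) {
    nxt <- h$arcs[h$arcs[, "parent"] %in% frontier, "child"]
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  ids <- sort(seen)
  if (!include_self) ids <- setdiff(ids, root_id)
  ids
}

# relative depth (longest path) of every descendant below root_id
relative_depths <- function(h, root_id) {
  keep <- descendants(h, root_id, include_self = TRUE)
  arcs <- h$arcs[h$arcs[, "parent"] %in% keep & h$arcs[, "child"] %in% keep, ,
                 drop = FALSE]
  lv <- longest_path_levels(max(h$node_ids), arcs, root_id)
  stats::setNames(lv[keep], keep)
}

# node payload by biclique id
hnode <- function(h, id) h$nodes[[match(id, h$node_ids)]]

#' View the hierarchy as nested pathway groups
#'
#' Relabels each hierarchy node by its pathway set, giving the companion
#' view of how the original pathways nest: an arc points from a broader
#' pathway group to a strictly contained one.
#'
#' @param h A `hierarchy_graph`.
#' @return Object of class `pathway_view`: `groups` (list, one character
#'   vector of pathway ids per node, named by biclique id) and `arcs`
#'   (the hierarchy's arcs).
#' @export
pathway_view <- function(h) {
  ids <- vapply(h$nodes, function(b) b$biclique_id, integer(1L))
  groups <- stats::setNames(lapply(h$nodes, `[[`, "pathway_ids"), ids)
  structure(list(groups = groups, arcs = h$arcs), class = "pathway_view")
}

#' @export
print.pathway_view <- function(x, ...) {
  cat(sprintf("Pathway group view: %d group(s)\n", length(x$groups)))
  for (i in seq_len(nrow(x$arcs))) {
    p <- x$groups[[as.character(x$arcs[i, "parent"])]]
    c <- x$groups[[as.character(x$arcs[i, "child"])]]
    cat(sprintf("  {%s} -> {%s}\n", paste(p, collapse = ","),
                paste(c, collapse = ",")))
  }
  invisible(x)
}
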