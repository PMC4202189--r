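#' Decode edge ids into a gene graph
#'
#' @param edge_ids Integer edge ids, all present in the catalog.
#' @param catalog An `edge_catalog`.
#' @return List with `nodes` (sorted gene ids) and `edges` (data.frame of
#'   canonical `gene_a`, `gene_b`, plus `edge_id`).
#' @export
edges_to_graph <- function(edge_ids, catalog) {
  edge_ids <- sort(unique(as.integer(edge_ids)))
  pr <- catalog_decode(catalog, edge_ids)
  list(nodes = sort_byte(unique(c(pr$gene_a, pr$gene_b))),
       edges = data.frame(gene_a = pr$gene_a, gene_b = pr$gene_b,
                          edge_id = edge_ids, stringsAsFactors = FALSE))
}

#' Connected components by breadth-first search
#'
#' Finds one component at a time by running a breadth-first search from
#' each node not reached by a previous search, over an adjacency-list
#' representation; total work is linear in nodes plus edges. The resulting
#' partition does not depend on visit order.
#'
#' @param nodes Character vector of node ids (isolated nodes allowed).
#' @param edges data.frame with columns `gene_a`, `gene_b` referencing
#'   `nodes`.
#' @return List of character vectors, one sorted vector per component;
#'   components ordered by decreasing size, ties by smallest member id.
#' @export
graph_components <- function(nodes, edges) {
  nodes <- sort_byte(unique(nodes))
  n <- length(nodes)
  if (n == 0L) return(list())
  if (!all(edges$gene_a %in% nodes) || !all(edges$gene_b %in% nodes)) {
    stop_input("edges reference unknown nodes")
  }
  adj <- adjacency_index(nodes, edges$gene_a, edges$gene_b)
  comp <- integer(n)
  ncomp <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    ncomp <- ncomp + 1L
    comp[s] <- ncomp
    frontier <- s
    while (length(frontier) > 0L) {
      nbr <- unique(unlist(adj[frontier], use.names = FALSE))
      nbr <- nbr[comp[nbr] == 0L]
      comp[nbr] <- ncomp
      frontier <- nbr
    }
  }
  parts <- split(nodes, comp)
  parts <- lapply(parts, sort_byte)
  first <- vapply(parts, `[`, character(1), 1L)
  parts <- parts[order(-lengths(parts), first, method = "radix")]
  unname(parts)
}

#' Select the largest connected component
#'
#' @param partition Nonempty list of components ([graph_components()]).
#' @return The component with the most nodes; ties broken by the
#'   lexicographically smallest member node id.
#' @export
largest_component <- function(partition) {
  if (length(partition) == 0L) stop_input("empty partition")
  sizes <- lengths(partition)
  cand <- which(sizes == max(sizes))
  first <- vapply(partition[cand], `[`, character(1), 1L)
  partition[[cand[order(first, method = "radix")[1L]]]]
}

#' Augment a root biclique with edges from two levels below
#'
#' Before the largest connected component of a root (top) graph is
#' computed, the edges of every hierarchy node within two levels below the
#' root are added, so the root graph carries the interpolated context of
#' its immediate refinements.
#'
#' @param h A `hierarchy_graph`.
#' @param root_id Id of a root node of `h`.
#' @param catalog An `edge_catalog` for decoding.
#' @return List with `edge_ids` (the union), `nodes` and `edges` as in
#'   [edges_to_graph()].
#' @export
augment_root <- function(h, root_id, catalog) {
  if (!root_id %in% h$node_ids) stop_input("unknown biclique id: ", root_id)
  if (!root_id %in% h$roots) stop_input("node ", root_id, " is not a root")
  depth <- relative_depths(h, root_id)
  take <- as.integer(names(depth)[depth <= 2L])
  ids <- sort(unique(unlist(lapply(take, function(i) hnode(h, i)$edge_ids))))
  c(list(edge_ids = ids), edges_to_graph(ids, catalog))
}

#' Materialize component graphs for every hierarchy node
#'
#' Builds each biclique's gene graph from its edges, partitions it into
#' connected components and selects the largest. Root graphs are first
#' augmented with the edges of nodes up to two levels below
#' ([augment_root()]), and their largest component is computed on the
#' augmented graph.
#'
#' @param h A `hierarchy_graph`.
#' @param catalog An `edge_catalog`.
#' @param augment_roots Apply root augmentation (default TRUE).
#' @return Named list (by biclique id) of `component_graph` objects: lists
#'   with `biclique_id`, `level`, `nodes`, `edges`, `components`, `lcc`
#'   (node set) and `lcc_edges` (induced edges).
#' @export
build_component_graphs <- function(h, catalog, augment_roots = TRUE) {
  out <- stats::setNames(vector("list", length(h$node_ids)),
                         as.character(h$node_ids))
  for (id in h$node_ids) {
    node <- hnode(h, id)
    if (augment_roots && id %in% h$roots) {
      g <- augment_root(h, id, catalog)
    } else {
      g <- edges_to_graph(node$edge_ids, catalog)
    }
    parts <- graph_components(g$nodes, g$edges)
    lcc <- largest_component(parts)
    in_lcc <- g$edges$gene_a %in% lcc & g$edges$gene_b %in% lcc
    out[[as.character(id)]] <- structure(
      list(biclique_id = id,
           level = unname(h$levels[as.character(id)]),
           nodes = g$nodes, edges = g$edges,
           components = parts, lcc = lcc,
           lcc_edges = g$edges[in_lcc, , drop = FALSE]),
      class = "component_graph")
  }
  out
}

#' Color genes by their highest hierarchical membership
#'
#' Every gene appearing in at least one largest connected component is
#' assigned the hierarchy node of minimum level whose largest component
#' contains it (level ties broken by smallest biclique id), and a color
#' index drawn deterministically from a fixed 12-color palette cycled by
#' biclique id. Genes outside every largest component stay uncolored.
#'
#' @param h A `hierarchy_graph`.
#' @param component_graphs Output of [build_component_graphs()].
#' @return data.frame `gene`, `biclique_id`, `level`, `color_index`,
#'   sorted by gene id.
#' @export
color_nodes <- function(h, component_graphs) {
  rows <- lapply(component_graphs, function(cg) {
    if (length(cg$lcc) == 0L) return(NULL)
    data.frame(gene = cg$lcc, biclique_id = cg$biclique_id,
               level = cg$level, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df) || nrow(df) == 0L) {
    return(data.frame(gene = character(0), biclique_id = integer(0),
                      level = integer(0), color_index = integer(0),
                      stringsAsFactors = FALSE))
  }
  df <- df[order(df$gene, df$level, df$biclique_id, method = "radix"), ,
           drop = FALSE]
  df <- df[!duplicated(df$gene), , drop = FALSE]
  df$color_index <- color_index_of(df$biclique_id)
  rownames(df) <- NULL
  df
}

color_index_of <- function(biclique_id) ((biclique_id - 1L) %% 12L) + 1L

#' Fixed 12-color palette for biclique coloring
#'
#' @return Character vector of 12 hex colors; bicliques cycle through it by
#'   id ([color_nodes()]).
#' @export
pathbic_palette <- function() {
  c("#8DD3C7", "#FFFFB3", "#BEBADA", "#FB8072", "#80B1D3", "#FDB462",
    "#B3DE69", "#FCCDE5", "#D9D9D9", "#BC80BD", "#CCEBC5", "#FFED6F")
}
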