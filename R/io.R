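# Serialization: TSV/JSON intermediates plus DOT and GraphML exports.
# All writers emit sorted, byte-stable output so that re-running a stage on
# identical input reproduces identical files.

#' Write decomposed gene edge lists as one long TSV
#'
#' Columns `pathway_id`, `gene_a`, `gene_b` (canonical order), rows sorted
#' by pathway then pair.
#'
#' @param edge_lists List of `gene_edge_list` objects.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_edge_lists_tsv <- function(edge_lists, path) {
  rows <- lapply(edge_lists, function(e) {
    if (nrow(e$pairs) == 0L) return(NULL)
    data.frame(pathway_id = e$pathway_id, e$pairs, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(pathway_id = character(0), gene_a = character(0),
                     gene_b = character(0), stringsAsFactors = FALSE)
  }
  df <- df[order(df$pathway_id, df$gene_a, df$gene_b, method = "radix"), ,
           drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a decomposed edge-list TSV back into gene edge lists
#'
#' Accepts the [write_edge_lists_tsv()] format, which doubles as the entry
#' point for pre-decomposed pathway-to-edge collections produced outside
#' the package.
#'
#' @param path TSV with columns `pathway_id`, `gene_a`, `gene_b`.
#' @param manifest Optional manifest data.frame supplying `name`/`source`.
#' @return List of `gene_edge_list` objects, pathway ids in byte order.
#' @export
read_edge_lists_tsv <- function(path, manifest = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          stringsAsFactors = FALSE)
  need <- c("pathway_id", "gene_a", "gene_b")
  if (!all(need %in% names(df))) {
    stop_input("edge-list TSV must have columns: ", paste(need, collapse = ", "))
  }
  cp <- canonical_pairs(df$gene_a, df$gene_b)
  if (any(cp$gene_a == cp$gene_b)) stop_input("edge-list TSV contains self-loops")
  pids <- sort_byte(unique(df$pathway_id))
  lapply(pids, function(p) {
    sel <- df$pathway_id == p
    pr <- cp[sel, , drop = FALSE]
    pr <- pr[!duplicated(pair_key(pr$gene_a, pr$gene_b)), , drop = FALSE]
    nm <- src <- ""
    if (!is.null(manifest)) {
      i <- match(p, manifest$pathway_id)
      if (!is.na(i)) { nm <- manifest$name[i]; src <- manifest$source[i] }
    }
    new_gene_edge_list(p, pr, name = nm, source = src)
  })
}

#' Write / read the edge catalog as JSON
#'
#' The catalog read path verifies integrity: consecutive ids from 1,
#' canonical pair orientation, and bijectivity. A corrupted file raises an
#' integrity error.
#'
#' @param catalog An `edge_catalog`.
#' @param path JSON file.
#' @return `write_catalog_json` returns `path` invisibly;
#'   `read_catalog_json` returns an `edge_catalog`.
#' @export
write_catalog_json <- function(catalog, path) {
  jsonlite::write_json(catalog$pairs, path, dataframe = "columns",
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_catalog_json
#' @export
read_catalog_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!all(c("edge_id", "gene_a", "gene_b") %in% names(obj))) {
    stop_integrity("catalog JSON missing required fields")
  }
  pairs <- data.frame(edge_id = as.integer(obj$edge_id),
                      gene_a = as.character(obj$gene_a),
                      gene_b = as.character(obj$gene_b),
                      stringsAsFactors = FALSE)
  if (nrow(pairs) > 0L) {
    if (!identical(pairs$edge_id, seq_len(nrow(pairs)))) {
      stop_integrity("catalog ids are not consecutive from 1")
    }
    u <- sort(unique(c(pairs$gene_a, pairs$gene_b)), method = "radix")
    if (any(match(pairs$gene_a, u) >= match(pairs$gene_b, u))) {
      stop_integrity("catalog pair not in canonical order")
    }
    if (anyDuplicated(pair_key(pairs$gene_a, pairs$gene_b))) {
      stop_integrity("catalog contains duplicate pairs")
    }
  }
  structure(list(pairs = pairs,
                 lookup = stats::setNames(pairs$edge_id,
                                          pair_key(pairs$gene_a, pairs$gene_b))),
            class = "edge_catalog")
}

#' Write maximal bicliques as JSON and long TSV
#'
#' JSON: array of `{biclique_id, edge_ids, pathway_ids, n_edges,
#' n_pathways}` in hierarchy sort order. TSV: one row per
#' (biclique, edge, pathway) triple.
#'
#' @param bicliques A `biclique_set`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_bicliques_json <- function(bicliques, path) {
  arr <- lapply(unclass(bicliques), function(b) {
    list(biclique_id = jsonlite::unbox(b$biclique_id),
         edge_ids = b$edge_ids,
         pathway_ids = b$pathway_ids,
         n_edges = jsonlite::unbox(length(b$edge_ids)),
         n_pathways = jsonlite::unbox(length(b$pathway_ids)))
  })
  jsonlite::write_json(arr, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_bicliques_json
#' @export
write_bicliques_tsv <- function(bicliques, path) {
  rows <- lapply(unclass(bicliques), function(b) {
    expand.grid(biclique_id = b$biclique_id, edge_id = b$edge_ids,
                pathway_id = b$pathway_ids, stringsAsFactors = FALSE,
                KEEP.OUT.ATTRS = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(biclique_id = integer(0), edge_id = integer(0),
                     pathway_id = character(0), stringsAsFactors = FALSE)
  }
  df <- df[order(df$biclique_id, df$edge_id, df$pathway_id, method = "radix"), ,
           drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read bicliques back from the JSON export
#'
#' @param path JSON produced by [write_bicliques_json()].
#' @return A `biclique_set`.
#' @export
read_bicliques_json <- function(path) {
  arr <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(arr, function(b) {
    list(edge_ids = sort(vapply(b$edge_ids, as.integer, integer(1))),
         pathway_ids = sort_byte(vapply(b$pathway_ids, as.character, character(1))))
  })
  new_biclique_set(out)
}

#' Export the hierarchy as JSON
#'
#' Structure: `{nodes: [{id, edge_ids, pathway_ids, level}], arcs:
#' [[parent, child], ...]}`.
#'
#' @param h A `hierarchy_graph`.
#' @param path JSON file.
#' @return Invisibly, `path`.
#' @export
write_hierarchy_json <- function(h, path) {
  nodes <- lapply(seq_along(h$node_ids), function(i) {
    b <- h$nodes[[i]]
    list(id = jsonlite::unbox(h$node_ids[i]),
         edge_ids = b$edge_ids,
         pathway_ids = b$pathway_ids,
         level = jsonlite::unbox(unname(h$levels[as.character(h$node_ids[i])])))
  })
  arcs <- lapply(seq_len(nrow(h$arcs)),
                 function(i) c(h$arcs[i, "parent"], h$arcs[i, "child"]))
  jsonlite::write_json(list(nodes = nodes, arcs = arcs), path,
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Export the hierarchy as DOT with one rank per level
#'
#' @param h A `hierarchy_graph`.
#' @param path DOT file.
#' @return Invisibly, `path`.
#' @export
write_hierarchy_dot <- function(h, path) {
  pal <- pathbic_palette()
  lines <- c("digraph hierarchy {",
             "  rankdir=TB;",
             "  node [shape=box, style=filled];")
  for (i in seq_along(h$node_ids)) {
    id <- h$node_ids[i]
    b <- h$nodes[[i]]
    lines <- c(lines, sprintf(
      "  n%d [label=\"B%d\\n%d pathways / %d edges\", fillcolor=\"%s\"];",
      id, id, length(b$pathway_ids), length(b$edge_ids),
      pal[color_index_of(id)]))
  }
  if (length(h$levels) > 0L) {
    for (l in sort(unique(unname(h$levels)))) {
      at <- h$node_ids[unname(h$levels[as.character(h$node_ids)]) == l]
      lines <- c(lines, sprintf("  { rank=same; %s }",
                                paste(sprintf("n%d;", at), collapse = " ")))
    }
  }
  for (i in seq_len(nrow(h$arcs))) {
    lines <- c(lines, sprintf("  n%d -> n%d;",
                              h$arcs[i, "parent"], h$arcs[i, "child"]))
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Export the colored shared-component graph
#'
#' The union of every hierarchy node's largest connected component, as
#' GraphML with node attributes `color_index`, `biclique_id`, `level`
#' (null for uncolored genes) and edge attribute `edge_id`, or as DOT with
#' fill colors from the fixed 12-color palette.
#'
#' @param h A `hierarchy_graph`.
#' @param component_graphs Output of [build_component_graphs()].
#' @param colors Output of [color_nodes()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_colored_graphml <- function(h, component_graphs, colors, path) {
  g <- union_lcc_graph(component_graphs)
  i <- match(g$nodes, colors$gene)
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
    "  <key id=\"d0\" for=\"node\" attr.name=\"color_index\" attr.type=\"int\"/>",
    "  <key id=\"d1\" for=\"node\" attr.name=\"biclique_id\" attr.type=\"int\"/>",
    "  <key id=\"d2\" for=\"node\" attr.name=\"level\" attr.type=\"int\"/>",
    "  <key id=\"d3\" for=\"edge\" attr.name=\"edge_id\" attr.type=\"int\"/>",
    "  <graph id=\"shared_components\" edgedefault=\"undirected\">")
  for (k in seq_along(g$nodes)) {
    nd <- xml_escape(g$nodes[k])
    if (is.na(i[k])) {
      lines <- c(lines, sprintf("    <node id=\"%s\"/>", nd))
    } else {
      lines <- c(lines, sprintf(
        "    <node id=\"%s\"><data key=\"d0\">%d</data><data key=\"d1\">%d</data><data key=\"d2\">%d</data></node>",
        nd, colors$color_index[i[k]], colors$biclique_id[i[k]],
        colors$level[i[k]]))
    }
  }
  for (k in seq_len(nrow(g$edges))) {
    lines <- c(lines, sprintf(
      "    <edge source=\"%s\" target=\"%s\"><data key=\"d3\">%d</data></edge>",
      xml_escape(g$edges$gene_a[k]), xml_escape(g$edges$gene_b[k]),
      g$edges$edge_id[k]))
  }
  writeLines(c(lines, "  </graph>", "</graphml>"), path)
  invisible(path)
}

#' @rdname write_colored_graphml
#' @export
write_colored_dot <- function(h, component_graphs, colors, path) {
  g <- union_lcc_graph(component_graphs)
  i <- match(g$nodes, colors$gene)
  pal <- pathbic_palette()
  lines <- c("graph shared_components {",
             "  node [shape=ellipse, style=filled];")
  for (k in seq_along(g$nodes)) {
    fill <- if (is.na(i[k])) "#FFFFFF" else pal[colors$color_index[i[k]]]
    lines <- c(lines, sprintf("  \"%s\" [fillcolor=\"%s\"];",
                              g$nodes[k], fill))
  }
  for (k in seq_len(nrow(g$edges))) {
    lines <- c(lines, sprintf("  \"%s\" -- \"%s\" [label=\"e%d\"];",
                              g$edges$gene_a[k], g$edges$gene_b[k],
                              g$edges$edge_id[k]))
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}

union_lcc_graph <- function(component_graphs) {
  nodes <- sort_byte(unique(unlist(lapply(component_graphs, `[[`, "lcc"),
                                   use.names = FALSE)))
  ed <- do.call(rbind, lapply(component_graphs, `[[`, "lcc_edges"))
  if (is.null(ed)) {
    ed <- data.frame(gene_a = character(0), gene_b = character(0),
                     edge_id = integer(0), stringsAsFactors = FALSE)
  }
  ed <- ed[!duplicated(ed$edge_id), , drop = FALSE]
  ed <- ed[order(ed$edge_id), , drop = FALSE]
  rownames(ed) <- NULL
  list(nodes = nodes, edges = ed)
}
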