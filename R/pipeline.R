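#' Shared-component analysis of a pathway collection
#'
#' End-to-end driver: assigns unique edge ids ([build_edge_catalog()]),
#' builds the edges-by-pathways incidence ([build_incidence()]), enumerates
#' all maximal bicliques ([enumerate_maximal_bicliques()]), arranges them
#' into the hierarchical similarity graph ([build_hierarchy()]), computes
#' per-biclique connected components with root augmentation
#' ([build_component_graphs()]) and colors genes by highest hierarchical
#' membership ([color_nodes()]).
#'
#' @param edge_lists List of `gene_edge_list` objects, e.g. from
#'   [read_pathway_collection()] or [generate_collection()].
#' @param min_pathways,min_edges Biclique size thresholds; defaults 2 and 1.
#' @param augment_roots Augment root graphs with edges from two hierarchy
#'   levels below before computing their largest component (default TRUE).
#' @return Object of class `pathbic`: list with `catalog`, `pathways`,
#'   `incidence`, `bicliques`, `hierarchy`, `components`, `colors` and
#'   `params`.
#' @examples
#' col <- generate_collection(default_synth_spec(seed = 1))
#' fit <- pathbic(col$edge_lists)
#' fit
#' summary(fit)
#' @export
pathbic <- function(edge_lists, min_pathways = 2L, min_edges = 1L,
                    augment_roots = TRUE) {
  built <- build_edge_catalog(edge_lists)
  incidence <- build_incidence(built$pathways)
  bicliques <- enumerate_maximal_bicliques(incidence, min_pathways, min_edges)
  hierarchy <- build_hierarchy(bicliques)
  components <- build_component_graphs(hierarchy, built$catalog, augment_roots)
  colors <- color_nodes(hierarchy, components)
  structure(list(catalog = built$catalog,
                 pathways = built$pathways,
                 incidence = incidence,
                 bicliques = hierarchy_bicliques(hierarchy),
                 hierarchy = hierarchy,
                 components = components,
                 colors = colors,
                 params = list(min_pathways = as.integer(min_pathways),
                               min_edges = as.integer(min_edges),
                               augment_roots = augment_roots)),
            class = "pathbic")
}

# biclique_set view of the hierarchy's nodes (same objects, same order)
hierarchy_bicliques <- function(h) structure(h$nodes, class = "biclique_set")

#' @export
print.pathbic <- function(x, ...) {
  cat(sprintf("Shared-component analysis: %d pathways, %d unique gene-gene edges\n",
              length(x$pathways), nrow(x$catalog$pairs)))
  cat(sprintf("  %d maximal biclique(s) (min %d pathways, min %d edges), %d hierarchy root(s)\n",
              length(x$bicliques), x$params$min_pathways, x$params$min_edges,
              length(x$hierarchy$roots)))
  invisible(x)
}

#' @export
summary.pathbic <- function(object, ...) {
  b <- object$bicliques
  df <- if (length(b) == 0L) {
    data.frame(biclique_id = integer(0), level = integer(0),
               n_pathways = integer(0), n_edges = integer(0),
               lcc_size = integer(0), pathways = character(0),
               stringsAsFactors = FALSE)
  } else {
    data.frame(
      biclique_id = vapply(b, `[[`, integer(1), "biclique_id"),
      level = unname(object$hierarchy$levels),
      n_pathways = vapply(b, function(x) length(x$pathway_ids), integer(1)),
      n_edges = vapply(b, function(x) length(x$edge_ids), integer(1)),
      lcc_size = vapply(object$components, function(cg) length(cg$lcc), integer(1)),
      pathways = vapply(b, function(x) paste(x$pathway_ids, collapse = ","),
                        character(1)),
      stringsAsFactors = FALSE)
  }
  structure(list(n_pathways = length(object$pathways),
                 n_genes = length(unique(c(object$catalog$pairs$gene_a,
                                           object$catalog$pairs$gene_b))),
                 n_edges = nrow(object$catalog$pairs),
                 table = df),
            class = "summary.pathbic")
}

#' @export
print.summary.pathbic <- function(x, ...) {
  cat(sprintf("Pathways: %d   Genes: %d   Unique gene-gene edges: %d\n",
              x$n_pathways, x$n_genes, x$n_edges))
  cat("Maximal bicliques (hierarchy order):\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Plot the hierarchical similarity graph
#'
#' Layered drawing of the biclique hierarchy: one row per level, the most
#' widely shared bicliques (roots) on top, arcs showing pathway-set
#' refinement, nodes filled from the fixed biclique palette.
#'
#' @param x A `pathbic` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pathbic <- function(x, ...) {
  h <- x$hierarchy
  n <- length(h$node_ids)
  if (n == 0L) {
    graphics::plot.new()
    graphics::title(main = "No maximal bicliques")
    return(invisible(x))
  }
  lev <- unname(h$levels)
  maxlev <- max(lev)
  xs <- numeric(n)
  for (l in unique(lev)) {
    at <- which(lev == l)
    xs[at] <- seq_along(at) / (length(at) + 1L)
  }
  ys <- 1 - lev / max(1L, maxlev)
  graphics::plot(xs, ys, type = "n", axes = FALSE, xlab = "", ylab = "",
                 xlim = c(0, 1), ylim = c(-0.1, 1.1),
                 main = "Biclique hierarchy", ...)
  if (nrow(h$arcs) > 0L) {
    pi_ <- match(h$arcs[, "parent"], h$node_ids)
    ci <- match(h$arcs[, "child"], h$node_ids)
    graphics::segments(xs[pi_], ys[pi_], xs[ci], ys[ci], col = "grey50")
  }
  pal <- pathbic_palette()
  ids <- vapply(h$nodes, `[[`, integer(1), "biclique_id")
  graphics::points(xs, ys, pch = 21, cex = 3,
                   bg = pal[color_index_of(ids)])
  lab <- sprintf("B%d\n%dp/%de", ids,
                 vapply(h$nodes, function(b) length(b$pathway_ids), integer(1)),
                 vapply(h$nodes, function(b) length(b$edge_ids), integer(1)))
  graphics::text(xs, ys, lab, cex = 0.6, pos = 4, offset = 0.8)
  invisible(x)
}
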