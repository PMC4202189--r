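# Independent oracles and random-instance generators used across the suite.
# Each oracle is a direct transcription of the defining property, kept free
# of the package's own algorithmic shortcuts.

# --- random instances -------------------------------------------------------

# random mixed graph: <= n_nodes nodes, each gene with prob p_gene,
# each unordered pair an edge with prob p_edge
random_mixed_graph <- function(n_nodes, p_edge = 0.3, p_gene = 0.5) {
  ids <- sprintf("n%02d", seq_len(n_nodes))
  is_gene <- stats::runif(n_nodes) < p_gene
  a <- character(0); b <- character(0)
  if (n_nodes >= 2L) {
    cmb <- utils::combn(n_nodes, 2L)
    pick <- stats::runif(ncol(cmb)) < p_edge
    a <- ids[cmb[1L, pick]]
    b <- ids[cmb[2L, pick]]
  }
  structure(list(pathway_id = "rand",
                 nodes = data.frame(node_id = ids, is_gene = is_gene,
                                    stringsAsFactors = FALSE),
                 edges = data.frame(a = a, b = b, stringsAsFactors = FALSE),
                 counts = c(self_loops_dropped = 0L)),
            class = "mixed_graph")
}

# random incidence over <= n_pathways pathways and <= n_edges candidate edges
random_incidence <- function(n_pathways, n_edges, density = 0.3) {
  pes <- list()
  for (p in seq_len(n_pathways)) {
    ids <- which(stats::runif(n_edges) < density)
    if (length(ids) == 0L) ids <- sample.int(n_edges, 1L)
    pes[[p]] <- structure(list(pathway_id = sprintf("P%02d", p),
                               name = "", source = "",
                               edge_ids = sort(ids)),
                          class = "pathway_edge_set")
  }
  build_incidence(pes)
}

make_pes <- function(pathway_id, edge_ids) {
  structure(list(pathway_id = pathway_id, name = "", source = "",
                 edge_ids = sort(as.integer(edge_ids))),
            class = "pathway_edge_set")
}

# small catalog over fabricated gene pairs, one per requested edge id
toy_catalog <- function(n_edges) {
  pairs <- data.frame(gene_a = sprintf("ga%02d", seq_len(n_edges)),
                      gene_b = sprintf("gb%02d", seq_len(n_edges)),
                      stringsAsFactors = FALSE)
  el <- structure(list(pathway_id = "toy", name = "", source = "",
                       pairs = pairs),
                  class = "gene_edge_list")
  build_edge_catalog(list(el))$catalog
}

# --- interpolation oracle ---------------------------------------------------

# all-simple-paths oracle: emit (g1, g2) iff some simple path joins them
# whose interior nodes are all non-gene and number <= max_internal_path
oracle_interpolate <- function(graph, max_internal_path) {
  nodes <- graph$nodes$node_id
  is_gene <- stats::setNames(graph$nodes$is_gene, nodes)
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(graph$edges))) {
    a <- graph$edges$a[i]; b <- graph$edges$b[i]
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  hit <- FALSE
  genes <- nodes[graph$nodes$is_gene]
  dfs <- function(cur, target, interior, visited) {
    for (nb in adj[[cur]]) {
      if (hit) return(invisible(NULL))
      if (nb == target) { hit <<- TRUE; next }
      if (nb %in% visited) next
      if (is_gene[[nb]]) next          # a gene interrupts the path
      if (interior + 1L > max_internal_path) next
      dfs(nb, target, interior + 1L, c(visited, nb))
    }
  }
  res_a <- character(0); res_b <- character(0)
  if (length(genes) >= 2L) {
    for (i in seq_len(length(genes) - 1L)) for (j in (i + 1L):length(genes)) {
      hit <- FALSE
      dfs(genes[i], genes[j], 0L, genes[i])
      if (hit) {
        res_a <- c(res_a, genes[i]); res_b <- c(res_b, genes[j])
      }
    }
  }
  if (length(res_a) == 0L) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      stringsAsFactors = FALSE))
  }
  u <- sort(unique(c(res_a, res_b)), method = "radix")
  swap <- match(res_a, u) > match(res_b, u)
  df <- data.frame(gene_a = ifelse(swap, res_b, res_a),
                   gene_b = ifelse(swap, res_a, res_b),
                   stringsAsFactors = FALSE)
  df[order(df$gene_a, df$gene_b, method = "radix"), , drop = FALSE]
}

pairs_key <- function(df) paste(df$gene_a, df$gene_b, sep = "|")

# --- union-find components oracle -------------------------------------------

union_find_components <- function(nodes, edges) {
  nodes <- sort(unique(nodes), method = "radix")
  parent <- seq_along(nodes)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(nrow(edges))) {
    ra <- find(match(edges$gene_a[i], nodes))
    rb <- find(match(edges$gene_b[i], nodes))
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  parts <- lapply(split(nodes, roots), function(v) sort(v, method = "radix"))
  first <- vapply(parts, `[`, character(1), 1L)
  unname(parts[order(-lengths(parts), first, method = "radix")])
}

random_gene_graph <- function(n_nodes, p_edge = 0.25) {
  ids <- sprintf("v%02d", seq_len(n_nodes))
  a <- character(0); b <- character(0)
  if (n_nodes >= 2L) {
    cmb <- utils::combn(n_nodes, 2L)
    pick <- stats::runif(ncol(cmb)) < p_edge
    a <- ids[cmb[1L, pick]]
    b <- ids[cmb[2L, pick]]
  }
  list(nodes = ids, edges = data.frame(gene_a = a, gene_b = b,
                                       stringsAsFactors = FALSE))
}

# --- biclique set comparison -------------------------------------------------

biclique_keys <- function(bic) {
  vapply(unclass(bic), function(b) {
    paste(paste(b$edge_ids, collapse = ","),
          paste(b$pathway_ids, collapse = ","), sep = " | ")
  }, character(1))
}

expect_same_biclique_sets <- function(a, b) {
  testthat::expect_setequal(biclique_keys(a), biclique_keys(b))
}
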