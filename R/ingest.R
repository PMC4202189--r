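#' Read a SIF-style pathway network file
#'
#' Parses a three-column, tab-separated interaction file
#' (`participant <TAB> interaction_type <TAB> participant`) into a mixed
#' graph of the pathway's nodes and undirected associations. Interaction
#' types are ignored: every line contributes one unordered node pair, so a
#' relation listed in both orientations or under several types collapses to
#' a single edge. Self-referential lines are dropped and counted. All nodes
#' start flagged as genes; [apply_id_mapping()] refines the flags.
#'
#' @param file Path to a SIF file, or a connection. Blank lines and lines
#'   starting with `#` are skipped. Fields are trimmed of surrounding
#'   whitespace; identifier comparison is case-sensitive.
#' @param pathway_id Identifier attached to the resulting graph.
#' @return An object of class `mixed_graph`: a list with `pathway_id`,
#'   `nodes` (data.frame of `node_id`, `is_gene`), `edges` (data.frame of
#'   canonically ordered `a`, `b`), and `counts` (named integer vector,
#'   including `self_loops_dropped`).
#' @examples
#' sif <- textConnection("g1\tinteracts\tg2\ng2\tinteracts\tg1")
#' g <- read_sif(sif, "toy")
#' nrow(g$edges)  # 1: both orientations collapse to one unordered pair
#' @seealso [apply_id_mapping()], [interpolate_gene_edges()]
#' @export
read_sif <- function(file, pathway_id) {
  lines <- readLines(file, warn = FALSE)
  keep <- !grepl("^[ \t]*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(new_mixed_graph(pathway_id, character(), logical(),
                           character(), character(),
                           c(self_loops_dropped = 0L)))
  }
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 3L)) {
    bad <- idx[which(nfield != 3L)[1L]]
    stop_input(sprintf("malformed SIF line %d in pathway '%s': expected 3 tab-separated columns, got %d",
                       bad, pathway_id, nfield[which(nfield != 3L)[1L]]))
  }
  m <- matrix(trim_ws(unlist(parts)), ncol = 3L, byrow = TRUE)
  a <- m[, 1L]
  b <- m[, 3L]
  if (any(a == "" | b == "")) {
    bad <- idx[which(a == "" | b == "")[1L]]
    stop_input(sprintf("malformed SIF line %d in pathway '%s': empty participant identifier",
                       bad, pathway_id))
  }
  self <- a == b
  n_self <- sum(self)
  nodes <- sort_byte(unique(c(a, b)))
  cp <- canonical_pairs(a[!self], b[!self])
  cp <- cp[!duplicated(pair_key(cp$gene_a, cp$gene_b)), , drop = FALSE]
  new_mixed_graph(pathway_id, nodes, rep(TRUE, length(nodes)),
                  cp$gene_a, cp$gene_b,
                  c(self_loops_dropped = n_self))
}

new_mixed_graph <- function(pathway_id, node_ids, is_gene, a, b, counts) {
  ord <- order(a, b, method = "radix")
  structure(list(
    pathway_id = pathway_id,
    nodes = data.frame(node_id = node_ids, is_gene = is_gene,
                       stringsAsFactors = FALSE),
    edges = data.frame(a = a[ord], b = b[ord], stringsAsFactors = FALSE),
    counts = counts
  ), class = "mixed_graph")
}

#' @export
print.mixed_graph <- function(x, ...) {
  cat(sprintf("Mixed pathway graph '%s': %d nodes (%d gene), %d edges\n",
              x$pathway_id, nrow(x$nodes), sum(x$nodes$is_gene), nrow(x$edges)))
  invisible(x)
}

#' Read an identifier mapping table
#'
#' Reads a tab-separated table with header columns `original_id`,
#' `canonical_id`, `is_gene` mapping pathway-file identifiers onto canonical
#' cluster identifiers (one canonical id per original id) with a gene /
#' non-gene flag per canonical node.
#'
#' @param file Path or connection to the TSV.
#' @return A data.frame with columns `original_id`, `canonical_id`
#'   (character) and `is_gene` (logical).
#' @export
read_id_mapping <- function(file) {
  df <- utils::read.delim(file, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("original_id", "canonical_id", "is_gene")
  if (!all(need %in% names(df))) {
    stop_input("mapping table must have columns: ", paste(need, collapse = ", "))
  }
  df <- df[, need]
  df$original_id <- trim_ws(df$original_id)
  df$canonical_id <- trim_ws(df$canonical_id)
  df$is_gene <- tolower(trim_ws(df$is_gene)) %in% c("true", "t", "1", "yes")
  validate_id_mapping(df)
}

validate_id_mapping <- function(df) {
  if (any(df$canonical_id == "")) stop_input("mapping contains empty canonical_id")
  if (anyDuplicated(df$original_id)) {
    stop_input("mapping is not a function: duplicated original_id '",
               df$original_id[duplicated(df$original_id)][1L], "'")
  }
  flag <- tapply(df$is_gene, df$canonical_id, function(v) length(unique(v)))
  if (any(flag > 1L)) {
    stop_input("inconsistent is_gene flag for canonical_id '",
               names(flag)[flag > 1L][1L], "'")
  }
  df
}

#' Harmonize node identifiers in a mixed graph
#'
#' Replaces each node identifier by its canonical cluster identifier and
#' takes the gene / non-gene flag from the mapping. Distinct originals may
#' map to the same canonical node; pairs that collapse onto a single node
#' become self-loops and are dropped with a count. Nodes absent from the
#' mapping are handled by `unmapped_policy`.
#'
#' @param graph A `mixed_graph` from [read_sif()].
#' @param mapping A mapping data.frame as returned by [read_id_mapping()].
#' @param unmapped_policy One of `"drop"` (remove the node and its edges),
#'   `"keep-as-nongene"` (retain under its original id, flagged non-gene) or
#'   `"keep-as-gene"` (retain, flagged gene).
#' @return A `mixed_graph` over canonical identifiers. `counts` gains
#'   `unmapped` (number of unmapped nodes seen) and accumulates
#'   `self_loops_dropped` for pairs collapsed by the mapping.
#' @export
apply_id_mapping <- function(graph, mapping,
                             unmapped_policy = c("drop", "keep-as-nongene", "keep-as-gene")) {
  unmapped_policy <- match.arg(unmapped_policy)
  mapping <- validate_id_mapping(mapping)
  old <- graph$nodes$node_id
  hit <- match(old, mapping$original_id)
  unmapped <- is.na(hit)
  n_unmapped <- sum(unmapped)

  new_id <- ifelse(unmapped, old, mapping$canonical_id[hit])
  new_gene <- ifelse(unmapped,
                     unmapped_policy == "keep-as-gene",
                     mapping$is_gene[hit])
  keep_node <- !(unmapped & unmapped_policy == "drop")

  rename <- stats::setNames(new_id, old)
  a <- unname(rename[graph$edges$a])
  b <- unname(rename[graph$edges$b])
  kept_ids <- new_id[keep_node]
  keep_edge <- graph$edges$a %in% old[keep_node] & graph$edges$b %in% old[keep_node]
  a <- a[keep_edge]; b <- b[keep_edge]
  self <- a == b
  n_self <- sum(self)
  cp <- canonical_pairs(a[!self], b[!self])
  cp <- cp[!duplicated(pair_key(cp$gene_a, cp$gene_b)), , drop = FALSE]

  nd <- data.frame(node_id = kept_ids, is_gene = new_gene[keep_node],
                   stringsAsFactors = FALSE)
  nd <- nd[!duplicated(nd$node_id), , drop = FALSE]
  ord <- order(nd$node_id, method = "radix")
  g <- new_mixed_graph(graph$pathway_id, nd$node_id[ord], nd$is_gene[ord],
                       cp$gene_a, cp$gene_b,
                       c(self_loops_dropped = unname(graph$counts["self_loops_dropped"]) + n_self,
                         unmapped = n_unmapped))
  if (n_unmapped > 0L) {
    pathbic_log("debug", sprintf("pathway '%s': %d unmapped node(s), policy=%s",
                                 graph$pathway_id, n_unmapped, unmapped_policy))
  }
  g
}

#' Contract paths through non-gene nodes into direct gene-gene edges
#'
#' Produces the pathway's discrete gene-to-gene edge list: a pair of genes
#' is emitted when the genes are directly adjacent, or joined by a
#' contiguous uninterrupted path whose internal nodes are all non-gene
#' entities (complexes, small molecules, reactions) and number at most
#' `max_internal_path`. A gene lying on the path interrupts it, so no edge
#' is drawn across an intermediate gene.
#'
#' @param graph A `mixed_graph` with harmonized `is_gene` flags.
#' @param max_internal_path Maximum number of internal non-gene nodes on a
#'   connecting path (0 keeps direct gene-gene edges only). Default 3,
#'   keeping contraction local.
#' @param blacklist Character vector of non-gene node ids never traversed,
#'   e.g. currency metabolites whose hub degree would otherwise contract
#'   unrelated genes together.
#' @return An object of class `gene_edge_list`: list with `pathway_id` and
#'   `pairs`, a data.frame of canonically ordered (`gene_a` < `gene_b` in
#'   byte order) gene pairs.
#' @details Implemented as a breadth-first search from each gene that
#'   expands through admissible non-gene nodes only; a gene reached within
#'   `max_internal_path` internal hops is recorded and not expanded.
#' @export
interpolate_gene_edges <- function(graph, max_internal_path = 3L,
                                   blacklist = character()) {
  stopifnot(max_internal_path >= 0L)
  nodes <- graph$nodes$node_id
  n <- length(nodes)
  is_gene <- graph$nodes$is_gene
  blocked <- nodes %in% blacklist
  adj <- adjacency_index(nodes, graph$edges$a, graph$edges$b)

  res_a <- character(0)
  res_b <- character(0)
  gene_idx <- which(is_gene)
  for (g in gene_idx) {
    # BFS layers; internal node count = edge distance - 1
    seen <- logical(n)
    seen[g] <- TRUE
    frontier <- adj[[g]]
    frontier <- frontier[!seen[frontier]]
    depth <- 0L  # internal nodes used to reach current frontier
    while (length(frontier) > 0L && depth <= max_internal_path) {
      seen[frontier] <- TRUE
      found <- frontier[is_gene[frontier]]
      if (length(found) > 0L) {
        res_a <- c(res_a, rep(nodes[g], length(found)))
        res_b <- c(res_b, nodes[found])
      }
      expand <- frontier[!is_gene[frontier] & !blocked[frontier]]
      if (length(expand) == 0L) break
      nxt <- unique(unlist(adj[expand], use.names = FALSE))
      frontier <- nxt[!seen[nxt]]
      depth <- depth + 1L
    }
  }
  cp <- canonical_pairs(res_a, res_b)
  cp <- cp[!duplicated(pair_key(cp$gene_a, cp$gene_b)), , drop = FALSE]
  new_gene_edge_list(graph$pathway_id, cp)
}

# node-index adjacency list from character edge endpoints
adjacency_index <- function(nodes, a, b) {
  ia <- match(a, nodes)
  ib <- match(b, nodes)
  adj <- vector("list", length(nodes))
  if (length(ia)) {
    sp <- split(c(ib, ia), c(ia, ib))
    adj[as.integer(names(sp))] <- lapply(sp, function(v) sort(unique(v)))
  }
  adj[vapply(adj, is.null, logical(1))] <- list(integer(0))
  adj
}

new_gene_edge_list <- function(pathway_id, pairs, name = "", source = "") {
  ord <- order(pairs$gene_a, pairs$gene_b, method = "radix")
  structure(list(pathway_id = pathway_id,
                 name = name, source = source,
                 pairs = pairs[ord, , drop = FALSE]),
            class = "gene_edge_list")
}

#' @export
print.gene_edge_list <- function(x, ...) {
  cat(sprintf("Gene edge list '%s': %d gene-gene edges\n",
              x$pathway_id, nrow(x$pairs)))
  invisible(x)
}

#' Read a pathway manifest
#'
#' @param file Path to a tab-separated manifest with header columns
#'   `pathway_id`, `name`, `source`, `file_path`.
#' @return data.frame with those four character columns.
#' @export
read_manifest <- function(file) {
  df <- utils::read.delim(file, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("pathway_id", "name", "source", "file_path")
  if (!all(need %in% names(df))) {
    stop_input("manifest must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$pathway_id)) {
    stop_input("manifest contains duplicate pathway_id '",
               df$pathway_id[duplicated(df$pathway_id)][1L], "'")
  }
  df[, need]
}

#' Read and decompose a whole pathway collection
#'
#' Convenience driver over [read_sif()], [apply_id_mapping()] and
#' [interpolate_gene_edges()] for every pathway in a manifest. Pathways are
#' processed and returned in byte order of `pathway_id`, so the result does
#' not depend on manifest row order.
#'
#' @param manifest Manifest path or data.frame ([read_manifest()] format).
#'   Relative `file_path` entries are resolved against the manifest's
#'   directory.
#' @param mapping Optional mapping table (path or data.frame); when `NULL`
#'   every node keeps its original id and counts as a gene.
#' @param unmapped_policy,max_internal_path,blacklist Passed through to
#'   [apply_id_mapping()] and [interpolate_gene_edges()].
#' @return List of `gene_edge_list` objects (one per pathway, manifest
#'   `name`/`source` attached), with attribute `counts`: a data.frame of
#'   per-pathway node/edge/dropped tallies.
#' @export
read_pathway_collection <- function(manifest, mapping = NULL,
                                    unmapped_policy = "keep-as-gene",
                                    max_internal_path = 3L,
                                    blacklist = character()) {
  base_dir <- "."
  if (is.character(manifest) && length(manifest) == 1L) {
    base_dir <- dirname(manifest)
    manifest <- read_manifest(manifest)
  }
  if (is.character(mapping) && length(mapping) == 1L) {
    mapping <- read_id_mapping(mapping)
  }
  ord <- order(manifest$pathway_id, method = "radix")
  manifest <- manifest[ord, , drop = FALSE]
  out <- vector("list", nrow(manifest))
  counts <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    pid <- manifest$pathway_id[i]
    fp <- manifest$file_path[i]
    if (!file.exists(fp)) fp <- file.path(base_dir, manifest$file_path[i])
    if (!file.exists(fp)) {
      stop_input(sprintf("pathway '%s': file not found: %s", pid,
                         manifest$file_path[i]))
    }
    g <- read_sif(fp, pid)
    if (!is.null(mapping)) g <- apply_id_mapping(g, mapping, unmapped_policy)
    el <- interpolate_gene_edges(g, max_internal_path, blacklist)
    el$name <- manifest$name[i]
    el$source <- manifest$source[i]
    out[[i]] <- el
    counts[[i]] <- data.frame(
      pathway_id = pid,
      n_nodes = nrow(g$nodes),
      n_gene_nodes = sum(g$nodes$is_gene),
      n_gene_edges = nrow(el$pairs),
      self_loops_dropped = unname(g$counts["self_loops_dropped"]),
      unmapped = if ("unmapped" %in% names(g$counts))
        unname(g$counts["unmapped"]) else NA_integer_,
      stringsAsFactors = FALSE)
  }
  structure(out, counts = do.call(rbind, counts))
}
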