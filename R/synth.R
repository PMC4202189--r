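#' Specify a synthetic pathway collection with planted shared kernels
#'
#' The generator plants "kernel" subgraphs — blocks of gene-gene edges
#' shared by prescribed groups of pathways — plus pathway-private noise
#' edges. When the kernel pathway groups form a laminar family (any two
#' disjoint or nested), the exact set of maximal bicliques the planted
#' structure induces is known in closed form, which makes recovery
#' checkable without a reference implementation.
#'
#' @param n_genes Number of genes in the universe; labels are zero-padded
#'   (`g0001`, ...) so byte and numeric order agree.
#' @param n_pathways Number of pathways, labelled `P01`, `P02`, ...
#' @param kernel_plan List of kernels, each a list with `edge_count`
#'   (>= 1) and `pathways` (integer indices, at least 2 per kernel so each
#'   planted biclique is genuinely shared).
#' @param noise_edges_per_pathway Private noise edges added to each
#'   pathway; never repeated across pathways, so noise cannot create
#'   shared bicliques.
#' @param seed Integer seed; the generated collection is a deterministic
#'   function of the spec.
#' @return Object of class `synth_spec`.
#' @export
synth_spec <- function(n_genes, n_pathways, kernel_plan,
                       noise_edges_per_pathway = 0L, seed = 1L) {
  stopifnot(n_genes >= 2L, n_pathways >= 1L)
  for (k in kernel_plan) {
    if (is.null(k$edge_count) || k$edge_count < 1L) {
      stop_input("kernel edge_count must be >= 1")
    }
    if (is.null(k$pathways) || length(k$pathways) < 2L) {
      stop_input("each kernel must span at least 2 pathways")
    }
    if (any(k$pathways < 1L | k$pathways > n_pathways)) {
      stop_input("kernel pathway index out of range")
    }
  }
  kernel_plan <- lapply(kernel_plan, function(k) {
    list(edge_count = as.integer(k$edge_count),
         pathways = sort(unique(as.integer(k$pathways))))
  })
  structure(list(n_genes = as.integer(n_genes),
                 n_pathways = as.integer(n_pathways),
                 kernel_plan = kernel_plan,
                 noise_edges_per_pathway = as.integer(noise_edges_per_pathway),
                 seed = as.integer(seed),
                 laminar = is_laminar(lapply(kernel_plan, `[[`, "pathways"))),
            class = "synth_spec")
}

is_laminar <- function(sets) {
  n <- length(sets)
  if (n < 2L) return(TRUE)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ov <- length(intersect(sets[[i]], sets[[j]]))
    if (ov > 0L && ov < min(length(sets[[i]]), length(sets[[j]]))) return(FALSE)
  }
  TRUE
}

#' Default synthetic study conditions
#'
#' A desk-scale collection emulating nested shared sub-pathways: 8
#' pathways over 60 genes with a three-level laminar kernel plan (1 edge
#' shared by all 8 pathways, 3 more by pathways 1-4, 4 more by pathways
#' 1-2) and 5 private noise edges per pathway.
#'
#' @param seed Integer seed.
#' @return A `synth_spec`.
#' @export
default_synth_spec <- function(seed = 1L) {
  synth_spec(
    n_genes = 60L, n_pathways = 8L,
    kernel_plan = list(
      list(edge_count = 1L, pathways = 1:8),
      list(edge_count = 3L, pathways = 1:4),
      list(edge_count = 4L, pathways = 1:2)),
    noise_edges_per_pathway = 5L,
    seed = seed)
}

#' Generate a synthetic pathway collection with known ground truth
#'
#' Draws distinct unordered gene pairs for every kernel and noise slot
#' (no pair is reused anywhere), assembles per-pathway gene edge lists,
#' and records the maximal bicliques the planted structure must yield. For
#' a laminar kernel plan the truth is closed-form: one biclique per
#' distinct kernel pathway group S, whose edges are those of every kernel
#' planted on a (weak) superset of S. For non-laminar plans the truth is
#' computed by the brute-force oracle on the generated collection.
#'
#' @param spec A `synth_spec`.
#' @return List with `edge_lists` (list of `gene_edge_list`), `truth`
#'   (class `ground_truth`: list of bicliques as `pairs` data.frame +
#'   `pathway_ids`, for thresholds min_pathways = 2, min_edges = 1) and
#'   `counts` (generator bookkeeping: per-pathway edge counts, total and
#'   distinct edge counts, gene count).
#' @export
generate_collection <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  genes <- sprintf("g%04d", seq_len(spec$n_genes))
  n_kernel_edges <- sum(vapply(spec$kernel_plan, `[[`, integer(1), "edge_count"))
  n_needed <- n_kernel_edges + spec$n_pathways * spec$noise_edges_per_pathway
  n_possible <- choose(spec$n_genes, 2L)
  if (n_needed > n_possible) {
    stop_input(sprintf("infeasible spec: %d distinct edges requested but only %.0f pairs exist over %d genes",
                       n_needed, n_possible, spec$n_genes))
  }
  set.seed(spec$seed)
  pair_idx <- sample.int(n_possible, n_needed)
  pairs <- decode_pair_index(pair_idx, spec$n_genes)
  pairs <- data.frame(gene_a = genes[pairs[, 1L]], gene_b = genes[pairs[, 2L]],
                      stringsAsFactors = FALSE)

  take <- 0L
  kernel_edges <- lapply(spec$kernel_plan, function(k) {
    block <- pairs[take + seq_len(k$edge_count), , drop = FALSE]
    take <<- take + k$edge_count
    block
  })
  pids <- sprintf("P%02d", seq_len(spec$n_pathways))
  edge_lists <- vector("list", spec$n_pathways)
  for (p in seq_len(spec$n_pathways)) {
    own <- lapply(seq_along(spec$kernel_plan), function(i) {
      if (p %in% spec$kernel_plan[[i]]$pathways) kernel_edges[[i]] else NULL
    })
    if (spec$noise_edges_per_pathway > 0L) {
      noise <- pairs[take + seq_len(spec$noise_edges_per_pathway), , drop = FALSE]
      take <- take + spec$noise_edges_per_pathway
      own <- c(own, list(noise))
    }
    block <- do.call(rbind, own)
    edge_lists[[p]] <- new_gene_edge_list(pids[p], block,
                                          name = sprintf("synthetic pathway %d", p),
                                          source = "synth")
  }

  if (spec$laminar) {
    groups <- lapply(spec$kernel_plan, `[[`, "pathways")
    gkey <- vapply(groups, set_key, character(1))
    uniq <- !duplicated(gkey)
    truth <- lapply(which(uniq), function(i) {
      S <- groups[[i]]
      covers <- vapply(groups, function(g) is_subset(S, g), logical(1))
      pr <- do.call(rbind, kernel_edges[covers])
      ord <- order(pr$gene_a, pr$gene_b, method = "radix")
      list(pairs = pr[ord, , drop = FALSE], pathway_ids = pids[S])
    })
  } else {
    built <- build_edge_catalog(edge_lists)
    inc <- build_incidence(built$pathways)
    found <- oracle_enumerate_bicliques(inc, min_pathways = 2L, min_edges = 1L)
    truth <- lapply(unclass(found), function(b) {
      list(pairs = catalog_decode(built$catalog, b$edge_ids),
           pathway_ids = b$pathway_ids)
    })
  }
  truth <- structure(truth, class = "ground_truth")

  counts <- list(
    n_pathways = spec$n_pathways,
    n_genes_used = length(unique(c(pairs$gene_a, pairs$gene_b))),
    n_distinct_edges = n_needed,
    per_pathway_edges = stats::setNames(
      vapply(edge_lists, function(e) nrow(e$pairs), integer(1)), pids),
    n_planted_bicliques = length(truth))
  list(edge_lists = edge_lists, truth = truth, counts = counts)
}

# map 1..choose(n,2) onto unordered index pairs (i < j), row-wise by i
decode_pair_index <- function(idx, n) {
  # cumulative pairs with first index <= i: c_i = sum_{k<=i} (n-k)
  cum <- cumsum((n - 1L):0L)
  i <- findInterval(idx - 1L, cum) + 1L
  prev <- c(0L, cum)[i]
  j <- i + (idx - prev)
  cbind(i, j)
}

#' @export
print.synth_spec <- function(x, ...) {
  cat(sprintf("Synthetic collection spec: %d pathways, %d genes, %d kernel(s)%s, %d noise edge(s)/pathway, seed %d\n",
              x$n_pathways, x$n_genes, length(x$kernel_plan),
              if (x$laminar) " (laminar)" else " (non-laminar)",
              x$noise_edges_per_pathway, x$seed))
  invisible(x)
}

#' Score biclique recovery against planted ground truth
#'
#' Exact-match precision and recall over (edge set, pathway set) pairs.
#' Edge sets are compared as gene-pair sets so the score does not depend
#' on edge-id assignment.
#'
#' @param found A `biclique_set` from enumeration.
#' @param truth A `ground_truth` from [generate_collection()].
#' @param catalog The `edge_catalog` used for enumeration, to decode found
#'   edge ids.
#' @return Named numeric vector `c(precision, recall)`, each in `[0, 1]`.
#'   An empty `found` has precision 1 by convention; an empty `truth` has
#'   recall 1.
#' @export
score_recovery <- function(found, truth, catalog) {
  bic_key <- function(pairs, pathway_ids) {
    k <- sort(pair_key(pairs$gene_a, pairs$gene_b), method = "radix")
    paste(paste(k, collapse = "\n"), set_key(sort_byte(pathway_ids)), sep = "\n\n")
  }
  fk <- vapply(unclass(found), function(b) {
    bic_key(catalog_decode(catalog, b$edge_ids), b$pathway_ids)
  }, character(1))
  tk <- vapply(unclass(truth), function(b) {
    bic_key(b$pairs, b$pathway_ids)
  }, character(1))
  hits <- length(intersect(fk, tk))
  c(precision = if (length(fk) == 0L) 1 else hits / length(fk),
    recall = if (length(tk) == 0L) 1 else hits / length(tk))
}

#' Write a synthetic collection to disk in ingest format
#'
#' Emits one SIF file per pathway, a manifest, and the ground truth as
#' JSON, so the generated collection round-trips through
#' [read_pathway_collection()].
#'
#' @param collection Output of [generate_collection()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_collection <- function(collection, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(collection$edge_lists, function(e) {
    fn <- paste0(e$pathway_id, ".sif")
    writeLines(paste(e$pairs$gene_a, "pp", e$pairs$gene_b, sep = "\t"),
               file.path(dir, fn))
    data.frame(pathway_id = e$pathway_id, name = e$name, source = e$source,
               file_path = fn, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_json <- lapply(unclass(collection$truth), function(b) {
    list(edges = paste(b$pairs$gene_a, b$pairs$gene_b, sep = "--"),
         pathway_ids = b$pathway_ids)
  })
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = FALSE, pretty = TRUE)
  jsonlite::write_json(collection$counts, file.path(dir, "counts.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(mpath)
}
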