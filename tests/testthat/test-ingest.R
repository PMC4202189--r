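sif <- function(...) textConnection(paste(c(...), collapse = "\n"))

test_that("read_sif parses tab-separated interactions into unordered pairs", {
  g <- read_sif(sif("g1\tinteracts\tg2"), "p")
  expect_equal(g$edges, data.frame(a = "g1", b = "g2", stringsAsFactors = FALSE))
  expect_setequal(g$nodes$node_id, c("g1", "g2"))
  expect_true(all(g$nodes$is_gene))

  # both orientations and repeated types collapse to one unordered pair
  g2 <- read_sif(sif("g1\ti\tg2", "g2\ti\tg1", "g1\tactivates\tg2"), "p")
  expect_equal(nrow(g2$edges), 1L)

  # comments, blank lines, surrounding whitespace
  g3 <- read_sif(sif("# header", "", "  g1 \ti\t g2  "), "p")
  expect_equal(g3$edges$a, "g1")
  expect_equal(g3$edges$b, "g2")
})

test_that("read_sif drops and counts self-loops, handles empty input", {
  g <- read_sif(sif("g1\ti\tg1"), "p")
  expect_equal(nrow(g$edges), 0L)
  expect_equal(unname(g$counts["self_loops_dropped"]), 1L)

  g0 <- read_sif(sif(character(0)), "p")
  expect_equal(nrow(g0$edges), 0L)
  expect_equal(nrow(g0$nodes), 0L)
})

test_that("read_sif rejects malformed lines naming the line number", {
  expect_error(read_sif(sif("g1\ti\tg2", "brokenline"), "p"),
               "line 2", class = "pathbic_input_error")
  expect_error(read_sif(sif("# c", "g1\ti\tg2\textra"), "p"),
               "line 2", class = "pathbic_input_error")
})

test_that("apply_id_mapping relabels, collapses and honors unmapped policies", {
  map <- data.frame(original_id = c("u1", "u2", "u3"),
                    canonical_id = c("G1", "G1", "M9"),
                    is_gene = c(TRUE, TRUE, FALSE),
                    stringsAsFactors = FALSE)
  g <- read_sif(sif("u1\ti\tu2", "u2\ti\tu3", "u3\ti\tx9"), "p")

  out <- apply_id_mapping(g, map, "drop")
  # u1-u2 collapses to G1 self-loop; u3->M9 flagged non-gene; x9 dropped
  expect_setequal(out$nodes$node_id, c("G1", "M9"))
  expect_false(out$nodes$is_gene[out$nodes$node_id == "M9"])
  expect_equal(unname(out$counts["self_loops_dropped"]), 1L)
  expect_equal(unname(out$counts["unmapped"]), 1L)
  expect_equal(nrow(out$edges), 1L)  # only G1-M9 survives

  keepg <- apply_id_mapping(g, map, "keep-as-gene")
  expect_true(keepg$nodes$is_gene[keepg$nodes$node_id == "x9"])
  keepn <- apply_id_mapping(g, map, "keep-as-nongene")
  expect_false(keepn$nodes$is_gene[keepn$nodes$node_id == "x9"])
  expect_equal(nrow(keepn$edges), 2L)
})

test_that("mapping validation rejects non-functions and empty targets", {
  expect_error(validate_map <- apply_id_mapping(
    read_sif(sif("a\ti\tb"), "p"),
    data.frame(original_id = c("a", "a"), canonical_id = c("G1", "G2"),
               is_gene = TRUE, stringsAsFactors = FALSE), "drop"),
    "not a function", class = "pathbic_input_error")
  expect_error(apply_id_mapping(
    read_sif(sif("a\ti\tb"), "p"),
    data.frame(original_id = "a", canonical_id = "", is_gene = TRUE,
               stringsAsFactors = FALSE), "drop"),
    "empty canonical_id", class = "pathbic_input_error")
})

mixed <- function(nodes, genes, edges) {
  # edges as list of c(a, b)
  a <- vapply(edges, `[`, character(1), 1L)
  b <- vapply(edges, `[`, character(1), 2L)
  structure(list(pathway_id = "p",
                 nodes = data.frame(node_id = nodes,
                                    is_gene = nodes %in% genes,
                                    stringsAsFactors = FALSE),
                 edges = data.frame(a = a, b = b, stringsAsFactors = FALSE),
                 counts = c(self_loops_dropped = 0L)),
            class = "mixed_graph")
}

test_that("interpolate_gene_edges contracts non-gene paths and stops at genes", {
  # direct gene-gene adjacency
  g <- mixed(c("g1", "g2"), c("g1", "g2"), list(c("g1", "g2")))
  expect_equal(pairs_key(interpolate_gene_edges(g)$pairs), "g1|g2")

  # one non-gene intermediate within the default bound
  g <- mixed(c("g1", "g2", "m1"), c("g1", "g2"),
             list(c("g1", "m1"), c("m1", "g2")))
  expect_equal(pairs_key(interpolate_gene_edges(g, 3L)$pairs), "g1|g2")
  # but not with max_internal_path = 0
  expect_equal(nrow(interpolate_gene_edges(g, 0L)$pairs), 0L)

  # an intermediate gene interrupts: g1-m1-g3-m2-g2 gives no g1-g2 edge
  g <- mixed(c("g1", "g2", "g3", "m1", "m2"), c("g1", "g2", "g3"),
             list(c("g1", "m1"), c("m1", "g3"), c("g3", "m2"), c("m2", "g2")))
  expect_setequal(pairs_key(interpolate_gene_edges(g, 3L)$pairs),
                  c("g1|g3", "g2|g3"))

  # blacklisted non-gene hub is never traversed
  g <- mixed(c("g1", "g2", "atp"), c("g1", "g2"),
             list(c("g1", "atp"), c("atp", "g2")))
  expect_equal(nrow(interpolate_gene_edges(g, 3L, blacklist = "atp")$pairs), 0L)
})

test_that("interpolation matches the all-simple-paths oracle on random graphs", {
  set.seed(42)
  for (rep in 1:60) {
    g <- random_mixed_graph(sample(2:12, 1L), p_edge = stats::runif(1, 0.1, 0.5))
    k <- sample(0:4, 1L)
    got <- interpolate_gene_edges(g, k)$pairs
    want <- oracle_interpolate(g, k)
    expect_setequal(pairs_key(got), pairs_key(want))
  }
})

test_that("raising max_internal_path never removes a gene pair", {
  set.seed(7)
  for (rep in 1:25) {
    g <- random_mixed_graph(sample(4:12, 1L), p_edge = 0.3)
    prev <- character(0)
    for (k in 0:4) {
      cur <- pairs_key(interpolate_gene_edges(g, k)$pairs)
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("decomposition is insensitive to input line order", {
  lines <- c("u1\ti\tu2", "u2\ti\tu3", "u3\ti\tu4", "u1\ti\tu4")
  map <- data.frame(original_id = paste0("u", 1:4),
                    canonical_id = paste0("G", 1:4),
                    is_gene = c(TRUE, FALSE, TRUE, TRUE),
                    stringsAsFactors = FALSE)
  ref <- interpolate_gene_edges(
    apply_id_mapping(read_sif(sif(lines), "p"), map, "drop"))
  set.seed(1)
  for (rep in 1:5) {
    perm <- sample(lines)
    got <- interpolate_gene_edges(
      apply_id_mapping(read_sif(sif(perm), "p"), map, "drop"))
    expect_identical(got$pairs, ref$pairs)
  }
})
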