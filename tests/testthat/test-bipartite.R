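gel <- function(pathway_id, pairs) {
  # pairs as list of c(gene_a, gene_b), already canonical
  df <- data.frame(gene_a = vapply(pairs, `[`, character(1), 1L),
                   gene_b = vapply(pairs, `[`, character(1), 2L),
                   stringsAsFactors = FALSE)
  structure(list(pathway_id = pathway_id, name = "", source = "", pairs = df),
            class = "gene_edge_list")
}

test_that("edge catalog is a deterministic bijection in lexicographic order", {
  p1 <- gel("P1", list(c("B", "C"), c("A", "B")))
  p2 <- gel("P2", list(c("A", "B")))
  built <- build_edge_catalog(list(p1, p2))
  expect_equal(built$catalog$pairs$edge_id, c(1L, 2L))
  expect_equal(built$catalog$pairs$gene_a, c("A", "B"))
  expect_equal(built$catalog$pairs$gene_b, c("B", "C"))
  # shared pair (A,B) has one id in both pathways
  expect_true(1L %in% built$pathways[[1]]$edge_ids)
  expect_true(1L %in% built$pathways[[2]]$edge_ids)

  # permuting the pathway list yields identical ids
  built2 <- build_edge_catalog(list(p2, p1))
  expect_identical(built$catalog$pairs, built2$catalog$pairs)
})

test_that("empty inputs: empty collection passes, empty pathway is excluded", {
  built0 <- build_edge_catalog(list())
  expect_equal(nrow(built0$catalog$pairs), 0L)
  expect_length(built0$pathways, 0L)

  expect_warning(
    built <- build_edge_catalog(list(gel("P1", list(c("A", "B"))),
                                     gel("P0", list()))),
    "P0")
  expect_length(built$pathways, 1L)
})

test_that("incidence maps are transposes of each other", {
  inc <- build_incidence(list(make_pes("P1", c(1, 2)), make_pes("P2", 1)))
  expect_equal(inc$edge_to_pathways[["1"]], c("P1", "P2"))
  expect_equal(inc$edge_to_pathways[["2"]], "P1")
  expect_equal(inc$pathway_to_edges[["P1"]], c(1L, 2L))
  expect_error(build_incidence(list(make_pes("P1", 1), make_pes("P1", 2))),
               "duplicate", class = "pathbic_input_error")
  expect_error(build_incidence(list()), class = "pathbic_input_error")
})

test_that("maximal bicliques on the shared three-pathway instance", {
  inc <- build_incidence(list(make_pes("P1", c(1, 2, 3)),
                              make_pes("P2", c(1, 2)),
                              make_pes("P3", c(1, 4))))
  bc <- enumerate_maximal_bicliques(inc, min_pathways = 2L)
  expect_length(bc, 2L)
  expect_equal(bc[[1]]$edge_ids, 1L)
  expect_equal(bc[[1]]$pathway_ids, c("P1", "P2", "P3"))
  expect_equal(bc[[2]]$edge_ids, c(1L, 2L))
  expect_equal(bc[[2]]$pathway_ids, c("P1", "P2"))
})

test_that("degenerate threshold cases", {
  one <- build_incidence(list(make_pes("P1", 1)))
  bc <- enumerate_maximal_bicliques(one, min_pathways = 1L)
  expect_length(bc, 1L)
  expect_equal(bc[[1]]$edge_ids, 1L)

  expect_length(enumerate_maximal_bicliques(one, min_pathways = 2L), 0L)

  disj <- build_incidence(list(make_pes("P1", 1), make_pes("P2", 2)))
  expect_length(enumerate_maximal_bicliques(disj, min_pathways = 2L), 0L)
  expect_length(oracle_enumerate_bicliques(disj, min_pathways = 2L), 0L)
})

test_that("oracle refuses instances beyond its combinatorial guard", {
  pes <- lapply(1:16, function(p) make_pes(sprintf("P%02d", p), 1))
  expect_error(oracle_enumerate_bicliques(build_incidence(pes)),
               "15", class = "pathbic_input_error")
})

test_that("fast enumeration equals the subset oracle on random incidences", {
  set.seed(11)
  for (rep in 1:60) {
    inc <- random_incidence(sample(1:8, 1L), sample(2:25, 1L),
                            density = stats::runif(1, 0.1, 0.6))
    mp <- sample(1:2, 1L)
    expect_same_biclique_sets(
      enumerate_maximal_bicliques(inc, mp, 1L),
      oracle_enumerate_bicliques(inc, mp, 1L))
  }
})

test_that("returned bicliques are closed and form an antichain", {
  set.seed(23)
  for (rep in 1:20) {
    inc <- random_incidence(sample(2:8, 1L), sample(4:25, 1L), 0.35)
    bc <- enumerate_maximal_bicliques(inc, 2L, 1L)
    keys <- lapply(unclass(bc), function(b) b)
    for (b in unclass(bc)) {
      # closure: E -> P -> E is a fixed point
      P <- names(Filter(function(es) all(b$edge_ids %in% es),
                        inc$pathway_to_edges))
      expect_equal(sort(P, method = "radix"), b$pathway_ids)
      E <- Reduce(intersect, inc$pathway_to_edges[b$pathway_ids])
      expect_equal(sort(E), b$edge_ids)
    }
    # antichain: distinct bicliques differ on both sides, with containment
    # directions opposed when comparable
    n <- length(bc)
    if (n >= 2L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      ei <- bc[[i]]$edge_ids; ej <- bc[[j]]$edge_ids
      pi_ <- bc[[i]]$pathway_ids; pj <- bc[[j]]$pathway_ids
      expect_false(setequal(ei, ej))
      expect_false(setequal(pi_, pj))
      if (all(pi_ %in% pj)) expect_true(all(ej %in% ei))
      if (all(pj %in% pi_)) expect_true(all(ei %in% ej))
    }
  }
})

test_that("enumeration output is byte-stable across identical runs", {
  set.seed(5)
  inc <- random_incidence(6L, 20L, 0.4)
  a <- enumerate_maximal_bicliques(inc, 2L, 1L)
  b <- enumerate_maximal_bicliques(inc, 2L, 1L)
  expect_identical(a, b)
  f1 <- tempfile(); f2 <- tempfile()
  write_bicliques_json(a, f1)
  write_bicliques_json(b, f2)
  expect_identical(readLines(f1), readLines(f2))
})
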