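bic <- function(edge_ids, pathway_ids) {
  list(edge_ids = sort(as.integer(edge_ids)),
       pathway_ids = sort(pathway_ids, method = "radix"))
}

test_that("containment hierarchy of the two-biclique instance", {
  h <- build_hierarchy(list(bic(1, c("P1", "P2", "P3")),
                            bic(c(1, 2), c("P1", "P2"))))
  expect_equal(h$roots, 1L)
  expect_equal(unname(h$levels), c(0L, 1L))
  expect_equal(nrow(h$arcs), 1L)
  expect_equal(unname(h$arcs[1, ]), c(1L, 2L))
})

test_that("single and incomparable bicliques give arc-free hierarchies", {
  h1 <- build_hierarchy(list(bic(1, c("P1", "P2"))))
  expect_equal(h1$roots, 1L)
  expect_equal(nrow(h1$arcs), 0L)

  h2 <- build_hierarchy(list(bic(1, c("P1", "P2")),
                             bic(2, c("P3", "P4"))))
  expect_length(h2$roots, 2L)
  expect_equal(nrow(h2$arcs), 0L)
  expect_equal(unname(h2$levels), c(0L, 0L))

  h0 <- build_hierarchy(list())
  expect_length(h0$nodes, 0L)
  expect_equal(nrow(h0$arcs), 0L)
})

chain4 <- function() {
  build_hierarchy(list(
    bic(1, paste0("P", 1:5)),
    bic(1:2, paste0("P", 1:4)),
    bic(1:3, paste0("P", 1:3)),
    bic(1:4, paste0("P", 1:2))))
}

test_that("subhierarchy reroots and recomputes levels", {
  h <- chain4()
  expect_equal(unname(h$levels), 0:3)

  # at the unique root: same nodes, arcs and levels
  s <- subhierarchy(h, 1L)
  expect_equal(s$node_ids, 1:4)
  expect_equal(unname(s$levels), 0:3)

  # at a leaf: single node
  leaf <- subhierarchy(h, 4L)
  expect_equal(leaf$node_ids, 4L)
  expect_equal(unname(leaf$levels), 0L)

  # at the middle of a chain: two-node chain with levels 0, 1
  mid <- subhierarchy(h, 3L)
  expect_equal(mid$node_ids, c(3L, 4L))
  expect_equal(unname(mid$levels), c(0L, 1L))

  expect_error(subhierarchy(h, 99L), "unknown", class = "pathbic_input_error")
})

test_that("pathway view relabels nodes by their pathway groups", {
  h <- build_hierarchy(list(bic(1, c("P1", "P2", "P3")),
                            bic(c(1, 2), c("P1", "P2"))))
  v <- pathway_view(h)
  expect_equal(v$groups[["1"]], c("P1", "P2", "P3"))
  expect_equal(v$groups[["2"]], c("P1", "P2"))
  expect_equal(nrow(v$arcs), 1L)

  v1 <- pathway_view(build_hierarchy(list(bic(1, c("P1", "P2")))))
  expect_equal(nrow(v1$arcs), 0L)
  v0 <- pathway_view(build_hierarchy(list()))
  expect_length(v0$groups, 0L)
})

reachable <- function(arcs, n) {
  # boolean reachability matrix over arcs
  r <- matrix(FALSE, n, n)
  for (i in seq_len(nrow(arcs))) r[arcs[i, 1L], arcs[i, 2L]] <- TRUE
  for (k in seq_len(n)) for (i in seq_len(n)) if (r[i, k]) {
    r[i, ] <- r[i, ] | r[k, ]
  }
  r
}

test_that("hierarchy invariants hold on enumerated biclique sets", {
  set.seed(31)
  for (rep in 1:20) {
    inc <- random_incidence(sample(3:8, 1L), sample(5:25, 1L), 0.4)
    bc <- enumerate_maximal_bicliques(inc, 2L, 1L)
    h <- build_hierarchy(bc)
    n <- length(h$node_ids)
    if (n == 0L) next
    r <- reachable(h$arcs, n)

    # acyclic
    expect_false(any(diag(r)))

    # strict inverse containment along every arc
    for (i in seq_len(nrow(h$arcs))) {
      p <- h$nodes[[h$arcs[i, "parent"]]]
      c <- h$nodes[[h$arcs[i, "child"]]]
      expect_true(all(c$pathway_ids %in% p$pathway_ids))
      expect_gt(length(p$pathway_ids), length(c$pathway_ids))
      expect_true(all(p$edge_ids %in% c$edge_ids))
      expect_gt(length(c$edge_ids), length(p$edge_ids))
    }

    # transitive reduction: every comparable pair is already reachable,
    # and no arc is implied by a two-arc path
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      pi_ <- h$nodes[[i]]$pathway_ids
      pj <- h$nodes[[j]]$pathway_ids
      if (length(pj) < length(pi_) && all(pj %in% pi_)) {
        expect_true(r[i, j])
      }
    }
    if (nrow(h$arcs) > 0L) {
      two_step <- r %*% r > 0
      for (i in seq_len(nrow(h$arcs))) {
        expect_false(two_step[h$arcs[i, 1L], h$arcs[i, 2L]])
      }
    }

    # levels: child level is one more than the deepest parent
    for (v in seq_len(n)) {
      par <- h$arcs[h$arcs[, "child"] == v, "parent"]
      if (length(par) == 0L) {
        expect_equal(unname(h$levels[as.character(v)]), 0L)
      } else {
        expect_equal(unname(h$levels[as.character(v)]),
                     max(unname(h$levels[as.character(par)])) + 1L)
      }
    }

    # round trip: flattening the nodes returns the input biclique set
    flat <- structure(lapply(h$nodes, function(b) {
      b$biclique_id <- NULL
      b
    }), class = "biclique_set")
    expect_same_biclique_sets(flat, bc)
  }
})

test_that("pathway count decreases and edge count grows along root-leaf paths", {
  col <- generate_collection(default_synth_spec(seed = 3))
  fit <- pathbic(col$edge_lists)
  h <- fit$hierarchy
  for (i in seq_len(nrow(h$arcs))) {
    p <- h$nodes[[h$arcs[i, "parent"]]]
    c <- h$nodes[[h$arcs[i, "child"]]]
    expect_gt(length(p$pathway_ids), length(c$pathway_ids))
    expect_lt(length(p$edge_ids), length(c$edge_ids))
  }
})
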