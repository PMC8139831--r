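test_that("read_swc parses minimal and chain skeletons", {
  f <- withr::local_tempfile(fileext = ".swc")
  writeLines("1 1 0 0 0 500 -1", f)
  sk <- read_swc(f, "n1")
  expect_s3_class(sk, "skeleton")
  expect_equal(nrow(sk$nodes), 1L)
  expect_equal(sk$root, 1)

  writeLines(c("1 0 0 0 0 100 -1",
               "2 0 0 0 1000 100 1",
               "3 0 0 0 2500 100 2"), f)
  sk <- read_swc(f)
  expect_equal(cable_length(sk), 2500)
})

test_that("read_swc rejects malformed files with informative errors", {
  f <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 0 0 0 0 100 -1", "2 0 0 0 1 100 1", "3 0 0 0 2 100 3"), f)
  expect_error(read_swc(f), "cycle|disconnected")

  writeLines(c("1 0 0 0 0 100 -1", "2 0 0 0 1 100 -1"), f)
  expect_error(read_swc(f), "multiple roots")

  writeLines(c("1 0 0 0 0 100 -1", "2 0 abc 0 1 100 1"), f)
  expect_error(read_swc(f), "line 2")
})

test_that("skeleton SWC round-trip is lossless", {
  sk <- small_connectome()$skeletons[[1]]
  f <- withr::local_tempfile(fileext = ".swc")
  write_swc(sk, f)
  back <- read_swc(f, sk$neuron_id)
  expect_equal(back$nodes, sk$nodes, tolerance = 1e-12)
  expect_equal(back$root, sk$root)
})

test_that("strahler_order follows the textbook rule", {
  path10 <- chain_skeleton(cbind(0, 0, seq(0, 9000, by = 1000)))
  expect_true(all(strahler_order(path10) == 1L))

  # fork: two leaf twigs joining at a node on a stem
  y_tree <- skeleton("y", data.frame(
    node_id = 1:5, parent_id = c(NA, 1, 2, 2, 1),
    x = c(0, 0, -500, 500, 0), y = 0, z = c(0, 1000, 2000, 2000, -1000),
    radius = 100))
  ord <- strahler_order(y_tree)
  expect_equal(unname(ord[c("3", "4")]), c(1L, 1L))
  expect_equal(unname(ord[c("1", "2")]), c(2L, 2L))

  # an order-2 branch joined by an order-1 twig keeps order 2 downstream
  t2 <- skeleton("t2", data.frame(
    node_id = 1:7, parent_id = c(NA, 1, 2, 3, 3, 2, 1),
    x = c(0, 0, 0, -1, 1, 2, 3), y = 0, z = c(0, 1, 2, 3, 3, 2.5, 1),
    radius = 100))
  ord <- strahler_order(t2)
  expect_equal(unname(ord["3"]), 2L)  # fork of two leaves
  expect_equal(unname(ord["2"]), 2L)  # order-2 + order-1 twig -> still 2
  expect_equal(unname(ord["1"]), 2L)
})

test_that("prune_by_strahler removes distal twigs and keeps the root", {
  y_tree <- skeleton("y", data.frame(
    node_id = 1:5, parent_id = c(NA, 1, 2, 2, 1),
    x = c(0, 0, -500, 500, 0), y = 0, z = c(0, 1000, 2000, 2000, -1000),
    radius = 100))
  expect_equal(prune_by_strahler(y_tree, 1)$nodes, y_tree$nodes)
  pruned <- prune_by_strahler(y_tree, 2)
  expect_setequal(pruned$nodes$node_id, c(1, 2))
  expect_warning(tiny <- prune_by_strahler(y_tree, 99), "exceeds")
  expect_equal(nrow(tiny$nodes), 1L)
  expect_equal(tiny$root, y_tree$root)
})

test_that("neuropil entry and cortex neurite length follow geodesics", {
  vol <- neuropil_box(c(2500, 1e9), c(-1e9, 1e9), c(-1e9, 1e9))
  chain <- chain_skeleton(cbind(seq(0, 5000, by = 1000), 0, 0))
  expect_equal(neuropil_entry(chain, vol), 4)  # node at x = 3000
  expect_equal(cortex_neurite_length(chain, vol), 3000)

  all_vol <- neuropil_box(c(-1, 1), c(-1, 1), c(-1, 1))
  soma_in <- chain_skeleton(cbind(0, 0, 0))
  expect_equal(neuropil_entry(soma_in, all_vol), 1)
  expect_equal(cortex_neurite_length(soma_in, all_vol), 0)

  # two branches entering the volume at geodesic 4000 and 6000 nm
  two <- skeleton("two", data.frame(
    node_id = 1:5, parent_id = c(NA, 1, 2, 1, 4),
    x = c(0, 2000, 4000, 3000, 6000), y = c(0, 0, 0, 1e5, 1e5), z = 0,
    radius = 100))
  vol2 <- neuropil_box(c(3500, 1e9), c(-1e9, 1e9), c(-1e9, 1e9))
  expect_equal(neuropil_entry(two, vol2), 3)
  expect_equal(cortex_neurite_length(two, vol2), 4000)
})

test_that("cortex length matches a shortest-path oracle on generated trees", {
  cn <- small_connectome()
  vol <- cn$config$neuropil
  for (sk in cn$skeletons[seq(1, length(cn$skeletons), by = 7)]) {
    # oracle: explicit Dijkstra-on-tree via igraph with edge lengths
    nd <- sk$nodes
    has_par <- !is.na(nd$parent_id)
    ij <- cbind(match(nd$parent_id[has_par], nd$node_id), which(has_par))
    w <- sqrt(rowSums((nd[ij[, 1], c("x", "y", "z")] -
                         nd[ij[, 2], c("x", "y", "z")])^2))
    g <- igraph::graph_from_edgelist(ij, directed = FALSE)
    dist <- igraph::distances(g, v = match(sk$root, nd$node_id),
                              weights = w)[1, ]
    inside <- volume_contains(vol, as.matrix(nd[c("x", "y", "z")]))
    oracle <- if (any(inside)) min(dist[inside]) else NA_real_
    expect_equal(cortex_neurite_length(sk, vol), oracle, tolerance = 1e-9)
  }
})

test_that("cortex length is invariant to node re-indexing and subdivision", {
  pts <- cbind(c(0, 1000, 2000, 3500, 5000), c(0, 200, 0, -200, 0), 0)
  vol <- neuropil_box(c(3000, 1e9), c(-1e9, 1e9), c(-1e9, 1e9))
  base <- chain_skeleton(pts)
  l0 <- cortex_neurite_length(base, vol)

  relab <- base$nodes
  relab$node_id <- relab$node_id * 10 + 3
  relab$parent_id <- relab$parent_id * 10 + 3
  expect_equal(cortex_neurite_length(skeleton("r", relab), vol), l0)

  mid <- (pts[-1, ] + pts[-nrow(pts), ]) / 2
  dense <- pts[rep(1, 0), ]
  for (i in seq_len(nrow(pts) - 1))
    dense <- rbind(dense, pts[i, ], mid[i, ])
  dense <- rbind(dense, pts[nrow(pts), ])
  expect_equal(cortex_neurite_length(chain_skeleton(dense), vol), l0,
               tolerance = 1e-9)
})

test_that("bilateral_mean_length averages and propagates single sides", {
  expect_equal(bilateral_mean_length(3000, 3000), 3000)
  expect_equal(bilateral_mean_length(2000, 4000), 3000)
  expect_warning(one <- bilateral_mean_length(c(2000, NA), c(NA, 1000)),
                 "single")
  expect_equal(one, c(2000, 1000))
})
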