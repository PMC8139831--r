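test_that("synapse similarity matches closed forms", {
  set.seed(5)
  a <- matrix(rnorm(60, sd = 1500), ncol = 3)
  expect_equal(synapse_similarity(a, a), 1)
  expect_equal(synapse_similarity(matrix(c(0, 0, 0), 1),
                                  matrix(c(2000, 0, 0), 1)),
               exp(-0.5))
  expect_error(synapse_similarity(a[0, , drop = FALSE], a), "non-empty")
})

test_that("directed scores equal the nested-loop oracle on random clouds", {
  set.seed(7)
  for (r in 1:8) {
    a <- matrix(rnorm(30, sd = 3000), ncol = 3)
    b <- matrix(rnorm(36, sd = 3000), ncol = 3) + 1000
    expect_equal(synapse_similarity(a, b),
                 oracle_synapse_similarity(a, b), tolerance = 1e-9)
    expect_equal(synapse_similarity(a, b, symmetric = TRUE),
                 (oracle_synapse_similarity(a, b) +
                    oracle_synapse_similarity(b, a)) / 2,
                 tolerance = 1e-9)
  }
})

test_that("overlap score handles empty sets, separation and asymmetry", {
  set.seed(9)
  pre <- matrix(rnorm(30, sd = 1000), ncol = 3)
  expect_message(z <- overlap_score(pre[0, , drop = FALSE], pre), "empty")
  expect_equal(z, 0)
  expect_equal(overlap_score(pre, pre + rep(c(0, 0, 1), each = 10)),
               synapse_similarity(pre, pre + rep(c(0, 0, 1), each = 10)))

  far <- pre + rep(c(20000, 0, 0), each = 10)  # 10 sigma away
  expect_lt(overlap_score(pre, far), 1e-5)

  small <- matrix(rnorm(6, sd = 500), ncol = 3)
  big <- matrix(rnorm(30, sd = 4000), ncol = 3)
  expect_false(isTRUE(all.equal(overlap_score(small, big),
                                overlap_score(big, small))))
  expect_equal(overlap_score(small, big),
               oracle_synapse_similarity(small, big), tolerance = 1e-9)
})

test_that("scores are invariant under rigid motion and joint rescaling", {
  set.seed(13)
  a <- matrix(rnorm(45, sd = 2500), ncol = 3)
  b <- matrix(rnorm(30, sd = 2500), ncol = 3) + 500
  s0 <- synapse_similarity(a, b)
  th <- 1.1
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  mv <- function(m) m %*% R + rep(c(-3e4, 2e3, 1e4), each = nrow(m))
  expect_equal(synapse_similarity(mv(a), mv(b)), s0, tolerance = 1e-9)
  expect_equal(synapse_similarity(3 * a, 3 * b, sigma = 6000, omega = 6000),
               s0, tolerance = 1e-9)
})

test_that("bilateral averaging propagates a missing side with a warning", {
  expect_equal(bilateral_average(0.4, 0.6), 0.5)
  expect_equal(bilateral_average(0.37, 0.37), 0.37)
  expect_warning(v <- bilateral_average(NA, 0.8), "single side")
  expect_equal(v, 0.8)
})

test_that("similarity_matrix averages homolog sides and flags diagonals", {
  cn <- small_connectome()
  ann <- cn$annotations
  inter <- ann$neuron_id[ann$cell_class == "interneuron"]
  sm <- suppressMessages(similarity_matrix(cn$connectors, ann, "pre_pre",
                                           neuron_ids = inter))
  expect_equal(unname(diag(sm)), rep(1, nrow(sm)), tolerance = 1e-12)
  expect_equal(attr(sm, "mode"), "pre_pre")

  # spot-check one off-diagonal entry against per-side recomputation
  ids <- attr(sm, "members")
  i <- names(ids)[1]; j <- names(ids)[2]
  manual <- mean(vapply(1:2, function(s) {
    synapse_similarity(presynapse_points(cn$connectors, ids[[i]][s]),
                       presynapse_points(cn$connectors, ids[[j]][s]))
  }, numeric(1)))
  expect_equal(sm[i, j], manual, tolerance = 1e-12)

  smx <- suppressMessages(similarity_matrix(cn$connectors, ann, "pre_post",
                                            neuron_ids = inter))
  expect_true(any(diag(smx) < 1))  # pre/post self-overlap is computed, not 1
})

test_that("density maps enclose the requested mass minimally", {
  set.seed(21)
  pts <- cbind(rnorm(300, sd = 2000), rnorm(300, sd = 1500), rnorm(300))
  dm <- density_map(pts, contour_fraction = 0.6)
  mass <- sum(dm$z[dm$z >= dm$contour_level]) * diff(dm$x)[1] * diff(dm$y)[1]
  expect_gte(mass, 0.6)
  # one grid step up in level drops below the requested fraction: minimal
  lv <- sort(unique(as.vector(dm$z)), decreasing = TRUE)
  nxt <- lv[which(lv == dm$contour_level) - 1]
  mass_up <- sum(dm$z[dm$z >= nxt]) * diff(dm$x)[1] * diff(dm$y)[1]
  expect_lt(mass_up, 0.6)

  single <- density_map(cbind(rnorm(80, sd = 300), rnorm(80, sd = 300), 0),
                        contour_fraction = 0.6)
  comp <- density_contours(single)
  expect_gte(length(comp), 1L)
})

test_that("well-separated clouds give two disjoint contour components", {
  set.seed(22)
  cl1 <- cbind(rnorm(200, sd = 1000), rnorm(200, sd = 1000), 0)
  cl2 <- cl1 + rep(c(20000, 0, 0), each = 200)
  dm <- density_map(rbind(cl1, cl2), bandwidth = c(1000, 1000),
                    contour_fraction = 0.6)
  comp <- density_contours(dm)
  expect_equal(length(comp), 2L)
})

test_that("polyadic weighting relocates the density mode", {
  set.seed(23)
  site_a <- cbind(rnorm(5, 0, 200), rnorm(5, 0, 200), 0)       # weight 5
  site_b <- cbind(rnorm(5, 20000, 200), rnorm(5, 0, 200), 0)   # weight 1
  dm <- density_map(rbind(site_a, site_b), weights = c(rep(5, 5), rep(1, 5)),
                    bandwidth = c(1000, 1000))
  mode_x <- dm$x[which(dm$z == max(dm$z), arr.ind = TRUE)[1]]
  expect_lt(abs(mode_x), 5000)
  expect_equal(dm$weights_policy, "polyadic")

  expect_warning(pm <- density_map(matrix(rep(c(1, 2, 3), 5), ncol = 3,
                                          byrow = TRUE)),
                 "identical")
  expect_equal(sum(pm$z > 0), 1L)
})

test_that("anteroposterior windows restrict the mapped synapses", {
  pts <- cbind(rnorm(100), rnorm(100), c(rep(0, 50), rep(1e6, 50)))
  dm <- density_map(pts, ap_window = c(-10, 10))
  expect_equal(dm$n_synapses, 50L)
})
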