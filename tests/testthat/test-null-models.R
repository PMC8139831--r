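test_that("connection probability models normalize as specified", {
  ids <- c("a", "b", "c")
  b <- matrix(c(0, 1, 1, 0, 0, 1, 0, 1, 0), 3, byrow = TRUE,
              dimnames = list(ids, ids))
  # in-degrees: a = 0, b = 2, c = 2 -> rows proportional, self excluded
  md <- connection_probabilities("input_degree", binary = b)
  expect_equal(md$p["a", ], c(a = 0, b = 0.5, c = 0.5))
  expect_equal(md$p["b", ], c(a = 0, b = 0, c = 1))

  ov <- matrix(c(0, 0.4, 0, 0, 0, 0.6, 0.4, 0.05, 0.55), 3, byrow = TRUE,
               dimnames = list(ids, ids))
  mo <- connection_probabilities("overlap", overlap_matrix = ov)
  expect_equal(unname(mo$p["c", ]), c(0.4, 0.05, 0) / 0.45)

  mo2 <- connection_probabilities("overlap", overlap_matrix = ov,
                                  overlap_threshold = 0.1)
  expect_equal(unname(mo2$p["c", ]), c(0.4 / 0.4, 0, 0))
  # hand-derived zero-then-renormalize on the spec-style row
  row <- c(0.4, 0.05, 0.55)
  row[row < 0.1] <- 0
  expect_equal(unname(row / sum(row)), c(0.421052631578947, 0,
                                         0.578947368421053),
               tolerance = 1e-12)

  expect_message(connection_probabilities("input_degree",
                                          binary = b * 0L), "no admissible")
})

test_that("shuffles preserve out-degree exactly and honour degeneracy", {
  set.seed(41)
  n <- 12
  ids <- sprintf("n%02d", 1:n)
  b <- matrix(rbinom(n * n, 1, 0.3), n, n, dimnames = list(ids, ids))
  diag(b) <- 0L
  ov <- matrix(runif(n * n), n, n, dimnames = list(ids, ids))
  diag(ov) <- 0
  model <- connection_probabilities("overlap", overlap_matrix = ov)
  for (k in 1:25) {
    sh <- shuffle_connectivity(b, model)
    expect_equal(rowSums(sh), rowSums(b))
    expect_true(all(sh %in% c(0L, 1L)))
    expect_true(all(diag(sh) == 0))
  }

  # concentrated row: the single admissible edge is drawn every time
  b1 <- matrix(0L, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  b1["a", "b"] <- 1L
  ov1 <- matrix(0, 3, 3, dimnames = dimnames(b1))
  ov1["a", "c"] <- 1
  m1 <- suppressMessages(connection_probabilities("overlap",
                                                  overlap_matrix = ov1))
  draws <- replicate(50, shuffle_connectivity(b1, m1)["a", "c"])
  expect_true(all(draws == 1L))

  # too few admissible targets is an error naming the neuron
  b2 <- b1
  b2["a", "c"] <- 1L
  expect_error(shuffle_connectivity(b2, m1), "a has out-degree 2")
})

test_that("uniform-probability shuffles draw targets uniformly", {
  ids <- c("s", "t1", "t2", "t3")
  b <- matrix(0L, 4, 4, dimnames = list(ids, ids))
  b["s", "t1"] <- 1L
  ov <- matrix(0, 4, 4, dimnames = list(ids, ids))
  ov["s", c("t1", "t2", "t3")] <- 1
  model <- suppressMessages(connection_probabilities("overlap",
                                                     overlap_matrix = ov))
  set.seed(42)
  n_rep <- 30000
  counts <- c(t1 = 0, t2 = 0, t3 = 0)
  for (k in seq_len(n_rep)) {
    sh <- shuffle_connectivity(b, model)
    counts <- counts + sh["s", c("t1", "t2", "t3")]
  }
  se <- sqrt(n_rep * (1 / 3) * (2 / 3))
  expect_true(all(abs(counts - n_rep / 3) < 3 * se))
})

test_that("input-degree shuffles track observed in-degrees", {
  set.seed(43)
  n <- 10
  ids <- sprintf("n%02d", 1:n)
  b <- matrix(rbinom(n * n, 1, 0.25), n, n, dimnames = list(ids, ids))
  diag(b) <- 0L
  model <- connection_probabilities("input_degree", binary = b)
  n_rep <- 2000
  acc <- matrix(0, n, n, dimnames = dimnames(b))
  for (k in seq_len(n_rep)) acc <- acc + shuffle_connectivity(b, model)
  sim_in <- colSums(acc) / n_rep
  # independent oracle: per-row inclusion frequencies from plain sample.int
  # draws with the same row probabilities
  exp_in <- rep(0, n)
  for (i in seq_len(n)) {
    d <- sum(b[i, ])
    if (d == 0) next
    pr <- model$p[i, ]
    inc <- rep(0, n)
    for (k in seq_len(n_rep)) {
      idx <- sample.int(n, d, prob = pr)
      inc[idx] <- inc[idx] + 1
    }
    exp_in <- exp_in + inc / n_rep
  }
  expect_true(all(abs(sim_in - exp_in) <=
                    4 * sqrt(exp_in + 0.1) / sqrt(n_rep)))
  # heavier-input neurons receive more shuffled inputs
  expect_gt(cor(sim_in, colSums(b), method = "spearman"), 0.9)
})

test_that("cohort connection frequency matches hand and brute-force oracles", {
  ids <- c("a1", "a2", "b1", "b2")
  cl <- list(A = c("a1", "a2"), B = c("b1", "b2"))
  b <- matrix(0L, 4, 4, dimnames = list(ids, ids))
  expect_equal(as.numeric(cohort_connection_frequency(b, cl)), 0)

  b["a1", "b1"] <- 1L
  b["a2", "b2"] <- 1L
  f <- cohort_connection_frequency(b, cl)
  expect_equal(as.numeric(f), 0.5)  # A's pair hits B; B's pair hits nothing
  expect_equal(attr(f, "n_combinations"), 2L)

  set.seed(44)
  n <- 20
  ids <- sprintf("n%02d", 1:n)
  bb <- matrix(rbinom(n * n, 1, 0.15), n, n, dimnames = list(ids, ids))
  diag(bb) <- 0L
  cl <- split(ids, rep(1:5, each = 4))
  names(cl) <- paste0("C", 1:5)
  expect_equal(as.numeric(cohort_connection_frequency(bb, cl)),
               oracle_cohort_frequency(bb, cl))

  expect_warning(und <- cohort_connection_frequency(bb, list(C1 = ids[1])),
                 "undefined")
  expect_true(is.na(und))
})

test_that("alternative statistic readings are consistent", {
  set.seed(45)
  n <- 16
  ids <- sprintf("n%02d", 1:n)
  b <- matrix(rbinom(n * n, 1, 0.2), n, n, dimnames = list(ids, ids))
  diag(b) <- 0L
  cl <- split(ids, rep(1:4, each = 4))
  f_pair <- as.numeric(cohort_connection_frequency(b, cl, "pair_both"))
  f_coh <- as.numeric(cohort_connection_frequency(b, cl, "cohort_pair"))
  f_neu <- as.numeric(cohort_connection_frequency(b, cl, "per_neuron"))
  # existence over pairs dominates the per-pair average; per-neuron
  # membership dominates the joint-pair requirement
  expect_gte(f_coh, f_pair)
  expect_gte(f_neu, f_pair)
})

test_that("null distribution reports a valid add-one empirical p", {
  cn <- small_connectome()
  ann <- cn$annotations
  ids <- ann$neuron_id
  b <- binarize(suppressMessages(build_connectivity(cn$connectors, ids)), 1)
  O <- matrix(runif(length(ids)^2), length(ids),
              dimnames = list(ids, ids))
  diag(O) <- 0
  model <- connection_probabilities("overlap", overlap_matrix = O)
  nt <- null_distribution(b, model, hlt_cohort(ann), n_iter = 100, seed = 9)
  expect_equal(nt$observed,
               as.numeric(cohort_connection_frequency(b, hlt_cohort(ann))))
  expect_gt(nt$p, 0)
  expect_lte(nt$p, 1)
  expect_equal(length(nt$samples), 100L)
  expect_equal(nt$p, (1 + sum(nt$samples >= nt$observed)) / 101)

  nt2 <- null_distribution(b, model, hlt_cohort(ann), n_iter = 100, seed = 9)
  expect_identical(nt$samples, nt2$samples)
})
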