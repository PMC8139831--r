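# Shared fixtures and independent oracles. Everything is built in code; the
# larger connectomes are generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Small connectome for unit-level checks (2 lineages x 2 groups x 2 neurons).
small_connectome <- function() {
  cached("small", suppressMessages(generate_connectome(
    generator_config(n_lineages = 2, temporal_groups_per_hemilineage = 2,
                     neurons_per_hlt = 2, seed = 42))))
}

# The default study-scale connectome (used by the recovery checks).
default_connectome <- function() {
  cached("default", suppressMessages(generate_connectome(
    generator_config(seed = 1))))
}

# Unbranched chain skeleton through the given points (rows = nodes, nm).
chain_skeleton <- function(pts, neuron_id = "chain") {
  n <- nrow(pts)
  skeleton(neuron_id,
           data.frame(node_id = seq_len(n),
                      parent_id = c(NA, seq_len(n - 1)),
                      x = pts[, 1], y = pts[, 2], z = pts[, 3],
                      radius = 100))
}

# Nested-loop synapse-similarity oracle: no vectorization, no shared code
# with the implementation beyond plain arithmetic.
oracle_synapse_similarity <- function(a, b, sigma = 2000, omega = 2000) {
  nf <- function(pts, p) {
    cnt <- 0
    for (r in seq_len(nrow(pts)))
      if (sqrt(sum((pts[r, ] - p)^2)) <= omega) cnt <- cnt + 1
    cnt / nrow(pts)
  }
  total <- 0
  for (s in seq_len(nrow(a))) {
    best <- Inf
    k <- NA
    for (t in seq_len(nrow(b))) {
      d <- sqrt(sum((a[s, ] - b[t, ])^2))
      if (d < best) {
        best <- d
        k <- t
      }
    }
    nis <- nf(a, a[s, ])
    njk <- nf(b, b[k, ])
    total <- total + exp(-best^2 / (2 * sigma^2)) *
      exp(-abs(nis - njk) / (nis + njk))
  }
  total / nrow(a)
}

# Breadth-first-search all-pairs distance oracle on an undirected adjacency.
oracle_bfs_distances <- function(adj) {
  n <- nrow(adj)
  und <- (adj + t(adj)) > 0
  out <- matrix(Inf, n, n, dimnames = dimnames(adj))
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      for (u in which(und[v, ])) {
        if (dist[u] > dist[v] + 1) {
          dist[u] <- dist[v] + 1
          queue <- c(queue, u)
        }
      }
    }
    out[s, ] <- dist
  }
  out
}

# Triple-loop oracle for the cohort connection frequency (pair_both reading).
oracle_cohort_frequency <- function(binary, cohort_list) {
  ids <- rownames(binary)
  cohort_list <- lapply(cohort_list, intersect, y = ids)
  cohort_list <- cohort_list[lengths(cohort_list) >= 2]
  good <- 0
  total <- 0
  for (a in names(cohort_list)) {
    members <- cohort_list[[a]]
    for (m1 in seq_along(members)) {
      for (m2 in seq_len(m1 - 1L)) {
        for (cc in setdiff(names(cohort_list), a)) {
          hit1 <- FALSE
          hit2 <- FALSE
          for (j in cohort_list[[cc]]) {
            if (binary[members[m1], j] > 0) hit1 <- TRUE
            if (binary[members[m2], j] > 0) hit2 <- TRUE
          }
          good <- good + (hit1 && hit2)
          total <- total + 1
        }
      }
    }
  }
  if (total == 0) return(NA_real_)
  good / total
}

# Global partition ARI helper: cluster labels per lineage-hemisegment block
# combined into one partition and compared against the true
# lineage x hemisegment x hemilineage partition.
pooled_cluster_ari <- function(clusters, annotations) {
  lab <- unlist(lapply(names(clusters), function(nm)
    stats::setNames(paste(nm, clusters[[nm]]), names(clusters[[nm]]))))
  truth <- annotations$hemilineage[match(names(lab), annotations$neuron_id)]
  lin <- annotations$lineage[match(names(lab), annotations$neuron_id)]
  seg <- annotations$hemisegment[match(names(lab), annotations$neuron_id)]
  mclust::adjustedRandIndex(lab, paste(lin, seg, truth))
}
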