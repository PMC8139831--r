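#' Classify premotor and postsensory interneurons
#'
#' A neuron is premotor when it places more than `threshold` synapses onto a
#' single motor neuron, and postsensory when it receives more than
#' `threshold` synapses from a single sensory neuron (strict inequality; the
#' default 3 means "more than three synapses"). Set `per_partner = FALSE` to
#' apply the threshold to the aggregate count over all motor (sensory)
#' neurons instead.
#'
#' @param matrix a `connectivity_matrix` (raw counts).
#' @param motor_ids,sensory_ids character vectors of motor and sensory neuron
#'   ids (disjoint from the interneurons being classified).
#' @param threshold synapse-count threshold (strict `>`).
#' @param per_partner apply the threshold per partner (default) or to the
#'   aggregate.
#' @return data frame with columns `neuron_id`, `premotor`, `postsensory`.
#' @export
classify_premotor_postsensory <- function(matrix, motor_ids, sensory_ids,
                                          threshold = 3L, per_partner = TRUE) {
  ids <- rownames(matrix)
  stopifnot(!is.null(ids), length(intersect(motor_ids, sensory_ids)) == 0)
  motor_ids <- intersect(motor_ids, ids)
  sensory_ids <- intersect(sensory_ids, ids)
  inter <- setdiff(ids, c(motor_ids, sensory_ids))
  to_motor <- unclass(matrix)[inter, motor_ids, drop = FALSE]
  from_sens <- t(unclass(matrix)[sensory_ids, inter, drop = FALSE])
  agg <- function(m) if (per_partner) apply(m, 1, function(r)
    if (length(r)) max(r) else 0) else rowSums(m)
  data.frame(neuron_id = inter,
             premotor = agg(to_motor) > threshold,
             postsensory = agg(from_sens) > threshold,
             row.names = NULL)
}

#' Fraction of a neuron set's synaptic output (or input) per target group
#'
#' For `direction = "outputs"`, the fraction of all synaptic outputs of the
#' source set landing on each target group; fractions over the listed groups
#' sum to at most 1 (the remainder goes to unlisted neurons). For
#' `direction = "inputs"`, the fraction of all synaptic inputs to the source
#' set arriving from each group.
#'
#' @param matrix a `connectivity_matrix` (raw counts).
#' @param source_ids neuron ids whose output (input) is decomposed.
#' @param target_groups named list of neuron-id vectors.
#' @param direction `"outputs"` or `"inputs"`.
#' @return data frame with columns `group`, `count`, `fraction`; fractions
#'   are `NA` (with a warning) when the source set has zero total.
#' @export
group_io_fractions <- function(matrix, source_ids, target_groups,
                               direction = c("outputs", "inputs")) {
  direction <- match.arg(direction)
  ids <- rownames(matrix)
  source_ids <- intersect(as.character(source_ids), ids)
  m <- unclass(matrix)
  total <- if (direction == "outputs") sum(m[source_ids, , drop = FALSE])
           else sum(m[, source_ids, drop = FALSE])
  counts <- vapply(target_groups, function(g) {
    g <- intersect(as.character(g), ids)
    if (direction == "outputs") sum(m[source_ids, g, drop = FALSE])
    else sum(m[g, source_ids, drop = FALSE])
  }, numeric(1))
  if (total == 0) {
    warning("source set has zero total ", direction, "; fractions undefined")
    frac <- rep(NA_real_, length(counts))
  } else frac <- counts / total
  data.frame(group = names(target_groups), count = counts, fraction = frac,
             row.names = NULL)
}

#' Cosine connectivity similarity
#'
#' One minus the cosine distance between row vectors (shared outputs) or
#' column vectors (shared inputs) of a binarized connectivity matrix. Pairs
#' involving an all-zero vector get similarity 0; their ids are recorded in
#' the `zero_units` attribute.
#'
#' @param binary 0/1 matrix (see [binarize()]).
#' @param axis `"outputs"` (rows) or `"inputs"` (columns).
#' @return symmetric similarity matrix in \[0, 1\].
#' @export
connectivity_similarity <- function(binary, axis = c("outputs", "inputs")) {
  axis <- match.arg(axis)
  stopifnot(is.matrix(binary), all(binary %in% c(0, 1)))
  v <- if (axis == "outputs") unclass(binary) else t(unclass(binary))
  nrm <- sqrt(rowSums(v^2))
  zero <- nrm == 0
  nrm[zero] <- 1
  s <- tcrossprod(v / nrm)
  s[zero, ] <- 0
  s[, zero] <- 0
  s <- pmin(pmax(s, 0), 1)
  attr(s, "axis") <- axis
  attr(s, "zero_units") <- rownames(v)[zero]
  s
}

#' Synaptic network distance
#'
#' Shortest path length, in synapses, between neurons in the binarized
#' connectivity graph. Directly connected pairs have distance 1; pairs
#' sharing a common input or output have distance 2 — the common-partner
#' reading forces direction-blind paths, so distances are computed on the
#' undirected support of the matrix. Unreachable pairs are `Inf`.
#'
#' @param binary 0/1 matrix (see [binarize()]).
#' @return symmetric numeric distance matrix (diagonal 0, `Inf` where
#'   unreachable).
#' @export
network_distance <- function(binary) {
  stopifnot(is.matrix(binary), all(binary %in% c(0, 1)))
  b <- unclass(binary)
  attr(b, "threshold") <- NULL
  g <- igraph::graph_from_adjacency_matrix(pmax(b, t(b)), mode = "undirected")
  d <- igraph::distances(g)
  dimnames(d) <- dimnames(binary)
  d
}

# Pair-category predicate tables -------------------------------------------

#' Within-cohort pair values under a developmental grouping
#'
#' Enumerates all unordered pairs of distinct units (neurons or bilateral
#' homolog pairs) that fall into one cohort of the requested grouping and
#' pools their pairwise metric values. Groupings: `hemilineage_temporal`
#' (same lineage, hemilineage and temporal group), `hemilineage_only` (same
#' lineage and hemilineage, different temporal group), `temporal_only` (same
#' temporal group, different hemilineage), `unrelated_same_hemisegment`
#' (different hemilineage and different temporal group). Only interneurons
#' with assigned labels participate; for neuron-level matrices pairs are
#' restricted to the same hemisegment; cohorts with fewer than two members
#' contribute no pairs.
#'
#' @param metric_matrix symmetric numeric matrix of pairwise scores whose
#'   dimnames are neuron ids or homolog-pair ids.
#' @param annotations an `annotation_table`.
#' @param grouping one of the four grouping kinds.
#' @return numeric vector of pooled pair values.
#' @export
grouping_pair_values <- function(metric_matrix, annotations,
                                 grouping = c("hemilineage_temporal",
                                              "hemilineage_only",
                                              "temporal_only",
                                              "unrelated_same_hemisegment")) {
  grouping <- match.arg(grouping)
  ids <- rownames(metric_matrix)
  stopifnot(!is.null(ids), identical(ids, colnames(metric_matrix)))
  ann <- resolve_units(ids, annotations)
  keep <- ann$cell_class == "interneuron" &
    ann$hemilineage %in% c("dorsal", "ventral") & !is.na(ann$temporal_group)
  ann <- ann[keep, , drop = FALSE]
  m <- metric_matrix[ann$unit, ann$unit, drop = FALSE]
  n <- nrow(ann)
  if (n < 2) return(numeric(0))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  same_seg <- is.na(ann$hemisegment[1]) |
    ann$hemisegment[i] == ann$hemisegment[j]
  same_hl <- ann$lineage[i] == ann$lineage[j] &
    ann$hemilineage[i] == ann$hemilineage[j]
  same_t <- ann$temporal_group[i] == ann$temporal_group[j]
  sel <- switch(grouping,
                hemilineage_temporal = same_hl & same_t,
                hemilineage_only = same_hl & !same_t,
                temporal_only = same_t & !same_hl,
                unrelated_same_hemisegment = !same_hl & !same_t)
  sel <- sel & same_seg
  m[cbind(i[sel], j[sel])]
}

# Map matrix units to annotation rows: neuron ids directly, homolog-pair ids
# via the left member (hemisegment then NA: pair units are side-averaged).
resolve_units <- function(ids, annotations) {
  a <- annotations
  if (all(ids %in% a$neuron_id)) {
    rows <- a[match(ids, a$neuron_id), , drop = FALSE]
    data.frame(unit = ids, lineage = rows$lineage,
               hemilineage = rows$hemilineage,
               temporal_group = rows$temporal_group,
               hemisegment = rows$hemisegment,
               cell_class = rows$cell_class, stringsAsFactors = FALSE)
  } else if (all(ids %in% a$homolog_id)) {
    left <- a[a$hemisegment == "left", , drop = FALSE]
    rows <- left[match(ids, left$homolog_id), , drop = FALSE]
    data.frame(unit = ids, lineage = rows$lineage,
               hemilineage = rows$hemilineage,
               temporal_group = rows$temporal_group,
               hemisegment = NA_character_,
               cell_class = rows$cell_class, stringsAsFactors = FALSE)
  } else {
    stop("matrix dimnames are neither neuron ids nor homolog-pair ids")
  }
}

#' Compare a pairwise metric across developmental groupings
#'
#' Pools within-cohort pair values for each requested grouping, summarizes
#' them (n, mean, median, SEM), pre-checks normality with a one-sample
#' Kolmogorov-Smirnov test against a fitted normal, and compares every pair
#' of groupings with a two-sided Wilcoxon rank-sum test plus a two-sample
#' Kolmogorov-Smirnov test on the empirical distributions.
#'
#' @inheritParams grouping_pair_values
#' @param groupings character vector of grouping kinds to compare.
#' @return an object of class `cohort_comparison`: `summary` and `tests`
#'   data frames plus the pooled `values` per grouping.
#' @export
cohort_comparison <- function(metric_matrix, annotations,
                              groupings = c("hemilineage_temporal",
                                            "hemilineage_only",
                                            "temporal_only",
                                            "unrelated_same_hemisegment")) {
  values <- lapply(stats::setNames(groupings, groupings), function(g)
    grouping_pair_values(metric_matrix, annotations, g))
  summ <- do.call(rbind, lapply(groupings, function(g) {
    v <- values[[g]]
    norm_p <- if (length(v) >= 3 && stats::sd(v) > 0)
      suppressWarnings(stats::ks.test(v, "pnorm", mean(v),
                                      stats::sd(v))$p.value)
    else NA_real_
    data.frame(grouping = g, n_pairs = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               median = if (length(v)) stats::median(v) else NA_real_,
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                     else NA_real_,
               normality_ks_p = norm_p, row.names = NULL)
  }))
  combs <- utils::combn(groupings, 2)
  tests <- do.call(rbind, lapply(seq_len(ncol(combs)), function(k) {
    ga <- combs[1, k]; gb <- combs[2, k]
    va <- values[[ga]]; vb <- values[[gb]]
    ok <- length(va) >= 2 && length(vb) >= 2
    data.frame(grouping_a = ga, grouping_b = gb,
               wilcoxon_p = if (ok) suppressWarnings(
                 stats::wilcox.test(va, vb)$p.value) else NA_real_,
               ks_p = if (ok) suppressWarnings(
                 stats::ks.test(va, vb)$p.value) else NA_real_,
               ks_stat = if (ok) suppressWarnings(
                 unname(stats::ks.test(va, vb)$statistic)) else NA_real_,
               row.names = NULL)
  }))
  structure(list(summary = summ, tests = tests, values = values),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat("<cohort_comparison>\n")
  print(x$summary, digits = 4)
  cat("\npairwise tests:\n")
  print(x$tests, digits = 4)
  invisible(x)
}
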