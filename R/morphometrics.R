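#' Strahler order of skeleton nodes
#'
#' Leaves have order 1; a parent has order m + 1 when at least two children
#' attain the maximal child order m, otherwise it inherits m. Orders never
#' decrease toward the root, so any superlevel set of orders is a connected
#' subtree containing the root.
#'
#' @param sk a `skeleton`.
#' @return named integer vector, one order per node id.
#' @export
strahler_order <- function(sk) {
  stopifnot(inherits(sk, "skeleton"))
  kids <- skeleton_children(sk)
  ord <- integer(nrow(sk$nodes))
  for (i in rev(skeleton_bfs_order(sk))) {
    ch <- kids[[i]]
    if (!length(ch)) {
      ord[i] <- 1L
    } else {
      m <- max(ord[ch])
      ord[i] <- if (sum(ord[ch] == m) >= 2L) m + 1L else m
    }
  }
  names(ord) <- sk$nodes$node_id
  ord
}

#' Prune a skeleton by Strahler order
#'
#' Removes the most distal twigs: keeps the subtree of nodes whose Strahler
#' order is at least `keep_min_order`. The root is always retained.
#'
#' @param sk a `skeleton`.
#' @param keep_min_order minimum order to keep (>= 1).
#' @return a pruned `skeleton`. If `keep_min_order` exceeds the maximum order
#'   the root-only skeleton is returned with a warning.
#' @export
prune_by_strahler <- function(sk, keep_min_order = 2L) {
  stopifnot(inherits(sk, "skeleton"), keep_min_order >= 1)
  ord <- strahler_order(sk)
  if (keep_min_order > max(ord)) {
    warning("keep_min_order ", keep_min_order, " exceeds maximum Strahler ",
            "order ", max(ord), "; returning root-only skeleton")
    keep <- sk$nodes$node_id == sk$root
  } else {
    keep <- ord >= keep_min_order
    keep[sk$nodes$node_id == sk$root] <- TRUE
  }
  skeleton(sk$neuron_id, sk$nodes[keep, , drop = FALSE])
}

#' Neuropil entry point and cortex neurite length
#'
#' The neuropil entry point is the skeleton node inside the neuropil volume
#' with the smallest geodesic (along-the-arbor) distance from the soma root.
#' The cortex neurite length is that geodesic distance in nm; it proxies
#' birth order, since later-born somata are displaced further from the
#' neuropil and their entry neurite is correspondingly longer.
#'
#' @param sk a `skeleton`.
#' @param volume a `neuropil_volume`.
#' @return `neuropil_entry()`: the entry node id, or `NA` if no node lies in
#'   the volume. `cortex_neurite_length()`: length in nm, or `NA`.
#' @export
neuropil_entry <- function(sk, volume) {
  stopifnot(inherits(sk, "skeleton"))
  inside <- volume_contains(volume, as.matrix(sk$nodes[c("x", "y", "z")]))
  if (!any(inside)) return(sk$nodes$node_id[NA_integer_])
  g <- root_geodesics(sk)
  idx <- which(inside)
  sk$nodes$node_id[idx[which.min(g[idx])]]
}

#' @rdname neuropil_entry
#' @export
cortex_neurite_length <- function(sk, volume) {
  entry <- neuropil_entry(sk, volume)
  if (is.na(entry)) return(NA_real_)
  g <- root_geodesics(sk)
  g[match(entry, sk$nodes$node_id)]
}

#' Mean of left/right homolog cortex neurite lengths
#'
#' Bilateral homologs give two measurements of one developmental quantity;
#' the per-neuron value is their mean. A missing side propagates the other
#' side's value with a warning; two missing sides give `NA`.
#'
#' @param left,right lengths in nm (possibly `NA`).
#' @return numeric vector of means.
#' @export
bilateral_mean_length <- function(left, right) {
  stopifnot(length(left) == length(right))
  out <- (left + right) / 2
  one <- xor(is.na(left), is.na(right))
  if (any(one)) {
    warning(sum(one), " homolog pair(s) with a single measured side; ",
            "using the available side")
    out[one] <- ifelse(is.na(left[one]), right[one], left[one])
  }
  out
}

#' Temporal-cohort bin boundaries from reference cell measurements
#'
#' Cortex neurite lengths of identified early-marker-positive (Hb+) and
#' late-marker-positive (Cas+) reference cells define four birth-order bins:
#' `t1 = mean(hb) + sd(hb)`, `t2 = mean(cas) - sd(cas)`, `t3 = mean(cas)`,
#' with the sample (n - 1) standard deviation. Construction fails when the
#' reference distributions overlap so much that `t1 > t2`, since four ordered
#' bins then do not exist.
#'
#' @param hb_lengths,cas_lengths numeric vectors of reference cortex neurite
#'   lengths (nm), each of length >= 2.
#' @return an object of class `temporal_binning` with elements `t1`, `t2`,
#'   `t3` and the reference sample sizes.
#' @examples
#' fit_temporal_bins(c(10, 12, 14), c(30, 34, 38))
#' @export
fit_temporal_bins <- function(hb_lengths, cas_lengths) {
  stopifnot(length(hb_lengths) >= 2, length(cas_lengths) >= 2,
            all(is.finite(hb_lengths)), all(is.finite(cas_lengths)))
  t1 <- mean(hb_lengths) + stats::sd(hb_lengths)
  t2 <- mean(cas_lengths) - stats::sd(cas_lengths)
  t3 <- mean(cas_lengths)
  if (t1 > t2)
    stop(sprintf(paste0("reference distributions overlap: t1 = %.4g > ",
                        "t2 = %.4g; four temporal bins are not defined"),
                 t1, t2))
  structure(list(t1 = t1, t2 = t2, t3 = t3,
                 n_hb = length(hb_lengths), n_cas = length(cas_lengths)),
            class = "temporal_binning")
}

#' @export
print.temporal_binning <- function(x, ...) {
  cat(sprintf(paste0("<temporal_binning> t1 = %.4g, t2 = %.4g, t3 = %.4g nm ",
                     "(n_hb = %d, n_cas = %d)\n"),
              x$t1, x$t2, x$t3, x$n_hb, x$n_cas))
  invisible(x)
}

#' Assign temporal groups from cortex neurite length
#'
#' Group 1: `L < t1`; group 2: `t1 <= L <= t2`; group 3: `t2 < L <= t3`;
#' group 4: `L > t3`. The assignment is exhaustive and monotone in `L`.
#'
#' @param length cortex neurite length(s) in nm.
#' @param bins a `temporal_binning`.
#' @return integer group(s) in 1-4 (`NA` in, `NA` out).
#' @export
assign_temporal_group <- function(length, bins) {
  stopifnot(inherits(bins, "temporal_binning"))
  g <- ifelse(length < bins$t1, 1L,
              ifelse(length <= bins$t2, 2L,
                     ifelse(length <= bins$t3, 3L, 4L)))
  as.integer(g)
}

# Unbranched chains of node positions: each chain runs from the root or a
# branch point down to the next leaf or branch point (inclusive), covering
# every edge exactly once.
skeleton_chains <- function(sk) {
  kids <- skeleton_children(sk)
  n_kids <- lengths(kids)
  root_pos <- match(sk$root, sk$nodes$node_id)
  anchors <- unique(c(root_pos, which(n_kids >= 2L)))
  chains <- list()
  for (a in anchors) {
    for (c0 in kids[[a]]) {
      chain <- c(a, c0)
      i <- c0
      while (n_kids[i] == 1L) {
        i <- kids[[i]][1]
        chain <- c(chain, i)
      }
      chains[[length(chains) + 1L]] <- chain
    }
  }
  if (!length(chains)) chains <- list(root_pos)
  chains
}

# Resample a polyline (matrix of points) at uniform arc-length spacing.
resample_polyline <- function(xyz, spacing) {
  seg <- sqrt(rowSums((xyz[-1, , drop = FALSE] -
                         xyz[-nrow(xyz), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total == 0) return(xyz[1, , drop = FALSE])
  at <- seq(0, total, by = spacing)
  if (total - at[length(at)] > 1e-9) at <- c(at, total)
  out <- sapply(1:3, function(j) stats::approx(s, xyz[, j], xout = at,
                                               ties = "ordered")$y)
  matrix(out, ncol = 3)
}

#' Convert a skeleton to a dotprops point cloud
#'
#' Resamples the arbor cable at uniform arc-length spacing and attaches to
#' each point a unit tangent: the dominant principal direction of its `k`
#' nearest resampled points (fewer when fewer exist). Tangent sign is
#' arbitrary and ignored downstream.
#'
#' @param sk a `skeleton` with at least 2 nodes.
#' @param spacing resampling step in nm.
#' @param k neighborhood size for the local tangent.
#' @return an object of class `dotprops` with matrices `points` and
#'   `tangents` (rows aligned).
#' @export
to_dotprops <- function(sk, spacing = 1000, k = 5L) {
  stopifnot(inherits(sk, "skeleton"), nrow(sk$nodes) >= 2, spacing > 0, k >= 1)
  xyz <- as.matrix(sk$nodes[c("x", "y", "z")])
  pts <- do.call(rbind, lapply(skeleton_chains(sk), function(ch)
    resample_polyline(xyz[ch, , drop = FALSE], spacing)))
  pts <- unique(pts)
  n <- nrow(pts)
  d2 <- as.matrix(stats::dist(pts))^2
  tang <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    nb <- order(d2[i, ])[seq_len(min(k, n))]
    p <- pts[nb, , drop = FALSE]
    p <- sweep(p, 2, colMeans(p))
    v <- svd(p, nu = 0, nv = 1)$v[, 1]
    tang[i, ] <- v / sqrt(sum(v^2))
  }
  structure(list(points = pts, tangents = tang,
                 spacing = spacing, k_neighbors = as.integer(k)),
            class = "dotprops")
}

#' Morphological similarity of two dotprops clouds
#'
#' For every query point the nearest target point contributes
#' `exp(-d^2 / (2 sigma_n^2)) * |u . v|`, the product of a Gaussian distance
#' kernel and the absolute tangent alignment. The raw sum is normalized by
#' the query's raw self-score, so a cloud scores exactly 1 against itself.
#' The score is asymmetric in general.
#'
#' @param query,target `dotprops` objects.
#' @param sigma_n distance bandwidth in nm.
#' @param normalize divide by the query self-score (default `TRUE`).
#' @return non-negative similarity score; normalized scores lie in \[0, 1\].
#' @export
morph_similarity <- function(query, target, sigma_n = 2000, normalize = TRUE) {
  stopifnot(inherits(query, "dotprops"), inherits(target, "dotprops"),
            nrow(query$points) > 0, nrow(target$points) > 0, sigma_n > 0)
  d2 <- cross_dist2(query$points, target$points)
  nn <- max.col(-d2, ties.method = "first")
  dmin2 <- d2[cbind(seq_len(nrow(d2)), nn)]
  align <- abs(rowSums(query$tangents * target$tangents[nn, , drop = FALSE]))
  raw <- sum(exp(-dmin2 / (2 * sigma_n^2)) * align)
  if (!normalize) return(raw)
  raw / nrow(query$points)  # raw self-score: every point matches itself
}

# Squared Euclidean cross-distance matrix between rows of a and b.
cross_dist2 <- function(a, b) {
  m <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  m[m < 0] <- 0
  m
}

#' Cluster neurons into hemilineages from morphological similarity
#'
#' Converts a pairwise normalized similarity matrix into the symmetric
#' distance `1 - (S + t(S)) / 2`, applies average-linkage hierarchical
#' clustering, and cuts the dendrogram at `height_cutoff`. Within one
#' neuroblast lineage the two largest morphological divisions are the dorsal
#' and ventral hemilineages.
#'
#' @param score_matrix square matrix of pairwise normalized similarity scores
#'   with neuron ids as dimnames.
#' @param height_cutoff dendrogram cut height. The default 0.65 was
#'   calibrated on the synthetic two-hemilineage fixture, where cutting
#'   anywhere on the wide plateau 0.6-0.75 recovers exactly the two
#'   hemilineages; it corresponds to merging groups whose mean mutual
#'   similarity exceeds 0.35.
#' @return named integer cluster labels with attributes `n_clusters` and
#'   `hclust` (the dendrogram).
#' @export
cluster_hemilineages <- function(score_matrix, height_cutoff = 0.65) {
  stopifnot(is.matrix(score_matrix), nrow(score_matrix) == ncol(score_matrix))
  if (nrow(score_matrix) == 1L) {
    lab <- stats::setNames(1L, rownames(score_matrix))
    attr(lab, "n_clusters") <- 1L
    return(lab)
  }
  d <- 1 - (score_matrix + t(score_matrix)) / 2
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  lab <- stats::cutree(hc, h = height_cutoff)
  attr(lab, "n_clusters") <- length(unique(lab))
  attr(lab, "hclust") <- hc
  lab
}
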