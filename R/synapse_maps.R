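#' Spatial synapse-similarity kernel
#'
#' Compares the 3D positions of two synapse point sets. For each synapse s of
#' set A, let k be the nearest synapse of set B (Euclidean distance, ties to
#' the lowest index) at distance `d_sk`, and let `n_is` and `n_jk` be the
#' fractions of A's (respectively B's) synapses within `omega` of s
#' (respectively k), each synapse counting itself so both fractions are
#' positive. The per-synapse kernel is
#' `f = exp(-d_sk^2 / (2 sigma^2)) * exp(-|n_is - n_jk| / (n_is + n_jk))`:
#' a Gaussian penalty on distance times a penalty on mismatched local synapse
#' density. The directed score is the mean of f over A's synapses; the
#' symmetric score is the mean of the two directed scores. Defaults
#' `sigma = omega = 2000` nm.
#'
#' @param syn_a,syn_b numeric matrices of synapse positions (columns x, y, z
#'   in nm), both non-empty.
#' @param sigma Gaussian bandwidth in nm.
#' @param omega neighborhood radius in nm for the density fractions.
#' @param symmetric return the mean of the two directed scores?
#' @return score in (0, 1]; identical sets score exactly 1.
#' @examples
#' a <- matrix(c(0, 0, 0), 1)
#' b <- matrix(c(2000, 0, 0), 1)
#' synapse_similarity(a, b)  # exp(-0.5)
#' @export
synapse_similarity <- function(syn_a, syn_b, sigma = 2000, omega = 2000,
                               symmetric = FALSE) {
  syn_a <- as_point_matrix(syn_a)
  syn_b <- as_point_matrix(syn_b)
  if (!nrow(syn_a) || !nrow(syn_b))
    stop("synapse_similarity requires non-empty point sets")
  stopifnot(sigma > 0, omega > 0)
  fa <- neighbor_fraction(syn_a, omega)
  fb <- neighbor_fraction(syn_b, omega)
  ab <- syn_sim_directed(syn_a, syn_b, fa, fb, sigma)
  if (!symmetric) return(ab)
  (ab + syn_sim_directed(syn_b, syn_a, fb, fa, sigma)) / 2
}

as_point_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3L)
  x <- as.matrix(x)
  stopifnot(ncol(x) == 3)
  storage.mode(x) <- "double"
  x
}

# Fraction of the set's own synapses within omega of each synapse (self
# included, so fractions are strictly positive).
neighbor_fraction <- function(pts, omega) {
  d2 <- cross_dist2(pts, pts)
  rowMeans(d2 <= omega^2)
}

syn_sim_directed <- function(a, b, frac_a, frac_b, sigma) {
  d2 <- cross_dist2(a, b)
  nn <- max.col(-d2, ties.method = "first")
  dmin2 <- d2[cbind(seq_len(nrow(a)), nn)]
  njk <- frac_b[nn]
  mean(exp(-dmin2 / (2 * sigma^2)) *
         exp(-abs(frac_a - njk) / (frac_a + njk)))
}

#' Pre/post synaptic overlap score
#'
#' The synapse-similarity kernel applied between the presynapses of one
#' neuron and the postsynapses of another: a proximity proxy for potential
#' connectivity. The score is asymmetric. An empty point set yields 0 by
#' convention, with a message.
#'
#' @param pre_a presynapse positions of the source neuron (matrix, nm).
#' @param post_b postsynapse positions of the target neuron.
#' @inheritParams synapse_similarity
#' @return score in \[0, 1\].
#' @export
overlap_score <- function(pre_a, post_b, sigma = 2000, omega = 2000) {
  pre_a <- as_point_matrix(pre_a)
  post_b <- as_point_matrix(post_b)
  if (!nrow(pre_a) || !nrow(post_b)) {
    message("empty pre- or postsynapse set: overlap score 0 by convention")
    return(0)
  }
  synapse_similarity(pre_a, post_b, sigma = sigma, omega = omega)
}

#' Average a score over the left and right hemisegments
#'
#' Bilateral homolog pairs give one measurement per side; the reported score
#' is their mean. A single missing side propagates the measured side with a
#' warning; two missing sides give `NA`.
#'
#' @param score_left,score_right numeric scores (possibly `NA`).
#' @return numeric vector of means.
#' @export
bilateral_average <- function(score_left, score_right) {
  stopifnot(length(score_left) == length(score_right))
  out <- (score_left + score_right) / 2
  one <- xor(is.na(score_left), is.na(score_right))
  if (any(one)) {
    warning(sum(one), " pair(s) scored on a single side")
    out[one] <- ifelse(is.na(score_left[one]), score_right[one],
                       score_left[one])
  }
  out
}

#' Pairwise synapse-similarity matrix over bilateral homolog pairs
#'
#' Computes, for every ordered pair of homolog neuron pairs, the directed
#' synapse-similarity (or pre/post overlap) score on the left and right
#' hemisegments and averages the two sides. `mode` selects which point sets
#' are compared: `pre_pre` presynapses vs presynapses, `post_post`
#' postsynapses vs postsynapses, `pre_post` presynapses of the row neuron vs
#' postsynapses of the column neuron. Neurons lacking a homolog partner or
#' the required synapse polarity on either side are excluded with a message.
#'
#' @param connectors a `connector_table`.
#' @param annotations an `annotation_table`; only rows with a `homolog_id`
#'   participate.
#' @param mode one of `"pre_pre"`, `"post_post"`, `"pre_post"`.
#' @param neuron_ids optional subset of neuron ids to consider.
#' @inheritParams synapse_similarity
#' @return square numeric matrix over homolog pair ids, with attributes
#'   `mode`, `sigma`, `omega` and `members` (the id pairs behind each row).
#' @export
similarity_matrix <- function(connectors, annotations,
                              mode = c("pre_pre", "post_post", "pre_post"),
                              neuron_ids = NULL, sigma = 2000, omega = 2000) {
  mode <- match.arg(mode)
  a <- annotations
  if (!is.null(neuron_ids)) a <- a[a$neuron_id %in% neuron_ids, , drop = FALSE]
  a <- a[!is.na(a$homolog_id), , drop = FALSE]
  pairs <- split(a$neuron_id[order(a$hemisegment)], a$homolog_id[order(a$hemisegment)])
  pairs <- pairs[lengths(pairs) == 2L]  # left, right (alphabetical order)

  need_pre <- mode %in% c("pre_pre", "pre_post")
  need_post <- mode %in% c("post_post", "pre_post")
  pre_sets <- post_sets <- list()
  for (id in unlist(pairs)) {
    if (need_pre) pre_sets[[id]] <- presynapse_points(connectors, id)
    if (need_post) post_sets[[id]] <- postsynapse_points(connectors, id)
  }
  has_pts <- vapply(pairs, function(ids) {
    ok <- TRUE
    if (need_pre) ok <- ok && all(vapply(pre_sets[ids], nrow, 1L) > 0)
    if (need_post) ok <- ok && all(vapply(post_sets[ids], nrow, 1L) > 0)
    ok
  }, logical(1))
  if (any(!has_pts))
    message(sum(!has_pts), " homolog pair(s) lacking required synapses ",
            "excluded from ", mode, " similarity matrix")
  pairs <- pairs[has_pts]
  np <- length(pairs)
  ids <- names(pairs)
  out <- matrix(NA_real_, np, np, dimnames = list(ids, ids))
  if (!np) return(out)

  # precompute per-neuron neighborhood fractions once
  row_sets <- if (need_pre) pre_sets else post_sets
  col_sets <- if (mode == "pre_pre") pre_sets else post_sets
  frac_row <- lapply(row_sets, neighbor_fraction, omega = omega)
  frac_col <- lapply(col_sets, neighbor_fraction, omega = omega)

  for (i in seq_len(np)) {
    for (j in seq_len(np)) {
      sides <- vapply(1:2, function(s) {
        ia <- pairs[[i]][s]; jb <- pairs[[j]][s]
        syn_sim_directed(row_sets[[ia]], col_sets[[jb]],
                         frac_row[[ia]], frac_col[[jb]], sigma)
      }, numeric(1))
      out[i, j] <- mean(sides)
    }
  }
  attr(out, "mode") <- mode
  attr(out, "sigma") <- sigma
  attr(out, "omega") <- omega
  attr(out, "members") <- pairs
  out
}

#' Kernel density map of synapse positions
#'
#' Gaussian product-kernel density estimate of synapse positions projected
#' onto the transverse (mediolateral, dorsoventral) plane, with optional
#' polyadic weighting (each presynaptic connector counted once per
#' postsynaptic partner) and an optional anteroposterior window restricting
#' which synapses enter the map. The outermost contour is placed at the
#' density level whose superlevel set is the smallest containing
#' `contour_fraction` of the total mass (60% for hemilineage maps, 80% for
#' lineage maps). 1D marginal KDEs along both axes are included.
#'
#' @param synapses matrix of synapse positions (columns x, y, z in nm).
#' @param weights optional non-negative weights, one per synapse (polyadic
#'   partner counts); `NULL` for uniform.
#' @param bandwidth `"scott"` (per-axis Scott's rule) or a numeric length-2
#'   bandwidth (nm) for the (x, y) axes.
#' @param contour_fraction probability mass enclosed by the outermost
#'   contour, in (0, 1\].
#' @param ap_window optional numeric length-2 anteroposterior (z) range;
#'   synapses outside it are dropped before estimation.
#' @param gridsize number of grid points per axis.
#' @return an object of class `density_map`: grid coordinates `x`, `y`,
#'   density matrix `z` (integrates to 1), `contour_level`, marginals, and
#'   the settings used.
#' @export
density_map <- function(synapses, weights = NULL, bandwidth = "scott",
                        contour_fraction = 0.6, ap_window = NULL,
                        gridsize = 128L) {
  pts <- as_point_matrix(synapses)
  if (is.null(weights)) {
    w <- attr(synapses, "weights")
    weights <- if (is.null(w)) rep(1, nrow(pts)) else w
    weights_policy <- if (is.null(w)) "uniform" else "polyadic"
  } else {
    weights_policy <- "polyadic"
  }
  stopifnot(length(weights) == nrow(pts), all(weights >= 0),
            contour_fraction > 0, contour_fraction <= 1)
  if (!is.null(ap_window)) {
    keep <- pts[, 3] >= ap_window[1] & pts[, 3] <= ap_window[2]
    pts <- pts[keep, , drop = FALSE]
    weights <- weights[keep]
  }
  if (nrow(pts) < 2) stop("density_map needs at least 2 synapses in window")
  w <- weights / sum(weights)
  xy <- pts[, 1:2, drop = FALSE]
  n_eff <- sum(weights)^2 / sum(weights^2)
  wsd <- vapply(1:2, function(j) {
    mu <- sum(w * xy[, j])
    sqrt(sum(w * (xy[, j] - mu)^2))
  }, numeric(1))
  degenerate <- all(wsd == 0)
  if (degenerate) {
    warning("all synapse positions identical: point-mass density map")
    h <- c(1, 1)
  } else if (identical(bandwidth, "scott")) {
    h <- pmax(wsd, max(wsd) * 1e-3) * n_eff^(-1 / 6)
  } else {
    stopifnot(is.numeric(bandwidth), length(bandwidth) == 2, all(bandwidth > 0))
    h <- bandwidth
  }
  gx <- seq(min(xy[, 1]) - 3 * h[1], max(xy[, 1]) + 3 * h[1],
            length.out = gridsize)
  gy <- seq(min(xy[, 2]) - 3 * h[2], max(xy[, 2]) + 3 * h[2],
            length.out = gridsize)
  cell <- diff(gx)[1] * diff(gy)[1]
  if (degenerate) {
    z <- matrix(0, gridsize, gridsize)
    z[which.min(abs(gx - xy[1, 1])), which.min(abs(gy - xy[1, 2]))] <-
      1 / cell
  } else {
    # product Gaussian kernels: z = Kx' diag(w) Ky
    kx <- stats::dnorm(outer(xy[, 1], gx, "-") / h[1]) / h[1]
    ky <- stats::dnorm(outer(xy[, 2], gy, "-") / h[2]) / h[2]
    z <- crossprod(kx, w * ky)
    total <- sum(z) * cell
    if (total > 0) z <- z / total
  }
  # smallest superlevel set holding contour_fraction of the mass
  ord <- order(z, decreasing = TRUE)
  cum <- cumsum(z[ord]) * cell
  level <- z[ord][which(cum >= contour_fraction)[1]]
  marg <- function(v) stats::density(v, weights = w,
                                     bw = stats::bw.nrd0(v) + 1e-12)
  structure(list(x = gx, y = gy, z = z,
                 bandwidth = h, contour_level = level,
                 contour_fraction = contour_fraction,
                 weights_policy = weights_policy,
                 n_synapses = nrow(pts), n_effective = n_eff,
                 marginal_x = if (!degenerate) marg(xy[, 1]),
                 marginal_y = if (!degenerate) marg(xy[, 2])),
            class = "density_map")
}

#' Contour polygons of a density map
#'
#' @param map a `density_map`.
#' @param level contour level; default the map's outermost-contour level.
#' @return list of polygons as returned by [grDevices::contourLines()].
#' @export
density_contours <- function(map, level = map$contour_level) {
  stopifnot(inherits(map, "density_map"))
  grDevices::contourLines(map$x, map$y, map$z, levels = level)
}

# Probability mass of the superlevel set at a given density level.
contour_mass <- function(map, level = map$contour_level) {
  cell <- diff(map$x)[1] * diff(map$y)[1]
  sum(map$z[map$z >= level]) * cell
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf(paste0("<density_map> %d synapses (%s weights), bandwidth ",
                     "(%.0f, %.0f) nm, %.0f%% contour at %.3g\n"),
              x$n_synapses, x$weights_policy, x$bandwidth[1], x$bandwidth[2],
              100 * x$contour_fraction, x$contour_level))
  invisible(x)
}

#' @export
plot.density_map <- function(x, ..., contour = TRUE) {
  graphics::image(x$x, x$y, x$z, col = grDevices::hcl.colors(64, "YlOrRd",
                                                             rev = TRUE),
                  xlab = "mediolateral (nm)", ylab = "dorsoventral (nm)", ...)
  if (contour)
    graphics::contour(x$x, x$y, x$z, levels = x$contour_level, add = TRUE,
                      drawlabels = FALSE)
  invisible(x)
}
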