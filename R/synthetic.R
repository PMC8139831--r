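#' Configuration of the synthetic connectome generator
#'
#' The generator emulates the developmental architecture of a larval ventral
#' nerve cord hemisegment pair: `n_lineages` neuroblast lineages, each split
#' into a dorsal and a ventral hemilineage, each hemilineage producing
#' `temporal_groups_per_hemilineage` temporal cohorts of `neurons_per_hlt`
#' neurons; somata sit in a cortex shell outside the neuropil with the
#' soma-to-neuropil neurite length increasing with birth order; dorsal
#' hemilineages cluster their presynapses (ventral ones their postsynapses)
#' around cohort-specific Gaussian centers in the dorsal (ventral) half of
#' the neuropil; polyadic connectors pick their postsynaptic partners with
#' probability proportional to pre/post spatial overlap times `1 + hlt_bonus`
#' for designated cohort pairs; and the right hemisegment is the x-mirrored
#' copy of the left with Gaussian jitter. Sensory neurons (purely ventral
#' presynapses) and motor neurons (purely dorsal postsynapses) are added as
#' extra cell classes.
#'
#' @param n_lineages number of neuroblast lineages per hemisegment.
#' @param temporal_groups_per_hemilineage temporal cohorts per hemilineage
#'   (at most 4).
#' @param neurons_per_hlt neurons per hemilineage-temporal cohort.
#' @param neuropil a `neuropil_volume` (default an ellipsoid with semi-axes
#'   40, 25 and 60 um in x, y, z).
#' @param cortex_shell_thickness radial depth of the soma cortex (nm); the
#'   latest-born cohort sits at its outer edge.
#' @param radial_noise_sd per-neuron noise on the radial soma position (nm).
#' @param cluster_sd spread of a cohort's synapse cloud (nm).
#' @param presyn_per_neuron,postsyn_per_neuron mean synapse counts; actual
#'   counts are `1 + Poisson(mean - 1)` so every neuron keeps at least one
#'   synapse of each polarity it owns.
#' @param polyadic_mean mean postsynaptic partners per connector (>= 1);
#'   counts are `1 + Poisson(polyadic_mean - 1)`.
#' @param base_connection_scale probability in (0, 1] that a presynaptic
#'   site is realized as a connector at all.
#' @param hlt_bonus multiplicative connection bonus epsilon >= 0 applied on
#'   designated cohort pairs (weight `1 + hlt_bonus`).
#' @param designated_partners_per_cohort designated partner cohorts drawn
#'   per hemilineage-temporal cohort (mirrored to the right side).
#' @param mirror_jitter_sd per-coordinate Gaussian jitter of the mirrored
#'   right hemisegment (nm).
#' @param n_sensory,n_motor sensory and motor neurons per hemisegment.
#' @param n_reference identified early-marker (Hb+) and late-marker (Cas+)
#'   reference cells whose cortex neurite lengths calibrate temporal bins.
#' @param seed integer RNG seed; the whole connectome is reproducible from
#'   it.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_lineages = 7L,
                             temporal_groups_per_hemilineage = 4L,
                             neurons_per_hlt = 4L,
                             neuropil = neuropil_ellipsoid(
                               radii = c(40000, 25000, 60000)),
                             cortex_shell_thickness = 20000,
                             radial_noise_sd = 1000,
                             cluster_sd = 6000,
                             presyn_per_neuron = 8,
                             postsyn_per_neuron = 20,
                             polyadic_mean = 1.3,
                             base_connection_scale = 1,
                             hlt_bonus = 4,
                             designated_partners_per_cohort = 4L,
                             mirror_jitter_sd = 500,
                             n_sensory = 6L,
                             n_motor = 6L,
                             n_reference = 80L,
                             seed = 1L) {
  stopifnot(n_lineages >= 1, temporal_groups_per_hemilineage >= 1,
            temporal_groups_per_hemilineage <= 4, neurons_per_hlt >= 1,
            inherits(neuropil, "neuropil_volume"),
            cortex_shell_thickness > 0, radial_noise_sd >= 0, cluster_sd > 0,
            presyn_per_neuron >= 1, postsyn_per_neuron >= 1,
            polyadic_mean >= 1, base_connection_scale > 0,
            base_connection_scale <= 1, hlt_bonus >= 0,
            designated_partners_per_cohort >= 0, mirror_jitter_sd >= 0,
            n_sensory >= 1, n_motor >= 1, n_reference >= 2, seed == round(seed))
  half_y <- diff(volume_bbox(neuropil)[, 2]) / 2
  # dorsal cloud centers sit at >= 0.35 * half_y above the midline (ventral
  # below), so the dorsal/ventral separation is >= 0.7 * half_y
  if (0.7 * half_y <= 2 * cluster_sd)
    stop("neuropil too small to separate dorsal and ventral synapse clouds ",
         "by more than 2 * cluster_sd")
  structure(list(n_lineages = as.integer(n_lineages),
                 temporal_groups_per_hemilineage =
                   as.integer(temporal_groups_per_hemilineage),
                 neurons_per_hlt = as.integer(neurons_per_hlt),
                 neuropil = neuropil,
                 cortex_shell_thickness = cortex_shell_thickness,
                 radial_noise_sd = radial_noise_sd,
                 cluster_sd = cluster_sd,
                 presyn_per_neuron = presyn_per_neuron,
                 postsyn_per_neuron = postsyn_per_neuron,
                 polyadic_mean = polyadic_mean,
                 base_connection_scale = base_connection_scale,
                 hlt_bonus = hlt_bonus,
                 designated_partners_per_cohort =
                   as.integer(designated_partners_per_cohort),
                 mirror_jitter_sd = mirror_jitter_sd,
                 n_sensory = as.integer(n_sensory),
                 n_motor = as.integer(n_motor),
                 n_reference = as.integer(n_reference),
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  n_int <- x$n_lineages * 2 * x$temporal_groups_per_hemilineage *
    x$neurons_per_hlt * 2
  cat(sprintf(paste0("<generator_config> %d lineages x 2 hemilineages x %d ",
                     "temporal groups x %d neurons x 2 sides = %d ",
                     "interneurons (+ %d sensory, %d motor per side), ",
                     "hlt_bonus %.1f, seed %d\n"),
              x$n_lineages, x$temporal_groups_per_hemilineage,
              x$neurons_per_hlt, n_int, x$n_sensory, x$n_motor,
              x$hlt_bonus, x$seed))
  invisible(x)
}

# Serialize / restore a generator_config (JSON-safe plain list).
config_to_list <- function(config) {
  out <- unclass(config)
  out$neuropil <- unclass(out$neuropil)
  out
}

config_from_list <- function(x) {
  x$neuropil <- neuropil_from_list(x$neuropil)
  do.call(generator_config, x)
}

# Point on the (slightly shrunk) ellipsoid-equivalent surface of the volume
# in unit-direction w (components on the unit sphere of scaled coordinates).
surface_point <- function(half, w) {
  w <- w / sqrt(sum(w^2))
  w * half * 0.998
}

# Draw one cloud center inside `volume`, rejection-sampled within the given
# coordinate windows (fractions of the half-extents).
draw_center <- function(volume, half, xw, yw, zw) {
  xw <- sort(xw); yw <- sort(yw); zw <- sort(zw)
  for (k in 1:200) {
    p <- c(stats::runif(1, xw[1], xw[2]) * half[1],
           stats::runif(1, yw[1], yw[2]) * half[2],
           stats::runif(1, zw[1], zw[2]) * half[3])
    if (sum((p / half)^2) <= 0.85^2) return(p)
  }
  stop("could not place a synapse-cloud center inside the neuropil")
}

# Straight polyline from a to b with n_seg segments (returns n_seg+1 points).
subdivide <- function(a, b, n_seg) {
  t <- seq(0, 1, length.out = n_seg + 1)
  outer(1 - t, a) + outer(t, b)
}

# Assemble a skeleton data frame from an ordered point matrix along the main
# path plus branch arms attached at the last path point.
path_skeleton <- function(neuron_id, path_pts, arms = list(), radius = 100) {
  pts <- path_pts
  parent <- c(NA, seq_len(nrow(path_pts) - 1))
  attach_at <- nrow(path_pts)
  for (arm in arms) {
    base <- attach_at
    for (r in seq_len(nrow(arm))) {
      pts <- rbind(pts, arm[r, ])
      parent <- c(parent, if (r == 1) base else nrow(pts) - 1)
    }
  }
  skeleton(neuron_id,
           data.frame(node_id = seq_len(nrow(pts)), parent_id = parent,
                      x = pts[, 1], y = pts[, 2], z = pts[, 3],
                      radius = radius))
}

rand_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

#' Generate a ground-truth-labelled synthetic connectome
#'
#' See [generator_config()] for the generative model. All randomness flows
#' from `config$seed`, so repeated calls with the same configuration are
#' identical.
#'
#' @param config a `generator_config`.
#' @return an object of class `synthetic_connectome`: named list of
#'   `skeletons`, a `connectors` table, `annotations` carrying the true
#'   labels, `designated_pairs` (cohort pairs receiving the connection
#'   bonus), `reference_lengths` (Hb+/Cas+ cortex neurite lengths for
#'   temporal binning), per-neuron `pre_clouds`/`post_clouds` and
#'   `cortex_length_truth`, plus the `config` echo.
#' @export
generate_connectome <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  np <- config$neuropil
  bb <- volume_bbox(np)
  half <- (bb[2, ] - bb[1, ]) / 2
  center <- (bb[2, ] + bb[1, ]) / 2
  stopifnot(all(abs(center) < 1e-9))  # generator assumes an origin-centred volume
  L <- config$n_lineages
  Tg <- config$temporal_groups_per_hemilineage
  n <- config$neurons_per_hlt
  spacing <- config$cortex_shell_thickness / Tg

  # lineage entry points on the left (-x) surface, spread along z
  sinphi <- if (L == 1) 0 else seq(-0.6, 0.6, length.out = L)
  entries <- lapply(seq_len(L), function(l) {
    surface_point(half, c(-sqrt(1 - sinphi[l]^2), 0, sinphi[l]))
  })

  left <- list()  # per-neuron records
  cohort_centers <- list()
  for (l in seq_len(L)) {
    for (hl in c("dorsal", "ventral")) {
      ysign <- if (hl == "dorsal") 1 else -1
      # hemilineage-specific projection waypoint: siblings of one
      # hemilineage share an initial neurite trajectory into their target
      # neuropil half, which is what morphology clustering keys on
      waypoint <- c(0.75 * entries[[l]][1], ysign * 0.45 * half[2],
                    0.75 * entries[[l]][3])
      for (t in seq_len(Tg)) {
        # all arbors share the segment's transverse neuropil band
        cl_center <- draw_center(np, half, c(-0.65, -0.15),
                                 ysign * c(0.35, 0.7), c(-0.2, 0.2))
        cohort <- sprintf("NB%d_%s_T%d", l, hl, t)
        cohort_centers[[cohort]] <- cl_center
        for (k in seq_len(n)) {
          w <- entries[[l]] / half
          w <- w + stats::rnorm(3, 0, 0.01)
          entry <- surface_point(half, w)
          nrm <- entry / half^2
          nrm <- nrm / sqrt(sum(nrm^2))
          d <- max(0.1 * spacing,
                   spacing * t + stats::rnorm(1, 0, config$radial_noise_sd))
          soma <- entry + nrm * d
          arbor <- cl_center + stats::rnorm(3, 0, config$cluster_sd / 2)
          n_pre <- 1 + stats::rpois(1, config$presyn_per_neuron - 1)
          n_post <- 1 + stats::rpois(1, config$postsyn_per_neuron - 1)
          clustered_sd <- config$cluster_sd
          diffuse_sd <- 2.5 * config$cluster_sd
          pre_sd <- if (hl == "dorsal") clustered_sd else diffuse_sd
          post_sd <- if (hl == "ventral") clustered_sd else diffuse_sd
          left[[length(left) + 1]] <- list(
            base_id = sprintf("NB%d_%s_T%d_n%d", l, hl, t, k),
            lineage = sprintf("NB%d", l), hemilineage = hl,
            temporal_group = t, cell_class = "interneuron",
            cohort = cohort,
            soma = soma, entry = entry, waypoint = waypoint, arbor = arbor,
            cortex_length = d,
            arms = lapply(1:2, function(a) {
              u <- rand_unit()
              rbind(arbor + u * 0.7 * config$cluster_sd,
                    arbor + u * 1.4 * config$cluster_sd)
            }),
            pre = matrix(rep(cl_center, each = n_pre), ncol = 3) +
              matrix(stats::rnorm(3 * n_pre, 0, pre_sd), ncol = 3),
            post = matrix(rep(cl_center, each = n_post), ncol = 3) +
              matrix(stats::rnorm(3 * n_post, 0, post_sd), ncol = 3))
        }
      }
    }
  }

  # sensory (purely ventral presynapses) and motor (purely dorsal
  # postsynapses) cell classes
  for (cls in c("sensory", "motor")) {
    n_cls <- if (cls == "sensory") config$n_sensory else config$n_motor
    ysign <- if (cls == "sensory") -1 else 1
    for (k in seq_len(n_cls)) {
      cl_center <- draw_center(np, half, c(-0.6, -0.1),
                               ysign * c(0.35, 0.7), c(-0.3, 0.3))
      w <- cl_center / half
      entry <- surface_point(half, w)
      nrm <- entry / half^2
      nrm <- nrm / sqrt(sum(nrm^2))
      soma <- entry + nrm * 0.5 * config$cortex_shell_thickness
      n_syn <- 1 + stats::rpois(1, (if (cls == "sensory")
        config$presyn_per_neuron else config$postsyn_per_neuron) - 1)
      cloud <- matrix(rep(cl_center, each = n_syn), ncol = 3) +
        matrix(stats::rnorm(3 * n_syn, 0, 2 * config$cluster_sd), ncol = 3)
      left[[length(left) + 1]] <- list(
        base_id = sprintf("%s%d", if (cls == "sensory") "SN" else "MN", k),
        lineage = if (cls == "sensory") "SN" else "MN",
        hemilineage = "unassigned", temporal_group = NA_integer_,
        cell_class = cls, cohort = NA_character_,
        soma = soma, entry = entry, arbor = cl_center,
        cortex_length = 0.5 * config$cortex_shell_thickness,
        arms = list(),
        pre = if (cls == "sensory") cloud else
          matrix(numeric(0), ncol = 3),
        post = if (cls == "motor") cloud else
          matrix(numeric(0), ncol = 3))
    }
  }

  # mirror to the right hemisegment with jitter
  jit <- function(m) {
    if (!nrow(m)) return(m)
    m[, 1] <- -m[, 1]
    m + matrix(stats::rnorm(length(m), 0, config$mirror_jitter_sd),
               nrow = nrow(m))
  }
  mirror_record <- function(rec) {
    rec$soma <- drop(jit(matrix(rec$soma, 1)))
    # keep the jittered entry point exactly on the neuropil surface, else
    # the measured neuropil entry slips to a node deep in the arbor
    rec$entry <- surface_point(half, drop(jit(matrix(rec$entry, 1))) / half)
    rec$cortex_length <- sqrt(sum((rec$soma - rec$entry)^2))
    rec$arbor <- drop(jit(matrix(rec$arbor, 1)))
    if (!is.null(rec$waypoint))
      rec$waypoint <- drop(jit(matrix(rec$waypoint, 1)))
    rec$arms <- lapply(rec$arms, jit)
    rec$pre <- jit(rec$pre)
    rec$post <- jit(rec$post)
    rec
  }
  right <- lapply(left, mirror_record)

  # Connectivity is sampled globally over both hemisegments with the same
  # kernel the analysis uses, so the generator's support coincides with the
  # support of the proximity null (cross-side weights are tiny but present).
  compute_weights <- function(recs) {
    ids <- names(recs)
    pre_ok <- vapply(recs, function(r) nrow(r$pre) > 0, logical(1))
    post_ok <- vapply(recs, function(r) nrow(r$post) > 0, logical(1))
    src <- ids[pre_ok]
    tgt <- ids[post_ok]
    frac_pre <- lapply(recs[src], function(r) neighbor_fraction(r$pre, 2000))
    frac_post <- lapply(recs[tgt], function(r) neighbor_fraction(r$post, 2000))
    W <- matrix(0, length(src), length(tgt), dimnames = list(src, tgt))
    for (i in src) {
      for (j in tgt) {
        if (i == j) next
        W[i, j] <- syn_sim_directed(recs[[i]]$pre, recs[[j]]$post,
                                    frac_pre[[i]], frac_post[[j]], 2000)
      }
    }
    W
  }

  # Designated partner cohorts are drawn uniformly among cohorts holding an
  # intermediate share (5%-35%) of the source cohort's total overlap:
  # readily reachable, so the bonus materializes as actual wiring, yet not
  # the proximity-dominant partner, so the extra wiring exceeds what
  # proximity alone predicts. Drawn on the left, mirrored to the right.
  draw_designated <- function(recs, W) {
    k <- config$designated_partners_per_cohort
    cohorts_l <- names(cohort_centers)
    if (k == 0 || length(cohorts_l) < 2)
      return(data.frame(from = character(0), to = character(0)))
    co <- vapply(recs, function(r)
      if (is.na(r$cohort) || r$side != "left") NA_character_ else r$cohort,
      character(1))
    cw <- matrix(0, length(cohorts_l), length(cohorts_l),
                 dimnames = list(cohorts_l, cohorts_l))
    for (a in cohorts_l) {
      ii <- intersect(rownames(W), names(co)[!is.na(co) & co == a])
      for (cc in cohorts_l) {
        if (a == cc) next
        jj <- intersect(colnames(W), names(co)[!is.na(co) & co == cc])
        cw[a, cc] <- mean(W[ii, jj])
      }
    }
    designated <- data.frame(from = character(0), to = character(0))
    for (a in cohorts_l) {
      others <- setdiff(cohorts_l, a)
      share <- cw[a, others] / sum(cw[a, others])
      reachable <- as.numeric(share >= 0.05 & share <= 0.35)
      if (sum(reachable) == 0)
        reachable <- as.numeric(share >= 0.02 & share <= 0.5)
      if (sum(reachable) == 0) reachable <- as.numeric(share > 0)
      if (sum(reachable) == 0) reachable <- reachable + 1
      tgt <- sample(others, min(k, sum(reachable > 0)), prob = reachable)
      designated <- rbind(designated, data.frame(from = a, to = tgt))
    }
    designated
  }

  build_edges <- function(recs, W, designated_sided) {
    ids <- names(recs)
    src <- rownames(W)
    tgt <- colnames(W)
    if (nrow(designated_sided) && config$hlt_bonus > 0) {
      co <- vapply(recs, function(r)
        if (is.na(r$cohort)) NA_character_
        else paste0(r$cohort, "_", r$side), character(1))
      for (r in seq_len(nrow(designated_sided))) {
        ii <- src[!is.na(co[src]) & co[src] == designated_sided$from[r]]
        jj <- tgt[!is.na(co[tgt]) & co[tgt] == designated_sided$to[r]]
        W[ii, jj] <- W[ii, jj] * (1 + config$hlt_bonus)
      }
    }
    # Partner sampling, two-stage so that proximity-only data are exactly
    # the analysis' degree-preserving null: (1) the number of distinct
    # partners d comes from a weighted multinomial over the partner slots;
    # (2) the partner *set* of size d is drawn by successive weighted
    # sampling without replacement, the same scheme the shuffle null uses;
    # (3) the slots are then allocated over the set (each partner >= 1).
    rows <- list()
    for (i in src) {
      w <- W[i, ]
      if (sum(w) == 0) next
      n_conn <- nrow(recs[[i]]$pre)
      kept <- if (config$base_connection_scale < 1)
        which(stats::runif(n_conn) <= config$base_connection_scale)
      else seq_len(n_conn)
      if (!length(kept)) next
      n_part <- 1 + stats::rpois(length(kept), config$polyadic_mean - 1)
      slots <- rep(kept, n_part)
      M <- length(slots)
      d <- length(unique(sample.int(length(w), M, TRUE, w)))
      set <- sample(seq_along(w), d, FALSE, w)
      counts <- rep(1L, d)
      if (M > d) {
        extra <- stats::rmultinom(1, M - d, w[set])[, 1]
        counts <- counts + extra
      }
      targets <- sample(rep(tgt[set], counts))  # permute labels over slots
      site <- t(vapply(targets, function(j)
        recs[[j]]$post[sample.int(nrow(recs[[j]]$post), 1), ],
        numeric(3)))
      rows[[length(rows) + 1]] <- data.frame(
        connector_id = sprintf("cn_%s_%d", i, slots), pre_neuron = i,
        pre_x = recs[[i]]$pre[slots, 1], pre_y = recs[[i]]$pre[slots, 2],
        pre_z = recs[[i]]$pre[slots, 3],
        post_neuron = targets, post_x = site[, 1], post_y = site[, 2],
        post_z = site[, 3])
    }
    list(rows = do.call(rbind, rows), weights = W)
  }

  for (k in seq_along(left)) left[[k]]$side <- "left"
  for (k in seq_along(right)) right[[k]]$side <- "right"
  names(left) <- vapply(left, function(r) paste0(r$base_id, "_L"),
                        character(1))
  names(right) <- vapply(right, function(r) paste0(r$base_id, "_R"),
                         character(1))
  all_recs <- c(left, right)

  W <- compute_weights(all_recs)
  designated <- draw_designated(all_recs, W)
  designated_full <- if (nrow(designated)) rbind(
    data.frame(from = paste0(designated$from, "_left"),
               to = paste0(designated$to, "_left")),
    data.frame(from = paste0(designated$from, "_right"),
               to = paste0(designated$to, "_right")))
  else data.frame(from = character(0), to = character(0))

  edges <- build_edges(all_recs, W, designated_full)

  skeletons <- lapply(names(all_recs), function(id) {
    r <- all_recs[[id]]
    path <- rbind(subdivide(r$soma, r$entry, 4),
                  if (!is.null(r$waypoint))
                    subdivide(r$entry, r$waypoint, 3)[-1, , drop = FALSE],
                  subdivide(if (is.null(r$waypoint)) r$entry else r$waypoint,
                            r$arbor, 3)[-1, , drop = FALSE])
    path_skeleton(id, path, r$arms)
  })
  names(skeletons) <- names(all_recs)

  ann <- do.call(rbind, lapply(names(all_recs), function(id) {
    r <- all_recs[[id]]
    data.frame(neuron_id = id, lineage = r$lineage,
               hemilineage = r$hemilineage,
               temporal_group = r$temporal_group,
               hemisegment = if (endsWith(id, "_L")) "left" else "right",
               homolog_id = r$base_id, cell_class = r$cell_class)
  }))
  ann <- annotation_table(ann)

  connectors <- connector_table(edges$rows)

  reference_lengths <- list(
    hb = stats::rnorm(config$n_reference, spacing, 0.5 * spacing),
    cas = stats::rnorm(config$n_reference, 3.5 * spacing, spacing))

  structure(list(skeletons = skeletons,
                 connectors = connectors,
                 annotations = ann,
                 designated_pairs = designated_full,
                 reference_lengths = reference_lengths,
                 pre_clouds = lapply(all_recs, `[[`, "pre"),
                 post_clouds = lapply(all_recs, `[[`, "post"),
                 cortex_length_truth = vapply(all_recs, `[[`,
                                              numeric(1), "cortex_length"),
                 cohort_centers = cohort_centers,
                 connection_weights = edges$weights,
                 config = config),
            class = "synthetic_connectome")
}

#' @export
print.synthetic_connectome <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_connectome> %d neurons, %d connector ",
                     "rows, %d designated cohort pairs, seed %d\n"),
              length(x$skeletons), nrow(x$connectors),
              nrow(x$designated_pairs), x$config$seed))
  invisible(x)
}

#' Write a synthetic connectome to a fixture directory
#'
#' Emits one SWC file per neuron under `skeletons/`, `connectors.csv`,
#' `annotations.csv` and `truth.json` (true labels, designated cohort pairs,
#' reference lengths, per-neuron true cortex lengths and the generator
#' configuration). The files load back through the core readers unchanged.
#'
#' @param connectome a `synthetic_connectome`.
#' @param directory output directory.
#' @param overwrite overwrite an existing fixture?
#' @return `directory`, invisibly.
#' @export
write_fixture <- function(connectome, directory, overwrite = FALSE) {
  stopifnot(inherits(connectome, "synthetic_connectome"))
  if (file.exists(file.path(directory, "truth.json")) && !overwrite)
    stop("fixture already exists at ", directory,
         "; use overwrite = TRUE to replace it")
  dir.create(file.path(directory, "skeletons"), recursive = TRUE,
             showWarnings = FALSE)
  for (id in names(connectome$skeletons))
    write_swc(connectome$skeletons[[id]],
              file.path(directory, "skeletons", paste0(id, ".swc")))
  write_connector_table(connectome$connectors,
                        file.path(directory, "connectors.csv"))
  write_annotation_table(connectome$annotations,
                         file.path(directory, "annotations.csv"))
  cloud_df <- function(clouds, polarity) do.call(rbind, lapply(
    names(clouds), function(id) {
      m <- clouds[[id]]
      if (!nrow(m)) return(NULL)
      data.frame(neuron_id = id, polarity = polarity,
                 x = m[, 1], y = m[, 2], z = m[, 3])
    }))
  utils::write.csv(rbind(cloud_df(connectome$pre_clouds, "pre"),
                         cloud_df(connectome$post_clouds, "post")),
                   file.path(directory, "synapses.csv"), row.names = FALSE)
  ann <- connectome$annotations
  labels <- lapply(seq_len(nrow(ann)), function(i)
    list(lineage = ann$lineage[i], hemilineage = ann$hemilineage[i],
         temporal_group = ann$temporal_group[i],
         hemisegment = ann$hemisegment[i],
         homolog_id = ann$homolog_id[i],
         cell_class = ann$cell_class[i]))
  names(labels) <- ann$neuron_id
  truth <- list(labels = labels,
                designated_pairs = connectome$designated_pairs,
                reference_lengths = connectome$reference_lengths,
                cortex_length_truth =
                  as.list(connectome$cortex_length_truth),
                config = config_to_list(connectome$config))
  jsonlite::write_json(truth, file.path(directory, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(directory)
}

#' Load a fixture directory written by [write_fixture()]
#'
#' @param directory fixture directory.
#' @return list with `skeletons`, `connectors`, `annotations`,
#'   `designated_pairs`, `reference_lengths`, `cortex_length_truth` and the
#'   restored `config`.
#' @export
read_connectome <- function(directory) {
  stopifnot(dir.exists(directory))
  swc <- list.files(file.path(directory, "skeletons"), pattern = "\\.swc$",
                    full.names = TRUE)
  skeletons <- lapply(swc, read_swc)
  names(skeletons) <- vapply(skeletons, `[[`, character(1), "neuron_id")
  truth <- jsonlite::read_json(file.path(directory, "truth.json"),
                               simplifyVector = TRUE)
  pre_clouds <- post_clouds <- NULL
  syn_path <- file.path(directory, "synapses.csv")
  if (file.exists(syn_path)) {
    syn <- utils::read.csv(syn_path, stringsAsFactors = FALSE)
    split_clouds <- function(pol) {
      rows <- syn[syn$polarity == pol, , drop = FALSE]
      out <- lapply(split(seq_len(nrow(rows)), rows$neuron_id), function(k) {
        m <- as.matrix(rows[k, c("x", "y", "z")])
        dimnames(m) <- list(NULL, c("x", "y", "z"))
        m
      })
      out[names(skeletons)[names(skeletons) %in% names(out)]]
    }
    pre_clouds <- split_clouds("pre")
    post_clouds <- split_clouds("post")
  }
  list(skeletons = skeletons,
       connectors = read_connector_table(file.path(directory,
                                                   "connectors.csv")),
       annotations = read_annotation_table(file.path(directory,
                                                     "annotations.csv")),
       designated_pairs = as.data.frame(truth$designated_pairs),
       reference_lengths = truth$reference_lengths,
       cortex_length_truth = unlist(truth$cortex_length_truth),
       pre_clouds = pre_clouds, post_clouds = post_clouds,
       config = config_from_list(truth$config))
}
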