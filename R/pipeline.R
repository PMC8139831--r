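#' Pipeline configuration
#'
#' Bundles every tunable of the full analysis: the data source (a
#' [generator_config()] for synthetic mode, or a fixture directory written by
#' [write_fixture()]), the synapse-kernel parameters, the thresholds, KDE
#' settings and null-model settings. A resolved copy of the configuration is
#' embedded in every report, and the whole run is deterministic given
#' `seed`.
#'
#' @param generator a `generator_config`, or `NULL` when loading a fixture.
#' @param input_dir fixture directory (ignored when `generator` is given).
#' @param sigma,omega synapse-similarity kernel parameters (nm).
#' @param binarize_threshold synapse-count threshold for the binarized
#'   matrix used by connectivity similarity and network distance.
#' @param null_threshold synapse-count threshold for the null-model
#'   analysis. The default 1 keeps the binarization approximately linear in
#'   connection weight, which is the regime in which the proximity-based
#'   shuffle is an exact null for proximity-only data; 2 reproduces the
#'   stricter two-synapse reading.
#' @param premotor_threshold per-partner synapse threshold (strict `>`) for
#'   premotor/postsensory classification.
#' @param overlap_null_threshold overlap scores below this are zeroed in the
#'   overlap connection-probability model.
#' @param null_mode `"overlap"` or `"input_degree"`.
#' @param n_iter Monte-Carlo shuffles for the null distribution.
#' @param contour_fraction KDE outermost-contour mass.
#' @param ap_window optional anteroposterior window (nm) for density maps.
#' @param strahler_keep minimum Strahler order kept before morphology
#'   comparison.
#' @param dotprops_spacing,dotprops_k dotprops resampling parameters.
#' @param cluster_cutoff dendrogram height for hemilineage clustering.
#' @param seed integer seed for the stochastic stages.
#' @param output_dir optional directory for report files.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = NULL, input_dir = NULL,
                            sigma = 2000, omega = 2000,
                            binarize_threshold = 1L, null_threshold = 1L,
                            premotor_threshold = 3L,
                            overlap_null_threshold = 0,
                            null_mode = c("overlap", "input_degree"),
                            n_iter = 500L, contour_fraction = 0.6,
                            ap_window = NULL, strahler_keep = 2L,
                            dotprops_spacing = 1000, dotprops_k = 5L,
                            cluster_cutoff = 0.65, seed = 1L,
                            output_dir = NULL) {
  null_mode <- match.arg(null_mode)
  if (is.null(generator) && is.null(input_dir))
    stop("pipeline_config needs either a generator config or an input_dir")
  if (!is.null(generator)) stopifnot(inherits(generator, "generator_config"))
  stopifnot(sigma > 0, omega > 0, binarize_threshold >= 1,
            null_threshold >= 1, n_iter >= 100)
  structure(list(generator = generator, input_dir = input_dir,
                 sigma = sigma, omega = omega,
                 binarize_threshold = as.integer(binarize_threshold),
                 null_threshold = as.integer(null_threshold),
                 premotor_threshold = as.integer(premotor_threshold),
                 overlap_null_threshold = overlap_null_threshold,
                 null_mode = null_mode, n_iter = as.integer(n_iter),
                 contour_fraction = contour_fraction, ap_window = ap_window,
                 strahler_keep = as.integer(strahler_keep),
                 dotprops_spacing = dotprops_spacing,
                 dotprops_k = as.integer(dotprops_k),
                 cluster_cutoff = cluster_cutoff, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "pipeline_config")
}

pipeline_config_to_list <- function(config) {
  out <- unclass(config)
  if (!is.null(out$generator)) out$generator <- config_to_list(out$generator)
  out
}

# Measured pre/post synapse point sets for a set of neurons.
measured_clouds <- function(connectors, ids) {
  list(pre = lapply(stats::setNames(ids, ids), function(i)
         presynapse_points(connectors, i)),
       post = lapply(stats::setNames(ids, ids), function(i)
         postsynapse_points(connectors, i)))
}

#' Directed pre/post overlap matrix over a set of neurons
#'
#' Applies [overlap_score()] between the presynapses of every neuron (rows)
#' and the postsynapses of every other neuron (columns). Neurons lacking a
#' polarity contribute zero rows or columns.
#'
#' @param clouds list with elements `pre` and `post`: named lists of synapse
#'   point matrices (columns x, y, z in nm), indexed by neuron id with
#'   identical names.
#' @inheritParams synapse_similarity
#' @return square numeric matrix of directed overlap scores, rows
#'   presynaptic, zero diagonal.
#' @export
overlap_matrix <- function(clouds, sigma = 2000, omega = 2000) {
  ids <- names(clouds$pre)
  frac_pre <- lapply(clouds$pre, function(p)
    if (nrow(p)) neighbor_fraction(p, omega) else numeric(0))
  frac_post <- lapply(clouds$post, function(p)
    if (nrow(p)) neighbor_fraction(p, omega) else numeric(0))
  O <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in ids) {
    if (!nrow(clouds$pre[[i]])) next
    for (j in ids) {
      if (i == j || !nrow(clouds$post[[j]])) next
      O[i, j] <- syn_sim_directed(clouds$pre[[i]], clouds$post[[j]],
                                  frac_pre[[i]], frac_post[[j]], sigma)
    }
  }
  O
}

#' Run the full developmental-connectomics pipeline
#'
#' Stages, in order: load or generate the connectome; skeleton morphometrics
#' (cortex neurite lengths, bilateral means, temporal-group assignment from
#' the reference-cell bins, per-lineage morphology clustering); synapse maps
#' (pre/pre and post/post similarity matrices, a polyadic-weighted density
#' map); connectivity statistics (binarized matrix, premotor/postsensory
#' flags, sensory output fractions, cosine connectivity similarity, network
#' distances, cohort comparison of synapse similarity); and the Monte-Carlo
#' proximity null for the hemilineage-temporal connection frequency. Stage
#' failures abort with the stage name; results computed so far are attached
#' to the error condition.
#'
#' @param config a `pipeline_config`.
#' @return an object of class `pipeline_report` (a named list of stage
#'   results plus the resolved configuration).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(config = pipeline_config_to_list(config))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      e$message <- paste0("pipeline stage '", name, "' failed: ", e$message)
      e$partial_report <- report
      stop(e)
    })
  }

  data <- stage("load", {
    if (!is.null(config$generator)) generate_connectome(config$generator)
    else read_connectome(config$input_dir)
  })
  neuropil <- data$config$neuropil
  ann <- data$annotations
  report$n_neurons <- nrow(ann)

  report$morphometrics <- stage("morphometrics", {
    lengths <- vapply(data$skeletons, cortex_neurite_length,
                      numeric(1), volume = neuropil)
    is_left <- ann$hemisegment == "left"
    pairs <- ann$homolog_id[!is.na(ann$homolog_id) & is_left]
    left_ids <- ann$neuron_id[is_left][match(pairs, ann$homolog_id[is_left])]
    right_tab <- ann[ann$hemisegment == "right", ]
    right_ids <- right_tab$neuron_id[match(pairs, right_tab$homolog_id)]
    mean_len <- bilateral_mean_length(lengths[left_ids], lengths[right_ids])
    names(mean_len) <- pairs
    bins <- fit_temporal_bins(data$reference_lengths$hb,
                              data$reference_lengths$cas)
    groups <- assign_temporal_group(mean_len, bins)
    names(groups) <- pairs
    # per-lineage, per-hemisegment morphology clustering of interneurons
    clusters <- list()
    inter <- ann[ann$cell_class == "interneuron", ]
    for (lin in unique(inter$lineage)) {
      for (seg in c("left", "right")) {
        ids <- inter$neuron_id[inter$lineage == lin &
                                 inter$hemisegment == seg]
        if (length(ids) < 2) next
        dps <- lapply(data$skeletons[ids], function(sk) {
          pruned <- tryCatch(
            suppressWarnings(prune_by_strahler(sk, config$strahler_keep)),
            error = function(e) sk)
          if (nrow(pruned$nodes) < 2) pruned <- sk
          to_dotprops(pruned, config$dotprops_spacing, config$dotprops_k)
        })
        S <- matrix(NA_real_, length(ids), length(ids),
                    dimnames = list(ids, ids))
        for (i in seq_along(ids)) for (j in seq_along(ids))
          S[i, j] <- morph_similarity(dps[[i]], dps[[j]])
        clusters[[paste(lin, seg, sep = "_")]] <-
          cluster_hemilineages(S, config$cluster_cutoff)
      }
    }
    list(lengths = lengths, bilateral_mean = mean_len, bins = bins,
         temporal_groups = groups, clusters = clusters)
  })

  report$synapse_maps <- stage("synapse_maps", {
    inter_ids <- ann$neuron_id[ann$cell_class == "interneuron"]
    sim_pre <- similarity_matrix(data$connectors, ann, "pre_pre",
                                 neuron_ids = inter_ids,
                                 sigma = config$sigma, omega = config$omega)
    sim_post <- similarity_matrix(data$connectors, ann, "post_post",
                                  neuron_ids = inter_ids,
                                  sigma = config$sigma, omega = config$omega)
    pre_pts <- do.call(rbind, lapply(inter_ids, function(i)
      presynapse_points(data$connectors, i, polyadic_weights = TRUE)))
    pre_w <- unlist(lapply(inter_ids, function(i)
      attr(presynapse_points(data$connectors, i, polyadic_weights = TRUE),
           "weights")))
    dmap <- density_map(pre_pts, weights = pre_w,
                        contour_fraction = config$contour_fraction,
                        ap_window = config$ap_window)
    list(similarity_pre = sim_pre, similarity_post = sim_post,
         density = dmap)
  })

  report$connectivity <- stage("connectivity", {
    ids <- ann$neuron_id
    cm <- build_connectivity(data$connectors, ids)
    b <- binarize(cm, config$binarize_threshold)
    motor_ids <- ann$neuron_id[ann$cell_class == "motor"]
    sensory_ids <- ann$neuron_id[ann$cell_class == "sensory"]
    flags <- classify_premotor_postsensory(cm, motor_ids, sensory_ids,
                                           config$premotor_threshold)
    groups <- list(
      dorsal = ann$neuron_id[ann$hemilineage == "dorsal"],
      ventral = ann$neuron_id[ann$hemilineage == "ventral"],
      motor = motor_ids)
    sens_out <- group_io_fractions(cm, sensory_ids, groups, "outputs")
    csim <- connectivity_similarity(b, "outputs")
    ndist <- network_distance(b)
    cohort_cmp <- cohort_comparison(report$synapse_maps$similarity_pre, ann)
    list(matrix = cm, binary = b, flags = flags,
         sensory_output_fractions = sens_out,
         connectivity_similarity = csim, network_distance = ndist,
         cohort_comparison = cohort_cmp)
  })

  report$null_models <- stage("null_models", {
    ids <- ann$neuron_id
    cm_i <- build_connectivity(data$connectors, ids)
    b_i <- binarize(cm_i, config$null_threshold)
    # the full synapse complement (available for generated or fixture data)
    # gives the cleanest proximity weights; measured contact sites are the
    # fallback for bare connector tables
    clouds <- if (!is.null(data$pre_clouds))
      list(pre = data$pre_clouds[ids], post = data$post_clouds[ids])
    else measured_clouds(data$connectors, ids)
    clouds$pre <- lapply(clouds$pre, function(p)
      if (is.null(p)) matrix(numeric(0), ncol = 3) else p)
    clouds$post <- lapply(clouds$post, function(p)
      if (is.null(p)) matrix(numeric(0), ncol = 3) else p)
    names(clouds$pre) <- names(clouds$post) <- ids
    O <- overlap_matrix(clouds, config$sigma, config$omega)
    model <- if (config$null_mode == "overlap")
      connection_probabilities("overlap", overlap_matrix = O,
                               overlap_threshold =
                                 config$overlap_null_threshold)
    else connection_probabilities("input_degree", binary = b_i)
    cohorts <- hlt_cohort(ann)
    null_distribution(b_i, model, cohorts, n_iter = config$n_iter,
                      seed = config$seed)
  })

  class(report) <- "pipeline_report"
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d neurons\n", x$n_neurons))
  cat(sprintf("  temporal bins: t1 = %.0f, t2 = %.0f, t3 = %.0f nm\n",
              x$morphometrics$bins$t1, x$morphometrics$bins$t2,
              x$morphometrics$bins$t3))
  print(x$null_models)
  invisible(x)
}

#' Write a machine-readable pipeline report
#'
#' Emits `report.json` (scalar summaries, the resolved configuration, null
#' samples) plus `lengths.csv` and `cohort_stats.csv` into `directory`.
#'
#' @param report a `pipeline_report`.
#' @param directory output directory (created if needed).
#' @return `directory`, invisibly.
#' @export
write_report <- function(report, directory) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  mo <- report$morphometrics
  lengths_df <- data.frame(homolog_id = names(mo$bilateral_mean),
                           mean_length = as.numeric(mo$bilateral_mean),
                           temporal_group = as.integer(mo$temporal_groups))
  utils::write.csv(lengths_df, file.path(directory, "lengths.csv"),
                   row.names = FALSE)
  cc <- report$connectivity$cohort_comparison
  utils::write.csv(cc$summary, file.path(directory, "cohort_stats.csv"),
                   row.names = FALSE)
  nm <- report$null_models
  json <- list(schema_version = 1L,
               config = report$config,
               n_neurons = report$n_neurons,
               temporal_bins = mo$bins[c("t1", "t2", "t3")],
               n_morphology_clusters = vapply(mo$clusters, function(cl)
                 attr(cl, "n_clusters"), integer(1)),
               cohort_summary = cc$summary,
               cohort_tests = cc$tests,
               null = list(mode = nm$mode, reading = nm$reading,
                           observed = nm$observed, p = nm$p,
                           n_iter = nm$n_iter, samples = nm$samples))
  jsonlite::write_json(json, file.path(directory, "report.json"),
                       auto_unbox = TRUE, digits = 12, na = "null",
                       null = "null")
  invisible(directory)
}
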