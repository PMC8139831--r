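#' Connection-probability models for shuffled connectivity
#'
#' Two nulls for "who would neuron i connect to if developmental identity did
#' not matter". `input_degree`: the probability of targeting neuron j is
#' proportional to j's binarized in-degree, identical for every presynaptic
#' neuron (self excluded, rows renormalized). `overlap`: the probability is
#' proportional to the pre/post synaptic overlap score of the (i, j) pair,
#' after zeroing entries below `overlap_threshold`; overlap 0 means
#' probability 0.
#'
#' @param mode `"input_degree"` or `"overlap"`.
#' @param binary binarized observed matrix (required for `input_degree`).
#' @param overlap_matrix pre/post overlap score matrix, rows presynaptic
#'   (required for `overlap`).
#' @param overlap_threshold scores below this are zeroed before
#'   normalization.
#' @return an object of class `connection_probability_model` with the
#'   row-normalized probability matrix `p` (all-zero rows flagged in
#'   `zero_rows` and left at zero).
#' @export
connection_probabilities <- function(mode = c("input_degree", "overlap"),
                                     binary = NULL, overlap_matrix = NULL,
                                     overlap_threshold = 0) {
  mode <- match.arg(mode)
  if (mode == "input_degree") {
    stopifnot(is.matrix(binary), all(binary %in% c(0, 1)))
    indeg <- colSums(unclass(binary))
    n <- length(indeg)
    p <- matrix(rep(indeg, each = n), n, n, dimnames = dimnames(binary))
  } else {
    stopifnot(is.matrix(overlap_matrix), all(overlap_matrix >= 0),
              overlap_threshold >= 0)
    p <- unclass(overlap_matrix)
    p[p < overlap_threshold] <- 0
  }
  diag(p) <- 0
  rs <- rowSums(p)
  zero_rows <- rownames(p)[rs == 0]
  if (length(zero_rows))
    message(length(zero_rows), " neuron(s) with no admissible targets ",
            "under the ", mode, " model")
  p <- p / ifelse(rs == 0, 1, rs)
  structure(list(mode = mode, p = p,
                 overlap_threshold = if (mode == "overlap") overlap_threshold,
                 zero_rows = zero_rows),
            class = "connection_probability_model")
}

#' @export
print.connection_probability_model <- function(x, ...) {
  cat(sprintf("<connection_probability_model> mode %s, %d neurons",
              x$mode, nrow(x$p)))
  if (!is.null(x$overlap_threshold))
    cat(sprintf(", overlap threshold %g", x$overlap_threshold))
  cat("\n")
  invisible(x)
}

#' Shuffle connectivity preserving each neuron's output degree
#'
#' For every presynaptic neuron with out-degree d in the binarized matrix,
#' draws d distinct targets without replacement with the probabilities of
#' the model's row. Out-degrees are preserved exactly in every replicate.
#'
#' @param binary 0/1 matrix whose out-degrees are preserved.
#' @param model a `connection_probability_model` over the same neurons.
#' @param seed optional integer seed for reproducibility.
#' @return shuffled 0/1 matrix with the same dimnames.
#' @export
shuffle_connectivity <- function(binary, model, seed = NULL) {
  stopifnot(is.matrix(binary), all(binary %in% c(0, 1)),
            inherits(model, "connection_probability_model"),
            identical(dim(binary), dim(model$p)))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(binary)
  out <- matrix(0L, n, n, dimnames = dimnames(binary))
  b <- unclass(binary)
  for (i in seq_len(n)) {
    d <- sum(b[i, ])
    if (d == 0) next
    pr <- model$p[i, ]
    adm <- which(pr > 0)
    if (length(adm) < d)
      stop("neuron ", rownames(binary)[i], " has out-degree ", d,
           " but only ", length(adm), " admissible targets; ",
           "consider lowering the overlap threshold")
    tgt <- if (length(adm) == d) adm
           else adm[sample.int(length(adm), d, prob = pr[adm])]
    out[i, tgt] <- 1L
  }
  out
}

# Normalize a cohort specification (named list of ids, or a vector of labels
# named by neuron id) to a list of id vectors restricted to `ids`.
as_cohort_list <- function(cohorts, ids) {
  if (!is.list(cohorts)) {
    stopifnot(!is.null(names(cohorts)))
    keep <- !is.na(cohorts)
    cohorts <- split(names(cohorts)[keep], as.character(cohorts[keep]))
  }
  lapply(cohorts, intersect, y = ids)
}

#' Frequency of shared cohort-to-cohort connectivity
#'
#' The headline statistic for "do hemilineage-temporal cohorts wire
#' together": over all unordered pairs of neurons (m, n) within one cohort
#' and all other cohorts C, the fraction of (pair, C) combinations in which
#' both m and n have at least one outgoing edge to some neuron of C
#' (`reading = "pair_both"`, the default; recorded in the result's
#' attributes). Alternative readings: `"cohort_pair"` scores each ordered
#' cohort pair (A, C) once, as whether any within-A pair jointly hits C;
#' `"per_neuron"` scores each (member neuron, other cohort) combination as
#' whether that neuron hits C. Cohorts with fewer than two members are
#' skipped.
#'
#' @param binary 0/1 connectivity matrix with neuron-id dimnames.
#' @param cohorts named list of neuron-id vectors, or a vector of cohort
#'   labels named by neuron id (e.g. from [hlt_cohort()]).
#' @param reading combinatorial universe; see above.
#' @return frequency in \[0, 1\] with attributes `reading` and
#'   `n_combinations`; `NA` with a warning when no combination is eligible.
#' @export
cohort_connection_frequency <- function(binary, cohorts,
                                        reading = c("pair_both",
                                                    "cohort_pair",
                                                    "per_neuron")) {
  reading <- match.arg(reading)
  stopifnot(is.matrix(binary), all(binary %in% c(0, 1)))
  ids <- rownames(binary)
  cl <- as_cohort_list(cohorts, ids)
  cl <- cl[lengths(cl) >= 2L]
  if (length(cl) < 2L) {
    warning("fewer than two cohorts with >= 2 members; frequency undefined")
    return(structure(NA_real_, reading = reading, n_combinations = 0L))
  }
  b <- unclass(binary)
  memb <- vapply(cl, function(g) ids %in% g, logical(length(ids)))
  hits <- (b %*% memb) > 0  # neuron x cohort: >=1 outgoing edge into cohort
  total <- 0L
  good <- 0L
  for (ci in seq_along(cl)) {
    members <- match(cl[[ci]], ids)
    others <- setdiff(seq_along(cl), ci)
    if (reading == "per_neuron") {
      good <- good + sum(hits[members, others])
      total <- total + length(members) * length(others)
      next
    }
    prs <- utils::combn(members, 2)
    # joint hits per (pair, other cohort)
    joint <- hits[prs[1, ], others, drop = FALSE] &
      hits[prs[2, ], others, drop = FALSE]
    if (reading == "pair_both") {
      good <- good + sum(joint)
      total <- total + length(joint)
    } else {  # cohort_pair: any within-cohort pair jointly hits C
      good <- good + sum(apply(joint, 2, any))
      total <- total + length(others)
    }
  }
  structure(good / total, reading = reading, n_combinations = total)
}

#' Monte-Carlo null distribution of the cohort connection frequency
#'
#' Recomputes [cohort_connection_frequency()] on `n_iter` out-degree
#' preserving shuffles of the observed binarized matrix and reports the
#' add-one empirical p-value `(1 + #{samples >= observed}) / (n_iter + 1)`,
#' which is never 0 and never exceeds 1.
#'
#' @param binary observed 0/1 matrix.
#' @param model a `connection_probability_model`.
#' @param cohorts cohort specification as in
#'   [cohort_connection_frequency()].
#' @param n_iter number of shuffles (>= 100).
#' @param seed optional integer seed.
#' @param reading statistic reading, passed through.
#' @return an object of class `null_test` with elements `observed`,
#'   `samples`, `p`, `n_iter`, `mode`, `reading`.
#' @export
null_distribution <- function(binary, model, cohorts, n_iter = 1000L,
                              seed = NULL, reading = "pair_both") {
  stopifnot(n_iter >= 100)
  if (!is.null(seed)) set.seed(seed)
  observed <- as.numeric(cohort_connection_frequency(binary, cohorts,
                                                     reading = reading))
  samples <- vapply(seq_len(n_iter), function(k) {
    sh <- shuffle_connectivity(binary, model)
    as.numeric(cohort_connection_frequency(sh, cohorts, reading = reading))
  }, numeric(1))
  p <- (1 + sum(samples >= observed)) / (n_iter + 1)
  structure(list(observed = observed, samples = samples, p = p,
                 n_iter = as.integer(n_iter), mode = model$mode,
                 reading = reading),
            class = "null_test")
}

#' @export
print.null_test <- function(x, ...) {
  cat(sprintf(paste0("<null_test> cohort connection frequency (%s reading)\n",
                     "  observed %.4f vs %s null: mean %.4f, ",
                     "empirical p = %.4g (%d shuffles)\n"),
              x$reading, x$observed, x$mode, mean(x$samples), x$p, x$n_iter))
  invisible(x)
}
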