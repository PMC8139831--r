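#' Polyadic connector tables
#'
#' A connector is one presynaptic site with one or more postsynaptic partner
#' sites (a polyadic synapse). The table stores one row per (connector,
#' partner) pair with columns `connector_id`, `pre_neuron`, `pre_x`, `pre_y`,
#' `pre_z`, `post_neuron`, `post_x`, `post_y`, `post_z` (coordinates nm).
#' Validation enforces a single presynaptic neuron and location per connector
#' id, and removes autaptic partner rows (the presynaptic neuron among its own
#' partners) with a warning, so that downstream neuron-to-neuron matrices have
#' a zero diagonal.
#'
#' @param df data frame with the columns above.
#' @return a `connector_table` (a validated data frame).
#' @export
connector_table <- function(df) {
  required <- c("connector_id", "pre_neuron", "pre_x", "pre_y", "pre_z",
                "post_neuron", "post_x", "post_y", "post_z")
  stopifnot(is.data.frame(df), all(required %in% names(df)))
  df <- df[required]
  df$connector_id <- as.character(df$connector_id)
  df$pre_neuron <- as.character(df$pre_neuron)
  df$post_neuron <- as.character(df$post_neuron)
  num <- c("pre_x", "pre_y", "pre_z", "post_x", "post_y", "post_z")
  for (col in num) df[[col]] <- as.numeric(df[[col]])
  if (!all(is.finite(as.matrix(df[num]))))
    stop("connector table parse error: non-numeric or non-finite coordinate")
  if (any(is.na(df$post_neuron) | df$post_neuron == ""))
    stop("connector table format error: connector with missing partner")
  # one presynaptic neuron + location per connector id
  key <- paste(df$pre_neuron, df$pre_x, df$pre_y, df$pre_z)
  n_pre <- tapply(key, df$connector_id, function(k) length(unique(k)))
  if (any(n_pre > 1))
    stop("connector table consistency error: connector(s) ",
         paste(utils::head(names(n_pre)[n_pre > 1], 3), collapse = ", "),
         " have conflicting presynaptic records")
  auta <- df$pre_neuron == df$post_neuron
  if (any(auta)) {
    warning(sum(auta), " autaptic partner row(s) removed")
    df <- df[!auta, , drop = FALSE]
  }
  if (!nrow(df)) stop("connector table is empty after validation")
  rownames(df) <- NULL
  class(df) <- c("connector_table", "data.frame")
  df
}

#' Read or write a connector table as CSV
#'
#' The CSV has a header row and one row per (connector, post-partner) pair;
#' rows sharing a `connector_id` form one polyadic connector. Partner order
#' within a connector follows file order.
#'
#' @param path CSV file path.
#' @return `read_connector_table()` returns a `connector_table`.
#' @export
read_connector_table <- function(path) {
  if (!file.exists(path)) stop("connector CSV does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  connector_table(df)
}

#' @rdname read_connector_table
#' @param connectors a `connector_table`.
#' @export
write_connector_table <- function(connectors, path) {
  stopifnot(inherits(connectors, "connector_table"))
  utils::write.csv(as.data.frame(connectors), path, row.names = FALSE)
  invisible(path)
}

#' Extract synapse point sets for one neuron
#'
#' `presynapse_points()` returns the unique presynaptic connector locations of
#' a neuron; with `polyadic_weights = TRUE` it also attaches the partner count
#' of each connector as a `weights` attribute. `postsynapse_points()` returns
#' the locations of the neuron's postsynaptic partner sites.
#'
#' @param connectors a `connector_table`.
#' @param neuron_id neuron identifier.
#' @param polyadic_weights attach per-connector partner counts?
#' @return numeric matrix with columns x, y, z (nm); zero rows if none.
#' @export
presynapse_points <- function(connectors, neuron_id, polyadic_weights = FALSE) {
  rows <- connectors[connectors$pre_neuron == as.character(neuron_id), ,
                     drop = FALSE]
  if (!nrow(rows)) return(matrix(numeric(0), ncol = 3,
                                 dimnames = list(NULL, c("x", "y", "z"))))
  first <- !duplicated(rows$connector_id)
  pts <- as.matrix(rows[first, c("pre_x", "pre_y", "pre_z")])
  colnames(pts) <- c("x", "y", "z")
  if (polyadic_weights)
    attr(pts, "weights") <-
      as.vector(table(rows$connector_id)[rows$connector_id[first]])
  pts
}

#' @rdname presynapse_points
#' @export
postsynapse_points <- function(connectors, neuron_id) {
  rows <- connectors[connectors$post_neuron == as.character(neuron_id), ,
                     drop = FALSE]
  pts <- as.matrix(rows[, c("post_x", "post_y", "post_z")])
  colnames(pts) <- c("x", "y", "z")
  pts
}

#' Build a neuron-by-neuron synaptic count matrix
#'
#' Entry (i, j) counts the (connector, post-partner) pairs from presynaptic
#' neuron i onto postsynaptic neuron j; polyadic connectors contribute once
#' per partner. Connector rows referencing neurons absent from `neuron_ids`
#' are dropped with a message stating the count (a traced subset of a larger
#' volume is the normal case).
#'
#' @param connectors a `connector_table`.
#' @param neuron_ids ordered character vector of neuron ids defining the
#'   matrix rows and columns.
#' @return a `connectivity_matrix`: an integer matrix with `neuron_ids` as
#'   dimnames, rows presynaptic, columns postsynaptic, zero diagonal.
#' @export
build_connectivity <- function(connectors, neuron_ids) {
  stopifnot(inherits(connectors, "connector_table"))
  neuron_ids <- as.character(neuron_ids)
  if (!length(neuron_ids)) stop("neuron_ids must be non-empty")
  if (anyDuplicated(neuron_ids)) stop("neuron_ids must be unique")
  known <- connectors$pre_neuron %in% neuron_ids &
    connectors$post_neuron %in% neuron_ids
  if (any(!known))
    message(sum(!known), " connector partner row(s) referencing unknown ",
            "neuron ids dropped")
  rows <- connectors[known, , drop = FALSE]
  m <- matrix(0L, length(neuron_ids), length(neuron_ids),
              dimnames = list(pre = neuron_ids, post = neuron_ids))
  if (nrow(rows)) {
    tab <- table(factor(rows$pre_neuron, levels = neuron_ids),
                 factor(rows$post_neuron, levels = neuron_ids))
    m[] <- as.integer(tab)
  }
  structure(m, class = c("connectivity_matrix", class(m)))
}

#' Binarize a connectivity matrix at a synapse-count threshold
#'
#' @param matrix a `connectivity_matrix` (or plain count matrix).
#' @param threshold minimum count (>= 1) for an edge to be kept.
#' @return 0/1 integer matrix with the same dimnames; the threshold is
#'   recorded in the `threshold` attribute.
#' @export
binarize <- function(matrix, threshold = 1L) {
  stopifnot(is.matrix(matrix), is.numeric(threshold), length(threshold) == 1)
  if (threshold < 1) stop("threshold must be >= 1")
  b <- (unclass(matrix) >= threshold) * 1L
  dimnames(b) <- dimnames(matrix)
  attr(b, "threshold") <- as.integer(threshold)
  b
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d neurons, %d synaptic contacts, %d edges\n",
              nrow(x), sum(x), sum(x > 0)))
  invisible(x)
}
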