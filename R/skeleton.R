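#' Neuron skeletons
#'
#' A skeleton is a rooted tree of 3D nodes in nanometres; the root is the soma.
#' Nodes are stored as a data frame with columns `node_id`, `parent_id` (`NA`
#' for the root), `x`, `y`, `z`, `radius`. Construction validates the tree:
#' exactly one root, every parent id present, every node reachable from the
#' root (which excludes cycles), and finite coordinates.
#'
#' @param neuron_id identifier of the neuron (coerced to character).
#' @param nodes data frame with columns `node_id`, `parent_id`, `x`, `y`, `z`,
#'   `radius`; coordinates in nm. `parent_id` is `NA` (or -1) for the root.
#' @return an object of class `skeleton`.
#' @examples
#' sk <- skeleton("n1", data.frame(node_id = 1:3, parent_id = c(NA, 1, 2),
#'                                 x = 0, y = 0, z = c(0, 1000, 2500),
#'                                 radius = 100))
#' cable_length(sk)
#' @export
skeleton <- function(neuron_id, nodes) {
  required <- c("node_id", "parent_id", "x", "y", "z", "radius")
  stopifnot(is.data.frame(nodes), all(required %in% names(nodes)))
  nodes <- nodes[required]
  nodes$parent_id[!is.na(nodes$parent_id) & nodes$parent_id == -1] <- NA
  if (anyDuplicated(nodes$node_id))
    stop("skeleton has duplicated node ids")
  if (!all(is.finite(as.matrix(nodes[c("x", "y", "z")]))))
    stop("skeleton coordinates must be finite")
  is_root <- is.na(nodes$parent_id)
  if (sum(is_root) != 1L)
    stop("skeleton must have exactly one root, found ", sum(is_root))
  if (!all(nodes$parent_id[!is_root] %in% nodes$node_id))
    stop("skeleton has parent ids that are not node ids")
  obj <- structure(list(neuron_id = as.character(neuron_id),
                        nodes = nodes,
                        root = nodes$node_id[is_root]),
                   class = "skeleton")
  reach <- skeleton_bfs_order(obj)
  if (length(reach) != nrow(nodes))
    stop("skeleton parent links contain a cycle or disconnected component")
  obj
}

# Children adjacency as a list indexed by node position; positions, not ids.
skeleton_children <- function(sk) {
  n <- nrow(sk$nodes)
  parent_pos <- match(sk$nodes$parent_id, sk$nodes$node_id)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    p <- parent_pos[i]
    if (!is.na(p)) kids[[p]] <- c(kids[[p]], i)
  }
  kids
}

# Breadth-first node positions from the root; stops silently at cycles.
skeleton_bfs_order <- function(sk) {
  kids <- skeleton_children(sk)
  root_pos <- match(sk$root, sk$nodes$node_id)
  order <- integer(0)
  queue <- root_pos
  seen <- logical(nrow(sk$nodes))
  while (length(queue)) {
    i <- queue[1]
    queue <- queue[-1]
    if (seen[i]) next
    seen[i] <- TRUE
    order <- c(order, i)
    queue <- c(queue, kids[[i]])
  }
  order
}

# Euclidean length of each node's edge to its parent (0 for the root).
edge_lengths <- function(sk) {
  xyz <- as.matrix(sk$nodes[c("x", "y", "z")])
  parent_pos <- match(sk$nodes$parent_id, sk$nodes$node_id)
  len <- numeric(nrow(xyz))
  has_par <- !is.na(parent_pos)
  d <- xyz[has_par, , drop = FALSE] - xyz[parent_pos[has_par], , drop = FALSE]
  len[has_par] <- sqrt(rowSums(d^2))
  len
}

#' Total cable length of a skeleton
#'
#' Sum of Euclidean parent-child edge lengths, in nm.
#' @param sk a `skeleton`.
#' @return numeric scalar (nm).
#' @export
cable_length <- function(sk) {
  stopifnot(inherits(sk, "skeleton"))
  sum(edge_lengths(sk))
}

# Geodesic distance (nm) from the root to every node, in node order.
root_geodesics <- function(sk) {
  len <- edge_lengths(sk)
  parent_pos <- match(sk$nodes$parent_id, sk$nodes$node_id)
  g <- numeric(nrow(sk$nodes))
  for (i in skeleton_bfs_order(sk)) {
    p <- parent_pos[i]
    g[i] <- if (is.na(p)) 0 else g[p] + len[i]
  }
  g
}

#' Read a skeleton from an SWC file
#'
#' Parses the 7-column whitespace-separated SWC dialect
#' (`id type x y z radius parent`); `#` starts a comment. Coordinates and
#' radius are interpreted in nanometres. Parent -1 marks the soma root.
#'
#' @param path path to an SWC file.
#' @param neuron_id neuron identifier; defaults to the file name without
#'   extension.
#' @return a `skeleton`.
#' @export
read_swc <- function(path, neuron_id = NULL) {
  if (!file.exists(path)) stop("SWC file does not exist: ", path)
  if (is.null(neuron_id)) neuron_id <- sub("\\.swc$", "", basename(path))
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  lineno <- which(keep)
  if (!length(lines)) stop("SWC file has no data lines: ", path)
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 7))
    stop("SWC parse error at line ", lineno[which(nf != 7)[1]],
         ": expected 7 columns, got ", nf[nf != 7][1])
  m <- suppressWarnings(
    matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE))
  if (anyNA(m)) {
    bad <- which(apply(m, 1, anyNA))[1]
    stop("SWC parse error at line ", lineno[bad], ": non-numeric field")
  }
  nodes <- data.frame(node_id = m[, 1], parent_id = m[, 7],
                      x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6])
  nodes$parent_id[nodes$parent_id == -1] <- NA
  n_root <- sum(is.na(nodes$parent_id))
  if (n_root == 0) stop("SWC format error: no root (parent -1) node in ", path)
  if (n_root > 1) stop("SWC format error: multiple roots in ", path)
  tryCatch(skeleton(neuron_id, nodes),
           error = function(e) stop("SWC format error in ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
}

#' Write a skeleton to an SWC file
#'
#' @param sk a `skeleton`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(sk, path) {
  stopifnot(inherits(sk, "skeleton"))
  nd <- sk$nodes
  parent <- ifelse(is.na(nd$parent_id), -1, nd$parent_id)
  lines <- sprintf("%s %d %.17g %.17g %.17g %.17g %s",
                   format(nd$node_id, trim = TRUE), 0L,
                   nd$x, nd$y, nd$z, nd$radius,
                   format(parent, trim = TRUE))
  writeLines(c("# SWC skeleton (nm)", lines), path)
  invisible(path)
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("<skeleton> neuron %s: %d nodes, root %s, cable %.0f nm\n",
              x$neuron_id, nrow(x$nodes), format(x$root), cable_length(x)))
  invisible(x)
}
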