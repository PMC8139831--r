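#' Neuropil volumes
#'
#' A neuropil volume is a bounded region of space with a deterministic
#' point-membership predicate. It is used to find where a neurite leaves the
#' cell-body cortex and enters the synaptic neuropil. The axis convention is
#' fixed throughout the package: x = mediolateral, y = dorsoventral (dorsal =
#' +y), z = anteroposterior. All coordinates are nanometres.
#'
#' @param xlim,ylim,zlim numeric length-2 ranges (nm) for an axis-aligned box.
#' @return an object of class `neuropil_volume`.
#' @examples
#' vol <- neuropil_box(c(-1e4, 1e4), c(-5e3, 5e3), c(0, 2e4))
#' volume_contains(vol, cbind(0, 0, 100))
#' @export
neuropil_box <- function(xlim, ylim, zlim) {
  stopifnot(length(xlim) == 2, length(ylim) == 2, length(zlim) == 2,
            all(is.finite(c(xlim, ylim, zlim))),
            xlim[1] < xlim[2], ylim[1] < ylim[2], zlim[1] < zlim[2])
  structure(list(kind = "axis_aligned_box",
                 xlim = as.numeric(xlim),
                 ylim = as.numeric(ylim),
                 zlim = as.numeric(zlim)),
            class = "neuropil_volume")
}

#' @rdname neuropil_box
#' @param center numeric length-3 centre (nm).
#' @param radii numeric length-3 semi-axes (nm), all positive.
#' @export
neuropil_ellipsoid <- function(center = c(0, 0, 0), radii) {
  stopifnot(length(center) == 3, length(radii) == 3,
            all(is.finite(c(center, radii))), all(radii > 0))
  structure(list(kind = "ellipsoid",
                 center = as.numeric(center),
                 radii = as.numeric(radii)),
            class = "neuropil_volume")
}

#' Test whether points fall inside a neuropil volume
#'
#' @param volume a `neuropil_volume`.
#' @param points numeric matrix with 3 columns (x, y, z in nm), or a length-3
#'   vector for a single point.
#' @return logical vector, one element per point.
#' @export
volume_contains <- function(volume, points) {
  stopifnot(inherits(volume, "neuropil_volume"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, all(is.finite(points)))
  if (volume$kind == "axis_aligned_box") {
    points[, 1] >= volume$xlim[1] & points[, 1] <= volume$xlim[2] &
      points[, 2] >= volume$ylim[1] & points[, 2] <= volume$ylim[2] &
      points[, 3] >= volume$zlim[1] & points[, 3] <= volume$zlim[2]
  } else {
    u <- sweep(points, 2, volume$center)
    u <- sweep(u, 2, volume$radii, "/")
    rowSums(u^2) <= 1
  }
}

# Axis-aligned bounding box of the volume, rows = (min, max), cols = x,y,z.
volume_bbox <- function(volume) {
  if (volume$kind == "axis_aligned_box") {
    rbind(c(volume$xlim[1], volume$ylim[1], volume$zlim[1]),
          c(volume$xlim[2], volume$ylim[2], volume$zlim[2]))
  } else {
    rbind(volume$center - volume$radii, volume$center + volume$radii)
  }
}

#' Read or write a neuropil volume as JSON
#'
#' @param path file path.
#' @return `read_neuropil_json()` returns a `neuropil_volume`;
#'   `write_neuropil_json()` returns `path` invisibly.
#' @export
read_neuropil_json <- function(path) {
  stopifnot(file.exists(path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  neuropil_from_list(x)
}

#' @rdname read_neuropil_json
#' @param volume a `neuropil_volume`.
#' @export
write_neuropil_json <- function(volume, path) {
  stopifnot(inherits(volume, "neuropil_volume"))
  jsonlite::write_json(unclass(volume), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

neuropil_from_list <- function(x) {
  if (is.null(x$kind)) stop("neuropil JSON lacks a 'kind' field")
  switch(x$kind,
         axis_aligned_box = neuropil_box(unlist(x$xlim), unlist(x$ylim),
                                         unlist(x$zlim)),
         ellipsoid = neuropil_ellipsoid(unlist(x$center), unlist(x$radii)),
         stop("unknown neuropil kind: ", x$kind))
}

#' @export
print.neuropil_volume <- function(x, ...) {
  cat("<neuropil_volume>", x$kind, "\n")
  bb <- volume_bbox(x)
  cat(sprintf("  bbox x [%g, %g]  y [%g, %g]  z [%g, %g] nm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}
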