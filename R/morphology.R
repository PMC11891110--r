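#' Structuring elements on the working grid
#'
#' Two element families drive the dilation-overlap segmentation:
#' * a sphere of given radius (mm): its offsets are exactly the lattice
#'   points whose centre-to-centre distance from the origin is <= radius;
#' * a vertical line of given one-sided extent (mm) along the craniocaudal
#'   axis: offsets span `+/- round(size / spacing_z)` voxels.
#'
#' At the 4 mm working grid the 4 mm sphere (one voxel radius) is the
#' 6-neighbourhood plus centre (7 offsets) and the 10 mm sphere has 81
#' offsets. The vertical element lengths 12 / 8 / 4 mm map to +/- 3 / 2 / 1
#' voxels.
#'
#' @param kind `"sphere"` or `"vertical-line"`.
#' @param size_mm radius (sphere) or one-sided extent (line), in mm.
#' @param spacing mm triple of the grid the element will act on.
#' @return Object of class `axskel_se` carrying an integer offset matrix
#'   (n x 3).
#' @export
structuring_element <- function(kind = c("sphere", "vertical-line"), size_mm,
                                spacing = c(4, 4, 4)) {
  kind <- match.arg(kind)
  if (!is.finite(size_mm) || size_mm < 0) stop("size_mm must be non-negative")
  if (kind == "sphere") {
    r <- floor(size_mm / spacing)
    off <- as.matrix(expand.grid(-r[1]:r[1], -r[2]:r[2], -r[3]:r[3]))
    d2 <- (off[, 1] * spacing[1])^2 + (off[, 2] * spacing[2])^2 +
      (off[, 3] * spacing[3])^2
    off <- off[d2 <= size_mm^2 + 1e-9, , drop = FALSE]
  } else {
    r <- round(size_mm / spacing[3])
    off <- cbind(0L, 0L, -r:r)
  }
  dimnames(off) <- NULL
  structure(list(kind = kind, size_mm = size_mm, spacing = spacing,
                 offsets = off), class = "axskel_se")
}

#' @export
print.axskel_se <- function(x, ...) {
  cat(sprintf("<axskel_se %s %.1f mm, %d offsets>\n", x$kind, x$size_mm,
              nrow(x$offsets)))
  invisible(x)
}

# shift a logical array by an integer offset, zero-filling
shift_mask <- function(mask, off) {
  d <- dim(mask)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    o <- off[a]
    if (o >= d[a] || -o >= d[a]) return(out)
    if (o >= 0) { src[[a]] <- 1:(d[a] - o); dst[[a]] <- (1 + o):d[a] }
    else { src[[a]] <- (1 - o):d[a]; dst[[a]] <- 1:(d[a] + o) }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
  out
}

#' Binary dilation by a structuring element
#'
#' The output is the union of the element translated to every foreground
#' voxel, clipped at the grid boundary; it always contains the input
#' (elements include the origin). Empty masks are allowed.
#'
#' @param mask logical 3-D array.
#' @param se an [structuring_element()].
#' @return logical 3-D array.
#' @export
binary_dilate <- function(mask, se) {
  stopifnot(inherits(se, "axskel_se"))
  out <- array(FALSE, dim(mask))
  if (!any(mask)) return(out)
  for (r in seq_len(nrow(se$offsets))) {
    out <- out | shift_mask(mask, se$offsets[r, ])
  }
  out
}

#' One-voxel binary erosion (6-connectivity)
#'
#' A voxel survives iff it and all six face neighbours are foreground;
#' voxels on the grid boundary never survive (out-of-grid neighbours count
#' as background). Used to strip the cortical shell of the femur and the
#' vascular lumen wall of the aorta before background SUV extraction.
#'
#' @param mask logical 3-D array.
#' @return logical 3-D array, a subset of `mask`.
#' @export
erode_one_voxel <- function(mask) {
  out <- mask
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  for (r in 1:6) out <- out & shift_mask(mask, offs[r, ])
  # boundary voxels have an out-of-grid neighbour -> background
  d <- dim(mask)
  out[c(1, d[1]), , ] <- FALSE
  out[, c(1, d[2]), ] <- FALSE
  out[, , c(1, d[3])] <- FALSE
  out
}

#' Centre of mass of a binary mask
#'
#' Unweighted mean of the foreground voxel indices (1-based, possibly
#' fractional). With `vol` supplied the mm coordinate is attached as
#' attribute `"mm"`.
#'
#' @param mask logical 3-D array, non-empty.
#' @param vol optional volume supplying spacing/origin for the mm coordinate.
#' @return numeric length-3 voxel coordinate.
#' @export
center_of_mass <- function(mask, vol = NULL) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("center_of_mass: empty mask")
  com <- colMeans(idx)
  names(com) <- NULL
  if (!is.null(vol)) attr(com, "mm") <- drop(voxel_to_mm(com, vol))
  com
}

#' Spherical VOI around a voxel centre
#'
#' All voxels whose centre lies within `radius_mm` of the centre voxel's
#' centre (closed ball), clipped at the grid boundary. With the default
#' 10 mm radius on the 4 mm grid an interior centre yields 81 voxels,
#' approximately the joint volume adopted for posterior-joint PET readout.
#'
#' @param center integer voxel index (1-based length-3).
#' @param dim grid dimensions.
#' @param radius_mm sphere radius in mm.
#' @param spacing grid spacing mm triple.
#' @return logical 3-D array.
#' @export
sphere_voi <- function(center, dim, radius_mm = 10, spacing = c(4, 4, 4)) {
  if (any(center < 1) || any(center > dim)) stop("center outside grid")
  se <- structuring_element("sphere", radius_mm, spacing)
  pts <- sweep(se$offsets, 2, as.integer(center), `+`)
  keep <- pts[, 1] >= 1 & pts[, 1] <= dim[1] &
    pts[, 2] >= 1 & pts[, 2] <= dim[2] &
    pts[, 3] >= 1 & pts[, 3] <= dim[3]
  out <- array(FALSE, dim)
  out[pts[keep, , drop = FALSE]] <- TRUE
  out
}

# iterative sphere dilation of two disjoint masks until they overlap;
# returns the overlap mask (possibly empty if cap reached) plus iteration
# count. Shared by the IVD/SIJ/joint-centre dilation-overlap logic.
dilate_until_overlap <- function(a, b, se, max_iter = 5) {
  da <- a; db <- b
  for (it in seq_len(max_iter)) {
    da <- binary_dilate(da, se)
    db <- binary_dilate(db, se)
    ov <- da & db
    if (any(ov)) return(list(overlap = ov, iterations = it))
  }
  list(overlap = array(FALSE, dim(a)), iterations = max_iter)
}
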