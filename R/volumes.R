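#' Image and label volume containers
#'
#' `image_volume()` wraps a 3-D scalar grid (CT in Hounsfield units or PET in
#' SUV) together with its voxel spacing and world origin. `label_volume()`
#' wraps a 3-D non-negative integer grid plus a taxonomy mapping label ids to
#' structure names.
#'
#' Axis convention: arrays are indexed `[i, j, k]` with `i` running
#' left-to-right, `j` posterior-to-anterior and `k` inferior-to-superior
#' (RAS-like). "Anterior of" and "superior of" are therefore plain index
#' comparisons. Voxel indices are 1-based throughout, the native R convention;
#' the world (mm) coordinate of voxel `(i,j,k)` is
#' `origin + (c(i,j,k) - 1) * spacing`.
#'
#' @param voxels 3-D numeric array.
#' @param spacing numeric length-3, voxel edge lengths in mm (strictly
#'   positive).
#' @param origin numeric length-3, world coordinate (mm) of the centre of
#'   voxel `(1,1,1)`.
#' @param modality `"CT-HU"` or `"PET-SUV"`; fixed at construction.
#' @return An object of class `axskel_image` (resp. `axskel_labels`).
#' @export
image_volume <- function(voxels, spacing, origin = c(0, 0, 0),
                         modality = c("CT-HU", "PET-SUV")) {
  modality <- match.arg(modality)
  check_grid(voxels, spacing, origin)
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), modality = modality),
            class = "axskel_image")
}

#' @rdname image_volume
#' @param taxonomy named integer vector mapping structure name -> label id;
#'   every non-zero value in `voxels` must appear in it. Label 0 is reserved
#'   for background.
#' @export
label_volume <- function(voxels, spacing, origin = c(0, 0, 0),
                         taxonomy = default_taxonomy()) {
  check_grid(voxels, spacing, origin)
  storage.mode(voxels) <- "integer"
  if (any(voxels < 0)) stop("label voxels must be non-negative")
  present <- setdiff(unique(as.vector(voxels)), 0L)
  if (!all(present %in% taxonomy))
    stop("labels not in taxonomy: ", paste(setdiff(present, taxonomy), collapse = ", "))
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), taxonomy = taxonomy),
            class = "axskel_labels")
}

check_grid <- function(voxels, spacing, origin) {
  if (length(dim(voxels)) != 3) stop("voxels must be a 3-D array")
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive mm values")
  if (length(origin) != 3 || any(!is.finite(origin)))
    stop("origin must be three finite mm values")
  invisible(TRUE)
}

#' @export
print.axskel_image <- function(x, ...) {
  cat(sprintf("<axskel_image %s> %s voxels @ %s mm\n", x$modality,
              paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

#' @export
print.axskel_labels <- function(x, ...) {
  n <- length(setdiff(unique(as.vector(x$voxels)), 0L))
  cat(sprintf("<axskel_labels> %s voxels @ %s mm, %d structures present\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing), collapse = "x"), n))
  invisible(x)
}

is_label_volume <- function(x) inherits(x, "axskel_labels")

#' Structure taxonomy of the skeletal label dialect
#'
#' Fixed label inventory consumed by the pipeline: the 24 vertebrae C1..L5,
#' left/right ribs 1..12, sacrum, left/right ilium (hip), spinal cord,
#' left/right femur, liver and aorta. Vertebra ids are ordered
#' C1 < C2 < ... < L5 < sacrum so craniocaudal traversal is an integer sort.
#' A converter for TotalSegmentator structure names is provided by
#' [totalsegmentator_name_map()].
#'
#' @return Named integer vector (structure name -> label id).
#' @export
default_taxonomy <- function() {
  verts <- c(paste0("C", 1:7), paste0("T", 1:12), paste0("L", 1:5))
  ids <- c(stats::setNames(1:24, paste0("vertebra_", verts)),
           sacrum = 25L, ilium_left = 26L, ilium_right = 27L,
           spinal_cord = 28L,
           stats::setNames(31:42, paste0("rib_left_", 1:12)),
           stats::setNames(43:54, paste0("rib_right_", 1:12)),
           femur_left = 55L, femur_right = 56L, liver = 57L, aorta = 58L)
  storage.mode(ids) <- "integer"
  ids
}

#' @rdname default_taxonomy
#' @export
totalsegmentator_name_map <- function() {
  verts <- c(paste0("C", 1:7), paste0("T", 1:12), paste0("L", 1:5))
  m <- c(stats::setNames(paste0("vertebra_", verts),
                         paste0("vertebrae_", verts)),
         sacrum = "sacrum", hip_left = "ilium_left", hip_right = "ilium_right",
         spinal_cord = "spinal_cord",
         stats::setNames(paste0("rib_left_", 1:12), paste0("rib_left_", 1:12)),
         stats::setNames(paste0("rib_right_", 1:12), paste0("rib_right_", 1:12)),
         femur_left = "femur_left", femur_right = "femur_right",
         liver = "liver", aorta = "aorta")
  m
}

#' Ordered vertebra structure names, C1 (cranial) to L5 (caudal)
#' @export
vertebra_names <- function() {
  paste0("vertebra_", c(paste0("C", 1:7), paste0("T", 1:12), paste0("L", 1:5)))
}

#' Spine region of a vertebral level
#'
#' @param level level string such as `"C4"`, `"T10"`, `"L2"` or `"S"`
#'   (sacrum). Sacral levels map to the lumbar region, the anatomically
#'   adjacent spine segment.
#' @return `"cervical"`, `"thoracic"` or `"lumbar"`.
#' @export
level_region <- function(level) {
  first <- substr(level, 1, 1)
  out <- c(C = "cervical", T = "thoracic", L = "lumbar", S = "lumbar")[first]
  if (any(is.na(out))) stop("unknown level: ", paste(level[is.na(out)], collapse = ", "))
  unname(out)
}

#' Extract a binary mask for one structure
#' @param labels an `axskel_labels` volume.
#' @param structure structure name (in the taxonomy) or integer label id.
#' @return logical 3-D array.
#' @export
structure_mask <- function(labels, structure) {
  id <- if (is.character(structure)) labels$taxonomy[[structure]] else as.integer(structure)
  if (is.null(id) || is.na(id)) stop("unknown structure: ", structure)
  labels$voxels == id
}

#' World (mm) coordinate of voxel indices
#' @param idx numeric vector of length 3 or n x 3 matrix of (possibly
#'   fractional) 1-based voxel indices.
#' @param vol a volume supplying `spacing` and `origin`.
#' @export
voxel_to_mm <- function(idx, vol) {
  if (is.null(dim(idx))) idx <- matrix(idx, nrow = 1)
  sweep(sweep(idx - 1, 2, vol$spacing, `*`), 2, vol$origin, `+`)
}

#' @rdname voxel_to_mm
#' @param mm mm coordinates, vector or n x 3 matrix.
#' @export
mm_to_voxel <- function(mm, vol) {
  if (is.null(dim(mm))) mm <- matrix(mm, nrow = 1)
  sweep(sweep(mm, 2, vol$origin, `-`), 2, vol$spacing, `/`) + 1
}

# round-half-away-from-zero; base round() is banker's rounding
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Read / write volumes as NIfTI
#'
#' Label volumes carry their taxonomy in a JSON sidecar (`<file>.taxonomy.json`)
#' written next to the image.
#'
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @param vol volume to write.
#' @return `read_image_nifti()` returns an `axskel_image`;
#'   `read_labels_nifti()` an `axskel_labels`.
#' @export
write_volume_nifti <- function(vol, path) {
  img <- RNifti::asNifti(vol$voxels)
  img <- RNifti::`pixdim<-`(img, vol$spacing)
  RNifti::writeNifti(img, path)
  if (is_label_volume(vol)) {
    jsonlite::write_json(as.list(vol$taxonomy), sidecar_path(path),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".taxonomy.json", path)
}

#' @rdname write_volume_nifti
#' @param modality modality tag to attach on read.
#' @export
read_image_nifti <- function(path, modality = "CT-HU") {
  img <- RNifti::readNifti(path)
  image_volume(array(as.numeric(img), dim = dim(img)),
               spacing = RNifti::pixdim(img)[1:3], modality = modality)
}

#' @rdname write_volume_nifti
#' @export
read_labels_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  sc <- sidecar_path(path)
  tax <- if (file.exists(sc)) {
    unlist(jsonlite::read_json(sc, simplifyVector = TRUE))
  } else default_taxonomy()
  storage.mode(tax) <- "integer"
  label_volume(array(as.integer(round(img)), dim = dim(img)),
               spacing = RNifti::pixdim(img)[1:3], taxonomy = tax)
}

#' Resample a volume to a target voxel spacing
#'
#' The working grid for all segmentation and PET logic is 4 x 4 x 4 mm, the
#' PET-matched resolution; inputs at other spacings are resampled on load.
#' Intensity volumes are interpolated trilinearly, label volumes by nearest
#' neighbour (so no new labels can appear). The world extent is preserved to
#' within one voxel: output dimensions are `ceiling(dim * spacing / target)`
#' and the origin is kept.
#'
#' @param vol `axskel_image` or `axskel_labels`.
#' @param target_spacing mm triple, strictly positive.
#' @return Volume of the same class on the target grid.
#' @export
resample_to_grid <- function(vol, target_spacing = c(4, 4, 4)) {
  if (length(target_spacing) == 1) target_spacing <- rep(target_spacing, 3)
  if (any(!is.finite(target_spacing)) || any(target_spacing <= 0))
    stop("target spacing must be strictly positive")
  if (isTRUE(all.equal(vol$spacing, as.numeric(target_spacing)))) return(vol)
  d <- dim(vol$voxels)
  nd <- pmax(1L, as.integer(ceiling(d * vol$spacing / target_spacing)))
  # continuous source index of each target voxel centre
  ax <- lapply(1:3, function(a) {
    ((seq_len(nd[a]) - 1) * target_spacing[a]) / vol$spacing[a] + 1
  })
  grid <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  if (is_label_volume(vol)) {
    vals <- sample_nearest(vol$voxels, grid)
    label_volume(array(as.integer(vals), dim = nd), target_spacing,
                 vol$origin, vol$taxonomy)
  } else {
    vals <- sample_trilinear(vol$voxels, grid)
    image_volume(array(vals, dim = nd), target_spacing, vol$origin,
                 vol$modality)
  }
}

# nearest-neighbour sampling at continuous 1-based indices (n x 3);
# outside the grid -> `outside`
sample_nearest <- function(arr, idx, outside = 0) {
  d <- dim(arr)
  i <- round_half_away(idx[, 1]); j <- round_half_away(idx[, 2]); k <- round_half_away(idx[, 3])
  ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
  out <- rep(outside, nrow(idx))
  out[ok] <- arr[cbind(i[ok], j[ok], k[ok])]
  out
}

# trilinear sampling at continuous 1-based indices; outside -> `outside`
sample_trilinear <- function(arr, idx, outside = 0) {
  d <- dim(arr)
  x <- idx[, 1]; y <- idx[, 2]; z <- idx[, 3]
  ok <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
  out <- rep(as.numeric(outside), length(x))
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  x0 <- pmin(pmax(floor(x), 1), d[1] - 1L); if (d[1] == 1L) x0 <- rep(1, length(x))
  y0 <- pmin(pmax(floor(y), 1), d[2] - 1L); if (d[2] == 1L) y0 <- rep(1, length(y))
  z0 <- pmin(pmax(floor(z), 1), d[3] - 1L); if (d[3] == 1L) z0 <- rep(1, length(z))
  x1 <- pmin(x0 + 1, d[1]); y1 <- pmin(y0 + 1, d[2]); z1 <- pmin(z0 + 1, d[3])
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  v <- function(a, b, c) arr[cbind(a, b, c)]
  val <-
    v(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
    v(x1, y0, z0) * fx       * (1 - fy) * (1 - fz) +
    v(x0, y1, z0) * (1 - fx) * fy       * (1 - fz) +
    v(x1, y1, z0) * fx       * fy       * (1 - fz) +
    v(x0, y0, z1) * (1 - fx) * (1 - fy) * fz +
    v(x1, y0, z1) * fx       * (1 - fy) * fz +
    v(x0, y1, z1) * (1 - fx) * fy       * fz +
    v(x1, y1, z1) * fx       * fy       * fz
  out[ok] <- val
  out
}
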