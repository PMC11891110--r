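#' Synthetic spine phantom specification
#'
#' The phantom is a deterministic, seedable stand-in for a patient low-dose
#' CT plus its whole-skeleton multi-label segmentation. It contains all 24
#' vertebrae (C1..L5), the spinal cord, 24 ribs, the sacrum, both ilia, both
#' femora, the liver and the aorta on the 4 mm working grid. Vertebrae are
#' rounded-off cuboids with a posterior arch (two lateral blocks joined to
#' the body by pedicles, plus a spinous block) so that the vertebral-body /
#' posterior split, facet-joint overlap and rib articulations are all
#' exercised; geometric realism is a non-goal.
#'
#' Vertebra heights default to 24 / 16 / 12 mm (lumbar / thoracic /
#' cervical) with a one-voxel (4 mm) disk gap between adjacent vertebrae and
#' between L5 and the sacrum. The sacro-iliac gaps are oblique single-voxel
#' planes. A global pose jitter (similarity transform) and CT noise make
#' atlas libraries and registration tests non-trivial.
#'
#' @param spacing_mm working voxel size (isotropic), mm.
#' @param height_lumbar_mm,height_thoracic_mm,height_cervical_mm vertebra
#'   block heights, mm.
#' @param gap_mm craniocaudal disk gap, mm (must be at least one voxel).
#' @param noise_sd_hu CT Gaussian noise, HU.
#' @param jitter_rot_deg,jitter_scale,jitter_trans_mm global pose jitter:
#'   rotation about the craniocaudal axis (degrees), isotropic scale factor
#'   (must lie in `[0.8, 1.2]`) and translation (mm triple).
#' @param seed integer seed controlling all randomness.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(spacing_mm = 4,
                         height_lumbar_mm = 24, height_thoracic_mm = 16,
                         height_cervical_mm = 12, gap_mm = 4,
                         noise_sd_hu = 15,
                         jitter_rot_deg = 0, jitter_scale = 1,
                         jitter_trans_mm = c(0, 0, 0),
                         seed = 1L) {
  if (gap_mm < spacing_mm) stop("disk gap must be at least one voxel")
  if (jitter_scale < 0.8 || jitter_scale > 1.2)
    stop("jitter scale must lie in [0.8, 1.2]")
  structure(list(spacing = rep(spacing_mm, 3),
                 heights = c(cervical = height_cervical_mm,
                             thoracic = height_thoracic_mm,
                             lumbar = height_lumbar_mm),
                 gap_mm = gap_mm, noise_sd_hu = noise_sd_hu,
                 jitter = list(rot_deg = jitter_rot_deg, scale = jitter_scale,
                               trans_mm = jitter_trans_mm),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# voxel layout of the phantom on its native grid; all indices 1-based.
# Cross-sections (x = left-right, y = posterior-anterior):
#   vertebral body  x 16..27, y 24..31
#   spinal cord     x 20..23, y 19..21
#   pedicles        x 15..18 / 25..28, y 18..23
#   lateral blocks  x 14..19 / 24..29, y 13..17
#   spinous block   x 18..25, y  9..12
#   ribs (thoracic) head bar x 7..14 / 29..36 y 25..27; posterior limb
#                   x 7..12 / 31..36 y 14..16; connector x 7..9 / 34..36
#   aorta           x 20..23, y 33..35
phantom_layout <- function(spec) {
  sp <- spec$spacing[3]
  hv <- stats::setNames(pmax(1L, as.integer(round(spec$heights / sp))),
                        names(spec$heights))
  g <- max(1L, as.integer(round(spec$gap_mm / sp)))
  # bottom-up: femur, gap, sacrum/ilium, gap, L5..L1, T12..T1, C7..C1
  femur_z <- c(2L, 9L)
  sac_z <- c(femur_z[2] + 2L, femur_z[2] + 8L)
  levels <- c(paste0("L", 5:1), paste0("T", 12:1), paste0("C", 7:1))
  region <- level_region(levels)
  h <- c(cervical = hv[["cervical"]], thoracic = hv[["thoracic"]],
         lumbar = hv[["lumbar"]])[region]
  z0 <- integer(24); z1 <- integer(24)
  z <- sac_z[2] + 1L + g
  for (i in seq_along(levels)) {
    z0[i] <- z; z1[i] <- z + h[i] - 1L
    z <- z1[i] + 1L + g
  }
  names(z0) <- names(z1) <- levels
  # margin around the anatomy so moderate pose jitter cannot clip it
  ox <- 2L; oz <- 8L
  z0 <- z0 + oz; z1 <- z1 + oz
  nz <- unname(z1[length(levels)]) + oz + 2L
  # x dimension chosen so the anatomy's mid-sagittal plane (x = 23.5) is
  # the grid centre: mirror symmetry is then an index reversal
  list(dim = c(46L, 40L + 2L * ox, nz), spacing = spec$spacing,
       off = c(ox, ox, oz),
       femur_z = femur_z + oz, sac_z = sac_z + oz, gap = g,
       levels = levels, z0 = z0, z1 = z1,
       cord_z = c(z0[["L5"]], z1[["C1"]]),
       vb_x = 16:27 + ox, vb_y = 24:31 + ox, cord_x = 20:23 + ox,
       cord_y = 19:21 + ox)
}

paint <- function(arr, id, x, y, z, strict = TRUE) {
  cur <- arr[x, y, z]
  if (strict && any(cur != 0L & cur != id))
    stop("phantom generation error: structure ", id,
         " overlaps label ", unique(cur[cur != 0 & cur != id])[1])
  arr[x, y, z] <- id
  arr
}

#' Generate a synthetic spine LDCT phantom
#'
#' Builds the multi-label skeletal map and a matching CT intensity image
#' (bone ~400 HU, soft tissue ~-80 HU, plus Gaussian noise). Any requested
#' pose jitter is applied as a similarity transform to both volumes (labels
#' nearest-neighbour). Reproducible: two calls with equal specs are
#' bit-identical.
#'
#' @param spec a [phantom_spec()].
#' @return `list(ct = axskel_image, labels = axskel_labels)`, with the voxel
#'   layout attached as attribute `"layout"` (native, pre-jitter frame).
#' @export
generate_phantom_ldct <- function(spec = phantom_spec()) {
  lay <- phantom_layout(spec)
  tax <- default_taxonomy()
  d <- lay$dim
  lab <- array(0L, d)
  ox <- lay$off[1]; oy <- lay$off[2]
  X <- function(v) v + ox
  Y <- function(v) v + oy
  MX <- function(v) sort(43L + 2L * ox - v)  # mirror about mid-sagittal plane

  # vertebrae: body + pedicles + lateral blocks + spinous
  for (i in seq_along(lay$levels)) {
    lv <- lay$levels[i]
    id <- tax[[paste0("vertebra_", lv)]]
    zz <- lay$z0[i]:lay$z1[i]
    lab <- paint(lab, id, lay$vb_x, lay$vb_y, zz)
    lab <- paint(lab, id, X(15:18), Y(18:23), zz)        # pedicle left
    lab <- paint(lab, id, X(25:28), Y(18:23), zz)        # pedicle right
    lab <- paint(lab, id, X(14:19), Y(13:17), zz)        # lateral block left
    lab <- paint(lab, id, X(24:29), Y(13:17), zz)        # lateral block right
    lab <- paint(lab, id, X(18:25), Y(9:12), zz)         # spinous
  }

  # spinal cord: continuous column behind the bodies
  lab <- paint(lab, tax[["spinal_cord"]], lay$cord_x, lay$cord_y,
               lay$cord_z[1]:lay$cord_z[2])

  # ribs: one per thoracic level and side, articulating with the body
  # (costovertebral) and the lateral block (costotransverse)
  for (t in 1:12) {
    lv <- paste0("T", t)
    zz <- lay$z0[[lv]] + 1:2
    idl <- tax[[paste0("rib_left_", t)]]
    lab <- paint(lab, idl, X(7:14), Y(25:27), zz)        # head bar
    lab <- paint(lab, idl, X(7:12), Y(14:16), zz)        # posterior limb
    lab <- paint(lab, idl, X(7:9), Y(17:24), zz)         # connector
    idr <- tax[[paste0("rib_right_", t)]]
    lab <- paint(lab, idr, MX(X(7:14)), Y(25:27), zz)
    lab <- paint(lab, idr, MX(X(7:12)), Y(14:16), zz)
    lab <- paint(lab, idr, MX(X(7:9)), Y(17:24), zz)
  }

  # sacrum with oblique flanks, ilia across a one-voxel oblique gap
  for (k in lay$sac_z[1]:lay$sac_z[2]) {
    xl <- X(16L - (k - lay$sac_z[1]) %/% 3L)             # sacrum left edge at k
    lab <- paint(lab, tax[["sacrum"]], xl:(43L + 2L * ox - xl), Y(15:29), k)
    lab <- paint(lab, tax[["ilium_left"]], X(6):(xl - 2L), Y(15:29), k)
    lab <- paint(lab, tax[["ilium_right"]], MX(X(6):(xl - 2L)), Y(15:29), k)
  }

  # femora, liver, aorta (PET background structures)
  lab <- paint(lab, tax[["femur_left"]], X(7:12), Y(17:26),
               lay$femur_z[1]:lay$femur_z[2])
  lab <- paint(lab, tax[["femur_right"]], MX(X(7:12)), Y(17:26),
               lay$femur_z[1]:lay$femur_z[2])
  lab <- paint(lab, tax[["aorta"]], X(20:23), Y(33:35),
               lay$sac_z[1]:lay$z1[["T1"]])
  liver_z <- lay$z0[["L1"]]:lay$z1[["T9"]]
  lab <- paint(lab, tax[["liver"]], X(29:37), Y(29:37), liver_z)

  # CT intensities
  hu <- array(-80, d)
  bone_ids <- tax[c(vertebra_names(), "sacrum", "ilium_left", "ilium_right",
                    paste0("rib_left_", 1:12), paste0("rib_right_", 1:12),
                    "femur_left", "femur_right")]
  hu[lab %in% bone_ids] <- 400
  hu[lab == tax[["spinal_cord"]]] <- 30
  hu[lab == tax[["liver"]]] <- 60
  hu[lab == tax[["aorta"]]] <- 45
  set.seed(spec$seed)
  if (spec$noise_sd_hu > 0)
    hu <- hu + array(stats::rnorm(prod(d), 0, spec$noise_sd_hu), d)

  ct <- image_volume(hu, lay$spacing, modality = "CT-HU")
  labels <- label_volume(lab, lay$spacing, taxonomy = tax)

  jit <- spec$jitter
  if (jit$rot_deg != 0 || jit$scale != 1 || any(jit$trans_mm != 0)) {
    tr <- similarity_transform(rotation_deg = c(0, 0, jit$rot_deg),
                               translation_mm = jit$trans_mm,
                               scale = jit$scale,
                               center_mm = (d - 1) / 2 * lay$spacing)
    ct <- apply_known_similarity(ct, tr)
    labels <- apply_known_similarity(labels, tr)
  }
  out <- list(ct = ct, labels = labels)
  attr(out, "layout") <- lay
  out
}

#' PET phantom specification and generator
#'
#' The PET volume is piecewise constant at region background SUV levels
#' (cervical / thoracic / lumbar spine, femur, liver, aortic blood pool,
#' soft tissue), with Gaussian focal lesions added on top and optional
#' voxel noise. Lesion ground truth is geometric: a VOI is truth-positive
#' iff a lesion centre voxel lies inside its mask, independent of any
#' uptake threshold, so detection operating points can be swept against a
#' fixed truth.
#'
#' Lesions are given as `list(structure=, peak=, sigma_mm=)` (centred at the
#' structure's centre of mass) or `list(center=, peak=, sigma_mm=)` with an
#' explicit voxel index. Peaks are additive over the local background.
#'
#' @param su_cervical,su_thoracic,su_lumbar,su_femur,su_liver,su_aorta,su_soft
#'   background SUV levels (all > 0).
#' @param lesions list of lesion descriptors (see Details).
#' @param noise_sd PET Gaussian noise, SUV.
#' @param seed integer seed.
#' @export
pet_phantom_spec <- function(su_cervical = 4, su_thoracic = 5, su_lumbar = 6,
                             su_femur = 3, su_liver = 5, su_aorta = 1.5,
                             su_soft = 0.5, lesions = list(),
                             noise_sd = 0, seed = 1L) {
  bg <- c(cervical = su_cervical, thoracic = su_thoracic, lumbar = su_lumbar,
          femur = su_femur, liver = su_liver, aorta = su_aorta,
          soft = su_soft)
  if (any(bg <= 0)) stop("background SUV levels must be positive")
  structure(list(background = bg, lesions = lesions,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "pet_phantom_spec")
}

#' @rdname pet_phantom_spec
#' @param labels an `axskel_labels` phantom label map.
#' @param spec a `pet_phantom_spec`.
#' @return `list(pet = axskel_image, lesions = data.frame)` where `lesions`
#'   has the resolved centre voxel of each planted focus. Use
#'   [voi_truth()] to derive the per-VOI truth table for an inventory.
#' @export
generate_phantom_pet <- function(labels, spec = pet_phantom_spec()) {
  tax <- labels$taxonomy
  d <- dim(labels$voxels)
  bg <- spec$background
  suv <- array(bg[["soft"]], d)
  reg_ids <- list(
    cervical = tax[paste0("vertebra_C", 1:7)],
    thoracic = c(tax[paste0("vertebra_T", 1:12)],
                 tax[c(paste0("rib_left_", 1:12), paste0("rib_right_", 1:12))]),
    lumbar = c(tax[paste0("vertebra_L", 1:5)],
               tax[c("sacrum", "ilium_left", "ilium_right")]),
    femur = tax[c("femur_left", "femur_right")],
    liver = tax[["liver"]], aorta = tax[["aorta"]])
  for (r in names(reg_ids)) suv[labels$voxels %in% reg_ids[[r]]] <- bg[[r]]
  suv[labels$voxels == tax[["spinal_cord"]]] <- bg[["soft"]]

  centers <- matrix(NA_real_, 0, 3)
  peaks <- sigmas <- numeric(0)
  for (les in spec$lesions) {
    if (!is.null(les$structure)) {
      id <- unname(tax[les$structure])
      if (length(id) != 1 || is.na(id) || !any(labels$voxels == id))
        stop("lesion target absent from labels: ", les$structure)
      ctr <- round_half_away(center_of_mass(labels$voxels == id))
    } else if (!is.null(les$center)) {
      ctr <- as.numeric(les$center)
      if (any(ctr < 1) || any(ctr > d)) stop("lesion center outside grid")
    } else stop("lesion needs a 'structure' or a 'center'")
    centers <- rbind(centers, ctr)
    peaks <- c(peaks, les$peak)
    sigmas <- c(sigmas, les$sigma_mm)
  }
  if (nrow(centers) > 0) {
    ax <- lapply(1:3, function(a) (seq_len(d[a]) - 1) * labels$spacing[a])
    for (l in seq_len(nrow(centers))) {
      cm <- (centers[l, ] - 1) * labels$spacing
      dx2 <- (ax[[1]] - cm[1])^2
      dy2 <- (ax[[2]] - cm[2])^2
      dz2 <- (ax[[3]] - cm[3])^2
      d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
      suv <- suv + peaks[l] * exp(-d2 / (2 * sigmas[l]^2))
    }
  }
  set.seed(spec$seed)
  if (spec$noise_sd > 0)
    suv <- suv + array(stats::rnorm(prod(d), 0, spec$noise_sd), d)
  lesions <- data.frame(i = centers[, 1], j = centers[, 2], k = centers[, 3],
                        peak = peaks, sigma_mm = sigmas)
  list(pet = image_volume(suv, labels$spacing, labels$origin, "PET-SUV"),
       lesions = lesions)
}

#' Per-VOI ground-truth positivity for planted lesions
#'
#' A VOI is truth-positive iff the centre voxel of at least one planted
#' lesion lies inside its mask.
#'
#' @param vois a VOI inventory from [build_voi_inventory()].
#' @param lesions the `lesions` data frame from [generate_phantom_pet()].
#' @return logical vector, one entry per VOI (named by VOI id).
#' @export
voi_truth <- function(vois, lesions) {
  out <- vapply(vois, function(v) {
    if (nrow(lesions) == 0) return(FALSE)
    any(vapply(seq_len(nrow(lesions)), function(l) {
      v$mask[lesions$i[l], lesions$j[l], lesions$k[l]]
    }, logical(1)))
  }, logical(1))
  names(out) <- vapply(vois, `[[`, "", "id")
  out
}

#' Similarity transforms (rotation + translation + isotropic scale)
#'
#' The transform maps target-frame mm points to source-frame mm points
#' (the resampling convention): `q = s * R * (p - c) + c + t`. Rotations
#' are intrinsic X-Y-Z Euler rotations in degrees.
#'
#' @param rotation_deg length-3 Euler angles, degrees.
#' @param translation_mm length-3 translation, mm.
#' @param scale isotropic scale, strictly positive.
#' @param center_mm rotation/scaling centre, mm.
#' @return An `axskel_similarity` object.
#' @export
similarity_transform <- function(rotation_deg = c(0, 0, 0),
                                 translation_mm = c(0, 0, 0),
                                 scale = 1, center_mm = c(0, 0, 0)) {
  if (!all(is.finite(c(rotation_deg, translation_mm, scale, center_mm))))
    stop("transform parameters must be finite")
  if (scale <= 0) stop("scale must be strictly positive")
  structure(list(rotation_deg = rotation_deg,
                 translation_mm = translation_mm,
                 scale = scale, center_mm = center_mm),
            class = "axskel_similarity")
}

rotation_matrix <- function(rotation_deg) {
  a <- rotation_deg * pi / 180
  rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])), c(0, sin(a[1]), cos(a[1])))
  ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0), c(-sin(a[2]), 0, cos(a[2])))
  rz <- rbind(c(cos(a[3]), -sin(a[3]), 0), c(sin(a[3]), cos(a[3]), 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

#' @rdname similarity_transform
#' @param transform an `axskel_similarity`.
#' @param pts n x 3 matrix of mm points (target frame).
#' @return `similarity_apply_points()`: n x 3 matrix of source-frame points.
#' @export
similarity_apply_points <- function(transform, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1)
  R <- rotation_matrix(transform$rotation_deg)
  ctr <- transform$center_mm
  q <- transform$scale * t(R %*% t(sweep(pts, 2, ctr)))
  sweep(sweep(q, 2, ctr, `+`), 2, transform$translation_mm, `+`)
}

#' @rdname similarity_transform
#' @export
similarity_inverse <- function(transform) {
  R <- rotation_matrix(transform$rotation_deg)
  # q = sR(p-c)+c+t  =>  p = (1/s) R^T (q - c - t) + c
  # expressed again as a similarity with the same centre:
  # p = s' R' (q - c) + c + t' with s' = 1/s, R' = R^T,
  # t' = -(1/s) R^T t
  Rt <- t(R)
  a <- -Rt %*% transform$translation_mm / transform$scale
  ang <- euler_from_matrix(Rt)
  similarity_transform(rotation_deg = ang,
                       translation_mm = as.numeric(a),
                       scale = 1 / transform$scale,
                       center_mm = transform$center_mm)
}

# Euler X-Y-Z angles (degrees) from a rotation matrix (R = Rz Ry Rx)
euler_from_matrix <- function(R) {
  ry <- asin(pmin(pmax(-R[3, 1], -1), 1))
  if (abs(cos(ry)) > 1e-8) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else {  # gimbal lock
    rx <- atan2(-R[2, 3], R[2, 2])
    rz <- 0
  }
  c(rx, ry, rz) * 180 / pi
}

#' Resample a volume under a known similarity transform
#'
#' The transform maps output (target) coordinates to input (source)
#' coordinates; intensity volumes are interpolated trilinearly, label
#' volumes nearest-neighbour. Applying a transform and then its
#' [similarity_inverse()] recovers the original up to interpolation loss.
#'
#' @param vol `axskel_image` or `axskel_labels`.
#' @param transform an [similarity_transform()].
#' @return Volume of the same class on the same grid.
#' @export
apply_known_similarity <- function(vol, transform) {
  d <- dim(vol$voxels)
  idx <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  src_mm <- similarity_apply_points(transform, voxel_to_mm(idx, vol))
  src_idx <- mm_to_voxel(src_mm, vol)
  if (is_label_volume(vol)) {
    vals <- sample_nearest(vol$voxels, src_idx)
    label_volume(array(as.integer(vals), d), vol$spacing, vol$origin,
                 vol$taxonomy)
  } else {
    vals <- sample_trilinear(vol$voxels, src_idx)
    image_volume(array(vals, d), vol$spacing, vol$origin, vol$modality)
  }
}
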