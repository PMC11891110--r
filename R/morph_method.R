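#' Split a vertebra into body and left/right posterior parts
#'
#' Slice-wise decomposition guided by the spinal cord. Per axial slice a
#' reference anteroposterior position is taken from the cord: the most
#' anterior cord voxel for C1-T3 (whose transverse processes sit relatively
#' anteriorly), the cord-slice centre for T4-L5 and the sacrum. Vertebra
#' voxels strictly anterior of the reference are classified as vertebral
#' body (VB); ties (the reference column itself) go to the posterior part.
#' The posterior remainder is split into left (LPV) and right (RPV) parts
#' by the sagittal plane through the whole-cord centre of mass.
#'
#' Slices holding vertebra voxels but no cord voxels fall back to the
#' nearest cord-bearing slice's reference, with a warning.
#'
#' @param vertebra_mask,cord_mask logical 3-D arrays on the same grid.
#' @param level vertebral level string (`"C1"` .. `"L5"`, or `"S"`).
#' @return `list(vb=, lpv=, rpv=)`: three pairwise-disjoint masks whose
#'   union is the input vertebra mask.
#' @export
split_vertebra <- function(vertebra_mask, cord_mask, level) {
  if (!any(cord_mask)) stop("split_vertebra: empty cord mask")
  anterior_rule <- level %in% c(paste0("C", 1:7), paste0("T", 1:3))
  d <- dim(vertebra_mask)
  com_x <- center_of_mass(cord_mask)[1]

  vert_idx <- which(vertebra_mask, arr.ind = TRUE)
  cord_idx <- which(cord_mask, arr.ind = TRUE)
  cord_slices <- sort(unique(cord_idx[, 3]))
  ref_by_slice <- vapply(cord_slices, function(k) {
    ys <- cord_idx[cord_idx[, 3] == k, 2]
    if (anterior_rule) max(ys) else mean(ys)
  }, numeric(1))
  names(ref_by_slice) <- cord_slices

  vb <- lpv <- rpv <- array(FALSE, d)
  need <- sort(unique(vert_idx[, 3]))
  missing_cord <- setdiff(need, cord_slices)
  if (length(missing_cord) > 0)
    warning("split_vertebra(", level, "): no cord on slice(s) ",
            paste(missing_cord, collapse = ","),
            "; using nearest cord slice reference")
  for (k in need) {
    kk <- if (k %in% cord_slices) k else
      cord_slices[which.min(abs(cord_slices - k))]
    ref <- ref_by_slice[[as.character(kk)]]
    sel <- vert_idx[vert_idx[, 3] == k, , drop = FALSE]
    ant <- sel[, 2] > ref
    vb[sel[ant, , drop = FALSE]] <- TRUE
    post <- sel[!ant, , drop = FALSE]
    left <- post[, 1] < com_x
    lpv[post[left, , drop = FALSE]] <- TRUE
    rpv[post[!left, , drop = FALSE]] <- TRUE
  }
  list(vb = vb, lpv = lpv, rpv = rpv)
}

#' Dilation-overlap segmentation of an intervertebral disk
#'
#' The two adjacent vertebral bodies are dilated with a vertical
#' (craniocaudal) structuring element whose one-sided extent depends on the
#' spine region: 12 mm lumbar, 8 mm thoracic, 4 mm cervical. Overlapping
#' dilated voxels that are not part of the initial bone segmentation are
#' classified as disk.
#'
#' @param vb_upper,vb_lower disjoint VB masks.
#' @param region `"cervical"`, `"thoracic"` or `"lumbar"`.
#' @param bone_mask union of all initial bone structures.
#' @param spacing grid spacing, mm.
#' @return logical disk mask; attribute `"qc"` is `"empty-ivd"` when no
#'   overlap survives.
#' @export
segment_ivd_morph <- function(vb_upper, vb_lower, region, bone_mask,
                              spacing = c(4, 4, 4)) {
  stopifnot(!any(vb_upper & vb_lower))
  len <- c(cervical = 4, thoracic = 8, lumbar = 12)[[region]]
  se <- structuring_element("vertical-line", len, spacing)
  ivd <- binary_dilate(vb_upper, se) & binary_dilate(vb_lower, se) & !bone_mask
  if (!any(ivd)) attr(ivd, "qc") <- "empty-ivd"
  ivd
}

#' Dilation-overlap segmentation of a sacro-iliac joint
#'
#' Sacrum and ilium are dilated iteratively with the 4 mm-radius spherical
#' element (one working voxel) until their dilations overlap; the joint is
#' the overlap minus the initial bone segmentation.
#'
#' @param sacrum_mask,ilium_mask disjoint masks.
#' @param bone_mask union of all initial bone structures.
#' @param spacing grid spacing, mm.
#' @param max_iter dilation cap; no overlap within the cap yields an empty
#'   mask with attribute `"qc" = "no-overlap"`.
#' @return logical joint mask.
#' @export
segment_sij_morph <- function(sacrum_mask, ilium_mask, bone_mask,
                              spacing = c(4, 4, 4), max_iter = 5) {
  stopifnot(!any(sacrum_mask & ilium_mask))
  se <- structuring_element("sphere", spacing[1], spacing)
  res <- dilate_until_overlap(sacrum_mask, ilium_mask, se, max_iter)
  sij <- res$overlap & !bone_mask
  if (!any(sij)) attr(sij, "qc") <- "no-overlap"
  sij
}

#' Joint-centre localisation by dilation overlap
#'
#' Both partner structures are dilated iteratively with the 4 mm sphere
#' until they overlap; the joint centre is the centre of mass of the
#' overlap, rounded to the nearest voxel. Applied to adjacent-level
#' posterior-part pairs (facet joints), rib vs same-level vertebral body
#' (costovertebral) and rib vs same-level ipsilateral posterior part
#' (costotransverse).
#'
#' @param mask_a,mask_b non-empty disjoint masks.
#' @param spacing grid spacing, mm.
#' @param max_iter dilation cap.
#' @return integer voxel index (length 3), or `NULL` with a warning when no
#'   overlap is reached within the cap.
#' @export
locate_joint_center_morph <- function(mask_a, mask_b, spacing = c(4, 4, 4),
                                      max_iter = 5) {
  if (!any(mask_a) || !any(mask_b)) stop("joint partner mask is empty")
  stopifnot(!any(mask_a & mask_b))
  se <- structuring_element("sphere", spacing[1], spacing)
  res <- dilate_until_overlap(mask_a, mask_b, se, max_iter)
  if (!any(res$overlap)) {
    warning("no dilation overlap within ", max_iter, " iterations")
    return(NULL)
  }
  as.integer(round_half_away(center_of_mass(res$overlap)))
}

# legal joint inventory: kind, level key, side
joint_inventory <- function() {
  pairs <- c(paste0("C", 1:7), paste0("T", 1:12), paste0("L", 1:5), "S")
  fj_levels <- paste0(pairs[1:24], "-", pairs[2:25])
  rbind(
    expand.grid(kind = "FJ", level = fj_levels, side = c("left", "right"),
                stringsAsFactors = FALSE),
    expand.grid(kind = "CVJ", level = paste0("T", 1:12),
                side = c("left", "right"), stringsAsFactors = FALSE),
    expand.grid(kind = "CTJ", level = paste0("T", 1:10),
                side = c("left", "right"), stringsAsFactors = FALSE))
}

#' Morphological segmentation of a labelled spine
#'
#' Runs the full morphological route on a skeletal label map: vertebra
#' decomposition for all 24 vertebrae, disk segmentation for the 24
#' adjacent pairs (C1-C2 .. L5-sacrum), both sacro-iliac joints, and
#' joint-centre localisation for the 48 facet, 24 costovertebral and 20
#' costotransverse joints (costotransverse articulations exist at T1-T10
#' only). For the lowest facet pair and disk the sacrum stands in as the
#' inferior partner.
#'
#' @param labels an `axskel_labels` skeletal segmentation on the working
#'   grid.
#' @param spacing working spacing, mm.
#' @return An `axskel_segmentation` list: `splits` (per-vertebra vb/lpv/rpv),
#'   `ivd` (per-pair masks), `sij` (left/right masks), `joints` (data frame
#'   kind/level/side/i/j/k), `qc` (character flags), `source = "morph"`.
#' @export
run_morph_method <- function(labels, spacing = labels$spacing) {
  tax <- labels$taxonomy
  d <- dim(labels$voxels)
  qc <- character(0)
  bone_ids <- tax[c(vertebra_names(), "sacrum", "ilium_left", "ilium_right",
                    paste0("rib_left_", 1:12), paste0("rib_right_", 1:12),
                    "femur_left", "femur_right")]
  bone <- array(labels$voxels %in% bone_ids, d)
  cord <- structure_mask(labels, "spinal_cord")

  lv_names <- sub("vertebra_", "", vertebra_names())
  splits <- list()
  for (lv in lv_names) {
    m <- structure_mask(labels, paste0("vertebra_", lv))
    if (!any(m)) { qc <- c(qc, paste0("missing-vertebra:", lv)); next }
    splits[[lv]] <- split_vertebra(m, cord, lv)
  }

  sacrum <- structure_mask(labels, "sacrum")
  pair_upper <- c(paste0("C", 1:7), paste0("T", 1:12), paste0("L", 1:5))
  pair_lower <- c(pair_upper[-1], "S")
  ivd <- list()
  for (p in seq_along(pair_upper)) {
    up <- pair_upper[p]; lo <- pair_lower[p]
    key <- paste0(up, "-", lo)
    if (is.null(splits[[up]])) next
    lower_vb <- if (lo == "S") sacrum else
      if (is.null(splits[[lo]])) NULL else splits[[lo]]$vb
    if (is.null(lower_vb)) next
    m <- segment_ivd_morph(splits[[up]]$vb, lower_vb, level_region(up),
                           bone, spacing)
    if (!is.null(attr(m, "qc"))) qc <- c(qc, paste0("empty-ivd:", key))
    ivd[[key]] <- m
  }

  sij <- list()
  for (side in c("left", "right")) {
    il <- structure_mask(labels, paste0("ilium_", side))
    if (!any(sacrum) || !any(il)) { qc <- c(qc, paste0("missing-sij:", side)); next }
    m <- segment_sij_morph(sacrum, il, bone, spacing)
    if (!is.null(attr(m, "qc"))) qc <- c(qc, paste0("empty-sij:", side))
    sij[[side]] <- m
  }

  inv <- joint_inventory()
  rows <- list()
  for (r in seq_len(nrow(inv))) {
    kind <- inv$kind[r]; level <- inv$level[r]; side <- inv$side[r]
    ab <- morph_joint_partners(kind, level, side, splits, sacrum, labels)
    if (is.null(ab)) { qc <- c(qc, paste0("missing-joint:", kind, ":", level, ":", side)); next }
    ctr <- locate_joint_center_morph(ab$a, ab$b, spacing)
    if (is.null(ctr)) { qc <- c(qc, paste0("no-overlap:", kind, ":", level, ":", side)); next }
    rows[[length(rows) + 1]] <- data.frame(kind = kind, level = level,
                                           side = side, i = ctr[1],
                                           j = ctr[2], k = ctr[3])
  }
  joints <- do.call(rbind, rows)
  structure(list(splits = splits, ivd = ivd, sij = sij, joints = joints,
                 qc = qc, source = "morph", spacing = spacing, dim = d,
                 sacrum = sacrum),
            class = "axskel_segmentation")
}

# partner masks for one joint; NULL when a required structure is missing
morph_joint_partners <- function(kind, level, side, splits, sacrum, labels) {
  post <- function(lv) if (side == "left") splits[[lv]]$lpv else splits[[lv]]$rpv
  if (kind == "FJ") {
    lv <- strsplit(level, "-")[[1]]
    a <- if (is.null(splits[[lv[1]]])) NULL else post(lv[1])
    b <- if (lv[2] == "S") { if (any(sacrum)) sacrum else NULL } else
      if (is.null(splits[[lv[2]]])) NULL else post(lv[2])
  } else {
    t <- level
    rib <- structure_mask(labels, paste0("rib_", side, "_", sub("T", "", t)))
    if (!any(rib)) return(NULL)
    a <- rib
    b <- if (kind == "CVJ") {
      if (is.null(splits[[t]])) NULL else splits[[t]]$vb
    } else {
      if (is.null(splits[[t]])) NULL else post(t)
    }
  }
  if (is.null(a) || is.null(b) || !any(a) || !any(b)) return(NULL)
  list(a = a, b = b)
}
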