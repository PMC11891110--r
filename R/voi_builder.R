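#' Split a vertebral body into eight quadrants
#'
#' The VB centre of mass fixes a mid-sagittal slice; the four corners of
#' the VB bounding box within that slice (antero-superior, antero-inferior,
#' postero-superior, postero-inferior) act as anchors. Every VB voxel is
#' assigned to the nearest corner by its (anteroposterior, craniocaudal)
#' mm coordinates, and the left/right split by the centre-of-mass sagittal
#' plane doubles the four groups into eight. The eight sub-masks partition
#' the VB. Distance ties go to the first corner in the order
#' ant-sup, ant-inf, post-sup, post-inf; voxels on the sagittal plane go to
#' the right half.
#'
#' @param vb_mask non-empty logical mask.
#' @param spacing grid spacing, mm.
#' @return Named list of 8 masks (`left-ant-sup`, ..., `right-post-inf`).
#'   A single-voxel VB collapses into one quadrant and carries attribute
#'   `"qc" = "degenerate-vb"`.
#' @export
split_vb_quadrants <- function(vb_mask, spacing = c(4, 4, 4)) {
  idx <- which(vb_mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("split_vb_quadrants: empty mask")
  com <- colMeans(idx)
  mid <- idx[idx[, 1] == round_half_away(com[1]), , drop = FALSE]
  if (nrow(mid) == 0) mid <- idx  # COM slice empty (hollow mask): use bbox of all
  yr <- range(mid[, 2]); zr <- range(mid[, 3])
  # corners in (anteroposterior, craniocaudal) mm; anterior = larger j
  corners <- rbind("ant-sup" = c(yr[2], zr[2]), "ant-inf" = c(yr[2], zr[1]),
                   "post-sup" = c(yr[1], zr[2]), "post-inf" = c(yr[1], zr[1]))
  dy <- outer(idx[, 2], corners[, 1], `-`) * spacing[2]
  dz <- outer(idx[, 3], corners[, 2], `-`) * spacing[3]
  nearest <- apply(dy^2 + dz^2, 1, which.min)  # which.min takes first on ties
  side <- ifelse(idx[, 1] < com[1], "left", "right")
  out <- list()
  for (s in c("left", "right")) for (q in rownames(corners)) {
    m <- array(FALSE, dim(vb_mask))
    sel <- side == s & rownames(corners)[nearest] == q
    m[idx[sel, , drop = FALSE]] <- TRUE
    out[[paste0(s, "-", q)]] <- m
  }
  if (nrow(idx) == 1) attr(out, "qc") <- "degenerate-vb"
  out
}

#' Compose a discovertebral unit
#'
#' DVU = the four inferior quadrants of the upper VB, the disk, and the
#' four superior quadrants of the lower VB.
#'
#' @param upper_quadrants,lower_quadrants outputs of
#'   [split_vb_quadrants()] for the two vertebrae.
#' @param ivd_mask disk mask (may be empty, e.g. ankylosis or the C1-C2
#'   unit; flagged via attribute `"qc"`).
#' @return logical DVU mask.
#' @export
compose_dvu <- function(upper_quadrants, ivd_mask, lower_quadrants) {
  pick <- function(quads, tag) {
    sel <- grep(tag, names(quads), value = TRUE)
    Reduce(`|`, quads[sel])
  }
  out <- pick(upper_quadrants, "-inf$") | ivd_mask | pick(lower_quadrants, "-sup$")
  if (!any(ivd_mask)) attr(out, "qc") <- "empty-ivd"
  out
}

#' Build the complete per-scan VOI inventory
#'
#' On a complete segmentation this yields exactly 118 records: 24 DVUs
#' (adjacent pairs C1-C2 .. L5-sacrum), 48 facet, 24 costovertebral and 20
#' costotransverse joint spheres, and 2 sacro-iliac joints. Joint centres
#' are expanded into spherical VOIs (default radius 10 mm). Missing
#' structures yield fewer records; each absence is QC-flagged.
#'
#' For the L5-sacrum unit the sacral contribution uses the same quadrant
#' rule applied to the sacrum mask. The inventory is a pure function of the
#' segmentation: re-running it is bit-identical.
#'
#' @param seg an `axskel_segmentation` (from [run_morph_method()] or
#'   [run_atlas_method()]).
#' @param sphere_radius_mm joint VOI radius, mm.
#' @return List of VOI records (`id`, `kind`, `level`, `side`, `region`,
#'   `source`, `mask`), with QC flags in attribute `"qc"`.
#' @export
build_voi_inventory <- function(seg, sphere_radius_mm = 10) {
  spacing <- seg$spacing; d <- seg$dim
  qc <- character(0)
  vois <- list()
  add <- function(kind, level, side, region, mask) {
    id <- paste(c(kind, level, if (!is.na(side)) side), collapse = ":")
    vois[[length(vois) + 1]] <<- list(id = id, kind = kind, level = level,
                                      side = side, region = region,
                                      source = seg$source, mask = mask)
  }

  pair_upper <- c(paste0("C", 1:7), paste0("T", 1:12), paste0("L", 1:5))
  pair_lower <- c(pair_upper[-1], "S")
  quads <- list()
  for (lv in names(seg$splits)) {
    if (any(seg$splits[[lv]]$vb))
      quads[[lv]] <- split_vb_quadrants(seg$splits[[lv]]$vb, spacing)
  }
  if (!is.null(seg$sacrum) && any(seg$sacrum))
    quads[["S"]] <- split_vb_quadrants(seg$sacrum, spacing)

  for (p in seq_along(pair_upper)) {
    up <- pair_upper[p]; lo <- pair_lower[p]
    key <- paste0(up, "-", lo)
    if (is.null(quads[[up]]) || is.null(quads[[lo]])) {
      qc <- c(qc, paste0("missing-dvu:", key)); next
    }
    ivd <- seg$ivd[[key]]
    if (is.null(ivd)) { ivd <- array(FALSE, d); qc <- c(qc, paste0("missing-ivd:", key)) }
    dvu <- compose_dvu(quads[[up]], ivd, quads[[lo]])
    add("DVU", key, NA_character_, level_region(up), dvu)
  }

  inv <- joint_inventory()
  for (r in seq_len(nrow(inv))) {
    sel <- !is.null(seg$joints) &&
      any(seg$joints$kind == inv$kind[r] & seg$joints$level == inv$level[r] &
            seg$joints$side == inv$side[r])
    if (!sel) { qc <- c(qc, paste0("missing-joint:", inv$kind[r], ":",
                                   inv$level[r], ":", inv$side[r])); next }
    row <- seg$joints[seg$joints$kind == inv$kind[r] &
                        seg$joints$level == inv$level[r] &
                        seg$joints$side == inv$side[r], ][1, ]
    mask <- sphere_voi(c(row$i, row$j, row$k), d, sphere_radius_mm, spacing)
    lvl1 <- strsplit(inv$level[r], "-")[[1]][1]
    add(inv$kind[r], inv$level[r], inv$side[r], level_region(lvl1), mask)
  }

  for (side in c("left", "right")) {
    m <- seg$sij[[side]]
    if (is.null(m) || !any(m)) { qc <- c(qc, paste0("missing-sij:", side)); next }
    add("SIJ", "S", side, "lumbar", m)
  }
  attr(vois, "qc") <- qc
  vois
}

#' Summarise a VOI inventory as a manifest data frame
#' @param vois output of [build_voi_inventory()].
#' @return data.frame (id, kind, level, side, region, source, n_voxels).
#' @export
voi_manifest <- function(vois) {
  do.call(rbind, lapply(vois, function(v)
    data.frame(id = v$id, kind = v$kind, level = v$level, side = v$side,
               region = v$region, source = v$source,
               n_voxels = sum(v$mask))))
}

#' Write a VOI inventory as a multi-label NIfTI plus CSV manifest
#'
#' Overlapping VOIs are resolved in inventory order: later VOIs never
#' overwrite earlier non-background voxels.
#'
#' @param vois VOI inventory.
#' @param spacing grid spacing, mm.
#' @param path output NIfTI path; the manifest gains a `label` column and is
#'   written beside it as `<path>.manifest.csv`.
#' @export
write_voi_nifti <- function(vois, spacing, path) {
  d <- dim(vois[[1]]$mask)
  arr <- array(0L, d)
  man <- voi_manifest(vois)
  man$label <- seq_along(vois)
  for (v in seq_along(vois)) {
    m <- vois[[v]]$mask & arr == 0L
    arr[m] <- v
  }
  write_volume_nifti(label_volume(arr, spacing,
                                  taxonomy = stats::setNames(man$label, man$id)),
                     path)
  utils::write.csv(man, paste0(path, ".manifest.csv"), row.names = FALSE)
  invisible(man)
}
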