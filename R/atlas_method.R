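#' Spinal length of a labelled scan
#'
#' Euclidean distance in mm between the centres of mass of C1 and the
#' sacrum; used as the anatomy summary that drives atlas selection.
#'
#' @param labels an `axskel_labels` volume.
#' @return length in mm.
#' @export
spinal_length <- function(labels) {
  for (s in c("vertebra_C1", "sacrum"))
    if (!any(labels$voxels == labels$taxonomy[[s]]))
      stop("spinal_length: missing structure ", s)
  a <- attr(center_of_mass(structure_mask(labels, "vertebra_C1"), labels), "mm")
  b <- attr(center_of_mass(structure_mask(labels, "sacrum"), labels), "mm")
  sqrt(sum((a - b)^2))
}

#' Select atlas scans at spinal-length percentiles
#'
#' Scans at the 10th, 30th, 50th, 70th and 90th percentiles of the
#' spinal-length distribution are chosen, ensuring anatomical diversity.
#' The percentile convention is nearest-rank ceiling on the ascending
#' (stable) sort: rank `ceiling(p * n / 100)`, clamped to `[1, n]`;
#' duplicate ranks step to the next unused rank.
#'
#' @param lengths numeric vector of spinal lengths (mm), at least as many
#'   as percentiles.
#' @param percentiles percentile set.
#' @return Integer indices into `lengths` identifying the selected scans,
#'   with the 1-based sorted ranks attached as attribute `"ranks"`.
#' @export
select_atlases <- function(lengths, percentiles = c(10, 30, 50, 70, 90)) {
  n <- length(lengths)
  if (n < length(percentiles))
    stop("need at least ", length(percentiles), " lengths")
  ord <- order(lengths)  # stable
  ranks <- integer(0)
  for (p in percentiles) {
    r <- as.integer(min(max(ceiling(p * n / 100), 1L), n))
    while (r %in% ranks && r < n) r <- r + 1L
    while (r %in% ranks && r > 1) r <- r - 1L
    ranks <- c(ranks, r)
  }
  structure(ord[ranks], ranks = ranks)
}

# the 26 partial-atlas units: 24 adjacent-vertebra pairs + 2 sacro-iliac
atlas_units <- function() {
  pairs <- c(paste0("C", 1:7), paste0("T", 1:12), paste0("L", 1:5), "S")
  units <- data.frame(
    unit = c(paste0(pairs[1:24], "-", pairs[2:25]), "S-ilL", "S-ilR"),
    kind = c(rep("pair", 24), "sij", "sij"),
    upper = c(paste0("vertebra_", pairs[1:24]), "sacrum", "sacrum"),
    lower = c(paste0("vertebra_", pairs[2:24]), "sacrum", "ilium_left",
              "ilium_right"))
  units
}

#' Bounding box of a mask and volume cropping
#'
#' `mask_bbox()` returns the tight `lo`/`hi` index box of a mask expanded
#' by a margin and clipped to the grid; `crop_image()` cuts a volume to a
#' box, keeping world coordinates consistent via the origin.
#'
#' @param mask logical array.
#' @param margin expansion in voxels.
#' @param dim grid dimensions for clipping.
#' @return `mask_bbox()`: 3 x 2 matrix (`lo`, `hi`), or `NULL` for an empty
#'   mask.
#' @export
mask_bbox <- function(mask, margin = 0L, dim = dim(mask)) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  lo <- pmax(apply(idx, 2, min) - margin, 1L)
  hi <- pmin(apply(idx, 2, max) + margin, dim)
  cbind(lo = lo, hi = hi)
}

#' @rdname mask_bbox
#' @param vol volume to crop.
#' @param box box from `mask_bbox()`.
#' @export
crop_image <- function(vol, box) {
  arr <- vol$voxels[box[1, 1]:box[1, 2], box[2, 1]:box[2, 2],
                    box[3, 1]:box[3, 2], drop = FALSE]
  origin <- drop(voxel_to_mm(box[, 1], vol))
  if (is_label_volume(vol)) label_volume(arr, vol$spacing, origin, vol$taxonomy)
  else image_volume(arr, vol$spacing, origin, vol$modality)
}

#' Zero-pad an image volume
#'
#' Adds a zero layer of `pad` voxels on every side before registration, so
#' the moving image cannot scale uncontrolledly outside the fixed field of
#' view. The origin shifts accordingly so world coordinates are unchanged.
#'
#' @param vol `axskel_image`.
#' @param pad layer width in voxels (default 10).
#' @export
pad_volume <- function(vol, pad = 10L) {
  d <- dim(vol$voxels)
  out <- array(0, d + 2L * pad)
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- vol$voxels
  image_volume(out, vol$spacing, vol$origin - pad * vol$spacing, vol$modality)
}

#' Build the 26 partial atlases for one atlas scan
#'
#' Each unit covers two adjacent structures (a vertebra pair, or the sacrum
#' and one ilium): the crop is the joint bounding box of the two structure
#' masks expanded by a margin, applied to the CT and to the reference label
#' map. The reference segmentation contributes unit-local labels (1 upper
#' VB / sacrum, 2 lower VB / ilium, 3 disk / SIJ) and the joint centres
#' that fall to the unit: the facet pair of the unit's level plus the
#' costovertebral/costotransverse joints of the upper member.
#'
#' @param ct `axskel_image` atlas CT.
#' @param labels `axskel_labels` skeletal map of the atlas scan.
#' @param reference an `axskel_segmentation` of the atlas scan (the
#'   manually curated reference in a clinical setting; the phantom's
#'   reference segmentation here).
#' @param margin crop margin in voxels.
#' @return List of `axskel_partial_atlas` objects (length 26 on a complete
#'   scan); missing structures skip their unit with a QC flag in attribute
#'   `"qc"`.
#' @export
make_partial_atlases <- function(ct, labels, reference, margin = 2L) {
  units <- atlas_units()
  qc <- character(0)
  out <- list()
  for (u in seq_len(nrow(units))) {
    un <- units[u, ]
    m_up <- structure_mask(labels, un$upper)
    m_lo <- structure_mask(labels, un$lower)
    if (!any(m_up) || !any(m_lo)) { qc <- c(qc, paste0("missing-unit:", un$unit)); next }
    box <- mask_bbox(m_up | m_lo, margin, dim(labels$voxels))
    ct_crop <- crop_image(ct, box)
    lab <- unit_reference_labels(un, reference, dim(labels$voxels), labels)
    lab_crop <- lab[box[1, 1]:box[1, 2], box[2, 1]:box[2, 2],
                    box[3, 1]:box[3, 2], drop = FALSE]
    pts <- unit_reference_points(un, reference, ct)
    out[[un$unit]] <- structure(
      list(unit = un$unit, kind = un$kind, box = box, ct = ct_crop,
           labels = lab_crop, points = pts),
      class = "axskel_partial_atlas")
  }
  attr(out, "qc") <- qc
  out
}

# unit-local reference label array in the full frame
unit_reference_labels <- function(un, reference, d, labels) {
  lab <- array(0L, d)
  if (un$kind == "pair") {
    lv <- strsplit(un$unit, "-")[[1]]
    up_vb <- reference$splits[[lv[1]]]$vb
    lo_vb <- if (lv[2] == "S") reference$sacrum else reference$splits[[lv[2]]]$vb
    ivd <- reference$ivd[[un$unit]]
    if (!is.null(up_vb)) lab[up_vb] <- 1L
    if (!is.null(lo_vb)) lab[lo_vb] <- 2L
    if (!is.null(ivd)) lab[ivd] <- 3L
  } else {
    side <- if (un$lower == "ilium_left") "left" else "right"
    lab[reference$sacrum] <- 1L
    lab[structure_mask(labels, un$lower)] <- 2L
    sij <- reference$sij[[side]]
    if (!is.null(sij)) lab[sij] <- 3L
  }
  lab
}

# joint centres belonging to a unit, in atlas-frame mm
unit_reference_points <- function(un, reference, vol) {
  if (un$kind != "pair" || is.null(reference$joints)) return(NULL)
  lv <- strsplit(un$unit, "-")[[1]]
  j <- reference$joints
  sel <- (j$kind == "FJ" & j$level == un$unit) |
    (j$kind %in% c("CVJ", "CTJ") & j$level == lv[1])
  j <- j[sel, , drop = FALSE]
  if (nrow(j) == 0) return(NULL)
  mm <- voxel_to_mm(as.matrix(j[, c("i", "j", "k")]), vol)
  cbind(j[, c("kind", "level", "side")],
        x_mm = mm[, 1], y_mm = mm[, 2], z_mm = mm[, 3])
}

#' Similarity-transform registration by stochastic gradient descent
#'
#' Estimates the similarity transform (rotation, translation, isotropic
#' scale about the fixed-image centre) mapping fixed-image coordinates to
#' moving-image coordinates, by minimising the mean squared intensity
#' difference over a random subsample of fixed voxels (a stochastic
#' approximation of the full metric, one draw per resolution level). The
#' optimiser is quasi-Newton gradient descent (BFGS) on numerically
#' differenced gradients with per-parameter scaling, run over two
#' resolution levels (mean-smoothed, then full resolution) for a fixed
#' total iteration budget. Deterministic given `seed`.
#'
#' @param fixed `axskel_image`, zero-padded by the caller (see
#'   [pad_volume()]).
#' @param moving `axskel_image`.
#' @param iterations total gradient iterations (default 100).
#' @param n_samples fixed-voxel subsample size per iteration.
#' @param seed RNG seed for the metric sampling.
#' @param init optional initial `axskel_similarity`.
#' @return An `axskel_similarity` with the final metric value in attribute
#'   `"metric"`.
#' @export
register_similarity <- function(fixed, moving, iterations = 100,
                                n_samples = 2000, seed = 1L, init = NULL) {
  if (stats::sd(fixed$voxels) == 0 || stats::sd(moving$voxels) == 0)
    stop("registration failure: constant image")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  d <- dim(fixed$voxels)
  center <- fixed$origin + (d - 1) / 2 * fixed$spacing
  # parameters: (rx, ry, rz rad, tx, ty, tz mm, log s)
  p <- if (is.null(init)) rep(0, 7) else c(
    init$rotation_deg * pi / 180, init$translation_mm, log(init$scale))
  half_extent <- sqrt(sum(((d - 1) * fixed$spacing / 2)^2))
  scales <- c(rep(half_extent, 3), rep(1, 3), half_extent)  # rad/mm/log -> mm

  fg_idx <- which(fixed$voxels != 0, arr.ind = TRUE)
  all_idx <- if (nrow(fg_idx) >= n_samples) fg_idx else
    which(array(TRUE, d), arr.ind = TRUE)

  levels <- list(list(fix = smooth_volume(fixed), mov = smooth_volume(moving),
                      iters = ceiling(iterations / 2), step = 4),
                 list(fix = fixed, mov = moving,
                      iters = floor(iterations / 2), step = 1))
  for (lev in levels) {
    mov_arr <- lev$mov$voxels
    metric <- function(par, pts_mm, vals) {
      q <- sim_map(par, pts_mm, center)
      qi <- sweep(sweep(q, 2, lev$mov$origin), 2, lev$mov$spacing, `/`) + 1
      mean((sample_trilinear(mov_arr, qi) - vals)^2)
    }
    sel <- sample.int(nrow(all_idx), min(n_samples, nrow(all_idx)))
    pts_mm <- voxel_to_mm(all_idx[sel, , drop = FALSE], fixed)
    vals <- lev$fix$voxels[all_idx[sel, , drop = FALSE]]
    # quasi-Newton descent in the scaled parameter space (mm-equivalent
    # units for all seven parameters)
    fn <- function(ps) metric(ps / scales, pts_mm, vals)
    opt <- stats::optim(p * scales, fn, method = "BFGS",
                        control = list(maxit = lev$iters, reltol = 1e-10,
                                       ndeps = rep(1e-2, 7)))
    p <- opt$par / scales
  }
  out <- similarity_transform(rotation_deg = p[1:3] * 180 / pi,
                              translation_mm = p[4:6], scale = exp(p[7]),
                              center_mm = center)
  attr(out, "metric") <- {
    pts_mm <- voxel_to_mm(all_idx, fixed)
    q <- sim_map(p, pts_mm, center)
    qi <- sweep(sweep(q, 2, moving$origin), 2, moving$spacing, `/`) + 1
    mean((sample_trilinear(moving$voxels, qi) - fixed$voxels[all_idx])^2)
  }
  out
}

sim_map <- function(par, pts_mm, center) {
  R <- rotation_matrix(par[1:3] * 180 / pi)
  q <- exp(par[7]) * t(R %*% t(sweep(pts_mm, 2, center)))
  sweep(sweep(q, 2, center, `+`), 2, par[4:6], `+`)
}

# separable 3^3 mean filter applied twice (approximate Gaussian)
smooth_volume <- function(vol) {
  arr <- vol$voxels
  for (rep in 1:2) for (a in 1:3) {
    off1 <- off2 <- c(0L, 0L, 0L); off1[a] <- 1L; off2[a] <- -1L
    arr <- (arr + shift_array(arr, off1) + shift_array(arr, off2)) / 3
  }
  image_volume(arr, vol$spacing, vol$origin, vol$modality)
}

shift_array <- function(arr, off) {
  d <- dim(arr)
  out <- array(0, d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    o <- off[a]
    if (abs(o) >= d[a]) return(out)
    if (o >= 0) { src[[a]] <- 1:(d[a] - o); dst[[a]] <- (1 + o):d[a] }
    else { src[[a]] <- (1 - o):d[a]; dst[[a]] <- 1:(d[a] + o) }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

#' Propagate an atlas label crop into a target frame
#'
#' Nearest-neighbour warp of the atlas unit label map through the
#' registration transform: each target voxel looks up the atlas label at
#' its mapped source position. The label set can only shrink, never grow.
#'
#' @param atlas an `axskel_partial_atlas`.
#' @param transform `axskel_similarity` from [register_similarity()]
#'   (fixed = target crop, moving = atlas crop).
#' @param target a volume defining the target crop grid (dims, spacing,
#'   origin).
#' @return integer label array on the target grid.
#' @export
propagate_labels <- function(atlas, transform, target) {
  d <- dim(target$voxels)
  idx <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  q <- similarity_apply_points(transform, voxel_to_mm(idx, target))
  qi <- sweep(sweep(q, 2, atlas$ct$origin), 2, atlas$ct$spacing, `/`) + 1
  array(as.integer(sample_nearest(atlas$labels, qi)), d)
}

#' Majority-vote label fusion
#'
#' Per voxel and per label: a label wins iff at least 3 of the 5 propagated
#' atlases assign it (a strict majority, so conflicting winners are
#' impossible). Voxels with no majority label stay background.
#'
#' @param propagated list of exactly 5 congruent integer label arrays.
#' @return fused integer label array.
#' @export
fuse_labels <- function(propagated) {
  if (length(propagated) != 5) stop("majority voting expects exactly 5 label maps")
  d <- dim(propagated[[1]])
  for (m in propagated) if (!identical(dim(m), d)) stop("incongruent grids")
  out <- array(0L, d)
  labs <- setdiff(unique(unlist(lapply(propagated, function(m) unique(as.vector(m))))), 0L)
  for (l in labs) {
    cnt <- Reduce(`+`, lapply(propagated, function(m) m == l))
    out[cnt >= 3] <- l
  }
  out
}

#' Fuse joint-centre estimates by coordinate averaging
#'
#' Component-wise mean of the five estimated mm locations, then rounded to
#' the nearest voxel (half away from zero).
#'
#' @param points_mm 5 x 3 matrix of finite mm coordinates.
#' @param vol volume defining the voxel grid.
#' @return integer voxel index (length 3).
#' @export
fuse_joint_centers <- function(points_mm, vol) {
  if (any(!is.finite(points_mm))) stop("non-finite joint centre")
  mean_mm <- colMeans(points_mm)
  as.integer(round_half_away(drop(mm_to_voxel(mean_mm, vol))))
}

#' Multi-atlas segmentation of a target scan
#'
#' For each of the 26 units the target is cropped with the skeletal-map
#' bounding boxes, zero-padded by 10 voxels, and the five corresponding
#' partial atlases are registered onto it; their label maps are propagated
#' and fused by majority voting, and their joint points by coordinate
#' averaging. The fused unit crops are re-integrated craniocaudally (then
#' the sacro-iliac units) into the target frame; later units never
#' overwrite earlier non-background voxels.
#'
#' @param ct target `axskel_image`.
#' @param labels target `axskel_labels` (the initial skeletal
#'   segmentation supplying the bounding boxes).
#' @param atlas_library list of 5 atlas scans, each a list of partial
#'   atlases from [make_partial_atlases()].
#' @param margin crop margin, voxels.
#' @param pad zero-padding, voxels.
#' @param iterations,n_samples,seed registration controls, see
#'   [register_similarity()].
#' @param units optional character subset of unit ids to segment.
#' @return An `axskel_segmentation` (source `"atlas"`).
#' @export
run_atlas_method <- function(ct, labels, atlas_library, margin = 2L,
                             pad = 10L, iterations = 100, n_samples = 2000,
                             seed = 1L, units = NULL) {
  if (length(atlas_library) < 5) stop("atlas library needs 5 atlas scans")
  tax <- labels$taxonomy
  d <- dim(labels$voxels)
  un_tab <- atlas_units()
  if (!is.null(units)) un_tab <- un_tab[un_tab$unit %in% units, ]
  qc <- character(0)
  up_lab <- array(0L, d)   # structure-coded fused map; first writer wins
  claim <- array(FALSE, d)
  splits <- list(); ivd <- list(); sij <- list()
  joint_pts <- list()

  for (u in seq_len(nrow(un_tab))) {
    un <- un_tab[u, ]
    m_up <- structure_mask(labels, un$upper)
    m_lo <- structure_mask(labels, un$lower)
    if (!any(m_up) || !any(m_lo)) { qc <- c(qc, paste0("missing-unit:", un$unit)); next }
    box <- mask_bbox(m_up | m_lo, margin, d)
    target_crop <- crop_image(ct, box)
    fixed <- pad_volume(target_crop, pad)
    props <- list(); pts <- list()
    ok <- TRUE
    for (s in seq_along(atlas_library)) {
      pa <- atlas_library[[s]][[un$unit]]
      if (is.null(pa)) { ok <- FALSE; break }
      tr <- tryCatch(
        register_similarity(fixed, pa$ct, iterations = iterations,
                            n_samples = n_samples, seed = seed + 1000L * s),
        error = function(e) NULL)
      if (is.null(tr)) { ok <- FALSE; break }
      props[[s]] <- propagate_labels(pa, tr, target_crop)
      if (!is.null(pa$points)) {
        inv_tr <- similarity_inverse(tr)
        tp <- similarity_apply_points(
          inv_tr, as.matrix(pa$points[, c("x_mm", "y_mm", "z_mm")]))
        pts[[s]] <- cbind(pa$points[, c("kind", "level", "side")],
                          x_mm = tp[, 1], y_mm = tp[, 2], z_mm = tp[, 3])
      }
    }
    if (!ok || length(props) < 5) {
      qc <- c(qc, paste0("registration-failure:", un$unit)); next
    }
    fused <- fuse_labels(props)
    # re-integrate into the full frame
    sl <- list(box[1, 1]:box[1, 2], box[2, 1]:box[2, 2], box[3, 1]:box[3, 2])
    sub_claim <- claim[sl[[1]], sl[[2]], sl[[3]]]
    fused[sub_claim] <- 0L
    if (un$kind == "pair") {
      lv <- strsplit(un$unit, "-")[[1]]
      for (code in 1:2) {
        nm <- lv[code]
        if (nm == "S") next
        vb <- array(FALSE, d)
        vb[sl[[1]], sl[[2]], sl[[3]]] <- fused == code
        if (is.null(splits[[nm]]))
          splits[[nm]] <- list(vb = vb, lpv = array(FALSE, d),
                               rpv = array(FALSE, d))
        else splits[[nm]]$vb <- splits[[nm]]$vb | vb
      }
      m <- array(FALSE, d)
      m[sl[[1]], sl[[2]], sl[[3]]] <- fused == 3L
      ivd[[un$unit]] <- m
      if (!any(m)) qc <- c(qc, paste0("empty-ivd:", un$unit))
    } else {
      side <- if (un$lower == "ilium_left") "left" else "right"
      m <- array(FALSE, d)
      m[sl[[1]], sl[[2]], sl[[3]]] <- fused == 3L
      sij[[side]] <- m
      if (!any(m)) qc <- c(qc, paste0("empty-sij:", side))
    }
    claim[sl[[1]], sl[[2]], sl[[3]]] <- sub_claim | fused != 0L
    if (length(pts) == 5) {
      keys <- unique(do.call(rbind, lapply(pts, function(x) x[, c("kind", "level", "side")])))
      for (r in seq_len(nrow(keys))) {
        coords <- do.call(rbind, lapply(pts, function(x) {
          sel <- x$kind == keys$kind[r] & x$level == keys$level[r] &
            x$side == keys$side[r]
          if (!any(sel)) return(NULL)
          as.matrix(x[sel, c("x_mm", "y_mm", "z_mm")])[1, , drop = FALSE]
        }))
        if (is.null(coords) || nrow(coords) < 5) next
        ctr <- fuse_joint_centers(coords, labels)
        ctr <- pmin(pmax(ctr, 1L), d)
        joint_pts[[length(joint_pts) + 1]] <-
          data.frame(kind = keys$kind[r], level = keys$level[r],
                     side = keys$side[r], i = ctr[1], j = ctr[2], k = ctr[3])
      }
    }
  }
  # vertebrae never produced by any segmented unit fall back to nothing;
  # the sacrum mask for DVU composition comes from the initial labels
  joints <- if (length(joint_pts)) do.call(rbind, joint_pts) else NULL
  structure(list(splits = splits, ivd = ivd, sij = sij, joints = joints,
                 qc = qc, source = "atlas", spacing = labels$spacing,
                 dim = d, sacrum = structure_mask(labels, "sacrum")),
            class = "axskel_segmentation")
}
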