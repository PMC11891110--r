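#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b logical masks on congruent grids.
#' @return value in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

#' Average (symmetric) Hausdorff distance
#'
#' Mean over voxels of A of the distance to the nearest voxel of B,
#' averaged with the reverse direction: `(mean_a d(a,B) + mean_b d(b,A)) / 2`,
#' with distances between voxel centres in mm. This symmetric
#' mean-of-directed-means variant is the common default; it is 0 iff the
#' masks are equal and scales linearly with spacing.
#'
#' @param a,b non-empty logical masks.
#' @param spacing grid spacing, mm.
#' @return distance in mm.
#' @export
average_hausdorff <- function(a, b, spacing = c(4, 4, 4)) {
  stopifnot(identical(dim(a), dim(b)))
  pa <- which(a, arr.ind = TRUE); pb <- which(b, arr.ind = TRUE)
  if (nrow(pa) == 0 || nrow(pb) == 0)
    stop("average_hausdorff undefined for an empty mask")
  pa <- sweep(pa, 2, spacing, `*`); pb <- sweep(pb, 2, spacing, `*`)
  (mean(min_dists(pa, pb)) + mean(min_dists(pb, pa))) / 2
}

# for each row of x, distance to the nearest row of y (chunked pairwise)
min_dists <- function(x, y) {
  chunk <- max(1L, floor(2e6 / nrow(y)))
  out <- numeric(nrow(x))
  y2 <- rowSums(y^2)
  for (s in seq(1, nrow(x), by = chunk)) {
    e <- min(s + chunk - 1, nrow(x))
    xx <- x[s:e, , drop = FALSE]
    d2 <- outer(rowSums(xx^2), y2, `+`) - 2 * xx %*% t(y)
    out[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Joint-centre error distance
#'
#' Euclidean distance in mm between the voxel centres of an estimated and
#' a reference joint centre. On the 4 mm working grid a one-voxel axial
#' offset gives 4.00 mm and a one-voxel in-plane diagonal offset 5.66 mm.
#'
#' @param p,q voxel indices (length 3) or joint rows with `i,j,k` fields.
#' @param spacing grid spacing, mm.
#' @param id_p,id_q optional joint identifiers; if both are given they must
#'   match.
#' @return distance in mm.
#' @export
error_distance <- function(p, q, spacing = c(4, 4, 4),
                           id_p = NULL, id_q = NULL) {
  if (!is.null(id_p) && !is.null(id_q) && !identical(id_p, id_q))
    stop("error_distance: mismatched joint ids (", id_p, " vs ", id_q, ")")
  if (is.list(p)) p <- c(p$i, p$j, p$k)
  if (is.list(q)) q <- c(q$i, q$j, q$k)
  sqrt(sum(((p - q) * spacing)^2))
}

#' Test-retest reproducibility of a segmentation method
#'
#' The spine bone mask of the second scan is rigidly aligned onto the
#' first (centre-of-mass translation plus principal-axes rotation, scale
#' locked to 1); the same transform is applied to the second scan's output
#' masks and joint centres, and the agreement is summarised with Dice,
#' average Hausdorff distance and joint-centre error distance.
#'
#' @param seg1,seg2 `axskel_segmentation` outputs of the two scans.
#' @param labels1,labels2 the two skeletal label maps (supply the spine
#'   bone masks used for alignment).
#' @return data.frame (structure, metric, value).
#' @export
test_retest <- function(seg1, seg2, labels1, labels2) {
  tr <- rigid_align(spine_bone_mask(labels2), spine_bone_mask(labels1),
                    labels2$spacing)
  sp <- labels1$spacing
  warp_mask <- function(m) {
    d <- dim(m)
    idx <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
    src <- similarity_apply_points(tr, voxel_to_mm(idx, labels1))
    si <- sweep(sweep(src, 2, labels2$origin), 2, labels2$spacing, `/`) + 1
    array(sample_nearest(m, si) > 0, d)
  }
  rows <- list()
  rec <- function(structure, metric, value)
    rows[[length(rows) + 1]] <<- data.frame(structure = structure,
                                            metric = metric, value = value)
  vols <- c(stats::setNames(paste0("DVU:", names(seg1$ivd)), names(seg1$ivd)))
  for (key in names(seg1$ivd)) {
    m1 <- seg1$ivd[[key]]; m2 <- seg2$ivd[[key]]
    if (is.null(m2)) next
    m2w <- warp_mask(m2)
    rec(paste0("IVD:", key), "dsc", dice(m1, m2w))
    if (any(m1) && any(m2w))
      rec(paste0("IVD:", key), "avg_hd_mm", average_hausdorff(m1, m2w, sp))
  }
  for (side in names(seg1$sij)) {
    m2 <- seg2$sij[[side]]
    if (is.null(m2)) next
    m2w <- warp_mask(m2)
    rec(paste0("SIJ:", side), "dsc", dice(seg1$sij[[side]], m2w))
    if (any(seg1$sij[[side]]) && any(m2w))
      rec(paste0("SIJ:", side), "avg_hd_mm",
          average_hausdorff(seg1$sij[[side]], m2w, sp))
  }
  if (!is.null(seg1$joints) && !is.null(seg2$joints)) {
    j1 <- seg1$joints; j2 <- seg2$joints
    inv_tr <- similarity_inverse(tr)
    for (r in seq_len(nrow(j1))) {
      sel <- j2$kind == j1$kind[r] & j2$level == j1$level[r] &
        j2$side == j1$side[r]
      if (!any(sel)) next
      p2 <- voxel_to_mm(as.numeric(j2[sel, c("i", "j", "k")][1, ]), labels2)
      p2w <- similarity_apply_points(inv_tr, p2)
      p1 <- voxel_to_mm(as.numeric(j1[r, c("i", "j", "k")]), labels1)
      # snap the aligned centre to the grid before measuring, as both
      # methods report voxel centres
      v2 <- round_half_away(drop(mm_to_voxel(p2w, labels1)))
      rec(paste(j1$kind[r], j1$level[r], j1$side[r], sep = ":"), "err_mm",
          error_distance(as.numeric(v2), drop(mm_to_voxel(p1, labels1)), sp))
    }
  }
  do.call(rbind, rows)
}

spine_bone_mask <- function(labels) {
  ids <- labels$taxonomy[c(vertebra_names(), "sacrum")]
  array(labels$voxels %in% ids, dim(labels$voxels))
}

# rigid alignment (rotation + translation) of mask `from` onto mask `to`,
# via centre-of-mass shift and principal-axes rotation; returned as a
# similarity transform (scale 1) mapping `to`-frame mm to `from`-frame mm
rigid_align <- function(from, to, spacing) {
  pf <- sweep(which(from, arr.ind = TRUE), 2, spacing, `*`)
  pt <- sweep(which(to, arr.ind = TRUE), 2, spacing, `*`)
  cf <- colMeans(pf); ctm <- colMeans(pt)
  ef <- eigen(stats::cov(pf))$vectors
  et <- eigen(stats::cov(pt))$vectors
  # align principal axes with consistent signs (axes are sign-ambiguous)
  for (a in 1:3) {
    if (sum(ef[, a] * et[, a]) < 0) ef[, a] <- -ef[, a]
  }
  R <- ef %*% t(et)
  if (det(R) < 0) { ef[, 3] <- -ef[, 3]; R <- ef %*% t(et) }
  ang <- euler_from_matrix(R)
  # q = R (p - c_to) + c_from
  similarity_transform(rotation_deg = ang,
                       translation_mm = as.numeric(cf - ctm), scale = 1,
                       center_mm = ctm)
}

#' Paired comparison of two segmentation methods
#'
#' Computes per-structure paired differences of a performance metric
#' between two methods, reporting the median difference, its inter-quartile
#' range, and a Wilcoxon signed-rank p-value (delegated to
#' [stats::wilcox.test()]). Unpaired structures are dropped with a warning.
#'
#' @param records_a,records_b data.frames with columns `structure` and
#'   `value` (e.g. from [test_retest()] filtered to one metric).
#' @return list (n, median_diff, iqr, p_value); differences are
#'   `a - b` per structure.
#' @export
compare_methods <- function(records_a, records_b) {
  m <- merge(records_a[, c("structure", "value")],
             records_b[, c("structure", "value")], by = "structure")
  dropped <- setdiff(union(records_a$structure, records_b$structure),
                     m$structure)
  if (length(dropped) > 0)
    warning("dropping unpaired structures: ", paste(dropped, collapse = ", "))
  d <- m$value.x - m$value.y
  p <- if (all(d == 0)) 1 else
    suppressWarnings(stats::wilcox.test(m$value.x, m$value.y,
                                        paired = TRUE)$p.value)
  list(n = length(d), median_diff = stats::median(d),
       iqr = stats::quantile(d, c(0.25, 0.75), names = FALSE),
       p_value = p)
}
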