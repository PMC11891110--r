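test_that("vertebra decomposition partitions the mask, symmetrically", {
  cord <- structure_mask(PH$labels, "spinal_cord")
  for (lv in c("C4", "T2", "T8", "L3")) {
    m <- structure_mask(PH$labels, paste0("vertebra_", lv))
    sp <- split_vertebra(m, cord, lv)
    expect_identical(sp$vb | sp$lpv | sp$rpv, m)
    expect_false(any(sp$vb & sp$lpv))
    expect_false(any(sp$vb & sp$rpv))
    expect_false(any(sp$lpv & sp$rpv))
    # mirror-symmetric phantom, cord centred: halves balance
    expect_equal(sum(sp$lpv), sum(sp$rpv))
  }
})

test_that("the anterior-point rule classifies strictly anterior voxels as VB", {
  # T8 uses the cord-centre rule: brute-force comparison per slice
  cord <- structure_mask(PH$labels, "spinal_cord")
  m <- structure_mask(PH$labels, "vertebra_T8")
  sp <- split_vertebra(m, cord, "T8")
  idx <- which(m, arr.ind = TRUE)
  cidx <- which(cord, arr.ind = TRUE)
  for (k in unique(idx[, 3])) {
    ref <- mean(cidx[cidx[, 3] == k, 2])
    sl <- idx[idx[, 3] == k, , drop = FALSE]
    manual_vb <- sl[sl[, 2] > ref, , drop = FALSE]
    expect_equal(sum(sp$vb[, , k]), nrow(manual_vb))
    expect_true(all(sp$vb[manual_vb]))
  }

  # rules genuinely differ: vertebra voxels lying between the cord centre
  # and the cord's anterior edge go to VB under the centre rule only
  d <- c(9, 9, 3)
  cordm <- mk_mask(d, expand.grid(4:5, 4:6, 1:3))  # cord y 4..6, centre 5
  vert <- mk_mask(d, expand.grid(7:8, 6:8, 1:3))   # vertebra spans y 6..8
  ant <- split_vertebra(vert, cordm, "C4")  # anterior-most rule: ref y = 6
  ctr <- split_vertebra(vert, cordm, "T8")  # centre rule: ref y = 5
  expect_lt(sum(ant$vb), sum(ctr$vb))
  expect_equal(sum(ctr$vb) - sum(ant$vb), 2 * 3)  # the y = 6 column
  # tie voxels (y equal to the reference) are posterior
  expect_false(any(ant$vb[, 6, ]))
})

test_that("slices without cord fall back to the nearest reference", {
  d <- c(9, 9, 4)
  cordm <- mk_mask(d, expand.grid(4:5, 4:6, 1:2))  # cord absent on slices 3,4
  vert <- mk_mask(d, expand.grid(6:7, 2:8, 1:4))
  expect_warning(sp <- split_vertebra(vert, cordm, "L1"), "nearest")
  expect_identical(sp$vb | sp$lpv | sp$rpv, vert)
})

test_that("disk segmentation is the dilation overlap minus bone", {
  d <- c(9, 9, 11)
  up <- mk_mask(d, expand.grid(3:7, 3:7, 7:9))
  lo <- mk_mask(d, expand.grid(3:7, 3:7, 3:5))   # one-voxel gap at k = 6
  bone <- up | lo
  ivd <- segment_ivd_morph(up, lo, "thoracic", bone)
  oracle <- mk_mask(d, expand.grid(3:7, 3:7, 6))
  expect_identical(unclass(ivd), unclass(oracle))

  # touching bodies: overlap is inside bone, disk empty
  lo2 <- mk_mask(d, expand.grid(3:7, 3:7, 3:6))
  ivd2 <- segment_ivd_morph(up, lo2, "thoracic", up | lo2)
  expect_false(any(ivd2))
  expect_equal(attr(ivd2, "qc"), "empty-ivd")

  # reach arithmetic on a wider gap: 3 empty slices between the bodies
  lo3 <- mk_mask(d, expand.grid(3:7, 3:7, 1:3))  # gap k = 4..6
  expect_false(any(segment_ivd_morph(up, lo3, "cervical", up | lo3)))
  expect_true(any(segment_ivd_morph(up, lo3, "lumbar", up | lo3)))
})

test_that("sacro-iliac segmentation finds the oblique gap and mirrors", {
  sac <- structure_mask(PH$labels, "sacrum")
  ill <- structure_mask(PH$labels, "ilium_left")
  ilr <- structure_mask(PH$labels, "ilium_right")
  bone <- array(PH$labels$voxels %in% PH$labels$taxonomy[
    c(vertebra_names(), "sacrum", "ilium_left", "ilium_right")],
    dim(PH$labels$voxels))
  sl <- segment_sij_morph(sac, ill, bone)
  sr <- segment_sij_morph(sac, ilr, bone)
  expect_true(any(sl) && any(sr))
  expect_false(any(sl & bone))
  expect_false(any(sr & bone))
  expect_identical(unclass(sl), unclass(mirror_mask(sr)))
  # the gap voxels themselves are recovered
  gap <- binary_dilate(sac, structuring_element("sphere", 4)) & ill
  expect_false(any(gap))  # one-voxel gap: no direct contact after one step

  # widening the gap by one voxel still converges, on a later iteration
  d <- c(11, 9, 9)
  a <- mk_mask(d, expand.grid(1:3, 1:9, 1:9))
  b <- mk_mask(d, expand.grid(7:9, 1:9, 1:9))   # 3-voxel gap
  s <- segment_sij_morph(a, b, a | b)
  expect_true(any(s))
  expect_true(all(which(s, arr.ind = TRUE)[, 1] %in% 4:6))
})

test_that("joint centres come from the overlap centre of mass", {
  d <- c(9, 9, 9)
  a <- mk_mask(d, c(3, 5, 5))
  b <- mk_mask(d, c(7, 5, 5))   # 4 voxels apart: converges on iteration 2
  ctr <- locate_joint_center_morph(a, b)
  expect_equal(ctr, c(5L, 5L, 5L))
  # symmetric configuration about a plane: centre lies on it
  a2 <- mk_mask(d, rbind(c(4, 3, 4), c(4, 7, 4)))
  b2 <- mk_mask(d, rbind(c(6, 3, 4), c(6, 7, 4)))
  expect_equal(locate_joint_center_morph(a2, b2)[1], 5L)
  expect_error(locate_joint_center_morph(mk_mask(d, NULL), b), "empty")
})

test_that("the full phantom yields the complete joint inventory", {
  j <- SEG_MORPH$joints
  expect_equal(sum(j$kind == "FJ"), 48)
  expect_equal(sum(j$kind == "CVJ"), 24)
  expect_equal(sum(j$kind == "CTJ"), 20)
  expect_false(any(duplicated(j[, c("kind", "level", "side")])))
  expect_true(all(j$i >= 1 & j$i <= dim(PH$labels$voxels)[1]))
  expect_true(all(j$level[j$kind == "CTJ"] %in% paste0("T", 1:10)))
})

test_that("disk and SIJ masks never intersect the input bone", {
  bone <- array(PH$labels$voxels %in% PH$labels$taxonomy[
    c(vertebra_names(), "sacrum", "ilium_left", "ilium_right",
      paste0("rib_left_", 1:12), paste0("rib_right_", 1:12),
      "femur_left", "femur_right")], dim(PH$labels$voxels))
  for (m in SEG_MORPH$ivd) expect_false(any(m & bone))
  for (m in SEG_MORPH$sij) expect_false(any(m & bone))
  expect_equal(length(SEG_MORPH$ivd), 24)
  expect_true(all(vapply(SEG_MORPH$ivd, any, logical(1))))
})
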