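test_that("spinal length is the C1-sacrum COM distance", {
  tax <- default_taxonomy()
  arr <- array(0L, c(25, 30, 5))
  arr[2, 2, 2] <- tax[["sacrum"]]
  arr[2 + 30 / 2, 2 + 40 / 2, 2] <- tax[["vertebra_C1"]]  # (30,40,0) mm offset
  lab <- label_volume(arr, c(2, 2, 2))
  expect_equal(spinal_length(lab), 50)

  arr2 <- array(0L, c(4, 4, 30))
  arr2[2, 2, 3] <- tax[["sacrum"]]
  arr2[2, 2, 28] <- tax[["vertebra_C1"]]
  expect_equal(spinal_length(label_volume(arr2, c(4, 4, 4))), 100)

  arr3 <- arr; arr3[arr3 == tax[["vertebra_C1"]]] <- 0L
  expect_error(spinal_length(label_volume(arr3, c(4, 4, 4))), "missing")

  # phantom: matches a brute-force COM computation
  com <- function(id) colMeans(which(PH$labels$voxels == id, arr.ind = TRUE))
  expected <- sqrt(sum(((com(tax[["vertebra_C1"]]) - com(tax[["sacrum"]])) * 4)^2))
  expect_equal(spinal_length(PH$labels), expected, tolerance = 1e-9)
})

test_that("atlas selection uses nearest-rank ceiling percentiles", {
  set.seed(2); l10 <- runif(10, 400, 600)
  sel <- select_atlases(l10, 50)
  expect_equal(attr(sel, "ranks"), 5L)           # ceil(0.5 * 10)
  expect_equal(sel, order(l10)[5], ignore_attr = TRUE)

  l45 <- runif(45, 400, 600)
  sel45 <- select_atlases(l45)
  expect_equal(attr(sel45, "ranks"), c(5L, 14L, 23L, 32L, 41L))
  expect_equal(sel45, order(l45)[c(5, 14, 23, 32, 41)], ignore_attr = TRUE)

  same <- rep(500, 8)
  s1 <- select_atlases(same); s2 <- select_atlases(same)
  expect_equal(length(unique(s1)), 5)            # distinct despite ties
  expect_identical(s1, s2)                       # deterministic

  expect_error(select_atlases(c(1, 2, 3)), "at least")
})

test_that("a complete scan yields 26 partial atlases covering their structures", {
  pa <- make_partial_atlases(PH$ct, PH$labels, SEG_MORPH)
  expect_equal(length(pa), 26)
  units <- vapply(pa, `[[`, "", "unit")
  expect_equal(sum(grepl("^S-il", units)), 2)    # 24 vertebra pairs + 2 SIJ boxes
  expect_equal(sum(!grepl("^S-il", units)), 24)
  # every voxel of both member structures lies inside the unit's box
  u <- pa[["T3-T4"]]
  for (s in c("vertebra_T3", "vertebra_T4")) {
    idx <- which(structure_mask(PH$labels, s), arr.ind = TRUE)
    expect_true(all(idx[, 1] >= u$box[1, 1] & idx[, 1] <= u$box[1, 2]))
    expect_true(all(idx[, 2] >= u$box[2, 1] & idx[, 2] <= u$box[2, 2]))
    expect_true(all(idx[, 3] >= u$box[3, 1] & idx[, 3] <= u$box[3, 2]))
  }
  # unit label crops carry upper VB / lower VB / disk codes
  expect_setequal(setdiff(unique(as.vector(u$labels)), 0L), 1:3)
  expect_true(all(c("FJ", "CVJ", "CTJ") %in% u$points$kind))
})

test_that("similarity registration recovers identity, translation and scale", {
  pa <- make_partial_atlases(PH$ct, PH$labels, SEG_MORPH)
  u <- pa[["T7-T8"]]
  fixed <- pad_volume(u$ct, 10L)

  self <- register_similarity(fixed, u$ct, seed = 1)
  expect_lt(sqrt(sum(self$translation_mm^2)), 1)
  expect_lt(abs(self$scale - 1), 0.02)

  # moving = the same unit cut from a phantom translated by 8 mm; the
  # recovered (pull) transform is the inverse, -8 mm
  tr8 <- similarity_transform(translation_mm = c(8, 0, 0))
  mov <- crop_image(apply_known_similarity(PH$ct, tr8), u$box)
  rec <- register_similarity(fixed, mov, seed = 1)
  expect_lt(sqrt(sum((rec$translation_mm - c(-8, 0, 0))^2)), 2)

  # global x1.1 scaling: the pull transform carries scale 1/1.1
  ctr <- (dim(PH$ct$voxels) - 1) / 2 * 4
  trs <- similarity_transform(scale = 1.1, center_mm = ctr)
  movs <- crop_image(apply_known_similarity(PH$ct, trs), u$box)
  recs <- register_similarity(fixed, movs, seed = 1)
  expect_lt(abs(recs$scale - 1 / 1.1), 0.03)

  expect_error(register_similarity(
    image_volume(array(1, c(4, 4, 4)), c(4, 4, 4)), u$ct), "constant")
})

test_that("label propagation shifts indices and never invents labels", {
  pa <- make_partial_atlases(PH$ct, PH$labels, SEG_MORPH)
  u <- pa[["L2-L3"]]
  target <- crop_image(PH$ct, u$box)
  ident <- propagate_labels(u, similarity_transform(), target)
  expect_identical(ident, u$labels)

  tr <- similarity_transform(translation_mm = c(4, 0, 0))  # +1 voxel lookup
  shifted <- propagate_labels(u, tr, target)
  d <- dim(u$labels)
  expect_identical(shifted[1:(d[1] - 1), , ], u$labels[2:d[1], , ])

  rnd <- similarity_transform(rotation_deg = c(3, -2, 7),
                              translation_mm = c(5, -4, 2), scale = 1.06,
                              center_mm = u$ct$origin)
  warped <- propagate_labels(u, rnd, target)
  expect_true(all(unique(as.vector(warped)) %in%
                    unique(as.vector(u$labels))))
})

test_that("majority voting follows the 3-of-5 rule and is idempotent", {
  base <- array(0L, c(3, 3, 3))
  m1 <- base; m1[1, 1, 1] <- 3L
  m2 <- m1; m3 <- m1
  m4 <- base; m4[1, 1, 1] <- 1L
  m5 <- base
  fused <- fuse_labels(list(m1, m2, m3, m4, m5))
  expect_equal(fused[1, 1, 1], 3L)     # 3 of 5 agree
  fused2 <- fuse_labels(list(m1, m2, m5, m4, m5))
  expect_equal(fused2[1, 1, 1], 0L)    # 2 of 5: background
  expect_identical(fuse_labels(rep(list(m1), 5)), m1)  # unanimity/idempotence
  expect_error(fuse_labels(list(m1, m2)), "exactly 5")

  set.seed(8)
  maps <- lapply(1:5, function(i) array(sample(0:3, 27, TRUE), c(3, 3, 3)))
  f <- fuse_labels(maps)
  expect_true(all(unique(as.vector(f)) %in% 0:3))
  for (v in which(f != 0)) {
    votes <- vapply(maps, function(m) m[v], integer(1))
    expect_gte(sum(votes == f[v]), 3)
  }
})

test_that("joint-centre fusion averages coordinates then snaps to voxel", {
  vol <- image_volume(array(0, c(10, 10, 10)), c(4, 4, 4))
  p <- matrix(rep(c(12, 16, 20), 5), ncol = 3, byrow = TRUE)
  expect_equal(fuse_joint_centers(p, vol), c(4L, 5L, 6L))
  # symmetric cloud about a point fuses to that point
  q <- rbind(c(0, 0, 0), c(8, 0, 0), c(0, 8, 0), c(8, 8, 0), c(4, 4, 0))
  expect_equal(fuse_joint_centers(q, vol), c(2L, 2L, 1L))
  # four at voxel 1 and one at voxel 6 (0,20 mm): mean 4 mm -> voxel 2
  r <- rbind(matrix(0, 4, 3), c(20, 0, 0))
  expect_equal(fuse_joint_centers(r, vol), c(2L, 1L, 1L))
  expect_error(fuse_joint_centers(rbind(matrix(0, 4, 3), c(NA, 0, 0)), vol),
               "finite")
})

test_that("self-atlas segmentation reproduces the reference labels", {
  # the target is itself one of the atlas scans: fused output must agree
  # with that scan's reference segmentation almost perfectly
  lib <- rep(list(make_partial_atlases(PH$ct, PH$labels, SEG_MORPH)), 5)
  seg <- run_atlas_method(PH$ct, PH$labels, lib, seed = 3,
                          units = c("T7-T8", "C3-C4", "S-ilL"))
  expect_gte(dice(seg$ivd[["T7-T8"]], SEG_MORPH$ivd[["T7-T8"]]), 0.95)
  expect_gte(dice(seg$ivd[["C3-C4"]], SEG_MORPH$ivd[["C3-C4"]]), 0.95)
  expect_gte(dice(seg$sij$left, SEG_MORPH$sij$left), 0.95)
  # fused joint centres land on the reference centres
  jm <- SEG_MORPH$joints
  for (r in seq_len(nrow(seg$joints))) {
    ref <- jm[jm$kind == seg$joints$kind[r] & jm$level == seg$joints$level[r] &
                jm$side == seg$joints$side[r], ]
    expect_lte(error_distance(seg$joints[r, ], ref), 4)
  }
})
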