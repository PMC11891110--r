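test_that("SUV metrics match direct arithmetic and a peak oracle", {
  d <- c(15, 15, 15)
  pet <- image_volume(array(5, d), c(4, 4, 4), modality = "PET-SUV")
  voi <- sphere_voi(c(8, 8, 8), d, 10)
  su <- extract_suv_metrics(pet, voi)
  expect_equal(unlist(su), c(suvmax = 5, suvpeak = 5, suvmean = 5))

  hot <- pet; hot$voxels[8, 8, 8] <- 10
  su2 <- extract_suv_metrics(hot, voi)
  expect_equal(su2$suvmax, 10)
  expect_equal(su2$suvmean, (10 + 80 * 5) / 81)

  # SUVpeak == brute-force neighbourhood-mean maximisation
  set.seed(17)
  for (rep in 1:20) {
    arr <- array(runif(8^3, 0, 10), c(8, 8, 8))
    p <- image_volume(arr, c(4, 4, 4), modality = "PET-SUV")
    m <- array(runif(8^3) < 0.3, c(8, 8, 8))
    if (!any(m)) m[1, 1, 1] <- TRUE
    got <- extract_suv_metrics(p, m)$suvpeak
    se <- structuring_element("sphere", 6)
    best <- -Inf
    for (v in seq_len(sum(m))) {
      ctr <- which(m, arr.ind = TRUE)[v, ]
      nb <- sweep(se$offsets, 2, ctr, `+`)
      ok <- apply(nb >= 1 & sweep(nb, 2, c(8, 8, 8), `<=`), 1, all)
      best <- max(best, mean(arr[nb[ok, , drop = FALSE]]))
    }
    expect_equal(got, best)
  }
  expect_error(extract_suv_metrics(pet, array(FALSE, d)), "empty")
})

test_that("background medians are region-matched and erosion-protected", {
  pp <- generate_phantom_pet(PH$labels, pet_phantom_spec(noise_sd = 0))
  bg <- background_medians(pp$pet, PH$labels)
  expect_equal(bg[["cervical"]], 4)
  expect_equal(bg[["thoracic"]], 5)
  expect_equal(bg[["lumbar"]], 6)
  expect_equal(bg[["liver"]], 5)
  expect_equal(bg[["aorta"]], 1.5)
  expect_equal(bg[["femur"]], 3)
  expect_true(bg[["spine"]] %in% 4:6)

  # a hot one-voxel cortical shell on the femur must not leak into the
  # background after the one-voxel erosion
  hot <- pp$pet
  fem <- structure_mask(PH$labels, "femur_left") |
    structure_mask(PH$labels, "femur_right")
  shell <- fem & !erode_one_voxel(fem)
  hot$voxels[shell] <- 50
  bg_hot <- background_medians(hot, PH$labels)
  expect_equal(bg_hot[["femur"]], 3)
  # without erosion the shell dominates
  expect_gt(stats::median(hot$voxels[fem]), 3)

  # single outlier voxel leaves a large-region median unchanged
  one <- pp$pet
  lum <- structure_mask(PH$labels, "vertebra_L2")
  iv <- which(lum, arr.ind = TRUE)[1, , drop = FALSE]
  one$voxels[iv] <- 500
  expect_equal(background_medians(one, PH$labels)[["lumbar"]], 6)
})

test_that("TBR is a guarded ratio", {
  expect_equal(tbr(10.8, 6), 1.8)
  expect_equal(tbr(6, 6), 1)
  expect_equal(tbr(2 * 10.8, 2 * 6), tbr(10.8, 6))
  expect_error(tbr(5, 0), "positive")
  expect_error(tbr(5, -1), "positive")
})

test_that("AUC equals the Mann-Whitney pair count on random score sets", {
  expect_equal(roc_auc(c(1, 2, 3, 11, 12), c(0, 0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(5, 8), rep(c(0, 1), 4))$auc, 0.5)
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")

  set.seed(31)
  for (rep in 1:200) {
    n1 <- sample(3:15, 1); n0 <- sample(3:15, 1)
    s <- round(c(rnorm(n0, 0, 1), rnorm(n1, 0.8, 1)), 1)  # rounding makes ties
    tr <- rep(c(FALSE, TRUE), c(n0, n1))
    u <- 0
    for (i in which(tr)) for (j in which(!tr))
      u <- u + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
    expect_equal(roc_auc(s, tr)$auc, u / (n1 * n0))
  }
})

test_that("the K-S threshold maximises TPR - FPR with the low-tie rule", {
  s <- c(1, 2, 3, 10, 11, 12); tr <- c(0, 0, 0, 1, 1, 1)
  expect_equal(ks_optimal_threshold(s, tr), 10)  # lowest positive score

  set.seed(13)
  for (rep in 1:100) {
    n <- sample(8:30, 1)
    s <- round(rnorm(n), 1)
    tr <- runif(n) < 0.5
    if (sum(tr) == 0 || sum(tr) == n) next
    got <- ks_optimal_threshold(s, tr)
    cand <- sort(unique(s))
    j <- sapply(cand, function(t) mean(s[tr] >= t) - mean(s[!tr] >= t))
    expect_equal(got, cand[which.max(j)])
    # rank property: a monotone transform moves the threshold with it
    expect_equal(ks_optimal_threshold(s^3, tr), got^3)
  }
})

test_that("DeLong comparison is symmetric and agrees with pROC", {
  set.seed(23)
  n <- 120
  tr <- runif(n) < 0.4
  a <- rnorm(n) + 1.2 * tr
  b <- 0.7 * a + rnorm(n, 0, 0.8)

  same <- delong_test(a, a, tr)
  expect_equal(same$auc_diff, 0)
  expect_equal(same$p_value, 1)

  res <- delong_test(a, b, tr)
  swap <- delong_test(b, a, tr)
  expect_equal(swap$auc_diff, -res$auc_diff)
  expect_equal(swap$p_value, res$p_value)

  ref <- pROC::roc.test(pROC::roc(tr, a, quiet = TRUE),
                        pROC::roc(tr, b, quiet = TRUE), method = "delong")
  expect_equal(res$p_value, as.numeric(ref$p.value), tolerance = 1e-8)
  expect_equal(abs(res$auc_diff),
               abs(as.numeric(ref$estimate[1]) - as.numeric(ref$estimate[2])),
               tolerance = 1e-12)
  expect_error(delong_test(a, b, rep(TRUE, n)), "both classes")
})

test_that("classification applies closed region-matched cut-offs", {
  pp <- generate_phantom_pet(PH$labels, pet_phantom_spec(noise_sd = 0))
  det <- classify_vois(pp$pet, VOIS_MORPH, PH$labels, rule = "tbr")
  expect_equal(nrow(det), 118)
  # background matching: every VOI uses the spine segment of its own level
  expect_true(all(det$background_region == det$region))
  expect_true(all(det$suvmean <= det$suvmax + 1e-12))
  expect_false(any(det$predicted))  # no lesions anywhere

  # boundary convention: TBR exactly at the cut-off is positive
  fj <- VOIS_MORPH[[which(MAN_MORPH$id == "FJ:L2-L3:left")]]
  idx <- which(fj$mask, arr.ind = TRUE)
  hot <- pp$pet
  hot$voxels[idx] <- 1.8 * 6.0   # lumbar SUVmedian is 6.0
  det2 <- classify_vois(hot, VOIS_MORPH, PH$labels, rule = "tbr")
  expect_true(det2$predicted[det2$id == "FJ:L2-L3:left"])
  expect_equal(det2$tbr[det2$id == "FJ:L2-L3:left"], 1.8)

  # raw-SUVmax rule with its own cut-offs
  det3 <- classify_vois(hot, VOIS_MORPH, PH$labels, rule = "suvmax")
  expect_true(det3$predicted[det3$id == "FJ:L2-L3:left"])  # 10.8 >= 10.4
  expect_false(any(det3$predicted[det3$kind == "DVU"]))    # < 13.0 everywhere
})

test_that("lesions planted only in costovertebral joints are found exactly", {
  cvj_ids <- c("CVJ:T3:left", "CVJ:T9:right")
  ctrs <- lapply(cvj_ids, function(id) {
    v <- VOIS_MORPH[[which(MAN_MORPH$id == id)]]
    as.numeric(SEG_MORPH$joints[SEG_MORPH$joints$kind == "CVJ" &
      paste("CVJ", SEG_MORPH$joints$level, SEG_MORPH$joints$side, sep = ":") == id,
      c("i", "j", "k")])
  })
  lesions <- lapply(ctrs, function(ctr) list(center = ctr, peak = 15,
                                             sigma_mm = 2.5))
  pp <- generate_phantom_pet(PH$labels, pet_phantom_spec(lesions = lesions,
                                                         noise_sd = 0))
  det <- classify_vois(pp$pet, VOIS_MORPH, PH$labels, rule = "tbr")
  expect_setequal(det$id[det$predicted], cvj_ids)
  truth <- voi_truth(VOIS_MORPH, pp$lesions)
  expect_setequal(names(truth)[truth], cvj_ids)
})

test_that("sensitivity and specificity follow the confusion counts", {
  expect_equal(sensitivity_specificity(c(TRUE, FALSE), c(TRUE, FALSE)),
               c(sensitivity = 100, specificity = 100))
  expect_equal(sensitivity_specificity(rep(TRUE, 4), c(TRUE, TRUE, FALSE, FALSE)),
               c(sensitivity = 100, specificity = 0))
  # constructed confusion table: TP 31, FN 5, TN 89, FP 11
  truth <- rep(c(TRUE, FALSE), c(36, 100))
  pred <- c(rep(TRUE, 31), rep(FALSE, 5), rep(FALSE, 89), rep(TRUE, 11))
  ss <- sensitivity_specificity(pred, truth)
  expect_equal(round(ss[["sensitivity"]], 1), 86.1)
  expect_equal(round(ss[["specificity"]], 1), 89.0)
  expect_true(is.na(sensitivity_specificity(c(TRUE, TRUE), c(TRUE, TRUE))[2]))
})
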