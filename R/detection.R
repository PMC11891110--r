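#' SUV metrics over a VOI
#'
#' SUVmax and SUVmean are the maximum and mean over the mask. SUVpeak is
#' the highest mean uptake in a ~1 mL spherical neighbourhood (radius 6 mm,
#' 19 voxels on the 4 mm grid) centred at any VOI voxel; neighbourhoods are
#' clipped at the grid boundary and draw values from the whole volume, the
#' usual peak convention.
#'
#' @param pet `axskel_image` in SUV units.
#' @param mask non-empty logical VOI mask on the same grid.
#' @param peak_radius_mm neighbourhood radius for SUVpeak.
#' @return list (suvmax, suvpeak, suvmean).
#' @export
extract_suv_metrics <- function(pet, mask, peak_radius_mm = 6) {
  if (!any(mask)) stop("extract_suv_metrics: empty VOI")
  stopifnot(identical(dim(pet$voxels), dim(mask)))
  vals <- pet$voxels[mask]
  se <- structuring_element("sphere", peak_radius_mm, pet$spacing)
  idx <- which(mask, arr.ind = TRUE)
  d <- dim(pet$voxels)
  peak <- -Inf
  for (r in seq_len(nrow(idx))) {
    nb <- sweep(se$offsets, 2, idx[r, ], `+`)
    keep <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    peak <- max(peak, mean(pet$voxels[nb[keep, , drop = FALSE]]))
  }
  list(suvmax = max(vals), suvpeak = peak, suvmean = mean(vals))
}

#' Region background SUVmedians
#'
#' Median SUV of the candidate background regions: cervical (C1-C7),
#' thoracic (T1-T12) and lumbar (L1-L5) spine, the whole spine, femur,
#' liver and aortic blood pool. Femur and aorta masks are eroded by one
#' voxel first, stripping cortical bone and the vascular wall and guarding
#' against PET/CT misalignment. Absent regions yield `NA` with a QC flag
#' in attribute `"qc"`.
#'
#' @param pet `axskel_image` in SUV units.
#' @param labels `axskel_labels` skeletal map on the same grid.
#' @return named numeric vector (cervical, thoracic, lumbar, spine, femur,
#'   liver, aorta).
#' @export
background_medians <- function(pet, labels) {
  tax <- labels$taxonomy
  region_ids <- list(
    cervical = tax[paste0("vertebra_C", 1:7)],
    thoracic = tax[paste0("vertebra_T", 1:12)],
    lumbar = tax[paste0("vertebra_L", 1:5)],
    spine = tax[vertebra_names()],
    femur = tax[c("femur_left", "femur_right")],
    liver = tax[["liver"]],
    aorta = tax[["aorta"]])
  qc <- character(0)
  out <- vapply(names(region_ids), function(r) {
    m <- array(labels$voxels %in% region_ids[[r]], dim(labels$voxels))
    if (r %in% c("femur", "aorta")) m <- erode_one_voxel(m)
    if (!any(m)) { qc <<- c(qc, paste0("missing-background:", r)); return(NA_real_) }
    stats::median(pet$voxels[m])
  }, numeric(1))
  attr(out, "qc") <- qc
  out
}

#' Target-to-background ratio
#'
#' @param metric SUV metric of the target VOI.
#' @param background matched background SUVmedian (strictly positive); for
#'   spine VOIs this is the spine segment of the VOI's own level.
#' @return unitless ratio.
#' @export
tbr <- function(metric, background) {
  if (any(!is.finite(background)) || any(background <= 0))
    stop("tbr: background must be positive")
  metric / background
}

#' ROC analysis of detection scores
#'
#' AUC by the rank (Mann-Whitney) formulation, which handles score ties
#' exactly and equals trapezoidal integration of the empirical ROC. The
#' result also carries the operating-point sweep (TPR/FPR at every
#' observed threshold, classification rule `score >= t`) and the
#' Kolmogorov-Smirnov optimal threshold.
#'
#' @param scores numeric scores (higher = more suspicious).
#' @param truth logical (or 0/1) reference labels; both classes must be
#'   present.
#' @return list (auc, thresholds, tpr, fpr, ks_threshold, confusion), the
#'   confusion counts taken at the K-S threshold.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) stop("roc_auc: need both classes")
  r <- rank(scores)
  auc <- (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  th <- sort(unique(scores))
  tpr <- vapply(th, function(t) mean(scores[truth] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(scores[!truth] >= t), numeric(1))
  ks <- ks_optimal_threshold(scores, truth)
  pred <- scores >= ks
  confusion <- c(tp = sum(pred & truth), fp = sum(pred & !truth),
                 tn = sum(!pred & !truth), fn = sum(!pred & truth))
  list(auc = auc, thresholds = th, tpr = tpr, fpr = fpr,
       ks_threshold = ks, confusion = confusion)
}

#' Kolmogorov-Smirnov optimal threshold
#'
#' The operating threshold maximising the separation of the positive and
#' negative empirical score distributions, i.e. the argmax of TPR - FPR
#' (Youden's J) over the observed scores with the closed rule
#' `score >= t`; ties are broken towards the lower threshold.
#'
#' @inheritParams roc_auc
#' @return threshold value.
#' @export
ks_optimal_threshold <- function(scores, truth) {
  truth <- as.logical(truth)
  if (sum(truth) == 0 || sum(!truth) == 0)
    stop("ks_optimal_threshold: need both classes")
  th <- sort(unique(scores))
  j <- vapply(th, function(t) mean(scores[truth] >= t) - mean(scores[!truth] >= t),
              numeric(1))
  th[which.max(j)]  # which.max returns the first (lowest) on ties
}

#' DeLong test for two correlated AUCs
#'
#' Fast DeLong estimate of the covariance of two AUCs computed from paired
#' scores on the same truth, with a two-sided p-value from the normal
#' approximation. Placement values use the midrank convention, so ties are
#' handled exactly.
#'
#' @param scores_a,scores_b paired score vectors.
#' @param truth shared reference labels, both classes present.
#' @return list (auc_a, auc_b, auc_diff, var_diff, z, p_value).
#' @export
delong_test <- function(scores_a, scores_b, truth) {
  truth <- as.logical(truth)
  m <- sum(truth); n <- sum(!truth)
  if (m == 0 || n == 0) stop("delong_test: need both classes")
  placements <- function(s) {
    x <- s[truth]; y <- s[!truth]
    # V10[i] = P(Y < x_i) + 0.5 P(Y = x_i); V01[j] likewise against X
    v10 <- vapply(x, function(xi) (sum(y < xi) + 0.5 * sum(y == xi)) / n,
                  numeric(1))
    v01 <- vapply(y, function(yj) (sum(x > yj) + 0.5 * sum(x == yj)) / m,
                  numeric(1))
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  pa <- placements(scores_a); pb <- placements(scores_b)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  S <- s10 / m + s01 / n
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  diff <- pa$auc - pb$auc
  if (var_diff <= .Machine$double.eps) {
    z <- if (abs(diff) < .Machine$double.eps^0.5) 0 else sign(diff) * Inf
  } else z <- diff / sqrt(var_diff)
  list(auc_a = pa$auc, auc_b = pb$auc, auc_diff = diff,
       var_diff = var_diff, z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Quantify and classify a VOI inventory on PET
#'
#' Extracts the SUV metrics of every VOI, matches each VOI to the spine
#' background of its own level (sacro-iliac VOIs use the lumbar segment,
#' the anatomically adjacent region), computes the TBR and applies the
#' detection rule: with `rule = "tbr"` the TBR of the chosen metric is
#' compared against 1.8 for joints/SIJs and 2.25 for DVUs; with
#' `rule = "suvmax"` the raw SUVmax against 10.4 and 13.0. Comparisons are
#' closed (`>= cutoff` is positive), so the cut-offs act as minimal
#' positive values. VOIs whose background is missing are skipped with a QC
#' flag.
#'
#' @param pet `axskel_image` in SUV units.
#' @param vois VOI inventory from [build_voi_inventory()].
#' @param labels skeletal label map for the background regions.
#' @param rule `"tbr"` or `"suvmax"`.
#' @param metric which SUV metric drives the rule (default `"suvmax"`, the
#'   most accurate detection metric).
#' @param cutoff_joint,cutoff_dvu decision thresholds; defaults depend on
#'   `rule`.
#' @return data.frame (voi id, kind, level, side, region, suvmax, suvpeak,
#'   suvmean, background_region, suvmedian_bg, tbr, threshold, predicted),
#'   QC flags in attribute `"qc"`.
#' @export
classify_vois <- function(pet, vois, labels, rule = c("tbr", "suvmax"),
                          metric = "suvmax",
                          cutoff_joint = NULL, cutoff_dvu = NULL) {
  rule <- match.arg(rule)
  defaults <- list(tbr = c(joint = 1.8, dvu = 2.25),
                   suvmax = c(joint = 10.4, dvu = 13.0))[[rule]]
  if (is.null(cutoff_joint)) cutoff_joint <- defaults[["joint"]]
  if (is.null(cutoff_dvu)) cutoff_dvu <- defaults[["dvu"]]
  bg <- background_medians(pet, labels)
  qc <- attr(bg, "qc")
  rows <- list()
  for (v in vois) {
    breg <- v$region  # cervical/thoracic/lumbar; SIJ mapped to lumbar upstream
    if (!is.finite(bg[[breg]])) {
      qc <- c(qc, paste0("skipped-no-background:", v$id)); next
    }
    su <- extract_suv_metrics(pet, v$mask)
    ratio <- tbr(su[[paste0("suv", sub("suv", "", metric))]], bg[[breg]])
    cutoff <- if (v$kind == "DVU") cutoff_dvu else cutoff_joint
    score <- if (rule == "tbr") ratio else su$suvmax
    rows[[length(rows) + 1]] <- data.frame(
      id = v$id, kind = v$kind, level = v$level, side = v$side,
      region = v$region, suvmax = su$suvmax, suvpeak = su$suvpeak,
      suvmean = su$suvmean, background_region = breg,
      suvmedian_bg = bg[[breg]], tbr = ratio, threshold = cutoff,
      predicted = score >= cutoff)
  }
  out <- do.call(rbind, rows)
  attr(out, "qc") <- qc
  out
}

#' Sensitivity and specificity of predictions
#'
#' @param predictions,truth logical vectors of equal length.
#' @return c(sensitivity, specificity) in percent; an empty truth class
#'   yields `NA` for its entry.
#' @export
sensitivity_specificity <- function(predictions, truth) {
  stopifnot(length(predictions) == length(truth))
  predictions <- as.logical(predictions); truth <- as.logical(truth)
  tp <- sum(predictions & truth); fn <- sum(!predictions & truth)
  tn <- sum(!predictions & !truth); fp <- sum(predictions & !truth)
  c(sensitivity = if (tp + fn == 0) NA_real_ else 100 * tp / (tp + fn),
    specificity = if (tn + fp == 0) NA_real_ else 100 * tn / (tn + fp))
}
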