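#' Pipeline configuration
#'
#' All defaults reproduce the reference settings of the two segmentation
#' routes and the detection layer: 4 mm isotropic working grid; vertical
#' disk elements of 12 / 8 / 4 mm (lumbar / thoracic / cervical); 4 mm
#' dilation sphere and 10 mm joint-VOI sphere; atlas selection at the
#' {10, 30, 50, 70, 90}th spinal-length percentiles; 100 registration
#' iterations; detection cut-offs 1.8 (joints/SIJs) and 2.25 (DVUs) on the
#' spine TBR, or 10.4 and 13.0 on raw SUVmax.
#'
#' @param working_spacing_mm working grid spacing.
#' @param element_mm named disk-element extents per region.
#' @param dilation_sphere_mm sphere radius for dilation-overlap steps.
#' @param voi_sphere_mm joint VOI radius.
#' @param atlas_percentiles spinal-length percentiles for atlas selection.
#' @param registration_iterations gradient iterations per registration.
#' @param detection_rule `"tbr"` or `"suvmax"`.
#' @param cutoff_joint,cutoff_dvu decision thresholds (NULL = rule default).
#' @param seed integer seed for all stochastic stages.
#' @return `axskel_config` list.
#' @export
pipeline_config <- function(working_spacing_mm = 4,
                            element_mm = c(cervical = 4, thoracic = 8,
                                           lumbar = 12),
                            dilation_sphere_mm = 4, voi_sphere_mm = 10,
                            atlas_percentiles = c(10, 30, 50, 70, 90),
                            registration_iterations = 100,
                            detection_rule = "tbr",
                            cutoff_joint = NULL, cutoff_dvu = NULL,
                            seed = 1L) {
  stopifnot(working_spacing_mm > 0, all(element_mm > 0), voi_sphere_mm > 0)
  structure(list(working_spacing_mm = working_spacing_mm,
                 element_mm = element_mm,
                 dilation_sphere_mm = dilation_sphere_mm,
                 voi_sphere_mm = voi_sphere_mm,
                 atlas_percentiles = atlas_percentiles,
                 registration_iterations = registration_iterations,
                 detection_rule = detection_rule,
                 cutoff_joint = cutoff_joint, cutoff_dvu = cutoff_dvu,
                 seed = as.integer(seed)),
            class = "axskel_config")
}

#' Run the end-to-end pipeline on one scan
#'
#' Segments the scan (morphological route by default, or multi-atlas when
#' an atlas library is supplied), builds the VOI inventory, and, when a PET
#' volume is given, quantifies and classifies every VOI. All artifacts are
#' written into `out_dir`: the VOI label NIfTI + manifest CSV, the joint
#' centre CSV, the detection CSV, a QC report and the resolved
#' configuration (JSON). Deterministic given the config seed; inputs are
#' never mutated.
#'
#' @param config an [pipeline_config()].
#' @param ct,labels `axskel_image` / `axskel_labels` on any grid (resampled
#'   to the working grid on load).
#' @param pet optional `axskel_image` in SUV units.
#' @param atlas_library optional atlas library (list of 5 partial-atlas
#'   sets); selects the atlas route.
#' @param out_dir output directory (created if needed); `NULL` skips file
#'   output.
#' @return list (seg, vois, manifest, detections, qc).
#' @export
run_pipeline <- function(config, ct, labels, pet = NULL,
                         atlas_library = NULL, out_dir = NULL) {
  sp <- rep(config$working_spacing_mm, 3)
  ct <- resample_to_grid(ct, sp)
  labels <- resample_to_grid(labels, sp)
  if (!is.null(pet)) pet <- resample_to_grid(pet, sp)

  seg <- if (is.null(atlas_library)) {
    run_morph_method(labels, sp)
  } else {
    run_atlas_method(ct, labels, atlas_library,
                     iterations = config$registration_iterations,
                     seed = config$seed)
  }
  vois <- build_voi_inventory(seg, config$voi_sphere_mm)
  manifest <- voi_manifest(vois)
  qc <- c(seg$qc, attr(vois, "qc"))

  detections <- NULL
  if (!is.null(pet)) {
    detections <- classify_vois(pet, vois, labels,
                                rule = config$detection_rule,
                                cutoff_joint = config$cutoff_joint,
                                cutoff_dvu = config$cutoff_dvu)
    qc <- c(qc, attr(detections, "qc"))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_voi_nifti(vois, sp, file.path(out_dir, "vois.nii.gz"))
    if (!is.null(seg$joints)) {
      j <- seg$joints
      mm <- voxel_to_mm(as.matrix(j[, c("i", "j", "k")]), labels)
      utils::write.csv(cbind(j, x_mm = mm[, 1], y_mm = mm[, 2], z_mm = mm[, 3]),
                       file.path(out_dir, "joint_centers.csv"),
                       row.names = FALSE)
    }
    if (!is.null(detections))
      utils::write.csv(detections, file.path(out_dir, "detections.csv"),
                       row.names = FALSE)
    writeLines(if (length(qc)) qc else "clean",
               file.path(out_dir, "qc_report.txt"))
    jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(seg = seg, vois = vois, manifest = manifest, detections = detections,
       qc = qc)
}

#' Build an atlas library from a set of scans
#'
#' Measures every scan's spinal length, selects the atlas scans at the
#' configured percentiles, builds each one's reference segmentation with
#' the morphological route and cuts it into 26 partial atlases.
#'
#' @param scans list of `list(ct=, labels=)` scans on the working grid.
#' @param config an [pipeline_config()].
#' @return list (library, selected, lengths).
#' @export
build_atlas_library <- function(scans, config = pipeline_config()) {
  lengths <- vapply(scans, function(s) spinal_length(s$labels), numeric(1))
  sel <- select_atlases(lengths, config$atlas_percentiles)
  library <- lapply(sel, function(i) {
    ref <- run_morph_method(scans[[i]]$labels)
    make_partial_atlases(scans[[i]]$ct, scans[[i]]$labels, ref)
  })
  list(library = library, selected = sel, lengths = lengths)
}
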