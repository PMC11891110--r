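# Shared fixtures, built once per test run.

PH <- generate_phantom_ldct(phantom_spec(seed = 42))
LAY <- attr(PH, "layout")
SEG_MORPH <- run_morph_method(PH$labels)
VOIS_MORPH <- build_voi_inventory(SEG_MORPH)
MAN_MORPH <- voi_manifest(VOIS_MORPH)

# small logical mask with foreground at the given (n x 3) index rows
mk_mask <- function(dims, idx) {
  m <- array(FALSE, dims)
  if (!is.null(idx)) {
    idx <- as.matrix(idx)
    if (ncol(idx) != 3) idx <- matrix(as.integer(idx), ncol = 3)
    storage.mode(idx) <- "integer"
    m[idx] <- TRUE
  }
  m
}

# mirror a mask about the phantom mid-sagittal plane
mirror_mask <- function(m) m[dim(m)[1]:1, , ]

phantom_mid_x <- function() (dim(PH$labels$voxels)[1] + 1) / 2
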