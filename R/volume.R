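# The 3D volume container used throughout the pipeline.
# Conventions: data is a numeric 3D array; the third array axis is the axial
# (slice) axis after canonical reorientation; indices are 0-based half-open
# ranges wherever slice bookkeeping is exposed.

#' Construct a volume
#'
#' A lightweight container for a 3D intensity (or label) image: the voxel
#' array, voxel spacing in mm, a 3x4 voxel-to-world affine, and a provenance
#' tag recording where the volume sits in the harmonization pipeline.
#'
#' @param data Numeric 3D array.
#' @param spacing Numeric length-3, mm per voxel along each axis (> 0).
#' @param origin Numeric length-3 world position of voxel (0,0,0), mm.
#' @param affine Optional 3x4 voxel-to-world matrix; defaults to
#'   `cbind(diag(spacing), origin)`.
#' @param provenance One of `"bl"`, `"fu"`, `"harmonized"`, `"reconstructed"`,
#'   `"mask"`, `"label"`.
#' @return An object of class `lh_volume`.
#' @export
new_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       affine = NULL,
                       provenance = c("bl", "fu", "harmonized",
                                      "reconstructed", "mask", "label")) {
  provenance <- match.arg(provenance)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_lh("volume data must be a 3D array")
  if (!all(is.finite(data))) stop_lh("volume data must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop_lh("spacing must be 3 positive values (mm)")
  if (is.null(affine)) affine <- cbind(diag(spacing), as.numeric(origin))
  structure(list(data = data, spacing = spacing,
                 affine = affine, provenance = provenance),
            class = "lh_volume")
}

#' @export
print.lh_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<lh_volume %dx%dx%d, spacing %s mm, provenance '%s', range [%.4g, %.4g]>\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = "x"),
              x$provenance, min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.lh_volume <- function(x) dim(x$data)

is_volume <- function(x) inherits(x, "lh_volume")

as_volume_like <- function(data, template, provenance = template$provenance) {
  new_volume(data, spacing = template$spacing, affine = template$affine,
             provenance = provenance)
}
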