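# Preprocessing chain: grid resampling, invertible min-max intensity
# normalization, axial slice extraction with percentage exclusion, slice
# pairing, and re-stacking of processed slices into the source volume.

#' Resample a volume onto an isotropic cubic grid
#'
#' Linearly interpolates the volume onto a `target_size`^3 grid at isotropic
#' `target_spacing`, with the physical field of view centred: the centre of
#' the input grid maps to the centre of the output grid. Label volumes should
#' use `method = "nearest"`.
#'
#' @param volume An [new_volume()] object.
#' @param target_size Voxels per axis of the output grid (default 256).
#' @param target_spacing Isotropic output spacing in mm (default 1).
#' @param method `"linear"` (intensities) or `"nearest"` (labels).
#' @return A resampled `lh_volume`.
#' @export
resample_to_grid <- function(volume, target_size = 256, target_spacing = 1,
                             method = c("linear", "nearest")) {
  method <- match.arg(method)
  if (!is_volume(volume)) stop_lh("resample_to_grid expects an lh_volume")
  if (!is.finite(target_spacing) || target_spacing <= 0)
    stop_lh("degenerate target spacing")
  d_in <- dim(volume$data)
  d_out <- rep(as.integer(target_size), 3L)
  # Map output voxel index v to input index: align physical centres, then
  # scale by the spacing ratio.
  scale <- target_spacing / volume$spacing
  t_off <- (d_in - 1) / 2 - scale * (d_out - 1) / 2
  out <- .resample_affine_cpp(volume$data, d_out, diag(scale), t_off,
                              nearest = (method == "nearest"), fill = 0,
                              clamp_edges = TRUE)
  new_volume(out, spacing = rep(target_spacing, 3),
             origin = volume$affine[, 4] %||% c(0, 0, 0),
             provenance = volume$provenance)
}

#' Min-max normalize a volume to [0, 1]
#'
#' Linearly maps the volume's intensity range onto `[0, 1]` and returns the
#' original range as an invertible record, mirroring the restore-on-inference
#' step of the harmonization pipeline.
#'
#' @param volume An `lh_volume`.
#' @return A list with `volume` (values in `[0,1]`, stored at 32-bit
#'   precision) and `record` (class `lh_intensity_record`, fields
#'   `original_min`, `original_max`).
#' @export
normalize_intensity <- function(volume) {
  if (!is_volume(volume)) stop_lh("normalize_intensity expects an lh_volume")
  lo <- min(volume$data); hi <- max(volume$data)
  if (hi <= lo) stop_lh("cannot normalize a constant volume (undefined scaling)")
  scaled <- (volume$data - lo) / (hi - lo)
  # Emulate float32 storage precision.
  scaled <- float32(scaled)
  rec <- structure(list(original_min = lo, original_max = hi),
                   class = "lh_intensity_record")
  list(volume = as_volume_like(scaled, volume), record = rec)
}

#' Invert min-max normalization
#'
#' @param volume01 Normalized `lh_volume` with values in `[0, 1]`.
#' @param record The `lh_intensity_record` produced by [normalize_intensity()].
#' @return An `lh_volume` on the original intensity scale.
#' @export
denormalize <- function(volume01, record) {
  if (!inherits(record, "lh_intensity_record")) stop_lh("invalid intensity record")
  if (record$original_max <= record$original_min) stop_lh("invalid intensity record range")
  out <- volume01$data * (record$original_max - record$original_min) +
    record$original_min
  as_volume_like(out, volume01)
}

float32 <- function(x) {
  y <- readBin(writeBin(as.numeric(x), raw(), size = 4L), "double",
               n = length(x), size = 4L)
  if (is.array(x)) array(y, dim = dim(x)) else y
}

#' Extract axial slices with symmetric exclusion
#'
#' Splits the volume into 2D axial slices (third array axis) and drops
#' `floor(exclude_fraction * N)` slices at each end, retaining the contiguous
#' middle. For the standard 256-slice grid at the default 10% exclusion this
#' retains 206 slices at 0-based indices `[25, 231)`.
#'
#' @param volume An `lh_volume`.
#' @param exclude_fraction Fraction excluded per end, in `[0, 0.5)`.
#' @return An `lh_slice_stack`: list of 2D matrices `slices`, retained
#'   0-based half-open range `lo`/`hi`, source dimensions and spacing.
#' @export
extract_axial_slices <- function(volume, exclude_fraction = 0.1) {
  if (!is_volume(volume)) stop_lh("extract_axial_slices expects an lh_volume")
  if (exclude_fraction < 0 || exclude_fraction >= 0.5)
    stop_lh("exclude_fraction must be in [0, 0.5)")
  n <- dim(volume$data)[3]
  drop_n <- floor(exclude_fraction * n)
  lo <- drop_n; hi <- n - drop_n          # 0-based half-open [lo, hi)
  if (hi <= lo) stop_lh("exclusion leaves no slices")
  slices <- lapply(seq.int(lo + 1L, hi), function(k) volume$data[, , k])
  structure(list(slices = slices, lo = lo, hi = hi,
                 source_dim = dim(volume$data), spacing = volume$spacing),
            class = "lh_slice_stack")
}

#' @export
length.lh_slice_stack <- function(x) length(x$slices)

#' Pair baseline and follow-up slice stacks
#'
#' @param bl_stack,fu_stack `lh_slice_stack`s from co-registered volumes with
#'   identical retained ranges.
#' @param subject_id Identifier carried on every pair.
#' @return List of `lh_slice_pair` objects (fields `bl_slice`, `fu_slice`,
#'   `subject_id`, `axial_index` 0-based).
#' @export
pair_slices <- function(bl_stack, fu_stack, subject_id = "subject") {
  if (!inherits(bl_stack, "lh_slice_stack") || !inherits(fu_stack, "lh_slice_stack"))
    stop_lh("pair_slices expects two lh_slice_stack objects")
  if (bl_stack$lo != fu_stack$lo || bl_stack$hi != fu_stack$hi)
    stop_lh("mismatched retained slice ranges: [%d,%d) vs [%d,%d)",
            bl_stack$lo, bl_stack$hi, fu_stack$lo, fu_stack$hi)
  lapply(seq_along(bl_stack$slices), function(i) {
    b <- bl_stack$slices[[i]]; f <- fu_stack$slices[[i]]
    if (!all(dim(b) == dim(f))) stop_lh("slice shape mismatch at index %d", i)
    structure(list(bl_slice = b, fu_slice = f, subject_id = subject_id,
                   axial_index = bl_stack$lo + i - 1L),
              class = "lh_slice_pair")
  })
}

#' Re-stack processed slices into a source volume
#'
#' Writes the (possibly transformed) slices of a stack back into their
#' retained index range of `source`; excluded slices pass through unchanged.
#'
#' @param stack An `lh_slice_stack` (slices may have been modified in place).
#' @param source The `lh_volume` the stack was extracted from.
#' @param provenance Provenance tag for the result.
#' @return An `lh_volume` with `source`'s grid and metadata.
#' @export
restack_slices <- function(stack, source, provenance = source$provenance) {
  if (!inherits(stack, "lh_slice_stack")) stop_lh("restack_slices expects an lh_slice_stack")
  if (!all(stack$source_dim == dim(source$data)))
    stop_lh("stack source dimensions do not match the supplied volume")
  out <- source$data
  for (i in seq_along(stack$slices)) out[, , stack$lo + i] <- stack$slices[[i]]
  as_volume_like(out, source, provenance = provenance)
}
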