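#' Derive background and thyroid reference ROIs
#'
#' The pre-processing chain needs two reference regions: a background ROI
#' whose mean is subtracted from the image, and a representative ROI of
#' normal gland tissue whose mean caps the image (so hotspots cannot be
#' segmented as a separate object). In the clinic these are drawn by an
#' operator with anatomical knowledge; here they are derived either
#' automatically from the image (`mode = "auto"`) or from the ground-truth
#' labels (`mode = "truth"`, the validation mode that emulates the
#' operator's anatomically informed placement).
#'
#' Automatic mode: the gland blob is the largest 6-connected component of
#' voxels above half the robust intensity maximum (the 100th-highest voxel),
#' eroded by one voxel for the thyroid ROI; the background ROI is the
#' body voxels (above 2 % of the robust maximum, excluding empty air),
#' eroded by `margin` voxels to stay clear of the edge roll-off, at
#' least `margin` voxels away from the gland blob -- a purely spatial
#' selection, so its mean is an unbiased background estimate. With no
#' measurable background activity the empty surround itself serves as
#' the background region.
#'
#' Truth mode: thyroid ROI = eroded `THYROID` voxels (hotspot excluded);
#' background ROI = [background_region()] of the phantom.
#'
#' @param recon a `recon_volume`
#' @param truth optional `label_phantom`, required for `mode = "truth"`
#' @param mode `"auto"` or `"truth"`
#' @param margin exclusion margin around the gland, in voxels
#' @return object of class `roi_pair`: logical arrays `background_roi`,
#'   `thyroid_roi`
#' @export
derive_rois <- function(recon, truth = NULL,
                        mode = c("auto", "truth"), margin = 3L) {
  mode <- match.arg(mode)
  v <- recon$values
  stopifnot(all(is.finite(v)))
  if (mode == "truth") {
    if (is.null(truth)) stop("truth mode requires a label phantom")
    thy <- erode3d(truth$labels == LABELS[["THYROID"]], 1L)
    if (!any(thy)) stop("thyroid ROI empty after erosion")
    bg <- background_region(truth, margin)
    if (!any(bg)) stop("background ROI empty")
    return(structure(list(background_roi = bg, thyroid_roi = thy),
                     class = "roi_pair"))
  }
  # robust gland peak: the 100th-highest voxel is well inside any gland
  # at benchmark scale (>= 230 voxels) yet immune to isolated noise spikes
  rmax <- sort(v, decreasing = TRUE)[min(100L, length(v))]
  if (rmax <= min(v)) stop("uniform image: no separable gland")
  blob <- largest_component3d(v >= 0.5 * rmax)
  thy <- erode3d(blob, 1L)
  if (!any(thy)) stop("thyroid ROI empty after erosion")
  body <- v > 0.02 * rmax
  bg <- erode3d(body, margin) & !dilate3d(blob, margin)
  # zero-background images have no body outside the gland: the (empty)
  # surround is then the background reference
  if (!any(bg)) bg <- !dilate3d(blob, margin)
  if (!any(bg)) stop("background ROI empty")
  structure(list(background_roi = bg, thyroid_roi = thy), class = "roi_pair")
}

#' Pre-process a reconstruction for segmentation
#'
#' Applies, in order: (1) subtraction of the background-ROI mean from every
#' voxel, clamping negatives to zero (equates background tissue to the
#' non-radioactive surround); (2) capping at the thyroid-ROI mean computed
#' after step 1 (prevents hotspots from being segmented as separate
#' objects); (3) linear quantization of [0, cap] to the integers 0..255,
#' rounding half-up, with the cap mapping to 255 exactly.
#'
#' @param recon a `recon_volume`
#' @param rois a `roi_pair` from [derive_rois()]
#' @return object of class `quantized_volume`: integer `values` in
#'   [0, 255], `voxel_mm`, and the audit fields `offset` (subtracted
#'   background mean) and `gain` (grey levels per intensity unit)
#' @export
preprocess_volume <- function(recon, rois) {
  stopifnot(inherits(rois, "roi_pair"),
            all(dim(recon$values) == dim(rois$background_roi)))
  offset <- mean(recon$values[rois$background_roi])
  shifted <- pmax(recon$values - offset, 0)
  cap <- mean(shifted[rois$thyroid_roi])
  if (cap <= 0) stop("background exceeds gland signal; cannot quantize")
  q <- floor(255 * pmin(shifted, cap) / cap + 0.5)
  structure(list(values = array(as.integer(q), dim(q)),
                 voxel_mm = recon$voxel_mm,
                 offset = offset, gain = 255 / cap),
            class = "quantized_volume")
}

#' @exportS3Method base::print
print.quantized_volume <- function(x, ...) {
  cat(sprintf("8-bit volume: %s grid, %.2f mm voxels, offset %.4g, gain %.4g\n",
              paste(dim(x$values), collapse = "x"), x$voxel_mm,
              x$offset, x$gain))
  invisible(x)
}
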