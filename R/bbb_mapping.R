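#' Delta-qT1 subtraction map
#'
#' Voxelwise qT1 difference map used as a blood-brain barrier dysfunction
#' biomarker. Two kinds exist, matching the session arithmetic:
#' `"ni"` = noncontrast minus interictal (interictal BBBD) and
#' `"ip"` = interictal minus postictal (peri-ictal BBBD). Units are ms before
#' normalization and dimensionless (fraction of the vascular reference
#' enhancement) after division by the superior-sagittal-sinus mean.
#'
#' @param data 3-D numeric array of differences.
#' @param kind `"ni"` or `"ip"`.
#' @param mask logical validity array (intersection of the input masks).
#' @param affine 4x4 voxel-to-world transform.
#' @param sss_mean SSS reference mean (ms) once normalized, otherwise `NA`.
#' @param normalized has the map been divided by `sss_mean`?
#' @return an object of class `delta_qt1_map`.
#' @export
delta_qt1_map <- function(data, kind = c("ni", "ip"), mask, affine = diag(4),
                          sss_mean = NA_real_, normalized = FALSE) {
  kind <- match.arg(kind)
  if (!identical(dim(data), dim(mask))) stop("mask and data must share shape")
  structure(list(data = data, kind = kind, mask = mask,
                 affine = as_affine(affine), sss_mean = sss_mean,
                 normalized = normalized),
            class = "delta_qt1_map")
}

#' @export
print.delta_qt1_map <- function(x, ...) {
  cat(sprintf("<delta_qt1_map> kind %s, %s, %d valid voxels%s\n",
              x$kind, if (x$normalized) "SSS-normalized" else "raw (ms)",
              sum(x$mask),
              if (x$normalized) sprintf(", sss_mean = %.3f ms", x$sss_mean) else ""))
  invisible(x)
}

delta_sessions <- list(ni = c("noncontrast", "interictal"),
                       ip = c("interictal", "postictal"))

#' Compute a qT1 subtraction map
#'
#' `kind = "ni"` subtracts the interictal from the noncontrast volume
#' (interictal gadolinium accumulation lowers interictal T1, so leakage shows
#' up positive); `kind = "ip"` subtracts the postictal from the interictal
#' volume. The inputs must already be co-registered on one grid; session
#' labels are checked against the requested kind.
#'
#' @param first,second [qt1_volume()] objects on the same grid, with session
#'   labels matching `kind` (ni: noncontrast, interictal; ip: interictal,
#'   postictal).
#' @param kind `"ni"` or `"ip"`.
#' @return a raw (ms) [delta_qt1_map()]; valid mask is the AND of the inputs.
#' @export
compute_delta <- function(first, second, kind = c("ni", "ip")) {
  kind <- match.arg(kind)
  stopifnot(inherits(first, "qt1_volume"), inherits(second, "qt1_volume"))
  if (!identical(dim(first$t1), dim(second$t1)))
    stop("volumes must share one grid (shape mismatch)")
  if (max(abs(first$affine - second$affine)) > 1e-6)
    stop("volumes must share one grid (affine mismatch)")
  want <- delta_sessions[[kind]]
  if (!identical(c(first$session, second$session), want))
    stop(sprintf("kind '%s' requires sessions %s - %s, got %s - %s",
                 kind, want[1], want[2], first$session, second$session))
  mask <- first$mask & second$mask
  data <- first$t1 - second$t1
  data[!mask] <- NA_real_
  delta_qt1_map(data, kind = kind, mask = mask, affine = first$affine)
}

#' Normalize a subtraction map by the superior sagittal sinus
#'
#' Divides every valid voxel by the mean of the map over the SSS label,
#' recording the reference value. The normalized map is a dimensionless
#' fraction of the vascular enhancement, which removes the effect of
#' between-subject differences in central gadolinium concentration
#' (injection-to-scan latency, pharmacokinetics). By construction the
#' normalized SSS mean equals 1.
#'
#' @param map a raw [delta_qt1_map()].
#' @param labels an [roi_label_map()] containing a non-empty `sss` label.
#' @param floor smallest acceptable |SSS mean| as a fraction of the map's
#'   dynamic range (default 1e-6); below it normalization is refused, since
#'   it would signal no measurable vascular contrast.
#' @return the normalized [delta_qt1_map()].
#' @export
normalize_by_sss <- function(map, labels, floor = 1e-6) {
  stopifnot(inherits(map, "delta_qt1_map"), inherits(labels, "roi_label_map"))
  if (map$normalized) stop("map is already normalized")
  sel <- roi_mask(labels, "sss") & map$mask
  if (!any(sel)) stop("SSS label is empty within the valid mask")
  sss_mean <- mean(map$data[sel])
  rng <- diff(range(map$data[map$mask]))
  if (!is.finite(sss_mean) || abs(sss_mean) <= floor * max(rng, 1))
    stop(sprintf("SSS reference mean (%.3g) is below the normalization floor: no measurable vascular contrast", sss_mean))
  data <- map$data / sss_mean
  delta_qt1_map(data, kind = map$kind, mask = map$mask, affine = map$affine,
                sss_mean = sss_mean, normalized = TRUE)
}

#' Region-of-interest readout of a subtraction map
#'
#' Mean and sample (n-1) standard deviation of the map over each requested
#' region, using valid voxels only. The whole-cortex readout excludes voxels
#' belonging to hippocampus and amygdala (they carry their own labels and
#' are analyzed separately). A region left empty after masking yields an
#' explicit missing value with a warning, never a silent zero.
#'
#' @param map a [delta_qt1_map()].
#' @param labels an [roi_label_map()].
#' @param rois region names to read out; default: whole cortex, bilateral
#'   hippocampus/amygdala/piriform and the SSS.
#' @param hemisphere `"both"` (default), `"left"` or `"right"`: restricts
#'   bilateral regions to one side (the cortex and SSS labels are not
#'   lateralized and are always included).
#' @param subject optional subject id to stamp on the rows.
#' @return data.frame with columns `subject`, `roi`, `hemisphere`, `kind`,
#'   `normalized`, `mean`, `sd`, `n_voxels`.
#' @export
roi_readout <- function(map, labels, rois = c("cortex", parenchymal_rois(), "sss"),
                        hemisphere = c("both", "left", "right"),
                        subject = NA_character_) {
  hemisphere <- match.arg(hemisphere)
  stopifnot(inherits(map, "delta_qt1_map"), inherits(labels, "roi_label_map"))
  missing_rois <- setdiff(rois, names(labels$dict))
  if (length(missing_rois))
    stop("requested ROIs absent from label map: ",
         paste(missing_rois, collapse = ", "))
  if (hemisphere != "both") {
    suffix <- if (hemisphere == "left") "_l" else "_r"
    lateral <- grepl("_(l|r)$", rois)
    rois <- rois[!lateral | endsWith(rois, suffix)]
  }
  rows <- lapply(rois, function(nm) {
    sel <- roi_mask(labels, nm) & map$mask
    hemi <- if (endsWith(nm, "_l")) "left" else if (endsWith(nm, "_r")) "right" else "both"
    if (!any(sel)) {
      warning("ROI '", nm, "' has no valid voxels; recording missing value")
      return(data.frame(subject = subject, roi = nm, hemisphere = hemi,
                        kind = map$kind, normalized = map$normalized,
                        mean = NA_real_, sd = NA_real_, n_voxels = 0L))
    }
    v <- map$data[sel]
    data.frame(subject = subject, roi = nm, hemisphere = hemi,
               kind = map$kind, normalized = map$normalized,
               mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               n_voxels = length(v))
  })
  do.call(rbind, rows)
}
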