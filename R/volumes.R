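#' Quantitative T1 volume
#'
#' Container for a voxelwise map of longitudinal relaxation times (ms) with an
#' invalid-voxel mask, spatial metadata and a session label. Voxels outside a
#' plausibility window, or flagged by upstream processing (failed fits,
#' out-of-field resampling), are masked and never interpolated, so that they
#' cannot silently bias region-of-interest means.
#'
#' @param t1 3-D numeric array of T1 values in milliseconds.
#' @param affine 4x4 voxel-to-world transform (NIfTI convention, 0-based voxel
#'   indices).
#' @param session one of `"noncontrast"`, `"interictal"`, `"postictal"`.
#' @param mask logical array of the same shape; `TRUE` marks valid voxels.
#'   Defaults to all finite, positive voxels.
#' @return an object of class `qt1_volume` with elements `t1`, `mask`,
#'   `affine`, `session`.
#' @export
qt1_volume <- function(t1, affine = diag(4),
                       session = c("noncontrast", "interictal", "postictal"),
                       mask = NULL) {
  session <- match.arg(session)
  if (length(dim(t1)) != 3L) stop("t1 must be a 3-D array")
  affine <- as_affine(affine)
  if (is.null(mask)) mask <- is.finite(t1) & t1 > 0
  if (!identical(dim(mask), dim(t1))) stop("mask and t1 map must share shape")
  structure(list(t1 = t1, mask = mask, affine = affine, session = session),
            class = "qt1_volume")
}

#' @export
print.qt1_volume <- function(x, ...) {
  cat(sprintf("<qt1_volume> %s session, %s voxels (%d valid)\n",
              x$session, paste(dim(x$t1), collapse = "x"), sum(x$mask)))
  v <- x$t1[x$mask]
  if (length(v))
    cat(sprintf("  T1 range %.1f-%.1f ms, median %.1f ms\n",
                min(v), max(v), stats::median(v)))
  invisible(x)
}

#' @export
dim.qt1_volume <- function(x) dim(x$t1)

#' Variable flip angle series
#'
#' A stack of spoiled gradient-echo magnitude volumes, one per flip angle,
#' sharing one repetition time and grid.
#'
#' @param volumes list of 3-D non-negative arrays, identical shapes, one per
#'   flip angle.
#' @param params an [acquisition_params()] object.
#' @param affine 4x4 voxel-to-world transform.
#' @return an object of class `vfa_series`.
#' @export
vfa_series <- function(volumes, params, affine = diag(4)) {
  stopifnot(inherits(params, "acquisition_params"))
  if (length(volumes) != length(params$flip_angles))
    stop("number of volumes must equal number of flip angles")
  shapes <- lapply(volumes, dim)
  if (!all(vapply(shapes, identical, logical(1), shapes[[1]])))
    stop("all volumes in a VFA series must share one shape")
  structure(list(volumes = volumes, params = params, affine = as_affine(affine)),
            class = "vfa_series")
}

#' ROI label map
#'
#' Integer-labeled volume identifying the analysis regions: whole cortex,
#' hippocampus, amygdala and piriform cortex per hemisphere, the superior
#' sagittal sinus (SSS) used as vascular reference, plus supporting tissue
#' labels. Labels are disjoint by construction (one integer per voxel).
#'
#' @param labels 3-D integer array; 0 is background.
#' @param dict named integer vector mapping region names to label values.
#' @param affine 4x4 voxel-to-world transform.
#' @return an object of class `roi_label_map`.
#' @export
roi_label_map <- function(labels, dict, affine = diag(4)) {
  if (length(dim(labels)) != 3L) stop("labels must be a 3-D array")
  if (is.null(names(dict)) || anyDuplicated(names(dict)) ||
      anyDuplicated(dict)) stop("dict must be uniquely named, unique values")
  structure(list(labels = labels, dict = dict, affine = as_affine(affine)),
            class = "roi_label_map")
}

#' @export
print.roi_label_map <- function(x, ...) {
  cat(sprintf("<roi_label_map> %s voxels\n", paste(dim(x$labels), collapse = "x")))
  counts <- vapply(x$dict, function(v) sum(x$labels == v), integer(1))
  for (nm in names(x$dict))
    cat(sprintf("  %-16s label %2d  %6d voxels\n", nm, x$dict[[nm]], counts[[nm]]))
  invisible(x)
}

#' Logical mask for one named region
#'
#' @param labels an [roi_label_map()].
#' @param roi region name present in the label dictionary.
#' @return logical array.
#' @export
roi_mask <- function(labels, roi) {
  if (!roi %in% names(labels$dict)) stop("unknown ROI: ", roi)
  labels$labels == labels$dict[[roi]]
}

as_affine <- function(a) {
  a <- as.matrix(a)
  if (!identical(dim(a), c(4L, 4L)) || !all(is.finite(a)))
    stop("affine must be a finite 4x4 matrix")
  storage.mode(a) <- "double"
  a
}

#' Write a qT1 volume to NIfTI-1
#'
#' The T1 map is written as the image; the validity mask and session label go
#' to a companion mask file and a YAML sidecar next to `path`.
#'
#' @param vol a [qt1_volume()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_qt1 <- function(vol, path) {
  img <- vol$t1
  img[!vol$mask] <- 0
  nii <- RNifti::asNifti(img)
  RNifti::sform(nii) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(nii, path)
  msk <- RNifti::asNifti(array(as.numeric(vol$mask), dim(vol$mask)))
  RNifti::sform(msk) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(msk, mask_path(path))
  yaml::write_yaml(list(session = vol$session), sidecar_path(path))
  invisible(path)
}

#' Read a qT1 volume written by [write_qt1()]
#'
#' @param path path to the `.nii`/`.nii.gz` T1 map.
#' @return a [qt1_volume()].
#' @export
read_qt1 <- function(path) {
  nii <- RNifti::readNifti(path)
  affine <- unclass(RNifti::xform(nii))
  t1 <- array(as.numeric(nii), dim(nii))
  mask <- NULL
  if (file.exists(mask_path(path))) {
    m <- RNifti::readNifti(mask_path(path))
    mask <- array(as.numeric(m) > 0.5, dim(m))
  }
  session <- "noncontrast"
  if (file.exists(sidecar_path(path))) {
    side <- yaml::read_yaml(sidecar_path(path))
    if (!is.null(side$session)) session <- side$session
  }
  qt1_volume(t1, affine = affine, session = session, mask = mask)
}

#' Write / read an ROI label map as NIfTI plus YAML label dictionary
#'
#' @param labels an [roi_label_map()].
#' @param path output NIfTI path.
#' @return `path` invisibly; `read_labels()` returns an [roi_label_map()].
#' @export
write_labels <- function(labels, path) {
  nii <- RNifti::asNifti(labels$labels)
  RNifti::sform(nii) <- structure(labels$affine, code = 2L)
  RNifti::writeNifti(nii, path, datatype = "int16")
  dict <- as.list(labels$dict)
  yaml::write_yaml(dict, sidecar_path(path))
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  nii <- RNifti::readNifti(path)
  dict <- unlist(yaml::read_yaml(sidecar_path(path)))
  roi_label_map(array(as.integer(nii), dim(nii)), dict = dict,
                affine = unclass(RNifti::xform(nii)))
}

mask_path <- function(path) sub("\\.nii(\\.gz)?$", "_mask.nii\\1", path)
sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".yaml", path)
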