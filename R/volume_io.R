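#' Default label map for inner-ear substructures
#'
#' Integer labels for the five bony-labyrinth substructures segmented
#' from temporal-bone CT: cochlea, vestibule and the posterior, lateral
#' and superior semicircular canals.
#'
#' @return named integer vector.
#' @export
default_label_map <- function() {
  c(cochlea = 1L, vestibule = 2L, PSC = 3L, LSC = 4L, SSC = 5L)
}

#' Construct a labeled voxel volume
#'
#' @param voxels 3-D integer array of labels (0 = background).
#' @param spacing_mm voxel spacing, length 1 (isotropic) or 3, in mm.
#' @param origin_mm world coordinate of the corner of voxel
#'   `[1, 1, 1]`; the voxel's center is at `origin_mm + spacing_mm / 2`.
#' @param label_map named integer vector mapping structure names to
#'   labels.
#' @return object of class `label_volume`.
#' @export
label_volume <- function(voxels, spacing_mm = 0.1, origin_mm = c(0, 0, 0),
                         label_map = default_label_map()) {
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3-D array")
  if (any(voxels != round(voxels))) stop("voxel data must be integer labels")
  storage.mode(voxels) <- "integer"
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  if (any(spacing_mm <= 0)) stop("spacing must be strictly positive")
  present <- setdiff(unique(as.integer(voxels)), 0L)
  stray <- setdiff(present, as.integer(label_map))
  if (length(stray))
    stop("volume contains labels not in the label map: ",
         paste(stray, collapse = ", "))
  structure(
    list(voxels = voxels, spacing_mm = spacing_mm,
         origin_mm = as.numeric(origin_mm), label_map = label_map),
    class = "label_volume"
  )
}

#' Write a label volume to NIfTI
#'
#' Writes the label array as integer NIfTI (`.nii` / `.nii.gz`) with the
#' voxel spacing in the header and the origin in the sform, plus a JSON
#' sidecar (`<path>.labels.json`) holding the label map. NIfTI voxel
#' coordinates address voxel centers, so the sform translation is
#' `origin_mm + spacing_mm / 2`.
#'
#' @param vol a `label_volume`.
#' @param path output file path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  img <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(img) <- vol$spacing_mm
  aff <- diag(4)
  diag(aff)[1:3] <- vol$spacing_mm
  aff[1:3, 4] <- vol$origin_mm + vol$spacing_mm / 2
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = "int16")
  jsonlite::write_json(as.list(vol$label_map), sidecar_path(path),
                       auto_unbox = TRUE)
  invisible(path)
}

sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".labels.json")
}

#' Read a label volume from NIfTI
#'
#' Spacing is taken from the header (anisotropic spacing is accepted
#' with a warning); the origin from the sform/qform when present. The
#' label map is read from the JSON sidecar written by
#' [write_label_volume()] unless supplied explicitly. Non-integer data
#' or labels absent from the map raise errors.
#'
#' @param path NIfTI file path.
#' @param label_map named integer vector; default: sidecar if present,
#'   else [default_label_map()].
#' @return a `label_volume`.
#' @export
read_label_volume <- function(path, label_map = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected a 3-D volume: ", path)
  vals <- as.numeric(img)
  if (any(vals != round(vals)))
    stop("volume does not contain integer label data: ", path)
  arr <- array(as.integer(round(vals)), dim = dim(img))
  spacing <- abs(RNifti::pixdim(img))[1:3]
  if (max(spacing) - min(spacing) > 1e-6 * max(spacing))
    warning("anisotropic voxel spacing: ",
            paste(format(spacing), collapse = " x "), " mm")
  xf <- tryCatch(RNifti::xform(img), error = function(e) NULL)
  origin <- if (!is.null(xf)) as.numeric(xf[1:3, 4]) - spacing / 2 else c(0, 0, 0)
  if (is.null(label_map)) {
    sc <- sidecar_path(path)
    label_map <- if (file.exists(sc)) {
      lm <- jsonlite::read_json(sc)
      stats::setNames(as.integer(unlist(lm)), names(lm))
    } else default_label_map()
  }
  label_volume(arr, spacing_mm = spacing, origin_mm = origin,
               label_map = label_map)
}

#' Extract the voxel-center coordinates of one structure
#'
#' Returns the world coordinates (mm) of the centers of all voxels
#' carrying the structure's label. The center convention is fixed
#' package-wide: a voxel with 0-based index `(i, j, k)` has its center at
#' `origin + (index + 1/2) * spacing` per axis.
#'
#' @param vol a `label_volume`.
#' @param structure structure name, one of `names(vol$label_map)`.
#' @return object of class `voxel_cloud`: list with `points_mm` (N x 3),
#'   `source_label` and `spacing_mm`.
#' @export
extract_voxel_cloud <- function(vol, structure) {
  stopifnot(inherits(vol, "label_volume"))
  if (!structure %in% names(vol$label_map))
    stop("unknown structure: ", structure)
  lab <- vol$label_map[[structure]]
  idx <- which(vol$voxels == lab, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop("structure '", structure, "' has no voxels in this volume")
  pts <- sweep(sweep(idx - 0.5, 2L, vol$spacing_mm, `*`),
               2L, vol$origin_mm, `+`)
  colnames(pts) <- c("x", "y", "z")
  voxel_cloud(pts, structure, vol$spacing_mm)
}

#' @rdname extract_voxel_cloud
#' @param points_mm N x 3 matrix of voxel-center coordinates in mm.
#' @param source_label structure name the points came from.
#' @param spacing_mm voxel spacing (length 1 or 3).
#' @export
voxel_cloud <- function(points_mm, source_label = "unknown",
                        spacing_mm = 0.1) {
  pts <- as_points3(points_mm)
  if (nrow(pts) < 1L) stop("a voxel cloud needs at least one point")
  structure(
    list(points_mm = pts, source_label = source_label,
         spacing_mm = rep_len(as.numeric(spacing_mm), 3L)),
    class = "voxel_cloud"
  )
}

#' Voxel-count volume of a structure
#'
#' Volume in cubic millimetres computed as the number of voxels times
#' the volume of one voxel, `prod(spacing_mm)`. The conversion constant
#' is always derived from the spacing: at 0.1 mm isotropic spacing one
#' voxel is 0.001 mm^3.
#'
#' @param cloud a `voxel_cloud`.
#' @return volume in mm^3.
#' @export
voxel_volume <- function(cloud) {
  stopifnot(inherits(cloud, "voxel_cloud"))
  nrow(cloud$points_mm) * prod(cloud$spacing_mm)
}

#' @export
print.label_volume <- function(x, ...) {
  cat("label_volume:", paste(dim(x$voxels), collapse = " x "),
      "voxels @", paste(format(x$spacing_mm), collapse = " x "), "mm\n")
  tab <- table(x$voxels[x$voxels != 0L])
  nm <- names(x$label_map)[match(as.integer(names(tab)), x$label_map)]
  for (i in seq_along(tab))
    cat(sprintf("  %-10s label %s: %d voxels\n", nm[i], names(tab)[i], tab[i]))
  invisible(x)
}

#' @export
print.voxel_cloud <- function(x, ...) {
  cat("voxel_cloud:", nrow(x$points_mm), "points from", x$source_label,
      "@", paste(format(x$spacing_mm), collapse = " x "), "mm\n")
  invisible(x)
}
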