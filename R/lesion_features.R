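#' Lesion-load feature extraction
#'
#' Converts a continuous or binary lesion image in standard (MNI) space,
#' plus an integer atlas parcellation on the same voxel grid, into the
#' region lesion-load predictors (proportion of each atlas region's voxels
#' overlapped by the binary lesion) and the three lesion-volume covariates
#' (total, left- and right-hemisphere volume in cm^3). The package does not
#' segment lesions from raw scans and does not resample: lesion and atlas
#' must already share a grid.
#'
#' @name lesion_features
NULL

#' Construct a lesion image
#'
#' @param voxels 3-D numeric array of lesion evidence, either continuous in
#'   \[0, 1\] or binary.
#' @param affine 4x4 voxel-to-world transform (mm); column-major, maps
#'   0-based voxel indices to world coordinates.
#' @return a `lesion_image` list with `voxels`, `affine` and `voxel_volume`
#'   (mm^3 per voxel, from the affine's Jacobian).
#' @export
lesion_image <- function(voxels, affine = diag(4)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("lesion_image: voxels must be a 3-D array", call. = FALSE)
  if (any(!is.finite(voxels)))
    stop("lesion_image: voxel values must be finite", call. = FALSE)
  if (min(voxels) < 0 || max(voxels) > 1)
    stop("lesion_image: lesion evidence must lie in [0, 1]", call. = FALSE)
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)) ||
      abs(det(affine[1:3, 1:3])) < .Machine$double.eps)
    stop("lesion_image: affine must be an invertible 4x4 transform",
         call. = FALSE)
  structure(list(voxels = voxels, affine = affine,
                 voxel_volume = abs(det(affine[1:3, 1:3]))),
            class = "lesion_image")
}

#' Construct an atlas parcellation
#'
#' @param labels 3-D integer array; 0 = background, 1..R = region ids.
#' @param affine 4x4 voxel-to-world transform shared with the lesion grid.
#' @param region_names optional names for regions 1..R.
#' @return an `atlas_parcellation` list.
#' @export
atlas_parcellation <- function(labels, affine = diag(4), region_names = NULL) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L)
    stop("atlas_parcellation: labels must be a 3-D array", call. = FALSE)
  if (any(labels < 0) || any(labels != round(labels)))
    stop("atlas_parcellation: labels must be non-negative integers",
         call. = FALSE)
  n_regions <- max(0L, as.integer(max(labels)))
  if (is.null(region_names)) {
    region_names <- head(lesion_feature_names(n_regions), n_regions)
  } else if (length(region_names) != n_regions) {
    stop("atlas_parcellation: need one name per region id", call. = FALSE)
  }
  structure(list(labels = labels, affine = as.matrix(affine),
                 region_names = region_names, n_regions = n_regions),
            class = "atlas_parcellation")
}

#' Read a lesion image or atlas from NIfTI
#'
#' @param path a `.nii` / `.nii.gz` file.
#' @return a `lesion_image` ([read_lesion_image()]) or
#'   `atlas_parcellation` ([read_atlas()]).
#' @export
read_lesion_image <- function(path) {
  img <- RNifti::readNifti(path)
  lesion_image(as.array(img), affine = unclass(RNifti::xform(img)))
}

#' @rdname read_lesion_image
#' @param region_names optional region names, passed through.
#' @export
read_atlas <- function(path, region_names = NULL) {
  img <- RNifti::readNifti(path)
  atlas_parcellation(round(as.array(img)),
                     affine = unclass(RNifti::xform(img)),
                     region_names = region_names)
}

is_binary_image <- function(image) all(image$voxels %in% c(0, 1))

#' Binarize a continuous lesion image
#'
#' A voxel is lesioned iff its continuous evidence strictly exceeds the
#' threshold; the conventional threshold for evidence produced by
#' normalisation-based lesion identification is 0.3. An already-binary
#' image passes through unchanged (with a warning if a non-default
#' threshold was requested, since it cannot have any effect).
#'
#' @param image a `lesion_image`.
#' @param threshold evidence cut-off in (0, 1).
#' @return a binary `lesion_image`.
#' @export
binarize_lesion <- function(image, threshold = 0.3) {
  stopifnot(inherits(image, "lesion_image"))
  if (threshold <= 0 || threshold >= 1)
    stop("binarize_lesion: threshold must lie in (0, 1)", call. = FALSE)
  if (is_binary_image(image)) {
    if (!isTRUE(all.equal(threshold, 0.3)))
      warning("binarize_lesion: input is already binary; threshold ",
              threshold, " has no effect", call. = FALSE)
    return(image)
  }
  out <- image
  out$voxels <- (image$voxels > threshold) * 1
  out
}

#' Compute per-region lesion loads
#'
#' `load_r` is the fraction of region r's voxels that are lesioned. Regions
#' with no voxels in the atlas are undefined and reported as `NA`.
#'
#' @param binary a binary `lesion_image`.
#' @param atlas an `atlas_parcellation` on the same voxel grid.
#' @return a `lesion_feature_set` list: `loads` (named, in \[0, 1\] or NA),
#'   `total_volume`, `left_volume`, `right_volume` (cm^3).
#' @export
compute_lesion_loads <- function(binary, atlas) {
  stopifnot(inherits(binary, "lesion_image"),
            inherits(atlas, "atlas_parcellation"))
  if (!is_binary_image(binary))
    stop("compute_lesion_loads: lesion image must be binary; ",
         "call binarize_lesion() first", call. = FALSE)
  if (!identical(dim(binary$voxels), dim(atlas$labels)))
    stop("compute_lesion_loads: lesion and atlas grids differ (",
         paste(dim(binary$voxels), collapse = "x"), " vs ",
         paste(dim(atlas$labels), collapse = "x"), ")", call. = FALSE)
  R <- atlas$n_regions
  lab <- as.integer(atlas$labels)
  les <- as.numeric(binary$voxels)
  in_region <- lab > 0L
  denom <- tabulate(lab[in_region], nbins = R)
  numer <- tabulate(lab[in_region & les > 0], nbins = R)
  loads <- ifelse(denom > 0, numer / denom, NA_real_)
  names(loads) <- atlas$region_names
  vols <- compute_volumes(binary)
  structure(list(loads = loads, total_volume = vols[["total"]],
                 left_volume = vols[["left"]], right_volume = vols[["right"]]),
            class = "lesion_feature_set")
}

#' Compute total and hemispheric lesion volumes
#'
#' Volume = lesioned voxel count x voxel volume, in cm^3. Hemisphere
#' membership follows the sign of each voxel centre's world x-coordinate
#' under the image affine (MNI convention: x < 0 is the left hemisphere);
#' voxels exactly on the midline count toward the total only.
#'
#' @param binary a binary `lesion_image`.
#' @return named vector `c(total, left, right)` in cm^3.
#' @export
compute_volumes <- function(binary) {
  stopifnot(inherits(binary, "lesion_image"))
  if (!is_binary_image(binary))
    stop("compute_volumes: lesion image must be binary", call. = FALSE)
  idx <- which(binary$voxels > 0, arr.ind = TRUE)
  mm3 <- binary$voxel_volume
  if (nrow(idx) == 0L)
    return(c(total = 0, left = 0, right = 0))
  # world x of voxel centres; NIfTI voxel indices are 0-based in the affine
  vox0 <- t(idx) - 1
  world_x <- binary$affine[1, 1:3] %*% vox0 + binary$affine[1, 4]
  world_x <- drop(world_x)
  c(total = nrow(idx) * mm3 / 1000,
    left = sum(world_x < 0) * mm3 / 1000,
    right = sum(world_x > 0) * mm3 / 1000)
}

#' Assemble a predictor row from lesion features
#'
#' Produces one row in the cohort `features.csv` dialect: region loads under
#' the atlas's region names followed by the three volume covariates.
#' Clinical covariates the image cannot supply are NA and must be merged in
#' by the caller.
#'
#' @param fs a `lesion_feature_set`.
#' @param patient_id id for the row.
#' @return one-row data.frame.
#' @export
lesion_feature_row <- function(fs, patient_id = "P00001") {
  stopifnot(inherits(fs, "lesion_feature_set"))
  row <- data.frame(patient_id = patient_id, t(fs$loads),
                    time_post_stroke = NA_real_, age_at_onset = NA_real_,
                    handedness = NA_real_, sex = NA_real_,
                    native_english = NA_real_,
                    total_volume = fs$total_volume,
                    left_volume = fs$left_volume,
                    right_volume = fs$right_volume,
                    check.names = FALSE)
  row
}
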