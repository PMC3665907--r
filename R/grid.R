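#' Brain sampling grid
#'
#' A `brain_grid` couples a rectangular voxel lattice with a 4x4
#' voxel-to-millimetre affine (MNI orientation) and a logical in-brain mask.
#' Every statistic map, seed region and time-series volume handled by this
#' package lives on such a grid. Voxel indices are 0-based in all affine
#' arithmetic (the NIfTI convention); millimetre coordinates are MNI
#' throughout — Talairach input is refused rather than silently converted.
#'
#' @param shape integer vector of length 3, voxels per axis.
#' @param voxel_mm voxel edge length in mm (isotropic) used when `affine` is
#'   not given; the default affine centres the grid so that mm (0,0,0) falls
#'   on the lattice centre.
#' @param affine optional 4x4 voxel-to-mm transform (0-based voxel indices).
#' @param mask optional logical array of dimension `shape`; defaults to an
#'   inscribed ellipsoid occupying 95% of the field of view, a stand-in
#'   "brain" that keeps tests free of atlas files.
#' @return An object of class `brain_grid` with fields `shape`, `affine`,
#'   `mask`.
#' @export
brain_grid <- function(shape, voxel_mm = 2, affine = NULL, mask = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("shape must be 3 positive integers")
  if (is.null(affine)) {
    affine <- diag(c(rep(voxel_mm, 3), 1))
    affine[1:3, 4] <- -voxel_mm * (shape - 1) / 2
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be 4x4")
  if (abs(det(affine)) < 1e-12) stop("affine must be invertible")
  vox_sizes <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(vox_sizes <= 0)) stop("voxel sizes must be strictly positive")
  if (is.null(mask)) {
    ctr <- as.numeric(affine %*% c((shape - 1) / 2, 1))[1:3]
    semi <- vox_sizes * shape / 2 * 0.95
    mask <- ellipsoid_mask(shape, affine, center_mm = ctr, semiaxes_mm = semi)
  }
  if (!is.logical(mask) || !all(dim(mask) == shape))
    stop("mask must be a logical array of dimension shape")
  if (!any(mask)) stop("mask must contain at least one in-brain voxel")
  g <- structure(list(shape = shape, affine = affine, mask = mask),
                 class = "brain_grid")
  .check_round_trip(g)
  g
}

.check_round_trip <- function(grid) {
  corners <- as.matrix(expand.grid(c(0, grid$shape[1] - 1),
                                   c(0, grid$shape[2] - 1),
                                   c(0, grid$shape[3] - 1)))
  back <- mm2vox(grid, vox2mm(grid, corners))
  if (max(abs(back - corners)) > 1e-6)
    stop("voxel->mm->voxel round trip failed; affine is ill-conditioned")
  invisible(TRUE)
}

#' MNI-extent grid with an ellipsoidal brain mask
#'
#' Covers the usual MNI bounding box (x -90..90, y -126..90, z -72..108 mm)
#' at the requested isotropic voxel size, with an ellipsoidal in-brain mask
#' whose axes approximate adult brain extents. Intended for analyses whose
#' coordinates must live at anatomically plausible MNI positions (for
#' example prefrontal seed centres); unit tests use smaller centred grids.
#'
#' @param voxel_mm isotropic voxel size in mm (default 4).
#' @return A `brain_grid`.
#' @export
mni_grid <- function(voxel_mm = 4) {
  lo <- c(-90, -126, -72)
  hi <- c(90, 90, 108)
  shape <- floor((hi - lo) / voxel_mm) + 1L
  affine <- diag(c(rep(voxel_mm, 3), 1))
  affine[1:3, 4] <- lo
  mask <- ellipsoid_mask(shape, affine, center_mm = c(0, -18, 15),
                         semiaxes_mm = c(72, 86, 76))
  brain_grid(shape, affine = affine, mask = mask)
}

#' Ellipsoidal mask on a voxel lattice
#'
#' @param shape,affine lattice geometry as in [brain_grid()].
#' @param center_mm ellipsoid centre (mm).
#' @param semiaxes_mm semi-axis lengths (mm) along x, y, z.
#' @return logical array of dimension `shape`.
#' @export
ellipsoid_mask <- function(shape, affine, center_mm, semiaxes_mm) {
  ijk <- as.matrix(expand.grid(0:(shape[1] - 1), 0:(shape[2] - 1),
                               0:(shape[3] - 1)))
  mm <- cbind(ijk, 1) %*% t(affine)
  d <- sweep(mm[, 1:3, drop = FALSE], 2, center_mm)
  r2 <- rowSums(sweep(d, 2, semiaxes_mm, "/")^2)
  array(r2 <= 1, dim = shape)
}

#' Voxel indices to millimetre coordinates
#'
#' @param grid a `brain_grid`.
#' @param ijk n x 3 matrix (or length-3 vector) of 0-based voxel indices.
#' @return n x 3 matrix of mm coordinates.
#' @export
vox2mm <- function(grid, ijk) {
  ijk <- rbind2mat(ijk)
  mm <- cbind(ijk, 1) %*% t(grid$affine)
  mm[, 1:3, drop = FALSE]
}

#' Millimetre coordinates to fractional voxel indices
#'
#' @param grid a `brain_grid`.
#' @param mm n x 3 matrix (or length-3 vector) of mm coordinates.
#' @return n x 3 matrix of 0-based (fractional) voxel indices.
#' @export
mm2vox <- function(grid, mm) {
  mm <- rbind2mat(mm)
  v <- cbind(mm, 1) %*% t(solve(grid$affine))
  v[, 1:3, drop = FALSE]
}

rbind2mat <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) return(matrix(as.numeric(x), nrow = 1))
  storage.mode(x) <- "double"
  x
}

#' Nearest voxel for mm coordinates
#'
#' Rounds the fractional voxel index to the nearest lattice point; exact
#' half-way ties break toward the lower index so that focus-to-voxel
#' assignment is deterministic.
#'
#' @inheritParams mm2vox
#' @return n x 3 integer matrix of 0-based voxel indices (possibly outside
#'   the lattice; see [in_grid()]).
#' @export
nearest_voxel <- function(grid, mm) {
  v <- mm2vox(grid, mm)
  storage.mode(v) <- "double"
  matrix(as.integer(ceiling(v - 0.5)), ncol = 3)
}

#' Are 0-based voxel indices inside the lattice?
#' @param grid a `brain_grid`.
#' @param ijk n x 3 integer matrix of 0-based indices.
#' @return logical vector.
#' @export
in_grid <- function(grid, ijk) {
  ijk <- rbind2mat(ijk)
  ijk[, 1] >= 0 & ijk[, 1] < grid$shape[1] &
    ijk[, 2] >= 0 & ijk[, 2] < grid$shape[2] &
    ijk[, 3] >= 0 & ijk[, 3] < grid$shape[3]
}

# 1-based R flat array index from 0-based ijk (rows)
flat_index <- function(grid, ijk) {
  ijk <- rbind2mat(ijk)
  as.integer(1 + ijk[, 1] + ijk[, 2] * grid$shape[1] +
               ijk[, 3] * grid$shape[1] * grid$shape[2])
}

#' Number of in-mask voxels
#' @param grid a `brain_grid`.
#' @export
n_voxels <- function(grid) sum(grid$mask)

#' @export
print.brain_grid <- function(x, ...) {
  vs <- sqrt(colSums(x$affine[1:3, 1:3]^2))
  cat(sprintf("<brain_grid> %dx%dx%d voxels, %.3gx%.3gx%.3g mm, %d in mask\n",
              x$shape[1], x$shape[2], x$shape[3], vs[1], vs[2], vs[3],
              sum(x$mask)))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-6) {
  all(a$shape == b$shape) && max(abs(a$affine - b$affine)) < tol
}

#' Per-voxel statistic map
#'
#' A scalar field on a [brain_grid()]. Values outside the mask are held at
#' zero, the package-wide missing marker (for p-value maps in particular,
#' an outside-mask zero is a marker, not a significance claim: all
#' thresholding operates strictly inside the mask).
#'
#' @param grid a `brain_grid`.
#' @param values numeric array of dimension `grid$shape` (a flat vector of
#'   matching length is accepted).
#' @param kind one of `"ale"`, `"p"`, `"z"`, `"r"`, `"diff"`, `"prob"`,
#'   `"mask"`, `"other"`; range invariants are enforced per kind
#'   (ALE in \[0,1), p in \[0,1\], r in \[-1,1\]).
#' @return An object of class `stat_map`.
#' @export
stat_map <- function(grid, values, kind = "other") {
  stopifnot(inherits(grid, "brain_grid"))
  if (is.null(dim(values))) {
    if (length(values) != prod(grid$shape))
      stop("values length does not match grid")
    values <- array(values, dim = grid$shape)
  }
  if (!all(dim(values) == grid$shape)) stop("values dimension mismatch")
  values[!grid$mask] <- 0
  inm <- values[grid$mask]
  if (kind == "ale" && (any(inm < 0) || any(inm >= 1)))
    stop("ALE values must lie in [0,1)")
  if (kind == "p" && (any(inm < 0) || any(inm > 1)))
    stop("p values must lie in [0,1]")
  if (kind == "r" && (any(inm < -1) || any(inm > 1)))
    stop("r values must lie in [-1,1]")
  structure(list(grid = grid, values = values, kind = kind),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  inm <- x$values[x$grid$mask]
  cat(sprintf("<stat_map:%s> range [%.4g, %.4g], %d nonzero in-mask voxels\n",
              x$kind, min(inm), max(inm), sum(inm != 0)))
  invisible(x)
}

#' Write a statistic map (or mask) as NIfTI-1
#'
#' Maps are stored as float32 with the statistic kind in the header
#' description; masks as uint8. Compressed output when the path ends in
#' `.nii.gz`.
#'
#' @param map a `stat_map`.
#' @param path output file path (`.nii` or `.nii.gz`).
#' @export
write_stat_map <- function(map, path) {
  stopifnot(inherits(map, "stat_map"))
  .write_volume(map$values, map$grid, path,
                datatype = if (map$kind == "mask") "uint8" else "float",
                descrip = map$kind)
}

.write_volume <- function(values, grid, path, datatype = "float",
                          descrip = "") {
  img <- RNifti::asNifti(array(as.numeric(values), dim = grid$shape))
  vs <- sqrt(colSums(grid$affine[1:3, 1:3]^2))
  RNifti::pixdim(img) <- vs
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(grid$affine, code = 2L))
  img$descrip <- descrip
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a NIfTI volume as a statistic map
#'
#' @param path NIfTI file.
#' @param kind statistic kind tag for the returned map.
#' @param grid optional `brain_grid` to impose (geometry must agree); when
#'   absent the grid is reconstructed from the header with the nonzero
#'   voxels as mask.
#' @return A `stat_map`.
#' @export
read_stat_map <- function(path, kind = "other", grid = NULL) {
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim = dim(img))
  if (is.null(grid)) {
    aff <- unclass(RNifti::xform(img))
    attributes(aff) <- list(dim = c(4L, 4L))
    grid <- brain_grid(dim(img), affine = aff,
                       mask = array(vals != 0, dim = dim(img)))
  } else if (!all(dim(img) == grid$shape)) {
    stop("volume dimensions do not match the supplied grid")
  }
  stat_map(grid, vals, kind = kind)
}
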