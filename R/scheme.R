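#' Acquisition scheme
#'
#' Per-volume diffusion weighting and timing of a DWI acquisition: b-values,
#' unit gradient directions, echo time and repetition time.  Directions follow
#' the FSL bvec dialect (image coordinate frame); no gradient reorientation is
#' ever applied because spatial registration is out of scope.
#'
#' @param bvals numeric vector of b-values in s/mm^2, one per volume; at least
#'   one must be 0.
#' @param dirs numeric matrix with one row per volume and 3 columns; rows with
#'   b > 0 must be unit vectors (non-unit rows are normalised with a warning);
#'   rows at b = 0 may be zero.
#' @param echo_time echo time in ms, a scalar or one value per volume.
#' @param repetition_time repetition time in ms (scalar).
#' @return An object of class `acq_scheme` with elements `bvals`, `dirs`,
#'   `echo_time`, `repetition_time`.
#' @examples
#' sch <- acq_scheme(c(0, 700), rbind(c(0, 0, 0), c(1, 0, 0)))
#' n_volumes(sch)
#' @export
acq_scheme <- function(bvals, dirs, echo_time = 67, repetition_time = 10000) {
  bvals <- as.numeric(bvals)
  dirs <- as.matrix(dirs)
  storage.mode(dirs) <- "double"
  if (ncol(dirs) != 3L)
    stop("dirs must have 3 columns")
  if (nrow(dirs) != length(bvals))
    stop("number of directions (", nrow(dirs), ") does not match number of b-values (",
         length(bvals), ")")
  if (any(!is.finite(bvals)) || any(bvals < 0))
    stop("b-values must be finite and non-negative")
  if (!any(bvals == 0))
    stop("scheme must contain at least one b = 0 volume")
  if (any(echo_time <= 0) || repetition_time <= 0)
    stop("echo_time and repetition_time must be positive")
  if (!length(echo_time) %in% c(1L, length(bvals)))
    stop("echo_time must be scalar or one value per volume")

  nrm <- sqrt(rowSums(dirs^2))
  dw <- bvals > 0
  if (any(dw & nrm == 0))
    stop("zero gradient direction at b > 0")
  off <- dw & abs(nrm - 1) > 1e-6
  if (any(off)) {
    warning(sum(off), " non-unit gradient direction(s) at b > 0 were normalised")
  }
  dirs[dw, ] <- dirs[dw, , drop = FALSE] / nrm[dw]

  structure(list(bvals = bvals, dirs = dirs,
                 echo_time = as.numeric(echo_time),
                 repetition_time = as.numeric(repetition_time)),
            class = "acq_scheme")
}

#' @rdname acq_scheme
#' @param scheme an `acq_scheme`.
#' @export
n_volumes <- function(scheme) length(scheme$bvals)

#' @export
print.acq_scheme <- function(x, ...) {
  tb <- table(x$bvals)
  cat("Acquisition scheme:", n_volumes(x), "volumes\n")
  cat("  shells (b : n):", paste(names(tb), unname(tb), sep = " : ", collapse = ", "), "\n")
  cat("  TE:", paste(unique(x$echo_time), collapse = ", "), "ms; TR:",
      x$repetition_time, "ms\n")
  invisible(x)
}

#' Per-volume echo times of a scheme
#'
#' @param scheme an `acq_scheme`.
#' @return numeric vector of length `n_volumes(scheme)`.
#' @keywords internal
scheme_te <- function(scheme) {
  rep_len(scheme$echo_time, n_volumes(scheme))
}

#' Build a multi-shell acquisition scheme
#'
#' Generates gradient directions for each non-zero shell by electrostatic
#' repulsion of antipodally symmetric point pairs from a seeded random start,
#' the usual design for diffusion acquisitions.  The result is deterministic
#' given `seed`.
#'
#' @param b_per_shell numeric vector of shell b-values in s/mm^2 (may include 0).
#' @param n_dirs_per_shell integer vector, directions per shell (same length).
#' @param echo_time,repetition_time timing in ms.
#' @param seed integer seed for the direction optimisation.
#' @param n_iter repulsion iterations per shell.
#' @return An [acq_scheme]; b = 0 volumes carry a zero direction.
#' @examples
#' sch <- build_scheme(c(0, 700, 2000), c(1, 32, 32), seed = 1)
#' n_volumes(sch)  # 65
#' @export
build_scheme <- function(b_per_shell, n_dirs_per_shell, echo_time = 67,
                         repetition_time = 10000, seed = 1, n_iter = 300) {
  if (length(b_per_shell) != length(n_dirs_per_shell))
    stop("b_per_shell and n_dirs_per_shell must have the same length")
  if (any(n_dirs_per_shell < 1))
    stop("each shell needs at least one direction")
  if (any(b_per_shell < 0))
    stop("b-values must be non-negative")
  bvals <- rep(b_per_shell, n_dirs_per_shell)
  dirs <- matrix(0, length(bvals), 3)
  row <- 1L
  for (s in seq_along(b_per_shell)) {
    n <- n_dirs_per_shell[s]
    if (b_per_shell[s] > 0) {
      dirs[row:(row + n - 1L), ] <-
        repulsion_directions(n, seed = seed + s, n_iter = n_iter)
    }
    row <- row + n
  }
  if (!any(bvals == 0)) {
    bvals <- c(0, bvals)
    dirs <- rbind(c(0, 0, 0), dirs)
  }
  acq_scheme(bvals, dirs, echo_time = echo_time, repetition_time = repetition_time)
}

# Electrostatic repulsion with antipodal symmetry: minimise
# sum_{i<j} 1/|xi-xj|^2 + 1/|xi+xj|^2 by projected gradient descent.
repulsion_directions <- function(n, seed = 1, n_iter = 300, step = 0.05) {
  if (n == 1L) return(matrix(c(0, 0, 1), 1, 3))
  set.seed(seed)
  x <- matrix(rnorm(3 * n), n, 3)
  x <- x / sqrt(rowSums(x^2))
  for (it in seq_len(n_iter)) {
    force <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      d1 <- sweep(x, 2, x[i, ], "-")   # xi - xj viewpoint handled by sign below
      d2 <- sweep(x, 2, x[i, ], "+")
      r1 <- rowSums(d1^2); r2 <- rowSums(d2^2)
      r1[i] <- Inf
      r2[r2 < 1e-12] <- Inf
      # gradient of 1/r^2 wrt xi, for both the point and its antipode
      force[i, ] <- -2 * colSums(d1 / r1^2) + 2 * colSums(d2 / r2^2)
    }
    nrm <- sqrt(rowSums(force^2))
    scale <- step / max(nrm, 1e-12)
    x <- x + force * scale
    x <- x / sqrt(rowSums(x^2))
  }
  # canonical hemisphere (z >= 0, ties broken on x then y) for reproducibility
  flip <- x[, 3] < 0 | (x[, 3] == 0 & (x[, 1] < 0 | (x[, 1] == 0 & x[, 2] < 0)))
  x[flip, ] <- -x[flip, ]
  x
}

#' DWI volume
#'
#' A 4D diffusion-weighted signal array together with its acquisition scheme,
#' NIfTI affine and brain mask.
#'
#' @param signal 4D numeric array (x, y, z, volume) of non-negative signals.
#' @param scheme an [acq_scheme]; its volume count must match `dim(signal)[4]`.
#' @param affine 4x4 voxel-to-world transform (NIfTI convention).
#' @param mask logical 3D array; defaults to all voxels.
#' @return An object of class `dwi_volume`.
#' @export
dwi_volume <- function(signal, scheme, affine = diag(4), mask = NULL) {
  signal <- unclass(signal)
  attributes(signal) <- list(dim = dim(signal))
  if (length(dim(signal)) != 4L)
    stop("signal must be a 4D array")
  if (dim(signal)[4] != n_volumes(scheme))
    stop("4th dimension (", dim(signal)[4], ") does not match scheme volumes (",
         n_volumes(scheme), ")")
  if (is.null(mask)) mask <- array(TRUE, dim(signal)[1:3])
  if (!identical(dim(mask), dim(signal)[1:3]))
    stop("mask dimensions do not match signal")
  inmask <- signal[rep_arr(mask, dim(signal)[4])]
  if (any(!is.finite(inmask)) || any(inmask < 0))
    stop("signal must be finite and non-negative within the mask")
  structure(list(signal = signal, scheme = scheme,
                 affine = as.matrix(affine), mask = mask),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  cat("DWI volume:", paste(dim(x$signal), collapse = " x "),
      "(", sum(x$mask), "voxels in mask )\n")
  print(x$scheme)
  invisible(x)
}

# replicate a 3D logical mask along a 4th dimension
rep_arr <- function(mask, n4) array(mask, c(dim(mask), n4))

#' Read a DWI dataset (NIfTI + FSL bval/bvec)
#'
#' @param image_path path to a 4D NIfTI-1 file (.nii or .nii.gz).
#' @param bval_path path to a whitespace-delimited 1 x N b-value table.
#' @param bvec_path path to a whitespace-delimited 3 x N gradient table.
#' @param mask_path optional path to a 3D mask NIfTI.
#' @param echo_time,repetition_time timing in ms (not stored in FSL tables).
#' @return A [dwi_volume].  Non-unit gradient columns at b > 0 are normalised
#'   with a warning; mismatched volume counts raise an error.
#' @export
read_dwi <- function(image_path, bval_path, bvec_path, mask_path = NULL,
                     echo_time = 67, repetition_time = 10000) {
  img <- RNifti::readNifti(image_path)
  bvals <- scan(bval_path, quiet = TRUE)
  bvec <- as.matrix(read.table(bvec_path))
  if (nrow(bvec) != 3L)
    stop("bvec must have 3 rows (FSL convention)")
  if (ncol(bvec) != length(bvals))
    stop("bvec has ", ncol(bvec), " columns but bval lists ", length(bvals),
         " volumes")
  arr <- as.array(img)
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  if (dim(arr)[4] != length(bvals))
    stop("image has ", dim(arr)[4], " volumes but bval lists ", length(bvals))
  scheme <- acq_scheme(bvals, t(bvec), echo_time = echo_time,
                       repetition_time = repetition_time)
  mask <- NULL
  if (!is.null(mask_path)) {
    mask <- as.array(RNifti::readNifti(mask_path)) > 0
  }
  dwi_volume(arr, scheme, affine = xform_of(img), mask = mask)
}

xform_of <- function(img) {
  structure(unclass(RNifti::xform(img)), dimnames = NULL, code = NULL,
            imagedim = NULL)
}

#' Write a 3D parameter map as NIfTI-1
#'
#' Values round-trip through [read_map()] to within 1e-6 and the affine is
#' preserved.
#'
#' @param values 3D numeric array (NA allowed; stored as-is in float data).
#' @param affine 4x4 voxel-to-world transform.
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_map <- function(values, affine, path) {
  if (any(!is.finite(values) & !is.na(values)))
    stop("values must be finite or NA")
  img <- RNifti::asNifti(array(as.numeric(values), dim(values)))
  img <- RNifti::`sform<-`(img, structure(as.matrix(affine), code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a 3D map written by [write_map()]
#'
#' @param path NIfTI path.
#' @return list with `values` (3D array) and `affine` (4x4 matrix).
#' @export
read_map <- function(path) {
  img <- RNifti::readNifti(path)
  list(values = as.array(img), affine = xform_of(img))
}

#' Write a DWI dataset (NIfTI + FSL bval/bvec)
#'
#' @param dwi a [dwi_volume].
#' @param image_path,bval_path,bvec_path output paths.
#' @return `image_path`, invisibly.
#' @export
write_dwi <- function(dwi, image_path, bval_path, bvec_path) {
  img <- RNifti::asNifti(dwi$signal)
  img <- RNifti::`sform<-`(img, structure(as.matrix(dwi$affine), code = 2L))
  RNifti::writeNifti(img, image_path, datatype = "double")
  cat(paste(format(dwi$scheme$bvals, trim = TRUE, scientific = FALSE),
            collapse = " "), "\n", file = bval_path)
  write.table(t(dwi$scheme$dirs), bvec_path, row.names = FALSE,
              col.names = FALSE)
  invisible(image_path)
}
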