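#' CT volume container
#'
#' A 3D scalar image with explicit physical-space metadata. All downstream
#' geometry works in physical millimetres: the physical position of voxel
#' index `(i, j, k)` (0-based) is `origin + direction %*% (spacing * c(i,j,k))`.
#' Intensities are Hounsfield-like; any rescale slope/intercept present in a
#' file header is applied at read time.
#'
#' @param data 3D numeric array of intensities; must be finite everywhere.
#' @param spacing Numeric length-3, per-axis voxel size in mm (all > 0).
#' @param origin Numeric length-3, physical position of voxel (0,0,0) in mm.
#' @param direction 3x3 orthonormal direction matrix (`|det| = 1` within 1e-6).
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing, origin = c(0, 0, 0), direction = diag(3)) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)", call. = FALSE)
  direction <- matrix(as.numeric(direction), 3, 3)
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6 ||
      abs(abs(det(direction)) - 1) > 1e-6)
    stop("`direction` must be orthonormal with |det| = 1 (within 1e-6)",
         call. = FALSE)
  if (any(!is.finite(data)))
    stop("volume data must be finite everywhere", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin,
                 direction = direction),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("ct_volume:", paste(dim(x$data), collapse = " x "),
      "voxels, spacing", paste(signif(x$spacing, 4), collapse = " x "),
      "mm\n  origin (", paste(signif(x$origin, 5), collapse = ", "),
      ") mm, intensity range [", signif(min(x$data), 4), ",",
      signif(max(x$data), 4), "]\n")
  invisible(x)
}

#' Binary mask on a CT grid
#'
#' Carries the same grid metadata as the volume it was derived from.
#'
#' @param data 3D logical array.
#' @param spacing,origin,direction Grid metadata, as in [ct_volume()].
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, spacing, origin = c(0, 0, 0), direction = diag(3)) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array", call. = FALSE)
  storage.mode(data) <- "logical"
  v <- ct_volume(array(0, dim(data)), spacing, origin, direction)  # metadata checks
  structure(list(data = data, spacing = v$spacing, origin = v$origin,
                 direction = v$direction),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("binary_mask:", paste(dim(x$data), collapse = " x "), "voxels,",
      sum(x$data), "set (", signif(voxel_volume(x) * sum(x$data), 6), "mm^3 )\n")
  invisible(x)
}

#' Volume of one voxel in mm^3
#' @param x A `ct_volume` or `binary_mask`.
#' @return Scalar voxel volume in mm^3.
#' @export
voxel_volume <- function(x) prod(x$spacing)

#' Physical coordinates of voxel centers
#'
#' @param x A `ct_volume` or `binary_mask`.
#' @param which Optional logical array or linear indices selecting voxels;
#'   defaults to all voxels.
#' @return N x 3 matrix of physical coordinates in mm.
#' @export
voxel_centers <- function(x, which = NULL) {
  d <- dim(x$data)
  if (is.null(which)) {
    idx <- seq_len(prod(d))
  } else if (is.logical(which)) {
    idx <- which(which)
  } else idx <- as.integer(which)
  ijk <- arrayInd(idx, d) - 1L
  sweep(ijk %*% (t(x$direction) * x$spacing), 2, x$origin, `+`)
}

.nifti_exts <- c("\\.nii$", "\\.nii\\.gz$")
.meta_exts <- c("\\.mha$", "\\.mhd$")

#' Read a CT volume
#'
#' Supports NIfTI-1 (`.nii`, `.nii.gz`) and MetaImage (`.mha`, `.mhd`).
#' Spacing, origin and direction are taken from the file header; a header
#' without usable spacing information is an error, never silently defaulted.
#' NIfTI rescale slope/intercept are applied to the intensities.
#'
#' @param path Path to the image file.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop("cannot read volume: file does not exist: ", path, call. = FALSE)
  if (any(vapply(.nifti_exts, grepl, logical(1), path)))
    return(.read_nifti(path))
  if (any(vapply(.meta_exts, grepl, logical(1), path)))
    return(.read_metaimage(path))
  stop("unsupported volume format (expect .nii, .nii.gz, .mha or .mhd): ",
       path, call. = FALSE)
}

.read_nifti <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("failed to read NIfTI file ", path,
                                           ": ", conditionMessage(e), call. = FALSE))
  hdr <- RNifti::niftiHeader(img)
  A <- unclass(RNifti::xform(img))[1:3, 1:4, drop = FALSE]
  spacing <- sqrt(colSums(A[, 1:3, drop = FALSE]^2))
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("NIfTI header of ", path, " carries no usable voxel spacing",
         call. = FALSE)
  direction <- A[, 1:3] %*% diag(1 / spacing)
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6)
    stop("NIfTI header of ", path, " has a non-orthonormal direction matrix",
         call. = FALSE)
  dat <- as.array(img)
  dat <- array(as.numeric(dat), dim(dat)[1:3])   # drop RNifti attributes
  slope <- hdr$scl_slope
  inter <- hdr$scl_inter
  if (is.finite(slope) && slope != 0 && !(slope == 1 && inter == 0))
    dat <- dat * slope + inter
  ct_volume(dat, spacing = spacing, origin = A[, 4], direction = direction)
}

#' Write a CT volume
#'
#' Format chosen from the file extension (NIfTI or MetaImage). Reading the
#' written file reproduces the data exactly and the metadata within 1e-6.
#'
#' @param volume A [ct_volume()].
#' @param path Output path; the parent directory must exist.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  if (!dir.exists(dirname(path)))
    stop("cannot write volume: directory does not exist: ", dirname(path),
         call. = FALSE)
  if (any(vapply(.nifti_exts, grepl, logical(1), path))) {
    A <- diag(4)
    A[1:3, 1:3] <- volume$direction %*% diag(volume$spacing)
    A[1:3, 4] <- volume$origin
    img <- RNifti::asNifti(volume$data, pixdim = volume$spacing)
    # sform only: writing the qform as well degrades the affine (quaternion
    # storage cannot carry it exactly and overwrites the stored geometry)
    img <- RNifti::`sform<-`(img, structure(A, code = 2L))
    RNifti::writeNifti(img, path)
  } else if (any(vapply(.meta_exts, grepl, logical(1), path))) {
    .write_metaimage(volume, path)
  } else {
    stop("unsupported volume format for writing: ", path, call. = FALSE)
  }
  invisible(path)
}

# MetaImage (.mha single-file, .mhd + .raw) -- uncompressed only.
.write_metaimage <- function(volume, path) {
  single <- grepl("\\.mha$", path)
  d <- dim(volume$data)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("TransformMatrix =", paste(format(t(volume$direction), digits = 17),
                                     collapse = " ")),
    paste("Offset =", paste(format(volume$origin, digits = 17), collapse = " ")),
    paste("ElementSpacing =", paste(format(volume$spacing, digits = 17),
                                    collapse = " ")),
    paste("DimSize =", paste(d, collapse = " ")),
    "ElementType = MET_DOUBLE")
  if (single) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c(hdr, "ElementDataFile = LOCAL"), con)
    writeBin(as.numeric(volume$data), con, size = 8, endian = "little")
  } else {
    raw_name <- sub("\\.mhd$", ".raw", basename(path))
    writeLines(c(hdr, paste("ElementDataFile =", raw_name)), path)
    con <- file(file.path(dirname(path), raw_name), "wb")
    on.exit(close(con))
    writeBin(as.numeric(volume$data), con, size = 8, endian = "little")
  }
  invisible(path)
}

.read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("truncated MetaImage header: ", path, call. = FALSE)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) next
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    fields[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (identical(tolower(fields$CompressedData %||% "false"), "true"))
    stop("compressed MetaImage not supported: ", path, call. = FALSE)
  if (is.null(fields$ElementSpacing))
    stop("MetaImage header of ", path, " carries no ElementSpacing", call. = FALSE)
  d <- as.integer(strsplit(fields$DimSize, "\\s+")[[1]])
  spacing <- as.numeric(strsplit(fields$ElementSpacing, "\\s+")[[1]])
  origin <- as.numeric(strsplit(fields$Offset %||% "0 0 0", "\\s+")[[1]])
  direction <- diag(3)
  if (!is.null(fields$TransformMatrix))
    direction <- t(matrix(as.numeric(strsplit(fields$TransformMatrix,
                                              "\\s+")[[1]]), 3, 3))
  type <- fields$ElementType
  n <- prod(d)
  reader <- switch(type,
    MET_DOUBLE = function(c_, n_) readBin(c_, "double", n_, size = 8, endian = "little"),
    MET_FLOAT  = function(c_, n_) readBin(c_, "double", n_, size = 4, endian = "little"),
    MET_SHORT  = function(c_, n_) readBin(c_, "integer", n_, size = 2, signed = TRUE, endian = "little"),
    MET_USHORT = function(c_, n_) readBin(c_, "integer", n_, size = 2, signed = FALSE, endian = "little"),
    MET_UCHAR  = function(c_, n_) readBin(c_, "integer", n_, size = 1, signed = FALSE, endian = "little"),
    stop("unsupported MetaImage ElementType: ", type, call. = FALSE))
  if (identical(fields$ElementDataFile, "LOCAL")) {
    dat <- reader(con, n)
  } else {
    rawpath <- file.path(dirname(path), fields$ElementDataFile)
    if (!file.exists(rawpath))
      stop("MetaImage data file missing: ", rawpath, call. = FALSE)
    con2 <- file(rawpath, "rb")
    on.exit(close(con2), add = TRUE)
    dat <- reader(con2, n)
  }
  if (length(dat) != n) stop("truncated MetaImage data in ", path, call. = FALSE)
  ct_volume(array(as.numeric(dat), d), spacing = spacing, origin = origin,
            direction = direction)
}

#' Resample a volume to isotropic spacing
#'
#' Linear interpolation onto a grid with the requested isotropic spacing,
#' covering the same physical extent (origin and direction unchanged).
#'
#' @param volume A [ct_volume()].
#' @param target_spacing Isotropic target voxel size in mm (> 0).
#' @return A resampled [ct_volume()].
#' @export
resample_isotropic <- function(volume, target_spacing) {
  stopifnot(inherits(volume, "ct_volume"))
  if (!is.numeric(target_spacing) || length(target_spacing) != 1L ||
      target_spacing <= 0)
    stop("`target_spacing` must be a single positive value (mm)", call. = FALSE)
  if (target_spacing > 4 * max(volume$spacing))
    warning("target spacing ", target_spacing, " mm is more than 4x coarser ",
            "than the native spacing; expect heavy smoothing", call. = FALSE)
  d <- dim(volume$data)
  extent <- (d - 1L) * volume$spacing
  nout <- pmax(2L, as.integer(round(extent / target_spacing)) + 1L)
  coords <- lapply(1:3, function(a)
    seq(0, by = target_spacing / volume$spacing[a], length.out = nout[a]))
  dat <- cpp_resample_trilinear(as.numeric(volume$data), as.integer(d),
                                coords[[1]], coords[[2]], coords[[3]])
  ct_volume(array(dat, nout), spacing = rep(target_spacing, 3),
            origin = volume$origin, direction = volume$direction)
}
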