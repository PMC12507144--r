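#' Construct a VelocityField
#'
#' @param vx,vy,vz 4D numeric arrays `[nx,ny,nz,nt]`, velocity in m/s.
#' @param mag 4D numeric array of signal magnitude; defaults to 1
#'   everywhere (unit weighting).
#' @param spacing numeric(3) voxel spacing in mm.
#' @param dt temporal resolution in ms.
#' @param venc velocity encoding in m/s (metadata only).
#' @return A [VelocityField-class].
#' @export
VelocityField <- function(vx, vy, vz, mag = NULL, spacing, dt, venc = 1.5) {
  if (is.null(mag)) mag <- array(1, dim = dim(vx))
  new("VelocityField", vx = vx, vy = vy, vz = vz, mag = mag,
      spacing = as.numeric(spacing), dt = as.numeric(dt),
      venc = as.numeric(venc))
}

#' Construct a Segmentation
#'
#' @param mask logical 3D array (lumen voxels TRUE).
#' @param spacing numeric(3) voxel spacing in mm.
#' @param checkConnected warn when the mask has more than one
#'   6-connected foreground component.
#' @return A [Segmentation-class].
#' @export
Segmentation <- function(mask, spacing, checkConnected = TRUE) {
  mask <- array(as.logical(mask), dim = dim(mask))
  seg <- new("Segmentation", mask = mask, spacing = as.numeric(spacing))
  if (checkConnected && countComponents(mask) > 1L)
    warning("segmentation mask has more than one connected component")
  seg
}

#' Time-averaged phase-contrast MR angiogram (PC-MRA)
#'
#' The PC-MRA is the over-time mean of magnitude times speed,
#' `mean_t(mag * |v|)`, per voxel; it is the image the lumen is
#' segmented on. By construction it is non-negative and invariant to
#' velocity sign flips and to any permutation of the timeframes.
#'
#' @param field a [VelocityField-class].
#' @return 3D numeric array `[nx,ny,nz]`.
#' @export
computePCMRA <- function(field) {
  stopifnot(is(field, "VelocityField"))
  speed <- sqrt(field@vx^2 + field@vy^2 + field@vz^2)
  w <- field@mag * speed
  d <- dim(w)
  rowMeans(array(w, dim = c(prod(d[1:3]), d[4])), dims = 1L) |>
    array(dim = d[1:3])
}

#' Peak-systole timeframe
#'
#' The timeframe in which the spatially averaged velocity magnitude
#' within the segmented lumen is highest (ties broken by the earliest
#' frame). Invariant to uniform velocity rescaling.
#'
#' @param field a [VelocityField-class].
#' @param seg a [Segmentation-class] on the same grid.
#' @return Integer frame index (1-based).
#' @export
peakSystoleIndex <- function(field, seg) {
  stopifnot(is(field, "VelocityField"), is(seg, "Segmentation"))
  d <- dim(field@vx)
  if (!identical(dim(seg@mask), d[1:3]))
    stop("segmentation grid does not match the velocity field")
  idx <- which(seg@mask)
  if (length(idx) == 0L) stop("empty segmentation mask")
  nt <- d[4L]
  nvol <- prod(d[1:3])
  sp <- numeric(nt)
  for (t in seq_len(nt)) {
    off <- (t - 1L) * nvol
    sp[t] <- mean(sqrt(field@vx[idx + off]^2 + field@vy[idx + off]^2 +
                         field@vz[idx + off]^2))
  }
  which.max(sp)  # which.max takes the earliest maximum
}

#' Read / write a 4D flow dataset
#'
#' A dataset directory holds one NIfTI volume per velocity component
#' (`vx.nii.gz`, `vy.nii.gz`, `vz.nii.gz`, 4th dimension = time), the
#' magnitude image (`mag.nii.gz`), the lumen mask (`mask.nii.gz`) and a
#' JSON sidecar `dataset.json` with keys `spacing_mm`, `dt_ms` and
#' `venc_ms`. Arrays are written as float64 so the write/read
#' round-trip is bit-exact.
#'
#' @param field a [VelocityField-class].
#' @param seg a [Segmentation-class].
#' @param path dataset directory.
#' @return `writeFlowDataset` returns `path` invisibly;
#'   `readFlowDataset` returns `list(field =, seg =)`.
#' @export
writeFlowDataset <- function(field, seg, path) {
  stopifnot(is(field, "VelocityField"), is(seg, "Segmentation"))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  pd <- field@spacing
  wr <- function(arr, file) {
    img <- RNifti::asNifti(arr, datatype = "double")
    img$pixdim[2:4] <- pd
    RNifti::writeNifti(img, file.path(path, file), datatype = "double")
  }
  wr(field@vx, "vx.nii.gz")
  wr(field@vy, "vy.nii.gz")
  wr(field@vz, "vz.nii.gz")
  wr(field@mag, "mag.nii.gz")
  mimg <- RNifti::asNifti(array(as.integer(seg@mask), dim = dim(seg@mask)),
                          datatype = "uint8")
  mimg$pixdim[2:4] <- seg@spacing
  RNifti::writeNifti(mimg, file.path(path, "mask.nii.gz"), datatype = "uint8")
  sidecar <- list(spacing_mm = field@spacing, dt_ms = field@dt,
                  venc_ms = field@venc)
  jsonlite::write_json(sidecar, file.path(path, "dataset.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeFlowDataset
#' @export
readFlowDataset <- function(path) {
  need <- c("vx.nii.gz", "vy.nii.gz", "vz.nii.gz", "mag.nii.gz",
            "mask.nii.gz", "dataset.json")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing) > 0L)
    stop("dataset is missing file(s): ", paste(missing, collapse = ", "))
  sidecar <- jsonlite::read_json(file.path(path, "dataset.json"),
                                 simplifyVector = TRUE)
  for (key in c("spacing_mm", "dt_ms", "venc_ms")) {
    if (is.null(sidecar[[key]]))
      stop("sidecar dataset.json is missing key '", key, "'")
  }
  rd <- function(file) {
    img <- RNifti::readNifti(file.path(path, file))
    array(as.numeric(img), dim = dim(img))
  }
  vx <- rd("vx.nii.gz"); vy <- rd("vy.nii.gz"); vz <- rd("vz.nii.gz")
  mag <- rd("mag.nii.gz")
  maskArr <- rd("mask.nii.gz")
  if (!identical(dim(maskArr), dim(vx)[1:3]))
    stop("mask grid shape ", paste(dim(maskArr), collapse = "x"),
         " does not match velocity grid ",
         paste(dim(vx)[1:3], collapse = "x"))
  field <- VelocityField(vx, vy, vz, mag,
                         spacing = sidecar$spacing_mm,
                         dt = sidecar$dt_ms, venc = sidecar$venc_ms)
  seg <- Segmentation(maskArr > 0.5, spacing = sidecar$spacing_mm,
                      checkConnected = FALSE)
  list(field = field, seg = seg)
}
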