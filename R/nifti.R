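#' Minimal NIfTI-1 volume I/O
#'
#' Reads and writes single-file NIfTI-1 volumes (`.nii`, `.nii.gz`),
#' enough for round-tripping 3D magnitude data: float32 storage on
#' write, the common integer/float datatypes on read, scale slope and
#' intercept applied, and the sform affine passed through untouched.
#'
#' @name nifti-io
NULL

.NIFTI_DT <- list(`2`  = list(what = "integer", size = 1, signed = FALSE),
                  `4`  = list(what = "integer", size = 2, signed = TRUE),
                  `8`  = list(what = "integer", size = 4, signed = TRUE),
                  `16` = list(what = "numeric", size = 4, signed = TRUE),
                  `64` = list(what = "numeric", size = 8, signed = TRUE),
                  `512` = list(what = "integer", size = 2, signed = FALSE))

#' Read a 3D volume from a NIfTI-1 file
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return list with `data` (3-way numeric array), `pixdim` (voxel
#'   sizes), `affine` (4 x 4 matrix from the sform when set, otherwise a
#'   diagonal from `pixdim`) and `sform_code`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  con <- gzfile(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L)
    stop(sprintf("corrupt NIfTI file (short header): %s", path), call. = FALSE)
  endian <- .Platform$endian
  rd <- function(off, what, n, size, signed = TRUE) {
    rc <- rawConnection(hdr[(off + 1):(off + n * size)])
    on.exit(close(rc))
    readBin(rc, what, n = n, size = size, signed = signed, endian = endian)
  }
  if (rd(0, "integer", 1, 4) != 348L) {
    endian <- "swap"
    if (rd(0, "integer", 1, 4) != 348L)
      stop(sprintf("not a NIfTI-1 file: %s", path), call. = FALSE)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop(sprintf("not a NIfTI-1 file (bad magic): %s", path), call. = FALSE)
  dim0 <- rd(40, "integer", 8, 2)
  nd <- dim0[1]
  dims <- dim0[2:(nd + 1)]
  if (nd > 3L) {
    if (all(dims[4:nd] == 1L)) dims <- dims[1:3]
    else stop(sprintf("expected a 3D volume, got %dD: %s", nd, path),
              call. = FALSE)
  } else if (nd < 3L) {
    stop(sprintf("expected a 3D volume, got %dD: %s", nd, path), call. = FALSE)
  }
  datatype <- rd(70, "integer", 1, 2)
  spec <- .NIFTI_DT[[as.character(datatype)]]
  if (is.null(spec))
    stop(sprintf("unsupported NIfTI datatype %d: %s", datatype, path),
         call. = FALSE)
  pixdim <- rd(76, "numeric", 8, 4)[2:4]
  vox_offset <- rd(108, "numeric", 1, 4)
  scl_slope <- rd(112, "numeric", 1, 4)
  scl_inter <- rd(116, "numeric", 1, 4)
  sform_code <- rd(254, "integer", 1, 2)
  srow <- matrix(rd(280, "numeric", 12, 4), nrow = 3, byrow = TRUE)
  if (vox_offset > 348) readBin(con, "raw", n = as.integer(vox_offset) - 348L)
  n <- prod(dims)
  data <- readBin(con, spec$what, n = n, size = spec$size,
                  signed = spec$signed, endian = endian)
  if (length(data) < n)
    stop(sprintf("corrupt NIfTI file (truncated data): %s", path),
         call. = FALSE)
  data <- as.numeric(data)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  affine <- if (sform_code > 0) rbind(srow, c(0, 0, 0, 1))
            else diag(c(pixdim, 1))
  list(data = array(data, dim = dims), pixdim = pixdim, affine = affine,
       sform_code = sform_code)
}

#' Write a 3D volume to a NIfTI-1 file
#'
#' Stores data as float32 with an sform affine; gzip compression is
#' chosen by the `.gz` extension.
#'
#' @param vol 3-way numeric array.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param affine 4 x 4 voxel-to-world matrix (default: diagonal from
#'   `pixdim`), written as the sform and passed through exactly.
#' @param pixdim voxel sizes, default `c(1, 1, 1)` mm.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path, affine = NULL, pixdim = c(1, 1, 1)) {
  .check_volume(vol)
  if (is.null(affine)) affine <- diag(c(pixdim, 1))
  stopifnot(identical(dim(affine), c(4L, 4L)) || identical(dim(affine), c(4, 4)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con), add = TRUE)
  wi <- function(x, size) writeBin(as.integer(x), con, size = size)
  wf <- function(x, size = 4) writeBin(as.numeric(x), con, size = size)
  wc <- function(s, len) {
    r <- raw(len)
    b <- charToRaw(s)
    if (length(b) > 0) r[seq_along(b)] <- b
    writeBin(r, con)
  }
  wi(348, 4)                        # sizeof_hdr
  wc("", 10); wc("", 18)            # data_type, db_name
  wi(0, 4); wi(0, 2); wc("r", 1); wc("", 1)  # extents, session_error, regular, dim_info
  wi(c(3, dim(vol), 1, 1, 1, 1), 2) # dim[8]
  wf(c(0, 0, 0)); wi(0, 2)          # intent_p1..p3, intent_code
  wi(16, 2); wi(32, 2); wi(0, 2)    # datatype float32, bitpix, slice_start
  wf(c(1, pixdim, 1, 1, 1, 1))      # pixdim[8]
  wf(352)                           # vox_offset
  wf(1); wf(0)                      # scl_slope, scl_inter
  wi(0, 2); wc("", 1); wc("", 1)    # slice_end, slice_code, xyzt_units
  wf(0); wf(0); wf(0); wf(0)        # cal_max, cal_min, slice_duration, toffset
  wi(0, 4); wi(0, 4)                # glmax, glmin
  wc("hosvdmri", 80); wc("", 24)    # descrip, aux_file
  wi(0, 2); wi(2, 2)                # qform_code, sform_code = 2 (aligned)
  wf(c(0, 0, 0)); wf(c(0, 0, 0))    # quatern, qoffset
  wf(t(affine[1:3, ]))              # srow_x, srow_y, srow_z
  wc("", 16)                        # intent_name
  wc("n+1", 3); writeBin(raw(1), con)  # magic
  writeBin(raw(4), con)             # extension flag
  writeBin(as.numeric(vol), con, size = 4)
  invisible(path)
}
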