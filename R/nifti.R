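#' @include AllClasses.R
NULL

# NIfTI-1 single-file (.nii / .nii.gz) read and write, implemented directly
# on the 348-byte header layout.  Scope: the subset this package produces
# and consumes -- 3D/4D volumes, datatypes uint8/int16/int32/float32/
# float64, sform or qform orientation, scl_slope/scl_inter scaling.

.niftiDatatypes <- list(
    `2`  = list(what = "integer", size = 1L, signed = FALSE),
    `4`  = list(what = "integer", size = 2L, signed = TRUE),
    `8`  = list(what = "integer", size = 4L, signed = TRUE),
    `16` = list(what = "double",  size = 4L, signed = TRUE),
    `64` = list(what = "double",  size = 8L, signed = TRUE))

.openMaybeGz <- function(path, mode) {
    if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

.quaternionToMat <- function(b, c, d, qfac) {
    a2 <- 1 - b * b - c * c - d * d
    a <- sqrt(max(a2, 0))
    m <- matrix(c(
        a * a + b * b - c * c - d * d, 2 * b * c - 2 * a * d, 2 * b * d + 2 * a * c,
        2 * b * c + 2 * a * d, a * a + c * c - b * b - d * d, 2 * c * d - 2 * a * b,
        2 * b * d - 2 * a * c, 2 * c * d + 2 * a * b, a * a + d * d - c * c - b * b),
        3, 3, byrow = TRUE)
    m[, 3] <- m[, 3] * qfac
    m
}

#' Read a NIfTI-1 volume
#'
#' Reads a 3D or 4D NIfTI-1 file (optionally gzip-compressed) into a
#' \linkS4class{TimeSeriesVolume}; 3D inputs get a time dimension of
#' length 1.  The affine is taken from the sform when present, else from
#' the qform, else from pixdim.  TR is read from pixdim[4] unless
#' overridden.
#'
#' @param path path to a .nii or .nii.gz file.
#' @param trSeconds optional repetition time overriding the header.
#' @return a \linkS4class{TimeSeriesVolume}.
#' @export
readNiftiVolume <- function(path, trSeconds = NULL) {
    if (!file.exists(path))
        stop(errorCondition(paste("NIfTI file not found:", path),
                            class = c("niftiFileMissing", "niftiError")))
    con <- .openMaybeGz(path, "rb")
    on.exit(close(con))
    sizeof <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    endian <- "little"
    if (sizeof != 348L) {
        swapped <- readBin(writeBin(sizeof, raw()), "integer", 1L,
                           size = 4L, endian = "big")
        # re-read assuming big endian
        if (swapped == 348L) endian <- "big"
        else stop(errorCondition(paste("not a NIfTI-1 file:", path),
                                 class = c("niftiFormatError", "niftiError")))
    }
    readBin(con, "raw", 36L)                        # unused fields
    dims <- readBin(con, "integer", 8L, size = 2L, endian = endian)
    readBin(con, "raw", 14L)                        # intent fields
    datatype <- readBin(con, "integer", 1L, size = 2L, endian = endian)
    readBin(con, "integer", 1L, size = 2L, endian = endian)   # bitpix
    readBin(con, "integer", 1L, size = 2L, endian = endian)   # slice_start
    pixdim <- readBin(con, "double", 8L, size = 4L, endian = endian)
    voxOffset <- readBin(con, "double", 1L, size = 4L, endian = endian)
    sclSlope <- readBin(con, "double", 1L, size = 4L, endian = endian)
    sclInter <- readBin(con, "double", 1L, size = 4L, endian = endian)
    # slice_end(2) slice_code(1) xyzt_units(1) cal_max(4) cal_min(4)
    # slice_duration(4) toffset(4) glmax(4) glmin(4) descrip(80) aux_file(24)
    readBin(con, "raw", 132L)
    qformCode <- readBin(con, "integer", 1L, size = 2L, endian = endian)
    sformCode <- readBin(con, "integer", 1L, size = 2L, endian = endian)
    quat <- readBin(con, "double", 6L, size = 4L, endian = endian)
    srow <- matrix(readBin(con, "double", 12L, size = 4L, endian = endian),
                   3L, 4L, byrow = TRUE)
    readBin(con, "raw", 16L)                        # intent_name
    magic <- rawToChar(readBin(con, "raw", 4L))
    if (!grepl("^n\\+1", magic))
        stop(errorCondition(paste("missing NIfTI magic in", path),
                            class = c("niftiFormatError", "niftiError")))

    ndim <- dims[1L]
    if (ndim < 3L || ndim > 4L)
        stop(errorCondition(sprintf("unsupported NIfTI dimensionality %d", ndim),
                            class = c("niftiFormatError", "niftiError")))
    shape <- dims[2:4]
    nt <- if (ndim == 4L) dims[5L] else 1L
    dt <- .niftiDatatypes[[as.character(datatype)]]
    if (is.null(dt))
        stop(errorCondition(sprintf("unsupported NIfTI datatype code %d", datatype),
                            class = c("niftiFormatError", "niftiError")))

    skip <- voxOffset - 348
    if (skip > 0) readBin(con, "raw", as.integer(skip))
    n <- prod(shape) * nt
    vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                    endian = endian)
    if (length(vals) != n)
        stop(errorCondition("NIfTI data shorter than header dimensions",
                            class = c("niftiShapeMismatch", "niftiError")))
    vals <- as.double(vals)
    if (is.finite(sclSlope) && sclSlope != 0 && !(sclSlope == 1 && sclInter == 0))
        vals <- vals * sclSlope + sclInter

    aff <- diag(4)
    if (sformCode > 0L) {
        aff[1:3, ] <- srow
    } else if (qformCode > 0L) {
        qfac <- if (pixdim[1L] < 0) -1 else 1
        rot <- .quaternionToMat(quat[1L], quat[2L], quat[3L], qfac)
        aff[1:3, 1:3] <- rot %*% diag(abs(pixdim[2:4]))
        aff[1:3, 4L] <- quat[4:6]
    } else {
        aff[1:3, 1:3] <- diag(abs(pixdim[2:4]))
    }
    vs <- sqrt(colSums(aff[1:3, 1:3]^2))
    grid <- new("VolumeGrid", shape = as.integer(shape), voxelSize = vs,
                affine = aff)
    tr <- if (!is.null(trSeconds)) trSeconds
          else if (ndim == 4L && pixdim[5L] > 0) pixdim[5L] else 1
    new("TimeSeriesVolume", grid = grid,
        data = array(vals, dim = c(shape, nt)), trSeconds = tr)
}

#' Write a NIfTI-1 volume
#'
#' Writes a \linkS4class{TimeSeriesVolume}, \linkS4class{BinaryMask},
#' \linkS4class{AlffMap} or \linkS4class{PairedTMap} as a single-file
#' NIfTI-1 volume.  Masks are written as unsigned 8-bit 0/1; everything
#' else as float64 so that write/read round-trips are bitwise exact.  The
#' affine is stored in the sform (and mirrored into the qform translation).
#'
#' @param x the object to write.
#' @param path output path; a ".gz" suffix selects gzip compression.
#' @return invisibly, \code{path}.
#' @export
writeNiftiVolume <- function(x, path) {
    if (is(x, "BinaryMask")) {
        data <- array(as.integer(x@members), dim = c(dim(x@members), 1L))
        datatype <- 2L; bitpix <- 8L; size <- 1L; what <- "integer"
        tr <- 1
    } else if (is(x, "TimeSeriesVolume")) {
        data <- x@data; datatype <- 64L; bitpix <- 64L; size <- 8L
        what <- "double"; tr <- x@trSeconds
    } else if (is(x, "AlffMap") || is(x, "PairedTMap")) {
        data <- array(x@values, dim = c(dim(x@values), 1L))
        datatype <- 64L; bitpix <- 64L; size <- 8L; what <- "double"; tr <- 1
    } else stop("cannot write object of class ", class(x), " as NIfTI")
    grid <- volumeGrid(x)
    shape <- dim(data)[1:3]
    nt <- dim(data)[4L]
    ndim <- if (nt > 1L) 4L else 3L

    con <- .openMaybeGz(path, "wb")
    on.exit(close(con))
    w <- function(v, size, what = "integer")
        writeBin(if (what == "integer") as.integer(v) else as.double(v),
                 con, size = size, endian = "little")
    w(348L, 4L)                                     # sizeof_hdr
    writeBin(raw(36L), con)                         # data_type..dim_info
    w(c(ndim, shape, nt, 1L, 1L, 1L), 2L)           # dim[8]
    writeBin(raw(14L), con)                         # intent_p1..intent_code
    w(datatype, 2L); w(bitpix, 2L); w(0L, 2L)       # datatype bitpix slice_start
    w(c(1, grid@voxelSize, tr, 0, 0, 0), 4L, "double")  # pixdim[8]
    w(352, 4L, "double")                            # vox_offset
    w(1, 4L, "double"); w(0, 4L, "double")          # scl_slope scl_inter
    writeBin(raw(2L + 1L + 1L), con)                # slice_end slice_code xyzt_units
    w(c(0, 0, 0, 0), 4L, "double")                  # cal_max cal_min slice_dur toffset
    w(c(0L, 0L), 4L)                                # glmax glmin
    writeBin(raw(80L + 24L), con)                   # descrip aux_file
    w(c(0L, 1L), 2L)                                # qform_code sform_code
    w(c(0, 0, 0, grid@affine[1:3, 4L]), 4L, "double")   # quaternions + offsets
    w(t(grid@affine[1:3, ]), 4L, "double")          # srow_x/y/z
    writeBin(raw(16L), con)                         # intent_name
    writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
    w(0, 4L, "double")                              # extension pad to 352
    writeBin(if (what == "integer") as.integer(data) else as.double(data),
             con, size = size, endian = "little")
    invisible(path)
}
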