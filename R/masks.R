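#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a VolumeGrid
#'
#' Builds a grid of \code{shape} voxels of size \code{voxelSize} mm.  If no
#' affine is given, the grid is centered on the world (MNI) origin with
#' axis-aligned voxels, i.e. the central voxel sits at (0, 0, 0) mm.  The
#' affine maps 0-based voxel indices to mm; all user-facing voxel indices
#' in this package are 1-based R indices and are shifted internally.
#'
#' @param shape integer(3), voxels per axis.
#' @param voxelSize numeric(3) or scalar, mm per voxel (default 3 mm
#'   isotropic).
#' @param affine optional 4x4 voxel-to-mm matrix.
#' @return a \linkS4class{VolumeGrid}.
#' @examples
#' g <- volumeGridCreate(c(61, 73, 61))
#' voxelToMm(g, matrix(c(31, 37, 31), 1))   # the central voxel, at origin
#' @export
volumeGridCreate <- function(shape, voxelSize = c(3, 3, 3), affine = NULL) {
    shape <- as.integer(shape)
    if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
    if (is.null(affine)) {
        affine <- diag(c(voxelSize, 1))
        affine[1:3, 4L] <- -voxelSize * (shape - 1L) / 2
    }
    new("VolumeGrid", shape = shape, voxelSize = as.numeric(voxelSize),
        affine = affine)
}

#' Voxel/world coordinate conversion
#'
#' @param grid a \linkS4class{VolumeGrid}.
#' @param ijk n x 3 matrix (or length-3 vector) of 1-based voxel indices.
#' @param xyz n x 3 matrix (or length-3 vector) of mm coordinates.
#' @return \code{voxelToMm}: n x 3 matrix of mm coordinates of the voxel
#'   centers; \code{mmToVoxel}: n x 3 matrix of (fractional) 1-based voxel
#'   indices.
#' @export
voxelToMm <- function(grid, ijk) {
    ijk <- rbind(ijk)
    t(grid@affine[1:3, 1:3] %*% t(ijk - 1) + grid@affine[1:3, 4L])
}

#' @rdname voxelToMm
#' @export
mmToVoxel <- function(grid, xyz) {
    xyz <- rbind(xyz)
    inv <- solve(grid@affine)
    t(inv[1:3, 1:3] %*% t(xyz) + inv[1:3, 4L]) + 1
}

#' Create a TimeSeriesVolume from an array
#'
#' @param data 3D or 4D numeric array.
#' @param grid a \linkS4class{VolumeGrid}; defaults to an origin-centered
#'   3 mm grid of matching shape.
#' @param trSeconds repetition time in seconds (default 2).
#' @return a \linkS4class{TimeSeriesVolume}.
#' @export
timeSeriesVolume <- function(data, grid = NULL, trSeconds = 2) {
    if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
    if (is.null(grid)) grid <- volumeGridCreate(dim(data)[1:3])
    new("TimeSeriesVolume", grid = grid, data = data, trSeconds = trSeconds)
}

#' Create a BinaryMask from a logical array
#'
#' @param members logical 3D array (or numeric, nonzero = member).
#' @param grid matching \linkS4class{VolumeGrid} (defaults to an
#'   origin-centered 3 mm grid).
#' @return a \linkS4class{BinaryMask}.
#' @export
binaryMask <- function(members, grid = NULL) {
    members <- array(as.logical(members != 0), dim = dim(members))
    if (is.null(grid)) grid <- volumeGridCreate(dim(members))
    new("BinaryMask", grid = grid, members = members)
}

#' Discard initial volumes
#'
#' Drops the first \code{n} time points of a 4D series (signal
#' equilibration scans), the standard first preprocessing step.
#'
#' @param vol a \linkS4class{TimeSeriesVolume}.
#' @param n number of leading volumes to discard (default 10).
#' @return the shortened \linkS4class{TimeSeriesVolume}.
#' @examples
#' v <- timeSeriesVolume(array(rnorm(2 * 2 * 2 * 240), c(2, 2, 2, 240)))
#' nTimepoints(discardInitialVolumes(v))   # 230
#' @export
discardInitialVolumes <- function(vol, n = 10L) {
    nt <- dim(vol@data)[4L]
    if (n < 0L) stop("n must be >= 0")
    if (n >= nt)
        stop(errorCondition(
            sprintf("cannot discard %d of %d volumes", n, nt),
            class = "volumeLengthError"))
    if (n == 0L) return(vol)
    new("TimeSeriesVolume", grid = vol@grid,
        data = vol@data[, , , (n + 1L):nt, drop = FALSE],
        trSeconds = vol@trSeconds)
}

# mm coordinates of every voxel center, as an N x 3 matrix (raster order)
.allVoxelMm <- function(grid) {
    s <- grid@shape
    ijk <- as.matrix(expand.grid(seq_len(s[1L]), seq_len(s[2L]), seq_len(s[3L])))
    voxelToMm(grid, ijk)
}

#' Build the two-sphere eyeball mask
#'
#' Marks every voxel whose center lies within \code{radiusMm} of either
#' eyeball center (MNI mm, defaults x = -36/+36, y = 60, z = -40).  The
#' spheres are generated analytically from the printed centers rather than
#' from an atlas tool.
#'
#' @param grid a \linkS4class{VolumeGrid} covering the centers.
#' @param centersMm 2 x 3 matrix of sphere centers in mm.
#' @param radiusMm sphere radius in mm (default 20).
#' @return a \linkS4class{BinaryMask}.
#' @export
buildEyeballMask <- function(grid,
                             centersMm = rbind(c(-36, 60, -40), c(36, 60, -40)),
                             radiusMm = 20) {
    mm <- .allVoxelMm(grid)
    member <- rep(FALSE, nrow(mm))
    for (i in seq_len(nrow(centersMm))) {
        d2 <- (mm[, 1L] - centersMm[i, 1L])^2 + (mm[, 2L] - centersMm[i, 2L])^2 +
              (mm[, 3L] - centersMm[i, 3L])^2
        member <- member | d2 <= radiusMm^2 + 1e-9
    }
    if (!any(member))
        stop(errorCondition("grid does not cover the eyeball centers; mask would be empty",
                            class = "emptyMaskError"))
    new("BinaryMask", grid = grid,
        members = array(member, dim = grid@shape))
}

#' Union of two masks
#'
#' @param brain,eyeballs \linkS4class{BinaryMask}s on the same grid.
#' @return the union \linkS4class{BinaryMask}.
#' @export
combineMasks <- function(brain, eyeballs) {
    if (!isTRUE(all.equal(brain@grid@affine, eyeballs@grid@affine)) ||
        !all(brain@grid@shape == eyeballs@grid@shape))
        stop(errorCondition("masks are on different grids",
                            class = "gridMismatchError"))
    new("BinaryMask", grid = brain@grid,
        members = brain@members | eyeballs@members)
}

#' Spherical ROI around a voxel
#'
#' Returns the voxels whose centers lie within \code{radiusMm} (inclusive)
#' of the center voxel's center, intersected with the mask.  On a 3 mm
#' isotropic grid an interior 5 mm ROI contains exactly 19 voxels.
#' ROIs truncated by the mask are kept, with a warning.
#'
#' @param centerVoxel length-3 vector of 1-based voxel indices.
#' @param radiusMm ROI radius in mm (default 5).
#' @param grid a \linkS4class{VolumeGrid}.
#' @param mask optional \linkS4class{BinaryMask} to intersect with.
#' @return integer n x 3 matrix of member voxel indices, in raster
#'   (ascending linear index) order.
#' @examples
#' g <- volumeGridCreate(c(11, 11, 11))
#' nrow(sphericalRoi(c(6, 6, 6), 5, g))   # 19
#' @export
sphericalRoi <- function(centerVoxel, radiusMm = 5, grid, mask = NULL) {
    if (any(centerVoxel < 1L) || any(centerVoxel > grid@shape))
        stop(errorCondition("ROI center outside the grid",
                            class = "roiCenterError"))
    # candidate offsets within radius along each axis (voxel units)
    ro <- ceiling(radiusMm / grid@voxelSize)
    off <- as.matrix(expand.grid(-ro[1L]:ro[1L], -ro[2L]:ro[2L], -ro[3L]:ro[3L]))
    cand <- sweep(off, 2L, as.numeric(centerVoxel), `+`)
    keep <- cand[, 1L] >= 1 & cand[, 1L] <= grid@shape[1L] &
            cand[, 2L] >= 1 & cand[, 2L] <= grid@shape[2L] &
            cand[, 3L] >= 1 & cand[, 3L] <= grid@shape[3L]
    cand <- cand[keep, , drop = FALSE]
    cmm <- voxelToMm(grid, matrix(centerVoxel, 1L))
    mm <- voxelToMm(grid, cand)
    d2 <- rowSums(sweep(mm, 2L, as.numeric(cmm), `-`)^2)
    roi <- cand[d2 <= radiusMm^2 + 1e-9, , drop = FALSE]
    if (!is.null(mask)) {
        if (!mask@members[matrix(as.integer(centerVoxel), 1L)])
            warning(warningCondition("ROI center lies outside the mask; ROI may be truncated",
                                     class = "roiOutsideMaskWarning"))
        inMask <- mask@members[roi]
        if (!all(inMask))
            roi <- roi[inMask, , drop = FALSE]
    }
    storage.mode(roi) <- "integer"
    ord <- order(roi[, 3L], roi[, 2L], roi[, 1L])   # ascending linear index
    roi[ord, , drop = FALSE]
}
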