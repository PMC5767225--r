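#' @include AllClasses.R
NULL

# 1D Gaussian convolution matrix (n x n, zero padded at the edges),
# sigma in voxel units, kernel truncated at ceiling(3.5 sigma)
.gaussMat <- function(n, sigma) {
    if (sigma <= 0) return(diag(n))
    r <- max(1L, ceiling(3.5 * sigma))
    k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
    k <- k / sum(k)
    m <- matrix(0, n, n)
    for (o in seq(-r, r)) {
        idx <- seq_len(n)
        src <- idx + o
        ok <- src >= 1L & src <= n
        m[cbind(idx[ok], src[ok])] <- m[cbind(idx[ok], src[ok])] + k[o + r + 1L]
    }
    m
}

#' Gaussian spatial smoothing
#'
#' Separable 3D Gaussian smoothing with the given full width at half
#' maximum, applied to a 3D array or independently to every time point of
#' a 4D array.  Zero padding at the grid edges.
#'
#' @param x numeric 3D or 4D array.
#' @param fwhmMm full width at half maximum in mm (0 = no smoothing).
#' @param voxelSize numeric(3) voxel size in mm.
#' @return the smoothed array, same shape.
#' @export
gaussianSmooth <- function(x, fwhmMm, voxelSize = c(3, 3, 3)) {
    if (fwhmMm <= 0) return(x)
    d <- dim(x)
    sigma <- fwhmMm / (2 * sqrt(2 * log(2))) / voxelSize
    s1 <- .gaussMat(d[1L], sigma[1L])
    s2 <- .gaussMat(d[2L], sigma[2L])
    s3 <- .gaussMat(d[3L], sigma[3L])
    rest <- if (length(d) == 4L) d[4L] else 1L
    dim(x) <- c(d[1L], prod(d[-1L]))
    x <- s1 %*% x                                   # axis 1
    dim(x) <- c(d[1L], d[2L], d[3L] * rest)
    x <- aperm(x, c(2L, 1L, 3L))
    dim(x) <- c(d[2L], d[1L] * d[3L] * rest)
    x <- s2 %*% x                                   # axis 2
    dim(x) <- c(d[2L], d[1L], d[3L], rest)
    x <- aperm(x, c(3L, 2L, 1L, 4L))
    dim(x) <- c(d[3L], d[1L] * d[2L] * rest)
    x <- s3 %*% x                                   # axis 3
    dim(x) <- c(d[3L], d[1L], d[2L], rest)
    x <- aperm(x, c(2L, 3L, 1L, 4L))
    dim(x) <- d
    x
}
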