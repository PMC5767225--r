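#' @import methods
NULL

#' VolumeGrid: voxel geometry of a 3D sampling grid
#'
#' Describes the geometry shared by all volumes in an analysis: the grid
#' shape in voxels, the voxel size in mm, and the 4x4 affine mapping
#' 0-based voxel indices to world (MNI) mm coordinates.  The affine is
#' authoritative; no storage-order assumption is made.
#'
#' @slot shape integer(3), grid extent in voxels per axis.
#' @slot voxelSize numeric(3), mm per voxel along each axis.
#' @slot affine 4x4 numeric matrix, voxel (0-based) to mm.
#' @export
setClass("VolumeGrid",
    representation(shape = "integer", voxelSize = "numeric", affine = "matrix"),
    validity = function(object) {
        msg <- character()
        if (length(object@shape) != 3L || any(object@shape < 1L))
            msg <- c(msg, "shape must be 3 positive integers")
        if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
            msg <- c(msg, "voxelSize must be 3 strictly positive values")
        if (!all(dim(object@affine) == c(4L, 4L)))
            msg <- c(msg, "affine must be a 4x4 matrix")
        else if (abs(det(object@affine)) < 1e-12)
            msg <- c(msg, "affine must be invertible")
        if (length(msg)) msg else TRUE
    })

#' TimeSeriesVolume: a 4D BOLD-like voxel time series
#'
#' @slot grid a \linkS4class{VolumeGrid}.
#' @slot data 4D numeric array (x, y, z, time).
#' @slot trSeconds repetition time (sampling interval) in seconds.
#' @export
setClass("TimeSeriesVolume",
    representation(grid = "VolumeGrid", data = "array", trSeconds = "numeric"),
    validity = function(object) {
        msg <- character()
        d <- dim(object@data)
        if (length(d) != 4L)
            msg <- c(msg, "data must be a 4D array (x, y, z, time)")
        else if (!all(d[1:3] == object@grid@shape))
            msg <- c(msg, "spatial dimensions must match the grid shape")
        if (length(object@trSeconds) != 1L || object@trSeconds <= 0)
            msg <- c(msg, "trSeconds must be a single positive number")
        if (anyNA(object@data) || any(!is.finite(object@data)))
            msg <- c(msg, "data must be finite (no NA/NaN/Inf)")
        if (length(msg)) msg else TRUE
    })

#' BinaryMask: voxel membership flags on a grid
#'
#' @slot grid a \linkS4class{VolumeGrid}.
#' @slot members logical 3D array, TRUE for voxels inside the mask.
#' @export
setClass("BinaryMask",
    representation(grid = "VolumeGrid", members = "array"),
    validity = function(object) {
        msg <- character()
        if (!is.logical(object@members))
            msg <- c(msg, "members must be a logical array")
        if (!all(dim(object@members) == object@grid@shape))
            msg <- c(msg, "members dimensions must match the grid shape")
        if (!any(object@members))
            msg <- c(msg, "mask must contain at least one voxel")
        if (length(msg)) msg else TRUE
    })

#' FrequencyBand: a closed frequency interval in Hz
#'
#' Band membership everywhere in the package is the closed interval
#' \code{lowHz <= f <= highHz}; touching edges of adjacent slow bands share
#' at most one frequency bin.
#'
#' @slot name band label, e.g. "conventional" or "slow4".
#' @slot lowHz,highHz band edges in Hz, 0 <= lowHz < highHz.
#' @export
setClass("FrequencyBand",
    representation(name = "character", lowHz = "numeric", highHz = "numeric"),
    validity = function(object) {
        msg <- character()
        if (object@lowHz < 0) msg <- c(msg, "lowHz must be >= 0")
        if (object@lowHz >= object@highHz) msg <- c(msg, "lowHz must be < highHz")
        if (length(msg)) msg else TRUE
    })

#' AlffMap: per-voxel band amplitude (ALFF or mALFF)
#'
#' Values are the mean square-rooted spectral power over the band's
#' frequency bins; zero outside the analysis mask.  When \code{normalized}
#' is TRUE the map has been divided by its mean over the mask (mALFF) and
#' that mean is 1.
#'
#' @slot grid a \linkS4class{VolumeGrid}.
#' @slot values numeric 3D array of amplitudes.
#' @slot band the \linkS4class{FrequencyBand} the map was computed in.
#' @slot normalized logical flag, TRUE for mALFF.
#' @export
setClass("AlffMap",
    representation(grid = "VolumeGrid", values = "array",
                   band = "FrequencyBand", normalized = "logical"),
    validity = function(object) {
        msg <- character()
        if (!all(dim(object@values) == object@grid@shape))
            msg <- c(msg, "values dimensions must match the grid shape")
        if (length(msg)) msg else TRUE
    })

#' PairedTMap: voxel-wise paired t statistics
#'
#' @slot grid a \linkS4class{VolumeGrid}.
#' @slot values numeric 3D array of t values (0 outside the mask).
#' @slot df degrees of freedom, m - 1 for m subjects.
#' @export
setClass("PairedTMap",
    representation(grid = "VolumeGrid", values = "array", df = "numeric"),
    validity = function(object) {
        msg <- character()
        if (!all(dim(object@values) == object@grid@shape))
            msg <- c(msg, "values dimensions must match the grid shape")
        if (object@df < 1) msg <- c(msg, "df must be >= 1")
        if (any(!is.finite(object@values)))
            msg <- c(msg, "t values must be finite")
        if (length(msg)) msg else TRUE
    })

#' ClusterSet: supra-threshold connected clusters of a paired-t map
#'
#' Positive and negative supra-threshold voxels are labeled separately by
#' 26-connectivity; clusters are ordered by descending extent, then
#' descending |peak t|.  \code{labels} assigns each member voxel its
#' 1-based cluster index (0 elsewhere).
#'
#' @slot grid a \linkS4class{VolumeGrid}.
#' @slot labels integer 3D array of cluster indices.
#' @slot table data.frame with one row per cluster: clusterIndex, sign,
#'   extentVoxels, extentMm3, peak voxel indices (1-based), peak MNI mm
#'   coordinates, peakT and roiMeanT (mean t over the 5 mm spherical ROI
#'   at the peak).
#' @slot tCrit,minExtent thresholds the set was built with.
#' @export
setClass("ClusterSet",
    representation(grid = "VolumeGrid", labels = "array", table = "data.frame",
                   tCrit = "numeric", minExtent = "numeric"))

#' FeatureSpec: feature locations selected from a cluster set
#'
#' Holds, per cluster, the peak voxel and its 5 mm spherical ROI, and the
#' extraction method: \code{"peak"} (ALFF at the peak voxel), \code{"mean"}
#' (mean ALFF over the ROI) or \code{"all"} (ALFF of every ROI voxel).
#' Feature dimensionality is k for peak/mean and sum of ROI sizes
#' (19 per interior cluster on a 3 mm grid) for all.
#'
#' @slot method one of "peak", "mean", "all".
#' @slot band the band the clusters came from.
#' @slot peaks k x 3 integer matrix of 1-based peak voxel indices.
#' @slot peakMm k x 3 matrix of peak MNI mm coordinates.
#' @slot rois list of k integer matrices of ROI voxel indices (raster order).
#' @slot featureIds character vector naming each feature column.
#' @slot grid the source grid.
#' @slot sourceDataset identifier of the dataset the spec was built from.
#' @export
setClass("FeatureSpec",
    representation(method = "character", band = "FrequencyBand",
                   peaks = "matrix", peakMm = "matrix", rois = "list",
                   featureIds = "character", grid = "VolumeGrid",
                   sourceDataset = "character"),
    validity = function(object) {
        msg <- character()
        if (!object@method %in% c("peak", "mean", "all"))
            msg <- c(msg, "method must be one of 'peak', 'mean', 'all'")
        if (nrow(object@peaks) != length(object@rois))
            msg <- c(msg, "one ROI per peak required")
        if (length(msg)) msg else TRUE
    })

#' FeatureMatrix: a labeled samples-by-features matrix
#'
#' Under the \code{"pair"} scheme rows are signed within-subject difference
#' maps: label -1 marks an EC-EO sample, +1 an EO-EC sample, and there are
#' m rows for m subjects.  Under \code{"unpair"} the conditions are stacked
#' as independent classes: 2m rows, EC labeled -1 and EO labeled +1.
#'
#' @slot X numeric matrix, samples x features.
#' @slot y numeric vector of labels in {-1, +1}.
#' @slot sampleIds character vector identifying each row.
#' @slot featureIds character vector identifying each column.
#' @slot scheme "pair" or "unpair".
#' @export
setClass("FeatureMatrix",
    representation(X = "matrix", y = "numeric", sampleIds = "character",
                   featureIds = "character", scheme = "character"),
    validity = function(object) {
        msg <- character()
        if (nrow(object@X) != length(object@y))
            msg <- c(msg, "rows of X must match length of y")
        if (!all(object@y %in% c(-1, 1)))
            msg <- c(msg, "labels must be -1 or +1")
        if (!object@scheme %in% c("pair", "unpair"))
            msg <- c(msg, "scheme must be 'pair' or 'unpair'")
        if (length(msg)) msg else TRUE
    })

#' LinearSvmModel: a trained linear soft-margin SVM
#'
#' The separating hyperplane sign(W'x + b) minimizing
#' (1/2)||W||^2 + (C/2) sum xi_i^2 subject to y_i (W'x_i + b) + xi_i >= 1
#' (L2-regularized squared hinge loss, unregularized bias).
#'
#' @slot weights per-feature weight vector W.
#' @slot bias scalar bias b.
#' @slot cost the soft-margin hyperparameter C.
#' @slot featureIds feature names matching a FeatureSpec.
#' @export
setClass("LinearSvmModel",
    representation(weights = "numeric", bias = "numeric", cost = "numeric",
                   featureIds = "character"),
    validity = function(object) {
        msg <- character()
        if (any(!is.finite(object@weights)) || !is.finite(object@bias))
            msg <- c(msg, "weights and bias must be finite")
        if (length(msg)) msg else TRUE
    })

#' EvaluationResult: accuracy of one classification evaluation
#'
#' @slot scheme "pair" or "unpair".
#' @slot method feature method ("peak", "mean", "all").
#' @slot band band name.
#' @slot accuracy fraction of correctly classified samples in [0, 1].
#' @slot correct logical per-sample correctness flags.
#' @slot model the model trained on all samples (for cross-dataset use).
#' @export
setClass("EvaluationResult",
    representation(scheme = "character", method = "character",
                   band = "character", accuracy = "numeric",
                   correct = "logical", model = "LinearSvmModel"),
    validity = function(object) {
        msg <- character()
        if (object@accuracy < 0 || object@accuracy > 1)
            msg <- c(msg, "accuracy must be in [0, 1]")
        if (length(object@correct) &&
            abs(mean(object@correct) - object@accuracy) > 1e-12)
            msg <- c(msg, "per-sample flags must average to accuracy")
        if (length(msg)) msg else TRUE
    })

#' SyntheticConfig: parameters of the paired-fMRI generator
#'
#' Defaults describe a small but realistic paired resting-state experiment:
#' a 24^3 grid of 3 mm voxels, TR 2 s, 240 time points (the first 10 to be
#' discarded downstream), 20 subjects, moderate multiplicative
#' between-subject variability and 6 mm spatial smoothing, with three
#' planted band-limited amplitude effects (a sensorimotor-like blob higher
#' in EC, an occipital-like blob higher in EO, and an eyeball-like sphere
#' with a high-band EO effect).
#'
#' @slot shape integer(3) grid shape.
#' @slot voxelSize numeric(3) voxel size in mm.
#' @slot trSeconds repetition time in seconds.
#' @slot nTimepoints time series length before discarding.
#' @slot nSubjects number m of paired subjects (m >= 4).
#' @slot regions list of planted regions; each a list with fields
#'   \code{center} (1-based voxel triple), \code{radiusMm}, \code{band}
#'   (a FrequencyBand), \code{favored} ("EC" or "EO") and \code{effect}
#'   (relative in-band amplitude boost in the favored condition).
#' @slot subjectSd SD of the log multiplicative subject baseline
#'   (applied both as a global gain and as a smooth spatial gain field,
#'   shared between a subject's two conditions).
#' @slot inbandAmp per-bin amplitude of the band-limited signal floor.
#' @slot noiseSd SD of the broadband Gaussian noise.
#' @slot driftSd SD of the per-voxel linear drift (total excursion units).
#' @slot fwhmMm spatial smoothing FWHM in mm.
#' @slot siteShiftSd log-SD of between-site amplitude/noise level shifts
#'   used by \code{\link{makeSitePair}}.
#' @slot seed RNG seed.
#' @export
setClass("SyntheticConfig",
    representation(shape = "integer", voxelSize = "numeric",
                   trSeconds = "numeric", nTimepoints = "integer",
                   nSubjects = "integer", regions = "list",
                   subjectSd = "numeric", inbandAmp = "numeric",
                   noiseSd = "numeric", driftSd = "numeric",
                   fwhmMm = "numeric", siteShiftSd = "numeric",
                   seed = "integer"),
    validity = function(object) {
        msg <- character()
        if (object@nSubjects < 4L) msg <- c(msg, "nSubjects must be >= 4")
        if (object@nTimepoints < 4L) msg <- c(msg, "nTimepoints must be >= 4")
        for (r in object@regions)
            if (r$effect < 0) msg <- c(msg, "region effects must be >= 0")
        if (length(msg)) msg else TRUE
    })

#' PairedFmriDataset: one synthetic (or loaded) paired-condition dataset
#'
#' @slot volumesEC,volumesEO per-subject lists of
#'   \linkS4class{TimeSeriesVolume}, subject-aligned.
#' @slot mask the analysis \linkS4class{BinaryMask}.
#' @slot truth list of ground-truth planted regions (possibly empty), each
#'   with \code{voxels} (index matrix), \code{favored}, \code{effect},
#'   \code{band}.
#' @slot name dataset identifier.
#' @export
setClass("PairedFmriDataset",
    representation(volumesEC = "list", volumesEO = "list",
                   mask = "BinaryMask", truth = "list", name = "character"),
    validity = function(object) {
        if (length(object@volumesEC) != length(object@volumesEO))
            "EC and EO subject lists must have equal length" else TRUE
    })
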