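#' @include AllClasses.R
NULL

#' Grid accessors
#'
#' @param x an object carrying a \linkS4class{VolumeGrid}.
#' @return \code{volumeGrid} returns the grid; \code{gridShape} its voxel
#'   extent; \code{voxelSize} the voxel size in mm; \code{affine} the 4x4
#'   voxel-to-mm matrix.
#' @export
setGeneric("volumeGrid", function(x) standardGeneric("volumeGrid"))

#' @rdname volumeGrid
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))

#' @rdname volumeGrid
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname volumeGrid
#' @export
setGeneric("affine", function(x) standardGeneric("affine"))

#' @rdname volumeGrid
#' @export
setMethod("volumeGrid", "VolumeGrid", function(x) x)

for (.cls in c("TimeSeriesVolume", "BinaryMask", "AlffMap", "PairedTMap",
               "ClusterSet", "FeatureSpec"))
    setMethod("volumeGrid", .cls, function(x) x@grid)

#' @rdname volumeGrid
#' @export
setMethod("gridShape", "ANY", function(x) volumeGrid(x)@shape)

#' @rdname volumeGrid
#' @export
setMethod("voxelSize", "ANY", function(x) volumeGrid(x)@voxelSize)

#' @rdname volumeGrid
#' @export
setMethod("affine", "ANY", function(x) volumeGrid(x)@affine)

#' Value accessors
#'
#' @param x a package object.
#' @return \code{mapValues} returns the 3D value array of a map;
#'   \code{maskMembers} the logical membership array of a mask;
#'   \code{trSeconds} the repetition time; \code{nTimepoints} the time
#'   dimension; \code{degreesOfFreedom} the t-map df.
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @rdname mapValues
#' @export
setMethod("mapValues", "AlffMap", function(x) x@values)

#' @rdname mapValues
#' @export
setMethod("mapValues", "PairedTMap", function(x) x@values)

#' @rdname mapValues
#' @export
setGeneric("maskMembers", function(x) standardGeneric("maskMembers"))

#' @rdname mapValues
#' @export
setMethod("maskMembers", "BinaryMask", function(x) x@members)

#' @rdname mapValues
#' @export
setGeneric("trSeconds", function(x) standardGeneric("trSeconds"))

#' @rdname mapValues
#' @export
setMethod("trSeconds", "TimeSeriesVolume", function(x) x@trSeconds)

#' @rdname mapValues
#' @export
setGeneric("nTimepoints", function(x) standardGeneric("nTimepoints"))

#' @rdname mapValues
#' @export
setMethod("nTimepoints", "TimeSeriesVolume", function(x) dim(x@data)[4L])

#' @rdname mapValues
#' @export
setGeneric("degreesOfFreedom", function(x) standardGeneric("degreesOfFreedom"))

#' @rdname mapValues
#' @export
setMethod("degreesOfFreedom", "PairedTMap", function(x) x@df)

#' Cluster accessors
#'
#' @param x a \linkS4class{ClusterSet}.
#' @return \code{clusterTable} the per-cluster summary data.frame;
#'   \code{nClusters} the number of clusters; \code{clusterLabels} the
#'   3D integer label array.
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))

#' @rdname clusterTable
#' @export
setMethod("clusterTable", "ClusterSet", function(x) x@table)

#' @rdname clusterTable
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname clusterTable
#' @export
setMethod("nClusters", "ClusterSet", function(x) nrow(x@table))

#' @rdname clusterTable
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname clusterTable
#' @export
setMethod("clusterLabels", "ClusterSet", function(x) x@labels)

#' Model and feature accessors
#'
#' @param x a \linkS4class{LinearSvmModel}, \linkS4class{FeatureMatrix},
#'   \linkS4class{FeatureSpec} or \linkS4class{EvaluationResult}.
#' @return \code{weights}: the SVM weight vector W; \code{bias}: the bias
#'   b; \code{featureIds}: feature names; \code{featureValues}: the X
#'   matrix; \code{sampleLabels}: the label vector y; \code{accuracy}: the
#'   fraction correct.
#' @export
setGeneric("weights", function(x) standardGeneric("weights"))

#' @rdname weights
#' @export
setMethod("weights", "LinearSvmModel", function(x) x@weights)

#' @rdname weights
#' @export
setGeneric("bias", function(x) standardGeneric("bias"))

#' @rdname weights
#' @export
setMethod("bias", "LinearSvmModel", function(x) x@bias)

#' @rdname weights
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname weights
#' @export
setMethod("featureIds", "LinearSvmModel", function(x) x@featureIds)

#' @rdname weights
#' @export
setMethod("featureIds", "FeatureMatrix", function(x) x@featureIds)

#' @rdname weights
#' @export
setMethod("featureIds", "FeatureSpec", function(x) x@featureIds)

#' @rdname weights
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname weights
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@X)

#' @rdname weights
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' @rdname weights
#' @export
setMethod("sampleLabels", "FeatureMatrix", function(x) x@y)

#' @rdname weights
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

#' @rdname weights
#' @export
setMethod("accuracy", "EvaluationResult", function(x) x@accuracy)

#' @rdname weights
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' @rdname weights
#' @export
setMethod("nSubjects", "PairedFmriDataset", function(x) length(x@volumesEC))

setMethod("show", "VolumeGrid", function(object) {
    cat("VolumeGrid:", paste(object@shape, collapse = " x "),
        "voxels,", paste(object@voxelSize, collapse = " x "), "mm\n")
})

setMethod("show", "TimeSeriesVolume", function(object) {
    d <- dim(object@data)
    cat("TimeSeriesVolume:", paste(d[1:3], collapse = " x "), "voxels,",
        d[4L], "time points, TR =", object@trSeconds, "s\n")
})

setMethod("show", "BinaryMask", function(object) {
    cat("BinaryMask:", sum(object@members), "of",
        prod(object@grid@shape), "voxels\n")
})

setMethod("show", "AlffMap", function(object) {
    cat(if (object@normalized) "mALFF" else "ALFF", "map, band",
        sprintf("%s [%.3f, %.3f] Hz,", object@band@name,
                object@band@lowHz, object@band@highHz),
        paste(object@grid@shape, collapse = " x "), "voxels\n")
})

setMethod("show", "PairedTMap", function(object) {
    cat("PairedTMap: df =", object@df, ", |t| range [",
        sprintf("%.3f, %.3f", min(abs(object@values[object@values != 0]), 0),
                max(abs(object@values))), "]\n")
})

setMethod("show", "ClusterSet", function(object) {
    cat("ClusterSet:", nrow(object@table), "clusters (|t| >=",
        sprintf("%.3f", object@tCrit), ", extent >=", object@minExtent,
        "voxels)\n")
    if (nrow(object@table)) print(utils::head(object@table, 10L))
})

setMethod("show", "FeatureSpec", function(object) {
    cat("FeatureSpec:", object@method, "features from",
        nrow(object@peaks), "clusters, band", object@band@name,
        ", dim =", length(object@featureIds), "\n")
})

setMethod("show", "FeatureMatrix", function(object) {
    cat("FeatureMatrix (", object@scheme, "): ", nrow(object@X),
        " samples x ", ncol(object@X), " features\n", sep = "")
})

setMethod("show", "LinearSvmModel", function(object) {
    cat("LinearSvmModel: ", length(object@weights),
        " features, C = ", object@cost,
        ", b = ", sprintf("%.4f", object@bias), "\n", sep = "")
})

setMethod("show", "EvaluationResult", function(object) {
    cat(sprintf("EvaluationResult: %s/%s/%s accuracy %.2f%% (%d samples)\n",
                object@scheme, object@method, object@band,
                100 * object@accuracy, length(object@correct)))
})

setMethod("show", "PairedFmriDataset", function(object) {
    cat("PairedFmriDataset '", object@name, "': ",
        length(object@volumesEC), " subjects x 2 conditions, ",
        sum(object@mask@members), " mask voxels, ",
        length(object@truth), " planted regions\n", sep = "")
})
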