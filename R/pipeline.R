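#' @include AllClasses.R AllGenerics.R alff.R paired-stats.R features.R classification.R synthetic.R
NULL

#' Per-band mALFF maps for a paired dataset
#'
#' Runs the per-subject ALFF stage: discard initial volumes, compute the
#' band ALFF map of every subject and condition, and normalize each by its
#' mask mean (mALFF).
#'
#' @param dataset a \linkS4class{PairedFmriDataset}.
#' @param band a \linkS4class{FrequencyBand}.
#' @param nDiscard initial volumes to discard (default 10).
#' @param normalize divide by the mask mean (default TRUE).
#' @return list with per-subject \code{mapsC} (EC) and \code{mapsO} (EO).
#' @export
datasetAlffMaps <- function(dataset, band, nDiscard = 10L, normalize = TRUE) {
    mk <- function(vol) {
        map <- alffMap(discardInitialVolumes(vol, nDiscard), dataset@mask, band)
        if (normalize) normalizeAlff(map, dataset@mask) else map
    }
    list(mapsC = lapply(dataset@volumesEC, mk),
         mapsO = lapply(dataset@volumesEO, mk))
}

.evalRow <- function(evaluation, dataset, band, method, scheme, res, k)
    data.frame(evaluation = evaluation, dataset = dataset, band = band,
               method = method, scheme = scheme,
               accuracy = res@accuracy, nCorrect = sum(res@correct),
               nSamples = length(res@correct), nFeatures = k,
               stringsAsFactors = FALSE)

#' Run the full experiment grid
#'
#' Config-driven reproduction of the whole analysis on one or two paired
#' datasets: per dataset and band, ALFF -> mALFF -> paired t -> cluster
#' extent correction -> feature spec -> features -> LOOCV for every
#' feature method and scheme; with two datasets also train-on-all plus
#' cross-application in both directions.  With two datasets, five bands,
#' three methods and two schemes the report has 5 x 3 x 2 x 4 = 120
#' accuracy cells.
#'
#' @param datasets list of one or two \linkS4class{PairedFmriDataset}s.
#' @param bands list of \linkS4class{FrequencyBand}s (default the five
#'   standard bands).
#' @param methods feature methods to run (default all three).
#' @param schemes classification schemes to run (default pair and unpair).
#' @param pVoxel voxel-wise p threshold (default 0.01).
#' @param extentVoxels cluster extent threshold in voxels; the default 47
#'   corresponds to 1269 mm^3 on a 3 mm grid.  Pass NULL to calibrate by
#'   Monte-Carlo simulation instead.
#' @param mcIter,mcAlpha,mcFwhm Monte-Carlo settings used when
#'   \code{extentVoxels} is NULL.
#' @param nDiscard initial volumes to discard (default 10).
#' @param cost SVM soft-margin C (default 1).
#' @param seed base seed for all sign vectors.
#' @return a list of class \code{"pairExperimentReport"}: \code{accuracy}
#'   (one row per cell), \code{clusters} and \code{specs} (per dataset and
#'   band), \code{weights} (per-region weight tables for mean features),
#'   and \code{log} (every seed and threshold used).
#' @export
runExperiment <- function(datasets, bands = standardBands(),
                          methods = c("peak", "mean", "all"),
                          schemes = c("pair", "unpair"),
                          pVoxel = 0.01, extentVoxels = 47L,
                          mcIter = 1000L, mcAlpha = 0.01, mcFwhm = 6,
                          nDiscard = 10L, cost = 1, seed = 1L) {
    if (is(datasets, "PairedFmriDataset")) datasets <- list(datasets)
    nd <- length(datasets)
    stopifnot(nd >= 1L, nd <= 2L)
    dnames <- vapply(datasets, function(d) d@name, character(1L))
    if (anyDuplicated(dnames)) dnames <- paste0(dnames, seq_len(nd))
    rows <- list(); clustersOut <- list(); specsOut <- list()
    weightsOut <- list()
    logLines <- c(sprintf("pVoxel=%g cost=%g seed=%d nDiscard=%d",
                          pVoxel, cost, seed, nDiscard))

    # per dataset and band: maps, t map, clusters, specs, features
    stage <- list()
    for (d in seq_len(nd)) {
        ds <- datasets[[d]]
        m <- nSubjects(ds)
        for (b in seq_along(bands)) {
            band <- bands[[b]]
            maps <- datasetAlffMaps(ds, band, nDiscard = nDiscard)
            tmap <- pairedTMap(maps$mapsC, maps$mapsO, ds@mask)
            tCrit <- voxelThresholdFromP(pVoxel, tmap@df)
            ext <- extentVoxels
            if (is.null(ext)) {
                ext <- monteCarloExtentThreshold(ds@mask, mcFwhm, pVoxel,
                                                 mcAlpha, mcIter,
                                                 seed = seed + 71L * d + b)
                logLines <- c(logLines,
                              sprintf("%s/%s: MC extent=%d", dnames[d],
                                      band@name, ext))
            }
            cl <- labelClusters(tmap, ds@mask, tCrit, ext)
            if (nClusters(cl) == 0L)
                stop(errorCondition(
                    sprintf("no clusters survive in %s band %s",
                            dnames[d], band@name),
                    class = "emptyClusterSetError"))
            clustersOut[[paste(dnames[d], band@name, sep = ".")]] <- cl
            a <- makeSignVector(m, seed + 13L * d)
            specs <- list(); feats <- list()
            for (method in methods) {
                sp <- buildFeatureSpec(cl, band, method, ds@mask,
                                       sourceDataset = dnames[d])
                cF <- extractColumns(maps$mapsC, sp)
                oF <- extractColumns(maps$mapsO, sp)
                specs[[method]] <- sp
                feats[[method]] <- list(
                    pair = pairTransform(cF, oF, a),
                    unpair = unpairStack(cF, oF))
            }
            specsOut[[paste(dnames[d], band@name, sep = ".")]] <- specs
            stage[[paste(d, b)]] <- list(d = d, b = b, maps = maps,
                                         clusters = cl, specs = specs,
                                         feats = feats)
            logLines <- c(logLines,
                          sprintf("%s/%s: tCrit=%.4f extent=%d K=%d signSeed=%d",
                                  dnames[d], band@name, tCrit, ext,
                                  nClusters(cl), seed + 13L * d))
        }
    }

    # LOOCV within datasets, cross-application across
    for (st in stage) {
        band <- bands[[st$b]]
        for (method in methods) for (scheme in schemes) {
            fm <- st$feats[[method]][[scheme]]
            res <- loocv(fm, C = cost)
            rows[[length(rows) + 1L]] <-
                .evalRow(sprintf("loocv_%s", dnames[st$d]), dnames[st$d],
                         band@name, method, scheme, res, ncol(fm@X))
            if (method == "mean" && scheme == "pair")
                weightsOut[[paste(dnames[st$d], band@name, sep = ".")]] <-
                    data.frame(clusterIndex = clusterTable(st$clusters)$clusterIndex,
                               roiMeanT = clusterTable(st$clusters)$roiMeanT,
                               weightLoocv = unname(res@model@weights))
            if (nd == 2L) {
                other <- stage[[paste(3L - st$d, st$b)]]
                tgt <- other$maps
                cres <- crossDatasetApply(res@model, st$specs[[method]],
                                          tgt$mapsC, tgt$mapsO, scheme,
                                          seed = seed + 29L * st$d)
                rows[[length(rows) + 1L]] <-
                    .evalRow(sprintf("cross_%s_to_%s", dnames[st$d],
                                     dnames[3L - st$d]),
                             dnames[st$d], band@name, method, scheme, cres,
                             ncol(fm@X))
            }
        }
    }
    report <- list(accuracy = do.call(rbind, rows), clusters = clustersOut,
                   specs = specsOut, weights = weightsOut, log = logLines)
    class(report) <- "pairExperimentReport"
    report
}

#' Aggregate an experiment report
#'
#' Mean accuracy over feature methods per band/scheme/evaluation, and mean
#' over bands per method/scheme/evaluation.
#'
#' @param report a report from \code{\link{runExperiment}}, or its
#'   \code{accuracy} data.frame.
#' @return list with data.frames \code{byBand} (methods averaged) and
#'   \code{byMethod} (bands averaged).
#' @export
summarizeReport <- function(report) {
    acc <- if (inherits(report, "pairExperimentReport")) report$accuracy
           else report
    if (is.null(acc) || !nrow(acc)) stop("empty report")
    byBand <- stats::aggregate(accuracy ~ evaluation + scheme + band,
                               data = acc, FUN = mean)
    byMethod <- stats::aggregate(accuracy ~ evaluation + scheme + method,
                                 data = acc, FUN = mean)
    list(byBand = byBand, byMethod = byMethod)
}

#' @export
print.pairExperimentReport <- function(x, ...) {
    cat("Paired-condition classification experiment report\n")
    acc <- x$accuracy
    acc$accuracy <- sprintf("%.2f%%", 100 * acc$accuracy)
    print(acc, row.names = FALSE)
    invisible(x)
}

#' Write report tables
#'
#' Writes the accuracy matrix, per-band cluster tables and per-band weight
#' tables as TSV, and feature specs as JSON, into a directory.
#'
#' @param report a report from \code{\link{runExperiment}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeReport <- function(report, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(report$accuracy, file.path(dir, "report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (nm in names(report$clusters))
        utils::write.table(clusterTable(report$clusters[[nm]]),
                           file.path(dir, sprintf("clusters_%s.tsv", nm)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    for (nm in names(report$weights))
        utils::write.table(report$weights[[nm]],
                           file.path(dir, sprintf("weights_%s.tsv", nm)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    for (nm in names(report$specs)) {
        sp <- report$specs[[nm]]$mean
        if (is.null(sp)) sp <- report$specs[[nm]][[1L]]
        jsonlite::write_json(
            list(method = sp@method, band = sp@band@name,
                 sourceDataset = sp@sourceDataset,
                 peaksMm = sp@peakMm, featureIds = sp@featureIds),
            file.path(dir, sprintf("spec_%s.json", nm)), auto_unbox = TRUE)
    }
    writeLines(report$log, file.path(dir, "log.txt"))
    invisible(dir)
}
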