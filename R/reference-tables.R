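#' @include AllClasses.R
NULL

#' Published region-level weight/t reference tables
#'
#' Region-level results transcribed from a published two-dataset
#' eyes-closed/eyes-open ALFF classification experiment (conventional
#' 0.01-0.08 Hz band, mean-ALFF features, PAIR scheme): per cluster, the
#' ROI mean paired-t value and the linear-SVM feature weight obtained by
#' LOOCV within each dataset and by cross-dataset application.  The
#' \code{"full"} variant has all 8 regions per dataset (16 rows); the
#' \code{"reduced"} variant repeats the analysis after eliminating the
#' lowest-|weight| feature of each dataset (an eyeball region in both),
#' leaving 14 rows.
#'
#' Useful as a reference input for \code{\link{weightTCorrelation}} and
#' for exercising \code{\link{dropFeature}}'s selection rule.
#'
#' @param variant "full" or "reduced".
#' @return data.frame with columns dataset, region, clusterIndex,
#'   roiMeanT, weightLoocv, weightCross.
#' @export
referenceRegionTable <- function(variant = c("full", "reduced")) {
    variant <- match.arg(variant)
    path <- system.file("extdata",
                        sprintf("region_weights_%s.tsv", variant),
                        package = "pairclass", mustWork = TRUE)
    utils::read.delim(path, stringsAsFactors = FALSE)
}
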