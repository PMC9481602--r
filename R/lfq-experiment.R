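#' @include utils.R
NULL

#' Label-free quantification experiment
#'
#' A \linkS4class{SummarizedExperiment} holding one \code{log2intensity}
#' assay (protein rows, sample columns, \code{NA} = not detected), a
#' \code{bait} and \code{replicate} column annotation, and per-protein
#' \code{reverse} / \code{contaminant} flags in \code{rowData}.
#'
#' @seealso \code{\link{loadAndFilterLFQ}}, \code{\link{imputeMissing}},
#'   \code{\link{anovaS0}}
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assay<- assayNames colData rowData
#'   rowData<- SummarizedExperiment
#' @importFrom S4Vectors DataFrame
#' @exportClass LFQExperiment
setClass("LFQExperiment", contains = "SummarizedExperiment")

setValidity("LFQExperiment", function(object) {
    if (!"log2intensity" %in% SummarizedExperiment::assayNames(object))
        return("assay 'log2intensity' is required")
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("bait", "replicate") %in% colnames(cd)))
        return("colData must have 'bait' and 'replicate'")
    if (any(is.na(cd$bait)))
        return("every sample needs a bait-group label")
    a <- SummarizedExperiment::assay(object, "log2intensity")
    if (any(is.infinite(a)))
        return("log2 intensities must be finite or NA")
    TRUE
})

#' Construct an LFQExperiment from a log2 matrix
#'
#' @param log2intensity Numeric matrix, proteins x samples, \code{NA} for
#'   missing values.
#' @param bait Character/factor bait-group label per column.
#' @param replicate Integer replicate index per column (default: running
#'   index within bait).
#' @param rowData Optional per-protein annotation.
#' @return An \linkS4class{LFQExperiment}.
#' @export
LFQExperiment <- function(log2intensity, bait,
                          replicate = stats::ave(seq_along(bait),
                                                 bait, FUN = seq_along),
                          rowData = NULL) {
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(log2intensity = as.matrix(log2intensity)),
        colData = S4Vectors::DataFrame(bait = as.character(bait),
                                       replicate = as.integer(replicate)))
    if (!is.null(rowData))
        SummarizedExperiment::rowData(se) <- rowData
    new("LFQExperiment", se)
}

#' Bait labels of an LFQ experiment
#'
#' @param object An \linkS4class{LFQExperiment}.
#' @return Character vector, one bait-group label per sample column.
#' @export
baits <- function(object) {
    stopifnot(is(object, "LFQExperiment"))
    SummarizedExperiment::colData(object)$bait
}
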