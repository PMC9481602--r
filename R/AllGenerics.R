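#' @include AllGenerics.R
NULL

#' Label of a data object
#'
#' Free-text label identifying a peak list, CSP profile, titration series or
#' structural ensemble (e.g. \code{"Ub 11AcK"}).
#'
#' @param object A ubimod data object.
#' @param value Replacement label (single character string).
#' @return \code{label} returns a single character string.
#' @examples
#' pl <- PeakList(data.frame(residue_number = 1L, residue_type = "M",
#'                           shift_h = 8.1, shift_n = 120.2),
#'                label = "wt")
#' label(pl)
#' @export
setGeneric("label", function(object) standardGeneric("label"))

#' @rdname label
#' @export
setGeneric("label<-", function(object, value) standardGeneric("label<-"))

#' Peak table of a peak list
#'
#' @param object A \linkS4class{PeakList}.
#' @return A \code{data.frame} with one row per assigned residue and columns
#'   \code{residue_number}, \code{residue_type}, \code{shift_h} (ppm),
#'   \code{shift_n} (ppm), \code{intensity}.
#' @export
setGeneric("peaks", function(object) standardGeneric("peaks"))

#' Residue numbers covered by an object
#'
#' @param object A ubimod data object with per-residue content.
#' @return Sorted integer vector of 1-based residue numbers.
#' @export
setGeneric("residues", function(object) standardGeneric("residues"))

#' Per-residue CSP values of a profile
#'
#' @param object A \linkS4class{CSPProfile}.
#' @return Named numeric vector of weighted CSPs (ppm); names are residue
#'   numbers.
#' @export
setGeneric("cspValues", function(object) standardGeneric("cspValues"))

#' Residues masked from cutoff statistics
#'
#' @param object A \linkS4class{CSPProfile} or \linkS4class{CutoffPair}.
#' @return Integer vector of residue numbers.
#' @export
setGeneric("excludedResidues", function(object) standardGeneric("excludedResidues"))

#' Significance classes of a classified profile
#'
#' @param object A \linkS4class{CSPProfile} after
#'   \code{\link{classifyAndCluster}}.
#' @return Named character vector with levels \code{"below_mean"},
#'   \code{"above_mean"}, \code{"above_mean_plus_sd"}.
#' @export
setGeneric("significanceClasses", function(object) standardGeneric("significanceClasses"))

#' Fitted dissociation constant
#'
#' @param object A \linkS4class{BindingFitResult}.
#' @return Kd in the concentration units of the titration (conventionally
#'   micromolar).
#' @export
setGeneric("kd", function(object) standardGeneric("kd"))

#' Per-residue saturation CSP amplitudes
#'
#' @param object A \linkS4class{BindingFitResult}.
#' @return Named numeric vector of fitted maximal CSPs (ppm) per residue.
#' @export
setGeneric("dmaxValues", function(object) standardGeneric("dmaxValues"))

#' Number of frames in a structural ensemble
#'
#' @param object A \linkS4class{StructureEnsemble} or
#'   \linkS4class{DistanceMatrix}.
#' @return Integer frame count.
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' Distance cutoff of a minimum-distance matrix
#'
#' @param object A \linkS4class{DistanceMatrix}.
#' @return Cutoff in nm.
#' @export
setGeneric("distCutoff", function(object) standardGeneric("distCutoff"))

#' Titration steps of a series
#'
#' @param object A \linkS4class{TitrationSeries}.
#' @return A \code{data.frame} with columns \code{step_index},
#'   \code{protein_conc}, \code{ligand_conc} (one row per recorded spectrum,
#'   step 0 first).
#' @export
setGeneric("titrationSteps", function(object) standardGeneric("titrationSteps"))

#' Write a peak list to disk
#'
#' @param object A \linkS4class{PeakList}.
#' @param path Output file path.
#' @param dialect \code{"sparky"} or \code{"tsv"}.
#' @return Invisibly, \code{path}.
#' @seealso \code{\link{readPeakList}}
#' @export
setGeneric("writePeakList", function(object, path, dialect = c("tsv", "sparky"))
    standardGeneric("writePeakList"))
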