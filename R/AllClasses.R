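#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## PeakList
## ---------------------------------------------------------------------------

#' Assigned 2D 1H-15N peak list
#'
#' One record per assigned backbone amide: 1-based residue number, one-letter
#' residue type, 1H and 15N chemical shifts in ppm and an optional intensity.
#' Prolines and unassigned residues are simply absent; there are no
#' placeholder rows.
#'
#' @slot label Free-text label (e.g. \code{"Ub 11AcK"}).
#' @slot peaks \code{data.frame} with columns \code{residue_number},
#'   \code{residue_type}, \code{shift_h}, \code{shift_n}, \code{intensity}.
#' @slot sourceDialect \code{"sparky"}, \code{"tsv"} or \code{"memory"}.
#' @seealso \code{\link{readPeakList}}, \code{\link{matchPeaks}},
#'   \code{\link{weightedCSP}}
#' @exportClass PeakList
setClass("PeakList",
    representation(label = "character", peaks = "data.frame",
                   sourceDialect = "character"),
    prototype(label = "", sourceDialect = "memory"))

setValidity("PeakList", function(object) {
    p <- object@peaks
    need <- c("residue_number", "residue_type", "shift_h", "shift_n",
              "intensity")
    if (!all(need %in% names(p)))
        return(paste("peak table must have columns:",
                     paste(need, collapse = ", ")))
    if (length(object@label) != 1L)
        return("'label' must be a single string")
    if (nrow(p) == 0L)
        return(TRUE)
    if (anyDuplicated(p$residue_number))
        return(sprintf("duplicate residue number(s): %s",
                       paste(unique(p$residue_number[duplicated(p$residue_number)]),
                             collapse = ", ")))
    if (any(p$residue_number < 1L))
        return("residue numbers must be >= 1")
    if (!all(is.finite(p$shift_h)) || !all(is.finite(p$shift_n)))
        return("chemical shifts must be finite")
    if (any(!is.na(p$intensity) & p$intensity < 0))
        return("intensities must be non-negative")
    TRUE
})

#' Construct a PeakList
#'
#' @param peaks \code{data.frame} with columns \code{residue_number},
#'   \code{residue_type}, \code{shift_h}, \code{shift_n} and optionally
#'   \code{intensity} (filled with \code{NA} if missing).
#' @param label Free-text label.
#' @param sourceDialect Origin of the data; set by \code{\link{readPeakList}}.
#' @return A \linkS4class{PeakList}, rows ordered by residue number.
#' @examples
#' pl <- PeakList(data.frame(residue_number = c(14L, 43L),
#'                           residue_type = c("T", "L"),
#'                           shift_h = c(8.72, 8.81),
#'                           shift_n = c(121.53, 124.36)),
#'                label = "wt")
#' peaks(pl)
#' @export
PeakList <- function(peaks, label = "", sourceDialect = "memory") {
    peaks <- as.data.frame(peaks)
    if (is.null(peaks$intensity))
        peaks$intensity <- NA_real_
    peaks$residue_number <- as.integer(peaks$residue_number)
    peaks <- peaks[order(peaks$residue_number),
                   c("residue_number", "residue_type", "shift_h", "shift_n",
                     "intensity"), drop = FALSE]
    rownames(peaks) <- NULL
    new("PeakList", label = label, peaks = peaks,
        sourceDialect = sourceDialect)
}

#' @rdname label
#' @export
setMethod("label", "PeakList", function(object) object@label)

#' @rdname label
#' @export
setReplaceMethod("label", "PeakList", function(object, value) {
    object@label <- value
    validObject(object)
    object
})

#' @rdname peaks
#' @export
setMethod("peaks", "PeakList", function(object) object@peaks)

#' @rdname residues
#' @export
setMethod("residues", "PeakList",
          function(object) sort(object@peaks$residue_number))

setMethod("show", "PeakList", function(object) {
    cat("PeakList \"", object@label, "\": ", nrow(object@peaks),
        " assigned residue(s)", sep = "")
    if (nrow(object@peaks) > 0L)
        cat(" [", min(object@peaks$residue_number), "..",
            max(object@peaks$residue_number), "]", sep = "")
    cat(", dialect=", object@sourceDialect, "\n", sep = "")
})

## ---------------------------------------------------------------------------
## PeakPairing
## ---------------------------------------------------------------------------

#' Pairing of peaks between two spectra
#'
#' Result of \code{\link{matchPeaks}}: matched (reference, target) peak pairs
#' keyed by residue number plus the residues of either input left unmatched.
#' The pairs and the unmatched sets partition each input's residues.
#'
#' @slot pairs \code{data.frame}: \code{residue_number} (reference numbering),
#'   \code{target_residue}, the four shift columns (\code{ref_h}, \code{ref_n},
#'   \code{tgt_h}, \code{tgt_n}), \code{distance} (Eq.-weighted ppm) and
#'   \code{tie} (ambiguity flag, nearest-trajectory mode only).
#' @slot unmatchedReference,unmatchedTarget Integer residue sets.
#' @slot mode \code{"by_assignment"} or \code{"nearest_trajectory"}.
#' @exportClass PeakPairing
setClass("PeakPairing",
    representation(pairs = "data.frame", unmatchedReference = "integer",
                   unmatchedTarget = "integer", mode = "character"))

setMethod("show", "PeakPairing", function(object) {
    cat("PeakPairing (", object@mode, "): ", nrow(object@pairs),
        " pair(s), ", length(object@unmatchedReference),
        " unmatched reference, ", length(object@unmatchedTarget),
        " unmatched target\n", sep = "")
})

## ---------------------------------------------------------------------------
## CSPProfile
## ---------------------------------------------------------------------------

#' Per-residue weighted chemical shift perturbation profile
#'
#' Holds the weighted CSP for every residue paired between a reference and a
#' variant spectrum, the set of residues excluded from cutoff statistics
#' (e.g. all lysines for acetyl-lysine comparisons, or the substituted
#' position for point variants) and, once classified, the significance class
#' of each non-excluded residue.
#'
#' @slot label Free-text label.
#' @slot values Named numeric: weighted CSP (ppm) per residue, names are
#'   residue numbers, all values >= 0.
#' @slot residueType Named character: one-letter code per residue.
#' @slot excluded Integer vector of residues masked from cutoff statistics
#'   (they retain values).
#' @slot classes Named character vector, filled by
#'   \code{\link{classifyAndCluster}}; excluded residues are never classified.
#' @slot dropped Residues present in only one input list (e.g. broadened
#'   out), reported but absent from \code{values}.
#' @seealso \code{\link{weightedCSP}}, \code{\link{significanceCutoffs}}
#' @exportClass CSPProfile
setClass("CSPProfile",
    representation(label = "character", values = "numeric",
                   residueType = "character", excluded = "integer",
                   classes = "character", dropped = "integer"),
    prototype(label = "", excluded = integer(), classes = character(),
              dropped = integer()))

setValidity("CSPProfile", function(object) {
    v <- object@values
    if (length(v) && is.null(names(v)))
        return("'values' must be named by residue number")
    if (any(!is.finite(v)) || any(v < 0))
        return("CSP values must be finite and >= 0")
    if (length(object@classes)) {
        if (any(names(object@classes) %in% as.character(object@excluded)))
            return("excluded residues must not carry significance classes")
        bad <- setdiff(object@classes,
                       c("below_mean", "above_mean", "above_mean_plus_sd"))
        if (length(bad))
            return(paste("unknown class:", paste(bad, collapse = ", ")))
    }
    TRUE
})

#' @rdname label
#' @export
setMethod("label", "CSPProfile", function(object) object@label)

#' @rdname cspValues
#' @export
setMethod("cspValues", "CSPProfile", function(object) object@values)

#' @rdname residues
#' @export
setMethod("residues", "CSPProfile",
          function(object) sort(as.integer(names(object@values))))

#' @rdname excludedResidues
#' @export
setMethod("excludedResidues", "CSPProfile", function(object) object@excluded)

#' @rdname significanceClasses
#' @export
setMethod("significanceClasses", "CSPProfile", function(object) object@classes)

setMethod("show", "CSPProfile", function(object) {
    cat("CSPProfile \"", object@label, "\": ", length(object@values),
        " residue(s), ", length(object@excluded), " excluded", sep = "")
    if (length(object@values))
        cat(sprintf(", max %.4f ppm at residue %s", max(object@values),
                    names(object@values)[which.max(object@values)]))
    if (length(object@classes))
        cat(", ", sum(object@classes != "below_mean"), " significant",
            sep = "")
    cat("\n")
})

## ---------------------------------------------------------------------------
## CutoffPair
## ---------------------------------------------------------------------------

#' Pooled significance cutoffs for CSP profiles
#'
#' Mean and mean-plus-one-standard-deviation of the pooled, non-excluded CSP
#' values of one or more profiles; residues above the mean are significant,
#' residues above mean + SD strongly so.
#'
#' @slot meanCutoff,meanPlusSdCutoff Cutoffs in ppm.
#' @slot nValues Number of pooled values.
#' @slot excludedResidues Union of the per-profile exclusion sets.
#' @seealso \code{\link{significanceCutoffs}}
#' @exportClass CutoffPair
setClass("CutoffPair",
    representation(meanCutoff = "numeric", meanPlusSdCutoff = "numeric",
                   nValues = "integer", excludedResidues = "integer"))

setValidity("CutoffPair", function(object) {
    if (object@meanCutoff < 0 || object@meanPlusSdCutoff < 0)
        return("cutoffs must be >= 0")
    if (object@meanPlusSdCutoff < object@meanCutoff - 1e-12)
        return("mean+SD cutoff cannot be below the mean cutoff")
    TRUE
})

#' @rdname excludedResidues
#' @export
setMethod("excludedResidues", "CutoffPair",
          function(object) object@excludedResidues)

setMethod("show", "CutoffPair", function(object) {
    cat(sprintf(
        "CutoffPair: mean %.4f ppm, mean+SD %.4f ppm (n = %d pooled values)\n",
        object@meanCutoff, object@meanPlusSdCutoff, object@nValues))
})

## ---------------------------------------------------------------------------
## TitrationSeries
## ---------------------------------------------------------------------------

#' Ordered HSQC titration series
#'
#' One assigned peak list per titration step together with the total protein
#' and ligand concentrations at that step. Step 0 is the ligand-free
#' reference; the ligand concentration is non-decreasing and the protein
#' concentration non-increasing (cumulative dilution).
#'
#' @slot label Free-text label.
#' @slot steps List of \linkS4class{PeakList}, one per step, step 0 first.
#' @slot proteinConc,ligandConc Numeric, total concentrations per step
#'   (conventionally micromolar).
#' @slot stepIndex Integer, strictly increasing, starting at 0.
#' @seealso \code{\link{perStepCSP}}, \code{\link{fitGlobalKd}}
#' @exportClass TitrationSeries
setClass("TitrationSeries",
    representation(label = "character", steps = "list",
                   proteinConc = "numeric", ligandConc = "numeric",
                   stepIndex = "integer"),
    prototype(label = ""))

setValidity("TitrationSeries", function(object) {
    n <- length(object@steps)
    if (n == 0L)
        return("a titration series needs at least one step")
    if (length(object@proteinConc) != n || length(object@ligandConc) != n ||
        length(object@stepIndex) != n)
        return("steps, concentrations and step indices must have equal length")
    if (!all(vapply(object@steps, is, logical(1), "PeakList")))
        return("every step must be a PeakList")
    if (any(diff(object@stepIndex) <= 0))
        return("step indices must be strictly increasing")
    if (any(object@proteinConc < 0) || any(object@ligandConc < 0))
        return("concentrations must be >= 0")
    if (object@ligandConc[1L] != 0)
        return("step 0 must have ligand concentration 0")
    if (any(diff(object@ligandConc) < -1e-9))
        return("ligand concentration must be non-decreasing")
    if (any(diff(object@proteinConc) > 1e-9))
        return("protein concentration must be non-increasing (dilution)")
    TRUE
})

#' Construct a TitrationSeries
#'
#' @param steps List of \linkS4class{PeakList}, step 0 (ligand-free) first.
#' @param proteinConc,ligandConc Per-step total concentrations
#'   (conventionally micromolar), e.g. from
#'   \code{\link{concentrationsFromScheme}}.
#' @param label Free-text label.
#' @param stepIndex Integer step indices; defaults to \code{0:(n-1)}.
#' @return A \linkS4class{TitrationSeries}.
#' @export
TitrationSeries <- function(steps, proteinConc, ligandConc, label = "",
                            stepIndex = seq_along(steps) - 1L) {
    new("TitrationSeries", label = label, steps = steps,
        proteinConc = as.numeric(proteinConc),
        ligandConc = as.numeric(ligandConc),
        stepIndex = as.integer(stepIndex))
}

#' @rdname label
#' @export
setMethod("label", "TitrationSeries", function(object) object@label)

#' @rdname titrationSteps
#' @export
setMethod("titrationSteps", "TitrationSeries", function(object) {
    data.frame(step_index = object@stepIndex,
               protein_conc = object@proteinConc,
               ligand_conc = object@ligandConc)
})

setMethod("show", "TitrationSeries", function(object) {
    cat("TitrationSeries \"", object@label, "\": ", length(object@steps),
        " step(s), [P] ", sprintf("%.2f", object@proteinConc[1L]), " -> ",
        sprintf("%.2f", utils::tail(object@proteinConc, 1L)), ", [L] 0 -> ",
        sprintf("%.2f", utils::tail(object@ligandConc, 1L)), "\n", sep = "")
})

## ---------------------------------------------------------------------------
## BindingFitResult
## ---------------------------------------------------------------------------

#' Result of the global 1:1 binding fit
#'
#' A single shared dissociation constant fitted across residues, the
#' per-residue saturation amplitudes, asymptotic standard error, optional
#' bootstrap confidence interval, and the per-(residue, step) residuals.
#'
#' @slot kd Fitted dissociation constant.
#' @slot kdSE Asymptotic standard error from the Jacobian at the optimum.
#' @slot kdCI Length-2 numeric (bootstrap percentile interval) or empty.
#' @slot dmax Named numeric, fitted saturation CSP per residue (ppm).
#' @slot residuals \code{data.frame}: \code{residue_number},
#'   \code{step_index}, \code{observed}, \code{fitted}, \code{residual}.
#' @slot converged Logical convergence flag.
#' @slot atBound Logical, \code{TRUE} if the optimum hit a Kd search bound.
#' @slot nPoints Number of (residue, step) observations fitted.
#' @seealso \code{\link{fitGlobalKd}}
#' @exportClass BindingFitResult
setClass("BindingFitResult",
    representation(kd = "numeric", kdSE = "numeric", kdCI = "numeric",
                   dmax = "numeric", residuals = "data.frame",
                   converged = "logical", atBound = "logical",
                   nPoints = "integer"),
    prototype(kdCI = numeric()))

setValidity("BindingFitResult", function(object) {
    if (object@kd <= 0)
        return("Kd must be > 0")
    if (any(object@dmax < 0))
        return("every dmax must be >= 0")
    if (object@nPoints < length(object@dmax) + 1L)
        return("fewer observations than parameters")
    TRUE
})

#' @rdname kd
#' @export
setMethod("kd", "BindingFitResult", function(object) object@kd)

#' @rdname dmaxValues
#' @export
setMethod("dmaxValues", "BindingFitResult", function(object) object@dmax)

setMethod("show", "BindingFitResult", function(object) {
    cat(sprintf("BindingFitResult: Kd = %.4g +/- %.2g", object@kd,
                object@kdSE))
    if (length(object@kdCI) == 2L)
        cat(sprintf(" (bootstrap 95%% CI %.4g..%.4g)", object@kdCI[1L],
                    object@kdCI[2L]))
    cat(sprintf("; %d residue(s), %d points, converged: %s\n",
                length(object@dmax), object@nPoints,
                if (object@converged) "yes" else "NO"))
    if (object@atBound)
        cat("  WARNING: Kd at search bound\n")
})

## ---------------------------------------------------------------------------
## StructureEnsemble
## ---------------------------------------------------------------------------

#' Coordinate ensemble of a protein structure
#'
#' Ordered frames sharing one topology; coordinates are stored in nm
#' (PDB Angstroms are converted on read).
#'
#' @slot label Free-text label.
#' @slot coords Numeric array \code{n_atoms x 3 x n_frames} (nm).
#' @slot atomResidue Integer, residue number per atom (1-based).
#' @slot atomName Character, atom name per atom (e.g. \code{"CA"}).
#' @slot atomElement Character, element symbol per atom.
#' @slot residueType Named character, three-letter residue name per residue.
#' @seealso \code{\link{readEnsemble}}, \code{\link{meanMinDistanceMatrix}}
#' @exportClass StructureEnsemble
setClass("StructureEnsemble",
    representation(label = "character", coords = "array",
                   atomResidue = "integer", atomName = "character",
                   atomElement = "character", residueType = "character"),
    prototype(label = ""))

setValidity("StructureEnsemble", function(object) {
    d <- dim(object@coords)
    if (length(d) != 3L || d[2L] != 3L)
        return("'coords' must be an n_atoms x 3 x n_frames array")
    if (length(object@atomResidue) != d[1L])
        return("one residue number per atom required")
    if (any(!is.finite(object@coords)))
        return("coordinates must be finite")
    TRUE
})

#' @rdname label
#' @export
setMethod("label", "StructureEnsemble", function(object) object@label)

#' @rdname nFrames
#' @export
setMethod("nFrames", "StructureEnsemble",
          function(object) dim(object@coords)[3L])

#' @rdname residues
#' @export
setMethod("residues", "StructureEnsemble",
          function(object) sort(unique(object@atomResidue)))

setMethod("show", "StructureEnsemble", function(object) {
    d <- dim(object@coords)
    cat("StructureEnsemble \"", object@label, "\": ", d[3L], " frame(s), ",
        d[1L], " atoms, ", length(unique(object@atomResidue)),
        " residues\n", sep = "")
})

## ---------------------------------------------------------------------------
## DistanceMatrix
## ---------------------------------------------------------------------------

#' Mean minimum-distance matrix
#'
#' Residue-by-residue mean of the per-frame minimum interatomic distance,
#' each per-frame minimum truncated at the cutoff before averaging
#' (mdmat-style semantics). Symmetric with zero diagonal; entries in
#' \code{[0, cutoff]} nm.
#'
#' @slot matrix Numeric matrix with residue-number dimnames.
#' @slot cutoff Truncation distance in nm (default 1.0).
#' @slot nFrames Number of frames averaged.
#' @slot label Free-text label.
#' @seealso \code{\link{meanMinDistanceMatrix}}, \code{\link{differenceMatrix}}
#' @exportClass DistanceMatrix
setClass("DistanceMatrix",
    representation(matrix = "matrix", cutoff = "numeric",
                   nFrames = "integer", label = "character"),
    prototype(label = ""))

setValidity("DistanceMatrix", function(object) {
    m <- object@matrix
    if (nrow(m) != ncol(m) || !isTRUE(all.equal(m, t(m), tolerance = 1e-9)))
        return("matrix must be symmetric")
    if (any(abs(diag(m)) > 1e-12))
        return("diagonal must be zero")
    if (any(m < -1e-12) || any(m > object@cutoff + 1e-9))
        return("entries must lie in [0, cutoff]")
    TRUE
})

#' Extract the distance matrix
#'
#' @param x A \linkS4class{DistanceMatrix}.
#' @param ... Ignored.
#' @return Base numeric matrix (nm) with residue-number dimnames.
#' @export
setMethod("as.matrix", "DistanceMatrix", function(x, ...) x@matrix)

#' @rdname distCutoff
#' @export
setMethod("distCutoff", "DistanceMatrix", function(object) object@cutoff)

#' @rdname nFrames
#' @export
setMethod("nFrames", "DistanceMatrix", function(object) object@nFrames)

#' @rdname label
#' @export
setMethod("label", "DistanceMatrix", function(object) object@label)

#' @rdname residues
#' @export
setMethod("residues", "DistanceMatrix",
          function(object) as.integer(rownames(object@matrix)))

setMethod("show", "DistanceMatrix", function(object) {
    cat("DistanceMatrix \"", object@label, "\": ", nrow(object@matrix), " x ",
        ncol(object@matrix), " residues, cutoff ", object@cutoff, " nm, ",
        object@nFrames, " frame(s)\n", sep = "")
})
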