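#' @include AllClasses.R
NULL

#' Read a multi-model PDB file as a coordinate ensemble
#'
#' Frames are ordered by MODEL number; a single-structure file yields a
#' one-frame ensemble. Coordinates are converted from Angstrom to nm on
#' read. Hydrogens, when present, are retained. All models must share one
#' topology (same atom count and ordering).
#'
#' @param path Path to a PDB file.
#' @param label Label for the ensemble; defaults to the file name.
#' @return A \linkS4class{StructureEnsemble}.
#' @seealso \code{\link{meanMinDistanceMatrix}},
#'   \code{\link{writeEnsemble}}
#' @export
readEnsemble <- function(path, label = basename(path)) {
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                    error = function(e)
                        stop("PDB parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
    at <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), , drop = FALSE]
    if (nrow(at) == 0L)
        stop("PDB parse error: no ATOM records in ", path, call. = FALSE)
    xyz <- pdb$xyz                      # n_models x (3 * n_atoms), Angstrom
    if (is.vector(xyz))
        xyz <- matrix(xyz, nrow = 1L)
    nAtoms <- ncol(xyz) / 3L
    if (nAtoms != nrow(at))
        stop("inconsistent atom count across models in ", path,
             call. = FALSE)
    nF <- nrow(xyz)
    coords <- array(NA_real_, dim = c(nAtoms, 3L, nF))
    for (f in seq_len(nF))
        coords[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE) / 10
    resno <- as.integer(at$resno)
    rt <- tapply(at$resid, resno, function(x) x[1L])
    new("StructureEnsemble", label = label, coords = coords,
        atomResidue = resno, atomName = as.character(at$elety),
        atomElement = as.character(at$elesy),
        residueType = stats::setNames(as.character(rt), names(rt)))
}

#' Write a coordinate ensemble as a multi-model PDB file
#'
#' Emits one MODEL/ENDMDL block per frame with fixed-width ATOM records;
#' coordinates are converted from nm back to Angstrom. Round-trips through
#' \code{\link{readEnsemble}} at the PDB precision of 0.001 Angstrom.
#'
#' @param object A \linkS4class{StructureEnsemble}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
writeEnsemble <- function(object, path) {
    stopifnot(is(object, "StructureEnsemble"))
    d <- dim(object@coords)
    rt <- object@residueType
    resnames <- if (length(rt)) rt[as.character(object@atomResidue)]
                else rep("GLY", d[1L])
    resnames[is.na(resnames)] <- "UNK"
    elem <- if (length(object@atomElement)) object@atomElement
            else substr(object@atomName, 1L, 1L)
    con <- file(path, "w")
    on.exit(close(con))
    for (f in seq_len(d[3L])) {
        writeLines(sprintf("MODEL     %4d", f), con)
        xyzA <- object@coords[, , f, drop = FALSE] * 10
        writeLines(sprintf(
            "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            seq_len(d[1L]),
            ifelse(nchar(object@atomName) < 4L,
                   paste0(" ", object@atomName), object@atomName),
            substr(resnames, 1L, 3L), object@atomResidue,
            xyzA[, 1L, 1L], xyzA[, 2L, 1L], xyzA[, 3L, 1L],
            toupper(substr(elem, 1L, 2L))), con)
        writeLines("ENDMDL", con)
    }
    writeLines("END", con)
    invisible(path)
}

## Per-frame minimum interatomic distance between two atom index sets,
## vectorised over one frame.
frameMinDist <- function(xyz, idxA, idxB) {
    a <- xyz[idxA, , drop = FALSE]
    b <- xyz[idxB, , drop = FALSE]
    d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
    sqrt(max(min(d2), 0))
}

#' Per-frame minimum distance between two residues
#'
#' For each frame, the minimum over all atom pairs (one atom from each
#' residue) of the Euclidean distance, in nm — the descriptor used to track
#' e.g. the approach of residue 11's side chain to residue 34.
#'
#' @param object A \linkS4class{StructureEnsemble}.
#' @param resA,resB Residue numbers (must be present in the topology).
#' @param heavyOnly Exclude hydrogens (default FALSE: all atoms
#'   participate).
#' @return Numeric vector of length \code{nFrames(object)} (nm).
#' @export
pairMinDistance <- function(object, resA, resB, heavyOnly = FALSE) {
    stopifnot(is(object, "StructureEnsemble"))
    sel <- atomSelection(object, heavyOnly)
    idxA <- which(object@atomResidue == resA & sel)
    idxB <- which(object@atomResidue == resB & sel)
    if (!length(idxA) || !length(idxB))
        stop("residue ", if (!length(idxA)) resA else resB,
             " not present in the ensemble", call. = FALSE)
    vapply(seq_len(dim(object@coords)[3L]), function(f)
        frameMinDist(object@coords[, , f], idxA, idxB), numeric(1))
}

atomSelection <- function(object, heavyOnly) {
    if (!heavyOnly)
        return(rep(TRUE, length(object@atomResidue)))
    elem <- object@atomElement
    if (!length(elem) || all(!nzchar(elem)))
        elem <- substr(gsub("^[0-9]", "", object@atomName), 1L, 1L)
    toupper(trimws(elem)) != "H"
}

#' Mean minimum-distance matrix of an ensemble
#'
#' For every residue pair, the per-frame minimum interatomic distance is
#' truncated at \code{cutoff} and then averaged over frames (mdmat-style
#' truncate-then-average semantics). The result is symmetric with zero
#' diagonal, entries in \code{[0, cutoff]} nm.
#'
#' @param object A \linkS4class{StructureEnsemble}.
#' @param cutoff Truncation distance in nm (default 1.0).
#' @param heavyOnly Exclude hydrogens (default FALSE).
#' @return A \linkS4class{DistanceMatrix}.
#' @export
meanMinDistanceMatrix <- function(object, cutoff = 1.0, heavyOnly = FALSE) {
    stopifnot(is(object, "StructureEnsemble"), cutoff > 0)
    sel <- atomSelection(object, heavyOnly)
    res <- sort(unique(object@atomResidue[sel]))
    nR <- length(res)
    nF <- dim(object@coords)[3L]
    idx <- lapply(res, function(r) which(object@atomResidue == r & sel))
    acc <- matrix(0, nR, nR, dimnames = list(res, res))
    for (f in seq_len(nF)) {
        xyz <- object@coords[, , f]
        for (i in seq_len(nR - 1L)) {
            for (j in seq.int(i + 1L, nR)) {
                d <- min(frameMinDist(xyz, idx[[i]], idx[[j]]), cutoff)
                acc[i, j] <- acc[i, j] + d
            }
        }
    }
    m <- (acc + t(acc)) / nF
    new("DistanceMatrix", matrix = m, cutoff = cutoff, nFrames = nF,
        label = object@label)
}

#' Difference of two mean minimum-distance matrices
#'
#' Elementwise \code{variant - reference}; positive entries mark residue
#' pairs that moved apart in the variant, negative entries pairs that
#' approached. Antisymmetric under argument swap.
#'
#' @param variant,reference \linkS4class{DistanceMatrix} objects over the
#'   same residue set and cutoff.
#' @return Signed numeric matrix (nm) with residue dimnames.
#' @export
differenceMatrix <- function(variant, reference) {
    stopifnot(is(variant, "DistanceMatrix"), is(reference, "DistanceMatrix"))
    if (!identical(rownames(variant@matrix), rownames(reference@matrix)))
        stop("residue sets differ between the two matrices", call. = FALSE)
    if (variant@cutoff != reference@cutoff)
        stop("cutoffs differ between the two matrices", call. = FALSE)
    variant@matrix - reference@matrix
}

#' Write a distance (or difference) matrix as TSV
#'
#' @param m A \linkS4class{DistanceMatrix} or plain matrix with residue
#'   dimnames.
#' @param path Output path for the square TSV (residue headers).
#' @param long Also write a flat long-format TSV (\code{res_i}, \code{res_j},
#'   \code{distance_nm}) with suffix \code{"_long.tsv"} (default TRUE).
#' @return Invisibly, \code{path}.
#' @export
writeDistanceMatrix <- function(m, path, long = TRUE) {
    mat <- if (is(m, "DistanceMatrix")) m@matrix else m
    utils::write.table(round(mat, 6), path, sep = "\t", quote = FALSE,
                       col.names = NA)
    if (long) {
        idx <- which(upper.tri(mat), arr.ind = TRUE)
        flat <- data.frame(res_i = rownames(mat)[idx[, 1L]],
                           res_j = colnames(mat)[idx[, 2L]],
                           distance_nm = round(mat[idx], 6))
        utils::write.table(flat, paste0(sub("\\.tsv$", "", path),
                                        "_long.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(path)
}
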