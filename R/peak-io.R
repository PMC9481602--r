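#' @include AllClasses.R
NULL

## Parse a Sparky-style amide assignment string like "T14N-H" into
## (residue_type, residue_number).
parseAssignment <- function(s, line = NA_integer_) {
    m <- regmatches(s, regexec("^([A-Za-z])([0-9]+)N-H$", s))[[1L]]
    if (length(m) != 3L)
        stop(sprintf("unparsable assignment string %s at line %s",
                     sQuote(s), line), call. = FALSE)
    list(residue_type = toupper(m[2L]), residue_number = as.integer(m[3L]))
}

#' Read an assigned 2D peak list
#'
#' Reads either a Sparky-style \code{.list} text file (columns: assignment
#' string such as \code{"T14N-H"}, w1 = 15N ppm, w2 = 1H ppm, optional
#' height) or a plain TSV with header \code{residue_number},
#' \code{residue_type}, \code{shift_n_ppm}, \code{shift_h_ppm},
#' \code{intensity}. One peak per assigned residue; duplicate residues are
#' rejected. An empty file yields an empty \linkS4class{PeakList}.
#'
#' @param path File path.
#' @param dialect \code{"sparky"} or \code{"tsv"}.
#' @param label Label for the returned list; defaults to the file name.
#' @return A \linkS4class{PeakList}.
#' @seealso \code{\link{writePeakList}}, \code{\link{matchPeaks}}
#' @examples
#' f <- tempfile(fileext = ".list")
#' writeLines(c("T14N-H 121.53 8.72 1.0e6", "L43N-H 124.36 8.81 9.5e5"), f)
#' readPeakList(f, "sparky")
#' @export
readPeakList <- function(path, dialect = c("sparky", "tsv"),
                         label = basename(path)) {
    dialect <- match.arg(dialect)
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    if (dialect == "sparky") {
        lines <- readLines(path, warn = FALSE)
        keep <- which(nzchar(trimws(lines)) &
                      !grepl("^\\s*(#|Assignment)", lines))
        rows <- lapply(keep, function(i) {
            f <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
            if (length(f) < 3L)
                stop(sprintf("malformed Sparky line %d in %s", i, path),
                     call. = FALSE)
            a <- parseAssignment(f[1L], i)
            data.frame(residue_number = a$residue_number,
                       residue_type = a$residue_type,
                       shift_h = as.numeric(f[3L]),
                       shift_n = as.numeric(f[2L]),
                       intensity = if (length(f) >= 4L)
                           as.numeric(f[4L]) else NA_real_)
        })
        tab <- if (length(rows)) do.call(rbind, rows) else
            data.frame(residue_number = integer(), residue_type = character(),
                       shift_h = numeric(), shift_n = numeric(),
                       intensity = numeric())
    } else {
        tab <- utils::read.delim(path, stringsAsFactors = FALSE)
        need <- c("residue_number", "residue_type", "shift_n_ppm",
                  "shift_h_ppm")
        if (!all(need %in% names(tab)))
            stop("TSV peak list must have columns: ",
                 paste(need, collapse = ", "), call. = FALSE)
        tab <- data.frame(residue_number = as.integer(tab$residue_number),
                          residue_type = tab$residue_type,
                          shift_h = tab$shift_h_ppm,
                          shift_n = tab$shift_n_ppm,
                          intensity = if ("intensity" %in% names(tab))
                              tab$intensity else NA_real_)
    }
    if (anyDuplicated(tab$residue_number))
        stop(sprintf("duplicate assignment for residue(s) %s in %s",
                     paste(unique(tab$residue_number[
                         duplicated(tab$residue_number)]), collapse = ", "),
                     path), call. = FALSE)
    PeakList(tab, label = label, sourceDialect = dialect)
}

#' @describeIn writePeakList Writes either dialect; chemical shifts are
#'   emitted with 4 decimal places (ppm), so write/read round-trips are exact
#'   at that precision.
#' @export
setMethod("writePeakList", "PeakList", function(object, path,
                                                dialect = c("tsv", "sparky")) {
    dialect <- match.arg(dialect)
    p <- object@peaks
    if (dialect == "sparky") {
        lines <- sprintf("%s%dN-H %10.4f %9.4f%s", p$residue_type,
                         p$residue_number, p$shift_n, p$shift_h,
                         ifelse(is.na(p$intensity), "",
                                sprintf(" %.6e", p$intensity)))
        writeLines(c("      Assignment         w1         w2   Height",
                     lines), path)
    } else {
        out <- data.frame(residue_number = p$residue_number,
                          residue_type = p$residue_type,
                          shift_n_ppm = sprintf("%.4f", p$shift_n),
                          shift_h_ppm = sprintf("%.4f", p$shift_h),
                          intensity = p$intensity)
        utils::write.table(out, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(path)
})

#' Pair peaks between two spectra
#'
#' \code{by_assignment} pairs peaks with identical residue numbers.
#' \code{nearest_trajectory} is a reproducible surrogate for visual peak
#' tracking: each reference peak is paired with the closest target peak under
#' the weighted shift metric (the same 1H/15N weighting as the CSP itself),
#' greedily in ascending-distance order, one-to-one; candidate pairs farther
#' than \code{maxJump} remain unmatched. Exact distance ties are resolved
#' deterministically in favour of the lower residue number and flagged in the
#' \code{tie} column.
#'
#' @param reference,target \linkS4class{PeakList} objects (non-empty).
#' @param mode \code{"by_assignment"} or \code{"nearest_trajectory"}.
#' @param maxJump Maximum weighted shift distance (ppm) for a pairing in
#'   nearest-trajectory mode; must be > 0.
#' @return A \linkS4class{PeakPairing}. Its pairs plus unmatched sets
#'   partition each input's residues.
#' @examples
#' a <- PeakList(data.frame(residue_number = c(14L, 43L),
#'                          residue_type = c("T", "L"),
#'                          shift_h = c(8.72, 8.81),
#'                          shift_n = c(121.53, 124.36)))
#' b <- PeakList(peaks(a)[2, ])
#' matchPeaks(a, b)
#' @export
matchPeaks <- function(reference, target,
                       mode = c("by_assignment", "nearest_trajectory"),
                       maxJump = NULL) {
    mode <- match.arg(mode)
    stopifnot(is(reference, "PeakList"), is(target, "PeakList"))
    pr <- peaks(reference)
    pt <- peaks(target)
    if (nrow(pr) == 0L || nrow(pt) == 0L)
        stop("both peak lists must be non-empty", call. = FALSE)

    if (mode == "by_assignment") {
        shared <- intersect(pr$residue_number, pt$residue_number)
        i <- match(shared, pr$residue_number)
        j <- match(shared, pt$residue_number)
        pairs <- data.frame(residue_number = shared,
                            target_residue = shared,
                            ref_h = pr$shift_h[i], ref_n = pr$shift_n[i],
                            tgt_h = pt$shift_h[j], tgt_n = pt$shift_n[j],
                            tie = FALSE)
        pairs$distance <- weightedShiftDistance(pairs$tgt_h - pairs$ref_h,
                                                pairs$tgt_n - pairs$ref_n)
        o <- order(pairs$residue_number)
        pairs <- pairs[o, , drop = FALSE]
        rownames(pairs) <- NULL
        return(new("PeakPairing", pairs = pairs,
                   unmatchedReference = sort(setdiff(pr$residue_number,
                                                     shared)),
                   unmatchedTarget = sort(setdiff(pt$residue_number, shared)),
                   mode = mode))
    }

    if (is.null(maxJump) || maxJump <= 0)
        stop("nearest_trajectory mode requires maxJump > 0", call. = FALSE)
    d <- outer(seq_len(nrow(pr)), seq_len(nrow(pt)), function(i, j)
        weightedShiftDistance(pr$shift_h[i] - pt$shift_h[j],
                              pr$shift_n[i] - pt$shift_n[j]))
    cand <- which(d <= maxJump, arr.ind = TRUE)
    ## greedy ascending distance; ties -> lower reference then target residue
    ord <- order(d[cand], pr$residue_number[cand[, 1L]],
                 pt$residue_number[cand[, 2L]])
    cand <- cand[ord, , drop = FALSE]
    usedR <- logical(nrow(pr))
    usedT <- logical(nrow(pt))
    take <- integer()
    tie <- logical()
    dv <- d[cand]
    for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1L]; j <- cand[k, 2L]
        if (usedR[i] || usedT[j])
            next
        usedR[i] <- TRUE; usedT[j] <- TRUE
        take <- c(take, k)
        ## a tie exists if another still-available candidate of this
        ## reference (or target) peak sits at the identical distance
        same <- which(abs(dv - dv[k]) < 1e-12)
        same <- same[same != k]
        tie <- c(tie, any(cand[same, 1L] == i | cand[same, 2L] == j))
    }
    sel <- cand[take, , drop = FALSE]
    pairs <- data.frame(residue_number = pr$residue_number[sel[, 1L]],
                        target_residue = pt$residue_number[sel[, 2L]],
                        ref_h = pr$shift_h[sel[, 1L]],
                        ref_n = pr$shift_n[sel[, 1L]],
                        tgt_h = pt$shift_h[sel[, 2L]],
                        tgt_n = pt$shift_n[sel[, 2L]],
                        tie = tie, distance = dv[take])
    o <- order(pairs$residue_number)
    pairs <- pairs[o, , drop = FALSE]
    rownames(pairs) <- NULL
    new("PeakPairing", pairs = pairs,
        unmatchedReference = sort(pr$residue_number[!usedR]),
        unmatchedTarget = sort(pt$residue_number[!usedT]),
        mode = mode)
}
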