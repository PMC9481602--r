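#' @include peak-io.R
NULL

#' Weighted chemical shift perturbation between two spectra
#'
#' For every residue assigned in both lists computes
#' \deqn{\Delta\omega = \sqrt{\frac{(\Delta^{1}H)^2 +
#'   \tfrac{1}{25}(\Delta^{15}N)^2}{2}}}
#' i.e. the nitrogen shift difference is scaled down 5-fold before the
#' root-mean-square combination, reflecting the ~5x wider 15N shift
#' dispersion. Residues present in only one list (e.g. broadened beyond
#' detection) are dropped from the profile and reported in the
#' \code{dropped} slot; residues in \code{excluded} keep their values but are
#' masked from cutoff statistics.
#'
#' @param reference,variant \linkS4class{PeakList} objects pairable by
#'   assignment.
#' @param excluded Integer residue numbers to mask from cutoff statistics
#'   (all seven lysines for acetyl-lysine comparisons; the substituted
#'   position for point variants).
#' @param label Label for the profile; defaults to
#'   \code{"<variant> vs <reference>"}.
#' @return A \linkS4class{CSPProfile}.
#' @examples
#' ref <- PeakList(data.frame(residue_number = 1:2, residue_type = c("M","Q"),
#'                            shift_h = c(8.0, 8.5), shift_n = c(120, 115)))
#' var <- PeakList(data.frame(residue_number = 1:2, residue_type = c("M","Q"),
#'                            shift_h = c(8.1, 8.5), shift_n = c(120.5, 115)))
#' cspValues(weightedCSP(ref, var))  # residue 1: sqrt((0.01 + 0.25/25)/2)
#' @export
weightedCSP <- function(reference, variant, excluded = integer(),
                        label = NULL) {
    pairing <- matchPeaks(reference, variant, mode = "by_assignment")
    pp <- pairing@pairs
    if (nrow(pp) == 0L)
        stop("no residues paired between the two peak lists", call. = FALSE)
    values <- weightedShiftDistance(pp$tgt_h - pp$ref_h, pp$tgt_n - pp$ref_n)
    names(values) <- pp$residue_number
    rt <- peaks(reference)$residue_type[match(pp$residue_number,
                                              peaks(reference)$residue_number)]
    names(rt) <- pp$residue_number
    if (is.null(label))
        label <- sprintf("%s vs %s", variant@label, reference@label)
    new("CSPProfile", label = label, values = values, residueType = rt,
        excluded = as.integer(excluded),
        dropped = sort(c(pairing@unmatchedReference,
                         pairing@unmatchedTarget)))
}

#' Pooled significance cutoffs
#'
#' Pools the non-excluded CSP values of one or more profiles and returns the
#' mean and the mean plus one sample standard deviation (n-1 denominator).
#' Values above the mean count as significant, values above mean + SD as
#' strongly significant. Each profile contributes its own exclusion set, so
#' acetyl-lysine panels can mask lysines while point-variant panels mask only
#' the substituted position.
#'
#' @param profiles A \linkS4class{CSPProfile} or a list of them (values are
#'   pooled across all of them, as when one pair of cutoff lines is drawn
#'   over several panels).
#' @return A \linkS4class{CutoffPair}.
#' @examples
#' p <- new("CSPProfile", values = c(`1` = 0.1, `2` = 0.2, `3` = 0.3,
#'                                   `4` = 0.4))
#' significanceCutoffs(p)  # mean 0.25, mean+SD ~0.3791
#' @export
significanceCutoffs <- function(profiles) {
    if (is(profiles, "CSPProfile"))
        profiles <- list(profiles)
    stopifnot(all(vapply(profiles, is, logical(1), "CSPProfile")))
    pooled <- unlist(lapply(profiles, function(p) {
        v <- p@values
        v[!(as.integer(names(v)) %in% p@excluded)]
    }), use.names = FALSE)
    if (length(pooled) < 2L)
        stop("need at least 2 non-excluded values to form cutoffs (SD is ",
             "undefined otherwise)", call. = FALSE)
    m <- mean(pooled)
    new("CutoffPair", meanCutoff = m,
        meanPlusSdCutoff = m + stats::sd(pooled),
        nValues = length(pooled),
        excludedResidues = sort(unique(unlist(lapply(profiles,
                                                     slot, "excluded")))))
}

#' Classify residues and find sequence clusters of perturbation
#'
#' Assigns each non-excluded residue one of three classes
#' (\code{below_mean}, \code{above_mean}, \code{above_mean_plus_sd}) against
#' the supplied cutoffs, then identifies clusters: maximal runs of
#' significant residues (class at least \code{above_mean}) in sequence
#' space, allowing interruptions of at most \code{gapTolerance} consecutive
#' non-significant residues, and retaining runs with at least \code{minSize}
#' significant members.
#'
#' @param profile A \linkS4class{CSPProfile}.
#' @param cutoffs A \linkS4class{CutoffPair} from
#'   \code{\link{significanceCutoffs}}.
#' @param gapTolerance Maximum run of non-significant residues bridged
#'   inside a cluster (default 1).
#' @param minSize Minimum number of significant members for a cluster to be
#'   reported (default 2).
#' @return A list with \code{profile} (classes filled) and \code{clusters},
#'   a \code{data.frame} with \code{first}, \code{last}, \code{n_members},
#'   \code{max_value} and a \code{members} list-column.
#' @examples
#' p <- new("CSPProfile",
#'          values = setNames(c(.5, .5, .5, .01, .5), c(7:9, 10, 30)))
#' co <- new("CutoffPair", meanCutoff = .1, meanPlusSdCutoff = .4,
#'           nValues = 5L, excludedResidues = integer())
#' classifyAndCluster(p, co)$clusters
#' @export
classifyAndCluster <- function(profile, cutoffs, gapTolerance = 1L,
                               minSize = 2L) {
    stopifnot(is(profile, "CSPProfile"), is(cutoffs, "CutoffPair"),
              gapTolerance >= 0, minSize >= 1)
    v <- profile@values
    res <- as.integer(names(v))
    keep <- !(res %in% profile@excluded)
    cls <- ifelse(v[keep] > cutoffs@meanPlusSdCutoff, "above_mean_plus_sd",
                  ifelse(v[keep] > cutoffs@meanCutoff, "above_mean",
                         "below_mean"))
    names(cls) <- res[keep]
    profile@classes <- cls
    validObject(profile)

    sig <- sort(as.integer(names(cls)[cls != "below_mean"]))
    clusters <- data.frame(first = integer(), last = integer(),
                           n_members = integer(), max_value = numeric())
    clusters$members <- list()
    if (length(sig)) {
        ## new cluster whenever the sequence gap exceeds gapTolerance + 1
        grp <- cumsum(c(1L, diff(sig) > gapTolerance + 1L))
        for (g in unique(grp)) {
            mem <- sig[grp == g]
            if (length(mem) < minSize)
                next
            clusters <- rbind(clusters, data.frame(
                first = min(mem), last = max(mem),
                n_members = length(mem),
                max_value = max(v[as.character(mem)]),
                members = I(list(mem))))
        }
        rownames(clusters) <- NULL
    }
    list(profile = profile, clusters = clusters)
}

#' Overlap of significant residues with a hydrophobic patch
#'
#' Reports how many of a patch's four member residues are significantly
#' perturbed (class \code{above_mean} or stronger) and the class each holds.
#'
#' @param profile A classified \linkS4class{CSPProfile} (run
#'   \code{\link{classifyAndCluster}} first).
#' @param patch Patch name (\code{"I44"} or \code{"I36"}) or an integer
#'   vector of member residues.
#' @return A list with \code{patch} (members), \code{n_significant},
#'   \code{fraction}, and \code{classes} (per member; \code{NA} for members
#'   without a class, e.g. unassigned).
#' @export
patchOverlap <- function(profile, patch = c("I44", "I36")) {
    stopifnot(is(profile, "CSPProfile"))
    if (!length(profile@classes))
        stop("profile has no significance classes; run classifyAndCluster()",
             call. = FALSE)
    members <- if (is.character(patch)) hydrophobicPatch(match.arg(patch))
               else as.integer(patch)
    cls <- profile@classes[as.character(members)]
    names(cls) <- members
    nsig <- sum(cls %in% c("above_mean", "above_mean_plus_sd"), na.rm = TRUE)
    list(patch = members, n_significant = nsig,
         fraction = nsig / length(members), classes = cls)
}

#' Pearson correlation between two CSP profiles
#'
#' Computed over the residues shared by both profiles and excluded in
#' neither; used to compare perturbation patterns between variants.
#'
#' @param a,b \linkS4class{CSPProfile} objects with at least 3 shared,
#'   non-excluded residues.
#' @return A list with \code{r} (Pearson correlation) and \code{n_shared}.
#' @export
profileCorrelation <- function(a, b) {
    stopifnot(is(a, "CSPProfile"), is(b, "CSPProfile"))
    shared <- intersect(names(a@values), names(b@values))
    shared <- shared[!(as.integer(shared) %in% c(a@excluded, b@excluded))]
    if (length(shared) < 3L)
        stop("need at least 3 shared non-excluded residues", call. = FALSE)
    x <- a@values[shared]
    y <- b@values[shared]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("correlation undefined: zero variance in one of the profiles",
             call. = FALSE)
    list(r = stats::cor(x, y), n_shared = length(shared))
}

#' Write a CSP profile (and optional cluster table) as TSV
#'
#' @param profile A \linkS4class{CSPProfile}.
#' @param path Output TSV path (columns \code{residue_number},
#'   \code{residue_type}, \code{delta_omega_ppm}, \code{class}).
#' @param clusters Optional cluster \code{data.frame} from
#'   \code{\link{classifyAndCluster}}; written next to \code{path} with
#'   suffix \code{"_clusters.tsv"}.
#' @return Invisibly, \code{path}.
#' @export
writeCSPProfile <- function(profile, path, clusters = NULL) {
    res <- names(profile@values)
    out <- data.frame(residue_number = as.integer(res),
                      residue_type = if (length(profile@residueType))
                          profile@residueType[res] else NA_character_,
                      delta_omega_ppm = sprintf("%.6f", profile@values),
                      class = ifelse(as.integer(res) %in% profile@excluded,
                                     "excluded",
                                     ifelse(res %in% names(profile@classes),
                                            profile@classes[res],
                                            "unclassified")))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(clusters) && nrow(clusters)) {
        cpath <- sub("\\.tsv$", "", path)
        utils::write.table(
            clusters[c("first", "last", "n_members", "max_value")],
            paste0(cpath, "_clusters.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
    }
    invisible(path)
}
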