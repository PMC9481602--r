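#' @include lfq-experiment.R
NULL

#' Load and filter a MaxQuant-style proteinGroups table
#'
#' Applies the standard label-free pre-processing chain, in fixed order:
#' remove reverse-database hits and common contaminants (and, when the
#' column exists, site-only identifications), log2-transform the LFQ
#' intensities (zero = not detected = \code{NA}), then keep only proteins
#' observed in at least \code{minValid} of the \code{nReplicates} runs of at
#' least one bait group (the missing-not-at-random-friendly reading; set
#' \code{validAcross = "all"} for a strict across-all-columns count).
#'
#' @param path TSV with a \code{Protein IDs} column, one
#'   \code{LFQ intensity <sample>} column per run, and \code{Reverse} /
#'   \code{Potential contaminant} marker columns (\code{"+"} = flagged).
#' @param groups Named character vector mapping sample name (the part after
#'   \code{"LFQ intensity "}) to bait-group label.
#' @param minValid Minimum observed values required (default 6).
#' @param nReplicates Runs per bait group (default 8); used only for
#'   validation of the group layout.
#' @param validAcross \code{"any_group"} (default) or \code{"all"}.
#' @param dropSiteOnly Remove \code{Only identified by site} rows when that
#'   column is present (default TRUE).
#' @return An \linkS4class{LFQExperiment}.
#' @export
loadAndFilterLFQ <- function(path, groups, minValid = 6L, nReplicates = 8L,
                             validAcross = c("any_group", "all"),
                             dropSiteOnly = TRUE) {
    validAcross <- match.arg(validAcross)
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (!"Protein IDs" %in% names(tab))
        stop("missing 'Protein IDs' column", call. = FALSE)
    for (col in c("Reverse", "Potential contaminant"))
        if (!col %in% names(tab))
            stop("missing marker column: ", col, call. = FALSE)
    keep <- !(tab$Reverse %in% "+") & !(tab$`Potential contaminant` %in% "+")
    if (dropSiteOnly && "Only identified by site" %in% names(tab))
        keep <- keep & !(tab$`Only identified by site` %in% "+")
    tab <- tab[keep, , drop = FALSE]

    lfqCols <- grep("^LFQ intensity ", names(tab), value = TRUE)
    if (!length(lfqCols))
        stop("no 'LFQ intensity <sample>' columns found", call. = FALSE)
    sampleNames <- sub("^LFQ intensity ", "", lfqCols)
    if (!all(sampleNames %in% names(groups)))
        stop("no bait group for sample(s): ",
             paste(setdiff(sampleNames, names(groups)), collapse = ", "),
             call. = FALSE)
    m <- as.matrix(tab[, lfqCols, drop = FALSE])
    storage.mode(m) <- "double"
    m[m == 0] <- NA            # zero intensity = not detected
    m <- log2(m)
    rownames(m) <- make.unique(tab$`Protein IDs`)
    colnames(m) <- sampleNames
    bait <- unname(groups[sampleNames])

    observed <- !is.na(m)
    keepRow <- if (validAcross == "any_group") {
        perGroup <- vapply(unique(bait), function(g)
            rowSums(observed[, bait == g, drop = FALSE]), numeric(nrow(m)))
        apply(as.matrix(perGroup), 1L, max) >= minValid
    } else {
        rowSums(observed) >= minValid
    }
    m <- m[keepRow, , drop = FALSE]
    LFQExperiment(m, bait = bait)
}

#' Impute left-censored missing values from a downshifted normal
#'
#' Models undetected proteins as lying just below the detection limit: per
#' sample column with observed mean \eqn{\mu} and standard deviation
#' \eqn{\sigma}, each missing entry is drawn independently from
#' \eqn{N(\mu - shift\cdot\sigma, (width\cdot\sigma)^2)}. Observed values
#' are never altered; given the same seed the result is bit-identical.
#'
#' @param object An \linkS4class{LFQExperiment}.
#' @param width,shift Multipliers of the per-column SD (defaults 0.3
#'   and 1.2).
#' @param seed Integer seed (default 1).
#' @return A complete \linkS4class{LFQExperiment}.
#' @export
imputeMissing <- function(object, width = 0.3, shift = 1.2, seed = 1L) {
    stopifnot(is(object, "LFQExperiment"), width > 0, shift >= 0)
    m <- SummarizedExperiment::assay(object, "log2intensity")
    withSeed(seed, {
        for (j in seq_len(ncol(m))) {
            miss <- is.na(m[, j])
            if (!any(miss))
                next
            obsv <- m[!miss, j]
            if (length(obsv) < 2L)
                stop("column ", colnames(m)[j],
                     " has fewer than 2 observed values", call. = FALSE)
            mu <- mean(obsv)
            sg <- stats::sd(obsv)
            m[miss, j] <- stats::rnorm(sum(miss), mean = mu - shift * sg,
                                       sd = width * sg)
        }
    })
    SummarizedExperiment::assay(object, "log2intensity") <- m
    object
}

## Vectorised moderated ANOVA statistic per row:
## d = sqrt(MS_between) / (sqrt(MS_within) + s0).
## s0 penalises proteins whose significance rests on tiny variances alone.
moderatedAnovaStat <- function(m, group, s0) {
    group <- as.factor(group)
    k <- nlevels(group)
    n <- ncol(m)
    G <- stats::model.matrix(~ 0 + group)        # n x k indicator
    ng <- colSums(G)
    gm <- (m %*% G) %*% diag(1 / ng, k)          # row group means
    overall <- rowMeans(m)
    ssb <- as.numeric((gm - overall)^2 %*% ng)
    ssw <- rowSums((m - gm[, as.integer(group), drop = FALSE])^2)
    msb <- ssb / (k - 1)
    msw <- ssw / (n - k)
    d <- sqrt(msb) / (sqrt(msw) + s0)
    d[msb == 0] <- 0      # no between-group signal (incl. the 0/0 case)
    d
}

## All distinct orderings of a label multiset (used to enumerate the label
## permutations completely when the design is small enough).
multisetPermutations <- function(labels) {
    labels <- as.character(labels)
    recurse <- function(remaining) {
        if (length(remaining) == 1L)
            return(list(remaining))
        out <- list()
        for (u in unique(remaining)) {
            rest <- remaining[-match(u, remaining)]
            out <- c(out, lapply(recurse(rest), function(p) c(u, p)))
        }
        out
    }
    recurse(labels)
}

#' Moderated ANOVA with permutation-based FDR
#'
#' Per protein computes the moderated statistic
#' \deqn{d = \sqrt{MS_{between}} \, / \, (\sqrt{MS_{within}} + s_0)}
#' across bait groups; \code{s0 = 0} recovers the square root of the
#' classical one-way F statistic up to a constant, so the ranking equals the
#' F ranking. False-discovery rates come from permuting the column group
#' labels: for each observed value \eqn{d^*},
#' \eqn{q(d^*) = \mathrm{mean}_{perm}\,\#\{d_{perm} \ge d^*\} \, / \,
#' \#\{d_{obs} \ge d^*\}}, capped at 1 and monotonised so that q never
#' decreases as d decreases. When the number of distinct label permutations
#' is small (<= \code{nPermutations}) they are enumerated completely;
#' otherwise random permutations are drawn (seeded).
#'
#' @param object A complete \linkS4class{LFQExperiment} (impute first).
#' @param s0 Moderation constant (default 4).
#' @param fdrTarget Significance threshold on q (default 0.002).
#' @param nPermutations Number of label permutations (default 250).
#' @param seed Integer seed for the permutation draw (default 1).
#' @return \code{data.frame} with \code{protein}, \code{d}, \code{q},
#'   \code{significant}; attribute \code{"n_permutations"} records the count
#'   actually used.
#' @export
anovaS0 <- function(object, s0 = 4, fdrTarget = 0.002, nPermutations = 250L,
                    seed = 1L) {
    stopifnot(is(object, "LFQExperiment"), s0 >= 0,
              fdrTarget > 0, fdrTarget < 1)
    m <- SummarizedExperiment::assay(object, "log2intensity")
    if (anyNA(m))
        stop("matrix has missing values; run imputeMissing() first",
             call. = FALSE)
    group <- baits(object)
    tabg <- table(group)
    if (length(tabg) < 2L || any(tabg < 2L))
        stop("need >= 2 groups with >= 2 columns each", call. = FALSE)

    d <- moderatedAnovaStat(m, group, s0)
    if (any(!is.finite(d)))
        warning("infinite statistic for ", sum(!is.finite(d)),
                " protein(s) (zero within-group variance with s0 = 0)")

    nDistinct <- exp(lfactorial(length(group)) - sum(lfactorial(tabg)))
    perms <- if (nDistinct <= nPermutations) {
        multisetPermutations(group)
    } else {
        withSeed(seed, lapply(seq_len(nPermutations),
                              function(b) sample(group)))
    }
    permD <- unlist(lapply(perms, function(g) moderatedAnovaStat(m, g, s0)),
                    use.names = FALSE)

    ## q(d*) = mean permutation exceedance count / observed exceedance count
    ord <- order(d, decreasing = TRUE)
    dSorted <- d[ord]
    nPermGE <- length(permD) -
        findInterval(dSorted, sort(permD), left.open = TRUE)
    q <- (nPermGE / length(perms)) / seq_along(dSorted)
    q <- pmin(q, 1)
    q <- cummax(q)          # monotone: q non-increasing in d
    qOut <- numeric(length(d))
    qOut[ord] <- q

    out <- data.frame(protein = rownames(m), d = d, q = qOut,
                      significant = qOut <= fdrTarget,
                      row.names = NULL)
    attr(out, "n_permutations") <- length(perms)
    out
}

#' Z-score, bait-median profiles and correlation clustering
#'
#' Restricts to the significant proteins, z-scores each row across all
#' samples (mean 0, SD 1), collapses replicates to the per-bait median, and
#' clusters the proteins hierarchically with distance \code{1 - Pearson}
#' and average linkage. Rows are pre-sorted by protein identifier so the
#' dendrogram and any exact-tie merges are deterministic.
#'
#' @param object The complete \linkS4class{LFQExperiment} used for testing.
#' @param result The \code{\link{anovaS0}} output.
#' @param k Number of clusters to cut the tree into (default 3); \code{NA}
#'   skips cutting.
#' @return A list with \code{zscores} (significant x samples),
#'   \code{medianProfiles} (significant x baits), \code{hclust},
#'   \code{clusters} (named integer vector, when \code{k} is given) and
#'   \code{order} (leaf order). With fewer than 2 significant proteins a
#'   degenerate result is returned with a warning.
#' @export
profileAndCluster <- function(object, result, k = 3L) {
    stopifnot(is(object, "LFQExperiment"))
    m <- SummarizedExperiment::assay(object, "log2intensity")
    sig <- sort(result$protein[result$significant])
    if (length(sig) < 2L) {
        warning("fewer than 2 significant proteins; nothing to cluster")
        return(list(zscores = m[sig, , drop = FALSE],
                    medianProfiles = NULL, hclust = NULL, clusters = NULL,
                    order = sig))
    }
    z <- t(scale(t(m[sig, , drop = FALSE])))   # row mean 0, SD 1
    bait <- baits(object)
    med <- vapply(unique(bait), function(g)
        apply(z[, bait == g, drop = FALSE], 1L, stats::median),
        numeric(nrow(z)))
    corr <- stats::cor(t(med))
    hc <- stats::hclust(stats::as.dist(1 - corr), method = "average")
    cl <- if (!is.na(k) && k >= 1L && k <= nrow(med))
        stats::cutree(hc, k = k) else NULL
    list(zscores = z, medianProfiles = med, hclust = hc, clusters = cl,
         order = rownames(med)[hc$order])
}

#' Bait-bait correlation of enriched-protein profiles
#'
#' Pearson correlation between the per-bait median z-score profiles of the
#' significantly enriched proteins — the interactome-similarity matrix
#' between bait variants.
#'
#' @param profiles Output of \code{\link{profileAndCluster}} with at least 3
#'   significant proteins.
#' @return Symmetric bait x bait correlation matrix with unit diagonal;
#'   zero-variance baits yield \code{NA} entries with a warning.
#' @export
baitCorrelation <- function(profiles) {
    med <- profiles$medianProfiles
    if (is.null(med) || nrow(med) < 3L)
        stop("need >= 3 significant proteins for bait correlations",
             call. = FALSE)
    sds <- apply(med, 2L, stats::sd)
    if (any(sds == 0))
        warning("zero-variance bait profile(s): ",
                paste(colnames(med)[sds == 0], collapse = ", "))
    cc <- suppressWarnings(stats::cor(med))
    diag(cc) <- 1
    cc
}

#' Normalised acetylation signal from targeted MS
#'
#' Ratio of the acetylated-peptide ion signal to the signal of a stably
#' abundant reference peptide (the ubiquitin C-terminal peptide aa 64-73),
#' removing run-to-run loading differences.
#'
#' @param acetylSignal Ion intensity of the acetylated peptide (>= 0).
#' @param referenceSignal Ion intensity of the reference peptide (> 0).
#' @return The ratio \code{acetylSignal / referenceSignal}.
#' @export
prmNormalize <- function(acetylSignal, referenceSignal) {
    stopifnot(all(acetylSignal >= 0))
    if (any(referenceSignal <= 0))
        stop("reference signal must be > 0", call. = FALSE)
    acetylSignal / referenceSignal
}

#' Fraction deacetylated from peak areas
#'
#' @param areaAcetylated,areaDeacetylated Peak areas (>= 0, sum > 0) of the
#'   acetylated and deacetylated protein species.
#' @return \code{areaDeacetylated / (areaAcetylated + areaDeacetylated)}.
#' @export
deacetylationFraction <- function(areaAcetylated, areaDeacetylated) {
    stopifnot(all(areaAcetylated >= 0), all(areaDeacetylated >= 0))
    tot <- areaAcetylated + areaDeacetylated
    if (any(tot == 0))
        stop("total peak area must be > 0", call. = FALSE)
    areaDeacetylated / tot
}
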