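#' @include struct-dist.R titration.R
NULL

## Decompose a target weighted CSP into 1H / 15N shift differences at angle
## theta: dH = w * sqrt(2) * cos(theta), dN = 5 * w * sqrt(2) * sin(theta).
## Plugging into the weighted combination returns w exactly for any theta.
decomposeCSP <- function(w, theta) {
    list(dh = w * sqrt(2) * cos(theta), dn = 5 * w * sqrt(2) * sin(theta))
}

## Base (unperturbed) synthetic HSQC peak positions for n residues: random
## but seeded positions in the typical amide region, plus residue types from
## the ubiquitin sequence when n == 76.
basePeakTable <- function(nResidues, seed) {
    seqv <- if (nResidues == 76L) ubiquitinSequence()
            else stats::setNames(rep("X", nResidues), seq_len(nResidues))
    pro <- which(seqv == "P")
    res <- setdiff(seq_len(nResidues), pro)
    withSeed(seed, data.frame(
        residue_number = res,
        residue_type = unname(seqv[res]),
        shift_h = stats::runif(length(res), 6.5, 10.5),
        shift_n = stats::runif(length(res), 103, 133),
        intensity = stats::runif(length(res), 0.8e6, 1.2e6)))
}

#' Specification for a synthetic reference/variant HSQC pair
#'
#' @param nResidues Protein length (default 76; at that length the residue
#'   types and proline gaps of ubiquitin are used).
#' @param planted \code{data.frame} with \code{residue_number}, \code{dw}
#'   (target weighted CSP, ppm) and optionally \code{theta} (1H/15N
#'   direction angle, radians; default: uniform random per residue, seeded).
#' @param noiseSD Gaussian shift noise SD (ppm), added to both dimensions of
#'   both spectra.
#' @param seed Integer seed.
#' @return A list spec for \code{\link{simulateCSPPair}}.
#' @export
hsqcSimSpec <- function(nResidues = 76L,
                        planted = data.frame(residue_number = c(7L, 8L, 9L),
                                             dw = 0.2),
                        noiseSD = 0, seed = 1L) {
    stopifnot(nResidues >= 1L, noiseSD >= 0)
    if (any(planted$residue_number < 1L |
            planted$residue_number > nResidues))
        stop("planted residues outside 1..nResidues", call. = FALSE)
    list(nResidues = as.integer(nResidues), planted = planted,
         noiseSD = noiseSD, seed = as.integer(seed))
}

#' Simulate a reference/variant peak-list pair with planted perturbations
#'
#' The variant peak of each planted residue is displaced so that the
#' weighted CSP computed on the noiseless pair equals the planted value
#' exactly (the 1H/15N split is controlled by the direction angle theta);
#' all other residues coincide. Gaussian noise of SD \code{noiseSD} is then
#' added independently to both dimensions of both spectra.
#'
#' @param spec A spec from \code{\link{hsqcSimSpec}}.
#' @return List with \code{reference}, \code{variant}
#'   (\linkS4class{PeakList}) and \code{truth} (the planted table with the
#'   realised \code{theta}).
#' @export
simulateCSPPair <- function(spec) {
    base <- basePeakTable(spec$nResidues, spec$seed)
    planted <- spec$planted
    withSeed(spec$seed + 1L, {
        if (is.null(planted$theta))
            planted$theta <- stats::runif(nrow(planted), 0, 2 * pi)
        var <- base
        i <- match(planted$residue_number, var$residue_number)
        if (anyNA(i))
            stop("planted residue has no amide peak (proline?)",
                 call. = FALSE)
        dec <- decomposeCSP(planted$dw, planted$theta)
        var$shift_h[i] <- var$shift_h[i] + dec$dh
        var$shift_n[i] <- var$shift_n[i] + dec$dn
        ref <- base
        if (spec$noiseSD > 0) {
            n <- nrow(base)
            ref$shift_h <- ref$shift_h + stats::rnorm(n, 0, spec$noiseSD)
            ref$shift_n <- ref$shift_n + stats::rnorm(n, 0, spec$noiseSD)
            var$shift_h <- var$shift_h + stats::rnorm(n, 0, spec$noiseSD)
            var$shift_n <- var$shift_n + stats::rnorm(n, 0, spec$noiseSD)
        }
        list(reference = PeakList(ref, label = "reference"),
             variant = PeakList(var, label = "variant"),
             truth = planted)
    })
}

#' Specification for a synthetic HSQC titration
#'
#' The defaults reproduce the low-concentration titration design of the
#' ubiquitin/UBA interaction study: protein start 33 uM in 500 uL, ligand
#' stock 803 uM, seven additions reaching roughly three-fold molar excess,
#' and six reporter residues with distinct saturation amplitudes.
#'
#' @param kd Generating dissociation constant (uM).
#' @param dmax Named numeric: saturation CSP (ppm) per reporter residue.
#'   Default: the study's six fit reporters T14, L43, F45, E51, L67, L71
#'   with amplitudes 0.05..0.5 ppm.
#' @param startProtein,startVolume,ligandStock,addedVolumes Dilution scheme
#'   (see \code{\link{concentrationsFromScheme}}).
#' @param broadeningBeta Named numeric in [0, 1]: exchange-broadening
#'   coefficient per residue; the intensity at a step is
#'   \code{I0 * (1 - beta * fractionBound)}, so beta near 1 drives a residue
#'   past the 90\%-loss exclusion near saturation. Default 0 for all.
#' @param nResidues Protein length (default 76).
#' @param noiseSD Gaussian CSP noise SD (ppm).
#' @param seed Integer seed.
#' @return A list spec for \code{\link{simulateTitration}}.
#' @export
titrationSimSpec <- function(kd = 8,
                             dmax = stats::setNames(
                                 seq(0.05, 0.5, length.out = 6),
                                 c(14L, 43L, 45L, 51L, 67L, 71L)),
                             startProtein = 33, startVolume = 500,
                             ligandStock = 803,
                             addedVolumes = c(4, 5, 7, 9, 11, 12, 14),
                             broadeningBeta = numeric(), nResidues = 76L,
                             noiseSD = 0, seed = 1L) {
    stopifnot(kd > 0, all(dmax >= 0), noiseSD >= 0)
    if (length(broadeningBeta) &&
        (any(broadeningBeta < 0) || any(broadeningBeta > 1)))
        stop("broadeningBeta must lie in [0, 1]", call. = FALSE)
    list(kd = kd, dmax = dmax, startProtein = startProtein,
         startVolume = startVolume, ligandStock = ligandStock,
         addedVolumes = addedVolumes, broadeningBeta = broadeningBeta,
         nResidues = as.integer(nResidues), noiseSD = noiseSD,
         seed = as.integer(seed))
}

#' Simulate an HSQC titration series from the 1:1 binding quadratic
#'
#' Per step and reporter residue the noiseless CSP follows the exact 1:1
#' isotherm at that step's concentrations; Gaussian noise (\code{noiseSD})
#' is added on the CSP scale and the displacement decomposed into 1H/15N
#' peak positions with a fixed random angle per residue. Peak intensities
#' decay as \code{I0 * (1 - beta * fractionBound)} for residues with a
#' broadening coefficient.
#'
#' @param spec A spec from \code{\link{titrationSimSpec}}.
#' @return List with \code{series} (a \linkS4class{TitrationSeries}) and
#'   \code{truth} (kd, dmax, residues, per-step concentrations).
#' @export
simulateTitration <- function(spec) {
    conc <- concentrationsFromScheme(spec$startProtein, spec$startVolume,
                                     spec$ligandStock, spec$addedVolumes)
    base <- basePeakTable(spec$nResidues, spec$seed)
    resFit <- as.integer(names(spec$dmax))
    if (!all(resFit %in% base$residue_number))
        stop("reporter residue without amide peak", call. = FALSE)
    beta <- rep(0, nrow(base))
    names(beta) <- base$residue_number
    if (length(spec$broadeningBeta))
        beta[names(spec$broadeningBeta)] <- spec$broadeningBeta

    withSeed(spec$seed + 2L, {
        theta <- stats::runif(length(resFit), 0, 2 * pi)
        steps <- lapply(seq_len(nrow(conc)), function(s) {
            tab <- base
            fb <- boundFraction(conc$protein_conc[s], conc$ligand_conc[s],
                                spec$kd)
            i <- match(resFit, tab$residue_number)
            w <- spec$dmax * fb
            if (spec$noiseSD > 0 && s > 1L)
                w <- pmax(w + stats::rnorm(length(w), 0, spec$noiseSD), 0)
            dec <- decomposeCSP(w, theta)
            tab$shift_h[i] <- tab$shift_h[i] + dec$dh
            tab$shift_n[i] <- tab$shift_n[i] + dec$dn
            ## exchange broadening: proportional to the bound fraction
            tab$intensity <- tab$intensity *
                (1 - beta[as.character(tab$residue_number)] * fb)
            PeakList(tab, label = sprintf("step %d", s - 1L))
        })
        list(series = TitrationSeries(steps,
                                      proteinConc = conc$protein_conc,
                                      ligandConc = conc$ligand_conc,
                                      label = "synthetic titration"),
             truth = list(kd = spec$kd, dmax = spec$dmax,
                          residues = resFit, concentrations = conc,
                          theta = theta))
    })
}

#' Specification for a synthetic label-free AE-MS intensity table
#'
#' Defaults emulate the structure of an eight-bait affinity-enrichment
#' screen: 300 background proteins plus three planted interactor clusters
#' (20 proteins each) enriched by 4-6 log2 units in bait-specific subsets,
#' log-normal baseline abundance, Gaussian noise and left-censoring at a
#' detection limit.
#'
#' @param nProteins Number of background (non-interactor) proteins.
#' @param baits Bait-group labels (default \code{bait1..bait8}).
#' @param nReplicates Runs per bait (default 8).
#' @param clusterSize Proteins per planted interactor cluster (default 20;
#'   three clusters are planted on bait subsets 1-3, 4-6 and 7-8).
#' @param effectRange Range of planted log2 enrichment (default 4..6).
#' @param baselineMean,baselineSD Log2 baseline abundance distribution
#'   (defaults 25 and 2).
#' @param noiseSD Log2 measurement noise (default 0.5).
#' @param detectionLimit Log2 detection threshold; simulated values below
#'   it are censored to missing (default 22; \code{-Inf} disables
#'   censoring).
#' @param seed Integer seed.
#' @return A list spec for \code{\link{simulateLFQ}}.
#' @export
lfqSimSpec <- function(nProteins = 300L,
                       baits = paste0("bait", 1:8), nReplicates = 8L,
                       clusterSize = 20L, effectRange = c(4, 6),
                       baselineMean = 25, baselineSD = 2, noiseSD = 0.5,
                       detectionLimit = 22, seed = 1L) {
    stopifnot(nProteins >= 1L, nReplicates >= 2L, length(baits) >= 2L,
              noiseSD >= 0)
    list(nProteins = as.integer(nProteins), baits = baits,
         nReplicates = as.integer(nReplicates),
         clusterSize = as.integer(clusterSize), effectRange = effectRange,
         baselineMean = baselineMean, baselineSD = baselineSD,
         noiseSD = noiseSD, detectionLimit = detectionLimit,
         seed = as.integer(seed))
}

#' Simulate a raw-scale LFQ intensity table with planted interactors
#'
#' Each protein's log2 intensity is baseline + bait effect + noise; values
#' below the detection limit are censored to missing (missing not at
#' random). Three interactor clusters are planted on fixed bait subsets
#' (baits 1-3, 4-6 and the remainder) with per-protein effects drawn from
#' \code{effectRange}. The table is exported on the raw intensity scale with
#' optional reverse/contaminant decoy rows, in the MaxQuant-style layout
#' consumed by \code{\link{loadAndFilterLFQ}}.
#'
#' @param spec A spec from \code{\link{lfqSimSpec}}.
#' @param decoys Number of reverse and of contaminant decoy rows to inject
#'   (default 2 each).
#' @return List with \code{table} (the raw-scale \code{data.frame}),
#'   \code{groups} (sample-to-bait map for \code{\link{loadAndFilterLFQ}})
#'   and \code{truth} (cluster label per protein, 0 = background).
#' @export
simulateLFQ <- function(spec, decoys = 2L) {
    nB <- length(spec$baits)
    third <- ceiling(nB / 3)
    baitSets <- list(seq_len(third),
                     seq.int(third + 1L, min(2L * third, nB)),
                     seq.int(min(2L * third, nB) + 1L, nB))
    samples <- paste0(rep(spec$baits, each = spec$nReplicates), "_r",
                      rep(seq_len(spec$nReplicates), nB))
    baitOfSample <- rep(spec$baits, each = spec$nReplicates)

    withSeed(spec$seed, {
        nClust <- 3L * spec$clusterSize
        nTot <- spec$nProteins + nClust
        cluster <- c(rep(0L, spec$nProteins),
                     rep(1:3, each = spec$clusterSize))
        baseline <- stats::rnorm(nTot, spec$baselineMean, spec$baselineSD)
        eff <- matrix(0, nTot, nB, dimnames = list(NULL, spec$baits))
        for (cl in 1:3) {
            rows <- which(cluster == cl)
            eff[rows, baitSets[[cl]]] <-
                stats::runif(length(rows), spec$effectRange[1L],
                             spec$effectRange[2L])
        }
        log2m <- baseline +
            eff[, match(baitOfSample, spec$baits), drop = FALSE] +
            matrix(stats::rnorm(nTot * length(samples), 0, spec$noiseSD),
                   nTot, length(samples))
        log2m[log2m < spec$detectionLimit] <- NA
        raw <- 2^log2m
        raw[is.na(raw)] <- 0
        colnames(raw) <- paste0("LFQ intensity ", samples)

        ids <- sprintf("PROT%04d", seq_len(nTot))
        tab <- data.frame(`Protein IDs` = ids, check.names = FALSE)
        tab$Reverse <- ""
        tab$`Potential contaminant` <- ""
        tab <- cbind(tab, as.data.frame(raw, check.names = FALSE))
        if (decoys > 0L) {
            mkDecoy <- function(prefix, marker) {
                d <- tab[sample.int(nTot, decoys), , drop = FALSE]
                d$`Protein IDs` <- paste0(prefix,
                                          sprintf("%02d", seq_len(decoys)))
                d[[marker]] <- "+"
                d
            }
            tab <- rbind(tab, mkDecoy("REV__", "Reverse"),
                         mkDecoy("CON__", "Potential contaminant"))
        }
        rownames(tab) <- NULL
        list(table = tab,
             groups = stats::setNames(baitOfSample, samples),
             truth = stats::setNames(cluster, ids))
    })
}

#' Simulate a coordinate ensemble with jitter and planted displacement
#'
#' Builds an extended-chain template (one residue every 0.5 nm along x,
#' \code{atomsPerResidue} dummy atoms spread 0.05 nm around each centre),
#' applies an optional systematic displacement to selected residues, and
#' adds independent Gaussian jitter per frame.
#'
#' @param nResidues Number of residues (default 10).
#' @param atomsPerResidue Atoms per residue (default 3).
#' @param jitterSD Per-coordinate Gaussian jitter SD (nm, default 0).
#' @param displacement \code{NULL}, or a list with \code{residues} (integer
#'   set) and \code{vector} (length-3 numeric, nm) applied to every frame.
#' @param nFrames Number of frames (default 5).
#' @param spacing Residue spacing along the chain axis (nm, default 0.5).
#' @param seed Integer seed.
#' @return A \linkS4class{StructureEnsemble}.
#' @export
simulateEnsemble <- function(nResidues = 10L, atomsPerResidue = 3L,
                             jitterSD = 0, displacement = NULL,
                             nFrames = 5L, spacing = 0.5, seed = 1L) {
    stopifnot(jitterSD >= 0, nResidues >= 1L, atomsPerResidue >= 1L,
              nFrames >= 1L)
    nAtoms <- nResidues * atomsPerResidue
    resOfAtom <- rep(seq_len(nResidues), each = atomsPerResidue)
    ## template: residue centres on the x axis, atoms offset deterministically
    offs <- seq(-0.05, 0.05, length.out = atomsPerResidue)
    template <- cbind(x = resOfAtom * spacing,
                      y = rep(offs, nResidues),
                      z = 0)
    if (!is.null(displacement)) {
        i <- resOfAtom %in% displacement$residues
        template[i, ] <- sweep(template[i, , drop = FALSE], 2L,
                               displacement$vector, `+`)
    }
    coords <- withSeed(seed, {
        a <- array(rep(template, nFrames), dim = c(nAtoms, 3L, nFrames))
        if (jitterSD > 0)
            a <- a + array(stats::rnorm(length(a), 0, jitterSD), dim = dim(a))
        a
    })
    new("StructureEnsemble", label = "synthetic ensemble", coords = coords,
        atomResidue = resOfAtom,
        atomName = rep(paste0("C", seq_len(atomsPerResidue)), nResidues),
        atomElement = rep("C", nAtoms),
        residueType = stats::setNames(rep("GLY", nResidues),
                                      seq_len(nResidues)))
}
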