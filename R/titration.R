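#' @include csp-core.R
NULL

#' Per-step concentrations from a cumulative dilution scheme
#'
#' Converts a titration scheme (protein start concentration and volume,
#' ligand stock concentration, volume added at each step) into total
#' concentrations per step:
#' \deqn{[P]_t = P_0 V_0 / (V_0 + \sum\Delta V), \qquad
#'       [L]_t = L_{stock} \sum\Delta V / (V_0 + \sum\Delta V).}
#'
#' @param startProtein Protein concentration before the first addition
#'   (conventionally micromolar).
#' @param startVolume Sample volume before the first addition (microlitre).
#' @param ligandStock Ligand stock concentration (same units as
#'   \code{startProtein}).
#' @param addedVolumes Volume of stock added at each step after step 0
#'   (microlitre, all > 0).
#' @return \code{data.frame} with \code{step_index}, \code{added_uL},
#'   \code{protein_conc}, \code{ligand_conc}; row 1 is the ligand-free
#'   step 0.
#' @examples
#' concentrationsFromScheme(33, 500, 803, c(10, 10))
#' @export
concentrationsFromScheme <- function(startProtein, startVolume, ligandStock,
                                     addedVolumes) {
    stopifnot(startProtein > 0, startVolume > 0, ligandStock > 0)
    if (any(addedVolumes <= 0))
        stop("added volumes must be positive", call. = FALSE)
    cum <- c(0, cumsum(addedVolumes))
    vol <- startVolume + cum
    data.frame(step_index = seq_along(cum) - 1L,
               added_uL = c(0, addedVolumes),
               protein_conc = startProtein * startVolume / vol,
               ligand_conc = ligandStock * cum / vol)
}

#' CSP profile of each titration step relative to step 0
#'
#' Applies \code{\link{weightedCSP}} between every step and the ligand-free
#' reference spectrum. A residue missing at some step (typically broadened
#' beyond detection) is simply absent from that step's profile.
#'
#' @param series A \linkS4class{TitrationSeries}.
#' @return Named list of \linkS4class{CSPProfile}, one per step > 0, names
#'   \code{"step<i>"}.
#' @export
perStepCSP <- function(series) {
    stopifnot(is(series, "TitrationSeries"))
    ref <- series@steps[[1L]]
    out <- lapply(seq_along(series@steps)[-1L], function(i)
        weightedCSP(ref, series@steps[[i]],
                    label = sprintf("%s step %d", series@label,
                                    series@stepIndex[i])))
    names(out) <- sprintf("step%d", series@stepIndex[-1L])
    out
}

#' Intensity attrition over a titration
#'
#' Fraction of the step-0 peak intensity remaining at the final step for
#' every residue. Residues losing more than 90\% of their intensity
#' (fraction strictly below 0.10) are flagged as exchange-broadened and are
#' excluded from Kd fitting; a residue absent at the final step gets
#' fraction 0. The boundary is strict: exactly 90\% loss is \emph{not}
#' flagged.
#'
#' @param series A \linkS4class{TitrationSeries} with intensities at step 0.
#' @param threshold Remaining-intensity fraction below which a residue is
#'   flagged (default 0.10, i.e. "more than 90\% decrease").
#' @return \code{data.frame} with \code{residue_number}, \code{fraction},
#'   \code{flagged}. Residues with zero or missing step-0 intensity are
#'   skipped with a warning.
#' @export
intensityAttrition <- function(series, threshold = 0.10) {
    stopifnot(is(series, "TitrationSeries"))
    p0 <- peaks(series@steps[[1L]])
    pf <- peaks(series@steps[[length(series@steps)]])
    if (all(is.na(p0$intensity)))
        stop("step 0 carries no intensities", call. = FALSE)
    bad <- is.na(p0$intensity) | p0$intensity == 0
    if (any(bad))
        warning("skipping residue(s) with zero/missing step-0 intensity: ",
                paste(p0$residue_number[bad], collapse = ", "))
    p0 <- p0[!bad, , drop = FALSE]
    fin <- pf$intensity[match(p0$residue_number, pf$residue_number)]
    frac <- ifelse(is.na(fin), 0, fin) / p0$intensity
    data.frame(residue_number = p0$residue_number, fraction = frac,
               flagged = frac < threshold)
}

#' Select residues for global Kd fitting
#'
#' A residue qualifies if it is significantly perturbed (class
#' \code{above_mean} or stronger at the titration endpoint) in \emph{every}
#' experiment and intensity-flagged in \emph{none} — mirroring the selection
#' of well-behaved fast-exchange reporters across parallel titrations.
#'
#' @param endpointProfiles List of endpoint \linkS4class{CSPProfile}, one
#'   per experiment.
#' @param cutoffs List of \linkS4class{CutoffPair} (one per experiment, the
#'   default) or a single pooled \linkS4class{CutoffPair} applied to all.
#' @param attrition List of attrition \code{data.frame}s from
#'   \code{\link{intensityAttrition}}, one per experiment.
#' @return Sorted integer vector of selected residues; an empty selection is
#'   an error (the fit could not proceed).
#' @export
selectFitResidues <- function(endpointProfiles, cutoffs, attrition) {
    if (is(endpointProfiles, "CSPProfile"))
        endpointProfiles <- list(endpointProfiles)
    n <- length(endpointProfiles)
    stopifnot(n >= 1L)
    if (is(cutoffs, "CutoffPair"))
        cutoffs <- rep(list(cutoffs), n)
    if (is.data.frame(attrition))
        attrition <- list(attrition)
    stopifnot(length(cutoffs) == n, length(attrition) == n)
    sigSets <- lapply(seq_len(n), function(i) {
        v <- endpointProfiles[[i]]@values
        as.integer(names(v)[v > cutoffs[[i]]@meanCutoff])
    })
    flagged <- unique(unlist(lapply(attrition, function(a)
        a$residue_number[a$flagged])))
    sel <- sort(setdiff(Reduce(intersect, sigSets), flagged))
    if (!length(sel))
        stop("empty selection: no residue is significant in every ",
             "experiment and unflagged in all", call. = FALSE)
    sel
}

#' Exact 1:1 binding isotherm
#'
#' Observed CSP of a residue at total protein concentration P and total
#' ligand concentration L for a binary complex with dissociation constant
#' \code{kd} and saturation amplitude \code{dmax}:
#' \deqn{\Delta\omega^{obs} = \Delta\omega^{max}
#'   \frac{P + L + K_d - \sqrt{(P + L + K_d)^2 - 4 P L}}{2P}.}
#' The discriminant is clamped at zero against floating-point round-off, so
#' the stoichiometric limit \code{kd -> 0} is exact.
#'
#' @param P Total protein concentration (> 0); recycled with \code{L}.
#' @param L Total ligand concentration (>= 0).
#' @param kd Dissociation constant (>= 0), same units as the concentrations.
#' @param dmax Saturation CSP (ppm).
#' @return Observed CSP (ppm), same length as \code{P}/\code{L}.
#' @examples
#' bindingIsotherm(33, 33, kd = 8, dmax = 1)   # 0.6141
#' bindingIsotherm(33, 66, kd = 0, dmax = 1)   # saturated: 1
#' @export
bindingIsotherm <- function(P, L, kd, dmax) {
    if (any(P <= 0))
        stop("protein concentration must be > 0", call. = FALSE)
    stopifnot(all(L >= 0), kd >= 0, all(dmax >= 0))
    s <- P + L + kd
    disc <- pmax(s^2 - 4 * P * L, 0)
    dmax * (s - sqrt(disc)) / (2 * P)
}

## Bound fraction (isotherm with dmax = 1); shared shape of all residues.
boundFraction <- function(P, L, kd) bindingIsotherm(P, L, kd, dmax = 1)

## Assemble the (residue, step) observation table for fitting: observed CSP
## of each selected residue at each step > 0 plus the step concentrations.
## Residues broadened out at a step contribute only their observed steps.
titrationObservations <- function(series, residues) {
    profs <- perStepCSP(series)
    idx <- seq_along(series@steps)[-1L]
    do.call(rbind, lapply(seq_along(profs), function(k) {
        v <- profs[[k]]@values
        keep <- names(v)[as.integer(names(v)) %in% residues]
        if (!length(keep))
            return(NULL)
        data.frame(residue_number = as.integer(keep),
                   step_index = series@stepIndex[idx[k]],
                   P = series@proteinConc[idx[k]],
                   L = series@ligandConc[idx[k]],
                   observed = unname(v[keep]))
    }))
}

## Profile reduction: for fixed kd each residue's dmax has the closed-form
## least-squares solution dmax_r = sum(y f) / sum(f^2) with f the bound
## fraction, truncated at 0 to honour dmax >= 0.
profiledSSR <- function(kd, obs) {
    f <- boundFraction(obs$P, obs$L, kd)
    num <- tapply(obs$observed * f, obs$residue_number, sum)
    den <- tapply(f * f, obs$residue_number, sum)
    dmax <- pmax(as.numeric(num) / pmax(as.numeric(den), .Machine$double.eps),
                 0)
    names(dmax) <- names(num)
    fitted <- dmax[as.character(obs$residue_number)] * f
    list(ssr = sum((obs$observed - fitted)^2), dmax = dmax, fitted = fitted)
}

#' Global 1:1 binding fit for a shared Kd
#'
#' Minimises the summed squared deviation between the observed per-step CSPs
#' of the selected residues and the exact 1:1 isotherm with \emph{one}
#' shared Kd and one saturation amplitude per residue. For fixed Kd every
#' amplitude has a closed-form least-squares solution, so the optimisation
#' is a one-dimensional search on log10(Kd) over \code{bounds}
#' (default 1e-3 .. 1e5, enforcing positivity), refined by golden-section /
#' parabolic interpolation. The Kd standard error is the asymptotic estimate
#' from the Jacobian of the full residual vector at the optimum; an optional
#' residual bootstrap gives a percentile confidence interval.
#'
#' @param series A \linkS4class{TitrationSeries} with at least 2 informative
#'   steps.
#' @param residues Residues to fit (e.g. from
#'   \code{\link{selectFitResidues}}).
#' @param bounds Kd search interval (same units as the concentrations).
#' @param bootstrap Number of residual-bootstrap replicates (0 = none).
#' @param seed Seed for the bootstrap resampling.
#' @return A \linkS4class{BindingFitResult}.
#' @examples
#' sim <- simulateTitration(titrationSimSpec(kd = 8, noiseSD = 0))
#' fit <- fitGlobalKd(sim$series, residues = sim$truth$residues)
#' kd(fit)
#' @export
fitGlobalKd <- function(series, residues, bounds = c(1e-3, 1e5),
                        bootstrap = 0L, seed = 1L) {
    stopifnot(is(series, "TitrationSeries"), length(residues) >= 1L)
    obs <- titrationObservations(series, residues)
    if (is.null(obs) || nrow(obs) < length(unique(obs$residue_number)) + 1L)
        stop("unidentifiable: fewer observations than parameters ",
             "(need >= 2 informative titration steps)", call. = FALSE)

    objective <- function(lk) profiledSSR(10^lk, obs)$ssr
    lb <- log10(bounds)
    ## coarse bracket on a log grid, then 1-D refinement
    grid <- seq(lb[1L], lb[2L], length.out = 161L)
    ssr <- vapply(grid, objective, numeric(1))
    i <- which.min(ssr)
    lo <- grid[max(1L, i - 1L)]
    hi <- grid[min(length(grid), i + 1L)]
    opt <- stats::optimize(objective, lower = lo, upper = hi,
                           tol = .Machine$double.eps^0.5)
    kdHat <- 10^opt$minimum
    sol <- profiledSSR(kdHat, obs)
    atBound <- opt$minimum <= lb[1L] + 1e-6 || opt$minimum >= lb[2L] - 1e-6
    converged <- is.finite(opt$objective) && !atBound

    resTab <- data.frame(residue_number = obs$residue_number,
                         step_index = obs$step_index,
                         observed = obs$observed,
                         fitted = unname(sol$fitted),
                         residual = obs$observed - unname(sol$fitted))

    kdSE <- kdAsymptoticSE(kdHat, sol$dmax, obs, sol$ssr)
    ci <- numeric()
    if (bootstrap > 0L) {
        ci <- withSeed(seed, {
            kds <- vapply(seq_len(bootstrap), function(b) {
                ob <- obs
                ob$observed <- pmax(sol$fitted +
                    sample(resTab$residual, nrow(ob), replace = TRUE), 0)
                g <- vapply(grid, function(lk) profiledSSR(10^lk, ob)$ssr,
                            numeric(1))
                j <- which.min(g)
                o <- stats::optimize(function(lk) profiledSSR(10^lk, ob)$ssr,
                                     lower = grid[max(1L, j - 1L)],
                                     upper = grid[min(length(grid), j + 1L)],
                                     tol = 1e-8)
                10^o$minimum
            }, numeric(1))
            unname(stats::quantile(kds, c(0.025, 0.975)))
        })
    }

    new("BindingFitResult", kd = kdHat, kdSE = kdSE, kdCI = ci,
        dmax = sol$dmax[as.character(sort(unique(obs$residue_number)))],
        residuals = resTab, converged = converged, atBound = atBound,
        nPoints = nrow(obs))
}

## Asymptotic SE of kd from the Jacobian of the residual vector with respect
## to (log10 kd, dmax_1..dmax_R), via the delta method back to the kd scale.
kdAsymptoticSE <- function(kdHat, dmax, obs, ssr) {
    resFun <- function(par) {
        kd <- 10^par[1L]
        dm <- par[-1L]
        names(dm) <- names(dmax)
        f <- boundFraction(obs$P, obs$L, kd)
        obs$observed - dm[as.character(obs$residue_number)] * f
    }
    par0 <- c(log10(kdHat), dmax)
    J <- vapply(seq_along(par0), function(j) {
        h <- max(1e-6, abs(par0[j]) * 1e-6)
        pp <- par0; pp[j] <- pp[j] + h
        pm <- par0; pm[j] <- pm[j] - h
        (resFun(pp) - resFun(pm)) / (2 * h)
    }, numeric(nrow(obs)))
    dof <- nrow(obs) - length(par0)
    if (dof < 1L)
        return(NA_real_)
    s2 <- ssr / dof
    cv <- tryCatch(solve(crossprod(J)), error = function(e) NULL)
    if (is.null(cv))
        return(NA_real_)
    seLog <- sqrt(s2 * cv[1L, 1L])
    seLog * log(10) * kdHat       # delta method: d(kd)/d(log10 kd)
}

#' Write a binding-fit report
#'
#' @param fit A \linkS4class{BindingFitResult}.
#' @param path Base path; writes \code{<path>.tsv} (per-residue amplitudes)
#'   and \code{<path>.json} (Kd, SE, diagnostics).
#' @return Invisibly, the JSON path.
#' @export
writeFitReport <- function(fit, path) {
    tsv <- data.frame(residue_number = as.integer(names(fit@dmax)),
                      dmax_ppm = sprintf("%.6f", fit@dmax))
    utils::write.table(tsv, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    rep <- list(kd = fit@kd, kd_se = fit@kdSE,
                kd_ci = if (length(fit@kdCI)) fit@kdCI else NULL,
                n_points = fit@nPoints, converged = fit@converged,
                at_bound = fit@atBound,
                dmax = as.list(fit@dmax))
    jsonlite::write_json(rep, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(paste0(path, ".json"))
}
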