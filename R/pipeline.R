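#' @include synthetic-data.R aems-stats.R
NULL

## Defaults shared by every pipeline stage; a config file overrides fields
## individually. These are the workflow's canonical constants: S0 = 4,
## FDR = 0.002, imputation width 0.3 / shift 1.2, >= 6/8 valid values,
## 1 nm distance cutoff, 90% attrition threshold.
pipelineDefaults <- function() {
    list(seed = 1L,
         csp = list(gap_tolerance = 1L, min_size = 2L, excluded = list()),
         titrate = list(bootstrap = 0L),
         interactome = list(min_valid = 6L, n_replicates = 8L, width = 0.3,
                            shift = 1.2, s0 = 4, fdr_target = 0.002,
                            n_permutations = 250L, k = 3L),
         distmat = list(cutoff = 1.0, heavy_only = FALSE))
}

mergeConfig <- function(defaults, config) {
    for (nm in names(config)) {
        defaults[[nm]] <- if (is.list(config[[nm]]) &&
                              is.list(defaults[[nm]]))
            mergeConfig(defaults[[nm]], config[[nm]]) else config[[nm]]
    }
    defaults
}

requireFields <- function(cfg, fields, where) {
    miss <- setdiff(fields, names(cfg))
    if (length(miss))
        stop("config block '", where, "' is missing field(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
}

checkInputs <- function(paths) {
    absent <- paths[!file.exists(paths)]
    if (length(absent))
        stop("input path(s) not found: ", paste(absent, collapse = ", "),
             call. = FALSE)
    invisible(paths)
}

#' Run a pipeline stage from a configuration
#'
#' Config-driven orchestration of the analysis stages. The configuration is
#' a YAML file (or an equivalent named list) with a block per subcommand;
#' defaults for every threshold equal the workflow's canonical constants
#' (S0 = 4, FDR = 0.002, imputation width 0.3 / shift 1.2, >= 6 of 8 valid
#' values, 1 nm distance cutoff, 90\% attrition). All stage outputs are
#' written below \code{outDir}; a JSON run report records the package
#' version, the merged configuration, every seed, and MD5 checksums of the
#' inputs. Inputs are never modified. With identical configuration and
#' seeds the outputs are byte-identical.
#'
#' Subcommands and their config blocks:
#' \describe{
#'   \item{\code{csp}}{\code{reference}, \code{variant} (peak-list paths),
#'     \code{dialect}, optional \code{excluded} residues; writes the CSP
#'     profile and cluster TSVs.}
#'   \item{\code{titrate}}{\code{steps} (peak-list paths in step order),
#'     \code{dialect}, and either \code{protein_conc} + \code{ligand_conc}
#'     per step or a \code{scheme} block
#'     (\code{start_protein_uM}, \code{start_volume_uL},
#'     \code{ligand_stock_uM}, \code{added_uL}); writes attrition, selected
#'     residues and the fit report.}
#'   \item{\code{interactome}}{\code{table} (proteinGroups TSV),
#'     \code{groups} (sample-to-bait map); writes statistics, z-scored
#'     profiles and the bait correlation matrix.}
#'   \item{\code{distmat}}{\code{ensembles} (multi-model PDB paths; the
#'     first is the reference), optional \code{pair} (two residues); writes
#'     distance and difference matrices.}
#'   \item{\code{simulate}}{\code{what}: \code{"csp"}, \code{"titration"},
#'     \code{"lfq"} or \code{"ensemble"}; writes the simulated input files
#'     plus a ground-truth JSON sidecar.}
#' }
#'
#' @param subcommand One of \code{"csp"}, \code{"titrate"},
#'   \code{"interactome"}, \code{"distmat"}, \code{"simulate"}.
#' @param config Path to a YAML file or a named list.
#' @param outDir Output directory (created if needed).
#' @param seed Overrides the config seed when not \code{NULL}.
#' @return Invisibly, the run-report list (also written as
#'   \code{run_report.json}).
#' @export
runPipeline <- function(subcommand = c("csp", "titrate", "interactome",
                                       "distmat", "simulate"),
                        config, outDir, seed = NULL) {
    subcommand <- match.arg(subcommand)
    cfgIn <- if (is.character(config)) {
        checkInputs(config)
        yaml::read_yaml(config)
    } else config
    cfg <- mergeConfig(pipelineDefaults(), cfgIn)
    if (!is.null(seed))
        cfg$seed <- as.integer(seed)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

    inputs <- character()
    artifacts <- switch(subcommand,
        csp = {
            blk <- cfg$csp
            requireFields(blk, c("reference", "variant"), "csp")
            inputs <- checkInputs(c(blk$reference, blk$variant))
            dialect <- blk$dialect %||% "tsv"
            ref <- readPeakList(blk$reference, dialect)
            var <- readPeakList(blk$variant, dialect)
            prof <- weightedCSP(ref, var,
                                excluded = unlist(blk$excluded))
            co <- significanceCutoffs(prof)
            cc <- classifyAndCluster(prof, co,
                                     gapTolerance = blk$gap_tolerance,
                                     minSize = blk$min_size)
            writeCSPProfile(cc$profile, file.path(outDir, "csp_profile.tsv"),
                            clusters = cc$clusters)
            c("csp_profile.tsv", "csp_profile_clusters.tsv")
        },
        titrate = {
            blk <- cfg$titrate
            requireFields(blk, "steps", "titrate")
            inputs <- checkInputs(unlist(blk$steps))
            dialect <- blk$dialect %||% "tsv"
            steps <- lapply(unlist(blk$steps), readPeakList,
                            dialect = dialect)
            if (!is.null(blk$scheme)) {
                s <- blk$scheme
                requireFields(s, c("start_protein_uM", "start_volume_uL",
                                   "ligand_stock_uM", "added_uL"),
                              "titrate$scheme")
                conc <- concentrationsFromScheme(s$start_protein_uM,
                                                 s$start_volume_uL,
                                                 s$ligand_stock_uM,
                                                 unlist(s$added_uL))
                pconc <- conc$protein_conc
                lconc <- conc$ligand_conc
            } else {
                requireFields(blk, c("protein_conc", "ligand_conc"),
                              "titrate")
                pconc <- unlist(blk$protein_conc)
                lconc <- unlist(blk$ligand_conc)
            }
            series <- TitrationSeries(steps, pconc, lconc,
                                      label = "titration")
            att <- intensityAttrition(series)
            utils::write.table(att, file.path(outDir, "attrition.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
            profs <- perStepCSP(series)
            endpoint <- profs[[length(profs)]]
            co <- significanceCutoffs(endpoint)
            sel <- if (!is.null(blk$residues)) as.integer(unlist(blk$residues))
                   else selectFitResidues(endpoint, co, att)
            writeLines(as.character(sel),
                       file.path(outDir, "fit_residues.txt"))
            fit <- fitGlobalKd(series, sel, bootstrap = blk$bootstrap,
                               seed = cfg$seed)
            writeFitReport(fit, file.path(outDir, "fit_report"))
            c("attrition.tsv", "fit_residues.txt", "fit_report.tsv",
              "fit_report.json")
        },
        interactome = {
            blk <- cfg$interactome
            requireFields(blk, c("table", "groups"), "interactome")
            inputs <- checkInputs(blk$table)
            lfq <- loadAndFilterLFQ(blk$table, unlist(blk$groups),
                                    minValid = blk$min_valid,
                                    nReplicates = blk$n_replicates)
            lfq <- imputeMissing(lfq, width = blk$width, shift = blk$shift,
                                 seed = cfg$seed)
            res <- anovaS0(lfq, s0 = blk$s0, fdrTarget = blk$fdr_target,
                           nPermutations = blk$n_permutations,
                           seed = cfg$seed)
            utils::write.table(res, file.path(outDir, "anova_stats.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
            out <- c("anova_stats.tsv")
            if (sum(res$significant) >= 2L) {
                prof <- profileAndCluster(lfq, res, k = blk$k)
                utils::write.table(round(prof$medianProfiles, 6),
                                   file.path(outDir, "median_profiles.tsv"),
                                   sep = "\t", quote = FALSE, col.names = NA)
                if (sum(res$significant) >= 3L) {
                    utils::write.table(round(baitCorrelation(prof), 6),
                                       file.path(outDir,
                                                 "bait_correlation.tsv"),
                                       sep = "\t", quote = FALSE,
                                       col.names = NA)
                    out <- c(out, "bait_correlation.tsv")
                }
                out <- c(out, "median_profiles.tsv")
            }
            out
        },
        distmat = {
            blk <- cfg$distmat
            requireFields(blk, "ensembles", "distmat")
            paths <- unlist(blk$ensembles)
            inputs <- checkInputs(paths)
            ens <- lapply(paths, readEnsemble)
            mats <- lapply(ens, meanMinDistanceMatrix,
                           cutoff = blk$cutoff, heavyOnly = blk$heavy_only)
            out <- character()
            for (i in seq_along(mats)) {
                f <- sprintf("distmat_%d.tsv", i)
                writeDistanceMatrix(mats[[i]], file.path(outDir, f))
                out <- c(out, f)
            }
            if (length(mats) > 1L) {
                for (i in seq_along(mats)[-1L]) {
                    f <- sprintf("diffmat_%d_vs_1.tsv", i)
                    writeDistanceMatrix(differenceMatrix(mats[[i]],
                                                         mats[[1L]]),
                                        file.path(outDir, f))
                    out <- c(out, f)
                }
            }
            if (!is.null(blk$pair)) {
                pr <- as.integer(unlist(blk$pair))
                series <- vapply(ens, function(e)
                    mean(pairMinDistance(e, pr[1L], pr[2L])), numeric(1))
                utils::write.table(
                    data.frame(ensemble = basename(paths),
                               mean_min_distance_nm = round(series, 6)),
                    file.path(outDir, "pair_distance.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
                out <- c(out, "pair_distance.tsv")
            }
            out
        },
        simulate = {
            blk <- cfg$simulate
            requireFields(blk, "what", "simulate")
            runSimulateStage(blk, cfg$seed, outDir)
        })

    report <- list(package = "ubimod",
                   version = as.character(utils::packageVersion("ubimod")),
                   subcommand = subcommand, seed = cfg$seed,
                   config = cfg,
                   input_md5 = if (length(inputs))
                       as.list(tools::md5sum(inputs)) else NULL,
                   artifacts = artifacts,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(report, file.path(outDir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## simulate subcommand: writes generator output in the on-disk formats the
## readers consume, plus a ground-truth JSON sidecar.
runSimulateStage <- function(blk, seed, outDir) {
    what <- match.arg(blk$what, c("csp", "titration", "lfq", "ensemble"))
    truthPath <- file.path(outDir, "truth.json")
    if (what == "csp") {
        sim <- simulateCSPPair(hsqcSimSpec(seed = seed,
                                           noiseSD = blk$noise_sd %||% 0))
        writePeakList(sim$reference, file.path(outDir, "reference.tsv"))
        writePeakList(sim$variant, file.path(outDir, "variant.tsv"))
        jsonlite::write_json(sim$truth, truthPath, auto_unbox = TRUE,
                             digits = NA)
        c("reference.tsv", "variant.tsv", "truth.json")
    } else if (what == "titration") {
        spec <- titrationSimSpec(kd = blk$kd %||% 8,
                                 noiseSD = blk$noise_sd %||% 0, seed = seed)
        sim <- simulateTitration(spec)
        files <- character()
        for (i in seq_along(sim$series@steps)) {
            f <- sprintf("step%02d.tsv", i - 1L)
            writePeakList(sim$series@steps[[i]], file.path(outDir, f))
            files <- c(files, f)
        }
        utils::write.table(sim$truth$concentrations,
                           file.path(outDir, "concentrations.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(list(kd = sim$truth$kd,
                                  dmax = as.list(sim$truth$dmax),
                                  residues = sim$truth$residues),
                             truthPath, auto_unbox = TRUE, digits = NA)
        c(files, "concentrations.tsv", "truth.json")
    } else if (what == "lfq") {
        sim <- simulateLFQ(lfqSimSpec(seed = seed))
        utils::write.table(sim$table,
                           file.path(outDir, "proteinGroups.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(list(groups = as.list(sim$groups),
                                  cluster = as.list(sim$truth)),
                             truthPath, auto_unbox = TRUE, digits = NA)
        c("proteinGroups.tsv", "truth.json")
    } else {
        ens <- simulateEnsemble(seed = seed,
                                jitterSD = blk$jitter_sd %||% 0.02,
                                nFrames = blk$n_frames %||% 5L)
        writeEnsemble(ens, file.path(outDir, "ensemble.pdb"))
        jsonlite::write_json(list(n_frames = nFrames(ens),
                                  n_residues = length(residues(ens))),
                             truthPath, auto_unbox = TRUE, digits = NA)
        c("ensemble.pdb", "truth.json")
    }
}
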