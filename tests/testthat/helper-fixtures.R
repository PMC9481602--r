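# Small in-code fixtures shared across test files.

# Peak list with given residues; shifts default to a deterministic spread.
makePeakList <- function(residues, shift_h = 8 + 0.01 * seq_along(residues),
                         shift_n = 118 + 0.1 * seq_along(residues),
                         intensity = 1e6, label = "fixture") {
    PeakList(data.frame(residue_number = residues,
                        residue_type = "X",
                        shift_h = shift_h, shift_n = shift_n,
                        intensity = intensity),
             label = label)
}

# Profile from named values without going through peak lists.
makeProfile <- function(values, excluded = integer(), label = "p") {
    new("CSPProfile", label = label,
        values = stats::setNames(as.numeric(values), names(values)),
        excluded = as.integer(excluded))
}

# Complete (no-missing) LFQExperiment from a matrix and bait labels.
makeLFQ <- function(m, bait) {
    rownames(m) <- rownames(m) %||% sprintf("P%03d", seq_len(nrow(m)))
    LFQExperiment(m, bait = bait)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force Kd oracle: profile grid over log-spaced Kd with the
# closed-form least-squares dmax per grid point. Independent of the
# package fitter except for the isotherm definition itself.
gridKdOracle <- function(obs, decades = c(-3, 3), n = 241L) {
    grid <- 10^seq(decades[1], decades[2], length.out = n)
    ssr <- vapply(grid, function(kdg) {
        s <- obs$P + obs$L + kdg
        f <- (s - sqrt(pmax(s^2 - 4 * obs$P * obs$L, 0))) / (2 * obs$P)
        sum(vapply(split(seq_len(nrow(obs)), obs$residue_number),
                   function(i) {
            dm <- sum(obs$observed[i] * f[i]) / sum(f[i]^2)
            sum((obs$observed[i] - dm * f[i])^2)
        }, numeric(1)))
    }, numeric(1))
    list(kd = grid[which.min(ssr)], grid = grid)
}

# Observation table (residue, step, P, L, observed CSP) for a titration,
# assembled outside the package fitter's own code path.
titrationObsTable <- function(sim) {
    profs <- perStepCSP(sim$series)
    st <- titrationSteps(sim$series)
    do.call(rbind, lapply(seq_along(profs), function(k) {
        v <- cspValues(profs[[k]])
        keep <- names(v)[as.integer(names(v)) %in% sim$truth$residues]
        data.frame(residue_number = as.integer(keep),
                   P = st$protein_conc[k + 1], L = st$ligand_conc[k + 1],
                   observed = unname(v[keep]))
    }))
}
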