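#' @include AllClasses.R
NULL

## Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
## RNG stream is untouched. seed = NULL runs expr on the global stream.
withSeed <- function(seed, expr) {
    if (is.null(seed))
        return(expr)
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has)
        old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has)
            assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

## Eq.-weighted combination of 1H / 15N shift differences (ppm):
## sqrt(((dH)^2 + (dN)^2 / 25) / 2). Vectorized.
weightedShiftDistance <- function(dh, dn) {
    sqrt((dh^2 + dn^2 / 25) / 2)
}

#' Canonical ubiquitin sequence
#'
#' The 76-residue human ubiquitin sequence used by the synthetic-data
#' generators so that simulated peak lists carry real residue types.
#'
#' @return Character vector of 76 one-letter codes, named by residue number.
#' @examples
#' ubiquitinSequence()[c(6, 11, 27, 29, 33, 48, 63)]  # the seven lysines
#' @export
ubiquitinSequence <- function() {
    s <- strsplit(paste0(
        "MQIFVKTLTGKTITLEVEPSDTIENVKAKIQDKEGIPPDQ",
        "QRLIFAGKQLEDGRTLSDYNIQKESTLHLVLRLRGG"), "")[[1L]]
    names(s) <- seq_along(s)
    s
}

#' Lysine positions of ubiquitin
#'
#' @return Integer vector \code{c(6, 11, 27, 29, 33, 48, 63)} — the residues
#'   excluded from pooled CSP cutoff statistics in acetyl-lysine comparisons.
#' @export
ubiquitinLysines <- function() {
    c(6L, 11L, 27L, 29L, 33L, 48L, 63L)
}

#' Hydrophobic patch definitions of ubiquitin
#'
#' The two canonical interaction epitopes on the ubiquitin surface: the I44
#' patch (L8, I44, H68, V70) used by most ubiquitin-binding domains, and the
#' I36 patch (L8, I36, L71, L73).
#'
#' @param name \code{"I44"} or \code{"I36"}.
#' @return Named integer vector of the four member residues.
#' @examples
#' hydrophobicPatch("I44")
#' @export
hydrophobicPatch <- function(name = c("I44", "I36")) {
    name <- match.arg(name)
    if (name == "I44")
        c(L8 = 8L, I44 = 44L, H68 = 68L, V70 = 70L)
    else
        c(L8 = 8L, I36 = 36L, L71 = 71L, L73 = 73L)
}

## Prolines of ubiquitin: no backbone amide, absent from HSQC peak lists.
ubiquitinProlines <- function() {
    which(ubiquitinSequence() == "P")
}
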