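# Write an LFQ table to disk in the MaxQuant-style layout.
writeLfqTable <- function(tab, path = withr::local_tempfile(
                              fileext = ".tsv",
                              .local_envir = parent.frame())) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
}

test_that("loading filters decoys, log2-transforms and applies the valid-value rule", {
    raw <- matrix(2^25, nrow = 5, ncol = 16)
    samples <- paste0(rep(c("a", "b"), each = 8), "_r", rep(1:8, 2))
    groups <- setNames(rep(c("a", "b"), each = 8), samples)
    # protein 4 observed 5/8 in both groups; protein 5 observed 6/8 in one
    raw[4, c(1:3, 9:11)] <- 0
    raw[5, c(1:2, 9:12)] <- 0
    tab <- data.frame(`Protein IDs` = paste0("P", 1:5),
                      Reverse = c("", "+", "", "", ""),
                      `Potential contaminant` = c("", "", "+", "", ""),
                      check.names = FALSE)
    colnames(raw) <- paste0("LFQ intensity ", samples)
    tab <- cbind(tab, raw)

    lfq <- loadAndFilterLFQ(writeLfqTable(tab), groups, minValid = 6L)
    # reverse + contaminant removed; P4 fails 6-of-8 in every group
    expect_equal(rownames(lfq), c("P1", "P5"))
    a <- SummarizedExperiment::assay(lfq, "log2intensity")
    expect_equal(unname(a["P1", 1]), 25)
    expect_equal(sum(is.na(a["P5", ])), 6L)   # zeros became missing

    # strict across-all-columns mode drops P5 too (10 < 12 observed)
    lfqAll <- loadAndFilterLFQ(writeLfqTable(tab), groups, minValid = 12L,
                               validAcross = "all")
    expect_equal(rownames(lfqAll), "P1")

    # fully observed table: row count unchanged
    tab0 <- tab[tab$Reverse == "" & tab$`Potential contaminant` == "", ]
    tab0[paste0("LFQ intensity ", samples)] <- 2^25
    expect_equal(nrow(loadAndFilterLFQ(writeLfqTable(tab0), groups)), 3L)

    bad <- tab[, setdiff(names(tab), "Reverse")]
    expect_error(loadAndFilterLFQ(writeLfqTable(bad), groups), "Reverse")
})

test_that("imputation draws from the downshifted normal and never alters observed values", {
    # column with observed mean exactly 25 and SD exactly 2
    obs <- as.numeric(scale(rnorm(50))) * 2 + 25
    m <- matrix(NA_real_, nrow = 10050, ncol = 2)
    m[1:50, 1] <- obs
    m[, 2] <- 20                       # fully observed companion column
    m[1:50, 2] <- rnorm(50, 20, 1)
    lfq <- makeLFQ(m, bait = c("a", "b"))
    imp <- imputeMissing(lfq, width = 0.3, shift = 1.2, seed = 99L)
    a <- SummarizedExperiment::assay(imp, "log2intensity")
    drawn <- a[51:10050, 1]
    expect_equal(mean(drawn), 25 - 1.2 * 2, tolerance = 0.02 / (22.6))
    expect_lt(abs(mean(drawn) - 22.6), 0.02)
    expect_lt(abs(sd(drawn) - 0.6), 0.02)
    # observed entries untouched
    expect_equal(unname(a[1:50, 1]), obs)
    # determinism
    imp2 <- imputeMissing(lfq, seed = 99L)
    expect_identical(SummarizedExperiment::assay(imp2, "log2intensity"), a)
    # complete matrix passes through unchanged
    full <- makeLFQ(matrix(rnorm(40, 25), 10), bait = rep(c("a", "b"), 2))
    expect_identical(
        SummarizedExperiment::assay(imputeMissing(full, seed = 1)),
        SummarizedExperiment::assay(full))
})

test_that("moderated statistic is zero for flat proteins and F-ranked at s0 = 0", {
    set.seed(11)
    m <- matrix(rnorm(20 * 6, 10, 1), nrow = 20)
    m[1, ] <- 7                               # identical in all columns
    m[2, ] <- c(10, 10.1, 9.9, 12, 12.1, 11.9)  # clear group effect
    bait <- rep(c("g1", "g2"), each = 3)
    lfq <- makeLFQ(m, bait)
    res <- anovaS0(lfq, s0 = 0, nPermutations = 50L, seed = 3L)
    expect_equal(res$d[1], 0)

    # oracle: classical one-way F per protein via lm/anova (skip the
    # degenerate all-constant row, where F itself is 0/0)
    fstat <- apply(m[-1, ], 1L, function(x)
        anova(lm(x ~ bait))[["F value"]][1])
    expect_equal(order(res$d[-1], decreasing = TRUE),
                 order(fstat, decreasing = TRUE))
    # at s0 = 0 the statistic is exactly sqrt(F)
    expect_equal(res$d[-1]^2, unname(fstat), tolerance = 1e-10)
})

test_that("q-values are monotone in d and flag a planted strong effect", {
    set.seed(21)
    m <- matrix(rnorm(100 * 16, 25, 0.5), nrow = 100)
    bait <- rep(c("a", "b"), each = 8)
    m[1:5, bait == "b"] <- m[1:5, bait == "b"] + 5
    res <- anovaS0(makeLFQ(m, bait), s0 = 4, fdrTarget = 0.002,
                   nPermutations = 100L, seed = 5L)
    expect_true(all(res$significant[1:5]))
    expect_false(any(res$significant[6:100]))
    o <- order(res$d, decreasing = TRUE)
    expect_true(all(diff(res$q[o]) >= 0))
    expect_true(all(res$q >= 0 & res$q <= 1))
})

test_that("a null matrix yields no hits at FDR 0.002 in almost all seeded runs", {
    hits <- vapply(1:40, function(s) {
        m <- withr::with_seed(4000 + s,
                              matrix(rnorm(100 * 12, 25, 1), nrow = 100))
        res <- anovaS0(makeLFQ(m, rep(c("a", "b", "c"), each = 4)),
                       s0 = 4, fdrTarget = 0.002, nPermutations = 100L,
                       seed = s)
        sum(res$significant)
    }, numeric(1))
    expect_gte(mean(hits == 0), 0.95)
})

test_that("z-scored rows are standardized and clustering recovers planted structure", {
    sim <- simulateLFQ(lfqSimSpec(seed = 17))
    f <- writeLfqTable(sim$table)
    lfq <- loadAndFilterLFQ(f, sim$groups)
    lfq <- imputeMissing(lfq, seed = 17L)
    res <- anovaS0(lfq, seed = 17L)
    prof <- profileAndCluster(lfq, res, k = 3L)
    expect_equal(unname(rowMeans(prof$zscores)),
                 rep(0, nrow(prof$zscores)), tolerance = 1e-12)
    expect_equal(unname(apply(prof$zscores, 1, sd)),
                 rep(1, nrow(prof$zscores)), tolerance = 1e-12)
    truth <- sim$truth[rownames(prof$medianProfiles)]
    expect_true(all(truth > 0))       # only planted interactors significant
    skip_if_not_installed("mclust")
    expect_gte(mclust::adjustedRandIndex(prof$clusters, truth), 0.9)
})

test_that("identical rows merge first and fewer than 2 significant degrades gracefully", {
    m <- matrix(rnorm(6 * 8, 25, 0.3), nrow = 6)
    bait <- rep(c("a", "b", "c", "d"), each = 2)
    m[1, ] <- 25 + rep(c(6, 0, 0, 0), each = 2)
    m[2, ] <- 24 + rep(c(6, 0, 0, 0), each = 2)   # same profile, shifted
    m[3, ] <- 25 + rep(c(0, 6, 0, 0), each = 2)
    res <- data.frame(protein = rownames(makeLFQ(m, bait)),
                      d = c(5, 5, 5, 0, 0, 0), q = c(0, 0, 0, 1, 1, 1),
                      significant = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
    prof <- profileAndCluster(makeLFQ(m, bait), res, k = 2L)
    merged <- prof$hclust$merge[1, ]
    expect_equal(sort(-merged), c(1, 2))   # rows 1 and 2 joined first
    expect_equal(unname(prof$clusters[1]), unname(prof$clusters[2]))

    resOne <- res
    resOne$significant <- c(TRUE, rep(FALSE, 5))
    expect_warning(p1 <- profileAndCluster(makeLFQ(m, bait), resOne),
                   "fewer than 2")
    expect_null(p1$hclust)
})

test_that("bait correlations are symmetric with unit diagonal and sign-faithful", {
    med <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4) * 2 + 1,
                 c = -c(1, 2, 3, 4))
    prof <- list(medianProfiles = med)
    cc <- baitCorrelation(prof)
    expect_equal(cc, t(cc))
    expect_equal(unname(diag(cc)), rep(1, 3))
    expect_equal(cc["a", "b"], 1)      # duplicated (affine) bait profile
    expect_equal(cc["a", "c"], -1)     # negated bait profile
    expect_error(baitCorrelation(list(medianProfiles = med[1:2, ])),
                 ">= 3")
    flat <- cbind(a = c(1, 2, 3), b = c(0, 0, 0))
    expect_warning(cc2 <- baitCorrelation(list(medianProfiles = flat)),
                   "zero-variance")
    expect_true(is.na(cc2["a", "b"]))
})

test_that("targeted-MS ratios behave as simple normalizations", {
    expect_equal(prmNormalize(100, 1000), 0.1)
    expect_equal(prmNormalize(200, 2000), 0.1)  # scale-invariant
    expect_error(prmNormalize(100, 0), "> 0")
    expect_equal(deacetylationFraction(0, 50), 1.0)
    expect_equal(deacetylationFraction(50, 50), 0.5)
    expect_equal(deacetylationFraction(100, 0), 0.0)
    expect_error(deacetylationFraction(0, 0), "> 0")
})
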