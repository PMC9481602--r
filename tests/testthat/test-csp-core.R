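test_that("weighted CSP reproduces hand-computed shift combinations", {
    ref <- makePeakList(1:4)
    p <- peaks(ref)
    # residue 1 unchanged; 2: dH only; 3: dN only; 4: both
    p$shift_h <- p$shift_h + c(0, 0.10, 0, 0.10)
    p$shift_n <- p$shift_n + c(0, 0.50, 1.00, 1.00)
    prof <- weightedCSP(ref, PeakList(p))
    v <- cspValues(prof)
    expect_equal(unname(v["1"]), 0, tolerance = 1e-12)
    expect_equal(unname(v["2"]), 0.10, tolerance = 1e-12)
    expect_equal(unname(v["3"]), sqrt(0.02), tolerance = 1e-12)
    expect_equal(unname(v["4"]), sqrt((0.01 + 1 / 25) / 2),
                 tolerance = 1e-12)
})

test_that("weighted CSP is symmetric in its inputs and drops one-sided residues", {
    ref <- makePeakList(1:5)
    p <- peaks(ref)
    p$shift_h <- p$shift_h + runif(5, -0.2, 0.2)
    var <- PeakList(p[1:4, ])           # residue 5 broadened out
    a <- weightedCSP(ref, var)
    b <- weightedCSP(var, ref)
    expect_equal(cspValues(a), cspValues(b))
    expect_equal(a@dropped, 5L)
    expect_false("5" %in% names(cspValues(a)))
})

test_that("pooled cutoffs match hand arithmetic and honour exclusions", {
    p <- makeProfile(c(`1` = 0.1, `2` = 0.2, `3` = 0.3, `4` = 0.4))
    co <- significanceCutoffs(p)
    expect_equal(co@meanCutoff, 0.25)
    expect_equal(co@meanPlusSdCutoff, 0.25 + sd(c(.1, .2, .3, .4)))
    expect_equal(co@meanPlusSdCutoff, 0.25 + sqrt(0.05 / 3),
                 tolerance = 1e-12)
    expect_equal(co@nValues, 4L)

    # zero variance: both cutoffs coincide
    co2 <- significanceCutoffs(makeProfile(c(`1` = .2, `2` = .2, `3` = .2)))
    expect_equal(co2@meanCutoff, co2@meanPlusSdCutoff)

    # masking the residue carrying 0.3 changes the pooled mean to 0.15
    co3 <- significanceCutoffs(makeProfile(c(`1` = .1, `2` = .2, `3` = .3),
                                           excluded = 3L))
    expect_equal(co3@meanCutoff, 0.15)
    expect_equal(co3@nValues, 2L)

    # pooling across profiles with per-profile exclusion sets
    co4 <- significanceCutoffs(list(
        makeProfile(c(`1` = .1, `6` = 9), excluded = 6L),
        makeProfile(c(`1` = .3, `11` = 9), excluded = 11L)))
    expect_equal(co4@meanCutoff, 0.2)
    expect_error(significanceCutoffs(makeProfile(c(`1` = .1))),
                 "at least 2")
})

test_that("classification fills three classes and clustering honours gap and size rules", {
    vals <- rep(0.01, 40)
    names(vals) <- 1:40
    vals[c(7, 8, 9, 30)] <- c(0.5, 0.9, 0.5, 0.5)
    p <- makeProfile(vals)
    co <- new("CutoffPair", meanCutoff = 0.1, meanPlusSdCutoff = 0.8,
              nValues = 40L, excludedResidues = integer())
    cc <- classifyAndCluster(p, co, gapTolerance = 1L, minSize = 2L)
    cls <- significanceClasses(cc$profile)
    expect_equal(unname(cls[c("7", "8", "9", "30")]),
                 c("above_mean", "above_mean_plus_sd", "above_mean",
                   "above_mean"))
    expect_equal(unname(cls["1"]), "below_mean")
    # residue 30 is alone -> dropped by minSize; one cluster spanning 7..9
    expect_equal(nrow(cc$clusters), 1L)
    expect_equal(cc$clusters$first, 7L)
    expect_equal(cc$clusters$last, 9L)
    expect_equal(cc$clusters$max_value, 0.9)

    # a gap of one non-significant residue is bridged
    vals2 <- rep(0.01, 20); names(vals2) <- 1:20
    vals2[c(5, 7)] <- 0.5
    cc2 <- classifyAndCluster(makeProfile(vals2), co, 1L, 2L)
    expect_equal(cc2$clusters$n_members, 2L)
    # ... but not with gapTolerance 0
    cc3 <- classifyAndCluster(makeProfile(vals2), co, 0L, 2L)
    expect_equal(nrow(cc3$clusters), 0L)

    # nothing significant -> empty cluster table
    cc4 <- classifyAndCluster(makeProfile(vals2 * 0.001), co, 1L, 2L)
    expect_equal(nrow(cc4$clusters), 0L)

    # excluded residues carry values but never classes
    p5 <- makeProfile(c(`6` = 5, `7` = 0.2), excluded = 6L)
    cc5 <- classifyAndCluster(p5, co, 1L, 1L)
    expect_false("6" %in% names(significanceClasses(cc5$profile)))
})

test_that("uniform scaling of shifts scales values and cutoffs, not classes", {
    ref <- makePeakList(1:30)
    p <- peaks(ref)
    set.seed(3)
    p$shift_h <- p$shift_h + rnorm(30, 0, 0.05)
    p$shift_n <- p$shift_n + rnorm(30, 0, 0.25)
    var <- PeakList(p)
    prof1 <- weightedCSP(ref, var)
    # scale all shift differences by c = 3
    p3 <- peaks(ref)
    p3$shift_h <- p3$shift_h + 3 * (p$shift_h - peaks(ref)$shift_h)
    p3$shift_n <- p3$shift_n + 3 * (p$shift_n - peaks(ref)$shift_n)
    prof3 <- weightedCSP(ref, PeakList(p3))
    expect_equal(cspValues(prof3), 3 * cspValues(prof1), tolerance = 1e-12)
    co1 <- significanceCutoffs(prof1)
    co3 <- significanceCutoffs(prof3)
    expect_equal(co3@meanCutoff, 3 * co1@meanCutoff, tolerance = 1e-12)
    expect_equal(co3@meanPlusSdCutoff, 3 * co1@meanPlusSdCutoff,
                 tolerance = 1e-12)
    c1 <- classifyAndCluster(prof1, co1)$profile
    c3 <- classifyAndCluster(prof3, co3)$profile
    expect_equal(significanceClasses(c1), significanceClasses(c3))
})

test_that("patch overlap counts significant patch members", {
    vals <- rep(0.01, 76); names(vals) <- 1:76
    vals[c(8, 44)] <- 0.5
    co <- new("CutoffPair", meanCutoff = 0.1, meanPlusSdCutoff = 0.4,
              nValues = 76L, excludedResidues = integer())
    prof <- classifyAndCluster(makeProfile(vals), co)$profile
    ov <- patchOverlap(prof, "I44")
    expect_equal(ov$n_significant, 2L)
    expect_equal(ov$fraction, 0.5)
    expect_equal(patchOverlap(prof, "I36")$n_significant, 1L)  # only L8

    # empty significant set -> 0/4; everything significant -> 4/4
    prof0 <- classifyAndCluster(makeProfile(setNames(rep(.01, 76), 1:76)),
                                co)$profile
    expect_equal(patchOverlap(prof0, "I44")$n_significant, 0L)
    profAll <- classifyAndCluster(makeProfile(setNames(rep(.9, 76), 1:76)),
                                  co)$profile
    expect_equal(patchOverlap(profAll, "I44")$fraction, 1)
})

test_that("profile correlation matches hand cases and rejects degenerate input", {
    a <- makeProfile(c(`1` = 0.1, `2` = 0.2, `3` = 0.3))
    b <- makeProfile(c(`1` = 0.3, `2` = 0.2, `3` = 0.1))
    expect_equal(profileCorrelation(a, b)$r, -1)
    expect_equal(profileCorrelation(a, a)$r, 1)
    expect_equal(profileCorrelation(a, b)$n_shared, 3L)
    expect_error(profileCorrelation(a, makeProfile(c(`1` = 1, `2` = 2))),
                 "3 shared")
    flat <- makeProfile(c(`1` = .2, `2` = .2, `3` = .2))
    expect_error(profileCorrelation(a, flat), "zero variance")
})

test_that("planted perturbation clusters are recovered from synthetic pairs", {
    # The pooled-mean cutoff sits near (sum of planted CSPs)/n, so exact
    # span recovery needs shift noise well below that level, not merely
    # below the planted amplitude.
    planted <- data.frame(residue_number = c(40L, 41L, 42L), dw = 0.3)
    for (seed in 1:3) {
        spec <- hsqcSimSpec(planted = planted, noiseSD = 0.003,
                            seed = seed)
        sim <- simulateCSPPair(spec)
        prof <- weightedCSP(sim$reference, sim$variant,
                            excluded = ubiquitinLysines())
        co <- significanceCutoffs(prof)
        cc <- classifyAndCluster(prof, co, gapTolerance = 1L, minSize = 2L)
        expect_equal(nrow(cc$clusters), 1L)
        expect_equal(cc$clusters$first, 40L)
        expect_equal(cc$clusters$last, 42L)
    }
})

test_that("CSP profiles serialize to TSV with classes and clusters", {
    vals <- setNames(c(0.5, 0.01, 0.6), c(7, 8, 9))
    co <- new("CutoffPair", meanCutoff = 0.1, meanPlusSdCutoff = 0.55,
              nValues = 3L, excludedResidues = integer())
    cc <- classifyAndCluster(makeProfile(vals), co, 1L, 2L)
    f <- withr::local_tempfile(fileext = ".tsv")
    writeCSPProfile(cc$profile, f, clusters = cc$clusters)
    tab <- read.delim(f)
    expect_equal(tab$class, c("above_mean", "below_mean",
                              "above_mean_plus_sd"))
    expect_true(file.exists(sub("\\.tsv$", "_clusters.tsv", f)))
})
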