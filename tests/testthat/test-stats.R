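test_that("two-group comparison matches the pooled-variance closed form", {
    A <- c(1, 2, 3, 4); B <- c(2, 3, 4, 5)
    cg <- compareGroups(list(ctrl = A, ko = B))
    # hand-computed pooled t: sp2 = (var(A)*3 + var(B)*3) / 6
    sp2 <- (var(A) * 3 + var(B) * 3) / 6
    tOracle <- (mean(A) - mean(B)) / sqrt(sp2 * (1 / 4 + 1 / 4))
    pOracle <- 2 * pt(-abs(tOracle), df = 6)
    expect_lt(abs(cg$statistic / tOracle - 1), 1e-10)
    expect_lt(abs(cg$p / pOracle - 1), 1e-10)
    expect_equal(cg$summary$sem, cg$summary$sd / sqrt(cg$summary$n))
    same <- compareGroups(list(a = A, b = A))
    expect_equal(same$statistic, 0)
    expect_equal(same$p, 1)
    expect_error(compareGroups(list(a = A, b = 1)), "n >= 2")
})

test_that("multi-group designs gate pairwise tests through ANOVA + BH", {
    set.seed(1)
    g <- list(a = rnorm(6), b = rnorm(6, 2), c = rnorm(6))
    cg <- compareGroups(g)
    expect_match(cg$test, "ANOVA")
    expect_equal(nrow(cg$pairwise), 3L)
    expect_true(all(cg$pairwise$p_adj >= cg$pairwise$p - 1e-12))
    expect_equal(cg$pairwise$p_adj, bhAdjust(cg$pairwise$p))
})

test_that("BH adjustment follows the step-up recursion", {
    expect_equal(bhAdjust(0.03), 0.03)
    expect_equal(bhAdjust(rep(0.02, 5)), rep(0.02, 5))
    # hand-computed: sorted (.01,.03,.04,.05), adj = (.04,.05,.05,.05) in
    # input order (0.01, 0.04, 0.03, 0.05)
    expect_equal(bhAdjust(c(0.01, 0.04, 0.03, 0.05)),
                 c(0.04, 0.05, 0.05, 0.05))
    p <- c(0.001, 0.2, 0.03, 0.7, 0.04)
    perm <- c(3, 1, 5, 2, 4)
    expect_equal(bhAdjust(p)[perm], bhAdjust(p[perm]))
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Pfaffl ratios follow the efficiency-corrected model", {
    expect_equal(pfafflRatio(2, 1, 2, 0), 2)
    expect_equal(pfafflRatio(2, 0, 2, 0), 1)
    expect_lt(abs(pfafflRatio(1.9, 2.5, 2.0, 1.0) /
                  (1.9^2.5 / 2.0) - 1), 1e-12)
    # delta-delta-Ct equivalence at perfect efficiency
    for (d in list(c(2.5, 1), c(-1, 0.5), c(0, 0))) {
        expect_lt(abs(pfafflRatio(2, d[1], 2, d[2]) /
                      2^(d[1] - d[2]) - 1), 1e-12)
    }
    expect_error(pfafflRatio(2.5, 1, 2, 0), "efficiencies")
})

test_that("membrane strain geometry reproduces the cap model", {
    g <- membraneStrain(0, 20)
    expect_equal(g@areaIncrease, 0)
    expect_equal(g@linearStrain, 0)
    # 11% area increase is 5% linear strain at integer rounding
    expect_equal(round(100 * strainFromArea(0.11)), 5)
    expect_equal(strainFromArea(0.11), sqrt(1.11) - 1)
    # round trip to 1e-12 on [0, 0.5]
    x <- seq(0, 0.5, by = 0.01)
    expect_lt(max(abs(areaFromStrain(strainFromArea(x)) - x)), 1e-12)
    # first-order small-strain behaviour: s ~ dA/(2A) within 1% at <= 0.02
    sm <- seq(0.001, 0.02, by = 0.001)
    expect_lt(max(abs(strainFromArea(sm) / (sm / 2) - 1)), 0.01)
    expect_error(membraneStrain(6, 0), "positive")
})

test_that("volcano filter recovers planted counts exactly", {
    sim <- synthProteomeTable(nProteins = 1500L, nUp = 71L, nDown = 105L,
                              seed = 1)
    vf <- volcanoFilter(sim$table)
    expect_equal(vf$nUp, 71L)
    expect_equal(vf$nDown, 105L)
    expect_equal(sum(vf$table$direction == "ns"), 1500L - 176L)
    empty <- data.frame(id = character(0), fold_change = numeric(0),
                        p_value = numeric(0))
    v0 <- volcanoFilter(empty)
    expect_equal(c(v0$nUp, v0$nDown), c(0L, 0L))
    # thresholds are inclusive
    edge <- data.frame(id = "x", fold_change = 1.5, p_value = 0.05)
    expect_equal(volcanoFilter(edge)$nUp, 1L)
    bad <- data.frame(id = c("a", "b"), fold_change = c(2, -1),
                      p_value = c(0.01, 0.01))
    expect_error(volcanoFilter(bad), "row 2")
})

test_that("planted volcano counts are recovered across random designs", {
    set.seed(7)
    for (i in 1:100) {
        nUp <- sample(0:60, 1); nDown <- sample(0:60, 1)
        sim <- synthProteomeTable(nProteins = 400L, nUp = nUp,
                                  nDown = nDown, seed = i)
        vf <- volcanoFilter(sim$table)
        expect_identical(c(vf$nUp, vf$nDown), c(nUp, nDown))
    }
})

test_that("log2 fold-change tables filter identically", {
    sim <- synthProteomeTable(nProteins = 300L, nUp = 12L, nDown = 30L,
                              seed = 9)
    tab <- as.data.frame(sim$table)
    logTab <- data.frame(id = tab$id, log2fc = log2(tab$fold_change),
                         p_value = tab$p_value)
    vf <- volcanoFilter(logTab, logFC = TRUE)
    expect_equal(c(vf$nUp, vf$nDown), c(12L, 30L))
})

test_that("mean intensity in mask is the masked arithmetic mean", {
    img <- matrix(7, 10, 10)
    mask <- matrix(TRUE, 10, 10)
    expect_equal(meanIntensityInMask(img, mask), 7)
    img2 <- matrix(0, 10, 10); img2[, 6:10] <- 10
    mask2 <- matrix(FALSE, 10, 10); mask2[, 6:10] <- TRUE
    expect_equal(meanIntensityInMask(img2, mask2), 10)
    set.seed(2)
    r <- matrix(runif(400), 20, 20)
    expect_lt(abs(meanIntensityInMask(r, matrix(TRUE, 20, 20)) - mean(r)),
              1e-10)
    expect_error(meanIntensityInMask(img, mask2[1:5, ]), "shape")
    expect_error(meanIntensityInMask(img, matrix(FALSE, 10, 10)), "empty")
})
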