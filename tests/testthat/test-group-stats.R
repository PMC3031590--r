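test_that("cost averaging is the unweighted mean over the grid", {
    mkProfile <- function(cost, v) new("NormalizedProfile",
        nodalEglobNorm = rep(v, 3), nodalElocNorm = rep(2 * v, 3),
        netEglobNorm = v, netElocNorm = 2 * v, cost = cost)
    costs <- costGrid()
    # constant curve
    const <- lapply(costs, mkProfile, v = 0.9)
    expect_equal(costAverage(const)$netEglobNorm, 0.9)
    # linear in cost index 1..16: mean equals midpoint value 8.5
    lin <- lapply(seq_along(costs),
                  function(i) mkProfile(costs[i], i))
    expect_equal(costAverage(lin)$netEglobNorm, 8.5)
    expect_equal(costAverage(lin)$nodalElocNorm, rep(17, 3))
    # a missing level is an error naming the costs
    expect_error(costAverage(lin[-3]), "0.14")
})

test_that("mixed ANOVA reproduces a hand-built sums-of-squares case", {
    # 4 subjects, 2 per group, chosen so every effect is nonzero
    d <- data.frame(
        subject = rep(c("a", "b", "c", "d"), each = 2),
        group = rep(c("younger", "younger", "older", "older"), each = 2),
        condition = rep(c("quiet", "noisy"), 4),
        y = c(10, 12, 11, 14, 7, 8, 6, 6))
    an <- mixedAnova2x2(d, "y")
    o <- oracleMixedAnova(d, "y")
    expect_equal(an$F[an$effect == "group"], unname(o$Fgroup),
                 tolerance = 1e-10)
    expect_equal(an$F[an$effect == "condition"], unname(o$Fcond),
                 tolerance = 1e-10)
    expect_equal(an$F[an$effect == "interaction"], unname(o$Fint),
                 tolerance = 1e-10)
    expect_equal(an$p[an$effect == "group"], unname(o$pgroup),
                 tolerance = 1e-10)
    expect_equal(an$df1, rep(1L, 3))
    expect_equal(an$df2, rep(2L, 3))
    expect_equal(an$direction[an$effect == "group"], "Y>O")
})

test_that("mixed ANOVA matches the aov oracle on random balanced designs", {
    set.seed(88)
    for (rep in 1:20) {
        d <- makeAnovaData(sample(3:12, 1))
        an <- mixedAnova2x2(d, "y")
        o <- oracleMixedAnova(d, "y")
        expect_equal(an$F, unname(c(o$Fgroup, o$Fcond, o$Fint)),
                     tolerance = 1e-10)
        expect_equal(an$p, unname(c(o$pgroup, o$pcond, o$pint)),
                     tolerance = 1e-10)
    }
})

test_that("swapping condition labels flips only the condition direction", {
    set.seed(99)
    d <- makeAnovaData(5)
    an1 <- mixedAnova2x2(d, "y")
    d2 <- d
    d2$condition <- ifelse(d$condition == "quiet", "noisy", "quiet")
    an2 <- mixedAnova2x2(d2, "y")
    expect_equal(an1$F, an2$F, tolerance = 1e-12)
    expect_equal(an1$p, an2$p, tolerance = 1e-12)
    expect_equal(an1$direction[1], an2$direction[1])  # group unchanged
})

test_that("mixed ANOVA rejects degenerate or incomplete designs", {
    d <- makeAnovaData(3, fun = function(n) rep(1, n))
    expect_error(mixedAnova2x2(d, "y"), "zero.*variance|degenerate")
    d2 <- makeAnovaData(3)
    d2 <- d2[-1, ]
    expect_error(mixedAnova2x2(d2, "y"), "both conditions")
})

test_that("ANOVA df equals n_subjects - 2 at the study size", {
    set.seed(123)
    d <- makeAnovaData(12)
    an <- mixedAnova2x2(d, "y")
    expect_equal(an$df2, rep(22L, 3))
})

test_that("covariate association reproduces the closed-form r", {
    d <- data.frame(cov = c(1, 2, 3, 4, 5), m = c(2, 1, 4, 3, 5))
    res <- covariateAssociation(d, "cov", "m")
    expect_equal(res$r, 0.8)
    expect_equal(res$df, 3)
    expect_identical(res$method, "pearson")
    # perfect linear function -> r = 1 (degenerate normality is gated to
    # spearman only if Shapiro fails; a straight line passes)
    d2 <- data.frame(cov = c(0.8, 1.9, 3.1, 4.0, 5.2))
    d2$m <- 2 * d2$cov + 1
    res2 <- covariateAssociation(d2, "cov", "m")
    expect_equal(res2$r, 1)
    expect_error(covariateAssociation(d[1:3, ], "cov", "m"), "4 subjects")
})

test_that("non-normal variables fall back to Spearman with a flag", {
    set.seed(12)
    d <- data.frame(cov = c(rep(0.01, 10), 100, 200, 300, 400, 500),
                    m = rnorm(15))
    res <- covariateAssociation(d, "cov", "m")
    expect_identical(res$method, "spearman")
    expect_false(res$normalityPass)
})

test_that("motion comparison matches the pooled-variance t oracle", {
    spec <- cohortSpec(nPerGroup = 3L, nRegions = 12L, nBlocks = 10L,
                       nModules = 3L, seed = 21L)
    cohort <- simulateCohort(spec)
    met <- networkMetrics(cohort, costs = c(0.2, 0.3), nSurrogates = 4,
                          seed = 2)
    res <- motionComparison(met)
    si <- subjectInfo(cohort)
    o <- t.test(si$motion[si$group == "younger"],
                si$motion[si$group == "older"], var.equal = TRUE)
    expect_equal(res$test$t, unname(o$statistic))
    expect_equal(res$test$df, 4)  # n - 2
    expect_equal(res$test$p, o$p.value)
    expect_equal(nrow(res$correlations), 4L)  # 2 conditions x 2 measures
    # closed-form check on a hand case
    x <- c(1, 2, 3); y <- c(4, 5, 6)
    sp <- sqrt((var(x) * 2 + var(y) * 2) / 4)
    expect_equal(unname(t.test(x, y, var.equal = TRUE)$statistic),
                 (mean(x) - mean(y)) / (sp * sqrt(2 / 3)))
})

test_that("regional screen flags strongly planted group effects", {
    spec <- cohortSpec(nPerGroup = 8L, deltaGroup = 0.5,
                       deltaInteraction = 0, subjectSd = 0.05, seed = 42L)
    cohort <- simulateCohort(spec)
    met <- networkMetrics(cohort, costs = c(0.10, 0.24, 0.40),
                          nSurrogates = 10, seed = 3)
    eff <- regionalEffects(met)
    expect_true(all(c("region", "measure", "effect", "direction", "F", "p")
                    %in% names(eff)))
    grp <- eff[eff$effect == "group" & eff$measure == "eglobNorm", ]
    expect_gt(nrow(grp), 5)
    expect_true(all(grp$p < 0.05))
    expect_true(mean(grp$direction == "Y>O") > 0.9)
})
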