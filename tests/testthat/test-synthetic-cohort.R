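test_that("cohort spec validates its parameters", {
    expect_s3_class(cohortSpec(), "CohortSpec")
    expect_error(cohortSpec(wIn = 1.5), "wIn")
    expect_error(cohortSpec(deltaGroup = -0.1), "deltaGroup")
    expect_error(cohortSpec(nBlocks = 2), "nBlocks")
    expect_error(cohortSpec(accuracyModel = c(a = 0.5)), "accuracyModel")
})

test_that("coupling template is block-structured with the set couplings", {
    spec <- cohortSpec(nRegions = 6L, nModules = 2L, wIn = 0.8, wOut = 0.1,
                       hubFraction = 0, nPerGroup = 2L)
    C <- buildGroundTruthCoupling(spec)
    expect_equal(dim(C), c(6L, 6L))
    expect_equal(C, t(C))
    expect_equal(diag(C), rep(0, 6))
    ut <- C[upper.tri(C)]
    # 2 modules of 3 nodes: 6 intra-module pairs, 9 inter-module pairs
    expect_equal(sum(abs(ut - 0.8) < 0.05), 6L)
    expect_equal(sum(abs(ut - 0.1) < 0.05), 9L)
    # PSD as a unit-diagonal matrix
    A <- C; diag(A) <- 1
    expect_gte(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
})

test_that("homogeneous degenerate case gives equal off-diagonals", {
    spec <- cohortSpec(nRegions = 8L, nModules = 2L, wIn = 0.3, wOut = 0.3,
                       hubFraction = 0)
    C <- buildGroundTruthCoupling(spec)
    expect_equal(unname(C[upper.tri(C)]), rep(0.3, 28))
})

test_that("coupling template is deterministic in the spec seed", {
    spec <- cohortSpec(seed = 123L)
    expect_identical(buildGroundTruthCoupling(spec),
                     buildGroundTruthCoupling(spec))
})

test_that("default cohort has the study dimensions", {
    cohort <- simulateCohort(cohortSpec(seed = 5L))
    expect_s4_class(cohort, "ResponseCohort")
    cd <- colData(cohort)
    expect_equal(nrow(cohort), 66L)  # regions
    expect_equal(ncol(cohort), 24L * 2L * 60L)
    expect_equal(length(unique(cd$subject)), 24L)
    expect_setequal(unique(cd$condition), c("quiet", "noisy"))
    expect_equal(as.integer(table(subjectInfo(cohort)$group)[c("younger",
                                                               "older")]),
                 c(12L, 12L))
    m <- responseMatrix(cohort, "S01", "quiet")
    expect_equal(dim(m), c(66L, 60L))
    expect_equal(rownames(m), atlasTable()$region)
    acc <- blockAccuracy(cohort, "S05", "noisy")
    expect_length(acc, 60L)
    expect_true(all(acc %in% ((0:4) / 4)))
})

test_that("simulation is byte-identical under the same seed", {
    spec <- cohortSpec(nPerGroup = 2L, nRegions = 12L, nBlocks = 10L,
                       nModules = 3L, seed = 77L)
    c1 <- simulateCohort(spec)
    c2 <- simulateCohort(spec)
    expect_identical(assay(c1), assay(c2))
    expect_identical(subjectInfo(c1), subjectInfo(c2))
})

test_that("groups are exchangeable when no effect is planted", {
    # with deltaGroup = deltaInteraction = 0 and no accuracy confound, the
    # response-generating distribution does not depend on the group label:
    # subject covariances are identical across groups given the same
    # latent factor, so only the subject's own draws matter
    spec <- cohortSpec(nPerGroup = 3L, nRegions = 12L, nBlocks = 10L,
                       nModules = 3L, deltaGroup = 0, deltaInteraction = 0,
                       seed = 9L)
    cohort <- simulateCohort(spec)
    si <- subjectInfo(cohort)
    # effective coupling factor is the latent factor, unattenuated
    expect_equal(si$couplingFactor[si$group == "older"],
                 si$couplingFactor[4:6])
    # direct check on the covariance builder: both groups, both conditions
    # collapse to the same matrix
    tmpl <- buildGroundTruthCoupling(spec)
    base <- tmpl; attributes(base) <- list(dim = dim(base))
    lr <- attr(tmpl, "longRange")
    off <- row(base) != col(base)
    for (f in c(0.9, 1.1)) {
        # intra-module factor for (group, condition) is
        # 1 + sign(group) * (+-1/2) * deltaInteraction = 1 for both groups
        iYoungerNoisy <- 1 + 1 * 0.5 * spec$deltaInteraction
        iOlderNoisy <- 1 - 1 * 0.5 * spec$deltaInteraction
        sigY <- cortnet:::.subjectCovariance(base, which(lr & off),
                                             which(!lr & off),
                                             spec$noiseSd, f, iYoungerNoisy)
        sigO <- cortnet:::.subjectCovariance(base, which(lr & off),
                                             which(!lr & off),
                                             spec$noiseSd, f, iOlderNoisy)
        expect_identical(sigY, sigO)
    }
})

test_that("planted group gap in normalized E_glob grows with deltaGroup", {
    gap <- vapply(c(0, 0.25, 0.5), function(dg) {
        gaps <- vapply(1:3, function(s) {
            spec <- cohortSpec(nPerGroup = 4L, deltaGroup = dg,
                               deltaInteraction = 0, subjectSd = 0,
                               seed = 400L + s)
            cohort <- simulateCohort(spec)
            met <- networkMetrics(cohort, costs = c(0.10, 0.24),
                                  nSurrogates = 8, seed = s)
            nm <- networkMeasures(met)
            mean(nm$eglobNorm[nm$group == "younger"]) -
                mean(nm$eglobNorm[nm$group == "older"])
        }, numeric(1))
        mean(gaps)
    }, numeric(1))
    expect_true(all(diff(gap) > 0))
    expect_lt(abs(gap[1]), 0.02)  # no planted effect: gap near zero
})

test_that("older group sits below younger in normalized E_glob when planted", {
    spec <- cohortSpec(deltaGroup = 0.4, deltaInteraction = 0,
                       nPerGroup = 6L, seed = 31L)
    cohort <- simulateCohort(spec)
    met <- networkMetrics(cohort, costs = c(0.10, 0.24, 0.40),
                          nSurrogates = 10, seed = 1)
    nm <- networkMeasures(met)
    expect_gt(mean(nm$eglobNorm[nm$group == "younger"]),
              mean(nm$eglobNorm[nm$group == "older"]))
})

test_that("thickness tracks the effective coupling factor", {
    spec <- cohortSpec(seed = 13L)
    cohort <- simulateCohort(spec)
    si <- subjectInfo(cohort)
    expect_gt(cor(si$thickness, si$couplingFactor), 0.5)
    # older group has attenuated coupling, hence thinner cortex on average
    expect_gt(mean(si$thickness[si$group == "younger"]),
              mean(si$thickness[si$group == "older"]))
})
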