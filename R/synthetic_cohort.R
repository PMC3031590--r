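#' Specification of a synthetic cohort
#'
#' Bundles the parameters of the synthetic cohort generator. The defaults
#' emulate the design of a two-group (12 younger, 12 older adults),
#' two-condition (quiet / noisy listening) study with 66 cortical regions
#' and 60 task blocks per condition: modular small-world inter-regional
#' coupling, an attenuation of long-range coupling in the older group
#' (driving a group deficit in global efficiency), a condition-dependent
#' modulation of intra-module coupling with opposite sign in the two groups
#' (driving a group x condition interaction in local efficiency), a cortical
#' thickness covariate linked to each subject's long-range coupling factor,
#' per-block task accuracy, and per-subject head motion summaries.
#'
#' @param nPerGroup subjects per group (default 12).
#' @param nRegions number of cortical regions / network nodes (default 66).
#' @param nBlocks task blocks per condition (default 60).
#' @param nModules ground-truth community count (default 6).
#' @param wIn intra-module coupling in \[0, 1\].
#' @param wOut inter-module baseline coupling in \[0, 1\].
#' @param wHub coupling of designated long-range "hub" edges in \[0, 1\].
#' @param hubFraction fraction of inter-module node pairs promoted to
#'   long-range hub edges.
#' @param deltaGroup multiplicative attenuation (>= 0) of all long-range
#'   (inter-module and hub) coupling in the older group.
#' @param deltaInteraction condition-dependent modulation of intra-module
#'   coupling within the task-modulated modules (the first half of the
#'   modules — condition effects are regionally specific), applied with
#'   opposite sign in the two groups (noisy vs quiet).
#' @param noiseSd observation noise standard deviation added on the diagonal
#'   of the response covariance.
#' @param subjectSd standard deviation of the per-subject long-range
#'   coupling factor (mean 1).
#' @param thicknessBase mean cortical thickness in mm at coupling factor 1.
#' @param thicknessSlope mm of thickness per unit of the subject's effective
#'   long-range coupling factor.
#' @param thicknessSd residual thickness standard deviation (mm).
#' @param accuracyModel named numeric vector of mean task accuracy in
#'   \[0, 1\] for `younger.quiet`, `younger.noisy`, `older.quiet`,
#'   `older.noisy`.
#' @param accuracyConfound amplitude of an accuracy-locked uniform signal
#'   added to every region (0 disables it). Used to plant a group
#'   difference that is carried entirely by task accuracy.
#' @param seed integer RNG seed stored with the spec.
#' @return object of class `CohortSpec` (a validated list).
#' @examples
#' spec <- cohortSpec(nPerGroup = 3, nRegions = 12, nBlocks = 20)
#' spec$nModules
#' @export
cohortSpec <- function(nPerGroup = 12L,
                       nRegions = 66L,
                       nBlocks = 60L,
                       nModules = 6L,
                       wIn = 0.55,
                       wOut = 0.25,
                       wHub = 0.55,
                       hubFraction = 0.15,
                       deltaGroup = 0.30,
                       deltaInteraction = 0.40,
                       noiseSd = 0.4,
                       subjectSd = 0.08,
                       thicknessBase = 2.50,
                       thicknessSlope = 0.70,
                       thicknessSd = 0.08,
                       accuracyModel = c(younger.quiet = 0.97,
                                         younger.noisy = 0.85,
                                         older.quiet = 0.95,
                                         older.noisy = 0.60),
                       accuracyConfound = 0,
                       seed = 1L) {
    spec <- list(nPerGroup = as.integer(nPerGroup),
                 nRegions = as.integer(nRegions),
                 nBlocks = as.integer(nBlocks),
                 nModules = as.integer(nModules),
                 wIn = wIn, wOut = wOut, wHub = wHub,
                 hubFraction = hubFraction,
                 deltaGroup = deltaGroup,
                 deltaInteraction = deltaInteraction,
                 noiseSd = noiseSd, subjectSd = subjectSd,
                 thicknessBase = thicknessBase,
                 thicknessSlope = thicknessSlope,
                 thicknessSd = thicknessSd,
                 accuracyModel = accuracyModel,
                 accuracyConfound = accuracyConfound,
                 seed = as.integer(seed))
    .validateCohortSpec(spec)
    class(spec) <- c("CohortSpec", "list")
    spec
}

.validateCohortSpec <- function(spec) {
    with(spec, {
        if (nPerGroup < 1L || nRegions < 2L || nBlocks < 3L || nModules < 1L)
            stop("nPerGroup >= 1, nRegions >= 2, nBlocks >= 3 and ",
                 "nModules >= 1 are required")
        for (p in c("wIn", "wOut", "wHub", "hubFraction"))
            if (spec[[p]] < 0 || spec[[p]] > 1)
                stop(p, " must lie in [0, 1]")
        if (deltaGroup < 0) stop("deltaGroup must be >= 0")
        if (noiseSd < 0 || subjectSd < 0 || thicknessSd < 0)
            stop("standard deviations must be >= 0")
        need <- c("younger.quiet", "younger.noisy",
                  "older.quiet", "older.noisy")
        if (!all(need %in% names(accuracyModel)))
            stop("accuracyModel must name: ", paste(need, collapse = ", "))
        if (any(accuracyModel < 0) || any(accuracyModel > 1))
            stop("accuracy means must lie in [0, 1]")
    })
    invisible(TRUE)
}

# Module assignment: nRegions nodes split as evenly as possible over
# nModules contiguous blocks.
.moduleAssignment <- function(nRegions, nModules) {
    sort(rep_len(seq_len(nModules), nRegions))
}

#' Ground-truth inter-regional coupling matrix
#'
#' Builds the modular coupling template shared by all subjects: intra-module
#' entries at `wIn`, inter-module entries at `wOut`, and a seeded random set
#' of inter-module pairs promoted to long-range hub edges at `wHub` (the
#' shortcuts that give the planted networks their small-world character).
#' The matrix is repaired to be positive semidefinite (as a correlation-type
#' matrix with unit diagonal) by eigenvalue clipping at 1e-8 followed by
#' rescaling to unit diagonal; the returned matrix stores a zero diagonal.
#'
#' @param spec a [cohortSpec()] object.
#' @return symmetric `nRegions` x `nRegions` matrix with zero diagonal and
#'   attributes `module` (integer module assignment) and `longRange`
#'   (logical matrix marking inter-module/hub entries).
#' @examples
#' C <- buildGroundTruthCoupling(cohortSpec(nRegions = 12, nModules = 3))
#' attr(C, "module")
#' @export
buildGroundTruthCoupling <- function(spec) {
    .validateCohortSpec(spec)
    set.seed(spec$seed)
    n <- spec$nRegions
    mod <- .moduleAssignment(n, spec$nModules)
    same <- outer(mod, mod, "==")
    C <- ifelse(same, spec$wIn, spec$wOut)
    longRange <- !same
    # promote a seeded fraction of inter-module pairs to hub shortcuts
    ut <- which(upper.tri(C) & longRange)
    nHub <- floor(spec$hubFraction * length(ut))
    if (nHub > 0) {
        hub <- sample(ut, nHub)
        C[hub] <- spec$wHub
        C[cbind((hub - 1) %% n + 1, (hub - 1) %/% n + 1)] <- spec$wHub
    }
    diag(C) <- 0
    C <- .repairPSD(C)
    attr(C, "module") <- mod
    attr(C, "longRange") <- longRange
    C
}

# PSD repair of a zero-diagonal coupling matrix, treated as a correlation
# matrix with unit diagonal: clip eigenvalues at 1e-8, rescale to unit
# diagonal, re-zero the stored diagonal. A Cholesky factorization is tried
# first as a cheap positive-definiteness certificate; the eigen repair only
# runs when it fails.
.repairPSD <- function(C) {
    n <- nrow(C)
    A <- C
    diag(A) <- 1
    if (!is.null(tryCatch(chol(A), error = function(e) NULL))) {
        diag(A) <- 0
        return(A)
    }
    ev <- eigen(A, symmetric = TRUE)
    if (min(ev$values) < 1e-8) {
        vals <- pmax(ev$values, 1e-8)
        A <- ev$vectors %*% (vals * t(ev$vectors))
        d <- diag(A)
        A <- A / sqrt(outer(d, d))
        check <- min(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
        if (check < -1e-10)
            stop("coupling matrix not positive semidefinite after repair ",
                 "(minimum eigenvalue ", format(check), ")")
    }
    A <- (A + t(A)) / 2
    diag(A) <- 0
    A
}

# Subject/condition response covariance: template modified by the subject's
# effective long-range factor and the condition-dependent intra-module
# modulation, PSD-repaired, plus noiseSd^2 on the diagonal. `base` is the
# bare template matrix (attributes stripped); `lrIdx` indexes its
# long-range off-diagonal entries and `inIdx` the intra-module entries the
# modulation applies to (the task-modulated half of the modules; condition
# effects are regionally specific, so only part of the cortex responds).
.subjectCovariance <- function(base, lrIdx, inIdx, noiseSd, longFactor,
                               intraFactor) {
    C <- base
    C[lrIdx] <- pmin(C[lrIdx] * longFactor, 0.98)
    C[inIdx] <- pmin(C[inIdx] * intraFactor, 0.98)
    C <- .repairPSD(C)
    diag(C) <- 1 + noiseSd^2
    C
}

#' Simulate a synthetic cohort of regional responses
#'
#' Draws, for every subject and condition, `nBlocks` independent samples
#' from a zero-mean multivariate normal whose covariance is the
#' subject/condition-specific coupling matrix (older-group attenuation of
#' long-range edges; condition-dependent intra-module modulation of the
#' task-relevant half of the modules, with opposite sign per group) plus
#' `noiseSd^2` observation noise on the diagonal. Per-block task
#' accuracy is Binomial(4, p)/4 with p from `accuracyModel`; cortical
#' thickness is a linear function of the subject's effective long-range
#' coupling factor plus noise; motion is a per-subject log-normal summary
#' with identical distribution in both groups. All draws are reproducible
#' from `spec$seed`.
#'
#' @param spec a [cohortSpec()] object.
#' @return a [ResponseCohort-class] object.
#' @examples
#' cohort <- simulateCohort(cohortSpec(nPerGroup = 2, nRegions = 12,
#'                                     nBlocks = 12, nModules = 3))
#' dim(assay(cohort))
#' @export
simulateCohort <- function(spec) {
    .validateCohortSpec(spec)
    template <- buildGroundTruthCoupling(spec)  # also seeds the RNG stream
    n <- spec$nRegions
    nSubj <- 2L * spec$nPerGroup
    conditions <- c("quiet", "noisy")
    labels <- .regionLabels(n)

    subjects <- sprintf("S%02d", seq_len(nSubj))
    groups <- rep(c("younger", "older"), each = spec$nPerGroup)

    lr <- attr(template, "longRange")
    mod <- attr(template, "module")
    base <- template
    attributes(base) <- list(dim = dim(base))
    offDiag <- row(base) != col(base)
    lrIdx <- which(lr & offDiag)
    # the condition modulation targets the first half of the modules (the
    # "task-relevant" communities); the rest keep their baseline coupling
    taskModules <- seq_len(ceiling(spec$nModules / 2))
    taskNode <- mod %in% taskModules
    inIdx <- which(!lr & offDiag & outer(taskNode, taskNode, "&"))

    # per-subject latent long-range coupling factor (mean 1)
    fs <- pmax(rnorm(nSubj, 1, spec$subjectSd), 0.2)
    effFactor <- fs * ifelse(groups == "older", 1 - spec$deltaGroup, 1)
    thickness <- spec$thicknessBase +
        spec$thicknessSlope * (effFactor - 1) +
        rnorm(nSubj, 0, spec$thicknessSd)
    motion <- rlnorm(nSubj, meanlog = log(0.12), sdlog = 0.35)

    nCols <- nSubj * 2L * spec$nBlocks
    resp <- matrix(NA_real_, n, nCols)
    colSubject <- character(nCols)
    colGroup <- character(nCols)
    colCondition <- character(nCols)
    colBlock <- integer(nCols)
    colAccuracy <- numeric(nCols)

    at <- 0L
    for (s in seq_len(nSubj)) {
        sgn <- if (groups[s] == "younger") 1 else -1
        for (cond in conditions) {
            csgn <- if (cond == "noisy") 0.5 else -0.5
            intraFactor <- 1 + sgn * csgn * spec$deltaInteraction
            Sigma <- .subjectCovariance(base, lrIdx, inIdx, spec$noiseSd,
                                        effFactor[s], intraFactor)
            Z <- matrix(rnorm(spec$nBlocks * n), spec$nBlocks, n)
            X <- t(Z %*% chol(Sigma))  # regions x blocks

            p <- spec$accuracyModel[paste(groups[s], cond, sep = ".")]
            acc <- rbinom(spec$nBlocks, 4L, p) / 4
            if (spec$accuracyConfound != 0)
                X <- X + spec$accuracyConfound *
                    matrix(acc, n, spec$nBlocks, byrow = TRUE)

            idx <- at + seq_len(spec$nBlocks)
            resp[, idx] <- X
            colSubject[idx] <- subjects[s]
            colGroup[idx] <- groups[s]
            colCondition[idx] <- cond
            colBlock[idx] <- seq_len(spec$nBlocks)
            colAccuracy[idx] <- acc
            at <- at + spec$nBlocks
        }
    }
    rownames(resp) <- labels

    rowDat <- if (n == 66L) atlasTable()
              else data.frame(region = labels, hemisphere = NA_character_,
                              abbreviation = labels, name = labels,
                              stringsAsFactors = FALSE)
    se <- SummarizedExperiment(
        assays = list(response = resp),
        rowData = DataFrame(rowDat, row.names = labels),
        colData = DataFrame(subject = colSubject, group = colGroup,
                            condition = colCondition, block = colBlock,
                            accuracy = colAccuracy))
    metadata(se)$subjects <- data.frame(
        subject = subjects, group = groups, thickness = thickness,
        motion = motion, couplingFactor = effFactor,
        stringsAsFactors = FALSE)
    metadata(se)$spec <- spec
    new("ResponseCohort", se)
}
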