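#' Cohort-level network metric table
#'
#' Result container for [networkMetrics()]: one row per subject x condition
#' of cost-averaged raw and normalized whole-cortex measures together with
#' the subject covariates, plus matrices of cost-averaged normalized nodal
#' values (rows aligned with the table, columns are regions).
#'
#' @slot network data.frame, one row per subject x condition: `subject`,
#'   `group`, `condition`, `eglob`, `eloc`, `eglobNorm`, `elocNorm`,
#'   `thickness`, `motion`, `accuracy` (mean fraction correct).
#' @slot nodalEglobNorm,nodalElocNorm numeric matrices (rows x regions).
#' @slot costs numeric cost grid used.
#' @slot nSurrogates integer(1) surrogates per network (0 = unnormalized).
#' @slot seed integer(1).
#' @exportClass CohortMetrics
setClass("CohortMetrics",
    representation(network = "data.frame",
                   nodalEglobNorm = "matrix", nodalElocNorm = "matrix",
                   costs = "numeric", nSurrogates = "integer",
                   seed = "integer"))

setValidity("CohortMetrics", function(object) {
    msg <- NULL
    if (nrow(object@network) != nrow(object@nodalEglobNorm) ||
        nrow(object@network) != nrow(object@nodalElocNorm))
        msg <- c(msg, "nodal matrices must align with the network table")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn CohortMetrics-class compact display
#' @param object a `CohortMetrics`
#' @export
setMethod("show", "CohortMetrics", function(object) {
    cat(sprintf(paste0(
        "CohortMetrics: %d subject x condition rows, %d regions,\n",
        "  %d costs (%.2f-%.2f), %d surrogates per network\n"),
        nrow(object@network), ncol(object@nodalEglobNorm),
        length(object@costs), min(object@costs), max(object@costs),
        object@nSurrogates))
})

#' Whole-cortex measure table of a CohortMetrics object
#' @param x a [CohortMetrics-class]
#' @return the subject x condition data.frame of cost-averaged measures.
#' @export
networkMeasures <- function(x) {
    stopifnot(is(x, "CohortMetrics"))
    x@network
}

#' Cost-averaged normalized nodal measures
#' @param x a [CohortMetrics-class]
#' @param measure `"eglobNorm"` or `"elocNorm"`
#' @return numeric matrix, rows aligned with [networkMeasures()], columns
#'   are regions.
#' @export
nodalMeasures <- function(x, measure = c("eglobNorm", "elocNorm")) {
    stopifnot(is(x, "CohortMetrics"))
    measure <- match.arg(measure)
    if (measure == "eglobNorm") x@nodalEglobNorm else x@nodalElocNorm
}

#' Run the network-construction and efficiency pipeline over a cohort
#'
#' For every subject and condition: build the zero-lag correlation matrix
#' (optionally after regressing per-block task accuracy out of the
#' responses), threshold it to each cost on the grid, compute raw global
#' and local efficiency, normalize against a degree-preserving surrogate
#' ensemble, and cost-average the resulting curves.
#'
#' Residualization follows the convention of regressing accuracy out of the
#' full functional data: the two conditions' blocks are concatenated per
#' subject, residualized jointly against an intercept and block accuracy,
#' and then re-split by condition before correlation.
#'
#' @param cohort a [ResponseCohort-class].
#' @param costs cost grid (default [costGrid()], 16 levels).
#' @param nSurrogates surrogates per subject x condition x cost (default
#'   50). `0` skips normalization (normalized columns become `NA`).
#' @param seed integer seed controlling the surrogate ensembles.
#' @param residualize regress per-block accuracy out of the responses
#'   before correlation (default `FALSE`).
#' @param nSwapAttempts attempted swaps per surrogate (default 10 x edges).
#' @return a [CohortMetrics-class].
#' @examples
#' cohort <- simulateCohort(cohortSpec(nPerGroup = 2, nRegions = 12,
#'                                     nBlocks = 20, nModules = 3))
#' m <- networkMetrics(cohort, costs = c(0.2, 0.3), nSurrogates = 5)
#' head(networkMeasures(m))
#' @export
networkMetrics <- function(cohort, costs = costGrid(), nSurrogates = 50L,
                           seed = 1L, residualize = FALSE,
                           nSwapAttempts = NULL) {
    stopifnot(is(cohort, "ResponseCohort"))
    set.seed(as.integer(seed))
    subj <- subjectInfo(cohort)
    cd <- colData(cohort)
    conditions <- .conditionLevels(cd$condition)
    labels <- rownames(cohort)
    resp <- assay(cohort, "response")
    # column indices per subject x condition, in block order
    ord <- order(cd$subject, cd$condition, cd$block)
    idxMap <- split(ord, paste(cd$subject[ord], cd$condition[ord]))

    rows <- list()
    nodG <- list()
    nodL <- list()
    k <- 0L
    for (s in seq_len(nrow(subj))) {
        id <- subj$subject[s]
        idxs <- lapply(conditions, function(cond)
            idxMap[[paste(id, cond)]])
        names(idxs) <- conditions
        mats <- lapply(idxs, function(ix) resp[, ix, drop = FALSE])
        accs <- lapply(idxs, function(ix) cd$accuracy[ix])
        if (residualize) {
            acc <- unlist(accs, use.names = FALSE)
            joint <- do.call(cbind, mats)
            resid <- residualizePerformance(joint, acc)
            nb <- vapply(mats, ncol, integer(1))
            off <- cumsum(c(0L, nb[-length(nb)]))
            mats <- lapply(seq_along(conditions), function(i)
                resid[, off[i] + seq_len(nb[i]), drop = FALSE])
            names(mats) <- conditions
        }
        for (cond in conditions) {
            R <- correlationMatrix(mats[[cond]])
            profiles <- vector("list", length(costs))
            rawG <- rawL <- numeric(length(costs))
            for (ci in seq_along(costs)) {
                net <- thresholdToCost(R, costs[ci])
                prof <- efficiencyProfile(net)
                rawG[ci] <- prof@netEglob
                rawL[ci] <- prof@netEloc
                if (nSurrogates > 0L) {
                    ens <- surrogateEnsemble(net, nSurrogates = nSurrogates,
                                             nSwapAttempts = nSwapAttempts)
                    profiles[[ci]] <- normalizeProfile(prof, ens)
                }
            }
            k <- k + 1L
            if (nSurrogates > 0L) {
                avg <- costAverage(profiles, costs = costs)
            } else {
                avg <- list(netEglobNorm = NA_real_, netElocNorm = NA_real_,
                            nodalEglobNorm = rep(NA_real_, length(labels)),
                            nodalElocNorm = rep(NA_real_, length(labels)))
            }
            acc <- accs[[cond]]
            rows[[k]] <- data.frame(
                subject = id, group = subj$group[s], condition = cond,
                eglob = mean(rawG), eloc = mean(rawL),
                eglobNorm = avg$netEglobNorm, elocNorm = avg$netElocNorm,
                thickness = subj$thickness[s], motion = subj$motion[s],
                accuracy = mean(acc), stringsAsFactors = FALSE)
            nodG[[k]] <- avg$nodalEglobNorm
            nodL[[k]] <- avg$nodalElocNorm
        }
    }
    network <- do.call(rbind, rows)
    rownames(network) <- NULL
    mG <- do.call(rbind, nodG)
    mL <- do.call(rbind, nodL)
    colnames(mG) <- colnames(mL) <- labels
    new("CohortMetrics", network = network, nodalEglobNorm = mG,
        nodalElocNorm = mL, costs = costs,
        nSurrogates = as.integer(nSurrogates), seed = as.integer(seed))
}

#' Group and condition inference over a cohort metric table
#'
#' Runs the whole-cortex two-by-two mixed ANOVAs (normalized global and
#' local efficiency), the regional effect screen, the thickness-measure
#' correlations per condition (Shapiro-Wilk gated), and the head-motion
#' control analyses.
#'
#' @param metrics a [CohortMetrics-class].
#' @param alpha regional significance threshold (default 0.05,
#'   uncorrected).
#' @return list with elements `wholeCortex` (data.frame of ANOVA rows for
#'   both measures), `regional`, `covariates`, `motion`.
#' @export
cohortStats <- function(metrics, alpha = 0.05) {
    stopifnot(is(metrics, "CohortMetrics"))
    net <- networkMeasures(metrics)
    whole <- do.call(rbind, lapply(c("eglobNorm", "elocNorm"), function(m) {
        an <- mixedAnova2x2(net, m)
        cbind(measure = m, an, stringsAsFactors = FALSE)
    }))
    rownames(whole) <- NULL
    regional <- regionalEffects(metrics, alpha = alpha)
    condMean <- aggregate(
        net[, c("eglobNorm", "elocNorm", "thickness")],
        list(subject = net$subject), mean)
    sets <- c(as.list(unique(net$condition)), list("mean"))
    covs <- do.call(rbind, lapply(sets, function(cond) {
        d <- if (identical(cond, "mean")) condMean
             else net[net$condition == cond, ]
        do.call(rbind, lapply(c("eglobNorm", "elocNorm"), function(m) {
            ca <- covariateAssociation(d, "thickness", m)
            cbind(condition = cond, measure = m, ca,
                  stringsAsFactors = FALSE)
        }))
    }))
    rownames(covs) <- NULL
    motion <- motionComparison(metrics)
    list(wholeCortex = whole, regional = regional, covariates = covs,
         motion = motion)
}
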