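#' Cohort of regional response matrices
#'
#' `ResponseCohort` extends [SummarizedExperiment::SummarizedExperiment] to
#' hold one cohort of parcellated regional responses. The single assay
#' `"response"` is a regions x observations matrix whose columns are
#' individual task blocks; `colData` identifies the subject, group, task
#' condition, block index and per-block task accuracy of each column, and
#' `rowData` carries the atlas (abbreviation, full name, hemisphere).
#' Subject-level covariates (thickness, motion, the latent coupling factor
#' when simulated) live in `metadata(x)$subjects`.
#'
#' @slot (inherited) see [SummarizedExperiment::SummarizedExperiment].
#' @aliases ResponseCohort
#' @exportClass ResponseCohort
setClass("ResponseCohort", contains = "SummarizedExperiment")

setValidity("ResponseCohort", function(object) {
    msg <- NULL
    if (!("response" %in% assayNames(object)))
        msg <- c(msg, "assay 'response' is required")
    need <- c("subject", "group", "condition", "block")
    miss <- setdiff(need, colnames(colData(object)))
    if (length(miss))
        msg <- c(msg, paste0("colData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    subj <- metadata(object)$subjects
    if (is.null(subj) || !is.data.frame(subj))
        msg <- c(msg, "metadata(x)$subjects data.frame is required")
    if (is.null(msg)) TRUE else msg
})

#' Fixed-cost weighted network
#'
#' A symmetric, zero-diagonal adjacency matrix whose nonzero entries are the
#' absolute correlations retained at a fixed cost (fraction of possible
#' edges present). `rC` is the realized cutoff, i.e. the smallest retained
#' absolute correlation.
#'
#' @slot W numeric matrix, symmetric, zero diagonal, entries in \[0, 1\].
#' @slot cost numeric(1), target fraction of possible edges.
#' @slot rC numeric(1), smallest retained absolute correlation.
#' @slot nEdges integer(1), number of retained edges.
#' @exportClass WeightedNetwork
setClass("WeightedNetwork",
    representation(W = "matrix", cost = "numeric", rC = "numeric",
                   nEdges = "integer"))

setValidity("WeightedNetwork", function(object) {
    W <- object@W
    msg <- NULL
    if (nrow(W) != ncol(W)) msg <- c(msg, "W must be square")
    else {
        if (any(abs(W - t(W)) > 1e-12)) msg <- c(msg, "W must be symmetric")
        if (any(diag(W) != 0)) msg <- c(msg, "W must have a zero diagonal")
        if (any(W < 0) || any(W > 1))
            msg <- c(msg, "weights must lie in [0, 1]")
    }
    if (length(object@cost) != 1 || object@cost <= 0 || object@cost > 1)
        msg <- c(msg, "cost must be a single value in (0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' Raw efficiency profile of a network
#'
#' Nodal and network-average global and local efficiency of a
#' [WeightedNetwork-class] at one cost, plus node degrees.
#'
#' @slot nodalEglob,nodalEloc numeric per-node efficiencies in \[0, 1\].
#' @slot netEglob,netEloc numeric(1) network averages (means over nodes).
#' @slot degree integer per-node degree.
#' @slot cost numeric(1) the network cost the profile was computed at.
#' @exportClass EfficiencyProfile
setClass("EfficiencyProfile",
    representation(nodalEglob = "numeric", nodalEloc = "numeric",
                   netEglob = "numeric", netEloc = "numeric",
                   degree = "integer", cost = "numeric"))

setValidity("EfficiencyProfile", function(object) {
    msg <- NULL
    if (length(object@nodalEglob) != length(object@nodalEloc))
        msg <- c(msg, "nodal vectors must have equal length")
    if (any(object@nodalEglob < -1e-12) || any(object@nodalEglob > 1 + 1e-12) ||
        any(object@nodalEloc  < -1e-12) || any(object@nodalEloc  > 1 + 1e-12))
        msg <- c(msg, "efficiencies must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' Surrogate ensemble summary
#'
#' Mean network-average efficiencies over an ensemble of degree-preserving
#' randomized surrogates of one network.
#'
#' @slot nSurrogates integer(1) ensemble size.
#' @slot seed integer(1) RNG seed used (NA if inherited from the session).
#' @slot meanNetEglob,meanNetEloc numeric(1) surrogate means.
#' @slot nSwapsMean numeric(1) mean accepted swap count per surrogate.
#' @exportClass SurrogateEnsemble
setClass("SurrogateEnsemble",
    representation(nSurrogates = "integer", seed = "integer",
                   meanNetEglob = "numeric", meanNetEloc = "numeric",
                   nSwapsMean = "numeric"))

#' Surrogate-normalized efficiency profile
#'
#' Raw efficiencies divided by the surrogate ensemble's mean network-average
#' values. Nodal values are divided by the surrogate network average (not by
#' per-node surrogate values).
#'
#' @slot nodalEglobNorm,nodalElocNorm numeric per-node normalized values.
#' @slot netEglobNorm,netElocNorm numeric(1) normalized network averages.
#' @slot cost numeric(1).
#' @exportClass NormalizedProfile
setClass("NormalizedProfile",
    representation(nodalEglobNorm = "numeric", nodalElocNorm = "numeric",
                   netEglobNorm = "numeric", netElocNorm = "numeric",
                   cost = "numeric"))

#' @describeIn WeightedNetwork-class compact display
#' @param object a `WeightedNetwork`
#' @export
setMethod("show", "WeightedNetwork", function(object) {
    cat(sprintf(
        "WeightedNetwork: %d nodes, %d edges (cost %.3f, r_c = %.4f)\n",
        nrow(object@W), object@nEdges, object@cost, object@rC))
})

#' @describeIn EfficiencyProfile-class compact display
#' @param object an `EfficiencyProfile`
#' @export
setMethod("show", "EfficiencyProfile", function(object) {
    cat(sprintf(
        "EfficiencyProfile (cost %.3f): E_glob = %.4f, E_loc = %.4f over %d nodes\n",
        object@cost, object@netEglob, object@netEloc,
        length(object@nodalEglob)))
})

#' @describeIn NormalizedProfile-class compact display
#' @param object a `NormalizedProfile`
#' @export
setMethod("show", "NormalizedProfile", function(object) {
    cat(sprintf(
        "NormalizedProfile (cost %.3f): E_glob^norm = %.4f, E_loc^norm = %.4f\n",
        object@cost, object@netEglobNorm, object@netElocNorm))
})

#' @describeIn SurrogateEnsemble-class compact display
#' @param object a `SurrogateEnsemble`
#' @export
setMethod("show", "SurrogateEnsemble", function(object) {
    cat(sprintf(
        "SurrogateEnsemble: %d surrogates, mean E_glob = %.4f, mean E_loc = %.4f\n",
        object@nSurrogates, object@meanNetEglob, object@meanNetEloc))
})

# ---- accessors ----

#' Adjacency matrix of a weighted network
#' @param x a [WeightedNetwork-class]
#' @return numeric matrix of edge weights.
#' @export
adjacency <- function(x) {
    stopifnot(is(x, "WeightedNetwork"))
    x@W
}

#' Network cost (fraction of possible edges present)
#' @param x a [WeightedNetwork-class], [EfficiencyProfile-class] or
#'   [NormalizedProfile-class]
#' @return numeric(1)
#' @export
networkCost <- function(x) x@cost

#' Number of edges of a weighted network
#' @param x a [WeightedNetwork-class]
#' @return integer(1)
#' @export
edgeCount <- function(x) {
    stopifnot(is(x, "WeightedNetwork"))
    x@nEdges
}

#' Realized correlation cutoff of a weighted network
#' @param x a [WeightedNetwork-class]
#' @return numeric(1), the smallest retained absolute correlation.
#' @export
cutoffR <- function(x) {
    stopifnot(is(x, "WeightedNetwork"))
    x@rC
}

#' Subject-level covariate table of a cohort
#'
#' @param x a [ResponseCohort-class]
#' @return a data.frame with one row per subject: `subject`, `group`,
#'   `thickness` (mm), `motion` (mm) and, for simulated cohorts,
#'   `couplingFactor` (the latent long-range coupling scale).
#' @export
subjectInfo <- function(x) {
    stopifnot(is(x, "ResponseCohort"))
    metadata(x)$subjects
}

#' Extract one subject/condition response matrix from a cohort
#'
#' @param x a [ResponseCohort-class]
#' @param subject subject identifier
#' @param condition condition label (e.g. `"quiet"` or `"noisy"`)
#' @return regions x blocks numeric matrix with region labels as rownames.
#' @export
responseMatrix <- function(x, subject, condition) {
    stopifnot(is(x, "ResponseCohort"))
    cd <- colData(x)
    sel <- cd$subject == subject & cd$condition == condition
    if (!any(sel))
        stop("no columns for subject '", subject, "', condition '",
             condition, "'")
    m <- assay(x, "response")[, sel, drop = FALSE]
    colnames(m) <- cd$block[sel]
    m[, order(cd$block[sel]), drop = FALSE]
}

#' Per-block task accuracy for one subject/condition
#'
#' @inheritParams responseMatrix
#' @return numeric vector of per-block fraction-correct values, in block
#'   order.
#' @export
blockAccuracy <- function(x, subject, condition) {
    stopifnot(is(x, "ResponseCohort"))
    cd <- colData(x)
    sel <- cd$subject == subject & cd$condition == condition
    if (!any(sel))
        stop("no columns for subject '", subject, "', condition '",
             condition, "'")
    acc <- cd$accuracy[sel]
    acc[order(cd$block[sel])]
}
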