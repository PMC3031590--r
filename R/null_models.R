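# edge list (i < j) and weights of a weighted network
.edgeList <- function(W) {
    ij <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
    list(edges = ij, weights = W[ij])
}

#' Degree-preserving rewiring of a weighted network
#'
#' Randomizes a network by repeated double-edge swaps: two edges `(a,b)`
#' and `(c,d)` are replaced by `(a,d)` and `(c,b)`, rejecting swaps that
#' would create self-loops or duplicate edges. Each surviving edge carries
#' its original weight with it, so the degree sequence and the multiset of
#' edge weights are preserved exactly. Graphs admitting no valid swap
#' (e.g. a triangle) are returned topologically unchanged with a message.
#'
#' @param net a [WeightedNetwork-class].
#' @param nSwapAttempts number of attempted swaps (default 10 x edge
#'   count, a standard mixing heuristic).
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   used.
#' @return a rewired [WeightedNetwork-class] with the same cost and `r_c`.
#' @examples
#' R <- correlationMatrix(matrix(rnorm(20 * 30), 20))
#' net <- thresholdToCost(R, 0.2)
#' surr <- rewireNetwork(net, seed = 1)
#' identical(sort(colSums(adjacency(surr) > 0)),
#'           sort(colSums(adjacency(net) > 0)))
#' @export
rewireNetwork <- function(net, nSwapAttempts = NULL, seed = NULL) {
    stopifnot(is(net, "WeightedNetwork"))
    if (net@nEdges < 2L) stop("rewiring requires at least 2 edges")
    if (!is.null(seed)) set.seed(seed)
    if (is.null(nSwapAttempts)) nSwapAttempts <- 10L * net@nEdges
    W <- adjacency(net)
    el <- .edgeList(W)
    res <- cpp_rewire(el$edges, nrow(W), as.integer(nSwapAttempts))
    if (res$n_swaps == 0L)
        message("no valid swap was accepted; returning the network ",
                "topologically unchanged")
    W2 <- matrix(0, nrow(W), ncol(W), dimnames = dimnames(W))
    e <- res$edges
    W2[e] <- el$weights
    W2[e[, c(2L, 1L), drop = FALSE]] <- el$weights
    new("WeightedNetwork", W = W2, cost = net@cost, rC = net@rC,
        nEdges = net@nEdges)
}

#' Ensemble of randomized surrogate networks
#'
#' Generates `nSurrogates` degree-preserving randomized surrogates of a
#' network and records the mean network-average global and local
#' efficiency across the ensemble, for use in [normalizeProfile()].
#'
#' @param net a [WeightedNetwork-class].
#' @param nSurrogates ensemble size (default 50).
#' @param nSwapAttempts attempted swaps per surrogate (default 10 x edges).
#' @param seed optional integer seed for the whole ensemble.
#' @return a [SurrogateEnsemble-class].
#' @examples
#' R <- correlationMatrix(matrix(rnorm(20 * 30), 20))
#' surrogateEnsemble(thresholdToCost(R, 0.2), nSurrogates = 5, seed = 1)
#' @export
surrogateEnsemble <- function(net, nSurrogates = 50L, nSwapAttempts = NULL,
                              seed = NULL) {
    stopifnot(is(net, "WeightedNetwork"), nSurrogates >= 1L)
    if (net@nEdges < 2L) stop("surrogates require at least 2 edges")
    if (!is.null(seed)) set.seed(seed)
    if (is.null(nSwapAttempts)) nSwapAttempts <- 10L * net@nEdges
    means <- cpp_surrogate_means(adjacency(net), as.integer(nSurrogates),
                                 as.integer(nSwapAttempts))
    new("SurrogateEnsemble",
        nSurrogates = as.integer(nSurrogates),
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
        meanNetEglob = means[1], meanNetEloc = means[2],
        nSwapsMean = NA_real_)
}

#' Normalize an efficiency profile against a surrogate ensemble
#'
#' Divides network-average efficiencies by the ensemble's mean
#' network-average values; nodal efficiencies are likewise divided by the
#' surrogate NETWORK averages (not by per-node surrogate values).
#'
#' @param profile an [EfficiencyProfile-class].
#' @param ensemble a [SurrogateEnsemble-class] built from the same network.
#' @return a [NormalizedProfile-class].
#' @export
normalizeProfile <- function(profile, ensemble) {
    stopifnot(is(profile, "EfficiencyProfile"),
              is(ensemble, "SurrogateEnsemble"))
    if (ensemble@meanNetEglob <= 0 || ensemble@meanNetEloc <= 0)
        stop("surrogate mean efficiencies must be > 0 to normalize")
    new("NormalizedProfile",
        nodalEglobNorm = profile@nodalEglob / ensemble@meanNetEglob,
        nodalElocNorm = profile@nodalEloc / ensemble@meanNetEloc,
        netEglobNorm = profile@netEglob / ensemble@meanNetEglob,
        netElocNorm = profile@netEloc / ensemble@meanNetEloc,
        cost = profile@cost)
}
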