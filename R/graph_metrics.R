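#' Shortest weighted path lengths
#'
#' All-pairs shortest path lengths of a weighted network, where traversing
#' an edge of weight `w` costs `1/w` (the functional distance: stronger
#' correlations are shorter). Unreachable pairs are `Inf`; the diagonal
#' is 0.
#'
#' @param net a [WeightedNetwork-class] (or a symmetric nonnegative
#'   adjacency matrix).
#' @return numeric n x n matrix of path lengths.
#' @examples
#' W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- W[2, 3] <- W[3, 2] <- 0.5
#' shortestPaths(W)[1, 3]  # 4 = 1/0.5 + 1/0.5
#' @export
shortestPaths <- function(net) {
    W <- if (is(net, "WeightedNetwork")) adjacency(net) else net
    stopifnot(is.matrix(W), nrow(W) == ncol(W), all(W >= 0))
    L <- cpp_shortest_paths(W)
    dimnames(L) <- dimnames(W)
    L
}

#' Nodal and network-average global efficiency
#'
#' `E_glob(i) = (1/(N-1)) * sum_{j != i} 1/L_ij` with `1/Inf = 0`, where
#' `L` are shortest weighted path lengths; the network value is the mean
#' over nodes.
#'
#' @param net a [WeightedNetwork-class] or adjacency matrix.
#' @param paths optional precomputed [shortestPaths()] matrix for `net`.
#' @return list with `nodal` (numeric per-node) and `network` (numeric(1)).
#' @examples
#' W <- matrix(1, 3, 3); diag(W) <- 0
#' globalEfficiency(W)$network  # complete unit-weight triangle: 1
#' @export
globalEfficiency <- function(net, paths = NULL) {
    W <- if (is(net, "WeightedNetwork")) adjacency(net) else net
    n <- nrow(W)
    if (n < 2L) stop("global efficiency requires at least 2 nodes")
    if (is.null(paths)) paths <- shortestPaths(W)
    inv <- ifelse(is.finite(paths) & paths > 0, 1 / paths, 0)
    diag(inv) <- 0
    nodal <- rowSums(inv) / (n - 1)
    names(nodal) <- rownames(W)
    list(nodal = nodal, network = mean(nodal))
}

#' Nodal and network-average local efficiency
#'
#' For a node `i` with degree `k_i >= 2`, shortest weighted paths are
#' computed strictly within the subgraph induced by the direct neighbours
#' of `i` (original weights restricted to neighbour-neighbour edges) and
#' `E_loc(i) = (1/(k_i(k_i-1))) * sum_{j != h} 1/L'_jh`. Nodes with
#' `k_i < 2` have `E_loc(i) = 0` and remain in the network average.
#'
#' @param net a [WeightedNetwork-class] or adjacency matrix.
#' @return list with `nodal`, `network` and `degree`.
#' @examples
#' W <- matrix(1, 3, 3); diag(W) <- 0
#' localEfficiency(W)$network  # unit-weight triangle: 1
#' @export
localEfficiency <- function(net) {
    W <- if (is(net, "WeightedNetwork")) adjacency(net) else net
    stopifnot(is.matrix(W), nrow(W) == ncol(W), all(W >= 0))
    eff <- cpp_efficiency(W)
    nodal <- eff$eloc
    names(nodal) <- rownames(W)
    list(nodal = nodal, network = mean(nodal), degree = eff$degree)
}

#' Full efficiency profile of a network
#'
#' Computes nodal and network-average global and local efficiency of a
#' fixed-cost weighted network in one call.
#'
#' @param net a [WeightedNetwork-class].
#' @return an [EfficiencyProfile-class].
#' @examples
#' R <- correlationMatrix(matrix(rnorm(20 * 30), 20))
#' efficiencyProfile(thresholdToCost(R, 0.2))
#' @export
efficiencyProfile <- function(net) {
    stopifnot(is(net, "WeightedNetwork"))
    W <- adjacency(net)
    if (nrow(W) < 2L) stop("efficiency requires at least 2 nodes")
    eff <- cpp_efficiency(W)
    nodalG <- eff$eglob
    nodalL <- eff$eloc
    names(nodalG) <- names(nodalL) <- rownames(W)
    new("EfficiencyProfile",
        nodalEglob = nodalG, nodalEloc = nodalL,
        netEglob = mean(nodalG), netEloc = mean(nodalL),
        degree = eff$degree, cost = net@cost)
}
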