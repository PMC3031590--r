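pathGraph <- function(weights) {
    n <- length(weights) + 1
    W <- matrix(0, n, n)
    for (i in seq_along(weights))
        W[i, i + 1] <- W[i + 1, i] <- weights[i]
    W
}

test_that("shortest paths follow reciprocal-weight lengths", {
    # unit-weight path a-b-c: L_ac = 2
    expect_equal(shortestPaths(pathGraph(c(1, 1)))[1, 3], 2)
    # weights 0.5: L_ac = 1/0.5 + 1/0.5 = 4
    expect_equal(shortestPaths(pathGraph(c(0.5, 0.5)))[1, 3], 4)
    # direct edge of weight 0.2 (length 5) loses to a 0.5/0.5 detour
    W <- pathGraph(c(0.5, 0.5))
    W[1, 3] <- W[3, 1] <- 0.2
    expect_equal(shortestPaths(W)[1, 3], 4)
    # disconnected pairs are infinite; empty graph all-infinite off-diagonal
    W0 <- matrix(0, 3, 3)
    L <- shortestPaths(W0)
    expect_true(all(is.infinite(L[upper.tri(L)])))
    expect_equal(diag(L), rep(0, 3))
})

test_that("global efficiency matches hand-derived small cases", {
    triangle <- matrix(1, 3, 3); diag(triangle) <- 0
    g <- globalEfficiency(triangle)
    expect_equal(unname(g$nodal), rep(1, 3))
    expect_equal(g$network, 1)
    # unit-weight 3-node path: pairwise inverse lengths (1, 1, 1/2)
    g2 <- globalEfficiency(pathGraph(c(1, 1)))
    expect_equal(g2$network, 5 / 6)
    # two isolated nodes
    expect_equal(globalEfficiency(matrix(0, 2, 2))$network, 0)
    expect_error(globalEfficiency(matrix(0, 1, 1)), "2 nodes")
})

test_that("local efficiency follows the neighbour-subgraph definition", {
    triangle <- matrix(1, 3, 3); diag(triangle) <- 0
    expect_equal(unname(localEfficiency(triangle)$nodal), rep(1, 3))
    # star centre: neighbours mutually unconnected
    star <- matrix(0, 4, 4)
    star[1, 2:4] <- star[2:4, 1] <- 1
    le <- localEfficiency(star)
    expect_equal(unname(le$nodal[1]), 0)
    # leaves have degree 1 -> 0 by convention
    expect_equal(unname(le$nodal[2:4]), rep(0, 3))
    # neighbour paths may not leave the subgraph: in a 4-cycle, node 1's
    # neighbours 2 and 4 are linked only through the excluded nodes
    cyc <- matrix(0, 4, 4)
    for (e in list(c(1, 2), c(2, 3), c(3, 4), c(4, 1)))
        cyc[e[1], e[2]] <- cyc[e[2], e[1]] <- 1
    expect_equal(unname(localEfficiency(cyc)$nodal), rep(0, 4))
})

test_that("efficiencies match exhaustive-enumeration oracles", {
    set.seed(101)
    for (rep in 1:25) {
        n <- sample(4:7, 1)
        W <- randomConnectedGraph(n)
        L <- shortestPaths(W)
        expect_equal(L, oracleShortestPaths(W), tolerance = 1e-12)
        g <- globalEfficiency(W, L)
        og <- oracleGlobalEfficiency(W)
        expect_equal(unname(g$nodal), og$nodal, tolerance = 1e-12)
        expect_equal(g$network, og$network, tolerance = 1e-12)
        l <- localEfficiency(W)
        ol <- oracleLocalEfficiency(W)
        expect_equal(unname(l$nodal), ol$nodal, tolerance = 1e-12)
    }
})

test_that("efficiencies agree with igraph on weighted graphs", {
    skip_if_not_installed("igraph")
    set.seed(202)
    for (rep in 1:5) {
        W <- randomConnectedGraph(10, extraEdges = 20)
        g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                                 weighted = TRUE)
        D <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
        expect_equal(unname(shortestPaths(W)), unname(D), tolerance = 1e-10)
        ge <- igraph::global_efficiency(g,
                                        weights = 1 / igraph::E(g)$weight)
        expect_equal(globalEfficiency(W)$network, ge, tolerance = 1e-10)
    }
})

test_that("scaling all weights by alpha scales efficiencies by alpha", {
    set.seed(33)
    W <- randomConnectedGraph(7)
    a <- 0.5
    g1 <- globalEfficiency(W); g2 <- globalEfficiency(a * W)
    expect_equal(g2$network, a * g1$network, tolerance = 1e-12)
    l1 <- localEfficiency(W); l2 <- localEfficiency(a * W)
    expect_equal(unname(l2$nodal), a * unname(l1$nodal), tolerance = 1e-12)
})

test_that("adding an edge never decreases nodal global efficiency", {
    set.seed(44)
    for (rep in 1:10) {
        W <- randomConnectedGraph(7, extraEdges = 2)
        absent <- which(W == 0 & upper.tri(W), arr.ind = TRUE)
        if (nrow(absent) == 0) next
        pick <- absent[sample(nrow(absent), 1), ]
        W2 <- W
        W2[pick[1], pick[2]] <- W2[pick[2], pick[1]] <- runif(1, 0.05, 1)
        before <- globalEfficiency(W)$nodal
        after <- globalEfficiency(W2)$nodal
        expect_true(all(after >= before - 1e-12))
    }
})

test_that("efficiencies are bounded in [0, 1] for weights <= 1", {
    set.seed(55)
    for (rep in 1:10) {
        W <- randomConnectedGraph(sample(3:7, 1))
        g <- globalEfficiency(W)$nodal
        l <- localEfficiency(W)$nodal
        expect_true(all(g >= 0 & g <= 1 + 1e-12))
        expect_true(all(l >= 0 & l <= 1 + 1e-12))
    }
})

test_that("efficiencyProfile bundles nodal and network values", {
    set.seed(66)
    R <- correlationMatrix(matrix(rnorm(20 * 30), 20))
    net <- thresholdToCost(R, 0.2)
    prof <- efficiencyProfile(net)
    expect_s4_class(prof, "EfficiencyProfile")
    expect_equal(prof@netEglob, mean(prof@nodalEglob))
    expect_equal(prof@netEloc, mean(prof@nodalEloc))
    expect_equal(prof@cost, 0.2)
    expect_equal(sum(prof@degree), 2L * edgeCount(net))
})
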