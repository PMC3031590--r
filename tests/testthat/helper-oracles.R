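# Independent oracles used across the test files. All are deliberately
# brute-force implementations kept separate from the package's own code
# paths.

# Exhaustive shortest-path oracle: enumerate every simple path between each
# pair of nodes and take the minimum sum of reciprocal weights. Only
# feasible for small graphs (<= 8 nodes).
oracleShortestPaths <- function(W) {
    n <- nrow(W)
    best <- matrix(Inf, n, n)
    diag(best) <- 0
    recurse <- function(current, target, visited, len) {
        if (current == target) {
            if (len < best[start, target])
                best[start, target] <<- len
            return(invisible())
        }
        for (nxt in seq_len(n)) {
            if (W[current, nxt] > 0 && !visited[nxt]) {
                v <- visited; v[nxt] <- TRUE
                recurse(nxt, target, v, len + 1 / W[current, nxt])
            }
        }
    }
    for (start in seq_len(n)) {
        for (target in seq_len(n)) {
            if (start == target) next
            visited <- rep(FALSE, n); visited[start] <- TRUE
            recurse(start, target, visited, 0)
        }
    }
    best
}

# Direct-formula efficiency oracle built on the enumeration oracle.
oracleGlobalEfficiency <- function(W) {
    n <- nrow(W)
    L <- oracleShortestPaths(W)
    nodal <- vapply(seq_len(n), function(i) {
        inv <- 1 / L[i, -i]
        inv[!is.finite(inv)] <- 0
        sum(inv) / (n - 1)
    }, numeric(1))
    list(nodal = nodal, network = mean(nodal))
}

oracleLocalEfficiency <- function(W) {
    n <- nrow(W)
    nodal <- vapply(seq_len(n), function(i) {
        nbr <- which(W[i, ] > 0)
        k <- length(nbr)
        if (k < 2) return(0)
        sub <- W[nbr, nbr, drop = FALSE]
        L <- oracleShortestPaths(sub)
        inv <- 1 / L
        inv[!is.finite(inv)] <- 0
        diag(inv) <- 0
        sum(inv) / (k * (k - 1))
    }, numeric(1))
    list(nodal = nodal, network = mean(nodal))
}

# Random connected weighted graph on n nodes: a random spanning tree plus
# extra random edges, weights uniform in (0, 1].
randomConnectedGraph <- function(n, extraEdges = n) {
    W <- matrix(0, n, n)
    perm <- sample(n)
    for (i in 2:n) {
        j <- perm[sample(i - 1, 1)]
        w <- runif(1, 0.05, 1)
        W[perm[i], j] <- W[j, perm[i]] <- w
    }
    for (e in seq_len(extraEdges)) {
        ij <- sample(n, 2)
        if (W[ij[1], ij[2]] == 0) {
            w <- runif(1, 0.05, 1)
            W[ij[1], ij[2]] <- W[ij[2], ij[1]] <- w
        }
    }
    W
}

# Mixed 2x2 ANOVA oracle via base aov() with an Error(subject) stratum.
oracleMixedAnova <- function(data, measure) {
    d <- data
    d$subject <- factor(d$subject)
    d$group <- factor(d$group)
    d$condition <- factor(d$condition)
    d$y <- d[[measure]]
    fit <- summary(aov(y ~ group * condition + Error(subject / condition),
                       data = d))
    betw <- fit[["Error: subject"]][[1]]
    with <- fit[["Error: subject:condition"]][[1]]
    list(Fgroup = betw["group", "F value"],
         pgroup = betw["group", "Pr(>F)"],
         Fcond = with["condition", "F value"],
         pcond = with["condition", "Pr(>F)"],
         Fint = with["group:condition", "F value"],
         pint = with["group:condition", "Pr(>F)"])
}

# Small balanced long-format dataset for ANOVA tests.
makeAnovaData <- function(nPerGroup, fun = rnorm) {
    n <- 2 * nPerGroup
    subjects <- sprintf("P%02d", seq_len(n))
    d <- expand.grid(subject = subjects,
                     condition = c("quiet", "noisy"),
                     stringsAsFactors = FALSE)
    d$group <- rep(c("younger", "older"),
                   each = nPerGroup)[match(d$subject, subjects)]
    d$y <- fun(nrow(d))
    d
}
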