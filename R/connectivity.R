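#' Zero-lag Pearson correlation matrix of regional responses
#'
#' Computes all pairwise zero-lag Pearson correlations between the rows
#' (regions) of a regions x blocks response matrix. The diagonal is stored
#' as 0 and never used downstream.
#'
#' @param responses numeric regions x blocks matrix (rownames are region
#'   labels), e.g. from [responseMatrix()].
#' @return symmetric correlation matrix with zero diagonal and the region
#'   labels as dimnames.
#' @examples
#' m <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 4, 3))
#' correlationMatrix(m)["a", "b"]  # 0.8
#' @export
correlationMatrix <- function(responses) {
    stopifnot(is.matrix(responses), is.numeric(responses))
    if (anyNA(responses)) stop("responses contain missing values")
    if (ncol(responses) < 3L)
        stop("at least 3 blocks are required to correlate")
    v <- apply(responses, 1L, var)
    if (any(v == 0)) {
        bad <- rownames(responses)[v == 0]
        if (is.null(bad)) bad <- which(v == 0)
        stop("zero-variance region(s): ", paste(bad, collapse = ", "))
    }
    R <- cor(t(responses))
    diag(R) <- 0
    R
}

#' Cost grid for network construction
#'
#' The fixed grid of network costs at which thresholded networks are built:
#' 0.10 to 0.40 in increments of 0.02 (16 levels, endpoints inclusive).
#'
#' @return numeric vector of length 16.
#' @examples
#' length(costGrid())
#' @export
costGrid <- function() {
    (5:20) / 50
}

# round-half-up of a nonnegative scalar (round() in R rounds half to even)
.roundHalfUp <- function(x) floor(x + 0.5)

#' Threshold a correlation matrix to a fixed-cost weighted network
#'
#' Retains exactly `round_half_up(cost * n(n-1)/2)` edges with the largest
#' absolute correlations, weighted `W_ij = |R_ij|`. Ties at the cutoff are
#' broken deterministically by ascending `(i, j)` node-index order, which
#' also makes edge sets nest across increasing costs. The realized cutoff
#' `r_c` is the smallest retained absolute correlation.
#'
#' @param R symmetric correlation matrix with zero (or ignorable) diagonal,
#'   e.g. from [correlationMatrix()].
#' @param cost target fraction of possible edges in (0, 1\].
#' @return a [WeightedNetwork-class].
#' @examples
#' R <- correlationMatrix(matrix(rnorm(66 * 60), 66))
#' edgeCount(thresholdToCost(R, 0.10))  # 215 of 2145 possible edges
#' @export
thresholdToCost <- function(R, cost) {
    stopifnot(is.matrix(R), nrow(R) == ncol(R))
    if (length(cost) != 1 || cost <= 0 || cost > 1)
        stop("cost must be a single value in (0, 1]")
    n <- nrow(R)
    nPairs <- n * (n - 1L) / 2L
    E <- .roundHalfUp(cost * nPairs)
    if (E < 1L) stop("cost ", cost, " yields zero edges for n = ", n)
    ij <- which(upper.tri(R), arr.ind = TRUE)
    a <- abs(R[upper.tri(R)])
    if (any(!is.finite(a)))
        stop("non-finite correlations present")
    if (E > length(a))
        stop("cost ", cost, " requires more edges than available pairs")
    ord <- order(-a, ij[, 1L], ij[, 2L])
    keep <- ord[seq_len(E)]
    W <- matrix(0, n, n, dimnames = dimnames(R))
    W[ij[keep, , drop = FALSE]] <- a[keep]
    W[ij[keep, c(2L, 1L), drop = FALSE]] <- a[keep]
    new("WeightedNetwork", W = W, cost = cost, rC = min(a[keep]),
        nEdges = as.integer(E))
}

#' Regress per-block task accuracy out of regional responses
#'
#' Replaces each region's row with the residuals of an ordinary
#' least-squares regression of that row on an intercept and the per-block
#' accuracy regressor, so the output rows have zero mean and zero sample
#' correlation with accuracy. If accuracy is constant across blocks (the
#' regressor is collinear with the intercept) the rows are simply demeaned,
#' with a warning.
#'
#' @param responses numeric regions x blocks matrix.
#' @param accuracy numeric vector of per-block fraction-correct values in
#'   \[0, 1\], one per column of `responses`.
#' @return matrix of residual responses, same shape and dimnames.
#' @examples
#' m <- rbind(r1 = c(1, 2, 3, 5))
#' residualizePerformance(m, c(0.25, 0.5, 0.75, 1))
#' @export
residualizePerformance <- function(responses, accuracy) {
    stopifnot(is.matrix(responses), is.numeric(accuracy))
    if (length(accuracy) != ncol(responses))
        stop("accuracy length must equal the number of blocks")
    if (any(accuracy < 0 | accuracy > 1))
        stop("accuracy must lie in [0, 1]")
    if (var(accuracy) == 0) {
        warning("accuracy is constant across blocks; demeaning responses")
        return(responses - rowMeans(responses))
    }
    X <- cbind(1, accuracy)
    fit <- lm.fit(X, t(responses))
    res <- t(fit$residuals)
    dimnames(res) <- dimnames(responses)
    res
}
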