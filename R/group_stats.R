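#' Cost-average normalized efficiency profiles
#'
#' Collapses the per-cost [NormalizedProfile-class] curve of one
#' subject/condition into summary values by an unweighted arithmetic mean
#' over the cost grid, for both the network-average and the nodal measures.
#'
#' @param profiles list of [NormalizedProfile-class] objects, one per cost.
#' @param costs the cost grid the profiles must cover (default
#'   [costGrid()], 16 levels). A missing cost level is an error.
#' @return list with `netEglobNorm`, `netElocNorm` (numeric(1)) and
#'   `nodalEglobNorm`, `nodalElocNorm` (numeric per node).
#' @export
costAverage <- function(profiles, costs = costGrid()) {
    stopifnot(is.list(profiles),
              all(vapply(profiles, is, TRUE, "NormalizedProfile")))
    have <- vapply(profiles, networkCost, numeric(1))
    miss <- costs[!vapply(costs, function(co) any(abs(have - co) < 1e-9),
                          logical(1))]
    if (length(miss))
        stop("missing cost level(s): ", paste(format(miss), collapse = ", "))
    use <- vapply(costs, function(co) which(abs(have - co) < 1e-9)[1L],
                  integer(1))
    pr <- profiles[use]
    list(netEglobNorm = mean(vapply(pr, function(p) p@netEglobNorm,
                                    numeric(1))),
         netElocNorm = mean(vapply(pr, function(p) p@netElocNorm,
                                   numeric(1))),
         nodalEglobNorm = rowMeans(vapply(
             pr, function(p) p@nodalEglobNorm,
             numeric(length(pr[[1]]@nodalEglobNorm)))),
         nodalElocNorm = rowMeans(vapply(
             pr, function(p) p@nodalElocNorm,
             numeric(length(pr[[1]]@nodalElocNorm)))))
}

# canonical condition ordering: quiet before noisy, otherwise alphabetical
.conditionLevels <- function(cond) {
    u <- unique(cond)
    if (setequal(u, c("quiet", "noisy"))) c("quiet", "noisy") else sort(u)
}

# canonical group ordering: younger before older, otherwise alphabetical
.groupLevels <- function(group) {
    u <- unique(group)
    if (setequal(u, c("younger", "older"))) c("younger", "older") else sort(u)
}

.initial <- function(x) toupper(substr(x, 1L, 1L))

#' Two-by-two repeated-measures mixed ANOVA
#'
#' Mixed-effects ANOVA with one between-subjects factor (group, 2 levels)
#' and one within-subjects factor (condition, 2 levels), computed from sums
#' of squares: the group effect is tested against subject-within-group
#' error, condition and group x condition against the condition x
#' subject-within-group error. With two conditions sphericity holds
#' trivially and every effect has `df = (1, n_subjects - 2)`. Direction
#' labels follow marginal means (e.g. `Y>O`, `N>Q`,
#' `Y(N>Q)>O(N>Q)` for an interaction where the younger group's
#' noisy-minus-quiet difference exceeds the older group's).
#'
#' @param data data.frame with columns `subject`, `group`, `condition` and
#'   the measure column; every subject must appear in both conditions.
#' @param measure name of the measure column to analyse.
#' @return data.frame with rows `group`, `condition`, `interaction` and
#'   columns `effect`, `F`, `df1`, `df2`, `p`, `direction`.
#' @examples
#' d <- expand.grid(subject = sprintf("S%d", 1:6),
#'                  condition = c("quiet", "noisy"))
#' d$group <- rep(c("younger", "older"), each = 3)[as.integer(d$subject)]
#' d$y <- rnorm(nrow(d))
#' mixedAnova2x2(d, "y")
#' @export
mixedAnova2x2 <- function(data, measure) {
    stopifnot(is.data.frame(data),
              all(c("subject", "group", "condition", measure) %in%
                  names(data)))
    gl <- .groupLevels(data$group)
    cl <- .conditionLevels(data$condition)
    if (length(gl) != 2L) stop("exactly 2 groups are required")
    if (length(cl) != 2L) stop("exactly 2 conditions are required")

    subjects <- unique(data$subject)
    n <- length(subjects)
    y <- matrix(NA_real_, n, 2L, dimnames = list(subjects, cl))
    grp <- character(n)
    for (r in seq_len(nrow(data))) {
        s <- match(data$subject[r], subjects)
        y[s, data$condition[r]] <- data[[measure]][r]
        grp[s] <- data$group[r]
    }
    if (anyNA(y)) stop("every subject must appear in both conditions")
    if (min(table(grp)) < 2L) stop("at least 2 subjects per group required")
    ng <- table(factor(grp, levels = gl))
    if (ng[1] != ng[2])
        warning("groups are unbalanced (", ng[1], " vs ", ng[2], ")")

    GM <- mean(y)
    Ms <- rowMeans(y)
    Mg <- tapply(Ms, factor(grp, levels = gl), mean)
    Mc <- colMeans(y)
    Mgc <- rbind(colMeans(y[grp == gl[1], , drop = FALSE]),
                 colMeans(y[grp == gl[2], , drop = FALSE]))

    ssGroup <- 2 * sum(ng * (Mg - GM)^2)
    ssSubj <- 2 * sum((Ms - Mg[match(grp, gl)])^2)
    ssCond <- n * sum((Mc - GM)^2)
    cellResid <- Mgc - outer(as.numeric(Mg), rep(0, 2L), "+") -
        matrix(Mc, 2L, 2L, byrow = TRUE) + GM
    ssInt <- sum(matrix(as.numeric(ng), 2L, 2L) * cellResid^2)
    ssBetween <- 2 * sum((Ms - GM)^2)
    ssTotal <- sum((y - GM)^2)
    ssErrW <- ssTotal - ssBetween - ssCond - ssInt

    dfe <- n - 2L
    msSubj <- ssSubj / dfe
    msErrW <- ssErrW / dfe
    if (msSubj <= 0 || msErrW <= 1e-300)
        stop("zero error variance: degenerate data")

    Fg <- (ssGroup / 1) / msSubj
    Fc <- (ssCond / 1) / msErrW
    Fi <- (ssInt / 1) / msErrW

    gAbb <- .initial(gl); cAbb <- .initial(cl)
    dirGroup <- if (Mg[1] >= Mg[2]) paste0(gAbb[1], ">", gAbb[2])
                else paste0(gAbb[2], ">", gAbb[1])
    dirCond <- if (Mc[2] >= Mc[1]) paste0(cAbb[2], ">", cAbb[1])
               else paste0(cAbb[1], ">", cAbb[2])
    dg <- Mgc[, 2] - Mgc[, 1]  # condition difference (level2 - level1)
    condDiff <- paste0(cAbb[2], ">", cAbb[1])
    dirInt <- if (dg[1] >= dg[2])
        paste0(gAbb[1], "(", condDiff, ")>", gAbb[2], "(", condDiff, ")")
    else
        paste0(gAbb[2], "(", condDiff, ")>", gAbb[1], "(", condDiff, ")")

    data.frame(effect = c("group", "condition", "interaction"),
               F = c(Fg, Fc, Fi),
               df1 = 1L, df2 = dfe,
               p = pf(c(Fg, Fc, Fi), 1, dfe, lower.tail = FALSE),
               direction = c(dirGroup, dirCond, dirInt),
               stringsAsFactors = FALSE)
}

#' Regional group/condition effects on nodal measures
#'
#' Runs the two-by-two mixed ANOVA per region and per measure on the
#' cost-averaged normalized nodal efficiencies and reports the effects
#' significant at an uncorrected p < 0.05 threshold (exploratory screen).
#' Optional Benjamini-Hochberg correction within each measure x effect
#' family is available but off by default.
#'
#' @param metrics a [CohortMetrics-class] from [networkMetrics()].
#' @param alpha significance threshold (default 0.05, uncorrected).
#' @param bhCorrect apply Benjamini-Hochberg correction across regions
#'   before thresholding (default `FALSE`).
#' @return data.frame with columns `region`, `measure`, `effect`,
#'   `direction`, `F`, `p` (empty when nothing passes).
#' @export
regionalEffects <- function(metrics, alpha = 0.05, bhCorrect = FALSE) {
    stopifnot(is(metrics, "CohortMetrics"))
    net <- networkMeasures(metrics)
    out <- list()
    for (measure in c("eglobNorm", "elocNorm")) {
        nodal <- if (measure == "eglobNorm") metrics@nodalEglobNorm
                 else metrics@nodalElocNorm
        rows <- lapply(colnames(nodal), function(reg) {
            d <- net[, c("subject", "group", "condition")]
            d$value <- nodal[, reg]
            an <- tryCatch(mixedAnova2x2(d, "value"), error = function(e) {
                message("region ", reg, " skipped: ", conditionMessage(e))
                NULL
            })
            if (is.null(an)) return(NULL)
            cbind(region = reg, measure = measure, an,
                  stringsAsFactors = FALSE)
        })
        out[[measure]] <- do.call(rbind, rows)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    if (bhCorrect) {
        for (m in unique(res$measure)) for (e in unique(res$effect)) {
            sel <- res$measure == m & res$effect == e
            res$p[sel] <- p.adjust(res$p[sel], method = "BH")
        }
    }
    res <- res[res$p < alpha, c("region", "measure", "effect", "direction",
                                "F", "p")]
    rownames(res) <- NULL
    res
}

#' Covariate association with normality gating
#'
#' Correlates a subject-level covariate with a network measure: both
#' variables are first screened with Shapiro-Wilk tests, and Pearson's
#' correlation (with two-tailed p and df = n - 2) is reported when both
#' pass (p > .05); otherwise Spearman's rho is reported with a flag.
#'
#' @param data data.frame with one row per subject.
#' @param covariate name of the covariate column (e.g. `"thickness"`).
#' @param measure name of the measure column.
#' @return data.frame with `r`, `p`, `df`, `method`, `normalityPass`.
#' @export
covariateAssociation <- function(data, covariate, measure) {
    stopifnot(is.data.frame(data),
              all(c(covariate, measure) %in% names(data)))
    x <- data[[covariate]]; y <- data[[measure]]
    if (anyNA(x) || anyNA(y)) stop("missing values in covariate or measure")
    n <- length(x)
    if (n < 4L) stop("at least 4 subjects are required")
    swp <- function(v) tryCatch(shapiro.test(v)$p.value,
                                error = function(e) 0)
    pass <- swp(x) > 0.05 && swp(y) > 0.05
    if (pass) {
        ct <- cor.test(x, y, method = "pearson")
        data.frame(r = unname(ct$estimate), p = ct$p.value,
                   df = unname(ct$parameter), method = "pearson",
                   normalityPass = TRUE)
    } else {
        ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
        data.frame(r = unname(ct$estimate), p = ct$p.value, df = NA_integer_,
                   method = "spearman", normalityPass = FALSE)
    }
}

#' Group comparison of head motion and motion-measure correlations
#'
#' Two-sample, two-tailed pooled-variance t-test (df = n - 2) of the
#' per-subject motion summaries between groups, plus Pearson correlations
#' of motion against each whole-cortex normalized measure within each
#' condition.
#'
#' @param metrics a [CohortMetrics-class].
#' @return list with `test` (data.frame: t, df, p) and `correlations`
#'   (data.frame: condition, measure, r, p), or `NULL` with a warning if
#'   motion is missing.
#' @export
motionComparison <- function(metrics) {
    stopifnot(is(metrics, "CohortMetrics"))
    net <- networkMeasures(metrics)
    subj <- net[!duplicated(net$subject),
                c("subject", "group", "motion")]
    if (is.null(subj$motion) || anyNA(subj$motion)) {
        warning("motion values missing; skipping motion comparison")
        return(NULL)
    }
    gl <- .groupLevels(subj$group)
    tt <- t.test(subj$motion[subj$group == gl[1]],
                 subj$motion[subj$group == gl[2]], var.equal = TRUE)
    cors <- do.call(rbind, lapply(unique(net$condition), function(cond) {
        d <- net[net$condition == cond, ]
        do.call(rbind, lapply(c("eglobNorm", "elocNorm"), function(m) {
            ct <- cor.test(d$motion, d[[m]], method = "pearson")
            data.frame(condition = cond, measure = m,
                       r = unname(ct$estimate), p = ct$p.value,
                       stringsAsFactors = FALSE)
        }))
    }))
    list(test = data.frame(t = unname(tt$statistic),
                           df = unname(tt$parameter),
                           p = tt$p.value),
         correlations = cors)
}
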