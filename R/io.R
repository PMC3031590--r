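#' Write a cohort to delimited text files
#'
#' Writes one response TSV per subject x condition (rows are regions with
#' their atlas labels, columns are task blocks), a `manifest.tsv` (subject,
#' group, condition, file path, thickness, motion) and an `accuracy.tsv`
#' (subject, condition, block, fraction_correct).
#'
#' @param cohort a [ResponseCohort-class].
#' @param dir output directory (created if absent).
#' @return the manifest path, invisibly.
#' @export
writeCohortTSV <- function(cohort, dir) {
    stopifnot(is(cohort, "ResponseCohort"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    subj <- subjectInfo(cohort)
    conditions <- .conditionLevels(colData(cohort)$condition)
    manifest <- list()
    accRows <- list()
    k <- 0L
    for (s in seq_len(nrow(subj))) {
        id <- subj$subject[s]
        for (cond in conditions) {
            m <- responseMatrix(cohort, id, cond)
            fname <- paste0(id, "_", cond, ".tsv")
            df <- data.frame(region = rownames(m), m, check.names = FALSE,
                             stringsAsFactors = FALSE)
            colnames(df) <- c("region",
                              paste0("block", seq_len(ncol(m))))
            write.table(df, file.path(dir, fname), sep = "\t",
                        quote = FALSE, row.names = FALSE)
            acc <- blockAccuracy(cohort, id, cond)
            k <- k + 1L
            manifest[[k]] <- data.frame(
                subject = id, group = subj$group[s], condition = cond,
                path = fname, thickness = subj$thickness[s],
                motion = subj$motion[s], stringsAsFactors = FALSE)
            accRows[[k]] <- data.frame(
                subject = id, condition = cond,
                block = seq_along(acc), fraction_correct = acc,
                stringsAsFactors = FALSE)
        }
    }
    manifestPath <- file.path(dir, "manifest.tsv")
    write.table(do.call(rbind, manifest), manifestPath, sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(do.call(rbind, accRows), file.path(dir, "accuracy.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(manifestPath)
}

#' Read a cohort from a manifest of response files
#'
#' Validates and loads a cohort written in the layout of
#' [writeCohortTSV()]: a manifest with columns `subject`, `group`,
#' `condition`, `path`, `thickness`, `motion` (one row per subject x
#' condition; paths relative to the manifest), and optionally an
#' `accuracy.tsv` next to it. Validation enumerates every violation:
#' missing columns, unknown group labels, duplicated subject x condition
#' rows, subjects lacking a condition, and missing files.
#'
#' @param path path to `manifest.tsv`.
#' @param groups allowed group labels (default `c("younger", "older")`).
#' @return a [ResponseCohort-class].
#' @export
readManifest <- function(path, groups = c("younger", "older")) {
    if (!file.exists(path)) stop("manifest not found: ", path)
    man <- read.delim(path, stringsAsFactors = FALSE)
    if (nrow(man) == 0L) stop("no subjects in manifest")
    problems <- character()
    need <- c("subject", "group", "condition", "path")
    miss <- setdiff(need, names(man))
    if (length(miss))
        stop("manifest lacks column(s): ", paste(miss, collapse = ", "))
    bad <- unique(man$group[!man$group %in% groups])
    if (length(bad))
        problems <- c(problems,
                      paste0("unknown group label(s): ",
                             paste(bad, collapse = ", ")))
    key <- paste(man$subject, man$condition)
    if (anyDuplicated(key))
        problems <- c(problems,
                      paste0("duplicated subject x condition: ",
                             paste(unique(key[duplicated(key)]),
                                   collapse = "; ")))
    conditions <- .conditionLevels(man$condition)
    for (id in unique(man$subject)) {
        have <- man$condition[man$subject == id]
        lack <- setdiff(conditions, have)
        if (length(lack))
            problems <- c(problems,
                          paste0("subject ", id, " lacks condition(s): ",
                                 paste(lack, collapse = ", ")))
    }
    base <- dirname(path)
    files <- file.path(base, man$path)
    absent <- !file.exists(files)
    if (any(absent))
        problems <- c(problems,
                      paste0("missing response file for ",
                             paste(paste(man$subject[absent],
                                         man$condition[absent]),
                                   collapse = "; ")))
    if (length(problems))
        stop("invalid manifest:\n  ",
             paste(problems, collapse = "\n  "))

    accPath <- file.path(base, "accuracy.tsv")
    acc <- if (file.exists(accPath))
        read.delim(accPath, stringsAsFactors = FALSE) else NULL

    respList <- list()
    cdList <- list()
    labels <- NULL
    for (r in seq_len(nrow(man))) {
        df <- read.delim(files[r], stringsAsFactors = FALSE,
                         check.names = FALSE)
        m <- as.matrix(df[, -1, drop = FALSE])
        rownames(m) <- df[[1]]
        if (is.null(labels)) labels <- rownames(m)
        else if (!identical(labels, rownames(m)))
            stop("region labels differ between response files (",
                 man$path[r], ")")
        nb <- ncol(m)
        a <- rep(NA_real_, nb)
        if (!is.null(acc)) {
            sel <- acc$subject == man$subject[r] &
                acc$condition == man$condition[r]
            if (sum(sel) == nb) a <- acc$fraction_correct[sel][
                order(acc$block[sel])]
        }
        respList[[r]] <- m
        cdList[[r]] <- data.frame(
            subject = man$subject[r], group = man$group[r],
            condition = man$condition[r], block = seq_len(nb),
            accuracy = a, stringsAsFactors = FALSE)
    }
    resp <- do.call(cbind, respList)
    cd <- do.call(rbind, cdList)
    subjRows <- !duplicated(man$subject)
    subjects <- data.frame(
        subject = man$subject[subjRows], group = man$group[subjRows],
        thickness = if ("thickness" %in% names(man))
            man$thickness[subjRows] else NA_real_,
        motion = if ("motion" %in% names(man))
            man$motion[subjRows] else NA_real_,
        stringsAsFactors = FALSE)

    n <- nrow(resp)
    rowDat <- if (n == 66L && identical(labels, atlasTable()$region))
        atlasTable()
    else data.frame(region = labels, hemisphere = NA_character_,
                    abbreviation = labels, name = labels,
                    stringsAsFactors = FALSE)
    se <- SummarizedExperiment(
        assays = list(response = resp),
        rowData = DataFrame(rowDat, row.names = labels),
        colData = DataFrame(cd))
    metadata(se)$subjects <- subjects
    new("ResponseCohort", se)
}

#' Run the full analysis and write its outputs
#'
#' End-to-end driver: computes [networkMetrics()] and [cohortStats()] for a
#' cohort and writes deterministic TSV outputs plus a plain-text run report
#' (seed, cost grid, surrogate count, residualization flag, package
#' version) to an output directory.
#'
#' @param cohort a [ResponseCohort-class] (simulated or read from a
#'   manifest).
#' @param outDir output directory.
#' @inheritParams networkMetrics
#' @param alpha regional significance threshold.
#' @return the [cohortStats()] list, invisibly; files are written to
#'   `outDir`.
#' @export
runPipeline <- function(cohort, outDir, costs = costGrid(),
                        nSurrogates = 50L, seed = 1L, residualize = FALSE,
                        alpha = 0.05) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    metrics <- networkMetrics(cohort, costs = costs,
                              nSurrogates = nSurrogates, seed = seed,
                              residualize = residualize)
    stats <- cohortStats(metrics, alpha = alpha)
    wt <- function(df, name) write.table(
        df, file.path(outDir, name), sep = "\t", quote = FALSE,
        row.names = FALSE)
    wt(networkMeasures(metrics), "network_measures.tsv")
    wt(stats$wholeCortex, "whole_cortex_anova.tsv")
    wt(stats$regional, "regional_effects.tsv")
    wt(stats$covariates, "covariates.tsv")
    if (!is.null(stats$motion)) {
        wt(stats$motion$test, "motion.tsv")
        wt(stats$motion$correlations, "motion_correlations.tsv")
    }
    report <- c(
        "cortnet run report",
        paste0("package version: ", as.character(packageVersion("cortnet"))),
        paste0("seed: ", seed),
        paste0("costs: ", paste(format(costs), collapse = ", "),
               " (", length(costs), " levels)"),
        paste0("surrogates per network: ", nSurrogates),
        paste0("residualize accuracy: ", residualize),
        paste0("regional alpha (uncorrected): ", alpha),
        paste0("subjects: ", length(unique(networkMeasures(metrics)$subject)),
               "; conditions: ",
               paste(unique(networkMeasures(metrics)$condition),
                     collapse = ", ")),
        "conventions: weights = |Pearson r|; edge length = 1/weight;",
        "  fixed-cost rank selection with round-half-up edge counts;",
        "  E_loc paths confined to the neighbour-induced subgraph;",
        "  surrogate swaps carry edge weights; nodal normalization by",
        "  surrogate network averages.")
    writeLines(report, file.path(outDir, "run_report.txt"))
    invisible(stats)
}
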