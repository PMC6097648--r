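## Group-comparison statistics: Shapiro-Wilk normality (reported, not
## used to auto-switch tests), one-way ANOVA, Tukey(-Kramer) HSD, and
## the star code convention of the figures.  N is the number of
## animals; SEM = sd / sqrt(N).

#' Shapiro-Wilk normality test
#'
#' Returns the Shapiro-Wilk p value for one sample.  The result is
#' reported alongside the ANOVA, never used to switch tests
#' automatically.  A zero-variance sample is degenerate: p is NA with
#' a warning.
#'
#' @param values numeric vector, n >= 3.
#' @return p value (NA for a degenerate constant sample), with the W
#'   statistic as attribute \code{"W"}.
#' @export
testNormality <- function(values) {
    values <- as.numeric(values)
    if (length(values) < 3L)
        stop("normality test needs at least 3 values")
    if (sd(values) == 0) {
        warning("constant sample: normality undefined, reported as NA")
        return(structure(NA_real_, W = NA_real_))
    }
    sw <- shapiro.test(values)
    structure(unname(sw$p.value), W = unname(sw$statistic))
}

#' Significance star codes
#'
#' \code{"ns"} for p > 0.05, \code{"*"} for p <= 0.05, \code{"**"} for
#' p <= 0.01, \code{"***"} for p <= 0.001 (boundaries inclusive).
#'
#' @param p numeric vector of p values in [0, 1].
#' @return character vector of codes.
#' @examples
#' stars(c(0.2, 0.04, 0.01, 0.001))  # "ns" "*" "**" "***"
#' @export
stars <- function(p) {
    if (any(is.na(p)) || any(p < 0 | p > 1))
        stop("p values must lie in [0, 1]")
    ifelse(p <= 0.001, "***",
           ifelse(p <= 0.01, "**",
                  ifelse(p <= 0.05, "*", "ns")))
}

#' Build a long-format group table
#'
#' Melts a per-specimen results data.frame (as produced by
#' [runStudy()]) into rows of (specimen_id, group, measure, value).
#'
#' @param results data.frame with columns \code{specimenId} (or
#'   \code{specimen_id}), \code{group} and numeric measure columns.
#' @param measures measure columns to keep (default: all numeric).
#' @return long data.frame.
#' @export
groupTable <- function(results, measures = NULL) {
    idCol <- intersect(c("specimenId", "specimen_id"), names(results))[1]
    if (is.na(idCol) || !"group" %in% names(results))
        stop("results must carry specimen ids and a 'group' column")
    num <- names(results)[vapply(results, is.numeric, logical(1))]
    num <- setdiff(num, c("seed"))
    if (!is.null(measures)) num <- intersect(num, measures)
    out <- do.call(rbind, lapply(num, function(m) {
        data.frame(specimen_id = results[[idCol]], group = results$group,
                   measure = m, value = results[[m]],
                   stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' For one measure of a long group table: per-group Shapiro-Wilk
#' normality, one-way ANOVA across groups, Tukey(-Kramer) HSD pairwise
#' p values (unequal group sizes allowed), star codes, and group means
#' with SEM (sd/sqrt(N), N = animals per group).
#'
#' @param table long data.frame as from [groupTable()] (columns
#'   specimen_id, group, measure, value).
#' @param measure measure name to analyse.
#' @return a \linkS4class{StatsReport}.
#' @examples
#' tab <- data.frame(specimen_id = as.character(1:9),
#'                   group = rep(c("a", "b", "c"), each = 3),
#'                   measure = "m",
#'                   value = c(1, 2, 3, 4, 5, 6, 9, 8, 7))
#' anovaTukey(tab, "m")
#' @export
anovaTukey <- function(table, measure) {
    rows <- table[table$measure == measure, ]
    if (nrow(rows) == 0L) stop(sprintf("no rows for measure '%s'", measure))
    rows$group <- factor(rows$group)
    ns <- table(rows$group)
    if (length(ns) < 2L) stop("need at least 2 groups")
    if (any(ns < 2L))
        stop(sprintf("group '%s' has fewer than 2 values",
                     names(ns)[which(ns < 2L)[1]]), call. = FALSE)
    normality <- do.call(rbind, lapply(levels(rows$group), function(gr) {
        v <- rows$value[rows$group == gr]
        p <- if (length(v) >= 3L && sd(v) > 0)
            suppressWarnings(testNormality(v)) else NA_real_
        data.frame(group = gr, n = length(v),
                   W = if (is.na(p)) NA_real_ else attr(p, "W"),
                   p = as.numeric(p), stringsAsFactors = FALSE)
    }))
    fit <- aov(value ~ group, data = rows)
    av <- summary(fit)[[1]]
    anova <- data.frame(dfBetween = av$Df[1], dfWithin = av$Df[2],
                        F = av$`F value`[1], p = av$`Pr(>F)`[1])
    ## equal group means give F = 0 and p = 1 (guard NaN when the
    ## residual variance is also 0)
    if (is.nan(anova$F)) { anova$F <- 0; anova$p <- 1 }
    tk <- TukeyHSD(fit)$group
    tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                        lwr = tk[, "lwr"], upr = tk[, "upr"],
                        p = tk[, "p adj"], stringsAsFactors = FALSE)
    tukey$p[is.nan(tukey$p)] <- 1
    tukey$stars <- stars(tukey$p)
    rownames(tukey) <- NULL
    means <- do.call(rbind, lapply(levels(rows$group), function(gr) {
        v <- rows$value[rows$group == gr]
        data.frame(group = gr, n = length(v), mean = mean(v),
                   sem = sd(v) / sqrt(length(v)), stringsAsFactors = FALSE)
    }))
    new("StatsReport", measure = measure, normality = normality,
        anova = anova, tukey = tukey, groupMeans = means)
}

## Serializable form used for report.json.
statsReportAsList <- function(report) {
    list(measure = report@measure,
         normality = report@normality,
         anova = report@anova,
         tukey = report@tukey,
         groupMeans = report@groupMeans)
}
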