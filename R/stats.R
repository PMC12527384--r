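# Statistical primitives shared by the characterization and region
# modules. The omnibus tests are written out from their sum-of-squares /
# studentized-range / Pearson definitions; the mixed model is delegated
# to lme4/lmerTest.

.checkGroups <- function(values, group) {
    stopifnot(length(values) == length(group))
    keep <- is.finite(values) & !is.na(group)
    values <- values[keep]
    group <- factor(group[keep])
    if (nlevels(group) < 2L) stop("need >= 2 groups", call. = FALSE)
    list(values = values, group = droplevels(group))
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA from the sum-of-squares
#' decomposition: `F = MS_between / MS_within` with `k - 1` and `n - k`
#' degrees of freedom, p-value from the upper tail of the F
#' distribution.
#'
#' @param values numeric observations.
#' @param group group label per observation (>= 2 groups).
#' @return list with `F`, `df1`, `df2`, `p`, `ms_within`, `means`,
#'   `n_per_group`.
#' @examples
#' oneWayAnova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))$F  # 0
#' @export
oneWayAnova <- function(values, group) {
    g <- .checkGroups(values, group)
    values <- g$values; group <- g$group
    n <- length(values); k <- nlevels(group)
    if (n <= k) stop("need more observations than groups", call. = FALSE)
    means <- tapply(values, group, mean)
    ni <- tabulate(group)
    grand <- mean(values)
    ssb <- sum(ni * (means - grand)^2)
    ssw <- sum((values - means[group])^2)
    df1 <- k - 1L; df2 <- n - k
    msw <- ssw / df2
    if (msw < .Machine$double.eps * max(1, abs(grand))^2) {
        if (ssb < .Machine$double.eps) {
            warning("zero variance everywhere; p undefined", call. = FALSE)
            return(list(F = NaN, df1 = df1, df2 = df2, p = NA_real_,
                        ms_within = msw, means = means, n_per_group = ni))
        }
    }
    Fstat <- (ssb / df1) / msw
    list(F = Fstat, df1 = df1, df2 = df2,
         p = pf(Fstat, df1, df2, lower.tail = FALSE),
         ms_within = msw, means = means, n_per_group = ni)
}

#' Tukey's Honest Significant Difference post hoc test
#'
#' Pairwise group comparisons after a one-way ANOVA, adjusted within the
#' family via the studentized-range distribution: for groups i, j the
#' statistic is `q = |m_i - m_j| / sqrt(MSE/2 (1/n_i + 1/n_j))` with
#' adjusted p `P(Q_{k, n-k} > q)` (Tukey-Kramer for unbalanced groups),
#' and the confidence interval uses the same critical value.
#'
#' @inheritParams oneWayAnova
#' @param conf_level family-wise confidence level for the intervals.
#' @return data.frame with one row per pair: `group1`, `group2`, `diff`,
#'   `lwr`, `upr`, `p_adj`.
#' @export
tukeyHsd <- function(values, group, conf_level = 0.95) {
    g <- .checkGroups(values, group)
    a <- oneWayAnova(g$values, g$group)
    k <- nlevels(g$group); df2 <- a$df2
    lev <- levels(g$group)
    pairs <- utils::combn(k, 2)
    qc <- qtukey(conf_level, k, df2)
    out <- apply(pairs, 2, function(idx) {
        i <- idx[1]; j <- idx[2]
        se <- sqrt(a$ms_within / 2 *
                   (1 / a$n_per_group[i] + 1 / a$n_per_group[j]))
        diff <- a$means[j] - a$means[i]
        q <- abs(diff) / se
        data.frame(group1 = lev[j], group2 = lev[i], diff = diff,
                   lwr = diff - qc * se, upr = diff + qc * se,
                   p_adj = ptukey(q, k, df2, lower.tail = FALSE),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, c(out, make.row.names = FALSE))
}

#' Pearson chi-square test on a contingency table
#'
#' `X^2 = sum (O - E)^2 / E` with expected counts from the product of
#' margins, `df = (r - 1)(c - 1)`, no continuity correction.
#'
#' @param table non-negative counts matrix (r x c), all margins > 0.
#' @return list with `chisq`, `df`, `p`, `expected`.
#' @examples
#' chiSquareContingency(matrix(c(20, 0, 0, 20), 2))$chisq  # 40
#' @export
chiSquareContingency <- function(table) {
    table <- as.matrix(table)
    if (any(table < 0) || anyNA(table)) {
        stop("counts must be non-negative", call. = FALSE)
    }
    rs <- rowSums(table); cs <- colSums(table)
    if (any(rs == 0) || any(cs == 0)) {
        stop("zero row or column margin", call. = FALSE)
    }
    n <- sum(table)
    expected <- outer(rs, cs) / n
    chisq <- sum((table - expected)^2 / expected)
    df <- (nrow(table) - 1L) * (ncol(table) - 1L)
    list(chisq = chisq, df = df,
         p = pchisq(chisq, df, lower.tail = FALSE), expected = expected)
}

#' Linear mixed-effects comparison across clusters
#'
#' Library-backed contract: fits `value ~ cluster + (1 | mouse)
#' [+ (1 | tme_class)]` with \pkg{lmerTest} (REML, Satterthwaite degrees
#' of freedom) and reports the fixed-effect omnibus p-value plus, when
#' \pkg{emmeans} is available, pairwise cluster contrasts with Tukey
#' adjustment. Non-convergence and singular fits are reported, never
#' silently downgraded to a fixed-effects ANOVA.
#'
#' @param data data.frame with the response and grouping columns.
#' @param response name of the numeric response column.
#' @param cluster name of the cluster (fixed-effect) column.
#' @param random character vector of random-intercept grouping columns,
#'   e.g. `c("mouse_id", "tme_class")`. Each needs >= 2 levels.
#' @return list with `formula`, `fit`, `fixed_p`, `converged`,
#'   `singular`, `contrasts` (data.frame or NULL).
#' @export
mixedModelCompare <- function(data, response, cluster,
                              random = "mouse_id") {
    stopifnot(is.data.frame(data),
              all(c(response, cluster, random) %in% names(data)))
    for (r in random) {
        if (length(unique(data[[r]])) < 2L) {
            stop("random-effect grouping '", r, "' has a single level; ",
                 "a mixed model cannot separate it from the residual",
                 call. = FALSE)
        }
    }
    data[[cluster]] <- factor(data[[cluster]])
    fml <- stats::as.formula(paste(
        response, "~", cluster, "+",
        paste(sprintf("(1 | %s)", random), collapse = " + ")))
    fit <- tryCatch(
        lmerTest::lmer(fml, data = data),
        error = function(e) e
    )
    if (inherits(fit, "error")) {
        return(list(formula = fml, fit = NULL, fixed_p = NA_real_,
                    converged = FALSE, singular = NA,
                    contrasts = NULL, message = conditionMessage(fit)))
    }
    conv <- length(fit@optinfo$conv$lme4$messages) == 0L
    a <- stats::anova(fit)
    contrasts <- NULL
    if (requireNamespace("emmeans", quietly = TRUE)) {
        em <- emmeans::emmeans(fit, cluster)
        contrasts <- as.data.frame(emmeans::contrast(em, "pairwise",
                                                     adjust = "tukey"))
    }
    list(formula = fml, fit = fit,
         fixed_p = a[cluster, "Pr(>F)"],
         converged = conv, singular = lme4::isSingular(fit),
         contrasts = contrasts)
}

#' Z-score within groups
#'
#' `(x - mean_group) / sd_group` with the sample (n - 1) standard
#' deviation. Singleton or zero-variance groups return NA with a
#' warning.
#'
#' @param values numeric vector.
#' @param group grouping vector of the same length.
#' @return numeric vector of standardized values.
#' @export
zscoreWithin <- function(values, group) {
    stopifnot(length(values) == length(group))
    group <- factor(group)
    out <- rep(NA_real_, length(values))
    warned <- FALSE
    for (g in levels(group)) {
        idx <- which(group == g & !is.na(values))
        if (length(idx) < 2L) { warned <- TRUE; next }
        s <- sd(values[idx])
        if (!is.finite(s) || s == 0) { warned <- TRUE; next }
        out[idx] <- (values[idx] - mean(values[idx])) / s
    }
    if (warned) {
        warning("group(s) with < 2 values or zero sd: z-scores set to NA",
                call. = FALSE)
    }
    out
}
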