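#' Per-gene Wilcoxon rank-sum differential expression
#'
#' Two-sided Mann-Whitney U test per gene between two cell groups, using
#' the normal approximation with tie correction (no continuity
#' correction), followed by Benjamini-Hochberg adjustment across genes.
#' Being rank-based, the verdicts are invariant to any strictly monotone
#' per-gene transformation of the input values. Genes that are constant
#' across all cells get p = 1 by convention.
#'
#' @param values genes x cells matrix of normalized or corrected values
#'   (dense or sparse).
#' @param groups per-cell labels with exactly two non-empty levels.
#' @param alpha significance threshold on the adjusted p-value (default
#'   0.05).
#' @param pseudocount added to group means before the log fold change.
#' @return data.frame with columns \code{gene}, \code{statistic} (U for
#'   the first group level), \code{p_value}, \code{adjusted_p},
#'   \code{log_fold_change}, \code{significant}.
#' @export
wilcoxonDE <- function(values, groups, alpha = 0.05, pseudocount = 1) {
    if (is(values, "CountMatrix")) values <- values@counts
    values <- as.matrix(values)
    if (is.null(rownames(values)))
        rownames(values) <- sprintf("gene%d", seq_len(nrow(values)))
    groups <- factor(groups)
    if (nlevels(groups) != 2 || any(tabulate(groups) == 0))
        stop("groups must contain exactly two non-empty levels")
    if (length(groups) != ncol(values))
        stop("groups must have one entry per cell")
    a <- groups == levels(groups)[1]
    nA <- sum(a); nB <- sum(!a); n <- nA + nB

    stats <- t(apply(values, 1, function(v) {
        r <- rank(v)
        u <- sum(r[a]) - nA * (nA + 1) / 2
        tie <- table(v)
        tiecor <- sum(tie^3 - tie)
        s2 <- nA * nB / 12 * ((n + 1) - tiecor / (n * (n - 1)))
        c(u = u, s2 = s2)
    }))
    mu_u <- nA * nB / 2
    z <- ifelse(stats[, "s2"] > 0,
                (stats[, "u"] - mu_u) / sqrt(stats[, "s2"]), 0)
    p <- ifelse(stats[, "s2"] > 0, 2 * pnorm(-abs(z)), 1)
    p <- pmin(p, 1)
    adj <- p.adjust(p, method = "BH")
    mA <- rowMeans(values[, a, drop = FALSE])
    mB <- rowMeans(values[, !a, drop = FALSE])
    data.frame(gene = rownames(values), statistic = stats[, "u"],
               p_value = p, adjusted_p = adj,
               log_fold_change = log((mA + pseudocount) /
                                     (mB + pseudocount)),
               significant = adj < alpha, row.names = NULL)
}

#' Mean vs residual-variance trend
#'
#' Quantifies how strongly residual variance depends on gene abundance: a
#' locally weighted (tricube) regression of residual variance on
#' \eqn{\log_{10}} mean, plus the Spearman rank correlation restricted to
#' genes with mean above 0.1 (below which estimates are dominated by
#' sampling noise). An effective variance stabilization leaves a flat
#' trend and a correlation near zero; a misspecified fixed-theta model
#' shows a strong positive trend.
#'
#' @param means per-gene arithmetic means (at least 20 genes).
#' @param residual_variances per-gene residual variances.
#' @param span loess span (default 0.3).
#' @return list with \code{trend} (data.frame of \code{log10_mean} and
#'   \code{fitted}), \code{rho} (Spearman correlation; 0 when degenerate),
#'   \code{n_genes} used for \code{rho}, and \code{degenerate} flag.
#' @export
meanVarianceTrend <- function(means, residual_variances, span = 0.3) {
    stopifnot(length(means) == length(residual_variances))
    if (length(means) < 20)
        stop("at least 20 genes are required to estimate a trend")
    ok <- means > 0 & is.finite(residual_variances)
    lx <- log10(means[ok]); y <- residual_variances[ok]
    if (sd(lx) == 0 || sd(y) == 0) {
        return(list(trend = data.frame(log10_mean = sort(lx),
                                       fitted = rep(mean(y), sum(ok))),
                    rho = 0, n_genes = sum(ok), degenerate = TRUE))
    }
    # exact functional relationships make loess complain about singular
    # local fits; the fitted curve is still well-defined
    fit <- suppressWarnings(loess(y ~ lx, span = span, degree = 2,
                                  family = "symmetric"))
    ord <- order(lx)
    sel <- means > 0.1 & is.finite(residual_variances)
    rho <- if (sum(sel) >= 3 && sd(means[sel]) > 0 &&
               sd(residual_variances[sel]) > 0)
        cor(means[sel], residual_variances[sel], method = "spearman")
    else 0
    list(trend = data.frame(log10_mean = lx[ord],
                            fitted = fitted(fit)[ord]),
         rho = rho, n_genes = sum(sel), degenerate = FALSE)
}

# Normalized value matrices for each DE input mode, each dataset fitted
# independently (the situation that produces depth-driven false positives
# for naive normalizations).
.de_values <- function(object, mode, n0 = NULL, n_genes = 2000,
                       n_cells = 2000, seed = NULL) {
    switch(mode,
        lograw = as.matrix(log1p(object@counts)),
        lognorm = {
            n <- depths(object)
            as.matrix(log1p(Matrix::t(Matrix::t(object@counts) *
                                      (1e4 / pmax(n, 1)))))
        },
        v1 = {
            fit <- vst(object, mode = "v1", n_genes = n_genes,
                       n_cells = n_cells, seed = seed)
            fit$residuals@residuals
        },
        v2 = {
            fit <- vst(object, mode = "v2", n_genes = n_genes,
                       n_cells = n_cells, seed = seed)
            cc <- correctedCounts(object, fit$params,
                                  n0 = if (is.null(n0)) "median" else n0)
            as.matrix(log1p(cc@counts))
        },
        stop("unknown normalization mode: ", mode))
}

#' Depth-confound false-positive experiment
#'
#' Creates a biologically identical copy of a (homogeneous) dataset at a
#' fraction \code{prop} of the sequencing depth by binomial thinning,
#' normalizes original and thinned copies independently under each
#' requested mode, and counts genes called differentially expressed
#' between the two copies by \code{\link{wilcoxonDE}}. Since the two
#' groups differ only in depth, every call is a false positive; an
#' effective depth normalization should yield (near) none.
#'
#' Modes: \code{"v2"} (log1p of corrected counts, with the reference depth
#' set to the smaller of the two median depths), \code{"v1"} (Pearson
#' residuals), \code{"lognorm"} (log1p of counts scaled to 10,000 per
#' cell), \code{"lograw"} (log1p of raw counts, no depth scaling).
#'
#' @param object a \linkS4class{CountMatrix} of a homogeneous population.
#' @param prop thinning proportion in (0, 1].
#' @param normalizations character vector of modes to evaluate.
#' @param seed optional integer seed (thinning and the VST fits derive
#'   sub-seeds from it).
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @param n_genes,n_cells estimation subset sizes for the VST fits.
#' @return data.frame with one row per mode: \code{mode},
#'   \code{n_significant}, \code{n_genes}, \code{fraction}.
#' @export
downsamplingFPExperiment <- function(object, prop = 0.2,
                                     normalizations = c("v2", "v1",
                                                        "lognorm",
                                                        "lograw"),
                                     seed = NULL, alpha = 0.05,
                                     n_genes = 2000, n_cells = 2000) {
    stopifnot(is(object, "CountMatrix"))
    ss <- .sub_seeds(seed, 3)
    thinned <- if (prop < 1) thinCounts(object, prop, seed = ss[1])
               else object
    groups <- factor(rep(c("full", "thinned"),
                         c(ncol(object), ncol(thinned))))
    n0_min <- min(median(depths(object)), median(depths(thinned)))
    out <- lapply(normalizations, function(mode) {
        vals <- cbind(
            .de_values(object, mode, n0 = n0_min, n_genes = n_genes,
                       n_cells = n_cells, seed = ss[2]),
            .de_values(thinned, mode, n0 = n0_min, n_genes = n_genes,
                       n_cells = n_cells, seed = ss[3]))
        de <- wilcoxonDE(vals, groups, alpha = alpha)
        data.frame(mode = mode, n_significant = sum(de$significant),
                   n_genes = nrow(de),
                   fraction = mean(de$significant))
    })
    do.call(rbind, out)
}
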