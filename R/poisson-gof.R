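#' Density-dependent subsampling of cells
#'
#' Samples \code{n_target} distinct cells with selection probability
#' proportional to \eqn{1/d(\log_{10} n_c)}, where \eqn{d} is a Gaussian
#' kernel density estimate (Silverman bandwidth) of the log10 depths of all
#' cells. Cells from sparsely populated depth regimes are over-represented,
#' so a small subsample still spans the full depth range of the dataset.
#'
#' @param object a \linkS4class{CountMatrix}; all depths must be positive.
#' @param n_target number of cells to keep (at most \code{ncol(object)}).
#' @param seed optional integer seed; when \code{NULL} the current RNG
#'   stream is used.
#' @return the subsampled \linkS4class{CountMatrix}.
#' @export
densitySubsampleCells <- function(object, n_target, seed = NULL) {
    stopifnot(is(object, "CountMatrix"))
    n <- depths(object)
    if (any(n <= 0))
        stop("all cells must have positive depth (log10 undefined at 0)")
    if (n_target > ncol(object))
        stop("n_target (", n_target, ") exceeds number of cells (",
             ncol(object), ")")
    if (n_target == ncol(object)) return(object)
    if (!is.null(seed)) set.seed(seed)
    w <- .inverse_density_weights(log10(n))
    keep <- sample.int(ncol(object), n_target, prob = w / sum(w))
    object[, sort(keep)]
}

#' Intercept of the offset Poisson GLM
#'
#' Maximum-likelihood intercept of the intercept-only Poisson GLM with log
#' link and offset \eqn{\ln n_c}; closed form
#' \eqn{\hat\beta = \ln(\sum_c x_c / \sum_c n_c)}. Fitted means are
#' \eqn{\mu_c = n_c e^{\hat\beta}}.
#'
#' @param x per-cell counts of one gene (must not be all zero).
#' @param depths per-cell total UMI (positive).
#' @return the intercept on the natural-log scale.
#' @examples
#' poissonOffsetIntercept(c(1, 2), c(100, 200))  # log(3/300)
#' @export
poissonOffsetIntercept <- function(x, depths) {
    if (sum(x) <= 0)
        stop("gene has zero total count; the offset GLM intercept is undefined")
    if (any(depths <= 0)) stop("depths must be positive")
    log(sum(x) / sum(depths))
}

#' Randomized quantile (Dunn-Smyth) residuals for Poisson fits
#'
#' For each observation draws \eqn{u_c} uniformly on
#' \eqn{(F(x_c - 1; \mu_c),\ F(x_c; \mu_c)]}, with \eqn{F} the Poisson CDF
#' and \eqn{F(-1) = 0}, and returns \eqn{\Phi^{-1}(u_c)}. Under a correctly
#' specified model the residuals are exactly standard normal, which makes
#' them suitable for a chi-squared goodness-of-fit test. Draws are clamped
#' away from 0 and 1 by machine epsilon so the normal quantile stays finite.
#'
#' @param x integer counts (vector or matrix).
#' @param mu fitted Poisson means, same shape as \code{x}, finite and
#'   positive.
#' @param seed optional integer seed making the draw reproducible.
#' @return residuals with the shape of \code{x}.
#' @references Dunn & Smyth (1996) Randomized quantile residuals,
#'   J. Comput. Graph. Stat. 5:236-244.
#' @export
randomizedQuantileResiduals <- function(x, mu, seed = NULL) {
    if (any(!is.finite(mu)) || any(mu <= 0))
        stop("fitted means must be finite and positive")
    if (!is.null(seed)) set.seed(seed)
    a <- ppois(x - 1, mu)
    b <- ppois(x, mu)
    u <- a + runif(length(x)) * (b - a)
    eps <- .Machine$double.eps
    u <- pmin(pmax(u, eps), 1 - eps)
    r <- qnorm(u)
    if (is.matrix(x)) dim(r) <- dim(x)
    r
}

#' Chi-squared goodness-of-fit test on quantile residuals
#'
#' The sum of squared quantile residuals of a well-specified model follows
#' a chi-squared distribution; following standard practice for this test
#' the degrees of freedom are taken as \eqn{N_{cells} - 1}. The p-value is
#' the upper tail probability.
#'
#' @param residuals finite residual vector.
#' @param n_cells number of cells (defaults to \code{length(residuals)};
#'   must be at least 2).
#' @return list with \code{statistic}, \code{dof} and \code{p_value}.
#' @export
gofTest <- function(residuals, n_cells = length(residuals)) {
    if (n_cells < 2) stop("goodness-of-fit test requires at least 2 cells")
    if (any(!is.finite(residuals))) stop("residuals must be finite")
    stat <- sum(residuals^2)
    list(statistic = stat, dof = n_cells - 1,
         p_value = pchisq(stat, df = n_cells - 1, lower.tail = FALSE))
}

#' Fraction of overdispersed genes per abundance bin
#'
#' Groups genes into half-open abundance bins \eqn{(lo, hi]} and reports
#' the fraction flagged overdispersed in each. Genes with mean at or below
#' the lowest edge are excluded. Default edges reproduce the standard
#' abundance-bin layout (0.001, 0.01, 0.1, 1, 5, 10, Inf).
#'
#' @param overdispersed logical per-gene verdicts.
#' @param means per-gene arithmetic mean abundance.
#' @param bin_edges ascending numeric bin edges.
#' @return data.frame with columns \code{bin}, \code{n_genes},
#'   \code{fraction}.
#' @export
overdispersionByBin <- function(overdispersed, means,
                                bin_edges = c(0.001, 0.01, 0.1, 1, 5, 10,
                                              Inf)) {
    stopifnot(length(overdispersed) == length(means),
              !is.unsorted(bin_edges, strictly = TRUE))
    keep <- means > bin_edges[1]
    bins <- cut(means[keep], breaks = bin_edges, right = TRUE)
    frac <- tapply(overdispersed[keep], bins, mean)
    n <- tapply(rep(1, sum(keep)), bins, sum)
    data.frame(bin = levels(bins),
               n_genes = as.integer(ifelse(is.na(n), 0, n)),
               fraction = as.numeric(frac), row.names = NULL)
}

#' Per-gene Poisson goodness-of-fit testing
#'
#' For every gene with at least one count, fits the intercept-only Poisson
#' GLM with library-size offset (closed form, see
#' \code{\link{poissonOffsetIntercept}}), computes randomized quantile
#' residuals, and tests the sum of squared residuals against a chi-squared
#' distribution with \eqn{N_{cells} - 1} degrees of freedom. P-values are
#' converted to Storey q-values and genes with \eqn{q} below
#' \code{q_threshold} are flagged overdispersed.
#'
#' Optionally the matrix is first reduced to \code{n_cells} cells by
#' density-dependent subsampling of the log10 depth distribution, which
#' bounds the computational cost on large datasets while retaining cells
#' across the whole depth range.
#'
#' @param object a \linkS4class{CountMatrix} with positive depths.
#' @param n_cells optional number of cells to subsample before testing.
#' @param q_threshold q-value threshold for the overdispersion verdict
#'   (default 0.01).
#' @param seed optional integer seed governing subsampling and the
#'   randomized residual draws.
#' @param bin_edges abundance bin edges passed to
#'   \code{\link{overdispersionByBin}} labels.
#' @return data.frame with one row per tested gene: \code{gene},
#'   \code{mean}, \code{poisson_intercept}, \code{statistic}, \code{dof},
#'   \code{p_value}, \code{q_value}, \code{overdispersed},
#'   \code{abundance_bin}.
#' @examples
#' spec <- simulationSpec(gene_means = rep(2, 50), theta = Inf,
#'                        n_cells = 100, seed = 1)
#' res <- poissonGofTest(simulateCounts(spec), seed = 1)
#' mean(res$overdispersed)  # Poisson data: close to 0
#' @export
poissonGofTest <- function(object, n_cells = NULL, q_threshold = 0.01,
                           seed = NULL,
                           bin_edges = c(0.001, 0.01, 0.1, 1, 5, 10, Inf)) {
    stopifnot(is(object, "CountMatrix"))
    if (!is.null(seed)) set.seed(seed)
    if (!is.null(n_cells) && n_cells < ncol(object))
        object <- densitySubsampleCells(object, n_cells, seed = NULL)
    n <- depths(object)
    if (any(n <= 0)) stop("all cells must have positive depth")
    x <- as.matrix(object@counts)
    rs <- rowSums(x)
    tested <- rs > 0
    x <- x[tested, , drop = FALSE]
    beta <- log(rs[tested] / sum(n))
    mu <- exp(beta) %o% n
    r <- randomizedQuantileResiduals(x, mu, seed = NULL)
    stat <- rowSums(r^2)
    dof <- ncol(x) - 1
    p <- pchisq(stat, df = dof, lower.tail = FALSE)
    q <- storeyQValues(p)
    means <- rs[tested] / ncol(x)
    bins <- cut(means, breaks = bin_edges, right = TRUE)
    data.frame(gene = geneIDs(object)[tested], mean = means,
               poisson_intercept = beta, statistic = stat, dof = dof,
               p_value = p, q_value = q,
               overdispersed = q < q_threshold,
               abundance_bin = as.character(bins), row.names = NULL)
}
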