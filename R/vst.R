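#' Density-dependent selection of estimation genes
#'
#' Samples genes for individual parameter estimation with probability
#' proportional to the inverse density of their \eqn{\log_{10}} geometric
#' mean abundance, so that sparsely populated abundance regimes are still
#' represented in the estimation set. Only estimable genes are considered:
#' variance exceeding the mean, arithmetic mean at least
#' \code{mean_floor}, and a positive geometric mean. If no more than
#' \code{n_genes} genes are estimable, all of them are returned.
#'
#' @param summaries output of \code{\link{geneSummaries}}.
#' @param n_genes number of genes to select (default 2000).
#' @param seed optional integer seed.
#' @param mean_floor minimum arithmetic mean (default 0.001, matching the
#'   abundance cutoff below which genes are treated as Poisson).
#' @return character vector of selected gene identifiers.
#' @export
selectEstimationGenes <- function(summaries, n_genes = 2000, seed = NULL,
                                  mean_floor = 0.001) {
    est <- summaries$variance > summaries$mean &
        summaries$mean >= mean_floor & summaries$gmean > 0
    ids <- summaries$gene[est]
    if (length(ids) <= n_genes) return(ids)
    if (!is.null(seed)) set.seed(seed)
    w <- .inverse_density_weights(log10(summaries$gmean[est]))
    ids[sort(sample.int(length(ids), n_genes, prob = w / sum(w)))]
}

#' Uniform subsampling of estimation cells
#'
#' Parameter estimation is robust to learning from a few thousand cells,
#' so large datasets are fitted on a uniform random cell subsample.
#'
#' @param object a \linkS4class{CountMatrix}.
#' @param n_cells number of cells to keep; when at least the total number
#'   of cells the input is returned unchanged.
#' @param seed optional integer seed.
#' @return a \linkS4class{CountMatrix} with \code{n_cells} columns.
#' @export
selectEstimationCells <- function(object, n_cells = 2000, seed = NULL) {
    stopifnot(is(object, "CountMatrix"))
    if (n_cells >= ncol(object)) return(object)
    if (!is.null(seed)) set.seed(seed)
    object[, sort(sample.int(ncol(object), n_cells))]
}

#' Regularize per-gene NB parameters across the abundance spectrum
#'
#' Pools individual gene fits by kernel regression against
#' \eqn{\log_{10}} geometric mean abundance: a Nadaraya-Watson Gaussian
#' smoother of \eqn{\ln\theta} (and of the intercept; under v1 also the
#' slope) is learned from the usable fits and evaluated at every gene of
#' the dataset, yielding regularized parameters for all genes. A first-pass
#' smooth is used to drop fits whose \eqn{\ln\theta} studentized residual
#' exceeds 4 before the final smooth, preventing single outlier genes from
#' bending the curve.
#'
#' Under v2 the slope is fixed at \eqn{\ln(10)} for all genes, and genes
#' with very low abundance (arithmetic mean < 0.001) or without evidence of
#' overdispersion (\eqn{\sigma^2 \le \mu}) are excluded from regularization:
#' they receive \eqn{\theta = \infty} and the analytic Poisson intercept
#' \eqn{\ln(\sum_c x_{gc}) - \ln(\sum_c n_c)}.
#'
#' @param fits data.frame from \code{\link{fitDispersionModels}} for the
#'   estimation gene subset.
#' @param summaries \code{\link{geneSummaries}} of the full dataset (all
#'   genes; supplies the smoothing covariate and exclusion statistics).
#' @param depths per-cell depths of the full dataset (defines
#'   \eqn{\sum_c n_c} for analytic intercepts and the reference depth
#'   \code{n0}).
#' @param mode \code{"v2"} (fixed slope, exclusion rules) or \code{"v1"}
#'   (slope smoothed like the other parameters).
#' @param bandwidth optional kernel bandwidth on the \eqn{\log_{10}} gmean
#'   scale; default 3 times a Sheather-Jones plug-in estimate of the
#'   covariate density bandwidth.
#' @param min_fits minimum number of usable fits (default 10).
#' @return a \linkS4class{ModelParameters} covering every gene in
#'   \code{summaries}.
#' @export
regularizeParameters <- function(fits, summaries, depths,
                                 mode = c("v2", "v1"), bandwidth = NULL,
                                 min_fits = 10L) {
    mode <- match.arg(mode)
    usable <- fits$excluded_reason == "none" & fits$converged &
        is.finite(fits$theta) & is.finite(fits$intercept)
    gm_fit <- summaries$gmean[match(fits$gene, summaries$gene)]
    usable <- usable & !is.na(gm_fit) & gm_fit > 0
    if (sum(usable) < min_fits)
        stop("only ", sum(usable), " usable fits; at least ", min_fits,
             " are required for regularization")
    xf <- log10(gm_fit[usable])
    lt <- log(fits$theta[usable])
    if (is.null(bandwidth)) {
        bandwidth <- 3 * tryCatch(bw.SJ(xf), error = function(e) bw.nrd0(xf))
    }

    # First pass: drop ln(theta) outliers, then refit. The reference is a
    # robust local median with local MAD studentization, so that genuinely
    # variable genes (locally stark outliers with spuriously low theta)
    # are flagged even where they are numerous enough to drag a kernel
    # mean, and even though the global ln(theta) scatter is much wider at
    # low abundance.
    # iterated: each pass removes the starkest outliers, cleaning the
    # local scale estimate for the next, until no further fit is dropped
    keep <- rep(TRUE, length(xf))
    for (pass in 1:5) {
        lm <- .local_median_mad(xf[keep], lt[keep], bandwidth)
        drop_now <- abs(lt[keep] - lm$center) > 4 * lm$scale
        if (!any(drop_now)) break
        keep[keep] <- !drop_now
    }
    xk <- xf[keep]; ltk <- lt[keep]

    # The raw intercept is a steep near-linear function of log10 abundance
    # (slope ~ ln 10), for which kernel averaging has severe boundary bias.
    # The intercept is therefore regularized as its offset from the
    # per-gene analytic Poisson intercept ln(sum x) - ln(sum n), which is
    # flat in abundance; the analytic part is added back exactly.
    pois0_all <- log(summaries$mean * length(depths)) - log(sum(depths))
    pois0_fit <- pois0_all[match(fits$gene, summaries$gene)]
    dk <- (fits$intercept[usable] - pois0_fit[usable])[keep]

    x_all <- log10(pmax(summaries$gmean, .Machine$double.xmin))
    theta_all <- exp(.ksmooth_gauss(xk, ltk, x_all, bandwidth))
    intercept_all <- pois0_all + .ksmooth_gauss(xk, dk, x_all, bandwidth)
    slope_all <- if (mode == "v2") rep(log(10), nrow(summaries))
        else .ksmooth_gauss(xk, fits$slope[usable][keep], x_all, bandwidth)

    flag <- rep("regularized", nrow(summaries))
    flag[summaries$gene %in% fits$gene[usable][keep]] <- "estimated"

    if (mode == "v2") {
        excl <- summaries$mean < 0.001 | summaries$variance <= summaries$mean
        theta_all[excl] <- Inf
        # analytic Poisson intercept: ln(sum_c x) - ln(sum_c n)
        total <- summaries$mean * length(depths)
        intercept_all[excl] <- log(total[excl]) - log(sum(depths))
        flag[excl] <- "poisson_fixed"
    }

    grid <- seq(min(xk), max(xk), length.out = 200)
    new("ModelParameters",
        gene_ids = summaries$gene, mean = summaries$mean,
        gmean = summaries$gmean, intercept = intercept_all,
        slope = slope_all, theta = theta_all, flag = flag, mode = mode,
        theta_curve = data.frame(
            log10_gmean = grid,
            log_theta = .ksmooth_gauss(xk, ltk, grid, bandwidth)),
        n0 = median(depths), bandwidth = bandwidth)
}

#' Fixed-theta comparison model
#'
#' Assigns the same inverse overdispersion \eqn{\theta} to every gene
#' (\code{Inf} gives the pure Poisson model), with the slope fixed at
#' \eqn{\ln(10)} and the analytic Poisson intercept
#' \eqn{\ln(\sum_c x_{gc}) - \ln(\sum_c n_c)}, which does not depend on
#' \eqn{\theta}. Used to study the variance-stabilization behavior of
#' one-size-fits-all parameterizations such as \eqn{\theta \in \{\infty,
#' 100, 10\}}.
#'
#' @param object a \linkS4class{CountMatrix}.
#' @param theta positive scalar or \code{Inf}.
#' @return a \linkS4class{ModelParameters} with mode \code{"fixed_theta"}.
#' @export
fixedThetaModel <- function(object, theta) {
    stopifnot(is(object, "CountMatrix"))
    if (length(theta) != 1 || is.na(theta) || theta <= 0)
        stop("theta must be a positive scalar or Inf")
    sm <- geneSummaries(object)
    n <- depths(object)
    intercept <- log(sm$mean * ncol(object)) - log(sum(n))
    th <- rep(theta, nrow(sm))
    new("ModelParameters",
        gene_ids = sm$gene, mean = sm$mean, gmean = sm$gmean,
        intercept = intercept, slope = rep(log(10), nrow(sm)), theta = th,
        flag = rep(if (is.infinite(theta)) "poisson_fixed" else "fixed",
                   nrow(sm)),
        mode = "fixed_theta",
        theta_curve = data.frame(log10_gmean = numeric(0),
                                 log_theta = numeric(0)),
        n0 = median(n), bandwidth = NA_real_)
}

.min_variance_value <- function(object, min_variance) {
    if (identical(min_variance, "auto"))
        (.nz_median_dataset(object@counts) / 5)^2
    else if (identical(min_variance, "none")) 0
    else if (is.numeric(min_variance) && length(min_variance) == 1 &&
             min_variance >= 0) min_variance
    else stop("min_variance must be 'auto', 'none' or a non-negative scalar")
}

.clip_bounds <- function(clip, n_cells) {
    if (identical(clip, "none")) c(-Inf, Inf)
    else if (identical(clip, "sqrt_n")) c(-1, 1) * sqrt(n_cells)
    else if (is.numeric(clip) && length(clip) == 1 && clip > 0)
        c(-clip, clip)
    else stop("clip must be 'none', 'sqrt_n' or a positive scalar")
}

# Expected means and floored standard deviations under a parameter set,
# for arbitrary per-cell depths. Returns list(mu, sigma).
.model_moments <- function(params, idx, n, min_var) {
    mu <- exp(outer(params@slope[idx], log10(n)) + params@intercept[idx])
    sigma2 <- mu + mu^2 / params@theta[idx]
    list(mu = mu, sigma = sqrt(pmax(sigma2, min_var)))
}

#' Pearson residuals under a regularized NB model
#'
#' Computes \eqn{Z_{gc} = (x_{gc} - \mu_{gc})/\sigma_{gc}} with
#' \eqn{\mu_{gc} = \exp(\beta_{g0} + \beta_{g1}\log_{10} n_c)} (equal to
#' \eqn{\exp(\beta_{g0} + \ln n_c)} under the fixed \eqn{\ln(10)} slope)
#' and \eqn{\sigma_{gc} = \sqrt{\mu_{gc} + \mu_{gc}^2/\theta_g}};
#' \eqn{\theta = \infty} gives the classical Poisson residual
#' \eqn{\sigma = \sqrt\mu}.
#'
#' With \code{min_variance = "auto"} the standard deviation is floored at
#' nzmedian/5, where nzmedian is the dataset-wide median of non-zero
#' counts. On typical UMI data nzmedian is 1 UMI, so a cell carrying a
#' single detected molecule of an extremely low-abundance gene cannot
#' receive a residual above 5; without the floor such cells dominate the
#' residual variance ranking.
#'
#' @param object a \linkS4class{CountMatrix} with positive depths.
#' @param params a \linkS4class{ModelParameters} covering all genes of
#'   \code{object}.
#' @param min_variance \code{"auto"} (floor variance at (nzmedian/5)^2),
#'   \code{"none"}, or a non-negative scalar variance floor.
#' @param clip \code{"none"}, \code{"sqrt_n"} (clip residuals to plus or
#'   minus the square root of the cell count, useful before PCA), or a
#'   positive scalar bound.
#' @return a \linkS4class{ResidualMatrix}.
#' @examples
#' # x = 10, mu = 4, theta = 4: Z = 6 / sqrt(4 + 16/4) = 2.12132
#' @export
pearsonResiduals <- function(object, params, min_variance = "auto",
                             clip = "none") {
    stopifnot(is(object, "CountMatrix"), is(params, "ModelParameters"))
    idx <- match(geneIDs(object), params@gene_ids)
    if (anyNA(idx))
        stop("parameters missing for ", sum(is.na(idx)), " gene(s), e.g. ",
             head(geneIDs(object)[is.na(idx)], 1))
    n <- depths(object)
    if (any(n <= 0)) stop("all cells must have positive depth")
    min_var <- .min_variance_value(object, min_variance)
    mm <- .model_moments(params, idx, n, min_var)
    z <- (as.matrix(object@counts) - mm$mu) / mm$sigma
    z[mm$sigma == 0] <- 0  # all-zero gene under mu = 0 without a floor
    bounds <- .clip_bounds(clip, ncol(object))
    if (is.finite(bounds[2])) z <- pmin(pmax(z, bounds[1]), bounds[2])
    dimnames(z) <- dimnames(object@counts)
    new("ResidualMatrix", residuals = z,
        residual_variance = setNames(.row_vars_dense(z), rownames(z)),
        clip_range = bounds, min_sd = sqrt(min_var))
}

#' Rank genes by residual variance
#'
#' Returns the \code{k} genes with the largest residual variance, the
#' variable-gene ranking used for downstream dimensional reduction. Ties
#' are broken in favor of the higher geometric mean, then lexicographic
#' gene identifier.
#'
#' @param variances named per-gene residual variances, or a
#'   \linkS4class{ResidualMatrix}.
#' @param k number of genes to return (at most the number of genes).
#' @param gmean optional per-gene geometric means for tie breaking, in the
#'   order of \code{variances}.
#' @return character vector of \code{k} gene identifiers, most variable
#'   first.
#' @export
selectVariableGenes <- function(variances, k, gmean = NULL) {
    if (is(variances, "ResidualMatrix"))
        variances <- residualVariance(variances)
    ids <- names(variances)
    if (is.null(ids)) ids <- as.character(seq_along(variances))
    if (k > length(variances))
        stop("k exceeds the number of genes")
    if (is.null(gmean)) gmean <- rep(0, length(variances))
    ord <- order(-variances, -gmean, ids)
    ids[ord][seq_len(k)]
}

#' Depth-corrected counts
#'
#' Re-expresses the observed counts as if every cell had been sequenced to
#' the same reference depth \eqn{n_0}: Pearson residuals are computed at
#' the native depths and inverted under the model evaluated at \eqn{n_0},
#' \eqn{y_{gc} = \lfloor Z_{gc}\,\sigma_g(n_0) + \mu_g(n_0) \rfloor},
#' clamped below at 0. The same variance floor is used in both directions
#' so that equal-depth input at \eqn{n_0} is reproduced exactly. A tiny
#' epsilon guards the floor operation against values representing an
#' integer from just below it in floating point.
#'
#' @param object a \linkS4class{CountMatrix}.
#' @param params a \linkS4class{ModelParameters} covering all genes.
#' @param n0 \code{"median"} (median depth of \code{object}) or a positive
#'   scalar reference depth; across datasets normalized independently, use
#'   the minimum of the two median depths.
#' @param min_variance,clip as in \code{\link{pearsonResiduals}}.
#' @return a \linkS4class{CountMatrix} of corrected counts.
#' @export
correctedCounts <- function(object, params, n0 = "median",
                            min_variance = "auto", clip = "none") {
    stopifnot(is(object, "CountMatrix"), is(params, "ModelParameters"))
    n0v <- if (identical(n0, "median")) median(depths(object)) else n0
    if (!is.numeric(n0v) || length(n0v) != 1 || n0v <= 0)
        stop("n0 must be 'median' or a positive scalar")
    res <- pearsonResiduals(object, params, min_variance, clip)
    idx <- match(geneIDs(object), params@gene_ids)
    min_var <- .min_variance_value(object, min_variance)
    mu0 <- exp(params@intercept[idx] + params@slope[idx] * log10(n0v))
    sigma0 <- sqrt(pmax(mu0 + mu0^2 / params@theta[idx], min_var))
    y <- floor(res@residuals * sigma0 + mu0 + 1e-6)
    y <- pmax(y, 0)
    y[!is.finite(y)] <- 0
    CountMatrix(y, gene_ids = geneIDs(object), cell_ids = cellIDs(object))
}

#' Regularized NB variance-stabilizing transformation
#'
#' The full pipeline: per-gene summary statistics, density-dependent
#' selection of up to \code{n_genes} estimation genes, uniform subsampling
#' of \code{n_cells} estimation cells, individual NB fits (offset model
#' under v2, free-slope model under v1), kernel regularization of the
#' parameters across the abundance spectrum, and Pearson residuals with
#' the minimum-variance clamp for every gene and cell of the input.
#'
#' @param object a \linkS4class{CountMatrix}.
#' @param mode \code{"v2"} (fixed \eqn{\ln(10)} slope, exclusion rules) or
#'   \code{"v1"} (free slope, all parameters smoothed).
#' @param n_genes,n_cells estimation subset sizes (defaults 2000 each).
#' @param seed optional integer seed; gene and cell sampling derive
#'   independent sub-seeds from it.
#' @param bandwidth optional smoothing bandwidth, see
#'   \code{\link{regularizeParameters}}.
#' @param min_variance,clip residual options, see
#'   \code{\link{pearsonResiduals}}.
#' @param return_corrected also compute depth-corrected counts at the
#'   median depth.
#' @return list with elements \code{params}
#'   (\linkS4class{ModelParameters}), \code{residuals}
#'   (\linkS4class{ResidualMatrix}), \code{gene_attributes} (data.frame
#'   with summary statistics and residual variance per gene), and
#'   optionally \code{corrected} (\linkS4class{CountMatrix}).
#' @examples
#' spec <- simulationSpec(gene_means = 10^runif(80, -1, 1), theta = 10,
#'                        n_cells = 300, seed = 7)
#' fit <- vst(simulateCounts(spec), seed = 7)
#' median(fit$gene_attributes$residual_variance)
#' @export
vst <- function(object, mode = c("v2", "v1"), n_genes = 2000,
                n_cells = 2000, seed = NULL, bandwidth = NULL,
                min_variance = "auto", clip = "none",
                return_corrected = FALSE) {
    stopifnot(is(object, "CountMatrix"))
    mode <- match.arg(mode)
    ss <- .sub_seeds(seed, 2)
    sm <- geneSummaries(object)
    cells <- selectEstimationCells(object, n_cells, seed = ss[1])
    genes <- selectEstimationGenes(sm, n_genes, seed = ss[2])
    if (length(genes) == 0)
        stop("no estimable genes (variance > mean and mean >= 0.001)")
    fits <- fitDispersionModels(cells, genes = genes,
                                model = if (mode == "v2") "offset"
                                        else "free_slope")
    params <- regularizeParameters(fits, sm, depths(object), mode = mode,
                                   bandwidth = bandwidth)
    res <- pearsonResiduals(object, params, min_variance, clip)
    out <- list(
        params = params, residuals = res,
        gene_attributes = cbind(sm,
            residual_variance = as.numeric(res@residual_variance)))
    if (return_corrected)
        out$corrected <- correctedCounts(object, params, "median",
                                         min_variance, clip)
    out
}
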