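#' @import methods
#' @importFrom Matrix Matrix sparseMatrix readMM writeMM drop0 t colSums rowSums rowMeans
#' @importFrom stats density approx bw.SJ bw.nrd0 dnbinom dpois ppois pchisq pnorm
#'   qnorm quantile rbinom rlnorm rnbinom rpois runif median var sd cor p.adjust
#'   loess predict smooth.spline setNames fitted mad
#' @importFrom utils head read.delim write.table
NULL

#' UMI count matrix
#'
#' An S4 container for a genes x cells matrix of unique molecular identifier
#' (UMI) counts. Genes are rows and cells are columns, following the Matrix
#' Market convention used by droplet-based platforms. All entries must be
#' non-negative integers, and row and column names (gene and cell
#' identifiers) must be present and unique. Per-cell sequencing depths
#' \eqn{n_c = \sum_g x_{gc}} are derived from the counts via
#' \code{\link{depths}} rather than stored, so they can never fall out of
#' sync with the matrix.
#'
#' @slot counts a \code{\link[Matrix]{dgCMatrix-class}} of UMI counts.
#'
#' @seealso \code{\link{CountMatrix}} (constructor), \code{\link{readCounts}},
#'   \code{\link{geneSummaries}}, \code{\link{qcFilterCells}}
#' @export
setClass("CountMatrix", representation(counts = "dgCMatrix"))

setValidity("CountMatrix", function(object) {
    x <- object@counts
    msg <- character()
    if (length(x@x)) {
        if (any(x@x < 0))
            msg <- c(msg, "counts contain negative entries")
        if (any(x@x != round(x@x)))
            msg <- c(msg, "counts contain non-integer entries")
    }
    gid <- rownames(x); cid <- colnames(x)
    if ((nrow(x) > 0 && is.null(gid)) || (ncol(x) > 0 && is.null(cid)))
        msg <- c(msg, "gene and cell identifiers must be set as dimnames")
    if (!is.null(gid) && anyDuplicated(gid))
        msg <- c(msg, "gene identifiers are not unique")
    if (!is.null(cid) && anyDuplicated(cid))
        msg <- c(msg, "cell identifiers are not unique")
    if (length(msg)) msg else TRUE
})

#' Fitted and regularized GLM parameters for every gene
#'
#' Holds one (intercept, slope, theta) triple per gene of a count matrix,
#' together with a provenance flag, the smoothed log-theta curve used for
#' regularization, and the reference depth \code{n0} used when inverting the
#' model into corrected counts. Under the v2 parameterization the slope is
#' fixed at \eqn{\ln(10)} for every gene (the predictor is
#' \eqn{\log_{10} n_c}, so the slope times the predictor equals the
#' \eqn{\ln n_c} library-size offset), genes excluded from regularization
#' carry \eqn{\theta = \infty} and the analytic Poisson intercept
#' \eqn{\ln(\sum_c x_{gc}) - \ln(\sum_c n_c)}.
#'
#' @slot gene_ids character, one entry per gene.
#' @slot mean,gmean per-gene arithmetic and geometric mean abundance.
#' @slot intercept,slope,theta per-gene GLM parameters; \code{theta} may be
#'   \code{Inf} (Poisson regime).
#' @slot flag provenance: \code{"estimated"} (gene contributed a usable
#'   individual fit), \code{"regularized"} (parameters obtained purely from
#'   the smoothed curves), \code{"poisson_fixed"} (excluded from
#'   regularization, Poisson parameters), or \code{"fixed"} (fixed-theta
#'   comparison model).
#' @slot mode one of \code{"v1"}, \code{"v2"}, \code{"fixed_theta"}.
#' @slot theta_curve data.frame with columns \code{log10_gmean} and
#'   \code{log_theta}: the smoothed curve evaluated on a grid (empty for
#'   fixed-theta models).
#' @slot n0 reference sequencing depth (median depth of the fitted data).
#' @slot bandwidth kernel bandwidth used for smoothing (NA for fixed models).
#'
#' @seealso \code{\link{regularizeParameters}}, \code{\link{fixedThetaModel}},
#'   \code{\link{pearsonResiduals}}, \code{\link{correctedCounts}}
#' @export
setClass("ModelParameters", representation(
    gene_ids = "character",
    mean = "numeric",
    gmean = "numeric",
    intercept = "numeric",
    slope = "numeric",
    theta = "numeric",
    flag = "character",
    mode = "character",
    theta_curve = "data.frame",
    n0 = "numeric",
    bandwidth = "numeric"
))

setValidity("ModelParameters", function(object) {
    n <- length(object@gene_ids)
    msg <- character()
    for (s in c("mean", "gmean", "intercept", "slope", "theta", "flag"))
        if (length(slot(object, s)) != n)
            msg <- c(msg, sprintf("slot '%s' must have one entry per gene", s))
    if (any(object@theta <= 0, na.rm = TRUE))
        msg <- c(msg, "theta must be positive (Inf allowed)")
    if (!object@mode %in% c("v1", "v2", "fixed_theta"))
        msg <- c(msg, "mode must be one of 'v1', 'v2', 'fixed_theta'")
    if (!all(object@flag %in% c("estimated", "regularized", "poisson_fixed", "fixed")))
        msg <- c(msg, "unknown provenance flag")
    if (object@mode == "v2" &&
        any(abs(object@slope - log(10)) > 1e-12))
        msg <- c(msg, "v2 parameterization requires slope == ln(10) for all genes")
    if (object@mode %in% c("v2", "fixed_theta")) {
        pf <- object@flag == "poisson_fixed"
        if (any(is.finite(object@theta[pf])))
            msg <- c(msg, "poisson_fixed genes must have theta == Inf")
    }
    if (length(msg)) msg else TRUE
})

#' Pearson residual matrix
#'
#' Genes x cells matrix of Pearson residuals \eqn{Z_{gc} = (x_{gc} -
#' \mu_{gc})/\sigma_{gc}} under a negative binomial (or Poisson) model, plus
#' the per-gene residual variance and a record of the clipping bound and
#' minimum standard deviation that were applied.
#'
#' @slot residuals dense numeric matrix of residuals with gene/cell dimnames.
#' @slot residual_variance per-gene sample variance of the residuals
#'   (divisor \eqn{C-1}, centered on the arithmetic mean residual).
#' @slot clip_range length-2 numeric; \code{c(-Inf, Inf)} when no clipping.
#' @slot min_sd standard-deviation floor applied (0 when none).
#'
#' @seealso \code{\link{pearsonResiduals}}, \code{\link{residualVariance}}
#' @export
setClass("ResidualMatrix", representation(
    residuals = "matrix",
    residual_variance = "numeric",
    clip_range = "numeric",
    min_sd = "numeric"
))

setValidity("ResidualMatrix", function(object) {
    msg <- character()
    if (length(object@residual_variance) != nrow(object@residuals))
        msg <- c(msg, "residual_variance must have one entry per gene")
    if (any(object@residual_variance < 0, na.rm = TRUE))
        msg <- c(msg, "residual_variance must be non-negative")
    if (length(object@clip_range) != 2 ||
        object@clip_range[1] > object@clip_range[2])
        msg <- c(msg, "clip_range must be an ordered pair")
    if (length(msg)) msg else TRUE
})

#' Specification of a synthetic UMI count experiment
#'
#' Describes a negative binomial (Poisson when \code{theta = Inf}) count
#' simulation: per-gene mean abundances at the reference depth, the inverse
#' overdispersion parameter (scalar or per-gene), the number of cells, a
#' sequencing-depth model, and optional planted cell groups with per-gene
#' fold changes. Cell \eqn{c} of gene \eqn{g} is drawn as
#' \eqn{x_{gc} \sim NB(m_g\, n_c / \bar n,\ \theta_g)} so that gene means are
#' expressed in UMI per cell at the average depth.
#'
#' @slot gene_means positive per-gene means (UMI/cell at reference depth).
#' @slot theta inverse overdispersion; scalar or per-gene, \code{Inf} allowed.
#' @slot n_cells number of cells to simulate.
#' @slot depth_model list with element \code{type}: \code{"equal"} (element
#'   \code{depth}), \code{"lognormal"} (elements \code{meanlog},
#'   \code{sdlog}), or \code{"empirical"} (element \code{depths}).
#' @slot seed integer seed making the simulation reproducible.
#' @slot group_labels factor of length \code{n_cells}, or a length-0 factor
#'   when there are no planted groups.
#' @slot fold_changes genes x groups matrix of positive multipliers applied
#'   to the means of cells in each group (0x0 when unused).
#'
#' @seealso \code{\link{simulationSpec}}, \code{\link{simulateCounts}},
#'   \code{\link{upsampleMeans}}
#' @export
setClass("SimulationSpec", representation(
    gene_means = "numeric",
    theta = "numeric",
    n_cells = "integer",
    depth_model = "list",
    seed = "integer",
    group_labels = "factor",
    fold_changes = "matrix"
))

setValidity("SimulationSpec", function(object) {
    msg <- character()
    if (length(object@gene_means) == 0 || any(object@gene_means <= 0) ||
        any(!is.finite(object@gene_means)))
        msg <- c(msg, "gene_means must be positive and finite")
    if (any(object@theta <= 0, na.rm = TRUE))
        msg <- c(msg, "theta must be positive (Inf allowed)")
    if (!length(object@theta) %in% c(1L, length(object@gene_means)))
        msg <- c(msg, "theta must be a scalar or one value per gene")
    if (object@n_cells < 1L)
        msg <- c(msg, "n_cells must be at least 1")
    dm <- object@depth_model
    if (is.null(dm$type) ||
        !dm$type %in% c("equal", "lognormal", "empirical"))
        msg <- c(msg, "depth_model$type must be 'equal', 'lognormal' or 'empirical'")
    else if (dm$type == "equal" && (is.null(dm$depth) || dm$depth <= 0))
        msg <- c(msg, "equal depth model requires a positive 'depth'")
    else if (dm$type == "lognormal" &&
             (is.null(dm$meanlog) || is.null(dm$sdlog) || dm$sdlog < 0))
        msg <- c(msg, "lognormal depth model requires 'meanlog' and 'sdlog' >= 0")
    else if (dm$type == "empirical" &&
             (is.null(dm$depths) || any(dm$depths <= 0)))
        msg <- c(msg, "empirical depth model requires positive 'depths'")
    if (length(object@group_labels) &&
        length(object@group_labels) != object@n_cells)
        msg <- c(msg, "group_labels must have one entry per cell")
    if (length(object@fold_changes)) {
        if (any(object@fold_changes <= 0))
            msg <- c(msg, "fold_changes must be positive")
        if (nrow(object@fold_changes) != length(object@gene_means))
            msg <- c(msg, "fold_changes must have one row per gene")
        if (length(object@group_labels) &&
            ncol(object@fold_changes) != nlevels(object@group_labels))
            msg <- c(msg, "fold_changes must have one column per group level")
    }
    if (length(msg)) msg else TRUE
})
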