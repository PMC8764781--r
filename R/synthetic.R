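#' Create a simulation specification
#'
#' Validates and bundles the design of a synthetic UMI experiment; see
#' \linkS4class{SimulationSpec} for the model. The default depth model,
#' lognormal with meanlog \eqn{\ln 5000} and sdlog 0.35, mimics the
#' depth spread of a typical droplet-based experiment.
#'
#' @param gene_means positive per-gene means (UMI/cell at the average
#'   depth); names become gene identifiers.
#' @param theta inverse overdispersion, scalar or per-gene; \code{Inf}
#'   simulates Poisson counts.
#' @param n_cells number of cells.
#' @param depth_model list describing the per-cell depth distribution; see
#'   \linkS4class{SimulationSpec}.
#' @param seed integer seed (simulation is bit-reproducible given the
#'   spec).
#' @param group_labels optional per-cell group assignment (anything
#'   coercible to factor).
#' @param fold_changes optional positive per-gene fold changes: a genes x
#'   groups matrix, or with exactly two groups a vector applied to the
#'   second group.
#' @return a \linkS4class{SimulationSpec}.
#' @export
simulationSpec <- function(gene_means, theta = Inf, n_cells,
                           depth_model = list(type = "lognormal",
                                              meanlog = log(5000),
                                              sdlog = 0.35),
                           seed = 1L, group_labels = NULL,
                           fold_changes = NULL) {
    if (is.null(names(gene_means)))
        names(gene_means) <- sprintf("gene%d", seq_along(gene_means))
    labels <- if (is.null(group_labels)) factor() else factor(group_labels)
    if (is.null(fold_changes)) {
        fc <- matrix(numeric(0), 0, 0)
    } else if (is.matrix(fold_changes)) {
        fc <- fold_changes
    } else {
        if (nlevels(labels) != 2)
            stop("a fold-change vector requires exactly two group levels")
        fc <- cbind(rep(1, length(gene_means)), as.numeric(fold_changes))
    }
    new("SimulationSpec", gene_means = gene_means,
        theta = as.numeric(theta), n_cells = as.integer(n_cells),
        depth_model = depth_model, seed = as.integer(seed),
        group_labels = labels, fold_changes = fc)
}

.draw_depths <- function(dm, n_cells) {
    switch(dm$type,
        equal = rep(dm$depth, n_cells),
        lognormal = rlnorm(n_cells, meanlog = dm$meanlog, sdlog = dm$sdlog),
        empirical = {
            d <- dm$depths
            if (length(d) == n_cells) d
            else sample(d, n_cells, replace = TRUE)
        })
}

#' Simulate UMI counts with fixed overdispersion
#'
#' Draws \eqn{x_{gc} \sim NB(m_g n_c / \bar n, \theta_g)} independently
#' (Poisson for \eqn{\theta = \infty}), with per-cell depth factors
#' \eqn{n_c} from the spec's depth model and planted-group fold changes
#' multiplying the means of labeled cells. The output is bit-reproducible
#' for a given spec.
#'
#' @param spec a \linkS4class{SimulationSpec}.
#' @return a \linkS4class{CountMatrix}.
#' @export
simulateCounts <- function(spec) {
    stopifnot(is(spec, "SimulationSpec"))
    validObject(spec)
    set.seed(spec@seed)
    G <- length(spec@gene_means)
    C <- spec@n_cells
    n <- .draw_depths(spec@depth_model, C)
    mu <- spec@gene_means %o% (n / mean(n))
    if (length(spec@group_labels) && length(spec@fold_changes))
        mu <- mu * spec@fold_changes[, as.integer(spec@group_labels),
                                     drop = FALSE]
    theta <- rep_len(spec@theta, G)
    x <- matrix(0L, G, C)
    pois <- is.infinite(theta)
    if (any(pois))
        x[pois, ] <- rpois(sum(pois) * C, lambda = mu[pois, ])
    if (any(!pois))
        x[!pois, ] <- rnbinom(sum(!pois) * C, mu = mu[!pois, ],
                              size = theta[!pois])
    rownames(x) <- names(spec@gene_means)
    colnames(x) <- sprintf("cell%d", seq_len(C))
    CountMatrix(x)
}

#' Simulate counts from a fitted parameter set
#'
#' Draws \eqn{x_{gc} \sim NB(\mu_{gc}, \theta_g)} with
#' \eqn{\mu_{gc} = \exp(\beta_{g0} + \beta_{g1}\log_{10} n_c)} for given
#' per-cell depths, i.e., data for which the parameter set is the correctly
#' specified model. Used to verify that Pearson residuals under the fitted
#' model have unit variance.
#'
#' @param params a \linkS4class{ModelParameters}.
#' @param depths per-cell depths at which to evaluate the model.
#' @param seed optional integer seed.
#' @return a \linkS4class{CountMatrix}.
#' @export
simulateFromModel <- function(params, depths, seed = NULL) {
    stopifnot(is(params, "ModelParameters"), all(depths > 0))
    if (!is.null(seed)) set.seed(seed)
    G <- length(params@gene_ids)
    C <- length(depths)
    mu <- exp(outer(params@slope, log10(depths)) + params@intercept)
    mu[!is.finite(mu)] <- 0
    theta <- rep_len(params@theta, G)
    x <- matrix(0L, G, C)
    pois <- is.infinite(theta)
    if (any(pois)) x[pois, ] <- rpois(sum(pois) * C, lambda = mu[pois, ])
    if (any(!pois)) x[!pois, ] <- rnbinom(sum(!pois) * C,
                                          mu = mu[!pois, ],
                                          size = theta[!pois])
    rownames(x) <- params@gene_ids
    colnames(x) <- sprintf("cell%d", seq_len(C))
    CountMatrix(x)
}

#' Renormalize intercepts to a depth-consistent scale
#'
#' Shifts all intercepts by a common constant so that
#' \eqn{\sum_g e^{\beta_{g0}} = 1}, i.e., so that the expected column sum
#' of counts simulated from the model at depth \eqn{n_c} is \eqn{n_c}
#' itself. Because the model conditions on the observed depth, a global
#' intercept shift is only a change of depth units and leaves residuals
#' and corrected counts invariant; the renormalized form is needed when
#' simulating from a fitted model (\code{\link{simulateFromModel}}), where
#' the realized depths of the simulation must reproduce the depths that
#' parameterize it.
#'
#' @param params a \linkS4class{ModelParameters}.
#' @return the renormalized \linkS4class{ModelParameters}.
#' @export
renormalizeIntercepts <- function(params) {
    stopifnot(is(params, "ModelParameters"))
    s <- sum(exp(params@intercept), na.rm = TRUE)
    if (!is.finite(s) || s <= 0)
        stop("intercepts do not define a positive total expression mass")
    params@intercept <- params@intercept - log(s)
    params
}

#' Binomial thinning of a count matrix
#'
#' Replaces each count by a Binomial(x, prop) draw, emulating a reduction
#' of sequencing depth to a fraction \code{prop} of the original: thinning
#' a Poisson matrix yields Poisson counts at the thinned rate, and the
#' expected total depth is \code{prop} times the original.
#'
#' @param object a \linkS4class{CountMatrix}.
#' @param prop retention probability in (0, 1]; with \code{per_cell =
#'   TRUE}, one probability per cell.
#' @param seed optional integer seed.
#' @param per_cell interpret \code{prop} as a per-cell vector.
#' @return the thinned \linkS4class{CountMatrix}.
#' @export
thinCounts <- function(object, prop, seed = NULL, per_cell = FALSE) {
    stopifnot(is(object, "CountMatrix"))
    if (per_cell) {
        if (length(prop) != ncol(object))
            stop("per_cell thinning requires one prop per cell")
    } else if (length(prop) != 1) {
        stop("prop must be a scalar (or set per_cell = TRUE)")
    }
    if (any(prop <= 0 | prop > 1)) stop("prop must lie in (0, 1]")
    if (all(prop == 1)) return(object)
    if (!is.null(seed)) set.seed(seed)
    x <- object@counts
    if (length(x@x)) {
        p_entry <- if (per_cell) {
            ci <- rep(seq_len(ncol(x)), diff(x@p))
            prop[ci]
        } else rep(prop, length(x@x))
        x@x <- as.double(rbinom(length(x@x), size = as.integer(round(x@x)),
                                prob = p_entry))
        x <- drop0(x)
    }
    new("CountMatrix", counts = x)
}

#' Downsample cells to a common target depth
#'
#' Emulates re-sequencing every cell to (approximately) the same depth:
#' cells with depth below 99% of the target are removed, the remaining
#' cells are binomially thinned at a single rate expected to yield the
#' target on average (target over the median remaining depth), and cells
#' whose thinned depth falls outside \code{target +/- tolerance} are
#' dropped.
#'
#' @param object a \linkS4class{CountMatrix}.
#' @param target desired UMI/cell.
#' @param tolerance retained band half-width in UMI (default 100).
#' @param seed optional integer seed.
#' @return a \linkS4class{CountMatrix} whose depths all lie within the
#'   band.
#' @export
downsampleToDepth <- function(object, target, tolerance = 100,
                              seed = NULL) {
    stopifnot(is(object, "CountMatrix"), target > 0, tolerance >= 0)
    if (!is.null(seed)) set.seed(seed)
    n <- depths(object)
    keep <- n >= 0.99 * target
    if (!any(keep))
        stop("no cells reach 99% of the target depth")
    sub <- object[, keep]
    rate <- min(target / median(depths(sub)), 1)
    thinned <- thinCounts(sub, rate, seed = NULL)
    n2 <- depths(thinned)
    band <- n2 >= target - tolerance & n2 <= target + tolerance
    if (!any(band))
        stop("no cells landed inside the target depth band")
    thinned[, band]
}

#' Pool cells into metacells
#'
#' Sums the UMI counts of all cells sharing a label into one pooled
#' pseudo-cell per label, increasing the effective sequencing depth while
#' conserving the total UMI count. Constructing the labels (i.e., grouping
#' transcriptionally similar cells) is up to the caller.
#'
#' @param object a \linkS4class{CountMatrix}.
#' @param labels per-cell group identifiers (coercible to factor).
#' @return a \linkS4class{CountMatrix} with one column per label level.
#' @export
poolMetacells <- function(object, labels) {
    stopifnot(is(object, "CountMatrix"))
    labels <- factor(labels)
    if (length(labels) != ncol(object))
        stop("labels must have one entry per cell")
    ind <- sparseMatrix(i = seq_along(labels), j = as.integer(labels),
                        x = 1, dims = c(length(labels), nlevels(labels)))
    pooled <- object@counts %*% ind
    colnames(pooled) <- levels(labels)
    CountMatrix(pooled, gene_ids = geneIDs(object))
}

#' Scale the gene means of a simulation spec
#'
#' Returns the spec with all gene means multiplied by \code{factor}
#' (default 500), the "upsampling" device used to show that the downward
#' bias of \eqn{\theta} estimates at low means is a sampling-depth
#' artifact: re-simulating at 500-fold larger means removes it.
#'
#' @param spec a \linkS4class{SimulationSpec}.
#' @param factor positive scale factor.
#' @return the modified \linkS4class{SimulationSpec}.
#' @export
upsampleMeans <- function(spec, factor = 500) {
    stopifnot(is(spec, "SimulationSpec"), factor > 0)
    spec@gene_means <- spec@gene_means * factor
    validObject(spec)
    spec
}
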